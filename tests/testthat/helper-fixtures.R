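# Shared fixtures, all generated in code.

# the published three-skill Q-matrix shape: three single-attribute items
# plus one two-attribute item
study_qmatrix <- function() {
  qmatrix(rbind(c(1, 0, 0), c(0, 1, 0), c(1, 0, 0), c(1, 0, 1)),
          items = paste0("item_", 1:4),
          attributes = c("Idea", "Structure", "Integration"))
}

# profile distribution with only four populated profiles (000,001,101,111)
study_profile_probs <- function() c(.139, .127, 0, 0, 0, .063, 0, .671)

# small planted 4-topic corpus used by STM/selection tests
planted_corpus <- local({
  cache <- list()
  function(seed = 1, n = 400, V = 120, mulen = 90) {
    key <- paste(seed, n, V, mulen)
    if (!is.null(cache[[key]])) return(cache[[key]])
    cfg <- default_sim_config(seed = seed, n_examinees = n)
    beta <- masterytopics:::default_topic_word_dists(4, V)
    profiles <- simulate_profiles(n, cfg$profile_probs, seed)
    corp <- simulate_corpus(profiles, cfg$prevalence_coefs,
                            cfg$prevalence_cov, beta,
                            list(name = "nbinom", mu = mulen, size = 3,
                                 min = 15), seed)
    X <- cbind(1, profiles)
    colnames(X) <- c("(Intercept)", "Idea", "Structure", "Integration")
    out <- list(counts = corp$counts, theta = corp$theta, X = X,
                beta_true = beta, config = cfg)
    cache[[key]] <<- out
    out
  }
})

# align fitted topics to true topics by cosine similarity of beta rows
match_topics <- function(beta_fit, beta_true) {
  nb <- function(m) m / sqrt(rowSums(m^2))
  cs <- nb(beta_fit) %*% t(nb(beta_true))
  perm <- apply(cs, 2, which.max)      # fitted topic for each true topic
  list(perm = perm, cosines = cs[cbind(perm, seq_len(ncol(cs)))],
       unique = length(unique(perm)) == ncol(cs))
}

# minimal hand-built lcdm object for classification readoff tests
fake_lcdm <- function(posterior, structural_probs) {
  S <- as.integer(round(log2(ncol(posterior))))
  profiles <- all_profiles(S)
  rownames(posterior) <- paste0("ex", seq_len(nrow(posterior)))
  colnames(posterior) <- rownames(profiles)
  structure(list(posterior = posterior,
                 structural_probs = structural_probs,
                 profiles = profiles,
                 converged = TRUE),
            class = "lcdm")
}

# independent brute-force implementations of the selection metrics, used
# as oracles on toy instances
brute_coherence <- function(beta_row, present, M) {
  top <- order(-beta_row, seq_along(beta_row))[seq_len(M)]
  total <- 0
  if (M >= 2) for (i in 2:M) for (j in seq_len(i - 1)) {
    Dij <- sum(present[, top[i]] & present[, top[j]])
    Dj <- sum(present[, top[j]])
    total <- total + log((Dij + 1) / Dj)
  }
  total
}

brute_frex <- function(beta, k, w = 0.7) {
  share <- beta[k, ] / colSums(beta)
  ex <- ecdf(share)(share)
  fr <- ecdf(beta[k, ])(beta[k, ])
  1 / (w / ex + (1 - w) / fr)
}

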