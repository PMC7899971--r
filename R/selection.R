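# Topic-number selection metrics: semantic coherence, FREX-style
# exclusivity, and mean pairwise cosine similarity between topic-word
# distributions, plus the K-search that fits a model per candidate K.

#' Semantic coherence of fitted topics
#'
#' For each topic's top-M words (by beta), the score is
#' sum over pairs (i > j) of log((D(v_i, v_j) + 1) / D(v_j)), where
#' D(v, w) counts documents containing both words and D(w) documents
#' containing w.  Scores are always <= 0 (within the +1 smoothing); higher
#' (closer to 0) means the topic's words co-occur more.
#'
#' @param beta K x V topic-word matrix (or an `stm_fit`).
#' @param dtm the document-term counts the model was fit on (a
#'   [build_dtm()] result or a plain matrix with matching columns).
#' @param M number of top words (default 10).
#' @return Numeric vector, one score per topic.
#' @export
semantic_coherence <- function(beta, dtm, M = 10L) {
  if (inherits(beta, "stm_fit")) beta <- beta$beta
  counts <- if (inherits(dtm, "dtm_counts")) dtm$counts else dtm
  stopifnot(M >= 1, ncol(beta) == ncol(counts))
  present <- as.matrix(counts > 0) * 1
  vapply(seq_len(nrow(beta)), function(k) {
    top <- order(-beta[k, ], seq_len(ncol(beta)))[seq_len(min(M, ncol(beta)))]
    sc <- 0
    for (i in seq_along(top)[-1]) for (j in seq_len(i - 1)) {
      Dij <- sum(present[, top[i]] * present[, top[j]])
      Dj <- sum(present[, top[j]])
      sc <- sc + log((Dij + 1) / Dj)
    }
    sc
  }, numeric(1))
}

#' FREX-style exclusivity of fitted topics
#'
#' Per word and topic, exclusivity is the column-normalized share
#' beta_kv / sum_k' beta_k'v.  Within each topic, both the exclusivity
#' shares and the frequencies beta_kv are converted to empirical-CDF ranks
#' over the vocabulary and combined harmonically with weight `frex_w` on
#' exclusivity.  A topic's score is the mean FREX value of its top-M words
#' by beta.
#'
#' @param beta K x V topic-word matrix (or an `stm_fit`); K >= 2.
#' @param M number of top words (default 10).
#' @param frex_w weight on exclusivity (default 0.7).
#' @return Numeric vector, one score per topic.
#' @export
exclusivity <- function(beta, M = 10L, frex_w = 0.7) {
  if (inherits(beta, "stm_fit")) beta <- beta$beta
  K <- nrow(beta)
  if (K < 2) stop("exclusivity is undefined for a single topic")
  share <- sweep(beta, 2, colSums(beta), "/")
  vapply(seq_len(K), function(k) {
    ex_rank <- stats::ecdf(share[k, ])(share[k, ])
    fr_rank <- stats::ecdf(beta[k, ])(beta[k, ])
    frex <- 1 / (frex_w / ex_rank + (1 - frex_w) / fr_rank)
    top <- order(-beta[k, ], seq_len(ncol(beta)))[seq_len(min(M, ncol(beta)))]
    mean(frex[top])
  }, numeric(1))
}

#' Mean pairwise cosine similarity between topics
#'
#' Mean over all unordered topic pairs of the cosine between rows of beta.
#' Lower values indicate more distinct topics.
#'
#' @param beta K x V topic-word matrix (or an `stm_fit`); K >= 2.
#' @return List with `mean` and `max` over pairs.
#' @export
mean_pairwise_cosine <- function(beta) {
  if (inherits(beta, "stm_fit")) beta <- beta$beta
  K <- nrow(beta)
  if (K < 2) stop("cosine similarity needs at least 2 topics")
  nb <- beta / sqrt(rowSums(beta^2))
  cs <- tcrossprod(nb)
  vals <- cs[upper.tri(cs)]
  list(mean = mean(vals), max = max(vals))
}

#' Search over candidate topic counts
#'
#' Fits one STM per K on the same data, design and settings, and tabulates
#' mean semantic coherence, mean exclusivity and mean pairwise cosine
#' similarity per K.  No winner is selected automatically: the table flags
#' "upper-right" candidates -- models on the coherence/exclusivity Pareto
#' front -- and among those the cosine minimizer, mirroring the practice of
#' picking a front model with the most distinct topics.
#'
#' @param dtm a [build_dtm()] result or counts matrix.
#' @param design prevalence design (or NULL for intercept only).
#' @param k_min,k_max candidate range (defaults 2 and 20).
#' @param seed integer seed (same seed used for every K).
#' @param M,frex_w metric settings, see [semantic_coherence()] and
#'   [exclusivity()].
#' @param ... further arguments to [fit_stm()] (e.g. `max_iter`, `tol`).
#' @return Object of class `selection_table`: data frame with one row per
#'   K (coherence, exclusivity, cosine_mean, cosine_max, converged,
#'   pareto, pick flags), with the fitted models in attribute `"fits"`.
#' @export
search_k <- function(dtm, design = NULL, k_min = 2L, k_max = 20L,
                     seed = 1L, M = 10L, frex_w = 0.7, ...) {
  stopifnot(k_min >= 2, k_max >= k_min)
  ks <- seq.int(k_min, k_max)
  rows <- vector("list", length(ks))
  fits <- vector("list", length(ks))
  for (i in seq_along(ks)) {
    K <- ks[i]
    res <- tryCatch({
      fit <- fit_stm(dtm, design, K = K, seed = seed, ...)
      fits[[i]] <- fit
      cos <- mean_pairwise_cosine(fit$beta)
      data.frame(K = K,
                 coherence = mean(semantic_coherence(fit$beta, dtm, M)),
                 exclusivity = mean(exclusivity(fit$beta, M, frex_w)),
                 cosine_mean = cos$mean, cosine_max = cos$max,
                 converged = fit$converged, error = NA_character_)
    }, error = function(e)
      data.frame(K = K, coherence = NA_real_, exclusivity = NA_real_,
                 cosine_mean = NA_real_, cosine_max = NA_real_,
                 converged = FALSE, error = conditionMessage(e)))
    rows[[i]] <- res
  }
  tab <- do.call(rbind, rows)
  tab$pareto <- pareto_front(tab$coherence, tab$exclusivity)
  tab$pick <- FALSE
  cand <- which(tab$pareto & is.finite(tab$cosine_mean))
  if (length(cand))
    tab$pick[cand[which.min(tab$cosine_mean[cand])]] <- TRUE
  attr(tab, "fits") <- fits
  class(tab) <- c("selection_table", "data.frame")
  tab
}

# TRUE for points not dominated in (higher x, higher y)
pareto_front <- function(x, y) {
  n <- length(x)
  out <- logical(n)
  for (i in seq_len(n)) {
    if (!is.finite(x[i]) || !is.finite(y[i])) next
    dominated <- any(x >= x[i] & y >= y[i] & (x > x[i] | y > y[i]),
                     na.rm = TRUE)
    out[i] <- !dominated
  }
  out
}

#' @exportS3Method base::print
print.selection_table <- function(x, ...) {
  cat("Topic-count search (coherence/exclusivity/cosine):\n")
  df <- as.data.frame(x)[, c("K", "coherence", "exclusivity",
                             "cosine_mean", "converged", "pareto", "pick")]
  df$coherence <- round(df$coherence, 2)
  df$exclusivity <- round(df$exclusivity, 3)
  df$cosine_mean <- round(df$cosine_mean, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Coherence-exclusivity scatter of a K search
#'
#' @param x a [search_k()] table.
#' @param ... passed to [graphics::plot()].
#' @export
plot.selection_table <- function(x, ...) {
  graphics::plot(x$coherence, x$exclusivity, type = "n",
                 xlab = "semantic coherence", ylab = "exclusivity", ...)
  graphics::text(x$coherence, x$exclusivity, labels = x$K,
                 col = ifelse(x$pick, "red", "black"))
  invisible(x)
}
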