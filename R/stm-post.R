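#' Covariate effects on topic proportions by the method of composition
#'
#' Propagates posterior uncertainty in the document topic proportions into
#' the covariate-effect regression: per simulation draw, each document's
#' free logits are sampled from its Laplace posterior, mapped to proportions
#' theta, and each topic's theta is regressed on the prevalence design by
#' least squares.  The reported estimate is the mean over draws; the SE
#' combines between-draw variance and the mean within-draw (OLS) variance;
#' t = estimate/SE with df = documents - terms.  Coefficients are on the
#' proportion scale: a coefficient of -0.15 means the expected use of that
#' topic is 0.15 lower for examinees mastering the skill.
#'
#' @param fit an [fit_stm()] result.
#' @param design optional design matrix (defaults to the fit's design).
#' @param n_sims number of composition draws (default 500, minimum 2).
#' @param seed integer seed.
#' @return Object of class `stm_effects`: data frame with columns `topic`,
#'   `term`, `estimate`, `se`, `t`, `p`, plus the per-draw coefficient
#'   array as attribute `"draws"`.
#' @export
estimate_effects <- function(fit, design = NULL, n_sims = 500L, seed = 1L) {
  stopifnot(inherits(fit, "stm_fit"))
  if (n_sims < 2) stop("n_sims must be >= 2 (variance undefined otherwise)")
  X <- if (is.null(design)) fit$design else as.matrix(design)
  D <- nrow(fit$eta); K <- fit$K; Pn <- ncol(X)
  stopifnot(nrow(X) == D)
  if (qr(X)$rank < Pn)
    stop("prevalence design is rank deficient; with modal covariates this ",
         "happens when fewer distinct profiles occur than attribute terms ",
         "- consider EAP covariates")
  set.seed(as.integer(seed) %% .Machine$integer.max)
  Km1 <- K - 1L
  # per-document Cholesky factors, flattened for vectorized sampling
  Lmat <- array(0, c(D, Km1, Km1))
  for (d in seq_len(D)) {
    S <- fit$lap_cov[[d]]
    Lmat[d, , ] <- chol((S + t(S)) / 2)
  }
  XtXinv <- solve(crossprod(X))
  hat <- XtXinv %*% t(X)
  est <- array(NA_real_, c(n_sims, Pn, K))
  wvar <- array(NA_real_, c(n_sims, Pn, K))
  dfree <- D - Pn
  for (s in seq_len(n_sims)) {
    Z <- matrix(stats::rnorm(D * Km1), D)
    noise <- matrix(0, D, Km1)
    for (i in seq_len(Km1)) for (j in seq_len(Km1))
      noise[, j] <- noise[, j] + Lmat[, i, j] * Z[, i]   # t(L_d) %*% z_d
    Eta_s <- fit$eta + noise
    Theta_s <- exp(cbind(Eta_s, 0))
    Theta_s <- Theta_s / rowSums(Theta_s)
    B <- hat %*% Theta_s                       # Pn x K coefficients
    res <- Theta_s - X %*% B
    s2 <- colSums(res^2) / dfree               # per topic
    est[s, , ] <- B
    wvar[s, , ] <- outer(diag(XtXinv), s2)
  }
  mean_est <- apply(est, c(2, 3), mean)
  between <- apply(est, c(2, 3), stats::var)
  within <- apply(wvar, c(2, 3), mean)
  se <- sqrt(between + within)
  tv <- mean_est / se
  pv <- 2 * stats::pt(-abs(tv), df = dfree)
  out <- do.call(rbind, lapply(seq_len(K), function(k)
    data.frame(topic = colnames(fit$theta)[k],
               term = colnames(X),
               estimate = mean_est[, k],
               se = se[, k], t = tv[, k], p = pv[, k],
               row.names = NULL)))
  attr(out, "draws") <- est
  attr(out, "df") <- dfree
  class(out) <- c("stm_effects", "data.frame")
  out
}

#' @exportS3Method base::print
print.stm_effects <- function(x, ...) {
  cat("Topic-prevalence effects (proportion scale, method of composition)\n")
  df <- as.data.frame(x)
  df$estimate <- round(df$estimate, 3)
  df$se <- round(df$se, 4)
  df$t <- round(df$t, 2)
  df$p <- signif(df$p, 2)
  print(df)
  invisible(x)
}

#' Predicted topic use for a mastery profile
#'
#' Linear prediction from an effect table: per topic, intercept plus the
#' sum of coefficients for mastered skills.  Values outside [0,1] are
#' clipped with a warning.
#'
#' @param effect_table an [estimate_effects()] result (or a data frame with
#'   columns topic, term, estimate).
#' @param profile named vector (or named list) giving 0/1 for every
#'   non-intercept term of the table.
#' @return Named numeric vector of expected topic proportions.
#' @examples
#' # with all coefficients zero the prediction is the intercept column
#' @export
predicted_topic_use <- function(effect_table, profile) {
  df <- as.data.frame(effect_table)
  terms <- setdiff(unique(df$term), "(Intercept)")
  profile <- unlist(profile)
  if (is.null(names(profile)) && length(profile) == length(terms))
    names(profile) <- terms
  missing_terms <- setdiff(terms, names(profile))
  if (length(missing_terms))
    stop("profile must supply a value for: ",
         paste(missing_terms, collapse = ", "))
  unknown <- setdiff(names(profile), terms)
  if (length(unknown))
    stop("unknown term label(s): ", paste(unknown, collapse = ", "))
  topics <- unique(df$topic)
  out <- vapply(topics, function(tp) {
    sub <- df[df$topic == tp, ]
    val <- sub$estimate[sub$term == "(Intercept)"]
    for (tm in terms)
      val <- val + sub$estimate[sub$term == tm] * as.numeric(profile[[tm]])
    val
  }, numeric(1))
  names(out) <- topics
  if (any(out < 0 | out > 1)) {
    warning("predicted topic use outside [0, 1]; clipping")
    out <- pmin(1, pmax(0, out))
  }
  out
}

#' Summarize fitted topics
#'
#' For each topic: the highest-probability words (ties broken by vocabulary
#' order), the documents with the highest topic proportion, and the
#' marginal mean proportion across documents.
#'
#' @param fit an [fit_stm()] result.
#' @param top_n number of top words (default 15).
#' @param top_docs number of representative documents per topic (default 1).
#' @return Object of class `stm_topic_summary`: list with `top_words`
#'   (top_n x K character matrix), `top_documents` (list per topic),
#'   `marginal_theta` (named numeric, sums to 1).
#' @export
summarize_topics <- function(fit, top_n = 15L, top_docs = 1L) {
  stopifnot(inherits(fit, "stm_fit"))
  V <- length(fit$vocabulary)
  if (top_n > V) {
    warning("top_n exceeds vocabulary size; truncating")
    top_n <- V
  }
  words <- vapply(seq_len(fit$K), function(k) {
    ord <- order(-fit$beta[k, ], seq_len(V))   # tie -> vocabulary order
    fit$vocabulary[ord[seq_len(top_n)]]
  }, character(top_n))
  if (is.null(dim(words))) words <- matrix(words, nrow = top_n)
  colnames(words) <- rownames(fit$beta)
  docs <- lapply(seq_len(fit$K), function(k) {
    ord <- order(-fit$theta[, k], seq_len(nrow(fit$theta)))
    fit$doc_ids[ord[seq_len(min(top_docs, length(ord)))]]
  })
  names(docs) <- rownames(fit$beta)
  structure(list(top_words = words, top_documents = docs,
                 marginal_theta = colMeans(fit$theta)),
            class = "stm_topic_summary")
}

#' @exportS3Method base::print
print.stm_topic_summary <- function(x, ...) {
  cat("Top words per topic:\n")
  print(x$top_words)
  cat("\nMarginal mean topic proportions:\n")
  print(round(x$marginal_theta, 3))
  invisible(x)
}

#' Topic use by rubric score
#'
#' Summaries of the per-document topic proportions grouped by rubric score:
#' quartiles (type-7 sample quantiles) and mean per (topic, score) cell.
#' Empty score groups are omitted with a note.
#'
#' @param fit an [fit_stm()] result.
#' @param scores numeric vector of rubric scores aligned with the fit's
#'   documents.
#' @return Data frame: topic, score, n, q25, median, q75, mean.
#' @export
topic_use_by_score <- function(fit, scores) {
  stopifnot(inherits(fit, "stm_fit"))
  if (length(scores) != nrow(fit$theta))
    stop("scores must align with the fitted documents")
  lv <- sort(unique(scores))
  out <- list()
  for (k in seq_len(fit$K)) for (sc in lv) {
    v <- fit$theta[scores == sc, k]
    if (!length(v)) next
    qs <- stats::quantile(v, c(.25, .5, .75), type = 7, names = FALSE)
    out[[length(out) + 1L]] <- data.frame(
      topic = colnames(fit$theta)[k], score = sc, n = length(v),
      q25 = qs[1], median = qs[2], q75 = qs[3], mean = mean(v))
  }
  do.call(rbind, out)
}

#' Boxplot-style display of topic use by score
#'
#' @param x an [fit_stm()] result.
#' @param scores rubric scores aligned with documents (optional; marginal
#'   distribution shown if absent).
#' @param ... passed to [graphics::boxplot()].
#' @export
plot.stm_fit <- function(x, scores = NULL, ...) {
  if (is.null(scores)) {
    graphics::boxplot(as.data.frame(x$theta),
                      ylab = "topic proportion", ...)
  } else {
    K <- x$K
    op <- graphics::par(mfrow = c(1, K))
    on.exit(graphics::par(op))
    for (k in seq_len(K))
      graphics::boxplot(x$theta[, k] ~ scores,
                        xlab = "score", ylab = "proportion",
                        main = colnames(x$theta)[k], ...)
  }
  invisible(x)
}
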