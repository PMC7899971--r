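# Structural topic model with topical-prevalence covariates.
# Inference is the Laplace variational EM used in the STM literature: per
# document, the posterior of the K-1 free topic logits eta is approximated
# by a Gaussian at its mode (Newton optimization with analytic gradient and
# Hessian); the M step updates prevalence coefficients by ridge regression,
# the logit covariance from Laplace covariances plus residual outer
# products, and topic-word distributions from token responsibilities.

#' Map free topic logits to topic proportions
#'
#' Softmax with the last topic as reference (logit fixed at 0), guarded
#' against overflow by max subtraction.
#'
#' @param eta numeric vector of K-1 free logits.
#' @return K-vector summing to 1.
#' @examples
#' softmax_theta(c(0, 0, 0))        # uniform over 4 topics
#' softmax_theta(c(log(2), 0, 0))   # (0.4, 0.2, 0.2, 0.2)
#' @export
softmax_theta <- function(eta) {
  stopifnot(all(is.finite(eta)))
  z <- c(eta, 0)
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

# Per-document collapsed objective: log N(eta; mu, Sigma) + sum_v c_v log
# sum_k theta_k beta_kv (constants in eta dropped).  `beta_d` is K x Vd for
# the words present; cv their counts.
doc_objective <- function(eta, Sinv, mu, beta_d, cv) {
  theta <- softmax_theta(eta)
  s <- drop(crossprod(beta_d, theta))
  -0.5 * drop(crossprod(eta - mu, Sinv %*% (eta - mu))) + sum(cv * log(s))
}

doc_grad_hess <- function(eta, Sinv, mu, beta_d, cv) {
  K <- length(eta) + 1L
  theta <- softmax_theta(eta)
  s <- drop(crossprod(beta_d, theta))            # Vd
  phi <- t(beta_d) * rep(theta, each = length(s))  # Vd x K responsibilities
  phi <- phi / s
  m <- drop(crossprod(phi, cv))                  # expected tokens per topic
  N <- sum(cv)
  g_word <- m - N * theta
  grad <- -Sinv %*% (eta - mu) + g_word[seq_len(K - 1)]
  # word-part Hessian: diag(m) - phi' C phi - N (diag(theta) - theta theta')
  Pc <- crossprod(phi * cv, phi)                 # K x K
  Hw <- diag(m, K) - Pc - N * (diag(theta, K) - tcrossprod(theta))
  nH <- Sinv - Hw[seq_len(K - 1), seq_len(K - 1), drop = FALSE]
  list(grad = drop(grad), nH = nH, theta = theta, phi = phi)
}

#' Variational E step for one document
#'
#' Finds the mode of the Laplace-approximate posterior of the document's
#' free topic logits by damped Newton iteration, then returns the mode, the
#' local Gaussian covariance (inverse negative Hessian), the implied topic
#' proportions and the token-topic responsibilities.
#'
#' @param counts integer vector of word counts over the full vocabulary, or
#'   a sparse row.
#' @param beta K x V topic-word matrix (strictly positive where counts are).
#' @param mu_d prior mean of the K-1 logits for this document.
#' @param Sigma (K-1) x (K-1) prior covariance.
#' @param eta_init optional warm start.
#' @return List `eta_hat`, `lap_cov`, `theta`, `phi` (Vd x K over present
#'   words), `word_idx`, `converged`.
#' @export
e_step_document <- function(counts, beta, mu_d, Sigma, eta_init = NULL) {
  counts <- as.numeric(counts)
  widx <- which(counts > 0)
  cv <- counts[widx]
  beta_d <- beta[, widx, drop = FALSE]
  K <- nrow(beta)
  Sinv <- solve(Sigma)
  eta <- if (is.null(eta_init)) as.numeric(mu_d) else as.numeric(eta_init)
  ok <- FALSE
  f_old <- doc_objective(eta, Sinv, mu_d, beta_d, cv)
  for (it in 1:100) {
    gh <- doc_grad_hess(eta, Sinv, mu_d, beta_d, cv)
    step <- tryCatch(solve(gh$nH, gh$grad), error = function(e) NULL)
    if (is.null(step)) {
      step <- solve(gh$nH + diag(1e-4 + abs(min(eigen(gh$nH,
        symmetric = TRUE, only.values = TRUE)$values)), K - 1), gh$grad)
    }
    # backtracking line search
    lam <- 1
    repeat {
      eta_new <- eta + lam * step
      f_new <- doc_objective(eta_new, Sinv, mu_d, beta_d, cv)
      if (is.finite(f_new) && f_new >= f_old - 1e-12) break
      lam <- lam / 2
      if (lam < 1e-6) { eta_new <- eta; f_new <- f_old; break }
    }
    moved <- sqrt(sum((eta_new - eta)^2))
    eta <- eta_new
    if (abs(f_new - f_old) < 1e-9 * (abs(f_old) + 1) && moved < 1e-7) {
      ok <- TRUE; f_old <- f_new; break
    }
    f_old <- f_new
  }
  if (!ok && is.null(eta_init)) {
    # retry from zero
    alt <- e_step_document(counts, beta, mu_d, Sigma,
                           eta_init = rep(0, K - 1))
    if (alt$converged) return(alt)
  }
  gh <- doc_grad_hess(eta, Sinv, mu_d, beta_d, cv)
  nH <- (gh$nH + t(gh$nH)) / 2
  # posterior precision floored at the prior's smallest precision so the
  # Laplace variance never exceeds the prior scale
  prec_floor <- 1 / max(eigen(Sigma, symmetric = TRUE,
                              only.values = TRUE)$values)
  ev <- eigen(nH, symmetric = TRUE)
  vals <- pmax(ev$values, prec_floor)
  lap_cov <- ev$vectors %*% (t(ev$vectors) / vals)
  lap_cov <- (lap_cov + t(lap_cov)) / 2
  list(eta_hat = eta, lap_cov = lap_cov, theta = gh$theta, phi = gh$phi,
       word_idx = widx, objective = f_old, converged = ok)
}

#' M step of the STM EM
#'
#' Updates prevalence coefficients gamma by ridge-penalized least squares of
#' the posterior logit modes on the design (penalty 1/sigma2, intercept
#' included in the penalty; the default prior variance is diffuse so the
#' penalty is numerically negligible), the logit covariance Sigma as the
#' mean of Laplace covariances plus residual outer products, and beta from
#' phi-weighted token counts with an additive 1/V pseudocount.
#'
#' @param posteriors list of [e_step_document()] results.
#' @param X document x term design matrix (first column ones).
#' @param counts document x vocabulary counts.
#' @param sigma2 prior variance of the prevalence coefficients (default 25).
#' @return List `gamma`, `Sigma`, `beta`.
#' @export
m_step <- function(posteriors, X, counts, sigma2 = 25) {
  D <- length(posteriors)
  stopifnot(D >= 1, nrow(X) == D)
  K <- length(posteriors[[1]]$theta)
  V <- ncol(counts)
  Eta <- matrix(vapply(posteriors, function(p) p$eta_hat, numeric(K - 1)),
                ncol = K - 1, byrow = TRUE)
  XtX <- crossprod(X)
  qrX <- qr(XtX)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qr(X)$pivot[-seq_len(qr(X)$rank)]]
    stop("prevalence design is rank deficient (collinear terms: ",
         paste(bad, collapse = ", "), ")")
  }
  A <- XtX + diag(1 / sigma2, ncol(X))
  gamma <- solve(A, crossprod(X, Eta))
  resid <- Eta - X %*% gamma
  Sig <- Reduce(`+`, lapply(posteriors, function(p) p$lap_cov)) / D +
    crossprod(resid) / D
  Sig <- (Sig + t(Sig)) / 2 + diag(1e-10, K - 1)

  beta_num <- matrix(1 / V, K, V)
  for (d in seq_len(D)) {
    p <- posteriors[[d]]
    cv <- as.numeric(counts[d, p$word_idx])
    beta_num[, p$word_idx] <- beta_num[, p$word_idx] + t(p$phi * cv)
  }
  beta <- beta_num / rowSums(beta_num)
  dimnames(gamma) <- list(colnames(X), NULL)
  list(gamma = gamma, Sigma = Sig, beta = beta)
}

# Vectorized Laplace E step over all documents at once.  Each global
# Newton sweep updates every document's free logits with a damped Newton
# step (per-document 3x3-ish solves; all word-sum quantities computed as
# D x V matrix operations).  Returns modes, Laplace covariances, objective
# values, topic proportions and the count/likelihood ratio matrix R used
# by the multiplicative beta update.
estep_all <- function(counts, beta, Mu, Sigma, Eta, max_newton = 8L) {
  D <- nrow(counts); V <- ncol(counts)
  K <- nrow(beta); Km1 <- K - 1L
  N <- rowSums(counts)
  Sinv <- solve(Sigma)
  pair_i <- rep(seq_len(K), times = K)
  pair_j <- rep(seq_len(K), each = K)
  obj_all <- function(Eta) {
    Theta <- exp(cbind(Eta, 0))
    Theta <- Theta / rowSums(Theta)
    S <- Theta %*% beta + 1e-300
    Dev <- Eta - Mu
    prior <- -0.5 * rowSums((Dev %*% Sinv) * Dev)
    list(Theta = Theta, S = S,
         f = prior + rowSums(counts * log(S)))
  }
  # guard against overflow in exp: recentre rows whose max logit exceeds 30
  center <- function(Eta) {
    rmax <- Eta[, 1]
    if (Km1 > 1) for (k in 2:Km1) rmax <- pmax(rmax, Eta[, k])
    hot <- which(rmax > 30)
    if (length(hot)) Eta[hot, ] <- Eta[hot, , drop = FALSE] - (rmax[hot] - 30)
    Eta
  }
  Eta <- center(Eta)
  o <- obj_all(Eta)
  active <- rep(TRUE, D)
  nH_store <- array(0, c(Km1, Km1, D))
  for (sweep in seq_len(max_newton)) {
    Theta <- o$Theta; S <- o$S
    R <- counts / S
    M <- (R %*% t(beta)) * Theta               # D x K expected tokens
    Gw <- M - N * Theta
    Grad <- -(Eta - Mu) %*% Sinv + Gw[, seq_len(Km1), drop = FALSE]
    gn <- sqrt(rowSums(Grad^2))
    active <- gn > 1e-6
    W <- R / S                                 # counts / S^2
    # per-pair quadratic sums: Q[d, (k,l)] = sum_v c W beta_k beta_l
    BB <- beta[pair_i, , drop = FALSE] * beta[pair_j, , drop = FALSE]
    Q <- W %*% t(BB)                           # D x K^2
    upd <- which(active)
    if (!length(upd)) break
    Step <- matrix(0, D, Km1)
    for (d in upd) {
      th <- Theta[d, ]
      P <- th[pair_i] * th[pair_j] * Q[d, ]
      dim(P) <- c(K, K)
      Hw <- diag(M[d, ], K) - P - N[d] * (diag(th, K) - tcrossprod(th))
      nH <- Sinv - Hw[seq_len(Km1), seq_len(Km1), drop = FALSE]
      st <- tryCatch(solve(nH, Grad[d, ]), error = function(e) NULL)
      if (is.null(st)) {
        ev <- eigen(nH, symmetric = TRUE)
        st <- ev$vectors %*% ((t(ev$vectors) %*% Grad[d, ]) /
                                pmax(ev$values, 1e-6))
      }
      Step[d, ] <- st
      nH_store[, , d] <- nH
    }
    # vectorized backtracking: halve steps only where the objective drops
    lam <- as.numeric(active)
    f_old <- o$f
    for (bt in 1:30) {
      Eta_new <- center(Eta + lam * Step)
      o_new <- obj_all(Eta_new)
      bad <- active & (!is.finite(o_new$f) | o_new$f < f_old - 1e-10)
      if (!any(bad)) break
      lam[bad] <- lam[bad] / 2
      lam[lam < 1e-7] <- 0
    }
    Eta <- center(Eta + lam * Step)
    o <- obj_all(Eta)
    if (max(abs(o$f - f_old)) < 1e-6) break
  }
  # final Hessians and Laplace covariances at the modes
  Theta <- o$Theta; S <- o$S
  R <- counts / S
  M <- (R %*% t(beta)) * Theta
  W <- R / S
  BB <- beta[pair_i, , drop = FALSE] * beta[pair_j, , drop = FALSE]
  Q <- W %*% t(BB)
  lap_cov <- vector("list", D)
  logdet_cov <- numeric(D)
  mean_lap <- matrix(0, Km1, Km1)
  # posterior variance cannot exceed the prior scale (exact when the word
  # log-likelihood is concave); flooring the precision there keeps a
  # degenerate document from blowing up the Sigma update
  prec_floor <- 1 / max(eigen(Sigma, symmetric = TRUE,
                              only.values = TRUE)$values)
  for (d in seq_len(D)) {
    th <- Theta[d, ]
    P <- th[pair_i] * th[pair_j] * Q[d, ]
    dim(P) <- c(K, K)
    Hw <- diag(M[d, ], K) - P - N[d] * (diag(th, K) - tcrossprod(th))
    nH <- Sinv - Hw[seq_len(Km1), seq_len(Km1), drop = FALSE]
    nH <- (nH + t(nH)) / 2
    ev <- eigen(nH, symmetric = TRUE)
    vals <- pmax(ev$values, prec_floor)
    cv <- ev$vectors %*% (t(ev$vectors) / vals)
    cv <- (cv + t(cv)) / 2
    lap_cov[[d]] <- cv
    logdet_cov[d] <- -sum(log(vals))
    mean_lap <- mean_lap + cv
  }
  list(Eta = Eta, Theta = Theta, R = R, objective = o$f,
       lap_cov = lap_cov, logdet_cov = logdet_cov,
       mean_lap_cov = mean_lap / D)
}

#' Fit a structural topic model
#'
#' Alternates the per-document Laplace E step and the global M step until
#' the relative change of the approximate objective (the sum of per-document
#' Laplace bounds) falls below `tol` or `max_iter` is reached.  The fit is
#' deterministic given the seed, which controls the random initialization
#' of the topic-word distributions.
#'
#' @param dtm a [build_dtm()] result, or a plain documents x vocabulary
#'   count matrix.
#' @param design a prevalence design: documents x terms numeric matrix with
#'   leading intercept column (see [join_covariates()]), or NULL for
#'   intercept only.
#' @param K number of topics (>= 2).
#' @param max_iter maximum EM iterations (default 500).
#' @param tol relative convergence tolerance on the approximate objective
#'   (default 1e-5).
#' @param sigma2 prevalence-coefficient prior variance (default 25).
#' @param init `"random"` (default) initializes the topic-word
#'   distributions with seeded frequency-scaled gamma noise; `"kmeans"`
#'   seeds them from a k-means clustering of length-normalized documents.
#' @param n_restarts number of independently initialized runs; the run
#'   with the highest final approximate objective is returned (the usual
#'   guard against local optima in mixture models).  Default 1.
#' @param seed integer seed for the initialization; restart r uses
#'   `seed + 10000 * (r - 1)`.
#' @param verbose print progress?
#' @return Object of class `stm_fit`: `beta` (K x V), `gamma`, `Sigma`,
#'   `eta` (D x K-1 modes), `theta` (D x K), `lap_cov` (list),
#'   `bound_trace`, `converged`, `iterations`, `vocabulary`, `doc_ids`,
#'   `design`, `K`, `seed`.
#' @export
fit_stm <- function(dtm, design = NULL, K, max_iter = 500L, tol = 1e-5,
                    sigma2 = 25, init = c("random", "kmeans"),
                    n_restarts = 1L, seed = 1L, verbose = FALSE) {
  init <- match.arg(init)
  if (n_restarts > 1L) {
    fits <- lapply(seq_len(n_restarts), function(r)
      fit_stm(dtm, design, K, max_iter = max_iter, tol = tol,
              sigma2 = sigma2, init = init, n_restarts = 1L,
              seed = seed + 10000L * (r - 1L), verbose = verbose))
    bounds <- vapply(fits, function(f)
      f$bound_trace[f$iterations], numeric(1))
    return(fits[[which.max(bounds)]])
  }
  counts <- if (inherits(dtm, "dtm_counts")) dtm$counts else dtm
  counts <- as.matrix(counts)
  vocab <- colnames(counts)
  if (is.null(vocab)) vocab <- paste0("w", seq_len(ncol(counts)))
  doc_ids <- rownames(counts)
  if (is.null(doc_ids)) doc_ids <- paste0("d", seq_len(nrow(counts)))
  D <- nrow(counts); V <- ncol(counts)
  if (K < 2) stop("K must be >= 2")
  if (K > D) warning("more topics than documents requested")
  if (is.null(design)) design <- matrix(1, D, 1,
                                        dimnames = list(NULL, "(Intercept)"))
  design <- as.matrix(design)
  if (nrow(design) != D) stop("design rows must match dtm documents")
  if (any(design[, 1] != 1)) stop("first design column must be an intercept")

  set.seed(as.integer(seed) %% .Machine$integer.max)
  beta <- NULL
  if (init == "kmeans" && D > K) {
    tf <- counts / pmax(rowSums(counts), 1)
    km <- tryCatch(stats::kmeans(tf, centers = K, nstart = 5,
                                 iter.max = 30),
                   error = function(e) NULL)
    if (!is.null(km)) {
      beta <- t(vapply(seq_len(K), function(k) {
        rows <- which(km$cluster == k)
        colSums(counts[rows, , drop = FALSE]) + 1
      }, numeric(V)))
      beta <- beta / rowSums(beta)
    }
  }
  if (is.null(beta)) {
    # seeded random init: corpus frequencies times gamma noise per topic
    wfreq <- colSums(counts) + 0.1
    beta <- t(vapply(seq_len(K), function(k)
      wfreq * stats::rgamma(V, shape = 2, rate = 2), numeric(V)))
    beta <- beta / rowSums(beta)
  }
  gamma <- matrix(0, ncol(design), K - 1,
                  dimnames = list(colnames(design), NULL))
  Sigma <- diag(1, K - 1)
  Eta <- matrix(0, D, K - 1)

  A <- crossprod(design) + diag(1 / sigma2, ncol(design))
  Ainv_Xt <- solve(A, t(design))

  bound_trace <- numeric(0)
  converged <- FALSE
  es <- NULL
  for (iter in seq_len(max_iter)) {
    Mu <- design %*% gamma
    es <- estep_all(counts, beta, Mu, Sigma, Eta)
    Eta <- es$Eta
    ldS <- determinant(Sigma, logarithm = TRUE)$modulus
    bound <- sum(es$objective) - 0.5 * D * ldS + 0.5 * sum(es$logdet_cov)
    bound_trace <- c(bound_trace, as.numeric(bound))

    # M step (same estimators as m_step(), vectorized)
    gamma <- Ainv_Xt %*% Eta
    dimnames(gamma) <- list(colnames(design), NULL)
    resid <- Eta - design %*% gamma
    Sigma <- es$mean_lap_cov + crossprod(resid) / D
    Sigma <- (Sigma + t(Sigma)) / 2 + diag(1e-10, K - 1)
    beta_num <- beta * t(crossprod(es$R, es$Theta)) + 1 / V
    beta <- beta_num / rowSums(beta_num)

    if (verbose) message("iter ", iter, " bound ", format(bound))
    if (iter >= 2) {
      prev <- bound_trace[iter - 1]
      if (abs(bound - prev) < tol * (abs(prev) + 1e-10)) {
        converged <- TRUE
        break
      }
    }
    if (is.infinite(tol)) { converged <- TRUE; break }
  }
  theta <- es$Theta
  dimnames(beta) <- list(paste0("topic_", seq_len(K)), vocab)
  colnames(theta) <- rownames(beta)
  rownames(theta) <- doc_ids

  structure(list(
    beta = beta, gamma = gamma, Sigma = Sigma,
    eta = Eta, theta = theta,
    lap_cov = es$lap_cov,
    bound_trace = bound_trace,
    converged = converged,
    iterations = length(bound_trace),
    vocabulary = vocab, doc_ids = doc_ids,
    design = design, K = K, sigma2 = sigma2, seed = seed
  ), class = "stm_fit")
}

#' @exportS3Method base::print
print.stm_fit <- function(x, ...) {
  cat("Structural topic model:", x$K, "topics,",
      length(x$doc_ids), "documents,", length(x$vocabulary), "word types\n")
  cat("prevalence terms:", paste(colnames(x$design), collapse = ", "), "\n")
  cat(if (x$converged) "converged" else "NOT converged",
      "after", x$iterations, "EM iterations\n")
  cat("marginal mean topic proportions:",
      paste(sprintf("%.3f", colMeans(x$theta)), collapse = " "), "\n")
  invisible(x)
}

#' @export
coef.stm_fit <- function(object, ...) object$gamma

#' @export
logLik.stm_fit <- function(object, ...) {
  structure(object$bound_trace[object$iterations],
            df = NA_integer_, class = "logLik")
}
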