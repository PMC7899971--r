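#' LCDM item response probability
#'
#' The log-linear cognitive diagnosis model (LCDM) gives the probability of a
#' correct response as a logistic function of an intercept plus effect terms
#' determined by the item's Q-matrix row:
#' \deqn{P(Y_{ij}=1 \mid \alpha_i) =
#'   \mathrm{logit}^{-1}\left(\lambda_{j0} +
#'   \sum_t \lambda_{jt} \prod_{s \in t} \alpha_{is}\right)}
#' where each term \eqn{t} is a set of attributes (singletons are main
#' effects, pairs two-way interactions).
#'
#' @param profile binary attribute vector (or matrix of profiles in rows).
#' @param item_params list with components `intercept` (scalar) and `coef`
#'   (numeric, one value per effect term, possibly length 0).
#' @param effect_terms list of integer vectors of attribute indices, as one
#'   element of [build_effect_structure()].
#' @return Probability (vector if `profile` is a matrix), strictly in (0,1).
#' @examples
#' # single-attribute item: non-master vs master
#' p <- list(intercept = -0.613, coef = 1.557)
#' item_response_probability(c(0), p, list(1L))  # ~0.351
#' item_response_probability(c(1), p, list(1L))  # ~0.720
#' @export
item_response_probability <- function(profile, item_params, effect_terms) {
  if (is.null(dim(profile))) profile <- matrix(profile, nrow = 1)
  need <- if (length(effect_terms)) max(unlist(effect_terms)) else 1L
  if (ncol(profile) < need)
    stop("profile length does not cover all attributes in the effect terms")
  X <- effect_design(profile, effect_terms)
  eta <- item_params$intercept +
    if (ncol(X)) drop(X %*% item_params$coef) else 0
  stats::plogis(eta)
}

# Item-by-profile response probability matrix (J x P).
item_profile_probs <- function(item_params, effect_structure, profiles) {
  t(vapply(seq_along(item_params), function(j)
    item_response_probability(profiles, item_params[[j]],
                              effect_structure[[j]]),
    numeric(nrow(profiles))))
}

# Pack/unpack item parameters to a flat vector (intercept first).
pack_item <- function(p) c(p$intercept, p$coef)
unpack_item <- function(v) list(intercept = v[1],
                                coef = if (length(v) > 1) v[-1] else numeric(0))

# Monotonicity constraint matrix for one item: rows u with u %*% lambda >= 0.
# Every conditional increment from gaining one attribute must be >= 0; for
# terms up to order 2 this reduces to: each main effect >= 0 and, for every
# interaction {s,u}, main_s + inter >= 0 and main_u + inter >= 0.
monotonicity_constraints <- function(terms) {
  np <- length(terms) + 1L
  rows <- list()
  main_idx <- function(s) which(vapply(terms, identical, logical(1), y = s)) + 1L
  for (i in seq_along(terms)) {
    t <- terms[[i]]
    if (length(t) == 1L) {
      r <- numeric(np); r[i + 1L] <- 1; rows[[length(rows) + 1L]] <- r
    } else if (length(t) == 2L) {
      for (s in t) {
        r <- numeric(np); r[i + 1L] <- 1
        mi <- main_idx(s)
        if (length(mi)) r[mi] <- 1
        rows[[length(rows) + 1L]] <- r
      }
    } else {
      # higher-order: require the term itself plus all contained mains >= 0
      r <- numeric(np); r[i + 1L] <- 1
      for (s in t) { mi <- main_idx(s); if (length(mi)) r[mi] <- 1 }
      rows[[length(rows) + 1L]] <- r
    }
  }
  if (length(rows)) do.call(rbind, rows) else matrix(0, 0, np)
}

# Weighted Bernoulli negative log-likelihood for one item over profiles,
# with a weak ridge penalty that keeps boundary items finite.
item_negll <- function(v, X1, n_c, r_c, ridge = 1e-3) {
  eta <- drop(X1 %*% v)
  p <- stats::plogis(eta)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -sum(r_c * log(p) + (n_c - r_c) * log(1 - p)) + ridge * sum(v^2) / 2
}

item_negll_grad <- function(v, X1, n_c, r_c, ridge = 1e-3) {
  p <- stats::plogis(drop(X1 %*% v))
  drop(-crossprod(X1, r_c - n_c * p)) + ridge * v
}

# M-step for one item: maximize expected complete-data log-likelihood under
# monotonicity constraints.  Tries box-constrained L-BFGS-B first (mains
# >= 0); falls back to constrOptim when an interaction-coupling constraint
# is violated.
maximize_item <- function(start, terms, X1, n_c, r_c, bound = 15) {
  np <- length(start)
  lower <- rep(-bound, np)
  upper <- rep(bound, np)
  is_main <- c(FALSE, vapply(terms, function(t) length(t) == 1L, logical(1)))
  lower[is_main] <- 0
  fit <- stats::optim(start, item_negll, item_negll_grad,
                      X1 = X1, n_c = n_c, r_c = r_c,
                      method = "L-BFGS-B", lower = lower, upper = upper)
  ui <- monotonicity_constraints(terms)
  if (nrow(ui) && any(ui %*% fit$par < -1e-8)) {
    th0 <- start
    th0[is_main] <- pmax(th0[is_main], 0.1)
    th0[!is_main] <- 0
    th0[1] <- start[1]
    if (any(ui %*% th0 <= 0)) th0 <- c(start[1], rep(0.1, np - 1))[seq_len(np)]
    fit <- tryCatch(
      stats::constrOptim(th0, item_negll, item_negll_grad,
                         ui = ui, ci = rep(0, nrow(ui)),
                         X1 = X1, n_c = n_c, r_c = r_c,
                         method = "BFGS"),
      error = function(e) fit)
    fit$par <- pmin(pmax(fit$par, -bound), bound)
  }
  list(par = fit$par, boundary = any(abs(fit$par) >= bound - 1e-6))
}

#' Fit an LCDM by marginal maximum likelihood EM
#'
#' Estimation alternates an E step, computing each examinee's posterior over
#' the 2^S mastery profiles, with an M step that updates the saturated
#' structural (profile-probability) distribution in closed form and each
#' item's logistic parameters by constrained quasi-Newton maximization of
#' the expected complete-data log-likelihood.  Main effects are constrained
#' non-negative and interactions so that mastery never lowers the response
#' probability (monotonicity).  Standard errors come from the numerically
#' computed observed information of the marginal log-likelihood.
#'
#' @param responses binary matrix/data frame, examinees in rows, items in
#'   columns.  No missing values are allowed.
#' @param q a [qmatrix()] whose rows match the response columns.
#' @param effect_structure an [build_effect_structure()] result; defaults to
#'   all main effects plus two-way interactions admitted by `q`.
#' @param max_iter maximum EM iterations.
#' @param tol relative log-likelihood change declaring convergence.
#' @param se compute standard errors (numeric observed information)?
#' @return Object of class `lcdm` with components `item_params`, `se`,
#'   `structural_probs`, `posterior`, `log_likelihood`, `loglik_trace`,
#'   `converged`, `iterations`, `boundary_items`, plus the inputs needed by
#'   downstream methods.
#' @seealso [classify_examinees()], [wald_tests_and_prune()]
#' @export
fit_lcdm <- function(responses, q, effect_structure = NULL,
                     max_iter = 200L, tol = 1e-6, se = TRUE) {
  Y <- as.matrix(responses)
  storage.mode(Y) <- "integer"
  if (any(is.na(Y)))
    stop("missing responses are not supported; remove or impute upstream")
  if (!all(Y %in% c(0L, 1L)))
    stop("responses must be binary 0/1")
  if (nrow(Y) < 1L) stop("at least one examinee is required")
  stopifnot(inherits(q, "qmatrix"), ncol(Y) == nrow(q))
  if (is.null(effect_structure))
    effect_structure <- build_effect_structure(q, max_order = 2L)
  S <- ncol(q); J <- ncol(Y); n <- nrow(Y)
  profiles <- all_profiles(S, colnames(q))
  P <- nrow(profiles)

  # collapse to unique response patterns for speed
  pat_key <- apply(Y, 1, paste, collapse = "")
  upat <- !duplicated(pat_key)
  Yu <- Y[upat, , drop = FALSE]
  pat_index <- match(pat_key, pat_key[upat])
  pat_w <- as.numeric(table(factor(pat_index, levels = seq_len(nrow(Yu)))))

  # design per item evaluated at all profiles, with leading 1 column
  X1 <- lapply(seq_len(J), function(j)
    cbind(1, effect_design(profiles, effect_structure[[j]])))

  item_params <- lapply(seq_len(J), function(j) {
    nt <- length(effect_structure[[j]])
    list(intercept = 0,
         coef = if (nt) rep(1, nt) else numeric(0))
  })
  names(item_params) <- rownames(q)
  structural <- rep(1 / P, P)

  loglik_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  boundary <- rep(FALSE, J)

  for (iter in seq_len(max_iter)) {
    pr <- item_profile_probs(item_params, effect_structure, profiles) # J x P
    logpr <- log(pmin(pmax(pr, 1e-12), 1 - 1e-12))
    log1m <- log(pmin(pmax(1 - pr, 1e-12), 1 - 1e-12))
    # log-likelihood of each unique pattern under each profile
    llmat <- Yu %*% logpr + (1L - Yu) %*% log1m            # Upat x P
    lj <- sweep(llmat, 2, log(pmax(structural, 1e-300)), "+")
    mx <- apply(lj, 1, max)
    wj <- exp(lj - mx)
    lik <- rowSums(wj)
    ll <- sum(pat_w * (log(lik) + mx))
    loglik_trace <- c(loglik_trace, ll)
    post_u <- wj / lik                                      # Upat x P

    # M step: structural probabilities (saturated multinomial)
    wpost <- post_u * pat_w
    structural <- colSums(wpost)
    structural <- structural / sum(structural)

    # M step: items
    n_c <- colSums(wpost)                                   # expected class sizes
    for (j in seq_len(J)) {
      r_c <- colSums(wpost * Yu[, j])
      res <- maximize_item(pack_item(item_params[[j]]),
                           effect_structure[[j]], X1[[j]], n_c, r_c)
      item_params[[j]] <- unpack_item(res$par)
      pj <- stats::plogis(drop(X1[[j]] %*% res$par))
      boundary[j] <- res$boundary || any(pj < 5e-4) || any(pj > 1 - 5e-4)
    }

    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1e-10)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }

  # final E step at the converged parameters
  pr <- item_profile_probs(item_params, effect_structure, profiles)
  logpr <- log(pmin(pmax(pr, 1e-12), 1 - 1e-12))
  log1m <- log(pmin(pmax(1 - pr, 1e-12), 1 - 1e-12))
  llmat <- Yu %*% logpr + (1L - Yu) %*% log1m
  lj <- sweep(llmat, 2, log(pmax(structural, 1e-300)), "+")
  mx <- apply(lj, 1, max)
  wj <- exp(lj - mx)
  lik <- rowSums(wj)
  ll <- sum(pat_w * (log(lik) + mx))
  post_u <- wj / lik
  posterior <- post_u[pat_index, , drop = FALSE]
  rownames(posterior) <- rownames(Y)
  colnames(posterior) <- rownames(profiles)

  fit <- structure(list(
    item_params = item_params,
    se = NULL,
    structural_probs = stats::setNames(structural, rownames(profiles)),
    posterior = posterior,
    log_likelihood = ll,
    loglik_trace = loglik_trace,
    converged = converged,
    iterations = length(loglik_trace),
    boundary_items = rownames(q)[boundary],
    qmatrix = q,
    effect_structure = effect_structure,
    profiles = profiles,
    responses = Y
  ), class = "lcdm")

  if (se) fit$se <- lcdm_standard_errors(fit)
  fit
}

# Marginal log-likelihood as a function of the flat item-parameter vector
# (structural probabilities held at their estimates via multinomial-logit
# parameters included in the vector).
lcdm_flat_marginal <- function(fit) {
  Y <- fit$responses
  profiles <- fit$profiles
  es <- fit$effect_structure
  J <- length(fit$item_params)
  lens <- vapply(seq_len(J), function(j) 1L + length(es[[j]]), integer(1))
  off <- cumsum(c(0L, lens))
  P <- nrow(profiles)
  X1 <- lapply(seq_len(J), function(j) cbind(1, effect_design(profiles, es[[j]])))
  function(theta) {
    ip <- lapply(seq_len(J), function(j)
      unpack_item(theta[(off[j] + 1L):off[j + 1L]]))
    zeta <- theta[(off[J + 1L] + 1L):(off[J + 1L] + P - 1L)]
    sp <- exp(c(zeta, 0) - max(c(zeta, 0)))
    sp <- sp / sum(sp)
    pr <- t(vapply(seq_len(J), function(j)
      stats::plogis(drop(X1[[j]] %*% pack_item(ip[[j]]))), numeric(P)))
    logpr <- log(pmin(pmax(pr, 1e-12), 1 - 1e-12))
    log1m <- log(pmin(pmax(1 - pr, 1e-12), 1 - 1e-12))
    lj <- sweep(Y %*% logpr + (1L - Y) %*% log1m, 2, log(sp), "+")
    mx <- apply(lj, 1, max)
    sum(log(rowSums(exp(lj - mx))) + mx)
  }
}

# Standard errors of item parameters from the inverse observed information
# of the marginal log-likelihood (numerical Hessian; structural
# probabilities profiled jointly through a multinomial-logit chart).
lcdm_standard_errors <- function(fit) {
  J <- length(fit$item_params)
  es <- fit$effect_structure
  lens <- vapply(seq_len(J), function(j) 1L + length(es[[j]]), integer(1))
  sp <- pmax(fit$structural_probs, 1e-8)
  zeta <- log(sp[-length(sp)] / sp[length(sp)])
  theta <- c(unlist(lapply(fit$item_params, pack_item)), zeta)
  f <- lcdm_flat_marginal(fit)
  H <- tryCatch(pracma::hessian(f, theta), error = function(e) NULL)
  np_items <- sum(lens)
  out <- lapply(seq_len(J), function(j) {
    nt <- lens[j]
    list(intercept = NA_real_, coef = rep(NA_real_, nt - 1L))
  })
  names(out) <- names(fit$item_params)
  singular <- TRUE
  if (!is.null(H)) {
    V <- tryCatch(solve(-H), error = function(e) NULL)
    if (!is.null(V)) {
      d <- diag(V)[seq_len(np_items)]
      d[d < 0] <- NA_real_
      ses <- sqrt(d)
      off <- cumsum(c(0L, lens))
      for (j in seq_len(J)) {
        v <- ses[(off[j] + 1L):off[j + 1L]]
        out[[j]] <- list(intercept = v[1],
                         coef = if (length(v) > 1) v[-1] else numeric(0))
      }
      singular <- FALSE
    }
  }
  if (singular)
    warning("observed information is singular; standard errors unavailable")
  out
}

#' @exportS3Method base::print
print.lcdm <- function(x, ...) {
  cat("LCDM fit:", nrow(x$responses), "examinees,",
      length(x$item_params), "items,", ncol(x$profiles), "attributes\n")
  cat("log-likelihood:", format(x$log_likelihood, digits = 8),
      if (x$converged) "(converged" else "(NOT converged",
      "after", x$iterations, "EM iterations)\n")
  if (length(x$boundary_items))
    cat("boundary parameters flagged for:",
        paste(x$boundary_items, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.lcdm <- function(object, ...) {
  labs <- colnames(object$qmatrix)
  do.call(rbind, lapply(seq_along(object$item_params), function(j) {
    terms <- object$effect_structure[[j]]
    p <- object$item_params[[j]]
    s <- object$se[[j]]
    data.frame(
      item = names(object$item_params)[j],
      term = c("(Intercept)",
               vapply(terms, function(t) paste(labs[t], collapse = ":"),
                      character(1))),
      estimate = c(p$intercept, p$coef),
      se = if (is.null(s)) NA_real_ else c(s$intercept, s$coef),
      row.names = NULL)
  }))
}

#' @export
logLik.lcdm <- function(object, ...) {
  np <- sum(vapply(object$effect_structure, length, integer(1))) +
    length(object$item_params) + length(object$structural_probs) - 1L
  structure(object$log_likelihood, df = np, nobs = nrow(object$responses),
            class = "logLik")
}

#' @exportS3Method base::summary
summary.lcdm <- function(object, ...) {
  tab <- coef(object)
  tab$z <- tab$estimate / tab$se
  tab$p_value <- 2 * stats::pnorm(-abs(tab$z))
  structure(list(coefficients = tab,
                 structural_probs = object$structural_probs,
                 log_likelihood = object$log_likelihood,
                 converged = object$converged,
                 iterations = object$iterations),
            class = "summary.lcdm")
}

#' @exportS3Method base::print
print.summary.lcdm <- function(x, ...) {
  cat("Item parameters (logit scale):\n")
  print(x$coefficients, digits = 3)
  cat("\nStructural profile probabilities:\n")
  print(round(x$structural_probs, 4))
  invisible(x)
}

#' @export
predict.lcdm <- function(object, profiles = NULL, ...) {
  if (is.null(profiles)) profiles <- object$profiles
  if (is.null(dim(profiles))) profiles <- matrix(profiles, nrow = 1)
  pr <- item_profile_probs(object$item_params, object$effect_structure,
                           profiles)
  dimnames(pr) <- list(names(object$item_params),
                       apply(profiles, 1, paste, collapse = ""))
  t(pr)
}
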