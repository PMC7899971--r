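#' Wald tests of interaction terms with backward pruning
#'
#' Computes Wald z statistics (estimate / SE) and two-sided p values for
#' every interaction term in the fitted model.  Non-significant interactions
#' are removed one order at a time (highest order first, least significant
#' first within an order), the model refit, and the tests repeated until all
#' retained interactions are significant at `alpha` or none remain.  Main
#' effects and intercepts are never pruned.
#'
#' @param fit an [fit_lcdm()] result.
#' @param alpha pruning significance level (default 0.05).  Tests at both
#'   0.05 and 0.01 are reported in the table.
#' @param max_refits safety cap on the number of refits.
#' @return List with `tests` (data frame of every interaction tested at each
#'   stage: item, term, estimate, se, z, p, sig at .05/.01, action) and
#'   `fit` (the final refit `lcdm`).
#' @export
wald_tests_and_prune <- function(fit, alpha = 0.05, max_refits = 10L) {
  stopifnot(inherits(fit, "lcdm"))
  labs <- colnames(fit$qmatrix)
  rows <- list()
  cur <- fit
  for (round in seq_len(max_refits)) {
    es <- cur$effect_structure
    cand <- list()
    for (j in seq_along(es)) {
      for (i in seq_along(es[[j]])) {
        t <- es[[j]][[i]]
        if (length(t) >= 2L) {
          est <- cur$item_params[[j]]$coef[i]  # terms and coefs are parallel
          sev <- if (is.null(cur$se)) NA_real_ else cur$se[[j]]$coef[i]
          cand[[length(cand) + 1L]] <- list(item = j, idx = i, term = t,
                                            est = est, se = sev)
        }
      }
    }
    if (!length(cand)) break
    tab <- do.call(rbind, lapply(cand, function(cc) {
      z <- cc$est / cc$se
      p <- 2 * stats::pnorm(-abs(z))
      data.frame(round = round,
                 item = names(cur$item_params)[cc$item],
                 term = paste(labs[cc$term], collapse = ":"),
                 order = length(cc$term),
                 estimate = cc$est, se = cc$se, z = z, p = p,
                 sig_05 = is.finite(p) && p < 0.05,
                 sig_01 = is.finite(p) && p < 0.01,
                 action = "retain", row.names = NULL)
    }))
    bad_se <- !is.finite(tab$p)
    if (any(bad_se))
      warning("standard error unavailable for ",
              paste(tab$term[bad_se], collapse = ", "),
              "; term retained")
    drop_pool <- which(!bad_se & tab$p >= alpha)
    if (!length(drop_pool)) {
      rows[[length(rows) + 1L]] <- tab
      break
    }
    # highest order first, then least significant
    drop_pool <- drop_pool[order(-tab$order[drop_pool], -tab$p[drop_pool])]
    k <- drop_pool[1]
    tab$action[k] <- "drop"
    rows[[length(rows) + 1L]] <- tab
    cc <- cand[[k]]
    es2 <- drop_effect_term(cur$effect_structure,
                            names(cur$item_params)[cc$item], cc$term)
    cur <- fit_lcdm(cur$responses, cur$qmatrix, es2,
                    se = !is.null(cur$se))
  }
  tests <- if (length(rows)) do.call(rbind, rows) else
    data.frame(round = integer(0), item = character(0), term = character(0),
               order = integer(0), estimate = numeric(0), se = numeric(0),
               z = numeric(0), p = numeric(0), sig_05 = logical(0),
               sig_01 = logical(0), action = character(0))
  list(tests = tests, fit = cur)
}

#' Classify examinees from a fitted LCDM
#'
#' Produces modal profile assignments (posterior argmax; ties broken toward
#' the lowest profile index, with a warning), per-attribute marginal mastery
#' probabilities (EAP), marginal mastery proportions (both EAP means and
#' modal shares), profile counts, and attribute correlations implied by the
#' structural distribution (both phi and tetrachoric).
#'
#' @param fit an [fit_lcdm()] result.
#' @return Object of class `lcdm_classification` with fields
#'   `modal_profile` (character labels), `modal_index`, `marginal_mastery`
#'   (examinee x attribute EAP matrix), `profile_counts`,
#'   `marginal_proportions` (EAP), `marginal_proportions_modal`,
#'   `attribute_correlations` (tetrachoric) and
#'   `attribute_correlations_phi`.
#' @export
classify_examinees <- function(fit) {
  stopifnot(inherits(fit, "lcdm"))
  post <- fit$posterior
  profiles <- fit$profiles
  ties <- apply(post, 1, function(r) sum(r == max(r)) > 1L)
  if (any(ties))
    warning(sum(ties), " examinee(s) with tied modal profiles; ",
            "assigned the lowest profile index")
  modal_index <- apply(post, 1, which.max)  # which.max takes first = lowest
  marginal <- post %*% profiles             # EAP mastery per attribute
  counts <- table(factor(modal_index, levels = seq_len(nrow(profiles))))
  names(counts) <- rownames(profiles)
  structure(list(
    modal_profile = rownames(profiles)[modal_index],
    modal_index = modal_index,
    marginal_mastery = marginal,
    profile_counts = counts,
    marginal_proportions = colMeans(marginal),
    marginal_proportions_modal = colMeans(profiles[modal_index, , drop = FALSE]),
    attribute_correlations = structural_attr_correlations(
      fit$structural_probs, profiles, method = "tetrachoric"),
    attribute_correlations_phi = structural_attr_correlations(
      fit$structural_probs, profiles, method = "phi"),
    profiles = profiles
  ), class = "lcdm_classification")
}

#' @exportS3Method base::print
print.lcdm_classification <- function(x, ...) {
  cat("LCDM classification of", length(x$modal_profile), "examinees\n")
  cat("Marginal mastery proportions (EAP):\n")
  print(round(x$marginal_proportions, 3))
  cat("Modal profile counts:\n")
  print(x$profile_counts)
  invisible(x)
}

# Pairwise attribute correlations under the structural profile distribution.
# phi: Pearson correlation of the binary margins.  tetrachoric: correlation
# of a latent bivariate normal whose quadrant probabilities match the 2x2
# cell probabilities implied by the structural distribution.
structural_attr_correlations <- function(structural_probs, profiles,
                                         method = c("tetrachoric", "phi")) {
  method <- match.arg(method)
  S <- ncol(profiles)
  R <- diag(1, S)
  dimnames(R) <- list(colnames(profiles), colnames(profiles))
  p_m <- drop(structural_probs %*% profiles)  # marginal mastery probs
  for (a in seq_len(S - 1)) for (b in (a + 1):S) {
    p11 <- sum(structural_probs[profiles[, a] == 1 & profiles[, b] == 1])
    if (method == "phi") {
      den <- sqrt(p_m[a] * (1 - p_m[a]) * p_m[b] * (1 - p_m[b]))
      r <- if (den < 1e-12) {
        if (abs(p11 - p_m[a] * p_m[b]) < 1e-12) 1 else NA_real_
      } else (p11 - p_m[a] * p_m[b]) / den
      # degenerate margins with perfectly coupled attributes count as 1
      if (den < 1e-12 && abs(p_m[a] - p_m[b]) < 1e-12) r <- 1
    } else {
      r <- tetrachoric_from_cell(p11, p_m[a], p_m[b])
    }
    R[a, b] <- R[b, a] <- r
  }
  R
}

# Upper-quadrant probability P(X > qnorm(1-pa), Y > qnorm(1-pb)) of a
# standard bivariate normal with correlation rho, by 1-D quadrature.
bvn_upper <- function(rho, pa, pb) {
  a <- stats::qnorm(1 - pa); b <- stats::qnorm(1 - pb)
  if (abs(rho) < 1e-12) return(pa * pb)
  f <- function(x)
    stats::dnorm(x) * stats::pnorm((rho * x - b) / sqrt(1 - rho^2))
  stats::integrate(f, a, Inf, rel.tol = 1e-10)$value
}

# Solve for the tetrachoric correlation matching P(both mastered) = p11
# given marginal mastery probabilities pa, pb.
tetrachoric_from_cell <- function(p11, pa, pb) {
  if (pa <= 1e-10 || pa >= 1 - 1e-10 || pb <= 1e-10 || pb >= 1 - 1e-10) {
    # degenerate margin: correlation undefined; perfectly coupled -> 1
    return(if (abs(p11 - pa * pb) < 1e-10 && abs(pa - pb) < 1e-10) 1
           else NA_real_)
  }
  lo <- max(0, pa + pb - 1); hi <- min(pa, pb)
  if (p11 >= hi - 1e-12) return(1)
  if (p11 <= lo + 1e-12) return(-1)
  g <- function(r) bvn_upper(r, pa, pb) - p11
  stats::uniroot(g, c(-0.9999, 0.9999), tol = 1e-9)$root
}

#' Profile frequency table
#'
#' One row per possible mastery profile with its modal count and percentage
#' of the total (percentages printed on a 0-100 scale).
#'
#' @param classification an [classify_examinees()] result, or a named vector
#'   of profile counts (one per profile in canonical order).
#' @return Data frame with columns `profile`, one column per attribute,
#'   `count`, `percent`.
#' @examples
#' profile_frequency_table(c(`000` = 323, `001` = 296, `010` = 0, `011` = 0,
#'                           `100` = 0, `101` = 146, `110` = 0, `111` = 1558))
#' @export
profile_frequency_table <- function(classification) {
  if (inherits(classification, "lcdm_classification")) {
    counts <- as.numeric(classification$profile_counts)
    profiles <- classification$profiles
  } else {
    counts <- as.numeric(classification)
    S <- as.integer(round(log2(length(counts))))
    if (2^S != length(counts))
      stop("counts length must be a power of two (one entry per profile)")
    profiles <- all_profiles(S)
  }
  total <- sum(counts)
  if (total == 0) stop("no examinees to tabulate")
  data.frame(profile = rownames(profiles),
             profiles,
             count = counts,
             percent = 100 * counts / total,
             row.names = NULL, check.names = FALSE)
}

#' Attribute classification reliability
#'
#' For each attribute the index is the expected agreement between two
#' independent classifications drawn from each examinee's marginal mastery
#' posterior p: agreement probability p^2 + (1-p)^2, averaged over examinees
#' and rescaled from its [0.5, 1] range to [0, 1]
#' (so certainty gives 1, a coin-flip posterior gives 0).
#'
#' @param fit an [fit_lcdm()] result, or a numeric matrix of marginal
#'   mastery posteriors (examinee x attribute).
#' @return Named numeric vector, one reliability per attribute.
#' @export
attribute_reliability <- function(fit) {
  marginal <- if (inherits(fit, "lcdm")) fit$posterior %*% fit$profiles
              else as.matrix(fit)
  agree <- marginal^2 + (1 - marginal)^2
  2 * colMeans(agree) - 1
}
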