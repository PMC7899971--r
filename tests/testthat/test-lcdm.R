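test_that("the item response probability evaluates the logistic closed form", {
  p <- list(intercept = -0.613, coef = 1.557)
  terms <- list(1L)
  expect_equal(item_response_probability(0, p, terms), plogis(-0.613),
               tolerance = 1e-12)
  expect_equal(item_response_probability(0, p, terms), 0.3514,
               tolerance = 1e-4)
  expect_equal(item_response_probability(1, p, terms), 0.7199,
               tolerance = 1e-4)
  # zero parameters give 1/2 for any profile
  p0 <- list(intercept = 0, coef = c(0, 0, 0))
  terms2 <- list(1L, 2L, c(1L, 2L))
  for (prof in list(c(0, 0), c(1, 0), c(1, 1)))
    expect_equal(item_response_probability(prof, p0, terms2), 0.5)
  # interactions multiply attribute indicators
  p2 <- list(intercept = -1, coef = c(1, 1, 0.5))
  expect_equal(item_response_probability(c(1, 1), p2, terms2),
               plogis(-1 + 1 + 1 + 0.5))
})

test_that("EM recovers a one-attribute toy and matches direct maximization", {
  q <- qmatrix(rbind(1, 1, 1), attributes = "A")
  es <- build_effect_structure(q, 1)
  ip <- list(list(intercept = -1, coef = 2), list(intercept = 0, coef = 1.5),
             list(intercept = -0.5, coef = 2.5))
  profiles <- simulate_profiles(5000, c(0.4, 0.6), seed = 5)
  Y <- simulate_item_responses(profiles, q, ip, es, seed = 5)
  fit <- fit_lcdm(Y, q, es, se = FALSE, tol = 1e-10, max_iter = 3000)

  # independent oracle: direct quasi-Newton maximization of the marginal
  # likelihood from several random starts
  marg_ll <- function(th) {
    p0 <- plogis(th[c(1, 3, 5)]); p1 <- plogis(th[c(1, 3, 5)] + th[c(2, 4, 6)])
    pi1 <- plogis(th[7])
    l0 <- Y %*% log(p0) + (1 - Y) %*% log(1 - p0)
    l1 <- Y %*% log(p1) + (1 - Y) %*% log(1 - p1)
    sum(log((1 - pi1) * exp(l0) + pi1 * exp(l1)))
  }
  set.seed(3)
  best <- max(vapply(1:5, function(i)
    -optim(rnorm(7), function(t) -marg_ll(t), method = "BFGS",
           control = list(maxit = 2000, reltol = 1e-14))$value, numeric(1)))
  expect_gte(fit$log_likelihood, best - 1e-3)

  # parameters close to truth at this sample size
  expect_lt(abs(fit$item_params[[1]]$intercept + 1), 0.25)
  expect_lt(abs(fit$item_params[[1]]$coef - 2), 0.35)
  expect_lt(abs(fit$structural_probs[2] - 0.6), 0.05)
})

test_that("EM invariants hold: monotone log-likelihood and simplex posteriors", {
  cfg <- recovery_sim_config(seed = 2, n_examinees = 500)
  profiles <- simulate_profiles(500, cfg$profile_probs, 2)
  Y <- simulate_item_responses(profiles, cfg$qmatrix, cfg$item_params,
                               cfg$effect_structure, 2)
  fit <- fit_lcdm(Y, cfg$qmatrix, cfg$effect_structure, se = FALSE)
  expect_true(all(diff(fit$loglik_trace) >
                    -1e-10 * (abs(fit$loglik_trace[-1]) + 1)))
  expect_true(all(abs(rowSums(fit$posterior) - 1) < 1e-10))
  expect_equal(sum(fit$structural_probs), 1, tolerance = 1e-10)

  # monotonicity: fitted response probability non-decreasing in each
  # attribute, checked exhaustively over all profiles
  profs <- fit$profiles
  pr <- predict(fit)
  for (j in seq_len(ncol(pr))) for (s in 1:3) {
    lo <- which(profs[, s] == 0)
    hi <- match(apply(sweep(profs[lo, , drop = FALSE], 2,
                            as.integer(seq_len(3) == s), "+"), 1,
                      paste, collapse = ""), rownames(profs))
    expect_true(all(pr[hi, j] >= pr[lo, j] - 1e-8))
  }
})

test_that("degenerate and malformed responses are handled", {
  q <- qmatrix(rbind(1, 1), attributes = "A")
  es <- build_effect_structure(q, 1)
  Y1 <- matrix(1L, 60, 2)
  fit <- fit_lcdm(Y1, q, es, se = FALSE, max_iter = 50)
  expect_true(length(fit$boundary_items) > 0)    # boundary flagged, no crash

  Ybad <- matrix(c(0L, 1L, 2L, 1L), 2, 2)
  expect_error(fit_lcdm(Ybad, q, es), "binary")
  Yna <- matrix(c(0L, NA, 1L, 1L), 2, 2)
  expect_error(fit_lcdm(Yna, q, es), "missing")
})

test_that("Wald pruning drops null interactions and keeps real ones", {
  mk <- function(inter, sd) {
    q <- qmatrix(rbind(c(1, 0), c(0, 1), c(1, 1), c(1, 0), c(0, 1)),
                 attributes = c("A", "B"))
    es <- build_effect_structure(q, 2)
    ip <- list(list(intercept = -1, coef = 2.5),
               list(intercept = -1, coef = 2.5),
               list(intercept = -1.5, coef = c(1.2, 1.2, inter)),
               list(intercept = -0.5, coef = 2),
               list(intercept = -0.5, coef = 2))
    profiles <- simulate_profiles(5000, c(.3, .2, .2, .3), sd)
    Y <- simulate_item_responses(profiles, q, ip, es, sd)
    wald_tests_and_prune(fit_lcdm(Y, q, es))
  }
  w0 <- mk(0, 21)
  expect_true(any(w0$tests$action == "drop"))
  expect_equal(length(w0$fit$effect_structure[[3]]), 2L)  # interaction gone

  w2 <- mk(2, 22)
  expect_false(any(w2$tests$action == "drop"))
  expect_true(all(w2$tests$p < 0.05))

  # model with no interactions: empty table, fit returned unchanged
  q1 <- qmatrix(rbind(1, 1), attributes = "A")
  es1 <- build_effect_structure(q1, 1)
  Y <- simulate_item_responses(simulate_profiles(300, c(.5, .5), 1),
                               q1, list(list(intercept = -1, coef = 2),
                                        list(intercept = 0, coef = 2)),
                               es1, 1)
  f1 <- fit_lcdm(Y, q1, es1, se = FALSE)
  wt <- wald_tests_and_prune(f1)
  expect_equal(nrow(wt$tests), 0L)
  expect_identical(wt$fit$item_params, f1$item_params)
})

test_that("classification reads off posteriors and tabulates profiles", {
  post <- rbind(c(0.9, 0.1), c(0.2, 0.8), c(0.5, 0.5))
  fit <- fake_lcdm(post, c(0.5, 0.5))
  expect_warning(cls <- classify_examinees(fit), "tied")
  expect_equal(cls$modal_profile, c("0", "1", "0"))   # tie -> lowest index
  expect_equal(unname(cls$marginal_mastery[, 1]), c(0.1, 0.8, 0.5))
  expect_equal(unname(cls$marginal_proportions), mean(c(0.1, 0.8, 0.5)))

  # perfectly coupled attributes: phi and tetrachoric correlations are 1
  post3 <- matrix(0, 4, 8); post3[, 1] <- c(1, 1, 0, 0); post3[, 8] <- c(0, 0, 1, 1)
  sp <- c(0.5, 0, 0, 0, 0, 0, 0, 0.5)
  fit3 <- fake_lcdm(post3, sp)
  cls3 <- classify_examinees(fit3)
  expect_true(all(abs(cls3$attribute_correlations_phi - 1) < 1e-8))
  expect_true(all(abs(cls3$attribute_correlations - 1) < 1e-6))

  # independent attributes: phi correlation 0 (flat posteriors tie)
  spI <- rep(1 / 8, 8)
  expect_warning(clsI <- classify_examinees(fake_lcdm(matrix(1 / 8, 2, 8), spI)),
                 "tied")
  off <- clsI$attribute_correlations_phi[upper.tri(diag(3))]
  expect_true(all(abs(off) < 1e-8))
})

test_that("strong-signal synthetic data classifies examinees accurately", {
  cfg <- recovery_sim_config(seed = 6, n_examinees = 800)
  profiles <- simulate_profiles(800, cfg$profile_probs, 6)
  Y <- simulate_item_responses(profiles, cfg$qmatrix, cfg$item_params,
                               cfg$effect_structure, 6)
  fit <- fit_lcdm(Y, cfg$qmatrix, cfg$effect_structure, se = FALSE)
  cls <- classify_examinees(fit)
  truth <- apply(profiles, 1, paste, collapse = "")
  expect_gte(mean(cls$modal_profile == truth), 0.75)
  # attribute-level accuracy is higher still
  acc <- colMeans((cls$marginal_mastery > 0.5) == (profiles == 1))
  expect_true(all(acc >= 0.9))
})

test_that("profile frequency tables reproduce printed percentages", {
  counts <- c(`000` = 323, `001` = 296, `010` = 0, `011` = 0,
              `100` = 0, `101` = 146, `110` = 0, `111` = 1558)
  tab <- profile_frequency_table(counts)
  expect_equal(sum(tab$count), 2323)
  expect_equal(round(tab$percent[tab$profile == "000"], 2), 13.90)
  expect_equal(round(tab$percent[tab$profile == "111"], 2), 67.07)
  expect_equal(sum(round(tab$percent, 2)), 100, tolerance = 0.05)

  # single examinee
  t1 <- profile_frequency_table(c(`0` = 0, `1` = 1))
  expect_equal(t1$percent, c(0, 100))

  # uniform sampling: all eight percentages near 12.5
  pr <- simulate_profiles(8000, rep(1 / 8, 8), seed = 12)
  cnt <- table(factor(attr(pr, "profile"), levels = rownames(all_profiles(3))))
  tabu <- profile_frequency_table(as.numeric(cnt))
  # 4 SEs: eight simultaneous cells
  expect_true(all(abs(tabu$percent - 12.5) < 4 * 100 * sqrt(.125 * .875 / 8000)))
})

test_that("attribute reliability is the rescaled double-draw agreement", {
  # certainty
  m <- matrix(c(1, 0, 1, 0), 4, 1)
  expect_equal(unname(attribute_reliability(m)), 1)
  # maximal uncertainty
  expect_equal(unname(attribute_reliability(matrix(0.5, 10, 1))), 0)
  # Monte-Carlo double-draw oracle
  set.seed(8)
  p <- matrix(runif(60), 30, 2)
  rel <- attribute_reliability(p)
  mc <- vapply(1:2, function(a) {
    draws1 <- matrix(rbinom(30 * 4000, 1, p[, a]), 30)
    draws2 <- matrix(rbinom(30 * 4000, 1, p[, a]), 30)
    2 * mean(draws1 == draws2) - 1
  }, numeric(1))
  expect_true(all(abs(rel - mc) < 0.01))
})

test_that("tetrachoric correlations match the latent bivariate-normal model", {
  # zero correlation: cell probability is the product of margins
  expect_equal(masterytopics:::tetrachoric_from_cell(0.3 * 0.6, 0.3, 0.6), 0,
               tolerance = 1e-6)
  # known rho: invert the quadrant probability computed by quadrature
  for (rho in c(-0.5, 0.4, 0.8)) {
    p11 <- masterytopics:::bvn_upper(rho, 0.4, 0.55)
    expect_equal(masterytopics:::tetrachoric_from_cell(p11, 0.4, 0.55), rho,
                 tolerance = 1e-5)
  }
  # boundary: p11 at its maximum gives 1
  expect_equal(masterytopics:::tetrachoric_from_cell(0.4, 0.4, 0.55), 1)
})
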