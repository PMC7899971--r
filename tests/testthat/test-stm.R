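test_that("softmax maps free logits to the simplex with a fixed reference", {
  expect_equal(softmax_theta(c(0, 0, 0)), rep(0.25, 4))
  expect_equal(softmax_theta(c(log(2), 0, 0)), c(0.4, 0.2, 0.2, 0.2))
  expect_equal(sum(softmax_theta(c(3, -2, 0.5))), 1, tolerance = 1e-12)
  # saturation without overflow
  th <- softmax_theta(c(800, 0, 0))
  expect_equal(th[1], 1, tolerance = 1e-12)
  expect_error(softmax_theta(c(NA, 0)))
})

test_that("the document E step finds the exact posterior mode", {
  # flat word distributions carry no topic information: mode equals the
  # prior mean exactly
  beta_flat <- rbind(c(.5, .3, .2), c(.5, .3, .2))
  p <- e_step_document(c(4, 2, 1), beta_flat, mu_d = 0.7,
                       Sigma = matrix(1, 1, 1))
  expect_equal(p$eta_hat, 0.7, tolerance = 1e-8)

  # grid-search oracle on a tiny instance
  b2 <- rbind(c(.7, .2, .1), c(.1, .2, .7))
  cnt <- c(3, 1, 4)
  p2 <- e_step_document(cnt, b2, 0.3, matrix(0.8, 1, 1))
  g <- seq(-5, 5, by = 1e-3)
  obj <- vapply(g, function(e) {
    th <- softmax_theta(e)
    -0.5 * (e - 0.3)^2 / 0.8 + sum(cnt * log(colSums(th * b2)))
  }, numeric(1))
  expect_lt(abs(p2$eta_hat - g[which.max(obj)]), 1e-3)

  # Laplace variance matches the numerical curvature at the mode
  h <- 1e-4
  f <- function(e) {
    th <- softmax_theta(e)
    -0.5 * (e - 0.3)^2 / 0.8 + sum(cnt * log(colSums(th * b2)))
  }
  d2 <- (f(p2$eta_hat + h) - 2 * f(p2$eta_hat) + f(p2$eta_hat - h)) / h^2
  expect_equal(drop(p2$lap_cov), -1 / d2, tolerance = 1e-4)

  # a single discriminating word pushes theta toward its topic (one token
  # of evidence against a diffuse prior centred on equal use)
  b3 <- rbind(c(.98, .01, .01), c(.01, .01, .98))
  p3 <- e_step_document(c(1, 0, 0), b3, 0, matrix(25, 1, 1))
  expect_gt(p3$theta[1], 0.9)
})

test_that("the M step matches its closed forms", {
  # two hand-built document posteriors, K = 2
  post <- list(
    list(eta_hat = 0.5, lap_cov = matrix(0.1, 1, 1),
         theta = softmax_theta(0.5), phi = rbind(c(.8, .2), c(.3, .7)),
         word_idx = c(1L, 2L)),
    list(eta_hat = -0.3, lap_cov = matrix(0.2, 1, 1),
         theta = softmax_theta(-0.3), phi = rbind(c(.5, .5), c(.9, .1)),
         word_idx = c(2L, 3L)))
  X <- cbind(1, c(0, 1))
  counts <- rbind(c(2, 1, 0), c(0, 3, 1))

  # diffuse prior, intercept only: gamma is the mean of the modes
  msI <- m_step(post, X[, 1, drop = FALSE], counts, sigma2 = 1e12)
  expect_equal(drop(msI$gamma), mean(c(0.5, -0.3)), tolerance = 1e-6)
  # infinite shrinkage sends gamma to zero
  ms0 <- m_step(post, X, counts, sigma2 = 1e-12)
  expect_lt(max(abs(ms0$gamma)), 1e-6)

  # beta matches the hand-normalized phi-weighted counts (+1/V smoothing)
  ms <- m_step(post, X, counts, sigma2 = 25)
  V <- 3
  num <- matrix(1 / V, 2, V)
  num[, 1] <- num[, 1] + c(.8, .2) * 2
  num[, 2] <- num[, 2] + c(.3, .7) * 1 + c(.5, .5) * 3
  num[, 3] <- num[, 3] + c(.9, .1) * 1
  expect_equal(ms$beta, num / rowSums(num), tolerance = 1e-10)

  # rank-deficient designs are reported
  Xbad <- cbind(1, c(1, 1))
  expect_error(m_step(post, Xbad, counts), "rank deficient")
})

test_that("fitting is deterministic and obeys its stopping rules", {
  pc <- planted_corpus(seed = 31, n = 120, V = 60, mulen = 40)
  f1 <- fit_stm(pc$counts, pc$X, K = 3, max_iter = 15, seed = 7)
  f2 <- fit_stm(pc$counts, pc$X, K = 3, max_iter = 15, seed = 7)
  expect_identical(f1$bound_trace, f2$bound_trace)
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$theta, f2$theta)

  # tol = Inf stops after one iteration, flagged converged
  f3 <- fit_stm(pc$counts, pc$X, K = 3, tol = Inf, seed = 7)
  expect_equal(f3$iterations, 1L)
  expect_true(f3$converged)

  expect_error(fit_stm(pc$counts, pc$X, K = 1), "K must be")
  expect_error(fit_stm(pc$counts, pc$X[1:10, ], K = 3), "design rows")

  # simplex invariants
  expect_true(all(abs(rowSums(f1$theta) - 1) < 1e-10))
  expect_true(all(abs(rowSums(f1$beta) - 1) < 1e-10))
})

test_that("planted topics are recovered at moderate scale", {
  pc <- planted_corpus(seed = 2, n = 400, V = 120, mulen = 90)
  fit <- fit_stm(pc$counts, pc$X, K = 4, max_iter = 150, seed = 2)
  m <- match_topics(fit$beta, pc$beta_true)
  expect_true(m$unique)
  expect_true(all(m$cosines >= 0.9))
  # document-level proportions track the truth
  expect_gt(mean(diag(cor(fit$theta[, m$perm], pc$theta))), 0.8)
})

test_that("composition effects close over the simplex and recover signs", {
  pc <- planted_corpus(seed = 5, n = 300, V = 100, mulen = 70)
  fit <- fit_stm(pc$counts, pc$X, K = 4, max_iter = 100, seed = 5)
  eff <- estimate_effects(fit, n_sims = 150, seed = 5)
  sums <- tapply(eff$estimate, eff$term, sum)
  expect_equal(unname(sums["(Intercept)"]), 1, tolerance = 1e-6)
  for (tm in c("Idea", "Structure", "Integration"))
    expect_equal(unname(sums[tm]), 0, tolerance = 1e-6)
  expect_true(all(eff$p >= 0 & eff$p <= 1))
  expect_error(estimate_effects(fit, n_sims = 1), "n_sims")

  # intercept-only design: estimates equal mean simulated theta per topic
  fit0 <- fit_stm(pc$counts, NULL, K = 4, max_iter = 60, seed = 5)
  eff0 <- estimate_effects(fit0, n_sims = 150, seed = 5)
  expect_equal(sum(eff0$estimate), 1, tolerance = 1e-6)
  expect_equal(eff0$estimate, unname(colMeans(attr(eff0, "draws")[, 1, ])),
               tolerance = 1e-12)
})

test_that("predicted topic use is linear in the mastery profile", {
  eff <- data.frame(
    topic = rep(c("t1", "t2", "t3", "t4"), each = 4),
    term = rep(c("(Intercept)", "Idea", "Structure", "Integration"), 4),
    estimate = c(0.11, 0.03, 0.02, 0.07,
                 0.49, -0.04, -0.03, -0.15,
                 0.16, 0.02, 0.01, 0.05,
                 0.24, -0.01, 0.01, 0.03))
  none <- predicted_topic_use(eff, c(Idea = 0, Structure = 0, Integration = 0))
  expect_equal(unname(none), c(0.11, 0.49, 0.16, 0.24))
  all3 <- predicted_topic_use(eff, c(Idea = 1, Structure = 1, Integration = 1))
  expect_equal(unname(all3["t2"]), 0.49 - 0.04 - 0.03 - 0.15)  # 0.27
  expect_error(predicted_topic_use(eff, c(Idea = 1)), "must supply")
  expect_error(predicted_topic_use(eff, c(Idea = 1, Structure = 0,
                                          Integration = 0, Bogus = 1)),
               "unknown term")
  # zero coefficients reproduce the intercepts
  eff0 <- eff; eff0$estimate[eff0$term != "(Intercept)"] <- 0
  expect_equal(unname(predicted_topic_use(
    eff0, c(Idea = 1, Structure = 1, Integration = 1))),
    c(0.11, 0.49, 0.16, 0.24))
})

test_that("topic summaries rank words and documents and close over topics", {
  pc <- planted_corpus(seed = 31, n = 120, V = 60, mulen = 40)
  fit <- fit_stm(pc$counts, pc$X, K = 3, max_iter = 30, seed = 7)
  ts <- summarize_topics(fit, top_n = 10)
  expect_equal(dim(ts$top_words), c(10L, 3L))
  expect_equal(sum(ts$marginal_theta), 1, tolerance = 1e-10)
  # a topic with all mass on one word lists that word first
  fit2 <- fit
  fit2$beta[1, ] <- c(1, rep(0, 59))
  ts2 <- summarize_topics(fit2, top_n = 3)
  expect_equal(unname(ts2$top_words[1, 1]), fit$vocabulary[1])
  expect_warning(summarize_topics(fit, top_n = 1000), "truncat")
  # top documents really do maximize theta
  top1 <- ts$top_documents[[1]][1]
  expect_equal(fit$theta[top1, 1], max(fit$theta[, 1]))
})

test_that("topic use by score groups with exact quartile conventions", {
  pc <- planted_corpus(seed = 31, n = 120, V = 60, mulen = 40)
  fit <- fit_stm(pc$counts, pc$X, K = 3, max_iter = 20, seed = 7)
  scores <- rep(c(2, 5), length.out = 120)
  tb <- topic_use_by_score(fit, scores)
  expect_equal(nrow(tb), 3L * 2L)
  g <- fit$theta[scores == 2, 1]
  row <- tb[tb$topic == "topic_1" & tb$score == 2, ]
  expect_equal(row$mean, mean(g))
  expect_equal(row$median, unname(quantile(g, .5, type = 7)))
  expect_equal(row$q75, unname(quantile(g, .75, type = 7)))
  # identical theta: all quartiles equal that value
  fitc <- fit; fitc$theta[] <- 1 / 3
  tbc <- topic_use_by_score(fitc, scores)
  expect_true(all(abs(tbc[, c("q25", "median", "q75", "mean")] - 1 / 3) < 1e-12))
  expect_error(topic_use_by_score(fit, scores[-1]), "align")
})
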