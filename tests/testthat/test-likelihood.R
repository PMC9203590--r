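test_that("lk_loglik matches hand-computed values", {
  fam <- fit_family("logistic", 1)
  # single shared point: numerator and background mean cancel for any beta
  same <- pb_dataset(P = 0.3, B = 0.3)
  for (b in list(c(0, 0), c(-2, 5), c(10, -4))) {
    expect_equal(lk_loglik(b, fam, same), 0, tolerance = 1e-12)
  }
  # P = {0}, B = {0, 1} at the linear-logistic coefficients:
  # ln p(0) - ln((p(0) + p(1))/2)
  d <- pb_dataset(P = 0, B = c(0, 1))
  p0 <- 1 / (1 + exp(-0.606)); p1 <- 1 / (1 + exp(-0.606 + 3.64))
  expect_equal(lk_loglik(c(-0.606, 3.64), fam, d),
               log(p0) - log((p0 + p1) / 2), tolerance = 1e-12)
  expect_equal(round(lk_loglik(c(-0.606, 3.64), fam, d), 4), 0.6246)
})

test_that("lk_loglik is bit-identical under any family scaling", {
  d <- cached_sim("hf_scaled", 200, 2000, seed = 81)
  fam <- fit_family("logistic", 1)
  b <- c(0.7, -1.2)
  ref <- lk_loglik(b, fam, d)
  for (k in c(0.5, 0.1, 2, 1e-6)) {
    expect_identical(lk_loglik(b, fam, d, scale = k), ref)
  }
  # independent direct-form oracle: the scale cancels analytically
  direct <- function(k) {
    p <- function(x) k / (1 + exp(b[1] + b[2] * x))
    sum(log(p(d$P))) - d$n1 * log(mean(p(d$B)))
  }
  expect_equal(direct(0.5), ref, tolerance = 1e-9)
  expect_equal(direct(1), ref, tolerance = 1e-9)
})

test_that("intercept profiling lands exactly on the constraint", {
  fam <- fit_family("logistic", 1)
  # single background point: closed form ln(1/pi0 - 1) - b1 x*
  b0 <- profile_intercept(2, fam, matrix(0.3), pi0 = 0.5)
  expect_equal(b0, -0.6, tolerance = 1e-9)
  # fixed point: pi0 equal to the mean at zero intercept returns zero
  B <- matrix(seq(-1, 1, length.out = 50))
  h <- 1.5 * B[, 1]
  pi_at0 <- mean(1 / (1 + exp(h)))
  expect_equal(profile_intercept(1.5, fam, B, pi_at0), 0, tolerance = 1e-9)
  # residual contract across links
  for (link in c("logistic", "exponential", "cloglog")) {
    famk <- fit_family(link, 2)
    b0 <- profile_intercept(c(0.8, -0.4), famk, B, pi0 = 0.3)
    p <- link_transform_probe(link, b0, c(0.8, -0.4), B)
    expect_lt(abs(mean(p) - 0.3), 1e-10)
  }
  # exponential infeasibility: the cap makes large pi0 unattainable
  fame <- fit_family("exponential", 1)
  expect_error(profile_intercept(5, fame, B, pi0 = 0.9),
               "unattainable")
})

test_that("fit_lk recovers a well-specified Category 1 function", {
  m <- catalog_model("cat1_linear")
  fam <- fit_family("logistic", 1)
  rmses <- vapply(1:5, function(r) {
    d <- cached_sim("cat1_linear", 2000, 20000, seed = 90 + r)
    f <- fit_lk(d, fam, n_starts = 3, seed = r)
    expect_true(f$converged)
    rmse_curve(f, m)
  }, numeric(1))
  expect_lt(median(rmses), 0.05)
})

test_that("degenerate designs are flagged, not fitted", {
  d <- pb_dataset(P = rep(0.5, 20), B = rep(0.5, 50))
  f <- fit_lk(d, fit_family("logistic", 1), n_starts = 2, seed = 1)
  expect_false(f$converged)
})

test_that("every converged CLK fit satisfies its constraint to 1e-8", {
  for (spec in list(list("cat1_linear", "logistic", 1),
                    list("cat2_gaussian", "exponential", 2),
                    list("cat3_quadratic", "logistic", 2))) {
    m <- catalog_model(spec[[1]])
    d <- cached_sim(spec[[1]], 500, 5000, seed = 101)
    pi0 <- true_prevalence(m)
    f <- fit_clk(d, fit_family(spec[[2]], spec[[3]]), pi0,
                 n_starts = 3, seed = 2)
    expect_true(f$converged, label = paste("CLK on", spec[[1]]))
    expect_lte(f$constraint_residual, 1e-8)
    mB <- mean(fitted_probability(f, d$B))
    expect_lt(abs(mB - pi0), 1e-8)
  }
})

test_that("the CLK optimum dominates random feasible coefficient vectors", {
  d <- cached_sim("cat1_linear", 500, 5000, seed = 101)
  fam <- fit_family("logistic", 1)
  pi0 <- true_prevalence(catalog_model("cat1_linear"))
  f <- fit_clk(d, fam, pi0, n_starts = 3, seed = 2)
  opt_presence_term <- sum(log(fitted_probability(f, d$P)))
  set.seed(33)
  for (i in 1:100) {
    rest <- stats::rnorm(1, sd = 2)
    b0 <- profile_intercept(rest, fam, d$B, pi0)
    p <- 1 / (1 + exp(b0 + rest * d$P[, 1]))
    expect_gte(opt_presence_term + 1e-6, sum(log(p)))
  }
})

test_that("CLK at the LK solution's background mean reproduces the LK fit", {
  d <- cached_sim("cat1_linear", 500, 5000, seed = 101)
  fam <- fit_family("logistic", 1)
  lk <- fit_lk(d, fam, n_starts = 3, seed = 4)
  pi_lk <- mean(fitted_probability(lk, d$B))
  clk <- fit_clk(d, fam, pi_lk, n_starts = 3, seed = 4)
  expect_equal(clk$loglik, lk$loglik, tolerance = 1e-6)
})

test_that("refined CLK is deterministic and exactly linear in q", {
  d <- cached_sim("cat3_quadratic", 400, 4000, seed = 111)
  fam <- fit_family("logistic", 2)
  r1 <- fit_refined_clk(d, fam, local_knowledge(q = 0.8),
                        classifier_config(seed = 1), seed = 55)
  r2 <- fit_refined_clk(d, fam, local_knowledge(q = 0.8),
                        classifier_config(seed = 1), seed = 55)
  expect_identical(r1$fit$beta, r2$fit$beta)
  expect_identical(r1$prevalence$pi_hat, r2$prevalence$pi_hat)
  # scaling q rescales the prevalence estimate exactly (same scores)
  r3 <- fit_refined_clk(d, fam, local_knowledge(q = 0.8 * 1.1),
                        classifier_config(seed = 1), seed = 55)
  expect_equal(r3$prevalence$pi_hat, 1.1 * r1$prevalence$pi_hat,
               tolerance = 1e-12)
})

test_that("fit results serialize to JSON", {
  d <- cached_sim("cat1_linear", 500, 5000, seed = 101)
  f <- fit_lk(d, fit_family("logistic", 1), n_starts = 2, seed = 1)
  path <- withr::local_tempfile(fileext = ".json")
  fit_to_json(f, path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(doc$beta, f$beta, tolerance = 1e-12)
  expect_identical(doc$method, "lk")
})
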