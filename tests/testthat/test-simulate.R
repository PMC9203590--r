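test_that("background draws are reproducible, bounded and centred", {
  b1 <- draw_background(1e5, c(-1, 1), seed = 11)
  b2 <- draw_background(1e5, c(-1, 1), seed = 11)
  expect_identical(b1, b2)
  expect_true(all(b1 >= -1 & b1 <= 1))
  expect_lt(abs(mean(b1)), 0.02)
  b3 <- draw_background(100, c(0, 1), seed = 3)
  expect_true(all(b3 >= 0 & b3 <= 1))
  expect_error(draw_background(10, c(1, -1), seed = 1), "bound")
})

test_that("presence draws follow the use-weighted covariate density", {
  # p == 1 everywhere: acceptance is certain, output is uniform
  flat <- rspf_model("exponential", c(0, 0), 1L, domain = c(-1, 1))
  x <- draw_presence(1e5, flat, seed = 5)
  expect_lt(abs(mean(x)), 0.02)
  # decreasing function: presences shift left of the background
  m <- catalog_model("cat1_linear")
  xp <- draw_presence(2e4, m, seed = 9)
  # independent oracle: E[x | y = 1] by numeric quadrature of x p(x)/int p
  num <- stats::integrate(function(t) t * evaluate_probability(m, t), -1, 1)$value
  den <- stats::integrate(function(t) evaluate_probability(m, t), -1, 1)$value
  expect_equal(mean(xp), num / den, tolerance = 0.02)
  expect_lt(mean(xp), 0)  # strictly below the background mean of 0
  expect_identical(draw_presence(500, m, seed = 9),
                   draw_presence(500, m, seed = 9))
})

test_that("presence sampling aborts when acceptance is hopeless", {
  dead <- rspf_model("exponential", c(-50, 0), 1L, domain = c(-1, 1))
  expect_error(draw_presence(10, dead, seed = 1), "rejection sampling")
})

test_that("true_prevalence matches closed forms and scales linearly", {
  half <- rspf_model("exponential", c(log(0.5), 0), 1L, domain = c(-1, 1))
  expect_equal(true_prevalence(half), 0.5, tolerance = 1e-9)
  # closed-form antiderivative for the linear logistic:
  # int 1/(1+exp(a+bx)) dx = -(1/b) log(1 + exp(-(a+bx)))
  a <- -0.606; b <- 3.64
  F <- function(x) -log1p(exp(-(a + b * x))) / b
  expect_equal(true_prevalence(catalog_model("cat1_linear")),
               (F(1) - F(-1)) / 2, tolerance = 1e-8)
  m1 <- rspf_model("exponential", c(-2, 0.7), 1L, domain = c(0, 1))
  m2 <- rspf_model("exponential", c(-2, 0.7), 1L, scale = 0.25,
                   domain = c(0, 1))
  expect_equal(true_prevalence(m2), 0.25 * true_prevalence(m1),
               tolerance = 1e-9)
})

test_that("simulated datasets carry consistent latent truth", {
  m <- catalog_model("cat2_gaussian")
  d <- simulate_pb(m, 500, 1e5, seed = 21)
  pi_true <- true_prevalence(m)
  se <- sqrt(pi_true * (1 - pi_true) / d$n0)
  expect_lt(abs(d$p2 / d$n0 - pi_true), 3 * se)
  expect_identical(d$c_implied, d$n1 / (d$n1 + d$p2))
  # implied c approaches n1/(n1 + n0 * pi) for large n0
  expect_equal(d$c_implied, d$n1 / (d$n1 + d$n0 * pi_true),
               tolerance = 0.02)
  # reproducibility of the whole dataset
  d2 <- simulate_pb(m, 500, 1e5, seed = 21)
  expect_identical(d$P, d2$P)
  expect_identical(d$B, d2$B)
  expect_identical(d$y_latent, d2$y_latent)
})

test_that("background labels match the prevalence for every category", {
  for (nm in c("cat1_cubic", "cat3_quadratic", "hf_scaled")) {
    m <- catalog_model(nm)
    d <- simulate_pb(m, 10, 2e4, seed = 31)
    pi_true <- true_prevalence(m)
    se <- sqrt(pi_true * (1 - pi_true) / d$n0)
    expect_lt(abs(d$p2 / d$n0 - pi_true), 3 * se,
              label = paste("prevalence of", nm))
  }
})
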