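test_that("catalogue entries evaluate to their printed values", {
  cat13 <- catalog()
  # Gaussian at its mode: 0.99 * exp(0)
  expect_equal(evaluate_probability(cat13$cat2_gaussian$model, 0.5), 0.99,
               tolerance = 1e-12)
  # linear logistic at 0: 1/(1 + e^-0.606)
  expect_equal(evaluate_probability(cat13$cat1_linear$model, 0),
               1 / (1 + exp(-0.606)), tolerance = 1e-12)
  expect_equal(round(evaluate_probability(cat13$cat1_linear$model, 0), 4),
               0.6470)
  # the scaled logistic pair: exactly half at every point
  x <- seq(-2.5, 2.5, length.out = 11)
  expect_identical(evaluate_probability(cat13$hf_scaled$model, x),
                   0.5 * evaluate_probability(cat13$hf_full$model, x))
  expect_equal(evaluate_probability(cat13$hf_full$model, 1), 0.5)
  expect_equal(evaluate_probability(cat13$hf_scaled$model, 1), 0.25)
})

test_that("scaling law holds to machine precision", {
  base <- rspf_model("exponential", c(-1, 0.5, -0.3), 2L, domain = c(0, 1))
  double <- rspf_model("exponential", c(-1, 0.5, -0.3), 2L, scale = 2,
                       domain = c(0, 1), validate = FALSE)
  x <- seq(0, 1, length.out = 101)
  expect_identical(evaluate_probability(double, x),
                   2 * evaluate_probability(base, x))
})

test_that("catalogue has 13 entries with the stated domains and maxima", {
  cat13 <- catalog()
  expect_length(cat13, 13L)
  for (nm in c("cat1_linear", "cat1_quadratic", "cat1_cubic",
               "cat3_linear", "cat3_quadratic", "cat3_cubic")) {
    expect_equal(unname(cat13[[nm]]$model$domain), rbind(-1, 1))
  }
  for (nm in c("cat2_scaled_logistic", "cat2_gaussian", "cat2_exponential")) {
    expect_equal(unname(cat13[[nm]]$model$domain), rbind(0, 1))
  }
  expect_equal(unname(cat13$hf_full$model$domain), rbind(-2.5, 2.5))
  expect_equal(unname(cat13$twocov_full$model$domain),
               cbind(c(-1, 1), c(-1, 1)))
  # stored maxima agree with the grid+polish search to 4 decimals
  for (e in cat13) {
    mx <- max_probability(e$model, 100001L)
    expect_equal(mx$max, e$true_max, tolerance = 1e-4,
                 label = paste("max of", e$name))
  }
})

test_that("max_probability agrees with a brute-force scan", {
  cat13 <- catalog()
  for (e in cat13) {
    d <- ncol(e$model$domain)
    n <- if (d == 1L) 1000001L else 2001L  # per-axis for d = 2
    lo <- e$model$domain[1L, ]; hi <- e$model$domain[2L, ]
    grid <- as.matrix(expand.grid(lapply(seq_len(d), function(j)
      seq(lo[j], hi[j], length.out = n)), KEEP.OUT.ATTRS = FALSE))
    brute <- max(evaluate_probability(e$model, grid))
    expect_equal(max_probability(e$model, 100001L)$max, brute,
                 tolerance = 1e-4, label = paste("brute-force max of", e$name))
  }
})

test_that("validate_model flags out-of-range probabilities", {
  ok <- rspf_model("logistic", c(4, -2), 1L, scale = 8.3, domain = c(0, 1))
  rep_ok <- validate_model(ok, 10001L)
  expect_true(rep_ok$valid)
  expect_equal(rep_ok$max, 8.3 / (1 + exp(2)), tolerance = 1e-6)
  # widening the domain pushes the scaled logistic far above 1
  wide <- rspf_model("logistic", c(4, -2), 1L, scale = 8.3,
                     domain = c(0, 10), validate = FALSE)
  rep_bad <- validate_model(wide, 10001L)
  expect_false(rep_bad$valid)
  expect_gt(rep_bad$max, 1)
  # and the constructor refuses it outright
  expect_error(rspf_model("logistic", c(4, -2), 1L, scale = 8.3,
                          domain = c(0, 10)), "not a probability")
})

test_that("evaluation guards the domain and coefficient sanity", {
  m <- catalog_model("cat1_linear")
  expect_error(evaluate_probability(m, 1.5), "outside the model domain")
  expect_silent(evaluate_probability(m, 1.5, allow_extrapolation = TRUE))
  expect_error(rspf_model("logistic", c(NA, 1), 1L, domain = c(-1, 1)),
               "non-finite")
  expect_error(rspf_model("logistic", c(0, 1), 1L, scale = -1,
                          domain = c(-1, 1)), "positive")
})

test_that("catalogue JSON round-trips", {
  path <- withr::local_tempfile(fileext = ".json")
  catalog_to_json(path)
  back <- catalog_from_json(path)
  expect_identical(names(back), names(catalog()))
  x <- seq(-1, 1, length.out = 7)
  expect_equal(evaluate_probability(back$cat3_cubic$model, x),
               evaluate_probability(catalog_model("cat3_cubic"), x))
  expect_equal(back$hf_scaled$model$scale, 0.5)
})
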