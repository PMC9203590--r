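test_that("rmse_curve measures pointwise error on the evaluation grid", {
  m <- catalog_model("cat1_linear")
  expect_equal(rmse_curve(function(x) evaluate_probability(m, x), m), 0)
  expect_equal(rmse_curve(function(x) evaluate_probability(m, x) + 0.1, m),
               0.1, tolerance = 1e-12)
  # halving a constant 0.8 function leaves a constant error of 0.4
  const <- rspf_model("exponential", c(log(0.8), 0), 1L, domain = c(0, 1))
  expect_equal(rmse_curve(function(x) 0.5 * evaluate_probability(const, x),
                          const), 0.4, tolerance = 1e-12)
  expect_error(rmse_curve(function(x) rep(NaN, nrow(x)), m), "non-finite")
})

test_that("run_experiment is reproducible and accounts for every replicate", {
  cfg <- experiment_config("cat1_linear", n1 = 200, n0 = 2000, reps = 2,
                           methods = c("lk", "clk_known_pi"), seed = 17,
                           n_starts = 2)
  r1 <- run_experiment(cfg)
  r2 <- run_experiment(cfg)
  expect_identical(r1$records, r2$records)
  expect_equal(nrow(r1$records), 2 * 2)   # reps x methods, none dropped
  for (s in r1$summaries) {
    rec <- r1$records[r1$records$method == s$method, ]
    expect_identical(s$nonconvergence_rate, sum(!rec$converged) / cfg$reps)
  }
})

test_that("mean fitted curves track the truth for a Category 1 function", {
  cfg <- experiment_config("cat1_linear", n1 = 500, n0 = 5000, reps = 8,
                           methods = c("lk", "refined_clk"), seed = 23,
                           n_starts = 3)
  rep_ <- run_experiment(cfg)
  for (m in cfg$methods) {
    s <- rep_$summaries[[m]]
    expect_true(all(abs(s$mean_curve - rep_$p_true) < 0.08),
                label = paste("mean curve of", m))
  }
})

test_that("the study suite encodes the published design", {
  suite <- paper_suite(reps = 10)
  # local-knowledge values assigned to Category 3 functions
  expect_equal(suite$cat3_lkn_cat3_cubic$lkn$q, 0.75)
  expect_equal(suite$cat3_lkn_cat3_quadratic$lkn$q, 0.8)
  expect_equal(suite$cat3_lkn_cat3_linear$lkn$q, 0.83)
  # the full/scaled logistic ladder of sample sizes
  ladder <- grep("^hf_suite_hf_scaled", names(suite), value = TRUE)
  sizes <- t(vapply(suite[ladder], function(cf) c(cf$n1, cf$n0), numeric(2)))
  expect_setequal(paste(sizes[, 1], sizes[, 2]),
                  c("50 5000", "500 5000", "5000 50000"))
  expect_equal(suite$hf_suite_hf_full_50_5000$lkn$q, 0.8)
  expect_equal(suite$hf_suite_hf_scaled_50_5000$lkn$q, 0.4)
  # every config echoes its generating function's domain
  for (cf in suite) {
    expect_identical(cf$domain, catalog()[[cf$function_id]]$model$domain)
  }
  # the very large configuration exists but is marked heavy
  heavy <- vapply(suite, `[[`, TRUE, "heavy")
  expect_true(any(heavy))
  expect_true(all(vapply(suite[heavy], function(cf) cf$n1 >= 50000, TRUE)))
  # mis-specification configs scale q by the stated +-10%
  expect_equal(suite[["cat3_lkn_misspec_cat3_cubic_0.9"]]$q_effective,
               0.75 * 0.9)
  expect_equal(suite[["cat3_lkn_misspec_cat3_cubic_1.1"]]$q_effective,
               0.75 * 1.1)
})

test_that("summaries flatten into the documented comparison table", {
  cfg <- experiment_config("cat1_linear", n1 = 200, n0 = 2000, reps = 2,
                           methods = "clk_known_pi", seed = 17, n_starts = 2)
  rep_ <- run_experiment(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  tab <- summarize_experiments(list(demo = rep_), path = path)
  expect_identical(names(tab),
                   c("experiment", "function_id", "method", "n1", "n0",
                     "reps", "rmse_mean", "rmse_median",
                     "nonconvergence_rate"))
  expect_identical(tab$experiment, "demo")
  expect_identical(tab$rmse_median[1],
                   rep_$summaries$clk_known_pi$rmse_median)
  back <- utils::read.csv(path)
  expect_identical(names(back), names(tab))
})

test_that("erroneously assuming local certainty inflates the level but keeps the ranking", {
  # q = 1 imposed on the scaled logistic whose true maximum is 0.41
  m <- catalog_model("hf_scaled")
  fam <- fit_family("logistic", 1)
  maxima <- numeric(3); spearman <- numeric(3)
  for (r in 1:3) {
    d <- simulate_pb(m, 2000, 20000, seed = 130 + r)
    rf <- fit_refined_clk(d, fam, local_knowledge(q = 1),
                          classifier_config(seed = r), seed = 200 + r,
                          n_starts = 3)
    grid <- matrix(seq(-2.5, 2.5, length.out = 201))
    pf <- fitted_probability(rf, grid)
    maxima[r] <- max(pf)
    spearman[r] <- stats::cor(pf, evaluate_probability(m, grid),
                              method = "spearman")
  }
  expect_gt(mean(maxima), 0.408787)       # overestimation of the level
  expect_true(all(spearman >= 0.95))      # ordering preserved
})
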