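#' Simulation experiments: replication, RMSE curves, nonconvergence
#'
#' The experiment engine replays the estimator-comparison design: for a
#' chosen generating function and sample sizes it simulates fresh
#' presence-background data each replicate, fits the requested methods, and
#' records the RMSE of fitted against true probabilities on an evaluation
#' grid together with convergence flags and prevalence estimates.
#'
#' @name experiment_engine
NULL

#' Experiment configuration
#'
#' @param function_id catalogue entry name (see [catalog()]).
#' @param n1,n0 presence / background sample sizes.
#' @param reps number of replicates (>= 1).
#' @param methods subset of `"lk"`, `"clk_known_pi"`, `"refined_clk"`.
#' @param fit_links named list of links per method; defaults fit logistic
#'   families of matching degree everywhere, except exponential for the
#'   refined/constrained fits on Category 2 entries (set explicitly in
#'   [paper_suite()]).
#' @param degree polynomial degree of the fitted families (defaults to the
#'   generating polynomial's degree).
#' @param lkn a [local_knowledge]; its `q` is multiplied by
#'   `misspec_factor`.
#' @param misspec_factor local-knowledge mis-specification factor
#'   (0.9 / 1.0 / 1.1 in the mis-specification study).
#' @param classifier a [classifier_config] for the refined pipeline.
#' @param seed master seed; replicate r uses sub-seed r.
#' @param grid_size evaluation grid points (default 1001).
#' @param n_starts optimizer starts per fit.
#' @param heavy marker for long-running configs (excluded from quick runs).
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(function_id, n1 = 5000L, n0 = 50000L,
                              reps = 1000L,
                              methods = c("lk", "refined_clk"),
                              fit_links = list(),
                              degree = NULL,
                              lkn = local_knowledge(),
                              misspec_factor = 1,
                              classifier = classifier_config(),
                              seed = 1L, grid_size = 1001L,
                              n_starts = 5L, heavy = FALSE) {
  stopifnot(reps >= 1L, grid_size >= 2L, misspec_factor > 0)
  entry <- catalog()[[function_id]]
  if (is.null(entry)) stop("unknown catalogue entry '", function_id, "'")
  methods <- match.arg(methods, c("lk", "clk_known_pi", "refined_clk"),
                       several.ok = TRUE)
  if (is.null(degree)) degree <- entry$model$degree
  links <- list(lk = "logistic", clk_known_pi = "logistic",
                refined_clk = "logistic")
  links[names(fit_links)] <- fit_links
  q_eff <- min(1, lkn$q * misspec_factor)
  structure(
    list(function_id = function_id, model = entry$model,
         domain = entry$model$domain, true_max = entry$true_max,
         n1 = as.integer(n1), n0 = as.integer(n0), reps = as.integer(reps),
         methods = methods, fit_links = links, degree = degree,
         lkn = lkn, misspec_factor = misspec_factor, q_effective = q_eff,
         classifier = classifier, seed = as.integer(seed),
         grid_size = as.integer(grid_size), n_starts = as.integer(n_starts),
         heavy = heavy),
    class = "experiment_config"
  )
}

#' RMSE of a fitted probability curve against the truth
#'
#' Root mean square error of fitted versus true probabilities over
#' `grid_size` equally spaced points on the truth's domain (a tensor grid
#' for more than one covariate).
#'
#' @param fit a `clk_fit` / `refined_clk_fit`, or any function mapping a
#'   covariate matrix to probabilities.
#' @param truth the generating [rspf_model].
#' @param grid_size number of grid points (default 1001).
#' @return the RMSE (scalar).
#' @export
rmse_curve <- function(fit, truth, grid_size = 1001L) {
  stopifnot(inherits(truth, "rspf_model"), grid_size >= 2L)
  d <- n_covariates(truth)
  grid <- domain_grid(truth$domain, max(2L, ceiling(grid_size^(1 / d))))
  p_true <- evaluate_probability(truth, grid)
  p_fit <- if (is.function(fit)) fit(grid) else fitted_probability(fit, grid)
  if (anyNA(p_fit) || any(!is.finite(p_fit))) {
    stop("non-finite fitted probabilities on the evaluation grid")
  }
  sqrt(mean((p_fit - p_true)^2))
}

#' Run a replicated experiment
#'
#' For each replicate: a fresh [simulate_pb()] dataset (per-replicate
#' sub-seed), each requested method fitted, RMSE and convergence recorded.
#' Summary curves average converged replicates only; the nonconvergence rate
#' is reported separately.  A replicate whose fit errors is recorded as
#' nonconverged, never dropped.
#'
#' @param config an [experiment_config].
#' @return a `replication_report`: per-replicate records (data.frame) plus
#'   per-method summaries (mean curve, RMSE statistics, nonconvergence
#'   rate) and the config echo.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  model <- config$model
  d <- n_covariates(model)
  grid <- domain_grid(model$domain,
                      max(2L, ceiling(config$grid_size^(1 / d))))
  p_true <- evaluate_probability(model, grid)
  pi_true <- true_prevalence(model)
  rep_seeds <- derive_seeds(config$seed, 3L * config$reps)
  records <- list()
  curves <- lapply(config$methods, function(m)
    matrix(NA_real_, config$reps, nrow(grid)))
  names(curves) <- config$methods
  for (r in seq_len(config$reps)) {
    data <- simulate_pb(model, config$n1, config$n0,
                        seed = rep_seeds[3L * (r - 1L) + 1L],
                        model_id = config$function_id)
    for (m in config$methods) {
      fam <- fit_family(config$fit_links[[m]], config$degree)
      fit <- tryCatch(
        switch(m,
          lk = fit_lk(data, fam, n_starts = config$n_starts,
                      seed = rep_seeds[3L * (r - 1L) + 2L]),
          clk_known_pi = fit_clk(data, fam, pi0 = pi_true,
                                 n_starts = config$n_starts,
                                 seed = rep_seeds[3L * (r - 1L) + 2L]),
          refined_clk = fit_refined_clk(
            data, fam,
            lkn = local_knowledge(config$q_effective,
                                  config$lkn$percentile,
                                  config$lkn$aggregator),
            classifier = config$classifier,
            seed = rep_seeds[3L * (r - 1L) + 3L],
            oracle_model = if (config$classifier$kind == "oracle") model,
            n_starts = config$n_starts)),
        error = function(e) e
      )
      if (inherits(fit, "error")) {
        records[[length(records) + 1L]] <- data.frame(
          replicate = r, method = m, converged = FALSE, rmse = NA_real_,
          pi_hat = NA_real_, loglik = NA_real_,
          error = conditionMessage(fit))
        next
      }
      core <- if (inherits(fit, "refined_clk_fit")) fit$fit else fit
      pf <- family_probability(core$family, core$beta, grid)
      rm_ <- if (all(is.finite(pf))) sqrt(mean((pf - p_true)^2)) else NA_real_
      pi_hat <- if (inherits(fit, "refined_clk_fit")) {
        fit$prevalence$pi_hat
      } else if (core$method == "clk") {
        core$pi_constraint
      } else {
        mean(family_probability(core$family, core$beta, data$B))
      }
      if (core$converged && all(is.finite(pf))) curves[[m]][r, ] <- pf
      records[[length(records) + 1L]] <- data.frame(
        replicate = r, method = m, converged = core$converged, rmse = rm_,
        pi_hat = pi_hat, loglik = core$loglik, error = NA_character_)
    }
  }
  records <- do.call(rbind, records)
  summaries <- lapply(config$methods, function(m) {
    rec <- records[records$method == m, ]
    conv <- rec$converged
    mean_curve <- if (any(conv)) {
      colMeans(curves[[m]][which(conv), , drop = FALSE])
    } else {
      rep(NA_real_, nrow(grid))
    }
    rr <- rec$rmse[conv]
    list(method = m,
         mean_curve = mean_curve,
         rmse_mean = if (length(rr)) mean(rr) else NA_real_,
         rmse_median = if (length(rr)) stats::median(rr) else NA_real_,
         rmse_q25 = if (length(rr)) unname(stats::quantile(rr, 0.25)) else NA_real_,
         rmse_q75 = if (length(rr)) unname(stats::quantile(rr, 0.75)) else NA_real_,
         nonconvergence_rate = sum(!conv) / config$reps,
         curve_all_converged = all(conv))
  })
  names(summaries) <- config$methods
  structure(
    list(config = config, grid = grid, p_true = p_true, pi_true = pi_true,
         records = records, summaries = summaries),
    class = "replication_report"
  )
}

#' @export
print.replication_report <- function(x, ...) {
  cat("Replication report:", x$config$function_id,
      sprintf("(n1 = %d, n0 = %d, reps = %d)\n",
              x$config$n1, x$config$n0, x$config$reps))
  for (s in x$summaries) {
    cat(sprintf("  %-14s RMSE mean %.4f median %.4f  nonconvergence %.1f%%\n",
                s$method, s$rmse_mean, s$rmse_median,
                100 * s$nonconvergence_rate))
  }
  invisible(x)
}

#' The full study's experiment configurations
#'
#' Named, fully specified configurations reproducing the simulation design:
#' the three categories at the main (5000/50000) and small (250/5000)
#' sample sizes, local-knowledge runs for Category 3 with and without
#' mis-specification, the erroneous local-certainty variant, the full/scaled
#' logistic pair across its sample-size ladder, and a very large
#' (50000/500000) configuration flagged `heavy`.
#'
#' @param reps replicates per configuration (default 1000; scale down for
#'   quick runs).
#' @param seed base seed (each config gets a distinct derived seed).
#' @return named list of [experiment_config] objects.
#' @export
paper_suite <- function(reps = 1000L, seed = 20220616L) {
  seeds <- derive_seeds(seed, 64L)
  i <- 0L
  nxt <- function() { i <<- i + 1L; seeds[i] }
  cfgs <- list()
  cat1 <- c("cat1_linear", "cat1_quadratic", "cat1_cubic")
  cat2 <- c("cat2_scaled_logistic", "cat2_gaussian", "cat2_exponential")
  cat3 <- c("cat3_linear", "cat3_quadratic", "cat3_cubic")
  cat3_q <- c(cat3_linear = 0.83, cat3_quadratic = 0.8, cat3_cubic = 0.75)
  for (f in cat1) {
    cfgs[[paste0("cat1_main_", f)]] <- experiment_config(
      f, 5000L, 50000L, reps, c("lk", "refined_clk"), seed = nxt())
    cfgs[[paste0("cat1_small_", f)]] <- experiment_config(
      f, 250L, 5000L, reps, c("lk", "refined_clk"), seed = nxt())
  }
  for (f in cat2) {
    cfgs[[paste0("cat2_main_", f)]] <- experiment_config(
      f, 5000L, 50000L, reps, c("lk", "refined_clk"),
      fit_links = list(refined_clk = "exponential"),
      degree = if (f == "cat2_scaled_logistic") 1L else NULL,
      seed = nxt())
  }
  for (f in cat3) {
    cfgs[[paste0("cat3_lkn_", f)]] <- experiment_config(
      f, 5000L, 50000L, reps, c("lk", "refined_clk"),
      lkn = local_knowledge(q = cat3_q[[f]]), seed = nxt())
    for (fac in c(0.9, 1.1)) {
      cfgs[[sprintf("cat3_lkn_misspec_%s_%g", f, fac)]] <- experiment_config(
        f, 5000L, 50000L, reps, "refined_clk",
        lkn = local_knowledge(q = cat3_q[[f]]), misspec_factor = fac,
        seed = nxt())
    }
    cfgs[[paste0("cat3_erroneous_lc_", f)]] <- experiment_config(
      f, 5000L, 50000L, reps, "refined_clk",
      lkn = local_knowledge(q = 1), seed = nxt())
    cfgs[[paste0("cat_verylarge_", f)]] <- experiment_config(
      f, 50000L, 500000L, reps, c("lk", "refined_clk"),
      lkn = local_knowledge(q = cat3_q[[f]]), seed = nxt(), heavy = TRUE)
  }
  cfgs$erroneous_lc_hf_scaled <- experiment_config(
    "hf_scaled", 5000L, 50000L, reps, "refined_clk",
    lkn = local_knowledge(q = 1), seed = nxt())
  hf_sizes <- list(c(50L, 5000L), c(500L, 5000L), c(5000L, 50000L))
  hf_q <- c(hf_full = 0.8, hf_scaled = 0.4)
  for (f in names(hf_q)) {
    for (sz in hf_sizes) {
      cfgs[[sprintf("hf_suite_%s_%d_%d", f, sz[1L], sz[2L])]] <-
        experiment_config(f, sz[1L], sz[2L], reps, c("lk", "refined_clk"),
                          lkn = local_knowledge(q = hf_q[[f]]), seed = nxt())
    }
  }
  cfgs
}

#' Summarize replication reports into a comparison table
#'
#' @param reports a list of `replication_report` objects (or a single one).
#' @param path optional CSV path to write the table to.
#' @return data.frame with columns `experiment`, `function_id`, `method`,
#'   `n1`, `n0`, `reps`, `rmse_mean`, `rmse_median`,
#'   `nonconvergence_rate`.
#' @export
summarize_experiments <- function(reports, path = NULL) {
  if (inherits(reports, "replication_report")) reports <- list(reports)
  stopifnot(length(reports) >= 1L)
  nm <- names(reports) %||% rep(NA_character_, length(reports))
  rows <- list()
  for (i in seq_along(reports)) {
    rep_ <- reports[[i]]
    for (s in rep_$summaries) {
      rows[[length(rows) + 1L]] <- data.frame(
        experiment = if (is.na(nm[i]) || nm[i] == "") rep_$config$function_id else nm[i],
        function_id = rep_$config$function_id,
        method = s$method, n1 = rep_$config$n1, n0 = rep_$config$n0,
        reps = rep_$config$reps,
        rmse_mean = s$rmse_mean, rmse_median = s$rmse_median,
        nonconvergence_rate = s$nonconvergence_rate)
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(path)) {
    utils::write.csv(format_numeric_df(out), path, row.names = FALSE,
                     quote = FALSE)
  }
  out
}

format_numeric_df <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- formatC(df[[j]], digits = 17,
                                               format = "g")
  }
  df
}
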