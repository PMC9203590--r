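#' Likelihood fitting: LK, constrained LK, and the refined pipeline
#'
#' The LK partial likelihood for presence-background data is
#' \deqn{L(\beta) = \sum_{x \in P} \ln p(x;\beta)
#'   - n_1 \ln\Big(\frac{1}{n_0}\sum_{x \in B} p(x;\beta)\Big),}
#' the background mean standing in for the prevalence.  Because a
#' multiplicative rescaling of \eqn{p} cancels between the two terms, the
#' likelihood cannot distinguish a probability function from any scaled
#' version of it; [lk_loglik()] therefore evaluates the scale-free form (the
#' cancellation is exact, not approximate).
#'
#' The constrained LK (CLK) method maximizes the same likelihood subject to
#' \eqn{\frac{1}{n_0}\sum_B p(x;\beta) = \pi_0} for a given prevalence
#' \eqn{\pi_0}.  The constraint is handled by profiling the intercept: for
#' every supported link the background mean is strictly monotone in
#' \eqn{\beta_0}, so the constraint surface is the graph of a scalar root
#' over the remaining coefficients, and on it the objective reduces to
#' \eqn{\sum_P \ln p - n_1 \ln \pi_0}.
#'
#' @name likelihood_fitting
NULL

#' Fitting family: link plus polynomial degree
#'
#' Fitted families are unscaled (`k = 1`); scale is intentionally not a free
#' parameter, since the LK likelihood cannot see it.
#'
#' @param link `"logistic"`, `"exponential"` or `"cloglog"` (printed-form
#'   conventions of [rspf_model]).
#' @param degree polynomial degree per covariate (>= 1).
#' @return a `fit_family` list.
#' @export
fit_family <- function(link = c("logistic", "exponential", "cloglog"),
                       degree = 1L) {
  link <- match.arg(link)
  degree <- as.integer(degree)
  stopifnot(all(degree >= 1L))
  structure(list(link = link, degree = degree,
                 n_beta = 1L + sum(degree)),
            class = "fit_family")
}

family_probability <- function(family, beta, x) {
  link_transform(family$link, drop(poly_design(x, family$degree) %*% beta))
}

#' LK log-likelihood
#'
#' @param beta coefficient vector (`1 + sum(degree)` entries, intercept
#'   first).
#' @param family a [fit_family].
#' @param data a [pb_dataset].
#' @param floor probabilities are floored at this value before logs
#'   (default `1e-300`); a family that vanishes on all background points
#'   yields `-Inf` rather than an error.
#' @param scale multiplicative scale `k` applied to the family.  It cancels
#'   from the likelihood *analytically*, so any positive value returns the
#'   identical number: this argument exists to make the scale blindness of
#'   the LK likelihood an explicit, testable contract.
#' @return the log-likelihood value (scalar).
#' @export
lk_loglik <- function(beta, family, data, floor = 1e-300, scale = 1) {
  stopifnot(is.numeric(scale), length(scale) == 1L, scale > 0)
  stopifnot(inherits(family, "fit_family"), inherits(data, "pb_dataset"))
  beta <- as.numeric(beta)
  if (length(beta) != family$n_beta) {
    stop("beta has length ", length(beta), "; family expects ", family$n_beta)
  }
  if (anyNA(beta) || any(!is.finite(beta))) stop("non-finite beta")
  pP <- family_probability(family, beta, data$P)
  pB <- family_probability(family, beta, data$B)
  mB <- mean(pB)
  if (!is.finite(mB) || mB <= 0) return(-Inf)
  sum(log(pmax(pP, floor))) - data$n1 * log(pmax(mB, floor))
}

# smooth validity penalty keeping unbounded links below 1: quadratic in the
# positive part of g over P and B (g <= 0 <=> p <= 1 for the exponential)
validity_penalty <- function(family, beta, data, lambda = 1e4) {
  if (family$link != "exponential") return(0)
  g <- c(drop(poly_design(data$P, family$degree) %*% beta),
         drop(poly_design(data$B, family$degree) %*% beta))
  lambda * sum(pmax(g, 0)^2)
}

# d ln p / d g and d p / d g for each link (printed-form conventions)
link_dlogp <- function(link, g, p) {
  switch(link,
    logistic    = -(1 - p),            # p = 1/(1+e^g)
    exponential = rep(1, length(g)),
    cloglog     = exp(g - exp(g)) / pmax(p, 1e-300))
}
link_dp <- function(link, g, p) {
  switch(link,
    logistic    = -p * (1 - p),
    exponential = p,
    cloglog     = exp(g - exp(g)))
}

num_gradient <- function(f, x, h0 = 1e-6) {
  vapply(seq_along(x), function(i) {
    h <- h0 * (1 + abs(x[i]))
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

make_fit_result <- function(beta, loglik, converged, n_starts_used,
                            grad_norm, family, method,
                            constraint_residual = NA_real_,
                            pi_constraint = NA_real_, diagnostics = list()) {
  structure(
    list(beta = beta, loglik = loglik, converged = converged,
         n_starts_used = n_starts_used, grad_norm = grad_norm,
         constraint_residual = constraint_residual,
         pi_constraint = pi_constraint, family = family, method = method,
         diagnostics = diagnostics),
    class = "clk_fit"
  )
}

#' @export
print.clk_fit <- function(x, ...) {
  cat(toupper(x$method), " fit (", x$family$link, " link, degree ",
      paste(x$family$degree, collapse = "/"), ")\n", sep = "")
  cat("  beta      =", paste(signif(x$beta, 6), collapse = ", "), "\n")
  cat("  loglik    =", format(x$loglik), "\n")
  cat("  converged =", x$converged,
      sprintf(" (grad_norm %.2e)", x$grad_norm), "\n")
  if (!is.na(x$pi_constraint)) {
    cat(sprintf("  constraint: pi0 = %.6f, residual %.2e\n",
                x$pi_constraint, x$constraint_residual))
  }
  invisible(x)
}

# shared multi-start driver.  Start 1 is the zero vector; the rest are iid
# standard normal.  Best converged start wins; ties by loglik then index.
multi_start_optim <- function(objective, n_par, n_starts, seed,
                              gradient = NULL,
                              check = function(par, val, grad_norm, code)
                                list(converged = is.finite(val))) {
  grad_fn <- gradient %||% function(b) num_gradient(objective, b)
  starts <- list(rep(0, n_par))
  if (n_starts > 1L) {
    extra <- with_seed(seed, stats::rnorm((n_starts - 1L) * n_par))
    for (i in seq_len(n_starts - 1L)) {
      starts[[i + 1L]] <- extra[((i - 1L) * n_par + 1L):(i * n_par)]
    }
  }
  runs <- vector("list", n_starts)
  for (i in seq_len(n_starts)) {
    v0 <- objective(starts[[i]])
    if (!is.finite(v0)) {
      runs[[i]] <- list(par = starts[[i]], value = -Inf, code = 99L,
                        converged = FALSE, grad_norm = Inf,
                        note = "non-finite objective at start")
      next
    }
    opt <- NULL
    par0 <- starts[[i]]
    grad_norm <- Inf
    # BFGS with restarts: a restart resets the Hessian approximation,
    # which rescues stalls on stiff (penalty-active) objectives
    for (pass in 1:3) {
      o <- tryCatch(
        stats::optim(par0, function(b) -objective(b),
                     gr = if (!is.null(gradient))
                       function(b) -gradient(b),
                     method = "BFGS",
                     control = list(maxit = 500L, reltol = 1e-10)),
        error = function(e) NULL
      )
      if (is.null(o) || !is.finite(o$value)) break
      opt <- o
      par0 <- o$par
      grad <- tryCatch(grad_fn(o$par), error = function(e) rep(Inf, n_par))
      grad_norm <- max(abs(grad)) / max(1, abs(-o$value))
      if (grad_norm <= 1e-4) break
    }
    if (is.null(opt) || !is.finite(opt$value)) {
      runs[[i]] <- list(par = starts[[i]], value = -Inf, code = 98L,
                        converged = FALSE, grad_norm = Inf,
                        note = "optimizer failure")
      next
    }
    val <- -opt$value
    chk <- check(opt$par, val, grad_norm, opt$convergence)
    runs[[i]] <- list(par = opt$par, value = val, code = opt$convergence,
                      converged = isTRUE(chk$converged),
                      grad_norm = grad_norm, iterations = opt$counts[["function"]])
  }
  conv <- which(vapply(runs, `[[`, TRUE, "converged"))
  pick_from <- if (length(conv)) conv else seq_len(n_starts)
  vals <- vapply(runs[pick_from], `[[`, 0, "value")
  best <- pick_from[which.max(vals)]
  list(best = runs[[best]], runs = runs, any_converged = length(conv) > 0)
}

fit_converged_check <- function(par, val, grad_norm, code,
                                beta_bound = 50, grad_tol = 1e-3) {
  list(converged = code == 0L && is.finite(val) &&
         grad_norm <= grad_tol && max(abs(par)) <= beta_bound)
}

#' Fit the (unconstrained) LK method
#'
#' Multi-start quasi-Newton maximization of [lk_loglik()].  A fit is flagged
#' converged when the optimizer reported success, the relative gradient norm
#' is at most `1e-3`, and no coefficient exceeds 50 in absolute value (the
#' runaway-coefficient signature of the likelihood's scale blindness).  If
#' no start qualifies, the best attempt is still returned with
#' `converged = FALSE`.
#'
#' @param data a [pb_dataset].
#' @param family a [fit_family].
#' @param n_starts number of optimizer starts (default 5; start 1 is the
#'   zero vector, the rest standard-normal draws).
#' @param seed seed for the random starts.
#' @return a `clk_fit` result.
#' @export
fit_lk <- function(data, family, n_starts = 5L, seed = 1L) {
  stopifnot(inherits(data, "pb_dataset"), inherits(family, "fit_family"))
  if (degenerate_design(data, family)) {
    return(make_fit_result(rep(NA_real_, family$n_beta), -Inf, FALSE, 0L,
                           Inf, family, "lk",
                           diagnostics = list(note = "rank-deficient design")))
  }
  XP <- poly_design(data$P, family$degree)
  XB <- poly_design(data$B, family$degree)
  lambda <- 1e4
  objective <- function(beta) {
    lk_loglik(beta, family, data) - validity_penalty(family, beta, data)
  }
  gradient <- function(beta) {
    gP <- drop(XP %*% beta); gB <- drop(XB %*% beta)
    pP <- link_transform(family$link, gP)
    pB <- link_transform(family$link, gB)
    gr <- drop(crossprod(XP, link_dlogp(family$link, gP, pP))) -
      data$n1 * drop(crossprod(XB, link_dp(family$link, gB, pB))) /
        max(sum(pB), 1e-300)
    if (family$link == "exponential") {
      gr <- gr - 2 * lambda *
        (drop(crossprod(XP, pmax(gP, 0))) + drop(crossprod(XB, pmax(gB, 0))))
    }
    gr
  }
  res <- multi_start_optim(objective, family$n_beta, n_starts, seed,
                           gradient = gradient,
                           check = fit_converged_check)
  ll <- lk_loglik(res$best$par, family, data)
  make_fit_result(res$best$par, ll,
                  res$best$converged, n_starts, res$best$grad_norm,
                  family, "lk", diagnostics = res$runs)
}

degenerate_design <- function(data, family) {
  X <- poly_design(rbind(data$P, data$B), family$degree)
  qr(X)$rank < ncol(X)
}

#' Profile the intercept onto the prevalence constraint
#'
#' Finds the unique \eqn{\beta_0} with
#' \eqn{\frac{1}{n_0}\sum_B p(x;\beta_0,\beta_{rest}) = \pi_0}.  The
#' background mean is strictly monotone in \eqn{\beta_0} for every
#' supported link (decreasing for the printed-form logistic, increasing
#' for exponential and cloglog), so the root is found by bracketing
#' followed by Newton polish to residual at most `1e-10`.  For the
#' exponential link the solution is closed-form, and a `pi0` above the
#' largest background mean attainable with all probabilities at most 1 is
#' an infeasibility error reporting the attainable interval.
#'
#' @param beta_rest non-intercept coefficients (`sum(degree)` values).
#' @param family a [fit_family].
#' @param B background covariate matrix.
#' @param pi0 target prevalence in (0, 1).
#' @param enforce_valid for the exponential link, raise an infeasibility
#'   error when no intercept keeps every background probability at most 1
#'   while meeting the constraint (default `TRUE`); `fit_clk()` disables
#'   this and lets its smooth validity penalty handle the excess instead,
#'   keeping the profiled objective smooth.
#' @return the intercept value `beta0`.
#' @export
profile_intercept <- function(beta_rest, family, B, pi0,
                              enforce_valid = TRUE) {
  stopifnot(inherits(family, "fit_family"), pi0 > 0, pi0 < 1)
  B <- as_points(B, length(family$degree))
  h <- drop(poly_design(B, family$degree)[, -1L, drop = FALSE] %*% beta_rest)
  if (family$link == "exponential") {
    # mean exp(b0 + h) = pi0  =>  b0 = log(pi0) - log(mean(exp(h)));
    # shift by max(h) for overflow safety.  Validity cap: with b0 at
    # -max(h) every p <= 1 and the mean is maximal among valid fits.
    hmax <- max(h)
    m0 <- mean(exp(h - hmax))          # mean at b0 = -hmax (max g = 0)
    if (enforce_valid && pi0 > m0 + 1e-12) {
      stop("pi0 = ", signif(pi0, 6), " is unattainable for this ",
           "exponential family: attainable background means are (0, ",
           signif(m0, 6), "]")
    }
    return(log(pi0) - hmax - log(m0))
  }
  mean_p <- function(b0) mean(link_transform(family$link, b0 + h))
  increasing <- family$link != "logistic"
  f <- function(b0) mean_p(b0) - pi0
  lo <- -800 - max(h); hi <- 800 - min(h)
  root <- stats::uniroot(f, lower = lo, upper = hi, tol = 1e-12,
                         f.lower = f(lo), f.upper = f(hi))$root
  # Newton polish with the analytic derivative of the background mean
  for (it in 1:20) {
    g <- root + h
    p <- link_transform(family$link, g)
    resid <- mean(p) - pi0
    if (abs(resid) <= 1e-12) break
    dp <- if (family$link == "logistic") {
      -mean(p * (1 - p))
    } else {                             # cloglog
      mean(exp(g - exp(g)))
    }
    if (!is.finite(dp) || dp == 0) break
    root <- root - resid / dp
  }
  if (abs(mean_p(root) - pi0) > 1e-10) {
    stop("intercept profiling failed to reach the constraint (residual ",
         signif(abs(mean_p(root) - pi0), 3), ")")
  }
  root
}

#' Fit the constrained LK (CLK) method
#'
#' Maximizes the LK likelihood subject to the background mean of the fitted
#' probabilities equalling `pi0`.  The intercept is profiled onto the
#' constraint at every objective evaluation, so every returned fit satisfies
#' the constraint to `1e-8` or better; on the constraint surface the
#' objective is \eqn{\sum_P \ln p - n_1 \ln \pi_0}.  Regions where `pi0` is
#' unattainable (exponential link) are handled by a penalty; if it is
#' unattainable everywhere the fit is returned with `converged = FALSE`.
#'
#' @param data a [pb_dataset].
#' @param family a [fit_family].
#' @param pi0 prevalence constraint in (0, 1).
#' @param n_starts,seed multi-start policy as in [fit_lk()].
#' @return a `clk_fit` with `pi_constraint` and `constraint_residual`.
#' @export
fit_clk <- function(data, family, pi0, n_starts = 5L, seed = 1L) {
  stopifnot(inherits(data, "pb_dataset"), inherits(family, "fit_family"),
            pi0 > 0, pi0 < 1)
  if (degenerate_design(data, family)) {
    return(make_fit_result(rep(NA_real_, family$n_beta), -Inf, FALSE, 0L,
                           Inf, family, "clk", pi_constraint = pi0,
                           diagnostics = list(note = "rank-deficient design")))
  }
  m <- family$n_beta - 1L
  n1 <- data$n1
  full_beta <- function(rest) {
    b0 <- tryCatch(
      profile_intercept(rest, family, data$B, pi0, enforce_valid = FALSE),
      error = function(e) NA_real_)
    if (!is.finite(b0)) return(NULL)
    c(b0, rest)
  }
  XP <- poly_design(data$P, family$degree)
  XB <- poly_design(data$B, family$degree)
  lambda <- 1e4
  objective <- function(rest) {
    beta <- full_beta(rest)
    if (is.null(beta)) return(-Inf)
    pP <- family_probability(family, beta, data$P)
    sum(log(pmax(pP, 1e-300))) - n1 * log(pi0) -
      validity_penalty(family, beta, data)
  }
  # gradient of the profiled objective: the intercept moves with beta_rest
  # along the constraint surface, db0/drest = -mean(dp.X)/mean(dp) on B
  gradient <- function(rest) {
    beta <- full_beta(rest)
    if (is.null(beta)) return(rep(NA_real_, m))
    gP <- drop(XP %*% beta); gB <- drop(XB %*% beta)
    pP <- link_transform(family$link, gP)
    pB <- link_transform(family$link, gB)
    dpB <- link_dp(family$link, gB, pB)
    denom <- sum(dpB)
    db0 <- if (abs(denom) < 1e-300) {
      rep(0, m)
    } else {
      -drop(crossprod(XB[, -1L, drop = FALSE], dpB)) / denom
    }
    dlP <- link_dlogp(family$link, gP, pP)
    gr <- drop(crossprod(XP[, -1L, drop = FALSE], dlP)) + sum(dlP) * db0
    if (family$link == "exponential") {
      gpP <- pmax(gP, 0); gpB <- pmax(gB, 0)
      gr <- gr - 2 * lambda * (
        drop(crossprod(XP[, -1L, drop = FALSE], gpP)) + sum(gpP) * db0 +
        drop(crossprod(XB[, -1L, drop = FALSE], gpB)) + sum(gpB) * db0)
    }
    gr
  }
  res <- multi_start_optim(objective, m, n_starts, seed,
                           gradient = gradient,
                           check = function(par, val, grad_norm, code) {
                             ok <- fit_converged_check(par, val, grad_norm,
                                                       code)$converged
                             list(converged = ok && !is.null(full_beta(par)))
                           })
  beta <- full_beta(res$best$par)
  if (is.null(beta)) {
    return(make_fit_result(c(NA_real_, res$best$par), -Inf, FALSE, n_starts,
                           res$best$grad_norm, family, "clk",
                           constraint_residual = Inf, pi_constraint = pi0,
                           diagnostics = res$runs))
  }
  residual <- abs(mean(family_probability(family, beta, data$B)) - pi0)
  converged <- res$best$converged && residual <= 1e-8 &&
    max(abs(beta)) <= 50
  make_fit_result(beta, lk_loglik(beta, family, data), converged, n_starts,
                  res$best$grad_norm, family, "clk",
                  constraint_residual = residual, pi_constraint = pi0,
                  diagnostics = res$runs)
}

#' Refined CLK: classifier, prevalence, constrained fit
#'
#' The full three-step pipeline: (1) train the Pr(s=1|x) classifier on the
#' pooled presence/background rows and score them; (2) rank the scores,
#' aggregate over the top share, and convert to a prevalence estimate using
#' the local-knowledge probability `q`; (3) fit CLK with the estimated
#' prevalence as the constraint.
#'
#' @param data a [pb_dataset].
#' @param family a [fit_family] for the CLK fit.
#' @param lkn a [local_knowledge] specification.
#' @param classifier a [classifier_config]; kind `"oracle"` uses the exact
#'   case-control scores and requires `oracle_model` plus latent truth in
#'   `data` (testing only).
#' @param seed master seed (classifier initialisation and optimizer starts
#'   use derived sub-seeds).
#' @param oracle_model generating [rspf_model], only for the oracle
#'   classifier.
#' @param n_starts optimizer starts for the CLK step.
#' @return a `refined_clk_fit`: list with `scores`, `prevalence`, `fit`,
#'   and a `suspicious` flag (set when the prevalence estimate was capped).
#' @export
fit_refined_clk <- function(data, family, lkn = local_knowledge(),
                            classifier = classifier_config(), seed = 1L,
                            oracle_model = NULL, n_starts = 5L) {
  stopifnot(inherits(data, "pb_dataset"))
  seeds <- derive_seeds(seed, 2L)
  if (classifier$kind == "oracle") {
    if (is.null(oracle_model) || is.na(data$c_implied)) {
      stop("oracle classifier requires oracle_model and latent truth")
    }
    scores <- oracle_scores(oracle_model, data$c_implied,
                            rbind(data$P, data$B), eps = classifier$eps,
                            n1 = data$n1, n0 = data$n0)
  } else {
    cfg <- classifier
    cfg$seed <- seeds[1L]
    scorer <- fit_s_classifier(data, cfg)
    scores <- scorer$train_scores
    scores$n1 <- data$n1; scores$n0 <- data$n0
  }
  prev <- prevalence_from_scores(scores, lkn)
  pi0 <- prev$pi_hat
  if (pi0 >= 1) pi0 <- 1 - 1e-6
  fit <- fit_clk(data, family, pi0, n_starts = n_starts, seed = seeds[2L])
  structure(
    list(scores = scores, prevalence = prev, fit = fit,
         suspicious = isTRUE(prev$capped),
         provenance = list(seed = seed, sub_seeds = seeds,
                           lkn = unclass(lkn),
                           classifier = classifier$kind)),
    class = "refined_clk_fit"
  )
}

#' @export
print.refined_clk_fit <- function(x, ...) {
  cat("Refined CLK fit\n")
  print(x$prevalence)
  print(x$fit)
  if (isTRUE(x$suspicious)) cat("  [suspicious: prevalence estimate capped]\n")
  invisible(x)
}

#' Evaluate the fitted probability function of a fit
#'
#' @param fit a `clk_fit` (or `refined_clk_fit`).
#' @param points covariate points.
#' @return numeric vector of fitted probabilities (raw link values; an
#'   exponential-link fit may marginally exceed 1).
#' @export
fitted_probability <- function(fit, points) {
  if (inherits(fit, "refined_clk_fit")) fit <- fit$fit
  stopifnot(inherits(fit, "clk_fit"))
  x <- as_points(points, length(fit$family$degree))
  family_probability(fit$family, fit$beta, x)
}

#' Serialize a fit result to JSON
#' @param fit a `clk_fit` or `refined_clk_fit`.
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
fit_to_json <- function(fit, path) {
  doc <- if (inherits(fit, "refined_clk_fit")) {
    list(type = "refined_clk",
         prevalence = unclass(fit$prevalence)[c("c_hat", "pi_hat", "q",
                                                "capped")],
         suspicious = fit$suspicious,
         fit = fit_fields(fit$fit))
  } else {
    fit_fields(fit)
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

fit_fields <- function(fit) {
  list(method = fit$method, link = fit$family$link,
       degree = fit$family$degree, beta = fit$beta, loglik = fit$loglik,
       converged = fit$converged, grad_norm = fit$grad_norm,
       constraint_residual = fit$constraint_residual,
       pi_constraint = fit$pi_constraint)
}
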