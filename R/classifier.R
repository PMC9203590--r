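#' Classifier for the sampling-stratum probability Pr(s=1|x)
#'
#' Step 1 of the refined CLK pipeline: pool the presence rows (s = 1) and
#' background rows (s = 0) and fit a binary classifier for the probability
#' of a site belonging to the presence sample.  Under case-control sampling
#' \deqn{\Pr(s=1\mid x) = \frac{1}{1 + \frac{1-c}{c}\cdot\frac{1}{p(x)}},}
#' an increasing function of the presence probability \eqn{p(x)}, so the
#' top-ranked scores identify the most suitable sites and their level
#' carries the labelling frequency \eqn{c}.
#'
#' Two calibration requirements shape the defaults and are not tunable
#' conveniences: the training loss is a plain per-row average log loss with
#' no class rebalancing (the score level must reflect the actual n1:n0
#' design), and scores are clipped to `[eps, 1-eps]` to protect downstream
#' ratios.  Covariates are standardized inside the classifier only.
#'
#' @name s_classifier
NULL

#' Classifier configuration
#'
#' @param kind `"neural_net"` (single-hidden-layer feed-forward network,
#'   the default), `"logistic_main_effects"` (weak baseline), or `"oracle"`
#'   (the exact case-control formula; requires the generating model and `c`,
#'   testing/diagnostics only).
#' @param hidden_units hidden layer size for the network (default 8).
#' @param decay ridge (weight-decay) strength on the per-row average loss
#'   (default `1e-5`).
#' @param maxit maximum training iterations (default 500).
#' @param eps score clipping constant in `(0, 0.01]` (default `1e-6`).
#' @param seed seed for weight initialisation.
#' @return a `classifier_config` list.
#' @export
classifier_config <- function(kind = c("neural_net", "logistic_main_effects",
                                       "oracle"),
                              hidden_units = 8L, decay = 1e-5,
                              maxit = 500L, eps = 1e-6, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(eps > 0, eps <= 0.01, hidden_units >= 1L, maxit >= 1L, decay >= 0)
  structure(list(kind = kind, hidden_units = as.integer(hidden_units),
                 decay = decay, maxit = as.integer(maxit), eps = eps,
                 seed = as.integer(seed)),
            class = "classifier_config")
}

#' Fit the Pr(s=1|x) classifier on pooled presence and background rows
#'
#' @param data a [pb_dataset] with `n1 >= 10` and `n0 >= 10`.
#' @param config a [classifier_config].
#' @return an `s_scorer` with a stored score vector for the training rows
#'   (presence rows first, then background), retrievable with [score()].
#' @export
fit_s_classifier <- function(data, config = classifier_config()) {
  stopifnot(inherits(data, "pb_dataset"))
  if (data$n1 < 10L || data$n0 < 10L) {
    stop("need at least 10 presence and 10 background rows")
  }
  x <- rbind(data$P, data$B)
  s <- c(rep(1, data$n1), rep(0, data$n0))
  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  scl[scl == 0] <- 1
  xs <- sweep(sweep(x, 2L, ctr, `-`), 2L, scl, `/`)
  n <- nrow(xs)
  fit <- switch(config$kind,
    neural_net = {
      # per-row weights 1/n make the loss an average, so duplicating the
      # data leaves the objective (and the fit) unchanged
      f <- NULL
      for (try in 0:2) {
        f <- with_seed(config$seed + try, tryCatch(
          nnet::nnet(xs, s, size = config$hidden_units,
                     decay = config$decay, maxit = config$maxit,
                     weights = rep(1 / n, n), entropy = TRUE,
                     trace = FALSE, MaxNWts = 10000L),
          error = function(e) NULL))
        if (!is.null(f) && all(is.finite(f$wts))) break
        f <- NULL
      }
      if (is.null(f)) stop("neural network training failed repeatedly")
      f
    },
    logistic_main_effects = {
      colnames(xs) <- paste0("X", seq_len(ncol(xs)))
      df <- data.frame(s = s, xs)
      stats::glm(s ~ ., data = df, family = stats::binomial())
    },
    oracle = stop("use oracle_scores() for the oracle classifier")
  )
  scorer <- structure(
    list(kind = config$kind, fit = fit, center = ctr, scale = scl,
         eps = config$eps, d = data$d, config = config,
         n1 = data$n1, n0 = data$n0),
    class = "s_scorer"
  )
  scorer$train_scores <- score(scorer, x, n1 = data$n1, n0 = data$n0)
  scorer
}

#' Score covariate points with a fitted classifier
#'
#' @param scorer an `s_scorer` from [fit_s_classifier()].
#' @param points covariate matrix (or vector for one covariate); may be
#'   empty.
#' @param n1,n0 optional row split recorded in the result.
#' @return an `s_scores` object: clipped scores plus `n1`/`n0` metadata.
#' @export
score <- function(scorer, points, n1 = NA_integer_, n0 = NA_integer_) {
  stopifnot(inherits(scorer, "s_scorer"))
  x <- as_points(points, scorer$d)
  if (nrow(x) == 0L) {
    return(s_scores(numeric(0), n1 = 0L, n0 = 0L))
  }
  xs <- sweep(sweep(x, 2L, scorer$center, `-`), 2L, scorer$scale, `/`)
  p <- if (!is.null(scorer$json)) {
    predict_json_scorer(scorer$json, xs)
  } else {
    switch(scorer$kind,
      neural_net = as.vector(stats::predict(scorer$fit, xs)),
      logistic_main_effects = {
        colnames(xs) <- paste0("X", seq_len(ncol(xs)))
        as.vector(stats::predict(scorer$fit,
                                 newdata = as.data.frame(xs),
                                 type = "response"))
      },
      stop("unsupported scorer kind ", scorer$kind)
    )
  }
  s_scores(clip01(p, scorer$eps), n1 = n1, n0 = n0)
}

#' Exact Pr(s=1|x) under the case-control sampling formula
#'
#' The ground-truth classifier used in tests and oracle pipelines:
#' \eqn{\Pr(s=1\mid x) = 1 / (1 + \frac{1-c}{c} / p(x))}, with
#' \eqn{p(x) = 0} mapped to score 0 before clipping.
#'
#' @param model generating [rspf_model].
#' @param c labelling frequency in (0, 1).
#' @param points covariate points.
#' @param eps clipping constant.
#' @param n1,n0 optional row split metadata.
#' @return an `s_scores` object.
#' @export
oracle_scores <- function(model, c, points, eps = 1e-6,
                          n1 = NA_integer_, n0 = NA_integer_) {
  stopifnot(inherits(model, "rspf_model"), c > 0, c < 1)
  p <- evaluate_probability(model, points)
  s <- ifelse(p <= 0, 0, 1 / (1 + (1 - c) / c / p))
  s_scores(clip01(s, eps), n1 = n1, n0 = n0)
}

#' Container for per-site scores
#' @param scores numeric vector of predicted Pr(s=1|x), ordered presence
#'   rows first then background rows.
#' @param n1,n0 the row split (may be `NA` when scoring arbitrary points).
#' @return object of class `s_scores`.
#' @export
s_scores <- function(scores, n1 = NA_integer_, n0 = NA_integer_) {
  scores <- as.numeric(scores)
  if (!is.na(n1) && !is.na(n0) && length(scores) &&
      length(scores) != n1 + n0) {
    stop("scores length must equal n1 + n0")
  }
  structure(list(scores = scores, n1 = as.integer(n1), n0 = as.integer(n0)),
            class = "s_scores")
}

#' @export
print.s_scores <- function(x, ...) {
  cat("Pr(s=1|x) scores:", length(x$scores), "sites")
  if (!is.na(x$n1)) cat(" (n1 =", x$n1, ", n0 =", x$n0, ")")
  cat("\n  range:", paste(signif(range(x$scores), 4), collapse = " .. "), "\n")
  invisible(x)
}

#' Serialize a fitted scorer to JSON (and back)
#'
#' Stores the architecture, standardization constants and weights so a
#' pipeline can be reproduced without refitting.  Deserialized neural-net
#' scorers use an explicit forward pass (logistic hidden and output units).
#'
#' @param scorer an `s_scorer`.
#' @param path JSON file path.
#' @return `scorer_to_json` returns `path` invisibly; `scorer_from_json`
#'   returns an `s_scorer`.
#' @export
scorer_to_json <- function(scorer, path) {
  stopifnot(inherits(scorer, "s_scorer"))
  doc <- list(kind = scorer$kind, d = scorer$d, eps = scorer$eps,
              center = unname(scorer$center), scale = unname(scorer$scale),
              n1 = scorer$n1, n0 = scorer$n0)
  if (scorer$kind == "neural_net") {
    doc$hidden_units <- scorer$fit$n[2L]
    doc$wts <- scorer$fit$wts
  } else {
    doc$coef <- unname(stats::coef(scorer$fit))
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname scorer_to_json
#' @export
scorer_from_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  sc <- structure(
    list(kind = paste0(doc$kind, "_json"), d = doc$d, eps = doc$eps,
         center = doc$center, scale = doc$scale,
         n1 = doc$n1, n0 = doc$n0, json = doc),
    class = "s_scorer"
  )
  sc
}

# forward pass for deserialized scorers
predict_json_scorer <- function(doc, xs) {
  if (startsWith(doc$kind %||% "", "logistic") ||
      !is.null(doc$coef)) {
    eta <- doc$coef[1L] + as.vector(xs %*% doc$coef[-1L])
    return(stats::plogis(eta))
  }
  h <- doc$hidden_units
  d <- doc$d
  w <- doc$wts
  # nnet weight layout: for each hidden unit, (bias, d inputs); then output
  # unit (bias, h hidden)
  H <- matrix(NA_real_, nrow(xs), h)
  k <- 0L
  for (j in seq_len(h)) {
    b <- w[k + 1L]; v <- w[(k + 2L):(k + 1L + d)]
    H[, j] <- stats::plogis(b + as.vector(xs %*% v))
    k <- k + 1L + d
  }
  b <- w[k + 1L]; v <- w[(k + 2L):(k + 1L + h)]
  stats::plogis(b + as.vector(H %*% v))
}
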