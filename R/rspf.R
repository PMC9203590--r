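#' Parametric resource selection probability functions
#'
#' An `rspf_model` represents an absolute probability of presence
#' \eqn{\Pr(y=1\mid x)} as a scaled link transform of an inner polynomial
#' \eqn{g(x) = \beta_0 + \sum_j \beta_{jp}\, x_j^p} (main-effect powers per
#' covariate, no interactions).  The supported links follow the printed-form
#' convention used throughout the catalogue:
#' \describe{
#'   \item{logistic}{\eqn{p(x) = k / (1 + \exp(g(x)))} -- note the *plus*
#'     sign: \eqn{g} is stored exactly as it appears inside `exp()` in the
#'     printed function, so a coefficient vector is never re-signed.}
#'   \item{exponential}{\eqn{p(x) = k \exp(g(x))}}
#'   \item{cloglog}{\eqn{p(x) = k (1 - \exp(-\exp(g(x))))}}
#' }
#' The scale \eqn{k > 0} multiplies the link output (default 1); models whose
#' maximum over the domain exceeds 1 are rejected at construction.
#'
#' @param link one of `"logistic"`, `"exponential"`, `"cloglog"`.
#' @param beta numeric coefficient vector `(beta0, then powers 1..degree[1] of
#'   x1, then powers 1..degree[2] of x2, ...)`; length must equal
#'   `1 + sum(degree)`.
#' @param degree integer vector, polynomial degree per covariate.
#' @param scale positive multiplier `k` on the link output.
#' @param domain per-covariate closed bounds: a length-2 vector for one
#'   covariate, or a 2 x d matrix `rbind(lower, upper)`.
#' @param validate check `p(x) in [0,1]` on a dense grid (default `TRUE`).
#' @param grid_size grid points (per covariate) used for validation.
#'
#' @return an object of class `rspf_model`.
#' @examples
#' m <- rspf_model("logistic", c(-0.606, 3.64), degree = 1, domain = c(-1, 1))
#' evaluate_probability(m, 0)   # 0.6470
#' @export
rspf_model <- function(link = c("logistic", "exponential", "cloglog"),
                       beta, degree = 1L, scale = 1,
                       domain, validate = TRUE, grid_size = 2001L) {
  link <- match.arg(link)
  beta <- as.numeric(beta)
  degree <- as.integer(degree)
  if (any(degree < 1L)) stop("polynomial degree must be >= 1 per covariate")
  if (length(beta) != 1L + sum(degree)) {
    stop("beta has length ", length(beta), "; expected ", 1L + sum(degree))
  }
  if (anyNA(beta) || any(!is.finite(beta))) stop("non-finite coefficient")
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) ||
      scale <= 0) {
    stop("scale k must be a positive number")
  }
  domain <- as_domain(domain, length(degree))
  m <- structure(
    list(link = link, beta = beta, degree = degree, scale = scale,
         domain = domain),
    class = "rspf_model"
  )
  if (validate) {
    rep <- validate_model(m, grid_size = grid_size)
    if (!rep$valid) {
      stop("model is not a probability on its domain: range [",
           signif(rep$min, 6), ", ", signif(rep$max, 6), "]")
    }
  }
  m
}

as_domain <- function(domain, d) {
  if (is.list(domain)) domain <- do.call(cbind, domain)
  if (is.null(dim(domain))) {
    if (length(domain) != 2L) stop("domain must be c(lower, upper) per covariate")
    domain <- matrix(domain, nrow = 2L)
  }
  domain <- matrix(as.numeric(domain), nrow = 2L)
  if (ncol(domain) == 1L && d > 1L) {
    domain <- domain[, rep(1L, d), drop = FALSE]
  }
  if (ncol(domain) != d) stop("domain has bounds for ", ncol(domain),
                              " covariates; expected ", d)
  if (any(domain[1L, ] > domain[2L, ])) stop("domain lower bound above upper")
  rownames(domain) <- c("lower", "upper")
  domain
}

n_covariates <- function(model) length(model$degree)

# main-effects polynomial design matrix: 1, x1, x1^2, ..., x2, x2^2, ...
poly_design <- function(x, degree) {
  cols <- vector("list", sum(degree) + 1L)
  cols[[1L]] <- rep(1, nrow(x))
  k <- 1L
  for (j in seq_along(degree)) {
    for (p in seq_len(degree[j])) {
      k <- k + 1L
      cols[[k]] <- x[, j]^p
    }
  }
  do.call(cbind, cols)
}

inner_polynomial <- function(model, x) {
  drop(poly_design(x, model$degree) %*% model$beta)
}

link_transform <- function(link, g) {
  switch(link,
    logistic    = 1 / (1 + exp(g)),
    exponential = exp(g),
    cloglog     = 1 - exp(-exp(g)),
    stop("unknown link ", link)
  )
}

#' Evaluate the probability of presence at covariate points
#'
#' @param model an [rspf_model].
#' @param points covariate points: numeric vector (one covariate) or matrix
#'   with one row per point.
#' @param allow_extrapolation evaluate outside the declared domain (for
#'   diagnostics); by default out-of-domain points are an error.
#' @return numeric vector of probabilities.
#' @export
evaluate_probability <- function(model, points, allow_extrapolation = FALSE) {
  stopifnot(inherits(model, "rspf_model"))
  x <- as_points(points, n_covariates(model))
  if (!allow_extrapolation && nrow(x) > 0L) {
    lo <- model$domain[1L, ]; hi <- model$domain[2L, ]
    tol <- 1e-12
    out <- x < matrix(lo - tol, nrow(x), ncol(x), byrow = TRUE) |
      x > matrix(hi + tol, nrow(x), ncol(x), byrow = TRUE)
    if (any(out)) {
      stop("point(s) outside the model domain (first offending row: ",
           which(rowSums(out) > 0)[1L],
           "); use allow_extrapolation = TRUE for diagnostics")
    }
  }
  if (nrow(x) == 0L) return(numeric(0))
  model$scale * link_transform(model$link, inner_polynomial(model, x))
}

domain_grid <- function(domain, n_per_dim) {
  axes <- lapply(seq_len(ncol(domain)), function(j) {
    lo <- domain[1L, j]; hi <- domain[2L, j]
    if (lo == hi) lo else seq(lo, hi, length.out = n_per_dim)
  })
  as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
}

#' Locate the maximum probability of a model over its domain
#'
#' Dense grid search followed by a local bounded quasi-Newton polish.  For
#' d > 1 covariates the grid uses roughly `grid_size^(1/d)` points per axis.
#'
#' @param model an [rspf_model].
#' @param grid_size total number of grid points (at least 2).
#' @return list with `argmax` (covariate point) and `max` (probability).
#' @export
max_probability <- function(model, grid_size = 100001L) {
  stopifnot(inherits(model, "rspf_model"), grid_size >= 2L)
  d <- n_covariates(model)
  lo <- model$domain[1L, ]; hi <- model$domain[2L, ]
  if (all(lo == hi)) {
    return(list(argmax = lo, max = evaluate_probability(model, matrix(lo, 1L))))
  }
  n_per_dim <- max(2L, ceiling(grid_size^(1 / d)))
  grid <- domain_grid(model$domain, n_per_dim)
  p <- evaluate_probability(model, grid)
  i <- which.max(p)
  x0 <- grid[i, ]
  # local polish within bounds (degenerate axes pinned)
  free <- hi > lo
  obj <- function(z) {
    x <- x0; x[free] <- z
    -evaluate_probability(model, matrix(x, 1L))
  }
  pol <- tryCatch(
    stats::optim(x0[free], obj, method = "L-BFGS-B",
                 lower = lo[free], upper = hi[free]),
    error = function(e) NULL
  )
  best_x <- x0; best_p <- p[i]
  if (!is.null(pol) && is.finite(pol$value) && -pol$value > best_p) {
    best_x[free] <- pol$par
    best_p <- -pol$value
  }
  list(argmax = unname(best_x), max = unname(best_p))
}

#' Check that a model is a probability over its domain
#'
#' Reports the min/max of \eqn{k \cdot \mathrm{link}(g(x))} on a dense grid
#' (with a local polish at the grid maximum); values outside `[0, 1]` are
#' flagged rather than raised.
#'
#' @param model an [rspf_model] (possibly built with `validate = FALSE`).
#' @param grid_size grid points used for the scan.
#' @return list with `valid`, `min`, `max`, `argmax`.
#' @export
validate_model <- function(model, grid_size = 100001L) {
  stopifnot(inherits(model, "rspf_model"))
  mx <- max_probability(model, grid_size = grid_size)
  grid <- domain_grid(model$domain,
                      max(2L, ceiling(grid_size^(1 / n_covariates(model)))))
  p <- evaluate_probability(model, grid)
  pmin_ <- min(p)
  list(valid = mx$max <= 1 + 1e-9 && pmin_ >= -1e-12,
       min = pmin_, max = mx$max, argmax = mx$argmax)
}

#' @export
print.rspf_model <- function(x, ...) {
  cat("RSPF model: ", x$link, " link, ",
      n_covariates(x), " covariate(s), degree ",
      paste(x$degree, collapse = "/"), "\n", sep = "")
  if (x$scale != 1) cat("  scale k =", x$scale, "\n")
  cat("  beta   =", paste(signif(x$beta, 6), collapse = ", "), "\n")
  cat("  domain =",
      paste(apply(x$domain, 2L, function(b)
        sprintf("[%g, %g]", b[1L], b[2L])), collapse = " x "), "\n")
  invisible(x)
}
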