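#' Presence-background simulation
#'
#' The simulator follows the case-control (use-availability) sampling scheme:
#' covariates are distributed uniformly over the rectangular domain; the
#' presence sample `P` contains `n1` iid draws from the covariate
#' distribution conditional on presence (density proportional to
#' \eqn{p(x) f(x)}, realised by rejection sampling); the background sample
#' `B` contains `n0` iid draws from the whole landscape.  Selection of a
#' presence into `P` depends on nothing but presence itself (SCAR), which
#' holds by construction here.  For simulated data the latent presence label
#' of every background site is retained, along with `p2` (the number of true
#' presences hidden in the background) and the implied labelling frequency
#' `c = n1 / (n1 + p2)`.
#'
#' @name pb_simulator
NULL

#' Draw background covariates uniformly over a domain
#'
#' @param n0 number of background sites (>= 1).
#' @param domain per-covariate bounds (vector `c(lo, hi)` or 2 x d matrix).
#' @param seed integer seed; the caller's RNG stream is left untouched.
#' @return an `n0` x d covariate matrix.
#' @export
draw_background <- function(n0, domain, seed) {
  stopifnot(n0 >= 1)
  domain <- as_domain(domain, if (is.null(dim(domain))) 1L else ncol(domain))
  if (any(domain[1L, ] >= domain[2L, ])) {
    stop("invalid bounds: lower >= upper")
  }
  d <- ncol(domain)
  with_seed(seed, {
    m <- matrix(stats::runif(n0 * d), nrow = n0)
    sweep(sweep(m, 2L, domain[2L, ] - domain[1L, ], `*`),
          2L, domain[1L, ], `+`)
  })
}

#' Draw presence covariates by rejection sampling
#'
#' Candidate sites are drawn uniformly over the model domain and accepted
#' with probability \eqn{p(x)}, so accepted sites are distributed as
#' \eqn{x \mid y = 1}.
#'
#' @param n1 number of presences required (>= 1).
#' @param model an [rspf_model], valid on its domain.
#' @param seed integer seed.
#' @param min_mean_p abort threshold: if the mean probability on a pilot grid
#'   is below this floor, acceptance is hopeless and an error is raised.
#' @return an `n1` x d covariate matrix.
#' @export
draw_presence <- function(n1, model, seed, min_mean_p = 1e-6) {
  stopifnot(inherits(model, "rspf_model"), n1 >= 1)
  d <- n_covariates(model)
  pilot <- domain_grid(model$domain, max(2L, ceiling(1001^(1 / d))))
  pbar <- mean(evaluate_probability(model, pilot))
  if (pbar < min_mean_p) {
    stop("mean probability on a pilot grid is ", signif(pbar, 3),
         " (< ", min_mean_p, "): rejection sampling would not terminate")
  }
  lo <- model$domain[1L, ]; hi <- model$domain[2L, ]
  with_seed(seed, {
    out <- matrix(NA_real_, nrow = n1, ncol = d)
    got <- 0L
    while (got < n1) {
      batch <- max(1000L, ceiling(1.2 * (n1 - got) / max(pbar, min_mean_p)))
      batch <- min(batch, 5e6)
      cand <- matrix(stats::runif(batch * d), ncol = d)
      cand <- sweep(sweep(cand, 2L, hi - lo, `*`), 2L, lo, `+`)
      keep <- stats::runif(batch) <= evaluate_probability(model, cand)
      acc <- which(keep)
      if (length(acc)) {
        take <- acc[seq_len(min(length(acc), n1 - got))]
        out[(got + 1L):(got + length(take)), ] <- cand[take, , drop = FALSE]
        got <- got + length(take)
      }
    }
    out
  })
}

#' Simulate a full presence-background dataset
#'
#' @param model generating [rspf_model].
#' @param n1,n0 presence / background sample sizes (defaults follow the main
#'   simulation design: 5000 presences, 50000 background sites).
#' @param seed master seed; presence draws, background draws and latent
#'   labels use fixed, independently derived sub-seeds.
#' @param latent keep per-site latent presence labels for the background
#'   (default `TRUE`; simulation diagnostics only).
#' @param model_id optional provenance tag (e.g. a catalogue name).
#' @return a `pb_dataset`: list with presence matrix `P`, background matrix
#'   `B`, latent labels `y_latent`, `p2`, implied labelling frequency
#'   `c_implied = n1/(n1+p2)`, and provenance.
#' @export
simulate_pb <- function(model, n1 = 5000L, n0 = 50000L, seed,
                        latent = TRUE, model_id = NULL) {
  stopifnot(inherits(model, "rspf_model"), n1 >= 1, n0 >= 1)
  seeds <- derive_seeds(seed, 3L)
  P <- draw_presence(n1, model, seed = seeds[1L])
  B <- draw_background(n0, model$domain, seed = seeds[2L])
  y <- NULL; p2 <- NA_integer_; c_implied <- NA_real_
  if (latent) {
    pB <- evaluate_probability(model, B)
    y <- with_seed(seeds[3L], stats::rbinom(n0, 1L, pB))
    p2 <- sum(y)
    c_implied <- n1 / (n1 + p2)
  }
  pb_dataset(P, B, y_latent = y,
             provenance = list(model_id = model_id, seed = seed,
                               sub_seeds = seeds))
}

#' Construct a presence-background dataset container
#'
#' @param P presence covariates (n1 x d matrix or vector).
#' @param B background covariates (n0 x d matrix or vector).
#' @param y_latent optional latent background labels (simulation only).
#' @param provenance optional list of provenance metadata.
#' @return object of class `pb_dataset`.
#' @export
pb_dataset <- function(P, B, y_latent = NULL, provenance = list()) {
  if (is.null(dim(P))) P <- matrix(as.numeric(P), ncol = 1L)
  if (is.null(dim(B))) B <- matrix(as.numeric(B), ncol = 1L)
  if (ncol(P) != ncol(B)) stop("P and B must share covariate dimension")
  if (nrow(P) < 1L || nrow(B) < 1L) stop("need n1 >= 1 and n0 >= 1")
  p2 <- NA_integer_; c_implied <- NA_real_
  if (!is.null(y_latent)) {
    y_latent <- as.integer(y_latent)
    if (length(y_latent) != nrow(B)) stop("y_latent must have one entry per background row")
    if (!all(y_latent %in% c(0L, 1L))) stop("y_latent must be 0/1")
    p2 <- sum(y_latent)
    c_implied <- nrow(P) / (nrow(P) + p2)
  }
  structure(
    list(P = P, B = B, n1 = nrow(P), n0 = nrow(B), d = ncol(P),
         y_latent = y_latent, p2 = p2, c_implied = c_implied,
         provenance = provenance),
    class = "pb_dataset"
  )
}

#' @export
print.pb_dataset <- function(x, ...) {
  cat("Presence-background dataset: n1 =", x$n1, ", n0 =", x$n0,
      ", d =", x$d, "\n")
  if (!is.na(x$p2)) {
    cat("  latent truth kept: p2 =", x$p2,
        sprintf("(implied c = %.4f)\n", x$c_implied))
  }
  invisible(x)
}

#' True population prevalence of a model
#'
#' The prevalence \eqn{\pi = \Pr(y=1) = E_f[p(x)]} under the uniform
#' covariate distribution on the domain, computed by deterministic
#' quadrature (adaptive for one covariate, tensor rule for two).
#'
#' @param model an [rspf_model].
#' @return the prevalence, accurate to about `1e-6` for the catalogue.
#' @export
true_prevalence <- function(model) {
  stopifnot(inherits(model, "rspf_model"))
  d <- n_covariates(model)
  lo <- model$domain[1L, ]; hi <- model$domain[2L, ]
  vol <- prod(hi - lo)
  if (vol == 0) {
    return(evaluate_probability(model, matrix(lo, 1L)))
  }
  if (d == 1L) {
    f <- function(x) evaluate_probability(model, x)
    stats::integrate(f, lo, hi, rel.tol = 1e-9,
                     subdivisions = 200L)$value / vol
  } else if (d == 2L) {
    pracma::integral2(Vectorize(function(x, y)
      evaluate_probability(model, matrix(c(x, y), 1L))),
      lo[1L], hi[1L], lo[2L], hi[2L], reltol = 1e-8)$Q / vol
  } else {
    stop("true_prevalence supports at most 2 covariates")
  }
}
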