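#' Prevalence estimation from classifier scores
#'
#' Step 2 of the refined CLK pipeline.  Under case-control sampling the
#' labelling frequency \eqn{c = p_1/(p_1 + p_2)} equals \eqn{\Pr(s=1\mid x)}
#' at any site where the presence probability is 1 (local certainty), and
#' more generally at a site with known presence probability \eqn{q}
#' \deqn{\pi = q\,\frac{p_1}{n_0}\,\frac{1 - \Pr(s=1\mid x)}{\Pr(s=1\mid x)}.}
#' The estimator ranks the pooled scores, aggregates them over the top
#' share (default the top 10th percentile), and converts the aggregate to a
#' prevalence.  `q = 1` encodes local certainty (prototypical presence
#' locations); `q < 1` encodes partial local knowledge, and enters the
#' estimate exactly linearly.
#'
#' @name prevalence_estimator
NULL

#' Local-knowledge specification
#'
#' @param q known probability of presence at the selected top sites, in
#'   (0, 1]; `q = 1` is local certainty.
#' @param percentile top share of pooled scores used, in (0, 100]
#'   (default 10).
#' @param aggregator `"mean"` (default), `"max"`, or `"ratio"` (top-set sum
#'   over background-row sum).
#' @return a `local_knowledge` list.
#' @export
local_knowledge <- function(q = 1, percentile = 10, aggregator = "mean") {
  stopifnot(q > 0, q <= 1, percentile > 0, percentile <= 100,
            aggregator %in% c("mean", "max", "ratio"))
  structure(list(q = q, percentile = percentile, aggregator = aggregator),
            class = "local_knowledge")
}

#' Select the top-ranked sites by score
#'
#' Returns the indices of the `ceil((percentile/100) * n)` largest scores in
#' the pooled presence-then-background vector.  Ties are broken by
#' descending score then ascending index, so the selection is stable.
#'
#' @param scores an `s_scores` object or plain numeric vector.
#' @param percentile share in (0, 100].
#' @param pool `"pooled"` ranks presence and background rows together (the
#'   default); `"presence"` restricts the candidate set to presence rows
#'   (requires `n1` metadata).
#' @return integer index vector into the pooled score vector.
#' @export
select_top_sites <- function(scores, percentile = 10, pool = c("pooled", "presence")) {
  pool <- match.arg(pool)
  v <- if (inherits(scores, "s_scores")) scores$scores else as.numeric(scores)
  if (!length(v)) stop("empty score vector")
  if (percentile <= 0 || percentile > 100) stop("percentile must be in (0, 100]")
  idx <- seq_along(v)
  if (pool == "presence") {
    if (!inherits(scores, "s_scores") || is.na(scores$n1)) {
      stop("presence-only pool requires s_scores with n1 metadata")
    }
    idx <- seq_len(scores$n1)
  }
  k <- ceiling(percentile / 100 * length(idx))
  ord <- order(-v[idx], idx)
  idx[ord[seq_len(k)]]
}

#' Aggregate top-site scores into a labelling-frequency estimate
#'
#' @param scores an `s_scores` object (the `"ratio"` aggregator needs its
#'   `n1`/`n0` metadata to locate the background rows).
#' @param top index set from [select_top_sites()].
#' @param aggregator `"mean"`, `"max"`, or `"ratio"`.
#' @param eps clipping constant keeping the estimate strictly inside (0, 1).
#' @return the estimated labelling frequency `c_hat`.
#' @export
estimate_c <- function(scores, top, aggregator = c("mean", "max", "ratio"),
                       eps = 1e-6) {
  aggregator <- match.arg(aggregator)
  v <- if (inherits(scores, "s_scores")) scores$scores else as.numeric(scores)
  if (!length(top)) stop("empty top-site set")
  c_hat <- switch(aggregator,
    mean = mean(v[top]),
    max  = max(v[top]),
    ratio = {
      if (!inherits(scores, "s_scores") || is.na(scores$n1) || is.na(scores$n0)) {
        stop("ratio aggregator requires s_scores with n1/n0 metadata")
      }
      bg <- v[(scores$n1 + 1L):(scores$n1 + scores$n0)]
      denom <- sum(bg)
      if (denom <= 0) stop("zero background score sum in ratio aggregator")
      sum(v[top]) / denom
    })
  clip01(c_hat, eps)
}

#' Convert a labelling-frequency estimate to a prevalence estimate
#'
#' \eqn{\hat\pi = q\,(p_1/n_0)\,(1-\hat c)/\hat c}; with `q = 1` this is the
#' local-certainty estimator.  An estimate above 1 is capped at 1 and
#' flagged rather than raised, because the downstream constrained fit
#' requires a prevalence in (0, 1).
#'
#' @param c_hat labelling-frequency estimate in (0, 1).
#' @param p1 number of observed presences.
#' @param n0 number of background sites.
#' @param q local-knowledge probability at the top sites (default 1).
#' @param method optional metadata list (aggregator, percentile, ...).
#' @return a `prevalence_estimate`: `c_hat`, `pi_hat`, `n_top`, flags.
#' @export
estimate_prevalence <- function(c_hat, p1, n0, q = 1, method = list()) {
  stopifnot(c_hat > 0, c_hat < 1, p1 >= 1, n0 >= 1, q > 0, q <= 1)
  # grouped so that the estimate is *bitwise* linear in q
  pi_raw <- q * ((p1 / n0) * ((1 - c_hat) / c_hat))
  capped <- pi_raw > 1
  structure(
    list(c_hat = c_hat, pi_hat = min(pi_raw, 1), pi_raw = pi_raw,
         p1 = p1, n0 = n0, q = q, capped = capped,
         suspicious = capped, method = method,
         n_top = method$n_top %||% NA_integer_),
    class = "prevalence_estimate"
  )
}

#' Estimate prevalence end-to-end from scores
#'
#' Convenience chain: [select_top_sites()] then [estimate_c()] then
#' [estimate_prevalence()].
#'
#' @param scores an `s_scores` with `n1`/`n0` metadata.
#' @param lkn a [local_knowledge] specification.
#' @param pool ranking pool, see [select_top_sites()].
#' @return a `prevalence_estimate`.
#' @export
prevalence_from_scores <- function(scores, lkn = local_knowledge(),
                                   pool = "pooled") {
  stopifnot(inherits(scores, "s_scores"))
  if (is.na(scores$n1) || is.na(scores$n0)) {
    stop("scores must carry n1/n0 metadata")
  }
  top <- select_top_sites(scores, lkn$percentile, pool = pool)
  c_hat <- estimate_c(scores, top, lkn$aggregator)
  estimate_prevalence(c_hat, p1 = scores$n1, n0 = scores$n0, q = lkn$q,
                      method = list(aggregator = lkn$aggregator,
                                    percentile = lkn$percentile,
                                    pool = pool, n_top = length(top)))
}

#' @export
print.prevalence_estimate <- function(x, ...) {
  cat(sprintf("Prevalence estimate: pi_hat = %.4f (c_hat = %.4f, q = %g)\n",
              x$pi_hat, x$c_hat, x$q))
  if (isTRUE(x$capped)) {
    cat("  [capped] raw estimate", signif(x$pi_raw, 4), "exceeded 1\n")
  }
  invisible(x)
}

#' Serialize a prevalence estimate to JSON
#' @param x a `prevalence_estimate`.
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
prevalence_to_json <- function(x, path) {
  stopifnot(inherits(x, "prevalence_estimate"))
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
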