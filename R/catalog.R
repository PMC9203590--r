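#' Catalogue of simulated species probability functions
#'
#' Returns the built-in catalogue of 13 probability-of-presence functions
#' used by the simulation study:
#' \itemize{
#'   \item Category 1 (local certainty and RSPF conditions hold): linear,
#'     quadratic and cubic logistic functions on \eqn{[-1,1]}.
#'   \item Category 2 (local certainty only): scaled linear logistic,
#'     Gaussian and cubic exponential functions on \eqn{[0,1]}.  The Gaussian
#'     \eqn{0.99\exp(-(4x-2)^2)} is stored as an exponential-link model with
#'     quadratic inner polynomial (its printed form is kept as metadata).
#'   \item Category 3 (RSPF conditions only, maximum below 1): linear,
#'     quadratic and cubic logistic functions on \eqn{[-1,1]}.
#'   \item `hf_full` / `hf_scaled`: the full logistic
#'     \eqn{1/(1+\exp(1-x))} on \eqn{[-2.5, 2.5]} and its exact half, the
#'     classic pair demonstrating that the LK likelihood cannot see a
#'     multiplicative scale.
#'   \item `twocov_full` / `twocov_scaled`: a two-covariate logistic function
#'     and its half, on \eqn{[-1,1]^2}.
#' }
#' Each entry carries the model, a category label, the true maximum
#' probability with its argmax, and the printed functional form.
#'
#' @return a named list of catalogue entries, class `rspf_catalog`.
#' @examples
#' cat13 <- catalog()
#' names(cat13)
#' evaluate_probability(cat13$cat2_gaussian$model, 0.5)  # 0.99
#' @export
catalog <- function() {
  entry <- function(name, model, category, true_max, argmax, printed) {
    list(name = name, model = model, category = category,
         true_max = true_max, argmax = argmax, printed = printed)
  }
  plogi <- function(g) 1 / (1 + exp(g))

  e <- list()
  ## Category 1: logistic, domain [-1,1]
  e$cat1_linear <- entry(
    "cat1_linear",
    rspf_model("logistic", c(-0.606, 3.64), 1L, domain = c(-1, 1)),
    "1", true_max = plogi(-0.606 - 3.64), argmax = -1,
    printed = "1/(1+exp(-0.606+3.64x))")
  e$cat1_quadratic <- entry(
    "cat1_quadratic",
    rspf_model("logistic", c(-0.606, 3.64, -1.26), 2L, domain = c(-1, 1)),
    "1", true_max = plogi(-0.606 - 3.64 - 1.26), argmax = -1,
    printed = "1/(1+exp(-0.606+3.64x-1.26x^2))")
  e$cat1_cubic <- entry(
    "cat1_cubic",
    rspf_model("logistic", c(0.284, 2.298, 0.232, -7.269), 3L, domain = c(-1, 1)),
    "1", true_max = plogi(0.284 + 2.298 + 0.232 - 7.269), argmax = 1,
    printed = "1/(1+exp(0.284+2.298x+0.232x^2-7.269x^3))")

  ## Category 2: domain [0,1]
  e$cat2_scaled_logistic <- entry(
    "cat2_scaled_logistic",
    rspf_model("logistic", c(4, -2), 1L, scale = 8.3, domain = c(0, 1)),
    "2", true_max = 8.3 / (1 + exp(2)), argmax = 1,
    printed = "8.3/(1+exp(4-2x))")
  e$cat2_gaussian <- entry(
    "cat2_gaussian",
    rspf_model("exponential", c(log(0.99) - 4, 16, -16), 2L, domain = c(0, 1)),
    "2", true_max = 0.99, argmax = 0.5,
    printed = "0.99*exp(-(4x-2)^2)")
  e$cat2_exponential <- entry(
    "cat2_exponential",
    rspf_model("exponential", c(-0.5, 0.5, -0.9, 0.9), 3L, domain = c(0, 1)),
    "2", true_max = 1, argmax = 1,
    printed = "exp(-0.5+0.5x-0.9x^2+0.9x^3)")

  ## Category 3: logistic, domain [-1,1], maxima below 1
  e$cat3_linear <- entry(
    "cat3_linear",
    rspf_model("logistic", c(-0.5855, -1.064), 1L, domain = c(-1, 1)),
    "3", true_max = plogi(-0.5855 - 1.064), argmax = 1,
    printed = "1/(1+exp(-0.5855-1.064x))")
  e$cat3_quadratic <- entry(
    "cat3_quadratic",
    rspf_model("logistic", c(-0.5855, -1.064, 0.218), 2L, domain = c(-1, 1)),
    "3", true_max = plogi(-0.5855 - 1.064 + 0.218), argmax = 1,
    printed = "1/(1+exp(-0.5855-1.064x+0.218x^2))")
  e$cat3_cubic <- entry(
    "cat3_cubic",
    rspf_model("logistic", c(-0.5855, -1.064, 0.218, 1.81), 3L, domain = c(-1, 1)),
    "3", true_max = plogi(-0.5855 + 1.064 + 0.218 - 1.81), argmax = -1,
    printed = "1/(1+exp(-0.5855-1.064x+0.218x^2+1.81x^3))")

  ## Full vs scaled logistic pair, domain [-2.5, 2.5]
  e$hf_full <- entry(
    "hf_full",
    rspf_model("logistic", c(1, -1), 1L, domain = c(-2.5, 2.5)),
    "hf", true_max = plogi(1 - 2.5), argmax = 2.5,
    printed = "1/(1+exp(1-x))")
  e$hf_scaled <- entry(
    "hf_scaled",
    rspf_model("logistic", c(1, -1), 1L, scale = 0.5, domain = c(-2.5, 2.5)),
    "hf", true_max = 0.5 * plogi(1 - 2.5), argmax = 2.5,
    printed = "0.5/(1+exp(1-x))")

  ## Two-covariate separability pair, domain [-1,1]^2
  e$twocov_full <- entry(
    "twocov_full",
    rspf_model("logistic", c(-0.606, 3.64, -1.26), c(1L, 1L),
               domain = cbind(c(-1, 1), c(-1, 1))),
    "2cov", true_max = plogi(-0.606 - 3.64 - 1.26), argmax = c(-1, 1),
    printed = "1/(1+exp(-0.606+3.64x1-1.26x2))")
  e$twocov_scaled <- entry(
    "twocov_scaled",
    rspf_model("logistic", c(-0.606, 3.64, -1.26), c(1L, 1L), scale = 0.5,
               domain = cbind(c(-1, 1), c(-1, 1))),
    "2cov", true_max = 0.5 * plogi(-0.606 - 3.64 - 1.26), argmax = c(-1, 1),
    printed = "0.5/(1+exp(-0.606+3.64x1-1.26x2))")

  structure(e, class = "rspf_catalog")
}

#' Fetch a single catalogue model by name
#' @param name entry name, e.g. `"cat1_linear"`.
#' @return the [rspf_model] stored under that name.
#' @export
catalog_model <- function(name) {
  cat13 <- catalog()
  if (!name %in% names(cat13)) {
    stop("unknown catalogue entry '", name, "'; see names(catalog())")
  }
  cat13[[name]]$model
}

#' @export
print.rspf_catalog <- function(x, ...) {
  cat("Probability-of-presence catalogue (", length(x), " entries)\n", sep = "")
  for (e in x) {
    cat(sprintf("  %-22s cat %-4s max %.4f  %s\n",
                e$name, e$category, e$true_max, e$printed))
  }
  invisible(x)
}

#' Export / import the catalogue as JSON
#'
#' The JSON document records, per entry: name, link, coefficients, degree,
#' scale, domain, category, true maximum and its argmax.
#'
#' @param path file path to write to / read from.
#' @param x an `rspf_catalog` (defaults to the built-in [catalog()]).
#' @return `catalog_to_json` returns `path` invisibly; `catalog_from_json`
#'   returns an `rspf_catalog`.
#' @export
catalog_to_json <- function(path, x = catalog()) {
  doc <- lapply(unname(x), function(e) {
    list(name = e$name, link = e$model$link, beta = e$model$beta,
         degree = e$model$degree, scale = e$model$scale,
         domain = list(lower = unname(e$model$domain[1L, ]),
                       upper = unname(e$model$domain[2L, ])),
         category = e$category, true_max = e$true_max,
         argmax = e$argmax, printed = e$printed)
  })
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname catalog_to_json
#' @export
catalog_from_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  e <- lapply(doc, function(d) {
    list(name = d$name,
         model = rspf_model(d$link, d$beta, d$degree, d$scale,
                            domain = rbind(d$domain$lower, d$domain$upper)),
         category = d$category, true_max = d$true_max,
         argmax = d$argmax, printed = d$printed)
  })
  names(e) <- vapply(e, `[[`, "", "name")
  structure(e, class = "rspf_catalog")
}
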