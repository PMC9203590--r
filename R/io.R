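#' Read and write presence-background datasets as CSV
#'
#' The dialect is pinned: comma separator, header row, UTF-8, `.` decimal,
#' doubles written with 17 significant digits.  Columns are `s` (1 =
#' presence row, 0 = background row), then `x1..xd`, then optionally
#' `y_latent` for simulated background rows.  Provenance travels in a
#' sidecar JSON (`<path>.json`) when present.
#'
#' @param data a [pb_dataset].
#' @param path CSV file path.
#' @param sidecar write/read the provenance sidecar JSON (default `TRUE`
#'   on write when provenance is non-empty).
#' @return `write_pb_csv` returns `path` invisibly; `read_pb_csv` returns a
#'   [pb_dataset].
#' @export
write_pb_csv <- function(data, path, sidecar = TRUE) {
  stopifnot(inherits(data, "pb_dataset"))
  x <- rbind(data$P, data$B)
  df <- data.frame(s = c(rep(1L, data$n1), rep(0L, data$n0)))
  for (j in seq_len(data$d)) df[[paste0("x", j)]] <- x[, j]
  if (!is.null(data$y_latent)) {
    df$y_latent <- c(rep(NA_integer_, data$n1), data$y_latent)
  }
  num <- vapply(df, is.double, TRUE)
  for (j in which(num)) df[[j]] <- formatC(df[[j]], digits = 17, format = "g")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8", na = "")
  if (sidecar && length(data$provenance)) {
    jsonlite::write_json(data$provenance, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' @rdname write_pb_csv
#' @export
read_pb_csv <- function(path, sidecar = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  if (!"s" %in% names(df)) stop("missing required column 's'")
  xcols <- grep("^x[0-9]+$", names(df), value = TRUE)
  if (!length(xcols)) stop("no covariate columns (x1, x2, ...) found")
  xcols <- xcols[order(as.integer(sub("^x", "", xcols)))]
  bad <- which(!df$s %in% c(0, 1))
  if (length(bad)) {
    stop("non-binary 's' value at data line(s) ",
         paste(utils::head(bad + 1L, 5L), collapse = ", "))
  }
  for (cn in xcols) {
    v <- df[[cn]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))))
      stop("non-numeric covariate '", cn, "' at data line(s) ",
           paste(utils::head(bad + 1L, 5L), collapse = ", "))
    }
    if (anyNA(v)) {
      stop("missing covariate '", cn, "' at data line(s) ",
           paste(utils::head(which(is.na(v)) + 1L, 5L), collapse = ", "))
    }
  }
  pres <- df$s == 1
  P <- as.matrix(df[pres, xcols, drop = FALSE])
  B <- as.matrix(df[!pres, xcols, drop = FALSE])
  y <- NULL
  if ("y_latent" %in% names(df)) {
    yv <- df$y_latent[!pres]
    if (!anyNA(yv)) y <- as.integer(yv)
  }
  prov <- list()
  sc <- paste0(path, ".json")
  if (sidecar && file.exists(sc)) {
    prov <- jsonlite::read_json(sc, simplifyVector = TRUE)
  }
  pb_dataset(P, B, y_latent = y, provenance = prov)
}
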