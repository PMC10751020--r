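# Reading and writing of signal files: one-column TSV/CSV signals and
# UCSC bedGraph count tracks (0-based, half-open intervals).

#' Read a one-dimensional signal or count track
#'
#' TSV/CSV files hold one value per position in a single column (a header
#' row is auto-detected and skipped; with two columns, the first is taken
#' as a position index and the second as the value). bedGraph files must
#' tile a contiguous, equally spaced interval; coordinates are 0-based and
#' half-open and are preserved on the returned object for round-tripping.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"tsv"`, `"csv"` or `"bedgraph"`.
#' @return Numeric vector of values; for bedGraph input, with attributes
#'   `chrom`, `start` (0-based) and `width`.
#' @export
read_signal <- function(path, format = c("auto", "tsv", "csv", "bedgraph")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", bedgraph = "bedgraph", bg = "bedgraph",
                     "tsv")
  }
  if (format == "bedgraph") return(.read_bedgraph(path))
  dt <- data.table::fread(path, header = "auto",
                          sep = if (format == "csv") "," else "\t")
  if (ncol(dt) == 0L || nrow(dt) == 0L) stop("empty signal file: ", path)
  col <- if (ncol(dt) >= 2) 2L else 1L
  vals <- suppressWarnings(as.numeric(dt[[col]]))
  bad <- which(!is.finite(vals))
  if (length(bad))
    stop("non-numeric or non-finite value in ", path, " at data line ",
         bad[1])
  vals
}

.read_bedgraph <- function(path) {
  dt <- data.table::fread(path, header = FALSE)
  if (ncol(dt) < 4) stop("bedGraph requires 4 columns: ", path)
  chrom <- as.character(dt[[1]])
  start <- as.numeric(dt[[2]])
  end <- as.numeric(dt[[3]])
  val <- suppressWarnings(as.numeric(dt[[4]]))
  bad <- which(!is.finite(val))
  if (length(bad))
    stop("non-finite value in ", path, " at line ", bad[1])
  if (length(unique(chrom)) != 1)
    stop("bedGraph must cover a single chromosome: ", path)
  widths <- end - start
  if (any(widths <= 0))
    stop("non-positive interval width in ", path, " at line ",
         which(widths <= 0)[1])
  if (length(unique(widths)) != 1)
    stop("bedGraph intervals must be equally spaced in ", path,
         " (first differing width at line ",
         which(widths != widths[1])[1], ")")
  gaps <- which(start[-1] != end[-length(end)])
  if (length(gaps))
    stop("bedGraph is not contiguous in ", path, ": gap after position ",
         format(end[gaps[1]], scientific = FALSE), " (line ", gaps[1], ")")
  structure(val, chrom = chrom[1], start = start[1], width = widths[1])
}

#' Write a smoothing result
#'
#' TSV output has columns `position` (1-based), `mu_hat` and, when
#' available, `sigma2_hat`, `band_lo`, `band_hi`; values carry 15
#' significant digits so a write/read round trip is lossless at working
#' precision. bedGraph output reuses the coordinates carried by the input
#' track.
#'
#' @param path Output file path.
#' @param result A `"gaussian_denoise"` object, a list with `mu_hat`
#'   (optionally `sigma2_hat`, `band_lo`, `band_hi`), or a bare numeric
#'   vector.
#' @param format `"tsv"` or `"bedgraph"`.
#' @param template For bedGraph output: the object returned by
#'   [read_signal()] carrying the input coordinates.
#' @return Invisibly, `path`.
#' @export
write_result <- function(path, result, format = c("tsv", "bedgraph"),
                         template = NULL) {
  format <- match.arg(format)
  if (is.numeric(result)) result <- list(mu_hat = as.numeric(result))
  mu <- result$mu_hat
  if (format == "bedgraph") {
    if (is.null(template) || is.null(attr(template, "chrom")))
      stop("bedGraph output requires a template track with coordinates")
    start <- attr(template, "start") + attr(template, "width") *
      (seq_along(mu) - 1)
    dt <- data.table::data.table(
      chrom = attr(template, "chrom"),
      start = format(start, scientific = FALSE, trim = TRUE),
      end = format(start + attr(template, "width"), scientific = FALSE,
                   trim = TRUE),
      value = formatC(mu, digits = 15, format = "g"))
    data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
    return(invisible(path))
  }
  dt <- data.table::data.table(position = seq_along(mu),
                               mu_hat = formatC(mu, digits = 15,
                                                format = "g"))
  for (field in c("sigma2_hat", "band_lo", "band_hi"))
    if (!is.null(result[[field]]))
      dt[[field]] <- formatC(result[[field]], digits = 15, format = "g")
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}
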