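#' XPS spectrum container
#'
#' An intensity trace on a strictly increasing binding-energy grid, with a
#' processing-provenance trail. Intensities are normally non-negative;
#' background-subtracted spectra may carry small negative excursions, which
#' are kept (not clipped) so later normalization is unbiased, and flagged in
#' the provenance.
#'
#' @param energy Binding energies in eV, strictly increasing.
#' @param intensity Intensities (counts or normalized units), same length.
#' @param provenance Character vector of processing steps applied, in order.
#' @return Object of class `xps_spectrum`.
#' @export
xps_spectrum <- function(energy, intensity, provenance = character()) {
  energy <- as.numeric(energy); intensity <- as.numeric(intensity)
  if (length(energy) != length(intensity))
    stop("energy and intensity must have the same length")
  if (length(energy) < 2L) stop("a spectrum needs at least two points")
  if (any(!is.finite(energy)) || any(!is.finite(intensity)))
    stop("non-finite values in spectrum")
  if (any(diff(energy) <= 0))
    stop("energy grid must be strictly increasing")
  if (any(intensity < 0) && !any(grepl("negative", provenance)))
    provenance <- c(provenance, "negative-intensities-present")
  structure(list(energy = energy, intensity = intensity,
                 provenance = provenance), class = "xps_spectrum")
}

add_provenance <- function(spec, step) {
  spec$provenance <- c(spec$provenance, step)
  spec
}

#' @export
print.xps_spectrum <- function(x, ...) {
  cat(sprintf("<xps_spectrum> %d points, %.2f-%.2f eV, max %.4g\n",
              length(x$energy), min(x$energy), max(x$energy),
              max(x$intensity)))
  if (length(x$provenance))
    cat("  provenance:", paste(x$provenance, collapse = " | "), "\n")
  invisible(x)
}

#' @export
as.data.frame.xps_spectrum <- function(x, ...) {
  data.frame(be_eV = x$energy, intensity = x$intensity)
}

#' @export
#' @importFrom graphics plot lines legend par
plot.xps_spectrum <- function(x, ..., xlab = "Binding energy (eV)",
                              ylab = "Intensity") {
  # XPS convention: binding energy decreases to the right
  plot(x$energy, x$intensity, type = "l", xlim = rev(range(x$energy)),
       xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Default binding-energy grid
#'
#' @param lo,hi,step Grid limits and spacing in eV.
#' @return Numeric vector, ascending.
#' @export
default_grid <- function(lo = 280, hi = 294, step = 0.05) seq(lo, hi, by = step)

#' Read / write two-column spectrum files
#'
#' The canonical dialect is comma-separated `be_eV,intensity` with optional
#' `#` comment lines (the writer stores the provenance there). Rows given in
#' descending binding energy (the XPS display convention) are re-sorted to
#' ascending storage order.
#'
#' @param path File path.
#' @return `read_spectrum_csv`: an [xps_spectrum()].
#' @export
read_spectrum_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.csv(path, comment.char = "#", header = FALSE,
                         stringsAsFactors = FALSE)
  if (suppressWarnings(is.na(as.numeric(tab[1, 1]))))  # tolerate a header row
    tab <- tab[-1, , drop = FALSE]
  if (ncol(tab) < 2) stop("expected two columns (be_eV, intensity) in ", path)
  e <- as.numeric(tab[[1]]); i <- as.numeric(tab[[2]])
  if (any(is.na(e)) || any(is.na(i))) stop("non-numeric spectrum data in ", path)
  o <- order(e)
  xps_spectrum(e[o], i[o], provenance = paste0("read:", basename(path)))
}

#' @param spec An [xps_spectrum()].
#' @rdname read_spectrum_csv
#' @export
write_spectrum_csv <- function(spec, path) {
  stopifnot(inherits(spec, "xps_spectrum"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# xpsprot %s | provenance: %s",
                     as.character(utils::packageVersion("xpsprot")),
                     paste(spec$provenance, collapse = " | ")), con)
  utils::write.table(data.frame(spec$energy, spec$intensity), con,
                     sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a CasaXPS-style ASCII export
#'
#' Tab-separated export with a header row; the first two numeric columns are
#' taken as binding energy (eV) and intensity.
#'
#' @param path File path.
#' @return An [xps_spectrum()].
#' @export
read_casaxps <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  num <- vapply(tab, function(col)
    !anyNA(suppressWarnings(as.numeric(col))), logical(1))
  if (sum(num) < 2) stop("fewer than two numeric columns in ", path)
  idx <- which(num)[1:2]
  e <- as.numeric(tab[[idx[1]]]); i <- as.numeric(tab[[idx[2]]])
  o <- order(e)
  xps_spectrum(e[o], i[o], provenance = paste0("read-casaxps:", basename(path)))
}

#' Resample a spectrum onto a target grid
#'
#' Linear interpolation; extrapolation outside the source span is refused.
#'
#' @param spec An [xps_spectrum()].
#' @param target_grid Ascending binding energies within the source span.
#' @return Resampled [xps_spectrum()].
#' @export
resample <- function(spec, target_grid) {
  stopifnot(inherits(spec, "xps_spectrum"))
  tol <- 1e-9
  if (min(target_grid) < min(spec$energy) - tol ||
      max(target_grid) > max(spec$energy) + tol)
    stop(sprintf(
      "resample would extrapolate: target [%.3f, %.3f] outside source [%.3f, %.3f] eV",
      min(target_grid), max(target_grid), min(spec$energy), max(spec$energy)))
  y <- stats::approx(spec$energy, spec$intensity, xout = target_grid,
                     rule = 1)$y
  xps_spectrum(target_grid, y, provenance = c(spec$provenance, "resampled"))
}

#' Normalize a spectrum to unit maximum
#'
#' @param spec An [xps_spectrum()].
#' @return Spectrum with maximum intensity exactly 1; idempotent.
#' @export
normalize_max <- function(spec) {
  stopifnot(inherits(spec, "xps_spectrum"))
  m <- max(spec$intensity)
  if (m <= 0) stop("cannot max-normalize: maximum intensity is not positive")
  spec$intensity <- spec$intensity / m
  if (!identical(utils::tail(spec$provenance, 1), "max-normalized"))
    spec <- add_provenance(spec, "max-normalized")
  spec
}

same_grid <- function(a, b, tol = 1e-8) {
  length(a$energy) == length(b$energy) &&
    max(abs(a$energy - b$energy)) <= tol
}
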