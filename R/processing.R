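#' Iterative Shirley background subtraction
#'
#' Computes the standard Shirley background inside an energy window: the
#' background at each binding energy rises in proportion to the integrated,
#' background-corrected signal on the low-binding-energy (high kinetic
#' energy) side, pinned to the endpoint intensities, and is iterated to a
#' fixed point. Endpoint levels are estimated as the mean intensity within
#' `endpoint_halfwidth` of each window edge, which makes them robust to
#' single-channel noise.
#'
#' @param spec An [xps_spectrum()].
#' @param window_lo,window_hi Window limits in eV (defaults: full grid span).
#' @param tol Relative convergence tolerance on the background update.
#' @param max_iter Maximum number of iterations; non-convergence is flagged,
#'   never silent.
#' @param endpoint_halfwidth Averaging half-width for endpoint levels (eV).
#' @param clip_negative Clip negative corrected intensities to zero
#'   (default `FALSE`: negatives are kept and flagged so max-normalization
#'   is unbiased).
#' @return Object of class `shirley_result`: `background` (an
#'   [xps_spectrum()] on the window grid), `corrected` (input minus
#'   background), `iterations_used`, `converged`, `n_negative`.
#' @export
shirley_background <- function(spec, window_lo = NULL, window_hi = NULL,
                               tol = 1e-6, max_iter = 50L,
                               endpoint_halfwidth = 0.2,
                               clip_negative = FALSE) {
  stopifnot(inherits(spec, "xps_spectrum"))
  if (is.null(window_lo)) window_lo <- min(spec$energy)
  if (is.null(window_hi)) window_hi <- max(spec$energy)
  if (window_lo >= window_hi) stop("window_lo must be below window_hi")
  if (window_lo < min(spec$energy) - 1e-9 ||
      window_hi > max(spec$energy) + 1e-9)
    stop("Shirley window must lie inside the spectrum grid")
  sel <- spec$energy >= window_lo - 1e-9 & spec$energy <= window_hi + 1e-9
  e <- spec$energy[sel]; y <- spec$intensity[sel]
  n <- length(e)
  if (n < 5L) stop("Shirley window contains too few points")
  i_lo <- mean(y[e <= e[1] + endpoint_halfwidth])
  i_hi <- mean(y[e >= e[n] - endpoint_halfwidth])

  trapz_cum <- function(f) cumsum(c(0, diff(e) * (utils::head(f, -1) + utils::tail(f, -1)) / 2))
  b <- i_lo + (i_hi - i_lo) * (e - e[1]) / (e[n] - e[1])  # linear start
  scale_ref <- max(abs(y)) + .Machine$double.eps
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    a <- trapz_cum(y - b)
    atot <- a[n]
    b_new <- if (abs(atot) < 1e-12 * scale_ref * (e[n] - e[1])) {
      # degenerate (no net peak area): fall back to the flat/linear pin
      i_lo + (i_hi - i_lo) * (e - e[1]) / (e[n] - e[1])
    } else {
      i_lo + (i_hi - i_lo) * a / atot
    }
    delta <- max(abs(b_new - b)) / scale_ref
    b <- b_new
    if (delta < tol) { converged <- TRUE; break }
  }
  corrected <- y - b
  n_neg <- sum(corrected < 0)
  if (clip_negative) corrected <- pmax(corrected, 0)
  prov <- c(spec$provenance,
            sprintf("shirley[%.2f,%.2f]", window_lo, window_hi),
            if (!converged) "shirley-not-converged")
  structure(list(
    background = xps_spectrum(e, b, provenance = "shirley-background"),
    corrected = xps_spectrum(e, corrected, provenance = prov),
    iterations_used = iter, converged = converged, n_negative = n_neg),
    class = "shirley_result")
}

#' @export
print.shirley_result <- function(x, ...) {
  cat(sprintf("<shirley_result> %d iterations, converged: %s, %d negative point(s)\n",
              x$iterations_used, x$converged, x$n_negative))
  invisible(x)
}

#' Calibrate the binding-energy scale on the main peak
#'
#' Rigidly shifts the grid so the apex of the dominant peak sits at
#' `reference_be` (285.0 eV, the aliphatic-carbon convention). The apex is
#' located by parabolic interpolation through the maximum channel and its two
#' neighbours, so calibration is finer than the grid step.
#'
#' @param spec An [xps_spectrum()] with a dominant peak.
#' @param reference_be Target apex position in eV.
#' @return Shifted [xps_spectrum()]; the applied shift is recorded in the
#'   provenance.
#' @export
calibrate_energy <- function(spec, reference_be = 285.0) {
  stopifnot(inherits(spec, "xps_spectrum"))
  y <- spec$intensity
  if (max(y) - min(y) <= 0) stop("cannot calibrate a flat spectrum (no apex)")
  i <- which.max(y)
  apex <- if (i == 1L || i == length(y)) spec$energy[i] else {
    # parabola through (e[i-1..i+1], y[i-1..i+1]); vertex offset in grid units
    y0 <- y[i - 1L]; y1 <- y[i]; y2 <- y[i + 1L]
    denom <- y0 - 2 * y1 + y2
    off <- if (abs(denom) < .Machine$double.eps) 0 else 0.5 * (y0 - y2) / denom
    spec$energy[i] + off * (spec$energy[i + 1L] - spec$energy[i])
  }
  shift <- reference_be - apex
  spec$energy <- spec$energy + shift
  add_provenance(spec, sprintf("calibrated(shift=%+.4f eV)", shift))
}
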