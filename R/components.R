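#' Default C1s component table
#'
#' One spectral line per carbon environment: binding energy (eV), FWHM (eV,
#' 1.1 for all components by default) and line shape. Shipped as
#' `inst/extdata/component_table.csv`; pass `path` to use your own table, or
#' edit the returned data.frame (e.g. to override one binding energy) and
#' hand it back to [simulate_protein_spectrum()].
#'
#' @param path Optional path to an alternative table in the same CSV format.
#' @return data.frame with columns `environment`, `be_eV`, `fwhm_eV`,
#'   `shape` ("gaussian" or "gl"), `gl_mix` (Lorentzian fraction for "gl").
#' @export
default_component_table <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.xps_cache$component_table)) return(.xps_cache$component_table)
    path <- system.file("extdata", "component_table.csv",
                        package = "xpsprot", mustWork = TRUE)
    cache <- TRUE
  } else cache <- FALSE
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                         check.names = FALSE)
  validate_component_table(tab)
  if (cache) .xps_cache$component_table <- tab
  tab
}

validate_component_table <- function(tab) {
  missing <- setdiff(carbon_environments(), tab$environment)
  if (length(missing))
    stop("component table must cover all ten environments; missing: ",
         paste(missing, collapse = ", "))
  if (any(tab$be_eV < 283 | tab$be_eV > 292))
    stop("component binding energies must lie within [283, 292] eV")
  if (any(tab$fwhm_eV <= 0)) stop("component FWHM must be > 0")
  invisible(tab)
}

# unit-area line shapes on an energy grid
peak_shape <- function(energy, be, fwhm, shape = "gaussian", gl_mix = 0) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  g <- stats::dnorm(energy, mean = be, sd = sigma)
  if (shape == "gaussian") return(g)
  if (shape == "gl") {
    gamma <- fwhm / 2
    l <- (gamma / pi) / ((energy - be)^2 + gamma^2)   # unit-area Lorentzian
    return((1 - gl_mix) * g + gl_mix * l)
  }
  stop("unknown line shape: ", shape)
}

#' Simulate a protein C1s spectrum from its composition
#'
#' Each carbon environment contributes one line centred at its tabulated
#' binding energy, weighted by its fraction of the protein's carbon atoms;
#' the sum is max-normalized to 1. The grid must span every active
#' component's centre by at least three FWHM on each side, so no line is
#' truncated.
#'
#' @param profile A [composition_profile()].
#' @param table Component table, see [default_component_table()].
#' @param grid Ascending binding-energy grid in eV.
#' @return An [xps_spectrum()] with provenance
#'   `"simulated"`, `"max-normalized"`.
#' @export
#' @examples
#' prof <- composition_profile(protein_sequence("GGGG"), termini = FALSE)
#' simulate_protein_spectrum(prof)
simulate_protein_spectrum <- function(profile, table = default_component_table(),
                                      grid = default_grid()) {
  stopifnot(inherits(profile, "composition_profile"))
  validate_component_table(table)
  rownames(table) <- table$environment
  active <- names(profile$env_fractions)[profile$env_fractions > 0]
  lo_need <- min(table[active, "be_eV"] - 3 * table[active, "fwhm_eV"])
  hi_need <- max(table[active, "be_eV"] + 3 * table[active, "fwhm_eV"])
  if (min(grid) > lo_need || max(grid) < hi_need)
    stop(sprintf("grid too narrow: must span at least [%.2f, %.2f] eV",
                 lo_need, hi_need))
  intensity <- numeric(length(grid))
  for (env in active) {
    row <- table[env, ]
    intensity <- intensity + profile$env_fractions[[env]] *
      peak_shape(grid, row$be_eV, row$fwhm_eV, row$shape, row$gl_mix)
  }
  normalize_max(xps_spectrum(grid, intensity, provenance = "simulated"))
}

#' Theoretical composition of the bare polyester substrate
#'
#' Carbon-environment fractions of the poly(epsilon-caprolactone) repeat unit
#' -(CH2)5-C(O)O-: five aliphatic carbons of which one is alpha to the ester
#' (C-C(O)O) and one bears the ester oxygen (mapped onto the C-OH slot,
#' 286.5 eV), plus the ester carbonyl carbon (mapped onto the COOH slot,
#' 289.0 eV). Fractions: CHx 3/6, C-C(O)O 1/6, C-O 1/6, ester 1/6.
#'
#' @return A [composition_profile()] (repeat-unit elements C6H10O2; the
#'   polymer has no nitrogen, so C/N is `NA`).
#' @export
pcl_theoretical_profile <- function() {
  new_composition_profile(
    c("CHx" = 3 / 6, "C-C(O)O" = 1 / 6, "C-OH" = 1 / 6, "COOH" = 1 / 6),
    c(C = 6, H = 10, N = 0, O = 2, S = 0),
    id = "pcl-theoretical")
}
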