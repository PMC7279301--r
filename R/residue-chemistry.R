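#' @keywords internal
"_PACKAGE"

#' The ten C1s carbon environments
#'
#' Closed set of carbon chemical-environment labels used throughout the
#' package. Every carbon atom of every standard amino-acid residue is
#' assigned to exactly one of these classes; no operation emits a label
#' outside this set.
#'
#' @return Character vector of length ten, in ascending default
#'   binding-energy order.
#' @export
#' @examples
#' carbon_environments()
carbon_environments <- function() {
  c("C=C", "CHx", "C=C-N", "C-C(O)O", "C-OH",
    "C-N", "C=N", "N-C=O", "C-S", "COOH")
}

ELEMENTS <- c("C", "H", "N", "O", "S")

# package-local cache for the parsed chemistry table
.xps_cache <- new.env(parent = emptyenv())

#' Per-residue chemistry table
#'
#' Reads (and caches) the packaged plain-text table mapping each of the 20
#' standard amino-acid residues, as in-chain residues (free amino acid minus
#' one water), to element counts and carbon-environment counts. The table
#' ships as `inst/extdata/residue_chemistry.tsv` so the chemistry can be
#' audited, or replaced, without reading code.
#'
#' @param path Path to an alternative table in the same format; the packaged
#'   default is used when `NULL`. Supplying a path bypasses the cache, which
#'   makes the assignment policy pluggable (e.g. a variant merging C-C(O)O
#'   into CHx).
#' @return A data.frame with one row per residue: `residue`, element counts
#'   `C,H,N,O,S`, and one count column per carbon environment.
#' @export
residue_chemistry_table <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.xps_cache$residue_table)) return(.xps_cache$residue_table)
    path <- system.file("extdata", "residue_chemistry.tsv",
                        package = "xpsprot", mustWork = TRUE)
    cache <- TRUE
  } else cache <- FALSE
  tab <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                           stringsAsFactors = FALSE)
  stopifnot(identical(sort(tab$residue), sort(AA_CODES)),
            all(carbon_environments() %in% names(tab)),
            all(ELEMENTS %in% names(tab)))
  envsum <- rowSums(tab[, carbon_environments()])
  if (any(envsum != tab$C))
    stop("chemistry table violates sum(env_counts) == C for residue(s): ",
         paste(tab$residue[envsum != tab$C], collapse = ", "))
  rownames(tab) <- tab$residue
  if (cache) .xps_cache$residue_table <- tab
  tab
}

AA_CODES <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

check_residue <- function(residue, context = NULL) {
  residue <- toupper(residue)
  bad <- !(residue %in% AA_CODES)
  if (any(bad)) {
    where <- if (is.null(context)) which(bad)[1L] else context
    stop(sprintf("unknown residue code '%s' (position %s)",
                 residue[bad][1L], as.character(where)), call. = FALSE)
  }
  residue
}

#' Carbon-environment counts of one residue
#'
#' @param residue One-letter code of a standard amino acid (case-insensitive).
#' @param table Chemistry table, see [residue_chemistry_table()].
#' @return Named integer vector over all ten environments (zeros included);
#'   its sum equals the residue's carbon count.
#' @export
#' @examples
#' residue_environment_counts("G")  # Calpha -> C-N, carbonyl -> N-C=O
residue_environment_counts <- function(residue, table = residue_chemistry_table()) {
  residue <- check_residue(residue)
  counts <- unlist(table[residue, carbon_environments()])
  stats::setNames(as.integer(counts), carbon_environments())
}

#' Element counts of one residue
#'
#' In-chain stoichiometry: the free amino acid minus one water.
#'
#' @inheritParams residue_environment_counts
#' @return Named integer vector over C, H, N, O, S.
#' @export
#' @examples
#' residue_elements("W")  # tryptophan C11H12N2O2 minus H2O
residue_elements <- function(residue, table = residue_chemistry_table()) {
  residue <- check_residue(residue)
  counts <- unlist(table[residue, ELEMENTS])
  stats::setNames(as.integer(counts), ELEMENTS)
}
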