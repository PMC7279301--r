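#' Protein sequence object
#'
#' Lightweight container for a validated amino-acid sequence.
#'
#' @param residues Character vector of one-letter codes, or a single string.
#' @param id Sequence identifier.
#' @param chain_count Number of polypeptide chains (for termini accounting).
#' @return An object of class `protein_sequence`.
#' @export
protein_sequence <- function(residues, id = "protein", chain_count = 1L) {
  if (length(residues) == 1L && nchar(residues[1L]) > 1L)
    residues <- strsplit(residues, "")[[1L]]
  residues <- toupper(residues)
  residues <- residues[residues != "*"]
  if (length(residues) == 0L) stop("empty sequence for record '", id, "'")
  bad <- which(!(residues %in% AA_CODES))
  if (length(bad))
    stop(sprintf("non-standard residue code '%s' in record '%s' at position %d",
                 residues[bad[1L]], id, bad[1L]), call. = FALSE)
  if (chain_count < 1L) stop("chain_count must be a positive integer")
  structure(list(id = id, residues = residues,
                 chain_count = as.integer(chain_count)),
            class = "protein_sequence")
}

#' @export
print.protein_sequence <- function(x, ...) {
  cat(sprintf("<protein_sequence> %s: %d residues, %d chain(s)\n",
              x$id, length(x$residues), x$chain_count))
  invisible(x)
}

#' @export
length.protein_sequence <- function(x) length(x$residues)

#' Read protein sequences from a FASTA file
#'
#' Parses via Biostrings, uppercases, strips `*` stop symbols, and validates
#' every residue against the 20-letter standard alphabet (reporting the
#' offending code, record and position on failure).
#'
#' @param path Path to a FASTA file.
#' @return List of [protein_sequence()] objects, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(set))
  lapply(seq_along(set), function(i)
    protein_sequence(as.character(set[[i]]), id = ids[i]))
}

#' Packaged protein sequence fixtures
#'
#' Returns one of the sequence stand-ins shipped with the package. These are
#' synthetic/reconstructed stand-ins (see the FASTA headers), not fetched
#' database entries. `"hrang"` is the recombinant angiogenin chimera built by
#' concatenating an artificial leader, the tandem ZZ domain and mature human
#' angiogenin into a single chain.
#'
#' @param id One of `"apoa1"`, `"zz"`, `"angiogenin"`, `"hrang"`,
#'   `"fibronectin"`.
#' @param leader Leader peptide prepended when `id = "hrang"`; the default is
#'   a synthetic 8-residue placeholder (the real leader is not published).
#' @return A [protein_sequence()].
#' @export
protein_fixture <- function(id = c("apoa1", "zz", "angiogenin", "hrang",
                                   "fibronectin"),
                            leader = "MASMTGGQ") {
  id <- match.arg(id)
  fixture <- function(stem)
    read_fasta(system.file("extdata", "sequences",
                           paste0("synthetic-", stem, ".fasta"),
                           package = "xpsprot", mustWork = TRUE))[[1L]]
  if (id == "hrang") {
    zz <- fixture("zz"); ang <- fixture("angiogenin")
    return(protein_sequence(c(strsplit(toupper(leader), "")[[1L]],
                              zz$residues, ang$residues), id = "hrang"))
  }
  fixture(id)
}

#' Whole-protein carbon-environment fractions and elemental ratios
#'
#' Aggregates per-residue chemistry over a sequence: environment counts are
#' summed (with an optional chain-termini correction) and normalized to the
#' total number of carbon atoms; element counts are summed likewise.
#'
#' The termini correction, applied once per chain, converts the C-terminal
#' backbone carbonyl from the amide class (N-C=O) to COOH and restores the
#' chain's water of hydrolysis (+H2O) in the element totals; the N-terminal
#' amine changes no carbon class. Negligible for proteins of 100+ residues
#' but kept for correctness on short peptides.
#'
#' @param seq A [protein_sequence()], or a string/character vector coerced to
#'   one.
#' @param termini Apply the chain-termini correction (default `TRUE`).
#' @param table Chemistry table, see [residue_chemistry_table()].
#' @return Object of class `composition_profile`: list with `env_fractions`
#'   (named, sums to 1), `elements` (named totals over C,H,N,O,S), `ratios`
#'   (`CN`, `NC`, `OC`), `n_residues` and `id`.
#' @export
#' @examples
#' composition_profile(protein_sequence("GGGG"), termini = FALSE)
composition_profile <- function(seq, termini = TRUE,
                                table = residue_chemistry_table()) {
  if (!inherits(seq, "protein_sequence")) seq <- protein_sequence(seq)
  rows <- table[seq$residues, , drop = FALSE]
  env <- colSums(rows[, carbon_environments(), drop = FALSE])
  ele <- colSums(rows[, ELEMENTS, drop = FALSE])
  if (termini) {
    k <- seq$chain_count
    if (env["N-C=O"] < k)
      stop("termini correction needs one backbone amide per chain")
    env["N-C=O"] <- env["N-C=O"] - k
    env["COOH"] <- env["COOH"] + k
    ele["H"] <- ele["H"] + 2L * k
    ele["O"] <- ele["O"] + k
  }
  total_c <- sum(env)
  stopifnot(total_c == ele[["C"]])
  new_composition_profile(env / total_c, ele, id = seq$id,
                          n_residues = length(seq$residues))
}

new_composition_profile <- function(env_fractions, elements, id = "profile",
                                    n_residues = NA_integer_) {
  full <- stats::setNames(numeric(length(carbon_environments())),
                          carbon_environments())
  full[names(env_fractions)] <- env_fractions
  if (abs(sum(full) - 1) > 1e-9)
    stop("environment fractions must sum to 1")
  if (any(full < 0 | full > 1)) stop("environment fractions must lie in [0,1]")
  ele <- stats::setNames(numeric(length(ELEMENTS)), ELEMENTS)
  ele[names(elements)] <- elements
  ratios <- list(
    CN = if (ele[["N"]] > 0) ele[["C"]] / ele[["N"]] else NA_real_,
    NC = ele[["N"]] / ele[["C"]],
    OC = ele[["O"]] / ele[["C"]])
  structure(list(env_fractions = full, elements = ele, ratios = ratios,
                 n_residues = n_residues, id = id),
            class = "composition_profile")
}

#' @export
print.composition_profile <- function(x, digits = 4, ...) {
  cat(sprintf("<composition_profile> %s (%s residues)\n", x$id,
              ifelse(is.na(x$n_residues), "?", x$n_residues)))
  f <- x$env_fractions[x$env_fractions > 0]
  print(round(f, digits))
  cat(sprintf("C/N = %s   N/C = %.4f   O/C = %.4f\n",
              ifelse(is.na(x$ratios$CN), "NA (no nitrogen)",
                     sprintf("%.4f", x$ratios$CN)),
              x$ratios$NC, x$ratios$OC))
  invisible(x)
}

#' Atomic ratio from survey atomic percentages
#'
#' Quotient of two atomic percentages (e.g. O/C or N/C from an XPS survey
#' quantification table), with the conventional two-decimal presentation.
#'
#' @param numerator_at_pct,denominator_at_pct Atomic percentages.
#' @return List with `value` (full precision) and `rounded` (2 d.p.).
#' @export
#' @examples
#' atomic_ratio(26.1, 73.9)$rounded  # O/C of the bare polyester surface
atomic_ratio <- function(numerator_at_pct, denominator_at_pct) {
  if (denominator_at_pct <= 0) stop("denominator atomic percentage must be > 0")
  if (numerator_at_pct < 0) stop("numerator atomic percentage must be >= 0")
  v <- numerator_at_pct / denominator_at_pct
  list(value = v, rounded = round(v, 2))
}

#' Integer-percent presentation
#'
#' Percentages are presented with the fractional part truncated (e.g. 28.64
#' is presented as 28), matching how coverage values are conventionally
#' printed in this workflow.
#'
#' @param value Percentage on the 0-100 scale.
#' @return Integer percent.
#' @export
percent_presentation <- function(value) as.integer(trunc(value))

#' Elemental (N/C) estimate of protein surface concentration
#'
#' Independent cross-check of the spectral mixture fit: the measured surface
#' nitrogen-to-carbon ratio, scaled by the protein's carbon-to-nitrogen ratio
#' computed from its sequence, estimates the fraction of surface carbon that
#' belongs to protein,
#' \deqn{\mathrm{conc} = \frac{N_{exp}}{C_{exp}} \times
#'       \frac{C_{protein}}{N_{protein}} \times 100\%.}
#'
#' @param nc_experiment Measured N/C atomic ratio (dimensionless).
#' @param cn_protein Protein C/N ratio from its composition (dimensionless).
#' @param allow_zero_nitrogen Permit `nc_experiment = 0` (returns 0) for
#'   surfaces where nitrogen is below the detection limit.
#' @return List with `value` (percent, full precision) and `percent`
#'   (integer presentation).
#' @export
#' @examples
#' eq_elemental_concentration(0.08, 3.58)
eq_elemental_concentration <- function(nc_experiment, cn_protein,
                                       allow_zero_nitrogen = FALSE) {
  if (cn_protein <= 0) stop("protein C/N ratio must be > 0")
  if (nc_experiment < 0 || (nc_experiment == 0 && !allow_zero_nitrogen))
    stop("experimental N/C ratio must be > 0 ",
         "(set allow_zero_nitrogen = TRUE for below-detection surfaces)")
  v <- nc_experiment * cn_protein * 100
  list(value = v, percent = percent_presentation(v))
}

#' Published sample compositions (at.%)
#'
#' Packaged XPS survey quantification table for the nanofiber samples
#' (carbon, oxygen, nitrogen atomic percent), used by examples and the
#' elemental estimator.
#'
#' @return data.frame with columns `sample`, `C_at`, `O_at`, `N_at`.
#' @export
sample_composition <- function() {
  utils::read.delim(system.file("extdata", "sample_composition.tsv",
                                package = "xpsprot", mustWork = TRUE),
                    comment.char = "#", stringsAsFactors = FALSE)
}
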