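#' Standardize SMILES for cross-database compound identity
#'
#' Converts arbitrary input SMILES into the unique standardized
#' representation used throughout the pipeline to integrate compounds
#' across activity databases. The ordered protocol is: parse, keep the
#' largest organic fragment (salt/solvent stripping), neutralize formal
#' charges where a valence-legal neutral protonation state exists, strip
#' stereochemistry and isotope labels, and emit the OpenBabel canonical
#' form. Two inputs denoting the same desalted, neutral, achiral molecule
#' yield byte-identical `standard_smiles`.
#'
#' The largest organic fragment is the connected fragment with the most
#' heavy atoms that contains at least one carbon; ties are broken by the
#' lexicographically smallest canonical SMILES. Permanent charges that
#' have no neutral protonation state (e.g. quaternary nitrogen) are left
#' intact. Tautomers are not merged.
#'
#' @param smiles character vector of SMILES strings.
#' @return A data.frame with one row per input and columns
#'   `input_smiles`, `standard_smiles`, `valid`, `rejection_reason`.
#'   Unparseable inputs carry `valid = FALSE` and reason `"parse_error"`;
#'   inputs with no carbon-containing fragment carry `"inorganic"`.
#' @examples
#' standardize_smiles(c("CC(=O)O.[Na+].[Cl-]", "C[C@@H](N)C(=O)O", "CC(=O)[O-]"))
#' @export
standardize_smiles <- function(smiles) {
  stopifnot(is.character(smiles))
  res <- lapply(smiles, standardize_one)
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(input_smiles = character(), standard_smiles = character(),
                      valid = logical(), rejection_reason = character(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

standardize_one <- function(s) {
  fail <- function(reason) {
    data.frame(input_smiles = if (is.na(s)) NA_character_ else s,
               standard_smiles = "", valid = FALSE,
               rejection_reason = reason, stringsAsFactors = FALSE)
  }
  if (is.na(s) || !nzchar(trimws(s))) return(fail("parse_error"))
  s0 <- trimws(s)
  # A dot only ever separates disconnected fragments in SMILES, so the
  # textual split is exact.
  frags <- strsplit(s0, ".", fixed = TRUE)[[1]]
  frags <- frags[nzchar(frags)]
  if (length(frags) == 0L) return(fail("parse_error"))
  block <- paste0(paste(frags, paste0("f", seq_along(frags))), "\n",
                  collapse = "")
  desc <- tryCatch(ob_describe(block, neutralize = TRUE),
                   error = function(e) NULL)
  # OpenBabel stops the stream on the first bad fragment; any shortfall
  # means some fragment failed to parse.
  if (is.null(desc) || nrow(desc) != length(frags)) return(fail("parse_error"))
  organic <- desc[formula_has_carbon(desc$formula), , drop = FALSE]
  if (nrow(organic) == 0L) return(fail("inorganic"))
  organic <- organic[order(-organic$n_heavy, organic$cansmi), , drop = FALSE]
  data.frame(input_smiles = s, standard_smiles = organic$cansmi[[1L]],
             valid = TRUE, rejection_reason = "", stringsAsFactors = FALSE)
}

#' Standardize a SMILES file in batch mode
#'
#' Reads one SMILES per line (optionally followed by a tab-separated
#' identifier), standardizes each, and writes a TSV with columns
#' `input_smiles`, `standard_smiles`, `valid`, `rejection_reason` (plus
#' `id` when identifiers were present).
#'
#' @param input path to the SMILES file.
#' @param output path of the TSV to write; when `NULL` the table is only
#'   returned.
#' @return The standardization table, invisibly when `output` is given.
#' @export
standardize_file <- function(input, output = NULL) {
  lines <- readLines(input, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  smi <- vapply(parts, function(p) p[[1L]], "")
  ids <- vapply(parts, function(p) if (length(p) > 1L) p[[2L]] else NA_character_, "")
  tab <- standardize_smiles(smi)
  if (any(!is.na(ids))) tab <- cbind(id = ids, tab)
  if (!is.null(output)) {
    utils::write.table(tab, output, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(tab))
  }
  tab
}
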