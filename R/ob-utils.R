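# Internal OpenBabel helpers shared by the chemistry modules.
#
# All conversions go through ChemmineOB::convertFormat, which maps the
# data.frame of options onto OpenBabel general options (so transformation
# ops such as --neutralize and --append are available). The "TXT" output
# format with an appended descriptor list is used to obtain, in a single
# pass per molecule stream: the title, the canonical SMILES without
# isotopes or stereochemistry (descriptor cansmiNS), the heavy-atom count
# (descriptor atoms; hydrogens stay implicit on SMILES input) and the
# molecular formula.

ob_opts <- function(...) {
  kv <- c(...)
  data.frame(names = names(kv), args = unname(kv), stringsAsFactors = FALSE)
}

# Convert a SMILES block (one molecule per line, optional title after
# whitespace) and return a data.frame keyed by title. Lines that fail to
# parse are *absent* from the result; OpenBabel aborts the stream at the
# first failure, so callers that need per-molecule error isolation must
# pass molecules one at a time or pre-validate.
ob_describe <- function(smiles_block, neutralize = FALSE) {
  opts <- if (neutralize) {
    ob_opts(neutralize = "", append = "cansmiNS atoms formula")
  } else {
    ob_opts(append = "cansmiNS atoms formula")
  }
  out <- suppressWarnings(
    ChemmineOB::convertFormat("SMI", "TXT", smiles_block, options = opts)
  )
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(id = character(), cansmi = character(),
                      n_heavy = integer(), formula = character(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, " +")
  data.frame(
    id      = vapply(parts, function(p) p[[1L]], ""),
    cansmi  = vapply(parts, function(p) p[[2L]], ""),
    n_heavy = as.integer(vapply(parts, function(p) p[[3L]], "")),
    formula = vapply(parts, function(p) p[[4L]], ""),
    stringsAsFactors = FALSE
  )
}

# TRUE for every SMILES string that OpenBabel parses. Each string gets
# its own conversion so one bad molecule cannot mask the others.
ob_smiles_valid <- function(smiles) {
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(FALSE)
    out <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat(
        "SMI", "TXT", paste0(s, " x\n"), options = ob_opts(append = "atoms"))),
      error = function(e) ""
    )
    nzchar(trimws(out))
  }, logical(1), USE.NAMES = FALSE)
}

# Parse a list of OBMol references from a block of pre-validated SMILES.
ob_mols <- function(smiles) {
  block <- paste0(paste(smiles, paste0("m", seq_along(smiles))), "\n",
                  collapse = "")
  ChemmineOB::forEachMol("SMILES", block, identity)
}

# Unique SMARTS match counts for a vector of pre-validated SMILES against
# one pattern.
ob_smarts_count <- function(mols, smarts) {
  as.integer(ChemmineOB::smartsSearch_OB(mols, smarts, uniqueMatches = TRUE))
}

# Does a formula string contain elemental carbon? Avoids Cl/Ca/Cd/Cr/...
formula_has_carbon <- function(formula) {
  grepl("C(?![a-z])", formula, perl = TRUE)
}

# Convert one or more V2000 molfile texts to canonical SMILES, batched in
# a single OpenBabel pass. Titles must be unique; output is keyed by them.
ob_molfiles_to_cansmi <- function(molfile_texts, titles) {
  stopifnot(length(molfile_texts) == length(titles))
  block <- paste0(paste0(molfile_texts, "$$$$\n"), collapse = "")
  out <- suppressWarnings(
    ChemmineOB::convertFormat("SDF", "CAN", block, options = ob_opts())
  )
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  smi <- sub("\t.*$", "", lines)
  ids <- sub("^[^\t]*\t", "", lines)
  smi[match(titles, ids)]
}

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
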