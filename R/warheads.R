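# Electrophilic warhead detection by SMARTS substructure matching.
#
# The pattern library covers the twelve warheads analyzed here plus the
# two (acrylamide, heterocyclic urea) from the earlier large-scale
# survey; compounds matching only those two are routed to the
# "previously studied" exclusion class rather than the covalent set.
# Published SMARTS are not available for these definitions, so each
# default pattern is authored from the depicted warhead structures and
# can be overridden from a YAML/JSON config.

.default_warheads <- function() {
  w <- rbind(
    # name, smarts, rank; lower rank = more specific
    c("aldehyde", "[CX3H1](=O)[#6]", 2L),
    c("alpha_haloketone", "[#6][CX3](=O)[CX4;H1,H2][F,Cl,Br,I]", 2L),
    c("acrylate", "[CX3]=[CX3][CX3](=O)[OX2][#6]", 2L),
    # ortho-alkynyl benzoate ester; called "alkynyl benzoxaxine" in part
    # of the source literature -- the benzoate reading is used here
    c("alkynyl_benzoate", "[CX2]#[CX2]c1ccccc1[CX3](=O)[OX2][#6]", 1L),
    c("boronic_acid", "[BX3]([OX2H])[OX2H]", 2L),
    c("cyanoacrylamide", "[NX1]#[CX2][CX3](=[CX3])[CX3](=O)[NX3]", 1L),
    c("cyanamide", "[NX3][CX2]#[NX1]", 2L),
    c("epoxide", "[CX4]1[OX2][CX4]1", 2L),
    # activated ester: nitroaryl, pentafluorophenyl or N-hydroxyimide
    # leaving group
    c("reactive_ester",
      paste0("[CX3](=O)[OX2][$(c1ccc(cc1)[N+](=O)[O-]),",
             "$(c1cccc(c1)[N+](=O)[O-]),$(c1ccccc1[N+](=O)[O-]),",
             "$(c1c(F)c(F)c(F)c(F)c1F),$([NX3]([CX3]=O)[CX3]=O)]"), 3L),
    c("sulfonyl_fluoride", "[SX4](=O)(=O)F", 2L),
    c("terminal_alkyne", "[CX2]#[CX2H1]", 3L),
    c("vinyl_sulfone", "[CX3]=[CX3][SX4](=O)(=O)[#6]", 2L),
    # previously studied warheads, detected but excluded from analysis
    c("acrylamide", "[CX3]=[CX3][CX3](=O)[NX3]", 3L),
    c("heterocyclic_urea",
      paste0("[c;$(c:[n,o,s]),$(c:c:[n,o,s]),$(c:c:c:[n,o,s])]",
             "[NX3][CX3](=O)[NX3]"), 2L)
  )
  data.frame(name = w[, 1L], smarts = w[, 2L],
             specificity_rank = as.integer(w[, 3L]),
             stringsAsFactors = FALSE)
}

# Declared nesting: every embedding of the general pattern inside an
# embedding of the specific one is suppressed.
.default_suppression <- data.frame(
  specific = c("cyanoacrylamide", "alkynyl_benzoate", "acrylate"),
  general = c("acrylamide", "terminal_alkyne", "reactive_ester"),
  stringsAsFactors = FALSE
)

#' Names of the warheads analyzed as covalent (excluding the prior-study
#' pair)
#' @return character vector of 12 warhead names.
#' @export
analyzed_warheads <- function() {
  setdiff(.default_warheads()$name, prior_warheads())
}

#' Names of the previously studied warheads routed to the exclusion class
#' @return character vector.
#' @export
prior_warheads <- function() c("acrylamide", "heterocyclic_urea")

#' Load the warhead pattern library
#'
#' With no config the 14 default patterns are returned. A YAML or JSON
#' config mapping warhead names to `{smarts, specificity_rank}` entries
#' overrides or extends the defaults; every pattern is validated at load
#' and an invalid SMARTS aborts with the offending warhead named.
#'
#' @param config_path optional path to a YAML/JSON config.
#' @return data.frame of class `warhead_library` with columns `name`,
#'   `smarts`, `specificity_rank` and a `suppression_pairs` attribute.
#' @export
load_warhead_library <- function(config_path = NULL) {
  lib <- .default_warheads()
  supp <- .default_suppression
  if (!is.null(config_path)) {
    cfg <- if (tolower(tools::file_ext(config_path)) == "json") {
      jsonlite::read_json(config_path)
    } else {
      yaml::read_yaml(config_path)
    }
    pairs <- cfg[["suppression_pairs"]]
    cfg[["suppression_pairs"]] <- NULL
    for (nm in names(cfg)) {
      entry <- cfg[[nm]]
      smarts <- if (is.list(entry)) entry$smarts else as.character(entry)
      rank <- if (is.list(entry) && !is.null(entry$specificity_rank)) {
        as.integer(entry$specificity_rank)
      } else if (nm %in% lib$name) {
        lib$specificity_rank[lib$name == nm]
      } else 2L
      if (nm %in% lib$name) {
        lib$smarts[lib$name == nm] <- smarts
        lib$specificity_rank[lib$name == nm] <- rank
      } else {
        lib <- rbind(lib, data.frame(name = nm, smarts = smarts,
                                     specificity_rank = rank,
                                     stringsAsFactors = FALSE))
      }
    }
    if (!is.null(pairs)) {
      supp <- do.call(rbind, lapply(pairs, function(p) {
        data.frame(specific = p[[1L]], general = p[[2L]],
                   stringsAsFactors = FALSE)
      }))
    }
  }
  stopifnot(!anyDuplicated(lib$name))
  probe <- ob_mols("CC")
  for (i in seq_len(nrow(lib))) {
    ok <- tryCatch({
      ob_smarts_count(probe, lib$smarts[[i]])
      TRUE
    }, error = function(e) FALSE)
    if (!ok) stop("invalid SMARTS pattern for warhead '", lib$name[[i]], "'")
  }
  rownames(lib) <- NULL
  structure(lib, suppression_pairs = supp,
            class = c("warhead_library", "data.frame"))
}

#' Detect electrophilic warheads in standardized compounds
#'
#' Matches every library pattern against every compound and applies the
#' specificity rule: a match of a less specific pattern is suppressed
#' when it is accounted for by an embedding of a declared more specific
#' pattern (e.g. the acrylamide embedding inside a cyanoacrylamide, or
#' the terminal-alkyne embedding inside an alkynyl benzoate). Because
#' unique match counts rather than atom maps drive the comparison, the
#' general pattern survives whenever it has more embeddings than the
#' specific one, i.e. when an independent copy of the motif is present.
#'
#' @param standard_smiles character vector of standardized SMILES.
#' @param library a `warhead_library` from [load_warhead_library()].
#' @return data.frame with columns `standard_smiles`, `matched`
#'   (semicolon-joined warhead names), `is_cpki` (matches at least one of
#'   the twelve analyzed warheads), and `excluded_prior` (matches only
#'   previously studied warheads).
#' @export
detect_warheads <- function(standard_smiles,
                            library = load_warhead_library()) {
  stopifnot(is.character(standard_smiles))
  if (length(standard_smiles) == 0L) {
    return(data.frame(standard_smiles = character(), matched = character(),
                      is_cpki = logical(), excluded_prior = logical(),
                      stringsAsFactors = FALSE))
  }
  if (!all(ob_smiles_valid(standard_smiles))) stop("parse_error")
  mols <- ob_mols(standard_smiles)
  counts <- vapply(seq_len(nrow(library)), function(i) {
    ob_smarts_count(mols, library$smarts[[i]])
  }, integer(length(standard_smiles)))
  counts <- matrix(counts, nrow = length(standard_smiles),
                   dimnames = list(NULL, library$name))
  supp <- attr(library, "suppression_pairs")
  eff <- counts
  for (k in seq_len(nrow(supp))) {
    sp <- supp$specific[[k]]; ge <- supp$general[[k]]
    if (sp %in% colnames(eff) && ge %in% colnames(eff)) {
      drop <- eff[, sp] > 0 & eff[, ge] > 0 & eff[, ge] <= eff[, sp]
      eff[drop, ge] <- 0L
    }
  }
  matched <- apply(eff > 0, 1L, function(row) {
    paste(colnames(eff)[row], collapse = ";")
  })
  sets <- strsplit(matched, ";", fixed = TRUE)
  prior <- prior_warheads()
  new_wh <- setdiff(library$name, prior)
  excluded <- vapply(sets, function(m) {
    length(m) > 0L && all(m %in% prior)
  }, logical(1))
  cpki <- vapply(sets, function(m) any(m %in% new_wh), logical(1)) & !excluded
  data.frame(standard_smiles = standard_smiles, matched = matched,
             is_cpki = cpki, excluded_prior = excluded,
             stringsAsFactors = FALSE)
}

#' Partition compounds into per-warhead subsets
#'
#' A compound joins the subset of every analyzed warhead it matches, so
#' subsets may overlap. Compounds matching no pattern form the
#' non-covalent set; compounds matching only previously studied warheads
#' appear in neither and are returned separately.
#'
#' @param assignments data.frame from [detect_warheads()].
#' @return list with `subsets` (named list of compound vectors, analyzed
#'   warheads only), `non_covalent` and `excluded_prior` vectors.
#' @export
partition_by_warhead <- function(assignments) {
  sets <- strsplit(assignments$matched, ";", fixed = TRUE)
  new_wh <- analyzed_warheads()
  subsets <- list()
  for (i in seq_along(sets)) {
    if (assignments$excluded_prior[[i]]) next
    for (w in intersect(sets[[i]], new_wh)) {
      subsets[[w]] <- c(subsets[[w]], assignments$standard_smiles[[i]])
    }
  }
  list(
    subsets = subsets,
    non_covalent = assignments$standard_smiles[
      !nzchar(assignments$matched)],
    excluded_prior = assignments$standard_smiles[assignments$excluded_prior]
  )
}
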