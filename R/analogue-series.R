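#' Decompose a compound into core/substituent pairs
#'
#' Enumerates retrosynthetic-style decompositions by cutting 1 to
#' `max_cuts` acyclic single bonds. For each cut subset the fragment
#' containing the largest ring assembly (most ring atoms, ties by heavy
#' atoms) becomes the core, with one attachment point per cut; every
#' other fragment must hang off the core through exactly one cut bond
#' and becomes a single-attachment substituent. Decompositions whose
#' core has fewer heavy atoms than twice the combined substituent heavy
#' atoms are discarded, which keeps cores dominant as in
#' matched-analogue practice. Acyclic molecules, and molecules with no
#' qualifying cut, yield an empty set.
#'
#' @param standard_smiles one standardized SMILES string.
#' @param max_cuts maximum number of simultaneous cuts (default 3).
#' @return data.frame with one row per decomposition: `core` (canonical
#'   SMILES with `*` attachment points), `substituents` (semicolon-joined
#'   canonical substituent SMILES, in the core's canonical
#'   attachment-point order), `n_cuts` and `core_heavy`.
#' @export
fragment_compound <- function(standard_smiles, max_cuts = 3) {
  stopifnot(length(standard_smiles) == 1L, max_cuts >= 1)
  empty <- data.frame(core = character(), substituents = character(),
                      n_cuts = integer(), core_heavy = integer(),
                      stringsAsFactors = FALSE)
  mg <- mol_graph(standard_smiles)
  rb <- ring_bonds(mg)
  if (length(rb) == 0L) return(empty)   # no ring assembly, no core
  ring_atoms <- unique(c(mg$bonds$a1[rb], mg$bonds$a2[rb]))
  cand <- setdiff(which(mg$bonds$order == 1L), rb)
  if (length(cand) == 0L) return(empty)

  subsets <- list()
  for (k in seq_len(min(max_cuts, length(cand)))) {
    if (choose(length(cand), k) > 5000) break
    subsets <- c(subsets, utils::combn(cand, k, simplify = FALSE))
  }

  decomps <- list()
  core_graphs <- list()
  sub_graph_sets <- list()
  for (cut in subsets) {
    memb <- components_after_cut(mg, cut)
    if (max(memb) != length(cut) + 1L) next
    ring_per_comp <- tabulate(memb[ring_atoms], nbins = max(memb))
    size_per_comp <- tabulate(memb, nbins = max(memb))
    core_comp <- order(-ring_per_comp, -size_per_comp)[[1L]]
    ends1 <- mg$bonds$a1[cut]; ends2 <- mg$bonds$a2[cut]
    in_core1 <- memb[ends1] == core_comp
    in_core2 <- memb[ends2] == core_comp
    if (any(in_core1 == in_core2)) next  # every cut must cross the core
    core_atoms <- which(memb == core_comp)
    core_heavy <- length(core_atoms)
    subs_heavy <- mg$n - core_heavy
    if (core_heavy < 2L * subs_heavy) next
    core_end <- ifelse(in_core1, ends1, ends2)
    sub_end <- ifelse(in_core1, ends2, ends1)
    core_g <- subgraph_with_dummies(
      mg, core_atoms, data.frame(atom = core_end, label = seq_along(cut)))
    sub_gs <- lapply(seq_along(cut), function(j) {
      subgraph_with_dummies(mg, which(memb == memb[sub_end[[j]]]),
                            data.frame(atom = sub_end[[j]], label = 1L))
    })
    decomps[[length(decomps) + 1L]] <-
      list(n_cuts = length(cut), core_heavy = core_heavy)
    core_graphs[[length(core_graphs) + 1L]] <- core_g
    sub_graph_sets[[length(sub_graph_sets) + 1L]] <- sub_gs
  }
  if (length(decomps) == 0L) return(empty)

  core_smi <- graphs_to_cansmi(core_graphs)
  rows <- vector("list", length(decomps))
  for (i in seq_along(decomps)) {
    core_g <- core_graphs[[i]]
    ord <- canonical_dummy_order(core_g, core_g$dummies)
    perm <- match(ord, core_g$dummies)
    sub_smi <- graphs_to_cansmi(sub_graph_sets[[i]])[perm]
    rows[[i]] <- data.frame(core = core_smi[[i]],
                            substituents = paste(sub_smi, collapse = ";"),
                            n_cuts = decomps[[i]]$n_cuts,
                            core_heavy = decomps[[i]]$core_heavy,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out[, c("core", "substituents")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Reassemble a compound from a core and its substituents
#'
#' Inverse of [fragment_compound()]: parses the canonical core (with `*`
#' attachment points) and the substituents (one `*` each), joins the
#' i-th substituent to the i-th attachment point in the core's canonical
#' attachment order, and returns the canonical SMILES of the result.
#'
#' @param core canonical core SMILES with `*` attachment points.
#' @param substituents character vector of substituent SMILES, one `*`
#'   each, ordered as in the `substituents` column of
#'   [fragment_compound()].
#' @return canonical SMILES of the reassembled molecule.
#' @export
reassemble_compound <- function(core, substituents) {
  core_g <- mol_graph(core)
  core_dummies <- which(core_g$elem == "*")
  stopifnot(length(core_dummies) == length(substituents))
  core_g$dummies <- core_dummies
  ord <- canonical_dummy_order(core_g, core_dummies)

  elem <- core_g$elem; charge <- core_g$charge; bonds <- core_g$bonds
  drop_atoms <- integer()
  for (i in seq_along(substituents)) {
    sg <- mol_graph(substituents[[i]])
    sd <- which(sg$elem == "*")
    stopifnot(length(sd) == 1L)
    off <- length(elem)
    elem <- c(elem, sg$elem); charge <- c(charge, sg$charge)
    sb <- sg$bonds; sb$a1 <- sb$a1 + off; sb$a2 <- sb$a2 + off
    bonds <- rbind(bonds, sb)
    cd <- ord[[i]]
    core_nb <- c(bonds$a2[bonds$a1 == cd & bonds$a2 <= off],
                 bonds$a1[bonds$a2 == cd & bonds$a1 <= off])
    sub_nb <- c(sb$a2[sb$a1 == sd + off], sb$a1[sb$a2 == sd + off])
    bonds <- bonds[!(bonds$a1 %in% c(cd, sd + off) |
                       bonds$a2 %in% c(cd, sd + off)), , drop = FALSE]
    bonds <- rbind(bonds, data.frame(a1 = core_nb[[1L]], a2 = sub_nb[[1L]],
                                     order = 1L))
    drop_atoms <- c(drop_atoms, cd, sd + off)
  }
  keep <- setdiff(seq_along(elem), drop_atoms)
  remap <- match(seq_along(elem), keep)
  bonds$a1 <- remap[bonds$a1]; bonds$a2 <- remap[bonds$a2]
  mg <- list(elem = elem[keep], charge = charge[keep], bonds = bonds,
             n = length(keep))
  graphs_to_cansmi(list(mg))
}

#' Organize compounds into analogue series by shared cores
#'
#' Applies the compound-core relationship idea: every compound is
#' decomposed with [fragment_compound()]; compounds sharing a
#' byte-identical canonical core form a series. Each compound joins at
#' most one series, through its decomposition with the largest core
#' (heavy atoms) that is shared with at least one other compound; cores
#' held by a single compound do not form series, and a compound whose
#' chosen group ends up singleton is left unassigned.
#'
#' @param compounds character vector of standardized, de-duplicated
#'   SMILES.
#' @param max_cuts maximum simultaneous cuts (default 3).
#' @return data.frame with columns `series_id`, `core`,
#'   `standard_smiles`, `substituents`; zero rows when no series exist.
#' @export
build_series <- function(compounds, max_cuts = 3) {
  empty <- data.frame(series_id = character(), core = character(),
                      standard_smiles = character(),
                      substituents = character(), stringsAsFactors = FALSE)
  if (length(compounds) < 2L) return(empty)
  dec <- lapply(compounds, function(s) {
    d <- fragment_compound(s, max_cuts = max_cuts)
    if (nrow(d) > 0L) d$standard_smiles <- s
    d
  })
  dec <- do.call(rbind, dec[vapply(dec, nrow, 1L) > 0L])
  if (is.null(dec) || nrow(dec) == 0L) return(empty)

  sharers <- tapply(dec$standard_smiles, dec$core,
                    function(x) length(unique(x)))
  shared <- names(sharers)[sharers >= 2L]
  dec <- dec[dec$core %in% shared, , drop = FALSE]
  if (nrow(dec) == 0L) return(empty)

  picks <- do.call(rbind, lapply(split(dec, dec$standard_smiles),
                                 function(d) {
    d[order(-d$core_heavy, d$core), , drop = FALSE][1L, , drop = FALSE]
  }))
  grp <- split(picks, picks$core)
  grp <- grp[vapply(grp, nrow, 1L) >= 2L]
  if (length(grp) == 0L) return(empty)
  grp <- grp[order(vapply(grp, function(g) g$core[[1L]], ""))]
  out <- do.call(rbind, lapply(seq_along(grp), function(i) {
    g <- grp[[i]]
    data.frame(series_id = sprintf("S%03d", i), core = g$core,
               standard_smiles = g$standard_smiles,
               substituents = g$substituents, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Extract covalent/non-covalent analogue pairs with large potency gaps
#'
#' Walks every series and emits one record per (covalent compound,
#' warhead-free compound, kinase) combination for which both members
#' have curated activity and the absolute potency difference reaches
#' `log10(min_fold)` log units. `delta_p` keeps its sign (covalent minus
#' non-covalent), so gains and losses are both admitted. A covalent
#' compound matching several analyzed warheads contributes one record
#' per warhead.
#'
#' @param series data.frame from [build_series()].
#' @param curated data.frame from [curate()]'s `curated` element.
#' @param assignments data.frame from [detect_warheads()].
#' @param min_fold minimum fold difference in potency (default 100).
#' @return data.frame with columns `cpki_smiles`, `pki_smiles`,
#'   `target_id`, `warhead`, `delta_p`, `series_id`.
#' @export
extract_pairs <- function(series, curated, assignments, min_fold = 100) {
  stopifnot(min_fold > 1)
  threshold <- log10(min_fold)
  empty <- data.frame(cpki_smiles = character(), pki_smiles = character(),
                      target_id = character(), warhead = character(),
                      delta_p = numeric(), series_id = character(),
                      stringsAsFactors = FALSE)
  if (nrow(series) == 0L) return(empty)
  amap <- stats::setNames(assignments$matched, assignments$standard_smiles)
  cpki_map <- stats::setNames(assignments$is_cpki,
                              assignments$standard_smiles)
  new_wh <- analyzed_warheads()
  rows <- list()
  for (sid in unique(series$series_id)) {
    members <- series$standard_smiles[series$series_id == sid]
    members <- members[members %in% names(amap)]
    cov <- members[cpki_map[members]]
    clean <- members[!nzchar(amap[members])]
    if (length(cov) == 0L || length(clean) == 0L) next
    for (c_smi in cov) {
      whs <- intersect(strsplit(amap[[c_smi]], ";")[[1L]], new_wh)
      c_act <- curated[curated$standard_smiles == c_smi, , drop = FALSE]
      for (p_smi in clean) {
        p_act <- curated[curated$standard_smiles == p_smi, , drop = FALSE]
        common <- intersect(c_act$target_id, p_act$target_id)
        for (tg in common) {
          dp <- c_act$pPotency[c_act$target_id == tg][[1L]] -
            p_act$pPotency[p_act$target_id == tg][[1L]]
          if (abs(dp) >= threshold) {
            for (w in whs) {
              rows[[length(rows) + 1L]] <- data.frame(
                cpki_smiles = c_smi, pki_smiles = p_smi, target_id = tg,
                warhead = w, delta_p = dp, series_id = sid,
                stringsAsFactors = FALSE)
            }
          }
        }
      }
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
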