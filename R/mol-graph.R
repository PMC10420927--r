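# Internal molecular-graph representation used by the analogue-series
# module. Molecules are parsed through ChemmineR/OpenBabel into plain
# atom/bond tables; graph work (ring-bond detection, components) is done
# with igraph; fragments are written back as V2000 molfiles and
# canonicalized by OpenBabel in batched calls.

# Molfile charge-column codes.
.chg_decode <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
                 `5` = -1L, `6` = -2L, `7` = -3L)

# Parse SMILES into a list of graphs: list(elem, charge, bonds, n).
mol_graphs <- function(smiles) {
  sdf <- ChemmineR::smiles2sdf(smiles)
  lapply(seq_along(smiles), function(i) {
    ab <- ChemmineR::atomblock(sdf[[i]])
    bb <- ChemmineR::bondblock(sdf[[i]])
    elem <- sub("_.*$", "", rownames(ab))
    chg_col <- ab[, "C6"]
    charge <- unname(.chg_decode[as.character(chg_col)])
    charge[is.na(charge)] <- 0L
    bonds <- if (is.null(dim(bb)) || nrow(bb) == 0L) {
      data.frame(a1 = integer(), a2 = integer(), order = integer())
    } else {
      data.frame(a1 = as.integer(bb[, 1L]), a2 = as.integer(bb[, 2L]),
                 order = as.integer(bb[, 3L]))
    }
    list(elem = elem, charge = as.integer(charge), bonds = bonds,
         n = length(elem))
  })
}

mol_graph <- function(smiles) mol_graphs(smiles)[[1L]]

# Indices of bonds that sit in rings (= non-bridge edges).
ring_bonds <- function(mg) {
  if (nrow(mg$bonds) == 0L) return(integer())
  g <- igraph::graph_from_edgelist(
    as.matrix(mg$bonds[, c("a1", "a2")]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, mg$n - igraph::vcount(g)))
  br <- igraph::bridges(g)
  setdiff(seq_len(nrow(mg$bonds)), as.integer(br))
}

# Connected components after deleting the bonds in `cut`; returns a
# vector of component ids per atom.
components_after_cut <- function(mg, cut) {
  keep <- setdiff(seq_len(nrow(mg$bonds)), cut)
  el <- as.matrix(mg$bonds[keep, c("a1", "a2"), drop = FALSE])
  g <- igraph::make_empty_graph(n = mg$n, directed = FALSE)
  if (nrow(el) > 0L) g <- igraph::add_edges(g, t(el))
  igraph::components(g)$membership
}

# Extract the subgraph on `atoms`, attaching one dummy atom ("*") for
# each (atom, cut-bond) incidence listed in `attach` (a data.frame with
# columns atom and label). Returns a graph plus the dummy indices in the
# order of `attach`.
subgraph_with_dummies <- function(mg, atoms, attach) {
  idx <- match(seq_len(mg$n), atoms)       # old -> new position
  keep <- mg$bonds$a1 %in% atoms & mg$bonds$a2 %in% atoms
  bonds <- mg$bonds[keep, , drop = FALSE]
  bonds$a1 <- idx[bonds$a1]
  bonds$a2 <- idx[bonds$a2]
  elem <- mg$elem[atoms]
  charge <- mg$charge[atoms]
  nd <- nrow(attach)
  dummy_idx <- integer(nd)
  if (nd > 0L) {
    for (k in seq_len(nd)) {
      elem <- c(elem, "*")
      charge <- c(charge, 0L)
      dummy_idx[k] <- length(elem)
      bonds <- rbind(bonds, data.frame(a1 = idx[attach$atom[k]],
                                       a2 = dummy_idx[k], order = 1L))
    }
  }
  list(elem = elem, charge = charge, bonds = bonds, n = length(elem),
       dummies = dummy_idx)
}

# Serialize a graph as a V2000 molfile. `iso` optionally assigns isotope
# mass numbers to atoms (named by index).
write_molfile <- function(mg, title = "mol", iso = NULL) {
  header <- c(title, "  covkin", "")
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                    mg$n, nrow(mg$bonds))
  atoms <- vapply(seq_len(mg$n), function(i) {
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            0, 0, 0, mg$elem[[i]])
  }, "")
  bonds <- vapply(seq_len(nrow(mg$bonds)), function(i) {
    sprintf("%3d%3d%3d  0  0  0  0", mg$bonds$a1[[i]], mg$bonds$a2[[i]],
            mg$bonds$order[[i]])
  }, "")
  props <- character()
  chg <- which(mg$charge != 0L)
  if (length(chg) > 0L) {
    props <- c(props, vapply(chg, function(i) {
      sprintf("M  CHG  1 %3d %3d", i, mg$charge[[i]])
    }, ""))
  }
  if (!is.null(iso) && length(iso) > 0L) {
    props <- c(props, vapply(seq_along(iso), function(k) {
      sprintf("M  ISO  1 %3d %3d", as.integer(names(iso)[[k]]), iso[[k]])
    }, ""))
  }
  paste(c(header, counts, atoms, bonds, props, "M  END", ""),
        collapse = "\n")
}

# Canonical SMILES for a list of graphs in one OpenBabel pass.
graphs_to_cansmi <- function(mgs) {
  if (length(mgs) == 0L) return(character())
  titles <- paste0("g", seq_along(mgs))
  texts <- vapply(seq_along(mgs), function(i) {
    write_molfile(mgs[[i]], titles[[i]])
  }, "")
  ob_molfiles_to_cansmi(texts, titles)
}

# Canonical ordering of a graph's dummy atoms: each dummy is isotope-
# labelled in turn and the resulting labelled canonical SMILES are
# sorted. Symmetry-equivalent dummies produce identical strings and tie
# arbitrarily, which is chemically equivalent. Returns the dummy indices
# in canonical order.
canonical_dummy_order <- function(mg, dummies) {
  if (length(dummies) <= 1L) return(dummies)
  titles <- paste0("d", seq_along(dummies))
  texts <- vapply(seq_along(dummies), function(k) {
    iso <- stats::setNames(2L, dummies[[k]])
    write_molfile(mg, titles[[k]], iso = iso)
  }, "")
  labelled <- ob_molfiles_to_cansmi(texts, titles)
  dummies[order(labelled, dummies)]
}
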