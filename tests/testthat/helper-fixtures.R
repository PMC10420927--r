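# Shared fixture builders. Everything is constructed in code; no data
# files are read except the packaged census tables.

# One clean activity record that passes every curation filter.
clean_record <- function(compound_smiles = "CCOc1ccc(cc1)C(=O)Nc1ccccn1",
                         target_id = "KIN001", measurement_type = "IC50",
                         relation = "=", value_nM = 100,
                         source = "chembl", ...) {
  base <- data.frame(
    compound_smiles = compound_smiles, target_id = target_id,
    measurement_type = measurement_type, relation = relation,
    value_nM = value_nM,
    relationship_type = if (source == "chembl") "D" else NA_character_,
    assay_confidence = if (source == "chembl") 9L else NA_integer_,
    assay_kinase_count = 1L, activity_comment = "", source = source,
    units = "nM", stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) base[[nm]] <- extra[[nm]]
  base
}

record_batch <- function(...) {
  dfs <- list(...)
  cols <- unique(unlist(lapply(dfs, names)))
  do.call(rbind, lapply(dfs, function(d) {
    for (nm in setdiff(cols, names(d))) d[[nm]] <- NA
    d[cols]
  }))
}

# Independent brute-force reimplementation of the curation cascade,
# used as the oracle for curate(). Deliberately written as plain loops
# over one record at a time.
brute_curate <- function(records, cutoff = 10000, sd_max = 1) {
  flagged <- c("uncertain", "potential transcription error",
               "outside typical range")
  decide <- function(r) {
    if (is.na(r$compound_smiles) || !nzchar(r$compound_smiles) ||
        is.na(r$target_id) || !nzchar(r$target_id) ||
        is.na(suppressWarnings(as.numeric(r$value_nM)))) {
      return("malformed_record")
    }
    if (!is.null(r$units) && !is.na(r$units) && r$units != "nM") {
      return("units")
    }
    if (r$relation != "=") return("relation")
    if (tolower(r$source) == "chembl" &&
        (is.na(r$relationship_type) || r$relationship_type != "D")) {
      return("relationship_type")
    }
    if (!(r$measurement_type %in% c("Ki", "Kd", "IC50"))) {
      return("measurement_type")
    }
    if (as.numeric(r$value_nM) > cutoff) return("potency_cutoff")
    if (r$assay_kinase_count != 1) return("assay_kinase_count")
    if (tolower(r$source) == "chembl" &&
        (is.na(r$assay_confidence) || r$assay_confidence != 9)) {
      return("assay_confidence")
    }
    for (ph in flagged) {
      if (grepl(ph, tolower(r$activity_comment), fixed = TRUE)) {
        return("activity_comment")
      }
    }
    ""
  }
  reasons <- vapply(seq_len(nrow(records)), function(i) {
    decide(records[i, , drop = FALSE])
  }, "")
  kept <- records[reasons == "", , drop = FALSE]
  if (nrow(kept) == 0L) {
    return(list(curated = data.frame(), reasons = reasons))
  }
  std <- standardize_smiles(unique(kept$compound_smiles))
  smap <- stats::setNames(std$standard_smiles, std$input_smiles)
  kept$std <- smap[kept$compound_smiles]
  out <- list()
  for (key in unique(paste(kept$std, kept$target_id))) {
    g <- kept[paste(kept$std, kept$target_id) == key, , drop = FALSE]
    use <- if (any(g$measurement_type %in% c("Ki", "Kd"))) {
      g[g$measurement_type %in% c("Ki", "Kd"), , drop = FALSE]
    } else g
    p <- -log10(as.numeric(use$value_nM) * 1e-9)
    s <- if (length(p) > 1) stats::sd(p) else 0
    if (s >= sd_max || mean(p) < -log10(cutoff * 1e-9)) next
    out[[key]] <- data.frame(standard_smiles = g$std[[1L]],
                             target_id = g$target_id[[1L]],
                             pPotency = mean(p), n = nrow(use),
                             stringsAsFactors = FALSE)
  }
  list(curated = do.call(rbind, c(out, make.row.names = FALSE)),
       reasons = reasons)
}

# Golden warhead molecules: >= 2 positives and >= 2 near-miss negatives
# per default pattern.
warhead_golden_set <- function() {
  list(
    aldehyde = list(pos = c("O=Cc1ccccc1", "CCCC=O"),
                    neg = c("CC(C)=O", "NC=O")),
    alpha_haloketone = list(pos = c("ClCC(=O)c1ccccc1", "CC(=O)CBr"),
                            neg = c("CC(=O)Cl", "CC(=O)CCCl")),
    acrylate = list(pos = c("C=CC(=O)OC", "C=C(C)C(=O)OCC"),
                    neg = c("C=CC(=O)O", "CCC(=O)OC")),
    alkynyl_benzoate = list(pos = c("C#Cc1ccccc1C(=O)OC",
                                    "CC#Cc1ccccc1C(=O)OCC"),
                            neg = c("C#Cc1ccccc1", "COC(=O)c1ccccc1")),
    boronic_acid = list(pos = c("OB(O)c1ccccc1", "CB(O)O"),
                        neg = c("COB(OC)c1ccccc1", "CB(C)O")),
    cyanoacrylamide = list(pos = c("N#C/C(=C/c1ccccc1)C(N)=O",
                                   "N#CC(=CC)C(=O)NC"),
                           neg = c("C=CC(N)=O", "N#CC=CC(N)=O")),
    cyanamide = list(pos = c("CN(C)C#N", "N#CN1CCCCC1"),
                     neg = c("CC#N", "NCC#N")),
    epoxide = list(pos = c("C1CO1", "c1ccccc1C1CO1"),
                   neg = c("C1CCO1", "C1CN1")),
    reactive_ester = list(pos = c("CC(=O)Oc1ccc(cc1)[N+](=O)[O-]",
                                  "CC(=O)ON1C(=O)CCC1=O"),
                          neg = c("CC(=O)Oc1ccccc1", "CC(=O)OC")),
    sulfonyl_fluoride = list(pos = c("O=S(=O)(F)c1ccccc1",
                                     "CCS(F)(=O)=O"),
                             neg = c("CCS(Cl)(=O)=O", "CCS(N)(=O)=O")),
    terminal_alkyne = list(pos = c("C#Cc1ccccc1", "NCC#C"),
                           neg = c("CC#CC", "CC#N")),
    vinyl_sulfone = list(pos = c("C=CS(=O)(=O)c1ccccc1", "C=CS(C)(=O)=O"),
                         neg = c("CCS(=O)(=O)c1ccccc1", "C=CS(C)=O")),
    acrylamide = list(pos = c("C=CC(N)=O", "C=CC(=O)Nc1ccccc1"),
                      neg = c("CCC(N)=O", "CC(=O)N")),
    heterocyclic_urea = list(pos = c("O=C(N)Nc1ccccn1",
                                     "O=C(NC)Nc1ccncc1"),
                             neg = c("O=C(N)Nc1ccccc1", "CNC(N)=O"))
  )
}

# Brute-force analogue-pair oracle: plain double loop over all compound
# pairs and targets, independent of extract_pairs' series walk.
brute_pairs <- function(series, curated, assignments, min_fold = 100) {
  thr <- log10(min_fold)
  new_wh <- analyzed_warheads()
  found <- character()
  for (i in seq_len(nrow(series))) {
    for (j in seq_len(nrow(series))) {
      if (i == j) next
      if (series$series_id[[i]] != series$series_id[[j]]) next
      a <- series$standard_smiles[[i]]; b <- series$standard_smiles[[j]]
      ma <- assignments$matched[assignments$standard_smiles == a]
      mb <- assignments$matched[assignments$standard_smiles == b]
      ia <- assignments$is_cpki[assignments$standard_smiles == a]
      if (length(ma) == 0L || length(mb) == 0L) next
      if (!ia || nzchar(mb)) next
      ta <- curated[curated$standard_smiles == a, ]
      tb <- curated[curated$standard_smiles == b, ]
      for (tg in intersect(ta$target_id, tb$target_id)) {
        dp <- ta$pPotency[ta$target_id == tg][[1L]] -
          tb$pPotency[tb$target_id == tg][[1L]]
        if (abs(dp) >= thr) {
          for (w in intersect(strsplit(ma, ";")[[1L]], new_wh)) {
            found <- c(found, paste(a, b, tg, w, round(dp, 9)))
          }
        }
      }
    }
  }
  sort(found)
}

# Random drug-like SMILES built from scaffold templates; valid by
# construction, used for standardization property tests.
random_library <- function(n, seed = 1) {
  frags <- c("C", "CC", "CCC", "C(C)C", "CCO", "CCN", "COC", "CF",
             "C(F)(F)F", "CCl", "CBr", "CS(C)(=O)=O", "CN(C)C",
             "C#N", "CC=O", "COC(C)=O", "Cc1ccccc1", "CCc1ccncc1")
    templates <- c(
    "O=C(Nc1ccc({R})cc1)c1ccccc1",
    "c1ccc2ncnc(N{R})c2c1",
    "CN1CCN(C(=O)c2ccc({R})cc2)CC1",
    "O=S(=O)(N{R})c1ccc2[nH]ccc2c1",
    "Cc1n[nH]c(N{R})c1-c1ccccc1")
  withr_seed <- function(code) covkin:::with_seed(seed, code)
  withr_seed({
    vapply(seq_len(n), function(i) {
      t <- sample(templates, 1L)
      gsub("{R}", sample(frags, 1L), t, fixed = TRUE)
    }, "")
  })
}
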