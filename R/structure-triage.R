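# Triage of X-ray structures of kinase-ligand complexes: resolution,
# ligand, keyword and covalent-link screening, plus the aggregation
# behind the allosteric-ligand census tables. PDB files are read with a
# line-based reader for the header records the triage needs (resolution
# remark, title, keywords, LINK) alongside the coordinate records;
# mmCIF files go through a minimal category reader, since no installed
# package exposes those non-coordinate categories.

#' Default keyword list for the structure scan
#' @return character vector of six keywords.
#' @export
triage_keywords <- function() {
  c("allosteric", "activator", "covalent", "inhibit", "noncompetitive",
    "uncompetitive")
}

#' Default chemical-component exclusion list
#'
#' Water, common ions, buffers and cryoprotectants that never count as
#' qualifying ligands.
#' @return character vector of component ids.
#' @export
default_ligand_exclusions <- function() {
  c("HOH", "DOD", "WAT", "NA", "K", "CL", "MG", "ZN", "MN", "CA", "CD",
    "NI", "CU", "FE", "CO", "BR", "IOD", "SO4", "PO4", "NO3", "ACT",
    "FMT", "GOL", "EDO", "PEG", "PG4", "PGE", "DMS", "TRS", "MES",
    "EPE", "IMD", "BME")
}

.pdb_field <- function(line, from, to) {
  trimws(substr(line, from, min(to, nchar(line))))
}

.element_of <- function(elem_field, atom_name) {
  e <- toupper(elem_field)
  if (nzchar(e)) return(e)
  nm <- gsub("[0-9' ]", "", atom_name)
  toupper(substr(nm, 1, 1))
}

parse_structure_pdb <- function(lines) {
  res <- NA_real_
  rr <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
  if (length(rr) > 0L) {
    m <- regmatches(rr[[1L]], regexpr("[0-9]+\\.[0-9]+", rr[[1L]]))
    if (length(m) > 0L) res <- as.numeric(m)
  }
  title <- paste(vapply(grep("^(TITLE|KEYWDS)", lines, value = TRUE),
                        function(l) .pdb_field(l, 11, 80), ""),
                 collapse = " ")
  year <- NA_integer_
  hd <- grep("^HEADER", lines, value = TRUE)
  if (length(hd) > 0L) {
    yy <- suppressWarnings(as.integer(.pdb_field(hd[[1L]], 58, 59)))
    if (!is.na(yy)) year <- if (yy < 50L) 2000L + yy else 1900L + yy
  }

  atom <- lines[startsWith(lines, "ATOM  ")]
  het <- lines[startsWith(lines, "HETATM")]
  atoms_tab <- function(ls) {
    if (length(ls) == 0L) {
      return(data.frame(comp = character(), chain = character(),
                        seq = character(), elem = character()))
    }
    data.frame(
      comp = vapply(ls, .pdb_field, "", 18, 20),
      chain = vapply(ls, .pdb_field, "", 22, 22),
      seq = vapply(ls, .pdb_field, "", 23, 26),
      elem = mapply(.element_of, vapply(ls, .pdb_field, "", 77, 78),
                    vapply(ls, .pdb_field, "", 13, 16)),
      stringsAsFactors = FALSE)
  }
  at <- atoms_tab(atom)
  ht <- atoms_tab(het)

  conn <- lines[startsWith(lines, "LINK")]
  links <- if (length(conn) == 0L) {
    data.frame(comp1 = character(), seq1 = character(), atom1 = character(),
               comp2 = character(), seq2 = character(), atom2 = character(),
               stringsAsFactors = FALSE)
  } else {
    data.frame(
      comp1 = vapply(conn, .pdb_field, "", 18, 20),
      seq1 = vapply(conn, .pdb_field, "", 23, 26),
      atom1 = vapply(conn, .pdb_field, "", 13, 16),
      comp2 = vapply(conn, .pdb_field, "", 48, 50),
      seq2 = vapply(conn, .pdb_field, "", 53, 56),
      atom2 = vapply(conn, .pdb_field, "", 43, 46),
      stringsAsFactors = FALSE)
  }
  list(resolution_A = res, title_and_keywords = title,
       deposition_year = year, polymer_atoms = at, het_atoms = ht,
       links = links)
}

# --- minimal mmCIF category reader ---------------------------------------

.cif_tokens <- function(line) {
  m <- gregexpr("'[^']*'|\"[^\"]*\"|\\S+", line)[[1L]]
  if (m[[1L]] == -1L) return(character())
  tk <- regmatches(line, gregexpr("'[^']*'|\"[^\"]*\"|\\S+", line))[[1L]]
  gsub("^['\"]|['\"]$", "", tk)
}

# Returns a named list: each element a data.frame (loop) or single-row
# data.frame (key-value items), keyed by category name without "_".
read_cif_categories <- function(lines) {
  lines <- lines[!startsWith(trimws(lines), "#")]
  out <- list()
  i <- 1L
  n <- length(lines)
  put <- function(cat, item, value) {
    if (is.null(out[[cat]])) out[[cat]] <<- list()
    out[[cat]][[item]] <<- value
  }
  read_semicolon <- function(i) {
    val <- character()
    i <- i + 1L
    while (i <= n && !startsWith(lines[[i]], ";")) {
      val <- c(val, lines[[i]])
      i <- i + 1L
    }
    list(value = paste(val, collapse = " "), next_i = i + 1L)
  }
  while (i <= n) {
    line <- trimws(lines[[i]])
    if (identical(line, "loop_")) {
      items <- character()
      i <- i + 1L
      while (i <= n && startsWith(trimws(lines[[i]]), "_")) {
        items <- c(items, trimws(lines[[i]]))
        i <- i + 1L
      }
      vals <- list()
      while (i <= n) {
        l2 <- lines[[i]]
        t2 <- trimws(l2)
        if (!nzchar(t2) || startsWith(t2, "_") || t2 == "loop_" ||
            startsWith(t2, "data_")) break
        if (startsWith(l2, ";")) {
          sv <- read_semicolon(i)
          vals[[length(vals) + 1L]] <- sv$value
          i <- sv$next_i
        } else {
          vals <- c(vals, as.list(.cif_tokens(l2)))
          i <- i + 1L
        }
      }
      if (length(items) > 0L && length(vals) %% length(items) == 0L) {
        mat <- matrix(unlist(vals), ncol = length(items), byrow = TRUE)
        cat_nm <- sub("\\..*$", "", items[[1L]])
        df <- as.data.frame(mat, stringsAsFactors = FALSE)
        names(df) <- sub("^[^.]*\\.", "", items)
        out[[sub("^_", "", cat_nm)]] <- df
      }
    } else if (startsWith(line, "_")) {
      tk <- .cif_tokens(line)
      key <- tk[[1L]]
      cat_nm <- sub("^_", "", sub("\\..*$", "", key))
      item <- sub("^[^.]*\\.", "", key)
      if (length(tk) >= 2L) {
        put(cat_nm, item, paste(tk[-1L], collapse = " "))
        i <- i + 1L
      } else if (i + 1L <= n && startsWith(lines[[i + 1L]], ";")) {
        sv <- read_semicolon(i + 1L)
        put(cat_nm, item, sv$value)
        i <- sv$next_i
      } else {
        put(cat_nm, item, .cif_tokens(lines[[i + 1L]])[[1L]])
        i <- i + 2L
      }
    } else {
      i <- i + 1L
    }
  }
  lapply(out, function(x) {
    if (is.data.frame(x)) x else as.data.frame(x, stringsAsFactors = FALSE)
  })
}

.cif_col <- function(df, ...) {
  for (nm in c(...)) if (nm %in% names(df)) return(df[[nm]])
  rep(NA_character_, nrow(df))
}

parse_structure_cif <- function(lines) {
  cats <- read_cif_categories(lines)
  res <- NA_real_
  if (!is.null(cats$refine)) {
    r <- suppressWarnings(as.numeric(cats$refine$ls_d_res_high[[1L]]))
    if (!is.na(r)) res <- r
  }
  title <- paste(c(if (!is.null(cats$struct)) cats$struct$title,
                   if (!is.null(cats$struct_keywords)) {
                     c(cats$struct_keywords$pdbx_keywords,
                       cats$struct_keywords$text)
                   }), collapse = " ")
  as_tab <- cats$atom_site
  at <- ht <- data.frame(comp = character(), chain = character(),
                         seq = character(), elem = character(),
                         stringsAsFactors = FALSE)
  if (!is.null(as_tab)) {
    tab <- data.frame(
      group = .cif_col(as_tab, "group_PDB"),
      comp = .cif_col(as_tab, "auth_comp_id", "label_comp_id"),
      chain = .cif_col(as_tab, "auth_asym_id", "label_asym_id"),
      seq = .cif_col(as_tab, "auth_seq_id", "label_seq_id"),
      elem = toupper(.cif_col(as_tab, "type_symbol")),
      stringsAsFactors = FALSE)
    at <- tab[tab$group == "ATOM", -1L, drop = FALSE]
    ht <- tab[tab$group == "HETATM", -1L, drop = FALSE]
  }
  links <- data.frame(comp1 = character(), seq1 = character(),
                      atom1 = character(), comp2 = character(),
                      seq2 = character(), atom2 = character(),
                      stringsAsFactors = FALSE)
  sc <- cats$struct_conn
  if (!is.null(sc)) {
    keep <- grepl("covale", .cif_col(sc, "conn_type_id"), ignore.case = TRUE)
    sc <- sc[keep, , drop = FALSE]
    if (nrow(sc) > 0L) {
      links <- data.frame(
        comp1 = .cif_col(sc, "ptnr1_auth_comp_id", "ptnr1_label_comp_id"),
        seq1 = .cif_col(sc, "ptnr1_auth_seq_id", "ptnr1_label_seq_id"),
        atom1 = .cif_col(sc, "ptnr1_label_atom_id"),
        comp2 = .cif_col(sc, "ptnr2_auth_comp_id", "ptnr2_label_comp_id"),
        seq2 = .cif_col(sc, "ptnr2_auth_seq_id", "ptnr2_label_seq_id"),
        atom2 = .cif_col(sc, "ptnr2_label_atom_id"),
        stringsAsFactors = FALSE)
    }
  }
  year <- NA_integer_
  if (!is.null(cats$pdbx_database_status) &&
      !is.null(cats$pdbx_database_status$recvd_initial_deposition_date)) {
    year <- suppressWarnings(as.integer(substr(
      cats$pdbx_database_status$recvd_initial_deposition_date[[1L]], 1, 4)))
  }
  list(resolution_A = res, title_and_keywords = title,
       deposition_year = year, polymer_atoms = at, het_atoms = ht,
       links = links)
}

#' Parse a macromolecular structure file for triage
#'
#' Reads a PDB or mmCIF file and extracts the fields the screening
#' protocol uses: resolution, title and keyword text, deposition year,
#' the ligand inventory (non-polymer chemical components excluding water
#' and the exclusion list, plus short polymer chains recorded as polymer
#' ligand entities with residue counts), and covalent links joining a
#' ligand atom to a polymer residue.
#'
#' @param path file path; dialect chosen by extension (`.cif`/`.mmcif`
#'   vs PDB).
#' @param exclude component ids never counted as ligands.
#' @return list of class `structure_entry` with `pdb_id`,
#'   `resolution_A`, `title_and_keywords`, `deposition_year`, `ligands`
#'   (data.frame: `component_id`, `heavy_atom_count`, `is_polymer`,
#'   `residue_count`), `covalent_links` (data.frame: `ligand_id`,
#'   `residue`, `atoms`).
#' @export
parse_structure <- function(path, exclude = default_ligand_exclusions()) {
  lines <- readLines(path, warn = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("cif", "mmcif")) parse_structure_cif(lines)
         else parse_structure_pdb(lines)

  ht <- raw$het_atoms
  ht <- ht[!(ht$comp %in% exclude), , drop = FALSE]
  lig <- if (nrow(ht) == 0L) {
    data.frame(component_id = character(), heavy_atom_count = integer(),
               is_polymer = logical(), residue_count = integer(),
               stringsAsFactors = FALSE)
  } else {
    key <- paste(ht$comp, ht$chain, ht$seq)
    heavy <- tapply(!(ht$elem %in% c("H", "D")), key, sum)
    comp <- tapply(ht$comp, key, function(x) x[[1L]])
    data.frame(component_id = as.character(comp),
               heavy_atom_count = as.integer(heavy),
               is_polymer = FALSE, residue_count = NA_integer_,
               stringsAsFactors = FALSE)
  }
  at <- raw$polymer_atoms
  if (nrow(at) > 0L) {
    res_per_chain <- tapply(paste(at$comp, at$seq), at$chain,
                            function(x) length(unique(x)))
    if (length(res_per_chain) > 1L) {
      main <- names(res_per_chain)[order(-res_per_chain,
                                         names(res_per_chain))][[1L]]
      for (ch in setdiff(names(res_per_chain), main)) {
        lig <- rbind(lig, data.frame(
          component_id = paste0("chain_", ch), heavy_atom_count = NA_integer_,
          is_polymer = TRUE,
          residue_count = as.integer(res_per_chain[[ch]]),
          stringsAsFactors = FALSE))
      }
    }
  }
  lk <- raw$links
  cov <- if (nrow(lk) == 0L) {
    data.frame(ligand_id = character(), residue = character(),
               atoms = character(), stringsAsFactors = FALSE)
  } else {
    lig_ids <- lig$component_id[!lig$is_polymer]
    rows <- lapply(seq_len(nrow(lk)), function(r) {
      in1 <- lk$comp1[[r]] %in% lig_ids
      in2 <- lk$comp2[[r]] %in% lig_ids
      if (in1 == in2) return(NULL)   # need ligand on exactly one side
      if (in1) {
        data.frame(ligand_id = lk$comp1[[r]],
                   residue = paste0(lk$comp2[[r]], lk$seq2[[r]]),
                   atoms = paste(lk$atom1[[r]], lk$atom2[[r]], sep = "-"),
                   stringsAsFactors = FALSE)
      } else {
        data.frame(ligand_id = lk$comp2[[r]],
                   residue = paste0(lk$comp1[[r]], lk$seq1[[r]]),
                   atoms = paste(lk$atom2[[r]], lk$atom1[[r]], sep = "-"),
                   stringsAsFactors = FALSE)
      }
    })
    out <- do.call(rbind, rows)
    if (is.null(out)) data.frame(ligand_id = character(),
                                 residue = character(), atoms = character(),
                                 stringsAsFactors = FALSE) else out
  }
  structure(list(pdb_id = toupper(sub("\\..*$", "", basename(path))),
                 resolution_A = raw$resolution_A,
                 title_and_keywords = raw$title_and_keywords,
                 deposition_year = raw$deposition_year,
                 ligands = lig, covalent_links = cov),
            class = "structure_entry")
}

#' Apply the structure screening filters
#'
#' An entry passes when its resolution is strictly below the cut-off,
#' it contains at least one qualifying ligand (a non-polymer component
#' with enough heavy atoms, or a polymer shorter than the peptide
#' limit), and its title/keyword text contains at least one keyword
#' (case-insensitive substring match).
#'
#' @param entry a `structure_entry` from [parse_structure()].
#' @param keywords keyword list (default the six-standard scan).
#' @param resolution_max strict resolution cut-off in Angstrom.
#' @param peptide_max_residues polymer ligands with at least this many
#'   residues count as large peptides, not qualifying ligands.
#' @param min_ligand_atoms minimum heavy atoms of a qualifying
#'   small-molecule ligand.
#' @return list with `passes`, `reasons` (failed filters) and
#'   `matched_keywords`.
#' @export
passes_filters <- function(entry, keywords = triage_keywords(),
                           resolution_max = 3.5, peptide_max_residues = 4,
                           min_ligand_atoms = 6) {
  reasons <- character()
  if (is.na(entry$resolution_A) || entry$resolution_A >= resolution_max) {
    reasons <- c(reasons, "resolution")
  }
  lig <- entry$ligands
  qualifying <- (!lig$is_polymer & lig$heavy_atom_count >= min_ligand_atoms) |
    (lig$is_polymer & lig$residue_count < peptide_max_residues)
  if (!any(qualifying)) reasons <- c(reasons, "no_ligand")
  hit <- keywords[vapply(keywords, function(k) {
    grepl(k, entry$title_and_keywords, ignore.case = TRUE)
  }, logical(1))]
  if (length(hit) == 0L) reasons <- c(reasons, "keywords")
  list(passes = length(reasons) == 0L, reasons = reasons,
       matched_keywords = unname(hit))
}

.ligand_types <- c("III", "IV", "V", "VI", "activator", "multi_site")

#' Census of allosteric ligand types against a baseline survey
#'
#' @param counts named integer vector or data.frame (`ligand_type`,
#'   `count`, optionally `baseline_count`) of per-type ligand counts.
#' @param baseline named integer vector of prior-survey counts; taken
#'   from the `baseline_count` column when absent.
#' @return list with `type_counts`, `total`, `baseline_total`,
#'   `new_ligands`, `apki_total`, `apki_baseline`, `new_apkis`, and the
#'   per-type `delta`. APKIs are all types except activators.
#' @export
ligand_census <- function(counts, baseline = NULL) {
  if (is.data.frame(counts)) {
    if (is.null(baseline) && "baseline_count" %in% names(counts)) {
      baseline <- stats::setNames(as.integer(counts$baseline_count),
                                  counts$ligand_type)
    }
    counts <- stats::setNames(as.integer(counts$count), counts$ligand_type)
  }
  types <- names(counts)
  total <- sum(counts)
  apki_types <- setdiff(types, "activator")
  apki_total <- sum(counts[apki_types])
  out <- list(type_counts = counts, total = total, apki_total = apki_total)
  if (!is.null(baseline)) {
    baseline <- baseline[types]
    baseline[is.na(baseline)] <- 0L
    names(baseline) <- types
    out$baseline_total <- sum(baseline)
    out$new_ligands <- total - out$baseline_total
    out$apki_baseline <- sum(baseline[apki_types])
    out$new_apkis <- apki_total - out$apki_baseline
    out$delta <- counts - baseline
  }
  out
}

#' Summarize curated allosteric-ligand records
#'
#' Aggregates per-ligand records (one row per structurally characterized
#' ligand) into the census of [ligand_census()] plus, for covalent
#' (type VI) entries, counts per kinase, per warhead and per modified
#' amino acid, and the numbers of distinct kinases and binding sites.
#'
#' @param records data.frame with columns `pdb_id`, `ligand_type`,
#'   `site`, `kinase`, `modified_residue`, `warhead` (the latter two may
#'   be empty for non-covalent entries).
#' @param baseline optional named vector of prior per-type counts.
#' @return list: the census fields plus `covalent` (list with
#'   `n`, `per_kinase`, `per_warhead`, `per_residue_aa`,
#'   `distinct_kinases`, `distinct_sites`).
#' @export
summarize_ligand_records <- function(records, baseline = NULL) {
  if (nrow(records) == 0L) {
    return(list(type_counts = stats::setNames(integer(0), character(0)),
                total = 0L, apki_total = 0L,
                covalent = list(n = 0L, per_kinase = integer(),
                                per_warhead = integer(),
                                per_residue_aa = integer(),
                                distinct_kinases = 0L,
                                distinct_sites = 0L)))
  }
  counts <- table(records$ligand_type)
  census <- ligand_census(stats::setNames(as.integer(counts),
                                          names(counts)), baseline)
  cov <- records[records$ligand_type == "VI", , drop = FALSE]
  aa <- sub("[0-9]+$", "", cov$modified_residue)
  census$covalent <- list(
    n = nrow(cov),
    per_kinase = if (nrow(cov)) c(table(cov$kinase)) else integer(),
    per_warhead = if (nrow(cov)) c(table(cov$warhead)) else integer(),
    per_residue_aa = if (nrow(cov)) c(table(aa)) else integer(),
    distinct_kinases = length(unique(cov$kinase)),
    distinct_sites = length(unique(cov$site)))
  census
}

#' Read a curated allosteric-ligand record table
#' @param path TSV with the columns of [summarize_ligand_records()].
#' @return data.frame of records.
#' @export
read_ligand_records <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, comment.char = "")
}

#' Read a per-type ligand count table
#' @param path TSV with columns `ligand_type`, `count`,
#'   `baseline_count`.
#' @return data.frame.
#' @export
read_ligand_type_counts <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, comment.char = "")
}
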