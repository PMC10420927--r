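# Writer for the minimal structure fixtures: one tiny PDB (or mmCIF)
# entry per triage filter branch, plus the packaged ligand-census
# tables. The files exercise the standard record layouts the parser
# reads (REMARK 2, TITLE/KEYWDS, ATOM/HETATM columns, LINK,
# struct_conn), at a few dozen atoms each.

.pdb_atom_line <- function(record, serial, name, res, chain, seq, elem,
                           x = 0, y = 0, z = 0) {
  sprintf("%-6s%5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00 20.00          %2s",
          record, serial, name, res, chain, seq, x, y, z, elem)
}

.pdb_protein_chain <- function(chain, n_res, serial0 = 1L, jitter) {
  res3 <- c("ALA", "GLY", "SER", "LEU", "VAL", "THR", "LYS", "GLU")
  lines <- character()
  s <- serial0
  for (r in seq_len(n_res)) {
    for (nm in c("N", "CA", "C", "O")) {
      lines <- c(lines, .pdb_atom_line(
        "ATOM", s, nm, res3[[(r - 1L) %% length(res3) + 1L]], chain, r,
        substr(nm, 1, 1),
        x = r * 3.8 + jitter[[1L]], y = jitter[[2L]], z = 0))
      s <- s + 1L
    }
  }
  list(lines = lines, next_serial = s)
}

.pdb_ligand <- function(comp, chain, seq, n_heavy, serial0, jitter) {
  lines <- character()
  s <- serial0
  for (k in seq_len(n_heavy)) {
    elem <- if (k %% 7L == 0L) "N" else if (k %% 5L == 0L) "O" else "C"
    lines <- c(lines, .pdb_atom_line(
      "HETATM", s, paste0(elem, k), comp, chain, seq, elem,
      x = 20 + k * 1.4 + jitter[[1L]], y = 5 + jitter[[2L]], z = 2))
    s <- s + 1L
  }
  list(lines = lines, next_serial = s)
}

.write_fixture_pdb <- function(path, pdb_id, resolution, title,
                               with_ligand = TRUE, peptide_chain = FALSE,
                               covalent_link = FALSE, jitter = c(0, 0)) {
  lines <- c(
    sprintf("HEADER    TRANSFERASE                             01-MAR-22   %s", pdb_id),
    sprintf("TITLE     %s", toupper(title)),
    "KEYWDS    TRANSFERASE, KINASE",
    sprintf("REMARK   2 RESOLUTION.    %4.2f ANGSTROMS.", resolution))
  pc <- .pdb_protein_chain("A", 12L, 1L, jitter)
  lines <- c(lines, pc$lines)
  s <- pc$next_serial
  if (peptide_chain) {
    pep <- .pdb_protein_chain("B", 8L, s, jitter)
    lines <- c(lines, pep$lines)
    s <- pep$next_serial
  }
  if (with_ligand) {
    lg <- .pdb_ligand("LIG", "A", 201L, 14L, s, jitter)
    lines <- c(lines, lg$lines)
    s <- lg$next_serial
  }
  # a water and a sulfate so the exclusion list is exercised
  lines <- c(lines,
             .pdb_atom_line("HETATM", s, "O", "HOH", "A", 301L, "O"),
             .pdb_atom_line("HETATM", s + 1L, "S", "SO4", "A", 302L, "S"))
  if (covalent_link) {
    lines <- c(lines, sprintf(
      "LINK         C1  LIG A 201                 SG  CYS A  45     1555   1555  1.80"))
  }
  lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(path)
}

.write_fixture_cif <- function(path, pdb_id, resolution, title) {
  lines <- c(
    sprintf("data_%s", pdb_id),
    sprintf("_struct.title '%s'", title),
    "_struct_keywords.pdbx_keywords 'TRANSFERASE/INHIBITOR'",
    sprintf("_refine.ls_d_res_high %.2f", resolution),
    "_pdbx_database_status.recvd_initial_deposition_date 2022-03-01",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.type_symbol",
    "_atom_site.label_comp_id",
    "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_seq_id",
    vapply(1:10, function(r) {
      sprintf("ATOM C ALA ALA A %d", r)
    }, ""),
    vapply(1:12, function(k) {
      sprintf("HETATM %s LIG LIG A 201",
              if (k %% 5L == 0L) "O" else "C")
    }, ""),
    "HETATM O HOH HOH A 301",
    "loop_",
    "_struct_conn.id",
    "_struct_conn.conn_type_id",
    "_struct_conn.ptnr1_auth_comp_id",
    "_struct_conn.ptnr1_auth_seq_id",
    "_struct_conn.ptnr1_label_atom_id",
    "_struct_conn.ptnr2_auth_comp_id",
    "_struct_conn.ptnr2_auth_seq_id",
    "_struct_conn.ptnr2_label_atom_id",
    "covale1 covale LIG 201 C1 CYS 45 SG")
  writeLines(lines, path)
  invisible(path)
}

#' Write the structure-triage fixture set
#'
#' Emits one tiny structure file per filter branch — a qualifying entry,
#' a 3.6 Angstrom entry, a ligand-free entry, a peptide-only entry, an
#' entry without scan keywords, a qualifying entry with a covalent
#' ligand-cysteine link (PDB format), and a qualifying mmCIF entry —
#' plus the packaged allosteric-ligand census tables. All files are
#' synthetic; the expected triage outcome of each is returned.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed; perturbs coordinates only, so the triage
#'   outcome is seed-independent and files are byte-identical per seed.
#' @return data.frame with `file`, `expected_pass`, `expected_reason`.
#' @export
generate_structure_fixtures <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jitter <- with_seed(seed, round(stats::runif(2, -0.2, 0.2), 3))
  specs <- list(
    list(file = "entry_pass.pdb", res = 1.9,
         title = "Structure of a kinase with a noncompetitive inhibitor",
         ligand = TRUE, peptide = FALSE, link = FALSE,
         pass = TRUE, reason = ""),
    list(file = "entry_lowres.pdb", res = 3.6,
         title = "Allosteric inhibitor complex",
         ligand = TRUE, peptide = FALSE, link = FALSE,
         pass = FALSE, reason = "resolution"),
    list(file = "entry_noligand.pdb", res = 2.1,
         title = "Covalent modification of a kinase",
         ligand = FALSE, peptide = FALSE, link = FALSE,
         pass = FALSE, reason = "no_ligand"),
    list(file = "entry_peptide.pdb", res = 2.0,
         title = "Kinase bound to an inhibitory peptide",
         ligand = FALSE, peptide = TRUE, link = FALSE,
         pass = FALSE, reason = "no_ligand"),
    list(file = "entry_nokeyword.pdb", res = 2.0,
         title = "Crystal structure of a transferase domain",
         ligand = TRUE, peptide = FALSE, link = FALSE,
         pass = FALSE, reason = "keywords"),
    list(file = "entry_covalent.pdb", res = 1.8,
         title = "Covalent allosteric inhibitor complex",
         ligand = TRUE, peptide = FALSE, link = TRUE,
         pass = TRUE, reason = ""))
  for (sp in specs) {
    .write_fixture_pdb(file.path(dir, sp$file),
                       toupper(substr(sub("entry_", "", sp$file), 1, 4)),
                       sp$res, sp$title, with_ligand = sp$ligand,
                       peptide_chain = sp$peptide,
                       covalent_link = sp$link, jitter = jitter)
  }
  .write_fixture_cif(file.path(dir, "entry_pass_cif.cif"), "9CIF", 2.2,
                     "Allosteric activator bound to a kinase domain")
  specs <- c(specs, list(list(file = "entry_pass_cif.cif", pass = TRUE,
                              reason = "")))
  for (f in c("allosteric_ligand_type_counts.tsv",
              "covalent_allosteric_ligands.tsv")) {
    src <- system.file("extdata", f, package = "covkin")
    if (nzchar(src)) file.copy(src, file.path(dir, f), overwrite = TRUE)
  }
  data.frame(file = vapply(specs, `[[`, "", "file"),
             expected_pass = vapply(specs, `[[`, TRUE, "pass"),
             expected_reason = vapply(specs, `[[`, "", "reason"),
             stringsAsFactors = FALSE)
}
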