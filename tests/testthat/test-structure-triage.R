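fixture_dir <- local({
  d <- file.path(tempdir(), "covkin-structures")
  generate_structure_fixtures(d, seed = 1)
  d
})

test_that("fixture structures are accepted or rejected exactly by design", {
  design <- generate_structure_fixtures(fixture_dir, seed = 1)
  for (i in seq_len(nrow(design))) {
    e <- parse_structure(file.path(fixture_dir, design$file[[i]]))
    pf <- passes_filters(e)
    expect_identical(pf$passes, design$expected_pass[[i]],
                     label = design$file[[i]])
    if (nzchar(design$expected_reason[[i]])) {
      expect_true(design$expected_reason[[i]] %in% pf$reasons,
                  label = design$file[[i]])
    }
  }
})

test_that("parsing excludes water/buffers and records covalent links", {
  e <- parse_structure(file.path(fixture_dir, "entry_pass.pdb"))
  expect_false(any(c("HOH", "SO4") %in% e$ligands$component_id))
  expect_identical(e$ligands$component_id, "LIG")
  expect_gte(e$ligands$heavy_atom_count, 10L)

  cov <- parse_structure(file.path(fixture_dir, "entry_covalent.pdb"))
  expect_identical(nrow(cov$covalent_links), 1L)
  expect_identical(cov$covalent_links$ligand_id, "LIG")
  expect_match(cov$covalent_links$residue, "^CYS")

  pep <- parse_structure(file.path(fixture_dir, "entry_peptide.pdb"))
  expect_true(any(pep$ligands$is_polymer))
  expect_gte(pep$ligands$residue_count[pep$ligands$is_polymer], 4L)
})

test_that("the mmCIF reader yields the same triage fields", {
  e <- parse_structure(file.path(fixture_dir, "entry_pass_cif.cif"))
  expect_equal(e$resolution_A, 2.2)
  expect_match(e$title_and_keywords, "activator", ignore.case = TRUE)
  expect_identical(e$ligands$component_id[!e$ligands$is_polymer], "LIG")
  expect_identical(nrow(e$covalent_links), 1L)
  expect_identical(e$deposition_year, 2022L)
})

test_that("keyword scan is case-insensitive and order-independent", {
  e <- parse_structure(file.path(fixture_dir, "entry_pass.pdb"))
  up <- passes_filters(e, keywords = toupper(triage_keywords()))
  expect_true(up$passes)
  shuffled <- passes_filters(e, keywords = rev(triage_keywords()))
  expect_setequal(tolower(shuffled$matched_keywords),
                  tolower(up$matched_keywords))
})

test_that("filter decisions agree with a brute-force recheck", {
  files <- list.files(fixture_dir, "\\.(pdb|cif)$", full.names = TRUE)
  for (f in files) {
    e <- parse_structure(f)
    pf <- passes_filters(e)
    lig_ok <- any(
      (!e$ligands$is_polymer & e$ligands$heavy_atom_count >= 6) |
        (e$ligands$is_polymer & e$ligands$residue_count < 4))
    manual <- !is.na(e$resolution_A) && e$resolution_A < 3.5 &&
      lig_ok &&
      any(vapply(triage_keywords(), grepl, TRUE,
                 x = tolower(e$title_and_keywords)))
    expect_identical(pf$passes, manual, label = basename(f))
  }
})

test_that("the ligand census reproduces the survey arithmetic", {
  counts <- read_ligand_type_counts(
    system.file("extdata", "allosteric_ligand_type_counts.tsv",
                package = "covkin"))
  cen <- ligand_census(counts)
  expect_identical(cen$total, sum(counts$count))
  expect_identical(cen$new_ligands, cen$total - cen$baseline_total)
  expect_identical(cen$new_apkis, cen$apki_total - cen$apki_baseline)
  expect_identical(cen$apki_total,
                   cen$total - cen$type_counts[["activator"]])
  expect_identical(sum(cen$delta), cen$new_ligands)
})

test_that("covalent-record aggregation and the empty summary behave", {
  rec <- read_ligand_records(
    system.file("extdata", "covalent_allosteric_ligands.tsv",
                package = "covkin"))
  s <- summarize_ligand_records(rec)
  expect_identical(s$covalent$n, nrow(rec))
  expect_identical(sum(s$covalent$per_kinase), nrow(rec))
  expect_identical(sum(s$covalent$per_warhead), nrow(rec))
  expect_identical(names(s$covalent$per_residue_aa), "Cys")
  empty <- summarize_ligand_records(rec[0, ])
  expect_identical(empty$total, 0L)
  expect_identical(empty$covalent$n, 0L)
})
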