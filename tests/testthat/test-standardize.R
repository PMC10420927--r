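test_that("salt stripping keeps the largest organic fragment", {
  r <- standardize_smiles(c("CC(=O)O.[Na+].[Cl-]", "CC(=O)O"))
  expect_true(all(r$valid))
  expect_identical(r$standard_smiles[[1L]], r$standard_smiles[[2L]])
  # the organic fragment wins even when an inorganic one is larger
  mix <- standardize_smiles("CCO.[Na+].[Na+].[Na+].[Na+]")
  expect_identical(mix$standard_smiles,
                   standardize_smiles("CCO")$standard_smiles)
})

test_that("stereoisomers and isotopologues collapse to one form", {
  r <- standardize_smiles(c("C[C@H](N)C(=O)O", "C[C@@H](N)C(=O)O",
                            "CC(N)C(=O)O", "C[13CH](N)C(=O)O",
                            "C/C=C/C(=O)O", "C/C=C\\C(=O)O"))
  expect_true(all(r$valid))
  expect_length(unique(r$standard_smiles[1:4]), 1L)
  expect_identical(r$standard_smiles[[5L]], r$standard_smiles[[6L]])
  expect_false(any(grepl("[@/\\\\]", r$standard_smiles)))
})

test_that("charges are neutralized where a neutral form exists", {
  r <- standardize_smiles(c("CC(=O)[O-]", "CC[NH3+]", "C[N+](C)(C)C"))
  expect_identical(r$standard_smiles[[1L]],
                   standardize_smiles("CC(=O)O")$standard_smiles)
  expect_identical(r$standard_smiles[[2L]],
                   standardize_smiles("CCN")$standard_smiles)
  # quaternary nitrogen has no neutral protonation state
  expect_match(r$standard_smiles[[3L]], "N+", fixed = TRUE)
})

test_that("invalid and inorganic inputs are rejected with reasons", {
  r <- standardize_smiles(c("not_a_smiles", "", "[Na+].[Cl-]", "CCO"))
  expect_identical(r$valid, c(FALSE, FALSE, FALSE, TRUE))
  expect_identical(r$rejection_reason,
                   c("parse_error", "parse_error", "inorganic", ""))
  # valid = FALSE if and only if a reason is present
  expect_identical(r$valid, !nzchar(r$rejection_reason))
})

test_that("standardization is idempotent on a generated library", {
  smi <- unique(random_library(1000, seed = 42))
  r1 <- standardize_smiles(smi)
  expect_true(all(r1$valid))
  r2 <- standardize_smiles(r1$standard_smiles)
  expect_identical(r2$standard_smiles, r1$standard_smiles)
})

test_that("standardization is invariant to atom-order permutation", {
  smi <- unique(random_library(60, seed = 7))
  std <- standardize_smiles(smi)$standard_smiles
  permuted <- vapply(seq_along(smi), function(i) {
    mg <- covkin:::mol_graph(smi[[i]])
    perm <- covkin:::with_seed(100 + i, sample(mg$n))
    inv <- match(seq_len(mg$n), perm)
    mg2 <- list(elem = mg$elem[perm], charge = mg$charge[perm],
                bonds = data.frame(a1 = inv[mg$bonds$a1],
                                   a2 = inv[mg$bonds$a2],
                                   order = mg$bonds$order),
                n = mg$n)
    # non-canonical SMILES written from the permuted atom order
    out <- ChemmineOB::convertFormat(
      "SDF", "SMI", covkin:::write_molfile(mg2, "p"))
    sub("\t.*", "", strsplit(out, "\n")[[1L]][[1L]])
  }, "")
  expect_identical(standardize_smiles(permuted)$standard_smiles, std)
})

test_that("batch file mode round-trips with ids", {
  f <- tempfile(fileext = ".smi")
  writeLines(c("CC(=O)[O-]\tc1", "bad\tc2"), f)
  out <- tempfile(fileext = ".tsv")
  tab <- standardize_file(f, out)
  expect_true(file.exists(out))
  back <- read.delim(out, stringsAsFactors = FALSE)
  expect_identical(back$id, c("c1", "c2"))
  expect_identical(back$valid, c(TRUE, FALSE))
})
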