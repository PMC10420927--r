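test_that("the default library has 14 validated patterns", {
  lib <- load_warhead_library()
  expect_identical(nrow(lib), 14L)
  expect_false(anyDuplicated(lib$name) > 0)
  expect_setequal(c(analyzed_warheads(), prior_warheads()), lib$name)
  expect_length(analyzed_warheads(), 12L)
})

test_that("config overrides and extends the library, bad SMARTS fail", {
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(aldehyde = list(smarts = "[CX3H1]=O",
                                        specificity_rank = 2L)), f)
  lib <- load_warhead_library(f)
  expect_identical(nrow(lib), 14L)
  expect_identical(lib$smarts[lib$name == "aldehyde"], "[CX3H1]=O")

  f2 <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(extra_warhead = list(smarts = "C(=S)Cl",
                                             specificity_rank = 1L)), f2)
  expect_identical(nrow(load_warhead_library(f2)), 15L)

  f3 <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(aldehyde = list(smarts = "[[broken")), f3)
  expect_error(load_warhead_library(f3), "aldehyde")
})

test_that("every pattern hits its positives and rejects its near-misses", {
  lib <- load_warhead_library()
  gold <- warhead_golden_set()
  for (w in names(gold)) {
    for (s in gold[[w]]$pos) {
      m <- strsplit(detect_warheads(s, lib)$matched, ";")[[1L]]
      expect_true(w %in% m, label = sprintf("%s should match %s", s, w))
    }
    for (s in gold[[w]]$neg) {
      m <- strsplit(detect_warheads(s, lib)$matched, ";")[[1L]]
      expect_false(w %in% m, label = sprintf("%s should not match %s", s, w))
    }
  }
})

test_that("nested embeddings are suppressed by the more specific pattern", {
  r <- detect_warheads("N#CC(=CC)C(N)=O")
  expect_identical(r$matched, "cyanoacrylamide")
  # an independent second acrylamide survives the suppression
  r2 <- detect_warheads("N#CC(=CC)C(=O)NCCNC(=O)C=C")
  m2 <- strsplit(r2$matched, ";")[[1L]]
  expect_true(all(c("cyanoacrylamide", "acrylamide") %in% m2))
  # terminal alkyne inside an alkynyl benzoate
  r3 <- detect_warheads("C#Cc1ccccc1C(=O)OC")
  expect_identical(r3$matched, "alkynyl_benzoate")
})

test_that("covalent/excluded/non-covalent classes follow the match sets", {
  r <- detect_warheads(c("C=CS(=O)(=O)c1ccccc1",  # vinyl sulfone
                         "C=CC(N)=O",             # prior acrylamide only
                         "O=C(N)Nc1ccccn1",       # prior urea only
                         "C=CC(=O)NCCS(=O)(=O)C=C",  # prior + analyzed
                         "CCO"))
  expect_identical(r$is_cpki, c(TRUE, FALSE, FALSE, TRUE, FALSE))
  expect_identical(r$excluded_prior, c(FALSE, TRUE, TRUE, FALSE, FALSE))
  expect_error(detect_warheads("not(a(smiles"), "parse_error")
})

test_that("partitioning conserves compounds across the three classes", {
  lib <- load_warhead_library()
  gold <- warhead_golden_set()
  one_each <- vapply(gold[analyzed_warheads()[1:7]],
                     function(g) g$pos[[1L]], "")
  cleans <- c("CCO", "c1ccccc1", "CCNCC")
  asg <- detect_warheads(unname(c(one_each, cleans)), lib)
  part <- partition_by_warhead(asg)
  expect_identical(length(part$non_covalent), 3L)
  expect_true(all(vapply(part$subsets, length, 1L) == 1L))
  covered <- length(unique(unlist(part$subsets))) +
    length(part$non_covalent) + length(part$excluded_prior)
  expect_identical(covered, nrow(asg))
  expect_identical(length(partition_by_warhead(
    detect_warheads(character()))$non_covalent), 0L)
})

test_that("detection is independent of input order and atom numbering", {
  smi <- c("C=CS(=O)(=O)c1ccccc1", "O=Cc1ccc(F)cc1", "CCO")
  fwd <- detect_warheads(smi)
  rev_ <- detect_warheads(rev(smi))
  expect_identical(fwd$matched, rev(rev_$matched))
  # a different SMILES writing of the same molecule matches identically
  alt <- standardize_smiles("c1ccccc1S(=O)(=O)C=C")$standard_smiles
  expect_identical(detect_warheads(alt)$matched, fwd$matched[[1L]])
})
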