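test_that("single-substituent ring compounds yield one decomposition", {
  d <- fragment_compound("Cc1ccccc1", max_cuts = 1)
  expect_identical(nrow(d), 1L)
  expect_identical(d$substituents, "*C")
  expect_identical(d$core_heavy, 6L)
  expect_identical(nrow(fragment_compound("c1ccccc1")), 0L)  # nothing to cut
  expect_identical(nrow(fragment_compound("CCCCCC")), 0L)    # no ring core
})

test_that("a disubstituted scaffold enumerates all cut subsets", {
  # two cuttable bonds: each alone plus both together = choose(2,1) +
  # choose(2,2) = 3 decompositions
  d <- fragment_compound("Clc1ccccc1Br", max_cuts = 2)
  expect_identical(nrow(d), 3L)
  expect_identical(sum(d$n_cuts == 1L), 2L)
  expect_identical(sum(d$n_cuts == 2L), 1L)
  both <- d[d$n_cuts == 2L, ]
  expect_setequal(strsplit(both$substituents, ";")[[1L]], c("*Cl", "*Br"))
})

test_that("cores reassemble their members exactly", {
  smi <- standardize_smiles(c("CCOc1ccc(CNC(C)=O)cc1",
                              "Cc1ccc2ncnc(NCC(F)(F)F)c2c1"))$standard_smiles
  for (s in smi) {
    d <- fragment_compound(s, max_cuts = 3)
    expect_gt(nrow(d), 0L)
    for (i in seq_len(nrow(d))) {
      rebuilt <- reassemble_compound(
        d$core[[i]], strsplit(d$substituents[[i]], ";")[[1L]])
      expect_identical(rebuilt, s,
                       label = sprintf("decomp %d of %s", i, s))
    }
  }
})

test_that("planted analogue series are recovered exactly", {
  # two scaffolds, three analogues each
  lib <- generate_library(generator_config(n_cores = 2,
                                           substituents_per_core = 3,
                                           warhead_fraction = 0, seed = 2))
  std <- standardize_smiles(lib$smiles)$standard_smiles
  ser <- build_series(std, max_cuts = 2)
  expect_identical(length(unique(ser$series_id)), 2L)
  expect_true(all(table(ser$series_id) == 3L))
  # all-distinct scaffolds form no series
  singles <- standardize_smiles(c("Cc1ccccc1", "CCc1ccncc1",
                                  "COc1ccc2[nH]ccc2c1"))$standard_smiles
  expect_identical(nrow(build_series(singles)), 0L)
})

test_that("pair extraction applies the fold threshold with signed delta", {
  series <- data.frame(series_id = "S001", core = "*c1ccccc1",
                       standard_smiles = c("A", "B", "C"),
                       substituents = "*", stringsAsFactors = FALSE)
  curated <- data.frame(standard_smiles = c("A", "B", "C"),
                        target_id = "KIN001",
                        pPotency = c(8.5, 6.0, 7.0),
                        stringsAsFactors = FALSE)
  asg <- data.frame(standard_smiles = c("A", "B", "C"),
                    matched = c("vinyl_sulfone", "", ""),
                    is_cpki = c(TRUE, FALSE, FALSE),
                    excluded_prior = FALSE, stringsAsFactors = FALSE)
  pr <- extract_pairs(series, curated, asg, min_fold = 100)
  expect_identical(nrow(pr), 1L)      # A-B qualifies, A-C misses (1.5 < 2)
  expect_identical(pr$pki_smiles, "B")
  expect_equal(pr$delta_p, 2.5)
  expect_identical(pr$warhead, "vinyl_sulfone")
  # the threshold is two log units at the default 100-fold
  expect_identical(nrow(extract_pairs(series, curated, asg)), 1L)
  # sign is kept when the covalent analogue is the weaker one
  curated$pPotency <- c(4.0, 6.5, 7.0)
  pr2 <- extract_pairs(series, curated, asg, min_fold = 100)
  expect_equal(sort(pr2$delta_p), c(-3.0, -2.5))
})

test_that("extract_pairs equals the brute-force pair oracle", {
  cfg <- generator_config(n_cores = 4, substituents_per_core = 6,
                          warhead_fraction = 0.3, seed = 21)
  lib <- generate_library(cfg)
  std <- standardize_smiles(lib$smiles)$standard_smiles
  expect_lte(length(std), 50L)
  cur <- curate(generate_activities(lib, cfg))$curated
  asg <- detect_warheads(unique(std))
  ser <- build_series(unique(std), max_cuts = 2)
  mine <- extract_pairs(ser, cur, asg, min_fold = 100)
  mine_keys <- sort(paste(mine$cpki_smiles, mine$pki_smiles,
                          mine$target_id, mine$warhead,
                          round(mine$delta_p, 9)))
  expect_identical(mine_keys, brute_pairs(ser, cur, asg, min_fold = 100))
})
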