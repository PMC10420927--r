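test_that("pPotency conversion matches the log definition", {
  expect_equal(to_ppotency(10000), 5.0)
  expect_equal(to_ppotency(1), 9.0)
  expect_equal(to_ppotency(100), 7.0)
  expect_error(to_ppotency(0), "nonpositive_potency")
  expect_error(to_ppotency(-5), "nonpositive_potency")
})

test_that("per-record filters reject with the first failing reason", {
  recs <- record_batch(
    clean_record(),
    clean_record(relation = ">"),
    clean_record(value_nM = 20000),
    clean_record(assay_confidence = 8L),
    clean_record(relationship_type = "B"),
    clean_record(measurement_type = "EC50"),
    clean_record(assay_kinase_count = 2L),
    clean_record(activity_comment = "Potential transcription error"),
    clean_record(units = "uM"),
    clean_record(compound_smiles = ""))
  f <- filter_records(recs)
  expect_identical(f$reject_reason,
                   c("", "relation", "potency_cutoff", "assay_confidence",
                     "relationship_type", "measurement_type",
                     "assay_kinase_count", "activity_comment", "units",
                     "malformed_record"))
  # bindingdb records have no confidence/relationship fields to fail
  bdb <- filter_records(clean_record(source = "bindingdb"))
  expect_true(bdb$keep)
})

test_that("replicates aggregate on the log scale with Ki/Kd priority", {
  # two IC50 records at 100 and 1000 nM: hand arithmetic on {7.0, 6.0}
  a <- aggregate_measurements(to_ppotency(c(100, 1000)), c("IC50", "IC50"))
  expect_equal(a$pPotency, 6.5)
  expect_equal(a$sd_log, sd(c(7, 6)))
  expect_true(a$retained)
  expect_identical(a$measurement_class, "IC50")
  # a Ki beats an IC50
  b <- aggregate_measurements(to_ppotency(c(50, 10)), c("Ki", "IC50"))
  expect_identical(b$measurement_class, "KiKd")
  expect_equal(b$pPotency, to_ppotency(50))
  expect_equal(b$n_measurements, 1L)
  # dispersion above one log unit drops the pair: sample sd of {8, 5}
  d <- aggregate_measurements(to_ppotency(c(10, 10000)), c("IC50", "IC50"))
  expect_false(d$retained)
  expect_identical(d$drop_reason, "sd_dispersion")
  expect_equal(d$sd_log, sd(c(8, 5)))
  expect_error(aggregate_measurements(numeric(), character()),
               "no_records")
})

test_that("duplicate rows merge into one pair and zero dispersion", {
  r <- clean_record()
  out <- curate(record_batch(r, r))
  expect_identical(nrow(out$curated), 1L)
  expect_identical(out$curated$n_measurements, 2L)
  expect_equal(out$curated$sd_log, 0)
  # aggregate of {v, v} equals aggregate of {v}
  one <- curate(r)
  expect_equal(out$curated$pPotency, one$curated$pPotency)
})

test_that("curation is empty-safe and conserves records", {
  empty <- curate(data.frame())
  expect_identical(nrow(empty$curated), 0L)
  expect_identical(empty$report$input, 0L)

  cfg <- generator_config(n_cores = 3, substituents_per_core = 5,
                          warhead_fraction = 0.2, seed = 5,
                          violation_rates = c(relation = 0.05,
                                              potency_cutoff = 0.05,
                                              activity_comment = 0.03))
  rec <- generate_activities(generate_library(cfg), cfg)
  out <- curate(rec)
  expect_identical(out$report$kept_records + sum(out$report$rejected),
                   out$report$input)
})

test_that("curate matches an independent brute-force cascade", {
  cfg <- generator_config(n_cores = 3, substituents_per_core = 5,
                          warhead_fraction = 0.2, seed = 13,
                          violation_rates = c(relation = 0.04,
                                              potency_cutoff = 0.04,
                                              assay_confidence = 0.04,
                                              assay_kinase_count = 0.04))
  rec <- generate_activities(generate_library(cfg), cfg)
  rec <- rec[seq_len(min(nrow(rec), 200L)), ]
  mine <- curate(rec)
  oracle <- brute_curate(rec)
  flt <- filter_records(rec)
  expect_identical(flt$reject_reason, oracle$reasons)
  a <- mine$curated[order(mine$curated$standard_smiles,
                          mine$curated$target_id), ]
  b <- oracle$curated[order(oracle$curated$standard_smiles,
                            oracle$curated$target_id), ]
  expect_identical(nrow(a), nrow(b))
  expect_equal(a$pPotency, b$pPotency)
  expect_identical(a$target_id, b$target_id)
})

test_that("contradictory active/inactive annotations are rejected", {
  r1 <- clean_record(activity_flag = "inactive")        # but 100 nM
  r2 <- clean_record(activity_comment = "active; marked inactive in source")
  f <- filter_records(record_batch(r1, r2))
  expect_identical(f$reject_reason,
                   c("activity_comment", "activity_comment"))
  off <- filter_records(r1, curation_config(check_flag_contradiction = FALSE))
  expect_true(off$keep)
})
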