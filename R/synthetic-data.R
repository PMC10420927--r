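# Deterministic synthetic-data generator. It emulates the statistical
# structure the analysis assumes in curated kinase bioactivity archives:
# analogue series enumerated from drug-like scaffold cores, a subset of
# members carrying electrophilic warheads with a planted potency gain of
# about two log units, log-normal measurement noise across replicates, a
# dominant fraction (72.5%) of single-kinase annotations, and optional
# records engineered to violate each curation filter.

# Kinase-inhibitor-like scaffold templates. {R} marks the single varied
# substitution site; everything else is fixed per series, which makes
# the shared core of a series its largest shared fragment under the
# compound-core decomposition.
.core_templates <- c(
  "O=C(Nc1ccc2ncnc(Nc3ccccc3)c2c1)c1cccc2c1cccc2Oc1ccc({R})cc1",
  "COc1cc2ncnc(Nc3ccc(NC(=O)c4ccccc4-c4ccncc4)cc3)c2cc1Oc1ccc({R})cc1",
  "CN1CCN(c2ccc(Nc3ncc4cc(-c5ccccc5C(=O)Nc5ccc({R})cc5)ccc4n3)cc2)CC1",
  "O=C(Nc1cccc(-c2nc3ccccc3o2)c1)c1ccc2[nH]ncc2c1-c1ccc({R})cc1",
  "Cn1cc(-c2ccc3ncnc(Nc4ccc(OCc5cccnc5)c(C(=O)Nc5ccc({R})cc5)c4)c3c2)cn1",
  "O=S(=O)(Nc1ccccn1)c1ccc(Nc2nccc(-c3cnc4ccccc4c3)n2)c({R})c1",
  "CC1(C)CCC(n2c(=O)cnc3cnc(Nc4ccc(C(=O)N5CCOCC5)cc4{R})nc32)CC1",
  "O=c1[nH]c2cc(-c3ccccc3)ccc2n1Cc1ccc(C(=O)Nc2cccnc2)c({R})c1",
  "COc1ccc(-c2cc3c(NCc4ccc(S(C)(=O)=O)cc4)ncnc3cn2)cc1Nc1ccc({R})cc1",
  "O=C(NC1CCN(Cc2ccccc2)CC1)c1cc2cnc(Nc3ccc(N4CCOCC4)cc3)nc2n1Cc1ccc({R})cc1",
  "CC(C)Oc1cc(-n2cnc3cc(-c4ccc(CN5CCS(=O)(=O)CC5)cc4)ccc32)ccc1Nc1ccc({R})cc1",
  "O=C(Nc1ccc(F)c(-c2nnc3ccccn23)c1)c1cccc(OCc2ccccc2)c1Nc1ccc({R})cc1"
)

# Plain substituents for the varied site. First attachment atoms are
# chosen so that no two substituents (or warhead moieties) share an
# attachment prefix; otherwise the largest-shared-core rule would pull
# prefix-sharing analogues into a deeper, unintended series.
.plain_substituents <- c("C", "CC", "N", "O", "F", "Cl", "Br", "S")

# Warhead moieties in attachment form (first atom bonds to the varied
# ring position).
.warhead_moieties <- c(
  aldehyde = "C=O",
  terminal_alkyne = "C#C",
  acrylate = "OC(=O)C=C",
  cyanamide = "N(C)C#N",
  cyanoacrylamide = "NC(=O)C(C#N)=C",
  vinyl_sulfone = "S(=O)(=O)C=C",
  reactive_ester = "C(=O)Oc1ccc(cc1)[N+](=O)[O-]",
  alpha_haloketone = "C(=O)CCl",
  boronic_acid = "B(O)O",
  sulfonyl_fluoride = "S(=O)(=O)F",
  epoxide = "C1OC1"
)

#' Synthetic-data generator configuration
#'
#' Defaults encode the study conditions the pipeline is meant to
#' recover: a planted covalent potency gain of 2.0 log units, log-unit
#' replicate noise of 0.3, and a 72.5% single-kinase annotation
#' fraction.
#'
#' @param n_cores number of scaffold cores / planted series (max 8).
#' @param substituents_per_core analogues enumerated per core (max 8).
#' @param warhead_fraction fraction of each series' members converted to
#'   warhead-bearing analogues.
#' @param warhead_names warheads to plant; defaults to the seven
#'   analyzed subsets.
#' @param planted_shift_log potency gain (log units) of warhead-bearing
#'   analogues.
#' @param noise_sd_log log-unit SD of replicate measurement noise.
#' @param single_target_fraction probability that a compound is
#'   annotated with a single kinase.
#' @param pd_tail list with `values` and `probs`: promiscuity degrees
#'   (and weights) for multi-kinase compounds.
#' @param n_replicates_range inclusive integer range of replicate
#'   measurements per compound-kinase pair.
#' @param n_targets size of the kinase target pool.
#' @param violation_rates named numeric vector: per-record probability of
#'   corruption violating the named curation filter.
#' @param seed integer seed; the generator is fully deterministic.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_cores = 5,
                             substituents_per_core = 8,
                             warhead_fraction = 0.25,
                             warhead_names = c("aldehyde", "terminal_alkyne",
                                               "acrylate", "cyanamide",
                                               "cyanoacrylamide",
                                               "vinyl_sulfone",
                                               "reactive_ester"),
                             planted_shift_log = 2.0,
                             noise_sd_log = 0.3,
                             single_target_fraction = 0.725,
                             pd_tail = list(values = 2:12,
                                            probs = 0.55^(0:10)),
                             n_replicates_range = c(1L, 3L),
                             n_targets = 30,
                             violation_rates = numeric(),
                             seed = 1L) {
  stopifnot(n_cores >= 1, n_cores <= length(.core_templates),
            substituents_per_core >= 2,
            substituents_per_core <= length(.plain_substituents),
            warhead_fraction >= 0, warhead_fraction <= 1,
            planted_shift_log >= 0, noise_sd_log >= 0,
            single_target_fraction >= 0, single_target_fraction <= 1,
            all(warhead_names %in% names(.warhead_moieties)))
  structure(list(n_cores = n_cores,
                 substituents_per_core = substituents_per_core,
                 warhead_fraction = warhead_fraction,
                 warhead_names = warhead_names,
                 planted_shift_log = planted_shift_log,
                 noise_sd_log = noise_sd_log,
                 single_target_fraction = single_target_fraction,
                 pd_tail = pd_tail,
                 n_replicates_range = as.integer(n_replicates_range),
                 n_targets = as.integer(n_targets),
                 violation_rates = violation_rates,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Generate a labeled compound library
#'
#' Enumerates analogues from `n_cores` scaffold cores by attaching each
#' plain substituent at the varied site, then converts a deterministic
#' fraction of each series to warhead-bearing analogues by replacing the
#' varied substituent with a warhead moiety (distinct warheads within a
#' series). Every emitted SMILES is validated; ground truth (series,
#' warhead, substituent) is recorded.
#'
#' @param config a [generator_config()].
#' @return data.frame with `compound_id`, `smiles`, `series_id`,
#'   `warhead` (NA for non-covalent members), `substituent`.
#' @export
generate_library <- function(config = generator_config()) {
  with_seed(config$seed, {
    rows <- list()
    for (ci in seq_len(config$n_cores)) {
      template <- .core_templates[[ci]]
      subs <- .plain_substituents[seq_len(config$substituents_per_core)]
      n_cov <- round(config$warhead_fraction * length(subs))
      n_cov <- min(n_cov, length(config$warhead_names), length(subs))
      cov_idx <- if (n_cov > 0L) {
        sample(seq_along(subs), n_cov)
      } else integer()
      whs <- if (n_cov > 0L) {
        config$warhead_names[
          ((seq_len(n_cov) - 1L + (ci - 1L)) %%
             length(config$warhead_names)) + 1L]
      } else character()
      for (si in seq_along(subs)) {
        k <- match(si, cov_idx)
        moiety <- if (!is.na(k)) .warhead_moieties[[whs[[k]]]] else subs[[si]]
        smi <- gsub("{R}", moiety, template, fixed = TRUE)
        rows[[length(rows) + 1L]] <- data.frame(
          compound_id = sprintf("CPD%02d_%02d", ci, si),
          smiles = smi,
          series_id = sprintf("GT%02d", ci),
          warhead = if (!is.na(k)) whs[[k]] else NA_character_,
          substituent = if (!is.na(k)) whs[[k]] else subs[[si]],
          stringsAsFactors = FALSE)
      }
    }
    lib <- do.call(rbind, rows)
    ok <- ob_smiles_valid(lib$smiles)
    if (any(!ok)) {
      warning("skipping ", sum(!ok), " invalid generated SMILES")
      lib <- lib[ok, , drop = FALSE]
    }
    rownames(lib) <- NULL
    lib
  })
}

# Corruptions that violate one named curation filter each.
.violators <- list(
  relation = function(r) { r$relation <- ">"; r },
  relationship_type = function(r) {
    r$source <- "chembl"; r$relationship_type <- "B"; r
  },
  measurement_type = function(r) { r$measurement_type <- "EC50"; r },
  potency_cutoff = function(r) {
    r$value_nM <- 20000 + round(stats::runif(1, 0, 30000)); r
  },
  assay_kinase_count = function(r) { r$assay_kinase_count <- 2L; r },
  assay_confidence = function(r) {
    # keep the record chembl-clean otherwise, so the confidence filter
    # is the first (and only) one it fails
    r$source <- "chembl"; r$relationship_type <- "D"
    r$assay_confidence <- 8L; r
  },
  activity_comment = function(r) { r$activity_comment <- "uncertain"; r },
  units = function(r) { r$units <- "uM"; r },
  malformed_record = function(r) { r$compound_smiles <- ""; r }
)

#' Names of the curation filters the generator can plant violations for
#' @return character vector of filter reason codes.
#' @export
violation_filters <- function() names(.violators)

#' Generate activity records for a labeled library
#'
#' Each compound receives 1 kinase with probability
#' `single_target_fraction` (always including its series' primary
#' kinase) or a promiscuity degree drawn from `pd_tail`. The true
#' pPotency of a (series, kinase) combination is Normal(7, 1) truncated
#' to at least 5; warhead-bearing analogues sit `planted_shift_log`
#' units higher. Replicate measurements add Normal(0, `noise_sd_log`)
#' log-unit noise, floored at the 10 uM reporting cut-off (archives only
#' carry qualifying measurements), and are back-converted to nM. With
#' probability `violation_rates[f]` a record is corrupted to violate
#' curation filter `f` (recorded in `violation`).
#'
#' @param library data.frame from [generate_library()].
#' @param config the same [generator_config()].
#' @return data.frame of activity records with ground-truth columns
#'   `compound_id`, `true_pPotency`, `violation` appended.
#' @export
generate_activities <- function(library, config = generator_config()) {
  with_seed(config$seed + 1L, {
    targets <- sprintf("KIN%03d", seq_len(config$n_targets))
    base_env <- new.env(parent = emptyenv())
    base_potency <- function(series, target) {
      key <- paste(series, target)
      if (is.null(base_env[[key]])) {
        p <- stats::rnorm(1, 7, 1)
        while (p < 5) p <- stats::rnorm(1, 7, 1)
        base_env[[key]] <- p
      }
      base_env[[key]]
    }
    rows <- list()
    for (i in seq_len(nrow(library))) {
      cpd <- library[i, ]
      series_idx <- as.integer(sub("GT", "", cpd$series_id))
      primary <- targets[[(series_idx - 1L) %% config$n_targets + 1L]]
      pd <- if (stats::runif(1) < config$single_target_fraction) 1L else {
        sample(config$pd_tail$values, 1L, prob = config$pd_tail$probs)
      }
      tg <- primary
      if (pd > 1L) {
        tg <- c(primary, sample(setdiff(targets, primary),
                                min(pd - 1L, config$n_targets - 1L)))
      }
      for (t in tg) {
        p_true <- base_potency(cpd$series_id, t) +
          if (!is.na(cpd$warhead)) config$planted_shift_log else 0
        n_rep <- sample(seq(config$n_replicates_range[[1L]],
                            config$n_replicates_range[[2L]]), 1L)
        mtype <- sample(c("IC50", "Ki", "Kd"), 1L,
                        prob = c(0.6, 0.25, 0.15))
        src <- sample(c("chembl", "bindingdb"), 1L)
        for (rep_i in seq_len(n_rep)) {
          p_meas <- max(p_true + stats::rnorm(1, 0, config$noise_sd_log), 5)
          rec <- data.frame(
            compound_smiles = cpd$smiles, target_id = t,
            measurement_type = mtype, relation = "=",
            value_nM = 10^(9 - p_meas),
            relationship_type = if (src == "chembl") "D" else NA_character_,
            assay_confidence = if (src == "chembl") 9L else NA_integer_,
            assay_kinase_count = 1L, activity_comment = "", source = src,
            units = "nM", compound_id = cpd$compound_id,
            true_pPotency = p_true, violation = "",
            stringsAsFactors = FALSE)
          for (f in names(config$violation_rates)) {
            if (rec$violation == "" &&
                stats::runif(1) < config$violation_rates[[f]]) {
              rec <- .violators[[f]](rec)
              rec$violation <- f
            }
          }
          rows[[length(rows) + 1L]] <- rec
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Build a batch with exactly one designed violator per curation filter
#'
#' Generates a clean activity batch and corrupts one distinct record per
#' filter reason code, so the curation report can be checked for exactly
#' one rejection per reason.
#'
#' @param config a [generator_config()].
#' @param filters filter reason codes to plant (default all).
#' @return list with `records` and `planted` (data.frame: row index and
#'   filter).
#' @export
generate_violation_fixture <- function(config = generator_config(),
                                       filters = violation_filters()) {
  lib <- generate_library(config)
  rec <- generate_activities(lib, config)
  stopifnot(nrow(rec) >= length(filters))
  idx <- with_seed(config$seed + 2L,
                   sample(nrow(rec), length(filters)))
  for (k in seq_along(filters)) {
    r <- .violators[[filters[[k]]]](rec[idx[[k]], , drop = FALSE])
    r$violation <- filters[[k]]
    rec[idx[[k]], ] <- r
  }
  list(records = rec,
       planted = data.frame(row = idx, filter = filters,
                            stringsAsFactors = FALSE))
}
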