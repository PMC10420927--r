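#' Convert a nanomolar potency to its negative decadic logarithm
#'
#' Potency measurements (Ki, Kd, IC50) are recorded throughout the
#' pipeline as negative decadic logarithms of the molar value, so a
#' 10,000 nM measurement maps to 5.0 and a 1 nM measurement to 9.0.
#'
#' @param value_nM positive numeric vector, nanomolar.
#' @return numeric vector of pPotency values.
#' @export
to_ppotency <- function(value_nM) {
  if (any(!is.finite(value_nM)) || any(value_nM <= 0)) {
    stop("nonpositive_potency")
  }
  -log10(value_nM * 1e-9)
}

#' Curation configuration
#'
#' Holds the high-confidence activity filters: the potency cut-off (a
#' record must report at most this nanomolar value), the admissible
#' measurement types, the required activity relation, the required
#' relationship type for ChEMBL-sourced records, the required assay
#' confidence score for ChEMBL, the flagged comment phrases, and the
#' maximum log-unit standard deviation tolerated when replicate
#' measurements of one compound-kinase pair are averaged.
#'
#' @param potency_cutoff_nM maximum admissible value in nM (default 10000).
#' @param sd_max maximum log-unit SD across replicates (default 1.0).
#' @param required_relation required activity relation (default "=").
#' @param required_relationship_type required ChEMBL relationship type
#'   (default "D", direct binding assay).
#' @param required_confidence required ChEMBL assay confidence score
#'   (default 9).
#' @param measurement_types admissible measurement types.
#' @param flagged_comments phrases that disqualify a record when found
#'   (case-insensitively) in its activity comment.
#' @param check_flag_contradiction reject records whose activity flag
#'   contradicts the measured activity (see Details).
#' @details A record is also rejected when an optional `activity_flag`
#'   column marks it "inactive" although the measured value passes the
#'   potency cut-off, or when the comment itself carries both an
#'   "active" and an "inactive" tag.
#' @return An object of class `curation_config`.
#' @export
curation_config <- function(potency_cutoff_nM = 10000,
                            sd_max = 1.0,
                            required_relation = "=",
                            required_relationship_type = "D",
                            required_confidence = 9,
                            measurement_types = c("Ki", "Kd", "IC50"),
                            flagged_comments = c("uncertain",
                                                 "potential transcription error",
                                                 "outside typical range"),
                            check_flag_contradiction = TRUE) {
  structure(list(potency_cutoff_nM = potency_cutoff_nM, sd_max = sd_max,
                 required_relation = required_relation,
                 required_relationship_type = required_relationship_type,
                 required_confidence = required_confidence,
                 measurement_types = measurement_types,
                 flagged_comments = flagged_comments,
                 check_flag_contradiction = check_flag_contradiction),
            class = "curation_config")
}

.mandatory_record_cols <- c("compound_smiles", "target_id", "measurement_type",
                            "relation", "value_nM", "source")

# Reason codes in their fixed evaluation order; the first failed filter
# names the rejection.
.filter_order <- c("malformed_record", "units", "relation",
                   "relationship_type", "measurement_type", "potency_cutoff",
                   "assay_kinase_count", "assay_confidence",
                   "activity_comment")

#' Apply the per-record activity filters
#'
#' Evaluates every filter on every record and reports, for rejected
#' records, the first failed filter in a fixed order (`malformed_record`,
#' `units`, `relation`, `relationship_type`, `measurement_type`,
#' `potency_cutoff`, `assay_kinase_count`, `assay_confidence`,
#' `activity_comment`). The relationship-type and assay-confidence
#' filters apply to ChEMBL-sourced records only; BindingDB carries
#' neither field.
#'
#' @param records data.frame of activity records; see
#'   [read_activity_table()] for the column contract.
#' @param config a [curation_config()].
#' @return `records` with logical column `keep` and character column
#'   `reject_reason` ("" for kept records) appended.
#' @export
filter_records <- function(records, config = curation_config()) {
  n <- nrow(records)
  reason <- character(n)
  col <- function(name, default = NA) {
    if (name %in% names(records)) records[[name]] else rep(default, n)
  }
  missing_cols <- setdiff(.mandatory_record_cols, names(records))
  value <- suppressWarnings(as.numeric(col("value_nM")))
  is_chembl <- tolower(as.character(col("source", ""))) == "chembl"

  malformed <- if (length(missing_cols) > 0L) rep(TRUE, n) else {
    is.na(records$compound_smiles) | !nzchar(records$compound_smiles) |
      is.na(records$target_id) | !nzchar(records$target_id) |
      is.na(value) | is.na(records$measurement_type) |
      is.na(records$relation)
  }

  units <- col("units", "nM")
  bad_units <- !is.na(units) & nzchar(units) & units != "nM"
  bad_relation <- col("relation", "") != config$required_relation
  rel_type <- col("relationship_type", NA_character_)
  bad_rel_type <- is_chembl &
    (is.na(rel_type) | rel_type != config$required_relationship_type)
  bad_mtype <- !(col("measurement_type", "") %in% config$measurement_types)
  bad_potency <- !is.na(value) & value > config$potency_cutoff_nM
  akc <- suppressWarnings(as.numeric(col("assay_kinase_count", 1)))
  bad_akc <- is.na(akc) | akc != 1
  conf <- suppressWarnings(as.numeric(col("assay_confidence", NA)))
  bad_conf <- is_chembl & (is.na(conf) | conf != config$required_confidence)

  comment <- tolower(as.character(col("activity_comment", "")))
  comment[is.na(comment)] <- ""
  bad_comment <- Reduce(`|`, lapply(config$flagged_comments, function(ph) {
    grepl(ph, comment, fixed = TRUE)
  }), rep(FALSE, n))
  if (isTRUE(config$check_flag_contradiction)) {
    flag <- tolower(as.character(col("activity_flag", "")))
    flag[is.na(flag)] <- ""
    contradictory <-
      (flag == "inactive" & !is.na(value) & value <= config$potency_cutoff_nM) |
      (grepl("\\binactive\\b", comment) &
         grepl("(?<!in)active\\b", comment, perl = TRUE))
    bad_comment <- bad_comment | contradictory
  }

  fails <- cbind(malformed_record = malformed, units = bad_units,
                 relation = bad_relation, relationship_type = bad_rel_type,
                 measurement_type = bad_mtype, potency_cutoff = bad_potency,
                 assay_kinase_count = bad_akc, assay_confidence = bad_conf,
                 activity_comment = bad_comment)
  fails[is.na(fails)] <- TRUE
  first <- apply(fails, 1L, function(f) {
    hit <- which(f)
    if (length(hit) == 0L) "" else colnames(fails)[hit[[1L]]]
  })
  records$keep <- first == ""
  records$reject_reason <- first
  records
}

#' Aggregate replicate measurements of one compound-kinase pair
#'
#' Ki/Kd measurements take priority: when any are present, IC50 records
#' are ignored and the pair's measurement class is `KiKd`, otherwise
#' `IC50`. The pair potency is the arithmetic mean of the per-record
#' pPotency values (averaging on the log scale, matching the log-unit SD
#' threshold) with the sample standard deviation (n-1 denominator, 0 for
#' a single record). Pairs whose SD reaches `sd_max` are dropped, as are
#' pairs whose mean pPotency falls below the cut-off equivalent.
#'
#' @param ppotency numeric vector of per-record pPotency values.
#' @param measurement_type character vector, same length, of "Ki", "Kd"
#'   or "IC50".
#' @param config a [curation_config()].
#' @return A list with `pPotency`, `measurement_class`, `n_measurements`,
#'   `sd_log` and `retained` (FALSE with `drop_reason` when the pair is
#'   discarded).
#' @export
aggregate_measurements <- function(ppotency, measurement_type,
                                   config = curation_config()) {
  if (length(ppotency) == 0L) stop("no_records")
  stopifnot(length(ppotency) == length(measurement_type))
  kikd <- measurement_type %in% c("Ki", "Kd")
  use <- if (any(kikd)) kikd else rep(TRUE, length(ppotency))
  vals <- ppotency[use]
  m <- mean(vals)
  s <- if (length(vals) > 1L) stats::sd(vals) else 0
  res <- list(pPotency = m,
              measurement_class = if (any(kikd)) "KiKd" else "IC50",
              n_measurements = length(vals), sd_log = s,
              retained = TRUE, drop_reason = "")
  if (s >= config$sd_max) {
    res$retained <- FALSE
    res$drop_reason <- "sd_dispersion"
  } else if (m < to_ppotency(config$potency_cutoff_nM)) {
    res$retained <- FALSE
    res$drop_reason <- "mean_potency"
  }
  res
}

#' Curate raw activity records into one potency per compound-kinase pair
#'
#' Runs the full curation cascade: compound standardization
#' ([standardize_smiles()]), per-record filtering ([filter_records()]),
#' grouping by (standard_smiles, target_id) across sources, and replicate
#' aggregation ([aggregate_measurements()]). Record conservation holds:
#' the records contributing to curated pairs plus the rejected records
#' sum to the input size.
#'
#' @param records data.frame of activity records.
#' @param config a [curation_config()].
#' @return A list with `curated` (data.frame: `standard_smiles`,
#'   `target_id`, `pPotency`, `measurement_class`, `n_measurements`,
#'   `sd_log`) and `report` (named rejection counts by reason, plus
#'   `input`, `kept_records` and `pairs`).
#' @export
curate <- function(records, config = curation_config()) {
  empty <- data.frame(standard_smiles = character(), target_id = character(),
                      pPotency = numeric(), measurement_class = character(),
                      n_measurements = integer(), sd_log = numeric(),
                      stringsAsFactors = FALSE)
  if (is.null(records) || nrow(records) == 0L) {
    return(list(curated = empty,
                report = list(input = 0L, kept_records = 0L, pairs = 0L,
                              rejected = integer())))
  }
  filt <- filter_records(records, config)

  # Standardize the compounds of records that survived the field filters.
  std_map <- character()
  passing <- which(filt$keep)
  if (length(passing) > 0L) {
    uniq <- unique(filt$compound_smiles[passing])
    std <- standardize_smiles(uniq)
    std_map <- stats::setNames(std$standard_smiles, uniq)
    bad <- uniq[!std$valid]
    fail_std <- passing[filt$compound_smiles[passing] %in% bad]
    filt$keep[fail_std] <- FALSE
    filt$reject_reason[fail_std] <- "compound_parse"
  }

  kept <- filt[filt$keep, , drop = FALSE]
  if (nrow(kept) > 0L) {
    kept$standard_smiles <- unname(std_map[kept$compound_smiles])
    kept$ppotency <- to_ppotency(as.numeric(kept$value_nM))
    key <- paste(kept$standard_smiles, kept$target_id, sep = "\r")
    groups <- split(seq_len(nrow(kept)), key)
    rows <- vector("list", length(groups))
    dropped_idx <- integer()
    drop_reason_by_row <- character(nrow(kept))
    for (i in seq_along(groups)) {
      idx <- groups[[i]]
      agg <- aggregate_measurements(kept$ppotency[idx],
                                    kept$measurement_type[idx], config)
      if (agg$retained) {
        rows[[i]] <- data.frame(
          standard_smiles = kept$standard_smiles[idx[[1L]]],
          target_id = kept$target_id[idx[[1L]]],
          pPotency = agg$pPotency,
          measurement_class = agg$measurement_class,
          n_measurements = agg$n_measurements,
          sd_log = agg$sd_log, stringsAsFactors = FALSE)
      } else {
        dropped_idx <- c(dropped_idx, idx)
        drop_reason_by_row[idx] <- agg$drop_reason
      }
    }
    curated <- do.call(rbind, rows)
    if (is.null(curated)) curated <- empty
    if (length(dropped_idx) > 0L) {
      orig <- match(rownames(kept)[dropped_idx], rownames(filt))
      filt$keep[orig] <- FALSE
      filt$reject_reason[orig] <- drop_reason_by_row[dropped_idx]
    }
  } else {
    curated <- empty
  }

  reasons <- filt$reject_reason[!filt$keep]
  report <- list(
    input = nrow(records),
    kept_records = sum(filt$keep),
    pairs = nrow(curated),
    rejected = if (length(reasons)) table(reasons) else integer()
  )
  rownames(curated) <- NULL
  list(curated = curated, report = report)
}

#' Read an activity table from CSV or TSV
#'
#' Expected header columns: `compound_smiles`, `target_id`,
#' `measurement_type`, `relation`, `value_nM`, `relationship_type`,
#' `assay_confidence`, `assay_kinase_count`, `activity_comment`,
#' `source`; optional `units` and `activity_flag`. The delimiter is taken
#' from the file extension (`.csv` vs anything else = tab).
#'
#' @param path input file path.
#' @return data.frame of activity records.
#' @export
read_activity_table <- function(path) {
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, comment.char = "")
}

#' Write curated activities and the curation report
#'
#' @param curation result of [curate()].
#' @param curated_path TSV path for the curated table.
#' @param report_path JSON path for the report; skipped when `NULL`.
#' @return `curation`, invisibly.
#' @export
write_curated <- function(curation, curated_path, report_path = NULL) {
  utils::write.table(curation$curated, curated_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(report_path)) {
    rep <- curation$report
    rep$rejected <- as.list(rep$rejected)
    jsonlite::write_json(rep, report_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(curation)
}
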