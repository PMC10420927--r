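#' Pipeline configuration
#'
#' Thresholds default to the study's printed values: activity cut-off
#' 10,000 nM, replicate SD limit 1 log unit, ChEMBL confidence 9,
#' analogue-pair threshold 100-fold, resolution cut-off 3.5 Angstrom.
#'
#' @param curation a [curation_config()].
#' @param min_fold analogue-pair potency-fold threshold.
#' @param max_cuts maximum simultaneous cuts in series decomposition.
#' @param resolution_max strict structure resolution cut-off (Angstrom).
#' @param peptide_max_residues large-peptide limit for triage.
#' @param keywords structure-scan keyword list.
#' @param warhead_config optional warhead library config path.
#' @param alpha significance level for the statistics.
#' @param seed integer seed for seeded stages.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(curation = curation_config(),
                            min_fold = 100,
                            max_cuts = 3,
                            resolution_max = 3.5,
                            peptide_max_residues = 4,
                            keywords = triage_keywords(),
                            warhead_config = NULL,
                            alpha = 0.05,
                            seed = 1L) {
  structure(list(curation = curation, min_fold = min_fold,
                 max_cuts = max_cuts, resolution_max = resolution_max,
                 peptide_max_residues = peptide_max_residues,
                 keywords = keywords, warhead_config = warhead_config,
                 alpha = alpha, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the end-to-end analysis
#'
#' Orchestrates curation, warhead detection, analogue-series and pair
#' extraction, potency statistics, and promiscuity profiling on an
#' activity table, plus structure triage when structure files or a
#' curated ligand-record table are supplied. Stage record counts are
#' conserved and logged; a stage failure aborts with the stage named,
#' leaving the outputs written so far in place.
#'
#' @param records data.frame of activity records (or a file path for
#'   [read_activity_table()]).
#' @param structures optional directory of PDB/mmCIF files to triage.
#' @param ligand_records optional path to a curated allosteric-ligand
#'   TSV for [summarize_ligand_records()].
#' @param ligand_baseline optional named vector of prior per-type counts.
#' @param out_dir optional output directory: per-stage TSVs, a
#'   `summary.json`, and a `pipeline.log` are written there.
#' @param config a [pipeline_config()].
#' @param stages subset of stage names to run (downstream stages of a
#'   skipped stage are skipped too).
#' @return list with the per-stage results and a `summary` list.
#' @export
run_pipeline <- function(records, structures = NULL, ligand_records = NULL,
                         ligand_baseline = NULL, out_dir = NULL,
                         config = pipeline_config(),
                         stages = c("curate", "warheads", "series", "pairs",
                                    "stats", "promiscuity", "triage")) {
  log_lines <- character()
  log <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S "), sprintf(...))
    log_lines <<- c(log_lines, line)
    message(line)
  }
  out <- list()
  save_tsv <- function(df, name) {
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      utils::write.table(df, file.path(out_dir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }
  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  if (is.character(records)) records <- read_activity_table(records)

  if ("curate" %in% stages) {
    out$curation <- run_stage("curate", function() {
      curate(records, config$curation)
    })
    rep <- out$curation$report
    stopifnot(rep$kept_records + sum(rep$rejected) == rep$input)
    log("curate: %d records in, %d kept, %d rejected, %d pairs",
        rep$input, rep$kept_records, sum(rep$rejected), rep$pairs)
    save_tsv(out$curation$curated, "curated.tsv")
  }

  compounds <- unique(out$curation$curated$standard_smiles)
  if ("warheads" %in% stages && !is.null(out$curation)) {
    out$assignments <- run_stage("warheads", function() {
      lib <- load_warhead_library(config$warhead_config)
      detect_warheads(compounds, lib)
    })
    out$partition <- partition_by_warhead(out$assignments)
    log("warheads: %d compounds, %d covalent, %d non-covalent, %d excluded",
        length(compounds), sum(out$assignments$is_cpki),
        length(out$partition$non_covalent),
        length(out$partition$excluded_prior))
    save_tsv(out$assignments, "warheads.tsv")
  }

  if ("series" %in% stages && !is.null(out$assignments)) {
    out$series <- run_stage("series", function() {
      build_series(compounds, max_cuts = config$max_cuts)
    })
    log("series: %d series covering %d compounds",
        length(unique(out$series$series_id)), nrow(out$series))
    save_tsv(out$series, "series.tsv")
  }

  if ("pairs" %in% stages && !is.null(out$series)) {
    out$pairs <- run_stage("pairs", function() {
      extract_pairs(out$series, out$curation$curated, out$assignments,
                    min_fold = config$min_fold)
    })
    log("pairs: %d analogue pairs (>= %g-fold)", nrow(out$pairs),
        config$min_fold)
    save_tsv(out$pairs, "pairs.tsv")
  }

  if ("stats" %in% stages && !is.null(out$partition)) {
    out$stats <- run_stage("stats", function() {
      cur <- out$curation$curated
      pvals <- function(cpds) cur$pPotency[cur$standard_smiles %in% cpds]
      subsets <- lapply(out$partition$subsets, pvals)
      noncov <- pvals(out$partition$non_covalent)
      gc <- if (length(noncov) >= 2L &&
                length(subsets) >= 1L &&
                any(vapply(subsets, length, 1L) >= 2L)) {
        compare_groups(noncov, subsets, alpha = config$alpha)
      } else NULL
      list(global = gc,
           pair_tests = if (!is.null(out$pairs)) pair_tests(out$pairs))
    })
    if (!is.null(out$stats$global)) {
      log("stats: ANOVA F=%.3f p=%.3g over %d groups",
          out$stats$global$F_statistic, out$stats$global$p_value,
          length(out$stats$global$group_names))
    }
  }

  if ("promiscuity" %in% stages && !is.null(out$partition)) {
    out$promiscuity <- run_stage("promiscuity", function() {
      profiles <- compute_pd(out$curation$curated)
      list(profiles = profiles,
           by_class = pd_by_class(profiles, out$partition))
    })
    log("promiscuity: %d compounds profiled",
        nrow(out$promiscuity$profiles))
    save_tsv(out$promiscuity$by_class, "promiscuity.tsv")
  }

  if ("triage" %in% stages &&
      (!is.null(structures) || !is.null(ligand_records))) {
    out$triage <- run_stage("triage", function() {
      tri <- list()
      if (!is.null(structures)) {
        files <- list.files(structures, "\\.(pdb|cif|mmcif)$",
                            full.names = TRUE)
        tri$decisions <- do.call(rbind, lapply(files, function(f) {
          e <- parse_structure(f)
          pf <- passes_filters(e, keywords = config$keywords,
                               resolution_max = config$resolution_max,
                               peptide_max_residues =
                                 config$peptide_max_residues)
          data.frame(file = basename(f), pdb_id = e$pdb_id,
                     resolution_A = e$resolution_A, passes = pf$passes,
                     reasons = paste(pf$reasons, collapse = ";"),
                     n_covalent_links = nrow(e$covalent_links),
                     stringsAsFactors = FALSE)
        }))
      }
      if (!is.null(ligand_records)) {
        tri$ligand_summary <- summarize_ligand_records(
          read_ligand_records(ligand_records), baseline = ligand_baseline)
      }
      tri
    })
    if (!is.null(out$triage$decisions)) {
      log("triage: %d structures, %d passing",
          nrow(out$triage$decisions), sum(out$triage$decisions$passes))
      save_tsv(out$triage$decisions, "triage.tsv")
    }
  }

  out$summary <- pipeline_summary(out)
  if (!is.null(out_dir)) {
    jsonlite::write_json(out$summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    writeLines(log_lines, file.path(out_dir, "pipeline.log"))
  }
  out
}

pipeline_summary <- function(out) {
  s <- list()
  if (!is.null(out$curation)) {
    rep <- out$curation$report
    s$curation <- list(input = rep$input, kept = rep$kept_records,
                       pairs = rep$pairs,
                       rejected = as.list(rep$rejected))
  }
  if (!is.null(out$assignments)) {
    s$warheads <- list(
      n_cpki = sum(out$assignments$is_cpki),
      n_non_covalent = length(out$partition$non_covalent),
      n_excluded_prior = length(out$partition$excluded_prior),
      subset_sizes = lapply(out$partition$subsets, length))
  }
  if (!is.null(out$series)) {
    s$series <- list(n_series = length(unique(out$series$series_id)),
                     n_members = nrow(out$series))
  }
  if (!is.null(out$pairs)) {
    s$pairs <- list(n_pairs = nrow(out$pairs),
                    mean_delta = if (nrow(out$pairs)) mean(out$pairs$delta_p)
                                 else NA)
  }
  if (!is.null(out$stats$global)) {
    s$anova <- list(F_statistic = out$stats$global$F_statistic,
                    p_value = out$stats$global$p_value,
                    medians = as.list(out$stats$global$medians))
  }
  if (!is.null(out$promiscuity)) {
    bc <- out$promiscuity$by_class
    pd1 <- bc[bc$subset == "non_covalent" & bc$bin == "PD1", "proportion"]
    s$promiscuity <- list(
      pd1_non_covalent = if (length(pd1)) pd1 else NA)
  }
  if (!is.null(out$triage$decisions)) {
    s$triage <- list(n_structures = nrow(out$triage$decisions),
                     n_passing = sum(out$triage$decisions$passes))
  }
  if (!is.null(out$triage$ligand_summary)) {
    ls <- out$triage$ligand_summary
    s$ligand_census <- list(total = ls$total, apki_total = ls$apki_total,
                            covalent_n = ls$covalent$n)
  }
  s
}
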