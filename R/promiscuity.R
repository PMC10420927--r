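#' Promiscuity degree per compound
#'
#' The promiscuity degree (PD) of a compound is the number of distinct
#' kinases it has qualifying curated activity against. Compounds are
#' binned as in the field's convention: PD 1, PD 2-4, PD 5-9, PD >= 10.
#'
#' @param curated data.frame from [curate()]'s `curated` element (one
#'   row per compound-kinase pair).
#' @return data.frame with `standard_smiles`, `pd`, `bin`.
#' @export
compute_pd <- function(curated) {
  if (nrow(curated) == 0L) {
    return(data.frame(standard_smiles = character(), pd = integer(),
                      bin = character(), stringsAsFactors = FALSE))
  }
  pd <- tapply(curated$target_id, curated$standard_smiles,
               function(t) length(unique(t)))
  out <- data.frame(standard_smiles = names(pd), pd = as.integer(pd),
                    stringsAsFactors = FALSE)
  out$bin <- pd_bin(out$pd)
  rownames(out) <- NULL
  out
}

#' Bin promiscuity degrees
#' @param pd integer vector of promiscuity degrees (>= 1).
#' @return character vector of bins: PD1, PD2_4, PD5_9, PD10plus.
#' @export
pd_bin <- function(pd) {
  stopifnot(all(pd >= 1L))
  cut(pd, breaks = c(0, 1, 4, 9, Inf),
      labels = c("PD1", "PD2_4", "PD5_9", "PD10plus")) |> as.character()
}

.pd_bins <- c("PD1", "PD2_4", "PD5_9", "PD10plus")

#' Promiscuity-degree distribution of a compound subset
#'
#' @param profiles data.frame from [compute_pd()].
#' @param subset optional character vector of compounds to restrict to;
#'   default all profiled compounds.
#' @return data.frame with one row per bin: `bin`, `count`,
#'   `proportion`; proportions sum to 1.
#' @export
pd_distribution <- function(profiles, subset = NULL) {
  p <- if (is.null(subset)) profiles else {
    profiles[profiles$standard_smiles %in% subset, , drop = FALSE]
  }
  if (nrow(p) == 0L) stop("empty_subset")
  counts <- table(factor(p$bin, levels = .pd_bins))
  data.frame(bin = .pd_bins, count = as.integer(counts),
             proportion = as.numeric(counts) / nrow(p),
             stringsAsFactors = FALSE)
}

#' Promiscuity-degree distributions per compound class
#'
#' Applies [pd_distribution()] to the non-covalent set and to each
#' warhead subset from [partition_by_warhead()]. Promiscuity analysis
#' from archival data is affected by incomplete kinome coverage (most
#' inhibitors are tested against very few kinases); the distributions
#' describe annotated activity, not exhaustive profiling — the returned
#' object carries this caveat in its `note` attribute.
#'
#' @param profiles data.frame from [compute_pd()].
#' @param partition list from [partition_by_warhead()].
#' @return data.frame with `subset`, `bin`, `count`, `proportion`.
#' @export
pd_by_class <- function(profiles, partition) {
  blocks <- c(list(non_covalent = partition$non_covalent),
              partition$subsets)
  rows <- lapply(names(blocks), function(nm) {
    members <- intersect(blocks[[nm]], profiles$standard_smiles)
    if (length(members) == 0L) return(NULL)
    d <- pd_distribution(profiles, members)
    cbind(subset = nm, d, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "note") <-
    "PDs reflect annotated activity only; most inhibitors are not exhaustively profiled."
  out
}
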