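#' Five-number summary of a pPotency distribution
#'
#' Median and quartiles use the linear-interpolation convention
#' (`stats::quantile` type 7).
#'
#' @param ppotencies numeric vector, length at least 1.
#' @return list with `median`, `q1`, `q3`, `n`.
#' @export
summarize_distribution <- function(ppotencies) {
  if (length(ppotencies) == 0L || all(is.na(ppotencies))) {
    stop("empty_distribution")
  }
  q <- stats::quantile(ppotencies, c(0.25, 0.5, 0.75), na.rm = TRUE,
                       names = FALSE, type = 7)
  list(median = q[[2L]], q1 = q[[1L]], q3 = q[[3L]],
       n = sum(!is.na(ppotencies)))
}

.check_groups <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(vapply(groups, length, 1L) < 2L)) stop("degenerate_group")
}

.stack_groups <- function(groups) {
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), vapply(groups, length, 1L)),
                   levels = names(groups))
  )
}

#' One-way analysis of variance across potency groups
#'
#' Standard between/within mean-square ratio with an F-distribution
#' p-value on (k-1, N-k) degrees of freedom, fitted with `stats::aov`.
#'
#' @param groups list of numeric vectors, each of length at least 2.
#' @return list with `F_statistic`, `p_value`, `df_between`, `df_within`.
#' @export
one_way_anova <- function(groups) {
  .check_groups(groups)
  d <- .stack_groups(groups)
  fit <- stats::aov(value ~ group, data = d)
  s <- summary(fit)[[1L]]
  Fv <- s[["F value"]][[1L]]
  p <- s[["Pr(>F)"]][[1L]]
  if (is.na(Fv)) { Fv <- 0; p <- 1 }  # zero within- and between-variance
  list(F_statistic = Fv, p_value = p,
       df_between = s[["Df"]][[1L]], df_within = s[["Df"]][[2L]])
}

#' Tukey-Kramer post hoc comparison of all group pairs
#'
#' Studentized-range procedure with the Tukey-Kramer standard error for
#' unequal group sizes (`stats::TukeyHSD` on the underlying ANOVA fit);
#' q statistics are recovered from the mean differences and the pooled
#' mean square.
#'
#' @param groups list of numeric vectors, each of length at least 2.
#' @param alpha significance level for the `significant` flag.
#' @return data.frame with one row per unordered group pair: `group_i`,
#'   `group_j`, `mean_diff`, `q_statistic`, `adjusted_p`, `significant`.
#' @export
tukey_hsd <- function(groups, alpha = 0.05) {
  .check_groups(groups)
  d <- .stack_groups(groups)
  fit <- stats::aov(value ~ group, data = d)
  mse <- sum(stats::residuals(fit)^2) / fit$df.residual
  tk <- stats::TukeyHSD(fit)$group
  nm <- strsplit(rownames(tk), "-", fixed = TRUE)
  sizes <- table(d$group)
  rows <- lapply(seq_len(nrow(tk)), function(r) {
    gi <- nm[[r]][[2L]]; gj <- nm[[r]][[1L]]   # TukeyHSD reports j-i
    se <- sqrt(mse / 2 * (1 / sizes[[gi]] + 1 / sizes[[gj]]))
    q <- if (se > 0) abs(tk[r, "diff"]) / se else 0
    p <- tk[r, "p adj"]
    if (is.na(p)) p <- 1
    data.frame(group_i = gi, group_j = gj, mean_diff = unname(tk[r, "diff"]),
               q_statistic = unname(q), adjusted_p = unname(p),
               significant = unname(p < alpha), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Paired t-test on potency deltas
#'
#' One-sample two-sided t-test of the deltas against zero, used for the
#' per-warhead analogue-pair comparisons.
#'
#' @param deltas numeric vector of paired potency differences, length at
#'   least 2.
#' @return list with `n_pairs`, `mean_delta`, `t_statistic`, `p_value`.
#' @export
paired_t_test <- function(deltas) {
  if (length(deltas) < 2L) stop("need at least 2 deltas")
  if (stats::sd(deltas) == 0) stop("zero_variance")
  tt <- stats::t.test(deltas, mu = 0, alternative = "two.sided")
  list(n_pairs = length(deltas), mean_delta = mean(deltas),
       t_statistic = unname(tt$statistic), p_value = tt$p.value)
}

#' Compare the non-covalent potency distribution with each warhead subset
#'
#' Builds the global group comparison: per-group sizes and medians, the
#' one-way ANOVA over all groups, and the Tukey-Kramer table.
#'
#' @param noncovalent numeric vector of non-covalent pPotency values.
#' @param subsets named list of numeric vectors, one per warhead subset.
#' @param alpha significance level.
#' @return list with `group_names`, `group_sizes`, `medians`,
#'   `F_statistic`, `p_value`, `tukey`.
#' @export
compare_groups <- function(noncovalent, subsets, alpha = 0.05) {
  groups <- c(list(non_covalent = noncovalent), subsets)
  groups <- groups[vapply(groups, length, 1L) >= 2L]
  an <- one_way_anova(groups)
  list(group_names = names(groups),
       group_sizes = vapply(groups, length, 1L),
       medians = vapply(groups, stats::median, 1.0),
       F_statistic = an$F_statistic, p_value = an$p_value,
       tukey = tukey_hsd(groups, alpha = alpha))
}

#' Per-warhead paired t-tests over analogue pairs
#'
#' @param pairs data.frame from [extract_pairs()].
#' @return data.frame with `warhead`, `n_pairs`, `mean_delta`,
#'   `t_statistic`, `p_value`; warheads with fewer than 2 pairs or zero
#'   delta variance carry NA statistics.
#' @export
pair_tests <- function(pairs) {
  if (nrow(pairs) == 0L) {
    return(data.frame(warhead = character(), n_pairs = integer(),
                      mean_delta = numeric(), t_statistic = numeric(),
                      p_value = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, lapply(split(pairs, pairs$warhead), function(p) {
    res <- tryCatch(paired_t_test(p$delta_p), error = function(e) NULL)
    data.frame(warhead = p$warhead[[1L]], n_pairs = nrow(p),
               mean_delta = mean(p$delta_p),
               t_statistic = if (is.null(res)) NA_real_ else res$t_statistic,
               p_value = if (is.null(res)) NA_real_ else res$p_value,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
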