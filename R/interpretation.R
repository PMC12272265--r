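# Interpretation of a trained model: cohort-level edge-importance rankings
# and brain-age-delta group comparisons.

#' Average per-subject edge-score matrices
#'
#' Cohort-level edge importance is the entrywise mean of the per-subject
#' score matrices across all test-fold evaluations (and runs, when score
#' matrices from several runs are supplied).
#'
#' @param per_subject_S list of n x n edge score matrices.
#' @return n x n mean score matrix.
#' @export
aggregate_edge_scores <- function(per_subject_S) {
  if (length(per_subject_S) < 1L) stopf("need at least one score matrix")
  d <- dim(per_subject_S[[1]])
  for (S in per_subject_S)
    if (!all(dim(S) == d)) stopf("edge score matrices differ in shape")
  Reduce(`+`, per_subject_S) / length(per_subject_S)
}

#' Rank the top-k connections by mean edge score
#'
#' All n^2 directed cells are candidates (the LR and RL blocks are distinct
#' connections); `symmetric = TRUE` collapses (i, j) and (j, i) to their
#' average first.  Ties are broken by (row, column) index order.
#'
#' @param S_mean n x n mean score matrix (region labels in dimnames, if
#'   available).
#' @param k number of edges to report (the headline analysis uses 30).
#' @param labels optional region labels; defaults to `dimnames(S_mean)`.
#' @param symmetric collapse mirrored cells before ranking.
#' @return data.frame of class `fagnn_edge_ranking` with columns
#'   `region_i`, `region_j`, `quadrant`, `score`, in non-increasing score
#'   order.
#' @export
top_edges <- function(S_mean, k = 30L, labels = NULL, symmetric = FALSE) {
  if (!is_count(k)) stopf("k must be a positive integer")
  n <- nrow(S_mean)
  if (is.null(labels)) labels <- rownames(S_mean) %||% default_region_labels(n)
  if (symmetric) S_mean <- (S_mean + t(S_mean)) / 2
  idx <- expand.grid(i = seq_len(n), j = seq_len(n))
  if (symmetric) idx <- idx[idx$i <= idx$j, ]
  score <- S_mean[cbind(idx$i, idx$j)]
  if (k > nrow(idx)) stopf("k = %d exceeds the %d candidate edges", k, nrow(idx))
  # non-increasing score; ties resolved by row-major (i, j) order
  ord <- order(-score, idx$i, idx$j)[seq_len(k)]
  m <- n %/% 2L
  quadrant <- paste0(ifelse(idx$i[ord] <= m, "L", "R"),
                     ifelse(idx$j[ord] <= m, "L", "R"))
  out <- data.frame(region_i = labels[idx$i[ord]],
                    region_j = labels[idx$j[ord]],
                    i = idx$i[ord], j = idx$j[ord],
                    quadrant = quadrant, score = score[ord],
                    stringsAsFactors = FALSE)
  class(out) <- c("fagnn_edge_ranking", "data.frame")
  out
}

#' Brain age delta
#'
#' `delta = predicted - chronological` (days); positive values indicate
#' accelerated brain aging.
#'
#' @param predicted,chronological equal-length age vectors in days.
#' @return numeric vector of deltas.
#' @export
brain_age_delta <- function(predicted, chronological) {
  if (length(predicted) != length(chronological))
    stopf("length mismatch: %d predicted vs %d chronological",
          length(predicted), length(chronological))
  predicted - chronological
}

#' Compare brain-age deltas between trait groups within age strata
#'
#' Within each age group (a 15-month cutoff by convention), deltas of the
#' two trait groups are compared with a group-indicator linear model
#' (equivalent to a two-sample t-test); two-sided p-values, significance
#' flagged at p < 0.05 with no cross-panel correction.
#'
#' @param deltas numeric vector of brain-age deltas (days).
#' @param group_labels two-level factor/vector (e.g. control vs high-fat).
#' @param age_group_labels age-stratum labels (e.g. "younger"/"old").
#' @param alpha significance threshold (default 0.05).
#' @return data.frame with one row per age stratum: group means, the
#'   difference estimate, t statistic, p-value, and `significant` flag.
#' @export
compare_delta_groups <- function(deltas, group_labels, age_group_labels,
                                 alpha = 0.05) {
  if (length(deltas) != length(group_labels) ||
      length(deltas) != length(age_group_labels))
    stopf("deltas, group_labels, age_group_labels must share length")
  if (any(!is.finite(deltas))) stopf("non-finite delta")
  rows <- list()
  for (ag in unique(age_group_labels)) {
    sel <- age_group_labels == ag
    g <- factor(group_labels[sel])
    if (nlevels(g) != 2L)
      stopf("age stratum '%s' does not have exactly 2 groups", ag)
    if (any(table(g) < 2L))
      stopf("age stratum '%s' has a group with fewer than 2 subjects", ag)
    fit <- lm(deltas[sel] ~ g)
    sm <- summary(fit)$coefficients
    est <- sm[2, "Estimate"]
    tstat <- sm[2, "t value"]
    p <- sm[2, "Pr(>|t|)"]
    rows[[ag]] <- data.frame(
      age_group = ag,
      group_ref = levels(g)[1], group_alt = levels(g)[2],
      mean_ref = mean(deltas[sel][g == levels(g)[1]]),
      mean_alt = mean(deltas[sel][g == levels(g)[2]]),
      estimate = est, statistic = tstat, p_value = p,
      significant = is.finite(p) && p < alpha,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export an edge ranking as CSV
#'
#' @param ranking a [top_edges()] result; `path` output file.
#' @return `path`, invisibly.
#' @export
export_edge_ranking <- function(ranking, path) {
  write.csv(ranking[, c("region_i", "region_j", "quadrant", "score")],
            path, row.names = FALSE)
  invisible(path)
}
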