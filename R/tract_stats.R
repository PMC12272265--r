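# Along-tract statistical validation battery.
#
# Diffusion metrics (FA, RTOP, RTAP, RTPP) sampled at ordered positions
# along a tract's streamlines are compared between groups with the
# nonparametric chain: Kruskal-Wallis omnibus test (tie-corrected), Dunn's
# rank-based post hoc pairwise z tests, and Holm step-down adjustment of
# the pairwise p-values to control the familywise error rate.  The tests
# are implemented from the rank formulas and validated against independent
# oracles in the test suite.

#' Per-position group summary of tract profiles
#'
#' @param profiles numeric matrix, streamlines x positions (one group's
#'   profiles), or a list of such row vectors.
#' @return data.frame with `position`, `mean`, `sd` (dispersion band).
#' @export
summarize_profile <- function(profiles) {
  if (is.list(profiles)) profiles <- do.call(rbind, profiles)
  if (!is.matrix(profiles)) profiles <- matrix(profiles, nrow = 1)
  if (nrow(profiles) < 1L) stopf("empty profile group")
  data.frame(position = seq_len(ncol(profiles)),
             mean = colMeans(profiles),
             sd = apply(profiles, 2, function(v)
               if (length(v) > 1L) sd(v) else 0))
}

# pooled dense midranks and the tie-correction term sum(t^3 - t)
pooled_ranks <- function(values) {
  r <- rank(values, ties.method = "average")
  tie_sizes <- table(values)
  list(r = r, tie_term = sum(tie_sizes^3 - tie_sizes))
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H statistic with a chi-square reference distribution on
#' `length(groups) - 1` degrees of freedom.  Degenerate all-tied input
#' yields `H = 0`, `p = 1`.
#'
#' @param groups list of numeric samples (at least 2 groups, total N >= 3).
#' @return list with `H`, `p`, `df`.
#' @examples
#' kruskal_wallis(list(c(1, 2), c(3, 4)))  # H = 2.4
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stopf("need at least two groups")
  sizes <- lengths(groups)
  if (any(sizes == 0L)) stopf("empty group")
  N <- sum(sizes)
  if (N < 3L) stopf("need a total of at least 3 observations")
  pooled <- unlist(groups, use.names = FALSE)
  pr <- pooled_ranks(pooled)
  g <- rep(seq_along(groups), sizes)
  Rj <- tapply(pr$r, g, sum)
  H <- 12 / (N * (N + 1)) * sum(Rj^2 / sizes) - 3 * (N + 1)
  correction <- 1 - pr$tie_term / (N^3 - N)
  if (correction <= 0) {            # all observations tied
    H <- 0
  } else {
    H <- H / correction
  }
  df <- length(groups) - 1L
  p <- if (H == 0) 1 else pchisq(H, df = df, lower.tail = FALSE)
  list(H = unname(H), p = unname(p), df = df)
}

#' Dunn's post hoc pairwise rank comparisons
#'
#' Pairwise z statistics from mean-rank differences on the pooled ranking,
#' standardized with the tie-corrected variance
#' `(N(N+1)/12 - T/(12(N-1))) (1/ni + 1/nj)`; two-sided normal p-values.
#'
#' @param groups named list of numeric samples.
#' @return data.frame with `group_i`, `group_j`, `z`, `p` (raw).
#' @export
dunn_posthoc <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stopf("need at least two groups")
  sizes <- lengths(groups)
  if (any(sizes == 0L)) stopf("empty group")
  nm <- names(groups) %||% paste0("g", seq_along(groups))
  N <- sum(sizes)
  pr <- pooled_ranks(unlist(groups, use.names = FALSE))
  g <- rep(seq_along(groups), sizes)
  mean_rank <- tapply(pr$r, g, mean)
  var_base <- N * (N + 1) / 12 - pr$tie_term / (12 * (N - 1))
  pairs <- utils::combn(seq_along(groups), 2)
  rows <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    se <- sqrt(var_base * (1 / sizes[i] + 1 / sizes[j]))
    z <- if (se == 0) 0 else (mean_rank[i] - mean_rank[j]) / se
    data.frame(group_i = nm[i], group_j = nm[j], z = unname(z),
               p = unname(2 * pnorm(-abs(z))), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Holm step-down p-value adjustment
#'
#' Sort ascending, multiply the i-th smallest by `(m - i + 1)`, enforce
#' monotonicity with a running maximum, cap at 1, and restore the original
#' order.  Adjusted values always dominate the raw ones.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return adjusted vector, same order as the input.
#' @examples
#' holm_adjust(c(0.01, 0.04))  # 0.02, 0.04
#' @export
holm_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1 | !is.finite(p_values)))
    stopf("p-values must lie in [0, 1]")
  m <- length(p_values)
  if (m <= 1L) return(p_values)
  o <- order(p_values)
  adj <- pmin(cummax(p_values[o] * (m - seq_len(m) + 1L)), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Full group-comparison chain for one sample collection
#'
#' Kruskal-Wallis omnibus, then Dunn's pairwise tests with Holm-adjusted
#' p-values; a `p < 0.01` label flag mirrors the along-tract figure
#' convention.
#'
#' @param groups named list of numeric samples.
#' @return list of class `fagnn_group_comparison` with `omnibus` (H, p) and
#'   `pairwise` (z, raw and adjusted p, significance flags).
#' @export
kw_dunn_holm <- function(groups) {
  omnibus <- kruskal_wallis(groups)
  pw <- dunn_posthoc(groups)
  pw$p_adj <- holm_adjust(pw$p)
  pw$sig_05 <- pw$p_adj < 0.05
  pw$sig_01 <- pw$p_adj < 0.01
  structure(list(omnibus = omnibus, pairwise = pw),
            class = "fagnn_group_comparison")
}

#' Read along-tract profiles from CSV
#'
#' Expected columns: `tract`, `subject`, `group`, `position`, `value`
#' (`tract` optional for single-tract files).
#'
#' @param path CSV file path.
#' @return data.frame with those columns (tract filled with "tract1" when
#'   absent).
#' @export
read_tract_profiles <- function(path) {
  if (!file.exists(path)) stopf("profile CSV '%s' not found", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "group", "position", "value")
  if (!all(need %in% names(df)))
    stopf("tract profile CSV must have columns %s",
          paste(need, collapse = ", "))
  if (!"tract" %in% names(df)) df$tract <- "tract1"
  if (any(!is.finite(df$value)))
    stopf("non-finite metric value at line %d",
          which(!is.finite(df$value))[1] + 1L)
  df
}

#' Per-tract group comparison report
#'
#' Applies the Kruskal-Wallis / Dunn / Holm chain to every tract in a
#' profile table, pooling each subject's streamline values.  Holm
#' adjustment is within tract by default; `adjust_across = TRUE` adjusts
#' the pairwise p-values jointly across all tracts.
#'
#' @param profiles data.frame from [read_tract_profiles()].
#' @param adjust_across adjust Holm across tracts jointly.
#' @return data.frame with one row per tract and group pair: H, z, raw and
#'   adjusted p.
#' @export
tract_group_report <- function(profiles, adjust_across = FALSE) {
  rows <- list()
  for (tr in unique(profiles$tract)) {
    sub <- profiles[profiles$tract == tr, ]
    groups <- split(sub$value, sub$group)
    om <- kruskal_wallis(groups)
    pw <- dunn_posthoc(groups)
    pw$tract <- tr
    pw$H <- om$H
    pw$H_p <- om$p
    rows[[tr]] <- pw
  }
  out <- do.call(rbind, rows)
  out$p_adj <- if (adjust_across) holm_adjust(out$p)
               else unlist(lapply(rows, function(r) holm_adjust(r$p)))
  out$sig_05 <- out$p_adj < 0.05
  out$sig_01 <- out$p_adj < 0.01
  rownames(out) <- NULL
  out[, c("tract", "group_i", "group_j", "H", "H_p", "z", "p", "p_adj",
          "sig_05", "sig_01")]
}
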