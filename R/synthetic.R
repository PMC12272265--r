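# Synthetic aging-cohort simulator.
#
# Generates cohorts with the statistical structure the model assumes —
# a bimodal age distribution (younger 12-15 months, old 15-20 months, with
# the 15-month cutoff at 450 days under a 30-day month), trait margins
# mirroring the reference cohort, an "effective brain age" latent variable
# modulated by the risk traits, hub-attached planted edges whose weights
# decay linearly with effective brain age, and behavior metrics that are
# monotone in effective brain age — plus the ground truth needed for
# recovery tests.

#' Simulator configuration
#'
#' Defaults mirror the reference cohort margins: N = 170 with 66 younger /
#' 104 old; APOE2/3/4 = 58/56/56; 82 male / 88 female; 95 mNos2 / 75 hNOS2;
#' 113 control / 57 high-fat diet.  Trait counts are assigned per age
#' cluster (the young-cluster mNos2 count is 28 so the margins total
#' correctly).  Risk effects are additive days on the effective brain age:
#' diet and NOS2 act only in the old cluster, sex only in the young one,
#' matching the significance pattern the model is expected to recover.
#'
#' @param N cohort size.
#' @param n_regions even region count (desk-scale default 32; a full
#'   mouse atlas has several hundred regions).
#' @param young_mean,young_sd,old_mean,old_sd age cluster parameters (days);
#'   clusters are truncated to [365, 449] and [451, 600].
#' @param diet_effect,nos2_effect,sex_effect,apoe_effect trait accelerations
#'   in days (APOE defaults to 0: no APOE delta effect is planted).
#' @param subject_noise_sd residual effective-brain-age noise (days).
#' @param planted_edges number of planted hub edges (even; half per
#'   hemisphere, mirrored).
#' @param decay_frac fractional weight loss of a planted edge across the
#'   full effective-age span.
#' @param plant_base baseline weight of planted edges (streamline-count
#'   scale).
#' @param conn_noise_sd additive connectome noise SD.
#' @param behavior_trials,behavior_metrics behavior matrix shape (Morris
#'   Water Maze style: trials chronological, 2 time metrics + 3 others).
#' @param behavior_noise_sd behavior noise SD on the [0, 1] scale.
#' @param seed RNG seed.
#' @return object of class `fagnn_sim_config`
#' @export
sim_config <- function(N = 170L, n_regions = 32L,
                       young_mean = 405, young_sd = 20,
                       old_mean = 525, old_sd = 35,
                       diet_effect = 40, nos2_effect = 40,
                       sex_effect = 30, apoe_effect = 0,
                       subject_noise_sd = 15,
                       planted_edges = 8L, decay_frac = 0.6,
                       plant_base = 60, conn_noise_sd = 2,
                       behavior_trials = 8L, behavior_metrics = 5L,
                       behavior_noise_sd = 0.05, seed = 1L) {
  if (n_regions %% 2L != 0L || n_regions < 8L)
    stopf("n_regions must be even and at least 8")
  if (planted_edges %% 2L != 0L)
    stopf("planted_edges must be even (edges are mirrored across hemispheres)")
  if (planted_edges / 2L + 1L > n_regions %/% 2L)
    stopf("too many planted edges for %d regions", n_regions)
  if (N < 4L) stopf("N must be at least 4")
  structure(as.list(environment()), class = "fagnn_sim_config")
}

# truncated normal draws by inverse-CDF so seeds stay deterministic
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

# assign a binary/ternary trait to exact per-cluster counts, shuffled
assign_counts <- function(n, counts, values) {
  if (any(counts < 0) || sum(counts) != n)
    stopf("infeasible trait margins: counts %s for cluster of %d",
          paste(counts, collapse = "/"), n)
  v <- rep(values, counts)
  v[sample.int(length(v))]
}

#' Simulate a cohort with planted ground truth
#'
#' @param cfg a [sim_config()].
#' @return list with `cohort` (a normalized [cohort()], raw matrices
#'   retained) and `truth` (planted edge indices, per-subject effective
#'   brain age, effect sizes, age-group labels).
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  N <- cfg$N; n <- cfg$n_regions; m <- n %/% 2L
  n_young <- round(N * 66 / 170)
  n_old <- N - n_young

  ages <- c(rtrunc_norm(n_young, cfg$young_mean, cfg$young_sd, 365, 449),
            rtrunc_norm(n_old, cfg$old_mean, cfg$old_sd, 451, 600))
  age_group <- rep(c("younger", "old"), c(n_young, n_old))

  scale_counts <- function(counts, total, size) {
    k <- round(counts * size / total)
    k[1] <- k[1] + (size - sum(k))     # absorb rounding in the first level
    k
  }
  # per-cluster margins (younger row / old row of the cohort table)
  apoe <- c(assign_counts(n_young, scale_counts(c(17, 24, 25), 66, n_young),
                          c(0, 0.5, 1)),
            assign_counts(n_old, scale_counts(c(41, 32, 31), 104, n_old),
                          c(0, 0.5, 1)))
  diet <- c(assign_counts(n_young, scale_counts(c(33, 33), 66, n_young),
                          c(0, 1)),
            assign_counts(n_old, scale_counts(c(80, 24), 104, n_old),
                          c(0, 1)))
  nos2 <- c(assign_counts(n_young, scale_counts(c(28, 38), 66, n_young),
                          c(0, 1)),
            assign_counts(n_old, scale_counts(c(67, 37), 104, n_old),
                          c(0, 1)))
  sex <- c(assign_counts(n_young, scale_counts(c(32, 34), 66, n_young),
                         c(0, 1)),
           assign_counts(n_old, scale_counts(c(50, 54), 104, n_old),
                         c(0, 1)))

  is_old <- age_group == "old"
  eff_age <- ages +
    cfg$diet_effect * diet * is_old +
    cfg$nos2_effect * nos2 * is_old +
    cfg$sex_effect * sex * !is_old +
    cfg$apoe_effect * apoe +
    rnorm(N, 0, cfg$subject_noise_sd)

  # hub nodes (one per hemisphere) with elevated baseline connectivity;
  # each subject draws its own symmetric gamma connectome, so between-
  # subject variability matches the biological spread of streamline counts
  hub <- c(1L, m + 1L)
  ut <- upper.tri(matrix(0, n, n))
  k_half <- cfg$planted_edges %/% 2L
  partners <- 1L + seq_len(k_half)
  planted <- rbind(
    data.frame(i = rep(hub[1], k_half), j = partners),
    data.frame(i = rep(hub[2], k_half), j = m + partners))

  # effective-age position on [0, 1] used by the decay and behavior maps
  age01 <- pmin(pmax((eff_age - 350) / 330, 0), 1)

  atlas <- region_atlas(default_region_labels(n))
  behav_kinds <- c(rep("time", 2L),
                   rep("other", cfg$behavior_metrics - 2L))
  trial_fac <- seq(1, 0.6, length.out = cfg$behavior_trials)  # learning

  raw_conn <- vector("list", N)
  raw_behav <- vector("list", N)
  for (s in seq_len(N)) {
    W <- matrix(0, n, n)
    W[ut] <- rgamma(sum(ut), shape = 2, rate = 0.2)
    W <- W + t(W)
    W[hub, ] <- W[hub, ] * 3
    W[, hub] <- W[, hub] * 3
    E <- matrix(0, n, n)
    E[ut] <- rnorm(sum(ut), 0, cfg$conn_noise_sd)
    W <- pmax(W + E + t(E), 0)
    w_pl <- cfg$plant_base * (1 - cfg$decay_frac * age01[s]) +
      rnorm(nrow(planted), 0, cfg$conn_noise_sd)
    for (e in seq_len(nrow(planted))) {
      w <- max(w_pl[e], 0)
      W[planted$i[e], planted$j[e]] <- w
      W[planted$j[e], planted$i[e]] <- w
    }
    diag(W) <- 0
    raw_conn[[s]] <- W

    sat <- age01[s] / (0.4 + age01[s])      # saturating aging map
    B <- matrix(0, cfg$behavior_trials, cfg$behavior_metrics)
    for (j in seq_len(cfg$behavior_metrics)) {
      slope <- c(0.55, 0.5, 0.45, -0.4, -0.45)[(j - 1L) %% 5L + 1L]
      base <- c(0.2, 0.25, 0.3, 0.7, 0.75)[(j - 1L) %% 5L + 1L]
      v <- base + slope * sat + 0.15 * trial_fac +
        rnorm(cfg$behavior_trials, 0, cfg$behavior_noise_sd)
      v <- pmin(pmax(v, 0), 1)
      B[, j] <- if (behav_kinds[j] == "time") v * 60 else v * 30
    }
    colnames(B) <- c("time_platform", "time_quadrant",
                     paste0("metric", seq_len(cfg$behavior_metrics - 2L)))
    raw_behav[[s]] <- B
  }

  col_max <- apply(do.call(rbind, raw_behav), 2, max)
  trait_dict <- default_trait_dict()
  subjects <- vector("list", N)
  for (s in seq_len(N)) {
    conn <- rank_normalize_connectome(connectome(raw_conn[[s]], atlas))
    conn$raw <- raw_conn[[s]]
    behav <- normalize_behavior(raw_behav[[s]], behav_kinds, col_max)
    traits <- c(sex = sex[s], diet = diet[s], apoe = apoe[s], nos2 = nos2[s])
    subjects[[s]] <- subject(sprintf("m%03d", s), ages[s], traits, behav,
                             conn)
    subjects[[s]]$raw_behavior <- raw_behav[[s]]
  }
  ch <- cohort(subjects, atlas)
  truth <- list(
    planted_edges = planted, hub = hub,
    effective_age = eff_age, age_group = age_group,
    effects = c(diet = cfg$diet_effect, nos2 = cfg$nos2_effect,
                sex = cfg$sex_effect, apoe = cfg$apoe_effect),
    config = cfg)
  list(cohort = ch, truth = truth)
}

#' Recovery of planted edges from an edge ranking
#'
#' A planted (undirected) edge contributes both of its directed cells; the
#' recall is the fraction of planted cells inside the top `top_fraction` of
#' the ranking, so a random ranking recovers `top_fraction` in expectation.
#'
#' @param ranking a full [top_edges()] ranking (k = all candidate cells)
#'   with `i`, `j` index columns.
#' @param truth ground truth from [simulate_cohort()].
#' @param top_fraction fraction of the ranking counted as "top".
#' @return list with `recall`, `mean_rank` (normalized to (0, 1]), and the
#'   planted cells' ranks.
#' @export
planted_edge_recovery <- function(ranking, truth, top_fraction) {
  pe <- truth$planted_edges
  if (is.null(pe) || nrow(pe) == 0L) stopf("empty planted edge set")
  cells <- rbind(pe, data.frame(i = pe$j, j = pe$i))
  key <- paste(ranking$i, ranking$j)
  pos <- match(paste(cells$i, cells$j), key)
  if (any(is.na(pos)))
    stopf("ranking does not cover all planted cells; rank all n^2 edges")
  top_n <- floor(top_fraction * nrow(ranking))
  list(recall = mean(pos <= top_n),
       mean_rank = mean(pos) / nrow(ranking),
       ranks = sort(pos))
}

#' Simulate along-tract metric profiles for two age groups
#'
#' Smooth per-position mean curves with streamline-level noise; `effect`
#' shifts the old group downward (FA-like decline).  `effect = 0` gives a
#' null configuration for calibration studies.
#'
#' @param n_per_group streamlines per group; `P` positions along the tract.
#' @param effect mean group difference (metric units).
#' @param noise_sd streamline noise SD.
#' @param seed RNG seed.
#' @return data.frame with `tract`, `subject`, `group`, `position`, `value`.
#' @export
simulate_tract_profiles <- function(n_per_group = 20L, P = 25L,
                                    effect = 0.05, noise_sd = 0.04,
                                    seed = 1L) {
  set.seed(seed)
  base <- 0.45 + 0.1 * sin(seq(0, pi, length.out = P))
  rows <- list()
  for (g in c("younger", "old")) {
    shift <- if (g == "old") -effect else 0
    for (s in seq_len(n_per_group)) {
      v <- base + shift + rnorm(P, 0, noise_sd)
      rows[[paste(g, s)]] <- data.frame(
        tract = "sim_tract", subject = sprintf("%s_%02d", g, s), group = g,
        position = seq_len(P), value = pmin(pmax(v, 0), 1),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
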