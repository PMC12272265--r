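# Shared fixtures, all built in code.

tiny_atlas <- function(n = 4L) region_atlas(fagnn:::default_region_labels(n))

# a minimal hand-built normalized cohort (n regions, N subjects)
make_tiny_cohort <- function(N = 4L, n = 4L, seed = 42L) {
  set.seed(seed)
  atlas <- tiny_atlas(n)
  subs <- lapply(seq_len(N), function(s) {
    W <- matrix(runif(n * n, 0, 20), n, n)
    W <- (W + t(W)) / 2
    diag(W) <- 0
    conn <- rank_normalize_connectome(connectome(W, atlas))
    conn$raw <- W
    behav <- matrix(runif(8L * 5L, 0, 1), 8L, 5L)
    colnames(behav) <- c("time_a", "time_b", "m1", "m2", "m3")
    sub <- subject(sprintf("t%02d", s), 360 + 40 * s,
                   c(sex = s %% 2, diet = (s %/% 2) %% 2, apoe = 0.5,
                     nos2 = 0),
                   behav, conn)
    sub$raw_behavior <- behav
    sub
  })
  fagnn:::new_cohort(subs, atlas)
}

# small simulated cohort used by several training tests
small_sim <- function(N = 16L, n = 8L, seed = 7L, ...) {
  simulate_cohort(sim_config(N = N, n_regions = n, planted_edges = 4L,
                             seed = seed, ...))
}

fast_train_config <- function(epochs = 5L, seed = 1L, ...) {
  train_config(epochs = epochs, seed = seed, ...)
}

expect_matrix_equal <- function(a, b, tol = 1e-12) {
  expect_lt(max(abs(a - b)), tol)
}

# JSON config for small CLI simulations
write_sim_config <- function(N = 8L, n_regions = 12L, planted_edges = 4L) {
  path <- withr::local_tempfile(fileext = ".json",
                                .local_envir = parent.frame())
  jsonlite::write_json(list(N = N, n_regions = n_regions,
                            planted_edges = planted_edges),
                       path, auto_unbox = TRUE)
  path
}
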