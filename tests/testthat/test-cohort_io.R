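test_that("rank normalization matches the dense-rank worked example", {
  out <- rank_normalize_connectome(matrix(c(0, 5, 5, 2), 2, byrow = TRUE))
  expect_equal(out, matrix(c(0, 1, 1, 0.5), 2, byrow = TRUE))
})

test_that("rank normalization degenerate and permutation cases", {
  expect_equal(rank_normalize_connectome(matrix(0, 3, 3)), matrix(0, 3, 3))
  # n^2 distinct values -> entries are a permutation of {0, 1/(n^2-1), .., 1}
  set.seed(1)
  m <- matrix(sample(seq_len(16)), 4, 4)
  out <- rank_normalize_connectome(m)
  expect_equal(sort(as.vector(out)), seq(0, 1, length.out = 16))
  # oracle: argsort of unique values
  u <- sort(unique(as.vector(m)))
  oracle <- matrix((match(as.vector(m), u) - 1) / (length(u) - 1), 4, 4)
  expect_equal(unname(out), oracle)
})

test_that("rank normalization is invariant to strictly monotone transforms", {
  set.seed(2)
  for (rep in 1:5) {
    m <- matrix(rpois(36, 40), 6, 6)
    a <- rank_normalize_connectome(m)
    expect_equal(a, rank_normalize_connectome(sqrt(m) + 3))
    expect_equal(a, rank_normalize_connectome(m^3))
  }
  expect_error(rank_normalize_connectome(matrix(c(-1, 0, 0, 1), 2)),
               "negative")
})

test_that("trait encoding follows the documented scaling", {
  expect_equal(unname(encode_traits("M", "HFD", "APOE4", "hNOS2")),
               c(0, 1, 1, 1))
  expect_equal(encode_traits("F", "CTRL", "APOE3", "mNos2")[["apoe"]], 0.5)
  expect_equal(encode_traits("F", "CTRL", "APOE2", "mNos2")[["apoe"]], 0)
  expect_equal(encode_traits("F", "CTRL", "APOE2", "mNos2")[["diet"]], 0)
  expect_error(encode_traits("F", "CTRL", "APOE5", "mNos2"), "APOE2")
  expect_error(encode_traits("X", "CTRL", "APOE2", "mNos2"), "sex")
})

test_that("trait encoding is a bijection on the permitted label set", {
  combos <- expand.grid(sex = c("M", "F"), diet = c("CTRL", "HFD"),
                        apoe = c("APOE2", "APOE3", "APOE4"),
                        nos2 = c("mNos2", "hNOS2"),
                        stringsAsFactors = FALSE)
  codes <- apply(combos, 1, function(r)
    paste(encode_traits(r[["sex"]], r[["diet"]], r[["apoe"]], r[["nos2"]]),
          collapse = "/"))
  expect_equal(length(unique(codes)), nrow(combos))
})

test_that("behavior normalization scales time by 60 and others by maxima", {
  raw <- cbind(time = c(30, 60), dist = c(2, 4))
  out <- normalize_behavior(raw, c("time", "other"))
  expect_equal(unname(out[, 1]), c(0.5, 1.0))
  expect_equal(unname(out[, 2]), c(0.5, 1.0))
  # cohort-level maxima
  out2 <- normalize_behavior(raw, c("time", "other"), col_max = c(NA, 8))
  expect_equal(unname(out2[, 2]), c(0.25, 0.5))
  expect_error(normalize_behavior(cbind(c(61, 10)), "time"), "60")
  # all-zero non-time column left untouched
  out3 <- normalize_behavior(cbind(a = c(0, 0)), "other")
  expect_equal(unname(out3[, 1]), c(0, 0))
})

test_that("cohort CSV round trip preserves data and validates", {
  ch <- make_tiny_cohort(N = 3)
  dir <- withr::local_tempdir()
  write_cohort(ch, dir)
  back <- read_cohort(file.path(dir, "metadata.csv"),
                      file.path(dir, "connectomes"),
                      file.path(dir, "behavior"))
  expect_equal(length(back$subjects), 3L)
  expect_equal(back$atlas$region_labels, ch$atlas$region_labels)
  for (i in 1:3) {
    expect_equal(back$subjects[[i]]$id, ch$subjects[[i]]$id)
    expect_equal(back$subjects[[i]]$age_days, ch$subjects[[i]]$age_days)
    expect_equal(unname(back$subjects[[i]]$connectome$matrix),
                 unname(ch$subjects[[i]]$connectome$matrix))
    expect_equal(back$subjects[[i]]$traits, ch$subjects[[i]]$traits)
  }
  expect_equal(nrow(validate_cohort(back)), 0L)
})

test_that("read_cohort reports missing and malformed files by id", {
  ch <- make_tiny_cohort(N = 2)
  dir <- withr::local_tempdir()
  write_cohort(ch, dir)
  meta <- read.csv(file.path(dir, "metadata.csv"))
  meta <- rbind(meta, data.frame(id = "m3", age_days = 400, sex = "M",
                                 diet = "CTRL", apoe = "APOE2",
                                 nos2 = "mNos2"))
  write.csv(meta, file.path(dir, "metadata.csv"), row.names = FALSE)
  expect_error(read_cohort(file.path(dir, "metadata.csv"),
                           file.path(dir, "connectomes"),
                           file.path(dir, "behavior")), "m3")
  # non-square connectome
  bad <- as.data.frame(matrix(1, 3, 4))
  rownames(bad) <- c("L01", "L02", "R01")
  write.csv(bad, file.path(dir, "connectomes", "m3.csv"))
  write.csv(ch$subjects[[1]]$raw_behavior,
            file.path(dir, "behavior", "m3.csv"), row.names = FALSE)
  expect_error(read_cohort(file.path(dir, "metadata.csv"),
                           file.path(dir, "connectomes"),
                           file.path(dir, "behavior")), "non-square")
})

test_that("validate_cohort reports violations without throwing", {
  ch <- make_tiny_cohort(N = 3)
  expect_equal(nrow(validate_cohort(ch)), 0L)
  bad <- ch
  bad$subjects[[2]]$age_days <- -1
  rep <- validate_cohort(bad)
  expect_true(any(rep$subject == "t02" & rep$field == "age_days"))
  bad2 <- ch
  bad2$subjects[[1]]$behavior <- bad2$subjects[[1]]$behavior[1:3, ]
  expect_true(any(validate_cohort(bad2)$field == "behavior"))
})

test_that("normalized model inputs all lie in [0, 1]", {
  sim <- small_sim(N = 10, seed = 3)
  for (s in sim$cohort$subjects) {
    expect_true(all(s$connectome$matrix >= 0 & s$connectome$matrix <= 1))
    expect_true(all(s$traits >= 0 & s$traits <= 1))
    expect_true(all(s$behavior >= 0 & s$behavior <= 1))
  }
})
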