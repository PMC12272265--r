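test_that("gnn_layer matches direct matrix arithmetic", {
  # n=2, H=I, S=ones, D=I, W=I at level 1 -> ReLU(I + I) = 2I
  out <- gnn_layer(diag(2), matrix(1, 2, 2), 1L, diag(2), D = diag(2))
  expect_equal(out, 2 * diag(2))
  # negative weights are clipped by the ReLU
  out2 <- gnn_layer(diag(2), matrix(1, 2, 2), 1L, -diag(2), D = diag(2))
  expect_equal(out2, matrix(0, 2, 2))
  # deeper levels ignore S entirely
  set.seed(40)
  H <- matrix(runif(16), 4, 4); W <- matrix(rnorm(16), 4, 4)
  expect_equal(gnn_layer(H, matrix(1, 4, 4), 2L, W),
               gnn_layer(H, matrix(0, 4, 4), 2L, W))
})

test_that("gnn_layer at level 1 is monotone in S for nonnegative inputs", {
  set.seed(41)
  H <- matrix(runif(16), 4, 4); W <- matrix(runif(16), 4, 4)
  D <- diag(runif(4, 0.5, 2))
  S <- matrix(runif(16), 4, 4)
  base <- gnn_layer(H, S, 1L, W, D = D)
  for (rep in 1:10) {
    S2 <- S
    ij <- sample(16, 1)
    S2[ij] <- S2[ij] + runif(1, 0, 2)
    expect_true(all(gnn_layer(H, S2, 1L, W, D = D) >= base - 1e-12))
  }
})

test_that("topk_pool keeps the highest-scoring nodes with the tie rule", {
  H <- matrix(1:9, 3, 3)
  expect_equal(topk_pool(H, c(0.9, 0.1, 0.5), 2 / 3)$kept, c(1L, 3L))
  p <- topk_pool(H, c(0.2, 0.9, 0.5), 1)
  expect_equal(p$kept, 1:3)
  expect_equal(p$H, H)
  # ties resolved toward the lowest index
  expect_equal(topk_pool(H, c(0.5, 0.5, 0.1), 1 / 3)$kept, 1L)
  expect_error(topk_pool(H, c(NaN, 1, 2), 0.5), "NaN")
  expect_error(topk_pool(H, c(1, 2, 3), 0), "ratio")
})

test_that("1D CNN matches identity and sliding-window oracles", {
  # single 1x1 unit kernel, unit linear readout: passthrough of the mean
  w_id <- list(conv = list(list(W = array(1, c(1, 1, 1)), b = 0)),
               lin = list(W = matrix(1), b = 0))
  expect_equal(cnn1d_forward(c(0.2, 0.4), w_id), 0.3)
  expect_equal(cnn1d_forward(c(0, 0), w_id), 0)
  # seeded random weights vs an explicit double-loop oracle
  set.seed(42)
  t <- runif(4)
  w <- list(conv = list(
    list(W = array(rnorm(3 * 1 * 2), c(3, 1, 2)), b = rnorm(3)),
    list(W = array(rnorm(4 * 3 * 2), c(4, 3, 2)), b = rnorm(4))),
    lin = list(W = matrix(rnorm(8), 2, 4), b = rnorm(2)))
  out <- cnn1d_forward(t, w)
  y1 <- matrix(0, 3, 3)
  for (c1 in 1:3) for (i in 1:3)
    y1[c1, i] <- max(w$conv[[1]]$b[c1] + sum(w$conv[[1]]$W[c1, 1, ] *
                                               t[i:(i + 1)]), 0)
  y2 <- matrix(0, 4, 2)
  for (c2 in 1:4) for (i in 1:2)
    y2[c2, i] <- max(w$conv[[2]]$b[c2] +
                       sum(w$conv[[2]]$W[c2, , ] * y1[, i:(i + 1)]), 0)
  oracle <- as.numeric(w$lin$W %*% rowMeans(y2) + w$lin$b)
  expect_equal(out, oracle, tolerance = 1e-12)
  expect_error(cnn1d_forward(c(0.5, 1.5), w_id), "\\[0, 1\\]")
})

test_that("2D CNN matches identity and sliding-window oracles", {
  w_id <- list(conv = list(list(W = array(1, c(1, 1, 1, 1)), b = 0)),
               lin = list(W = matrix(1), b = 0))
  B <- matrix(c(0.1, 0.3, 0.5, 0.7), 2, 2)
  expect_equal(cnn2d_forward(B, w_id), mean(B))
  expect_equal(cnn2d_forward(matrix(0, 3, 3), w_id), 0)
  set.seed(43)
  B <- matrix(runif(30), 6, 5)
  w <- list(conv = list(
    list(W = array(rnorm(2 * 1 * 3 * 3), c(2, 1, 3, 3)), b = rnorm(2)),
    list(W = array(rnorm(3 * 2 * 3 * 3), c(3, 2, 3, 3)), b = rnorm(3))),
    lin = list(W = matrix(rnorm(6), 2, 3), b = rnorm(2)))
  out <- cnn2d_forward(B, w)
  y1 <- array(0, c(2, 4, 3))
  for (c1 in 1:2) for (i in 1:4) for (j in 1:3)
    y1[c1, i, j] <- max(w$conv[[1]]$b[c1] +
      sum(w$conv[[1]]$W[c1, 1, , ] * B[i:(i + 2), j:(j + 2)]), 0)
  y2 <- array(0, c(3, 2, 1))
  for (c2 in 1:3) for (i in 1:2) for (j in 1:1)
    y2[c2, i, j] <- max(w$conv[[2]]$b[c2] +
      sum(w$conv[[2]]$W[c2, , , ] * y1[, i:(i + 2), j:(j + 2)]), 0)
  oracle <- as.numeric(w$lin$W %*% apply(y2, 1, mean) + w$lin$b)
  expect_equal(out, oracle, tolerance = 1e-9)
})

test_that("fusion MLP obeys shape, constant, and dot-product laws", {
  mlp1 <- list(list(W = matrix(0, 1, 3), b = 42))
  expect_equal(fuse_predict(c(1, 2), 3, NULL, mlp1), 42)
  wv <- c(0.5, -1, 2)
  mlp2 <- list(list(W = matrix(wv, 1, 3), b = 1))
  expect_equal(fuse_predict(c(1, 2, 3), NULL, NULL, mlp2),
               sum(wv * c(1, 2, 3)) + 1)
  expect_error(fuse_predict(NULL, NULL, NULL, mlp1), "ablated")
})

test_that("compiled forward equals the pure-R reference forward", {
  sim <- small_sim(N = 6, seed = 9)
  m <- train_model(sim$cohort, fast_train_config(epochs = 3, seed = 2))
  data <- fagnn:::cohort_tensors(sim$cohort)
  p <- predict(m, sim$cohort)
  for (i in c(1L, 4L)) {
    fr <- fagnn_forward_r(m$weights, data$X[[i]], data$traits[i, ],
                          data$behavior[[i]])
    expect_equal(m$y_center + m$y_scale * fr$yhat, unname(p[i]),
                 tolerance = 1e-10)
  }
})

test_that("compiled gradients match finite differences", {
  sim <- small_sim(N = 4, seed = 5)
  data <- fagnn:::cohort_tensors(sim$cohort)
  acfg <- attention_config(h = 2L, dk = 2L)
  fcfg <- fusion_config(c1_channels = c(2L, 3L), c2_channels = c(2L, 3L),
                        embed_dim = 4L, mlp_hidden = c(8L, 4L))
  w <- init_fagnn_weights(8L, 4L, dim(data$behavior[[1]]), acfg, fcfg,
                          "full", seed = 11L)
  y <- data$y
  data$y <- (y - mean(y)) / sd(y)
  flags <- fagnn:::model_flags(w)
  gn <- fagnn:::param_group_names
  res <- fagnn:::fagnn_core(w[gn], data, flags, 0L, TRUE, FALSE)
  group_len <- vapply(gn, function(g)
    length(fagnn:::flatten_group(w[[g]])), integer(1))
  theta <- unlist(lapply(gn, function(g) fagnn:::flatten_group(w[[g]])))
  grad <- unlist(lapply(gn, function(g)
    fagnn:::flatten_group(res$grad[[g]])))
  lossfun <- function(th) {
    o <- 0L; w2 <- w
    for (g in gn) {
      if (group_len[[g]] == 0L) next
      w2[[g]] <- fagnn:::unflatten_group(
        w2[[g]], th[(o + 1L):(o + group_len[[g]])])
      o <- o + group_len[[g]]
    }
    fagnn:::fagnn_core(w2[gn], data, flags, 0L, FALSE, FALSE)$loss
  }
  set.seed(3)
  idx <- sort(sample(length(theta), 60))
  h <- 1e-5
  num <- vapply(idx, function(k) {
    tp <- theta; tp[k] <- tp[k] + h
    tm <- theta; tm[k] <- tm[k] - h
    (lossfun(tp) - lossfun(tm)) / (2 * h)
  }, 0)
  rel <- abs(num - grad[idx]) / pmax(1e-6, abs(num) + abs(grad[idx]))
  expect_lt(max(rel), 1e-3)
})

test_that("every hidden layer output is nonnegative", {
  sim <- small_sim(N = 4, seed = 6)
  data <- fagnn:::cohort_tensors(sim$cohort)
  w <- init_fagnn_weights(8L, 4L, dim(data$behavior[[1]]),
                          attention_config(h = 2L, dk = 2L),
                          fusion_config(), "full", seed = 2L)
  X <- data$X[[1]]
  S <- qam_edge_scores(X, w$qam, w$acfg)
  H1 <- gnn_layer(X, S, 1L, w$gnn$W1)
  expect_true(all(H1 >= 0))
  p1 <- topk_pool(H1, rowMeans(H1), 0.5)
  H2 <- gnn_layer(p1$H, NULL, 2L, w$gnn$W2)
  expect_true(all(H2 >= 0))
})

test_that("checkpoint round trip reproduces predictions bit-identically", {
  sim <- small_sim(N = 6, seed = 10)
  m <- train_model(sim$cohort, fast_train_config(epochs = 3, seed = 4))
  path <- withr::local_tempfile(fileext = ".rds")
  save_fagnn(m, path)
  m2 <- load_fagnn(path)
  expect_identical(predict(m, sim$cohort), predict(m2, sim$cohort))
})

test_that("ablated subnetworks make predictions independent of their input", {
  sim <- small_sim(N = 6, seed = 11)
  m <- train_model(sim$cohort, fast_train_config(epochs = 3, seed = 5,
                                                 ablation = "comp4"))
  p1 <- predict(m, sim$cohort)
  shuffled <- sim$cohort
  perm <- c(2:6, 1)
  for (i in seq_along(shuffled$subjects))
    shuffled$subjects[[i]]$behavior <- sim$cohort$subjects[[perm[i]]]$behavior
  expect_identical(unname(p1), unname(predict(m, shuffled)))
  # comp1 ignores traits too
  m1 <- train_model(sim$cohort, fast_train_config(epochs = 3, seed = 5,
                                                  ablation = "comp1"))
  q1 <- predict(m1, sim$cohort)
  sh2 <- sim$cohort
  for (i in seq_along(sh2$subjects))
    sh2$subjects[[i]]$traits <- sim$cohort$subjects[[perm[i]]]$traits
  expect_identical(unname(q1), unname(predict(m1, sh2)))
})
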