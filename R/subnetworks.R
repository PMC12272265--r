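# The three parallel subnetworks and their fusion.
#
# Graph branch: node features start as the connectome itself (H^(0) = X,
# rows = node features).  Layer update
#   H^(l+1) = ReLU[(I + H^(l) (.) S [l = 1]  +  H^(l) [l > 1]) D^(l) W^(l)],
# where D^(l) is the diagonal degree matrix of the current (score-weighted)
# adjacency (degrees = row sums; zero-degree isolated nodes get degree 1;
# an inverse-degree mode is available).  Each graph layer is followed by
# top-K pooling that keeps the highest-strength nodes.  Trait vectors pass
# through a 1D CNN, behavior matrices through a 2D CNN, and the three
# embeddings are concatenated into a small MLP that emits the predicted
# brain age.

#' One graph convolution layer
#'
#' At `level == 1` the adjacency is the edge-score-weighted connectome
#' `H * S`; deeper levels use `H` unweighted (the delta-function gating of
#' the update rule).
#'
#' @param H current node-feature matrix (k x k).
#' @param S edge score matrix (used only at `level == 1`; pass `NULL` or
#'   anything at deeper levels).
#' @param level layer index (1-based).
#' @param W k x k weight matrix.
#' @param D optional diagonal degree matrix; when `NULL` it is computed
#'   from the (weighted) adjacency with degrees the row sums and isolated
#'   nodes given degree 1 (an inverse-degree mode exists internally).
#' @return ReLU-activated next node-feature matrix.
#' @export
gnn_layer <- function(H, S, level, W, D = NULL) {
  A <- if (level == 1L) {
    if (is.null(S)) stopf("level-1 layer requires the edge score matrix S")
    apply_edge_scores(H, S)
  } else H
  k <- nrow(A)
  if (is.null(D)) D <- degree_normalizer(A)
  Z <- (diag(k) + A) %*% D %*% W
  pmax(Z, 0)
}

degree_normalizer <- function(A, inverse = FALSE) {
  d <- rowSums(A)
  d[d <= 0] <- 1
  diag(if (inverse) 1 / d else d, nrow = nrow(A))
}

#' Top-K node pooling
#'
#' Keeps `ceiling(ratio * k)` nodes with the highest scores; ties are broken
#' by the lowest node index.  Both the feature rows and the corresponding
#' columns are retained (node features are connectivity to kept nodes), so
#' the result is the induced subgraph on the kept nodes in original index
#' order.
#'
#' @param H k x k node-feature matrix.
#' @param node_scores length-k numeric scores.
#' @param ratio fraction of nodes to keep, in (0, 1].
#' @return list with `H` (reduced matrix) and `kept` (indices, ascending).
#' @export
topk_pool <- function(H, node_scores, ratio) {
  if (!(ratio > 0 && ratio <= 1)) stopf("ratio must be in (0, 1]")
  if (any(is.na(node_scores))) stopf("NaN node score")
  k <- length(node_scores)
  keep_n <- ceiling(ratio * k)
  # order(-scores, index) realizes the lowest-index tie rule
  kept <- sort(order(-node_scores, seq_len(k))[seq_len(keep_n)])
  list(H = H[kept, kept, drop = FALSE], kept = kept)
}

#' 1D CNN forward pass over the trait vector
#'
#' A stack of valid-mode 1D convolutions with ReLU:
#' `out[c, i] = ReLU(b[c] + sum_u W[c, ., u] . in[., i+u-1])`.
#'
#' @param t normalized trait vector (entries in `[0, 1]`).
#' @param w list of layers; each layer has `W` (out_ch x in_ch x kw array)
#'   and `b` (length out_ch).  A final `lin` layer (`W` e x ch, `b` length
#'   e) maps the position-averaged channels to the embedding.
#' @return embedding vector.
#' @export
cnn1d_forward <- function(t, w) {
  if (any(t < 0 | t > 1)) stopf("trait input outside [0, 1]")
  x <- matrix(t, nrow = 1)                       # channels x positions
  for (layer in w$conv) {
    W <- layer$W; b <- layer$b
    kw <- dim(W)[3]; oc <- dim(W)[1]
    tout <- ncol(x) - kw + 1L
    if (tout < 1L) stopf("1D input too short for kernel width %d", kw)
    y <- matrix(0, oc, tout)
    for (c2 in seq_len(oc)) for (i in seq_len(tout)) {
      acc <- b[c2]
      for (u in seq_len(kw)) acc <- acc + sum(W[c2, , u] * x[, i + u - 1L])
      y[c2, i] <- max(acc, 0)
    }
    x <- y
  }
  g <- rowMeans(x)                               # global average pool
  as.numeric(w$lin$W %*% g + w$lin$b)
}

#' 2D CNN forward pass over the behavior matrix
#'
#' Valid-mode 2D convolutions with ReLU, global average pooling, and a
#' linear embedding layer; mirrors [cnn1d_forward()] in two dimensions.
#'
#' @param b normalized trials x metrics matrix.
#' @param w layer list as in [cnn1d_forward()], with `W` arrays of shape
#'   out_ch x in_ch x kh x kw.
#' @return embedding vector.
#' @export
cnn2d_forward <- function(b, w) {
  if (any(b < 0 | b > 1)) stopf("behavior input outside [0, 1]")
  x <- array(b, dim = c(1, nrow(b), ncol(b)))    # channels x h x w
  for (layer in w$conv) {
    W <- layer$W; bias <- layer$b
    oc <- dim(W)[1]; kh <- dim(W)[3]; kw <- dim(W)[4]
    ho <- dim(x)[2] - kh + 1L; wo <- dim(x)[3] - kw + 1L
    if (ho < 1L || wo < 1L)
      stopf("2D input %dx%d too small for %dx%d kernel",
            dim(x)[2], dim(x)[3], kh, kw)
    y <- array(0, dim = c(oc, ho, wo))
    for (c2 in seq_len(oc)) for (i in seq_len(ho)) for (j in seq_len(wo)) {
      acc <- bias[c2]
      for (u in seq_len(kh)) for (v in seq_len(kw))
        acc <- acc + sum(W[c2, , u, v] * x[, i + u - 1L, j + v - 1L])
      y[c2, i, j] <- max(acc, 0)
    }
    x <- y
  }
  g <- apply(x, 1, mean)
  as.numeric(w$lin$W %*% g + w$lin$b)
}

#' Fuse subnetwork embeddings and predict age
#'
#' Concatenates the enabled embeddings and runs them through the fully
#' connected block (ReLU between hidden layers, linear scalar readout).
#'
#' @param gnn_out,c1_out,c2_out embedding vectors (`NULL` when the branch is
#'   ablated; at least one must be present).
#' @param mlp list of layers with `W` and `b`; the last layer has one row.
#' @return scalar predicted age.
#' @export
fuse_predict <- function(gnn_out, c1_out, c2_out, mlp) {
  f <- c(gnn_out, c1_out, c2_out)
  if (length(f) == 0L) stopf("all subnetworks ablated; nothing to fuse")
  nl <- length(mlp)
  for (i in seq_len(nl)) {
    f <- as.numeric(mlp[[i]]$W %*% f + mlp[[i]]$b)
    if (i < nl) f <- pmax(f, 0)
  }
  if (length(f) != 1L) stopf("fusion MLP must end in a scalar")
  f
}

# ---------------------------------------------------------------------------
# Full-model parameter initialization and the pure-R reference forward pass.
# The C++ training core uses the identical layout (see fagnn_pack_params).

#' Fusion / architecture configuration
#'
#' @param topk_ratio fraction of nodes kept by each pooling step.
#' @param degree_mode `"raw"` multiplies by the degree matrix D itself (the
#'   update rule as printed, amplifying well-connected nodes; zero-degree
#'   isolated nodes get degree 1), `"inverse"` uses the GCN-style
#'   random-walk normalizer 1/degree.
#' @param c1_channels,c2_channels channel plan of the two CNN stacks.
#' @param c1_kernel kernel width of the 1D stack; the 2D stack uses
#'   `c2_kernel` x `c2_kernel` kernels.
#' @param embed_dim width of the CNN embeddings.
#' @param mlp_hidden hidden widths of the fully connected block.
#' @return object of class `fagnn_fusion_config`
#' @export
fusion_config <- function(topk_ratio = 0.5, c1_channels = c(8L, 16L),
                          c1_kernel = 2L, c2_channels = c(8L, 16L),
                          c2_kernel = 3L, embed_dim = 32L,
                          mlp_hidden = c(64L, 16L), degree_mode = "raw") {
  if (!(topk_ratio > 0 && topk_ratio <= 1))
    stopf("topk_ratio must be in (0, 1]")
  if (!degree_mode %in% c("raw", "inverse"))
    stopf("degree_mode must be 'raw' or 'inverse'")
  structure(list(topk_ratio = topk_ratio, degree_mode = degree_mode,
                 c1_channels = as.integer(c1_channels),
                 c1_kernel = as.integer(c1_kernel),
                 c2_channels = as.integer(c2_channels),
                 c2_kernel = as.integer(c2_kernel),
                 embed_dim = as.integer(embed_dim),
                 mlp_hidden = as.integer(mlp_hidden)),
            class = "fagnn_fusion_config")
}

uinit_mat <- function(nin, nout) {
  lim <- 1 / sqrt(nin)
  matrix(runif(nin * nout, -lim, lim), nin, nout)
}

#' Initialize all learnable weights of the model
#'
#' @param n region count; `trait_len` trait vector length; `behavior_dim`
#'   `c(trials, metrics)`.
#' @param acfg an [attention_config()]; `fcfg` a [fusion_config()].
#' @param ablation one of `"full"`, `"comp1"` (GNN only, S = 1), `"comp2"`
#'   (QAM+GNN), `"comp3"` (QAM+GNN+behavior), `"comp4"` (QAM+GNN+traits).
#' @param seed RNG seed for reproducible initialization.
#' @return list of weight structures plus resolved dimensions.
#' @export
init_fagnn_weights <- function(n, trait_len = 4L, behavior_dim = c(8L, 5L),
                               acfg = attention_config(),
                               fcfg = fusion_config(),
                               ablation = "full", seed = 1L) {
  set.seed(seed)
  if (is.null(acfg$dk)) acfg$dk <- max(1L, (n %/% 2L) %/% acfg$h)
  abl <- resolve_ablation(ablation)
  k1 <- ceiling(fcfg$topk_ratio * n)
  k2 <- ceiling(fcfg$topk_ratio * k1)
  qam <- if (abl$use_qam) init_qam_weights(n, acfg) else NULL
  gnn <- list(W1 = uinit_mat(n, n), W2 = uinit_mat(k1, k1))
  c1 <- c2 <- NULL
  if (abl$use_traits) {
    ch <- fcfg$c1_channels; kw <- fcfg$c1_kernel
    t1 <- trait_len - kw + 1L; t2 <- t1 - kw + 1L
    if (t2 < 1L) stopf("trait vector too short for the 1D CNN plan")
    c1 <- list(conv = list(
      list(W = array(runif(ch[1] * 1 * kw, -1, 1) / sqrt(kw),
                     dim = c(ch[1], 1, kw)), b = numeric(ch[1])),
      list(W = array(runif(ch[2] * ch[1] * kw, -1, 1) / sqrt(ch[1] * kw),
                     dim = c(ch[2], ch[1], kw)), b = numeric(ch[2]))),
      lin = list(W = t(uinit_mat(ch[2], fcfg$embed_dim)),
                 b = numeric(fcfg$embed_dim)))
  }
  if (abl$use_behavior) {
    ch <- fcfg$c2_channels; kk <- fcfg$c2_kernel
    h2 <- behavior_dim[1] - 2L * (kk - 1L); w2 <- behavior_dim[2] - 2L * (kk - 1L)
    if (h2 < 1L || w2 < 1L)
      stopf("behavior matrix %dx%d too small for two %dx%d conv layers",
            behavior_dim[1], behavior_dim[2], kk, kk)
    c2 <- list(conv = list(
      list(W = array(runif(ch[1] * 1 * kk * kk, -1, 1) / kk,
                     dim = c(ch[1], 1, kk, kk)), b = numeric(ch[1])),
      list(W = array(runif(ch[2] * ch[1] * kk * kk, -1, 1) /
                       sqrt(ch[1] * kk * kk),
                     dim = c(ch[2], ch[1], kk, kk)), b = numeric(ch[2]))),
      lin = list(W = t(uinit_mat(ch[2], fcfg$embed_dim)),
                 b = numeric(fcfg$embed_dim)))
  }
  din <- k2 * k2 + (abl$use_traits + abl$use_behavior) * fcfg$embed_dim
  widths <- c(din, fcfg$mlp_hidden, 1L)
  mlp <- lapply(seq_len(length(widths) - 1L), function(i)
    list(W = t(uinit_mat(widths[i], widths[i + 1L])),
         b = numeric(widths[i + 1L])))
  list(qam = qam, gnn = gnn, c1 = c1, c2 = c2, mlp = mlp,
       dims = list(n = n, k1 = k1, k2 = k2, din = din,
                   trait_len = trait_len, behavior_dim = behavior_dim),
       acfg = acfg, fcfg = fcfg, ablation = abl, seed = seed)
}

resolve_ablation <- function(ablation) {
  if (is.list(ablation)) return(ablation)
  switch(ablation,
    comp1 = list(name = "comp1", use_qam = FALSE, use_traits = FALSE,
                 use_behavior = FALSE),
    comp2 = list(name = "comp2", use_qam = TRUE, use_traits = FALSE,
                 use_behavior = FALSE),
    comp3 = list(name = "comp3", use_qam = TRUE, use_traits = FALSE,
                 use_behavior = TRUE),
    comp4 = list(name = "comp4", use_qam = TRUE, use_traits = TRUE,
                 use_behavior = FALSE),
    full  = list(name = "full", use_qam = TRUE, use_traits = TRUE,
                 use_behavior = TRUE),
    stopf("unknown ablation '%s' (use comp1..comp4 or full)", ablation))
}

#' Reference forward pass of the full model (pure R)
#'
#' Used for documentation and for cross-checking the compiled training core;
#' returns the prediction on the standardized-age scale together with the
#' per-subject edge score matrix.
#'
#' @param weights from [init_fagnn_weights()].
#' @param X normalized connectome matrix, `traits` trait vector, `behavior`
#'   normalized behavior matrix.
#' @return list with `yhat` (scalar, standardized scale) and `S`.
#' @export
fagnn_forward_r <- function(weights, X, traits, behavior) {
  abl <- weights$ablation
  n <- nrow(X)
  S <- if (abl$use_qam) qam_edge_scores(X, weights$qam, weights$acfg)
       else matrix(1, n, n)
  inv <- identical(weights$fcfg$degree_mode, "inverse")
  A1 <- apply_edge_scores(X, S)
  H1 <- gnn_layer(X, S, 1L, weights$gnn$W1, D = degree_normalizer(A1, inv))
  p1 <- topk_pool(H1, rowMeans(H1), weights$fcfg$topk_ratio)
  H1p <- p1$H
  H2 <- gnn_layer(H1p, NULL, 2L, weights$gnn$W2,
                  D = degree_normalizer(H1p, inv))
  p2 <- topk_pool(H2, rowMeans(H2), weights$fcfg$topk_ratio)
  g <- as.numeric(p2$H)                  # row-flatten readout
  e1 <- if (abl$use_traits) cnn1d_forward(traits, weights$c1) else NULL
  e2 <- if (abl$use_behavior) cnn2d_forward(behavior, weights$c2) else NULL
  list(yhat = fuse_predict(g, e1, e2, weights$mlp), S = S)
}
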