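# Quadrant attention module (QAM).
#
# The connectome X (n x n, left-hemisphere regions first) is split into the
# four hemispheric quadrants
#   X_LL = X[alpha, alpha], X_LR = X[alpha, beta],
#   X_RL = X[beta,  alpha], X_RR = X[beta,  beta],
# with alpha = 1..n/2 and beta = n/2+1..n.  Each quadrant is scored by its
# own multihead scaled dot-product attention,
#   head_j = softmax(X W_j^Q (X W_j^K)^T / sqrt(d_k)) X W_j^V,
#   MHA(X_pq) = Concat(head_1, ..., head_h) W^O,
# and the four (n/2 x n/2) score blocks are reassembled into the n x n edge
# score matrix S that elementwise-weights the graph before convolution.

#' Attention configuration
#'
#' @param h number of attention heads (default 4).
#' @param dk per-head key/value dimension; default `(n/2)/h` at model build
#'   time (`NULL` here), keeping the concatenated head width equal to the
#'   quadrant width.
#' @param quadrant_weight_sharing if `TRUE` the four quadrants share one
#'   weight set (ablation aid); default independent weights.
#' @param clamp_scores if `TRUE`, S is clamped to `[0, Inf)` before the
#'   elementwise product (interpretability aid); default raw scores, as no
#'   nonlinearity appears in the score equations.
#' @return object of class `fagnn_attention_config`
#' @export
attention_config <- function(h = 4L, dk = NULL,
                             quadrant_weight_sharing = FALSE,
                             clamp_scores = FALSE) {
  if (!is_count(h)) stopf("h must be a positive integer")
  if (!is.null(dk) && !is_count(dk)) stopf("dk must be a positive integer")
  structure(list(h = as.integer(h), dk = if (is.null(dk)) NULL
                 else as.integer(dk),
                 quadrant_weight_sharing = isTRUE(quadrant_weight_sharing),
                 clamp_scores = isTRUE(clamp_scores)),
            class = "fagnn_attention_config")
}

#' Partition a connectome into hemispheric quadrants
#'
#' @param X n x n matrix, n even, left-hemisphere rows/columns first.
#' @return list with matrices `LL`, `LR`, `RL`, `RR`.
#' @export
partition_quadrants <- function(X) {
  if (!is.matrix(X) || nrow(X) != ncol(X)) stopf("X must be square")
  n <- nrow(X)
  if (n %% 2L != 0L) stopf("region count must be even, got %d", n)
  a <- seq_len(n %/% 2L)
  b <- seq.int(n %/% 2L + 1L, n)
  list(LL = X[a, a, drop = FALSE], LR = X[a, b, drop = FALSE],
       RL = X[b, a, drop = FALSE], RR = X[b, b, drop = FALSE])
}

#' Reassemble quadrant score blocks into the full edge-score matrix
#'
#' @param blocks list with `LL`, `LR`, `RL`, `RR` blocks of equal shape.
#' @return n x n matrix `[LL LR; RL RR]`.
#' @export
assemble_edge_scores <- function(blocks) {
  need <- c("LL", "LR", "RL", "RR")
  if (!all(need %in% names(blocks))) stopf("blocks must contain LL, LR, RL, RR")
  dims <- vapply(blocks[need], function(b) paste(dim(b), collapse = "x"), "")
  if (length(unique(dims)) != 1L)
    stopf("quadrant blocks disagree in shape: %s", paste(dims, collapse = ", "))
  rbind(cbind(blocks$LL, blocks$LR), cbind(blocks$RL, blocks$RR))
}

#' Scaled dot-product attention
#'
#' `softmax(Q K^T / sqrt(dk)) V` with a row-wise softmax, so the attention
#' weight matrix is row-stochastic.
#'
#' @param Q,K m x dk query/key matrices; `V` an m x dv value matrix.
#' @param dk key dimension used in the scaling (defaults to `ncol(K)`).
#' @return m x dv matrix.
#' @export
scaled_dot_attention <- function(Q, K, V, dk = ncol(K)) {
  if (dk <= 0) stopf("dk must be positive")
  if (nrow(Q) < 1L || nrow(K) != nrow(V))
    stopf("row counts of K and V must agree")
  Z <- (Q %*% t(K)) / sqrt(dk)
  A <- row_softmax(Z)
  A %*% V
}

row_softmax <- function(Z) {
  Z <- Z - apply(Z, 1, max)        # numerical stabilization
  E <- exp(Z)
  E / rowSums(E)
}

#' Initialize weights for one quadrant's multihead attention
#'
#' Seeded uniform on `(-1/sqrt(fan_in), 1/sqrt(fan_in))`.
#'
#' @param m quadrant width `n/2`.
#' @param cfg an [attention_config()]; a `NULL` `dk` resolves to
#'   `max(1, floor(m / h))`.
#' @return list with per-head `WQ`, `WK`, `WV` (each a list of h `m x dk`
#'   matrices) and the `(h*dk) x m` output matrix `WO`.
#' @export
init_quadrant_weights <- function(m, cfg = attention_config()) {
  dk <- cfg$dk %||% max(1L, m %/% cfg$h)
  uinit <- function(nin, nout) {
    lim <- 1 / sqrt(nin)
    matrix(runif(nin * nout, -lim, lim), nin, nout)
  }
  list(WQ = replicate(cfg$h, uinit(m, dk), simplify = FALSE),
       WK = replicate(cfg$h, uinit(m, dk), simplify = FALSE),
       WV = replicate(cfg$h, uinit(m, dk), simplify = FALSE),
       WO = uinit(cfg$h * dk, m))
}

#' Multihead attention over one quadrant
#'
#' @param Xpq (n/2) x (n/2) quadrant matrix.
#' @param w weights from [init_quadrant_weights()].
#' @param cfg an [attention_config()].
#' @return (n/2) x (n/2) score block.
#' @export
multihead_attention <- function(Xpq, w, cfg = attention_config(h = length(w$WQ))) {
  h <- cfg$h
  if (length(w$WQ) < h) stopf("weights provide %d heads, config wants %d",
                              length(w$WQ), h)
  heads <- lapply(seq_len(h), function(j)
    scaled_dot_attention(Xpq %*% w$WQ[[j]], Xpq %*% w$WK[[j]],
                         Xpq %*% w$WV[[j]], dk = ncol(w$WK[[j]])))
  C <- do.call(cbind, heads)
  if (ncol(C) != nrow(w$WO))
    stopf("concatenated heads (%d cols) do not match WO (%d rows)",
          ncol(C), nrow(w$WO))
  C %*% w$WO
}

#' Compute the full edge-score matrix S for one connectome
#'
#' @param X normalized n x n connectome matrix.
#' @param weights list of four quadrant weight sets named LL, LR, RL, RR
#'   (see [init_qam_weights()]).
#' @param cfg an [attention_config()].
#' @return n x n edge score matrix S.
#' @export
qam_edge_scores <- function(X, weights, cfg = attention_config()) {
  q <- partition_quadrants(X)
  blocks <- lapply(names(q), function(nm) {
    w <- if (cfg$quadrant_weight_sharing) weights[["LL"]] else weights[[nm]]
    multihead_attention(q[[nm]], w, cfg)
  })
  names(blocks) <- names(q)
  S <- assemble_edge_scores(blocks)
  if (cfg$clamp_scores) S[S < 0] <- 0
  S
}

#' Initialize the four quadrant weight sets
#'
#' @param n region count (even); each quadrant is `n/2` wide.
#' @param cfg an [attention_config()].
#' @return named list LL, LR, RL, RR of quadrant weights.
#' @export
init_qam_weights <- function(n, cfg = attention_config()) {
  m <- n %/% 2L
  out <- lapply(c("LL", "LR", "RL", "RR"), function(nm)
    init_quadrant_weights(m, cfg))
  names(out) <- c("LL", "LR", "RL", "RR")
  out
}

#' Elementwise product of a connectome with its edge scores
#'
#' @param X n x n matrix; `S` an n x n edge score matrix.
#' @return `X * S` elementwise.
#' @export
apply_edge_scores <- function(X, S) {
  if (!all(dim(X) == dim(S)))
    stopf("shape mismatch: X is %dx%d, S is %dx%d",
          nrow(X), ncol(X), nrow(S), ncol(S))
  X * S
}

#' Export per-subject and cohort-mean edge scores as labeled CSVs
#'
#' @param scores list of n x n score matrices named by subject id.
#' @param atlas the shared [region_atlas()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
export_edge_scores <- function(scores, atlas, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lab <- atlas$region_labels
  for (id in names(scores)) {
    m <- scores[[id]]
    dimnames(m) <- list(lab, lab)
    write.csv(m, file.path(dir, paste0("edge_scores_", id, ".csv")))
  }
  mean_s <- Reduce(`+`, scores) / length(scores)
  dimnames(mean_s) <- list(lab, lab)
  write.csv(mean_s, file.path(dir, "edge_scores_cohort_mean.csv"))
  invisible(dir)
}
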