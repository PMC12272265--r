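# Training (per-subnetwork Adam), prediction, and the evaluation protocol:
# repeated k-fold cross-validation with t-interval CIs, ablations, and the
# group-transfer delta-MAE comparison.

#' Training configuration
#'
#' Defaults follow the reference protocol: per-subnetwork Adam learning
#' rates of 0.001 (attention), 0.001 (GNN), 0.002 (1D CNN), 0.002 (2D CNN),
#' 0.003 (fully connected block), 100 epochs, full-batch steps.
#'
#' @param lr_qam,lr_gnn,lr_c1,lr_c2,lr_fc per-subnetwork learning rates.
#' @param epochs number of training epochs.
#' @param batch_size subjects per Adam step (default 8; the reference
#'   timing implies per-minibatch steps, and full-batch training at these
#'   learning rates underfits within 100 epochs).  `Inf` = full batch.
#' @param seed RNG seed controlling initialization and batching.
#' @param ablation `"full"`, `"comp1"` (GNN only), `"comp2"` (QAM+GNN),
#'   `"comp3"` (QAM+GNN+behavior), or `"comp4"` (QAM+GNN+traits).
#' @return object of class `fagnn_train_config`
#' @export
train_config <- function(lr_qam = 0.001, lr_gnn = 0.001, lr_c1 = 0.002,
                         lr_c2 = 0.002, lr_fc = 0.003, epochs = 100L,
                         batch_size = 8L, seed = 1L, ablation = "full") {
  lrs <- c(lr_qam, lr_gnn, lr_c1, lr_c2, lr_fc)
  if (any(lrs <= 0)) stopf("learning rates must be positive")
  if (!is_count(epochs)) stopf("epochs must be a positive integer")
  structure(list(lr_qam = lr_qam, lr_gnn = lr_gnn, lr_c1 = lr_c1,
                 lr_c2 = lr_c2, lr_fc = lr_fc, epochs = as.integer(epochs),
                 batch_size = batch_size, seed = as.integer(seed),
                 ablation = ablation),
            class = "fagnn_train_config")
}

# stack a normalized cohort into the arrays the compiled core consumes
cohort_tensors <- function(c) {
  list(X = lapply(c$subjects, function(s) unname(s$connectome$matrix)),
       traits = do.call(rbind, lapply(c$subjects, function(s)
         as.numeric(s$traits))),
       behavior = lapply(c$subjects, function(s) {
         b <- s$behavior
         attributes(b)[setdiff(names(attributes(b)), "dim")] <- NULL
         b
       }),
       y = vapply(c$subjects, `[[`, numeric(1), "age_days"),
       ids = vapply(c$subjects, `[[`, character(1), "id"))
}

flatten_group <- function(x) {
  if (is.null(x)) return(numeric(0))
  as.numeric(unlist(x, use.names = FALSE))
}

# fill the numeric leaves of `template` from `values`, preserving shapes
unflatten_group <- function(template, values) {
  pos <- 0L
  fill <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.numeric(x)) {
      len <- length(x)
      out <- values[(pos + 1L):(pos + len)]
      pos <<- pos + len
      dim(out) <- dim(x)
      return(out)
    }
    lapply(x, fill)
  }
  out <- fill(template)
  stopifnot(pos == length(values))
  out
}

param_group_names <- c("qam", "gnn", "c1", "c2", "mlp")

model_flags <- function(weights) {
  abl <- weights$ablation
  list(use_qam = abl$use_qam, use_traits = abl$use_traits,
       use_behavior = abl$use_behavior,
       clamp = weights$acfg$clamp_scores,
       h = weights$acfg$h, dk = weights$acfg$dk,
       topk_ratio = weights$fcfg$topk_ratio,
       inv_degree = identical(weights$fcfg$degree_mode, "inverse"),
       share = weights$acfg$quadrant_weight_sharing)
}

#' Train the full model (or an ablation) on a normalized cohort
#'
#' Minimizes the mean squared error between predicted and chronological age
#' with Adam, each subnetwork under its own learning rate.  The age target
#' is standardized internally (the scalers are stored on the model and
#' inverted at prediction time), so reported errors stay in days.
#'
#' @param cohort a normalized [cohort()].
#' @param cfg a [train_config()].
#' @param acfg an [attention_config()] (a `NULL` `dk` resolves to
#'   `(n/2)/h`).
#' @param fcfg a [fusion_config()].
#' @return object of class `fagnn_model` with the fitted weights, scalers,
#'   configuration and per-epoch loss `history`.
#' @export
train_model <- function(cohort, cfg = train_config(),
                        acfg = attention_config(), fcfg = fusion_config()) {
  if (length(cohort$subjects) < 2L) stopf("need at least 2 subjects")
  data <- cohort_tensors(cohort)
  n <- cohort$atlas$n
  if (is.null(acfg$dk)) acfg$dk <- max(1L, (n %/% 2L) %/% acfg$h)
  weights <- init_fagnn_weights(
    n, trait_len = ncol(data$traits), behavior_dim = dim(data$behavior[[1]]),
    acfg = acfg, fcfg = fcfg, ablation = cfg$ablation, seed = cfg$seed)
  if (acfg$quadrant_weight_sharing && weights$ablation$use_qam)
    for (q in c("LR", "RL", "RR")) weights$qam[[q]] <- weights$qam$LL

  # standardized age target
  y <- data$y
  mu <- mean(y)
  sdv <- sd(y)
  if (!is.finite(sdv) || sdv == 0) sdv <- 1
  data$y <- (y - mu) / sdv

  flags <- model_flags(weights)
  group_len <- vapply(param_group_names, function(g)
    length(flatten_group(weights[[g]])), integer(1))
  lr_vec <- rep(c(cfg$lr_qam, cfg$lr_gnn, cfg$lr_c1, cfg$lr_c2, cfg$lr_fc),
                times = group_len)
  theta <- unlist(lapply(param_group_names, function(g)
    flatten_group(weights[[g]])))
  m_adam <- v_adam <- numeric(length(theta))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; step <- 0L

  N <- length(data$y)
  bs <- if (!is.finite(cfg$batch_size)) N else min(N, cfg$batch_size)
  set.seed(child_seed(cfg$seed, 7L))
  history <- numeric(cfg$epochs)

  rebuild <- function(theta) {
    off <- 0L
    for (g in param_group_names) {
      if (group_len[[g]] == 0L) next
      weights[[g]] <<- unflatten_group(
        weights[[g]], theta[(off + 1L):(off + group_len[[g]])])
      off <- off + group_len[[g]]
    }
  }

  for (epoch in seq_len(cfg$epochs)) {
    order_ <- if (bs < N) sample.int(N) else seq_len(N)
    batches <- split(order_ - 1L, ceiling(seq_along(order_) / bs))
    ep_loss <- 0
    for (batch in batches) {
      rebuild(theta)
      res <- fagnn_core(weights[param_group_names], data, flags,
                        as.integer(batch), TRUE, FALSE)
      if (!is.finite(res$loss))
        stopf("non-finite training loss at epoch %d", epoch)
      ep_loss <- ep_loss + res$loss * length(batch) / N
      grad <- unlist(lapply(param_group_names, function(g)
        if (group_len[[g]] > 0L) flatten_group(res$grad[[g]])
        else numeric(0)))
      step <- step + 1L
      m_adam <- b1 * m_adam + (1 - b1) * grad
      v_adam <- b2 * v_adam + (1 - b2) * grad^2
      mhat <- m_adam / (1 - b1^step)
      vhat <- v_adam / (1 - b2^step)
      theta <- theta - lr_vec * mhat / (sqrt(vhat) + eps)
    }
    if (flags$share && weights$ablation$use_qam) {
      rebuild(theta)
      for (q in c("LR", "RL", "RR")) weights$qam[[q]] <- weights$qam$LL
      theta <- unlist(lapply(param_group_names, function(g)
        flatten_group(weights[[g]])))
    }
    history[epoch] <- ep_loss
  }
  rebuild(theta)
  structure(list(weights = weights, y_center = mu, y_scale = sdv,
                 atlas = cohort$atlas, cfg = cfg, history = history,
                 schema = "fagnn-checkpoint-1"),
            class = "fagnn_model")
}

#' @export
print.fagnn_model <- function(x, ...) {
  cat(sprintf(
    "fagnn model (%s): %d regions, %d epochs, final training loss %.4g\n",
    x$weights$ablation$name, x$atlas$n, x$cfg$epochs,
    x$history[length(x$history)]))
  invisible(x)
}

#' Predict brain age (days) for normalized subjects
#'
#' @param object a trained `fagnn_model`.
#' @param cohort a [cohort()] (or list of subjects) normalized with the
#'   training cohort's scalers.
#' @param want_scores also return the per-subject edge score matrices.
#' @param ... unused.
#' @return numeric vector of predicted ages in days, or (with
#'   `want_scores`) a list with `pred` and `S`.
#' @export
predict.fagnn_model <- function(object, cohort, want_scores = FALSE, ...) {
  if (inherits(cohort, "fagnn_cohort") &&
      !identical(cohort$atlas$region_labels, object$atlas$region_labels))
    stopf("cohort atlas does not match the training atlas (%d vs %d regions)",
          cohort$atlas$n, object$atlas$n)
  if (!inherits(cohort, "fagnn_cohort"))
    cohort <- new_cohort(cohort, object$atlas)
  data <- cohort_tensors(cohort)
  if (nrow(data$X[[1]]) != object$atlas$n)
    stopf("subject has %d regions; model expects %d",
          nrow(data$X[[1]]), object$atlas$n)
  data$y <- numeric(length(data$y))
  flags <- model_flags(object$weights)
  res <- fagnn_core(object$weights[param_group_names], data, flags,
                    seq_along(data$X) - 1L, FALSE, want_scores)
  pred <- object$y_center + object$y_scale * res$yhat
  names(pred) <- data$ids
  if (!want_scores) return(pred)
  names(res$S) <- data$ids
  list(pred = pred, S = res$S)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single archive holding every weight array plus the
#' configuration; reloading reproduces predictions bit-identically.
#'
#' @param model a `fagnn_model`; `path` file path.
#' @return `path` / the reloaded model.
#' @export
save_fagnn <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_fagnn
#' @param path checkpoint file written by [save_fagnn()].
#' @export
load_fagnn <- function(path) {
  model <- readRDS(path)
  if (!identical(model$schema, "fagnn-checkpoint-1"))
    stopf("unrecognized checkpoint schema")
  model
}

#' Prediction-error metrics
#'
#' @param pred,true equal-length numeric vectors (ages in days).
#' @return list with `mae`, `rmse`, and Pearson `r` (`NA` with a warning
#'   flag when either vector has zero variance).
#' @export
evaluate_predictions <- function(pred, true) {
  if (length(pred) != length(true)) stopf("length mismatch")
  if (length(pred) < 2L) stopf("need at least 2 predictions")
  err <- pred - true
  r <- if (sd(pred) == 0 || sd(true) == 0) NA_real_ else cor(pred, true)
  list(mae = mean(abs(err)), rmse = sqrt(mean(err^2)), r = r,
       r_defined = !is.na(r))
}

#' Seeded k-fold assignment
#'
#' Uniform shuffle (optionally stratified); fold sizes differ by at most 1.
#'
#' @param ids subject ids; `k` fold count; `seed` RNG seed.
#' @param stratify_by optional vector (e.g. age-group labels) to stratify
#'   the shuffle within.
#' @return named integer vector: id -> fold index in `1..k`.
#' @export
make_folds <- function(ids, k, seed = 1L, stratify_by = NULL) {
  n <- length(ids)
  if (k < 2L) stopf("k must be at least 2")
  if (k > n) stopf("k = %d exceeds cohort size %d", k, n)
  set.seed(seed)
  fold <- integer(n)
  if (is.null(stratify_by)) {
    fold[sample.int(n)] <- rep(seq_len(k), length.out = n)
  } else {
    for (g in unique(stratify_by)) {
      idx <- which(stratify_by == g)
      fold[idx[sample.int(length(idx))]] <-
        rep(seq_len(k), length.out = length(idx))
    }
  }
  names(fold) <- ids
  fold
}

#' Repeated k-fold cross-validation
#'
#' Every subject is predicted exactly once per run by the model that never
#' saw it; MAE/RMSE are pooled per run and summarized with Student
#' t-intervals across runs.  Each run draws a fresh seeded fold split.
#'
#' @param cohort a normalized [cohort()].
#' @param cfg a [train_config()]; `k` folds; `runs` repeats.
#' @param acfg,fcfg architecture configurations.
#' @param collect_scores accumulate the mean edge-score matrix over all
#'   test-fold evaluations (for interpretation).
#' @param stratify_by optional stratification vector for the fold split.
#' @return object of class `fagnn_eval`: per-run metrics, 95% CIs,
#'   per-subject predictions, and optionally `mean_scores`.
#' @export
cross_validate <- function(cohort, cfg = train_config(), k = 5L, runs = 1L,
                           acfg = attention_config(), fcfg = fusion_config(),
                           collect_scores = FALSE, stratify_by = NULL) {
  N <- length(cohort$subjects)
  if (k > N) stopf("k = %d exceeds cohort size %d", k, N)
  ids <- vapply(cohort$subjects, `[[`, character(1), "id")
  run_rows <- list(); pred_rows <- list()
  score_sum <- NULL; score_n <- 0L
  for (run in seq_len(runs)) {
    run_seed <- child_seed(cfg$seed, run)
    folds <- make_folds(ids, k, seed = run_seed, stratify_by = stratify_by)
    pred <- true <- numeric(N); names(pred) <- ids
    for (f in seq_len(k)) {
      test_idx <- which(folds == f)
      train_idx <- which(folds != f)
      sub_train <- new_cohort(cohort$subjects[train_idx], cohort$atlas)
      sub_test <- new_cohort(cohort$subjects[test_idx], cohort$atlas)
      fold_cfg <- cfg
      fold_cfg$seed <- child_seed(run_seed, f)
      model <- train_model(sub_train, fold_cfg, acfg, fcfg)
      if (collect_scores) {
        out <- predict(model, sub_test, want_scores = TRUE)
        p <- out$pred
        for (S in out$S) {
          score_sum <- if (is.null(score_sum)) S else score_sum + S
          score_n <- score_n + 1L
        }
      } else {
        p <- predict(model, sub_test)
      }
      pred[test_idx] <- p
      true[test_idx] <- vapply(cohort$subjects[test_idx], `[[`,
                               numeric(1), "age_days")
    }
    met <- evaluate_predictions(pred, true)
    run_rows[[run]] <- data.frame(run = run, mae = met$mae, rmse = met$rmse,
                                  r = met$r)
    pred_rows[[run]] <- data.frame(run = run, id = ids, true = true,
                                   pred = unname(pred),
                                   stringsAsFactors = FALSE)
  }
  runs_df <- do.call(rbind, run_rows)
  out <- list(runs = runs_df,
              ci = list(mae = t_interval(runs_df$mae),
                        rmse = t_interval(runs_df$rmse)),
              predictions = do.call(rbind, pred_rows),
              k = k, n_runs = runs)
  if (collect_scores) out$mean_scores <- score_sum / score_n
  structure(out, class = "fagnn_eval")
}

# Student t 95% interval of the mean across repeated runs
t_interval <- function(x, level = 0.95) {
  m <- mean(x)
  if (length(x) < 2L || sd(x) == 0)
    return(c(mean = m, lower = m, upper = m))
  half <- qt(1 - (1 - level) / 2, df = length(x) - 1L) * sd(x) / sqrt(length(x))
  c(mean = m, lower = m - half, upper = m + half)
}

#' @export
print.fagnn_eval <- function(x, ...) {
  cat(sprintf("fagnn CV: %d-fold, %d run(s)\n", x$k, x$n_runs))
  cat(sprintf("  MAE  %.2f days (95%% CI %.2f, %.2f)\n",
              x$ci$mae["mean"], x$ci$mae["lower"], x$ci$mae["upper"]))
  cat(sprintf("  RMSE %.2f days (95%% CI %.2f, %.2f)\n",
              x$ci$rmse["mean"], x$ci$rmse["lower"], x$ci$rmse["upper"]))
  invisible(x)
}

# subset a cohort by a subject predicate or a named trait-value list
subset_cohort <- function(x, filter) {
  keep <- vapply(x$subjects, function(s) {
    if (is.function(filter)) return(isTRUE(filter(s)))
    all(vapply(names(filter), function(nm)
      isTRUE(all.equal(unname(s$traits[[nm]]), filter[[nm]])), logical(1)))
  }, logical(1))
  new_cohort(x$subjects[keep], x$atlas)
}

#' Group-transfer evaluation (delta MAE)
#'
#' For each run: (a) k-fold cross-validation within the reference (control)
#' group gives the reference MAE; (b) a model trained on the full reference
#' group and tested on the risk group gives the transfer MAE.  Delta MAE is
#' the mean transfer MAE minus the mean reference MAE, a sensitivity
#' measure for risk-factor-accelerated aging.
#'
#' @param cohort a normalized [cohort()].
#' @param train_group,test_group subject predicates (functions) or named
#'   trait-value lists, e.g. `list(diet = 0)` vs `list(diet = 1)`.
#' @param cfg a [train_config()]; `runs` repeats; `k` reference folds.
#' @param acfg,fcfg architecture configurations.
#' @return list with per-run MAEs for both groups and `delta_mae`.
#' @export
group_transfer_eval <- function(cohort, train_group, test_group,
                                cfg = train_config(), runs = 1L, k = 5L,
                                acfg = attention_config(),
                                fcfg = fusion_config()) {
  ctrl <- subset_cohort(cohort, train_group)
  risk <- subset_cohort(cohort, test_group)
  if (length(ctrl$subjects) == 0L) stopf("empty train group after filtering")
  if (length(risk$subjects) == 0L) stopf("empty test group after filtering")
  ctrl_ids <- vapply(ctrl$subjects, `[[`, character(1), "id")
  risk_ids <- vapply(risk$subjects, `[[`, character(1), "id")
  if (length(intersect(ctrl_ids, risk_ids)) > 0L)
    stopf("train and test groups overlap")
  ctrl_mae <- risk_mae <- numeric(runs)
  for (run in seq_len(runs)) {
    run_cfg <- cfg
    run_cfg$seed <- child_seed(cfg$seed, 100L + run)
    cv <- cross_validate(ctrl, run_cfg, k = min(k, length(ctrl$subjects)),
                         runs = 1L, acfg = acfg, fcfg = fcfg)
    ctrl_mae[run] <- cv$runs$mae[1]
    model <- train_model(ctrl, run_cfg, acfg, fcfg)
    pred <- predict(model, risk)
    true <- vapply(risk$subjects, `[[`, numeric(1), "age_days")
    risk_mae[run] <- mean(abs(pred - true))
  }
  list(control_mae = ctrl_mae, risk_mae = risk_mae,
       delta_mae = mean(risk_mae) - mean(ctrl_mae))
}
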