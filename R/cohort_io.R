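# Cohort data model: atlases, connectomes, traits, behavior, subjects.
#
# Every quantity that enters the network is normalized to [0, 1]:
# connectomes by dense-rank normalization, binary traits to {0, 1}, APOE to
# {0, 0.5, 1}, time-based behavior metrics by the 60 s trial cap, and other
# behavior metrics by their cohort-wide maxima.

#' Region atlas
#'
#' An ordered set of brain-region labels with the left-hemisphere block
#' first and the right-hemisphere block second.  The hemisphere split at
#' `n/2` defines the four connectome quadrants (LL, LR, RL, RR) used by the
#' quadrant attention module.
#'
#' @param region_labels character vector of unique region names; the first
#'   half are left-hemisphere regions, the second half right-hemisphere.
#' @return An object of class `fagnn_atlas` with fields `region_labels`,
#'   `n`, and `hemisphere_split`.
#' @export
region_atlas <- function(region_labels) {
  region_labels <- as.character(region_labels)
  n <- length(region_labels)
  if (n < 4L) stopf("atlas needs at least 4 regions, got %d", n)
  if (n %% 2L != 0L) stopf("atlas region count must be even, got %d", n)
  if (anyDuplicated(region_labels))
    stopf("atlas region labels must be unique")
  structure(
    list(region_labels = region_labels, n = n, hemisphere_split = n %/% 2L),
    class = "fagnn_atlas")
}

#' Default mouse region labels for a simulated atlas
#' @param n even region count
#' @return character vector `L01..L<n/2>, R01..R<n/2>`
#' @keywords internal
default_region_labels <- function(n) {
  m <- n %/% 2L
  c(sprintf("L%02d", seq_len(m)), sprintf("R%02d", seq_len(m)))
}

#' Connectome container
#'
#' @param matrix square nonnegative numeric matrix of connection weights
#'   (streamline-count derived).
#' @param atlas a [region_atlas()]; if `NULL`, synthetic labels are used.
#' @param normalized logical, whether `matrix` is already rank-normalized.
#' @return object of class `fagnn_connectome`
#' @export
connectome <- function(matrix, atlas = NULL, normalized = FALSE) {
  if (!is.matrix(matrix) || nrow(matrix) != ncol(matrix))
    stopf("connectome must be a square matrix (got %d x %d)",
          nrow(matrix), ncol(matrix))
  if (any(!is.finite(matrix))) stopf("connectome has non-finite entries")
  if (any(matrix < 0)) stopf("connectome has negative entries")
  if (is.null(atlas)) atlas <- region_atlas(default_region_labels(nrow(matrix)))
  if (atlas$n != nrow(matrix))
    stopf("atlas has %d regions but connectome is %d x %d",
          atlas$n, nrow(matrix), ncol(matrix))
  dimnames(matrix) <- list(atlas$region_labels, atlas$region_labels)
  structure(list(matrix = matrix, atlas = atlas, normalized = normalized),
            class = "fagnn_connectome")
}

# default label dictionaries for the binary traits
default_trait_dict <- function() {
  list(sex  = c(M = 0, F = 1),
       diet = c(CTRL = 0, HFD = 1),
       nos2 = c(mNos2 = 0, hNOS2 = 1))
}

#' Encode categorical risk-factor traits to the [0, 1] scale
#'
#' APOE alleles 2/3/4 map to 0/0.5/1; the binary traits (sex, diet, NOS2
#' variant) map to 0/1 through a configurable two-value dictionary.
#'
#' @param sex_raw,diet_raw,nos2_raw labels found in `dict`.
#' @param apoe_raw one of `"APOE2"`, `"APOE3"`, `"APOE4"`.
#' @param dict named list with `sex`, `diet`, `nos2` two-value named vectors.
#' @return named numeric vector `c(sex, diet, apoe, nos2)`, all in `[0, 1]`.
#' @examples
#' encode_traits("F", "HFD", "APOE4", "hNOS2")
#' @export
encode_traits <- function(sex_raw, diet_raw, apoe_raw, nos2_raw,
                          dict = default_trait_dict()) {
  lookup <- function(value, map, what) {
    value <- as.character(value)
    if (!value %in% names(map))
      stopf("unknown %s label '%s'; permitted: %s", what, value,
            paste(names(map), collapse = ", "))
    unname(map[[value]])
  }
  apoe_map <- c(APOE2 = 0, APOE3 = 0.5, APOE4 = 1)
  c(sex  = lookup(sex_raw,  dict$sex,  "sex"),
    diet = lookup(diet_raw, dict$diet, "diet"),
    apoe = lookup(apoe_raw, apoe_map,  "apoe"),
    nos2 = lookup(nos2_raw, dict$nos2, "nos2"))
}

#' Rank-normalize a connectome
#'
#' Dense ranking over the multiset of matrix entries: equal weights share a
#' rank, the minimum value maps to rank 0, and ranks are divided by the
#' maximum rank so the result lies in `[0, 1]`.  An all-equal matrix (e.g.
#' all zeros) maps to all zeros.  Because only the ordering of weights is
#' used, the output is invariant to strictly monotone transforms of the raw
#' weights.
#'
#' @param x a [connectome()] or a plain square nonnegative matrix.
#' @return the same type with normalized entries.
#' @examples
#' rank_normalize_connectome(matrix(c(0, 5, 5, 2), 2, byrow = TRUE))
#' @export
rank_normalize_connectome <- function(x) {
  m <- if (inherits(x, "fagnn_connectome")) x$matrix else x
  if (!is.matrix(m) || nrow(m) != ncol(m)) stopf("expected a square matrix")
  if (any(m < 0)) stopf("negative entries are not allowed")
  u <- sort(unique(as.vector(m)))
  r <- matrix(match(as.vector(m), u) - 1L, nrow(m), ncol(m))
  max_rank <- length(u) - 1L
  out <- if (max_rank == 0L) r * 0 else r / max_rank
  dimnames(out) <- dimnames(m)
  if (inherits(x, "fagnn_connectome")) {
    x$matrix <- out
    x$normalized <- TRUE
    x
  } else out
}

#' Normalize a behavioral matrix to [0, 1]
#'
#' Time-based metrics (Morris Water Maze latencies etc.) are divided by the
#' 60 s trial cap; other metrics are divided by their per-column maxima
#' computed over the cohort so subjects stay comparable.
#'
#' @param raw trials x metrics numeric matrix (rows chronological, similar
#'   metrics adjacent in columns).
#' @param metric_kinds character vector, one of `"time"`/`"other"` per
#'   column.
#' @param col_max cohort-level per-column maxima for the non-time columns;
#'   defaults to the maxima of `raw` itself (single-subject cohort).
#' @return normalized matrix with attribute `metric_kinds`.
#' @export
normalize_behavior <- function(raw, metric_kinds, col_max = NULL) {
  if (!is.matrix(raw)) raw <- as.matrix(raw)
  if (length(metric_kinds) != ncol(raw))
    stopf("metric_kinds has %d entries for %d columns",
          length(metric_kinds), ncol(raw))
  if (!all(metric_kinds %in% c("time", "other")))
    stopf("metric_kinds must be 'time' or 'other'")
  if (is.null(col_max)) col_max <- apply(raw, 2, max)
  out <- raw
  for (j in seq_len(ncol(raw))) {
    if (metric_kinds[j] == "time") {
      if (any(raw[, j] > 60))
        stopf("time-based metric in column %d exceeds the 60 s trial cap", j)
      if (any(raw[, j] < 0)) stopf("negative time in column %d", j)
      out[, j] <- raw[, j] / 60
    } else {
      mx <- col_max[j]
      out[, j] <- if (mx > 0) raw[, j] / mx else raw[, j]
    }
  }
  if (any(out < 0 | out > 1))
    stopf("normalized behavior falls outside [0, 1]; check cohort maxima")
  attr(out, "metric_kinds") <- metric_kinds
  out
}

#' Construct one subject record
#'
#' @param id subject identifier.
#' @param age_days positive chronological age in days (regression target).
#' @param traits numeric vector from [encode_traits()].
#' @param behavior normalized behavior matrix.
#' @param connectome a normalized [connectome()].
#' @return object of class `fagnn_subject`
#' @export
subject <- function(id, age_days, traits, behavior, connectome) {
  if (!is.numeric(age_days) || length(age_days) != 1L || age_days <= 0)
    stopf("subject '%s': age_days must be a positive scalar", id)
  structure(list(id = as.character(id), age_days = as.numeric(age_days),
                 traits = traits, behavior = behavior,
                 connectome = connectome),
            class = "fagnn_subject")
}

#' Construct a cohort
#'
#' @param subjects list of [subject()] records sharing one atlas.
#' @param atlas the shared [region_atlas()].
#' @return object of class `fagnn_cohort`
#' @export
cohort <- function(subjects, atlas) {
  structure(list(subjects = subjects, atlas = atlas),
            class = "fagnn_cohort")
}

# internal alias usable where a local variable is named `cohort`
new_cohort <- cohort

#' @export
print.fagnn_cohort <- function(x, ...) {
  ages <- vapply(x$subjects, `[[`, numeric(1), "age_days")
  cat(sprintf("fagnn cohort: %d subjects, %d regions, age %.0f-%.0f days\n",
              length(x$subjects), x$atlas$n, min(ages), max(ages)))
  invisible(x)
}

#' Read a cohort from metadata + per-subject CSV files
#'
#' The metadata CSV must have columns `id, age_days, sex, diet, apoe, nos2`.
#' For every id, `<connectome_dir>/<id>.csv` holds an (n+1) x (n+1) labeled
#' connectome (header row/column of region labels, left hemisphere first)
#' and `<behavior_dir>/<id>.csv` a trials x metrics table with a header of
#' metric names.  Connectomes are rank-normalized, traits encoded, and
#' behavior scaled with cohort-level maxima.
#'
#' @param metadata_path path to the metadata CSV.
#' @param connectome_dir,behavior_dir directories of per-subject CSVs.
#' @param metric_kinds per-column behavior metric kinds (`"time"`/`"other"`);
#'   defaults to treating columns whose name contains `"time"` or
#'   `"latency"` as time-based.
#' @param trait_dict label dictionary, see [encode_traits()].
#' @return a validated [cohort()]; raw matrices are kept in `$raw` fields.
#' @export
read_cohort <- function(metadata_path, connectome_dir, behavior_dir,
                        metric_kinds = NULL,
                        trait_dict = default_trait_dict()) {
  meta <- read.csv(metadata_path, stringsAsFactors = FALSE)
  need <- c("id", "age_days", "sex", "diet", "apoe", "nos2")
  if (!all(need %in% names(meta)))
    stopf("metadata must have columns %s", paste(need, collapse = ", "))
  atlas <- NULL
  raw_conn <- list(); raw_behav <- list()
  for (i in seq_len(nrow(meta))) {
    id <- as.character(meta$id[i])
    cpath <- file.path(connectome_dir, paste0(id, ".csv"))
    bpath <- file.path(behavior_dir, paste0(id, ".csv"))
    if (!file.exists(cpath)) stopf("missing connectome file for id '%s'", id)
    if (!file.exists(bpath)) stopf("missing behavior file for id '%s'", id)
    ctab <- read.csv(cpath, row.names = 1, check.names = FALSE)
    cm <- as.matrix(ctab)
    if (nrow(cm) != ncol(cm))
      stopf("non-square connectome for id '%s' (%d x %d)",
            id, nrow(cm), ncol(cm))
    if (nrow(cm) %% 2L != 0L)
      stopf("odd region count (%d) in connectome for id '%s'", nrow(cm), id)
    if (is.null(atlas)) atlas <- region_atlas(rownames(cm))
    if (!identical(rownames(cm), atlas$region_labels))
      stopf("connectome for id '%s' does not match the cohort atlas", id)
    raw_conn[[id]] <- cm
    raw_behav[[id]] <- as.matrix(read.csv(bpath, check.names = FALSE))
  }
  shapes <- vapply(raw_behav, function(b) paste(dim(b), collapse = "x"), "")
  if (length(unique(shapes)) > 1L)
    stopf("behavior matrices differ in shape across subjects")
  b1 <- raw_behav[[1]]
  if (is.null(metric_kinds)) {
    nm <- tolower(colnames(b1) %||% rep("", ncol(b1)))
    metric_kinds <- ifelse(grepl("time|latency", nm), "time", "other")
  }
  # cohort-level maxima for the non-time columns
  col_max <- apply(do.call(rbind, raw_behav), 2, max)
  subjects <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    id <- as.character(meta$id[i])
    conn <- rank_normalize_connectome(connectome(raw_conn[[id]], atlas))
    conn$raw <- raw_conn[[id]]
    behav <- normalize_behavior(raw_behav[[id]], metric_kinds, col_max)
    traits <- encode_traits(meta$sex[i], meta$diet[i], meta$apoe[i],
                            meta$nos2[i], trait_dict)
    subjects[[i]] <- subject(id, meta$age_days[i], traits, behav, conn)
    subjects[[i]]$raw_behavior <- raw_behav[[id]]
  }
  out <- cohort(subjects, atlas)
  rep <- validate_cohort(out)
  if (nrow(rep) > 0L)
    stopf("cohort failed validation:\n%s",
          paste(sprintf("  %s/%s: %s", rep$subject, rep$field, rep$message),
                collapse = "\n"))
  out
}

#' Validate a cohort against the data-model invariants
#'
#' Checks atlas consistency, normalization ranges, trait codes, behavior
#' shapes, and positive ages.  Report-only: never throws.
#'
#' @param x a [cohort()]
#' @return data.frame with columns `subject`, `field`, `message`; zero rows
#'   iff the cohort is valid.
#' @export
validate_cohort <- function(x) {
  viol <- list()
  add <- function(subject, field, message)
    viol[[length(viol) + 1L]] <<- data.frame(
      subject = subject, field = field, message = message,
      stringsAsFactors = FALSE)
  if (length(x$subjects) < 2L)
    add("<cohort>", "subjects", "fewer than 2 subjects")
  shapes <- vapply(x$subjects, function(s) paste(dim(s$behavior),
                                                 collapse = "x"), "")
  if (length(unique(shapes)) > 1L)
    add("<cohort>", "behavior", "behavior matrix shapes differ")
  for (s in x$subjects) {
    if (!is.numeric(s$age_days) || s$age_days <= 0)
      add(s$id, "age_days", "age must be positive")
    if (!identical(s$connectome$atlas$region_labels, x$atlas$region_labels))
      add(s$id, "connectome", "atlas mismatch")
    m <- s$connectome$matrix
    if (nrow(m) != ncol(m)) add(s$id, "connectome", "not square")
    if (any(m < 0 | m > 1)) add(s$id, "connectome", "entries outside [0,1]")
    else if (s$connectome$normalized && any(m > 0) && max(m) != 1)
      add(s$id, "connectome", "normalized matrix lacks a unit entry")
    tr <- s$traits
    if (length(tr) != 4L || any(tr < 0 | tr > 1))
      add(s$id, "traits", "traits outside [0,1] or wrong length")
    else if (!tr[["apoe"]] %in% c(0, 0.5, 1))
      add(s$id, "traits", "apoe not in {0, 0.5, 1}")
    if (any(s$behavior < 0 | s$behavior > 1))
      add(s$id, "behavior", "entries outside [0,1]")
  }
  if (length(viol) == 0L)
    return(data.frame(subject = character(), field = character(),
                      message = character(), stringsAsFactors = FALSE))
  do.call(rbind, viol)
}

#' Write a cohort to the CSV layouts that [read_cohort()] consumes
#'
#' @param x a [cohort()]; subjects must retain `$raw` connectomes and
#'   `$raw_behavior` matrices (the simulator provides both).
#' @param dir output directory (created if missing).
#' @param trait_dict dictionary used to decode traits back to labels.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(x, dir, trait_dict = default_trait_dict()) {
  dir.create(file.path(dir, "connectomes"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "behavior"), recursive = TRUE,
             showWarnings = FALSE)
  decode <- function(map, v) names(map)[match(v, map)]
  apoe_map <- c(APOE2 = 0, APOE3 = 0.5, APOE4 = 1)
  meta <- do.call(rbind, lapply(x$subjects, function(s) data.frame(
    id = s$id, age_days = s$age_days,
    sex  = decode(trait_dict$sex,  s$traits[["sex"]]),
    diet = decode(trait_dict$diet, s$traits[["diet"]]),
    apoe = decode(apoe_map, s$traits[["apoe"]]),
    nos2 = decode(trait_dict$nos2, s$traits[["nos2"]]),
    stringsAsFactors = FALSE)))
  write.csv(meta, file.path(dir, "metadata.csv"), row.names = FALSE)
  for (s in x$subjects) {
    raw <- s$connectome$raw %||% s$connectome$matrix
    dimnames(raw) <- list(x$atlas$region_labels, x$atlas$region_labels)
    write.csv(raw, file.path(dir, "connectomes", paste0(s$id, ".csv")))
    rb <- s$raw_behavior %||% s$behavior
    write.csv(as.data.frame(rb),
              file.path(dir, "behavior", paste0(s$id, ".csv")),
              row.names = FALSE)
  }
  invisible(dir)
}
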