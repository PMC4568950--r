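# Two-stage plasma normalization and the tissue-phase feature filter /
# scale normalization.
#
# Stage 1 (reference normalization) equalizes, per protein, the median
# heavy-reference intensity across runs and shifts every intensity of that
# protein in a run by the same constant: it removes acquisition drift.
# Stage 2 (standard normalization) summarizes each spiked standard protein
# to one value per run, screens the standards for stability against the
# per-run sample medians (Pearson r > 0.6), and shifts every light
# intensity in a run so the chosen standard's summary is constant across
# runs: it removes sample-preparation bias. Both stages are pure shifts on
# the log2 scale, so within-run peptide differences are preserved.

#' Stage 1: reference-peptide normalization
#'
#' For each protein with heavy-reference records, computes per-run shifts
#' `global median(heavy) - run median(heavy)` and applies them to all light
#' and heavy records of that protein in that run. After the operation each
#' protein's per-run heavy median is constant across runs. A protein
#' lacking heavy records in some run is left unshifted there with a
#' warning.
#'
#' @param records data.frame of quantification records (log2 scale). Both
#'   endogenous and spiked standard proteins are normalized against their
#'   own heavy references (in the targeting method every monitored
#'   peptide, standard peptides included, has a heavy counterpart).
#' @return list with `records` (shifted) and `report` (an object of class
#'   `normalization_report` accumulating per-protein targets and shifts).
#' @export
normalize_by_reference <- function(records) {
  validate_quant_records(records)
  rec <- records
  heavy <- rec$channel == "heavy" & !is.na(rec$log2_intensity)
  shift_tables <- list()
  targets <- c()
  unshifted <- character(0)
  for (pid in unique(rec$protein_id)) {
    hsel <- heavy & rec$protein_id == pid
    psel <- rec$protein_id == pid
    if (!any(hsel)) {
      unshifted <- c(unshifted, pid)
      next
    }
    target <- median(rec$log2_intensity[hsel])
    run_med <- vapply(split(rec$log2_intensity[hsel], rec$run_id[hsel]), median, 0)
    shift <- target - run_med
    runs_with_light <- unique(rec$run_id[psel])
    missing_runs <- setdiff(runs_with_light, names(shift))
    if (length(missing_runs)) {
      warnf("protein %s has no heavy reference in %d run(s); left unshifted there",
            pid, length(missing_runs))
    }
    idx <- which(psel & rec$run_id %in% names(shift))
    rec$log2_intensity[idx] <- rec$log2_intensity[idx] + shift[rec$run_id[idx]]
    shift_tables[[pid]] <- data.frame(protein_id = pid, run_id = names(shift),
                                      shift = unname(shift), stringsAsFactors = FALSE)
    targets[pid] <- target
  }
  if (length(unshifted)) {
    warnf("no heavy reference records for protein(s): %s; left unnormalized",
          paste(unshifted, collapse = ", "))
  }
  report <- structure(list(
    reference_targets = targets,
    reference_shifts = if (length(shift_tables)) {
      do.call(rbind, c(shift_tables, list(make.row.names = FALSE)))
    },
    standard_summaries = NULL, stability = NULL, standard_shifts = NULL
  ), class = "normalization_report")
  list(records = rec, report = report)
}

#' Summarize a spiked standard protein to one value per run
#'
#' Additive two-way fixed-effects model (peptide + run) fit by least
#' squares on observed cells; the per-run summary is the intercept plus
#' run effect with sum-to-zero peptide effects, which reduces to the
#' per-run mean on balanced data. Runs where every peptide of the standard
#' is missing get NA.
#'
#' @param records quantification records.
#' @param standard_id protein id of the spiked standard.
#' @return named numeric vector, one summary per run in which the standard
#'   was targeted.
#' @export
summarize_standard_protein <- function(records, standard_id) {
  sel <- records$protein_id == standard_id & records$channel == "light"
  if (!any(sel)) stopf("standard protein %s not present in the records", standard_id)
  sub <- records[sel, ]
  if (length(unique(sub$run_id)) < 2L) {
    stopf("standard protein %s observed in fewer than 2 runs", standard_id)
  }
  additive_summary(sub$log2_intensity, sub$run_id, sub$peptide_id,
                   all_units = unique(sub$run_id))
}

#' Screen a standard protein for stability
#'
#' Pearson correlation between the standard's per-run summaries and the
#' per-run medians of the endogenous sample intensities; the standard is
#' considered stable when r exceeds the cutoff (default 0.6, strict).
#' Zero variance in either vector leaves r undefined: the standard is
#' reported unstable with a warning.
#'
#' @param standard_summaries named per-run summary vector
#'   ([summarize_standard_protein()]).
#' @param sample_medians named per-run sample medians
#'   ([per_run_sample_medians()]).
#' @param cutoff stability cutoff on r (strict inequality).
#' @return list with `r` and `stable`.
#' @export
assess_standard_stability <- function(standard_summaries, sample_medians,
                                      cutoff = 0.6) {
  runs <- intersect(names(standard_summaries), names(sample_medians))
  x <- standard_summaries[runs]; y <- sample_medians[runs]
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stopf("need >= 3 paired run values to assess stability")
  if (sd(x) == 0 || sd(y) == 0) {
    warnf("zero variance: stability correlation undefined; reporting unstable")
    return(list(r = NA_real_, stable = FALSE))
  }
  r <- cor(x, y)
  list(r = r, stable = r > cutoff)
}

#' Per-run summary of the endogenous plasma signal
#'
#' The quantity the standard-protein summaries are screened against:
#' by default the per-run median over all endogenous light log2
#' intensities ("median"); `basis = "sum"` uses the per-run total instead.
#'
#' @param records quantification records.
#' @param basis `"median"` (default) or `"sum"`.
#' @return named numeric vector per run.
#' @export
per_run_sample_medians <- function(records, basis = c("median", "sum")) {
  basis <- match.arg(basis)
  sel <- !records$is_standard & records$channel == "light" &
    !is.na(records$log2_intensity)
  f <- if (basis == "median") median else sum
  vapply(split(records$log2_intensity[sel], records$run_id[sel]), f, 0)
}

#' Stage 2: standard-protein run-shift normalization
#'
#' Shifts every light intensity in a run by
#' `global median(standard summaries) - run summary` so the standard's
#' per-run summaries become constant across runs, removing systematic
#' sample-preparation bias. Refuses to normalize against a standard that
#' fails the stability screen; a standard whose summaries are already
#' constant (zero variance) yields zero shifts, which makes the operation
#' idempotent.
#'
#' @param records quantification records (after stage 1).
#' @param standard_id standard protein to normalize against.
#' @param check_stability run [assess_standard_stability()] first
#'   (default TRUE).
#' @param basis passed to [per_run_sample_medians()].
#' @param cutoff stability cutoff.
#' @return list with `records`, `shifts` (named per-run vector) and
#'   `stability`.
#' @export
normalize_by_standard <- function(records, standard_id, check_stability = TRUE,
                                  basis = "median", cutoff = 0.6) {
  summaries <- summarize_standard_protein(records, standard_id)
  stability <- NULL
  if (stats::sd(summaries, na.rm = TRUE) > 1e-12 && check_stability) {
    stability <- assess_standard_stability(summaries,
                                           per_run_sample_medians(records, basis),
                                           cutoff = cutoff)
    if (!stability$stable) {
      stopf("standard %s is unstable (r = %s <= %.2f); pick another standard or skip stage 2",
            standard_id, format(stability$r, digits = 3), cutoff)
    }
  }
  target <- median(summaries, na.rm = TRUE)
  shifts <- target - summaries
  shifts[is.na(shifts)] <- 0
  rec <- records
  idx <- which(rec$channel == "light" & rec$run_id %in% names(shifts))
  rec$log2_intensity[idx] <- rec$log2_intensity[idx] + shifts[rec$run_id[idx]]
  list(records = rec, shifts = shifts, stability = stability)
}

#' Equalize the grand medians of two abundance matrices
#'
#' Shifts matrix `b` by a single constant so its grand median over
#' observed cells equals that of matrix `a`; used to make a validation
#' cohort comparable to the training cohort before prediction.
#'
#' @param a,b `abundance_matrix` objects sharing at least one protein.
#' @return the shifted `b`, with the applied shift in attribute `"shift"`.
#' @export
equalize_cohort_medians <- function(a, b) {
  shared <- intersect(colnames(a$values), colnames(b$values))
  if (!length(shared)) stopf("the two matrices share no protein")
  ma <- med_obs(a$values); mb <- med_obs(b$values)
  if (is.na(ma) || is.na(mb)) stopf("cannot equalize: a matrix has no observed cells")
  shift <- ma - mb
  b$values <- b$values + shift
  attr(b, "shift") <- shift
  b
}

#' Tissue-phase sparse-feature filter
#'
#' Removes a feature when it is missing in more than five-sixths of all
#' runs, or missing in every run of at least one experimental group.
#'
#' @param feature_table list with `values` (features x runs matrix, NA =
#'   missing) and `groups` (per-run labels), as produced by
#'   [generate_feature_fixture()]; a bare matrix plus `groups` argument is
#'   also accepted.
#' @param groups per-run group labels (when `feature_table` is a matrix).
#' @param max_missing_frac removal threshold on the overall missing
#'   fraction (strict inequality; default 5/6).
#' @return the filtered table (same shape of input), with removed feature
#'   ids in attribute `"removed"`.
#' @export
filter_sparse_features <- function(feature_table, groups = NULL,
                                   max_missing_frac = 5 / 6) {
  if (is.list(feature_table) && !is.null(feature_table$values)) {
    values <- feature_table$values
    groups <- groups %||% feature_table$groups
  } else {
    values <- feature_table
  }
  if (is.null(groups) || length(groups) != ncol(values)) {
    stopf("`groups` must provide one label per run")
  }
  miss <- is.na(values)
  frac <- rowMeans(miss)
  all_missing_in_group <- Reduce(`|`, lapply(split(seq_len(ncol(values)), groups),
                                             function(cols) {
                                               rowSums(!miss[, cols, drop = FALSE]) == 0
                                             }))
  remove <- frac > max_missing_frac | all_missing_in_group
  out_values <- values[!remove, , drop = FALSE]
  out <- if (is.list(feature_table) && !is.null(feature_table$values)) {
    list(values = out_values, groups = groups)
  } else out_values
  attr(out, "removed") <- rownames(values)[remove]
  out
}

#' Scale normalization of a log2 feature table
#'
#' Equalizes the spread of the runs: each run (column) is centered at its
#' median and its median absolute deviation about that median is rescaled
#' to the geometric mean of the per-run MADs. Runs with fewer than two
#' observed values, or with zero MAD, are skipped with a warning.
#'
#' @param feature_table features x runs matrix of log2 values (NA allowed)
#'   or a list with a `values` element.
#' @return normalized table of the same shape; per-run scale factors in
#'   attribute `"scale_factors"`.
#' @export
scale_normalize <- function(feature_table) {
  is_list <- is.list(feature_table) && !is.null(feature_table$values)
  values <- if (is_list) feature_table$values else feature_table
  meds <- apply(values, 2, med_obs)
  mads <- vapply(seq_len(ncol(values)), function(j) {
    x <- values[, j]; x <- x[!is.na(x)]
    if (length(x) < 2L) return(NA_real_)
    median(abs(x - median(x)))
  }, 0)
  usable <- !is.na(mads) & mads > 0
  if (any(!usable)) {
    warnf("%d run(s) skipped in scale normalization (too few values or zero MAD)",
          sum(!usable))
  }
  if (!any(usable)) stopf("no run usable for scale normalization")
  target <- exp(mean(log(mads[usable])))
  factors <- ifelse(usable, target / mads, 1)
  out <- values
  for (j in which(usable)) {
    out[, j] <- meds[j] + (values[, j] - meds[j]) * factors[j]
  }
  res <- if (is_list) list(values = out, groups = feature_table$groups) else out
  attr(res, "scale_factors") <- setNames(factors, colnames(values))
  res
}
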