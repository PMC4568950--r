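# ROC/AUC machinery with bootstrap inference, confusion metrics,
# stratified subgroup evaluation, CEA comparison, decile response curves,
# probability surfaces, univariate tests and Ward clustering.

#' Area under the ROC curve
#'
#' `AUC = P(score_case > score_control) + 0.5 P(equal)`, computed from the
#' Mann-Whitney rank statistic; ties between a case and a control score
#' receive half credit. Equals the trapezoidal area under the empirical
#' ROC curve.
#'
#' @param scores numeric scores (higher = more case-like).
#' @param labels binary labels (TRUE/1 = case).
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stopf("both classes must be present")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Empirical ROC curve with optional bootstrap confidence interval
#'
#' Operating points are evaluated at every distinct score (rule: predict
#' case iff score >= threshold) plus sentinels; the AUC is computed with
#' [roc_auc()] and, when `B > 0`, a stratified percentile bootstrap CI is
#' attached.
#'
#' @inheritParams roc_auc
#' @param B bootstrap rounds for the CI (0 disables).
#' @param seed RNG seed for the bootstrap.
#' @param conf confidence level.
#' @return object of class `roc_curve`: `points` (threshold, sensitivity,
#'   specificity), `auc`, `ci_low`, `ci_high`, `n_bootstrap`, `seed`.
#' @export
roc_curve <- function(scores, labels, B = 0, seed = 1L, conf = 0.95) {
  labels <- as.logical(labels)
  thr <- c(-Inf, sort(unique(scores)), Inf)
  pts <- data.frame(
    threshold = thr,
    sensitivity = vapply(thr, function(t) mean(scores[labels] >= t), 0),
    specificity = vapply(thr, function(t) mean(scores[!labels] < t), 0)
  )
  auc <- roc_auc(scores, labels)
  ci <- c(NA_real_, NA_real_)
  if (B > 0) {
    bi <- bootstrap_auc_ci(scores, labels, B = B, seed = seed, conf = conf)
    ci <- c(bi$ci_low, bi$ci_high)
  }
  structure(list(points = pts, auc = auc, ci_low = ci[1], ci_high = ci[2],
                 n_bootstrap = B, seed = seed), class = "roc_curve")
}

#' Bootstrap confidence interval for an AUC
#'
#' Class-stratified nonparametric bootstrap of the subjects with a
#' percentile interval. Degenerate resamples cannot occur under stratified
#' resampling of both classes.
#'
#' @inheritParams roc_auc
#' @param B number of bootstrap samples (default 2000).
#' @param seed RNG seed.
#' @param conf confidence level (default 0.95).
#' @return list with `auc`, `ci_low`, `ci_high`, `B`, `seed`.
#' @export
bootstrap_auc_ci <- function(scores, labels, B = 2000, seed = 1L, conf = 0.95) {
  labels <- as.logical(labels)
  assert_count(B, "B")
  s1 <- scores[labels]; s0 <- scores[!labels]
  if (!length(s1) || !length(s0)) stopf("both classes must be present")
  aucs <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      x1 <- s1[sample.int(length(s1), replace = TRUE)]
      x0 <- s0[sample.int(length(s0), replace = TRUE)]
      roc_auc(c(x1, x0), rep(c(TRUE, FALSE), c(length(x1), length(x0))))
    }, 0)
  })
  alpha <- (1 - conf) / 2
  ci <- unname(quantile(aucs, c(alpha, 1 - alpha)))
  list(auc = roc_auc(scores, labels), ci_low = ci[1], ci_high = ci[2],
       B = B, seed = seed)
}

#' Paired bootstrap comparison of two AUCs
#'
#' Both score vectors are evaluated on the same subjects, so the curves
#' are not independent; a paired, class-stratified bootstrap of the
#' subjects yields the distribution of the AUC difference, and the
#' two-sided p-value is the proportion of the bootstrap distribution
#' crossing zero, doubled and capped at 1.
#'
#' @param scores_a,scores_b score vectors on the same subjects.
#' @inheritParams bootstrap_auc_ci
#' @return list with `delta_auc` (a minus b on the original data),
#'   `p_value`, `auc_a`, `auc_b`, `B`.
#' @export
compare_auc_bootstrap <- function(scores_a, scores_b, labels, B = 2000, seed = 1L) {
  labels <- as.logical(labels)
  if (length(scores_a) != length(scores_b) || length(scores_a) != length(labels)) {
    stopf("score vectors and labels must be parallel")
  }
  idx_case <- which(labels); idx_ctrl <- which(!labels)
  if (!length(idx_case) || !length(idx_ctrl)) stopf("both classes must be present")
  deltas <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- c(idx_case[sample.int(length(idx_case), replace = TRUE)],
               idx_ctrl[sample.int(length(idx_ctrl), replace = TRUE)])
      l <- labels[idx]
      roc_auc(scores_a[idx], l) - roc_auc(scores_b[idx], l)
    }, 0)
  })
  p <- min(1, 2 * min(mean(deltas <= 0), mean(deltas >= 0)))
  list(delta_auc = roc_auc(scores_a, labels) - roc_auc(scores_b, labels),
       p_value = p,
       auc_a = roc_auc(scores_a, labels), auc_b = roc_auc(scores_b, labels),
       B = B)
}

#' Confusion metrics at a fixed threshold
#'
#' Predict case iff score >= threshold; accuracy is
#' (TP + TN) / (P + N).
#'
#' @inheritParams roc_auc
#' @param threshold classification threshold.
#' @return list with `sensitivity`, `specificity`, `accuracy`, counts.
#' @export
confusion_metrics <- function(scores, labels, threshold) {
  labels <- as.logical(labels)
  pred <- scores >= threshold
  tp <- sum(pred & labels); tn <- sum(!pred & !labels)
  list(sensitivity = tp / sum(labels),
       specificity = tn / sum(!labels),
       accuracy = (tp + tn) / length(labels),
       tp = tp, tn = tn, fp = sum(pred & !labels), fn = sum(!pred & labels))
}

#' Build evaluation strata from subject metadata
#'
#' Standard stratifications of the CRC subjects: by clinical stage, by
#' tumor-size bin (\[0, 3.5), \[3.5, 6), \[6, Inf) cm), and by CEA
#' positivity (> cutoff ng/ml). CRC subjects with a missing stratifying
#' variable are excluded from that stratification (their count is
#' reported by [stratified_evaluate()]).
#'
#' @param metadata subject metadata table.
#' @param by `"stage"`, `"size"` or `"cea"`.
#' @param size_breaks tumor-diameter breaks in cm.
#' @param cea_cutoff CEA positivity cutoff in ng/ml (strict >).
#' @return named list of CRC subject-id vectors.
#' @export
make_strata <- function(metadata, by = c("stage", "size", "cea"),
                        size_breaks = c(3.5, 6), cea_cutoff = 5) {
  by <- match.arg(by)
  crc <- metadata[metadata$group == "CRC", ]
  switch(by,
    stage = lapply(split(crc$subject_id, factor(crc$stage, c("I", "II", "III", "IV"))),
                   as.character),
    size = {
      d <- crc$tumor_diameter_cm
      labs <- c(sprintf("<%.1fcm", size_breaks[1]),
                sprintf("%.1f-%.1fcm", size_breaks[1], size_breaks[2]),
                sprintf(">=%.1fcm", size_breaks[2]))
      bin <- cut(d, c(-Inf, size_breaks, Inf), labels = labs, right = FALSE)
      lapply(split(crc$subject_id, bin), as.character)
    },
    cea = {
      pos <- cea_classify(crc$cea_ng_ml, cutoff = cea_cutoff)
      list(`CEA_negative` = crc$subject_id[!is.na(pos) & !pos],
           `CEA_positive` = crc$subject_id[!is.na(pos) & pos])
    }
  )
}

#' Stratified evaluation of a signature model
#'
#' Evaluates each CRC stratum separately against the full shared control
#' group: ROC curve, AUC, and sensitivity/specificity/accuracy at the
#' fixed threshold.
#'
#' @param model a `signature_model` (or a named probability vector via
#'   `scores`).
#' @param matrix complete [abundance_matrix()] of the evaluation cohort.
#' @param metadata matching subject metadata.
#' @param strata named list of CRC subject-id vectors ([make_strata()]).
#' @param threshold classification threshold; defaults to the model's.
#' @param scores optional pre-computed probabilities named by subject id
#'   (then `model`/`matrix` may be NULL).
#' @return object of class `stratified_report`: per-stratum list of `n`,
#'   `auc`, `roc`, `metrics`; plus `n_unstratified_crc` (CRC subjects in
#'   no stratum, e.g. missing tumor size).
#' @export
stratified_evaluate <- function(model = NULL, matrix = NULL, metadata, strata,
                                threshold = NULL, scores = NULL) {
  if (is.null(scores)) {
    scores <- predict_probability(model, matrix)
  }
  threshold <- threshold %||% model$threshold
  controls <- metadata$subject_id[metadata$group != "CRC"]
  controls <- intersect(controls, names(scores))
  crc_all <- intersect(metadata$subject_id[metadata$group == "CRC"], names(scores))
  out <- lapply(strata, function(ids) {
    ids <- intersect(ids, names(scores))
    if (!length(ids)) return(list(n = 0L, auc = NA_real_, roc = NULL, metrics = NULL))
    s <- c(scores[ids], scores[controls])
    l <- rep(c(TRUE, FALSE), c(length(ids), length(controls)))
    list(n = length(ids),
         auc = roc_auc(s, l),
         roc = roc_curve(s, l),
         metrics = confusion_metrics(s, l, threshold))
  })
  structure(list(strata = out,
                 threshold = threshold,
                 n_controls = length(controls),
                 n_unstratified_crc = length(setdiff(crc_all, unlist(strata)))),
            class = "stratified_report")
}

#' Classify subjects by the clinical CEA rule
#'
#' Positive iff CEA > cutoff ng/ml (strict); NA values are excluded and
#' counted in attribute `"n_excluded"`.
#'
#' @param cea_values CEA concentrations in ng/ml.
#' @param cutoff positivity cutoff (default 5).
#' @return logical vector (NA preserved for missing input).
#' @export
cea_classify <- function(cea_values, cutoff = 5) {
  out <- cea_values > cutoff
  attr(out, "n_excluded") <- sum(is.na(cea_values))
  out
}

#' Decile response curve of a single protein
#'
#' Subjects are partitioned by rank of abundance into near-equal bins
#' (sizes differing by at most one, larger bins first; ties broken by
#' stable order), and the per-bin case proportion is reported against the
#' per-bin mean abundance. A loess smoother can be overlaid for
#' presentation.
#'
#' @param abundance numeric abundances (>= 10 subjects).
#' @param labels binary labels.
#' @param n_bins number of bins (default 10).
#' @param smooth also return a loess fit (span 0.75); presentational.
#' @return data.frame with `bin`, `n`, `mean_abundance`, `case_proportion`
#'   (and attribute `"smooth"` when requested).
#' @export
decile_response <- function(abundance, labels, n_bins = 10, smooth = FALSE) {
  labels <- as.logical(labels)
  n <- length(abundance)
  if (n < n_bins) stopf("need at least %d subjects", n_bins)
  ord <- order(abundance)  # stable for ties
  base_size <- n %/% n_bins
  sizes <- rep(base_size, n_bins)
  extra <- n %% n_bins
  if (extra) sizes[seq_len(extra)] <- base_size + 1L
  bin <- rep(seq_len(n_bins), sizes)
  df <- data.frame(
    bin = seq_len(n_bins),
    n = sizes,
    mean_abundance = vapply(split(abundance[ord], bin), mean, 0),
    case_proportion = vapply(split(as.numeric(labels[ord]), bin), mean, 0),
    row.names = NULL
  )
  if (smooth) {
    attr(df, "smooth") <- tryCatch(
      loess(case_proportion ~ mean_abundance, df, span = 0.75),
      error = function(e) NULL)
  }
  df
}

#' Predicted-probability curves along one protein
#'
#' Sweeps the abundance of one model protein over its observed range while
#' the other model proteins are fixed at chosen quantiles of their
#' training distribution; one curve per quantile specification.
#'
#' @param model a `signature_model`.
#' @param matrix training [abundance_matrix()] providing the observed
#'   ranges and quantiles.
#' @param varying_protein the protein to sweep (must be in the model).
#' @param fixed_specs list of named numeric vectors; each gives, per
#'   non-varying model protein, the quantile (in \[0,1\]) at which to fix
#'   it. Defaults to all-at-median.
#' @param n_grid grid points along the sweep.
#' @return data.frame with `curve`, `abundance`, `probability`.
#' @export
probability_surface <- function(model, matrix, varying_protein,
                                fixed_specs = NULL, n_grid = 50) {
  vals <- if (inherits(matrix, "abundance_matrix")) matrix$values else matrix
  if (!varying_protein %in% model$protein_ids) {
    stopf("unknown model protein: %s", varying_protein)
  }
  others <- setdiff(model$protein_ids, varying_protein)
  fixed_specs <- fixed_specs %||%
    list(median = setNames(rep(0.5, length(others)), others))
  xr <- range(vals[, varying_protein], na.rm = TRUE)
  grid <- seq(xr[1], xr[2], length.out = n_grid)
  curves <- lapply(names(fixed_specs), function(nm) {
    spec <- fixed_specs[[nm]]
    if (length(others) && !all(others %in% names(spec))) {
      stopf("fixed spec \"%s\" must assign a quantile to every non-varying model protein", nm)
    }
    fixed_vals <- vapply(others, function(p) {
      unname(quantile(vals[, p], spec[[p]], na.rm = TRUE))
    }, 0)
    eta <- model$intercept + model$coefficients[[varying_protein]] * grid +
      (if (length(others)) sum(model$coefficients[others] * fixed_vals) else 0)
    data.frame(curve = nm, abundance = grid, probability = plogis(eta),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, curves)
}

#' Two-sample pooled-variance t-test
#'
#' Two-sided. A degenerate comparison (zero pooled variance) yields p = 1
#' when the means are equal and p = 0 otherwise.
#'
#' @param a,b numeric vectors (each of length >= 2).
#' @return list with `t`, `p_value`, `df`, `mean_diff`.
#' @export
group_mean_test <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) stopf("each group needs >= 2 values")
  df <- length(a) + length(b) - 2
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / df
  d <- mean(a) - mean(b)
  if (sp2 == 0) {
    return(list(t = if (d == 0) 0 else sign(d) * Inf,
                p_value = if (d == 0) 1 else 0, df = df, mean_diff = d))
  }
  tstat <- d / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  list(t = tstat, p_value = 2 * pt(abs(tstat), df, lower.tail = FALSE),
       df = df, mean_diff = d)
}

#' Ward clustering of subjects by protein abundance
#'
#' Agglomerative hierarchical clustering of the subjects with Euclidean
#' distance and Ward linkage (`ward.D2`), as used for cohort heatmaps.
#' The matrix must be complete (impute first).
#'
#' @param matrix complete [abundance_matrix()] or bare matrix.
#' @return list with `order` (leaf order of subject ids), `merge`,
#'   `height`, and the underlying `hclust` object.
#' @export
ward_clustering <- function(matrix) {
  vals <- if (inherits(matrix, "abundance_matrix")) matrix$values else matrix
  if (any(is.na(vals))) stopf("matrix has missing cells; run impute_lod() first")
  if (nrow(vals) == 1L) {
    return(list(order = rownames(vals), merge = NULL, height = numeric(0),
                hclust = NULL))
  }
  hc <- hclust(dist(vals), method = "ward.D2")
  list(order = rownames(vals)[hc$order], merge = hc$merge, height = hc$height,
       hclust = hc)
}
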