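# Pipeline orchestration: configuration, logging and the report bundle.

#' Run the full signature-discovery pipeline
#'
#' Chains the stages end to end on a training and a validation cohort:
#' simulate (or read) the quantification tables, two-stage normalization,
#' protein summarization, cross-cohort median equalization, missingness
#' filtering and LOD imputation, differential abundance, consensus
#' cross-validated signature discovery on the training cohort, and ROC
#' evaluation (overall and stratified) on the validation cohort. All
#' stages are seeded, and the report bundle is byte-reproducible for a
#' fixed configuration.
#'
#' @param config a configuration list or the path of a JSON file. Must
#'   contain either a `simulation` block (arguments for [sim_config()],
#'   plus optional `validation` overrides such as
#'   `list(n_crc = 202, n_benign = 17, n_healthy = 50)`) or an `input`
#'   block naming `training_quant`, `training_metadata`,
#'   `validation_quant`, `validation_metadata` (and optional `dialect`,
#'   `intensities`). An optional `params` block tunes `k`, `min_count`,
#'   `alpha`, `fc_cutoff`, `use_adjusted`, `B` and `seed`.
#' @param out_dir output directory for the report bundle (created).
#' @return invisibly, a list with the fitted `model`, the `cv_report`, the
#'   evaluation list, and the bundle paths.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (is.null(config$simulation) && is.null(config$input)) {
    stopf("configuration error: need a `simulation` or an `input` block")
  }
  params <- modifyList(list(k = 10, min_count = 5, alpha = 0.05,
                            fc_cutoff = 1.1, use_adjusted = TRUE,
                            B = 2000, seed = 1L),
                       config$params %||% list())
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline_log.txt")
  log_lines <- character(0)
  log <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    message("[srmsig] ", line)
  }

  # ---- stage: inputs ---------------------------------------------------
  if (!is.null(config$simulation)) {
    sim <- config$simulation
    overrides <- sim[setdiff(names(sim), "validation")]
    cfg_train <- do.call(sim_config, overrides)
    val_over <- modifyList(overrides, as.list(sim$validation %||% list()))
    cfg_val <- do.call(sim_config, val_over)
    log("simulate: seed %d, training %d/%d/%d, validation %d/%d/%d, %d proteins",
        cfg_train$seed, cfg_train$n_crc, cfg_train$n_benign, cfg_train$n_healthy,
        cfg_val$n_crc, cfg_val$n_benign, cfg_val$n_healthy, cfg_train$n_proteins)
    train <- generate_cohort(cfg_train, "training")
    val <- generate_cohort(cfg_val, "validation")
    truth <- train$truth
  } else {
    inp <- config$input
    need <- c("training_quant", "training_metadata",
              "validation_quant", "validation_metadata")
    if (!all(need %in% names(inp))) {
      stopf("configuration error: `input` must name %s", paste(need, collapse = ", "))
    }
    dialect <- inp$dialect %||% "native"
    intensities <- inp$intensities %||% "log2"
    log("read: dialect %s, intensities %s", dialect, intensities)
    train <- list(records = read_quant_table(inp$training_quant, dialect,
                                             intensities = intensities),
                  metadata = read_metadata(inp$training_metadata))
    val <- list(records = read_quant_table(inp$validation_quant, dialect,
                                           intensities = intensities),
                metadata = read_metadata(inp$validation_metadata))
    truth <- NULL
  }

  # ---- stage: normalization + summarization ---------------------------
  process_cohort <- function(cohort, label) {
    n1 <- normalize_by_reference(cohort$records)
    log("normalize[%s]: stage 1 reference normalization of %d protein(s)",
        label, length(n1$report$reference_targets))
    std_ids <- unique(n1$records$protein_id[n1$records$is_standard])
    chosen <- NULL
    rec <- n1$records
    medians <- per_run_sample_medians(rec)
    for (sid in std_ids) {
      st <- assess_standard_stability(summarize_standard_protein(rec, sid), medians)
      log("normalize[%s]: standard %s r = %.3f (%s)", label, sid, st$r,
          if (st$stable) "stable" else "unstable")
      if (st$stable && is.null(chosen)) chosen <- list(id = sid, r = st$r)
    }
    if (!is.null(chosen)) {
      n2 <- normalize_by_standard(rec, chosen$id, check_stability = FALSE)
      rec <- n2$records
      log("normalize[%s]: stage 2 run-shift against %s", label, chosen$id)
    } else {
      warnf("no stable standard protein in cohort %s; stage 2 skipped", label)
      log("normalize[%s]: stage 2 skipped (no stable standard)", label)
    }
    mat <- summarize_protein_abundance(rec, cohort_label = label)
    log("summarize[%s]: %d subjects x %d proteins, %s missing cells",
        label, nrow(mat$values), ncol(mat$values), pct(mean(is.na(mat$values))))
    list(matrix = mat, standard = chosen)
  }
  ptr <- process_cohort(train, "training")
  pva <- process_cohort(val, "validation")

  # ---- stage: predictive preprocessing --------------------------------
  mval <- equalize_cohort_medians(ptr$matrix, pva$matrix)
  log("equalize: validation shifted by %.4f", attr(mval, "shift"))
  mtr <- filter_missing_proteins(ptr$matrix, max_frac = 0.40)
  log("filter: %d protein(s) removed for >40%% missingness; %d kept",
      length(attr(mtr, "removed")), ncol(mtr$values))
  shared <- intersect(colnames(mtr$values), colnames(mval$values))
  mval$values <- mval$values[, shared, drop = FALSE]
  mtr$values <- mtr$values[, shared, drop = FALSE]
  mtr <- impute_lod(mtr)
  mval <- impute_lod(mval)

  is_case_tr <- train$metadata$group[match(rownames(mtr$values),
                                           train$metadata$subject_id)] == "CRC"
  is_case_va <- val$metadata$group[match(rownames(mval$values),
                                         val$metadata$subject_id)] == "CRC"

  diff_tr <- differential_abundance(mtr, is_case_tr, preset = "plasma",
                                    alpha = params$alpha,
                                    fc_cutoff = params$fc_cutoff,
                                    use_adjusted = params$use_adjusted)
  diff_va <- differential_abundance(mval, is_case_va, preset = "plasma",
                                    alpha = params$alpha,
                                    fc_cutoff = params$fc_cutoff,
                                    use_adjusted = params$use_adjusted)
  log("differential: %d/%d significant (training), %d/%d (validation)",
      sum(diff_tr$significant), nrow(diff_tr),
      sum(diff_va$significant), nrow(diff_va))

  # ---- stage: signature discovery -------------------------------------
  cv <- consensus_cv(mtr, is_case_tr, k = params$k, min_count = params$min_count,
                     alpha = params$alpha, fc_cutoff = params$fc_cutoff,
                     use_adjusted = params$use_adjusted, seed = params$seed)
  model <- cv$model
  log("discover: consensus of %d protein(s) {%s}, threshold %.3f",
      length(model$protein_ids), paste(model$protein_ids, collapse = ", "),
      model$threshold)

  # ---- stage: evaluation on the validation cohort ---------------------
  evaluation <- NULL
  if (length(model$protein_ids)) {
    probs <- predict_probability(model, mval)
    auc_ci <- bootstrap_auc_ci(probs, is_case_va, B = params$B, seed = params$seed)
    cm <- confusion_metrics(probs, is_case_va, model$threshold)
    log("evaluate: validation AUC %.3f [%.3f, %.3f], accuracy %.3f at %.3f",
        auc_ci$auc, auc_ci$ci_low, auc_ci$ci_high, cm$accuracy, model$threshold)
    strat <- lapply(c(stage = "stage", size = "size", cea = "cea"), function(by) {
      rep_ <- stratified_evaluate(model, mval, val$metadata,
                                  make_strata(val$metadata, by),
                                  threshold = model$threshold)
      lapply(rep_$strata, function(s) {
        list(n = s$n, auc = s$auc,
             accuracy = if (!is.null(s$metrics)) s$metrics$accuracy,
             sensitivity = if (!is.null(s$metrics)) s$metrics$sensitivity)
      })
    })
    # CEA as a competing classifier on subjects with a CEA measurement
    cea <- val$metadata$cea_ng_ml[match(names(probs), val$metadata$subject_id)]
    keep <- !is.na(cea)
    cea_cmp <- compare_auc_bootstrap(probs[keep], cea[keep], is_case_va[keep],
                                     B = params$B, seed = params$seed)
    cea_cm <- confusion_metrics(as.numeric(cea_classify(cea[keep])),
                                is_case_va[keep], 1)
    evaluation <- list(
      auc = auc_ci$auc, ci_low = auc_ci$ci_low, ci_high = auc_ci$ci_high,
      threshold = model$threshold,
      sensitivity = cm$sensitivity, specificity = cm$specificity,
      accuracy = cm$accuracy,
      strata = strat,
      cea_comparison = list(delta_auc = cea_cmp$delta_auc,
                            p_value = cea_cmp$p_value,
                            auc_signature = cea_cmp$auc_a,
                            auc_cea = cea_cmp$auc_b,
                            accuracy_cea_rule = cea_cm$accuracy),
      B = params$B, seed = params$seed
    )
  } else {
    log("evaluate: skipped (no stable signature)")
  }

  # ---- stage: report bundle -------------------------------------------
  paths <- list(
    training_abundance = file.path(out_dir, "training_abundance.tsv"),
    validation_abundance = file.path(out_dir, "validation_abundance.tsv"),
    differential_training = file.path(out_dir, "differential_training.tsv"),
    differential_validation = file.path(out_dir, "differential_validation.tsv"),
    signature = file.path(out_dir, "signature.json"),
    cv_report = file.path(out_dir, "cv_report.json"),
    normalization = file.path(out_dir, "normalization_report.json"),
    evaluation = file.path(out_dir, "evaluation.json"),
    log = log_path
  )
  write_abundance_matrix(mtr, paths$training_abundance)
  write_abundance_matrix(mval, paths$validation_abundance)
  write_differential_table(diff_tr, paths$differential_training)
  write_differential_table(diff_va, paths$differential_validation)
  write_signature_json(model, paths$signature)
  write_signature_json(cv$report, paths$cv_report)
  writeLines(jsonlite::toJSON(list(
    schema = "srmsig/normalization_report/1",
    training_standard = ptr$standard, validation_standard = pva$standard,
    validation_median_shift = attr(mval, "shift") %||% NULL,
    removed_proteins = attr(mtr, "removed")
  ), auto_unbox = TRUE, digits = 10, null = "null"), paths$normalization)
  writeLines(jsonlite::toJSON(list(schema = "srmsig/evaluation/1",
                                   evaluation = evaluation),
                              auto_unbox = TRUE, digits = 10, null = "null"),
             paths$evaluation)
  writeLines(log_lines, log_path)

  invisible(list(model = model, cv_report = cv$report, evaluation = evaluation,
                 truth = truth, paths = paths,
                 training_matrix = mtr, validation_matrix = mval))
}

#' Write a differential-abundance table to TSV
#'
#' Stable column order matching the `DifferentialResult` schema.
#' @param diff data.frame from [differential_abundance()].
#' @param path output file.
#' @export
write_differential_table <- function(diff, path) {
  cols <- c("protein_id", "log2fc", "se_log2", "dof", "p_value", "adj_p",
            "fc_original", "se_original", "n_case", "n_control", "significant")
  out <- diff[, cols]
  for (col in setdiff(cols, c("protein_id", "significant", "n_case", "n_control"))) {
    out[[col]] <- formatC(out[[col]], digits = 10, format = "g")
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}
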