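# Signature discovery: LOD imputation, missingness filtering, logistic
# regression with stepwise AIC selection, consensus cross-validation,
# threshold selection and the exhaustive bootstrapped subset search.

#' Impute missing abundances at the limit of detection
#'
#' Every masked cell of a protein is set to the minimal observed relative
#' quantification of that protein within the same cohort (its empirical
#' limit of detection). Observed cells are never changed. A protein with
#' no observed value in some cohort cannot be imputed and raises an error
#' naming it.
#'
#' @param matrix an [abundance_matrix()].
#' @return the imputed matrix (no missing cells).
#' @export
impute_lod <- function(matrix) {
  vals <- matrix$values
  for (co in unique(matrix$cohort)) {
    rows <- matrix$cohort == co
    block <- vals[rows, , drop = FALSE]
    mins <- suppressWarnings(apply(block, 2, min, na.rm = TRUE))
    bad <- !is.finite(mins) & colSums(is.na(block)) > 0
    if (any(bad)) {
      stopf("cannot impute protein(s) entirely missing in cohort %s: %s",
            co, paste(colnames(vals)[bad], collapse = ", "))
    }
    na_idx <- which(is.na(block), arr.ind = TRUE)
    if (nrow(na_idx)) block[na_idx] <- mins[na_idx[, 2]]
    vals[rows, ] <- block
  }
  matrix$values <- vals
  matrix
}

#' Filter proteins with excessive missingness
#'
#' Removes proteins for which more than `max_frac` of the subjects have
#' missing relative quantifications (strict inequality; default 40%).
#' Applied before imputation.
#'
#' @param matrix an [abundance_matrix()].
#' @param max_frac removal threshold on the missing fraction.
#' @return the filtered matrix; removed protein ids in attribute
#'   `"removed"`.
#' @export
filter_missing_proteins <- function(matrix, max_frac = 0.40) {
  frac <- colMeans(is.na(matrix$values))
  remove <- frac > max_frac
  out <- matrix
  out$values <- matrix$values[, !remove, drop = FALSE]
  attr(out, "removed") <- colnames(matrix$values)[remove]
  out
}

#' Maximum-likelihood logistic regression
#'
#' Fit by iteratively reweighted least squares (at most 30 iterations).
#' Complete or quasi-complete separation is flagged -- not silently
#' accepted -- when any fitted linear predictor exceeds 30 in absolute
#' value or the fit fails to converge.
#'
#' @param x numeric predictor matrix (subjects x proteins), or NULL for an
#'   intercept-only model.
#' @param y binary response (0/1 or logical).
#' @param covariates optional additional predictor matrix (e.g. age),
#'   always retained by [stepwise_select()].
#' @return list with `coefficients` (named; `(Intercept)` first),
#'   `loglik`, `aic`, `converged`, `separation`, `fitted`.
#' @export
fit_logistic <- function(x = NULL, y, covariates = NULL) {
  y <- as.numeric(y)
  if (length(unique(y)) < 2L) stopf("both classes must be present in `y`")
  X <- cbind(`(Intercept)` = rep(1, length(y)),
             if (!is.null(x)) as.matrix(x),
             if (!is.null(covariates)) as.matrix(covariates))
  fit <- suppressWarnings(
    glm.fit(X, y, family = binomial(), control = list(maxit = 30))
  )
  eta <- as.vector(X %*% ifelse(is.na(fit$coefficients), 0, fit$coefficients))
  mu <- plogis(eta)
  eps <- 1e-12
  ll <- sum(y * log(pmax(mu, eps)) + (1 - y) * log(pmax(1 - mu, eps)))
  k <- sum(!is.na(fit$coefficients))
  list(coefficients = fit$coefficients,
       loglik = ll,
       aic = -2 * ll + 2 * k,
       converged = isTRUE(fit$converged),
       separation = max(abs(eta)) > 30 || !isTRUE(fit$converged),
       fitted = mu)
}

#' Bidirectional stepwise selection by AIC
#'
#' Greedy search starting (by default) from the intercept-only model: at
#' each step every single-protein addition and drop is evaluated and the
#' move with the lowest AIC is applied if it improves on the current AIC;
#' the search stops otherwise. Fits flagged for separation are excluded
#' from the candidate moves. The accepted AIC sequence is strictly
#' decreasing.
#'
#' @param x predictor matrix (subjects x candidate proteins).
#' @param y binary response.
#' @param covariates optional always-included covariate matrix.
#' @param start `"empty"` (default) or `"full"`.
#' @return list with `selected` (protein ids, possibly empty),
#'   `aic_trace`, and the final `fit`.
#' @export
stepwise_select <- function(x, y, covariates = NULL, start = c("empty", "full")) {
  start <- match.arg(start)
  candidates <- colnames(x) %||% character(0)
  current <- if (start == "empty") character(0) else candidates
  fit_for <- function(set) {
    fit_logistic(if (length(set)) x[, set, drop = FALSE], y, covariates)
  }
  cur_fit <- fit_for(current)
  trace <- cur_fit$aic
  repeat {
    moves <- c(lapply(setdiff(candidates, current), function(p) union(current, p)),
               lapply(current, function(p) setdiff(current, p)))
    if (!length(moves)) break
    fits <- lapply(moves, function(set) tryCatch(fit_for(set), error = function(e) NULL))
    ok <- vapply(fits, function(f) !is.null(f) && !f$separation, TRUE)
    if (!any(ok)) break
    aics <- vapply(fits[ok], `[[`, 0, "aic")
    best <- which.min(aics)
    if (aics[best] >= cur_fit$aic - 1e-10) break
    current <- moves[ok][[best]]
    cur_fit <- fits[ok][[best]]
    trace <- c(trace, cur_fit$aic)
  }
  list(selected = current, aic_trace = trace, fit = cur_fit)
}

new_signature_model <- function(protein_ids, coefficients, intercept,
                                threshold = 0.5, covariates = character(0),
                                covariate_coefficients = numeric(0),
                                fold_selection_counts = NULL) {
  stopifnot(length(coefficients) == length(protein_ids))
  structure(list(protein_ids = protein_ids,
                 coefficients = setNames(as.numeric(coefficients), protein_ids),
                 intercept = as.numeric(intercept),
                 threshold = threshold,
                 covariates = covariates,
                 covariate_coefficients = setNames(as.numeric(covariate_coefficients),
                                                   covariates),
                 fold_selection_counts = fold_selection_counts),
            class = "signature_model")
}

#' @export
print.signature_model <- function(x, ...) {
  cat(sprintf("<signature_model> %d protein(s), threshold %.3f\n",
              length(x$protein_ids), x$threshold))
  if (length(x$protein_ids)) {
    print(round(x$coefficients, 4))
  } else {
    cat("  (no stable signature: intercept-only model)\n")
  }
  invisible(x)
}

#' Predicted disease probability of a signature model
#'
#' Inverse-logit of the linear predictor over the model's proteins (and
#' covariates, if any). All model proteins must be present and observed.
#'
#' @param model a `signature_model`.
#' @param matrix an [abundance_matrix()] or bare subjects x proteins
#'   matrix.
#' @param covariates optional covariate matrix matching the model's
#'   covariates.
#' @return named numeric vector of probabilities in (0, 1).
#' @export
predict_probability <- function(model, matrix, covariates = NULL) {
  vals <- if (inherits(matrix, "abundance_matrix")) matrix$values else matrix
  missing_p <- setdiff(model$protein_ids, colnames(vals))
  if (length(missing_p)) {
    stopf("matrix lacks model protein(s): %s", paste(missing_p, collapse = ", "))
  }
  eta <- rep(model$intercept, nrow(vals))
  if (length(model$protein_ids)) {
    eta <- eta + as.vector(vals[, model$protein_ids, drop = FALSE] %*%
                             model$coefficients)
  }
  if (length(model$covariates)) {
    if (is.null(covariates)) stopf("model uses covariates: supply `covariates`")
    eta <- eta + as.vector(as.matrix(covariates)[, model$covariates, drop = FALSE] %*%
                             model$covariate_coefficients)
  }
  if (any(is.na(eta))) stopf("missing abundances for model proteins; impute first")
  setNames(plogis(eta), rownames(vals))
}

#' Choose the classification threshold by best training accuracy
#'
#' Candidate thresholds are the midpoints between consecutive sorted
#' unique probabilities plus the 0 and 1 sentinels; the candidate with the
#' highest accuracy (rule: predict case iff probability >= threshold) is
#' returned, ties broken toward the smallest threshold.
#'
#' @param probabilities predicted probabilities.
#' @param labels binary labels (TRUE/1 = case).
#' @return the selected threshold.
#' @export
choose_threshold <- function(probabilities, labels) {
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2L) stopf("both classes must be present")
  u <- sort(unique(probabilities))
  cand <- c(0, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, 1)
  acc <- vapply(cand, function(t) mean((probabilities >= t) == labels), 0)
  cand[which.max(acc)]
}

# Stratified, seeded fold assignment keyed by sorted subject id, so the
# folds do not depend on row order.
assign_folds <- function(subject_ids, is_case, k, seed) {
  fold <- setNames(integer(length(subject_ids)), subject_ids)
  with_seed(seed, {
    for (cls in c(TRUE, FALSE)) {
      ids <- sort(subject_ids[is_case == cls])
      ids <- sample(ids)
      fold[ids] <- rep_len(seq_len(k), length(ids))
    }
  })
  fold
}

#' Consensus cross-validated signature discovery
#'
#' k-fold stratified cross-validation on the training cohort. Within each
#' fold, the candidate list is narrowed by a differential-abundance filter
#' on the k-1 training folds ([differential_abundance()], plasma preset),
#' the surviving proteins enter a stepwise-AIC logistic regression
#' ([stepwise_select()]), and the selected model is scored by held-out
#' AUC. The consensus signature consists of the proteins selected in at
#' least `min_count` folds; the final model is refit on the full training
#' set with those proteins and its threshold set by [choose_threshold()].
#' An empty consensus yields an explicit intercept-only "no stable
#' signature" model, not an error.
#'
#' @param matrix complete (imputed) [abundance_matrix()] of the training
#'   cohort.
#' @param is_case logical per subject, TRUE for the disease group.
#' @param k number of folds (>= 2; 10 by default, 8-fold variant
#'   supported with `min_count = 4`... see `min_count`).
#' @param min_count consensus rule: selected in at least this many folds
#'   (default 5 for k = 10).
#' @param alpha,fc_cutoff,use_adjusted per-fold differential filter
#'   parameters (see [differential_abundance()]).
#' @param covariates optional covariate matrix (e.g. age) carried through
#'   every fit.
#' @param seed RNG seed driving the fold assignment.
#' @return list with `report` (class `cv_report`: per-fold selections,
#'   held-out AUCs, fold assignment, parameters) and `model` (a
#'   `signature_model`).
#' @export
consensus_cv <- function(matrix, is_case, k = 10, min_count = 5,
                         alpha = 0.05, fc_cutoff = 1.1, use_adjusted = TRUE,
                         covariates = NULL, seed = 1L) {
  assert_count(k, "k", min = 2L)
  vals <- matrix$values
  if (any(is.na(vals))) stopf("matrix has missing cells; run impute_lod() first")
  is_case <- as.logical(is_case)
  subjects <- rownames(vals)
  fold <- assign_folds(subjects, is_case, k, seed)

  fold_sets <- vector("list", k)
  fold_auc <- rep(NA_real_, k)
  for (f in seq_len(k)) {
    train <- fold[subjects] != f
    da <- differential_abundance(vals[train, , drop = FALSE], is_case[train],
                                 preset = "plasma", alpha = alpha,
                                 fc_cutoff = fc_cutoff,
                                 use_adjusted = use_adjusted)
    cand <- da$protein_id[da$significant]
    sel <- if (length(cand)) {
      stepwise_select(vals[train, cand, drop = FALSE], is_case[train],
                      covariates = if (!is.null(covariates))
                        covariates[train, , drop = FALSE])$selected
    } else character(0)
    fold_sets[[f]] <- sel
    fit <- fit_logistic(if (length(sel)) vals[train, sel, drop = FALSE],
                        is_case[train],
                        if (!is.null(covariates)) covariates[train, , drop = FALSE])
    test <- !train
    if (length(unique(is_case[test])) == 2L) {
      co <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
      Xt <- cbind(1, if (length(sel)) vals[test, sel, drop = FALSE],
                  if (!is.null(covariates)) covariates[test, , drop = FALSE])
      fold_auc[f] <- roc_auc(plogis(as.vector(Xt %*% co)), is_case[test])
    }
  }

  counts <- table(unlist(fold_sets))
  consensus <- sort(names(counts)[counts >= min_count])
  count_vec <- setNames(as.integer(counts), names(counts))

  if (length(consensus)) {
    final <- fit_logistic(vals[, consensus, drop = FALSE], is_case, covariates)
    co <- final$coefficients
    model <- new_signature_model(
      protein_ids = consensus,
      coefficients = co[consensus],
      intercept = co[["(Intercept)"]],
      covariates = colnames(covariates) %||% character(0),
      covariate_coefficients = if (!is.null(covariates))
        co[colnames(covariates)] else numeric(0),
      fold_selection_counts = count_vec
    )
    probs <- predict_probability(model, vals, covariates)
    model$threshold <- choose_threshold(probs, is_case)
  } else {
    base_rate <- mean(is_case)
    model <- new_signature_model(character(0), numeric(0),
                                 intercept = qlogis(min(max(base_rate, 1e-6), 1 - 1e-6)),
                                 fold_selection_counts = count_vec)
    model$no_stable_signature <- TRUE
  }

  report <- structure(list(
    fold_selected = fold_sets, fold_auc = fold_auc, fold_assignment = fold,
    selection_counts = count_vec, consensus = consensus,
    parameters = list(k = k, min_count = min_count, alpha = alpha,
                      fc_cutoff = fc_cutoff, use_adjusted = use_adjusted,
                      seed = seed)
  ), class = "cv_report")
  list(report = report, model = model)
}

#' Exhaustive bootstrapped subset search
#'
#' Enumerates every protein subset of size 1..`max_size` (all
#' \eqn{\sum_k C(p, k)} models), validates each with `B` out-of-bag
#' bootstrap rounds (class-stratified resampling with replacement for
#' training, AUC on the out-of-bag subjects), and ranks models by median
#' AUC. Proteins of the models tying the best median AUC are ranked by
#' their frequency among those models. The same pre-drawn bootstrap
#' resamples are used for every model so rankings are paired.
#'
#' At the full scale of a real study (70 proteins, sizes up to 5: about
#' 13 million models) the enumeration is refused unless `allow_large =
#' TRUE`; the default pool cap is 15 proteins.
#'
#' @param matrix complete [abundance_matrix()] or bare matrix.
#' @param is_case logical response.
#' @param max_size maximal subset size (default 5).
#' @param B bootstrap rounds per model (default 100).
#' @param seed RNG seed for the bootstrap resamples.
#' @param max_proteins refusal cap on the candidate pool size.
#' @param allow_large lift the cap.
#' @return object of class `exhaustive_result`: `models` (data.frame with
#'   `proteins`, `size`, `median_auc`, ranked), `protein_frequency` (among
#'   top-tied models), `n_models`, `parameters`.
#' @export
exhaustive_search <- function(matrix, is_case, max_size = 5, B = 100, seed = 1L,
                              max_proteins = 15, allow_large = FALSE) {
  vals <- if (inherits(matrix, "abundance_matrix")) matrix$values else matrix
  if (any(is.na(vals))) stopf("matrix has missing cells; impute first")
  is_case <- as.logical(is_case)
  p <- ncol(vals)
  max_size <- min(max_size, p)
  n_models <- sum(vapply(seq_len(max_size), function(k) choose(p, k), 0))
  if (p > max_proteins && !allow_large) {
    stopf("pool of %d proteins implies %s models (sizes 1..%d); restrict the candidate pool or set allow_large = TRUE",
          p, format(n_models, big.mark = ","), max_size)
  }

  boots <- draw_bootstrap_rounds(is_case, B, seed)

  subsets <- unlist(lapply(seq_len(max_size), function(k) {
    asplit(combn(colnames(vals), k), 2)
  }), recursive = FALSE)

  med_auc <- vapply(subsets, function(set) {
    aucs <- vapply(seq_len(B), function(b) {
      tr <- boots$train[[b]]; oob <- boots$oob[[b]]
      f <- tryCatch(fit_logistic(vals[tr, set, drop = FALSE], is_case[tr]),
                    error = function(e) NULL)
      if (is.null(f)) return(NA_real_)
      co <- ifelse(is.na(f$coefficients), 0, f$coefficients)
      eta <- co[1] + as.vector(vals[oob, set, drop = FALSE] %*% co[-1])
      roc_auc(eta, is_case[oob])
    }, 0)
    median(aucs, na.rm = TRUE)
  }, 0)

  ord <- order(med_auc, decreasing = TRUE)
  models <- data.frame(
    proteins = vapply(subsets[ord], paste, "", collapse = "+"),
    size = vapply(subsets[ord], length, 0L),
    median_auc = med_auc[ord], stringsAsFactors = FALSE
  )
  top <- abs(med_auc[ord] - med_auc[ord][1]) < 1e-12
  freq <- sort(table(unlist(subsets[ord][top])), decreasing = TRUE)

  structure(list(models = models,
                 protein_frequency = freq,
                 n_models = n_models,
                 n_redrawn = boots$n_redrawn,
                 parameters = list(max_size = max_size, B = B, seed = seed)),
            class = "exhaustive_result")
}

# Pre-draw B class-stratified bootstrap resamples; rounds whose out-of-bag
# set lacks a class are redrawn (counted).
draw_bootstrap_rounds <- function(is_case, B, seed) {
  n <- length(is_case)
  idx_case <- which(is_case); idx_ctrl <- which(!is_case)
  train <- vector("list", B); oob <- vector("list", B)
  n_redrawn <- 0L
  with_seed(seed, {
    for (b in seq_len(B)) {
      repeat {
        tr <- c(sample(idx_case, length(idx_case), TRUE),
                sample(idx_ctrl, length(idx_ctrl), TRUE))
        out <- setdiff(seq_len(n), tr)
        if (any(is_case[out]) && any(!is_case[out])) break
        n_redrawn <- n_redrawn + 1L
      }
      train[[b]] <- tr; oob[[b]] <- out
    }
  })
  list(train = train, oob = oob, n_redrawn = n_redrawn)
}

#' Serialize a signature model (or CV report) to JSON
#'
#' @param x a `signature_model` or `cv_report`.
#' @param path output file.
#' @export
write_signature_json <- function(x, path) {
  obj <- if (inherits(x, "signature_model")) {
    list(schema = "srmsig/signature_model/1",
         protein_ids = x$protein_ids,
         coefficients = as.list(x$coefficients),
         intercept = x$intercept,
         threshold = x$threshold,
         covariates = x$covariates,
         covariate_coefficients = as.list(x$covariate_coefficients),
         fold_selection_counts = as.list(x$fold_selection_counts %||% integer(0)),
         no_stable_signature = isTRUE(x$no_stable_signature))
  } else if (inherits(x, "cv_report")) {
    list(schema = "srmsig/cv_report/1",
         fold_selected = x$fold_selected,
         fold_auc = x$fold_auc,
         selection_counts = as.list(x$selection_counts),
         consensus = x$consensus,
         parameters = x$parameters)
  } else stopf("unsupported object")
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = 10, null = "null"),
             path)
  invisible(path)
}
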