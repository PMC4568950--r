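# Synthetic SRM cohort generator.
#
# Emulates the structure of a targeted plasma glycoproteomics case-control
# study: one LC-SRM run per subject, 1-3 peptides per protein, a heavy
# stable-isotope reference paired with every endogenous peptide, two spiked
# bovine standard glycoproteins, run-level acquisition drift, batch-level
# sample-preparation shifts, left-censoring at a limit of detection, and a
# small planted marker panel (four up-regulated, one down-regulated by
# default) whose effects the downstream analysis should recover.

#' Simulation configuration for a synthetic SRM cohort
#'
#' All intensities are on the log2 scale. The intensity model is additive:
#' \deqn{y = baseline_p + peptide_{pj} + subject_{sp} + group_{sp} +
#'       batch_b + run_r + \epsilon}
#' Heavy reference peptides share the peptide and run terms (they are
#' spiked after sample preparation, so they track acquisition drift but not
#' preparation bias); spiked standard proteins share the batch and run
#' terms but carry no subject or group term (they are added at equal
#' amounts to every sample before preparation).
#'
#' @param n_crc,n_benign,n_healthy subjects per diagnostic group.
#' @param n_proteins number of endogenous candidate proteins.
#' @param peptides_per_protein integer range (min, max) of peptides per
#'   protein; each protein draws uniformly from it.
#' @param n_signature number of planted marker proteins.
#' @param planted_log2fc signed log2 fold-change per marker (CRC minus
#'   control); length `n_signature`. The default plants four positive and
#'   one negative marker with |log2FC| in \[0.4, 1\].
#' @param subject_sd biological between-subject SD (log2 units).
#' @param peptide_sd SD of the fixed per-peptide response offsets.
#' @param run_sd SD of per-run acquisition drift shifts.
#' @param batch_sd SD of per-batch sample-preparation shifts.
#' @param noise_sd SD of i.i.d. measurement noise per record. The source
#'   study does not state a plasma noise model; this is an explicit
#'   assumption of the generator.
#' @param baseline_range (min, max) of uniform baseline log2 abundances;
#'   the default spans ~6 orders of magnitude (20 log2 units).
#' @param lod limit of detection (log2 units): endogenous light intensities
#'   below it are emitted as missing.
#' @param random_missing_rate extra missing-completely-at-random fraction
#'   applied to endogenous light records, in \[0, 1).
#' @param tumor_size_effect per-cm log2 slope of the size-responsive
#'   markers (applied with the sign of each marker's planted effect).
#' @param cea_params list with `meanlog` (named: healthy, benign, I-IV) and
#'   `sdlog` for the per-subject lognormal CEA draw (ng/ml).
#' @param age_shift mean age difference (years) of CRC subjects vs
#'   controls.
#' @param n_batches number of sample-preparation batches.
#' @param stage_props unnormalized stage I-IV proportions for CRC
#'   subjects.
#' @param seed integer; fully determines the generated cohort.
#' @return object of class `srm_config`.
#' @export
sim_config <- function(n_crc = 100, n_benign = 34, n_healthy = 66,
                       n_proteins = 70,
                       peptides_per_protein = c(1L, 3L),
                       n_signature = 5,
                       planted_log2fc = NULL,
                       subject_sd = 0.5, peptide_sd = 0.7,
                       run_sd = 0.3, batch_sd = 0.5, noise_sd = 0.2,
                       baseline_range = c(8, 28),
                       lod = 10,
                       random_missing_rate = 0.02,
                       tumor_size_effect = 0.15,
                       cea_params = NULL,
                       age_shift = 5,
                       n_batches = 4,
                       stage_props = c(I = 43, II = 58, III = 49, IV = 52),
                       seed = 1L) {
  assert_count(n_crc, "n_crc"); assert_count(n_benign, "n_benign")
  assert_count(n_healthy, "n_healthy"); assert_count(n_proteins, "n_proteins")
  assert_count(n_batches, "n_batches")
  assert_count(n_signature, "n_signature", min = 0L)
  for (nm in c("subject_sd", "peptide_sd", "run_sd", "batch_sd", "noise_sd")) {
    assert_number(get(nm), nm, min = 0)
  }
  if (length(peptides_per_protein) != 2L || any(peptides_per_protein < 1)) {
    stopf("`peptides_per_protein` must be a (min, max) pair of counts >= 1")
  }
  if (length(baseline_range) != 2L || diff(baseline_range) < 0) {
    stopf("`baseline_range` must be (min, max) with min <= max")
  }
  if (lod > baseline_range[2]) {
    stopf("`lod` (%.3g) exceeds the baseline range maximum (%.3g): every record would be censored",
          lod, baseline_range[2])
  }
  if (random_missing_rate < 0 || random_missing_rate >= 1) {
    stopf("`random_missing_rate` must be in [0, 1)")
  }
  if (is.null(planted_log2fc)) {
    planted_log2fc <- if (n_signature == 0) numeric(0) else {
      base <- c(1.0, 0.8, 0.6, 0.5, -0.7, 0.9, 0.45, -0.55, 0.75, 0.65)
      fc <- rep_len(base, n_signature)
      # at least one negative marker whenever two or more are planted
      if (n_signature >= 2 && all(fc > 0)) fc[n_signature] <- -abs(fc[n_signature])
      fc
    }
  }
  if (length(planted_log2fc) != n_signature) {
    stopf("`planted_log2fc` must have exactly n_signature = %d entries", n_signature)
  }
  if (n_signature > 0 && any(planted_log2fc == 0)) {
    stopf("planted effects must be non-zero")
  }
  if (is.null(cea_params)) {
    cea_params <- list(
      meanlog = c(healthy = log(1.8), benign = log(2.2),
                  I = log(2.5), II = log(3.5), III = log(5), IV = log(10)),
      sdlog = 0.9
    )
  }
  structure(list(
    n_crc = as.integer(n_crc), n_benign = as.integer(n_benign),
    n_healthy = as.integer(n_healthy), n_proteins = as.integer(n_proteins),
    peptides_per_protein = as.integer(peptides_per_protein),
    n_signature = as.integer(n_signature), planted_log2fc = planted_log2fc,
    subject_sd = subject_sd, peptide_sd = peptide_sd, run_sd = run_sd,
    batch_sd = batch_sd, noise_sd = noise_sd,
    baseline_range = baseline_range, lod = lod,
    random_missing_rate = random_missing_rate,
    tumor_size_effect = tumor_size_effect, cea_params = cea_params,
    age_shift = age_shift, n_batches = as.integer(n_batches),
    stage_props = stage_props, seed = as.integer(seed)
  ), class = "srm_config")
}

# Deterministic 32-bit sub-seed for a cohort label, so that training and
# validation cohorts generated from one config share the protein panel but
# draw independent subjects.
label_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.double(seed) * 7919 + h * 1009) %% 2147483647)
}

#' Generate a synthetic SRM cohort
#'
#' Returns the long-format quantification records, the subject metadata
#' table, and the planted ground truth needed to score downstream stages.
#' The protein panel (baselines, peptide layout, marker identity) depends
#' only on `config$seed`, so cohorts generated under different labels from
#' one config share their panel, as two clinical cohorts measured with the
#' same targeting method would.
#'
#' @param config an [sim_config()] object.
#' @param cohort_label cohort name recorded in the records ("training",
#'   "validation", ...).
#' @return list with elements `records` (data.frame of quant records),
#'   `metadata` (data.frame of subject records) and `truth`
#'   (`ground_truth` object).
#' @export
generate_cohort <- function(config, cohort_label = "training") {
  if (!inherits(config, "srm_config")) stopf("`config` must come from sim_config()")

  panel <- with_seed(config$seed, draw_protein_panel(config))

  with_seed(label_seed(config$seed, cohort_label), {
    n <- config$n_crc + config$n_benign + config$n_healthy
    group <- rep(c("CRC", "benign", "healthy"),
                 c(config$n_crc, config$n_benign, config$n_healthy))
    subject_id <- sprintf("%s_S%04d", cohort_label, seq_len(n))

    stage <- rep(NA_character_, n)
    props <- config$stage_props / sum(config$stage_props)
    stage[group == "CRC"] <- sample(names(props), config$n_crc, TRUE, props)

    tumor <- rep(NA_real_, n)
    tumor[group == "CRC"] <- rlnorm(config$n_crc, log(4.5), 0.45)

    cea_key <- ifelse(group == "CRC", stage, group)
    cea <- rlnorm(n, config$cea_params$meanlog[cea_key], config$cea_params$sdlog)

    age <- rnorm(n, 60, 8) + ifelse(group == "CRC", config$age_shift, 0)

    # block-randomized run order, contiguous preparation batches
    run_order <- sample.int(n)
    run_id <- character(n)
    run_id[run_order] <- sprintf("%s_R%04d", cohort_label, seq_len(n))
    batch_of_run <- sprintf("B%02d", as.integer(cut(seq_len(n), config$n_batches, labels = FALSE)))
    batch_id <- character(n)
    batch_id[run_order] <- batch_of_run

    metadata <- data.frame(
      subject_id = subject_id, cohort = cohort_label, group = group,
      stage = stage, tumor_diameter_cm = tumor, cea_ng_ml = cea,
      age_years = age, run_id = run_id, stringsAsFactors = FALSE
    )

    run_shift <- setNames(rnorm(n, 0, config$run_sd), run_id)
    batch_levels <- sprintf("B%02d", seq_len(config$n_batches))
    batch_shift <- setNames(rnorm(config$n_batches, 0, config$batch_sd), batch_levels)

    # subject x protein biological effects
    P <- config$n_proteins
    subj_eff <- matrix(rnorm(n * P, 0, config$subject_sd), n, P,
                       dimnames = list(subject_id, panel$protein_id))

    # planted group effects (CRC only), plus tumor-size slopes
    grp_eff <- matrix(0, n, P, dimnames = dimnames(subj_eff))
    if (config$n_signature > 0) {
      is_crc <- group == "CRC"
      for (i in seq_along(panel$marker_ids)) {
        pid <- panel$marker_ids[i]
        grp_eff[is_crc, pid] <- panel$true_log2fc[i]
      }
      if (config$tumor_size_effect != 0) {
        for (pid in panel$size_responsive_ids) {
          slope <- config$tumor_size_effect *
            sign(panel$true_log2fc[match(pid, panel$marker_ids)])
          grp_eff[is_crc, pid] <- grp_eff[is_crc, pid] +
            slope * (tumor[is_crc] - 4.5)
        }
      }
    }

    # endogenous records: one light + one heavy per subject x peptide
    pep <- panel$peptides     # protein_id, peptide_id, offset, baseline
    npep <- nrow(pep)
    si <- rep(seq_len(n), each = npep)
    pi <- rep(seq_len(npep), times = n)
    base_term <- pep$baseline[pi] + pep$offset[pi]
    run_term <- run_shift[run_id[si]]
    light <- base_term +
      subj_eff[cbind(si, match(pep$protein_id[pi], panel$protein_id))] +
      grp_eff[cbind(si, match(pep$protein_id[pi], panel$protein_id))] +
      batch_shift[batch_id[si]] + run_term +
      rnorm(n * npep, 0, config$noise_sd)
    heavy <- base_term + run_term + rnorm(n * npep, 0, config$noise_sd)

    # left-censoring at the LOD plus an MCAR component (endogenous light only)
    light[light < config$lod] <- NA_real_
    if (config$random_missing_rate > 0) {
      drop <- runif(n * npep) < config$random_missing_rate
      light[drop] <- NA_real_
    }

    endo <- data.frame(
      run_id = rep(run_id[si], 2L),
      cohort_id = cohort_label,
      subject_id = rep(subject_id[si], 2L),
      protein_id = rep(pep$protein_id[pi], 2L),
      peptide_id = rep(pep$peptide_id[pi], 2L),
      channel = rep(c("light", "heavy"), each = n * npep),
      is_standard = FALSE,
      batch_id = rep(batch_id[si], 2L),
      log2_intensity = c(light, heavy),
      stringsAsFactors = FALSE
    )

    # spiked standard proteins: no subject/group term, but batch bias in
    # the light channel (spiked before preparation); their heavy reference
    # peptides see acquisition drift only, like every targeted peptide
    std <- panel$standards
    nstd <- nrow(std)
    si2 <- rep(seq_len(n), each = nstd)
    pi2 <- rep(seq_len(nstd), times = n)
    std_base <- std$baseline[pi2] + std$offset[pi2]
    std_run <- run_shift[run_id[si2]]
    std_light <- std_base + batch_shift[batch_id[si2]] + std_run +
      rnorm(n * nstd, 0, config$noise_sd)
    std_heavy <- std_base + std_run + rnorm(n * nstd, 0, config$noise_sd)
    std_rec <- data.frame(
      run_id = rep(run_id[si2], 2L), cohort_id = cohort_label,
      subject_id = rep(subject_id[si2], 2L),
      protein_id = rep(std$protein_id[pi2], 2L),
      peptide_id = rep(std$peptide_id[pi2], 2L),
      channel = rep(c("light", "heavy"), each = n * nstd),
      is_standard = TRUE, batch_id = rep(batch_id[si2], 2L),
      log2_intensity = c(std_light, std_heavy), stringsAsFactors = FALSE
    )

    records <- rbind(endo, std_rec)
    records <- records[order(records$run_id, records$protein_id,
                             records$peptide_id, records$channel), ]
    rownames(records) <- NULL

    truth <- structure(list(
      marker_ids = panel$marker_ids,
      true_log2fc = setNames(panel$true_log2fc, panel$marker_ids),
      size_responsive_ids = panel$size_responsive_ids,
      generative_coefficients = panel$generative_coefficients,
      protein_ids = panel$protein_id,
      config = config
    ), class = "ground_truth")

    list(records = records, metadata = metadata, truth = truth)
  })
}

# Protein panel shared across cohorts: baselines, peptide offsets, marker
# identity and the coefficients of the generative (Bayes) disease model.
draw_protein_panel <- function(config) {
  P <- config$n_proteins
  protein_id <- sprintf("PROT%03d", seq_len(P))
  baseline <- runif(P, config$baseline_range[1], config$baseline_range[2])
  npep <- if (config$peptides_per_protein[1] == config$peptides_per_protein[2]) {
    rep(config$peptides_per_protein[1], P)
  } else {
    sample(seq(config$peptides_per_protein[1], config$peptides_per_protein[2]), P, TRUE)
  }
  peptides <- data.frame(
    protein_id = rep(protein_id, npep),
    peptide_id = unlist(lapply(seq_len(P), function(i) {
      sprintf("%s_PEP%d", protein_id[i], seq_len(npep[i]))
    })),
    offset = rnorm(sum(npep), 0, config$peptide_sd),
    baseline = rep(baseline, npep),
    stringsAsFactors = FALSE
  )

  marker_ids <- character(0); true_fc <- numeric(0); size_ids <- character(0)
  if (config$n_signature > 0) {
    # markers are drawn among well-detected proteins, mirroring the fact
    # that a validated panel consists of consistently quantified proteins
    eligible <- protein_id[baseline >= config$lod + 4]
    if (length(eligible) < config$n_signature) {
      eligible <- protein_id[order(baseline, decreasing = TRUE)][seq_len(config$n_signature)]
    }
    marker_ids <- sort(sample(eligible, config$n_signature))
    true_fc <- config$planted_log2fc
    if (config$n_signature >= 2 && config$tumor_size_effect != 0) {
      up <- marker_ids[true_fc > 0]; down <- marker_ids[true_fc < 0]
      size_ids <- c(
        if (length(up)) up[which.max(true_fc[true_fc > 0])],
        if (length(down)) down[which.min(true_fc[true_fc < 0])]
      )
    }
  }

  # Bayes-optimal logistic coefficients for summarized abundances under the
  # equal-covariance Gaussian generative model.
  gen <- NULL
  if (config$n_signature > 0) {
    mean_npep <- npep[match(marker_ids, protein_id)]
    v <- pmax(config$subject_sd^2 + config$noise_sd^2 / mean_npep, 1e-8)
    beta <- setNames(true_fc / v, marker_ids)
    pep_mean <- vapply(split(peptides$offset, peptides$protein_id), mean, 0)
    mu0 <- baseline[match(marker_ids, protein_id)] + pep_mean[marker_ids]
    prior <- log(config$n_crc / (config$n_benign + config$n_healthy))
    intercept <- prior - sum(beta * (mu0 + true_fc / 2))
    gen <- list(beta = beta, intercept = unname(intercept))
  }

  standards <- data.frame(
    protein_id = rep(c("STD_BOV_FETUA", "STD_BOV_A1AG"), c(3L, 2L)),
    peptide_id = c(sprintf("STD_BOV_FETUA_PEP%d", 1:3),
                   sprintf("STD_BOV_A1AG_PEP%d", 1:2)),
    offset = rnorm(5, 0, config$peptide_sd),
    baseline = rep(c(19, 17), c(3L, 2L)),
    stringsAsFactors = FALSE
  )

  list(protein_id = protein_id, baseline = baseline, peptides = peptides,
       standards = standards, marker_ids = marker_ids,
       true_log2fc = true_fc, size_responsive_ids = size_ids,
       generative_coefficients = gen)
}

#' Generate a null cohort (no planted effects)
#'
#' Same structure as [generate_cohort()] with `n_signature = 0`; used for
#' false-discovery and specificity testing.
#' @inheritParams generate_cohort
#' @export
generate_null_cohort <- function(config, cohort_label = "training") {
  null_cfg <- config
  null_cfg$n_signature <- 0L
  null_cfg$planted_log2fc <- numeric(0)
  generate_cohort(null_cfg, cohort_label)
}

#' Generate a tissue-style feature table with controlled missingness
#'
#' Small fixture generator for the tissue-phase feature filter and scale
#' normalization: a features x runs matrix of log2 abundances with an
#' optional missingness pattern, plus a run-level group assignment.
#'
#' @param n_features,n_runs table dimensions (`n_runs >= 2`).
#' @param missing_pattern optional logical features x runs matrix marking
#'   cells to blank out.
#' @param groups character vector of per-run group labels; defaults to two
#'   equal halves "tumor"/"normal".
#' @param seed RNG seed.
#' @return list with `values` (matrix, NA = missing) and `groups`.
#' @export
generate_feature_fixture <- function(n_features, n_runs, missing_pattern = NULL,
                                     groups = NULL, seed = 1L) {
  assert_count(n_features, "n_features")
  assert_count(n_runs, "n_runs", min = 2L)
  groups <- groups %||% rep(c("tumor", "normal"), length.out = n_runs)
  if (length(groups) != n_runs) stopf("`groups` must have one label per run")
  with_seed(seed, {
    values <- matrix(rnorm(n_features * n_runs, 20, 2), n_features, n_runs,
                     dimnames = list(sprintf("FEAT%04d", seq_len(n_features)),
                                     sprintf("RUN%03d", seq_len(n_runs))))
    if (!is.null(missing_pattern)) {
      if (!identical(dim(missing_pattern), dim(values))) {
        stopf("`missing_pattern` must be a %d x %d logical matrix",
              n_features, n_runs)
      }
      values[missing_pattern] <- NA_real_
    }
    list(values = values, groups = groups)
  })
}

#' Bayes-reference signature model from planted ground truth
#'
#' Converts the generative logistic coefficients of a synthetic cohort into
#' a [signature model][consensus_cv] so the generative (Bayes) classifier
#' can be evaluated with the same prediction machinery as fitted models.
#' @param truth a `ground_truth` object.
#' @return a `signature_model`.
#' @export
generative_model <- function(truth) {
  if (!inherits(truth, "ground_truth")) stopf("`truth` must be a ground_truth object")
  gen <- truth$generative_coefficients
  if (is.null(gen)) stopf("null cohorts have no generative disease model")
  new_signature_model(protein_ids = names(gen$beta),
                      coefficients = unname(gen$beta),
                      intercept = gen$intercept, threshold = 0.5)
}
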