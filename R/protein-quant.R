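# Protein-level summarization per subject, group comparison with BH
# adjustment, and original-scale fold-change reporting.

#' Summarize peptide intensities to protein abundance per subject
#'
#' For each endogenous protein, fits an additive two-way fixed-effects
#' model (peptide + subject) by least squares on the observed light
#' intensities and reports the per-subject summary (intercept + subject
#' effect with sum-to-zero peptide effects). On complete balanced data
#' this equals the per-subject mean across peptides. A cell is masked (NA)
#' when the subject has no observed peptide for the protein; a protein
#' observed in zero subjects is dropped with a warning.
#'
#' @param records normalized quantification records.
#' @param cohort_label cohort tag stored in the matrix; defaults to the
#'   records' `cohort_id`.
#' @return an [abundance_matrix()].
#' @export
summarize_protein_abundance <- function(records, cohort_label = NULL) {
  sel <- !records$is_standard & records$channel == "light"
  sub <- records[sel, ]
  subjects <- unique(sub$subject_id)
  proteins <- unique(sub$protein_id)
  vals <- matrix(NA_real_, length(subjects), length(proteins),
                 dimnames = list(subjects, proteins))
  dropped <- character(0)
  for (pid in proteins) {
    psel <- sub$protein_id == pid
    if (!any(!is.na(sub$log2_intensity[psel]))) {
      dropped <- c(dropped, pid)
      next
    }
    vals[, pid] <- additive_summary(sub$log2_intensity[psel],
                                    sub$subject_id[psel],
                                    sub$peptide_id[psel],
                                    all_units = subjects)
  }
  if (length(dropped)) {
    warnf("dropped %d protein(s) with no observed intensity: %s",
          length(dropped), paste(dropped, collapse = ", "))
    vals <- vals[, setdiff(proteins, dropped), drop = FALSE]
  }
  cohort <- cohort_label %||% sub$cohort_id[match(subjects, sub$subject_id)]
  abundance_matrix(vals, cohort)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `adj_i = min over j >= i of p_(j) * m / j` on the ascending sort,
#' capped at 1 and returned in the input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values.
#' @export
adjust_bh <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stopf("p-values must lie in [0, 1]")
  m <- length(p)
  if (m <= 1L) return(p)
  o <- order(p)
  adj <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  adj[order(o)]
}

#' Delta-method transform of a log2 fold change to the original scale
#'
#' `fc = 2^log2fc` and `se = se_log2 * ln(2) * 2^log2fc`.
#'
#' @param log2fc log2 fold change(s).
#' @param se_log2 standard error(s) on the log2 scale (>= 0).
#' @return list with `fc_original` and `se_original`.
#' @export
delta_transform <- function(log2fc, se_log2) {
  if (any(se_log2 < 0, na.rm = TRUE)) stopf("`se_log2` must be >= 0")
  fc <- 2^log2fc
  list(fc_original = fc, se_original = se_log2 * log(2) * fc)
}

#' Differential protein abundance between two groups
#'
#' Per protein, a two-sample pooled-variance t-test on the summarized
#' subject-level abundances (cases minus controls), BH adjustment across
#' the tested proteins, and the Delta-method original-scale fold change.
#' Significance presets:
#' \describe{
#'   \item{plasma}{p (adjusted by default) <= `alpha` AND original-scale
#'     FC outside \[1/`fc_cutoff`, `fc_cutoff`\] with `fc_cutoff = 1.1`.
#'     This is the per-fold candidate filter of the signature discovery.}
#'   \item{tissue}{adjusted p < `alpha` AND |log2FC| >= `lfc_cutoff` with
#'     `lfc_cutoff = 1.5`.}
#'   \item{custom}{thresholds exactly as supplied.}
#' }
#' Proteins with fewer than two observed values in either group are
#' skipped and excluded from the BH family.
#'
#' @param matrix an [abundance_matrix()] (or bare matrix) of log2
#'   abundances.
#' @param is_case logical per subject, TRUE for the disease group.
#' @param preset `"plasma"`, `"tissue"` or `"custom"`.
#' @param alpha significance level on the (adjusted) p-value.
#' @param fc_cutoff original-scale fold-change cutoff (plasma preset).
#' @param lfc_cutoff log2 fold-change cutoff (tissue preset).
#' @param use_adjusted filter on BH-adjusted p (TRUE, default) or raw p.
#' @return data.frame with one row per tested protein: `protein_id`,
#'   `log2fc`, `se_log2`, `dof`, `p_value`, `adj_p`, `fc_original`,
#'   `se_original`, `n_case`, `n_control`, `significant`.
#' @export
differential_abundance <- function(matrix, is_case,
                                   preset = c("plasma", "tissue", "custom"),
                                   alpha = 0.05, fc_cutoff = 1.1,
                                   lfc_cutoff = 1.5, use_adjusted = TRUE) {
  preset <- match.arg(preset)
  vals <- if (inherits(matrix, "abundance_matrix")) matrix$values else matrix
  if (length(is_case) != nrow(vals)) stopf("`is_case` must match the subject rows")
  is_case <- as.logical(is_case)

  stats_tab <- vectorized_t(vals[is_case, , drop = FALSE],
                            vals[!is_case, , drop = FALSE])
  tested <- stats_tab$n1 >= 2 & stats_tab$n0 >= 2
  if (any(!tested)) {
    message(sprintf("differential_abundance: %d protein(s) skipped (fewer than 2 values in a group)",
                    sum(!tested)))
  }
  tab <- stats_tab[tested, , drop = FALSE]
  if (!nrow(tab)) return(empty_differential())
  adj_p <- adjust_bh(tab$p_value)
  dt <- delta_transform(tab$log2fc, tab$se_log2)
  filt_p <- if (use_adjusted) adj_p else tab$p_value
  significant <- switch(preset,
    plasma = filt_p <= alpha & (dt$fc_original > fc_cutoff | dt$fc_original < 1 / fc_cutoff),
    tissue = adj_p < alpha & abs(tab$log2fc) >= lfc_cutoff,
    custom = filt_p <= alpha & abs(tab$log2fc) >= 0
  )
  data.frame(protein_id = tab$protein_id, log2fc = tab$log2fc,
             se_log2 = tab$se_log2, dof = tab$dof, p_value = tab$p_value,
             adj_p = adj_p, fc_original = dt$fc_original,
             se_original = dt$se_original, n_case = tab$n1,
             n_control = tab$n0, significant = significant,
             stringsAsFactors = FALSE)
}

empty_differential <- function() {
  data.frame(protein_id = character(0), log2fc = numeric(0),
             se_log2 = numeric(0), dof = numeric(0), p_value = numeric(0),
             adj_p = numeric(0), fc_original = numeric(0),
             se_original = numeric(0), n_case = integer(0),
             n_control = integer(0), significant = logical(0),
             stringsAsFactors = FALSE)
}

# Column-wise pooled-variance two-sample t statistics (NA-aware).
vectorized_t <- function(a, b) {
  n1 <- colSums(!is.na(a)); n0 <- colSums(!is.na(b))
  m1 <- colMeans(a, na.rm = TRUE); m0 <- colMeans(b, na.rm = TRUE)
  ss1 <- colSums(sweep(a, 2, m1)^2, na.rm = TRUE)
  ss0 <- colSums(sweep(b, 2, m0)^2, na.rm = TRUE)
  dof <- n1 + n0 - 2
  sp2 <- ifelse(dof > 0, (ss1 + ss0) / dof, NA_real_)
  se <- sqrt(sp2 * (1 / n1 + 1 / n0))
  diff <- m1 - m0
  tstat <- ifelse(se > 0, diff / se, ifelse(diff == 0, 0, sign(diff) * Inf))
  p <- ifelse(is.finite(tstat), 2 * pt(abs(tstat), dof, lower.tail = FALSE),
              ifelse(is.infinite(tstat), 0, NA_real_))
  p[dof > 0 & se == 0 & diff == 0] <- 1
  data.frame(protein_id = colnames(a), log2fc = diff, se_log2 = se,
             dof = dof, p_value = p, n1 = n1, n0 = n0,
             stringsAsFactors = FALSE, row.names = NULL)
}
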