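# Data model and file I/O: long-format quantification tables, subject
# metadata, abundance matrices, and the column-map dialects of common
# SRM export formats.

QUANT_COLUMNS <- c("run_id", "cohort_id", "subject_id", "protein_id",
                   "peptide_id", "channel", "is_standard", "batch_id",
                   "log2_intensity")

META_COLUMNS <- c("subject_id", "cohort", "group", "stage",
                  "tumor_diameter_cm", "cea_ng_ml", "age_years", "run_id")

# Column maps: native column name -> exported column name. The intensity
# entry maps to "log2_intensity" for pre-logged exports and "intensity"
# semantics are controlled by the `intensities` flag of read_quant_table().
quant_dialects <- list(
  native = setNames(QUANT_COLUMNS, QUANT_COLUMNS),
  multiquant = c(run_id = "Sample Name", cohort_id = "Cohort",
                 subject_id = "Subject", protein_id = "Protein Name",
                 peptide_id = "Component Group Name", channel = "Label",
                 is_standard = "Standard", batch_id = "Batch",
                 log2_intensity = "Area"),
  skyline = c(run_id = "File Name", cohort_id = "Condition",
              subject_id = "BioReplicate", protein_id = "Protein",
              peptide_id = "Peptide Sequence",
              channel = "Isotope Label Type", is_standard = "Standard Type",
              batch_id = "Batch", log2_intensity = "Total Area")
)

read_table_auto <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  read.delim(path, sep = sep, stringsAsFactors = FALSE, comment.char = "#",
             check.names = FALSE, na.strings = c("NA", ""))
}

#' Read a long-format SRM quantification table
#'
#' Accepts the native schema or MultiQuant/Skyline-like exports via a
#' column-map dialect. Raw intensities are log2-transformed at this single
#' boundary; all downstream code works on log2 intensities. Missing
#' measurements may be encoded as empty intensity cells or absent rows;
#' both yield the same missingness downstream.
#'
#' @param path TSV (default) or CSV file; `.csv` extension selects comma
#'   separation. Lines starting with `#` are ignored.
#' @param dialect one of `"native"`, `"multiquant"`, `"skyline"`, or
#'   `"custom"` (then `col_map` is required).
#' @param col_map named character vector mapping native column names to the
#'   file's column names (overrides the dialect).
#' @param intensities `"log2"` if the intensity column is already log2
#'   transformed, `"raw"` for raw peak areas (log2 applied on read; raw
#'   values must be positive).
#' @return data.frame of validated quantification records (one row per
#'   run x peptide x channel).
#' @export
read_quant_table <- function(path, dialect = c("native", "multiquant", "skyline", "custom"),
                             col_map = NULL, intensities = c("log2", "raw")) {
  dialect <- match.arg(dialect)
  intensities <- match.arg(intensities)
  map <- col_map %||% quant_dialects[[dialect]]
  if (is.null(map)) stopf("dialect \"custom\" requires `col_map`")
  missing_native <- setdiff(QUANT_COLUMNS, names(map))
  if (length(missing_native)) {
    stopf("col_map lacks entries for: %s", paste(missing_native, collapse = ", "))
  }
  raw <- read_table_auto(path)
  absent <- setdiff(unname(map), names(raw))
  if (length(absent)) {
    stopf("%s: missing required column(s): %s", path, paste(absent, collapse = ", "))
  }
  rec <- raw[, unname(map[QUANT_COLUMNS]), drop = FALSE]
  names(rec) <- QUANT_COLUMNS
  rec$channel <- tolower(as.character(rec$channel))
  bad_ch <- which(!rec$channel %in% c("light", "heavy"))
  if (length(bad_ch)) {
    stopf("%s: row %d: channel must be \"light\" or \"heavy\" (got \"%s\")",
          path, bad_ch[1], rec$channel[bad_ch[1]])
  }
  rec$is_standard <- parse_flag(rec$is_standard, path)
  y <- rec$log2_intensity
  if (!is.numeric(y)) {
    suppressWarnings(num <- as.numeric(as.character(y)))
    bad <- which(!is.na(y) & y != "" & is.na(num))
    if (length(bad)) {
      stopf("%s: row %d: non-numeric intensity \"%s\"", path, bad[1], y[bad[1]])
    }
    y <- num
  }
  if (intensities == "raw") {
    if (any(y <= 0, na.rm = TRUE)) {
      stopf("%s: raw intensities must be positive before log2 transform", path)
    }
    y <- log2(y)
  }
  if (any(!is.finite(y) & !is.na(y))) {
    stopf("%s: row %d: non-finite intensity", path, which(!is.finite(y) & !is.na(y))[1])
  }
  rec$log2_intensity <- y
  validate_quant_records(rec, context = path)
}

parse_flag <- function(x, path) {
  if (is.logical(x)) return(x)
  v <- tolower(as.character(x))
  out <- v %in% c("true", "t", "1", "yes")
  bad <- which(!v %in% c("true", "t", "1", "yes", "false", "f", "0", "no", ""))
  if (length(bad)) {
    stopf("%s: row %d: cannot parse standard flag \"%s\"", path, bad[1], x[bad[1]])
  }
  out
}

#' Validate a collection of quantification records
#'
#' Enforces the record invariants: required columns, valid channels, a
#' unique (run, peptide, channel) key, and finite intensities where
#' present.
#' @param records data.frame of quantification records.
#' @param context label used in error messages (e.g. a file path).
#' @return the validated records, invisibly unchanged.
#' @export
validate_quant_records <- function(records, context = "records") {
  missing_cols <- setdiff(QUANT_COLUMNS, names(records))
  if (length(missing_cols)) {
    stopf("%s: missing column(s): %s", context, paste(missing_cols, collapse = ", "))
  }
  key <- paste(records$run_id, records$peptide_id, records$channel, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    i <- dup[1]
    stopf("%s: duplicate (run, peptide, channel) key: (%s, %s, %s)",
          context, records$run_id[i], records$peptide_id[i], records$channel[i])
  }
  records
}

#' Write quantification records to TSV
#'
#' @param records data.frame of quantification records.
#' @param path output file.
#' @param comment optional character vector written as `# `-prefixed header
#'   lines (e.g. the generator seed).
#' @export
write_quant_table <- function(records, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  write.table(records[, QUANT_COLUMNS], con, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  invisible(path)
}

#' Read a subject metadata table
#'
#' Validates group labels and the rule that a clinical stage may only be
#' recorded for CRC subjects; empty CEA / tumor-size / age cells become NA.
#'
#' @param path TSV or CSV file with the metadata schema (see README).
#' @return data.frame of subject records.
#' @export
read_metadata <- function(path) {
  meta <- read_table_auto(path)
  missing_cols <- setdiff(META_COLUMNS, names(meta))
  if (length(missing_cols)) {
    stopf("%s: missing column(s): %s", path, paste(missing_cols, collapse = ", "))
  }
  meta <- meta[, META_COLUMNS]
  bad_group <- which(!meta$group %in% c("CRC", "benign", "healthy"))
  if (length(bad_group)) {
    stopf("%s: row %d: unknown group label \"%s\"",
          path, bad_group[1], meta$group[bad_group[1]])
  }
  meta$stage <- as.character(meta$stage)
  bad_stage <- which(!is.na(meta$stage) & meta$group != "CRC")
  if (length(bad_stage)) {
    stopf("%s: row %d: stage recorded for non-CRC subject %s",
          path, bad_stage[1], meta$subject_id[bad_stage[1]])
  }
  unknown_stage <- which(!is.na(meta$stage) & !meta$stage %in% c("I", "II", "III", "IV"))
  if (length(unknown_stage)) {
    stopf("%s: row %d: unknown stage \"%s\"", path, unknown_stage[1],
          meta$stage[unknown_stage[1]])
  }
  for (col in c("tumor_diameter_cm", "cea_ng_ml", "age_years")) {
    meta[[col]] <- as.numeric(meta[[col]])
    if (any(meta[[col]] < 0, na.rm = TRUE)) stopf("%s: negative %s", path, col)
  }
  if (anyDuplicated(meta$subject_id)) stopf("%s: duplicated subject_id", path)
  meta
}

#' @rdname read_metadata
#' @param metadata data.frame of subject records.
#' @param comment optional `# `-prefixed header lines.
#' @export
write_metadata <- function(metadata, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  write.table(metadata[, META_COLUMNS], con, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  invisible(path)
}

# ---- abundance matrix -------------------------------------------------

#' Construct a subjects x proteins abundance matrix
#'
#' The container used by the predictive analysis: log2 relative protein
#' abundances with NA marking missing (masked) cells and a per-subject
#' cohort label.
#'
#' @param values numeric matrix, subjects in rows, proteins in columns;
#'   dimnames required.
#' @param cohort per-subject cohort label (recycled if length 1).
#' @return object of class `abundance_matrix`.
#' @export
abundance_matrix <- function(values, cohort = "training") {
  if (!is.matrix(values) || is.null(rownames(values)) || is.null(colnames(values))) {
    stopf("`values` must be a matrix with subject and protein dimnames")
  }
  cohort <- rep_len(as.character(cohort), nrow(values))
  structure(list(values = values, cohort = setNames(cohort, rownames(values))),
            class = "abundance_matrix")
}

#' @export
dim.abundance_matrix <- function(x) dim(x$values)

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("<abundance_matrix> %d subjects x %d proteins, %d missing cells (%s)\n",
              nrow(x$values), ncol(x$values), sum(is.na(x$values)),
              paste(unique(x$cohort), collapse = "+")))
  invisible(x)
}

#' Missingness mask of an abundance matrix
#' @param x an `abundance_matrix`.
#' @return logical matrix, TRUE where the cell is missing.
#' @export
missing_mask <- function(x) is.na(x$values)

#' Write / read an abundance matrix as TSV
#'
#' Subjects in rows; first two columns are `subject_id` and `cohort`.
#' @param x an `abundance_matrix`.
#' @param path file path.
#' @export
write_abundance_matrix <- function(x, path) {
  df <- data.frame(subject_id = rownames(x$values), cohort = unname(x$cohort),
                   x$values, check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_abundance_matrix
#' @export
read_abundance_matrix <- function(path) {
  df <- read_table_auto(path)
  vals <- as.matrix(df[, setdiff(names(df), c("subject_id", "cohort")), drop = FALSE])
  rownames(vals) <- df$subject_id
  abundance_matrix(vals, df$cohort)
}
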