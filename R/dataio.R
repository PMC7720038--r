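## Readers, writers and validation for the three on-disk tables.
## All format dialects are decided here: expression is tab-separated with
## gene IDs in the first column; clinical and event tables are CSV with a
## required header; reports are JSON plus TSV summaries.

CLINICAL_REQUIRED <- c(
  "subject_id", "age", "sex", "prism_iii", "nonpulm_organ_failures",
  "immunocompromised", "stem_cell_transplant", "etiology_direct",
  "etiology_infectious", "etiology_category", "anc", "alc",
  "pf_onset", "pf_24h", "oi_onset", "oi_24h")

VASOPRESSOR_DRUGS <- c("dopamine", "dobutamine", "epinephrine",
                       "norepinephrine", "phenylephrine", "milrinone",
                       "vasopressin")

ETIOLOGY_LEVELS <- c("infectious pneumonia", "nonpulmonary sepsis",
                     "aspiration", "trauma", "other")

EVENT_HORIZON <- 28

#' Validate a genes-by-samples expression matrix
#'
#' @param x Numeric matrix, genes in rows (unique rownames), samples in
#'   columns (unique colnames); values finite and non-negative.
#' @return `x`, invisibly, after validation.
#' @export
validate_expression <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop_domain("expression must be a numeric matrix (genes x samples)")
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop_domain("expression matrix needs gene rownames and sample colnames")
  }
  dup <- rownames(x)[duplicated(rownames(x))]
  if (length(dup)) stop_domain("duplicate gene IDs: ", paste(unique(dup), collapse = ", "))
  dups <- colnames(x)[duplicated(colnames(x))]
  if (length(dups)) stop_domain("duplicate sample IDs: ", paste(unique(dups), collapse = ", "))
  if (anyNA(x) || any(!is.finite(x))) stop_domain("expression values must be finite (no missing)")
  if (any(x < 0)) stop_domain("expression values must be non-negative")
  invisible(x)
}

#' Read an expression matrix from tab-separated text
#'
#' First column holds gene IDs; the header row holds sample IDs.
#'
#' @param path Path to a TSV file.
#' @return Validated numeric matrix, genes x samples.
#' @export
read_expression <- function(path) {
  nf <- count.fields(path, sep = "\t", quote = "\"", comment.char = "")
  if (length(unique(nf)) > 1L) {
    bad <- which(nf != nf[1])[1]
    stop_domain("ragged expression file: line ", bad, " has ", nf[bad],
                " fields, expected ", nf[1])
  }
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character")
  if (ncol(df) < 2L) stop_domain("expression file needs gene IDs plus >= 1 sample column")
  gene_ids <- df[[1L]]
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup)) stop_domain("duplicate gene IDs: ", paste(dup, collapse = ", "))
  vals <- suppressWarnings(
    vapply(df[-1L], as.numeric, numeric(nrow(df))))
  if (nrow(df) == 1L) vals <- matrix(vals, nrow = 1L, dimnames = list(NULL, colnames(df)[-1L]))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop_domain("non-numeric expression value at line ", bad[["row"]] + 1L,
                ", sample '", colnames(vals)[bad[["col"]]], "'")
  }
  rownames(vals) <- gene_ids
  validate_expression(vals)
  vals
}

#' Write an expression matrix as tab-separated text
#'
#' @param x Validated expression matrix (see [validate_expression()]).
#' @param path Output path.
#' @export
write_expression <- function(x, path) {
  validate_expression(x)
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a clinical covariate table
#'
#' Checks the declared schema: one row per subject, unique subject IDs,
#' physiologic numeric fields finite and non-negative, flags boolean, and
#' vasopressor dose columns present (absent doses default to 0).
#'
#' @param df Data frame with the columns listed in the package vignette.
#' @return The validated table (with dose columns filled in), invisibly
#'   usable downstream.
#' @export
validate_clinical <- function(df) {
  missing_cols <- setdiff(CLINICAL_REQUIRED, names(df))
  if (length(missing_cols)) {
    stop_domain("clinical table missing required columns: ",
                paste(missing_cols, collapse = ", "))
  }
  for (d in VASOPRESSOR_DRUGS) {
    if (!d %in% names(df)) df[[d]] <- 0
    df[[d]][is.na(df[[d]])] <- 0
  }
  if (anyDuplicated(df$subject_id)) stop_domain("duplicate subject_id in clinical table")
  if (!all(df$sex %in% c("female", "male"))) stop_domain("sex must be 'female' or 'male'")
  if (!all(df$etiology_category %in% ETIOLOGY_LEVELS)) {
    stop_domain("etiology_category must be one of: ", paste(ETIOLOGY_LEVELS, collapse = ", "))
  }
  num_cols <- c("age", "prism_iii", "nonpulm_organ_failures", "anc", "alc",
                "pf_onset", "pf_24h", "oi_onset", "oi_24h", VASOPRESSOR_DRUGS)
  for (cc in num_cols) {
    v <- df[[cc]]
    if (!is.numeric(v) || anyNA(v) || any(!is.finite(v)) || any(v < 0)) {
      stop_domain("clinical column '", cc, "' must be finite, non-negative and complete")
    }
  }
  for (cc in c("immunocompromised", "stem_cell_transplant",
               "etiology_direct", "etiology_infectious")) {
    v <- df[[cc]]
    if (is.numeric(v) && all(v %in% c(0, 1))) v <- as.logical(v)
    if (is.character(v)) v <- as.logical(v)
    if (!is.logical(v) || anyNA(v)) stop_domain("clinical column '", cc, "' must be boolean")
    df[[cc]] <- v
  }
  df
}

#' Read the clinical table from CSV
#' @param path CSV path with header.
#' @return Validated clinical data frame.
#' @export
read_clinical <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  validate_clinical(df)
}

#' Write the clinical table to CSV
#' @param df Clinical data frame.
#' @param path Output path.
#' @export
write_clinical <- function(df, path) {
  df <- validate_clinical(df)
  write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Validate an event-history table
#'
#' One row per invasive-ventilation interval, with subject-level columns
#' repeated. Day units are real-valued days from ARDS onset; intervals are
#' half-open `[start, end)`. The first interval of every subject starts at
#' day 0, intervals are sorted and non-overlapping, `death_day` is present
#' only for PICU nonsurvivors, and follow-up is administratively capped at
#' day 28.
#'
#' @param df Data frame with columns `subject_id`, `vent_start`,
#'   `vent_end`, `death_day` (NA when absent), `picu_survivor`.
#' @return The validated table.
#' @export
validate_events <- function(df) {
  req <- c("subject_id", "vent_start", "vent_end", "death_day", "picu_survivor")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop_domain("events table missing required columns: ",
                paste(missing_cols, collapse = ", "))
  }
  if (is.character(df$picu_survivor)) df$picu_survivor <- as.logical(df$picu_survivor)
  if (is.numeric(df$picu_survivor)) df$picu_survivor <- as.logical(df$picu_survivor)
  if (anyNA(df$picu_survivor)) stop_domain("picu_survivor must be boolean")
  if (!is.numeric(df$vent_start) || !is.numeric(df$vent_end) ||
      anyNA(df$vent_start) || anyNA(df$vent_end)) {
    stop_domain("vent_start/vent_end must be numeric and complete")
  }
  if (any(df$vent_end <= df$vent_start)) stop_domain("ventilation intervals need end > start")
  for (sid in unique(df$subject_id)) {
    rows <- df[df$subject_id == sid, ]
    o <- order(rows$vent_start)
    rows <- rows[o, ]
    if (rows$vent_start[1] != 0) {
      stop_domain("subject ", sid, ": first ventilation interval must start at day 0")
    }
    if (nrow(rows) > 1 && any(rows$vent_start[-1] < rows$vent_end[-nrow(rows)])) {
      stop_domain("subject ", sid, ": overlapping ventilation intervals")
    }
    if (length(unique(rows$picu_survivor)) > 1 ||
        length(unique(rows$death_day)) > 1) {
      stop_domain("subject ", sid, ": subject-level columns differ across rows")
    }
    dd <- rows$death_day[1]
    if (rows$picu_survivor[1] && !is.na(dd)) {
      stop_domain("subject ", sid, ": death_day present for a PICU survivor")
    }
    if (!rows$picu_survivor[1] && is.na(dd)) {
      stop_domain("subject ", sid, ": PICU nonsurvivor without death_day")
    }
    if (!is.na(dd) && (dd <= 0 || dd > EVENT_HORIZON)) {
      stop_domain("subject ", sid, ": death_day must lie in (0, ", EVENT_HORIZON, "]")
    }
  }
  df
}

#' Read the event-history table from CSV
#' @param path CSV path with header.
#' @return Validated events data frame.
#' @export
read_events <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if ("death_day" %in% names(df)) df$death_day <- as.numeric(df$death_day)
  validate_events(df)
}

#' Write the event-history table to CSV
#' @param df Events data frame.
#' @param path Output path.
#' @export
write_events <- function(df, path) {
  df <- validate_events(df)
  write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Check that expression, clinical and event tables describe one cohort
#'
#' @param expression Genes x samples matrix.
#' @param clinical Clinical table.
#' @param events Events table.
#' @return Subject IDs in expression-column order.
#' @export
align_subjects <- function(expression, clinical, events) {
  ids <- colnames(expression)
  miss_c <- setdiff(ids, clinical$subject_id)
  extra_c <- setdiff(clinical$subject_id, ids)
  miss_e <- setdiff(ids, events$subject_id)
  extra_e <- setdiff(events$subject_id, ids)
  bad <- c(miss_c, extra_c, miss_e, extra_e)
  if (length(bad)) {
    stop_domain("subject IDs do not align across tables: ",
                paste(unique(bad), collapse = ", "))
  }
  ids
}

#' Write an analysis report bundle
#'
#' Data-frame elements of `results` are written as TSV files named after
#' the element; everything else is collected into a single JSON file.
#'
#' @param results Named list of data frames and JSON-serializable values.
#' @param dir Output directory (created if needed).
#' @return Paths written, invisibly.
#' @export
write_report <- function(results, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  meta <- list()
  for (nm in names(results)) {
    el <- results[[nm]]
    if (is.data.frame(el)) {
      p <- file.path(dir, paste0(nm, ".tsv"))
      write.table(el, p, sep = "\t", quote = FALSE, row.names = FALSE)
      paths <- c(paths, p)
    } else {
      meta[[nm]] <- el
    }
  }
  if (length(meta)) {
    p <- file.path(dir, "report.json")
    jsonlite::write_json(meta, p, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA, null = "null")
    paths <- c(paths, p)
  }
  invisible(paths)
}
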