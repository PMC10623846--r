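## Cohort data model: one row per tumor specimen. Mandatory columns are
## sample_id, subtype, driver_vaf, assay, mgmt_call; everything else is
## optional and never imputed.

COHORT_COLUMNS <- c(
  "sample_id", "subtype", "driver_gene", "driver_vaf", "assay", "mgmt_score",
  "mgmt_call", "site_p1", "site_p2", "site_p3", "site_p4",
  "micro_cellularity", "classifier_score", "sex", "age", "who_grade",
  "is_recurrent"
)
COHORT_MANDATORY <- c("sample_id", "subtype", "driver_vaf", "assay", "mgmt_call")
SITE_COLUMNS <- paste0("site_p", 1:4)

#' Construct a validated glioma cohort table
#'
#' Coerces a data frame to the cohort schema, canonicalizes enum tokens
#' (case-insensitively), checks every per-sample invariant, and returns a
#' tibble of class `glioma_cohort`. All cohort-consuming functions in the
#' package accept either a `glioma_cohort` or a plain data frame with the
#' same columns (which they validate on entry).
#'
#' Invariants enforced per row:
#' * `driver_vaf` in \[0, 1\]; all percent-scale fields in \[0, 100\];
#'   `classifier_score` in \[0, 1\].
#' * For pyrosequencing samples with all four per-CpG site percents present,
#'   `mgmt_score` must equal their arithmetic mean within 0.01.
#' * Subtype/driver-gene consistency: IDH-wildtype GBM carries a TERT
#'   promoter mutation; IDH-mutant subtypes carry IDH1 or IDH2 (checked only
#'   when `driver_gene` is present).
#' * `sample_id` unique within the table.
#'
#' @param x A data frame with at least the mandatory columns `sample_id`,
#'   `subtype`, `driver_vaf`, `assay`, `mgmt_call`.
#' @param provenance Free-text provenance note stored as an attribute
#'   (source file, simulation config hash, ...).
#' @return A `glioma_cohort` tibble. Unknown extra columns are preserved.
#' @export
as_cohort <- function(x, provenance = "in-memory") {
  if (!is.data.frame(x)) {
    stop_mgmtvaf("`x` must be a data frame", "mgmtvaf_argument_error")
  }
  x <- tibble::as_tibble(x)
  missing_cols <- setdiff(COHORT_MANDATORY, names(x))
  if (length(missing_cols) > 0) {
    stop_mgmtvaf(
      paste0("cohort is missing mandatory column(s): ",
             paste(missing_cols, collapse = ", ")),
      "mgmtvaf_schema_error"
    )
  }
  # add absent optional columns as NA so downstream code can rely on them
  for (col in setdiff(COHORT_COLUMNS, names(x))) {
    x[[col]] <- switch(col,
      is_recurrent = NA,
      sample_id = , subtype = , driver_gene = , assay = , mgmt_call = ,
      sex = NA_character_,
      NA_real_
    )
  }
  x <- x[, c(COHORT_COLUMNS, setdiff(names(x), COHORT_COLUMNS))]

  x$sample_id <- as.character(x$sample_id)
  x$subtype <- canonicalize_enum(x$subtype, SUBTYPES, "subtype")
  x$driver_gene <- canonicalize_enum(x$driver_gene, DRIVER_GENES, "driver_gene")
  x$assay <- canonicalize_enum(x$assay, ASSAYS, "assay")
  x$mgmt_call <- canonicalize_enum(x$mgmt_call, CALLS, "mgmt_call")
  for (col in c("driver_vaf", "mgmt_score", SITE_COLUMNS, "micro_cellularity",
                "classifier_score", "age")) {
    x[[col]] <- as_numeric_strict(x[[col]], col)
  }
  x$is_recurrent <- as_logical_strict(x$is_recurrent)
  x$sex <- as.character(x$sex)
  if (!is.numeric(x$who_grade)) x$who_grade <- as_numeric_strict(x$who_grade, "who_grade")

  problems <- validate_cohort_rows(x)
  if (length(problems) > 0) {
    stop_mgmtvaf(
      paste0("cohort validation failed:\n  ",
             paste(problems, collapse = "\n  ")),
      "mgmtvaf_validation_error"
    )
  }
  structure(x, provenance = provenance,
            class = c("glioma_cohort", class(x)))
}

canonicalize_enum <- function(values, vocabulary, field) {
  values <- as.character(values)
  idx <- match(toupper(values), toupper(vocabulary))
  bad <- !is.na(values) & values != "" & is.na(idx)
  if (any(bad)) {
    rows <- which(bad)
    stop_mgmtvaf(
      sprintf("unknown %s token(s) %s in row(s) %s (allowed: %s)",
              field,
              paste(unique(values[bad]), collapse = ", "),
              paste(rows, collapse = ", "),
              paste(vocabulary, collapse = ", ")),
      "mgmtvaf_validation_error"
    )
  }
  out <- vocabulary[idx]
  out[is.na(values) | values == ""] <- NA_character_
  out
}

as_numeric_strict <- function(values, field) {
  if (is.numeric(values)) return(as.numeric(values))
  values <- as.character(values)
  values[values == ""] <- NA_character_
  out <- suppressWarnings(as.numeric(values))
  bad <- !is.na(values) & is.na(out)
  if (any(bad)) {
    stop_mgmtvaf(
      sprintf("non-numeric %s value(s) in row(s) %s", field,
              paste(which(bad), collapse = ", ")),
      "mgmtvaf_validation_error"
    )
  }
  out
}

as_logical_strict <- function(values) {
  if (is.logical(values)) return(values)
  values <- toupper(as.character(values))
  values[values == ""] <- NA_character_
  out <- rep(NA, length(values))
  out[values %in% c("TRUE", "T", "1", "YES")] <- TRUE
  out[values %in% c("FALSE", "F", "0", "NO")] <- FALSE
  out
}

validate_cohort_rows <- function(x) {
  problems <- character(0)
  note <- function(rows, msg) {
    if (any(rows, na.rm = TRUE)) {
      ids <- x$sample_id[which(rows)]
      problems <<- c(problems, sprintf(
        "row(s) %s (%s): %s", paste(which(rows), collapse = ", "),
        paste(ids, collapse = ", "), msg))
    }
  }
  note(is.na(x$sample_id) | x$sample_id == "", "empty sample_id")
  if (anyDuplicated(x$sample_id)) {
    dup <- unique(x$sample_id[duplicated(x$sample_id)])
    problems <- c(problems, paste0("duplicated sample_id: ",
                                   paste(dup, collapse = ", ")))
  }
  note(is.na(x$subtype), "missing subtype")
  note(is.na(x$assay), "missing assay")
  note(is.na(x$mgmt_call), "missing mgmt_call")
  note(is.na(x$driver_vaf), "missing driver_vaf")
  note(!is.na(x$driver_vaf) & (x$driver_vaf < 0 | x$driver_vaf > 1),
       "driver_vaf outside [0, 1]")
  for (col in c(SITE_COLUMNS, "micro_cellularity")) {
    note(!is.na(x[[col]]) & (x[[col]] < 0 | x[[col]] > 100),
         paste0(col, " outside [0, 100]"))
  }
  note(!is.na(x$classifier_score) &
         (x$classifier_score < 0 | x$classifier_score > 1),
       "classifier_score outside [0, 1]")

  sites <- as.matrix(x[, SITE_COLUMNS])
  has_sites <- rowSums(is.na(sites)) == 0
  check_mean <- has_sites & x$assay == "PYRO" & !is.na(x$mgmt_score)
  if (any(check_mean)) {
    mean_mismatch <- check_mean &
      abs(rowMeans(sites) - x$mgmt_score) > 0.01
    note(mean_mismatch, "mgmt_score differs from mean of site percents by > 0.01")
  }

  has_gene <- !is.na(x$driver_gene)
  note(has_gene & x$subtype == "GBM_IDHwt" & x$driver_gene != "TERTp",
       "IDH-wildtype GBM must carry a TERT promoter (TERTp) driver")
  note(has_gene & x$subtype != "GBM_IDHwt" &
         !(x$driver_gene %in% c("IDH1", "IDH2")),
       "IDH-mutant subtypes must carry an IDH1 or IDH2 driver")
  problems
}

#' Read a glioma cohort table from delimited text
#'
#' Reads a UTF-8 tab- or comma-delimited cohort file. The delimiter is
#' auto-detected from the header line (tab wins if present), or can be forced
#' with `delim`. Enum tokens are matched case-insensitively; empty fields are
#' missing values, never zeros. Rows violating any schema invariant abort the
#' read with row-level diagnostics.
#'
#' @param path Path to a delimited text file whose header names at least
#'   `sample_id`, `subtype`, `driver_vaf`, `assay`, `mgmt_call`.
#' @param delim Optional delimiter override (`"\t"` or `","`).
#' @return A `glioma_cohort` tibble (possibly with zero rows for a
#'   header-only file), with the source path recorded as provenance.
#' @seealso [write_cohort()] for the inverse operation.
#' @export
read_cohort <- function(path, delim = NULL) {
  if (!file.exists(path)) {
    stop_mgmtvaf(paste0("file not found: ", path), "mgmtvaf_io_error")
  }
  header <- readLines(path, n = 1L, encoding = "UTF-8")
  if (length(header) == 0) {
    stop_mgmtvaf(paste0("empty file (no header): ", path), "mgmtvaf_schema_error")
  }
  delim <- delim %||% (if (grepl("\t", header)) "\t" else ",")
  raw <- readr::read_delim(
    path, delim = delim,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(), progress = FALSE, show_col_types = FALSE
  )
  raw[raw == ""] <- NA
  as_cohort(raw, provenance = path)
}

#' Write a glioma cohort table to tab-delimited text
#'
#' The written file round-trips through [read_cohort()] without loss: enum
#' tokens are written in canonical form and missing optional values are
#' written as empty strings (never zeros).
#'
#' @param cohort A `glioma_cohort` (or coercible data frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  cohort <- ensure_cohort(cohort)
  readr::write_tsv(as.data.frame(cohort), path, na = "", progress = FALSE)
  invisible(path)
}

ensure_cohort <- function(x) {
  if (inherits(x, "glioma_cohort")) x else as_cohort(x)
}

## Samples usable for downstream statistics: QNS is retained in the table but
## excluded from every analysis.
usable_samples <- function(cohort) {
  cohort[cohort$mgmt_call != "QNS", , drop = FALSE]
}

## Binary-call subset helper shared by curves / cutpoints / report. Equivocal
## and QNS calls are excluded; callers decide whether to warn.
binary_call_samples <- function(cohort, warn = TRUE) {
  keep <- cohort$mgmt_call %in% c("POSITIVE", "NEGATIVE")
  dropped <- sum(!keep)
  if (warn && dropped > 0) {
    warning(sprintf("excluded %d sample(s) with EQUIVOCAL or QNS calls", dropped),
            call. = FALSE)
  }
  cohort[keep, , drop = FALSE]
}

#' Summarize a glioma cohort
#'
#' Tabulates counts by subtype, sex, WHO grade, assay and call, and computes
#' per-subtype VAF order statistics (mean, median, min, max). QNS samples are
#' counted in the call table but excluded from VAF statistics. The median of
#' an even-sized set is the midpoint of the two middle values.
#'
#' @param cohort A `glioma_cohort` (or coercible data frame).
#' @return A `cohort_summary` list with elements `n`, `counts` (named list of
#'   contingency tables as named integer vectors) and `vaf` (per-subtype
#'   tibble of statistics), plus overall VAF statistics. An empty cohort
#'   yields `n = 0` and empty components, not an error.
#' @export
summarize_cohort <- function(cohort) {
  cohort <- ensure_cohort(cohort)
  if (nrow(cohort) == 0) {
    out <- list(n = 0L, counts = list(), vaf = tibble::tibble(), vaf_overall = NULL)
    class(out) <- "cohort_summary"
    return(out)
  }
  count_of <- function(col) {
    v <- cohort[[col]]
    tab <- table(v[!is.na(v)])
    stats::setNames(as.integer(tab), names(tab))
  }
  counts <- list(
    subtype = count_of("subtype"),
    sex = count_of("sex"),
    who_grade = count_of("who_grade"),
    assay = count_of("assay"),
    mgmt_call = count_of("mgmt_call")
  )
  usable <- usable_samples(cohort)
  vaf_stats <- function(v) {
    tibble::tibble(n = length(v), mean = mean(v), median = stats::median(v),
                   min = min(v), max = max(v))
  }
  by_subtype <- lapply(split(usable$driver_vaf, usable$subtype), vaf_stats)
  vaf <- do.call(rbind, by_subtype)
  if (!is.null(vaf)) {
    vaf <- tibble::as_tibble(cbind(subtype = names(by_subtype), vaf))
  }
  out <- list(
    n = nrow(cohort),
    counts = counts,
    vaf = vaf %||% tibble::tibble(),
    vaf_overall = if (nrow(usable) > 0) vaf_stats(usable$driver_vaf) else NULL
  )
  class(out) <- "cohort_summary"
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Glioma cohort summary:", x$n, "samples\n")
  for (nm in names(x$counts)) {
    v <- x$counts[[nm]]
    if (length(v) == 0) next
    cat("  ", nm, ": ", paste(names(v), v, sep = "=", collapse = ", "), "\n", sep = "")
  }
  if (!is.null(x$vaf) && nrow(x$vaf) > 0) {
    cat("  VAF by subtype:\n")
    print(x$vaf)
  }
  invisible(x)
}

#' @export
print.glioma_cohort <- function(x, ...) {
  cat("<glioma_cohort> ", nrow(x), " samples (provenance: ",
      attr(x, "provenance") %||% "unknown", ")\n", sep = "")
  NextMethod()
}

#' Serialize a cohort summary to JSON
#'
#' @param summary A `cohort_summary` from [summarize_cohort()].
#' @param path Optional output path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
summary_to_json <- function(summary, path = NULL) {
  stopifnot(inherits(summary, "cohort_summary"))
  json <- jsonlite::toJSON(unclass(summary), auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null")
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}
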