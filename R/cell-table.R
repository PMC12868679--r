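#' Cell tables and clinical tables
#'
#' The pipeline's tabular interchange unit is a *cell table*: one row per
#' segmented cell with per-core identifiers, planar centroid coordinates in
#' micrometres (`x_um`, `y_um`), per-marker positivity probabilities
#' (`<marker>_prob`) and/or binary calls (`<marker>_pos`), and the label
#' columns filled in by downstream stages (`cell_type`, `functional_states`,
#' `cn2_label`, `cn3_label`, `mbn_label`). Several cores are held in a single
#' data frame keyed by `core_id`; coordinates are in a per-core frame with
#' the origin at the core bounding-box corner.
#'
#' @name cell_table
NULL

prob_cols <- function(markers) paste0(markers, "_prob")
pos_cols  <- function(markers) paste0(markers, "_pos")

#' Validate a cell table against a panel
#'
#' Checks identifier/coordinate columns, probability bounds, and (when both
#' probabilities and calls are present together with a threshold set) the
#' consistency `pos == (prob >= threshold)`.
#'
#' @param cells data.frame cell table.
#' @param panel [panel_config()].
#' @param thresholds optional named per-marker threshold vector used for the
#'   prob/pos consistency check.
#' @return the validated table, invisibly classed as `cell_table`.
#' @export
validate_cell_table <- function(cells, panel, thresholds = NULL) {
  for (col in c("core_id", "patient_id", "cell_id", "x_um", "y_um")) {
    if (!col %in% names(cells))
      stopf("cell table is missing mandatory column '%s'", col)
  }
  for (col in c("x_um", "y_um")) {
    if (!is.numeric(cells[[col]]))
      stopf("column '%s' must be numeric", col)
    bad <- which(!is.finite(cells[[col]]))
    if (length(bad))
      stopf("non-finite coordinate in column '%s' at row %d", col, bad[1])
  }
  markers <- panel_markers(panel)
  has_prob <- prob_cols(markers) %in% names(cells)
  has_pos  <- pos_cols(markers) %in% names(cells)
  # lineage markers are mandatory (typing depends on them); functional and
  # metabolic columns are required only by the stages that consume them
  lin <- markers %in% panel$lineage_markers
  if (any(lin & !(has_prob | has_pos)))
    stopf("no probability or positivity column for marker(s): %s",
          paste(markers[lin & !(has_prob | has_pos)], collapse = ", "))
  for (m in markers[has_prob]) {
    p <- cells[[prob_cols(m)]]
    if (any(p < 0 | p > 1, na.rm = TRUE))
      stopf("probability outside [0,1] for marker '%s'", m)
  }
  if (!is.null(thresholds)) {
    for (m in intersect(markers[has_prob & has_pos], names(thresholds))) {
      expect <- cells[[prob_cols(m)]] >= thresholds[[m]]
      obs <- as.logical(cells[[pos_cols(m)]])
      if (any(expect != obs, na.rm = TRUE))
        stopf("marker '%s': positivity calls inconsistent with probabilities at the given threshold", m)
    }
  }
  class(cells) <- unique(c("cell_table", class(cells)))
  invisible(cells)
}

#' Read / write cell tables
#'
#' CSV with one row per cell. Unknown columns are preserved. Row order is
#' stable across a write/read round trip.
#'
#' @param path CSV path.
#' @param panel [panel_config()] used for validation.
#' @rdname cell_table_io
#' @export
read_cell_table <- function(path, panel) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  cells <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  pos <- pos_cols(panel_markers(panel))
  for (col in intersect(pos, names(cells)))
    cells[[col]] <- as.logical(cells[[col]])
  validate_cell_table(cells, panel)
  cells
}

#' @param cells a cell table.
#' @rdname cell_table_io
#' @export
write_cell_table <- function(cells, path) {
  write.csv(full_precision(as.data.frame(cells)), path, row.names = FALSE)
  invisible(path)
}

# doubles serialized with 17 significant digits round-trip exactly
full_precision <- function(df) {
  for (j in seq_along(df))
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  df
}

#' Read / write the patient-level clinical table
#'
#' Columns: `patient_id`, `cohort_id`, `pfs_time`/`pfs_event`,
#' `os_time`/`os_event` (times in months, events logical), RECIST best
#' overall response `bor` (CR/PR/SD/PD) and the derived clinical-benefit
#' flag `cb6`.
#'
#' @param path CSV path.
#' @rdname clinical_io
#' @export
read_clinical_table <- function(path) {
  cl <- read.csv(path, stringsAsFactors = FALSE)
  for (col in c("pfs_event", "os_event", "cb6"))
    if (col %in% names(cl)) cl[[col]] <- as.logical(cl[[col]])
  validate_clinical_table(cl)
  cl
}

#' @param clinical clinical table data.frame.
#' @rdname clinical_io
#' @export
write_clinical_table <- function(clinical, path) {
  write.csv(full_precision(clinical), path, row.names = FALSE)
  invisible(path)
}

validate_clinical_table <- function(cl) {
  if (!"patient_id" %in% names(cl)) stopf("clinical table needs patient_id")
  for (col in c("pfs_time", "os_time")) {
    if (col %in% names(cl) && any(cl[[col]] <= 0, na.rm = TRUE))
      stopf("%s must be positive", col)
  }
  if ("bor" %in% names(cl)) {
    bad <- setdiff(stats::na.omit(unique(cl$bor)), c("CR", "PR", "SD", "PD"))
    if (length(bad)) stopf("unknown BOR category: %s", bad[1])
  }
  invisible(cl)
}

#' Derive clinical benefit at six months (CB6)
#'
#' A patient has clinical benefit when they achieved an objective response
#' (best overall response CR or PR) or remained progression-free beyond six
#' months. Progression at exactly six months counts as no benefit (strict
#' inequality).
#'
#' @param clinical clinical table with `bor` and/or `pfs_time`.
#' @return the table with a logical `cb6` column.
#' @export
derive_cb6 <- function(clinical) {
  has_bor <- "bor" %in% names(clinical)
  has_pfs <- "pfs_time" %in% names(clinical)
  if (!has_bor && !has_pfs)
    stopf("cannot derive cb6: need bor or pfs_time")
  bor_ok <- if (has_bor) clinical$bor %in% c("CR", "PR") else
    rep(NA, nrow(clinical))
  pfs_ok <- if (has_pfs) clinical$pfs_time > 6 else rep(NA, nrow(clinical))
  undef <- (if (has_bor) is.na(clinical$bor) else TRUE) &
    (if (has_pfs) is.na(clinical$pfs_time) else TRUE)
  if (any(undef))
    stopf("cb6 undefined for patient(s) with neither bor nor pfs: %s",
          paste(clinical$patient_id[undef], collapse = ", "))
  cb6 <- mapply(function(b, p) isTRUE(b) || isTRUE(p), bor_ok, pfs_ok)
  clinical$cb6 <- as.logical(cb6)
  clinical
}

# split/join the comma-separated functional_states column
states_split <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  strsplit(x, ",")
}
states_join <- function(lst) vapply(lst, paste, "", collapse = ",")
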