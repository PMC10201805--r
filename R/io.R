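#' Read a Bonn-style ASCII EEG segment
#'
#' The Bonn epilepsy corpus distributes each segment as a plain text file
#' with one sample value per line (nominally 4097 samples at 173.61 Hz).
#' Blank lines are ignored; integer, decimal and scientific notation are
#' accepted. Segment length is not enforced at read time, so truncated
#' fixtures remain usable.
#'
#' @param path Path to the ASCII file.
#' @param fs Sampling rate to attach, in Hz (default 173.61).
#' @return An [eeg_segment()] with `source_id` set to the file stem and no
#'   label.
#' @export
read_bonn_segment <- function(path, fs = 173.61) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0L) {
    stop("parse error in ", path, ": no sample values found", call. = FALSE)
  }
  vals <- suppressWarnings(as.numeric(trimws(lines[keep])))
  bad <- which(is.na(vals))
  if (length(bad) > 0L) {
    stop("parse error in ", path, " at line ", keep[bad[1L]],
         ": cannot parse '", lines[keep[bad[1L]]], "' as a number",
         call. = FALSE)
  }
  eeg_segment(vals, fs = fs,
              source_id = sub("\\.[^.]*$", "", basename(path)))
}

#' Read a New-Delhi-style MAT EEG segment
#'
#' Each MAT file is expected to hold exactly one numeric vector (nominally
#' 1024 samples at 200 Hz). The vector is flattened to 1-D regardless of
#' row/column orientation. Files with zero or several numeric variables are
#' rejected with the offending variable names listed, never guessed among.
#'
#' @param path Path to the MAT (v5) file.
#' @return An [eeg_segment()] with `fs = 200` and `source_id` set to the
#'   file stem.
#' @export
read_delhi_segment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  vars <- read_mat5(path)
  numeric_vars <- Filter(function(v) isTRUE(v$numeric), vars)
  if (length(numeric_vars) != 1L) {
    nms <- vapply(vars, function(v) v$name, character(1))
    stop("expected exactly one numeric variable in ", path, ", found ",
         length(numeric_vars),
         if (length(nms)) paste0(" (variables: ", paste(nms, collapse = ", "), ")"),
         call. = FALSE)
  }
  eeg_segment(as.numeric(numeric_vars[[1L]]$values), fs = 200,
              source_id = sub("\\.[^.]*$", "", basename(path)))
}

.cases_env <- new.env(parent = emptyenv())

#' Binary classification case definitions
#'
#' The 18 two-class tasks over the Bonn sets (A--E) and the New Delhi states
#' (preictal/interictal/ictal): for each case, the sets labeled 0 and the
#' sets labeled 1. Shipped as a human-readable JSON table in
#' `inst/extdata/cases.json`.
#'
#' @param case_id Optional case identifier (`"case1"` .. `"case18"`); when
#'   omitted the full table is returned.
#' @return A named list with `positive_sets` and `negative_sets` (for one
#'   case), or the list of all cases.
#' @export
case_spec <- function(case_id = NULL) {
  if (is.null(.cases_env$cases)) {
    path <- system.file("extdata", "cases.json", package = "eegseize",
                        mustWork = TRUE)
    .cases_env$cases <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  }
  cases <- .cases_env$cases
  if (is.null(case_id)) return(cases)
  spec <- cases[[case_id]]
  if (is.null(spec)) {
    stop("unknown case_id '", case_id, "'; known: ",
         paste(names(cases), collapse = ", "), call. = FALSE)
  }
  list(case_id = case_id,
       negative_sets = unlist(spec$negative_sets),
       positive_sets = unlist(spec$positive_sets))
}

#' Assemble a labeled dataset for one classification case
#'
#' Takes segments grouped by set name and returns the union of the sets a
#' case references, with labels attached (0 for the case's negative sets,
#' 1 for its positive sets). Ordering is deterministic: sets in the order
#' the case lists them (negatives first), then `source_id` lexicographic
#' (C locale) within each set, so downstream splits are reproducible from a
#' seed alone.
#'
#' @param case_id Case identifier (`"case1"` .. `"case18"`).
#' @param segments_by_set Named list: set name -> list of [eeg_segment()]s.
#' @return A list of labeled `eeg_segment` objects.
#' @export
assemble_case <- function(case_id, segments_by_set) {
  spec <- case_spec(case_id)
  wanted <- c(spec$negative_sets, spec$positive_sets)
  missing <- setdiff(wanted, names(segments_by_set))
  if (length(missing) > 0L) {
    stop("missing set(s) for ", case_id, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- list()
  for (set_name in wanted) {
    segs <- segments_by_set[[set_name]]
    ids <- vapply(segs, function(s) s$source_id, character(1))
    segs <- segs[order(ids, method = "radix")]
    lab <- if (set_name %in% spec$positive_sets) 1L else 0L
    segs <- lapply(segs, function(s) { s$label <- lab; s })
    out <- c(out, segs)
  }
  out
}

#' Feature matrix container
#'
#' Rows are segments, columns are named features, with an aligned label
#' vector. All values must be finite and column names unique.
#'
#' @param values Numeric matrix (segments x features) with column names.
#' @param labels Class tag per row (length = `nrow(values)`).
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, labels) {
  values <- as.matrix(values)
  if (is.null(colnames(values)) || anyDuplicated(colnames(values))) {
    stop("feature matrix needs unique column names", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("feature matrix contains non-finite values", call. = FALSE)
  }
  if (length(labels) != nrow(values)) {
    stop("labels length (", length(labels), ") != row count (",
         nrow(values), ")", call. = FALSE)
  }
  structure(list(values = values, feature_names = colnames(values),
                 labels = labels),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix> ", nrow(x$values), " segments x ",
      ncol(x$values), " features; labels: ",
      paste(names(table(x$labels)), table(x$labels), sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Write / read a feature table as CSV
#'
#' RFC-4180 CSV with a header row of feature names plus a final `label`
#' column. Values survive a round trip to at least 12 significant digits.
#'
#' @param fm A [feature_matrix()].
#' @param path Output (input) CSV path.
#' @return `write_feature_table()` returns `path` invisibly;
#'   `read_feature_table()` returns a [feature_matrix()].
#' @export
write_feature_table <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (!all(is.finite(fm$values))) {
    stop("refusing to write non-finite feature values", call. = FALSE)
  }
  df <- as.data.frame(fm$values, check.names = FALSE)
  df[["label"]] <- fm$labels
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!("label" %in% names(df))) {
    stop("feature table ", path, " has no 'label' column", call. = FALSE)
  }
  labels <- df[["label"]]
  df[["label"]] <- NULL
  if (ncol(df) == 0L) stop("feature table ", path, " has no feature columns",
                           call. = FALSE)
  feature_matrix(as.matrix(df), labels)
}
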