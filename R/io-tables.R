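#' Observable-table schemas
#'
#' Long-format residue-indexed NMR tables. Each kind has a fixed column set:
#' \describe{
#'   \item{tempseries}{`residue`, `temperature_K`, `shift_ppm` — amide proton
#'     chemical shift (ppm) per residue per temperature (K).}
#'   \item{hdx}{`residue`, `time_h`, `intensity` — cross-peak intensity per
#'     residue per exchange time (hours).}
#'   \item{relaxation}{`residue`, `r1`, `r2`, `noe`, `field_MHz` — 15N
#'     longitudinal/transverse rates (1/s), heteronuclear NOE, 1H field.}
#' }
#' @name observable_table
#' @keywords internal
NULL

obs_schema <- list(
  tempseries = list(key = c("residue", "temperature_K"),
                    numeric = c("temperature_K", "shift_ppm")),
  hdx = list(key = c("residue", "time_h"),
             numeric = c("time_h", "intensity")),
  relaxation = list(key = "residue",
                    numeric = c("r1", "r2", "noe", "field_MHz"))
)

new_observable_table <- function(df, kind, ground_truth = NULL) {
  kind <- match.arg(kind, names(obs_schema))
  sch <- obs_schema[[kind]]
  missing_cols <- setdiff(c(sch$key, sch$numeric), names(df))
  if (length(missing_cols) > 0) {
    stop(sprintf("%s table missing column(s): %s", kind,
                 paste(missing_cols, collapse = ", ")))
  }
  keys <- do.call(paste, df[sch$key])
  if (anyDuplicated(keys)) {
    stop(sprintf("duplicate %s key(s): %s", paste(sch$key, collapse = "+"),
                 paste(unique(keys[duplicated(keys)]), collapse = "; ")))
  }
  rownames(df) <- NULL
  structure(df, class = c("observable_table", "data.frame"),
            kind = kind, ground_truth = ground_truth)
}

#' Read a delimited table of NMR observables
#'
#' Accepts tab- or comma-delimited text with a header row. Missing cells are
#' kept as `NA`, never coerced to zero; non-numeric text in a numeric column
#' and duplicate residue keys are errors.
#'
#' @param path Path to the file.
#' @param kind One of `"tempseries"`, `"hdx"`, `"relaxation"` (see
#'   [observable_table]).
#' @return A data.frame of class `"observable_table"` with attribute `kind`.
#' @export
read_observable_table <- function(path,
                                  kind = c("tempseries", "hdx", "relaxation")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else if (grepl(",", header)) "," else ""
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""),
                          colClasses = "character")
  sch <- obs_schema[[kind]]
  for (col in sch$numeric) {
    if (!col %in% names(df)) next
    raw <- df[[col]]
    parsed <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(parsed))
    if (length(bad) > 0) {
      stop(sprintf("non-numeric value %s in column %s at row %d of %s",
                   dQuote(raw[bad[1]]), dQuote(col), bad[1], path))
    }
    df[[col]] <- parsed
  }
  new_observable_table(df, kind)
}

#' Write an observable table (tab-delimited)
#'
#' When the table carries generator ground truth, it is written alongside as
#' `<path>.truth.tsv` so synthetic datasets stay self-describing.
#'
#' @param table An `"observable_table"`.
#' @param path Output path.
#' @param with_truth Also write the ground-truth side-car if present.
#' @return `path`, invisibly.
#' @export
write_observable_table <- function(table, path, with_truth = TRUE) {
  stopifnot(inherits(table, "observable_table"))
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  gt <- attr(table, "ground_truth")
  if (with_truth && !is.null(gt)) {
    utils::write.table(as.data.frame(gt), paste0(path, ".truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @export
print.observable_table <- function(x, ...) {
  cat(sprintf("Observable table (%s): %d rows, %d residues\n",
              attr(x, "kind"), nrow(x), length(unique(x$residue))))
  NextMethod()
}
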