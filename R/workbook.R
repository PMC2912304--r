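# The acquisition workbook: a primary sheet of contextual-data rows plus any
# number of user-added extra sheets carried as opaque bytes. On disk a
# workbook is either a single CSV file (primary sheet only, RFC 4180, UTF-8)
# or a "workbook directory": manifest.json + primary.csv + the extra sheets
# stored verbatim. Extra sheets round-trip byte-identically through parse,
# storage and retrieval.

WORKBOOK_FORMAT_VERSION <- "1.0"

#' Construct an acquisition workbook in memory
#'
#' @param primary data.frame (character cells) with a header row of field
#'   names; one row per sample.
#' @param packages character vector of package names whose fields the
#'   template carries (recorded in the manifest so parsing needs no
#'   guesswork).
#' @param extra_sheets named list of raw vectors: user-added sheets kept as
#'   opaque bytes.
#' @param sheet_name name of the primary sheet.
#' @return An `acquisition_workbook`.
#' @export
acquisition_workbook <- function(primary, packages = character(0),
                                 extra_sheets = list(),
                                 sheet_name = "contextual_data") {
  stopifnot(is.data.frame(primary))
  primary[] <- lapply(primary, function(col) {
    vapply(col, format_raw, character(1), USE.NAMES = FALSE)
  })
  if (length(extra_sheets)) {
    stopifnot(!is.null(names(extra_sheets)),
              all(nzchar(names(extra_sheets))),
              all(vapply(extra_sheets, is.raw, logical(1))))
  }
  structure(list(primary = primary, packages = as.character(packages),
                 extra_sheets = extra_sheets, sheet_name = sheet_name),
            class = "acquisition_workbook")
}

#' @export
print.acquisition_workbook <- function(x, ...) {
  cat(sprintf("<acquisition_workbook> '%s': %d row(s) x %d column(s)",
              x$sheet_name, nrow(x$primary), ncol(x$primary)))
  if (length(x$packages)) cat("; packages:", paste(x$packages, collapse = ", "))
  if (length(x$extra_sheets)) {
    cat("; extra sheets:", paste(names(x$extra_sheets), collapse = ", "))
  }
  cat("\n")
  invisible(x)
}

#' Add an extra sheet to a workbook
#' @param wb an `acquisition_workbook`.
#' @param name sheet name.
#' @param content raw vector or character (encoded UTF-8) content.
#' @return The updated workbook.
#' @export
add_extra_sheet <- function(wb, name, content) {
  stopifnot(inherits(wb, "acquisition_workbook"))
  if (is.character(content)) {
    content <- charToRaw(paste(content, collapse = "\n"))
  }
  stopifnot(is.raw(content))
  wb$extra_sheets[[name]] <- content
  wb
}

# RFC 4180 CSV, deterministic: every cell quoted, CRLF-free LF line ends,
# UTF-8, no row names. Reading keeps every cell as verbatim text.
write_sheet_csv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  esc <- function(x) paste0('"', gsub('"', '""', x, fixed = TRUE), '"')
  writeLines(paste(esc(names(df)), collapse = ","), con, sep = "\n",
             useBytes = TRUE)
  if (nrow(df)) {
    rows <- apply(as.matrix(df), 1L, function(r) paste(esc(r), collapse = ","))
    writeLines(rows, con, sep = "\n", useBytes = TRUE)
  }
  invisible(path)
}

read_sheet_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        na.strings = character(0), fileEncoding = "UTF-8")
  if (is.null(names(df)) || ncol(df) == 0L) {
    stop_structural("missing_header", paste("no header row in", path))
  }
  df
}

#' Write a workbook to disk
#'
#' A path ending in `.csv` writes the primary sheet as a single CSV file
#' (refused when extra sheets are present, as they would be lost); any other
#' path becomes a workbook directory holding `manifest.json`, the primary
#' sheet CSV and each extra sheet verbatim.
#'
#' @param wb an `acquisition_workbook`.
#' @param path destination file or directory.
#' @return `path`, invisibly.
#' @export
write_workbook <- function(wb, path) {
  stopifnot(inherits(wb, "acquisition_workbook"))
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    if (length(wb$extra_sheets)) {
      stop("workbook has extra sheets; a single CSV cannot carry them (use a directory path)",
           call. = FALSE)
    }
    return(invisible(write_sheet_csv(wb$primary, path)))
  }
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  extra_files <- character(0)
  if (length(wb$extra_sheets)) {
    extra_files <- sprintf("sheet%02d_%s", seq_along(wb$extra_sheets) + 1L,
                           gsub("[^A-Za-z0-9._-]", "_", names(wb$extra_sheets)))
    for (i in seq_along(wb$extra_sheets)) {
      writeBin(wb$extra_sheets[[i]], file.path(path, extra_files[i]))
    }
  }
  manifest <- list(format_version = WORKBOOK_FORMAT_VERSION,
                   primary_sheet = list(name = wb$sheet_name, file = "sheet01.csv"),
                   packages = as.list(wb$packages),
                   extra_sheets = if (length(wb$extra_sheets)) {
                     lapply(seq_along(wb$extra_sheets), function(i) {
                       list(name = names(wb$extra_sheets)[i], file = extra_files[i])
                     })
                   } else list())
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  write_sheet_csv(wb$primary, file.path(path, "sheet01.csv"))
  invisible(path)
}

#' Read a workbook from disk
#'
#' Accepts a workbook directory (with `manifest.json`) or a bare CSV file
#' (primary sheet only). The input is never modified.
#'
#' @param path workbook directory or CSV file.
#' @return An `acquisition_workbook`.
#' @export
read_workbook <- function(path) {
  if (dir.exists(path)) {
    mf_path <- file.path(path, "manifest.json")
    if (!file.exists(mf_path)) {
      stop_structural("unreadable_file",
                      paste("workbook directory lacks manifest.json:", path))
    }
    mf <- jsonlite::read_json(mf_path, simplifyVector = FALSE)
    primary <- read_sheet_csv(file.path(path, mf$primary_sheet$file))
    extras <- list()
    for (es in mf$extra_sheets) {
      f <- file.path(path, es$file)
      extras[[es$name]] <- readBin(f, what = "raw", n = file.size(f))
    }
    return(acquisition_workbook(primary,
                                packages = as.character(unlist(mf$packages)),
                                extra_sheets = extras,
                                sheet_name = mf$primary_sheet$name %||% "contextual_data"))
  }
  if (!file.exists(path)) {
    stop_structural("unreadable_file", paste("no such workbook:", path))
  }
  acquisition_workbook(read_sheet_csv(path))
}

# structural parse problems carry a machine-readable code
stop_structural <- function(code, message) {
  cond <- structure(class = c("fieldbar_structural_error", "error", "condition"),
                    list(message = paste0("[", code, "] ", message),
                         call = NULL, code = code))
  stop(cond)
}
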