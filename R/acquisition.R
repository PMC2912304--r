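#' Build an acquisition spreadsheet template
#'
#' The template is what field scientists take sampling: one pre-filled
#' identifier per row (read-only by convention) and empty contextual-data
#' columns — the core x, y, z, t fields, names, seqID, then the fields of the
#' packages chosen at template time, in registry order. A field name shared
#' by several chosen packages is written package-qualified
#' (`"water:temperature"`) to keep columns unambiguous; otherwise bare names
#' are used.
#'
#' @param identifiers non-empty list of `sample_identifier`s.
#' @param packages character vector of registered package names.
#' @param registry the package registry.
#' @return An `acquisition_workbook` with one data row per identifier.
#' @examples
#' ids <- block_identifiers(allocate_block(7, 3, 0), institute_code = 2)
#' wb <- build_template(ids, packages = "air")
#' names(wb$primary)[1:5]
#' @export
build_template <- function(identifiers, packages = character(0),
                           registry = default_registry()) {
  if (length(identifiers) == 0L) {
    stop("at least one identifier is required to build a template", call. = FALSE)
  }
  cols <- template_columns(packages, registry)
  df <- as.data.frame(matrix("", nrow = length(identifiers), ncol = length(cols)),
                      stringsAsFactors = FALSE)
  names(df) <- cols
  df$identifier <- vapply(identifiers, function(id) {
    stopifnot(is_sample_identifier(id))
    format(id)
  }, character(1))
  acquisition_workbook(df, packages = packages)
}

template_columns <- function(packages, registry = default_registry()) {
  pkg_fields <- lapply(packages, function(p) names(get_package(p, registry)$fields))
  all_names <- unlist(pkg_fields)
  dup <- unique(all_names[duplicated(all_names)])
  pkg_cols <- unlist(lapply(seq_along(packages), function(i) {
    ifelse(pkg_fields[[i]] %in% dup,
           paste0(packages[i], ":", pkg_fields[[i]]), pkg_fields[[i]])
  }))
  c("identifier", CORE_FIELDS, pkg_cols)
}

# field names unique to exactly one registered package; used to infer which
# packages a bare CSV (no manifest) was built with
unique_field_owners <- function(registry = default_registry()) {
  owners <- list()
  for (p in registry_packages(registry)) {
    for (f in names(get_package(p, registry)$fields)) {
      owners[[f]] <- c(owners[[f]], p)
    }
  }
  out <- vapply(owners, function(x) if (length(x) == 1L) x else NA_character_,
                character(1))
  out[!is.na(out)]
}

#' Parse a filled acquisition workbook into contextual records
#'
#' Each non-empty row of the primary sheet becomes one [contextual_record()].
#' Known columns map to core fields or attached-package fields; unknown
#' columns are kept per record under `extras` — they are never dropped.
#' Worksheets after the first are preserved verbatim in the result. The input
#' file is never modified; a full validation report is attached.
#'
#' INSDC-style columns written by the MIxS exporter are understood on the way
#' back in: `lat_lon` splits into latitude/longitude, `collection_date`
#' parses `DD-Mmm-YYYY`, and `depth`/`altitude` map to the signed vertical
#' position (depth positive, altitude negative).
#'
#' Rows whose cells are all empty are skipped. Structural problems — an
#' unreadable file, a missing header or identifier column, an empty or
#' unparseable identifier on an otherwise filled row, or the same identifier
#' on two rows — raise a `fieldbar_structural_error` whose `code` field is
#' one of `unreadable_file`, `missing_header`, `missing_identifier_column`,
#' `empty_identifier`, `bad_identifier`, `duplicate_identifier`.
#'
#' @param x an `acquisition_workbook`, a workbook directory or a CSV path.
#' @param registry the package registry.
#' @param packages packages the sheet's columns belong to; defaults to the
#'   workbook manifest, or (bare CSV) to inference from columns whose field
#'   name is unique to one registered package.
#' @param today reference date for the future-timestamp check (see
#'   [validate_record()]).
#' @return A `parse_result`: list with `records`, `report`
#'   (a `validation_report` with row numbers), `extra_sheets`, `packages`.
#' @export
parse_workbook <- function(x, registry = default_registry(), packages = NULL,
                           today = NULL) {
  wb <- if (inherits(x, "acquisition_workbook")) x else read_workbook(x)
  df <- wb$primary
  if (is.null(packages)) {
    packages <- if (length(wb$packages)) wb$packages else
      infer_packages(names(df), registry)
  }
  for (p in packages) get_package(p, registry)

  if (!"identifier" %in% names(df)) {
    stop_structural("missing_identifier_column",
                    "primary sheet has no 'identifier' column")
  }
  owners <- unique_field_owners(registry)
  records <- list(); keys_seen <- character(0); rows_used <- integer(0)
  for (i in seq_len(nrow(df))) {
    row <- as.list(df[i, , drop = FALSE])
    row <- lapply(row, function(v) trimws(as.character(v)))
    if (all(!nzchar(unlist(row)))) next  # blank row: skipped, not an error
    if (!nzchar(row$identifier)) {
      stop_structural("empty_identifier",
                      sprintf("row %d has values but no identifier", i))
    }
    id <- tryCatch(parse_identifier(row$identifier), error = function(e) {
      stop_structural("bad_identifier",
                      sprintf("row %d: %s", i, conditionMessage(e)))
    })
    key <- format(id, "numeric")
    if (key %in% keys_seen) {
      stop_structural("duplicate_identifier",
                      sprintf("identifier %s appears on more than one row", format(id)))
    }
    keys_seen <- c(keys_seen, key)
    records[[length(records) + 1L]] <- row_to_record(id, row, packages,
                                                    registry, owners)
    rows_used <- c(rows_used, i)
  }
  report <- combine_reports(lapply(seq_along(records), function(k) {
    validate_record(records[[k]], registry, row = rows_used[k], today = today)
  }))
  structure(list(records = records, report = report,
                 extra_sheets = wb$extra_sheets, packages = packages),
            class = "parse_result")
}

infer_packages <- function(cols, registry) {
  owners <- unique_field_owners(registry)
  bare <- sub("^[^:]+:", "", cols)
  qualified <- grepl(":", cols, fixed = TRUE)
  inferred <- unique(c(vapply(cols[qualified], function(cn) {
    strsplit(cn, ":", fixed = TRUE)[[1L]][1L]
  }, character(1)), unname(owners[intersect(cols[!qualified], names(owners))])))
  intersect(registry_packages(registry), inferred)  # registry order
}

row_to_record <- function(id, row, packages, registry, owners) {
  rec <- contextual_record(id)
  for (p in packages) rec <- attach_package(rec, p, registry)
  pkg_fields <- lapply(packages, function(p) names(get_package(p, registry)$fields))
  names(pkg_fields) <- packages
  for (cn in setdiff(names(row), "identifier")) {
    v <- row[[cn]]
    if (cn %in% CORE_FIELDS) {
      rec$core[[cn]] <- v
    } else if (cn == "lat_lon") {
      if (nzchar(v)) {
        ll <- tryCatch(parse_lat_lon(v), error = function(e) NULL)
        if (is.null(ll)) {
          rec$core$latitude <- v  # surfaces as a validation error, not a crash
        } else {
          rec$core$latitude <- format_raw(ll$latitude)
          rec$core$longitude <- format_raw(ll$longitude)
        }
      }
    } else if (cn == "collection_date") {
      if (nzchar(v)) {
        d <- tryCatch(parse_collection_date(v), error = function(e) NULL)
        rec$core$collection_timestamp <- if (is.null(d)) v else format(d)
      }
    } else if (cn == "depth") {
      if (nzchar(v)) rec$core$vertical_position <- v
    } else if (cn == "altitude") {
      if (nzchar(v)) {
        num <- parse_raw_number(v)
        rec$core$vertical_position <- if (is.na(num)) v else format_raw(-num)
      }
    } else if (grepl(":", cn, fixed = TRUE)) {
      parts <- strsplit(cn, ":", fixed = TRUE)[[1L]]
      if (parts[1L] %in% packages &&
          parts[2L] %in% pkg_fields[[parts[1L]]]) {
        if (nzchar(v)) rec <- set_field(rec, cn, v, registry)
      } else {
        rec$extras[[cn]] <- v
      }
    } else {
      hit <- packages[vapply(packages, function(p) cn %in% pkg_fields[[p]],
                             logical(1))]
      if (length(hit)) {
        if (nzchar(v)) rec <- set_field(rec, paste0(hit[1L], ":", cn), v, registry)
      } else {
        rec$extras[[cn]] <- v
      }
    }
  }
  rec
}

#' @export
print.parse_result <- function(x, ...) {
  cat(sprintf("<parse_result> %d record(s); packages: %s\n", length(x$records),
              if (length(x$packages)) paste(x$packages, collapse = ", ") else "none"))
  print(x$report)
  invisible(x)
}

#' Merge an updated record into an existing one
#'
#' The acquisition loop is repeated whenever data need editing: a re-uploaded
#' sheet carries the same identifiers with corrected or added values. Merging
#' lets non-empty incoming values overwrite while empty incoming cells leave
#' the stored values untouched; extras merge by key with (non-empty) incoming
#' precedence; package attachments are unioned.
#'
#' @param existing,incoming `contextual_record`s with the same identifier.
#' @param registry the package registry.
#' @return The merged `contextual_record`.
#' @export
merge_update <- function(existing, incoming, registry = default_registry()) {
  stopifnot(inherits(existing, "contextual_record"),
            inherits(incoming, "contextual_record"))
  if (format(existing$identifier) != format(incoming$identifier)) {
    stop(sprintf("cannot merge records with different identifiers: %s vs %s",
                 format(existing$identifier), format(incoming$identifier)),
         call. = FALSE)
  }
  out <- existing
  for (f in names(incoming$core)) {
    if (!is_empty_raw(incoming$core[[f]])) out$core[[f]] <- incoming$core[[f]]
  }
  for (p in incoming$attached_packages) out <- attach_package(out, p, registry)
  for (k in names(incoming$field_values)) {
    if (!is_empty_raw(incoming$field_values[[k]])) {
      out$field_values[[k]] <- incoming$field_values[[k]]
    }
  }
  for (k in names(incoming$extras)) {
    if (!is_empty_raw(incoming$extras[[k]]) || is.null(out$extras[[k]])) {
      out$extras[[k]] <- incoming$extras[[k]]
    }
  }
  out
}
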