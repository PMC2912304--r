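#' Validate contextual records against the package registry
#'
#' Runs the value- and record-level checks that the acquisition workflow
#' applies before data are stored or exported. All problems are reported,
#' never raised: the result is an ordered list of issues, each an ERROR or a
#' WARNING tied to a field (and a row, when validating a parsed sheet).
#'
#' ERRORs: a missing component of the required x, y, z, t tuple; latitude or
#' longitude unparseable or outside \[-90, 90\] / \[-180, 180\]; an
#' unparseable vertical position or collection timestamp; a numeric package
#' field that is not a number, not an integer where one is required, or
#' outside its declared range; a value outside a field's controlled
#' vocabulary. WARNINGs: a collection timestamp in the future (clocks drift
#' on vessels, so this is not fatal) and an empty mandatory package field.
#' A report is `acceptable` iff it contains no ERRORs.
#'
#' Issue order is deterministic: by row, then core fields in canonical order,
#' then attached packages in attachment order with fields in registry order.
#'
#' @param record a `contextual_record`.
#' @param registry the package registry.
#' @param row optional row number to stamp on the issues (used when the
#'   record came from a sheet).
#' @param today reference date for the future-timestamp check; defaults to
#'   the current UTC date.
#' @return A `validation_report`: list with `issues` (data.frame with columns
#'   severity, field, row, message) and `acceptable`.
#' @examples
#' r <- contextual_record(make_identifier(2, 1, 1), latitude = 91,
#'                        longitude = 0, vertical_position = 0,
#'                        collection_timestamp = "2009-10-05")
#' validate_record(r)$issues
#' @export
validate_record <- function(record, registry = default_registry(), row = NA,
                            today = NULL) {
  stopifnot(inherits(record, "contextual_record"))
  if (is.null(today)) today <- as.Date(format(Sys.time(), tz = "UTC"))
  iss <- issue_collector()

  core <- record$core
  # x, y: presence, parseability, range
  for (f in c("latitude", "longitude")) {
    v <- core[[f]]
    lim <- if (f == "latitude") 90 else 180
    if (is_empty_raw(v)) {
      iss$add("ERROR", f, row, sprintf("%s is required (x,y,z,t tuple)", f))
    } else {
      num <- parse_raw_number(v)
      if (is.na(num)) {
        iss$add("ERROR", f, row, sprintf("%s '%s' is not a number", f, format_raw(v)))
      } else if (num < -lim || num > lim) {
        iss$add("ERROR", f, row,
                sprintf("%s %s outside [%d, %d] decimal degrees", f,
                        format_raw(num), -lim, lim))
      }
    }
  }
  # z
  v <- core$vertical_position
  if (is_empty_raw(v)) {
    iss$add("ERROR", "vertical_position", row,
            "vertical_position is required (x,y,z,t tuple)")
  } else if (is.na(parse_raw_number(v))) {
    iss$add("ERROR", "vertical_position", row,
            sprintf("vertical_position '%s' is not a number", format_raw(v)))
  }
  # t
  v <- core$collection_timestamp
  if (is_empty_raw(v)) {
    iss$add("ERROR", "collection_timestamp", row,
            "collection_timestamp is required (x,y,z,t tuple)")
  } else {
    ts <- parse_raw_timestamp(v)
    if (is.na(ts$date)) {
      iss$add("ERROR", "collection_timestamp", row,
              sprintf("collection_timestamp '%s' is not an ISO 8601 date or date+time",
                      format_raw(v)))
    } else if (ts$date > today) {
      iss$add("WARNING", "collection_timestamp", row,
              sprintf("collection_timestamp %s is in the future", ts$date))
    }
  }

  # package fields, attachment order then registry field order
  for (pkg in record$attached_packages) {
    def <- get_package(pkg, registry)
    for (fld in names(def$fields)) {
      fdef <- def$fields[[fld]]
      key <- paste0(pkg, ":", fld)
      v <- record$field_values[[key]]
      if (is.null(v) || is_empty_raw(v)) {
        if (fdef$requirement == "mandatory") {
          iss$add("WARNING", key, row,
                  sprintf("mandatory field '%s' of package '%s' is empty", fld, pkg))
        }
        next
      }
      check_field_value(iss, key, fdef, v, row)
    }
  }
  # orphaned field values (package detached or never attached)
  known <- unlist(lapply(record$attached_packages, function(p) {
    paste0(p, ":", names(get_package(p, registry)$fields))
  }))
  for (key in setdiff(names(record$field_values), known)) {
    iss$add("ERROR", key, row,
            sprintf("value for '%s' does not resolve to an attached package field", key))
  }
  validation_report(iss$get())
}

check_field_value <- function(iss, key, fdef, v, row) {
  txt <- format_raw(v)
  switch(fdef$value_type,
    decimal = , integer = {
      num <- parse_raw_number(v)
      if (is.na(num)) {
        iss$add("ERROR", key, row, sprintf("'%s' is not a number for field '%s'",
                                           txt, key))
      } else if (fdef$value_type == "integer" && num != trunc(num)) {
        iss$add("ERROR", key, row, sprintf("'%s' is not an integer for field '%s'",
                                           txt, key))
      } else if (!is.null(fdef$numeric_range) &&
                 (num < fdef$numeric_range[1L] || num > fdef$numeric_range[2L])) {
        iss$add("ERROR", key, row,
                sprintf("%s outside declared range [%s, %s] for field '%s'%s",
                        txt, format_raw(fdef$numeric_range[1L]),
                        format_raw(fdef$numeric_range[2L]), key,
                        if (nzchar(fdef$units)) paste0(" (", fdef$units, ")") else ""))
      }
    },
    timestamp = {
      if (is.na(parse_raw_timestamp(v)$date)) {
        iss$add("ERROR", key, row,
                sprintf("'%s' is not a timestamp for field '%s'", txt, key))
      }
    },
    vocabulary = {
      if (!txt %in% fdef$vocabulary) {
        iss$add("ERROR", key, row,
                sprintf("'%s' is not in the vocabulary {%s} of field '%s'",
                        txt, paste(fdef$vocabulary, collapse = ", "), key))
      }
    },
    text = NULL
  )
  invisible(NULL)
}

issue_collector <- function() {
  sev <- character(0); fld <- character(0); row <- integer(0); msg <- character(0)
  list(
    add = function(severity, field, rown, message) {
      sev <<- c(sev, severity); fld <<- c(fld, field)
      row <<- c(row, if (is.na(rown)) NA_integer_ else as.integer(rown))
      msg <<- c(msg, message)
    },
    get = function() data.frame(severity = sev, field = fld, row = row,
                                message = msg, stringsAsFactors = FALSE)
  )
}

validation_report <- function(issues) {
  structure(list(issues = issues,
                 acceptable = !any(issues$severity == "ERROR")),
            class = "validation_report")
}

#' Combine per-row validation reports into one
#' @param reports list of `validation_report`s.
#' @return One `validation_report` with issues concatenated in order.
#' @export
combine_reports <- function(reports) {
  validation_report(do.call(rbind, c(lapply(reports, `[[`, "issues"),
                                     list(make.row.names = FALSE))))
}

#' Validate a list of records, stamping 1-based row numbers
#' @param records list of `contextual_record`s.
#' @inheritParams validate_record
#' @return A combined `validation_report`.
#' @export
validate_records <- function(records, registry = default_registry(),
                             today = NULL) {
  combine_reports(lapply(seq_along(records), function(i) {
    validate_record(records[[i]], registry, row = i, today = today)
  }))
}

#' @export
print.validation_report <- function(x, ...) {
  n_err <- sum(x$issues$severity == "ERROR")
  n_warn <- sum(x$issues$severity == "WARNING")
  cat(sprintf("<validation_report> %s: %d error(s), %d warning(s)\n",
              if (x$acceptable) "acceptable" else "NOT acceptable",
              n_err, n_warn))
  if (nrow(x$issues)) print(x$issues, row.names = FALSE)
  invisible(x)
}
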