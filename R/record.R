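#' Contextual-data records
#'
#' A contextual record holds everything known about one sample: its
#' identifier, the core georeferencing context (the x, y, z, t tuple plus
#' names and the seqID link to sequence data), values for fields of attached
#' GSC packages, and free-form extra columns a user added to the acquisition
#' sheet. Values are stored raw (as entered); [validate_record()] judges them.
#'
#' The vertical position is one signed field in meters relative to sea level:
#' positive values are depth below, negative values altitude above. The split
#' into separate depth/altitude columns happens only at export.
#'
#' @param identifier a `sample_identifier` (or canonical/numeric string).
#' @param latitude,longitude decimal degrees (WGS84); raw values accepted.
#' @param vertical_position signed meters (positive = depth below sea level).
#' @param collection_timestamp ISO 8601 date or date+time (naive times are
#'   treated as UTC).
#' @param sample_name,collector free text.
#' @param seqID optional sequence identifier matching FASTA headers at
#'   submission time.
#' @return An object of class `contextual_record`.
#' @examples
#' r <- contextual_record(make_identifier(2, 123, 45),
#'                        latitude = 54.18, longitude = 7.9,
#'                        vertical_position = 10,
#'                        collection_timestamp = "2009-10-05",
#'                        sample_name = "helgoland-1", collector = "pm1")
#' r <- attach_package(r, "water")
#' r <- set_field(r, "temperature", 9.5)
#' @export
contextual_record <- function(identifier,
                              latitude = NA, longitude = NA,
                              vertical_position = NA,
                              collection_timestamp = NA,
                              sample_name = "", collector = "",
                              seqID = "") {
  if (is.character(identifier)) identifier <- parse_identifier(identifier)
  stopifnot(is_sample_identifier(identifier))
  core <- list(latitude = latitude, longitude = longitude,
               vertical_position = vertical_position,
               collection_timestamp = collection_timestamp,
               sample_name = sample_name, collector = collector,
               seqID = seqID)
  structure(list(identifier = identifier, core = core,
                 attached_packages = character(0),
                 field_values = list(), extras = list()),
            class = "contextual_record")
}

#' @export
print.contextual_record <- function(x, ...) {
  cat("<contextual_record>", format(x$identifier), "\n")
  cat("  core:", paste(sprintf("%s=%s", names(x$core),
                               vapply(x$core, format_raw, character(1))),
                       collapse = ", "), "\n")
  if (length(x$attached_packages)) {
    cat("  packages:", paste(x$attached_packages, collapse = ", "), "\n")
  }
  if (length(x$field_values)) {
    cat("  fields:", paste(sprintf("%s=%s", names(x$field_values),
                                   vapply(x$field_values, format_raw, character(1))),
                           collapse = ", "), "\n")
  }
  if (length(x$extras)) {
    cat("  extras:", paste(names(x$extras), collapse = ", "), "\n")
  }
  invisible(x)
}

# raw cell values: anything a spreadsheet cell can hold, rendered as text
format_raw <- function(v) {
  if (is.null(v) || length(v) == 0L || (length(v) == 1L && is.na(v))) return("")
  if (is.numeric(v)) {
    return(format(v, scientific = FALSE, trim = TRUE, digits = 15))
  }
  as.character(v)
}

is_empty_raw <- function(v) !nzchar(format_raw(v))

#' Attach a GSC package to a record
#'
#' Appends the named package to the record's attachment list (idempotent: a
#' second attachment of the same package is a no-op) and makes its fields
#' settable via [set_field()].
#'
#' @param record a `contextual_record`.
#' @param name registered package name.
#' @param registry the package registry to resolve against.
#' @return The updated record.
#' @export
attach_package <- function(record, name, registry = default_registry()) {
  stopifnot(inherits(record, "contextual_record"))
  get_package(name, registry)  # errors on unknown package
  if (!name %in% record$attached_packages) {
    record$attached_packages <- c(record$attached_packages, name)
  }
  record
}

# Resolve a field reference against a record's attached packages.
# Accepts qualified "package:field" or a bare field name (matched against
# attached packages in attachment order). Returns list(package, field) or
# errors when unresolvable.
resolve_field <- function(record, ref, registry = default_registry()) {
  if (grepl(":", ref, fixed = TRUE)) {
    parts <- strsplit(ref, ":", fixed = TRUE)[[1L]]
    pkg <- parts[1L]; fld <- paste(parts[-1L], collapse = ":")
    if (!pkg %in% record$attached_packages) {
      stop(sprintf("package '%s' is not attached to record %s",
                   pkg, format(record$identifier)), call. = FALSE)
    }
    def <- get_package(pkg, registry)
    if (!fld %in% names(def$fields)) {
      stop(sprintf("package '%s' has no field '%s'", pkg, fld), call. = FALSE)
    }
    return(list(package = pkg, field = fld))
  }
  for (pkg in record$attached_packages) {
    def <- get_package(pkg, registry)
    if (ref %in% names(def$fields)) return(list(package = pkg, field = ref))
  }
  stop(sprintf(
    "field '%s' does not resolve to any attached package of record %s (attached: %s)",
    ref, format(record$identifier),
    if (length(record$attached_packages)) paste(record$attached_packages, collapse = ", ")
    else "none"), call. = FALSE)
}

#' Set a package field value on a record
#'
#' @param record a `contextual_record` with the field's package attached.
#' @param field field name, bare (`"temperature"`, resolved against attached
#'   packages in attachment order) or qualified (`"water:temperature"`).
#' @param value raw value (text or number, as a spreadsheet cell would hold).
#' @param registry the package registry.
#' @return The updated record.
#' @export
set_field <- function(record, field, value, registry = default_registry()) {
  stopifnot(inherits(record, "contextual_record"))
  res <- resolve_field(record, field, registry)
  key <- paste0(res$package, ":", res$field)
  record$field_values[[key]] <- value
  record
}

#' Read a package field value from a record
#' @inheritParams set_field
#' @return The raw value, or `NULL` when unset.
#' @export
get_field <- function(record, field, registry = default_registry()) {
  res <- resolve_field(record, field, registry)
  record$field_values[[paste0(res$package, ":", res$field)]]
}

#' Set a free-form extra column on a record
#'
#' Extras are user-added spreadsheet columns outside the data model; they are
#' preserved through parsing, storage and export but never validated against
#' the registry. An extra may not shadow a registered field of an attached
#' package.
#'
#' @inheritParams set_field
#' @param name extra column name.
#' @export
set_extra <- function(record, name, value, registry = default_registry()) {
  stopifnot(inherits(record, "contextual_record"))
  for (pkg in record$attached_packages) {
    if (name %in% names(get_package(pkg, registry)$fields)) {
      stop(sprintf("extra column '%s' collides with a field of attached package '%s'",
                   name, pkg), call. = FALSE)
    }
  }
  record$extras[[name]] <- value
  record
}

#' Is a record export-eligible?
#'
#' A record is eligible for the standards-compliant exports once the full
#' x, y, z, t tuple (latitude, longitude, vertical position, collection
#' timestamp) is present and parseable and the coordinates are in range.
#'
#' @param record a `contextual_record`.
#' @return `TRUE` or `FALSE`.
#' @export
is_export_eligible <- function(record) {
  lat <- parse_raw_number(record$core$latitude)
  lon <- parse_raw_number(record$core$longitude)
  z <- parse_raw_number(record$core$vertical_position)
  t <- parse_raw_timestamp(record$core$collection_timestamp)
  !is.na(lat) && !is.na(lon) && !is.na(z) && !is.na(t$date) &&
    lat >= -90 && lat <= 90 && lon >= -180 && lon <= 180
}

# ---- raw value coercion -----------------------------------------------------
# Spreadsheet cells arrive as text or numbers; these coercers are shared by
# validation, export and parsing. They return NA for unparseable input and
# never raise.

parse_raw_number <- function(v) {
  if (is.null(v) || length(v) == 0L) return(NA_real_)
  if (is.numeric(v)) return(as.numeric(v))
  s <- trimws(as.character(v))
  if (!nzchar(s) || is.na(s)) return(NA_real_)
  if (!grepl("^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?$", s)) {
    return(NA_real_)
  }
  as.numeric(s)
}

MONTHS_EN <- c("Jan", "Feb", "Mar", "Apr", "May", "Jun",
               "Jul", "Aug", "Sep", "Oct", "Nov", "Dec")

# Accepts ISO 8601 "YYYY-MM-DD", optionally followed by "THH:MM[:SS]" or
# " HH:MM[:SS]", optional trailing "Z". Naive times are treated as UTC.
# Returns list(date = Date or NA, time = "HH:MM:SS" or "").
parse_raw_timestamp <- function(v) {
  empty <- list(date = as.Date(NA), time = "")
  if (is.null(v) || length(v) == 0L) return(empty)
  if (inherits(v, "Date")) return(list(date = v, time = ""))
  if (inherits(v, "POSIXct")) {
    return(list(date = as.Date(v, tz = "UTC"),
                time = format(v, "%H:%M:%S", tz = "UTC")))
  }
  s <- trimws(as.character(v))
  if (!nzchar(s) || is.na(s)) return(empty)
  m <- regexec(paste0("^([0-9]{4})-([0-9]{2})-([0-9]{2})",
                      "([T ]([0-9]{2}):([0-9]{2})(:([0-9]{2}))?)?Z?$"), s)
  g <- regmatches(s, m)[[1L]]
  if (length(g) == 0L) return(empty)
  d <- as.Date(paste(g[2L], g[3L], g[4L], sep = "-"), format = "%Y-%m-%d")
  if (is.na(d)) return(empty)  # e.g. Feb 30
  # as.Date() with %d accepts day 00 on some platforms; reject explicitly
  if (as.integer(g[4L]) < 1L || as.integer(g[3L]) < 1L || as.integer(g[3L]) > 12L) {
    return(empty)
  }
  time <- ""
  if (nzchar(g[5L])) {
    hh <- as.integer(g[6L]); mm <- as.integer(g[7L])
    ss <- if (nzchar(g[9L])) as.integer(g[9L]) else 0L
    if (hh > 23L || mm > 59L || ss > 60L) return(empty)
    time <- sprintf("%02d:%02d:%02d", hh, mm, ss)
  }
  list(date = d, time = time)
}
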