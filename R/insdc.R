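# INSDC source-qualifier syntaxes: lat_lon ("48.5 N 123.25 W") and
# collection_date ("05-Oct-2009"). English month abbreviations are used
# regardless of locale.

#' Format coordinates as an INSDC lat_lon qualifier
#'
#' Latitude prints before longitude, as absolute values with hemisphere
#' letters (N for latitude >= 0, S below; E for longitude >= 0, W below), to
#' at most 4 decimal places (about 11 m) with trailing zeros trimmed.
#'
#' @param latitude decimal degrees in \[-90, 90\].
#' @param longitude decimal degrees in \[-180, 180\].
#' @return Single string, e.g. `"48.5 N 123.25 W"`.
#' @examples
#' format_lat_lon(0, 0)            # "0 N 0 E"
#' format_lat_lon(-34.03, 117.59)  # "34.03 S 117.59 E"
#' @export
format_lat_lon <- function(latitude, longitude) {
  lat <- parse_raw_number(latitude); lon <- parse_raw_number(longitude)
  if (is.na(lat) || lat < -90 || lat > 90) {
    stop(sprintf("latitude '%s' is not in [-90, 90]", format_raw(latitude)),
         call. = FALSE)
  }
  if (is.na(lon) || lon < -180 || lon > 180) {
    stop(sprintf("longitude '%s' is not in [-180, 180]", format_raw(longitude)),
         call. = FALSE)
  }
  paste(trim_decimal(abs(lat)), if (lat >= 0) "N" else "S",
        trim_decimal(abs(lon)), if (lon >= 0) "E" else "W")
}

trim_decimal <- function(x, digits = 4L) {
  s <- formatC(round(x, digits), format = "f", digits = digits)
  s <- sub("0+$", "", s)
  sub("\\.$", "", s)
}

#' Parse an INSDC lat_lon qualifier back to signed degrees
#' @param text e.g. `"48.5 N 123.25 W"`.
#' @return List with numeric `latitude` and `longitude`.
#' @export
parse_lat_lon <- function(text) {
  m <- regexec("^([0-9]+(\\.[0-9]+)?) ([NS]) ([0-9]+(\\.[0-9]+)?) ([EW])$",
               trimws(text))
  g <- regmatches(trimws(text), m)[[1L]]
  if (length(g) == 0L) {
    stop(sprintf("'%s' is not an INSDC lat_lon value", text), call. = FALSE)
  }
  list(latitude = as.numeric(g[2L]) * (if (g[4L] == "S") -1 else 1),
       longitude = as.numeric(g[5L]) * (if (g[7L] == "W") -1 else 1))
}

#' Format a date as an INSDC collection_date qualifier
#'
#' Renders `DD-Mmm-YYYY` with capitalised English three-letter months
#' (`"05-Oct-2009"`). Time of day, even when recorded, is not emitted.
#'
#' @param timestamp a `Date`, or raw cell text accepted by the record model
#'   (ISO 8601 date or date+time).
#' @return Single string `"DD-Mmm-YYYY"`.
#' @examples
#' format_collection_date("2009-10-05")  # "05-Oct-2009"
#' @export
format_collection_date <- function(timestamp) {
  ts <- parse_raw_timestamp(timestamp)
  if (is.na(ts$date)) {
    stop(sprintf("'%s' is not a valid date; cannot render collection_date",
                 format_raw(timestamp)), call. = FALSE)
  }
  d <- as.POSIXlt(ts$date)
  sprintf("%02d-%s-%04d", d$mday, MONTHS_EN[d$mon + 1L], d$year + 1900L)
}

#' Parse an INSDC collection_date back to a Date
#' @param text e.g. `"05-Oct-2009"`.
#' @return A `Date`.
#' @export
parse_collection_date <- function(text) {
  m <- regexec("^([0-9]{2})-([A-Z][a-z]{2})-([0-9]{4})$", trimws(text))
  g <- regmatches(trimws(text), m)[[1L]]
  if (length(g) == 0L || !g[3L] %in% MONTHS_EN) {
    stop(sprintf("'%s' is not an INSDC collection_date value", text),
         call. = FALSE)
  }
  d <- as.Date(sprintf("%s-%02d-%s", g[4L], match(g[3L], MONTHS_EN), g[2L]),
               format = "%Y-%m-%d")
  if (is.na(d)) {
    stop(sprintf("'%s' is not a real calendar date", text), call. = FALSE)
  }
  d
}
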