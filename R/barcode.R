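# Code 128 set C encoding of the 14-digit numeric identifier form.
# Set C packs two digits per symbol (values 0..99); the check character is
# the weighted sum (start value + sum(position_i * value_i)) mod 103.

CODE128_START_C <- 105L
CODE128_STOP <- 106L

#' Encode a numeric payload as a Code 128 set C barcode symbol
#'
#' Sample identifiers are printed on labels as Code 128 barcodes in set C,
#' which encodes an even-length digit string two digits per symbol. The
#' returned object carries the full symbol value sequence (start, digit-pair
#' data values, check value, stop) — the contract a label printer or image
#' renderer consumes. The check value follows the Code 128 rule: the start
#' value plus each data value weighted by its 1-based position, modulo 103.
#'
#' @param payload even-length digit string, e.g. the 14-digit numeric
#'   identifier form.
#' @return An object of class `barcode_symbol` with fields `payload`,
#'   `data_values` (digit pairs, 0..99), `check_value` (0..102) and
#'   `symbol_values` (start, data, check, stop).
#' @examples
#' sym <- encode_code128c("02000123000045")
#' sym$check_value
#' sym$symbol_values
#' @export
encode_code128c <- function(payload) {
  if (!is.character(payload) || length(payload) != 1L || is.na(payload)) {
    stop("payload must be a single character string", call. = FALSE)
  }
  if (!grepl("^[0-9]+$", payload)) {
    stop(sprintf("cannot encode '%s': payload must contain digits only", payload),
         call. = FALSE)
  }
  n <- nchar(payload)
  if (n %% 2L != 0L) {
    stop(sprintf("cannot encode '%s': Code 128 set C needs an even number of digits (got %d)",
                 payload, n), call. = FALSE)
  }
  pairs <- substring(payload, seq(1L, n, by = 2L), seq(2L, n, by = 2L))
  data_values <- as.integer(pairs)
  check_value <- (CODE128_START_C +
                    sum(seq_along(data_values) * data_values)) %% 103L
  structure(
    list(payload = payload,
         data_values = data_values,
         check_value = as.integer(check_value),
         symbol_values = c(CODE128_START_C, data_values,
                           as.integer(check_value), CODE128_STOP)),
    class = "barcode_symbol"
  )
}

#' @export
print.barcode_symbol <- function(x, ...) {
  cat("<barcode_symbol> payload", x$payload, "\n values:",
      paste(x$symbol_values, collapse = " "), "\n")
  invisible(x)
}

#' Write a plain-text label file for a set of identifiers
#'
#' One label per identifier, blank-line separated: the canonical identifier,
#' optional human-readable annotation lines, and the barcode symbol value
#' sequence. The symbol sequence is the printing contract; rendering to a
#' specific printer language or image is deliberately out of scope.
#'
#' @param identifiers list of `sample_identifier` objects.
#' @param path output file (UTF-8 text); omit to return lines invisibly only.
#' @param annotations optional character vector (one per identifier) of extra
#'   human-readable lines, e.g. a sample or project name.
#' @return Invisibly, the character vector of file lines.
#' @export
write_labels <- function(identifiers, path = NULL, annotations = NULL) {
  if (length(identifiers) == 0L) stop("no identifiers to label", call. = FALSE)
  if (!is.null(annotations) && length(annotations) != length(identifiers)) {
    stop("annotations must match identifiers in length", call. = FALSE)
  }
  blocks <- vapply(seq_along(identifiers), function(i) {
    id <- identifiers[[i]]
    stopifnot(is_sample_identifier(id))
    sym <- encode_code128c(format(id, "numeric"))
    lines <- c(format(id),
               if (!is.null(annotations) && nzchar(annotations[i])) annotations[i],
               paste("code128c:", paste(sym$symbol_values, collapse = " ")))
    paste(lines, collapse = "\n")
  }, character(1))
  out <- paste(blocks, collapse = "\n\n")
  if (!is.null(path)) writeLines(out, path, useBytes = TRUE)
  invisible(strsplit(out, "\n", fixed = TRUE)[[1L]])
}
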