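#' Unique three-part sample identifiers
#'
#' A sample identifier is the triple (institute code, project number, sample
#' number). The institute code is a fixed two-digit value per installation,
#' the project number a six-digit counter incremented per new project, and the
#' sample number a six-digit counter incremented per new sample. The
#' combination of the three parts uniquely identifies a sample; the canonical
#' printed form is `"II-PPPPPP-SSSSSS"` and the numeric (barcode) form the
#' 14-digit string `"IIPPPPPPSSSSSS"`.
#'
#' @param institute_code integer in 0..99.
#' @param project_number integer in 0..999999.
#' @param sample_number integer in 0..999999.
#' @return An object of class `sample_identifier` with fields
#'   `institute_code`, `project_number`, `sample_number`.
#' @examples
#' id <- make_identifier(2, 123, 45)
#' format(id)                 # "02-000123-000045"
#' format(id, "numeric")      # "02000123000045"
#' @seealso [parse_identifier()], [allocate_block()]
#' @export
make_identifier <- function(institute_code, project_number, sample_number) {
  check_component(institute_code, "institute_code", 99L)
  check_component(project_number, "project_number", 999999L)
  check_component(sample_number, "sample_number", 999999L)
  structure(
    list(
      institute_code = as.integer(institute_code),
      project_number = as.integer(project_number),
      sample_number = as.integer(sample_number)
    ),
    class = "sample_identifier"
  )
}

check_component <- function(x, name, max) {
  if (length(x) != 1L || is.na(x) || !is.numeric(x) || x != trunc(x)) {
    stop(sprintf("identifier component '%s' must be a single integer", name),
         call. = FALSE)
  }
  if (x < 0 || x > max) {
    stop(sprintf("identifier component '%s' out of range [0, %d]: %s",
                 name, max, format(x, scientific = FALSE)), call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
format.sample_identifier <- function(x, form = c("canonical", "numeric"), ...) {
  form <- match.arg(form)
  parts <- c(sprintf("%02d", x$institute_code),
             sprintf("%06d", x$project_number),
             sprintf("%06d", x$sample_number))
  if (form == "canonical") paste(parts, collapse = "-") else
    paste(parts, collapse = "")
}

#' @export
print.sample_identifier <- function(x, ...) {
  cat("<sample_identifier>", format(x), "\n")
  invisible(x)
}

#' @export
`==.sample_identifier` <- function(e1, e2) {
  identical(unclass(e1), unclass(e2))
}

#' Parse a sample identifier from text
#'
#' Accepts the canonical hyphenated form (`^[0-9]{2}-[0-9]{6}-[0-9]{6}$`) or
#' the 14-digit numeric form (`^[0-9]{14}$`). Parsing is the exact inverse of
#' [format.sample_identifier()]: `parse_identifier(format(id))` recovers `id`
#' for every valid identifier in either form.
#'
#' @param text a single character string.
#' @return A `sample_identifier`.
#' @examples
#' parse_identifier("02-000123-000045")
#' parse_identifier("00000000000001")
#' @export
parse_identifier <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stop("identifier text must be a single character string", call. = FALSE)
  }
  if (grepl("^[0-9]{2}-[0-9]{6}-[0-9]{6}$", text)) {
    parts <- strsplit(text, "-", fixed = TRUE)[[1L]]
    return(make_identifier(as.integer(parts[1L]), as.integer(parts[2L]),
                           as.integer(parts[3L])))
  }
  if (grepl("^[0-9]{14}$", text)) {
    return(make_identifier(as.integer(substr(text, 1L, 2L)),
                           as.integer(substr(text, 3L, 8L)),
                           as.integer(substr(text, 9L, 14L))))
  }
  # diagnose the first offending position for the error message
  bad <- regexpr("[^0-9-]", text)
  if (bad > 0L) {
    stop(sprintf("cannot parse identifier '%s': invalid character at position %d",
                 text, bad), call. = FALSE)
  }
  if (nchar(text) != 14L && nchar(text) != 16L) {
    stop(sprintf(
      "cannot parse identifier '%s': wrong length %d (expected 14 digits or II-PPPPPP-SSSSSS)",
      text, nchar(text)), call. = FALSE)
  }
  hy <- which(strsplit(text, "")[[1L]] == "-")
  stop(sprintf(
    "cannot parse identifier '%s': hyphens at position(s) %s (expected 3 and 10)",
    text, paste(hy, collapse = ", ")), call. = FALSE)
}

#' Is an object a sample identifier?
#' @param x object to test.
#' @return `TRUE` for `sample_identifier` objects.
#' @export
is_sample_identifier <- function(x) inherits(x, "sample_identifier")

#' Allocate a block of consecutive sample numbers
#'
#' Sample numbers are issued from a single monotone counter per installation,
#' so identifiers can be reserved before, during or after a sampling campaign
#' and blocks issued from one counter never overlap. The function is pure: it
#' takes the current counter state and returns the block plus the advanced
#' state; persisting the state before handing identifiers out is the caller's
#' job (the repository does this, see [repo_allocate()]).
#'
#' @param project_number project the block belongs to.
#' @param count number of consecutive sample numbers to reserve (>= 1).
#' @param counter_state next unissued sample number (0-based).
#' @return A list of class `identifier_block` with `project_number`,
#'   `first_sample_number`, `count`, and `counter_state` (the new state).
#' @examples
#' b <- allocate_block(7, 5, counter_state = 0)
#' block_sample_numbers(b)  # 0 1 2 3 4
#' b$counter_state          # 5
#' @export
allocate_block <- function(project_number, count, counter_state) {
  check_component(project_number, "project_number", 999999L)
  if (length(count) != 1L || is.na(count) || count != trunc(count) || count < 1) {
    stop("count must be a positive integer", call. = FALSE)
  }
  if (length(counter_state) != 1L || is.na(counter_state) ||
      counter_state != trunc(counter_state) || counter_state < 0) {
    stop("counter_state must be a non-negative integer", call. = FALSE)
  }
  if (counter_state + count > 1e6) {
    stop(sprintf(
      "sample counter capacity exceeded: %d + %d > 1000000 six-digit numbers",
      as.integer(counter_state), as.integer(count)), call. = FALSE)
  }
  structure(
    list(project_number = as.integer(project_number),
         first_sample_number = as.integer(counter_state),
         count = as.integer(count),
         counter_state = as.integer(counter_state + count)),
    class = "identifier_block"
  )
}

#' Sample numbers contained in an allocation block
#' @param block an `identifier_block` from [allocate_block()].
#' @return Integer vector of `count` consecutive sample numbers.
#' @export
block_sample_numbers <- function(block) {
  stopifnot(inherits(block, "identifier_block"))
  seq.int(block$first_sample_number, length.out = block$count)
}

#' Expand an allocation block into sample identifiers
#' @param block an `identifier_block`.
#' @param institute_code the installation's two-digit institute code.
#' @return List of `sample_identifier` objects.
#' @export
block_identifiers <- function(block, institute_code) {
  lapply(block_sample_numbers(block), function(s) {
    make_identifier(institute_code, block$project_number, s)
  })
}
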