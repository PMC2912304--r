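#' Generate a synthetic filled acquisition workbook
#'
#' Produces the workbook a sampling campaign would return: identifiers
#' allocated from a fresh counter, plausible random core values (latitude and
#' longitude uniform over their full ranges at 4 decimal places, vertical
#' positions spanning shallow altitude to deep water, collection dates in a
#' fixed past window so clean fixtures never trip the future-date warning),
#' and package fields drawn within their declared ranges or vocabularies.
#' Mandatory package fields are always filled; optional ones with
#' probability 0.8.
#'
#' With probability `error_rate` a corruptible cell is replaced by a value
#' that violates exactly one validation rule, and the corruption is logged as
#' (row, field, kind) with `field` named the way the validation report names
#' it (package fields qualified as `"package:field"`). Corruption kinds:
#' `out_of_range` (latitude, longitude, ranged numeric fields), `bad_date`
#' (collection timestamp), `not_a_number` (vertical position),
#' `vocabulary_miss` (vocabulary fields). The injection log is the ground
#' truth the validation report can be checked against: each log entry must
#' surface as exactly one ERROR at its (row, field).
#'
#' Generation is reproducible: the same seed yields a byte-identical workbook
#' and log. The caller's random-number state is left untouched.
#'
#' @param n_samples number of records (>= 1).
#' @param packages registered package names to attach.
#' @param error_rate per-cell corruption probability in \[0, 1\].
#' @param seed integer seed.
#' @param institute_code installation code for the generated identifiers.
#' @param project_number project the samples belong to.
#' @param registry the package registry.
#' @return List with `workbook` (an `acquisition_workbook`), `log`
#'   (data.frame: row, field, kind) and `identifiers`.
#' @examples
#' fx <- generate_campaign_fixture(5, packages = "water", error_rate = 0,
#'                                 seed = 1)
#' parse_workbook(fx$workbook)$report$acceptable
#' @export
generate_campaign_fixture <- function(n_samples, packages = character(0),
                                      error_rate = 0, seed = 1,
                                      institute_code = 2, project_number = 1,
                                      registry = default_registry()) {
  if (n_samples < 1) stop("n_samples must be >= 1", call. = FALSE)
  if (error_rate < 0 || error_rate > 1) {
    stop("error_rate must be in [0, 1]", call. = FALSE)
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  ids <- block_identifiers(allocate_block(project_number, n_samples, 0),
                           institute_code)
  wb <- build_template(ids, packages, registry)
  df <- wb$primary
  cols <- names(df)
  pkg_defs <- lapply(packages, get_package, registry = registry)
  names(pkg_defs) <- packages

  date_window <- as.Date(c("2009-06-01", "2010-06-01"))
  collectors <- c("pm1", "pm2", "pa")
  log_row <- integer(0); log_field <- character(0); log_kind <- character(0)
  note <- function(i, field, kind) {
    log_row <<- c(log_row, i); log_field <<- c(log_field, field)
    log_kind <<- c(log_kind, kind)
  }
  corrupt <- function() error_rate > 0 && stats::runif(1) < error_rate

  for (i in seq_len(n_samples)) {
    df[i, "latitude"] <- trim_decimal(stats::runif(1, -90, 90))
    df[i, "longitude"] <- trim_decimal(stats::runif(1, -180, 180))
    df[i, "vertical_position"] <- trim_decimal(stats::runif(1, -100, 2000), 1L)
    df[i, "collection_timestamp"] <- format(
      date_window[1L] + sample.int(as.integer(diff(date_window)), 1L))
    df[i, "sample_name"] <- sprintf("sample-%04d", i)
    df[i, "collector"] <- sample(collectors, 1L)
    df[i, "seqID"] <- sprintf("seq-%02d-%06d-%06d", ids[[i]]$institute_code,
                              ids[[i]]$project_number, ids[[i]]$sample_number)

    if (corrupt()) {
      df[i, "latitude"] <- trim_decimal(stats::runif(1, 90.5, 120))
      note(i, "latitude", "out_of_range")
    }
    if (corrupt()) {
      df[i, "longitude"] <- trim_decimal(stats::runif(1, -360, -180.5))
      note(i, "longitude", "out_of_range")
    }
    if (corrupt()) {
      df[i, "vertical_position"] <- "about ten meters"
      note(i, "vertical_position", "not_a_number")
    }
    if (corrupt()) {
      df[i, "collection_timestamp"] <- sample(c("2010-02-30", "31/12/2009",
                                                "yesterday"), 1L)
      note(i, "collection_timestamp", "bad_date")
    }

    for (p in packages) {
      for (fld in names(pkg_defs[[p]]$fields)) {
        fdef <- pkg_defs[[p]]$fields[[fld]]
        col <- if (paste0(p, ":", fld) %in% cols) paste0(p, ":", fld) else fld
        key <- paste0(p, ":", fld)
        if (fdef$requirement != "mandatory" && stats::runif(1) > 0.8) next
        df[i, col] <- clean_field_value(fdef, date_window)
        if (!is.null(fdef$numeric_range) && corrupt()) {
          hi <- fdef$numeric_range[2L]
          df[i, col] <- trim_decimal(hi + 1 + stats::runif(1, 0, 10), 2L)
          note(i, key, "out_of_range")
        } else if (fdef$value_type == "vocabulary" && corrupt()) {
          df[i, col] <- "not-a-registered-term"
          note(i, key, "vocabulary_miss")
        }
      }
    }
  }
  wb$primary <- df
  list(workbook = wb,
       log = data.frame(row = log_row, field = log_field, kind = log_kind,
                        stringsAsFactors = FALSE),
       identifiers = ids)
}

clean_field_value <- function(fdef, date_window) {
  switch(fdef$value_type,
    decimal = {
      lo <- fdef$numeric_range[1L] %||% 0
      hi <- fdef$numeric_range[2L] %||% 100
      trim_decimal(stats::runif(1, lo, min(hi, lo + 1000)), 2L)
    },
    integer = {
      lo <- fdef$numeric_range[1L] %||% 0
      hi <- fdef$numeric_range[2L] %||% 100
      format_raw(lo + sample.int(as.integer(min(hi - lo, 1000)), 1L) - 1L)
    },
    vocabulary = sample(fdef$vocabulary, 1L),
    timestamp = format(date_window[1L] +
                         sample.int(as.integer(diff(date_window)), 1L)),
    text = paste0("obs-", paste(sample(letters, 6L, replace = TRUE),
                                collapse = ""))
  )
}

#' Write a fixture injection log as JSON lines
#' @param log data.frame from [generate_campaign_fixture()].
#' @param path output file; one JSON object (row, field, kind) per line.
#' @return `path`, invisibly.
#' @export
write_injection_log <- function(log, path) {
  lines <- vapply(seq_len(nrow(log)), function(i) {
    jsonlite::toJSON(as.list(log[i, , drop = FALSE]), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
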