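# Shared export plumbing: eligibility gating and the deterministic field
# order every exporter uses (core fields in canonical order, then attached
# packages in attachment order with fields in registry order, then extras).

check_export_eligible <- function(records) {
  bad <- Filter(Negate(is_export_eligible), records)
  if (length(bad)) {
    stop(sprintf(
      "record(s) not export-eligible (incomplete or out-of-range x,y,z,t tuple): %s; nothing written",
      paste(vapply(bad, function(r) format(r$identifier), character(1)),
            collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

# non-empty (name, value) pairs for one record, in export order; package
# fields are bare unless the name is shared across the record's packages
export_fields <- function(record, registry = default_registry(),
                          include_core = TRUE) {
  nm <- character(0); val <- character(0)
  if (include_core) {
    for (f in CORE_FIELDS) {
      v <- format_raw(record$core[[f]])
      if (nzchar(v)) { nm <- c(nm, f); val <- c(val, v) }
    }
  }
  pkg_fields <- lapply(record$attached_packages, function(p) {
    names(get_package(p, registry)$fields)
  })
  dup <- unique(unlist(pkg_fields)[duplicated(unlist(pkg_fields))])
  for (i in seq_along(record$attached_packages)) {
    p <- record$attached_packages[i]
    for (f in pkg_fields[[i]]) {
      v <- format_raw(record$field_values[[paste0(p, ":", f)]])
      if (nzchar(v)) {
        nm <- c(nm, if (f %in% dup) paste0(p, ":", f) else f)
        val <- c(val, v)
      }
    }
  }
  for (f in names(record$extras)) {
    v <- format_raw(record$extras[[f]])
    if (nzchar(v)) { nm <- c(nm, f); val <- c(val, v) }
  }
  stats::setNames(val, nm)
}

#' Export sampling sites as a KML document
#'
#' One Placemark per record: the canonical identifier as the name, a Point at
#' (longitude, latitude) with altitude = minus the vertical position (KML
#' altitudes are above sea level, the record's vertical axis is depth-
#' positive), and every non-empty field as an ExtendedData Data element. The
#' output carries no timestamps or other run-dependent content, so exporting
#' the same records twice is byte-identical.
#'
#' @param records list of export-eligible `contextual_record`s.
#' @param path optional output file.
#' @param registry the package registry.
#' @return An `xml_document` (KML 2.2), invisibly when `path` is given.
#' @export
export_kml <- function(records, path = NULL, registry = default_registry()) {
  check_export_eligible(records)
  doc <- xml2::read_xml('<kml xmlns="http://www.opengis.net/kml/2.2"/>')
  root <- xml2::xml_add_child(doc, "Document")
  xml2::xml_add_child(root, "name", "sampling sites")
  for (r in records) {
    pm <- xml2::xml_add_child(root, "Placemark")
    xml2::xml_add_child(pm, "name", format(r$identifier))
    fields <- export_fields(r, registry)
    ext <- xml2::xml_add_child(pm, "ExtendedData")
    for (f in names(fields)) {
      d <- xml2::xml_add_child(ext, "Data", name = f)
      xml2::xml_add_child(d, "value", fields[[f]])
    }
    lon <- parse_raw_number(r$core$longitude)
    lat <- parse_raw_number(r$core$latitude)
    alt <- -parse_raw_number(r$core$vertical_position)
    pt <- xml2::xml_add_child(pm, "Point")
    xml2::xml_add_child(pt, "coordinates",
                        paste(format_raw(lon), format_raw(lat),
                              format_raw(alt), sep = ","))
  }
  # re-parse so every node carries the default namespace
  doc <- xml2::read_xml(as.character(doc))
  if (!is.null(path)) {
    xml2::write_xml(doc, path)
    return(invisible(doc))
  }
  doc
}

#' Export records as a GCDML-style XML report
#'
#' A schema-inspired (not schema-validated) report document for data
#' exchange: one `report` element per sample holding the identifier, the
#' core x, y, z, t tuple, the attached packages with their field values
#' (name/units as attributes), and any extras. Element order is stable and
#' the output is deterministic for identical input.
#'
#' @inheritParams export_kml
#' @return An `xml_document`.
#' @export
export_gcdml <- function(records, path = NULL, registry = default_registry()) {
  check_export_eligible(records)
  doc <- xml2::read_xml(
    '<gcdmlReportSet xmlns="http://fieldbar.org/ns/gcdml-style/1.0"/>')
  for (r in records) {
    rep <- xml2::xml_add_child(doc, "report")
    xml2::xml_add_child(rep, "identifier", format(r$identifier))
    core <- xml2::xml_add_child(rep, "coreContext")
    for (f in CORE_FIELDS) {
      v <- format_raw(r$core[[f]])
      if (nzchar(v)) xml2::xml_add_child(core, f, v)
    }
    for (p in r$attached_packages) {
      def <- get_package(p, registry)
      pnode <- xml2::xml_add_child(rep, "package", name = p, kind = def$kind)
      for (f in names(def$fields)) {
        v <- format_raw(r$field_values[[paste0(p, ":", f)]])
        if (!nzchar(v)) next
        fdef <- def$fields[[f]]
        if (nzchar(fdef$units)) {
          xml2::xml_add_child(pnode, "field", v, name = f, units = fdef$units)
        } else {
          xml2::xml_add_child(pnode, "field", v, name = f)
        }
      }
    }
    if (length(r$extras)) {
      xnode <- xml2::xml_add_child(rep, "extras")
      for (f in names(r$extras)) {
        v <- format_raw(r$extras[[f]])
        if (nzchar(v)) xml2::xml_add_child(xnode, "extra", v, name = f)
      }
    }
  }
  doc <- xml2::read_xml(as.character(doc))
  if (!is.null(path)) {
    xml2::write_xml(doc, path)
    return(invisible(doc))
  }
  doc
}

#' Export a MIxS-style submission sheet
#'
#' One row per record. Coordinates are rendered as an INSDC `lat_lon` column
#' and the timestamp as `collection_date`; the signed vertical position
#' splits into a `depth` column (meters, values >= 0) and/or an `altitude`
#' column (meters above sea level, emitted only when some record lies above
#' sea level). Package-field columns are the union of populated fields across
#' records, in registry order; extras follow. The sheet re-parses with
#' [parse_workbook()], which understands the INSDC renderings, so the
#' round trip is lossless to the serialized precision.
#'
#' @inheritParams export_kml
#' @param path optional CSV output path.
#' @return An `acquisition_workbook` holding the sheet.
#' @export
export_mixs_sheet <- function(records, path = NULL,
                              registry = default_registry()) {
  check_export_eligible(records)
  zs <- vapply(records, function(r) parse_raw_number(r$core$vertical_position),
               numeric(1))
  z_cols <- c(if (any(zs >= 0)) "depth", if (any(zs < 0)) "altitude")

  all_pkgs <- unique(unlist(lapply(records, `[[`, "attached_packages")))
  all_pkgs <- intersect(registry_packages(registry), all_pkgs)
  populated <- unique(unlist(lapply(records, function(r) {
    keys <- names(r$field_values)
    keys[!vapply(r$field_values, is_empty_raw, logical(1))]
  })))
  pkg_cols <- template_columns(all_pkgs, registry)
  pkg_cols <- setdiff(pkg_cols, c("identifier", CORE_FIELDS))
  keep <- vapply(pkg_cols, function(cn) {
    key <- if (grepl(":", cn, fixed = TRUE)) cn else {
      hits <- paste0(all_pkgs, ":", cn)
      hits[hits %in% populated][1L] %||% cn
    }
    key %in% populated
  }, logical(1))
  pkg_cols <- pkg_cols[keep]
  extra_cols <- unique(unlist(lapply(records, function(r) names(r$extras))))
  cols <- c("identifier", "sample_name", "collector", "lat_lon",
            "collection_date", z_cols, "seqID", pkg_cols, extra_cols)

  df <- as.data.frame(matrix("", nrow = length(records), ncol = length(cols)),
                      stringsAsFactors = FALSE)
  names(df) <- cols
  for (i in seq_along(records)) {
    r <- records[[i]]
    df[i, "identifier"] <- format(r$identifier)
    df[i, "sample_name"] <- format_raw(r$core$sample_name)
    df[i, "collector"] <- format_raw(r$core$collector)
    df[i, "lat_lon"] <- format_lat_lon(r$core$latitude, r$core$longitude)
    df[i, "collection_date"] <- format_collection_date(r$core$collection_timestamp)
    if (zs[i] >= 0) df[i, "depth"] <- format_raw(zs[i]) else
      df[i, "altitude"] <- format_raw(-zs[i])
    df[i, "seqID"] <- format_raw(r$core$seqID)
    for (cn in pkg_cols) {
      key <- if (grepl(":", cn, fixed = TRUE)) cn else {
        owner <- r$attached_packages[vapply(r$attached_packages, function(p) {
          cn %in% names(get_package(p, registry)$fields)
        }, logical(1))]
        if (length(owner)) paste0(owner[1L], ":", cn) else NA_character_
      }
      if (!is.na(key)) df[i, cn] <- format_raw(r$field_values[[key]])
    }
    for (cn in extra_cols) {
      if (cn %in% names(r$extras)) df[i, cn] <- format_raw(r$extras[[cn]])
    }
  }
  wb <- acquisition_workbook(df, packages = all_pkgs)
  if (!is.null(path)) write_workbook(wb, path)
  wb
}

# report package -> structured-comment prefix; no report package means a
# (single-)genome study, hence MIGS
comment_prefix <- function(record) {
  if ("me" %in% record$attached_packages) return("MIMS")
  if ("miens_c" %in% record$attached_packages) return("MIENS")
  "MIGS"
}

#' Render one record as an INSDC structured comment block
#'
#' GenBank-flat-file style: `##<prefix>-Data-START##`, one `key :: value`
#' line per non-empty field, `##<prefix>-Data-END##`. The prefix follows the
#' record's report package: `me` maps to MIMS, `miens_c` to MIENS, and a
#' record without a report package to MIGS. Coordinates and date are rendered
#' in INSDC syntax.
#'
#' @param record an export-eligible `contextual_record`.
#' @param registry the package registry.
#' @return Character vector of lines.
#' @export
structured_comment <- function(record, registry = default_registry()) {
  check_export_eligible(list(record))
  prefix <- comment_prefix(record)
  fields <- export_fields(record, registry, include_core = FALSE)
  z <- parse_raw_number(record$core$vertical_position)
  core <- c(lat_lon = format_lat_lon(record$core$latitude, record$core$longitude),
            collection_date = format_collection_date(record$core$collection_timestamp),
            if (z >= 0) c(depth = paste0(format_raw(z), " m")) else
              c(altitude = paste0(format_raw(-z), " m")),
            if (!is_empty_raw(record$core$sample_name))
              c(sample_name = format_raw(record$core$sample_name)),
            if (!is_empty_raw(record$core$collector))
              c(collected_by = format_raw(record$core$collector)))
  kv <- c(core, fields)
  c(sprintf("##%s-Data-START##", prefix),
    sprintf("%s :: %s", names(kv), unname(kv)),
    sprintf("##%s-Data-END##", prefix))
}

#' Export a submission bundle pairing contextual data with FASTA sequences
#'
#' Matches records to sequences via the `seqID` field against FASTA headers
#' (first whitespace-delimited token). Writes, without ever altering a
#' sequence: a verbatim copy of the FASTA, a tab-separated source-modifier
#' table (one row per matched sequence: SeqID, lat_lon, collection_date,
#' depth or altitude, collected_by, sample_name, identifier), and one
#' structured-comment file per matched sample. FASTA headers with no
#' matching record, and records without (or with unmatched) seqIDs, are
#' reported as warnings in the result; the same seqID on two records is a
#' fatal ambiguity.
#'
#' @param records list of export-eligible `contextual_record`s.
#' @param fasta path to the FASTA file.
#' @param out_dir optional directory to write `sequences.fasta`,
#'   `source_modifiers.tsv` and `<identifier>.cmt` files into.
#' @param registry the package registry.
#' @return A `submission_bundle`: list with `table` (data.frame),
#'   `comments` (named list of line vectors, by canonical identifier),
#'   `warnings` (character), and when written, `files`.
#' @export
export_submission_bundle <- function(records, fasta, out_dir = NULL,
                                     registry = default_registry()) {
  check_export_eligible(records)
  seqs <- Biostrings::readBStringSet(fasta)
  headers <- vapply(strsplit(names(seqs), "[ \t]"), `[[`, character(1), 1L)

  seq_ids <- vapply(records, function(r) format_raw(r$core$seqID), character(1))
  dup <- unique(seq_ids[nzchar(seq_ids) & duplicated(seq_ids)])
  if (length(dup)) {
    stop(sprintf("seqID(s) %s appear on more than one record; ambiguous mapping",
                 paste(dup, collapse = ", ")), call. = FALSE)
  }
  warnings <- character(0)
  no_id <- vapply(records[!nzchar(seq_ids)], function(r) format(r$identifier),
                  character(1))
  if (length(no_id)) {
    warnings <- c(warnings, sprintf("record(s) without seqID not bundled: %s",
                                    paste(no_id, collapse = ", ")))
  }
  unmatched_rec <- setdiff(seq_ids[nzchar(seq_ids)], headers)
  if (length(unmatched_rec)) {
    warnings <- c(warnings, sprintf("seqID(s) with no FASTA sequence: %s",
                                    paste(unmatched_rec, collapse = ", ")))
  }
  unmatched_fa <- setdiff(headers, seq_ids)
  if (length(unmatched_fa)) {
    warnings <- c(warnings, sprintf("FASTA sequence(s) with no record: %s",
                                    paste(unmatched_fa, collapse = ", ")))
  }

  matched <- which(nzchar(seq_ids) & seq_ids %in% headers)
  tab <- data.frame(SeqID = character(0), lat_lon = character(0),
                    collection_date = character(0), depth = character(0),
                    altitude = character(0), collected_by = character(0),
                    sample_name = character(0), identifier = character(0),
                    stringsAsFactors = FALSE)
  comments <- list()
  for (i in matched) {
    r <- records[[i]]
    z <- parse_raw_number(r$core$vertical_position)
    tab[nrow(tab) + 1L, ] <- c(
      seq_ids[i],
      format_lat_lon(r$core$latitude, r$core$longitude),
      format_collection_date(r$core$collection_timestamp),
      if (z >= 0) format_raw(z) else "",
      if (z < 0) format_raw(-z) else "",
      format_raw(r$core$collector),
      format_raw(r$core$sample_name),
      format(r$identifier))
    comments[[format(r$identifier)]] <- structured_comment(r, registry)
  }
  bundle <- structure(list(table = tab, comments = comments,
                           warnings = warnings),
                      class = "submission_bundle")
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    fasta_out <- file.path(out_dir, "sequences.fasta")
    file.copy(fasta, fasta_out, overwrite = TRUE)  # sequences untouched
    tsv <- file.path(out_dir, "source_modifiers.tsv")
    utils::write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    cmt <- vapply(names(comments), function(id) {
      f <- file.path(out_dir, paste0(id, ".cmt"))
      writeLines(comments[[id]], f, useBytes = TRUE)
      f
    }, character(1))
    bundle$files <- c(fasta = fasta_out, table = tsv, cmt)
  }
  bundle
}

#' @export
print.submission_bundle <- function(x, ...) {
  cat(sprintf("<submission_bundle> %d matched sequence(s), %d warning(s)\n",
              nrow(x$table), length(x$warnings)))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}
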