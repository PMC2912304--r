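eligible_records <- function(n = 3, seed = 21, packages = c("water", "me")) {
  fx <- generate_campaign_fixture(n, packages = packages, error_rate = 0,
                                  seed = seed)
  parse_workbook(fx$workbook)$records
}

test_that("lat_lon renders hemisphere letters with trimmed 4-decimal precision", {
  expect_equal(format_lat_lon(0, 0), "0 N 0 E")
  expect_equal(format_lat_lon(48.5, -123.25), "48.5 N 123.25 W")
  expect_equal(format_lat_lon(-34.03, 117.59), "34.03 S 117.59 E")
  expect_equal(format_lat_lon(10.00001, -0.12345), "10 N 0.1235 W")
  expect_error(format_lat_lon(91, 0), "latitude")
  expect_error(format_lat_lon(0, 200), "longitude")
})

test_that("lat_lon round-trips its own output to within 0.0001 degrees", {
  set.seed(31)
  for (i in seq_len(300)) {
    lat <- stats::runif(1, -90, 90); lon <- stats::runif(1, -180, 180)
    back <- parse_lat_lon(format_lat_lon(lat, lon))
    expect_lt(abs(back$latitude - lat), 1e-4)
    expect_lt(abs(back$longitude - lon), 1e-4)
  }
})

test_that("collection_date renders and parses DD-Mmm-YYYY", {
  expect_equal(format_collection_date("2009-10-05"), "05-Oct-2009")
  expect_equal(format_collection_date("2010-06-30"), "30-Jun-2010")
  expect_equal(format_collection_date("2009-10-05T14:30:00Z"), "05-Oct-2009")
  expect_error(format_collection_date("2010-02-30"), "not a valid date")
  expect_error(format_collection_date(""), "not a valid date")
  expect_equal(parse_collection_date("05-Oct-2009"), as.Date("2009-10-05"))
})

test_that("KML holds one Placemark per record with lon,lat,-depth coordinates", {
  r <- valid_record(lat = 48.5, lon = -123.25, z = 10)
  doc <- export_kml(list(r))
  ns <- c(k = "http://www.opengis.net/kml/2.2")
  pms <- xml2::xml_find_all(doc, "//k:Placemark", ns)
  expect_length(pms, 1)
  expect_equal(xml2::xml_text(xml2::xml_find_first(doc, "//k:coordinates", ns)),
               "-123.25,48.5,-10")
  expect_equal(xml2::xml_text(xml2::xml_find_first(doc, "//k:Placemark/k:name", ns)),
               "02-000001-000001")
  # every non-empty field appears as ExtendedData
  data_names <- xml2::xml_attr(xml2::xml_find_all(doc, "//k:Data", ns), "name")
  expect_true(all(c("latitude", "sample_name", "collector") %in% data_names))

  empty <- export_kml(list())
  expect_length(xml2::xml_find_all(empty, "//k:Placemark", ns), 0)
  expect_equal(xml2::xml_name(xml2::xml_root(empty)), "kml")
})

test_that("KML and GCDML exports are strict-parseable and count one node per record", {
  recs <- eligible_records(10)
  dir <- withr::local_tempdir()
  export_kml(recs, file.path(dir, "sites.kml"))
  kml <- xml2::read_xml(file.path(dir, "sites.kml"))
  expect_length(xml2::xml_find_all(kml, "//*[local-name()='Placemark']"), 10)

  export_gcdml(recs, file.path(dir, "reports.xml"))
  g <- xml2::read_xml(file.path(dir, "reports.xml"))
  expect_length(xml2::xml_find_all(g, "//*[local-name()='report']"), 10)
})

test_that("ineligible records abort exports with nothing written", {
  bad <- valid_record(); bad$core$collection_timestamp <- ""
  path <- file.path(withr::local_tempdir(), "x.kml")
  expect_error(export_kml(list(valid_record(2), bad), path), "not export-eligible")
  expect_false(file.exists(path))
})

test_that("XML-special characters are escaped and exports are deterministic", {
  r <- valid_record()
  r$core$sample_name <- 'A<B & "C"'
  dir <- withr::local_tempdir()
  export_gcdml(list(r), file.path(dir, "a.xml"))
  export_gcdml(list(r), file.path(dir, "b.xml"))
  expect_identical(readBin(file.path(dir, "a.xml"), "raw", 1e6),
                   readBin(file.path(dir, "b.xml"), "raw", 1e6))
  reread <- xml2::read_xml(file.path(dir, "a.xml"))
  expect_equal(xml2::xml_text(xml2::xml_find_first(
    reread, "//*[local-name()='sample_name']")), 'A<B & "C"')

  export_kml(list(r), file.path(dir, "a.kml"))
  export_kml(list(r), file.path(dir, "b.kml"))
  expect_identical(readBin(file.path(dir, "a.kml"), "raw", 1e6),
                   readBin(file.path(dir, "b.kml"), "raw", 1e6))
})

test_that("the MIxS sheet uses INSDC syntax, splits the vertical axis, and re-parses", {
  below <- valid_record(1, z = 10)
  above <- valid_record(2, z = -150)  # a mountain soil sample
  wb <- export_mixs_sheet(list(below, above))
  expect_true(all(c("lat_lon", "collection_date", "depth", "altitude")
                  %in% names(wb$primary)))
  expect_equal(wb$primary$depth, c("10", ""))
  expect_equal(wb$primary$altitude, c("", "150"))
  expect_equal(wb$primary$collection_date[1], "05-Oct-2009")

  only_depth <- export_mixs_sheet(list(below))
  expect_false("altitude" %in% names(only_depth$primary))

  empty <- export_mixs_sheet(list())
  expect_equal(nrow(empty$primary), 0)
  expect_true("lat_lon" %in% names(empty$primary))
})

test_that("records survive the MIxS export round trip to serialized precision", {
  recs <- eligible_records(8, seed = 13, packages = c("water", "me"))
  path <- withr::local_tempfile(fileext = ".csv")
  export_mixs_sheet(recs, path)
  back <- parse_workbook(path)
  expect_true(back$report$acceptable)
  expect_length(back$records, length(recs))
  for (i in seq_along(recs)) {
    a <- recs[[i]]; b <- back$records[[i]]
    expect_true(a$identifier == b$identifier)
    expect_lt(abs(as.numeric(a$core$latitude) - as.numeric(b$core$latitude)),
              1e-4)
    expect_equal(as.numeric(a$core$vertical_position),
                 as.numeric(b$core$vertical_position))
    expect_equal(a$core$sample_name, b$core$sample_name)
    expect_equal(a$core$seqID, b$core$seqID)
    expect_identical(a$field_values, b$field_values)
  }
})

test_that("structured comments are delimiter-exact with the mapped prefix", {
  r <- attach_package(valid_record(seqID = "seqA"), "me")
  r <- set_field(r, "project_name", "EXAMPLE")
  lines <- structured_comment(r)
  expect_equal(lines[1], "##MIMS-Data-START##")
  expect_equal(lines[length(lines)], "##MIMS-Data-END##")
  body <- lines[c(-1, -length(lines))]
  expect_true(all(grepl("^[^ ]+ :: .+$", body)))
  expect_true("lat_lon :: 54.1777 N 7.8921 E" %in% body)
  expect_true("collection_date :: 05-Oct-2009" %in% body)
  expect_true("project_name :: EXAMPLE" %in% body)

  expect_equal(structured_comment(
    attach_package(valid_record(), "miens_c"))[1], "##MIENS-Data-START##")
  expect_equal(structured_comment(valid_record())[1], "##MIGS-Data-START##")
})

test_that("submission bundles join records to FASTA by seqID and never alter sequences", {
  recs <- list(attach_package(valid_record(1, seqID = "A"), "me"),
               valid_record(2, seqID = "B"),
               valid_record(3, seqID = "Z"),   # no sequence
               valid_record(4))                # no seqID
  dir <- withr::local_tempdir()
  fasta <- file.path(dir, "seqs.fasta")
  writeLines(c(">A first isolate", "ACGTACGTAA", ">B", "GGGCCCTTTA",
               ">C orphan", "ATATATATAT"), fasta)
  b <- export_submission_bundle(recs, fasta, out_dir = file.path(dir, "out"))
  expect_equal(b$table$SeqID, c("A", "B"))
  expect_equal(nrow(b$table), 2)
  expect_length(b$warnings, 3)
  expect_match(paste(b$warnings, collapse = "; "), "C")
  expect_match(paste(b$warnings, collapse = "; "), "Z")
  expect_match(paste(b$warnings, collapse = "; "), "02-000001-000004")
  # FASTA copied verbatim
  expect_identical(readBin(fasta, "raw", 1e6),
                   readBin(file.path(dir, "out", "sequences.fasta"), "raw", 1e6))
  # comment files per matched sample, prefix from the report package
  cmt <- readLines(file.path(dir, "out", "02-000001-000001.cmt"))
  expect_equal(cmt[1], "##MIMS-Data-START##")
  tsv <- utils::read.delim(file.path(dir, "out", "source_modifiers.tsv"),
                           colClasses = "character")
  expect_equal(tsv$SeqID, c("A", "B"))

  dup <- list(valid_record(1, seqID = "A"), valid_record(2, seqID = "A"))
  expect_error(export_submission_bundle(dup, fasta), "more than one record")
})
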