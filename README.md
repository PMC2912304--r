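# fieldbar

Barcoded sample identifiers and standards-compliant contextual data for
environmental sequencing campaigns.

Sequence data without context — where, when, how deep, from what environment
— cannot be placed on a map, compared across studies or meaningfully
re-used. fieldbar is for field scientists and data managers who need the
minimal georeferencing tuple *x, y, z, t* (latitude, longitude, vertical
position relative to sea level, sampling time) and richer Genomic Standards
Consortium (GSC / MIxS-style) parameters to stay attached to every sample
from the sampling event to INSDC sequence submission. It covers the whole
workflow:

1. **Identifiers** — unique three-part identifiers `II-PPPPPP-SSSSSS`
   (2-digit institute code, 6-digit project number, 6-digit sample number
   from a monotone per-installation counter), allocated in blocks before,
   during or after a campaign, and encoded as Code 128 set C barcode symbol
   sequences with the standard check character
   `c = (105 + Σᵢ i·vᵢ) mod 103`.
2. **Acquisition spreadsheets** — templates with pre-filled identifiers and
   the fields of chosen GSC packages; filled sheets are parsed (extra
   user-added worksheets preserved byte-identically) and validated
   parser-side: coordinate ranges, declared numeric ranges, controlled
   vocabularies, calendar dates; problems come back as an ordered
   (severity, field, row) report, never as crashes.
3. **A multi-user repository** — a single-file JSON store with one site
   admin, project admins and users; per-sample ownership, read/write
   grants, atomic ownership transfer, and identifier/text queries filtered
   by read permission (a barcode scan is just an identifier query).
4. **Four exports** — KML 2.2 for sampling-site visualization, GCDML-style
   XML for data exchange, a MIxS-style sheet with INSDC `lat_lon`
   (`"48.5 N 123.25 W"`) and `collection_date` (`"05-Oct-2009"`) syntax,
   and a submission bundle pairing unmodified FASTA sequences with a
   source-modifier table and GenBank-style structured comments
   (`##MIMS-Data-START##` … `##MIMS-Data-END##`), joined on the record's
   `seqID` against FASTA headers.

## Worked example

```r
library(fieldbar)

# reserve three identifiers for project 1 at institute 02
b   <- allocate_block(project_number = 1, count = 3, counter_state = 0)
ids <- block_identifiers(b, institute_code = 2)
for (id in ids) cat(format(id), "\n")
#> 02-000001-000000
#> 02-000001-000001
#> 02-000001-000002

# the barcode a label printer would receive (start, 7 digit pairs, check, stop)
encode_code128c(format(ids[[1]], "numeric"))
#> <barcode_symbol> payload 02000001000000
#>  values: 105 2 0 0 1 0 0 0 8 106

# an acquisition template with the "water" package attached
build_template(ids, packages = "water")
#> <acquisition_workbook> 'contextual_data': 3 row(s) x 18 column(s); packages: water

# a deliberately messy synthetic campaign, then parse + validate
fx  <- generate_campaign_fixture(3, packages = "water", error_rate = 0.4, seed = 42)
res <- parse_workbook(fx$workbook)
res$report
#> <validation_report> NOT acceptable: 15 error(s), 0 warning(s)
#>  severity                  field row
#>     ERROR      vertical_position   1
#>     ERROR         water:salinity   1
#>     ...
#>                        50.62 outside declared range [0, 45] for field 'water:salinity' (psu)
```

Every ERROR names the offending field and row — `50.62` exceeds the
declared 0–45 psu salinity range, row 3's `2010-02-30` is not a real date —
so the sheet can be fixed in place and re-uploaded; merging overwrites only
non-empty incoming cells. Once a record is clean, the INSDC renderings are
one call away:

```r
r <- res$records[[1]]
format_lat_lon(r$core$latitude, r$core$longitude)
#> [1] "74.6651 N 157.3471 E"
format_collection_date(r$core$collection_timestamp)
#> [1] "01-Nov-2009"
```

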