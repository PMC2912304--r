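---
title: "Consistent contextual data for barcoded field samples"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consistent contextual data for barcoded field samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(fieldbar)
```

## The problem fieldbar addresses

Most sequence records in the public INSDC databases carry little or no
information about where, when and from what environment the underlying sample
was taken. Once a sample leaves the field, its context — latitude, longitude,
vertical position relative to sea level and the sampling time, the *x, y, z,
t* tuple — is easily lost in notebooks and ad-hoc spreadsheets, and it rarely
survives the journey to sequence submission. fieldbar keeps that link intact
by giving every sample a unique, barcode-printable identifier *before* the
campaign, a validated acquisition spreadsheet *during* it, and
standards-compliant exports *after* it.

## The identifier model

An identifier is the triple (institute code, project number, sample number)
with fixed digit widths 2, 6 and 6. The institute code is constant per
installation; project numbers increment with every new project; sample
numbers are issued from a single monotone counter per installation. Either
counter can in principle be scoped differently — we chose a global sample
counter because uniqueness is already guaranteed by the triple, and a global
counter makes disjointness of pre-allocated blocks trivial to reason about
and to test. The canonical printed form is `II-PPPPPP-SSSSSS`; the numeric
form concatenates the 14 digits and is what the barcode carries.

Blocks of consecutive sample numbers can be reserved before, during or after
a campaign ([allocate_block()] is a pure function of the counter state; the
repository persists the advanced counter *before* identifiers are handed
out, so a crash cannot reissue numbers).

### Barcodes

Identifiers are encoded as Code 128 set C, the symbology of choice for
even-length all-numeric payloads because it packs two digits per symbol. The
encoder emits the full symbol value sequence — start (105), seven digit-pair
values, the check character and stop (106) — and the check character follows
the standard weighted-sum rule

$$c = \left(105 + \sum_{i=1}^{7} i \cdot v_i\right) \bmod 103 .$$

The symbol value sequence, not a rendered image, is the printing contract;
any label printer driver or image renderer can be layered on top. Tests
verify the check character against an independently coded brute-force sum.

## The data model and validation

A contextual record holds the identifier, the core context (the x, y, z, t
tuple plus sample name, collector and the `seqID` link to sequence data),
values for fields of attached GSC-style packages, and free-form extras.
Choices worth noting:

* **One signed vertical axis.** Depth and altitude are one field (meters,
  positive = depth below sea level). Splitting into separate `depth` /
  `altitude` columns happens only at export, which avoids records that claim
  both.
* **Timestamps.** ISO 8601 date or date+time; naive times are treated as
  UTC since ships cross time zones mid-campaign. A *future* date is a
  warning, not an error — vessel clocks drift and a wrong-but-plausible date
  should not block an upload the scientist can still correct.
* **Validation is parser-side.** The original acquisition workflow this
  package re-implements validated inside the spreadsheet application via
  macros; we validate in the library instead, so the rules are identical for
  every input dialect and are directly testable. Everything is *reported*
  (severity, field, row), never raised: a report with zero ERRORs is
  `acceptable`. Empty mandatory package fields and future dates are
  warnings; range, vocabulary, type and coordinate violations are errors.

### The package registry

Environmental packages (air, host-associated, human-associated, sediment,
soil, wastewater_sludge, water) and report packages (`miens_c` for cultured
isolates, `me` for metagenomes — these also choose the MIENS/MIMS structured
comment prefix, with MIGS as the default) are declared in a versioned JSON
file shipped under `inst/extdata/`, so field sets can be amended without
code changes. The air package carries the full 23-field community list
(barometric pressure through wind speed); the field membership of the other
packages is a plausible MIxS-style approximation with permissive types —
they are registry *content*, not code, and explicitly amendable. No ontology
(EnvO) validation is attempted.

## Spreadsheets

The acquisition workbook is CSV-based: a single CSV file for a bare primary
sheet, or a "workbook directory" (a `manifest.json` plus one file per sheet)
when user-added extra sheets ride along. Extra sheets are opaque bytes and
round-trip byte-identically through parsing, storage and retrieval — they
are the users' own notes and must never be touched. The CSV dialect is
RFC 4180 with every cell quoted, which makes writes deterministic and
diff-able.

Parsing is forgiving about content (any cell value is accepted and judged by
validation) but strict about structure: a missing identifier column, an
empty or malformed identifier on a filled row, or a duplicated identifier is
a coded structural error. Fully blank rows are skipped — half-filled
templates are the normal state of a campaign in progress. Columns that
resolve to no known field land in per-record `extras` and are never dropped.
Re-uploading merges: non-empty incoming values overwrite, empty cells leave
stored values alone (the alternative — empty meaning *delete* — destroys data
whenever a user uploads a partially filled sheet, which is the common case).

## Exports

Four artifacts, all deterministic (no embedded timestamps) so repeated
exports are byte-identical:

1. **KML 2.2** — one Placemark per record, `lon,lat,alt` with
   `alt = −vertical_position`, all non-empty fields as ExtendedData.
2. **GCDML-style XML** — schema-*inspired* report elements; the exact XSD
   version the original tool targeted is not recoverable, so no schema
   validation is claimed.
3. **MIxS-style sheet** — INSDC renderings (`lat_lon`, `collection_date`),
   vertical axis split into depth/altitude, package columns in registry
   order. The parser understands these renderings, so export → re-parse is
   lossless to the serialized precision.
4. **Submission bundle** — a verbatim copy of the FASTA (sequences are never
   altered), a tab-separated source-modifier table keyed by `SeqID`, and one
   structured comment per matched sample, using the GenBank flat-file
   delimiter grammar `##PREFIX-Data-START##` / `##PREFIX-Data-END##` with
   `key :: value` lines.

`lat_lon` prints at most 4 decimal places (≈ 11 m, below typical shipboard
GPS accuracy) with trailing zeros trimmed; `collection_date` prints
`DD-Mmm-YYYY` with English month names regardless of locale, and time of day
is deliberately not emitted. Records lacking any part of the x, y, z, t
tuple are not export-eligible; exporters refuse the whole set and name the
offenders rather than writing a partial artifact.

## The repository and the permission model

Samples are stored with an owner and a project in an immutable-value
repository persisted as a single JSON file (typed core fields, key-value
package fields, base64 extra-sheet blobs), loadable with [repo_load()] as a
complete backup. The decision procedure of [authorize()]:

| action | allowed for |
|--------|-------------|
| delete | site admin only |
| write  | owner, write-grantee, site admin |
| read   | all of the above, read-grantee, project admin of the sample's project |

There is exactly one site admin per installation, and no operation sequence
can create a second. Project admins get implicit *read* (not write) on their
project's samples — a deliberate choice so a project's consolidated data can
be reviewed for errors before submission without letting admins edit other
people's measurements. Ownership transfers are all-or-none across the given
set. Removing a member revokes their grants in that project but never their
ownership: owners must be transferred out first, which keeps the
owner-is-a-member invariant.

Authentication is out of scope; callers are pre-authenticated principals,
and the CLI's `--as-user` impersonation exists for scripting and testing the
permission model (it is logged prominently).

## The synthetic campaign generator

`generate_campaign_fixture()` emulates a filled field spreadsheet: latitude
and longitude uniform over their full ranges at 4 decimal places, vertical
positions from −100 m (land/altitude) to 2000 m depth, collection dates
uniform in a fixed past window (June 2009 – June 2010) so clean fixtures can
never trip the future-date warning, package fields drawn inside their
declared ranges and vocabularies, mandatory fields always filled and
optional ones with probability 0.8. With a given `error_rate`, each
corruptible cell is independently replaced by a value violating exactly one
rule, and logged as (row, field, kind) — the ground truth that validation
recall is measured against.

What it does **not** emulate: spatially clustered stations, correlated
environmental parameters, missing-not-at-random cells, multi-error cells,
or free-text typos in numeric columns beyond the injected kinds. Passing the
recall checks therefore shows the validator finds every violation *of the
kinds the rules define*, at the declared positions — not that it understands
messier real-world sheets.

## Problem sizes and numerical choices

The shipped checks run at sizes a laptop handles in seconds: 1,000 random
identifiers and barcode payloads for the round-trip and check-character
properties, 200-record campaigns for the spreadsheet round trip, five
100-record corrupted fixtures (10 % cell error rate) for validation recall,
and the full 8-principal × 3-action permission table. Coordinate round-trip
agreement is asserted at the serialized precision (10⁻⁴ degrees); text
fields are compared exactly. Numeric cell text is preserved verbatim through
parse/export cycles, so no floating-point drift enters the round trip.

## Known limitations

* The non-air package field sets approximate community checklists rather
  than reproducing any specific MIxS version.
* The workbook container is CSV-based; native spreadsheet files from office
  suites should be exported to CSV (the validation contract is parser-side,
  so nothing is lost but in-cell dropdown hints).
* The repository targets single-process use; there is no locking for
  concurrent writers.
* GCDML output is schema-inspired and not validated against an XSD.
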