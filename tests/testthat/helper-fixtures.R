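# Shared test helpers: an independent Code 128 check-value oracle, a
# ready-made valid record, and a small populated repository scenario
# mirroring a two-member sampling campaign.

# brute-force weighted sum, written independently of encode_code128c()
oracle_check_value <- function(payload) {
  total <- 105  # start value for set C
  pos <- 0
  for (i in seq(1, nchar(payload), by = 2)) {
    pos <- pos + 1
    total <- total + pos * as.integer(substr(payload, i, i + 1))
  }
  total %% 103
}

valid_record <- function(sample_number = 1, seqID = "",
                         lat = 54.1777, lon = 7.8921, z = 10,
                         ts = "2009-10-05") {
  contextual_record(make_identifier(2, 1, sample_number),
                    latitude = lat, longitude = lon, vertical_position = z,
                    collection_timestamp = ts,
                    sample_name = sprintf("helgoland-%d", sample_number),
                    collector = "pm1", seqID = seqID)
}

# repo with site admin "root", project admin "pa", members "pm1"/"pm2" in
# project EXAMPLE, outsider "out", and n samples stored by pm1
example_repo <- function(n_samples = 2) {
  repo <- repo_create(2, admin = "root")
  repo <- repo_add_user(repo, "root", "pa", role = "project_admin")
  repo <- repo_add_user(repo, "root", "pm1")
  repo <- repo_add_user(repo, "root", "pm2")
  repo <- repo_add_user(repo, "root", "out")
  repo <- manage_project(repo, "pa", "create", "EXAMPLE")
  repo <- manage_project(repo, "pa", "add_member", "EXAMPLE", "pm1")
  repo <- manage_project(repo, "pa", "add_member", "EXAMPLE", "pm2")
  for (i in seq_len(n_samples)) {
    repo <- repo_store(repo, "pm1", valid_record(i), "EXAMPLE")
  }
  repo
}

expect_error_code <- function(expr, code) {
  err <- tryCatch(expr, fieldbar_structural_error = function(e) e)
  expect_s3_class(err, "fieldbar_structural_error")
  expect_identical(err$code, code)
}
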