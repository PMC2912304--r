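test_that("the case-study campaign works end to end", {
  repo <- example_repo(0)
  expect_setequal(repo$projects$EXAMPLE$members, c("pa", "pm1", "pm2"))

  # two members allocate five identifiers each from the shared counter
  a1 <- repo_allocate(repo, "EXAMPLE", 5); repo <- a1$repo
  a2 <- repo_allocate(repo, "EXAMPLE", 5); repo <- a2$repo
  nums <- c(vapply(a1$identifiers, function(i) i$sample_number, integer(1)),
            vapply(a2$identifiers, function(i) i$sample_number, integer(1)))
  expect_equal(nums, 0:9)

  for (i in 1:5) repo <- repo_store(repo, "pm1", valid_record(i), "EXAMPLE")
  # the project admin reviews everyone's consolidated data
  expect_length(repo_query(repo, "pa", text = "helgoland"), 5)
  # transfer the five push cores to pm2
  repo <- transfer_ownership(repo, "pa",
                             lapply(1:5, function(i) make_identifier(2, 1, i)),
                             "pm2")
  expect_true(all(vapply(repo$samples, `[[`, character(1), "owner") == "pm2"))
  # old owner kept no implicit access
  expect_false(authorize(repo, "pm1", "read", make_identifier(2, 1, 1)))
})

test_that("project management enforces roles and ownership conflicts", {
  repo <- example_repo(1)  # pm1 owns sample 1
  expect_s3_class(tryCatch(manage_project(repo, "pm1", "create", "ROGUE"),
                           condition = identity),
                  "fieldbar_authorization_error")
  expect_error(manage_project(repo, "pa", "remove_member", "EXAMPLE", "pm1"),
               "transfer ownership first")
  # after transfer, removal succeeds and revokes grants
  repo <- grant_permission(repo, "pm1", valid_record(1), "pm2", "read")
  repo <- transfer_ownership(repo, "pa", list(make_identifier(2, 1, 1)), "pm2")
  repo <- grant_permission(repo, "pm2", valid_record(1), "pm1", "read")
  repo <- manage_project(repo, "pa", "remove_member", "EXAMPLE", "pm1")
  expect_false("pm1" %in% repo$projects$EXAMPLE$members)
  expect_false(authorize(repo, "pm1", "read", make_identifier(2, 1, 1)))
})

test_that("grants give, limit and withdraw access; only owners share", {
  repo <- example_repo(1)
  id <- make_identifier(2, 1, 1)
  repo <- grant_permission(repo, "pm1", id, "pm2", "read")
  expect_true(authorize(repo, "pm2", "read", id))
  expect_false(authorize(repo, "pm2", "write", id))
  repo <- grant_permission(repo, "pm1", id, "pm2", "write")
  expect_true(authorize(repo, "pm2", "write", id))
  repo <- grant_permission(repo, "pm1", id, "pm2", "none")
  expect_false(authorize(repo, "pm2", "read", id))

  expect_s3_class(tryCatch(grant_permission(repo, "pm2", id, "pa", "read"),
                           condition = identity),
                  "fieldbar_authorization_error")
  expect_error(grant_permission(repo, "pm1", id, "out", "read"),
               "not a member")
})

test_that("ownership transfer is all-or-none", {
  repo <- example_repo(2)
  # a sample in a project pa does not administer
  repo <- repo_add_user(repo, "root", "pa2", role = "project_admin")
  repo <- manage_project(repo, "pa2", "create", "OTHER")
  repo <- manage_project(repo, "pa2", "add_member", "OTHER", "pm1")
  foreign <- contextual_record(make_identifier(2, 2, 99), latitude = 1,
                               longitude = 1, vertical_position = 0,
                               collection_timestamp = "2009-01-01")
  repo <- repo_store(repo, "pm1", foreign, "OTHER")

  ids <- list(make_identifier(2, 1, 1), make_identifier(2, 2, 99))
  expect_s3_class(tryCatch(transfer_ownership(repo, "pa", ids, "pm2"),
                           condition = identity),
                  "fieldbar_authorization_error")
  # nothing moved
  expect_equal(repo$samples[["02000001000001"]]$owner, "pm1")
  expect_equal(repo$samples[["02000002000099"]]$owner, "pm1")
})

test_that("authorize matches the hand-enumerated role x relationship x action table", {
  # rows: relationship; per role, expected (read, write, delete)
  relationships <- c("owner", "read_grantee", "write_grantee", "member",
                     "admin_of", "outsider")
  expected <- list(
    user = list(owner        = c(TRUE,  TRUE,  FALSE),
                read_grantee  = c(TRUE,  FALSE, FALSE),
                write_grantee = c(TRUE,  TRUE,  FALSE),
                member        = c(FALSE, FALSE, FALSE),
                # a plain user cannot be made project admin; behaves as member
                admin_of      = c(FALSE, FALSE, FALSE),
                outsider      = c(FALSE, FALSE, FALSE)),
    project_admin = list(
                owner         = c(TRUE,  TRUE,  FALSE),
                read_grantee  = c(TRUE,  FALSE, FALSE),
                write_grantee = c(TRUE,  TRUE,  FALSE),
                member        = c(FALSE, FALSE, FALSE),
                admin_of      = c(TRUE,  FALSE, FALSE),
                outsider      = c(FALSE, FALSE, FALSE)),
    site_admin = list(
                owner         = c(TRUE, TRUE, TRUE),
                read_grantee  = c(TRUE, TRUE, TRUE),
                write_grantee = c(TRUE, TRUE, TRUE),
                member        = c(TRUE, TRUE, TRUE),
                admin_of      = c(TRUE, TRUE, TRUE),
                outsider      = c(TRUE, TRUE, TRUE)))

  build_scenario <- function(role, rel) {
    repo <- repo_create(2, admin = "root")
    repo <- repo_add_user(repo, "root", "pa", role = "project_admin")
    repo <- repo_add_user(repo, "root", "owner")
    repo <- manage_project(repo, "pa", "create", "P")
    repo <- manage_project(repo, "pa", "add_member", "P", "owner")
    repo <- repo_store(repo, "owner", valid_record(1), "P")
    if (role == "site_admin") {
      subject <- "root"
      if (rel == "owner") {
        repo <- manage_project(repo, "pa", "add_member", "P", "root")
        repo <- transfer_ownership(repo, "root",
                                   list(make_identifier(2, 1, 1)), "root")
      }
      return(list(repo = repo, subject = subject))
    }
    subject <- "subj"
    repo <- repo_add_user(repo, "root", subject,
                          role = if (role == "project_admin") "project_admin"
                                 else "user")
    if (rel != "outsider") {
      repo <- manage_project(repo, "pa", "add_member", "P", subject,
                             as_admin = rel == "admin_of" &&
                               role == "project_admin")
    }
    if (rel == "owner") {
      repo <- transfer_ownership(repo, "pa", list(make_identifier(2, 1, 1)),
                                 subject)
    }
    if (rel == "read_grantee") {
      repo <- grant_permission(repo, repo$samples[[1]]$owner,
                               make_identifier(2, 1, 1), subject, "read")
    }
    if (rel == "write_grantee") {
      repo <- grant_permission(repo, repo$samples[[1]]$owner,
                               make_identifier(2, 1, 1), subject, "write")
    }
    list(repo = repo, subject = subject)
  }

  for (role in names(expected)) {
    for (rel in relationships) {
      sc <- build_scenario(role, rel)
      for (k in 1:3) {
        action <- c("read", "write", "delete")[k]
        expect_identical(
          authorize(sc$repo, sc$subject, action, make_identifier(2, 1, 1)),
          expected[[role]][[rel]][k],
          label = sprintf("%s/%s/%s", role, rel, action))
      }
    }
  }

  # the user/admin_of cell is unconstructible by design
  repo <- example_repo(0)
  expect_s3_class(tryCatch(
    manage_project(repo, "pa", "add_member", "EXAMPLE", "pm1", as_admin = TRUE),
    condition = identity), "fieldbar_authorization_error")
})

test_that("queries match identifiers exactly, text case-insensitively, and filter by read access", {
  repo <- example_repo(3)
  hit <- repo_query(repo, "pm1", identifier = "02000001000002")
  expect_length(hit, 1)
  expect_equal(hit[[1]]$record$core$sample_name, "helgoland-2")
  expect_length(repo_query(repo, "pm1", identifier = "02-000001-000002"), 1)
  expect_error(repo_query(repo, "pm1", identifier = "2-1-2"), "parse|length")

  expect_length(repo_query(repo, "pm1", text = "PM1", field = "collector"), 3)
  expect_length(repo_query(repo, "pm1", text = "helgoland"), 3)
  expect_length(repo_query(repo, "pm1", text = "absent-text"), 0)

  # pm2 cannot read pm1's samples: empty result, not an error
  expect_length(repo_query(repo, "pm2", identifier = "02000001000001"), 0)
  expect_length(repo_query(repo, "out", text = "helgoland"), 0)
  expect_length(repo_query(repo, "root", text = "helgoland"), 3)
})

test_that("the repository state survives a save/load round trip", {
  repo <- example_repo(2)
  blob <- as.raw(c(0x00, 0xde, 0xad, 0x0a))
  rec3 <- attach_package(valid_record(3, seqID = "sq3"), "water")
  rec3 <- set_field(rec3, "temperature", "9.5")
  rec3 <- set_extra(rec3, "vessel", "RV Heincke")
  repo <- repo_store(repo, "pm1", rec3, "EXAMPLE",
                     extra_sheets = list(notes = blob))
  repo <- grant_permission(repo, "pm1", rec3, "pm2", "write")

  path <- withr::local_tempfile(fileext = ".json")
  repo_save(repo, path)
  back <- repo_load(path)

  expect_equal(back$sample_counter, repo$sample_counter)
  expect_equal(names(back$samples), names(repo$samples))
  s <- repo_query(back, "pm1", identifier = rec3$identifier)[[1]]
  expect_equal(s$record$core$sample_name, "helgoland-3")
  expect_equal(get_field(s$record, "temperature"), "9.5")
  expect_equal(s$record$extras$vessel, "RV Heincke")
  expect_identical(s$extra_sheets$notes, blob)
  expect_true(authorize(back, "pm2", "write", rec3$identifier))
  expect_false(authorize(back, "pm2", "read", make_identifier(2, 1, 1)))
})

test_that("exactly one site admin exists after any operation sequence", {
  count_admins <- function(repo) {
    sum(vapply(repo$users, function(u) u$role == "site_admin", logical(1)))
  }
  expect_s3_class(tryCatch(
    repo_add_user(example_repo(0), "root", "root2", role = "site_admin"),
    condition = identity), "fieldbar_authorization_error")
  expect_s3_class(tryCatch(
    repo_set_role(example_repo(0), "root", "pm1", "site_admin"),
    condition = identity), "fieldbar_authorization_error")

  set.seed(5)
  repo <- example_repo(1)
  users <- names(repo$users)
  for (i in seq_len(200)) {
    op <- sample(5, 1)
    repo <- tryCatch(switch(op,
      repo_add_user(repo, sample(users, 1), paste0("u", i),
                    role = sample(c("user", "project_admin", "site_admin"), 1)),
      repo_set_role(repo, sample(users, 1), sample(users, 1),
                    sample(c("user", "project_admin", "site_admin"), 1)),
      manage_project(repo, sample(users, 1), "create", paste0("p", i)),
      manage_project(repo, sample(users, 1), "add_member", "EXAMPLE",
                     sample(users, 1)),
      grant_permission(repo, sample(users, 1), make_identifier(2, 1, 1),
                       sample(c("pm1", "pm2", "pa"), 1),
                       sample(c("none", "read", "write"), 1))),
      error = function(e) repo, condition = function(e) repo)
    users <- names(repo$users)
    expect_equal(count_admins(repo), 1)
  }
})
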