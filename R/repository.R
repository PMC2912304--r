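#' Sample repository with roles, ownership and permissions
#'
#' The repository persists contextual records together with their owner,
#' project and any preserved extra worksheets, and enforces the multi-user
#' model: one `site_admin` per installation (the only role that can create
#' users or delete samples), `project_admin`s who create projects, manage
#' membership and transfer ownership, and plain `user`s who own the samples
#' they store and may share them with project colleagues via read or write
#' grants.
#'
#' Repository values are immutable: every operation takes a repository and
#' returns an updated copy, so sequences of operations are easy to test and
#' the whole state can be saved to / loaded from a single JSON file
#' ([repo_save()], [repo_load()]).
#'
#' @param institute_code two-digit installation code used for all identifiers
#'   allocated from this repository.
#' @param admin username of the installation's single site admin.
#' @return A `fieldbar_repo`.
#' @examples
#' repo <- repo_create(2, admin = "root")
#' repo <- repo_add_user(repo, "root", "pa", role = "project_admin")
#' repo <- manage_project(repo, "pa", "create", "EXAMPLE")
#' @export
repo_create <- function(institute_code, admin = "admin") {
  check_component(institute_code, "institute_code", 99L)
  structure(list(
    institute_code = as.integer(institute_code),
    sample_counter = 0L,
    project_counter = 0L,
    users = stats::setNames(list(list(username = admin, role = "site_admin")),
                            admin),
    projects = list(),
    samples = list(),
    grants = list()  # named by sample key: named character(level) by grantee
  ), class = "fieldbar_repo")
}

#' @export
print.fieldbar_repo <- function(x, ...) {
  cat(sprintf("<fieldbar_repo> institute %02d: %d user(s), %d project(s), %d sample(s)\n",
              x$institute_code, length(x$users), length(x$projects),
              length(x$samples)))
  invisible(x)
}

ROLES <- c("site_admin", "project_admin", "user")

repo_user <- function(repo, username) {
  u <- repo$users[[username]]
  if (is.null(u)) stop(sprintf("unknown user '%s'", username), call. = FALSE)
  u
}

repo_sample <- function(repo, sample) {
  key <- sample_key(sample)
  s <- repo$samples[[key]]
  if (is.null(s)) stop(sprintf("unknown sample '%s'", key), call. = FALSE)
  s
}

sample_key <- function(sample) {
  if (is_sample_identifier(sample)) return(format(sample, "numeric"))
  if (inherits(sample, "contextual_record")) {
    return(format(sample$identifier, "numeric"))
  }
  format(parse_identifier(sample), "numeric")
}

stop_auth <- function(message) {
  cond <- structure(class = c("fieldbar_authorization_error", "error", "condition"),
                    list(message = message, call = NULL))
  stop(cond)
}

#' Create a user (site admin only)
#'
#' There is exactly one site admin per installation; attempting to create a
#' second is refused, which keeps the singleton invariant under any sequence
#' of operations.
#'
#' @param repo a `fieldbar_repo`.
#' @param actor acting username (must be the site admin).
#' @param username new user's name.
#' @param role `"user"` or `"project_admin"`.
#' @return Updated repository.
#' @export
repo_add_user <- function(repo, actor, username, role = "user") {
  if (repo_user(repo, actor)$role != "site_admin") {
    stop_auth(sprintf("only the site admin can create users (actor '%s')", actor))
  }
  role <- match.arg(role, ROLES)
  if (role == "site_admin") {
    stop_auth("there is exactly one site admin per installation")
  }
  if (username %in% names(repo$users)) {
    stop(sprintf("user '%s' already exists", username), call. = FALSE)
  }
  repo$users[[username]] <- list(username = username, role = role)
  repo
}

#' Promote or demote a user between user and project_admin (site admin only)
#' @inheritParams repo_add_user
#' @export
repo_set_role <- function(repo, actor, username, role) {
  if (repo_user(repo, actor)$role != "site_admin") {
    stop_auth("only the site admin can assign or dismiss project admins")
  }
  role <- match.arg(role, ROLES)
  if (role == "site_admin" || repo_user(repo, username)$role == "site_admin") {
    stop_auth("the site admin role cannot be granted or revoked")
  }
  repo$users[[username]]$role <- role
  repo
}

is_project_admin_of <- function(repo, username, project) {
  p <- repo$projects[[project]]
  !is.null(p) && username %in% p$admins &&
    repo$users[[username]]$role %in% c("project_admin", "site_admin")
}

#' Create projects and manage their membership
#'
#' `create` may be performed by any project admin or the site admin; the
#' creating project admin becomes the project's first member and admin.
#' `add_member`/`remove_member` require the site admin or an admin of the
#' target project. Removing a member revokes their grants on the project's
#' samples but never their ownership: a member who still owns samples in the
#' project cannot be removed until ownership is transferred.
#'
#' @param repo a `fieldbar_repo`.
#' @param actor acting username.
#' @param action `"create"`, `"add_member"` or `"remove_member"`.
#' @param project project name.
#' @param member username the action applies to (membership actions).
#' @param as_admin when adding a member, also make them an admin of this
#'   project; refused unless the member holds the `project_admin` (or
#'   `site_admin`) role, which keeps `admins` a subset of qualified members.
#' @return Updated repository.
#' @export
manage_project <- function(repo, actor,
                           action = c("create", "add_member", "remove_member"),
                           project, member = NULL, as_admin = FALSE) {
  action <- match.arg(action)
  role <- repo_user(repo, actor)$role
  if (action == "create") {
    if (!role %in% c("project_admin", "site_admin")) {
      stop_auth(sprintf("role '%s' may not create projects", role))
    }
    if (project %in% names(repo$projects)) {
      stop(sprintf("project '%s' already exists", project), call. = FALSE)
    }
    repo$project_counter <- repo$project_counter + 1L
    repo$projects[[project]] <- list(
      name = project, project_number = repo$project_counter,
      members = if (role == "project_admin") actor else character(0),
      admins = if (role == "project_admin") actor else character(0))
    return(repo)
  }
  p <- repo$projects[[project]]
  if (is.null(p)) stop(sprintf("unknown project '%s'", project), call. = FALSE)
  if (role != "site_admin" && !is_project_admin_of(repo, actor, project)) {
    stop_auth(sprintf("'%s' does not administer project '%s'", actor, project))
  }
  repo_user(repo, member)
  if (action == "add_member") {
    p$members <- union(p$members, member)
    if (as_admin) {
      if (!repo$users[[member]]$role %in% c("project_admin", "site_admin")) {
        stop_auth(sprintf(
          "'%s' holds role '%s' and cannot administer a project",
          member, repo$users[[member]]$role))
      }
      p$admins <- union(p$admins, member)
    }
  } else {
    owned <- Filter(function(s) s$project == project && s$owner == member,
                    repo$samples)
    if (length(owned)) {
      stop(sprintf(
        "cannot remove '%s' from '%s': still owns %d sample(s); transfer ownership first",
        member, project, length(owned)), call. = FALSE)
    }
    p$members <- setdiff(p$members, member)
    p$admins <- setdiff(p$admins, member)
    for (key in names(repo$samples)) {
      if (repo$samples[[key]]$project == project) {
        repo$grants[[key]] <- repo$grants[[key]][
          names(repo$grants[[key]]) != member]
      }
    }
  }
  repo$projects[[project]] <- p
  repo
}

#' Allocate identifiers from the repository's sample counter
#'
#' The single installation-wide counter is advanced and persisted in the
#' returned repository before the identifiers are handed out, so blocks
#' allocated over the life of a repository never overlap.
#'
#' @param repo a `fieldbar_repo`.
#' @param project project name (must exist; its number goes into the
#'   identifiers).
#' @param count how many consecutive sample numbers to reserve.
#' @return List with `repo` (counter advanced), `block` and `identifiers`.
#' @export
repo_allocate <- function(repo, project, count) {
  p <- repo$projects[[project]]
  if (is.null(p)) stop(sprintf("unknown project '%s'", project), call. = FALSE)
  block <- allocate_block(p$project_number, count, repo$sample_counter)
  repo$sample_counter <- block$counter_state
  list(repo = repo,
       block = block,
       identifiers = block_identifiers(block, repo$institute_code))
}

#' Store (or merge-update) a contextual record
#'
#' A new sample is owned by the storing user, who must be a member of the
#' project. Re-storing an existing sample requires write permission and
#' merges via [merge_update()] (non-empty incoming values overwrite);
#' ownership is unchanged. Extra worksheets are kept byte-identical.
#'
#' @param repo a `fieldbar_repo`.
#' @param actor storing username.
#' @param record a `contextual_record`.
#' @param project project the sample belongs to.
#' @param extra_sheets named list of raw vectors preserved with the sample.
#' @param registry the package registry (for merge resolution).
#' @return Updated repository.
#' @export
repo_store <- function(repo, actor, record, project, extra_sheets = list(),
                       registry = default_registry()) {
  stopifnot(inherits(record, "contextual_record"))
  repo_user(repo, actor)
  p <- repo$projects[[project]]
  if (is.null(p)) stop(sprintf("unknown project '%s'", project), call. = FALSE)
  key <- sample_key(record)
  if (!is.null(repo$samples[[key]])) {
    if (!authorize(repo, actor, "write", key)) {
      stop_auth(sprintf("'%s' may not update sample %s", actor, key))
    }
    s <- repo$samples[[key]]
    s$record <- merge_update(s$record, record, registry)
    if (length(extra_sheets)) {
      s$extra_sheets[names(extra_sheets)] <- extra_sheets
    }
    repo$samples[[key]] <- s
    return(repo)
  }
  if (!actor %in% p$members) {
    stop_auth(sprintf("'%s' is not a member of project '%s'", actor, project))
  }
  repo$samples[[key]] <- list(record = record, owner = actor,
                              project = project, extra_sheets = extra_sheets)
  repo
}

#' Grant, change or revoke access to a sample
#'
#' Only the sample's owner (or the site admin) shares a sample. The grantee
#' must be a member of the sample's project. Level `"write"` implies read;
#' `"none"` removes any existing grant, withdrawing access.
#'
#' @param repo a `fieldbar_repo`.
#' @param actor acting username (owner or site admin).
#' @param sample identifier (object or canonical/numeric string).
#' @param grantee username receiving the grant.
#' @param level `"none"`, `"read"` or `"write"`.
#' @return Updated repository.
#' @export
grant_permission <- function(repo, actor, sample, grantee,
                             level = c("none", "read", "write")) {
  level <- match.arg(level)
  repo_user(repo, actor); repo_user(repo, grantee)
  key <- sample_key(sample)
  s <- repo_sample(repo, key)
  if (actor != s$owner && repo$users[[actor]]$role != "site_admin") {
    stop_auth(sprintf("'%s' does not own sample %s and may not share it",
                      actor, key))
  }
  if (!grantee %in% repo$projects[[s$project]]$members) {
    stop(sprintf("grantee '%s' is not a member of project '%s'",
                 grantee, s$project), call. = FALSE)
  }
  g <- repo$grants[[key]] %||% character(0)
  if (level == "none") g <- g[names(g) != grantee] else g[[grantee]] <- level
  repo$grants[[key]] <- g
  repo
}

#' Transfer ownership of a set of samples (all or none)
#'
#' A project admin of the samples' project (or the site admin) reassigns
#' ownership of a whole set atomically: if any sample is outside the actor's
#' administration or the new owner is not a project member, nothing is
#' transferred. The previous owner keeps only whatever access was granted
#' explicitly.
#'
#' @param repo a `fieldbar_repo`.
#' @param actor acting username.
#' @param samples list/vector of sample identifiers.
#' @param new_owner username taking ownership.
#' @return Updated repository.
#' @export
transfer_ownership <- function(repo, actor, samples, new_owner) {
  repo_user(repo, actor); repo_user(repo, new_owner)
  if (!is.list(samples)) samples <- as.list(samples)
  keys <- vapply(samples, sample_key, character(1))
  actor_is_site <- repo$users[[actor]]$role == "site_admin"
  for (key in keys) {  # validate everything before touching anything
    s <- repo_sample(repo, key)
    if (!actor_is_site && !is_project_admin_of(repo, actor, s$project)) {
      stop_auth(sprintf(
        "'%s' does not administer project '%s' of sample %s; no sample transferred",
        actor, s$project, key))
    }
    if (!new_owner %in% repo$projects[[s$project]]$members) {
      stop(sprintf("new owner '%s' is not a member of project '%s'; no sample transferred",
                   new_owner, s$project), call. = FALSE)
    }
  }
  for (key in keys) repo$samples[[key]]$owner <- new_owner
  repo
}

#' Decide whether a user may read, write or delete a sample
#'
#' The decision procedure: deletion is reserved to the site admin; writing is
#' allowed to the owner, a write-grantee or the site admin; reading to any of
#' those, a read-grantee, or a project admin of the sample's project (so a
#' project's consolidated data can be reviewed before submission).
#'
#' @param repo a `fieldbar_repo`.
#' @param user username (unknown users are an error, not a denial).
#' @param action `"read"`, `"write"` or `"delete"`.
#' @param sample sample identifier.
#' @return `TRUE` or `FALSE`.
#' @export
authorize <- function(repo, user, action = c("read", "write", "delete"),
                      sample) {
  action <- match.arg(action)
  u <- repo_user(repo, user)
  s <- repo_sample(repo, sample)
  if (u$role == "site_admin") return(TRUE)
  if (action == "delete") return(FALSE)
  if (s$owner == user) return(TRUE)
  level <- (repo$grants[[sample_key(sample)]] %||% character(0))[user]
  level <- if (is.na(level)) "none" else unname(level)
  if (action == "write") return(level == "write")
  # read
  level %in% c("read", "write") || is_project_admin_of(repo, user, s$project)
}

#' Delete a sample (site admin only)
#' @inheritParams authorize
#' @param actor acting username.
#' @return Updated repository.
#' @export
repo_delete <- function(repo, actor, sample) {
  key <- sample_key(sample)
  repo_sample(repo, key)
  if (!authorize(repo, actor, "delete", key)) {
    stop_auth(sprintf("'%s' may not delete sample %s", actor, key))
  }
  repo$samples[[key]] <- NULL
  repo$grants[[key]] <- NULL
  repo
}

#' Query stored samples by identifier or metadata text
#'
#' An identifier query (canonical or numeric form, e.g. from a barcode scan)
#' matches exactly one sample. A text query matches case-insensitive
#' substrings on the named field — a core field, a `package:field` key or an
#' extra — or on all fields when `field` is `NULL`. Results are filtered by
#' [authorize()]: samples the caller may not read are silently absent, never
#' an error.
#'
#' @param repo a `fieldbar_repo`.
#' @param caller username running the query.
#' @param identifier identifier string/object (exact match), or `NULL`.
#' @param text substring to search for (ignored for identifier queries).
#' @param field restrict the text search to one field name.
#' @return Named list (by numeric identifier) of stored samples, each a list
#'   with `record`, `owner`, `project`, `extra_sheets`.
#' @export
repo_query <- function(repo, caller, identifier = NULL, text = NULL,
                       field = NULL) {
  repo_user(repo, caller)
  keys <- names(repo$samples)
  if (!is.null(identifier)) {
    key <- sample_key(identifier)  # malformed identifiers raise a parse error
    keys <- intersect(keys, key)
  } else if (!is.null(text)) {
    keys <- Filter(function(k) {
      sample_matches_text(repo$samples[[k]]$record, text, field)
    }, keys)
  }
  keys <- Filter(function(k) authorize(repo, caller, "read", k), keys)
  repo$samples[keys]
}

sample_matches_text <- function(record, text, field = NULL) {
  vals <- c(stats::setNames(vapply(record$core, format_raw, character(1)),
                            names(record$core)),
            vapply(record$field_values, format_raw, character(1)),
            vapply(record$extras, format_raw, character(1)))
  if (!is.null(field)) vals <- vals[names(vals) == field]
  any(grepl(text, vals, ignore.case = TRUE, fixed = FALSE))
}

# ---- persistence ------------------------------------------------------------

record_to_list <- function(r) {
  list(identifier = format(r$identifier, "numeric"),
       core = lapply(r$core, format_raw),
       attached_packages = as.list(r$attached_packages),
       field_values = lapply(r$field_values, format_raw),
       extras = lapply(r$extras, format_raw))
}

record_from_list <- function(l) {
  rec <- contextual_record(parse_identifier(l$identifier))
  for (f in names(l$core)) rec$core[[f]] <- l$core[[f]]
  rec$attached_packages <- as.character(unlist(l$attached_packages))
  rec$field_values <- l$field_values
  rec$extras <- l$extras
  rec
}

#' Save the full repository state to one JSON file
#'
#' Typed record fields, package key-values, users, projects, grants and the
#' sample counter are written as documented JSON; preserved extra worksheets
#' are embedded base64-encoded so the dump is a complete backup.
#'
#' @param repo a `fieldbar_repo`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
repo_save <- function(repo, path) {
  dump <- list(
    format = "fieldbar-repo", format_version = "1.0",
    institute_code = repo$institute_code,
    sample_counter = repo$sample_counter,
    project_counter = repo$project_counter,
    users = unname(repo$users),
    projects = lapply(unname(repo$projects), function(p) {
      list(name = p$name, project_number = p$project_number,
           members = as.list(p$members), admins = as.list(p$admins))
    }),
    samples = lapply(unname(repo$samples), function(s) {
      list(record = record_to_list(s$record), owner = s$owner,
           project = s$project,
           extra_sheets = lapply(s$extra_sheets, jsonlite::base64_enc))
    }),
    grants = lapply(names(repo$grants), function(k) {
      list(sample = k,
           grants = lapply(names(repo$grants[[k]]), function(u) {
             list(grantee = u, level = unname(repo$grants[[k]][[u]]))
           }))
    }))
  jsonlite::write_json(dump, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Load a repository from a JSON dump written by [repo_save()]
#' @param path dump file.
#' @return A `fieldbar_repo`.
#' @export
repo_load <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(d$format, "fieldbar-repo")) {
    stop("not a repository dump: ", path, call. = FALSE)
  }
  repo <- repo_create(d$institute_code)
  repo$sample_counter <- as.integer(d$sample_counter)
  repo$project_counter <- as.integer(d$project_counter)
  repo$users <- stats::setNames(
    lapply(d$users, function(u) list(username = u$username, role = u$role)),
    vapply(d$users, `[[`, character(1), "username"))
  repo$projects <- stats::setNames(
    lapply(d$projects, function(p) {
      list(name = p$name, project_number = as.integer(p$project_number),
           members = as.character(unlist(p$members)),
           admins = as.character(unlist(p$admins)))
    }),
    vapply(d$projects, `[[`, character(1), "name"))
  repo$samples <- stats::setNames(
    lapply(d$samples, function(s) {
      list(record = record_from_list(s$record), owner = s$owner,
           project = s$project,
           extra_sheets = lapply(s$extra_sheets, jsonlite::base64_dec))
    }),
    vapply(d$samples, function(s) s$record$identifier, character(1)))
  for (g in d$grants) {
    lv <- vapply(g$grants, `[[`, character(1), "level")
    names(lv) <- vapply(g$grants, `[[`, character(1), "grantee")
    repo$grants[[g$sample]] <- lv
  }
  repo
}
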