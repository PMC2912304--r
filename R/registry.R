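# Package registry: named GSC-style sets of extra contextual-data fields.
# Shipped as a versioned JSON file so field sets can be amended without code
# changes; an alternative registry file can be supplied everywhere a registry
# is accepted.

CORE_FIELDS <- c("latitude", "longitude", "vertical_position",
                 "collection_timestamp", "sample_name", "collector", "seqID")

REQUIRED_CORE <- c("latitude", "longitude", "vertical_position",
                   "collection_timestamp")

#' Load the contextual-data package registry
#'
#' The registry declares the environmental packages (air, host-associated,
#' human-associated, sediment, soil, wastewater_sludge, water) and the
#' report-type packages (miens_c for cultured-isolate studies, me for
#' metagenome studies), each an ordered list of field definitions with value
#' type, units, optional numeric range or controlled vocabulary, and a
#' mandatory/optional requirement level.
#'
#' @param path path to a registry JSON file; default is the registry shipped
#'   with the package.
#' @return A `package_registry` object (list of `package_definition`s, in
#'   registry order).
#' @export
load_registry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "package_registry.json", package = "fieldbar",
                        mustWork = TRUE)
  }
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(raw$packages)) {
    stop("registry file has no 'packages' element: ", path, call. = FALSE)
  }
  pkgs <- lapply(raw$packages, as_package_definition)
  names(pkgs) <- vapply(pkgs, `[[`, character(1), "name")
  if (anyDuplicated(names(pkgs))) {
    stop("duplicate package names in registry", call. = FALSE)
  }
  structure(list(version = raw$registry_version %||% "unversioned",
                 packages = pkgs),
            class = "package_registry")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

VALUE_TYPES <- c("decimal", "integer", "text", "timestamp", "vocabulary")

as_field_definition <- function(f) {
  stopifnot(is.character(f$name), length(f$name) == 1L)
  type <- match.arg(f$value_type, VALUE_TYPES)
  rng <- if (!is.null(f$numeric_range)) as.numeric(unlist(f$numeric_range))
  voc <- if (!is.null(f$vocabulary)) as.character(unlist(f$vocabulary))
  if (!is.null(rng) && !type %in% c("decimal", "integer")) {
    stop(sprintf("field '%s': numeric_range only valid for decimal/integer",
                 f$name), call. = FALSE)
  }
  if (!is.null(voc) && type != "vocabulary") {
    stop(sprintf("field '%s': vocabulary only valid for vocabulary type",
                 f$name), call. = FALSE)
  }
  if (type == "vocabulary" && is.null(voc)) {
    stop(sprintf("field '%s': vocabulary type needs a term list", f$name),
         call. = FALSE)
  }
  structure(list(name = f$name, value_type = type,
                 units = f$units %||% "",
                 numeric_range = rng, vocabulary = voc,
                 requirement = match.arg(f$requirement %||% "optional",
                                         c("optional", "mandatory"))),
            class = "field_definition")
}

as_package_definition <- function(p) {
  stopifnot(is.character(p$name), length(p$name) == 1L)
  kind <- match.arg(p$kind, c("environmental", "report"))
  fields <- lapply(p$fields, as_field_definition)
  fnames <- vapply(fields, `[[`, character(1), "name")
  if (anyDuplicated(fnames)) {
    stop(sprintf("package '%s': duplicate field names", p$name), call. = FALSE)
  }
  names(fields) <- fnames
  structure(list(name = p$name, kind = kind, fields = fields),
            class = "package_definition")
}

#' Look up a package definition in the registry
#'
#' @param name registered package name (e.g. `"air"`, `"water"`, `"me"`).
#' @param registry a `package_registry`; default is the shipped registry.
#' @return The `package_definition` (treat as immutable).
#' @examples
#' air <- get_package("air")
#' names(air$fields)
#' @export
get_package <- function(name, registry = default_registry()) {
  stopifnot(inherits(registry, "package_registry"))
  if (!is.character(name) || length(name) != 1L || !name %in% names(registry$packages)) {
    stop(sprintf("unknown package '%s'; registered packages: %s",
                 as.character(name)[1L],
                 paste(names(registry$packages), collapse = ", ")),
         call. = FALSE)
  }
  registry$packages[[name]]
}

#' Names of all registered packages
#' @param registry a `package_registry`.
#' @param kind optionally restrict to `"environmental"` or `"report"`.
#' @return Character vector in registry order.
#' @export
registry_packages <- function(registry = default_registry(), kind = NULL) {
  stopifnot(inherits(registry, "package_registry"))
  nm <- names(registry$packages)
  if (!is.null(kind)) {
    kinds <- vapply(registry$packages, `[[`, character(1), "kind")
    nm <- nm[kinds == kind]
  }
  nm
}

# the shipped registry, loaded once per session
registry_cache <- new.env(parent = emptyenv())

#' The registry shipped with the package
#' @return A `package_registry` (cached per session).
#' @export
default_registry <- function() {
  if (is.null(registry_cache$default)) registry_cache$default <- load_registry()
  registry_cache$default
}

#' @export
print.package_registry <- function(x, ...) {
  cat("<package_registry> version", x$version, "-", length(x$packages),
      "packages:", paste(names(x$packages), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.package_definition <- function(x, ...) {
  cat(sprintf("<package_definition> %s (%s), %d fields\n",
              x$name, x$kind, length(x$fields)))
  invisible(x)
}
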