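# Plugin registry: a data-source plugin is a directory holding manifest.json
# and the parser script it names. The manifest declares where the payload
# lives (file:// or http(s)://), which parser function turns a dumped
# release into documents, and optionally a cron schedule and merge priority.

hub_error <- function(msg, class, ...) {
  structure(
    class = c(class, "annohub_error", "error", "condition"),
    list(message = msg, call = NULL, ...)
  )
}

#' Load and validate a plugin manifest
#'
#' Reads `manifest.json` from a plugin directory (or an explicit path to
#' the file) and returns a fully defaulted source descriptor. Required
#' keys: `name`, `location`, `parser_ref`. Defaults: `priority` 100,
#' no schedule (manual trigger only). All validation failures are reported
#' at once, never one at a time.
#'
#' @param path A plugin directory containing `manifest.json`, or the path
#'   to the manifest file itself.
#' @return A `SourceDescriptor`: list with `name`, `location`,
#'   `parser_ref`, `schedule` (or `NULL`), `priority`, `metadata`,
#'   `plugin_dir`.
#' @export
load_manifest <- function(path) {
  mf <- if (dir.exists(path)) file.path(path, "manifest.json") else path
  if (!file.exists(mf)) {
    stop(hub_error(sprintf("manifest not found: %s", mf), "annohub_validation_error"))
  }
  raw <- jsonlite::fromJSON(mf, simplifyVector = FALSE)
  problems <- character(0)
  missing <- setdiff(c("name", "location", "parser_ref"), names(raw))
  if (length(missing)) {
    problems <- c(problems, sprintf("missing required key(s): %s",
                                    paste(missing, collapse = ", ")))
  }
  nm <- raw[["name"]]
  if (!is.null(nm) && (!is.character(nm) || !grepl("^[A-Za-z0-9_]+$", nm))) {
    problems <- c(problems, "`name` must match [A-Za-z0-9_]+")
  }
  pr <- raw[["priority"]]
  if (!is.null(pr) && (!is.numeric(pr) || length(pr) != 1L || pr < 1 || pr != trunc(pr))) {
    problems <- c(problems, "`priority` must be a positive integer")
  }
  sched <- raw[["schedule"]]
  if (!is.null(sched)) {
    tryCatch(parse_cron(sched), error = function(e) {
      problems <<- c(problems, conditionMessage(e))
    })
  }
  pref <- raw[["parser_ref"]]
  if (!is.null(pref) && (!is.character(pref) || !grepl("^[^:]+:[^:]+$", pref))) {
    problems <- c(problems, "`parser_ref` must have the form \"unit:callable\"")
  }
  if (length(problems)) {
    stop(hub_error(paste0("invalid manifest ", mf, ":\n  - ",
                          paste(problems, collapse = "\n  - ")),
                   "annohub_validation_error", problems = problems,
                   missing = missing))
  }
  structure(list(
    name = nm,
    location = raw[["location"]],
    parser_ref = pref,
    schedule = sched,
    priority = as.integer(if (is.null(pr)) 100L else pr),
    metadata = if (is.null(raw[["metadata"]])) list() else raw[["metadata"]],
    plugin_dir = normalizePath(dirname(mf), mustWork = FALSE)
  ), class = "annohub_source")
}

#' @export
print.annohub_source <- function(x, ...) {
  cat(sprintf("<source %s> %s\n  parser: %s  priority: %d  schedule: %s\n",
              x$name, x$location, x$parser_ref, x$priority,
              if (is.null(x$schedule)) "(manual)" else x$schedule))
  invisible(x)
}

# Resolve "unit:callable" against the plugin directory: source <unit>.R in a
# private environment and fetch the named function. Fails fast.
resolve_parser <- function(d) {
  bits <- strsplit(d$parser_ref, ":", fixed = TRUE)[[1]]
  unit <- bits[1]
  fun <- bits[2]
  script <- file.path(d$plugin_dir, paste0(unit, ".R"))
  if (!file.exists(script)) {
    stop(hub_error(sprintf("cannot resolve parser_ref \"%s\": no file %s",
                           d$parser_ref, script), "annohub_registration_error"))
  }
  env <- new.env(parent = baseenv())
  sys.source(script, envir = env)
  if (!exists(fun, envir = env, inherits = FALSE) ||
      !is.function(get(fun, envir = env))) {
    stop(hub_error(sprintf("cannot resolve parser_ref \"%s\": no function `%s` in %s",
                           d$parser_ref, fun, script), "annohub_registration_error"))
  }
  get(fun, envir = env)
}

#' Create an empty plugin registry
#'
#' A registry maps source names to descriptors and tracks per-source state
#' (last dump time, last known release).
#'
#' @return An `annohub_registry` object.
#' @export
registry <- function() {
  structure(list(descriptors = list(), state = list()),
            class = "annohub_registry")
}

#' Register a source descriptor
#'
#' The parser entry point is resolved eagerly so a broken plugin fails at
#' registration, not at upload. Re-registering an existing name replaces
#' the descriptor and preserves accumulated state.
#'
#' @param reg An [registry()] object.
#' @param d A descriptor from [load_manifest()].
#' @param resolve Resolve `parser_ref` now (default `TRUE`).
#' @return The updated registry.
#' @export
register_source <- function(reg, d, resolve = TRUE) {
  stopifnot(inherits(reg, "annohub_registry"), inherits(d, "annohub_source"))
  if (resolve) resolve_parser(d)
  if (!is.null(reg$descriptors[[d$name]])) {
    message(sprintf("replacing registered source `%s`", d$name))
  }
  reg$descriptors[[d$name]] <- d
  reg
}

#' Look up a registered source
#'
#' @param reg A registry.
#' @param name Source name.
#' @return The descriptor, or an error of class `annohub_not_found` when
#'   the name is unknown.
#' @export
registry_get <- function(reg, name) {
  d <- reg$descriptors[[name]]
  if (is.null(d)) {
    stop(hub_error(sprintf("source not registered: %s", name), "annohub_not_found"))
  }
  d
}

#' List registered source names
#' @param reg A registry.
#' @return Character vector of names (registration order).
#' @export
registry_names <- function(reg) names(reg$descriptors)

registry_set_state <- function(reg, name, last_dump_time = NULL, last_release = NULL) {
  st <- reg$state[[name]]
  if (is.null(st)) st <- list()
  if (!is.null(last_dump_time)) st$last_dump_time <- as.character(last_dump_time)
  if (!is.null(last_release)) st$last_release <- last_release
  reg$state[[name]] <- st
  reg
}

#' Persist a registry to the hub's data root
#'
#' Written as a single JSON state file `registry.json`.
#'
#' @param reg A registry.
#' @param data_root Hub data root directory.
#' @return The file path, invisibly.
#' @export
registry_save <- function(reg, data_root) {
  path <- file.path(data_root, "registry.json")
  dir.create(data_root, recursive = TRUE, showWarnings = FALSE)
  payload <- list(
    descriptors = lapply(reg$descriptors, function(d) {
      d[c("name", "location", "parser_ref", "schedule", "priority",
          "metadata", "plugin_dir")]
    }),
    state = reg$state
  )
  writeLines(as.character(jsonlite::toJSON(payload, auto_unbox = TRUE,
                                           digits = NA, null = "null")), path)
  invisible(path)
}

#' Load a registry previously saved with [registry_save()]
#'
#' @param data_root Hub data root directory.
#' @return A registry; empty if no state file exists.
#' @export
registry_load <- function(data_root) {
  path <- file.path(data_root, "registry.json")
  reg <- registry()
  if (!file.exists(path)) return(reg)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (d in raw$descriptors) {
    desc <- structure(list(
      name = d$name, location = d$location, parser_ref = d$parser_ref,
      schedule = d$schedule,
      priority = as.integer(d$priority),
      metadata = if (is.null(d$metadata)) list() else d$metadata,
      plugin_dir = d$plugin_dir
    ), class = "annohub_source")
    reg$descriptors[[desc$name]] <- desc
  }
  reg$state <- if (is.null(raw$state)) list() else raw$state
  reg
}
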