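# Build stage: merge per-source documents sharing an `_id` into one
# document per entity. Merge policy is source-namespaced: each source's
# body lands under a top-level key equal to the source name, which makes
# merging total, lossless and order-invariant (namespaces cannot collide).
# Root sources gate membership: when any are configured, an id must occur
# in at least one root source to enter the build.

#' Define a build configuration
#'
#' @param name Build name (used as the prefix of build versions).
#' @param sources Character vector of source names, or a named character
#'   vector/list mapping source name to a release selector (`"latest"` or
#'   an explicit release tag value). Unnamed entries select `"latest"`.
#' @param root_sources Subset of `sources` whose identifier space gates
#'   build membership; empty means no gate.
#' @return An `annohub_build_config` object.
#' @export
#' @examples
#' build_config("demo", c("alpha", "beta"), root_sources = "alpha")
build_config <- function(name, sources, root_sources = character(0)) {
  if (is.list(sources)) sources <- unlist(sources)
  if (is.null(names(sources))) {
    sel <- setNames(rep("latest", length(sources)), sources)
  } else {
    nm <- ifelse(nzchar(names(sources)), names(sources), sources)
    sel <- setNames(ifelse(nzchar(names(sources)), unname(sources), "latest"), nm)
  }
  if (length(sel) == 0L) stop(hub_error("build needs at least one source",
                                        "annohub_build_error"))
  if (anyDuplicated(names(sel))) {
    stop(hub_error("duplicate source names in build config", "annohub_build_error"))
  }
  root_sources <- as.character(root_sources)
  if (!all(root_sources %in% names(sel))) {
    stop(hub_error("root_sources must be a subset of sources", "annohub_build_error"))
  }
  structure(list(name = name, selectors = sel, root_sources = root_sources,
                 merge_mode = "source-namespaced"),
            class = "annohub_build_config")
}

#' Read a build configuration from a JSON file
#'
#' Schema: `{"name": ..., "sources": [{"name": ..., "release"?: ...}, ...]
#' or ["alpha","beta"], "root_sources"?: [...]}`.
#'
#' @param path Path to the JSON file.
#' @return An `annohub_build_config`.
#' @export
read_build_config <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  srcs <- raw$sources
  if (is.null(raw$name) || is.null(srcs)) {
    stop(hub_error("build config needs `name` and `sources`", "annohub_build_error"))
  }
  sel <- character(0)
  for (s in srcs) {
    if (is.character(s)) {
      sel[s] <- "latest"
    } else {
      sel[s$name] <- if (is.null(s$release)) "latest" else s$release
    }
  }
  build_config(raw$name, sel,
               root_sources = unlist(raw$root_sources %||% list()) %||% character(0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Resolve releases and take an identifier census for a build
#'
#' `"latest"` selectors resolve to the highest uploaded release tag;
#' explicit selectors are used verbatim even when newer uploads exist.
#'
#' @param cfg A [build_config()].
#' @param store A document store holding uploaded releases.
#' @return A `BuildPlan`: resolved `releases` (name -> tag value), per
#'   source id sets and counts, `union_ids`, `root_ids`, and the id set
#'   `merged_ids` the build will emit.
#' @export
plan_build <- function(cfg, store) {
  releases <- character(0)
  id_sets <- list()
  for (s in names(cfg$selectors)) {
    have <- store_releases(store, s)
    if (length(have) == 0L) {
      stop(hub_error(sprintf("source never uploaded: %s", s),
                     "annohub_build_error", source = s))
    }
    sel <- cfg$selectors[[s]]
    rel <- if (identical(sel, "latest")) have[[length(have)]] else sel
    if (!(rel %in% have)) {
      stop(hub_error(sprintf("release %s of source %s not uploaded", rel, s),
                     "annohub_build_error", source = s))
    }
    releases[s] <- rel
    id_sets[[s]] <- names(store_docs(store, s, rel))
  }
  union_ids <- sort(unique(unlist(id_sets, use.names = FALSE)), method = "radix")
  root_ids <- if (length(cfg$root_sources)) {
    sort(unique(unlist(id_sets[cfg$root_sources], use.names = FALSE)),
         method = "radix")
  } else {
    union_ids
  }
  merged_ids <- intersect(union_ids, root_ids)
  structure(list(config = cfg, releases = releases,
                 ids_per_source = lapply(id_sets, length),
                 id_sets = id_sets,
                 union_ids = union_ids, root_ids = root_ids,
                 merged_ids = merged_ids),
            class = "annohub_build_plan")
}

#' Merge the per-source documents of one entity
#'
#' All inputs must share the same `_id`. Each source's body (its document
#' minus `_id`) is namespaced under a top-level key equal to the source
#' name; sources with an empty body contribute nothing. Namespace keys are
#' emitted in sorted source-name order, so the merged tree is invariant to
#' the order of the inputs.
#'
#' @param per_source A list of `list(source =, priority =, doc =)` entries.
#' @param cfg A [build_config()] (kept for the contract; the namespaced
#'   policy does not consult priority).
#' @return The merged document tree.
#' @export
#' @examples
#' merge_documents(list(
#'   list(source = "alpha", priority = 100L,
#'        doc = list(`_id` = "g1", symbol = "CDK2", taxid = 9606L)),
#'   list(source = "beta", priority = 100L,
#'        doc = list(`_id` = "g1", pathway = list("cell_cycle", "dna_repair")))
#' ), build_config("demo", c("alpha", "beta")))
merge_documents <- function(per_source, cfg = NULL) {
  ids <- vapply(per_source, function(e) e$doc[["_id"]], character(1))
  if (length(unique(ids)) != 1L) {
    stop(hub_error(sprintf("merge inputs disagree on `_id`: %s",
                           paste(unique(ids), collapse = ", ")),
                   "annohub_contract_error"))
  }
  srcs <- vapply(per_source, function(e) e$source, character(1))
  merged <- list(`_id` = ids[[1]])
  for (i in order(srcs, method = "radix")) {
    body <- per_source[[i]]$doc
    body[["_id"]] <- NULL
    if (length(body) == 0L) next
    merged[[srcs[[i]]]] <- body
  }
  merged
}

#' Run a build: merge configured sources into one corpus
#'
#' Emits one merged document per id in the union of source ids, gated by
#' the root-source rule, in ascending `_id`. The result is persisted under
#' `<data_root>/builds/<build_version>/` as `merged.jsonl` plus a
#' `build.json` metadata file; no partial build directory survives a
#' failure.
#'
#' @param cfg A [build_config()].
#' @param store A document store.
#' @param data_root Hub data root; `NULL` skips persistence.
#' @param registry Optional registry supplying per-source priorities.
#' @return A `BuildResult`: `merged` (named list of documents, ascending
#'   `_id`) and `metadata` (`build_name`, `build_version`, `sources`,
#'   `merged_count`, `root_excluded_count`).
#' @export
run_build <- function(cfg, store, data_root = NULL, registry = NULL) {
  plan <- plan_build(cfg, store)
  src_names <- names(cfg$selectors)
  per_source_docs <- lapply(src_names, function(s) {
    store_docs(store, s, plan$releases[[s]])
  })
  names(per_source_docs) <- src_names
  prio <- vapply(src_names, function(s) {
    if (!is.null(registry)) {
      d <- registry$descriptors[[s]]
      if (!is.null(d)) return(d$priority)
    }
    100L
  }, integer(1))

  merged <- vector("list", length(plan$merged_ids))
  names(merged) <- plan$merged_ids
  for (id in plan$merged_ids) {
    contribs <- list()
    for (s in src_names) {
      doc <- per_source_docs[[s]][[id]]
      if (!is.null(doc)) {
        contribs[[length(contribs) + 1L]] <-
          list(source = s, priority = prio[[s]], doc = doc)
      }
    }
    merged[[id]] <- merge_documents(contribs, cfg)
  }

  version <- build_version_for(cfg$name, data_root)
  metadata <- list(
    build_name = cfg$name,
    build_version = version,
    sources = lapply(src_names, function(s) {
      list(name = s, release = plan$releases[[s]],
           doc_count = plan$ids_per_source[[s]])
    }),
    merged_count = length(merged),
    root_excluded_count = length(plan$union_ids) - length(plan$merged_ids)
  )
  result <- structure(list(merged = merged, metadata = metadata),
                      class = "annohub_build")
  if (!is.null(data_root)) persist_build(result, data_root)
  result
}

build_version_for <- function(name, data_root) {
  stamp <- format(Sys.time(), "%Y%m%d%H%M%S", tz = "UTC")
  version <- paste0(name, ".", stamp)
  if (!is.null(data_root)) {
    n <- 0L
    while (dir.exists(file.path(data_root, "builds", version))) {
      n <- n + 1L
      version <- paste0(name, ".", stamp, "-", n)
    }
  }
  version
}

persist_build <- function(build, data_root) {
  dir.create(file.path(data_root, "builds"), recursive = TRUE, showWarnings = FALSE)
  final <- file.path(data_root, "builds", build$metadata$build_version)
  tmp <- tempfile(pattern = ".tmp-build-", tmpdir = file.path(data_root, "builds"))
  dir.create(tmp)
  ok <- FALSE
  on.exit(if (!ok && dir.exists(tmp)) unlink(tmp, recursive = TRUE))
  write_jsonl(build$merged, file.path(tmp, "merged.jsonl"))
  writeLines(as.character(jsonlite::toJSON(build$metadata, auto_unbox = TRUE,
                                           digits = NA)),
             file.path(tmp, "build.json"))
  file.rename(tmp, final)
  ok <- TRUE
  invisible(final)
}

#' Load a persisted build
#'
#' @param build_version Build version string.
#' @param data_root Hub data root.
#' @return An `annohub_build` object.
#' @export
read_build <- function(build_version, data_root) {
  dir <- file.path(data_root, "builds", build_version)
  if (!dir.exists(dir)) {
    stop(hub_error(sprintf("no such build: %s", build_version), "annohub_not_found"))
  }
  merged <- read_jsonl(file.path(dir, "merged.jsonl"))
  names(merged) <- vapply(merged, function(d) d[["_id"]], character(1))
  metadata <- jsonlite::fromJSON(file.path(dir, "build.json"), simplifyVector = FALSE)
  structure(list(merged = merged, metadata = metadata), class = "annohub_build")
}

#' @export
print.annohub_build <- function(x, ...) {
  cat(sprintf("<build %s> %d merged document(s), %d root-excluded, %d source(s)\n",
              x$metadata$build_version, x$metadata$merged_count,
              x$metadata$root_excluded_count, length(x$metadata$sources)))
  invisible(x)
}
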