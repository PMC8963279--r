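# DocumentStore backend contract: a logical namespace (source, release)
# holds a collection of documents with unique `_id`, iterated in ascending
# `_id`. Two reference backends: in-memory (environment-backed) and
# JSON-lines-on-disk under <data_root>/store/<source>/<release>.jsonl.

#' Create an in-memory document store
#' @return An `annohub_store` object.
#' @export
doc_store_memory <- function() {
  structure(list(kind = "memory", env = new.env(parent = emptyenv())),
            class = "annohub_store")
}

#' Create a JSON-lines-on-disk document store
#'
#' Documents live under `<data_root>/store/<source>/<release>.jsonl`, one
#' UTF-8 JSON object per line, sorted by `_id`.
#'
#' @param data_root Hub data root.
#' @return An `annohub_store` object.
#' @export
doc_store_jsonl <- function(data_root) {
  root <- file.path(data_root, "store")
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  structure(list(kind = "jsonl", root = root), class = "annohub_store")
}

ns_key <- function(source, release) paste0(source, "\x1f", release)

# Replace a namespace wholesale with `docs` (named list id -> doc).
store_put <- function(store, source, release, docs) {
  ids <- vapply(docs, function(d) d[["_id"]], character(1))
  ord <- order(ids, method = "radix")
  docs <- docs[ord]
  names(docs) <- ids[ord]
  if (store$kind == "memory") {
    assign(ns_key(source, release), docs, envir = store$env)
  } else {
    dir.create(file.path(store$root, source), recursive = TRUE, showWarnings = FALSE)
    tmp <- tempfile(tmpdir = file.path(store$root, source))
    write_jsonl(docs, tmp)
    file.rename(tmp, file.path(store$root, source, paste0(release, ".jsonl")))
  }
  invisible(store)
}

#' Fetch the documents of a (source, release) namespace
#'
#' @param store A store from [doc_store_memory()] or [doc_store_jsonl()].
#' @param source Source name.
#' @param release Release tag value (string).
#' @return Named list of documents in ascending `_id`; error of class
#'   `annohub_not_found` when the namespace does not exist.
#' @export
store_docs <- function(store, source, release) {
  if (store$kind == "memory") {
    k <- ns_key(source, release)
    if (!exists(k, envir = store$env, inherits = FALSE)) {
      stop(hub_error(sprintf("no uploaded release %s/%s", source, release),
                     "annohub_not_found"))
    }
    return(get(k, envir = store$env))
  }
  f <- file.path(store$root, source, paste0(release, ".jsonl"))
  if (!file.exists(f)) {
    stop(hub_error(sprintf("no uploaded release %s/%s", source, release),
                   "annohub_not_found"))
  }
  docs <- read_jsonl(f)
  names(docs) <- vapply(docs, function(d) d[["_id"]], character(1))
  docs
}

#' List uploaded releases of a source
#'
#' @inheritParams store_docs
#' @return Character vector of release tag values, ascending; empty when
#'   the source has no uploads.
#' @export
store_releases <- function(store, source) {
  if (store$kind == "memory") {
    keys <- ls(store$env)
    pre <- paste0(source, "\x1f")
    rel <- substring(keys[startsWith(keys, pre)], nchar(pre) + 1L)
    return(sort(rel, method = "radix"))
  }
  d <- file.path(store$root, source)
  if (!dir.exists(d)) return(character(0))
  sort(sub("\\.jsonl$", "", list.files(d, pattern = "\\.jsonl$")),
       method = "radix")
}

store_drop <- function(store, source, release) {
  if (store$kind == "memory") {
    k <- ns_key(source, release)
    if (exists(k, envir = store$env, inherits = FALSE)) rm(list = k, envir = store$env)
  } else {
    unlink(file.path(store$root, source, paste0(release, ".jsonl")))
  }
  invisible(store)
}
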