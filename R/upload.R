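# Upload stage: run the plugin's parser over a dumped release, validate
# every emitted document, and load the survivors into the per-source store.
# Parsers may return either a list of document trees or a zero-argument
# iterator closure yielding one document per call and NULL at exhaustion,
# so large payloads never need to fit in memory at once.

as_doc_iterator <- function(x) {
  if (is.function(x)) return(x)
  if (is.list(x)) {
    i <- 0L
    return(function() {
      i <<- i + 1L
      if (i > length(x)) NULL else x[[i]]
    })
  }
  stop(hub_error("parser must return a list of documents or an iterator function",
                 "annohub_upload_error"))
}

#' Run a plugin's parser over a dumped release folder
#'
#' Resolves the descriptor's `parser_ref` and invokes it with the dump
#' folder path. The result is normalized to an iterator: a zero-argument
#' function yielding one raw document tree per call and `NULL` when the
#' stream is exhausted.
#'
#' @param d A source descriptor.
#' @param dump_folder Path to a dumped release folder.
#' @return A document iterator function.
#' @export
run_parser <- function(d, dump_folder) {
  if (!dir.exists(dump_folder)) {
    stop(hub_error(sprintf("dump folder does not exist: %s", dump_folder),
                   "annohub_upload_error"))
  }
  parser <- resolve_parser(d)
  as_doc_iterator(parser(dump_folder))
}

#' Parse, validate, and load one release into the document store
#'
#' The (source, release) namespace is replaced wholesale, so re-uploading
#' the same release is idempotent. Documents failing validation are
#' skipped and counted with their rejection reasons; duplicate `_id`s
#' within the stream are collapsed last-write-wins. If the parser raises
#' mid-stream, the namespace is left exactly as before the call.
#'
#' @param d A source descriptor.
#' @param release A [release_tag()] or release value string of a dumped
#'   release.
#' @param store A document store.
#' @param data_root Hub data root (where the dump lives).
#' @return An `UploadStats` list: `source`, `release`, `accepted`,
#'   `rejected`, `rejections` (list of `(ordinal, reason)`),
#'   `duplicate_ids_collapsed`.
#' @export
upload_source <- function(d, release, store, data_root) {
  rel_value <- if (inherits(release, "annohub_release")) release$value else release
  folder <- file.path(data_root, d$name, rel_value)
  it <- run_parser(d, folder)

  docs <- list()         # staged namespace; swapped in only on success
  accepted <- 0L
  rejected <- 0L
  dup <- 0L
  rejections <- list()
  ordinal <- 0L
  repeat {
    raw <- tryCatch(it(), error = function(e) {
      stop(hub_error(
        sprintf("parser for `%s` failed after %d document(s): %s",
                d$name, ordinal, conditionMessage(e)),
        "annohub_upload_error", last_good_ordinal = ordinal))
    })
    if (is.null(raw)) break
    ordinal <- ordinal + 1L
    problems <- validate_document(raw)
    if (length(problems)) {
      rejected <- rejected + 1L
      rejections[[length(rejections) + 1L]] <-
        list(ordinal = ordinal, reason = paste(problems, collapse = "; "))
      next
    }
    accepted <- accepted + 1L
    id <- raw[["_id"]]
    if (!is.null(docs[[id]])) dup <- dup + 1L
    docs[[id]] <- raw
  }
  store_put(store, d$name, rel_value, docs)
  structure(list(source = d$name, release = rel_value, accepted = accepted,
                 rejected = rejected, rejections = rejections,
                 duplicate_ids_collapsed = dup),
            class = "annohub_upload_stats")
}

#' @export
print.annohub_upload_stats <- function(x, ...) {
  cat(sprintf("<upload %s/%s> accepted %d, rejected %d, duplicates collapsed %d\n",
              x$source, x$release, x$accepted, x$rejected,
              x$duplicate_ids_collapsed))
  invisible(x)
}
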