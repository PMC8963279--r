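# Annotation documents are plain R trees: named lists are JSON objects,
# unnamed lists are JSON arrays, length-1 atomic vectors are scalars.
# Atomic vectors of length != 1 are treated as arrays of scalars.

is_subtree <- function(x) {
  is.list(x) && !is.null(names(x)) && length(x) > 0L && all(nzchar(names(x)))
}

is_array_node <- function(x) {
  (is.list(x) && !is_subtree(x)) || (is.atomic(x) && length(x) != 1L)
}

is_scalar_leaf <- function(x) {
  is.atomic(x) && length(x) == 1L && !is.null(x)
}

#' Read annotation documents from a JSON-lines file
#'
#' One JSON object per line; scalars stay scalars and arrays stay arrays
#' (no vector simplification), so documents round-trip byte-exactly.
#'
#' @param path Path to a `.jsonl` file.
#' @return A list of document trees.
#' @export
read_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, jsonlite::fromJSON, simplifyVector = FALSE)
}

#' Write annotation documents as JSON lines
#'
#' @param docs List of document trees.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_jsonl <- function(docs, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (d in docs) {
    writeLines(doc_to_json(d), con, useBytes = TRUE)
  }
  invisible(path)
}

#' Serialize one document tree to a single JSON line
#'
#' @param doc A document tree.
#' @return A length-1 character string of JSON.
#' @export
doc_to_json <- function(doc) {
  as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null"))
}

#' Validate a raw document tree
#'
#' Checks the document contract: a non-empty `_id` (at most 512 characters,
#' no surrounding whitespace), keys that are non-empty, contain no `"."` and
#' do not start with `"$"`, and leaves that are finite scalars (no NA, NaN
#' or infinite values, no NULLs). All violations are collected and returned
#' together, never just the first.
#'
#' @param raw A document tree (named list).
#' @return A character vector of violation messages; `character(0)` means
#'   the document is valid.
#' @export
#' @examples
#' validate_document(list(`_id` = "g1", symbol = "CDK2"))   # character(0)
#' validate_document(list(symbol = "CDK2"))                 # missing _id
validate_document <- function(raw) {
  v <- character(0)
  if (!is.list(raw) || is.null(names(raw))) {
    return("document is not a JSON object")
  }
  id <- raw[["_id"]]
  if (is.null(id)) {
    v <- c(v, "missing `_id`")
  } else if (!is.character(id) || length(id) != 1L || is.na(id)) {
    v <- c(v, "`_id` is not a single string")
  } else {
    if (!nzchar(id)) v <- c(v, "`_id` is empty")
    if (nchar(id, type = "bytes") > 512L) v <- c(v, "`_id` exceeds 512 characters")
    if (nzchar(id) && id != trimws(id)) v <- c(v, "`_id` has leading/trailing whitespace")
  }
  v <- c(v, check_node(raw, path = character(0), top = TRUE))
  v
}

check_node <- function(x, path, top = FALSE) {
  v <- character(0)
  loc <- if (length(path)) paste(path, collapse = ".") else "<root>"
  if (is.null(x)) {
    return(sprintf("null value at %s", loc))
  }
  if (is_subtree(x) || (is.list(x) && length(x) > 0L && !is.null(names(x)))) {
    ks <- names(x)
    for (i in seq_along(ks)) {
      k <- ks[[i]]
      if (top && identical(k, "_id")) next
      if (!nzchar(k)) {
        v <- c(v, sprintf("empty key under %s", loc))
        next
      }
      if (grepl(".", k, fixed = TRUE)) v <- c(v, sprintf("key contains \".\": %s", k))
      if (startsWith(k, "$")) v <- c(v, sprintf("key starts with \"$\": %s", k))
      v <- c(v, check_node(x[[i]], c(path, k)))
    }
    return(v)
  }
  if (is.list(x)) { # unnamed list = array
    for (el in x) v <- c(v, check_node(el, path))
    return(v)
  }
  if (is.atomic(x)) {
    if (is.numeric(x) && any(is.nan(x) | is.infinite(x))) {
      v <- c(v, sprintf("non-finite number at %s", loc))
    }
    if (anyNA(x) && !(is.numeric(x) && all(is.nan(x[is.na(x)])))) {
      v <- c(v, sprintf("missing (NA) value at %s", loc))
    }
    if (!is.character(x) && !is.numeric(x) && !is.logical(x)) {
      v <- c(v, sprintf("unsupported leaf type %s at %s", class(x)[1], loc))
    }
    return(v)
  }
  c(v, sprintf("unsupported node type %s at %s", class(x)[1], loc))
}

# Collect the scalar values found at a dotted path; lists are transparent
# (they do not extend the path, each element is visited).
path_values <- function(node, segs) {
  if (is.null(node)) return(list())
  if (is.atomic(node) && length(node) != 1L) {
    node <- as.list(node)
  }
  if (length(segs) == 0L) {
    if (is_scalar_leaf(node)) return(list(node))
    if (is.list(node) && is.null(names(node))) {
      out <- list()
      for (el in node) out <- c(out, path_values(el, segs))
      return(out)
    }
    return(list()) # subtree terminal: no scalar values
  }
  if (is_subtree(node)) {
    return(path_values(node[[segs[[1]]]], segs[-1L]))
  }
  if (is.list(node) && is.null(names(node))) {
    out <- list()
    for (el in node) out <- c(out, path_values(el, segs))
    return(out)
  }
  list()
}

split_path <- function(path) strsplit(path, ".", fixed = TRUE)[[1]]

#' Project a document onto a set of field paths
#'
#' `_id` is always included; a requested path keeps its entire subtree;
#' paths absent from the document contribute nothing. Key order of the
#' stored document is preserved.
#'
#' @param doc A document tree with `_id`.
#' @param fields Character vector of dotted paths, or the string `"all"`.
#' @return The projected document tree.
#' @export
#' @examples
#' d <- list(`_id` = "g1", alpha = list(symbol = "CDK2", taxid = 9606L))
#' project_fields(d, "alpha.symbol")
project_fields <- function(doc, fields = "all") {
  if (length(fields) == 1L && identical(fields, "all")) return(doc)
  want <- lapply(fields, split_path)
  out <- filter_tree(doc, character(0), want, top = TRUE)
  if (is.null(out)) out <- structure(list(), names = character(0))
  out[["_id"]] <- NULL
  c(list(`_id` = doc[["_id"]]), out)
}

filter_tree <- function(node, path, want, top = FALSE) {
  keep_whole <- any(vapply(want, function(w) {
    length(w) <= length(path) && identical(w, path[seq_along(w)])
  }, logical(1)))
  if (keep_whole) return(node)
  if (is_subtree(node)) {
    out <- list()
    for (k in names(node)) {
      if (top && identical(k, "_id")) next
      child_path <- c(path, k)
      on_route <- any(vapply(want, function(w) {
        length(w) >= length(child_path) &&
          identical(w[seq_along(child_path)], child_path)
      }, logical(1)))
      if (!on_route) next
      sub <- filter_tree(node[[k]], child_path, want)
      if (!is.null(sub)) out[[k]] <- sub
    }
    if (length(out) == 0L) return(NULL)
    return(out)
  }
  if (is.list(node) && is.null(names(node))) {
    kept <- list()
    for (el in node) {
      sub <- filter_tree(el, path, want)
      if (!is.null(sub)) kept[[length(kept) + 1L]] <- sub
    }
    if (length(kept) == 0L) return(NULL)
    return(kept)
  }
  NULL
}

# Canonical term string for keyword matching/indexing: lowercase text;
# numbers and booleans use their JSON rendering.
scalar_term <- function(v) {
  if (is.logical(v)) return(if (isTRUE(v)) "true" else "false")
  if (is.numeric(v)) {
    if (is.integer(v) || (is.finite(v) && v == trunc(v) && abs(v) < 1e15)) {
      return(sprintf("%.0f", as.numeric(v)))
    }
    return(tolower(format(v, scientific = FALSE, trim = TRUE, digits = 15)))
  }
  tolower(as.character(v))
}
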