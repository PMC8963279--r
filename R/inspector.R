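# Inspector: stream over a corpus and profile every field path's observed
# types, then derive a typed index mapping. Paths are dotted; lists are
# transparent (they never extend the path, their elements are profiled at
# the same path with in_list = TRUE). `_id` is never profiled.

ALL_TYPES <- c("string", "integer", "float", "boolean", "subtree")

leaf_type <- function(v) {
  if (is.character(v)) "string"
  else if (is.integer(v)) "integer"
  else if (is.double(v)) "float"
  else if (is.logical(v)) "boolean"
  else NA_character_
}

#' Profile the field paths of a document stream
#'
#' Scans each document once, recording per dotted path: the multiset of
#' observed leaf/subtree types, whether the path was ever seen inside a
#' list, the number of documents containing it, and up to three distinct
#' example values. Memory use is constant in corpus size and linear in the
#' number of distinct paths.
#'
#' @param docs A list of documents or an iterator function (see
#'   [run_parser()]).
#' @return An `InspectionReport`: list with `paths` (path ->
#'   `TypeProfile`), `total_docs`, `conflict_paths` (paths observed as
#'   both subtree and scalar).
#' @export
#' @examples
#' rep <- inspect_documents(list(list(`_id` = "g1", alpha = list(taxid = 9606L))))
#' rep$paths[["alpha.taxid"]]$observed
inspect_documents <- function(docs) {
  it <- as_doc_iterator(docs)
  acc <- new.env(parent = emptyenv())
  total <- 0L
  repeat {
    doc <- it()
    if (is.null(doc)) break
    total <- total + 1L
    seen <- new.env(parent = emptyenv()) # paths in this document
    walk_node(doc, character(0), in_list = FALSE, acc = acc, seen = seen,
              top = TRUE)
    for (p in ls(seen)) {
      prof <- get(p, envir = acc)
      prof$doc_count <- prof$doc_count + 1L
      assign(p, prof, envir = acc)
    }
  }
  paths <- mget(ls(acc), envir = acc)
  paths <- paths[order(names(paths), method = "radix")]
  conflicts <- names(paths)[vapply(paths, function(p) {
    "subtree" %in% names(p$observed) &&
      any(setdiff(names(p$observed), "subtree") %in% ALL_TYPES)
  }, logical(1))]
  structure(list(paths = paths, total_docs = total,
                 conflict_paths = conflicts),
            class = "annohub_inspection")
}

observe <- function(acc, seen, path, type, in_list, example = NULL) {
  key <- paste(path, collapse = ".")
  prof <- if (exists(key, envir = acc, inherits = FALSE)) {
    get(key, envir = acc)
  } else {
    list(path = key, observed = integer(0), in_list = FALSE, doc_count = 0L,
         examples = list())
  }
  prof$observed[type] <- (if (is.na(prof$observed[type])) 0L
                          else prof$observed[[type]]) + 1L
  prof$in_list <- prof$in_list || in_list
  if (!is.null(example) && length(prof$examples) < 3L &&
      !any(vapply(prof$examples, identical, logical(1), y = example))) {
    prof$examples[[length(prof$examples) + 1L]] <- example
  }
  assign(key, prof, envir = acc)
  assign(key, TRUE, envir = seen)
  invisible(NULL)
}

walk_node <- function(node, path, in_list, acc, seen, top = FALSE) {
  if (is_subtree(node) || (is.list(node) && !is.null(names(node)))) {
    if (!top && length(path)) {
      observe(acc, seen, path, "subtree", in_list)
    }
    for (k in names(node)) {
      if (top && identical(k, "_id")) next
      walk_node(node[[k]], c(path, k), in_list = FALSE, acc = acc, seen = seen)
    }
    return(invisible(NULL))
  }
  if (is.list(node) || (is.atomic(node) && length(node) != 1L)) {
    for (el in as.list(node)) {
      walk_node(el, path, in_list = TRUE, acc = acc, seen = seen)
    }
    return(invisible(NULL))
  }
  t <- leaf_type(node)
  if (!is.na(t) && length(path)) {
    observe(acc, seen, path, t, in_list, example = node)
  }
  invisible(NULL)
}

#' Join observed type sets into a mapped index type
#'
#' The type lattice used for mapping generation: `{integer}` maps to
#' `integer`; `integer` with `float` maps to `float`; any set containing
#' `string` (without `subtree`) maps to `keyword`; `{boolean}` maps to
#' `boolean` but `boolean` mixed with anything else maps to `keyword`;
#' `{subtree}` maps to `object`; `subtree` mixed with any scalar is a
#' `conflict`.
#'
#' @param a,b Character vectors of observed types (subsets of
#'   `c("string","integer","float","boolean","subtree")`). `b` may be
#'   empty.
#' @return One of `"keyword"`, `"integer"`, `"float"`, `"boolean"`,
#'   `"object"`, `"conflict"`.
#' @export
#' @examples
#' join_types("integer", "float")    # "float"
#' join_types("integer", "string")   # "keyword"
#' join_types("subtree", "string")   # "conflict"
join_types <- function(a, b = character(0)) {
  s <- union(a, b)
  bad <- setdiff(s, ALL_TYPES)
  if (length(bad)) {
    stop(hub_error(sprintf("unknown type(s): %s", paste(bad, collapse = ", ")),
                   "annohub_contract_error"))
  }
  if (length(s) == 0L) return("conflict")
  has_sub <- "subtree" %in% s
  scalars <- setdiff(s, "subtree")
  if (has_sub && length(scalars)) return("conflict")
  if (has_sub) return("object")
  if ("string" %in% s) return("keyword")
  if ("boolean" %in% s) {
    return(if (length(s) == 1L) "boolean" else "keyword")
  }
  if (setequal(s, "integer")) return("integer")
  "float" # {float} or {integer, float}
}

#' Derive a typed index mapping from an inspection report
#'
#' Each non-conflict path is mapped through [join_types()] over its
#' observed type set; conflict paths (seen as both subtree and scalar) are
#' excluded with reason `"object/scalar conflict"` and are not queryable.
#'
#' @param report An [inspect_documents()] report.
#' @return An `annohub_mapping`: list with `types` (named character
#'   vector path -> type) and `excluded` (named character vector path ->
#'   reason).
#' @export
generate_mapping <- function(report) {
  types <- character(0)
  excluded <- character(0)
  for (p in names(report$paths)) {
    obs <- names(report$paths[[p]]$observed)
    t <- join_types(obs)
    if (t == "conflict") {
      excluded[p] <- "object/scalar conflict"
    } else {
      types[p] <- t
    }
  }
  structure(list(types = types, excluded = excluded),
            class = "annohub_mapping")
}

#' @export
print.annohub_mapping <- function(x, ...) {
  cat(sprintf("<mapping> %d path(s), %d excluded\n",
              length(x$types), length(x$excluded)))
  if (length(x$types)) {
    for (p in names(x$types)) cat(sprintf("  %s: %s\n", p, x$types[[p]]))
  }
  if (length(x$excluded)) {
    for (p in names(x$excluded)) cat(sprintf("  - %s (%s)\n", p, x$excluded[[p]]))
  }
  invisible(x)
}

#' Write a mapping as an Elasticsearch-7-style mapping file
#'
#' Leaf paths become `{"type": ...}` entries and object paths become
#' nested `{"properties": {...}}` blocks, so an external search-engine
#' adapter can consume the file unchanged. Excluded paths are recorded
#' under a top-level `"_excluded"` key.
#'
#' @param mapping An [generate_mapping()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mapping <- function(mapping, path) {
  props <- list()
  leaf_paths <- names(mapping$types)[mapping$types != "object"]
  for (p in leaf_paths) {
    segs <- split_path(p)
    props <- insert_property(props, segs, mapping$types[[p]])
  }
  # object paths with no mapped descendants still appear as empty blocks
  for (p in names(mapping$types)[mapping$types == "object"]) {
    segs <- split_path(p)
    props <- insert_property(props, segs, NULL)
  }
  out <- list(properties = props)
  if (length(mapping$excluded)) {
    out[["_excluded"]] <- lapply(as.list(mapping$excluded), identity)
  }
  writeLines(as.character(jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA,
                                           pretty = TRUE)), path)
  invisible(path)
}

insert_property <- function(props, segs, type) {
  k <- segs[[1]]
  if (length(segs) == 1L) {
    if (is.null(type)) {
      if (is.null(props[[k]])) props[[k]] <- list(properties = structure(list(), names = character(0)))
    } else {
      props[[k]] <- list(type = type)
    }
    return(props)
  }
  node <- props[[k]]
  if (is.null(node) || is.null(node$properties)) node <- list(properties = list())
  node$properties <- insert_property(node$properties, segs[-1L], type)
  props[[k]] <- node
  props
}

#' Read a mapping file written by [write_mapping()]
#'
#' @param path Path to the mapping JSON file.
#' @return An `annohub_mapping`.
#' @export
read_mapping <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  types <- character(0)
  flatten <- function(props, prefix) {
    for (k in names(props)) {
      node <- props[[k]]
      p <- if (nzchar(prefix)) paste0(prefix, ".", k) else k
      if (!is.null(node$type)) {
        types[p] <<- node$type
      }
      if (!is.null(node$properties)) {
        types[p] <<- "object"
        flatten(node$properties, p)
      }
    }
  }
  flatten(raw$properties, "")
  excluded <- character(0)
  for (k in names(raw[["_excluded"]])) excluded[k] <- raw[["_excluded"]][[k]]
  structure(list(types = types, excluded = excluded),
            class = "annohub_mapping")
}
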