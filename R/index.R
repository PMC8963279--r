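# Embedded inverted index. Only mapped paths are queryable; every stored
# document remains retrievable in full by `_id`, including unmapped
# fields — the indexed-versus-stored distinction is the point.
#
# Structures: docs (env id -> document), terms (env "path\x1fterm" ->
# character vector of ids), numerics (per-path list of ids + values for
# exact and range lookups), plus the mapping the index was built with.

#' Build an inverted index over a merged build
#'
#' Keyword terms are normalized to lowercase at index time; list values
#' index each element; numeric paths are indexed as numbers. Paths not in
#' the mapping are stored with the document but absent from every
#' inverted structure. A value typed contrary to the mapping (for example
#' a string where `integer` is mapped) does not fail the build: the
#' document is stored, the offending value is skipped, and the skip is
#' counted in the index's build report.
#'
#' @param build An `annohub_build` (from [run_build()] or [read_build()]),
#'   or a plain list of documents.
#' @param mapping An `annohub_mapping`.
#' @return An `annohub_index`.
#' @export
build_index <- function(build, mapping) {
  docs <- if (inherits(build, "annohub_build")) build$merged else build
  if (is.null(names(docs))) {
    names(docs) <- vapply(docs, function(d) d[["_id"]], character(1))
  }
  docs <- docs[order(names(docs), method = "radix")]
  doc_env <- new.env(parent = emptyenv())
  term_env <- new.env(parent = emptyenv())
  numerics <- list()
  mistyped <- 0L
  kw_paths <- names(mapping$types)[mapping$types %in% c("keyword", "boolean")]
  num_paths <- names(mapping$types)[mapping$types %in% c("integer", "float")]
  for (id in names(docs)) {
    assign(id, docs[[id]], envir = doc_env)
    doc <- docs[[id]]
    for (p in kw_paths) {
      vals <- path_values(doc, split_path(p))
      for (v in vals) {
        key <- paste0(p, "\x1f", scalar_term(v))
        prev <- if (exists(key, envir = term_env, inherits = FALSE)) {
          get(key, envir = term_env)
        } else character(0)
        if (!(id %in% prev)) assign(key, c(prev, id), envir = term_env)
      }
    }
    for (p in num_paths) {
      vals <- path_values(doc, split_path(p))
      for (v in vals) {
        if (!is.numeric(v)) { mistyped <- mistyped + 1L; next }
        slot <- numerics[[p]]
        if (is.null(slot)) slot <- list(ids = character(0), values = numeric(0))
        slot$ids <- c(slot$ids, id)
        slot$values <- c(slot$values, as.numeric(v))
        numerics[[p]] <- slot
      }
    }
  }
  metadata <- if (inherits(build, "annohub_build")) build$metadata else NULL
  structure(list(docs = doc_env, ids = names(docs), terms = term_env,
                 numerics = numerics, mapping = mapping,
                 metadata = metadata,
                 report = list(mistyped_values_skipped = mistyped)),
            class = "annohub_index")
}

#' @export
print.annohub_index <- function(x, ...) {
  cat(sprintf("<index> %d document(s), %d mapped path(s)\n",
              length(x$ids), length(x$mapping$types)))
  invisible(x)
}

#' Fetch one stored document by identifier
#'
#' Identifiers are case-sensitive. The stored document is returned in
#' full, unmapped fields included.
#'
#' @param index An `annohub_index`.
#' @param id Document identifier.
#' @return The document, or `NULL` when not found (not-found is a value,
#'   not an error).
#' @export
get_by_id <- function(index, id) {
  if (!is.character(id) || length(id) != 1L) return(NULL)
  if (!exists(id, envir = index$docs, inherits = FALSE)) return(NULL)
  get(id, envir = index$docs)
}

# Mapped type of a path, or NULL when the path is unmapped.
mapped_type <- function(mapping, path) {
  t <- unname(mapping$types[path])
  if (length(t) == 0L || is.na(t)) NULL else t
}

unqueryable <- function(path, why = "not in the index mapping") {
  hub_error(sprintf("unqueryable field: %s (%s)", path, why),
            "annohub_unqueryable", field = path)
}

keyword_paths <- function(index) {
  names(index$mapping$types)[index$mapping$types %in% c("keyword", "boolean")]
}

lookup_term <- function(index, path, term) {
  key <- paste0(path, "\x1f", term)
  if (exists(key, envir = index$terms, inherits = FALSE)) {
    get(key, envir = index$terms)
  } else character(0)
}

lookup_prefix <- function(index, path, prefix) {
  keys <- ls(index$terms)
  pre <- paste0(path, "\x1f", prefix)
  hit_keys <- keys[startsWith(keys, pre)]
  out <- list()
  for (k in hit_keys) out[[k]] <- get(k, envir = index$terms)
  out
}

empty_score <- function() setNames(integer(0), character(0))

# Evaluate an AST to a named integer vector: id -> score. The score is the
# number of primitive predicate matches (a Term searching p paths scores
# one per matching path), summed through And/Or; it drives the rank order.
eval_ast <- function(index, ast) {
  switch(ast$kind,
    term = {
      score <- empty_score()
      t <- tolower(ast$value)
      for (p in keyword_paths(index)) {
        ids <- lookup_term(index, p, t)
        score <- add_score(score, ids)
      }
      score
    },
    field_term = {
      p <- ast$path
      t <- mapped_type(index$mapping, p)
      if (is.null(t) || is.na(t)) stop(unqueryable(p))
      if (t %in% c("keyword", "boolean")) {
        add_score(empty_score(), lookup_term(index, p, tolower(ast$value)))
      } else if (t %in% c("integer", "float")) {
        num <- suppressWarnings(as.numeric(ast$value))
        slot <- index$numerics[[p]]
        if (is.na(num) || is.null(slot)) return(empty_score())
        add_score(empty_score(), unique(slot$ids[slot$values == num]))
      } else {
        stop(unqueryable(p, sprintf("mapped as %s, not a leaf type", t)))
      }
    },
    range = {
      p <- ast$path
      t <- mapped_type(index$mapping, p)
      if (is.null(t) || is.na(t)) stop(unqueryable(p))
      if (!(t %in% c("integer", "float"))) {
        stop(unqueryable(p, sprintf("range query on non-numeric type %s", t)))
      }
      slot <- index$numerics[[p]]
      if (is.null(slot)) return(empty_score())
      keep <- switch(ast$op,
                     ">" = slot$values > ast$number,
                     ">=" = slot$values >= ast$number,
                     "<" = slot$values < ast$number,
                     "<=" = slot$values <= ast$number)
      add_score(empty_score(), unique(slot$ids[keep]))
    },
    wildcard = {
      pre <- tolower(ast$prefix)
      paths <- if (is.null(ast$path)) keyword_paths(index) else {
        t <- mapped_type(index$mapping, ast$path)
        if (is.null(t) || is.na(t)) stop(unqueryable(ast$path))
        if (!(t %in% c("keyword", "boolean"))) {
          stop(unqueryable(ast$path, sprintf("wildcard on non-keyword type %s", t)))
        }
        ast$path
      }
      score <- empty_score()
      for (p in paths) {
        hits <- lookup_prefix(index, p, pre)
        ids <- unique(unlist(hits, use.names = FALSE))
        score <- add_score(score, ids)
      }
      score
    },
    and = {
      parts <- lapply(ast$children, function(ch) eval_ast(index, ch))
      ids <- Reduce(intersect, lapply(parts, names))
      if (length(ids) == 0L) return(empty_score())
      total <- setNames(integer(length(ids)), ids)
      for (p in parts) total[ids] <- total[ids] + p[ids]
      total
    },
    or = {
      parts <- lapply(ast$children, function(ch) eval_ast(index, ch))
      ids <- unique(unlist(lapply(parts, names), use.names = FALSE))
      if (length(ids) == 0L) return(empty_score())
      total <- setNames(integer(length(ids)), ids)
      for (p in parts)

        if (length(p)) total[names(p)] <- total[names(p)] + p
      total
    },
    stop(hub_error(sprintf("unknown AST node kind: %s", ast$kind),
                   "annohub_contract_error"))
  )
}

add_score <- function(score, ids) {
  if (length(ids) == 0L) return(score)
  new_ids <- setdiff(ids, names(score))
  if (length(new_ids)) score[new_ids] <- 0L
  score[ids] <- score[ids] + 1L
  score
}

#' Execute a parsed query against an index
#'
#' Bare terms search every keyword-mapped path; matching is
#' case-insensitive exact (prefix for wildcards); `AND` intersects and
#' `OR` unions matching id sets. Rank order is fully deterministic:
#' descending per-document match count, ties broken by ascending `_id`.
#' Fielded queries on unmapped (or wrongly typed) paths raise an
#' `annohub_unqueryable` error rather than silently matching nothing.
#'
#' @param index An `annohub_index`.
#' @param ast A [parse_query()] result (a query string is also accepted).
#' @param from Zero-based offset of the first hit (default 0).
#' @param size Page size, 0 to 1000 (default 10). `size = 0` returns a
#'   count-only result.
#' @param fields Projection applied to each hit (see [project_fields()]).
#' @return A `QueryResult`: list with `total`, `hits` (projected
#'   documents), `from`, `size`.
#' @export
execute_query <- function(index, ast, from = 0L, size = 10L, fields = "all") {
  if (is.character(ast)) ast <- parse_query(ast)
  if (!is.numeric(from) || length(from) != 1L || is.na(from) || from < 0) {
    stop(hub_error("`from` must be a non-negative integer", "annohub_request_error"))
  }
  if (!is.numeric(size) || length(size) != 1L || is.na(size) || size < 0) {
    stop(hub_error("`size` must be a non-negative integer", "annohub_request_error"))
  }
  if (size > 1000) {
    stop(hub_error("`size` exceeds the cap of 1000", "annohub_request_error"))
  }
  from <- as.integer(from)
  size <- as.integer(size)
  score <- eval_ast(index, ast)
  ids <- names(score) %||% character(0)
  ord <- order(-as.integer(score), ids, method = "radix")
  ranked <- ids[ord]
  total <- length(ranked)
  page <- if (from >= total || size == 0L) character(0) else {
    ranked[seq.int(from + 1L, min(from + size, total))]
  }
  hits <- lapply(page, function(id) project_fields(get_by_id(index, id), fields))
  structure(list(total = total, hits = hits, from = from, size = size),
            class = "annohub_query_result")
}

#' @export
print.annohub_query_result <- function(x, ...) {
  cat(sprintf("<query result> total %d, showing %d (from %d)\n",
              x$total, length(x$hits), x$from))
  invisible(x)
}

#' Persist an index beside its build
#'
#' The on-disk layout under `.../index/` is private to this backend and
#' not portable across versions.
#'
#' @param index An `annohub_index`.
#' @param dir Output directory (conventionally
#'   `<data_root>/builds/<build_version>/index`).
#' @return `dir`, invisibly.
#' @export
index_save <- function(index, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  docs <- mget(index$ids, envir = index$docs)
  write_jsonl(docs, file.path(dir, "docs.jsonl"))
  term_keys <- sort(ls(index$terms), method = "radix")
  terms <- lapply(term_keys, function(k) {
    bits <- strsplit(k, "\x1f", fixed = TRUE)[[1]]
    list(path = bits[1], term = paste(bits[-1], collapse = "\x1f"),
         ids = as.list(get(k, envir = index$terms)))
  })
  payload <- list(
    terms = terms,
    numerics = lapply(index$numerics, function(s) {
      list(ids = as.list(s$ids), values = as.list(s$values))
    }),
    mapping = list(types = as.list(index$mapping$types),
                   excluded = as.list(index$mapping$excluded)),
    metadata = index$metadata,
    report = index$report
  )
  writeLines(as.character(jsonlite::toJSON(payload, auto_unbox = TRUE,
                                           digits = NA, null = "null")),
             file.path(dir, "index.json"))
  invisible(dir)
}

#' Load an index persisted by [index_save()]
#'
#' @param dir The index directory.
#' @return An `annohub_index`.
#' @export
index_load <- function(dir) {
  docs <- read_jsonl(file.path(dir, "docs.jsonl"))
  names(docs) <- vapply(docs, function(d) d[["_id"]], character(1))
  raw <- jsonlite::fromJSON(file.path(dir, "index.json"), simplifyVector = FALSE)
  doc_env <- new.env(parent = emptyenv())
  for (id in names(docs)) assign(id, docs[[id]], envir = doc_env)
  term_env <- new.env(parent = emptyenv())
  for (t in raw$terms) {
    assign(paste0(t$path, "\x1f", t$term),
           vapply(t$ids, as.character, character(1)), envir = term_env)
  }
  numerics <- lapply(raw$numerics, function(s) {
    list(ids = vapply(s$ids, as.character, character(1)),
         values = vapply(s$values, as.numeric, numeric(1)))
  })
  mapping <- structure(list(
    types = unlist(lapply(raw$mapping$types, as.character)) %||% character(0),
    excluded = unlist(lapply(raw$mapping$excluded, as.character)) %||% character(0)
  ), class = "annohub_mapping")
  structure(list(docs = doc_env, ids = names(docs), terms = term_env,
                 numerics = numerics, mapping = mapping,
                 metadata = raw$metadata, report = raw$report),
            class = "annohub_index")
}
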