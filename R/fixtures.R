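# Deterministic synthetic data sources with controlled identifier overlap
# and type pathologies, plus ground-truth calculators, so every hub stage
# is testable offline. Each generated source is a complete plugin
# directory (manifest.json + parser.R + payload) dogfooding the registry.

#' Describe a synthetic fixture
#'
#' @param seed Integer master seed; the same `(seed, spec)` pair always
#'   yields byte-identical generated files.
#' @param sources A list of per-source recipes, each a list with: `name`;
#'   `format` (`"tsv"`, `"csv"` or `"jsonl"`); `n_docs`; `id_offset`
#'   (position of the source's first id in the shared `g<number>` pool,
#'   so overlapping ranges produce overlapping id sets); optional
#'   `nested_depth` (0-3, default 0), `list_field` (logical, default
#'   FALSE; jsonl only), `mixed_type_prob` (probability a numeric field
#'   value is emitted as a float or string instead of an integer, default
#'   0), `conflict` (logical, default FALSE: inject an object/scalar
#'   conflict on the path `extra`; jsonl only).
#' @return An `annohub_fixture_spec`.
#' @export
fixture_spec <- function(seed, sources) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  sources <- lapply(sources, function(s) {
    stopifnot(!is.null(s$name), !is.null(s$format), !is.null(s$n_docs))
    s$id_offset <- s$id_offset %||% 0L
    s$nested_depth <- s$nested_depth %||% 0L
    s$list_field <- isTRUE(s$list_field)
    s$mixed_type_prob <- s$mixed_type_prob %||% 0
    s$conflict <- isTRUE(s$conflict)
    s
  })
  structure(list(seed = as.integer(seed), sources = sources),
            class = "annohub_fixture_spec")
}

fixture_ids <- function(s) {
  sprintf("g%04d", seq.int(s$id_offset + 1L, s$id_offset + s$n_docs))
}

# Counter-based value generation: every random draw is a pure function of
# (seed, source name, doc ordinal, field), so regenerating any subset of
# sources is stable.
fx_unit <- function(seed, ...) {
  h <- digest::digest(paste(seed, ..., sep = "|"), algo = "crc32", serialize = FALSE)
  strtoi(substr(h, 1, 7), base = 16L) / 16^7
}

fx_word <- function(seed, ...) {
  syll <- c("ka", "re", "mi", "to", "su", "ne", "va", "lo", "dri", "pax")
  u <- fx_unit(seed, ..., "w")
  n <- 2L + (floor(u * 997) %% 3L)
  idx <- vapply(seq_len(n), function(i) {
    1L + as.integer(floor(fx_unit(seed, ..., "w", i) * 10)) %% 10L
  }, integer(1))
  paste(syll[idx], collapse = "")
}

fx_doc <- function(spec, s, ord, id) {
  seed <- spec$seed
  u <- fx_unit(seed, s$name, ord, "score")
  doc <- list(`_id` = id,
              symbol = toupper(fx_word(seed, s$name, ord, "sym")),
              taxid = 9000L + as.integer(floor(u * 1e6)) %% 1000L)
  mt <- fx_unit(seed, s$name, ord, "mixed")
  if (s$mixed_type_prob > 0 && mt < s$mixed_type_prob) {
    # emit the numeric field as float or string, to exercise type joins
    doc$taxid <- if (mt < s$mixed_type_prob / 2) {
      as.numeric(doc$taxid) + 0.5
    } else {
      as.character(doc$taxid)
    }
  }
  if (s$nested_depth >= 1L) {
    node <- list(level = s$nested_depth,
                 label = fx_word(seed, s$name, ord, "leaf"))
    d <- s$nested_depth - 1L
    while (d >= 1L) {
      node <- setNames(list(node), paste0("lvl", d))
      node$tag <- fx_word(seed, s$name, ord, "tag", d)
      d <- d - 1L
    }
    doc$nested <- node
  }
  if (s$list_field) {
    n <- 1L + as.integer(floor(fx_unit(seed, s$name, ord, "ln") * 3)) %% 3L
    doc$tags <- lapply(seq_len(n), function(i) fx_word(seed, s$name, ord, "tagv", i))
  }
  if (s$conflict) {
    # alternate scalar / subtree occurrences of the same path
    doc$extra <- if (ord %% 2L == 1L) "flat" else list(note = "deep")
  }
  doc
}

fx_manifest <- function(name, payload_file, format) {
  list(name = name,
       location = paste0("file://", payload_file),
       parser_ref = "parser:parse",
       metadata = list(description = sprintf("synthetic %s source", format)))
}

fx_parser_code <- function(format) {
  body <- switch(format,
    tsv = ,
    csv = sprintf('
parse <- function(dump_folder) {
  f <- list.files(dump_folder, pattern = "\\\\.%s$", full.names = TRUE)[1]
  tab <- utils::read.delim(f, sep = "%s", stringsAsFactors = FALSE,
                           colClasses = "character")
  docs <- lapply(seq_len(nrow(tab)), function(i) {
    row <- as.list(tab[i, , drop = FALSE])
    doc <- list(`_id` = row[["X_id"]] %%||%% row[["_id"]])
    for (k in setdiff(names(row), c("X_id", "_id"))) {
      v <- row[[k]]
      doc[[k]] <- if (grepl("^-?[0-9]+$", v)) as.integer(v) else
        if (grepl("^-?[0-9]*\\\\.[0-9]+$", v)) as.numeric(v) else v
    }
    doc
  })
  docs
}
`%%||%%` <- function(a, b) if (is.null(a)) b else a
', format, if (format == "tsv") "\\t" else ","),
    jsonl = '
parse <- function(dump_folder) {
  f <- list.files(dump_folder, pattern = "\\\\.jsonl$", full.names = TRUE)[1]
  lines <- readLines(f, warn = FALSE)
  lapply(lines[nzchar(lines)], jsonlite::fromJSON, simplifyVector = FALSE)
}
')
  body
}

write_fx_payload <- function(docs, path, format) {
  if (format == "jsonl") {
    write_jsonl(docs, path)
    return(invisible(path))
  }
  sep <- if (format == "tsv") "\t" else ","
  cols <- unique(unlist(lapply(docs, names)))
  lines <- c(paste(cols, collapse = sep),
             vapply(docs, function(d) {
               paste(vapply(cols, function(k) {
                 v <- d[[k]]
                 if (is.null(v)) "" else as.character(v)
               }, character(1)), collapse = sep)
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Generate synthetic data-source plugins with ground truth
#'
#' Writes, for every source in the spec, a plugin directory
#' `<out_dir>/<name>/` containing `manifest.json`, `parser.R` and a
#' payload directory `<out_dir>/<name>/payload/` the manifest points at.
#' Returns truth tables computed during generation (never by re-parsing
#' the files).
#'
#' @param spec An [fixture_spec()].
#' @param out_dir Output directory (created).
#' @return A `FixtureTruth`: `id_sets` (per source), `union_ids`,
#'   `intersection_ids`, `merged_ids(root_sources)` closure, `docs` (the
#'   generated documents per source), `conflict_paths`, `plugin_dirs`.
#' @export
generate_fixture <- function(spec, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  id_sets <- list()
  docs_by_source <- list()
  plugin_dirs <- character(0)
  conflict_paths <- character(0)
  for (s in spec$sources) {
    ids <- fixture_ids(s)
    docs <- lapply(seq_along(ids), function(i) fx_doc(spec, s, i, ids[[i]]))
    pdir <- file.path(out_dir, s$name)
    pay <- file.path(pdir, "payload")
    dir.create(pay, recursive = TRUE, showWarnings = FALSE)
    payload_file <- file.path(pay, paste0("data.", s$format))
    write_fx_payload(docs, payload_file, s$format)
    writeLines(as.character(jsonlite::toJSON(
      fx_manifest(s$name, normalizePath(pay), s$format),
      auto_unbox = TRUE, digits = NA)), file.path(pdir, "manifest.json"))
    writeLines(fx_parser_code(s$format), file.path(pdir, "parser.R"))
    id_sets[[s$name]] <- ids
    docs_by_source[[s$name]] <- setNames(docs, ids)
    plugin_dirs[s$name] <- pdir
    if (s$conflict && s$n_docs >= 2L) conflict_paths <- union(conflict_paths, "extra")
  }
  union_ids <- sort(unique(unlist(id_sets, use.names = FALSE)), method = "radix")
  inter <- Reduce(intersect, id_sets)
  merged_ids <- function(root_sources = character(0)) {
    if (length(root_sources) == 0L) return(union_ids)
    sort(intersect(union_ids,
                   unique(unlist(id_sets[root_sources], use.names = FALSE))),
         method = "radix")
  }
  structure(list(id_sets = id_sets, union_ids = union_ids,
                 intersection_ids = inter, merged_ids = merged_ids,
                 docs = docs_by_source, conflict_paths = conflict_paths,
                 plugin_dirs = plugin_dirs),
            class = "annohub_fixture_truth")
}

#' The canonical two-source demonstration fixture
#'
#' Source `alpha` (TSV): `g1 {symbol:"CDK2", taxid:9606}`,
#' `g2 {symbol:"TP53", taxid:9606}`. Source `beta` (JSON lines):
#' `g1 {pathway:["cell_cycle","dna_repair"]}`, `g3 {pathway:["apoptosis"]}`.
#' Their id sets overlap only on `g1`, so a build rooted on `alpha` merges
#' `{g1, g2}` and root-excludes `g3`.
#'
#' @param out_dir Directory the two plugin directories are written into.
#' @return A `FixtureTruth` as in [generate_fixture()].
#' @export
fixture_fix1 <- function(out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  alpha_docs <- list(
    g1 = list(`_id` = "g1", symbol = "CDK2", taxid = 9606L),
    g2 = list(`_id` = "g2", symbol = "TP53", taxid = 9606L)
  )
  beta_docs <- list(
    g1 = list(`_id` = "g1", pathway = list("cell_cycle", "dna_repair")),
    g3 = list(`_id` = "g3", pathway = list("apoptosis"))
  )
  plugin_dirs <- character(0)
  for (src in list(list(name = "alpha", docs = alpha_docs, format = "tsv"),
                   list(name = "beta", docs = beta_docs, format = "jsonl"))) {
    pdir <- file.path(out_dir, src$name)
    pay <- file.path(pdir, "payload")
    dir.create(pay, recursive = TRUE, showWarnings = FALSE)
    write_fx_payload(unname(src$docs), file.path(pay, paste0("data.", src$format)),
                     src$format)
    writeLines(as.character(jsonlite::toJSON(
      fx_manifest(src$name, normalizePath(pay), src$format),
      auto_unbox = TRUE, digits = NA)), file.path(pdir, "manifest.json"))
    writeLines(fx_parser_code(src$format), file.path(pdir, "parser.R"))
    plugin_dirs[src$name] <- pdir
  }
  id_sets <- list(alpha = c("g1", "g2"), beta = c("g1", "g3"))
  union_ids <- c("g1", "g2", "g3")
  merged_ids <- function(root_sources = character(0)) {
    if (length(root_sources) == 0L) return(union_ids)
    sort(intersect(union_ids,
                   unique(unlist(id_sets[root_sources], use.names = FALSE))),
         method = "radix")
  }
  structure(list(id_sets = id_sets, union_ids = union_ids,
                 intersection_ids = "g1", merged_ids = merged_ids,
                 docs = list(alpha = alpha_docs, beta = beta_docs),
                 conflict_paths = character(0), plugin_dirs = plugin_dirs),
            class = "annohub_fixture_truth")
}

# ---------------------------------------------------------------------------
# Brute-force query referee: evaluates an AST per document by recursive
# scan, with no index. Shares the engine's matching semantics (lowercase
# exact keyword matching, numeric comparison, unqueryable-field errors
# driven by the supplied mapping) but none of its machinery.

#' Evaluate a query over raw documents by linear scan
#'
#' The independent referee for the query engine's oracle-equivalence
#' property: no inverted structure is consulted, every document is
#' scanned recursively.
#'
#' @param docs A list of documents.
#' @param ast A [parse_query()] result (or query string).
#' @param mapping An `annohub_mapping` governing which paths are
#'   queryable; fielded queries on unmapped paths raise the same
#'   `annohub_unqueryable` error as the engine.
#' @return Sorted character vector of matching `_id`s.
#' @export
oracle_query <- function(docs, ast, mapping) {
  if (is.character(ast)) ast <- parse_query(ast)
  if (is.null(names(docs)) && length(docs)) {
    names(docs) <- vapply(docs, function(d) d[["_id"]], character(1))
  }
  kw <- names(mapping$types)[mapping$types %in% c("keyword", "boolean")]
  hit <- vapply(docs, function(d) oracle_match(d, ast, mapping, kw), logical(1))
  sort(names(docs)[hit], method = "radix")
}

oracle_match <- function(doc, ast, mapping, kw) {
  switch(ast$kind,
    term = {
      t <- tolower(ast$value)
      any(vapply(kw, function(p) {
        any(vapply(path_values(doc, split_path(p)),
                   function(v) identical(scalar_term(v), t), logical(1)))
      }, logical(1)))
    },
    field_term = {
      ty <- mapped_type(mapping, ast$path)
      if (is.null(ty) || is.na(ty)) stop(unqueryable(ast$path))
      vals <- path_values(doc, split_path(ast$path))
      if (ty %in% c("keyword", "boolean")) {
        t <- tolower(ast$value)
        any(vapply(vals, function(v) identical(scalar_term(v), t), logical(1)))
      } else if (ty %in% c("integer", "float")) {
        num <- suppressWarnings(as.numeric(ast$value))
        if (is.na(num)) return(FALSE)
        any(vapply(vals, function(v) is.numeric(v) && as.numeric(v) == num,
                   logical(1)))
      } else {
        stop(unqueryable(ast$path, sprintf("mapped as %s, not a leaf type", ty)))
      }
    },
    range = {
      ty <- mapped_type(mapping, ast$path)
      if (is.null(ty) || is.na(ty)) stop(unqueryable(ast$path))
      if (!(ty %in% c("integer", "float"))) {
        stop(unqueryable(ast$path, sprintf("range query on non-numeric type %s", ty)))
      }
      vals <- path_values(doc, split_path(ast$path))
      cmp <- switch(ast$op, ">" = `>`, ">=" = `>=`, "<" = `<`, "<=" = `<=`)
      any(vapply(vals, function(v) is.numeric(v) && cmp(as.numeric(v), ast$number),
                 logical(1)))
    },
    wildcard = {
      pre <- tolower(ast$prefix)
      paths <- if (is.null(ast$path)) kw else {
        ty <- mapped_type(mapping, ast$path)
        if (is.null(ty) || is.na(ty)) stop(unqueryable(ast$path))
        if (!(ty %in% c("keyword", "boolean"))) {
          stop(unqueryable(ast$path, sprintf("wildcard on non-keyword type %s", ty)))
        }
        ast$path
      }
      any(vapply(paths, function(p) {
        any(vapply(path_values(doc, split_path(p)),
                   function(v) startsWith(scalar_term(v), pre), logical(1)))
      }, logical(1)))
    },
    and = all(vapply(ast$children, function(ch) oracle_match(doc, ch, mapping, kw),
                     logical(1))),
    or = any(vapply(ast$children, function(ch) oracle_match(doc, ch, mapping, kw),
                    logical(1))),
    stop(hub_error(sprintf("unknown AST node kind: %s", ast$kind),
                   "annohub_contract_error"))
  )
}
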