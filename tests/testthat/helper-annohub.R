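# Shared test helpers: temp hubs, tiny plugin builders, random document
# corpora, and independent brute-force oracles kept deliberately separate
# from the package's own code paths.

tmp_dir <- function(prefix = "annohub-test") {
  d <- tempfile(prefix)
  dir.create(d, recursive = TRUE)
  d
}

# Write a plugin directory by hand (manifest + parser + payload) without
# going through the fixture generator.
make_plugin <- function(dir, name, docs, schedule = NULL, priority = NULL,
                        parser_body = NULL) {
  pdir <- file.path(dir, name)
  pay <- file.path(pdir, "payload")
  dir.create(pay, recursive = TRUE, showWarnings = FALSE)
  annohub::write_jsonl(docs, file.path(pay, "data.jsonl"))
  manifest <- list(name = name,
                   location = paste0("file://", normalizePath(pay)),
                   parser_ref = "parser:parse")
  if (!is.null(schedule)) manifest$schedule <- schedule
  if (!is.null(priority)) manifest$priority <- priority
  writeLines(as.character(jsonlite::toJSON(manifest, auto_unbox = TRUE)),
             file.path(pdir, "manifest.json"))
  if (is.null(parser_body)) {
    parser_body <- '
parse <- function(dump_folder) {
  f <- list.files(dump_folder, pattern = "\\\\.jsonl$", full.names = TRUE)[1]
  lapply(readLines(f, warn = FALSE), jsonlite::fromJSON, simplifyVector = FALSE)
}
'
  }
  writeLines(parser_body, file.path(pdir, "parser.R"))
  pdir
}

# Run the FIX1 pipeline (register -> dump -> upload x2 -> build -> inspect
# -> index) inside a fresh temp hub; returns everything the tests poke at.
fix1_pipeline <- function(root_sources = "alpha", mapping = NULL) {
  root <- tmp_dir("hub")
  fxd <- tmp_dir("fx")
  truth <- annohub::fixture_fix1(fxd)
  reg <- annohub::registry()
  for (p in truth$plugin_dirs) {
    reg <- annohub::register_source(reg, annohub::load_manifest(p))
  }
  store <- annohub::doc_store_jsonl(root)
  for (nm in annohub::registry_names(reg)) {
    d <- annohub::registry_get(reg, nm)
    res <- annohub::dump_source(d, root)
    annohub::upload_source(d, res$release, store, root)
  }
  cfg <- annohub::build_config("fixdemo", c("alpha", "beta"),
                               root_sources = root_sources)
  build <- annohub::run_build(cfg, store, data_root = root, registry = reg)
  report <- annohub::inspect_documents(unname(build$merged))
  if (is.null(mapping)) mapping <- annohub::generate_mapping(report)
  index <- annohub::build_index(build, mapping)
  list(root = root, truth = truth, registry = reg, store = store,
       config = cfg, build = build, report = report, mapping = mapping,
       index = index)
}

# --- independent oracles ----------------------------------------------------

# Recursive path enumeration, written independently of the inspector's
# streaming accumulator: returns the sorted set of dotted paths (leaves
# and subtrees), `_id` excluded, lists transparent.
oracle_enum_paths <- function(docs) {
  paths <- character(0)
  rec <- function(x, prefix) {
    if (is.list(x) && !is.null(names(x)) && all(nzchar(names(x)))) {
      if (nzchar(prefix)) paths <<- c(paths, prefix)
      for (k in names(x)) {
        rec(x[[k]], if (nzchar(prefix)) paste(prefix, k, sep = ".") else k)
      }
    } else if (is.list(x)) {
      for (el in x) rec(el, prefix)
    } else if (is.atomic(x) && nzchar(prefix)) {
      paths <<- c(paths, prefix)
    }
  }
  for (d in docs) {
    d[["_id"]] <- NULL
    rec(d, "")
  }
  sort(unique(paths), method = "radix")
}

# Set-algebra referee for build membership: scans the stored documents.
oracle_merged_ids <- function(store, sources, releases, root_sources) {
  ids <- lapply(seq_along(sources), function(i) {
    names(annohub::store_docs(store, sources[[i]], releases[[i]]))
  })
  names(ids) <- sources
  all_ids <- Reduce(union, ids)
  keep <- if (length(root_sources) == 0L) all_ids else {
    intersect(all_ids, Reduce(union, ids[root_sources]))
  }
  sort(keep, method = "radix")
}

# --- random generators ------------------------------------------------------

rand_word <- function(n = 1L) {
  vapply(seq_len(n), function(i) {
    paste(sample(letters, sample(3:8, 1), replace = TRUE), collapse = "")
  }, character(1))
}

# A random annotation corpus with nesting, lists and numeric fields;
# returns named list of documents keyed by `_id`.
gen_random_docs <- function(n, p_nested = 0.5, p_list = 0.5) {
  vocab <- rand_word(12)
  docs <- lapply(seq_len(n), function(i) {
    doc <- list(`_id` = sprintf("g%04d", i),
                symbol = toupper(sample(vocab, 1)),
                score = sample(1:500, 1))
    if (stats::runif(1) < 0.5) doc$flag <- sample(c(TRUE, FALSE), 1)
    if (stats::runif(1) < p_nested) {
      doc$info <- list(label = sample(vocab, 1),
                       depth = list(value = stats::runif(1) * 10))
    }
    if (stats::runif(1) < p_list) {
      doc$tags <- as.list(sample(vocab, sample(1:3, 1)))
    }
    doc
  })
  names(docs) <- vapply(docs, `[[`, character(1), "_id")
  docs
}

# A random query AST over the mapped paths of a corpus: depth <= 3,
# leaves reference values that exist (mostly) so hit sets are non-trivial.
gen_random_ast <- function(mapping, docs, depth = 3L) {
  kw <- names(mapping$types)[mapping$types %in% c("keyword", "boolean")]
  num <- names(mapping$types)[mapping$types %in% c("integer", "float")]
  pick_value <- function(path) {
    vals <- unlist(lapply(docs, function(d) {
      vapply(annohub:::path_values(d, strsplit(path, ".", fixed = TRUE)[[1]]),
             function(v) as.character(v), character(1))
    }), use.names = FALSE)
    if (length(vals) == 0L || stats::runif(1) < 0.15) rand_word(1) else sample(vals, 1)
  }
  leaf <- function() {
    kind <- sample(c("term", "field", "range", "wild"), 1,
                   prob = c(0.3, 0.3, if (length(num)) 0.2 else 0, 0.2))
    if (kind == "term") {
      p <- sample(kw, 1)
      list(kind = "term", value = pick_value(p))
    } else if (kind == "field") {
      p <- sample(kw, 1)
      list(kind = "field_term", path = p, value = pick_value(p))
    } else if (kind == "range") {
      p <- sample(num, 1)
      list(kind = "range", path = p, op = sample(c(">", ">=", "<", "<="), 1),
           number = sample(1:500, 1))
    } else {
      p <- sample(kw, 1)
      v <- pick_value(p)
      list(kind = "wildcard",
           path = if (stats::runif(1) < 0.5) p else NULL,
           prefix = substr(v, 1, max(1L, nchar(v) - 2L)))
    }
  }
  build <- function(d) {
    if (d <= 1L || stats::runif(1) < 0.4) return(leaf())
    op <- sample(c("and", "or"), 1)
    k <- sample(2:3, 1)
    list(kind = op, children = lapply(seq_len(k), function(i) build(d - 1L)))
  }
  build(depth)
}
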