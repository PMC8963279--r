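fix1_index <- function(root_sources = "alpha") {
  docs <- list(
    g1 = list(`_id` = "g1", alpha = list(symbol = "CDK2", taxid = 9606L),
              beta = list(pathway = list("cell_cycle", "dna_repair"))),
    g2 = list(`_id` = "g2", alpha = list(symbol = "TP53", taxid = 9606L))
  )
  if (length(root_sources) == 0) {
    docs$g3 <- list(`_id` = "g3", beta = list(pathway = list("apoptosis")))
    docs <- docs[c("g1", "g2", "g3")]
  }
  mapping <- generate_mapping(inspect_documents(unname(docs)))
  list(docs = docs, mapping = mapping, index = build_index(docs, mapping))
}

test_that("term lookup over the canonical fixture matches the hand-derived postings", {
  fx <- fix1_index()
  expect_identical(annohub:::lookup_term(fx$index, "alpha.symbol", "cdk2"), "g1")
  r <- execute_query(fx$index, "cdk2")
  expect_identical(r$total, 1L)
  expect_identical(r$hits[[1]][["_id"]], "g1")
  # list values index each element
  expect_identical(execute_query(fx$index, "apoptosis")$total, 0L)
  expect_identical(execute_query(fx$index, "dna_repair")$total, 1L)
})

test_that("numeric ranges rank by match count with ascending-id tie-break", {
  fx <- fix1_index()
  r <- execute_query(fx$index, "alpha.taxid:>9000")
  expect_identical(r$total, 2L)
  expect_identical(vapply(r$hits, `[[`, character(1), "_id"), c("g1", "g2"))
  expect_identical(execute_query(fx$index, "alpha.taxid:>9606")$total, 0L)
  expect_identical(execute_query(fx$index, "alpha.taxid:>=9606")$total, 2L)
  expect_identical(execute_query(fx$index, "alpha.taxid:9606")$total, 2L)
})

test_that("count-only queries return the total with no hits", {
  fx <- fix1_index()
  r <- execute_query(fx$index, "alpha.taxid:9606", from = 0, size = 0)
  expect_identical(r$total, 2L)
  expect_length(r$hits, 0)
})

test_that("fielded queries on unmapped paths error rather than matching nothing", {
  fx <- fix1_index()
  err <- expect_error(execute_query(fx$index, "beta.notes:x"),
                      class = "annohub_unqueryable")
  expect_identical(err$field, "beta.notes")
  # range on a keyword-mapped path is mistyped
  expect_error(execute_query(fx$index, "alpha.symbol:>5"),
               class = "annohub_unqueryable")
  # fielded query on an object-mapped path
  expect_error(execute_query(fx$index, "alpha:x"),
               class = "annohub_unqueryable")
  # bare terms never error: they search only keyword paths
  expect_identical(execute_query(fx$index, "zzz")$total, 0L)
})

test_that("every mapped leaf path is queryable; every unmapped one is not", {
  fx <- fix1_index()
  for (p in names(fx$mapping$types)) {
    t <- fx$mapping$types[[p]]
    if (t == "object") next
    expect_no_error(execute_query(fx$index, paste0(p, ":whatever")))
  }
  expect_error(execute_query(fx$index, "not.a.path:x"),
               class = "annohub_unqueryable")
})

test_that("size and from are validated with the documented cap", {
  fx <- fix1_index()
  expect_error(execute_query(fx$index, "cdk2", size = 2000),
               class = "annohub_request_error")
  expect_error(execute_query(fx$index, "cdk2", from = -1),
               class = "annohub_request_error")
  expect_no_error(execute_query(fx$index, "cdk2", size = 1000))
})

test_that("get_by_id is byte-exact and case-sensitive; misses are values", {
  fx <- fix1_index()
  expect_identical(doc_to_json(get_by_id(fx$index, "g1")),
                   doc_to_json(fx$docs$g1))
  expect_null(get_by_id(fx$index, "g9"))
  expect_null(get_by_id(fx$index, "G1"))
})

test_that("an empty build indexes cleanly and answers total = 0", {
  idx <- build_index(list(), structure(list(types = character(0),
                                            excluded = character(0)),
                                       class = "annohub_mapping"))
  expect_identical(execute_query(idx, "anything")$total, 0L)
})

test_that("engine matching equals the linear-scan oracle on random corpora and ASTs", {
  set.seed(21)
  for (corpus_i in 1:5) {
    docs <- gen_random_docs(sample(20:80, 1))
    mapping <- generate_mapping(inspect_documents(unname(docs)))
    idx <- build_index(docs, mapping)
    for (ast_i in 1:20) {
      ast <- gen_random_ast(mapping, docs)
      got <- sort(names(annohub:::eval_ast(idx, ast)), method = "radix")
      want <- oracle_query(unname(docs), ast, mapping)
      expect_identical(got, want)
    }
  }
})

test_that("pagination pages concatenate to the full ranked list exactly once", {
  set.seed(33)
  docs <- gen_random_docs(60)
  mapping <- generate_mapping(inspect_documents(unname(docs)))
  idx <- build_index(docs, mapping)
  ast <- parse_query("score:>0") # matches most documents
  full <- execute_query(idx, ast, from = 0, size = 1000)
  full_ids <- vapply(full$hits, `[[`, character(1), "_id")
  for (k in c(1L, 3L, 7L, 50L)) {
    pages <- character(0)
    from <- 0L
    repeat {
      page <- execute_query(idx, ast, from = from, size = k)
      expect_identical(page$total, full$total)
      if (length(page$hits) == 0) break
      pages <- c(pages, vapply(page$hits, `[[`, character(1), "_id"))
      from <- from + k
    }
    expect_identical(pages, full_ids)
  }
})

test_that("identical inputs give identical results across repeated runs", {
  set.seed(44)
  docs <- gen_random_docs(40)
  mapping <- generate_mapping(inspect_documents(unname(docs)))
  idx1 <- build_index(docs, mapping)
  idx2 <- build_index(docs, mapping)
  q <- "symbol:a* OR score:<=250"
  r1 <- execute_query(idx1, q, from = 2, size = 5)
  r2 <- execute_query(idx2, q, from = 2, size = 5)
  expect_identical(r1, r2)
})

test_that("values typed contrary to the mapping are stored but not indexed", {
  docs <- list(
    g1 = list(`_id` = "g1", taxid = 9606L),
    g2 = list(`_id` = "g2", taxid = "not-a-number")
  )
  mapping <- structure(list(types = c(taxid = "integer"),
                            excluded = character(0)),
                       class = "annohub_mapping")
  idx <- build_index(docs, mapping)
  expect_identical(idx$report$mistyped_values_skipped, 1L)
  # the document itself is stored byte-exact
  expect_identical(doc_to_json(get_by_id(idx, "g2")), doc_to_json(docs$g2))
  # and invisible to numeric queries
  expect_identical(execute_query(idx, "taxid:>0")$total, 1L)
})

test_that("a persisted index reloads with identical query behavior", {
  set.seed(55)
  docs <- gen_random_docs(25)
  mapping <- generate_mapping(inspect_documents(unname(docs)))
  idx <- build_index(docs, mapping)
  dir <- tmp_dir()
  index_save(idx, dir)
  back <- index_load(dir)
  for (q in c("score:>100", "symbol:a*", "tags:xyz OR score:<=50")) {
    a <- execute_query(back, q)
    b <- execute_query(idx, q)
    expect_identical(a[c("total", "from", "size")], b[c("total", "from", "size")])
    # hit equality at the JSON level: the store's serialization is the contract
    expect_identical(lapply(a$hits, doc_to_json), lapply(b$hits, doc_to_json))
  }
  expect_identical(doc_to_json(get_by_id(back, idx$ids[1])),
                   doc_to_json(get_by_id(idx, idx$ids[1])))
})
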