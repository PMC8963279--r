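# Build a store directly from named per-source doc lists.
store_from <- function(per_source, release = "r1") {
  st <- doc_store_memory()
  for (s in names(per_source)) {
    annohub:::store_put(st, s, release, unname(per_source[[s]]))
  }
  st
}

fix1_docs <- function() {
  list(alpha = list(list(`_id` = "g1", symbol = "CDK2", taxid = 9606L),
                    list(`_id` = "g2", symbol = "TP53", taxid = 9606L)),
       beta = list(list(`_id` = "g1", pathway = list("cell_cycle", "dna_repair")),
                   list(`_id` = "g3", pathway = list("apoptosis"))))
}

test_that("plan_build resolves releases and takes the id census", {
  st <- store_from(fix1_docs())
  plan <- plan_build(build_config("b", c("alpha", "beta"), root_sources = "alpha"), st)
  expect_identical(plan$union_ids, c("g1", "g2", "g3"))
  expect_identical(plan$root_ids, c("g1", "g2"))
  expect_identical(plan$merged_ids, c("g1", "g2"))
  expect_identical(plan$ids_per_source$alpha, 2L)

  # "latest" resolves to the highest tag; a pinned selector wins over newer
  st2 <- store_from(fix1_docs())
  annohub:::store_put(st2, "alpha", "r2", list(list(`_id` = "g9")))
  p_latest <- plan_build(build_config("b", c("alpha", "beta")), st2)
  expect_identical(unname(p_latest$releases["alpha"]), "r2")
  p_pin <- plan_build(build_config("b", c(alpha = "r1", beta = "latest")), st2)
  expect_identical(unname(p_pin$releases["alpha"]), "r1")

  expect_error(plan_build(build_config("b", c("alpha", "ghost")), st),
               class = "annohub_build_error")
})

test_that("merge_documents namespaces each source and is input-order invariant", {
  cfg <- build_config("b", c("alpha", "beta"))
  a <- list(source = "alpha", priority = 100L,
            doc = list(`_id` = "g1", symbol = "CDK2", taxid = 9606L))
  b <- list(source = "beta", priority = 100L,
            doc = list(`_id` = "g1", pathway = list("cell_cycle", "dna_repair")))
  m <- merge_documents(list(a, b), cfg)
  expect_identical(m, list(`_id` = "g1",
                           alpha = list(symbol = "CDK2", taxid = 9606L),
                           beta = list(pathway = list("cell_cycle", "dna_repair"))))
  expect_identical(merge_documents(list(b, a), cfg), m)

  # single source
  solo <- merge_documents(list(list(source = "alpha", priority = 100L,
                                    doc = list(`_id` = "g2", symbol = "TP53",
                                               taxid = 9606L))), cfg)
  expect_identical(solo, list(`_id` = "g2",
                              alpha = list(symbol = "TP53", taxid = 9606L)))

  # an empty body contributes nothing
  empty <- list(source = "beta", priority = 100L, doc = list(`_id` = "g1"))
  expect_identical(merge_documents(list(a, empty), cfg),
                   list(`_id` = "g1", alpha = list(symbol = "CDK2", taxid = 9606L)))

  expect_error(merge_documents(list(a, list(source = "beta", priority = 100L,
                                            doc = list(`_id` = "gX"))), cfg),
               class = "annohub_contract_error")
})

test_that("root sources gate build membership; an empty root set admits everything", {
  st <- store_from(fix1_docs())
  rooted <- run_build(build_config("b", c("alpha", "beta"),
                                   root_sources = "alpha"), st)
  expect_identical(names(rooted$merged), c("g1", "g2"))
  expect_identical(rooted$metadata$merged_count, 2L)
  expect_identical(rooted$metadata$root_excluded_count, 1L)
  expect_identical(names(rooted$merged$g1), c("_id", "alpha", "beta"))

  open <- run_build(build_config("b", c("alpha", "beta")), st)
  expect_identical(names(open$merged), c("g1", "g2", "g3"))
  expect_identical(open$metadata$root_excluded_count, 0L)
})

test_that("permuting source order never changes any merged tree", {
  set.seed(7)
  for (rep in 1:5) {
    per <- list(a1 = gen_random_docs(8), b2 = gen_random_docs(10),
                c3 = gen_random_docs(6))
    st <- store_from(per)
    m1 <- run_build(build_config("b", c("a1", "b2", "c3")), st)$merged
    m2 <- run_build(build_config("b", c("c3", "a1", "b2")), st)$merged
    expect_identical(lapply(m1, doc_to_json), lapply(m2, doc_to_json))
  }
})

test_that("merged id sets equal the brute-force set-algebra oracle", {
  set.seed(99)
  for (rep in 1:10) {
    nsrc <- sample(2:3, 1)
    nms <- paste0("s", seq_len(nsrc))
    per <- setNames(lapply(seq_len(nsrc), function(i) {
      n <- sample(3:20, 1)
      offset <- sample(0:10, 1)
      docs <- lapply(seq_len(n), function(j) {
        list(`_id` = sprintf("g%03d", offset + j), v = j)
      })
      setNames(docs, vapply(docs, `[[`, character(1), "_id"))
    }), nms)
    st <- store_from(per)
    roots <- sample(nms, sample(0:nsrc, 1))
    build <- run_build(build_config("b", nms, root_sources = roots), st)
    expect_identical(names(build$merged),
                     oracle_merged_ids(st, nms, rep("r1", nsrc), roots))
  }
})

test_that("rebuilds on an unchanged store are identical apart from the version", {
  st <- store_from(fix1_docs())
  cfg <- build_config("b", c("alpha", "beta"), root_sources = "alpha")
  b1 <- run_build(cfg, st)
  b2 <- run_build(cfg, st)
  expect_identical(lapply(b1$merged, doc_to_json), lapply(b2$merged, doc_to_json))
  expect_identical(b1$metadata[setdiff(names(b1$metadata), "build_version")],
                   b2$metadata[setdiff(names(b2$metadata), "build_version")])
})

test_that("every merged leaf value exists verbatim in exactly one contributing source", {
  set.seed(13)
  per <- list(alpha = gen_random_docs(6), beta = gen_random_docs(6))
  st <- store_from(per)
  build <- run_build(build_config("b", c("alpha", "beta")), st)
  for (id in names(build$merged)) {
    doc <- build$merged[[id]]
    for (src in setdiff(names(doc), "_id")) {
      original <- per[[src]][[id]]
      original[["_id"]] <- NULL
      expect_identical(doc[[src]], original)
    }
  }
})

test_that("builds persist atomically with metadata and reload intact", {
  st <- store_from(fix1_docs())
  root <- tmp_dir()
  cfg <- build_config("demo", c("alpha", "beta"), root_sources = "alpha")
  b <- run_build(cfg, st, data_root = root)
  v <- b$metadata$build_version
  expect_match(v, "^demo\\.[0-9]{14}")
  back <- read_build(v, root)
  expect_identical(lapply(back$merged, doc_to_json), lapply(b$merged, doc_to_json))
  expect_identical(back$metadata$merged_count, 2L)
  # two builds within one second get distinct -N suffixed versions
  b2 <- run_build(cfg, st, data_root = root)
  expect_false(identical(b2$metadata$build_version, v))
})
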