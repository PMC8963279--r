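api_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- fix1_pipeline()
    cache
  }
})

test_that("annotation endpoint returns documents, projections, and enveloped 404s", {
  fx <- api_fixture()
  app <- api_app(fx$index, "gene")
  r <- handle_request(app, "GET", "/gene/g1")
  expect_identical(r$status, 200L)
  expect_setequal(setdiff(names(r$body), "_id"), c("alpha", "beta"))

  miss <- handle_request(app, "GET", "/gene/g9")
  expect_identical(miss$status, 404L)
  expect_false(miss$body$success)
  expect_identical(miss$body$error, "not found")
  expect_identical(miss$body$code, 404L)

  proj <- handle_request(app, "GET", "/gene/g1", "fields=alpha.symbol")
  expect_identical(proj$body, list(`_id` = "g1", alpha = list(symbol = "CDK2")))
})

test_that("query endpoint mirrors execute_query and reports structured 400s", {
  fx <- api_fixture()
  app <- api_app(fx$index, "gene")
  r <- handle_request(app, "GET", "/query", "q=cdk2")
  expect_identical(r$status, 200L)
  expect_identical(r$body$total, 1L)
  expect_length(r$body$hits, 1)
  expect_true(is.numeric(r$body$took))

  bad <- handle_request(app, "GET", "/query", "q=%22unbalanced")
  expect_identical(bad$status, 400L)
  expect_match(bad$body$error, "position")

  cap <- handle_request(app, "GET", "/query", "q=cdk2&size=2000")
  expect_identical(cap$status, 400L)
  expect_match(cap$body$error, "1000")

  neg <- handle_request(app, "GET", "/query", "q=cdk2&from=-1")
  expect_identical(neg$status, 400L)

  unq <- handle_request(app, "GET", "/query", "q=beta.notes:x")
  expect_identical(unq$status, 400L)
  expect_match(unq$body$error, "unqueryable")
})

test_that("the HTTP layer adds nothing over direct calls", {
  fx <- api_fixture()
  app <- api_app(fx$index, "gene")
  direct <- execute_query(fx$index, "alpha.taxid:>9000", from = 0, size = 10)
  via_http <- handle_request(app, "GET", "/query",
                             "q=alpha.taxid:%3E9000&size=10&from=0")
  expect_identical(via_http$body$total, direct$total)
  expect_identical(via_http$body$hits, direct$hits)
  expect_identical(handle_request(app, "GET", "/gene/g2")$body,
                   get_by_id(fx$index, "g2"))
})

test_that("batch responses align with request order, repeat ids, and cap at 1000", {
  fx <- api_fixture()
  app <- api_app(fx$index, "gene")
  r <- handle_batch(app, c("g1", "g9"))
  expect_identical(r$status, 200L)
  expect_length(r$body, 2)
  expect_identical(r$body[[1]]$query, "g1")
  expect_identical(r$body[[1]][["_id"]], "g1")
  expect_identical(r$body[[2]], list(query = "g9", notfound = TRUE))

  twice <- handle_batch(app, c("g1", "g1"))
  expect_identical(twice$body[[1]], twice$body[[2]])

  over <- handle_batch(app, sprintf("id%04d", 1:1001))
  expect_identical(over$status, 400L)
  expect_match(over$body$error, "1000")
  expect_identical(handle_batch(app, character(0))$status, 400L)

  # POST /query parses JSON and form bodies identically
  via_json <- handle_request(app, "POST", "/query",
                             body = '{"ids": ["g1", "g9"]}')
  via_form <- handle_request(app, "POST", "/query", body = "ids=g1,g9")
  expect_identical(via_json$body, via_form$body)
  expect_identical(via_json$body, r$body)
})

test_that("batch for one id equals the annotation endpoint modulo the query wrapper", {
  fx <- api_fixture()
  app <- api_app(fx$index, "gene")
  single <- handle_annotation(app, "g1")
  batch <- handle_batch(app, "g1")
  el <- batch$body[[1]]
  el$query <- NULL
  expect_identical(el, single$body)
})

test_that("scoped batch ids can match several documents as adjacent elements", {
  fx <- api_fixture()
  app <- api_app(fx$index, "gene")
  # both g1 and g2 carry taxid 9606 under alpha
  r <- handle_batch(app, "9606", scopes = "alpha.taxid")
  expect_length(r$body, 2)
  expect_identical(vapply(r$body, `[[`, character(1), "query"),
                   c("9606", "9606"))
  expect_identical(vapply(r$body, `[[`, character(1), "_id"), c("g1", "g2"))
  # scoping to an unmapped path errors
  expect_identical(handle_batch(app, "x", scopes = "beta.notes")$status, 400L)
})

test_that("metadata endpoints expose build provenance and the flattened mapping", {
  fx <- api_fixture()
  app <- api_app(fx$index, "gene")
  md <- handle_request(app, "GET", "/metadata")
  expect_identical(md$status, 200L)
  expect_identical(md$body$total_documents, 2L)
  expect_length(md$body$sources, 2)
  rels <- vapply(md$body$sources, `[[`, character(1), "release")
  expect_true(all(nzchar(rels)))

  flds <- handle_request(app, "GET", "/metadata/fields")
  expect_identical(flds$body$alpha.taxid$type, "integer")
  expect_identical(flds$body$beta.pathway$type, "keyword")

  st <- handle_request(app, "GET", "/status")
  expect_identical(st$status, 200L)
  expect_true(st$body$success)

  lost <- handle_request(app, "GET", "/nope/route/here")
  expect_identical(lost$status, 404L)
  expect_false(lost$body$success)
})

test_that("all error responses share one envelope", {
  fx <- api_fixture()
  app <- api_app(fx$index, "gene")
  errs <- list(handle_request(app, "GET", "/gene/zz"),
               handle_request(app, "GET", "/query", "q=%22x"),
               handle_request(app, "POST", "/query", body = ""),
               handle_request(app, "GET", "/missing"))
  for (e in errs) {
    expect_setequal(names(e$body), c("success", "error", "code"))
    expect_false(e$body$success)
    expect_identical(e$body$code, e$status)
  }
})

test_that("the embedded socket server answers real HTTP requests", {
  fx <- api_fixture()
  idx_dir <- tmp_dir()
  index_save(fx$index, idx_dir)
  port <- 20000L + (Sys.getpid() %% 10000L)
  srv <- callr::r_bg(function(idx_dir, port) {
    library(annohub)
    app <- api_app(index_load(idx_dir), "gene")
    serve_app(app, port, max_requests = 3)
  }, args = list(idx_dir = idx_dir, port = port))
  on.exit(srv$kill(), add = TRUE)

  http_get <- function(target) {
    for (attempt in 1:50) {
      con <- tryCatch(socketConnection("127.0.0.1", port, open = "r+b",
                                       blocking = TRUE, timeout = 10),
                      error = function(e) NULL, warning = function(w) NULL)
      if (!is.null(con)) break
      Sys.sleep(0.2)
    }
    if (is.null(con)) stop("server did not come up")
    on.exit(close(con))
    writeBin(charToRaw(sprintf("GET %s HTTP/1.1\r\nHost: x\r\n\r\n", target)), con)
    raw <- raw(0)
    repeat {
      chunk <- readBin(con, "raw", 65536)
      if (length(chunk) == 0) break
      raw <- c(raw, chunk)
    }
    txt <- rawToChar(raw)
    split <- regexpr("\r\n\r\n", txt, fixed = TRUE)
    list(status = as.integer(strsplit(txt, " ")[[1]][2]),
         body = jsonlite::fromJSON(substr(txt, split + 4, nchar(txt)),
                                   simplifyVector = FALSE))
  }

  st <- http_get("/status")
  expect_identical(st$status, 200L)
  expect_true(st$body$success)
  ann <- http_get("/gene/g1")
  expect_identical(ann$status, 200L)
  expect_setequal(setdiff(names(ann$body), "_id"), c("alpha", "beta"))
  q <- http_get("/query?q=cdk2")
  expect_identical(q$body$total, 1L)
  srv$wait(timeout = 5000)
})
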