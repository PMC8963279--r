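# Annotation-API-style read-only service over one indexed build. The HTTP
# layer adds nothing: every response body is a pure function of the app
# and the parsed request, and the same handlers are callable directly.
# Endpoints: GET /{entity}/{id}, GET /query, POST /query (batch),
# GET /metadata, GET /metadata/fields, GET /status.

#' Assemble an API application over an index
#'
#' @param index An `annohub_index`.
#' @param entity Entity label used in annotation URLs (lowercase letters,
#'   e.g. `"gene"`).
#' @param default_size Default query page size (default 10).
#' @return An `annohub_app`.
#' @export
api_app <- function(index, entity = "gene", default_size = 10L) {
  if (!grepl("^[a-z]+$", entity)) {
    stop(hub_error("entity label must match [a-z]+", "annohub_config_error"))
  }
  structure(list(index = index, entity = entity,
                 default_size = as.integer(default_size)),
            class = "annohub_app")
}

api_error <- function(code, message) {
  list(status = code,
       body = list(success = FALSE, error = message, code = code))
}

api_ok <- function(body) list(status = 200L, body = body)

#' Annotation endpoint: one document by identifier
#'
#' @param app An [api_app()].
#' @param id Document identifier.
#' @param fields Comma-separated dotted paths, or `"all"` (default).
#' @return A response list: `status` (HTTP code) and `body` (R tree to be
#'   serialized as JSON).
#' @export
handle_annotation <- function(app, id, fields = "all") {
  doc <- get_by_id(app$index, id)
  if (is.null(doc)) return(api_error(404L, "not found"))
  api_ok(project_fields(doc, parse_fields_param(fields)))
}

parse_fields_param <- function(fields) {
  if (is.null(fields) || identical(fields, "all") || !nzchar(fields)) return("all")
  trimws(strsplit(fields, ",", fixed = TRUE)[[1]])
}

#' Query endpoint
#'
#' @param app An [api_app()].
#' @param q Query string.
#' @param fields Comma-separated projection paths or `"all"`.
#' @param size Page size (cap 1000).
#' @param from Zero-based offset.
#' @return A response list; a 200 body carries `took` (integer
#'   milliseconds), `total`, `from`, `size`, `hits`.
#' @export
handle_query <- function(app, q, fields = "all", size = NULL, from = 0L) {
  if (is.null(size)) size <- app$default_size
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(
    execute_query(app$index, q, from = from, size = size,
                  fields = parse_fields_param(fields)),
    annohub_parse_error = function(e) e,
    annohub_unqueryable = function(e) e,
    annohub_request_error = function(e) e
  )
  if (inherits(res, "condition")) {
    return(api_error(400L, conditionMessage(res)))
  }
  took <- as.integer(round((proc.time()[["elapsed"]] - t0) * 1000))
  api_ok(list(took = took, total = res$total, from = res$from,
              size = res$size, hits = res$hits))
}

#' Batch endpoint: resolve up to 1000 identifiers in one call
#'
#' The response is a list aligned with the request ids in request order;
#' each element repeats the requested id under `"query"`; misses appear
#' as `{"query": id, "notfound": true}`. With `scopes`, ids are matched
#' against the given mapped paths instead of `_id`, and an id matching
#' several documents yields several adjacent elements.
#'
#' @param app An [api_app()].
#' @param ids Character vector of identifiers (1 to 1000).
#' @param fields Projection (comma-separated or `"all"`).
#' @param scopes Optional character vector of mapped paths to match ids
#'   against; default matches `_id` only.
#' @return A response list whose 200 body is the aligned list.
#' @export
handle_batch <- function(app, ids, fields = "all", scopes = NULL) {
  if (is.null(ids) || length(ids) == 0L) {
    return(api_error(400L, "batch request needs 1 to 1000 ids"))
  }
  if (length(ids) > 1000L) {
    return(api_error(400L, sprintf(
      "batch size %d exceeds the cap of 1000 ids", length(ids))))
  }
  fl <- parse_fields_param(fields)
  out <- list()
  for (id in ids) {
    matches <- character(0)
    if (is.null(scopes)) {
      if (!is.null(get_by_id(app$index, id))) matches <- id
    } else {
      hits <- tryCatch({
        asts <- lapply(scopes, function(p) ast_field_term(p, id))
        ast <- if (length(asts) == 1L) asts[[1]] else ast_or(asts)
        names(eval_ast(app$index, ast))
      }, annohub_unqueryable = function(e) e)
      if (inherits(hits, "condition")) {
        return(api_error(400L, conditionMessage(hits)))
      }
      matches <- sort(hits, method = "radix")
    }
    if (length(matches) == 0L) {
      out[[length(out) + 1L]] <- list(query = id, notfound = TRUE)
    } else {
      for (m in matches) {
        doc <- project_fields(get_by_id(app$index, m), fl)
        out[[length(out) + 1L]] <- c(list(query = id), doc)
      }
    }
  }
  api_ok(out)
}

#' Metadata endpoints
#'
#' `/metadata` reports the build version, per-source releases and counts,
#' and total document count; `/metadata/fields` reports the flattened
#' mapping (dotted path to type), omitting excluded conflict paths.
#'
#' @param app An [api_app()].
#' @param fields_view `TRUE` for `/metadata/fields`.
#' @return A response list.
#' @export
handle_metadata <- function(app, fields_view = FALSE) {
  if (fields_view) {
    types <- app$index$mapping$types
    body <- setNames(lapply(names(types), function(p) list(type = types[[p]])),
                     names(types))
    if (length(body) == 0L) body <- structure(list(), names = character(0))
    return(api_ok(body))
  }
  md <- app$index$metadata
  api_ok(list(
    build_version = md$build_version %||% NA_character_,
    sources = md$sources %||% list(),
    total_documents = length(app$index$ids)
  ))
}

# ---------------------------------------------------------------------------
# Request-level dispatch (still pure: no sockets involved).

parse_query_string <- function(qs) {
  if (is.null(qs) || !nzchar(qs)) return(list())
  parts <- strsplit(qs, "&", fixed = TRUE)[[1]]
  out <- list()
  for (p in parts) {
    kv <- strsplit(p, "=", fixed = TRUE)[[1]]
    if (length(kv) >= 1L && nzchar(kv[1])) {
      out[[url_decode(kv[1])]] <- url_decode(paste(kv[-1], collapse = "="))
    }
  }
  out
}

url_decode <- function(x) utils::URLdecode(chartr("+", " ", x))

num_param <- function(params, name, default) {
  v <- params[[name]]
  if (is.null(v)) return(default)
  n <- suppressWarnings(as.numeric(v))
  if (is.na(n)) return(structure(list(name = name), class = "annohub_bad_param"))
  n
}

#' Dispatch one parsed HTTP request
#'
#' The single entry point the socket server calls; also usable directly
#' in tests. Unknown routes get a 404 with the standard error envelope
#' `{"success": false, "error": ..., "code": ...}`.
#'
#' @param app An [api_app()].
#' @param method `"GET"` or `"POST"`.
#' @param path URL path, e.g. `"/gene/g1"`.
#' @param query Raw query string (after `?`), or `""`.
#' @param body Request body text (for POST), or `""`.
#' @return A response list: `status`, `body`.
#' @export
handle_request <- function(app, method, path, query = "", body = "") {
  params <- parse_query_string(query)
  segs <- strsplit(sub("^/", "", path), "/", fixed = TRUE)[[1]]
  if (method == "GET" && length(segs) == 1L && segs[1] == "status") {
    return(api_ok(list(success = TRUE, status = "ok",
                       documents = length(app$index$ids))))
  }
  if (method == "GET" && length(segs) == 1L && segs[1] == "metadata") {
    return(handle_metadata(app))
  }
  if (method == "GET" && length(segs) == 2L && segs[1] == "metadata" &&
      segs[2] == "fields") {
    return(handle_metadata(app, fields_view = TRUE))
  }
  if (method == "GET" && length(segs) == 1L && segs[1] == "query") {
    q <- params[["q"]]
    if (is.null(q)) return(api_error(400L, "missing query parameter `q`"))
    size <- num_param(params, "size", NULL)
    from <- num_param(params, "from", 0L)
    for (p in list(size, from)) {
      if (inherits(p, "annohub_bad_param")) {
        return(api_error(400L, sprintf("parameter `%s` is not a number", p$name)))
      }
    }
    return(handle_query(app, q, fields = params[["fields"]] %||% "all",
                        size = size, from = from))
  }
  if (method == "POST" && length(segs) == 1L && segs[1] == "query") {
    parsed <- parse_batch_body(body)
    if (inherits(parsed, "condition")) {
      return(api_error(400L, conditionMessage(parsed)))
    }
    return(handle_batch(app, parsed$ids, fields = parsed$fields %||% "all",
                        scopes = parsed$scopes))
  }
  if (method == "GET" && length(segs) == 2L && segs[1] == app$entity) {
    return(handle_annotation(app, url_decode(segs[2]),
                             fields = params[["fields"]] %||% "all"))
  }
  api_error(404L, sprintf("no route for %s %s", method, path))
}

parse_batch_body <- function(body) {
  body <- trimws(body %||% "")
  if (!nzchar(body)) {
    return(hub_error("empty batch body", "annohub_request_error"))
  }
  if (startsWith(body, "{")) {
    raw <- tryCatch(jsonlite::fromJSON(body, simplifyVector = FALSE),
                    error = function(e) e)
    if (inherits(raw, "error")) {
      return(hub_error("batch body is not valid JSON", "annohub_request_error"))
    }
    ids <- vapply(raw$ids %||% list(), as.character, character(1))
    scopes <- if (is.null(raw$scopes)) NULL else
      vapply(raw$scopes, as.character, character(1))
    return(list(ids = ids, fields = raw$fields, scopes = scopes))
  }
  # form encoding: ids=g1,g2&fields=...&scopes=a,b
  params <- parse_query_string(body)
  ids <- if (is.null(params$ids)) character(0) else
    trimws(strsplit(params$ids, ",", fixed = TRUE)[[1]])
  scopes <- if (is.null(params$scopes)) NULL else
    trimws(strsplit(params$scopes, ",", fixed = TRUE)[[1]])
  list(ids = ids, fields = params$fields, scopes = scopes)
}

# ---------------------------------------------------------------------------
# Minimal embedded HTTP/1.1 server over base R sockets: one connection at
# a time, Content-Length framed bodies, connection closed per response.

response_json <- function(resp) {
  as.character(jsonlite::toJSON(resp$body, auto_unbox = TRUE, digits = NA,
                                null = "null"))
}

http_status_text <- function(code) {
  switch(as.character(code), "200" = "OK", "400" = "Bad Request",
         "404" = "Not Found", "500" = "Internal Server Error", "OK")
}

#' Serve an app over HTTP
#'
#' Blocking single-threaded server intended for local and test use. Each
#' request is dispatched through [handle_request()]; bodies are JSON,
#' UTF-8. Stops after `max_requests` requests when that is finite (the
#' testing escape hatch).
#'
#' @param app An [api_app()].
#' @param port TCP port.
#' @param host Bind address (default 127.0.0.1).
#' @param max_requests Stop after this many requests (default `Inf`).
#' @return Number of requests served, invisibly.
#' @export
serve_app <- function(app, port, host = "127.0.0.1", max_requests = Inf) {
  srv <- serverSocket(port)
  on.exit(close(srv), add = TRUE)
  served <- 0L
  while (served < max_requests) {
    con <- socketAccept(srv, blocking = TRUE, open = "r+b", timeout = 3600)
    served <- served + 1L
    tryCatch({
      req <- read_http_request(con)
      resp <- if (is.null(req)) {
        api_error(400L, "malformed request")
      } else {
        tryCatch(handle_request(app, req$method, req$path, req$query, req$body),
                 error = function(e) api_error(500L, conditionMessage(e)))
      }
      json <- response_json(resp)
      payload <- charToRaw(json)
      head <- sprintf(paste0(
        "HTTP/1.1 %d %s\r\n",
        "Content-Type: application/json; charset=utf-8\r\n",
        "Content-Length: %d\r\n",
        "Connection: close\r\n\r\n"),
        resp$status, http_status_text(resp$status), length(payload))
      writeBin(c(charToRaw(head), payload), con)
    }, error = function(e) NULL)
    try(close(con), silent = TRUE)
  }
  invisible(served)
}

read_http_request <- function(con) {
  line <- read_crlf_line(con)
  if (is.null(line) || !nzchar(line)) return(NULL)
  parts <- strsplit(line, " ", fixed = TRUE)[[1]]
  if (length(parts) < 2L) return(NULL)
  method <- parts[1]
  target <- parts[2]
  qpos <- regexpr("?", target, fixed = TRUE)
  path <- if (qpos > 0) substr(target, 1, qpos - 1) else target
  query <- if (qpos > 0) substr(target, qpos + 1, nchar(target)) else ""
  clen <- 0L
  repeat {
    h <- read_crlf_line(con)
    if (is.null(h) || !nzchar(h)) break
    if (grepl("^content-length:", tolower(h))) {
      clen <- as.integer(trimws(sub("^[^:]+:", "", h)))
    }
  }
  body <- if (clen > 0L) {
    rawToChar(readBin(con, "raw", n = clen))
  } else ""
  list(method = method, path = path, query = query, body = body)
}

read_crlf_line <- function(con) {
  buf <- raw(0)
  repeat {
    b <- readBin(con, "raw", n = 1L)
    if (length(b) == 0L) return(if (length(buf)) rawToChar(buf) else NULL)
    if (b == as.raw(10L)) break
    if (b != as.raw(13L)) buf <- c(buf, b)
  }
  rawToChar(buf)
}
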