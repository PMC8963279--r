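# Dump stage: fetch a source payload into <data_root>/<source>/<release>/,
# where the release tag is derived from content. Release identity is the
# payload checksum; modification times and HTTP headers only make the tag
# sortable and human-readable.

uri_to_path <- function(uri) {
  if (!startsWith(uri, "file://")) return(NULL)
  p <- sub("^file://", "", uri)
  # file:///abs/path keeps the leading slash
  p
}

sha256_file <- function(path) digest::digest(file = path, algo = "sha256")

sha256_string <- function(x) digest::digest(x, algo = "sha256", serialize = FALSE)

#' Construct a release tag
#'
#' @param value Sortable tag string.
#' @param origin One of `"mtime"`, `"http-header"`, `"checksum"`, `"manual"`.
#' @param checksum Content SHA-256 backing the tag (optional).
#' @return An `annohub_release` object.
#' @export
release_tag <- function(value, origin = "manual", checksum = NULL) {
  stopifnot(is.character(value), nzchar(value),
            origin %in% c("mtime", "http-header", "checksum", "manual"))
  structure(list(value = value, origin = origin, checksum = checksum),
            class = "annohub_release")
}

# List payload files for a file:// location: a single file, or a directory
# copied recursively. Returns data.frame(abs, rel).
local_payload_files <- function(path) {
  if (dir.exists(path)) {
    rel <- list.files(path, recursive = TRUE, all.files = FALSE)
    rel <- sort(rel)
    data.frame(abs = file.path(path, rel), rel = rel, stringsAsFactors = FALSE)
  } else if (file.exists(path)) {
    data.frame(abs = path, rel = basename(path), stringsAsFactors = FALSE)
  } else {
    NULL
  }
}

# Content identity of a payload: sha256 over the sorted (relpath, file sha)
# listing, so multi-file sources get a stable combined checksum.
payload_checksum <- function(files) {
  per <- vapply(files$abs, sha256_file, character(1))
  sha256_string(paste(files$rel, per, sep = "\t", collapse = "\n"))
}

fmt_tag_time <- function(t) {
  format(as.POSIXct(t, tz = "UTC"), "%Y-%m-%dT%H-%M-%S", tz = "UTC")
}

#' Detect whether a source has a new release
#'
#' For `file://` locations the tag combines the newest payload modification
#' time with a SHA-256 content checksum; for `http(s)://` locations the
#' `Last-Modified`/`ETag` header is used when present, falling back to a
#' checksum of the body. Two tags denote the same release iff their content
#' checksums agree, so touching a file without changing bytes is
#' "unchanged".
#'
#' @param d A source descriptor.
#' @param known The last known [release_tag()], or `NULL`.
#' @return A new `annohub_release`, or the string `"unchanged"` when the
#'   current content matches `known`.
#' @export
detect_release <- function(d, known = NULL) {
  loc <- d$location
  p <- uri_to_path(loc)
  if (!is.null(p)) {
    files <- local_payload_files(p)
    if (is.null(files) || nrow(files) == 0L) {
      stop(hub_error(sprintf("unreachable location: %s", loc),
                     "annohub_retrieval_error", uri = loc))
    }
    cks <- payload_checksum(files)
    mtime <- max(file.mtime(files$abs))
    tag <- release_tag(paste0(fmt_tag_time(mtime), "-", substr(cks, 1, 12)),
                       origin = "mtime", checksum = cks)
  } else if (grepl("^https?://", loc)) {
    tag <- http_release_tag(loc)
  } else {
    stop(hub_error(sprintf("unsupported location scheme: %s", loc),
                   "annohub_retrieval_error", uri = loc))
  }
  if (!is.null(known) && tags_same_release(tag, known)) return("unchanged")
  tag
}

tags_same_release <- function(a, b) {
  ca <- a$checksum
  cb <- b$checksum
  if (!is.null(ca) && !is.null(cb)) return(identical(ca, cb))
  identical(a$value, b$value)
}

http_release_tag <- function(loc) {
  if (!requireNamespace("curl", quietly = TRUE)) {
    stop(hub_error("http(s) locations require the curl package",
                   "annohub_retrieval_error", uri = loc))
  }
  resp <- tryCatch(curl::curl_fetch_memory(loc), error = function(e) {
    stop(hub_error(sprintf("unreachable location: %s (%s)", loc, conditionMessage(e)),
                   "annohub_retrieval_error", uri = loc))
  })
  if (resp$status_code >= 400) {
    stop(hub_error(sprintf("unreachable location: %s (HTTP %d)", loc, resp$status_code),
                   "annohub_retrieval_error", uri = loc))
  }
  hdrs <- curl::parse_headers_list(resp$headers)
  cks <- sha256_string(rawToChar(resp$content))
  lm <- hdrs[["last-modified"]]
  if (!is.null(lm)) {
    t <- as.POSIXct(lm, format = "%a, %d %b %Y %H:%M:%S", tz = "GMT")
    if (!is.na(t)) {
      return(release_tag(paste0(fmt_tag_time(t), "-", substr(cks, 1, 12)),
                         origin = "http-header", checksum = cks))
    }
  }
  et <- hdrs[["etag"]]
  if (!is.null(et)) {
    clean <- gsub("[^A-Za-z0-9._-]", "", et)
    return(release_tag(paste0(clean, "-", substr(cks, 1, 12)),
                       origin = "http-header", checksum = cks))
  }
  release_tag(substr(cks, 1, 16), origin = "checksum", checksum = cks)
}

read_sidecar <- function(folder) {
  sc <- file.path(folder, "release.json")
  if (!file.exists(sc)) return(NULL)
  jsonlite::fromJSON(sc, simplifyVector = FALSE)
}

#' Dump a source payload into a versioned release folder
#'
#' When the detected release is new (or `force` is set) the payload is
#' copied into `<data_root>/<source>/<release>/` atomically: files land in
#' a temporary folder first and are renamed into place only on success. A
#' `release.json` sidecar records the tag, retrieval time and per-file
#' SHA-256 checksums. An unchanged source is skipped.
#'
#' @param d A source descriptor.
#' @param data_root Hub data root (created if missing).
#' @param force Re-fetch even when unchanged.
#' @return A `DumpResult` list (`source`, `release`, `files`, `folder`),
#'   or the string `"skipped"`.
#' @export
dump_source <- function(d, data_root, force = FALSE) {
  dir.create(data_root, recursive = TRUE, showWarnings = FALSE)
  src_dir <- file.path(data_root, d$name)
  known <- latest_known_tag(d$name, data_root)
  det <- detect_release(d, known)
  if (identical(det, "unchanged") && !force) return("skipped")
  tag <- if (identical(det, "unchanged")) known else det
  folder <- file.path(src_dir, tag$value)
  tmp <- tempfile(pattern = ".tmp-", tmpdir = src_dir)
  dir.create(tmp, recursive = TRUE, showWarnings = FALSE)
  ok <- FALSE
  on.exit(if (!ok && dir.exists(tmp)) unlink(tmp, recursive = TRUE))
  p <- uri_to_path(d$location)
  fault <- getOption("annohub.copy_fault", NULL) # testing seam
  if (!is.null(p)) {
    files <- local_payload_files(p)
    expected <- vapply(files$abs, sha256_file, character(1))
    for (i in seq_len(nrow(files))) {
      if (!is.null(fault) && isTRUE(fault(i))) {
        stop(hub_error("injected copy fault", "annohub_retrieval_error"))
      }
      dest <- file.path(tmp, files$rel[i])
      dir.create(dirname(dest), recursive = TRUE, showWarnings = FALSE)
      if (!file.copy(files$abs[i], dest, overwrite = TRUE)) {
        stop(hub_error(sprintf("copy failed: %s", files$rel[i]),
                       "annohub_retrieval_error"))
      }
      if (!identical(sha256_file(dest), expected[[i]])) {
        stop(hub_error(sprintf("checksum mismatch after copy: %s", files$rel[i]),
                       "annohub_retrieval_error"))
      }
    }
    rels <- files$rel
  } else {
    resp <- curl::curl_fetch_memory(d$location)
    if (resp$status_code >= 400) {
      stop(hub_error(sprintf("unreachable location: %s", d$location),
                     "annohub_retrieval_error", uri = d$location))
    }
    rels <- basename(sub("[?#].*$", "", d$location))
    if (!nzchar(rels)) rels <- "payload"
    writeBin(resp$content, file.path(tmp, rels))
  }
  file_rows <- lapply(rels, function(r) {
    f <- file.path(tmp, r)
    list(path = r, bytes = file.size(f), sha256 = sha256_file(f))
  })
  sidecar <- list(release = tag$value, origin = tag$origin,
                  checksum = tag$checksum,
                  retrieved_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
                  files = file_rows)
  writeLines(as.character(jsonlite::toJSON(sidecar, auto_unbox = TRUE,
                                           digits = NA)),
             file.path(tmp, "release.json"))
  if (dir.exists(folder)) unlink(folder, recursive = TRUE) # force re-fetch, same tag
  if (!file.rename(tmp, folder)) {
    stop(hub_error(sprintf("could not move release into place: %s", folder),
                   "annohub_retrieval_error"))
  }
  ok <- TRUE
  structure(list(source = d$name, release = tag, files = file_rows,
                 folder = folder), class = "annohub_dump")
}

latest_known_tag <- function(source, data_root) {
  tags <- list_local_releases(source, data_root)
  if (length(tags) == 0L) return(NULL)
  tags[[length(tags)]]
}

#' List locally dumped releases of a source
#'
#' @param source Source name.
#' @param data_root Hub data root.
#' @return A list of [release_tag()]s in ascending tag order; empty if the
#'   source was never dumped.
#' @export
list_local_releases <- function(source, data_root) {
  src_dir <- file.path(data_root, source)
  if (!dir.exists(src_dir)) return(list())
  vals <- sort(setdiff(list.dirs(src_dir, recursive = FALSE, full.names = FALSE),
                       character(0)))
  vals <- vals[!startsWith(vals, ".tmp-")]
  lapply(vals, function(v) {
    sc <- read_sidecar(file.path(src_dir, v))
    release_tag(v,
                origin = if (is.null(sc$origin)) "manual" else sc$origin,
                checksum = sc$checksum)
  })
}
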