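# Five-field cron expressions (minute hour day-of-month month day-of-week),
# evaluated at minute granularity in UTC. Supported syntax per field:
# "*", "a", "a,b,c", "a-b", "*/n", "a-b/n". Day-of-week 0-7 with 7 == 0
# (Sunday). Standard cron day semantics: when both day-of-month and
# day-of-week are restricted, a time matches if either does.

cron_field_range <- list(
  minute = c(0L, 59L), hour = c(0L, 23L), dom = c(1L, 31L),
  month = c(1L, 12L), dow = c(0L, 7L)
)

#' Parse a five-field cron expression
#'
#' @param expr A cron string such as `"0 3 * * 1"`.
#' @return An object of class `annohub_cron` holding the allowed value set
#'   per field and whether each field was restricted.
#' @export
#' @examples
#' parse_cron("0 3 * * *")   # every day at 03:00
parse_cron <- function(expr) {
  if (!is.character(expr) || length(expr) != 1L || is.na(expr)) {
    stop(cron_error(expr, "schedule is not a single string"))
  }
  parts <- strsplit(trimws(expr), "\\s+")[[1]]
  if (length(parts) != 5L) {
    stop(cron_error(expr, sprintf("expected 5 fields, got %d", length(parts))))
  }
  fields <- names(cron_field_range)
  sets <- vector("list", 5L)
  wild <- logical(5L)
  for (i in seq_len(5L)) {
    rng <- cron_field_range[[i]]
    parsed <- parse_cron_field(parts[[i]], rng[1], rng[2])
    if (is.null(parsed)) {
      stop(cron_error(expr, sprintf("malformed field `%s` (%s)", parts[[i]], fields[[i]])))
    }
    vals <- parsed$values
    if (fields[[i]] == "dow") vals <- sort(unique(ifelse(vals == 7L, 0L, vals)))
    sets[[i]] <- vals
    wild[[i]] <- parsed$wild
  }
  structure(list(expr = expr, sets = setNames(sets, fields),
                 wild = setNames(wild, fields)),
            class = "annohub_cron")
}

cron_error <- function(expr, msg) {
  structure(
    class = c("annohub_config_error", "error", "condition"),
    list(message = sprintf("invalid schedule %s: %s",
                           deparse1(substr(as.character(expr)[1], 1, 60)), msg),
         call = NULL, field = "schedule")
  )
}

parse_cron_field <- function(tok, lo, hi) {
  out <- integer(0)
  wild <- FALSE
  for (piece in strsplit(tok, ",", fixed = TRUE)[[1]]) {
    step <- 1L
    if (grepl("/", piece, fixed = TRUE)) {
      bits <- strsplit(piece, "/", fixed = TRUE)[[1]]
      if (length(bits) != 2L || !grepl("^[0-9]+$", bits[2])) return(NULL)
      step <- as.integer(bits[2])
      if (step < 1L) return(NULL)
      piece <- bits[1]
    }
    if (piece == "*") {
      vals <- seq.int(lo, hi)
      if (step == 1L) wild <- TRUE
    } else if (grepl("^[0-9]+-[0-9]+$", piece)) {
      bits <- as.integer(strsplit(piece, "-", fixed = TRUE)[[1]])
      if (bits[1] > bits[2]) return(NULL)
      vals <- seq.int(bits[1], bits[2])
    } else if (grepl("^[0-9]+$", piece)) {
      vals <- as.integer(piece)
    } else {
      return(NULL)
    }
    if (step > 1L) vals <- vals[seq(1L, length(vals), by = step)]
    if (any(vals < lo | vals > hi)) return(NULL)
    out <- c(out, vals)
  }
  if (length(out) == 0L) return(NULL)
  list(values = sort(unique(out)), wild = wild)
}

# Vectorized: which of the POSIXct times (UTC) match the cron spec.
cron_matches <- function(cron, times) {
  lt <- as.POSIXlt(times, tz = "UTC")
  ok_min <- lt$min %in% cron$sets$minute
  ok_hour <- lt$hour %in% cron$sets$hour
  ok_month <- (lt$mon + 1L) %in% cron$sets$month
  dom_ok <- lt$mday %in% cron$sets$dom
  dow_ok <- lt$wday %in% cron$sets$dow
  day_ok <- if (!cron$wild[["dom"]] && !cron$wild[["dow"]]) {
    dom_ok | dow_ok
  } else if (!cron$wild[["dom"]]) {
    dom_ok
  } else if (!cron$wild[["dow"]]) {
    dow_ok
  } else {
    rep(TRUE, length(times))
  }
  ok_min & ok_hour & ok_month & day_ok
}

#' Is a scheduled source due for a refresh?
#'
#' Pure function of its arguments: no clock is read. A source with no
#' schedule is manual-trigger only and is never due; a scheduled source
#' with no recorded last run is always due; otherwise the source is due
#' iff at least one schedule firing time falls in `(last_run, now]`.
#'
#' @param d A `SourceDescriptor` (see [load_manifest()]).
#' @param last_run A `POSIXct` timestamp of the last dump, or `NULL`.
#' @param now A `POSIXct` timestamp.
#' @return `TRUE` or `FALSE`.
#' @export
schedule_due <- function(d, last_run, now) {
  if (is.null(d$schedule)) return(FALSE)
  cron <- parse_cron(d$schedule)
  if (is.null(last_run)) return(TRUE)
  last_run <- as.POSIXct(last_run, tz = "UTC")
  now <- as.POSIXct(now, tz = "UTC")
  if (now <= last_run) return(FALSE)
  # scan minute by minute in chunks; any cron with a feasible date fires at
  # least yearly, so a bounded number of chunks suffices
  from <- floor_minute(last_run) + 60
  to <- floor_minute(now)
  if (from > to) return(FALSE)
  chunk <- 60 * 60 * 24 * 185 # ~6 months of minutes per chunk
  start <- from
  while (start <= to) {
    end <- min(start + chunk - 60, to)
    times <- seq(start, end, by = 60)
    if (any(cron_matches(cron, times))) return(TRUE)
    start <- end + 60
  }
  FALSE
}

floor_minute <- function(t) {
  as.POSIXct(floor(as.numeric(t) / 60) * 60, origin = "1970-01-01", tz = "UTC")
}
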