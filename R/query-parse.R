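# Query grammar (deliberately minimal, exact-match oriented):
#   FieldTerm  = path ":" value          alpha.symbol:CDK2
#   Range      = path ":" op number      alpha.taxid:>9000   (op: > >= < <=)
#   Term       = bare token              cdk2
#   Wildcard   = value ending in "*"     CDK* or alpha.symbol:CDK*
#   AND / OR   = explicit uppercase operators; AND binds tighter than OR;
#                adjacent bare expressions are implicitly AND-ed
#   ( ... )    = grouping; "quoted values" preserve spaces
# Matching is case-insensitive exact (prefix for wildcards).

parse_error <- function(msg, pos) {
  hub_error(sprintf("query parse error at position %d: %s", pos, msg),
            "annohub_parse_error", position = pos)
}

tokenize_query <- function(q) {
  tokens <- list()
  i <- 1L
  n <- nchar(q)
  push <- function(type, text, pos) {
    tokens[[length(tokens) + 1L]] <<- list(type = type, text = text, pos = pos)
  }
  while (i <= n) {
    ch <- substr(q, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch == "(") { push("lparen", "(", i); i <- i + 1L; next }
    if (ch == ")") { push("rparen", ")", i); i <- i + 1L; next }
    if (ch == "\"") {
      j <- i + 1L
      while (j <= n && substr(q, j, j) != "\"") j <- j + 1L
      if (j > n) stop(parse_error("unbalanced quote", i))
      push("quoted", substr(q, i + 1L, j - 1L), i)
      i <- j + 1L
      next
    }
    # bare word: up to whitespace or paren; may contain ':' and a quoted value
    j <- i
    buf <- ""
    quoted_tail <- FALSE
    while (j <= n) {
      cj <- substr(q, j, j)
      if (grepl("^\\s$", cj) || cj == "(" || cj == ")") break
      if (cj == "\"") {
        k <- j + 1L
        while (k <= n && substr(q, k, k) != "\"") k <- k + 1L
        if (k > n) stop(parse_error("unbalanced quote", j))
        buf <- paste0(buf, substr(q, j + 1L, k - 1L))
        quoted_tail <- TRUE
        j <- k + 1L
        next
      }
      buf <- paste0(buf, cj)
      j <- j + 1L
    }
    if (!quoted_tail && buf == "AND") push("and", buf, i)
    else if (!quoted_tail && buf == "OR") push("or", buf, i)
    else push(if (quoted_tail) "wordq" else "word", buf, i)
    i <- j
  }
  tokens
}

# AST constructors ----------------------------------------------------------

ast_term <- function(value) list(kind = "term", value = value)
ast_field_term <- function(path, value) list(kind = "field_term", path = path, value = value)
ast_range <- function(path, op, number) list(kind = "range", path = path, op = op, number = number)
ast_wildcard <- function(path, prefix) list(kind = "wildcard", path = path, prefix = prefix)
ast_and <- function(children) list(kind = "and", children = children)
ast_or <- function(children) list(kind = "or", children = children)

#' Parse a query string into an abstract syntax tree
#'
#' See the grammar in the package vignette: fielded terms
#' (`path:value`), numeric ranges (`path:>n`, `>=`, `<`, `<=`), bare
#' terms searched across all keyword fields, trailing-`*` prefix
#' wildcards, uppercase `AND`/`OR` (AND binds tighter), parentheses, and
#' double-quoted values. Adjacent bare expressions are implicitly AND-ed.
#'
#' @param q Query string (non-empty after trimming).
#' @return A `QueryAST` (nested list with a `kind` field).
#' @export
#' @examples
#' parse_query("alpha.symbol:CDK2")
#' parse_query("CDK2 OR TP53")
#' parse_query("alpha.taxid:>9000 AND beta.pathway:cell_cycle")
parse_query <- function(q) {
  if (!is.character(q) || length(q) != 1L || is.na(q) || !nzchar(trimws(q))) {
    stop(parse_error("empty query", 1L))
  }
  toks <- tokenize_query(q)
  if (length(toks) == 0L) stop(parse_error("empty query", 1L))
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$i <- 1L
  ast <- parse_or(st)
  if (st$i <= length(st$toks)) {
    t <- st$toks[[st$i]]
    stop(parse_error(sprintf("unexpected `%s`", t$text), t$pos))
  }
  ast
}

peek <- function(st) if (st$i <= length(st$toks)) st$toks[[st$i]] else NULL
advance <- function(st) { t <- st$toks[[st$i]]; st$i <- st$i + 1L; t }

parse_or <- function(st) {
  children <- list(parse_and(st))
  repeat {
    t <- peek(st)
    if (is.null(t) || t$type != "or") break
    advance(st)
    if (is.null(peek(st))) stop(parse_error("dangling OR", t$pos))
    children[[length(children) + 1L]] <- parse_and(st)
  }
  if (length(children) == 1L) children[[1]] else ast_or(children)
}

parse_and <- function(st) {
  children <- list(parse_unit(st))
  repeat {
    t <- peek(st)
    if (is.null(t)) break
    if (t$type == "and") {
      advance(st)
      if (is.null(peek(st))) stop(parse_error("dangling AND", t$pos))
      children[[length(children) + 1L]] <- parse_unit(st)
    } else if (t$type %in% c("word", "wordq", "quoted", "lparen")) {
      children[[length(children) + 1L]] <- parse_unit(st) # implicit AND
    } else {
      break
    }
  }
  if (length(children) == 1L) children[[1]] else ast_and(children)
}

parse_unit <- function(st) {
  t <- peek(st)
  if (is.null(t)) stop(parse_error("unexpected end of query", 0L))
  if (t$type == "lparen") {
    advance(st)
    inner <- parse_or(st)
    t2 <- peek(st)
    if (is.null(t2) || t2$type != "rparen") {
      stop(parse_error("unbalanced parenthesis", t$pos))
    }
    advance(st)
    return(inner)
  }
  if (t$type == "rparen") stop(parse_error("unbalanced parenthesis", t$pos))
  if (t$type %in% c("and", "or")) {
    stop(parse_error(sprintf("dangling %s", t$text), t$pos))
  }
  advance(st)
  word_to_ast(t)
}

word_to_ast <- function(tok) {
  txt <- tok$text
  if (tok$type == "quoted") return(ast_term(txt))
  colon <- regexpr(":", txt, fixed = TRUE)
  if (colon > 0L) {
    path <- substr(txt, 1L, colon - 1L)
    value <- substr(txt, colon + 1L, nchar(txt))
    if (!nzchar(path)) stop(parse_error("missing field before ':'", tok$pos))
    if (!nzchar(value)) stop(parse_error("missing value after ':'", tok$pos))
    m <- regmatches(value, regexec("^(>=|<=|>|<)(.+)$", value))[[1]]
    if (length(m)) {
      num <- suppressWarnings(as.numeric(m[3]))
      if (is.na(num)) {
        stop(parse_error(sprintf("range needs a number, got `%s`", m[3]), tok$pos))
      }
      return(ast_range(path, m[2], num))
    }
    if (endsWith(value, "*") && tok$type == "word") {
      return(ast_wildcard(path, substr(value, 1L, nchar(value) - 1L)))
    }
    return(ast_field_term(path, value))
  }
  if (endsWith(txt, "*") && tok$type == "word") {
    return(ast_wildcard(NULL, substr(txt, 1L, nchar(txt) - 1L)))
  }
  ast_term(txt)
}
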