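# Parameterized SPARQL SELECT queries over AOP-Wiki-shaped triples.
#
# build_query() renders deterministic SPARQL 1.1 text for each entity kind.
# Because no SPARQL engine ships with the R library set, execution is split:
#   - local_file sources evaluate the query *plan* directly against the
#     parsed triple table (execute_plan);
#   - memory:// endpoints parse the rendered SPARQL text back into a plan
#     (parse_query) and evaluate it, exercising the text round trip;
#   - http(s) endpoints POST the text to a live SPARQL service.
# The restricted query shape is: SELECT vars / VALUES block / required
# triple patterns / single-pattern OPTIONALs / one FILTER ... IN over
# literals / ORDER BY the selected vars.

query_kinds_public <- c("aop", "ke", "ker", "gene_link", "author")
query_kinds_internal <- c("aop_ke", "aop_mie", "aop_ao", "ke_aop")

build_query_plan <- function(entity_kind, ids, status_filter = NULL,
                             vocabulary = default_vocabulary()) {
  check_vocabulary(vocabulary)
  kinds <- c(query_kinds_public, query_kinds_internal)
  if (!is.character(entity_kind) || length(entity_kind) != 1L ||
      !entity_kind %in% kinds) {
    stop("unknown entity_kind '", paste(entity_kind, collapse = ","),
         "'; expected one of: ", paste(query_kinds_public, collapse = ", "),
         call. = FALSE)
  }
  ids <- as.character(ids)
  if (!length(ids)) {
    stop("empty id list: '", entity_kind, "' queries are id-parameterized",
         call. = FALSE)
  }
  if (!is.null(status_filter)) {
    if (entity_kind != "aop") {
      stop("status_filter applies only to entity_kind 'aop'", call. = FALSE)
    }
    bad <- setdiff(status_filter, vocabulary$statuses)
    if (length(bad)) {
      stop("unknown status string(s): ", paste(bad, collapse = ", "),
           "; vocabulary defines: ",
           paste(vocabulary$statuses, collapse = ", "), call. = FALSE)
    }
  }
  rel <- function(name) vocab_relation(vocabulary, name)
  px <- vocabulary$prefixes
  iris <- function(ns) paste0(px[[ns]], sort_ids(ids))
  pat <- function(s, p, o) list(s = s, p = p, o = o)
  plan <- switch(entity_kind,
    aop = list(
      select = c("?aop", "?title", "?status"),
      values = list(var = "?aop", terms = iris("aop")),
      patterns = list(pat("?aop", RDF_TYPE, vocabulary$classes[["aop"]])),
      optionals = list(pat("?aop", rel("entity-title"), "?title"),
                       pat("?aop", rel("aop-status"), "?status")),
      filter = if (length(status_filter))
        list(var = "?status", set = sort(unique(status_filter)))
    ),
    ke = list(
      select = c("?ke", "?title"),
      values = list(var = "?ke", terms = iris("ke")),
      patterns = list(pat("?ke", RDF_TYPE, vocabulary$classes[["ke"]])),
      optionals = list(pat("?ke", rel("entity-title"), "?title")),
      filter = NULL
    ),
    ker = list(
      select = c("?aop", "?ker", "?upstream", "?downstream"),
      values = list(var = "?aop", terms = iris("aop")),
      patterns = list(pat("?aop", rel("aop-has-ker"), "?ker"),
                      pat("?ker", rel("ker-upstream-ke"), "?upstream"),
                      pat("?ker", rel("ker-downstream-ke"), "?downstream")),
      optionals = list(), filter = NULL
    ),
    gene_link = list(
      select = c("?ke", "?gene", "?genelabel"),
      values = list(var = "?ke", terms = iris("ke")),
      patterns = list(pat("?ke", rel("ke-gene"), "?gene")),
      optionals = list(pat("?gene", rel("entity-title"), "?genelabel")),
      filter = NULL
    ),
    author = list(
      select = c("?aop", "?author"),
      values = list(var = "?aop", terms = iris("aop")),
      patterns = list(pat("?aop", rel("aop-author"), "?author")),
      optionals = list(), filter = NULL
    ),
    aop_ke = list(
      select = c("?aop", "?ke"),
      values = list(var = "?aop", terms = iris("aop")),
      patterns = list(pat("?aop", rel("aop-has-ke"), "?ke")),
      optionals = list(), filter = NULL
    ),
    aop_mie = list(
      select = c("?aop", "?ke"),
      values = list(var = "?aop", terms = iris("aop")),
      patterns = list(pat("?aop", rel("aop-has-mie"), "?ke")),
      optionals = list(), filter = NULL
    ),
    aop_ao = list(
      select = c("?aop", "?ke"),
      values = list(var = "?aop", terms = iris("aop")),
      patterns = list(pat("?aop", rel("aop-has-ao"), "?ke")),
      optionals = list(), filter = NULL
    ),
    ke_aop = list(
      select = c("?ke", "?aop"),
      values = list(var = "?ke", terms = iris("ke")),
      patterns = list(pat("?aop", rel("aop-has-ke"), "?ke")),
      optionals = list(), filter = NULL
    )
  )
  plan
}

term_txt <- function(x) if (startsWith(x, "?")) x else paste0("<", x, ">")

render_query <- function(plan) {
  lines <- c(
    paste("SELECT", paste(plan$select, collapse = " ")),
    "WHERE {",
    paste0("  VALUES ", plan$values$var, " { ",
           paste0("<", plan$values$terms, ">", collapse = " "), " }")
  )
  for (p in plan$patterns) {
    lines <- c(lines, paste0("  ", term_txt(p$s), " ", term_txt(p$p), " ",
                             term_txt(p$o), " ."))
  }
  for (p in plan$optionals) {
    lines <- c(lines, paste0("  OPTIONAL { ", term_txt(p$s), " ",
                             term_txt(p$p), " ", term_txt(p$o), " . }"))
  }
  if (!is.null(plan$filter)) {
    lines <- c(lines, paste0("  FILTER ( ", plan$filter$var, " IN ( ",
                             paste0('"', ttl_escape(plan$filter$set), '"',
                                    collapse = ", "), " ) )"))
  }
  lines <- c(lines, "}",
             paste("ORDER BY", paste(plan$select, collapse = " ")))
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Build a SPARQL SELECT query for one entity kind
#'
#' Renders deterministic, id-parameterized SPARQL 1.1 text selecting AOPs,
#' Key Events, Key Event Relationships, KE-gene links or AOP authors from an
#' AOP-Wiki-shaped graph.  Identical inputs produce byte-identical text.
#'
#' @param entity_kind one of `"aop"`, `"ke"`, `"ker"`, `"gene_link"`,
#'   `"author"`.  `"aop"`/`"ke"` queries are parameterized by ids of that
#'   kind; `"ker"` and `"author"` by the asserting AOP ids; `"gene_link"` by
#'   KE ids.
#' @param ids nonempty character vector of bare numeric identifiers.
#' @param status_filter optional character vector of OECD status strings
#'   (only for `entity_kind = "aop"`); must come from
#'   `vocabulary$statuses`.
#' @param vocabulary see [default_vocabulary()].
#' @return SPARQL query text (character scalar).
#' @examples
#' cat(build_query("aop", c("12", "260")))
#' @export
build_query <- function(entity_kind, ids, status_filter = NULL,
                        vocabulary = default_vocabulary()) {
  if (!is.character(entity_kind) || length(entity_kind) != 1L ||
      !entity_kind %in% query_kinds_public) {
    stop("unknown entity_kind '", paste(entity_kind, collapse = ","),
         "'; expected one of: ", paste(query_kinds_public, collapse = ", "),
         call. = FALSE)
  }
  render_query(build_query_plan(entity_kind, ids, status_filter, vocabulary))
}

# Parse the restricted SPARQL shape render_query() emits back into a plan.
parse_query <- function(text) {
  lines <- trimws(strsplit(text, "\n", fixed = TRUE)[[1]])
  lines <- lines[nzchar(lines)]
  plan <- list(select = character(), values = NULL, patterns = list(),
               optionals = list(), filter = NULL)
  term_rx <- "(\\?[A-Za-z][A-Za-z0-9_]*|<[^>]*>)"
  unterm <- function(x) if (startsWith(x, "<")) substr(x, 2L, nchar(x) - 1L) else x
  for (ln in lines) {
    if (grepl("^SELECT ", ln)) {
      plan$select <- strsplit(sub("^SELECT ", "", ln), " ", fixed = TRUE)[[1]]
    } else if (grepl("^VALUES ", ln)) {
      m <- regmatches(ln, regexec("^VALUES (\\?[A-Za-z0-9_]+) \\{ (.*) \\}$", ln))[[1]]
      if (length(m) != 3L) stop("cannot parse VALUES clause: ", ln, call. = FALSE)
      terms <- regmatches(m[3], gregexpr("<[^>]*>", m[3]))[[1]]
      plan$values <- list(var = m[2], terms = vapply(terms, unterm, "", USE.NAMES = FALSE))
    } else if (grepl("^OPTIONAL \\{", ln)) {
      rx <- paste0("^OPTIONAL \\{ ", term_rx, " ", term_rx, " ", term_rx, " \\. \\}$")
      m <- regmatches(ln, regexec(rx, ln))[[1]]
      if (length(m) != 4L) stop("cannot parse OPTIONAL clause: ", ln, call. = FALSE)
      plan$optionals <- c(plan$optionals,
                          list(list(s = unterm(m[2]), p = unterm(m[3]), o = unterm(m[4]))))
    } else if (grepl("^FILTER ", ln)) {
      m <- regmatches(ln, regexec("^FILTER \\( (\\?[A-Za-z0-9_]+) IN \\( (.*) \\) \\)$", ln))[[1]]
      if (length(m) != 3L) stop("cannot parse FILTER clause: ", ln, call. = FALSE)
      vals <- regmatches(m[3], gregexpr('"(?:\\\\.|[^"\\\\])*"', m[3]))[[1]]
      plan$filter <- list(var = m[2],
                          set = ttl_unescape(substr(vals, 2L, nchar(vals) - 1L)))
    } else if (grepl(paste0("^", term_rx, " ", term_rx, " ", term_rx, " \\.$"), ln)) {
      m <- regmatches(ln, regexec(paste0("^", term_rx, " ", term_rx, " ",
                                         term_rx, " \\.$"), ln))[[1]]
      plan$patterns <- c(plan$patterns,
                         list(list(s = unterm(m[2]), p = unterm(m[3]), o = unterm(m[4]))))
    } else if (ln %in% c("WHERE {", "}") || grepl("^ORDER BY ", ln)) {
      # structural; ORDER BY is implied by the select list
    } else {
      stop("cannot parse query line: ", ln, call. = FALSE)
    }
  }
  if (is.null(plan$values) || !length(plan$select)) {
    stop("query lacks SELECT or VALUES clause", call. = FALSE)
  }
  plan
}

# Evaluate a plan against a triple table; returns a data.frame whose columns
# are the selected variable names (without '?'), character, NA = unbound.
execute_plan <- function(triples, plan) {
  varname <- function(v) substring(v, 2L)
  match_pattern <- function(p) {
    cand <- triples[triples$predicate == p$p, c("subject", "object")]
    if (!startsWith(p$s, "?")) cand <- cand[cand$subject == p$s, , drop = FALSE]
    if (!startsWith(p$o, "?")) cand <- cand[cand$object == p$o, , drop = FALSE]
    keep <- character(0)
    nms <- character(0)
    if (startsWith(p$s, "?")) { keep <- c(keep, "subject"); nms <- c(nms, varname(p$s)) }
    if (startsWith(p$o, "?")) { keep <- c(keep, "object"); nms <- c(nms, varname(p$o)) }
    out <- cand[, keep, drop = FALSE]
    names(out) <- nms
    if (!length(nms)) out <- data.frame(.exists = rep(TRUE, nrow(cand)))
    unique(out)
  }
  bind <- setNames(data.frame(plan$values$terms, stringsAsFactors = FALSE),
                   varname(plan$values$var))
  for (p in plan$patterns) {
    cand <- match_pattern(p)
    if (".exists" %in% names(cand)) {
      if (!nrow(cand)) bind <- bind[0, , drop = FALSE]
      next
    }
    shared <- intersect(names(bind), names(cand))
    bind <- if (length(shared)) merge(bind, cand, by = shared, sort = FALSE)
            else merge(bind, cand, by = NULL)
  }
  for (p in plan$optionals) {
    cand <- match_pattern(p)
    shared <- intersect(names(bind), names(cand))
    bind <- merge(bind, cand, by = shared, all.x = TRUE, sort = FALSE)
  }
  if (!is.null(plan$filter)) {
    v <- bind[[varname(plan$filter$var)]]
    bind <- bind[!is.na(v) & v %in% plan$filter$set, , drop = FALSE]
  }
  cols <- vapply(plan$select, varname, "")
  for (cl in setdiff(cols, names(bind))) bind[[cl]] <- NA_character_
  bind <- unique(bind[, cols, drop = FALSE])
  if (nrow(bind)) {
    bind <- bind[do.call(order, c(unname(bind), list(method = "radix"))), ,
                 drop = FALSE]
  }
  rownames(bind) <- NULL
  bind
}

# HTTP SPARQL SELECT (JSON results).  Unreachable in offline test runs; the
# memory:// endpoint exercises the same query-text path in-process.
sparql_http_select <- function(url, query, timeout = 30, retries = 2) {
  full <- paste0(url, if (grepl("\\?", url)) "&" else "?", "query=",
                 utils::URLencode(query, reserved = TRUE))
  attempt <- function() {
    con <- url(full, headers = c(Accept = "application/sparql-results+json"))
    on.exit(close(con), add = TRUE)
    paste(readLines(con, warn = FALSE), collapse = "\n")
  }
  txt <- NULL
  for (i in seq_len(retries + 1L)) {
    txt <- tryCatch(withr_timeout(attempt, timeout), error = function(e) e)
    if (!inherits(txt, "error")) break
  }
  if (inherits(txt, "error")) {
    stop("connectivity error: endpoint '", url, "' unreachable (",
         conditionMessage(txt), ")", call. = FALSE)
  }
  res <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  vars <- unlist(res$head$vars)
  rows <- res$results$bindings
  out <- setNames(as.data.frame(matrix(NA_character_, length(rows), length(vars)),
                                stringsAsFactors = FALSE), vars)
  for (i in seq_along(rows)) {
    for (v in names(rows[[i]])) out[i, v] <- rows[[i]][[v]]$value
  }
  out
}

withr_timeout <- function(f, timeout) {
  setTimeLimit(elapsed = timeout, transient = TRUE)
  on.exit(setTimeLimit(elapsed = Inf), add = TRUE)
  f()
}

# Execution context for one retrieval session: reads/parses the source once.
query_context <- function(source) {
  stopifnot(inherits(source, "rdf_source"))
  if (source$kind == "local_file") {
    if (!file.exists(source$locator)) {
      stop("connectivity error: cannot read RDF file '", source$locator, "'",
           call. = FALSE)
    }
    txt <- paste(readLines(source$locator, warn = FALSE), collapse = "\n")
    list(mode = "triples", triples = parse_turtle(txt), source = source)
  } else if (startsWith(source$locator, "memory://")) {
    trips <- memory_endpoint_triples(sub("^memory://", "", source$locator))
    list(mode = "text",
         exec = function(q) execute_plan(trips, parse_query(q)),
         source = source)
  } else {
    list(mode = "text",
         exec = function(q) sparql_http_select(source$locator, q,
                                               source$timeout, source$retries),
         source = source)
  }
}

run_query <- function(ctx, entity_kind, ids, status_filter = NULL) {
  plan <- build_query_plan(entity_kind, ids, status_filter,
                           ctx$source$vocabulary)
  if (ctx$mode == "triples") execute_plan(ctx$triples, plan)
  else ctx$exec(render_query(plan))
}
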