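#' Default AOP-Wiki-style RDF vocabulary
#'
#' The logical relation names used throughout the package mapped to concrete
#' RDF predicate IRIs, plus entity class IRIs, identifier namespace prefixes
#' and the recognised OECD status strings.  The defaults mirror the shape of
#' the public AOP-Wiki RDF schema; every piece is overridable so the package
#' survives upstream schema drift — pass a modified copy to
#' [rdf_source()].
#'
#' The ten logical relations are: `aop-has-ke`, `aop-has-mie`, `aop-has-ao`,
#' `aop-has-ker`, `ker-upstream-ke`, `ker-downstream-ke`, `entity-title`,
#' `aop-status`, `aop-author`, `ke-gene`.
#'
#' @return A list with components `relations` (named character, the ten
#'   logical relations), `classes` (IRIs for the AOP, KE and KER classes),
#'   `prefixes` (identifier namespaces used to shorten entity IRIs to bare
#'   ids) and `statuses` (recognised status strings for filtering).
#' @examples
#' v <- default_vocabulary()
#' v$relations[["entity-title"]]
#' @export
default_vocabulary <- function() {
  aopo <- "http://aopkb.org/aop_ontology#"
  dc <- "http://purl.org/dc/elements/1.1/"
  list(
    relations = c(
      `aop-has-ke` = paste0(aopo, "has_key_event"),
      `aop-has-mie` = paste0(aopo, "has_molecular_initiating_event"),
      `aop-has-ao` = paste0(aopo, "has_adverse_outcome"),
      `aop-has-ker` = paste0(aopo, "has_key_event_relationship"),
      `ker-upstream-ke` = paste0(aopo, "has_upstream_key_event"),
      `ker-downstream-ke` = paste0(aopo, "has_downstream_key_event"),
      `entity-title` = paste0(dc, "title"),
      `aop-status` = paste0(aopo, "has_oecd_status"),
      `aop-author` = paste0(dc, "creator"),
      `ke-gene` = paste0(aopo, "has_gene")
    ),
    classes = c(
      aop = paste0(aopo, "AdverseOutcomePathway"),
      ke = paste0(aopo, "KeyEvent"),
      ker = paste0(aopo, "KeyEventRelationship")
    ),
    prefixes = c(
      aop = "https://identifiers.org/aop/",
      ke = "https://identifiers.org/aop.events/",
      ker = "https://identifiers.org/aop.relationships/",
      gene = "https://identifiers.org/hgnc/"
    ),
    statuses = c("Under Development", "Under Review", "Endorsed")
  )
}

#' Look up a logical relation in a vocabulary
#'
#' Fails loudly on an unknown relation name rather than silently matching
#' nothing.
#'
#' @param vocabulary a vocabulary list, see [default_vocabulary()].
#' @param name one of the ten logical relation names.
#' @return The predicate IRI (character scalar).
#' @export
vocab_relation <- function(vocabulary, name) {
  stopifnot(is.list(vocabulary), is.character(name), length(name) == 1L)
  if (!name %in% names(vocabulary$relations)) {
    stop("unknown logical relation '", name, "'; vocabulary defines: ",
         paste(names(vocabulary$relations), collapse = ", "), call. = FALSE)
  }
  unname(vocabulary$relations[[name]])
}

check_vocabulary <- function(vocabulary) {
  required <- names(default_vocabulary()$relations)
  missing <- setdiff(required, names(vocabulary$relations))
  if (length(missing)) {
    stop("vocabulary is missing logical relations: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Describe an RDF source
#'
#' An `rdf_source` bundles where AOP-Wiki-shaped triples live (a local Turtle
#' file, an HTTP SPARQL endpoint, or an in-process `memory://` endpoint
#' registered with [register_memory_endpoint()]) with the vocabulary used to
#' interpret them.  All retrieval goes through this object so that the rest
#' of the package is oblivious to network I/O.
#'
#' @param locator file path (for `kind = "local_file"`) or endpoint URL
#'   (`http(s)://...` or `memory://<name>`).
#' @param kind `"local_file"` or `"endpoint"`; defaults to `"endpoint"` when
#'   the locator looks like a URL, `"local_file"` otherwise.
#' @param vocabulary see [default_vocabulary()].
#' @param timeout request timeout in seconds (endpoints only).
#' @param retries number of retries after a failed request (endpoints only).
#' @return An object of class `rdf_source`.
#' @examples
#' ttl <- tempfile(fileext = ".ttl")
#' writeLines(case_study_fixture()$turtle, ttl)
#' src <- rdf_source(ttl)
#' src$kind
#' @export
rdf_source <- function(locator, kind = NULL, vocabulary = default_vocabulary(),
                       timeout = 30, retries = 2) {
  stopifnot(is.character(locator), length(locator) == 1L)
  if (!nzchar(locator)) stop("locator must be nonempty", call. = FALSE)
  if (is.null(kind)) {
    kind <- if (grepl("^(https?|memory)://", locator)) "endpoint" else "local_file"
  }
  kind <- match.arg(kind, c("local_file", "endpoint"))
  check_vocabulary(vocabulary)
  structure(
    list(kind = kind, locator = locator, vocabulary = vocabulary,
         timeout = timeout, retries = retries),
    class = "rdf_source"
  )
}

#' @export
print.rdf_source <- function(x, ...) {
  cat("<rdf_source> ", x$kind, ": ", x$locator, "\n", sep = "")
  invisible(x)
}

# registry for in-process endpoints (used to exercise the SPARQL text path
# without network access)
.memory_endpoints <- new.env(parent = emptyenv())

#' Register an in-process SPARQL endpoint
#'
#' Stores a triple table under `memory://<name>` so that an
#' `rdf_source(kind = "endpoint")` can be queried without any network: the
#' SPARQL text produced by [build_query()] is parsed back and evaluated
#' against the stored triples.  Useful for tests and offline work.
#'
#' @param name endpoint name (the part after `memory://`).
#' @param triples a triple table as returned by [parse_turtle()].
#' @return The `memory://` locator, invisibly.
#' @export
register_memory_endpoint <- function(name, triples) {
  stopifnot(is.character(name), length(name) == 1L, is.data.frame(triples))
  assign(name, triples, envir = .memory_endpoints)
  invisible(paste0("memory://", name))
}

memory_endpoint_triples <- function(name) {
  if (!exists(name, envir = .memory_endpoints, inherits = FALSE)) {
    stop("no in-process endpoint registered under 'memory://", name, "'",
         call. = FALSE)
  }
  get(name, envir = .memory_endpoints, inherits = FALSE)
}

# Strip a known identifier namespace from an IRI, returning the bare id
# (users cite "AOP 12", not IRIs).  Unknown namespaces are returned intact.
strip_iri <- function(iri, prefixes) {
  out <- iri
  for (p in prefixes) {
    hit <- startsWith(out, p)
    out[hit] <- substring(out[hit], nchar(p) + 1L)
  }
  out
}

# Deterministic id ordering: numeric ids sort numerically, anything else
# lexicographically after them.
sort_ids <- function(x) {
  if (!length(x)) return(character(0))
  x <- unique(as.character(x))
  num <- suppressWarnings(as.numeric(x))
  is_num <- !is.na(num)
  c(x[is_num][order(num[is_num])], sort(x[!is_num]))
}

id_lt <- function(a, b) {
  o <- sort_ids(c(a, b))
  length(o) == 2L && o[[1L]] == a
}
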