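# Minimal Turtle reader/writer.
#
# The R library set ships no RDF engine, so this file implements the small
# Turtle subset the AOP-Wiki-shaped sources use: @prefix declarations,
# <IRI> and prefix:local terms, double-quoted plain literals with \" \\ \n
# \t escapes, the 'a' keyword, and ';' / ',' predicate-object lists.
# Datatyped/lang-tagged literals, blank nodes and collections are out of
# scope and rejected.  Triples are represented as a data.frame with columns
# subject, predicate, object (full IRIs or literal text) and object_type
# ("iri" or "literal").

triple_frame <- function(subject = character(), predicate = character(),
                         object = character(), object_type = character()) {
  data.frame(subject = as.character(subject),
             predicate = as.character(predicate),
             object = as.character(object),
             object_type = as.character(object_type),
             stringsAsFactors = FALSE)
}

ttl_tokenize <- function(text) {
  re <- paste0(
    '<[^>]*>',                                  # IRI
    '|"(?:\\\\.|[^"\\\\])*"',                   # quoted literal
    '|#[^\n]*',                                 # comment
    '|@prefix|@base',
    '|[;,.]',
    '|[A-Za-z][A-Za-z0-9_.+-]*:[A-Za-z0-9_.+-]*', # prefixed name
    '|\\ba\\b'
  )
  m <- gregexpr(re, text, perl = TRUE)[[1]]
  if (m[1] == -1) return(character(0))
  toks <- regmatches(text, list(m))[[1]]
  toks <- toks[!startsWith(toks, "#")]
  # a prefixed name may have swallowed a statement-terminating dot
  fix <- grepl(":", toks, fixed = TRUE) & endsWith(toks, ".") &
    !startsWith(toks, "<") & !startsWith(toks, '"')
  if (any(fix)) {
    out <- character(0)
    for (i in seq_along(toks)) {
      if (fix[i]) out <- c(out, sub("\\.$", "", toks[i]), ".") else out <- c(out, toks[i])
    }
    toks <- out
  }
  toks
}

ttl_unescape <- function(s) {
  s <- gsub("\\\\n", "\n", s)
  s <- gsub("\\\\t", "\t", s)
  s <- gsub('\\\\"', '"', s)
  gsub("\\\\\\\\", "\\\\", s)
}

ttl_escape <- function(s) {
  s <- gsub("\\\\", "\\\\\\\\", s)
  s <- gsub('"', '\\\\"', s)
  s <- gsub("\n", "\\\\n", s)
  gsub("\t", "\\\\t", s)
}

RDF_TYPE <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"

#' Parse Turtle text into a triple table
#'
#' Supports the Turtle subset used by AOP-Wiki-shaped sources (see the
#' package fixtures): prefix declarations, IRIs, prefixed names, plain
#' string literals and predicate-object lists.
#'
#' @param text Turtle source, a character scalar (or vector of lines).
#' @return A data.frame with columns `subject`, `predicate`, `object`
#'   (full IRIs / literal text) and `object_type` (`"iri"` or `"literal"`).
#' @examples
#' parse_turtle('@@prefix ex: <http://example.org/> . ex:s ex:p "v" .')
#' @export
parse_turtle <- function(text) {
  text <- paste(text, collapse = "\n")
  toks <- ttl_tokenize(text)
  prefixes <- c(rdf = "http://www.w3.org/1999/02/22-rdf-syntax-ns#")
  expand <- function(tok, what) {
    if (startsWith(tok, "<")) return(substr(tok, 2L, nchar(tok) - 1L))
    if (tok == "a") return(RDF_TYPE)
    colon <- regexpr(":", tok, fixed = TRUE)
    if (colon < 1L) stop("malformed RDF: expected IRI or prefixed name for ",
                         what, ", got '", tok, "'", call. = FALSE)
    p <- substr(tok, 1L, colon - 1L)
    if (!p %in% names(prefixes)) {
      stop("malformed RDF: undeclared prefix '", p, ":' in '", tok, "'",
           call. = FALSE)
    }
    paste0(prefixes[[p]], substring(tok, colon + 1L))
  }
  subs <- preds <- objs <- types <- character(0)
  i <- 1L
  n <- length(toks)
  peek <- function() if (i <= n) toks[i] else ""
  take <- function() { t <- toks[i]; i <<- i + 1L; t }
  while (i <= n) {
    tok <- take()
    if (tok == "@prefix") {
      pname <- take()
      iri <- take()
      dot <- take()
      if (!endsWith(pname, ":") || !startsWith(iri, "<") || dot != ".")
        stop("malformed RDF: bad @prefix declaration near '", pname, "'",
             call. = FALSE)
      prefixes[[sub(":$", "", pname)]] <- substr(iri, 2L, nchar(iri) - 1L)
      next
    }
    if (tok == "@base") stop("malformed RDF: @base is not supported", call. = FALSE)
    subj <- expand(tok, "subject")
    repeat {
      pred <- expand(take(), "predicate")
      repeat {
        otok <- take()
        if (startsWith(otok, '"')) {
          objs <- c(objs, ttl_unescape(substr(otok, 2L, nchar(otok) - 1L)))
          types <- c(types, "literal")
        } else {
          objs <- c(objs, expand(otok, "object"))
          types <- c(types, "iri")
        }
        subs <- c(subs, subj)
        preds <- c(preds, pred)
        if (peek() == ",") { take(); next }
        break
      }
      if (peek() == ";") { take(); if (peek() == ".") { take(); break }; next }
      if (peek() == ".") { take(); break }
      if (i > n) stop("malformed RDF: statement not terminated by '.'",
                      call. = FALSE)
    }
  }
  triple_frame(subs, preds, objs, types)
}

compact_iri <- function(iri, prefixes) {
  out <- paste0("<", iri, ">")
  for (nm in names(prefixes)) {
    p <- prefixes[[nm]]
    local <- substring(iri, nchar(p) + 1L)
    hit <- startsWith(iri, p) & nchar(iri) > nchar(p) &
      grepl("^[A-Za-z0-9_.+-]+$", local)
    out[hit] <- paste0(nm, ":", local[hit])
  }
  out
}

#' Serialize a triple table to Turtle
#'
#' Deterministic output: prefixes, subjects, predicates and objects are
#' emitted in sorted (byte) order, so identical triple tables produce
#' byte-identical Turtle.
#'
#' @param triples a triple table, see [parse_turtle()].
#' @param prefixes named character vector, prefix name to namespace IRI.
#' @return Turtle text, a character scalar.
#' @export
write_turtle <- function(triples, prefixes = character()) {
  stopifnot(is.data.frame(triples))
  prefixes <- c(prefixes, c(rdf = "http://www.w3.org/1999/02/22-rdf-syntax-ns#"))
  prefixes <- prefixes[!duplicated(names(prefixes))]
  prefixes <- prefixes[order(names(prefixes), method = "radix")]
  out <- sprintf("@prefix %s: <%s> .", names(prefixes), unname(prefixes))
  if (nrow(triples)) {
    t2 <- triples[order(triples$subject, triples$predicate, triples$object,
                        method = "radix"), , drop = FALSE]
    obj_txt <- ifelse(t2$object_type == "literal",
                      paste0('"', ttl_escape(t2$object), '"'),
                      compact_iri(t2$object, prefixes))
    pred_txt <- ifelse(t2$predicate == RDF_TYPE, "a",
                       compact_iri(t2$predicate, prefixes))
    subj_txt <- compact_iri(t2$subject, prefixes)
    out <- c(out, "")
    for (s in unique(subj_txt)) {
      rows <- which(subj_txt == s)
      lines <- paste0("    ", pred_txt[rows], " ", obj_txt[rows])
      sep <- c(rep(" ;", length(rows) - 1L), " .")
      out <- c(out, s, paste0(lines, sep))
    }
  }
  paste0(paste(out, collapse = "\n"), "\n")
}
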