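# Retrieval: turn query results into a raw entity bundle.

empty_df <- function(...) {
  cols <- c(...)
  setNames(as.data.frame(replicate(length(cols), character(0),
                                   simplify = FALSE)), cols)
}

new_bundle <- function(aops, memberships, key_events, kers, gene_links,
                       authors, warnings, missing = character(0)) {
  structure(
    list(aops = aops, memberships = memberships, key_events = key_events,
         kers = kers, gene_links = gene_links, authors = authors,
         warnings = warnings, missing = missing,
         retrieved_at = format(Sys.time(), tz = "UTC")),
    class = "aop_bundle"
  )
}

#' Retrieve a raw AOP bundle from an RDF source
#'
#' Fetches the requested AOPs and/or Key Events together with all Key Event
#' Relationships asserted by the requested AOPs, the gene links of the
#' retrieved KEs, and the AOP authors.  Requested-but-absent ids are reported
#' in the bundle's `warnings`, never as an error.  When KEs are requested
#' directly, the AOPs containing them are included as context records
#' (title, status, authors, and membership for the requested KEs only) so
#' every retrieved KE has a pathway of origin; their full chains are not
#' expanded.
#'
#' @param source an [rdf_source()].
#' @param aop_ids,ke_ids character vectors of bare numeric ids; at least one
#'   must be nonempty.
#' @param status_filter optional status strings; AOPs with another status are
#'   dropped with a warning entry.
#' @param log optional [audit_log()]; when given, a `fetch` entry plus one
#'   `credit` entry per retrieved AOP (BY-SA author credit) are appended.
#' @return An object of class `aop_bundle` with data.frame components
#'   `aops` (aop_id, title, status), `memberships` (aop_id, ke_id, role),
#'   `key_events` (ke_id, title, source_iri), `kers` (ker_id, upstream,
#'   downstream, aop_id), `gene_links` (ke_id, gene_id, gene_label),
#'   `authors` (aop_id, author), plus `warnings` and `retrieved_at`.
#' @examples
#' ttl <- tempfile(fileext = ".ttl")
#' writeLines(case_study_fixture()$turtle, ttl)
#' b <- fetch_bundle(rdf_source(ttl), aop_ids = c("12", "260"))
#' nrow(b$aops)
#' @export
fetch_bundle <- function(source, aop_ids = character(), ke_ids = character(),
                         status_filter = NULL, log = NULL) {
  aop_ids <- sort_ids(as.character(aop_ids))
  ke_ids <- sort_ids(as.character(ke_ids))
  if (!length(aop_ids) && !length(ke_ids)) {
    stop("at least one of aop_ids, ke_ids must be nonempty", call. = FALSE)
  }
  ctx <- query_context(source)
  voc <- source$vocabulary
  px <- voc$prefixes
  bare <- function(x) strip_iri(x, px)
  warnings <- character(0)

  # --- directly requested KEs: reverse-lookup their containing AOPs -------
  context_aops <- character(0)
  requested_ke_rows <- empty_df("ke_id", "aop_id")
  if (length(ke_ids)) {
    rev <- run_query(ctx, "ke_aop", ke_ids)
    if (nrow(rev)) {
      requested_ke_rows <- data.frame(ke_id = bare(rev$ke),
                                      aop_id = bare(rev$aop))
      context_aops <- setdiff(sort_ids(requested_ke_rows$aop_id), aop_ids)
    }
  }
  all_aop_ids <- sort_ids(c(aop_ids, context_aops))

  # --- AOP records (status filter applies to directly requested AOPs) -----
  aops <- empty_df("aop_id", "title", "status")
  if (length(all_aop_ids)) {
    res <- run_query(ctx, "aop", all_aop_ids)
    if (nrow(res)) {
      aops <- data.frame(aop_id = bare(res$aop),
                         title = ifelse(is.na(res$title), "", res$title),
                         status = ifelse(is.na(res$status), "", res$status))
    }
  }
  missing_aops <- setdiff(aop_ids, aops$aop_id)
  if (length(missing_aops)) {
    warnings <- c(warnings, paste0("requested AOP not found in source: ",
                                   missing_aops))
  }
  if (length(status_filter)) {
    bad_status <- setdiff(status_filter, voc$statuses)
    if (length(bad_status)) {
      stop("unknown status string(s): ", paste(bad_status, collapse = ", "),
           call. = FALSE)
    }
    drop <- aops$aop_id %in% aop_ids & !aops$status %in% status_filter
    if (any(drop)) {
      warnings <- c(warnings,
                    paste0("AOP ", aops$aop_id[drop], " excluded by status filter (status '",
                           aops$status[drop], "')"))
      aops <- aops[!drop, , drop = FALSE]
    }
  }
  found_aops <- intersect(aop_ids, aops$aop_id)
  context_aops <- intersect(context_aops, aops$aop_id)

  # --- memberships and roles for fully requested AOPs ----------------------
  memberships <- empty_df("aop_id", "ke_id", "role")
  if (length(found_aops)) {
    kes <- run_query(ctx, "aop_ke", found_aops)
    mies <- run_query(ctx, "aop_mie", found_aops)
    aos <- run_query(ctx, "aop_ao", found_aops)
    if (nrow(kes)) {
      m <- data.frame(aop_id = bare(kes$aop), ke_id = bare(kes$ke))
      mie_key <- paste(bare(mies$aop), bare(mies$ke))
      ao_key <- paste(bare(aos$aop), bare(aos$ke))
      key <- paste(m$aop_id, m$ke_id)
      m$role <- ifelse(key %in% mie_key, "MIE",
                       ifelse(key %in% ao_key, "AO", "KE"))
      memberships <- m
    }
  }
  # context memberships for directly requested KEs (role KE/MIE/AO unknown
  # without chain expansion; recorded as plain KE)
  if (nrow(requested_ke_rows)) {
    ctx_rows <- requested_ke_rows[requested_ke_rows$aop_id %in% context_aops, ,
                                  drop = FALSE]
    if (nrow(ctx_rows)) {
      memberships <- rbind(memberships,
                           data.frame(aop_id = ctx_rows$aop_id,
                                      ke_id = ctx_rows$ke_id, role = "KE"))
      warnings <- c(warnings,
                    paste0("AOP ", sort_ids(ctx_rows$aop_id),
                           " included as context for directly requested KEs"))
    }
  }
  memberships <- unique(memberships)

  # --- KERs: only those asserted by the requested (and retained) AOPs ------
  kers <- empty_df("ker_id", "upstream", "downstream", "aop_id")
  if (length(found_aops)) {
    res <- run_query(ctx, "ker", found_aops)
    if (nrow(res)) {
      kers <- data.frame(ker_id = bare(res$ker),
                         upstream = bare(res$upstream),
                         downstream = bare(res$downstream),
                         aop_id = bare(res$aop))
    }
  }

  # --- KE records: members + requested + KER endpoints ---------------------
  want_kes <- sort_ids(c(memberships$ke_id, ke_ids, kers$upstream,
                         kers$downstream))
  key_events <- empty_df("ke_id", "title", "source_iri")
  if (length(want_kes)) {
    res <- run_query(ctx, "ke", want_kes)
    if (nrow(res)) {
      key_events <- data.frame(ke_id = bare(res$ke),
                               title = ifelse(is.na(res$title), "", res$title),
                               source_iri = res$ke)
    }
  }
  missing_kes <- setdiff(ke_ids, key_events$ke_id)
  if (length(missing_kes)) {
    warnings <- c(warnings, paste0("requested KE not found in source: ",
                                   missing_kes))
  }
  # a KER endpoint not typed as a KE in the source still becomes a record so
  # referential integrity holds; flagged, never fatal
  dangling <- setdiff(c(kers$upstream, kers$downstream), key_events$ke_id)
  if (length(dangling)) {
    dangling <- sort_ids(dangling)
    warnings <- c(warnings, paste0("KER endpoint KE ", dangling,
                                   " has no KeyEvent record in source"))
    key_events <- rbind(key_events,
                        data.frame(ke_id = dangling, title = "",
                                   source_iri = paste0(px[["ke"]], dangling)))
  }
  memberships <- memberships[memberships$ke_id %in% key_events$ke_id, ,
                             drop = FALSE]
  orphan <- setdiff(key_events$ke_id, memberships$ke_id)
  if (length(orphan)) {
    warnings <- c(warnings, paste0("KE ", sort_ids(orphan),
                                   " has no retrieved AOP membership"))
  }

  # --- gene links ----------------------------------------------------------
  gene_links <- empty_df("ke_id", "gene_id", "gene_label")
  if (nrow(key_events)) {
    res <- run_query(ctx, "gene_link", sort_ids(key_events$ke_id))
    if (nrow(res)) {
      gene_links <- data.frame(ke_id = bare(res$ke), gene_id = bare(res$gene),
                               gene_label = ifelse(is.na(res$genelabel),
                                                   bare(res$gene), res$genelabel))
    }
  }

  # --- authors -------------------------------------------------------------
  authors <- empty_df("aop_id", "author")
  if (nrow(aops)) {
    authors <- fetch_authors_ctx(ctx, sort_ids(aops$aop_id))
    no_auth <- setdiff(aops$aop_id, authors$aop_id)
    if (length(no_auth)) {
      warnings <- c(warnings, paste0("AOP ", sort_ids(no_auth),
                                     " has no author information"))
    }
  }

  ord <- function(df, cols) {
    if (!nrow(df)) return(df)
    df <- unique(df)
    df <- df[do.call(order, c(unname(df[cols]), list(method = "radix"))), ,
             drop = FALSE]
    rownames(df) <- NULL
    df
  }
  missing_requested <- sort_ids(c(missing_aops, missing_kes))
  bundle <- new_bundle(
    aops = ord(aops, "aop_id"),
    memberships = ord(memberships, c("aop_id", "ke_id")),
    key_events = ord(key_events, "ke_id"),
    kers = ord(kers, c("ker_id", "aop_id")),
    gene_links = ord(gene_links, c("ke_id", "gene_id")),
    authors = ord(authors, c("aop_id", "author")),
    warnings = warnings,
    missing = missing_requested
  )
  validate_bundle(bundle)
  if (!is.null(log)) {
    record(log, "fetch",
           parameters = list(aop_ids = aop_ids, ke_ids = ke_ids,
                             status_filter = status_filter %||% character(0),
                             source = source$locator),
           affected_ids = sort_ids(c(bundle$aops$aop_id,
                                     bundle$key_events$ke_id)))
    credit_authors(log, bundle$authors, all_aops = sort_ids(bundle$aops$aop_id))
  }
  bundle
}

fetch_authors_ctx <- function(ctx, aop_ids) {
  res <- run_query(ctx, "author", aop_ids)
  px <- ctx$source$vocabulary$prefixes
  out <- if (nrow(res)) {
    data.frame(aop_id = strip_iri(res$aop, px), author = res$author)
  } else empty_df("aop_id", "author")
  out <- unique(out)
  out <- out[order(suppressWarnings(as.numeric(out$aop_id)), out$aop_id,
                   out$author, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Retrieve (AOP, author) pairs for BY-SA credit
#'
#' @param source an [rdf_source()].
#' @param aop_ids nonempty character vector of AOP ids.
#' @return data.frame with columns `aop_id`, `author`, sorted by AOP id then
#'   author name; AOPs without author triples contribute no rows (the caller
#'   sees the gap in [fetch_bundle()]'s warnings).
#' @export
fetch_authors <- function(source, aop_ids) {
  aop_ids <- sort_ids(as.character(aop_ids))
  if (!length(aop_ids)) stop("aop_ids must be nonempty", call. = FALSE)
  fetch_authors_ctx(query_context(source), aop_ids)
}

validate_bundle <- function(bundle) {
  stopifnot(inherits(bundle, "aop_bundle"))
  dup <- function(x, what) {
    d <- unique(x[duplicated(x)])
    if (length(d)) stop("duplicate ", what, " id(s): ",
                        paste(d, collapse = ", "), call. = FALSE)
  }
  # exact duplicate records are legal (and deduplicated at assembly);
  # two *different* records under one id are a conflict
  dup(unique(bundle$aops)$aop_id, "AOP")
  dup(unique(bundle$key_events)$ke_id, "KE")
  u <- unique(bundle$kers[c("ker_id", "upstream", "downstream")])
  dup(u$ker_id, "KER")
  miss <- setdiff(c(bundle$kers$upstream, bundle$kers$downstream),
                  bundle$key_events$ke_id)
  if (length(miss)) {
    stop("bundle integrity: KER endpoint(s) missing from key_events: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  miss <- setdiff(bundle$gene_links$ke_id, bundle$key_events$ke_id)
  if (length(miss)) {
    stop("bundle integrity: gene_link KE(s) missing from key_events: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.aop_bundle <- function(x, ...) {
  cat("<aop_bundle> ", nrow(x$aops), " AOPs, ", nrow(x$key_events),
      " KEs, ", nrow(unique(x$kers[c("ker_id", "upstream", "downstream")])),
      " KERs, ", nrow(x$gene_links), " gene links, ", nrow(x$authors),
      " author pairs\n", sep = "")
  if (length(x$warnings)) {
    cat("warnings:\n")
    cat(paste0("  - ", x$warnings, collapse = "\n"), "\n")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a bundle as JSON
#'
#' Plain-JSON persistence for `aop_bundle` objects, used by the command-line
#' session to hand the retrieval result from `fetch` to `build`.
#'
#' @param bundle an `aop_bundle`.
#' @param path file path.
#' @return `write_bundle` returns `path` invisibly; `read_bundle` the bundle.
#' @export
write_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "aop_bundle"))
  x <- unclass(bundle)
  jsonlite::write_json(x, path, dataframe = "columns", auto_unbox = FALSE,
                       null = "list", pretty = FALSE)
  invisible(path)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  as_chr_df <- function(df, cols) {
    if (is.null(df) || !length(df) || (is.data.frame(df) && !nrow(df))) {
      return(empty_df(cols))
    }
    df <- as.data.frame(df, stringsAsFactors = FALSE)
    for (cl in cols) df[[cl]] <- as.character(df[[cl]])
    df[cols]
  }
  b <- new_bundle(
    aops = as_chr_df(x$aops, c("aop_id", "title", "status")),
    memberships = as_chr_df(x$memberships, c("aop_id", "ke_id", "role")),
    key_events = as_chr_df(x$key_events, c("ke_id", "title", "source_iri")),
    kers = as_chr_df(x$kers, c("ker_id", "upstream", "downstream", "aop_id")),
    gene_links = as_chr_df(x$gene_links, c("ke_id", "gene_id", "gene_label")),
    authors = as_chr_df(x$authors, c("aop_id", "author")),
    warnings = as.character(unlist(x$warnings)),
    missing = as.character(unlist(x$missing))
  )
  b$retrieved_at <- as.character(unlist(x$retrieved_at))
  b
}
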