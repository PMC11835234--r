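# Replayable audit logging.
#
# Every retrieval and network-altering operation appends one structured
# entry; the log is a JSON-lines file that can be replayed against an RDF
# source to regenerate the network ("the recipe, not the snapshot": if the
# source changed, the replayed network legitimately reflects the change).
# The log is an append-only environment so entries accumulate across the
# value-semantics network objects that share it.

AUDIT_ACTIONS <- c("fetch", "assemble", "filter_status", "merge", "ego",
                   "export", "credit")

required_params <- function(action) {
  switch(action,
    fetch = c("aop_ids", "ke_ids"),
    assemble = character(0),
    filter_status = "allowed",
    merge = c("keep_id", "drop_id", "merged_label"),
    ego = c("seed_ke_ids", "degree", "include_genes"),
    export = c("format", "path"),
    credit = c("aop_id", "authors")
  )
}

#' Create an empty audit log
#'
#' The log is anonymous by default (no user identifier is recorded); pass an
#' `actor` label only if you explicitly want one attached to every entry.
#'
#' @param actor optional actor label.
#' @return An object of class `audit_log` (an append-only environment).
#' @export
audit_log <- function(actor = NULL) {
  log <- new.env(parent = emptyenv())
  log$entries <- list()
  log$created_at <- format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  log$actor <- actor
  class(log) <- "audit_log"
  log
}

#' Append one entry to an audit log
#'
#' @param log an [audit_log()].
#' @param action one of `fetch`, `assemble`, `filter_status`, `merge`,
#'   `ego`, `export`, `credit`.
#' @param parameters named list; values are coerced to character vectors.
#'   Each action has required parameter names (e.g. `merge` requires
#'   `keep_id`, `drop_id`, `merged_label`); a missing one is a validation
#'   error naming it.
#' @param affected_ids character vector of entity ids the action touched.
#' @return The appended entry (a list), invisibly equal to the last entry of
#'   the log.
#' @export
record <- function(log, action, parameters = list(), affected_ids = character()) {
  stopifnot(inherits(log, "audit_log"))
  if (!is.character(action) || length(action) != 1L ||
      !action %in% AUDIT_ACTIONS) {
    stop("unknown audit action '", paste(action, collapse = ","),
         "'; expected one of: ", paste(AUDIT_ACTIONS, collapse = ", "),
         call. = FALSE)
  }
  miss <- setdiff(required_params(action), names(parameters))
  if (length(miss)) {
    stop("audit entry for action '", action,
         "' is missing required parameter(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  parameters <- lapply(parameters, function(v) as.character(v %||% character(0)))
  if (!is.null(log$actor)) parameters$actor <- as.character(log$actor)
  entry <- list(
    sequence_number = length(log$entries) + 1L,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    action = action,
    parameters = parameters,
    affected_ids = as.character(affected_ids),
    tool_version = as.character(utils::packageVersion("aopnetworkr"))
  )
  log$entries[[entry$sequence_number]] <- entry
  invisible(entry)
}

#' Record BY-SA author-credit entries
#'
#' One `credit` entry per AOP, listing its authors in stable order, so a
#' downloaded log always names the original pathway creators.  An AOP
#' without author information still gets a credit entry, flagged with
#' `missing_authors`.
#'
#' @param log an [audit_log()].
#' @param author_pairs data.frame with columns `aop_id`, `author` (as from
#'   [fetch_authors()]).
#' @param all_aops optional AOP ids that must receive a credit entry even if
#'   they contribute no author pairs.
#' @return List of the appended entries, invisibly.
#' @export
credit_authors <- function(log, author_pairs, all_aops = NULL) {
  stopifnot(inherits(log, "audit_log"), is.data.frame(author_pairs))
  aops <- sort_ids(c(author_pairs$aop_id, all_aops))
  entries <- lapply(aops, function(id) {
    auth <- sort(author_pairs$author[author_pairs$aop_id == id])
    record(log, "credit",
           parameters = list(aop_id = id, authors = auth,
                             missing_authors = as.character(length(auth) == 0L)),
           affected_ids = id)
  })
  invisible(entries)
}

entry_to_json <- function(entry) {
  box <- jsonlite::unbox
  params <- lapply(entry$parameters, as.character)
  as.character(jsonlite::toJSON(
    list(sequence_number = box(as.integer(entry$sequence_number)),
         timestamp = box(entry$timestamp),
         action = box(entry$action),
         parameters = params,
         affected_ids = as.character(entry$affected_ids),
         tool_version = box(entry$tool_version)),
    auto_unbox = FALSE, null = "null"))
}

#' Write / read an audit log as JSON lines
#'
#' One entry per line; `read_log(write_log(log))` reproduces the log
#' field-for-field.  A malformed line is a parse error citing its line
#' number.
#'
#' @param log an [audit_log()].
#' @param path file path.
#' @return `write_log` returns `path` invisibly; `read_log` the log.
#' @export
write_log <- function(log, path) {
  stopifnot(inherits(log, "audit_log"))
  lines <- vapply(log$entries, entry_to_json, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_log
#' @export
read_log <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  log <- audit_log()
  log$entries <- lapply(seq_along(lines), function(i) {
    x <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
                  error = function(e) NULL)
    ok <- !is.null(x) && all(c("sequence_number", "timestamp", "action",
                               "parameters", "affected_ids", "tool_version")
                             %in% names(x))
    if (!ok) stop("audit log parse error at line ", i, " of '", path, "'",
                  call. = FALSE)
    params <- lapply(as.list(x$parameters), as.character)
    list(sequence_number = as.integer(x$sequence_number),
         timestamp = as.character(x$timestamp),
         action = as.character(x$action),
         parameters = params,
         affected_ids = as.character(unlist(x$affected_ids) %||% character(0)),
         tool_version = as.character(x$tool_version))
  })
  seqs <- vapply(log$entries, `[[`, 1L, "sequence_number")
  if (length(seqs) && !identical(seqs, seq_along(seqs))) {
    stop("audit log sequence numbers are not gapless from 1 in '", path, "'",
         call. = FALSE)
  }
  log
}

#' @export
print.audit_log <- function(x, ...) {
  cat("<audit_log> ", length(x$entries), " entries\n", sep = "")
  for (e in x$entries) {
    cat(sprintf("  %3d %-13s [%s]\n", e$sequence_number, e$action,
                paste(utils::head(e$affected_ids, 5L), collapse = ", ")))
  }
  invisible(x)
}

#' Replay an audit log against an RDF source
#'
#' Re-executes the `fetch`, `assemble`, `filter_status`, `merge` and `ego`
#' entries in sequence; `export` and `credit` entries are skipped.  On an
#' unchanged source the result is canonically identical (see
#' [canonical_json()]) to the network whose session wrote the log; on a
#' changed source the replayed network reflects the current data — which is
#' the point of keeping the recipe rather than a snapshot.  Timestamps play
#' no role in replay.
#'
#' @param log an [audit_log()] (typically from [read_log()]).
#' @param source an [rdf_source()].
#' @return The regenerated `aop_network` (empty network for an empty log).
#' @export
replay <- function(log, source) {
  stopifnot(inherits(log, "audit_log"), inherits(source, "rdf_source"))
  net <- new_network(list(), list(), list(), character(0), character(0))
  bundle <- NULL
  for (e in log$entries) {
    step <- function(expr) {
      tryCatch(expr, error = function(err) {
        stop("replay error at entry ", e$sequence_number, " (",
             e$action, "): ", conditionMessage(err), call. = FALSE)
      })
    }
    p <- e$parameters
    switch(e$action,
      fetch = {
        aop_ids <- p$aop_ids %||% character(0)
        ke_ids <- p$ke_ids %||% character(0)
        status_filter <- p$status_filter
        if (!length(status_filter)) status_filter <- NULL
        bundle <- step(fetch_bundle(source, aop_ids = aop_ids,
                                    ke_ids = ke_ids,
                                    status_filter = status_filter))
        miss <- bundle$missing
        if (length(miss)) {
          stop("replay error at entry ", e$sequence_number,
               " (fetch): entity no longer present in source: ",
               paste(sort_ids(miss), collapse = ", "), call. = FALSE)
        }
      },
      assemble = {
        if (is.null(bundle)) {
          stop("replay error at entry ", e$sequence_number,
               " (assemble): no preceding fetch entry", call. = FALSE)
        }
        net <- step(assemble(bundle))
      },
      filter_status = {
        net <- step(filter_by_status(net, p$allowed))
      },
      merge = {
        label <- p$merged_label
        if (!length(label) || !nzchar(label)) label <- NULL
        net <- step(apply_merge(net, p$keep_id, p$drop_id, label))
      },
      ego = {
        net <- step(ego_network(net, p$seed_ke_ids,
                                degree = as.integer(p$degree),
                                include_genes = as.logical(p$include_genes)))
      },
      export = NULL,
      credit = NULL,
      stop("replay error at entry ", e$sequence_number,
           ": unknown action '", e$action, "'", call. = FALSE)
    )
  }
  net
}
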