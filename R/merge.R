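# Fuzzy Key-Event deduplication: Levenshtein distance on normalized labels,
# merge suggestions, and user-confirmed node contractions with provenance.
#
# Suggestions are pure (never mutate); merges are explicit directives — the
# expert confirms each one, mirroring the curation workflow the network is
# built for.

#' Levenshtein edit distance
#'
#' Minimum number of single-character insertions, deletions and
#' substitutions transforming `a` into `b`.  Vectorized over its arguments
#' (usual recycling of a length-1 argument); distances are computed on the
#' raw bytes of the strings, so normalize (e.g. [normalize_label()]) before
#' comparing user-facing labels.
#'
#' @param a,b character vectors of equal length (or length 1).
#' @return Integer vector of distances.
#' @examples
#' levenshtein("kitten", "sitting")            # 3
#' levenshtein("N/A, Neurodegeneration", "Neurodegeneration")  # 5
#' @export
levenshtein <- function(a, b) {
  lev_dist_cpp(as.character(a), as.character(b))
}

#' Full distance matrix between two label vectors
#'
#' @param x,y character vectors.
#' @return Integer matrix `length(x)` by `length(y)`.
#' @export
levenshtein_matrix <- function(x, y = x) {
  lev_matrix_cpp(as.character(x), as.character(y))
}

#' Normalize a Key Event label for comparison
#'
#' Case-folds, strips leading/trailing whitespace and collapses internal
#' whitespace runs to a single space.  Idempotent.
#'
#' @param s character vector.
#' @return Normalized character vector.
#' @examples
#' normalize_label("  N/A,   Neurodegeneration ")
#' @export
normalize_label <- function(s) {
  s <- tolower(as.character(s))
  s <- gsub("[[:space:]]+", " ", s)
  trimws(s)
}

label_similarity <- function(label_a, label_b) {
  na <- normalize_label(label_a)
  nb <- normalize_label(label_b)
  d <- levenshtein(na, nb)
  len <- pmax(nchar(na), nchar(nb))
  ifelse(len == 0L, 1, 1 - d / len)
}

#' Suggest merges of functionally similar Key Events
#'
#' Compares every unordered pair of KE labels (normalized) by Levenshtein
#' distance and returns the pairs whose similarity
#' `1 - distance / max(nchar)` reaches `threshold`.  The user is expected to
#' confirm each suggestion on expert knowledge and apply it with
#' [apply_merge()]; this function never mutates the network.
#'
#' All-pairs comparison is O(n^2) in the number of KEs — ample at
#' AOP-Wiki scale (thousands of KEs).
#'
#' @param net an `aop_network`.
#' @param threshold similarity threshold in (0, 1]; default 0.75 admits the
#'   classic "N/A, "-prefixed duplicate (similarity ~0.77 at typical label
#'   lengths) while leaving short unrelated labels unpaired.
#' @return data.frame with columns `ke_id_a`, `ke_id_b` (canonical pair
#'   order, id a before id b), `label_a`, `label_b`, `distance`,
#'   `similarity`; sorted by similarity (descending) then pair order.
#' @export
suggest_merges <- function(net, threshold = 0.75) {
  stopifnot(inherits(net, "aop_network"))
  if (length(threshold) != 1L || !is.finite(threshold) || threshold <= 0 ||
      threshold > 1) {
    stop("threshold must be a single value in (0, 1]", call. = FALSE)
  }
  empty <- data.frame(ke_id_a = character(0), ke_id_b = character(0),
                      label_a = character(0), label_b = character(0),
                      distance = integer(0), similarity = numeric(0))
  ids <- sort_ids(names(net$key_events))
  if (length(ids) < 2L) return(empty)
  labels <- vapply(net$key_events[ids], `[[`, "", "title")
  norm <- normalize_label(labels)
  d <- levenshtein_matrix(norm, norm)
  n <- length(ids)
  i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n))
  dist <- d[cbind(i, j)]
  len <- pmax(nchar(norm)[i], nchar(norm)[j])
  sim <- ifelse(len == 0L, 1, 1 - dist / len)
  keep <- sim >= threshold
  out <- data.frame(ke_id_a = ids[i][keep], ke_id_b = ids[j][keep],
                    label_a = unname(labels[i][keep]),
                    label_b = unname(labels[j][keep]),
                    distance = as.integer(dist[keep]),
                    similarity = sim[keep])
  out <- out[order(-out$similarity, match(out$ke_id_a, ids),
                   match(out$ke_id_b, ids)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge two Key Events into one node
#'
#' Contracts `drop_id` into `keep_id`: all edges of the dropped node are
#' re-attached to the kept node, self-loops arising from the contraction are
#' removed, parallel edges collapse with their `asserting_aops` unioned, and
#' the kept node's memberships, roles, genes and source IRIs become the
#' union over both nodes.  Every AOP record referencing the dropped node is
#' rewritten.  The directive is recorded to the network's audit log (when
#' one is attached) before the mutation, so a session log always reflects
#' attempted merges.
#'
#' @param net an `aop_network`.
#' @param keep_id,drop_id distinct KE ids present in the network.  By
#'   convention the node with the cleaner label is kept; the CLI defaults
#'   `keep` to the shorter normalized label.
#' @param merged_label optional new title for the kept node; default keeps
#'   the kept node's title.
#' @return A new `aop_network` with exactly one node fewer.
#' @export
apply_merge <- function(net, keep_id, drop_id, merged_label = NULL) {
  stopifnot(inherits(net, "aop_network"))
  keep_id <- as.character(keep_id)
  drop_id <- as.character(drop_id)
  if (identical(keep_id, drop_id)) {
    stop("keep_id and drop_id must differ", call. = FALSE)
  }
  for (id in c(keep_id, drop_id)) {
    if (!id %in% names(net$key_events)) {
      stop("KE '", id, "' not found in network", call. = FALSE)
    }
  }
  if (!is.null(net$audit)) {
    record(net$audit, "merge",
           parameters = list(keep_id = keep_id, drop_id = drop_id,
                             merged_label = merged_label %||% ""),
           affected_ids = c(keep_id, drop_id))
  }
  keep <- net$key_events[[keep_id]]
  drop <- net$key_events[[drop_id]]
  keep$title <- merged_label %||% keep$title
  keep$roles <- role_sort(c(keep$roles, drop$roles))
  keep$gene_ids <- sort_ids(c(keep$gene_ids, drop$gene_ids))
  keep$source_iris <- sort(unique(c(keep$source_iris, drop$source_iris)))
  keep$member_aops <- sort_ids(c(keep$member_aops, drop$member_aops))
  if (!nzchar(keep$biological_level)) keep$biological_level <- drop$biological_level
  if (!nzchar(keep$description)) keep$description <- drop$description

  key_events <- net$key_events
  key_events[[drop_id]] <- NULL
  key_events[[keep_id]] <- keep

  # re-attach edges, drop self-loops, collapse parallels
  subst <- function(x) ifelse(x == drop_id, keep_id, x)
  edges <- lapply(net$kers, function(k) {
    k$upstream_ke_id <- subst(k$upstream_ke_id)
    k$downstream_ke_id <- subst(k$downstream_ke_id)
    k
  })
  edges <- Filter(function(k) k$upstream_ke_id != k$downstream_ke_id, edges)
  kers <- list()
  remap <- character(0)  # old ker_id -> canonical ker_id
  if (length(edges)) {
    keyv <- vapply(edges, function(k)
      paste(k$upstream_ke_id, k$downstream_ke_id, sep = "\r"), "")
    for (k in unique(keyv)) {
      grp <- edges[keyv == k]
      cid <- sort_ids(vapply(grp, `[[`, "", "ker_id"))[[1L]]
      kers[[cid]] <- list(
        ker_id = cid,
        upstream_ke_id = grp[[1L]]$upstream_ke_id,
        downstream_ke_id = grp[[1L]]$downstream_ke_id,
        asserting_aops = sort_ids(unlist(lapply(grp, `[[`, "asserting_aops")))
      )
      remap[vapply(grp, `[[`, "", "ker_id")] <- cid
    }
  }

  aops <- lapply(net$aops, function(a) {
    a$ke_ids <- sort_ids(subst(a$ke_ids))
    a$mie_ids <- sort_ids(subst(a$mie_ids))
    a$ao_ids <- sort_ids(subst(a$ao_ids))
    a$ker_ids <- sort_ids(unname(remap[intersect(a$ker_ids, names(remap))]))
    a
  })

  out <- new_network(key_events[sort_ids(names(key_events))],
                     kers[sort_ids(names(kers))], aops, net$gene_nodes,
                     net$warnings, audit = net$audit)
  if (!is_dag_network(out)) {
    msg <- paste0("merge of KE ", drop_id, " into ", keep_id,
                  " created a directed cycle")
    if (!msg %in% out$warnings) out$warnings <- c(out$warnings, msg)
  }
  validate_network(out)
  out
}
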