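# The in-memory AOP network model: assembly with deduplication, status
# filtering, node details, AOP highlighting and ego-network extraction.
#
# A network holds three id-keyed maps (key_events, kers, aops) plus gene
# annotation nodes in their own namespace.  All maps are kept in sorted id
# order so exports and canonical serializations are byte-stable.

ROLE_ORDER <- c("MIE", "KE", "AO")

role_sort <- function(r) intersect(ROLE_ORDER, unique(r))

new_network <- function(key_events, kers, aops, gene_nodes, warnings,
                        audit = NULL) {
  structure(list(key_events = key_events, kers = kers, aops = aops,
                 gene_nodes = gene_nodes, warnings = warnings, audit = audit),
            class = "aop_network")
}

#' Assemble a multi-AOP network from a raw bundle
#'
#' Joins AOPs through their shared Key Events: a KE id occurring in several
#' AOPs becomes a single node whose roles and AOP memberships are the union
#' over the contributing pathways; parallel assertions of the same directed
#' KE pair collapse into one edge whose `asserting_aops` is the union.
#' Assembly is idempotent: a bundle containing the same AOP twice assembles
#' to the same network as the bundle listing it once.
#'
#' Cycles arising from cross-AOP joins raise a warning entry, not an error:
#' individual AOPs are acyclic by design, but a network of independently
#' curated AOPs may legitimately conflict.
#'
#' @param bundle an [fetch_bundle()] result.
#' @param log optional [audit_log()]; records an `assemble` entry.
#' @return An object of class `aop_network`.
#' @examples
#' ttl <- tempfile(fileext = ".ttl")
#' writeLines(case_study_fixture()$turtle, ttl)
#' net <- assemble(fetch_bundle(rdf_source(ttl), aop_ids = c("12", "260")))
#' net
#' @export
assemble <- function(bundle, log = NULL) {
  validate_bundle(bundle)
  warnings <- unique(bundle$warnings)
  mem <- unique(bundle$memberships)
  kes_df <- unique(bundle$key_events)
  kers_df <- unique(bundle$kers)
  genes_df <- unique(bundle$gene_links)
  aops_df <- unique(bundle$aops)
  authors_df <- unique(bundle$authors)

  self <- kers_df$upstream == kers_df$downstream
  if (any(self)) {
    warnings <- c(warnings, paste0("dropped self-loop KER ",
                                   sort_ids(kers_df$ker_id[self])))
    kers_df <- kers_df[!self, , drop = FALSE]
  }

  # collapse parallel assertions of the same directed KE pair
  kers <- list()
  if (nrow(kers_df)) {
    key <- paste(kers_df$upstream, kers_df$downstream, sep = "\r")
    edge_of_row <- setNames(character(nrow(kers_df)), NULL)
    for (k in unique(key)) {
      rows <- kers_df[key == k, , drop = FALSE]
      cid <- sort_ids(rows$ker_id)[[1L]]
      kers[[cid]] <- list(ker_id = cid,
                          upstream_ke_id = rows$upstream[[1L]],
                          downstream_ke_id = rows$downstream[[1L]],
                          asserting_aops = sort_ids(rows$aop_id))
      edge_of_row[key == k] <- cid
    }
    kers_df$canonical_id <- edge_of_row
  }

  key_events <- list()
  for (i in seq_len(nrow(kes_df))) {
    id <- kes_df$ke_id[[i]]
    m <- mem[mem$ke_id == id, , drop = FALSE]
    g <- genes_df$gene_id[genes_df$ke_id == id]
    roles <- role_sort(m$role)
    if (!length(roles)) roles <- "KE"
    key_events[[id]] <- list(
      ke_id = id, title = kes_df$title[[i]], roles = roles,
      biological_level = "", description = "",
      gene_ids = sort_ids(g),
      source_iris = sort(unique(kes_df$source_iri[[i]])),
      member_aops = sort_ids(m$aop_id)
    )
  }

  aops <- list()
  for (i in seq_len(nrow(aops_df))) {
    id <- aops_df$aop_id[[i]]
    m <- mem[mem$aop_id == id, , drop = FALSE]
    krows <- if (nrow(kers_df)) kers_df[kers_df$aop_id == id, , drop = FALSE]
             else kers_df
    auth <- authors_df$author[authors_df$aop_id == id]
    aops[[id]] <- list(
      aop_id = id, title = aops_df$title[[i]], status = aops_df$status[[i]],
      authors = as.character(auth),
      ke_ids = sort_ids(m$ke_id),
      ker_ids = sort_ids(if (nrow(krows)) krows$canonical_id else character(0)),
      mie_ids = sort_ids(m$ke_id[m$role == "MIE"]),
      ao_ids = sort_ids(m$ke_id[m$role == "AO"])
    )
  }

  gene_nodes <- character(0)
  if (nrow(genes_df)) {
    g <- unique(genes_df[c("gene_id", "gene_label")])
    g <- g[order(g$gene_id, method = "radix"), , drop = FALSE]
    gene_nodes <- setNames(g$gene_label, g$gene_id)
  }

  net <- new_network(key_events[sort_ids(names(key_events))],
                     kers[sort_ids(names(kers))],
                     aops[sort_ids(names(aops))],
                     gene_nodes, warnings, audit = log)
  if (!is_dag_network(net)) {
    net$warnings <- c(net$warnings,
                      "assembled network contains a directed cycle")
  }
  # opposite-direction assertions of the same KE pair are kept, but flagged
  if (length(net$kers)) {
    pairs <- vapply(net$kers, function(k)
      paste(sort(c(k$upstream_ke_id, k$downstream_ke_id)), collapse = "\r"), "")
    rev_dup <- unique(pairs[duplicated(pairs)])
    if (length(rev_dup)) {
      net$warnings <- c(net$warnings, vapply(strsplit(rev_dup, "\r"),
        function(p) paste0("KEs ", p[1], " and ", p[2],
                           " are linked in both directions"), ""))
    }
  }
  validate_network(net)
  if (!is.null(log)) {
    record(log, "assemble",
           parameters = list(n_aops = as.character(length(net$aops)),
                             n_kes = as.character(length(net$key_events)),
                             n_kers = as.character(length(net$kers))),
           affected_ids = names(net$aops))
  }
  net
}

is_dag_network <- function(net) {
  if (!length(net$kers)) return(TRUE)
  igraph::is_dag(as_igraph(net))
}

#' Convert a network to an igraph object
#'
#' KE nodes carry `title`, `roles` and `node_kind = "ke"`; when
#' `include_genes`, gene annotation nodes (`node_kind = "gene"`, vertex name
#' `gene:<id>`) are attached to their KEs by undirected-styled `annotates`
#' edges.  KE-KE edges are directed upstream to downstream.
#'
#' @param net an `aop_network`.
#' @param include_genes attach gene annotation nodes.
#' @return An igraph directed graph.
#' @export
as_igraph <- function(net, include_genes = FALSE) {
  stopifnot(inherits(net, "aop_network"))
  ke_ids <- names(net$key_events)
  verts <- data.frame(
    name = ke_ids,
    title = vapply(net$key_events, `[[`, "", "title", USE.NAMES = FALSE),
    roles = vapply(net$key_events, function(k) paste(k$roles, collapse = "|"),
                   "", USE.NAMES = FALSE),
    node_kind = rep("ke", length(ke_ids)),
    stringsAsFactors = FALSE
  )
  edges <- data.frame(from = character(0), to = character(0),
                      ker_id = character(0), kind = character(0))
  if (length(net$kers)) {
    edges <- data.frame(
      from = vapply(net$kers, `[[`, "", "upstream_ke_id", USE.NAMES = FALSE),
      to = vapply(net$kers, `[[`, "", "downstream_ke_id", USE.NAMES = FALSE),
      ker_id = names(net$kers),
      kind = "KER", stringsAsFactors = FALSE
    )
  }
  if (include_genes && length(net$gene_nodes)) {
    gused <- sort_ids(unlist(lapply(net$key_events, `[[`, "gene_ids"),
                             use.names = FALSE))
    gused <- intersect(names(net$gene_nodes), gused)
    if (length(gused)) {
      verts <- rbind(verts, data.frame(name = paste0("gene:", gused),
                                       title = unname(net$gene_nodes[gused]),
                                       roles = "", node_kind = "gene"))
      for (ke in names(net$key_events)) {
        g <- intersect(net$key_events[[ke]]$gene_ids, gused)
        if (length(g)) {
          edges <- rbind(edges, data.frame(from = paste0("gene:", g), to = ke,
                                           ker_id = "", kind = "annotates"))
        }
      }
    }
  }
  igraph::graph_from_data_frame(edges, directed = TRUE, vertices = verts)
}

#' Validate network referential integrity
#'
#' Checks the structural invariants: unique ids; every KER endpoint, AOP
#' member KE and KER reference resolves; at most one edge per ordered KE
#' pair; each KE's `member_aops` equals the set of AOPs listing it; roles
#' nonempty with MIE/AO ids subsets of the member KE ids.
#'
#' @param net an `aop_network`.
#' @return `TRUE` invisibly; stops with an informative message on violation.
#' @export
validate_network <- function(net) {
  stopifnot(inherits(net, "aop_network"))
  ke_ids <- names(net$key_events)
  fail <- function(...) stop("network integrity: ", ..., call. = FALSE)
  if (anyDuplicated(ke_ids)) fail("duplicate KE ids")
  if (anyDuplicated(names(net$kers))) fail("duplicate KER ids")
  if (anyDuplicated(names(net$aops))) fail("duplicate AOP ids")
  pair_seen <- character(0)
  for (k in net$kers) {
    if (k$upstream_ke_id == k$downstream_ke_id) {
      fail("self-loop KER ", k$ker_id)
    }
    for (e in c(k$upstream_ke_id, k$downstream_ke_id)) {
      if (!e %in% ke_ids) fail("dangling KER endpoint '", e, "' in KER ",
                               k$ker_id)
    }
    key <- paste(k$upstream_ke_id, k$downstream_ke_id, sep = "\r")
    if (key %in% pair_seen) fail("parallel edges for KE pair ",
                                 gsub("\r", " -> ", key))
    pair_seen <- c(pair_seen, key)
  }
  membership <- list()
  for (a in net$aops) {
    bad_ke <- setdiff(a$ke_ids, ke_ids)
    if (length(bad_ke)) fail("AOP ", a$aop_id, " lists unknown KE(s): ",
                             paste(bad_ke, collapse = ", "))
    bad_ker <- setdiff(a$ker_ids, names(net$kers))
    if (length(bad_ker)) fail("AOP ", a$aop_id, " lists unknown KER(s): ",
                              paste(bad_ker, collapse = ", "))
    if (length(setdiff(a$mie_ids, a$ke_ids)) ||
        length(setdiff(a$ao_ids, a$ke_ids))) {
      fail("AOP ", a$aop_id, " MIE/AO ids not a subset of its KE ids")
    }
    for (kid in a$ker_ids) {
      k <- net$kers[[kid]]
      if (!k$upstream_ke_id %in% a$ke_ids || !k$downstream_ke_id %in% a$ke_ids)
        fail("AOP ", a$aop_id, " KER ", kid, " has endpoints outside the AOP")
    }
    for (ke in a$ke_ids) membership[[ke]] <- c(membership[[ke]], a$aop_id)
  }
  for (ke in net$key_events) {
    if (!length(ke$roles)) fail("KE ", ke$ke_id, " has empty roles")
    expected <- sort_ids(membership[[ke$ke_id]] %||% character(0))
    if (!identical(sort_ids(ke$member_aops), expected)) {
      fail("KE ", ke$ke_id, " member_aops inconsistent with AOP records")
    }
  }
  for (k in net$kers) {
    bad <- setdiff(k$asserting_aops, names(net$aops))
    if (length(bad)) fail("KER ", k$ker_id, " asserted by unknown AOP(s): ",
                          paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

# Induced subnetwork on a KE id subset.  All edges among retained KEs are
# kept; AOP records are intersected with the retained sets and AOPs left
# without any KE are dropped; member_aops are recomputed.
induce_kes <- function(net, keep_kes, include_genes = TRUE) {
  keep_kes <- intersect(names(net$key_events), keep_kes)
  kers <- Filter(function(k) k$upstream_ke_id %in% keep_kes &&
                   k$downstream_ke_id %in% keep_kes, net$kers)
  aops <- list()
  for (a in net$aops) {
    a$ke_ids <- intersect(a$ke_ids, keep_kes)
    if (!length(a$ke_ids)) next
    a$ker_ids <- intersect(a$ker_ids, names(kers))
    a$mie_ids <- intersect(a$mie_ids, a$ke_ids)
    a$ao_ids <- intersect(a$ao_ids, a$ke_ids)
    aops[[a$aop_id]] <- a
  }
  kers <- lapply(kers, function(k) {
    k$asserting_aops <- intersect(k$asserting_aops, names(aops))
    k
  })
  key_events <- net$key_events[sort_ids(keep_kes)]
  key_events <- lapply(key_events, function(ke) {
    ke$member_aops <- sort_ids(names(Filter(function(a)
      ke$ke_id %in% a$ke_ids, aops)))
    ke
  })
  gene_nodes <- character(0)
  if (include_genes && length(net$gene_nodes)) {
    gused <- sort_ids(unlist(lapply(key_events, `[[`, "gene_ids"),
                             use.names = FALSE))
    gused <- intersect(names(net$gene_nodes), gused)
    gene_nodes <- net$gene_nodes[gused]
  }
  if (!include_genes) {
    key_events <- lapply(key_events, function(ke) {
      ke$gene_ids <- character(0)
      ke
    })
  }
  new_network(key_events, kers[sort_ids(names(kers))],
              aops[sort_ids(names(aops))], gene_nodes, net$warnings,
              audit = net$audit)
}

#' Filter a network by OECD status
#'
#' Keeps exactly the AOPs whose status is in `allowed`, together with the
#' KEs and KERs reachable from at least one retained AOP; per-KE AOP
#' memberships are recomputed.  The input network is not modified.
#'
#' @param net an `aop_network`.
#' @param allowed nonempty character vector of status strings.
#' @return A new `aop_network` (possibly empty, with a warning entry).
#' @export
filter_by_status <- function(net, allowed) {
  stopifnot(inherits(net, "aop_network"))
  if (!length(allowed)) stop("allowed status set must be nonempty",
                             call. = FALSE)
  keep_aops <- names(Filter(function(a) a$status %in% allowed, net$aops))
  out <- net
  out$aops <- net$aops[keep_aops]
  keep_kes <- sort_ids(unlist(lapply(out$aops, `[[`, "ke_ids"),
                              use.names = FALSE))
  out <- induce_kes(out, keep_kes, include_genes = TRUE)
  out$kers <- Filter(function(k) length(k$asserting_aops) > 0, out$kers)
  out$aops <- lapply(out$aops, function(a) {
    a$ker_ids <- intersect(a$ker_ids, names(out$kers))
    a
  })
  if (!length(out$aops)) {
    out$warnings <- c(out$warnings,
                      paste0("status filter {", paste(allowed, collapse = ", "),
                             "} retained no AOPs"))
  }
  validate_network(out)
  if (!is.null(out$audit)) {
    record(out$audit, "filter_status",
           parameters = list(allowed = sort(unique(allowed))),
           affected_ids = keep_aops)
  }
  out
}

#' Detailed information about one Key Event node
#'
#' @param net an `aop_network`.
#' @param ke_id a KE id present in the network.
#' @return A read-only projection of the stored KE (class `ke_detail`):
#'   id, title, roles, biological level, description, member AOPs, gene ids.
#' @export
node_detail <- function(net, ke_id) {
  stopifnot(inherits(net, "aop_network"))
  ke <- net$key_events[[as.character(ke_id)]]
  if (is.null(ke)) stop("KE '", ke_id, "' not found in network", call. = FALSE)
  structure(ke[c("ke_id", "title", "roles", "biological_level",
                 "description", "member_aops", "gene_ids")],
            class = "ke_detail")
}

#' @export
print.ke_detail <- function(x, ...) {
  cat("KE ", x$ke_id, ": ", x$title, "\n", sep = "")
  cat("  roles: ", paste(x$roles, collapse = ", "), "\n", sep = "")
  if (nzchar(x$biological_level))
    cat("  level: ", x$biological_level, "\n", sep = "")
  cat("  member AOPs: ", paste(x$member_aops, collapse = ", "), "\n", sep = "")
  if (length(x$gene_ids))
    cat("  genes: ", paste(x$gene_ids, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Node and edge ids belonging to one AOP within the assembled network
#'
#' @param net an `aop_network`.
#' @param aop_id an AOP id present in the network.
#' @return A list with components `nodes` (KE ids) and `edges` (KER ids),
#'   both sorted.
#' @export
highlight_aop <- function(net, aop_id) {
  stopifnot(inherits(net, "aop_network"))
  a <- net$aops[[as.character(aop_id)]]
  if (is.null(a)) stop("AOP '", aop_id, "' not found in network",
                       call. = FALSE)
  list(nodes = sort_ids(a$ke_ids), edges = sort_ids(a$ker_ids))
}

#' Extract the degree-1/2 neighbourhood of a set of Key Events
#'
#' Returns the induced subnetwork on all KE nodes within undirected graph
#' distance `degree` of any seed KE.  Distance is measured on the undirected
#' skeleton (both up- and downstream neighbours count); edge direction is
#' preserved in the result.  Gene nodes are annotation-only: they never count
#' as a step and are attached to the retained KEs only when `include_genes`.
#'
#' @param net an `aop_network`.
#' @param seed_ke_ids nonempty set of KE ids present in the network.
#' @param degree 1 or 2.
#' @param include_genes keep gene annotation nodes of the retained KEs.
#' @return A new `aop_network`.
#' @export
ego_network <- function(net, seed_ke_ids, degree, include_genes = FALSE) {
  stopifnot(inherits(net, "aop_network"))
  seed_ke_ids <- sort_ids(as.character(seed_ke_ids))
  if (!length(seed_ke_ids)) stop("seed_ke_ids must be nonempty", call. = FALSE)
  missing <- setdiff(seed_ke_ids, names(net$key_events))
  if (length(missing)) stop("KE '", missing[[1L]], "' not found in network",
                            call. = FALSE)
  if (length(degree) != 1L || !degree %in% c(1L, 2L)) {
    stop("degree must be 1 or 2", call. = FALSE)
  }
  g <- as_igraph(net)
  d <- igraph::distances(g, v = seed_ke_ids, mode = "all")
  keep <- colnames(d)[apply(d, 2L, min) <= degree]
  out <- induce_kes(net, keep, include_genes = include_genes)
  validate_network(out)
  if (!is.null(out$audit)) {
    record(out$audit, "ego",
           parameters = list(seed_ke_ids = seed_ke_ids,
                             degree = as.character(degree),
                             include_genes = as.character(include_genes)),
           affected_ids = sort_ids(keep))
  }
  out
}

#' @export
print.aop_network <- function(x, ...) {
  cat("<aop_network> ", length(x$key_events), " KEs, ", length(x$kers),
      " KERs, ", length(x$aops), " AOPs, ", length(x$gene_nodes),
      " gene nodes\n", sep = "")
  invisible(x)
}

#' @export
summary.aop_network <- function(object, ...) {
  roles <- table(unlist(lapply(object$key_events, `[[`, "roles")))
  shared <- sum(vapply(object$key_events,
                       function(k) length(k$member_aops) > 1L, NA))
  cat("AOP network\n")
  cat("  AOPs:       ", length(object$aops), "\n")
  cat("  Key Events: ", length(object$key_events),
      sprintf(" (%d shared by >1 AOP)", shared), "\n", sep = "")
  for (r in ROLE_ORDER) {
    if (!is.na(roles[r])) cat("    role ", r, ": ", roles[[r]], "\n", sep = "")
  }
  cat("  KERs:       ", length(object$kers), "\n")
  cat("  gene nodes: ", length(object$gene_nodes), "\n")
  if (length(object$warnings)) {
    cat("  warnings:\n")
    cat(paste0("    - ", object$warnings, collapse = "\n"), "\n")
  }
  invisible(object)
}

#' Plot an AOP network
#'
#' Quick base-graphics view via igraph: MIEs green, AOs red, intermediate
#' KEs grey, gene nodes (if present) small and white.  Layout and styling
#' are intentionally minimal; Cytoscape (via [write_graphml()]) is the
#' intended rendering environment.
#'
#' @param x an `aop_network`.
#' @param include_genes show gene annotation nodes.
#' @param ... passed to `plot.igraph`.
#' @export
plot.aop_network <- function(x, include_genes = FALSE, ...) {
  g <- as_igraph(x, include_genes = include_genes)
  roles <- igraph::V(g)$roles
  kind <- igraph::V(g)$node_kind
  col <- ifelse(kind == "gene", "white",
                ifelse(grepl("MIE", roles), "palegreen3",
                       ifelse(grepl("AO", roles), "indianred2", "grey80")))
  igraph::plot.igraph(g, vertex.color = col,
                      vertex.label = igraph::V(g)$title,
                      vertex.size = ifelse(kind == "gene", 6, 14),
                      edge.arrow.size = 0.4, ...)
  invisible(x)
}

# ---- canonical serialization --------------------------------------------

canonical_network_list <- function(net) {
  ke <- lapply(net$key_events, function(k) {
    list(ke_id = k$ke_id, title = k$title, roles = role_sort(k$roles),
         biological_level = k$biological_level, description = k$description,
         gene_ids = sort_ids(k$gene_ids), source_iris = sort(k$source_iris),
         member_aops = sort_ids(k$member_aops))
  })
  kr <- lapply(net$kers, function(k) {
    list(ker_id = k$ker_id, upstream_ke_id = k$upstream_ke_id,
         downstream_ke_id = k$downstream_ke_id,
         asserting_aops = sort_ids(k$asserting_aops))
  })
  ao <- lapply(net$aops, function(a) {
    list(aop_id = a$aop_id, title = a$title, status = a$status,
         authors = as.character(a$authors), ke_ids = sort_ids(a$ke_ids),
         ker_ids = sort_ids(a$ker_ids), mie_ids = sort_ids(a$mie_ids),
         ao_ids = sort_ids(a$ao_ids))
  })
  gn <- net$gene_nodes[sort_ids(names(net$gene_nodes))]
  list(key_events = ke[sort_ids(names(ke))], kers = kr[sort_ids(names(kr))],
       aops = ao[sort_ids(names(ao))],
       gene_nodes = as.list(gn))
}

#' Canonical JSON serialization of a network
#'
#' A deterministic, audit-free rendering of the network content (KEs, KERs,
#' AOPs, gene nodes, all sorted).  Two networks are operationally identical
#' exactly when their canonical JSON strings are byte-equal; this is the
#' comparator used by replay and round-trip checks.
#'
#' @param net an `aop_network`.
#' @return A JSON character scalar.
#' @export
canonical_json <- function(net) {
  stopifnot(inherits(net, "aop_network"))
  as.character(jsonlite::toJSON(canonical_network_list(net),
                                auto_unbox = FALSE, null = "null",
                                digits = NA))
}

#' Compare two networks for canonical equality
#'
#' @param a,b `aop_network` objects.
#' @return `TRUE` if the canonical serializations are identical.
#' @export
network_equal <- function(a, b) {
  identical(canonical_json(a), canonical_json(b))
}

#' Write / read a network as canonical JSON
#'
#' Persistence for `aop_network` objects (used by the CLI to carry session
#' state between invocations).  Warnings travel with the file; the audit log
#' does not (it lives in its own JSON-lines file, see [write_log()]).
#'
#' @param net an `aop_network`.
#' @param path file path.
#' @return `write_network` returns `path` invisibly; `read_network` the
#'   network (with a `NULL` audit slot).
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "aop_network"))
  payload <- c(canonical_network_list(net),
               list(warnings = as.character(net$warnings)))
  writeLines(as.character(jsonlite::toJSON(payload, auto_unbox = FALSE,
                                           null = "null", digits = NA)),
             path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  chr <- function(v) as.character(unlist(v))
  ke <- lapply(x$key_events, function(k) {
    list(ke_id = chr(k$ke_id), title = paste(chr(k$title), collapse = ""),
         roles = chr(k$roles), biological_level = paste(chr(k$biological_level), collapse = ""),
         description = paste(chr(k$description), collapse = ""),
         gene_ids = chr(k$gene_ids), source_iris = chr(k$source_iris),
         member_aops = chr(k$member_aops))
  })
  kr <- lapply(x$kers, function(k) {
    list(ker_id = chr(k$ker_id), upstream_ke_id = chr(k$upstream_ke_id),
         downstream_ke_id = chr(k$downstream_ke_id),
         asserting_aops = chr(k$asserting_aops))
  })
  ao <- lapply(x$aops, function(a) {
    list(aop_id = chr(a$aop_id), title = paste(chr(a$title), collapse = ""),
         status = paste(chr(a$status), collapse = ""),
         authors = chr(a$authors), ke_ids = chr(a$ke_ids),
         ker_ids = chr(a$ker_ids), mie_ids = chr(a$mie_ids),
         ao_ids = chr(a$ao_ids))
  })
  gn <- setNames(as.character(unlist(x$gene_nodes)), names(x$gene_nodes))
  if (!length(x$gene_nodes)) gn <- character(0)
  net <- new_network(ke, kr, ao, gn, chr(x$warnings), audit = NULL)
  validate_network(net)
  net
}
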