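# Serialization: Cytoscape-compatible GraphML and SIF, flat node/edge
# tables (CSV/XLSX), and raw pre-assembly bundle tables.
#
# Everything here is byte-stable: identical networks produce identical
# files.  No timestamps are ever written into graph or table artifacts —
# timestamps belong to the audit log.

new_export_manifest <- function(format, path, count) {
  structure(list(format = format, path = path,
                 row_or_element_count = as.integer(count),
                 checksum = unname(tools::md5sum(path))),
            class = "export_manifest")
}

#' @export
print.export_manifest <- function(x, ...) {
  cat("<export_manifest> ", x$format, " ", x$path, " (",
      x$row_or_element_count, " rows/elements, md5 ", x$checksum, ")\n",
      sep = "")
  invisible(x)
}

xml_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  s <- gsub(">", "&gt;", s, fixed = TRUE)
  gsub('"', "&quot;", s, fixed = TRUE)
}

join_bar <- function(x) paste(x, collapse = "|")

graphml_node_keys <- c(title = "d_title", roles = "d_roles",
                       member_aops = "d_member_aops", node_kind = "d_node_kind",
                       biological_level = "d_level", description = "d_description",
                       source_iris = "d_source_iris", genes = "d_genes")
graphml_edge_keys <- c(kind = "e_kind", ker_id = "e_ker_id",
                       asserting_aops = "e_asserting_aops")

#' Export a network to GraphML (Cytoscape-compatible)
#'
#' One `<node>` per KE (plus one per gene annotation node when the network
#' carries genes) and one directed `<edge>` per KER (plus gene `annotates`
#' edges).  Node attributes: title, roles, member AOPs, node kind, level,
#' description, source IRIs and gene list; edge attributes: kind, KER id,
#' asserting AOPs; multi-valued attributes are "|"-joined sorted strings.
#' AOP records travel as a graph-level JSON attribute so that
#' [read_graphml()] restores the full network.  Elements are emitted in
#' sorted-id order; output is byte-stable.
#'
#' @param net an `aop_network`.
#' @param path output file path.
#' @return An `export_manifest` (format, path, element count, checksum).
#' @export
write_graphml <- function(net, path) {
  stopifnot(inherits(net, "aop_network"))
  validate_network(net)
  canon <- canonical_network_list(net)
  aops_json <- as.character(jsonlite::toJSON(canon$aops, auto_unbox = FALSE,
                                             digits = NA))
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    sprintf('  <key id="%s" for="node" attr.name="%s" attr.type="string"/>',
            unname(graphml_node_keys), names(graphml_node_keys)),
    sprintf('  <key id="%s" for="edge" attr.name="%s" attr.type="string"/>',
            unname(graphml_edge_keys), names(graphml_edge_keys)),
    '  <key id="g_aops" for="graph" attr.name="aops_json" attr.type="string"/>',
    '  <key id="g_warnings" for="graph" attr.name="warnings" attr.type="string"/>',
    '  <graph id="aop_network" edgedefault="directed">',
    paste0('    <data key="g_aops">', xml_escape(aops_json), '</data>'),
    paste0('    <data key="g_warnings">',
           xml_escape(join_bar(net$warnings)), '</data>')
  )
  node_el <- function(id, attrs) {
    c(paste0('    <node id="', xml_escape(id), '">'),
      sprintf('      <data key="%s">%s</data>',
              unname(graphml_node_keys[names(attrs)]),
              xml_escape(unlist(attrs))),
      "    </node>")
  }
  n_nodes <- 0L
  for (ke in net$key_events) {
    lines <- c(lines, node_el(paste0("ke:", ke$ke_id), list(
      title = ke$title, roles = join_bar(ke$roles),
      member_aops = join_bar(ke$member_aops), node_kind = "ke",
      biological_level = ke$biological_level, description = ke$description,
      source_iris = join_bar(ke$source_iris), genes = join_bar(ke$gene_ids))))
    n_nodes <- n_nodes + 1L
  }
  for (g in sort_ids(names(net$gene_nodes))) {
    lines <- c(lines, node_el(paste0("gene:", g), list(
      title = unname(net$gene_nodes[[g]]), roles = "", member_aops = "",
      node_kind = "gene", biological_level = "", description = "",
      source_iris = "", genes = "")))
    n_nodes <- n_nodes + 1L
  }
  edge_el <- function(from, to, attrs) {
    c(paste0('    <edge source="', xml_escape(from), '" target="',
             xml_escape(to), '">'),
      sprintf('      <data key="%s">%s</data>',
              unname(graphml_edge_keys[names(attrs)]),
              xml_escape(unlist(attrs))),
      "    </edge>")
  }
  n_edges <- 0L
  for (k in net$kers) {
    lines <- c(lines, edge_el(paste0("ke:", k$upstream_ke_id),
                              paste0("ke:", k$downstream_ke_id),
                              list(kind = "KER", ker_id = k$ker_id,
                                   asserting_aops = join_bar(k$asserting_aops))))
    n_edges <- n_edges + 1L
  }
  for (ke in net$key_events) {
    for (g in intersect(ke$gene_ids, names(net$gene_nodes))) {
      lines <- c(lines, edge_el(paste0("gene:", g), paste0("ke:", ke$ke_id),
                                list(kind = "annotates", ker_id = "",
                                     asserting_aops = "")))
      n_edges <- n_edges + 1L
    }
  }
  lines <- c(lines, "  </graph>", "</graphml>")
  writeLines(lines, path, useBytes = TRUE)
  if (!is.null(net$audit)) {
    record(net$audit, "export",
           parameters = list(format = "graphml", path = basename(path)),
           affected_ids = character(0))
  }
  new_export_manifest("graphml", path, n_nodes + n_edges)
}

split_bar <- function(s) {
  if (!length(s) || is.na(s) || !nzchar(s)) character(0)
  else strsplit(s, "|", fixed = TRUE)[[1]]
}

#' Read a network back from GraphML written by [write_graphml()]
#'
#' Foreign GraphML lacking the required attribute keys is rejected with a
#' schema error listing the missing keys.
#'
#' @param path GraphML file path.
#' @return An `aop_network` (audit slot empty).
#' @export
read_graphml <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "'", call. = FALSE)
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  keys <- xml2::xml_find_all(doc, ".//key")
  have <- setNames(xml2::xml_attr(keys, "attr.name"), xml2::xml_attr(keys, "id"))
  need <- c(graphml_node_keys[c("title", "roles", "member_aops", "node_kind")],
            graphml_edge_keys[c("kind", "ker_id", "asserting_aops")], "g_aops")
  missing <- setdiff(need, names(have))
  if (length(missing)) {
    stop("GraphML schema error: missing attribute key(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  gdata <- xml2::xml_find_all(doc, "./graph/data")
  gmap <- setNames(xml2::xml_text(gdata), xml2::xml_attr(gdata, "key"))
  data_of <- function(el) {
    d <- xml2::xml_find_all(el, "./data")
    setNames(xml2::xml_text(d), xml2::xml_attr(d, "key"))
  }
  at <- function(m, k) if (k %in% names(m)) m[[k]] else ""
  key_events <- list()
  gene_nodes <- character(0)
  for (el in xml2::xml_find_all(doc, "./graph/node")) {
    id <- xml2::xml_attr(el, "id")
    m <- data_of(el)
    kind <- at(m, "d_node_kind")
    bare <- sub("^(ke|gene):", "", id)
    if (kind == "gene") {
      gene_nodes[bare] <- at(m, "d_title")
    } else {
      key_events[[bare]] <- list(
        ke_id = bare, title = at(m, "d_title"),
        roles = split_bar(at(m, "d_roles")),
        biological_level = at(m, "d_level"),
        description = at(m, "d_description"),
        gene_ids = split_bar(at(m, "d_genes")),
        source_iris = split_bar(at(m, "d_source_iris")),
        member_aops = split_bar(at(m, "d_member_aops")))
    }
  }
  kers <- list()
  for (el in xml2::xml_find_all(doc, "./graph/edge")) {
    m <- data_of(el)
    if (at(m, "e_kind") != "KER") next
    id <- at(m, "e_ker_id")
    kers[[id]] <- list(
      ker_id = id,
      upstream_ke_id = sub("^ke:", "", xml2::xml_attr(el, "source")),
      downstream_ke_id = sub("^ke:", "", xml2::xml_attr(el, "target")),
      asserting_aops = split_bar(at(m, "e_asserting_aops")))
  }
  aops_raw <- jsonlite::fromJSON(gmap[["g_aops"]], simplifyVector = FALSE)
  chr <- function(v) as.character(unlist(v))
  aops <- lapply(aops_raw, function(a) {
    list(aop_id = chr(a$aop_id), title = paste(chr(a$title), collapse = ""),
         status = paste(chr(a$status), collapse = ""), authors = chr(a$authors),
         ke_ids = chr(a$ke_ids), ker_ids = chr(a$ker_ids),
         mie_ids = chr(a$mie_ids), ao_ids = chr(a$ao_ids))
  })
  warnings <- split_bar(if ("g_warnings" %in% names(gmap)) gmap[["g_warnings"]] else "")
  net <- new_network(key_events[sort_ids(names(key_events))],
                     kers[sort_ids(names(kers))], aops,
                     gene_nodes[sort_ids(names(gene_nodes))], warnings)
  validate_network(net)
  net
}

#' Export a network to SIF (simple interaction format)
#'
#' One tab-separated line per edge (`upstream  KER  downstream` for KE-KE
#' edges, `gene  annotates  ke` for gene annotations) and one single-column
#' line per isolated node, all in sorted order.
#'
#' @param net an `aop_network`.
#' @param path output file path.
#' @return An `export_manifest` whose count is the number of lines.
#' @export
write_sif <- function(net, path) {
  stopifnot(inherits(net, "aop_network"))
  validate_network(net)
  lines <- character(0)
  connected <- character(0)
  for (kid in sort_ids(names(net$kers))) {
    k <- net$kers[[kid]]
    lines <- c(lines, paste(k$upstream_ke_id, "KER", k$downstream_ke_id,
                            sep = "\t"))
    connected <- c(connected, k$upstream_ke_id, k$downstream_ke_id)
  }
  for (ke in net$key_events) {
    for (g in intersect(ke$gene_ids, names(net$gene_nodes))) {
      lines <- c(lines, paste(paste0("gene:", g), "annotates", ke$ke_id,
                              sep = "\t"))
      connected <- c(connected, ke$ke_id, paste0("gene:", g))
    }
  }
  isolated <- setdiff(names(net$key_events), connected)
  lines <- c(lines, sort_ids(isolated))
  writeLines(lines, path, useBytes = TRUE)
  if (!is.null(net$audit)) {
    record(net$audit, "export",
           parameters = list(format = "sif", path = basename(path)),
           affected_ids = character(0))
  }
  new_export_manifest("sif", path, length(lines))
}

# --- CSV dialect: comma delimiter, quote only when a field contains
# delimiter/quote/newline, UTF-8, LF line endings -------------------------

csv_cell <- function(x) {
  x <- as.character(x)
  need <- grepl('[",\n]', x)
  x[need] <- paste0('"', gsub('"', '""', x[need], fixed = TRUE), '"')
  x
}

write_csv_file <- function(df, path) {
  lines <- paste(vapply(names(df), csv_cell, ""), collapse = ",")
  if (nrow(df)) {
    cells <- vapply(df, csv_cell, character(nrow(df)))
    if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L)
    lines <- c(lines, apply(cells, 1L, paste, collapse = ","))
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read back a CSV file written by the package exporters
#'
#' @param path CSV file path.
#' @return data.frame of character columns.
#' @export
read_csv_file <- function(path) {
  utils::read.csv(path, colClasses = "character", check.names = FALSE)
}

xlsx_helper <- function() {
  script <- system.file("python", "xlsx_io.py", package = "aopnetworkr")
  py <- Sys.which("python")
  if (!nzchar(py)) stop("xlsx export requires a 'python' interpreter with ",
                        "openpyxl on the PATH", call. = FALSE)
  list(py = py, script = script)
}

write_xlsx_sheets <- function(sheets, path) {
  # sheets: named list of data.frames (all-character)
  h <- xlsx_helper()
  spec <- list(sheets = lapply(names(sheets), function(nm) {
    df <- sheets[[nm]]
    list(name = jsonlite::unbox(nm), columns = names(df),
         rows = if (nrow(df)) unname(lapply(seq_len(nrow(df)), function(i)
           as.character(unlist(df[i, ], use.names = FALSE)))) else list())
  }))
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp), add = TRUE)
  jsonlite::write_json(spec, tmp, auto_unbox = FALSE)
  out <- system2(h$py, c(h$script, "write", tmp, path),
                 stdout = TRUE, stderr = TRUE)
  if (!is.null(attr(out, "status"))) {
    stop("xlsx write failed: ", paste(out, collapse = "\n"), call. = FALSE)
  }
  invisible(path)
}

#' Read the sheets of an xlsx workbook written by the package exporters
#'
#' @param path xlsx file path.
#' @return Named list of data.frames (all cells as character).
#' @export
read_xlsx_sheets <- function(path) {
  h <- xlsx_helper()
  out <- system2(h$py, c(h$script, "read", path), stdout = TRUE, stderr = "")
  x <- jsonlite::fromJSON(paste(out, collapse = ""), simplifyVector = FALSE)
  sheets <- list()
  for (sh in x$sheets) {
    cols <- as.character(unlist(sh$columns))
    rows <- sh$rows
    m <- if (length(rows)) {
      do.call(rbind, lapply(rows, function(r) as.character(unlist(r))))
    } else matrix(character(0), 0L, length(cols))
    df <- as.data.frame(m, stringsAsFactors = FALSE)
    names(df) <- cols
    sheets[[as.character(sh$name)]] <- df
  }
  sheets
}

network_node_table <- function(net) {
  ids <- sort_ids(names(net$key_events))
  data.frame(
    ke_id = ids,
    title = vapply(net$key_events[ids], `[[`, "", "title"),
    roles = vapply(net$key_events[ids], function(k) join_bar(k$roles), ""),
    biological_level = vapply(net$key_events[ids], `[[`, "", "biological_level"),
    member_aops = vapply(net$key_events[ids],
                         function(k) join_bar(sort_ids(k$member_aops)), ""),
    genes = vapply(net$key_events[ids],
                   function(k) join_bar(sort_ids(k$gene_ids)), ""),
    row.names = NULL, stringsAsFactors = FALSE)
}

network_edge_table <- function(net) {
  ids <- sort_ids(names(net$kers))
  data.frame(
    ker_id = ids,
    upstream = vapply(net$kers[ids], `[[`, "", "upstream_ke_id"),
    downstream = vapply(net$kers[ids], `[[`, "", "downstream_ke_id"),
    asserting_aops = vapply(net$kers[ids],
                            function(k) join_bar(sort_ids(k$asserting_aops)), ""),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Export node and edge tables
#'
#' Writes a node table (one row per KE) and an edge table (one row per KER)
#' either as two CSV files (`<prefix>_nodes.csv`, `<prefix>_edges.csv`) or
#' as one xlsx workbook (`<prefix>.xlsx`, sheets `nodes` and `edges`).
#' Multi-valued cells are "|"-joined sorted strings; row order is
#' deterministic; CSV and XLSX of the same network contain identical cell
#' values.
#'
#' @param net an `aop_network`.
#' @param path_prefix output path prefix.
#' @param sheet_format `"csv"` or `"xlsx"`.
#' @return List of `export_manifest` objects (one per table).
#' @export
write_tables <- function(net, path_prefix, sheet_format = c("csv", "xlsx")) {
  stopifnot(inherits(net, "aop_network"))
  sheet_format <- match.arg(sheet_format)
  validate_network(net)
  tables <- list(nodes = network_node_table(net),
                 edges = network_edge_table(net))
  manifests <- export_table_set(tables, path_prefix, sheet_format)
  if (!is.null(net$audit)) {
    record(net$audit, "export",
           parameters = list(format = sheet_format,
                             path = basename(path_prefix)),
           affected_ids = character(0))
  }
  manifests
}

export_table_set <- function(tables, path_prefix, sheet_format) {
  if (sheet_format == "csv") {
    manifests <- list()
    for (nm in names(tables)) {
      p <- paste0(path_prefix, "_", nm, ".csv")
      write_csv_file(tables[[nm]], p)
      manifests[[nm]] <- new_export_manifest("csv", p, nrow(tables[[nm]]))
    }
    manifests
  } else {
    p <- paste0(path_prefix, ".xlsx")
    write_xlsx_sheets(tables, p)
    setNames(lapply(names(tables), function(nm)
      new_export_manifest("xlsx", p, nrow(tables[[nm]]))), names(tables))
  }
}

#' Export raw retrieved data as flat tables
#'
#' One table per entity kind — `aops`, `key_events`, `kers`, `gene_links`,
#' `authors` — exactly as retrieved (pre-assembly, pre-merge), as CSV files
#' `<prefix>_<kind>.csv` or one xlsx workbook `<prefix>.xlsx` with one sheet
#' per table.  Header rows are always present.
#'
#' @param bundle an `aop_bundle`.
#' @param path_prefix output path prefix.
#' @param sheet_format `"csv"` or `"xlsx"`.
#' @param log optional [audit_log()]; records an `export` entry.
#' @return List of `export_manifest` objects, one per table.
#' @export
export_raw <- function(bundle, path_prefix, sheet_format = c("csv", "xlsx"),
                       log = NULL) {
  stopifnot(inherits(bundle, "aop_bundle"))
  sheet_format <- match.arg(sheet_format)
  validate_bundle(bundle)
  tables <- list(aops = bundle$aops,
                 key_events = bundle$key_events,
                 kers = bundle$kers,
                 gene_links = bundle$gene_links,
                 authors = bundle$authors)
  manifests <- export_table_set(tables, path_prefix, sheet_format)
  if (!is.null(log)) {
    record(log, "export",
           parameters = list(format = paste0("raw_", sheet_format),
                             path = basename(path_prefix)),
           affected_ids = character(0))
  }
  manifests
}
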