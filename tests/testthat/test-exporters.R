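test_that("graphml export writes one element per node and edge", {
  fx <- generate_fixture(fixture_spec(n_aops = 1, ke_per_aop = 3,
                                      share_prob = 0,
                                      n_gene_links_per_ke = 0, seed = 6))
  net <- fixture_network(fx)
  path <- tempfile(fileext = ".graphml")
  m <- write_graphml(net, path)
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  expect_length(xml2::xml_find_all(doc, "./graph/node"), 3L)
  expect_length(xml2::xml_find_all(doc, "./graph/edge"), 2L)
  expect_equal(m$row_or_element_count, 5L)
  expect_equal(m$checksum, unname(tools::md5sum(path)))
})

test_that("graphml round trip is byte-identical and network-identical", {
  for (seed in c(13, 77)) {
    fx <- generate_fixture(fixture_spec(seed = seed))
    net <- fixture_network(fx)
    p1 <- tempfile(fileext = ".graphml")
    p2 <- tempfile(fileext = ".graphml")
    write_graphml(net, p1)
    back <- read_graphml(p1)
    expect_true(network_equal(back, net))
    write_graphml(back, p2)
    expect_identical(readBin(p1, "raw", file.size(p1) + 10),
                     readBin(p2, "raw", file.size(p2) + 10))
  }
  # empty network round trip
  empty <- aopnetworkr:::new_network(list(), list(), list(), character(0),
                                     character(0))
  p <- tempfile(fileext = ".graphml")
  write_graphml(empty, p)
  expect_true(network_equal(read_graphml(p), empty))
})

test_that("identical networks export identical bytes (no timestamps)", {
  net <- case_study_network()
  p1 <- tempfile(); p2 <- tempfile()
  m1 <- write_graphml(net, p1)
  Sys.sleep(1.1)
  m2 <- write_graphml(net, p2)
  expect_identical(m1$checksum, m2$checksum)
  s1 <- tempfile(); s2 <- tempfile()
  expect_identical(write_sif(net, s1)$checksum, write_sif(net, s2)$checksum)
})

test_that("foreign graphml without required keys is a schema error", {
  p <- tempfile(fileext = ".graphml")
  writeLines(c(
    '<?xml version="1.0"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="d_title" for="node" attr.name="title" attr.type="string"/>',
    '  <graph id="g" edgedefault="directed"><node id="ke:1"/></graph>',
    '</graphml>'), p)
  expect_error(read_graphml(p), "missing attribute key.*d_node_kind")
})

test_that("post-merge case-study graphml has one Neurodegeneration node", {
  net <- apply_merge(case_study_network(), CS_AO_PLAIN, CS_AO_NA)
  p <- tempfile(fileext = ".graphml")
  write_graphml(net, p)
  doc <- xml2::read_xml(p)
  xml2::xml_ns_strip(doc)
  titles <- xml2::xml_text(xml2::xml_find_all(
    doc, './graph/node/data[@key="d_title"]'))
  expect_equal(sum(titles == "Neurodegeneration"), 1L)
  expect_false(any(titles == "N/A, Neurodegeneration"))
})

test_that("sif line count equals edges plus isolated nodes", {
  net <- case_study_network()
  p <- tempfile(fileext = ".sif")
  m <- write_sif(net, p)
  lines <- readLines(p)
  # 7 KERs + 2 gene annotations, no isolated nodes
  expect_equal(length(lines), 9L)
  expect_equal(m$row_or_element_count, 9L)
  expect_equal(sum(grepl("\tKER\t", lines)), 7L)
  expect_equal(sum(grepl("\tannotates\t", lines)), 2L)
  for (seed in c(3, 21, 55)) {
    fx <- generate_fixture(fixture_spec(seed = seed))
    gnet <- fixture_network(fx)
    gp <- tempfile(fileext = ".sif")
    write_sif(gnet, gp)
    glines <- readLines(gp)
    gene_edges <- sum(vapply(gnet$key_events,
                             function(k) length(k$gene_ids), 0L))
    connected <- unique(unlist(lapply(gnet$kers, function(k)
      c(k$upstream_ke_id, k$downstream_ke_id))))
    isolated <- setdiff(names(gnet$key_events),
                        c(connected,
                          names(Filter(function(k) length(k$gene_ids) > 0,
                                       gnet$key_events))))
    expect_equal(length(glines),
                 length(gnet$kers) + gene_edges + length(isolated))
  }
})

test_that("an isolated KE becomes a single-column sif line", {
  src <- fixture_source(case_study_fixture())
  b <- fetch_bundle(src, aop_ids = c("12", "260"))
  b$kers <- b$kers[0, ]
  b$gene_links <- b$gene_links[0, ]
  net <- assemble(b)
  p <- tempfile(fileext = ".sif")
  write_sif(net, p)
  lines <- readLines(p)
  expect_equal(length(lines), 9L)
  expect_false(any(grepl("\t", lines)))
})

test_that("csv and xlsx tables carry identical cell values", {
  net <- apply_merge(case_study_network(), CS_AO_PLAIN, CS_AO_NA)
  prefix <- tempfile()
  mc <- write_tables(net, prefix, "csv")
  mx <- write_tables(net, prefix, "xlsx")
  nodes_csv <- read_csv_file(paste0(prefix, "_nodes.csv"))
  edges_csv <- read_csv_file(paste0(prefix, "_edges.csv"))
  sheets <- read_xlsx_sheets(paste0(prefix, ".xlsx"))
  expect_identical(unname(as.matrix(nodes_csv)), unname(as.matrix(sheets$nodes)))
  expect_identical(unname(as.matrix(edges_csv)), unname(as.matrix(sheets$edges)))
  expect_identical(names(nodes_csv), names(sheets$nodes))
  # one row per KE / KER, count fields match an independent parse
  expect_equal(nrow(nodes_csv), length(net$key_events))
  expect_equal(mc$nodes$row_or_element_count, nrow(nodes_csv))
  expect_equal(mc$edges$row_or_element_count, nrow(edges_csv))
  expect_equal(mx$nodes$row_or_element_count, nrow(sheets$nodes))
  # exactly one merged AO row survives
  expect_equal(sum(nodes_csv$title == "Neurodegeneration"), 1L)
})

test_that("csv quoting survives delimiters, quotes and newlines", {
  net <- case_study_network()
  net$key_events[["101"]]$title <- 'Weird, "label"\nwith newline'
  prefix <- tempfile()
  write_tables(net, prefix, "csv")
  back <- read_csv_file(paste0(prefix, "_nodes.csv"))
  expect_equal(back$title[back$ke_id == "101"], 'Weird, "label"\nwith newline')
})

test_that("raw export writes one table per entity kind", {
  src <- fixture_source(case_study_fixture())
  b <- fetch_bundle(src, aop_ids = c("12", "260"))
  prefix <- tempfile()
  ms <- export_raw(b, prefix, "csv")
  expect_setequal(names(ms),
                  c("aops", "key_events", "kers", "gene_links", "authors"))
  expect_equal(ms$aops$row_or_element_count, 2L)
  expect_equal(nrow(read_csv_file(paste0(prefix, "_aops.csv"))), 2L)
  # raw means pre-assembly: per-AOP KER rows, not collapsed edges
  expect_equal(ms$kers$row_or_element_count, 7L)
  fx <- generate_fixture(fixture_spec(seed = 17))
  bg <- fetch_bundle(fixture_source(fx), aop_ids = manifest_aop_ids(fx))
  mg <- export_raw(bg, tempfile(), "csv")
  expect_equal(mg$gene_links$row_or_element_count,
               fx$manifest$counts$gene_links)
  expect_equal(mg$authors$row_or_element_count, fx$manifest$counts$authors)
})

test_that("an empty bundle exports five header-only tables", {
  src <- fixture_source(case_study_fixture())
  b <- suppressWarnings(fetch_bundle(src, aop_ids = "999"))
  prefix <- tempfile()
  ms <- export_raw(b, prefix, "csv")
  expect_length(ms, 5L)
  for (nm in names(ms)) {
    expect_equal(ms[[nm]]$row_or_element_count, 0L)
    lines <- readLines(ms[[nm]]$path)
    expect_length(lines, 1L)  # just the header
  }
})
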