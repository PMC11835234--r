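test_that("record appends gapless sequence numbers and validates input", {
  log <- audit_log()
  e1 <- record(log, "merge",
               parameters = list(keep_id = "1", drop_id = "2",
                                 merged_label = ""),
               affected_ids = c("1", "2"))
  expect_equal(e1$sequence_number, 1L)
  e2 <- record(log, "assemble")
  expect_equal(e2$sequence_number, 2L)
  expect_identical(log$entries[[2]], e2)
  expect_error(record(log, "paint"), "unknown audit action")
  expect_error(record(log, "merge", parameters = list(keep_id = "1")),
               "drop_id")
  expect_length(log$entries, 2L)  # failed records append nothing
})

test_that("every fetched AOP receives a credit entry with its authors", {
  log <- audit_log()
  src <- fixture_source(case_study_fixture())
  fetch_bundle(src, aop_ids = c("12", "260"), log = log)
  acts <- vapply(log$entries, `[[`, "", "action")
  credits <- log$entries[acts == "credit"]
  expect_length(credits, 2L)
  by_aop <- setNames(credits, vapply(credits, function(e)
    e$parameters$aop_id, ""))
  expect_setequal(names(by_aop), c("12", "260"))
  expect_equal(by_aop[["12"]]$parameters$authors, c("A. Smith", "B. Jones"))
  expect_equal(by_aop[["260"]]$parameters$authors, "C. Nguyen")
  expect_equal(by_aop[["12"]]$parameters$missing_authors, "FALSE")
})

test_that("an AOP without authors is credited with a missing-authors flag", {
  log <- audit_log()
  credit_authors(log, data.frame(aop_id = character(0),
                                 author = character(0)),
                 all_aops = "42")
  expect_length(log$entries, 1L)
  expect_equal(log$entries[[1]]$parameters$missing_authors, "TRUE")
  expect_length(log$entries[[1]]$parameters$authors, 0L)
})

test_that("log write/read round trip is exact", {
  log <- audit_log()
  src <- fixture_source(case_study_fixture())
  b <- fetch_bundle(src, aop_ids = c("12", "260"), log = log)
  net <- assemble(b, log = log)
  net <- apply_merge(net, "105", "204")
  write_graphml(net, tempfile(fileext = ".graphml"))
  p <- tempfile(fileext = ".jsonl")
  write_log(log, p)
  back <- read_log(p)
  expect_length(back$entries, length(log$entries))
  for (i in seq_along(log$entries)) {
    expect_identical(back$entries[[i]], log$entries[[i]])
  }
  # rewriting the read log is byte-identical
  p2 <- tempfile(fileext = ".jsonl")
  write_log(back, p2)
  expect_identical(readLines(p2), readLines(p))
  # empty log round trip
  p3 <- tempfile(fileext = ".jsonl")
  write_log(audit_log(), p3)
  expect_length(read_log(p3)$entries, 0L)
})

test_that("a corrupted log line is a parse error citing its line number", {
  log <- audit_log()
  for (i in 1:4) record(log, "assemble")
  p <- tempfile(fileext = ".jsonl")
  write_log(log, p)
  lines <- readLines(p)
  lines[3] <- substr(lines[3], 1, 20)
  writeLines(lines, p)
  expect_error(read_log(p), "line 3")
})

test_that("replay regenerates the session network exactly", {
  src <- fixture_source(case_study_fixture())
  log <- audit_log()
  b <- fetch_bundle(src, aop_ids = c("12", "260"), log = log)
  net <- assemble(b, log = log)
  net <- apply_merge(net, "105", "204")
  net <- ego_network(net, "105", degree = 2, include_genes = TRUE)
  write_tables(net, tempfile(), "csv")  # export entries must be skipped
  p <- tempfile(fileext = ".jsonl")
  write_log(log, p)
  replayed <- replay(read_log(p), src)
  expect_true(network_equal(replayed, net))
})

test_that("replay of an empty log is an empty network", {
  src <- fixture_source(case_study_fixture())
  net <- replay(audit_log(), src)
  expect_length(net$key_events, 0L)
  expect_length(net$aops, 0L)
})

test_that("replay fails at the fetch entry when an AOP has vanished", {
  fx <- case_study_fixture()
  src <- fixture_source(fx)
  log <- audit_log()
  b <- fetch_bundle(src, aop_ids = c("12", "260"), log = log)
  assemble(b, log = log)
  # rebuild the source without AOP 260
  trips <- parse_turtle(fx$turtle)
  trips <- trips[!grepl("aop/260$", trips$subject), ]
  ttl2 <- tempfile(fileext = ".ttl")
  writeLines(write_turtle(trips, default_vocabulary()$prefixes), ttl2,
             sep = "")
  expect_error(replay(log, rdf_source(ttl2)),
               "replay error at entry 1.*260")
})

test_that("replay fails with the entry number when a merge target is gone", {
  src <- fixture_source(case_study_fixture())
  log <- audit_log()
  b <- fetch_bundle(src, aop_ids = "12", log = log)
  net <- assemble(b, log = log)
  # forge a directive referencing a node the source no longer yields
  record(log, "merge", parameters = list(keep_id = "105", drop_id = "204",
                                         merged_label = ""),
         affected_ids = c("105", "204"))
  expect_error(replay(log, src), "replay error at entry")
})

test_that("status-filtered fetches replay without spurious missing-id errors", {
  src <- fixture_source(case_study_fixture())
  log <- audit_log()
  b <- fetch_bundle(src, aop_ids = c("12", "260"),
                    status_filter = "Endorsed", log = log)
  expect_equal(nrow(b$aops), 1L)
  net <- assemble(b, log = log)
  replayed <- replay(log, src)
  expect_true(network_equal(replayed, net))
})
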