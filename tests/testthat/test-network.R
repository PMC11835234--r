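test_that("a single linear AOP assembles to its chain", {
  fx <- generate_fixture(fixture_spec(n_aops = 1, ke_per_aop = 3,
                                      share_prob = 0, seed = 2))
  net <- fixture_network(fx)
  expect_length(net$key_events, 3L)
  expect_length(net$kers, 2L)
  expect_length(net$aops, 1L)
  a <- net$aops[[1]]
  expect_length(a$mie_ids, 1L)
  expect_length(a$ao_ids, 1L)
  expect_valid_network(net)
})

test_that("case-study AOPs share no KE node before any merge", {
  net <- case_study_network()
  shared <- Filter(function(k) length(k$member_aops) > 1L, net$key_events)
  expect_length(shared, 0L)
  expect_length(net$key_events, 9L)
  expect_setequal(net$key_events[[CS_AO_PLAIN]]$member_aops, "12")
  expect_setequal(net$key_events[[CS_AO_NA]]$member_aops, "260")
})

test_that("assembly deduplicates: doubled bundle equals single bundle", {
  for (seed in c(7, 19, 33)) {
    fx <- generate_fixture(fixture_spec(seed = seed))
    b <- fetch_bundle(fixture_source(fx), aop_ids = manifest_aop_ids(fx))
    doubled <- b
    for (part in c("aops", "memberships", "key_events", "kers", "gene_links",
                   "authors")) {
      doubled[[part]] <- rbind(b[[part]], b[[part]])
    }
    expect_true(network_equal(assemble(doubled), assemble(b)))
  }
})

test_that("node counts equal the generator's distinct-KE ground truth", {
  fx <- generate_fixture(fixture_spec(seed = 7))
  net <- fixture_network(fx)
  expect_length(net$key_events, fx$manifest$counts$key_events)
  expect_length(net$kers, fx$manifest$counts$kers)
})

test_that("assembly rejects a dangling KER endpoint by name", {
  b <- fetch_bundle(fixture_source(case_study_fixture()),
                    aop_ids = c("12", "260"))
  b$kers$downstream[b$kers$ker_id == "301"] <- "777"
  b$key_events <- b$key_events[b$key_events$ke_id != "777", ]
  expect_error(assemble(b), "777")
})

test_that("filter_by_status keeps exactly the allowed AOPs' subgraph", {
  net <- case_study_network()
  f <- filter_by_status(net, "Endorsed")
  expect_equal(names(f$aops), "260")
  expect_setequal(names(f$key_events), c("201", "202", "203", "204"))
  expect_length(f$kers, 3L)
  expect_valid_network(f)
  # identity when every present status is allowed
  f_all <- filter_by_status(net, c("Under Development", "Endorsed"))
  expect_true(network_equal(f_all, net))
  # the input network is not modified
  expect_length(net$aops, 2L)
  # empty result is legal, with a warning entry
  f_none <- filter_by_status(net, "Under Review")
  expect_length(f_none$aops, 0L)
  expect_true(any(grepl("retained no AOPs", f_none$warnings)))
  expect_error(filter_by_status(net, character(0)), "nonempty")
})

test_that("filtered KE set equals the brute-force union over allowed AOPs", {
  for (seed in c(5, 14, 27)) {
    fx <- generate_fixture(fixture_spec(seed = seed))
    net <- fixture_network(fx)
    statuses <- unique(vapply(net$aops, `[[`, "", "status"))
    allowed <- statuses[1]
    f <- filter_by_status(net, allowed)
    keep <- Filter(function(a) a$status %in% allowed, net$aops)
    expect_setequal(names(f$key_events),
                    unique(unlist(lapply(keep, `[[`, "ke_ids"))))
    expect_valid_network(f)
  }
})

test_that("node_detail is a faithful projection and errors on unknown ids", {
  net <- case_study_network()
  d <- node_detail(net, "203")
  expect_equal(d$title, "Oxidative stress")
  expect_equal(d$member_aops, "260")
  expect_error(node_detail(net, "0"), "not found")
})

test_that("highlight_aop returns exactly the AOP's chain", {
  net <- case_study_network()
  h <- highlight_aop(net, "12")
  expect_equal(h$nodes, c("101", "102", "103", "104", "105"))
  expect_equal(h$edges, c("301", "302", "303", "304"))
  expect_error(highlight_aop(net, "777"), "not found")
  # generated fixtures: highlight equals the stored Aop record
  fx <- generate_fixture(fixture_spec(seed = 9))
  gnet <- fixture_network(fx)
  for (a in gnet$aops) {
    h <- highlight_aop(gnet, a$aop_id)
    expect_setequal(h$nodes, a$ke_ids)
    expect_setequal(h$edges, a$ker_ids)
  }
})

test_that("ego_network matches path-graph expectations on a 5-chain", {
  fx <- generate_fixture(fixture_spec(n_aops = 1, ke_per_aop = 5,
                                      share_prob = 0, seed = 4))
  net <- fixture_network(fx)
  chain <- fx$manifest$aops[[1]]$ke_ids
  center <- chain[3]
  e1 <- ego_network(net, center, degree = 1)
  expect_setequal(names(e1$key_events), chain[2:4])
  expect_length(e1$kers, 2L)
  e2 <- ego_network(net, center, degree = 2)
  expect_setequal(names(e2$key_events), chain)
  expect_error(ego_network(net, "nope", 1), "not found")
  expect_error(ego_network(net, center, 3), "degree must be 1 or 2")
  expect_error(ego_network(net, character(0), 1), "nonempty")
})

test_that("ego_network node sets equal an independent BFS oracle", {
  for (seed in 101:120) {
    fx <- generate_fixture(fixture_spec(n_aops = 3, ke_per_aop = 4,
                                        seed = seed))
    net <- fixture_network(fx)
    ids <- names(net$key_events)
    set.seed(seed)
    seeds <- sample(ids, min(2L, length(ids)))
    from <- vapply(net$kers, `[[`, "", "upstream_ke_id")
    to <- vapply(net$kers, `[[`, "", "downstream_ke_id")
    prev <- NULL
    for (deg in 1:2) {
      e <- ego_network(net, seeds, degree = deg)
      expect_identical(sort(names(e$key_events)),
                       bfs_oracle(ids, from, to, seeds, deg))
      expect_valid_network(e)
      if (!is.null(prev)) {
        expect_true(all(names(prev$key_events) %in% names(e$key_events)))
        expect_true(all(names(prev$kers) %in% names(e$kers)))
      }
      prev <- e
    }
  }
})

test_that("gene nodes are annotation-only in neighbourhood extraction", {
  net <- case_study_network()
  e <- ego_network(net, "201", degree = 1, include_genes = TRUE)
  # CYP2E1 is attached to the retained MIE but contributes no extra KE hops
  expect_setequal(names(e$key_events), c("201", "202"))
  expect_equal(names(e$gene_nodes), "CYP2E1")
  e2 <- ego_network(net, "201", degree = 1, include_genes = FALSE)
  expect_length(e2$gene_nodes, 0L)
})

test_that("referential integrity violations are caught by the validator", {
  net <- case_study_network()
  broken <- net
  broken$key_events[["105"]]$member_aops <- c("12", "260")
  expect_error(validate_network(broken), "member_aops inconsistent")
  broken2 <- net
  broken2$kers[["301"]]$downstream_ke_id <- "12345"
  expect_error(validate_network(broken2), "dangling KER endpoint")
})
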