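test_that("normalize_label strips, folds and collapses whitespace", {
  expect_equal(normalize_label("  Neurodegeneration "), "neurodegeneration")
  expect_equal(normalize_label("N/A,   Neurodegeneration"),
               "n/a, neurodegeneration")
  expect_equal(normalize_label("A\tB\n C"), "a b c")
  set.seed(1)
  for (i in 1:50) {
    s <- rand_string(sample(0:15, 1), c(LETTERS, letters, " ", "\t", ",", "/"))
    expect_identical(normalize_label(normalize_label(s)), normalize_label(s))
  }
})

test_that("levenshtein handles the boundary and paper-pair cases", {
  expect_equal(levenshtein("Neurodegeneration", "Neurodegeneration"), 0L)
  expect_equal(levenshtein("", "abc"), 3L)
  expect_equal(levenshtein("abc", ""), 3L)
  expect_equal(levenshtein("kitten", "sitting"), 3L)
  # the case-study pair, checked against the memoized-recursion oracle
  pair <- c("n/a, neurodegeneration", "neurodegeneration")
  expect_equal(levenshtein(pair[1], pair[2]), 5L)
  expect_equal(lev_memo(pair[1], pair[2]), 5L)
})

test_that("levenshtein equals the naive recursion exhaustively at small n", {
  alphabet <- c("a", "b", "c")
  strs <- ""
  for (len in 1:3) {
    strs <- c(strs, apply(expand.grid(rep(list(alphabet), len)), 1, paste,
                          collapse = ""))
  }
  d <- levenshtein_matrix(strs, strs)
  ok <- TRUE
  for (i in seq_along(strs)) {
    for (j in seq_len(i)) {
      ok <- ok && identical(d[i, j], lev_naive(strs[i], strs[j]))
    }
  }
  expect_true(ok)
})

test_that("levenshtein is a metric on random strings", {
  set.seed(99)
  strs <- vapply(1:30, function(i) rand_string(sample(0:12, 1), c("a", "b", "c", "d")), "")
  d <- levenshtein_matrix(strs, strs)
  expect_true(all(diag(d) == 0L))
  expect_identical(d, t(d))
  n <- length(strs)
  for (k in 1:200) {
    ijk <- sample(n, 3, replace = TRUE)
    expect_lte(d[ijk[1], ijk[3]], d[ijk[1], ijk[2]] + d[ijk[2], ijk[3]])
  }
  # identity of indiscernibles
  expect_true(all((d == 0L) == outer(strs, strs, `==`)))
})

test_that("suggest_merges proposes the case-study pair at the default threshold", {
  net <- case_study_network()
  s <- suggest_merges(net)
  expect_equal(nrow(s), 1L)
  expect_equal(s$ke_id_a, CS_AO_PLAIN)
  expect_equal(s$ke_id_b, CS_AO_NA)
  expect_setequal(c(s$label_a, s$label_b),
                  c("Neurodegeneration", "N/A, Neurodegeneration"))
  expect_equal(s$distance, 5L)
  expect_equal(s$similarity, 1 - 5 / 22, tolerance = 1e-12)
})

test_that("suggest_merges is monotone in threshold and validates input", {
  fx <- generate_fixture(fixture_spec(seed = 31, near_dup_rate = 0.5,
                                      share_prob = 0.5))
  net <- fixture_network(fx)
  prev <- NULL
  for (th in c(0.95, 0.85, 0.75, 0.6, 0.4)) {
    s <- suggest_merges(net, threshold = th)
    key <- paste(s$ke_id_a, s$ke_id_b)
    if (!is.null(prev)) expect_true(all(prev %in% key))
    expect_true(all(s$ke_id_a != s$ke_id_b))
    expect_true(all(s$similarity >= th))
    prev <- key
  }
  expect_error(suggest_merges(net, threshold = 0), "threshold")
  expect_error(suggest_merges(net, threshold = 1.2), "threshold")
})

test_that("threshold 1 pairs only label-identical nodes", {
  fx <- generate_fixture(fixture_spec(n_aops = 2, ke_per_aop = 4,
                                      share_prob = 0, seed = 8))
  net <- fixture_network(fx)  # all labels distinct by construction
  expect_equal(nrow(suggest_merges(net, threshold = 1)), 0L)
})

test_that("merging the case-study AOs joins the two pathways", {
  log <- audit_log()
  net <- case_study_network(log = log)
  merged <- apply_merge(net, keep_id = CS_AO_PLAIN, drop_id = CS_AO_NA)
  expect_length(merged$key_events, length(net$key_events) - 1L)
  ao <- merged$key_events[[CS_AO_PLAIN]]
  expect_equal(ao$title, "Neurodegeneration")
  expect_setequal(ao$member_aops, c("12", "260"))
  expect_equal(ao$roles, "AO")
  # both AOP highlights now contain the shared AO node
  expect_true(CS_AO_PLAIN %in% highlight_aop(merged, "12")$nodes)
  expect_true(CS_AO_PLAIN %in% highlight_aop(merged, "260")$nodes)
  # detail of the merged node is the union projection
  d <- node_detail(merged, CS_AO_PLAIN)
  expect_setequal(d$member_aops, c("12", "260"))
  expect_valid_network(merged)
  # the directive was recorded before mutation
  acts <- vapply(log$entries, `[[`, "", "action")
  expect_true("merge" %in% acts)
  m <- log$entries[[which(acts == "merge")[1]]]
  expect_equal(m$parameters$keep_id, CS_AO_PLAIN)
  expect_equal(m$parameters$drop_id, CS_AO_NA)
})

test_that("merging two isolated nodes leaves the edge count at zero", {
  src <- fixture_source(case_study_fixture())
  b <- fetch_bundle(src, aop_ids = c("12", "260"))
  b$kers <- b$kers[0, ]  # a source with its KERs missing: isolated KEs
  net <- assemble(b)
  expect_length(net$kers, 0L)
  merged <- apply_merge(net, "105", "204")
  expect_length(merged$kers, 0L)
  expect_length(merged$key_events, length(net$key_events) - 1L)
})

test_that("apply_merge validates its directive", {
  net <- case_study_network()
  expect_error(apply_merge(net, "105", "105"), "must differ")
  expect_error(apply_merge(net, "105", "999"), "not found")
  expect_error(apply_merge(net, "999", "105"), "not found")
  relabeled <- apply_merge(net, "105", "204", merged_label = "Custom AO")
  expect_equal(relabeled$key_events[["105"]]$title, "Custom AO")
})

test_that("merge conserves neighbourhoods and asserting-AOP sets", {
  for (seed in 301:320) {
    fx <- generate_fixture(fixture_spec(n_aops = 3, ke_per_aop = 4,
                                        share_prob = 0.4, seed = seed))
    net <- fixture_network(fx)
    ids <- names(net$key_events)
    set.seed(seed)
    pick <- sample(ids, 2L)
    keep <- pick[1]; drop <- pick[2]
    # oracles computed on the pre-merge graph
    nbrs <- function(v) {
      unique(unlist(lapply(net$kers, function(k) {
        if (k$upstream_ke_id == v) k$downstream_ke_id
        else if (k$downstream_ke_id == v) k$upstream_ke_id
      })))
    }
    expect_deg <- length(setdiff(union(nbrs(keep), nbrs(drop)), c(keep, drop)))
    aop_multiset <- sort(unlist(lapply(net$kers, function(k) {
      u <- ifelse(k$upstream_ke_id == drop, keep, k$upstream_ke_id)
      d <- ifelse(k$downstream_ke_id == drop, keep, k$downstream_ke_id)
      if (u == d) character(0)
      else paste(u, d, k$asserting_aops, sep = "\r")
    }), use.names = FALSE))
    merged <- apply_merge(net, keep, drop)
    expect_length(merged$key_events, length(ids) - 1L)
    expect_valid_network(merged)
    g <- as_igraph(merged)
    und <- igraph::as_undirected(igraph::simplify(g))
    expect_equal(unname(igraph::degree(und, keep)), expect_deg)
    got_multiset <- sort(unlist(lapply(merged$kers, function(k) {
      paste(k$upstream_ke_id, k$downstream_ke_id, k$asserting_aops, sep = "\r")
    }), use.names = FALSE))
    expect_identical(got_multiset, unique(aop_multiset))
    # member-AOP union on the kept node
    expect_setequal(merged$key_events[[keep]]$member_aops,
                    union(net$key_events[[keep]]$member_aops,
                          net$key_events[[drop]]$member_aops))
    # gene nodes outside the participants are untouched
    expect_identical(merged$gene_nodes, net$gene_nodes)
  }
})
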