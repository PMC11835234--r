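# Independent oracles and fixture helpers shared across the test files.

# Naive exponential-recursion edit distance: the slow, obviously-correct
# definition, independent of the package's iterative DP.
lev_naive <- function(a, b) {
  if (!nchar(a)) return(nchar(b))
  if (!nchar(b)) return(nchar(a))
  cost <- if (substr(a, 1, 1) == substr(b, 1, 1)) 0L else 1L
  ta <- substring(a, 2)
  tb <- substring(b, 2)
  min(lev_naive(ta, tb) + cost, lev_naive(ta, b) + 1L, lev_naive(a, tb) + 1L)
}

# Memoized top-down recursion: same recurrence, tractable at length ~20.
lev_memo <- function(a, b) {
  m <- nchar(a)
  n <- nchar(b)
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  memo <- matrix(NA_integer_, m + 1L, n + 1L)
  rec <- function(i, j) {
    if (!is.na(memo[i + 1L, j + 1L])) return(memo[i + 1L, j + 1L])
    v <- if (i == 0L) j else if (j == 0L) i else {
      cost <- if (ca[i] == cb[j]) 0L else 1L
      min(rec(i - 1L, j - 1L) + cost, rec(i - 1L, j) + 1L, rec(i, j - 1L) + 1L)
    }
    memo[i + 1L, j + 1L] <<- v
    v
  }
  rec(m, n)
}

rand_string <- function(len, alphabet = letters) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Breadth-first-search oracle over an undirected edge list, independent of
# igraph: nodes within `degree` hops of any seed.
bfs_oracle <- function(nodes, edges_from, edges_to, seeds, degree) {
  adj <- setNames(vector("list", length(nodes)), nodes)
  for (i in seq_along(edges_from)) {
    adj[[edges_from[i]]] <- c(adj[[edges_from[i]]], edges_to[i])
    adj[[edges_to[i]]] <- c(adj[[edges_to[i]]], edges_from[i])
  }
  dist <- setNames(rep(Inf, length(nodes)), nodes)
  dist[seeds] <- 0
  frontier <- seeds
  d <- 0
  while (length(frontier) && d < degree) {
    d <- d + 1
    nxt <- character(0)
    for (v in frontier) {
      for (w in adj[[v]]) {
        if (dist[[w]] > d) {
          dist[[w]] <- d
          nxt <- c(nxt, w)
        }
      }
    }
    frontier <- unique(nxt)
  }
  sort(names(dist)[is.finite(dist)])
}

# Write a fixture's Turtle to a temp file (cleaned with the session tempdir)
# and return an rdf_source.
fixture_source <- function(fx, env = parent.frame()) {
  ttl <- tempfile(fileext = ".ttl")
  writeLines(fx$turtle, ttl, sep = "")
  rdf_source(ttl)
}

manifest_aop_ids <- function(fx) {
  vapply(fx$manifest$aops, function(a) a$aop_id, "")
}

# Fetch + assemble one generated fixture.
fixture_network <- function(fx, env = parent.frame(), log = NULL) {
  src <- fixture_source(fx, env = env)
  assemble(fetch_bundle(src, aop_ids = manifest_aop_ids(fx), log = log),
           log = log)
}

case_study_network <- function(env = parent.frame(), log = NULL) {
  fixture_network(case_study_fixture(), env = env, log = log)
}

# The two case-study adverse-outcome node ids.
CS_AO_PLAIN <- "105"   # "Neurodegeneration"
CS_AO_NA <- "204"      # "N/A, Neurodegeneration"

expect_valid_network <- function(net) {
  expect_true(validate_network(net))
}
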