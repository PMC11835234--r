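# Synthetic AOP-Wiki-shaped RDF fixtures.
#
# Each generated AOP is a linear MIE -> KE ... -> AO chain; chains
# probabilistically reuse existing KEs (which is what makes multi-AOP
# networks connect) and occasionally reuse a *concept* under a new id with
# a perturbed label — the near-duplicate situation the Levenshtein merge
# suggestion exists for.  A ground-truth manifest accompanies the Turtle so
# ingest and assembly can be checked against independent counts.

KE_PHRASES <- c(
  "Activation, CYP2E1", "Formation, Protein adducts", "Oxidative stress",
  "Increased, Reactive oxygen species", "Mitochondrial dysfunction",
  "Decreased, ATP production", "Increased, Apoptosis",
  "Inhibition, Acetylcholinesterase", "Accumulation, Acetylcholine",
  "Receptor desensitization", "Decreased, Synaptic transmission",
  "Impaired, Learning and memory", "Neuroinflammation",
  "Activation, Microglia", "Increased, Pro-inflammatory cytokines",
  "Disruption, Blood brain barrier", "Decreased, Neuronal network function",
  "Binding, Thyroid hormone receptor", "Decreased, Thyroxine levels",
  "Altered, Gene expression", "Increased, Lipid peroxidation",
  "DNA damage", "Cell cycle arrest", "Increased, Cell proliferation",
  "Hepatic steatosis", "Increased, Liver fibrosis", "Cholestasis",
  "Decreased, Testosterone synthesis", "Impaired, Spermatogenesis",
  "Reduced, Fertility", "Agonism, Aryl hydrocarbon receptor",
  "Induction, CYP1A1", "Thymocyte apoptosis", "Immunosuppression",
  "Increased, Susceptibility to infection", "Kidney tubule necrosis",
  "Decreased, Glomerular filtration", "Renal failure",
  "Vascular endothelial dysfunction", "Increased, Blood pressure",
  "Cardiac hypertrophy", "Heart failure", "Bronchoconstriction",
  "Airway inflammation", "Decreased, Lung function",
  "Follicular atresia", "Decreased, Estradiol", "Anovulation",
  "Increased, Osteoclast activity", "Decreased, Bone density"
)

GENE_SYMBOLS <- c("CYP2E1", "GRIN1", "ACHE", "TNF", "IL6", "NFE2L2", "TP53",
                  "CASP3", "BAX", "SOD1", "CAT", "GPX1", "AHR", "CYP1A1",
                  "ESR1", "AR", "THRB", "BDNF", "APP", "MAPT")

AUTHOR_NAMES <- c("A. Smith", "B. Jones", "C. Nguyen", "D. Okafor",
                  "E. Virtanen", "F. Rossi", "G. Tanaka", "H. Mueller")

#' Describe a synthetic fixture
#'
#' @param n_aops number of AOPs (positive).
#' @param ke_per_aop chain length per AOP (>= 2, so each AOP has an MIE and
#'   an AO).
#' @param share_prob probability in `[0, 1]` that a chain slot reuses an
#'   existing KE rather than introducing a fresh one.
#' @param near_dup_rate probability in `[0, 1]` that a reuse instead becomes
#'   a near-duplicate: a new id carrying a perturbed copy of the reused
#'   label.
#' @param n_gene_links_per_ke gene links attached to each fresh KE.
#' @param statuses status strings sampled uniformly per AOP.
#' @param seed integer seed; identical spec + seed gives byte-identical
#'   Turtle.
#' @return A validated `fixture_spec` list.
#' @export
fixture_spec <- function(n_aops = 6, ke_per_aop = 5, share_prob = 0.3,
                         near_dup_rate = 0.2, n_gene_links_per_ke = 1,
                         statuses = c("Under Development", "Under Review",
                                      "Endorsed"),
                         seed = 1L) {
  spec <- list(n_aops = as.integer(n_aops), ke_per_aop = as.integer(ke_per_aop),
               share_prob = share_prob, near_dup_rate = near_dup_rate,
               n_gene_links_per_ke = as.integer(n_gene_links_per_ke),
               statuses = as.character(statuses), seed = as.integer(seed))
  if (spec$n_aops < 1L) stop("n_aops must be positive", call. = FALSE)
  if (spec$ke_per_aop < 2L) {
    stop("ke_per_aop must be >= 2 (every AOP needs an MIE and an AO)",
         call. = FALSE)
  }
  for (p in c("share_prob", "near_dup_rate")) {
    if (!is.finite(spec[[p]]) || spec[[p]] < 0 || spec[[p]] > 1) {
      stop(p, " must be in [0, 1]", call. = FALSE)
    }
  }
  if (spec$n_gene_links_per_ke < 0L) {
    stop("n_gene_links_per_ke must be non-negative", call. = FALSE)
  }
  if (!length(spec$statuses)) stop("statuses must be nonempty", call. = FALSE)
  class(spec) <- "fixture_spec"
  spec
}

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Perturbation menu for near-duplicate labels; the "N/A, " prefix first.
# The chosen perturbation is required to stay suggestible at the default
# threshold (0.75 on normalized labels) so injected pairs are recoverable;
# if a draw would fall below, the single-typo fallback (distance 1 after
# normalization) is used.
perturb_label <- function(label, rng_draw) {
  cands <- list(
    function(s) paste0("N/A, ", s),
    function(s) toupper(s),
    function(s) gsub(" ", "  ", s, fixed = TRUE),
    function(s) {  # single-character substitution typo
      i <- max(2L, nchar(s) %/% 2L)
      ch <- substr(s, i, i)
      repl <- if (identical(ch, "x")) "y" else "x"
      paste0(substr(s, 1L, i - 1L), repl, substring(s, i + 1L))
    }
  )
  pick <- cands[[rng_draw]]
  out <- pick(label)
  if (label_similarity(label, out) < 0.75) out <- cands[[4L]](label)
  out
}

fixture_vocab_prefixes <- function(vocabulary) {
  c(vocabulary$prefixes,
    aopo = "http://aopkb.org/aop_ontology#",
    dc = "http://purl.org/dc/elements/1.1/")
}

fixture_triples <- function(entities, vocabulary) {
  rel <- function(name) vocab_relation(vocabulary, name)
  px <- vocabulary$prefixes
  t <- triple_frame()
  add <- function(s, p, o, type) {
    t <<- rbind(t, triple_frame(s, p, o, type))
  }
  for (a in entities$aops) {
    s <- paste0(px[["aop"]], a$aop_id)
    add(s, RDF_TYPE, vocabulary$classes[["aop"]], "iri")
    add(s, rel("entity-title"), a$title, "literal")
    add(s, rel("aop-status"), a$status, "literal")
    for (auth in a$authors) add(s, rel("aop-author"), auth, "literal")
    for (ke in a$ke_ids) {
      add(s, rel("aop-has-ke"), paste0(px[["ke"]], ke), "iri")
    }
    add(s, rel("aop-has-mie"), paste0(px[["ke"]], a$mie_id), "iri")
    add(s, rel("aop-has-ao"), paste0(px[["ke"]], a$ao_id), "iri")
    for (kr in a$ker_ids) {
      add(s, rel("aop-has-ker"), paste0(px[["ker"]], kr), "iri")
    }
  }
  for (ke in entities$key_events) {
    s <- paste0(px[["ke"]], ke$ke_id)
    add(s, RDF_TYPE, vocabulary$classes[["ke"]], "iri")
    add(s, rel("entity-title"), ke$title, "literal")
    for (g in ke$gene_ids) {
      add(s, rel("ke-gene"), paste0(px[["gene"]], g), "iri")
    }
  }
  for (k in entities$kers) {
    s <- paste0(px[["ker"]], k$ker_id)
    add(s, RDF_TYPE, vocabulary$classes[["ker"]], "iri")
    add(s, rel("ker-upstream-ke"), paste0(px[["ke"]], k$upstream), "iri")
    add(s, rel("ker-downstream-ke"), paste0(px[["ke"]], k$downstream), "iri")
  }
  for (g in entities$genes) {
    s <- paste0(px[["gene"]], g$gene_id)
    add(s, rel("entity-title"), g$label, "literal")
  }
  t
}

fixture_manifest <- function(entities, near_dups) {
  n_memberships <- sum(vapply(entities$aops, function(a) length(a$ke_ids), 0L))
  n_gene_links <- sum(vapply(entities$key_events,
                             function(k) length(k$gene_ids), 0L))
  n_authors <- sum(vapply(entities$aops, function(a) length(a$authors), 0L))
  list(
    counts = list(
      aops = length(entities$aops),
      key_events = length(entities$key_events),
      kers = length(entities$kers),
      memberships = n_memberships,
      gene_links = n_gene_links,
      authors = n_authors
    ),
    aops = entities$aops,
    key_events = entities$key_events,
    kers = entities$kers,
    genes = entities$genes,
    near_duplicates = near_dups
  )
}

#' Generate a synthetic AOP-Wiki-shaped fixture
#'
#' @param spec a [fixture_spec()].
#' @param vocabulary see [default_vocabulary()]; the Turtle uses its
#'   predicate IRIs and identifier prefixes.
#' @return A list with `turtle` (text) and `manifest` (ground-truth entity
#'   listing, counts and injected near-duplicate pairs).
#' @examples
#' fx <- generate_fixture(fixture_spec(n_aops = 2, ke_per_aop = 3, seed = 7))
#' fx$manifest$counts
#' @export
generate_fixture <- function(spec = fixture_spec(),
                             vocabulary = default_vocabulary()) {
  stopifnot(inherits(spec, "fixture_spec"))
  check_vocabulary(vocabulary)
  with_seed(spec$seed, {
    phrase_pool <- sample(KE_PHRASES)
    phrase_i <- 0L
    next_phrase <- function() {
      phrase_i <<- phrase_i + 1L
      if (phrase_i <= length(phrase_pool)) phrase_pool[[phrase_i]]
      else paste0(phrase_pool[[((phrase_i - 1L) %% length(phrase_pool)) + 1L]],
                  " (variant ", (phrase_i - 1L) %/% length(phrase_pool), ")")
    }
    ke_counter <- 100L
    ker_counter <- 9000L
    kes <- list()        # ke_id -> list(ke_id, title, gene_ids)
    kers <- list()       # "up\rdown" -> ker_id
    near_dups <- list()
    gene_ids_used <- character(0)
    aops <- list()
    ker_records <- list()
    new_ke <- function(title) {
      ke_counter <<- ke_counter + 1L
      id <- as.character(ke_counter)
      genes <- character(0)
      if (spec$n_gene_links_per_ke > 0L) {
        genes <- sample(GENE_SYMBOLS,
                        min(spec$n_gene_links_per_ke, length(GENE_SYMBOLS)))
        gene_ids_used <<- unique(c(gene_ids_used, genes))
      }
      kes[[id]] <<- list(ke_id = id, title = title, gene_ids = sort(genes))
      id
    }
    for (ai in seq_len(spec$n_aops)) {
      chain <- character(0)
      for (slot in seq_len(spec$ke_per_aop)) {
        reusable <- setdiff(names(kes), chain)
        reuse <- length(reusable) > 0L && stats::runif(1) < spec$share_prob
        if (reuse) {
          src <- sample(reusable, 1L)
          if (stats::runif(1) < spec$near_dup_rate) {
            draw <- sample.int(4L, 1L)
            dup_id <- new_ke(perturb_label(kes[[src]]$title, draw))
            near_dups[[length(near_dups) + 1L]] <-
              list(original_ke = src, duplicate_ke = dup_id,
                   original_label = kes[[src]]$title,
                   duplicate_label = kes[[dup_id]]$title)
            chain <- c(chain, dup_id)
          } else {
            chain <- c(chain, src)
          }
        } else {
          chain <- c(chain, new_ke(next_phrase()))
        }
      }
      ker_ids <- character(0)
      for (i in seq_len(length(chain) - 1L)) {
        key <- paste(chain[i], chain[i + 1L], sep = "\r")
        if (is.null(kers[[key]])) {
          ker_counter <- ker_counter + 1L
          kers[[key]] <- as.character(ker_counter)
          ker_records[[kers[[key]]]] <- list(ker_id = kers[[key]],
                                             upstream = chain[i],
                                             downstream = chain[i + 1L])
        }
        ker_ids <- c(ker_ids, kers[[key]])
      }
      aid <- as.character(ai)
      aops[[aid]] <- list(
        aop_id = aid,
        title = paste0("Synthetic pathway ", aid, ": ", kes[[chain[1L]]]$title,
                       " leading to ", kes[[chain[length(chain)]]]$title),
        status = sample(spec$statuses, 1L),
        authors = sort(sample(AUTHOR_NAMES, sample(1:2, 1L))),
        ke_ids = chain, mie_id = chain[1L], ao_id = chain[length(chain)],
        ker_ids = ker_ids
      )
    }
    genes <- lapply(sort(gene_ids_used),
                    function(g) list(gene_id = g, label = g))
    entities <- list(aops = aops, key_events = kes, kers = ker_records,
                     genes = genes)
    list(turtle = write_turtle(fixture_triples(entities, vocabulary),
                               fixture_vocab_prefixes(vocabulary)),
         manifest = fixture_manifest(entities, near_dups))
  })
}

#' The deterministic neurotoxicity case-study fixture
#'
#' Two AOPs with disjoint KE chains: AOP 260, "CYP2E1 activation and
#' formation of protein adducts leading to neurodegeneration" (status
#' Endorsed), ending in the adverse outcome labelled
#' `"N/A, Neurodegeneration"`, and AOP 12, "Chronic binding of antagonist to
#' N-methyl-D-aspartate receptors (NMDARs) during brain development leads to
#' neurodegeneration with impairment in learning and memory in aging"
#' (status Under Development), ending in `"Neurodegeneration"`.  Assembled
#' as retrieved, the two pathways share no KE node; merging the two AO
#' labels connects them — the canonical demonstration of the merge
#' workflow.  The chain interiors are synthetic; only the AOP titles, AO
#' labels and the disjoint-then-merged topology are modelled on the real
#' pathways.
#'
#' @param vocabulary see [default_vocabulary()].
#' @return A list with `turtle` and `manifest`, as [generate_fixture()].
#' @export
case_study_fixture <- function(vocabulary = default_vocabulary()) {
  check_vocabulary(vocabulary)
  ke <- function(id, title, genes = character(0)) {
    list(ke_id = id, title = title, gene_ids = genes)
  }
  kes <- list(
    `101` = ke("101", "Binding of antagonist, NMDA receptors", "GRIN1"),
    `102` = ke("102", "Inhibition, NMDARs"),
    `103` = ke("103", "Decreased, Calcium influx"),
    `104` = ke("104", "Aberrant, Dendritic morphology"),
    `105` = ke("105", "Neurodegeneration"),
    `201` = ke("201", "Activation, CYP2E1", "CYP2E1"),
    `202` = ke("202", "Formation, Protein adducts"),
    `203` = ke("203", "Oxidative stress"),
    `204` = ke("204", "N/A, Neurodegeneration")
  )
  ker <- function(id, up, down) list(ker_id = id, upstream = up,
                                     downstream = down)
  kers <- list(
    `301` = ker("301", "101", "102"), `302` = ker("302", "102", "103"),
    `303` = ker("303", "103", "104"), `304` = ker("304", "104", "105"),
    `401` = ker("401", "201", "202"), `402` = ker("402", "202", "203"),
    `403` = ker("403", "203", "204")
  )
  aops <- list(
    `12` = list(
      aop_id = "12",
      title = paste("Chronic binding of antagonist to N-methyl-D-aspartate",
                    "receptors (NMDARs) during brain development leads to",
                    "neurodegeneration with impairment in learning and",
                    "memory in aging"),
      status = "Under Development",
      authors = c("A. Smith", "B. Jones"),
      ke_ids = c("101", "102", "103", "104", "105"),
      mie_id = "101", ao_id = "105",
      ker_ids = c("301", "302", "303", "304")
    ),
    `260` = list(
      aop_id = "260",
      title = paste("CYP2E1 activation and formation of protein adducts",
                    "leading to neurodegeneration"),
      status = "Endorsed",
      authors = "C. Nguyen",
      ke_ids = c("201", "202", "203", "204"),
      mie_id = "201", ao_id = "204",
      ker_ids = c("401", "402", "403")
    )
  )
  genes <- list(list(gene_id = "CYP2E1", label = "CYP2E1"),
                list(gene_id = "GRIN1", label = "GRIN1"))
  entities <- list(aops = aops, key_events = kes, kers = kers, genes = genes)
  near_dups <- list(list(original_ke = "105", duplicate_ke = "204",
                         original_label = "Neurodegeneration",
                         duplicate_label = "N/A, Neurodegeneration"))
  list(turtle = write_turtle(fixture_triples(entities, vocabulary),
                             fixture_vocab_prefixes(vocabulary)),
       manifest = fixture_manifest(entities, near_dups))
}
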