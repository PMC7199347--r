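#' Default synthetic MeSH vocabulary
#'
#' The background term vocabulary of the synthetic corpus generator. Each
#' term carries `p_article`, its per-article occurrence probability, and
#' `p_major`, the probability that an occurrence is flagged as a major
#' topic. `tree_numbers` places terms in a synthetic MeSH tree: some under
#' the immune categories A15/G12, some under other branches, and some
#' deliberately unmapped, so the category filter always has both outcomes
#' to exercise. Tree numbers are synthetic stand-ins shaped like real MeSH
#' codes, not the NLM assignments.
#'
#' @return Data frame with columns `term`, `p_article`, `p_major`,
#'   `tree_numbers` (semicolon-joined; empty = unmapped).
#' @export
default_vocabulary <- function() {
  data.frame(
    term = c("Signal Transduction", "Fish Diseases", "Brain", "Liver",
             "Transcription Factors", "Apoptosis", "Cell Movement",
             "Oncorhynchus mykiss", "Spleen", "Immune Evasion",
             "B-Lymphocytes", "Adaptive Immunity", "Aquaculture",
             "Gene Expression Profiling"),
    p_article = c(0.22, 0.20, 0.15, 0.15, 0.12, 0.12, 0.10,
                  0.10, 0.08, 0.05, 0.06, 0.06, 0.08, 0.10),
    p_major = c(0.5, 0.4, 0.3, 0.3, 0.5, 0.6, 0.5,
                0.2, 0.4, 0.6, 0.5, 0.6, 0.3, 0.4),
    tree_numbers = c("G07.690", "C22.362", "A08.186.211", "A03.620",
                     "D12.776.930", "G04.146", "G04.198",
                     "B01.050.150", "A15.382.520;A10.549",
                     "G12.450.050", "A15.145.229", "G12.425.069",
                     "", ""),
    stringsAsFactors = FALSE)
}

#' Specification of a synthetic annotation corpus
#'
#' Describes the jointly consistent fixture set the generator emits: a
#' BLAST hit table with rank-decaying identities, an accession-to-PMID link
#' table, an article store with major/minor MeSH headings, a synthetic MeSH
#' tree map, and accession-to-taxid maps. A term enrichment can be planted:
#' articles linked to a chosen target subset of queries carry the planted
#' term with probability `p_hi`, all other articles with `p_lo`, giving a
#' known ground truth for recovery tests. The defaults are the generator's
#' study conditions: 50 queries, 20 of them targets, `p_hi = 0.8`,
#' `p_lo = 0.05`, 5 hits per query, and about 6 linked articles per query.
#'
#' @param n_queries Number of query contigs.
#' @param hits_per_query Hits emitted per query (before filtering).
#' @param identity_decay Length-2 numeric: percent identity at rank 1 and at
#'   the deepest rank; identities decay linearly between them (plus a small
#'   rank-local jitter) and never cross the 40% floor.
#' @param n_articles Size of the PMID pool articles are drawn from without
#'   replacement.
#' @param vocabulary Background term table (see [default_vocabulary()]).
#' @param planted `NULL`, or a list with `term`, `targets` (query IDs;
#'   `NULL` = first `min(20, n_queries)` queries), `p_hi`, `p_lo`, `facet`
#'   (`"major"` or `"minor"`), and optionally `tree_numbers` for the planted
#'   term's place in the synthetic MeSH tree.
#' @param link_density Expected linked PMIDs per accession (Poisson); every
#'   query is guaranteed at least one linked article overall.
#' @param accession_share Probability that a hit reuses an accession already
#'   emitted for an earlier query (exercises the article-sharing and
#'   deduplication paths; 0 keeps queries' literatures disjoint).
#' @param seed RNG seed; the whole bundle is a deterministic function of the
#'   spec including this seed.
#' @return A `corpus_spec` list.
#' @export
corpus_spec <- function(n_queries = 50L,
                        hits_per_query = 5L,
                        identity_decay = c(95, 55),
                        n_articles = 2000L,
                        vocabulary = default_vocabulary(),
                        planted = list(term = "Immunity, Innate",
                                       targets = NULL,
                                       p_hi = 0.8, p_lo = 0.05,
                                       facet = "major",
                                       tree_numbers = "G12.425.214"),
                        link_density = 1.2,
                        accession_share = 0,
                        seed = 1L) {
  n_queries <- as.integer(n_queries)
  hits_per_query <- as.integer(hits_per_query)
  stopifnot(n_queries >= 0L, hits_per_query >= 0L, n_articles >= 0L,
            length(identity_decay) == 2L,
            all(identity_decay >= 40, identity_decay <= 100),
            link_density >= 0, accession_share >= 0, accession_share <= 1,
            all(vocabulary$p_article >= 0 & vocabulary$p_article <= 1),
            all(vocabulary$p_major >= 0 & vocabulary$p_major <= 1))
  queries <- sprintf("q%03d", seq_len(n_queries))
  if (!is.null(planted)) {
    if (is.null(planted$targets)) {
      planted$targets <- queries[seq_len(min(20L, n_queries))]
    }
    if (!all(planted$targets %in% queries)) {
      stop("planted target subset is not a subset of the corpus queries")
    }
    stopifnot(planted$p_hi >= 0, planted$p_hi <= 1,
              planted$p_lo >= 0, planted$p_lo <= 1,
              planted$p_hi > planted$p_lo,
              planted$facet %in% c("major", "minor"))
    if (planted$term %in% vocabulary$term) {
      stop("planted term must not also be a background vocabulary term")
    }
    if (is.null(planted$tree_numbers)) planted$tree_numbers <- ""
  }
  structure(list(n_queries = n_queries, hits_per_query = hits_per_query,
                 identity_decay = as.numeric(identity_decay),
                 n_articles = as.integer(n_articles),
                 vocabulary = vocabulary, planted = planted,
                 link_density = link_density,
                 accession_share = accession_share,
                 seed = as.integer(seed), queries = queries,
                 rng = "Mersenne-Twister"),
            class = "corpus_spec")
}

corpus_files <- c(hits = "hits.tsv", links = "links.tsv",
                  articles = "articles.tsv", mesh_tree = "mesh_tree.tsv",
                  acc2tax = "acc2tax.tsv", tax_names = "tax_names.tsv",
                  queries = "queries.fa")

#' Generate a synthetic annotation corpus
#'
#' Writes a mutually consistent fixture bundle (hit table, link TSV,
#' article TSV, MeSH tree TSV, taxonomic maps, placeholder query FASTA)
#' into `out_dir` and returns the paths plus the planted-enrichment ground
#' truth. Fully deterministic: the same spec (including its seed) produces
#' byte-identical files; the RNG algorithm is recorded in the spec so this
#' is a supported promise. Every accession appearing in the hit table
#' appears in the link table (with `-` when unlinked), and every linked
#' PMID appears in the article TSV. Identities decrease with hit rank, so
#' the bundle also serves the depth-scan monotonicity checks.
#'
#' @param spec A [corpus_spec()].
#' @param out_dir Output directory (created if needed).
#' @return A `corpus_bundle`: list with `paths` (named file paths), `spec`
#'   and `ground_truth` (`planted_term`, `targets`, `facet`; `NULL` when
#'   nothing is planted).
#' @export
generate_corpus <- function(spec, out_dir) {
  stopifnot(inherits(spec, "corpus_spec"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- setNames(file.path(out_dir, corpus_files), names(corpus_files))
  with_seed(spec$seed, {
    n <- spec$n_queries
    h <- spec$hits_per_query
    queries <- spec$queries

    # --- hit table: accessions, rank-decaying identities -------------------
    acc_counter <- 0L
    acc_pool <- character()
    hit_rows <- vector("list", n)
    acc_by_query <- vector("list", n)
    for (i in seq_len(n)) {
      accs <- character(h)
      for (r in seq_len(h)) {
        reuse <- spec$accession_share > 0 && length(acc_pool) > 0L &&
          runif(1) < spec$accession_share
        if (reuse) {
          cand <- sample(acc_pool, 1L)
          if (cand %in% accs[seq_len(r - 1L)]) reuse <- FALSE else accs[r] <- cand
        }
        if (!reuse) {
          acc_counter <- acc_counter + 1L
          accs[r] <- sprintf("XP_%06d.1", acc_counter)
        }
      }
      acc_pool <- unique(c(acc_pool, accs))
      if (h > 0L) {
        base <- if (h == 1L) spec$identity_decay[1L] else
          seq(spec$identity_decay[1L], spec$identity_decay[2L], length.out = h)
        ident <- sort(pmin(100, pmax(41, base + runif(h, -1.5, 1.5))),
                      decreasing = TRUE)
        expo <- sort(seq(80, 10, length.out = h) + runif(h, -1, 1),
                     decreasing = TRUE)
        expo <- pmax(expo, 6.2)
        bits <- sort(round(seq(500, 60, length.out = h) + runif(h, -5, 5), 1),
                     decreasing = TRUE)
        alen <- 150L + as.integer(round(runif(h, 0, 100)))
        hit_rows[[i]] <- data.frame(
          query_id = queries[i], subject_accession = accs,
          percent_identity = round(ident, 1), length = alen,
          mismatch = as.integer(round(alen * (1 - ident / 100))),
          gapopen = 0L, qstart = 1L, qend = alen * 3L,
          sstart = 1L, send = alen,
          evalue = 10^-round(expo, 1), bitscore = bits,
          stringsAsFactors = FALSE)
      }
      acc_by_query[[i]] <- accs
    }
    df <- if (n > 0L && h > 0L) do.call(rbind, hit_rows) else
      as.data.frame(setNames(
        list(character(), character(), numeric(), integer(), integer(),
             integer(), integer(), integer(), integer(), integer(),
             numeric(), numeric()), outfmt6_columns))
    df$rank <- if (nrow(df) > 0L)
      as.integer(ave(seq_len(nrow(df)), df$query_id, FUN = seq_along)) else integer()
    hits <- new_hit_table(df, queries, provenance = "synthetic")

    # --- accession -> PMID links ------------------------------------------
    all_accs <- unique(unlist(acc_by_query, use.names = FALSE))
    pmid_pool <- sample.int(max(spec$n_articles, 1L))
    pool_pos <- 0L
    take_pmids <- function(k) {
      if (k == 0L) return(integer())
      if (pool_pos + k > length(pmid_pool)) {
        stop("n_articles too small for the requested link density")
      }
      out <- pmid_pool[pool_pos + seq_len(k)]
      pool_pos <<- pool_pos + k
      out
    }
    links <- setNames(vector("list", length(all_accs)), all_accs)
    for (a in all_accs) links[[a]] <- take_pmids(rpois(1L, spec$link_density))
    # Guarantee every query at least one linked article.
    for (i in seq_len(n)) {
      accs <- unique(acc_by_query[[i]])
      if (length(accs) > 0L && sum(lengths(links[accs])) == 0L) {
        a <- accs[sample.int(length(accs), 1L)]
        links[[a]] <- take_pmids(1L)
      }
    }

    # --- articles: planted + background terms -----------------------------
    used_pmids <- sort(unique(unlist(links, use.names = FALSE)))
    target_accs <- if (is.null(spec$planted)) character() else
      unique(unlist(acc_by_query[match(spec$planted$targets, queries)],
                    use.names = FALSE))
    target_pmids <- sort(unique(unlist(links[target_accs], use.names = FALSE)))
    journals <- c("Fish Shellfish Immunol", "Dev Comp Immunol",
                  "J Fish Biol", "Aquaculture", "BMC Genomics",
                  "J Virol", "Mol Immunol", "Gene")
    voc <- spec$vocabulary
    records <- vector("list", length(used_pmids))
    for (j in seq_along(used_pmids)) {
      p <- used_pmids[j]
      major <- character()
      minor <- character()
      if (!is.null(spec$planted)) {
        pr <- if (p %in% target_pmids) spec$planted$p_hi else spec$planted$p_lo
        if (runif(1) < pr) {
          if (spec$planted$facet == "major") major <- spec$planted$term
          else minor <- spec$planted$term
        }
      }
      for (t in seq_len(nrow(voc))) {
        if (runif(1) < voc$p_article[t]) {
          if (runif(1) < voc$p_major[t]) major <- c(major, voc$term[t])
          else minor <- c(minor, voc$term[t])
        }
      }
      records[[j]] <- article_record(
        p, journal = journals[1L + (p %% length(journals))],
        year = 1995L + (p %% 25L), major = major, minor = minor)
    }
    store <- article_store(records, provenance = "synthetic")

    # --- taxonomic maps ---------------------------------------------------
    fish <- c("8022" = "Oncorhynchus mykiss", "7955" = "Danio rerio",
              "8030" = "Salmo salar", "8049" = "Gadus morhua",
              "8175" = "Epinephelus coioides", "8187" = "Oreochromis niloticus")
    taxids <- as.integer(names(fish))
    acc2tax <- setNames(taxids[1L + (seq_along(all_accs) %% length(taxids))],
                        all_accs)

    # --- write the bundle -------------------------------------------------
    write_hit_table(hits, paths[["hits"]])
    link_rows <- unlist(lapply(all_accs, function(a) {
      p <- links[[a]]
      if (length(p) == 0L) paste0(a, "\t-") else paste0(a, "\t", sort(p))
    }), use.names = FALSE)
    writeLines(link_rows %||% character(), paths[["links"]])
    dump_article_tsv(store, paths[["articles"]])
    tree_rows <- character()
    for (t in seq_len(nrow(voc))) {
      tns <- strsplit(voc$tree_numbers[t], ";", fixed = TRUE)[[1L]]
      tns <- tns[nzchar(tns)]
      if (length(tns)) tree_rows <- c(tree_rows, paste0(voc$term[t], "\t", tns))
    }
    if (!is.null(spec$planted) && nzchar(spec$planted$tree_numbers)) {
      tns <- strsplit(spec$planted$tree_numbers, ";", fixed = TRUE)[[1L]]
      tree_rows <- c(tree_rows, paste0(spec$planted$term, "\t", tns))
    }
    writeLines(tree_rows, paths[["mesh_tree"]])
    writeLines(if (length(all_accs)) paste0(all_accs, "\t", acc2tax[all_accs])
               else character(), paths[["acc2tax"]])
    writeLines(paste0(names(fish), "\t", unname(fish)), paths[["tax_names"]])
    writeLines(unlist(lapply(queries, function(q) c(paste0(">", q), "ACGTACGTACGT")),
                      use.names = FALSE) %||% character(), paths[["queries"]])
  })
  structure(list(paths = paths, spec = spec,
                 ground_truth = if (is.null(spec$planted)) NULL else
                   list(planted_term = spec$planted$term,
                        targets = spec$planted$targets,
                        facet = spec$planted$facet)),
            class = "corpus_bundle")
}

#' Independent brute-force term-score oracle
#'
#' Recomputes the per-term total score and annotated-query count for a
#' generated corpus by the most naive possible method: the bundle's files
#' are re-read with base table readers (no shared code with the pipeline's
#' parsers) and scored with explicit nested loops over queries, articles
#' and terms. Used as the reference implementation in equivalence tests;
#' deliberately slow and simple.
#'
#' @param bundle A `corpus_bundle` from [generate_corpus()].
#' @param facet `"major"` or `"minor"`.
#' @param identity_floor,evalue_cutoff,max_hits Filter thresholds, matching
#'   the pipeline defaults.
#' @return Data frame `term`, `total_score`, `annotated_queries`, sorted by
#'   term name.
#' @export
oracle_scores <- function(bundle, facet = c("major", "minor"),
                          identity_floor = 40, evalue_cutoff = 1e-6,
                          max_hits = 500L) {
  facet <- match.arg(facet)
  stopifnot(inherits(bundle, "corpus_bundle"))
  hit_lines <- readLines(bundle$paths[["hits"]])
  hit_lines <- hit_lines[!startsWith(hit_lines, "#")]
  link_lines <- readLines(bundle$paths[["links"]])
  art <- read.delim(bundle$paths[["articles"]], colClasses = "character",
                    quote = "", na.strings = NULL)

  # accession -> pmids, by explicit loop
  acc_pmids <- list()
  for (ln in link_lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (f[2L] != "-") {
      acc_pmids[[f[1L]]] <- c(acc_pmids[[f[1L]]], as.integer(f[2L]))
    } else if (is.null(acc_pmids[[f[1L]]])) {
      acc_pmids[[f[1L]]] <- integer()
    }
  }
  # pmid -> facet terms, by explicit loop
  art_terms <- list()
  for (i in seq_len(nrow(art))) {
    v <- strsplit(art[[facet]][i], ";", fixed = TRUE)[[1L]]
    art_terms[[art$pmid[i]]] <- v[nzchar(v)]
  }
  # query -> surviving accessions, replaying the filter naively
  q_accs <- list()
  q_order <- character()
  for (ln in hit_lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    q <- f[1L]; a <- f[2L]
    if (!(q %in% q_order)) q_order <- c(q_order, q)
    if (as.numeric(f[3L]) < identity_floor) next
    if (as.numeric(f[11L]) > evalue_cutoff) next
    if (a %in% q_accs[[q]]) next
    if (length(q_accs[[q]]) >= max_hits) next
    q_accs[[q]] <- c(q_accs[[q]], a)
  }
  totals <- list()
  ann <- list()
  for (q in q_order) {
    pmids <- integer()
    for (a in q_accs[[q]]) pmids <- c(pmids, acc_pmids[[a]])
    pmids <- unique(pmids)
    pmids <- pmids[as.character(pmids) %in% art$pmid]
    n_art <- length(pmids)
    if (n_art == 0L) next
    counts <- list()
    for (p in pmids) {
      for (t in art_terms[[as.character(p)]]) {
        counts[[t]] <- (counts[[t]] %||% 0L) + 1L
      }
    }
    for (t in names(counts)) {
      totals[[t]] <- (totals[[t]] %||% 0) + counts[[t]] / n_art
      ann[[t]] <- (ann[[t]] %||% 0L) + 1L
    }
  }
  terms <- sort(names(totals))
  data.frame(term = terms,
             total_score = vapply(terms, function(t) totals[[t]], numeric(1L)),
             annotated_queries = vapply(terms, function(t) ann[[t]], integer(1L)),
             row.names = NULL, stringsAsFactors = FALSE)
}
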