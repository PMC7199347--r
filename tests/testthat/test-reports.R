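test_that("depth scan reproduces hand-computed annotation percentages", {
  # query A annotated via its rank-1 hit, query B only via a rank-10 hit
  rows <- c(hit_row("A", "a1", 95, "1e-30"),
            unname(mapply(hit_row, "B", sprintf("b%d.1", 1:10),
                          seq(90, 70, length.out = 10),
                          rep("1e-20", 10))))
  tab <- apply_hit_filters(hit_table_from_rows(rows))
  links <- c(list(a1 = 11L, b10.1 = c(21L, 22L)),
             setNames(rep(list(integer()), 9), sprintf("b%d.1", 1:9)))
  store <- article_store(list(article_record(11, "J1", 2000, major = "X"),
                              article_record(21, "J2", 2001, major = "Y"),
                              article_record(22, "J1", 2002, minor = "X")))
  dp <- depth_scan(tab, links, store, ks = c(1, 5, 10))
  expect_equal(dp$pct_annotated, c(50, 50, 100))
  expect_equal(dp$total_articles, c(1L, 1L, 3L))
  expect_equal(dp$articles_per_annotated_query, c(1, 1, 1.5))
  expect_equal(dp$total_mesh_terms, c(1L, 1L, 2L))   # X, then X and Y
  expect_equal(dp$term_tokens, c(1L, 1L, 3L))
  # k beyond the deepest list equals the full-table row
  full <- depth_scan(tab, links, store, ks = 10)
  deep <- depth_scan(tab, links, store, ks = 99)
  expect_equal(full[-1], deep[-1])
  expect_error(depth_scan(tab, links, store, ks = numeric()), "at least one")
  expect_error(depth_scan(tab, links, store, ks = c(5, 1)), "ascending")
})

test_that("depth metrics are monotone on generated corpora", {
  for (seed in c(51, 52)) {
    b <- generate_corpus(small_corpus_spec(seed), tempfile())
    tab <- apply_hit_filters(parse_hit_table(b$paths[["hits"]],
                                             query_universe = b$spec$queries))
    dp <- depth_scan(tab, load_link_table(b$paths[["links"]]),
                     load_article_tsv(b$paths[["articles"]]), ks = 1:4)
    expect_true(all(diff(dp$pct_annotated) >= 0))
    expect_true(all(diff(dp$total_articles) >= 0))
    # generator identities decay with rank, so mean identity never rises
    expect_true(all(diff(dp$mean_identity_pct) <= 0))
  }
})

test_that("taxonomic distribution counts one best hit per query", {
  rows <- c(hit_row("q1", "a1", 95, "1e-30"), hit_row("q1", "a2", 90, "1e-20"),
            hit_row("q2", "a3", 94, "1e-30"),
            hit_row("q3", "a4", 93, "1e-30"),
            hit_row("q4", "a5", 92, "1e-30"),
            hit_row("q5", "a6", 91, "1e-30"))
  tab <- apply_hit_filters(hit_table_from_rows(rows, sprintf("q%d", 1:6)))
  acc2tax <- c(a1 = 8001L, a3 = 8001L, a4 = 8001L, a5 = 8002L)  # a6 unmapped
  nm <- c("8001" = "fishA", "8002" = "fishB")
  dist <- taxonomic_distribution(tab, acc2tax, nm)
  expect_equal(dist$label, c("fishA", "fishB", "unknown"))
  expect_equal(dist$count, c(3L, 1L, 1L))
  # conservation: counts sum to the number of queries with >= 1 hit (q6 has none)
  expect_equal(sum(dist$count), 5L)
  # missing names map falls back to the taxid number
  dist2 <- taxonomic_distribution(tab, acc2tax, c("8001" = "fishA"))
  expect_true("8002" %in% dist2$label)
})

test_that("journal distribution pools distinct articles across queries", {
  store <- article_store(list(article_record(1, "J1", 2000),
                              article_record(2, "J1", 2001),
                              article_record(3, "J2", 2002)))
  qa <- structure(list(q1 = c(1L, 2L), q2 = c(2L, 3L), q3 = integer()),
                  class = "query_articles")
  dist <- journal_distribution(qa, store)
  expect_equal(dist$label, c("J1", "J2"))
  expect_equal(dist$count, c(2L, 1L))
  expect_equal(sum(dist$count), 3L)  # distinct resolvable PMIDs
  empty <- journal_distribution(structure(list(), class = "query_articles"),
                                store)
  expect_equal(nrow(empty), 0L)
  # unresolvable PMIDs are skipped
  qa2 <- structure(list(q1 = c(1L, 99L)), class = "query_articles")
  expect_equal(sum(journal_distribution(qa2, store)$count), 1L)
})

test_that("job IDs are MD5 digests with the RFC 1321 test vectors", {
  expect_equal(job_id(raw()), "d41d8cd98f00b204e9800998ecf8427e")
  expect_equal(job_id(charToRaw("abc")), "900150983cd24fb0d6963f7d28e17f72")
  f <- tempfile()
  writeLines("some uploaded fasta", f)
  expect_equal(job_id(f), job_id(f))
  expect_equal(job_id(f), unname(tools::md5sum(f)))
  expect_error(job_id(42), "raw vector or the path")
})

test_that("the report bundle writes seven deterministic files and reloads losslessly", {
  b <- generate_corpus(small_corpus_spec(61), tempfile())
  hits <- parse_hit_table(b$paths[["hits"]], query_universe = b$spec$queries)
  res <- annotate_queries(hits,
                          load_link_table(b$paths[["links"]]),
                          load_article_tsv(b$paths[["articles"]]),
                          load_mesh_tree(b$paths[["mesh_tree"]]),
                          acc2tax = load_acc2tax(b$paths[["acc2tax"]]),
                          tax_names = load_tax_names(b$paths[["tax_names"]]),
                          depth_grid = c(1, 2, 4))
  out <- tempfile()
  paths <- render_report(res, out)
  expect_length(paths, 7L)
  expect_true(all(file.exists(paths)))
  expect_setequal(basename(unname(paths)),
                  c("top_major_terms.tsv", "top_minor_terms.tsv",
                    "top_immune_terms.tsv", "taxonomic_distribution.tsv",
                    "journal_distribution.tsv", "depth_profile.tsv",
                    "annotation.json"))
  # scores are rendered with two decimals in the TSVs
  top <- readLines(paths[["top_major_terms.tsv"]])[-1]
  expect_true(all(grepl("\t[0-9]+\\.[0-9]{2}\t", top)))
  # JSON evidence bundle reloads to the in-memory results at full precision
  back <- read_report_json(paths[["annotation.json"]])
  expect_identical(back$query_articles, res$query_articles)
  for (facet in c("major_terms", "minor_terms", "immune_terms")) {
    expect_identical(back[[facet]]$term, res[[facet]]$term)
    expect_identical(back[[facet]]$total_score, res[[facet]]$total_score)
    expect_identical(back[[facet]]$annotated_queries,
                     res[[facet]]$annotated_queries)
    expect_identical(back[[facet]]$supporting_queries,
                     res[[facet]]$supporting_queries)
  }
  for (q in names(res$scores_major)) {
    expect_identical(back$scores_major[[q]]$scores, res$scores_major[[q]]$scores)
    expect_identical(back$scores_major[[q]]$n_articles,
                     res$scores_major[[q]]$n_articles)
  }
  expect_equal(back$taxonomic, res$taxonomic)
  expect_equal(back$journals, res$journals)
  expect_equal(back$depth, res$depth)
  # unwritable destination is an I/O error
  blocker <- tempfile()
  writeLines("x", blocker)
  expect_error(render_report(res, file.path(blocker, "sub")), "cannot create")
})
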