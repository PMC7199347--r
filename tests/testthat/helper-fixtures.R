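# Shared in-code fixtures: everything is generated at test time.

write_lines_tmp <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

# Hit table parsed from explicit outfmt-6 rows.
hit_table_from_rows <- function(rows, query_universe = NULL) {
  parse_hit_table(write_lines_tmp(rows), query_universe = query_universe)
}

hit_row <- function(q, acc, pident, evalue, bitscore = 100) {
  paste(q, acc, pident, 150, 10, 0, 1, 450, 1, 150, evalue, bitscore,
        sep = "\t")
}

# Random outfmt-6 rows exercising both filter boundaries.
random_hit_rows <- function(seed, n_queries = 5, max_hits = 30) {
  set.seed(seed)
  rows <- character()
  for (i in seq_len(n_queries)) {
    nh <- sample.int(max_hits, 1)
    accs <- sprintf("ACC_%d_%d.1", i, sample.int(nh + 5, nh, replace = TRUE))
    pid <- round(runif(nh, 20, 100), 1)
    pid[sample.int(nh, 1)] <- 40.0  # boundary value present in every table
    ev <- 10^-round(runif(nh, 0, 12), 2)
    ev[sample.int(nh, 1)] <- 1e-6   # boundary value present in every table
    bits <- round(seq(300, 50, length.out = nh), 1)
    rows <- c(rows, mapply(hit_row, sprintf("q%02d", i), accs, pid, ev, bits))
  }
  unname(rows)
}

# Small deterministic article store built in code.
tiny_store <- function() {
  article_store(list(
    article_record(101, "J Virol", 2015,
                   major = c("Apoptosis", "Signal Transduction"),
                   minor = "Fish Diseases"),
    article_record(102, "J Virol", 2016, major = "Apoptosis",
                   minor = c("Brain", "Fish Diseases")),
    article_record(103, "Gene", 2017, major = c("Apoptosis", "Spleen")),
    article_record(104, "Gene", 2018, minor = "Brain"),
    article_record(105, "Aquaculture", 2019)))  # article with no headings
}

tiny_tree <- function() {
  f <- write_lines_tmp(c("Spleen\tA15.382.520",
                         "Spleen\tA10.549",
                         "Immune Evasion\tG12.450.050",
                         "Signal Transduction\tG07.690",
                         "Brain\tA08.186.211"))
  load_mesh_tree(f)
}

# Full package pipeline from a generated corpus bundle to a term summary.
pipeline_summaries <- function(bundle, facet) {
  hits <- parse_hit_table(bundle$paths[["hits"]],
                          query_universe = bundle$spec$queries)
  filt <- apply_hit_filters(hits, annotation_config())
  links <- load_link_table(bundle$paths[["links"]])
  store <- load_article_tsv(bundle$paths[["articles"]])
  qa <- collect_query_pmids(filt, links)
  per_q <- lapply(names(qa), function(q) {
    score_query(qa[[q]], store, facet, query_id = q)
  })
  aggregate_terms(per_q)
}

# Compare pipeline summary vs. the brute-force oracle as term -> value maps.
expect_matches_oracle <- function(summary, oracle, tol = 1e-12) {
  expect_setequal(summary$term, oracle$term)
  m <- merge(summary[c("term", "total_score", "annotated_queries")],
             oracle, by = "term")
  expect_true(all(abs(m$total_score.x - m$total_score.y) <= tol))
  expect_identical(m$annotated_queries.x, m$annotated_queries.y)
}

# A small corpus spec used where the defaults would be slower than needed.
small_corpus_spec <- function(seed, ...) {
  corpus_spec(n_queries = 10L, hits_per_query = 4L, n_articles = 300L,
              link_density = 1.0, accession_share = 0.2, seed = seed, ...)
}

# MEDLINE/PubMed citation XML fixture covering the major-topic edge cases.
medline_xml_fixture <- function() {
  paste0(
    '<?xml version="1.0"?><PubmedArticleSet>',
    '<PubmedArticle><MedlineCitation><PMID>201</PMID><Article>',
    '<Journal><Title>J Virol</Title><JournalIssue><PubDate><Year>2015</Year></PubDate></JournalIssue></Journal>',
    '</Article><MeshHeadingList>',
    '<MeshHeading><DescriptorName MajorTopicYN="Y">Signal Transduction</DescriptorName></MeshHeading>',
    '<MeshHeading><DescriptorName MajorTopicYN="N">Brain</DescriptorName></MeshHeading>',
    '<MeshHeading><DescriptorName MajorTopicYN="N">Liver</DescriptorName>',
    '<QualifierName MajorTopicYN="Y">immunology</QualifierName></MeshHeading>',
    '</MeshHeadingList></MedlineCitation></PubmedArticle>',
    '<PubmedArticle><MedlineCitation><PMID>202</PMID><Article>',
    '<Journal><Title>Gene</Title><JournalIssue><PubDate>',
    '<MedlineDate>1998 Jul-Aug</MedlineDate></PubDate></JournalIssue></Journal>',
    '</Article><MeshHeadingList>',
    '<MeshHeading><DescriptorName MajorTopicYN="N">Apoptosis</DescriptorName>',
    '<QualifierName MajorTopicYN="N">genetics</QualifierName></MeshHeading>',
    '</MeshHeadingList></MedlineCitation></PubmedArticle>',
    '<PubmedArticle><MedlineCitation><PMID>203</PMID><Article>',
    '<Journal><Title>Aquaculture</Title><JournalIssue><PubDate></PubDate></JournalIssue></Journal>',
    '</Article></MedlineCitation></PubmedArticle>',
    '</PubmedArticleSet>')
}

# Random parent-pointer forest over n nodes, rooted at a self-parented node.
# Returns nodes.dmp-dialect lines plus the (taxid, parent) integer vectors.
random_taxonomy <- function(seed, n = 1000) {
  set.seed(seed)
  labels <- sample.int(10 * n, n)  # shuffled taxid labels
  parent_idx <- c(1L, vapply(2:n, function(i) sample.int(i - 1L, 1L), integer(1)))
  taxid <- labels
  parent <- labels[parent_idx]
  parent[1] <- taxid[1]  # root is its own parent
  lines <- paste0(taxid, "\t|\t", parent, "\t|\tno rank\t|")
  list(lines = lines, taxid = taxid, parent = parent)
}

# Brute-force subtree oracle: walk every node's ancestor chain.
subtree_oracle <- function(taxid, parent, root) {
  parent_of <- stats::setNames(parent, taxid)
  keep <- logical(length(taxid))
  for (i in seq_along(taxid)) {
    node <- taxid[i]
    repeat {
      if (node == root) {
        keep[i] <- TRUE
        break
      }
      nxt <- parent_of[[as.character(node)]]
      if (nxt == node) break
      node <- nxt
    }
  }
  sort(taxid[keep])
}
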