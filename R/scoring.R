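#' Score one query's MeSH terms
#'
#' The core per-query statistic. Popular genes accumulate more articles and
#' hence more term occurrences, so raw term counts are normalized by the
#' query's article count: for each term `t` in the chosen facet,
#' `score(t) = (# of the query's resolved articles whose facet set contains
#' t) / n_articles`. A MeSH descriptor appears at most once per article, so
#' every score lies in (0, 1], reaching 1 exactly when the term occurs in
#' all of the query's articles. PMIDs not resolvable in the store are
#' excluded from both numerator and denominator; resolvable articles with no
#' headings still count in the denominator. Scores are descriptive ranks,
#' not test statistics: no p-values are attached.
#'
#' @param pmids Deduplicated integer PMIDs of one query (from
#'   [collect_query_pmids()]).
#' @param store An `article_store`.
#' @param facet `"major"` or `"minor"`.
#' @param query_id Optional query label carried into the evidence trail.
#' @return A `query_term_scores` list: `query_id`, `facet`, `n_articles`
#'   (resolved article count) and `scores` (named numeric, empty when
#'   `n_articles` is 0, i.e. the query is unannotated in this facet source).
#' @export
#' @examples
#' store <- article_store(list(
#'   article_record(1, "J", 2019, major = "Apoptosis"),
#'   article_record(2, "J", 2019, major = "Apoptosis"),
#'   article_record(3, "J", 2019, major = c("Apoptosis", "Spleen")),
#'   article_record(4, "J", 2019, minor = "Brain")))
#' score_query(1:4, store, "major")$scores  # Apoptosis 0.75, Spleen 0.25
score_query <- function(pmids, store, facet = c("major", "minor"),
                        query_id = NA_character_) {
  facet <- match.arg(facet)
  stopifnot(inherits(store, "article_store"))
  recs <- store_lookup(store, unique(as.integer(pmids)))
  n <- length(recs)
  if (n == 0L) {
    return(structure(list(query_id = query_id, facet = facet,
                          n_articles = 0L, scores = setNames(numeric(), character())),
                     class = "query_term_scores"))
  }
  terms <- unlist(lapply(recs, `[[`, facet), use.names = FALSE)
  if (is.null(terms) || length(terms) == 0L) {
    return(structure(list(query_id = query_id, facet = facet,
                          n_articles = n,
                          scores = setNames(numeric(), character())),
                     class = "query_term_scores"))
  }
  counts <- table(terms)
  scores <- setNames(as.numeric(counts) / n, names(counts))
  structure(list(query_id = query_id, facet = facet, n_articles = n,
                 scores = scores[order(names(scores))]),
            class = "query_term_scores")
}

#' Aggregate per-query term scores into a ranked summary
#'
#' One row per distinct term: `total_score` is the sum of the term's
#' per-query correlation scores, `annotated_queries` the number of queries
#' with a positive score for the term, and `supporting_queries` the evidence
#' (the query IDs themselves). Rows are sorted by `total_score` descending;
#' ties break by `annotated_queries` descending, then term name ascending,
#' so output is fully deterministic. Because every per-query score is at
#' most 1, every row satisfies `0 < total_score <= annotated_queries`.
#'
#' @param per_query List of `query_term_scores`, all of one facet.
#' @return A `term_summary` data frame with columns `term`, `total_score`,
#'   `annotated_queries` and list-column `supporting_queries`.
#' @export
aggregate_terms <- function(per_query) {
  stopifnot(is.list(per_query))
  per_query <- Filter(function(s) inherits(s, "query_term_scores"), per_query)
  empty <- data.frame(term = character(), total_score = numeric(),
                      annotated_queries = integer(), stringsAsFactors = FALSE)
  empty$supporting_queries <- list()
  if (length(per_query) == 0L) {
    return(structure(empty, facet = NA_character_,
                     class = c("term_summary", "data.frame")))
  }
  facets <- unique(vapply(per_query, `[[`, character(1L), "facet"))
  if (length(facets) != 1L) {
    stop("mixed facets in aggregate_terms() input: ",
         paste(facets, collapse = ", "))
  }
  qids <- vapply(seq_along(per_query), function(i) {
    q <- per_query[[i]]$query_id
    if (is.null(q) || is.na(q)) sprintf("query_%d", i) else q
  }, character(1L))
  term <- unlist(lapply(per_query, function(s) names(s$scores)),
                 use.names = FALSE)
  if (is.null(term) || length(term) == 0L) {
    return(structure(empty, facet = facets,
                     class = c("term_summary", "data.frame")))
  }
  score <- unlist(lapply(per_query, function(s) unname(s$scores)),
                  use.names = FALSE)
  qid <- rep(qids, vapply(per_query, function(s) length(s$scores), integer(1L)))
  f <- factor(term)
  total <- tapply(score, f, sum)
  supporting <- tapply(qid, f, function(v) sort(unique(v)), simplify = FALSE)
  terms <- levels(f)
  ann <- vapply(supporting, length, integer(1L))
  ord <- order(-as.numeric(total), -ann, terms)
  out <- data.frame(term = terms[ord],
                    total_score = as.numeric(total)[ord],
                    annotated_queries = as.integer(ann)[ord],
                    stringsAsFactors = FALSE)
  sup <- supporting[ord]
  attributes(sup) <- NULL
  out$supporting_queries <- sup
  structure(out, facet = facets, class = c("term_summary", "data.frame"))
}

#' Restrict a term summary to MeSH categories
#'
#' Keeps exactly the terms with at least one tree number under one of the
#' category prefixes (dot-boundary matching; see [term_in_categories()]).
#' This is a restriction of the ranked list, not a re-normalization: scores
#' and relative order are unchanged, so the result is a subsequence of the
#' input. With the default immune categories (A15, G12) this produces the
#' immune-system-specific view of the annotation.
#'
#' @param summaries A sorted `term_summary` from [aggregate_terms()].
#' @param tree A MeSH tree map.
#' @param categories Character vector of tree prefixes.
#' @return The filtered `term_summary`.
#' @export
filter_categories <- function(summaries, tree, categories = c("A15", "G12")) {
  stopifnot(inherits(summaries, "term_summary"))
  keep <- vapply(summaries$term, term_in_categories, logical(1L),
                 tree = tree, categories = categories)
  out <- summaries[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, facet = attr(summaries, "facet"),
            class = c("term_summary", "data.frame"))
}

#' Top n rows of a ranked term summary
#'
#' @param summaries A sorted `term_summary`.
#' @param n Number of rows to keep (>= 0).
#' @return The first `min(n, nrow)` rows.
#' @export
top_terms <- function(summaries, n) {
  stopifnot(inherits(summaries, "term_summary"),
            is.numeric(n), length(n) == 1L, n >= 0)
  out <- head(summaries, n)
  structure(out, facet = attr(summaries, "facet"),
            class = c("term_summary", "data.frame"))
}

#' Write a ranked term summary as TSV
#'
#' Columns `term`, `score` (rendered with 2 decimals; full precision lives
#' in the JSON evidence bundle) and `annotated_queries`.
#'
#' @param summaries A `term_summary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_term_summary <- function(summaries, path) {
  stopifnot(inherits(summaries, "term_summary"))
  rows <- sprintf("%s\t%.2f\t%d", summaries$term, summaries$total_score,
                  summaries$annotated_queries)
  writeLines(c("term\tscore\tannotated_queries", rows), path)
  invisible(path)
}
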