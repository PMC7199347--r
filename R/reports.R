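#' Hit-depth sensitivity scan
#'
#' Re-runs article collection at increasing hit-list depths k (shallower
#' `max_target_seqs` settings carved out of one deep, filtered table) and
#' reports, per depth: percent of the query universe annotated (>= 1 linked
#' article), mean percent identity over the retained hits, mean distinct
#' articles per annotated query, distinct MeSH descriptors (pooled over both
#' facets) and descriptor occurrence tokens, and distinct pooled articles.
#' Because deeper truncations only add hits, per-query article sets nest
#' across depths and percent annotated and article counts are non-decreasing
#' in k. This quantifies the coverage-versus-credibility trade-off of deep
#' hit lists: coverage rises with k while mean hit identity falls.
#'
#' @param table A filtered `hit_table`.
#' @param links A link map.
#' @param store An `article_store`.
#' @param ks Ascending positive depths (default
#'   `c(1, 5, 10, 25, 50, 100, 200, 300, 400, 500)`).
#' @return A `depth_profile` data frame with one row per depth: columns `k`,
#'   `pct_annotated`, `mean_identity_pct`, `articles_per_annotated_query`,
#'   `total_mesh_terms`, `term_tokens`, `total_articles`.
#' @export
depth_scan <- function(table, links, store,
                       ks = c(1, 5, 10, 25, 50, 100, 200, 300, 400, 500)) {
  stopifnot(inherits(table, "hit_table"), inherits(store, "article_store"))
  if (length(ks) == 0L) stop("`ks` must contain at least one depth")
  if (any(ks < 1) || is.unsorted(ks, strictly = TRUE)) {
    stop("`ks` must be strictly ascending positive depths")
  }
  n_universe <- length(query_universe(table))
  rows <- lapply(ks, function(k) {
    tk <- truncate_depth(table, k)
    dfk <- as.data.frame(tk)
    qa <- collect_query_pmids(tk, links)
    annotated <- lengths(qa) > 0L
    pooled <- sort(unique(unlist(qa, use.names = FALSE)))
    recs <- store_lookup(store, pooled)
    all_terms <- unlist(lapply(recs, function(r) c(r$major, r$minor)),
                        use.names = FALSE)
    data.frame(
      k = as.integer(k),
      pct_annotated = if (n_universe > 0L) 100 * sum(annotated) / n_universe else NA_real_,
      mean_identity_pct = if (nrow(dfk) > 0L) mean(dfk$percent_identity) else NA_real_,
      articles_per_annotated_query =
        if (any(annotated)) mean(lengths(qa)[annotated]) else NA_real_,
      total_mesh_terms = length(unique(all_terms)),
      term_tokens = length(all_terms),
      total_articles = length(pooled))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("depth_profile", "data.frame")
  out
}

distribution_table <- function(labels) {
  if (length(labels) == 0L) {
    return(data.frame(label = character(), count = integer(),
                      stringsAsFactors = FALSE))
  }
  tab <- table(labels)
  df <- data.frame(label = names(tab), count = as.integer(tab),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$count, df$label), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Taxonomic distribution of best hits
#'
#' Counts, over queries with at least one retained hit, the taxon of the
#' rank-1 (highest-scoring) hit — one vote per query, so deep hit lists
#' cannot drown the table in low-rank species. Accessions without a taxid
#' mapping are binned as `"unknown"`. Counts therefore sum to the number of
#' queries with >= 1 hit.
#'
#' @param table A filtered `hit_table`.
#' @param acc2tax Named integer vector, accession -> taxid (see
#'   [load_acc2tax()]).
#' @param tax_names Optional named character vector, taxid -> scientific
#'   name; unmapped taxids are labelled by their number.
#' @return Data frame `label`, `count`, sorted by count descending then
#'   label ascending.
#' @export
taxonomic_distribution <- function(table, acc2tax, tax_names = NULL) {
  stopifnot(inherits(table, "hit_table"))
  df <- as.data.frame(table)
  best <- df[df$rank == 1L, , drop = FALSE]
  if (nrow(best) == 0L) return(distribution_table(character()))
  tid <- acc2tax[best$subject_accession]
  label <- ifelse(is.na(tid), "unknown",
                  ifelse(is.na(tax_names[as.character(tid)]),
                         as.character(tid),
                         tax_names[as.character(tid)]))
  distribution_table(label)
}

#' Load an accession-to-taxid table
#'
#' Headerless TSV `accession<TAB>taxid`.
#'
#' @param path Path to the TSV.
#' @return Named integer vector, accession -> taxid.
#' @export
load_acc2tax <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(setNames(integer(), character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) != 2L)) {
    stop(sprintf("malformed accession-taxid row at line %d",
                 which(lengths(fields) != 2L)[1L]))
  }
  tid <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1L), 2L)))
  if (anyNA(tid)) {
    stop(sprintf("non-integer taxid at line %d", which(is.na(tid))[1L]))
  }
  setNames(tid, vapply(fields, `[[`, character(1L), 1L))
}

#' Load a taxid-to-name table
#'
#' Headerless TSV `taxid<TAB>name`.
#'
#' @param path Path to the TSV.
#' @return Named character vector, taxid -> name.
#' @export
load_tax_names <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(setNames(character(), character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  setNames(vapply(fields, `[[`, character(1L), 2L),
           vapply(fields, `[[`, character(1L), 1L))
}

#' Journal distribution of the evidence corpus
#'
#' Counts journals over the set of distinct PMIDs pooled across all queries:
#' an article cited by many queries counts once, because the table describes
#' the reference sources backing the annotation, not citation traffic.
#' PMIDs not resolvable in the store are skipped, so counts sum to the
#' number of distinct resolvable pooled articles.
#'
#' @param qa A `query_articles` object.
#' @param store An `article_store`.
#' @return Data frame `label`, `count`, sorted by count descending then
#'   label ascending.
#' @export
journal_distribution <- function(qa, store) {
  stopifnot(inherits(store, "article_store"))
  pooled <- sort(unique(unlist(qa, use.names = FALSE)))
  recs <- store_lookup(store, pooled)
  distribution_table(vapply(recs, `[[`, character(1L), "journal"))
}

#' MD5 job identifier for an uploaded file
#'
#' Jobs are identified by the MD5 digest of the submitted file's bytes, so
#' re-uploading an identical file maps to the same job.
#'
#' @param x A raw vector of bytes, or a path to an existing file.
#' @return 32-character lowercase hex digest.
#' @export
#' @examples
#' job_id(charToRaw("abc"))  # "900150983cd24fb0d6963f7d28e17f72"
job_id <- function(x) {
  if (is.raw(x)) {
    f <- tempfile()
    on.exit(unlink(f), add = TRUE)
    writeBin(x, f)
  } else if (is.character(x) && length(x) == 1L && file.exists(x)) {
    f <- x
  } else {
    stop("`x` must be a raw vector or the path of an existing file")
  }
  unname(tools::md5sum(f))
}

#' Run the full annotation pipeline
#'
#' Filters the hit table, collects each query's deduplicated article set,
#' scores the major and minor MeSH facets independently, aggregates and
#' ranks terms, derives the immune-restricted view of the major facet, and
#' (when the inputs are supplied) computes the taxonomic and journal
#' distributions and the hit-depth sensitivity scan.
#'
#' @param hits A `hit_table` (unfiltered is fine; filtering is applied).
#' @param links A link map.
#' @param store An `article_store`.
#' @param mesh_tree A MeSH tree map.
#' @param cfg An [annotation_config()].
#' @param acc2tax,tax_names Optional taxonomic maps for the best-hit taxon
#'   distribution.
#' @param depth_grid Optional ascending depth grid for [depth_scan()];
#'   `NULL` skips the scan.
#' @return A `mesh_annotation` list: `filtered` (hit table),
#'   `query_articles`, `scores_major`/`scores_minor` (per-query score
#'   objects named by query), `major_terms`/`minor_terms`/`immune_terms`
#'   (ranked summaries), `taxonomic`, `journals`, `depth`, `cfg`.
#' @export
annotate_queries <- function(hits, links, store, mesh_tree,
                             cfg = annotation_config(),
                             acc2tax = NULL, tax_names = NULL,
                             depth_grid = NULL) {
  filtered <- apply_hit_filters(hits, cfg)
  qa <- collect_query_pmids(filtered, links)
  scores_major <- lapply(names(qa), function(q) {
    score_query(qa[[q]], store, "major", query_id = q)
  })
  scores_minor <- lapply(names(qa), function(q) {
    score_query(qa[[q]], store, "minor", query_id = q)
  })
  names(scores_major) <- names(qa)
  names(scores_minor) <- names(qa)
  major_terms <- aggregate_terms(scores_major)
  minor_terms <- aggregate_terms(scores_minor)
  immune_terms <- filter_categories(major_terms, mesh_tree,
                                    cfg$immune_categories)
  structure(list(
    filtered = filtered,
    query_articles = qa,
    scores_major = scores_major,
    scores_minor = scores_minor,
    major_terms = major_terms,
    minor_terms = minor_terms,
    immune_terms = immune_terms,
    taxonomic = if (!is.null(acc2tax)) {
      taxonomic_distribution(filtered, acc2tax, tax_names)
    },
    journals = journal_distribution(qa, store),
    depth = if (!is.null(depth_grid)) {
      depth_scan(filtered, links, store, ks = depth_grid)
    },
    cfg = cfg), class = "mesh_annotation")
}

report_files <- c("top_major_terms.tsv", "top_minor_terms.tsv",
                  "top_immune_terms.tsv", "taxonomic_distribution.tsv",
                  "journal_distribution.tsv", "depth_profile.tsv",
                  "annotation.json")

write_distribution_tsv <- function(df, path) {
  rows <- if (is.null(df) || nrow(df) == 0L) character() else
    sprintf("%s\t%d", df$label, df$count)
  writeLines(c("label\tcount", rows), path)
}

#' Write the annotation report bundle
#'
#' Writes seven files into `out_dir`: the top major (default 20), minor
#' (10) and immune-restricted (10) term tables (TSV, scores rendered with
#' two decimals), the taxonomic and journal distribution tables, the depth
#' profile, and a JSON evidence bundle retaining full numeric precision,
#' the per-query article sets and scores, and the supporting query IDs of
#' every term. The file set and contents are deterministic for fixed
#' inputs.
#'
#' @param result A `mesh_annotation` from [annotate_queries()].
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of the seven file paths.
#' @export
render_report <- function(result, out_dir) {
  stopifnot(inherits(result, "mesh_annotation"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("cannot create output directory '%s'", out_dir))
  }
  cfg <- result$cfg
  paths <- setNames(file.path(out_dir, report_files), report_files)
  write_term_summary(top_terms(result$major_terms, cfg$top_n_major),
                     paths[["top_major_terms.tsv"]])
  write_term_summary(top_terms(result$minor_terms, cfg$top_n_minor),
                     paths[["top_minor_terms.tsv"]])
  write_term_summary(top_terms(result$immune_terms, cfg$top_n_immune),
                     paths[["top_immune_terms.tsv"]])
  write_distribution_tsv(result$taxonomic,
                         paths[["taxonomic_distribution.tsv"]])
  write_distribution_tsv(result$journals,
                         paths[["journal_distribution.tsv"]])
  dp <- result$depth
  dp_rows <- if (is.null(dp) || nrow(dp) == 0L) character() else
    sprintf("%d\t%.1f\t%s\t%s\t%d\t%d",
            dp$k, dp$pct_annotated,
            ifelse(is.na(dp$mean_identity_pct), "NA",
                   sprintf("%.1f", dp$mean_identity_pct)),
            ifelse(is.na(dp$articles_per_annotated_query), "NA",
                   sprintf("%.2f", dp$articles_per_annotated_query)),
            dp$total_mesh_terms, dp$total_articles)
  writeLines(c(paste("k", "pct_annotated", "mean_identity_pct",
                     "articles_per_annotated_query", "total_mesh_terms",
                     "total_articles", sep = "\t"), dp_rows),
             paths[["depth_profile.tsv"]])
  jsonlite::write_json(annotation_to_list(result),
                       paths[["annotation.json"]],
                       digits = I(17), auto_unbox = TRUE, null = "null",
                       na = "null")
  paths
}

summary_to_list <- function(s) {
  lapply(seq_len(nrow(s)), function(i) {
    list(term = s$term[i], total_score = s$total_score[i],
         annotated_queries = s$annotated_queries[i],
         supporting_queries = as.list(s$supporting_queries[[i]]))
  })
}

scores_to_list <- function(scores) {
  lapply(scores, function(s) {
    list(query_id = s$query_id, n_articles = s$n_articles,
         scores = as.list(s$scores))
  })
}

distribution_to_list <- function(df) {
  if (is.null(df)) return(list())
  lapply(seq_len(nrow(df)), function(i) {
    list(label = df$label[i], count = df$count[i])
  })
}

annotation_to_list <- function(result) {
  dp <- result$depth
  list(
    config = unclass(result$cfg),
    query_articles = lapply(result$query_articles, as.list),
    per_query_scores = list(major = scores_to_list(result$scores_major),
                            minor = scores_to_list(result$scores_minor)),
    term_summaries = list(major = summary_to_list(result$major_terms),
                          minor = summary_to_list(result$minor_terms),
                          immune = summary_to_list(result$immune_terms)),
    distributions = list(taxonomic = distribution_to_list(result$taxonomic),
                         journals = distribution_to_list(result$journals)),
    depth = if (is.null(dp)) list() else
      lapply(seq_len(nrow(dp)), function(i) as.list(dp[i, , drop = FALSE])))
}

list_to_summary <- function(x, facet = NA_character_) {
  df <- data.frame(
    term = vapply(x, function(r) r$term, character(1L)),
    total_score = vapply(x, function(r) as.numeric(r$total_score), numeric(1L)),
    annotated_queries = vapply(x, function(r) as.integer(r$annotated_queries),
                               integer(1L)),
    stringsAsFactors = FALSE)
  df$supporting_queries <- lapply(x, function(r) {
    as.character(unlist(r$supporting_queries))
  })
  structure(df, facet = facet, class = c("term_summary", "data.frame"))
}

list_to_scores <- function(x, facet) {
  out <- lapply(x, function(s) {
    sc <- unlist(s$scores)
    sc <- setNames(as.numeric(sc), names(sc))
    structure(list(query_id = s$query_id, facet = facet,
                   n_articles = as.integer(s$n_articles),
                   scores = if (length(sc) == 0L) setNames(numeric(), character())
                            else sc[order(names(sc))]),
              class = "query_term_scores")
  })
  setNames(out, vapply(x, function(s) s$query_id, character(1L)))
}

list_to_distribution <- function(x) {
  data.frame(label = vapply(x, function(r) r$label, character(1L)),
             count = vapply(x, function(r) as.integer(r$count), integer(1L)),
             stringsAsFactors = FALSE)
}

#' Reload a JSON evidence bundle
#'
#' Reconstructs, from the `annotation.json` written by [render_report()],
#' the per-query article sets and scores, the three ranked term summaries,
#' the distribution tables and the depth profile, at full numeric
#' precision.
#'
#' @param path Path to `annotation.json`.
#' @return List with elements `config`, `query_articles`, `scores_major`,
#'   `scores_minor`, `major_terms`, `minor_terms`, `immune_terms`,
#'   `taxonomic`, `journals`, `depth`.
#' @export
read_report_json <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  qa <- lapply(j$query_articles, function(v) sort(as.integer(unlist(v))))
  qa <- structure(lapply(qa, function(v) if (length(v)) v else integer()),
                  class = "query_articles")
  dp <- if (length(j$depth) == 0L) NULL else {
    df <- do.call(rbind, lapply(j$depth, function(r) {
      data.frame(k = as.integer(r$k),
                 pct_annotated = as.numeric(r$pct_annotated),
                 mean_identity_pct = if (is.null(r$mean_identity_pct))
                   NA_real_ else as.numeric(r$mean_identity_pct),
                 articles_per_annotated_query =
                   if (is.null(r$articles_per_annotated_query)) NA_real_
                   else as.numeric(r$articles_per_annotated_query),
                 total_mesh_terms = as.integer(r$total_mesh_terms),
                 term_tokens = as.integer(r$term_tokens),
                 total_articles = as.integer(r$total_articles))
    }))
    rownames(df) <- NULL
    class(df) <- c("depth_profile", "data.frame")
    df
  }
  list(config = do.call(annotation_config, lapply(j$config, unlist)),
       query_articles = qa,
       scores_major = list_to_scores(j$per_query_scores$major, "major"),
       scores_minor = list_to_scores(j$per_query_scores$minor, "minor"),
       major_terms = list_to_summary(j$term_summaries$major, "major"),
       minor_terms = list_to_summary(j$term_summaries$minor, "minor"),
       immune_terms = list_to_summary(j$term_summaries$immune, "major"),
       taxonomic = list_to_distribution(j$distributions$taxonomic),
       journals = list_to_distribution(j$distributions$journals),
       depth = dp)
}
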