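#' Annotation pipeline configuration
#'
#' Bundles the tunable thresholds of the annotation pipeline. The defaults
#' are the pipeline's operating point for fish transcriptome annotation:
#' E-value cut-off 1e-6, identity floor 40%, and a deep hit list of up to
#' 500 protein subjects per query so that poorly documented best hits can
#' still be annotated through lower-ranked homologs.
#'
#' @param evalue_cutoff Maximum E-value retained (inclusive). Must be > 0.
#' @param identity_floor_pct Minimum percent identity retained (inclusive);
#'   hits strictly below this are considered too diverged to contribute
#'   trustworthy literature. In `[0, 100]`.
#' @param max_hits_per_query Hit-list depth cap per query (the
#'   `max_target_seqs` analogue). Must be >= 1.
#' @param immune_categories MeSH tree prefixes defining the immune-specific
#'   report (default A15, Hemic and Immune Systems; G12, Immune System
#'   Phenomena).
#' @param top_n_major,top_n_minor,top_n_immune Table lengths for the ranked
#'   term reports.
#' @return An object of class `annotation_config`.
#' @export
#' @examples
#' cfg <- annotation_config()
#' cfg$evalue_cutoff
annotation_config <- function(evalue_cutoff = 1e-6,
                              identity_floor_pct = 40,
                              max_hits_per_query = 500L,
                              immune_categories = c("A15", "G12"),
                              top_n_major = 20L,
                              top_n_minor = 10L,
                              top_n_immune = 10L) {
  stopifnot(is.numeric(evalue_cutoff), length(evalue_cutoff) == 1L,
            evalue_cutoff > 0)
  stopifnot(is.numeric(identity_floor_pct), length(identity_floor_pct) == 1L,
            identity_floor_pct >= 0, identity_floor_pct <= 100)
  max_hits_per_query <- as.integer(max_hits_per_query)
  stopifnot(length(max_hits_per_query) == 1L, !is.na(max_hits_per_query),
            max_hits_per_query >= 1L)
  stopifnot(is.character(immune_categories))
  structure(list(evalue_cutoff = evalue_cutoff,
                 identity_floor_pct = identity_floor_pct,
                 max_hits_per_query = max_hits_per_query,
                 immune_categories = immune_categories,
                 top_n_major = as.integer(top_n_major),
                 top_n_minor = as.integer(top_n_minor),
                 top_n_immune = as.integer(top_n_immune)),
            class = "annotation_config")
}

outfmt6_columns <- c("query_id", "subject_accession", "percent_identity",
                     "length", "mismatch", "gapopen", "qstart", "qend",
                     "sstart", "send", "evalue", "bitscore")

new_hit_table <- function(df, query_universe, provenance = NA_character_) {
  rownames(df) <- NULL
  structure(df,
            query_universe = as.character(query_universe),
            provenance = provenance,
            class = c("hit_table", "data.frame"))
}

#' @export
as.data.frame.hit_table <- function(x, ...) {
  attr(x, "query_universe") <- NULL
  attr(x, "provenance") <- NULL
  class(x) <- "data.frame"
  x
}

#' Query universe of a hit table
#'
#' All query IDs submitted for annotation, including queries that ended up
#' with zero retained hits. This is the denominator of "percent annotated".
#'
#' @param table A `hit_table`.
#' @return Character vector of query IDs.
#' @export
query_universe <- function(table) {
  stopifnot(inherits(table, "hit_table"))
  attr(table, "query_universe")
}

#' Parse a BLAST tabular hit file
#'
#' Reads 12-column tab-separated BLAST output (`-outfmt 6` column order:
#' qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore). Comment lines starting with `#` (the `-outfmt 7`
#' dialect) are skipped. Hits are grouped by query in file order and ranked
#' 1..n per query by encounter order; the input order is trusted (BLAST's
#' bitscore order) and never re-sorted.
#'
#' @param path Path to the tabular file (or a connection readable by
#'   [readLines()]).
#' @param query_universe Optional character vector of all submitted query
#'   IDs (e.g. from the query FASTA via [read_query_ids()]). Defaults to the
#'   queries seen in the file. Queries present here but absent from the file
#'   are retained with zero hits.
#' @return A `hit_table`: a data frame with the 12 outfmt-6 columns plus
#'   `rank`, carrying the query universe as an attribute.
#' @export
parse_hit_table <- function(path, query_universe = NULL) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "#")
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    df <- as.data.frame(setNames(
      c(list(character(), character(), numeric(), integer(), integer(),
             integer(), integer(), integer(), integer(), integer(),
             numeric(), numeric()), list(integer())),
      c(outfmt6_columns, "rank")))
    return(new_hit_table(df, query_universe %||% character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L)) {
    bad <- which(nf != 12L)[1L]
    stop(sprintf("malformed hit row at line %d: expected 12 tab-separated columns, got %d",
                 line_no[bad], nf[bad]))
  }
  m <- matrix(unlist(fields, use.names = FALSE), ncol = 12L, byrow = TRUE)
  num <- function(col, name, check = NULL) {
    v <- suppressWarnings(as.numeric(m[, col]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1L]
      stop(sprintf("non-numeric %s '%s' at line %d", name, m[bad, col],
                   line_no[bad]))
    }
    if (!is.null(check)) check(v, line_no)
    v
  }
  pident <- num(3L, "pident", function(v, ln) {
    if (any(v < 0 | v > 100)) {
      bad <- which(v < 0 | v > 100)[1L]
      stop(sprintf("percent identity out of [0,100] at line %d", ln[bad]))
    }
  })
  evalue <- num(11L, "evalue", function(v, ln) {
    if (any(v < 0)) stop(sprintf("negative E-value at line %d",
                                 ln[which(v < 0)[1L]]))
  })
  q <- m[, 1L]
  df <- data.frame(query_id = q,
                   subject_accession = m[, 2L],
                   percent_identity = pident,
                   length = as.integer(m[, 4L]),
                   mismatch = as.integer(m[, 5L]),
                   gapopen = as.integer(m[, 6L]),
                   qstart = as.integer(m[, 7L]),
                   qend = as.integer(m[, 8L]),
                   sstart = as.integer(m[, 9L]),
                   send = as.integer(m[, 10L]),
                   evalue = evalue,
                   bitscore = num(12L, "bitscore"),
                   stringsAsFactors = FALSE)
  df$rank <- as.integer(ave(seq_along(q), q, FUN = seq_along))
  universe <- if (is.null(query_universe)) unique(q) else as.character(query_universe)
  missing <- setdiff(unique(q), universe)
  if (length(missing) > 0L) {
    stop(sprintf("hit file contains %d quer%s absent from the supplied query universe (first: '%s')",
                 length(missing), if (length(missing) == 1L) "y" else "ies",
                 missing[1L]))
  }
  src <- if (is.character(path)) path else NA_character_
  new_hit_table(df, universe, provenance = src)
}

#' Extract query IDs from a FASTA file
#'
#' Returns the first whitespace-delimited token of every sequence header,
#' for use as the `query_universe` of [parse_hit_table()].
#'
#' @param fasta Path to a FASTA file.
#' @return Character vector of sequence IDs.
#' @export
read_query_ids <- function(fasta) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("read_query_ids() requires the Biostrings package")
  }
  desc <- Biostrings::fasta.index(fasta)$desc
  vapply(strsplit(desc, "[ \t]"), `[[`, character(1L), 1L)
}

#' Filter a hit table
#'
#' Applies, per query and in this order: the identity floor (strictly lower
#' identities are discarded; the boundary value is kept), the E-value
#' cut-off (inclusive: hits at exactly the cut-off are kept, matching BLAST
#' `-evalue` semantics), deduplication of subject accessions keeping the
#' first (highest-ranked) occurrence so that multiple HSPs to one subject
#' cannot double-link articles, and truncation to the first
#' `max_hits_per_query` survivors. Survivors are re-ranked 1..n. The query
#' universe is unchanged: queries may end with zero hits but stay in the
#' "percent annotated" denominator. Filtering is idempotent.
#'
#' @param table A `hit_table`.
#' @param cfg An [annotation_config()].
#' @return The filtered `hit_table`.
#' @export
apply_hit_filters <- function(table, cfg = annotation_config()) {
  stopifnot(inherits(table, "hit_table"), inherits(cfg, "annotation_config"))
  df <- as.data.frame(table)
  keep <- df$percent_identity >= cfg$identity_floor_pct &
    df$evalue <= cfg$evalue_cutoff
  df <- df[keep, , drop = FALSE]
  dup <- duplicated(paste0(df$query_id, "\r", df$subject_accession))
  df <- df[!dup, , drop = FALSE]
  pos <- ave(seq_len(nrow(df)), df$query_id, FUN = seq_along)
  df <- df[pos <= cfg$max_hits_per_query, , drop = FALSE]
  df$rank <- as.integer(ave(seq_len(nrow(df)), df$query_id, FUN = seq_along))
  new_hit_table(df, query_universe(table), attr(table, "provenance"))
}

#' Truncate a hit table to the top k hits per query
#'
#' Keeps hits with rank <= k, emulating a shallower `max_target_seqs`
#' setting on an already filtered table. Truncations nest: the hits at depth
#' k are a subset of the hits at any deeper k'.
#'
#' @param table A filtered `hit_table`.
#' @param k Depth, a positive integer.
#' @return The truncated `hit_table` (query universe unchanged).
#' @export
truncate_depth <- function(table, k) {
  stopifnot(inherits(table, "hit_table"))
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1) {
    stop("`k` must be a positive integer")
  }
  df <- as.data.frame(table)
  df <- df[df$rank <= k, , drop = FALSE]
  new_hit_table(df, query_universe(table), attr(table, "provenance"))
}

#' Write a hit table in BLAST outfmt-6 dialect
#'
#' Writes the 12 standard columns tab-separated, preserving hit order, so
#' that `parse_hit_table(write_hit_table(x))` round-trips.
#'
#' @param table A `hit_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(table, path) {
  stopifnot(inherits(table, "hit_table"))
  df <- as.data.frame(table)
  cols <- lapply(outfmt6_columns, function(cn) as.character(df[[cn]]))
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

#' Build the external blastx invocation
#'
#' Returns the argument vector for the external `blastx` call used to
#' produce hit tables: fast task mode, tabular output, and the configured
#' E-value cut-off and hit-list depth. Nothing is executed.
#'
#' @param query_fasta Path to the nucleotide query FASTA.
#' @param db Path/name of the protein BLAST database.
#' @param cfg An [annotation_config()].
#' @return Character vector of program and arguments.
#' @export
#' @examples
#' build_blastx_invocation("queries.fa", "bonyfish_7898")
build_blastx_invocation <- function(query_fasta, db, cfg = annotation_config()) {
  if (!is.character(query_fasta) || length(query_fasta) != 1L || !nzchar(query_fasta)) {
    stop("`query_fasta` must be a non-empty path")
  }
  if (!is.character(db) || length(db) != 1L || !nzchar(db)) {
    stop("`db` must be a non-empty database path")
  }
  stopifnot(inherits(cfg, "annotation_config"))
  c("blastx",
    "-task", "blastx-fast",
    "-query", query_fasta,
    "-db", db,
    "-evalue", format(cfg$evalue_cutoff, scientific = TRUE),
    "-max_target_seqs", as.character(cfg$max_hits_per_query),
    "-outfmt", "6")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
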