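#' Load an accession-to-PMID link table
#'
#' Reads a two-column TSV `accession<TAB>pmid`, the offline backend for
#' Entrez protein-to-PubMed links. Repeated accessions merge into one PMID
#' set; an explicit `accession<TAB>-` row records an accession known to have
#' no linked articles.
#'
#' @param path Path to the TSV (no header).
#' @return A link map: named list, accession -> sorted integer vector of
#'   distinct PMIDs (possibly empty).
#' @export
load_link_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(structure(list(), names = character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 2L)) {
    bad <- which(nf != 2L)[1L]
    stop(sprintf("malformed link row at line %d: expected 2 tab-separated columns, got %d",
                 bad, nf[bad]))
  }
  acc <- vapply(fields, `[[`, character(1L), 1L)
  pmid_chr <- vapply(fields, `[[`, character(1L), 2L)
  pmid <- suppressWarnings(as.integer(pmid_chr))
  bad <- is.na(pmid) & pmid_chr != "-"
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf("non-integer PMID '%s' at line %d", pmid_chr[i], i))
  }
  if (any(pmid <= 0L, na.rm = TRUE)) {
    i <- which(pmid <= 0L)[1L]
    stop(sprintf("non-positive PMID at line %d", i))
  }
  lapply(split(pmid, factor(acc, levels = unique(acc))),
         function(v) sort(unique(v[!is.na(v)])))
}

#' Resolve accessions to PMIDs through a link-service backend
#'
#' Deduplicates the input accessions, requests them in batches from a
#' pluggable client, retries transient failures a bounded number of times,
#' and guarantees total coverage: every requested accession appears in the
#' result, with an empty PMID set when the service reports no links.
#'
#' @param accessions Character vector of protein accessions (duplicates
#'   allowed; requested once).
#' @param client A function `function(accessions)` returning a named list of
#'   integer PMID vectors for (a subset of) the batch. [entrez_link_client()]
#'   builds a live E-utilities backend; tests use in-memory mocks.
#' @param batch_size Accessions per request.
#' @param max_retries Attempts per batch before the failure is surfaced.
#' @return A link map (named list accession -> sorted integer PMIDs)
#'   covering every distinct input accession.
#' @export
elink_resolve <- function(accessions, client, batch_size = 200L,
                          max_retries = 3L) {
  stopifnot(is.function(client), batch_size >= 1L, max_retries >= 1L)
  accs <- unique(as.character(accessions))
  out <- setNames(vector("list", length(accs)), accs)
  if (length(accs) == 0L) return(out)
  batches <- split(accs, ceiling(seq_along(accs) / batch_size))
  for (batch in batches) {
    res <- NULL
    last_err <- NULL
    for (attempt in seq_len(max_retries)) {
      res <- tryCatch(client(batch), error = function(e) {
        last_err <<- conditionMessage(e)
        NULL
      })
      if (!is.null(res)) break
    }
    if (is.null(res)) {
      stop(sprintf("link resolution failed after %d attempts for batch starting at accession '%s': %s",
                   max_retries, batch[1L], last_err))
    }
    for (a in batch) {
      v <- res[[a]]
      out[[a]] <- if (is.null(v)) integer() else sort(unique(as.integer(v)))
    }
  }
  out
}

#' Live NCBI E-utilities ELink backend
#'
#' Builds a client for [elink_resolve()] that queries the Entrez ELink
#' service (`dbfrom=protein`, `db=pubmed`, accession IDs). Requests are
#' paced at no more than `rate` per second per NCBI usage policy. Requires
#' network access; the test suite never calls it.
#'
#' @param rate Maximum requests per second (default 3).
#' @param base_url E-utilities endpoint.
#' @return A client function for [elink_resolve()].
#' @export
entrez_link_client <- function(rate = 3,
                               base_url = "https://eutils.ncbi.nlm.nih.gov/entrez/eutils/elink.fcgi") {
  stopifnot(rate > 0)
  last <- 0
  function(accessions) {
    wait <- 1 / rate - (as.numeric(Sys.time()) - last)
    if (wait > 0) Sys.sleep(wait)
    last <<- as.numeric(Sys.time())
    url <- paste0(base_url,
                  "?dbfrom=protein&db=pubmed&retmode=json&idtype=acc&id=",
                  paste(utils::URLencode(accessions, reserved = TRUE),
                        collapse = "&id="))
    j <- jsonlite::fromJSON(url, simplifyVector = FALSE)
    out <- list()
    for (ls in j$linksets) {
      ids <- unlist(lapply(ls$linksetdbs, function(db) {
        if (identical(db$dbto, "pubmed")) unlist(db$links) else NULL
      }))
      acc <- unlist(ls$ids)[1L]
      if (!is.null(acc)) out[[as.character(acc)]] <- as.integer(ids)
    }
    out
  }
}

#' Collect each query's deduplicated article set
#'
#' Per query, unions the PMID sets of the query's retained subject
#' accessions into one deduplicated article set: an article cited by many
#' hits of one query counts once for that query, but counts independently
#' in every query that reaches it. Queries with no hits or no linked
#' articles get empty sets (unannotated). Accessions absent from the link
#' map are treated as having no links and reported in one warning.
#'
#' @param table A filtered `hit_table`.
#' @param links A link map (from [load_link_table()] or [elink_resolve()]).
#' @return A `query_articles` object: named list, query ID (in query-universe
#'   order) -> sorted integer vector of distinct PMIDs.
#' @export
collect_query_pmids <- function(table, links) {
  stopifnot(inherits(table, "hit_table"), is.list(links))
  universe <- query_universe(table)
  df <- as.data.frame(table)
  accs_by_query <- split(df$subject_accession,
                         factor(df$query_id, levels = universe))
  missing <- setdiff(unique(df$subject_accession), names(links))
  if (length(missing) > 0L) {
    warning(sprintf("%d accession(s) absent from the link map treated as unlinked (first: '%s')",
                    length(missing), missing[1L]))
  }
  out <- lapply(accs_by_query, function(accs) {
    v <- unlist(links[unique(accs)], use.names = FALSE)
    if (is.null(v)) integer() else sort(unique(as.integer(v)))
  })
  structure(out, class = "query_articles")
}

#' Write per-query PMID sets to a TSV
#'
#' Two columns `query_id<TAB>pmid`, one row per (query, article) pair;
#' unannotated queries are written as `query_id<TAB>-` so the query universe
#' survives a round trip.
#'
#' @param qa A `query_articles` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_query_pmids <- function(qa, path) {
  rows <- unlist(lapply(names(qa), function(q) {
    p <- qa[[q]]
    if (length(p) == 0L) paste0(q, "\t-") else paste0(q, "\t", p)
  }), use.names = FALSE)
  writeLines(rows %||% character(), path)
  invisible(path)
}
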