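#' Construct a single article record
#'
#' @param pmid Positive integer PubMed ID.
#' @param journal Journal name.
#' @param year Publication year (0 when unknown).
#' @param major,minor Character vectors of MeSH descriptor names; the major
#'   set holds the headings flagged as major topics, the minor set the rest.
#'   The two must be disjoint.
#' @return An `article_record` list.
#' @export
article_record <- function(pmid, journal = "", year = 0L,
                           major = character(), minor = character()) {
  pmid <- as.integer(pmid)
  stopifnot(length(pmid) == 1L, !is.na(pmid), pmid > 0L)
  major <- unique(as.character(major))
  minor <- unique(as.character(minor))
  overlap <- intersect(major, minor)
  if (length(overlap) > 0L) {
    stop(sprintf("PMID %d: term(s) in both major and minor sets: %s",
                 pmid, paste(overlap, collapse = ", ")))
  }
  structure(list(pmid = pmid, journal = as.character(journal),
                 year = as.integer(year), major = major, minor = minor),
            class = "article_record")
}

#' Build an article store from records
#'
#' @param records List of [article_record()]s.
#' @param provenance Free-text source note.
#' @return An `article_store`: records indexed by PMID. Lookups of absent
#'   PMIDs return `NULL`, distinct from a present article with no headings.
#' @export
article_store <- function(records = list(), provenance = NA_character_) {
  pmids <- vapply(records, function(r) r$pmid, integer(1L))
  if (anyDuplicated(pmids)) {
    stop(sprintf("duplicate PMID %d in article store", pmids[anyDuplicated(pmids)]))
  }
  structure(list(records = setNames(records, as.character(pmids)),
                 provenance = provenance),
            class = "article_store")
}

#' Look up articles by PMID
#'
#' @param store An `article_store`.
#' @param pmids Integer PMIDs.
#' @return List of `article_record`s for the PMIDs present in the store,
#'   in input order; absent PMIDs are dropped.
#' @export
store_lookup <- function(store, pmids) {
  stopifnot(inherits(store, "article_store"))
  recs <- store$records[as.character(pmids)]
  recs[!vapply(recs, is.null, logical(1L))]
}

#' Number of articles in a store
#' @param store An `article_store`.
#' @return Integer count.
#' @export
store_size <- function(store) length(store$records)

#' Parse MEDLINE/PubMed citation XML
#'
#' Reads the PubMed baseline-file dialect: each `MedlineCitation` yields one
#' article record with PMID, journal title, year and MeSH headings. A
#' heading's descriptor is filed as a major term iff the `DescriptorName`
#' carries `MajorTopicYN="Y"` or any attached `QualifierName` does (NLM
#' marks topical emphasis on qualifiers, so a descriptor-only rule would
#' systematically undercount major topics); all other descriptors are minor.
#' Qualifier names themselves are never emitted as terms. A missing
#' `PubDate/Year` falls back to the first 4-digit year in `MedlineDate`,
#' else 0.
#'
#' @param x Path to an XML file, or a length-1 character XML string.
#' @param strict If `TRUE`, a citation without a PMID aborts the parse;
#'   otherwise such records are skipped and counted in the `skipped`
#'   attribute (with a warning).
#' @return List of [article_record()]s, with attribute `skipped`.
#' @export
parse_medline_xml <- function(x, strict = FALSE) {
  doc <- xml2::read_xml(x)
  cites <- xml2::xml_find_all(doc, ".//MedlineCitation")
  skipped <- 0L
  records <- list()
  for (cite in cites) {
    pmid_node <- xml2::xml_find_first(cite, "./PMID")
    pmid <- suppressWarnings(as.integer(xml2::xml_text(pmid_node)))
    if (is.na(pmid)) {
      if (strict) stop("MedlineCitation without a PMID element")
      skipped <- skipped + 1L
      next
    }
    journal <- xml2::xml_text(
      xml2::xml_find_first(cite, ".//Journal/Title"))
    if (is.na(journal)) journal <- ""
    year <- suppressWarnings(as.integer(xml2::xml_text(
      xml2::xml_find_first(cite, ".//JournalIssue/PubDate/Year"))))
    if (is.na(year)) {
      md <- xml2::xml_text(
        xml2::xml_find_first(cite, ".//JournalIssue/PubDate/MedlineDate"))
      m <- regmatches(md, regexpr("[0-9]{4}", md))
      year <- if (!is.na(md) && length(m) == 1L) as.integer(m) else 0L
    }
    headings <- xml2::xml_find_all(cite, ".//MeshHeadingList/MeshHeading")
    major <- character()
    minor <- character()
    for (h in headings) {
      dn <- xml2::xml_find_first(h, "./DescriptorName")
      term <- trimws(xml2::xml_text(dn))
      if (is.na(term) || !nzchar(term)) next
      flags <- c(xml2::xml_attr(dn, "MajorTopicYN"),
                 xml2::xml_attr(xml2::xml_find_all(h, "./QualifierName"),
                                "MajorTopicYN"))
      if (any(flags == "Y", na.rm = TRUE)) {
        major <- c(major, term)
      } else {
        minor <- c(minor, term)
      }
    }
    # A descriptor repeated across headings with conflicting flags is major.
    minor <- setdiff(minor, major)
    records[[length(records) + 1L]] <-
      article_record(pmid, journal, year, unique(major), unique(minor))
  }
  if (skipped > 0L) {
    warning(sprintf("skipped %d citation(s) without a PMID", skipped))
  }
  attr(records, "skipped") <- skipped
  records
}

#' Load an article store from TSV
#'
#' Columns `pmid`, `journal`, `year`, `major`, `minor` (header row); the
#' term columns are semicolon-joined descriptor lists. Duplicate PMIDs and
#' rows whose major and minor sets overlap are errors.
#'
#' @param path Path to the TSV.
#' @return An `article_store`.
#' @export
load_article_tsv <- function(path) {
  df <- read.delim(path, colClasses = "character", stringsAsFactors = FALSE,
                   quote = "", na.strings = NULL)
  need <- c("pmid", "journal", "year", "major", "minor")
  if (!all(need %in% names(df))) {
    stop(sprintf("article TSV must have columns %s", paste(need, collapse = ", ")))
  }
  split_terms <- function(s) {
    v <- strsplit(s, ";", fixed = TRUE)[[1L]]
    v[nzchar(v)]
  }
  records <- lapply(seq_len(nrow(df)), function(i) {
    article_record(df$pmid[i], df$journal[i], as.integer(df$year[i]),
                   split_terms(df$major[i]), split_terms(df$minor[i]))
  })
  article_store(records, provenance = if (is.character(path)) path else NA_character_)
}

#' Dump an article store to TSV
#'
#' Inverse of [load_article_tsv()]; lossless for stores whose term names
#' contain no tabs or semicolons.
#'
#' @param store An `article_store`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
dump_article_tsv <- function(store, path) {
  stopifnot(inherits(store, "article_store"))
  rows <- vapply(store$records, function(r) {
    paste(r$pmid, r$journal, r$year,
          paste(r$major, collapse = ";"),
          paste(r$minor, collapse = ";"), sep = "\t")
  }, character(1L))
  writeLines(c("pmid\tjournal\tyear\tmajor\tminor", unname(rows)), path)
  invisible(path)
}

#' Load a MeSH descriptor-to-tree-number map
#'
#' Reads a headerless TSV `descriptor_name<TAB>tree_number`; repeated
#' descriptors merge. Descriptors absent from the file are simply unmapped
#' (category unknown).
#'
#' @param path Path to the TSV.
#' @return Named list, descriptor -> character vector of tree numbers.
#' @export
load_mesh_tree <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(structure(list(), names = character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  # strsplit drops a trailing empty field; restore it so the empty-tree-number
  # check below sees it
  trailing <- endsWith(lines, "\t")
  fields[trailing] <- lapply(fields[trailing], c, "")
  nf <- lengths(fields)
  if (any(nf != 2L)) {
    bad <- which(nf != 2L)[1L]
    stop(sprintf("malformed MeSH tree row at line %d", bad))
  }
  term <- vapply(fields, `[[`, character(1L), 1L)
  tn <- vapply(fields, `[[`, character(1L), 2L)
  if (any(!nzchar(tn))) {
    stop(sprintf("empty tree number at line %d", which(!nzchar(tn))[1L]))
  }
  lapply(split(tn, factor(term, levels = unique(term))),
         function(v) sort(unique(v)))
}

#' Does a descriptor fall under any of the given MeSH categories?
#'
#' Matching is dot-boundary aware: prefix `A15` matches tree numbers `A15`
#' and `A15.x...` but never `A150.x`, so category prefixes cannot collide.
#' Unmapped descriptors never match.
#'
#' @param term Descriptor name (exact, case-sensitive match against the map).
#' @param tree A MeSH tree map from [load_mesh_tree()].
#' @param categories Character vector of tree prefixes (e.g. `c("A15", "G12")`).
#' @return `TRUE` iff at least one of the term's tree numbers falls under at
#'   least one category.
#' @export
term_in_categories <- function(term, tree, categories) {
  tns <- tree[[term]]
  if (is.null(tns) || length(categories) == 0L) return(FALSE)
  for (cat in categories) {
    if (any(tns == cat | startsWith(tns, paste0(cat, ".")))) return(TRUE)
  }
  FALSE
}
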