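#' Parse an NCBI taxonomy nodes.dmp file
#'
#' Reads the pipe-delimited, tab-padded `nodes.dmp` dialect
#' (`taxid\t|\tparent\t|\t...`) into a parent-pointer tree. The NCBI root
#' convention (taxid 1 is its own parent) is accepted; any cycle among
#' non-root nodes, or a parent missing from the file, is a structural error.
#' Validation uses pointer doubling, so multi-million-node dumps are handled
#' without recursion.
#'
#' @param path Path to a nodes.dmp-dialect file (or connection).
#' @return A `taxonomy_tree`: list with `parent_of`, an integer vector of
#'   parent taxids named by child taxid.
#' @export
parse_nodes <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(sub("\t\\|$", "", lines), "\t|\t", fixed = TRUE)
  get_int <- function(i, what) {
    v <- suppressWarnings(as.integer(vapply(fields, `[`, character(1L), i)))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1L]
      stop(sprintf("non-integer %s field at line %d", what, bad))
    }
    v
  }
  taxid <- get_int(1L, "taxid")
  parent <- get_int(2L, "parent taxid")
  if (anyDuplicated(taxid)) {
    stop(sprintf("duplicate taxid %d in nodes file", taxid[anyDuplicated(taxid)]))
  }
  p_idx <- match(parent, taxid)
  if (anyNA(p_idx)) {
    bad <- which(is.na(p_idx))[1L]
    stop(sprintf("parent taxid %d of node %d not present in nodes file",
                 parent[bad], taxid[bad]))
  }
  # Pointer-doubling ancestor chase: after ceiling(log2(n)) squarings every
  # chain of length <= n has been absorbed by a self-parented root; anything
  # not at a root then lies on or above a cycle.
  n <- length(taxid)
  is_root <- p_idx == seq_len(n)
  if (n > 0L && !any(is_root)) {
    stop("taxonomy has no root node (no taxid that is its own parent)")
  }
  p <- p_idx
  reps <- max(1L, ceiling(log2(max(n, 2L))) + 1L)
  for (i in seq_len(reps)) p <- p[p]
  if (any(!is_root[p])) {
    bad <- which(!is_root[p])[1L]
    stop(sprintf("cycle detected in taxonomy: node %d never reaches the root",
                 taxid[bad]))
  }
  structure(list(parent_of = setNames(parent, taxid)),
            class = "taxonomy_tree")
}

#' Parse scientific names from an NCBI names.dmp file
#'
#' Keeps only rows whose name class is `scientific name`.
#'
#' @param path Path to a names.dmp-dialect file.
#' @return Character vector of names, named by taxid.
#' @export
parse_names <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(sub("\t\\|$", "", lines), "\t|\t", fixed = TRUE)
  cls <- vapply(fields, function(f) if (length(f) >= 4L) f[[4L]] else "",
                character(1L))
  keep <- cls == "scientific name"
  taxid <- vapply(fields[keep], `[[`, character(1L), 1L)
  nm <- vapply(fields[keep], `[[`, character(1L), 2L)
  setNames(nm, taxid)
}

#' All taxids in the subtree rooted at a node
#'
#' Enumerates every taxid whose ancestor chain passes through `root`,
#' including `root` itself (sequence records attached at the root rank must
#' not be dropped when the list is used to extract database sequences).
#' Traversal is an iterative breadth-first walk over precomputed child
#' lists, so arbitrarily deep real-world dumps are safe.
#'
#' @param tree A `taxonomy_tree` from [parse_nodes()].
#' @param root Taxid of the subtree root (e.g. 7898 for Actinopterygii, the
#'   ray-finned fishes).
#' @return Sorted integer vector of taxids.
#' @export
subtree_taxids <- function(tree, root) {
  stopifnot(inherits(tree, "taxonomy_tree"))
  taxid <- as.integer(names(tree$parent_of))
  root <- as.integer(root)
  start <- match(root, taxid)
  if (is.na(start)) stop(sprintf("taxid %d not found in taxonomy", root))
  n <- length(taxid)
  p_idx <- match(unname(tree$parent_of), taxid)
  self <- p_idx == seq_len(n)
  kids <- split(seq_len(n)[!self], p_idx[!self])
  queue <- integer(n)
  queue[1L] <- start
  head_i <- 1L
  tail_i <- 1L
  while (head_i <= tail_i) {
    node <- queue[head_i]
    head_i <- head_i + 1L
    ch <- kids[[as.character(node)]]
    if (!is.null(ch)) {
      queue[(tail_i + 1L):(tail_i + length(ch))] <- ch
      tail_i <- tail_i + length(ch)
    }
  }
  sort(taxid[queue[seq_len(tail_i)]])
}

#' Write a taxid list for database extraction tools
#'
#' One integer per line, ascending — the format consumed as a taxid filter
#' by `blastdbcmd -taxidlist` / `makeblastdb` style tooling.
#'
#' @param taxids Non-empty set of taxids.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_taxid_list <- function(taxids, path) {
  taxids <- as.integer(taxids)
  if (length(taxids) == 0L) {
    stop("refusing to write an empty taxid list (an empty filter is almost certainly a mistake)")
  }
  writeLines(as.character(sort(unique(taxids))), path)
  invisible(path)
}

#' Read a taxid list written by [write_taxid_list()]
#'
#' @param path Path to a one-taxid-per-line file.
#' @return Integer vector of taxids.
#' @export
read_taxid_list <- function(path) {
  as.integer(readLines(path))
}
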