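#' Aligned nucleotide sequences
#'
#' Container for an aligned set of mtDNA control-region sequences. Stored
#' internally as an upper-case character matrix (records x columns) over
#' the alphabet A, C, G, T, '-', N and IUPAC ambiguity codes.
#'
#' @param x named character vector of equal-length sequences, or a
#'   character matrix (one row per record, one column per site).
#' @return object of class `dna_alignment`: `seqs` (character matrix),
#'   `length` (number of columns).
#' @export
dna_alignment <- function(x) {
  if (is.character(x) && is.null(dim(x))) {
    if (is.null(names(x))) names(x) <- as.character(seq_along(x))
    lens <- nchar(x)
    if (length(unique(lens)) != 1L)
      stop("all sequences in an alignment must have equal length")
    m <- do.call(rbind, strsplit(toupper(x), ""))
    rownames(m) <- names(x)
  } else {
    m <- toupper(as.matrix(x))
    if (is.null(rownames(m))) rownames(m) <- as.character(seq_len(nrow(m)))
  }
  if (nrow(m) < 1L) stop("alignment must contain at least one record")
  if (anyDuplicated(rownames(m)))
    stop("record ids must be unique")
  structure(list(seqs = m, length = ncol(m)), class = "dna_alignment")
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat("DNA alignment:", nrow(x$seqs), "records,", x$length, "columns\n")
  invisible(x)
}

#' Read an aligned FASTA file
#'
#' @param path FASTA file of aligned sequences.
#' @return a [dna_alignment()].
#' @export
read_alignment <- function(path) {
  m <- ape::read.dna(path, format = "fasta", as.character = TRUE,
                     as.matrix = TRUE)
  dna_alignment(m)
}

#' Write an alignment as FASTA
#'
#' @param aln a [dna_alignment()].
#' @param path output path.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "dna_alignment"))
  seqs <- apply(aln$seqs, 1L, paste0, collapse = "")
  writeLines(paste0(">", names(seqs), "\n", seqs), path)
  invisible(path)
}

#' Remove alignment columns with gaps or unresolved bases
#'
#' Drops every column in which any record carries a gap ('-'), an 'N', or
#' any other IUPAC ambiguity code, leaving only columns that are A/C/G/T in
#' every record. This is the standard cleaning step before haplotype
#' collapsing, and it is idempotent.
#'
#' @param aln a [dna_alignment()].
#' @return filtered [dna_alignment()]; attribute `removed_sites` records
#'   how many columns were dropped.
#' @export
filter_alignment_sites <- function(aln) {
  stopifnot(inherits(aln, "dna_alignment"))
  clean <- aln$seqs %in% c("A", "C", "G", "T")
  dim(clean) <- dim(aln$seqs)
  keep <- apply(clean, 2L, all)
  if (!any(keep))
    stop("site filtering removed every column: no unambiguous sites")
  out <- dna_alignment(aln$seqs[, keep, drop = FALSE])
  attr(out, "removed_sites") <- sum(!keep)
  out
}

#' Collapse identical sequences into haplotypes
#'
#' Merges identical (case-insensitive) records of a site-filtered alignment
#' into haplotypes, preserving counts. Haplotypes are labelled H01, H02, ...
#' in order of decreasing frequency, ties broken alphabetically by
#' sequence, so the labelling is invariant to record order.
#'
#' @param aln a site-filtered [dna_alignment()] (A/C/G/T only).
#' @return object of class `haplotype_set`: `haplotypes` (named character
#'   vector of sequences), `counts`, `membership` (record id -> haplotype
#'   id), `length`.
#' @export
collapse_haplotypes <- function(aln) {
  stopifnot(inherits(aln, "dna_alignment"))
  if (!all(aln$seqs %in% c("A", "C", "G", "T")))
    stop("alignment contains gaps or ambiguity codes; ",
         "run filter_alignment_sites() first")
  seqs <- apply(aln$seqs, 1L, paste0, collapse = "")
  counts_raw <- table(seqs)
  ord <- order(-as.integer(counts_raw), names(counts_raw))
  uniq <- names(counts_raw)[ord]
  hap_ids <- sprintf("H%02d", seq_along(uniq))
  membership <- stats::setNames(hap_ids[match(seqs, uniq)], names(seqs))
  structure(
    list(haplotypes = stats::setNames(uniq, hap_ids),
         counts = stats::setNames(as.integer(counts_raw)[ord], hap_ids),
         membership = membership, length = aln$length),
    class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat("Haplotype set:", length(x$haplotypes), "haplotypes from",
      sum(x$counts), "records,", x$length, "bp\n")
  invisible(x)
}

#' Pairwise nucleotide differences between haplotypes
#'
#' @param haps a [collapse_haplotypes()] result (or named character vector
#'   of equal-length sequences).
#' @return symmetric integer matrix of Hamming distances, zero diagonal.
#' @export
pairwise_differences <- function(haps) {
  seqs <- if (inherits(haps, "haplotype_set")) haps$haplotypes
          else haps
  if (length(unique(nchar(seqs))) != 1L)
    stop("haplotype sequences must have equal length")
  m <- do.call(rbind, strsplit(toupper(seqs), ""))
  H <- nrow(m)
  d <- matrix(0L, H, H, dimnames = list(names(seqs), names(seqs)))
  if (H > 1L)
    for (i in seq_len(H - 1L))
      for (j in (i + 1L):H)
        d[i, j] <- d[j, i] <- sum(m[i, ] != m[j, ])
  d
}

## follow parent pointers to the component root (haplotype counts are tiny,
## so no path compression is needed)
.uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Minimum-spanning haplotype network
#'
#' Builds a minimum spanning tree over haplotypes from a matrix of
#' mutational steps (Kruskal's algorithm; ties broken by the sorted pair of
#' node ids, so the result is deterministic), and additionally reports
#' every non-tree pair whose distance equals the bottleneck (maximum edge)
#' on the tree path between its endpoints — the alternative equal-length
#' connections a haplotype network displays alongside the tree.
#'
#' @param dist symmetric non-negative matrix of mutational steps (e.g. from
#'   [pairwise_differences()]).
#' @param counts optional named vector of haplotype frequencies.
#' @return object of class `haplo_network`: `nodes` (data.frame id, freq),
#'   `edges` (data.frame from, to, steps; the tree), `alternative_edges`
#'   (same columns; equal-length non-tree connections).
#' @export
build_msn <- function(dist, counts = NULL) {
  d <- as.matrix(dist)
  H <- nrow(d)
  if (H < 1L) stop("need at least one haplotype")
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- sprintf("H%02d", seq_len(H))
  }
  ids <- rownames(d)
  if (!isTRUE(all.equal(d, t(d))) || any(d < 0))
    stop("distance matrix must be symmetric and non-negative")
  if (is.null(counts)) counts <- stats::setNames(rep(1L, H), ids)
  nodes <- data.frame(id = ids, freq = as.integer(counts[ids]))

  if (H == 1L) {
    empty <- data.frame(from = character(), to = character(),
                        steps = numeric())
    return(structure(list(nodes = nodes, edges = empty,
                          alternative_edges = empty),
                     class = "haplo_network"))
  }
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  cand <- data.frame(i = pairs[, 1L], j = pairs[, 2L],
                     from = ids[pairs[, 1L]], to = ids[pairs[, 2L]],
                     steps = d[pairs])
  ## lexicographic tie-break on the sorted node-id pair
  lo <- pmin(cand$from, cand$to)
  hi <- pmax(cand$from, cand$to)
  cand <- cand[order(cand$steps, lo, hi), ]
  parent <- seq_len(H)
  in_tree <- logical(nrow(cand))
  taken <- 0L
  for (e in seq_len(nrow(cand))) {
    ri <- .uf_find(parent, cand$i[e])
    rj <- .uf_find(parent, cand$j[e])
    if (ri != rj) {
      parent[ri] <- rj
      in_tree[e] <- TRUE
      taken <- taken + 1L
      if (taken == H - 1L) break
    }
  }
  tree <- cand[in_tree, c("from", "to", "steps")]
  rownames(tree) <- NULL

  ## bottleneck (max edge weight) along the unique tree path, by BFS from
  ## each node over the tree adjacency
  adj <- vector("list", H)
  names(adj) <- ids
  tr_i <- match(tree$from, ids)
  tr_j <- match(tree$to, ids)
  for (e in seq_len(nrow(tree))) {
    adj[[tr_i[e]]] <- rbind(adj[[tr_i[e]]], c(tr_j[e], tree$steps[e]))
    adj[[tr_j[e]]] <- rbind(adj[[tr_j[e]]], c(tr_i[e], tree$steps[e]))
  }
  bottleneck <- matrix(0, H, H)
  for (s in seq_len(H)) {
    visited <- rep(FALSE, H)
    visited[s] <- TRUE
    queue <- s
    while (length(queue)) {
      v <- queue[1L]
      queue <- queue[-1L]
      nb <- adj[[v]]
      if (!is.null(nb)) for (row in seq_len(nrow(nb))) {
        w <- nb[row, 1L]
        if (!visited[w]) {
          visited[w] <- TRUE
          bottleneck[s, w] <- max(bottleneck[s, v], nb[row, 2L])
          queue <- c(queue, w)
        }
      }
    }
  }
  non_tree <- cand[!in_tree & seq_len(nrow(cand)) <= nrow(cand), , drop = FALSE]
  alt_sel <- non_tree$steps == bottleneck[cbind(non_tree$i, non_tree$j)]
  alt <- non_tree[alt_sel, c("from", "to", "steps")]
  rownames(alt) <- NULL
  structure(list(nodes = nodes, edges = tree, alternative_edges = alt),
            class = "haplo_network")
}

#' @export
print.haplo_network <- function(x, ...) {
  cat("Haplotype network:", nrow(x$nodes), "nodes,", nrow(x$edges),
      "tree edges (total", sum(x$edges$steps), "steps),",
      nrow(x$alternative_edges), "alternative edges\n")
  invisible(x)
}

#' In-silico diagnostic restriction screen
#'
#' Classifies a sequence as `"cut"` or `"uncut"` by presence of a
#' restriction recognition motif. The default motif GTTAAC is the HpaI
#' recognition site, which is its own reverse complement, so scanning the
#' forward strand suffices. If the motif is absent but some window could
#' match it were its N bases resolved, the call is indeterminate and an
#' error is raised.
#'
#' @param seq a single nucleotide string over A/C/G/T/N (ungapped).
#' @param site recognition motif (default `"GTTAAC"`, HpaI).
#' @return `"cut"` or `"uncut"`.
#' @export
rflp_assign <- function(seq, site = "GTTAAC") {
  s <- toupper(as.character(seq))
  if (length(s) != 1L || !nzchar(s)) stop("need one non-empty sequence")
  if (grepl("[^ACGTN]", s)) stop("sequence must be over A/C/G/T/N")
  site <- toupper(site)
  w <- nchar(site)
  if (nchar(s) < w) return("uncut")
  sc <- strsplit(s, "")[[1L]]
  mc <- strsplit(site, "")[[1L]]
  indeterminate <- FALSE
  for (start in seq_len(nchar(s) - w + 1L)) {
    win <- sc[start:(start + w - 1L)]
    is_n <- win == "N"
    if (all(win[!is_n] == mc[!is_n])) {
      if (!any(is_n)) return("cut")
      indeterminate <- TRUE
    }
  }
  if (indeterminate)
    stop("indeterminate: N within a window that could match the motif")
  "uncut"
}

#' Screen many sequences with a diagnostic restriction motif
#'
#' Vectorised wrapper around [rflp_assign()]; indeterminate sequences are
#' returned as `NA` with a warning rather than an error.
#'
#' @param seqs character vector of sequences, or a [dna_alignment()]
#'   (gaps are stripped per record before scanning).
#' @param site recognition motif.
#' @return named character vector of `"cut"` / `"uncut"` / `NA`.
#' @export
rflp_screen <- function(seqs, site = "GTTAAC") {
  if (inherits(seqs, "dna_alignment"))
    seqs <- gsub("-", "", apply(seqs$seqs, 1L, paste0, collapse = ""))
  ## partially resolved IUPAC codes carry no information for the screen:
  ## degrade them to N so only motif-window ambiguity is indeterminate
  seqs <- gsub("[RYSWKMBDHV]", "N", toupper(seqs))
  out <- vapply(seqs, function(s) {
    tryCatch(rflp_assign(s, site), error = function(e) NA_character_)
  }, character(1L))
  if (anyNA(out))
    warning(sum(is.na(out)), " sequence(s) indeterminate (N in a candidate",
            " window); returned as NA")
  out
}
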