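#' Diploid microsatellite genotype matrix
#'
#' @param a1,a2 integer matrices (individuals x loci) holding the two
#'   alleles of each genotype; `NA` marks missing data. Allele labels are
#'   positive integers (e.g. fragment sizes).
#' @param pop character or factor vector of population labels, one per
#'   individual.
#' @param loci optional locus names.
#' @param ids optional individual ids.
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(a1, a2, pop, loci = NULL, ids = NULL) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  if (!identical(dim(a1), dim(a2)))
    stop("'a1' and 'a2' must have identical dimensions")
  n <- nrow(a1)
  if (length(pop) != n) stop("need one population label per individual")
  if (any(stats::na.omit(c(a1, a2)) < 1))
    stop("allele labels must be positive integers")
  if (is.null(loci)) loci <- colnames(a1)
  if (is.null(loci)) loci <- paste0("L", seq_len(ncol(a1)))
  if (is.null(ids)) ids <- rownames(a1)
  if (is.null(ids)) ids <- paste0("ind", seq_len(n))
  dimnames(a1) <- dimnames(a2) <- list(ids, loci)
  structure(list(a1 = a1, a2 = a2, pop = as.character(pop),
                 loci = loci, ids = ids),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("Genotype matrix:", length(x$ids), "individuals,",
      length(x$loci), "loci,", length(unique(x$pop)), "populations\n")
  invisible(x)
}

#' Read genotypes from a plain delimited table
#'
#' Expects columns `id`, `pop`, then two columns per locus named
#' `<locus>_1` and `<locus>_2`. Missing alleles may be `NA` or `0`.
#'
#' @param path delimited text file (tab or whitespace separated).
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path) {
  tab <- utils::read.table(path, header = TRUE, check.names = FALSE)
  if (!all(c("id", "pop") %in% names(tab)))
    stop("genotype table needs 'id' and 'pop' columns")
  acols <- setdiff(names(tab), c("id", "pop"))
  base <- sub("_[12]$", "", acols)
  loci <- unique(base)
  if (!all(paste0(rep(loci, each = 2), c("_1", "_2")) %in% acols))
    stop("each locus needs '<locus>_1' and '<locus>_2' columns")
  a1 <- as.matrix(tab[paste0(loci, "_1")])
  a2 <- as.matrix(tab[paste0(loci, "_2")])
  a1[a1 == 0] <- NA; a2[a2 == 0] <- NA
  genotype_matrix(a1, a2, pop = tab$pop, loci = loci, ids = tab$id)
}

#' Write genotypes as a plain delimited table
#'
#' @param g a [genotype_matrix()].
#' @param path output path.
#' @export
write_genotypes <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  out <- data.frame(id = g$ids, pop = g$pop, check.names = FALSE)
  for (l in seq_along(g$loci)) {
    out[[paste0(g$loci[l], "_1")]] <- g$a1[, l]
    out[[paste0(g$loci[l], "_2")]] <- g$a2[, l]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a Genepop-format genotype file
#'
#' Minimal reader for the classic Genepop layout: a title line, one locus
#' name per line (or a single comma-separated line), `pop` separator lines,
#' then `individual , 0102 0304 ...` records with 2- or 3-digit allele
#' codes (`00`/`000` = missing). Populations are named pop1, pop2, ... or
#' by the id of their last individual prefixed line is not parsed.
#'
#' @param path Genepop file.
#' @return a [genotype_matrix()].
#' @export
read_genepop <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (length(lines) < 3L) stop("not a Genepop file: too few lines")
  lines <- lines[-1L]  # title
  pop_rows <- grep("^[Pp][Oo][Pp]$", lines)
  if (!length(pop_rows)) stop("no 'pop' separators found")
  locus_lines <- lines[seq_len(pop_rows[1L] - 1L)]
  loci <- trimws(unlist(strsplit(locus_lines, ",")))
  loci <- loci[nzchar(loci)]
  ids <- character(); pops <- character()
  a1 <- a2 <- NULL
  pop_i <- 0L
  for (r in seq_along(lines)) {
    if (r %in% pop_rows) { pop_i <- pop_i + 1L; next }
    if (r < pop_rows[1L]) next
    parts <- strsplit(lines[r], ",")[[1L]]
    if (length(parts) != 2L) stop("malformed Genepop record: ", lines[r])
    codes <- strsplit(trimws(parts[2L]), "[[:space:]]+")[[1L]]
    if (length(codes) != length(loci))
      stop("record '", trimws(parts[1L]), "': expected ", length(loci),
           " loci, found ", length(codes))
    w <- nchar(codes[1L]) / 2L
    al1 <- as.integer(substr(codes, 1L, w))
    al2 <- as.integer(substr(codes, w + 1L, 2L * w))
    al1[al1 == 0L] <- NA; al2[al2 == 0L] <- NA
    ids <- c(ids, trimws(parts[1L]))
    pops <- c(pops, paste0("pop", pop_i))
    a1 <- rbind(a1, al1); a2 <- rbind(a2, al2)
  }
  genotype_matrix(a1, a2, pop = pops, loci = loci, ids = ids)
}

## Weir-Cockerham (1984) variance components for one locus and two
## populations; returns c(a, b, c) summed over alleles.
.wc_components <- function(g1_1, g1_2, g2_1, g2_2) {
  ok1 <- !is.na(g1_1) & !is.na(g1_2)
  ok2 <- !is.na(g2_1) & !is.na(g2_2)
  n1 <- sum(ok1); n2 <- sum(ok2)
  if (n1 < 2L || n2 < 2L) return(c(0, 0, 0))
  alleles <- sort(unique(c(g1_1[ok1], g1_2[ok1], g2_1[ok2], g2_2[ok2])))
  if (length(alleles) < 2L) return(c(0, 0, 0))
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  A <- B <- C <- 0
  for (u in alleles) {
    p1 <- (sum(g1_1[ok1] == u) + sum(g1_2[ok1] == u)) / (2 * n1)
    p2 <- (sum(g2_1[ok2] == u) + sum(g2_2[ok2] == u)) / (2 * n2)
    h1 <- sum(ok1 & ((g1_1 == u) != (g1_2 == u))) / n1
    h2 <- sum(ok2 & ((g2_1 == u) != (g2_2 == u))) / n2
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    A <- A + (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    B <- B + (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    C <- C + hbar / 2
  }
  c(A, B, C)
}

#' Weir-Cockerham pairwise FST (theta)
#'
#' Multiallelic theta of Weir & Cockerham (1984) between two populations,
#' combining loci as the ratio of summed variance components. Missing
#' genotypes are excluded per locus (complete-case within the pair); loci
#' monomorphic across the pair contribute nothing. Negative estimates are
#' reported as computed.
#'
#' @param g a [genotype_matrix()].
#' @param popA,popB population labels present in `g$pop`.
#' @return numeric theta.
#' @export
wc_fst <- function(g, popA, popB) {
  stopifnot(inherits(g, "genotype_matrix"))
  iA <- which(g$pop == popA)
  iB <- which(g$pop == popB)
  if (length(iA) < 2L || length(iB) < 2L)
    stop("need at least 2 individuals per population")
  comp <- vapply(seq_along(g$loci), function(l)
    .wc_components(g$a1[iA, l], g$a2[iA, l], g$a1[iB, l], g$a2[iB, l]),
    numeric(3L))
  num <- sum(comp[1L, ])
  den <- sum(comp)
  if (den == 0)
    stop("no polymorphic locus shared by ", popA, " and ", popB,
         ": theta undefined")
  num / den
}

#' Permutation test of pairwise FST
#'
#' Shuffles individuals between the two populations (genotypes travel with
#' individuals) and recomputes theta under each permutation. The p-value
#' uses the add-one rule `p = (1 + #(theta* >= theta)) / (n_perm + 1)`, so
#' it is bounded below by `1/(n_perm + 1)`.
#'
#' @param g a [genotype_matrix()].
#' @param popA,popB population labels.
#' @param n_perm number of permutations (default 1000).
#' @param seed optional integer seed.
#' @return object of class `fst_result`: `pair`, `theta`, `p_value`,
#'   `n_perm`.
#' @export
fst_permutation_test <- function(g, popA, popB, n_perm = 1000L,
                                 seed = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (n_perm < 1L) stop("n_perm must be positive")
  theta <- wc_fst(g, popA, popB)
  idx <- which(g$pop %in% c(popA, popB))
  nA <- sum(g$pop == popA)
  if (!is.null(seed)) set.seed(as.integer(seed))
  sub <- genotype_matrix(g$a1[idx, , drop = FALSE],
                         g$a2[idx, , drop = FALSE],
                         pop = g$pop[idx], loci = g$loci,
                         ids = g$ids[idx])
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    perm <- sample(length(idx))
    lab <- rep(popB, length(idx))
    lab[perm[seq_len(nA)]] <- popA
    sub$pop <- lab
    th <- tryCatch(wc_fst(sub, popA, popB), error = function(e) NA_real_)
    if (!is.na(th) && th >= theta) exceed <- exceed + 1L
  }
  structure(list(pair = c(popA, popB), theta = theta,
                 p_value = (1 + exceed) / (n_perm + 1),
                 n_perm = as.integer(n_perm)),
            class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf("FST %s vs %s: theta = %.4f, p = %.4g (%d permutations)\n",
              x$pair[1L], x$pair[2L], x$theta, x$p_value, x$n_perm))
  invisible(x)
}

#' All pairwise FST values with permutation p-values
#'
#' @param g a [genotype_matrix()].
#' @param n_perm permutations per pair.
#' @param seed integer seed; each pair gets a deterministic substream.
#' @return data.frame with columns popA, popB, theta, p_value, n_perm.
#' @export
pairwise_fst <- function(g, n_perm = 1000L, seed = 1L) {
  stopifnot(inherits(g, "genotype_matrix"))
  pops <- sort(unique(g$pop))
  if (length(pops) < 2L) stop("need at least two populations")
  rows <- list()
  pair_i <- 0L
  for (i in seq_len(length(pops) - 1L)) {
    for (j in (i + 1L):length(pops)) {
      pair_i <- pair_i + 1L
      res <- fst_permutation_test(
        g, pops[i], pops[j], n_perm = n_perm,
        seed = (abs(as.integer(seed)) %% 1000000L) * 1000L + pair_i)
      rows[[pair_i]] <- data.frame(popA = pops[i], popB = pops[j],
                                   theta = res$theta,
                                   p_value = res$p_value,
                                   n_perm = res$n_perm)
    }
  }
  do.call(rbind, rows)
}
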