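## shared fixtures and independent oracles, built in code at test time

rand_config <- function(k, sd = 1) matrix(rnorm(2L * k, sd = sd), k, 2L)

## small dataset of noisy copies of one base shape
make_noisy_dataset <- function(n, k, noise = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  base <- rand_config(k)
  landmark_dataset(lapply(seq_len(n), function(i)
    base + matrix(rnorm(2L * k, 0, noise), k, 2L)))
}

## similarity transform of one configuration
transform_config <- function(m, angle = 0, scale = 1, shift = c(0, 0)) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2L, 2L)
  scale * m %*% R + matrix(shift, nrow(m), 2L, byrow = TRUE)
}

## exhaustive minimum spanning-tree weight: scan edge subsets of size
## n-1 in ascending total weight until one is spanning
brute_mst_weight <- function(d) {
  n <- nrow(d)
  if (n == 1L) return(0)
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  w <- d[pairs]
  m <- nrow(pairs)
  subsets <- utils::combn(m, n - 1L)
  totals <- colSums(matrix(w[subsets], n - 1L))
  ord <- order(totals)
  for (s in ord) {
    edges <- subsets[, s]
    parent <- seq_len(n)
    root <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    comp <- n
    for (e in edges) {
      ri <- root(pairs[e, 1L]); rj <- root(pairs[e, 2L])
      if (ri != rj) { parent[ri] <- rj; comp <- comp - 1L }
    }
    if (comp == 1L) return(totals[s])
  }
  stop("no spanning subset found")
}

## plain bootstrap range-extension oracle (apply-based, no shared code
## with the package implementation)
boot_extension_oracle <- function(h, p, B, n) {
  rng <- max(p) - min(p)
  ext <- vapply(seq_len(B), function(b) {
    s <- sample(h, n, replace = TRUE)
    100 * (max(0, max(s) - max(p)) + max(0, min(p) - min(s))) / rng
  }, 0)
  ext
}

## brood construction shortcut: genotypes as loci x 2 matrices
geno <- function(..., loci = NULL) {
  v <- c(...)
  m <- matrix(v, ncol = 2L, byrow = TRUE)
  rownames(m) <- if (is.null(loci)) paste0("L", seq_len(nrow(m))) else loci
  m
}
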