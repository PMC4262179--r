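test_that("site filtering removes gap and ambiguity columns, idempotently", {
  # one gap column (2) and one N column (5) in a 5-column alignment
  aln <- dna_alignment(c(s1 = "A-CGT", s2 = "AACGN", s3 = "AACGT"))
  f <- filter_alignment_sites(aln)
  expect_equal(f$length, 3L)
  expect_equal(attr(f, "removed_sites"), 2L)
  clean <- dna_alignment(c(a = "ACGT", b = "ACGA"))
  expect_equal(filter_alignment_sites(clean)$seqs, clean$seqs)
  expect_equal(filter_alignment_sites(f)$seqs, f$seqs)  # idempotent
  # IUPAC ambiguity codes count as unresolved
  expect_equal(filter_alignment_sites(
    dna_alignment(c(x = "ARGT", y = "AAGT")))$length, 3L)
  expect_error(filter_alignment_sites(dna_alignment(c(x = "N-"))),
               "every column")
})

test_that("haplotype collapsing merges identical records with counts", {
  aln <- dna_alignment(c(s1 = "ACG", s2 = "ACG", s3 = "ACT"))
  h <- collapse_haplotypes(aln)
  expect_equal(length(h$haplotypes), 2L)
  expect_equal(unname(h$counts), c(2L, 1L))
  expect_equal(unname(h$membership[c("s1", "s2", "s3")]),
               c("H01", "H01", "H02"))
  # all distinct
  aln2 <- dna_alignment(c(a = "AAA", b = "AAC", c = "ACC"))
  expect_equal(length(collapse_haplotypes(aln2)$haplotypes), 3L)
  expect_error(collapse_haplotypes(dna_alignment(c(a = "AC-"))),
               "filter_alignment_sites")
})

test_that("204 records built from 48 templates collapse to exactly 48", {
  set.seed(20)
  templates <- character(0)
  while (length(templates) < 48L)
    templates <- unique(c(templates,
                          paste0(sample(c("A", "C", "G", "T"), 40L,
                                        replace = TRUE), collapse = "")))
  picks <- c(seq_len(48L), sample.int(48L, 204L - 48L, replace = TRUE))
  aln <- dna_alignment(setNames(templates[picks], paste0("ind", 1:204)))
  h <- collapse_haplotypes(aln)
  expect_equal(length(h$haplotypes), 48L)
  expect_equal(sum(h$counts), 204L)
})

test_that("pairwise differences are Hamming distances obeying the triangle inequality", {
  expect_equal(pairwise_differences(c(a = "ACG", b = "ACT"))[1, 2], 1L,
               ignore_attr = TRUE)
  expect_equal(pairwise_differences(c(a = "ACG", b = "ACG"))[1, 2], 0L,
               ignore_attr = TRUE)
  set.seed(21)
  seqs <- setNames(replicate(8L, paste0(
    sample(c("A", "C", "G", "T"), 15L, replace = TRUE), collapse = "")),
    paste0("h", 1:8))
  d <- pairwise_differences(seqs)
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))
  for (i in 1:8) for (j in 1:8) for (k in 1:8)
    expect_lte(d[i, j], d[i, k] + d[k, j])
  expect_error(pairwise_differences(c(a = "ACG", b = "AC")), "equal length")
})

test_that("the unique minimum spanning tree is found on a 3-node chain", {
  d <- matrix(c(0, 1, 3,
                1, 0, 2,
                3, 2, 0), 3L, 3L,
              dimnames = list(c("H1", "H2", "H3"), c("H1", "H2", "H3")))
  net <- build_msn(d)
  expect_equal(nrow(net$edges), 2L)
  expect_equal(sum(net$edges$steps), 3)
  pairs <- paste(net$edges$from, net$edges$to)
  expect_setequal(pairs, c("H1 H2", "H2 H3"))
  # single haplotype: one node, no edges
  single <- build_msn(matrix(0, 1L, 1L, dimnames = list("H1", "H1")))
  expect_equal(nrow(single$nodes), 1L)
  expect_equal(nrow(single$edges), 0L)
  expect_error(build_msn(matrix(c(0, 1, 2, 0), 2L)), "symmetric")
})

test_that("equal-length alternative connections are reported", {
  # equilateral triangle: 2 tree edges plus 1 alternative of equal length
  d <- matrix(1, 3L, 3L); diag(d) <- 0
  dimnames(d) <- list(paste0("H", 1:3), paste0("H", 1:3))
  net <- build_msn(d)
  expect_equal(nrow(net$edges), 2L)
  expect_equal(nrow(net$alternative_edges), 1L)
  expect_equal(net$alternative_edges$steps, 1)
})

test_that("tree weight matches exhaustive enumeration on small instances", {
  set.seed(22)
  for (rep in 1:60) {
    n <- sample(2:7, 1L)
    d <- matrix(0L, n, n)
    d[upper.tri(d)] <- sample.int(9L, n * (n - 1L) / 2L, replace = TRUE)
    d <- d + t(d)
    dimnames(d) <- list(paste0("H", 1:n), paste0("H", 1:n))
    net <- build_msn(d)
    expect_equal(sum(net$edges$steps), brute_mst_weight(d))
    expect_equal(nrow(net$edges), n - 1L)
  }
})

test_that("restriction screening detects the motif with the ambiguity rule", {
  expect_equal(rflp_assign("AAGTTAACA"), "cut")
  expect_equal(rflp_assign("aagttaaca"), "cut")   # case-insensitive
  expect_equal(rflp_assign("AAAAAA"), "uncut")
  expect_equal(rflp_assign("GTT"), "uncut")       # shorter than the motif
  expect_error(rflp_assign("AAGTNAACA"), "indeterminate")
  # N that cannot complete the motif is harmless
  expect_equal(rflp_assign("CCNCCCCCC"), "uncut")
  expect_error(rflp_assign(""), "non-empty")
  v <- suppressWarnings(rflp_screen(c(a = "AAGTTAACA", b = "CCCCCCC",
                                      c = "AGTNAACAA")))
  expect_equal(unname(v), c("cut", "uncut", NA))
})

test_that("Weir-Cockerham theta hits the poles and a hand-worked toy case", {
  # complete fixation for different alleles
  g <- genotype_matrix(matrix(c(1, 1, 2, 2)), matrix(c(1, 1, 2, 2)),
                       pop = c("A", "A", "B", "B"))
  expect_equal(wc_fst(g, "A", "B"), 1)
  # hand-worked 4-individual toy: pop1 {(1,1),(1,2)}, pop2 {(2,2),(1,2)}
  # variance components per allele: a = 0.0625, b = 0, c = 0.25,
  # summed over the two alleles theta = 0.125 / 0.625 = 0.2
  toy <- genotype_matrix(matrix(c(1, 1, 2, 1)), matrix(c(1, 2, 2, 2)),
                         pop = c("p1", "p1", "p2", "p2"))
  expect_equal(wc_fst(toy, "p1", "p2"), 0.2, tolerance = 1e-12)
  # duplicated population: no differentiation beyond sampling noise
  set.seed(23)
  a1 <- matrix(sample.int(6L, 100L * 10L, replace = TRUE), 100L)
  a2 <- matrix(sample.int(6L, 100L * 10L, replace = TRUE), 100L)
  dup <- genotype_matrix(rbind(a1, a1), rbind(a2, a2),
                         pop = rep(c("x", "y"), each = 100L))
  expect_lt(abs(wc_fst(dup, "x", "y")), 0.02)
  mono <- genotype_matrix(matrix(1, 4L), matrix(1, 4L),
                          pop = c("A", "A", "B", "B"))
  expect_error(wc_fst(mono, "A", "B"), "polymorphic")
})

test_that("permutation p-values obey the add-one rule and find fixation", {
  g <- genotype_matrix(
    matrix(rep(c(1L, 2L), each = 10L), ncol = 1L),
    matrix(rep(c(1L, 2L), each = 10L), ncol = 1L),
    pop = rep(c("A", "B"), each = 10L))
  res <- fst_permutation_test(g, "A", "B", n_perm = 999L, seed = 1)
  expect_equal(res$theta, 1)
  expect_equal(res$p_value, 0.001)          # 1/(n_perm + 1): the floor
  # reproducible by seed
  res2 <- fst_permutation_test(g, "A", "B", n_perm = 999L, seed = 1)
  expect_identical(res$p_value, res2$p_value)
})

test_that("null permutation p-values are not anticonservative", {
  set.seed(24)
  hits <- replicate(20L, {
    a1 <- matrix(sample.int(8L, 60L * 5L, replace = TRUE), 60L)
    a2 <- matrix(sample.int(8L, 60L * 5L, replace = TRUE), 60L)
    g <- genotype_matrix(a1, a2, pop = rep(c("A", "B"), each = 30L))
    fst_permutation_test(g, "A", "B", n_perm = 99L)$p_value > 0.05
  })
  expect_gte(mean(hits), 0.8)
})

test_that("Genepop files round-trip through the plain-table reader", {
  gen <- withr::local_tempfile(fileext = ".gen")
  writeLines(c("synthetic contact-zone screen",
               "UNH154", "Pzeb5",
               "pop",
               "liw01 , 0102 0304",
               "liw02 , 0101 0000",
               "pop",
               "sal01 , 0202 0303"), gen)
  g <- read_genepop(gen)
  expect_equal(g$loci, c("UNH154", "Pzeb5"))
  expect_equal(g$pop, c("pop1", "pop1", "pop2"))
  expect_equal(unname(g$a1[, "UNH154"]), c(1L, 1L, 2L))
  expect_true(is.na(g$a1[2L, "Pzeb5"]))    # 0000 is missing
  # plain-table writer/reader round-trip
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(g, tsv)
  back <- read_genotypes(tsv)
  expect_equal(back$a1, g$a1, ignore_attr = TRUE)
  expect_equal(back$pop, g$pop)
})

test_that("the haplotype pipeline is invariant to record order", {
  sq <- gen_sequences(genetic_sim_config(n_per_haplogroup = 20L, seed = 25))
  run <- function(aln) {
    h <- collapse_haplotypes(filter_alignment_sites(aln))
    net <- build_msn(pairwise_differences(h), h$counts)
    # name edges by haplotype sequence so labels are order-free
    seqs <- h$haplotypes
    sort(paste(pmin(seqs[net$edges$from], seqs[net$edges$to]),
               pmax(seqs[net$edges$from], seqs[net$edges$to]),
               net$edges$steps))
  }
  aln <- sq$alignment
  set.seed(26)
  perm <- dna_alignment(aln$seqs[sample(nrow(aln$seqs)), ])
  expect_identical(run(aln), run(perm))
})
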