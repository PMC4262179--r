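test_that("exclusion assigns the only compatible candidate", {
  b <- brood("b1", "mom", geno(1, 1), replicate(8L, geno(1, 2),
                                                simplify = FALSE),
             replicate_id = "rep1", mother_lineage = "Salima")
  cands <- list(m1 = geno(2, 2), m2 = geno(3, 3))
  rec <- assign_paternity(b, cands,
                          candidate_lineages = c(m1 = "Ruvuma",
                                                 m2 = "Salima"))
  expect_equal(rec$status, "assigned")
  expect_equal(rec$father_id, "m1")
  expect_false(rec$homotypic)     # Salima mother, Ruvuma sire
  # two compatible candidates are ambiguous
  rec2 <- assign_paternity(b, list(m1 = geno(1, 2), m2 = geno(2, 2)))
  expect_equal(rec2$status, "ambiguous")
  expect_true(is.na(rec2$father_id))
  # nobody compatible and no two-sire split possible: excluded
  rec3 <- assign_paternity(b, list(m1 = geno(3, 3)))
  expect_equal(rec3$status, "excluded")
})

test_that("strict exclusion never assigns a candidate with any mismatch", {
  set.seed(30)
  for (rep in 1:40) {
    cfg <- genetic_sim_config(seed = 3000 + rep, n_replicates = 1L,
                              females_per_lineage = 1L)
    mc <- gen_matechoice(cfg)
    rp <- mc$replicates$rep1
    for (b in rp$broods) {
      rec <- assign_paternity(b, rp$candidates, rp$candidate_lineages,
                              mismatch_tolerance = 0L)
      for (i in which(rec$status == "assigned" & !rec$multiple)) {
        cand <- rp$candidates[[rec$father_id[i]]]
        mism <- sum(vapply(b$fry, function(f) {
          sum(!vapply(rownames(b$mother), function(l) {
            fa <- f[l, ]; mo <- b$mother[l, ]; ca <- cand[l, ]
            (fa[1] %in% mo && fa[2] %in% ca) ||
              (fa[2] %in% mo && fa[1] %in% ca)
          }, TRUE))
        }, 0))
        expect_equal(mism, 0)
      }
    }
  }
})

test_that("the true sire is recovered from Mendelian broods", {
  set.seed(31)
  correct <- 0L; total <- 0L
  for (chunk in 1:25) {
    cfg <- genetic_sim_config(seed = 500 + chunk, n_replicates = 1L)
    mc <- gen_matechoice(cfg)       # 12 broods, 6 candidates, 5 loci, 8 fry
    rp <- mc$replicates$rep1
    for (b in rp$broods) {
      rec <- assign_paternity(b, rp$candidates, rp$candidate_lineages)
      total <- total + 1L
      truth <- mc$truth$true_father[mc$truth$brood_id == b$brood_id]
      if (nrow(rec) == 1L && rec$status == "assigned" &&
          rec$father_id == truth)
        correct <- correct + 1L
    }
  }
  expect_gte(correct / total, 0.95)
})

test_that("a mixed brood is split between two flagged sires", {
  # fry carry paternal alleles 2 (m1) or 3 (m2) at every locus; no single
  # candidate explains all fry
  fry <- c(replicate(4L, geno(1, 2, 1, 2), simplify = FALSE),
           replicate(4L, geno(1, 3, 1, 3), simplify = FALSE))
  b <- brood("b1", "mom", geno(1, 1, 1, 1), fry, replicate_id = "rep1",
             mother_lineage = "Salima")
  cands <- list(m1 = geno(2, 2, 2, 2), m2 = geno(3, 3, 3, 3),
                m3 = geno(4, 4, 4, 4))
  rec <- assign_paternity(b, cands,
                          candidate_lineages = c(m1 = "Salima",
                                                 m2 = "Ruvuma",
                                                 m3 = "Ruvuma"))
  expect_equal(nrow(rec), 2L)
  expect_setequal(rec$father_id, c("m1", "m2"))
  expect_true(all(rec$multiple))
  expect_equal(sum(rec$n_fry), 8L)
})

test_that("tallies drop unresolved records and count heterotypic matings", {
  rec <- data.frame(
    brood_id = paste0("b", 1:10), replicate = "rep1",
    father_id = c(paste0("m", 1:8), NA, NA),
    status = c(rep("assigned", 8L), "ambiguous", "excluded"),
    female_lineage = "Salima",
    male_lineage = c(rep("Salima", 7L), "Ruvuma", NA, NA),
    homotypic = c(rep(TRUE, 7L), FALSE, NA, NA),
    multiple = FALSE, n_fry = 8L)
  t <- tally_matings(rec)
  r1 <- t[t$replicate == "rep1", ]
  expect_equal(r1$k, 1L)
  expect_equal(r1$n, 8L)
  expect_equal(r1$pct_heterotypic, 12.5)
  expect_equal(t[t$replicate == "pooled", "n"], 8L)
  # all homotypic
  rec$homotypic <- TRUE; rec$male_lineage <- "Salima"
  expect_equal(tally_matings(rec)[1L, "k"], 0L)
})

test_that("exact binomial tails match the closed forms and a CDF oracle", {
  expect_equal(binomial_assortment_test(1L, 11L)$p_value, 12 / 2048,
               tolerance = 1e-12)
  expect_equal(binomial_assortment_test(1L, 9L)$p_value, 10 / 512,
               tolerance = 1e-12)
  expect_equal(binomial_assortment_test(1L, 8L)$p_value, 9 / 256,
               tolerance = 1e-12)
  expect_equal(binomial_assortment_test(0L, 1L)$p_value, 0.5)
  # independent cumulative-distribution oracle across n <= 30
  for (n in c(1L, 2L, 5L, 11L, 17L, 24L, 30L)) {
    for (k in unique(c(0L, 1L, n %/% 2L, n))) {
      for (p0 in c(0.3, 0.5, 0.8)) {
        expect_equal(binomial_assortment_test(k, n, p0)$p_value,
                     pbinom(k, n, p0), tolerance = 1e-12)
      }
    }
  }
  expect_error(binomial_assortment_test(5L, 4L), "k <= n")
  expect_error(binomial_assortment_test(1L, 4L, p0 = 1), "strictly")
})

test_that("heterotypic fraction converges to 1 - assortment at 500 females", {
  cfg <- genetic_sim_config(seed = 32, n_replicates = 1L,
                            females_per_lineage = 250L, assortment = 0.8)
  mc <- gen_matechoice(cfg)
  frac <- mean(!mc$truth$homotypic)
  se <- sqrt(0.2 * 0.8 / 500)
  expect_lt(abs(frac - 0.2), 2 * se + 1e-9)
})

test_that("per-replicate tests append exact p-values", {
  t <- data.frame(replicate = c("rep1", "pooled"), k = c(1L, 1L),
                  n = c(11L, 11L), pct_heterotypic = c(100 / 11, 100 / 11))
  out <- assortment_tests(t)
  expect_equal(out$p_value, rep(12 / 2048, 2L), tolerance = 1e-12)
})
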