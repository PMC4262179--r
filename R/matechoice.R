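#' A mouthbrooding female's brood
#'
#' Bundles one brood from the free mate-choice experiment: the mother's
#' diploid genotype and the genotypes of the fry sampled from her mouth
#' (a minimum of eight fry per brood is the customary screening depth).
#' Genotypes are `loci x 2` integer matrices with loci as rownames.
#'
#' @param brood_id brood identifier.
#' @param mother_id mother identifier.
#' @param mother `loci x 2` integer matrix, the mother's genotype.
#' @param fry list of `loci x 2` integer matrices, one per fry.
#' @param replicate_id experimental replicate label.
#' @param mother_lineage lineage label of the mother (e.g. "Salima").
#' @return object of class `brood`.
#' @export
brood <- function(brood_id, mother_id, mother, fry, replicate_id = NA,
                  mother_lineage = NA_character_) {
  mother <- as.matrix(mother)
  if (is.null(rownames(mother)))
    rownames(mother) <- paste0("L", seq_len(nrow(mother)))
  if (ncol(mother) != 2L) stop("mother genotype must be a loci x 2 matrix")
  if (anyNA(mother)) stop("missing mother genotype not allowed")
  if (length(fry) < 1L) stop("brood must contain at least one fry")
  loci <- rownames(mother)
  fry <- lapply(fry, function(f) {
    f <- as.matrix(f)
    if (is.null(rownames(f))) rownames(f) <- loci
    if (!identical(sort(rownames(f)), sort(loci)))
      stop("fry genotyped at a different locus set than the mother")
    f[loci, , drop = FALSE]
  })
  structure(list(brood_id = as.character(brood_id),
                 mother_id = as.character(mother_id),
                 mother = mother, fry = fry,
                 replicate_id = replicate_id,
                 mother_lineage = mother_lineage),
            class = "brood")
}

## can candidate allele pair explain fry f given mother m at one locus?
## TRUE if one fry allele can come from the mother and the other from the
## candidate. NA alleles (missing data) cannot exclude.
.locus_compatible <- function(f, m, c) {
  if (anyNA(f) || anyNA(c)) return(TRUE)
  (f[1L] %in% m && f[2L] %in% c) || (f[2L] %in% m && f[1L] %in% c)
}

## mismatch count of one candidate against all fry of a brood
.candidate_mismatches <- function(br, cand) {
  loci <- rownames(br$mother)
  sum(vapply(br$fry, function(f) {
    sum(!vapply(loci, function(l)
      .locus_compatible(f[l, ], br$mother[l, ], cand[l, ]), TRUE))
  }, 0))
}

#' Assign paternity of a brood by genotypic exclusion
#'
#' For each candidate father, every fry must be explicable at every locus:
#' after removing one allele matching the mother, the remaining allele must
#' occur in the candidate's genotype. Candidates with more than
#' `mismatch_tolerance` incompatible (fry, locus) combinations are
#' excluded. A single surviving candidate is assigned; several give an
#' `ambiguous` record; none triggers a multiple-paternity fallback that
#' greedily splits the fry between at most two sires (each counting as a
#' mating, flagged `multiple = TRUE`), and failing that the brood is
#' `excluded`.
#'
#' @param brood a [brood()].
#' @param candidates named list of `loci x 2` candidate-father genotype
#'   matrices.
#' @param candidate_lineages optional named character vector of lineage
#'   labels for the candidates.
#' @param mismatch_tolerance allowed incompatibilities before exclusion
#'   (default 0, strict exclusion; 1 tolerates a single genotyping error).
#' @return data.frame (class `mating_record`) with one row per resolved
#'   mating: `brood_id`, `replicate`, `father_id`, `status` (assigned /
#'   ambiguous / excluded), `female_lineage`, `male_lineage`, `homotypic`,
#'   `multiple`, `n_fry`.
#' @export
assign_paternity <- function(brood, candidates, candidate_lineages = NULL,
                             mismatch_tolerance = 0L) {
  stopifnot(inherits(brood, "brood"))
  if (length(candidates) < 1L) stop("need at least one candidate father")
  if (is.null(names(candidates)))
    names(candidates) <- paste0("male", seq_along(candidates))
  loci <- rownames(brood$mother)
  candidates <- lapply(candidates, function(cc) {
    cc <- as.matrix(cc)
    if (is.null(rownames(cc))) rownames(cc) <- loci
    if (!identical(sort(rownames(cc)), sort(loci)))
      stop("candidate genotyped at a different locus set than the brood")
    cc[loci, , drop = FALSE]
  })
  mk_row <- function(father_id, status, multiple = FALSE, n_fry) {
    male_lin <- if (!is.na(father_id) && !is.null(candidate_lineages))
      unname(candidate_lineages[father_id]) else NA_character_
    data.frame(brood_id = brood$brood_id,
               replicate = brood$replicate_id,
               father_id = father_id, status = status,
               female_lineage = brood$mother_lineage,
               male_lineage = male_lin,
               homotypic = if (status == "assigned" &&
                               !is.na(male_lin) &&
                               !is.na(brood$mother_lineage))
                 male_lin == brood$mother_lineage else NA,
               multiple = multiple, n_fry = n_fry)
  }
  mism <- vapply(candidates, .candidate_mismatches, 0, br = brood)
  surviving <- names(candidates)[mism <= mismatch_tolerance]
  n_fry <- length(brood$fry)
  if (length(surviving) == 1L) {
    rec <- mk_row(surviving, "assigned", n_fry = n_fry)
  } else if (length(surviving) > 1L) {
    rec <- mk_row(NA_character_, "ambiguous", n_fry = n_fry)
  } else {
    ## multiple-paternity fallback: greedy cover of fry by <= 2 sires
    per_fry_ok <- vapply(candidates, function(cand)
      vapply(brood$fry, function(f) {
        all(vapply(loci, function(l)
          .locus_compatible(f[l, ], brood$mother[l, ], cand[l, ]), TRUE))
      }, TRUE), logical(n_fry))
    per_fry_ok <- matrix(per_fry_ok, nrow = n_fry,
                         dimnames = list(NULL, names(candidates)))
    cover <- colSums(per_fry_ok)
    first <- names(candidates)[which.max(cover)]
    left <- !per_fry_ok[, first]
    if (!any(left) || cover[first] == 0L) {
      rec <- mk_row(NA_character_, "excluded", n_fry = n_fry)
    } else {
      rest <- setdiff(names(candidates), first)
      cover2 <- colSums(per_fry_ok[left, rest, drop = FALSE])
      second <- rest[which.max(cover2)]
      if (sum(per_fry_ok[left, second]) == sum(left)) {
        rec <- rbind(
          mk_row(first, "assigned", multiple = TRUE,
                 n_fry = sum(!left)),
          mk_row(second, "assigned", multiple = TRUE,
                 n_fry = sum(left)))
      } else {
        rec <- mk_row(NA_character_, "excluded", n_fry = n_fry)
      }
    }
  }
  class(rec) <- c("mating_record", "data.frame")
  rec
}

#' Tally homotypic versus heterotypic matings
#'
#' Drops ambiguous and excluded records, then counts heterotypic matings
#' (female and assigned male from different lineages) per replicate and
#' pooled.
#'
#' @param records a `mating_record` data.frame (rows from
#'   [assign_paternity()], typically `rbind`-ed across broods).
#' @return data.frame with columns `replicate`, `k` (heterotypic), `n`
#'   (assigned matings), `pct_heterotypic`; the final row pools all
#'   replicates (`replicate = "pooled"`).
#' @export
tally_matings <- function(records) {
  if (is.null(records) || nrow(records) == 0L)
    return(data.frame(replicate = "pooled", k = 0L, n = 0L,
                      pct_heterotypic = NaN))
  ok <- records$status == "assigned" & !is.na(records$homotypic)
  rec <- records[ok, , drop = FALSE]
  reps <- unique(as.character(records$replicate))
  rows <- lapply(reps, function(r) {
    sub <- rec[as.character(rec$replicate) == r, , drop = FALSE]
    data.frame(replicate = r, k = sum(!sub$homotypic), n = nrow(sub))
  })
  out <- do.call(rbind, rows)
  out <- rbind(out, data.frame(replicate = "pooled",
                               k = sum(out$k), n = sum(out$n)))
  out$pct_heterotypic <- 100 * out$k / out$n
  out
}

#' Exact binomial test of assortative mating
#'
#' One-sided lower-tail exact binomial probability
#' `P(X <= k | n, p0)`, computed by explicit summation of the binomial
#' mass, for testing whether the heterotypic mating count `k` out of `n`
#' assigned matings is smaller than expected under random mating
#' (`p0 = 0.5`). A two-sided variant (summing all outcomes with mass not
#' exceeding that of `k`) is available via `alternative`.
#'
#' @param k heterotypic mating count.
#' @param n total assigned matings.
#' @param p0 null probability of a heterotypic mating (default 0.5).
#' @param alternative `"less"` (default) or `"two.sided"`.
#' @return object of class `binomial_test`: `k`, `n`, `p0`, `p_value`,
#'   `alternative`.
#' @export
binomial_assortment_test <- function(k, n, p0 = 0.5,
                                     alternative = c("less", "two.sided")) {
  alternative <- match.arg(alternative)
  k <- as.integer(k); n <- as.integer(n)
  if (is.na(k) || is.na(n) || k < 0L || n < 1L || k > n)
    stop("need 0 <= k <= n with n >= 1")
  if (p0 <= 0 || p0 >= 1) stop("p0 must lie strictly between 0 and 1")
  mass <- stats::dbinom(0:n, n, p0)
  p <- if (alternative == "less") {
    sum(mass[seq_len(k + 1L)])
  } else {
    sum(mass[mass <= mass[k + 1L] * (1 + 1e-7)])
  }
  structure(list(k = k, n = n, p0 = p0, p_value = min(1, p),
                 alternative = alternative),
            class = "binomial_test")
}

#' @export
print.binomial_test <- function(x, ...) {
  cat(sprintf("Exact binomial test (%s): k = %d, n = %d, p0 = %g, p = %.4g\n",
              x$alternative, x$k, x$n, x$p0, x$p_value))
  invisible(x)
}

#' Per-replicate assortative-mating tests
#'
#' Applies [binomial_assortment_test()] to each replicate row of a
#' [tally_matings()] table.
#'
#' @param tallies output of [tally_matings()].
#' @param p0,alternative passed to [binomial_assortment_test()].
#' @return the tally data.frame with a `p_value` column appended.
#' @export
assortment_tests <- function(tallies, p0 = 0.5,
                             alternative = c("less", "two.sided")) {
  alternative <- match.arg(alternative)
  tallies$p_value <- vapply(seq_len(nrow(tallies)), function(i) {
    if (tallies$n[i] < 1L) return(NA_real_)
    binomial_assortment_test(tallies$k[i], tallies$n[i], p0,
                             alternative)$p_value
  }, 0)
  tallies
}
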