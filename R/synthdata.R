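#' Configuration for the morphometric simulator
#'
#' Describes a common-garden design: two parental lines reared alongside
#' F1, backcross and F2 hybrid crosses, digitised with a shared landmark
#' scheme. Shape variation is generated in a low-dimensional score space
#' spanned by orthonormal deviation axes of the mean shape and mapped back
#' to landmarks, so per-axis ground truth (group means, spreads, injected
#' transgression) is well defined.
#'
#' @param k number of 2-D landmarks (default 25).
#' @param n_parentA,n_parentB parental sample sizes (default 25 each, so
#'   the pooled parental sample is 50).
#' @param n_F1,n_backcrossA,n_backcrossB,n_F2 hybrid group sizes.
#' @param divergence Procrustes distance between the two parental mean
#'   shapes (placed along shape axis 1).
#' @param axis_sds within-group score standard deviations, one per shape
#'   axis (unit-centroid-size scale).
#' @param landmark_noise_sd digitisation noise sd per landmark coordinate.
#' @param allometry_slopes per-axis allometric effect, expressed in units
#'   of `axis_sds` per standard deviation of log centroid size (0.25
#'   keeps size under 10% of score variance).
#' @param hybrid_transgression per-axis true percentage range extension
#'   injected into all hybrid groups (0 = hybrids segregate within the
#'   parental mixture).
#' @param mean_size,size_log_sd lognormal centroid-size distribution in
#'   image units.
#' @param seed integer seed.
#' @return validated list of class `morpho_sim_config`.
#' @export
morpho_sim_config <- function(k = 25L, n_parentA = 25L, n_parentB = 25L,
                              n_F1 = 50L, n_backcrossA = 50L,
                              n_backcrossB = 50L, n_F2 = 50L,
                              divergence = 0.08,
                              axis_sds = c(0.020, 0.014, 0.010,
                                           0.007, 0.005, 0.0035),
                              landmark_noise_sd = 0.001,
                              allometry_slopes = rep(0.25, 6L),
                              hybrid_transgression = rep(0, 6L),
                              mean_size = 250, size_log_sd = 0.15,
                              seed = 1L) {
  cfg <- list(k = as.integer(k), n_parentA = as.integer(n_parentA),
              n_parentB = as.integer(n_parentB), n_F1 = as.integer(n_F1),
              n_backcrossA = as.integer(n_backcrossA),
              n_backcrossB = as.integer(n_backcrossB),
              n_F2 = as.integer(n_F2), divergence = divergence,
              axis_sds = axis_sds, landmark_noise_sd = landmark_noise_sd,
              allometry_slopes = allometry_slopes,
              hybrid_transgression = hybrid_transgression,
              mean_size = mean_size, size_log_sd = size_log_sd,
              seed = as.integer(seed))
  if (cfg$k < 4L) stop("'k': need at least 4 landmarks")
  sizes <- c(cfg$n_parentA, cfg$n_parentB, cfg$n_F1, cfg$n_backcrossA,
             cfg$n_backcrossB, cfg$n_F2)
  if (any(sizes < 2L)) stop("all group sizes must be at least 2")
  if (length(cfg$axis_sds) != length(cfg$allometry_slopes) ||
      length(cfg$axis_sds) != length(cfg$hybrid_transgression))
    stop("'axis_sds', 'allometry_slopes' and 'hybrid_transgression' must",
         " have equal length")
  if (any(cfg$axis_sds <= 0)) stop("'axis_sds' must be positive")
  if (cfg$landmark_noise_sd <= 0) stop("'landmark_noise_sd' must be positive")
  if (any(cfg$hybrid_transgression < 0))
    stop("'hybrid_transgression' percentages must be non-negative")
  if (cfg$divergence <= 0) stop("'divergence' must be positive")
  if (2L * cfg$k - 4L < length(cfg$axis_sds))
    stop("shape space too small for the requested number of axes")
  structure(cfg, class = "morpho_sim_config")
}

## orthonormal shape-deviation axes: 2k-vectors orthogonal to translation,
## scaling of the mean, and rotation about the mean
.shape_basis <- function(mean_flat, n_axes) {
  two_k <- length(mean_flat)
  k <- two_k / 2L
  tx <- c(rep(1, k), rep(0, k)) / sqrt(k)
  ty <- c(rep(0, k), rep(1, k)) / sqrt(k)
  sc <- mean_flat / sqrt(sum(mean_flat^2))
  rot <- c(-mean_flat[(k + 1L):two_k], mean_flat[seq_len(k)])
  rot <- rot / sqrt(sum(rot^2))
  constraints <- cbind(tx, ty, sc, rot)
  raw <- matrix(stats::rnorm(two_k * n_axes), two_k, n_axes)
  raw <- raw - constraints %*% crossprod(constraints, raw)
  qr.Q(qr(raw))[, seq_len(n_axes), drop = FALSE]
}

#' Generate a synthetic common-garden landmark dataset
#'
#' Parental specimens are Gaussian perturbations around their line's mean
#' shape (the two means differ by `divergence` along shape axis 1); F1
#' individuals scatter around the mid-shape; backcross and F2 individuals
#' segregate between the parental means (backcrosses weighted 3:1 toward
#' the recurrent parent, F2 1:1, so with no injected transgression the F2
#' score distribution is the parental mixture). A positive
#' `hybrid_transgression` entry replaces hybrid scores on that axis with a
#' uniform draw over the pooled parental empirical range widened by that
#' percentage, making the true extension explicit. An allometric size
#' effect and digitisation noise are then added, and each specimen is
#' randomly scaled, rotated and translated into image coordinates.
#'
#' @param cfg a [morpho_sim_config()].
#' @return list with `dataset` (a [landmark_dataset()] with group labels),
#'   and `truth` (generating axes, per-specimen scores and sizes, group
#'   labels, the injected extension percentages, and the config).
#' @export
gen_landmarks <- function(cfg = morpho_sim_config()) {
  stopifnot(inherits(cfg, "morpho_sim_config"))
  set.seed(cfg$seed)
  k <- cfg$k
  m_axes <- length(cfg$axis_sds)

  ## fish-like template: ellipse tapered toward the caudal end
  th <- seq(0, 2 * pi, length.out = k + 1L)[seq_len(k)]
  base <- cbind(cos(th), 0.45 * sin(th) * (1.15 - 0.35 * cos(th)))
  base <- sweep(base, 2L, colMeans(base))
  base <- base / sqrt(sum(base^2))
  mean_flat <- as.vector(base)
  axes <- .shape_basis(mean_flat, m_axes)

  groups <- c(rep("parentA", cfg$n_parentA), rep("parentB", cfg$n_parentB),
              rep("F1", cfg$n_F1), rep("backcrossA", cfg$n_backcrossA),
              rep("backcrossB", cfg$n_backcrossB), rep("F2", cfg$n_F2))
  n <- length(groups)
  hybrid <- !(groups %in% c("parentA", "parentB"))

  ## axis-1 component means: parental divergence and hybrid segregation
  half <- cfg$divergence / 2
  mu1 <- numeric(n)
  mu1[groups == "parentA"] <- half
  mu1[groups == "parentB"] <- -half
  mu1[groups == "F1"] <- 0
  seg <- function(p_up, size) half * (2 * stats::rbinom(size, 1L, p_up) - 1)
  mu1[groups == "backcrossA"] <- seg(0.75, cfg$n_backcrossA)
  mu1[groups == "backcrossB"] <- seg(0.25, cfg$n_backcrossB)
  mu1[groups == "F2"] <- seg(0.5, cfg$n_F2)

  scores <- matrix(stats::rnorm(n * m_axes), n, m_axes) %*%
    diag(cfg$axis_sds, m_axes)
  scores[, 1L] <- scores[, 1L] + mu1

  ## allometry: shape scores drift with log centroid size
  sizes <- cfg$mean_size * exp(stats::rnorm(n, 0, cfg$size_log_sd))
  z <- as.vector(scale(log(sizes)))
  scores <- scores + outer(z, cfg$allometry_slopes * cfg$axis_sds)

  ## inject transgression last, so the injected uniform scores are final on
  ## those axes and the true extension equals the configured percentage
  parent_idx <- !hybrid
  for (j in seq_len(m_axes)) {
    e <- cfg$hybrid_transgression[j]
    if (e > 0) {
      p_rng <- range(scores[parent_idx, j])
      mid <- mean(p_rng)
      hw <- diff(p_rng) / 2 * (1 + e / 100)
      scores[hybrid, j] <- stats::runif(sum(hybrid), mid - hw, mid + hw)
    }
  }

  ids <- sprintf("%s_%03d", groups, stats::ave(seq_len(n), groups,
                                               FUN = seq_along))
  configs <- vector("list", n)
  for (i in seq_len(n)) {
    flat <- mean_flat + axes %*% scores[i, ]
    shp <- matrix(flat, k, 2L) +
      matrix(stats::rnorm(2L * k, 0, cfg$landmark_noise_sd), k, 2L)
    ang <- stats::runif(1L, 0, 2 * pi)
    R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2L, 2L)
    configs[[i]] <- shp %*% R * sizes[i] +
      matrix(stats::runif(2L, 0, 4 * cfg$mean_size), k, 2L, byrow = TRUE)
  }
  dataset <- landmark_dataset(configs, specimen_ids = ids,
                              groups = stats::setNames(groups, ids))
  list(dataset = dataset,
       truth = list(axes = axes, scores = scores, sizes = sizes,
                    groups = stats::setNames(groups, ids),
                    mean_flat = mean_flat,
                    hybrid_transgression = cfg$hybrid_transgression,
                    config = cfg))
}

#' Configuration for the genetic simulators
#'
#' One configuration covers the three genetic generators: divergent mtDNA
#' haplogroups with a diagnostic restriction site ([gen_sequences()]),
#' structured microsatellite populations under the Balding-Nichols model
#' ([gen_genotypes()]), and the mate-choice experiment with Mendelian
#' broods ([gen_matechoice()]).
#'
#' @param n_per_haplogroup individuals sequenced per haplogroup.
#' @param seq_length alignment length in bp before site filtering.
#' @param divergence_sites fixed differences between the two haplogroup
#'   ancestors (one of them inside the diagnostic motif).
#' @param private_mutation_rate Poisson mean of private mutations per
#'   individual.
#' @param dirty_column_rate fraction of alignment columns seeded with a
#'   gap or ambiguity in at least one record (these columns are what site
#'   filtering removes).
#' @param motif diagnostic restriction recognition motif (HpaI, GTTAAC).
#' @param motif_group haplogroup carrying the intact motif ("LMC").
#' @param n_pops,n_per_pop,n_loci,n_alleles microsatellite design.
#' @param target_fst Balding-Nichols differentiation parameter in (0, 1).
#' @param n_replicates,females_per_lineage,males_per_lineage mate-choice
#'   design (defaults: 4 replicates, 6 females and 3 males per lineage).
#' @param assortment probability a female mates homotypically (default
#'   0.805, i.e. 19.5% heterotypic matings in expectation).
#' @param paternity_loci,paternity_alleles,fry_per_brood brood screening
#'   design (5 loci, 8 alleles per locus, 8 fry per brood).
#' @param seed integer seed.
#' @return validated list of class `genetic_sim_config`.
#' @export
genetic_sim_config <- function(n_per_haplogroup = 105L, seq_length = 403L,
                               divergence_sites = 10L,
                               private_mutation_rate = 1.5,
                               dirty_column_rate = 0.115,
                               motif = "GTTAAC", motif_group = "LMC",
                               n_pops = 4L, n_per_pop = 50L, n_loci = 7L,
                               n_alleles = 8L, target_fst = 0.1,
                               n_replicates = 4L,
                               females_per_lineage = 6L,
                               males_per_lineage = 3L, assortment = 0.805,
                               paternity_loci = 5L,
                               paternity_alleles = 8L,
                               fry_per_brood = 8L, seed = 1L) {
  cfg <- list(n_per_haplogroup = as.integer(n_per_haplogroup),
              seq_length = as.integer(seq_length),
              divergence_sites = as.integer(divergence_sites),
              private_mutation_rate = private_mutation_rate,
              dirty_column_rate = dirty_column_rate,
              motif = toupper(motif), motif_group = motif_group,
              n_pops = as.integer(n_pops), n_per_pop = as.integer(n_per_pop),
              n_loci = as.integer(n_loci), n_alleles = as.integer(n_alleles),
              target_fst = target_fst,
              n_replicates = as.integer(n_replicates),
              females_per_lineage = as.integer(females_per_lineage),
              males_per_lineage = as.integer(males_per_lineage),
              assortment = assortment,
              paternity_loci = as.integer(paternity_loci),
              paternity_alleles = as.integer(paternity_alleles),
              fry_per_brood = as.integer(fry_per_brood),
              seed = as.integer(seed))
  if (cfg$assortment < 0 || cfg$assortment > 1)
    stop("'assortment' must be a probability in [0, 1]")
  if (cfg$dirty_column_rate < 0 || cfg$dirty_column_rate > 0.8)
    stop("'dirty_column_rate' must lie in [0, 0.8]")
  if (cfg$target_fst <= 0 || cfg$target_fst >= 1)
    stop("'target_fst' must lie strictly in (0, 1)")
  if (cfg$divergence_sites < 1L) stop("'divergence_sites' must be >= 1")
  if (cfg$seq_length < cfg$divergence_sites + nchar(cfg$motif) + 10L)
    stop("'seq_length' too short for the requested divergence and motif")
  if (cfg$private_mutation_rate < 0)
    stop("'private_mutation_rate' must be non-negative")
  counts <- c(cfg$n_per_haplogroup, cfg$n_pops, cfg$n_per_pop, cfg$n_loci,
              cfg$n_alleles, cfg$n_replicates, cfg$females_per_lineage,
              cfg$males_per_lineage, cfg$paternity_loci,
              cfg$paternity_alleles, cfg$fry_per_brood)
  if (any(counts < 1L)) stop("all design counts must be positive")
  structure(cfg, class = "genetic_sim_config")
}

.BASES <- c("A", "C", "G", "T")

.mutate_base <- function(b) sample(setdiff(.BASES, b), 1L)

#' Generate a two-haplogroup mtDNA control-region alignment
#'
#' Two ancestral sequences differ at `divergence_sites` fixed positions;
#' the `motif_group` ancestor carries the intact diagnostic restriction
#' motif while the other ancestor differs inside it (one of the fixed
#' differences). Individuals accumulate Poisson-distributed private
#' mutations outside the motif window; a fraction of columns is then
#' seeded with gaps/ambiguities in some records, emulating the raw
#' alignment before site filtering. Individuals whose private mutations
#' would create or destroy a motif occurrence are redrawn (bounded
#' retries).
#'
#' @param cfg a [genetic_sim_config()].
#' @return list with `alignment` (a [dna_alignment()]) and `truth`
#'   (haplogroup per record, the two ancestors, motif position, dirty
#'   columns).
#' @export
gen_sequences <- function(cfg = genetic_sim_config()) {
  stopifnot(inherits(cfg, "genetic_sim_config"))
  set.seed(cfg$seed + 1L)
  L <- cfg$seq_length
  w <- nchar(cfg$motif)
  motif_chars <- strsplit(cfg$motif, "")[[1L]]

  for (attempt in seq_len(50L)) {
    anc_cut <- sample(.BASES, L, replace = TRUE)
    pos <- sample(seq_len(L - w + 1L), 1L)
    win <- pos:(pos + w - 1L)
    anc_cut[win] <- motif_chars
    ## ancestor must carry the motif exactly once
    if (length(gregexpr(cfg$motif, paste0(anc_cut, collapse = ""),
                        fixed = TRUE)[[1L]]) != 1L) next
    anc_uncut <- anc_cut
    broken <- sample(win, 1L)
    anc_uncut[broken] <- .mutate_base(anc_uncut[broken])
    extra <- sample(setdiff(seq_len(L), win), cfg$divergence_sites - 1L)
    for (s in extra) anc_uncut[s] <- .mutate_base(anc_uncut[s])
    if (!grepl(cfg$motif, paste0(anc_uncut, collapse = ""), fixed = TRUE))
      break
    if (attempt == 50L)
      stop("could not place a unique diagnostic motif; relax the config")
  }
  groups <- c("LMC", "SEC")
  cut_group <- cfg$motif_group
  uncut_group <- setdiff(groups, cut_group)
  ancestors <- list(anc_cut, anc_uncut)
  names(ancestors) <- c(cut_group, uncut_group)
  fixed_sites <- which(anc_cut != anc_uncut)

  n <- cfg$n_per_haplogroup
  free_sites <- setdiff(seq_len(L), union(win, fixed_sites))
  ## control-region variation is concentrated at hypervariable sites:
  ## each haplogroup mutates within its own small site pool, with a fixed
  ## alternative base per site, so haplotypes recur across individuals
  pool_size <- min(25L, length(free_sites) %/% 2L)
  pools <- list(sample(free_sites, pool_size))
  pools[[2L]] <- sample(setdiff(free_sites, pools[[1L]]), pool_size)
  names(pools) <- c(cut_group, uncut_group)
  alt_base <- vapply(seq_len(L), function(p)
    .mutate_base(anc_cut[p]), "")
  records <- matrix("", 2L * n, L)
  hg <- rep(c(cut_group, uncut_group), each = n)
  ids <- sprintf("%s_%03d", hg, c(seq_len(n), seq_len(n)))
  for (i in seq_len(2L * n)) {
    anc <- ancestors[[hg[i]]]
    pool <- pools[[hg[i]]]
    for (try in seq_len(20L)) {
      s <- anc
      nm <- stats::rpois(1L, cfg$private_mutation_rate)
      if (nm > 0L) {
        at <- sample(pool, min(nm, length(pool)))
        s[at] <- alt_base[at]
      }
      hits <- gregexpr(cfg$motif, paste0(s, collapse = ""),
                       fixed = TRUE)[[1L]]
      n_hits <- if (hits[1L] == -1L) 0L else length(hits)
      want <- if (hg[i] == cut_group) 1L else 0L
      if (n_hits == want) break
      if (try == 20L) s <- anc  # fall back to the unmutated ancestor
    }
    records[i, ] <- s
  }
  rownames(records) <- ids

  ## seed gap/ambiguity columns outside the motif window and fixed sites
  protected <- union(win, fixed_sites)
  eligible <- setdiff(seq_len(L), protected)
  n_dirty <- round(cfg$dirty_column_rate * L)
  dirty <- sort(sample(eligible, min(n_dirty, length(eligible))))
  for (col in dirty) {
    n_aff <- max(1L, stats::rbinom(1L, 2L * n, 0.05))
    rows <- sample(2L * n, n_aff)
    records[rows, col] <- sample(c("-", "N", "R", "Y"), n_aff,
                                 replace = TRUE,
                                 prob = c(0.5, 0.3, 0.1, 0.1))
  }
  list(alignment = dna_alignment(records),
       truth = list(haplogroup = stats::setNames(hg, ids),
                    ancestors = lapply(ancestors, paste0, collapse = ""),
                    motif_position = pos, motif_group = cut_group,
                    fixed_sites = fixed_sites, dirty_columns = dirty))
}

## Dirichlet draw via gamma variates
.rdirichlet <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha)
  if (sum(x) == 0) x <- rep(1, length(alpha))
  x / sum(x)
}

#' Generate structured microsatellite genotypes (Balding-Nichols)
#'
#' Each locus draws ancestral allele frequencies from a flat Dirichlet;
#' population frequencies are Dirichlet-distributed around them with
#' concentration `(1 - F)/F`, so allele-frequency variance among
#' populations matches a target FST of `F`. Diploid genotypes are drawn
#' allele-wise from the population frequencies.
#'
#' @param cfg a [genetic_sim_config()].
#' @return list with `genotypes` (a [genotype_matrix()]) and `truth`
#'   (ancestral and realized per-population allele frequencies, target
#'   FST).
#' @export
gen_genotypes <- function(cfg = genetic_sim_config()) {
  stopifnot(inherits(cfg, "genetic_sim_config"))
  set.seed(cfg$seed + 2L)
  P <- cfg$n_pops; n <- cfg$n_per_pop
  L <- cfg$n_loci; A <- cfg$n_alleles
  F <- cfg$target_fst
  pops <- paste0("pop", seq_len(P))
  a1 <- a2 <- matrix(NA_integer_, P * n, L)
  anc <- pop_freqs <- vector("list", L)
  for (l in seq_len(L)) {
    p0 <- .rdirichlet(rep(1, A))
    anc[[l]] <- p0
    pf <- matrix(0, P, A)
    for (pp in seq_len(P))
      pf[pp, ] <- .rdirichlet(p0 * (1 - F) / F)
    pop_freqs[[l]] <- pf
    for (pp in seq_len(P)) {
      rows <- ((pp - 1L) * n + 1L):(pp * n)
      a1[rows, l] <- sample.int(A, n, replace = TRUE, prob = pf[pp, ])
      a2[rows, l] <- sample.int(A, n, replace = TRUE, prob = pf[pp, ])
    }
  }
  g <- genotype_matrix(a1, a2, pop = rep(pops, each = n),
                       loci = paste0("msat", seq_len(L)))
  list(genotypes = g,
       truth = list(ancestral_freqs = anc, pop_freqs = pop_freqs,
                    target_fst = F))
}

.uniform_genotype <- function(loci, n_alleles) {
  matrix(sample.int(n_alleles, 2L * length(loci), replace = TRUE),
         length(loci), 2L, dimnames = list(loci, NULL))
}

#' Generate a mate-choice experiment with Mendelian broods
#'
#' Emulates the partial-partition free-choice design: in each replicate,
#' females of two lineages choose among compartment-bound males of both
#' lineages. A female mates homotypically with probability `assortment`;
#' the sire is drawn uniformly within the chosen lineage. Each brood's
#' sampled fry inherit one maternal and one paternal allele per locus.
#' Adult genotypes are drawn with uniform allele frequencies.
#'
#' @param cfg a [genetic_sim_config()].
#' @return list with `replicates` (per replicate: `broods` list of
#'   [brood()] objects, `candidates` named list of genotypes,
#'   `candidate_lineages`) and `truth` (data.frame of brood_id, replicate,
#'   true father, homotypic flag).
#' @export
gen_matechoice <- function(cfg = genetic_sim_config()) {
  stopifnot(inherits(cfg, "genetic_sim_config"))
  set.seed(cfg$seed + 3L)
  loci <- if (cfg$paternity_loci == 5L)
    c("Pzeb5", "UNH154", "TMOM5", "TMOM11", "Ppun21")
  else paste0("L", seq_len(cfg$paternity_loci))
  lineages <- c("Salima", "Ruvuma")
  reps <- vector("list", cfg$n_replicates)
  truth_rows <- list()
  for (r in seq_len(cfg$n_replicates)) {
    male_lin <- rep(lineages, each = cfg$males_per_lineage)
    male_ids <- sprintf("rep%d_M%d", r, seq_along(male_lin))
    candidates <- stats::setNames(
      lapply(seq_along(male_ids), function(i)
        .uniform_genotype(loci, cfg$paternity_alleles)), male_ids)
    cand_lin <- stats::setNames(male_lin, male_ids)
    broods <- list()
    for (f in seq_len(2L * cfg$females_per_lineage)) {
      fem_lin <- lineages[(f - 1L) %/% cfg$females_per_lineage + 1L]
      mother_id <- sprintf("rep%d_F%d", r, f)
      mother <- .uniform_genotype(loci, cfg$paternity_alleles)
      homo <- stats::runif(1L) < cfg$assortment
      sire_lin <- if (homo) fem_lin else setdiff(lineages, fem_lin)
      sire <- sample(male_ids[cand_lin == sire_lin], 1L)
      fry <- lapply(seq_len(cfg$fry_per_brood), function(i) {
        f1 <- mother[cbind(seq_along(loci),
                           sample(1:2, length(loci), replace = TRUE))]
        f2 <- candidates[[sire]][cbind(seq_along(loci),
                                       sample(1:2, length(loci),
                                              replace = TRUE))]
        matrix(c(f1, f2), length(loci), 2L, dimnames = list(loci, NULL))
      })
      bid <- sprintf("rep%d_B%d", r, f)
      broods[[bid]] <- brood(bid, mother_id, mother, fry,
                             replicate_id = paste0("rep", r),
                             mother_lineage = fem_lin)
      truth_rows[[length(truth_rows) + 1L]] <-
        data.frame(brood_id = bid, replicate = paste0("rep", r),
                   true_father = sire, homotypic = homo)
    }
    reps[[r]] <- list(broods = broods, candidates = candidates,
                      candidate_lineages = cand_lin)
  }
  names(reps) <- paste0("rep", seq_len(cfg$n_replicates))
  list(replicates = reps, truth = do.call(rbind, truth_rows))
}
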