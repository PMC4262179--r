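## stage-level orchestration: each run_* function reads standard input
## files, runs the corresponding analysis chain, writes delimited outputs
## plus a JSON provenance record, and returns its results invisibly.

.log <- function(verbose, ...) if (verbose) message("[contactzone] ", ...)

.provenance <- function(out_dir, stage, params, files) {
  rec <- list(stage = stage, params = params,
              package_version = as.character(utils::packageVersion("contactzone")),
              r_version = R.version.string,
              timestamp = format(Sys.time(), tz = "UTC"),
              outputs = as.list(tools::md5sum(files)))
  jsonlite::write_json(rec, file.path(out_dir, paste0(stage, "_run.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Write mate-choice input tables
#'
#' Serialises the broods and candidate fathers of a [gen_matechoice()]
#' experiment as two delimited files: `candidates` (replicate, id,
#' lineage, two columns per locus) and `broods` (replicate, brood_id,
#' role mother/fry, id, lineage, two columns per locus).
#'
#' @param experiment the `replicates` element of a [gen_matechoice()]
#'   result (or an equivalently shaped list).
#' @param broods_path,candidates_path output paths.
#' @export
write_matechoice_tables <- function(experiment, broods_path,
                                    candidates_path) {
  loci <- rownames(experiment[[1L]]$broods[[1L]]$mother)
  allele_cols <- function(geno) {
    v <- as.vector(t(geno))
    stats::setNames(as.list(v),
                    paste0(rep(loci, each = 2L), c("_1", "_2")))
  }
  cand_rows <- list()
  brood_rows <- list()
  for (rep_name in names(experiment)) {
    rep <- experiment[[rep_name]]
    for (mid in names(rep$candidates))
      cand_rows[[length(cand_rows) + 1L]] <- data.frame(
        replicate = rep_name, id = mid,
        lineage = unname(rep$candidate_lineages[mid]),
        allele_cols(rep$candidates[[mid]]))
    for (b in rep$broods) {
      brood_rows[[length(brood_rows) + 1L]] <- data.frame(
        replicate = rep_name, brood_id = b$brood_id, role = "mother",
        id = b$mother_id, lineage = b$mother_lineage,
        allele_cols(b$mother))
      for (fi in seq_along(b$fry))
        brood_rows[[length(brood_rows) + 1L]] <- data.frame(
          replicate = rep_name, brood_id = b$brood_id, role = "fry",
          id = paste0(b$brood_id, "_fry", fi), lineage = NA,
          allele_cols(b$fry[[fi]]))
    }
  }
  utils::write.table(do.call(rbind, cand_rows), candidates_path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(do.call(rbind, brood_rows), broods_path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(broods_path, candidates_path))
}

#' Read mate-choice input tables
#'
#' Inverse of [write_matechoice_tables()].
#'
#' @param broods_path,candidates_path paths written by
#'   [write_matechoice_tables()].
#' @return list shaped like the `replicates` element of
#'   [gen_matechoice()].
#' @export
read_matechoice_tables <- function(broods_path, candidates_path) {
  cand <- utils::read.table(candidates_path, header = TRUE,
                            check.names = FALSE)
  brd <- utils::read.table(broods_path, header = TRUE, check.names = FALSE)
  acols <- grep("_[12]$", names(cand), value = TRUE)
  loci <- unique(sub("_[12]$", "", acols))
  geno_of <- function(row) {
    m <- matrix(as.integer(row[paste0(rep(loci, each = 2L), c("_1", "_2"))]),
                length(loci), 2L, byrow = TRUE,
                dimnames = list(loci, NULL))
    m
  }
  out <- list()
  for (rep_name in unique(cand$replicate)) {
    cr <- cand[cand$replicate == rep_name, , drop = FALSE]
    candidates <- stats::setNames(
      lapply(seq_len(nrow(cr)), function(i)
        geno_of(unlist(cr[i, ]))), cr$id)
    cand_lin <- stats::setNames(cr$lineage, cr$id)
    br <- brd[brd$replicate == rep_name, , drop = FALSE]
    broods <- list()
    for (bid in unique(br$brood_id)) {
      bb <- br[br$brood_id == bid, , drop = FALSE]
      mrow <- bb[bb$role == "mother", , drop = FALSE]
      frows <- bb[bb$role == "fry", , drop = FALSE]
      broods[[bid]] <- brood(
        bid, mrow$id[1L], geno_of(unlist(mrow[1L, ])),
        lapply(seq_len(nrow(frows)), function(i)
          geno_of(unlist(frows[i, ]))),
        replicate_id = rep_name, mother_lineage = mrow$lineage[1L])
    }
    out[[rep_name]] <- list(broods = broods, candidates = candidates,
                            candidate_lineages = cand_lin)
  }
  out
}

#' Generate a full synthetic input directory
#'
#' Runs every synthetic generator and writes the files the analysis stages
#' read: a TPS landmark file with a group sidecar, an aligned FASTA of
#' control-region sequences, a microsatellite genotype table, and the
#' mate-choice brood/candidate tables, together with a ground-truth JSON
#' and a manifest of file checksums.
#'
#' @param out_dir run directory (created if missing).
#' @param morpho_cfg a [morpho_sim_config()].
#' @param genetic_cfg a [genetic_sim_config()].
#' @param seed optional master seed overriding both configs' seeds.
#' @param verbose narrate stage boundaries.
#' @return invisibly, a named vector of the files written.
#' @export
run_simulate <- function(out_dir, morpho_cfg = morpho_sim_config(),
                         genetic_cfg = genetic_sim_config(), seed = NULL,
                         verbose = FALSE) {
  if (!is.null(seed)) {
    morpho_cfg$seed <- as.integer(seed)
    genetic_cfg$seed <- as.integer(seed)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(tps = file.path(out_dir, "landmarks.tps"),
             groups = file.path(out_dir, "groups.tsv"),
             fasta = file.path(out_dir, "sequences.fasta"),
             genotypes = file.path(out_dir, "genotypes.tsv"),
             broods = file.path(out_dir, "broods.tsv"),
             candidates = file.path(out_dir, "candidates.tsv"),
             truth = file.path(out_dir, "truth.json"))

  .log(verbose, "simulating landmarks (", morpho_cfg$k, " landmarks)")
  lm <- gen_landmarks(morpho_cfg)
  write_tps(lm$dataset, files["tps"])
  write_group_map(lm$truth$groups, files["groups"])

  .log(verbose, "simulating mtDNA alignment")
  sq <- gen_sequences(genetic_cfg)
  write_alignment(sq$alignment, files["fasta"])

  .log(verbose, "simulating microsatellite genotypes")
  gt <- gen_genotypes(genetic_cfg)
  write_genotypes(gt$genotypes, files["genotypes"])

  .log(verbose, "simulating mate-choice broods")
  mc <- gen_matechoice(genetic_cfg)
  write_matechoice_tables(mc$replicates, files["broods"],
                          files["candidates"])

  truth <- list(
    morpho = list(seed = morpho_cfg$seed,
                  hybrid_transgression = morpho_cfg$hybrid_transgression,
                  divergence = morpho_cfg$divergence),
    sequences = list(haplogroup = as.list(sq$truth$haplogroup),
                     motif_group = sq$truth$motif_group,
                     motif_position = sq$truth$motif_position),
    genotypes = list(target_fst = gt$truth$target_fst),
    matechoice = mc$truth,
    seeds = list(morpho = morpho_cfg$seed, genetic = genetic_cfg$seed))
  jsonlite::write_json(truth, files["truth"], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  .provenance(out_dir, "simulate",
              list(morpho_seed = morpho_cfg$seed,
                   genetic_seed = genetic_cfg$seed), files)
  invisible(files)
}

#' Morphometric stage: landmarks to transgression table
#'
#' Reads a TPS file and its group sidecar, runs Procrustes alignment,
#' relative warps and centroid-size correction, then bootstraps the
#' range-extension statistic for every hybrid cross on the leading axes.
#' Writes a scores table, the long-format transgression results and the
#' wide (axes x crosses) presentation with significance stars.
#'
#' @param tps_path TPS landmark file.
#' @param groups_path two-column specimen-to-group sidecar.
#' @param out_dir output directory.
#' @param hybrid_groups,parent_groups group labels (defaults match the
#'   synthetic common-garden design).
#' @param axes,B,n,seed transgression-test parameters
#'   (see [transgression_table()]).
#' @param verbose narrate stages.
#' @return invisibly, a list with `gpa`, `space`, `corrected` and `table`.
#' @export
run_morpho <- function(tps_path, groups_path, out_dir,
                       hybrid_groups = c("F1", "backcrossA",
                                         "backcrossB", "F2"),
                       parent_groups = c("parentA", "parentB"),
                       axes = 1:6, B = 500L, n = 50L, seed = 1L,
                       verbose = FALSE) {
  if (!file.exists(groups_path))
    stop("morpho stage: group sidecar not found: ", groups_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  .log(verbose, "reading TPS landmarks")
  dataset <- read_tps(tps_path, group_map = groups_path)
  if (is.null(dataset$groups))
    stop("morpho stage: no group labels available")
  .log(verbose, "Procrustes alignment of ", dataset$n, " specimens")
  fit <- gpa(dataset)
  space <- relative_warps(fit)
  .log(verbose, "variance captured on first axes: ",
       paste(round(100 * space$variance_fraction[
         seq_len(min(6L, length(space$variance_fraction)))], 1),
         collapse = "/"), " %")
  corrected <- allometry_residuals(space, fit$centroid_sizes)
  groups <- unname(dataset$groups[dataset$specimen_ids])
  tab <- transgression_table(corrected, groups, hybrid_groups,
                             parent_groups, axes = axes, B = B, n = n,
                             seed = seed)
  files <- c(scores = file.path(out_dir, "scores.tsv"),
             long = file.path(out_dir, "transgression_long.tsv"),
             wide = file.path(out_dir, "transgression_table.tsv"))
  write_scores(corrected, files["scores"], groups = dataset$groups)
  utils::write.table(tab, files["long"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(format_transgression_table(tab), files["wide"],
                     sep = "\t", quote = FALSE, col.names = NA)
  .provenance(out_dir, "morpho",
              list(B = B, n = n, seed = seed,
                   axes = paste(axes, collapse = ","),
                   variance_fraction = unname(space$variance_fraction[
                     seq_len(min(6L, length(space$variance_fraction)))]),
                   gpa_iterations = fit$iterations), files)
  invisible(list(gpa = fit, space = space, corrected = corrected,
                 table = tab))
}

#' Population-genetics stage: alignment and genotypes to network and FST
#'
#' Filters gapped/ambiguous sites, collapses haplotypes, builds the
#' minimum-spanning haplotype network, screens each raw sequence with the
#' diagnostic restriction motif, and computes pairwise Weir-Cockerham FST
#' with permutation p-values for all population pairs.
#'
#' @param fasta_path aligned FASTA of control-region sequences.
#' @param genotype_path genotype table readable by [read_genotypes()] (or
#'   a Genepop file; detected by extension `.gen`).
#' @param out_dir output directory.
#' @param motif diagnostic restriction motif (default HpaI, GTTAAC).
#' @param n_perm permutations per population pair.
#' @param seed integer seed for the permutation tests.
#' @param verbose narrate stages.
#' @return invisibly, a list with `haplotypes`, `network`, `rflp`, `fst`.
#' @export
run_popgen <- function(fasta_path, genotype_path, out_dir,
                       motif = "GTTAAC", n_perm = 1000L, seed = 1L,
                       verbose = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  .log(verbose, "reading alignment")
  aln <- read_alignment(fasta_path)
  filtered <- filter_alignment_sites(aln)
  .log(verbose, "site filtering: ", aln$length, " -> ", filtered$length,
       " bp (", attr(filtered, "removed_sites"), " columns removed)")
  haps <- collapse_haplotypes(filtered)
  .log(verbose, nrow(filtered$seqs), " records -> ",
       length(haps$haplotypes), " haplotypes")
  d <- pairwise_differences(haps)
  net <- build_msn(d, haps$counts)
  rflp <- rflp_screen(aln, site = motif)

  g <- if (grepl("\\.gen$", genotype_path)) read_genepop(genotype_path)
       else read_genotypes(genotype_path)
  .log(verbose, "pairwise FST over ", length(unique(g$pop)),
       " populations (", n_perm, " permutations)")
  fst <- pairwise_fst(g, n_perm = n_perm, seed = seed)

  files <- c(haplotypes = file.path(out_dir, "haplotypes.tsv"),
             dist = file.path(out_dir, "haplotype_distances.tsv"),
             edges = file.path(out_dir, "network_edges.tsv"),
             alt = file.path(out_dir, "network_alternative_edges.tsv"),
             rflp = file.path(out_dir, "rflp_assignments.tsv"),
             fst = file.path(out_dir, "fst.tsv"))
  utils::write.table(
    data.frame(haplotype = names(haps$haplotypes), count = haps$counts,
               sequence = unname(haps$haplotypes)),
    files["haplotypes"], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(d, files["dist"], sep = "\t", quote = FALSE,
                     col.names = NA)
  utils::write.table(net$edges, files["edges"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(net$alternative_edges, files["alt"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(id = names(rflp), assignment = unname(rflp)),
    files["rflp"], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(fst, files["fst"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  .provenance(out_dir, "popgen",
              list(motif = motif, n_perm = n_perm, seed = seed,
                   alignment_columns = aln$length,
                   filtered_columns = filtered$length,
                   n_haplotypes = length(haps$haplotypes)), files)
  invisible(list(haplotypes = haps, network = net, rflp = rflp,
                 fst = fst))
}

#' Mate-choice stage: broods to per-replicate binomial tests
#'
#' Assigns each brood's sire by genotypic exclusion against the
#' replicate's candidate males, tallies homotypic versus heterotypic
#' matings per replicate, and tests assortative preference with one-sided
#' exact binomial tests.
#'
#' @param broods_path,candidates_path tables written by
#'   [write_matechoice_tables()].
#' @param out_dir output directory.
#' @param mismatch_tolerance passed to [assign_paternity()].
#' @param p0 null heterotypic probability (default 0.5).
#' @param verbose narrate stages.
#' @return invisibly, a list with `records` (all mating records) and
#'   `tests` (per-replicate and pooled tallies with p-values).
#' @export
run_matechoice <- function(broods_path, candidates_path, out_dir,
                           mismatch_tolerance = 0L, p0 = 0.5,
                           verbose = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  .log(verbose, "reading mate-choice tables")
  experiment <- read_matechoice_tables(broods_path, candidates_path)
  records <- list()
  for (rep_name in names(experiment)) {
    rep <- experiment[[rep_name]]
    for (b in rep$broods)
      records[[length(records) + 1L]] <-
        assign_paternity(b, rep$candidates, rep$candidate_lineages,
                         mismatch_tolerance = mismatch_tolerance)
  }
  records <- do.call(rbind, records)
  .log(verbose, sum(records$status == "assigned"), " of ",
       nrow(records), " records assigned a sire")
  tests <- assortment_tests(tally_matings(records), p0 = p0)
  files <- c(records = file.path(out_dir, "mating_records.tsv"),
             tests = file.path(out_dir, "assortment_tests.tsv"))
  utils::write.table(records, files["records"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(tests, files["tests"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  .provenance(out_dir, "matechoice",
              list(mismatch_tolerance = mismatch_tolerance, p0 = p0),
              files)
  invisible(list(records = records, tests = tests))
}
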