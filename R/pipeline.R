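#' Assemble a pipeline configuration
#'
#' Collects file paths, QC thresholds, the focal-locus specification, group
#' roles and model settings for [run_pipeline()]. Groups are the labels in
#' the metadata `group` column; `scan_groups` names the two compared in the
#' F_ST scan (pre- and post-selection).
#'
#' @param ped,map,meta Paths to the PED, MAP and metadata TSV files.
#' @param focal List `(chrom, pos_bp)` of the focal locus.
#' @param scan_groups Character vector of length 2: the cohorts compared.
#' @param qc List of QC thresholds (`geno_max`, `mind_max`, `maf_min`,
#'   `king_cutoff`).
#' @param drift_models List of drift models, each a list with `name`, `ne`,
#'   `male_fraction`, `generations`, `replicates`; `q_start_year` picks the
#'   trend year whose frequency seeds the null.
#' @param q_start_year Birth year whose observed frequency starts the drift
#'   null.
#' @param haplotypes Optional named list (group -> haplotype file path) of
#'   phased 0/1 haplotypes for the EHH stage; files must cover the
#'   chromosome named in `hap_chrom`, columns following the (QC'd) map.
#' @param hap_chrom Chromosome covered by the haplotype files.
#' @param roh List of ROH parameters (see [detect_roh()]).
#' @param top_fraction Upper-tail fraction for [rank_scan()].
#' @param ehh_window_bp EHH half-window (default 1e6).
#' @param ne_maf_floor MAF floor for [ld_ne()].
#' @param seed Root seed; stage seeds are derived as `seed + <stage offset>`
#'   (drift +1, LD-Ne +2) so stages are reproducible in isolation.
#' @param out_dir Optional output directory for the report files.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(ped, map, meta, focal, scan_groups,
                            qc = list(geno_max = 0.01, mind_max = 0.01,
                                      maf_min = 0.01, king_cutoff = 0.176),
                            drift_models = list(list(name = "large", ne = 540,
                                                     male_fraction = 0.2,
                                                     generations = 6,
                                                     replicates = 10000)),
                            q_start_year = NULL,
                            haplotypes = NULL, hap_chrom = NULL,
                            roh = list(min_snp = 41, max_gap = 1e6,
                                       min_length_bp = 5e4,
                                       min_density = 1 / 5000),
                            top_fraction = 0.001, ehh_window_bp = 1e6,
                            ne_maf_floor = 0.01,
                            seed = 20231218, out_dir = NULL) {
  cfg <- list(ped = ped, map = map, meta = meta, focal = focal,
              scan_groups = scan_groups, qc = qc,
              drift_models = drift_models, q_start_year = q_start_year,
              haplotypes = haplotypes, hap_chrom = hap_chrom, roh = roh,
              top_fraction = top_fraction, ehh_window_bp = ehh_window_bp,
              ne_maf_floor = ne_maf_floor, seed = seed, out_dir = out_dir)
  for (f in c("ped", "map", "meta")) {
    if (!file.exists(cfg[[f]])) stop("missing input file: ", cfg[[f]], call. = FALSE)
  }
  stopifnot(length(scan_groups) == 2)
  structure(cfg, class = "pipeline_config")
}

stage_msg <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full monitoring pipeline
#'
#' Fixed stage order: read inputs, QC filter, kinship pruning, genotype
#' trend + drift nulls, F_ST scan (+ EHH when phased haplotypes are
#' supplied), Ho / ROH / F_ROH, PCA / NJ tree / Nei's D / LD-Ne. Each stage
#' logs its sample and SNP counts; a failing stage halts with its name. The
#' run is deterministic given the config seed.
#'
#' @param cfg A [pipeline_config()].
#' @return A `bw_report` list with one element per result block (trend,
#'   drift, fst, ehh, inbreeding, structure, ne, counts). If
#'   `cfg$out_dir` is set, also writes `report.json` and per-block TSV/
#'   Newick files there.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  report <- list(schema = "bw_report/1")

  stage_msg("io", "reading %s", cfg$ped)
  gm <- read_ped_map(cfg$ped, cfg$map)
  meta <- read_cohort_table(cfg$meta)
  groups_present <- table(meta$group)
  if (any(groups_present == 0) || !all(cfg$scan_groups %in% names(groups_present))) {
    stop("stage io: scan group(s) missing or empty in metadata", call. = FALSE)
  }
  stage_msg("io", "%d samples x %d SNPs; %d metadata rows",
            length(gm$samples), nrow(gm$map), nrow(meta))

  gm_qc <- qc_filter(gm, geno_max = cfg$qc$geno_max, mind_max = cfg$qc$mind_max,
                     maf_min = cfg$qc$maf_min)
  qc_log <- attr(gm_qc, "qc_log")
  stage_msg("qc", "%d SNPs retained", nrow(gm_qc$map))

  pruned <- prune_relatives(gm_qc, cutoff = cfg$qc$king_cutoff)
  gm_kept <- subset_geno(gm_qc, samples = pruned$kept)
  stage_msg("kinship", "removed %d close relative(s), %d dogs remain",
            length(pruned$removed), length(pruned$kept))

  meta_kept <- dplyr::filter(meta, .data$id %in% gm_kept$samples)

  # trend + drift
  trend <- trend_ci(build_trend(meta))
  q_start_year <- cfg$q_start_year %||% min(trend$birth_year)
  q0 <- trend$q[trend$birth_year == q_start_year]
  if (length(q0) != 1) stop("stage trend: q_start_year not in trend table", call. = FALSE)
  drift <- purrr::map(cfg$drift_models, function(m) {
    sim <- simulate_drift(ne = m$ne, q_start = q0,
                          male_fraction = m$male_fraction %||% 0.2,
                          generations = m$generations %||% 6,
                          replicates = m$replicates %||% 10000,
                          seed = cfg$seed + 1L)
    obs <- dplyr::filter(trend, .data$birth_year > q_start_year,
                         .data$birth_year <= q_start_year + sim$generations)
    list(model = glance.drift_sim(sim),
         band = tidy.drift_sim(sim),
         p = dplyr::mutate(
           empirical_p(sim, obs$q, obs$birth_year - q_start_year),
           birth_year = obs$birth_year, .before = 1))
  })
  names(drift) <- purrr::map_chr(cfg$drift_models, "name")
  stage_msg("trend", "trend over %d year(s); drift nulls: %s",
            nrow(trend), paste(names(drift), collapse = ", "))

  # F_ST scan
  ids_a <- meta_kept$id[meta_kept$group == cfg$scan_groups[1]]
  ids_b <- meta_kept$id[meta_kept$group == cfg$scan_groups[2]]
  fst <- rank_scan(wc_fst(gm_kept, ids_a, ids_b), cfg$top_fraction)
  top <- attr(fst, "top_snp")
  top_dist <- if (as.character(top$chrom) == as.character(cfg$focal$chrom)) {
    abs(top$pos_bp - cfg$focal$pos_bp)
  } else NA_real_
  stage_msg("fst", "top SNP %s (chrom %s pos %d, fst %.3f), %s bp from focal locus",
            top$id, top$chrom, top$pos_bp, top$fst,
            ifelse(is.na(top_dist), "other-chromosome", format(top_dist)))

  # EHH around the top-ranked SNP of the haplotyped (focal) chromosome
  ehh_curves <- NULL
  if (!is.null(cfg$haplotypes)) {
    on_hap <- dplyr::filter(fst, .data$chrom == as.character(cfg$hap_chrom),
                            !is.na(.data$fst))
    core_id <- on_hap$id[which.max(on_hap$fst)]
    # haplotype files follow the original map; drop columns removed by QC
    hap_map_full <- gm$map[gm$map$chrom == as.character(cfg$hap_chrom), ]
    cols_keep <- hap_map_full$id %in% gm_kept$map$id
    hap_map <- hap_map_full[cols_keep, , drop = FALSE]
    later <- cfg$scan_groups[2]
    h_later <- read_haplotypes(cfg$haplotypes[[later]])[, cols_keep, drop = FALSE]
    core_allele <- default_core_allele(h_later, hap_map, core_id)
    ehh_curves <- purrr::imap_dfr(cfg$haplotypes, function(path, grp) {
      h <- read_haplotypes(path)[, cols_keep, drop = FALSE]
      dplyr::mutate(ehh(h, hap_map, core_id, core_allele, cfg$ehh_window_bp),
                    group = grp, .before = 1)
    })
    stage_msg("ehh", "curves for %d group(s) around %s (core allele %d)",
              length(cfg$haplotypes), core_id, core_allele)
  }

  # inbreeding
  ho <- ho_by_group(gm_kept, meta_kept)
  runs <- detect_roh(gm_kept, min_snp = cfg$roh$min_snp,
                     max_gap = cfg$roh$max_gap,
                     min_length_bp = cfg$roh$min_length_bp,
                     min_density = cfg$roh$min_density)
  froh <- f_roh(runs, gm_kept)
  froh_groups <- froh_group_summary(froh, meta_kept)
  stage_msg("inbreeding", "%d ROH in %d dogs; mean F_ROH %.3f",
            nrow(runs), length(unique(runs$id)), mean(froh$f_roh))

  # structure + Ne
  pca <- pca_genotypes(gm_kept)
  tree <- nj_tree(p_distance_matrix(gm_kept))
  nei <- neis_d_matrix(gm_kept, meta_kept)
  ne <- ld_ne_by_group(gm_kept, meta_kept, maf_floor = cfg$ne_maf_floor,
                       seed = cfg$seed + 2L)
  stage_msg("structure", "PCA, NJ tree (%d tips), Nei's D (%d groups), LD-Ne (%d group(s))",
            length(tree$tip.label), nrow(nei), nrow(ne))

  report <- c(report, list(
    counts = list(qc = qc_log,
                  pruned = length(pruned$removed),
                  samples_final = length(gm_kept$samples),
                  snps_final = nrow(gm_kept$map)),
    trend = trend,
    drift = drift,
    fst = list(scan = fst, top_snp = top, top_snp_focal_dist_bp = top_dist,
               threshold = attr(fst, "threshold")),
    ehh = ehh_curves,
    inbreeding = list(ho = ho, roh = runs, f_roh = froh,
                      groups = froh_groups),
    structure = list(pca = tidy.geno_pca(pca),
                     pca_var = pca$var_explained,
                     tree_newick = ape::write.tree(tree),
                     neis_d = nei),
    ne = ne,
    seed = cfg$seed))
  class(report) <- "bw_report"

  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

#' @export
print.bw_report <- function(x, ...) {
  cat("<bw_report>", x$schema, "\n")
  cat(sprintf("  %d dogs, %d SNPs after QC/pruning\n",
              x$counts$samples_final, x$counts$snps_final))
  cat(sprintf("  top F_ST SNP: %s (fst %.3f)\n", x$fst$top_snp$id, x$fst$top_snp$fst))
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' `report.json` holds the full report; the main tables are also written as
#' TSVs and the NJ tree as Newick.
#'
#' @param report A `bw_report`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the directory path.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(unclass(report), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, matrix = "rowmajor",
                       force = TRUE, na = "null")
  readr::write_tsv(report$trend, file.path(out_dir, "trend.tsv"))
  readr::write_tsv(report$fst$scan, file.path(out_dir, "fst.tsv"))
  if (!is.null(report$ehh)) readr::write_tsv(report$ehh, file.path(out_dir, "ehh.tsv"))
  readr::write_tsv(report$inbreeding$roh, file.path(out_dir, "roh.tsv"))
  readr::write_tsv(report$inbreeding$f_roh, file.path(out_dir, "f_roh.tsv"))
  readr::write_tsv(report$structure$pca, file.path(out_dir, "pca.tsv"))
  writeLines(report$structure$tree_newick, file.path(out_dir, "tree.nwk"))
  if (nrow(report$ne)) readr::write_tsv(report$ne, file.path(out_dir, "ne.tsv"))
  invisible(out_dir)
}

#' Default end-to-end selection scenario
#'
#' The reference synthetic scenario for validating the whole analysis chain:
#' a closed breed of 200 founders genotyped at 4,000 SNPs on two 63 Mb
#' autosomes, mutant allele starting near 0.5, and a fully-complied
#' clear-sires + cull regime from 2019. [selection_replicate()] runs one
#' seeded replicate: it simulates the scenario, compares a pre-selection
#' (2017) and a post-selection (2022) birth cohort with the Weir-Cockerham
#' scan, and tests the observed allele decline against a drift null built
#' from the realized breeding census.
#'
#' @return A `sim_config`.
#' @export
selection_scenario_config <- function() {
  sim_config(n_founders = 200, n_snps = 4000, n_chroms = 2,
             ancestral_pool = 10, founder_mosaic_segments = 8,
             focal = list(chrom = 1, pos_bp = 2.6e7, q0 = 0.5),
             years = c(2016, 2022), selection_start_year = 2019,
             selection_policy = "clear_sires_cull",
             policy_compliance = 1, male_fraction_breeding = 0.3,
             max_litters_per_year = 60, recruits_per_year = 0)
}

#' @rdname selection_scenario_config
#' @param seed Integer seed for the replicate.
#' @param n_sample Dogs sampled per birth cohort for the scan (default 90).
#' @param top_fraction Upper-tail fraction flagged in the scan.
#' @param drift_replicates Trajectories in the drift null.
#' @return `selection_replicate`: one-row tibble with `q_pre` and `q_post`
#'   (focal allele frequency in the 2017/2022 cohorts), `ne_census`
#'   (realized breeding census behind the drift null), `drift_p` (lower-tail
#'   empirical p of the observed decline), `top_fst`, `focal_fst`,
#'   `focal_hit` (TRUE if a flagged SNP lies within 1 Mb of the focal
#'   locus).
#' @export
selection_replicate <- function(seed, n_sample = 90, top_fraction = 0.001,
                                drift_replicates = 2000) {
  cfg <- selection_scenario_config()
  pop <- breed_forward(simulate_founders(cfg, seed = seed), seed = seed + 10000L)
  ped <- pop$pedigree
  set.seed(seed + 20000L)
  pick <- function(yr) {
    ids <- ped$id[ped$birth_year == yr]
    sort(ids[sample.int(length(ids), min(n_sample, length(ids)))])
  }
  pre <- pick(2017); post <- pick(2022)
  gm <- as_geno_matrix(pop, ids = c(pre, post))
  scan <- rank_scan(wc_fst(gm, paste0("dog", pre), paste0("dog", post)),
                    top_fraction)
  flagged <- dplyr::filter(scan, .data$flagged)
  focal_hit <- any(flagged$chrom == as.character(cfg$focal$chrom) &
                     abs(flagged$pos_bp - cfg$focal$pos_bp) <= 1e6)
  # drift null sized from the realized breeding census of the policy years
  par_year <- function(y) {
    k <- ped[!is.na(ped$sire) & ped$birth_year == y, ]
    c(length(unique(k$sire)), length(unique(k$dam)))
  }
  pm <- rowMeans(vapply(2019:2022, par_year, numeric(2)))
  q <- focal_freq_by_year(pop)
  q_pre <- q$q[q$birth_year == 2017]
  q_post <- q$q[q$birth_year == 2022]
  drift <- simulate_drift(ne = round(sum(pm)), q_start = q_pre,
                          male_fraction = pm[1] / sum(pm), generations = 5,
                          replicates = drift_replicates, seed = seed + 30000L)
  p <- empirical_p(drift, q_post, 5)$p_value
  tibble::tibble(seed = seed, q_pre = q_pre, q_post = q_post,
                 ne_census = round(sum(pm)), drift_p = p,
                 top_fst = max(scan$fst, na.rm = TRUE),
                 focal_fst = scan$fst[scan$chrom == as.character(cfg$focal$chrom) &
                                        scan$pos_bp == cfg$focal$pos_bp],
                 focal_hit = focal_hit)
}
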