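test_that("WC F_ST matches the hand-derived variance components", {
  # fixed difference between the groups: a = 0.5, b = c = 0, fst = 1
  gm <- gm_from_calls(rbind(matrix(2L, 10, 1), matrix(0L, 10, 1)))
  res <- wc_fst(gm, gm$samples[1:10], gm$samples[11:20])
  expect_equal(res$a, 0.5)
  expect_equal(res$b, 0)
  expect_equal(res$c, 0)
  expect_equal(res$fst, 1)

  # everyone heterozygous in both groups: a = 0, c = 0.5, fst = 0 exactly
  gm2 <- gm_from_calls(matrix(1L, 20, 1))
  res2 <- wc_fst(gm2, gm2$samples[1:10], gm2$samples[11:20])
  expect_equal(res2$a, 0)
  expect_equal(res2$c, 0.5)
  expect_equal(res2$fst, 0)

  # monomorphic SNP is undefined
  gm3 <- gm_from_calls(matrix(0L, 20, 1))
  expect_true(is.na(wc_fst(gm3, gm3$samples[1:10], gm3$samples[11:20])$fst))
})

test_that("WC F_ST is symmetric under group swap and allele relabelling", {
  gm <- gm_hwe(40, 200, p = runif(200, 0.1, 0.9), seed = 31)
  a <- gm$samples[1:20]; b <- gm$samples[21:40]
  f1 <- wc_fst(gm, a, b)
  f2 <- wc_fst(gm, b, a)
  expect_equal(f1$fst, f2$fst)

  flipped <- geno_matrix(2L - gm$calls, gm$map, gm$samples)
  f3 <- wc_fst(flipped, a, b)
  expect_equal(f1$fst, f3$fst)
})

test_that("random split of a panmictic population has mean F_ST near zero", {
  set.seed(32)
  gm <- gm_hwe(60, 1000, p = runif(1000, 0.1, 0.9), seed = 33)
  idx <- sample(gm$samples)
  res <- wc_fst(gm, idx[1:30], idx[31:60])
  se <- stats::sd(res$fst, na.rm = TRUE) / sqrt(sum(!is.na(res$fst)))
  expect_lt(abs(mean(res$fst, na.rm = TRUE)), 3 * se)
})

test_that("rank_scan flags by ceiling rule with ties kept", {
  fst <- tibble::tibble(id = paste0("s", 1:143013), chrom = "1",
                        pos_bp = 1:143013,
                        fst = seq(0, 1, length.out = 143013))
  flagged <- rank_scan(fst, 0.001)
  expect_equal(sum(flagged$flagged), 144)  # ceil(0.001 * 143013)
  expect_equal(attr(flagged, "top_snp")$id, "s143013")

  ties <- tibble::tibble(id = paste0("s", 1:100), chrom = "1",
                         pos_bp = 1:100, fst = rep(0.2, 100))
  expect_true(all(rank_scan(ties, 0.05)$flagged))
})

test_that("EHH reproduces the 4-haplotype worked example", {
  # carrier haplotypes read A-C-A, A-C-A, A-C-G, A-T-G from the core:
  # encode C/A as 0 and T/G as 1 at the flanking sites
  haps <- rbind(c(1L, 0L, 0L),
                c(1L, 0L, 0L),
                c(1L, 0L, 1L),
                c(1L, 1L, 1L),
                c(0L, 0L, 0L))  # non-carrier, must be ignored
  map <- tibble::tibble(id = c("core", "f1", "f2"), chrom = "1",
                        pos_bp = c(100L, 200L, 300L))
  curve <- ehh(haps, map, "core", 1L)
  expect_equal(curve$ehh[curve$id == "core"], 1)
  expect_equal(curve$ehh[curve$id == "f1"], 0.5)     # groups {3,1}: 3/6
  expect_equal(curve$ehh[curve$id == "f2"], 1 / 6)   # groups {2,1,1}: 1/6
  expect_equal(attr(curve, "n_carriers"), 4L)
})

test_that("EHH is bounded, non-increasing away from the core, zero after full breakup", {
  set.seed(41)
  for (rep in 1:10) {
    n_h <- 12; m <- 30
    haps <- matrix(rbinom(n_h * m, 1L, 0.5), n_h, m)
    core <- 15
    haps[, core] <- rep(c(0L, 1L), each = n_h / 2)
    map <- tibble::tibble(id = paste0("s", 1:m), chrom = "1",
                          pos_bp = seq(1000L, by = 1000L, length.out = m))
    curve <- ehh(haps, map, "s15", 1L, window_bp = 1e6)
    expect_true(all(curve$ehh >= 0 & curve$ehh <= 1))
    left <- curve$ehh[curve$distance_bp <= 0]
    right <- curve$ehh[curve$distance_bp >= 0]
    expect_true(all(diff(left) >= -1e-12))   # rises toward the core
    expect_true(all(diff(right) <= 1e-12))   # decays away from it
  }

  # all carriers distinct at the first flank -> ehh 0 from there on
  haps <- cbind(rep(1L, 4), diag(4L)[, 1:2], matrix(0L, 4, 1))
  haps[, 2:3] <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  map <- tibble::tibble(id = paste0("s", 1:4), chrom = "1",
                        pos_bp = c(100L, 200L, 300L, 400L))
  curve <- ehh(haps, map, "s1", 1L)
  expect_equal(curve$ehh[curve$id %in% c("s3", "s4")], c(0, 0))

  expect_error(ehh(haps[1, , drop = FALSE], map, "s1", 1L), "fewer than 2")
})

test_that("haplotype text files round-trip", {
  h <- matrix(rbinom(40, 1, 0.5), 8, 5)
  path <- withr::local_tempfile(fileext = ".txt")
  write_haplotypes(h, path)
  expect_identical(read_haplotypes(path), h + 0L)
  writeLines(c("0 1", "0"), path)
  expect_error(read_haplotypes(path), "line 2")
})

test_that("selection leaves longer EHH in the pre-selection cohort on average", {
  cfg <- sim_config(n_founders = 80, n_snps = 2000, n_chroms = 2,
                    focal = list(chrom = 1, pos_bp = 2.6e7, q0 = 0.5),
                    years = c(2016, 2022), selection_start_year = 2019,
                    selection_policy = "cull_mutant_offspring",
                    policy_compliance = 1, max_litters_per_year = 30)
  diffs <- vapply(1:5, function(s) {
    pop <- breed_forward(simulate_founders(cfg, seed = 300 + s), seed = 400 + s)
    ped <- pop$pedigree
    pre <- ped$id[ped$birth_year == 2018][1:25]
    post <- ped$id[ped$birth_year == 2022][1:25]
    hp_pre <- sim_haplotypes(pop, pre, 1)
    hp_post <- sim_haplotypes(pop, post, 1)
    core <- hp_pre$map$id[hp_pre$map$pos_bp == 2.6e7]
    allele <- default_core_allele(hp_post$haps, hp_post$map, core)
    e_pre <- ehh(hp_pre$haps, hp_pre$map, core, allele)
    e_post <- ehh(hp_post$haps, hp_post$map, core, allele)
    j <- dplyr::inner_join(e_pre, e_post, by = "id", suffix = c("_pre", "_post"))
    mean(j$ehh_pre - j$ehh_post)
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("without selection the focal SNP's F_ST rank is uniform across replicates", {
  ranks <- vapply(1:30, function(s) {
    cfg <- sim_config(n_founders = 60, n_snps = 1000, n_chroms = 2,
                      ancestral_pool = 10, founder_mosaic_segments = 8,
                      focal = list(chrom = 1, pos_bp = 2.6e7, q0 = 0.5),
                      years = c(2016, 2020), selection_policy = "none",
                      max_litters_per_year = 25)
    pop <- breed_forward(simulate_founders(cfg, seed = 700 + s), seed = 800 + s)
    ped <- pop$pedigree
    set.seed(900 + s)
    pick <- function(yr) {
      ids <- ped$id[ped$birth_year == yr]
      sort(ids[sample.int(length(ids), min(30, length(ids)))])
    }
    a <- pick(2017); b <- pick(2020)
    fst <- wc_fst(as_geno_matrix(pop, ids = c(a, b)),
                  paste0("dog", a), paste0("dog", b))
    focal <- fst$fst[fst$chrom == "1" & fst$pos_bp == 2.6e7]
    if (is.na(focal)) return(NA_real_)
    mean(fst$fst[!is.na(fst$fst)] <= focal)
  }, numeric(1))
  ranks <- ranks[!is.na(ranks)]
  expect_gt(stats::ks.test(ranks, "punif")$p.value, 0.01)
})
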