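test_that("observed heterozygosity spans its extremes and matches HWE expectation", {
  all_het <- gm_from_calls(matrix(1L, 5, 20))
  expect_equal(as.numeric(observed_het(all_het)), 1)
  all_hom <- gm_from_calls(matrix(rep(c(0L, 2L), 50), 5, 20))
  expect_equal(as.numeric(observed_het(all_hom)), 0)

  gm <- gm_hwe(200, 500, p = 0.5, seed = 51)
  ho <- observed_het(gm)
  # E[Ho] = 2p(1-p) = 0.5; SE over 200x500 Bernoulli(0.5) draws
  se <- sqrt(0.25 / (200 * 500))
  expect_lt(abs(ho - 0.5), 3 * se * 5)  # conservative: SNP means are correlated
})

test_that("ROH boundary suite: all four thresholds at their edges", {
  # 41 homozygous SNPs spanning exactly 50,000 bp -> one run
  pos <- as.integer(seq(1, 50000, length.out = 41))
  pos[41] <- 50000L
  calls <- matrix(0L, 1, 41)
  gm <- gm_from_calls(calls, pos = pos)
  runs <- detect_roh(gm)
  expect_equal(nrow(runs), 1)
  expect_equal(runs$n_snps, 41L)
  expect_equal(runs$length_bp, 50000)

  # 40 SNPs otherwise passing -> nothing
  gm40 <- gm_from_calls(matrix(0L, 1, 40), pos = pos[1:40])
  expect_equal(nrow(detect_roh(gm40)), 0)

  # span below 50 kb -> nothing
  gm_short <- gm_from_calls(matrix(0L, 1, 41), pos = seq(1L, by = 1000L, length.out = 41))
  expect_equal(nrow(detect_roh(gm_short)), 0)

  # density below 1/5000 -> nothing (41 SNPs over 250 kb)
  gm_sparse <- gm_from_calls(matrix(0L, 1, 41),
                             pos = as.integer(seq(1, 2.5e5, length.out = 41)))
  expect_equal(nrow(detect_roh(gm_sparse)), 0)

  # a 1,000,001 bp gap splits 82 SNPs into two 41-SNP runs
  pos82 <- c(pos, pos + 50000L + 1000001L)
  gm82 <- gm_from_calls(matrix(0L, 1, 82), pos = pos82)
  runs82 <- detect_roh(gm82)
  expect_equal(nrow(runs82), 2)
  expect_equal(runs82$n_snps, c(41L, 41L))
  # a gap of exactly 1e6 stays inside one run (dense blocks so density passes)
  block <- as.integer(seq(1, 150000, length.out = 300))
  pos_ok <- c(block, block + 150000L - 1L + 1000000L)
  gap_ok <- gm_from_calls(matrix(0L, 1, 600), pos = pos_ok)
  expect_equal(nrow(detect_roh(gap_ok)), 1)
  pos_over <- c(block, block + 150000L + 1000000L)  # gap 1,000,001
  gap_over <- gm_from_calls(matrix(0L, 1, 600), pos = pos_over)
  expect_equal(nrow(detect_roh(gap_over)), 2)

  # a heterozygote interrupts a run under maxHet = 0 but not maxHet = 1
  calls_het <- matrix(0L, 1, 83)
  calls_het[1, 42] <- 1L
  pos83 <- as.integer(seq(1, 103000, length.out = 83))
  gmh <- gm_from_calls(calls_het, pos = pos83)
  expect_equal(nrow(detect_roh(gmh)), 2)
  expect_equal(nrow(detect_roh(gmh, max_het = 1)), 1)

  # unsorted map is refused
  gm_bad <- gm_from_calls(matrix(0L, 1, 41), pos = rev(pos))
  expect_error(detect_roh(gm_bad), "sorted")
})

test_that("runs are disjoint, maximal and in coordinate order", {
  pop <- shared_sim_pop()
  gm <- as_geno_matrix(pop, ids = pop$pedigree$id[1:20])
  # density threshold matched to this map's ~80 kb marker spacing
  runs <- detect_roh(gm, min_snp = 20, min_density = 1 / 2e5)
  expect_gt(nrow(runs), 0)
  by_sc <- split(runs, list(runs$id, runs$chrom), drop = TRUE)
  for (grp in by_sc) {
    if (nrow(grp) < 2) next
    expect_true(all(diff(grp$start_bp) > 0))
    expect_true(all(grp$start_bp[-1] > grp$end_bp[-nrow(grp)]))  # disjoint
  }
})

test_that("F_ROH arithmetic and invariance to chromosome order", {
  runs <- tibble::tibble(id = "a", chrom = "1", start_bp = 1L,
                         end_bp = 500000L, n_snps = 100L, length_bp = 5e5)
  fr <- f_roh(runs, 2e6, sample_ids = c("a", "b"))
  expect_equal(fr$f_roh, c(0.25, 0))

  pop <- shared_sim_pop()
  gm <- as_geno_matrix(pop, ids = pop$pedigree$id[1:12])
  # reversing chromosome block order must not change per-sample totals
  ord <- order(match(gm$map$chrom, rev(unique(gm$map$chrom))))
  gm_rev <- subset_geno(gm, snps = ord)
  f1 <- f_roh(detect_roh(gm, min_snp = 20, min_density = 1 / 2e5), gm)
  f2 <- f_roh(detect_roh(gm_rev, min_snp = 20, min_density = 1 / 2e5), gm_rev)
  expect_equal(f1$f_roh, f2$f_roh)
  expect_gt(max(f1$f_roh), 0)
})

test_that("full-sib inbreeding raises F_ROH over outbred dogs", {
  # dogs bred from full sibs (F = 0.25) vs outbred dogs, same marker density
  cfg <- sim_config(n_founders = 40, n_snps = 2000, n_chroms = 2,
                    ancestral_pool = 20, years = c(2016, 2016))
  hits <- vapply(1:20, function(s) {
    pop <- simulate_founders(cfg, seed = 600 + s)
    set.seed(700 + s)
    # sibs from founders 1 x 2; their offspring is inbred
    sib_gametes <- function() {
      list(sire = make_gamete_for_test(pop, 1L), dam = make_gamete_for_test(pop, 2L))
    }
    add_dog <- function(pop, gam, sex, year, sire = NA_integer_, dam = NA_integer_) {
      id <- max(pop$pedigree$id) + 1L
      for (cc in seq_along(pop$haplos)) {
        pop$haplos[[cc]] <- rbind(pop$haplos[[cc]], gam$sire[[cc]], gam$dam[[cc]])
      }
      pop$pedigree <- dplyr::bind_rows(
        pop$pedigree, tibble::tibble(id = id, sex = sex, birth_year = year,
                                     sire = sire, dam = dam))
      pop
    }
    pop <- add_dog(pop, sib_gametes(), "M", 2017, 1L, 2L)
    pop <- add_dog(pop, sib_gametes(), "F", 2017, 1L, 2L)
    sib1 <- max(pop$pedigree$id) - 1L; sib2 <- max(pop$pedigree$id)
    inbred_gam <- list(sire = make_gamete_for_test(pop, sib1),
                       dam = make_gamete_for_test(pop, sib2))
    pop <- add_dog(pop, inbred_gam, "M", 2018, sib1, sib2)
    inbred <- max(pop$pedigree$id)
    outbred_gam <- list(sire = make_gamete_for_test(pop, 3L),
                        dam = make_gamete_for_test(pop, 4L))
    pop <- add_dog(pop, outbred_gam, "F", 2018, 3L, 4L)
    outbred <- max(pop$pedigree$id)
    gm <- as_geno_matrix(pop, ids = c(inbred, outbred))
    fr <- f_roh(detect_roh(gm, min_snp = 20, min_density = 1 / 2e5), gm)
    fr$f_roh[1] > fr$f_roh[2]
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("F_ROH ranks dogs like their pedigree inbreeding coefficient", {
  # a 10-chromosome genome: with fewer chromosomes the Mendelian sampling
  # variance of realized inbreeding around its pedigree expectation
  # dominates and no ROH measure could rank dogs reliably
  cfg <- sim_config(n_founders = 12, n_snps = 5000, n_chroms = 10,
                    ancestral_pool = 30, years = c(2016, 2024),
                    male_fraction_breeding = 0.05,
                    max_litters_per_year = 8)
  pop <- breed_forward(simulate_founders(cfg, seed = 90), seed = 91)
  ped <- pop$pedigree
  late <- ped$id[ped$birth_year >= 2022]
  set.seed(92)
  ids <- sort(late[sample.int(length(late), 50)])
  pk <- pedigree_kinship(ped)
  expect_gt(stats::sd(pk$f_ped[ids]), 0)
  gm <- as_geno_matrix(pop, ids = ids)
  fr <- f_roh(detect_roh(gm, min_snp = 10, min_density = 1 / 4e5), gm)
  rho <- stats::cor(pk$f_ped[ids], fr$f_roh, method = "spearman")
  expect_gt(rho, 0.5)
})

test_that("group F_ROH summaries include Welch tests", {
  set.seed(84)
  froh <- tibble::tibble(id = paste0("d", 1:40),
                         n_roh = 1L, roh_total_bp = 1,
                         f_roh = c(rnorm(20, 0.30, 0.05), rnorm(20, 0.28, 0.05)))
  cohort <- tibble::tibble(id = froh$id, group = rep(c("g1", "g2"), each = 20))
  res <- froh_group_summary(froh, cohort)
  expect_equal(nrow(res$summary), 2)
  expect_equal(nrow(res$tests), 1)
  ref <- stats::t.test(froh$f_roh[1:20], froh$f_roh[21:40])
  expect_equal(res$tests$p_value, ref$p.value)
})
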