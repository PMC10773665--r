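test_that("PCA separates structured populations and gives duplicates identical scores", {
  # two subpopulations with clearly different allele frequencies
  set.seed(61)
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    m <- 400
    p1 <- runif(m, 0.2, 0.8)
    # frequency shift scaled to give differentiation around F_ST ~ 0.1
    p2 <- pmin(0.95, pmax(0.05, p1 + rnorm(m, 0, sqrt(0.1 * p1 * (1 - p1)))))
    calls <- rbind(matrix(rbinom(20 * m, 2L, rep(p1, each = 20)), 20, m, byrow = FALSE),
                   matrix(rbinom(20 * m, 2L, rep(p2, each = 20)), 20, m, byrow = FALSE))
    gm <- gm_from_calls(calls)
    pc <- pca_genotypes(gm, k = 2)
    pc1 <- pc$scores$PC1
    max(pc1[1:20]) < min(pc1[21:40]) || min(pc1[1:20]) > max(pc1[21:40])
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  gm <- gm_hwe(10, 300, p = runif(300, 0.2, 0.8), seed = 62)
  dup <- geno_matrix(rbind(gm$calls, gm$calls[1, , drop = FALSE]), gm$map,
                     c(gm$samples, "copy"))
  pc <- pca_genotypes(dup, k = 3)
  sc <- pc$scores
  expect_equal(unlist(sc[sc$id == "ind1", -1]), unlist(sc[sc$id == "copy", -1]),
               tolerance = 1e-8)
})

test_that("panmictic PCA shows no dominant axis relative to a permutation oracle", {
  gm <- gm_hwe(40, 500, p = runif(500, 0.2, 0.8), seed = 63)
  pc <- pca_genotypes(gm, k = 5)
  set.seed(64)
  perm_pc1 <- replicate(10, {
    calls <- apply(gm$calls, 2, sample)
    pca_genotypes(gm_from_calls(calls), k = 2)$var_explained[1]
  })
  expect_lt(pc$var_explained[1], 3 * mean(perm_pc1))
})

test_that("p-distance counts genotype-state mismatches over complete cases", {
  gm <- gm_from_calls(rbind(rep(0L, 100), c(rep(1L, 25), rep(0L, 75))))
  expect_equal(p_distance(gm, 1, 2), 0.25)
  expect_equal(p_distance(gm, 1, 1), 0)

  # missing entries drop out of the comparison
  calls <- rbind(c(0L, 1L, 2L, NA), c(0L, 2L, NA, 1L))
  gm2 <- gm_from_calls(calls)
  expect_equal(p_distance(gm2, 1, 2), 0.5)  # 2 shared sites, 1 mismatch

  dm <- p_distance_matrix(gm)
  expect_true(isSymmetric(unname(dm)))
  expect_equal(unname(diag(dm)), c(0, 0))
  expect_equal(dm[1, 2], 0.25)
})

test_that("NJ recovers additive trees exactly", {
  # 4-taxon caterpillar: tips 1,2,3,4 with external branches 1,2,3,4, internal 1
  dm <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  d <- function(i, j, v) dm[i, j] <<- dm[j, i] <<- v
  d("a", "b", 3); d("a", "c", 5); d("a", "d", 6)
  d("b", "c", 6); d("b", "d", 7); d("c", "d", 7)
  tree <- nj_tree(dm)
  expect_s3_class(tree, "phylo")
  cd <- ape::cophenetic.phylo(tree)[letters[1:4], letters[1:4]]
  expect_equal(cd, dm, tolerance = 1e-10)
  expect_true(all(tree$edge.length >= 0))

  # 3 taxa: the unique topology solves the three-point equations exactly
  dm3 <- matrix(c(0, 2, 3, 2, 0, 5, 3, 5, 0), 3,
                dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  t3 <- nj_tree(dm3)
  cd3 <- ape::cophenetic.phylo(t3)[c("x", "y", "z"), c("x", "y", "z")]
  expect_equal(cd3, dm3, tolerance = 1e-10)

  # random additive trees up to 8 tips round-trip through their distance matrix
  set.seed(65)
  for (n in c(5, 6, 8)) {
    ref <- ape::rtree(n, rooted = FALSE)
    ref$edge.length <- runif(length(ref$edge.length), 0.5, 2)
    dmr <- ape::cophenetic.phylo(ref)
    rec <- nj_tree(dmr)
    expect_equal(ape::cophenetic.phylo(rec)[rownames(dmr), colnames(dmr)],
                 dmr, tolerance = 1e-8)
    expect_equal(ape::dist.topo(ape::unroot(ref), rec), structure(0, names = "PH85"),
                 ignore_attr = TRUE)
  }

  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2)), "symmetric|taxa")
  asym <- matrix(c(0, 1, 2, 3, 0, 4, 5, 6, 0), 3)
  expect_error(nj_tree(asym), "symmetric")
})

test_that("identical distances resolve deterministically", {
  dm <- matrix(1, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  diag(dm) <- 0
  t1 <- nj_tree(dm)
  t2 <- nj_tree(dm)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_true(all(t1$edge.length >= 0))
})

test_that("Nei's D identities and the two-locus worked value", {
  x <- runif(50, 0.1, 0.9)
  expect_equal(neis_d(x, x), 0)
  y <- runif(50, 0.1, 0.9)
  expect_equal(neis_d(x, y), neis_d(y, x))
  expect_gte(neis_d(x, y), 0)

  # locus 1 fixed for opposite alleles, locus 2 fixed shared: D = ln 2
  fx <- rbind(c(1, 0), c(1, 0))
  fy <- rbind(c(0, 1), c(1, 0))
  expect_equal(neis_d(fx, fy), log(2), tolerance = 1e-12)
})

test_that("LD-Ne formula branches and sampling correction behave", {
  # no drift signal -> infinite estimate
  gm <- gm_hwe(50, 200, p = runif(200, 0.2, 0.8), seed = 71,
               chrom = rep(c("1", "2"), each = 100))
  res <- ld_ne(gm)
  expect_true(res$r2_drift <= 0 || res$ne_hat > 200)

  # sampling component halves-ish when S doubles (1/S dominates)
  gm2 <- gm_hwe(100, 200, p = runif(200, 0.2, 0.8), seed = 72,
                chrom = rep(c("1", "2"), each = 100))
  e50 <- ld_ne(gm)$r2_sample_exp
  e100 <- ld_ne(gm2)$r2_sample_exp
  expect_lt(e100, e50)
  expect_equal(e50, 1 / 50 + 3.19 / 50^2)
  expect_equal(e100, 1 / 100 + 3.19 / 100^2)

  # guards
  expect_error(ld_ne(gm_hwe(5, 100, seed = 73)), "at least 10")
  expect_error(ld_ne(gm_hwe(20, 100, seed = 74, chrom = "1")), "2 chromosomes")
})

test_that("LD-Ne recovers a known small effective size", {
  # closed random-mating population of true Ne = 50 for 10 generations
  est <- vapply(1:6, function(s) {
    cfg <- sim_config(n_founders = 50, n_snps = 2000, n_chroms = 4,
                      ancestral_pool = 50, founder_mosaic_segments = 10)
    pop <- simulate_founders(cfg, seed = 500 + s)
    set.seed(550 + s)
    pop <- breed_discrete_generations(pop, n_gen = 10, n_per_gen = 50,
                                      start_year = 2011L)
    ped <- pop$pedigree
    last <- ped$id[ped$birth_year == 2020]
    ids <- sort(last[sample.int(length(last), 40)])
    gm <- as_geno_matrix(pop, ids = ids)
    ld_ne(gm, maf_floor = 0.05)$ne_hat
  }, numeric(1))
  expect_gte(stats::median(est), 20)
  expect_lte(stats::median(est), 110)
})

test_that("widening the breeding pool after selection raises contemporary Ne", {
  res <- vapply(1:7, function(s) {
    cfg <- sim_config(n_founders = 120, n_snps = 2000, n_chroms = 4,
                      ancestral_pool = 12, founder_mosaic_segments = 8,
                      focal = list(chrom = 1, pos_bp = 2.6e7, q0 = 0.5),
                      years = c(2016, 2022), selection_start_year = 2019,
                      selection_policy = "clear_sires_cull",
                      policy_compliance = 1, max_litters_per_year = 30,
                      recruits_per_year = 25, recruit_pool = 40,
                      post_selection_breeding_boost = 2)
    pop <- breed_forward(simulate_founders(cfg, seed = s), seed = s + 5000)
    ped <- pop$pedigree
    set.seed(s + 9000)
    pick <- function(yr) {
      ids <- ped$id[ped$birth_year == yr]
      sort(ids[sample.int(length(ids), min(40, length(ids)))])
    }
    ne_pre <- ld_ne(as_geno_matrix(pop, ids = pick(2018)), maf_floor = 0.05)$ne_hat
    ne_post <- ld_ne(as_geno_matrix(pop, ids = pick(2022)), maf_floor = 0.05)$ne_hat
    ne_post > ne_pre
  }, logical(1))
  expect_gt(mean(res), 0.5)  # majority of replicates
})
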