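# shared fixture builders; everything is generated in code at test time

# tiny geno_matrix from an explicit call matrix (rows = samples)
gm_from_calls <- function(calls, chrom = "1", pos = NULL, samples = NULL) {
  m <- ncol(calls)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  chrom <- rep_len(chrom, m)
  map <- tibble::tibble(id = paste0("s", seq_len(m)), chrom = chrom,
                        pos_bp = as.integer(pos), a1 = "A", a2 = "G")
  if (is.null(samples)) samples <- paste0("ind", seq_len(nrow(calls)))
  geno_matrix(calls, map, samples = samples)
}

# n samples x m SNPs under HWE at frequency p (scalar or per-SNP vector)
gm_hwe <- function(n, m, p = 0.5, seed = 1, chrom = "1") {
  set.seed(seed)
  p <- rep_len(p, m)
  calls <- matrix(stats::rbinom(n * m, 2L, rep(p, each = n)), n, m)
  gm_from_calls(calls, chrom = chrom)
}

# genotype vectors for many independent parent-offspring pairs at freq p:
# offspring gets one allele transmitted from the parent, one from the population
mendelian_po_pair <- function(m, p) {
  parent <- stats::rbinom(m, 2L, p)
  transmitted <- stats::rbinom(m, 1L, parent / 2)
  offspring <- transmitted + stats::rbinom(m, 1L, p)
  rbind(parent, offspring)
}

# independent-enumeration oracle for the two-sided Fisher test on a 2x2 table
fisher_2x2_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(ks, c1, n - c1, r1)
  p_obs <- stats::dhyper(tab[1, 1], c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-10)])
}

# one recombinant gamete from a simulated parent (internal meiosis machinery)
make_gamete_for_test <- function(pop, parent_id) {
  breedwatch:::make_gamete(pop, parent_id)
}

# discrete-generation random-mating population at constant census size:
# every dog in generation g has both parents drawn from generation g - 1,
# so the variance effective size stays near n_per_gen throughout
breed_discrete_generations <- function(pop, n_gen, n_per_gen, start_year) {
  prev <- pop$pedigree$id
  for (g in seq_len(n_gen)) {
    sexes <- pop$pedigree$sex[prev]
    males <- prev[sexes == "M"]; females <- prev[sexes == "F"]
    ids <- max(pop$pedigree$id) + seq_len(n_per_gen)
    new_rows <- tibble::tibble(id = ids,
                               sex = rep_len(c("M", "F"), n_per_gen),
                               birth_year = start_year + g - 1L,
                               sire = NA_integer_, dam = NA_integer_)
    gams <- lapply(seq_len(n_per_gen), function(i) {
      s <- males[sample.int(length(males), 1)]
      d <- females[sample.int(length(females), 1)]
      new_rows$sire[i] <<- s; new_rows$dam[i] <<- d
      list(make_gamete_for_test(pop, s), make_gamete_for_test(pop, d))
    })
    for (cc in seq_along(pop$haplos)) {
      block <- do.call(rbind, lapply(gams, function(g2) {
        rbind(g2[[1]][[cc]], g2[[2]][[cc]])
      }))
      pop$haplos[[cc]] <- rbind(pop$haplos[[cc]], block)
    }
    pop$pedigree <- dplyr::bind_rows(pop$pedigree, new_rows)
    prev <- ids
  }
  pop
}

# study-like scenario: closed breed, genotype-test-and-remove selection with
# imperfect uptake from 2020, four genotype-by-year cohorts exported with
# phased haplotypes on the focal chromosome
make_study_dataset <- function(dir, seed = 101) {
  cfg <- sim_config(n_founders = 150, n_snps = 1500, n_chroms = 2,
                    focal = list(chrom = 1, pos_bp = 2.6e7, q0 = 0.55),
                    years = c(2016, 2022), selection_start_year = 2020,
                    selection_policy = "cull_mutant_offspring",
                    policy_compliance = 0.85, max_litters_per_year = 60)
  pop <- breed_forward(simulate_founders(cfg, seed = seed), seed = seed + 1)
  groups <- tibble::tibble(
    group = c("Wild2019", "Wild2022", "Mutant2019", "Mutant2022"),
    birth_year = c(2019, 2022, 2019, 2022),
    focal_genotype = c("Wild", "Wild", "Mutant", "Mutant"),
    n = c(42, 49, 24, 2))
  res <- export_cohorts(pop, groups, dir, seed = seed + 2,
                        haplotypes_chrom = "1")
  res$pop <- pop
  res$cfg <- cfg
  res
}

# small bottlenecked population used by several suites (cached per session)
shared_sim_pop <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_founders = 60, n_snps = 1500, n_chroms = 2,
                        ancestral_pool = 6, max_litters_per_year = 25,
                        years = c(2016, 2020))
      pop <- simulate_founders(cfg, seed = 42)
      cache <<- breed_forward(pop, seed = 43)
    }
    cache
  }
})
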