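#' Configuration for the closed-breed cohort simulator
#'
#' Defines a small, bottlenecked closed breed: founders draw their
#' chromosomes from a limited pool of ancestral haplotypes (creating the
#' long-range LD and background homozygosity typical of pedigree breeds), and
#' the population then breeds forward one cycle per year with a skewed sex
#' ratio (few sires, many dams). A biallelic focal locus starts at high
#' mutant frequency; from `selection_start_year` a genotype-based breeding
#' policy can act against it.
#'
#' @param n_founders Number of founder dogs (default 100).
#' @param n_snps Total SNPs across the genome (default 5000).
#' @param n_chroms Number of autosomes (default 2).
#' @param chrom_len_bp Chromosome length in bp (default 63e6, a typical dog
#'   autosome).
#' @param founder_freq_beta Beta(a, b) parameters for ancestral allele
#'   frequencies (default c(2, 2)).
#' @param ancestral_pool Haplotype templates per chromosome from which all
#'   founder chromosomes are drawn (default 6; smaller = stronger
#'   bottleneck, more homozygosity).
#' @param founder_mosaic_segments Mean number of template switches per
#'   founder chromosome (Poisson; default 5). Founder chromosomes are
#'   mosaics of pool templates, emulating a few generations of mixing since
#'   the breed bottleneck; 0 copies templates verbatim.
#' @param recomb_rate Per-bp crossover probability per meiosis (default 1e-8,
#'   about 1 cM/Mb).
#' @param focal List: `chrom`, `pos_bp`, `q0` (initial mutant allele
#'   frequency). The mutant allele is coded 1 at this SNP.
#' @param years Integer vector `c(start, end)` of breeding years simulated.
#' @param selection_start_year First year the breeding policy applies.
#' @param selection_policy One of `"none"`, `"avoid_mutant_matings"` (no
#'   litter from two carrier parents), `"cull_mutant_offspring"` (mutant
#'   homozygote pups removed at birth), or `"clear_sires_cull"` (studs are
#'   chosen mutation-free and mutant homozygote pups are removed: the
#'   test-informed mate-selection regime that produces study-scale allele
#'   declines).
#' @param policy_compliance Fraction of matings at which the policy is
#'   actually applied (default 0.9; testing uptake is never universal).
#' @param litters_per_female_year Litters per breeding dam per year.
#' @param litter_size_mean Mean litter size (Poisson).
#' @param male_fraction_breeding Share of eligible males used as sires
#'   (default 0.2, i.e. a 20:80 sire:dam ratio).
#' @param max_litters_per_year Cap on litters per year, bounding population
#'   growth (default 40).
#' @param post_selection_breeding_boost Multiplier on the sire share and the
#'   litter cap from `selection_start_year` when a policy is active
#'   (default 1.5): breeders avoiding a mutation widen the breeding pool.
#' @param recruits_per_year Founder-like dogs from outside lineages recruited
#'   into the breeding population each year once a policy is active
#'   (default 10). Recruits draw their chromosomes from a separate template
#'   pool and are free of the mutant allele: the "different lineages" used
#'   to avoid carrier x carrier matings.
#' @param recruit_pool Number of ancestral templates behind the recruited
#'   lineages (default = `ancestral_pool`).
#' @param breeding_ages Inclusive age window (years) for breeding
#'   eligibility.
#'
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_founders = 100,
                       n_snps = 5000,
                       n_chroms = 2,
                       chrom_len_bp = 63e6,
                       founder_freq_beta = c(2, 2),
                       ancestral_pool = 6,
                       founder_mosaic_segments = 5,
                       recomb_rate = 1e-8,
                       focal = list(chrom = 1, pos_bp = 26540342, q0 = 0.5),
                       years = c(2016, 2022),
                       selection_start_year = 2019,
                       selection_policy = c("none", "avoid_mutant_matings",
                                            "cull_mutant_offspring",
                                            "clear_sires_cull"),
                       policy_compliance = 0.9,
                       litters_per_female_year = 1,
                       litter_size_mean = 5,
                       male_fraction_breeding = 0.2,
                       max_litters_per_year = 40,
                       post_selection_breeding_boost = 1.5,
                       recruits_per_year = 10,
                       recruit_pool = NULL,
                       breeding_ages = c(1, 6)) {
  selection_policy <- match.arg(selection_policy)
  cfg <- list(n_founders = n_founders, n_snps = n_snps, n_chroms = n_chroms,
              chrom_len_bp = chrom_len_bp, founder_freq_beta = founder_freq_beta,
              ancestral_pool = ancestral_pool,
              founder_mosaic_segments = founder_mosaic_segments,
              recomb_rate = recomb_rate,
              focal = focal, years = years,
              selection_start_year = selection_start_year,
              selection_policy = selection_policy,
              policy_compliance = policy_compliance,
              litters_per_female_year = litters_per_female_year,
              litter_size_mean = litter_size_mean,
              male_fraction_breeding = male_fraction_breeding,
              max_litters_per_year = max_litters_per_year,
              post_selection_breeding_boost = post_selection_breeding_boost,
              recruits_per_year = recruits_per_year,
              recruit_pool = recruit_pool %||% ancestral_pool,
              breeding_ages = breeding_ages)
  stopifnot(cfg$focal$q0 > 0, cfg$focal$q0 < 1,
            cfg$focal$chrom >= 1, cfg$focal$chrom <= n_chroms,
            cfg$focal$pos_bp >= 1, cfg$focal$pos_bp <= chrom_len_bp,
            male_fraction_breeding > 0, male_fraction_breeding < 1,
            policy_compliance >= 0, policy_compliance <= 1,
            ancestral_pool >= 2)
  structure(cfg, class = "sim_config")
}

#' Simulate the founder generation
#'
#' Builds the marker map (uniform positions per chromosome, the focal locus
#' placed exactly at its specified position), an ancestral haplotype pool per
#' chromosome with allele frequencies drawn from the configured Beta
#' distribution, and founders whose two chromosomes are drawn with
#' replacement from that pool. At the focal SNP, `round(q0 * pool)` templates
#' carry the mutant allele, so the mutant rides specific ancestral
#' backgrounds (creating the local LD a selection scan needs) and the
#' realized founder frequency is `q0` up to binomial sampling error.
#'
#' Founder birth years are spread over the four years before the simulated
#' period so the first breeding year has eligible parents.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @return A `sim_population`: pedigree tibble (`id`, `sex`, `birth_year`,
#'   `sire`, `dam`), per-chromosome phased haplotype matrices (rows `2i-1`,
#'   `2i` belong to dog `i`), marker map, and the focal-locus spec.
#' @export
simulate_founders <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_founders < 4) stop("need at least 4 founders", call. = FALSE)
  set.seed(seed)
  per_chrom <- diff_round(cfg$n_snps, cfg$n_chroms)

  map <- purrr::map_dfr(seq_len(cfg$n_chroms), function(cc) {
    m <- per_chrom[cc]
    pos <- sort(sample.int(cfg$chrom_len_bp, m))
    if (cc == cfg$focal$chrom) {
      # place the focal locus exactly; replace the nearest marker
      k <- which.min(abs(pos - cfg$focal$pos_bp))
      pos[k] <- cfg$focal$pos_bp
      pos <- sort(unique(pos))
      while (length(pos) < m) {
        extra <- sample.int(cfg$chrom_len_bp, m - length(pos))
        pos <- sort(unique(c(pos, extra)))
      }
    }
    tibble::tibble(chrom = as.character(cc), pos_bp = pos)
  })
  map$id <- sprintf("snp_%s_%d", map$chrom, map$pos_bp)
  map <- map[, c("id", "chrom", "pos_bp")]

  K <- cfg$ancestral_pool
  K2 <- cfg$recruit_pool
  pool <- vector("list", cfg$n_chroms)
  recruit_pool <- vector("list", cfg$n_chroms)
  for (cc in seq_len(cfg$n_chroms)) {
    m <- sum(map$chrom == as.character(cc))
    # breed-wide allele frequencies shared by both lineage pools
    p <- stats::rbeta(m, cfg$founder_freq_beta[1], cfg$founder_freq_beta[2])
    pool[[cc]] <- matrix(stats::rbinom(K * m, 1L, rep(p, each = K)), K, m)
    recruit_pool[[cc]] <- matrix(stats::rbinom(K2 * m, 1L, rep(p, each = K2)), K2, m)
  }
  # focal column: fix the number of carrier templates to match q0;
  # recruited lineages are clear of the mutation
  fc <- cfg$focal$chrom
  fidx <- which(map$pos_bp[map$chrom == as.character(fc)] == cfg$focal$pos_bp)
  n_carrier <- max(1L, min(K - 1L, round(cfg$focal$q0 * K)))
  col <- integer(K)
  col[sample.int(K, n_carrier)] <- 1L
  pool[[fc]][, fidx] <- col
  recruit_pool[[fc]][, fidx] <- 0L

  n <- cfg$n_founders
  haplos <- vector("list", cfg$n_chroms)
  for (cc in seq_len(cfg$n_chroms)) {
    pos <- map$pos_bp[map$chrom == as.character(cc)]
    haplos[[cc]] <- do.call(rbind, lapply(seq_len(2 * n), function(i) {
      mosaic_haplotype(pool[[cc]], pos, cfg$chrom_len_bp,
                       cfg$founder_mosaic_segments)
    }))
  }
  pedigree <- tibble::tibble(
    id = seq_len(n),
    sex = sample(c("M", "F"), n, replace = TRUE),
    birth_year = sample(seq(cfg$years[1] - 4, cfg$years[1] - 1), n, replace = TRUE),
    sire = NA_integer_, dam = NA_integer_)
  # guarantee both sexes
  if (!any(pedigree$sex == "M")) pedigree$sex[1] <- "M"
  if (!any(pedigree$sex == "F")) pedigree$sex[1] <- "F"

  structure(list(pedigree = pedigree, haplos = haplos, map = map,
                 focal = cfg$focal,
                 focal_col = list(chrom = fc, idx = fidx),
                 recruit_pool = recruit_pool,
                 cfg = cfg),
            class = "sim_population")
}

# one founder chromosome: a template mosaic with ~Poisson(switches) breakpoints
mosaic_haplotype <- function(pool, pos, len, switches) {
  K <- nrow(pool)
  if (switches <= 0) return(pool[sample.int(K, 1L), ])
  k <- stats::rpois(1L, switches)
  if (k == 0L) return(pool[sample.int(K, 1L), ])
  breaks <- sort(stats::runif(k, 1, len))
  seg <- findInterval(pos, breaks) + 1L          # 1..k+1
  templates <- sample.int(K, k + 1L, replace = TRUE)
  pool[cbind(templates[seg], seq_along(pos))]
}

diff_round <- function(total, k) {
  base <- rep(total %/% k, k)
  extra <- total %% k
  if (extra > 0) base[seq_len(extra)] <- base[seq_len(extra)] + 1L
  base
}

#' @export
print.sim_population <- function(x, ...) {
  cat(sprintf("<sim_population> %d dogs (%d founders), %d SNPs on %d chromosome(s), years %s\n",
              nrow(x$pedigree), sum(is.na(x$pedigree$sire)), nrow(x$map),
              length(x$haplos),
              paste(range(x$pedigree$birth_year), collapse = "-")))
  invisible(x)
}

focal_allele_count <- function(pop, ids = pop$pedigree$id) {
  h <- pop$haplos[[pop$focal_col$chrom]]
  j <- pop$focal_col$idx
  h[2L * ids - 1L, j] + h[2L * ids, j]
}

#' Focal-locus diploid genotypes
#'
#' @param pop A `sim_population`.
#' @param ids Dog ids (default all).
#' @return Character vector: `"Wild"`, `"Hetero"` or `"Mutant"` (0, 1, 2
#'   copies of the mutant allele).
#' @export
focal_genotypes <- function(pop, ids = pop$pedigree$id) {
  c("Wild", "Hetero", "Mutant")[focal_allele_count(pop, ids) + 1L]
}

#' True focal allele frequency by birth year
#'
#' @param pop A `sim_population`.
#' @return Tibble: `birth_year`, `n`, `q` (mutant allele frequency).
#' @export
focal_freq_by_year <- function(pop) {
  cnt <- focal_allele_count(pop)
  dplyr::summarise(
    dplyr::group_by(
      tibble::tibble(birth_year = pop$pedigree$birth_year, cnt = cnt),
      .data$birth_year),
    n = dplyr::n(), q = sum(.data$cnt) / (2 * dplyr::n()), .groups = "drop")
}

# one gamete from a parent: recombine the parent's two haplotypes on one chromosome
meiose_chrom <- function(h1, h2, pos, rate, len) {
  k <- stats::rpois(1L, rate * len)
  if (k == 0L) {
    if (stats::runif(1) < 0.5) return(h1) else return(h2)
  }
  breaks <- sort(stats::runif(k, 1, len))
  seg <- findInterval(pos, breaks)  # 0..k
  start <- stats::rbinom(1L, 1L, 0.5)
  use_first <- (seg + start) %% 2L == 0L
  ifelse(use_first, h1, h2)
}

make_gamete <- function(pop, parent_id) {
  lapply(seq_along(pop$haplos), function(cc) {
    h <- pop$haplos[[cc]]
    pos <- pop$map$pos_bp[pop$map$chrom == as.character(cc)]
    meiose_chrom(h[2L * parent_id - 1L, ], h[2L * parent_id, ], pos,
                 pop$cfg$recomb_rate, pop$cfg$chrom_len_bp)
  })
}

carries_mutant <- function(pop, id) focal_allele_count(pop, id) >= 1L

#' Breed the population forward through the configured years
#'
#' Each year: dogs inside the breeding age window are eligible; the top
#' `male_fraction_breeding` share of eligible males (by id) serve as sires;
#' up to `max_litters_per_year` dams each whelp a Poisson-sized litter by a
#' randomly drawn sire. From `selection_start_year` the configured policy
#' acts on each litter with probability `policy_compliance`:
#' `avoid_mutant_matings` rejects a mating between two carriers of the
#' mutant allele and redraws the sire (up to 1000 tries per litter);
#' `cull_mutant_offspring` removes mutant homozygote pups at birth (a
#' genotype-test-and-remove regime, the stronger selection on the allele).
#' Offspring genotypes arise by meiosis with Poisson recombination.
#'
#' @param pop A `sim_population` from [simulate_founders()].
#' @param seed Integer seed.
#' @param years Optional override of the years to simulate (default
#'   `cfg$years[1]:cfg$years[2]`).
#' @return The extended `sim_population`.
#' @export
breed_forward <- function(pop, seed = 1L, years = NULL) {
  stopifnot(inherits(pop, "sim_population"))
  cfg <- pop$cfg
  set.seed(seed)
  if (is.null(years)) years <- seq(cfg$years[1], cfg$years[2])

  for (yr in years) {
    boosting <- cfg$selection_policy != "none" && yr >= cfg$selection_start_year
    if (boosting && cfg$recruits_per_year > 0) {
      pop <- recruit_dogs(pop, n = cfg$recruits_per_year, birth_year = yr - 1L)
    }
    ped <- pop$pedigree
    age <- yr - ped$birth_year
    eligible <- age >= cfg$breeding_ages[1] & age <= cfg$breeding_ages[2]
    males <- ped$id[eligible & ped$sex == "M"]
    females <- ped$id[eligible & ped$sex == "F"]
    if (length(males) < 1 || length(females) < 1) {
      stop(sprintf("year %d: no eligible breeding %s", yr,
                   if (length(males) < 1) "males" else "females"), call. = FALSE)
    }
    boost <- if (boosting) cfg$post_selection_breeding_boost else 1
    n_sires <- max(1L, ceiling(boost * cfg$male_fraction_breeding * length(males)))
    n_sires <- min(n_sires, length(males))
    sires <- males[seq_len(n_sires)]
    n_litters <- min(length(females) * cfg$litters_per_female_year,
                     as.integer(round(boost * cfg$max_litters_per_year)))
    dam_pool <- rep(females, cfg$litters_per_female_year)
    dams <- dam_pool[sample.int(length(dam_pool))][seq_len(n_litters)]

    policy_on <- cfg$selection_policy != "none" && yr >= cfg$selection_start_year
    new_haps <- vector("list", n_litters)
    new_rows <- vector("list", n_litters)
    next_id <- max(ped$id)

    for (li in seq_len(n_litters)) {
      dam <- dams[li]
      enforce <- policy_on && stats::runif(1) < cfg$policy_compliance
      sire <- sires[sample.int(length(sires), 1L)]
      reject_sire <- enforce &&
        ((cfg$selection_policy == "avoid_mutant_matings" && carries_mutant(pop, dam)) ||
           cfg$selection_policy == "clear_sires_cull")
      if (reject_sire) {
        tries <- 0L
        while (carries_mutant(pop, sire)) {
          tries <- tries + 1L
          if (tries > 1000L) {
            stop("mating rejection cap (1000) exceeded: no non-carrier sire available; relax the selection policy or widen the sire pool",
                 call. = FALSE)
          }
          sire <- sires[sample.int(length(sires), 1L)]
        }
      }
      n_pups <- stats::rpois(1L, cfg$litter_size_mean)
      if (n_pups == 0L) next
      pup_haps <- vector("list", n_pups)
      keep <- logical(n_pups)
      for (pp in seq_len(n_pups)) {
        g_s <- make_gamete(pop, sire)
        g_d <- make_gamete(pop, dam)
        pup_haps[[pp]] <- list(sire = g_s, dam = g_d)
        mut <- g_s[[pop$focal_col$chrom]][pop$focal_col$idx] +
          g_d[[pop$focal_col$chrom]][pop$focal_col$idx]
        culls <- cfg$selection_policy %in% c("cull_mutant_offspring", "clear_sires_cull")
        keep[pp] <- !(policy_on && culls && enforce && mut == 2L)
      }
      pup_haps <- pup_haps[keep]
      n_keep <- length(pup_haps)
      if (n_keep == 0L) next
      ids <- next_id + seq_len(n_keep)
      next_id <- next_id + n_keep
      new_rows[[li]] <- tibble::tibble(
        id = ids,
        sex = sample(c("M", "F"), n_keep, replace = TRUE),
        birth_year = yr, sire = sire, dam = dam)
      new_haps[[li]] <- pup_haps
    }

    new_rows <- dplyr::bind_rows(new_rows)
    if (nrow(new_rows) == 0) next
    pup_haps <- unlist(new_haps, recursive = FALSE)
    for (cc in seq_along(pop$haplos)) {
      block <- do.call(rbind, lapply(pup_haps, function(ph) {
        rbind(ph$sire[[cc]], ph$dam[[cc]])
      }))
      pop$haplos[[cc]] <- rbind(pop$haplos[[cc]], block)
    }
    pop$pedigree <- dplyr::bind_rows(pop$pedigree, new_rows)
  }
  pop
}

# add founder-like dogs from the recruited-lineage template pool
recruit_dogs <- function(pop, n, birth_year) {
  K2 <- nrow(pop$recruit_pool[[1]])
  ids <- max(pop$pedigree$id) + seq_len(n)
  for (cc in seq_along(pop$haplos)) {
    draw <- sample.int(K2, 2 * n, replace = TRUE)
    pop$haplos[[cc]] <- rbind(pop$haplos[[cc]],
                              pop$recruit_pool[[cc]][draw, , drop = FALSE])
  }
  pop$pedigree <- dplyr::bind_rows(
    pop$pedigree,
    tibble::tibble(id = ids,
                   sex = rep_len(c("M", "F"), n),
                   birth_year = birth_year,
                   sire = NA_integer_, dam = NA_integer_))
  pop
}

#' Pedigree kinship matrix and inbreeding coefficients
#'
#' Exact expected kinships from the recorded pedigree (founders assumed
#' unrelated and non-inbred): the recursive tabular method. The inbreeding
#' coefficient of a dog is the kinship of its parents.
#'
#' @param pedigree Tibble with `id`, `sire`, `dam` (ids are 1..n in
#'   birth order, parents before offspring).
#' @return List: `kinship` (n x n matrix) and `f_ped` (numeric vector of
#'   pedigree inbreeding coefficients).
#' @export
pedigree_kinship <- function(pedigree) {
  n <- nrow(pedigree)
  stopifnot(all(pedigree$id == seq_len(n)))
  K <- matrix(0, n, n)
  f <- numeric(n)
  for (i in seq_len(n)) {
    s <- pedigree$sire[i]; d <- pedigree$dam[i]
    if (is.na(s)) {
      K[i, i] <- 0.5
    } else {
      if (i > 1) {
        prev <- seq_len(i - 1L)
        K[i, prev] <- 0.5 * (K[s, prev] + K[d, prev])
        K[prev, i] <- K[i, prev]
      }
      f[i] <- K[s, d]
      K[i, i] <- 0.5 * (1 + f[i])
    }
  }
  dimnames(K) <- list(pedigree$id, pedigree$id)
  list(kinship = K, f_ped = f)
}

#' Convert simulated dogs to a genotype matrix
#'
#' @param pop A `sim_population`.
#' @param ids Dog ids to include (default all).
#' @param prefix Sample-id prefix (default `"dog"`).
#' @return A [geno_matrix()]; allele 0 is written `A`, allele 1 (the counted
#'   A2, mutant at the focal locus) is written `G`.
#' @export
as_geno_matrix <- function(pop, ids = pop$pedigree$id, prefix = "dog") {
  stopifnot(inherits(pop, "sim_population"))
  calls <- do.call(cbind, lapply(seq_along(pop$haplos), function(cc) {
    h <- pop$haplos[[cc]]
    h[2L * ids - 1L, , drop = FALSE] + h[2L * ids, , drop = FALSE]
  }))
  map <- pop$map
  map$a1 <- "A"; map$a2 <- "G"
  geno_matrix(calls, map, samples = paste0(prefix, ids))
}

#' Extract phased haplotypes for a chromosome
#'
#' @param pop A `sim_population`.
#' @param ids Dog ids.
#' @param chrom Chromosome label or index.
#' @return List: `haps` (2 x n_ids rows of 0/1 alleles, two consecutive rows
#'   per dog) and `map` (marker tibble for that chromosome).
#' @export
sim_haplotypes <- function(pop, ids, chrom) {
  cc <- if (is.character(chrom)) match(chrom, as.character(seq_along(pop$haplos))) else chrom
  h <- pop$haplos[[cc]]
  rows <- as.vector(rbind(2L * ids - 1L, 2L * ids))
  list(haps = h[rows, , drop = FALSE],
       map = pop$map[pop$map$chrom == as.character(cc), , drop = FALSE])
}

#' Export time-stamped cohorts for the analysis pipeline
#'
#' Selects dogs by birth year and focal genotype into named groups, and
#' writes PLINK text PED/MAP, a metadata TSV (`id`, `birth_year`,
#' `focal_genotype`, `group`) and a truth JSON holding exact quantities from
#' the simulation for use as test oracles: per-year focal allele
#' frequencies, pedigree kinships among exported dogs, and pedigree
#' inbreeding coefficients.
#'
#' @param pop A `sim_population`.
#' @param groups Tibble with columns `group`, `birth_year`, `focal_genotype`,
#'   `n` (requested size).
#' @param out_dir Output directory (created if needed).
#' @param basename File basename (default `"cohorts"`).
#' @param seed Seed for the within-stratum sampling of dogs.
#' @param haplotypes_chrom Optional chromosome label; if set, also writes one
#'   phased 0/1 haplotype file per group (`<basename>.<group>.haps.txt`, two
#'   rows per dog, columns following the MAP order of that chromosome) for
#'   the EHH stage.
#' @return Invisibly, a list with the selected metadata tibble, the
#'   `geno_matrix`, and the file paths.
#' @export
export_cohorts <- function(pop, groups, out_dir, basename = "cohorts", seed = 1L,
                           haplotypes_chrom = NULL) {
  stopifnot(inherits(pop, "sim_population"))
  groups <- tibble::as_tibble(groups)
  set.seed(seed)
  geno <- focal_genotypes(pop)
  chosen <- purrr::pmap_dfr(groups, function(group, birth_year, focal_genotype, n) {
    pool <- pop$pedigree$id[pop$pedigree$birth_year == birth_year &
                              geno == focal_genotype]
    if (length(pool) < n) {
      stop(sprintf("group '%s': requested %d dogs but only %d available (%s born %d)",
                   group, n, length(pool), focal_genotype, birth_year),
           call. = FALSE)
    }
    tibble::tibble(dog = sort(pool[sample.int(length(pool), n)]), group = group,
                   birth_year = birth_year, focal_genotype = focal_genotype)
  })
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gm <- as_geno_matrix(pop, ids = chosen$dog)
  paths <- list(ped = file.path(out_dir, paste0(basename, ".ped")),
                map = file.path(out_dir, paste0(basename, ".map")),
                meta = file.path(out_dir, paste0(basename, ".meta.tsv")),
                truth = file.path(out_dir, paste0(basename, ".truth.json")))
  write_ped_map(gm, paths$ped, paths$map)
  meta <- tibble::tibble(id = gm$samples, birth_year = chosen$birth_year,
                         focal_genotype = chosen$focal_genotype,
                         group = chosen$group)
  readr::write_tsv(meta, paths$meta)

  if (!is.null(haplotypes_chrom)) {
    paths$haplotypes <- list()
    for (grp in unique(chosen$group)) {
      hp <- sim_haplotypes(pop, chosen$dog[chosen$group == grp], haplotypes_chrom)
      hpath <- file.path(out_dir, sprintf("%s.%s.haps.txt", basename, grp))
      write_haplotypes(hp$haps, hpath)
      paths$haplotypes[[grp]] <- hpath
    }
  }

  pk <- pedigree_kinship(pop$pedigree)
  ksub <- pk$kinship[chosen$dog, chosen$dog, drop = FALSE]
  dimnames(ksub) <- list(gm$samples, gm$samples)
  truth <- list(
    focal_freq_by_year = focal_freq_by_year(pop),
    f_ped = stats::setNames(pk$f_ped[chosen$dog], gm$samples),
    kinship = ksub,
    focal = pop$focal)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(list(meta = meta, gm = gm, paths = paths, truth = truth))
}
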