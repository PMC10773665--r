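#' Genotype matrix objects
#'
#' A `geno_matrix` bundles diploid SNP calls with their marker map. Calls are
#' stored as an integer matrix (samples in rows, SNPs in columns) counting
#' copies of the A2 allele: 0, 1, 2, or `NA` for missing. The marker map is a
#' tibble with one row per SNP: `id`, `chrom`, `pos_bp` (1-based physical
#' position), and the two allele symbols `a1`/`a2`. A2 is fixed as the
#' alphabetically second allele observed when the data are first read, so all
#' downstream allele frequencies are orientation-stable.
#'
#' @param calls Integer matrix, samples x SNPs, values in {0, 1, 2, NA}.
#' @param map Tibble with columns `id`, `chrom`, `pos_bp`, `a1`, `a2`.
#' @param samples Character vector of sample ids (defaults to rownames).
#'
#' @return A `geno_matrix` object.
#' @export
geno_matrix <- function(calls, map, samples = rownames(calls)) {
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(calls)))
  map <- tibble::as_tibble(map)
  stopifnot(
    ncol(calls) == nrow(map),
    length(samples) == nrow(calls),
    !anyDuplicated(map$id),
    !anyDuplicated(samples)
  )
  storage.mode(calls) <- "integer"
  bad <- calls[!is.na(calls)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L)) {
    stop("genotype calls must be 0, 1, 2 or NA", call. = FALSE)
  }
  dimnames(calls) <- list(samples, map$id)
  structure(list(calls = calls, map = map, samples = samples),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d samples x %d SNPs on %d chromosome(s)\n",
              length(x$samples), nrow(x$map), length(unique(x$map$chrom))))
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing rate %.4f\n", miss))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$calls)

#' Subset a genotype matrix by samples and/or SNPs
#'
#' @param gm A `geno_matrix`.
#' @param samples Character vector of sample ids (or logical/integer index).
#' @param snps Character vector of SNP ids (or logical/integer index).
#' @return The subsetted `geno_matrix`; marker order is preserved.
#' @export
subset_geno <- function(gm, samples = NULL, snps = NULL) {
  stopifnot(inherits(gm, "geno_matrix"))
  si <- if (is.null(samples)) seq_along(gm$samples) else {
    if (is.character(samples)) match(samples, gm$samples) else samples
  }
  if (anyNA(si)) stop("unknown sample id(s): ",
                      paste(samples[is.na(match(samples, gm$samples))], collapse = ", "),
                      call. = FALSE)
  mi <- if (is.null(snps)) seq_len(nrow(gm$map)) else {
    if (is.character(snps)) match(snps, gm$map$id) else snps
  }
  if (anyNA(mi)) stop("unknown SNP id(s)", call. = FALSE)
  geno_matrix(gm$calls[si, mi, drop = FALSE], gm$map[mi, , drop = FALSE],
              gm$samples[si])
}

#' Per-SNP allele frequency of the counted (A2) allele
#'
#' @param gm A `geno_matrix`.
#' @param samples Optional sample ids to restrict to.
#' @return Tibble: `id`, `chrom`, `pos_bp`, `n_called`, `freq_a2`, `maf`.
#' @export
allele_freq <- function(gm, samples = NULL) {
  if (!is.null(samples)) gm <- subset_geno(gm, samples = samples)
  n_called <- colSums(!is.na(gm$calls))
  freq <- colSums(gm$calls, na.rm = TRUE) / (2 * pmax(n_called, 1L))
  freq[n_called == 0] <- NA_real_
  dplyr::mutate(gm$map[, c("id", "chrom", "pos_bp")],
                n_called = as.integer(n_called),
                freq_a2 = unname(freq),
                maf = pmin(.data$freq_a2, 1 - .data$freq_a2))
}

valid_alleles <- c("A", "C", "G", "T", "0")

#' Read PLINK text PED/MAP files into a genotype matrix
#'
#' Parses the classic whitespace-separated PLINK text formats: a MAP file with
#' four columns (chromosome, SNP id, genetic position, bp position) and a PED
#' file with six leading columns (FID, IID, PAT, MAT, SEX, PHENO) followed by
#' two allele symbols per SNP. Genotypes are recoded to counts of the A2
#' allele, where A2 is the alphabetically second allele observed at the SNP;
#' `0 0` becomes missing.
#'
#' @param ped_path,map_path Paths to the PED and MAP files.
#' @return A `geno_matrix`. Sample metadata from the six leading PED columns
#'   is attached as attribute `"fam"` (a tibble).
#' @export
read_ped_map <- function(ped_path, map_path) {
  stopifnot(file.exists(ped_path), file.exists(map_path))
  map_lines <- readLines(map_path)
  map_fields <- strsplit(trimws(map_lines), "[ \t]+")
  nf <- lengths(map_fields)
  if (any(nf != 4L)) {
    stop(sprintf("MAP parse error: line %d has %d fields, expected 4",
                 which(nf != 4L)[1], nf[nf != 4L][1]), call. = FALSE)
  }
  mm <- do.call(rbind, map_fields)
  map <- tibble::tibble(id = mm[, 2], chrom = mm[, 1],
                        pos_bp = as.integer(mm[, 4]))
  n_snp <- nrow(map)

  ped_lines <- readLines(ped_path)
  ped_fields <- strsplit(trimws(ped_lines), "[ \t]+")
  nf <- lengths(ped_fields)
  expected <- 6L + 2L * n_snp
  if (any(nf != expected)) {
    stop(sprintf("PED parse error: line %d has %d fields, expected %d",
                 which(nf != expected)[1], nf[nf != expected][1], expected),
         call. = FALSE)
  }
  ped <- do.call(rbind, ped_fields)
  fam <- tibble::tibble(fid = ped[, 1], iid = ped[, 2], pat = ped[, 3],
                        mat = ped[, 4], sex = ped[, 5], pheno = ped[, 6])
  if (anyDuplicated(fam$iid)) stop("duplicate sample ids in PED", call. = FALSE)

  al1 <- ped[, 6L + 2L * seq_len(n_snp) - 1L, drop = FALSE]
  al2 <- ped[, 6L + 2L * seq_len(n_snp), drop = FALSE]
  bad <- matrix(!(al1 %in% valid_alleles) | !(al2 %in% valid_alleles),
                nrow = nrow(al1))
  if (any(bad)) {
    j <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("PED parse error: sample '%s', SNP '%s': allele symbol not in {A,C,G,T,0}",
                 fam$iid[j[1]], map$id[j[2]]), call. = FALSE)
  }
  half_missing <- xor(al1 == "0", al2 == "0")
  if (any(half_missing)) stop("PED parse error: half-missing genotype", call. = FALSE)

  n_samp <- nrow(ped)
  calls <- matrix(NA_integer_, n_samp, n_snp)
  a1 <- a2 <- character(n_snp)
  for (s in seq_len(n_snp)) {
    x <- al1[, s]; y <- al2[, s]
    obs <- sort(unique(c(x[x != "0"], y[y != "0"])))
    if (length(obs) > 2L) {
      stop(sprintf("SNP '%s' has >2 alleles", map$id[s]), call. = FALSE)
    }
    if (length(obs) == 0L) obs <- c("0", "0")
    if (length(obs) == 1L) obs <- c("0", obs)  # monomorphic: A2 = observed
    a1[s] <- obs[1]; a2[s] <- obs[2]
    calls[, s] <- ifelse(x == "0", NA_integer_,
                         (x == a2[s]) + (y == a2[s]))
  }
  map$a1 <- a1
  map$a2 <- a2
  gm <- geno_matrix(calls, map, samples = fam$iid)
  attr(gm, "fam") <- fam
  gm
}

#' Write a genotype matrix to PLINK text PED/MAP files
#'
#' Inverse of [read_ped_map()]: heterozygotes are written `a1 a2`, missing as
#' `0 0`, genetic position as 0. Round-tripping a file written by this
#' function is byte-identical.
#'
#' @param gm A `geno_matrix`.
#' @param ped_path,map_path Output paths.
#' @param fam Optional tibble of the six leading PED columns (default: the
#'   `"fam"` attribute if present, else FID = IID = sample id, rest 0).
#' @return Invisibly, the two paths.
#' @export
write_ped_map <- function(gm, ped_path, map_path, fam = attr(gm, "fam")) {
  stopifnot(inherits(gm, "geno_matrix"))
  if (is.null(fam)) {
    fam <- tibble::tibble(fid = gm$samples, iid = gm$samples,
                          pat = "0", mat = "0", sex = "0", pheno = "0")
  }
  map_out <- sprintf("%s\t%s\t0\t%d", gm$map$chrom, gm$map$id, gm$map$pos_bp)
  writeLines(map_out, map_path)
  a1 <- gm$map$a1; a2 <- gm$map$a2
  rows <- vapply(seq_along(gm$samples), function(i) {
    g <- gm$calls[i, ]
    x <- ifelse(is.na(g), "0", ifelse(g == 0L, a1, ifelse(g == 1L, a1, a2)))
    y <- ifelse(is.na(g), "0", ifelse(g == 0L, a1, a2))
    paste(fam$fid[i], fam$iid[i], fam$pat[i], fam$mat[i], fam$sex[i],
          fam$pheno[i], paste(rbind(x, y), collapse = " "))
  }, character(1))
  writeLines(rows, ped_path)
  invisible(c(ped = ped_path, map = map_path))
}

#' Read a sample metadata (cohort) table
#'
#' Headered TSV with columns `id`, `birth_year`, `focal_genotype`
#' (Wild/Hetero/Mutant/unknown) and `group`.
#'
#' @param path Path to the TSV.
#' @return A tibble (one row per dog).
#' @export
read_cohort_table <- function(path) {
  ct <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          id = readr::col_character(),
                          birth_year = readr::col_integer(),
                          focal_genotype = readr::col_character(),
                          group = readr::col_character()))
  ok <- c("Wild", "Hetero", "Mutant", "unknown")
  bad <- setdiff(unique(ct$focal_genotype), ok)
  if (length(bad)) stop("unknown focal_genotype value(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  ct
}

autosome_chroms <- function(chrom) {
  suppressWarnings(!is.na(as.integer(chrom))) & !(toupper(chrom) %in% c("X", "Y", "XY", "MT", "M"))
}

#' Quality-control filter for a genotype matrix
#'
#' Applies the standard closed-population QC chain in a fixed order: drop
#' non-autosomal markers, then SNPs by missing rate, then samples by missing
#' rate, then SNPs by minor allele frequency. Thresholds follow common
#' practice for SNP-array data in pedigree breeds: missing rates must be
#' below 1% for both loci and individuals, and SNPs with MAF < 0.01 are
#' excluded. Hardy-Weinberg filtering is deliberately not applied (mating in
#' a managed breed is not random).
#'
#' @param gm A `geno_matrix`.
#' @param geno_max Maximum per-SNP missing rate (exclusive; default 0.01).
#' @param mind_max Maximum per-sample missing rate (exclusive; default 0.01).
#' @param maf_min Minimum minor allele frequency (inclusive; default 0.01).
#' @param autosomes_only Drop non-autosomal chromosomes first (default TRUE).
#' @return The filtered `geno_matrix`, with a `"qc_log"` attribute: a tibble
#'   of per-stage SNP/sample counts (in, removed, out).
#' @export
qc_filter <- function(gm, geno_max = 0.01, mind_max = 0.01, maf_min = 0.01,
                      autosomes_only = TRUE) {
  stopifnot(inherits(gm, "geno_matrix"), nrow(gm$map) > 0, length(gm$samples) > 0)
  log <- list()
  note <- function(stage, unit, n_in, n_out) {
    tibble::tibble(stage = stage, unit = unit, n_in = n_in,
                   n_removed = n_in - n_out, n_out = n_out)
  }

  if (autosomes_only) {
    keep <- autosome_chroms(gm$map$chrom)
    log[[length(log) + 1]] <- note("autosomes", "snp", nrow(gm$map), sum(keep))
    gm <- subset_geno(gm, snps = which(keep))
  }
  if (nrow(gm$map) == 0) stop("empty after QC (autosome filter)", call. = FALSE)

  snp_miss <- colMeans(is.na(gm$calls))
  keep <- snp_miss < geno_max
  log[[length(log) + 1]] <- note("snp_missingness", "snp", length(keep), sum(keep))
  if (!any(keep)) stop("empty after QC (SNP missingness)", call. = FALSE)
  gm <- subset_geno(gm, snps = which(keep))

  samp_miss <- rowMeans(is.na(gm$calls))
  keep <- samp_miss < mind_max
  log[[length(log) + 1]] <- note("sample_missingness", "sample", length(keep), sum(keep))
  if (!any(keep)) stop("empty after QC (sample missingness)", call. = FALSE)
  gm <- subset_geno(gm, samples = which(keep))

  maf <- allele_freq(gm)$maf
  keep <- !is.na(maf) & maf >= maf_min
  log[[length(log) + 1]] <- note("maf", "snp", length(keep), sum(keep))
  if (!any(keep)) stop("empty after QC (MAF filter)", call. = FALSE)
  gm <- subset_geno(gm, snps = which(keep))

  attr(gm, "qc_log") <- dplyr::bind_rows(log)
  gm
}

king_components <- function(gm) {
  g <- gm$calls
  het <- (g == 1L); het[is.na(het)] <- FALSE
  hom0 <- (g == 0L); hom0[is.na(hom0)] <- FALSE
  hom2 <- (g == 2L); hom2[is.na(hom2)] <- FALSE
  ok <- !is.na(g)
  storage.mode(het) <- storage.mode(hom0) <- storage.mode(hom2) <-
    storage.mode(ok) <- "double"
  list(
    n_hethet = tcrossprod(het),
    n_opp = tcrossprod(hom0, hom2) + tcrossprod(hom2, hom0),
    het_i = het %*% t(ok),       # het count of row sample over sites shared with col sample
    n_shared = tcrossprod(ok)
  )
}

#' KING-robust kinship between two samples
#'
#' The between-family KING-robust estimator from unphased genotypes over
#' shared non-missing SNPs:
#' \deqn{\phi = \frac{N_{Aa,Aa} - 2 N_{AA,aa}}{N_{Aa}(i) + N_{Aa}(j)}}
#' where \eqn{N_{Aa,Aa}} counts SNPs at which both samples are heterozygous,
#' \eqn{N_{AA,aa}} counts opposite homozygotes, and \eqn{N_{Aa}(\cdot)} are
#' the per-sample heterozygote counts. Duplicates give 0.5, first-degree
#' relatives about 0.25; the estimator is robust to population structure.
#'
#' @param gm A `geno_matrix`.
#' @param i,j Sample ids (or indices).
#' @param min_shared Minimum shared non-missing SNPs required (default 100).
#' @return The kinship estimate `phi` (scalar; `NA` if no heterozygous sites).
#' @export
king_kinship <- function(gm, i, j, min_shared = 100) {
  stopifnot(inherits(gm, "geno_matrix"))
  if (is.character(i)) i <- match(i, gm$samples)
  if (is.character(j)) j <- match(j, gm$samples)
  stopifnot(!is.na(i), !is.na(j))
  gi <- gm$calls[i, ]; gj <- gm$calls[j, ]
  ok <- !is.na(gi) & !is.na(gj)
  if (sum(ok) < min_shared) {
    stop(sprintf("only %d shared non-missing SNPs (need >= %d)", sum(ok), min_shared),
         call. = FALSE)
  }
  gi <- gi[ok]; gj <- gj[ok]
  n_hethet <- sum(gi == 1L & gj == 1L)
  n_opp <- sum((gi == 0L & gj == 2L) | (gi == 2L & gj == 0L))
  denom <- sum(gi == 1L) + sum(gj == 1L)
  if (denom == 0) return(NA_real_)
  (n_hethet - 2 * n_opp) / denom
}

#' All pairwise KING-robust kinships
#'
#' @param gm A `geno_matrix`.
#' @param min_shared Minimum shared non-missing SNPs per pair; pairs below the
#'   floor get `phi = NA`.
#' @return Tibble with one row per unordered pair: `id_i`, `id_j`,
#'   `n_shared`, `phi`.
#' @export
king_kinship_all <- function(gm, min_shared = 100) {
  stopifnot(inherits(gm, "geno_matrix"))
  k <- king_components(gm)
  denom <- k$het_i + t(k$het_i)
  phi <- (k$n_hethet - 2 * k$n_opp) / denom
  phi[denom == 0] <- NA_real_
  phi[k$n_shared < min_shared] <- NA_real_
  idx <- which(upper.tri(phi), arr.ind = TRUE)
  tibble::tibble(id_i = gm$samples[idx[, 1]], id_j = gm$samples[idx[, 2]],
                 n_shared = as.integer(k$n_shared[idx]),
                 phi = phi[idx])
}

#' Prune close relatives by KING kinship
#'
#' Greedy pruning: while any pair exceeds the cutoff, drop the sample
#' involved in the most above-cutoff pairs (ties broken by dropping the
#' higher sample index). The default cutoff 0.176 separates first-degree
#' relatives and duplicates (phi >= ~0.177) from second-degree and beyond.
#'
#' @param gm A `geno_matrix`.
#' @param cutoff Kinship threshold (exclusive; default 0.176).
#' @param min_shared Passed to [king_kinship_all()].
#' @return A list of class `king_prune`: `pairs` (tibble of all pairwise
#'   phis), `kept` and `removed` (character vectors of sample ids).
#' @export
prune_relatives <- function(gm, cutoff = 0.176, min_shared = 100) {
  pairs <- king_kinship_all(gm, min_shared = min_shared)
  kept <- gm$samples
  active <- dplyr::filter(pairs, !is.na(.data$phi), .data$phi > cutoff)
  removed <- character(0)
  while (nrow(active) > 0) {
    counts <- table(factor(c(active$id_i, active$id_j), levels = kept))
    worst <- max(counts)
    cand <- names(counts)[counts == worst]
    drop_id <- cand[which.max(match(cand, gm$samples))]  # tie: higher index
    removed <- c(removed, drop_id)
    kept <- setdiff(kept, drop_id)
    active <- dplyr::filter(active, .data$id_i != drop_id, .data$id_j != drop_id)
  }
  structure(list(pairs = pairs, kept = kept, removed = removed,
                 cutoff = cutoff),
            class = "king_prune")
}

#' @export
print.king_prune <- function(x, ...) {
  cat(sprintf("<king_prune> cutoff %.3f: kept %d, removed %d sample(s)\n",
              x$cutoff, length(x$kept), length(x$removed)))
  invisible(x)
}
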