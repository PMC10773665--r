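#' Principal component analysis of genotypes
#'
#' Standard population-structure PCA: per SNP, calls are mean-centered and
#' variance-standardized by `sqrt(p (1 - p))` where p is the sample allele
#' frequency (Patterson scaling), missing calls are mean-imputed, and
#' zero-variance SNPs are skipped; the eigendecomposition of the resulting
#' sample covariance (GRM) gives the component scores.
#'
#' @param gm A [geno_matrix()].
#' @param group_ids Samples to include (default all).
#' @param k Number of components to return (default 10, capped at n - 1).
#' @return A `geno_pca` object: `scores` tibble (`id`, `PC1`, ...),
#'   `eigenvalues`, `var_explained` (proportions), `n_snps_used`.
#' @export
pca_genotypes <- function(gm, group_ids = NULL, k = 10) {
  if (!is.null(group_ids)) gm <- subset_geno(gm, samples = group_ids)
  n <- length(gm$samples)
  if (n < 3) stop("PCA needs at least 3 samples", call. = FALSE)
  g <- gm$calls
  mu <- colMeans(g, na.rm = TRUE)
  idx <- which(is.na(g))
  if (length(idx)) g[idx] <- mu[(idx - 1) %/% n + 1]
  p <- mu / 2
  sdv <- sqrt(p * (1 - p))
  usable <- sdv > 0
  x <- sweep(g[, usable, drop = FALSE], 2, mu[usable])
  x <- sweep(x, 2, sdv[usable], "/")
  grm <- tcrossprod(x) / sum(usable)
  eig <- eigen(grm, symmetric = TRUE)
  k <- min(k, n - 1)
  ev <- pmax(eig$values, 0)
  scores <- eig$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(k)]), k)
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(
    scores = dplyr::bind_cols(tibble::tibble(id = gm$samples),
                              tibble::as_tibble(scores)),
    eigenvalues = ev[seq_len(k)],
    var_explained = ev[seq_len(k)] / sum(ev),
    n_snps_used = sum(usable)),
    class = "geno_pca")
}

#' @export
print.geno_pca <- function(x, ...) {
  cat(sprintf("<geno_pca> %d samples, %d SNPs; PC1 %.1f%%, PC2 %.1f%% of variance\n",
              nrow(x$scores), x$n_snps_used, 100 * x$var_explained[1],
              100 * x$var_explained[2]))
  invisible(x)
}

#' @rdname pca_genotypes
#' @param x A `geno_pca`.
#' @param ... Unused.
#' @method tidy geno_pca
#' @export
tidy.geno_pca <- function(x, ...) x$scores

#' @rdname pca_genotypes
#' @method glance geno_pca
#' @export
glance.geno_pca <- function(x, ...) {
  tibble::tibble(n_samples = nrow(x$scores), n_snps_used = x$n_snps_used,
                 pc1_var = x$var_explained[1], pc2_var = x$var_explained[2])
}

#' Genotype-state p-distance between two samples
#'
#' Each SNP is one character with three states (hom-ref / het / hom-alt);
#' the distance is the proportion of mismatching characters over shared
#' non-missing SNPs.
#'
#' @param gm A [geno_matrix()].
#' @param i,j Sample ids or indices.
#' @return Scalar in \[0, 1\].
#' @export
p_distance <- function(gm, i, j) {
  if (is.character(i)) i <- match(i, gm$samples)
  if (is.character(j)) j <- match(j, gm$samples)
  gi <- gm$calls[i, ]; gj <- gm$calls[j, ]
  ok <- !is.na(gi) & !is.na(gj)
  if (!any(ok)) stop("no shared non-missing SNPs", call. = FALSE)
  mean(gi[ok] != gj[ok])
}

#' All pairwise genotype p-distances
#'
#' @param gm A [geno_matrix()].
#' @param samples Samples to include (default all).
#' @return Symmetric matrix with zero diagonal, labelled by sample id;
#'   attribute `"metric"` is `"p_distance"`.
#' @export
p_distance_matrix <- function(gm, samples = NULL) {
  if (!is.null(samples)) gm <- subset_geno(gm, samples = samples)
  g <- gm$calls
  ok <- !is.na(g)
  match_sum <- matrix(0, nrow(g), nrow(g))
  for (state in 0:2) {
    s <- (g == state); s[is.na(s)] <- FALSE
    storage.mode(s) <- "double"
    match_sum <- match_sum + tcrossprod(s)
  }
  storage.mode(ok) <- "double"
  shared <- tcrossprod(ok)
  if (any(shared == 0)) stop("sample pair with no shared non-missing SNPs", call. = FALSE)
  d <- 1 - match_sum / shared
  diag(d) <- 0
  dimnames(d) <- list(gm$samples, gm$samples)
  attr(d, "metric") <- "p_distance"
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via `ape::nj`), followed by the standard
#' cleanup for the estimator's occasional negative branch lengths: each
#' negative branch is clamped to zero and the excess transferred to the
#' adjacent branch so path lengths between tips are preserved. On an
#' additive distance matrix the generating tree is recovered exactly.
#'
#' @param dm Symmetric distance matrix with labels (or a `dist`).
#' @return An unrooted `phylo` tree; write with `ape::write.tree()`.
#' @export
nj_tree <- function(dm) {
  if (inherits(dm, "dist")) dm <- as.matrix(dm)
  if (!isSymmetric(unname(dm), tol = 1e-8)) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  if (nrow(dm) < 3) stop("need at least 3 taxa", call. = FALSE)
  tree <- ape::nj(stats::as.dist(dm))
  neg <- which(tree$edge.length < 0)
  for (e in neg) {
    excess <- tree$edge.length[e]           # negative
    parent <- tree$edge[e, 1]
    sibs <- which(tree$edge[, 1] == parent & seq_along(tree$edge.length) != e)
    if (length(sibs)) {
      tree$edge.length[sibs[1]] <- tree$edge.length[sibs[1]] + excess
    }
    tree$edge.length[e] <- 0
  }
  tree
}

#' Nei's standard genetic distance D between two populations
#'
#' From per-locus allele frequency vectors: with normalized gene identities
#' `Jxy = mean_l sum_a x_la y_la`, `Jx = mean_l sum_a x_la^2`, `Jy`
#' likewise, `D = -ln( Jxy / sqrt(Jx Jy) )` (the original 1972 quantities,
#' no small-sample correction).
#'
#' @param freqs_x,freqs_y Loci x alleles matrices of allele frequencies
#'   (rows sum to 1), or numeric vectors of the counted-allele frequency at
#'   biallelic loci.
#' @return Scalar D >= 0.
#' @export
neis_d <- function(freqs_x, freqs_y) {
  if (is.null(dim(freqs_x))) freqs_x <- cbind(1 - freqs_x, freqs_x)
  if (is.null(dim(freqs_y))) freqs_y <- cbind(1 - freqs_y, freqs_y)
  stopifnot(all(dim(freqs_x) == dim(freqs_y)),
            all(abs(rowSums(freqs_x) - 1) < 1e-8),
            all(abs(rowSums(freqs_y) - 1) < 1e-8))
  jxy <- mean(rowSums(freqs_x * freqs_y))
  jx <- mean(rowSums(freqs_x^2))
  jy <- mean(rowSums(freqs_y^2))
  if (jx == 0 || jy == 0) stop("zero gene identity within a population", call. = FALSE)
  -log(jxy / sqrt(jx * jy))
}

#' Nei's D between all groups of a cohort
#'
#' @param gm A [geno_matrix()].
#' @param cohort Metadata tibble with `id` and `group`.
#' @return Symmetric matrix of Nei's D between groups, attribute `"metric"`
#'   = `"neis_D"`.
#' @export
neis_d_matrix <- function(gm, cohort) {
  cohort <- dplyr::filter(cohort, .data$id %in% gm$samples)
  groups <- sort(unique(cohort$group))
  freqs <- lapply(groups, function(g) {
    allele_freq(gm, samples = cohort$id[cohort$group == g])$freq_a2
  })
  d <- matrix(0, length(groups), length(groups),
              dimnames = list(groups, groups))
  for (i in seq_along(groups)) {
    for (j in seq_len(i - 1L)) {
      ok <- !is.na(freqs[[i]]) & !is.na(freqs[[j]])
      d[i, j] <- d[j, i] <- neis_d(freqs[[i]][ok], freqs[[j]][ok])
    }
  }
  attr(d, "metric") <- "neis_D"
  d
}

#' LD-based contemporary effective population size
#'
#' The Waples (2006) linkage-disequilibrium method as implemented for
#' unphased diploid genotypes: for locus pairs on different chromosomes
#' (physically unlinked) with MAF at or above `maf_floor`, squared
#' correlation is computed from Burrows' composite disequilibrium with
#' Weir's small-sample correction,
#' `r^2 = (S/(S-1) cov(X, Y)/2)^2 / (p_A(1-p_A) p_B(1-p_B))`; the mean over
#' pairs is
#' corrected for the expected sampling contribution (`1/S + 3.19/S^2` for
#' S >= 30, else `0.0018 + 0.907/S + 4.44/S^2`), and the bias-corrected
#' drift signal `r2'` is inverted to
#' `Ne = (1/3 + sqrt(1/9 - 2.76 r2'))/(2 r2')` (random-mating model; the
#' small-S variant uses the 0.308/2.08 coefficients). A non-positive drift
#' signal means no detectable LD beyond sampling: Ne is reported infinite.
#' The parametric CI treats `n_pairs * mean_r2 / E[r2]` as chi-squared
#' (a simplification of the usual locus-pair CI; independent pairs
#' assumed).
#'
#' @param gm A [geno_matrix()].
#' @param group_ids Samples of the group (default all); at least 10.
#' @param maf_floor Minimum within-group MAF (default 0.01).
#' @param max_snps SNP cap; if exceeded, a seeded subsample is used to bound
#'   the pair count (default 2000, about 1.5e6 inter-chromosome pairs at 4
#'   chromosomes).
#' @param conf Confidence level for the parametric CI.
#' @param seed Seed for the SNP subsample.
#' @return One-row tibble: `s` (sample size), `n_snps`, `n_pairs`,
#'   `r2_mean`, `r2_sample_exp`, `r2_drift`, `ne_hat` (may be `Inf`),
#'   `ne_low`, `ne_high`.
#' @export
ld_ne <- function(gm, group_ids = NULL, maf_floor = 0.01, max_snps = 2000,
                  conf = 0.95, seed = 1L) {
  if (!is.null(group_ids)) gm <- subset_geno(gm, samples = group_ids)
  s <- length(gm$samples)
  if (s < 10) stop("LD-Ne needs at least 10 individuals", call. = FALSE)
  af <- allele_freq(gm)
  keep <- which(!is.na(af$maf) & af$maf >= maf_floor)
  if (length(unique(gm$map$chrom[keep])) < 2) {
    stop("LD-Ne needs SNPs on at least 2 chromosomes (unlinked pairs)", call. = FALSE)
  }
  if (length(keep) > max_snps) {
    set.seed(seed)
    keep <- sort(keep[sample.int(length(keep), max_snps)])
  }
  gm <- subset_geno(gm, snps = keep)
  g <- gm$calls
  storage.mode(g) <- "double"
  # Burrows composite covariance with Weir's S/(S-1) small-sample correction;
  # with it, the pure-sampling expectation of r^2 matches the Waples term
  cv <- stats::cov(g, use = "pairwise.complete.obs") * s / (s - 1)
  p <- colMeans(g, na.rm = TRUE) / 2
  v <- p * (1 - p)
  r2 <- (cv / 2)^2 / outer(v, v)
  inter <- outer(gm$map$chrom, gm$map$chrom, "!=") & upper.tri(r2)
  vals <- r2[inter]
  vals <- vals[is.finite(vals)]
  n_pairs <- length(vals)
  r2_mean <- mean(vals)
  e_samp <- if (s >= 30) 1 / s + 3.19 / s^2 else 0.0018 + 0.907 / s + 4.44 / s^2
  r2_drift <- r2_mean - e_samp

  invert <- function(r2p) {
    if (is.na(r2p) || r2p <= 0) return(Inf)
    if (s >= 30) {
      (1 / 3 + sqrt(max(0, 1 / 9 - 2.76 * r2p))) / (2 * r2p)
    } else {
      (0.308 + sqrt(max(0, 0.308^2 - 2.08 * r2p))) / (2 * r2p)
    }
  }
  ne_hat <- invert(r2_drift)
  alpha <- 1 - conf
  # chi-squared parametric interval on the mean r2, then invert
  r2_lo <- r2_mean * n_pairs / stats::qchisq(1 - alpha / 2, df = n_pairs)
  r2_hi <- r2_mean * n_pairs / stats::qchisq(alpha / 2, df = n_pairs)
  tibble::tibble(s = s, n_snps = nrow(gm$map), n_pairs = n_pairs,
                 r2_mean = r2_mean, r2_sample_exp = e_samp,
                 r2_drift = r2_drift, ne_hat = ne_hat,
                 ne_low = invert(r2_hi - e_samp),
                 ne_high = invert(r2_lo - e_samp))
}

#' LD-Ne per group
#'
#' @param gm A [geno_matrix()].
#' @param cohort Metadata tibble with `id` and `group`.
#' @param ... Passed to [ld_ne()].
#' @return Tibble with one row per group (groups below 10 dogs are skipped
#'   with a message).
#' @export
ld_ne_by_group <- function(gm, cohort, ...) {
  cohort <- dplyr::filter(cohort, .data$id %in% gm$samples)
  out <- list()
  for (g in sort(unique(cohort$group))) {
    ids <- cohort$id[cohort$group == g]
    if (length(ids) < 10) {
      message(sprintf("ld_ne_by_group: skipping group '%s' (n = %d < 10)", g, length(ids)))
      next
    }
    out[[g]] <- dplyr::mutate(ld_ne(gm, group_ids = ids, ...), group = g,
                              .before = 1)
  }
  dplyr::bind_rows(out)
}
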