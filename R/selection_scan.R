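wc_group_stats <- function(calls) {
  ok <- !is.na(calls)
  n <- colSums(ok)
  p <- colSums(calls, na.rm = TRUE) / (2 * pmax(n, 1L))
  h <- colSums(calls == 1L, na.rm = TRUE) / pmax(n, 1L)
  list(n = n, p = p, h = h)
}

#' Per-SNP Weir-Cockerham F_ST between two groups
#'
#' The 1984 variance-components estimator for two populations, computed per
#' SNP on complete cases within each group: with per-group sample sizes
#' `n_i`, counted-allele frequencies `p_i` and observed heterozygote
#' proportions `h_i`, the among-population (`a`), among-individual-within
#' (`b`) and within-individual (`c`) components give `fst = a/(a+b+c)`.
#' Small negative values are a known property of the estimator and are kept;
#' SNPs with `a+b+c = 0` (e.g. monomorphic across both groups) or fewer than
#' two genotyped samples in either group get `fst = NA`.
#'
#' @param gm A [geno_matrix()].
#' @param group_a_ids,group_b_ids Sample ids of the two groups.
#' @return Tibble per SNP: `id`, `chrom`, `pos_bp`, `n_a`, `n_b`, `p_a`,
#'   `p_b`, `a`, `b`, `c`, `fst`.
#' @export
wc_fst <- function(gm, group_a_ids, group_b_ids) {
  stopifnot(inherits(gm, "geno_matrix"),
            length(group_a_ids) > 0, length(group_b_ids) > 0)
  ga <- subset_geno(gm, samples = group_a_ids)$calls
  gb <- subset_geno(gm, samples = group_b_ids)$calls
  s1 <- wc_group_stats(ga)
  s2 <- wc_group_stats(gb)
  n1 <- s1$n; n2 <- s2$n
  nbar <- (n1 + n2) / 2
  nsum <- n1 + n2
  nc <- nsum - (n1^2 + n2^2) / nsum            # (sum n - sum n^2 / sum n) / (r - 1), r = 2
  pbar <- (n1 * s1$p + n2 * s2$p) / nsum
  s2v <- (n1 * (s1$p - pbar)^2 + n2 * (s2$p - pbar)^2) / nbar
  hbar <- (n1 * s1$h + n2 * s2$h) / nsum

  a <- nbar / nc * (s2v - (pbar * (1 - pbar) - s2v / 2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - s2v / 2 -
                              (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  denom <- a + b + cc
  fst <- a / denom
  bad <- n1 < 2 | n2 < 2 | denom == 0 | !is.finite(fst)
  a[n1 < 2 | n2 < 2] <- NA_real_
  b[n1 < 2 | n2 < 2] <- NA_real_
  cc[n1 < 2 | n2 < 2] <- NA_real_
  fst[bad] <- NA_real_
  dplyr::mutate(gm$map[, c("id", "chrom", "pos_bp")],
                n_a = as.integer(n1), n_b = as.integer(n2),
                p_a = unname(s1$p), p_b = unname(s2$p),
                a = unname(a), b = unname(b), c = unname(cc),
                fst = unname(fst))
}

#' Flag the upper tail of an F_ST scan
#'
#' Flags SNPs at or above the `1 - top_fraction` empirical quantile of the
#' defined F_ST values, using a ceiling rule on the flag count (`k =
#' ceiling(top_fraction * n_defined)`) and keeping all SNPs tied at the
#' threshold. The top-ranked SNP is attached as attribute `"top_snp"`.
#'
#' @param fst A [wc_fst()] tibble.
#' @param top_fraction Upper-tail fraction to flag (default 0.001).
#' @return The input tibble with a logical `flagged` column, plus attributes
#'   `"threshold"` and `"top_snp"` (one-row tibble).
#' @export
rank_scan <- function(fst, top_fraction = 0.001) {
  stopifnot(top_fraction > 0, top_fraction < 1)
  vals <- fst$fst[!is.na(fst$fst)]
  if (length(vals) == 0) stop("no defined F_ST values to rank", call. = FALSE)
  k <- ceiling(top_fraction * length(vals))
  threshold <- sort(vals, decreasing = TRUE)[k]
  out <- dplyr::mutate(fst, flagged = !is.na(.data$fst) & .data$fst >= threshold)
  attr(out, "threshold") <- threshold
  attr(out, "top_snp") <- out[which.max(out$fst), , drop = FALSE]
  out
}

#' Read/write phased haplotypes
#'
#' Plain-text transposed-haplotype format: one row per haplotype, 0/1
#' alleles separated by spaces; columns follow the accompanying marker map.
#' Two consecutive rows belong to one individual.
#'
#' @param path File path.
#' @return `read_haplotypes`: integer matrix (haplotypes x SNPs).
#' @export
read_haplotypes <- function(path) {
  stopifnot(file.exists(path))
  rows <- strsplit(trimws(readLines(path)), "[ \t]+")
  nf <- lengths(rows)
  if (length(unique(nf)) != 1) {
    stop(sprintf("haplotype parse error: line %d has %d fields, expected %d",
                 which(nf != nf[1])[1], nf[nf != nf[1]][1], nf[1]), call. = FALSE)
  }
  m <- do.call(rbind, lapply(rows, as.integer))
  if (any(is.na(m)) || any(!m %in% c(0L, 1L))) {
    stop("haplotype parse error: alleles must be 0/1", call. = FALSE)
  }
  m
}

#' @rdname read_haplotypes
#' @param haps Integer matrix of 0/1 alleles (haplotypes x SNPs).
#' @export
write_haplotypes <- function(haps, path) {
  writeLines(apply(haps, 1, paste, collapse = " "), path)
  invisible(path)
}

#' Extended haplotype homozygosity around a core SNP
#'
#' For the haplotypes carrying `core_allele` at the core SNP, EHH at a
#' flanking SNP x is the probability that two randomly drawn carrier
#' haplotypes are identical over the whole interval between the core and x:
#' grouping the n carriers by their sequence over `[core, x]`,
#' `ehh(x) = sum_h C(n_h, 2) / C(n, 2)`. EHH is 1 at the core and
#' non-increasing with distance on each side; it is evaluated at marker
#' positions only, within a window around the core.
#'
#' @param haps Integer 0/1 matrix, one row per phased haplotype; columns
#'   follow `map`.
#' @param map Marker tibble (`id`, `chrom`, `pos_bp`) for the columns of
#'   `haps` (one chromosome).
#' @param core_snp SNP id of the core marker.
#' @param core_allele Core allele (0 or 1) whose carriers are followed.
#' @param window_bp Half-window around the core in bp (default 1e6).
#' @return Tibble: `id`, `pos_bp`, `distance_bp` (signed), `ehh`; class
#'   `ehh_curve` with attributes `core_snp`, `core_allele`, `n_carriers`.
#' @export
ehh <- function(haps, map, core_snp, core_allele, window_bp = 1e6) {
  stopifnot(ncol(haps) == nrow(map), length(unique(map$chrom)) == 1)
  core <- match(core_snp, map$id)
  if (is.na(core)) stop("core SNP not in map: ", core_snp, call. = FALSE)
  carriers <- which(haps[, core] == core_allele)
  n <- length(carriers)
  if (n < 2) stop("fewer than 2 haplotypes carry the core allele", call. = FALSE)
  h <- haps[carriers, , drop = FALSE]
  core_pos <- map$pos_bp[core]
  in_win <- abs(map$pos_bp - core_pos) <= window_bp
  pairs_total <- choose(n, 2)

  side_ehh <- function(idx) {  # idx: column indices walking away from the core
    out <- numeric(length(idx))
    grp <- rep(1L, n)
    for (k in seq_along(idx)) {
      grp <- as.integer(factor(grp * 2L + h[, idx[k]]))
      out[k] <- sum(choose(tabulate(grp), 2)) / pairs_total
    }
    out
  }

  right <- which(in_win & seq_len(nrow(map)) > core)
  left <- rev(which(in_win & seq_len(nrow(map)) < core))
  out <- tibble::tibble(
    id = c(map$id[rev(left)], map$id[core], map$id[right]),
    pos_bp = c(map$pos_bp[rev(left)], core_pos, map$pos_bp[right]),
    ehh = c(rev(side_ehh(left)), 1, side_ehh(right)))
  out$distance_bp <- out$pos_bp - core_pos
  out <- out[, c("id", "pos_bp", "distance_bp", "ehh")]
  attr(out, "core_snp") <- core_snp
  attr(out, "core_allele") <- core_allele
  attr(out, "n_carriers") <- n
  class(out) <- c("ehh_curve", class(out))
  out
}

#' Default core-allele choice for EHH
#'
#' Without an outgroup the derived allele is unknowable; the convention here
#' is the allele that is more common in the later cohort (the one presumed
#' favoured or hitchhiking after selection). Override by passing
#' `core_allele` to [ehh()] explicitly.
#'
#' @param haps Haplotype matrix for the later cohort.
#' @param map Marker map matching `haps`.
#' @param core_snp Core SNP id.
#' @return 0 or 1.
#' @export
default_core_allele <- function(haps, map, core_snp) {
  core <- match(core_snp, map$id)
  if (is.na(core)) stop("core SNP not in map: ", core_snp, call. = FALSE)
  as.integer(mean(haps[, core]) >= 0.5)
}
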