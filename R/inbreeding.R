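#' Observed heterozygosity of a group
#'
#' Ho = mean over SNPs of the heterozygote fraction among non-missing calls.
#' SNPs with no non-missing call in the group are skipped (their count is
#' attached as attribute `"n_skipped"`).
#'
#' @param gm A [geno_matrix()].
#' @param group_ids Sample ids to include (default all).
#' @return Scalar Ho.
#' @export
observed_het <- function(gm, group_ids = NULL) {
  if (!is.null(group_ids)) gm <- subset_geno(gm, samples = group_ids)
  if (length(gm$samples) == 0) stop("empty group", call. = FALSE)
  n_called <- colSums(!is.na(gm$calls))
  het <- colSums(gm$calls == 1L, na.rm = TRUE)
  usable <- n_called > 0
  ho <- mean(het[usable] / n_called[usable])
  attr(ho, "n_skipped") <- sum(!usable)
  ho
}

#' Observed heterozygosity per group
#'
#' @param gm A [geno_matrix()].
#' @param cohort Metadata tibble with `id` and `group`.
#' @return Tibble: `group`, `n`, `ho`.
#' @export
ho_by_group <- function(gm, cohort) {
  cohort |>
    dplyr::filter(.data$id %in% gm$samples) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = dplyr::n(),
                     ho = as.numeric(observed_het(gm, .data$id)),
                     .groups = "drop")
}

#' Detect runs of homozygosity (consecutive-SNP method)
#'
#' Scans each chromosome of each sample for maximal stretches of consecutive
#' homozygous calls, allowing up to `max_het` heterozygous and `max_miss`
#' missing calls inside a run (defaults 0) and breaking the run whenever the
#' gap between adjacent SNPs exceeds `max_gap`. A candidate stretch is
#' reported as a run only if it satisfies all of: at least `min_snp` SNPs,
#' span (`end - start + 1`) at least `min_length_bp`, and SNP density
#' `n_snps / length_bp` at least `min_density`. Runs always start and end on
#' a homozygous SNP. The default thresholds (41 SNPs, 1 Mb gap, 50 kb,
#' 1/5000 per bp) are standard for ~150k-SNP canine array data.
#'
#' @param gm A [geno_matrix()]; the map must be position-sorted within each
#'   chromosome.
#' @param sample_ids Samples to scan (default all).
#' @param min_snp Minimum SNPs per run (default 41).
#' @param max_gap Maximum adjacent-SNP gap inside a run, bp (default 1e6).
#' @param min_length_bp Minimum run span, bp (default 5e4).
#' @param min_density Minimum SNPs per bp (default 1/5000).
#' @param max_het Heterozygous calls tolerated inside a run (default 0).
#' @param max_miss Missing calls tolerated inside a run (default 0).
#' @return Tibble, one row per run: `id`, `chrom`, `start_bp`, `end_bp`,
#'   `n_snps`, `length_bp`, in coordinate order per sample.
#' @export
detect_roh <- function(gm, sample_ids = NULL, min_snp = 41, max_gap = 1e6,
                       min_length_bp = 5e4, min_density = 1 / 5000,
                       max_het = 0, max_miss = 0) {
  stopifnot(inherits(gm, "geno_matrix"))
  if (is.null(sample_ids)) sample_ids <- gm$samples
  by_chrom <- split(seq_len(nrow(gm$map)), gm$map$chrom)
  for (idx in by_chrom) {
    if (is.unsorted(gm$map$pos_bp[idx], strictly = TRUE)) {
      stop("marker map not position-sorted within chromosome ",
           gm$map$chrom[idx[1]], call. = FALSE)
    }
  }
  out <- list()
  for (sid in sample_ids) {
    g <- gm$calls[match(sid, gm$samples), ]
    for (chrom in names(by_chrom)) {
      idx <- by_chrom[[chrom]]
      pos <- gm$map$pos_bp[idx]
      calls <- g[idx]
      runs <- scan_chrom_runs(calls, pos, max_gap, max_het, max_miss)
      if (nrow(runs) == 0) next
      runs$length_bp <- runs$end_bp - runs$start_bp + 1
      keep <- runs$n_snps >= min_snp &
        runs$length_bp >= min_length_bp &
        runs$n_snps / runs$length_bp >= min_density
      runs <- runs[keep, , drop = FALSE]
      if (nrow(runs) == 0) next
      runs$id <- sid
      runs$chrom <- chrom
      out[[length(out) + 1]] <- runs
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(id = character(), chrom = character(),
                          start_bp = integer(), end_bp = integer(),
                          n_snps = integer(), length_bp = numeric()))
  }
  dplyr::bind_rows(out)[, c("id", "chrom", "start_bp", "end_bp", "n_snps", "length_bp")]
}

# greedy consecutive scan of one sample x chromosome; returns candidate runs
# (start/end indices trimmed to homozygous SNPs) before threshold filtering
scan_chrom_runs <- function(calls, pos, max_gap, max_het, max_miss) {
  m <- length(calls)
  state <- ifelse(is.na(calls), "miss", ifelse(calls == 1L, "het", "hom"))
  starts <- integer(0); ends <- integer(0); nsnps <- integer(0)
  i <- 1L
  while (i <= m) {
    if (state[i] != "hom") { i <- i + 1L; next }
    # open a run at a homozygous SNP
    j <- i
    het_used <- 0L; miss_used <- 0L
    last_hom <- i
    while (j < m) {
      nxt <- j + 1L
      if (pos[nxt] - pos[j] > max_gap) break
      s <- state[nxt]
      if (s == "het") {
        if (het_used + 1L > max_het) break
        het_used <- het_used + 1L
      } else if (s == "miss") {
        if (miss_used + 1L > max_miss) break
        miss_used <- miss_used + 1L
      } else {
        last_hom <- nxt
      }
      j <- nxt
    }
    starts <- c(starts, i)
    ends <- c(ends, last_hom)
    nsnps <- c(nsnps, last_hom - i + 1L)
    i <- j + 1L
  }
  tibble::tibble(start_bp = pos[starts], end_bp = pos[ends], n_snps = nsnps)
}

#' Span of the genotyped genome
#'
#' Sum over chromosomes of (last SNP position - first SNP position + 1): the
#' denominator for F_ROH, matched to the genotyped genome rather than the
#' assembly length.
#'
#' @param gm A [geno_matrix()].
#' @return Scalar bp.
#' @export
genome_span <- function(gm) {
  sum(vapply(split(gm$map$pos_bp, gm$map$chrom),
             function(p) max(p) - min(p) + 1, numeric(1)))
}

#' Genomic inbreeding coefficient F_ROH per sample
#'
#' F_ROH = total ROH length / genotyped genome span. Samples present in the
#' genotype matrix but without any run get F_ROH = 0.
#'
#' @param runs A [detect_roh()] tibble.
#' @param gm The `geno_matrix` the runs came from (supplies the sample list
#'   and the span), or a numeric `genome_span` with `sample_ids` given.
#' @param sample_ids Optional explicit sample list.
#' @return Tibble: `id`, `n_roh`, `roh_total_bp`, `f_roh`.
#' @export
f_roh <- function(runs, gm, sample_ids = NULL) {
  if (inherits(gm, "geno_matrix")) {
    span <- genome_span(gm)
    if (is.null(sample_ids)) sample_ids <- gm$samples
  } else {
    span <- as.numeric(gm)
    if (is.null(sample_ids)) sample_ids <- unique(runs$id)
  }
  stopifnot(span > 0)
  per <- runs |>
    dplyr::group_by(id = .data$id) |>
    dplyr::summarise(n_roh = dplyr::n(),
                     roh_total_bp = sum(.data$length_bp), .groups = "drop")
  tibble::tibble(id = sample_ids) |>
    dplyr::left_join(per, by = "id") |>
    tidyr::replace_na(list(n_roh = 0L, roh_total_bp = 0)) |>
    dplyr::mutate(f_roh = .data$roh_total_bp / span)
}

#' Group summaries and pairwise Welch tests for F_ROH
#'
#' @param froh A [f_roh()] tibble.
#' @param cohort Metadata tibble with `id` and `group`.
#' @return List of two tibbles: `summary` (`group`, `n`, `mean_f_roh`,
#'   `sd_f_roh`) and `tests` (pairwise Welch's t-test: `group_a`, `group_b`,
#'   `t`, `df`, `p_value`; groups with fewer than 2 dogs are skipped).
#' @export
froh_group_summary <- function(froh, cohort) {
  joined <- dplyr::inner_join(froh, cohort[, c("id", "group")], by = "id")
  summ <- joined |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = dplyr::n(), mean_f_roh = mean(.data$f_roh),
                     sd_f_roh = stats::sd(.data$f_roh), .groups = "drop")
  groups <- summ$group
  tests <- list()
  if (length(groups) >= 2) {
    for (i in seq_len(length(groups) - 1)) {
      for (j in seq(i + 1, length(groups))) {
        xa <- joined$f_roh[joined$group == groups[i]]
        xb <- joined$f_roh[joined$group == groups[j]]
        if (length(xa) < 2 || length(xb) < 2) next
        tt <- stats::t.test(xa, xb)  # Welch by default
        tests[[length(tests) + 1]] <- tibble::tibble(
          group_a = groups[i], group_b = groups[j],
          t = unname(tt$statistic), df = unname(tt$parameter),
          p_value = tt$p.value)
      }
    }
  }
  list(summary = summ,
       tests = if (length(tests)) dplyr::bind_rows(tests) else
         tibble::tibble(group_a = character(), group_b = character(),
                        t = numeric(), df = numeric(), p_value = numeric()))
}
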