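#' Genotype-frequency trend plot
#'
#' Stacked genotype frequencies per birth year with the mutant allele
#' frequency overlaid.
#'
#' @param trend A [build_trend()] (optionally [trend_ci()]) tibble.
#' @return A ggplot.
#' @export
plot_trend <- function(trend) {
  long <- trend |>
    dplyr::select("birth_year", "freq_wild", "freq_hetero", "freq_mutant") |>
    tidyr::pivot_longer(-"birth_year", names_to = "genotype",
                        names_prefix = "freq_", values_to = "freq") |>
    dplyr::mutate(genotype = factor(.data$genotype,
                                    levels = c("mutant", "hetero", "wild"),
                                    labels = c("Mutant", "Hetero", "Wild")))
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$birth_year, .data$freq,
                                          fill = .data$genotype)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::geom_line(data = trend,
                       ggplot2::aes(.data$birth_year, .data$q),
                       inherit.aes = FALSE, linewidth = 0.8) +
    ggplot2::labs(x = "Birth year", y = "Frequency", fill = "Genotype") +
    ggplot2::theme_minimal()
  if ("q_low" %in% names(trend)) {
    p <- p + ggplot2::geom_ribbon(
      data = trend,
      ggplot2::aes(.data$birth_year, ymin = .data$q_low, ymax = .data$q_high),
      inherit.aes = FALSE, alpha = 0.2)
  }
  p
}

#' Drift-null trajectory plot
#'
#' Simulated frequency band (2.5/97.5% quantiles) with optional observed
#' frequencies overlaid.
#'
#' @param object A `drift_sim`.
#' @param observed Optional tibble with `generation` and `q`.
#' @param n_spaghetti Individual trajectories to draw (default 100).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot drift_sim
#' @export
autoplot.drift_sim <- function(object, observed = NULL, n_spaghetti = 100, ...) {
  band <- tidy.drift_sim(object)
  idx <- seq_len(min(n_spaghetti, object$replicates))
  spag <- tibble::tibble(
    replicate = rep(idx, each = object$generations + 1),
    generation = rep(0:object$generations, length(idx)),
    q = as.vector(t(object$trajectories[idx, , drop = FALSE])))
  p <- ggplot2::ggplot(band, ggplot2::aes(.data$generation)) +
    ggplot2::geom_line(data = spag,
                       ggplot2::aes(y = .data$q, group = .data$replicate),
                       alpha = 0.05, colour = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$q2.5), linetype = "dashed",
                       colour = "blue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$q97.5), linetype = "dashed",
                       colour = "blue") +
    ggplot2::labs(x = "Generation", y = "Allele frequency") +
    ggplot2::theme_minimal()
  if (!is.null(observed)) {
    p <- p + ggplot2::geom_line(data = observed,
                                ggplot2::aes(.data$generation, .data$q),
                                colour = "darkorange", linewidth = 1)
  }
  p
}

#' Manhattan plot of an F_ST scan
#'
#' @param fst A [wc_fst()] (optionally [rank_scan()]) tibble.
#' @return A ggplot; flagged SNPs (if present) drawn in red.
#' @export
plot_fst_scan <- function(fst) {
  fst <- dplyr::filter(fst, !is.na(.data$fst))
  p <- ggplot2::ggplot(fst, ggplot2::aes(.data$pos_bp / 1e6, .data$fst)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = "Position (Mb)", y = expression(F[ST])) +
    ggplot2::theme_minimal()
  if ("flagged" %in% names(fst)) {
    p <- p + ggplot2::geom_point(data = dplyr::filter(fst, .data$flagged),
                                 colour = "red", size = 0.8)
  }
  p
}

#' EHH decay plot
#'
#' @param object An [ehh()] curve, or several row-bound with a `group`
#'   column.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ehh_curve
#' @export
autoplot.ehh_curve <- function(object, ...) {
  aes <- if ("group" %in% names(object)) {
    ggplot2::aes(.data$distance_bp / 1e3, .data$ehh, colour = .data$group)
  } else {
    ggplot2::aes(.data$distance_bp / 1e3, .data$ehh)
  }
  ggplot2::ggplot(object, aes) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Distance from core SNP (kb)", y = "EHH") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' F_ROH group plot
#'
#' @param froh A [f_roh()] tibble.
#' @param cohort Metadata tibble with `id` and `group`.
#' @return A ggplot (boxplot + jitter per group).
#' @export
plot_froh <- function(froh, cohort) {
  joined <- dplyr::inner_join(froh, cohort[, c("id", "group")], by = "id")
  ggplot2::ggplot(joined, ggplot2::aes(.data$group, .data$f_roh)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 0.8) +
    ggplot2::labs(x = NULL, y = expression(F[ROH])) +
    ggplot2::theme_minimal()
}

#' PCA scores plot
#'
#' @param object A `geno_pca`.
#' @param cohort Optional metadata tibble with `id` and `group` for
#'   colouring.
#' @param ... Unused.
#' @return A ggplot of PC1 vs PC2.
#' @method autoplot geno_pca
#' @export
autoplot.geno_pca <- function(object, cohort = NULL, ...) {
  sc <- object$scores
  if (!is.null(cohort)) {
    sc <- dplyr::inner_join(sc, cohort[, c("id", "group")], by = "id")
    aes <- ggplot2::aes(.data$PC1, .data$PC2, colour = .data$group)
  } else {
    aes <- ggplot2::aes(.data$PC1, .data$PC2)
  }
  ggplot2::ggplot(sc, aes) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$var_explained[2])) +
    ggplot2::theme_minimal()
}
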