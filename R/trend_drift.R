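#' Round half away from zero
#'
#' Commercial rounding (0.5 always rounds up in magnitude), unlike base
#' `round()`'s round-half-to-even. Used wherever a reported percentage or a
#' head count is derived.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Breeding-stock effective size from registration counts
#'
#' A coarse census-based effective size: the share of registered dogs used
#' for breeding. With the default 10% breeding fraction, 5,395 registered
#' dogs give Ne = 540.
#'
#' @param n_registered Registered dogs in the reference year.
#' @param breeding_fraction Share used for breeding (default 0.10).
#' @return Integer Ne (round-half-up).
#' @export
breeding_ne <- function(n_registered, breeding_fraction = 0.1) {
  as.integer(round_half_up(n_registered * breeding_fraction))
}

#' Genotype and allele frequency trend by birth year
#'
#' Tabulates focal-locus diploid genotypes (Wild / Hetero / Mutant) per birth
#' year and derives genotype frequencies and the mutant allele frequency
#' `q = (2 n_mutant + n_hetero) / (2 n_total)`. Rows with unknown genotype
#' are excluded (their count is attached as attribute `"n_unknown"` and
#' reported via a message); years with no classified dogs are omitted.
#'
#' @param cohort Tibble with at least `birth_year` and `focal_genotype`.
#' @return Tibble: `birth_year`, `n_wild`, `n_hetero`, `n_mutant`, `n_total`,
#'   `freq_wild`, `freq_hetero`, `freq_mutant`, `q`.
#' @export
build_trend <- function(cohort) {
  stopifnot(all(c("birth_year", "focal_genotype") %in% names(cohort)))
  known <- c("Wild", "Hetero", "Mutant")
  n_unknown <- sum(!cohort$focal_genotype %in% known)
  if (n_unknown > 0) {
    message(sprintf("build_trend: excluded %d dog(s) with unknown focal genotype", n_unknown))
  }
  tt <- cohort |>
    dplyr::filter(.data$focal_genotype %in% known) |>
    dplyr::count(.data$birth_year, .data$focal_genotype) |>
    tidyr::pivot_wider(names_from = "focal_genotype", values_from = "n",
                       values_fill = 0L) |>
    dplyr::arrange(.data$birth_year)
  for (g in known) if (!g %in% names(tt)) tt[[g]] <- 0L
  tt <- tt |>
    dplyr::transmute(
      birth_year = .data$birth_year,
      n_wild = .data$Wild, n_hetero = .data$Hetero, n_mutant = .data$Mutant,
      n_total = .data$Wild + .data$Hetero + .data$Mutant,
      freq_wild = .data$n_wild / .data$n_total,
      freq_hetero = .data$n_hetero / .data$n_total,
      freq_mutant = .data$n_mutant / .data$n_total,
      q = (2 * .data$n_mutant + .data$n_hetero) / (2 * .data$n_total)) |>
    dplyr::filter(.data$n_total > 0)
  attr(tt, "n_unknown") <- n_unknown
  tt
}

#' Fisher's exact test on an r x c contingency table
#'
#' Two-sided exact p-value (sum of probabilities of all tables with the same
#' margins whose probability does not exceed the observed table's). Tables
#' beyond the exact-enumeration budget are handled by Monte-Carlo with a
#' reported standard error. A table with a zero margin carries no
#' information: p = 1 by convention, flagged in `method`.
#'
#' @param table Matrix of non-negative integer counts.
#' @param max_exact_n Largest table total handled exactly for tables bigger
#'   than 2 x 2 (default 500).
#' @param b Monte-Carlo replicates when sampling is needed (default 1e5).
#' @param seed Optional seed for the Monte-Carlo path.
#' @return One-row tibble: `p_value`, `method` (`"exact"`, `"monte_carlo"`
#'   or `"degenerate_margin"`), `mc_se` (`NA` unless Monte-Carlo).
#' @export
fisher_exact <- function(table, max_exact_n = 500, b = 1e5, seed = NULL) {
  table <- as.matrix(table)
  stopifnot(all(table >= 0), all(table == round(table)))
  # all-zero rows/columns carry no information; drop them before testing
  table <- table[rowSums(table) > 0, colSums(table) > 0, drop = FALSE]
  if (nrow(table) < 2 || ncol(table) < 2) {
    warning("zero margin: table carries no information, p = 1", call. = FALSE)
    return(tibble::tibble(p_value = 1, method = "degenerate_margin", mc_se = NA_real_))
  }
  exact_ok <- all(dim(table) == 2L) || sum(table) <= max_exact_n
  if (exact_ok) {
    p <- stats::fisher.test(table, workspace = 2e7)$p.value
    tibble::tibble(p_value = p, method = "exact", mc_se = NA_real_)
  } else {
    if (!is.null(seed)) set.seed(seed)
    p <- stats::fisher.test(table, simulate.p.value = TRUE, B = b)$p.value
    tibble::tibble(p_value = p, method = "monte_carlo",
                   mc_se = sqrt(p * (1 - p) / b))
  }
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Bounds from Beta quantiles: `lo = qbeta(alpha/2, k, n-k+1)`,
#' `hi = qbeta(1-alpha/2, k+1, n-k)`, with `lo = 0` at `k = 0` and `hi = 1`
#' at `k = n`. Vectorized over `k`/`n`.
#'
#' @param k Successes.
#' @param n Trials.
#' @param conf Confidence level (default 0.95).
#' @return Tibble: `k`, `n`, `estimate`, `conf_low`, `conf_high`.
#' @export
clopper_pearson <- function(k, n, conf = 0.95) {
  stopifnot(all(k >= 0), all(k <= n), all(n >= 1))
  alpha <- 1 - conf
  lo <- ifelse(k == 0, 0, stats::qbeta(alpha / 2, k, n - k + 1))
  hi <- ifelse(k == n, 1, stats::qbeta(1 - alpha / 2, k + 1, n - k))
  tibble::tibble(k = k, n = n, estimate = k / n, conf_low = lo, conf_high = hi)
}

#' Confidence intervals for the trend's allele frequencies
#'
#' @param trend A [build_trend()] table.
#' @param conf Confidence level.
#' @param unit Whether the binomial n counts chromosomes (`2 * n_total`,
#'   default: alleles are the sampling unit) or dogs.
#' @return The trend tibble with `q_low`, `q_high` columns appended.
#' @export
trend_ci <- function(trend, conf = 0.95, unit = c("chromosomes", "dogs")) {
  unit <- match.arg(unit)
  if (unit == "chromosomes") {
    ci <- clopper_pearson(2 * trend$n_mutant + trend$n_hetero,
                          2 * trend$n_total, conf)
  } else {
    ci <- clopper_pearson(round_half_up(trend$q * trend$n_total), trend$n_total, conf)
  }
  dplyr::mutate(trend, q_low = ci$conf_low, q_high = ci$conf_high)
}

#' Sex-structured Wright-Fisher drift null
#'
#' Simulates neutral allele-frequency trajectories for a population of `ne`
#' breeding dogs of which a fraction `male_fraction` are sires. Each
#' generation the next frequency is the average of two binomial draws, one
#' through each sex: sires contribute `Binomial(2 Nm, q)` allele copies and
#' dams `Binomial(2 Nf, q)`, with `Nm = round_half_up(male_fraction * ne)`
#' and `Nf = ne - Nm`. This reproduces the textbook unequal-sex-ratio
#' variance effective size `Ne_eff = 4 Nm Nf / (Nm + Nf)`: the
#' one-generation variance of q is `q(1-q)/(2 Ne_eff)`.
#'
#' @param ne Breeding population size (dogs).
#' @param q_start Initial allele frequency.
#' @param male_fraction Sire share of the breeding population (default 0.2).
#' @param generations Breeding cycles simulated (default 6; one per year).
#' @param replicates Number of trajectories (default 10000).
#' @param seed Integer seed (default 20231218).
#' @return A `drift_sim` object: `trajectories` (replicates x generations+1
#'   matrix, column g+1 = frequency after g generations) and the model
#'   parameters. See [tidy.drift_sim()] and [empirical_p()].
#' @export
simulate_drift <- function(ne, q_start, male_fraction = 0.2, generations = 6,
                           replicates = 10000, seed = 20231218) {
  stopifnot(ne >= 2, q_start >= 0, q_start <= 1, male_fraction > 0,
            male_fraction < 1, generations >= 1, replicates >= 1)
  nm <- as.integer(round_half_up(male_fraction * ne))
  nf <- as.integer(ne) - nm
  if (nm == 0 || nf == 0) {
    stop("sex-structured model needs at least one sire and one dam", call. = FALSE)
  }
  set.seed(seed)
  traj <- matrix(NA_real_, replicates, generations + 1)
  traj[, 1] <- q_start
  q <- rep(q_start, replicates)
  for (g in seq_len(generations)) {
    q_sires <- stats::rbinom(replicates, 2L * nm, q) / (2 * nm)
    q_dams <- stats::rbinom(replicates, 2L * nf, q) / (2 * nf)
    q <- (q_sires + q_dams) / 2
    traj[, g + 1] <- q
  }
  structure(list(trajectories = traj, ne = ne, nm = nm, nf = nf,
                 ne_eff = 4 * nm * nf / (nm + nf),
                 male_fraction = male_fraction, generations = generations,
                 q_start = q_start, replicates = replicates, seed = seed),
            class = "drift_sim")
}

#' @export
print.drift_sim <- function(x, ...) {
  cat(sprintf("<drift_sim> Ne = %d (%d sires + %d dams, Ne_eff = %.1f), q0 = %.3f, %d generation(s) x %d replicate(s)\n",
              x$ne, x$nm, x$nf, x$ne_eff, x$q_start, x$generations, x$replicates))
  invisible(x)
}

#' Per-generation summary of a drift simulation
#'
#' @param x A `drift_sim`.
#' @param probs Quantiles to report (default the 95% simulation band).
#' @param ... Unused.
#' @return Tibble: `generation` (0 = start), `mean_q`, `sd_q` and one column
#'   per requested quantile (`q2.5`, `q97.5`, ...).
#' @method tidy drift_sim
#' @export
tidy.drift_sim <- function(x, probs = c(0.025, 0.975), ...) {
  qm <- t(apply(x$trajectories, 2, stats::quantile, probs = probs))
  colnames(qm) <- paste0("q", probs * 100)
  out <- tibble::tibble(generation = 0:x$generations,
                        mean_q = colMeans(x$trajectories),
                        sd_q = apply(x$trajectories, 2, stats::sd))
  dplyr::bind_cols(out, tibble::as_tibble(qm))
}

#' One-row model summary of a drift simulation
#'
#' @param x A `drift_sim`.
#' @param ... Unused.
#' @return One-row tibble of the model parameters plus the fraction of
#'   trajectories absorbed at 0 or 1 by the final generation.
#' @method glance drift_sim
#' @export
glance.drift_sim <- function(x, ...) {
  qf <- x$trajectories[, x$generations + 1]
  tibble::tibble(ne = x$ne, nm = x$nm, nf = x$nf, ne_eff = x$ne_eff,
                 q_start = x$q_start, generations = x$generations,
                 replicates = x$replicates,
                 p_lost = mean(qf == 0), p_fixed = mean(qf == 1))
}

#' Empirical lower-tail p-value against the drift null
#'
#' The probability that pure drift alone would carry the allele frequency
#' below the observed one: the fraction of simulated trajectories strictly
#' below `observed_q` at the given generation. A count of zero is reported
#' as `p < 1/replicates` via `p_label`.
#'
#' @param sim A [simulate_drift()] result.
#' @param observed_q Observed allele frequency (vectorized).
#' @param generation Generations after the start (vectorized, recycled
#'   against `observed_q`).
#' @return Tibble: `generation`, `observed_q`, `n_lower`, `replicates`,
#'   `p_value`, `p_label`.
#' @export
empirical_p <- function(sim, observed_q, generation) {
  stopifnot(inherits(sim, "drift_sim"),
            all(generation >= 0), all(generation <= sim$generations))
  n <- max(length(observed_q), length(generation))
  observed_q <- rep_len(observed_q, n)
  generation <- rep_len(generation, n)
  n_lower <- vapply(seq_len(n), function(i) {
    sum(sim$trajectories[, generation[i] + 1] < observed_q[i])
  }, numeric(1))
  p <- n_lower / sim$replicates
  tibble::tibble(generation = generation, observed_q = observed_q,
                 n_lower = as.integer(n_lower), replicates = sim$replicates,
                 p_value = p,
                 p_label = ifelse(n_lower == 0,
                                  sprintf("< %g", 1 / sim$replicates),
                                  sprintf("%g", p)))
}
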