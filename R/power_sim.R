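# Monte-Carlo power analysis for the co-carrier depletion test.
#
# Pipeline per replicate: two-locus HWE population -> penetrance-scaled
# removal of co-carriers -> renormalization -> one multinomial cohort of
# size N -> allele-frequency re-estimation -> HWE expected counts at the
# estimated frequencies -> chi-squared goodness-of-fit (collapsed 1 df
# or full 6 df). The pre-sampling population is treated as infinite.

#' Power simulation scenario
#'
#' @param q1,q2 Generating alternate-allele frequencies.
#' @param penetrance Probability that a co-carrier develops the disease
#'   and is therefore absent from the healthy cohort; 1 is complete
#'   penetrance, 0 the null (no depletion).
#' @param N Cohort size (individuals).
#' @param iterations Monte-Carlo replicates (default 1000).
#' @param alpha Significance threshold (default 0.05).
#' @param mode \code{"collapsed"} (1 df) or \code{"full"} (6 df).
#' @param seed RNG seed; every replicate seed is derived from it.
#' @param min_expected Minimum expected co-carrier count for a replicate
#'   to be testable. Default 0 (rule disabled): power simulations report
#'   the raw behaviour of the test; set 5 to mirror the screening
#'   filter.
#' @return An object of class \code{power_scenario}.
#' @export
power_scenario <- function(q1, q2, penetrance, N, iterations = 1000,
                           alpha = 0.05, mode = c("collapsed", "full"),
                           seed = 1L, min_expected = 0) {
  mode <- match.arg(mode)
  .check_freq(q1, "q1"); .check_freq(q2, "q2")
  .check_freq(penetrance, "penetrance")
  stopifnot(N >= 1, iterations >= 1, alpha > 0, alpha < 1)
  structure(list(q1 = q1, q2 = q2, penetrance = penetrance, N = N,
                 iterations = as.integer(iterations), alpha = alpha,
                 mode = mode, seed = as.integer(seed),
                 min_expected = min_expected),
            class = "power_scenario")
}

#' Remove co-carriers according to penetrance
#'
#' Multiplies the four co-carrier genotype classes (\code{AaBb},
#' \code{Aabb}, \code{aaBb}, \code{aabb}) by \code{1 - penetrance},
#' leaves the five single-carrier and non-carrier classes untouched, and
#' renormalizes all nine frequencies to sum to 1. A penetrance of 0.2
#' removes 20\% of co-carriers (the fraction that develops disease and
#' is absent from a healthy cohort).
#'
#' @param freqs9 Named genotype frequency vector over
#'   \code{genotype_classes()}.
#' @param penetrance In [0, 1].
#' @return Renormalized frequency vector.
#' @export
apply_penetrance <- function(freqs9, penetrance) {
  .check_freq(penetrance, "penetrance")
  freqs9 <- .check_counts9(freqs9, allow_real = TRUE)
  freqs9[.COCARRIER_CLASSES] <- freqs9[.COCARRIER_CLASSES] * (1 - penetrance)
  freqs9 / sum(freqs9)
}

#' Draw one cohort from a genotype distribution
#'
#' A single multinomial draw of \code{N} individuals over the nine
#' genotype classes, using the current RNG state.
#'
#' @param freqs9 Genotype frequencies over \code{genotype_classes()}.
#' @param N Cohort size.
#' @return Named integer count vector summing to \code{N}.
#' @export
sample_cohort <- function(freqs9, N) {
  freqs9 <- .check_counts9(freqs9, allow_real = TRUE)
  stopifnot(N >= 1)
  setNames(as.vector(rmultinom(1L, size = N, prob = freqs9)),
           .GENOTYPE_CLASSES)
}

#' Estimate allele frequencies from nine-class counts
#'
#' Allele counting: heterozygotes at a locus contribute one alternate
#' allele, homozygotes two, over \code{2N} chromosomes.
#'
#' @param counts9 Named count vector over \code{genotype_classes()}.
#' @return Named numeric \code{c(q1, q2)}.
#' @export
estimate_allele_freqs <- function(counts9) {
  counts9 <- .check_counts9(counts9, allow_real = TRUE)
  if (sum(counts9) < 1) stop("N must be >= 1", call. = FALSE)
  .estimate_q_from_counts9(counts9)
}

#' One power-simulation replicate
#'
#' Runs the full per-replicate pipeline on a cohort drawn with the
#' current RNG state (callers control seeding). Replicates monomorphic
#' at either locus, or with expected co-carriers below
#' \code{scenario$min_expected}, are flagged untestable.
#'
#' @param scenario A \code{\link{power_scenario}}.
#' @param freqs9 Optional pre-computed penetrance-adjusted population
#'   frequencies (recomputed from the scenario when omitted).
#' @return List with \code{p_value} and \code{testable}.
#' @export
run_replicate <- function(scenario, freqs9 = NULL) {
  if (is.null(freqs9)) {
    freqs9 <- apply_penetrance(
      hwe_genotype_freqs9(scenario$q1, scenario$q2), scenario$penetrance)
  }
  counts9 <- sample_cohort(freqs9, scenario$N)
  q <- .estimate_q_from_counts9(counts9)
  if (any(q <= 0) || any(q >= 1)) {
    return(list(p_value = NA_real_, testable = FALSE))
  }
  N <- sum(counts9)
  exp4 <- expected_collapsed_counts(q[[1]], q[[2]], N)
  if (exp4[["cocarriers"]] < scenario$min_expected) {
    return(list(p_value = NA_real_, testable = FALSE))
  }
  if (scenario$mode == "collapsed") {
    expected <- exp4
    observed <- collapse_counts(counts9)
    df <- 1L
  } else {
    expected <- expected_counts9(q[[1]], q[[2]], N)
    observed <- counts9
    df <- 6L
  }
  gof <- chi2_gof(observed, expected, df = df)
  list(p_value = gof$p_value, testable = TRUE)
}

#' Estimate statistical power by simulation
#'
#' Runs \code{scenario$iterations} replicates and reports the fraction
#' significant at \code{scenario$alpha}. Untestable replicates
#' (monomorphic draws, or expected co-carriers below the threshold when
#' the rule is enabled) count as non-significant and are tallied
#' separately, so rare-frequency power is not biased upward.
#'
#' @param scenario A \code{\link{power_scenario}}.
#' @return An object of class \code{power_estimate}: the scenario, the
#'   \code{power}, its binomial Monte-Carlo standard error
#'   \code{mc_stderr}, and \code{replicates_untestable}.
#' @export
#' @examples
#' estimate_power(power_scenario(0.06, 0.06, penetrance = 0.3, N = 38341,
#'                               iterations = 200, seed = 1))
estimate_power <- function(scenario) {
  stopifnot(inherits(scenario, "power_scenario"))
  freqs9 <- apply_penetrance(
    hwe_genotype_freqs9(scenario$q1, scenario$q2), scenario$penetrance)
  set.seed(scenario$seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, scenario$iterations)
  sig <- 0L
  untestable <- 0L
  for (i in seq_len(scenario$iterations)) {
    set.seed(rep_seeds[i])
    r <- run_replicate(scenario, freqs9 = freqs9)
    if (!r$testable) {
      untestable <- untestable + 1L
    } else if (r$p_value < scenario$alpha) {
      sig <- sig + 1L
    }
  }
  power <- sig / scenario$iterations
  structure(list(scenario = scenario,
                 power = power,
                 mc_stderr = sqrt(power * (1 - power) / scenario$iterations),
                 replicates_untestable = untestable),
            class = "power_estimate")
}

#' @export
print.power_estimate <- function(x, ...) {
  s <- x$scenario
  cat(sprintf(
    "Power estimate: %.3f (MC se %.3f) at q1=%g q2=%g pen=%g N=%d (%s, %d iters)\n",
    x$power, x$mc_stderr, s$q1, s$q2, s$penetrance, s$N, s$mode,
    s$iterations))
  if (x$replicates_untestable > 0) {
    cat("  untestable replicates:", x$replicates_untestable, "\n")
  }
  invisible(x)
}

#' Power over a grid of scenarios
#'
#' Estimates power over the Cartesian product of allele frequencies
#' (used for both variants), penetrance values and cohort sizes. Each
#' scenario gets a seed deterministically derived from \code{seed}, so
#' the grid is reproducible and individual cells can be recomputed in
#' isolation.
#'
#' @param q_values Allele frequencies (applied to both variants).
#' @param penetrance_values Penetrance grid.
#' @param N_values Cohort sizes.
#' @param iterations,alpha,mode,min_expected Shared scenario settings;
#'   see \code{\link{power_scenario}}.
#' @param seed Base seed.
#' @return Long-format data.frame: \code{q1, q2, penetrance, N, mode,
#'   iterations, power, mc_stderr, untestable, seed}.
#' @export
power_grid <- function(q_values, penetrance_values, N_values,
                       iterations = 1000, alpha = 0.05,
                       mode = c("collapsed", "full"), seed = 1L,
                       min_expected = 0) {
  mode <- match.arg(mode)
  stopifnot(length(q_values) >= 1, length(penetrance_values) >= 1,
            length(N_values) >= 1)
  cells <- expand.grid(q = q_values, penetrance = penetrance_values,
                       N = N_values, KEEP.OUT.ATTRS = FALSE)
  set.seed(seed)
  cell_seeds <- sample.int(.Machine$integer.max - 1L, nrow(cells))
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sc <- power_scenario(cells$q[i], cells$q[i], cells$penetrance[i],
                         cells$N[i], iterations = iterations,
                         alpha = alpha, mode = mode,
                         seed = cell_seeds[i], min_expected = min_expected)
    est <- estimate_power(sc)
    data.frame(q1 = sc$q1, q2 = sc$q2, penetrance = sc$penetrance,
               N = sc$N, mode = mode, iterations = iterations,
               power = est$power, mc_stderr = est$mc_stderr,
               untestable = est$replicates_untestable,
               seed = sc$seed, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Plot power curves from a power grid
#'
#' Power versus penetrance, one curve per allele frequency, one panel
#' per cohort size, with a dashed reference line at 80\% power.
#' Requires ggplot2.
#'
#' @param grid Data.frame from \code{\link{power_grid}}.
#' @param path Optional output file (PDF/PNG by extension); when
#'   \code{NULL} the ggplot object is returned.
#' @return The ggplot object, invisibly when written to file.
#' @export
plot_power_curves <- function(grid, path = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_power_curves requires the ggplot2 package", call. = FALSE)
  }
  grid$frequency <- factor(grid$q1)
  p <- ggplot2::ggplot(grid, ggplot2::aes(x = .data$penetrance,
                                          y = .data$power,
                                          colour = .data$frequency)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = 0.8, linetype = "dashed",
                        colour = "red") +
    ggplot2::facet_wrap(~N, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Combination penetrance", y = "Statistical power",
                  colour = "Allele frequency") +
    ggplot2::ylim(0, 1) + ggplot2::theme_bw()
  if (is.null(path)) return(p)
  ggplot2::ggsave(path, p, width = 8, height = 4)
  invisible(p)
}
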