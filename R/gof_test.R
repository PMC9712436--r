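# Chi-squared goodness-of-fit depletion test for digenic combinations.

#' Test configuration
#'
#' @param mode \code{"collapsed"} compares the 4 collapsed categories
#'   with 1 df; \code{"full"} compares all 9 genotype classes with 6 df.
#'   The degrees of freedom are fixed per mode (categories minus one
#'   minus the two estimated allele frequencies).
#' @param min_expected_cocarriers Minimum expected co-carrier count for a
#'   pair to be testable (default 5). Applied to the co-carrier category
#'   only unless \code{require_all_expected} is set.
#' @param alpha Significance level used for flags/stars (default 0.05).
#' @param multiple_testing One of \code{"none"},
#'   \code{"benjamini-hochberg"}, \code{"bonferroni"}.
#' @param require_all_expected If \code{TRUE}, additionally require every
#'   expected category to reach \code{min_expected_cocarriers} (stricter
#'   than the default co-carrier-only rule).
#' @return An object of class \code{digenic_test_config}.
#' @export
test_config <- function(mode = c("collapsed", "full"),
                        min_expected_cocarriers = 5,
                        alpha = 0.05,
                        multiple_testing = c("none", "benjamini-hochberg",
                                             "bonferroni"),
                        require_all_expected = FALSE) {
  mode <- match.arg(mode)
  multiple_testing <- match.arg(multiple_testing)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("'alpha' must lie in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(min_expected_cocarriers) || min_expected_cocarriers < 0) {
    stop("'min_expected_cocarriers' must be >= 0", call. = FALSE)
  }
  structure(list(mode = mode,
                 min_expected_cocarriers = min_expected_cocarriers,
                 alpha = alpha,
                 multiple_testing = multiple_testing,
                 require_all_expected = isTRUE(require_all_expected)),
            class = "digenic_test_config")
}

#' Pearson chi-squared goodness-of-fit test
#'
#' Computes the Pearson statistic \eqn{\sum (O-E)^2/E} and its upper-tail
#' p-value under a chi-squared distribution with the given degrees of
#' freedom. No continuity correction is applied.
#'
#' @param observed,expected Numeric vectors of category counts, equal
#'   length; every expected entry must be strictly positive and the two
#'   totals must agree.
#' @param df Degrees of freedom.
#' @return List with \code{statistic} and \code{p_value}.
#' @export
#' @examples
#' chi2_gof(c(2, 3060, 97, 35182), c(8.098, 3053.9, 90.9, 35188.1), df = 1)
chi2_gof <- function(observed, expected, df) {
  if (length(observed) != length(expected)) {
    stop("'observed' and 'expected' must have the same number of categories",
         call. = FALSE)
  }
  zero <- which(expected <= 0)
  if (length(zero)) {
    nm <- names(expected)[zero]
    if (is.null(nm) || any(!nzchar(nm))) nm <- paste0("category ", zero)
    stop("expected count is zero (or negative) for: ",
         paste(nm, collapse = ", "), call. = FALSE)
  }
  tot <- sum(expected)
  if (abs(sum(observed) - tot) > 1e-6 * max(1, tot)) {
    stop("observed and expected totals differ (",
         format(sum(observed)), " vs ", format(tot), ")", call. = FALSE)
  }
  statistic <- sum((observed - expected)^2 / expected)
  list(statistic = statistic,
       p_value = pchisq(statistic, df = df, lower.tail = FALSE))
}

.new_test_result <- function(pair_id, q1_hat, q2_hat, N,
                             observed_cocarriers, expected_cocarriers,
                             chi2_statistic = NA_real_, df = NA_integer_,
                             p_value = NA_real_, testable = TRUE,
                             mode = "collapsed", note = NA_character_) {
  structure(list(pair_id = pair_id,
                 q1_hat = q1_hat, q2_hat = q2_hat, N = N,
                 observed_cocarriers = observed_cocarriers,
                 expected_cocarriers = expected_cocarriers,
                 difference = observed_cocarriers - expected_cocarriers,
                 chi2_statistic = chi2_statistic, df = df,
                 p_value = p_value,
                 adjusted_p = NA_real_,
                 testable = testable, mode = mode, note = note),
            class = "digenic_test_result")
}

#' @export
print.digenic_test_result <- function(x, ...) {
  cat("Digenic co-carrier depletion test",
      if (!is.null(x$pair_id) && !is.na(x$pair_id)) paste0("[", x$pair_id, "]"),
      "\n")
  cat(sprintf("  q1_hat = %.6g, q2_hat = %.6g, N = %d (%s mode)\n",
              x$q1_hat, x$q2_hat, x$N, x$mode))
  cat(sprintf("  co-carriers: observed %.4g, expected %.4f, diff %+.4f\n",
              x$observed_cocarriers, x$expected_cocarriers, x$difference))
  if (isTRUE(x$testable)) {
    cat(sprintf("  chi-squared = %.4f on %d df, p = %.4g%s\n",
                x$chi2_statistic, x$df, x$p_value,
                if (!is.na(x$p_value) && x$p_value < 0.05) " *" else ""))
  } else {
    cat("  untestable:", x$note, "\n")
  }
  invisible(x)
}

.estimate_q_from_counts9 <- function(counts9) {
  N <- sum(counts9)
  q1 <- (sum(counts9[.HET1_CLASSES]) + 2 * sum(counts9[.HOM1_CLASSES])) / (2 * N)
  q2 <- (sum(counts9[.HET2_CLASSES]) + 2 * sum(counts9[.HOM2_CLASSES])) / (2 * N)
  c(q1 = q1, q2 = q2)
}

#' Digenic depletion test from observed nine-class counts
#'
#' Estimates the two alternate-allele frequencies by allele counting
#' from the observed table (each heterozygote contributes one alternate
#' allele, each homozygote two, over \code{2N} chromosomes), rebuilds the
#' expected counts under Hardy-Weinberg equilibrium at those frequencies
#' for the same \code{N}, and compares observed to expected with a
#' Pearson chi-squared goodness-of-fit test: collapsed 4-category table
#' with 1 df, or full 9-class table with 6 df.
#'
#' Pairs whose expected co-carrier count falls below
#' \code{config$min_expected_cocarriers}, and pairs monomorphic at either
#' locus in the sample, are flagged untestable and no p-value is
#' computed.
#'
#' @param observed9 Named count vector over \code{genotype_classes()}.
#' @param config A \code{\link{test_config}}.
#' @param pair_id Optional identifier carried into the result.
#' @return A \code{digenic_test_result}.
#' @export
digenic_test <- function(observed9, config = test_config(), pair_id = NA_character_) {
  observed9 <- genotype_counts9(observed9)
  N <- sum(observed9)
  if (N < 1) stop("N must be >= 1 (empty genotype table)", call. = FALSE)
  q <- .estimate_q_from_counts9(observed9)
  obs4 <- collapse_counts(observed9)
  exp4 <- expected_collapsed_counts(max(q[1], 0), max(q[2], 0), N)

  res <- .new_test_result(pair_id, q[[1]], q[[2]], as.integer(N),
                          obs4[["cocarriers"]], exp4[["cocarriers"]],
                          mode = config$mode)
  if (any(q == 0) || any(q == 1)) {
    res$testable <- FALSE
    res$note <- "monomorphic variant in sample (q_hat is 0 or 1)"
    return(res)
  }
  if (exp4[["cocarriers"]] < config$min_expected_cocarriers) {
    res$testable <- FALSE
    res$note <- sprintf("expected co-carriers %.3f < minimum %.3g",
                        exp4[["cocarriers"]], config$min_expected_cocarriers)
    return(res)
  }
  if (config$mode == "collapsed") {
    expected <- exp4
    observed <- obs4
    df <- 1L
  } else {
    expected <- expected_counts9(q[[1]], q[[2]], N)
    observed <- observed9
    df <- 6L
  }
  if (config$require_all_expected &&
      any(expected < config$min_expected_cocarriers)) {
    res$testable <- FALSE
    res$note <- "an expected category falls below the minimum count"
    return(res)
  }
  gof <- chi2_gof(observed, expected, df = df)
  res$chi2_statistic <- gof$statistic
  res$df <- df
  res$p_value <- gof$p_value
  res
}

#' Depletion test from summary-level inputs
#'
#' Table-style entry point for pairs where only the two allele
#' frequencies, the cohort size and the observed co-carrier count are
#' known. The expected 4-category table is built from the frequencies;
#' the observed table is imputed as the expected table with the
#' co-carrier cell replaced by \code{observed_cocarriers} and the deficit
#' (or excess) redistributed over the two single-carrier cells in
#' proportion to their expected sizes. This is an approximation --
#' the true single-carrier observed counts are unknown -- and the result
#' is flagged accordingly.
#'
#' @param q1,q2 Alternate-allele frequencies, strictly inside (0, 1).
#' @param N Cohort size.
#' @param observed_cocarriers Observed co-carrier individuals (0..N).
#' @param pair_id Optional identifier.
#' @param config A \code{\link{test_config}} (collapsed mode only).
#' @return A \code{digenic_test_result} with \code{note = "imputed"}.
#' @export
#' @examples
#' test_from_summary(0.0415, 0.0013, 38341, observed_cocarriers = 2)
test_from_summary <- function(q1, q2, N, observed_cocarriers,
                              pair_id = NA_character_,
                              config = test_config()) {
  .check_freq(q1, "q1"); .check_freq(q2, "q2")
  if (q1 %in% c(0, 1) || q2 %in% c(0, 1)) {
    stop("'q1' and 'q2' must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (observed_cocarriers < 0 || observed_cocarriers > N) {
    stop("'observed_cocarriers' must lie in [0, N]", call. = FALSE)
  }
  exp4 <- expected_collapsed_counts(q1, q2, N)
  deficit <- exp4[["cocarriers"]] - observed_cocarriers
  singles <- exp4[c("carriers1_only", "carriers2_only")]
  obs4 <- exp4
  obs4[["cocarriers"]] <- observed_cocarriers
  obs4[c("carriers1_only", "carriers2_only")] <-
    singles + deficit * singles / sum(singles)

  res <- .new_test_result(pair_id, q1, q2, as.integer(round(N)),
                          observed_cocarriers, exp4[["cocarriers"]],
                          mode = "collapsed",
                          note = "single-carrier observed counts imputed")
  if (exp4[["cocarriers"]] < config$min_expected_cocarriers) {
    res$testable <- FALSE
    res$note <- sprintf("expected co-carriers %.3f < minimum %.3g",
                        exp4[["cocarriers"]], config$min_expected_cocarriers)
    return(res)
  }
  gof <- chi2_gof(obs4, exp4, df = 1L)
  res$chi2_statistic <- gof$statistic
  res$df <- 1L
  res$p_value <- gof$p_value
  res
}

#' Adjust p-values across a batch of test results
#'
#' Fills \code{adjusted_p} on testable results; untestable results are
#' left \code{NA} and do not count towards the number of tests.
#'
#' @param results List of \code{digenic_test_result}.
#' @param method \code{"none"}, \code{"benjamini-hochberg"} or
#'   \code{"bonferroni"}.
#' @return The list with \code{adjusted_p} filled.
#' @export
adjust_pvalues <- function(results,
                           method = c("none", "benjamini-hochberg",
                                      "bonferroni")) {
  method <- match.arg(method)
  stats_method <- switch(method,
                         "none" = "none",
                         "benjamini-hochberg" = "BH",
                         "bonferroni" = "bonferroni")
  testable <- vapply(results, function(r) isTRUE(r$testable), logical(1))
  p <- vapply(results[testable], function(r) r$p_value, numeric(1))
  adj <- p.adjust(p, method = stats_method)
  j <- 0L
  for (i in seq_along(results)) {
    if (testable[i]) {
      j <- j + 1L
      results[[i]]$adjusted_p <- adj[[j]]
    }
  }
  results
}

#' Tabulate test results
#'
#' @param results List of \code{digenic_test_result} (a single result is
#'   accepted too).
#' @param alpha Significance level used for the star column.
#' @return A data.frame with one row per pair, mirroring the standard
#'   report layout: identifiers, frequencies, observed/expected/diff
#'   co-carriers (4 decimals), chi-squared, df, p-value, adjusted p,
#'   testable flag, and a \code{"*"} marker for p below \code{alpha}.
#' @export
results_table <- function(results, alpha = 0.05) {
  if (inherits(results, "digenic_test_result")) results <- list(results)
  rows <- lapply(results, function(r) {
    data.frame(pair_id = as.character(r$pair_id),
               freq1 = r$q1_hat, freq2 = r$q2_hat, N = r$N,
               obs = r$observed_cocarriers,
               exp = round(r$expected_cocarriers, 4),
               diff = round(r$difference, 4),
               chi2 = r$chi2_statistic, df = r$df,
               p_value = r$p_value,
               adjusted_p = r$adjusted_p,
               testable = r$testable,
               significant = ifelse(isTRUE(r$testable) && !is.na(r$p_value) &&
                                      r$p_value < alpha, "*", ""),
               note = as.character(r$note),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write test results to TSV or JSON
#'
#' @param results List of \code{digenic_test_result}.
#' @param path Output file path.
#' @param format \code{"tsv"} (default) or \code{"json"}.
#' @param alpha Significance level for the star column.
#' @return \code{path}, invisibly.
#' @export
write_results <- function(results, path, format = c("tsv", "json"),
                          alpha = 0.05) {
  format <- match.arg(format)
  tab <- results_table(results, alpha = alpha)
  if (format == "tsv") {
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "NA")
  } else {
    jsonlite::write_json(tab, path, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}
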