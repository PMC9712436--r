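# Two-locus Hardy-Weinberg genotype model.
#
# Locus 1 alleles are written A (reference, frequency p1) / a (alternate,
# frequency q1); locus 2 B/b analogously. Lowercase is always the
# alternate allele. The nine two-locus genotype classes are ordered with
# locus 1 varying slowest.

.GENOTYPE_CLASSES <- c("AABB", "AABb", "AAbb",
                       "AaBB", "AaBb", "Aabb",
                       "aaBB", "aaBb", "aabb")
.COCARRIER_CLASSES <- c("AaBb", "Aabb", "aaBb", "aabb")
.CARRIER1_ONLY_CLASSES <- c("AaBB", "aaBB")
.CARRIER2_ONLY_CLASSES <- c("AABb", "AAbb")
.COLLAPSED_CATEGORIES <- c("cocarriers", "carriers1_only",
                           "carriers2_only", "noncarriers")

# classes carrying 1 / 2 copies of the alternate allele at each locus
.HET1_CLASSES <- c("AaBB", "AaBb", "Aabb")
.HOM1_CLASSES <- c("aaBB", "aaBb", "aabb")
.HET2_CLASSES <- c("AABb", "AaBb", "aaBb")
.HOM2_CLASSES <- c("AAbb", "Aabb", "aabb")

#' Two-locus genotype class labels
#'
#' The nine diploid two-locus genotype classes in canonical order.
#' \code{A}/\code{B} are the reference alleles of variants 1 and 2,
#' \code{a}/\code{b} the alternate alleles.
#'
#' @return Character vector of length 9.
#' @export
#' @examples
#' genotype_classes()
genotype_classes <- function() .GENOTYPE_CLASSES

#' Co-carrier genotype class labels
#'
#' The four classes whose members carry at least one alternate allele at
#' both loci (\code{AaBb}, \code{Aabb}, \code{aaBb}, \code{aabb}).
#'
#' @return Character vector of length 4.
#' @export
cocarrier_classes <- function() .COCARRIER_CLASSES

.check_freq <- function(q, name = deparse(substitute(q))) {
  if (!is.numeric(q) || length(q) == 0L || anyNA(q) ||
      any(q < 0) || any(q > 1)) {
    stop(sprintf("'%s' must be a frequency in [0, 1], got %s",
                 name, paste(format(q), collapse = ", ")), call. = FALSE)
  }
  invisible(q)
}

#' Carrier probability under Hardy-Weinberg equilibrium
#'
#' Probability that a random individual carries at least one alternate
#' allele at a biallelic locus with alternate-allele frequency \code{q}:
#' \eqn{2pq + q^2 = 1 - (1-q)^2} with \eqn{p = 1 - q}.
#'
#' @param q Alternate-allele frequency (or vector thereof), in [0, 1].
#' @return Carrier probability, same length as \code{q}.
#' @export
#' @examples
#' carrier_frequency(0.0735)   # 0.14159775
carrier_frequency <- function(q) {
  .check_freq(q, "q")
  1 - (1 - q)^2
}

#' Nine-class two-locus genotype frequencies under HWE
#'
#' Forms the joint two-locus genotype distribution as the product of the
#' per-locus Hardy-Weinberg proportions, i.e. assuming linkage
#' equilibrium between the two variants. Pairs of variants in strong LD
#' (e.g. nearby sites on one haplotype) violate this assumption and must
#' be excluded by the user.
#'
#' @param q1,q2 Alternate-allele frequencies of variants 1 and 2.
#' @return Named numeric vector over \code{genotype_classes()}, summing
#'   to 1.
#' @export
#' @examples
#' hwe_genotype_freqs9(0.5, 0.5)[["AaBb"]]  # 0.25
hwe_genotype_freqs9 <- function(q1, q2) {
  .check_freq(q1, "q1"); .check_freq(q2, "q2")
  stopifnot(length(q1) == 1L, length(q2) == 1L)
  g1 <- c((1 - q1)^2, 2 * (1 - q1) * q1, q1^2)
  g2 <- c((1 - q2)^2, 2 * (1 - q2) * q2, q2^2)
  setNames(as.vector(t(outer(g1, g2))), .GENOTYPE_CLASSES)
}

.check_counts9 <- function(counts, allow_real = FALSE) {
  if (is.null(names(counts)) || !setequal(names(counts), .GENOTYPE_CLASSES)) {
    stop("genotype counts must be named with the 9 classes: ",
         paste(.GENOTYPE_CLASSES, collapse = ", "), call. = FALSE)
  }
  counts <- counts[.GENOTYPE_CLASSES]
  if (anyNA(counts) || any(counts < 0)) {
    stop("genotype counts must be non-negative", call. = FALSE)
  }
  if (!allow_real && any(abs(counts - round(counts)) > 1e-8)) {
    stop("genotype counts must be integers", call. = FALSE)
  }
  counts
}

#' Genotype counts over the nine two-locus classes
#'
#' Validates and canonically orders a vector of per-class individual
#' counts.
#'
#' @param counts Named non-negative integer vector over
#'   \code{genotype_classes()} (any order; all nine names required).
#' @return Named integer-valued numeric vector in canonical class order.
#' @export
genotype_counts9 <- function(counts) {
  .check_counts9(counts)
}

#' Collapse nine-class counts to the four test categories
#'
#' Maps the nine two-locus genotype classes onto the four categories of
#' the depletion test: co-carriers (\code{Aa/aa + Bb/bb}), single
#' carriers of variant 1 only (\code{Aa/aa + BB}), single carriers of
#' variant 2 only (\code{AA + Bb/bb}), and non-carriers
#' (\code{AA + BB}). Totals are conserved.
#'
#' @param counts9 Named vector over \code{genotype_classes()}; counts or
#'   expected (real-valued) counts.
#' @return Named numeric vector \code{cocarriers}, \code{carriers1_only},
#'   \code{carriers2_only}, \code{noncarriers}.
#' @export
collapse_counts <- function(counts9) {
  counts9 <- .check_counts9(counts9, allow_real = TRUE)
  setNames(c(sum(counts9[.COCARRIER_CLASSES]),
             sum(counts9[.CARRIER1_ONLY_CLASSES]),
             sum(counts9[.CARRIER2_ONLY_CLASSES]),
             counts9[["AABB"]]),
           .COLLAPSED_CATEGORIES)
}

#' Expected counts in the four collapsed categories under HWE
#'
#' Expected numbers of individuals per category in a cohort of size
#' \code{N}, from the per-locus carrier probabilities
#' \eqn{c_i = 1-(1-q_i)^2}: co-carriers \eqn{c_1 c_2 N}, single carriers
#' \eqn{c_1(1-c_2)N} and \eqn{(1-c_1)c_2 N}, non-carriers
#' \eqn{(1-c_1)(1-c_2)N}. The four entries sum to \code{N} exactly.
#'
#' @param q1,q2 Alternate-allele frequencies.
#' @param N Cohort size (individuals), positive.
#' @return Named numeric vector of expected counts (not rounded).
#' @export
#' @examples
#' expected_collapsed_counts(0.0415, 0.0013, 38341)
expected_collapsed_counts <- function(q1, q2, N) {
  if (!is.numeric(N) || length(N) != 1L || is.na(N) || N <= 0) {
    stop("'N' must be a positive cohort size", call. = FALSE)
  }
  c1 <- carrier_frequency(q1)
  c2 <- carrier_frequency(q2)
  setNames(N * c(c1 * c2, c1 * (1 - c2), (1 - c1) * c2,
                 (1 - c1) * (1 - c2)),
           .COLLAPSED_CATEGORIES)
}

#' Expected counts over the nine genotype classes under HWE
#'
#' @inheritParams expected_collapsed_counts
#' @return Named numeric vector over \code{genotype_classes()} summing
#'   to \code{N}.
#' @export
expected_counts9 <- function(q1, q2, N) {
  if (!is.numeric(N) || length(N) != 1L || is.na(N) || N <= 0) {
    stop("'N' must be a positive cohort size", call. = FALSE)
  }
  hwe_genotype_freqs9(q1, q2) * N
}
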