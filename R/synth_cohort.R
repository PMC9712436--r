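# Synthetic diploid cohort generator: two unlinked biallelic variants at
# HWE with optional penetrance-scaled co-carrier depletion and
# per-genotype missingness. Everything downstream (counting, testing,
# screening) is exercisable without external data.

#' Synthetic cohort specification
#'
#' @param N Number of individuals.
#' @param q1,q2 Generating alternate-allele frequencies.
#' @param penetrance Co-carrier depletion strength; 0 is a pure HWE
#'   null cohort, 1 removes every co-carrier.
#' @param missing_rate Per-genotype missingness probability, applied
#'   independently to each sample at each site.
#' @param seed RNG seed; identical specs with identical seeds produce
#'   byte-identical cohorts.
#' @param variants List of two \code{\link{variant_key}}s defining the
#'   VCF records; defaults to two sites on a synthetic contig
#'   \code{chrS}.
#' @return An object of class \code{synthetic_cohort_spec}.
#' @export
cohort_spec <- function(N, q1, q2, penetrance = 0, missing_rate = 0,
                        seed = 1L,
                        variants = list(
                          variant_key("chrS", 1000L, "A", "G"),
                          variant_key("chrS", 2000L, "C", "T"))) {
  .check_freq(q1, "q1"); .check_freq(q2, "q2")
  .check_freq(penetrance, "penetrance")
  if (!is.numeric(missing_rate) || missing_rate < 0 || missing_rate >= 1) {
    stop("'missing_rate' must lie in [0, 1)", call. = FALSE)
  }
  stopifnot(N >= 1, length(variants) == 2L)
  structure(list(N = as.integer(N), q1 = q1, q2 = q2,
                 penetrance = penetrance, missing_rate = missing_rate,
                 seed = as.integer(seed), variants = variants),
            class = "synthetic_cohort_spec")
}

# class label -> (alt copies at locus 1, alt copies at locus 2)
.CLASS_DOSAGE <- cbind(d1 = rep(0:2, each = 3), d2 = rep(0:2, times = 3))
rownames(.CLASS_DOSAGE) <- .GENOTYPE_CLASSES

#' Generate a synthetic cohort
#'
#' Draws per-sample two-locus genotypes from the penetrance-adjusted
#' nine-class HWE distribution (one multinomial draw expanded to
#' individuals in random order), then masks genotypes independently with
#' \code{missing_rate}. The returned truth record keeps both the drawn
#' counts (before missingness) and the realized counts over samples
#' complete at both sites -- the latter is what
#' \code{\link{count_pair}} recovers from the written VCF.
#'
#' @param spec A \code{\link{cohort_spec}}.
#' @return An object of class \code{synthetic_cohort}: \code{spec},
#'   per-sample alternate-allele dosages \code{dosage1}/\code{dosage2}
#'   (\code{NA} = missing), \code{sample_names}, \code{drawn_counts9},
#'   \code{realized_counts9}, \code{realized_q} and \code{n_missing}.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  set.seed(spec$seed)
  freqs <- apply_penetrance(hwe_genotype_freqs9(spec$q1, spec$q2),
                            spec$penetrance)
  drawn <- sample_cohort(freqs, spec$N)
  cls <- sample(rep(.GENOTYPE_CLASSES, times = drawn))  # random sample order
  d1 <- .CLASS_DOSAGE[cls, "d1"]
  d2 <- .CLASS_DOSAGE[cls, "d2"]
  if (spec$missing_rate > 0) {
    d1[runif(spec$N) < spec$missing_rate] <- NA_integer_
    d2[runif(spec$N) < spec$missing_rate] <- NA_integer_
  }
  complete <- !is.na(d1) & !is.na(d2)
  realized <- table(factor(cls[complete], levels = .GENOTYPE_CLASSES))
  realized <- setNames(as.numeric(realized), .GENOTYPE_CLASSES)
  realized_q <- if (any(complete)) {
    .estimate_q_from_counts9(realized)
  } else c(q1 = NA_real_, q2 = NA_real_)
  structure(list(spec = spec,
                 sample_names = sprintf("S%05d", seq_len(spec$N)),
                 dosage1 = unname(d1), dosage2 = unname(d2),
                 drawn_counts9 = drawn,
                 realized_counts9 = realized,
                 realized_q = realized_q,
                 n_missing = sum(!complete)),
            class = "synthetic_cohort")
}

.dosage_to_gt <- function(d) {
  gt <- c("0/0", "0/1", "1/1")[d + 1L]
  gt[is.na(d)] <- "./."
  gt
}

#' Write a synthetic cohort as a multi-sample VCF
#'
#' Produces a VCFv4.2 file with two GT-only records (one per variant)
#' and one column per sample; missing genotypes are written \code{./.}.
#' The file round-trips through \code{\link{count_pair}} to the cohort's
#' realized nine-class counts exactly.
#'
#' @param cohort A \code{synthetic_cohort}.
#' @param path Output file path (plain text; no compression).
#' @return \code{path}, invisibly.
#' @export
write_cohort_vcf <- function(cohort, path) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  v <- cohort$spec$variants
  contigs <- unique(vapply(v, `[[`, "", "chrom"))
  maxpos <- max(vapply(v, `[[`, 0L, "pos"))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=digenica_synthetic_cohort",
    sprintf("##contig=<ID=%s,length=%d>", contigs, maxpos + 1000L),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", cohort$sample_names), collapse = "\t"))
  rec <- function(key, dosage, id) {
    paste(c(key$chrom, key$pos, id, key$ref, key$alt, ".", "PASS", ".",
            "GT", .dosage_to_gt(dosage)), collapse = "\t")
  }
  # records in coordinate order within each contig
  recs <- c(rec(v[[1]], cohort$dosage1, "var1"),
            rec(v[[2]], cohort$dosage2, "var2"))
  ord <- order(vapply(v, `[[`, "", "chrom"), vapply(v, `[[`, 0L, "pos"))
  writeLines(c(header, recs[ord]), path)
  invisible(path)
}

#' Write the truth sidecar for a synthetic cohort
#'
#' JSON record of the generating parameters (including the seed) and the
#' realized counts, so downstream tests never re-derive the truth from
#' file names.
#'
#' @param cohort A \code{synthetic_cohort}.
#' @param path Output JSON path.
#' @return \code{path}, invisibly.
#' @export
write_cohort_truth <- function(cohort, path) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  s <- cohort$spec
  truth <- list(
    N = s$N, q1 = s$q1, q2 = s$q2, penetrance = s$penetrance,
    missing_rate = s$missing_rate, seed = s$seed,
    variants = lapply(s$variants, function(k)
      list(chrom = k$chrom, pos = k$pos, ref = k$ref, alt = k$alt)),
    drawn_counts9 = as.list(cohort$drawn_counts9),
    realized_counts9 = as.list(cohort$realized_counts9),
    realized_q1 = cohort$realized_q[["q1"]],
    realized_q2 = cohort$realized_q[["q2"]],
    realized_cocarriers =
      sum(cohort$realized_counts9[.COCARRIER_CLASSES]),
    n_missing = cohort$n_missing)
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
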