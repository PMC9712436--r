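# Shared fixtures and independent oracles for the test suite.

CLASSES <- genotype_classes()
COCARRIERS <- cocarrier_classes()

# Independent chi-squared goodness-of-fit oracle: Pearson sum written out
# longhand, upper-tail probability by numeric integration of the density
# (never pchisq, which the implementation uses).
chi2_oracle <- function(observed, expected, df) {
  stat <- 0
  for (i in seq_along(observed)) {
    stat <- stat + (observed[i] - expected[i])^2 / expected[i]
  }
  p <- stats::integrate(function(x) stats::dchisq(x, df),
                        lower = stat, upper = Inf,
                        rel.tol = 1e-12, abs.tol = 1e-14)$value
  list(statistic = unname(stat), p_value = min(1, p))
}

# Brute-force per-sample co-carrier tally straight from VCF text, used as
# the oracle for count_pair. Parses the file line by line without any
# VCF library.
brute_force_counts <- function(vcf_path, key1, key2) {
  lines <- readLines(vcf_path)
  body <- lines[!startsWith(lines, "##")]
  header <- strsplit(body[1], "\t")[[1]]
  samples <- header[-(1:9)]
  find_row <- function(key) {
    for (ln in body[-1]) {
      f <- strsplit(ln, "\t")[[1]]
      if (f[1] == key$chrom && as.integer(f[2]) == key$pos &&
          f[4] == key$ref) {
        alts <- strsplit(f[5], ",")[[1]]
        a <- match(key$alt, alts)
        if (!is.na(a)) return(list(gt = f[-(1:9)], alt_index = a))
      }
    }
    stop("oracle: variant not found")
  }
  dose <- function(row) {
    vapply(strsplit(row$gt, "[/|]"), function(al) {
      if (length(al) != 2L || any(al == ".")) return(NA_integer_)
      sum(al == as.character(row$alt_index))
    }, integer(1))
  }
  d1 <- dose(find_row(key1)); d2 <- dose(find_row(key2))
  counts <- setNames(numeric(9), CLASSES)
  for (i in seq_along(samples)) {
    if (is.na(d1[i]) || is.na(d2[i])) next
    cls <- CLASSES[d1[i] * 3L + d2[i] + 1L]
    counts[cls] <- counts[cls] + 1
  }
  counts
}

# random genotype count table at HWE-ish proportions, for property loops
random_counts9 <- function(N, q1, q2) {
  setNames(as.vector(rmultinom(1, N, hwe_genotype_freqs9(q1, q2))),
           CLASSES)
}

# write a multi-record GT-only VCF from a list of per-sample genotype
# string vectors (one element per record)
write_toy_vcf <- function(path, records, samples) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chrT,length=100000>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(records, function(r) {
    paste(c(r$chrom, r$pos, ".", r$ref, r$alt, ".", "PASS", ".", "GT",
            r$gt), collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
  path
}
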