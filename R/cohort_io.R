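# Carrier counting from multi-sample VCFs.
#
# A carrier is any individual whose genotype contains at least one copy
# of the requested alternate allele; phase is ignored, and genotypes
# carrying only *other* alternate alleles of a multi-allelic record
# count as non-carriers for the requested pair.

#' Variant identifier
#'
#' @param chrom Chromosome/contig name.
#' @param pos 1-based position.
#' @param ref Reference allele string.
#' @param alt One alternate allele string (one allele of a multi-allelic
#'   record is addressed by naming it here).
#' @param label Optional human-readable label (e.g. gene + cDNA change).
#' @return An object of class \code{variant_key}.
#' @export
variant_key <- function(chrom, pos, ref, alt, label = NULL) {
  pos <- as.integer(pos)
  if (is.na(pos) || pos < 1L) stop("'pos' must be >= 1", call. = FALSE)
  ref <- toupper(as.character(ref)); alt <- toupper(as.character(alt))
  if (!nzchar(ref) || !nzchar(alt)) {
    stop("'ref' and 'alt' must be non-empty", call. = FALSE)
  }
  if (identical(ref, alt)) stop("'ref' and 'alt' must differ", call. = FALSE)
  structure(list(chrom = as.character(chrom), pos = pos, ref = ref,
                 alt = alt,
                 label = if (is.null(label)) NA_character_
                         else as.character(label)),
            class = "variant_key")
}

#' @export
format.variant_key <- function(x, ...) {
  paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")
}

#' @export
print.variant_key <- function(x, ...) {
  cat("<variant>", format(x),
      if (!is.na(x$label)) paste0("(", x$label, ")"), "\n")
  invisible(x)
}

#' Parse a chrom:pos:ref:alt string
#'
#' @param s String like \code{"chrS:1000:A:G"}.
#' @return A \code{\link{variant_key}}.
#' @export
parse_variant_key <- function(s) {
  parts <- strsplit(s, ":", fixed = TRUE)[[1]]
  if (length(parts) != 4L) {
    stop("variant string must be chrom:pos:ref:alt, got '", s, "'",
         call. = FALSE)
  }
  variant_key(parts[1], parts[2], parts[3], parts[4])
}

#' Load a cohort VCF into memory
#'
#' Thin wrapper over \code{VariantAnnotation::readVcf} reading only the
#' GT field. Pass the returned object to the counting functions to avoid
#' re-reading the file for every pair.
#'
#' @param path VCF file (plain or bgzipped).
#' @return A \code{VariantAnnotation::VCF} object.
#' @export
load_cohort_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF not found: ", path, call. = FALSE)
  param <- VariantAnnotation::ScanVcfParam(info = NA, geno = "GT")
  VariantAnnotation::readVcf(path, genome = "unknown", param = param)
}

.as_vcf <- function(vcf) {
  if (is.character(vcf)) load_cohort_vcf(vcf) else vcf
}

# locate the record (and alt-allele index) matching a variant_key
.locate_variant <- function(vcf, variant) {
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  ref <- as.character(rr$REF)
  hits <- which(chrom == variant$chrom & pos == variant$pos &
                ref == variant$ref)
  for (i in hits) {
    alts <- as.character(rr$ALT[[i]])
    a <- match(variant$alt, alts)
    if (!is.na(a)) return(list(row = i, alt_index = a))
  }
  near <- which(chrom == variant$chrom)
  near <- near[order(abs(pos[near] - variant$pos))]
  near <- head(near, 3L)
  nearest <- if (length(near)) {
    paste(sprintf("%s:%d:%s>%s", chrom[near], pos[near], ref[near],
                  vapply(near, function(i)
                    paste(as.character(rr$ALT[[i]]), collapse = ","), "")),
          collapse = "; ")
  } else "none on that contig"
  stop("variant ", format(variant), " not found in VCF; nearest records: ",
       nearest, call. = FALSE)
}

# GT strings -> alt-allele dosage for one requested allele index
# (0, 1, 2, or NA for missing/malformed)
.gt_dosage <- function(gt, alt_index) {
  alleles <- strsplit(gt, "[/|]")
  vapply(alleles, function(a) {
    if (length(a) != 2L || any(a == ".") || any(!a %in% as.character(0:99))) {
      return(NA_integer_)
    }
    sum(a == as.character(alt_index))
  }, integer(1))
}

#' Per-sample carrier state for one variant
#'
#' @param vcf A loaded VCF object (see \code{\link{load_cohort_vcf}}) or
#'   a file path.
#' @param variant A \code{\link{variant_key}}. Multi-allelic records are
#'   matched on the requested alternate allele only.
#' @return Named character vector over samples with values
#'   \code{"non-carrier"}, \code{"het"}, \code{"hom"}, \code{"missing"}.
#'   Phased genotypes are treated like unphased; malformed genotype
#'   fields are counted missing with a warning.
#' @export
extract_genotypes <- function(vcf, variant) {
  vcf <- .as_vcf(vcf)
  loc <- .locate_variant(vcf, variant)
  gt <- VariantAnnotation::geno(vcf)$GT[loc$row, ]
  d <- .gt_dosage(gt, loc$alt_index)
  malformed <- is.na(d) & !(gt %in% c("./.", ".|.", "."))
  if (any(malformed)) {
    warning(sum(malformed), " malformed genotype(s) at ", format(variant),
            " counted as missing", call. = FALSE)
  }
  state <- c("non-carrier", "het", "hom")[d + 1L]
  state[is.na(d)] <- "missing"
  setNames(state, names(gt))
}

#' Count two-locus genotypes for a variant pair
#'
#' Tallies the nine two-locus genotype classes over all samples with
#' non-missing genotypes at both sites; samples missing at either site
#' are excluded pairwise. Also records the zygosity breakdown of the
#' co-carriers (Het/Het, Het/Hom, Hom/Het, Hom/Hom, variant 1 first).
#'
#' @param vcf Loaded VCF object or file path.
#' @param var1,var2 \code{\link{variant_key}}s; must be distinct sites.
#' @return An object of class \code{pair_observation}: \code{var1},
#'   \code{var2}, \code{counts9}, \code{N} (complete samples),
#'   \code{n_missing}, \code{zygosity}.
#' @export
count_pair <- function(vcf, var1, var2) {
  if (identical(format(var1), format(var2))) {
    stop("a pair must be two distinct variants, got ", format(var1),
         " twice", call. = FALSE)
  }
  vcf <- .as_vcf(vcf)
  s1 <- extract_genotypes(vcf, var1)
  s2 <- extract_genotypes(vcf, var2)
  ok <- s1 != "missing" & s2 != "missing"
  d1 <- match(s1[ok], c("non-carrier", "het", "hom")) - 1L
  d2 <- match(s2[ok], c("non-carrier", "het", "hom")) - 1L
  cls <- .GENOTYPE_CLASSES[d1 * 3L + d2 + 1L]
  counts9 <- setNames(
    as.numeric(table(factor(cls, levels = .GENOTYPE_CLASSES))),
    .GENOTYPE_CLASSES)
  zyg <- c(het_het = counts9[["AaBb"]], het_hom = counts9[["Aabb"]],
           hom_het = counts9[["aaBb"]], hom_hom = counts9[["aabb"]])
  structure(list(var1 = var1, var2 = var2, counts9 = counts9,
                 N = sum(ok), n_missing = sum(!ok), zygosity = zyg),
            class = "pair_observation")
}

#' @export
print.pair_observation <- function(x, ...) {
  cat("<pair>", format(x$var1), "x", format(x$var2), "\n")
  cat("  N =", x$N, "complete samples,", x$n_missing, "excluded (missing)\n")
  cat("  co-carriers:", sum(x$counts9[.COCARRIER_CLASSES]),
      sprintf("(Het/Het %d, Het/Hom %d, Hom/Het %d, Hom/Hom %d)\n",
              x$zygosity[["het_het"]], x$zygosity[["het_hom"]],
              x$zygosity[["hom_het"]], x$zygosity[["hom_hom"]]))
  invisible(x)
}

#' Read a variant-pair list
#'
#' Accepts a tab-separated file with columns \code{chrom1 pos1 ref1 alt1
#' chrom2 pos2 ref2 alt2} (header optional) plus an optional 9th
#' \code{label} column, or a character vector of
#' \code{"chrom:pos:ref:alt,chrom:pos:ref:alt"} strings.
#'
#' @param x File path or character vector.
#' @return List of two-element lists of \code{\link{variant_key}}s.
#' @export
read_pair_list <- function(x) {
  if (length(x) == 1L && file.exists(x)) {
    first <- readLines(x, n = 1L)
    has_header <- grepl("chrom|pos", tolower(first))
    tab <- read.delim(x, header = has_header, colClasses = "character",
                      stringsAsFactors = FALSE)
    if (ncol(tab) < 8L) {
      stop("pair list needs 8 columns (chrom1 pos1 ref1 alt1 chrom2 pos2 ",
           "ref2 alt2), got ", ncol(tab), call. = FALSE)
    }
    lapply(seq_len(nrow(tab)), function(i) {
      label <- if (ncol(tab) >= 9L) as.character(tab[i, 9L]) else NULL
      list(variant_key(tab[i, 1L], tab[i, 2L], tab[i, 3L], tab[i, 4L],
                       label = label),
           variant_key(tab[i, 5L], tab[i, 6L], tab[i, 7L], tab[i, 8L],
                       label = label))
    })
  } else {
    lapply(x, function(s) {
      parts <- strsplit(s, ",", fixed = TRUE)[[1]]
      if (length(parts) != 2L) {
        stop("pair string must be 'var1,var2', got '", s, "'",
             call. = FALSE)
      }
      list(parse_variant_key(parts[1]), parse_variant_key(parts[2]))
    })
  }
}

#' Screen a list of variant pairs in a cohort VCF
#'
#' For each pair: count the two-locus genotypes
#' (\code{\link{count_pair}}), run the depletion test
#' (\code{\link{digenic_test}}) with the minimum-expected-co-carrier
#' rule, then adjust p-values across the testable pairs and sort by
#' p-value. Failures on individual pairs (e.g. a variant absent from the
#' VCF) are reported as untestable rows, not fatal to the batch.
#'
#' @param vcf Loaded VCF object or file path.
#' @param pairs Pair list as returned by \code{\link{read_pair_list}}.
#' @param config A \code{\link{test_config}}.
#' @return List of \code{digenic_test_result}, sorted by p-value
#'   (untestable pairs last).
#' @export
screen_pairs <- function(vcf, pairs, config = test_config()) {
  if (!length(pairs)) stop("'pairs' must be non-empty", call. = FALSE)
  vcf <- .as_vcf(vcf)
  results <- lapply(pairs, function(pr) {
    id <- paste(format(pr[[1]]), format(pr[[2]]), sep = " x ")
    if (!is.na(pr[[1]]$label)) id <- pr[[1]]$label
    tryCatch({
      obs <- count_pair(vcf, pr[[1]], pr[[2]])
      if (obs$N == 0L) {
        r <- .new_test_result(id, NA_real_, NA_real_, 0L, 0, 0,
                              testable = FALSE, mode = config$mode,
                              note = "all samples missing at one site")
        return(r)
      }
      digenic_test(obs$counts9, config = config, pair_id = id)
    }, error = function(e) {
      message("pair ", id, " failed: ", conditionMessage(e))
      .new_test_result(id, NA_real_, NA_real_, 0L, NA_real_, NA_real_,
                       testable = FALSE, mode = config$mode,
                       note = conditionMessage(e))
    })
  })
  results <- adjust_pvalues(results, method = config$multiple_testing)
  p <- vapply(results, function(r)
    if (isTRUE(r$testable)) r$p_value else Inf, numeric(1))
  results[order(p)]
}
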