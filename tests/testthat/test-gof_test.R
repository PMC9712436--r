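test_that("chi2_gof matches the Pearson formula and the integration oracle", {
  # perfect fit
  expect_equal(chi2_gof(c(10, 20, 30), c(10, 20, 30), df = 2),
               list(statistic = 0, p_value = 1))
  # depleted co-carrier table; oracle values frozen from
  # direct Pearson sum + numeric integration of the chi2(1) density
  g <- chi2_gof(c(2, 3060, 97, 35182),
                c(8.098, 3053.9, 90.9, 35188.1), df = 1)
  expect_equal(g$statistic, 5.014542, tolerance = 1e-6)
  expect_equal(g$p_value, 0.02513528, tolerance = 1e-6)
  # the classic 3.84 critical value gives p ~ 0.05 at 1 df
  g2 <- chi2_gof(c(100 + sqrt(3.84 * 50), 100 - sqrt(3.84 * 50)),
                 c(100, 100), df = 1)
  expect_equal(g2$statistic, 3.84, tolerance = 1e-9)
  expect_equal(g2$p_value, 0.05004352, tolerance = 1e-6)
})

test_that("chi2_gof rejects malformed tables with informative errors", {
  expect_error(chi2_gof(c(1, 2), c(1, 2, 3), df = 1), "same number")
  expect_error(
    chi2_gof(c(1, 0, 2), c(1, 0, 2), df = 1), "category 2")
  e <- c(cocarriers = 0, other = 3)
  expect_error(chi2_gof(c(0, 3), e, df = 1), "cocarriers")
  expect_error(chi2_gof(c(10, 10), c(5, 5), df = 1), "totals differ")
})

test_that("chi2_gof agrees with the independent oracle on random tables", {
  set.seed(42)
  for (i in 1:100) {
    k <- sample(2:9, 1)
    expected <- runif(k, 5, 200)
    observed <- as.vector(rmultinom(1, round(sum(expected)),
                                    expected / sum(expected)))
    expected <- expected / sum(expected) * sum(observed)
    df <- sample(1:8, 1)
    got <- chi2_gof(observed, expected, df)
    want <- chi2_oracle(observed, expected, df)
    expect_equal(got$statistic, want$statistic, tolerance = 1e-10)
    expect_equal(got$p_value, want$p_value, tolerance = 1e-10)
  }
})

test_that("digenic_test estimates frequencies by allele counting", {
  # 10 alternate alleles at locus 1 over 2N = 200 chromosomes
  cnt <- setNames(numeric(9), CLASSES)
  cnt["AABB"] <- 91; cnt["AaBB"] <- 8; cnt["aaBB"] <- 1
  r <- digenic_test(cnt)
  expect_equal(r$q1_hat, 0.05)
  expect_equal(r$q2_hat, 0)
  expect_false(r$testable)           # locus 2 monomorphic
  expect_match(r$note, "monomorphic")
  # collapsed and full modes share the estimates
  set.seed(9)
  cnt2 <- random_counts9(5000, 0.2, 0.3)
  rc <- digenic_test(cnt2, test_config(mode = "collapsed"))
  rf <- digenic_test(cnt2, test_config(mode = "full"))
  expect_equal(rc$q1_hat, rf$q1_hat)
  expect_equal(rc$q2_hat, rf$q2_hat)
  expect_equal(rc$df, 1L)
  expect_equal(rf$df, 6L)
})

test_that("digenic_test is exact-null at a perfectly HWE table", {
  # q1 = q2 = 0.5, N = 16: all nine HWE expectations are integers
  cnt <- setNames(hwe_genotype_freqs9(0.5, 0.5) * 16, CLASSES)
  r <- digenic_test(genotype_counts9(cnt))
  expect_equal(r$chi2_statistic, 0)
  expect_equal(r$p_value, 1)
  expect_equal(r$difference, 0)
})

test_that("the minimum-expected-co-carrier rule flags pairs untestable", {
  cnt <- setNames(numeric(9), CLASSES)
  cnt["AABB"] <- 960; cnt["AaBB"] <- 20; cnt["AABb"] <- 19; cnt["AaBb"] <- 1
  r <- digenic_test(cnt)   # expected co-carriers ~ 0.8 << 5
  expect_false(r$testable)
  expect_true(is.na(r$p_value))
  expect_match(r$note, "expected co-carriers")
  r2 <- digenic_test(cnt, test_config(min_expected_cocarriers = 0))
  expect_true(r2$testable)
  expect_error(digenic_test(setNames(numeric(9), CLASSES)), "N must be")
})

test_that("difference preserves the sign of the depletion", {
  set.seed(13)
  cnt <- random_counts9(20000, 0.1, 0.1)
  # remove co-carriers by hand to force a deficit
  removed <- sum(cnt[COCARRIERS]) - c(1, 0, 0, 0)
  cnt[COCARRIERS] <- c(1, 0, 0, 0)
  cnt["AABB"] <- cnt["AABB"] + sum(removed)
  r <- digenic_test(genotype_counts9(cnt))
  expect_lt(r$difference, 0)
  expect_equal(r$difference, r$observed_cocarriers - r$expected_cocarriers)
})

test_that("null calibration: rejection rate is near alpha at large counts", {
  set.seed(2024)
  f <- hwe_genotype_freqs9(0.2, 0.2)   # collapsed expectations all >> 10
  reps <- 2000
  rej <- 0L
  for (i in seq_len(reps)) {
    cnt <- setNames(as.vector(rmultinom(1, 500, f)), CLASSES)
    r <- digenic_test(cnt)
    if (isTRUE(r$testable) && r$p_value < 0.05) rej <- rej + 1L
  }
  rate <- rej / reps
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("test_from_summary imputes single carriers and reproduces the table pattern", {
  # observed equal to expected -> perfect fit
  e <- expected_collapsed_counts(0.03, 0.04, 10000)
  r0 <- test_from_summary(0.03, 0.04, 10000, e[["cocarriers"]])
  expect_equal(r0$p_value, 1)
  # strong depletion at a rare/common pair is flagged significant
  r1 <- test_from_summary(0.0415, 0.0013, 38341, 2, pair_id = "depleted")
  expect_lt(r1$p_value, 0.05)
  expect_lt(r1$difference, 0)
  expect_match(r1$note, "imputed")
  # near-perfect agreement gives p close to 1
  r2 <- test_from_summary(0.00334, 0.0735, 38341, 36)
  expect_gt(r2$p_value, 0.9)
  expect_error(test_from_summary(0.1, 0.1, 100, 101), "\\[0, N\\]")
  expect_error(test_from_summary(0, 0.1, 100, 1), "strictly inside")
  # below the minimum expected co-carriers -> untestable, no p
  r3 <- test_from_summary(0.001, 0.001, 38341, 0)
  expect_false(r3$testable)
})

test_that("adjust_pvalues implements none/BH/bonferroni over testable results", {
  mk <- function(p, testable = TRUE) {
    r <- test_from_summary(0.05, 0.05, 10000, 93)
    r$p_value <- p; r$testable <- testable
    r
  }
  rs <- adjust_pvalues(list(mk(0.01), mk(0.02), mk(0.03)),
                       "benjamini-hochberg")
  expect_equal(vapply(rs, `[[`, 0, "adjusted_p"), c(0.03, 0.03, 0.03))
  one <- adjust_pvalues(list(mk(0.0171)), "benjamini-hochberg")
  expect_equal(one[[1]]$adjusted_p, 0.0171)
  bf <- adjust_pvalues(rep(list(mk(0.0237)), 5), "bonferroni")
  expect_equal(bf[[1]]$adjusted_p, 0.1185)
  none <- adjust_pvalues(list(mk(0.4)), "none")
  expect_equal(none[[1]]$adjusted_p, 0.4)
  # untestable results keep NA and do not count towards m
  mix <- adjust_pvalues(list(mk(0.01), mk(NA_real_, testable = FALSE)),
                        "bonferroni")
  expect_equal(mix[[1]]$adjusted_p, 0.01)   # m = 1
  expect_true(is.na(mix[[2]]$adjusted_p))
  expect_error(adjust_pvalues(list(mk(0.1)), "holm"), "arg")
})

test_that("results are tabulated and written with the report conventions", {
  rs <- list(test_from_summary(0.0415, 0.0013, 38341, 2, pair_id = "a"),
             test_from_summary(0.00334, 0.0735, 38341, 36, pair_id = "b"))
  rs <- adjust_pvalues(rs, "none")
  tab <- results_table(rs)
  expect_equal(tab$significant, c("*", ""))
  expect_equal(tab$exp, round(c(rs[[1]]$expected_cocarriers,
                                rs[[2]]$expected_cocarriers), 4))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_results(rs, tsv)
  back <- read.delim(tsv)
  expect_equal(nrow(back), 2)
  expect_equal(back$p_value, tab$p_value, tolerance = 1e-12)
  js <- withr::local_tempfile(fileext = ".json")
  write_results(rs, js, format = "json")
  expect_equal(jsonlite::read_json(js, simplifyVector = TRUE)$pair_id,
               c("a", "b"))
})
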