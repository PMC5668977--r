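make_mat <- function(counts, totals) {
  tpm <- sweep(counts, 2, totals, "/") * 1e6
  structure(list(counts = counts, tpm = tpm, totals = totals),
            class = "mirna_expression")
}

test_that("chi-square test matches hand-evaluated examples and symmetry", {
  r <- chisq_test(100, 1e6, 50, 1e6)
  expect_equal(r$chi2, chi2_closed(100, 1e6, 50, 1e6), tolerance = 1e-12)
  expect_equal(r$chi2, 16.67, tolerance = 1e-3)
  expect_equal(r$p, pchisq(r$chi2, 1, lower.tail = FALSE))
  expect_equal(r$p, 4.5e-5, tolerance = 0.02)

  same <- chisq_test(50, 1e6, 50, 1e6)
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)

  ab <- chisq_test(120, 5e5, 80, 7e5)
  ba <- chisq_test(80, 7e5, 120, 5e5)
  expect_equal(ab$chi2, ba$chi2)
  expect_equal(ab$p, ba$p)

  expect_error(chisq_test(10, 5, 1, 100), "count")
  expect_error(chisq_test(1, 100, 1, 0), "total")
})

test_that("chi-square equals the textbook closed form on random tables", {
  set.seed(99)
  for (i in 1:300) {
    ta <- sample(1e4:1e6, 1); tb <- sample(1e4:1e6, 1)
    a <- rbinom(1, ta, runif(1, 1e-4, 0.01))
    b <- rbinom(1, tb, runif(1, 1e-4, 0.01))
    if (a + b == 0) next
    r <- chisq_test(a, ta, b, tb)
    expect_equal(r$chi2, chi2_closed(a, ta, b, tb), tolerance = 1e-9)
  }
})

test_that("differential calls apply both fold-change and p thresholds", {
  counts <- matrix(c(400L, 100L, 15L, 10L, 6L, 2L),
                   nrow = 3, byrow = TRUE,
                   dimnames = list(c("m_up", "m_small_fc", "m_weak_p"),
                                   c("HS", "CK")))
  # per-library totals chosen so TPM equals count/1e4 * 1e6
  mat <- make_mat(counts, c(HS = 1e4, CK = 1e4))
  de <- call_differential(mat, "HS", "CK", contrast = "t")
  up <- de[de$mirna == "m_up", ]
  expect_equal(up$call, "up")
  expect_gt(up$log2fc, 1.9)
  expect_lt(up$p, 0.001)
  expect_equal(de[de$mirna == "m_small_fc", ]$call, "ns")   # |lfc| < 1
  weak <- de[de$mirna == "m_weak_p", ]
  expect_gte(abs(weak$log2fc), 1)                            # fc ok...
  expect_gt(weak$p, 0.05)                                    # ...but p fails
  expect_equal(weak$call, "ns")
})

test_that("swapping conditions negates log2fc and preserves p", {
  set.seed(7)
  counts <- matrix(rpois(40, 60), nrow = 10,
                   dimnames = list(paste0("m", 1:10), c("a1", "a2", "b1", "b2")))
  mat <- make_mat(counts, setNames(rep(2e5, 4), colnames(counts)))
  d1 <- call_differential(mat, c("a1", "a2"), c("b1", "b2"))
  d2 <- call_differential(mat, c("b1", "b2"), c("a1", "a2"))
  expect_equal(d1$log2fc, -d2$log2fc)
  expect_equal(d1$p, d2$p)
})

test_that("null Poisson counts give a calibrated type-I error (quick check)", {
  set.seed(11)
  n <- 600
  a <- rpois(n, 50); b <- rpois(n, 50)
  p <- chisq_test(a, 2e5, b, 2e5)$p
  rate <- mean(p <= 0.05)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})

test_that("replicate correlations behave at the extremes", {
  designs <- data.frame(library_id = c("r1", "r2"), tissue = "stamen",
                        condition = "CK", timepoint = "2d", replicate = 1:2)
  x <- c(10, 200, 3000, 0, 55)
  mat <- make_mat(cbind(r1 = x, r2 = x), c(r1 = 1e4, r2 = 1e4))
  rc <- replicate_correlation(mat, designs)
  expect_equal(rc$r, 1.0)

  # perfect anticorrelation on three points of log2(TPM+1)
  lx <- c(1, 2, 3)
  mat2 <- make_mat(cbind(r1 = 2^lx - 1, r2 = 2^(4 - lx) - 1),
                   c(r1 = 1e6, r2 = 1e6))
  rc2 <- replicate_correlation(mat2, designs)
  expect_equal(rc2$r, -1.0)

  # independent Poisson profiles decorrelate
  set.seed(4)
  mat3 <- make_mat(cbind(r1 = rpois(500, 40), r2 = rpois(500, 40)),
                   c(r1 = 1e6, r2 = 1e6))
  expect_lt(abs(replicate_correlation(mat3, designs)$r), 0.2)

  # zero variance flags undefined instead of erroring
  mat4 <- make_mat(cbind(r1 = rep(5, 4), r2 = c(1, 2, 3, 4)),
                   c(r1 = 1e4, r2 = 1e4))
  rc4 <- replicate_correlation(mat4, designs)
  expect_true(rc4$undefined)
  expect_true(is.na(rc4$r))
})

test_that("tissue specificity distinguishes specific, preferential and shared", {
  designs <- data.frame(
    library_id = c("st1", "st2", "pi1", "pi2"),
    tissue = rep(c("stamen", "pistil"), each = 2),
    condition = "CK", timepoint = "2d", replicate = c(1, 2, 1, 2))
  counts <- matrix(c(60, 60, 0, 0,        # stamen-specific
                     200, 200, 45, 45,    # stamen-preferential
                     50, 50, 48, 47),     # shared
                   nrow = 3, byrow = TRUE,
                   dimnames = list(c("sp", "pref", "sh"),
                                   c("st1", "st2", "pi1", "pi2")))
  mat <- make_mat(counts, setNames(rep(1e6, 4), colnames(counts)))
  ts <- tissue_specificity(mat, designs)
  expect_equal(ts$label, c("stamen-specific", "stamen-preferential", "shared"))
})

test_that("composition statistics normalise lengths and positions", {
  cs <- composition_stats(rep("TGACAGAAGAGAGTGAGCACAGCT", 5))  # all 24 nt
  expect_equal(cs$length_dist$length, 24L)
  expect_equal(cs$length_dist$fraction, 1.0)

  seqs <- c(rep("TGACAGAAGAGAGTGAG", 5), rep("GGACAGAAGAGAGTGAG", 5))
  cs2 <- composition_stats(seqs)
  expect_equal(cs2$five_prime_u, 0.5)
  sums <- rowSums(cs2$base_freq[1:17, ])
  expect_equal(sums, rep(1, 17), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("2^-ddCt fold changes follow the worked arithmetic", {
  expect_equal(ddct_fold_change(20, 18, 22, 18)$fold_change, 4.0)
  expect_equal(ddct_fold_change(19, 19, 19, 19)$fold_change, 1.0)
  expect_equal(ddct_fold_change(24, 18, 22, 18)$fold_change, 0.25)
  # replicate triplets: mean ddCt with propagated SE
  r <- ddct_fold_change(c(20, 20.2, 19.8), c(18, 18, 18),
                        c(22, 22, 22), c(18.1, 17.9, 18))
  expect_equal(r$ddct, -2, tolerance = 0.01)
  expect_false(is.na(r$se))
  expect_error(ddct_fold_change(NA, 18, 22, 18), "finite")
})

test_that("D-value summary measures stigma exsertion with a Welch test", {
  d <- dvalue_summary(c(8, 8, 8), c(8.37, 8.37, 8.37))
  expect_equal(d$d_value, -0.37)
  expect_true(d$undefined_variance)

  same <- dvalue_summary(c(8, 8, 8), c(8, 8, 8))
  expect_equal(same$d_value, 0)
  expect_equal(same$p, 1)

  set.seed(8)
  st <- rnorm(10, 8.0, 0.1); pi <- rnorm(10, 8.37, 0.1)
  ds <- dvalue_summary(st, pi)
  expect_lt(ds$p, 0.05)
  expect_lt(ds$d_value, 0)
  # Monte-Carlo oracle: Welch t-test run directly agrees
  expect_equal(ds$p, t.test(st, pi)$p.value)
  expect_error(dvalue_summary(c(1, 2), c(1, 2, 3)), "3 measurements")
})

test_that("DE overlap tables mirror Venn membership", {
  ov <- de_overlap(list(stamen = c("a", "b", "c"), pistil = c("b", "d")))
  expect_equal(ov$membership[ov$mirna == "b"], "stamen&pistil")
  expect_equal(ov$membership[ov$mirna == "a"], "stamen")
  expect_equal(nrow(ov), 4L)
})
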