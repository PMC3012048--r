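test_that("site frequencies follow the counting and small-sample formulas", {
  # 4 identical single-base sites
  expect_equal(unname(site_frequencies(rep("A", 4))["A", 1]), 1)
  f3 <- site_frequencies(rep("A", 4), small_sample = TRUE)
  expect_equal(unname(f3["A", 1]), (4 + 1) / 8, tolerance = 1e-12)   # 0.625
  expect_equal(unname(f3["C", 1]), (0 + 1) / 8, tolerance = 1e-12)   # 0.125
  expect_equal(sum(f3[, 1]), 1, tolerance = 1e-12)
  # plain counting on a mixed column
  f1 <- site_frequencies(c("A", "A", "C", "G", "T", "T", "T", "G", "C",
                           "A"))
  expect_equal(as.numeric(f1[, 1]), c(3, 2, 2, 3) / 10, tolerance = 1e-12)
})

test_that("log-odds weights are log2(f/p) with the stated background", {
  # small-sample weights for the 4x"A" case, hand arithmetic
  p <- build_pwm(rep("A", 4), small_sample = TRUE)
  expect_equal(unname(p$weights["A", 1]), log2(0.625 / 0.3), tolerance = 1e-12)
  expect_equal(unname(p$weights["C", 1]), log2(0.125 / 0.2), tolerance = 1e-12)
  expect_equal(unname(p$weights["T", 1]), log2(0.125 / 0.3), tolerance = 1e-12)
  # without the correction the same frequencies give log2(1/0.3)
  f <- site_frequencies(rep("A", 4))
  expect_equal(unname(log2(f["A", 1] / 0.3)), log2(1 / 0.3), tolerance = 1e-12)
  # a column whose A fraction equals the background weight is zero
  sites <- c("A", "A", "A", "C", "C", "G", "G", "T", "T", "T")
  p2 <- build_pwm(sites)
  expect_equal(unname(p2$weights["A", 1]), 0, tolerance = 1e-12)
  # zero count without the correction is refused with guidance
  expect_error(build_pwm(rep("A", 4)), "small_sample")
  expect_error(build_pwm(character()), "no binding sites")
})

test_that("hand-evaluated scores on a two-column toy matrix", {
  # sites: AC, AC, AG, TG -> f: col1 A=3/4, T=1/4; col2 C=1/2, G=1/2
  p <- build_pwm(c("AC", "AC", "AG", "TG"), small_sample = TRUE,
                 core = c(1, 2))
  # small-sample f: col1 A=(3+1)/8=.5, C=1/8, G=1/8, T=(1+1)/8=.25
  w_a1 <- log2(0.5 / 0.3); w_t1 <- log2(0.25 / 0.3)
  w_c2 <- log2(0.375 / 0.2); w_g2 <- log2(0.375 / 0.2)
  expect_equal(unname(p$weights["A", 1]), w_a1, tolerance = 1e-12)
  sc <- pwm_score(p, "TC")
  w_min1 <- min(p$weights[, 1]); w_min2 <- min(p$weights[, 2])
  w_max1 <- max(p$weights[, 1]); w_max2 <- max(p$weights[, 2])
  expect_equal(sc$s_seq, w_t1 + w_c2, tolerance = 1e-12)
  expect_equal(sc$s_pwm,
               (w_t1 + w_c2 - (w_min1 + w_min2)) /
                 (w_max1 + w_max2 - (w_min1 + w_min2)),
               tolerance = 1e-12)
})

test_that("consensus and anti-consensus windows hit the score bounds", {
  set.seed(31)
  for (i in 1:10) {
    p <- random_test_pwm()
    cons <- pwm_consensus(p)
    anti <- paste(c("A", "C", "G", "T")[apply(p$weights, 2, which.min)],
                  collapse = "")
    expect_equal(pwm_score(p, cons)$s_pwm, 1)
    expect_equal(core_score(p, cons), 1)
    expect_equal(pwm_score(p, anti)$s_pwm, 0)
    # all scores stay inside [0, 1] on random windows
    win <- random_test_seq(p$n)
    s <- pwm_score(p, win)$s_pwm
    expect_true(s >= 0 && s <= 1)
    cs <- core_score(p, win)
    expect_true(cs >= 0 && cs <= 1)
  }
})

test_that("small-sample weights are always finite", {
  set.seed(77)
  for (i in 1:10) {
    p <- random_test_pwm(m = sample(2:6, 1))  # tiny site sets
    expect_true(all(is.finite(p$weights)))
    expect_true(all(p$freq > 0 & p$freq < 1))
    expect_equal(colSums(p$freq), rep(1, p$n), tolerance = 1e-9)
  }
})

test_that("auto core selection maximizes information content, leftmost on ties", {
  # identical columns everywhere: every window ties -> leftmost
  p <- build_pwm(rep(strrep("A", 8), 4), small_sample = TRUE)
  expect_equal(p$core, c(1L, 5L))
  # conserved block at columns 4-8 flanked by balanced (low-information)
  # columns: the unique maximum window is 4..8
  cols <- list(c("A", "C", "G", "T"), c("C", "G", "T", "A"),
               c("G", "T", "A", "C"), rep("A", 4), rep("C", 4),
               rep("G", 4), rep("T", 4), rep("G", 4),
               c("T", "A", "C", "G"), c("A", "C", "G", "T"),
               c("C", "G", "T", "A"))
  sites <- vapply(1:4, function(i)
    paste(vapply(cols, `[`, character(1), i), collapse = ""), character(1))
  p2 <- build_pwm(sites, small_sample = TRUE)
  expect_equal(p2$core, c(4L, 8L))
})

test_that("scanner finds planted sites, skips N, and respects strand", {
  p <- toy_pwm()
  cons <- pwm_consensus(p)
  seq <- paste0("TTTTTTTTTTTT", cons, "TTTTTTTT")
  hits <- scan_sequence(p, seq, strands = "forward")
  expect_equal(hits$offset, 12L)
  expect_equal(hits$strand, "+")
  expect_equal(hits$s_pwm, 1)
  expect_equal(hits$s_core, 1)

  # all-N sequence yields nothing
  expect_equal(nrow(scan_sequence(p, strrep("N", 50))), 0L)
  # sequence shorter than the matrix yields nothing (not an error)
  expect_equal(nrow(scan_sequence(p, "ACGT")), 0L)

  # reverse complement hit on the minus strand at the mirrored offset
  rc_hits <- scan_sequence(p, reverse_complement(seq))
  expect_equal(rc_hits$strand, "-")
  expect_equal(rc_hits$offset, nchar(seq) - p$n - 12L)
})

test_that("hits mirror exactly between a sequence and its reverse complement", {
  set.seed(19)
  for (i in 1:5) {
    p <- random_test_pwm()
    s <- random_test_seq(300)
    h1 <- scan_sequence(p, s, core_threshold = 0.6, pwm_threshold = 0.7)
    h2 <- scan_sequence(p, reverse_complement(s), core_threshold = 0.6,
                        pwm_threshold = 0.7)
    flip <- data.frame(offset = nchar(s) - p$n - h2$offset,
                       strand = ifelse(h2$strand == "+", "-", "+"),
                       stringsAsFactors = FALSE)
    ord1 <- order(h1$offset, h1$strand)
    ord2 <- order(flip$offset, flip$strand)
    expect_equal(h1$offset[ord1], flip$offset[ord2])
    expect_equal(h1$strand[ord1], flip$strand[ord2])
  }
})

test_that("scan output equals exhaustive enumeration on random cases", {
  set.seed(57)
  for (i in 1:8) {
    p <- random_test_pwm()
    s <- random_test_seq(sample(60:250, 1), n_prob = 0.01)
    ct <- runif(1, 0.4, 0.9)
    pt <- runif(1, 0.5, 0.9)
    got <- scan_sequence(p, s, core_threshold = ct, pwm_threshold = pt)
    want <- oracle_scan(p$weights, p$core, s, ct, pt)
    expect_equal(got$offset, want$offset)
    expect_equal(got$strand, want$strand)
    expect_equal(got$s_pwm, want$s_pwm, tolerance = 1e-9)
    expect_equal(got$s_core, want$s_core, tolerance = 1e-9)
  }
})
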