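# Independent oracle implementations used to cross-check the package.
# These share no code with the package internals: sequences are handled
# as character vectors, scores computed by direct transliteration of the
# scoring formulas, and the Fisher tail by explicit binomial-coefficient
# sums.

oracle_rc <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1L]]),
        collapse = "")
}

# exhaustive window scoring; returns data.frame(offset, strand, s_pwm,
# s_core) of windows meeting both thresholds (1e-9 comparison slack for
# floating-point summation order)
oracle_scan <- function(weights, core, seq, core_threshold, pwm_threshold,
                        strands = "both") {
  bases <- c("A", "C", "G", "T")
  n <- ncol(weights)
  smin <- sum(apply(weights, 2, min))
  smax <- sum(apply(weights, 2, max))
  k1 <- core[1L]; k2 <- core[2L]; k <- k2 - k1 + 1L
  cw <- weights[, k1:k2, drop = FALSE]
  cmin <- sum(apply(cw, 2, min))
  cmax <- sum(apply(cw, 2, max))

  score_strand <- function(s, strand) {
    idx <- match(strsplit(s, "", fixed = TRUE)[[1L]], bases)
    L <- length(idx)
    if (L < n) return(NULL)
    rows <- lapply(seq_len(L - n + 1L), function(d) {
      win <- idx[d:(d + n - 1L)]
      if (anyNA(win)) return(NULL)
      sseq <- sum(weights[cbind(win, seq_len(n))])
      spwm <- if (smax == smin) 1 else (sseq - smin) / (smax - smin)
      raws <- vapply(seq_len(n - k + 1L), function(dd)
        sum(cw[cbind(win[dd:(dd + k - 1L)], seq_len(k))]), numeric(1L))
      score <- if (cmax == cmin) 1 else (max(raws) - cmin) / (cmax - cmin)
      if (spwm >= pwm_threshold - 1e-9 && score >= core_threshold - 1e-9) {
        data.frame(offset = if (strand == "+") d - 1L else L - n - (d - 1L),
                   strand = strand, s_pwm = spwm, s_core = score,
                   stringsAsFactors = FALSE)
      } else NULL
    })
    do.call(rbind, rows)
  }

  out <- score_strand(seq, "+")
  if (strands == "both") out <- rbind(out, score_strand(oracle_rc(seq), "-"))
  if (is.null(out)) {
    out <- data.frame(offset = integer(), strand = character(),
                      s_pwm = numeric(), s_core = numeric(),
                      stringsAsFactors = FALSE)
  }
  out <- out[order(out$offset, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# brute-force shuffle-and-rescan loop (character-level, own RNG draws)
oracle_shuffle_ratio <- function(weights, core, seq, n_shuffles,
                                 core_threshold, pwm_threshold,
                                 strands = "both") {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- logical(n_shuffles)
  for (i in seq_len(n_shuffles)) {
    s <- paste(sample(ch), collapse = "")
    hit[i] <- nrow(oracle_scan(weights, core, s, core_threshold,
                               pwm_threshold, strands)) > 0L
  }
  mean(hit)
}

# one-sided hypergeometric tail P(X >= k) by explicit coefficient sums
oracle_fisher_tail <- function(k, n_a, n_b, N) {
  hi <- min(n_a, n_b)
  if (k > hi) return(0)
  sum(vapply(k:hi, function(i) {
    exp(lchoose(n_a, i) + lchoose(N - n_a, n_b - i) - lchoose(N, n_b))
  }, numeric(1L)))
}

# random PWM for property tests (drawn from the caller's RNG stream)
random_test_pwm <- function(n = sample(6:12, 1L), m = sample(6:20, 1L)) {
  bases <- c("A", "C", "G", "T")
  sites <- vapply(seq_len(m), function(i)
    paste(sample(bases, n, replace = TRUE), collapse = ""), character(1L))
  build_pwm(sites, small_sample = TRUE, core = "auto",
            name = sprintf("rand%d", n))
}

# random DNA with optional N contamination
random_test_seq <- function(len, n_prob = 0) {
  alph <- c("A", "C", "G", "T")
  s <- sample(alph, len, replace = TRUE, prob = c(.3, .2, .2, .3))
  if (n_prob > 0) {
    flip <- runif(len) < n_prob
    s[flip] <- "N"
  }
  paste(s, collapse = "")
}
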