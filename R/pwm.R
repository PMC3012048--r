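#' Background base composition model
#'
#' A background model assigns each base a strictly positive probability;
#' the probabilities must sum to 1. The default is the approximate human
#' genome composition used throughout the pipeline: A/T at 30%, C/G at 20%.
#'
#' @param p Named numeric vector of probabilities for A, C, G, T.
#' @return A named numeric vector of class `"background_model"`.
#' @examples
#' background_model()                       # human-like default
#' background_model(c(A = .25, C = .25, G = .25, T = .25))
#' @export
background_model <- function(p = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)) {
  if (!is.numeric(p) || length(p) != 4L) {
    stop("background must be a numeric vector of length 4 (A, C, G, T)")
  }
  if (is.null(names(p))) names(p) <- DNA_BASES
  p <- p[DNA_BASES]
  if (anyNA(p)) stop("background must name all of A, C, G, T")
  if (any(p <= 0)) stop("background probabilities must be strictly positive")
  if (abs(sum(p) - 1) > 1e-9) stop("background probabilities must sum to 1")
  structure(p, class = "background_model")
}

#' Per-column base frequencies of an aligned site set
#'
#' The frequency matrix underlying [build_pwm()]: `f(i,j)` is the
#' fraction of the `m` sites carrying base `i` at column `j`; with
#' `small_sample = TRUE` the additive `m/4` pseudocount version
#' `f = (count + m/4) / (m + m)` is returned instead.
#'
#' @param sites Character vector of equal-length DNA strings over
#'   \{A,C,G,T\}.
#' @param small_sample Apply the pseudocount correction.
#' @return A 4 x n numeric matrix with rows A, C, G, T; columns sum to 1.
#' @examples
#' site_frequencies(rep("A", 4))                      # f(A,1) = 1
#' site_frequencies(rep("A", 4), small_sample = TRUE) # f(A,1) = 5/8
#' @export
site_frequencies <- function(sites, small_sample = FALSE) {
  sites <- toupper(unlist(sites, use.names = FALSE))
  if (length(sites) == 0L) stop("no binding sites supplied")
  n <- unique(nchar(sites))
  if (length(n) != 1L || n == 0L) {
    stop("binding sites must all have the same non-zero length")
  }
  m <- length(sites)
  codes <- matrix(vapply(sites, .encode_dna, integer(n),
                         USE.NAMES = FALSE), nrow = n, ncol = m)
  if (anyNA(codes)) stop("binding sites must be unambiguous (no N allowed)")
  counts <- vapply(seq_len(n), function(j) tabulate(codes[j, ], nbins = 4L),
                   numeric(4L))
  freq <- if (small_sample) (counts + m / 4) / (2 * m) else counts / m
  dimnames(freq) <- list(DNA_BASES, NULL)
  freq
}

#' Build a position weight matrix from aligned binding sites
#'
#' Computes the per-column base frequency matrix from `m` aligned,
#' equal-length binding sites and converts it to log2 odds against a
#' background model: `w(i,j) = log2(f(i,j) / p(i))`. With
#' `small_sample = TRUE` the frequencies receive an additive pseudocount of
#' `m/4` per base, `f = (count + m/4) / (m + m)`, which keeps every
#' frequency strictly inside (0, 1) so all weights are finite. Without the
#' correction a zero count is an error, since its log-odds weight would be
#' `-Inf`.
#'
#' The core region is the contiguous column span used by [core_score()] as
#' a stringent pre-filter. With `core = "auto"` the window of
#' `core_length` consecutive columns (or all columns when the matrix is
#' shorter) maximizing summed relative entropy versus the background is
#' chosen, ties going to the leftmost window.
#'
#' @param sites Character vector of equal-length DNA strings over
#'   \{A,C,G,T\}, or a list of such strings.
#' @param background A [background_model()].
#' @param small_sample Apply the additive `m/4` pseudocount correction.
#' @param core Either `"auto"` or an integer vector `c(k1, k2)` of 1-based
#'   inclusive core column bounds.
#' @param core_length Core window length used when `core = "auto"`.
#' @param name Matrix name (carried into hits and network edges).
#' @return An object of class `"pwm"`: a list with elements `name`, `n`,
#'   `freq` (4 x n), `weights` (4 x n), `core` (`c(k1, k2)`),
#'   `background`, and `small_sample`.
#' @examples
#' build_pwm(c("ACGT", "ACGT", "ACGA"), small_sample = TRUE)
#' @seealso [pwm_score()], [core_score()], [scan_sequence()]
#' @export
build_pwm <- function(sites, background = background_model(),
                      small_sample = FALSE, core = "auto",
                      core_length = 5L, name = "pwm") {
  background <- background_model(unclass(background))
  freq <- site_frequencies(sites, small_sample = small_sample)
  n <- ncol(freq)
  if (!small_sample && any(freq == 0)) {
    stop("zero base count in at least one column; use small_sample = TRUE ",
         "(log2(0) is undefined)")
  }
  weights <- log2(freq / as.numeric(background))

  if (identical(core, "auto")) {
    k <- min(as.integer(core_length), n)
    # relative entropy of each column against the background
    ic <- colSums(freq * log2(freq / as.numeric(background)))
    win <- vapply(seq_len(n - k + 1L),
                  function(s) sum(ic[s:(s + k - 1L)]), numeric(1L))
    k1 <- which.max(win)                       # leftmost maximum
    core <- c(k1, k1 + k - 1L)
  } else {
    core <- as.integer(core)
    if (length(core) != 2L || core[1L] < 1L || core[2L] > n ||
        core[1L] > core[2L]) {
      stop("core must be \"auto\" or c(k1, k2) with 1 <= k1 <= k2 <= n")
    }
  }

  structure(list(name = name, n = n, freq = freq, weights = weights,
                 core = as.integer(core), background = background,
                 small_sample = isTRUE(small_sample)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM '%s': %d columns, core columns %d-%d%s\n", x$name, x$n,
              x$core[1L], x$core[2L],
              if (x$small_sample) " (small-sample corrected)" else ""))
  cat("Consensus:", pwm_consensus(x), "\n")
  print(round(x$freq, 3), ...)
  invisible(x)
}

#' Per-column argmax consensus of a PWM
#'
#' @param pwm A [build_pwm()] object.
#' @return The consensus string (ties resolved to the first base in
#'   A, C, G, T order).
#' @export
pwm_consensus <- function(pwm) {
  paste(DNA_BASES[apply(pwm$weights, 2L, which.max)], collapse = "")
}

# column-wise minima / maxima of the weights over a column span
.col_extremes <- function(weights, cols) {
  w <- weights[, cols, drop = FALSE]
  list(smin = sum(apply(w, 2L, min)), smax = sum(apply(w, 2L, max)))
}

# min-max normalization; a constant matrix (smax == smin) scores 1 by
# convention so the consensus identity s = 1 still holds. Values within
# 1e-12 of the exact bounds are snapped to 0/1 so that a perfect
# (anti-)consensus match scores exactly 1 (0) regardless of floating-point
# summation order — the inclusive thresholds (core score 1) rely on it.
.minmax <- function(s, smin, smax) {
  if (smax == smin) {
    out <- s
    out[!is.na(out)] <- 1
    return(out)
  }
  out <- (s - smin) / (smax - smin)
  out[!is.na(out) & abs(out - 1) < 1e-12] <- 1
  out[!is.na(out) & abs(out) < 1e-12] <- 0
  out
}

#' Score one window with a PWM
#'
#' The raw sequence score is the sum of the matched log-odds weights,
#' `S_seq = sum_j w(base_j, j)`; it is normalized to `[0, 1]` by the
#' column-wise extremes, `S_PWM = (S_seq - S_min) / (S_max - S_min)` where
#' `S_min` (`S_max`) sums the per-column minimum (maximum) weight. The
#' per-column argmax window therefore scores exactly 1 and the argmin
#' window exactly 0. Windows containing N receive `NA` scores (callers
#' skip them).
#'
#' @param pwm A [build_pwm()] object.
#' @param window DNA string whose length equals the number of PWM columns.
#' @return A list with `s_seq`, `s_pwm`, `s_min`, `s_max`.
#' @examples
#' p <- build_pwm(c("ACGT", "ACGT", "ACGA"), small_sample = TRUE)
#' pwm_score(p, "ACGT")
#' @export
pwm_score <- function(pwm, window) {
  stopifnot(inherits(pwm, "pwm"))
  codes <- .encode_dna(window)
  if (length(codes) != pwm$n) {
    stop("window length ", length(codes), " does not match PWM width ", pwm$n)
  }
  ex <- .col_extremes(pwm$weights, seq_len(pwm$n))
  s_seq <- sum(pwm$weights[cbind(codes, seq_len(pwm$n))])
  list(s_seq = s_seq,
       s_pwm = .minmax(s_seq, ex$smin, ex$smax),
       s_min = ex$smin, s_max = ex$smax)
}

#' Core score of one window
#'
#' The core columns `k1..k2` (length `k`) of the matrix are slid along the
#' window: for each of the `n - k + 1` placements `d` the raw score
#' `S_seq,d` sums the core-column weights evaluated at window positions
#' `d..d+k-1`; each placement is min-max normalized using the extremes of
#' the core columns only, and the core score is the maximum over
#' placements. A core score of 1 therefore means some placement matches
#' the core's best bases perfectly.
#'
#' @inheritParams pwm_score
#' @return The core score in `[0, 1]` (`NA` if the window contains N).
#' @export
core_score <- function(pwm, window) {
  stopifnot(inherits(pwm, "pwm"))
  codes <- .encode_dna(window)
  if (length(codes) != pwm$n) {
    stop("window length ", length(codes), " does not match PWM width ", pwm$n)
  }
  if (anyNA(codes)) return(NA_real_)
  k1 <- pwm$core[1L]; k2 <- pwm$core[2L]
  k <- k2 - k1 + 1L
  ex <- .col_extremes(pwm$weights, k1:k2)
  cols <- k1:k2
  raw <- vapply(seq_len(pwm$n - k + 1L), function(d) {
    sum(pwm$weights[cbind(codes[d:(d + k - 1L)], cols)])
  }, numeric(1L))
  max(.minmax(raw, ex$smin, ex$smax))
}

# Vectorized window scoring over a matrix of encoded sequences.
# M: S x L integer matrix (rows = sequences, NA = N). Returns NULL when the
# sequences are shorter than the matrix, otherwise matrices s_seq, s_pwm,
# s_core of dimension S x (L - n + 1). Windows touching an N have NA s_seq
# and s_pwm; their s_core is the max over N-free core placements (possibly
# NA) but such windows are masked by callers via is.na(s_seq).
.window_scores <- function(pwm, M) {
  n <- pwm$n
  L <- ncol(M)
  if (is.null(L) || L < n) return(NULL)
  S <- nrow(M)
  W <- L - n + 1L

  w <- pwm$weights
  s_seq <- matrix(0, S, W)
  for (j in seq_len(n)) {
    s_seq <- s_seq + matrix(w[, j][M[, j:(j + W - 1L), drop = FALSE]], S, W)
  }
  ex <- .col_extremes(w, seq_len(n))
  s_pwm <- .minmax(s_seq, ex$smin, ex$smax)

  k1 <- pwm$core[1L]; k2 <- pwm$core[2L]
  k <- k2 - k1 + 1L
  P <- L - k + 1L
  C <- matrix(0, S, P)
  for (j in k1:k2) {
    off <- j - k1
    C <- C + matrix(w[, j][M[, (1L + off):(P + off), drop = FALSE]], S, P)
  }
  cex <- .col_extremes(w, k1:k2)
  # per-window max over the n - k + 1 core placements inside the window
  ncand <- n - k + 1L
  core_raw <- C[, 1:W, drop = FALSE]
  if (ncand > 1L) {
    for (d in 2:ncand) {
      core_raw <- pmax(core_raw, C[, d:(d + W - 1L), drop = FALSE],
                       na.rm = TRUE)
    }
  }
  s_core <- .minmax(core_raw, cex$smin, cex$smax)

  list(s_seq = s_seq, s_pwm = s_pwm, s_core = s_core)
}

#' Scan a sequence for PWM hits
#'
#' Slides an n-column window along the sequence (and along its reverse
#' complement when `strands = "both"`) and reports every window whose
#' core score and PWM score reach the thresholds. The defaults — core
#' score 1 (a perfect core match) and PWM score 0.95 — are the stringent
#' settings used for calling binding sites inside ChIP peak regions.
#' Windows containing N are skipped. Offsets are 0-based window starts in
#' forward-strand coordinates for both strands; hits are ordered by
#' offset, `+` before `-` at equal offset.
#'
#' @param pwm A [build_pwm()] object.
#' @param seq DNA string (may contain N).
#' @param core_threshold,pwm_threshold Inclusive hit thresholds.
#' @param strands `"both"` or `"forward"`.
#' @param sequence_id Identifier copied into the hit table.
#' @return A data frame of hits with columns `sequence_id`, `offset`,
#'   `strand`, `s_seq`, `s_pwm`, `s_core`. Sequences shorter than the
#'   matrix yield zero rows.
#' @examples
#' p <- build_pwm(c("ACGTA", "ACGTA", "ACGTT"), small_sample = TRUE)
#' scan_sequence(p, paste0("TTTT", pwm_consensus(p), "TTTT"))
#' @export
scan_sequence <- function(pwm, seq, core_threshold = 1.0,
                          pwm_threshold = 0.95,
                          strands = c("both", "forward"),
                          sequence_id = "seq") {
  stopifnot(inherits(pwm, "pwm"))
  strands <- match.arg(strands)
  codes <- .encode_dna(seq)
  empty <- data.frame(sequence_id = character(), offset = integer(),
                      strand = character(), s_seq = numeric(),
                      s_pwm = numeric(), s_core = numeric(),
                      stringsAsFactors = FALSE)
  L <- length(codes)
  if (L < pwm$n) return(empty)

  one_strand <- function(cod, strand) {
    sc <- .window_scores(pwm, matrix(cod, nrow = 1L))
    ok <- which(!is.na(sc$s_seq[1L, ]) &
                  sc$s_pwm[1L, ] >= pwm_threshold &
                  !is.na(sc$s_core[1L, ]) &
                  sc$s_core[1L, ] >= core_threshold)
    if (length(ok) == 0L) return(empty)
    # map 1-based window index d to a 0-based forward-strand offset
    offset <- if (strand == "+") ok - 1L else L - pwm$n - (ok - 1L)
    data.frame(sequence_id = sequence_id, offset = offset, strand = strand,
               s_seq = sc$s_seq[1L, ok], s_pwm = sc$s_pwm[1L, ok],
               s_core = sc$s_core[1L, ok], stringsAsFactors = FALSE)
  }

  hits <- one_strand(codes, "+")
  if (strands == "both") {
    hits <- rbind(hits, one_strand(.revcomp_codes(codes), "-"))
  }
  hits <- hits[order(hits$offset, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Select the highest-enrichment peaks
#'
#' Returns the `n` peaks with the largest enrichment scores, ties broken
#' deterministically by (chrom, start) ascending. Used to pick the top
#' peaks (2000 in the original analysis) fed to de novo motif discovery.
#'
#' @param peaks Peak data frame (see [read_peaks()]).
#' @param n Number of peaks to keep; if fewer peaks exist all are returned.
#' @return The selected rows, highest score first.
#' @export
select_top_peaks <- function(peaks, n = 2000L) {
  if (!is.numeric(n) || length(n) != 1L || n <= 0) {
    stop("n must be a positive integer")
  }
  if (is.null(peaks$score)) stop("peaks must carry enrichment scores")
  ord <- order(-peaks$score, peaks$chrom, peaks$start)
  out <- peaks[ord[seq_len(min(as.integer(n), nrow(peaks)))], , drop = FALSE]
  rownames(out) <- NULL
  out
}
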