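# Differential-expression calls feeding the network layer. Two modes
# mirror the two experimental designs: a time series scored by the sign
# of the late-minus-early difference, and replicated control/treated
# matrices scored by Welch's t-test plus a fold-change cutoff.

#' Up/down calls from a time series
#'
#' A gene is called up-regulated when its expression at `t_late` exceeds
#' that at `t_early` and down-regulated when it is lower; genes with an
#' exactly zero difference receive no call. This is the sign rule applied
#' to the 0/3/6/12 h estrogen-stimulation series in the original
#' analysis (12 h minus 0 h).
#'
#' @param expr Data frame with a `gene_id` column and one numeric column
#'   per time point, named by the hour (see [read_expression()]).
#' @param t_late,t_early Time points (hours) to difference.
#' @return Data frame of calls: `gene_id`, `direction` (`"up"`/`"down"`),
#'   `magnitude` (signed difference), `p_value` (`NA`; no test is
#'   involved). Zero-difference genes are dropped.
#' @export
classify_timeseries <- function(expr, t_late = 12, t_early = 0) {
  tcols <- setdiff(names(expr), "gene_id")
  tvals <- suppressWarnings(as.numeric(tcols))
  pick <- function(t) {
    j <- which(!is.na(tvals) & tvals == t)
    if (length(j) != 1L) stop("time point ", t, " h missing from table")
    expr[[tcols[j]]]
  }
  magnitude <- pick(t_late) - pick(t_early)
  if (any(!is.finite(magnitude))) stop("expression values must be finite")
  keep <- magnitude != 0
  data.frame(gene_id = expr$gene_id[keep],
             direction = ifelse(magnitude[keep] > 0, "up", "down"),
             magnitude = magnitude[keep],
             p_value = NA_real_,
             stringsAsFactors = FALSE)
}

# Welch two-sample t-test for one gene; handles the degenerate
# zero-variance case (p = 0 when the means differ, 1 when equal)
.welch_p <- function(control, treated) {
  if (stats::var(control) + stats::var(treated) == 0) {
    return(if (mean(control) == mean(treated)) 1 else 0)
  }
  stats::t.test(treated, control, var.equal = FALSE)$p.value
}

#' Up/down calls from replicated control/treated expression
#'
#' Per gene, a two-tailed Welch t-test (unequal variances,
#' Welch–Satterthwaite degrees of freedom) compares treated to control
#' replicates; a call is made iff `p < alpha` and the linear-scale mean
#' fold change `mean(treated)/mean(control)` is at least `fold` or at
#' most `1/fold`. The defaults (p < 0.05, 2-fold) are the cutoffs used
#' for the replicated tamoxifen-resistant-line arrays. When both groups
#' have zero variance the test is degenerate: p is taken as 0 when the
#' means differ and no call is made when they are equal.
#'
#' @param expr Data frame with `gene_id` plus columns prefixed
#'   `control_` and `treated_` (at least two of each; all values
#'   positive).
#' @param alpha P-value cutoff.
#' @param fold Fold-change cutoff (> 1).
#' @param log_scale If `TRUE`, values are treated as log2 intensities and
#'   the fold change is `2^(mean(treated) - mean(control))`.
#' @return Data frame of calls: `gene_id`, `direction`, `magnitude`
#'   (log2 fold change), `p_value`. Genes failing either cutoff are
#'   dropped.
#' @export
classify_replicates <- function(expr, alpha = 0.05, fold = 2.0,
                                log_scale = FALSE) {
  ccols <- grep("^control_", names(expr), value = TRUE)
  tcols <- grep("^treated_", names(expr), value = TRUE)
  if (length(ccols) < 2L || length(tcols) < 2L) {
    stop("need at least 2 control and 2 treated replicates")
  }
  cm <- as.matrix(expr[, ccols, drop = FALSE])
  tm <- as.matrix(expr[, tcols, drop = FALSE])
  if (!log_scale && any(cm <= 0 | tm <= 0)) {
    stop("expression values must be positive on the linear scale")
  }
  fc <- if (log_scale) 2^(rowMeans(tm) - rowMeans(cm)) else
    rowMeans(tm) / rowMeans(cm)
  p <- vapply(seq_len(nrow(expr)),
              function(i) .welch_p(cm[i, ], tm[i, ]), numeric(1L))
  keep <- p < alpha & (fc >= fold | fc <= 1 / fold) & fc != 1
  data.frame(gene_id = expr$gene_id[keep],
             direction = ifelse(fc[keep] > 1, "up", "down"),
             magnitude = log2(fc[keep]),
             p_value = p[keep],
             stringsAsFactors = FALSE)
}
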