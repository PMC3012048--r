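# Ground-truth simulation. The generator emulates exactly the data the
# pipeline consumes — an annotated toy chromosome, standardized ChIP
# peaks for two antibodies, 500 bp peak sequences with hub motifs planted
# at controlled match strength, and an expression time series with chosen
# up/down directions — and records everything it planted so recovery can
# be checked exactly.

#' Simulation configuration
#'
#' Defaults describe the standard study conditions used throughout the
#' test suite: one chromosome carrying 200 non-overlapping genes (30 of
#' them transcription factors), three 12-bp hub PWMs built from 12
#' high-fidelity sites each (informative enough that a stringent scan of
#' background sequence essentially never fires by chance), half the genes bound by both antibodies, motifs planted at
#' PWM score >= 0.97 into the factor peaks of 30% of the eligible target
#' TFs per hub, and a 0/3/6/12 h expression series with a 2-unit
#' late-time effect and 0.25-sd noise.
#'
#' @param seed Master seed; every output is reproducible from it.
#' @param n_genes Number of genes.
#' @param tf_count Number of genes labelled transcription factors.
#' @param gene_spacing Distance between successive gene starts (bp); must
#'   leave the 100 kb assignment windows of neighbours disjoint.
#' @param gene_length_range Min/max transcript length (bp).
#' @param chrom Chromosome name.
#' @param margin Flank kept free at both chromosome ends (bp).
#' @param peak_width Standardized peak width (bp).
#' @param frac_dual,frac_er_only,frac_pol_only Fractions of genes bound
#'   by both antibodies, the factor only, or Pol-II only (the remainder
#'   is unbound).
#' @param er_offsets Offsets (bp, strand-aware, downstream-positive) of
#'   factor-peak midpoints from the TSS, sampled uniformly.
#' @param pol_max_offset Pol-II peak midpoints are placed within this
#'   many bp of the TSS.
#' @param frac_de Fraction of genes given a true expression effect.
#' @param effect_size Planted late-time expression difference (units of
#'   the expression scale).
#' @param noise_sd Per-measurement Gaussian noise sd.
#' @param timepoints Hours of the expression series.
#' @param n_hubs,motif_length,sites_per_hub,site_consensus_prob Hub PWM
#'   generation: number of hubs, motif width, number of sites per hub,
#'   and the per-position probability that a site carries the consensus
#'   base.
#' @param plant_frac Per hub, the fraction of eligible target TFs
#'   (TF, dual-binding, with a true effect) receiving a planted motif.
#' @param plant_spwm Minimum PWM score of planted motif instances.
#' @param background A [background_model()].
#' @return A list of class `"simulation_config"`.
#' @export
simulation_config <- function(seed = 1L, n_genes = 200L, tf_count = 30L,
                              gene_spacing = 350000L,
                              gene_length_range = c(5000L, 20000L),
                              chrom = "chr1", margin = 200000L,
                              peak_width = 500L,
                              frac_dual = 0.5, frac_er_only = 0.2,
                              frac_pol_only = 0.1,
                              er_offsets = c(-50000L, -5000L, -1000L, 0L,
                                             1000L, 5000L, 50000L),
                              pol_max_offset = 2000L,
                              frac_de = 0.6, effect_size = 2.0,
                              noise_sd = 0.25,
                              timepoints = c(0, 3, 6, 12),
                              n_hubs = 3L, motif_length = 12L,
                              sites_per_hub = 12L,
                              site_consensus_prob = 0.95,
                              plant_frac = 0.3, plant_spwm = 0.97,
                              background = background_model()) {
  cfg <- as.list(environment())
  if (cfg$frac_dual + cfg$frac_er_only + cfg$frac_pol_only > 1 + 1e-9) {
    stop("binding fractions must sum to at most 1")
  }
  stopifnot(cfg$n_genes >= 1L, cfg$tf_count <= cfg$n_genes,
            all(diff(cfg$timepoints) > 0))
  need <- max(cfg$gene_length_range) + 2L * max(abs(cfg$er_offsets)) +
    2L * 100000L
  if (cfg$gene_spacing < need) {
    stop("gene_spacing too small: neighbouring 100 kb assignment windows ",
         "would overlap (need >= ", need, " bp)")
  }
  cfg$chrom_length <- 2L * cfg$margin + cfg$n_genes * cfg$gene_spacing
  structure(cfg, class = "simulation_config")
}

#' Plant a motif instance into a sequence
#'
#' Replaces the bases at `offset` (0-based) with a string drawn from the
#' PWM: core columns are forced to their consensus base (so the core
#' score is exactly 1) and the remaining columns are sampled from the
#' frequency matrix, rejection-sampling until the full-window PWM score
#' reaches `min_s_pwm`. With `min_s_pwm = 1` the per-column argmax
#' consensus is planted directly. Draws come from the caller's RNG
#' stream.
#'
#' @param seq DNA string to modify.
#' @param pwm A [build_pwm()] object.
#' @param offset 0-based position of the planted window.
#' @param min_s_pwm Required minimum PWM score of the planted instance.
#' @param max_tries Rejection-sampling budget before falling back to the
#'   consensus.
#' @return The modified sequence.
#' @export
plant_motif <- function(seq, pwm, offset, min_s_pwm = 0.95,
                        max_tries = 1000L) {
  stopifnot(inherits(pwm, "pwm"))
  if (min_s_pwm > 1) stop("min_s_pwm cannot exceed 1")
  n <- pwm$n
  if (offset < 0 || offset + n > nchar(seq)) {
    stop("motif does not fit in the sequence at offset ", offset)
  }
  consensus <- strsplit(pwm_consensus(pwm), "", fixed = TRUE)[[1L]]
  core_cols <- pwm$core[1L]:pwm$core[2L]
  draw <- function() {
    bases <- vapply(seq_len(n), function(j)
      sample(DNA_BASES, 1L, prob = pwm$freq[, j]), character(1L))
    bases[core_cols] <- consensus[core_cols]
    paste(bases, collapse = "")
  }
  inst <- NULL
  if (min_s_pwm >= 1) {
    inst <- paste(consensus, collapse = "")
  } else {
    for (i in seq_len(max_tries)) {
      cand <- draw()
      if (pwm_score(pwm, cand)$s_pwm >= min_s_pwm) { inst <- cand; break }
    }
    if (is.null(inst)) inst <- paste(consensus, collapse = "")
  }
  paste0(substr(seq, 1L, offset), inst,
         substr(seq, offset + n + 1L, nchar(seq)))
}

# random hub PWM: pick a consensus, then sample sites around it
.random_hub_pwm <- function(cfg, name) {
  consensus <- sample(DNA_BASES, cfg$motif_length, replace = TRUE)
  sites <- vapply(seq_len(cfg$sites_per_hub), function(i) {
    paste(vapply(consensus, function(b) {
      if (stats::runif(1) < cfg$site_consensus_prob) b
      else sample(setdiff(DNA_BASES, b), 1L)
    }, character(1L)), collapse = "")
  }, character(1L))
  build_pwm(sites, background = cfg$background, small_sample = TRUE,
            core = "auto", name = name)
}

#' Simulate a complete ChIP + expression study with planted ground truth
#'
#' Generates, reproducibly from `config$seed`: a gene annotation on one
#' toy chromosome; standardized factor and Pol-II peaks placed at
#' controlled strand-aware offsets; i.i.d. background peak sequences
#' with hub-motif instances planted into the factor peaks of the chosen
#' target genes; an expression time series with chosen directions; the
#' TF universe; and a `truth` record listing every planted edge, motif
#' offset, binding class and regulation direction. Every planted edge
#' connects a hub to a gene that is a TF, dual-binding, and truly
#' regulated, so the full pipeline can recover the edge set exactly.
#'
#' @param config A [simulation_config()].
#' @return A list of class `"regulatory_simulation"` with elements
#'   `config`, `genes`, `er_peaks`, `pol_peaks`, `peak_seqs` (named by
#'   peak_id; factor peaks only), `expression`, `tf_universe`,
#'   `hub_pwms`, `truth`.
#' @export
simulate_regulatory_study <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config

  # --- genes (stream 1) ------------------------------------------------
  genes <- .with_seed(cfg$seed + 1L, {
    len <- sample(cfg$gene_length_range[1L]:cfg$gene_length_range[2L],
                  cfg$n_genes, replace = TRUE)
    start <- cfg$margin + (seq_len(cfg$n_genes) - 1L) * cfg$gene_spacing
    strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
    make_gene_table(sprintf("G%03d", seq_len(cfg$n_genes)),
                    cfg$chrom, strand, start, start + len)
  })
  tf_universe <- .with_seed(cfg$seed + 2L,
                            sort(sample(genes$gene_id, cfg$tf_count)))

  # --- hub PWMs (stream 3) ---------------------------------------------
  hub_pwms <- .with_seed(cfg$seed + 3L, {
    hubs <- lapply(seq_len(cfg$n_hubs), function(i)
      .random_hub_pwm(cfg, sprintf("HUB%d", i)))
    stats::setNames(hubs, vapply(hubs, `[[`, character(1L), "name"))
  })

  # --- binding classes and peak placement (stream 4) --------------------
  placement <- .with_seed(cfg$seed + 4L, {
    cls <- sample(c("dual", "er", "pol", "none"), cfg$n_genes,
                  replace = TRUE,
                  prob = c(cfg$frac_dual, cfg$frac_er_only,
                           cfg$frac_pol_only,
                           1 - cfg$frac_dual - cfg$frac_er_only -
                             cfg$frac_pol_only))
    sgn <- ifelse(genes$strand == "+", 1L, -1L)
    er_off <- sample(cfg$er_offsets, cfg$n_genes, replace = TRUE)
    er_mid <- genes$tss + sgn * er_off
    pol_mid <- genes$tss + sgn * sample(seq(-cfg$pol_max_offset,
                                            cfg$pol_max_offset),
                                        cfg$n_genes, replace = TRUE)
    score <- round(stats::runif(2L * cfg$n_genes, 1, 100), 2)
    list(cls = cls, er_off = er_off, er_mid = er_mid, pol_mid = pol_mid,
         score = score)
  })
  has_er <- placement$cls %in% c("dual", "er")
  has_pol <- placement$cls %in% c("dual", "pol")
  half <- cfg$peak_width %/% 2L

  peak_df <- function(mids, ids, scores) {
    data.frame(peak_id = ids, chrom = cfg$chrom,
               start = mids - half, end = mids - half + cfg$peak_width,
               score = scores, summit = mids, stringsAsFactors = FALSE)
  }
  er_genes <- genes$gene_id[has_er]
  er_peaks <- peak_df(placement$er_mid[has_er], paste0("ER_", er_genes),
                      placement$score[seq_len(sum(has_er))])
  pol_genes <- genes$gene_id[has_pol]
  pol_peaks <- peak_df(placement$pol_mid[has_pol], paste0("POL_", pol_genes),
                       placement$score[sum(has_er) + seq_len(sum(has_pol))])

  # --- expression (stream 5) -------------------------------------------
  expression <- .with_seed(cfg$seed + 5L, {
    de <- sample(c(TRUE, FALSE), cfg$n_genes, replace = TRUE,
                 prob = c(cfg$frac_de, 1 - cfg$frac_de))
    dir <- ifelse(de & sample(c(TRUE, FALSE), cfg$n_genes, replace = TRUE),
                  "up", ifelse(de, "down", "none"))
    tp <- cfg$timepoints
    ramp <- (tp - tp[1L]) / (tp[length(tp)] - tp[1L])
    vals <- vapply(seq_len(cfg$n_genes), function(i) {
      eff <- switch(dir[i], up = cfg$effect_size,
                    down = -cfg$effect_size, 0)
      8 + eff * ramp + stats::rnorm(length(tp), 0, cfg$noise_sd)
    }, numeric(length(tp)))
    df <- data.frame(gene_id = genes$gene_id, t(vals),
                     check.names = FALSE, stringsAsFactors = FALSE)
    names(df) <- c("gene_id", as.character(tp))
    attr(df, "true_direction") <- dir
    df
  })
  true_dir <- attr(expression, "true_direction")
  attr(expression, "true_direction") <- NULL

  # --- peak sequences and planting (streams 6, 7) -----------------------
  peak_seqs <- .with_seed(cfg$seed + 6L, {
    s <- vapply(seq_len(nrow(er_peaks)), function(i)
      .random_dna(cfg$peak_width, cfg$background), character(1L))
    stats::setNames(s, er_peaks$peak_id)
  })

  eligible <- genes$gene_id[placement$cls == "dual" & true_dir != "none" &
                              genes$gene_id %in% tf_universe]
  planted <- .with_seed(cfg$seed + 7L, {
    rows <- list()
    occupied <- list()   # per peak: starts of already-planted instances
    for (h in names(hub_pwms)) {
      n_pick <- if (cfg$plant_frac <= 0) 0L else
        min(max(1L, round(cfg$plant_frac * length(eligible))),
            length(eligible))
      if (n_pick == 0L) next
      tg <- sort(sample(eligible, n_pick))
      for (g in tg) {
        pid <- paste0("ER_", g)
        n_h <- hub_pwms[[h]]$n
        # keep instances planted in the same peak from overwriting each
        # other: sample among offsets clear of every earlier instance
        taken <- unlist(lapply(occupied[[pid]], function(prev)
          (prev$start - n_h + 1L):(prev$start + prev$n - 1L)))
        allowed <- setdiff(0:(cfg$peak_width - n_h), taken)
        if (length(allowed) == 0L) {
          stop("peak ", pid, " cannot host another planted motif")
        }
        off <- if (length(allowed) == 1L) allowed else sample(allowed, 1L)
        occupied[[pid]] <- c(occupied[[pid]],
                             list(list(start = off, n = n_h)))
        peak_seqs[[pid]] <- plant_motif(peak_seqs[[pid]], hub_pwms[[h]],
                                        off, min_s_pwm = cfg$plant_spwm)
        rows[[length(rows) + 1L]] <- data.frame(
          hub = h, gene_id = g, peak_id = pid, offset = off,
          stringsAsFactors = FALSE)
      }
    }
    if (length(rows)) do.call(rbind, rows) else
      data.frame(hub = character(), gene_id = character(),
                 peak_id = character(), offset = integer(),
                 stringsAsFactors = FALSE)
  })

  truth <- list(
    edges = planted,
    binding = data.frame(gene_id = genes$gene_id, class = placement$cls,
                         er_offset = ifelse(has_er, placement$er_off, NA),
                         stringsAsFactors = FALSE),
    direction = data.frame(gene_id = genes$gene_id, direction = true_dir,
                           stringsAsFactors = FALSE),
    eligible_targets = eligible)

  structure(list(config = cfg, genes = genes, er_peaks = er_peaks,
                 pol_peaks = pol_peaks, peak_seqs = peak_seqs,
                 expression = expression, tf_universe = tf_universe,
                 hub_pwms = hub_pwms, truth = truth),
            class = "regulatory_simulation")
}

#' @export
print.regulatory_simulation <- function(x, ...) {
  cat(sprintf(
    "simulated study: %d genes (%d TFs), %d factor peaks, %d Pol-II peaks\n",
    nrow(x$genes), length(x$tf_universe), nrow(x$er_peaks),
    nrow(x$pol_peaks)))
  cat(sprintf("  %d hub PWMs, %d planted edges (seed %d)\n",
              length(x$hub_pwms), nrow(x$truth$edges), x$config$seed))
  invisible(x)
}

#' Write a simulated study to disk in the pipeline's input formats
#'
#' Writes `genes.tsv`, `er_peaks.bed`, `pol_peaks.bed`,
#' `er_peak_seqs.fa`, `expression.tsv`, `tf_universe.txt` and
#' `ground_truth.json` under `dir`, exactly the dialects read by the
#' `read_*` functions.
#'
#' @param sim A [simulate_regulatory_study()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "regulatory_simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_gene_table(sim$genes, file.path(dir, "genes.tsv"))
  write_peaks(sim$er_peaks, file.path(dir, "er_peaks.bed"))
  write_peaks(sim$pol_peaks, file.path(dir, "pol_peaks.bed"))
  write_fasta_sequences(sim$peak_seqs, file.path(dir, "er_peak_seqs.fa"))
  write_expression(sim$expression, file.path(dir, "expression.tsv"))
  writeLines(sim$tf_universe, file.path(dir, "tf_universe.txt"))
  jsonlite::write_json(sim$truth, file.path(dir, "ground_truth.json"),
                       dataframe = "columns", pretty = TRUE)
  invisible(dir)
}
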