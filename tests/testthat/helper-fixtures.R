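# Small deterministic fixtures shared across test files.

# 10-column toy PWM with an unambiguous consensus and a strong core
toy_pwm <- function(name = "toy") {
  build_pwm(c("ACGTACGTAC", "ACGTACGTAC", "ACGTACGTAT", "ACGAACGTAC"),
            small_sample = TRUE, core = "auto", name = name)
}

# hand-assembled network object for exercising the writers
fixture_network <- function(edges = NULL, nodes = NULL) {
  if (is.null(edges)) {
    edges <- data.frame(hub = c("FOXA1", "RORA"),
                        target = c("MYC", "GATA3"),
                        n_peaks = c(1L, 2L), n_hit_peaks = c(1L, 1L),
                        n_hits = c(1L, 3L), best_ratio = c(0.01, 0.1),
                        retained = c(TRUE, TRUE),
                        stringsAsFactors = FALSE)
  }
  if (is.null(nodes)) {
    nodes <- data.frame(gene_id = c("FOXA1", "GATA3", "MYC", "RORA"),
                        role = c("hub", "target", "target", "hub"),
                        direction = c("none", "down", "up", "none"),
                        stringsAsFactors = FALSE)
  }
  structure(list(nodes = nodes, edges = edges, candidates = edges,
                 provenance = list(seed = 1L, hubs = c("FOXA1", "RORA"),
                                   pwm_threshold = 0.95,
                                   core_threshold = 1,
                                   n_shuffles = 10L, ratio_cutoff = 0.2)),
            class = "regulatory_network")
}

# ten 20-kb genes, alternating strand, 1 Mb apart: far enough that the
# scripted peak offsets (up to 150 kb) never interact across genes
fixture_genes_10 <- function() {
  start <- (1:10) * 1000000L
  make_gene_table(sprintf("T%02d", 1:10), "chr1",
                  rep(c("+", "-"), 5L), start, start + 20000L)
}

# place a 500 bp peak whose midpoint sits at a strand-aware offset from
# the TSS (anchor = "tss") or TTS (anchor = "tts") of one gene
peak_at_offset <- function(gene, offset, anchor = c("tss", "tts"),
                           peak_id = "p") {
  anchor <- match.arg(anchor)
  sgn <- if (gene$strand == "+") 1L else -1L
  mid <- (if (anchor == "tss") gene$tss else gene$tts) + sgn * offset
  data.frame(peak_id = peak_id, chrom = gene$chrom, start = mid - 250L,
             end = mid + 250L, score = 1, summit = mid,
             stringsAsFactors = FALSE)
}

# the scripted localization truth table: offsets from TSS and TTS with
# their hand-derived categories for a 20-kb gene (tx length 20000,
# strand-aware), plus whether the 100 kb / 10 kb windows admit the peak
localization_truth <- function() {
  rbind(
    data.frame(anchor = "tss",
               offset = c(0L, -1000L, 1000L, -5000L, 5000L, -50000L,
                          50000L, -150000L, 150000L),
               category = c("FiveTSS", "FivePrimeCore", "WithinGeneCore",
                            "FivePrimeProximal", "IntraGenic",
                            "FivePrimeDistal", "ThreePrimeDistal",
                            "GeneDesert", "GeneDesert"),
               in_100kb = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
                            FALSE, FALSE),
               in_10kb = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE,
                           FALSE, FALSE),
               stringsAsFactors = FALSE),
    data.frame(anchor = "tts",
               offset = c(0L, 1000L, -1000L, 5000L, -5000L, 50000L,
                          150000L),
               category = c("ThreePrimeCore", "ThreePrimeCore",
                            "IntraGenic", "ThreePrimeProximal",
                            "IntraGenic", "ThreePrimeDistal",
                            "GeneDesert"),
               in_100kb = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
               in_10kb = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
               stringsAsFactors = FALSE))
}

# small simulated study used where full-size runs would be wasteful
small_sim <- function(seed = 3L, ...) {
  simulate_regulatory_study(simulation_config(seed = seed, n_genes = 40L,
                                              tf_count = 12L, ...))
}

edge_key <- function(df, hub = "hub", target = if ("target" %in% names(df))
  "target" else "gene_id") {
  if (nrow(df) == 0L) return(character())
  sort(paste(df[[hub]], df[[target]], sep = "->"))
}
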