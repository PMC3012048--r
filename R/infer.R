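#' Infer the hub-TF regulatory network from study components
#'
#' The top-level pipeline: assigns factor peaks to genes with the wide
#' window (100 kb default) and Pol-II peaks with the narrow window
#' (10 kb default), intersects to the dual-binding gene set, derives
#' up/down regulation calls from the expression table, and hands
#' everything to [build_network()]. Works identically on real inputs
#' (read with the `read_*` functions) and on
#' [simulate_regulatory_study()] components.
#'
#' @param er_peaks,pol_peaks Standardized peak data frames for the
#'   ChIP'd factor and Pol-II.
#' @param genes Gene annotation data frame.
#' @param peak_seqs Named character vector: factor peak_id -> sequence.
#' @param expression Expression table; its layout selects the call mode
#'   (time columns vs `control_`/`treated_` columns).
#' @param tf_universe Character vector of transcription-factor gene ids.
#' @param hub_pwms Named list of [build_pwm()] objects.
#' @param er_window,pol_window Assignment windows in bp (applied both
#'   upstream and downstream).
#' @param ... Passed to [build_network()] (thresholds, `n_shuffles`,
#'   `ratio_cutoff`, `strands`, `edge_support`).
#' @param seed Master seed for the permutation streams.
#' @return A `"regulatory_network"` object (see [build_network()]).
#' @examples
#' \donttest{
#' sim <- simulate_regulatory_study(simulation_config(seed = 7,
#'   n_genes = 40, tf_count = 10))
#' net <- infer_network(sim$er_peaks, sim$pol_peaks, sim$genes,
#'                      sim$peak_seqs, sim$expression, sim$tf_universe,
#'                      sim$hub_pwms, n_shuffles = 100, seed = 7)
#' print(net)
#' }
#' @export
infer_network <- function(er_peaks, pol_peaks, genes, peak_seqs,
                          expression, tf_universe, hub_pwms,
                          er_window = 100000L, pol_window = 10000L,
                          ..., seed = 1L) {
  er_map <- assign_peaks_to_genes(er_peaks, genes,
                                  upstream = er_window,
                                  downstream = er_window)
  pol_map <- assign_peaks_to_genes(pol_peaks, genes,
                                   upstream = pol_window,
                                   downstream = pol_window)
  dual <- genes_with_dual_binding(er_map, pol_map)
  calls <- if (any(grepl("^control_", names(expression))))
    classify_replicates(expression) else classify_timeseries(expression)
  build_network(hub_pwms, er_map, dual, peak_seqs, calls, tf_universe,
                seed = seed, ...)
}
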