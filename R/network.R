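# Hub-TF -> target-TF network construction. An edge hub -> gene means the
# hub's motif is found (at the stringent core/PWM thresholds) in at least
# one ChIP peak assigned to the gene, and the sequence-shuffling
# permutation test rates that occurrence as sequence-specific.

# restore the caller's RNG state after seeded internal draws
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# deterministic per-(hub, peak) substream seed below 2^31
.substream_seed <- function(seed, hub_index, peak_index) {
  ((seed %% 1000003) * 1009 + hub_index * 97003 + peak_index * 101) %%
    2147483647
}

#' Sequence-shuffling permutation ratio for a motif occurrence
#'
#' Shuffles the sequence `n_shuffles` times (each shuffle a uniform
#' random permutation of its characters, so base composition is
#' preserved), rescans every shuffle with the same thresholds, and
#' returns the fraction of shuffles in which at least one hit survives.
#' A low ratio means the observed hit depends on the arrangement of the
#' sequence rather than its composition; the original analysis retains
#' edges with ratio at or below 0.2 over 1000 shuffles.
#'
#' @param pwm A [build_pwm()] object.
#' @param seq DNA string (typically a 500 bp peak sequence).
#' @param n_shuffles Number of shuffles.
#' @param pwm_threshold,core_threshold Inclusive hit thresholds (see
#'   [scan_sequence()]).
#' @param strands `"both"` or `"forward"`.
#' @param seed Integer seed for the shuffle stream; the caller's RNG
#'   state is left untouched.
#' @param chunk Shuffles scored per vectorized block (memory knob).
#' @return The ratio in `[0, 1]`, with attribute `"hits_per_shuffle"`
#'   giving the per-shuffle hit counts (a diagnostic; the ratio counts
#'   shuffles with at least one hit).
#' @export
permutation_ratio <- function(pwm, seq, n_shuffles = 1000L,
                              pwm_threshold = 0.95, core_threshold = 1.0,
                              strands = c("both", "forward"),
                              seed = 1L, chunk = 250L) {
  stopifnot(inherits(pwm, "pwm"), n_shuffles >= 1L)
  strands <- match.arg(strands)
  codes <- .encode_dna(seq)
  L <- length(codes)
  n_shuffles <- as.integer(n_shuffles)
  if (L < pwm$n) {
    out <- 0
    attr(out, "hits_per_shuffle") <- integer(n_shuffles)
    return(out)
  }
  ex <- .col_extremes(pwm$weights, seq_len(pwm$n))

  hits <- .with_seed(seed, {
    done <- 0L
    acc <- integer(0L)
    while (done < n_shuffles) {
      S <- min(chunk, n_shuffles - done)
      idx <- vapply(seq_len(S), function(i) sample.int(L), integer(L))
      M <- matrix(codes[idx], nrow = S, ncol = L, byrow = TRUE)
      acc <- c(acc, .count_window_hits(pwm, M, pwm_threshold,
                                       core_threshold, strands))
      done <- done + S
    }
    acc
  })
  out <- mean(hits > 0L)
  attr(out, "hits_per_shuffle") <- hits
  out
}

# per-row hit counts over a matrix of encoded sequences
.count_window_hits <- function(pwm, M, pwm_threshold, core_threshold,
                               strands) {
  count_one <- function(mat) {
    sc <- .window_scores(pwm, mat)
    if (is.null(sc)) return(integer(nrow(mat)))
    hit <- !is.na(sc$s_seq) & !is.na(sc$s_core) &
      sc$s_pwm >= pwm_threshold & sc$s_core >= core_threshold
    as.integer(rowSums(hit))
  }
  n <- count_one(M)
  if (strands == "both") {
    Mrc <- (5L - M)[, rev(seq_len(ncol(M))), drop = FALSE]
    n <- n + count_one(Mrc)
  }
  n
}

#' Build the hub-TF regulatory network
#'
#' Candidate targets are the genes that (a) belong to the transcription
#' factor universe, (b) are bound by both antibodies (`dual_genes`), and
#' (c) carry an up/down regulation call. For each (hub, target) pair
#' every ChIP peak assigned to the target is scanned with the hub's PWM
#' at the stringent thresholds; a candidate edge exists when at least one
#' peak has a hit, and the edge is retained when at least one hit-bearing
#' peak has [permutation_ratio()] at or below `ratio_cutoff`
#' (`edge_support = "all"` instead requires every hit-bearing peak to
#' pass). Edges are directed hub -> target; self-edges are allowed. The
#' result is deterministic given `seed`: each (hub, peak) pair draws its
#' shuffles from its own derived substream.
#'
#' @param hub_pwms Named list of [build_pwm()] objects (names are the hub
#'   node ids).
#' @param er_map [assign_peaks_to_genes()] result for the ChIP'd factor
#'   (100 kb windows).
#' @param dual_genes Character vector from [genes_with_dual_binding()].
#' @param peak_seqs Named character vector mapping peak_id to its DNA
#'   sequence.
#' @param calls Regulation calls ([classify_timeseries()] or
#'   [classify_replicates()]).
#' @param tf_universe Character vector of transcription-factor gene ids.
#' @param pwm_threshold,core_threshold Hit thresholds.
#' @param n_shuffles Shuffles per permutation test.
#' @param ratio_cutoff Inclusive permutation-ratio cutoff for retaining
#'   an edge.
#' @param strands Strand handling for scanning.
#' @param edge_support `"any"` (default) or `"all"` peak aggregation.
#' @param seed Master seed.
#' @return An object of class `"regulatory_network"`: list with `nodes`
#'   (`gene_id`, `role`, `direction`), `edges` (retained), `candidates`
#'   (all scanned candidate edges with their ratios) and `provenance`.
#' @export
build_network <- function(hub_pwms, er_map, dual_genes, peak_seqs, calls,
                          tf_universe, pwm_threshold = 0.95,
                          core_threshold = 1.0, n_shuffles = 1000L,
                          ratio_cutoff = 0.2,
                          strands = c("both", "forward"),
                          edge_support = c("any", "all"), seed = 1L) {
  stopifnot(inherits(er_map, "gene_peak_map"))
  strands <- match.arg(strands)
  edge_support <- match.arg(edge_support)
  if (is.null(names(hub_pwms)) || any(!nzchar(names(hub_pwms)))) {
    stop("hub_pwms must be a named list")
  }
  direction <- setNames(calls$direction, calls$gene_id)
  targets <- sort(Reduce(intersect, list(names(er_map$assignments),
                                         as.character(dual_genes),
                                         as.character(tf_universe),
                                         calls$gene_id)))
  hubs <- sort(names(hub_pwms))
  all_peaks <- sort(unique(unlist(er_map$assignments[targets],
                                  use.names = FALSE)))
  missing_seq <- all_peaks[!all_peaks %in% names(peak_seqs)]
  if (length(missing_seq)) {
    bad_gene <- targets[vapply(targets, function(g)
      any(er_map$assignments[[g]] %in% missing_seq), logical(1L))][1L]
    stop("no sequence available for peak(s) of gene ", bad_gene)
  }

  cand <- list()
  for (h in hubs) {
    pwm <- hub_pwms[[h]]
    h_i <- match(h, hubs)
    for (g in targets) {
      pids <- er_map$assignments[[g]]
      peak_rows <- lapply(pids, function(pid) {
        hits <- scan_sequence(pwm, peak_seqs[[pid]],
                              core_threshold = core_threshold,
                              pwm_threshold = pwm_threshold,
                              strands = strands, sequence_id = pid)
        if (nrow(hits) == 0L) return(NULL)
        sub_seed <- .substream_seed(seed, h_i, match(pid, all_peaks))
        ratio <- permutation_ratio(pwm, peak_seqs[[pid]],
                                   n_shuffles = n_shuffles,
                                   pwm_threshold = pwm_threshold,
                                   core_threshold = core_threshold,
                                   strands = strands, seed = sub_seed)
        data.frame(peak_id = pid, n_hits = nrow(hits),
                   ratio = as.numeric(ratio), stringsAsFactors = FALSE)
      })
      peak_rows <- do.call(rbind, peak_rows)
      if (is.null(peak_rows) || nrow(peak_rows) == 0L) next
      retained <- if (edge_support == "any")
        any(peak_rows$ratio <= ratio_cutoff) else
          all(peak_rows$ratio <= ratio_cutoff)
      cand[[length(cand) + 1L]] <- data.frame(
        hub = h, target = g, n_peaks = length(pids),
        n_hit_peaks = nrow(peak_rows),
        n_hits = sum(peak_rows$n_hits),
        best_ratio = min(peak_rows$ratio),
        retained = retained, stringsAsFactors = FALSE)
    }
  }
  candidates <- if (length(cand)) do.call(rbind, cand) else
    data.frame(hub = character(), target = character(),
               n_peaks = integer(), n_hit_peaks = integer(),
               n_hits = integer(), best_ratio = numeric(),
               retained = logical(), stringsAsFactors = FALSE)
  edges <- candidates[candidates$retained, , drop = FALSE]
  rownames(edges) <- rownames(candidates) <- NULL

  node_ids <- sort(unique(c(hubs, edges$target)))
  role <- ifelse(node_ids %in% hubs & node_ids %in% edges$target, "both",
                 ifelse(node_ids %in% hubs, "hub", "target"))
  dir <- ifelse(node_ids %in% names(direction),
                unname(direction[node_ids]), "none")
  nodes <- data.frame(gene_id = node_ids, role = role, direction = dir,
                      stringsAsFactors = FALSE)

  structure(list(
    nodes = nodes, edges = edges, candidates = candidates,
    provenance = list(seed = as.integer(seed),
                      pwm_threshold = pwm_threshold,
                      core_threshold = core_threshold,
                      n_shuffles = as.integer(n_shuffles),
                      ratio_cutoff = ratio_cutoff, strands = strands,
                      edge_support = edge_support,
                      hubs = hubs, n_targets_considered = length(targets))),
    class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat(sprintf(
    "regulatory network: %d nodes, %d retained edges (%d candidates)\n",
    nrow(x$nodes), nrow(x$edges), nrow(x$candidates)))
  cat(sprintf("  hubs: %s\n", paste(x$provenance$hubs, collapse = ", ")))
  cat(sprintf(
    "  thresholds: core >= %g, PWM >= %g; ratio cutoff <= %g (%d shuffles)\n",
    x$provenance$core_threshold, x$provenance$pwm_threshold,
    x$provenance$ratio_cutoff, x$provenance$n_shuffles))
  invisible(x)
}

#' @method summary regulatory_network
#' @export
summary.regulatory_network <- function(object, ...) {
  nd <- object$nodes
  tg <- nd[nd$role %in% c("target", "both"), , drop = FALSE]
  out <- list(n_nodes = nrow(nd), n_edges = nrow(object$edges),
              n_candidates = nrow(object$candidates),
              n_hubs = sum(nd$role %in% c("hub", "both")),
              n_targets = nrow(tg),
              n_up = sum(tg$direction == "up"),
              n_down = sum(tg$direction == "down"),
              ratio_range = if (nrow(object$edges))
                range(object$edges$best_ratio) else c(NA_real_, NA_real_))
  class(out) <- "summary.regulatory_network"
  out
}

#' @export
print.summary.regulatory_network <- function(x, ...) {
  cat(sprintf("nodes: %d (%d hubs, %d targets: %d up, %d down)\n",
              x$n_nodes, x$n_hubs, x$n_targets, x$n_up, x$n_down))
  cat(sprintf("edges: %d retained of %d candidates\n",
              x$n_edges, x$n_candidates))
  if (!is.na(x$ratio_range[1L])) {
    cat(sprintf("permutation ratios of retained edges: %.3f - %.3f\n",
                x$ratio_range[1L], x$ratio_range[2L]))
  }
  invisible(x)
}

#' Convert a regulatory network to an igraph graph
#'
#' @param network A [build_network()] result.
#' @return A directed [igraph::graph] with node attributes `role` and
#'   `direction` and edge attributes `permutation_ratio`, `n_hits`.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "regulatory_network"))
  e <- network$edges[order(network$edges$hub, network$edges$target), ,
                     drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = e$hub, to = e$target,
               permutation_ratio = e$best_ratio, n_hits = e$n_hits,
               stringsAsFactors = FALSE),
    directed = TRUE, vertices = network$nodes)
  g
}

#' Plot a regulatory network
#'
#' Hubs are drawn blue, up-regulated targets red, down-regulated targets
#' green — the coloring convention of the original network figures.
#'
#' @param x A [build_network()] result.
#' @param ... Passed to [igraph::plot.igraph()].
#' @method plot regulatory_network
#' @export
plot.regulatory_network <- function(x, ...) {
  g <- as_igraph(x)
  role <- igraph::V(g)$role
  dir <- igraph::V(g)$direction
  col <- ifelse(role %in% c("hub", "both"), "steelblue",
                ifelse(dir == "up", "firebrick", "forestgreen"))
  igraph::plot.igraph(g, vertex.color = col, edge.arrow.size = 0.4, ...)
  invisible(x)
}

#' One-sided Fisher exact test for the overlap of two gene sets
#'
#' Tests enrichment of the overlap `k = |A` \eqn{\cap} `B|` against a
#' genome universe of `universe_size` genes (30,000 in the original
#' analysis), using the 2x2 table
#' `[[k, |A|-k], [|B|-k, N-|A|-|B|+k]]` and the one-sided
#' (greater) alternative.
#'
#' @param set_a,set_b Character vectors (duplicates ignored).
#' @param universe_size Genome gene count `N`.
#' @return List with `overlap` and `p_value`.
#' @export
overlap_fisher <- function(set_a, set_b, universe_size = 30000L) {
  a <- unique(as.character(set_a))
  b <- unique(as.character(set_b))
  if (length(a) > universe_size || length(b) > universe_size) {
    stop("set sizes cannot exceed the universe size")
  }
  k <- length(intersect(a, b))
  tab <- matrix(c(k, length(a) - k, length(b) - k,
                  universe_size - length(a) - length(b) + k), nrow = 2L)
  if (any(tab < 0)) stop("inconsistent 2x2 table (negative cell)")
  p <- stats::fisher.test(tab, alternative = "greater")$p.value
  list(overlap = k, p_value = p)
}

#' Compare two regulatory networks
#'
#' Reports the hub and target overlap between two networks, the common
#' target percentage (denominator: the smaller target set, matching the
#' "about 25% common targets" style of cross-platform comparisons), and
#' the Jaccard index of the directed edge sets.
#'
#' @param net_a,net_b [build_network()] results.
#' @return List with `common_hubs`, `common_targets`,
#'   `pct_common_targets`, `edge_jaccard`, and the per-network hub and
#'   target counts.
#' @export
compare_networks <- function(net_a, net_b) {
  stopifnot(inherits(net_a, "regulatory_network"),
            inherits(net_b, "regulatory_network"))
  hubs <- function(n) n$nodes$gene_id[n$nodes$role %in% c("hub", "both")]
  tgts <- function(n) n$nodes$gene_id[n$nodes$role %in% c("target", "both")]
  edges <- function(n) if (nrow(n$edges))
    paste(n$edges$hub, n$edges$target, sep = "->") else character()
  ta <- tgts(net_a); tb <- tgts(net_b)
  common_t <- intersect(ta, tb)
  ea <- edges(net_a); eb <- edges(net_b)
  uni <- union(ea, eb)
  list(common_hubs = sort(intersect(hubs(net_a), hubs(net_b))),
       common_targets = sort(common_t),
       n_targets_a = length(ta), n_targets_b = length(tb),
       pct_common_targets = if (min(length(ta), length(tb)) == 0) NA_real_
       else 100 * length(common_t) / min(length(ta), length(tb)),
       edge_jaccard = if (length(uni) == 0) 1 else
         length(intersect(ea, eb)) / length(uni))
}
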