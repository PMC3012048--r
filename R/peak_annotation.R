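# Peak localization relative to genes. Every peak is anchored at its
# midpoint, which makes the region taxonomy a true partition: each
# (peak, nearest gene) pair lands in exactly one category.

#' Region taxonomy boundaries
#'
#' Boundaries (bp) for the strand-aware region taxonomy around a gene.
#' With the defaults, and writing `x` for the signed midpoint-to-TSS
#' distance (positive downstream) and `y` for the signed
#' midpoint-to-TTS distance (positive past the 3' end):
#'
#' * `FiveTSS`: |x| <= `tss_flank` (200 bp)
#' * `FivePrimeCore`: `-promoter_up` <= x < `-tss_flank`
#' * `FivePrimeProximal`: `-proximal_limit` <= x < `-promoter_up`
#' * `FivePrimeDistal`: `-distal_limit` <= x < `-proximal_limit`
#' * `WithinGeneCore`: inside the gene, `tss_flank` < x <= `promoter_down`
#' * `IntraGenic`: inside the gene beyond `promoter_down` of the TSS
#' * `ThreePrimeCore`: `-tss_flank` <= y <= `promoter_up` (mirrored core)
#' * `ThreePrimeProximal`: `promoter_up` < y <= `proximal_limit`
#' * `ThreePrimeDistal`: `proximal_limit` < y <= `distal_limit`
#' * `GeneDesert`: more than `distal_limit` from every TSS and TTS
#'
#' The promoter region of the original analysis (2 kb either side of the
#' TSS) is the union of `FivePrimeCore`, `FiveTSS` and `WithinGeneCore`.
#'
#' @param promoter_up,promoter_down Promoter extent upstream/downstream of
#'   the TSS (bp).
#' @param tss_flank Half-width of the `FiveTSS` / `ThreePrimeCore` anchor
#'   bands (bp).
#' @param proximal_limit,distal_limit Outer bounds of the proximal and
#'   distal bands (bp); beyond `distal_limit` from every gene end lies
#'   gene desert.
#' @return A list of class `"region_schema"`.
#' @export
region_schema <- function(promoter_up = 2000L, promoter_down = 2000L,
                          tss_flank = 200L, proximal_limit = 10000L,
                          distal_limit = 100000L) {
  s <- list(promoter_up = as.integer(promoter_up),
            promoter_down = as.integer(promoter_down),
            tss_flank = as.integer(tss_flank),
            proximal_limit = as.integer(proximal_limit),
            distal_limit = as.integer(distal_limit))
  if (s$tss_flank <= 0L || s$promoter_up <= s$tss_flank ||
      s$promoter_down <= s$tss_flank ||
      s$proximal_limit < max(s$promoter_up, s$promoter_down) ||
      s$distal_limit < s$proximal_limit) {
    stop("region schema must satisfy 0 < tss_flank < promoter bounds <= ",
         "proximal_limit <= distal_limit")
  }
  structure(s, class = "region_schema")
}

REGION_CATEGORIES <- c("FivePrimeDistal", "FivePrimeProximal",
                       "FivePrimeCore", "FiveTSS", "WithinGeneCore",
                       "IntraGenic", "ThreePrimeCore", "ThreePrimeProximal",
                       "ThreePrimeDistal", "GeneDesert")

# signed distances of genomic position `pos` to one gene, in strand-aware
# gene coordinates: x from the TSS (positive downstream into the gene),
# y from the TTS (positive past the 3' end)
.gene_coords <- function(pos, gene) {
  sgn <- if (gene$strand == "+") 1L else -1L
  list(x = sgn * (pos - gene$tss), y = sgn * (pos - gene$tts))
}

.categorize_one <- function(mid, chrom, genes, schema) {
  same <- genes[genes$chrom == chrom, , drop = FALSE]
  if (nrow(same) == 0L) {
    return(list(category = "GeneDesert", gene_id = NA_character_,
                distance = Inf))
  }
  d <- pmin(abs(mid - same$tss), abs(mid - same$tts))
  ord <- order(d, same$gene_id)
  g <- same[ord[1L], , drop = FALSE]
  dist <- d[ord[1L]]
  if (dist > schema$distal_limit) {
    return(list(category = "GeneDesert", gene_id = NA_character_,
                distance = dist))
  }
  co <- .gene_coords(mid, g)
  x <- co$x; y <- co$y
  t <- schema$tss_flank
  cat <- if (abs(x) <= t) {
    "FiveTSS"
  } else if (x < -t) {
    if (x >= -schema$promoter_up) "FivePrimeCore"
    else if (x >= -schema$proximal_limit) "FivePrimeProximal"
    else "FivePrimeDistal"            # dist <= distal_limit already holds
  } else if (y >= -t) {
    if (y <= schema$promoter_up) "ThreePrimeCore"
    else if (y <= schema$proximal_limit) "ThreePrimeProximal"
    else "ThreePrimeDistal"
  } else {                            # strictly inside the gene body
    if (x <= schema$promoter_down) "WithinGeneCore" else "IntraGenic"
  }
  list(category = cat, gene_id = g$gene_id, distance = dist)
}

#' Categorize peaks relative to the nearest gene
#'
#' Each peak's midpoint is placed in exactly one region category of its
#' nearest gene (nearest by minimum distance to any TSS or TTS on the
#' same chromosome; ties by smaller distance, then lexicographic
#' gene_id). Midpoints farther than `distal_limit` from every gene end
#' are `GeneDesert`.
#'
#' @param peaks Peak data frame.
#' @param genes Gene data frame ([read_gene_table()]).
#' @param schema A [region_schema()].
#' @return Data frame with `peak_id`, `category` (factor over all ten
#'   categories), `gene_id` (`NA` for gene desert), `distance`.
#' @export
categorize_peaks <- function(peaks, genes, schema = region_schema()) {
  stopifnot(inherits(schema, "region_schema"))
  if (is.null(genes) || nrow(genes) == 0L) stop("gene table is empty")
  mids <- (peaks$start + peaks$end) %/% 2L
  res <- lapply(seq_len(nrow(peaks)), function(i) {
    .categorize_one(mids[i], peaks$chrom[i], genes, schema)
  })
  data.frame(peak_id = if (is.null(peaks$peak_id))
    sprintf("peak%05d", seq_len(nrow(peaks))) else peaks$peak_id,
    category = factor(vapply(res, `[[`, character(1L), "category"),
                      levels = REGION_CATEGORIES),
    gene_id = vapply(res, `[[`, character(1L), "gene_id"),
    distance = vapply(res, `[[`, numeric(1L), "distance"),
    stringsAsFactors = FALSE)
}

#' Region category counts and fractions
#'
#' @inheritParams categorize_peaks
#' @return Data frame with one row per category: `category`, `count`,
#'   `fraction` (fractions sum to 1 over all peaks).
#' @export
region_distribution <- function(peaks, genes, schema = region_schema()) {
  cats <- categorize_peaks(peaks, genes, schema)$category
  counts <- table(cats)
  data.frame(category = factor(names(counts), levels = REGION_CATEGORIES),
             count = as.integer(counts),
             fraction = as.numeric(counts) / length(cats),
             stringsAsFactors = FALSE)
}

#' Assign peaks to genes with an asymmetric window rule
#'
#' A peak is assigned to a gene iff the peak midpoint lies within
#' `upstream` bp 5' of the TSS through `downstream` bp 3' of the TTS, in
#' strand-aware gene coordinates (both ends inclusive). One peak may be
#' assigned to several genes. The original windows are 100 kb both sides
#' for the ChIP'd factor and 10 kb both sides for Pol-II.
#'
#' @param peaks Peak data frame.
#' @param genes Gene data frame.
#' @param upstream,downstream Window extents in bp (positive).
#' @return An object of class `"gene_peak_map"`: list with `assignments`
#'   (named list gene_id -> character vector of peak_ids; only genes with
#'   at least one peak), `peaks`, `upstream`, `downstream`.
#' @export
assign_peaks_to_genes <- function(peaks, genes, upstream = 100000L,
                                  downstream = 100000L) {
  if (upstream <= 0 || downstream <= 0) stop("windows must be positive")
  if (is.null(peaks$peak_id)) {
    peaks$peak_id <- sprintf("peak%05d", seq_len(nrow(peaks)))
  }
  mids <- (peaks$start + peaks$end) %/% 2L
  assignments <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    lo <- if (g$strand == "+") g$tx_start - upstream else
      g$tx_start - downstream
    hi <- if (g$strand == "+") (g$tx_end - 1L) + downstream else
      (g$tx_end - 1L) + upstream
    hit <- peaks$chrom == g$chrom & mids >= lo & mids <= hi
    if (any(hit)) assignments[[g$gene_id]] <- peaks$peak_id[hit]
  }
  structure(list(assignments = assignments, peaks = peaks,
                 upstream = as.integer(upstream),
                 downstream = as.integer(downstream)),
            class = "gene_peak_map")
}

#' @export
print.gene_peak_map <- function(x, ...) {
  cat(sprintf(
    "gene-peak map: %d genes with >=1 peak (window %d bp up / %d bp down)\n",
    length(x$assignments), x$upstream, x$downstream))
  invisible(x)
}

#' Genes bound by both antibodies
#'
#' Intersects the gene sets of two gene-peak maps — typically the
#' ChIP'd-factor map built with the 100 kb window and the Pol-II map
#' built with the 10 kb window. The two peaks need not overlap; they must
#' only land in the same gene's window.
#'
#' @param er_map,polII_map [assign_peaks_to_genes()] results.
#' @return Sorted character vector of gene ids present in both maps.
#' @export
genes_with_dual_binding <- function(er_map, polII_map) {
  stopifnot(inherits(er_map, "gene_peak_map"),
            inherits(polII_map, "gene_peak_map"))
  sort(intersect(names(er_map$assignments), names(polII_map$assignments)))
}
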