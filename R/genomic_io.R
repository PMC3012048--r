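# File formats. All coordinates are 0-based, half-open (BED convention)
# both on disk and in memory. Peak files are BED3 plus an optional score
# (column 4) and optional summit position (column 5); gene tables are
# 5-column TSV (gene_id, chrom, strand, tx_start, tx_end), no header.

#' Read ChIP peaks and standardize them to a fixed width
#'
#' Reads a tab-separated peak file (chrom, start, end, optional score,
#' optional summit; 0-based half-open) and, unless `standardize = FALSE`,
#' narrows every peak to `width` bp centered on its summit when present,
#' otherwise on the interval midpoint `floor((start + end) / 2)`. Peaks
#' whose standardized interval would start before position 0 are shifted
#' right so the width is preserved.
#'
#' @param path Input file.
#' @param width Standardized peak width in bp (500 in the original
#'   analysis).
#' @param standardize Set to `FALSE` to return the intervals as stored.
#' @return A data frame with columns `peak_id` (generated, input order),
#'   `chrom`, `start`, `end`, `score`, `summit` (`NA` when absent).
#' @examples
#' f <- tempfile()
#' writeLines("chr1\t1000\t2000\t8.5", f)
#' read_peaks(f, width = 500)
#' @export
read_peaks <- function(path, width = 500L, standardize = TRUE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("peak file is empty: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("malformed peak line ", which(nf < 3L)[1L],
         ": expected at least 3 tab-separated columns")
  }
  get <- function(i) vapply(fields, function(x)
    if (length(x) >= i) x[[i]] else NA_character_, character(1L))
  start <- suppressWarnings(as.integer(get(2L)))
  end <- suppressWarnings(as.integer(get(3L)))
  bad <- is.na(start) | is.na(end)
  if (any(bad)) {
    stop("malformed peak line ", which(bad)[1L],
         ": non-integer coordinates")
  }
  if (any(start < 0 | end < 0)) {
    stop("malformed peak line ", which(start < 0 | end < 0)[1L],
         ": negative coordinates")
  }
  if (any(start >= end)) {
    stop("malformed peak line ", which(start >= end)[1L],
         ": start must be < end")
  }
  score <- suppressWarnings(as.numeric(get(4L)))
  score[is.na(score)] <- 0
  if (any(score < 0)) stop("enrichment scores must be non-negative")
  summit <- suppressWarnings(as.integer(get(5L)))

  peaks <- data.frame(peak_id = sprintf("peak%05d", seq_along(lines)),
                      chrom = get(1L), start = start, end = end,
                      score = score, summit = summit,
                      stringsAsFactors = FALSE)
  if (standardize) peaks <- standardize_peaks(peaks, width) else peaks
}

#' Standardize peak intervals to a fixed width
#'
#' @param peaks Peak data frame (`chrom`, `start`, `end`, optional
#'   `score`, `summit`).
#' @param width Target width in bp.
#' @return The peaks with `start`/`end` replaced by the standardized
#'   interval (clipped at chromosome start 0 by shifting).
#' @export
standardize_peaks <- function(peaks, width = 500L) {
  width <- as.integer(width)
  if (width <= 0L) stop("width must be positive")
  summit <- if (is.null(peaks$summit)) rep(NA_integer_, nrow(peaks)) else
    peaks$summit
  center <- ifelse(is.na(summit),
                   (peaks$start + peaks$end) %/% 2L,
                   summit)
  start <- pmax(0L, as.integer(center) - width %/% 2L)
  peaks$start <- start
  peaks$end <- start + width
  peaks
}

#' Write peaks back to the BED-like peak dialect
#'
#' @param peaks Peak data frame.
#' @param path Output file.
#' @export
write_peaks <- function(peaks, path) {
  summit <- if (is.null(peaks$summit)) rep(NA_integer_, nrow(peaks)) else
    peaks$summit
  lines <- sprintf("%s\t%d\t%d\t%s%s", peaks$chrom, peaks$start, peaks$end,
                   formatC(peaks$score, format = "fg"),
                   ifelse(is.na(summit), "", sprintf("\t%d", summit)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene annotation table
#'
#' Five tab-separated columns, no header: gene_id, chrom, strand (+/-),
#' tx_start, tx_end (0-based half-open). The strand-aware transcription
#' start site is `tx_start` on + genes and `tx_end - 1` on - genes; the
#' transcription termination site is the opposite end.
#'
#' @param path Input file.
#' @return A data frame with columns `gene_id`, `chrom`, `strand`,
#'   `tx_start`, `tx_end`, `tss`, `tts`.
#' @export
read_gene_table <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("gene_id", "chrom", "strand",
                                        "tx_start", "tx_end"))
  make_gene_table(df$gene_id, df$chrom, df$strand, df$tx_start, df$tx_end)
}

#' Construct and validate a gene table in memory
#'
#' @param gene_id,chrom,strand,tx_start,tx_end Parallel vectors of gene
#'   fields (0-based half-open coordinates).
#' @return A validated gene data frame with derived `tss` and `tts`
#'   columns.
#' @export
make_gene_table <- function(gene_id, chrom, strand, tx_start, tx_end) {
  tx_start <- as.integer(tx_start)
  tx_end <- as.integer(tx_end)
  if (any(!strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-' (gene ",
         gene_id[which(!strand %in% c("+", "-"))[1L]], ")")
  }
  if (any(tx_start < 0)) stop("negative transcript coordinates")
  if (any(tx_start >= tx_end)) {
    stop("tx_start must be < tx_end (gene ",
         gene_id[which(tx_start >= tx_end)[1L]], ")")
  }
  if (anyDuplicated(gene_id)) {
    stop("duplicate gene_id: ", gene_id[duplicated(gene_id)][1L])
  }
  data.frame(gene_id = as.character(gene_id), chrom = as.character(chrom),
             strand = strand, tx_start = tx_start, tx_end = tx_end,
             tss = ifelse(strand == "+", tx_start, tx_end - 1L),
             tts = ifelse(strand == "+", tx_end - 1L, tx_start),
             stringsAsFactors = FALSE)
}

#' Write a gene table
#'
#' @param genes Gene data frame (see [read_gene_table()]).
#' @param path Output file.
#' @export
write_gene_table <- function(genes, path) {
  utils::write.table(genes[, c("gene_id", "chrom", "strand",
                               "tx_start", "tx_end")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an aligned binding-site set
#'
#' Accepts FASTA or one-sequence-per-line text. Sites must be equal
#' length, non-empty, and unambiguous (N is rejected: sites feed directly
#' into frequency counting). Case is folded to upper case.
#'
#' @param path Input file.
#' @return Character vector of uppercase site strings.
#' @export
read_sites <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("site file is empty: ", path)
  if (startsWith(lines[[1L]], ">")) {
    ss <- Biostrings::readDNAStringSet(path)
    sites <- toupper(as.character(ss))
  } else {
    sites <- toupper(trimws(lines))
  }
  if (length(sites) == 0L) stop("site file contains no sequences: ", path)
  if (length(unique(nchar(sites))) != 1L) {
    stop("binding sites must all have the same length")
  }
  if (any(grepl("N", sites, fixed = TRUE))) {
    stop("binding sites must be unambiguous (no N allowed)")
  }
  if (any(grepl("[^ACGT]", sites))) {
    stop("binding sites contain characters outside {A,C,G,T}")
  }
  unname(sites)
}

#' Read sequences from FASTA (N allowed)
#'
#' @param path FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta_sequences <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of DNA strings.
#' @param path Output file.
#' @export
write_fasta_sequences <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read an expression table
#'
#' Tab-separated with a header. Time-series mode: `gene_id` plus one
#' numeric column per time point, named by the hour (e.g. `0 3 6 12`).
#' Replicate mode: `gene_id` plus columns prefixed `control_` and
#' `treated_`.
#'
#' @param path Input file.
#' @return Data frame with `gene_id` first; column names preserved.
#' @export
read_expression <- function(path) {
  utils::read.delim(path, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Write an expression table
#'
#' @param expr Expression data frame (see [read_expression()]).
#' @param path Output file.
#' @export
write_expression <- function(expr, path) {
  utils::write.table(expr, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Export a regulatory network as SIF plus node attributes
#'
#' Writes one line per retained edge, `HUB<TAB>regulates<TAB>TARGET`, in
#' lexicographic (hub, target) order, and a companion node-attribute file
#' (`node<TAB>class` header) mapping every node to `hub`, `up` or `down`
#' — the node coloring convention of the original figures (hubs blue,
#' up-regulated targets red, down-regulated green).
#'
#' @param network A [build_network()] result.
#' @param path SIF output file.
#' @param attr_path Node-attribute output file (default: `path` with a
#'   `.noa.tsv` suffix).
#' @return `path`, invisibly.
#' @export
write_network_sif <- function(network, path,
                              attr_path = paste0(path, ".noa.tsv")) {
  stopifnot(inherits(network, "regulatory_network"))
  e <- network$edges
  e <- e[order(e$hub, e$target), , drop = FALSE]
  writeLines(if (nrow(e)) sprintf("%s\tregulates\t%s", e$hub, e$target)
             else character(), path)
  nd <- network$nodes
  cls <- ifelse(nd$role %in% c("hub", "both"), "hub", nd$direction)
  ord <- order(nd$gene_id)
  writeLines(c("node\tclass",
               if (nrow(nd)) sprintf("%s\t%s", nd$gene_id[ord], cls[ord])),
             attr_path)
  invisible(path)
}

#' Export a regulatory network as GraphML
#'
#' Node attributes `role` and `direction` and edge attributes
#' `permutation_ratio` and `n_hits` are carried into the GraphML.
#'
#' @param network A [build_network()] result.
#' @param path Output file.
#' @export
write_network_graphml <- function(network, path) {
  g <- as_igraph(network)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Export the retained edge table
#'
#' Tab-separated columns hub, target, n_peaks, n_hit_peaks, best_ratio.
#'
#' @param network A [build_network()] result.
#' @param path Output file.
#' @export
write_edge_table <- function(network, path) {
  stopifnot(inherits(network, "regulatory_network"))
  e <- network$edges[order(network$edges$hub, network$edges$target), ,
                     drop = FALSE]
  utils::write.table(e, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write the binary hub-by-gene relationship table
#'
#' The table consumed by dynamic regulatory-map tools: rows are the gene
#' universe, one column per hub, cell 1 when the hub's motif was found in
#' the gene's peak region(s) and 0 otherwise.
#'
#' @param assignments Named list mapping hub name to a character vector of
#'   gene ids.
#' @param universe Character vector of gene ids forming the row universe.
#' @param path Output file.
#' @export
write_drem_table <- function(assignments, universe, path) {
  hubs <- sort(names(assignments))
  for (h in hubs) {
    extra <- setdiff(assignments[[h]], universe)
    if (length(extra)) {
      stop("hub ", h, " assigns gene(s) outside the universe: ",
           paste(extra, collapse = ", "))
    }
  }
  m <- vapply(hubs, function(h) as.integer(universe %in% assignments[[h]]),
              integer(length(universe)))
  m <- matrix(m, nrow = length(universe),
              dimnames = list(NULL, hubs))
  df <- data.frame(gene_id = universe, m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
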