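#' Simulate ATAC peak intervals and gene TSS annotations
#'
#' Places `n_peaks` non-overlapping peak intervals, each centred on a
#' randomly chosen panel variant (so every peak contains at least one
#' variant), and `n_genes` genes with TSSs drawn uniformly along the region.
#' Coordinates follow the BED convention for peaks (0-based, half-open) and
#' are 1-based for TSSs.
#'
#' @param panel a `genotype_panel`.
#' @param n_peaks,n_genes feature counts.
#' @param peak_width peak width in basepairs.
#' @param seed integer seed.
#' @return list with `peaks` (data.frame: chrom, start, end, id) and
#'   `genes` (data.frame: id, chrom, tss, strand).
#' @export
simulate_features <- function(panel, n_peaks, n_genes, peak_width = 400,
                              seed = 1L) {
  stopifnot(inherits(panel, "genotype_panel"), n_peaks >= 1, n_genes >= 1)
  set.seed(derive_seed(seed, "features"))
  pos <- panel$variants$pos
  region_length <- panel$params$region_length
  anchors <- sort(sample(pos, min(n_peaks, length(pos))))
  start <- pmax(0L, as.integer(anchors - peak_width %/% 2))
  end <- pmin(as.integer(region_length), start + as.integer(peak_width))
  peaks <- data.frame(
    chrom = "chr1", start = start, end = end,
    id = sprintf("peak%04d", seq_along(start)), stringsAsFactors = FALSE
  )
  # drop overlaps introduced by clustered anchor variants
  keep <- c(TRUE, peaks$start[-1] >= peaks$end[-nrow(peaks)])
  peaks <- peaks[keep, , drop = FALSE]
  peaks$id <- sprintf("peak%04d", seq_len(nrow(peaks)))
  genes <- data.frame(
    id = sprintf("gene%04d", seq_len(n_genes)),
    chrom = "chr1",
    tss = sort(sample.int(region_length, n_genes)),
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    stringsAsFactors = FALSE
  )
  list(peaks = peaks, genes = genes)
}

#' Shortest distance from a peak edge to a gene TSS
#'
#' Zero when the TSS falls inside the peak interval; otherwise the smaller of
#' the distances from the 1-based TSS to the two peak edge positions
#' `start + 1` and `end - 1` (the BED half-open interval's flanking bases on
#' the 1-based scale used for TSSs).
#'
#' @param peak one-row data.frame (or list) with `chrom`, `start`, `end`.
#' @param gene one-row data.frame (or list) with `chrom`, `tss`.
#' @return distance in basepairs (non-negative integer).
#' @export
peak_tss_distance <- function(peak, gene) {
  if (peak$chrom != gene$chrom) stop("peak and gene on different chromosomes")
  tss <- gene$tss
  if (tss >= peak$start + 1 && tss <= peak$end) return(0)
  min(abs(tss - (peak$start + 1)), abs(tss - (peak$end - 1)))
}

# vectorized peak-to-TSS distance over aligned rows
peak_tss_distance_vec <- function(peaks, genes) {
  inside <- genes$tss >= peaks$start + 1 & genes$tss <= peaks$end
  d <- pmin(abs(genes$tss - (peaks$start + 1)), abs(genes$tss - (peaks$end - 1)))
  d[inside] <- 0
  d
}
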