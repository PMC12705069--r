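#' Annotate peaks with strength quintiles and histone-mark overlap
#'
#' Peak "strength" is the 95th-percentile CPM across samples; peaks are
#' stratified into quintiles by descending strength (quintile 1 =
#' strongest). Each peak is tested for overlap of at least 1 bp with every
#' supplied histone-mark interval set (0-based half-open coordinates, as
#' BED). When marks named `H3K27ac` and `H3K4me3` are present, derived
#' labels follow the standard chromatin-signature definitions:
#' promoter-like = H3K27ac and H3K4me3; enhancer-like = H3K27ac but no
#' H3K4me3; ATAC-only = none of the supplied marks.
#'
#' @param peaks peak table (chrom, start, end, id).
#' @param cpm CPM matrix with peak ids as rownames.
#' @param mark_intervals named list of interval data.frames
#'   (chrom, start, end).
#' @return data.frame: peak_id, strength (95th-pct CPM), quintile, one
#'   logical column per mark, and (when applicable) promoter_like,
#'   enhancer_like, atac_only.
#' @export
annotate_peak_subsets <- function(peaks, cpm, mark_intervals = list()) {
  q95 <- apply(cpm[peaks$id, , drop = FALSE], 1, stats::quantile,
               probs = 0.95)
  # descending strength; rank 1 = strongest peak
  rk <- rank(-q95, ties.method = "min")
  quintile <- pmin(5L, (5L * (rk - 1L)) %/% length(rk) + 1L)
  out <- data.frame(peak_id = peaks$id, strength = unname(q95),
                    quintile = quintile, stringsAsFactors = FALSE,
                    row.names = NULL)
  pk_ir <- IRanges::IRanges(start = peaks$start + 1L, end = peaks$end)
  for (mk in names(mark_intervals)) {
    iv <- mark_intervals[[mk]]
    same_chr <- iv$chrom[1] == peaks$chrom[1] # single-chromosome panels
    mk_ir <- IRanges::IRanges(start = iv$start + 1L, end = iv$end)
    hits <- IRanges::overlapsAny(pk_ir, mk_ir, minoverlap = 1L)
    out[[mk]] <- hits & same_chr
  }
  if (all(c("H3K27ac", "H3K4me3") %in% names(mark_intervals))) {
    out$promoter_like <- out$H3K27ac & out$H3K4me3
    out$enhancer_like <- out$H3K27ac & !out$H3K4me3
  }
  if (length(mark_intervals) > 0) {
    mk_cols <- names(mark_intervals)
    out$atac_only <- rowSums(as.matrix(out[, mk_cols, drop = FALSE])) == 0
  }
  out
}

#' Proportion of mediated heritability within TSS windows
#'
#' For each window size, the proportion of the total per-peak mediated
#' heritability carried by peaks whose distance to the nearest gene TSS is
#' at most the window, alongside the proportion of peaks in that window.
#'
#' @param peaks_med peak table with an `h2_med` column of per-peak
#'   mediation totals.
#' @param genes gene table (chrom, tss).
#' @param windows ascending vector of window sizes in basepairs.
#' @return data.frame: window, prop_h2med, prop_peaks, n_peaks.
#' @export
tss_window_mediated_h2 <- function(peaks_med, genes, windows) {
  stopifnot(!is.unsorted(windows), "h2_med" %in% names(peaks_med))
  d_near <- vapply(seq_len(nrow(peaks_med)), function(i) {
    min(peak_tss_distance_vec(peaks_med[rep(i, nrow(genes)), , drop = FALSE],
                              genes))
  }, numeric(1))
  total <- sum(peaks_med$h2_med)
  res <- lapply(windows, function(w) {
    inw <- d_near <= w
    data.frame(window = w,
               prop_h2med = if (total > 0) sum(peaks_med$h2_med[inw]) / total
               else NA_real_,
               prop_peaks = mean(inw), n_peaks = sum(inw))
  })
  do.call(rbind, res)
}
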