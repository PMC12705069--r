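#' Export a simulated bundle to plain-text files
#'
#' Writes the panel, features, count matrices, summary statistics and truth
#' ledger to a directory as BED/TSV/JSON so a run can be inspected or
#' re-imported bit-exactly. Numeric values are serialized with 17
#' significant digits (round-trip exact for doubles).
#'
#' @param bundle list with any of: `panel` (genotype_panel), `peaks`,
#'   `genes`, `counts` (named list of count matrices), `sumstats` (named
#'   list of summary-stat tables), `truth` (list of scalars/vectors).
#' @param directory output directory.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return invisibly, the vector of files written.
#' @export
export_fixture <- function(bundle, directory, overwrite = FALSE) {
  if (dir.exists(directory) && length(dir(directory)) > 0 && !overwrite)
    stop("directory exists and is not empty: ", directory)
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  put <- function(name) { files <<- c(files, file.path(directory, name)); files[length(files)] }

  if (!is.null(bundle$peaks)) {
    bed <- bundle$peaks[, c("chrom", "start", "end", "id")]
    write_tsv17(bed, put("peaks.bed"), col.names = FALSE)
  }
  if (!is.null(bundle$genes))
    write_tsv17(bundle$genes, put("genes.tsv"))
  if (!is.null(bundle$panel)) {
    write_tsv17(bundle$panel$variants, put("variants.tsv"))
    dos <- data.frame(sample_id = rownames(bundle$panel$dosages),
                      bundle$panel$dosages, check.names = FALSE)
    write_tsv17(dos, put("dosages.tsv"))
  }
  for (nm in names(bundle$counts)) {
    cm <- bundle$counts[[nm]]
    df <- data.frame(feature_id = rownames(cm), cm, check.names = FALSE)
    write_tsv17(df, put(sprintf("counts_%s.tsv", nm)))
  }
  for (nm in names(bundle$sumstats))
    write_tsv17(as.data.frame(bundle$sumstats[[nm]]),
                put(sprintf("sumstats_%s.tsv", nm)))
  if (!is.null(bundle$truth))
    jsonlite::write_json(bundle$truth, put("truth.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(files)
}

#' Re-import a fixture directory written by [export_fixture()]
#' @param directory directory containing the exported files.
#' @return a bundle list (matrices and tables; the genotype panel is
#'   returned as `variants` + `dosages`, not a full `genotype_panel`).
#' @export
import_fixture <- function(directory) {
  rd <- function(name, ...) utils::read.delim(file.path(directory, name),
                                              stringsAsFactors = FALSE, check.names = FALSE, ...)
  out <- list()
  f <- file.path(directory, "peaks.bed")
  if (file.exists(f)) {
    out$peaks <- utils::read.delim(f, header = FALSE,
                                   col.names = c("chrom", "start", "end", "id"),
                                   stringsAsFactors = FALSE)
  }
  if (file.exists(file.path(directory, "genes.tsv"))) out$genes <- rd("genes.tsv")
  if (file.exists(file.path(directory, "variants.tsv")))
    out$variants <- rd("variants.tsv")
  if (file.exists(file.path(directory, "dosages.tsv"))) {
    d <- rd("dosages.tsv")
    m <- as.matrix(d[, -1, drop = FALSE])
    rownames(m) <- d$sample_id
    out$dosages <- m
  }
  for (f in dir(directory, pattern = "^counts_.*\\.tsv$")) {
    d <- rd(f)
    m <- as.matrix(d[, -1, drop = FALSE])
    rownames(m) <- d$feature_id
    out$counts[[sub("^counts_(.*)\\.tsv$", "\\1", f)]] <- m
  }
  for (f in dir(directory, pattern = "^sumstats_.*\\.tsv$"))
    out$sumstats[[sub("^sumstats_(.*)\\.tsv$", "\\1", f)]] <- rd(f)
  if (file.exists(file.path(directory, "truth.json")))
    out$truth <- jsonlite::read_json(file.path(directory, "truth.json"),
                                     simplifyVector = TRUE)
  out
}

# TSV writer with round-trip-exact numeric formatting
write_tsv17 <- function(df, path, col.names = TRUE) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = col.names)
  invisible(path)
}
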