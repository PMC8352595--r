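#' Write / read a gene count table as TSV
#'
#' Columns: `gene_id`, `length`, then one column per sample named
#' `<genotype>_<fraction>_rep<k>`. The same schema carries both
#' simulated and real data.
#'
#' @param table gene count table.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_gene_counts <- function(table, path) {
  validate_gene_counts(table)
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_gene_counts
#' @export
read_gene_counts <- function(path) {
  tbl <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  validate_gene_counts(tbl)
  tbl
}

#' Write / read a time-lapse stack as multi-page TIFF with a JSON sidecar
#'
#' Frames are written as one TIFF page each (intensities scaled by the
#' bit range); the acquisition frequency and bit depth go into a JSON
#' sidecar next to the TIFF (default `<path>.json`).
#'
#' @param stack a [time_lapse_stack()].
#' @param path TIFF output path.
#' @param sidecar JSON sidecar path.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path,
                             sidecar = paste0(path, ".json")) {
  stopifnot(inherits(stack, "time_lapse_stack"))
  mx <- bit_max(stack)
  pages <- lapply(seq_len(dim(stack$frames)[3]),
                  function(k) stack$frames[, , k] / mx)
  tiff::writeTIFF(pages, path,
                  bits.per.sample = if (stack$bit_depth == 8) 8L else 16L)
  jsonlite::write_json(
    list(acquisition_frequency = stack$acquisition_frequency,
         bit_depth = stack$bit_depth),
    sidecar, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path, sidecar = paste0(path, ".json")) {
  meta <- jsonlite::read_json(sidecar)
  pages <- tiff::readTIFF(path, all = TRUE)
  mx <- 2^meta$bit_depth - 1
  fr <- array(0, c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) fr[, , k] <- round(pages[[k]] * mx)
  time_lapse_stack(fr, meta$acquisition_frequency, meta$bit_depth)
}

#' Write a PSR result table as TSV
#'
#' @param psr_table output of [psr_analysis()].
#' @param path output TSV path.
#' @param summary_path optional JSON path for the run summary (thresholds
#'   and sample manifest).
#' @return `path`, invisibly.
#' @export
write_psr_table <- function(psr_table, path, summary_path = NULL) {
  utils::write.table(psr_table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(summary_path)) {
    s <- attr(psr_table, "summary")
    s$samples <- NULL
    jsonlite::write_json(s, summary_path, auto_unbox = TRUE)
  }
  invisible(path)
}

#' Write a CBF report as JSON
#'
#' @param report a `cbf_report` from [run_cbf()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_cbf_report <- function(report, path) {
  stopifnot(inherits(report, "cbf_report"))
  jsonlite::write_json(
    list(cbf_hz = report$cbf_hz, cbf_defined = report$cbf_defined,
         n_signal_pixels = report$n_signal_pixels,
         power_threshold = report$power_threshold,
         params = unclass(report$params)),
    path, auto_unbox = TRUE, na = "null", digits = NA)
  invisible(path)
}

#' Write an LFQ intensity matrix as TSV
#'
#' @param lfq protein x sample matrix (NA = absent).
#' @param path output TSV path.
#' @param zero_for_missing write absent entries as 0 (the convention of
#'   common quantification exporters) instead of NA.
#' @return `path`, invisibly.
#' @export
write_lfq_matrix <- function(lfq, path, zero_for_missing = TRUE) {
  m <- as.matrix(lfq)
  if (zero_for_missing) m[is.na(m)] <- 0
  df <- data.frame(protein_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
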