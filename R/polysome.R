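#' Parse sample metadata from gene-count column names
#'
#' Count tables use one column per sequencing sample, named
#' `<genotype>_<fraction>_rep<k>` (e.g. `WT_poly_rep1`, `NRS_sub_rep3`).
#' Fractions are `poly` (polysomal), `sub` (subpolysomal) and optionally
#' `cyto` (total cytoplasmic).
#'
#' @param sample_names character vector of sample column names.
#' @return data.frame with columns `sample`, `genotype`, `fraction`,
#'   `replicate`.
#' @export
parse_sample_names <- function(sample_names) {
  m <- regmatches(sample_names,
                  regexec("^(.+)_(poly|sub|cyto)_rep([0-9]+)$", sample_names))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) {
    stop("malformed sample name(s): ",
         paste(sample_names[bad], collapse = ", "),
         " (expected <genotype>_<fraction>_rep<k>)")
  }
  data.frame(
    sample    = sample_names,
    genotype  = vapply(m, `[`, "", 2L),
    fraction  = vapply(m, `[`, "", 3L),
    replicate = as.integer(vapply(m, `[`, "", 4L)),
    stringsAsFactors = FALSE
  )
}

count_columns <- function(table) {
  setdiff(colnames(table), c("gene_id", "length"))
}

validate_gene_counts <- function(table) {
  stopifnot(is.data.frame(table))
  if (!all(c("gene_id", "length") %in% colnames(table)))
    stop("gene count table needs 'gene_id' and 'length' columns")
  if (any(table$length <= 0)) stop("transcript lengths must be > 0")
  cc <- count_columns(table)
  if (length(cc) == 0L) stop("gene count table has no sample columns")
  cnt <- as.matrix(table[cc])
  if (any(cnt < 0) || any(cnt != round(cnt)))
    stop("counts must be non-negative integers")
  if (anyDuplicated(cc)) stop("sample labels must be unique")
  invisible(table)
}

#' Pool replicate counts for one genotype and fraction
#'
#' Gene-level counts from all replicates of a (genotype, fraction) sample
#' are summed into a single pooled sample, the form in which polysome
#' indices are computed. (Per-replicate indices are used only for the
#' significance test, see [psr_significance()].)
#'
#' @param table gene count table (see [parse_sample_names()] for the
#'   column naming scheme).
#' @param genotype,fraction sample labels to pool over.
#' @return named numeric vector of pooled counts (names = gene ids), with
#'   attribute `pooled_samples` recording the replicate columns summed.
#' @export
pool_replicates <- function(table, genotype, fraction) {
  validate_gene_counts(table)
  info <- parse_sample_names(count_columns(table))
  sel <- info$sample[info$genotype == genotype & info$fraction == fraction]
  if (length(sel) == 0L)
    stop("no samples match genotype '", genotype,
         "' and fraction '", fraction, "'")
  pooled <- rowSums(as.matrix(table[sel]))
  names(pooled) <- table$gene_id
  attr(pooled, "pooled_samples") <- sel
  pooled
}

#' Transcripts-per-million read-count density
#'
#' For gene a with count n(a) and transcript length L(a), the density is
#' \deqn{d(a) = 10^6 \frac{n(a)/L(a)}{\sum_j n(j)/L(j)}}
#' so every sample's densities sum to one million, making fraction samples
#' of different depths comparable.
#'
#' @param counts non-negative per-gene read counts.
#' @param lengths transcript lengths in nucleotides (> 0).
#' @return per-gene TPM densities, summing to 1e6.
#' @export
tpm_density <- function(counts, lengths) {
  if (length(counts) != length(lengths))
    stop("counts and lengths differ in length")
  if (any(lengths <= 0)) stop("transcript lengths must be > 0")
  if (any(counts < 0)) stop("counts must be non-negative")
  rate <- counts / lengths
  tot <- sum(rate)
  if (tot <= 0) stop("empty sample: all counts are zero")
  1e6 * rate / tot
}

#' TPM densities for every sample column of a count table
#'
#' @param table gene count table.
#' @return matrix (genes x samples) of TPM densities, rownames = gene ids.
#' @export
density_table <- function(table) {
  validate_gene_counts(table)
  cc <- count_columns(table)
  d <- vapply(cc, function(s) tpm_density(table[[s]], table$length),
              numeric(nrow(table)))
  rownames(d) <- table$gene_id
  d
}

#' Polysome index
#'
#' PI(a) = d_poly(a) / (d_poly(a) + d_sub(a)): the proportion of a
#' transcript's copies engaged in polysomes. Undefined (NA) where both
#' densities are zero.
#'
#' @param d_poly,d_sub TPM density vectors over the same gene set
#'   (names, if present, must agree).
#' @return per-gene PI in \[0, 1\], NA where undefined.
#' @export
polysome_index <- function(d_poly, d_sub) {
  if (length(d_poly) != length(d_sub))
    stop("density vectors differ in length")
  if (!is.null(names(d_poly)) && !is.null(names(d_sub)) &&
      !identical(names(d_poly), names(d_sub)))
    stop("density vectors are over different gene sets")
  tot <- d_poly + d_sub
  pi <- ifelse(tot > 0, d_poly / tot, NA_real_)
  names(pi) <- names(d_poly)
  pi
}

#' Polysome shift ratio
#'
#' PSR(a) = log2(PI_mut(a) / PI_wt(a)). Negative values mean the gene is
#' depleted from polysomes in the mutant. Undefined (NA) when either PI is
#' missing or zero (log of zero is not reported as -Inf).
#'
#' @param pi_mut,pi_wt polysome indices for the mutant and wild-type
#'   genotypes over the same gene set.
#' @return per-gene PSR in log2 units, NA where undefined.
#' @export
polysome_shift_ratio <- function(pi_mut, pi_wt) {
  if (length(pi_mut) != length(pi_wt))
    stop("PI vectors differ in length")
  ok <- !is.na(pi_mut) & !is.na(pi_wt) & pi_mut > 0 & pi_wt > 0
  psr <- rep(NA_real_, length(pi_mut))
  psr[ok] <- log2(pi_mut[ok] / pi_wt[ok])
  names(psr) <- names(pi_mut)
  psr
}

#' Per-gene significance of the polysome shift
#'
#' Two-sided equal-variance (pooled) two-sample t-test on the polysome
#' indices of individual replicates, vectorised over genes. Degenerate
#' cases follow a documented convention: zero pooled variance with equal
#' group means gives p = 1; zero pooled variance with unequal means gives
#' p = 0. Genes with fewer than two defined replicate PIs in either
#' genotype are untestable and get p = NA.
#'
#' @param pis_mut,pis_wt numeric matrices (genes x replicates) of
#'   per-replicate polysome indices; NA entries are dropped per gene.
#' @return data.frame with columns `t`, `df`, `p_value` (one row per gene).
#' @export
psr_significance <- function(pis_mut, pis_wt) {
  pis_mut <- as.matrix(pis_mut)
  pis_wt <- as.matrix(pis_wt)
  if (nrow(pis_mut) != nrow(pis_wt))
    stop("replicate PI matrices differ in gene count")
  n1 <- rowSums(!is.na(pis_mut))
  n2 <- rowSums(!is.na(pis_wt))
  m1 <- rowMeans(pis_mut, na.rm = TRUE)
  m2 <- rowMeans(pis_wt, na.rm = TRUE)
  ss1 <- rowSums((pis_mut - m1)^2, na.rm = TRUE)
  ss2 <- rowSums((pis_wt - m2)^2, na.rm = TRUE)
  testable <- n1 >= 2 & n2 >= 2
  df <- n1 + n2 - 2
  sp2 <- (ss1 + ss2) / df               # pooled variance
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tval <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(tval), df)
  degen <- testable & sp2 <= 0
  p[degen] <- ifelse(m1[degen] == m2[degen], 1, 0)
  tval[degen & m1 == m2] <- 0
  p[!testable] <- NA_real_
  tval[!testable] <- NA_real_
  data.frame(t = tval, df = ifelse(testable, df, NA_real_), p_value = p)
}

#' Classify genes by polysome shift
#'
#' A gene is `down` if p < alpha and PSR < 0, `up` if p < alpha and
#' PSR > 0, `undefined` if its PSR or p-value is missing, otherwise
#' `unchanged`. No multiple-testing correction is applied by default,
#' matching the raw p < 0.05 convention of polysome-shift screens; set
#' `fdr = TRUE` to classify on Benjamini-Hochberg adjusted p-values.
#'
#' @param psr_table data.frame with columns `PSR` and `p_value`.
#' @param alpha significance level (default 0.05).
#' @param fdr classify on BH-adjusted p-values instead of raw ones.
#' @return `psr_table` with a `class` column added (factor levels
#'   down/up/unchanged/undefined).
#' @export
classify_shifted_genes <- function(psr_table, alpha = 0.05, fdr = FALSE) {
  stopifnot(all(c("PSR", "p_value") %in% colnames(psr_table)))
  p <- psr_table$p_value
  if (fdr) p <- stats::p.adjust(p, method = "BH")
  psr <- psr_table$PSR
  cls <- rep("unchanged", nrow(psr_table))
  cls[!is.na(p) & !is.na(psr) & p < alpha & psr < 0] <- "down"
  cls[!is.na(p) & !is.na(psr) & p < alpha & psr > 0] <- "up"
  cls[is.na(psr) | is.na(p)] <- "undefined"
  psr_table$class <- factor(cls, levels = c("down", "up", "unchanged",
                                            "undefined"))
  psr_table
}

#' Gene lists for GO-enrichment input
#'
#' Selects genes shifted by at least the given fold changes in PI. The
#' log2 bounds are rounded to two decimals before comparison so that the
#' down threshold is exactly -0.23 for the default 0.85-fold (and 0.20
#' for 1.15-fold), with inclusive comparisons.
#'
#' @param psr_table data.frame with `gene_id` and `PSR` columns.
#' @param down_fold,up_fold fold-change bounds in PI ratio (must be in
#'   (0, Inf)).
#' @return list with elements `down` and `up` (character gene-id vectors)
#'   and the rounded log2 `thresholds` used.
#' @export
go_input_filter <- function(psr_table, down_fold = 0.85, up_fold = 1.15) {
  if (!is.finite(down_fold) || down_fold <= 0 ||
      !is.finite(up_fold) || up_fold <= 0)
    stop("fold thresholds must be finite and > 0")
  lo <- round(log2(down_fold), 2)
  hi <- round(log2(up_fold), 2)
  psr <- psr_table$PSR
  list(
    down = psr_table$gene_id[!is.na(psr) & psr <= lo],
    up   = psr_table$gene_id[!is.na(psr) & psr >= hi],
    thresholds = c(down = lo, up = hi)
  )
}

#' Filter genes on mean expression
#'
#' Keeps genes whose mean TPM across the supplied density columns is
#' strictly greater than the threshold.
#'
#' @param densities matrix (genes x samples) of TPM densities.
#' @param min_mean_tpm expression threshold (default 0.5; strict >).
#' @return logical vector: TRUE for genes retained.
#' @export
expression_filter <- function(densities, min_mean_tpm = 0.5) {
  rowMeans(as.matrix(densities)) > min_mean_tpm
}

#' Full polysome-shift analysis
#'
#' Runs the complete pipeline on a gene count table: per-sample TPM
#' densities, replicate-pooled polysome indices per genotype, polysome
#' shift ratios, per-gene pooled-t significance from per-replicate PIs,
#' expression filtering and classification.
#'
#' @param table gene count table with poly and sub fraction samples for
#'   both genotypes.
#' @param wt,mut genotype labels (defaults `"WT"` and `"NRS"`).
#' @param alpha significance level for classification.
#' @param min_mean_tpm expression filter threshold on the mean TPM over
#'   all samples; genes at or below it are dropped before testing.
#' @param fdr use BH-adjusted p-values for classification.
#' @return data.frame (one row per retained gene) with columns `gene_id`,
#'   `PI_wt`, `PI_mut`, `PSR`, `p_value`, `mean_tpm`, `class`, plus a
#'   `summary` attribute recording thresholds and the sample manifest.
#' @export
psr_analysis <- function(table, wt = "WT", mut = "NRS", alpha = 0.05,
                         min_mean_tpm = 0.5, fdr = FALSE) {
  validate_gene_counts(table)
  info <- parse_sample_names(count_columns(table))
  for (g in c(wt, mut)) for (f in c("poly", "sub")) {
    if (!any(info$genotype == g & info$fraction == f))
      stop("no '", f, "' samples for genotype '", g, "'")
  }
  dens <- density_table(table)
  keep <- expression_filter(dens, min_mean_tpm)
  tbl <- table[keep, , drop = FALSE]
  dens <- dens[keep, , drop = FALSE]

  pooled_pi <- function(geno) {
    dp <- tpm_density(pool_replicates(tbl, geno, "poly"), tbl$length)
    ds <- tpm_density(pool_replicates(tbl, geno, "sub"), tbl$length)
    polysome_index(dp, ds)
  }
  pi_wt <- pooled_pi(wt)
  pi_mut <- pooled_pi(mut)
  psr <- polysome_shift_ratio(pi_mut, pi_wt)

  rep_pis <- function(geno) {
    sp <- info[info$genotype == geno & info$fraction == "poly", ]
    ss <- info[info$genotype == geno & info$fraction == "sub", ]
    reps <- intersect(sp$replicate, ss$replicate)
    vapply(reps, function(r) {
      dp <- tpm_density(tbl[[sp$sample[sp$replicate == r]]], tbl$length)
      ds <- tpm_density(tbl[[ss$sample[ss$replicate == r]]], tbl$length)
      polysome_index(dp, ds)
    }, numeric(nrow(tbl)))
  }
  sig <- psr_significance(rep_pis(mut), rep_pis(wt))

  out <- data.frame(
    gene_id = tbl$gene_id,
    PI_wt = unname(pi_wt),
    PI_mut = unname(pi_mut),
    PSR = unname(psr),
    p_value = sig$p_value,
    mean_tpm = unname(rowMeans(dens)),
    stringsAsFactors = FALSE
  )
  out <- classify_shifted_genes(out, alpha = alpha, fdr = fdr)
  attr(out, "summary") <- list(
    wt = wt, mut = mut, alpha = alpha, min_mean_tpm = min_mean_tpm,
    fdr = fdr, n_genes_in = nrow(table), n_genes_tested = nrow(out),
    samples = info
  )
  out
}
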