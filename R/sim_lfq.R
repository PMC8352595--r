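#' Simulate a label-free proteomics time course
#'
#' Generates log-normal LFQ intensities for proteins measured across
#' differentiation stages (e.g. air-liquid-interface days) in two
#' genotypes with replicates. Each protein follows a smooth stage
#' trajectory (protein-specific slope over standardised stage); the
#' mutant genotype loses signal progressively, reaching `group_effect`
#' log2 units below wild type at the final stage. Entries are missing
#' completely at random at `missing_rate` (represented as NA; see
#' [write_lfq_matrix()] for emitting 0s instead).
#'
#' @param n_proteins number of proteins.
#' @param timepoints numeric stage labels (e.g. `c(4, 6, 8, 10, 14, 18)`).
#' @param n_replicates replicates per genotype and stage.
#' @param missing_rate fraction of entries absent, in \[0, 1).
#' @param group_effect log2-unit depletion of the mutant at the final
#'   stage.
#' @param seed integer seed.
#' @return list with `lfq` (protein x sample matrix of raw-scale
#'   intensities, NA = absent; sample metadata in attribute `samples`)
#'   and `truth` (per-protein slopes, the missing mask, parameters,
#'   seed).
#' @export
generate_lfq_timecourse <- function(n_proteins = 500,
                                    timepoints = c(4, 6, 8, 10, 14, 18),
                                    n_replicates = 3,
                                    missing_rate = 0.1,
                                    group_effect = 1,
                                    seed = 1) {
  if (missing_rate < 0 || missing_rate >= 1)
    stop("invalid 'missing_rate': must be in [0, 1)")
  if (n_proteins < 1 || n_replicates < 1 || length(timepoints) < 2)
    stop("need >= 1 protein, >= 1 replicate and >= 2 timepoints")
  set.seed(seed)
  stages <- seq_along(timepoints)
  z <- (stages - mean(stages)) / stats::sd(stages)
  ramp <- (stages - 1) / (length(stages) - 1)
  genotypes <- c("WT", "NRS")
  samples <- expand.grid(replicate = seq_len(n_replicates),
                         stage = timepoints, genotype = genotypes,
                         stringsAsFactors = FALSE)[, c(3, 2, 1)]
  samples$sample <- sprintf("%s_ALI%g_rep%d", samples$genotype,
                            samples$stage, samples$replicate)

  base <- stats::rnorm(n_proteins, 25, 2)
  slope <- stats::rnorm(n_proteins, 1, 0.5)
  lg <- matrix(NA_real_, n_proteins, nrow(samples),
               dimnames = list(sprintf("prot_%04d", seq_len(n_proteins)),
                               samples$sample))
  for (j in seq_len(nrow(samples))) {
    s <- match(samples$stage[j], timepoints)
    mu <- base + slope * z[s] -
      if (samples$genotype[j] == "NRS") group_effect * ramp[s] else 0
    lg[, j] <- mu + stats::rnorm(n_proteins, 0, 0.3)
  }
  missing <- matrix(stats::runif(length(lg)) < missing_rate, nrow(lg))
  lfq <- 2^lg
  lfq[missing] <- NA
  attr(lfq, "samples") <- samples
  list(lfq = lfq,
       truth = list(base = base, slope = slope, missing = missing,
                    group_effect = group_effect, timepoints = timepoints,
                    seed = seed))
}
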