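#' Configuration for the polysome-profiling count simulator
#'
#' Defines a two-genotype (WT vs NRS) polysome-profiling experiment with a
#' planted set of translationally shifted genes. Defaults emulate a bulk
#' experiment of realistic size: 2000 genes, one million reads per
#' fraction sample, three biological replicates per genotype, and mild
#' negative-binomial overdispersion.
#'
#' @param n_genes number of genes.
#' @param length_range min/max transcript length in nucleotides.
#' @param total_reads_per_sample sequencing depth of each fraction sample.
#' @param pi_baseline_mean,pi_baseline_sd mean and SD of the clipped-normal
#'   distribution the wild-type polysome indices are drawn from; the mean
#'   plus/minus 3 SD must stay inside (0, 1) (a degenerate sd = 0 with
#'   mean in (0, 1\] is allowed for constructing exact fixtures).
#' @param shifted_fraction fraction of genes translationally shifted in
#'   the mutant.
#' @param true_delta_psr log2 PI-ratio applied to shifted genes in the
#'   mutant (negative = depleted from polysomes).
#' @param n_replicates replicates per genotype and fraction.
#' @param dispersion negative-binomial overdispersion (variance =
#'   mu + dispersion * mu^2); 0 gives exact multinomial allocation.
#' @param seed integer seed; the generator is fully deterministic given
#'   the config.
#' @return validated config object of class `polysome_sim_config`.
#' @export
polysome_sim_config <- function(n_genes = 2000,
                                length_range = c(500L, 5000L),
                                total_reads_per_sample = 1e6,
                                pi_baseline_mean = 0.5,
                                pi_baseline_sd = 0.1,
                                shifted_fraction = 0.1,
                                true_delta_psr = -1,
                                n_replicates = 3,
                                dispersion = 0.05,
                                seed = 1) {
  chk <- function(ok, field, msg) {
    if (!ok) stop("invalid '", field, "': ", msg)
  }
  chk(is.numeric(n_genes) && n_genes >= 1, "n_genes", "need >= 1 gene")
  chk(length(length_range) == 2 && all(length_range > 0) &&
        length_range[1] <= length_range[2],
      "length_range", "need 0 < min <= max")
  chk(total_reads_per_sample > 0, "total_reads_per_sample", "must be > 0")
  chk(pi_baseline_mean > 0 && pi_baseline_mean <= 1,
      "pi_baseline_mean", "must be in (0, 1]")
  chk(pi_baseline_sd >= 0, "pi_baseline_sd", "must be >= 0")
  if (pi_baseline_sd > 0) {
    chk(pi_baseline_mean - 3 * pi_baseline_sd > 0 &&
          pi_baseline_mean + 3 * pi_baseline_sd < 1,
        "pi_baseline_sd", "mean +/- 3 SD must stay inside (0, 1)")
  }
  chk(shifted_fraction >= 0 && shifted_fraction <= 1,
      "shifted_fraction", "must be in [0, 1]")
  chk(is.finite(true_delta_psr), "true_delta_psr", "must be finite")
  chk(n_replicates >= 1, "n_replicates", "need >= 1 replicate")
  chk(dispersion >= 0, "dispersion", "must be >= 0")
  chk(is.numeric(seed) && length(seed) == 1, "seed", "must be one integer")
  structure(list(
    n_genes = as.integer(n_genes), length_range = as.integer(length_range),
    total_reads_per_sample = total_reads_per_sample,
    pi_baseline_mean = pi_baseline_mean, pi_baseline_sd = pi_baseline_sd,
    shifted_fraction = shifted_fraction, true_delta_psr = true_delta_psr,
    n_replicates = as.integer(n_replicates), dispersion = dispersion,
    seed = as.integer(seed)
  ), class = "polysome_sim_config")
}

# Abundance tilt making the TPM-level PI equal the planted PI exactly.
#
# Both fraction samples are TPM-normalised to 1e6 independently, so the
# density-level PI of gene a is PI*S_s / (PI*S_s + (1-PI)*S_p), with
# S_p = sum(u*PI), S_s = sum(u*(1-PI)) over effective abundances u. The
# estimate equals the planted PI for every gene iff S_p = S_s, i.e. the
# abundance-weighted mean PI is 1/2. We therefore solve a minimal tilt
# u = w * (alpha + beta*PI) with sum(u*PI) = sum(u*(1-PI)) = 1. When the
# system is infeasible (e.g. all PIs equal but != 1/2) we fall back to
# u = w, accepting the small global bias of the plain proportional split.
pi_exact_abundance <- function(w, pi) {
  A <- sum(w * pi); B <- sum(w * pi^2); C <- sum(w)
  M <- matrix(c(A, C - A, B, A - B), 2, 2)
  rhs <- c(1, 1)
  u <- NULL
  det <- M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1]
  if (is.finite(det) && abs(det) > 1e-12 * max(abs(M))^2) {
    ab <- solve(M, rhs)
    cand <- w * (ab[1] + ab[2] * pi)
    if (all(cand > 0)) u <- cand
  }
  if (is.null(u)) u <- w / sum(w)  # fallback: proportional allocation
  u
}

draw_counts <- function(p, depth, dispersion) {
  if (sum(p) <= 0) return(integer(length(p)))
  p <- p / sum(p)
  if (dispersion == 0) {
    as.integer(stats::rmultinom(1, size = depth, prob = p))
  } else {
    as.integer(stats::rnbinom(length(p), mu = depth * p,
                              size = 1 / dispersion))
  }
}

#' Simulate a polysome-profiling experiment with known ground truth
#'
#' Draws wild-type polysome indices from a clipped normal, shifts a
#' planted subset of genes in the mutant by `true_delta_psr` log2 units
#' (multiplicatively on PI where that stays below 1, otherwise on the
#' odds scale so PI remains in (0, 1)), and allocates reads to the poly
#' and sub fraction samples of each genotype so that the TPM-level
#' polysome index reproduces the planted PI exactly in expectation (see
#' the methods vignette for the abundance-tilt construction). Counts are
#' negative-binomial around their expectations, or an exact multinomial
#' split of `total_reads_per_sample` when `dispersion = 0`.
#'
#' @param config a [polysome_sim_config()].
#' @return list with `counts` (gene count table as consumed by
#'   [psr_analysis()]) and `truth` (per-gene data.frame: `gene_id`,
#'   `pi_wt`, `pi_mut`, `true_psr` = log2(pi_mut/pi_wt) exactly,
#'   `shifted`; plus the config echo and seed).
#' @export
generate_polysome_experiment <- function(config) {
  if (!inherits(config, "polysome_sim_config"))
    config <- do.call(polysome_sim_config, config)
  set.seed(config$seed)
  n <- config$n_genes
  lengths <- sample(seq(config$length_range[1], config$length_range[2]),
                    n, replace = TRUE)
  w <- stats::rlnorm(n, meanlog = 0, sdlog = 1)

  m <- config$pi_baseline_mean; s <- config$pi_baseline_sd
  pi_wt <- if (s == 0) rep(m, n) else
    pmin(pmax(stats::rnorm(n, m, s), 1e-3), 1 - 1e-3)

  n_shift <- round(config$shifted_fraction * n)
  shifted <- rep(FALSE, n)
  if (n_shift > 0) shifted[sample.int(n, n_shift)] <- TRUE
  pi_mut <- pi_wt
  if (n_shift > 0 && config$true_delta_psr != 0) {
    target <- pi_wt[shifted] * 2^config$true_delta_psr
    odds <- (pi_wt[shifted] / (1 - pi_wt[shifted])) * 2^config$true_delta_psr
    pi_mut[shifted] <- ifelse(target < 1 - 1e-6, target, odds / (1 + odds))
  }

  genotypes <- c(WT = "WT", NRS = "NRS")
  pis <- list(WT = pi_wt, NRS = pi_mut)
  counts <- data.frame(gene_id = sprintf("gene_%04d", seq_len(n)),
                       length = lengths, stringsAsFactors = FALSE)
  for (g in genotypes) {
    u <- pi_exact_abundance(w, pis[[g]])
    p_poly <- lengths * u * pis[[g]]
    p_sub <- lengths * u * (1 - pis[[g]])
    for (r in seq_len(config$n_replicates)) {
      counts[[sprintf("%s_poly_rep%d", g, r)]] <-
        draw_counts(p_poly, config$total_reads_per_sample, config$dispersion)
      counts[[sprintf("%s_sub_rep%d", g, r)]] <-
        draw_counts(p_sub, config$total_reads_per_sample, config$dispersion)
    }
  }

  truth <- list(
    genes = data.frame(
      gene_id = counts$gene_id,
      pi_wt = pi_wt, pi_mut = pi_mut,
      true_psr = log2(pi_mut / pi_wt),
      shifted = shifted, stringsAsFactors = FALSE
    ),
    config = config, seed = config$seed
  )
  list(counts = counts, truth = truth)
}
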