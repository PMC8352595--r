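# Independent oracles and tiny fixture builders used across the suite.

# O(T^2) discrete Fourier transform power, bins 0..floor(T/2).
brute_dft_power <- function(x) {
  T <- length(x)
  k <- 0:floor(T / 2)
  vapply(k, function(kk) {
    Mod(sum(x * exp(-2i * pi * kk * (0:(T - 1)) / T)))^2
  }, numeric(1))
}

# Two-sided Fisher exact p by exhaustive enumeration of all 2x2 tables
# with the observed margins (probability-ordering rule).
fisher_enum_p <- function(m) {
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  lo <- max(0, c1 - (n - r1)); hi <- min(r1, c1)
  probs <- dhyper(lo:hi, r1, n - r1, c1)
  p_obs <- dhyper(m[1, 1], r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Closed-form pooled-variance two-sample t-test (two-sided).
pooled_t_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / (n1 + n2 - 2)
  tt <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  2 * pt(-abs(tt), n1 + n2 - 2)
}

# Five-gene count table with two genotypes x two fractions x two reps.
small_count_table <- function() {
  set.seed(42)
  tbl <- data.frame(gene_id = paste0("g", 1:5),
                    length = c(1000L, 1500L, 800L, 2000L, 1200L))
  for (g in c("WT", "NRS")) for (f in c("poly", "sub")) {
    for (r in 1:2) {
      tbl[[sprintf("%s_%s_rep%d", g, f, r)]] <-
        as.integer(rpois(5, c(100, 300, 50, 400, 150)))
    }
  }
  tbl
}

# Noiseless single-frequency stack at an exact DFT bin.
sinusoid_stack <- function(freq = 20, acq = 250, T = 250, H = 8, W = 8,
                           amplitude = 50, baseline = 100,
                           mask = matrix(TRUE, H, W)) {
  cfg <- cilia_sim_config(height = H, width = W, n_frames = T,
                          acquisition_frequency = acq,
                          regions = list(cilia_region(mask, freq,
                                                      amplitude)),
                          baseline_intensity = baseline, noise_sd = 0,
                          seed = 1)
  generate_cilia_stack(cfg)
}
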