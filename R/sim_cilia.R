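#' Oscillating region for the cilia video simulator
#'
#' @param mask logical height x width matrix marking the region's pixels.
#' @param frequency oscillation frequency in Hz.
#' @param amplitude peak intensity amplitude (arbitrary units).
#' @param phase phase offset in radians.
#' @return list describing the region.
#' @export
cilia_region <- function(mask, frequency, amplitude, phase = 0) {
  stopifnot(is.logical(mask), is.matrix(mask))
  if (frequency <= 0) stop("region frequency must be > 0")
  if (amplitude < 0) stop("region amplitude must be >= 0")
  list(mask = mask, frequency = frequency, amplitude = amplitude,
       phase = phase)
}

#' Rectangular region mask helper
#'
#' @param height,width image dimensions in pixels.
#' @param rows,cols integer ranges of rows/columns inside the rectangle.
#' @return logical height x width matrix.
#' @export
rect_mask <- function(height, width, rows, cols) {
  m <- matrix(FALSE, height, width)
  m[rows, cols] <- TRUE
  m
}

#' Configuration for the cilia time-lapse simulator
#'
#' Defaults emulate a high-speed (250 Hz) acquisition of a beating
#' ciliary bundle: a 128 x 128 px field with one oscillating region over
#' a noisy static background, 8-bit camera output.
#'
#' @param height,width image size in pixels.
#' @param n_frames number of frames (>= 2).
#' @param acquisition_frequency frame rate in Hz.
#' @param regions list of [cilia_region()]s; every region frequency must
#'   lie strictly below the Nyquist frequency (acquisition/2).
#' @param baseline_intensity constant background intensity.
#' @param noise_sd SD of per-pixel Gaussian noise.
#' @param bit_depth 8 (default) or 16; intensities are clipped to the bit
#'   range and rounded to integers, matching camera quantisation.
#' @param seed integer seed.
#' @return validated config of class `cilia_sim_config`.
#' @export
cilia_sim_config <- function(height = 128, width = 128, n_frames = 512,
                             acquisition_frequency = 250,
                             regions = list(), baseline_intensity = 100,
                             noise_sd = 10, bit_depth = 8, seed = 1) {
  if (height < 1 || width < 1) stop("invalid image size")
  if (n_frames < 2) stop("invalid 'n_frames': need at least 2 frames")
  if (acquisition_frequency <= 0)
    stop("invalid 'acquisition_frequency': must be > 0")
  for (rg in regions) {
    stopifnot(is.list(rg), all(dim(rg$mask) == c(height, width)))
    if (rg$frequency >= acquisition_frequency / 2)
      stop("invalid region frequency ", rg$frequency,
           " Hz: must be below the Nyquist frequency (",
           acquisition_frequency / 2, " Hz)")
  }
  if (noise_sd < 0) stop("invalid 'noise_sd': must be >= 0")
  if (!bit_depth %in% c(8, 16)) stop("bit_depth must be 8 or 16")
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_frames = as.integer(n_frames),
                 acquisition_frequency = acquisition_frequency,
                 regions = regions,
                 baseline_intensity = baseline_intensity,
                 noise_sd = noise_sd, bit_depth = as.integer(bit_depth),
                 seed = as.integer(seed)),
            class = "cilia_sim_config")
}

#' Simulate a cilia time-lapse stack with known pixel frequencies
#'
#' Pixel (x, y) at frame k (k = 0, 1, ...) has intensity
#' baseline + sum over regions of amplitude * sin(2 pi f k / acq + phase)
#' over the region masks, plus Gaussian noise, clipped to the bit range
#' and rounded. Deterministic given the config seed.
#'
#' @param config a [cilia_sim_config()].
#' @return list with `stack` (a [time_lapse_stack()]) and `truth`
#'   (per-pixel `frequency_map` in Hz, 0 = non-oscillating; later regions
#'   overwrite earlier ones where masks overlap; plus the config echo and
#'   seed).
#' @export
generate_cilia_stack <- function(config) {
  stopifnot(inherits(config, "cilia_sim_config"))
  set.seed(config$seed)
  H <- config$height; W <- config$width; T <- config$n_frames
  tt <- (seq_len(T) - 1) / config$acquisition_frequency
  fr <- array(config$baseline_intensity, c(H, W, T))
  freq_map <- matrix(0, H, W)
  for (rg in config$regions) {
    wave <- rg$amplitude * sin(2 * pi * rg$frequency * tt + rg$phase)
    sel <- which(rg$mask)
    for (k in seq_len(T)) {
      slice <- fr[, , k]
      slice[sel] <- slice[sel] + wave[k]
      fr[, , k] <- slice
    }
    freq_map[rg$mask] <- rg$frequency
  }
  if (config$noise_sd > 0)
    fr <- fr + array(stats::rnorm(length(fr), 0, config$noise_sd), dim(fr))
  mx <- 2^config$bit_depth - 1
  fr <- round(pmin(pmax(fr, 0), mx))
  list(stack = time_lapse_stack(fr, config$acquisition_frequency,
                                config$bit_depth),
       truth = list(frequency_map = freq_map, config = config,
                    seed = config$seed))
}
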