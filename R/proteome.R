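#' Impute missing label-free intensities from a downshifted normal
#'
#' Replaces absent entries (NA, and optionally zeros) column by column
#' with draws from a normal distribution centred `downshift` column-SDs
#' below the column mean of the observed log-intensities, with SD
#' `width` times the column SD - the usual left-censored imputation for
#' label-free proteomics, where missingness concentrates near the
#' detection limit.
#'
#' The returned matrix is on the log2 scale throughout (observed entries
#' log2-transformed, imputed entries drawn on that scale); downstream
#' Z-normalisation operates on log intensities.
#'
#' @param matrix protein x sample intensity matrix, positive reals with
#'   NA for absent values.
#' @param width imputation SD as a fraction of the column SD (default
#'   0.3).
#' @param downshift centre shift in column SDs (default 1.8).
#' @param seed integer seed (imputation is stochastic).
#' @param zero_as_missing treat exact zeros as absent (default TRUE,
#'   matching exporters that write 0 for missing values).
#' @return log2-intensity matrix with no missing entries; attribute
#'   `imputed` is a logical matrix marking imputed cells.
#' @export
impute_missing <- function(matrix, width = 0.3, downshift = 1.8,
                           seed = 1, zero_as_missing = TRUE) {
  m <- as.matrix(matrix)
  if (zero_as_missing) m[!is.na(m) & m == 0] <- NA
  if (any(!is.na(m) & m <= 0)) stop("intensities must be positive")
  absent <- is.na(m)
  lg <- log2(m)
  set.seed(seed)
  for (j in seq_len(ncol(lg))) {
    obs <- lg[!absent[, j], j]
    if (length(obs) < 2)
      stop("column ", j, " has fewer than 2 observed values")
    nmiss <- sum(absent[, j])
    if (nmiss > 0) {
      mu <- mean(obs); sd <- stats::sd(obs)
      lg[absent[, j], j] <- stats::rnorm(nmiss, mu - downshift * sd,
                                         width * sd)
    }
  }
  attr(lg, "imputed") <- absent
  lg
}

#' Row-wise Z-score normalisation
#'
#' Each protein's profile is centred to mean 0 and scaled to unit sample
#' SD (denominator n - 1). Constant rows become all-zero profiles and
#' are flagged rather than producing NaN.
#'
#' @param matrix protein x sample matrix (log intensities).
#' @return Z-profile matrix; attribute `flagged` is a logical vector
#'   marking constant rows.
#' @export
z_normalize <- function(matrix) {
  m <- as.matrix(matrix)
  if (ncol(m) < 2) stop("need at least 2 samples per row")
  mu <- rowMeans(m)
  sd <- apply(m, 1, stats::sd)
  flagged <- sd == 0 | !is.finite(sd)
  sd[flagged] <- 1
  z <- (m - mu) / sd
  z[flagged, ] <- 0
  attr(z, "flagged") <- unname(flagged)
  z
}

#' Subset a protein matrix by a GO-term substring
#'
#' Retains proteins whose concatenated GO annotation strings contain the
#' term as a case-insensitive substring (so `"cilia"` also matches
#' `"ciliary basal body"`). Proteins without annotations are treated as
#' having no terms and dropped.
#'
#' @param matrix protein x sample matrix with protein ids as rownames.
#' @param annotations data.frame with columns `protein_id` and
#'   `go_terms`.
#' @param term substring to match (default `"cilia"`).
#' @return the retained sub-matrix.
#' @export
go_subset <- function(matrix, annotations, term = "cilia") {
  m <- as.matrix(matrix)
  if (is.null(rownames(m))) stop("matrix needs protein ids as rownames")
  stopifnot(all(c("protein_id", "go_terms") %in% colnames(annotations)))
  terms <- annotations$go_terms[match(rownames(m),
                                      annotations$protein_id)]
  terms[is.na(terms)] <- ""
  keep <- grepl(tolower(term), tolower(terms), fixed = TRUE)
  m[keep, , drop = FALSE]
}

#' Label proteins as matching or deviating from the group trajectory
#'
#' The group mean trajectory is the per-stage mean of the Z-profiles;
#' each protein is labelled `match` if its Pearson correlation with that
#' mean reaches `r_threshold`, otherwise `deviate`. Proteins with a
#' constant profile have undefined correlation and are labelled
#' `deviate` with a flag.
#'
#' @param zmatrix protein x stage matrix of Z-profiles (>= 2 proteins,
#'   >= 3 stages).
#' @param r_threshold correlation threshold for `match` (default 0.8).
#' @return data.frame with `protein_id`, `r`, `label`, `flagged`;
#'   attribute `mean_trajectory` holds the group mean profile.
#' @export
trajectory_match <- function(zmatrix, r_threshold = 0.8) {
  m <- as.matrix(zmatrix)
  if (nrow(m) < 2) stop("need at least 2 proteins")
  if (ncol(m) < 3) stop("need at least 3 stages")
  mean_traj <- colMeans(m)
  r <- suppressWarnings(apply(m, 1, stats::cor, y = mean_traj))
  flagged <- !is.finite(r)
  label <- ifelse(!flagged & r >= r_threshold, "match", "deviate")
  out <- data.frame(
    protein_id = if (is.null(rownames(m))) as.character(seq_len(nrow(m)))
                 else rownames(m),
    r = unname(r), label = label, flagged = unname(flagged),
    stringsAsFactors = FALSE
  )
  attr(out, "mean_trajectory") <- mean_traj
  out
}
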