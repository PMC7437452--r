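#' Z'-factor of a plate's control window
#'
#' The screening-window coefficient
#' `Z' = 1 - (3*sigma_hc + 3*sigma_lc) / (mu_hc - mu_lc)`.
#' A value above 0.5 indicates an excellent assay window; Z' never exceeds 1
#' and equals 1 only when both control groups have zero variance.
#'
#' @param mu_hc,mu_lc means of the high- and low-control signal.
#' @param sigma_hc,sigma_lc standard deviations of the two control groups.
#' @return Dimensionless Z'-factor.
#' @examples
#' compute_zprime(100, 0, 5, 5)  # 0.70
#' @export
compute_zprime <- function(mu_hc, mu_lc, sigma_hc, sigma_lc) {
  if (any(mu_hc == mu_lc)) {
    stop("undefined Z': mu_hc equals mu_lc", call. = FALSE)
  }
  1 - (3 * sigma_hc + 3 * sigma_lc) / (mu_hc - mu_lc)
}

#' Signal-to-background ratio
#'
#' `S/B = mu_hc / mu_lc`, the fold change of the stimulated over the
#' unstimulated control signal.
#'
#' @param mu_hc,mu_lc means of the high- and low-control signal;
#'   `mu_lc` must be nonzero.
#' @return Dimensionless S/B ratio.
#' @export
compute_sb <- function(mu_hc, mu_lc) {
  if (any(mu_lc == 0)) stop("undefined S/B: mu_lc is 0", call. = FALSE)
  mu_hc / mu_lc
}

#' Coefficient of variation of replicate measurements
#'
#' `CV = 100 * SD / mean` with the n-1 SD denominator, in percent.
#'
#' @param values numeric replicate measurements, length >= 2, nonzero mean.
#' @return CV in percent.
#' @export
compute_cv <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("CV needs >= 2 values", call. = FALSE)
  m <- mean(values)
  if (m == 0) stop("undefined CV: mean is 0", call. = FALSE)
  100 * stats::sd(values) / m
}

#' Per-plate quality control from raw control summaries
#'
#' Computes the Z'-factor and S/B ratio of each plate/analyte from the
#' UNCLEANED control statistics (outlier exclusion is applied for
#' normalization but not for QC) and gates each plate at a Z' threshold
#' with strict inequality (`pass = z_prime > threshold`). Plates with a
#' degenerate control window get `pass = FALSE` and an `error` flag rather
#' than being dropped; excluding failing plates is a pipeline-level choice.
#'
#' @param controls control-summary data.frame from [normalize_screen()]
#'   (one row per plate and analyte, with `mu_hc_raw`, `sigma_hc_raw`,
#'   `mu_lc_raw`, `sigma_lc_raw`).
#' @param threshold Z' pass cutoff; default 0.5.
#' @return A data.frame with `plate_id`, `analyte`, `z_prime`, `sb_ratio`,
#'   `n_hc`, `n_lc`, `pass`, `error`.
#' @export
qc_plate <- function(controls, threshold = 0.5) {
  n <- nrow(controls)
  z <- rep(NA_real_, n)
  sb <- rep(NA_real_, n)
  err <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (controls$mu_hc_raw[i] == controls$mu_lc_raw[i]) {
      err[i] <- TRUE
      next
    }
    z[i] <- compute_zprime(controls$mu_hc_raw[i], controls$mu_lc_raw[i],
                           controls$sigma_hc_raw[i], controls$sigma_lc_raw[i])
    sb[i] <- if (controls$mu_lc_raw[i] != 0) {
      compute_sb(controls$mu_hc_raw[i], controls$mu_lc_raw[i])
    } else NA_real_
  }
  data.frame(
    plate_id = controls$plate_id, analyte = controls$analyte,
    z_prime = z, sb_ratio = sb,
    n_hc = controls$n_hc_raw, n_lc = controls$n_lc_raw,
    pass = !err & !is.na(z) & z > threshold, error = err,
    stringsAsFactors = FALSE
  )
}
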