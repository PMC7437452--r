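#' HTRF ratio from the two emission channels
#'
#' The assay signal is the acceptor/donor emission ratio scaled by 10^4:
#' `10000 * em665 / em620`. The donor channel must be strictly positive;
#' a zero donor reading makes the ratio undefined and raises an error
#' (callers working plate-wise drop such wells with a warning instead, see
#' [normalize_plate()]).
#'
#' @param em665 acceptor-channel counts (665 nm), >= 0.
#' @param em620 donor-channel counts (620 nm), > 0.
#' @return Numeric vector of dimensionless HTRF ratios.
#' @examples
#' htrf_ratio(1000, 10000)  # 1000
#' @export
htrf_ratio <- function(em665, em620) {
  if (any(!is.finite(em620)) || any(em620 <= 0)) {
    stop("undefined HTRF ratio: em620 must be > 0", call. = FALSE)
  }
  if (any(!is.finite(em665)) || any(em665 < 0)) {
    stop("em665 must be >= 0", call. = FALSE)
  }
  10000 * em665 / em620
}

#' Summarize control wells of one plate and analyte
#'
#' Computes the mean and standard deviation (n-1 denominator) of control
#' HTRF ratios. With `exclude_outliers = TRUE` a single pass is applied:
#' mean and SD are computed on all values, values falling outside
#' mean +/- 3SD are excluded as outliers, and the statistics are recomputed
#' on the remainder. The uncleaned statistics (`exclude_outliers = FALSE`)
#' are the ones used for Z'-factor and S/B computation; the cleaned ones
#' anchor percent-inhibition normalization.
#'
#' @param values numeric control ratios, length >= 2.
#' @param wells optional well labels parallel to `values`, used to report
#'   which wells were excluded.
#' @param exclude_outliers apply the single-pass mean +/- 3SD rule.
#' @return A list with `mu`, `sigma`, `n`, `outlier_wells` (character),
#'   `outlier_idx` (integer positions excluded) and `cleaned` (logical).
#' @export
summarize_controls <- function(values, wells = NULL, exclude_outliers = TRUE) {
  values <- as.numeric(values)
  if (length(values) < 2L || any(!is.finite(values))) {
    stop("insufficient controls: need >= 2 finite control values",
         call. = FALSE)
  }
  if (is.null(wells)) wells <- as.character(seq_along(values))
  mu <- mean(values)
  sigma <- stats::sd(values)
  out_idx <- integer(0)
  if (exclude_outliers && sigma > 0) {
    out_idx <- which(values < mu - 3 * sigma | values > mu + 3 * sigma)
    if (length(out_idx) > 0L) {
      keep <- values[-out_idx]
      if (length(keep) < 2L) {
        stop("insufficient controls after outlier exclusion", call. = FALSE)
      }
      mu <- mean(keep)
      sigma <- stats::sd(keep)
    }
  }
  list(mu = mu, sigma = sigma,
       n = length(values) - length(out_idx),
       outlier_wells = wells[out_idx], outlier_idx = out_idx,
       cleaned = exclude_outliers)
}

#' Percent inhibition of a well relative to the plate's DMSO controls
#'
#' Linear rescaling that maps the mean high-control (stimulated, vehicle)
#' ratio to 0% and the mean low-control (unstimulated) ratio to 100%:
#' `100 * (mu_hc - x) / (mu_hc - mu_lc)`. Values below the high control
#' (secretion enhancement) come out negative.
#'
#' @param x well HTRF ratio(s).
#' @param mu_hc mean high-control ratio.
#' @param mu_lc mean low-control ratio; must differ from `mu_hc`.
#' @return Percent inhibition (numeric, same length as `x`).
#' @export
percent_inhibition <- function(x, mu_hc, mu_lc) {
  if (!is.finite(mu_hc) || !is.finite(mu_lc) || mu_hc == mu_lc) {
    stop("degenerate control window: mu_hc must differ from mu_lc",
         call. = FALSE)
  }
  100 * (mu_hc - x) / (mu_hc - mu_lc)
}

# Control summaries (cleaned and raw) for one plate+analyte as a one-row
# data.frame; `sub` holds that plate/analyte's measurements with ratios.
summarize_plate_controls <- function(sub, plate_id, analyte) {
  hc <- sub[sub$role == "high_control", ]
  lc <- sub[sub$role == "low_control", ]
  if (nrow(hc) < 2L || nrow(lc) < 2L) {
    stop(sprintf("plate %s (%s): fewer than 2 control wells per group",
                 plate_id, analyte), call. = FALSE)
  }
  cl_hc <- summarize_controls(hc$ratio, hc$well, exclude_outliers = TRUE)
  cl_lc <- summarize_controls(lc$ratio, lc$well, exclude_outliers = TRUE)
  raw_hc <- summarize_controls(hc$ratio, hc$well, exclude_outliers = FALSE)
  raw_lc <- summarize_controls(lc$ratio, lc$well, exclude_outliers = FALSE)
  data.frame(
    plate_id = plate_id, analyte = analyte,
    mu_hc = cl_hc$mu, sigma_hc = cl_hc$sigma, n_hc = cl_hc$n,
    mu_lc = cl_lc$mu, sigma_lc = cl_lc$sigma, n_lc = cl_lc$n,
    mu_hc_raw = raw_hc$mu, sigma_hc_raw = raw_hc$sigma,
    mu_lc_raw = raw_lc$mu, sigma_lc_raw = raw_lc$sigma,
    n_hc_raw = length(hc$ratio), n_lc_raw = length(lc$ratio),
    outlier_wells = paste(c(cl_hc$outlier_wells, cl_lc$outlier_wells),
                          collapse = ";"),
    window_ok = cl_hc$mu > cl_lc$mu,
    stringsAsFactors = FALSE
  )
}

#' Normalize one plate and analyte to percent inhibition
#'
#' Converts raw emissions of one plate/analyte to HTRF ratios, summarizes
#' its own high and low controls (outlier-cleaned for normalization, raw
#' in parallel for QC), and expresses every compound well as percent
#' inhibition anchored to those same-plate controls. Wells with a zero
#' donor channel are dropped with a warning. Control and empty wells yield
#' no activity record.
#'
#' @param measurements data.frame of well measurements (see
#'   [read_well_table()]) restricted to one `plate_id` and one `analyte`.
#' @return A list with `activity` (one row per compound well: `compound_id`,
#'   `plate_id`, `well`, `analyte`, `concentration_uM`, `htrf_ratio`,
#'   `percent_inhibition`) and `controls` (a one-row control-summary
#'   data.frame carrying cleaned and raw statistics).
#' @export
normalize_plate <- function(measurements) {
  stopifnot(length(unique(measurements$plate_id)) == 1L,
            length(unique(measurements$analyte)) == 1L)
  plate_id <- measurements$plate_id[1]
  analyte <- measurements$analyte[1]
  drop <- which(measurements$em620 <= 0)
  if (length(drop) > 0L) {
    warning(sprintf("plate %s (%s): dropping %d well(s) with em620=0: %s",
                    plate_id, analyte, length(drop),
                    paste(measurements$well[drop], collapse = ", ")))
    measurements <- measurements[-drop, ]
  }
  measurements$ratio <- htrf_ratio(measurements$em665, measurements$em620)
  ctrl <- summarize_plate_controls(measurements, plate_id, analyte)
  cmp <- measurements[measurements$role == "compound", ]
  activity <- data.frame(
    compound_id = cmp$compound_id,
    plate_id = rep(plate_id, nrow(cmp)), well = cmp$well,
    analyte = rep(analyte, nrow(cmp)),
    concentration_uM = cmp$concentration_uM,
    htrf_ratio = cmp$ratio,
    percent_inhibition = if (nrow(cmp) > 0) {
      percent_inhibition(cmp$ratio, ctrl$mu_hc, ctrl$mu_lc)
    } else numeric(0),
    stringsAsFactors = FALSE
  )
  list(activity = activity, controls = ctrl)
}

#' Normalize a whole screen plate by plate
#'
#' Applies [normalize_plate()] to every (plate, analyte) stratum of a
#' well-measurement table.
#'
#' @param wells data.frame of well measurements for any number of plates
#'   and both analytes.
#' @return A list with `activity` (all compound-well activities) and
#'   `controls` (one control-summary row per plate and analyte).
#' @export
normalize_screen <- function(wells) {
  strata <- unique(wells[c("plate_id", "analyte")])
  acts <- vector("list", nrow(strata))
  ctrls <- vector("list", nrow(strata))
  for (i in seq_len(nrow(strata))) {
    sub <- wells[wells$plate_id == strata$plate_id[i] &
                   wells$analyte == strata$analyte[i], ]
    res <- normalize_plate(sub)
    acts[[i]] <- res$activity
    ctrls[[i]] <- res$controls
  }
  list(activity = do.call(rbind, acts), controls = do.call(rbind, ctrls))
}
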