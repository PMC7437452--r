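#' Default assay calibration of the simulator
#'
#' Per-analyte control distributions of the HTRF ratio, chosen so the
#' closed-form plate statistics match the screen this package models:
#' IL-1beta `mu_hc = 8980`, `mu_lc = 1000`, `sigma_hc = 450`,
#' `sigma_lc = 160` (population Z' = 1 - 3*610/7980 = 0.7707, S/B = 8.98);
#' IL-6 `mu_hc = 4290`, `mu_lc = 1000`, `sigma_hc = 430`, `sigma_lc = 150`
#' (population Z' = 1 - 3*580/3290 = 0.4711, S/B = 4.29).
#'
#' @return Named list of per-analyte parameter lists (`IL1B`, `IL6`), each
#'   with `mu_hc`, `mu_lc`, `sigma_hc`, `sigma_lc`.
#' @export
default_calibration <- function() {
  list(
    IL1B = list(mu_hc = 8980, mu_lc = 1000, sigma_hc = 450, sigma_lc = 160),
    IL6 = list(mu_hc = 4290, mu_lc = 1000, sigma_hc = 430, sigma_lc = 150)
  )
}

EFFECT_CLASSES <- c("inactive", "selective_inhibitor",
                    "nonspecific_inhibitor", "enhancer", "cytotoxic")

#' Simulation configuration
#'
#' Describes a synthetic screen: plate count and geometry, control counts,
#' compound count, per-analyte control distributions of the HTRF ratio,
#' the mixture of compound effect classes, the potency distribution of
#' active compounds, and the donor-channel distribution used to decompose
#' ratios into emission pairs.
#'
#' Effect classes: `inactive` (no effect on either cytokine),
#' `selective_inhibitor` (inhibits IL-1beta only, Hill-1 curve at a
#' log-uniform IC50 from `potency_range`), `nonspecific_inhibitor` (same
#' curve applied to both cytokines), `enhancer` (fractional effect -0.5 on
#' both, i.e. secretion increased), `cytotoxic` (apparent fractional
#' inhibition 0.9 of both).
#'
#' @param n_plates number of 384-well plates; default 16.
#' @param n_compounds number of distinct compounds; default 4825. Must fit
#'   the compound capacity `n_plates * (384 - 2*controls_per_plate)`.
#' @param controls_per_plate high (= low) controls per plate; default 16.
#' @param analyte_params per-analyte control distributions; default
#'   [default_calibration()].
#' @param effect_mix named proportions over the five effect classes,
#'   summing to 1.
#' @param class_counts optional named integer vector fixing the exact count
#'   of one or more classes (e.g. `c(selective_inhibitor = 50)`); the
#'   remaining compounds are shared among the unfixed classes in proportion
#'   to `effect_mix`.
#' @param assignment `"random"` (multinomial draw from `effect_mix`) or
#'   `"deterministic"` (exact expected counts, largest-remainder rounding);
#'   fixed `class_counts` are always exact.
#' @param potency_range log-uniform IC50 range in uM for active compounds;
#'   default `c(0.01, 0.6)`, i.e. true 1-uM fractional inhibition between
#'   0.625 and ~0.99.
#' @param screening_dose compound concentration in the primary screen, uM.
#' @param em620_mean,em620_sd donor-channel count distribution (truncated
#'   at > 0); defaults 10000 / 500.
#' @param noise_scale multiplier on all ratio-scale noise SDs (0 gives a
#'   noiseless screen); default 1.
#' @return An object of class `"sim_config"` (a named list).
#' @export
simulation_config <- function(n_plates = 16L,
                              n_compounds = 4825L,
                              controls_per_plate = 16L,
                              analyte_params = default_calibration(),
                              effect_mix = c(inactive = 0.94,
                                             selective_inhibitor = 0.01,
                                             nonspecific_inhibitor = 0.02,
                                             enhancer = 0.01,
                                             cytotoxic = 0.02),
                              class_counts = NULL,
                              assignment = c("random", "deterministic"),
                              potency_range = c(0.01, 0.6),
                              screening_dose = 1,
                              em620_mean = 10000,
                              em620_sd = 500,
                              noise_scale = 1) {
  assignment <- match.arg(assignment)
  if (!setequal(names(effect_mix), EFFECT_CLASSES)) {
    stop("effect_mix must name exactly the classes: ",
         paste(EFFECT_CLASSES, collapse = ", "), call. = FALSE)
  }
  if (abs(sum(effect_mix) - 1) > 1e-8) {
    stop("effect_mix proportions must sum to 1 (got ",
         signif(sum(effect_mix), 6), ")", call. = FALSE)
  }
  if (!is.null(class_counts)) {
    if (!all(names(class_counts) %in% EFFECT_CLASSES) ||
        sum(class_counts) > n_compounds) {
      stop("class_counts must name known classes and fit n_compounds",
           call. = FALSE)
    }
  }
  capacity <- n_plates * (384L - 2L * controls_per_plate)
  if (n_compounds > capacity) {
    stop(sprintf("n_compounds (%d) exceeds plate capacity (%d wells)",
                 n_compounds, capacity), call. = FALSE)
  }
  for (p in analyte_params) {
    stopifnot(p$sigma_hc >= 0, p$sigma_lc >= 0, p$mu_hc > p$mu_lc)
  }
  stopifnot(length(potency_range) == 2L, all(potency_range > 0),
            potency_range[1] <= potency_range[2], screening_dose > 0,
            noise_scale >= 0)
  cfg <- list(n_plates = as.integer(n_plates),
              n_compounds = as.integer(n_compounds),
              controls_per_plate = as.integer(controls_per_plate),
              analyte_params = analyte_params,
              effect_mix = effect_mix[EFFECT_CLASSES],
              class_counts = class_counts,
              assignment = assignment,
              potency_range = potency_range,
              screening_dose = screening_dose,
              em620_mean = em620_mean, em620_sd = em620_sd,
              noise_scale = noise_scale)
  class(cfg) <- "sim_config"
  cfg
}

# Exact class counts under largest-remainder rounding of the proportions.
deterministic_counts <- function(prop, n) {
  raw <- prop * n
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    o <- order(raw - cnt, decreasing = TRUE)
    cnt[o[seq_len(rem)]] <- cnt[o[seq_len(rem)]] + 1L
  }
  as.integer(cnt)
}

# Draw effect classes for all compounds, honoring fixed class_counts.
draw_effect_classes <- function(config) {
  n <- config$n_compounds
  fixed <- config$class_counts
  cls <- character(0)
  if (!is.null(fixed)) {
    cls <- rep(names(fixed), times = fixed)
  }
  n_free <- n - length(cls)
  if (n_free > 0L) {
    free_classes <- setdiff(EFFECT_CLASSES, names(fixed))
    prop <- config$effect_mix[free_classes]
    prop <- prop / sum(prop)
    if (config$assignment == "deterministic") {
      cnt <- deterministic_counts(prop, n_free)
      cls <- c(cls, rep(free_classes, times = cnt))
    } else {
      cls <- c(cls, sample(free_classes, n_free, replace = TRUE,
                           prob = prop))
    }
  }
  sample(cls)  # shuffle positions across plates
}

# Ground truth per compound: effect class, true IC50s, and the true
# fractional effect on each cytokine at the screening dose.
make_truth <- function(config) {
  n <- config$n_compounds
  cls <- draw_effect_classes(config)
  lo <- log10(config$potency_range[1])
  hi <- log10(config$potency_range[2])
  ic50 <- 10^stats::runif(n, lo, hi)
  d <- config$screening_dose
  f_hill <- d / (d + ic50)  # hill = 1, full efficacy

  f1 <- numeric(n)
  f6 <- numeric(n)
  ic1 <- rep(NA_real_, n)
  ic6 <- rep(NA_real_, n)
  sel <- cls == "selective_inhibitor"
  f1[sel] <- f_hill[sel]; ic1[sel] <- ic50[sel]
  non <- cls == "nonspecific_inhibitor"
  f1[non] <- f_hill[non]; f6[non] <- f_hill[non]
  ic1[non] <- ic50[non]; ic6[non] <- ic50[non]
  f1[cls == "enhancer"] <- -0.5; f6[cls == "enhancer"] <- -0.5
  f1[cls == "cytotoxic"] <- 0.9; f6[cls == "cytotoxic"] <- 0.9

  data.frame(compound_id = sprintf("CMP%05d", seq_len(n)),
             effect_class = cls,
             true_ic50_il1b = ic1, true_ic50_il6 = ic6,
             true_inhibition_il1b = 100 * f1,
             true_inhibition_il6 = 100 * f6,
             stringsAsFactors = FALSE)
}

# Plate map for the whole screen: columns 1-22 hold compounds filled
# sequentially by compound id, column 23 the 16 high and column 24 the 16
# low controls; unfilled compound wells are role=empty. The layout is
# emitted in (and read back from) the map, never assumed downstream.
make_plate_map <- function(config, truth) {
  n_ctrl <- config$controls_per_plate
  cap <- 384L - 2L * n_ctrl
  maps <- vector("list", config$n_plates)
  next_cmp <- 1L
  for (p in seq_len(config$n_plates)) {
    pid <- sprintf("P%02d", p)
    cmp_cols <- seq_len(cap / 16L)  # 22 columns of compound wells
    wells <- as.vector(outer(PLATE_ROWS, cmp_cols, paste0))
    k <- min(cap, config$n_compounds - next_cmp + 1L)
    k <- max(k, 0L)
    role <- rep("empty", cap)
    cid <- rep(NA_character_, cap)
    conc <- rep(NA_real_, cap)
    if (k > 0L) {
      role[seq_len(k)] <- "compound"
      cid[seq_len(k)] <- truth$compound_id[next_cmp:(next_cmp + k - 1L)]
      conc[seq_len(k)] <- config$screening_dose
      next_cmp <- next_cmp + k
    }
    hc_wells <- paste0(PLATE_ROWS[seq_len(n_ctrl)], 23L)
    lc_wells <- paste0(PLATE_ROWS[seq_len(n_ctrl)], 24L)
    maps[[p]] <- data.frame(
      plate_id = pid,
      well = c(wells, hc_wells, lc_wells),
      role = c(role, rep("high_control", n_ctrl),
               rep("low_control", n_ctrl)),
      compound_id = c(cid, rep(NA_character_, 2L * n_ctrl)),
      concentration_uM = c(conc, rep(NA_real_, 2L * n_ctrl)),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, maps)
}

rnorm_pos <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  while (any(x <= 0)) {
    bad <- x <= 0
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  x
}

#' Simulate a full two-cytokine screen with known ground truth
#'
#' Generates raw two-channel well measurements for every well of every
#' plate and both analytes. For a well whose compound has true fractional
#' inhibition `f` of the analyte (f = 0 for high controls and inactive
#' compounds, f = 1 for low controls), the target HTRF ratio is
#' `mu_lc + (1 - f) * (mu_hc - mu_lc) + Normal(0, sigma_well)`, where
#' `sigma_well` interpolates linearly between `sigma_lc` (at f = 1) and
#' `sigma_hc` (at f = 0) and is scaled by `noise_scale`. The donor channel
#' is drawn as `em620 ~ Normal(em620_mean, em620_sd)` truncated positive
#' and the acceptor channel set to `em665 = ratio * em620 / 10000`, so
#' [htrf_ratio()] recovers the target ratio exactly. Output is
#' deterministic under a fixed seed.
#'
#' @param config a [simulation_config()].
#' @param seed integer seed governing all draws.
#' @return A list with `wells` (raw measurement table in the
#'   [read_well_table()] schema), `map` (plate map), `annotations`
#'   (singleton, non-steroid annotations for every compound), `truth`
#'   (per-compound ground truth) and `config`.
#' @export
simulate_screen <- function(config = simulation_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(as.integer(seed))
  truth <- make_truth(config)
  map <- make_plate_map(config, truth)

  # fractional effect per map row per analyte
  f_by_role <- function(frac_cmp) {
    f <- numeric(nrow(map))
    f[map$role == "high_control"] <- 0
    f[map$role == "low_control"] <- 1
    f[map$role == "empty"] <- 1  # no cells: background signal only
    i <- map$role == "compound"
    f[i] <- frac_cmp[match(map$compound_id[i], truth$compound_id)]
    f
  }
  fr <- list(IL1B = f_by_role(truth$true_inhibition_il1b / 100),
             IL6 = f_by_role(truth$true_inhibition_il6 / 100))

  out <- vector("list", 2L)
  for (a in seq_along(ANALYTES)) {
    an <- ANALYTES[a]
    p <- config$analyte_params[[an]]
    f <- fr[[an]]
    mu <- p$mu_lc + (1 - f) * (p$mu_hc - p$mu_lc)
    w <- pmin(pmax(1 - f, 0), 1)
    sigma <- (p$sigma_lc + w * (p$sigma_hc - p$sigma_lc)) *
      config$noise_scale
    ratio <- mu + stats::rnorm(nrow(map), 0, 1) * sigma
    ratio <- pmax(ratio, 1e-6)
    em620 <- if (config$em620_sd > 0) {
      rnorm_pos(nrow(map), config$em620_mean, config$em620_sd)
    } else rep(config$em620_mean, nrow(map))
    out[[a]] <- data.frame(
      plate_id = map$plate_id, well = map$well, role = map$role,
      compound_id = map$compound_id,
      concentration_uM = map$concentration_uM,
      analyte = an, em620 = em620, em665 = ratio * em620 / 10000,
      stringsAsFactors = FALSE
    )
  }
  wells <- do.call(rbind, out)
  rownames(wells) <- NULL
  annotations <- data.frame(compound_id = truth$compound_id,
                            library = "SYNTHETIC",
                            duplicate_group = NA_character_,
                            is_steroid = FALSE, stringsAsFactors = FALSE)
  list(wells = wells, map = map, annotations = annotations, truth = truth,
       config = config)
}

#' Simulate confirmation dose-response data from ground truth
#'
#' For every compound in `truth`, draws replicate percent-inhibition
#' responses for both analytes on a shared dose grid. Inhibitor classes
#' respond along the Hill-1 curve `100 * d / (d + IC50)` of their true
#' IC50 (selective inhibitors only on IL-1beta); enhancers sit at -50% and
#' cytotoxic compounds at 90% on both analytes; inactive compounds at 0%.
#' Gaussian noise with SD `noise_sd` percentage points is added per well.
#'
#' @param truth ground-truth data.frame from [simulate_screen()] (or any
#'   subset of its rows).
#' @param doses dose grid in uM; default five half-log doses 0.1-10.
#' @param replicates wells per dose; default 4.
#' @param noise_sd response noise SD in percentage points; default 10.
#' @param seed integer seed.
#' @return A data.frame with `compound_id`, `analyte`, `concentration_uM`,
#'   `replicate`, `percent_inhibition`.
#' @export
simulate_dose_response <- function(truth, doses = 10^seq(-1, 1, by = 0.5),
                                   replicates = 4L, noise_sd = 10,
                                   seed = 1L) {
  stopifnot(all(doses > 0), replicates >= 1L, noise_sd >= 0)
  set.seed(as.integer(seed))
  grid <- expand.grid(replicate = seq_len(replicates),
                      concentration_uM = doses,
                      analyte = ANALYTES,
                      compound_id = truth$compound_id,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  i <- match(grid$compound_id, truth$compound_id)
  cls <- truth$effect_class[i]
  ic50 <- ifelse(grid$analyte == "IL1B", truth$true_ic50_il1b[i],
                 truth$true_ic50_il6[i])
  d <- grid$concentration_uM
  mean_resp <- numeric(nrow(grid))
  inh <- cls %in% c("selective_inhibitor", "nonspecific_inhibitor") &
    !is.na(ic50)
  mean_resp[inh] <- 100 * d[inh] / (d[inh] + ic50[inh])
  mean_resp[cls == "enhancer"] <- -50
  mean_resp[cls == "cytotoxic"] <- 90
  grid$percent_inhibition <- mean_resp +
    stats::rnorm(nrow(grid), 0, noise_sd)
  grid[c("compound_id", "analyte", "concentration_uM", "replicate",
         "percent_inhibition")]
}
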