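#' Run the primary-screen analysis end to end
#'
#' Normalizes every plate and analyte (ratios, control summaries, percent
#' inhibition), computes per-plate QC, applies the primary triage cascade,
#' and optionally writes all result tables plus a JSON run manifest. When
#' `config$exclude_failing_plates` is set, compounds residing on a plate
#' whose IL-1beta or IL-6 Z' fails the gate are removed before triage
#' (with a message); by default failing plates are flagged in the QC table
#' but analysed.
#'
#' The written scatter file holds the per-compound (IL-1beta%, IL-6%) pairs
#' clipped to [-100, 100] for display; the triage table keeps the
#' unclipped values and all decisions are made on unclipped values.
#'
#' @param wells raw well-measurement table (see [read_well_table()]).
#' @param map plate map; used to validate control counts.
#' @param annotations optional compound annotations.
#' @param config a [screen_config()].
#' @param out_dir optional output directory; when given, tables and a
#'   manifest are written there.
#' @param inputs optional named character vector of input file paths,
#'   digested into the manifest.
#' @return A list with `activity`, `controls`, `qc`, `outcomes`, `counts`,
#'   `scatter` and (when written) `manifest`.
#' @export
run_screen <- function(wells, map = NULL, annotations = NULL,
                       config = screen_config(), out_dir = NULL,
                       inputs = NULL) {
  if (!is.null(map)) validate_plate_map(map, config$controls_per_plate)
  norm <- normalize_screen(wells)
  qc <- qc_plate(norm$controls, config$zprime_threshold)

  activity <- norm$activity
  if (config$exclude_failing_plates) {
    bad_plates <- unique(qc$plate_id[!qc$pass])
    if (length(bad_plates) > 0L) {
      message("excluding ", length(bad_plates),
              " QC-failing plate(s): ", paste(bad_plates, collapse = ", "))
      activity <- activity[!activity$plate_id %in% bad_plates, ]
    }
  }
  triage <- triage_primary(activity, annotations, config)
  pairs <- activity_pairs(activity)
  scatter <- data.frame(
    compound_id = pairs$compound_id,
    il1b_percent = pmin(pmax(pairs$il1b, -100), 100),
    il6_percent = pmin(pmax(pairs$il6, -100), 100),
    stringsAsFactors = FALSE
  )
  res <- list(activity = activity, controls = norm$controls, qc = qc,
              outcomes = triage$outcomes, counts = triage$counts,
              scatter = scatter)
  if (!is.null(out_dir)) {
    tables <- list(activity = activity, controls = norm$controls, qc = qc,
                   triage = triage$outcomes, cascade = triage$counts,
                   scatter = scatter)
    res$manifest <- write_run(tables, out_dir, config, inputs,
                              stage_counts = triage$counts)
  }
  res
}

#' Run the confirmation screen on dose-response data
#'
#' Fits the 4PL model per compound and analyte, derives per-dose
#' IL-1beta-predominance calls, and classifies each compound as
#' `confirmed_hit`, `rejected_ic50` or `rejected_predominance` under the
#' configured rules.
#'
#' @param dr data.frame of dose-response observations: `compound_id`,
#'   `analyte`, `concentration_uM`, `percent_inhibition` (replicate rows
#'   allowed; see [simulate_dose_response()]).
#' @param config a [screen_config()].
#' @param out_dir optional output directory for tables and manifest.
#' @param inputs optional named input paths digested into the manifest.
#' @return A list with `fits` (per compound/analyte 4PL parameter table),
#'   `predominance` (per compound/dose calls), `outcomes` (confirmation
#'   calls), `counts` and (when written) `manifest`.
#' @export
run_confirm <- function(dr, config = screen_config(), out_dir = NULL,
                        inputs = NULL) {
  stopifnot(all(c("compound_id", "analyte", "concentration_uM",
                  "percent_inhibition") %in% names(dr)))
  ids <- unique(dr$compound_id)
  fit_rows <- vector("list", 2L * length(ids))
  pred_rows <- vector("list", length(ids))
  conf_rows <- vector("list", length(ids))
  k <- 0L
  for (j in seq_along(ids)) {
    id <- ids[j]
    sub <- dr[dr$compound_id == id, ]
    a1 <- sub[sub$analyte == "IL1B", ]
    a6 <- sub[sub$analyte == "IL6", ]
    if (nrow(a1) == 0L || nrow(a6) == 0L) {
      stop("incomplete dose-response data for compound ", id,
           call. = FALSE)
    }
    f1 <- fit_4pl(a1$concentration_uM, a1$percent_inhibition)
    f6 <- fit_4pl(a6$concentration_uM, a6$percent_inhibition)
    for (ft in list(list(an = "IL1B", f = f1), list(an = "IL6", f = f6))) {
      k <- k + 1L
      fit_rows[[k]] <- data.frame(
        compound_id = id, analyte = ft$an, ic50_uM = ft$f$ic50,
        hill = ft$f$hill, top = ft$f$top, bottom = ft$f$bottom,
        converged = ft$f$converged, method = ft$f$method,
        stringsAsFactors = FALSE)
    }
    pr <- assess_predominance(a1$concentration_uM, a1$percent_inhibition,
                              a6$percent_inhibition,
                              dose_il6 = a6$concentration_uM,
                              margin = config$predominance_margin,
                              floor = config$predominance_floor)
    pred_rows[[j]] <- cbind(compound_id = id, pr)
    conf_rows[[j]] <- data.frame(
      compound_id = id, ic50_uM = f1$ic50,
      n_predominant = attr(pr, "n_predominant"),
      stringsAsFactors = FALSE)
  }
  fits <- do.call(rbind, fit_rows[seq_len(k)])
  predominance <- do.call(rbind, pred_rows)
  outcomes <- confirm_hits(do.call(rbind, conf_rows), config)
  counts <- summarize_cascade(outcomes)
  res <- list(fits = fits, predominance = predominance,
              outcomes = outcomes, counts = counts)
  if (!is.null(out_dir)) {
    tables <- list(fits = fits, predominance = predominance,
                   confirmation = outcomes, cascade = counts)
    res$manifest <- write_run(tables, out_dir, config, inputs,
                              stage_counts = counts)
  }
  res
}

#' Simulate a screen and write it to disk
#'
#' Wraps [simulate_screen()] and writes the well table, plate map,
#' annotations and truth table in the formats consumed by the readers,
#' plus a run manifest.
#'
#' @param config a [simulation_config()].
#' @param out_dir output directory.
#' @param seed integer seed.
#' @return The simulation list, with the manifest added.
#' @export
run_simulate <- function(config = simulation_config(), out_dir,
                         seed = 1L) {
  sim <- simulate_screen(config, seed)
  tables <- list(wells = sim$wells, plate_map = sim$map,
                 annotations = sim$annotations, truth = sim$truth)
  cfg <- unclass(config)
  cfg$analyte_params <- NULL
  cfg$seed <- as.integer(seed)
  sim$manifest <- write_run(tables, out_dir, cfg, inputs = NULL,
                            stage_counts = NULL)
  sim
}

# One manifest per run: timestamp, full config echo, input digests, stage
# counts, and the written files with row counts.
write_run <- function(tables, out_dir, config, inputs, stage_counts) {
  manifest_files <- write_screen_results(tables, out_dir)
  digests <- if (!is.null(inputs)) {
    as.list(tools::md5sum(inputs))
  } else NULL
  manifest <- list(
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(config),
    input_digests = digests,
    stage_counts = if (!is.null(stage_counts)) {
      stats::setNames(as.list(stage_counts$count), stage_counts$stage)
    } else NULL,
    files = stats::setNames(as.list(manifest_files$rows),
                            basename(manifest_files$file))
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  manifest
}
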