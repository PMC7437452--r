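#' Screen configuration
#'
#' Bundles every tunable threshold of the triage cascade so that each run
#' reports exactly the rules it applied. Defaults follow the published
#' criteria where the screen states them (primary IL-1beta cutoff "more
#' than 30%", confirmation IC50 "less than 10 uM", predominance "at least
#' at two different doses", Z' "over 0.5") and documented choices where it
#' does not (the relaxed IL-6 counter-screen band, the numeric predominance
#' margin and floor).
#'
#' @param il1b_threshold primary-screen IL-1beta percent-inhibition cutoff;
#'   compounds are kept when strictly above it. Default 30.
#' @param il6_exclusion_band symmetric IL-6 band in percent; compounds with
#'   `|IL-6%| > band` are excluded as nonspecific inhibitors or enhancers.
#'   Default 50.
#' @param ic50_cutoff confirmation IC50 cutoff in uM, strict `<`. Default 10.
#' @param min_predominant_doses confirmation requirement on the number of
#'   doses with predominant IL-1beta inhibition. Default 2.
#' @param predominance_margin,predominance_floor per-dose predominance rule
#'   in percentage points (see [assess_predominance()]). Defaults 30 / 30.
#' @param zprime_threshold plate-QC Z' gate, strict `>`. Default 0.5.
#' @param exclude_failing_plates drop compounds on QC-failing plates from
#'   triage (default `FALSE`: failing plates are flagged but analysed).
#' @param controls_per_plate expected high (= low) controls per plate.
#' @param seed integer seed recorded with the run.
#' @return An object of class `"screen_config"` (a named list).
#' @export
screen_config <- function(il1b_threshold = 30,
                          il6_exclusion_band = 50,
                          ic50_cutoff = 10,
                          min_predominant_doses = 2L,
                          predominance_margin = 30,
                          predominance_floor = 30,
                          zprime_threshold = 0.5,
                          exclude_failing_plates = FALSE,
                          controls_per_plate = 16L,
                          seed = 1L) {
  cfg <- list(il1b_threshold = il1b_threshold,
              il6_exclusion_band = il6_exclusion_band,
              ic50_cutoff = ic50_cutoff,
              min_predominant_doses = as.integer(min_predominant_doses),
              predominance_margin = predominance_margin,
              predominance_floor = predominance_floor,
              zprime_threshold = zprime_threshold,
              exclude_failing_plates = isTRUE(exclude_failing_plates),
              controls_per_plate = as.integer(controls_per_plate),
              seed = as.integer(seed))
  num <- unlist(cfg[1:7])
  if (any(!is.finite(num))) stop("all thresholds must be finite",
                                 call. = FALSE)
  class(cfg) <- "screen_config"
  cfg
}

#' @export
print.screen_config <- function(x, ...) {
  cat("Screen configuration:\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, x[[nm]]))
  invisible(x)
}

# Terminal triage categories; every screened compound ends in exactly one.
TRIAGE_STAGES <- c("primary_selected", "excluded_below_il1b_threshold",
                   "excluded_il6_nonspecific", "excluded_steroid",
                   "excluded_duplicate", "confirmation_tested",
                   "confirmed_hit", "rejected_ic50",
                   "rejected_predominance")

#' Primary-screen triage cascade
#'
#' Applies the staged selection of the primary screen to per-compound
#' dual-cytokine activities at the screening dose:
#' \enumerate{
#'   \item keep compounds with IL-1beta inhibition strictly above
#'     `il1b_threshold` (ties fall on the excluded side);
#'   \item exclude compounds whose IL-6 inhibition falls outside the
#'     symmetric counter-screen band (`|IL-6%| > il6_exclusion_band`) as
#'     nonspecific inhibitors or enhancers;
#'   \item exclude annotated steroids;
#'   \item collapse each duplicate group to its strongest IL-1beta
#'     inhibitor, excluding the rest.
#' }
#' Survivors are `primary_selected`. Compounds missing from the annotation
#' table are treated as non-steroid singletons (a note is emitted).
#'
#' @param activity data.frame with columns `compound_id`, `analyte`,
#'   `percent_inhibition`; every compound must appear with both analytes
#'   (IL1B and IL6). Extra columns are ignored.
#' @param annotations optional annotation data.frame (see
#'   [read_annotations()]).
#' @param config a [screen_config()].
#' @return A list with `outcomes` (one row per compound: `compound_id`,
#'   `il1b_percent`, `il6_percent`, `stage`) and `counts` (stage-count
#'   table from [summarize_cascade()]).
#' @export
triage_primary <- function(activity, annotations = NULL,
                           config = screen_config()) {
  wide <- activity_pairs(activity)
  n <- nrow(wide)
  stage <- rep(NA_character_, n)

  stage[wide$il1b <= config$il1b_threshold] <- "excluded_below_il1b_threshold"
  open <- is.na(stage)
  stage[open & abs(wide$il6) > config$il6_exclusion_band] <-
    "excluded_il6_nonspecific"

  ann <- match_annotations(wide$compound_id, annotations)
  open <- is.na(stage)
  stage[open & ann$is_steroid] <- "excluded_steroid"

  # duplicate collapse among compounds still in play: keep the strongest
  # IL-1beta inhibitor of each group
  open <- which(is.na(stage) & !is.na(ann$duplicate_group))
  if (length(open) > 0L) {
    for (grp in unique(ann$duplicate_group[open])) {
      idx <- open[ann$duplicate_group[open] == grp]
      if (length(idx) > 1L) {
        keep <- idx[which.max(wide$il1b[idx])]
        stage[setdiff(idx, keep)] <- "excluded_duplicate"
      }
    }
  }
  stage[is.na(stage)] <- "primary_selected"

  outcomes <- data.frame(compound_id = wide$compound_id,
                         il1b_percent = wide$il1b, il6_percent = wide$il6,
                         stage = stage, stringsAsFactors = FALSE)
  list(outcomes = outcomes, counts = summarize_cascade(outcomes))
}

# Reshape long per-analyte activity into one row per compound with il1b and
# il6 columns; errors on compounds lacking either analyte.
activity_pairs <- function(activity) {
  stopifnot(all(c("compound_id", "analyte", "percent_inhibition") %in%
                  names(activity)))
  a1 <- activity[activity$analyte == "IL1B", ]
  a6 <- activity[activity$analyte == "IL6", ]
  ids <- sort(unique(activity$compound_id))
  i1 <- match(ids, a1$compound_id)
  i6 <- match(ids, a6$compound_id)
  bad <- ids[is.na(i1) | is.na(i6)]
  if (length(bad) > 0L) {
    stop("incomplete analyte pair for compound(s): ",
         paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)
  }
  data.frame(compound_id = ids,
             il1b = a1$percent_inhibition[i1],
             il6 = a6$percent_inhibition[i6],
             stringsAsFactors = FALSE)
}

match_annotations <- function(ids, annotations) {
  if (is.null(annotations)) {
    return(data.frame(is_steroid = rep(FALSE, length(ids)),
                      duplicate_group = rep(NA_character_, length(ids)),
                      stringsAsFactors = FALSE))
  }
  i <- match(ids, annotations$compound_id)
  if (anyNA(i)) {
    message(sum(is.na(i)), " compound(s) missing from annotations; ",
            "treated as non-steroid singletons")
  }
  data.frame(
    is_steroid = ifelse(is.na(i), FALSE, annotations$is_steroid[i]),
    duplicate_group = ifelse(is.na(i), NA_character_,
                             annotations$duplicate_group[i]),
    stringsAsFactors = FALSE
  )
}

#' Confirmation-screen hit calls
#'
#' A primary-selected compound is confirmed when its IL-1beta dose-response
#' IC50 is strictly below `ic50_cutoff` AND at least
#' `min_predominant_doses` doses show predominant IL-1beta inhibition.
#' The first failing rule is recorded (`rejected_ic50` before
#' `rejected_predominance`); a missing or flat IL-1beta fit rejects on the
#' IC50 rule.
#'
#' @param fits data.frame with one row per compound: `compound_id`,
#'   `ic50_uM` (the IL-1beta IC50, `NA` when absent) and `n_predominant`
#'   (count of predominant doses from [assess_predominance()]).
#' @param config a [screen_config()].
#' @return A data.frame with `compound_id`, `ic50_uM`, `n_predominant`,
#'   `stage` (one of `confirmed_hit`, `rejected_ic50`,
#'   `rejected_predominance`).
#' @export
confirm_hits <- function(fits, config = screen_config()) {
  stopifnot(all(c("compound_id", "ic50_uM", "n_predominant") %in%
                  names(fits)))
  stage <- ifelse(
    is.na(fits$ic50_uM) | fits$ic50_uM >= config$ic50_cutoff,
    "rejected_ic50",
    ifelse(fits$n_predominant >= config$min_predominant_doses,
           "confirmed_hit", "rejected_predominance"))
  data.frame(compound_id = fits$compound_id, ic50_uM = fits$ic50_uM,
             n_predominant = fits$n_predominant, stage = stage,
             stringsAsFactors = FALSE)
}

#' Stage counts of a triage run
#'
#' Tabulates terminal categories; the counts always sum to the number of
#' compounds, since the categories partition the compound set.
#'
#' @param outcomes data.frame with a `stage` column.
#' @return A data.frame with `stage` (all known categories, in cascade
#'   order) and `count`.
#' @export
summarize_cascade <- function(outcomes) {
  counts <- table(factor(outcomes$stage, levels = TRIAGE_STAGES))
  data.frame(stage = names(counts), count = as.integer(counts),
             stringsAsFactors = FALSE)
}
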