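# Shared fixture builders; everything is generated in code at test time.

# Minimal valid well table: one plate, both analytes, n_ctrl high + low
# controls and a few compound wells with prescribed HTRF ratios.
make_well_fixture <- function(ratios_cmp = c(4500, 8000),
                              mu_hc = 8000, mu_lc = 1000,
                              n_ctrl = 16, analyte = "IL1B",
                              plate_id = "P01", em620 = 10000) {
  n_cmp <- length(ratios_cmp)
  wells_cmp <- paste0(LETTERS[seq_len(n_cmp)], 1)
  wells_hc <- paste0(LETTERS[1:n_ctrl], 23)
  wells_lc <- paste0(LETTERS[1:n_ctrl], 24)
  ratio <- c(ratios_cmp, rep(mu_hc, n_ctrl), rep(mu_lc, n_ctrl))
  data.frame(
    plate_id = plate_id,
    well = c(wells_cmp, wells_hc, wells_lc),
    role = c(rep("compound", n_cmp), rep("high_control", n_ctrl),
             rep("low_control", n_ctrl)),
    compound_id = c(sprintf("C%03d", seq_len(n_cmp)),
                    rep(NA_character_, 2 * n_ctrl)),
    concentration_uM = c(rep(1, n_cmp), rep(NA_real_, 2 * n_ctrl)),
    analyte = analyte,
    em620 = em620,
    em665 = ratio * em620 / 10000,
    stringsAsFactors = FALSE
  )
}

# Long-format activity table for triage tests from per-compound
# (il1b, il6) percent inhibitions.
make_activity <- function(il1b, il6, ids = sprintf("C%03d",
                                                   seq_along(il1b))) {
  data.frame(
    compound_id = rep(ids, 2),
    analyte = rep(c("IL1B", "IL6"), each = length(ids)),
    percent_inhibition = c(il1b, il6),
    stringsAsFactors = FALSE
  )
}

# A small simulated screen shared by several tests (2 plates, 100
# compounds, deterministic class mixture).
small_sim <- function(seed = 11, n_compounds = 100, noise_scale = 1,
                      class_counts = NULL) {
  cfg <- simulation_config(n_plates = 2, n_compounds = n_compounds,
                           class_counts = class_counts,
                           assignment = "deterministic",
                           noise_scale = noise_scale)
  simulate_screen(cfg, seed = seed)
}

write_tmp_csv <- function(df, name) {
  path <- file.path(withr::local_tempdir(.local_envir = parent.frame()),
                    name)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
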