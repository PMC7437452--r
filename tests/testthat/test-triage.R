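test_that("primary triage applies the staged criteria with strict cutoffs", {
  act <- make_activity(il1b = c(50, 30, 60, 31, -20),
                       il6 = c(5, 0, -80, 60, 0))
  res <- triage_primary(act)
  out <- setNames(res$outcomes$stage, res$outcomes$compound_id)
  expect_equal(unname(out["C001"]), "primary_selected")
  # exactly 30% fails the "more than 30%" rule
  expect_equal(unname(out["C002"]), "excluded_below_il1b_threshold")
  # IL-6 enhancement beyond the band excludes, like inhibition
  expect_equal(unname(out["C003"]), "excluded_il6_nonspecific")
  expect_equal(unname(out["C004"]), "excluded_il6_nonspecific")
  expect_equal(unname(out["C005"]), "excluded_below_il1b_threshold")
})

test_that("steroids and duplicate groups are excluded after the activity criteria", {
  act <- make_activity(il1b = c(50, 70, 60, 40), il6 = c(0, 0, 0, 0))
  ann <- data.frame(compound_id = sprintf("C%03d", 1:4),
                    library = "L",
                    duplicate_group = c(NA, "g1", "g1", NA),
                    is_steroid = c(FALSE, FALSE, FALSE, TRUE))
  res <- triage_primary(act, ann)
  out <- setNames(res$outcomes$stage, res$outcomes$compound_id)
  expect_equal(unname(out["C004"]), "excluded_steroid")
  # the strongest IL-1beta inhibitor of the duplicate pair survives
  expect_equal(unname(out["C002"]), "primary_selected")
  expect_equal(unname(out["C003"]), "excluded_duplicate")
  expect_equal(unname(out["C001"]), "primary_selected")
})

test_that("a compound with one analyte missing raises an incomplete-pair error", {
  act <- make_activity(il1b = c(50, 60), il6 = c(0, 0))
  act <- act[-4, ]
  expect_error(triage_primary(act), "incomplete analyte pair.*C002")
})

test_that("triage outcomes partition the compound set on random fixtures", {
  set.seed(603)
  for (i in 1:10) {
    n <- sample(20:80, 1)
    act <- make_activity(il1b = runif(n, -120, 120),
                         il6 = runif(n, -120, 120))
    res <- triage_primary(act)
    expect_equal(sum(res$counts$count), n)
    expect_equal(nrow(res$outcomes), n)
    expect_false(any(is.na(res$outcomes$stage)))
  }
})

test_that("the IL-1beta and IL-6 criteria commute on random fixtures", {
  set.seed(604)
  for (i in 1:5) {
    n <- 60
    il1b <- runif(n, -120, 120)
    il6 <- runif(n, -120, 120)
    selected_12 <- which(il1b > 30 & abs(il6) <= 50)
    selected_21 <- which(abs(il6) <= 50 & il1b > 30)
    res <- triage_primary(make_activity(il1b, il6))
    expect_equal(which(res$outcomes$stage == "primary_selected"),
                 selected_12)
    expect_equal(selected_12, selected_21)
  }
})

test_that("raising the IL-1beta threshold never increases the selected count", {
  set.seed(605)
  act <- make_activity(il1b = runif(100, -120, 120),
                       il6 = runif(100, -120, 120))
  counts <- vapply(c(10, 30, 50, 70), function(thr) {
    res <- triage_primary(act, config = screen_config(il1b_threshold = thr))
    sum(res$outcomes$stage == "primary_selected")
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("confirmation applies the IC50 and predominance rules in order", {
  fits <- data.frame(compound_id = c("a", "b", "c", "d"),
                     ic50_uM = c(5, 15, 5, NA),
                     n_predominant = c(3, 5, 1, 4))
  out <- confirm_hits(fits, screen_config())
  expect_equal(out$stage, c("confirmed_hit", "rejected_ic50",
                            "rejected_predominance", "rejected_ic50"))
  # exactly 10 uM fails the "less than 10 uM" rule
  out10 <- confirm_hits(data.frame(compound_id = "x", ic50_uM = 10,
                                   n_predominant = 5), screen_config())
  expect_equal(out10$stage, "rejected_ic50")
})

test_that("cascade summary conserves counts and handles empty input", {
  out <- summarize_cascade(data.frame(stage = c("primary_selected",
                                                "excluded_steroid",
                                                "primary_selected")))
  expect_equal(sum(out$count), 3L)
  expect_equal(out$count[out$stage == "primary_selected"], 2L)
  empty <- summarize_cascade(data.frame(stage = character()))
  expect_true(all(empty$count == 0L))
})

test_that("screen_config validates thresholds and echoes them", {
  cfg <- screen_config(il6_exclusion_band = 40)
  expect_s3_class(cfg, "screen_config")
  expect_output(print(cfg), "il6_exclusion_band")
  expect_error(screen_config(il1b_threshold = NA), "finite")
})
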