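test_that("well label <-> (row, col) maps compose to identity on all 384 wells", {
  grid <- expand.grid(row = 0:15, col = 0:23)
  labels <- index_to_well(grid$row, grid$col)
  expect_equal(length(unique(labels)), 384L)
  idx <- well_to_index(labels)
  expect_equal(idx$row, grid$row)
  expect_equal(idx$col, grid$col)
  expect_equal(index_to_well(idx$row, idx$col), labels)
})

test_that("padded, unpadded and lower-case well labels are accepted; bad labels are not", {
  expect_equal(well_to_index(c("A01", "a1", "A1"))$well, rep("A1", 3))
  bad <- well_to_index(c("Q25", "Z9", "A0", "A25", "AA1", ""))
  expect_true(all(is.na(bad$row)))
})

test_that("well table round-trips through write and read", {
  wells <- make_well_fixture(ratios_cmp = c(4500, 8000, 300))
  path <- write_tmp_csv(wells, "wells.csv")
  back <- read_well_table(path)
  expect_equal(back, wells, ignore_attr = TRUE)
})

test_that("well table reader rejects structural problems with row context", {
  wells <- make_well_fixture()
  wells$well[2] <- "Z9"
  expect_error(read_well_table(write_tmp_csv(wells, "w.csv")),
               "Z9.*row.* 2")

  wells <- make_well_fixture()
  wells$em665[1] <- -5
  expect_error(read_well_table(write_tmp_csv(wells, "w2.csv")),
               "negative")

  wells <- make_well_fixture()
  wells$compound_id[1] <- NA
  expect_error(read_well_table(write_tmp_csv(wells, "w3.csv")),
               "without compound_id")

  wells <- make_well_fixture()[, -3]
  expect_error(read_well_table(write_tmp_csv(wells, "w4.csv")),
               "missing required column")
})

test_that("header-only well table yields an empty collection with a warning", {
  path <- write_tmp_csv(make_well_fixture()[0, ], "empty.csv")
  expect_warning(out <- read_well_table(path), "no rows")
  expect_equal(nrow(out), 0L)
})

test_that("plate map validation enforces control counts and unique assignment", {
  sim <- small_sim()
  path <- write_tmp_csv(sim$map, "map.csv")
  map <- read_plate_map(path)
  expect_equal(nrow(map), nrow(sim$map))
  expect_equal(sum(map$role == "high_control" & map$plate_id == "P01"), 16L)

  dup <- sim$map
  dup$well[dup$plate_id == "P01"][1:2] <- "A1"
  expect_error(read_plate_map(write_tmp_csv(dup, "dup.csv")),
               "more than once")

  short <- sim$map[-match("high_control", sim$map$role), ]
  expect_error(read_plate_map(write_tmp_csv(short, "short.csv")),
               "requires 16")
  # a non-default design is accepted when configured
  expect_error(read_plate_map(path, controls_per_plate = 15), "requires 15")
})

test_that("annotation reader enforces unique ids and duplicate-group arity", {
  ann <- data.frame(compound_id = c("A", "B", "C", "D"),
                    library = "LIB",
                    duplicate_group = c("g1", "g1", NA, NA),
                    is_steroid = c(FALSE, FALSE, TRUE, FALSE))
  out <- read_annotations(write_tmp_csv(ann, "ann.csv"))
  expect_equal(out$is_steroid, c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(out$duplicate_group, c("g1", "g1", NA, NA))

  ann$duplicate_group <- c("g1", NA, NA, NA)
  expect_error(read_annotations(write_tmp_csv(ann, "solo.csv")),
               "single member")
  ann$duplicate_group <- NA
  ann$compound_id <- c("A", "A", "B", "C")
  expect_error(read_annotations(write_tmp_csv(ann, "dupid.csv")),
               "duplicated compound_id")
})

test_that("compound-result reader tolerates renamed headers", {
  df <- data.frame(Compound = c("x1", "x2"),
                   `IL-1b % inhibition` = c(45, -10),
                   `IL-6 % inhibition` = c(5, 80), check.names = FALSE)
  out <- read_compound_results(write_tmp_csv(df, "s2.csv"))
  expect_equal(nrow(out), 4L)
  expect_equal(out$percent_inhibition[out$compound_id == "x1" &
                                        out$analyte == "IL1B"], 45)
  expect_equal(out$percent_inhibition[out$compound_id == "x2" &
                                        out$analyte == "IL6"], 80)
  names(df) <- c("thing", "foo", "bar")
  expect_error(read_compound_results(write_tmp_csv(df, "bad.csv")),
               "could not locate")
})

test_that("write_screen_results manifest row counts equal table lengths", {
  dir <- withr::local_tempdir()
  tables <- list(activity = make_well_fixture(),
                 empty = make_well_fixture()[0, ])
  man <- write_screen_results(tables, dir)
  expect_equal(man$rows, c(nrow(tables$activity), 0L))
  expect_true(all(file.exists(man$file)))
  # header-only file for the empty table
  expect_length(readLines(man$file[2]), 1L)
})
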