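# Canonical row letters of a 384-well plate (16 rows x 24 columns).
PLATE_ROWS <- LETTERS[1:16]
PLATE_COLS <- 1:24

WELL_ROLES <- c("high_control", "low_control", "compound", "empty")
ANALYTES <- c("IL1B", "IL6")

#' Parse 384-well labels into 0-based (row, column) indices
#'
#' Labels use row letters A--P and column numbers 1--24, as printed on the
#' plate. Zero-padded column numbers ("A01") are accepted on input; the
#' canonical form produced by [index_to_well()] is unpadded ("A1").
#'
#' @param well character vector of well labels.
#' @return A data.frame with integer columns `row` (0--15) and `col`
#'   (0--23), one row per input label, plus the canonical label in `well`.
#'   Unparsable labels yield `NA` rows.
#' @examples
#' well_to_index(c("A1", "P24", "h07"))
#' @export
well_to_index <- function(well) {
  well <- toupper(trimws(as.character(well)))
  m <- regmatches(well, regexec("^([A-P])0?([1-9][0-9]?)$", well))
  row <- vapply(m, function(x) {
    if (length(x) == 3) match(x[2], PLATE_ROWS) - 1L else NA_integer_
  }, integer(1))
  col <- vapply(m, function(x) {
    if (length(x) == 3) as.integer(x[3]) - 1L else NA_integer_
  }, integer(1))
  col[!is.na(col) & col > 23L] <- NA_integer_
  row[is.na(col)] <- NA_integer_
  col[is.na(row)] <- NA_integer_
  ok <- !is.na(row)
  canon <- rep(NA_character_, length(well))
  canon[ok] <- paste0(PLATE_ROWS[row[ok] + 1L], col[ok] + 1L)
  data.frame(well = canon, row = row, col = col, stringsAsFactors = FALSE)
}

#' Build canonical well labels from 0-based (row, column) indices
#'
#' @param row integer vector, 0--15.
#' @param col integer vector, 0--23.
#' @return Character vector of labels such as "A1", "P24".
#' @export
index_to_well <- function(row, col) {
  stopifnot(all(row >= 0 & row <= 15), all(col >= 0 & col <= 23))
  paste0(PLATE_ROWS[row + 1L], col + 1L)
}

# Guess the delimiter of a delimited text file from its header line.
detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) return(",")
  if (grepl("\t", header)) "\t" else ","
}

read_delim_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) sep <- detect_sep(path)
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, comment.char = "",
                    blank.lines.skip = TRUE, check.names = FALSE)
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
}

# Validate + canonicalize well labels; `rows` are 1-based data rows used in
# error messages so users can find the offending lines.
validate_wells <- function(well, what) {
  idx <- well_to_index(well)
  bad <- which(is.na(idx$row))
  if (length(bad) > 0L) {
    stop(sprintf("%s: unparsable well label(s) %s at row(s) %s", what,
                 paste(unique(well[bad]), collapse = ", "),
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  idx$well
}

#' Read a long-format well-measurement table
#'
#' One row per well per analyte, carrying the raw 620 nm (donor) and 665 nm
#' (acceptor) emission counts of the HTRF readout. Expected columns:
#' `plate_id`, `well`, `role`, `compound_id`, `concentration_uM`, `analyte`,
#' `em620`, `em665`. The delimiter (comma or tab) is auto-detected.
#'
#' Structural problems -- missing columns, unparsable well labels, unknown
#' roles or analytes, negative emission counts, compound rows without a
#' compound id -- raise an error naming the offending rows.
#'
#' @param path path to the delimited text file.
#' @param sep optional field separator; auto-detected when `NULL`.
#' @return A data.frame of well measurements with canonical well labels.
#' @seealso [write_screen_results()], [simulate_screen()]
#' @export
read_well_table <- function(path, sep = NULL) {
  df <- read_delim_table(path, sep)
  require_columns(df, c("plate_id", "well", "role", "compound_id",
                        "concentration_uM", "analyte", "em620", "em665"),
                  "well table")
  if (nrow(df) == 0L) {
    warning("well table ", path, " contains a header but no rows")
    return(empty_well_table())
  }
  df$well <- validate_wells(df$well, "well table")
  check_role_analyte(df, "well table")
  df$compound_id <- as.character(df$compound_id)
  df$compound_id[df$compound_id %in% c("", "NA")] <- NA_character_
  df$concentration_uM <- as.numeric(df$concentration_uM)
  df$em620 <- as.numeric(df$em620)
  df$em665 <- as.numeric(df$em665)
  bad <- which(!is.finite(df$em620) | !is.finite(df$em665) |
                 df$em620 < 0 | df$em665 < 0)
  if (length(bad) > 0L) {
    stop("well table: negative or non-numeric emission counts at row(s) ",
         paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)
  }
  check_compound_fields(df, "well table")
  df[c("plate_id", "well", "role", "compound_id", "concentration_uM",
       "analyte", "em620", "em665")]
}

empty_well_table <- function() {
  data.frame(plate_id = character(), well = character(), role = character(),
             compound_id = character(), concentration_uM = numeric(),
             analyte = character(), em620 = numeric(), em665 = numeric(),
             stringsAsFactors = FALSE)
}

check_role_analyte <- function(df, what) {
  bad <- which(!df$role %in% WELL_ROLES)
  if (length(bad) > 0L) {
    stop(sprintf("%s: unknown role(s) %s at row(s) %s", what,
                 paste(unique(df$role[bad]), collapse = ", "),
                 paste(utils::head(bad, 10L), collapse = ", ")),
         call. = FALSE)
  }
  if ("analyte" %in% names(df)) {
    bad <- which(!df$analyte %in% ANALYTES)
    if (length(bad) > 0L) {
      stop(sprintf("%s: unknown analyte(s) %s at row(s) %s", what,
                   paste(unique(df$analyte[bad]), collapse = ", "),
                   paste(utils::head(bad, 10L), collapse = ", ")),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

# role=compound requires a compound id; control wells are DMSO and carry none.
check_compound_fields <- function(df, what) {
  bad <- which(df$role == "compound" & is.na(df$compound_id))
  if (length(bad) > 0L) {
    stop(sprintf("%s: role=compound without compound_id at row(s) %s", what,
                 paste(utils::head(bad, 10L), collapse = ", ")),
         call. = FALSE)
  }
  bad <- which(df$role %in% c("high_control", "low_control") &
                 !is.na(df$compound_id))
  if (length(bad) > 0L) {
    stop(sprintf("%s: control wells must not carry a compound_id, row(s) %s",
                 what, paste(utils::head(bad, 10L), collapse = ", ")),
         call. = FALSE)
  }
  bad <- which(!is.na(df$concentration_uM) & df$concentration_uM <= 0)
  if (length(bad) > 0L) {
    stop(sprintf("%s: non-positive concentration at row(s) %s", what,
                 paste(utils::head(bad, 10L), collapse = ", ")),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a plate map
#'
#' A plate map assigns every used well of every plate a role
#' (`high_control`, `low_control`, `compound` or `empty`) and, for compound
#' wells, a compound id and concentration. Columns: `plate_id`, `well`,
#' `role`, `compound_id`, `concentration_uM`.
#'
#' Each plate must carry exactly `controls_per_plate` high controls and the
#' same number of low controls (the screen design places 16 of each on every
#' 384-well plate), and no well may be assigned twice.
#'
#' @param path path to the delimited text file.
#' @param controls_per_plate required number of high (and of low) controls
#'   per plate; default 16.
#' @param sep optional field separator; auto-detected when `NULL`.
#' @return A data.frame plate map with canonical well labels.
#' @export
read_plate_map <- function(path, controls_per_plate = 16L, sep = NULL) {
  df <- read_delim_table(path, sep)
  require_columns(df, c("plate_id", "well", "role", "compound_id",
                        "concentration_uM"), "plate map")
  df$well <- validate_wells(df$well, "plate map")
  check_role_analyte(df, "plate map")
  df$compound_id <- as.character(df$compound_id)
  df$compound_id[df$compound_id %in% c("", "NA")] <- NA_character_
  df$concentration_uM <- as.numeric(df$concentration_uM)
  check_compound_fields(df, "plate map")
  validate_plate_map(df, controls_per_plate)
  df[c("plate_id", "well", "role", "compound_id", "concentration_uM")]
}

validate_plate_map <- function(map, controls_per_plate = 16L) {
  key <- paste(map$plate_id, map$well)
  dup <- unique(key[duplicated(key)])
  if (length(dup) > 0L) {
    stop("plate map assigns well(s) more than once: ",
         paste(utils::head(dup, 5L), collapse = "; "), call. = FALSE)
  }
  for (pid in unique(map$plate_id)) {
    sub <- map[map$plate_id == pid, ]
    n_hc <- sum(sub$role == "high_control")
    n_lc <- sum(sub$role == "low_control")
    if (n_hc != controls_per_plate || n_lc != controls_per_plate) {
      stop(sprintf(paste0("plate %s has %d high and %d low controls; ",
                          "the plate design requires %d of each"),
                   pid, n_hc, n_lc, controls_per_plate), call. = FALSE)
    }
  }
  invisible(map)
}

#' Read a compound annotation table
#'
#' Columns: `compound_id`, `library`, `duplicate_group`, `is_steroid`.
#' Compound ids must be unique; a duplicate group, when present, must have
#' at least two members.
#'
#' @param path path to the delimited text file.
#' @param sep optional field separator; auto-detected when `NULL`.
#' @return A data.frame of annotations with logical `is_steroid`.
#' @export
read_annotations <- function(path, sep = NULL) {
  df <- read_delim_table(path, sep)
  require_columns(df, c("compound_id", "library", "duplicate_group",
                        "is_steroid"), "annotation table")
  df$compound_id <- as.character(df$compound_id)
  if (anyDuplicated(df$compound_id)) {
    stop("annotation table: duplicated compound_id(s): ",
         paste(utils::head(unique(df$compound_id[duplicated(df$compound_id)]),
                           5L), collapse = ", "), call. = FALSE)
  }
  df$duplicate_group <- as.character(df$duplicate_group)
  df$duplicate_group[df$duplicate_group %in% c("", "NA")] <- NA_character_
  grp <- table(df$duplicate_group)
  solo <- names(grp)[grp < 2L]
  if (length(solo) > 0L) {
    stop("annotation table: duplicate_group(s) with a single member: ",
         paste(utils::head(solo, 5L), collapse = ", "), call. = FALSE)
  }
  df$is_steroid <- as.logical(df$is_steroid)
  df[c("compound_id", "library", "duplicate_group", "is_steroid")]
}

#' Read a per-compound screen-result table
#'
#' Reader for delimited-text exports of per-compound primary-screen results
#' (one row per compound with the percent inhibition of each cytokine), such
#' as an exported supplementary compound-result workbook. Header matching is
#' tolerant: the compound-id column may be named `compound_id`, `compound`,
#' `id` or `name`, and the two inhibition columns are recognized from any
#' header containing "il-1"/"il1" or "il-6"/"il6" (case-insensitive).
#'
#' @param path path to the delimited text file.
#' @param sep optional field separator; auto-detected when `NULL`.
#' @return A data.frame in long activity format: `compound_id`, `analyte`,
#'   `percent_inhibition`.
#' @export
read_compound_results <- function(path, sep = NULL) {
  df <- read_delim_table(path, sep)
  nm <- tolower(gsub("[^a-z0-9]", "", tolower(names(df))))
  id_col <- which(nm %in% c("compoundid", "compound", "id", "name",
                            "compoundname"))[1]
  il1_col <- grep("il1", nm)[1]
  il6_col <- grep("il6", nm)[1]
  if (is.na(id_col) || is.na(il1_col) || is.na(il6_col)) {
    stop("compound-result table: could not locate compound-id and ",
         "IL-1β/IL-6 inhibition columns in header: ",
         paste(names(df), collapse = ", "), call. = FALSE)
  }
  data.frame(
    compound_id = rep(as.character(df[[id_col]]), 2L),
    analyte = rep(c("IL1B", "IL6"), each = nrow(df)),
    percent_inhibition = c(as.numeric(df[[il1_col]]),
                           as.numeric(df[[il6_col]])),
    stringsAsFactors = FALSE
  )
}

#' Write result tables to a directory
#'
#' Writes each table in `tables` as a comma-delimited text file
#' `<name>.csv` with a deterministic column order (the table's own order)
#' and returns a manifest listing every file with its row count.
#'
#' @param tables named list of data.frames.
#' @param out_dir output directory, created if needed.
#' @return A data.frame manifest with columns `name`, `file`, `rows`.
#' @export
write_screen_results <- function(tables, out_dir) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) {
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  files <- character(length(tables))
  rows <- integer(length(tables))
  for (i in seq_along(tables)) {
    files[i] <- file.path(out_dir, paste0(names(tables)[i], ".csv"))
    utils::write.csv(tables[[i]], files[i], row.names = FALSE, quote = FALSE)
    rows[i] <- nrow(tables[[i]])
  }
  data.frame(name = names(tables), file = files, rows = rows,
             stringsAsFactors = FALSE)
}
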