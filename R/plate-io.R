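WELL_ROLES <- c("reaction", "negative_control", "substrate_control",
                "basal_control", "standard", "blank")

#' Validate and canonicalise 96-well addresses
#'
#' Well addresses are a row letter `A`--`H` followed by a 1-based column
#' number `1`--`12`, in unpadded form (`"A1"`, `"H12"`). Zero-padded input
#' (`"A01"`) is accepted and canonicalised.
#'
#' @param x character vector of well addresses.
#' @return character vector of canonical addresses.
#' @examples
#' well_address(c("A1", "h12", "B03"))
#' @export
well_address <- function(x) {
  x <- toupper(trimws(as.character(x)))
  m <- regmatches(x, regexec("^([A-H])0*([1-9][0-9]?)$", x))
  bad <- vapply(m, length, 0L) == 0L
  if (any(bad)) {
    stop("invalid well address(es): ", paste(x[bad], collapse = ", "),
         call. = FALSE)
  }
  row <- vapply(m, `[`, "", 2L)
  col <- as.integer(vapply(m, `[`, "", 3L))
  if (any(col > 12L)) {
    stop("well column out of range 1-12: ",
         paste(x[col > 12L], collapse = ", "), call. = FALSE)
  }
  paste0(row, col)
}

#' Read a plate-layout CSV
#'
#' The layout assigns each well a role and, where applicable, an enzyme,
#' nucleoside substrate, phosphate donor, donor concentration and replicate
#' index. Expected columns: `well, role, enzyme, substrate, donor,
#' donor_conc_uM, replicate`. Roles (case-insensitive): `reaction`,
#' `negative_control`, `substrate_control`, `basal_control`, `standard`,
#' `blank`.
#'
#' Validation enforces: unique well addresses, known roles, standards
#' carrying a donor concentration and no enzyme, reactions carrying
#' enzyme + substrate + donor.
#'
#' @param path path to the CSV file.
#' @param plate_id plate identifier; defaults to the file name without
#'   extension.
#' @return a `plate_layout`: data frame with columns `well`, `role`,
#'   `enzyme`, `substrate`, `donor`, `donor_conc_uM`, `replicate` and a
#'   `plate_id` attribute.
#' @export
read_plate_layout <- function(path, plate_id = NULL) {
  if (!file.exists(path)) stop("layout file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  if (is.null(plate_id)) plate_id <- sub("\\.[^.]*$", "", basename(path))
  as_plate_layout(df, plate_id = plate_id)
}

#' Construct a validated plate layout from a data frame
#'
#' @param df data frame with the layout columns (see
#'   [read_plate_layout()]).
#' @param plate_id plate identifier.
#' @return a `plate_layout` object.
#' @export
as_plate_layout <- function(df, plate_id = "plate") {
  need <- c("well", "role")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("layout is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("enzyme", "substrate", "donor")) {
    if (is.null(df[[col]])) df[[col]] <- NA_character_
    df[[col]] <- as.character(df[[col]])
    df[[col]][!is.na(df[[col]]) & !nzchar(trimws(df[[col]]))] <- NA_character_
  }
  if (is.null(df$donor_conc_uM)) df$donor_conc_uM <- NA_real_
  df$donor_conc_uM <- as.numeric(df$donor_conc_uM)
  if (is.null(df$replicate)) df$replicate <- 1L
  df$replicate[is.na(df$replicate)] <- 1L
  df$replicate <- as.integer(df$replicate)

  df$well <- well_address(df$well)
  dup <- df$well[duplicated(df$well)]
  if (length(dup)) {
    stop("duplicate well address(es) in layout: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }

  role <- tolower(trimws(as.character(df$role)))
  unknown <- setdiff(unique(role), WELL_ROLES)
  if (length(unknown)) {
    stop("unknown well role(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  df$role <- role

  std <- df$role == "standard"
  if (any(std & is.na(df$donor_conc_uM))) {
    stop("standard well(s) without donor_conc_uM: ",
         paste(df$well[std & is.na(df$donor_conc_uM)], collapse = ", "),
         call. = FALSE)
  }
  if (any(std & !is.na(df$enzyme))) {
    stop("standard well(s) must not carry an enzyme: ",
         paste(df$well[std & !is.na(df$enzyme)], collapse = ", "),
         call. = FALSE)
  }
  rx <- df$role == "reaction"
  bad_rx <- rx & (is.na(df$enzyme) | is.na(df$substrate) | is.na(df$donor))
  if (any(bad_rx)) {
    stop("reaction well(s) missing enzyme/substrate/donor: ",
         paste(df$well[bad_rx], collapse = ", "), call. = FALSE)
  }
  if (any(df$replicate < 1L, na.rm = TRUE)) {
    stop("replicate indices must be >= 1", call. = FALSE)
  }

  out <- df[, c("well", "role", "enzyme", "substrate", "donor",
                "donor_conc_uM", "replicate")]
  rownames(out) <- NULL
  attr(out, "plate_id") <- as.character(plate_id)
  class(out) <- c("plate_layout", "data.frame")
  out
}

#' Write a plate layout back to CSV
#'
#' Inverse of [read_plate_layout()] on canonical layouts.
#'
#' @param layout a `plate_layout`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_plate_layout <- function(layout, path) {
  stopifnot(inherits(layout, "plate_layout"))
  utils::write.csv(as.data.frame(layout), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @export
print.plate_layout <- function(x, ...) {
  cat("Plate layout '", attr(x, "plate_id"), "': ", nrow(x), " wells (",
      sum(x$role == "reaction"), " reaction, ",
      sum(x$role == "standard"), " standard, ",
      sum(x$role %in% c("negative_control", "substrate_control",
                        "basal_control")), " control, ",
      sum(x$role == "blank"), " blank)\n", sep = "")
  print(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("...", nrow(x) - 10L, "more wells\n")
  invisible(x)
}

# Parse RLU strings: plain integers/decimals and comma-thousands ("57,892").
# Dot-thousands is deliberately not auto-detected (ambiguous with decimals).
parse_rlu <- function(x) {
  x <- trimws(as.character(x))
  grouped <- grepl("^[0-9]{1,3}(,[0-9]{3})+(\\.[0-9]+)?$", x)
  x[grouped] <- gsub(",", "", x[grouped], fixed = TRUE)
  suppressWarnings(as.numeric(x))
}

#' Read a plate-reader luminescence export
#'
#' Expects a CSV with columns `well, rlu`, one row per measured well.
#' Numbers may use comma thousands separators (`"57,892"`); values must be
#' non-negative.
#'
#' @param path path to the CSV file.
#' @param plate_id plate identifier the readings belong to.
#' @return a `plate_reading`: data frame `well`, `rlu` with a `plate_id`
#'   attribute.
#' @export
read_reader_export <- function(path, plate_id = NULL) {
  if (!file.exists(path)) stop("reader export not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (is.null(plate_id)) plate_id <- sub("\\.[^.]*$", "", basename(path))
  if (!all(c("well", "rlu") %in% names(df))) {
    stop("reader export needs columns well,rlu", call. = FALSE)
  }
  rlu <- parse_rlu(df$rlu)
  if (anyNA(rlu)) {
    stop("unparseable RLU value(s) at data row(s): ",
         paste(which(is.na(rlu)), collapse = ", "), call. = FALSE)
  }
  as_plate_reading(data.frame(well = df$well, rlu = rlu,
                              stringsAsFactors = FALSE), plate_id)
}

#' Construct a validated plate reading from a data frame
#'
#' @param df data frame with columns `well`, `rlu`.
#' @param plate_id plate identifier.
#' @return a `plate_reading` object.
#' @export
as_plate_reading <- function(df, plate_id = "plate") {
  stopifnot(all(c("well", "rlu") %in% names(df)))
  df$well <- well_address(df$well)
  df$rlu <- as.numeric(df$rlu)
  if (any(df$rlu < 0)) {
    stop("negative RLU at well(s): ",
         paste(df$well[df$rlu < 0], collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$well)) {
    stop("duplicate reading for well(s): ",
         paste(unique(df$well[duplicated(df$well)]), collapse = ", "),
         call. = FALSE)
  }
  out <- df[, c("well", "rlu")]
  rownames(out) <- NULL
  attr(out, "plate_id") <- as.character(plate_id)
  class(out) <- c("plate_reading", "data.frame")
  out
}

#' Read an HPLC peak table
#'
#' Expects a CSV with columns `sample_id, rt_min, area` and an optional
#' `analyte` column. Areas and retention times must be non-negative; unit
#' (typically mAU s) is carried opaquely.
#'
#' @param path path to the CSV file.
#' @return a `peak_table`: data frame `sample_id`, `rt_min`, `area`,
#'   `analyte`.
#' @export
read_peak_table <- function(path) {
  if (!file.exists(path)) stop("peak table not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  as_peak_table(df)
}

#' Construct a validated peak table from a data frame
#'
#' @param df data frame with columns `sample_id`, `rt_min`, `area` and
#'   optionally `analyte`.
#' @return a `peak_table` object.
#' @export
as_peak_table <- function(df) {
  need <- c("sample_id", "rt_min", "area")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("peak table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(df$analyte)) df$analyte <- NA_character_
  df$analyte <- as.character(df$analyte)
  df$rt_min <- as.numeric(df$rt_min)
  df$area <- as.numeric(df$area)
  if (any(df$area < 0, na.rm = TRUE)) stop("negative peak area", call. = FALSE)
  if (any(df$rt_min < 0, na.rm = TRUE)) {
    stop("negative retention time", call. = FALSE)
  }
  lab <- !is.na(df$analyte)
  if (any(lab)) {
    key <- paste(df$sample_id[lab], df$analyte[lab], sep = "\r")
    if (anyDuplicated(key)) {
      stop("analyte labelled more than once within a sample: ",
           paste(unique(sub("\r", "/", key[duplicated(key)])),
                 collapse = ", "), call. = FALSE)
    }
  }
  out <- df[, c("sample_id", "rt_min", "area", "analyte")]
  rownames(out) <- NULL
  class(out) <- c("peak_table", "data.frame")
  out
}

#' Join plate readings to their layout
#'
#' Produces one record per non-blank layout well carrying the well's role
#' annotations and its RLU. Readings for wells absent from the layout are
#' dropped with a warning; a non-blank layout well without a reading is an
#' error.
#'
#' @param readings a `plate_reading`.
#' @param layout a `plate_layout` for the same plate.
#' @return an `annotated_plate`: data frame with `plate_id`, `well`,
#'   `role`, `enzyme`, `substrate`, `donor`, `donor_conc_uM`, `replicate`,
#'   `rlu`.
#' @export
join_layout <- function(readings, layout) {
  stopifnot(inherits(readings, "plate_reading"), inherits(layout, "plate_layout"))
  pid_r <- attr(readings, "plate_id")
  pid_l <- attr(layout, "plate_id")
  if (!identical(pid_r, pid_l)) {
    stop("plate_id mismatch: readings '", pid_r, "' vs layout '", pid_l, "'",
         call. = FALSE)
  }
  lay <- as.data.frame(layout)[layout$role != "blank", , drop = FALSE]
  missing <- setdiff(lay$well, readings$well)
  if (length(missing)) {
    stop("layout well(s) without a reading: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(readings$well, lay$well)
  if (length(extra)) {
    warning("reading(s) for well(s) absent from layout dropped: ",
            paste(extra, collapse = ", "), call. = FALSE)
  }
  idx <- match(lay$well, readings$well)
  out <- cbind(plate_id = pid_l, lay,
               rlu = readings$rlu[idx], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("annotated_plate", "data.frame")
  out
}
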