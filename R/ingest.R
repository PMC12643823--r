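#' Default column map for encounter files
#'
#' Maps the logical fields of an encounter table to the column names used in
#' the input CSV. The defaults match the layout written by
#' [make_study_fixture()]: `individual_id`, `year`, `sex` (coded `M`/`F`/`U`),
#' `age` (`J` for birds first captured in their hatch year, `A` for older
#' birds), and `detections` (number of within-year captures/resights).
#'
#' @param individual_id,year,sex,age,detections column names in the CSV.
#' @return Named character vector usable as the `schema` argument of
#'   [read_encounters()].
#' @export
encounter_schema <- function(individual_id = "individual_id",
                             year = "year",
                             sex = "sex",
                             age = "age",
                             detections = "detections") {
  c(individual_id = individual_id, year = year, sex = sex, age = age,
    detections = detections)
}

#' Read an individual encounter table
#'
#' Reads a CSV of individual-by-year detections and normalises it to one
#' record per (individual, year): duplicate rows are merged by summing their
#' detection counts, sex codes are mapped to `male`/`female`/`unknown`
#' (blank or `NA` sex becomes `unknown`), and age at first capture is made
#' constant per individual.
#'
#' @param path path to a UTF-8 CSV with a header row.
#' @param schema named character vector mapping logical fields to column
#'   names; see [encounter_schema()].
#' @return A data.frame of encounter records with columns `individual_id`
#'   (character), `year` (integer), `sex` (`"male"`, `"female"` or
#'   `"unknown"`), `age_at_first_capture` (`"juvenile"` or `"adult"`), and
#'   `n_detections_in_year` (positive integer).
#' @export
read_encounters <- function(path, schema = encounter_schema()) {
  if (!file.exists(path)) stop("encounter file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  missing_cols <- setdiff(unname(schema), names(raw))
  if (length(missing_cols) > 0) {
    stop("encounter file is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df <- data.frame(
    individual_id = trimws(raw[[schema[["individual_id"]]]]),
    year_raw      = trimws(raw[[schema[["year"]]]]),
    sex_raw       = trimws(raw[[schema[["sex"]]]]),
    age_raw       = trimws(raw[[schema[["age"]]]]),
    det_raw       = trimws(raw[[schema[["detections"]]]]),
    stringsAsFactors = FALSE
  )

  year <- suppressWarnings(as.integer(df$year_raw))
  bad_year <- which(is.na(year) | as.character(year) != df$year_raw)
  if (length(bad_year) > 0) {
    stop("non-integer year at data row(s): ",
         paste(utils::head(bad_year, 10), collapse = ", "))
  }
  det <- suppressWarnings(as.integer(df$det_raw))
  det[df$det_raw == ""] <- 1L  # a bare record counts as one detection
  bad_det <- which(is.na(det) | det < 0)
  if (length(bad_det) > 0) {
    stop("non-integer or negative detection count at data row(s): ",
         paste(utils::head(bad_det, 10), collapse = ", "))
  }

  sex <- decode_sex(df$sex_raw)
  age <- decode_age(df$age_raw)

  rec <- data.frame(
    individual_id = df$individual_id,
    year = year,
    sex = sex,
    age_at_first_capture = age,
    n_detections_in_year = det,
    stringsAsFactors = FALSE
  )
  rec <- rec[rec$n_detections_in_year > 0, , drop = FALSE]

  # merge duplicate (individual, year) rows, summing detections
  key <- paste(rec$individual_id, rec$year, sep = "\r")
  if (anyDuplicated(key)) {
    det_sum <- tapply(rec$n_detections_in_year, key, sum)
    first <- rec[!duplicated(key), , drop = FALSE]
    first$n_detections_in_year <- as.integer(det_sum[paste(
      first$individual_id, first$year, sep = "\r")])
    rec <- first
  }

  rec <- resolve_individual_metadata(rec)
  rec <- rec[order(rec$individual_id, rec$year), , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

decode_sex <- function(x) {
  out <- rep("unknown", length(x))
  up <- toupper(x)
  out[up %in% c("M", "MALE")] <- "male"
  out[up %in% c("F", "FEMALE")] <- "female"
  bad <- !(up %in% c("M", "MALE", "F", "FEMALE", "U", "UNK", "UNKNOWN", "",
                     "NA"))
  if (any(bad)) {
    stop("unrecognised sex code(s): ",
         paste(unique(x[bad]), collapse = ", "))
  }
  out
}

decode_age <- function(x) {
  up <- toupper(x)
  out <- rep(NA_character_, length(x))
  out[up %in% c("J", "JUV", "JUVENILE")] <- "juvenile"
  out[up %in% c("A", "AD", "ADULT")] <- "adult"
  if (anyNA(out)) {
    stop("unrecognised age code(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "))
  }
  out
}

# Enforce per-individual constancy: sex, once known, is constant; age at
# first capture is taken from the earliest record (a bird first caught as a
# juvenile stays in the juvenile-marked group for life).
resolve_individual_metadata <- function(rec) {
  rec <- rec[order(rec$individual_id, rec$year), , drop = FALSE]
  for (id in unique(rec$individual_id[duplicated(rec$individual_id)])) {
    idx <- which(rec$individual_id == id)
    known <- setdiff(unique(rec$sex[idx]), "unknown")
    if (length(known) > 1) {
      stop("individual ", id, " recorded with conflicting sexes: ",
           paste(known, collapse = ", "))
    }
    if (length(known) == 1) rec$sex[idx] <- known
    rec$age_at_first_capture[idx] <- rec$age_at_first_capture[idx[1]]
  }
  rec
}

#' Randomly assign a sex to unknown-sex juveniles
#'
#' Juveniles whose sex was never determined are assigned `male` or `female`
#' with equal probability (a 1:1 offspring sex ratio), reproducibly for a
#' given seed. Adults of unknown sex are not eligible: the capture-history
#' model groups adults by sex, and an adult whose sex was never determined
#' cannot be placed in a group.
#'
#' @param records encounter records from [read_encounters()].
#' @param seed integer seed for the assignment.
#' @return Records with every `sex` equal to `"male"` or `"female"`; known
#'   sexes are untouched.
#' @export
assign_unknown_sex <- function(records, seed) {
  unk <- records$sex == "unknown"
  if (!any(unk)) return(records)
  if (any(records$age_at_first_capture[unk] != "juvenile")) {
    bad <- unique(records$individual_id[unk &
                    records$age_at_first_capture != "juvenile"])
    stop("adult(s) of unknown sex cannot be assigned a sex: ",
         paste(utils::head(bad, 10), collapse = ", "),
         "; drop them from the history data instead")
  }
  ids <- sort(unique(records$individual_id[unk]))
  drawn <- with_seed(seed, sample(c("male", "female"), length(ids),
                                  replace = TRUE))
  names(drawn) <- ids
  records$sex[unk] <- drawn[records$individual_id[unk]]
  records
}

#' Build a capture-history matrix from encounter records
#'
#' Collapses within-year detections to annual binary occasions: one row per
#' individual, 1 wherever the bird was detected at least once that year.
#' Each individual is labelled with its group, the combination of sex and
#' age class at first capture, which indexes the group-specific survival and
#' recapture parameters of the CJS model. Adults of unknown sex are excluded
#' (with a warning) because they cannot be grouped.
#'
#' @param records resolved encounter records (no unknown-sex juveniles).
#' @param years optional integer vector of study years (defaults to the full
#'   observed range).
#' @return A list of class `capture_histories` with elements `histories`
#'   (individuals x years 0/1 matrix, rownames = individual ids, colnames =
#'   years), `first_occasion` (integer index of first capture per
#'   individual), and `group` (factor with levels
#'   `juvenile_male`, `juvenile_female`, `adult_male`, `adult_female`).
#' @export
build_capture_histories <- function(records, years = NULL) {
  rec <- records
  drop <- rec$sex == "unknown" & rec$age_at_first_capture == "adult"
  if (any(drop)) {
    warning(sum(drop), " record(s) of unknown-sex adults excluded from ",
            "capture histories")
    rec <- rec[!drop, , drop = FALSE]
  }
  if (any(rec$sex == "unknown")) {
    stop("unknown-sex juveniles remain; run assign_unknown_sex() first")
  }
  if (is.null(years)) years <- seq(min(rec$year), max(rec$year))
  rec <- rec[rec$year %in% years, , drop = FALSE]
  if (nrow(rec) == 0) stop("no records within the requested years")

  ids <- sort(unique(rec$individual_id))
  H <- matrix(0L, nrow = length(ids), ncol = length(years),
              dimnames = list(ids, years))
  H[cbind(match(rec$individual_id, ids), match(rec$year, years))] <- 1L

  first <- apply(H, 1, function(r) which(r == 1L)[1])
  ord <- order(rec$individual_id, rec$year)
  rec1 <- rec[ord, , drop = FALSE]
  rec1 <- rec1[!duplicated(rec1$individual_id), , drop = FALSE]
  grp <- paste(rec1$age_at_first_capture, rec1$sex, sep = "_")
  names(grp) <- rec1$individual_id
  group <- factor(grp[ids],
                  levels = c("juvenile_male", "juvenile_female",
                             "adult_male", "adult_female"))

  structure(list(histories = H,
                 first_occasion = as.integer(first),
                 group = group,
                 years = as.integer(years)),
            class = "capture_histories")
}

#' Annual population counts from encounter records
#'
#' The annual count is the number of distinct individuals (adults and
#' juveniles, including unknown-sex birds) detected at least once in that
#' year's breeding season.
#'
#' @param records encounter records.
#' @param years optional integer vector of study years.
#' @return data.frame with columns `year` and `count`.
#' @export
build_counts <- function(records, years = NULL) {
  if (is.null(years)) years <- seq(min(records$year), max(records$year))
  count <- vapply(years, function(y) {
    length(unique(records$individual_id[records$year == y &
                                          records$n_detections_in_year > 0]))
  }, integer(1))
  data.frame(year = as.integer(years), count = count)
}

#' Annual productivity table
#'
#' Returns, per year, the number of breeding females observed (`B`) and the
#' number of juveniles recorded (`J`). If `nest_table` is supplied it is
#' validated and used directly (this is the usual route: the juvenile count
#' comes from nest monitoring, which finds only a fraction of broods — the
#' fecundity denominator in the IPM absorbs that). Otherwise both counts are
#' derived from the encounter records: `B` = adult females detected, `J` =
#' juveniles detected.
#'
#' @param records encounter records (used when `nest_table` is `NULL`).
#' @param nest_table optional data.frame with columns `year`, `females`,
#'   `juveniles`.
#' @param years optional integer vector of study years.
#' @return data.frame with columns `year`, `B` (females), `J` (juveniles).
#' @export
build_productivity <- function(records = NULL, nest_table = NULL,
                               years = NULL) {
  if (!is.null(nest_table)) {
    req <- c("year", "females", "juveniles")
    if (!all(req %in% names(nest_table))) {
      stop("nest_table needs columns: ", paste(req, collapse = ", "))
    }
    if (any(nest_table$females < 0) || any(nest_table$juveniles < 0)) {
      stop("negative counts in nest_table")
    }
    out <- data.frame(year = as.integer(nest_table$year),
                      B = as.integer(nest_table$females),
                      J = as.integer(nest_table$juveniles))
    return(out[order(out$year), ])
  }
  if (is.null(records)) stop("supply records or nest_table")
  if (is.null(years)) years <- seq(min(records$year), max(records$year))
  # age in year y: a bird first captured as a juvenile is a juvenile only in
  # its first capture year and an adult in any later year
  first_year <- tapply(records$year, records$individual_id, min)
  is_juv <- records$age_at_first_capture == "juvenile" &
    records$year == first_year[records$individual_id]
  B <- vapply(years, function(y) {
    length(unique(records$individual_id[
      records$year == y & !is_juv & records$sex == "female"]))
  }, integer(1))
  J <- vapply(years, function(y) {
    length(unique(records$individual_id[records$year == y & is_juv]))
  }, integer(1))
  data.frame(year = as.integer(years), B = B, J = J)
}

# Run expr under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
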