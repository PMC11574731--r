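# Domain tables: encounters, populations, category metadata, share vectors.
# All tables are data.tables carrying a light S3 class for dispatch and
# validation; zip codes are opaque strings (leading zeros preserved).

.required_encounter_cols <- c("year", "zip", "age", "sex", "category_id",
                              "hospital_id")
.optional_encounter_cols <- c("payer", "race", "cost", "los_days", "died",
                              "elective")
.payer_levels <- c("medicare", "medicaid", "private", "self", "other")
.race_levels  <- c("white", "black", "hispanic", "other")

#' Default age bands for population stratification
#'
#' Contiguous, exhaustive age intervals used to stratify both the
#' population denominators and encounter ages. The upper band is open
#' (`"75+"`).
#'
#' @return Character vector of band labels, e.g. `"0-17"`.
#' @export
default_age_bands <- function() c("0-17", "18-44", "45-64", "65-74", "75+")

# Parse band labels like "0-17", "75+" into lower bounds; returns a
# data.table(age_band, lo, hi) with hi = Inf for the open band.
parse_age_bands <- function(bands) {
  bands <- as.character(unique(bands))
  open <- grepl("\\+$", bands)
  lo <- suppressWarnings(ifelse(open, as.numeric(sub("\\+$", "", bands)),
                                as.numeric(sub("-.*$", "", bands))))
  hi <- suppressWarnings(ifelse(open, Inf,
                                as.numeric(sub("^.*-", "", bands))))
  if (anyNA(lo) || anyNA(hi))
    stop("unparseable age band label(s): ",
         paste(bands[is.na(lo) | is.na(hi)], collapse = ", "))
  out <- data.table(age_band = bands, lo = lo, hi = hi)
  setorder(out, lo)
  if (any(out$lo[-1] != out$hi[-nrow(out)] + 1))
    stop("age bands must be contiguous: ", paste(bands, collapse = ", "))
  out[]
}

# Assign integer ages to band labels; ages outside all bands become NA.
assign_age_band <- function(age, bands) {
  spec <- parse_age_bands(bands)
  lab <- rep(NA_character_, length(age))
  for (i in seq_len(nrow(spec))) {
    sel <- !is.na(age) & age >= spec$lo[i] & age <= spec$hi[i]
    lab[sel] <- spec$age_band[i]
  }
  lab
}

# Read a delimited table (comma or tab; dialect auto-detected) with all
# columns as character so zip codes keep leading zeros; typed coercion
# happens per schema afterwards.
read_delim_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  fread(path, colClasses = "character", header = TRUE, sep = "auto",
        na.strings = c("", "NA"))
}

# Resolve a schema_config (named list canonical -> file column, or a YAML
# file path) against the columns present in `dt`, renaming in place.
apply_schema_config <- function(dt, schema_config) {
  if (is.null(schema_config)) return(dt)
  if (is.character(schema_config) && length(schema_config) == 1L)
    schema_config <- yaml::read_yaml(schema_config)
  stopifnot(is.list(schema_config))
  for (canonical in names(schema_config)) {
    src <- schema_config[[canonical]]
    if (src %in% names(dt)) setnames(dt, src, canonical)
  }
  dt
}

as_logical_col <- function(x) {
  if (is.logical(x)) return(x)
  lx <- tolower(as.character(x))
  out <- rep(NA, length(x))
  out[lx %in% c("true", "t", "1", "yes")] <- TRUE
  out[lx %in% c("false", "f", "0", "no")] <- FALSE
  out
}

#' Read and validate an encounter-level discharge table
#'
#' One row per hospital discharge. Required columns: `year`, `zip`, `age`,
#' `sex` (F/M), `category_id`, `hospital_id`; optional columns `payer`,
#' `race`, `cost`, `los_days`, `died`, `elective` are typed and kept when
#' present. Rows failing row-level validation (unparseable age, sex outside
#' \{F, M\}, missing zip, negative cost or length of stay) are dropped,
#' counted in the `n_rejected` attribute, and summarized in a message. A
#' missing required column is a schema error naming the column.
#'
#' @param path Path to a CSV/TSV file with a header row.
#' @param schema_config Optional column-name remapping: a named list (or a
#'   YAML file of one) mapping canonical names to the file's column names,
#'   e.g. `list(zip = "ZIP5", category_id = "ccsr")`.
#' @return An `encounter_table` (a data.table) with attribute `n_rejected`.
#' @export
read_encounters <- function(path, schema_config = NULL) {
  dt <- read_delim_table(path)
  apply_schema_config(dt, schema_config)
  as_encounter_table(dt)
}

#' Coerce and validate an in-memory encounter table
#'
#' @param dt A data.frame/data.table with the columns of [read_encounters()].
#' @return A validated `encounter_table`.
#' @export
as_encounter_table <- function(dt) {
  dt <- as.data.table(dt)
  missing_cols <- setdiff(.required_encounter_cols, names(dt))
  if (length(missing_cols))
    stop("encounter table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  n0 <- nrow(dt)
  dt[, year := suppressWarnings(as.integer(year))]
  dt[, age := suppressWarnings(as.integer(as.numeric(age)))]
  dt[, sex := toupper(trimws(as.character(sex)))]
  dt[, zip := trimws(as.character(zip))]
  dt[, category_id := as.character(category_id)]
  dt[, hospital_id := as.character(hospital_id)]
  ok <- !is.na(dt$year) & !is.na(dt$age) & dt$age >= 0L &
    dt$sex %in% c("F", "M") & !is.na(dt$zip) & nzchar(dt$zip) &
    !is.na(dt$category_id) & nzchar(dt$category_id) &
    !is.na(dt$hospital_id) & nzchar(dt$hospital_id)
  for (col in c("cost", "los_days")) if (col %in% names(dt)) {
    dt[, (col) := suppressWarnings(as.numeric(get(col)))]
    ok <- ok & (is.na(dt[[col]]) | dt[[col]] >= 0)
  }
  if ("los_days" %in% names(dt)) dt[, los_days := as.integer(los_days)]
  for (col in c("died", "elective")) if (col %in% names(dt))
    dt[, (col) := as_logical_col(get(col))]
  if ("payer" %in% names(dt)) dt[, payer := tolower(as.character(payer))]
  if ("race" %in% names(dt)) dt[, race := tolower(as.character(race))]
  out <- dt[ok]
  n_rejected <- n0 - nrow(out)
  if (n_rejected > 0)
    message(sprintf("encounter validation: rejected %d of %d row(s)",
                    n_rejected, n0))
  setattr(out, "n_rejected", n_rejected)
  setattr(out, "class", c("encounter_table", class(out)))
  out[]
}

#' Read and validate a zip-level population table
#'
#' Columns: `zip`, `age_band`, `sex`, `population`. (zip, age_band, sex)
#' must be unique, populations nonnegative integers, age bands contiguous.
#'
#' @inheritParams read_encounters
#' @return A `population_table` (a data.table).
#' @export
read_population <- function(path, schema_config = NULL) {
  dt <- read_delim_table(path)
  apply_schema_config(dt, schema_config)
  as_population_table(dt)
}

#' Coerce and validate an in-memory population table
#' @param dt A data.frame/data.table with `zip`, `age_band`, `sex`,
#'   `population`.
#' @return A validated `population_table`.
#' @export
as_population_table <- function(dt) {
  dt <- as.data.table(dt)
  need <- c("zip", "age_band", "sex", "population")
  missing_cols <- setdiff(need, names(dt))
  if (length(missing_cols))
    stop("population table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  dt[, zip := trimws(as.character(zip))]
  dt[, age_band := as.character(age_band)]
  dt[, sex := toupper(trimws(as.character(sex)))]
  dt[, population := suppressWarnings(as.numeric(population))]
  if (anyNA(dt$population) || any(dt$population < 0))
    stop("population must be a nonnegative number for every stratum")
  if (!all(dt$sex %in% c("F", "M")))
    stop("population sex must be F or M")
  parse_age_bands(dt$age_band)  # errors if malformed / non-contiguous
  if (anyDuplicated(dt, by = c("zip", "age_band", "sex")))
    stop("(zip, age_band, sex) must be unique in the population table")
  setattr(dt, "class", c("population_table", class(dt)))
  dt[]
}

#' Read and validate the procedure-category metadata table
#'
#' Columns: `category_id`, `label`, `minimally_invasive`, `era_new`
#' (introduced in the 1990s or later), `device_implant`. The flags are
#' consumed as supplied metadata, never derived here.
#'
#' @inheritParams read_encounters
#' @return A `category_metadata` table.
#' @export
read_category_metadata <- function(path, schema_config = NULL) {
  dt <- read_delim_table(path)
  apply_schema_config(dt, schema_config)
  as_category_metadata(dt)
}

#' Coerce and validate in-memory category metadata
#' @param dt A data.frame/data.table with `category_id`, `label`, and the
#'   boolean flags `minimally_invasive`, `era_new`, `device_implant`.
#' @return A validated `category_metadata` table.
#' @export
as_category_metadata <- function(dt) {
  dt <- as.data.table(dt)
  need <- c("category_id", "label", "minimally_invasive", "era_new",
            "device_implant")
  missing_cols <- setdiff(need, names(dt))
  if (length(missing_cols))
    stop("category metadata is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  dt[, category_id := as.character(category_id)]
  if (anyDuplicated(dt$category_id))
    stop("category_id must be unique in the metadata table")
  for (col in c("minimally_invasive", "era_new", "device_implant"))
    dt[, (col) := as_logical_col(get(col))]
  setattr(dt, "class", c("category_metadata", class(dt)))
  dt[]
}

#' Construct a share vector over zip codes
#'
#' Nonnegative weights over zips summing to 1 (within 1e-9): the container
#' for observed utilization shares and for the expected-utilization
#' reference.
#'
#' @param zip Character vector of unique zip codes.
#' @param share Numeric weights, nonnegative, summing to 1.
#' @return A `share_vector` data.table with columns `zip`, `share`.
#' @export
share_vector <- function(zip, share) {
  zip <- as.character(zip)
  share <- as.numeric(share)
  if (length(zip) != length(share)) stop("zip and share lengths differ")
  if (anyDuplicated(zip)) stop("share vector zips must be unique")
  if (anyNA(share) || any(share < 0))
    stop("shares must be nonnegative and non-missing")
  if (abs(sum(share) - 1) > 1e-9)
    stop(sprintf("shares must sum to 1 (got %.12f)", sum(share)))
  out <- data.table(zip = zip, share = share)
  setattr(out, "class", c("share_vector", class(out)))
  out[]
}

is_share_vector <- function(x) inherits(x, "share_vector")

#' Cross-table consistency report
#'
#' Checks that every encounter zip appears in the population table and
#' every encounter category in the metadata table. The report is
#' informational (no error is raised); `ok` is TRUE iff both lists are
#' empty.
#'
#' @param enc An `encounter_table`.
#' @param pop A `population_table`.
#' @param meta A `category_metadata` table.
#' @return A `pai_validation` list with `unknown_zips`,
#'   `unknown_categories`, `ok`.
#' @export
validate_consistency <- function(enc, pop, meta) {
  unknown_zips <- sort(setdiff(unique(enc$zip), unique(pop$zip)))
  unknown_categories <- sort(setdiff(unique(enc$category_id),
                                     unique(meta$category_id)))
  structure(list(unknown_zips = unknown_zips,
                 unknown_categories = unknown_categories,
                 ok = length(unknown_zips) == 0L &&
                   length(unknown_categories) == 0L),
            class = "pai_validation")
}

#' @export
print.pai_validation <- function(x, ...) {
  if (x$ok) {
    cat("consistency check: OK\n")
  } else {
    cat("consistency check: FAILED\n")
    if (length(x$unknown_zips))
      cat("  zips absent from population table:",
          paste(x$unknown_zips, collapse = ", "), "\n")
    if (length(x$unknown_categories))
      cat("  categories absent from metadata:",
          paste(x$unknown_categories, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a result table as CSV
#'
#' Plain RFC-4180 CSV with a header row; doubles are written with full
#' round-trip precision so write-then-read reproduces values exactly.
#'
#' @param x A data.frame/data.table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result <- function(x, path) {
  fwrite(as.data.table(x), path)
  invisible(path)
}
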