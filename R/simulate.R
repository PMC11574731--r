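# Synthetic encounter-data generator with known ground truth. The world:
# zips on a unit square with log-normal populations split by a fixed
# national age-sex profile; hospitals on the same square; each procedure
# category offered by a subset of hospitals; zip-level demand is Poisson
# with mean = population x stratum rate, attenuated by
# exp(-access_decay x distance to the nearest offering hospital).
# Suppressed demand is lost (forgone care), not redistributed; patients
# are assigned to their nearest offering hospital.

.sim_age_weights <- c("0-17" = 0.22, "18-44" = 0.35, "45-64" = 0.26,
                      "65-74" = 0.10, "75+" = 0.07)
.sim_age_mult <- c("0-17" = 0.3, "18-44" = 0.6, "45-64" = 1.0,
                   "65-74" = 1.6, "75+" = 2.0)
.sim_female_share <- 0.51

#' Configuration for the synthetic encounter simulator
#'
#' Defaults describe a desk-scale analog of a multi-state discharge
#' extract: 200 zips with log-normally distributed populations (median
#' 10 000, sigma 1), 40 hospitals, 8 procedure categories observed over
#' 2016-2019, full offering and no distance gating (the null world).
#'
#' @param n_zips,n_hospitals,n_categories Counts (all >= 1).
#' @param years Integer vector of calendar years.
#' @param zip_pop_median,zip_pop_sigma Log-normal law for zip populations.
#' @param stratum_rate_profiles Optional data.table `(category_id,
#'   age_band, sex, rate)` of per-person-per-year utilization rates; when
#'   NULL, profiles are drawn per category (log-normal base rate around
#'   2e-4, age multipliers rising with age, a mild sex tilt).
#' @param offering_fraction Fraction of hospitals offering each category,
#'   in (0, 1]; scalar or one value per category.
#' @param access_decay Distance-gating strength (>= 0); 0 disables gating.
#' @param offering_growth Per-year multiplicative growth of the offering
#'   fraction (default 0: offering sets fixed over time). Positive values
#'   emulate staged roll-out of a new procedure across hospitals; the
#'   sets are nested so a hospital never stops offering.
#' @param target_volume Optional expected encounters per category per year
#'   before gating; rates are rescaled to hit it (scalar or per category).
#' @param seed Integer seed; a fixed seed gives bit-identical output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_zips = 200L, n_hospitals = 40L, n_categories = 8L,
                       years = 2016:2019, zip_pop_median = 10000,
                       zip_pop_sigma = 1, stratum_rate_profiles = NULL,
                       offering_fraction = 1, access_decay = 0,
                       offering_growth = 0, target_volume = NULL,
                       seed = 1L) {
  stopifnot(n_zips >= 1, n_hospitals >= 1, n_categories >= 1,
            length(years) >= 1, zip_pop_median > 0, zip_pop_sigma >= 0,
            access_decay >= 0, offering_growth >= 0)
  offering_fraction <- rep_len(offering_fraction, n_categories)
  if (any(offering_fraction <= 0) || any(offering_fraction > 1))
    stop("offering_fraction must be in (0, 1]")
  if (!is.null(target_volume)) {
    target_volume <- rep_len(target_volume, n_categories)
    stopifnot(all(target_volume > 0))
  }
  structure(list(n_zips = as.integer(n_zips),
                 n_hospitals = as.integer(n_hospitals),
                 n_categories = as.integer(n_categories),
                 years = as.integer(years),
                 zip_pop_median = zip_pop_median,
                 zip_pop_sigma = zip_pop_sigma,
                 stratum_rate_profiles = stratum_rate_profiles,
                 offering_fraction = offering_fraction,
                 access_decay = access_decay,
                 offering_growth = offering_growth,
                 target_volume = target_volume,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Draw ages uniformly within a band; the open band is truncated at 94.
sample_age_in_band <- function(band, n) {
  spec <- parse_age_bands(unique(band))
  lo <- spec$lo[match(band, spec$age_band)]
  hi <- pmin(spec$hi[match(band, spec$age_band)], 94)
  lo + floor(runif(n) * (hi - lo + 1))
}

#' Simulate encounter, population, and metadata tables
#'
#' Generates the three pipeline inputs plus a ground-truth record of every
#' latent quantity (coordinates, offering sets, distances, rates, expected
#' demand). Optional encounter columns (payer, race, cost, los_days, died,
#' elective) are drawn with plausible but simple categorical laws so that
#' tercile-style summaries have material to work with.
#'
#' @param config A [sim_config()].
#' @return A `pai_sim` list: `encounters`, `population`, `metadata`,
#'   `truth` (itself a list of `zips`, `hospitals`, `offerings`, `rates`,
#'   `access` per category-zip, `expected_volume` per category).
#' @export
simulate_encounters <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(config$seed)
  bands <- default_age_bands()

  zips <- data.table(
    zip = sprintf("Z%04d", seq_len(config$n_zips)),
    x = runif(config$n_zips), y = runif(config$n_zips),
    pop_total = pmax(100, round(rlnorm(config$n_zips,
                                       log(config$zip_pop_median),
                                       config$zip_pop_sigma))))
  strata <- CJ(age_band = bands, sex = c("F", "M"), sorted = FALSE)
  strata[, w := .sim_age_weights[age_band] *
           fifelse(sex == "F", .sim_female_share, 1 - .sim_female_share)]
  ns <- nrow(strata)
  pop <- data.table(
    zip = rep(zips$zip, each = ns),
    age_band = rep(strata$age_band, times = config$n_zips),
    sex = rep(strata$sex, times = config$n_zips),
    population = round(rep(zips$pop_total, each = ns) *
                         rep(strata$w, times = config$n_zips)))
  population <- as_population_table(pop)

  hospitals <- data.table(
    hospital_id = sprintf("H%03d", seq_len(config$n_hospitals)),
    x = runif(config$n_hospitals), y = runif(config$n_hospitals))

  cat_ids <- sprintf("C%03d", seq_len(config$n_categories))
  metadata <- as_category_metadata(data.table(
    category_id = cat_ids,
    label = sprintf("Synthetic procedure %s", cat_ids),
    minimally_invasive = runif(config$n_categories) < 0.5,
    era_new = runif(config$n_categories) < 0.35,
    device_implant = runif(config$n_categories) < 0.4))

  rates <- config$stratum_rate_profiles
  if (is.null(rates)) {
    base <- rlnorm(config$n_categories, log(2e-4), 0.7)
    sex_tilt <- runif(config$n_categories, 0.7, 1.3)
    rates <- CJ(category_id = cat_ids, age_band = bands, sex = c("F", "M"),
                sorted = FALSE)
    rates[, rate := base[match(category_id, cat_ids)] *
            .sim_age_mult[age_band] *
            fifelse(sex == "F", sex_tilt[match(category_id, cat_ids)],
                    2 - sex_tilt[match(category_id, cat_ids)])]
  } else {
    rates <- as.data.table(rates)
  }
  if (!is.null(config$target_volume)) {
    popstrat <- as.data.table(population)
    base_exp <- merge(popstrat, rates, by = c("age_band", "sex"),
                      allow.cartesian = TRUE)[
                        , .(expected = sum(population * rate)),
                        by = category_id]
    scale <- config$target_volume[match(base_exp$category_id, cat_ids)] /
      base_exp$expected
    rates[, rate := rate * scale[match(category_id, base_exp$category_id)]]
  }

  # per-category offering priority order; in year t the offering set is
  # the first k_t hospitals of the order, with k growing by
  # offering_growth per year (nested sets emulate staged roll-out)
  dist_mat <- outer(zips$x, hospitals$x, "-")^2 +
    outer(zips$y, hospitals$y, "-")^2
  dist_mat <- sqrt(dist_mat)
  priority <- replicate(config$n_categories,
                        sample.int(config$n_hospitals), simplify = FALSE)
  names(priority) <- cat_ids
  year_offset <- config$years - min(config$years)
  offerings <- list()
  access_list <- list()
  base_pop_rates <- merge(as.data.table(population), rates,
                          by = c("age_band", "sex"),
                          allow.cartesian = TRUE)
  enc_list <- vector("list", length(config$years))
  cell_list <- vector("list", length(config$years))
  for (yi in seq_along(config$years)) {
    yr <- config$years[yi]
    access <- vector("list", config$n_categories)
    for (ci in seq_len(config$n_categories)) {
      f <- min(1, config$offering_fraction[ci] *
                 (1 + config$offering_growth)^year_offset[yi])
      k <- max(1L, round(f * config$n_hospitals))
      offer_idx <- priority[[ci]][seq_len(k)]
      offerings[[paste(cat_ids[ci], yr, sep = ".")]] <-
        hospitals$hospital_id[offer_idx]
      sub <- dist_mat[, offer_idx, drop = FALSE]
      nearest <- max.col(-sub, ties.method = "first")
      access[[ci]] <- data.table(
        category_id = cat_ids[ci], year = yr, zip = zips$zip,
        distance = sub[cbind(seq_len(nrow(sub)), nearest)],
        nearest_hospital = hospitals$hospital_id[offer_idx][nearest])
    }
    access <- rbindlist(access)
    access_list[[yi]] <- access
    cell <- merge(base_pop_rates, access, by = c("category_id", "zip"))
    cell[, lambda := population * rate *
           exp(-config$access_decay * distance)]
    cell_list[[yi]] <- cell
    counts <- cell[, .(category_id, zip, age_band, sex, nearest_hospital,
                       n = rpois(.N, lambda))][n > 0]
    rows <- counts[rep(seq_len(.N), n)]
    rows[, `:=`(year = yr, age = sample_age_in_band(age_band, .N))]
    enc_list[[yi]] <- rows[, .(year, zip, age, sex, category_id,
                               hospital_id = nearest_hospital)]
  }
  enc <- rbindlist(enc_list)
  access <- rbindlist(access_list)
  cell <- rbindlist(cell_list)

  # optional patient/procedure characteristics
  n <- nrow(enc)
  cost_base <- rlnorm(config$n_categories, log(20000), 0.5)
  elective_p <- runif(config$n_categories, 0.2, 0.9)
  ci <- match(enc$category_id, cat_ids)
  payer_young <- c("medicaid", "private", "self", "other")
  enc[, payer := fifelse(age >= 65,
                         fifelse(runif(n) < 0.85, "medicare",
                                 sample(payer_young, n, replace = TRUE)),
                         sample(payer_young, n, replace = TRUE,
                                prob = c(0.25, 0.6, 0.08, 0.07)))]
  enc[, race := sample(c("white", "black", "hispanic", "other"), n,
                       replace = TRUE, prob = c(0.62, 0.15, 0.15, 0.08))]
  enc[, cost := round(rlnorm(n, log(cost_base[ci]), 0.4), 2)]
  enc[, los_days := rpois(n, 3L)]
  enc[, died := runif(n) < 0.015]
  enc[, elective := runif(n) < elective_p[ci]]
  encounters <- as_encounter_table(enc)

  expected_volume <- cell[, .(expected = sum(lambda)),
                          by = .(category_id, year)]
  truth <- list(zips = zips[], hospitals = hospitals[],
                offerings = offerings, rates = rates[], access = access[],
                expected_volume = expected_volume[],
                config = config)
  structure(list(encounters = encounters, population = population,
                 metadata = metadata, truth = truth),
            class = "pai_sim")
}

#' Write simulator output as CSV fixtures
#'
#' Writes `encounters.csv`, `population.csv`, `metadata.csv` and two
#' ground-truth files (`truth_access.csv` with per-category zip distances
#' and nearest offering hospital, `truth_volume.csv` with expected volume
#' per category) into `outdir`.
#'
#' @param sim A `pai_sim` from [simulate_encounters()].
#' @param outdir Output directory (created if absent).
#' @return `outdir`, invisibly.
#' @export
write_sim_fixtures <- function(sim, outdir) {
  stopifnot(inherits(sim, "pai_sim"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fwrite(sim$encounters, file.path(outdir, "encounters.csv"))
  fwrite(sim$population, file.path(outdir, "population.csv"))
  fwrite(sim$metadata, file.path(outdir, "metadata.csv"))
  fwrite(sim$truth$access, file.path(outdir, "truth_access.csv"))
  fwrite(sim$truth$expected_volume, file.path(outdir, "truth_volume.csv"))
  invisible(outdir)
}
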