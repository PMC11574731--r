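# Indirect age-sex standardization: population-wide stratum rates applied
# to each zip's stratum populations give the expected-utilization baseline
# that proxies condition prevalence.

#' Population-wide utilization rates by age band and sex
#'
#' Computes rate(a, s) = events in stratum (a, s) across all zips divided by
#' the total population of that stratum. With
#' `mode = "all_hospitalizations"` every encounter counts (the baseline used
#' for the PAI = 0 reference); with `mode = "category_specific"` only
#' encounters of `category_id` count, giving a condition-prevalence proxy
#' specific to that procedure.
#'
#' Sparse category-specific strata can optionally fall back to pooled
#' rates: strata with fewer than `min_events` category events take their
#' rate from `fallback` (typically the all-hospitalizations rates).
#'
#' @param enc An `encounter_table` (already filtered to the year of
#'   interest if a per-year baseline is wanted).
#' @param pop A `population_table`; its age bands define the strata.
#' @param mode `"all_hospitalizations"` (default) or `"category_specific"`.
#' @param category_id Category to restrict to when
#'   `mode = "category_specific"`.
#' @param min_events Minimum events per stratum before falling back.
#' @param fallback Optional `stratum_rates` table used below `min_events`.
#' @return A `stratum_rates` data.table: `age_band`, `sex`, `rate`
#'   (events per person per year), one row per stratum in `pop`.
#' @export
stratum_rates <- function(enc, pop,
                          mode = c("all_hospitalizations",
                                   "category_specific"),
                          category_id = NULL,
                          min_events = 0L, fallback = NULL) {
  mode <- match.arg(mode)
  if (mode == "category_specific") {
    if (is.null(category_id))
      stop("category_id is required for mode = 'category_specific'")
    cid <- category_id
    enc <- enc[enc$category_id == cid]
  }
  bands <- unique(pop$age_band)
  ev <- as.data.table(enc)[, .(age, sex)]
  ev[, age_band := assign_age_band(age, bands)]
  n_unbanded <- sum(is.na(ev$age_band))
  if (n_unbanded > 0)
    message(sprintf("stratum_rates: %d encounter(s) outside the age bands",
                    n_unbanded))
  counts <- ev[!is.na(age_band), .(events = .N), by = .(age_band, sex)]
  denom <- as.data.table(pop)[, .(population = sum(population)),
                              by = .(age_band, sex)]
  out <- merge(denom, counts, by = c("age_band", "sex"), all.x = TRUE)
  out[is.na(events), events := 0L]
  bad <- out[events > 0 & population <= 0]
  if (nrow(bad))
    stop("stratum with events but zero population: ",
         paste(sprintf("(%s, %s)", bad$age_band, bad$sex), collapse = ", "))
  out[, rate := fifelse(population > 0, events / population, 0)]
  if (min_events > 0L && !is.null(fallback)) {
    fb <- as.data.table(fallback)[, .(age_band, sex, fb_rate = rate)]
    out <- merge(out, fb, by = c("age_band", "sex"), all.x = TRUE)
    out[events < min_events & !is.na(fb_rate), rate := fb_rate]
    out[, fb_rate := NULL]
  }
  out <- out[, .(age_band, sex, rate)]
  setorder(out, age_band, sex)
  setattr(out, "class", c("stratum_rates", class(out)))
  out[]
}

#' Expected event counts per zip under indirect standardization
#'
#' expected(z) = sum over strata of pop(z, a, s) * rate(a, s): the event
#' count a zip would see if stratum-specific rates were geographically
#' uniform, so that differences across zips reflect only population size
#' and age-sex composition.
#'
#' @param rates A `stratum_rates` table covering every stratum in `pop`.
#' @param pop A `population_table`.
#' @return An `expected_counts` data.table: `zip`, `expected`, one row per
#'   zip in `pop`.
#' @export
expected_counts <- function(rates, pop) {
  p <- as.data.table(pop)
  r <- as.data.table(rates)
  missing_strata <- p[!r, on = c("age_band", "sex")]
  if (nrow(missing_strata))
    stop("rates missing for stratum/strata present in the population: ",
         paste(unique(sprintf("(%s, %s)", missing_strata$age_band,
                              missing_strata$sex)), collapse = ", "))
  m <- merge(p, r, by = c("age_band", "sex"))
  out <- m[, .(expected = sum(population * rate)), by = zip]
  setorder(out, zip)
  setattr(out, "class", c("expected_counts", class(out)))
  out[]
}

#' Reference (baseline) shares from expected counts
#'
#' Normalizes expected counts into the reference distribution against
#' which observed procedure shares are compared; this distribution defines
#' PAI = 0 ("perfect equality").
#'
#' @param exp_counts An `expected_counts` table with positive total.
#' @return A [share_vector()] over the zips of `exp_counts`.
#' @export
reference_shares <- function(exp_counts) {
  tot <- sum(exp_counts$expected)
  if (!is.finite(tot) || tot <= 0)
    stop("degenerate input: total expected count must be positive")
  share_vector(exp_counts$zip, exp_counts$expected / tot)
}
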