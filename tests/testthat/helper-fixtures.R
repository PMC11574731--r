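# Shared fixtures and independent oracles. Oracles are written long-hand
# (explicit loops, no package internals) so they stay independent of the
# code paths they check.

library(data.table)

# Encounter rows from parallel vectors (recycled).
make_enc <- function(year = 2019, zip = "Z1", age = 50, sex = "F",
                     category_id = "C1", hospital_id = "H1") {
  as_encounter_table(data.table(year = year, zip = zip, age = age,
                                sex = sex, category_id = category_id,
                                hospital_id = hospital_id))
}

# Population table with one adult stratum per sex and a fixed 50/50 split,
# for tests where age-sex structure is irrelevant.
make_pop <- function(zips, totals) {
  rows <- list()
  for (i in seq_along(zips)) {
    for (s in c("F", "M")) {
      rows[[length(rows) + 1L]] <- data.table(
        zip = zips[i], age_band = "0-74", sex = s,
        population = totals[i] / 2)
    }
  }
  as_population_table(rbindlist(rows))
}

make_meta <- function(ids, mi = FALSE, era = FALSE, dev = FALSE) {
  as_category_metadata(data.table(
    category_id = ids, label = paste("cat", ids),
    minimally_invasive = rep_len(mi, length(ids)),
    era_new = rep_len(era, length(ids)),
    device_implant = rep_len(dev, length(ids))))
}

# Long-hand PAI oracle on integer zip counts and a reference share vector
# (named numeric). Share-concentration functional, written as explicit
# loops over zips.
oracle_pai <- function(counts, ref) {
  total <- 0
  for (z in names(counts)) total <- total + counts[[z]]
  d_real <- 0
  for (z in names(counts)) d_real <- d_real + (counts[[z]] / total)^2
  d_base <- 0
  for (z in names(ref)) d_base <- d_base + ref[[z]]^2
  (d_real - d_base) / (1 - d_base)
}

# Long-hand HHI oracle on hospital volumes (percent-share-squared scale).
oracle_hhi <- function(volumes) {
  total <- sum(volumes)
  out <- 0
  for (v in volumes) out <- out + (100 * v / total)^2
  out
}

# Textbook OLS slope/intercept/correlation on (x, y).
oracle_ols <- function(x, y) {
  xbar <- mean(x); ybar <- mean(y)
  slope <- sum((x - xbar) * (y - ybar)) / sum((x - xbar)^2)
  list(slope = slope, intercept = ybar - slope * xbar,
       correlation = sum((x - xbar) * (y - ybar)) /
         sqrt(sum((x - xbar)^2) * sum((y - ybar)^2)))
}

# Mean PAI of category "C001" across simulator seeds for a given config
# template (list of sim_config args without seed).
mean_pai_over_seeds <- function(sim_args, seeds) {
  vals <- vapply(seeds, function(s) {
    sim_args$seed <- s
    sim <- simulate_encounters(do.call(sim_config, sim_args))
    p <- suppressMessages(pai_by_category_year(sim$encounters,
                                               sim$population,
                                               sim$metadata))
    mean(p$pai)
  }, numeric(1))
  mean(vals)
}
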