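# Hospital-market concentration per procedure category: the
# Herfindahl-Hirschman Index on the percent-share-squared (0-10000) scale,
# matching the convention where equal volumes across 40 hospitals give
# HHI = 250 and across 80 hospitals give 125.

#' Herfindahl-Hirschman Index for one procedure category and year
#'
#' With s_h = 100 * (encounters at hospital h / total encounters),
#' HHI = sum of s_h^2: 10000 for a single-hospital monopoly, 10000/K when
#' K hospitals split the volume equally. Hospitals are pooled across the
#' full data extent (no geographic sub-markets).
#'
#' @param enc An `encounter_table`.
#' @param category_id Procedure category.
#' @param year Calendar year.
#' @param scale `"percent"` (default; 0-10000) or `"fraction"` (0-1).
#' @return A one-row data.table: `category_id`, `year`, `n_hospitals`,
#'   `hhi`.
#' @export
hhi <- function(enc, category_id, year, scale = c("percent", "fraction")) {
  scale <- match.arg(scale)
  cid <- category_id; yr <- year
  sub <- as.data.table(enc)[category_id == cid & year == yr]
  if (nrow(sub) == 0L)
    stop(sprintf("no encounters for category '%s' in year %s", cid, yr))
  vol <- sub[, .N, by = hospital_id]
  s <- vol$N / sum(vol$N)
  if (scale == "percent") s <- 100 * s
  data.table(category_id = cid, year = yr, n_hospitals = nrow(vol),
             hhi = sum(s^2))
}

#' HHI for every procedure category and year
#'
#' @param enc An `encounter_table`.
#' @param min_volume Minimum encounters for a cell to be reported.
#' @param scale See [hhi()].
#' @return A data.table: `category_id`, `year`, `n_hospitals`, `hhi`.
#' @export
hhi_by_category_year <- function(enc, min_volume = 1L,
                                 scale = c("percent", "fraction")) {
  scale <- match.arg(scale)
  enc <- as.data.table(enc)
  vol <- enc[, .N, by = .(category_id, year, hospital_id)]
  out <- vol[, {
    tot <- sum(N)
    s <- N / tot
    if (scale == "percent") s <- 100 * s
    .(n_procedures = tot, n_hospitals = .N, hhi = sum(s^2))
  }, by = .(category_id, year)]
  out <- out[n_procedures >= min_volume]
  out[, n_procedures := NULL]
  setorder(out, category_id, year)
  out[]
}
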