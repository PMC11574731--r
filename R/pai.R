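# The PAI score: normalized gap between the realized dispersion of a
# procedure's patient-residence distribution and the baseline dispersion
# of the age-sex-adjusted expected-utilization distribution.

.functionals <- c("share_concentration", "gini_vs_reference",
                  "theil_vs_reference")

#' Observed utilization shares of a procedure category over zip codes
#'
#' share(z) = encounters of (`category_id`, `year`) with residence zip z,
#' divided by the total. The support is the full zip universe of the
#' population table: zips with zero encounters are retained with share 0
#' (restricting to observed zips would bias the baseline dispersion).
#' Encounters whose zip is absent from the population table cannot be
#' standardized; they are excluded here with a logged count.
#'
#' @param enc An `encounter_table`.
#' @param category_id Procedure category.
#' @param year Calendar year.
#' @param pop A `population_table` defining the zip universe.
#' @return A [share_vector()] over all zips in `pop`, with attribute
#'   `n_encounters` (encounters used) and `n_dropped` (unknown-zip rows).
#' @export
observed_shares <- function(enc, category_id, year, pop) {
  cid <- category_id; yr <- year
  sub <- as.data.table(enc)[category_id == cid & year == yr]
  if (nrow(sub) == 0L)
    stop(sprintf("no encounters for category '%s' in year %s", cid, yr))
  universe <- sort(unique(pop$zip))
  known <- sub$zip %in% universe
  n_dropped <- sum(!known)
  if (n_dropped > 0)
    message(sprintf(
      "observed_shares(%s, %s): dropped %d encounter(s) with unknown zip",
      cid, yr, n_dropped))
  sub <- sub[known]
  if (nrow(sub) == 0L)
    stop(sprintf("all encounters for category '%s' in %s have unknown zips",
                 cid, yr))
  counts <- sub[, .N, by = zip]
  n <- setNames(rep(0, length(universe)), universe)
  n[counts$zip] <- counts$N
  out <- share_vector(universe, n / sum(n))
  setattr(out, "n_encounters", nrow(sub))
  setattr(out, "n_dropped", n_dropped)
  out
}

# Align v (and reference) on a common zip ordering; errors if universes
# differ when both are given.
align_shares <- function(v, reference = NULL) {
  v <- as.data.table(v)
  if (is.null(reference)) {
    setorder(v, zip)
    return(list(v = v$share, r = NULL, zip = v$zip))
  }
  r <- as.data.table(reference)
  if (!setequal(v$zip, r$zip))
    stop("observed and reference share vectors are on different zip universes")
  setorder(v, zip); setorder(r, zip)
  list(v = v$share, r = r$share, zip = v$zip)
}

#' Dispersion of a share vector
#'
#' Three functionals are available. `share_concentration` (the default and
#' the one used throughout the package) is the Simpson/Herfindahl
#' concentration of the shares, sum of v_z^2: it equals 1/K for the uniform
#' distribution over K zips and attains its maximum 1 exactly at a point
#' mass. `gini_vs_reference` is the concentration-curve Gini of `v` against
#' `reference` (0 when v = reference); `theil_vs_reference` is the
#' Kullback-Leibler/Theil divergence sum v_z log(v_z / r_z). The
#' reference-relative functionals require `reference`.
#'
#' @param v A [share_vector()].
#' @param functional One of `"share_concentration"`, `"gini_vs_reference"`,
#'   `"theil_vs_reference"`.
#' @param reference Reference [share_vector()] on the same zip universe
#'   (required for the reference-relative functionals).
#' @return A single dispersion value.
#' @export
dispersion <- function(v, functional = .functionals, reference = NULL) {
  functional <- match.arg(functional)
  if (!is_share_vector(v)) v <- share_vector(v$zip, v$share)
  if (functional == "share_concentration") {
    a <- align_shares(v)
    return(sum(a$v^2))
  }
  if (is.null(reference))
    stop("functional '", functional, "' requires a reference share vector")
  a <- align_shares(v, reference)
  if (functional == "theil_vs_reference") {
    if (any(a$v > 0 & a$r == 0))
      stop("theil_vs_reference undefined: observed mass on a zip with ",
           "zero reference share")
    pos <- a$v > 0
    return(sum(a$v[pos] * log(a$v[pos] / a$r[pos])))
  }
  # gini_vs_reference: concentration-curve Gini. Sort zips by v/r
  # ascending (zips with r = 0, v > 0 sort last); Gini = 1 - sum over
  # segments of (R_k - R_{k-1}) * (V_k + V_{k-1}).
  ratio <- ifelse(a$r > 0, a$v / a$r, ifelse(a$v > 0, Inf, 0))
  ord <- order(ratio, a$v)
  rv <- a$r[ord]; vv <- a$v[ord]
  R <- cumsum(rv); V <- cumsum(vv)
  R0 <- c(0, head(R, -1)); V0 <- c(0, head(V, -1))
  1 - sum((R - R0) * (V + V0))
}

# Maximum attainable dispersion over single-zip point masses, used as the
# normalization ceiling. For share_concentration it is exactly 1; for the
# reference-relative functionals it depends on the reference.
dispersion_max <- function(functional, reference) {
  if (functional == "share_concentration") return(1)
  r <- as.data.table(reference)$share
  rmin <- min(r[r > 0])
  if (functional == "gini_vs_reference") return(1 - rmin)
  log(1 / rmin)  # theil point mass on the smallest positive-reference zip
}

#' The Procedure Access Inequality score
#'
#' With realized dispersion D_real of the observed shares `o`, baseline
#' dispersion D_base of the reference shares `r`, and the point-mass
#' ceiling D_max,
#' \deqn{PAI = (D_{real} - D_{base}) / (D_{max} - D_{base}).}
#' The score is 0 when the observed distribution equals the baseline
#' ("perfect equality": the procedure is distributed like all
#' hospitalizations), 1 when all recipients live in a single zip code
#' ("perfect inequality"), and may be negative when the observed
#' distribution is more uniform than the baseline.
#'
#' An optional finite-sample correction (off by default) replaces each
#' share-concentration dispersion D with (D - 1/n)/(1 - 1/n), `n` being
#' the encounter count.
#'
#' @param o Observed [share_vector()].
#' @param r Reference [share_vector()] on the same zip universe.
#' @param functional Dispersion functional, see [dispersion()].
#' @param bias_correct Apply the finite-sample correction (requires `n`;
#'   `share_concentration` only).
#' @param n Encounter count behind `o`, used only by the correction.
#' @return A list: `d_baseline`, `d_realized`, `pai`, `functional`.
#' @export
compute_pai <- function(o, r, functional = .functionals,
                        bias_correct = FALSE, n = NULL) {
  functional <- match.arg(functional)
  if (!setequal(as.data.table(o)$zip, as.data.table(r)$zip))
    stop("observed and reference share vectors are on different zip universes")
  d_real <- dispersion(o, functional, reference = r)
  d_base <- if (functional == "share_concentration")
    dispersion(r, functional) else 0
  d_max <- dispersion_max(functional, r)
  if (bias_correct) {
    if (functional != "share_concentration")
      stop("bias correction is defined for share_concentration only")
    if (is.null(n) || n <= 1)
      stop("bias correction requires the encounter count n > 1")
    d_real <- (d_real - 1 / n) / (1 - 1 / n)
    d_base <- (d_base - 1 / n) / (1 - 1 / n)
  }
  if (d_max - d_base < 1e-12)
    stop("degenerate normalization: baseline dispersion equals the ",
         "point-mass maximum (reference is a point mass)")
  list(d_baseline = d_base, d_realized = d_real,
       pai = (d_real - d_base) / (d_max - d_base),
       functional = functional)
}

#' Configuration for the PAI pipeline
#'
#' @param functional Dispersion functional, see [dispersion()].
#' @param reference_mode `"all_hospitalizations"` (baseline from every
#'   encounter of the year; the published PAI = 0 condition) or
#'   `"category_specific"` (indirect standardization on the category's own
#'   stratum rates).
#' @param min_volume Minimum encounters for a (category, year) to be
#'   scored; smaller cells are skipped and logged.
#' @param bias_correct Finite-sample correction, see [compute_pai()].
#' @param min_stratum_events Under `category_specific`, strata with fewer
#'   events fall back to all-hospitalizations rates.
#' @return A `pai_config` list.
#' @export
pai_config <- function(functional = "share_concentration",
                       reference_mode = c("all_hospitalizations",
                                          "category_specific"),
                       min_volume = 1L, bias_correct = FALSE,
                       min_stratum_events = 0L) {
  functional <- match.arg(functional, .functionals)
  reference_mode <- match.arg(reference_mode)
  structure(list(functional = functional, reference_mode = reference_mode,
                 min_volume = as.integer(min_volume),
                 bias_correct = isTRUE(bias_correct),
                 min_stratum_events = as.integer(min_stratum_events)),
            class = "pai_config")
}

#' PAI scores for every procedure category and year
#'
#' Runs the full index pipeline: per year, stratum rates and the reference
#' distribution are built from that year's encounters (pooled across
#' categories under `reference_mode = "all_hospitalizations"`, per
#' category otherwise), observed shares are computed over the population
#' zip universe, and the PAI score is evaluated. Deterministic given
#' inputs and config.
#'
#' @param enc An `encounter_table`.
#' @param pop A `population_table`.
#' @param meta A `category_metadata` table (categories absent from it are
#'   still scored; consistency is the caller's concern, see
#'   [validate_consistency()]).
#' @param config A [pai_config()].
#' @return A data.table with one row per scored (category, year):
#'   `category_id`, `year`, `n_procedures`, `n_zips` (zips with at least
#'   one encounter), `d_baseline`, `d_realized`, `pai`, `functional`,
#'   `reference_mode`. Skipped cells are recorded in the `skipped`
#'   attribute.
#' @export
pai_by_category_year <- function(enc, pop, meta = NULL,
                                 config = pai_config()) {
  stopifnot(inherits(config, "pai_config"))
  enc <- as.data.table(enc)
  universe <- sort(unique(pop$zip))
  enc_known <- enc[zip %in% universe]
  n_unknown <- nrow(enc) - nrow(enc_known)
  if (n_unknown > 0)
    message(sprintf(
      "pai_by_category_year: %d encounter(s) with unknown zip excluded",
      n_unknown))
  cells <- enc[, .(n_procedures = .N), by = .(category_id, year)]
  skipped <- cells[n_procedures < config$min_volume]
  cells <- cells[n_procedures >= config$min_volume]
  setorder(cells, category_id, year)
  if (nrow(skipped))
    message(sprintf("pai_by_category_year: skipped %d cell(s) below ",
                    nrow(skipped)), "min_volume = ", config$min_volume)

  rows <- vector("list", nrow(cells))
  for (yr in sort(unique(cells$year))) {
    enc_y <- enc_known[year == yr]
    pooled_rates <- stratum_rates(enc_y, pop, mode = "all_hospitalizations")
    ref_pooled <- reference_shares(expected_counts(pooled_rates, pop))
    idx <- which(cells$year == yr)
    for (i in idx) {
      cid <- cells$category_id[i]
      o <- observed_shares(enc_known, cid, yr, pop)
      r <- if (config$reference_mode == "all_hospitalizations") {
        ref_pooled
      } else {
        cr <- stratum_rates(enc_y, pop, mode = "category_specific",
                            category_id = cid,
                            min_events = config$min_stratum_events,
                            fallback = pooled_rates)
        reference_shares(expected_counts(cr, pop))
      }
      frag <- compute_pai(o, r, functional = config$functional,
                          bias_correct = config$bias_correct,
                          n = attr(o, "n_encounters"))
      rows[[i]] <- data.table(
        category_id = cid, year = yr,
        n_procedures = cells$n_procedures[i],
        n_zips = length(unique(enc_known[category_id == cid & year == yr,
                                         zip])),
        d_baseline = frag$d_baseline, d_realized = frag$d_realized,
        pai = frag$pai, functional = frag$functional,
        reference_mode = config$reference_mode)
    }
  }
  out <- rbindlist(rows)
  setorder(out, category_id, year)
  setattr(out, "skipped", skipped[])
  out[]
}

#' Nonparametric bootstrap confidence interval for one PAI score
#'
#' Resamples encounter rows of the (category, year) cell with replacement,
#' recomputes the score against a fixed reference, and returns the
#' percentile interval. The reference distribution is held fixed: the
#' uncertainty quantified is sampling noise in the observed utilization.
#'
#' @inheritParams observed_shares
#' @param r Reference [share_vector()].
#' @param config A [pai_config()].
#' @param B Bootstrap replicates.
#' @param conf Confidence level.
#' @param seed Optional seed for reproducibility.
#' @return List: `pai`, `lower`, `upper`, `B`, `conf`.
#' @export
pai_bootstrap <- function(enc, category_id, year, pop, r,
                          config = pai_config(), B = 200L, conf = 0.95,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cid <- category_id; yr <- year
  sub <- as.data.table(enc)[category_id == cid & year == yr &
                              zip %in% unique(pop$zip)]
  if (nrow(sub) == 0L)
    stop(sprintf("no encounters for category '%s' in year %s", cid, yr))
  o <- observed_shares(sub, cid, yr, pop)
  point <- compute_pai(o, r, functional = config$functional,
                       bias_correct = config$bias_correct,
                       n = nrow(sub))$pai
  universe <- sort(unique(pop$zip))
  reps <- vapply(seq_len(B), function(b) {
    zips <- sample(sub$zip, nrow(sub), replace = TRUE)
    cnt <- table(factor(zips, levels = universe))
    ob <- share_vector(universe, as.numeric(cnt) / sum(cnt))
    compute_pai(ob, r, functional = config$functional,
                bias_correct = config$bias_correct, n = nrow(sub))$pai
  }, numeric(1))
  alpha <- (1 - conf) / 2
  qs <- unname(quantile(reps, c(alpha, 1 - alpha), type = 7))
  list(pai = point, lower = qs[1], upper = qs[2], B = B, conf = conf)
}
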