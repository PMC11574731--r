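# Analysis surfaces built on the PAI and HHI tables: ranked league table,
# cross-sectional and longitudinal inequality-vs-hospital-count fits,
# percent-difference comparisons, and tercile summaries of procedure
# characteristics.

#' Ranked procedure league table for one year
#'
#' Selects the `top_n` highest-volume categories of the year, then orders
#' them by PAI score descending (most to least unequally distributed);
#' ties in PAI are broken by volume descending. Rank is contiguous from 1.
#'
#' @param pai_results Output of [pai_by_category_year()].
#' @param hhi_results Output of [hhi_by_category_year()].
#' @param year Calendar year to report.
#' @param top_n Number of highest-volume categories to keep (truncated
#'   with a warning if fewer exist).
#' @param meta Optional `category_metadata`; adds labels when given.
#' @return A data.table: `rank`, `category_id` (and `label` if `meta`),
#'   `pai`, `n_procedures`, `n_hospitals`, `hhi`.
#' @export
ranked_table <- function(pai_results, hhi_results, year, top_n = 40L,
                         meta = NULL) {
  yr <- year
  p <- as.data.table(pai_results)[year == yr]
  if (nrow(p) == 0L) stop("no PAI results for year ", yr)
  h <- as.data.table(hhi_results)[year == yr,
                                  .(category_id, n_hospitals, hhi)]
  x <- merge(p, h, by = "category_id", all.x = TRUE)
  if (top_n > nrow(x)) {
    warning(sprintf("top_n = %d exceeds the %d available categories",
                    top_n, nrow(x)))
    top_n <- nrow(x)
  }
  setorder(x, -n_procedures)
  x <- head(x, top_n)
  setorder(x, -pai, -n_procedures)
  x[, rank := seq_len(.N)]
  cols <- c("rank", "category_id", "pai", "n_procedures", "n_hospitals",
            "hhi")
  if (!is.null(meta)) {
    x <- merge(x, as.data.table(meta)[, .(category_id, label)],
               by = "category_id", all.x = TRUE, sort = FALSE)
    cols <- append(cols, "label", after = 2L)
  }
  x[, ..cols]
}

#' Percent difference between two PAI scores
#'
#' 100 * (pai_a / pai_b - 1): how much higher (or lower) `pai_a` is than
#' `pai_b`, the form used to compare procedures that differ only by
#' approach (e.g. endovascular vs open). Report to one decimal.
#'
#' @param pai_a,pai_b Scores to compare; `pai_b` must be nonzero.
#' @return The percent difference (unrounded).
#' @export
percent_difference <- function(pai_a, pai_b) {
  if (any(pai_b == 0))
    stop("percent difference undefined: reference score is 0")
  100 * (pai_a / pai_b - 1)
}

#' Cross-sectional fit of PAI on hospital count
#'
#' Ordinary least squares of PAI score on the number of hospitals
#' performing the category, over the highest-volume categories of a year
#' (top `volume_quantile` by encounter count). A negative slope says that
#' procedures offered in more hospitals are more equally distributed.
#'
#' @inheritParams ranked_table
#' @param volume_quantile Fraction of categories kept, by volume (default
#'   0.2 = top quintile).
#' @return A list: `slope` (PAI per additional hospital), `se`,
#'   `correlation` (Pearson), `intercept`, `n` (categories used), and the
#'   underlying `data`.
#' @export
pai_hospitals_fit <- function(pai_results, hhi_results, year,
                              volume_quantile = 0.2) {
  yr <- year
  p <- as.data.table(pai_results)[year == yr]
  h <- as.data.table(hhi_results)[year == yr,
                                  .(category_id, n_hospitals)]
  x <- merge(p, h, by = "category_id")
  cutoff <- quantile(x$n_procedures, 1 - volume_quantile, type = 7)
  x <- x[n_procedures >= cutoff]
  if (nrow(x) < 3L)
    stop("need at least 3 categories after the volume filter")
  if (length(unique(x$n_hospitals)) < 2L)
    stop("degenerate fit: hospital count is constant across categories")
  fit <- lm(pai ~ n_hospitals, data = x)
  sm <- summary(fit)$coefficients
  list(slope = unname(coef(fit)["n_hospitals"]),
       se = unname(sm["n_hospitals", "Std. Error"]),
       correlation = cor(x$n_hospitals, x$pai),
       intercept = unname(coef(fit)["(Intercept)"]),
       n = nrow(x), data = x[])
}

#' Longitudinal change in PAI versus change in hospital count
#'
#' For every category present in both years, computes the percent change
#' 100 * (x1/x0 - 1) in PAI and in hospital count, plus the level change
#' in PAI, and regresses the change in PAI on the percent change in
#' hospital count. `response = "delta"` (default) uses the level change
#' (index points per percent); `response = "percent"` uses the percent
#' change in PAI. Categories missing in either year are excluded and
#' logged.
#'
#' @inheritParams ranked_table
#' @param year0,year1 Baseline and comparison years.
#' @param response `"delta"` or `"percent"` (see above).
#' @return A list: `data` (per-category `pct_change_pai`,
#'   `pct_change_hospitals`, `delta_pai`), `slope`, `se`, `correlation`,
#'   `n`, `response`.
#' @export
longitudinal_change <- function(pai_results, hhi_results, year0, year1,
                                response = c("delta", "percent")) {
  response <- match.arg(response)
  p <- as.data.table(pai_results)
  h <- as.data.table(hhi_results)
  y0 <- merge(p[year == year0, .(category_id, pai0 = pai)],
              h[year == year0, .(category_id, nh0 = n_hospitals)],
              by = "category_id")
  y1 <- merge(p[year == year1, .(category_id, pai1 = pai)],
              h[year == year1, .(category_id, nh1 = n_hospitals)],
              by = "category_id")
  x <- merge(y0, y1, by = "category_id")
  n_excluded <- length(union(y0$category_id, y1$category_id)) - nrow(x)
  if (n_excluded > 0)
    message(sprintf(
      "longitudinal_change: %d category(ies) missing in one year excluded",
      n_excluded))
  if (nrow(x) == 0L) stop("no category present in both years")
  x <- x[pai0 != 0 & nh0 > 0]
  x[, `:=`(pct_change_pai = 100 * (pai1 / pai0 - 1),
           pct_change_hospitals = 100 * (nh1 / nh0 - 1),
           delta_pai = pai1 - pai0)]
  yvar <- if (response == "delta") x$delta_pai else x$pct_change_pai
  if (length(unique(x$pct_change_hospitals)) < 2L ||
      length(unique(yvar)) < 2L)
    stop("degenerate fit: no variation in change measures")
  fit <- lm(yvar ~ x$pct_change_hospitals)
  sm <- summary(fit)$coefficients
  list(data = x[], slope = unname(coef(fit)[2]),
       se = unname(sm[2, "Std. Error"]),
       correlation = cor(x$pct_change_hospitals, yvar),
       n = nrow(x), response = response)
}

#' Per-category characteristic summary
#'
#' Averages patient-level encounter characteristics within each category
#' (age, percent female, payer and race mix, cost, length of stay,
#' mortality, elective share) and joins the category-level flags from the
#' metadata, volumes, and - when supplied - hospital counts and HHI. Each
#' category contributes one observation, the unit of analysis for tercile
#' summaries.
#'
#' @param enc An `encounter_table` (typically one year).
#' @param meta A `category_metadata` table.
#' @param hhi_results Optional [hhi_by_category_year()] rows for the year.
#' @return A data.table with one row per category.
#' @export
category_characteristics <- function(enc, meta, hhi_results = NULL) {
  e <- as.data.table(enc)
  chars <- e[, {
    out <- list(n_procedures = .N,
                mean_age = mean(age),
                pct_female = 100 * mean(sex == "F"))
    if ("payer" %in% names(e))
      out$pct_medicare <- 100 * mean(payer == "medicare", na.rm = TRUE)
    if ("race" %in% names(e)) {
      out$pct_white <- 100 * mean(race == "white", na.rm = TRUE)
      out$pct_hispanic <- 100 * mean(race == "hispanic", na.rm = TRUE)
    }
    if ("cost" %in% names(e)) out$mean_cost <- mean(cost, na.rm = TRUE)
    if ("los_days" %in% names(e))
      out$mean_los <- mean(los_days, na.rm = TRUE)
    if ("died" %in% names(e))
      out$pct_died <- 100 * mean(died, na.rm = TRUE)
    if ("elective" %in% names(e))
      out$pct_elective <- 100 * mean(elective, na.rm = TRUE)
    out
  }, by = category_id]
  m <- as.data.table(meta)[, .(category_id,
                               pct_minimally_invasive =
                                 100 * as.numeric(minimally_invasive),
                               pct_era_new = 100 * as.numeric(era_new),
                               pct_device = 100 * as.numeric(device_implant))]
  out <- merge(chars, m, by = "category_id", all.x = TRUE)
  if (!is.null(hhi_results))
    out <- merge(out,
                 as.data.table(hhi_results)[, .(category_id, n_hospitals,
                                                hhi)],
                 by = "category_id", all.x = TRUE)
  out[]
}

# Tercile sizes differ by <= 1 with remainders assigned to the lower
# terciles: 356 categories split 119 / 119 / 118 (low / mid / high).
tercile_sizes <- function(n) {
  n <- as.integer(n)
  base <- n %/% 3L
  rem <- n %% 3L
  c(low = base + as.integer(rem >= 1L),
    mid = base + as.integer(rem >= 2L),
    high = base)
}

#' Tercile summary of procedure characteristics by PAI score
#'
#' Ranks categories by PAI, partitions them into low/mid/high terciles
#' (sizes differing by at most one, remainders to the lower terciles),
#' and reports the per-tercile mean and SD of each characteristic, with a
#' Welch two-sample t-test p-value for the top-versus-bottom tercile
#' difference. Characteristics with zero variance in both extreme
#' terciles (and equal means) get p = 1 by convention.
#'
#' @param pai_results [pai_by_category_year()] rows for one year.
#' @param enc The matching year's `encounter_table`.
#' @param meta A `category_metadata` table.
#' @param characteristics Character vector of characteristic columns to
#'   summarize; defaults to everything [category_characteristics()]
#'   produces (plus `pai`). Absent columns are skipped with a warning.
#' @param hhi_results Optional HHI rows for the year, adds `n_hospitals`
#'   and `hhi` characteristics.
#' @return A `tercile_summary` data.table: `characteristic`, then
#'   `low_mean`, `low_sd`, `mid_mean`, `mid_sd`, `high_mean`, `high_sd`,
#'   `p_value`, plus an `n_categories` attribute with the tercile sizes.
#' @export
tercile_summary <- function(pai_results, enc, meta,
                            characteristics = NULL, hhi_results = NULL) {
  p <- as.data.table(pai_results)
  if (length(unique(p$year)) > 1L)
    stop("tercile_summary expects PAI results for a single year")
  if (nrow(p) < 3L) stop("need at least 3 categories")
  chars <- category_characteristics(enc, meta, hhi_results)
  x <- merge(p[, .(category_id, pai)], chars, by = "category_id")
  setorder(x, pai)  # ascending: first block = low tercile
  sz <- tercile_sizes(nrow(x))
  x[, tercile := rep(c("low", "mid", "high"), times = sz)]
  if (is.null(characteristics))
    characteristics <- setdiff(names(x), c("category_id", "tercile"))
  absent <- setdiff(characteristics, names(x))
  if (length(absent)) {
    warning("characteristic column(s) absent, skipped: ",
            paste(absent, collapse = ", "))
    characteristics <- setdiff(characteristics, absent)
  }
  rows <- lapply(characteristics, function(cc) {
    v <- x[[cc]]
    grp <- function(t) v[x$tercile == t]
    lo <- grp("low"); hi <- grp("high")
    sd_lo <- sd(lo); sd_hi <- sd(hi)
    p_val <- if (!is.na(sd_lo) && !is.na(sd_hi) && sd_lo == 0 &&
                 sd_hi == 0) {
      # degenerate: no within-group variation at either extreme
      if (isTRUE(all.equal(mean(lo), mean(hi)))) 1 else 0
    } else {
      # Welch by default; untestable groups (n < 2) give NA
      tryCatch(t.test(hi, lo)$p.value, error = function(e) NA_real_)
    }
    data.table(characteristic = cc,
               low_mean = mean(lo), low_sd = sd(lo),
               mid_mean = mean(grp("mid")), mid_sd = sd(grp("mid")),
               high_mean = mean(hi), high_sd = sd(hi),
               p_value = p_val)
  })
  out <- rbindlist(rows)
  setattr(out, "n_categories", sz)
  setattr(out, "class", c("tercile_summary", class(out)))
  out[]
}

#' Scatterplot of PAI against hospital count with the linear fit
#'
#' @param fit Output of [pai_hospitals_fit()] or [longitudinal_change()].
#' @param path PNG output path.
#' @return `path`, invisibly.
#' @export
plot_pai_fit <- function(fit, path) {
  grDevices::png(path, width = 900, height = 650, res = 120)
  on.exit(grDevices::dev.off())
  if (!is.null(fit$response)) {
    xv <- fit$data$pct_change_hospitals
    yv <- if (fit$response == "delta") fit$data$delta_pai else
      fit$data$pct_change_pai
    xlab <- "% change in hospitals offering"
    ylab <- if (fit$response == "delta") "Change in PAI score" else
      "% change in PAI score"
  } else {
    xv <- fit$data$n_hospitals; yv <- fit$data$pai
    xlab <- "Hospitals offering the procedure"; ylab <- "PAI score"
  }
  graphics::plot(xv, yv, pch = 19, col = "#00000088",
                 xlab = xlab, ylab = ylab,
                 main = sprintf("slope = %.4g (SE %.3g), r = %.3f",
                                fit$slope, fit$se, fit$correlation))
  graphics::abline(lm(yv ~ xv), lty = 2, col = "firebrick")
  invisible(path)
}
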