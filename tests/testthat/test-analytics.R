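# Study analytics: ranked table, percent differences, fits, terciles

fake_pai <- function(category_id, year, pai, n = 1000) {
  data.table(category_id = category_id, year = year, n_procedures = n,
             n_zips = 10L, d_baseline = 0.1, d_realized = 0.2, pai = pai,
             functional = "share_concentration",
             reference_mode = "all_hospitalizations")
}

fake_hhi <- function(category_id, year, n_hospitals, hhi = 100) {
  data.table(category_id = category_id, year = year,
             n_hospitals = n_hospitals, hhi = hhi)
}

test_that("ranked_table sorts by pai with the volume tie-break", {
  p <- fake_pai(c("A", "B", "C", "D"), 2019, c(0.2, 0.5, 0.2, 0.1),
                n = c(100, 400, 300, 200))
  h <- fake_hhi(c("A", "B", "C", "D"), 2019, c(10, 20, 30, 40))
  rt <- ranked_table(p, h, 2019, top_n = 4)
  expect_identical(rt$category_id, c("B", "C", "A", "D"))  # tie: C > A
  expect_identical(rt$rank, 1:4)
  expect_identical(ranked_table(p, h, 2019, top_n = 1)$category_id, "B")
  # top_n selects by volume first, then sorts the kept set by pai
  rt2 <- ranked_table(p, h, 2019, top_n = 2)
  expect_identical(rt2$category_id, c("B", "C"))
  expect_warning(ranked_table(p, h, 2019, top_n = 9), "exceeds")
})

test_that("percent_difference matches hand arithmetic and inverts", {
  expect_equal(percent_difference(0.3, 0.2), 50)
  expect_equal(percent_difference(0.2, 0.2), 0)
  expect_error(percent_difference(0.1, 0), "undefined")
  set.seed(91)
  for (i in 1:20) {
    a <- runif(1, -1, 1); b <- runif(1, 0.05, 1)
    p_ab <- percent_difference(a, b)
    if (a != 0) {
      p_ba <- percent_difference(b, a)
      expect_equal((1 + p_ab / 100) * (1 + p_ba / 100), 1,
                   tolerance = 1e-12)
    }
  }
})

test_that("pai_hospitals_fit equals the closed-form OLS", {
  p <- fake_pai(c("A", "B", "C"), 2019, c(0.3, 0.2, 0.1))
  h <- fake_hhi(c("A", "B", "C"), 2019, c(100, 200, 300))
  # suppressWarnings: lm warns on exactly collinear toy points
  f <- suppressWarnings(pai_hospitals_fit(p, h, 2019,
                                          volume_quantile = 1))
  expect_equal(f$slope, -0.001, tolerance = 1e-12)
  expect_equal(f$correlation, -1, tolerance = 1e-12)
  # random instances against the textbook formulas
  set.seed(101)
  for (i in 1:10) {
    k <- sample(4:12, 1)
    nh <- sample(50:900, k)
    pv <- runif(k, -0.05, 0.4)
    f2 <- suppressWarnings(
      pai_hospitals_fit(fake_pai(paste0("C", 1:k), 2019, pv),
                        fake_hhi(paste0("C", 1:k), 2019, nh),
                        2019, volume_quantile = 1))
    o <- oracle_ols(nh, pv)
    expect_equal(f2$slope, o$slope, tolerance = 1e-12)
    expect_equal(f2$intercept, o$intercept, tolerance = 1e-12)
    expect_equal(f2$correlation, o$correlation, tolerance = 1e-12)
  }
  # volume filter keeps the top quantile
  p2 <- fake_pai(paste0("C", 1:10), 2019, seq(0.1, 0.28, by = 0.02),
                 n = seq(100, 1000, by = 100))
  h2 <- fake_hhi(paste0("C", 1:10), 2019, seq(100, 1000, by = 100))
  f3 <- suppressWarnings(pai_hospitals_fit(p2, h2, 2019,
                                           volume_quantile = 0.3))
  expect_equal(f3$n, 3L)
  expect_error(pai_hospitals_fit(fake_pai(c("A", "B", "C"), 2019,
                                          c(0.1, 0.2, 0.3)),
                                 fake_hhi(c("A", "B", "C"), 2019,
                                          c(5, 5, 5)),
                                 2019, volume_quantile = 1),
               "degenerate")
})

test_that("longitudinal_change computes percent changes and the fit", {
  p <- rbind(fake_pai(c("A", "B", "C"), 2016, c(0.347, 0.2, 0.15)),
             fake_pai(c("A", "B", "C", "D"), 2019, c(0.238, 0.25, 0.12,
                                                     0.3)))
  h <- rbind(fake_hhi(c("A", "B", "C"), 2016, c(100, 200, 400)),
             fake_hhi(c("A", "B", "C", "D"), 2019, c(131, 190, 500, 40)))
  expect_message(lc <- longitudinal_change(p, h, 2016, 2019), "excluded")
  a <- lc$data[category_id == "A"]
  expect_equal(round(a$pct_change_pai, 1), -31.4)
  expect_equal(a$pct_change_hospitals, 31, tolerance = 1e-9)
  expect_equal(a$delta_pai, 0.238 - 0.347, tolerance = 1e-12)
  expect_equal(lc$n, 3L)  # D missing in 2016
  o <- oracle_ols(lc$data$pct_change_hospitals, lc$data$delta_pai)
  expect_equal(lc$slope, o$slope, tolerance = 1e-12)
  lcp <- suppressMessages(longitudinal_change(p, h, 2016, 2019,
                                              response = "percent"))
  o2 <- oracle_ols(lcp$data$pct_change_hospitals,
                   lcp$data$pct_change_pai)
  expect_equal(lcp$slope, o2$slope, tolerance = 1e-12)
  # all-constant changes are a degenerate fit
  pc <- rbind(fake_pai(c("A", "B"), 2016, c(0.2, 0.3)),
              fake_pai(c("A", "B"), 2019, c(0.2, 0.3)))
  hc <- rbind(fake_hhi(c("A", "B"), 2016, c(10, 20)),
              fake_hhi(c("A", "B"), 2019, c(10, 20)))
  expect_error(longitudinal_change(pc, hc, 2016, 2019), "degenerate")
})

test_that("tercile sizes partition with remainders to the lower terciles", {
  for (n in c(3, 4, 5, 6, 100, 355, 356, 357)) {
    sz <- paindex:::tercile_sizes(n)
    expect_equal(sum(sz), n)
    expect_lte(max(sz) - min(sz), 1L)
    expect_gte(sz[["low"]], sz[["high"]])
    expect_gte(sz[["mid"]], sz[["high"]])
  }
})

test_that("tercile_summary separates characteristics and tests extremes", {
  ids <- paste0("C", 1:6)
  p <- fake_pai(ids, 2019, c(0.05, 0.08, 0.1, 0.2, 0.25, 0.3))
  meta <- make_meta(ids, mi = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  enc <- make_enc(zip = "Z1", category_id = rep(ids, each = 4),
                  age = rep(c(30, 70), 12),
                  sex = rep(c("F", "M"), 12))
  ts <- tercile_summary(p, enc, meta)
  expect_identical(unname(attr(ts, "n_categories")), c(2L, 2L, 2L))
  mi <- ts[characteristic == "pct_minimally_invasive"]
  expect_equal(mi$low_mean, 0)
  expect_equal(mi$high_mean, 100)
  # identical characteristic across categories -> p = 1 by convention
  age_row <- ts[characteristic == "mean_age"]
  expect_equal(age_row$p_value, 1)
  # pai itself must differ between extremes with a finite p-value
  pai_row <- ts[characteristic == "pai"]
  expect_lt(pai_row$high_mean - pai_row$low_mean, 0.3)
  expect_gte(pai_row$p_value, 0)
  expect_lte(pai_row$p_value, 1)
  # every category lands in exactly one tercile
  expect_warning(
    tercile_summary(p, enc, meta, characteristics = c("pai", "nope")),
    "absent")
})
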