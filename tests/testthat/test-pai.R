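# The PAI score: observed shares, dispersion functionals, normalization,
# and the category-year pipeline.

uniform_sv <- function(k) share_vector(paste0("Z", 1:k), rep(1 / k, k))

test_that("observed_shares normalizes counts over the zip universe", {
  pop <- make_pop(c("Z1", "Z2", "Z3"), c(100, 100, 100))
  enc <- make_enc(zip = c("Z1", "Z1", "Z2", "Z2"))
  o <- observed_shares(enc, "C1", 2019, pop)
  expect_equal(o$share[match(c("Z1", "Z2", "Z3"), o$zip)], c(0.5, 0.5, 0))

  pop4 <- make_pop(paste0("Z", 1:4), rep(100, 4))
  enc4 <- make_enc(zip = rep(paste0("Z", 1:4), 1:4))
  o4 <- observed_shares(enc4, "C1", 2019, pop4)
  expect_equal(sort(o4$share), c(0.1, 0.2, 0.3, 0.4))

  expect_error(observed_shares(enc, "C9", 2019, pop), "no encounters")
  # unknown zips are dropped with a logged count
  enc_bad <- make_enc(zip = c("Z1", "ZX"))
  expect_message(o2 <- observed_shares(enc_bad, "C1", 2019, pop),
                 "dropped 1")
  expect_identical(attr(o2, "n_dropped"), 1L)
  expect_identical(attr(o2, "n_encounters"), 1L)
})

test_that("share_concentration dispersion matches closed forms", {
  for (k in c(2, 3, 10)) expect_equal(dispersion(uniform_sv(k)), 1 / k)
  expect_equal(dispersion(share_vector("Z1", 1)), 1)
  expect_equal(dispersion(share_vector(c("a", "b", "c"), c(0.5, 0.5, 0))),
               0.5)
})

test_that("reference-relative functionals are zero at equality", {
  set.seed(21)
  for (i in 1:5) {
    w <- runif(6); r <- share_vector(paste0("Z", 1:6), w / sum(w))
    expect_equal(dispersion(r, "gini_vs_reference", reference = r), 0,
                 tolerance = 1e-12)
    expect_equal(dispersion(r, "theil_vs_reference", reference = r), 0,
                 tolerance = 1e-12)
  }
  expect_error(dispersion(uniform_sv(3), "gini_vs_reference"), "reference")
  # gini of a point mass against r is 1 - r at that zip
  r <- share_vector(c("Z1", "Z2", "Z3"), c(0.2, 0.3, 0.5))
  pm <- share_vector(c("Z1", "Z2", "Z3"), c(0, 1, 0))
  expect_equal(dispersion(pm, "gini_vs_reference", reference = r), 0.7,
               tolerance = 1e-12)
  # theil with observed mass on a zero-reference zip is undefined
  r0 <- share_vector(c("Z1", "Z2", "Z3"), c(0.5, 0.5, 0))
  pm3 <- share_vector(c("Z1", "Z2", "Z3"), c(0, 0, 1))
  expect_error(dispersion(pm3, "theil_vs_reference", reference = r0),
               "zero reference")
})

test_that("compute_pai hits the stated endpoints and closed forms", {
  u3 <- uniform_sv(3)
  set.seed(31)
  for (i in 1:5) {
    w <- runif(5) + 0.05
    r <- share_vector(paste0("Z", 1:5), w / sum(w))
    expect_identical(compute_pai(r, r)$pai, 0)  # equality endpoint, exact
  }
  for (k in c(2, 5, 40)) {
    pm <- share_vector(paste0("Z", 1:k), c(1, rep(0, k - 1)))
    expect_equal(compute_pai(pm, uniform_sv(k))$pai, 1)
  }
  o <- share_vector(paste0("Z", 1:3), c(0.5, 0.5, 0))
  expect_equal(compute_pai(o, u3)$pai, 0.25)
  # sub-zero regime: observed more uniform than the reference
  expect_equal(compute_pai(u3, o)$pai, -1 / 3)
  # degenerate reference
  pm3 <- share_vector(paste0("Z", 1:3), c(1, 0, 0))
  expect_error(compute_pai(u3, pm3), "degenerate")
  # mismatched universes
  expect_error(compute_pai(uniform_sv(4), u3), "universe")
})

test_that("pai is permutation-equivariant and bounded by 1", {
  set.seed(41)
  for (i in 1:20) {
    k <- sample(3:8, 1)
    cnt <- rpois(k, 5) + (i %% 2)  # allow zero counts
    if (sum(cnt) == 0) cnt[1] <- 1
    w <- runif(k) + 0.02
    zips <- paste0("Z", 1:k)
    o <- share_vector(zips, cnt / sum(cnt))
    r <- share_vector(zips, w / sum(w))
    p <- compute_pai(o, r)$pai
    expect_lte(p, 1)
    # relabel zips by a random permutation
    perm <- sample(k)
    o2 <- share_vector(zips[perm], cnt / sum(cnt))
    r2 <- share_vector(zips[perm], w / sum(w))
    expect_equal(compute_pai(o2, r2)$pai, p, tolerance = 1e-12)
    # pai = 1 iff point mass
    expect_identical(p == 1, sum(cnt > 0) == 1L)
  }
})

test_that("merging two zips never decreases share concentration", {
  set.seed(51)
  for (i in 1:20) {
    k <- sample(3:9, 1)
    w <- runif(k)
    v <- w / sum(w)
    d0 <- dispersion(share_vector(paste0("Z", 1:k), v))
    ij <- sample(k, 2)
    merged <- c(v[-ij], sum(v[ij]))
    d1 <- dispersion(share_vector(paste0("M", seq_along(merged)), merged))
    expect_gte(d1, d0)
  }
})

test_that("pai matches the long-hand oracle on small integer instances", {
  set.seed(61)
  for (i in 1:50) {
    k <- sample(2:6, 1)
    cnt <- sample(0:20, k, replace = TRUE)
    if (sum(cnt) == 0) cnt[sample(k, 1)] <- sample(1:20, 1)
    w <- sample(1:20, k, replace = TRUE)
    zips <- paste0("Z", 1:k)
    names(cnt) <- zips
    ref <- w / sum(w); names(ref) <- zips
    o <- share_vector(zips, cnt / sum(cnt))
    r <- share_vector(zips, ref)
    expect_equal(compute_pai(o, r)$pai, oracle_pai(as.list(cnt),
                                                   as.list(ref)),
                 tolerance = 1e-12)
  }
})

test_that("optional finite-sample correction keeps the zero endpoint", {
  r <- uniform_sv(4)
  expect_equal(compute_pai(r, r, bias_correct = TRUE, n = 100)$pai, 0)
  expect_error(compute_pai(r, r, bias_correct = TRUE), "n > 1")
  expect_error(compute_pai(r, r, functional = "gini_vs_reference",
                           bias_correct = TRUE, n = 10),
               "share_concentration")
})

test_that("pai_by_category_year scores each cell once and skips small ones", {
  pop <- make_pop(c("Z1", "Z2"), c(1000, 1000))
  enc <- make_enc(year = rep(c(2018, 2019), each = 6),
                  zip = rep(c("Z1", "Z2"), 6),
                  category_id = rep(c("C1", "C1", "C2"), 4))
  meta <- make_meta(c("C1", "C2"))
  res <- pai_by_category_year(enc, pop, meta)
  expect_equal(nrow(res), 4L)  # 2 categories x 2 years
  expect_setequal(res$year, c(2018, 2019))
  expect_true(all(c("d_baseline", "d_realized", "functional",
                    "reference_mode") %in% names(res)))

  # min_volume filters and logs
  res2 <- suppressMessages(
    pai_by_category_year(enc, pop, meta,
                         config = pai_config(min_volume = 3)))
  expect_equal(sort(unique(res2$category_id)), "C1")
  expect_equal(nrow(attr(res2, "skipped")), 2L)

  # both reference modes run and are recorded
  res3 <- pai_by_category_year(enc, pop, meta,
                               config = pai_config(
                                 reference_mode = "category_specific"))
  expect_true(all(res3$reference_mode == "category_specific"))
})

test_that("bootstrap CI is reproducible and brackets the point estimate", {
  pop <- make_pop(paste0("Z", 1:5), rep(1000, 5))
  set.seed(71)
  enc <- make_enc(zip = sample(paste0("Z", 1:5), 400, replace = TRUE,
                               prob = c(0.4, 0.3, 0.15, 0.1, 0.05)))
  rates <- stratum_rates(enc, pop)
  r <- reference_shares(expected_counts(rates, pop))
  b1 <- pai_bootstrap(enc, "C1", 2019, pop, r, B = 50, seed = 9)
  b2 <- pai_bootstrap(enc, "C1", 2019, pop, r, B = 50, seed = 9)
  expect_identical(b1, b2)
  expect_lte(b1$lower, b1$upper)
  expect_gte(b1$pai, b1$lower - 0.05)
  expect_lte(b1$pai, b1$upper + 0.05)
})
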