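test_that("heritability reproduces all published reference cells at 2 dp", {
  ref <- barley_reference_varcomp()
  expect_equal(nrow(ref), 12)
  h2 <- heritability(ref$sigma2_G, ref$sigma2_e, ref$E)$h2
  expect_equal(round(h2, 2), ref$h2)
})

test_that("heritability formula behaves at its limits and rejects bad input", {
  expect_equal(heritability(10, 0, 3)$h2, 1)
  expect_error(heritability(10, 5, 0.5), "E_bar")
  # strictly increasing in sigma2_G and E_bar, decreasing in sigma2_e_bar
  grid <- seq(1, 50, length.out = 10)
  expect_true(all(diff(heritability(grid, 10, 3)$h2) > 0))
  expect_true(all(diff(heritability(20, grid, 3)$h2) < 0))
  expect_true(all(diff(heritability(20, 10, 1 + grid / 10)$h2) > 0))
})

test_that("year CV divides the error SD by the estimated year mean", {
  fake <- structure(list(
    spec = model_spec(genotype = "random", year = "fixed"),
    mu_hat = 18,
    year_effects = tibble::tibble(harvest_year = c(1970L, 1971L),
                                  estimate = c(2, -2), type = "fixed"),
    varcomp = list(sigma2_e_by_year = c("1970" = 4, "1971" = 16))),
    class = "rp_fit")
  cv <- year_cv(fake)
  expect_equal(cv$per_year$cv, c(sqrt(4) / 20, sqrt(16) / 16))
  expect_equal(cv$mean_cv, mean(c(0.1, 0.25)))
  expect_equal(cv$min_cv, 0.1)
})

test_that("year CV recovers a generator-controlled target", {
  # construct data whose true per-year error SD is 5% of the year mean
  set.seed(13)
  nG <- 120; nY <- 6
  mu <- 100
  u <- stats::rnorm(nY, 0, 4)
  year_mean <- mu + u
  s_e <- 0.05 * year_mean
  g <- stats::rnorm(nG, 0, 5)
  rec <- expand.grid(gi = 1:nG, yi = 1:nY)
  val <- mu + g[rec$gi] + u[rec$yi] + stats::rnorm(nrow(rec), 0, s_e[rec$yi])
  ds <- make_dataset(sprintf("G%03d", rec$gi), 1970 + rec$yi, val)
  cv <- year_cv(fit_mixed(ds, spec_yearcv()))
  expect_equal(cv$mean_cv, 0.05, tolerance = 0.2)
  expect_true(all(abs(cv$per_year$cv - 0.05) < 0.02))
})

test_that("year CV on noiseless data is zero", {
  ds <- make_noiseless_grid(g = 1:6, u = c(-3, 1, 2), mu = 50)
  cv <- suppressWarnings(year_cv(fit_mixed(ds, spec_yearcv())))
  expect_true(all(cv$per_year$cv < 1e-3))
})

test_that("year-pair correlations honour the overlap rule", {
  # year B duplicates year A for 60 accessions: one qualifying pair, r = 1
  acc <- sprintf("A%03d", 1:60)
  vals <- stats::rnorm(60, 50, 5)
  ds <- make_dataset(rep(acc, 2), rep(c(1970, 1971), each = 60),
                     c(vals, vals))
  res <- year_pair_correlations(ds, min_overlap = 50)
  expect_equal(res$n_pairs, 1)
  expect_equal(res$pairs$r, 1)
  expect_equal(res$pairs$n_overlap, 60)

  # 49 shared accessions: below the threshold, no qualifying pair
  ds49 <- make_dataset(rep(acc[1:49], 2), rep(c(1970, 1971), each = 49),
                       stats::rnorm(98, 50, 5))
  res49 <- year_pair_correlations(ds49, min_overlap = 50)
  expect_equal(res49$n_pairs, 0)
  expect_true(res49$no_qualifying_pairs)
  expect_true(is.na(res49$mean_r))
})

test_that("year-pair correlations average replicates and ignore record order", {
  set.seed(23)
  sim <- simulate_dataset(sim_params(n_genotypes = 80, n_years = 4,
                                     occupancy = 0.9, dup_rate = 0.05),
                          seed = 23)
  r1 <- year_pair_correlations(sim$dataset, min_overlap = 10)
  shuffled <- rebuild_dataset(
    tibble::as_tibble(sim$dataset)[sample(nrow(sim$dataset)), ],
    sim$dataset)
  r2 <- year_pair_correlations(shuffled, min_overlap = 10)
  expect_equal(r1$pairs, r2$pairs)
})

test_that("mean year-pair correlation approaches its analytic value", {
  # under the additive model the expected correlation of accession values
  # between two years is sigma2_G / (sigma2_G + mean sigma2_e)
  sim <- simulate_dataset(sim_params(n_genotypes = 600, n_years = 6,
                                     occupancy = 0.9, dup_rate = 0,
                                     sigma2_G = 27,
                                     sigma2_e_range = c(16, 18)),
                          seed = 33)
  res <- year_pair_correlations(sim$dataset, min_overlap = 50)
  analytic <- 27 / (27 + mean(sim$truth$year_effects$sigma2_e))
  expect_equal(res$mean_r, analytic, tolerance = 0.06)
})

test_that("origin table computes shares, tail row and total", {
  st <- tibble::tibble(accession_id = sprintf("A%02d", 1:10),
                       country = c(rep("Ethiopia", 7), rep("Germany", 3)),
                       comment = "")
  tab <- origin_table(st)
  expect_equal(tab$percentage[tab$origin == "Ethiopia"], 70)
  expect_equal(tab$percentage[tab$origin == "Germany"], 30)
  expect_equal(tab$n[tab$origin == "Total"], 10)

  expect_equal(nrow(origin_table(st[0, ])), 0)

  # 70 distinct origins with rank cutoff 22 collapse into Others (48 origins)
  st70 <- tibble::tibble(
    accession_id = sprintf("B%03d", 1:140),
    country = rep(sprintf("Country%02d", 1:70), times = 2),
    comment = "")
  tab70 <- origin_table(st70, rank_cutoff = 22)
  expect_true("Others (48 origins)" %in% tab70$origin)
  expect_equal(nrow(tab70), 22 + 2)  # named origins + Others + Total
  body <- tab70[tab70$origin != "Total", ]
  expect_equal(sum(body$n), 140)
  # each displayed share is rounded to 1 dp, so the sum can drift by up to
  # 0.05 per row
  expect_lt(abs(sum(body$percentage) - 100), 0.05 * nrow(body) + 1e-9)
})

test_that("origin table can use comment-column groups", {
  st <- tibble::tibble(accession_id = c("A1", "A2", "A3"),
                       country = c("Russia", "Estonia", "Germany"),
                       comment = c("Soviet Union", "Soviet Union", ""))
  tab <- origin_table(st, use_comment_groups = TRUE)
  expect_equal(tab$n[tab$origin == "Soviet Union"], 2)
  expect_equal(tab$n[tab$origin == "Germany"], 1)
})
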