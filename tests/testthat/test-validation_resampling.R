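balanced_sim <- function(A = 60, Y = 4, seed = 1, sigma2_e_range = c(9, 25)) {
  sim <- simulate_dataset(
    sim_params(n_genotypes = A, n_years = Y, occupancy = 1, dup_rate = 0,
               sigma2_e_range = sigma2_e_range), seed = seed)
  extract_balanced(sim$dataset, sort(unique(sim$dataset$harvest_year)))
}

test_that("extract_balanced keeps only fully observed accessions", {
  ds <- make_dataset(
    accession_id = c("A", "A", "A", "B", "B", "C", "C", "C", "D"),
    harvest_year = c(1970, 1971, 1972, 1970, 1971, 1970, 1971, 1972, 1972),
    value = 1:9)
  bal <- extract_balanced(ds, c(1970, 1971, 1972))
  expect_setequal(attr(bal, "accessions"), c("A", "C"))
  expect_equal(nrow(bal), 6)
  expect_error(extract_balanced(ds, c(1970, 1999)), "absent")
  # replicates are averaged into the cell value
  dsr <- make_dataset(c("A", "A", "B"), c(1970, 1970, 1970), c(10, 12, 5))
  suppressWarnings(balr <- extract_balanced(dsr, 1970))
  expect_equal(balr$value[balr$accession_id == "A"], 11)
})

test_that("scenario samples keep the specified structure", {
  bal <- balanced_sim(A = 50, Y = 6)
  for (sc in c("S1_random", "S2_random_clusters")) {
    s <- sample_scenario(bal, sc, n_years_kept = 3, n_groups = 5, seed = 4)
    expect_equal(s$n_points, 50 * 3)
    per_acc <- table(s$kept$accession_id)
    expect_true(all(per_acc == 3))
  }
  # S2: clusters partition the accessions and share one year set each
  s2 <- sample_scenario(bal, "S2_random_clusters", n_years_kept = 3,
                        n_groups = 5, seed = 4)
  expect_equal(sort(s2$clusters$accession_id), attr(bal, "accessions"))
  joined <- dplyr::inner_join(s2$kept, s2$clusters, by = "accession_id")
  sets <- tapply(joined$harvest_year, joined$group,
                 function(v) paste(sort(unique(v)), collapse = ","))
  per_group_sets <- tapply(
    joined$harvest_year, list(joined$group, joined$accession_id),
    function(v) paste(sort(v), collapse = ","))
  for (gname in rownames(per_group_sets)) {
    vals <- stats::na.omit(per_group_sets[gname, ])
    expect_equal(length(unique(vals)), 1)
  }
  # S3 requires groups and follows them
  expect_error(sample_scenario(bal, "S3_origin_groups", seed = 1), "groups")
  grp <- stats::setNames(rep(c("g1", "g2"), length.out = 50),
                         attr(bal, "accessions"))
  s3 <- sample_scenario(bal, "S3_origin_groups", n_years_kept = 3,
                        groups = grp, seed = 5)
  expect_equal(s3$n_points, 150)
  # keeping all years returns the full grid regardless of scenario
  sfull <- sample_scenario(bal, "S1_random", n_years_kept = 6, seed = 6)
  expect_equal(sfull$n_points, nrow(bal))
})

test_that("scenario draws are reproducible from their seed", {
  bal <- balanced_sim(A = 40, Y = 6)
  s1 <- sample_scenario(bal, "S2_random_clusters", seed = 123)
  s2 <- sample_scenario(bal, "S2_random_clusters", seed = 123)
  expect_identical(s1$kept, s2$kept)
  s3 <- sample_scenario(bal, "S2_random_clusters", seed = 124)
  expect_false(identical(s1$kept, s3$kept))
})

test_that("relative bias is (estimate - reference) / reference", {
  # the statistic itself, on hand numbers: d_hat = 1.1, d = 1.0 -> 0.1
  expect_equal((1.1 - 1.0) / 1.0, 0.1)
  bal <- balanced_sim(A = 40, Y = 4)
  bs <- bias_study(bal, "S1_random", runs = 2, seed = 9, n_years_kept = 2)
  # recompute one run's rel_bias from its parts
  expect_true(all(bs$runs$rel_bias_G > -1))
  expect_equal(bs$n_failed, 0)
})

test_that("subsampling nothing gives zero bias and an identity regression", {
  bal <- balanced_sim(A = 40, Y = 4)
  bs <- bias_study(bal, "S1_random", runs = 3, seed = 2,
                   n_years_kept = 4)
  expect_true(all(abs(bs$runs$rel_bias_G) < 1e-8))
  expect_true(all(abs(bs$runs$rel_bias_e) < 1e-8))
  expect_true(all(abs(bs$runs$intercept) < 1e-6))
  expect_true(all(abs(bs$runs$slope - 1) < 1e-8))
  expect_true(all(bs$runs$r2 > 1 - 1e-10))
})

test_that("random missingness is ignorable: S1 bias centres on zero", {
  bal <- balanced_sim(A = 80, Y = 6, seed = 3)
  bs <- bias_study(bal, "S1_random", runs = 30, seed = 10, n_years_kept = 3)
  ok <- bs$runs$converged
  m_G <- mean(bs$runs$rel_bias_G[ok])
  se_G <- stats::sd(bs$runs$rel_bias_G[ok]) / sqrt(sum(ok))
  expect_lt(abs(m_G), 4 * se_G + 0.02)
  expect_equal(mean(bs$runs$slope[ok]), 1, tolerance = 0.05)
})

test_that("split-half precision is 1 on noiseless data and reproducible", {
  sim <- simulate_dataset(
    sim_params(n_genotypes = 40, n_years = 6, occupancy = 0.9, dup_rate = 0,
               sigma2_e_range = c(0, 0)), seed = 15)
  pr <- split_half_precision(sim$dataset, runs = 3, seed = 44)
  expect_true(all(pr$per_run$r[pr$per_run$ok] > 1 - 1e-6))
  pr2 <- split_half_precision(sim$dataset, runs = 3, seed = 44)
  expect_identical(pr$per_run, pr2$per_run)
})

test_that("split-half precision matches a reliability approximation", {
  # with k records per accession in each half, the expected correlation of
  # the two half BLUEs is about sigma2_G / (sigma2_G + sigma2_e_bar / k)
  sim <- simulate_dataset(
    sim_params(n_genotypes = 150, n_years = 8, occupancy = 0.5,
               dup_rate = 0, sigma2_G = 27, sigma2_e_range = c(16, 18)),
    seed = 16)
  pr <- split_half_precision(sim$dataset, runs = 10, seed = 17)
  k_half <- nrow(sim$dataset) / 2 / 150
  expected <- 27 / (27 + 17 / k_half)
  expect_equal(pr$mean_r, expected, tolerance = 0.12)
})

test_that("split-half precision increases with simulated heritability", {
  mean_r <- vapply(c(5, 27, 150), function(s2g) {
    sim <- simulate_dataset(
      sim_params(n_genotypes = 80, n_years = 6, occupancy = 0.7,
                 dup_rate = 0, sigma2_G = s2g,
                 sigma2_e_range = c(16, 18)), seed = 18)
    split_half_precision(sim$dataset, runs = 5, seed = 19)$mean_r
  }, numeric(1))
  expect_true(all(diff(mean_r) > 0))
})
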