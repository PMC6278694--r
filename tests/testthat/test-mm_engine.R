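# The engine is checked against independent oracles that use the direct
# dense-V formulation (helper-oracles.R): a grid search over the restricted
# likelihood, closed-form balanced ANOVA, and generalized least squares.

# six fixed values chosen so the REML optimum is interior (no variance
# component on the boundary), which a grid search can then bracket
toy_3x2 <- make_dataset(
  accession_id = rep(c("G1", "G2", "G3"), each = 2),
  harvest_year = rep(c(1970, 1971), 3),
  value = c(13, 14, 18, 23, 11, 23))

test_that("noiseless balanced grid: BLUEs are the row means, errors at floor", {
  ds <- make_noiseless_grid()
  fit <- fit_mixed(ds, spec_blue())
  rowmeans <- tapply(ds$value, ds$accession_id, mean)
  expect_equal(blues(fit)$BLUE,
               as.numeric(rowmeans[sort(names(rowmeans))]),
               tolerance = 1e-6)
  err <- fit$varcomp$sigma2_e_by_year
  expect_true(all(err < 1e-6 * stats::var(ds$value)))
  boundary_err <- fit$varcomp$boundary[grepl("sigma2_e", names(fit$varcomp$boundary))]
  expect_true(all(boundary_err))
})

test_that("exposed restricted log-likelihood agrees with the dense-V oracle", {
  for (role in list(c("fixed", "random"), c("random", "random"),
                    c("random", "fixed"))) {
    spec <- model_spec(genotype = role[1], year = role[2], min_year_n = 3)
    vc <- list(sigma2_G = 9, sigma2_Y = 4,
               sigma2_e.1970 = 2.5, sigma2_e.1971 = 6)
    mine <- reml_loglik(toy_3x2, spec, vc)
    orac <- oracle_reml_loglik(
      toy_3x2, genotype_role = role[1], year_role = role[2],
      sigma2_G = 9, sigma2_Y = 4,
      sigma2_e_by_year = c("1970" = 2.5, "1971" = 6))
    expect_equal(mine, orac, tolerance = 1e-8,
                 info = paste(role, collapse = "/"))
  }
})

test_that("REML fit matches a dense grid search over the likelihood", {
  fit <- fit_mixed(toy_3x2, spec_varcomp())
  vy <- stats::var(toy_3x2$value)
  # coarse-to-fine log grid over (sigma2_G, sigma2_Y, sigma2_e1, sigma2_e2),
  # evaluated with the independent dense-V oracle
  grid_pass <- function(centers, span, m) {
    axes <- lapply(centers, function(cc)
      exp(seq(log(cc) - span, log(cc) + span, length.out = m)))
    pts <- as.matrix(expand.grid(axes))
    ll <- apply(pts, 1, function(p)
      oracle_reml_loglik(toy_3x2, "random", "random", p[[1]], p[[2]],
                         c("1970" = p[[3]], "1971" = p[[4]])))
    list(best = pts[which.max(ll), ], loglik = max(ll),
         step = span * 2 / (m - 1))
  }
  p1 <- grid_pass(rep(vy, 4) * 0.5, span = log(60) / 2, m = 9)
  p2 <- grid_pass(p1$best, span = p1$step, m = 9)
  # the engine's optimum is at least as good as the best grid point,
  # and the grid argmax lies within one refined grid step of it
  expect_gte(fit$reml_loglik + 1e-6, p2$loglik)
  theta_fit <- c(fit$varcomp$sigma2_G, fit$varcomp$sigma2_Y,
                 unname(fit$varcomp$sigma2_e_by_year))
  expect_true(all(abs(log(theta_fit) - log(p2$best)) <= p2$step + 1e-8))
})

test_that("balanced one-way design reproduces closed-form ANOVA estimators", {
  set.seed(5)
  nG <- 6; nrep <- 5
  g_eff <- c(-4, -2, 0, 1, 2, 3)
  val <- 50 + rep(g_eff, each = nrep) + stats::rnorm(nG * nrep, 0, 2)
  ds <- historical_dataset(
    tibble::tibble(accession_id = rep(sprintf("G%02d", 1:nG), each = nrep),
                   harvest_year = 1970L,
                   value = val),
    trait = "PH", habit = "spring")
  fit <- fit_mixed(ds, spec_yearcv(), tol_loglik = 1e-12, tol_param = 1e-9)
  gm <- tapply(val, rep(1:nG, each = nrep), mean)
  msg <- nrep * sum((gm - mean(val))^2) / (nG - 1)
  mse <- sum((val - rep(gm, each = nrep))^2) / (nG * (nrep - 1))
  expect_equal(fit$varcomp$sigma2_e_bar, mse, tolerance = 1e-6)
  expect_equal(fit$varcomp$sigma2_G, (msg - mse) / nrep, tolerance = 1e-6)
})

test_that("fitted BLUEs equal the GLS solution at the fitted variances", {
  sim <- simulate_dataset(sim_params(n_genotypes = 20, n_years = 5,
                                     occupancy = 0.6, dup_rate = 0),
                          seed = 21)
  fit <- fit_mixed(sim$dataset, spec_blue())
  gls <- oracle_gls_blues(sim$dataset, fit$varcomp$sigma2_Y,
                          fit$varcomp$sigma2_e_by_year)
  expect_equal(blues(fit)$BLUE, unname(gls), tolerance = 1e-8)
})

test_that("a single-record accession's BLUE is its value minus the year BLUP", {
  ds <- make_dataset(
    accession_id = c("A", "A", "A", "B", "B", "SOLO"),
    harvest_year = c(1970, 1971, 1972, 1970, 1971, 1971),
    value = c(10, 12, 11, 13, 16, 30))
  fit <- fit_mixed(ds, spec_blue(min_year_n = 2,
                                 heteroscedastic = FALSE))
  yb <- fit$year_effects
  solo_blue <- blues(fit)$BLUE[blues(fit)$accession_id == "SOLO"]
  expect_equal(solo_blue,
               30 - yb$estimate[yb$harvest_year == 1971],
               tolerance = 1e-8)
  # the same holds under the dense GLS + BLUP oracle
  s2e <- fit$varcomp$sigma2_e_by_year
  blup <- oracle_year_blups(ds, fit$varcomp$sigma2_Y, s2e)
  expect_equal(unname(blup["1971"]), yb$estimate[yb$harvest_year == 1971],
               tolerance = 1e-8)
})

test_that("the engine agrees with nlme's heteroscedastic REML", {
  sim <- simulate_dataset(sim_params(n_genotypes = 30, n_years = 5,
                                     occupancy = 0.7, dup_rate = 0),
                          seed = 7)
  fit <- fit_mixed(sim$dataset, spec_blue())
  d <- tibble::as_tibble(sim$dataset)
  d$g <- factor(d$accession_id)
  d$yr <- factor(d$harvest_year)
  lf <- nlme::lme(value ~ g, random = ~ 1 | yr,
                  weights = nlme::varIdent(form = ~ 1 | yr),
                  data = d, method = "REML",
                  control = nlme::lmeControl(opt = "optim", maxIter = 200,
                                             msMaxIter = 200))
  expect_equal(fit$reml_loglik, as.numeric(stats::logLik(lf)),
               tolerance = 1e-6)
  expect_equal(fit$varcomp$sigma2_Y,
               as.numeric(nlme::VarCorr(lf)[1, 1]), tolerance = 1e-3)
  em <- nlme::fixef(lf)
  blue_nlme <- sort(unname(em[1] + c(0, em[-1])))
  expect_equal(sort(blues(fit)$BLUE), blue_nlme, tolerance = 1e-4)
})

test_that("record order does not change the fit", {
  sim <- simulate_dataset(sim_params(n_genotypes = 15, n_years = 4,
                                     occupancy = 0.8), seed = 31)
  fit1 <- fit_mixed(sim$dataset, spec_blue(),
                    tol_loglik = 1e-13, tol_param = 1e-10)
  set.seed(99)
  shuffled <- rebuild_dataset(
    tibble::as_tibble(sim$dataset)[sample(nrow(sim$dataset)), ],
    sim$dataset)
  fit2 <- fit_mixed(shuffled, spec_blue(),
                    tol_loglik = 1e-13, tol_param = 1e-10)
  expect_equal(blues(fit1)$BLUE, blues(fit2)$BLUE, tolerance = 1e-9)
  expect_equal(fit1$theta, fit2$theta, tolerance = 1e-8)
})

test_that("reported BLUEs and variances are invariant to the identifiability coding", {
  sim <- simulate_dataset(sim_params(n_genotypes = 12, n_years = 4,
                                     occupancy = 0.9), seed = 41)
  f_tr <- fit_mixed(sim$dataset, spec_blue(), coding = "treatment")
  f_sum <- fit_mixed(sim$dataset, spec_blue(), coding = "sum")
  expect_equal(blues(f_tr)$BLUE, blues(f_sum)$BLUE, tolerance = 1e-5)
  expect_equal(f_tr$theta, f_sum$theta, tolerance = 1e-4)
})

test_that("variance estimates are scale-equivariant", {
  sim <- simulate_dataset(sim_params(n_genotypes = 15, n_years = 4,
                                     occupancy = 0.8), seed = 51)
  f1 <- fit_mixed(sim$dataset, spec_varcomp())
  scaled <- rebuild_dataset(
    dplyr::mutate(tibble::as_tibble(sim$dataset), value = value * 3),
    sim$dataset)
  f2 <- fit_mixed(scaled, spec_varcomp())
  expect_equal(f2$varcomp$sigma2_G, 9 * f1$varcomp$sigma2_G,
               tolerance = 1e-3)
  expect_equal(f2$varcomp$sigma2_e_bar, 9 * f1$varcomp$sigma2_e_bar,
               tolerance = 1e-3)
})

test_that("EM iterations never decrease the restricted log-likelihood", {
  sim <- simulate_dataset(sim_params(n_genotypes = 25, n_years = 5,
                                     occupancy = 0.6), seed = 61)
  fit <- fit_mixed(sim$dataset, spec_varcomp(), method = "em",
                   max_iter = 150)
  expect_true(all(diff(fit$loglik_trace) > -1e-7))
})

test_that("the optimum beats random parameter perturbations", {
  fit <- fit_mixed(toy_3x2, spec_varcomp())
  set.seed(7)
  theta <- fit$theta
  for (i in 1:50) {
    vc <- as.list(theta * exp(stats::rnorm(length(theta), 0, 0.4)))
    names(vc) <- names(theta)
    expect_lte(reml_loglik(toy_3x2, spec_varcomp(), vc),
               fit$reml_loglik + 1e-6)
  }
})

test_that("variance components are recovered without bias at moderate scale", {
  reps <- 30
  est <- t(vapply(seq_len(reps), function(i) {
    sim <- simulate_dataset(sim_params(n_genotypes = 80, n_years = 6,
                                       occupancy = 0.6, dup_rate = 0.01),
                            seed = 7000 + i)
    f <- fit_mixed(sim$dataset, spec_varcomp())
    c(G = f$varcomp$sigma2_G, Y = f$varcomp$sigma2_Y,
      e = f$varcomp$sigma2_e_bar,
      e_true = mean(sim$truth$year_effects$sigma2_e))
  }, numeric(4)))
  se <- apply(est, 2, stats::sd) / sqrt(reps)
  expect_lt(abs(mean(est[, "G"]) - 27), 3 * se["G"])
  expect_lt(abs(mean(est[, "Y"]) - 49), 3 * se["Y"])
  expect_lt(abs(mean(est[, "e"] - est[, "e_true"])), 3 * se["e"])
})

test_that("degenerate designs raise informative errors", {
  one_year <- make_dataset(c("A", "B", "C"), rep(1970, 3), c(1, 2, 3))
  expect_error(fit_mixed(one_year, spec_blue()), "single year")
  expect_error(fit_mixed(one_year[0, ], spec_blue()), "empty")
  sparse <- make_dataset(c("A", "B"), c(1970, 1971), c(1, 2))
  # both strata pool to a single 2-record pooled stratum: fine
  expect_error(fit_mixed(sparse, spec_blue(min_year_n = 3)), NA)
  # requesting BLUEs from a random-genotype fit is a usage error
  f <- fit_mixed(toy_3x2, spec_varcomp())
  expect_error(blues(f), "BLUP")
})

test_that("tidy and glance return well-formed summaries", {
  fit <- fit_mixed(toy_3x2, spec_blue())
  td <- tidy(fit)
  expect_setequal(unique(td$term), c("genotype", "year"))
  expect_equal(nrow(td), 3 + 2)
  gl <- glance(fit)
  expect_equal(gl$n_records, 6)
  expect_true(gl$converged)
})
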