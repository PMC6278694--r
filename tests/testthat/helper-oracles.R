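# Test fixtures and independent oracles.
#
# The oracles here deliberately use the direct dense-V formulation of the
# restricted likelihood and of generalized least squares, a different code
# path from the package's mixed-model-equation engine, so agreement between
# the two is a meaningful check.

make_dataset <- function(accession_id, harvest_year, value,
                         trait = "FT", habit = "spring") {
  historical_dataset(
    tibble::tibble(accession_id = accession_id,
                   harvest_year = as.integer(harvest_year),
                   value = value),
    trait = trait, habit = habit)
}

# Balanced noiseless grid: value = mu + g[i] + u[y]
make_noiseless_grid <- function(g = c(1, 2, 3, 4, 5), u = c(-2, 0, 1, 1),
                                mu = 10) {
  gi <- rep(seq_along(g), each = length(u))
  yi <- rep(seq_along(u), length(g))
  make_dataset(paste0("G", gi), 1970 + yi, mu + g[gi] + u[yi])
}

# Dense-V restricted log-likelihood, fixed effects profiled out.
# sigma2_e_by_year: named by year (every year its own stratum).
oracle_reml_loglik <- function(dataset, genotype_role, year_role,
                               sigma2_G = NULL, sigma2_Y = NULL,
                               sigma2_e_by_year) {
  rec <- tibble::as_tibble(dataset)
  y <- rec$value
  n <- length(y)
  g <- factor(rec$accession_id, levels = sort(unique(rec$accession_id)))
  yr <- factor(rec$harvest_year, levels = sort(unique(rec$harvest_year)))
  X <- matrix(1, n, 1)
  if (genotype_role == "fixed") {
    X <- cbind(X, stats::model.matrix(~g)[, -1, drop = FALSE])
  }
  if (year_role == "fixed" && nlevels(yr) > 1) {
    X <- cbind(X, stats::model.matrix(~yr)[, -1, drop = FALSE])
  }
  V <- diag(sigma2_e_by_year[as.character(rec$harvest_year)], n)
  if (genotype_role == "random") {
    Zg <- stats::model.matrix(~ g - 1)
    V <- V + sigma2_G * tcrossprod(Zg)
  }
  if (year_role == "random") {
    Zy <- stats::model.matrix(~ yr - 1)
    V <- V + sigma2_Y * tcrossprod(Zy)
  }
  Vi <- solve(V)
  XtViX <- crossprod(X, Vi %*% X)
  P <- Vi - Vi %*% X %*% solve(XtViX, crossprod(X, Vi))
  as.numeric(-0.5 * (determinant(V)$modulus +
                     determinant(XtViX)$modulus +
                     crossprod(y, P %*% y) +
                     (n - ncol(X)) * log(2 * pi)))
}

# GLS estimable accession means at given variance parameters (genotype fixed,
# year random), by direct dense algebra.
oracle_gls_blues <- function(dataset, sigma2_Y, sigma2_e_by_year) {
  rec <- tibble::as_tibble(dataset)
  y <- rec$value
  n <- length(y)
  g <- factor(rec$accession_id, levels = sort(unique(rec$accession_id)))
  yr <- factor(rec$harvest_year, levels = sort(unique(rec$harvest_year)))
  X <- cbind(1, stats::model.matrix(~g)[, -1, drop = FALSE])
  Zy <- stats::model.matrix(~ yr - 1)
  V <- diag(sigma2_e_by_year[as.character(rec$harvest_year)], n) +
    sigma2_Y * tcrossprod(Zy)
  Vi <- solve(V)
  b <- solve(crossprod(X, Vi %*% X), crossprod(X, Vi %*% y))
  stats::setNames(b[1] + c(0, b[-1]), levels(g))
}

# Year BLUPs at given variance parameters (genotype fixed, year random).
oracle_year_blups <- function(dataset, sigma2_Y, sigma2_e_by_year) {
  rec <- tibble::as_tibble(dataset)
  y <- rec$value
  n <- length(y)
  g <- factor(rec$accession_id, levels = sort(unique(rec$accession_id)))
  yr <- factor(rec$harvest_year, levels = sort(unique(rec$harvest_year)))
  X <- cbind(1, stats::model.matrix(~g)[, -1, drop = FALSE])
  Zy <- stats::model.matrix(~ yr - 1)
  V <- diag(sigma2_e_by_year[as.character(rec$harvest_year)], n) +
    sigma2_Y * tcrossprod(Zy)
  Vi <- solve(V)
  b <- solve(crossprod(X, Vi %*% X), crossprod(X, Vi %*% y))
  r <- y - X %*% b
  stats::setNames(as.numeric(sigma2_Y * crossprod(Zy, Vi %*% r)),
                  levels(yr))
}

write_study_fixture <- function(path, header = c("accession_id",
                                                 "accession_number",
                                                 "sowing_date", "harvest_year",
                                                 "country", "comment"),
                                rows) {
  writeLines(c(paste(header, collapse = "\t"),
               vapply(rows, paste, character(1), collapse = "\t")), path)
  path
}
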