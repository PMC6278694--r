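# REML engine for the two-way model  value = mu + genotype + year + error
# with year-specific error variances, on unbalanced plot-level data.
#
# Estimation works on Henderson's mixed-model equations (MME), so the cost per
# iteration is O(n) plus a Cholesky of the (p + q) x (p + q) coefficient
# matrix, never an n x n solve. Updates are average-information (AI) steps
# with EM fallback whenever an AI step would leave the feasible region or
# decrease the restricted likelihood. The following standard identities make
# everything computable from the MME solution (C = inverse coefficient
# matrix, Py = R^-1 (y - X b - Z u)):
#   -2 l_R = log|R| + log|G| + log|M| + y'Py + (n - p) log 2pi
#   tr(P Z_i Z_i') = (q_i s2_i - tr(C_ii)) / s2_i^2       (random factor i)
#   tr(P D_s)      = sum_{j in s} [ 1/d_j - w_j' C w_j / d_j^2 ]  (stratum s)
#   y'P Z_i Z_i' P y = ||u_i||^2 / s2_i^2
#   y'P D_s P y      = sum_{j in s} (Py)_j^2

#' Specify a variant of the two-way mixed model
#'
#' The three variants used in the curation workflow are available as presets:
#' [spec_blue()] (genotype fixed, year random) for outlier detection and
#' BLUEs, [spec_varcomp()] (both random) for variance components and
#' heritability, and [spec_yearcv()] (genotype random, year fixed) for
#' per-year coefficients of variation.
#'
#' @param genotype,year `"fixed"` or `"random"`.
#' @param heteroscedastic Model a separate error variance per year?
#' @param min_year_n Years with fewer records than this share one pooled
#'   error variance (every error stratum must keep >= 2 records). This
#'   generalises dropping a 2-record year outright, which remains available
#'   through `drop_years_below_n` in [detect_and_enhance()].
#' @return An object of class `rp_model_spec`.
#' @export
model_spec <- function(genotype = c("fixed", "random"),
                       year = c("random", "fixed"),
                       heteroscedastic = TRUE,
                       min_year_n = 3) {
  genotype <- match.arg(genotype)
  year <- match.arg(year)
  stopifnot(is.logical(heteroscedastic), min_year_n >= 2)
  structure(list(genotype = genotype, year = year,
                 heteroscedastic = heteroscedastic,
                 min_year_n = as.integer(min_year_n)),
            class = "rp_model_spec")
}

#' @rdname model_spec
#' @param ... Passed on to [model_spec()] to override defaults.
#' @export
spec_blue <- function(...) model_spec(genotype = "fixed", year = "random", ...)

#' @rdname model_spec
#' @export
spec_varcomp <- function(...) model_spec(genotype = "random", year = "random", ...)

#' @rdname model_spec
#' @export
spec_yearcv <- function(...) model_spec(genotype = "random", year = "fixed", ...)

#' @export
print.rp_model_spec <- function(x, ...) {
  cat(sprintf("<rp_model_spec> genotype %s, year %s, %s errors, min_year_n %d\n",
              x$genotype, x$year,
              if (x$heteroscedastic) "per-year" else "homoscedastic",
              x$min_year_n))
  invisible(x)
}

# ---- internal design construction -------------------------------------------

# Assign each record to an error stratum: its year when the year has at least
# min_year_n records, otherwise a shared "pooled" stratum.
error_strata <- function(harvest_year, heteroscedastic, min_year_n) {
  if (!heteroscedastic) {
    return(factor(rep("all", length(harvest_year))))
  }
  tab <- table(harvest_year)
  own <- names(tab)[tab >= min_year_n]
  lab <- ifelse(as.character(harvest_year) %in% own,
                as.character(harvest_year), "pooled")
  factor(lab, levels = c(sort(names(tab)[names(tab) %in% own]),
                         if (any(lab == "pooled")) "pooled"))
}

# Sparse incidence matrix of a factor (n x nlevels).
incidence <- function(f) {
  Matrix::sparseMatrix(i = seq_along(f), j = as.integer(f),
                       x = 1, dims = c(length(f), nlevels(f)))
}

# Fixed-effect design for a factor under a contrast coding, with intercept.
# Estimable cell means are recovered as intercept + K %*% beta.
contrast_design <- function(f, coding) {
  G <- nlevels(f)
  if (G == 1) {
    return(list(X = NULL, K = matrix(0, 1, 0)))
  }
  K <- switch(coding,
              treatment = stats::contr.treatment(G),
              sum = stats::contr.sum(G))
  list(X = Matrix::Matrix(K[as.integer(f), , drop = FALSE], sparse = TRUE),
       K = K)
}

build_mm <- function(dataset, spec, coding) {
  rec <- tibble::as_tibble(dataset)
  if (nrow(rec) == 0) stop("empty dataset", call. = FALSE)
  g <- factor(rec$accession_id, levels = sort(unique(rec$accession_id)))
  yr <- factor(rec$harvest_year, levels = sort(unique(rec$harvest_year)))
  if (spec$year == "random" && nlevels(yr) < 2) {
    stop("all records come from a single year; the year variance is not ",
         "identifiable with year treated as random", call. = FALSE)
  }
  if (spec$genotype == "random" && nlevels(g) < 2) {
    stop("genotype variance requires at least two accessions", call. = FALSE)
  }
  strat <- error_strata(rec$harvest_year, spec$heteroscedastic, spec$min_year_n)
  small <- table(strat) < 2
  if (any(small)) {
    stop("error stratum/strata with fewer than 2 records after pooling: ",
         paste(names(which(small)), collapse = ", "), call. = FALSE)
  }

  n <- nrow(rec)
  Xparts <- list(Matrix::Matrix(1, n, 1, sparse = TRUE))
  Kg <- Ky <- NULL
  Zparts <- list()
  ran_names <- character()
  ran_q <- integer()
  if (spec$genotype == "fixed") {
    d <- contrast_design(g, coding)
    Xparts <- c(Xparts, list(d$X))
    Kg <- d$K
  } else {
    Zparts <- c(Zparts, list(incidence(g)))
    ran_names <- c(ran_names, "sigma2_G")
    ran_q <- c(ran_q, nlevels(g))
  }
  if (spec$year == "fixed") {
    d <- contrast_design(yr, coding)
    if (!is.null(d$X)) Xparts <- c(Xparts, list(d$X))
    Ky <- d$K
  } else {
    Zparts <- c(Zparts, list(incidence(yr)))
    ran_names <- c(ran_names, "sigma2_Y")
    ran_q <- c(ran_q, nlevels(yr))
  }
  X <- do.call(cbind, Xparts)
  Z <- if (length(Zparts) > 0) do.call(cbind, Zparts) else NULL
  list(y = rec$value, X = X, Z = Z, g = g, yr = yr, strat = strat,
       Kg = Kg, Ky = Ky, ran_names = ran_names, ran_q = ran_q,
       n = n, p = ncol(X), records = rec)
}

# Restricted log-likelihood and all REML working quantities at one parameter
# point. theta = c(<random factor variances>, <stratum error variances>).
reml_eval <- function(mm, theta, want_work = TRUE) {
  k_ran <- length(mm$ran_names)
  n_strat <- nlevels(mm$strat)
  sig_ran <- theta[seq_len(k_ran)]
  sig_err <- theta[k_ran + seq_len(n_strat)]
  d <- sig_err[as.integer(mm$strat)]
  rinv <- 1 / d

  W <- if (is.null(mm$Z)) mm$X else cbind(mm$X, mm$Z)
  pq <- ncol(W)
  p <- mm$p
  Wr <- W * rinv                       # R^-1 W, sparse scaled rows
  M <- as.matrix(Matrix::crossprod(W, Wr))
  # add G^-1 on the random-effect diagonal
  if (k_ran > 0) {
    off <- p
    for (i in seq_len(k_ran)) {
      idx <- off + seq_len(mm$ran_q[i])
      diag(M)[idx] <- diag(M)[idx] + 1 / sig_ran[i]
      off <- off + mm$ran_q[i]
    }
  }
  cholM <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(cholM)) {
    return(list(loglik = -Inf, ok = FALSE))
  }
  rhs <- as.numeric(Matrix::crossprod(W, rinv * mm$y))
  sol <- backsolve(cholM, backsolve(cholM, rhs, transpose = TRUE))
  yPy <- sum(rinv * mm$y^2) - sum(sol * rhs)
  logdetM <- 2 * sum(log(diag(cholM)))
  logdetR <- sum(log(d))
  logdetG <- if (k_ran > 0) sum(mm$ran_q * log(sig_ran)) else 0
  loglik <- -0.5 * (logdetR + logdetG + logdetM + yPy +
                    (mm$n - p) * log(2 * pi))
  out <- list(loglik = loglik, ok = is.finite(loglik), sol = sol, yPy = yPy)
  if (!want_work || !out$ok) return(out)

  C <- chol2inv(cholM)
  Py <- rinv * (mm$y - as.numeric(W %*% sol))
  # per-record w_j' C w_j through one sparse product
  A <- W %*% C                         # n x pq, computed via sparse rows
  wCw <- Matrix::rowSums(W * A)
  diagP <- rinv - rinv^2 * wCw

  k <- k_ran + n_strat
  tr <- quad <- qsize <- numeric(k)
  S <- matrix(0, mm$n, k)
  off <- p
  for (i in seq_len(k_ran)) {
    idx <- off + seq_len(mm$ran_q[i])
    u_i <- sol[idx]
    trC <- sum(diag(C)[idx])
    tr[i] <- (mm$ran_q[i] * sig_ran[i] - trC) / sig_ran[i]^2
    quad[i] <- sum(u_i^2) / sig_ran[i]^2
    qsize[i] <- mm$ran_q[i]
    f <- if (mm$ran_names[i] == "sigma2_G") mm$g else mm$yr
    S[, i] <- u_i[as.integer(f)] / sig_ran[i]
    off <- off + mm$ran_q[i]
  }
  for (s in seq_len(n_strat)) {
    j <- which(as.integer(mm$strat) == s)
    tr[k_ran + s] <- sum(diagP[j])
    quad[k_ran + s] <- sum(Py[j]^2)
    qsize[k_ran + s] <- length(j)
    S[j, k_ran + s] <- Py[j]
  }
  # AI matrix: 0.5 S' P S with P v = R^-1 (v - W M^-1 W' R^-1 v)
  T0 <- as.matrix(Matrix::crossprod(W, rinv * S))
  B <- backsolve(cholM, backsolve(cholM, T0, transpose = TRUE))
  PS <- rinv * (S - as.matrix(W %*% B))
  AI <- 0.5 * crossprod(S, PS)
  AI <- (AI + t(AI)) / 2
  grad <- -0.5 * (tr - quad)
  c(out, list(C = C, Py = Py, tr = tr, quad = quad, qsize = qsize,
              grad = grad, AI = AI, diagP = diagP, rinv = rinv))
}

em_step <- function(theta, work) {
  theta + (theta^2 / work$qsize) * (work$quad - work$tr)
}

#' Fit the two-way mixed model by REML
#'
#' Fits `value ~ mu + genotype + year + error` on plot-level records with
#' year-specific error variances, in the variant given by `spec`. Variance
#' parameters are estimated by restricted maximum likelihood using
#' average-information updates with EM fallback; effects solve the mixed-model
#' equations at the REML optimum. Fitting is fully deterministic; internal
#' ordering is by sorted accession id and year.
#'
#' @param dataset A [historical_dataset()] (or a plain data frame with
#'   `accession_id`, `harvest_year`, `value`, in which case trait/habit
#'   metadata is not carried).
#' @param spec An [model_spec()]; default [spec_blue()].
#' @param method `"ai"` (average information with EM fallback) or `"em"`
#'   (pure EM; slower, with a monotone non-decreasing restricted
#'   log-likelihood).
#' @param max_iter Iteration cap.
#' @param tol_loglik,tol_param Stopping rule: relative restricted
#'   log-likelihood change below `tol_loglik` and maximum relative parameter
#'   change below `tol_param`.
#' @param coding Internal identifiability coding for fixed factors. Reported
#'   effects are estimable means, identical under either coding.
#' @param start Optional named starting values for the variance parameters.
#'
#' @return An object of class `rp_fit` with elements `mu_hat`,
#'   `genotype_effects` (tibble: `accession_id`, `estimate`; estimable means
#'   (BLUEs) when genotype is fixed, centred BLUPs when random),
#'   `year_effects` (tibble: `harvest_year`, `estimate`, centred in both
#'   roles), `varcomp` (list: `sigma2_G`, `sigma2_Y`, `sigma2_e_by_year`,
#'   `sigma2_e_bar`, `boundary`), `residuals` (per-record tibble with
#'   conditional residual and error stratum), `reml_loglik`, `converged`,
#'   `n_iter`, `E_bar` (mean number of distinct years per accession),
#'   `loglik_trace` and the `spec`.
#' @export
fit_mixed <- function(dataset, spec = spec_blue(),
                      method = c("ai", "em"),
                      max_iter = 200, tol_loglik = 1e-8, tol_param = 1e-6,
                      coding = c("treatment", "sum"), start = NULL) {
  method <- match.arg(method)
  coding <- match.arg(coding)
  stopifnot(inherits(spec, "rp_model_spec"))
  mm <- build_mm(dataset, spec, coding)

  vy <- stats::var(mm$y)
  if (!is.finite(vy) || vy <= 0) vy <- max(abs(mm$y[1]), 1)^2 * 1e-6 + 1e-12
  floor_v <- 1e-8 * vy

  k_ran <- length(mm$ran_names)
  n_strat <- nlevels(mm$strat)
  k <- k_ran + n_strat
  theta <- rep(vy / (k_ran + 1), k)
  names(theta) <- c(mm$ran_names, paste0("sigma2_e.", levels(mm$strat)))
  if (!is.null(start)) {
    common <- intersect(names(start), names(theta))
    theta[common] <- pmax(unlist(start)[common], floor_v)
  }

  work <- reml_eval(mm, theta)
  if (!work$ok) stop("restricted likelihood not computable at start",
                     call. = FALSE)
  trace <- work$loglik
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    if (method == "em") {
      theta_new <- pmax(em_step(theta, work), floor_v)
      work_new <- reml_eval(mm, theta_new)
    } else {
      delta <- tryCatch(solve(work$AI, work$grad), error = function(e) NULL)
      accepted <- FALSE
      if (!is.null(delta) && all(is.finite(delta))) {
        step <- 1
        for (h in 1:5) {
          cand <- pmax(theta + step * delta, floor_v)
          w <- reml_eval(mm, cand)
          if (w$ok && w$loglik >= work$loglik - 1e-10) {
            theta_new <- cand; work_new <- w; accepted <- TRUE
            break
          }
          step <- step / 2
        }
      }
      if (!accepted) {
        theta_new <- pmax(em_step(theta, work), floor_v)
        work_new <- reml_eval(mm, theta_new)
        if (!work_new$ok) {
          theta_new <- theta
          work_new <- work
        }
      }
    }
    rel_l <- abs(work_new$loglik - work$loglik) /
      (abs(work$loglik) + tol_loglik)
    rel_p <- max(abs(theta_new - theta) / pmax(theta, floor_v))
    theta <- theta_new
    work <- work_new
    trace <- c(trace, work$loglik)
    if (rel_l < tol_loglik && rel_p < tol_param) {
      converged <- TRUE
      break
    }
  }

  # ---- assemble results at the final parameter point ----
  sol <- work$sol
  p <- mm$p
  beta <- sol[seq_len(p)]
  mu_int <- beta[1]
  boundary <- theta <= floor_v * (1 + 1e-12)

  idx <- p
  genotype_effects <- NULL
  year_effects <- NULL
  sigma2_G <- NA_real_
  sigma2_Y <- NA_real_
  for (i in seq_len(k_ran)) {
    u_i <- sol[idx + seq_len(mm$ran_q[i])]
    if (mm$ran_names[i] == "sigma2_G") {
      sigma2_G <- unname(theta[i])
      genotype_effects <- tibble::tibble(
        accession_id = levels(mm$g), estimate = u_i, type = "BLUP")
    } else {
      sigma2_Y <- unname(theta[i])
      year_effects <- tibble::tibble(
        harvest_year = as.integer(levels(mm$yr)), estimate = u_i,
        type = "BLUP")
    }
    idx <- idx + mm$ran_q[i]
  }
  off <- 1
  mu_hat <- mu_int
  if (spec$genotype == "fixed") {
    nb <- ncol(mm$Kg)
    means <- mu_int + as.numeric(mm$Kg %*% beta[off + seq_len(nb)])
    genotype_effects <- tibble::tibble(
      accession_id = levels(mm$g), estimate = means, type = "BLUE")
    mu_hat <- mean(means)
    off <- off + nb
  }
  if (spec$year == "fixed") {
    nb <- if (is.null(mm$Ky)) 0 else ncol(mm$Ky)
    ymeans <- mu_int + if (nb > 0)
      as.numeric(mm$Ky %*% beta[off + seq_len(nb)]) else 0
    if (spec$genotype == "random") mu_hat <- mean(ymeans)
    year_effects <- tibble::tibble(
      harvest_year = as.integer(levels(mm$yr)),
      estimate = ymeans - mean(ymeans), type = "fixed")
    off <- off + nb
  }

  W <- if (is.null(mm$Z)) mm$X else cbind(mm$X, mm$Z)
  resid <- mm$y - as.numeric(W %*% sol)
  sig_err <- theta[k_ran + seq_len(n_strat)]
  strat_of_year <- function(yy) {
    if (!spec$heteroscedastic) return(rep(levels(mm$strat), length(yy)))
    lab <- as.character(yy)
    ifelse(lab %in% levels(mm$strat), lab, "pooled")
  }
  years <- as.integer(levels(mm$yr))
  sigma2_e_by_year <- stats::setNames(
    unname(sig_err[match(strat_of_year(years), levels(mm$strat))]),
    levels(mm$yr))
  # var(e_hat) = R - W C W' evaluated at the REML optimum; its diagonal is
  # d_j^2 * diag(P)_j, already available from the working quantities
  d_j <- unname(sig_err[as.integer(mm$strat)])
  resid_sd <- d_j * sqrt(pmax(work$diagP, 0))
  residuals <- tibble::tibble(
    accession_id = mm$records$accession_id,
    harvest_year = mm$records$harvest_year,
    replicate_index = mm$records$replicate_index,
    fitted = mm$y - resid,
    residual = resid,
    stratum = as.character(mm$strat),
    sigma2_e = d_j,
    resid_sd = resid_sd)

  E_bar <- mean(tapply(mm$records$harvest_year, mm$records$accession_id,
                       function(v) length(unique(v))))

  structure(list(
    spec = spec,
    method = method,
    coding = coding,
    mu_hat = mu_hat,
    genotype_effects = genotype_effects,
    year_effects = year_effects,
    varcomp = list(sigma2_G = sigma2_G, sigma2_Y = sigma2_Y,
                   sigma2_e_by_year = sigma2_e_by_year,
                   sigma2_e_bar = mean(sigma2_e_by_year),
                   sigma2_e_by_stratum = stats::setNames(unname(sig_err),
                                                         levels(mm$strat)),
                   boundary = boundary),
    theta = theta,
    residuals = residuals,
    reml_loglik = work$loglik,
    loglik_trace = trace,
    converged = converged,
    n_iter = iter,
    E_bar = E_bar,
    n_records = mm$n,
    n_genotypes = nlevels(mm$g),
    n_years = nlevels(mm$yr),
    trait = dataset_trait(dataset),
    habit = dataset_habit(dataset)
  ), class = "rp_fit")
}

#' @export
print.rp_fit <- function(x, ...) {
  cat(sprintf(
    "<rp_fit> genotype %s, year %s | %d records, %d accessions, %d years\n",
    x$spec$genotype, x$spec$year, x$n_records, x$n_genotypes, x$n_years))
  cat(sprintf("  REML loglik %.4f (%s in %d iterations)\n", x$reml_loglik,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  cat(sprintf("  sigma2_G = %s, sigma2_Y = %s, mean sigma2_e = %.4g, Ybar = %.2f\n",
              format(x$varcomp$sigma2_G, digits = 4),
              format(x$varcomp$sigma2_Y, digits = 4),
              x$varcomp$sigma2_e_bar, x$E_bar))
  invisible(x)
}

#' Restricted log-likelihood at given variance parameters
#'
#' Evaluates the REML criterion (fixed effects profiled out) for the model
#' variant in `spec` at user-supplied variance components. [fit_mixed()]
#' maximises exactly this function, so grid searches over it are a valid
#' independent check of the optimiser.
#'
#' @inheritParams fit_mixed
#' @param varcomp Named list/vector with the applicable entries among
#'   `sigma2_G`, `sigma2_Y`, and either `sigma2_e` (scalar, recycled over
#'   strata) or `sigma2_e.<stratum>` values for each error stratum (strata
#'   are years with at least `min_year_n` records, plus `pooled`).
#' @return The restricted log-likelihood (includes its additive constant).
#' @export
reml_loglik <- function(dataset, spec, varcomp,
                        coding = c("treatment", "sum")) {
  coding <- match.arg(coding)
  mm <- build_mm(dataset, spec, coding)
  k_ran <- length(mm$ran_names)
  n_strat <- nlevels(mm$strat)
  vc <- unlist(varcomp)
  theta <- numeric(k_ran + n_strat)
  for (i in seq_len(k_ran)) {
    if (!mm$ran_names[i] %in% names(vc)) {
      stop("varcomp is missing ", mm$ran_names[i], call. = FALSE)
    }
    theta[i] <- vc[[mm$ran_names[i]]]
  }
  strat_names <- paste0("sigma2_e.", levels(mm$strat))
  if ("sigma2_e" %in% names(vc) && !any(strat_names %in% names(vc))) {
    theta[k_ran + seq_len(n_strat)] <- vc[["sigma2_e"]]
  } else {
    hit <- match(strat_names, names(vc))
    if (anyNA(hit)) {
      stop("varcomp is missing error variance(s): ",
           paste(strat_names[is.na(hit)], collapse = ", "), call. = FALSE)
    }
    theta[k_ran + seq_len(n_strat)] <- vc[hit]
  }
  if (any(theta <= 0)) stop("all variance parameters must be positive",
                            call. = FALSE)
  reml_eval(mm, theta, want_work = FALSE)$loglik
}

#' Extract BLUEs of accessions from a fixed-genotype fit
#'
#' @param fit An `rp_fit` with `spec$genotype == "fixed"`.
#' @return A tibble `accession_id`, `BLUE` — the estimable accession means
#'   (population mean plus genotype effect), invariant to the internal
#'   identifiability coding.
#' @export
blues <- function(fit) {
  stopifnot(inherits(fit, "rp_fit"))
  if (fit$spec$genotype != "fixed") {
    stop("genotype was fitted as random; use fit$genotype_effects for BLUPs ",
         "or refit with spec_blue()", call. = FALSE)
  }
  tibble::tibble(accession_id = fit$genotype_effects$accession_id,
                 BLUE = fit$genotype_effects$estimate)
}
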