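#' Settings for individual and population fits
#'
#' @param error_model Residual error model for serum concentrations;
#'   `"lognormal"` (multiplicative, the default) or `"additive"`.
#' @param loq Quantification limit used for censored points when the
#'   series itself does not carry one (censored points store the limit
#'   as their value).
#' @param tol Relative convergence tolerance of the individual
#'   optimizer.
#' @param pop_tol Relative movement of population means below which the
#'   two-stage iteration stops.
#' @param maxit Maximum optimizer iterations.
#' @param pop_maxit Maximum two-stage iterations.
#' @param n_restarts Number of jittered restarts of the individual
#'   optimizer (the best objective wins).
#' @param seed Seed controlling restart jitter; every stochastic step in
#'   the package is seed-controlled.
#' @return A `fit_settings` list.
#' @export
fit_settings <- function(error_model = c("lognormal", "additive"),
                         loq = NULL, tol = 1e-10, pop_tol = 1e-4,
                         maxit = 500, pop_maxit = 25,
                         n_restarts = 3, seed = 1L) {
  error_model <- match.arg(error_model)
  stopifnot(tol > 0, pop_tol > 0, maxit > 0, n_restarts >= 1)
  structure(list(error_model = error_model, loq = loq, tol = tol,
                 pop_tol = pop_tol, maxit = maxit, pop_maxit = pop_maxit,
                 n_restarts = n_restarts, seed = as.integer(seed)),
            class = "fit_settings")
}

## negative log-likelihood of one individual's sessions given
## log-parameters (k_pc, k_cp, k_el, vol_per_m2) and log sigma
serum_nll <- function(logtheta, log_sigma, sessions, bsa, error_model) {
  th <- exp(logtheta)
  if (any(!is.finite(th))) return(1e10)
  p <- structure(list(k_pc = th[1], k_cp = th[2], k_el = th[3],
                      vol_per_m2 = th[4]),
                 class = "two_compartment_params")
  sigma <- exp(log_sigma)
  nll <- 0
  for (s in sessions) {
    f <- predict_concentration(p, bsa, s$infusions, s$series$time_h)
    y <- s$series$value
    cen <- s$series$censored
    if (error_model == "lognormal") {
      f <- pmax(f, 1e-300)
      r <- (log(y[!cen]) - log(f[!cen])) / sigma
      nll <- nll + sum(log(sigma) + 0.5 * r^2)
      if (any(cen)) {
        z <- (log(y[cen]) - log(f[cen])) / sigma
        nll <- nll - sum(pnorm(z, log.p = TRUE))
      }
    } else {
      r <- (y[!cen] - f[!cen]) / sigma
      nll <- nll + sum(log(sigma) + 0.5 * r^2)
      if (any(cen)) {
        z <- (y[cen] - f[cen]) / sigma
        nll <- nll - sum(pnorm(z, log.p = TRUE))
      }
    }
  }
  if (!is.finite(nll)) 1e10 else nll
}

## heuristic starting values from the data
naive_init <- function(sessions, bsa) {
  s <- sessions[[1]]
  dose <- sum(vapply(if (inherits(s$infusions, "infusion_record"))
    list(s$infusions) else s$infusions, function(i) i$dose, 0))
  ok <- !s$series$censored & s$series$value > 0
  y <- s$series$value[ok]; t <- s$series$time_h[ok]
  cmax <- max(y)
  vol0 <- max(dose / (bsa * cmax), 1e-3)
  n <- length(y)
  kel0 <- 0.1
  if (n >= 2) {
    sl <- (log(y[1]) - log(y[n])) / max(t[n] - t[1], 1e-6)
    if (is.finite(sl) && sl > 1e-4) kel0 <- sl * 2
  }
  c(log(kel0 / 5), log(kel0 / 20), log(kel0), log(vol0))
}

#' Fit one individual's serum kinetics
#'
#' Maximum-likelihood (or, with a prior, maximum a posteriori) fit of a
#' two-compartment infusion model to one individual's serum series.
#' Several sessions may be fitted jointly with a single shared parameter
#' set.  The residual error is multiplicative lognormal by default;
#' points below the quantification limit contribute through the
#' cumulative-density term of the likelihood.
#'
#' @param sessions Either a single [concentration_series()] (then
#'   `infusions` must be given) or a list of sessions, each a list with
#'   elements `series` and `infusions`.
#' @param infusions Infusion history when `sessions` is a single series.
#' @param bsa Body surface area (m2).
#' @param settings A [fit_settings()].
#' @param init Optional starting values on the natural scale
#'   `c(k_pc, k_cp, k_el, vol_per_m2)`.
#' @param prior Optional lognormal prior: list with `mu` (log-scale
#'   means) and `omega` (log-scale SDs), both length 4.  Used by
#'   [fit_population()] for shrinkage.
#' @param sigma Optional fixed residual SD (log scale for the lognormal
#'   error model).  When `NULL` (default) sigma is estimated jointly
#'   with the kinetic parameters; [fit_population()] fixes it at the
#'   pooled population value, where it is far better identified than
#'   from a single patient's partly censored series.
#' @return A `pk_fit` list: `params` ([two_compartment_params()]),
#'   `sigma`, `objective`, `converged`, `n_obs`.
#' @export
fit_individual <- function(sessions, infusions = NULL, bsa,
                           settings = fit_settings(), init = NULL,
                           prior = NULL, sigma = NULL) {
  if (inherits(sessions, "concentration_series")) {
    if (is.null(infusions)) stop("infusions required with a single series")
    sessions <- list(list(series = sessions, infusions = infusions))
  }
  n_obs <- sum(vapply(sessions, function(s) sum(!s$series$censored), 0L))
  if (n_obs == 0) stop("all observations are censored; cannot fit")
  if (n_obs < 4 && is.null(prior))
    stop("fewer informative points (", n_obs, ") than free parameters")
  start <- if (is.null(init)) naive_init(sessions, bsa) else log(init)
  any_cens <- any(vapply(sessions, function(s) any(s$series$censored),
                         TRUE))
  ## without censoring sigma has a closed-form profile (RMS residual),
  ## which keeps the objective well conditioned as residuals vanish;
  ## with censored points sigma is estimated jointly
  profile_sigma <- is.null(sigma) && !any_cens
  np <- if (is.null(sigma) && !profile_sigma) 5L else 4L
  prof <- function(logtheta) {
    r <- unlist(lapply(sessions, function(s) {
      th <- exp(logtheta)
      p <- structure(list(k_pc = th[1], k_cp = th[2], k_el = th[3],
                          vol_per_m2 = th[4]),
                     class = "two_compartment_params")
      f <- predict_concentration(p, bsa, s$infusions, s$series$time_h)
      if (settings$error_model == "lognormal")
        log(s$series$value) - log(pmax(f, 1e-300))
      else s$series$value - f
    }))
    if (any(!is.finite(r))) return(list(nll = 1e10, sigma = NA_real_))
    s2 <- max(mean(r^2), 1e-28)
    list(nll = length(r) / 2 * (log(s2) + 1), sigma = sqrt(s2))
  }
  obj <- function(x) {
    nll <- if (profile_sigma) {
      prof(x[1:4])$nll
    } else {
      ls <- if (is.null(sigma)) x[5] else log(sigma)
      serum_nll(x[1:4], ls, sessions, bsa, settings$error_model)
    }
    if (!is.null(prior))
      nll <- nll + sum(((x[1:4] - prior$mu) / prior$omega)^2) / 2
    nll
  }
  best <- NULL
  set.seed(settings$seed)
  jitters <- rbind(rep(0, np),
                   matrix(rnorm(np * (settings$n_restarts - 1), 0, 0.5),
                          ncol = np))
  start_full <- if (np == 5L) c(start, log(0.15)) else start
  ## sigma is bounded away from zero: on noise-free data the profiled
  ## likelihood diverges as sigma -> 0
  lower <- c(rep(-30, 4), log(1e-8))[seq_len(np)]
  for (k in seq_len(settings$n_restarts)) {
    st <- pmax(start_full + jitters[k, ], lower + 1)
    fit <- tryCatch(
      nlminb(st, obj, lower = lower,
             control = list(iter.max = settings$maxit,
                            rel.tol = settings$tol)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$objective < best$objective))
      best <- fit
  }
  if (is.null(best)) stop("individual fit failed from all starts")
  th <- exp(best$par[1:4])
  ## posterior variance of the log-parameters from the curvature at the
  ## optimum; used by the population variance update
  post_var <- rep(NA_real_, 4)
  hess <- tryCatch(optimHess(best$par, obj), error = function(e) NULL)
  if (!is.null(hess)) {
    cv <- tryCatch(solve(hess), error = function(e) NULL)
    if (!is.null(cv)) {
      d <- diag(cv)[1:4]
      if (all(is.finite(d)) && all(d > 0)) post_var <- d
    }
  }
  sig_hat <- if (!is.null(sigma)) sigma
             else if (profile_sigma) prof(best$par[1:4])$sigma
             else exp(best$par[5])
  structure(list(
    params = two_compartment_params(th[1], th[2], th[3], th[4]),
    sigma = sig_hat,
    objective = best$objective,
    # residuals at the numerical floor mean an (essentially) exact fit;
    # the optimizer then stops on a flat objective and reports "false
    # convergence" although the solution is fully determined
    converged = best$convergence == 0 || sig_hat < 1e-8,
    n_obs = n_obs,
    log_post_var = post_var,
    message = best$message),
    class = "pk_fit")
}

#' @export
print.pk_fit <- function(x, ...) {
  cat(sprintf("Individual two-compartment fit (%s, n = %d, obj = %.3f)\n",
              if (x$converged) "converged" else "NOT converged",
              x$n_obs, x$objective))
  print(x$params)
  invisible(x)
}

#' Population fit by global two-stage estimation
#'
#' Iterates individual MAP fits against a lognormal population
#' distribution whose mean and variance are updated from the current
#' individual estimates, until the population means move less than
#' `settings$pop_tol` (relative).  With the BSA covariate active the
#' volume parameter is the BSA-normalised central volume (L/m2), which
#' carries much less between-patient dispersion than the raw central
#' volume; with the covariate disabled the volume parameter is the raw
#' Vc.
#'
#' @param cohort A list of records, each a list with `id`, `bsa`, and
#'   `sessions` (a list of `list(series, infusions)`).  A record is one
#'   estimation unit: a patient (antibody, sessions pooled) or a
#'   patient-isotope series (hapten).
#' @param settings A [fit_settings()].
#' @param covariate_bsa If `TRUE` (default) set `Vc = vol_per_m2 * bsa`;
#'   if `FALSE` fit the raw central volume (bsa treated as 1).
#' @param init Optional natural-scale starting values passed to every
#'   individual fit.
#' @return A `population_estimate`: `population_mean` and
#'   `population_sd` (natural scale, per parameter), `individual`
#'   (data frame of per-record estimates with derived `vc` and
#'   `clearance`), `summary` (mean/SD/CV% table), `iterations`,
#'   `converged`.
#' @export
fit_population <- function(cohort, settings = fit_settings(),
                           covariate_bsa = TRUE, init = NULL) {
  if (length(cohort) == 0) stop("empty cohort")
  if (length(cohort) == 1) {
    warning("single record: population estimate degrades to the ",
            "individual fit")
  }
  pnames <- c("k_pc", "k_cp", "k_el", "vol_per_m2")
  bsas <- vapply(cohort, function(r) if (covariate_bsa) r$bsa else 1, 0)
  fit_one <- function(i, prior, warm = NULL, sigma = NULL) {
    fit_individual(cohort[[i]]$sessions, bsa = bsas[i],
                   settings = settings,
                   init = if (is.null(warm)) init else warm[i, ],
                   prior = prior, sigma = sigma)
  }
  fits <- lapply(seq_along(cohort), fit_one, prior = NULL)
  ## residual error is a population-level quantity: pool it across
  ## individuals (n-weighted RMS) and fix it during the MAP iterations
  pooled_sigma <- function(fits) {
    n <- vapply(fits, function(f) f$n_obs, 0L)
    s <- vapply(fits, function(f) f$sigma, 0)
    sqrt(sum(n * s^2) / sum(n))
  }
  get_logth <- function(fits) t(vapply(fits, function(f)
    log(unlist(f$params[pnames])), numeric(4)))
  ## EM-style variance update: dispersion of the (shrunken) estimates
  ## plus the mean posterior variance, so that shrinkage does not
  ## collapse the population variance
  get_omega <- function(fits, logth, mu) {
    pv <- t(vapply(fits, function(f) f$log_post_var, numeric(4)))
    pv[!is.finite(pv)] <- 0
    disp <- colMeans((logth - matrix(mu, nrow(logth), 4,
                                     byrow = TRUE))^2)
    pmax(sqrt(disp + colMeans(pv)), 0.02)
  }
  logth <- get_logth(fits)
  mu <- colMeans(logth)
  iterations <- 0L
  converged <- TRUE
  if (length(cohort) > 1) {
    converged <- FALSE
    omega <- get_omega(fits, logth, mu)
    sig <- pooled_sigma(fits)
    for (it in seq_len(settings$pop_maxit)) {
      fits <- lapply(seq_along(cohort), fit_one,
                     prior = list(mu = mu, omega = omega),
                     warm = exp(logth), sigma = sig)
      logth <- get_logth(fits)
      mu_new <- colMeans(logth)
      omega <- get_omega(fits, logth, mu_new)
      iterations <- it
      if (max(abs(mu_new - mu) / pmax(abs(mu), 1e-8)) < settings$pop_tol) {
        mu <- mu_new
        converged <- TRUE
        break
      }
      mu <- mu_new
    }
  }
  est <- exp(logth)
  colnames(est) <- pnames
  ind <- data.frame(id = vapply(cohort, function(r) as.character(r$id), ""),
                    est, row.names = NULL)
  ind$vc <- ind$vol_per_m2 * vapply(cohort, function(r) r$bsa, 0)
  ind$clearance <- ind$vc * ind$k_el
  structure(list(
    population_mean = setNames(exp(mu), pnames),
    population_sd = setNames(apply(est, 2, sd), pnames),
    individual = ind,
    summary = summarize_individuals(ind[, c(pnames, "vc", "clearance")]),
    fits = fits,
    iterations = iterations,
    converged = converged,
    covariate_bsa = covariate_bsa),
    class = "population_estimate")
}

#' @export
print.population_estimate <- function(x, ...) {
  cat(sprintf("Population estimate over %d records (%s, %d iterations)\n",
              nrow(x$individual),
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  print(x$summary, digits = 3)
  invisible(x)
}

#' Mean, SD and CV of individual parameter estimates
#'
#' Column-wise mean, sample standard deviation (n - 1 denominator) and
#' coefficient of variation in percent, computed over individual
#' estimates as in population PK summary tables.
#'
#' @param estimates A data frame or matrix of per-individual parameter
#'   values (numeric columns).
#' @return A data frame with columns `parameter`, `mean`, `sd`,
#'   `cv_percent`.
#' @examples
#' tab <- pk_table_tf2()
#' summarize_individuals(tab[, c("k_el", "clearance")])
#' @export
summarize_individuals <- function(estimates) {
  estimates <- as.data.frame(estimates)
  num <- vapply(estimates, is.numeric, TRUE)
  estimates <- estimates[, num, drop = FALSE]
  if (nrow(estimates) < 1) stop("no individuals to summarize")
  m <- vapply(estimates, mean, 0)
  s <- if (nrow(estimates) > 1) vapply(estimates, sd, 0) else
    setNames(rep(0, ncol(estimates)), names(m))
  data.frame(parameter = names(m), mean = unname(m), sd = unname(s),
             cv_percent = unname(100 * s / m), row.names = NULL)
}
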