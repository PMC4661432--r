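#' Radionuclide physical constants
#'
#' @param name Isotope label, e.g. `"In111"` or `"Lu177"`.
#' @param half_life_h Physical half-life in hours.  The bundled defaults
#'   ([isotope_in111()], [isotope_lu177()]) are configuration values and
#'   can be overridden.
#' @return An `isotope_spec` with `name`, `half_life_h` and the decay
#'   constant `lambda_phys = ln 2 / half_life_h` (1/h).
#' @export
isotope_spec <- function(name, half_life_h) {
  if (half_life_h <= 0) stop("half_life_h must be positive")
  structure(list(name = name, half_life_h = half_life_h,
                 lambda_phys = log(2) / half_life_h),
            class = "isotope_spec")
}

#' @rdname isotope_spec
#' @export
isotope_in111 <- function() isotope_spec("In111", 67.32)

#' @rdname isotope_spec
#' @export
isotope_lu177 <- function() isotope_spec("Lu177", 159.53)

#' Fit mono- or biexponential function to a time-activity curve
#'
#' Organ time-activity points (decay-corrected) are adjusted with a sum
#' of decaying exponentials with nonnegative coefficients:
#' monoexponential when fewer than 4 points are available,
#' biexponential otherwise (a biexponential has four unknowns and needs
#' at least four points to be identifiable).
#'
#' @param times Measurement times (h).
#' @param activities Decay-corrected activities (MBq), nonnegative.
#' @param form `"auto"` (default rule), `"mono"` or `"bi"`.
#' @return An `exponential_fit`: `form`, `coef` (MBq), `rates` (1/h),
#'   `converged`, `degenerate` (flagged when the optimizer pinned a
#'   component to zero or failed to separate rates).
#' @examples
#' t <- c(1, 24, 48, 120)
#' fit_time_activity(t, 100 * exp(-0.05 * t))
#' @export
fit_time_activity <- function(times, activities, form = c("auto", "mono", "bi")) {
  form <- match.arg(form)
  if (length(times) != length(activities))
    stop("times and activities must have equal length")
  if (length(times) < 2) stop("at least 2 points are required")
  if (any(activities < 0)) stop("activities must be nonnegative")
  if (form == "auto") form <- if (length(times) < 4) "mono" else "bi"
  if (form == "bi" && length(times) < 4)
    stop("biexponential fit needs at least 4 points")
  pos <- activities > 0
  if (sum(pos) < 2) stop("need at least 2 positive activities")
  ## mono init from log-linear regression on positive points
  lf <- lm(log(activities[pos]) ~ times[pos])
  c0 <- exp(coef(lf)[1])
  l0 <- max(-coef(lf)[2], 1e-4)
  ssq <- function(x) {
    p <- exp(x)
    k <- length(p) / 2
    pred <- rowSums(vapply(seq_len(k), function(i)
      p[i] * exp(-p[k + i] * times), numeric(length(times))))
    s <- sum((activities - pred)^2)
    if (!is.finite(s)) 1e10 else s
  }
  if (form == "mono") {
    fit <- nlminb(log(c(c0, l0)), ssq, control = list(iter.max = 500))
    cf <- exp(fit$par[1]); rt <- exp(fit$par[2])
  } else {
    starts <- list(log(c(0.7 * c0, 0.3 * c0, l0 * 3, l0 / 3)),
                   log(c(0.5 * c0, 0.5 * c0, l0 * 10, max(l0 / 10, 1e-5))),
                   log(c(0.9 * c0, 0.1 * c0, l0, l0 / 5)))
    fit <- NULL
    for (st in starts) {
      f <- tryCatch(nlminb(st, ssq, control = list(iter.max = 1000)),
                    error = function(e) NULL)
      if (!is.null(f) && (is.null(fit) || f$objective < fit$objective))
        fit <- f
    }
    p <- exp(fit$par)
    ord <- order(p[3:4], decreasing = TRUE)
    cf <- p[1:2][ord]; rt <- p[3:4][ord]
  }
  degenerate <- any(cf < 1e-10 * max(cf)) ||
    (form == "bi" && rt[1] / rt[2] < 1 + 1e-6)
  structure(list(form = form, coef = unname(cf), rates = unname(rt),
                 converged = fit$convergence == 0,
                 degenerate = degenerate),
            class = "exponential_fit")
}

#' Cumulated activity of a fitted time-activity curve
#'
#' Closed-form time integral from 0 to infinity of the fitted
#' decay-corrected curve with physical decay re-applied:
#' \deqn{\tilde A = \sum_i \frac{c_i}{\lambda_i + \lambda_{phys}}.}
#' Stored activities are decay-corrected to injection time, so the
#' physical decay constant enters only here.
#'
#' @param fit An `exponential_fit` (see [fit_time_activity()]) or a list
#'   with `coef` and `rates`.
#' @param isotope An [isotope_spec()].
#' @return Cumulated activity in MBq h.
#' @examples
#' cumulated_activity(list(coef = 1, rates = 0), isotope_spec("X", 1))
#' @export
cumulated_activity <- function(fit, isotope) {
  lam <- fit$rates + isotope$lambda_phys
  if (any(lam <= 0)) stop("lambda_bio + lambda_phys must be positive")
  sum(fit$coef / lam)
}

#' Translate a cumulated activity between radionuclides
#'
#' Under the assumption that the biological kinetics are identical for
#' the two labels, the imaging-session estimate is rescaled to the
#' therapy radionuclide by recomputing the integral with the target
#' physical decay constant.
#'
#' @param fit An `exponential_fit` of decay-corrected data.
#' @param from,to [isotope_spec()] of the measured and target labels.
#' @return Cumulated activity (MBq h) under the target isotope's decay.
#' @export
translate_isotope <- function(fit, from, to) {
  # `from` enters only through the shared biological fit; the integral
  # is recomputed with the target physical constant
  stopifnot(inherits(to, "isotope_spec"))
  cumulated_activity(fit, to)
}

#' Absorbed doses from cumulated activities and S factors
#'
#' MIRD-style dose estimate: the dose to each target organ is the sum
#' over source organs of cumulated activity times the S factor, with
#' the self-dose S factor rescaled by reference/patient organ mass
#' (electron self-absorption scales inversely with mass; photon
#' cross-organ terms are left unscaled).
#'
#' @param cumulated Named numeric vector of cumulated activities
#'   (MBq h) per source organ.
#' @param s_table An S-factor table as returned by [sfactor_table()] or
#'   [read_sfactor_table()]: data frame with `source`, `target`,
#'   `S_mGy_per_MBq_h`, `ref_mass_kg` (reference mass of the target).
#' @param organ_masses Named numeric vector of patient organ masses (kg)
#'   for every target organ.
#' @param administered Administered activity (MBq) used for the
#'   normalized dose; `NA` leaves the normalized column `NA`.
#' @param session,cohort Labels carried into the report.
#' @return A `dose_report` data frame: `organ`, `cumulated_MBq_h`,
#'   `dose_mGy`, `dose_mGy_per_MBq`, `session`, `cohort`.
#' @export
absorbed_dose <- function(cumulated, s_table, organ_masses,
                          administered = NA_real_, session = "S1",
                          cohort = NA_character_) {
  if (is.null(names(cumulated)) || any(names(cumulated) == ""))
    stop("cumulated must be a named vector of source organs")
  if (any(cumulated < 0)) stop("cumulated activities must be nonnegative")
  if (any(organ_masses <= 0)) stop("organ masses must be positive")
  targets <- names(cumulated)
  dose <- setNames(numeric(length(targets)), targets)
  for (tg in targets) {
    if (!tg %in% names(organ_masses))
      stop("no patient mass for organ ", tg)
    for (src in names(cumulated)) {
      row <- s_table[s_table$source == src & s_table$target == tg, ]
      if (nrow(row) == 0)
        stop("missing S factor for pair (", src, " -> ", tg, ")")
      scale <- if (src == tg) row$ref_mass_kg[1] / organ_masses[tg] else 1
      dose[tg] <- dose[tg] +
        cumulated[src] * row$S_mGy_per_MBq_h[1] * scale
    }
  }
  structure(data.frame(organ = targets,
                       cumulated_MBq_h = unname(cumulated),
                       dose_mGy = unname(dose),
                       dose_mGy_per_MBq = unname(dose) / administered,
                       session = session, cohort = cohort,
                       row.names = NULL),
            class = c("dose_report", "data.frame"))
}

## all permutations of 1..n (n! x n matrix); n <= 8 in exact tests
all_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Spearman correlation with exact permutation p-value
#'
#' Spearman's rho computed from mid-ranks, with a two-sided p-value by
#' exhaustive enumeration of all n! permutations for n <= 8 and a
#' t-approximation above.
#'
#' @param x,y Numeric vectors of equal length (n >= 3).
#' @param exact_max Largest n for which the exact enumeration is used.
#' @return List with `rho`, `p_value`, `method`.
#' @export
spearman_exact <- function(x, y, exact_max = 8) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3) stop("need at least 3 pairs")
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) stop("constant ranks: rho undefined")
  rho <- cor(rx, ry)
  if (n <= exact_max) {
    pm <- all_perms(n)
    rhos <- apply(pm, 1, function(p) cor(rx, ry[p]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, 1e-12))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    method <- "t approximation"
  }
  list(rho = rho, p_value = p, method = method)
}

#' Compare absorbed doses between sessions
#'
#' Tests whether imaging-session (S1) normalized doses predict
#' therapy-session (S2) doses: Spearman rank correlation with exact
#' permutation p-value for small organ sets, and a paired Wilcoxon
#' signed-rank test for a location shift.
#'
#' @param report_s1,report_s2 `dose_report`s (see [absorbed_dose()])
#'   over identical organ sets.
#' @param value Column compared; default the normalized dose.
#' @return List with `spearman` (rho, p_value, method) and `wilcoxon`
#'   (`htest`).
#' @export
compare_sessions <- function(report_s1, report_s2,
                             value = "dose_mGy_per_MBq") {
  if (!setequal(report_s1$organ, report_s2$organ) ||
      nrow(report_s1) != nrow(report_s2))
    stop("mismatched organ sets between sessions")
  s2 <- report_s2[match(report_s1$organ, report_s2$organ), ]
  x <- report_s1[[value]]
  y <- s2[[value]]
  sp <- spearman_exact(x, y)
  wx <- suppressWarnings(wilcox.test(x, y, paired = TRUE))
  list(spearman = sp, wilcoxon = wx)
}

#' Compare doses across dosing cohorts
#'
#' Kruskal-Wallis rank-sum test of absorbed doses across two or more
#' cohorts.
#'
#' @param doses Numeric vector of doses.
#' @param cohorts Factor or character vector of cohort labels, same
#'   length as `doses`.
#' @return The `htest` returned by [stats::kruskal.test()].
#' @export
compare_cohorts <- function(doses, cohorts) {
  if (length(unique(cohorts)) < 2) stop("need at least 2 cohorts")
  kruskal.test(doses, factor(cohorts))
}
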