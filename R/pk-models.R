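#' Two-compartment kinetic parameters
#'
#' Rate constants of a mammillary two-compartment model with elimination
#' from the central compartment.  The naming is directional and
#' unambiguous: `k_pc` transfers peripheral to central, `k_cp` central to
#' peripheral.  Published tables that print generic `k_2,1`/`k_1,2`
#' labels are mapped onto these names by the fixture loaders (see
#' [pk_table_tf2()]), which record the mapping they applied.
#'
#' @param k_pc Transfer rate peripheral -> central (1/h).
#' @param k_cp Transfer rate central -> peripheral (1/h).
#' @param k_el Elimination rate from the central compartment (1/h).
#' @param vol_per_m2 Central volume per body surface area (L/m2).
#'   The central volume of a patient is `vol_per_m2 * bsa`.
#' @return An object of class `two_compartment_params`.
#' @examples
#' two_compartment_params(k_pc = 0.034, k_cp = 0.0075, k_el = 0.182,
#'                        vol_per_m2 = 1.86)
#' @export
two_compartment_params <- function(k_pc, k_cp, k_el, vol_per_m2 = NA_real_) {
  stopifnot(is.numeric(k_pc), is.numeric(k_cp), is.numeric(k_el))
  if (k_pc < 0 || k_cp < 0 || k_el < 0)
    stop("rate constants must be nonnegative")
  if (!is.na(vol_per_m2) && vol_per_m2 <= 0)
    stop("vol_per_m2 must be positive")
  structure(list(k_pc = k_pc, k_cp = k_cp, k_el = k_el,
                 vol_per_m2 = vol_per_m2),
            class = "two_compartment_params")
}

#' @export
print.two_compartment_params <- function(x, ...) {
  cat("Two-compartment parameters (1/h):\n")
  cat(sprintf("  k_pc = %.4g  k_cp = %.4g  k_el = %.4g  vol/m2 = %.4g L/m2\n",
              x$k_pc, x$k_cp, x$k_el, x$vol_per_m2))
  invisible(x)
}

#' An administered infusion
#'
#' A zero-order intravenous infusion of antibody (molar dose) or of
#' radiolabelled hapten (molar dose or activity).  Doses are amounts,
#' not amounts per surface area: scale by BSA before constructing the
#' record.
#'
#' @param dose Amount administered (nmol for molar series, MBq for
#'   activity series).  Must be nonnegative.
#' @param t_start Start of the infusion (h).
#' @param duration Infusion length (h); default 0.5 h (infusions of
#'   30-60 min are typical; configurable per record).
#' @param session Session label, e.g. `"S1"` (imaging) or `"S2"`
#'   (therapy).
#' @param analyte One of `"TF2"`, `"IMP288-In111"`, `"IMP288-Lu177"`, or
#'   any user label.
#' @return An object of class `infusion_record`.
#' @export
infusion_record <- function(dose, t_start = 0, duration = 0.5,
                            session = "S1", analyte = "TF2") {
  if (dose < 0) stop("dose must be nonnegative")
  if (duration <= 0) stop("duration must be positive")
  if (t_start < 0) stop("t_start must be nonnegative")
  structure(list(dose = dose, t_start = t_start, duration = duration,
                 session = session, analyte = analyte),
            class = "infusion_record")
}

#' A timestamped serum concentration (or activity) series
#'
#' @param times Sampling times (h, relative to infusion start); strictly
#'   increasing.
#' @param values Concentrations (nmol/L or MBq/L).  For censored points
#'   the value is the quantification limit.
#' @param below_limit Logical censoring flag per point.
#' @param analyte,session Labels carried along.
#' @return A `concentration_series`, a data frame with attributes.
#' @export
concentration_series <- function(times, values,
                                 below_limit = rep(FALSE, length(times)),
                                 analyte = "TF2", session = "S1") {
  if (length(times) != length(values) || length(times) != length(below_limit))
    stop("times, values and below_limit must have equal length")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(values[!below_limit] < 0))
    stop("uncensored values must be nonnegative")
  structure(data.frame(time_h = times, value = values,
                       censored = as.logical(below_limit)),
            analyte = analyte, session = session,
            class = c("concentration_series", "data.frame"))
}

## Eigenvalues (disposition rate constants) of the two-compartment
## system and the unit-bolus coefficients of the central compartment.
## lambda1 >= lambda2; c1 + c2 = 1.
macro_rates <- function(p) {
  s <- p$k_el + p$k_cp + p$k_pc
  disc <- s^2 - 4 * p$k_el * p$k_pc # = (k_el-k_pc)^2 + k_cp*(k_cp+2k_el+2k_pc) >= 0
  d <- sqrt(max(disc, 0))
  l1 <- (s + d) / 2
  l2 <- (s - d) / 2
  if (d < 1e-12 * max(s, 1e-300)) {
    # repeated root (only when k_cp = 0 and k_el = k_pc); nudge to keep
    # the biexponential form well conditioned
    l1 <- l1 * (1 + 1e-9)
    l2 <- l2 / (1 + 1e-9)
  }
  c1 <- (l1 - p$k_pc) / (l1 - l2)
  c2 <- (p$k_pc - l2) / (l1 - l2)
  list(l1 = l1, l2 = l2, c1 = c1, c2 = c2)
}

## (1 - exp(-l*t))/l with the l -> 0 limit t  (l scalar, t vector)
expi <- function(l, t) {
  if (l == 0) t else -expm1(-l * t) / l
}

## unit-rate infusion response factor for one exponential mode:
## integral_0^min(t,T) exp(-l (t - s)) ds
infusion_g <- function(l, t, Tdur) {
  tin <- pmin(t, Tdur)
  tout <- pmax(t - Tdur, 0)
  exp(-l * tout) * expi(l, tin)
}

## time integral of infusion_g from 0 to t (for cumulative elimination)
infusion_G <- function(l, t, Tdur) {
  tin <- pmin(t, Tdur)
  tout <- pmax(t - Tdur, 0)
  during <- if (l == 0) tin^2 / 2 else (tin - expi(l, tin)) / l
  after <- expi(l, Tdur) * expi(l, tout)
  during + after
}

## Amounts in central (A1), peripheral (A2) and cumulatively eliminated
## (E) under superposed zero-order infusions.  Returns a data frame.
compartment_amounts <- function(params, infusions, times) {
  if (inherits(infusions, "infusion_record")) infusions <- list(infusions)
  if (any(times < 0)) stop("times must be nonnegative")
  m <- macro_rates(params)
  a1 <- a2 <- el <- numeric(length(times))
  for (inf in infusions) {
    if (inf$dose == 0) next
    rate <- inf$dose / inf$duration
    tt <- pmax(times - inf$t_start, 0)
    g1 <- infusion_g(m$l1, tt, inf$duration)
    g2 <- infusion_g(m$l2, tt, inf$duration)
    a1 <- a1 + rate * (m$c1 * g1 + m$c2 * g2)
    a2 <- a2 + rate * params$k_cp / (m$l1 - m$l2) * (g2 - g1)
    el <- el + rate * params$k_el *
      (m$c1 * infusion_G(m$l1, tt, inf$duration) +
       m$c2 * infusion_G(m$l2, tt, inf$duration))
  }
  data.frame(time_h = times, central = a1, peripheral = a2, eliminated = el)
}

#' Predict central-compartment concentration under infusion input
#'
#' Analytic biexponential solution of the two-compartment model with
#' zero-order infusion input; multiple infusions are handled by linear
#' superposition (the model is linear).  The central volume is
#' `vol_per_m2 * bsa`.
#'
#' @param params A [two_compartment_params()].
#' @param bsa Body surface area (m2); must be positive.
#' @param infusions A single [infusion_record()] or a list of them.
#' @param times Times (h, nonnegative) at which to evaluate.
#' @return Numeric vector of concentrations (same unit as dose per L).
#' @examples
#' p <- two_compartment_params(0.034, 0.0075, 0.182, 1.86)
#' predict_concentration(p, bsa = 1.9, infusion_record(80), times = c(1, 24))
#' @export
predict_concentration <- function(params, bsa, infusions, times) {
  if (!inherits(params, "two_compartment_params"))
    stop("params must be a two_compartment_params object")
  if (is.na(params$vol_per_m2)) stop("params$vol_per_m2 is required")
  if (bsa <= 0) stop("bsa must be positive")
  if (any(times < 0)) stop("times must be nonnegative")
  vc <- params$vol_per_m2 * bsa
  compartment_amounts(params, infusions, times)$central / vc
}

#' Distribution (alpha) and terminal (beta) half-lives
#'
#' Half-lives of the fast and slow exponential phases, computed from the
#' disposition eigenvalues
#' \deqn{\lambda_{\alpha,\beta} = \frac{(k_{el}+k_{cp}+k_{pc}) \pm
#'   \sqrt{(k_{el}+k_{cp}+k_{pc})^2 - 4 k_{el} k_{pc}}}{2}.}
#' In the degenerate one-compartment limit (`k_cp = k_pc = 0`) both
#' phases collapse to the elimination half-life.  When the slow
#' eigenvalue is zero with nonzero amplitude (e.g. `k_el = 0`) the
#' terminal phase is undefined and an error is signalled.
#'
#' @param params A [two_compartment_params()].
#' @return Named numeric vector `c(alpha = ..., beta = ...)` in hours,
#'   with `alpha <= beta`.
#' @examples
#' halflives(two_compartment_params(0.034, 0.0075, 0.182))
#' @export
halflives <- function(params) {
  if (!inherits(params, "two_compartment_params"))
    stop("params must be a two_compartment_params object")
  if (params$k_cp == 0 && params$k_pc == 0) {
    if (params$k_el <= 0) stop("terminal phase undefined: all rates zero")
    hl <- log(2) / params$k_el
    return(c(alpha = hl, beta = hl))
  }
  m <- macro_rates(params)
  if (m$l2 <= 0)
    stop("terminal phase undefined: slow eigenvalue is zero ",
         "(k_el or k_pc is zero)")
  c(alpha = log(2) / m$l1, beta = log(2) / m$l2)
}

#' Total serum clearance
#'
#' Clearance is the product of the central volume and the elimination
#' rate, `Vc * k_el`, with `Vc = vol_per_m2 * bsa`.
#'
#' @inheritParams predict_concentration
#' @return Clearance in L/h.
#' @examples
#' clearance(two_compartment_params(0.033, 0.0062, 0.194, 2.00), bsa = 2.005)
#' @export
clearance <- function(params, bsa) {
  if (bsa <= 0) stop("bsa must be positive")
  if (is.na(params$vol_per_m2)) stop("params$vol_per_m2 is required")
  params$vol_per_m2 * bsa * params$k_el
}
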