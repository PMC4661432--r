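#' Whole-body kinetic parameters
#'
#' The whole-body activity is modelled as the sum of a central and a
#' distribution compartment; elimination from the central compartment
#' depends on the hapten/antibody molar ratio through a power law,
#' `k_el = A_wb * MR^B_wb`.
#'
#' @param k_pc,k_cp Exchange rates (1/h), peripheral->central and
#'   central->peripheral.
#' @param A_wb Power-law coefficient (1/h); positive.
#' @param B_wb Power-law exponent (dimensionless).
#' @return A `wholebody_params` object.
#' @examples
#' wholebody_params(k_pc = 0.0096, k_cp = 0.0163, A_wb = 0.105, B_wb = 0.14)
#' @export
wholebody_params <- function(k_pc, k_cp, A_wb, B_wb) {
  if (k_pc < 0 || k_cp < 0) stop("rates must be nonnegative")
  if (A_wb <= 0) stop("A_wb must be positive")
  structure(list(k_pc = k_pc, k_cp = k_cp, A_wb = A_wb, B_wb = B_wb),
            class = "wholebody_params")
}

## resolve the MR-dependent elimination rate into plain two-compartment
## parameters
wb_resolve <- function(params, mr) {
  if (mr <= 0) stop("mr must be positive")
  two_compartment_params(params$k_pc, params$k_cp,
                         clearance_power_law(params$A_wb, params$B_wb, mr))
}

#' Predict whole-body activity
#'
#' Decay-corrected whole-body activity under a zero-order infusion:
#' the sum of the amounts in the central and distribution compartments,
#' with elimination rate `A_wb * mr^B_wb` from the central compartment.
#'
#' @param params A [wholebody_params()].
#' @param mr Molar ratio at hapten injection (positive).
#' @param infusions An [infusion_record()] (activity dose, MBq) or list.
#' @param times Times (h) relative to the hapten infusion start.
#' @return Whole-body activity (MBq) at `times`.
#' @export
predict_wholebody <- function(params, mr, infusions, times) {
  p <- wb_resolve(params, mr)
  am <- compartment_amounts(p, infusions, times)
  am$central + am$peripheral
}

#' Organ uptake parameters
#'
#' Minimal linear organ model: a fraction of the central-compartment
#' activity in fast equilibrium with the tissue, plus a tissue-specific
#' distribution compartment filled at rate `k_on` from the central
#' amount and emptied at rate `k_off`.
#'
#' @param k_on Uptake rate into the tissue compartment (1/h).
#' @param k_off Release rate (1/h).
#' @param fraction Apparent fractional volume of central activity
#'   attributed to the tissue (L/kg).
#' @param tissue_mass Tissue mass (kg).
#' @return A `tissue_params` object.
#' @export
tissue_params <- function(k_on, k_off, fraction, tissue_mass = 1) {
  if (any(c(k_on, k_off, fraction, tissue_mass) < 0))
    stop("tissue parameters must be nonnegative")
  structure(list(k_on = k_on, k_off = k_off, fraction = fraction,
                 tissue_mass = tissue_mass),
            class = "tissue_params")
}

## Piecewise-exponential representation of the central amount under
## superposed infusions.  Each piece is a list(start, end, terms) with
## terms data.frame(coef, rate, ref): value = sum coef*exp(-rate*(t-ref)).
central_pieces <- function(params, infusions) {
  if (inherits(infusions, "infusion_record")) infusions <- list(infusions)
  m <- macro_rates(params)
  if (m$l2 <= 0)
    stop("central input requires a strictly positive elimination rate")
  starts <- vapply(infusions, function(i) i$t_start, 0)
  ends <- starts + vapply(infusions, function(i) i$duration, 0)
  brk <- sort(unique(c(0, starts, ends)))
  pieces <- vector("list", length(brk))
  for (j in seq_along(brk)) {
    a <- brk[j]
    b <- if (j < length(brk)) brk[j + 1] else Inf
    terms <- data.frame(coef = numeric(0), rate = numeric(0),
                        ref = numeric(0))
    for (i in seq_along(infusions)) {
      inf <- infusions[[i]]
      if (inf$dose == 0) next
      R <- inf$dose / inf$duration
      if (a >= ends[i]) {
        k1 <- R * m$c1 * expi(m$l1, inf$duration)
        k2 <- R * m$c2 * expi(m$l2, inf$duration)
        terms <- rbind(terms, data.frame(
          coef = c(k1, k2), rate = c(m$l1, m$l2), ref = ends[i]))
      } else if (a >= starts[i]) {
        terms <- rbind(terms, data.frame(
          coef = c(R * (m$c1 / m$l1 + m$c2 / m$l2),
                   -R * m$c1 / m$l1, -R * m$c2 / m$l2),
          rate = c(0, m$l1, m$l2),
          ref = c(starts[i], starts[i], starts[i])))
      }
    }
    pieces[[j]] <- list(start = a, end = b, terms = terms)
  }
  pieces
}

## (exp(-l*dt) - exp(-k*dt)) / (k - l), stable at k ~ l
conv_phi <- function(l, k, dt) {
  if (abs(k - l) < 1e-10 * max(abs(k), abs(l), 1)) {
    dt * exp(-k * dt)
  } else {
    (exp(-l * dt) - exp(-k * dt)) / (k - l)
  }
}

## distribution-compartment amount D(t): dD/dt = k_on*A_c(t) - k_off*D
tissue_store <- function(pieces, k_on, k_off, times) {
  ord <- order(times)
  ts <- times[ord]
  out <- numeric(length(ts))
  D <- 0
  idx <- 1
  for (pc in pieces) {
    advance <- function(d_at_a, dt) {
      v <- d_at_a * exp(-k_off * dt)
      if (nrow(pc$terms) > 0) {
        for (r in seq_len(nrow(pc$terms))) {
          b0 <- pc$terms$coef[r] *
            exp(-pc$terms$rate[r] * (pc$start - pc$terms$ref[r]))
          v <- v + k_on * b0 * conv_phi(pc$terms$rate[r], k_off, dt)
        }
      }
      v
    }
    while (idx <= length(ts) && ts[idx] < pc$end) {
      out[idx] <- advance(D, max(ts[idx] - pc$start, 0))
      idx <- idx + 1
    }
    if (is.finite(pc$end)) D <- advance(D, pc$end - pc$start)
    if (idx > length(ts)) break
  }
  out[ord] <- out
  out
}

#' Whole-body central input function
#'
#' Bundles resolved whole-body kinetics with the infusion history into
#' the input function driving organ models.
#'
#' @inheritParams predict_wholebody
#' @param vc Central volume (L) used to convert the central amount into
#'   a concentration for the fast-equilibrium fraction term.
#' @return A `wb_input` object.
#' @export
wholebody_input <- function(params, mr, infusions, vc) {
  if (vc <= 0) stop("vc must be positive")
  p <- wb_resolve(params, mr)
  if (inherits(infusions, "infusion_record")) infusions <- list(infusions)
  structure(list(params = p, infusions = infusions, vc = vc,
                 pieces = central_pieces(p, infusions)),
            class = "wb_input")
}

#' Predict organ activity
#'
#' Organ activity is the fast-equilibrium fraction of the central
#' activity plus a tissue distribution compartment:
#' \deqn{A_{organ}(t) = f \, m \, C_c(t) + D(t), \qquad
#'   D'(t) = k_{on} A_c(t) - k_{off} D(t), \quad D(0) = 0,}
#' where \eqn{A_c} is the central amount (MBq), \eqn{C_c = A_c / V_c}
#' its concentration, \eqn{f} the fraction (L/kg) and \eqn{m} the organ
#' mass (kg).  Both terms are evaluated in closed form (piecewise
#' exponential convolution).
#'
#' @param input A [wholebody_input()].
#' @param tissue A [tissue_params()].
#' @param times Times (h).
#' @return Organ activity (MBq) at `times`.
#' @export
predict_tissue <- function(input, tissue, times) {
  if (!inherits(input, "wb_input")) stop("input must be a wb_input")
  if (any(times < 0)) stop("times must be nonnegative")
  ac <- compartment_amounts(input$params, input$infusions, times)$central
  fast <- tissue$fraction * tissue$tissue_mass * ac / input$vc
  store <- if (tissue$k_on > 0)
    tissue_store(input$pieces, tissue$k_on, tissue$k_off, times)
  else numeric(length(times))
  fast + store
}

#' Fit organ uptake parameters
#'
#' Least-squares estimation of `k_on`, `k_off` and `fraction` from organ
#' time-activity curves, using the whole-body central compartment as the
#' input function.  Named organs are fitted with one shared parameter
#' set across all contributing curves (population fit); tumours are
#' fitted individually per curve, their kinetics being too variable to
#' pool.
#'
#' @param curves Data frame with columns `patient_id`, `session`,
#'   `organ`, `time_h`, `activity_MBq` (decay-corrected).
#' @param inputs Named list of [wholebody_input()] objects keyed by
#'   `"<patient_id>.<session>"`.
#' @param masses Organ masses: named numeric vector (per organ) or data
#'   frame with `patient_id`, `organ`, `mass_kg`.
#' @param tumor_label Organ label treated as tumour (individual fits);
#'   default `"tumor"`.
#' @param settings A [fit_settings()] (optimizer controls reused).
#' @return Data frame with one row per fitted unit: `organ`,
#'   `patient_id` (`NA` for population fits), `session`, `k_on`,
#'   `k_off`, `fraction`, `level`, `converged`.
#' @export
fit_tissue <- function(curves, inputs, masses, tumor_label = "tumor",
                       settings = fit_settings()) {
  need <- c("patient_id", "session", "organ", "time_h", "activity_MBq")
  miss <- setdiff(need, names(curves))
  if (length(miss) > 0)
    stop("curves is missing required column(s): ",
         paste(miss, collapse = ", "))
  lookup_mass <- function(pid, organ) {
    if (is.data.frame(masses)) {
      m <- masses$mass_kg[masses$patient_id == pid & masses$organ == organ]
      if (length(m) == 0) stop("no mass for patient ", pid, " organ ", organ)
      m[1]
    } else {
      if (!organ %in% names(masses)) stop("no mass for organ ", organ)
      unname(masses[organ])
    }
  }
  key <- function(pid, ses) paste(pid, ses, sep = ".")
  fit_curveset <- function(sub) {
    ids <- unique(sub[, c("patient_id", "session")])
    if (all(sub$activity_MBq == 0))
      return(list(par = c(0, 0, 0), converged = TRUE))
    ssq <- function(logpar) {
      th <- exp(logpar)
      tot <- 0
      for (r in seq_len(nrow(ids))) {
        k <- key(ids$patient_id[r], ids$session[r])
        inp <- inputs[[k]]
        if (is.null(inp)) stop("no wholebody input for ", k)
        cc <- sub[sub$patient_id == ids$patient_id[r] &
                  sub$session == ids$session[r], ]
        tp <- tissue_params(th[1], th[2], th[3],
                            lookup_mass(cc$patient_id[1], cc$organ[1]))
        pred <- predict_tissue(inp, tp, cc$time_h)
        w <- max(mean(cc$activity_MBq), 1e-12)
        tot <- tot + sum(((cc$activity_MBq - pred) / w)^2)
      }
      if (!is.finite(tot)) 1e10 else tot
    }
    best <- NULL
    set.seed(settings$seed)
    starts <- rbind(log(c(2e-3, 2e-2, 3e-2)),
                    matrix(log(c(2e-3, 2e-2, 3e-2)) +
                             rnorm(3 * (settings$n_restarts - 1), 0, 1),
                           ncol = 3, byrow = TRUE))
    for (k in seq_len(nrow(starts))) {
      f <- tryCatch(nlminb(starts[k, ], ssq,
                           control = list(iter.max = settings$maxit,
                                          rel.tol = settings$tol)),
                    error = function(e) NULL)
      if (!is.null(f) && (is.null(best) || f$objective < best$objective))
        best <- f
    }
    if (is.null(best)) return(list(par = rep(NA_real_, 3), converged = FALSE))
    list(par = exp(best$par), converged = best$convergence == 0)
  }
  out <- list()
  for (org in unique(curves$organ)) {
    sub <- curves[curves$organ == org, ]
    if (any(table(paste(sub$patient_id, sub$session)) < 3))
      stop("organ ", org, ": fewer than 3 time points in a curve")
    if (org == tumor_label) {
      ids <- unique(sub[, c("patient_id", "session")])
      for (r in seq_len(nrow(ids))) {
        cc <- sub[sub$patient_id == ids$patient_id[r] &
                  sub$session == ids$session[r], ]
        f <- fit_curveset(cc)
        out[[length(out) + 1]] <- data.frame(
          organ = org, patient_id = ids$patient_id[r],
          session = ids$session[r], k_on = f$par[1], k_off = f$par[2],
          fraction = f$par[3], level = "individual",
          converged = f$converged)
      }
    } else {
      f <- fit_curveset(sub)
      out[[length(out) + 1]] <- data.frame(
        organ = org, patient_id = NA_character_, session = NA_character_,
        k_on = f$par[1], k_off = f$par[2], fraction = f$par[3],
        level = "population", converged = f$converged)
    }
  }
  do.call(rbind, out)
}
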