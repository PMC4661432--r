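#' Molar ratio of injected hapten to circulating antibody
#'
#' The covariate driving hapten clearance in pretargeting: the ratio of
#' the number of moles of hapten injected to the number of moles of
#' bispecific antibody still in the circulation at the time of hapten
#' injection.  The circulating amount is the fitted antibody
#' concentration interpolated at the injection time multiplied by the
#' antibody central volume (`vol_per_m2 * bsa`).
#'
#' @param n_hapten Injected hapten amount (nmol).
#' @param tf2_params Fitted antibody [two_compartment_params()].
#' @param tf2_infusions The antibody infusion history
#'   ([infusion_record()] or list of them).
#' @param t_inj Hapten injection time (h, on the same clock as the
#'   antibody infusions; must be after the end of the antibody
#'   infusion).
#' @param bsa Body surface area (m2).
#' @return The dimensionless molar ratio (MR).
#' @examples
#' p <- two_compartment_params(0.034, 0.0075, 0.182, 1.86)
#' compute_mr(8, p, infusion_record(84), t_inj = 48, bsa = 1.9)
#' @export
compute_mr <- function(n_hapten, tf2_params, tf2_infusions, t_inj, bsa) {
  if (inherits(tf2_infusions, "infusion_record"))
    tf2_infusions <- list(tf2_infusions)
  ends <- vapply(tf2_infusions, function(i) i$t_start + i$duration, 0)
  if (any(t_inj < ends))
    stop("t_inj must be after the end of the antibody infusion")
  conc <- predict_concentration(tf2_params, bsa, tf2_infusions, t_inj)
  if (conc <= 0)
    stop("predicted antibody concentration at t_inj is not positive; ",
         "molar ratio undefined")
  vc <- tf2_params$vol_per_m2 * bsa
  n_hapten / (conc * vc)
}

#' Power-law clearance as a function of molar ratio
#'
#' Hapten clearance rises with the excess of hapten over circulating
#' antibody: `CL = A * MR^B`.  The elimination rate constant is obtained
#' as `CL / Vc`.
#'
#' @param A Coefficient (units of the response, e.g. L/h).
#' @param B Dimensionless exponent.
#' @param mr Molar ratio (positive).
#' @return `A * mr^B`, same units as `A`.
#' @examples
#' clearance_power_law(1.35, 0.169, 124.2) # ~3.05 L/h
#' @export
clearance_power_law <- function(A, B, mr) {
  if (A <= 0) stop("A must be positive")
  if (any(mr <= 0)) stop("mr must be positive")
  A * mr^B
}

#' Fit a power law by log-log ordinary least squares
#'
#' Fits `response = A * covariate^B` by unweighted OLS on the natural
#' logarithms; `A = exp(intercept)`, `B = slope`.  R-squared is reported
#' on the log scale, the scale of fitting.
#'
#' @param mr Covariate values (positive), typically molar ratios.
#' @param response Response values (positive), e.g. clearances (L/h) or
#'   elimination rates (1/h).
#' @return A `power_law_fit` list with `A`, `B`, `r_squared`, `n`.
#' @examples
#' tab <- pk_table_hapten()
#' fit_power_law(tab$mr, tab$clearance) # A ~ 1.33, B ~ 0.18, R2 ~ 0.66
#' @export
fit_power_law <- function(mr, response) {
  if (length(mr) != length(response))
    stop("mr and response must have equal length")
  if (length(mr) < 3) stop("at least 3 pairs are required")
  if (any(mr <= 0) || any(response <= 0))
    stop("all mr and response values must be positive")
  if (length(unique(mr)) < 2)
    stop("all covariate values identical: slope undefined")
  fit <- lm(log(response) ~ log(mr))
  structure(list(A = unname(exp(coef(fit)[1])),
                 B = unname(coef(fit)[2]),
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 n = length(mr)),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("Power law: response = %.4g * MR^%.4g  (R2 = %.3f, n = %d)\n",
              x$A, x$B, x$r_squared, x$n))
  invisible(x)
}

#' Serialize a power-law fit to JSON
#'
#' @param fit A `power_law_fit`.
#' @param analyte Label stored alongside the coefficients.
#' @param path Output file; if `NULL`, the JSON string is returned.
#' @return The path (invisibly) or the JSON string.
#' @export
write_power_law <- function(fit, analyte, path = NULL) {
  obj <- list(analyte = analyte, A = fit$A, B = fit$B,
              r_squared = fit$r_squared, n = fit$n)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}
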