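#' Dosing scheme presets
#'
#' The three dosing conditions of the optimisation trial: antibody and
#' hapten molar doses per body surface area, pretargeting delay, and
#' administered activities for the imaging (S1, In-111) and therapy
#' (S2, Lu-177) sessions.
#'
#' @param cohort `"I"`, `"II"` or `"III"`.
#' @return A `dosing_scheme` list with fields `cohort`,
#'   `s1_tf2_nmol_m2`, `s2_tf2_nmol_m2`, `s1_hapten_nmol_m2`,
#'   `s2_hapten_nmol_m2`, `delay_h`, `s1_activity_MBq`,
#'   `s2_activity_MBq_m2`.
#' @examples
#' dosing_scheme("I")
#' @export
dosing_scheme <- function(cohort = c("I", "II", "III")) {
  cohort <- match.arg(cohort)
  tab <- dosing_table()
  row <- tab[tab$cohort == cohort, ]
  structure(as.list(row), class = "dosing_scheme")
}

#' Population configuration of the virtual-cohort generator
#'
#' Defaults anchor the generator to the published population estimates:
#' antibody serum kinetics, hapten serum kinetics with molar-ratio
#' power-law clearance, whole-body kinetics, and per-organ uptake
#' parameters.  Between-patient variability is lognormal with the
#' log-scale SDs given here (approximately the observed CVs).
#'
#' @param bsa_mean,bsa_sd,bsa_range Truncated-normal BSA distribution
#'   (m2); defaults 1.9 +/- 0.2 bounded to 1.4-2.4, a plausible adult
#'   range consistent with the spread of central volumes.
#' @param tumor_mass_kg Default tumour mass.
#' @param tumor_cv Lognormal dispersion of tumour `k_on`/`k_off`
#'   (qualitative only: tumour kinetics are highly variable).
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(bsa_mean = 1.9, bsa_sd = 0.2,
                          bsa_range = c(1.4, 2.4),
                          tumor_mass_kg = 0.02, tumor_cv = 0.5) {
  tis <- tissue_table()
  organs <- tis$organ[tis$organ != "tumor"]
  tissues <- lapply(organs, function(o) {
    r <- tis[tis$organ == o, ]
    list(k_on = r$k_on, k_off = r$k_off, fraction = r$fraction)
  })
  names(tissues) <- organs
  structure(list(
    bsa_mean = bsa_mean, bsa_sd = bsa_sd, bsa_range = bsa_range,
    tf2 = list(mean = c(k_pc = 0.034, k_cp = 0.0075, k_el = 0.182,
                        vol_per_m2 = 1.86),
               omega = c(k_pc = 0.055, k_cp = 0.145, k_el = 0.09,
                         vol_per_m2 = 0.077)),
    hapten = list(mean = c(k_pc = 0.027, k_cp = 0.019, vol_per_m2 = 6.38),
                  omega = c(k_pc = 0.045, k_cp = 0.14, vol_per_m2 = 0.041),
                  A = 1.42, B = 0.182, omega_cl = 0.10),
    wb = list(mean = c(k_pc = 0.0096, k_cp = 0.0163, A_wb = 0.105,
                       B_wb = 0.14),
              omega = c(k_pc = 0.058, k_cp = 0.139, A_wb = 0.15,
                        B_wb = 0)),
    tissues = tissues,
    tissue_omega = 0.10,
    tumor = list(k_on = 2e-3, k_off = 1.5e-2,
                 fraction = tis$fraction[tis$organ == "tumor"],
                 cv = tumor_cv, mass_kg = tumor_mass_kg),
    organ_mass_ref = c(lung = 1.0, liver = 1.8, kidneys = 0.31,
                       spleen = 0.18, heart = 0.33, aorta = 0.10),
    organ_mass_cv = 0.10),
    class = "cohort_config")
}

## lognormal draw with arithmetic mean mu and CV ~ omega
rln <- function(n, mu, omega) {
  if (all(omega == 0)) return(rep(mu, length.out = n))
  rlnorm(n, meanlog = log(mu) - omega^2 / 2, sdlog = omega)
}

#' Draw one virtual patient
#'
#' Samples body surface area from a truncated normal and individual
#' kinetic parameters from lognormal distributions centred (in
#' arithmetic mean) on the configured population values.  Deterministic
#' given the seed.
#'
#' @param seed Integer seed.
#' @param cohort Dosing cohort label (`"I"`, `"II"`, `"III"`).
#' @param config A [cohort_config()].
#' @return A `virtual_patient` list: `id`, `bsa`, `cohort`, true
#'   parameter sets `tf2`, `hapten`, `wb`, `tissues`, `tumor`,
#'   `organ_masses`, and the `seed`.
#' @export
sample_patient <- function(seed, cohort = "I", config = cohort_config()) {
  if (!inherits(config, "cohort_config")) stop("invalid config")
  set.seed(as.integer(seed))
  repeat {
    bsa <- rnorm(1, config$bsa_mean, config$bsa_sd)
    if (bsa >= config$bsa_range[1] && bsa <= config$bsa_range[2]) break
  }
  tf2 <- mapply(function(m, o) rln(1, m, o),
                config$tf2$mean, config$tf2$omega)
  hap <- mapply(function(m, o) rln(1, m, o),
                config$hapten$mean, config$hapten$omega)
  cl_mult <- rln(1, 1, config$hapten$omega_cl)
  wb <- mapply(function(m, o) rln(1, m, o),
               config$wb$mean, config$wb$omega)
  tissues <- lapply(config$tissues, function(tp)
    list(k_on = rln(1, tp$k_on, config$tissue_omega),
         k_off = rln(1, tp$k_off, config$tissue_omega),
         fraction = rln(1, tp$fraction, config$tissue_omega)))
  tumor <- list(k_on = rln(1, config$tumor$k_on, config$tumor$cv),
                k_off = rln(1, config$tumor$k_off, config$tumor$cv),
                fraction = rln(1, config$tumor$fraction,
                               config$tissue_omega),
                mass_kg = config$tumor$mass_kg)
  masses <- mapply(function(m) rln(1, m, config$organ_mass_cv),
                   config$organ_mass_ref)
  structure(list(
    id = sprintf("VP%03d", as.integer(seed) %% 1000L),
    bsa = bsa, cohort = cohort,
    tf2 = two_compartment_params(unname(tf2["k_pc"]), unname(tf2["k_cp"]),
                                 unname(tf2["k_el"]),
                                 unname(tf2["vol_per_m2"])),
    hapten = list(k_pc = unname(hap["k_pc"]), k_cp = unname(hap["k_cp"]),
                  vol_per_m2 = unname(hap["vol_per_m2"]),
                  A = config$hapten$A, B = config$hapten$B,
                  cl_mult = cl_mult),
    wb = wholebody_params(unname(wb["k_pc"]), unname(wb["k_cp"]),
                          unname(wb["A_wb"]), unname(wb["B_wb"])),
    tissues = tissues, tumor = tumor,
    organ_masses = masses, seed = as.integer(seed)),
    class = "virtual_patient")
}

#' Noise and schedule configuration for trial simulation
#'
#' @param serum_cv Multiplicative lognormal CV of serum samples.
#' @param imaging_cv Multiplicative lognormal CV of image-derived
#'   activities.
#' @param loq_tf2,loq_hapten Quantification limits (nmol/L, MBq/L);
#'   simulated values below the limit are reported at the limit with
#'   the censoring flag set.
#' @param serum_times Sampling schedule (h after infusion start).  The
#'   default realises the protocol schedule: 5 min before the end of a
#'   30-min infusion, 5 min / 1 h / 2-4 h (taken as 3 h) after the end,
#'   24 h, then four times over 7 days.
#' @param imaging_times Imaging schedule (h after hapten injection),
#'   3-5 points between 1 h and 7 days.
#' @return A `noise_config` list.
#' @export
noise_config <- function(serum_cv = 0.10, imaging_cv = 0.15,
                         loq_tf2 = 0.05, loq_hapten = 0.05,
                         serum_times = c(0.42, 0.58, 1.5, 3.5, 24, 48,
                                         96, 120, 168),
                         imaging_times = c(1, 24, 48, 96, 168)) {
  stopifnot(serum_cv >= 0, imaging_cv >= 0)
  structure(list(serum_cv = serum_cv, imaging_cv = imaging_cv,
                 loq_tf2 = loq_tf2, loq_hapten = loq_hapten,
                 serum_times = serum_times, imaging_times = imaging_times),
            class = "noise_config")
}

mult_noise <- function(x, cv) {
  if (cv == 0) return(x)
  x * rlnorm(length(x), -cv^2 / 2, cv)
}

censor_series <- function(times, values, loq, analyte, session) {
  cen <- values < loq
  values[cen] <- loq
  concentration_series(times, values, cen, analyte = analyte,
                       session = session)
}

#' Simulate a full pretargeting trial dataset for one patient
#'
#' Generates, for both the imaging (S1) and therapy (S2) sessions:
#' the antibody serum series, the hapten serum activity series, the
#' whole-body curve, and the organ and tumour time-activity curves.
#' Hapten elimination is derived from the patient's true molar ratio
#' through the power law, so the coupling between antibody dose, delay
#' and hapten kinetics is built in.  All randomness is controlled by
#' `seed`.
#'
#' @param patient A [sample_patient()] result.
#' @param scheme A [dosing_scheme()]; defaults to the patient's cohort.
#' @param noise A [noise_config()].
#' @param seed Integer seed for measurement noise.
#' @return A `trial_data` list with `patient`, `scheme`, per-session
#'   elements (`tf2`, `hapten` concentration series; `wb` and `organs`
#'   data frames; `mr`, doses), and `truth` (the generating parameters
#'   and molar ratios).
#' @export
simulate_trial <- function(patient, scheme = dosing_scheme(patient$cohort),
                           noise = noise_config(), seed = 1L) {
  stopifnot(inherits(patient, "virtual_patient"),
            inherits(scheme, "dosing_scheme"))
  set.seed(as.integer(seed))
  bsa <- patient$bsa
  vc_tf2 <- patient$tf2$vol_per_m2 * bsa
  vc_hap <- patient$hapten$vol_per_m2 * bsa
  sessions <- list()
  truth_mr <- c()
  for (ses in c("S1", "S2")) {
    tf2_dose <- (if (ses == "S1") scheme$s1_tf2_nmol_m2
                 else scheme$s2_tf2_nmol_m2) * bsa
    hap_nmol <- (if (ses == "S1") scheme$s1_hapten_nmol_m2
                 else scheme$s2_hapten_nmol_m2) * bsa
    activity <- if (ses == "S1") scheme$s1_activity_MBq
                else scheme$s2_activity_MBq_m2 * bsa
    isotope <- if (ses == "S1") "In111" else "Lu177"
    tf2_inf <- infusion_record(tf2_dose, 0, 0.5, ses, "TF2")
    ## antibody serum series
    c_tf2 <- predict_concentration(patient$tf2, bsa, tf2_inf,
                                   noise$serum_times)
    tf2_series <- censor_series(noise$serum_times,
                                mult_noise(c_tf2, noise$serum_cv),
                                noise$loq_tf2, "TF2", ses)
    ## molar ratio at the (noise-free) truth level
    mr <- compute_mr(hap_nmol, patient$tf2, tf2_inf, scheme$delay_h, bsa)
    truth_mr[ses] <- mr
    ## hapten serum kinetics: clearance from the power law
    cl <- clearance_power_law(patient$hapten$A, patient$hapten$B, mr) *
      patient$hapten$cl_mult
    hap_params <- two_compartment_params(patient$hapten$k_pc,
                                         patient$hapten$k_cp,
                                         cl / vc_hap,
                                         patient$hapten$vol_per_m2)
    hap_inf <- infusion_record(activity, 0, 0.5, ses,
                               paste0("IMP288-", isotope))
    c_hap <- predict_concentration(hap_params, bsa, hap_inf,
                                   noise$serum_times)
    hap_series <- censor_series(noise$serum_times,
                                mult_noise(c_hap, noise$serum_cv),
                                noise$loq_hapten,
                                paste0("IMP288-", isotope), ses)
    ## whole-body and organ curves
    wb_act <- predict_wholebody(patient$wb, mr, hap_inf,
                                noise$imaging_times)
    wb <- data.frame(time_h = noise$imaging_times,
                     activity_MBq = mult_noise(wb_act, noise$imaging_cv),
                     isotope = isotope)
    inp <- wholebody_input(patient$wb, mr, hap_inf, vc_hap)
    organ_rows <- list()
    for (org in names(patient$tissues)) {
      tp0 <- patient$tissues[[org]]
      tp <- tissue_params(tp0$k_on, tp0$k_off, tp0$fraction,
                          patient$organ_masses[org])
      act <- predict_tissue(inp, tp, noise$imaging_times)
      organ_rows[[org]] <- data.frame(
        patient_id = patient$id, session = ses, organ = org,
        time_h = noise$imaging_times,
        activity_MBq = mult_noise(act, noise$imaging_cv),
        isotope = isotope)
    }
    tu <- patient$tumor
    act <- predict_tissue(inp, tissue_params(tu$k_on, tu$k_off,
                                             tu$fraction, tu$mass_kg),
                          noise$imaging_times)
    organ_rows[["tumor"]] <- data.frame(
      patient_id = patient$id, session = ses, organ = "tumor",
      time_h = noise$imaging_times,
      activity_MBq = mult_noise(act, noise$imaging_cv),
      isotope = isotope)
    sessions[[ses]] <- list(
      tf2 = tf2_series, hapten = hap_series, wb = wb,
      organs = do.call(rbind, c(organ_rows, make.row.names = FALSE)),
      mr = mr, tf2_infusion = tf2_inf, hapten_infusion = hap_inf,
      administered_MBq = activity, isotope = isotope,
      hapten_params = hap_params)
  }
  structure(list(patient = patient, scheme = scheme, noise = noise,
                 seed = as.integer(seed), S1 = sessions$S1,
                 S2 = sessions$S2,
                 truth = list(mr = truth_mr,
                              vc_tf2 = vc_tf2, vc_hapten = vc_hap)),
            class = "trial_data")
}
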