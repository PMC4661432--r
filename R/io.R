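extdata <- function(file) {
  path <- system.file("extdata", file, package = "prait")
  if (path == "") stop("bundled fixture not found: ", file)
  path
}

#' Published parameter tables
#'
#' Loaders for the transcribed parameter tables of the optimisation
#' trial.  Printed tables label the exchange rates generically
#' (`k_2,1`, `k_1,2`); the loaders resolve them into the package's
#' directional names using the mapping that reproduces the printed
#' half-lives, and record which mapping was applied in the `"mapping"`
#' attribute:
#' * serum tables (antibody, hapten): printed `k_2,1` is
#'   peripheral->central (`k_pc`), `k_1,2` is central->peripheral
#'   (`k_cp`);
#' * whole-body table: the opposite (`k_2,1` -> `k_cp`,
#'   `k_1,2` -> `k_pc`).
#'
#' `pk_table_tf2()` returns the eight individual antibody records
#' (rates in 1/h, volumes in L/m2 and L, clearance in L/h).
#' `pk_table_hapten()` returns the sixteen patient-isotope hapten serum
#' records including the molar ratio and power-law coefficients.
#' `pk_table_wholebody()` returns the sixteen whole-body records.
#' `tissue_table()` returns the per-organ uptake parameters (1/h,
#' L/kg).  `dosing_table()` returns the three cohort dosing presets.
#'
#' @return A data frame; see Details.
#' @examples
#' head(pk_table_tf2())
#' @export
pk_table_tf2 <- function() {
  tab <- read.csv(extdata("table_tf2_serum.csv"))
  out <- data.frame(patient = tab$patient,
                    k_pc = tab$k21, k_cp = tab$k12, k_el = tab$kel,
                    vol_per_m2 = tab$vol_per_m2, vc = tab$vc,
                    clearance = tab$clearance)
  attr(out, "mapping") <- "k21 -> k_pc (peripheral to central)"
  out
}

#' @rdname pk_table_tf2
#' @export
pk_table_hapten <- function() {
  tab <- read.csv(extdata("table_hapten_serum.csv"))
  out <- data.frame(patient = tab$patient, isotope = tab$isotope,
                    k_pc = tab$k21, k_cp = tab$k12,
                    A = tab$A, B = tab$B, mr = tab$mr, k_el = tab$kel,
                    vol_per_m2 = tab$vol_per_m2, vc = tab$vc,
                    clearance = tab$clearance)
  attr(out, "mapping") <- "k21 -> k_pc (peripheral to central)"
  out
}

#' @rdname pk_table_tf2
#' @export
pk_table_wholebody <- function() {
  tab <- read.csv(extdata("table_wholebody.csv"))
  out <- data.frame(patient = tab$patient, isotope = tab$isotope,
                    k_pc = tab$k12, k_cp = tab$k21,
                    A_wb = tab$A, B_wb = tab$B, mr = tab$mr,
                    k_el = tab$kel)
  attr(out, "mapping") <- "k21 -> k_cp (central to peripheral)"
  out
}

#' @rdname pk_table_tf2
#' @export
tissue_table <- function() {
  read.csv(extdata("table_tissue.csv"))
}

#' @rdname pk_table_tf2
#' @export
dosing_table <- function() {
  read.csv(extdata("table_dosing.csv"))
}

#' Bundled S-factor table
#'
#' A small adult S-factor table (mGy per MBq h, at the reference organ
#' masses in the `ref_mass_kg` column) for the organs reported in the
#' dose figures.  The table is synthetic: self-dose terms are derived
#' from the mean electron and photon energy per decay of each isotope
#' with nominal absorbed fractions, and photon cross-organ terms use
#' nominal geometry factors.  It is a placeholder intended to be
#' replaced by a production MIRD/OLINDA table via
#' [read_sfactor_table()]; the pipeline only requires the CSV schema
#' `source`, `target`, `S_mGy_per_MBq_h`, `ref_mass_kg`.
#'
#' @param isotope `"Lu177"` or `"In111"`.
#' @return Data frame with columns `source`, `target`,
#'   `S_mGy_per_MBq_h`, `ref_mass_kg`.
#' @export
sfactor_table <- function(isotope = c("Lu177", "In111")) {
  isotope <- match.arg(isotope)
  tab <- read.csv(extdata("sfactors_synthetic.csv"))
  tab <- tab[tab$isotope == isotope,
             c("source", "target", "S_mGy_per_MBq_h", "ref_mass_kg")]
  rownames(tab) <- NULL
  tab
}

#' Read an S-factor table from CSV
#'
#' @param path CSV with columns `source`, `target`, `S_mGy_per_MBq_h`,
#'   `ref_mass_kg`.
#' @return Validated data frame.
#' @export
read_sfactor_table <- function(path) {
  tab <- read.csv(path)
  need <- c("source", "target", "S_mGy_per_MBq_h", "ref_mass_kg")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0)
    stop("S-factor table is missing required column(s): ",
         paste(miss, collapse = ", "))
  for (org in unique(c(tab$source, tab$target)))
    if (!any(tab$source == org & tab$target == org))
      stop("missing self-dose entry for organ ", org)
  tab
}

series_cols <- c("patient_id", "session", "analyte", "time_h", "value",
                 "unit", "censored")

#' Read and write concentration series CSV
#'
#' The on-disk schema is one row per sample with columns `patient_id`,
#' `session`, `analyte`, `time_h`, `value`, `unit`, `censored` (0/1).
#'
#' @param path CSV path.
#' @return `read_series_csv()`: a data frame in the schema above.
#'   Use [series_from_frame()] to extract one
#'   [concentration_series()].
#' @export
read_series_csv <- function(path) {
  tab <- read.csv(path)
  miss <- setdiff(series_cols, names(tab))
  if (length(miss) > 0)
    stop("series CSV is missing required column(s): ",
         paste(miss, collapse = ", "))
  tab
}

#' @rdname read_series_csv
#' @param series A [concentration_series()] or list of them.
#' @param patient_id Patient label written to the file.
#' @param unit Unit string (`"nmol/L"` or `"MBq/L"`).
#' @export
write_series_csv <- function(series, path, patient_id, unit = "nmol/L") {
  if (inherits(series, "concentration_series")) series <- list(series)
  rows <- lapply(series, function(s)
    data.frame(patient_id = patient_id,
               session = attr(s, "session"),
               analyte = attr(s, "analyte"),
               time_h = s$time_h, value = s$value, unit = unit,
               censored = as.integer(s$censored)))
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_series_csv
#' @param frame A data frame from `read_series_csv()`.
#' @param session,analyte Selectors identifying one series.
#' @export
series_from_frame <- function(frame, patient_id, session, analyte) {
  sub <- frame[frame$patient_id == patient_id &
               frame$session == session & frame$analyte == analyte, ]
  if (nrow(sub) == 0) stop("no rows match the requested series")
  concentration_series(sub$time_h, sub$value, sub$censored == 1,
                       analyte = analyte, session = session)
}

#' Read and write organ time-activity CSV
#'
#' Schema: `patient_id`, `session`, `organ`, `time_h`, `activity_MBq`,
#' `isotope`.
#'
#' @param path CSV path.
#' @return A validated data frame.
#' @export
read_organ_csv <- function(path) {
  tab <- read.csv(path)
  need <- c("patient_id", "session", "organ", "time_h", "activity_MBq",
            "isotope")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0)
    stop("organ CSV is missing required column(s): ",
         paste(miss, collapse = ", "))
  tab
}

#' @rdname read_organ_csv
#' @param curves Data frame in the organ schema.
#' @export
write_organ_csv <- function(curves, path) {
  write.csv(curves, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a population estimate in table layout
#'
#' CSV mirroring the published table layout: a population block
#' (typical value per parameter), the individual block, and
#' mean/SD/CV% rows computed from the individual estimates.
#'
#' @param pop A `population_estimate` from [fit_population()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_population_csv <- function(pop, path) {
  ind <- pop$individual
  num <- names(ind)[vapply(ind, is.numeric, TRUE)]
  sm <- pop$summary
  pick <- function(v) vapply(num, function(p)
    if (p %in% names(v)) unname(v[p]) else NA_real_, 0)
  block <- rbind(
    data.frame(row = "Population", rbind(pick(pop$population_mean))),
    data.frame(row = ind$id, as.matrix(ind[, num, drop = FALSE])),
    data.frame(row = "Mean", rbind(pick(setNames(sm$mean, sm$parameter)))),
    data.frame(row = "SD", rbind(pick(setNames(sm$sd, sm$parameter)))),
    data.frame(row = "CV%", rbind(pick(setNames(sm$cv_percent,
                                                sm$parameter)))))
  names(block) <- c("row", num)
  write.csv(block, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a run configuration (JSON or YAML)
#'
#' A run configuration names inputs, scheme, fit settings, isotope
#' constants, S-factor table path, seed and output directory.  The
#' `seed` field is mandatory: every stochastic stage is seeded.
#'
#' @param path `.json` (always supported) or `.yaml`/`.yml` (requires
#'   the yaml package).
#' @return Named list.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the yaml package")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (is.null(cfg$seed)) stop("run config must set a seed")
  cfg
}
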