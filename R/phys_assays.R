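# ---------------------------------------------------------------------------
# Physiological assay computations: flow-cytometry C-values, net CO2
# assimilation, and titratable acidity from two-wavelength titration
# curves read against a pH indicator calibration.
# ---------------------------------------------------------------------------

#' Flow-cytometry 1C value
#'
#' `1C_object = (FI_object / FI_standard) * 1C_standard`, the ratio of
#' G0/1 peak mean fluorescence intensities scaled by the internal
#' standard's genome size (e.g. Pisum sativum, 4.42 pg/1C).
#'
#' @param fi_object,fi_standard Peak mean fluorescence intensities
#'   (arbitrary units, > 0).
#' @param c_standard Standard 1C value in pg.
#' @return 1C value of the object in pg.
#' @export
c_value <- function(fi_object, fi_standard, c_standard) {
  if (any(fi_object <= 0) || any(fi_standard <= 0)) {
    stop("fluorescence intensities must be positive")
  }
  (fi_object / fi_standard) * c_standard
}

#' Net CO2 assimilation rate
#'
#' `net = assimilation - respiration` (umol CO2 m^-2 s^-1).
#'
#' @param assimilation,respiration Numeric vectors.
#' @return Net assimilation.
#' @export
net_assimilation <- function(assimilation, respiration) {
  assimilation - respiration
}

#' Smooth gas-exchange records
#'
#' Post-processing of IRGA logs: negative stomatal conductance values are
#' corrected to zero, then records are averaged over consecutive
#' non-overlapping windows of `k` measurements (5-minute logging averaged
#' in fives gives one point per ~20 minutes).
#'
#' @param records `data.frame` with `net_assimilation` and `conductance`
#'   columns (and optionally `time`).
#' @param k Window size (default 5).
#' @return `data.frame` of window means.
#' @export
smooth_gas_exchange <- function(records, k = 5L) {
  records$conductance <- pmax(0, records$conductance)
  grp <- (seq_len(nrow(records)) - 1L) %/% k
  out <- aggregate(records[, setdiff(names(records), "group"),
                           drop = FALSE],
                   by = list(window = grp), FUN = mean)
  out$window <- out$window + 1L
  out
}

#' Titratable acidity from a two-wavelength titration curve
#'
#' Each titration step's A615/A445 ratio is converted to pH by monotone
#' interpolation of the buffer-standard calibration; the NaOH volume
#' `V*` reaching pH 7.0 is found by linear interpolation between the
#' bracketing steps; the acidity is scaled from the titrated aliquot to
#' the full extract per gram fresh weight:
#' `TA = V*(L) * M(mol/L) / aliquot_volume * extract_volume / tissue_mass`
#' reported in umol H+ per g fresh weight.
#'
#' @param steps `data.frame` with `volume_ul` (cumulative NaOH, strictly
#'   increasing), `a445`, `a615`.
#' @param calibration `data.frame` with `ph` and `ratio` (A615/A445) of
#'   the buffer standards; must span pH 7.0.
#' @param tissue_mass_g Fresh weight extracted (g).
#' @param extract_volume_ul Extraction volume (uL).
#' @param aliquot_volume_ul Titrated aliquot (uL).
#' @param naoh_molarity NaOH concentration (mol/L).
#' @param interpolation `"monotone"` (Hyman-filtered spline) or
#'   `"linear"` calibration interpolation.
#' @return List: `ta_umol_per_gfw`, `v_star_ul`, `ph_trace`.
#' @export
titratable_acidity <- function(steps, calibration,
                               tissue_mass_g, extract_volume_ul,
                               aliquot_volume_ul, naoh_molarity,
                               interpolation = c("monotone", "linear")) {
  interpolation <- match.arg(interpolation)
  if (max(calibration$ph) < 7 || min(calibration$ph) > 7) {
    stop("calibration must span pH 7.0")
  }
  if (any(diff(steps$volume_ul) <= 0)) {
    stop("cumulative NaOH volumes must be strictly increasing")
  }
  cal <- calibration[order(calibration$ratio), ]
  ratio <- steps$a615 / steps$a445
  ratio_cl <- pmin(max(cal$ratio), pmax(min(cal$ratio), ratio))
  ph <- if (interpolation == "monotone") {
    stats::splinefun(cal$ratio, cal$ph, method = "hyman")(ratio_cl)
  } else {
    stats::approx(cal$ratio, cal$ph, xout = ratio_cl)$y
  }
  if (any(diff(ph) < -1e-9)) {
    warning("non-monotone pH trace; applying isotonic correction")
    ph <- stats::isoreg(seq_along(ph), ph)$yf
  }
  if (max(ph) < 7) {
    stop("insufficient titration: curve never reaches pH 7.0")
  }
  if (ph[1] >= 7) {
    v_star <- 0
  } else {
    i <- which(ph >= 7)[1]
    v0 <- steps$volume_ul[i - 1L]; v1 <- steps$volume_ul[i]
    p0 <- ph[i - 1L]; p1 <- ph[i]
    v_star <- v0 + (7 - p0) / (p1 - p0) * (v1 - v0)
  }
  ta <- (v_star * 1e-6) * naoh_molarity / aliquot_volume_ul *
    extract_volume_ul / tissue_mass_g * 1e6
  list(ta_umol_per_gfw = ta, v_star_ul = v_star,
       ph_trace = data.frame(volume_ul = steps$volume_ul, ratio = ratio,
                             ph = ph))
}

#' Forward-simulate a titration curve
#'
#' Generates the observable two-wavelength titration data for an extract
#' of known titratable H+ content (defined, as in the assay itself, as
#' the NaOH equivalents needed to bring the aliquot to pH 7.0). The
#' aliquot is modelled as a mixture of weak acids (a malate-like buffer
#' spread over several pKa values, scaled so that exactly `h_umol`
#' equivalents in the full extract titrate to pH 7.0); the indicator
#' ratio follows a logistic response around the indicator pKa
#' (bromothymol blue ~7.1); both absorbance channels carry a common
#' arbitrary scale factor per step (only the ratio is informative).
#' Used as the independent generator in acidity-recovery checks.
#'
#' @param h_umol Titratable H+ (to pH 7.0) in the full extract, umol.
#' @param tissue_mass_g,extract_volume_ul,aliquot_volume_ul,naoh_molarity
#'   As in [titratable_acidity()].
#' @param pkas,weights Weak-acid mixture of the extract buffer.
#' @param step_ul Titration step (1 uL per the assay protocol).
#' @param indicator_pka,ratio_range Indicator response parameters.
#' @return List with `steps`, `calibration`, the true `v_star_ul` (NaOH
#'   uL to pH 7.0) and the equivalence volume `v_eq_ul`.
#' @export
simulate_titration_curve <- function(h_umol, tissue_mass_g = 0.045,
                                     extract_volume_ul = 500,
                                     aliquot_volume_ul = 10,
                                     naoh_molarity = 0.01,
                                     pkas = c(3.8, 5.2, 6.4),
                                     weights = c(0.5, 0.3, 0.2),
                                     step_ul = 1,
                                     indicator_pka = 7.1,
                                     ratio_range = c(0.05, 2.2)) {
  weights <- weights / sum(weights)
  h_aliquot <- h_umol * aliquot_volume_ul / extract_volume_ul   # umol
  base_per_ul <- naoh_molarity                                  # umol/uL
  frac_deprot <- function(ph) sum(weights / (1 + 10^(pkas - ph)))
  # scale total acid so that exactly h_aliquot equivalents reach pH 7
  n_tot <- h_aliquot / frac_deprot(7)
  v_star <- h_aliquot / base_per_ul
  ph_of_v <- function(v) {
    base <- v * base_per_ul
    if (base >= n_tot * frac_deprot(10.49)) return(10.5)
    # below the model floor the indicator is saturated acid-side anyway
    if (base <= n_tot * frac_deprot(2.5)) return(2.5)
    stats::uniroot(function(ph) n_tot * frac_deprot(ph) - base,
                   c(2.5, 10.49), tol = 1e-9)$root
  }
  ratio_of_ph <- function(ph) {
    ratio_range[1] + diff(ratio_range) / (1 + 10^(indicator_pka - ph))
  }
  v_eq <- n_tot / base_per_ul
  vols <- seq(0, ceiling(v_eq) + 5, by = step_ul)
  ph <- vapply(vols, ph_of_v, numeric(1))
  scale <- runif(length(vols), 0.8, 1.2)
  calibration <- data.frame(ph = seq(4.6, 7.8, by = 0.4))
  calibration$ratio <- ratio_of_ph(calibration$ph)
  list(steps = data.frame(volume_ul = vols, a445 = scale,
                          a615 = scale * ratio_of_ph(ph)),
       calibration = calibration,
       v_star_ul = v_star,
       v_eq_ul = v_eq)
}
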