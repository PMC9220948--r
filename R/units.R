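## Unit system: every quantity inside the package is SI (m, m^2, N, V, J).
## The user-facing surface speaks the field's mixed units (angstrom^2 for
## area per lipid, nm for lengths, um^2 for membrane areas, pN for line
## tension, mV for dipole potentials) and converts once, on construction.

#' Unit conversion constants
#'
#' Multiplicative factors taking the stated unit to SI.
#' @name unit-constants
#' @keywords internal
NULL

.PN_PER_N <- 1e12 # piconewtons per newton
.NM <- 1e-9 # m per nm
.A2 <- 1e-20 # m^2 per angstrom^2
.UM2 <- 1e-12 # m^2 per um^2
.EPS0 <- 8.8541878128e-12 # vacuum permittivity, F/m (CODATA 2018)
.J_PER_PN_NM <- 1e-21 # joules per pN nm

#' Convert an energy in joules to piconewton-nanometres
#'
#' Convenience conversion for readability: thermal and membrane energies are
#' conventionally quoted in pN nm (1 pN nm = 1e-21 J, about 0.24 kT at 300 K).
#'
#' @param E_J energy in joules.
#' @return energy in pN nm.
#' @export
#' @examples
#' joules_to_pN_nm(4.1e-21) # ~ kT at room temperature
joules_to_pN_nm <- function(E_J) E_J / .J_PER_PN_NM

#' Convert an energy in piconewton-nanometres to joules
#' @param E_pN_nm energy in pN nm.
#' @return energy in joules.
#' @export
pN_nm_to_joules <- function(E_pN_nm) E_pN_nm * .J_PER_PN_NM

#' Bilayer model parameters
#'
#' Bundles every physical parameter of the domain-size energy model and
#' converts it to SI. Defaults are the model's stated membrane constants:
#' area per lipid 55 A^2, dipole-plane separation between leaflets
#' h = 3.5 nm, local dielectric constant 8, and a total raft-covered area of
#' 20 um^2 shared by all domains. The dipole potential difference between
#' the ordered and disordered phase (`delta_V_mV`) and the distance of
#' closest approach of two headgroup dipoles (`d_min_nm`) have no published
#' value here; the defaults (140 mV, 1.0 nm) sit in the physically measured
#' range for ordered/disordered dipole-potential contrasts and headgroup
#' spacings, and are chosen so that the default line-tension sweep
#' (0.1-3 pN) has its energy minimum strictly inside the physical radius
#' range (see the package vignette).
#'
#' @param sigma_pN line tension of the ordered/disordered phase boundary, pN.
#' @param A_L_A2 area per lipid, square angstrom.
#' @param h_nm separation between the dipole planes of the two leaflets, nm.
#' @param eps relative dielectric constant of the bilayer near the dipoles.
#' @param delta_V_mV electrostatic potential difference between the raft
#'   domain and the surrounding disordered phase, mV.
#' @param d_min_nm distance of closest approach of two dipoles, nm; lower
#'   integration cutoff for the singular intra-leaflet kernel.
#' @param A_tot_um2 total area covered by all raft domains, um^2.
#' @return a validated object of class `bilayer_params` with fields
#'   `sigma`, `A_L`, `h`, `eps`, `eps0`, `delta_V`, `d_min`, `A_tot`,
#'   all in SI units.
#' @export
#' @examples
#' p <- bilayer_params(sigma_pN = 1)
#' p$sigma # 1e-12 N
bilayer_params <- function(sigma_pN = 1,
                           A_L_A2 = 55,
                           h_nm = 3.5,
                           eps = 8,
                           delta_V_mV = 140,
                           d_min_nm = 1.0,
                           A_tot_um2 = 20) {
  p <- structure(
    list(
      sigma = sigma_pN / .PN_PER_N,
      A_L = A_L_A2 * .A2,
      h = h_nm * .NM,
      eps = eps,
      eps0 = .EPS0,
      delta_V = delta_V_mV * 1e-3,
      d_min = d_min_nm * .NM,
      A_tot = A_tot_um2 * .UM2
    ),
    class = "bilayer_params"
  )
  validate_params(p)
}

#' Validate bilayer parameters
#'
#' Checks the physical invariants of a `bilayer_params` object: strictly
#' positive lengths, areas and dielectric constant; non-negative line
#' tension; a closest-approach distance smaller than the largest possible
#' domain diameter. An area per lipid outside the physically sane guard
#' range of 30-120 A^2 triggers a warning (not an error), so exploratory
#' sweeps are not blocked.
#'
#' @param params a `bilayer_params` object (fields in SI).
#' @return `params`, invisibly unchanged, if valid; otherwise an error
#'   naming the offending field.
#' @export
validate_params <- function(params) {
  if (!inherits(params, "bilayer_params")) {
    stop("`params` must be a `bilayer_params` object", call. = FALSE)
  }
  needed <- c("sigma", "A_L", "h", "eps", "eps0", "delta_V", "d_min", "A_tot")
  missing_f <- setdiff(needed, names(params))
  if (length(missing_f) > 0) {
    stop("missing field(s): ", paste(missing_f, collapse = ", "), call. = FALSE)
  }
  for (f in needed) {
    v <- params[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("field `", f, "` must be a single finite number", call. = FALSE)
    }
  }
  for (f in c("A_L", "h", "eps", "eps0", "d_min", "A_tot")) {
    if (params[[f]] <= 0) {
      stop("field `", f, "` must be strictly positive", call. = FALSE)
    }
  }
  if (params$sigma < 0) {
    stop("field `sigma` must be non-negative", call. = FALSE)
  }
  R_max <- sqrt(params$A_tot / pi)
  if (params$d_min >= 2 * R_max) {
    stop(
      "field `d_min` must be smaller than the maximal domain diameter (",
      format(2 * R_max / .NM), " nm)",
      call. = FALSE
    )
  }
  A_L_A2 <- params$A_L / .A2
  if (A_L_A2 < 30 || A_L_A2 > 120) {
    warning(
      "area per lipid ", format(A_L_A2),
      " A^2 is outside the physically expected 30-120 A^2 range",
      call. = FALSE
    )
  }
  invisible(params)
}

#' @export
print.bilayer_params <- function(x, ...) {
  cat("Bilayer parameters (internal SI):\n")
  cat(sprintf("  line tension sigma : %g pN\n", x$sigma * .PN_PER_N))
  cat(sprintf("  area per lipid A_L : %g A^2\n", x$A_L / .A2))
  cat(sprintf("  leaflet separation h : %g nm\n", x$h / .NM))
  cat(sprintf("  dielectric eps : %g\n", x$eps))
  cat(sprintf("  dipole potential delta_V : %g mV\n", x$delta_V * 1e3))
  cat(sprintf("  closest approach d_min : %g nm\n", x$d_min / .NM))
  cat(sprintf("  total domain area A_tot : %g um^2\n", x$A_tot / .UM2))
  invisible(x)
}

#' Convert a cytokine activity concentration to molarity
#'
#' Standardising cytokine doses on an equimolar basis requires converting an
#' activity concentration (units of biological activity per microlitre) to a
#' molar concentration via the specific activity and the molecular mass:
#' mass/volume = activity/volume divided by specific activity, and molarity =
#' mass/volume divided by molar mass. For wild-type IL-2 (specific activity
#' 15e6 U/mg, 15.5 kDa) an activity of 1000 U/uL computes to 4.30 uM.
#'
#' @param activity_per_uL activity concentration, units of activity per uL.
#' @param specific_activity_U_per_mg specific activity, units per mg.
#' @param molar_mass_kDa molecular mass, kDa.
#' @return molar concentration in uM.
#' @export
#' @examples
#' iu_to_molar(1000, 15e6, 15.5) # 4.30 uM
iu_to_molar <- function(activity_per_uL, specific_activity_U_per_mg,
                        molar_mass_kDa) {
  if (any(activity_per_uL < 0)) {
    stop("`activity_per_uL` must be non-negative", call. = FALSE)
  }
  if (any(specific_activity_U_per_mg <= 0)) {
    stop("`specific_activity_U_per_mg` must be strictly positive", call. = FALSE)
  }
  if (any(molar_mass_kDa <= 0)) {
    stop("`molar_mass_kDa` must be strictly positive", call. = FALSE)
  }
  U_per_mL <- activity_per_uL * 1e3
  mg_per_mL <- U_per_mL / specific_activity_U_per_mg # = g/L
  g_per_mol <- molar_mass_kDa * 1e3
  mol_per_L <- mg_per_mL / g_per_mol
  mol_per_L * 1e6 # uM
}

#' Tumor volume from two perpendicular diameters
#'
#' Volume of a sphere, (4/3) pi r^3, with the radius taken as the mean
#' radius of the two perpendicular caliper diameters, r = (d1 + d2)/4.
#'
#' @param d1_mm,d2_mm perpendicular tumor diameters, mm.
#' @return tumor volume in mm^3.
#' @export
#' @examples
#' tumor_volume(4, 6) # 65.45 mm^3
tumor_volume <- function(d1_mm, d2_mm) {
  if (any(d1_mm < 0) || any(d2_mm < 0)) {
    stop("diameters must be non-negative", call. = FALSE)
  }
  r <- (d1_mm + d2_mm) / 4
  (4 / 3) * pi * r^3
}
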