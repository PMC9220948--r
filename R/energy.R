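## Energy terms of the domain-size model. A population of N_D circular
## ordered domains of radius R_D covers a fixed total area A_tot. The total
## energy is the boundary (line-tension) energy plus the electrostatic
## energy of the permanent lipid dipoles, evaluated as expectations of the
## pairwise dipole-dipole interaction under the disk pair-distance
## distribution.

#' Number of domains at fixed total raft area
#'
#' All domains share one fixed total area, so the (continuous) domain count
#' is `N_D = A_tot / (pi R_D^2)`. It is not rounded: the energy minimisation
#' over radius needs a smooth objective.
#'
#' @param R_D_nm domain radius, nm.
#' @param A_tot_um2 total raft-covered area, um^2 (default 20).
#' @return domain count (dimensionless, continuous).
#' @export
#' @examples
#' domain_count(500, 20) # ~25.46 domains of radius 0.5 um
domain_count <- function(R_D_nm, A_tot_um2 = 20) {
  R_max_nm <- sqrt(A_tot_um2 * .UM2 / pi) / .NM
  if (any(R_D_nm <= 0) || any(R_D_nm > R_max_nm * (1 + 1e-12))) {
    stop(
      "`R_D_nm` must lie in (0, ", format(R_max_nm),
      "] nm for A_tot = ", A_tot_um2, " um^2",
      call. = FALSE
    )
  }
  (A_tot_um2 * .UM2) / (pi * (R_D_nm * .NM)^2)
}

#' Boundary (line-tension) energy of the domain population
#'
#' `E_perim = N_D * 2 pi R_D * sigma`: each domain pays its circumference
#' times the line tension of the ordered/disordered boundary. With the
#' fixed-area coupling `N_D = A_tot/(pi R_D^2)` this is `2 A_tot sigma /
#' R_D`, so the boundary term always favours fewer, larger domains.
#'
#' @param R_D_nm domain radius, nm.
#' @param N_D domain count (continuous, >= 1 permitted to be fractional).
#' @param sigma line tension in newtons (1 pN = 1e-12 N).
#' @return energy in joules.
#' @export
perimeter_energy <- function(R_D_nm, N_D, sigma) {
  if (any(R_D_nm <= 0)) stop("`R_D_nm` must be positive", call. = FALSE)
  if (any(N_D <= 0)) stop("`N_D` must be positive", call. = FALSE)
  if (any(sigma < 0)) stop("`sigma` must be non-negative", call. = FALSE)
  N_D * 2 * pi * (R_D_nm * .NM) * sigma
}

#' Dipole moment per lipid from the phase dipole-potential difference
#'
#' Parallel-plate relation between a uniform dipole sheet and the potential
#' jump across it: a surface density `mu_d / A_L` of dipoles normal to the
#' plane produces a potential difference `delta_V = mu_d / (eps eps0 A_L)`,
#' hence `mu_d = eps eps0 delta_V A_L`. The difference in dipole potential
#' between the ordered and disordered phases maps to an excess dipole
#' moment per lipid of the raft phase.
#'
#' @param delta_V potential difference, volts.
#' @param eps relative dielectric constant near the dipoles.
#' @param eps0 vacuum permittivity, F/m.
#' @param A_L area per lipid, m^2.
#' @return dipole moment per lipid, C m.
#' @export
#' @examples
#' dipole_moment_per_lipid(0.1, 8, 8.8541878128e-12, 55e-20) # ~3.9e-30 C m
dipole_moment_per_lipid <- function(delta_V, eps, eps0, A_L) {
  if (any(eps <= 0) || any(eps0 <= 0) || any(A_L <= 0)) {
    stop("`eps`, `eps0` and `A_L` must be positive", call. = FALSE)
  }
  eps * eps0 * delta_V * A_L
}

## dipoles per leaflet in one domain of radius R (m)
.lipids_per_leaflet <- function(R, params) pi * R^2 / params$A_L

## common prefactor mu^2 / (4 pi eps eps0) of both dipole kernels, J m^3
.dipole_prefactor <- function(params) {
  mu <- dipole_moment_per_lipid(params$delta_V, params$eps, params$eps0, params$A_L)
  mu^2 / (4 * pi * params$eps * params$eps0)
}

#' Intra-leaflet dipole repulsion energy
#'
#' Expected pairwise interaction of like-oriented dipoles within each
#' leaflet of every domain. Two parallel dipoles normal to the membrane at
#' in-plane separation `r` repel with energy `mu^2 / (4 pi eps eps0 r^3)`;
#' the expectation over the disk pair-distance distribution is taken with
#' the closest-approach cutoff `d_min` as lower limit (the kernel is
#' singular at contact), multiplied by the `n^2` dipole pairs of the two
#' leaflets (`n = pi R_D^2 / A_L` per leaflet, counting the `n(n-1)/2 ~
#' n^2/2` pairs of each leaflet) and by the domain count `N_D`.
#' Strictly positive whenever `delta_V != 0`, and proportional to
#' `delta_V^2`.
#'
#' @param R_D_nm domain radius, nm.
#' @param params validated [bilayer_params()].
#' @return energy in joules.
#' @export
intraleaflet_energy <- function(R_D_nm, params) {
  validate_params(params)
  R <- R_D_nm * .NM
  if (params$delta_V == 0) {
    return(0)
  }
  if (2 * R <= params$d_min) {
    return(0) # no pair farther apart than the closest approach
  }
  pref <- .dipole_prefactor(params) # J m^3
  n <- .lipids_per_leaflet(R, params)
  N_D <- domain_count(R_D_nm, params$A_tot / .UM2)
  ## quadrature in nm; kernel r^-3 picks up a nm^-3 -> m^-3 factor
  mean_r3 <- expected_kernel_value(
    R / .NM, function(r) (r * .NM)^-3,
    r_lo = params$d_min / .NM
  )
  N_D * n^2 * pref * mean_r3
}

#' Inter-leaflet dipole coupling energy
#'
#' Expected interaction between dipoles in opposing leaflets. With the
#' bilayer normal as the common alignment reference for the dipoles of both
#' leaflets, a pair separated in-plane by `r` and vertically by the
#' dipole-plane distance `h` interacts with the parallel-dipole energy
#' `mu^2 (r^2 - 2 h^2) / (4 pi eps eps0 (r^2 + h^2)^(5/2))`: attractive for
#' stacked pairs (`r < sqrt(2) h`), repulsive beyond, where it reinforces
#' the in-plane repulsion of the intra-leaflet term. The kernel is finite
#' at `r = 0` because `h > 0`, so no contact cutoff is applied.
#'
#' @inheritParams intraleaflet_energy
#' @return energy in joules.
#' @export
interleaflet_energy <- function(R_D_nm, params) {
  validate_params(params)
  R <- R_D_nm * .NM
  if (params$delta_V == 0) {
    return(0)
  }
  pref <- .dipole_prefactor(params)
  n <- .lipids_per_leaflet(R, params)
  N_D <- domain_count(R_D_nm, params$A_tot / .UM2)
  h <- params$h
  kern <- function(r) {
    rm <- r * .NM
    (rm^2 - 2 * h^2) / (rm^2 + h^2)^2.5
  }
  ## integrate the attractive (r < sqrt(2) h) and repulsive pieces
  ## separately: the kernel's sign change defeats pure relative error
  ## control when a panel's contributions cancel
  r_zero_nm <- sqrt(2) * h / .NM
  mean_k <- expected_kernel_value(R / .NM, kern, r_lo = 0, r_hi = r_zero_nm) +
    expected_kernel_value(R / .NM, kern, r_lo = min(r_zero_nm, 2 * R / .NM))
  N_D * n^2 * pref * mean_k
}

#' Combined electrostatic energy of the leaflet dipoles
#'
#' Sum of the intra-leaflet repulsion and the inter-leaflet coupling; the
#' term that opposes line tension in the total energy, growing with domain
#' radius at fixed total area and scaling with the square of the dipole
#' potential difference.
#'
#' @inheritParams intraleaflet_energy
#' @return energy in joules.
#' @export
electrostatic_energy <- function(R_D_nm, params) {
  intraleaflet_energy(R_D_nm, params) + interleaflet_energy(R_D_nm, params)
}

#' Total domain energy and its breakdown
#'
#' Evaluates every energy term for one candidate domain radius under the
#' fixed-total-area constraint: `E_total = E_perim + E_elec` with
#' `E_elec = E_intra + E_inter`. The minimum of `E_total` over `R_D`
#' determines the equilibrium raft size (see [minimize_total_energy()]).
#'
#' @inheritParams intraleaflet_energy
#' @return an `energy_breakdown` object: list with `R_D_nm`, `N_D`,
#'   `E_perim`, `E_intra`, `E_inter`, `E_elec`, `E_total` (joules).
#' @export
#' @examples
#' p <- bilayer_params(sigma_pN = 1)
#' total_energy(100, p)
total_energy <- function(R_D_nm, params) {
  validate_params(params)
  N_D <- domain_count(R_D_nm, params$A_tot / .UM2)
  E_perim <- perimeter_energy(R_D_nm, N_D, params$sigma)
  E_intra <- intraleaflet_energy(R_D_nm, params)
  E_inter <- interleaflet_energy(R_D_nm, params)
  E_elec <- E_intra + E_inter
  structure(
    list(
      R_D_nm = R_D_nm, N_D = N_D,
      E_perim = E_perim, E_intra = E_intra, E_inter = E_inter,
      E_elec = E_elec, E_total = E_perim + E_elec
    ),
    class = "energy_breakdown"
  )
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf(
    "Energy breakdown at R_D = %g nm (N_D = %.4g):\n", x$R_D_nm, x$N_D
  ))
  for (f in c("E_perim", "E_intra", "E_inter", "E_elec", "E_total")) {
    cat(sprintf(
      "  %-7s = %12.5g J  (%.5g pN nm)\n", f, x[[f]], joules_to_pN_nm(x[[f]])
    ))
  }
  invisible(x)
}

#' Flatten an energy breakdown to a one-row data frame
#'
#' @param x an `energy_breakdown`.
#' @param ... unused.
#' @return one-row `data.frame` with the breakdown fields.
#' @export
as.data.frame.energy_breakdown <- function(x, ...) {
  data.frame(
    R_D_nm = x$R_D_nm, N_D = x$N_D, E_perim = x$E_perim,
    E_intra = x$E_intra, E_inter = x$E_inter, E_elec = x$E_elec,
    E_total = x$E_total
  )
}
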