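#' @useDynLib sugres, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

vec3 <- function(x) {
  if (!is.numeric(x) || length(x) != 3L) stop("expected a length-3 coordinate", call. = FALSE)
  as.numeric(x)
}

unit <- function(x) {
  n <- sqrt(sum(x^2))
  if (n < 1e-12) stop("zero-length orientation vector", call. = FALSE)
  x / n
}

# shared anisotropy helper: the Gay-Berne S function of the scalar products
# a = rhat.u1, b = rhat.u2, c = u1.u2 at coupling chi
gb_S_fun <- function(a, b, c, chi) {
  (a + b)^2 / (1 + chi * c) + (a - b)^2 / (1 - chi * c)
}

#' Gay-Berne tail-tail interaction energy
#'
#' Orientation-dependent generalization of the Lennard-Jones potential for
#' the uncharged (tail) parts of two interaction sites.  The energy is zero
#' at the orientation-dependent contact distance `sigma(omega)` and tends to
#' zero at large separation; with both anisotropies zero it reduces exactly
#' to the isotropic Lennard-Jones potential with parameters
#' (`sigma0_tail`, `eps_tail`).
#'
#' The shifted Gay-Berne form is used:
#' \deqn{E = 4\epsilon(\omega)\,(\rho^{-12} - \rho^{-6}),\quad
#'       \rho = (r - \sigma(\omega) + \sigma^0)/\sigma^0}
#' with the standard anisotropic \eqn{\sigma(\omega)} (shape, `chi_gb`) and
#' \eqn{\epsilon(\omega)} (well depth, exponents \eqn{\mu = 2,\ \nu = 1},
#' coupling `chi_gb_prime`).
#'
#' @param tail_i,tail_j Tail coordinates, length-3 (Angstrom).
#' @param u_i,u_j Site axis unit vectors (tail-to-head directions).
#' @param params [cg_params()].
#' @return Energy, kcal/mol.
#' @export
gay_berne <- function(tail_i, tail_j, u_i, u_j, params) {
  rv <- vec3(tail_j) - vec3(tail_i)
  r <- sqrt(sum(rv^2))
  if (r < 1e-10) stop("singularity: coincident tails", call. = FALSE)
  u1 <- unit(vec3(u_i)); u2 <- unit(vec3(u_j))
  rhat <- rv / r
  a <- sum(rhat * u1); b <- sum(rhat * u2); c <- sum(u1 * u2)
  s0 <- params$sigma0_tail; e0 <- params$eps_tail
  chi <- params$chi_gb; chip <- params$chi_gb_prime
  if (chi == 0 && chip == 0) {
    sigma <- s0; eps <- e0
  } else {
    gg <- 1 - chi / 2 * gb_S_fun(a, b, c, chi)
    if (gg <= 0) return(Inf)
    sigma <- s0 / sqrt(gg)
    e1 <- 1 / sqrt(1 - chi^2 * c^2)
    e2 <- 1 - chip / 2 * gb_S_fun(a, b, c, chip)
    eps <- e0 * e1 * e2^2
  }
  rho <- (r - sigma + s0) / s0
  if (rho <= 0) return(Inf)
  4 * eps * (rho^-12 - rho^-6)
}

#' Generalized Born interpolation function
#'
#' Still's smooth interpolation between the Born self-energy limit at zero
#' separation, \eqn{f_{GB}(0) = \sqrt{a_i a_j}}, and the Coulomb limit
#' \eqn{f_{GB}(r) \to r} at large separation:
#' \deqn{f_{GB}(r) = \sqrt{r^2 + a_i a_j \exp(-r^2 / 4 a_i a_j)}}
#'
#' @param r Separation, Angstrom (`>= 0`).
#' @param a_i,a_j Born radii, Angstrom (`> 0`).
#' @return \eqn{f_{GB}} in Angstrom (vectorized over `r`).
#' @export
gb_function <- function(r, a_i, a_j) {
  if (a_i <= 0 || a_j <= 0) stop("Born radii must be > 0", call. = FALSE)
  if (any(r < 0)) stop("separation must be >= 0", call. = FALSE)
  aij <- a_i * a_j
  sqrt(r^2 + aij * exp(-r^2 / (4 * aij)))
}

#' Generalized Born polarization energy of two charged heads
#'
#' Solvent-polarization contribution of a pair of charged heads,
#' \deqn{E = -k_e\left(\frac{1}{\epsilon_{in}} - \frac{1}{\epsilon_{out}}\right)
#'       \frac{q_i q_j}{f_{GB}(r'_{ij})}}
#' which is stabilizing (negative) for like charges in a high-dielectric
#' solvent and vanishes when either charge is zero or when
#' `eps_in == eps_out` (no polarization contrast).
#'
#' @param head_i,head_j Head coordinates, length-3 (Angstrom).
#' @param q_i,q_j Head charges, e.
#' @param params [cg_params()].
#' @return Energy, kcal/mol.
#' @export
gb_polarization <- function(head_i, head_j, q_i, q_j, params) {
  if (params$eps_in <= 0 || params$eps_out <= 0) {
    stop("dielectric constants must be > 0", call. = FALSE)
  }
  r <- sqrt(sum((vec3(head_j) - vec3(head_i))^2))
  f <- gb_function(r, params$born_radius, params$born_radius)
  -332.0716 * (1 / params$eps_in - 1 / params$eps_out) * q_i * q_j / f
}

#' Head-tail polarization energy
#'
#' Interaction of the charged head of each site with the polarizable
#' uncharged tail of the other, modeled as a screened charge-induced-dipole
#' attraction.  For each of the two cross distances (head i - tail j at
#' \eqn{r''_{ij}}, head j - tail i at \eqn{r''_{ji}}):
#' \deqn{E = -\left(\frac{1}{\epsilon_{in}} - \frac{1}{\epsilon_{out}}\right)
#'   q^2\left[\alpha_1 \frac{e^{-2\kappa r}(1+\kappa r)^2}{r^4}
#'          + \alpha_2 \frac{e^{-2\kappa r}}{r^6}\right]}
#' where q is the polarizing head's charge.  The form is symmetric under
#' particle exchange (which swaps the two cross distances), reduces to the
#' unscreened charge-induced-dipole form at `kappa = 0`, and vanishes when
#' `alpha1 = alpha2 = 0`.
#'
#' @param head_i,tail_i,head_j,tail_j Coordinates, length-3 (Angstrom).
#' @param q_i,q_j Head charges, e.
#' @param params [cg_params()].
#' @return Energy, kcal/mol.
#' @export
head_tail_polarization <- function(head_i, tail_i, q_i, head_j, tail_j, q_j, params) {
  r_ij <- sqrt(sum((vec3(tail_j) - vec3(head_i))^2))   # head i polarizes tail j
  r_ji <- sqrt(sum((vec3(tail_i) - vec3(head_j))^2))   # head j polarizes tail i
  if (r_ij < 1e-10 || r_ji < 1e-10) {
    stop("singularity: zero head-tail cross distance", call. = FALSE)
  }
  pol_part(r_ij, q_i, params) + pol_part(r_ji, q_j, params)
}

pol_part <- function(r, q, params) {
  k <- params$kappa
  C <- (1 / params$eps_in - 1 / params$eps_out) * q^2
  ex <- exp(-2 * k * r)
  -C * (params$alpha1 * ex * (1 + k * r)^2 / r^4 + params$alpha2 * ex / r^6)
}

#' Isotropic cavity term of two charged heads
#'
#' Solvent cavity (desolvation shell) free energy of the charged heads: a
#' Gaussian shell of amplitude `eps_cav_iso` and width `cav_width` centered
#' at the contact distance \eqn{\sigma_i^{iso} + \sigma_j^{iso}}.  Finite
#' everywhere, symmetric in i and j, and decaying to zero at large
#' separation.
#'
#' @param head_i,head_j Head coordinates, length-3 (Angstrom).
#' @param params [cg_params()].
#' @return Energy, kcal/mol.
#' @export
cavity_iso <- function(head_i, head_j, params) {
  r <- sqrt(sum((vec3(head_j) - vec3(head_i))^2))
  if (r < 1e-10) stop("singularity: coincident heads", call. = FALSE)
  s <- 2 * params$sigma_iso
  params$eps_cav_iso * exp(-(r - s)^2 / (2 * params$cav_width^2))
}

#' Anisotropic cavity term of two uncharged tails
#'
#' Same desolvation-shell form as [cavity_iso()] but centered at an
#' orientation-dependent contact distance
#' \eqn{\sigma(\omega) = \sigma^0 [1 - (\chi''^{(1)}/2) S(\chi''^{(2)})]^{-1/2}}
#' built from the Gay-Berne S function of the site axes.  With
#' `chi_cav_1 = 0` the orientation dependence vanishes and the term equals
#' the isotropic evaluation at contact distance `sigma0_tail`.
#'
#' @param tail_i,tail_j Tail coordinates, length-3 (Angstrom).
#' @param u_i,u_j Site axis unit vectors.
#' @param params [cg_params()].
#' @return Energy, kcal/mol.
#' @export
cavity_tails <- function(tail_i, tail_j, u_i, u_j, params) {
  rv <- vec3(tail_j) - vec3(tail_i)
  r <- sqrt(sum(rv^2))
  if (r < 1e-10) stop("singularity: coincident tails", call. = FALSE)
  s0 <- params$sigma0_tail
  sigma <- s0
  if (params$chi_cav_1 != 0) {
    u1 <- unit(vec3(u_i)); u2 <- unit(vec3(u_j))
    rhat <- rv / r
    a <- sum(rhat * u1); b <- sum(rhat * u2); c <- sum(u1 * u2)
    gg <- 1 - params$chi_cav_1 / 2 * gb_S_fun(a, b, c, params$chi_cav_2)
    if (gg <= 0) return(Inf)
    sigma <- s0 / sqrt(gg)
  }
  params$eps_cav_tail * exp(-(r - sigma)^2 / (2 * params$cav_width^2))
}

#' Lennard-Jones interaction of two polar heads
#'
#' Isotropic 12-6 potential with contact distance `sigma_head` (zero energy)
#' and well depth `eps_head` (minimum \eqn{-\epsilon'} at
#' \eqn{2^{1/6}\sigma'}).
#'
#' @param head_i,head_j Head coordinates, length-3 (Angstrom).
#' @param params [cg_params()].
#' @return Energy, kcal/mol.
#' @export
lj_heads <- function(head_i, head_j, params) {
  r <- sqrt(sum((vec3(head_j) - vec3(head_i))^2))
  if (r < 1e-10) stop("singularity: coincident heads", call. = FALSE)
  sr6 <- (params$sigma_head / r)^6
  4 * params$eps_head * (sr6^2 - sr6)
}

#' Screened electrostatic interaction of two charged heads
#'
#' Debye-Hueckel screened Coulomb energy,
#' \deqn{E = k_e \frac{q_i q_j}{\epsilon_{in}\, r'}\, e^{-\kappa r'}}
#' carrying its own weight (`eel`) separately from the other non-bonded
#' terms.  The configured dielectric is the interior constant
#' \eqn{\epsilon_{in}}: dielectric solvent screening is supplied by the
#' generalized Born polarization term ([gb_polarization()]), so that the sum
#' of the two tends to the solvent-screened Coulomb interaction
#' \eqn{k_e q_i q_j / (\epsilon_{out} r)} at large separation.  At
#' `kappa = 0` the counterion screening factor drops out; like charges are
#' repulsive.
#'
#' @param head_i,head_j Head coordinates, length-3 (Angstrom).
#' @param q_i,q_j Head charges, e.
#' @param params [cg_params()].
#' @return Energy, kcal/mol.
#' @export
electrostatics <- function(head_i, head_j, q_i, q_j, params) {
  r <- sqrt(sum((vec3(head_j) - vec3(head_i))^2))
  if (r < 1e-10) stop("singularity: coincident heads", call. = FALSE)
  332.0716 * q_i * q_j * exp(-params$kappa * r) / (params$eps_in * r)
}

#' Temperature factor of an energy term
#'
#' Per-term multiplier encoding the temperature dependence of the effective
#' free-energy terms,
#' \deqn{f_n(T) = \frac{\ln(e + e^{-1})}
#'  {\ln\left[\exp((T/T_0)^{n-1}) + \exp(-(T/T_0)^{n-1})\right]}}
#' with \eqn{T_0 = 300} K, equal to 1 for every term at \eqn{T = T_0}.
#' Bonded terms (`bond`, `ang`, `tor`) are first order (\eqn{f \equiv 1});
#' all inter-residue pair terms, including the separately weighted
#' electrostatic term, are second order.
#'
#' @param term Term name (see [default_weights()]) or an integer order.
#' @param T Temperature, K (> 0).
#' @param params [cg_params()] (supplies `T0`).
#' @return The multiplier \eqn{f_n(T)}.
#' @export
temperature_factor <- function(term, T, params = cg_params()) {
  if (!is.numeric(T) || any(T <= 0)) stop("temperature must be > 0", call. = FALSE)
  order <- if (is.numeric(term)) {
    as.integer(term)
  } else {
    if (!term %in% energy_term_names()) stop("unknown term: ", term, call. = FALSE)
    if (term %in% c("bond", "ang", "tor")) 1L else 2L
  }
  if (order <= 1L) return(rep(1, length(T)))
  y <- (T / params$T0)^(order - 1L)
  log(exp(1) + exp(-1)) / log(exp(y) + exp(-y))
}

#' Bonded energy of a chain
#'
#' Virtual-bond stretching, virtual-bond-angle bending and virtual-bond
#' torsional energies.  The shipped functional forms (pluggable parameters,
#' see [cg_params()]) are
#' \deqn{U_{bond} = \tfrac{k_d}{2}(d_i - d_0)^2,\quad
#'       U_b = \tfrac{k_\theta}{2}(\theta_i - \theta_0)^2,}
#' \deqn{U_{tor} = k_\gamma \sin\theta_{i-1}\sin\theta_i\,
#'       [1 - \cos(\gamma_i - \gamma_0)]}
#' The torsional term receives the dihedral and both adjacent virtual-bond
#' angles jointly; its sine factors switch the torsion off continuously as
#' either adjacent angle approaches collinearity, where the dihedral is
#' ill-defined.
#'
#' @param chain An `hp_chain`.
#' @param params [cg_params()].
#' @return List with `e_bond`, `e_angle`, `e_torsion` (kcal/mol, unweighted).
#' @export
bonded_energy <- function(chain, params) {
  stopifnot(inherits(chain, "hp_chain"))
  if (is.null(params$k_bond) || is.null(params$k_angle) || is.null(params$k_tor)) {
    stop("missing bonded-term coefficients", call. = FALSE)
  }
  th0 <- params$theta0 * pi / 180
  g0 <- params$gamma0 * pi / 180
  e_bond <- 0.5 * params$k_bond * sum((chain$d - params$d0)^2)
  th <- chain$theta * pi / 180
  e_angle <- if (length(th)) 0.5 * params$k_angle * sum((th - th0)^2) else 0
  e_torsion <- 0
  ng <- length(chain$gamma)
  if (ng) {
    ga <- chain$gamma * pi / 180
    e_torsion <- params$k_tor *
      sum(sin(th[seq_len(ng)]) * sin(th[seq_len(ng) + 1L]) * (1 - cos(ga - g0)))
  }
  list(e_bond = e_bond, e_angle = e_angle, e_torsion = e_torsion)
}

#' Total effective energy of a chain
#'
#' Evaluates every term of the weighted effective energy function
#' \deqn{U = \sum_k w_k f_k(T)\, U_k}
#' over the bonded internal coordinates and all non-bonded site pairs
#' (pairs closer in sequence than `params$exclude_near` are excluded: their
#' geometry is governed by the bonded terms).  No distance cutoff is
#' applied.  The computation runs in compiled code with analytic gradients;
#' [forces()] returns the same evaluation's forces.
#'
#' @param chain An `hp_chain`.
#' @param params [cg_params()].
#' @param forces Also return forces on the anchors?
#' @return An `energy_report`: per-term raw energies, weights, temperature
#'   factors, weighted contributions, `total` (kcal/mol), and optionally
#'   `forces` ((dp+1) x 3, kcal/mol/Angstrom).
#' @export
total_energy <- function(chain, params, forces = FALSE) {
  stopifnot(inherits(chain, "hp_chain"))
  validate_params(params)
  res <- cpp_energy(chain$anchors, chain$charges, params_for_kernel(params),
                    forces = forces)
  if (!res$finite) {
    stop("singularity error: non-finite energy (overlapping interaction points)",
         call. = FALSE)
  }
  rep <- list(
    raw = res$raw,
    weights = res$weights,
    f_factors = res$f_factors,
    contributions = res$raw * res$weights * res$f_factors,
    total = res$total
  )
  if (forces) rep$forces <- res$forces
  class(rep) <- "energy_report"
  rep
}

#' Forces on the anchor points
#'
#' Analytic negative gradient of [total_energy()] with respect to every
#' anchor coordinate (heads, tails and site centers are deterministic
#' functions of the anchors, so their contributions are chain-ruled onto the
#' anchors).  The net force and net torque on the whole chain vanish.
#'
#' @param chain An `hp_chain`.
#' @param params [cg_params()].
#' @return A `(dp + 1) x 3` matrix, kcal/mol/Angstrom.
#' @export
forces <- function(chain, params) {
  total_energy(chain, params, forces = TRUE)$forces
}

#' @export
print.energy_report <- function(x, ...) {
  cat("SUGRES-1P energy report (kcal/mol)\n")
  df <- as.data.frame(x)
  print(df, row.names = FALSE, digits = 6)
  cat(sprintf("  total: %.6f kcal/mol\n", x$total))
  invisible(x)
}

#' @export
as.data.frame.energy_report <- function(x, ...) {
  data.frame(term = names(x$raw),
             raw = as.numeric(x$raw),
             weight = as.numeric(x$weights),
             f_T = as.numeric(x$f_factors),
             contribution = as.numeric(x$contributions),
             stringsAsFactors = FALSE)
}

#' Write an energy report as a tabular text file
#'
#' One row per term: name, raw energy, weight, temperature factor and
#' weighted contribution; the total is appended as a final row.
#'
#' @param report An `energy_report`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_energy_report <- function(report, path) {
  df <- as.data.frame(report)
  df <- rbind(df, data.frame(term = "total", raw = NA, weight = NA, f_T = NA,
                             contribution = report$total))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
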