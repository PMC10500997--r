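#' Coarse-grained force-field parameters
#'
#' Builds the full parameter set of the SUGRES-1P effective energy function
#' for heparin.  Every interaction site (one per sugar residue, placed midway
#' between the flanking glycosidic oxygens) carries a charged "head" and an
#' uncharged "tail"; the parameters below control the geometry of that
#' subdivision and every energy term evaluated between sites.
#'
#' Units are Angstrom, kcal/mol, elementary charges and Kelvin throughout.
#' The numeric defaults for well depths, radii, anisotropies and bonded-term
#' coefficients are documented placeholders at physically sensible
#' coarse-grained magnitudes: the published parametrization tables are not
#' shipped, and [read_params()] loads user-supplied values.
#'
#' @param sigma0_tail Tail-tail contact distance \eqn{\sigma_{ij}^0} (side-to-side
#'   zero of the Gay-Berne term), Angstrom.
#' @param eps_tail Gay-Berne well depth \eqn{\epsilon_{ij}}, kcal/mol.
#' @param chi_gb,chi_gb_prime Gay-Berne shape and well-depth anisotropies
#'   (dimensionless, in (-1, 1); 0 recovers the isotropic Lennard-Jones limit).
#' @param sigma_head,eps_head Head-head Lennard-Jones contact distance
#'   \eqn{\sigma_{ij}'} (Angstrom) and well depth \eqn{\epsilon_{ij}'} (kcal/mol).
#' @param born_radius Generalized-Born radius \eqn{a_i} of a charged head, Angstrom.
#' @param eps_in,eps_out Effective dielectric constants inside the particles and
#'   of the bulk solvent (dimensionless, `eps_out > eps_in > 0`).
#' @param alpha1,alpha2 Tail solvation (head-tail polarization) coefficients
#'   \eqn{\alpha_1} (kcal mol^-1 A^4 e^-2) and \eqn{\alpha_2} (kcal mol^-1 A^6 e^-2).
#' @param chi_cav_1,chi_cav_2 Anisotropies of the tail cavity term (strength and
#'   orientational coupling; both 0 recovers the isotropic cavity form).
#' @param sigma_iso Minimum-distance radius \eqn{\sigma_i^{iso}} of a charged
#'   head entering the isotropic cavity term, Angstrom.
#' @param eps_cav_iso,eps_cav_tail Amplitudes of the head and tail cavity
#'   (desolvation-shell) terms, kcal/mol.
#' @param cav_width Width of the cavity desolvation shell, Angstrom.
#' @param kappa Debye-Hueckel inverse screening length \eqn{\kappa}, 1/Angstrom.
#'   Enters the screened electrostatic and head-tail polarization terms;
#'   `kappa = 0` is the unscreened (counterion-free) limit.
#' @param weights Named numeric vector of the ten energy-term weights
#'   (see [default_weights()]); all non-negative.
#' @param temperature Simulation temperature T, Kelvin.
#' @param T0 Reference temperature of the temperature factors, Kelvin (300).
#' @param d0,k_bond Equilibrium virtual-bond length (Angstrom) and harmonic
#'   stretching constant (kcal mol^-1 A^-2).
#' @param theta0,k_angle Equilibrium virtual-bond angle (degrees) and bending
#'   constant (kcal mol^-1 rad^-2).
#' @param k_tor,gamma0 Torsional amplitude (kcal/mol) and equilibrium
#'   virtual-bond dihedral (degrees; 180 is the extended conformation).
#' @param charge_split Length-2 numeric: charges of the two residues of one
#'   IdoA2S-GlcNS6S disaccharide, e.  Must sum to -4.
#' @param head_offset,tail_offset Signed displacement of the head and tail from
#'   the site center along the site axis (the virtual-bond direction), Angstrom.
#'   Setting both to 0 collapses head = tail = site ("collapsed" isotropic mode).
#' @param site_mass Mass attributed to each anchor point, amu.
#' @param exclude_near Non-bonded exclusion window: site pairs with
#'   `|i - j| <= exclude_near` are omitted from the pair sum (their geometry is
#'   governed by the bonded terms).  Default 2.
#'
#' @return An object of class `cg_params` (a validated named list).
#' @seealso [default_weights()], [read_params()], [write_params()]
#' @export
#' @examples
#' p <- cg_params()
#' p$weights[["eel"]] <- 7
#' p$kappa <- 0.2
cg_params <- function(sigma0_tail = 4.5,
                      eps_tail = 0.30,
                      chi_gb = 0.30,
                      chi_gb_prime = 0.20,
                      sigma_head = 4.0,
                      eps_head = 0.20,
                      born_radius = 3.0,
                      eps_in = 2.0,
                      eps_out = 80.0,
                      alpha1 = 5.0,
                      alpha2 = 0.0,
                      chi_cav_1 = 0.30,
                      chi_cav_2 = 0.20,
                      sigma_iso = 2.0,
                      eps_cav_iso = 0.50,
                      eps_cav_tail = 0.50,
                      cav_width = 2.0,
                      kappa = 0.0,
                      weights = default_weights(),
                      temperature = 300,
                      T0 = 300,
                      d0 = 5.0,
                      k_bond = 20.0,
                      theta0 = 150,
                      k_angle = 8.0,
                      k_tor = 1.0,
                      gamma0 = 180,
                      charge_split = c(-2, -2),
                      head_offset = 1.0,
                      tail_offset = -1.0,
                      site_mass = 288.0,
                      exclude_near = 2) {
  p <- list(
    sigma0_tail = sigma0_tail, eps_tail = eps_tail,
    chi_gb = chi_gb, chi_gb_prime = chi_gb_prime,
    sigma_head = sigma_head, eps_head = eps_head,
    born_radius = born_radius, eps_in = eps_in, eps_out = eps_out,
    alpha1 = alpha1, alpha2 = alpha2,
    chi_cav_1 = chi_cav_1, chi_cav_2 = chi_cav_2,
    sigma_iso = sigma_iso, eps_cav_iso = eps_cav_iso,
    eps_cav_tail = eps_cav_tail, cav_width = cav_width,
    kappa = kappa, weights = weights,
    temperature = temperature, T0 = T0,
    d0 = d0, k_bond = k_bond, theta0 = theta0, k_angle = k_angle,
    k_tor = k_tor, gamma0 = gamma0,
    charge_split = charge_split,
    head_offset = head_offset, tail_offset = tail_offset,
    site_mass = site_mass, exclude_near = exclude_near
  )
  class(p) <- "cg_params"
  validate_params(p)
  p
}

#' Default energy-term weights
#'
#' One dimensionless weight per named term of the effective energy function.
#' All weights default to 1; the calibration sweep varies one family at a time.
#'
#' @return Named numeric vector with entries `bond`, `ang`, `tor`, `GBerne`,
#'   `polGB`, `pol`, `caviso`, `cavtail`, `vdw`, `eel`.
#' @export
default_weights <- function() {
  c(bond = 1, ang = 1, tor = 1, GBerne = 1, polGB = 1,
    pol = 1, caviso = 1, cavtail = 1, vdw = 1, eel = 1)
}

energy_term_names <- function() {
  c("bond", "ang", "tor", "GBerne", "polGB", "pol",
    "caviso", "cavtail", "vdw", "eel")
}

#' @export
print.cg_params <- function(x, ...) {
  cat("SUGRES-1P coarse-grained parameters\n")
  cat(sprintf("  tails : sigma0 %.3g A, eps %.3g kcal/mol, chi %.3g / %.3g\n",
              x$sigma0_tail, x$eps_tail, x$chi_gb, x$chi_gb_prime))
  cat(sprintf("  heads : sigma' %.3g A, eps' %.3g kcal/mol, Born a %.3g A\n",
              x$sigma_head, x$eps_head, x$born_radius))
  cat(sprintf("  dielectrics: eps_in %.3g, eps_out %.3g; kappa %.3g 1/A\n",
              x$eps_in, x$eps_out, x$kappa))
  cat(sprintf("  bonded: d0 %.3g A (k %.3g), theta0 %.3g deg (k %.3g), k_tor %.3g\n",
              x$d0, x$k_bond, x$theta0, x$k_angle, x$k_tor))
  cat(sprintf("  T %.4g K (T0 %.4g K), offsets %+.2f / %+.2f A, mass %.3g amu\n",
              x$temperature, x$T0, x$head_offset, x$tail_offset, x$site_mass))
  w <- x$weights
  cat("  weights:", paste(sprintf("%s=%g", names(w), w), collapse = " "), "\n")
  invisible(x)
}

validate_params <- function(p) {
  stopifnot(inherits(p, "cg_params") || is.list(p))
  pos <- c("sigma0_tail", "eps_tail", "sigma_head", "eps_head", "born_radius",
           "eps_in", "eps_out", "sigma_iso", "cav_width", "d0", "site_mass")
  for (f in pos) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1L || !is.finite(p[[f]]) || p[[f]] <= 0) {
      stop("parameter '", f, "' must be a single positive number", call. = FALSE)
    }
  }
  if (p$eps_out <= p$eps_in) {
    stop("eps_out must exceed eps_in (solvent more polarizable than the particle interior)",
         call. = FALSE)
  }
  if (p$kappa < 0) stop("kappa must be >= 0", call. = FALSE)
  if (p$temperature <= 0) stop("temperature must be > 0", call. = FALSE)
  if (p$T0 <= 0) stop("T0 must be > 0", call. = FALSE)
  if (abs(p$chi_gb) >= 1 || abs(p$chi_gb_prime) >= 1 || abs(p$chi_cav_2) >= 1) {
    stop("anisotropy couplings must lie in (-1, 1)", call. = FALSE)
  }
  w <- p$weights
  if (!is.numeric(w) || is.null(names(w)) ||
      !setequal(names(w), energy_term_names())) {
    stop("weights must be a named numeric vector covering: ",
         paste(energy_term_names(), collapse = ", "), call. = FALSE)
  }
  if (any(w < 0)) stop("weights must be >= 0", call. = FALSE)
  if (length(p$charge_split) != 2L || abs(sum(p$charge_split) + 4) > 1e-9) {
    stop("charge_split must contain two per-residue charges summing to -4 e",
         call. = FALSE)
  }
  invisible(p)
}

#' Read / write a flat key-value parameter file
#'
#' The on-disk schema is one `key = value` pair per line (`#` comments
#' allowed); `weights.<term>` keys address individual energy-term weights and
#' `charge_split.1` / `charge_split.2` the per-residue charges.  All units as
#' in [cg_params()].  Keys absent from the file keep their defaults.
#'
#' @param path File path.
#' @param params A `cg_params` object (for writing).
#' @return `read_params()` returns a validated `cg_params` object;
#'   `write_params()` returns `path` invisibly.
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  p <- cg_params()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("malformed parameter line: '", ln, "'", call. = FALSE)
    key <- trimws(kv[1]); val <- suppressWarnings(as.numeric(trimws(kv[2])))
    if (is.na(val)) stop("non-numeric value for key '", key, "'", call. = FALSE)
    if (startsWith(key, "weights.")) {
      term <- sub("^weights\\.", "", key)
      if (!term %in% energy_term_names()) stop("unknown weight key: ", key, call. = FALSE)
      p$weights[[term]] <- val
    } else if (startsWith(key, "charge_split.")) {
      i <- as.integer(sub("^charge_split\\.", "", key))
      p$charge_split[i] <- val
    } else if (key %in% names(p)) {
      p[[key]] <- val
    } else {
      stop("unknown parameter key: ", key, call. = FALSE)
    }
  }
  validate_params(p)
  p
}

#' @rdname read_params
#' @export
write_params <- function(params, path) {
  validate_params(params)
  scal <- setdiff(names(params), c("weights", "charge_split"))
  lines <- c(
    "# SUGRES-1P parameter file (A, kcal/mol, e, K)",
    sprintf("%s = %.12g", scal, unlist(params[scal])),
    sprintf("weights.%s = %.12g", names(params$weights), params$weights),
    sprintf("charge_split.%d = %.12g", 1:2, params$charge_split)
  )
  writeLines(lines, path)
  invisible(path)
}

# flatten for the C++ kernel: scalars only, weights appended by name
params_for_kernel <- function(p) {
  list(
    sigma0_tail = p$sigma0_tail, eps_tail = p$eps_tail,
    chi_gb = p$chi_gb, chi_gb_prime = p$chi_gb_prime,
    sigma_head = p$sigma_head, eps_head = p$eps_head,
    born_radius = p$born_radius, eps_in = p$eps_in, eps_out = p$eps_out,
    alpha1 = p$alpha1, alpha2 = p$alpha2,
    chi_cav_1 = p$chi_cav_1, chi_cav_2 = p$chi_cav_2,
    sigma_iso = p$sigma_iso, eps_cav_iso = p$eps_cav_iso,
    eps_cav_tail = p$eps_cav_tail, cav_width = p$cav_width,
    kappa = p$kappa,
    weights = as.numeric(p$weights[energy_term_names()]),
    temperature = p$temperature, T0 = p$T0,
    d0 = p$d0, k_bond = p$k_bond,
    theta0 = p$theta0, k_angle = p$k_angle,
    k_tor = p$k_tor, gamma0 = p$gamma0,
    head_offset = p$head_offset, tail_offset = p$tail_offset,
    site_mass = p$site_mass, exclude_near = as.integer(p$exclude_near)
  )
}
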