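#' Harmonic frequency set
#'
#' Wavenumbers of the harmonic normal modes of one structure, with an
#' optional global scale factor (default 1: unscaled frequencies are used
#' throughout unless the user requests otherwise).
#'
#' @param frequencies numeric vector of wavenumbers, cm^-1. Negative
#'   entries denote imaginary modes.
#' @param scale_factor multiplicative scaling applied to every mode.
#' @param drop_imaginary if `TRUE`, imaginary (negative) modes are removed
#'   with a warning instead of raising an error.
#' @return object of class `"frequency_set"`.
#' @export
frequency_set <- function(frequencies, scale_factor = 1,
                          drop_imaginary = FALSE) {
  frequencies <- as.numeric(frequencies)
  stopifnot(is.numeric(scale_factor), length(scale_factor) == 1L,
            scale_factor > 0)
  if (any(frequencies <= 0)) {
    n_im <- sum(frequencies <= 0)
    if (!drop_imaginary)
      stop(n_im, " imaginary/zero frequencies present; a minimum should ",
           "have none (use drop_imaginary = TRUE to discard them)")
    warning("dropping ", n_im, " imaginary/zero frequencies")
    frequencies <- frequencies[frequencies > 0]
  }
  obj <- list(frequencies = frequencies, scale_factor = scale_factor)
  class(obj) <- "frequency_set"
  obj
}

#' @export
print.frequency_set <- function(x, ...) {
  cat(sprintf("<frequency_set> %d modes", length(x$frequencies)))
  if (length(x$frequencies))
    cat(sprintf(", %.0f-%.0f cm^-1", min(x$frequencies), max(x$frequencies)))
  if (x$scale_factor != 1) cat(sprintf(", scale %.4f", x$scale_factor))
  cat("\n")
  invisible(x)
}

#' Check that a frequency set has the right mode count for a structure
#'
#' Nonlinear molecules have 3N-6 modes, linear ones 3N-5, atoms none.
#'
#' @param f a [frequency_set()].
#' @param s the corresponding `xyz_structure`.
#' @return `f`, invisibly; errors on a count mismatch.
#' @export
validate_mode_count <- function(f, s) {
  rot <- rotational_constants(s)
  expected <- switch(rot$linearity,
                     atom = 0L,
                     linear = 3L * n_atoms(s) - 5L,
                     nonlinear = 3L * n_atoms(s) - 6L)
  if (length(f$frequencies) != expected)
    stop(sprintf("expected %d modes for a %s with %d atoms, got %d",
                 expected, rot$linearity, n_atoms(s), length(f$frequencies)))
  invisible(f)
}

#' Harmonic zero-point vibrational energy
#'
#' Half the sum of the (scaled) mode energies, ZPE = sum(h c nu_i) / 2.
#'
#' @param f a [frequency_set()].
#' @return ZPE in hartree (0 for an empty mode set).
#' @export
zero_point_energy <- function(f) {
  stopifnot(inherits(f, "frequency_set"))
  if (!length(f$frequencies)) return(0)
  nu <- f$frequencies * f$scale_factor
  sum(codata2018$h * codata2018$c_cm * nu) / 2 / codata2018$hartree_J
}

#' Rotational constants from the inertia tensor
#'
#' Diagonalises the moment-of-inertia tensor about the centre of mass and
#' converts the principal moments to rotational constants; classifies the
#' structure as atom, linear or nonlinear.
#'
#' @param s an `xyz_structure`.
#' @param masses atomic masses in u (defaults to standard atomic weights).
#' @return list with `constants_GHz` (descending; length 0 for an atom, 2
#'   for a linear molecule), `moments_amuA2` (principal moments, u
#'   Angstrom^2) and `linearity` (`"atom"`, `"linear"`, `"nonlinear"`).
#' @export
rotational_constants <- function(s, masses = atomic_mass(s$elements)) {
  stopifnot(inherits(s, "xyz_structure"), length(masses) == n_atoms(s))
  if (n_atoms(s) == 1L)
    return(list(constants_GHz = numeric(0), moments_amuA2 = numeric(0),
                linearity = "atom"))
  com <- colSums(s$coords * masses) / sum(masses)
  r <- sweep(s$coords, 2, com)
  Ixx <- sum(masses * (r[, 2]^2 + r[, 3]^2))
  Iyy <- sum(masses * (r[, 1]^2 + r[, 3]^2))
  Izz <- sum(masses * (r[, 1]^2 + r[, 2]^2))
  Ixy <- -sum(masses * r[, 1] * r[, 2])
  Ixz <- -sum(masses * r[, 1] * r[, 3])
  Iyz <- -sum(masses * r[, 2] * r[, 3])
  I <- matrix(c(Ixx, Ixy, Ixz, Ixy, Iyy, Iyz, Ixz, Iyz, Izz), 3, 3)
  mom <- sort(eigen(I, symmetric = TRUE, only.values = TRUE)$values) # u A^2
  linear <- mom[1] < 1e-6 * max(mom[3], 1)
  mom_SI <- mom * codata2018$amu * 1e-20                            # kg m^2
  B_GHz <- codata2018$h / (8 * pi^2 * mom_SI) / 1e9
  # moments ascend, so the constants B = h / (8 pi^2 I) already descend
  if (linear) {
    list(constants_GHz = B_GHz[2:3], moments_amuA2 = mom[2:3],
         linearity = "linear")
  } else {
    list(constants_GHz = B_GHz, moments_amuA2 = mom,
         linearity = "nonlinear")
  }
}

#' Rigid-rotor harmonic-oscillator thermochemistry
#'
#' Ideal-gas statistical thermodynamics of a single structure: translation
#' at pressure `P`, classical rigid rotor with symmetry number `sigma`,
#' harmonic vibrations with the zero-point energy separated out, and an
#' electronic degeneracy factor. The enthalpy is
#' H = E_elec + ZPE + E_thermal + RT and G = H - T S identically.
#'
#' All energies are in hartree and entropies in hartree/K; use
#' [convert_energy()] for kcal/mol or kJ/mol.
#'
#' @param s an `xyz_structure` with its electronic energy set.
#' @param f a [frequency_set()] with the 3N-6 (3N-5, 0) modes of `s`.
#' @param T temperature, K (> 0).
#' @param P pressure, atm. The 1 atm ideal-gas standard state is used for
#'   every species, gas-phase and continuum-embedded alike; no 1 atm to
#'   1 mol/L correction is applied unless requested via `standard_state`.
#' @param sigma rotational symmetry number (default 1: cluster structures
#'   are asymmetric; set e.g. 2 for the water monomer).
#' @param g_elec electronic (spin) degeneracy of the ground state.
#' @param masses atomic masses in u.
#' @param standard_state `"1atm"` (default) or `"1M"`; the latter adds the
#'   R T ln(24.46) gas-to-solution concentration correction to G.
#' @return object of class `"thermo_record"`: list with `T`, `P`, `E_elec`,
#'   `ZPE`, `H`, `S`, `G`, `sigma` (energies hartree, `S` hartree/K).
#' @export
rrho_thermo <- function(s, f, T = 298.15, P = 1, sigma = 1, g_elec = 1,
                        masses = atomic_mass(s$elements),
                        standard_state = c("1atm", "1M")) {
  stopifnot(inherits(s, "xyz_structure"), inherits(f, "frequency_set"),
            T > 0, P > 0, sigma >= 1)
  standard_state <- match.arg(standard_state)
  if (is.na(s$energy)) stop("structure has no electronic energy")
  validate_mode_count(f, s)
  cst <- codata2018
  kT <- cst$kB * T

  # translation (Sackur-Tetrode)
  m <- sum(masses) * cst$amu
  q_t <- (2 * pi * m * kT / cst$h^2)^1.5 * kT / (P * cst$atm_Pa)
  S_t <- cst$R * (log(q_t) + 1 + 1.5)
  E_t <- 1.5 * cst$R * T

  # rotation
  rot <- rotational_constants(s, masses)
  if (rot$linearity == "atom") {
    S_r <- 0; E_r <- 0
  } else {
    theta <- cst$h * rot$constants_GHz * 1e9 / cst$kB  # K
    if (rot$linearity == "linear") {
      q_r <- T / (sigma * theta[1])
      S_r <- cst$R * (log(q_r) + 1)
      E_r <- cst$R * T
    } else {
      q_r <- sqrt(pi) / sigma * sqrt(T^3 / prod(theta))
      S_r <- cst$R * (log(q_r) + 1.5)
      E_r <- 1.5 * cst$R * T
    }
  }

  # vibrations (harmonic oscillator, ZPE separated)
  nu <- f$frequencies * f$scale_factor
  if (length(nu)) {
    x <- cst$h * cst$c_cm * nu / kT
    E_v <- cst$R * T * sum(x / expm1(x))
    S_v <- cst$R * sum(x / expm1(x) - log(-expm1(-x)))
  } else {
    E_v <- 0; S_v <- 0
  }

  S_e <- cst$R * log(g_elec)
  to_hartree <- 1 / (cst$hartree_J * cst$N_A)  # J/mol -> hartree

  zpe <- zero_point_energy(f)
  H <- s$energy + zpe + (E_t + E_r + E_v + cst$R * T) * to_hartree
  S <- (S_t + S_r + S_v + S_e) * to_hartree
  G <- H - T * S
  if (standard_state == "1M")
    G <- G + cst$R * T * log(24.46) * to_hartree
  obj <- list(T = T, P = P, E_elec = s$energy, ZPE = zpe,
              H = H, S = S, G = G, sigma = sigma, phase = s$phase,
              label = s$label)
  class(obj) <- "thermo_record"
  obj
}

#' @export
print.thermo_record <- function(x, ...) {
  cat(sprintf(
    "<thermo_record> %s T=%.2f K P=%g atm\n  E_elec=%.6f  ZPE=%.6f  H=%.6f  G=%.6f hartree\n  S=%.2f J/(mol K)\n",
    if (nzchar(x$label)) x$label else "(unlabelled)", x$T, x$P,
    x$E_elec, x$ZPE, x$H, x$G,
    x$S * codata2018$hartree_J * codata2018$N_A))
  invisible(x)
}

#' Thermochemistry over a temperature grid
#'
#' @inheritParams rrho_thermo
#' @param T_grid strictly increasing temperatures, K, all > 0.
#' @param ... passed on to [rrho_thermo()].
#' @return data.frame with one row per temperature and columns `T`, `H`,
#'   `S`, `G`, `ZPE`, `E_elec` (hartree scale), plus the full records in
#'   attribute `"records"`.
#' @export
thermo_scan <- function(s, f, T_grid, P = 1, sigma = 1, ...) {
  stopifnot(all(T_grid > 0), !is.unsorted(T_grid, strictly = TRUE))
  recs <- lapply(T_grid, function(Ti) rrho_thermo(s, f, Ti, P, sigma, ...))
  out <- data.frame(
    T = T_grid,
    H = vapply(recs, `[[`, numeric(1), "H"),
    S = vapply(recs, `[[`, numeric(1), "S"),
    G = vapply(recs, `[[`, numeric(1), "G"),
    ZPE = vapply(recs, `[[`, numeric(1), "ZPE"),
    E_elec = vapply(recs, `[[`, numeric(1), "E_elec"))
  attr(out, "records") <- recs
  out
}
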