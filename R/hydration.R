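# Cluster-continuum hydration thermodynamics: the hydration enthalpy and
# free energy of imidazole are the reaction quantities of
#   IMZ(gas) + (H2O)_n(aq)  ->  IMZ(H2O)_n(aq)
# evaluated per explicit-water count n, followed by convergence analysis
# in n and a temperature scan.

.leg_HGT <- function(x, what) {
  if (inherits(x, "cluster_ensemble"))
    return(list(H = x$H_avg, G = x$G_avg, T = x$T, phase = x$phase))
  if (inherits(x, "thermo_record") || is.list(x)) {
    need <- c("H", "G", "T")
    if (!all(need %in% names(x)))
      stop(what, " must carry H, G and T")
    return(list(H = x$H, G = x$G, T = x$T,
                phase = if (!is.null(x$phase)) x$phase else NA_character_))
  }
  stop(what, " must be a cluster_ensemble, thermo_record, or list")
}

#' Hydration enthalpy and free energy at one cluster size
#'
#' Delta H_solv(n) = H[IMZ(H2O)n]_water - H[(H2O)n]_water - H[IMZ]_gas
#' (and the same for G), with the solvated legs entering as
#' Boltzmann-weighted ensemble averages. Results are reported in kJ/mol.
#'
#' @param imzw_solv solvated imidazole-water leg: a [cluster_ensemble()]
#'   (its `H_avg`/`G_avg` are used) or anything carrying `H`, `G`, `T`,
#'   `phase`.
#' @param waters_solv solvated water-cluster leg, same forms.
#' @param imz_gas gas-phase imidazole leg (typically a `thermo_record`).
#' @param check_phase verify the solvent/gas phase tags of the legs.
#' @return named vector `c(dH, dG)` in kJ/mol.
#' @export
hydration_deltas <- function(imzw_solv, waters_solv, imz_gas,
                             check_phase = TRUE) {
  a <- .leg_HGT(imzw_solv, "imzw_solv")
  b <- .leg_HGT(waters_solv, "waters_solv")
  c_ <- .leg_HGT(imz_gas, "imz_gas")
  Ts <- c(a$T, b$T, c_$T)
  if (diff(range(Ts)) > 1e-6)
    stop(sprintf("temperature mismatch between legs: %s",
                 paste(format(Ts), collapse = ", ")))
  if (check_phase) {
    if (identical(a$phase, "gas") || identical(b$phase, "gas"))
      stop("solvated legs are tagged gas-phase")
    if (identical(c_$phase, "solvent"))
      stop("the isolated imidazole leg must be gas-phase")
  }
  c(dH = convert_energy(a$H - b$H - c_$H, "hartree", "kJ/mol"),
    dG = convert_energy(a$G - b$G - c_$G, "hartree", "kJ/mol"))
}

#' Hydration profile over cluster sizes
#'
#' Container for Delta H_solv(n) and Delta G_solv(n) at one temperature,
#' with the stable ranges used for the converged estimates. The default
#' ranges are n = 5-7 for the enthalpy and n = 3-7 for the free energy,
#' the windows in which the respective profiles are flat.
#'
#' @param n_values cluster sizes (sorted ascending internally).
#' @param dH,dG hydration enthalpy/free energy per size, kJ/mol.
#' @param T temperature, K.
#' @param range_H,range_G inclusive n-ranges for the stable-range
#'   averages (clipped to the available sizes; empty clip is an error at
#'   estimate time, not construction time).
#' @return object of class `"hydration_profile"`.
#' @export
hydration_profile <- function(n_values, dH, dG, T = 298.15,
                              range_H = 5:7, range_G = 3:7) {
  stopifnot(length(n_values) == length(dH), length(dH) == length(dG))
  ord <- order(n_values)
  obj <- list(n_values = as.integer(n_values[ord]),
              dH = dH[ord], dG = dG[ord], T = T,
              range_H = range_H, range_G = range_G)
  obj$estimates <- tryCatch(stable_range_average(obj),
                            error = function(e) c(dH_hyd = NA_real_,
                                                  dG_hyd = NA_real_))
  class(obj) <- "hydration_profile"
  obj
}

#' @export
print.hydration_profile <- function(x, ...) {
  cat(sprintf("<hydration_profile> T = %.2f K, n = %s\n", x$T,
              paste(range(x$n_values), collapse = "-")))
  print(data.frame(n = x$n_values, dH_kJmol = round(x$dH, 2),
                   dG_kJmol = round(x$dG, 2)), row.names = FALSE)
  if (!anyNA(x$estimates))
    cat(sprintf(
      "  dH_hyd = %.1f kJ/mol (mean over n = %d-%d), dG_hyd = %.1f kJ/mol (n = %d-%d)\n",
      x$estimates["dH_hyd"], min(x$range_H), max(x$range_H),
      x$estimates["dG_hyd"], min(x$range_G), max(x$range_G)))
  invisible(x)
}

#' @export
plot.hydration_profile <- function(x, ...) {
  graphics::matplot(x$n_values, cbind(x$dH, x$dG), type = "b", pch = 16,
                    lty = 1, xlab = "explicit waters n",
                    ylab = "kJ/mol", ...)
  graphics::legend("bottomleft",
                   legend = c(expression(Delta * H[solv]),
                              expression(Delta * G[solv])),
                   col = 1:2, lty = 1, pch = 16, bty = "n")
  invisible(x)
}

#' Hydration profile of a synthetic study
#'
#' Runs the full cluster-continuum machinery on a [generate_study()]
#' bundle at temperature `T`: per size, RRHO thermochemistry and Boltzmann
#' averaging of the solvated legs, then the reaction differences.
#'
#' @param study a `microhydration_study`.
#' @param T temperature, K.
#' @param n_values sizes to include (default all).
#' @param noise_sd,seed noise control for the implanted solvated leg, see
#'   [solvated_ensembles()].
#' @param ... passed to [hydration_profile()] (e.g. custom stable ranges).
#' @return a [hydration_profile()].
#' @export
hydration_from_study <- function(study, T = study$T_ref,
                                 n_values = seq_len(study$n_max),
                                 noise_sd = study$noise_solv,
                                 seed = study$seed, ...) {
  deltas <- vapply(n_values, function(n) {
    legs <- solvated_ensembles(study, n, T = T, noise_sd = noise_sd,
                               seed = seed)
    hydration_deltas(legs$imzw_solv, legs$waters_solv, legs$imz_gas)
  }, numeric(2))
  hydration_profile(n_values, deltas["dH", ], deltas["dG", ], T = T, ...)
}

.profile_values <- function(profile, quantity = c("dH", "dG")) {
  quantity <- match.arg(quantity)
  profile[[quantity]]
}

#' Variation of a hydration profile over a window
#'
#' Variation is max - min of the quantity over the inclusive n-window.
#'
#' @param profile a [hydration_profile()].
#' @param quantity `"dH"` or `"dG"`.
#' @param range n-window (default: all available sizes).
#' @return variation in kJ/mol.
#' @export
profile_variation <- function(profile, quantity = c("dH", "dG"),
                              range = profile$n_values) {
  v <- .profile_values(profile, quantity)
  keep <- profile$n_values %in% range
  if (!any(keep)) stop("window contains no available sizes")
  max(v[keep]) - min(v[keep])
}

#' Convergence metrics of a hydration profile
#'
#' Overall variation (max - min over all sizes) of both quantities, the
#' variation over each profile's stable range, and a suggested stable
#' range per quantity: the longest window ending at the largest size
#' whose variation stays below `tol`.
#'
#' @param profile a [hydration_profile()].
#' @param tol plateau tolerance for the suggested ranges, kJ/mol.
#' @return list with `overall` (named vector, kJ/mol), `stable`
#'   (variation over the profile's own ranges) and `suggested_range`
#'   (list of n-vectors per quantity).
#' @export
convergence_profile <- function(profile, tol = 2.5) {
  stopifnot(length(profile$n_values) >= 2L)
  overall <- c(dH = profile_variation(profile, "dH"),
               dG = profile_variation(profile, "dG"))
  in_range_var <- function(q, rng) {
    rng <- intersect(rng, profile$n_values)
    if (!length(rng)) return(NA_real_)
    profile_variation(profile, q, rng)
  }
  stable <- c(dH = in_range_var("dH", profile$range_H),
              dG = in_range_var("dG", profile$range_G))
  suggest <- lapply(c(dH = "dH", dG = "dG"), function(q) {
    v <- .profile_values(profile, q)
    nn <- profile$n_values
    last <- length(nn)
    start <- last
    while (start > 1L &&
           max(v[(start - 1L):last]) - min(v[(start - 1L):last]) <= tol)
      start <- start - 1L
    nn[start:last]
  })
  list(overall = overall, stable = stable, suggested_range = suggest)
}

#' Stable-range averages: the converged hydration estimates
#'
#' Plain arithmetic means of Delta H_solv(n) over `range_H` and of
#' Delta G_solv(n) over `range_G`.
#'
#' @param profile a [hydration_profile()].
#' @param range_H,range_G inclusive n-ranges (default: the profile's own,
#'   i.e. 5-7 for H and 3-7 for G).
#' @return named vector `c(dH_hyd, dG_hyd)`, kJ/mol.
#' @export
stable_range_average <- function(profile, range_H = profile$range_H,
                                 range_G = profile$range_G) {
  kH <- profile$n_values %in% range_H
  kG <- profile$n_values %in% range_G
  if (!any(kH) || !any(kG))
    stop("stable range lies outside the available sizes")
  c(dH_hyd = mean(profile$dH[kH]), dG_hyd = mean(profile$dG[kG]))
}

#' Temperature dependence of the hydration estimates
#'
#' Re-evaluates the hydration profile of a study over a temperature grid
#' and reports the converged estimates per temperature, the linear-fit
#' slope of Delta G_hyd(T) (an entropy read-out: slope = -dS_hyd), and
#' the bracketing temperatures of any sign change of Delta G_hyd.
#'
#' @param study a `microhydration_study`.
#' @param T_grid strictly increasing temperatures, K.
#' @param ... passed to [hydration_from_study()].
#' @return object of class `"hydration_scan"`: list with `table`
#'   (data.frame T, dH_hyd, dG_hyd), `dG_fit` (intercept, slope from
#'   `lm`), `dH_range` (max - min of dH_hyd over the scan) and
#'   `sign_change` (c(T_lo, T_hi) bracketing dG_hyd = 0, or NULL).
#' @export
temperature_scan <- function(study, T_grid = seq(200, 400, by = 20),
                             ...) {
  stopifnot(!is.unsorted(T_grid, strictly = TRUE), all(T_grid > 0))
  est <- vapply(T_grid, function(Ti) {
    hydration_from_study(study, T = Ti, ...)$estimates
  }, numeric(2))
  tab <- data.frame(T = T_grid, dH_hyd = est["dH_hyd", ],
                    dG_hyd = est["dG_hyd", ])
  fit <- stats::lm(dG_hyd ~ T, data = tab)
  sc <- NULL
  sgn <- sign(tab$dG_hyd)
  flip <- which(diff(sgn) != 0 & sgn[-length(sgn)] != 0)
  if (length(flip))
    sc <- c(T_lo = tab$T[flip[1]], T_hi = tab$T[flip[1] + 1L])
  obj <- list(table = tab, dG_fit = stats::coef(fit),
              dH_range = max(tab$dH_hyd) - min(tab$dH_hyd),
              sign_change = sc)
  class(obj) <- "hydration_scan"
  obj
}

#' @export
print.hydration_scan <- function(x, ...) {
  cat(sprintf(
    "<hydration_scan> T = %g-%g K (%d points)\n  dG_hyd(T): intercept %.2f kJ/mol, slope %.4f kJ/(mol K)\n  dH_hyd spread %.2f kJ/mol\n",
    min(x$table$T), max(x$table$T), nrow(x$table),
    x$dG_fit[1], x$dG_fit[2], x$dH_range))
  if (!is.null(x$sign_change))
    cat(sprintf("  dG_hyd changes sign between %g and %g K\n",
                x$sign_change["T_lo"], x$sign_change["T_hi"]))
  invisible(x)
}
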