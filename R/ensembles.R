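#' Boltzmann weights of an ensemble of conformers
#'
#' w_i proportional to exp(-(G_i - G_min)/kT), normalised to sum to one.
#' The minimum shift makes the evaluation numerically stable for any
#' energy spread. At T = 0 (allowed) all mass concentrates on the minimum;
#' degenerate minima (within `tie_tol` hartree) split equally.
#'
#' @param G numeric vector of free energies (hartree). Any consistent
#'   energy (e.g. electronic energies) may be weighted the same way.
#' @param T temperature, K (>= 0).
#' @param tie_tol degeneracy tolerance at T = 0, hartree.
#' @return numeric probability vector summing to 1.
#' @export
boltzmann_weights <- function(G, T, tie_tol = 1e-10) {
  if (!length(G)) stop("empty energy vector")
  stopifnot(T >= 0)
  if (T == 0) {
    w <- as.numeric(G <= min(G) + tie_tol)
    return(w / sum(w))
  }
  kT <- codata2018$kB_hartree * T
  w <- exp(-(G - min(G)) / kT)
  w / sum(w)
}

#' Boltzmann-weighted ensemble average
#'
#' @param values per-member scalars.
#' @param weights normalised probabilities (e.g. from
#'   [boltzmann_weights()]).
#' @return sum(w_i x_i).
#' @export
ensemble_average <- function(values, weights) {
  if (length(values) != length(weights))
    stop("values and weights differ in length")
  if (abs(sum(weights) - 1) > 1e-8)
    stop("weights are not normalised")
  sum(values * weights)
}

#' Partition-function (free-energy) ensemble aggregate
#'
#' -kT log sum_i exp(-G_i/kT), the free energy of the combined ensemble.
#' Always less than or equal to the Boltzmann-weighted mean of G (Gibbs
#' inequality); available for comparison with [ensemble_average()].
#'
#' @inheritParams boltzmann_weights
#' @return scalar, hartree.
#' @export
partition_free_energy <- function(G, T) {
  if (!length(G)) stop("empty energy vector")
  stopifnot(T > 0)
  kT <- codata2018$kB_hartree * T
  min(G) - kT * log(sum(exp(-(G - min(G)) / kT)))
}

#' Conformer ensemble of one cluster size
#'
#' Bundles the located structures of an IMZ(H2O)_n (or (H2O)_n) cluster
#' with their thermochemistry records and Boltzmann weights at the records'
#' temperature. All members must share the water count and phase.
#'
#' @param structures list of `xyz_structure`.
#' @param records list of `thermo_record`, parallel to `structures`.
#' @param weight_on `"G"` (default: free energies at the evaluation
#'   temperature) or `"E"` (electronic energies).
#' @return object of class `"cluster_ensemble"`: list with `n`, `phase`,
#'   `T`, `structures`, `records`, `weights`, and the weighted averages
#'   `H_avg`, `G_avg` (hartree).
#' @export
cluster_ensemble <- function(structures, records, weight_on = c("G", "E")) {
  weight_on <- match.arg(weight_on)
  stopifnot(length(structures) == length(records), length(structures) >= 1L)
  ns <- vapply(structures, count_waters, integer(1))
  phases <- vapply(structures, `[[`, character(1), "phase")
  Ts <- vapply(records, `[[`, numeric(1), "T")
  if (length(unique(ns)) != 1L) stop("members differ in water count")
  if (length(unique(phases)) != 1L) stop("members differ in phase")
  if (diff(range(Ts)) > 1e-9) stop("members differ in temperature")
  G <- vapply(records, `[[`, numeric(1), "G")
  H <- vapply(records, `[[`, numeric(1), "H")
  E <- vapply(records, `[[`, numeric(1), "E_elec")
  w <- boltzmann_weights(if (weight_on == "G") G else E, Ts[1])
  obj <- list(n = ns[1], phase = phases[1], T = Ts[1],
              structures = structures, records = records, weights = w,
              H_avg = ensemble_average(H, w),
              G_avg = ensemble_average(G, w))
  class(obj) <- "cluster_ensemble"
  obj
}

#' @export
print.cluster_ensemble <- function(x, ...) {
  cat(sprintf(
    "<cluster_ensemble> n=%d, %d member(s), phase=%s, T=%.2f K\n  <H>=%.6f  <G>=%.6f hartree; top weight %.3f\n",
    x$n, length(x$structures), x$phase, x$T, x$H_avg, x$G_avg,
    max(x$weights)))
  invisible(x)
}

#' Relative populations as a function of temperature
#'
#' Evaluates Boltzmann populations of the ensemble members over a
#' temperature grid and flags the members that ever exceed the reporting
#' threshold (structures below it are conventionally considered
#' negligible; default 5 percent).
#'
#' @param G member free energies: either a numeric vector (temperature-
#'   independent energies, e.g. electronic) or a members x temperatures
#'   matrix giving G at each grid point.
#' @param T_grid non-negative temperatures, K; T = 0 is handled as the
#'   limit (all mass on the minimum, ties split equally).
#' @param threshold reporting threshold on the population fraction.
#' @param labels optional member labels.
#' @return object of class `"population_curves"`: list with `T` (the
#'   grid), `population` (members x temperatures matrix), `reported`
#'   (logical: exceeds the threshold at any grid point) and `threshold`.
#' @export
population_vs_temperature <- function(G, T_grid, threshold = 0.05,
                                      labels = NULL) {
  stopifnot(all(T_grid >= 0), length(T_grid) >= 1L)
  if (is.matrix(G)) {
    stopifnot(ncol(G) == length(T_grid))
  } else {
    G <- matrix(G, nrow = length(G), ncol = length(T_grid))
  }
  pop <- vapply(seq_along(T_grid), function(j) {
    boltzmann_weights(G[, j], T_grid[j])
  }, numeric(nrow(G)))
  pop <- matrix(pop, nrow = nrow(G))
  if (is.null(labels)) labels <- paste0("member_", seq_len(nrow(G)))
  rownames(pop) <- labels
  colnames(pop) <- T_grid
  obj <- list(T = T_grid, population = pop,
              reported = apply(pop >= threshold, 1, any),
              threshold = threshold)
  class(obj) <- "population_curves"
  obj
}

#' @export
print.population_curves <- function(x, ...) {
  cat(sprintf(
    "<population_curves> %d member(s) over T = %g-%g K; %d above the %.0f%% threshold\n",
    nrow(x$population), min(x$T), max(x$T), sum(x$reported),
    100 * x$threshold))
  invisible(x)
}

#' @export
plot.population_curves <- function(x, ...) {
  keep <- which(x$reported)
  if (!length(keep)) keep <- seq_len(nrow(x$population))
  graphics::matplot(x$T, t(x$population[keep, , drop = FALSE]), type = "l",
                    lty = 1, xlab = "T (K)", ylab = "population fraction",
                    ...)
  graphics::abline(h = x$threshold, lty = 3)
  graphics::legend("topright", legend = rownames(x$population)[keep],
                   col = seq_along(keep), lty = 1, cex = 0.8, bty = "n")
  invisible(x)
}
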