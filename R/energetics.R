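#' Energy ladder over cluster sizes
#'
#' Total energies (electronic or enthalpy) of the IMZ(H2O)_n clusters
#' together with the isolated imidazole and water monomer energies, the
#' inputs for binding and incremental clustering energies.
#'
#' @param n_values cluster sizes (unique; stored sorted).
#' @param E_n energy per size, parallel to `n_values`.
#' @param E_water water monomer energy.
#' @param E_imz imidazole monomer energy.
#' @param unit `"hartree"`, `"kcal/mol"` or `"kJ/mol"` (one tag for every
#'   field).
#' @param quantity `"electronic"` or `"enthalpy"`.
#' @return object of class `"energy_ladder"`.
#' @export
energy_ladder <- function(n_values, E_n, E_water, E_imz,
                          unit = "hartree",
                          quantity = c("electronic", "enthalpy")) {
  quantity <- match.arg(quantity)
  unit <- match.arg(unit, c("hartree", "kcal/mol", "kJ/mol"))
  stopifnot(length(n_values) == length(E_n),
            !anyDuplicated(n_values),
            is.finite(E_water), is.finite(E_imz), all(is.finite(E_n)))
  ord <- order(n_values)
  obj <- list(n_values = as.integer(n_values[ord]), E_n = E_n[ord],
              E_water = E_water, E_imz = E_imz,
              unit = unit, quantity = quantity)
  class(obj) <- "energy_ladder"
  obj
}

.ladder_E <- function(ladder, n) {
  if (n == 0L) return(ladder$E_imz)
  i <- match(n, ladder$n_values)
  if (is.na(i)) stop("no energy for cluster size n = ", n)
  ladder$E_n[i]
}

#' Binding energy of the n-water cluster
#'
#' Delta E_n = E_n - E(IMZ) - n E(H2O); negative for bound clusters.
#'
#' @param ladder an [energy_ladder()].
#' @param n cluster size(s) present in the ladder.
#' @return binding energy/energies in the ladder's unit.
#' @export
binding_energy <- function(ladder, n = ladder$n_values) {
  stopifnot(inherits(ladder, "energy_ladder"))
  vapply(n, function(ni) {
    .ladder_E(ladder, ni) - ladder$E_imz - ni * ladder$E_water
  }, numeric(1))
}

#' Incremental clustering energy
#'
#' Energy change on adding one water to the (n-1)-cluster,
#' Delta E_n = E_n - E_(n-1) - E(H2O), with E_0 taken as E(IMZ) so the
#' increments telescope exactly to the binding energy.
#'
#' @inheritParams binding_energy
#' @return incremental energy/energies in the ladder's unit.
#' @export
incremental_energy <- function(ladder, n = ladder$n_values) {
  stopifnot(inherits(ladder, "energy_ladder"))
  vapply(n, function(ni) {
    if (ni >= 2L && !(ni - 1L) %in% ladder$n_values)
      stop("missing predecessor size n = ", ni - 1L)
    .ladder_E(ladder, ni) - .ladder_E(ladder, ni - 1L) - ladder$E_water
  }, numeric(1))
}

#' Relative energies within one cluster size
#'
#' Offsets of the member energies from the lowest one, in input order.
#'
#' @param values member energies (any single unit).
#' @param convert optional unit conversion applied to the offsets, e.g.
#'   `c("hartree", "kcal/mol")`.
#' @return non-negative offsets, minimum exactly 0.
#' @export
relative_energies <- function(values, convert = NULL) {
  if (!length(values)) stop("empty energy vector")
  off <- values - min(values)
  if (!is.null(convert)) off <- convert_energy(off, convert[1], convert[2])
  off
}
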