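# Classical rigid-body energy: point-charge Coulomb plus Lennard-Jones,
# inter-fragment pairs only (fragments are rigid, so intra-fragment terms
# are constant and excluded).

.COULOMB_KCAL <- 332.06371  # kcal mol^-1 Angstrom e^-2

# per-atom charge/eps/sigma for a structure whose fragments are all
# water or imidazole, matched to the templates via element/role identity
.site_params <- function(s, f, params = ff_params()) {
  n <- n_atoms(s)
  out <- data.frame(charge = numeric(n), eps = numeric(n),
                    sigma = numeric(n))
  for (fid in seq_along(f$formulas)) {
    atoms <- which(f$fragment_ids == fid)
    if (f$formulas[fid] == "H2O") {
      o <- atoms[s$elements[atoms] == "O"]
      h <- atoms[s$elements[atoms] == "H"]
      out[o, ] <- params$water[1, ]
      out[h, ] <- params$water[2:3, ][seq_along(h), ]
    } else if (f$formulas[fid] == "C3H4N2") {
      roles <- label_imidazole(s, f)
      h_on <- function(a) which(f$adjacency[a, ] & s$elements == "H")[1]
      idx <- c(roles$N1, roles$C2, roles$N3, roles$C4, roles$C5,
               roles$H_N1, h_on(roles$C2), h_on(roles$C4), h_on(roles$C5))
      out[idx, ] <- params$imidazole
    } else {
      stop("no force-field parameters for fragment ", f$formulas[fid])
    }
  }
  out
}

# vectorised pair energy over precomputed inter-body pair lists
.pair_energy <- function(coords, pp) {
  dx <- coords[pp$i, , drop = FALSE] - coords[pp$j, , drop = FALSE]
  r2 <- rowSums(dx * dx)
  if (any(r2 < 1e-6)) return(Inf)
  r <- sqrt(r2)
  sr6 <- (pp$sig / r)^6
  sum(pp$qq / r) + sum(4 * pp$eps * (sr6 * sr6 - sr6))
}

.make_pairs <- function(body, charge, eps, sigma) {
  m <- length(body)
  pr <- which(outer(body, body, "!=") & upper.tri(matrix(0, m, m)),
              arr.ind = TRUE)
  i <- pr[, 1]; j <- pr[, 2]
  list(i = i, j = j,
       qq = .COULOMB_KCAL * charge[i] * charge[j],
       eps = sqrt(eps[i] * eps[j]),
       sig = (sigma[i] + sigma[j]) / 2)
}

#' Classical Lennard-Jones + Coulomb energy of a rigid cluster
#'
#' Sum over all inter-fragment site pairs of the Coulomb term
#' q_i q_j / (4 pi eps0 r) and the 12-6 Lennard-Jones term with
#' Lorentz-Berthelot combination; intra-fragment terms are excluded
#' (fragments are rigid). This is the potential driving the configuration
#' sampler; only electrostatic and dispersion/repulsion physics enters.
#'
#' @param s an `xyz_structure` whose fragments are waters and at most one
#'   imidazole.
#' @param params force-field parameters, see [ff_params()].
#' @param f precomputed fragments of `s`.
#' @return energy in kcal/mol (0 for a single fragment).
#' @export
classical_energy <- function(s, params = ff_params(),
                             f = perceive_fragments(s)) {
  sp <- .site_params(s, f, params)
  pp <- .make_pairs(f$fragment_ids, sp$charge, sp$eps, sp$sigma)
  if (!length(pp$i)) return(0)
  d <- s$coords[pp$i, , drop = FALSE] - s$coords[pp$j, , drop = FALSE]
  if (any(rowSums(d * d) < 1e-6))
    stop("singular configuration: overlapping sites (r < 1e-3 Angstrom)")
  .pair_energy(s$coords, pp)
}
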