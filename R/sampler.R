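# Rigid-body configuration sampler: seeded basin hopping with an elitist
# pool. Emulates the role of a swarm-based global cluster optimiser --
# producing a diverse set of low-energy candidate geometries on the
# classical LJ+Coulomb surface -- at desk scale. Moves are rigid-body
# translations and rotations of single waters; the solute stays at the
# origin.

#' Sampler configuration
#'
#' @param n_waters number of water molecules to place (>= 0).
#' @param pool elitist pool size (number of candidate structures kept).
#' @param iterations basin-hopping perturbation cycles.
#' @param maxit_local iteration cap of each local minimisation.
#' @param seed integer seed fixing the full random stream.
#' @return object of class `"sampler_config"`.
#' @export
sampler_config <- function(n_waters, pool = 6, iterations = 30,
                           maxit_local = 40, seed = 1) {
  stopifnot(n_waters >= 0, pool >= 1, iterations >= 0, maxit_local >= 1)
  obj <- list(n_waters = as.integer(n_waters), pool = as.integer(pool),
              iterations = as.integer(iterations),
              maxit_local = as.integer(maxit_local),
              seed = as.integer(seed))
  class(obj) <- "sampler_config"
  obj
}

.euler_rotation <- function(a) {
  ca <- cos(a[1]); sa <- sin(a[1])
  cb <- cos(a[2]); sb <- sin(a[2])
  cc <- cos(a[3]); sc <- sin(a[3])
  Rx <- matrix(c(1, 0, 0, 0, ca, sa, 0, -sa, ca), 3, 3)
  Ry <- matrix(c(cb, 0, -sb, 0, 1, 0, sb, 0, cb), 3, 3)
  Rz <- matrix(c(cc, sc, 0, -sc, cc, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

# solute template ("imidazole", "water", or "none") for the sampler
.solute_template <- function(solute) {
  switch(solute,
         imidazole = imidazole_template(),
         water = water_template(),
         none = NULL,
         stop("unknown solute '", solute, "'"))
}

# assemble the full-site coordinate matrix from a 6-DOF-per-water pose
# vector; solute sites first (fixed at the origin frame)
.pose_coords <- function(par, solute_coords, water_coords) {
  n_w <- length(par) / 6L
  pieces <- vector("list", n_w + 1L)
  pieces[[1L]] <- solute_coords
  for (w in seq_len(n_w)) {
    p <- par[(6 * (w - 1) + 1):(6 * w)]
    R <- .euler_rotation(p[4:6])
    pieces[[w + 1L]] <- sweep(water_coords %*% t(R), 2, -p[1:3])
  }
  do.call(rbind, pieces)
}

#' Build an `xyz_structure` from rigid-body water poses
#'
#' @param par pose vector, 6 values per water (tx, ty, tz then three
#'   Euler angles).
#' @param solute `"imidazole"`, `"water"` (a fixed water at the origin) or
#'   `"none"`.
#' @param label,phase passed to the structure.
#' @return an `xyz_structure` (solute atoms first, then waters).
#' @export
pose_structure <- function(par, solute = "imidazole", label = "",
                           phase = "gas") {
  tmpl <- .solute_template(solute)
  wat <- water_template()
  solute_coords <- if (is.null(tmpl)) matrix(numeric(0), 0, 3) else
    tmpl$coords
  coords <- .pose_coords(par, solute_coords, wat$coords)
  elements <- c(if (is.null(tmpl)) character(0) else tmpl$elements,
                rep(wat$elements, length(par) / 6L))
  structure_xyz(elements, coords, label = label, phase = phase)
}

# fast energy closure for a fixed composition: precomputes site parameters
# and inter-body pair lists once
.energy_fn <- function(n_waters, solute, params) {
  tmpl <- .solute_template(solute)
  wat <- water_template()
  wp <- params$water
  if (is.null(tmpl)) {
    solute_coords <- matrix(numeric(0), 0, 3)
    sq <- numeric(0); se <- numeric(0); ss <- numeric(0)
  } else {
    solute_coords <- tmpl$coords
    if (identical(tmpl$label, "H2O") || nrow(tmpl$coords) == 3L) {
      sq <- wp$charge; se <- wp$eps; ss <- wp$sigma
    } else {
      ip <- params$imidazole
      sq <- ip$charge; se <- ip$eps; ss <- ip$sigma
    }
  }
  body <- c(rep(0L, nrow(solute_coords)),
            rep(seq_len(n_waters), each = 3L))
  charge <- c(sq, rep(wp$charge, n_waters))
  eps <- c(se, rep(wp$eps, n_waters))
  sigma <- c(ss, rep(wp$sigma, n_waters))
  pp <- .make_pairs(body, charge, eps, sigma)
  function(par) {
    coords <- .pose_coords(par, solute_coords, wat$coords)
    .pair_energy(coords, pp)
  }
}

# local minimisation with a guaranteed-descent guard
.minimise_local <- function(par, efn, maxit) {
  e0 <- efn(par)
  safe <- function(p) {
    e <- efn(p)
    if (!is.finite(e)) 1e6 else e
  }
  res <- tryCatch(
    stats::optim(par, safe, method = "L-BFGS-B",
                 control = list(maxit = maxit)),
    error = function(e) list(par = par, value = e0))
  if (!is.finite(res$value) || res$value > e0)
    list(par = par, value = e0)
  else
    list(par = res$par, value = res$value)
}

.random_pose <- function(n_waters, r_min = 2.8, r_max = NULL) {
  if (is.null(r_max)) r_max <- 3.5 + 0.6 * n_waters
  par <- numeric(6 * n_waters)
  for (w in seq_len(n_waters)) {
    u <- stats::rnorm(3)
    u <- u / sqrt(sum(u^2))
    r <- stats::runif(1, r_min, r_max)
    par[(6 * (w - 1) + 1):(6 * w)] <-
      c(r * u, stats::runif(3, 0, 2 * pi))
  }
  par
}

#' Sample low-energy cluster configurations
#'
#' Seeded basin hopping on the classical LJ+Coulomb surface: a pool of
#' random rigid-body placements is locally minimised, then single-water
#' perturbation moves (translation + rotation) with re-minimisation
#' update an elitist pool. Deterministic for a fixed seed; structures are
#' returned sorted by classical energy (ascending) with the energy in
#' attribute `"classical_energy"` (kcal/mol).
#'
#' @param cfg a [sampler_config()].
#' @param params force-field parameters, see [ff_params()].
#' @param solute `"imidazole"` (default), `"water"` or `"none"`.
#' @param phase phase tag for the returned structures.
#' @return list of `xyz_structure`, best first; length `min(pool, ...)`.
#' @export
sample_clusters <- function(cfg, params = ff_params(),
                            solute = "imidazole", phase = "gas") {
  stopifnot(inherits(cfg, "sampler_config"))
  prefix <- switch(solute, imidazole = "IMZW", water = "W", none = "W")
  n_total <- cfg$n_waters + as.integer(solute == "water")
  mklabel <- function(k) sprintf("%s%d_%d", prefix, n_total, k)
  if (cfg$n_waters == 0L) {
    tmpl <- .solute_template(solute)
    if (is.null(tmpl)) return(list())
    tmpl$phase <- phase
    tmpl$label <- mklabel(1L)
    attr(tmpl, "classical_energy") <- 0
    return(list(tmpl))
  }
  set.seed(cfg$seed)
  efn <- .energy_fn(cfg$n_waters, solute, params)
  pool <- vector("list", cfg$pool)
  for (k in seq_len(cfg$pool)) {
    repeat {
      par <- .random_pose(cfg$n_waters)
      if (is.finite(efn(par))) break
    }
    pool[[k]] <- .minimise_local(par, efn, cfg$maxit_local)
  }
  energies <- vapply(pool, `[[`, numeric(1), "value")
  for (it in seq_len(cfg$iterations)) {
    k <- sample.int(cfg$pool, 1)
    par <- pool[[k]]$par
    w <- sample.int(cfg$n_waters, 1)
    idx <- (6 * (w - 1) + 1):(6 * w)
    par[idx] <- par[idx] + c(stats::rnorm(3, 0, 0.6),
                             stats::rnorm(3, 0, 0.5))
    if (!is.finite(efn(par))) next
    cand <- .minimise_local(par, efn, cfg$maxit_local)
    worst <- which.max(energies)
    # elitist replacement; skip near-duplicates of existing pool members
    if (cand$value < energies[worst] &&
        all(abs(cand$value - energies) > 1e-7)) {
      pool[[worst]] <- cand
      energies[worst] <- cand$value
    }
  }
  ord <- order(energies)
  lapply(seq_along(ord), function(rank) {
    s <- pose_structure(pool[[ord[rank]]]$par, solute = solute,
                        label = mklabel(rank), phase = phase)
    attr(s, "classical_energy") <- energies[ord[rank]]
    s
  })
}
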