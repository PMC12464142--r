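# End-to-end synthetic study bundle: everything the analysis pipeline
# consumes (geometries, mock energies, mock frequencies, a multi-method
# binding-energy table, and matched solvated legs with an implanted
# hydration response) generated from a single seed.

#' Ground-truth hydration response implanted by the study generator
#'
#' The per-n hydration enthalpy/free energy (kJ/mol) that the synthetic
#' solvated legs encode, shaped like a converging cluster-continuum
#' profile: a linear approach that plateaus at `dH_inf` from
#' `n_stable_H` on (resp. `dG_inf` from `n_stable_G`), with overall
#' rises `rise_H`/`rise_G` at n = 1. The entropy component is
#' temperature-independent, so dG(n, T) = dH(n) - T dS(n) with
#' dS(n) fixed by the values at `T_ref`.
#'
#' @param n cluster size(s).
#' @param T temperature, K.
#' @param dH_inf,dG_inf plateau (converged) hydration enthalpy and free
#'   energy, kJ/mol.
#' @param rise_H,rise_G total rise of the profile between n = 1 and the
#'   plateau, kJ/mol.
#' @param n_stable_H,n_stable_G first size of each plateau.
#' @param T_ref temperature at which `dG_inf` is anchored, K.
#' @return matrix with columns `dH`, `dG` (kJ/mol), one row per `n`.
#' @export
default_hydration_response <- function(n, T = 298.15,
                                       dH_inf = -58.9, dG_inf = -13.6,
                                       rise_H = 15.8, rise_G = 7.3,
                                       n_stable_H = 5, n_stable_G = 3,
                                       T_ref = 298.15) {
  dH <- dH_inf + rise_H * pmax(0, n_stable_H - n) / (n_stable_H - 1)
  dG_ref <- dG_inf + rise_G * pmax(0, n_stable_G - n) / (n_stable_G - 1)
  dS <- (dH - dG_ref) / T_ref            # kJ/(mol K), T-independent
  cbind(dH = dH, dG = dH - T * dS)
}

.member <- function(s, freqs, energy) {
  s$energy <- energy
  list(structure = s, freqs = freqs, energy = energy)
}

#' Generate a complete synthetic micro-hydration study
#'
#' For each cluster size n = 1..`n_max`, samples gas-phase IMZ(H2O)_n
#' candidate structures and matched solvated (H2O)_n water clusters with
#' the rigid-body sampler, attaches mock electronic energies and harmonic
#' frequencies, tags solvent-phase copies of the cluster geometries, and
#' assembles a multi-method binding-energy table. The solvated
#' imidazole-water leg carries an implanted hydration response
#' (see [default_hydration_response()]) so that the downstream hydration
#' analysis has a known ground truth.
#'
#' @param n_max largest cluster size (>= 1).
#' @param members ensemble members kept per size.
#' @param seed master seed; every random stream derives from it.
#' @param T_ref reference temperature, K.
#' @param cfg mock-QM configuration ([mock_qm_config()]).
#' @param params force-field parameters ([ff_params()]).
#' @param response hydration ground truth: function of (n, T) returning a
#'   matrix with columns dH, dG in kJ/mol.
#' @param noise_solv per-member Gaussian noise on the implanted solvated
#'   thermochemistry, kJ/mol (0 = exact implant).
#' @param pool,iterations,maxit_local sampler effort per size (see
#'   [sampler_config()]).
#' @return object of class `"microhydration_study"`.
#' @export
generate_study <- function(n_max = 8, members = 3, seed = 1,
                           T_ref = 298.15,
                           cfg = mock_qm_config(seed = seed),
                           params = ff_params(),
                           response = default_hydration_response,
                           noise_solv = 0,
                           pool = max(3L, members), iterations = 10,
                           maxit_local = 25) {
  stopifnot(n_max >= 1, members >= 1)
  ref <- cfg$reference

  imz_s <- imidazole_template()
  imz_e <- mock_qm_energies(list(imz_s), cfg, ref, seed = seed,
                            params = params)
  imz_gas <- .member(imz_s, mock_frequencies(imz_s, cfg), imz_e)

  wat_s <- water_template()
  wat_e <- mock_qm_energies(list(wat_s), cfg, ref, seed = seed,
                            params = params)
  water_gas <- .member(wat_s, mock_frequencies(wat_s, cfg), wat_e)

  clusters <- vector("list", n_max)
  for (n in seq_len(n_max)) {
    gas_structs <- sample_clusters(
      sampler_config(n, pool = pool, iterations = iterations,
                     maxit_local = maxit_local, seed = seed + 11L * n),
      params, solute = "imidazole", phase = "gas")
    gas_structs <- gas_structs[seq_len(min(members, length(gas_structs)))]
    gas_e <- mock_qm_energies(gas_structs, cfg, ref, seed = seed + n,
                              params = params)
    gas <- lapply(seq_along(gas_structs), function(j) {
      .member(gas_structs[[j]],
              mock_frequencies(gas_structs[[j]], cfg), gas_e[j])
    })

    if (n == 1L) {
      ws <- wat_s
      ws$phase <- "solvent"
      ws$label <- "W1_1"
      attr(ws, "classical_energy") <- 0
      wat_structs <- list(ws)
    } else {
      wat_structs <- sample_clusters(
        sampler_config(n - 1L, pool = pool, iterations = iterations,
                       maxit_local = maxit_local, seed = seed + 23L * n),
        params, solute = "water", phase = "solvent")
      wat_structs <- wat_structs[seq_len(min(members,
                                             length(wat_structs)))]
    }
    wat_e <- mock_qm_energies(wat_structs, cfg, ref, seed = seed + 7L * n,
                              params = params)
    waters_solv <- lapply(seq_along(wat_structs), function(j) {
      .member(wat_structs[[j]],
              mock_frequencies(wat_structs[[j]], cfg), wat_e[j])
    })

    imzw_solv <- lapply(gas, function(m) {
      s <- m$structure
      s$phase <- "solvent"
      s
    })
    clusters[[n]] <- list(n = n, gas = gas, waters_solv = waters_solv,
                          imzw_solv = imzw_solv)
  }

  # multi-method binding-energy table from the lowest structure per size
  best <- lapply(clusters, function(cl) cl$gas[[1]]$structure)
  methods <- names(cfg$method_bias)
  bind_mat <- vapply(methods, function(m) {
    e <- mock_qm_energies(c(list(imz_s), list(wat_s), best), cfg, m,
                          seed = seed, params = params)
    ladder <- energy_ladder(seq_len(n_max), e[-(1:2)],
                            E_water = e[2], E_imz = e[1])
    convert_energy(binding_energy(ladder), "hartree", "kcal/mol")
  }, numeric(n_max))
  etab <- energy_table(bind_mat, seq_len(n_max), methods, reference = ref)

  obj <- list(n_max = as.integer(n_max), members = as.integer(members),
              seed = as.integer(seed), T_ref = T_ref, cfg = cfg,
              params = params, response = response,
              noise_solv = noise_solv,
              imz_gas = imz_gas, water_gas = water_gas,
              clusters = clusters, energy_table = etab,
              sampler = list(pool = pool, iterations = iterations,
                             maxit_local = maxit_local))
  class(obj) <- "microhydration_study"
  obj
}

#' @export
print.microhydration_study <- function(x, ...) {
  cat(sprintf(
    "<microhydration_study> n = 1..%d, %d member(s)/size, seed %d, T_ref %.2f K\n  methods: %s (reference %s)\n",
    x$n_max, x$members, x$seed, x$T_ref,
    paste(names(x$cfg$method_bias), collapse = ", "), x$cfg$reference))
  invisible(x)
}

#' Build a conformer ensemble from study members at a temperature
#'
#' Runs RRHO thermochemistry for each stored member (structure + mock
#' frequencies + mock electronic energy) at the requested conditions.
#'
#' @param members list of study members (structure/freqs/energy).
#' @param T temperature, K.
#' @param P pressure, atm.
#' @param sigma rotational symmetry number applied to every member.
#' @param weight_on weighting energy, see [cluster_ensemble()].
#' @return a [cluster_ensemble()].
#' @export
ensemble_at <- function(members, T = 298.15, P = 1, sigma = 1,
                        weight_on = "G") {
  records <- lapply(members, function(m) {
    rrho_thermo(m$structure, m$freqs, T = T, P = P, sigma = sigma)
  })
  cluster_ensemble(lapply(members, `[[`, "structure"), records,
                   weight_on = weight_on)
}

#' Solvated legs of the hydration reaction for one cluster size
#'
#' Assembles, at temperature `T`, the three legs of the cluster-continuum
#' hydration reaction for size n: the solvated water-cluster ensemble
#' (RRHO on the stored members), the gas-phase imidazole record, and the
#' solvated imidazole-water ensemble. The last is built by implanting the
#' study's ground-truth hydration response on top of the water leg and
#' the gas-phase imidazole record (plus optional per-member noise), so
#' the hydration machinery can be validated against a known answer.
#'
#' @param study a [generate_study()] bundle.
#' @param n cluster size.
#' @param T temperature, K.
#' @param noise_sd per-member noise on the implanted leg, kJ/mol
#'   (defaults to the study's `noise_solv`).
#' @param seed seed for the noise draw (defaults to the study seed).
#' @return list with `imzw_solv` and `waters_solv` (cluster ensembles)
#'   and `imz_gas` (a `thermo_record`).
#' @export
solvated_ensembles <- function(study, n, T = study$T_ref,
                               noise_sd = study$noise_solv,
                               seed = study$seed) {
  stopifnot(inherits(study, "microhydration_study"),
            n >= 1, n <= study$n_max)
  cl <- study$clusters[[n]]
  waters <- ensemble_at(cl$waters_solv, T = T)
  imz_rec <- rrho_thermo(study$imz_gas$structure, study$imz_gas$freqs,
                         T = T)
  resp <- study$response(n, T)
  k <- length(waters$records)
  set.seed((seed + 101L * n) %% .Machine$integer.max)
  noise_H <- if (noise_sd > 0) stats::rnorm(k, 0, noise_sd) else numeric(k)
  noise_G <- if (noise_sd > 0) stats::rnorm(k, 0, noise_sd) else numeric(k)
  to_h <- 1 / codata2018$hartree_kJ
  geoms <- cl$imzw_solv[((seq_len(k) - 1L) %% length(cl$imzw_solv)) + 1L]
  records <- lapply(seq_len(k), function(j) {
    wrec <- waters$records[[j]]
    H <- wrec$H + imz_rec$H + (resp[1, "dH"] + noise_H[j]) * to_h
    G <- wrec$G + imz_rec$G + (resp[1, "dG"] + noise_G[j]) * to_h
    rec <- list(T = T, P = wrec$P, E_elec = geoms[[j]]$energy,
                ZPE = wrec$ZPE, H = H, S = (H - G) / T, G = G,
                sigma = 1, phase = "solvent", label = geoms[[j]]$label)
    class(rec) <- "thermo_record"
    rec
  })
  imzw <- cluster_ensemble(geoms, records)
  list(imzw_solv = imzw, waters_solv = waters, imz_gas = imz_rec)
}
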