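# Mock "QM-level" data: per-structure electronic energies with a
# controllable per-method systematic bias and Gaussian noise, and harmonic
# frequency sets with modes drawn in chemically sensible ranges. These
# stand in for electronic-structure output so the full analysis pipeline
# can be exercised and calibrated against known ground truth.

# baseline monomer electronic energies (hartree), realistic magnitudes
.E0_WATER <- -76.4
.E0_IMZ <- -226.2

#' Mock-QM configuration
#'
#' @param method_bias named numeric vector: systematic binding-energy bias
#'   per added molecule (kcal/mol) for each "method". The first entry is
#'   the designated reference (conventionally bias 0). The default set
#'   mimics a DFT benchmark in which every functional overbinds slightly,
#'   with per-water biases on the scale seen in real functional
#'   benchmarks.
#' @param noise_sd Gaussian noise on each structure energy, kcal/mol.
#' @param seed integer seed for the mock-data stream.
#' @param freq_ranges list of wavenumber ranges (cm^-1) for the mode
#'   classes: `inter` (intermolecular), `water` (3 intramolecular water
#'   modes), `imz_fp` / `imz_ch` / `imz_nh` (imidazole fingerprint, CH
#'   stretch, NH stretch).
#' @return object of class `"mock_qm_config"`.
#' @export
mock_qm_config <- function(method_bias = c("CCSD(T)/CBS" = 0,
                                           "M06L-D3" = -0.25,
                                           "PW6B95D3" = -0.45,
                                           "MN15" = -0.55,
                                           "M06-D3" = -0.60,
                                           "wB97XD" = -0.70),
                           noise_sd = 0.2, seed = 1,
                           freq_ranges = list(
                             inter = c(30, 800),
                             water_bend = c(1590, 1660),
                             water_sym = c(3580, 3700),
                             water_asym = c(3700, 3790),
                             imz_fp = c(600, 1700),
                             imz_ch = c(3000, 3300),
                             imz_nh = c(3450, 3550))) {
  stopifnot(noise_sd >= 0, !is.null(names(method_bias)),
            all(vapply(freq_ranges, function(r) all(r > 0) && r[2] >= r[1],
                       logical(1))))
  obj <- list(method_bias = method_bias,
              reference = names(method_bias)[1],
              noise_sd = noise_sd, seed = as.integer(seed),
              freq_ranges = freq_ranges)
  class(obj) <- "mock_qm_config"
  obj
}

#' Mock electronic energies for a set of structures
#'
#' E = (monomer baselines) + classical LJ+Coulomb energy +
#' (n_fragments - 1) * bias(method) + N(0, noise_sd), converted to
#' hartree. The bias is per *added* molecule, so monomers are bias-free
#' and a cluster's binding energy acquires exactly n * bias of systematic
#' error relative to the bias-free reference.
#'
#' @param structures list of `xyz_structure` (classical energies are taken
#'   from the `"classical_energy"` attribute when present, else computed).
#' @param cfg a [mock_qm_config()].
#' @param method method name (must be in `cfg$method_bias`).
#' @param seed seed for the noise draw (default `cfg$seed`); the method
#'   name is folded in so different methods get independent noise.
#' @param params force-field parameters for any classical energies that
#'   must be recomputed.
#' @return numeric vector of electronic energies, hartree.
#' @export
mock_qm_energies <- function(structures, cfg, method = cfg$reference,
                             seed = cfg$seed, params = ff_params()) {
  stopifnot(inherits(cfg, "mock_qm_config"))
  if (!method %in% names(cfg$method_bias))
    stop("unknown method '", method, "'")
  bias <- cfg$method_bias[[method]]
  set.seed((seed + sum(utf8ToInt(method))) %% .Machine$integer.max)
  vapply(structures, function(s) {
    f <- perceive_fragments(s)
    e_class <- attr(s, "classical_energy")
    if (is.null(e_class)) e_class <- classical_energy(s, params, f)
    n_frag <- length(f$formulas)
    base <- length(f$water_fragments) * .E0_WATER +
      (!is.na(f$imidazole_fragment)) * .E0_IMZ
    e_kcal <- e_class + (n_frag - 1) * bias +
      if (cfg$noise_sd > 0) stats::rnorm(1, 0, cfg$noise_sd) else 0
    base + convert_energy(e_kcal, "kcal/mol", "hartree")
  }, numeric(1))
}

#' Mock harmonic frequencies for a structure
#'
#' Draws exactly 3N-6 positive wavenumbers (0 for an atom, 3N-5 for a
#' linear molecule): each water fragment contributes its bend and two
#' stretches, an imidazole fragment its 21 intramolecular modes
#' (fingerprint + CH + NH stretches), and the 6(f-1) intermolecular modes
#' of an f-fragment cluster are drawn in the low-wavenumber range.
#'
#' @param s an `xyz_structure` made of water/imidazole fragments.
#' @param cfg a [mock_qm_config()].
#' @param seed seed for the draw (default derives from `cfg$seed` and the
#'   structure label).
#' @return a [frequency_set()] with modes sorted ascending.
#' @export
mock_frequencies <- function(s, cfg = mock_qm_config(),
                             seed = cfg$seed + sum(utf8ToInt(s$label))) {
  if (n_atoms(s) == 1L) return(frequency_set(numeric(0)))
  f <- perceive_fragments(s)
  fr <- cfg$freq_ranges
  set.seed(seed %% .Machine$integer.max)
  modes <- numeric(0)
  for (fid in seq_along(f$formulas)) {
    if (f$formulas[fid] == "H2O") {
      modes <- c(modes,
                 stats::runif(1, fr$water_bend[1], fr$water_bend[2]),
                 stats::runif(1, fr$water_sym[1], fr$water_sym[2]),
                 stats::runif(1, fr$water_asym[1], fr$water_asym[2]))
    } else if (f$formulas[fid] == "C3H4N2") {
      modes <- c(modes,
                 stats::runif(15, fr$imz_fp[1], fr$imz_fp[2]),
                 stats::runif(5, fr$imz_ch[1], fr$imz_ch[2]),
                 stats::runif(1, fr$imz_nh[1], fr$imz_nh[2]))
    } else {
      stop("no mock frequency model for fragment ", f$formulas[fid])
    }
  }
  n_inter <- 6L * (length(f$formulas) - 1L)
  if (n_inter > 0)
    modes <- c(modes, stats::runif(n_inter, fr$inter[1], fr$inter[2]))
  frequency_set(sort(modes))
}
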