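# Two-point complete-basis-set (CBS) extrapolation. The SCF energy decays
# exponentially in the square root of the cardinal number while the
# correlation energy follows an inverse power law, so the two parts are
# extrapolated separately and summed.

#' Cardinal number of a correlation-consistent basis set
#'
#' Maps basis-set names to the cardinal (maximum angular momentum) number
#' used by the extrapolation formulas: (aug-)cc-pVDZ -> 2, TZ -> 3,
#' QZ -> 4, 5Z -> 5. Integers pass through unchanged.
#'
#' @param x basis name(s) (e.g. `"aug-cc-pVTZ"`, `"aVQZ"`, `"TZ"`) or
#'   integer cardinal number(s).
#' @return integer cardinal number(s).
#' @export
basis_cardinal <- function(x) {
  if (is.numeric(x)) {
    stopifnot(all(x == round(x)), all(x >= 2))
    return(as.integer(x))
  }
  key <- toupper(gsub("[^A-Za-z0-9]", "", x))
  card <- c(D = 2L, T = 3L, Q = 4L, "5" = 5L, "6" = 6L)
  m <- regmatches(key, regexec("(D|T|Q|5|6)Z$", key))
  out <- vapply(m, function(g) {
    if (length(g) < 2L) NA_integer_ else card[[g[2]]]
  }, integer(1))
  if (anyNA(out))
    stop("unrecognised basis set name(s): ",
         paste(x[is.na(out)], collapse = ", "))
  out
}

.check_cbs_pair <- function(N, M, param_supplied = TRUE) {
  stopifnot(length(N) == 1L, length(M) == 1L)
  if (M == N) stop("the two cardinal numbers must differ (M > N)")
  if (M < N) stop("M must exceed N")
  if (N < 2) stop("cardinal numbers below 2 are not meaningful")
  if (!(N == 3L && M == 4L) && !param_supplied)
    stop("the default extrapolation parameters are calibrated for the ",
         "(N, M) = (3, 4) pair; supply alpha/beta explicitly for other pairs")
  invisible(TRUE)
}

#' Extrapolate the SCF energy to the basis-set limit
#'
#' E_SCF(inf) = [E_SCF(M) exp(-a sqrt(N)) - E_SCF(N) exp(-a sqrt(M))] /
#' [exp(-a sqrt(N)) - exp(-a sqrt(M))], the two-point exponential form.
#' The default a = 5.79 is calibrated for the (N, M) = (3, 4) pair, i.e.
#' the aug-cc-pVTZ / aug-cc-pVQZ combination.
#'
#' @param E_N,E_M SCF energies (hartree) at cardinal numbers `N` and `M`.
#' @param N,M cardinal numbers (integers or basis names), M > N >= 2.
#' @param alpha exponential decay parameter (> 0).
#' @return extrapolated SCF energy, hartree.
#' @export
extrapolate_scf <- function(E_N, E_M, N = 3, M = 4, alpha = 5.79) {
  supplied <- !missing(alpha)
  N <- basis_cardinal(N); M <- basis_cardinal(M)
  .check_cbs_pair(N, M, supplied)
  stopifnot(alpha > 0)
  eN <- exp(-alpha * sqrt(N))
  eM <- exp(-alpha * sqrt(M))
  (E_M * eN - E_N * eM) / (eN - eM)
}

#' Extrapolate the correlation energy to the basis-set limit
#'
#' E_corr(inf) = [E_corr(N) N^b - E_corr(M) M^b] / (N^b - M^b), the
#' two-point power-law form. The default b = 3.05 is calibrated for the
#' (N, M) = (3, 4) pair.
#'
#' @param E_N,E_M correlation energies (hartree) at cardinals `N` and `M`.
#' @inheritParams extrapolate_scf
#' @param beta power-law exponent (> 0).
#' @return extrapolated correlation energy, hartree.
#' @export
extrapolate_corr <- function(E_N, E_M, N = 3, M = 4, beta = 3.05) {
  supplied <- !missing(beta)
  N <- basis_cardinal(N); M <- basis_cardinal(M)
  .check_cbs_pair(N, M, supplied)
  stopifnot(beta > 0)
  (E_N * N^beta - E_M * M^beta) / (N^beta - M^beta)
}

#' Total CBS energy from a two-point extrapolation
#'
#' Sum of the separately extrapolated SCF and correlation parts.
#'
#' @param scf_N,scf_M SCF energies at the two cardinals, hartree.
#' @param corr_N,corr_M correlation energies at the two cardinals, hartree.
#' @inheritParams extrapolate_scf
#' @param beta power-law exponent for the correlation part.
#' @return object of class `"cbs_result"`: list with `scf_inf`,
#'   `corr_inf`, `total` (hartree) and the inputs.
#' @export
cbs_total <- function(scf_N, scf_M, corr_N, corr_M, N = 3, M = 4,
                      alpha = 5.79, beta = 3.05) {
  scf_inf <- extrapolate_scf(scf_N, scf_M, N, M, alpha)
  corr_inf <- extrapolate_corr(corr_N, corr_M, N, M, beta)
  obj <- list(scf_inf = scf_inf, corr_inf = corr_inf,
              total = scf_inf + corr_inf,
              N = basis_cardinal(N), M = basis_cardinal(M),
              alpha = alpha, beta = beta)
  class(obj) <- "cbs_result"
  obj
}

#' @export
print.cbs_result <- function(x, ...) {
  cat(sprintf(
    "<cbs_result> (N, M) = (%d, %d), alpha = %g, beta = %g\n  E_SCF(inf)  = %.8f hartree\n  E_corr(inf) = %.8f hartree\n  E(inf)      = %.8f hartree\n",
    x$N, x$M, x$alpha, x$beta, x$scf_inf, x$corr_inf, x$total))
  invisible(x)
}
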