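# Rigid monomer templates used by the synthetic sampler and as fixtures.
# Geometries are idealised (planar ring, TIP3P-like water); force-field
# parameters are package fixtures in the CHARMM style, not fitted values.

#' Rigid water monomer template
#'
#' 3-site water with r(OH) = 0.9572 Angstrom and a 104.52 degree angle
#' (TIP3P geometry), oxygen at the origin, in the xy plane. Atom order
#' O, H, H.
#'
#' @return an `xyz_structure` labelled `"H2O"`.
#' @export
water_template <- function() {
  r <- 0.9572
  a <- 104.52 * pi / 180
  coords <- rbind(c(0, 0, 0),
                  c(r, 0, 0),
                  c(r * cos(a), r * sin(a), 0))
  structure_xyz(c("O", "H", "H"), coords, label = "H2O")
}

#' Rigid imidazole monomer template
#'
#' Planar C3H4N2 ring built on a regular pentagon of circumradius 1.16
#' Angstrom (ring bonds 1.364 Angstrom) in the z = 0 plane, with hydrogens
#' placed radially outward (N-H 1.01, C-H 1.08 Angstrom). Atom order
#' N1, C2, N3, C4, C5, H(N1), H(C2), H(C4), H(C5): N1 is the pyrrole-type
#' (H-bearing, donor) nitrogen, N3 the pyridine-type acceptor nitrogen.
#'
#' @return an `xyz_structure` labelled `"IMZ"`.
#' @export
imidazole_template <- function() {
  R_ring <- 1.16
  ang <- (90 - 72 * (0:4)) * pi / 180   # N1 at top, clockwise N1 C2 N3 C4 C5
  ring <- cbind(R_ring * cos(ang), R_ring * sin(ang), 0)
  h_len <- c(1.01, 1.08, 1.08, 1.08)    # H on N1, C2, C4, C5
  h_on <- c(1L, 2L, 4L, 5L)
  hpos <- t(vapply(seq_along(h_on), function(i) {
    u <- ring[h_on[i], ] / sqrt(sum(ring[h_on[i], ]^2))
    ring[h_on[i], ] + h_len[i] * u
  }, numeric(3)))
  structure_xyz(c("N", "C", "N", "C", "C", "H", "H", "H", "H"),
                rbind(ring, hpos), label = "IMZ")
}

#' Force-field parameters for the rigid-body sampler
#'
#' Point charges (e) and Lennard-Jones parameters (epsilon kcal/mol,
#' sigma Angstrom) for the 3-site water and the 9-site imidazole template,
#' combined with Lorentz-Berthelot rules. Values are TIP3P for water and
#' CHARMM-style assignments for imidazole; both fragments are net neutral.
#'
#' @return list with elements `water` and `imidazole`, each a data.frame
#'   with columns `charge`, `eps`, `sigma` in template atom order.
#' @export
ff_params <- function() {
  water <- data.frame(
    charge = c(-0.834, 0.417, 0.417),
    eps    = c(0.1521, 0, 0),
    sigma  = c(3.15066, 0.4, 0.4))
  imidazole <- data.frame(
    charge = c(-0.36, 0.25, -0.70, 0.22, -0.05, 0.32, 0.13, 0.09, 0.10),
    eps    = c(0.17, 0.07, 0.17, 0.07, 0.07, 0.046, 0.03, 0.03, 0.03),
    sigma  = c(3.25, 3.55, 3.25, 3.55, 3.55, 0.40, 2.42, 2.42, 2.42))
  stopifnot(abs(sum(water$charge)) < 1e-12,
            abs(sum(imidazole$charge)) < 1e-12)
  list(water = water, imidazole = imidazole)
}
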