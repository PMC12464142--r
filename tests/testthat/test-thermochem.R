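# Independent closed-form oracles for the RRHO machinery, evaluated with
# constants written out in the tests themselves.

.h <- 6.62607015e-34
.kB <- 1.380649e-23
.NA_ <- 6.02214076e23
.c_cm <- 2.99792458e10
.R_ <- 8.31446261815324
.Eh <- 4.3597447222071e-18

test_that("zero-point energy matches the closed form and scales linearly", {
  expect_identical(zero_point_energy(frequency_set(numeric(0))), 0)
  z <- zero_point_energy(frequency_set(1000))
  oracle_J_mol <- .NA_ * .h * .c_cm * 1000 / 2   # 5981.3 J/mol
  expect_equal(convert_energy(z, "hartree", "kJ/mol"), oracle_J_mol / 1000,
               tolerance = 1e-10)
  half <- zero_point_energy(frequency_set(1000, scale_factor = 0.5))
  expect_equal(half, z / 2, tolerance = 1e-14)
  # imaginary modes: error by default, droppable with a warning
  expect_error(frequency_set(c(100, -50)), "imaginary")
  expect_warning(fs <- frequency_set(c(100, -50), drop_imaginary = TRUE),
                 "dropping")
  expect_length(fs$frequencies, 1L)
})

test_that("rotational constants classify and order correctly", {
  ar <- structure_xyz("Ar", matrix(0, 1, 3))
  expect_identical(rotational_constants(ar)$linearity, "atom")

  h2 <- structure_xyz(c("H", "H"), rbind(c(0, 0, 0), c(0.74, 0, 0)))
  rh2 <- rotational_constants(h2)
  expect_identical(rh2$linearity, "linear")
  expect_length(rh2$constants_GHz, 2L)
  expect_equal(rh2$constants_GHz[1], rh2$constants_GHz[2],
               tolerance = 1e-12)

  w <- water_template()
  rw <- rotational_constants(w)
  expect_identical(rw$linearity, "nonlinear")
  expect_true(all(diff(rw$constants_GHz) < 0) && all(rw$constants_GHz > 0))
  # oracle: B = h / (8 pi^2 I) for each principal moment
  m <- c(15.9994, 1.00794, 1.00794) * 1.66053906660e-27
  xyz <- sweep(w$coords, 2, colSums(w$coords * m) / sum(m)) * 1e-10
  I <- matrix(0, 3, 3)
  for (k in 1:3) {
    I <- I + m[k] * (sum(xyz[k, ]^2) * diag(3) - outer(xyz[k, ], xyz[k, ]))
  }
  B_oracle <- sort(.h / (8 * pi^2 * eigen(I)$values) / 1e9,
                   decreasing = TRUE)
  expect_equal(rw$constants_GHz, B_oracle, tolerance = 1e-8)
})

test_that("monatomic entropy matches the Sackur-Tetrode closed form", {
  sackur_tetrode <- function(mass_u, T, P_atm) {
    m <- mass_u * 1.66053906660e-27
    q <- (2 * pi * m * .kB * T / .h^2)^1.5 * .kB * T / (P_atm * 101325)
    .R_ * (log(q) + 2.5)
  }
  for (case in list(c(39.948, 298.15, 1), c(4.002602, 298.15, 1),
                    c(39.948, 400, 2))) {
    el <- if (case[1] > 10) "Ar" else "He"
    s <- structure_xyz(el, matrix(0, 1, 3), energy = 0)
    rec <- rrho_thermo(s, frequency_set(numeric(0)), T = case[2],
                       P = case[3])
    S_J <- rec$S * .Eh * .NA_
    expect_equal(S_J, sackur_tetrode(case[1], case[2], case[3]),
                 tolerance = 0.01 / 155)
  }
})

test_that("G = H - T S identically and H -> E_elec + ZPE as T -> 0", {
  w <- water_template()
  w$energy <- -76.4
  f <- frequency_set(c(1650, 3650, 3750))
  for (T in c(50, 298.15, 400)) {
    rec <- rrho_thermo(w, f, T = T)
    expect_lt(abs(rec$G - (rec$H - rec$T * rec$S)), 1e-10)
    expect_gt(rec$S, 0)
  }
  cold <- rrho_thermo(w, f, T = 1e-4)
  expect_equal(cold$H, w$energy + cold$ZPE, tolerance = 1e-9)
  # missing energy and wrong mode count are rejected
  w2 <- water_template()
  expect_error(rrho_thermo(w2, f), "no electronic energy")
  expect_error(rrho_thermo(w, frequency_set(c(1650, 3650))), "expected 3")
})

test_that("dG/dT = -S by central finite differences", {
  w <- water_template()
  w$energy <- -76.4
  f <- frequency_set(c(1650, 3650, 3750))
  for (T in c(250, 300, 380)) {
    dT <- 1e-3
    Gp <- rrho_thermo(w, f, T = T + dT)$G
    Gm <- rrho_thermo(w, f, T = T - dT)$G
    S <- rrho_thermo(w, f, T = T)$S
    expect_equal((Gp - Gm) / (2 * dT), -S, tolerance = 1e-4)
  }
})

test_that("thermo_scan is monotone in the right directions and concave in G", {
  w <- water_template()
  w$energy <- -76.4
  f <- frequency_set(c(1650, 3650, 3750))
  grid <- seq(200, 400, by = 20)
  sc <- thermo_scan(w, f, grid)
  expect_identical(nrow(sc), length(grid))
  expect_true(all(diff(sc$S) > 0))
  expect_true(all(diff(sc$G) < 0))
  # concavity: dG/dT = -S decreases, so second differences are negative
  expect_true(all(diff(sc$G, differences = 2) < 0))
  one <- thermo_scan(w, f, 298.15)
  expect_equal(one$G, rrho_thermo(w, f, 298.15)$G, tolerance = 1e-14)
  expect_error(thermo_scan(w, f, c(300, 250)), "unsorted|strictly",
               class = "simpleError")
})

test_that("vibrational entropy limits: stiff modes freeze out, soft modes go classical", {
  w <- water_template()
  w$energy <- 0
  loose <- rrho_thermo(w, frequency_set(c(10, 3650, 3750)), T = 298.15)
  stiff <- rrho_thermo(w, frequency_set(c(3600, 3650, 3750)), T = 298.15)
  expect_gt(loose$S, stiff$S)
  # a very stiff mode contributes nothing: swapping it for an even
  # stiffer one changes S by nothing measurable
  vstiff <- rrho_thermo(w, frequency_set(c(1e5, 3650, 3750)), T = 298.15)
  hard <- rrho_thermo(w, frequency_set(c(1e9, 3650, 3750)), T = 298.15)
  expect_equal(vstiff$S, hard$S, tolerance = 1e-14)
  # one soft mode approaches the classical limit S = R(1 - ln(hc nu / kT))
  nu <- 5
  x <- .h * .c_cm * nu / (.kB * 298.15)
  S_classical <- .R_ * (1 - log(x))
  soft <- rrho_thermo(w, frequency_set(c(nu, 3650, 3750)), T = 298.15)
  S_soft_mode <- (soft$S - hard$S) * .Eh * .NA_
  expect_equal(S_soft_mode, S_classical, tolerance = 1e-3)
})

test_that("E_elec + ZPE is additive over non-interacting copies", {
  f1 <- frequency_set(c(1650, 3650, 3750))
  f2 <- frequency_set(rep(c(1650, 3650, 3750), 2))
  expect_equal(zero_point_energy(f2), 2 * zero_point_energy(f1),
               tolerance = 1e-14)
})
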