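# Shared fixtures, built in code. Heavy synthetic studies are memoised so
# several test files can reuse one generation run.

.fixture_env <- new.env(parent = emptyenv())

# small study: quick, used by hydration/pipeline unit tests
get_small_study <- function() {
  if (is.null(.fixture_env$small))
    .fixture_env$small <- generate_study(n_max = 3, members = 2, seed = 42,
                                         pool = 2, iterations = 5,
                                         maxit_local = 20)
  .fixture_env$small
}

# full-depth study: reaches the n = 5-7 / 3-7 stable ranges
get_full_study <- function() {
  if (is.null(.fixture_env$full))
    .fixture_env$full <- generate_study(n_max = 7, members = 2, seed = 11,
                                        pool = 2, iterations = 5,
                                        maxit_local = 20)
  .fixture_env$full
}

# deterministic random rotation matrix
rand_rotation <- function(seed = 1) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

transform_structure <- function(s, R = diag(3), t = c(0, 0, 0)) {
  s$coords <- sweep(s$coords %*% t(R), 2, -t)
  s
}

# water molecule whose first O-H bond points from `o_pos` toward `target`
water_pointing <- function(o_pos, target, roll = 0) {
  u <- target - o_pos
  u <- u / sqrt(sum(u^2))
  # arbitrary perpendicular
  p <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- p - sum(p * u) * u
  v <- v / sqrt(sum(v^2))
  w <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  v2 <- cos(roll) * v + sin(roll) * w
  r <- 0.9572
  a <- 104.52 * pi / 180
  h1 <- o_pos + r * u
  h2 <- o_pos + r * (cos(a) * u + sin(a) * v2)
  rbind(o_pos, h1, h2)
}

# near-linear water dimer: donor O-H...O with given O...O distance
make_water_dimer <- function(d_oo = 2.9) {
  donor <- water_pointing(c(0, 0, 0), c(d_oo, 0, 0))
  acc_o <- c(d_oo, 0, 0)
  # acceptor hydrogens point away from the donor
  acc <- water_pointing(acc_o, acc_o + c(1, 1, 0.3))
  structure_xyz(rep(c("O", "H", "H"), 2), rbind(donor, acc),
                label = "water_dimer")
}

# ill-tautomerised fixture: the C2 hydrogen relocated onto N3, so both
# ring nitrogens bear H (same C3H4N2 formula, invalid role pattern)
make_imidazolium <- function() {
  imz <- imidazole_template()
  n3 <- imz$coords[3, ]
  imz$coords[7, ] <- n3 + 1.01 * n3 / sqrt(sum(n3^2))
  imz$label <- "bad_tautomer"
  imz
}

# independent connected-components oracle (igraph) for fragment tests
igraph_components <- function(s, scale = 1.2) {
  radii <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66)[s$elements]
  d <- as.matrix(dist(s$coords))
  adj <- d < outer(radii, radii, "+") * scale
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::components(g)$membership
}

# independent brute-force hydrogen-bond enumeration (oracle)
manual_hbond_triples <- function(s, d_max = 2.6, angle_min = 120,
                                 scale = 1.2) {
  radii <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66)[s$elements]
  d <- as.matrix(dist(s$coords))
  bonded <- d < outer(radii, radii, "+") * scale
  diag(bonded) <- FALSE
  frag <- igraph_components(s, scale)
  out <- NULL
  for (h in which(s$elements == "H")) {
    dn <- which(bonded[h, ] & s$elements %in% c("O", "N", "C"))
    if (!length(dn)) next
    dn <- dn[1]
    for (a in which(s$elements %in% c("O", "N"))) {
      if (frag[a] == frag[h]) next
      if (d[h, a] > d_max) next
      u <- s$coords[dn, ] - s$coords[h, ]
      v <- s$coords[a, ] - s$coords[h, ]
      ang <- acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
      if (ang < angle_min) next
      out <- rbind(out, c(donor = dn, h = h, acceptor = a))
    }
  }
  out
}
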