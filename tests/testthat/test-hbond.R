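test_that("constructed dimers yield exactly the built-in contact", {
  dimer <- make_water_dimer(2.9)
  rep_ <- detect_contacts(dimer)
  expect_identical(nrow(rep_$contacts), 1L)
  expect_identical(rep_$contacts$type, "OH...O")
  expect_lt(rep_$contacts$d_ha, 2.6)
  expect_gt(rep_$contacts$angle, 150)
  expect_identical(unname(rep_$census["water_water"]), 1L)

  # water donating to N3: place the O 1.9 + 0.9572 along the N3 lone
  # pair direction, O-H pointing at N3
  imz <- imidazole_template()
  roles <- label_imidazole(imz)
  n3 <- imz$coords[roles$N3, ]
  u <- n3 / sqrt(sum(n3^2))      # ring is centred near the origin
  o_pos <- n3 + (1.9 + 0.9572) * u
  wat <- water_pointing(o_pos, n3)
  s <- structure_xyz(c(imz$elements, "O", "H", "H"),
                     rbind(imz$coords, wat))
  rep2 <- detect_contacts(s)
  expect_identical(unname(rep2$census["N3_accepted"]), 1L)
  expect_true("OH...N3" %in% rep2$contacts$type)
  on3 <- rep2$contacts[rep2$contacts$type == "OH...N3", ]
  expect_equal(on3$d_ha, 1.9, tolerance = 1e-6)
  # in-plane donor -> out-of-plane angle 0
  expect_equal(on3$out_of_plane, 0, tolerance = 1e-6)
})

test_that("a 3-water donor/acceptor motif gives the expected census", {
  # N3 accepts one bond (donor water above the ring plane), N1-H donates
  # to a second water, a third water bridges the first two
  imz <- imidazole_template()
  roles <- label_imidazole(imz)
  n3 <- imz$coords[roles$N3, ]
  n1 <- imz$coords[roles$N1, ]
  h1 <- imz$coords[roles$H_N1, ]
  u3 <- n3 / sqrt(sum(n3^2))
  # donor to N3, lifted out of plane
  o1 <- n3 + 2.85 * (u3 * cos(0.6) + c(0, 0, 1) * sin(0.6))
  w1 <- water_pointing(o1, n3)
  # acceptor of the N1-H bond, along the N1-H direction
  un1 <- (h1 - n1) / sqrt(sum((h1 - n1)^2))
  o2 <- n1 + 2.9 * un1
  w2 <- water_pointing(o2, o2 + c(0.3, 1, 0.5))
  # bridge from w2's oxygen toward w1's oxygen
  o3 <- (o1 + o2) / 2 + c(0, 0, 2.0)
  w3 <- water_pointing(o3, o1)
  s <- structure_xyz(c(imz$elements, rep(c("O", "H", "H"), 3)),
                     rbind(imz$coords, w1, w2, w3), label = "IMZW3_motif")
  rep_ <- detect_contacts(s)
  expect_identical(unname(rep_$census["N3_accepted"]), 1L)
  expect_identical(unname(rep_$census["N1H_donated"]), 1L)
  # the N3 donor is out of the ring plane
  oop <- rep_$contacts$out_of_plane
  expect_gt(max(oop, na.rm = TRUE), 20)

  # oracle: independent brute-force triple enumeration finds the same
  # donor-H-acceptor triples (O/N acceptors)
  oracle <- manual_hbond_triples(s)
  got <- rep_$contacts[!is.na(rep_$contacts$acceptor), c("donor", "h", "acceptor")]
  got <- got[order(got$h, got$acceptor), ]
  oracle <- oracle[order(oracle[, "h"], oracle[, "acceptor"]), , drop = FALSE]
  expect_identical(nrow(got), nrow(oracle))
  expect_equal(unname(as.matrix(got)), unname(oracle))
})

test_that("out-of-plane angle: limits and frame invariance", {
  imz <- imidazole_template()
  roles <- label_imidazole(imz)
  n3 <- imz$coords[roles$N3, ]
  in_plane <- n3 * 1.8                   # still in the z = 0 ring plane
  expect_equal(out_of_plane_angle(imz, roles, in_plane), 0,
               tolerance = 1e-8)
  along_normal <- n3 + 3 * roles$normal
  expect_equal(out_of_plane_angle(imz, roles, along_normal), 90,
               tolerance = 1e-8)
  # rotation + translation leaves the angle unchanged
  R <- rand_rotation(5)
  t <- c(3, -1, 2)
  moved <- transform_structure(imz, R, t)
  roles_m <- label_imidazole(moved)
  p <- n3 + c(0.8, 0.5, 1.7)
  ang0 <- out_of_plane_angle(imz, roles, p)
  ang1 <- out_of_plane_angle(moved, roles_m, as.numeric(R %*% p + t))
  expect_equal(ang1, ang0, tolerance = 1e-8)
})

test_that("contact detection is invariant and monotone in the criteria", {
  s <- sample_clusters(sampler_config(4, pool = 2, iterations = 4,
                                      seed = 21))[[1]]
  rep0 <- detect_contacts(s)
  # all contacts are inter-fragment
  f <- perceive_fragments(s)
  ok <- !is.na(rep0$contacts$acceptor)
  expect_true(all(f$fragment_ids[rep0$contacts$h[ok]] !=
                    f$fragment_ids[rep0$contacts$acceptor[ok]]))
  # rigid motion + relabelling does not change counts
  moved <- transform_structure(s, rand_rotation(9), c(1, 2, -3))
  expect_identical(detect_contacts(moved)$census, rep0$census)
  set.seed(6)
  perm <- sample(n_atoms(s))
  sp <- structure_xyz(s$elements[perm], s$coords[perm, ])
  expect_identical(unname(detect_contacts(sp)$census),
                   unname(rep0$census))
  # tightening any cutoff never increases the number of contacts
  n0 <- nrow(rep0$contacts)
  for (crit in list(contact_criteria(d_ha_max = 2.2),
                    contact_criteria(d_ha_pi_max = 2.4),
                    contact_criteria(angle_min = 150))) {
    expect_lte(nrow(detect_contacts(s, criteria = crit)$contacts), n0)
  }
})

test_that("census aggregation reports distributions and modal counts", {
  dimer <- make_water_dimer()
  r1 <- detect_contacts(dimer)
  single <- census_summary(list(r1))
  expect_identical(nrow(single$counts), 1L)
  expect_identical(unname(single$modal["water_water"]), 1)

  far <- structure_xyz(rep(c("O", "H", "H"), 2),
                       rbind(water_template()$coords,
                             sweep(water_template()$coords, 2,
                                   -c(12, 0, 0))))
  r0 <- detect_contacts(far)
  expect_identical(nrow(r0$contacts), 0L)
  all_empty <- census_summary(list(r0, r0))
  expect_true(all(all_empty$counts == 0))
  mixed <- census_summary(list(r1, r1, r0))
  expect_identical(unname(mixed$modal["water_water"]), 1)
  expect_error(census_summary(list()), "no contact reports")
})
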