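test_that("centering translates the centroid to the origin", {
  g <- center_geometry(rbind(c(1, 0, 0), c(-1, 0, 0)))
  expect_equal(g$norm_sq, 2)
  expect_equal(g$coords, rbind(c(1, 0, 0), c(-1, 0, 0)))
  g2 <- center_geometry(rbind(c(2, 0, 0), c(4, 0, 0)))
  expect_equal(g2$coords, rbind(c(-1, 0, 0), c(1, 0, 0)))
  expect_equal(g2$norm_sq, 2)
  m <- random_molecule(17)
  g3 <- center_geometry(m)
  expect_lt(sqrt(sum(colMeans(g3$coords)^2)), 1e-12)
  expect_error(center_geometry(rbind(c(1, 1, 1), c(1, 1, 1))), "degenerate")
})

test_that("permutation validity enforces cycles, classes and bonds", {
  expect_true(validate_permutation(1:5, "c3"))
  expect_false(validate_permutation(c(2, 3, 1), "c2"))    # 3-cycle under C2
  # involutions of S4: 10 of the 24 permutations are valid for C2
  P <- all_permutations(4)
  n_valid <- sum(apply(P, 1, validate_permutation, group = "c2"))
  expect_equal(n_valid, 10)
  # class respect
  m <- csm_molecule(c("C", "C", "O", "O"), matrix(rnorm(12), ncol = 3))
  part <- equivalence_partition(m)
  expect_false(validate_permutation(c(3, 4, 1, 2), "c2", part))
  expect_true(validate_permutation(c(2, 1, 4, 3), "c2", part))
  # bond automorphism
  bonds <- rbind(c(1, 2))
  expect_false(validate_permutation(c(1, 3, 2, 4), "c2", bonds = bonds,
                                    keep_structure = TRUE))
  expect_true(validate_permutation(c(2, 1, 3, 4), "c2", bonds = bonds,
                                   keep_structure = TRUE))
})

test_that("symmetrize produces an exactly symmetric structure", {
  # averaging a fixed point returns it
  mol <- make_symmetric("c3", 2, seed = 4)
  g <- center_geometry(mol)
  op <- generator_operation("c3", c(0, 0, 1))
  perm <- c(2, 3, 1, 5, 6, 4)
  Q <- symmetrize(g, perm, op)
  expect_lt(max(abs(Q - g$coords)), 1e-12)
  # Ci two-term average
  gi <- csm_geometry(rbind(c(1, 0, 0), c(-1, 0.2, 0)))
  Qi <- symmetrize(gi, c(2, 1), generator_operation("ci"))
  expect_equal(Qi[1, ], c(1, -0.1, 0))
  expect_equal(Qi[2, ], c(-1, 0.1, 0))
  # random valid perm for C3: symmetry identity Q[perm(i),] = G Q[i,]
  gr <- center_geometry(matrix(rnorm(18), ncol = 3))
  p3 <- c(2, 3, 1, 5, 6, 4)   # two 3-cycles
  Q3 <- symmetrize(gr, p3, op)
  expect_lt(max(abs(Q3[p3, ] - Q3 %*% t(op$matrix))), 1e-10)
})

test_that("the functional matches its closed forms", {
  g <- center_geometry(matrix(rnorm(15), ncol = 3))
  expect_equal(csm_functional(g, g$coords), 0)
  expect_equal(csm_functional(g, 0 * g$coords), 100)
  gi <- csm_geometry(rbind(c(1, 0, 0), c(-1, 0.2, 0)))
  r <- csm_for_permutation(gi, c(2, 1), "ci")
  expect_equal(r$value, 100 * 0.02 / 2.04, tolerance = 1e-12)
})

test_that("analytic axis optimisation agrees with the dense numeric search", {
  # exact symmetry about z recovered
  mol <- make_symmetric("c4", 1, seed = 9)
  g <- center_geometry(mol)
  r <- optimal_axis(g, c(2, 3, 4, 1), "c4")
  expect_lt(r$value, 1e-10)
  expect_lt(min(sum((r$op$axis - c(0, 0, 1))^2),
                sum((r$op$axis + c(0, 0, 1))^2)), 1e-12)
  # CI: value independent of any axis
  gr <- center_geometry(matrix(rnorm(12), ncol = 3))
  expect_equal(optimal_axis(gr, c(2, 1, 4, 3), "ci")$value,
               direct_value(gr, c(2, 1, 4, 3), point_group("ci"), c(1, 1, 1) / sqrt(3)),
               tolerance = 1e-10)
  # random 6-atom geometries vs grid+polish oracle
  for (seed in 1:8) {
    gg <- center_geometry(csmeasure:::with_seed(seed, matrix(rnorm(18), ncol = 3)))
    for (lab in c("c2", "c3", "cs", "s4")) {
      h <- point_group(lab)$group_order_h
      perm <- switch(lab, c2 = c(2, 1, 4, 3, 5, 6), cs = c(2, 1, 4, 3, 5, 6),
                     c3 = c(2, 3, 1, 5, 6, 4), s4 = c(2, 3, 4, 1, 6, 5))
      a <- optimal_axis(gg, perm, lab)$value
      b <- oracle_axis_min(gg, perm, lab, ngrid = 400)
      expect_lt(abs(a - b), 1e-6)
    }
  }
})

test_that("the measure is invariant under rigid motion", {
  mol <- perturb(make_symmetric("c3", 2, seed = 12), 0.08, seed = 3)
  v0 <- exact_csm(mol, "c3")$value
  for (seed in c(21, 22)) {
    R <- random_rotation(seed)
    m2 <- csm_molecule(mol$atoms$element,
                       coords(mol) %*% t(R) + rep(1, n_atoms(mol)) %o% c(5, -1, 2))
    expect_equal(exact_csm(m2, "c3")$value, v0, tolerance = 1e-8)
  }
})

test_that("CCM is zero for planar structures and minimal over Sn", {
  # any planar molecule has a mirror plane: CCM = 0 via S1
  planar <- csm_molecule(c("C", "N", "O", "F"),
                         cbind(matrix(rnorm(8), ncol = 2), 0))
  r <- ccm(planar, sn_max = 4)
  expect_lt(r$value, 1e-8)
  expect_equal(r$subgroup$label, "Cs")
  # reported value is the min over the subgroups it scans
  m <- random_molecule(33)
  r2 <- ccm(m, sn_max = 4)
  per <- vapply(csmeasure:::expand_ch(4), function(g) exact_csm(m, g)$value, 1)
  expect_equal(r2$value, min(per), tolerance = 1e-10)
  # 4 distinct-element atoms at generic positions are chiral
  chiral <- csm_molecule(c("C", "N", "O", "F"),
                         rbind(c(0, 0, 0), c(1.6, 0, 0), c(0.3, 1.4, 0),
                               c(0.5, 0.4, 1.3)))
  rc <- ccm(chiral, sn_max = 2)
  expect_gt(rc$value, 1e-4)
  oracle <- min(oracle_exact_csm(chiral, "cs"), oracle_exact_csm(chiral, "ci"))
  expect_equal(rc$value, oracle, tolerance = 1e-6)
})

test_that("results recompute and rescore consistently", {
  mol <- perturb(make_symmetric("s4", 2, seed = 8), 0.05, seed = 2)
  r <- exact_csm(mol, "s4")
  g <- center_geometry(mol)
  # invariant: value reproducible from (perm, operation)
  expect_equal(csm_functional(g, symmetrize(g, r$perm, r$op)), r$value,
               tolerance = 1e-10)
  # nearest structure is exactly symmetric and rescores to zero
  Q <- r$nearest
  expect_lt(max(abs(Q[r$perm, ] - Q %*% t(r$op$matrix))), 1e-8)
  m2 <- set_coords(mol, Q)
  expect_lt(exact_csm(m2, "s4")$value, 1e-8)
})
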