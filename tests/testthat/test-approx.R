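test_that("the Fibonacci sphere is deterministic and near-uniform", {
  expect_equal(nrow(fibonacci_sphere(1)), 1)
  expect_equal(sqrt(sum(fibonacci_sphere(1)^2)), 1, tolerance = 1e-12)
  D2 <- fibonacci_sphere(2)
  expect_false(isTRUE(all.equal(D2[1, 3], D2[2, 3])))
  D <- fibonacci_sphere(100)
  expect_lt(max(abs(sqrt(rowSums(D^2)) - 1)), 1e-12)
  expect_lt(sqrt(sum(colMeans(D)^2)), 0.05)
  expect_identical(fibonacci_sphere(100), D)
  expect_error(fibonacci_sphere(0), "positive")
})

test_that("hungarian assignment equals the brute-force optimum", {
  for (seed in 1:6) {
    C <- csmeasure:::with_seed(seed, matrix(stats::runif(25), 5, 5))
    a <- hungarian_assignment(C)
    expect_true(all(sort(a) == 1:5))
    cost <- sum(C[cbind(1:5, a)])
    best <- min(apply(all_permutations(5), 1, function(p)
      sum(C[cbind(1:5, p)])))
    expect_equal(cost, best, tolerance = 1e-12)
  }
})

test_that("greedy can be trapped where hungarian is not", {
  # greedy commits the cheapest pair first and pays for it
  C <- rbind(c(0, 10), c(1, 100))
  g <- csmeasure:::greedy_assignment(C, cls = 1:2, A = NULL,
                                     perm_global = integer(2),
                                     structure_priority = FALSE)
  expect_equal(g, c(1L, 2L))                 # cost 100
  h <- hungarian_assignment(C)
  expect_equal(h, c(2L, 1L))                 # cost 11
  expect_gt(sum(C[cbind(1:2, g)]), sum(C[cbind(1:2, h)]))
})

test_that("zero distortion at the true axis recovers the true permutation", {
  mol <- make_symmetric("c4", 1, seed = 6)
  g <- center_geometry(mol)
  op <- generator_operation("c4", c(0, 0, 1))
  perm <- assignment_for_direction(g, op, equivalence_partition(mol))
  expect_equal(sort(csmeasure:::perm_cycle_lengths(perm)), 4)
  expect_lt(csm_functional(g, symmetrize(g, perm, op)), 1e-10)
})

test_that("cycle repair collapses inadmissible cycles to fixed points", {
  expect_equal(repair_cycles(c(2, 3, 1, 5, 4), 2L), c(1, 2, 3, 5, 4))
  expect_equal(repair_cycles(c(2, 3, 1, 5, 4), 3L), c(2, 3, 1, 4, 5))
  expect_equal(repair_cycles(1:4, 6L), 1:4)
})

test_that("refinement converges and its accepted values never increase", {
  mol <- make_symmetric("c3", 2, seed = 31)
  g <- center_geometry(mol)
  r <- refine_direction(g, "c3", c(0, 0, 1), equivalence_partition(mol))
  expect_lt(r$value, 1e-8)
  expect_true(attr(r, "converged"))
  for (seed in c(5, 6)) {
    m <- perturb(make_symmetric("c4", 2, seed = seed, orient = TRUE),
                 0.05, seed = seed)
    rr <- refine_direction(center_geometry(m), "c4", c(1, 0, 0),
                           equivalence_partition(m))
    tr <- attr(rr, "trace")
    expect_true(all(diff(tr) <= 0))
  }
})

test_that("approximate values upper-bound the exact minimum", {
  for (seed in 1:6) {
    m <- random_molecule(seed + 300)
    lab <- c("c2", "c3", "cs")[(seed %% 3) + 1]
    ex <- exact_csm(m, lab)$value
    for (alg in c("hungarian", "greedy")) {
      ap <- approx_csm(m, lab, algorithm = alg)$value
      expect_gte(ap, ex - 1e-8)
    }
  }
  # perturbed square ring: approx finds the exact optimum
  m <- perturb(make_symmetric("c4", 1, seed = 13), 0.01, seed = 4)
  expect_equal(approx_csm(m, "c4")$value, exact_csm(m, "c4")$value,
               tolerance = 1e-6)
})

test_that("approximate search is deterministic and benefits from more starts", {
  m <- perturb(make_symmetric("c3", 2, seed = 44, orient = TRUE), 0.02, seed = 1)
  r1 <- approx_csm(m, "c3", directions = fibonacci_sphere(20))
  r2 <- approx_csm(m, "c3", directions = fibonacci_sphere(20))
  expect_identical(r1$perm, r2$perm)
  expect_identical(r1$value, r2$value)
  A <- cartesian_directions()
  B <- fibonacci_sphere(10)
  vu <- approx_csm(m, "c3", directions = rbind(A, B))$value
  expect_lte(vu, approx_csm(m, "c3", directions = A)$value + 1e-10)
  expect_lte(vu, approx_csm(m, "c3", directions = B)$value + 1e-10)
})

test_that("fibonacci seeding can beat the cartesian triple on oblique axes", {
  # symmetric fixture rotated so its axis is far from x, y and z
  mol <- make_symmetric("c3", 3, seed = 77, orient = TRUE)
  vals_fib <- approx_csm(mol, "c3", directions = fibonacci_sphere(50))$value
  vals_cart <- approx_csm(mol, "c3")$value
  expect_lte(vals_fib, vals_cart + 1e-10)
})
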