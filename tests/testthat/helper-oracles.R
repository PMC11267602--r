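# Independent oracles used across the suite.  These deliberately avoid the
# analytic axis solver and the pruned enumeration: axis minima come from a
# dense Fibonacci grid plus Nelder-Mead polish of the symmetrize-based
# functional, and permutation minima from filtering ALL n! permutations.

# all permutations of 1..n as rows (Heap's algorithm), cached
.perm_cache <- new.env()
all_permutations <- function(n) {
  key <- as.character(n)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  out <- matrix(0L, factorial(n), n)
  row <- 0L
  a <- seq_len(n)
  c <- rep(1L, n)
  out[row <- row + 1L, ] <- a
  i <- 1L
  while (i <= n) {
    if (c[i] < i) {
      if (i %% 2L == 1L) { tmp <- a[1]; a[1] <- a[i]; a[i] <- tmp }
      else { tmp <- a[c[i]]; a[c[i]] <- a[i]; a[i] <- tmp }
      out[row <- row + 1L, ] <- a
      c[i] <- c[i] + 1L
      i <- 1L
    } else {
      c[i] <- 1L
      i <- i + 1L
    }
  }
  .perm_cache[[key]] <- out
  out
}

# direct CSM evaluation: symmetrize + functional (no B/w algebra)
direct_value <- function(geom, perm, group, axis) {
  op <- generator_operation(group, axis)
  csm_functional(geom, symmetrize(geom, perm, op))
}

# axis minimum for a fixed permutation: grid + polish
oracle_axis_min <- function(geom, perm, group, ngrid = 300) {
  group <- point_group(group)
  if (group$kind == "CI") return(direct_value(geom, perm, group, c(0, 0, 1)))
  D <- fibonacci_sphere(ngrid)
  vals <- apply(D, 1, function(ax) direct_value(geom, perm, group, ax))
  b <- which.min(vals)
  ang <- c(acos(max(-1, min(1, D[b, 3]))), atan2(D[b, 2], D[b, 1]))
  o <- stats::optim(ang, function(a)
    direct_value(geom, perm, group,
                 c(sin(a[1]) * cos(a[2]), sin(a[1]) * sin(a[2]), cos(a[1]))),
    method = "Nelder-Mead", control = list(reltol = 1e-15, maxit = 3000))
  min(o$value, vals[b])
}

# brute-force exact CSM: every n! permutation, validity-filtered; axis minima
# from a coarse grid for ranking, polished for the best few permutations
oracle_exact_csm <- function(mol, group, ngrid = 300, polish_top = 5) {
  group <- point_group(group)
  geom <- center_geometry(mol)
  part <- equivalence_partition(mol)
  n <- n_atoms(mol)
  P <- all_permutations(n)
  valid <- P[apply(P, 1, validate_permutation, group = group,
                   partition = part), , drop = FALSE]
  if (!nrow(valid)) stop("no valid permutation")
  coarse <- apply(valid, 1, function(p) {
    if (group$kind == "CI") return(direct_value(geom, p, group, c(0, 0, 1)))
    D <- fibonacci_sphere(60)
    min(apply(D, 1, function(ax) direct_value(geom, p, group, ax)))
  })
  top <- order(coarse)[seq_len(min(polish_top, nrow(valid)))]
  min(vapply(top, function(k)
    oracle_axis_min(geom, valid[k, ], group, ngrid), numeric(1)))
}

# deterministic random test molecule: 4-7 atoms, mixed elements
random_molecule <- function(seed, nmin = 4, nmax = 7) {
  csmeasure:::with_seed(seed, {
    n <- sample(nmin:nmax, 1)
    el <- sample(c("C", "C", "N", "O"), n, replace = TRUE)
    csm_molecule(el, matrix(stats::rnorm(3 * n, sd = 1.5), ncol = 3))
  })
}

# groups cycled through by the random-molecule checks
oracle_groups <- c("c2", "c3", "c4", "cs", "ci", "s4", "s6")

random_rotation <- function(seed) {
  csmeasure:::with_seed(seed, {
    ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
    csmeasure:::rotation_matrix(ax, stats::runif(1, 0, 2 * pi))
  })
}
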