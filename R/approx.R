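#' Fibonacci-sphere direction set
#'
#' Deterministic spiral lattice of `n` near-uniform unit vectors on the
#' sphere, used to seed the axis search of the approximate algorithm.
#'
#' @param n positive integer.
#' @return n x 3 matrix of unit vectors.
#' @export
fibonacci_sphere <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 1) stop("n must be a positive integer")
  i <- seq_len(n) - 1
  z <- 1 - 2 * (i + 0.5) / n
  r <- sqrt(pmax(0, 1 - z^2))
  golden <- pi * (3 - sqrt(5))
  phi <- i * golden
  cbind(r * cos(phi), r * sin(phi), z)
}

#' The three Cartesian start directions
#' @return 3 x 3 matrix of unit vectors (x, y, z).
#' @export
cartesian_directions <- function() diag(3)

#' Build a permutation for a fixed symmetry-element direction
#'
#' Rotates every atom by the group generator about the current axis and
#' matches rotated atoms to original atoms within each equivalence class:
#' `hungarian` minimises the total squared distance of the class assignment,
#' `greedy` repeatedly commits the globally closest unmatched pair, and
#' `structure_priority` is the greedy scheme that refuses pairings breaking
#' bond preservation against already-committed pairs (falling back to the
#' cheapest pair when none is consistent).  The raw assignment is then
#' repaired to an admissible cycle structure: cycles whose length does not
#' divide the group order are collapsed to fixed points.
#'
#' @param geom a `csm_geometry`.
#' @param op generator `csm_symmetry_operation` at the current axis.
#' @param partition a `csm_partition`.
#' @param algorithm `"hungarian"`, `"greedy"` or `"structure_priority"`.
#' @param bonds bond matrix (used by `structure_priority`).
#' @return admissible permutation vector.
#' @export
assignment_for_direction <- function(geom, op, partition,
                                     algorithm = c("hungarian", "greedy",
                                                   "structure_priority"),
                                     bonds = NULL) {
  algorithm <- match.arg(algorithm)
  P <- geom$coords
  RP <- P %*% t(op$matrix)               # op applied to each atom
  n <- nrow(P)
  perm <- integer(n)
  A <- NULL
  if (algorithm == "structure_priority") {
    if (is.null(bonds)) stop("structure_priority requires bonds")
    b <- canonical_bonds(bonds, n)
    A <- matrix(FALSE, n, n)
    if (nrow(b)) { A[b] <- TRUE; A[b[, c(2, 1), drop = FALSE]] <- TRUE }
  }
  for (cls in partition) {
    m <- length(cls)
    if (m == 1L) { perm[cls] <- cls; next }
    # cost[i, j] = || op P_cls[i] - P_cls[j] ||^2
    D <- outer(rowSums(RP[cls, , drop = FALSE]^2),
               rowSums(P[cls, , drop = FALSE]^2), `+`) -
      2 * RP[cls, , drop = FALSE] %*% t(P[cls, , drop = FALSE])
    if (algorithm == "hungarian") {
      a <- hungarian_assignment(D)
      perm[cls] <- cls[a]
    } else {
      perm[cls] <- cls[greedy_assignment(D, cls, A, perm,
                                         structure_priority = !is.null(A))]
    }
  }
  repair_cycles(perm, op$group$group_order_h)
}

# Greedy pairing on a class cost matrix; with structure_priority, a pairing
# (i -> j) is consistent when for every committed (u -> v) in the whole
# molecule, bond(i, u) == bond(j, v).
greedy_assignment <- function(D, cls, A, perm_global, structure_priority) {
  m <- nrow(D)
  a <- integer(m)
  rows <- seq_len(m); colsfree <- rep(TRUE, m); rowsfree <- rep(TRUE, m)
  committed <- which(perm_global != 0L)
  ord <- order(D)
  consistent <- function(i, j) {
    for (u in committed) {
      if (A[cls[i], u] != A[cls[j], perm_global[u]]) return(FALSE)
    }
    for (k in which(!rowsfree)) {
      if (A[cls[i], cls[k]] != A[cls[j], cls[a[k]]]) return(FALSE)
    }
    TRUE
  }
  for (pass in 1:2) {
    for (idx in ord) {
      if (!any(rowsfree)) break
      i <- ((idx - 1L) %% m) + 1L
      j <- ((idx - 1L) %/% m) + 1L
      if (!rowsfree[i] || !colsfree[j]) next
      if (structure_priority && pass == 1L && !consistent(i, j)) next
      a[i] <- j; rowsfree[i] <- FALSE; colsfree[j] <- FALSE
    }
    if (!any(rowsfree)) break
  }
  a
}

#' Collapse inadmissible cycles to fixed points
#'
#' Cycles of the raw assignment whose length does not divide the group order
#' are broken into fixed points (the conservative repair: the result is
#' always admissible).
#'
#' @param perm permutation vector.
#' @param h group order.
#' @return repaired permutation.
#' @export
repair_cycles <- function(perm, h) {
  n <- length(perm)
  seen <- logical(n)
  for (i in seq_len(n)) {
    if (seen[i]) next
    cyc <- i; j <- perm[i]
    while (j != i) { cyc <- c(cyc, j); j <- perm[j] }
    seen[cyc] <- TRUE
    if (h %% length(cyc) != 0L) perm[cyc] <- cyc
  }
  perm
}

#' Alternating direction-permutation refinement
#'
#' From a start axis, alternates [assignment_for_direction()] (permutation for
#' the current axis) with [optimal_axis()] (axis for the current permutation)
#' until the improvement drops below `tol` or `max_iter` sweeps; returns the
#' best (value, permutation, axis) visited.  An iteration that fails to
#' improve terminates the loop, so the sequence of accepted values is
#' non-increasing.
#'
#' @param geom a `csm_geometry`.
#' @param group point group (label or object).
#' @param start_axis unit 3-vector.
#' @param partition a `csm_partition`.
#' @param algorithm assignment algorithm, see [assignment_for_direction()].
#' @param bonds bonds for `structure_priority`.
#' @param tol convergence tolerance on the measure (default 1e-10).
#' @param max_iter maximum alternations (default 50).
#' @return a `csm_result` with attributes `"trace"` (accepted values) and
#'   `"converged"`.
#' @export
refine_direction <- function(geom, group, start_axis, partition,
                             algorithm = "hungarian", bonds = NULL,
                             tol = 1e-10, max_iter = 50L) {
  group <- point_group(group)
  axis <- start_axis / sqrt(sum(start_axis^2))
  best <- NULL
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    op <- generator_operation(group, axis)
    perm <- assignment_for_direction(geom, op, partition, algorithm, bonds)
    r <- csm_for_permutation(geom, perm, group,
                             algorithm = paste0("approx/", algorithm))
    gain <- if (is.null(best)) Inf else best$value - r$value
    if (gain <= 0) { converged <- TRUE; break }    # no improvement: stop
    best <- r
    trace <- c(trace, r$value)
    axis <- r$axis
    if (gain < tol || best$value < 1e-14) { converged <- TRUE; break }
  }
  attr(best, "trace") <- trace
  attr(best, "converged") <- converged
  best
}

#' Approximate CSM via the direction-permutation approach
#'
#' Runs the alternating refinement from every start direction (by default the
#' three Cartesian axes; optionally a Fibonacci-sphere set) and, for proper
#' rotations of order > 2, from both orientations of each axis, returning the
#' best result.  Deterministic for fixed options.
#'
#' @param mol a `csm_molecule`.
#' @param group point group (label or object); `"ch"` dispatches to [ccm()].
#' @param algorithm `"hungarian"` (default), `"greedy"` or
#'   `"structure_priority"` (the approximate keep-structure scheme).
#' @param directions matrix of start directions (rows), or `NULL` for the
#'   Cartesian triple; see [fibonacci_sphere()].
#' @param ignore_sym single equivalence class instead of per-element classes.
#' @param tol,max_iter refinement controls, see [refine_direction()].
#' @param weights centering weights.
#' @return a `csm_result`.
#' @export
approx_csm <- function(mol, group, algorithm = "hungarian", directions = NULL,
                       ignore_sym = FALSE, tol = 1e-10, max_iter = 50L,
                       weights = "uniform") {
  group <- point_group(group)
  if (group$kind == "CH")
    return(ccm(mol, solver = function(m, g, ...)
      approx_csm(m, g, algorithm = algorithm, directions = directions,
                 ignore_sym = ignore_sym, tol = tol, max_iter = max_iter,
                 weights = weights)))
  if (is.null(directions)) directions <- cartesian_directions()
  directions <- as.matrix(directions)
  if (!nrow(directions)) stop("directions must be nonempty")
  geom <- center_geometry(mol, weights)
  partition <- equivalence_partition(mol, ignore_sym = ignore_sym)
  bonds <- NULL
  if (algorithm == "structure_priority") {
    bonds <- mol$bonds
    if (nrow(bonds) == 0) {
      message("structure_priority with no stored bonds: inferring connectivity")
      bonds <- infer_bonds(mol)
    }
  }
  both_signs <- group$kind == "CN" && group$order_n > 2
  best <- NULL
  for (d in seq_len(nrow(directions))) {
    starts <- list(directions[d, ])
    if (both_signs) starts <- c(starts, list(-directions[d, ]))
    for (s in starts) {
      r <- refine_direction(geom, group, s, partition, algorithm, bonds,
                            tol = tol, max_iter = max_iter)
      if (is.null(best) || r$value < best$value) best <- r
    }
  }
  best
}
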