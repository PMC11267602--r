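#' Construct a geometry from coordinates taken as already centered
#'
#' Low-level constructor: the coordinates are used exactly as given and the
#' CSM normalisation `sum ||P_i||^2` is computed from them directly.  Use
#' [center_geometry()] for the standard pipeline, which translates the
#' centroid to the origin first; this constructor exists for closed-form
#' checks where the deviation from a non-centroid origin is itself the
#' quantity of interest.
#'
#' @param coords n x 3 numeric matrix.
#' @return a `csm_geometry`.
#' @export
csm_geometry <- function(coords) {
  P <- as.matrix(coords)
  if (ncol(P) != 3 || nrow(P) < 2) stop("coords must be n x 3 with n >= 2")
  nsq <- sum(P^2)
  if (nsq < 1e-20) stop("degenerate geometry: all atoms at the origin")
  structure(list(coords = P, norm_sq = nsq, weights = "as_given",
                 center = c(0, 0, 0)),
            class = "csm_geometry")
}

#' Center a molecular geometry at the origin
#'
#' Translates the coordinates so that the (uniform or mass-weighted) centroid
#' sits at the origin and records the squared norm used to normalise the
#' symmetry measure.
#'
#' @param mol a `csm_molecule`, or a bare n x 3 coordinate matrix.
#' @param weights `"uniform"` (geometric centroid, the default) or `"mass"`.
#' @return a `csm_geometry`: list with `coords` (n x 3, centered), `norm_sq`
#'   (sum of squared centered coordinates, Angstrom^2) and `weights`.
#' @export
center_geometry <- function(mol, weights = c("uniform", "mass")) {
  weights <- match.arg(weights)
  if (inherits(mol, "csm_molecule")) {
    P <- coords(mol)
    w <- if (weights == "mass") atomic_mass(mol$atoms$element) else rep(1, nrow(P))
  } else {
    P <- as.matrix(mol)
    w <- rep(1, nrow(P))
    if (weights == "mass")
      stop("mass weighting needs a csm_molecule (element symbols)")
  }
  if (nrow(P) < 2) stop("need at least 2 atoms")
  ctr <- colSums(P * w) / sum(w)
  P <- sweep(P, 2, ctr)
  nsq <- sum(P^2)
  if (nsq < 1e-20)
    stop("degenerate geometry: all atoms coincide")
  structure(list(coords = P, norm_sq = nsq, weights = weights, center = ctr),
            class = "csm_geometry")
}

#' Equivalence partition of the atoms
#'
#' Atoms may only be interchanged within an equivalence class.  The default
#' groups atoms by chemical element; `ignore_sym = TRUE` places all atoms in
#' a single class (a pure shape descriptor).
#'
#' @param mol a `csm_molecule`.
#' @param ignore_sym logical; treat all atoms as chemically equivalent.
#' @return a `csm_partition`: list of integer index vectors (disjoint, covering
#'   all atoms), with attribute `basis`.
#' @export
equivalence_partition <- function(mol, ignore_sym = FALSE) {
  n <- n_atoms(mol)
  if (ignore_sym) {
    classes <- list(seq_len(n))
    basis <- "all_equivalent"
  } else {
    classes <- split(seq_len(n), mol$atoms$element)
    classes <- classes[order(vapply(classes, min, 1L))]
    names(classes) <- NULL
    basis <- "element_only"
  }
  structure(classes, basis = basis, n_atoms = n, class = "csm_partition")
}

# class id per atom, from a partition
class_ids <- function(partition) {
  n <- attr(partition, "n_atoms")
  id <- integer(n)
  for (k in seq_along(partition)) id[partition[[k]]] <- k
  id
}

# cycle lengths of a permutation vector (perm[i] = image of i)
perm_cycle_lengths <- function(perm) {
  n <- length(perm)
  seen <- logical(n)
  out <- integer(0)
  for (i in seq_len(n)) {
    if (seen[i]) next
    len <- 0L; j <- i
    repeat {
      seen[j] <- TRUE; len <- len + 1L; j <- perm[j]
      if (j == i) break
    }
    out <- c(out, len)
  }
  out
}

#' Validate a permutation against a point group
#'
#' A permutation is admissible for a group of order `h` when (a) every cycle
#' length divides `h`, (b) it maps each equivalence class into itself, and
#' (c) with `keep_structure`, it is an automorphism of the bond graph: bonded
#' pairs map exactly onto bonded pairs.
#'
#' @param perm integer vector, `perm[i]` = 1-based image of atom `i`.
#' @param group a point group (label or `csm_point_group`).
#' @param partition optional `csm_partition`.
#' @param bonds optional bond matrix (required when `keep_structure`).
#' @param keep_structure logical.
#' @return `TRUE` or `FALSE`.
#' @export
validate_permutation <- function(perm, group, partition = NULL, bonds = NULL,
                                 keep_structure = FALSE) {
  group <- point_group(group)
  n <- length(perm)
  if (!identical(sort(as.integer(perm)), seq_len(n))) return(FALSE)
  h <- group$group_order_h
  if (any(h %% perm_cycle_lengths(perm) != 0L)) return(FALSE)
  if (!is.null(partition)) {
    id <- class_ids(partition)
    if (any(id[perm] != id)) return(FALSE)
  }
  if (keep_structure) {
    if (is.null(bonds)) stop("keep_structure requires bonds")
    b <- canonical_bonds(bonds, n)
    key <- function(i, j) paste(pmin(i, j), pmax(i, j))
    orig <- key(b[, 1], b[, 2])
    img <- key(perm[b[, 1]], perm[b[, 2]])
    if (!setequal(orig, img) || length(unique(img)) != length(img)) return(FALSE)
  }
  TRUE
}

#' Symmetrize a geometry under (permutation, operation)
#'
#' Group-averages the permuted, back-rotated coordinates:
#' `Q[i,] = (1/h) * sum_k G^(-k) P[perm^k(i),]`.  The result is exactly
#' invariant under the group: `Q[perm(i),] = G Q[i,]`.
#'
#' @param geom a `csm_geometry`.
#' @param perm admissible permutation vector.
#' @param op a `csm_symmetry_operation` (the generator).
#' @return n x 3 matrix of symmetrized coordinates.
#' @export
symmetrize <- function(geom, perm, op) {
  P <- geom$coords
  h <- op$group$group_order_h
  Q <- P                       # k = 0 term
  pk <- seq_len(nrow(P))
  for (k in seq_len(h - 1)) {
    pk <- perm[pk]             # perm^k
    Gk <- operation_power(op, -k)
    Q <- Q + P[pk, , drop = FALSE] %*% t(Gk)
  }
  Q / h
}

#' The CSM functional
#'
#' `100 * sum_i ||P_i - Q_i||^2 / sum_i ||P_i||^2` for a centered geometry
#' `P` and a candidate symmetric structure `Q`.  Zero for perfect symmetry;
#' 100 when the nearest symmetric structure collapses to the origin.
#'
#' @param geom a `csm_geometry`.
#' @param Q n x 3 matrix.
#' @return value in `[0, 100]`.
#' @export
csm_functional <- function(geom, Q) {
  100 * sum((geom$coords - Q)^2) / geom$norm_sq
}

# --- analytic axis optimisation -------------------------------------------
#
# For a fixed admissible permutation the measure is
#   S(m)/100 = ((h-1)*|P|^2 - f(m)) / (h*|P|^2)
# where f(m) = sum_{k=1}^{h-1} sum_i P_i' Gk(m)^T ... collects, via the
# Rodrigues expansion of each group element, into
#   f(m) = const + m' B m + w' m ,  |m| = 1 .
# Maximising a quadratic-plus-linear form on the unit sphere is a 3x3
# trust-region-style subproblem solved from the eigen-decomposition of B and
# a secular equation in the Lagrange multiplier.

# Build (const, B, w) for group of order h about a free axis.
axis_objective_parts <- function(geom, perm, group) {
  P <- geom$coords
  n <- nrow(P)
  h <- group$group_order_h
  improper <- is_improper_group(group)
  theta <- 2 * pi / group$order_n
  cnst <- 0
  B <- matrix(0, 3, 3)
  w <- numeric(3)
  pk <- seq_len(n)
  for (k in seq_len(h - 1)) {
    pk <- perm[pk]                       # y_i = P[perm^k(i)]
    Y <- P[pk, , drop = FALSE]
    odd_improper <- improper && (k %% 2 == 1)
    ck <- cos(k * theta)
    sk <- -sin(k * theta)                # coefficient of [m]_x in G^{-k}
    gk <- if (odd_improper) -(1 + ck) else (1 - ck)
    # sum_i x_i . y_i
    cnst <- cnst + ck * sum(P * Y)
    # sum_i x_i' [m]_x y_i = m . sum_i (y_i x x_i)
    V <- cbind(Y[, 2] * P[, 3] - Y[, 3] * P[, 2],
               Y[, 3] * P[, 1] - Y[, 1] * P[, 3],
               Y[, 1] * P[, 2] - Y[, 2] * P[, 1])
    w <- w + sk * colSums(V)
    # sum_i (m.x_i)(m.y_i) = m' Sym(X'Y) m
    M <- crossprod(P, Y)
    B <- B + gk * (M + t(M)) / 2
  }
  list(const = cnst, B = B, w = w, h = h)
}

# Maximise m'Bm + w'm over the unit sphere.  Returns list(axis, fmax).
max_quadratic_on_sphere <- function(B, w) {
  es <- eigen(B, symmetric = TRUE)
  d <- es$values            # decreasing
  E <- es$vectors
  wt <- drop(crossprod(E, w))
  scale <- max(abs(d), sum(abs(w)), 1)
  f_of <- function(m) drop(crossprod(m, B %*% m) + crossprod(w, m))
  if (sqrt(sum(w^2)) < 1e-13 * scale) {
    m <- E[, 1]
    return(list(axis = m, fmax = f_of(m)))
  }
  # stationary: (2B - 2*lam I) m = -w  =>  m_j = wt_j / (2(lam - d_j)),
  # with the maximiser at the root lam >= d1 of |m(lam)| = 1.
  phi <- function(lam) sum((wt / (2 * (lam - d)))^2) - 1
  d1 <- d[1]
  top <- abs(d - d1) <= 1e-10 * scale
  hard <- all(abs(wt[top]) < 1e-11 * sqrt(sum(w^2)))
  if (hard) {
    rest <- !top
    s0 <- sum((wt[rest] / (2 * (d1 - d[rest])))^2)
    if (s0 <= 1) {
      mt <- numeric(3)
      mt[rest] <- wt[rest] / (2 * (d1 - d[rest]))
      mt[which(top)[1]] <- sqrt(max(0, 1 - s0))
      m <- drop(E %*% mt)
      m <- m / sqrt(sum(m^2))
      return(list(axis = m, fmax = f_of(m)))
    }
  }
  # bracket the root in (d1, d1 + |w|/2]
  wn <- sqrt(sum(w^2))
  eps <- max(1e-14 * max(1, abs(d1)), 1e-300)
  lo <- d1 + eps
  while (phi(lo) <= 0 && eps < wn) { eps <- eps * 10; lo <- d1 + eps }
  hi <- d1 + wn / 2 + 1e-12 * scale
  if (phi(lo) <= 0) {
    # numerically at the boundary: fall back to top eigenvector
    m <- E[, 1]
    return(list(axis = m, fmax = f_of(m)))
  }
  lam <- stats::uniroot(phi, c(lo, hi), tol = 1e-14 * max(1, abs(d1)))$root
  mt <- wt / (2 * (lam - d))
  m <- drop(E %*% mt)
  m <- m / sqrt(sum(m^2))
  list(axis = m, fmax = f_of(m))
}

# axis sign convention: first component > 1e-8 in absolute value is positive,
# applied only when the objective is sign-symmetric.
canonical_axis <- function(axis, sign_free) {
  if (!sign_free) return(axis)
  for (c in axis) {
    if (abs(c) > 1e-8) return(if (c < 0) -axis else axis)
  }
  axis
}

#' Optimal symmetry-element direction for a fixed permutation
#'
#' Finds, analytically, the axis of the group generator minimising the CSM
#' over all unit directions, for the given admissible permutation.  For Ci
#' (inversion) the axis is immaterial and `(0, 0, 1)` is reported.
#'
#' @param geom a `csm_geometry`.
#' @param perm admissible permutation vector.
#' @param group point group (label or object).
#' @return list with `op` (a `csm_symmetry_operation` at the optimal axis)
#'   and `value` (the CSM).
#' @export
optimal_axis <- function(geom, perm, group) {
  group <- point_group(group)
  parts <- axis_objective_parts(geom, perm, group)
  h <- parts$h
  if (group$kind == "CI") {
    axis <- c(0, 0, 1)
    fmax <- parts$const
  } else {
    sol <- max_quadratic_on_sphere(parts$B, parts$w)
    wterm <- abs(sum(parts$w * sol$axis))
    axis <- canonical_axis(sol$axis, sign_free = wterm < 1e-9 * max(1, abs(sol$fmax)))
    fmax <- parts$const + sol$fmax
  }
  value <- 100 * ((h - 1) * geom$norm_sq - fmax) / (h * geom$norm_sq)
  value <- min(100, max(0, value))
  list(op = generator_operation(group, axis), value = value)
}

#' CSM of a single permutation
#'
#' Composes [optimal_axis()], [symmetrize()] and [csm_functional()]: optimises
#' the symmetry-element direction for the permutation, builds the nearest
#' symmetric structure, and evaluates the measure.  The trivial calculation
#' is this function with the identity permutation.
#'
#' @param geom a `csm_geometry`.
#' @param perm admissible permutation vector.
#' @param group point group (label or object).
#' @param algorithm provenance string stored in the result.
#' @return a `csm_result`; see [csm_result()].
#' @export
csm_for_permutation <- function(geom, perm, group, algorithm = "trivial") {
  group <- point_group(group)
  opt <- optimal_axis(geom, perm, group)
  Q <- symmetrize(geom, perm, opt$op)
  value <- csm_functional(geom, Q)
  csm_result(value = value, perm = perm, op = opt$op,
             nearest = Q, group = group, algorithm = algorithm)
}

#' Construct a CSM result object
#'
#' @param value the measure, in `[0, 100]`.
#' @param perm permutation vector (1-based images).
#' @param op the generator `csm_symmetry_operation` at the optimal axis.
#' @param nearest n x 3 coordinates of the nearest symmetric structure
#'   (centered frame).
#' @param group the target point group.
#' @param algorithm provenance string (`"exact"`, `"approx"`, `"trivial"`, ...).
#' @param subgroup for CCM results, which Sn attained the minimum.
#' @export
csm_result <- function(value, perm, op, nearest, group, algorithm,
                       subgroup = NULL) {
  structure(list(value = value, perm = as.integer(perm), op = op,
                 axis = op$axis, nearest = nearest, group = group,
                 algorithm = algorithm, subgroup = subgroup),
            class = "csm_result")
}

#' @export
print.csm_result <- function(x, ...) {
  lab <- x$group$label
  if (!is.null(x$subgroup)) lab <- paste0(lab, " (min at ", x$subgroup$label, ")")
  cat(sprintf("S(%s) = %.6f   [%s]\n", lab, x$value, x$algorithm))
  cat(sprintf("  axis: (%.6f, %.6f, %.6f)\n", x$axis[1], x$axis[2], x$axis[3]))
  cat("  permutation:", paste(x$perm, collapse = " "), "\n")
  invisible(x)
}

#' @export
as.data.frame.csm_result <- function(x, ...) {
  data.frame(group = x$group$label, value = x$value, algorithm = x$algorithm,
             axis_x = x$axis[1], axis_y = x$axis[2], axis_z = x$axis[3],
             subgroup = if (is.null(x$subgroup)) NA_character_ else x$subgroup$label,
             stringsAsFactors = FALSE)
}

#' Continuous chirality measure
#'
#' Evaluates the CSM with respect to every achiral cyclic group S1 (= Cs),
#' S2 (= Ci), S4, S6, ... up to `sn_max` and returns the minimum; the
#' structure is achiral exactly when the CCM is zero.
#'
#' @param mol a `csm_molecule`.
#' @param sn_max even integer, largest Sn tried (default 8).
#' @param solver function `(mol, group)` returning a `csm_result`; defaults
#'   to [exact_csm()].
#' @param ... passed on to the solver.
#' @return a `csm_result` with `subgroup` naming the minimising Sn.
#' @export
ccm <- function(mol, sn_max = 8L, solver = exact_csm, ...) {
  groups <- expand_ch(sn_max)
  best <- NULL
  errs <- character(0)
  for (g in groups) {
    res <- tryCatch(solver(mol, g, ...), error = function(e) e)
    if (inherits(res, "error")) {
      errs <- c(errs, paste0(g$label, ": ", conditionMessage(res)))
      next
    }
    if (is.null(best) || res$value < best$value) {
      res$subgroup <- g
      best <- res
    }
  }
  if (is.null(best))
    stop("CCM failed for every subgroup:\n  ", paste(errs, collapse = "\n  "))
  best$group <- point_group("ch")
  best
}
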