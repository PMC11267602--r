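#' Parse a point-group label
#'
#' Accepted labels (case-insensitive): `"cs"`, `"ci"`, `"c2"`, `"c3"`, ...,
#' `"s4"`, `"s6"`, ... and `"ch"` (the chirality meta-group, expanded to
#' S1, S2, S4, S6, ... by [ccm()]).  Cs and Ci are represented internally as
#' the rotoreflection groups S1 and S2 so a single improper-generator code
#' path serves Cs, Ci and Sn.
#'
#' @param label character scalar, e.g. `"c3"`.
#' @return a `csm_point_group` with fields `kind` (`"CS"`, `"CI"`, `"CN"`,
#'   `"SN"` or `"CH"`), `order_n` (n of Cn/Sn; 1 for Cs, 2 for Ci) and
#'   `group_order_h` (number of group elements generated).
#' @examples
#' point_group("c3")
#' point_group("S4")
#' @export
point_group <- function(label) {
  if (inherits(label, "csm_point_group")) return(label)
  lab <- tolower(trimws(as.character(label)))
  if (length(lab) != 1 || !nzchar(lab))
    stop("point-group label must be a single non-empty string")
  if (lab == "cs") return(new_point_group("CS", 1L, 2L, "Cs"))
  if (lab == "ci") return(new_point_group("CI", 2L, 2L, "Ci"))
  if (lab == "ch") return(new_point_group("CH", NA_integer_, NA_integer_, "Ch"))
  m <- regmatches(lab, regexec("^([cs])([0-9]+)$", lab))[[1]]
  if (length(m) != 3)
    stop("unrecognised point-group label: '", label, "'")
  n <- as.integer(m[3])
  if (m[2] == "c") {
    if (n < 2) stop("Cn requires n >= 2 (use 'cs'/'ci' for mirror/inversion)")
    return(new_point_group("CN", n, n, paste0("C", n)))
  }
  # s<n>
  if (n == 1L) return(new_point_group("CS", 1L, 2L, "Cs"))
  if (n == 2L) return(new_point_group("CI", 2L, 2L, "Ci"))
  if (n %% 2L != 0L) stop("Sn requires even n (n = 4, 6, 8, ...)")
  new_point_group("SN", n, n, paste0("S", n))
}

new_point_group <- function(kind, n, h, label) {
  structure(list(kind = kind, order_n = n, group_order_h = h, label = label),
            class = "csm_point_group")
}

#' @export
print.csm_point_group <- function(x, ...) {
  cat(sprintf("<point group %s> kind=%s n=%s h=%s\n", x$label, x$kind,
              x$order_n, x$group_order_h))
  invisible(x)
}

is_improper_group <- function(group) group$kind %in% c("CS", "CI", "SN")

#' Rotation matrix about an axis (Rodrigues form)
#' @param axis 3-vector (normalised internally).
#' @param angle radians.
#' @keywords internal
rotation_matrix <- function(axis, angle) {
  m <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, m[3], -m[2], -m[3], 0, m[1], m[2], -m[1], 0), 3, 3)
  diag(3) * cos(angle) + sin(angle) * K + (1 - cos(angle)) * tcrossprod(m)
}

#' Generator operation of a cyclic point group
#'
#' Builds the 3x3 orthogonal matrix generating the group about a given axis:
#' a proper rotation by 2*pi/n for Cn; a rotation by 2*pi/n composed with
#' reflection through the plane normal to the axis for Sn; a pure reflection
#' for Cs; the inversion -I for Ci (axis immaterial).
#'
#' @param group a `csm_point_group` (not `"ch"`, which must be expanded first).
#' @param axis unit 3-vector (normalised internally).
#' @return a `csm_symmetry_operation`: list with `axis`, `angle`, `improper`,
#'   `matrix`.
#' @export
generator_operation <- function(group, axis = c(0, 0, 1)) {
  group <- point_group(group)
  if (group$kind == "CH")
    stop("'ch' is a meta-group; expand it to S1, S2, S4, ... first (see ccm())")
  axis <- as.numeric(axis)
  nrm <- sqrt(sum(axis^2))
  if (!is.finite(nrm) || nrm < 1e-12) stop("axis must be a nonzero 3-vector")
  axis <- axis / nrm
  n <- group$order_n
  theta <- 2 * pi / n
  improper <- is_improper_group(group)
  R <- rotation_matrix(axis, theta)
  if (improper) {
    sigma <- diag(3) - 2 * tcrossprod(axis)   # reflection through plane normal to axis
    R <- sigma %*% R
  }
  structure(list(axis = axis, angle = theta, improper = improper,
                 matrix = R, group = group),
            class = "csm_symmetry_operation")
}

#' @export
print.csm_symmetry_operation <- function(x, ...) {
  cat(sprintf("<symmetry operation %s> axis = (%.6f, %.6f, %.6f)%s\n",
              x$group$label, x$axis[1], x$axis[2], x$axis[3],
              if (x$improper) " [improper]" else ""))
  invisible(x)
}

# Matrix of the k-th group element generated by `op` (k = 0 .. h-1).
# For improper generators, even powers are proper rotations.
operation_power <- function(op, k) {
  h <- op$group$group_order_h
  k <- ((k %% h) + h) %% h
  if (k == 0) return(diag(3))
  theta <- op$angle * k
  R <- rotation_matrix(op$axis, theta)
  if (op$improper && k %% 2 == 1)
    R <- (diag(3) - 2 * tcrossprod(op$axis)) %*% R
  R
}

#' Expand the chirality meta-group into its achiral subgroups
#' @param sn_max even integer; largest Sn considered.
#' @return list of `csm_point_group`: S1 (=Cs), S2 (=Ci), S4, ..., S(sn_max).
#' @keywords internal
expand_ch <- function(sn_max = 8L) {
  if (sn_max < 2) stop("sn_max must be >= 2")
  groups <- list(point_group("cs"), point_group("ci"))
  n <- 4L
  while (n <= sn_max) {
    groups <- c(groups, list(point_group(paste0("s", n))))
    n <- n + 2L
  }
  groups
}
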