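#' Molecule container
#'
#' A molecule is a list with class `"csm_molecule"` holding an ordered atom
#' table and an undirected bond set.  Atom order is preserved exactly as read:
#' every permutation the package reports is expressed against this order.
#'
#' @param element character vector of element symbols.
#' @param xyz numeric matrix (n x 3) of Cartesian coordinates in Angstrom.
#' @param bonds integer matrix (m x 2) of 1-based atom index pairs, or `NULL`.
#' @param chain,resname,resseq,atomname optional per-atom PDB-style metadata.
#' @param source_format one of `"xyz"`, `"pdb"`, `"mol"`, `"sdf"`, `"csm"`.
#' @param model_index 1-based model number within the source file.
#'
#' @return an object of class `csm_molecule` with components `atoms`
#'   (data.frame: element, x, y, z, chain, resname, resseq, atomname) and
#'   `bonds` (2-column integer matrix of unordered pairs, `i < j`).
#' @export
csm_molecule <- function(element, xyz, bonds = NULL,
                         chain = NA_character_, resname = NA_character_,
                         resseq = NA_integer_, atomname = NA_character_,
                         source_format = "xyz", model_index = 1L) {
  xyz <- as.matrix(xyz)
  if (is.null(dim(xyz)) || ncol(xyz) != 3)
    stop("xyz must be an n x 3 matrix")
  n <- nrow(xyz)
  if (length(element) != n)
    stop("element length (", length(element), ") != number of rows of xyz (", n, ")")
  if (!all(is.finite(xyz)))
    stop("coordinates must be finite")
  element <- normalize_element(as.character(element))
  atoms <- data.frame(
    element = element,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    chain = rep_len(as.character(chain), n),
    resname = rep_len(as.character(resname), n),
    resseq = rep_len(as.integer(resseq), n),
    atomname = rep_len(as.character(atomname), n),
    stringsAsFactors = FALSE
  )
  structure(
    list(atoms = atoms,
         bonds = canonical_bonds(bonds, n),
         source_format = source_format,
         model_index = as.integer(model_index)),
    class = "csm_molecule"
  )
}

# Put a bond list into canonical form: 2-column integer matrix, i < j,
# no duplicates, no self loops, all indices within 1..n.
canonical_bonds <- function(bonds, n) {
  if (is.null(bonds) || length(bonds) == 0)
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j"))))
  bonds <- matrix(as.integer(as.matrix(bonds)), ncol = 2)
  if (any(bonds < 1L) || any(bonds > n))
    stop("bond indices out of range 1..", n)
  if (any(bonds[, 1] == bonds[, 2]))
    stop("self-loop in bond list")
  b <- cbind(pmin(bonds[, 1], bonds[, 2]), pmax(bonds[, 1], bonds[, 2]))
  b <- unique(b)
  b <- b[order(b[, 1], b[, 2]), , drop = FALSE]
  dimnames(b) <- list(NULL, c("i", "j"))
  b
}

#' Number of atoms in a molecule
#' @param mol a `csm_molecule`.
#' @export
n_atoms <- function(mol) nrow(mol$atoms)

#' Coordinate matrix of a molecule
#' @param mol a `csm_molecule`.
#' @return n x 3 numeric matrix.
#' @export
coords <- function(mol) {
  m <- as.matrix(mol$atoms[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
}

#' @export
print.csm_molecule <- function(x, ...) {
  cat(sprintf("<csm_molecule> %d atoms, %d bonds, format=%s, model=%d\n",
              n_atoms(x), nrow(x$bonds), x$source_format, x$model_index))
  tab <- table(x$atoms$element)
  cat("  composition:", paste0(names(tab), tab, collapse = " "), "\n")
  invisible(x)
}

#' @export
as.data.frame.csm_molecule <- function(x, ...) x$atoms

# Adjacency logical matrix from the bond set (internal helper).
adjacency_matrix <- function(mol) {
  n <- n_atoms(mol)
  A <- matrix(FALSE, n, n)
  b <- mol$bonds
  if (nrow(b)) {
    A[b] <- TRUE
    A[b[, c(2, 1), drop = FALSE]] <- TRUE
  }
  A
}

#' Replace a molecule's coordinates, keeping everything else
#' @param mol a `csm_molecule`.
#' @param xyz n x 3 numeric matrix.
#' @return the molecule with new coordinates.
#' @export
set_coords <- function(mol, xyz) {
  xyz <- as.matrix(xyz)
  stopifnot(nrow(xyz) == n_atoms(mol), ncol(xyz) == 3)
  mol$atoms$x <- xyz[, 1]; mol$atoms$y <- xyz[, 2]; mol$atoms$z <- xyz[, 3]
  mol
}
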