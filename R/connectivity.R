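#' Infer covalent bonds from interatomic distances
#'
#' Declares a bond between atoms `i` and `j` when their distance does not
#' exceed `tolerance_factor` times the sum of the two covalent radii.
#' Invariant under rigid rotation and translation of the coordinates.
#'
#' @param mol a `csm_molecule`.
#' @param tolerance_factor positive multiplier on the radius sum
#'   (default 1.15, a common perception heuristic).
#' @return 2-column integer bond matrix (canonical form).
#' @export
infer_bonds <- function(mol, tolerance_factor = 1.15) {
  stopifnot(tolerance_factor > 0)
  n <- n_atoms(mol)
  if (n < 2) return(canonical_bonds(NULL, n))
  P <- coords(mol)
  r <- covalent_radius(mol$atoms$element)
  D <- as.matrix(stats::dist(P))
  cutoff <- tolerance_factor * outer(r, r, `+`)
  sel <- which(D <= cutoff & upper.tri(D), arr.ind = TRUE)
  canonical_bonds(sel, n)
}

#' Parse a plain-text connectivity listing
#'
#' Each non-empty line reads `i j k ...`: atom `i` (1-based) is bonded to
#' `j`, `k`, ....  Reciprocal declarations are merged.
#'
#' @param text character vector of lines, or the path of a file.
#' @param n_atoms number of atoms in the already-read molecule.
#' @return 2-column integer bond matrix.
#' @export
parse_connectivity_file <- function(text, n_atoms) {
  if (length(text) == 1 && file.exists(text) && !grepl("\n", text))
    text <- readLines(text, warn = FALSE)
  text <- text[nzchar(trimws(text))]
  if (!length(text)) {
    warning("empty connectivity listing: no bonds", call. = FALSE)
    return(canonical_bonds(NULL, n_atoms))
  }
  edges <- list()
  for (k in seq_along(text)) {
    f <- suppressWarnings(as.integer(strsplit(trimws(text[k]), "\\s+")[[1]]))
    if (anyNA(f))
      stop("connectivity error at line ", k, ": non-integer token")
    if (any(f < 1L | f > n_atoms))
      stop("connectivity error at line ", k, ": atom index out of range 1..",
           n_atoms)
    if (length(f) >= 2)
      edges[[length(edges) + 1L]] <- cbind(f[1], f[-1])
  }
  if (!length(edges)) return(canonical_bonds(NULL, n_atoms))
  canonical_bonds(do.call(rbind, edges), n_atoms)
}

#' Select atoms and/or drop hydrogens
#'
#' Applies the fragment selection first, then hydrogen removal; surviving
#' atoms are re-indexed contiguously and bonds are induced on the surviving
#' set.  When a connectivity file describes the complete structure, attach
#' its bonds to the molecule before calling this.
#'
#' @param mol a `csm_molecule`.
#' @param select_atoms optional 1-based indices of the fragment to keep.
#' @param remove_hy drop hydrogen atoms.
#' @return list with `molecule` (re-indexed fragment) and `index_map`
#'   (integer vector: old index -> new index, `NA` for dropped atoms).
#' @export
apply_selection <- function(mol, select_atoms = NULL, remove_hy = FALSE) {
  n <- n_atoms(mol)
  keep <- rep(FALSE, n)
  if (is.null(select_atoms)) {
    keep[] <- TRUE
  } else {
    sel <- as.integer(select_atoms)
    if (any(sel < 1L | sel > n))
      stop("select_atoms index out of range 1..", n)
    keep[sel] <- TRUE
  }
  if (remove_hy) keep <- keep & mol$atoms$element != "H"
  if (!any(keep)) stop("selection removes every atom")
  idx <- which(keep)
  index_map <- rep(NA_integer_, n)
  index_map[idx] <- seq_along(idx)
  b <- mol$bonds
  if (nrow(b)) {
    kb <- keep[b[, 1]] & keep[b[, 2]]
    b <- cbind(index_map[b[kb, 1]], index_map[b[kb, 2]])
  }
  at <- mol$atoms[idx, , drop = FALSE]
  out <- csm_molecule(at$element, as.matrix(at[, c("x", "y", "z")]),
                      bonds = b, chain = at$chain, resname = at$resname,
                      resseq = at$resseq, atomname = at$atomname,
                      source_format = mol$source_format,
                      model_index = mol$model_index)
  list(molecule = out, index_map = index_map)
}
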