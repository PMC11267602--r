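.amino3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
             "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
             "TYR", "VAL", "MSE", "SEC", "PYL")

.backbone_atoms <- c("N", "CA", "C", "O")   # OXT excluded (termini only)

#' Prepare a protein homo-oligomer for symmetry analysis
#'
#' Retains the selected chains, then the same residue serial numbers in every
#' chain, then (optionally) only the backbone atoms N, CA, C, O.  Non-amino
#' residues (waters, ligands, glycans) are dropped.  Verifies that every
#' chain ends up with the same residue signature (residue name + ordinal) and
#' atom count.
#'
#' @param mol a pdb-derived `csm_molecule` with chain/residue metadata.
#' @param select_chains optional chain-id character vector.
#' @param select_res optional residue serial numbers (same set taken from all
#'   chains).
#' @param use_backbone keep only N, CA, C, O atoms.
#' @return a `csm_homomer`: list with `molecule` (re-indexed), `chains`,
#'   `per_chain_length` and `chain_atoms` (per-chain index lists in matched
#'   order).
#' @export
prepare_homomer <- function(mol, select_chains = NULL, select_res = NULL,
                            use_backbone = FALSE) {
  at <- mol$atoms
  if (all(is.na(at$chain)) || all(is.na(at$resseq)))
    stop("molecule carries no chain/residue metadata; read it from pdb")
  keep <- at$resname %in% .amino3
  if (!is.null(select_chains)) {
    unknown <- setdiff(select_chains, unique(at$chain))
    if (length(unknown))
      stop("unknown chain id(s): ", paste(unknown, collapse = ", "))
    keep <- keep & at$chain %in% select_chains
  }
  if (!is.null(select_res)) keep <- keep & at$resseq %in% select_res
  if (use_backbone) keep <- keep & at$atomname %in% .backbone_atoms
  if (!any(keep)) stop("selection removes every atom")
  sel <- apply_selection(mol, select_atoms = which(keep))
  m <- sel$molecule
  at <- m$atoms
  chains <- unique(at$chain)
  if (length(chains) < 2) stop("need at least 2 chains for a homomer")
  per_chain <- split(seq_len(nrow(at)), factor(at$chain, levels = chains))
  lens <- lengths(per_chain)
  sig <- lapply(per_chain, function(ix) {
    res <- at[ix, ]
    paste(match(res$resseq, unique(res$resseq)), res$resname, res$atomname,
          res$element)
  })
  ref <- sig[[1]]
  for (c in seq_along(sig)[-1]) {
    if (lens[c] != lens[1] || !identical(sig[[c]], ref)) {
      bad <- if (lens[c] != lens[1]) min(lens[c], lens[1]) + 1L
             else which(sig[[c]] != ref)[1]
      bad_res <- at$resseq[per_chain[[c]][min(bad, lens[c])]]
      stop("chains ", chains[1], " and ", chains[c],
           " differ (first mismatch near residue ", bad_res,
           " of chain ", chains[c], "); pre-clean the structure")
    }
  }
  structure(list(molecule = m, chains = chains,
                 per_chain_length = lens[[1]],
                 chain_atoms = per_chain),
            class = "csm_homomer")
}

#' @export
print.csm_homomer <- function(x, ...) {
  cat(sprintf("<csm_homomer> %d chains (%s), %d atoms per chain\n",
              length(x$chains), paste(x$chains, collapse = ","),
              x$per_chain_length))
  invisible(x)
}

#' Sequence-based equivalence partition
#'
#' Atoms are equivalent exactly when they share residue ordinal, residue
#' type, atom name and element across different chains; after preparation
#' every class holds one atom per chain.
#'
#' @param h a `csm_homomer`.
#' @return a `csm_partition` with basis `"sequence_based"`.
#' @export
sequence_equivalence <- function(h) {
  at <- h$molecule$atoms
  n <- nrow(at)
  ord <- integer(n)
  for (ix in h$chain_atoms) {
    res <- at$resseq[ix]
    ord[ix] <- match(res, unique(res))
  }
  key <- paste(ord, at$resname, at$atomname, at$element)
  classes <- split(seq_len(n), factor(key, levels = unique(key)))
  names(classes) <- NULL
  structure(classes, basis = "sequence_based", n_atoms = n,
            class = "csm_partition")
}

#' Chain-permutation search for homomer CSM
#'
#' Enumerates the chain permutations admissible for the group (cycle lengths
#' dividing the group order; exhaustive for up to 8 chains, Hungarian-matched
#' on chain centroids above that).  Each chain permutation dictates the atom
#' permutation through the matched per-chain atom order; the symmetry-element
#' direction is then optimised analytically and the best result returned.
#' With sequence-based equivalence classes (one atom per chain) the
#' `"assignment"` and `"sequence_dictated"` atom modes coincide.
#'
#' @param h a `csm_homomer`.
#' @param group point group (label or object).
#' @param atom_mode `"assignment"` or `"sequence_dictated"` (equivalent here).
#' @param weights centering weights.
#' @return a `csm_result`; attribute `"chain_perm"` records the winning chain
#'   permutation (indices into `h$chains`).
#' @export
chain_permutation_search <- function(h, group,
                                     atom_mode = c("assignment",
                                                   "sequence_dictated"),
                                     weights = "uniform") {
  atom_mode <- match.arg(atom_mode)
  group <- point_group(group)
  nc <- length(h$chains)
  geom <- center_geometry(h$molecule, weights)
  chain_perms <- if (nc <= 8) {
    part <- structure(list(seq_len(nc)), basis = "all_equivalent",
                      n_atoms = nc, class = "csm_partition")
    enumerate_valid_permutations(part, group)
  } else {
    list(centroid_chain_permutation(h, group))
  }
  if (!length(chain_perms))
    stop("no chain permutation has cycle lengths dividing the group order ",
         group$group_order_h)
  best <- NULL
  best_cp <- NULL
  for (cp in chain_perms) {
    perm <- atom_perm_from_chain_perm(h, cp)
    r <- csm_for_permutation(geom, perm, group,
                             algorithm = paste0("protein/", atom_mode))
    if (is.null(best) || r$value < best$value) { best <- r; best_cp <- cp }
  }
  attr(best, "chain_perm") <- best_cp
  best
}

# chain perm (indices into h$chains) -> atom permutation via matched order
atom_perm_from_chain_perm <- function(h, chain_perm) {
  n <- nrow(h$molecule$atoms)
  perm <- integer(n)
  for (c in seq_along(h$chains)) {
    src <- h$chain_atoms[[c]]
    dst <- h$chain_atoms[[chain_perm[c]]]
    perm[src] <- dst
  }
  perm
}

# >8 chains: single candidate from Hungarian matching of rotated chain
# centroids, repaired to admissible cycles.
centroid_chain_permutation <- function(h, group) {
  geom <- center_geometry(h$molecule)
  cen <- t(vapply(h$chain_atoms, function(ix)
    colMeans(geom$coords[ix, , drop = FALSE]), numeric(3)))
  # axis from the best of the Cartesian axes on centroids
  best <- NULL
  for (d in seq_len(3)) {
    op <- generator_operation(group, diag(3)[d, ])
    RC <- cen %*% t(op$matrix)
    D <- outer(rowSums(RC^2), rowSums(cen^2), `+`) - 2 * RC %*% t(cen)
    a <- hungarian_assignment(D)
    cost <- sum(D[cbind(seq_len(nrow(D)), a)])
    if (is.null(best) || cost < best$cost) best <- list(a = a, cost = cost)
  }
  repair_cycles(best$a, group$group_order_h)
}

#' Trivial homomer CSM
#'
#' With `use_chains = FALSE`, evaluates the identity atom permutation.  With
#' `use_chains = TRUE`, the chains' permutation is searched but the atom
#' permutation within the chain mapping stays dictated by the sequence.
#'
#' @param h a `csm_homomer`.
#' @param group point group (label or object).
#' @param use_chains search the chain permutation.
#' @param weights centering weights.
#' @return a `csm_result`.
#' @export
trivial_protein_csm <- function(h, group, use_chains = FALSE,
                                weights = "uniform") {
  group <- point_group(group)
  if (use_chains)
    return(chain_permutation_search(h, group, atom_mode = "sequence_dictated",
                                    weights = weights))
  geom <- center_geometry(h$molecule, weights)
  csm_for_permutation(geom, seq_len(nrow(h$molecule$atoms)), group,
                      algorithm = "trivial")
}
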