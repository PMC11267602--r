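# Deterministic generators of test geometries: exactly symmetric structures
# for any supported group, controlled Gaussian perturbations, and synthetic
# protein homomers.  All randomness is seed-parameterised and the global RNG
# state is left untouched.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate an exactly symmetric molecule
#'
#' Places `n_orbits` seed atoms at seeded-random positions and closes each
#' orbit under the group generator (orbit size = group order for generic
#' seeds).  The result has exact symmetry: its CSM for the group is below
#' 1e-10.
#'
#' @param group point group (label or object); not `"ch"`.
#' @param n_orbits number of orbits (default 2).
#' @param elements element symbols, one per orbit (recycled; default a
#'   palette of distinct heavy atoms so each orbit is its own equivalence
#'   class).
#' @param seed integer seed.
#' @param axis generator axis (default z).
#' @param orient apply an additional seeded random rigid rotation.
#' @return a `csm_molecule`.
#' @export
make_symmetric <- function(group, n_orbits = 2L,
                           elements = c("C", "N", "O", "S", "P", "F"),
                           seed = 1L, axis = c(0, 0, 1), orient = FALSE) {
  group <- point_group(group)
  if (group$kind == "CH") stop("pick a concrete group, not 'ch'")
  if (n_orbits < 1) stop("n_orbits >= 1 required")
  elements <- rep_len(elements, n_orbits)
  op <- generator_operation(group, axis)
  h <- group$group_order_h
  with_seed(seed, {
    el <- character(0)
    P <- NULL
    for (k in seq_len(n_orbits)) {
      # seed point in a shell, kept away from the symmetry element
      repeat {
        p <- stats::rnorm(3)
        p <- p / sqrt(sum(p^2)) * stats::runif(1, 1, 2)
        if (sum(p^2) - sum(p * op$axis)^2 > 0.1) break
      }
      orbit <- t(vapply(seq_len(h) - 1L,
                        function(j) drop(operation_power(op, j) %*% p),
                        numeric(3)))
      P <- rbind(P, orbit)
      el <- c(el, rep(elements[k], h))
    }
    if (orient) {
      q <- stats::rnorm(3); q <- q / sqrt(sum(q^2))
      ang <- stats::runif(1, 0, 2 * pi)
      P <- P %*% t(rotation_matrix(q, ang))
    }
    csm_molecule(el, P)
  })
}

#' Gaussian perturbation of a molecule
#'
#' Adds seeded i.i.d. Gaussian displacement with standard deviation `sigma`
#' (Angstrom) to every coordinate; `sigma = 0` is the identity.
#'
#' @param mol a `csm_molecule`.
#' @param sigma displacement standard deviation per coordinate (Angstrom).
#' @param seed integer seed.
#' @return a perturbed `csm_molecule`.
#' @export
perturb <- function(mol, sigma, seed = 1L) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(mol)
  P <- coords(mol)
  noise <- with_seed(seed,
    matrix(stats::rnorm(length(P), sd = sigma), nrow = nrow(P)))
  set_coords(mol, P + noise)
}

#' Generate a synthetic protein homomer
#'
#' Builds one seeded random chain of `n_residues` (atoms N, CA, C, O, CB per
#' residue, residue name ALA, serials 1..n), replicates it by the group
#' operation into `n_chains` chains with ids A, B, C, ..., and perturbs by
#' `sigma`.  With `sigma = 0` and `n_chains` equal to the group order the
#' result is exactly symmetric.
#'
#' @param n_chains number of chains (equal to the group order for exact
#'   closure).
#' @param n_residues residues per chain.
#' @param group point group (default Cn with n = `n_chains`).
#' @param sigma perturbation, Angstrom.
#' @param seed integer seed.
#' @return a `csm_molecule` with pdb-like metadata.
#' @export
make_homomer <- function(n_chains = 3L, n_residues = 5L, group = NULL,
                         sigma = 0, seed = 1L) {
  if (is.null(group)) group <- point_group(paste0("c", n_chains))
  group <- point_group(group)
  op <- generator_operation(group, c(0, 0, 1))
  atoms_per_res <- c("N", "CA", "C", "O", "CB")
  chain_ids <- LETTERS[seq_len(n_chains)]
  mol <- with_seed(seed, {
    # random-walk backbone displaced well away from the symmetry axis
    el <- character(0); nm <- character(0); rs <- integer(0)
    P <- NULL
    base <- c(6, 0, 0)
    pos <- base
    for (r in seq_len(n_residues)) {
      pos <- pos + stats::rnorm(3, sd = 1.2)
      pos[1] <- max(pos[1], 4)           # keep off-axis
      for (a in atoms_per_res) {
        P <- rbind(P, pos + stats::rnorm(3, sd = 0.6))
        el <- c(el, substring(a, 1, 1))
        nm <- c(nm, a)
        rs <- c(rs, r)
      }
    }
    n1 <- nrow(P)
    allP <- NULL; allch <- character(0)
    for (c in seq_len(n_chains) - 1L) {
      allP <- rbind(allP, P %*% t(operation_power(op, c)))
      allch <- c(allch, rep(chain_ids[c + 1L], n1))
    }
    csm_molecule(rep(el, n_chains), allP, chain = allch,
                 resname = "ALA", resseq = rep(rs, n_chains),
                 atomname = rep(nm, n_chains), source_format = "pdb")
  })
  perturb(mol, sigma, seed = seed + 1L)
}
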