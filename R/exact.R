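#' Enumerate admissible permutations
#'
#' Streams every permutation passing [validate_permutation()] exactly once:
#' built class by class, cycle by cycle, with cycle lengths restricted to
#' divisors of the group order.  Each cycle starts at its smallest member so
#' no permutation is produced twice; the order is deterministic (classes
#' ascending by smallest member, partners in ascending lexicographic order).
#' With `keep_structure`, a partial assignment is abandoned as soon as an
#' already-assigned bonded pair maps to a non-bonded pair (or vice versa) —
#' the pruning that makes structure-preserving search tractable.
#'
#' @param partition a `csm_partition`.
#' @param group point group (label or object).
#' @param bonds bond matrix, required when `keep_structure`.
#' @param keep_structure restrict to bond-graph automorphisms.
#' @param visitor optional `function(perm)`; called once per permutation.
#'   Returning `FALSE` stops the enumeration early.  When `NULL`, all
#'   permutations are collected and returned as a list.
#' @return invisibly, the number of permutations emitted; or the list of
#'   permutations when `visitor` is `NULL`.
#' @export
enumerate_valid_permutations <- function(partition, group, bonds = NULL,
                                         keep_structure = FALSE,
                                         visitor = NULL) {
  group <- point_group(group)
  h <- group$group_order_h
  n <- attr(partition, "n_atoms")
  divisors <- which(h %% seq_len(h) == 0L)
  A <- NULL
  if (keep_structure) {
    if (is.null(bonds)) stop("keep_structure requires bonds")
    b <- canonical_bonds(bonds, n)
    A <- matrix(FALSE, n, n)
    if (nrow(b)) { A[b] <- TRUE; A[b[, c(2, 1), drop = FALSE]] <- TRUE }
  }
  collect <- is.null(visitor)
  out <- if (collect) vector("list", 0L) else NULL
  count <- 0L
  stopped <- FALSE

  perm <- rep(NA_integer_, n)
  assigned <- integer(0)       # atoms whose image is already fixed

  # does setting perm[i] = j keep bond structure consistent so far?
  ok_assign <- function(i, j) {
    if (is.null(A)) return(TRUE)
    for (u in assigned) {
      if (A[i, u] != A[j, perm[u]]) return(FALSE)
    }
    TRUE
  }

  emit <- function() {
    count <<- count + 1L
    if (collect) {
      out[[count]] <<- perm
    } else {
      res <- visitor(perm)
      if (identical(res, FALSE)) stopped <<- TRUE
    }
  }

  classes <- lapply(partition, sort)

  # recursive cycle construction within class ci, then next class
  build_class <- function(ci, remaining) {
    if (stopped) return()
    if (!length(remaining)) { next_class(ci + 1L); return() }
    a <- remaining[1]
    rest <- remaining[-1]
    for (L in divisors) {
      if (stopped) return()
      if (L == 1L) {
        if (ok_assign(a, a)) {
          perm[a] <<- a; assigned <<- c(assigned, a)
          build_class(ci, rest)
          perm[a] <<- NA_integer_; assigned <<- assigned[-length(assigned)]
        }
        next
      }
      if (length(rest) < L - 1L) next
      extend_cycle(ci, a, a, rest, L - 1L, rest)
    }
  }

  # grow the cycle started at `start`; `prev` is the last atom placed,
  # `todo` the count of members still to add, `avail` the candidates,
  # `rest_all` the unassigned atoms of the class besides `start`.
  extend_cycle <- function(ci, start, prev, avail, todo, rest_all) {
    if (stopped) return()
    if (todo == 0L) {
      if (ok_assign(prev, start)) {
        perm[prev] <<- start; assigned <<- c(assigned, prev)
        build_class(ci, setdiff(rest_all, used_in_cycle(start)))
        perm[prev] <<- NA_integer_; assigned <<- assigned[-length(assigned)]
      }
      return()
    }
    for (b in avail) {
      if (stopped) return()
      if (!ok_assign(prev, b)) next
      perm[prev] <<- b; assigned <<- c(assigned, prev)
      extend_cycle(ci, start, b, setdiff(avail, b), todo - 1L, rest_all)
      perm[prev] <<- NA_integer_; assigned <<- assigned[-length(assigned)]
    }
  }

  # members of the (complete) cycle through `start`
  used_in_cycle <- function(start) {
    members <- start; j <- perm[start]
    while (!is.na(j) && j != start) { members <- c(members, j); j <- perm[j] }
    members
  }

  next_class <- function(ci) {
    if (stopped) return()
    if (ci > length(classes)) { emit(); return() }
    build_class(ci, classes[[ci]])
  }

  next_class(1L)
  if (collect) out else invisible(count)
}

#' Exact CSM by permutation enumeration
#'
#' Minimises the CSM over all admissible permutations — every class-respecting
#' permutation with cycle lengths dividing the group order, optionally
#' restricted to bond-graph automorphisms (`keep_structure`).  Ties are broken
#' by the first permutation found in the documented deterministic enumeration
#' order.
#'
#' @param mol a `csm_molecule`.
#' @param group point group (label or object); `"ch"` dispatches to [ccm()].
#' @param keep_structure only scan permutations preserving connectivity.
#'   Bonds are taken from the molecule; if it carries none they are inferred
#'   with [infer_bonds()] defaults (a message is emitted).
#' @param ignore_sym treat all atoms as chemically equivalent.
#' @param use_perm optional explicit permutation (1-based images); validated
#'   and used as the single candidate.
#' @param timeout seconds before the search is abandoned (default 300).
#' @param weights centering weights, `"uniform"` or `"mass"`.
#' @return a `csm_result`; attribute `"n_permutations"` counts candidates
#'   examined.
#' @export
exact_csm <- function(mol, group, keep_structure = FALSE, ignore_sym = FALSE,
                      use_perm = NULL, timeout = 300, weights = "uniform") {
  group <- point_group(group)
  if (group$kind == "CH")
    return(ccm(mol, solver = function(m, g, ...)
      exact_csm(m, g, keep_structure = keep_structure,
                ignore_sym = ignore_sym, timeout = timeout,
                weights = weights)))
  geom <- center_geometry(mol, weights)
  partition <- equivalence_partition(mol, ignore_sym = ignore_sym)
  bonds <- mol$bonds
  if (keep_structure && nrow(bonds) == 0) {
    message("keep_structure with no stored bonds: inferring connectivity")
    bonds <- infer_bonds(mol)
  }

  if (!is.null(use_perm)) {
    use_perm <- as.integer(use_perm)
    if (!validate_permutation(use_perm, group, partition,
                              bonds = if (keep_structure) bonds else NULL,
                              keep_structure = keep_structure)) {
      why <- permutation_violation(use_perm, group, partition, bonds,
                                   keep_structure)
      stop("supplied permutation is not admissible: ", why)
    }
    res <- csm_for_permutation(geom, use_perm, group, algorithm = "exact/use-perm")
    attr(res, "n_permutations") <- 1L
    return(res)
  }

  best_value <- Inf
  best_perm <- NULL
  count <- 0L
  timed_out <- FALSE
  t0 <- proc.time()[["elapsed"]]
  visitor <- function(perm) {
    count <<- count + 1L
    v <- optimal_axis(geom, perm, group)$value
    if (v < best_value) { best_value <<- v; best_perm <<- perm }
    if (count %% 256L == 0L &&
        proc.time()[["elapsed"]] - t0 > timeout) {
      timed_out <<- TRUE
      return(FALSE)
    }
    TRUE
  }
  enumerate_valid_permutations(partition, group,
                               bonds = if (keep_structure) bonds else NULL,
                               keep_structure = keep_structure,
                               visitor = visitor)
  if (timed_out)
    stop("exact search abandoned after ", count,
         " permutations (timeout ", timeout, " s)")
  if (is.null(best_perm))
    stop("no admissible permutation exists for ", group$label,
         if (keep_structure) " under keep_structure" else "")
  best <- csm_for_permutation(geom, best_perm, group, algorithm = "exact")
  attr(best, "n_permutations") <- count
  best
}

# human-readable reason a permutation fails validation
permutation_violation <- function(perm, group, partition, bonds,
                                  keep_structure) {
  n <- length(perm)
  if (!identical(sort(as.integer(perm)), seq_len(n)))
    return("not a bijection on 1..n")
  h <- group$group_order_h
  cl <- perm_cycle_lengths(perm)
  if (any(h %% cl != 0L))
    return(sprintf("cycle of length %d does not divide group order %d",
                   cl[which(h %% cl != 0L)[1]], h))
  id <- class_ids(partition)
  if (any(id[perm] != id))
    return("maps atoms across equivalence classes (different elements)")
  if (keep_structure &&
      !validate_permutation(perm, group, bonds = bonds, keep_structure = TRUE))
    return("breaks the bond structure (not a graph automorphism)")
  "unknown violation"
}
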