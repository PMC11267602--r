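#' Write a molecular structure
#'
#' Writes a single molecule in xyz, pdb, mol/sdf (V2000) or the internal csm
#' dialect.  xyz and csm are written with 10 decimal places; pdb and mol/sdf
#' use their fixed-width column precision (3 and 4 decimals respectively, by
#' format definition).  Element sequence and bonds always round-trip exactly.
#'
#' @param mol a `csm_molecule`.
#' @param destination output file path.
#' @param format one of `"xyz"`, `"pdb"`, `"mol"`, `"sdf"`, `"csm"`;
#'   defaults to the molecule's source format.
#' @return `destination`, invisibly.
#' @export
write_structure <- function(mol, destination, format = NULL) {
  if (is.null(format)) format <- mol$source_format
  format <- match.arg(format, c("xyz", "pdb", "mol", "sdf", "csm"))
  switch(format,
    xyz = write_xyz(mol, destination),
    csm = write_csm(mol, destination),
    pdb = write_pdb(mol, destination),
    mol = ,
    sdf = write_sdf(mol, destination))
  invisible(destination)
}

write_xyz <- function(mol, destination) {
  P <- coords(mol)
  lines <- c(
    as.character(n_atoms(mol)),
    "written by csmeasure",
    sprintf("%-3s %17.10f %17.10f %17.10f",
            mol$atoms$element, P[, 1], P[, 2], P[, 3])
  )
  writeLines(lines, destination)
}

write_csm <- function(mol, destination) {
  P <- coords(mol)
  n <- n_atoms(mol)
  A <- adjacency_matrix(mol)
  adj <- vapply(seq_len(n), function(i) {
    nb <- which(A[i, ])
    paste(c(i, nb), collapse = " ")
  }, "")
  lines <- c(
    as.character(n),
    sprintf("%-3s %17.10f %17.10f %17.10f",
            mol$atoms$element, P[, 1], P[, 2], P[, 3]),
    adj
  )
  writeLines(lines, destination)
}

write_pdb <- function(mol, destination) {
  at <- mol$atoms
  n <- n_atoms(mol)
  chain <- ifelse(is.na(at$chain), "A", at$chain)
  resno <- ifelse(is.na(at$resseq), 1L, at$resseq)
  resid <- ifelse(is.na(at$resname), "MOL", at$resname)
  elety <- ifelse(is.na(at$atomname) | !nzchar(at$atomname),
                  at$element, at$atomname)
  bio3d::write.pdb(file = destination,
                   xyz = as.numeric(t(coords(mol))),
                   resno = resno, chain = chain, resid = resid,
                   eleno = seq_len(n), elety = elety,
                   elesy = at$element)
  if (nrow(mol$bonds)) append_conect(destination, mol$bonds, n)
  invisible(destination)
}

# bio3d does not write CONECT records; add them before END.
append_conect <- function(destination, bonds, n) {
  lines <- readLines(destination, warn = FALSE)
  A <- matrix(FALSE, n, n)
  A[bonds] <- TRUE
  A[bonds[, c(2, 1), drop = FALSE]] <- TRUE
  con <- unlist(lapply(seq_len(n), function(i) {
    nb <- which(A[i, ])
    if (!length(nb)) return(character(0))
    sprintf("CONECT%5d%s", i, paste(sprintf("%5d", nb), collapse = ""))
  }))
  end <- grepl("^END", lines)
  writeLines(c(lines[!end], con, lines[end]), destination)
}

# Minimal MDL V2000 writer (coordinates at the format's 4 decimals).
write_sdf <- function(mol, destination) {
  P <- coords(mol)
  n <- n_atoms(mol)
  b <- mol$bonds
  lines <- c(
    "csmeasure",
    "  csmeasure",
    "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nrow(b)),
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            P[, 1], P[, 2], P[, 3], mol$atoms$element)
  )
  if (nrow(b))
    lines <- c(lines, sprintf("%3d%3d  1  0  0  0  0", b[, 1], b[, 2]))
  lines <- c(lines, "M  END", "$$$$")
  writeLines(lines, destination)
}
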