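#' Read molecular structures
#'
#' Reads one or more molecular models from a file in xyz, pdb, mol/sdf (V2000)
#' or the internal csm dialect, or from a directory of such files.
#' Concatenated multi-model files (xyz blocks, SDF records, PDB MODELs) yield
#' one molecule per model.  Formats that carry connectivity (mol/sdf bond
#' block, PDB CONECT, csm adjacency lines) populate the bond set; xyz leaves
#' it empty (see [infer_bonds()]).
#'
#' @param path file (or directory) to read.
#' @param format `"xyz"`, `"pdb"`, `"mol"`, `"sdf"` or `"csm"`; deduced from
#'   the file extension when `NULL`.
#' @param selected_models optional 1-based model indices to retain.
#' @return list of `csm_molecule`.
#' @export
read_structures <- function(path, format = NULL, selected_models = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (dir.exists(path)) {
    files <- sort(list.files(path, full.names = TRUE))
    mols <- unlist(lapply(files, read_structures), recursive = FALSE)
    return(select_models(mols, selected_models))
  }
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      xyz = "xyz", pdb = "pdb", ent = "pdb", mol = "mol", sdf = "sdf",
      sd = "sdf", csm = "csm",
      stop("cannot deduce format from extension '.", ext,
           "'; pass format= explicitly"))
  }
  format <- match.arg(format, c("xyz", "pdb", "mol", "sdf", "csm"))
  mols <- switch(format,
    xyz = read_xyz(path),
    csm = read_csm(path),
    pdb = read_pdb_models(path),
    mol = ,
    sdf = read_sdf(path, format))
  select_models(mols, selected_models)
}

select_models <- function(mols, selected_models) {
  if (is.null(selected_models)) return(mols)
  sel <- as.integer(selected_models)
  if (any(sel < 1L | sel > length(mols)))
    stop("selected model index out of range 1..", length(mols))
  mols[sel]
}

# ---- xyz ------------------------------------------------------------------

read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  mols <- list()
  i <- 1L
  model <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1)
      stop("xyz parse error at line ", i, ": expected atom count, got '",
           lines[i], "'")
    if (i + 1L + n > length(lines))
      stop("xyz parse error at line ", i, ": ", n,
           " atoms declared but file ends early")
    block <- lines[(i + 2L):(i + 1L + n)]
    toks <- strsplit(trimws(block), "\\s+")
    bad <- which(vapply(toks, length, 1L) < 4L)
    if (length(bad))
      stop("xyz parse error at line ", i + 1L + bad[1],
           ": need 'element x y z'")
    el <- vapply(toks, `[`, "", 1L)
    xyz <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3)))
    if (!all(is.finite(xyz)))
      stop("xyz parse error near line ", i + 2L, ": non-numeric coordinate")
    model <- model + 1L
    mols[[model]] <- csm_molecule(el, xyz, source_format = "xyz",
                                  model_index = model)
    i <- i + 2L + n
  }
  if (!length(mols)) stop("xyz parse error: no models found in ", path)
  mols
}

# ---- internal csm dialect -------------------------------------------------
# line 1: atom count N; N lines "element x y z"; then up to N adjacency lines
# "i j k ..." (1-based; atom i bonded to j, k, ...), as in the connectivity
# file.  Multiple models may be concatenated.

read_csm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  mols <- list()
  i <- 1L; model <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1)
      stop("csm parse error at line ", i, ": expected atom count")
    if (i + n > length(lines))
      stop("csm parse error at line ", i, ": file ends before ", n, " atoms")
    toks <- strsplit(trimws(lines[(i + 1L):(i + n)]), "\\s+")
    if (any(vapply(toks, length, 1L) < 4L))
      stop("csm parse error near line ", i + 1L, ": need 'element x y z'")
    el <- vapply(toks, `[`, "", 1L)
    xyz <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3)))
    i <- i + n + 1L
    # adjacency lines until next model header (a lone integer that starts a
    # valid model) or EOF; the dialect always writes exactly n of them.
    adj <- character(0)
    while (i <= length(lines) && length(adj) < n) {
      if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
      adj <- c(adj, lines[i]); i <- i + 1L
    }
    if (length(adj) < n)
      stop("csm parse error: expected ", n, " adjacency lines, got ",
           length(adj))
    bonds <- parse_connectivity_file(adj, n)
    model <- model + 1L
    mols[[model]] <- csm_molecule(el, xyz, bonds = bonds,
                                  source_format = "csm", model_index = model)
  }
  if (!length(mols)) stop("csm parse error: no models found in ", path)
  mols
}

# ---- pdb ------------------------------------------------------------------

read_pdb_models <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  alt <- at$alt
  bad_alt <- !(is.na(alt) | alt == "" | alt == "A")
  if (any(bad_alt))
    stop("PDB contains alternate locations other than blank/'A' (first at ",
         "atom serial ", at$eleno[which(bad_alt)[1]],
         "); pre-clean the file before the symmetry calculation")
  el <- at$elesy
  missing_el <- is.na(el) | !nzchar(trimws(el))
  if (any(missing_el))
    el[missing_el] <- sub("^[0-9]*", "", trimws(at$elety[missing_el]))
  el <- normalize_element(el)
  bonds <- parse_conect_records(path, at$eleno)
  nmod <- nrow(pdb$xyz)
  if (is.null(nmod) || is.na(nmod)) nmod <- 1L
  lapply(seq_len(nmod), function(m) {
    xyz <- matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)
    csm_molecule(el, xyz, bonds = bonds,
                 chain = at$chain, resname = at$resid, resseq = at$resno,
                 atomname = trimws(at$elety),
                 source_format = "pdb", model_index = m)
  })
}

# CONECT columns reference atom serial numbers; map them back to row order.
parse_conect_records <- function(path, serials) {
  lines <- grep("^CONECT", readLines(path, warn = FALSE), value = TRUE)
  if (!length(lines)) return(NULL)
  edges <- list()
  for (ln in lines) {
    f <- suppressWarnings(as.integer(strsplit(trimws(sub("^CONECT", "", ln)),
                                              "\\s+")[[1]]))
    f <- f[!is.na(f)]
    if (length(f) >= 2)
      edges[[length(edges) + 1L]] <- cbind(f[1], f[-1])
  }
  if (!length(edges)) return(NULL)
  e <- do.call(rbind, edges)
  i1 <- match(e[, 1], serials)
  i2 <- match(e[, 2], serials)
  keep <- !is.na(i1) & !is.na(i2)
  e <- cbind(i1, i2)[keep, , drop = FALSE]
  if (!nrow(e)) NULL else e
}

# ---- mol / sdf (V2000) ----------------------------------------------------

read_sdf <- function(path, format) {
  lines <- readLines(path, warn = FALSE)
  if (!any(grepl("^\\$\\$\\$\\$", lines))) lines <- c(lines, "$$$$")
  tmp <- tempfile(fileext = ".sdf")
  on.exit(unlink(tmp))
  writeLines(lines, tmp)
  sdfset <- ChemmineR::read.SDFset(tmp, skipErrors = TRUE)
  lapply(seq_along(sdfset), function(m) {
    sdf <- sdfset[[m]]
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    el <- sub("_[0-9]+$", "", rownames(ab))
    xyz <- ab[, 1:3, drop = FALSE]
    bonds <- if (length(bb) && nrow(bb)) bb[, 1:2, drop = FALSE] else NULL
    csm_molecule(el, xyz, bonds = bonds, source_format = format,
                 model_index = m)
  })
}
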