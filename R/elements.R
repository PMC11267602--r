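# Covalent radii (Angstrom), single-bond values from the Cordero et al. (2008)
# compilation; carbon uses the sp3 value.  Used only for bond perception.
.covalent_radii <- c(
  H = 0.31, He = 0.28,
  Li = 1.28, Be = 0.96, B = 0.84, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
  Ne = 0.58,
  Na = 1.66, Mg = 1.41, Al = 1.21, Si = 1.11, P = 1.07, S = 1.05, Cl = 1.02,
  Ar = 1.06,
  K = 2.03, Ca = 1.76, Sc = 1.70, Ti = 1.60, V = 1.53, Cr = 1.39, Mn = 1.39,
  Fe = 1.32, Co = 1.26, Ni = 1.24, Cu = 1.32, Zn = 1.22, Ga = 1.22,
  Ge = 1.20, As = 1.19, Se = 1.20, Br = 1.20, Kr = 1.16,
  Rb = 2.20, Sr = 1.95, Y = 1.90, Zr = 1.75, Nb = 1.64, Mo = 1.54,
  Tc = 1.47, Ru = 1.46, Rh = 1.42, Pd = 1.39, Ag = 1.45, Cd = 1.44,
  In = 1.42, Sn = 1.39, Sb = 1.39, Te = 1.38, I = 1.39, Xe = 1.40,
  Cs = 2.44, Ba = 2.15, La = 2.07, W = 1.62, Re = 1.51, Os = 1.44,
  Ir = 1.41, Pt = 1.36, Au = 1.36, Hg = 1.32, Tl = 1.45, Pb = 1.46,
  Bi = 1.48, U = 1.96
)

# Fallback radius when an element is unrecognised (classic carbon-like value).
.default_radius <- 0.77

# Standard atomic weights, for optional mass-weighted centering.
.atomic_masses <- c(
  H = 1.008, He = 4.0026, Li = 6.94, Be = 9.0122, B = 10.81, C = 12.011,
  N = 14.007, O = 15.999, F = 18.998, Ne = 20.180, Na = 22.990, Mg = 24.305,
  Al = 26.982, Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45, Ar = 39.948,
  K = 39.098, Ca = 40.078, Ti = 47.867, V = 50.942, Cr = 51.996, Mn = 54.938,
  Fe = 55.845, Co = 58.933, Ni = 58.693, Cu = 63.546, Zn = 65.38,
  Br = 79.904, Ru = 101.07, Rh = 102.91, Pd = 106.42, Ag = 107.87,
  Cd = 112.41, Sn = 118.71, I = 126.90, Pt = 195.08, Au = 196.97,
  Hg = 200.59, Pb = 207.2
)

atomic_mass <- function(elements) {
  m <- .atomic_masses[normalize_element(elements)]
  m[is.na(m)] <- 12.011
  unname(m)
}

#' Look up covalent radii
#'
#' @param elements character vector of element symbols.
#' @return numeric vector of radii in Angstrom.  Unknown symbols fall back to
#'   0.77 Angstrom with a warning.
#' @keywords internal
covalent_radius <- function(elements) {
  r <- .covalent_radii[normalize_element(elements)]
  if (anyNA(r)) {
    unknown <- unique(elements[is.na(r)])
    warning("no covalent radius for element(s) ", paste(unknown, collapse = ", "),
            "; using fallback 0.77 Angstrom", call. = FALSE)
    r[is.na(r)] <- .default_radius
  }
  unname(r)
}

#' Normalise an element symbol to standard capitalisation
#' @param x character vector (e.g. "FE", "fe", "Fe").
#' @keywords internal
normalize_element <- function(x) {
  x <- trimws(x)
  bad <- !nzchar(x)
  out <- paste0(toupper(substring(x, 1, 1)), tolower(substring(x, 2)))
  out[bad] <- "X"
  out
}
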