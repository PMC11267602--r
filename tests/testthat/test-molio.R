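test_that("xyz reading handles minimal and concatenated files", {
  f <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("1", "one oxygen", "O 0 0 0"), f)
  mols <- read_structures(f)
  expect_length(mols, 1)
  expect_equal(n_atoms(mols[[1]]), 1)
  expect_equal(mols[[1]]$atoms$element, "O")
  expect_equal(nrow(mols[[1]]$bonds), 0)

  # five concatenated models, distinguishable by coordinates
  lines <- unlist(lapply(1:5, function(k)
    c("2", paste("model", k), sprintf("C %d 0 0", k), "N 0 1 0")))
  writeLines(lines, f)
  sel <- read_structures(f, selected_models = c(2, 4))
  expect_length(sel, 2)
  expect_equal(vapply(sel, function(m) m$model_index, 1L), c(2L, 4L))
  expect_equal(coords(sel[[1]])[1, 1], 2)
  expect_equal(coords(sel[[2]])[1, 1], 4)

  expect_error(read_structures(f, selected_models = 9), "out of range")
  writeLines(c("2", "truncated", "C 0 0 0"), f)
  expect_error(read_structures(f), "line 1")
})

test_that("sdf V2000 bond block is honoured", {
  f <- withr::local_tempfile(fileext = ".sdf")
  writeLines(c(
    "water", "  test", "",
    "  3  2  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
    "    0.9600    0.0000    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "   -0.2400    0.9300    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  1  0  0  0  0",
    "  1  3  1  0  0  0  0",
    "M  END", "$$$$"), f)
  mol <- read_structures(f)[[1]]
  expect_equal(mol$atoms$element, c("O", "H", "H"))
  expect_equal(nrow(mol$bonds), 2)
  expect_equal(mol$bonds[, "i"], c(1L, 1L), ignore_attr = TRUE)
  expect_equal(mol$bonds[, "j"], c(2L, 3L), ignore_attr = TRUE)
})

test_that("covalent bond inference follows the radius rule", {
  h2 <- csm_molecule(c("H", "H"), rbind(c(0, 0, 0), c(0.74, 0, 0)))
  expect_equal(nrow(infer_bonds(h2, 1.2)), 1)
  he2 <- csm_molecule(c("He", "He"), rbind(c(0, 0, 0), c(10, 0, 0)))
  expect_equal(nrow(infer_bonds(he2)), 0)
  water <- csm_molecule(c("O", "H", "H"),
                        rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0)))
  b <- infer_bonds(water)
  expect_equal(nrow(b), 2)       # two O-H, no H..H
  expect_true(all(b[, 1] == 1))
  # invariance under rigid motion
  R <- random_rotation(5)
  water2 <- csm_molecule(c("O", "H", "H"),
                         coords(water) %*% t(R) + rep(1, 3) %o% c(3, -2, 7))
  expect_identical(infer_bonds(water2), b)
  # unknown element falls back with a warning
  xx <- csm_molecule(c("Zz", "Zz"), rbind(c(0, 0, 0), c(1.0, 0, 0)))
  expect_warning(bz <- infer_bonds(xx), "fallback")
  expect_equal(nrow(bz), 1)
})

test_that("connectivity files parse, merge and range-check", {
  b <- parse_connectivity_file(c("1 2", "2 1 3"), n_atoms = 3)
  expect_equal(unname(b), cbind(c(1L, 2L), c(2L, 3L)))
  expect_error(parse_connectivity_file("1 4", n_atoms = 3), "line 1")
  ring <- sprintf("%d %d %d", 1:6, c(6, 1:5), c(2:6, 1))
  expect_equal(nrow(parse_connectivity_file(ring, 6)), 6)
  expect_warning(parse_connectivity_file(character(0), 3), "empty")
})

test_that("selection and hydrogen removal induce the right subgraph", {
  # methane
  ch4 <- csm_molecule(c("C", "H", "H", "H", "H"),
                      rbind(0, c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1),
                            c(-1, -1, 1)) * 0.63)
  ch4$bonds <- infer_bonds(ch4)
  r <- apply_selection(ch4, remove_hy = TRUE)
  expect_equal(n_atoms(r$molecule), 1)
  expect_equal(nrow(r$molecule$bonds), 0)
  expect_equal(r$index_map, c(1L, NA, NA, NA, NA))

  chain <- csm_molecule(rep("C", 5), cbind(1:5 * 1.4, 0, 0),
                        bonds = cbind(1:4, 2:5))
  r2 <- apply_selection(chain, select_atoms = c(2, 3, 4))
  expect_equal(n_atoms(r2$molecule), 3)
  expect_equal(unname(r2$molecule$bonds), cbind(c(1L, 2L), c(2L, 3L)))

  # benzene ring: hydrogens removed, the 6 ring bonds survive
  ang <- 2 * pi * (0:5) / 6
  bz <- csm_molecule(c(rep("C", 6), rep("H", 6)),
                     rbind(cbind(1.39 * cos(ang), 1.39 * sin(ang), 0),
                           cbind(2.47 * cos(ang), 2.47 * sin(ang), 0)))
  bz$bonds <- infer_bonds(bz)
  r3 <- apply_selection(bz, remove_hy = TRUE)
  expect_equal(n_atoms(r3$molecule), 6)
  expect_equal(nrow(r3$molecule$bonds), 6)
  expect_error(apply_selection(csm_molecule("H", cbind(0, 0, 0)),
                               remove_hy = TRUE), "every atom")
})

test_that("write/read round-trips preserve elements, bonds and precision", {
  m <- perturb(make_symmetric("c3", 2, seed = 5), 0.1, seed = 1)
  m$bonds <- infer_bonds(m, 2.5)
  for (fmt in c("xyz", "csm", "sdf", "pdb")) {
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_structure(m, f, format = fmt)
    m2 <- read_structures(f)[[1]]
    expect_identical(m2$atoms$element, m$atoms$element)
    if (fmt != "xyz") expect_identical(m2$bonds, m$bonds)
    tol <- switch(fmt, xyz = 1e-6, csm = 1e-6, sdf = 1e-3, pdb = 5e-3)
    expect_lt(max(abs(coords(m2) - coords(m))), tol)
  }
  # 1e-7-scale coordinate differences survive the xyz round trip
  base <- coords(m)
  shifted <- base + 1e-7
  f <- withr::local_tempfile(fileext = ".xyz")
  write_structure(csm_molecule(m$atoms$element, shifted), f)
  back <- coords(read_structures(f)[[1]])
  expect_lt(max(abs(back - shifted)), 1e-9)
  expect_gt(max(abs(back - base)), 5e-8)
})

test_that("pdb metadata and CONECT records round-trip", {
  mol <- make_homomer(3, 4, seed = 2)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(mol, f, format = "pdb")
  m2 <- read_structures(f)[[1]]
  expect_equal(unique(m2$atoms$chain), c("A", "B", "C"))
  expect_identical(m2$atoms$atomname, mol$atoms$atomname)
  expect_identical(m2$atoms$resseq, mol$atoms$resseq)
  # bonds via CONECT
  small <- csm_molecule(c("O", "H", "H"),
                        rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0)),
                        bonds = rbind(c(1, 2), c(1, 3)))
  write_structure(small, f, format = "pdb")
  m3 <- read_structures(f)[[1]]
  expect_identical(m3$bonds, small$bonds)
})
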