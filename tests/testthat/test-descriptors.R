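test_that("valence delta values follow the electron-minus-hydrogen rule", {
  expect_equal(valence_delta(mol_benzene()), rep(3, 6))
  ph <- mol_phenol()
  expect_equal(valence_delta(ph)[ph$atoms$element == "O"], 5)
  cb <- parse_smiles("Clc1ccccc1")
  # higher-row halogen: (Zv - h) / (Z - Zv - 1) = 7/9
  expect_equal(valence_delta(cb)[cb$atoms$element == "Cl"], 7 / 9)
  bb <- parse_smiles("Brc1ccccc1")
  expect_equal(valence_delta(bb)[bb$atoms$element == "Br"], 7 / 27)
  # delta ignores bond order: carbonyl C in acetophenone has delta 4
  ac <- parse_smiles("CC(=O)c1ccccc1")
  co <- which(ac$atoms$element == "C" & ac$atoms$degree == 3 &
                !ac$atoms$aromatic)
  expect_equal(valence_delta(ac)[co], 4)
})

test_that("connectivity index reproduces printed values for representative compounds", {
  expect_equal(chi1(mol_benzene()), 2, tolerance = 5e-4)
  expect_equal(chi1(mol_toluene()), 2.411, tolerance = 5e-4)
  expect_equal(chi1(mol_phenol()), 2.134, tolerance = 5e-4)
  expect_equal(chi1(parse_smiles("Clc1ccccc1")), 2.477, tolerance = 5e-4)
  expect_equal(chi1(parse_smiles("CC")), 1)
  expect_equal(chi1(parse_smiles("C")), 0)  # no bonds: empty sum
})

test_that("n-alkane connectivity index matches the closed form for k = 3..20", {
  for (k in 3:20) {
    expect_equal(chi1(parse_smiles(n_alkane_smiles(k))),
                 chi_nalkane_closed_form(k), tolerance = 1e-12)
  }
})

test_that("connectivity index equals brute-force edge enumeration on random alkanes", {
  set.seed(7)
  for (k in c(4, 6, 8, 10, 12)) {
    mol <- parse_smiles(generate_alkane(k))
    # independent route: for saturated acyclic hydrocarbons delta = degree,
    # so sum (deg_i * deg_j)^-0.5 over the edge list directly
    deg <- mol$atoms$degree
    brute <- sum((deg[mol$bonds$i] * deg[mol$bonds$j])^-0.5)
    expect_equal(chi1(mol), brute, tolerance = 1e-12)
    expect_true(all(deg <= 4))
  }
})

test_that("connectivity index decreases with branching at fixed carbon count", {
  path5 <- chi1(parse_smiles("CCCCC"))
  branch5 <- chi1(parse_smiles("CC(C)CC"))
  star5 <- chi1(parse_smiles("CC(C)(C)C"))
  expect_true(path5 > branch5)
  expect_true(branch5 > star5)
})

test_that("polarizability reproduces printed values for representative compounds", {
  expect_equal(polarizability(mol_cyclopentane()), 0.733, tolerance = 5e-4)
  expect_equal(polarizability(mol_benzene()), 0.165, tolerance = 5e-4)
  expect_equal(polarizability(mol_toluene()), 0.502, tolerance = 5e-4)
  expect_equal(polarizability(parse_smiles("CC(=O)c1ccccc1")), -0.605,
               tolerance = 5e-4)
  # methane: carbon + 4 H, no bonds
  expect_equal(polarizability(parse_smiles("C")), 0.577 - 4 * 0.120,
               tolerance = 1e-12)
})

test_that("polarizability is isomer-invariant for saturated hydrocarbons", {
  c7 <- c("CCCC(C)(C)C", "CC(C)CC(C)C", "CC(C)C(C)(C)C", "CCCCC(C)C",
          "CCCC(C)CC", "CCC(C)C(C)C", "CCCCCCC")
  phis <- vapply(c7, function(s) polarizability(parse_smiles(s)), numeric(1))
  expect_true(all(abs(phis - 2.119) < 5e-4))
  # closed form for any acyclic alkane: 0.577k - 0.120(2k+2) = 0.337k - 0.240
  set.seed(11)
  for (k in c(5, 9, 14)) {
    expect_equal(polarizability(parse_smiles(generate_alkane(k))),
                 0.337 * k - 0.240, tolerance = 1e-9)
  }
})

test_that("feature counts implement the aromatic-ring and oxygen conventions", {
  tol_counts <- count_features(mol_toluene())
  expect_equal(tol_counts[["carbon"]], 7L)
  expect_equal(tol_counts[["hydrogen"]], 8L)
  expect_equal(tol_counts[["double_bond"]], 3L)
  expect_equal(tol_counts[["cycle"]], 0L)  # aromatic ring: no cycle term

  cp_counts <- count_features(mol_cyclopentane())
  expect_equal(cp_counts[["cycle"]], 1L)
  expect_equal(cp_counts[["hydrogen"]], 10L)

  ac_counts <- count_features(parse_smiles("CC(=O)c1ccccc1"))
  expect_equal(ac_counts[["oxygen"]], 1L)
  expect_equal(ac_counts[["double_bond"]], 4L)  # 3 aromatic + carbonyl

  # fused aromatics contribute three double-bond terms per ring
  expect_equal(count_features(parse_smiles("c1ccc2ccccc2c1"))[["double_bond"]],
               6L)
})

test_that("scheme flags switch hydrogen counting and hydroxyl classification", {
  ph <- mol_phenol()
  # default counts the O-H hydrogen
  expect_equal(count_features(ph)[["hydrogen"]], 6L)
  c_only <- pdms_scheme(count_heteroatom_hydrogens = FALSE)
  expect_equal(count_features(ph, c_only)[["hydrogen"]], 5L)
  expect_equal(polarizability(ph, c_only), -0.540, tolerance = 5e-4)

  # default: all oxygens take the oxygen factor, even aliphatic OH
  bz_alc <- parse_smiles("OCc1ccccc1")
  expect_equal(count_features(bz_alc)[["hydroxyl"]], 0L)
  expect_equal(polarizability(bz_alc), -0.323, tolerance = 5e-4)
  literal <- pdms_scheme(hydroxyl_factor = "aliphatic")
  expect_equal(count_features(bz_alc, literal)[["hydroxyl"]], 1L)
  # phenolic OH is on an aromatic carbon: stays plain oxygen either way
  expect_equal(count_features(ph, literal)[["hydroxyl"]], 0L)

  # factor overrides are applied and unknown features rejected
  expect_equal(polarizability(parse_smiles("C"),
                              pdms_scheme(factors = c(carbon = 1))),
               1 - 4 * 0.120, tolerance = 1e-12)
  expect_error(pdms_scheme(factors = c(helium = 1)), "unknown")
})

test_that("descriptors are invariant across Kekule assignments of benzenoid rings", {
  # same molecule entered so that depth-first matching starts from
  # different atoms, exercising different Kekule patterns
  variants <- c("c1ccc2ccccc2c1", "c1cc2ccccc2cc1")
  chis <- vapply(variants, function(s) chi1(parse_smiles(s)), numeric(1))
  phis <- vapply(variants, function(s) polarizability(parse_smiles(s)),
                 numeric(1))
  expect_equal(chis[[1]], chis[[2]])
  expect_equal(phis[[1]], phis[[2]])
})

test_that("indicator variable follows the hydrogen-bonding rules", {
  expect_equal(hb_indicator(parse_smiles("C1CCCCC1")), 0L)  # cyclohexane
  expect_equal(hb_indicator(parse_smiles("CC(C)C(C)C")), 0L)
  expect_equal(hb_indicator(mol_toluene()), 1L)   # aromatic ring H
  expect_equal(hb_indicator(mol_phenol()), 1L)
  expect_equal(hb_indicator(parse_smiles("CC#C")), 1L)   # acetylenic
  # halogen on an H-bearing carbon vs fully substituted carbon
  expect_equal(hb_indicator(parse_smiles("ClCC")), 1L)
  expect_equal(hb_indicator(parse_smiles("ClC(Cl)(Cl)Cl")), 0L)
})

test_that("compute_descriptors assembles the full row", {
  d <- compute_descriptors(parse_smiles("c1ccccc1", "benzene"), ws = 1790,
                           log_kow = 2.13)
  expect_equal(d$chi1, 2, tolerance = 5e-4)
  expect_equal(d$phi, 0.165, tolerance = 5e-4)
  expect_equal(d$indicator, 1L)
  expect_equal(d$mw, 78, tolerance = 0.12)
  expect_equal(d$ws, 1790)

  batch <- descriptor_table(c("c1ccccc1", "not_a_smiles"), .error = "report")
  expect_true(is.na(batch$error[1]))
  expect_false(is.na(batch$error[2]))
  expect_error(descriptor_table(c("c1ccccc1", "not_a_smiles")), "position")
})
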