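test_that("ATS autocorrelation matches hand-enumerated pair sums", {
  p <- atom_property_table()
  w_O <- p["O", "mass"] / p["C", "mass"]
  expect_equal(ats_autocorrelation(parse_molecule("CC"), 1, "mass"), 1)
  expect_equal(ats_autocorrelation(parse_molecule("C"), 1, "mass"), 0)
  expect_equal(ats_autocorrelation(parse_molecule("C"), 5, "mass"), 0)
  expect_equal(ats_autocorrelation(parse_molecule("CCO"), 1, "mass"),
               1 + w_O, tolerance = 1e-12)
  # ethanol lag 2: single C..O pair through the middle atom
  expect_equal(ats_autocorrelation(parse_molecule("CCO"), 2, "mass"),
               w_O, tolerance = 1e-12)
  # benzene: six bonded pairs, six meta pairs, three para pairs, all weight 1
  gb <- parse_molecule("c1ccccc1")
  expect_equal(ats_autocorrelation(gb, 1, "mass"), 6)
  expect_equal(ats_autocorrelation(gb, 2, "mass"), 6)
  expect_equal(ats_autocorrelation(gb, 3, "mass"), 3)
  expect_equal(ats_autocorrelation(gb, 4, "mass"), 0)
})

test_that("Burden matrix follows the stated off-diagonal convention", {
  expect_equal(burden_matrix(parse_molecule("C")), matrix(1, 1, 1))
  # ethane: terminal augmentation 0.1 * 1 + 0.01
  expect_equal(burden_matrix(parse_molecule("CC")),
               matrix(c(1, 0.11, 0.11, 1), 2, 2))
  # propane: both bonds touch a terminal atom; non-bonded pair gets 0.001
  B <- burden_matrix(parse_molecule("CCC"))
  expect_equal(B[1, 2], 0.11); expect_equal(B[2, 3], 0.11)
  expect_equal(B[1, 3], 0.001)
  # benzene: aromatic order 1.5, no terminal atoms -> 0.15
  Bb <- burden_matrix(parse_molecule("c1ccccc1"))
  expect_equal(Bb[1, 2], 0.15)
  expect_equal(Bb[1, 4], 0.001)
  # double bond in the interior: 0.2 (+0.01 only at terminals)
  Bd <- burden_matrix(parse_molecule("C=C"))
  expect_equal(Bd[1, 2], 0.21)
  for (seed in 1:10) {
    g <- random_mol_graph(sample(2:10, 1), seed)
    M <- burden_matrix(g, "polarizability")
    expect_identical(M, t(M))
  }
})

test_that("Burden eigenvalues follow the BEL/BEH ordering and padding policy", {
  # ethane 2x2: eigenvalues 1 -/+ 0.11 analytically
  expect_equal(as.numeric(burden_eigenvalue(parse_molecule("CC"), "mass", 1,
                                            "lowest")), 0.89)
  expect_equal(as.numeric(burden_eigenvalue(parse_molecule("CC"), "mass", 1,
                                            "highest")), 1.11)
  padded <- burden_eigenvalue(parse_molecule("CC"), "mass", 6, "lowest")
  expect_equal(as.numeric(padded), 0)
  expect_true(attr(padded, "pad"))
  # one-atom molecule: eigenvalue 1 is the carbon-scaled weight itself
  p <- atom_property_table()
  expect_equal(as.numeric(burden_eigenvalue(parse_molecule("O"), "mass", 1,
                                            "lowest")),
               p["O", "mass"] / p["C", "mass"])
  # BEL series ascending, BEH descending; multiset matches a dense solve
  for (seed in 1:10) {
    g <- random_mol_graph(sample(3:12, 1), seed + 100)
    n <- n_atoms(g)
    bel <- vapply(1:n, function(k) {
      as.numeric(burden_eigenvalue(g, "volume", k, "lowest"))
    }, numeric(1))
    beh <- vapply(1:n, function(k) {
      as.numeric(burden_eigenvalue(g, "volume", k, "highest"))
    }, numeric(1))
    expect_true(all(diff(bel) >= -1e-12))
    expect_true(all(diff(beh) <= 1e-12))
    oracle <- sort(eigen(burden_matrix(g, "volume"), symmetric = TRUE,
                         only.values = TRUE)$values)
    expect_equal(bel, oracle, tolerance = 1e-9)
    expect_equal(sort(beh), oracle, tolerance = 1e-9)
  }
})

test_that("edge adjacency matrices carry the stated weights", {
  expect_equal(edge_adjacency_matrix(parse_molecule("CCC"), "edge_degree"),
               matrix(c(1, 1, 1, 1), 2, 2))
  expect_equal(edge_adjacency_matrix(parse_molecule("CC"), "edge_degree"),
               matrix(0, 1, 1))
  expect_equal(edge_adjacency_matrix(parse_molecule("CC"), "bond_dipole"),
               matrix(0, 1, 1))           # homonuclear single bond
  dip <- bond_dipole_table()
  E <- edge_adjacency_matrix(parse_molecule("CO"), "bond_dipole")
  expect_equal(E[1, 1], dip$dipole[dip$element_a == "C" & dip$element_b == "O" &
                                   dip$order == "single"])
  expect_error(edge_adjacency_matrix(parse_molecule("C"), "edge_degree"),
               "no bonds")
})

test_that("edge eigenvalues and spectral moments satisfy their identities", {
  g3 <- parse_molecule("CCC")
  expect_equal(as.numeric(edge_eigenvalue(g3, "edge_degree", 1)), 2)
  expect_equal(as.numeric(edge_spectral_moment(g3, "edge_degree", 2)), 4)
  expect_equal(as.numeric(edge_spectral_moment(g3, "edge_degree", 0)), 2)
  expect_equal(as.numeric(edge_spectral_moment(parse_molecule("CC"),
                                               "bond_dipole", 2)), 0)
  pad <- edge_eigenvalue(parse_molecule("CCCCCC"), "edge_degree", 12)
  expect_equal(as.numeric(pad), 0); expect_true(attr(pad, "pad"))

  for (seed in 1:10) {
    g <- random_mol_graph(sample(3:12, 1), seed + 200)
    E <- edge_adjacency_matrix(g, "edge_degree")
    m <- nrow(E)
    eigs <- vapply(1:m, function(k) {
      as.numeric(edge_eigenvalue(g, "edge_degree", k))
    }, numeric(1))
    # eigenvalues sum to the trace; order-2 moment is the squared Frobenius norm
    expect_equal(sum(eigs), sum(diag(E)), tolerance = 1e-9)
    expect_equal(as.numeric(edge_spectral_moment(g, "edge_degree", 2)),
                 sum(E^2), tolerance = 1e-9)
    expect_gte(as.numeric(edge_spectral_moment(g, "edge_degree", 4)), 0)
  }
})

test_that("descriptor blocks follow the grammar, padding and internal consistency", {
  v <- compute_descriptor_block(parse_molecule("CC"))
  expect_named(v, c("ATS1m", "EEig12x", "ESpm02d", "BELv6", "BELe6", "BELp6"))
  expect_equal(attr(v, "pad"), c(FALSE, TRUE, FALSE, TRUE, TRUE, TRUE))
  expect_error(compute_descriptor_block(parse_molecule("CC"), "XYZ1q"),
               "grammar")

  g <- parse_molecule("c1ccc(CC(=O)NCCCl)cc1")
  blk <- compute_descriptor_block(g, c("ATS1m", "ATS2p", "BEL2e", "BEH1v",
                                       "EEig1x", "ESpm02d", "ESpm3x"))
  expect_equal(blk[["ATS1m"]], ats_autocorrelation(g, 1, "mass"))
  expect_equal(blk[["ATS2p"]], ats_autocorrelation(g, 2, "polarizability"))
  expect_equal(blk[["BEL2e"]],
               as.numeric(burden_eigenvalue(g, "electronegativity", 2, "lowest")))
  expect_equal(blk[["BEH1v"]],
               as.numeric(burden_eigenvalue(g, "volume", 1, "highest")))
  expect_equal(blk[["EEig1x"]], as.numeric(edge_eigenvalue(g, "edge_degree", 1)))
  expect_equal(blk[["ESpm3x"]],
               as.numeric(edge_spectral_moment(g, "edge_degree", 3)))
  # Dragon-style Burden spelling is accepted
  expect_equal(compute_descriptor_block(g, "BELv6"),
               compute_descriptor_block(g, "BEL6v"), ignore_attr = TRUE)
})

test_that("every descriptor is invariant under atom relabeling", {
  spec <- c("ATS1m", "ATS2v", "EEig1x", "EEig12x", "ESpm02d", "ESpm02x",
            "BELv6", "BELe6", "BELp6", "BEH1m")
  mols <- c("c1ccccc1", "CC(=O)NCCc1ccccc1", "ClCC(CO)CN")
  for (s in mols) {
    g <- parse_molecule(s)
    ref <- compute_descriptor_block(g, spec)
    for (rep in 1:25) {
      set.seed(rep)
      gp <- permute_mol_graph(g, sample(n_atoms(g)))
      expect_equal(compute_descriptor_block(gp, spec), ref,
                   tolerance = 1e-9, ignore_attr = TRUE)
    }
  }
})
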