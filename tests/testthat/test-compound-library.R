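test_that("compound table matches the published data set structure", {
  tbl <- fixture_table()
  expect_equal(nrow(tbl), 39)
  expect_equal(sum(tbl$split == "test"), 8)
  expect_equal(sort(tbl$no[tbl$split == "test"]),
               c(16, 19, 22, 24, 25, 28, 35, 37))
  expect_equal(tbl$no[tbl$split == "excluded"], c(38, 39))
  expect_equal(tbl$no[tbl$outlier], 14)

  # record 7: the strongest inhibitor
  r7 <- tbl[tbl$no == 7, ]
  expect_equal(r7$mol_id, "C5")
  expect_equal(r7$spec[[1]]$position_3, "benzoyl")
  expect_equal(unname(r7$spec[[1]]$ring_subs["7"]), "benzyloxy")
  expect_equal(r7$lox_pct, 96.6)
  expect_equal(r7$log_lox, 1.98)

  # record 8: plain coumarin
  r8 <- tbl[tbl$no == 8, ]
  expect_equal(r8$spec[[1]]$position_3, "none")
  expect_length(r8$spec[[1]]$ring_subs, 0)
  expect_equal(r8$lox_pct, 23.1)
})

test_that("training-set bookkeeping matches both model configurations", {
  tbl <- fixture_table()
  expect_equal(nrow(modeling_rows(tbl, "eq1", "train")), 29)
  expect_equal(nrow(modeling_rows(tbl, "eq2", "train")), 28)
  expect_equal(nrow(modeling_rows(tbl, "eq2", "test")), 8)
  expect_false(14 %in% modeling_rows(tbl, "eq2", "train")$no)
  expect_true(14 %in% modeling_rows(tbl, "eq1", "train")$no)
})

test_that("log activity column is consistent with the percent column", {
  tbl <- fixture_table()
  has <- !is.na(tbl$lox_pct)
  # both columns are rounded prints; equality holds up to half an ULP of
  # the log column plus the log-propagated half-ULP of the percent column
  tol <- 0.005 + 0.05 / (tbl$lox_pct[has] * log(10))
  expect_true(all(abs(log10(tbl$lox_pct[has]) - tbl$log_lox[has]) <= tol))
})

test_that("substituent specs reject out-of-vocabulary input", {
  expect_error(substituent_spec("nitro"), "unknown position-3 group")
  expect_error(substituent_spec("acetyl", c("5" = "bromo")), "positions")
  expect_error(substituent_spec("acetyl", c("6" = "sulfo")), "unknown ring group")
})

test_that("generated SMILES give the expected molecular formulas", {
  formula_of <- function(mol) {
    t <- table(mol$elements)
    paste0(names(t), t, collapse = "")
  }
  m_coum <- embed_3d(smiles_from_spec(substituent_spec()))
  expect_equal(formula_of(m_coum), "C9H6O2")
  m_ac <- embed_3d(smiles_from_spec(substituent_spec("acetyl")))
  expect_equal(formula_of(m_ac), "C11H8O3")
  m7 <- fixture_mol(7)
  expect_equal(formula_of(m7), "C23H16O4")
  expect_equal(sum(m7$elements != "H"), 27)
})

test_that("all compound structures are unique", {
  tbl <- fixture_table()
  expect_equal(length(unique(tbl$smiles)), 39)
  # canonical-form uniqueness via OpenBabel canonical SMILES
  canon <- vapply(tbl$smiles, function(s) {
    ChemmineOB::convertFormat("SMI", "CAN", source = s)
  }, "", USE.NAMES = FALSE)
  expect_equal(length(unique(canon)), 39)
})

test_that("3D embedding is deterministic and hydrogen-explicit", {
  smi <- "C"  # methane
  m <- embed_3d(smi)
  expect_equal(length(m$elements), 5)
  expect_true(all(m$topo_dist <= 2))
  # repeated calls return bitwise-identical coordinates
  m2 <- embed_3d(smi)
  expect_identical(m$coords, m2$coords)
  # a re-embedding from scratch reproduces the geometry itself (the global
  # orientation is arbitrary, so compare the interatomic distance matrix)
  rm(list = smi, envir = coumlox:::.embed_cache)
  m3 <- embed_3d(smi)
  expect_equal(as.matrix(dist(m$coords)), as.matrix(dist(m3$coords)),
               tolerance = 1e-3)

  smi7 <- fixture_table()$smiles[7]
  d1 <- as.matrix(dist(embed_3d(smi7)$coords))
  rm(list = smi7, envir = coumlox:::.embed_cache)
  expect_equal(as.matrix(dist(embed_3d(smi7)$coords)), d1, tolerance = 1e-3)
})

test_that("embedding failures name the compound", {
  expect_error(embed_3d("not-a-smiles", name = "bogus"), "bogus")
})

test_that("topological distances match a brute-force BFS oracle", {
  tbl <- fixture_table()
  for (no in c(2, 7, 8, 15, 26)) {
    m <- fixture_mol(no)
    expect_equal(m$topo_dist, bfs_distances(m), info = paste("compound", no))
    expect_true(isSymmetric(m$topo_dist))
    expect_true(all(diag(m$topo_dist) == 0))
  }
  # triangle inequality on one molecule
  D <- fixture_mol(15)$topo_dist
  n <- nrow(D)
  for (k in seq_len(n)) {
    expect_true(all(D <= outer(D[, k], D[k, ], `+`) + 1e-9))
  }
})

test_that("aromaticity is restricted to six-membered carbocycles", {
  benzene <- embed_3d("c1ccccc1")
  expect_equal(sum(benzene$aromatic), 6)
  expect_true(all(benzene$elements[benzene$aromatic] == "C"))

  coum <- fixture_mol(8)
  expect_equal(sum(coum$aromatic), 6)  # benzo ring only, lactone ring excluded

  m7 <- fixture_mol(7)
  expect_equal(sum(m7$aromatic), 18)   # three benzene rings

  furan <- embed_3d("c1ccoc1")         # five-membered heteroaromatic: none
  expect_equal(sum(furan$aromatic), 0)
})

test_that("compound table exports round-trip through CSV", {
  tbl <- fixture_table()
  csv <- tempfile(fileext = ".csv")
  smi <- tempfile(fileext = ".smi")
  write_compound_table(tbl, csv, smi)
  back <- read.csv(csv, check.names = FALSE)
  expect_equal(nrow(back), 39)
  expect_equal(back$smiles, tbl$smiles)
  expect_equal(length(readLines(smi)), 39)
  unlink(c(csv, smi))
})

test_that("embedded structures export as SDF", {
  path <- tempfile(fileext = ".sdf")
  write_molecules_sdf(list(fixture_mol(8), fixture_mol(5)), path)
  txt <- readLines(path)
  expect_equal(sum(grepl("^\\$\\$\\$\\$", txt)), 2)
  expect_true(any(grepl("V2000", txt)))
  unlink(path)
})
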