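test_that("atomic weight tables are carbon-scaled and complete", {
  for (s in c("m", "v", "e", "p")) {
    w <- atomic_weights(s)
    expect_equal(unname(w["C"]), 1)
    expect_true(all(w > 0))
    expect_true(all(c("H", "C", "N", "O", "Cl", "Br") %in% names(w)))
  }
  expect_true(all(atomic_weights("u") == 1))
  raw <- atomic_weights("p", scaled = FALSE)
  expect_equal(unname(raw["C"]), 1.76)
  expect_equal(unname(raw["O"]), 0.802)
})

test_that("R-CX-R fragment counting matches hand-typed toy structures", {
  toys <- fixture_toys()
  expect_equal(count_c026(toys$phenol), 1)
  expect_equal(count_c026(toys$anisole), 1)
  expect_equal(count_c026(toys$catechol), 2)
  expect_equal(count_c026(toys$toluene), 0)
  expect_equal(count_c026(toys$bromobenzene), 1)
  expect_equal(count_c026(toys$benzene), 0)
  # pyranone-fused benzene: the fused carbon bearing the ring oxygen counts
  expect_equal(count_c026(fixture_mol(8)), 1)
})

test_that("R-CX-R counts on the real compounds match their interpretation", {
  expect_equal(count_c026(fixture_mol(5)), 1)
  expect_equal(count_c026(fixture_mol(7)), 2)
})

test_that("fragment classes partition the carbons", {
  for (no in c(5, 7, 15)) {
    m <- fixture_mol(no)
    expect_equal(sum(acf_counts(m)), sum(m$elements == "C"),
                 info = paste("compound", no))
  }
})

test_that("RDF closed-form cases are exact", {
  toys <- fixture_toys()
  # two atoms exactly 3.5 A apart, unit weights: exp(0) = 1, one pair
  expect_equal(rdf_value(toys$diatomic, 3.5, weight = "u"), 1.0)
  # single atom: no pairs
  single <- molecule3d("C", matrix(0, 1, 3), matrix(integer(0), 0, 3))
  expect_equal(rdf_value(single, 3.5), 0)
  expect_true(rdf_value(fixture_mol(2), 3.5) >= 0)
})

test_that("RDF and HATS are invariant to rigid motion", {
  set.seed(42)
  for (no in c(2, 15)) {
    m <- fixture_mol(no)
    m2 <- rigid_transform(m, random_rotation(), rnorm(3, sd = 10))
    expect_equal(rdf_value(m2, 3.5), rdf_value(m, 3.5), tolerance = 1e-9)
    expect_equal(hats_value(m2, 8), hats_value(m, 8), tolerance = 1e-9)
    expect_equal(hats_value(m2, 3), hats_value(m, 3), tolerance = 1e-9)
  }
})

test_that("unit-weight RDF integrates to the pair count over the grid", {
  # Gaussian mass conservation: summing RDF over the radius grid times the
  # grid step approximates the number of atom pairs, for geometries whose
  # distances lie inside the grid
  # the Gaussian kernel at beta = 100 is ~0.07 A wide, so quadrature needs
  # a step well below that; each pair contributes sqrt(pi/beta) in total
  toys <- fixture_toys()
  step <- 0.02
  radii <- seq(0.5, 16, by = step)
  for (m in list(toys$chain, toys$tetrahedron)) {
    n <- length(m$elements)
    npairs <- n * (n - 1) / 2
    total <- sum(vapply(radii, rdf_value, numeric(1), mol = m, weight = "u")) * step
    expect_equal(total / sqrt(pi / 100), npairs, tolerance = 0.1)
  }
})

test_that("influence leverages are a projector diagonal", {
  m <- fixture_mol(5)
  h <- influence_leverages(m)
  expect_true(all(h >= 0 & h <= 1))
  expect_equal(sum(h), 3, tolerance = 1e-9)       # rank-3 geometry
  toys <- fixture_toys()
  expect_equal(sum(influence_leverages(toys$benzene)), 2, tolerance = 1e-9)  # planar
  expect_equal(sum(influence_leverages(toys$chain)), 1, tolerance = 1e-9)    # linear
  # regular tetrahedron: symmetry forces equal leverages; verify against
  # direct matrix arithmetic with an explicit inverse
  tet <- toys$tetrahedron
  h_tet <- influence_leverages(tet)
  expect_true(max(h_tet) - min(h_tet) < 1e-12)
  M <- scale(tet$coords, scale = FALSE)
  H <- M %*% solve(crossprod(M)) %*% t(M)
  expect_equal(h_tet, unname(diag(H)), tolerance = 1e-10)
  # degenerate geometry errors
  flat <- molecule3d(c("C", "C"), matrix(0, 2, 3), cbind(1L, 2L, 1L))
  expect_error(influence_leverages(flat), "degenerate")
})

test_that("HATS matches a brute-force pair-loop oracle", {
  hats_oracle <- function(mol, lag, weight = "p") {
    h <- influence_leverages(mol)
    w <- coumlox:::weights_for(mol, weight)
    if (lag == 0) return(sum((h * w)^2))
    s <- 0
    n <- length(h)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (mol$topo_dist[i, j] == lag) s <- s + h[i] * w[i] * h[j] * w[j]
    }
    s
  }
  for (no in c(2, 15)) {
    m <- fixture_mol(no)
    for (lag in 0:8) {
      expect_equal(hats_value(m, lag), hats_oracle(m, lag),
                   info = paste("compound", no, "lag", lag))
    }
  }
})

test_that("HATS edge cases and domain errors", {
  toys <- fixture_toys()
  expect_equal(hats_value(toys$ethane, 8), 0)   # lag beyond graph diameter
  # diatomic, lag 1, unit weights: the single pair gives h1*h2
  h <- influence_leverages(toys$diatomic)
  expect_equal(hats_value(toys$diatomic, 1, weight = "u"), h[1] * h[2])
  expect_error(hats_value(toys$diatomic, -1), "lag")
  expect_error(hats_value(toys$diatomic, 9), "lag")
})

test_that("descriptor matrix has the contracted shape and names", {
  desc <- fixture_descriptors()
  expect_equal(nrow(desc), 37)
  expect_false(any(is.na(desc)))
  expect_equal(sum(colnames(desc) == "RDF035p"), 1)
  expect_equal(sum(colnames(desc) == "HATS8p"), 1)
  expect_equal(sum(colnames(desc) == "C-026"), 1)
  expect_equal(unname(desc[c("5", "7"), "C-026"]), c(1, 2))
  # spot-check grid columns against the scalar functions
  m15 <- fixture_mol(15)
  expect_equal(unname(desc["15", "HATS8p"]), hats_value(m15, 8))
  expect_equal(unname(desc["15", "RDF035p"]), rdf_value(m15, 3.5))
})

test_that("descriptor matrix round-trips through CSV with sidecar", {
  desc <- fixture_descriptors()
  csv <- tempfile(fileext = ".csv")
  sidecar <- write_descriptor_matrix(desc, csv)
  back <- read.csv(csv, check.names = FALSE)
  expect_equal(nrow(back), 37)
  expect_equal(back[["RDF035p"]], unname(desc[, "RDF035p"]))
  meta <- jsonlite::read_json(sidecar)
  expect_equal(meta$beta, 100)
  expect_equal(meta$weighting, "carbon-scaled")
  unlink(c(csv, sidecar))
})
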