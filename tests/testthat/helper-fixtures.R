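# Shared fixtures, built once per test run. embed_3d() caches per SMILES,
# so repeated access across test files is cheap.
.fixture_env <- new.env()

fixture_table <- function() {
  if (is.null(.fixture_env$tbl)) .fixture_env$tbl <- coumarin_table()
  .fixture_env$tbl
}

fixture_mol <- function(no) {
  tbl <- fixture_table()
  embed_3d(tbl$smiles[tbl$no == no], name = paste0("compound ", no))
}

fixture_toys <- function() {
  if (is.null(.fixture_env$toys)) .fixture_env$toys <- gen_toy_molecules()
  .fixture_env$toys
}

# Full descriptor matrix over all modelled compounds (used by the pipeline
# and acceptance tests); computed once.
fixture_descriptors <- function() {
  if (is.null(.fixture_env$desc)) {
    tbl <- fixture_table()
    .fixture_env$desc <- descriptor_matrix(tbl[tbl$split != "excluded", ])
  }
  .fixture_env$desc
}

# Brute-force BFS shortest-path oracle, independent of igraph.
bfs_distances <- function(mol) {
  n <- length(mol$elements)
  adj <- vector("list", n)
  for (b in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds[b, 1]; j <- mol$bonds[b, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    D[s, s] <- 0
    frontier <- s
    d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[D[s, nxt] == Inf]
      D[s, nxt] <- d
      frontier <- nxt
    }
  }
  D
}

# Random rigid rotation matrix (QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

rigid_transform <- function(mol, rot, shift) {
  m2 <- mol
  m2$coords <- sweep(mol$coords %*% rot, 2, -shift)
  m2
}
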