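# Atomic property tables for descriptor weighting. Values are the standard
# handbook/descriptor-software constants; each scheme is scaled so that
# carbon has weight 1 (the convention of the 3D-descriptor literature).
#   m: relative atomic mass        v: van der Waals volume (A^3)
#   e: Sanderson electronegativity p: atomic polarizability (A^3)
.atom_props <- list(
  m = c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
        F = 18.998, Cl = 35.453, Br = 79.904, I = 126.904),
  v = c(H = 6.709, C = 22.449, N = 15.599, O = 11.494, S = 24.429,
        F = 9.203, Cl = 23.228, Br = 31.059, I = 38.631),
  e = c(H = 2.592, C = 2.746, N = 3.194, O = 3.654, S = 2.957,
        F = 4.000, Cl = 3.475, Br = 3.219, I = 2.778),
  p = c(H = 0.667, C = 1.76, N = 1.10, O = 0.802, S = 2.90,
        F = 0.557, Cl = 2.18, Br = 3.05, I = 5.35)
)
.weight_codes <- c("u", "m", "v", "e", "p")
.heteroatoms <- c("N", "O", "S", "F", "Cl", "Br", "I")

#' Carbon-scaled atomic weights for 3D descriptors
#'
#' @param scheme one of `"u"` (unit), `"m"` (atomic mass), `"v"` (van der
#'   Waals volume), `"e"` (Sanderson electronegativity), `"p"` (atomic
#'   polarizability). All non-unit schemes are scaled so that w(C) = 1;
#'   polarizability, for instance, divides by 1.76 (the carbon value).
#' @param scaled if `FALSE`, return the raw property values instead of the
#'   carbon-scaled weights.
#' @return named numeric vector over the supported elements.
#' @export
atomic_weights <- function(scheme = c("u", "m", "v", "e", "p"), scaled = TRUE) {
  scheme <- match.arg(scheme)
  if (scheme == "u") {
    w <- .atom_props$p
    w[] <- 1
    return(w)
  }
  tab <- .atom_props[[scheme]]
  if (scaled) tab / tab[["C"]] else tab
}

weights_for <- function(mol, scheme, scaled = TRUE) {
  tab <- atomic_weights(scheme, scaled = scaled)
  missing <- setdiff(unique(mol$elements), names(tab))
  if (length(missing)) stop("no weight for element(s): ", paste(missing, collapse = ", "))
  unname(tab[mol$elements])
}

#' Count R-CX-R atom-centered fragment carbons (C-026)
#'
#' Counts the aromatic carbons whose two ring neighbours are aromatic
#' carbons (R) and whose single remaining heavy substituent is a heteroatom
#' (X: N, O, S or halogen). Aromaticity follows the package rule
#' ([perceive_aromatic()]): only six-membered carbocycles qualify, so the
#' coumarin lactone ring is not aromatic and the fused carbon bearing the
#' ring oxygen is counted through its two benzo-ring neighbours. Carbons at
#' a fusion of two aromatic rings (three aromatic neighbours) never match.
#'
#' @param mol a [molecule3d()].
#' @return integer count.
#' @examples
#' count_c026(embed_3d("c1ccccc1O"))  # phenol: 1
#' @export
count_c026 <- function(mol) {
  sum(acf_counts(mol)[["C-026"]])
}

#' Atom-centered fragment carbon counts
#'
#' Classifies every carbon into the fragment types distinguishable on this
#' chemistry and returns their counts. Aromatic carbons flanked by two
#' aromatic carbons (R) split by their third substituent: hydrogen
#' (`C-024`), carbon (`C-025`), heteroatom (`C-026`); the variants flanked
#' by an aromatic heteroatom (`C-027`/`C-028`/`C-029`) are carried for
#' completeness but cannot occur under the carbocycle-only aromaticity
#' rule. Non-aromatic carbons fall into carbonyl (`C=O`), nitrile (`C#N`),
#' sp3 CH3/CH2/other (`C-sp3.CH3`, `C-sp3.CH2`, `C-sp3`) and a residual
#' class (`C-sp2`).
#'
#' @param mol a [molecule3d()].
#' @return named integer vector of fragment counts.
#' @export
acf_counts <- function(mol) {
  adj <- neighbour_list(mol)
  el <- mol$elements
  arom <- mol$aromatic
  types <- c("C-024", "C-025", "C-026", "C-027", "C-028", "C-029",
             "C=O", "C#N", "C-sp3.CH3", "C-sp3.CH2", "C-sp3", "C-sp2")
  counts <- stats::setNames(integer(length(types)), types)
  dbl <- bond_order_lookup(mol)
  for (i in seq_along(el)) {
    if (el[i] != "C") next
    nb <- adj[[i]]
    heavy <- nb[el[nb] != "H"]
    if (arom[i]) {
      ar_nb <- heavy[arom[heavy]]
      if (length(ar_nb) >= 3) next                      # ring fusion: no type
      flank_het <- any(el[ar_nb] != "C")
      subst <- setdiff(heavy, ar_nb)
      kind <- if (!length(subst)) "H"
              else if (el[subst[1]] %in% .heteroatoms) "X"
              else "R"
      type <- if (!flank_het) switch(kind, H = "C-024", R = "C-025", X = "C-026")
              else            switch(kind, H = "C-027", R = "C-028", X = "C-029")
      counts[type] <- counts[type] + 1L
      next
    }
    orders <- vapply(nb, function(j) dbl[[bond_key(i, j)]], numeric(1))
    nH <- sum(el[nb] == "H")
    if (any(orders == 3) && any(el[nb] == "N")) {
      counts["C#N"] <- counts["C#N"] + 1L
    } else if (any(orders == 2 & el[nb] == "O")) {
      counts["C=O"] <- counts["C=O"] + 1L
    } else if (all(orders == 1)) {
      type <- if (nH >= 3) "C-sp3.CH3" else if (nH == 2) "C-sp3.CH2" else "C-sp3"
      counts[type] <- counts[type] + 1L
    } else {
      counts["C-sp2"] <- counts["C-sp2"] + 1L
    }
  }
  counts
}

#' Radial distribution function descriptor
#'
#' Evaluates the Gaussian-smoothed radial distribution function of the
#' molecule at radius `r`:
#' \deqn{RDF(r) = \sum_{i<j} w_i w_j \exp(-\beta (r - r_{ij})^2)}
#' over all atom pairs (hydrogens included), where \eqn{r_{ij}} is the
#' Euclidean interatomic distance and the weights are carbon-scaled atomic
#' properties. `RDF035p` in the published model is this value at r = 3.5
#' Angstrom with polarizability weights.
#'
#' @param mol a [molecule3d()].
#' @param radius radius r in Angstrom.
#' @param weight weighting scheme code (see [atomic_weights()]).
#' @param beta Gaussian smoothing constant in 1/Angstrom^2. The descriptor
#'   literature's conventional default of 100 is used.
#' @return non-negative numeric value (0 for a single-atom molecule).
#' @export
rdf_value <- function(mol, radius, weight = "p", beta = 100) {
  n <- length(mol$elements)
  if (n < 2) return(0)
  w <- weights_for(mol, weight)
  d <- as.matrix(stats::dist(mol$coords))
  ut <- upper.tri(d)
  ww <- outer(w, w)
  sum(ww[ut] * exp(-beta * (radius - d[ut])^2))
}

#' Atomic leverages from the molecular influence matrix
#'
#' Computes H = M (M'M)^-1 M' with M the row-centered atomic coordinate
#' matrix and returns its diagonal (the atomic leverages of the GETAWAY
#' descriptor family). Rank-deficient geometries (planar or linear
#' molecules) are handled through the pseudo-inverse, so the leverages sum
#' to the coordinate rank (3, 2 or 1).
#'
#' @param mol a [molecule3d()] with at least two atoms.
#' @return numeric vector of leverages in \[0, 1\].
#' @export
influence_leverages <- function(mol) {
  if (length(mol$elements) < 2) stop("need at least two atoms")
  M <- scale(mol$coords, scale = FALSE)
  sv <- svd(M)
  keep <- sv$d > max(sv$d) * 1e-8
  if (!any(keep)) stop("degenerate geometry: all atoms coincident")
  rowSums(sv$u[, keep, drop = FALSE]^2)
}

#' GETAWAY leverage autocorrelation (HATS)
#'
#' \deqn{HATS_k(w) = \sum_{i<j:\, d_{ij}=k} (h_i w_i)(h_j w_j)}
#' for lag k >= 1, where \eqn{h_i} are the atomic leverages of
#' [influence_leverages()], \eqn{d_{ij}} the topological distance, and w
#' carbon-scaled atomic weights; the lag-0 term is
#' \eqn{\sum_i (h_i w_i)^2}. `HATS8p` in the published model is lag 8 with
#' polarizability weights.
#'
#' @param mol a [molecule3d()].
#' @param lag integer topological distance, 0 to 8.
#' @param weight weighting scheme code (see [atomic_weights()]).
#' @return non-negative numeric value (0 when the lag exceeds the graph
#'   diameter).
#' @export
hats_value <- function(mol, lag, weight = "p") {
  if (length(lag) != 1 || lag < 0 || lag > 8) stop("lag must be in 0..8")
  h <- influence_leverages(mol)
  w <- weights_for(mol, weight)
  hw <- h * w
  if (lag == 0) return(sum(hw^2))
  D <- mol$topo_dist
  ut <- upper.tri(D)
  sel <- ut & D == lag
  if (!any(sel)) return(0)
  sum(outer(hw, hw)[sel])
}

.rdf_radii <- seq(1, 15.5, by = 0.5)

rdf_name <- function(radius, weight) {
  sprintf("RDF%03d%s", as.integer(round(radius * 10)), weight)
}

#' Descriptor matrix for a set of compounds
#'
#' Embeds every compound in 3D and computes the full descriptor grid used
#' for feature selection: the atom-centered fragment carbon counts, the
#' radial distribution function at the 30 radii 1.0-15.5 Angstrom for all
#' five weighting schemes, and the leverage autocorrelations at lags 0-8
#' for all five weighting schemes. Column names are stable
#' (`C-026`, `RDF035p`, `HATS8p`, ...).
#'
#' @param compounds a [coumarin_table()] (or any data frame with `no`,
#'   `mol_id` and `smiles` columns).
#' @param seed integer passed to [embed_3d()].
#' @param beta RDF smoothing constant, see [rdf_value()].
#' @return numeric matrix of class `descriptor_matrix` (rows = compounds in
#'   input order, named by compound number) with the weighting metadata in
#'   attributes.
#' @export
descriptor_matrix <- function(compounds, seed = 1L, beta = 100) {
  mols <- lapply(seq_len(nrow(compounds)), function(i) {
    embed_3d(compounds$smiles[i], seed = seed,
             name = paste0("compound ", compounds$no[i]))
  })
  rows <- lapply(mols, function(mol) {
    acf <- acf_counts(mol)
    rdf <- unlist(lapply(.weight_codes, function(wc) {
      vals <- vapply(.rdf_radii, rdf_value, numeric(1), mol = mol,
                     weight = wc, beta = beta)
      stats::setNames(vals, rdf_name(.rdf_radii, wc))
    }))
    hats <- unlist(lapply(.weight_codes, function(wc) {
      vals <- vapply(0:8, hats_value, numeric(1), mol = mol, weight = wc)
      stats::setNames(vals, paste0("HATS", 0:8, wc))
    }))
    c(acf, rdf, hats)
  })
  m <- do.call(rbind, rows)
  rownames(m) <- as.character(compounds$no)
  structure(m, class = c("descriptor_matrix", class(m)),
            weighting = "carbon-scaled", beta = beta, seed = seed)
}

#' @export
print.descriptor_matrix <- function(x, ...) {
  cat("descriptor_matrix:", nrow(x), "compounds x", ncol(x), "descriptors",
      "(beta =", attr(x, "beta"), ", weights:", attr(x, "weighting"), ")\n")
  invisible(x)
}

#' Write a descriptor matrix as CSV with a JSON sidecar
#'
#' @param m a [descriptor_matrix()].
#' @param csv_path output CSV path; the sidecar records the weighting
#'   scheme, smoothing constant, seed and package version next to it.
#' @return invisibly, the sidecar path.
#' @export
write_descriptor_matrix <- function(m, csv_path) {
  df <- data.frame(no = rownames(m), as.data.frame(unclass(m), check.names = FALSE),
                   check.names = FALSE)
  write.csv(df, csv_path, row.names = FALSE)
  sidecar <- paste0(csv_path, ".json")
  jsonlite::write_json(list(
    weighting = attr(m, "weighting"), beta = attr(m, "beta"),
    seed = attr(m, "seed"),
    package = as.character(utils::packageVersion("coumlox"))
  ), sidecar, auto_unbox = TRUE)
  invisible(sidecar)
}
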