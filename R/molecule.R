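#' Molecular structures with 3D coordinates and graph metadata
#'
#' A `molecule3d` bundles everything the 3D descriptors need: element
#' symbols (hydrogens explicit), Cartesian coordinates in Angstrom, the
#' bond list with formal bond orders, per-atom aromaticity flags, and the
#' topological distance matrix (shortest-path bond counts).
#'
#' @param elements character vector of element symbols, hydrogens included.
#' @param coords numeric matrix, one row per atom, columns x/y/z in Angstrom.
#' @param bonds two- or three-column matrix: atom index pairs and (optionally)
#'   formal bond order (1, 2, 3; 4 for an explicitly aromatic bond). Order
#'   defaults to 1.
#' @param name optional molecule label carried through error messages.
#' @return An object of class `molecule3d`.
#' @export
molecule3d <- function(elements, coords, bonds, name = NULL) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  n <- length(elements)
  stopifnot(nrow(coords) == n, ncol(coords) == 3)
  if (!all(is.finite(coords))) stop("non-finite coordinates in molecule ", name)
  bonds <- as.matrix(bonds)
  if (ncol(bonds) == 2) bonds <- cbind(bonds, 1L)
  bonds <- bonds[, 1:3, drop = FALSE]
  storage.mode(bonds) <- "integer"
  colnames(bonds) <- c("from", "to", "order")
  mol <- structure(
    list(elements = elements, coords = coords, bonds = bonds, name = name),
    class = "molecule3d"
  )
  mol$topo_dist <- topological_distances(mol)
  mol$aromatic <- perceive_aromatic(mol)
  mol
}

#' @export
print.molecule3d <- function(x, ...) {
  heavy <- sum(x$elements != "H")
  cat("molecule3d", if (!is.null(x$name)) paste0("'", x$name, "'"), "\n")
  cat("  atoms:", length(x$elements), "(", heavy, "heavy ),",
      nrow(x$bonds), "bonds,", sum(x$aromatic), "aromatic atoms\n")
  invisible(x)
}

#' Shortest-path bond-count matrix
#'
#' Integer matrix of topological distances between all atom pairs, computed
#' on the bond graph. Symmetric with a zero diagonal; disconnected pairs
#' (which do not occur in valid molecules) would be `Inf`.
#'
#' @param mol a `molecule3d` (only `elements` and `bonds` are used).
#' @return integer-valued matrix of shortest-path lengths.
#' @export
topological_distances <- function(mol) {
  n <- length(mol$elements)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, t(mol$bonds[, 1:2, drop = FALSE]))
  d <- igraph::distances(g)
  dimnames(d) <- NULL
  d
}

# Session-scoped cache so each SMILES is embedded at most once.
.embed_cache <- new.env(parent = emptyenv())

#' Embed a SMILES string as a single low-energy 3D conformer
#'
#' Parses the SMILES, adds explicit hydrogens, builds a 3D conformer with
#' OpenBabel's rule-based structure generator and minimizes it with a
#' classical force field (via ChemmineOB). Results are cached per session,
#' so repeated calls with the same SMILES return bitwise-identical
#' coordinates; a rebuild from scratch reproduces the same geometry up to
#' its arbitrary global orientation, which leaves every descriptor in this
#' package (all rotation/translation invariant) unchanged. The `seed`
#' argument is accepted for interface stability but does not alter the
#' result.
#'
#' @param smiles a single SMILES string.
#' @param seed integer; retained for call-signature compatibility with the
#'   stochastic stages of the pipeline (the rule-based builder needs none).
#' @param name optional label used in error messages.
#' @return a [molecule3d].
#' @export
embed_3d <- function(smiles, seed = 1L, name = NULL) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  key <- smiles
  if (!is.null(.embed_cache[[key]])) {
    mol <- .embed_cache[[key]]
    mol$name <- if (is.null(name)) mol$name else name
    return(mol)
  }
  sdf <- tryCatch({
    txt <- ChemmineOB::convertFormat(
      "SMI", "SDF", source = smiles,
      options = data.frame(names = "gen3d", args = "", stringsAsFactors = FALSE))
    if (!nzchar(txt)) stop("OpenBabel returned no structure")
    ChemmineR::read.SDFset(unlist(strsplit(txt, "\n", fixed = TRUE)))
  },
    error = function(e) stop("3D embedding failed for ",
                             if (is.null(name)) smiles else name,
                             ": ", conditionMessage(e), call. = FALSE),
    warning = function(w) stop("3D embedding failed for ",
                               if (is.null(name)) smiles else name,
                               ": ", conditionMessage(w), call. = FALSE)
  )
  ab <- ChemmineR::atomblock(sdf[[1]])
  bb <- ChemmineR::bondblock(sdf[[1]])
  elements <- sub("_.*$", "", rownames(ab))
  coords <- unname(ab[, 1:3, drop = FALSE])
  bonds <- unname(as.matrix(bb[, 1:3, drop = FALSE]))
  mol <- molecule3d(elements, coords, bonds, name = if (is.null(name)) smiles else name)
  mol$sdf <- sdf
  assign(key, mol, envir = .embed_cache)
  mol
}

#' Flag aromatic atoms (six-membered carbocycles only)
#'
#' The aromaticity rule used throughout the package is deliberately narrow:
#' exactly the atoms of six-membered all-carbon rings whose ring bonds carry
#' an alternating single/double Kekule pattern (or explicit aromatic bond
#' order 4) are flagged. The pyranone ring of the coumarin scaffold is never
#' aromatic under this rule, which is what makes the atom-centered fragment
#' counts match their worked interpretation (the ring-fusion carbon bearing
#' the lactone oxygen counts once per scaffold).
#'
#' @param mol a `molecule3d`.
#' @return logical vector, one flag per atom.
#' @export
perceive_aromatic <- function(mol) {
  n <- length(mol$elements)
  flags <- logical(n)
  rings <- six_membered_rings(mol)
  order_lookup <- bond_order_lookup(mol)
  for (ring in rings) {
    if (!all(mol$elements[ring] == "C")) next
    cyc <- c(ring, ring[1])
    orders <- vapply(seq_len(6), function(k) {
      order_lookup[[bond_key(cyc[k], cyc[k + 1])]]
    }, numeric(1))
    aromatic <- all(orders == 4) ||
      (sum(orders == 2) == 3 && sum(orders == 1) == 3 &&
         all(abs(diff(c(orders, orders[1]))) == 1))
    if (aromatic) flags[ring] <- TRUE
  }
  flags
}

bond_key <- function(i, j) paste(min(i, j), max(i, j))

bond_order_lookup <- function(mol) {
  lk <- new.env(parent = emptyenv())
  for (b in seq_len(nrow(mol$bonds))) {
    assign(bond_key(mol$bonds[b, 1], mol$bonds[b, 2]),
           as.numeric(mol$bonds[b, 3]), envir = lk)
  }
  lk
}

# Enumerate all simple cycles of length 6 in the bond graph, each once
# (as an ordered vertex walk). Molecules here have < 60 atoms, so a plain
# DFS from each starting edge is ample.
six_membered_rings <- function(mol) {
  n <- length(mol$elements)
  adj <- vector("list", n)
  for (b in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds[b, 1]; j <- mol$bonds[b, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  seen <- character(0)
  rings <- list()
  walk <- function(path) {
    last <- path[length(path)]
    if (length(path) == 6) {
      if (path[1] %in% adj[[last]]) {
        key <- paste(sort(path), collapse = "-")
        if (!key %in% seen) {
          seen <<- c(seen, key)
          rings[[length(rings) + 1]] <<- path
        }
      }
      return(invisible())
    }
    for (nb in adj[[last]]) {
      if (nb > path[1] && !nb %in% path) walk(c(path, nb))
    }
  }
  for (v in seq_len(n)) walk(v)
  rings
}

#' Heavy-atom neighbour lists
#'
#' @param mol a `molecule3d`.
#' @return list of integer vectors: for each atom, the indices of its bonded
#'   neighbours (hydrogens included; filter by element as needed).
#' @keywords internal
neighbour_list <- function(mol) {
  n <- length(mol$elements)
  adj <- vector("list", n)
  for (b in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds[b, 1]; j <- mol$bonds[b, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

#' Export embedded structures as an SDF (V2000) file
#'
#' @param mols list of `molecule3d` objects produced by [embed_3d()] (the
#'   OpenBabel SDF record is carried on the object).
#' @param path output file path.
#' @return `path`, invisibly.
#' @importFrom methods as
#' @export
write_molecules_sdf <- function(mols, path) {
  sdfs <- lapply(mols, function(m) {
    if (is.null(m$sdf)) stop("molecule '", m$name, "' carries no SDF record")
    m$sdf[[1]]
  })
  names(sdfs) <- vapply(seq_along(mols), function(i) {
    if (is.null(mols[[i]]$name)) paste0("CMP", i) else mols[[i]]$name
  }, "")
  set <- methods::as(sdfs, "SDFset")
  ChemmineR::write.SDF(set, file = path)
  invisible(path)
}
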