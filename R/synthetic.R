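#' Specification of a synthetic QSAR data set
#'
#' Defines a descriptor matrix with block-correlated Gaussian columns and a
#' sparse linear response, so that variable selection and every validation
#' statistic can be exercised against known ground truth without a single
#' molecule. The defaults mirror the modelled data set's geometry: 28
#' training-sized observations, 50 candidate descriptors in correlated
#' blocks, and a 3-descriptor truth.
#'
#' @param n_compounds number of rows.
#' @param n_descriptors number of columns.
#' @param block_size columns per correlated block (the last block may be
#'   smaller); use 1 for independent columns.
#' @param rho within-block correlation (compound correlation matrix must be
#'   positive semi-definite: rho > -1/(block_size - 1)).
#' @param true_subset column indices carrying signal.
#' @param coefficients their regression coefficients.
#' @param intercept response intercept.
#' @param noise_sd Gaussian noise standard deviation.
#' @param n_count_cols how many of the first columns are converted to
#'   non-negative integer counts (rounded, clamped at zero), emulating
#'   fragment-count descriptors.
#' @param seed mandatory integer seed.
#' @return a list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_compounds = 28, n_descriptors = 50,
                           block_size = 5, rho = 0.5,
                           true_subset = c(5, 12, 21),
                           coefficients = c(3, -2, 1),
                           intercept = 0, noise_sd = 0.5,
                           n_count_cols = 0, seed) {
  stopifnot(!missing(seed),
            length(true_subset) == length(coefficients),
            all(true_subset >= 1), all(true_subset <= n_descriptors),
            block_size >= 1)
  if (block_size > 1 && (rho >= 1 || rho <= -1 / (block_size - 1))) {
    stop("correlation structure is not positive semi-definite")
  }
  structure(list(n_compounds = n_compounds, n_descriptors = n_descriptors,
                 block_size = block_size, rho = rho,
                 true_subset = as.integer(true_subset),
                 coefficients = coefficients, intercept = intercept,
                 noise_sd = noise_sd, n_count_cols = n_count_cols,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

with_seed <- function(seed, expr) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  expr
}

#' Generate the synthetic descriptor matrix
#'
#' Standard-normal marginals with the block-correlation structure of the
#' spec, drawn reproducibly from the spec's seed.
#'
#' @param spec a [synthetic_spec()].
#' @return numeric matrix `n_compounds` x `n_descriptors` with columns
#'   `X1`, `X2`, ...
#' @export
gen_descriptors <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    p <- spec$n_descriptors; n <- spec$n_compounds; bs <- spec$block_size
    blocks <- split(seq_len(p), ceiling(seq_len(p) / bs))
    X <- matrix(NA_real_, n, p)
    for (idx in blocks) {
      b <- length(idx)
      S <- matrix(spec$rho, b, b); diag(S) <- 1
      X[, idx] <- matrix(stats::rnorm(n * b), n, b) %*% chol(S)
    }
    if (spec$n_count_cols > 0) {
      cc <- seq_len(min(spec$n_count_cols, p))
      X[, cc] <- pmax(0, round(X[, cc] + 1))
    }
    colnames(X) <- paste0("X", seq_len(p))
    X
  })
}

#' Generate the synthetic response
#'
#' y = intercept + sum over the true subset of b_j x_j + N(0, noise_sd^2),
#' drawn from a seed offset from the spec's (so X and the noise are
#' independent streams). Optionally rescaled affinely into a target range,
#' e.g. the 0.85-1.98 span of a log-percent activity column.
#'
#' @param X matrix from [gen_descriptors()] (or any conforming matrix).
#' @param spec the same [synthetic_spec()].
#' @param rescale_range optional length-2 numeric: affinely map the response
#'   onto this range.
#' @return numeric response vector with the noiseless signal in
#'   `attr(, "signal")`.
#' @export
gen_response <- function(X, spec, rescale_range = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"), ncol(X) >= max(spec$true_subset))
  signal <- spec$intercept +
    drop(X[, spec$true_subset, drop = FALSE] %*% spec$coefficients)
  y <- with_seed(spec$seed + 1L,
                 signal + stats::rnorm(nrow(X), 0, spec$noise_sd))
  if (!is.null(rescale_range)) {
    stopifnot(length(rescale_range) == 2)
    y <- (y - min(y)) / diff(range(y)) * diff(rescale_range) + rescale_range[1]
  }
  attr(y, "signal") <- signal
  y
}

# Geometry helpers for the toy fixtures.
.hexagon <- function(r) {
  ang <- (0:5) * pi / 3
  cbind(r * cos(ang), r * sin(ang), 0)
}

#' Deterministic toy molecules for descriptor unit tests
#'
#' Small hand-built geometries covering the descriptor edge cases: a
#' carbon diatomic at exactly 3.5 Angstrom (the RDF exp(0) case), a linear
#' butane-like chain, planar benzene (a rank-2 geometry), phenol and
#' anisole (one R-CX-R carbon each), catechol (two), toluene (none),
#' bromobenzene, a regular tetrahedron of carbons, and ethane with
#' hydrogens (graph diameter < 8).
#'
#' @return named list of [molecule3d()] objects.
#' @export
gen_toy_molecules <- function() {
  benz_c <- .hexagon(1.39)
  benz_h <- .hexagon(2.47)
  ring_bonds <- cbind(1:6, c(2:6, 1), rep(c(2L, 1L), 3))
  benzene <- molecule3d(
    rep(c("C", "H"), each = 6), rbind(benz_c, benz_h),
    rbind(ring_bonds, cbind(1:6, 7:12, 1L)), name = "benzene")
  sub_ring <- function(name, el_extra, coords_extra, bonds_extra, elements6 = rep("C", 6)) {
    molecule3d(c(elements6, rep("H", 5), el_extra),
               rbind(benz_c, benz_h[2:6, ], coords_extra),
               rbind(ring_bonds, cbind(2:6, 7:11, 1L), bonds_extra),
               name = name)
  }
  phenol <- sub_ring("phenol", c("O", "H"),
                     rbind(c(2.75, 0, 0), c(3.3, 0.8, 0)),
                     rbind(c(1L, 12L, 1L), c(12L, 13L, 1L)))
  anisole <- sub_ring("anisole", c("O", "C", "H", "H", "H"),
                      rbind(c(2.75, 0, 0), c(3.4, 1.2, 0), c(4.5, 1.1, 0),
                            c(3.1, 1.7, 0.9), c(3.1, 1.7, -0.9)),
                      rbind(c(1L, 12L, 1L), c(12L, 13L, 1L), c(13L, 14L, 1L),
                            c(13L, 15L, 1L), c(13L, 16L, 1L)))
  toluene <- sub_ring("toluene", c("C", "H", "H", "H"),
                      rbind(c(2.9, 0, 0), c(3.3, 0.5, 0.9), c(3.3, 0.5, -0.9),
                            c(3.3, -1, 0)),
                      rbind(c(1L, 12L, 1L), c(12L, 13L, 1L), c(12L, 14L, 1L),
                            c(12L, 15L, 1L)))
  bromobenzene <- sub_ring("bromobenzene", "Br", rbind(c(3.29, 0, 0)),
                           rbind(c(1L, 12L, 1L)))
  catechol <- molecule3d(
    c(rep("C", 6), rep("H", 4), "O", "H", "O", "H"),
    rbind(benz_c, benz_h[3:6, ], c(2.75, 0, 0), c(3.3, 0.8, 0),
          c(1.375, 2.382, 0), c(2.1, 3.0, 0)),
    rbind(ring_bonds, cbind(3:6, 7:10, 1L),
          c(1L, 11L, 1L), c(11L, 12L, 1L), c(2L, 13L, 1L), c(13L, 14L, 1L)),
    name = "catechol")
  diatomic <- molecule3d(c("C", "C"),
                         rbind(c(0, 0, 0), c(3.5, 0, 0)),
                         cbind(1L, 2L, 1L), name = "C2 at 3.5 A")
  chain <- molecule3d(rep("C", 4),
                      cbind(seq(0, 4.5, by = 1.5), 0, 0),
                      cbind(1:3, 2:4, 1L), name = "linear C4")
  tetrahedron <- molecule3d(rep("C", 4),
                            rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)),
                            rbind(c(1L, 2L, 1L), c(1L, 3L, 1L), c(1L, 4L, 1L)),
                            name = "tetrahedron")
  ethane <- embed_3d("CC", name = "ethane")
  list(benzene = benzene, phenol = phenol, anisole = anisole,
       toluene = toluene, catechol = catechol, bromobenzene = bromobenzene,
       diatomic = diatomic, chain = chain, tetrahedron = tetrahedron,
       ethane = ethane)
}

#' Planted-signal recovery experiment for the subset-selection GA
#'
#' Runs the end-to-end recovery check: for each seed, draw a synthetic
#' descriptor matrix and sparse response from `spec`, run [ga_select()],
#' and record whether the top-ranked subset is exactly the planted one.
#'
#' @param spec a [synthetic_spec()] (its seed is replaced per run).
#' @param seeds integer vector of run seeds.
#' @param config_fn function(seed) returning the [ga_config()] to use.
#' @return list: `recovery_rate`, logical `recovered` per seed, and the
#'   per-run top subsets.
#' @export
ga_recovery_experiment <- function(spec, seeds = 1:20,
                                   config_fn = function(s) ga_config(seed = s)) {
  results <- lapply(seeds, function(s) {
    sp <- spec
    sp$seed <- as.integer(s)
    X <- gen_descriptors(sp)
    y <- gen_response(X, sp)
    ga <- ga_select(X, as.numeric(y), config_fn(s))
    top <- match(ga$subsets[[1]], colnames(X))
    list(recovered = identical(sort(top), sort(sp$true_subset)),
         top = top, model = ga$models[[1]])
  })
  recovered <- vapply(results, `[[`, logical(1), "recovered")
  list(recovery_rate = mean(recovered), recovered = recovered,
       subsets = lapply(results, `[[`, "top"),
       models = lapply(results, `[[`, "model"))
}
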