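#' Genetic-algorithm configuration
#'
#' Hyperparameters of the subset-selection GA. The subset size limit
#' defaults to three descriptors, the cap used for the published model.
#'
#' @param population_size number of chromosomes per generation.
#' @param generations number of generations.
#' @param p_crossover crossover probability per offspring.
#' @param p_mutation per-gene mutation probability.
#' @param subset_size number of descriptors per model.
#' @param elitism number of best chromosomes copied unchanged.
#' @param seed mandatory integer seed; the run is fully reproducible.
#' @param n_keep how many top-ranked unique subsets to refit and return.
#' @return a list of class `ga_config`.
#' @export
ga_config <- function(population_size = 200, generations = 300,
                      p_crossover = 0.8, p_mutation = 0.05,
                      subset_size = 3, elitism = 5, seed, n_keep = 10) {
  stopifnot(p_crossover >= 0, p_crossover <= 1,
            p_mutation >= 0, p_mutation <= 1,
            subset_size >= 1, elitism >= 0, !missing(seed))
  structure(list(population_size = population_size, generations = generations,
                 p_crossover = p_crossover, p_mutation = p_mutation,
                 subset_size = subset_size, elitism = elitism,
                 seed = as.integer(seed), n_keep = n_keep),
            class = "ga_config")
}

# Leave-one-out Q2 of the OLS fit on a column subset; -Inf for unusable
# (rank-deficient or leverage-one) subsets so they lose every comparison.
subset_fitness <- function(x, y, cols) {
  X <- cbind(1, x[, cols, drop = FALSE])
  qx <- qr(X)
  if (qx$rank < ncol(X)) return(-Inf)
  h <- rowSums(qr.Q(qx)^2)
  if (any(h > 1 - 1e-10)) return(-Inf)
  e <- qr.resid(qx, y)
  1 - sum((e / (1 - h))^2) / sum((y - mean(y))^2)
}

#' Genetic-algorithm descriptor subset selection for MLR
#'
#' Evolves fixed-length descriptor subsets; the fitness of a subset is the
#' leave-one-out cross-validated Q^2 of its OLS fit, so selection rewards
#' predictive rather than merely descriptive subsets. Tournament selection,
#' union-resampling crossover, per-gene uniform mutation, and elitism.
#' Every subset ever evaluated is cached, so the returned ranking draws on
#' the whole search history, with duplicates collapsed.
#'
#' @param x numeric descriptor matrix with column names.
#' @param y numeric response.
#' @param config a [ga_config()] (the seed is mandatory).
#' @return an object of class `lox_ga`: ranked list of refitted `lox_mlr`
#'   models (`$models`), their subsets and fitness values, and the
#'   best-fitness trajectory per generation (`$history`, non-decreasing by
#'   elitism).
#' @export
ga_select <- function(x, y, config) {
  stopifnot(inherits(config, "ga_config"))
  x <- as.matrix(x)
  p <- ncol(x); k <- config$subset_size
  if (p < k) stop("fewer columns than the subset size")
  if (nrow(x) < k + 3) stop("too few rows for cross-validated fitting")
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(p))

  cache <- new.env(parent = emptyenv())
  evaluate <- function(cols) {
    key <- paste(cols, collapse = ",")
    val <- cache[[key]]
    if (is.null(val)) {
      val <- subset_fitness(x, y, cols)
      assign(key, val, envir = cache)
    }
    val
  }

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  new_chrom <- function() sort(sample.int(p, k))
  pop <- replicate(config$population_size, new_chrom(), simplify = FALSE)
  fit <- vapply(pop, evaluate, numeric(1))
  history <- numeric(config$generations)

  for (gen in seq_len(config$generations)) {
    ord <- order(fit, decreasing = TRUE)
    elite <- pop[ord[seq_len(min(config$elitism, length(pop)))]]
    tournament <- function() {
      cand <- sample.int(length(pop), 2)
      pop[[cand[which.max(fit[cand])]]]
    }
    children <- vector("list", config$population_size - length(elite))
    for (i in seq_along(children)) {
      child <- if (stats::runif(1) < config$p_crossover) {
        pool <- unique(c(tournament(), tournament()))
        sort(sample(pool, k))
      } else tournament()
      mut <- stats::runif(k) < config$p_mutation
      n_mut <- min(sum(mut), p - k)
      if (n_mut > 0) {
        free <- setdiff(seq_len(p), child)
        child[which(mut)[seq_len(n_mut)]] <- free[sample.int(length(free), n_mut)]
        child <- sort(child)
      }
      children[[i]] <- child
    }
    pop <- c(elite, children)
    fit <- vapply(pop, evaluate, numeric(1))
    history[gen] <- max(fit)
  }

  keys <- ls(cache)
  scores <- vapply(keys, function(k_) cache[[k_]], numeric(1))
  subsets <- lapply(strsplit(keys, ","), as.integer)
  # rank: fitness desc, then fewer descriptors, then lexicographic subset
  lex <- vapply(subsets, function(s) paste(sprintf("%05d", s), collapse = ""), "")
  ord <- order(-scores, lengths(subsets), lex)
  top <- head(ord, config$n_keep)
  models <- lapply(subsets[top], function(s) mlr_fit(x[, s, drop = FALSE], y))
  structure(list(
    models = models,
    subsets = lapply(subsets[top], function(s) colnames(x)[s]),
    fitness = unname(scores[top]),
    n_evaluated = length(keys),
    history = history,
    config = config
  ), class = "lox_ga")
}

#' @export
print.lox_ga <- function(x, ...) {
  cat("GA descriptor selection:", x$n_evaluated, "unique subsets evaluated\n")
  for (i in seq_along(x$models)) {
    cat(sprintf("  %2d. Q2loo = %7.4f  {%s}\n", i, x$fitness[i],
                paste(x$subsets[[i]], collapse = ", ")))
    if (i >= 5) break
  }
  invisible(x)
}

#' @importFrom utils head
NULL
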