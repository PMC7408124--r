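#' Percent inhibition from assay absorbances
#'
#' Inhibition rate (%) = (1 - (A_S - A_B) / (A_C - A_B)) * 100, where A_S
#' is the sample absorbance, A_B the blank and A_C the uninhibited
#' control. Values below 0 (activation) or above 100 are legitimate and
#' returned as-is.
#'
#' @param a_s,a_b,a_c sample, blank and control absorbances (vectorized).
#' @return percent inhibition.
#' @examples
#' inhibition_rate(0.5, 0.1, 0.9)  # halfway between blank and control: 50
#' @export
inhibition_rate <- function(a_s, a_b, a_c) {
  if (any(a_c == a_b)) stop("control and blank absorbances coincide")
  (1 - (a_s - a_b) / (a_c - a_b)) * 100
}

#' Base-10 log of a percent activity
#'
#' The modelling response is the base-10 logarithm of the percent
#' inhibition; non-positive percentages have no log and are a domain error
#' (such compounds are excluded from modelling).
#'
#' @param pct percent inhibition, must be > 0 (vectorized).
#' @return log10 of the percentage.
#' @examples
#' log_activity(100)  # 2
#' @export
log_activity <- function(pct) {
  if (any(!is.finite(pct)) || any(pct <= 0)) {
    stop("percent activity must be finite and positive")
  }
  log10(pct)
}

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis under a single seed.
#'
#' @param seed top-level integer seed keying every stochastic stage.
#' @param beta RDF Gaussian smoothing constant (1/Angstrom^2).
#' @param min_nonzero_fraction zero-test threshold, see [zero_test()].
#' @param r2_threshold correlation-pruning threshold, see
#'   [correlation_prune()].
#' @param split `"fixture"` honours the published train/test assignment;
#'   `"clustering"` re-derives a test set with [select_test_set()].
#' @param n_test test-set size when `split = "clustering"`.
#' @param model which published training configuration to mirror: `"eq2"`
#'   (outlier removed, n = 28) or `"eq1"` (n = 29).
#' @param ga a [ga_config()]; defaults to the package defaults keyed to
#'   `seed`.
#' @param n_scramble Y-scrambling permutations.
#' @param outdir output directory for [run_pipeline()] artifacts.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, beta = 100, min_nonzero_fraction = 0.1,
                            r2_threshold = 0.7,
                            split = c("fixture", "clustering"), n_test = 8,
                            model = c("eq2", "eq1"),
                            ga = ga_config(seed = seed),
                            n_scramble = 500, outdir = tempfile("coumlox_run_")) {
  structure(list(seed = as.integer(seed), beta = beta,
                 min_nonzero_fraction = min_nonzero_fraction,
                 r2_threshold = r2_threshold, split = match.arg(split),
                 n_test = n_test, model = match.arg(model), ga = ga,
                 n_scramble = n_scramble, outdir = outdir),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order on the coumarin data set: build the
#' compound table, embed and compute descriptors, filter them, assign the
#' train/test split, select descriptor subsets with the GA, validate the
#' best model, place all compounds in the applicability domain, and
#' predict with the frozen published equation. All tables are written to
#' `config$outdir` (descriptor CSV + JSON sidecar, filter report, split
#' assignment, ranked models, validation report, Williams data, and a
#' predictions table comparing the refit and the published equation
#' against the published calculated column), together with a log of seeds
#' and timings.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with every intermediate object (`table`,
#'   `descriptors`, `filter`, `split`, `ga`, `fit`, `validation`,
#'   `predictions`, `paths`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(config$outdir, f)
  log_lines <- c(paste("seed:", config$seed),
                 paste("package:", as.character(utils::packageVersion("coumlox"))))

  tbl <- coumarin_table()
  write_compound_table(tbl, path("compounds.csv"), path("compounds.smi"))

  modeled <- tbl[tbl$split != "excluded", , drop = FALSE]
  desc <- descriptor_matrix(modeled, seed = config$seed, beta = config$beta)
  write_descriptor_matrix(desc, path("descriptors.csv"))

  filt <- filter_descriptors(desc, config$min_nonzero_fraction, config$r2_threshold)
  write_filter_report(filt$report, path("filter_report.json"))

  if (config$split == "fixture") {
    split <- modeled$split
  } else {
    split <- select_test_set(filt$matrix, modeled$log_lox, n_test = config$n_test)
  }
  if (config$model == "eq2") split[split == "train" & modeled$outlier] <- "excluded"
  split_df <- data.frame(no = modeled$no, mol_id = modeled$mol_id, split = split)
  write.csv(split_df, path("split.csv"), row.names = FALSE)

  train <- split == "train"
  test <- split == "test"
  x_tr <- filt$matrix[train, , drop = FALSE]
  y_tr <- modeled$log_lox[train]
  x_te <- filt$matrix[test, , drop = FALSE]
  y_te <- modeled$log_lox[test]

  ga <- ga_select(x_tr, y_tr, config$ga)
  fit <- ga$models[[1]]
  jsonlite::write_json(list(
    subsets = ga$subsets, fitness = ga$fitness,
    best = list(descriptors = fit$descriptor_names,
                coefficients = as.list(fit$coefficients),
                std_coefficients = as.list(fit$std_coefficients),
                n = fit$n, R2 = fit$r_squared, s = fit$sigma)
  ), path("models.json"), auto_unbox = TRUE, digits = NA)

  val <- validate_model(fit, x_te, y_te, n_scramble = config$n_scramble,
                        seed = config$seed,
                        ids_train = modeled$no[train], ids_ext = modeled$no[test])
  write_validation_report(val, path("validation.json"), path("validation.csv"),
                          path("williams.csv"))

  pub <- published_model(config$model)
  full <- descriptor_columns(desc, pub$descriptor_names)
  predictions <- data.frame(
    no = modeled$no, mol_id = modeled$mol_id, split = split,
    log_lox = modeled$log_lox,
    calc_published = round(modeled$calc_eq2, 2),
    pred_published = round(predict(pub, full), 2),
    pred_refit = round(predict(fit, as.data.frame(desc, check.names = FALSE)), 2)
  )
  write.csv(predictions, path("predictions.csv"), row.names = FALSE)

  log_lines <- c(log_lines,
                 paste("descriptors:", ncol(desc), "->", ncol(filt$matrix), "after filtering"),
                 paste("train/test:", sum(train), "/", sum(test)),
                 paste("best subset:", paste(fit$descriptor_names, collapse = ", ")),
                 paste("elapsed_s:", round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 1)))
  writeLines(log_lines, path("run.log"))

  invisible(list(table = tbl, descriptors = desc, filter = filt$report,
                 split = split_df, ga = ga, fit = fit, validation = val,
                 predictions = predictions,
                 paths = list(outdir = config$outdir)))
}

descriptor_columns <- function(desc, names) {
  missing <- setdiff(names, colnames(desc))
  if (length(missing)) stop("descriptor column(s) missing: ",
                            paste(missing, collapse = ", "))
  as.data.frame(unclass(desc)[, names, drop = FALSE], check.names = FALSE)
}
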