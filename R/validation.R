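#' Leave-one-out cross-validated Q^2
#'
#' Q^2 = 1 - PRESS/TSS with PRESS computed in closed form from the hat
#' diagonal, PRESS = sum((e_i / (1 - h_ii))^2), which is algebraically
#' identical to refitting the model n times with one observation held out.
#'
#' @param x descriptor matrix (no intercept column).
#' @param y response vector.
#' @return Q^2 (can be negative for models worse than the training mean).
#' @export
q2_loo <- function(x, y) {
  x <- as.matrix(x)
  qx <- qr(cbind(1, x))
  if (qx$rank < ncol(x) + 1) stop("rank-deficient descriptor block")
  h <- rowSums(qr.Q(qx)^2)
  if (any(h > 1 - 1e-10)) stop("degenerate leverage (h = 1): LOO undefined")
  e <- qr.resid(qx, y)
  1 - sum((e / (1 - h))^2) / sum((y - mean(y))^2)
}

#' Leave-one-out predictions of a fitted model
#'
#' @param fit a fitted [mlr_fit()] model.
#' @return vector of deleted-observation predictions.
#' @export
loo_predictions <- function(fit) {
  stopifnot(inherits(fit, "lox_mlr"))
  fit$y - fit$residuals / (1 - fit$hat)
}

#' Lin's concordance correlation coefficient
#'
#' Agreement of two vectors around the identity line:
#' CCC = 2 s_xy / (s_x^2 + s_y^2 + (mean x - mean y)^2), with population
#' (1/n) moments.
#'
#' @param x,y numeric vectors of equal length.
#' @return CCC in \[-1, 1\].
#' @export
ccc <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxy <- sum((x - mx) * (y - my)) / n
  sx2 <- sum((x - mx)^2) / n
  sy2 <- sum((y - my)^2) / n
  2 * sxy / (sx2 + sy2 + (mx - my)^2)
}

#' External predictivity metrics
#'
#' The external-validation block of a QSAR report: prediction errors on the
#' held-out compounds and the three predictive squared correlation
#' coefficients, which differ only in the reference variance:
#' Q2F1 references the external deviations from the *training* mean, Q2F2
#' from the external mean, and Q2F3 compares per-observation mean squared
#' errors against the training variance. Q2F1 >= Q2F2 always, because the
#' external sum of squares about the training mean is never smaller than
#' about its own mean.
#'
#' @param model a fitted `lox_mlr` (or [published_model()]).
#' @param x_ext descriptor matrix (or data frame) of the external set.
#' @param y_ext observed external responses.
#' @param y_train observed training responses (for the reference mean and
#'   variance).
#' @return named list: `RMSE_ext`, `MAE_ext`, `R2_ext`, `CCC_ext`, `Q2_F1`,
#'   `Q2_F2`, `Q2_F3`.
#' @export
external_metrics <- function(model, x_ext, y_ext, y_train) {
  stopifnot(length(y_ext) >= 1)
  pred <- predict(model, x_ext)
  press <- sum((y_ext - pred)^2)
  n_ext <- length(y_ext)
  f2_den <- sum((y_ext - mean(y_ext))^2)
  degenerate <- stats::sd(pred) == 0 || stats::sd(y_ext) == 0
  list(
    RMSE_ext = sqrt(press / n_ext),
    MAE_ext = mean(abs(y_ext - pred)),
    R2_ext = if (degenerate) NA_real_ else stats::cor(y_ext, pred)^2,
    CCC_ext = ccc(y_ext, pred),
    Q2_F1 = 1 - press / sum((y_ext - mean(y_train))^2),
    Q2_F2 = if (f2_den == 0) NA_real_ else 1 - press / f2_den,
    Q2_F3 = 1 - (press / n_ext) /
      (sum((y_train - mean(y_train))^2) / length(y_train))
  )
}

# Squared correlation of a no-intercept (through-origin) fit of y on x,
# with the ordinary total sum of squares in the denominator.
r2_origin <- function(x, y) {
  k <- sum(x * y) / sum(x^2)
  1 - sum((y - k * x)^2) / sum((y - mean(y))^2)
}

#' The rm^2 agreement metrics
#'
#' rm^2 = r^2 (1 - sqrt(r^2 - r0^2)), where r^2 is the ordinary squared
#' correlation of observed and predicted values and r0^2 its through-origin
#' counterpart. Computed in both directions (observed on predicted and
#' predicted on observed); reported as their mean and absolute difference.
#' Systematic shifts between the two vectors penalize the through-origin
#' fit and drive rm^2 down, which is what the metric is for.
#'
#' @param y_obs,y_pred numeric vectors (length >= 3).
#' @return list with `average` and `difference`.
#' @export
r2m_metrics <- function(y_obs, y_pred) {
  stopifnot(length(y_obs) == length(y_pred), length(y_obs) >= 3)
  if (stats::sd(y_obs) == 0 || stats::sd(y_pred) == 0) {
    stop("zero variance in observed or predicted values")
  }
  r2 <- stats::cor(y_obs, y_pred)^2
  rm2_dir <- function(x, y) {         # regression of y on x
    r02 <- r2_origin(x, y)
    r2 * (1 - sqrt(pmax(r2 - r02, 0)))
  }
  a <- rm2_dir(y_pred, y_obs)
  b <- rm2_dir(y_obs, y_pred)
  list(average = (a + b) / 2, difference = abs(a - b))
}

#' Multivariate K correlation index
#'
#' The global correlation index of a variable block, computed from the
#' eigenvalues of its correlation matrix:
#' K = sum_j |lambda_j / sum(lambda) - 1/p| / (2 (p - 1) / p).
#' K = 0 for mutually orthogonal columns (all eigenvalues equal) and K = 1
#' for total collinearity. With `y` supplied, the response is appended as
#' an extra column (the Kxy of a QSAR report; deltaK = Kxy - Kxx).
#'
#' @param x numeric matrix with at least two columns.
#' @param y optional response vector to append.
#' @return K in \[0, 1\].
#' @export
k_correlation <- function(x, y = NULL) {
  x <- as.matrix(x)
  if (!is.null(y)) x <- cbind(x, y)
  if (ncol(x) < 2) stop("need at least two columns")
  if (any(apply(x, 2, stats::sd) == 0)) stop("constant column in K computation")
  lambda <- eigen(stats::cor(x), symmetric = TRUE, only.values = TRUE)$values
  p <- ncol(x)
  sum(abs(lambda / sum(lambda) - 1 / p)) / (2 * (p - 1) / p)
}

#' Y-scrambling robustness test
#'
#' Permutes the response `n_iter` times, refits the model on each permuted
#' response, and reports the mean (with standard error) of the resulting
#' R^2 and Q^2_LOO. A real structure-activity model should have scrambled
#' means far below its own statistics; under a pure-noise null the expected
#' R^2 is about p / (n - 1).
#'
#' @param x descriptor matrix.
#' @param y response vector.
#' @param n_iter number of permutations (at least 100).
#' @param seed integer seed; the permutation stream is reproducible.
#' @return list: `R2_scr`, `Q2_scr` (means), `R2_scr_se`, `Q2_scr_se`.
#' @export
y_scramble <- function(x, y, n_iter = 500, seed = 1L) {
  stopifnot(n_iter >= 100)
  x <- as.matrix(x)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  qx <- qr(cbind(1, x))
  h <- rowSums(qr.Q(qx)^2)
  r2 <- numeric(n_iter); q2 <- numeric(n_iter)
  for (i in seq_len(n_iter)) {
    ys <- sample(y)
    e <- qr.resid(qx, ys)
    tss <- sum((ys - mean(ys))^2)
    r2[i] <- 1 - sum(e^2) / tss
    q2[i] <- 1 - sum((e / (1 - h))^2) / tss
  }
  list(R2_scr = mean(r2), Q2_scr = mean(q2),
       R2_scr_se = stats::sd(r2) / sqrt(n_iter),
       Q2_scr_se = stats::sd(q2) / sqrt(n_iter))
}

#' Leverage-based applicability domain (Williams plot data)
#'
#' Computes, for every supplied compound, its leverage
#' h = x' (X'X)^-1 x (with intercept-augmented descriptor vectors and X the
#' training block) and its standardized residual e/s (s = the training
#' residual standard deviation). Training compounds with |standardized
#' residual| > 2 are flagged response outliers; any compound with h above
#' the warning leverage h* = 3 p'/n is outside the applicability domain.
#'
#' @param fit a fitted [mlr_fit()] model.
#' @param x_new descriptor matrix of the compounds to place (training
#'   and/or external); must carry the model's descriptor columns.
#' @param y_new observed responses aligned with `x_new` (NA allowed; those
#'   rows get no residual).
#' @param ids optional identifiers for the rows.
#' @param set optional character vector labelling each row (e.g.
#'   `"train"`/`"test"`).
#' @return data frame of class `williams_data` with columns `id`, `set`,
#'   `leverage`, `std_residual`, `outlier`, `out_of_domain`; the warning
#'   leverage is in `attr(, "h_star")`.
#' @export
applicability_domain <- function(fit, x_new, y_new = NULL, ids = NULL, set = NULL) {
  stopifnot(inherits(fit, "lox_mlr"))
  if (is.null(fit$x)) stop("the model carries no training data")
  Xtr <- cbind(1, fit$x)
  xtx_inv <- chol2inv(chol(crossprod(Xtr)))
  nd <- as.matrix(as.data.frame(x_new)[, fit$descriptor_names, drop = FALSE])
  Xn <- cbind(1, nd)
  lev <- rowSums((Xn %*% xtx_inv) * Xn)
  h_star <- 3 * (fit$p + 1) / fit$n
  std_res <- rep(NA_real_, nrow(Xn))
  if (!is.null(y_new)) {
    pred <- drop(Xn %*% fit$coefficients)
    std_res <- (y_new - pred) / fit$sigma
  }
  out <- data.frame(
    id = if (is.null(ids)) seq_len(nrow(Xn)) else ids,
    set = if (is.null(set)) "train" else set,
    leverage = lev,
    std_residual = std_res,
    outlier = !is.na(std_res) & abs(std_res) > 2,
    out_of_domain = lev > h_star,
    stringsAsFactors = FALSE
  )
  attr(out, "h_star") <- h_star
  class(out) <- c("williams_data", "data.frame")
  out
}

#' Full validation report for a QSAR model
#'
#' Assembles the complete statistic set of a QSAR model report: training
#' fit (R^2, adjusted R^2, s, F, RMSE, MAE, CCC), descriptor collinearity
#' (Kxx, deltaK), internal validation (Q^2_LOO and the cross-validated
#' RMSE/MAE/CCC from leave-one-out predictions), Y-scrambling means,
#' external validation (RMSE, MAE, R^2, CCC, Q2F1-F3, rm^2 average and
#' difference), and the Williams applicability-domain data for the training
#' and external compounds.
#'
#' @param fit a fitted [mlr_fit()] model.
#' @param x_ext,y_ext external (test) descriptors and responses.
#' @param n_scramble permutations for the Y-scrambling block.
#' @param seed seed for the scrambling permutations.
#' @param ids_train,ids_ext optional compound identifiers.
#' @return an object of class `lox_validation`: a list of statistics plus
#'   `$williams`; `print` shows the report table, `as.data.frame` flattens
#'   the statistics, `plot` draws the Williams plot.
#' @export
validate_model <- function(fit, x_ext, y_ext, n_scramble = 500, seed = 1L,
                           ids_train = NULL, ids_ext = NULL) {
  stopifnot(inherits(fit, "lox_mlr"))
  y <- fit$y
  n <- fit$n
  loo <- loo_predictions(fit)
  scr <- y_scramble(fit$x, y, n_iter = n_scramble, seed = seed)
  ext <- external_metrics(fit, x_ext, y_ext, y)
  rm2 <- r2m_metrics(y_ext, predict(fit, x_ext))
  kxx <- k_correlation(fit$x)
  will <- rbind(
    applicability_domain(fit, fit$x, y, ids = ids_train, set = "train"),
    applicability_domain(fit, x_ext, y_ext, ids = ids_ext, set = "test")
  )
  attr(will, "h_star") <- 3 * (fit$p + 1) / n
  stats_list <- list(
    N_tr = n, N_ext = length(y_ext),
    R2 = fit$r_squared, R2_adj = fit$adj_r_squared,
    s = fit$sigma, F = fit$fstatistic,
    Kxx = kxx, dK = k_correlation(fit$x, y) - kxx,
    RMSE_tr = sqrt(mean(fit$residuals^2)),
    MAE_tr = mean(abs(fit$residuals)),
    CCC_tr = ccc(y, fit$fitted),
    Q2_LOO = q2_loo(fit$x, y),
    RMSE_cv = sqrt(mean((y - loo)^2)),
    MAE_cv = mean(abs(y - loo)),
    CCC_cv = ccc(y, loo),
    R2_Yscr = scr$R2_scr, Q2_Yscr = scr$Q2_scr,
    RMSE_ext = ext$RMSE_ext, MAE_ext = ext$MAE_ext,
    R2_ext = ext$R2_ext, CCC_ext = ext$CCC_ext,
    Q2_F1 = ext$Q2_F1, Q2_F2 = ext$Q2_F2, Q2_F3 = ext$Q2_F3,
    r2m_average = rm2$average, r2m_difference = rm2$difference
  )
  structure(c(stats_list, list(
    h_star = 3 * (fit$p + 1) / n,
    williams = will,
    outliers = will$id[will$outlier],
    out_of_domain = will$id[will$out_of_domain]
  )), class = "lox_validation")
}

#' @export
print.lox_validation <- function(x, digits = 3, ...) {
  stat_names <- c("N_tr", "N_ext", "R2", "R2_adj", "s", "F", "Kxx", "dK",
                  "RMSE_tr", "MAE_tr", "CCC_tr", "Q2_LOO", "RMSE_cv",
                  "MAE_cv", "CCC_cv", "R2_Yscr", "Q2_Yscr", "RMSE_ext",
                  "MAE_ext", "R2_ext", "CCC_ext", "Q2_F1", "Q2_F2", "Q2_F3",
                  "r2m_average", "r2m_difference")
  cat("QSAR validation report\n")
  for (nm in stat_names) {
    cat(sprintf("  %-16s %s\n", nm, signif(x[[nm]], digits)))
  }
  cat(sprintf("  %-16s %s\n", "h*", signif(x$h_star, digits)))
  cat("  outliers (|std res| > 2):",
      if (length(x$outliers)) paste(x$outliers, collapse = ", ") else "none", "\n")
  cat("  out of domain (h > h*):",
      if (length(x$out_of_domain)) paste(x$out_of_domain, collapse = ", ") else "none", "\n")
  invisible(x)
}

#' @export
as.data.frame.lox_validation <- function(x, ...) {
  keep <- !names(x) %in% c("williams", "outliers", "out_of_domain")
  data.frame(statistic = names(x)[keep],
             value = unlist(x[keep], use.names = FALSE))
}

#' @export
plot.lox_validation <- function(x, ...) {
  will <- x$williams
  pch <- ifelse(will$set == "test", 17, 16)
  ylim <- range(c(will$std_residual, -2.5, 2.5), na.rm = TRUE)
  xlim <- range(c(will$leverage, x$h_star * 1.1))
  graphics::plot(will$leverage, will$std_residual, pch = pch,
                 xlab = "leverage h", ylab = "standardized residual",
                 xlim = xlim, ylim = ylim,
                 main = "Williams plot", ...)
  graphics::abline(h = c(-2, 2), lty = 2)
  graphics::abline(v = x$h_star, lty = 3)
  flagged <- will$outlier | will$out_of_domain
  if (any(flagged)) {
    graphics::text(will$leverage[flagged], will$std_residual[flagged],
                   labels = will$id[flagged], pos = 3, cex = 0.8)
  }
  invisible(x)
}

#' Write a validation report as JSON and flat CSV
#'
#' @param report a `lox_validation`.
#' @param json_path,csv_path,williams_path output paths (`NULL` skips).
#' @return invisibly, the list of paths written.
#' @export
write_validation_report <- function(report, json_path = NULL, csv_path = NULL,
                                    williams_path = NULL) {
  if (!is.null(json_path)) {
    keep <- !names(report) %in% c("williams")
    jsonlite::write_json(unclass(report)[keep], json_path,
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv_path)) write.csv(as.data.frame(report), csv_path, row.names = FALSE)
  if (!is.null(williams_path)) {
    write.csv(as.data.frame(report$williams), williams_path, row.names = FALSE)
  }
  invisible(list(json = json_path, csv = csv_path, williams = williams_path))
}
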