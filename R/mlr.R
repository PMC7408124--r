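#' Ordinary least squares with QSAR diagnostics
#'
#' Fits a multiple linear regression of a response on a small descriptor
#' block and returns the quantities the downstream validation battery
#' needs: coefficients, standardized coefficients, residuals, the hat
#' diagonal, and the fit statistics R^2, adjusted R^2, residual standard
#' deviation s and the Fisher ratio F.
#'
#' @param x numeric matrix or data frame of descriptors (no intercept
#'   column; one is added).
#' @param y numeric response vector.
#' @param ... unused.
#' @return an object of class `lox_mlr` with `print`, `summary`, `coef`,
#'   `predict`, `residuals` and `fitted` methods.
#' @examples
#' x <- matrix(rnorm(60), 20); colnames(x) <- c("a", "b", "c")
#' fit <- mlr_fit(x, x %*% c(1, -1, 2) + rnorm(20, sd = 0.1))
#' summary(fit)
#' @export
mlr_fit <- function(x, y, ...) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  n <- nrow(x); p <- ncol(x)
  stopifnot(length(y) == n)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(p))
  if (n <= p + 1) stop("need more observations than parameters")
  X <- cbind("(Intercept)" = 1, x)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop_cols <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("descriptor block is rank deficient; collinear column(s): ",
         paste(drop_cols, collapse = ", "))
  }
  beta <- qr.coef(qx, y)
  fitted <- drop(X %*% beta)
  res <- y - fitted
  hat <- rowSums(qr.Q(qx)^2)
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  p_prime <- p + 1
  structure(list(
    coefficients = beta,
    descriptor_names = colnames(x),
    std_coefficients = beta[-1] * apply(x, 2, stats::sd) / stats::sd(y),
    n = n, p = p,
    fitted = fitted, residuals = res, hat = hat,
    r_squared = r2,
    adj_r_squared = 1 - (1 - r2) * (n - 1) / (n - p_prime),
    sigma = sqrt(rss / (n - p_prime)),
    fstatistic = (r2 / p) / ((1 - r2) / (n - p_prime)),
    x = x, y = y,
    call = match.call()
  ), class = "lox_mlr")
}

#' Fit an MLR from a formula
#'
#' Convenience wrapper around [mlr_fit()] with the usual formula/data
#' interface (no transformations beyond column selection are intended).
#'
#' @param formula model formula, e.g. log_lox on the three model descriptors
#'   (backtick non-syntactic names such as C-026).
#' @param data data frame holding the response and descriptors.
#' @return a `lox_mlr` object.
#' @export
mlr_fit_formula <- function(formula, data) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  x <- stats::model.matrix(attr(mf, "terms"), mf)[, -1, drop = FALSE]
  mlr_fit(x, y)
}

#' @export
coef.lox_mlr <- function(object, ...) object$coefficients

#' @export
residuals.lox_mlr <- function(object, ...) object$residuals

#' @export
fitted.lox_mlr <- function(object, ...) object$fitted

#' @export
predict.lox_mlr <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  nd <- as.matrix(as.data.frame(newdata)[, object$descriptor_names, drop = FALSE])
  drop(cbind(1, nd) %*% object$coefficients)
}

#' @export
print.lox_mlr <- function(x, digits = 3, ...) {
  cat("Multiple linear QSAR model (", x$p, " descriptors, n = ", x$n, ")\n", sep = "")
  b <- signif(x$coefficients, digits)
  terms <- paste0(b[-1], " * ", names(b)[-1],
                  " (beta = ", signif(x$std_coefficients, digits), ")")
  cat("  y =", b[1], "+", paste(terms, collapse = " + "), "\n")
  cat("  R2 =", signif(x$r_squared, digits),
      " R2adj =", signif(x$adj_r_squared, digits),
      " s =", signif(x$sigma, digits),
      " F =", signif(x$fstatistic, digits), "\n")
  invisible(x)
}

#' @export
summary.lox_mlr <- function(object, ...) {
  print(object)
  cat("  leverage range: [", signif(min(object$hat), 3), ", ",
      signif(max(object$hat), 3), "], sum = ", round(sum(object$hat), 6), "\n", sep = "")
  invisible(object)
}

#' Standardized regression coefficients
#'
#' beta_j = b_j * sd(x_j) / sd(y): the coefficients the model would have on
#' z-scored variables, used to rank descriptors by relative importance.
#'
#' @param model a fitted `lox_mlr`.
#' @return named numeric vector (intercept excluded).
#' @export
standardized_coefficients <- function(model) {
  stopifnot(inherits(model, "lox_mlr"))
  if (stats::sd(model$y) == 0) stop("response has zero variance")
  model$std_coefficients
}

# Frozen coefficients of the two published regression equations for
# log(% lipoxygenase inhibition): the three-descriptor model on the full
# 29-compound training set (eq1) and its refit after removal of the
# outlier compound 14 (eq2).
.published_coefficients <- list(
  eq1 = c("(Intercept)" = 0.73, "C-026" = 0.40, "RDF035p" = 0.06, "HATS8p" = -1.59),
  eq2 = c("(Intercept)" = 0.67, "C-026" = 0.42, "RDF035p" = 0.07, "HATS8p" = -1.85)
)
.published_std_coefficients <- list(
  eq1 = c("C-026" = 0.66, "RDF035p" = 0.34, "HATS8p" = -0.30),
  eq2 = c("C-026" = 0.72, "RDF035p" = 0.43, "HATS8p" = -0.36)
)

#' The published regression equations as frozen predictors
#'
#' Returns the published three-descriptor model (coefficients exactly as
#' printed) as a predict-capable object. `"eq1"` is the model fitted on all
#' 29 training compounds; `"eq2"` the final model refitted without the
#' outlier (compound 14).
#'
#' @param which `"eq2"` (default) or `"eq1"`.
#' @return an object of classes `lox_published` and `lox_mlr` supporting
#'   `coef` and `predict` (on data with columns `C-026`, `RDF035p`,
#'   `HATS8p`).
#' @export
published_model <- function(which = c("eq2", "eq1")) {
  which <- match.arg(which)
  structure(list(
    coefficients = .published_coefficients[[which]],
    std_coefficients = .published_std_coefficients[[which]],
    descriptor_names = c("C-026", "RDF035p", "HATS8p"),
    which = which,
    n = if (which == "eq2") 28L else 29L, p = 3L
  ), class = c("lox_published", "lox_mlr"))
}

#' @export
print.lox_published <- function(x, digits = 3, ...) {
  b <- x$coefficients
  cat("Published QSAR model (", x$which, "), n = ", x$n, ":\n", sep = "")
  cat("  log(% inhibition) =", b[1], "+", b[2], "* C-026 +", b[3],
      "* RDF035p", b[4], "* HATS8p\n")
  invisible(x)
}

#' Predict log(% inhibition) with a published equation
#'
#' Evaluates the frozen published coefficients on a descriptor triple.
#'
#' @param c026 R-CX-R fragment count.
#' @param rdf035p polarizability-weighted RDF at 3.5 Angstrom.
#' @param hats8p polarizability-weighted leverage autocorrelation, lag 8.
#' @param model `"eq2"` (default) or `"eq1"`.
#' @return predicted base-10 log of the percent inhibition (vectorized).
#' @examples
#' predict_published(0, 0, 0)              # the eq2 intercept, 0.67
#' @export
predict_published <- function(c026, rdf035p, hats8p, model = c("eq2", "eq1")) {
  b <- .published_coefficients[[match.arg(model)]]
  stopifnot(all(is.finite(c026)), all(is.finite(rdf035p)), all(is.finite(hats8p)))
  unname(b[1] + b[2] * c026 + b[3] * rdf035p + b[4] * hats8p)
}
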