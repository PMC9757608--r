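#' Fit a ridge-stabilised binary logistic panel model
#'
#' Fits a binomial logistic regression of case status on a marker subset by
#' iteratively reweighted least squares, maximising the ridge-penalised
#' log-likelihood (the intercept is unpenalised). Inputs are z-scored with
#' center and scale learned from the training data and frozen into the
#' model, so markers measured on arbitrary fluorescence scales are
#' comparable; prediction always re-applies the training-time
#' standardisation. The small default ridge (`1e-6`) guarantees finite
#' coefficients under complete separation; separable fits are flagged.
#'
#' @param table sample table (data frame) with a `group` column
#'   (case/benign/normal) or 0/1/logical labels via `labels`.
#' @param markers character vector of predictor column names.
#' @param ridge ridge penalty (>= 0) on the standardised coefficients.
#' @param labels optional explicit labels overriding `table$group`.
#' @param standardize z-score the predictors (default TRUE).
#' @param max_iter,tol IRLS iteration cap and convergence tolerance
#'   (max absolute coefficient update).
#' @return object of class `panel_model`: markers, `coefficients` (named,
#'   standardised scale), `intercept`, `center`/`scale`, `ridge`,
#'   `converged`, `iterations`, `separable`, and the training sample ids
#'   (for leakage checks in [validate_panel()]).
#' @examples
#' sim <- simulate_panel_data(panel_sim_config(
#'   n_case_train = 40, n_benign_train = 20, n_normal_train = 20,
#'   n_case_test = 10, n_benign_test = 10, seed = 3))
#' train <- sim$table[sim$table$split == "train", ]
#' fit <- fit_logistic(train, sim$truth$panel_true[1:2])
#' coef(fit)
#' @export
fit_logistic <- function(table, markers, ridge = 1e-6, labels = NULL,
                         standardize = TRUE, max_iter = 100, tol = 1e-8) {
  check_markers_present(table, markers)
  if (!is.numeric(ridge) || length(ridge) != 1L || ridge < 0) {
    stop("'ridge' must be a single value >= 0", call. = FALSE)
  }
  y <- as_case_labels(if (is.null(labels)) table$group else labels)
  if (length(y) != nrow(table)) {
    stop("labels length must match rows of 'table'", call. = FALSE)
  }
  if (sum(y) == 0L || sum(!y) == 0L) {
    stop("at least one sample per class is required", call. = FALSE)
  }
  X <- as.matrix(table[, markers, drop = FALSE])
  storage.mode(X) <- "double"
  if (anyNA(X)) stop("missing values in marker columns", call. = FALSE)
  if (standardize) {
    center <- colMeans(X)
    scale <- apply(X, 2, stats::sd)
    scale[scale == 0] <- 1
  } else {
    center <- setNames(rep(0, ncol(X)), markers)
    scale <- setNames(rep(1, ncol(X)), markers)
  }
  Z <- sweep(sweep(X, 2, center, "-"), 2, scale, "/")
  fit <- irls_ridge_cpp(Z, as.numeric(y), ridge, max_iter, tol)
  if (!fit$converged) {
    stop(sprintf("IRLS did not converge in %d iterations (ridge = %g); consider increasing 'ridge' or 'max_iter'",
                 fit$iterations, ridge), call. = FALSE)
  }
  beta <- drop(fit$coefficients)
  coefs <- setNames(beta[-1], markers)
  eta <- beta[1] + Z %*% beta[-1]
  scores <- plogis(drop(eta))
  separable <- min(scores[y]) > max(scores[!y])
  structure(list(
    markers = markers,
    coefficients = coefs,
    intercept = beta[1],
    center = setNames(center, markers),
    scale = setNames(scale, markers),
    ridge = ridge,
    standardize = standardize,
    converged = fit$converged,
    iterations = fit$iterations,
    separable = separable,
    n = nrow(table),
    n_case = sum(y),
    train_ids = if ("sample_id" %in% names(table)) table$sample_id else NULL,
    fitted = scores,
    y = y
  ), class = "panel_model")
}

#' Predict case probabilities from a fitted panel model
#'
#' @param object a [fit_logistic()] model.
#' @param newdata data frame containing the model's marker columns.
#' @param type `"response"` (probabilities, default) or `"link"`.
#' @param ... unused.
#' @return numeric vector, one score per row of `newdata`.
#' @export
predict.panel_model <- function(object, newdata,
                                type = c("response", "link"), ...) {
  type <- match.arg(type)
  missing <- setdiff(object$markers, names(newdata))
  if (length(missing)) {
    stop("marker column(s) missing from newdata: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  X <- as.matrix(newdata[, object$markers, drop = FALSE])
  storage.mode(X) <- "double"
  Z <- sweep(sweep(X, 2, object$center, "-"), 2, object$scale, "/")
  eta <- drop(object$intercept + Z %*% object$coefficients)
  if (type == "link") eta else plogis(eta)
}

#' @export
coef.panel_model <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' @export
print.panel_model <- function(x, ...) {
  cat(sprintf("Panel logistic model (%d markers, ridge = %g%s)\n",
              length(x$markers), x$ridge,
              if (x$separable) ", separable" else ""))
  print(round(coef(x), 4))
  invisible(x)
}

#' @export
summary.panel_model <- function(object, ...) {
  cat(sprintf("Panel logistic model: %d markers, n = %d (%d cases), ridge = %g\n",
              length(object$markers), object$n, object$n_case, object$ridge))
  cat(sprintf("IRLS converged in %d iterations%s\n", object$iterations,
              if (object$separable) " (training classes separable)" else ""))
  cat(sprintf("Training AUC: %.4f\n", roc_auc(object$fitted, object$y)))
  invisible(object)
}

#' Simulate case labels from a fitted panel model
#'
#' Draws Bernoulli outcomes from the fitted case probabilities, either on
#' the training data (default) or on `newdata`.
#'
#' @param object a `panel_model`.
#' @param nsim number of label vectors to draw.
#' @param seed integer seed.
#' @param newdata optional data frame to score.
#' @param ... unused.
#' @return matrix of 0/1 draws, `nsim` columns.
#' @export
simulate.panel_model <- function(object, nsim = 1, seed = NULL,
                                 newdata = NULL, ...) {
  p <- if (is.null(newdata)) object$fitted else predict(object, newdata)
  draw <- function() rbinom(length(p), 1L, p)
  if (is.null(seed)) {
    matrix(replicate(nsim, draw()), ncol = nsim)
  } else {
    with_seed(seed, matrix(replicate(nsim, draw()), ncol = nsim))
  }
}

#' Serialize a panel model to JSON (and back)
#'
#' The JSON records markers, coefficients, intercept, standardisation
#' parameters and ridge, so a model can be frozen and re-applied elsewhere.
#'
#' @param model a `panel_model`.
#' @param path output / input file path.
#' @return `write_panel_model()`: the path, invisibly;
#'   `read_panel_model()`: a `panel_model`.
#' @export
write_panel_model <- function(model, path) {
  stopifnot(inherits(model, "panel_model"))
  payload <- list(markers = model$markers,
                  coefficients = unname(model$coefficients),
                  intercept = model$intercept,
                  center = unname(model$center),
                  scale = unname(model$scale),
                  ridge = model$ridge,
                  standardize = model$standardize,
                  train_ids = model$train_ids)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_panel_model
#' @export
read_panel_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    markers = p$markers,
    coefficients = setNames(p$coefficients, p$markers),
    intercept = p$intercept,
    center = setNames(p$center, p$markers),
    scale = setNames(p$scale, p$markers),
    ridge = p$ridge,
    standardize = isTRUE(p$standardize),
    converged = TRUE, iterations = NA_integer_, separable = NA,
    n = NA_integer_, n_case = NA_integer_,
    train_ids = p$train_ids, fitted = NULL
  ), class = "panel_model")
}
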