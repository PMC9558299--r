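#' Linear discriminant analysis of survey outcomes
#'
#' Fits linear discriminant axes separating experiment outcome classes in
#' environment space (light, nitrogen, prey), the summary used to read the
#' survey maps: which linear combinations of the drivers separate, say,
#' sensitive-dominant from tolerant-dominant from non-surviving holobionts,
#' and how much between-class variance each axis carries.
#'
#' Class priors are the observed class proportions and the variables are not
#' standardized or transformed. Columns that are constant across the whole
#' data set carry no information and are dropped with a message; a column
#' that is constant within every class but varies between classes makes the
#' within-class scatter singular and raises an error naming it. Axis signs
#' are not identifiable and may differ between equivalent fits.
#'
#' @param features Data frame of numeric predictor columns (typically
#'   `light`, `din`, `prey`).
#' @param labels Outcome label per row (character or factor); at least two
#'   classes must be present.
#' @return An object of class `env_lda`: list with `class_labels`,
#'   `scalings` (variable loadings per axis), `proportion_of_trace`
#'   (between-class variance share per axis, summing to 1), `class_means`
#'   (class centroids in discriminant space), `variables`, and the
#'   underlying fit.
#' @export
fit_lda <- function(features, labels) {
  stopifnot(is.data.frame(features))
  labels <- factor(as.character(labels))
  if (nrow(features) != length(labels))
    stop("`features` and `labels` lengths differ", call. = FALSE)
  if (nlevels(droplevels(labels)) < 2)
    stop("at least two outcome classes are required", call. = FALSE)
  labels <- droplevels(labels)
  num <- vapply(features, is.numeric, logical(1))
  if (!all(num)) stop("all feature columns must be numeric", call. = FALSE)
  const <- vapply(features, function(x) stats::var(x) == 0, logical(1))
  if (any(const)) {
    message("dropping constant feature column(s): ",
            paste(names(features)[const], collapse = ", "))
    features <- features[!const]
  }
  if (ncol(features) == 0)
    stop("no informative feature columns remain", call. = FALSE)
  x <- as.matrix(features)
  # MASS's default tol = 1e-4 misreads genuinely varying predictors on
  # molar scales (~1e-7) as constant; the explicit constant-column screen
  # above keeps the real degeneracies caught.
  fit <- tryCatch(
    MASS::lda(x, grouping = labels, tol = 1e-12),
    error = function(e) {
      stop(sprintf(
        "within-class scatter is degenerate (%s)", conditionMessage(e)),
        call. = FALSE)
    }
  )
  ptrace <- fit$svd^2 / sum(fit$svd^2)
  names(ptrace) <- colnames(fit$scaling)
  class_means <- stats::predict(fit, fit$means)$x
  rownames(class_means) <- rownames(fit$means)
  structure(list(class_labels = levels(labels),
                 scalings = fit$scaling,
                 proportion_of_trace = ptrace,
                 class_means = class_means,
                 variables = colnames(x),
                 fit = fit),
            class = "env_lda")
}

#' Project environments onto fitted discriminant axes
#'
#' Centers the features on the fitted grand mean and applies the
#' discriminant loadings.
#'
#' @param model An `env_lda` from [fit_lda()].
#' @param features Data frame containing (at least) the fitted variables.
#' @return Matrix of discriminant coordinates (columns `LD1`, `LD2`, ...).
#' @export
project <- function(model, features) {
  stopifnot(inherits(model, "env_lda"))
  missing <- setdiff(model$variables, names(features))
  if (length(missing))
    stop("feature columns missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  stats::predict(model$fit,
                 as.matrix(features[model$variables]))$x
}

#' @export
print.env_lda <- function(x, ...) {
  cat(sprintf("<env_lda> %d classes (%s), %d axis/axes\n",
              length(x$class_labels),
              paste(x$class_labels, collapse = ", "),
              ncol(x$scalings)))
  cat("proportion of trace:",
      paste(sprintf("%s = %.1f%%", names(x$proportion_of_trace),
                    100 * x$proportion_of_trace), collapse = ", "), "\n")
  invisible(x)
}

#' Export an LDA summary as JSON
#'
#' @param model An `env_lda`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_lda_summary <- function(model, path) {
  doc <- list(
    class_labels = model$class_labels,
    variables = model$variables,
    scalings = as.data.frame(model$scalings),
    proportion_of_trace = as.list(model$proportion_of_trace),
    class_means = as.data.frame(model$class_means)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "columns")
  invisible(path)
}
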