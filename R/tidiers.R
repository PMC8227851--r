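#' Tidy an importance table
#'
#' @param x An `ec_importance`.
#' @param per_model Return the cell-level (replicate x model) importances
#'   instead of the ranked means.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy ec_importance
#' @export
tidy.ec_importance <- function(x, per_model = FALSE, ...) {
  if (per_model) attr(x, "per_model") else as_tibble(x)
}

#' @rdname tidy.ec_importance
#' @method glance ec_importance
#' @export
glance.ec_importance <- function(x, ...) {
  tibble(
    n_variables = nrow(x),
    n_reps = attr(x, "n_reps"),
    n_dropped = nrow(attr(x, "dropped") %||% tibble()),
    top_variable = x$variable[1],
    top_mean_importance = x$mean_importance[1]
  )
}

#' Tidy a fitted system model
#'
#' @param x An `ec_fit`.
#' @param ... Unused.
#' @return Coefficients as a tibble (`term`, `estimate`; multinomial fits
#'   add a `category` column).
#' @method tidy ec_fit
#' @export
tidy.ec_fit <- function(x, ...) {
  if (is.matrix(x$coefficients)) {
    as_tibble(x$coefficients, rownames = "term") |>
      tidyr::pivot_longer(-"term", names_to = "category", values_to = "estimate")
  } else {
    tibble(term = names(x$coefficients), estimate = unname(x$coefficients))
  }
}

#' @rdname tidy.ec_fit
#' @method glance ec_fit
#' @export
glance.ec_fit <- function(x, ...) {
  tibble(
    system = x$system, panel = x$panel_name,
    n_variables = length(x$variables), ridge = x$ridge
  )
}

#' Tidy a LOOCV result
#'
#' @param x An `ec_loocv`.
#' @param ... Unused.
#' @return `tidy()`: the per-sample prediction tibble; `glance()`: a one-row
#'   summary with the out-of-sample error.
#' @method tidy ec_loocv
#' @export
tidy.ec_loocv <- function(x, ...) x$predictions

#' @rdname tidy.ec_loocv
#' @method glance ec_loocv
#' @export
glance.ec_loocv <- function(x, ...) {
  tibble(
    system = x$system, panel = x$panel_name, n = x$n,
    error = as.numeric(x$error),
    n_clipped = attr(x$error, "n_clipped") %||% 0L
  )
}

#' Tidy an outcome report
#'
#' @param x An `ec_report`.
#' @param ... Unused.
#' @return `tidy()`: per-class sensitivity/specificity; `glance()`: one row
#'   with correct/incorrect/inconclusive percentages.
#' @method tidy ec_report
#' @export
tidy.ec_report <- function(x, ...) x$per_class

#' @rdname tidy.ec_report
#' @method glance ec_report
#' @export
glance.ec_report <- function(x, ...) {
  pct <- setNames(x$outcome$percent, x$outcome$outcome)
  tibble(
    system = x$system, panel = x$panel_name,
    threshold = if (identical(x$policy$threshold, "pmax")) "pmax" else as.character(x$policy$threshold),
    n = x$n,
    pct_correct = pct[["correct"]],
    pct_incorrect = pct[["incorrect"]],
    pct_inconclusive = pct[["inconclusive"]]
  )
}
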