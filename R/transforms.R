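#' PIE-score from pixel counts
#'
#' The pixel index of the eye (PIE) score summarises an iris photograph as
#' `(blue - brown) / (blue + brown)` over its classified pixels: 1 means only
#' blue pixels, -1 only brown pixels.
#'
#' @param blue_pixels,brown_pixels Non-negative pixel counts (vectorised).
#' @return PIE-scores in `[-1, 1]`.
#' @examples
#' pie_from_pixel_counts(272214, 0)   # fully blue iris -> 1
#' pie_from_pixel_counts(25, 75)      # -0.5
#' @export
pie_from_pixel_counts <- function(blue_pixels, brown_pixels) {
  if (any(blue_pixels < 0) || any(brown_pixels < 0)) {
    abort("pixel counts must be non-negative")
  }
  total <- blue_pixels + brown_pixels
  if (any(total == 0)) {
    abort("PIE-score undefined when both pixel counts are zero")
  }
  (blue_pixels - brown_pixels) / total
}

#' Transform PIE-scores to the unbounded modelling scale and back
#'
#' Quantitative modelling is done on `y = logit(0.5 + 0.499 * r)`, which maps
#' the bounded PIE-score `r` in `[-1, 1]` to `[logit(0.001), logit(0.999)]`,
#' i.e. roughly `[-6.91, 6.91]`.  The 0.499 factor keeps the logit argument
#' away from 0 and 1 so the transform is finite at `r = +/-1`.
#' `inverse_transform()` maps any real number back into `(-1, 1)` (and the
#' endpoints of the transformed range back to exactly `+/-1`).
#'
#' @param r PIE-scores in `[-1, 1]` (vectorised).
#' @param y Transformed scores (any real, vectorised).
#' @return `transform_pie()`: transformed scores; `inverse_transform()`:
#'   PIE-scores.
#' @examples
#' transform_pie(0)                  # 0
#' transform_pie(1)                  # log(999)
#' inverse_transform(transform_pie(0.37))
#' @export
transform_pie <- function(r) {
  if (any(is.na(r)) || any(r < -1) || any(r > 1)) {
    abort("PIE-scores must lie in [-1, 1]")
  }
  qlogis(0.5 + r * 0.499)
}

#' @rdname transform_pie
#' @export
inverse_transform <- function(y) {
  # beyond the transformed endpoints +/- logit(0.999) the raw inverse would
  # leave [-1, 1] (by at most 1/499); saturate so every real maps to a valid
  # PIE-score while the round-trip on [-1, 1] stays exact
  pmin(pmax((plogis(y) - 0.5) / 0.499, -1), 1)
}

#' Eye-colour category systems
#'
#' Two reporting systems partition the PIE-score range: the two-category
#' system calls `r > 0.2` blue and `r <= 0.2` brown; the three-category system
#' calls `r > 0.8` blue, `-0.5 <= r <= 0.8` intermediate and `r < -0.5` brown.
#' Boundaries are closed exactly as stated; no tolerance is applied.
#'
#' @param name `"two_category"` or `"three_category"`.
#' @return A `CategorySystem` list with `name`, ordered `labels` and
#'   `thresholds`.
#' @examples
#' category_system("two_category")$labels
#' @export
category_system <- function(name = c("two_category", "three_category")) {
  name <- match.arg(name)
  sys <- switch(name,
    two_category = list(
      name = "two_category",
      labels = c("blue", "brown"),
      thresholds = c(blue_over = 0.2)
    ),
    three_category = list(
      name = "three_category",
      labels = c("blue", "intermediate", "brown"),
      thresholds = c(blue_over = 0.8, brown_under = -0.5)
    )
  )
  structure(sys, class = "ec_category_system")
}

#' Categorise PIE-scores
#'
#' @param r PIE-scores in `[-1, 1]` (vectorised).
#' @param system A [category_system()] or its name.
#' @return A factor of category labels with the system's level order.
#' @examples
#' categorise_pie(c(0.2, 0.21), "two_category")   # brown, blue
#' categorise_pie(-0.5, "three_category")         # intermediate
#' @export
categorise_pie <- function(r, system = "two_category") {
  if (is.character(system)) system <- category_system(system)
  if (any(is.na(r)) || any(r < -1) || any(r > 1)) {
    abort("PIE-scores must lie in [-1, 1]")
  }
  lab <- if (system$name == "two_category") {
    ifelse(r > system$thresholds[["blue_over"]], "blue", "brown")
  } else {
    ifelse(r > system$thresholds[["blue_over"]], "blue",
      ifelse(r < system$thresholds[["brown_under"]], "brown", "intermediate")
    )
  }
  factor(lab, levels = system$labels)
}
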