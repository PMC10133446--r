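#' jnd-scaled feature ladder
#'
#' A ladder turns a base feature value and a relative just-noticeable
#' difference (jnd) into the set of singleton feature values used by a
#' design. Brightness ladders act on the spectral centroid (relative
#' jnd 5%); roughness ladders act on the amplitude-modulation depth
#' (jnd 10% of the full depth scale, stepped additively from 0).
#'
#' @param feature `"brightness_sc"` (values in Hz) or
#'   `"roughness_depth"` (modulation depth in `[0, 1]`).
#' @param base Base feature value: the distractor's centroid in Hz, or
#'   the distractor's depth (normally 0).
#' @param jnd_fraction Relative jnd (0.05 for the centroid, 0.10 for
#'   modulation depth).
#' @param multipliers jnd multipliers, possibly negative for downward
#'   steps.
#' @param mode `"additive"`: `base * (1 + jnd_fraction * k)`;
#'   `"compound"`: `base * (1 + jnd_fraction)^k`. Depth ladders are
#'   always additive on the depth scale: `base + jnd_fraction * k`.
#' @return An object of class `feature_ladder`.
#' @export
#' @examples
#' build_ladder(feature_ladder("brightness_sc", 512, 0.05, c(1, 2, 5, 10)),
#'              rounded = TRUE)
feature_ladder <- function(feature = c("brightness_sc", "roughness_depth"),
                           base, jnd_fraction, multipliers,
                           mode = c("additive", "compound")) {
  feature <- match.arg(feature)
  mode <- match.arg(mode)
  stopifnot(length(multipliers) >= 1, is.numeric(base), base >= 0,
            jnd_fraction > 0)
  structure(
    list(feature = feature, base = base, jnd_fraction = jnd_fraction,
         multipliers = multipliers, mode = mode),
    class = "feature_ladder"
  )
}

#' Build the feature values of a ladder
#'
#' @param ladder A [feature_ladder()].
#' @param rounded Round to report precision: nearest Hz for centroids,
#'   nearest 0.1 for modulation depths. Default FALSE (exact values).
#' @return Numeric vector, one value per multiplier.
#' @export
build_ladder <- function(ladder, rounded = FALSE) {
  stopifnot(inherits(ladder, "feature_ladder"))
  k <- ladder$multipliers
  j <- ladder$jnd_fraction
  values <- if (ladder$feature == "roughness_depth") {
    ladder$base + j * k
  } else if (ladder$mode == "additive") {
    ladder$base * (1 + j * k)
  } else {
    ladder$base * (1 + j)^k
  }
  if (ladder$feature == "roughness_depth") {
    if (any(values < 0 | values > 1)) {
      stop("ladder produces modulation depths outside [0, 1]: ",
           paste(signif(values, 3), collapse = ", "))
    }
    if (rounded) values <- round(values, 1)
  } else {
    if (any(values <= 0)) {
      stop("ladder produces non-positive spectral centroids")
    }
    if (rounded) values <- round(values)
  }
  values
}
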