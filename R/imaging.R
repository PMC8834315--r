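# Filipin LSO compartment-ratio statistic and Pearson colocalization.

validate_intensity_image <- function(pixels, name = "pixels") {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    abort_validation(sprintf("'%s' must be a numeric matrix", name))
  if (any(!is.finite(pixels)) || any(pixels < 0))
    abort_validation(sprintf("'%s' must be finite and non-negative", name))
  invisible(pixels)
}

validate_mask <- function(mask, pixels) {
  if (is.null(mask)) return(invisible(NULL))
  if (!is.matrix(mask) || !is.logical(mask) ||
      !identical(dim(mask), dim(pixels)))
    abort_validation("'mask' must be a logical matrix with the image's shape")
  if (!any(mask))
    abort_validation("'mask' selects no pixels")
  invisible(mask)
}

#' LSO compartment ratio of a filipin image
#'
#' The lysosome-like storage organelle (LSO) compartment ratio relates
#' perinuclear cholesterol accumulation to total cell area: the summed
#' fluorescence intensity of all pixels strictly above the high
#' threshold, divided by the number of pixels strictly above the low
#' threshold (the low threshold delineates the total cell area, the
#' high one the bright filipin-stained LSO regions).  The numerator uses
#' the full intensity of supra-threshold pixels, not the excess over the
#' threshold.
#'
#' @param pixels numeric matrix of non-negative intensities.
#' @param t_low,t_high thresholds in intensity units,
#'   \code{0 <= t_low <= t_high}.
#' @param mask optional logical matrix restricting the computation.
#' @param field_id optional identifier carried into the result.
#' @return a one-row \code{data.frame} (class \code{lso_measurement})
#'   with \code{field_id}, \code{ratio}, \code{sum_high}, \code{n_low},
#'   \code{t_low}, \code{t_high}.
#' @export
lso_compartment_ratio <- function(pixels, t_low, t_high, mask = NULL,
                                  field_id = NA_character_) {
  validate_intensity_image(pixels)
  stopifnot_scalar_number(t_low, "t_low")
  stopifnot_scalar_number(t_high, "t_high")
  if (t_low < 0 || t_low > t_high)
    abort_validation("thresholds must satisfy 0 <= t_low <= t_high")
  validate_mask(mask, pixels)
  px <- if (is.null(mask)) as.vector(pixels) else pixels[mask]
  n_low <- sum(px > t_low)
  if (n_low == 0L)
    abort(sprintf("degenerate field%s: no pixel above the low threshold",
                  if (is.na(field_id)) "" else paste0(" '", field_id, "'")),
          "npcquant_degenerate_error")
  sum_high <- sum(px[px > t_high])
  out <- data.frame(field_id = field_id, ratio = sum_high / n_low,
                    sum_high = sum_high, n_low = n_low,
                    t_low = t_low, t_high = t_high,
                    stringsAsFactors = FALSE)
  class(out) <- c("lso_measurement", "data.frame")
  out
}

#' Aggregate per-field LSO measurements into an experiment replicate
#'
#' Fields within one experiment (the study design uses 10 randomly
#' chosen fields per experiment) are averaged arithmetically; the
#' per-experiment mean is the replicate value passed on to group
#' statistics.
#'
#' @param measurements a \code{data.frame} of \code{lso_measurement}
#'   rows (e.g. \code{rbind} of \code{\link{lso_compartment_ratio}}
#'   results), or a list of them, or a bare numeric vector of ratios.
#' @return list with \code{mean}, \code{sd} (NA for a single field) and
#'   \code{n_fields}.
#' @export
aggregate_fields <- function(measurements) {
  ratios <- if (is.numeric(measurements)) {
    measurements
  } else if (is.data.frame(measurements)) {
    measurements$ratio
  } else if (is.list(measurements)) {
    vapply(measurements, function(m) m$ratio, numeric(1))
  } else NULL
  if (is.null(ratios) || length(ratios) == 0L || anyNA(ratios))
    abort_validation("need at least one LSO measurement with a ratio")
  list(mean = mean(ratios), sd = stats::sd(ratios),
       n_fields = length(ratios))
}

#' Pearson pixel-intensity colocalization
#'
#' Pearson's correlation coefficient over paired pixel intensities of
#' two channels (e.g. NPC1 and the lysosomal marker LAMP2), the plain
#' whole-image statistic with no intensity thresholding:
#' \deqn{r = \frac{\sum_i (a_i-\bar a)(b_i-\bar b)}
#'                {\sqrt{\sum_i (a_i-\bar a)^2 \sum_i (b_i-\bar b)^2}}.}
#' When a mask is supplied only in-mask pixels enter the sums.
#'
#' @param ch1,ch2 numeric matrices of identical shape.
#' @param mask optional logical matrix restricting the computation.
#' @return a one-row \code{data.frame} (class \code{coloc_measurement})
#'   with \code{r} and \code{n_pixels}.
#' @export
pearson_colocalization <- function(ch1, ch2, mask = NULL) {
  validate_intensity_image(ch1, "ch1")
  validate_intensity_image(ch2, "ch2")
  if (!identical(dim(ch1), dim(ch2)))
    abort_validation("'ch1' and 'ch2' must have identical shapes")
  validate_mask(mask, ch1)
  a <- if (is.null(mask)) as.vector(ch1) else ch1[mask]
  b <- if (is.null(mask)) as.vector(ch2) else ch2[mask]
  if (length(a) < 2L)
    abort_validation("need at least 2 pixels in scope")
  if (stats::var(a) == 0 || stats::var(b) == 0)
    abort("undefined correlation: a channel is constant in scope",
          "npcquant_degenerate_error")
  out <- data.frame(r = stats::cor(a, b), n_pixels = length(a))
  class(out) <- c("coloc_measurement", "data.frame")
  out
}

#' Percentile-based threshold suggestion (artifact default)
#'
#' The study never reports its two LSO thresholds; they are explicit
#' per-run configuration.  For synthetic work this helper proposes
#' \code{t_low} and \code{t_high} as intensity percentiles of a control
#' image (defaults: 50th and 99th).  These are artifact defaults, not
#' values from any publication.
#'
#' @param pixels control-image intensity matrix.
#' @param p_low,p_high percentiles in [0, 1], \code{p_low <= p_high}.
#' @return list with \code{t_low} and \code{t_high}.
#' @export
suggest_thresholds <- function(pixels, p_low = 0.5, p_high = 0.99) {
  validate_intensity_image(pixels)
  if (p_low < 0 || p_high > 1 || p_low > p_high)
    abort_validation("need 0 <= p_low <= p_high <= 1")
  q <- stats::quantile(as.vector(pixels), c(p_low, p_high), names = FALSE)
  list(t_low = q[1], t_high = q[2])
}
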