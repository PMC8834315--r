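# Western-blot densitometry: beta-actin normalization, fold changes vs
# the DMSO vehicle control, and Endo H glycoform fractions.
#
# Inputs are assumed background-corrected upstream; no further
# background subtraction is applied.  Truncated alleles (e.g.
# P543Rfs*20) produce no band with a C-terminal antibody and are
# invisible to this quantification: only the full-length signal is
# modelled.

#' Actin-normalized NPC1 level
#'
#' Divides the total-NPC1 band signal (~180 kDa) by the beta-actin
#' loading-control signal (43 kDa) of the same lane.  The result is
#' dimensionless and independent of the densitometer's arbitrary units.
#'
#' @param npc1_signal non-negative band signal(s).
#' @param actin_signal strictly positive band signal(s).
#' @return numeric vector of normalized levels.
#' @export
relative_npc1_level <- function(npc1_signal, actin_signal) {
  if (!is.numeric(npc1_signal) || anyNA(npc1_signal) || any(npc1_signal < 0))
    abort_validation("'npc1_signal' must be numeric and >= 0")
  if (!is.numeric(actin_signal) || anyNA(actin_signal))
    abort_validation("'actin_signal' must be numeric")
  if (any(actin_signal <= 0))
    abort_domain("'actin_signal' must be > 0")
  npc1_signal / actin_signal
}

#' Fold change of a treated level over its control
#'
#' @param treated_level normalized level(s) under treatment.
#' @param control_level strictly positive normalized control level
#'   (e.g. the matching DMSO lane or condition mean).
#' @return numeric fold change(s), \code{treated / control}.
#' @export
fold_change_vs_control <- function(treated_level, control_level) {
  if (!is.numeric(treated_level) || anyNA(treated_level))
    abort_validation("'treated_level' must be numeric")
  if (!is.numeric(control_level) || anyNA(control_level))
    abort_validation("'control_level' must be numeric")
  if (any(control_level <= 0))
    abort_domain("'control_level' must be > 0")
  treated_level / control_level
}

#' Endo H glycoform fractions
#'
#' Expresses the Endo H-resistant (~170 kDa, post-medial-Golgi) and
#' Endo H-sensitive (~130 kDa, ER-retained) NPC1 band signals as
#' fractions of total NPC1 (\code{R + S}).  The two fractions sum to 1
#' exactly and are invariant to the densitometer's units.
#'
#' @param endoH_R,endoH_S non-negative band signals; their sum must be
#'   positive (per lane).
#' @return \code{data.frame} with columns \code{f_R} and \code{f_S}.
#' @export
glycoform_fractions <- function(endoH_R, endoH_S) {
  if (!is.numeric(endoH_R) || !is.numeric(endoH_S) ||
      anyNA(endoH_R) || anyNA(endoH_S))
    abort_validation("glycoform signals must be numeric without NA")
  if (length(endoH_R) != length(endoH_S))
    abort_validation("'endoH_R' and 'endoH_S' must have equal length")
  if (any(endoH_R < 0) || any(endoH_S < 0))
    abort_domain("glycoform signals must be >= 0")
  total <- endoH_R + endoH_S
  if (any(total <= 0))
    abort_domain("endoH_R + endoH_S must be > 0 in every lane")
  data.frame(f_R = endoH_R / total, f_S = endoH_S / total)
}

#' Summarize a densitometry table into levels and fold changes
#'
#' Computes per-lane actin-normalized levels, averages them per
#' condition, and reports each condition's fold change over the control
#' condition's mean level.  Per-experiment fold changes are aggregated
#' arithmetically (mean and SD).
#'
#' @param lanes \code{data.frame} with columns \code{lane_id},
#'   \code{condition}, \code{npc1_signal}, \code{actin_signal}.
#' @param control control condition label (default \code{"DMSO"}).
#' @return list with \code{lanes} (input plus a \code{level} column) and
#'   \code{conditions} (per-condition \code{mean_level}, \code{sd_level},
#'   \code{n}, \code{fold_change}).
#' @export
summarize_blot <- function(lanes, control = "DMSO") {
  need <- c("lane_id", "condition", "npc1_signal", "actin_signal")
  miss <- setdiff(need, names(lanes))
  if (length(miss))
    abort_validation(paste0("densitometry table lacks column(s): ",
                            paste(miss, collapse = ", ")))
  if (!control %in% lanes$condition)
    abort_validation(sprintf("control condition '%s' absent from table",
                             control))
  lanes$level <- relative_npc1_level(lanes$npc1_signal, lanes$actin_signal)
  agg <- do.call(rbind, lapply(split(lanes, lanes$condition), function(d) {
    data.frame(condition = d$condition[1], mean_level = mean(d$level),
               sd_level = stats::sd(d$level), n = nrow(d))
  }))
  rownames(agg) <- NULL
  ctrl_level <- agg$mean_level[agg$condition == control]
  agg$fold_change <- fold_change_vs_control(agg$mean_level, ctrl_level)
  list(lanes = lanes, conditions = agg, control = control)
}
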