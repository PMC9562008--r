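#' Classify dephosphorylation patterns of matched spots
#'
#' After chemical dephosphorylation a protein spot can respond in one of
#' four ways on the gel, plus the null case:
#' \describe{
#'   \item{reduced}{less volume at the same gel position.}
#'   \item{shifted_basic}{displaced toward basic pI (loss of negative
#'     phosphate charge), usually with reduced volume.}
#'   \item{disappeared}{no longer detected after treatment.}
#'   \item{novel}{appears only in the dephosphorylated profile.}
#'   \item{unchanged}{no volume drop beyond threshold and no basic shift.}
#' }
#'
#' Decision order: novel (no reference presence) > disappeared (no
#' dephospho presence) > shifted_basic (consensus dephospho pI minus
#' reference pI >= \code{pi_shift_min}; acidic shifts never fire this
#' class) > reduced (mean D < (1 - vol_drop_min) x mean T) > unchanged.
#' Presence on a profile reuses the study's replicate detection rule, so
#' one consistent rule governs matching, rates and patterns. Mr
#' displacement is recorded (\code{delta_logmr}, when a marker ladder is
#' supplied) but never drives the class.
#'
#' @param matched a \code{matched_spots} object.
#' @param vol_drop_min minimum fractional volume drop for "reduced"
#'   (default 0.10).
#' @param pi_shift_min minimum basic pI shift in pH units for
#'   "shifted_basic" (default 0.05).
#' @param gradient [ph_gradient()] used to convert x displacement to pH
#'   units.
#' @param ladder optional [marker_ladder()]; when given, Mr displacement is
#'   reported as \code{delta_logmr}.
#' @return data frame with one row per spot: \code{spot_id},
#'   \code{pattern}, \code{delta_volume_frac} (signed (D-T)/T),
#'   \code{delta_pi} (pH units, positive = toward basic),
#'   \code{delta_logmr} (log10 kDa), populated where computable.
#' @export
classify_patterns <- function(matched, vol_drop_min = 0.10,
                              pi_shift_min = 0.05,
                              gradient = ph_gradient(), ladder = NULL) {
  stopifnot(inherits(matched, "matched_spots"))
  if (vol_drop_min <= 0 || pi_shift_min <= 0)
    stop("thresholds must be positive")
  ids <- spot_ids(matched)
  out <- data.frame(spot_id = ids, pattern = NA_character_,
                    delta_volume_frac = NA_real_, delta_pi = NA_real_,
                    delta_logmr = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    call <- classify_spot(matched, ids[i], vol_drop_min, pi_shift_min,
                          gradient, ladder)
    out[i, names(call)] <- call
  }
  out
}

#' Classify a single matched spot
#'
#' @rdname classify_patterns
#' @param spot_id master spot id to classify.
#' @export
classify_spot <- function(matched, spot_id, vol_drop_min = 0.10,
                          pi_shift_min = 0.05, gradient = ph_gradient(),
                          ladder = NULL) {
  v <- matched$volumes[matched$volumes$spot_id == spot_id, , drop = FALSE]
  if (!nrow(v)) stop("unknown spot id: ", spot_id)
  co <- matched$coords[matched$coords$spot_id == spot_id, , drop = FALSE]
  design <- matched$design
  ref_present <- apply_detection_rule(!is.na(v$T), design)
  dep_present <- apply_detection_rule(!is.na(v$D), design)
  if (!any(!is.na(v$T)) && !any(!is.na(v$D)))
    stop("spot ", spot_id, " absent from both reference and dephospho profiles")

  mean_T <- if (any(!is.na(v$T))) mean(v$T, na.rm = TRUE) else NA_real_
  mean_D <- if (any(!is.na(v$D))) mean(v$D, na.rm = TRUE) else NA_real_
  dvol <- if (!is.na(mean_T) && mean_T > 0 && !is.na(mean_D))
    (mean_D - mean_T) / mean_T else NA_real_
  dpi <- if (!is.na(co$x_reference) && !is.na(co$x_dephospho))
    pi_from_x(co$x_dephospho, gradient) - pi_from_x(co$x_reference, gradient)
  else NA_real_
  dlogmr <- if (!is.null(ladder) && !is.na(co$y_reference) &&
                !is.na(co$y_dephospho))
    log10(mr_from_y(co$y_dephospho, ladder)) -
      log10(mr_from_y(co$y_reference, ladder))
  else NA_real_

  pattern <-
    if (!ref_present) "novel"
    else if (!dep_present) "disappeared"
    else if (!is.na(dpi) && dpi >= pi_shift_min) "shifted_basic"
    else if (!is.na(dvol) && mean_D < (1 - vol_drop_min) * mean_T) "reduced"
    else "unchanged"

  data.frame(spot_id = spot_id, pattern = pattern,
             delta_volume_frac = dvol, delta_pi = dpi, delta_logmr = dlogmr,
             stringsAsFactors = FALSE)
}

#' Write the pattern table
#' @param patterns data frame from [classify_patterns()].
#' @param path output path.
#' @export
write_pattern_table <- function(patterns, path) {
  utils::write.table(patterns, path, sep = ",", row.names = FALSE,
                     col.names = TRUE, qmethod = "double", quote = TRUE,
                     na = "")
  invisible(path)
}
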