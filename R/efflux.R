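#' Fractional Rb+ efflux of a well
#'
#' Rubidium measured in the efflux solution divided by total rubidium
#' (efflux solution + cell lysate).  This is the intact-cell channel
#' activity readout: open channels let the surrogate permeant ion out, so
#' a channel blocker lowers the fraction.
#'
#' @param efflux_signal,lysate_signal nonnegative instrument readings
#'   (e.g. atomic-absorption Rb+ concentrations), vectorized.
#' @return fractions in \[0, 1\].
#' @export
fractional_efflux <- function(efflux_signal, lysate_signal) {
  if (any(efflux_signal < 0) || any(lysate_signal < 0))
    stop("signals must be nonnegative")
  tot <- efflux_signal + lysate_signal
  bad <- which(tot == 0)
  if (length(bad))
    stop("efflux and lysate signals both zero in well(s): ",
         paste(bad, collapse = ", "))
  efflux_signal / tot
}

#' Preprocess an efflux plate into normalized fractional efflux
#'
#' Per biological replicate: technical duplicates are averaged, the mean
#' untransfected (background) fraction is subtracted, and values are
#' divided by the mean background-subtracted fraction of the reference
#' condition (typically the construct of interest under metabolic
#' inhibition with vehicle only).  Negative background-subtracted values
#' are clipped to 0 and flagged, never silently.
#'
#' @param wells data.frame with columns `condition`, `dose_uM`,
#'   `technical_rep`, `biological_rep`, `efflux_signal`, `lysate_signal`,
#'   `is_untransfected` (the plate schema written by [gen_plate()]).
#' @param reference_condition condition label used for normalization.
#' @param reference_dose dose (µM) of the reference wells; default 0
#'   (vehicle).
#' @return data.frame of class `fractional_efflux_table` with columns
#'   `condition`, `dose_uM`, `biological_rep`, `fraction`, `clipped`;
#'   attribute `provenance` lists the transforms applied.  Applying this
#'   function to its own output is refused (preprocessing is not
#'   idempotent and double-normalization would be silent corruption).
#' @export
preprocess_efflux <- function(wells, reference_condition,
                              reference_dose = 0) {
  if (inherits(wells, "fractional_efflux_table"))
    stop("input is already a preprocessed fractional efflux table; ",
         "refusing to preprocess twice")
  need <- c("condition", "dose_uM", "technical_rep", "biological_rep",
            "efflux_signal", "lysate_signal", "is_untransfected")
  miss <- setdiff(need, names(wells))
  if (length(miss))
    stop("plate table lacks column(s): ", paste(miss, collapse = ", "))
  if (!any(wells$is_untransfected))
    stop("no untransfected (background) wells present")
  is_ref <- !wells$is_untransfected &
    wells$condition == reference_condition &
    wells$dose_uM == reference_dose
  if (!any(is_ref))
    stop("no reference wells for condition '", reference_condition,
         "' at dose ", reference_dose, " uM")

  wells$fraction <- fractional_efflux(wells$efflux_signal,
                                      wells$lysate_signal)
  # average technical duplicates within (condition, dose, biological rep)
  agg <- aggregate(fraction ~ condition + dose_uM + biological_rep +
                     is_untransfected, data = wells, FUN = mean)

  out <- NULL
  for (br in unique(agg$biological_rep)) {
    a <- agg[agg$biological_rep == br, , drop = FALSE]
    bg_rows <- a$is_untransfected
    if (!any(bg_rows))
      stop("biological replicate '", br, "' has no untransfected wells")
    bg <- mean(a$fraction[bg_rows])
    a$fraction <- a$fraction - bg
    clipped <- a$fraction < 0
    a$fraction[clipped] <- 0
    ref_rows <- !a$is_untransfected &
      a$condition == reference_condition & a$dose_uM == reference_dose
    if (!any(ref_rows))
      stop("biological replicate '", br, "' has no reference wells for '",
           reference_condition, "'")
    ref <- mean(a$fraction[ref_rows])
    if (ref <= 0)
      stop("reference fraction is not positive in biological replicate '",
           br, "'")
    a$fraction <- a$fraction / ref
    a$clipped <- clipped
    out <- rbind(out, a[!a$is_untransfected,
                        c("condition", "dose_uM", "biological_rep",
                          "fraction", "clipped")])
  }
  out <- out[order(out$condition, out$dose_uM, out$biological_rep), ]
  rownames(out) <- NULL
  attr(out, "provenance") <- c("technical_duplicates_averaged",
                               "background_subtracted",
                               "normalized_to_reference")
  attr(out, "reference_condition") <- reference_condition
  class(out) <- c("fractional_efflux_table", class(out))
  out
}
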