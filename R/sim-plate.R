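#' Specification of a synthetic Rb+ efflux plate
#'
#' Defaults emulate a wild-type channel inhibition experiment: vehicle
#' plus eight log-spaced doses spanning 1--200 µM, technical duplicates,
#' three biological replicates (independent transfections), 5%
#' multiplicative noise on raw signals, fractional efflux of 0.70 for
#' fully open channels over a 0.10 untransfected background, and a planted
#' inhibition curve with IC50 9.23 µM and unit Hill slope.
#'
#' @param top,bottom,ic50,slope planted Hill-curve truth (fractions, µM).
#' @param doses dose vector (µM; 0 = vehicle).
#' @param n_technical technical replicates per dose.
#' @param n_biological biological replicates (independent transfections).
#' @param noise_cv coefficient of variation of the multiplicative
#'   log-normal noise applied to raw signals.
#' @param background_fraction fractional efflux of untransfected cells;
#'   `background_fraction + top` must not exceed 1.
#' @param total_rb total Rb+ per well in instrument units.
#' @param seed RNG seed (recorded in the truth record).
#' @return list of class `plate_spec`.
#' @export
plate_spec <- function(top = 0.70, bottom = 0, ic50 = 9.23, slope = 1,
                       doses = c(0, round(exp(seq(log(1), log(200),
                                                 length.out = 8)), 2)),
                       n_technical = 2L, n_biological = 3L,
                       noise_cv = 0.05, background_fraction = 0.10,
                       total_rb = 1000, seed = 1L) {
  stopifnot(ic50 > 0, slope > 0, all(doses >= 0),
            bottom >= 0, bottom <= top,
            background_fraction >= 0, background_fraction < top,
            n_technical >= 1, n_biological >= 1, noise_cv >= 0,
            total_rb > 0)
  if (background_fraction + top > 1)
    stop("background_fraction + top must not exceed 1 ",
         "(fractional efflux cannot exceed 1)")
  structure(list(top = top, bottom = bottom, ic50 = ic50, slope = slope,
                 doses = doses, n_technical = as.integer(n_technical),
                 n_biological = as.integer(n_biological),
                 noise_cv = noise_cv,
                 background_fraction = background_fraction,
                 total_rb = total_rb, seed = as.integer(seed)),
            class = "plate_spec")
}

#' Generate a synthetic efflux plate with known truth
#'
#' Each well's noiseless fractional efflux is
#' `background_fraction + hill_curve(dose)`; untransfected control wells
#' carry background only.  Raw efflux and lysate signals are drawn by
#' splitting a fixed total Rb+ by the fraction and applying independent
#' mean-one multiplicative log-normal noise to each signal -- raw
#' instrument readings are positive, and the derived fractions then
#' inherit realistic heteroscedasticity.
#'
#' @param spec a [plate_spec()].
#' @return list: `wells` (the plate data.frame consumed by
#'   [preprocess_efflux()], condition `"WT"` plus untransfected wells) and
#'   `truth` (planted parameters, noiseless fraction per dose, seed).
#' @export
gen_plate <- function(spec) {
  stopifnot(inherits(spec, "plate_spec"))
  withr::with_seed(spec$seed, {
    grid <- expand.grid(dose_uM = spec$doses,
                        technical_rep = seq_len(spec$n_technical),
                        biological_rep = seq_len(spec$n_biological),
                        KEEP.OUT.ATTRS = FALSE)
    grid$condition <- "WT"
    grid$is_untransfected <- FALSE
    ut <- expand.grid(dose_uM = 0,
                      technical_rep = seq_len(spec$n_technical),
                      biological_rep = seq_len(spec$n_biological),
                      KEEP.OUT.ATTRS = FALSE)
    ut$condition <- "untransfected"
    ut$is_untransfected <- TRUE
    wells <- rbind(grid, ut)

    f_true <- ifelse(wells$is_untransfected,
                     spec$background_fraction,
                     spec$background_fraction +
                       hill_curve(wells$dose_uM, spec$top, spec$bottom,
                                  spec$ic50, spec$slope))
    noise <- function(n) {
      if (spec$noise_cv == 0) return(rep(1, n))
      sig2 <- log(1 + spec$noise_cv^2)
      exp(stats::rnorm(n, -sig2 / 2, sqrt(sig2)))   # mean-one log-normal
    }
    n <- nrow(wells)
    wells$efflux_signal <- f_true * spec$total_rb * noise(n)
    wells$lysate_signal <- (1 - f_true) * spec$total_rb * noise(n)
    wells <- wells[c("condition", "dose_uM", "technical_rep",
                     "biological_rep", "efflux_signal", "lysate_signal",
                     "is_untransfected")]
    truth <- list(spec = spec,
                  noiseless_fraction = data.frame(
                    dose_uM = spec$doses,
                    fraction = spec$background_fraction +
                      hill_curve(spec$doses, spec$top, spec$bottom,
                                 spec$ic50, spec$slope)),
                  seed = spec$seed)
    list(wells = wells, truth = truth)
  })
}
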