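# Mechanoregulation: scalar stimulus and tissue classification.

#' Stimulus normalizers
#'
#' Empirical normalizers of the mechanoregulation stimulus
#' `S = gamma / a + nu / b`: `a` scales the octahedral shear strain
#' (dimensionless) and `b` the interstitial fluid speed (mm/s).
#'
#' @param a Strain normalizer, default 0.0375.
#' @param b Fluid-speed normalizer in mm/s, default 0.03.
#' @return An object of class `stimulus_params`.
#' @export
stimulus_params <- function(a = 0.0375, b = 0.03) {
  stopifnot(a > 0, b > 0)
  structure(list(a = a, b = b), class = "stimulus_params")
}

#' Tissue-phenotype stimulus thresholds
#'
#' Upper bounds of the stimulus bins favoring, in order: bone resorption,
#' mature bone, immature bone and cartilage; stimuli above `cartilage_upper`
#' favor fibrous tissue. Bins are half-open, closed on the left, so every
#' stimulus value maps to exactly one tissue.
#'
#' @param resorption_upper,mature_upper,immature_upper,cartilage_upper Bin
#'   upper bounds on the S scale.
#' @return An object of class `tissue_thresholds`.
#' @export
tissue_thresholds <- function(resorption_upper = 0.01, mature_upper = 0.53,
                              immature_upper = 1, cartilage_upper = 3) {
  stopifnot(0 < resorption_upper, resorption_upper < mature_upper,
            mature_upper < immature_upper, immature_upper < cartilage_upper)
  structure(list(resorption_upper = resorption_upper,
                 mature_upper = mature_upper,
                 immature_upper = immature_upper,
                 cartilage_upper = cartilage_upper),
            class = "tissue_thresholds")
}

#' Mechanoregulation stimulus
#'
#' `S = gamma / a + nu / b`, combining octahedral shear strain and
#' interstitial fluid speed.
#'
#' @param gamma Octahedral shear strain (dimensionless, >= 0); vectorized.
#' @param nu Fluid speed in mm/s (>= 0); vectorized.
#' @param params A [stimulus_params()].
#' @return Stimulus S (dimensionless).
#' @examples
#' stimulus(0.0375, 0.03) # 2
#' @export
stimulus <- function(gamma, nu, params = stimulus_params()) {
  if (any(gamma < 0) || any(nu < 0)) {
    stop("gamma and nu must be non-negative", call. = FALSE)
  }
  gamma / params$a + nu / params$b
}

#' Tissue favored by a stimulus value
#'
#' Maps the stimulus to the locally favored tissue: `[0, 0.01)` resorption,
#' `[0.01, 0.53)` mature bone, `[0.53, 1)` immature bone, `[1, 3)` cartilage
#' and `[3, Inf)` fibrous tissue (defaults; see [tissue_thresholds()]).
#'
#' @param S Stimulus values (>= 0); vectorized.
#' @param thresholds A [tissue_thresholds()].
#' @return A factor with levels `RESORPTION`, `MATURE_BONE`, `IMMATURE_BONE`,
#'   `CARTILAGE`, `FIBROUS`.
#' @export
classify_stimulus <- function(S, thresholds = tissue_thresholds()) {
  lv <- c("RESORPTION", "MATURE_BONE", "IMMATURE_BONE", "CARTILAGE", "FIBROUS")
  idx <- findInterval(S, c(thresholds$resorption_upper, thresholds$mature_upper,
                           thresholds$immature_upper,
                           thresholds$cartilage_upper)) + 1L
  factor(lv[idx], levels = lv)
}
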