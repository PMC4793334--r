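#' @keywords internal
#' @aliases bandmove-package
"_PACKAGE"

#' End-to-end movement estimation from banding records
#'
#' Convenience wrapper chaining the full pipeline: tally banded totals
#' from the unfiltered records, apply the record-selection rules
#' ([filterRecords()]), build per-band-type recovery matrices
#' ([buildRecoveryMatrices()]), sample each band type's posterior
#' ([samplePosterior()]), and combine them with data-contribution
#' weights ([bandTypeWeights()], [combinePosteriors()]).
#'
#' @param records banding-record data.frame including never-recovered
#'   birds (they supply the banded totals), e.g. from [loadRecords()]
#'   or [simulateDataset()].
#' @param priors a [PriorConfig-class] with a lambda prior for every
#'   band type present.
#' @param cfg an [MCMCConfig-class].
#' @param filter_cfg a [FilterConfig-class].
#' @param banded_totals optional data.frame `band_type, region,
#'   n_banded`; when NULL (default) totals are tallied from `records`.
#' @param weight_by passed to [bandTypeWeights()].
#' @return list with `summary` (a [PosteriorSummary-class]), `draws`
#'   (per-band-type [PosteriorDraws-class]), `matrices`, `audit` (drop
#'   counts from filtering) and `n_recovered` (records surviving the
#'   filters).
#' @export
fitMovement <- function(records, priors, cfg = mcmcConfig(),
                        filter_cfg = filterConfig(), banded_totals = NULL,
                        weight_by = "recoveries") {
  if (is.null(banded_totals))
    banded_totals <- tallyBandedTotals(records, filter_cfg)
  flt <- filterRecords(records, filter_cfg)
  mats <- buildRecoveryMatrices(flt$kept, banded_totals)
  draws <- lapply(mats, samplePosterior, priors = priors, cfg = cfg)
  w <- bandTypeWeights(mats, weight_by = weight_by)
  summary <- combinePosteriors(draws, w)
  list(summary = summary, draws = draws, matrices = mats,
       audit = flt$audit, n_recovered = nrow(flt$kept))
}
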