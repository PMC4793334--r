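#' @import methods
NULL

#' RecoveryMatrix: per-band-type recovery counts
#'
#' Holds, for one band type, the 7x7 matrix \eqn{D} of recovery counts
#' (\eqn{D_{ij}}: birds banded in region \eqn{i}, recovered in region
#' \eqn{j}) together with the banded totals \eqn{N_i} per region and the
#' span of calendar years covered. Rows/columns are indexed by the
#' canonical region names of [regionRegistry()].
#'
#' @slot bandType single character label (free-form; band types are not
#'   an enum).
#' @slot D 7x7 integer matrix of non-negative recovery counts, dimnames
#'   both equal to `regionNames()`.
#' @slot N named integer vector of length 7, banded totals per region;
#'   every row must satisfy `sum(D[i, ]) <= N[i]`.
#' @slot yearSpan integer vector `c(first, last)` of calendar years.
#' @export
setClass("RecoveryMatrix",
  representation(bandType = "character", D = "matrix",
                 N = "integer", yearSpan = "integer"),
  validity = function(object) {
    msg <- character()
    rn <- regionNames()
    if (length(object@bandType) != 1L || is.na(object@bandType) ||
        !nzchar(object@bandType))
      msg <- c(msg, "bandType must be a single non-empty string")
    if (!identical(dim(object@D), c(N_REGIONS, N_REGIONS)))
      msg <- c(msg, "D must be 7x7")
    if (!identical(rownames(object@D), rn) ||
        !identical(colnames(object@D), rn))
      msg <- c(msg, "D dimnames must be the canonical region names")
    if (any(object@D < 0) || any(object@D != round(object@D)))
      msg <- c(msg, "D entries must be non-negative integers")
    if (length(object@N) != N_REGIONS || !identical(names(object@N), rn))
      msg <- c(msg, "N must be a length-7 vector named by region")
    else {
      if (any(object@N < 0)) msg <- c(msg, "N entries must be >= 0")
      if (identical(dim(object@D), c(N_REGIONS, N_REGIONS)) &&
          any(rowSums(object@D) > object@N))
        msg <- c(msg, "row sums of D exceed banded totals N")
    }
    if (length(object@yearSpan) != 2L ||
        (all(!is.na(object@yearSpan)) && object@yearSpan[1] > object@yearSpan[2]))
      msg <- c(msg, "yearSpan must be c(first, last) with first <= last")
    if (length(msg)) msg else TRUE
  }
)

#' Construct a RecoveryMatrix
#'
#' @param bandType band-type label.
#' @param D 7x7 matrix of recovery counts (dimnames optional; if absent
#'   the canonical region order is assumed).
#' @param N banded totals per region: either a named vector or an
#'   unnamed length-7 vector in canonical region order.
#' @param yearSpan `c(first, last)` calendar years (defaults to NA).
#' @return A [RecoveryMatrix-class] object.
#' @examples
#' D <- matrix(0L, 7, 7); D[3, 4] <- 2L
#' recoveryMatrix("legacy", D, N = rep(100L, 7))
#' @export
recoveryMatrix <- function(bandType, D, N, yearSpan = c(NA_integer_, NA_integer_)) {
  rn <- regionNames()
  D <- as.matrix(D)
  storage.mode(D) <- "integer"
  if (is.null(dimnames(D))) dimnames(D) <- list(rn, rn)
  if (is.null(names(N))) names(N) <- rn
  N <- N[rn]
  N <- stats::setNames(as.integer(N), rn)
  new("RecoveryMatrix", bandType = as.character(bandType),
      D = D[rn, rn, drop = FALSE], N = N,
      yearSpan = as.integer(yearSpan))
}

#' @describeIn RecoveryMatrix-class band-type label
#' @param object,x a `RecoveryMatrix`
#' @export
setGeneric("bandType", function(x) standardGeneric("bandType"))
#' @export
setMethod("bandType", "RecoveryMatrix", function(x) x@bandType)

#' @describeIn RecoveryMatrix-class 7x7 recovery-count matrix
#' @export
setGeneric("recoveryCounts", function(x) standardGeneric("recoveryCounts"))
#' @export
setMethod("recoveryCounts", "RecoveryMatrix", function(x) x@D)

#' @describeIn RecoveryMatrix-class banded totals per region
#' @export
setGeneric("bandedTotals", function(x) standardGeneric("bandedTotals"))
#' @export
setMethod("bandedTotals", "RecoveryMatrix", function(x) x@N)

setMethod("show", "RecoveryMatrix", function(object) {
  cat("RecoveryMatrix for band type '", object@bandType, "'\n", sep = "")
  cat("  recoveries:", sum(object@D), " banded:", sum(object@N),
      " years:", paste(object@yearSpan, collapse = "-"), "\n")
  print(object@D)
})

#' PriorConfig: prior specification for the movement model
#'
#' @slot dirichletAlpha positive symmetric Dirichlet concentration for
#'   each row of the movement matrix (1 = flat on the simplex).
#' @slot lambdaPriors data.frame with columns `band_type`, `alpha`,
#'   `beta`: Beta priors for the reporting probability of each band type.
#' @slot hPrior numeric `c(alpha, beta)` Beta prior for the harvest rate.
#' @export
setClass("PriorConfig",
  representation(dirichletAlpha = "numeric", lambdaPriors = "data.frame",
                 hPrior = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@dirichletAlpha) != 1L || object@dirichletAlpha <= 0)
      msg <- c(msg, "dirichletAlpha must be a single positive number")
    lp <- object@lambdaPriors
    if (!all(c("band_type", "alpha", "beta") %in% names(lp)))
      msg <- c(msg, "lambdaPriors needs columns band_type, alpha, beta")
    else if (nrow(lp) && (any(lp$alpha <= 0) || any(lp$beta <= 0)))
      msg <- c(msg, "lambda Beta parameters must be > 0")
    if (length(object@hPrior) != 2L || any(object@hPrior <= 0))
      msg <- c(msg, "hPrior must be c(alpha, beta), both > 0")
    if (length(msg)) msg else TRUE
  }
)

#' Construct a PriorConfig
#'
#' Reporting-probability (lambda) priors can be given either as explicit
#' Beta parameters (`lambda_priors` with columns `band_type`, `alpha`,
#' `beta`) or as means with a prior strength (columns `band_type`,
#' `mean`, optional `strength`), converted via [betaFromMean()].
#'
#' The harvest-rate prior defaults to Beta(2, 19). Note its analytic
#' mean is 2/21 ~ 0.095; continental harvest-rate syntheses put the mean
#' nearer 0.055, which Beta(2, 19) approximates by its mode (1/19).
#' `h_prior_mode = "mean_matched"` instead uses a Beta moment-matched to
#' mean 0.055 at the same strength (alpha + beta = 21).
#'
#' @param lambda_priors data.frame as described above.
#' @param dirichlet_alpha symmetric Dirichlet concentration (default 1).
#' @param h_prior Beta parameters for the harvest rate (default
#'   `c(2, 19)`); ignored when `h_prior_mode = "mean_matched"`.
#' @param h_prior_mode `"as_printed"` (use `h_prior`) or
#'   `"mean_matched"` (Beta with mean 0.055, strength 21).
#' @param default_strength prior strength used when `lambda_priors`
#'   supplies means without a `strength` column.
#' @return A [PriorConfig-class] object.
#' @examples
#' priorConfig(data.frame(band_type = "mail_in", mean = 0.32))
#' @export
priorConfig <- function(lambda_priors,
                        dirichlet_alpha = 1,
                        h_prior = c(2, 19),
                        h_prior_mode = c("as_printed", "mean_matched"),
                        default_strength = 20) {
  h_prior_mode <- match.arg(h_prior_mode)
  lp <- as.data.frame(lambda_priors)
  if (!"band_type" %in% names(lp))
    stop("lambda_priors needs a band_type column")
  if (!all(c("alpha", "beta") %in% names(lp))) {
    if (!"mean" %in% names(lp))
      stop("lambda_priors needs either (alpha, beta) or mean [+ strength]")
    s <- if ("strength" %in% names(lp)) lp$strength else
      rep(default_strength, nrow(lp))
    ab <- mapply(betaFromMean, lp$mean, s)
    lp$alpha <- ab[1, ]
    lp$beta <- ab[2, ]
  }
  lp <- lp[, c("band_type", "alpha", "beta")]
  lp$band_type <- as.character(lp$band_type)
  if (h_prior_mode == "mean_matched") {
    h_prior <- betaFromMean(0.055, 21)
  }
  new("PriorConfig", dirichletAlpha = dirichlet_alpha,
      lambdaPriors = lp, hPrior = as.numeric(h_prior))
}

setMethod("show", "PriorConfig", function(object) {
  cat("PriorConfig: Dirichlet(", object@dirichletAlpha, ") rows, h ~ Beta(",
      object@hPrior[1], ", ", object@hPrior[2], ")\n", sep = "")
  cat("lambda priors:\n")
  print(object@lambdaPriors, row.names = FALSE)
})

# look up the Beta prior for one band type
lambdaPriorFor <- function(priors, band_type) {
  lp <- priors@lambdaPriors
  i <- match(band_type, lp$band_type)
  if (is.na(i))
    stop("no lambda prior for band type '", band_type, "'", call. = FALSE)
  c(alpha = lp$alpha[i], beta = lp$beta[i])
}

#' FilterConfig: record-selection rules
#'
#' Encodes the study-design filters: birds must be banded during the
#' preseason (1 Jul - 30 Sep), recovered during the hunting season
#' (Oct-Feb, when migration occurs), and direct same-region recoveries
#' (shot in the first hunting season after banding, in the banding
#' region, i.e. with no opportunity to move) are removed.
#'
#' @slot preseasonStart,preseasonEnd month-day strings `"MM-DD"`.
#' @slot huntingMonths integer months defining recovery eligibility.
#' @slot dropDirectSameRegion drop same-region direct recoveries?
#' @export
setClass("FilterConfig",
  representation(preseasonStart = "character", preseasonEnd = "character",
                 huntingMonths = "integer", dropDirectSameRegion = "logical"),
  validity = function(object) {
    msg <- character()
    md <- "^[01][0-9]-[0-3][0-9]$"
    if (!grepl(md, object@preseasonStart) || !grepl(md, object@preseasonEnd))
      msg <- c(msg, "preseason bounds must be 'MM-DD' strings")
    if (length(object@huntingMonths) == 0 ||
        any(!object@huntingMonths %in% 1:12))
      msg <- c(msg, "huntingMonths must be a non-empty subset of 1..12")
    if (length(msg)) msg else TRUE
  }
)

#' Construct a FilterConfig
#'
#' @param preseason_start,preseason_end preseason banding window bounds,
#'   `"MM-DD"`; defaults 1 Jul - 30 Sep.
#' @param hunting_months months in which recoveries are eligible;
#'   default Oct-Feb (`c(10, 11, 12, 1, 2)`).
#' @param drop_direct_same_region drop birds recovered in the hunting
#'   season immediately after banding and in their banding region
#'   (default TRUE).
#' @return A [FilterConfig-class] object.
#' @export
filterConfig <- function(preseason_start = "07-01", preseason_end = "09-30",
                         hunting_months = c(10L, 11L, 12L, 1L, 2L),
                         drop_direct_same_region = TRUE) {
  new("FilterConfig", preseasonStart = preseason_start,
      preseasonEnd = preseason_end,
      huntingMonths = as.integer(hunting_months),
      dropDirectSameRegion = isTRUE(drop_direct_same_region))
}

setMethod("show", "FilterConfig", function(object) {
  cat("FilterConfig: preseason ", object@preseasonStart, "..",
      object@preseasonEnd, ", hunting months ",
      paste(object@huntingMonths, collapse = ","),
      ", drop direct same-region: ", object@dropDirectSameRegion, "\n",
      sep = "")
})

#' MCMCConfig: sampler settings
#'
#' @slot nChains number of independent chains (>= 2 for diagnostics).
#' @slot nIter iterations per chain (including burn-in).
#' @slot nBurn burn-in iterations discarded per chain.
#' @slot thin keep every `thin`-th post-burn-in draw.
#' @slot seed master seed; chain c uses a deterministic sub-stream.
#' @slot proposalScale initial Dirichlet proposal concentration for
#'   movement rows (larger = smaller steps); adapted per row during
#'   burn-in toward a 30% acceptance rate, frozen afterwards.
#' @slot rwSd initial logit-scale random-walk sd for lambda and h;
#'   adapted during burn-in toward 44% acceptance.
#' @slot rhatThreshold convergence flag threshold (default 1.1).
#' @export
setClass("MCMCConfig",
  representation(nChains = "integer", nIter = "integer", nBurn = "integer",
                 thin = "integer", seed = "integer",
                 proposalScale = "numeric", rwSd = "numeric",
                 rhatThreshold = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@nChains < 1L) msg <- c(msg, "nChains must be >= 1")
    if (object@nBurn >= object@nIter) msg <- c(msg, "nBurn must be < nIter")
    if (object@thin < 1L) msg <- c(msg, "thin must be >= 1")
    if (object@proposalScale <= 0) msg <- c(msg, "proposalScale must be > 0")
    if (object@rwSd <= 0) msg <- c(msg, "rwSd must be > 0")
    if (length(msg)) msg else TRUE
  }
)

#' Construct an MCMCConfig
#'
#' @param n_chains chains (default 3).
#' @param n_iter iterations per chain (default 4000).
#' @param n_burn burn-in (default `n_iter / 2`).
#' @param thin thinning interval (default 1).
#' @param seed master seed (default 1).
#' @param proposal_scale Dirichlet proposal concentration (default 250).
#' @param rw_sd logit random-walk sd for lambda and h (default 0.25).
#' @param rhat_threshold R-hat convergence threshold (default 1.1).
#' @return An [MCMCConfig-class] object.
#' @export
mcmcConfig <- function(n_chains = 3, n_iter = 4000, n_burn = floor(n_iter / 2),
                       thin = 1, seed = 1, proposal_scale = 250,
                       rw_sd = 0.25, rhat_threshold = 1.1) {
  new("MCMCConfig", nChains = as.integer(n_chains), nIter = as.integer(n_iter),
      nBurn = as.integer(n_burn), thin = as.integer(thin),
      seed = as.integer(seed), proposalScale = proposal_scale,
      rwSd = rw_sd, rhatThreshold = rhat_threshold)
}

#' PosteriorDraws: retained MCMC samples for one band type
#'
#' @slot bandType band-type label.
#' @slot psi numeric array `[draw, chain, cell]` of movement-probability
#'   draws; cells are the row-major 7x7 (or KxK) entries named
#'   `"Psi[i,j]"` by region. Every draw's rows sum to 1.
#' @slot lambda matrix `[draw, chain]` of reporting-rate draws.
#' @slot h matrix `[draw, chain]` of harvest-rate draws.
#' @slot regions region names indexing the movement matrix.
#' @slot acceptance named acceptance fractions per proposal block.
#' @slot rhat named R-hat per scalar parameter (filled by the sampler).
#' @slot converged TRUE when all R-hat < threshold.
#' @export
setClass("PosteriorDraws",
  representation(bandType = "character", psi = "array", lambda = "matrix",
                 h = "matrix", regions = "character",
                 acceptance = "numeric", rhat = "numeric",
                 converged = "logical"),
  validity = function(object) {
    msg <- character()
    K <- length(object@regions)
    if (dim(object@psi)[3] != K * K)
      msg <- c(msg, "psi third dimension must be K^2")
    if (length(msg)) msg else TRUE
  }
)

#' @export
setMethod("bandType", "PosteriorDraws", function(x) x@bandType)

#' Flattened movement-probability draws
#'
#' @param x a `PosteriorDraws`
#' @return matrix `[total draws across chains, K^2]`, columns named
#'   `"Psi[banding,recovery]"`.
#' @export
setGeneric("psiDraws", function(x) standardGeneric("psiDraws"))
#' @export
setMethod("psiDraws", "PosteriorDraws", function(x) {
  d <- dim(x@psi)
  out <- matrix(aperm(x@psi, c(1, 2, 3)), nrow = d[1] * d[2], ncol = d[3])
  colnames(out) <- dimnames(x@psi)[[3]]
  out
})

#' Posterior mean movement matrix
#'
#' @param x a `PosteriorDraws`
#' @return KxK matrix of posterior means (rows sum to 1).
#' @export
setGeneric("psiMean", function(x) standardGeneric("psiMean"))
#' @export
setMethod("psiMean", "PosteriorDraws", function(x) {
  K <- length(x@regions)
  matrix(colMeans(psiDraws(x)), K, K, byrow = TRUE,
         dimnames = list(x@regions, x@regions))
})

setMethod("show", "PosteriorDraws", function(object) {
  d <- dim(object@psi)
  cat("PosteriorDraws for band type '", object@bandType, "': ",
      d[1], " draws x ", d[2], " chains, ", length(object@regions),
      " regions\n", sep = "")
  cat("  converged:", object@converged,
      " max R-hat:", round(max(object@rhat, na.rm = TRUE), 4), "\n")
  cat("  acceptance:", paste(names(object@acceptance),
      round(object@acceptance, 2), collapse = ", "), "\n")
})

#' PosteriorSummary: combined movement-probability summary
#'
#' The band-type-weighted posterior of the movement matrix: elementwise
#' mean, SD and central 95% credible bounds, plus the pooled weighted
#' draws the quantiles were computed from (kept so derived summaries can
#' propagate full posterior uncertainty).
#'
#' @slot mean,sd,ciLow,ciHigh 7x7 (or KxK) matrices.
#' @slot weights named band-type weights used.
#' @slot draws pooled draw matrix `[draw, K^2]` across band types.
#' @slot drawWeights normalized per-draw weights for `draws`.
#' @slot regions region names.
#' @export
setClass("PosteriorSummary",
  representation(mean = "matrix", sd = "matrix", ciLow = "matrix",
                 ciHigh = "matrix", weights = "numeric", draws = "matrix",
                 drawWeights = "numeric", regions = "character"),
  validity = function(object) {
    msg <- character()
    K <- length(object@regions)
    for (s in c("mean", "sd", "ciLow", "ciHigh"))
      if (!identical(dim(slot(object, s)), c(K, K)))
        msg <- c(msg, paste0(s, " must be ", K, "x", K))
    if (!length(msg)) {
      if (any(abs(rowSums(object@mean) - 1) > 1e-6))
        msg <- c(msg, "mean rows must sum to 1 (within 1e-6)")
      if (any(object@ciLow > object@mean + 1e-9) ||
          any(object@ciHigh < object@mean - 1e-9))
        msg <- c(msg, "need ciLow <= mean <= ciHigh elementwise")
    }
    if (length(msg)) msg else TRUE
  }
)

setMethod("show", "PosteriorSummary", function(object) {
  cat("PosteriorSummary over band types: ",
      paste(names(object@weights), sprintf("(w=%.3f)", object@weights),
            collapse = ", "), "\n", sep = "")
  cat("posterior mean movement probabilities:\n")
  print(round(object@mean, 3))
})

#' Accessors for PosteriorSummary
#'
#' @param x a `PosteriorSummary`
#' @return the requested component matrix or weight vector.
#' @name PosteriorSummary-accessors
NULL

#' @rdname PosteriorSummary-accessors
#' @export
setGeneric("psiMeans", function(x) standardGeneric("psiMeans"))
#' @rdname PosteriorSummary-accessors
#' @export
setMethod("psiMeans", "PosteriorSummary", function(x) x@mean)
#' @rdname PosteriorSummary-accessors
#' @export
setGeneric("psiSds", function(x) standardGeneric("psiSds"))
#' @rdname PosteriorSummary-accessors
#' @export
setMethod("psiSds", "PosteriorSummary", function(x) x@sd)
#' @rdname PosteriorSummary-accessors
#' @export
setGeneric("credLow", function(x) standardGeneric("credLow"))
#' @rdname PosteriorSummary-accessors
#' @export
setMethod("credLow", "PosteriorSummary", function(x) x@ciLow)
#' @rdname PosteriorSummary-accessors
#' @export
setGeneric("credHigh", function(x) standardGeneric("credHigh"))
#' @rdname PosteriorSummary-accessors
#' @export
setMethod("credHigh", "PosteriorSummary", function(x) x@ciHigh)
#' @rdname PosteriorSummary-accessors
#' @export
setGeneric("weightsUsed", function(x) standardGeneric("weightsUsed"))
#' @rdname PosteriorSummary-accessors
#' @export
setMethod("weightsUsed", "PosteriorSummary", function(x) x@weights)

#' SyntheticTruth: known generating parameters for a simulation
#'
#' @slot psi 7x7 row-stochastic movement matrix used to generate data.
#' @slot lambda named reporting probability per band type.
#' @slot h harvest rate.
#' @slot cohorts data.frame `band_type, region, year, n`: banded cohort
#'   sizes.
#' @slot seed integer simulation seed.
#' @export
setClass("SyntheticTruth",
  representation(psi = "matrix", lambda = "numeric", h = "numeric",
                 cohorts = "data.frame", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (!identical(dim(object@psi), c(N_REGIONS, N_REGIONS)))
      msg <- c(msg, "psi must be 7x7")
    else if (any(abs(rowSums(object@psi) - 1) > 1e-9))
      msg <- c(msg, "psi rows must sum to 1")
    if (any(object@psi < 0) || any(object@psi > 1))
      msg <- c(msg, "psi entries must lie in [0, 1]")
    if (any(object@lambda < 0) || any(object@lambda > 1) ||
        is.null(names(object@lambda)))
      msg <- c(msg, "lambda must be named probabilities")
    if (length(object@h) != 1L || object@h < 0 || object@h > 1)
      msg <- c(msg, "h must be a single probability")
    need <- c("band_type", "region", "year", "n")
    if (!all(need %in% names(object@cohorts)))
      msg <- c(msg, "cohorts needs columns band_type, region, year, n")
    else if (nrow(object@cohorts) && any(object@cohorts$n < 0))
      msg <- c(msg, "cohort sizes must be >= 0")
    if (length(msg)) msg else TRUE
  }
)

#' Construct a SyntheticTruth
#'
#' @param psi 7x7 row-stochastic movement matrix (canonical region
#'   order; dimnames optional).
#' @param lambda named vector of reporting probabilities per band type.
#' @param h harvest rate.
#' @param cohorts data.frame with columns `band_type`, `region`, `year`,
#'   `n` giving banded cohort sizes.
#' @param seed simulation seed.
#' @return A [SyntheticTruth-class] object.
#' @export
syntheticTruth <- function(psi, lambda, h, cohorts, seed = 1L) {
  rn <- regionNames()
  psi <- as.matrix(psi)
  dimnames(psi) <- list(rn, rn)
  cohorts <- as.data.frame(cohorts)
  cohorts$region <- assertRegions(cohorts$region, "cohort region")
  cohorts$band_type <- as.character(cohorts$band_type)
  new("SyntheticTruth", psi = psi, lambda = lambda, h = h,
      cohorts = cohorts, seed = as.integer(seed))
}

#' @describeIn SyntheticTruth-class the generating movement matrix
#' @param x a `SyntheticTruth`
#' @export
setGeneric("truePsi", function(x) standardGeneric("truePsi"))
#' @export
setMethod("truePsi", "SyntheticTruth", function(x) x@psi)

setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth: ", nrow(object@cohorts), " cohorts, ",
      sum(object@cohorts$n), " birds banded, h = ", object@h, "\n", sep = "")
  cat("band types:", paste(names(object@lambda),
      sprintf("(lambda=%.2f)", object@lambda), collapse = ", "), "\n")
  cat("expected recoveries: ",
      round(expectedRecoveries(object)), "\n", sep = "")
})

#' Expected number of reported recoveries under a synthetic truth
#'
#' Each banded bird is recovered-and-reported with probability
#' `lambda[band type] * h`, so the expectation is
#' `sum_k lambda_k * h * N_k`.
#'
#' @param truth a [SyntheticTruth-class].
#' @return expected recovery count (numeric).
#' @export
expectedRecoveries <- function(truth) {
  stopifnot(is(truth, "SyntheticTruth"))
  nk <- tapply(truth@cohorts$n, truth@cohorts$band_type, sum)
  sum(truth@lambda[names(nk)] * truth@h * nk)
}
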