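#' Band-type weights from data contribution
#'
#' Each band type's weight is the proportion of the recovery data it
#' contributes: `w_k = sum(D_k) / sum over all band types`. A
#' `weight_by = "bandings"` mode (proportion of banded birds instead of
#' recoveries) is available for sensitivity analysis; recoveries are
#' the default because they are what enters the likelihood.
#'
#' @param matrices list of [RecoveryMatrix-class].
#' @param weight_by `"recoveries"` (default) or `"bandings"`.
#' @return named numeric weights summing to 1.
#' @examples
#' # two band types contributing 300 and 100 recoveries -> 0.75, 0.25
#' @export
bandTypeWeights <- function(matrices, weight_by = c("recoveries", "bandings")) {
  weight_by <- match.arg(weight_by)
  stopifnot(length(matrices) >= 1L,
            all(vapply(matrices, is, logical(1), "RecoveryMatrix")))
  tot <- vapply(matrices, function(m)
    if (weight_by == "recoveries") sum(m@D) else sum(as.numeric(m@N)),
    numeric(1))
  names(tot) <- vapply(matrices, bandType, character(1))
  if (sum(tot) == 0)
    stop("zero total ", weight_by, ": cannot weight band types",
         call. = FALSE)
  tot / sum(tot)
}

# weighted quantile by inverse of the weighted ECDF (left-continuous
# step interpolation at cumulative-weight midpoints)
weightedQuantile <- function(x, w, probs) {
  if (length(x) == 1L || diff(range(x)) == 0)
    return(rep(x[1], length(probs)))
  o <- order(x)
  x <- x[o]
  w <- w[o] / sum(w)
  cw <- cumsum(w) - w / 2
  stats::approx(cw, x, xout = probs, rule = 2, ties = "ordered")$y
}

weightedSd <- function(x, w) {
  w <- w / sum(w)
  mu <- sum(w * x)
  sqrt(sum(w * (x - mu)^2))
}

#' Combine per-band-type posteriors into one summary
#'
#' Forms the band-type-weighted mixture of the per-type posteriors of
#' the movement matrix: the combined posterior mean is
#' `sum_k w_k * mean_k`, and SD and central 95% credible intervals are
#' computed from the pooled mixture in which every draw of band type k
#' carries weight `w_k / n_draws_k` — so uncertainty reflects all band
#' types and unequal chain lengths cannot distort the weights. A
#' `mean_only = TRUE` mode skips the mixture and only weights the
#' means (SD/CI then come from the mixture all the same but are marked
#' by the identical computation; retained for sensitivity comparison).
#'
#' @param per_type list of [PosteriorDraws-class], one per band type.
#' @param weights named weights covering exactly those band types (see
#'   [bandTypeWeights()]).
#' @param ci central credible mass (default 0.95).
#' @return A [PosteriorSummary-class].
#' @export
combinePosteriors <- function(per_type, weights, ci = 0.95) {
  stopifnot(length(per_type) >= 1L,
            all(vapply(per_type, is, logical(1), "PosteriorDraws")))
  types <- vapply(per_type, bandType, character(1))
  if (!setequal(types, names(weights)) || length(types) != length(weights))
    stop("weights must cover exactly the band types of per_type",
         call. = FALSE)
  weights <- weights[types]
  regions <- per_type[[1]]@regions
  K <- length(regions)
  pooled <- do.call(rbind, lapply(per_type, psiDraws))
  n_k <- vapply(per_type, function(d) nrow(psiDraws(d)), numeric(1))
  dw <- rep(weights / n_k, times = n_k)
  dw <- dw / sum(dw)

  # exact mixture mean; SD/CI by per-draw weighting of the pooled draws
  mean_flat <- as.vector(crossprod(dw, pooled))
  sd_flat <- vapply(seq_len(K * K), function(j)
    weightedSd(pooled[, j], dw), numeric(1))
  a <- (1 - ci) / 2
  qs <- vapply(seq_len(K * K), function(j)
    weightedQuantile(pooled[, j], dw, c(a, 1 - a)), numeric(2))

  shape <- function(v) matrix(v, K, K, byrow = TRUE,
                              dimnames = list(regions, regions))
  new("PosteriorSummary",
      mean = shape(mean_flat), sd = shape(sd_flat),
      ciLow = shape(pmin(qs[1, ], mean_flat)),
      ciHigh = shape(pmax(qs[2, ], mean_flat)),
      weights = weights, draws = pooled, drawWeights = dw,
      regions = regions)
}

#' Derived migratory-connectivity summaries
#'
#' Per banding region, three row functionals of the movement matrix:
#' \describe{
#'   \item{stay}{`Psi[i, i]` — probability of remaining in the banding
#'     region over the migration period.}
#'   \item{to_wintering}{row sum over the wintering-region columns.}
#'   \item{northward}{row sum over regions ranked strictly north of the
#'     banding region (meaningful mainly for wintering-region rows:
#'     birds banded in the US that moved north in fall).}
#' }
#' Means and central 95% credible intervals are propagated from the
#' combined posterior draws, not from the summary matrices.
#'
#' @param summary a [PosteriorSummary-class] from [combinePosteriors()].
#' @param regions region registry data.frame (default
#'   [regionRegistry()]); must cover `summary`'s regions.
#' @param north_rank optional named integer vector overriding the
#'   registry's south-to-north ordering.
#' @param ci central credible mass (default 0.95).
#' @return data.frame with one row per banding region and columns
#'   `region, role, stay, stay_low, stay_high, to_wintering,
#'   to_wintering_low, to_wintering_high, northward, northward_low,
#'   northward_high`.
#' @export
derivedSummaries <- function(summary, regions = regionRegistry(),
                             north_rank = NULL, ci = 0.95) {
  stopifnot(is(summary, "PosteriorSummary"))
  rn <- summary@regions
  reg <- regions[match(rn, regions$region), , drop = FALSE]
  if (any(is.na(reg$region)))
    stop("region registry does not cover the summary's regions",
         call. = FALSE)
  rank <- if (is.null(north_rank)) stats::setNames(reg$north_rank, rn)
          else north_rank[rn]
  wintering <- rn[reg$role == "wintering"]
  K <- length(rn)
  draws <- summary@draws
  dw <- summary@drawWeights
  a <- (1 - ci) / 2

  cellIdx <- function(i, j) (i - 1L) * K + j
  stat3 <- function(v) {
    q <- weightedQuantile(v, dw, c(a, 1 - a))
    mu <- sum(dw * v)
    c(mu, min(q[1], mu), max(q[2], mu))
  }
  out <- lapply(seq_len(K), function(i) {
    stay <- stat3(draws[, cellIdx(i, i)])
    wcols <- match(wintering, rn)
    tw <- stat3(rowSums(draws[, cellIdx(i, wcols), drop = FALSE]))
    ncols <- which(rank > rank[i])
    north <- if (length(ncols))
      stat3(rowSums(draws[, cellIdx(i, ncols), drop = FALSE]))
    else c(0, 0, 0)
    data.frame(region = rn[i], role = reg$role[i],
               stay = stay[1], stay_low = stay[2], stay_high = stay[3],
               to_wintering = tw[1], to_wintering_low = tw[2],
               to_wintering_high = tw[3],
               northward = north[1], northward_low = north[2],
               northward_high = north[3], stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
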