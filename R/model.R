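#' The movement model
#'
#' For one band type, the probability that a bird banded in region
#' \eqn{i} is recovered (shot and reported) in region \eqn{j} is
#' \deqn{\pi_{ij} = \Psi_{ij} \lambda h}
#' where \eqn{\Psi_{ij}} is the movement probability (rows constrained
#' to the probability simplex), \eqn{\lambda} the band-type-specific
#' reporting probability and \eqn{h} the harvest rate, held constant
#' across regions. The counts are modelled as independent binomials
#' \eqn{D_{ij} \sim Bin(N_i, \pi_{ij})} with \eqn{N_i} the banded total
#' of region \eqn{i}. Priors: each row of \eqn{\Psi} is Dirichlet
#' (symmetric, flat by default), \eqn{\lambda \sim Beta(\alpha_k,
#' \beta_k)} moment-matched to each band type's reporting probability,
#' and \eqn{h \sim Beta(2, 19)}. \eqn{\lambda} and \eqn{h} are
#' confounded (only their product enters the likelihood); fixing their
#' priors makes \eqn{\Psi} identifiable.
#'
#' @name movement-model
NULL

# concentration offset added to Dirichlet proposals so proposals near a
# simplex face remain proper and reversible
PROP_EPS <- 0.05

#' Beta parameters from a mean and prior strength
#'
#' Moment parameterization of the Beta: `alpha = mean * strength`,
#' `beta = (1 - mean) * strength`, so the Beta mean equals `mean`
#' exactly and `strength = alpha + beta` controls concentration.
#'
#' @param mean target mean, in (0, 1).
#' @param strength prior strength (pseudo-observations), > 0.
#' @return numeric `c(alpha, beta)`.
#' @examples
#' betaFromMean(0.5, 2)   # c(1, 1): uniform
#' betaFromMean(0.8, 10)  # c(8, 2)
#' @export
betaFromMean <- function(mean, strength) {
  if (!is.finite(mean) || mean <= 0 || mean >= 1)
    stop("mean must lie strictly in (0, 1)", call. = FALSE)
  if (!is.finite(strength) || strength <= 0)
    stop("strength must be > 0", call. = FALSE)
  c(alpha = mean * strength, beta = (1 - mean) * strength)
}

# log density of the Dirichlet distribution at simplex point x
logDirichlet <- function(x, alpha) {
  if (length(alpha) == 1L) alpha <- rep(alpha, length(x))
  sum((alpha - 1) * log(x)) + lgamma(sum(alpha)) - sum(lgamma(alpha))
}

# one Dirichlet draw via normalized gammas
rDirichlet <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  s <- sum(g)
  if (s <= 0) return(rep(1 / length(alpha), length(alpha)))
  g / s
}

#' ModelState: one point in the model's parameter space
#'
#' @slot psi KxK row-stochastic movement matrix (rows sum to 1 within
#'   1e-12, entries in (0, 1)).
#' @slot lambda reporting probability in (0, 1).
#' @slot h harvest rate in (0, 1).
#' @export
setClass("ModelState",
  representation(psi = "matrix", lambda = "numeric", h = "numeric"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@psi) != ncol(object@psi))
      msg <- c(msg, "psi must be square")
    if (any(abs(rowSums(object@psi) - 1) > 1e-12))
      msg <- c(msg, "psi rows must sum to 1 within 1e-12")
    if (any(object@psi <= 0) || any(object@psi >= 1))
      msg <- c(msg, "psi entries must lie strictly in (0, 1)")
    if (object@lambda <= 0 || object@lambda >= 1 ||
        object@h <= 0 || object@h >= 1)
      msg <- c(msg, "lambda and h must lie strictly in (0, 1)")
    if (length(msg)) msg else TRUE
  }
)

#' Construct a ModelState
#'
#' @param psi row-stochastic movement matrix.
#' @param lambda reporting probability.
#' @param h harvest rate.
#' @return A [ModelState-class].
#' @export
modelState <- function(psi, lambda, h) {
  new("ModelState", psi = as.matrix(psi), lambda = lambda, h = h)
}

setMethod("show", "ModelState", function(object) {
  cat("ModelState: ", nrow(object@psi), "x", ncol(object@psi),
      " psi, lambda = ", signif(object@lambda, 4),
      ", h = ", signif(object@h, 4), "\n", sep = "")
})

# log likelihood of one row of counts given its movement row
rowLogLik <- function(d, n, psi_row, lamh) {
  sum(stats::dbinom(d, n, psi_row * lamh, log = TRUE))
}

# log posterior on raw components (engine internal)
logPosteriorCore <- function(psi, lam, h, D, Nvec, dir_alpha, lam_ab, h_ab) {
  lamh <- lam * h
  P <- psi * lamh
  ll <- sum(stats::dbinom(D, matrix(Nvec, nrow(D), ncol(D)), P, log = TRUE))
  lp <- sum(apply(psi, 1L, logDirichlet, alpha = dir_alpha)) +
    stats::dbeta(lam, lam_ab[1], lam_ab[2], log = TRUE) +
    stats::dbeta(h, h_ab[1], h_ab[2], log = TRUE)
  ll + lp
}

#' Log posterior density of a model state
#'
#' Sum of the binomial recovery log-likelihood
#' \eqn{\sum_{ij} \log Bin(D_{ij}; N_i, \Psi_{ij}\lambda h)}, the
#' Dirichlet log-prior over the movement rows, and the Beta log-priors
#' of the reporting and harvest rates. Returns `-Inf` (never an error)
#' for boundary states, so samplers can simply reject them.
#'
#' @param state a [ModelState-class].
#' @param mat a [RecoveryMatrix-class]; its `bandType` selects the
#'   lambda prior.
#' @param priors a [PriorConfig-class].
#' @param n_mode `"per_region"`: row i's binomials share the region's
#'   banded total `N[i]` (default); `"global"`: all cells share
#'   `sum(N)` (sensitivity mode).
#' @return a single finite number for interior states, `-Inf` on the
#'   boundary.
#' @export
logPosterior <- function(state, mat, priors,
                         n_mode = c("per_region", "global")) {
  stopifnot(is(state, "ModelState"), is(mat, "RecoveryMatrix"),
            is(priors, "PriorConfig"))
  n_mode <- match.arg(n_mode)
  Nvec <- if (n_mode == "global") rep(sum(mat@N), N_REGIONS) else mat@N
  lam_ab <- lambdaPriorFor(priors, mat@bandType)
  v <- logPosteriorCore(state@psi, state@lambda, state@h, mat@D, Nvec,
                        priors@dirichletAlpha, lam_ab, priors@hPrior)
  if (is.nan(v)) -Inf else v
}

# Metropolis-within-Gibbs engine, generic in the number of regions.
# Blocks: each movement row (Dirichlet proposal centred at the current
# row, concentration = scale * row + PROP_EPS), lambda and h
# (logit-scale Gaussian random walks), and a product-preserving
# lambda/h exchange that moves along the confounding ridge. Proposal
# scales are adapted toward standard acceptance targets during burn-in
# (windowed multiplicative updates) and frozen before any draw is
# retained, so the retained chain has a fixed, valid kernel.
mcmcEngine <- function(D, Nvec, dir_alpha, lam_ab, h_ab, cfg,
                       fix_lambda = NULL, fix_h = NULL, regions = NULL) {
  K <- nrow(D)
  if (is.null(regions)) regions <- paste0("r", seq_len(K))
  n_keep <- length(seq.int(cfg@nBurn + 1L, cfg@nIter, by = cfg@thin))
  nc <- cfg@nChains
  psi_draws <- array(NA_real_, c(n_keep, nc, K * K))
  lam_draws <- matrix(NA_real_, n_keep, nc)
  h_draws <- matrix(NA_real_, n_keep, nc)
  acc <- matrix(0, nc, 4,
                dimnames = list(NULL, c("psi_rows", "lambda", "h", "swap")))

  set.seed(cfg@seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, nc)
  Nmat <- matrix(Nvec, K, K)
  ADAPT_WINDOW <- 25L
  TARGET_ROW <- 0.30   # multivariate block
  TARGET_RW <- 0.44    # 1-D random walk

  for (ch in seq_len(nc)) {
    set.seed(chain_seeds[ch])
    # per-block proposal scales, adapted during burn-in only
    s_row <- rep(cfg@proposalScale, K)
    rw_lam <- cfg@rwSd
    rw_h <- cfg@rwSd
    rw_swap <- cfg@rwSd
    win <- matrix(0, K + 3L, 2L)  # per block: accepts, tries

    # dispersed overdispersed starts drawn from the priors
    psi <- t(vapply(seq_len(K), function(i) rDirichlet(rep(1, K)),
                    numeric(K)))
    lam <- if (is.null(fix_lambda)) stats::rbeta(1, lam_ab[1], lam_ab[2])
           else fix_lambda
    h <- if (is.null(fix_h)) stats::rbeta(1, h_ab[1], h_ab[2]) else fix_h
    lam <- min(max(lam, 1e-6), 1 - 1e-6)
    h <- min(max(h, 1e-6), 1 - 1e-6)
    lamh <- lam * h
    rowll <- vapply(seq_len(K), function(i)
      rowLogLik(D[i, ], Nvec[i], psi[i, ], lamh), numeric(1))

    n_acc <- c(psi_rows = 0, lambda = 0, h = 0, swap = 0)
    n_try <- c(psi_rows = 0, lambda = 0, h = 0, swap = 0)
    keep_i <- 0L
    for (it in seq_len(cfg@nIter)) {
      adapting <- it <= cfg@nBurn
      # -- movement rows --------------------------------------------
      for (i in seq_len(K)) {
        cur <- psi[i, ]
        conc_f <- s_row[i] * cur + PROP_EPS
        prop <- rDirichlet(conc_f)
        ok <- FALSE
        if (min(prop) >= 1e-12) {
          conc_r <- s_row[i] * prop + PROP_EPS
          ll_prop <- rowLogLik(D[i, ], Nvec[i], prop, lamh)
          logr <- (ll_prop + sum((dir_alpha - 1) * log(prop))) -
                  (rowll[i] + sum((dir_alpha - 1) * log(cur))) +
                  logDirichlet(cur, conc_r) - logDirichlet(prop, conc_f)
          if (is.finite(logr) && log(stats::runif(1)) < logr) {
            psi[i, ] <- prop
            rowll[i] <- ll_prop
            ok <- TRUE
          }
        }
        win[i, ] <- win[i, ] + c(ok, 1)
        if (!adapting) {
          n_acc["psi_rows"] <- n_acc["psi_rows"] + ok
          n_try["psi_rows"] <- n_try["psi_rows"] + 1
        }
      }
      # -- reporting rate -------------------------------------------
      if (is.null(fix_lambda)) {
        th <- stats::qlogis(lam) + stats::rnorm(1, 0, rw_lam)
        lam_p <- stats::plogis(th)
        lamh_p <- lam_p * h
        rowll_p <- rowSums(stats::dbinom(D, Nmat, psi * lamh_p, log = TRUE))
        logr <- sum(rowll_p) - sum(rowll) +
          stats::dbeta(lam_p, lam_ab[1], lam_ab[2], log = TRUE) -
          stats::dbeta(lam, lam_ab[1], lam_ab[2], log = TRUE) +
          log(lam_p * (1 - lam_p)) - log(lam * (1 - lam))
        ok <- is.finite(logr) && log(stats::runif(1)) < logr
        if (ok) { lam <- lam_p; lamh <- lamh_p; rowll <- rowll_p }
        win[K + 1L, ] <- win[K + 1L, ] + c(ok, 1)
        if (!adapting) {
          n_acc["lambda"] <- n_acc["lambda"] + ok
          n_try["lambda"] <- n_try["lambda"] + 1
        }
      }
      # -- harvest rate ---------------------------------------------
      if (is.null(fix_h)) {
        th <- stats::qlogis(h) + stats::rnorm(1, 0, rw_h)
        h_p <- stats::plogis(th)
        lamh_p <- lam * h_p
        rowll_p <- rowSums(stats::dbinom(D, Nmat, psi * lamh_p, log = TRUE))
        logr <- sum(rowll_p) - sum(rowll) +
          stats::dbeta(h_p, h_ab[1], h_ab[2], log = TRUE) -
          stats::dbeta(h, h_ab[1], h_ab[2], log = TRUE) +
          log(h_p * (1 - h_p)) - log(h * (1 - h))
        ok <- is.finite(logr) && log(stats::runif(1)) < logr
        if (ok) { h <- h_p; lamh <- lamh_p; rowll <- rowll_p }
        win[K + 2L, ] <- win[K + 2L, ] + c(ok, 1)
        if (!adapting) {
          n_acc["h"] <- n_acc["h"] + ok
          n_try["h"] <- n_try["h"] + 1
        }
      }
      # -- confounding-ridge exchange: lambda * h unchanged ----------
      if (is.null(fix_lambda) && is.null(fix_h)) {
        u <- stats::rnorm(1, 0, rw_swap)
        lam_p <- lam * exp(u)
        h_p <- h * exp(-u)
        ok <- FALSE
        if (lam_p < 1 && h_p < 1) {
          # likelihood depends only on the product, which is preserved;
          # the map's Jacobian is 1, the u-draw is symmetric
          logr <- stats::dbeta(lam_p, lam_ab[1], lam_ab[2], log = TRUE) +
            stats::dbeta(h_p, h_ab[1], h_ab[2], log = TRUE) -
            stats::dbeta(lam, lam_ab[1], lam_ab[2], log = TRUE) -
            stats::dbeta(h, h_ab[1], h_ab[2], log = TRUE)
          if (is.finite(logr) && log(stats::runif(1)) < logr) {
            lam <- lam_p; h <- h_p
            ok <- TRUE
          }
        }
        win[K + 3L, ] <- win[K + 3L, ] + c(ok, 1)
        if (!adapting) {
          n_acc["swap"] <- n_acc["swap"] + ok
          n_try["swap"] <- n_try["swap"] + 1
        }
      }
      # -- adapt proposal scales during burn-in ----------------------
      if (adapting && it %% ADAPT_WINDOW == 0L) {
        rate <- ifelse(win[, 2] > 0, win[, 1] / win[, 2], NA)
        # larger Dirichlet concentration = smaller steps = higher acceptance
        adj <- exp(pmin(1, pmax(-1, TARGET_ROW - rate[seq_len(K)])) * 1.5)
        s_row <- pmin(pmax(s_row * adj, 5), 1e8)
        bump <- function(sd, r) if (is.na(r)) sd else
          min(max(sd * exp((r - TARGET_RW) * 1.5), 1e-4), 3)
        rw_lam <- bump(rw_lam, rate[K + 1L])
        rw_h <- bump(rw_h, rate[K + 2L])
        rw_swap <- bump(rw_swap, rate[K + 3L])
        win[] <- 0
      }
      # -- record ----------------------------------------------------
      if (it > cfg@nBurn && (it - cfg@nBurn - 1L) %% cfg@thin == 0L) {
        keep_i <- keep_i + 1L
        psi_draws[keep_i, ch, ] <- as.vector(t(psi))  # row-major
        lam_draws[keep_i, ch] <- lam
        h_draws[keep_i, ch] <- h
      }
    }
    acc[ch, ] <- ifelse(n_try > 0, n_acc / n_try, NA)
  }
  cell_names <- paste0("Psi[", rep(regions, each = K), ",",
                       rep(regions, times = K), "]")
  dimnames(psi_draws) <- list(NULL, NULL, cell_names)
  list(psi = psi_draws, lambda = lam_draws, h = h_draws,
       acceptance = colMeans(acc), regions = regions)
}

#' Sample the posterior of the movement model
#'
#' Runs `n_chains` independent Metropolis-within-Gibbs chains over the
#' posterior of \eqn{(\Psi, \lambda, h)} given one band type's recovery
#' matrix: each movement row is updated with a Dirichlet proposal
#' centred at the current row, \eqn{\lambda} and \eqn{h} with
#' logit-scale Gaussian random walks. Runs are deterministic given the
#' config seed (each chain uses a derived sub-seed). R-hat is computed
#' for every sampled scalar; non-convergence is flagged on the result
#' (and warned about), never silently accepted.
#'
#' @param mat a [RecoveryMatrix-class], or a plain KxK count matrix for
#'   reduced toy problems (then `N` must be given and the lambda prior
#'   is matched by `band_type`).
#' @param priors a [PriorConfig-class].
#' @param cfg an [MCMCConfig-class].
#' @param fix_lambda,fix_h optionally hold the reporting or harvest
#'   rate fixed at a value instead of sampling it (used for oracle
#'   checks and sensitivity analyses).
#' @param allow_empty permit a data-free run (all `N = 0`), in which
#'   case the posterior equals the prior; default FALSE errors with
#'   "no banded birds".
#' @param n_mode `"per_region"` (default) or `"global"`; see
#'   [logPosterior()].
#' @param N banded totals, only for the plain-matrix method.
#' @param band_type band-type label, only for the plain-matrix method.
#' @param ... passed through to the method.
#' @return A [PosteriorDraws-class].
#' @export
setGeneric("samplePosterior",
           function(mat, priors, cfg, ...) standardGeneric("samplePosterior"))

samplePosteriorImpl <- function(D, Nvec, band_type, regions, priors, cfg,
                                fix_lambda, fix_h, allow_empty, n_mode) {
  if (all(Nvec == 0) && !allow_empty)
    stop("no banded birds (all banded totals are zero); ",
         "pass allow_empty = TRUE for a prior-only run", call. = FALSE)
  if (cfg@nChains < 2L)
    warning("fewer than 2 chains: R-hat diagnostics unavailable")
  if (n_mode == "global") Nvec <- rep(sum(Nvec), length(Nvec))
  lam_ab <- lambdaPriorFor(priors, band_type)
  raw <- mcmcEngine(D, Nvec, priors@dirichletAlpha, lam_ab, priors@hPrior,
                    cfg, fix_lambda, fix_h, regions)
  draws <- new("PosteriorDraws", bandType = band_type, psi = raw$psi,
               lambda = raw$lambda, h = raw$h, regions = raw$regions,
               acceptance = raw$acceptance,
               rhat = NA_real_, converged = NA)
  rhat <- if (cfg@nChains >= 2L) gelmanRubin(draws) else NA_real_
  draws@rhat <- rhat
  conv <- if (all(is.na(rhat))) NA else all(rhat < cfg@rhatThreshold,
                                            na.rm = TRUE)
  draws@converged <- conv
  if (isFALSE(conv))
    warning("chains not converged for band type '", band_type,
            "': max R-hat = ", round(max(rhat, na.rm = TRUE), 3))
  draws
}

#' @rdname samplePosterior
#' @export
setMethod("samplePosterior", "RecoveryMatrix",
  function(mat, priors, cfg, fix_lambda = NULL, fix_h = NULL,
           allow_empty = FALSE, n_mode = c("per_region", "global")) {
    n_mode <- match.arg(n_mode)
    samplePosteriorImpl(mat@D, mat@N, mat@bandType, regionNames(),
                        priors, cfg, fix_lambda, fix_h, allow_empty, n_mode)
  })

#' @rdname samplePosterior
#' @export
setMethod("samplePosterior", "matrix",
  function(mat, priors, cfg, N, band_type, fix_lambda = NULL,
           fix_h = NULL, allow_empty = FALSE,
           n_mode = c("per_region", "global")) {
    n_mode <- match.arg(n_mode)
    stopifnot(nrow(mat) == ncol(mat), length(N) == nrow(mat))
    regions <- rownames(mat)
    if (is.null(regions)) regions <- paste0("r", seq_len(nrow(mat)))
    samplePosteriorImpl(mat, N, band_type, regions, priors, cfg,
                        fix_lambda, fix_h, allow_empty, n_mode)
  })

# classical potential scale reduction factor for one scalar across
# chains; x is [draw, chain]
psrfScalar <- function(x) {
  n <- nrow(x)
  mu <- colMeans(x)
  W <- mean(apply(x, 2L, stats::var))
  B_over_n <- stats::var(mu)
  if (!is.finite(W) || W < 1e-14)
    return(if (!is.finite(B_over_n) || B_over_n < 1e-14) 1 else Inf)
  # clamped at 1: with no between-chain spread the finite-sample
  # estimate dips below 1, which carries no diagnostic information
  max(1, sqrt(((n - 1) / n * W + B_over_n) / W))
}

#' Gelman-Rubin convergence diagnostic
#'
#' Potential scale reduction factor (R-hat) per scalar parameter: each
#' movement-matrix cell, the reporting rate and the harvest rate.
#' Values near 1 indicate the chains have mixed; by convention values
#' below 1.1 are accepted. Parameters held fixed during sampling (zero
#' variance everywhere) report R-hat 1.
#'
#' @param draws a [PosteriorDraws-class] with at least 2 chains and 10
#'   retained draws per chain.
#' @return named numeric vector of R-hat values (`Psi[i,j]` cells, then
#'   `lambda` and `h`).
#' @export
gelmanRubin <- function(draws) {
  stopifnot(is(draws, "PosteriorDraws"))
  d <- dim(draws@psi)
  if (d[2] < 2L) stop("need at least 2 chains for R-hat", call. = FALSE)
  if (d[1] < 10L) stop("need at least 10 retained draws per chain",
                       call. = FALSE)
  cells <- vapply(seq_len(d[3]), function(j) psrfScalar(draws@psi[, , j]),
                  numeric(1))
  names(cells) <- dimnames(draws@psi)[[3]]
  c(cells, lambda = psrfScalar(draws@lambda), h = psrfScalar(draws@h))
}
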