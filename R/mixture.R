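#' EM / fitting configuration
#'
#' Control knobs for the per-variant binomial mixture fits. Defaults: 8
#' restarts (one deterministic data-driven start, one start at the degenerate
#' one-component solution -- which guarantees the nested-model inequality
#' logL_M1 >= logL_M0 -- and six seeded random starts), convergence when the
#' observed-data log-likelihood changes by less than \code{tol}, and cells
#' with depth below \code{min_dp} excluded from both the likelihood and the
#' BIC cell count.
#'
#' @param n_restarts number of EM initialisations per variant (>= 1).
#' @param max_iter maximum EM iterations per restart.
#' @param tol convergence tolerance on the log-likelihood.
#' @param rng_seed integer seed; per-variant restart draws come from a
#'   deterministic substream keyed on \code{rng_seed + variant index}, so
#'   results do not depend on evaluation order or batch composition.
#' @param min_dp minimum per-cell depth for a cell to enter a variant's
#'   likelihood (default 1: only zero-depth cells are excluded).
#' @param min_cells minimum number of usable cells for a variant to be fit;
#'   variants below this get a \code{-Inf} deltaBIC sentinel.
#' @return A list of class \code{"FitConfig"}.
#' @export
fitConfig <- function(n_restarts = 8L, max_iter = 500L, tol = 1e-6,
                      rng_seed = 1L, min_dp = 1L, min_cells = 5L) {
    stopifnot(n_restarts >= 1L, max_iter >= 1L, tol > 0)
    structure(list(n_restarts = as.integer(n_restarts),
                   max_iter = as.integer(max_iter),
                   tol = tol, rng_seed = as.integer(rng_seed),
                   min_dp = as.numeric(min_dp),
                   min_cells = as.integer(min_cells)),
              class = "FitConfig")
}

#' Binomial log probability mass
#'
#' log P(AD | DP, theta) for the binomial model, with the boundary
#' conventions 0 * log 0 = 0 so that theta = 0 gives probability 1 to AD = 0
#' and theta = 1 to AD = DP.
#'
#' @param ad,dp non-negative counts with \code{ad <= dp} (vectorised).
#' @param theta success rate in [0, 1] (scalar or vectorised).
#' @return Numeric log-probabilities.
#' @examples
#' binomLogpmf(5, 10, 0.5)   # log(0.24609375)
#' binomLogpmf(0, 10, 0)     # 0
#' @export
binomLogpmf <- function(ad, dp, theta) {
    if (any(ad < 0) || any(ad > dp))
        stop("require 0 <= ad <= dp")
    if (any(theta < 0) || any(theta > 1))
        stop("theta must lie in [0, 1]")
    n <- max(length(ad), length(dp), length(theta))
    ad <- rep_len(ad, n); dp <- rep_len(dp, n); theta <- rep_len(theta, n)
    out <- numeric(n)
    lo <- theta <= 0
    hi <- theta >= 1
    mid <- !lo & !hi
    out[lo] <- ifelse(ad[lo] == 0, 0, -Inf)
    out[hi] <- ifelse(ad[hi] == dp[hi], 0, -Inf)
    out[mid] <- lchoose(dp[mid], ad[mid]) + ad[mid] * log(theta[mid]) +
        (dp[mid] - ad[mid]) * log1p(-theta[mid])
    out
}

#' One-component binomial fit (closed form)
#'
#' The maximum-likelihood estimate of a single shared heteroplasmy level is
#' the pooled proportion \code{sum(AD) / sum(DP)}.
#'
#' @param ad,dp count vectors of equal length; \code{sum(dp)} must be > 0.
#' @return \code{list(theta = ..., logL = ...)}.
#' @export
fitOneComponent <- function(ad, dp) {
    stopifnot(length(ad) == length(dp))
    if (any(ad < 0) || any(ad > dp)) stop("require 0 <= ad <= dp")
    if (sum(dp) <= 0) stop("sum(dp) must be positive (no information)")
    theta <- sum(ad) / sum(dp)
    list(theta = theta, logL = sum(binomLogpmf(ad, dp, theta)))
}

## Vectorised Park-Miller (minstd) uniform substreams: one stream per
## variant, seeded deterministically at (rng_seed + variant index), so
## restart initialisations are independent of evaluation order.
.pmUniforms <- function(seeds, n_draws) {
    m <- 2147483647
    state <- (as.numeric(seeds) %% m)
    state[state == 0] <- 1
    u <- matrix(0, length(seeds), n_draws)
    for (k in seq_len(n_draws)) {
        state <- (16807 * state) %% m
        u[, k] <- state / m
    }
    u
}

## Restart initialisations: columns are restarts, rows variants.
## Restart 1: data-driven (pi = 0.1, theta0 = clipped pooled rate,
## theta1 = max per-cell AF). Restart 2: degenerate one-component solution.
## Restarts 3..R: random (pi ~ U(0.05, 0.5), theta0 ~ U(0, 0.05),
## theta1 ~ U(0.1, 1)).
.emInits <- function(AD, DP, used, config) {
    V <- nrow(AD)
    R <- config$n_restarts
    ADu <- AD * used
    DPu <- DP * used
    pooled <- rowSums(ADu) / pmax(rowSums(DPu), 1)
    af <- ifelse(DPu > 0, ADu / pmax(DPu, 1), 0)
    max_af <- apply(af, 1L, max)
    init_pi <- matrix(0.5, V, R)
    init_t0 <- matrix(0, V, R)
    init_t1 <- matrix(0, V, R)
    init_pi[, 1] <- 0.1
    init_t0[, 1] <- pmin(pmax(pooled, 1e-4), 0.5)
    init_t1[, 1] <- pmax(max_af, 0.01)
    init_pi[, 2] <- 0.5
    init_t0[, 2] <- pooled
    init_t1[, 2] <- pooled
    if (R > 2) {
        nr <- R - 2L
        u <- .pmUniforms(config$rng_seed + seq_len(V), 3L * nr)
        for (r in seq_len(nr)) {
            init_pi[, 2 + r] <- 0.05 + 0.45 * u[, 3 * r - 2]
            init_t0[, 2 + r] <- 0.05 * u[, 3 * r - 1]
            init_t1[, 2 + r] <- 0.1 + 0.9 * u[, 3 * r]
        }
    }
    list(pi = init_pi, t0 = init_t0, t1 = init_t1)
}

#' Two-component binomial mixture fit for one variant (EM)
#'
#' Maximises the two-component binomial mixture likelihood over multiple
#' restarts by expectation-maximisation. Components are relabelled so that
#' \code{theta1 >= theta0}; \code{pi} is the mixing weight of the
#' high-heteroplasmy component.
#'
#' @param ad,dp count vectors for one variant across cells.
#' @param config a \code{\link{fitConfig}}.
#' @param variant_index index used to derive this variant's restart
#'   substream (keeps single-variant fits identical to the same variant
#'   inside a batch fit).
#' @param trace if TRUE, also return per-restart log-likelihood traces
#'   (each non-decreasing across iterations).
#' @return \code{list(theta0, theta1, pi, logL, n_cells_used, trace)}.
#' @export
fitTwoComponentEM <- function(ad, dp, config = fitConfig(),
                              variant_index = 1L, trace = FALSE) {
    stopifnot(length(ad) == length(dp))
    if (any(ad < 0) || any(ad > dp)) stop("require 0 <= ad <= dp")
    if (sum(dp) <= 0) stop("all depths are zero")
    AD <- matrix(as.numeric(ad), 1L)
    DP <- matrix(as.numeric(dp), 1L)
    used <- DP >= config$min_dp & DP > 0
    inits <- .emInits(AD, DP, used, .shiftSeed(config, variant_index))
    fit <- em_batch_cpp(AD, DP, inits$pi, inits$t0, inits$t1,
                        config$tol, config$max_iter, config$min_dp,
                        keep_trace = trace)
    out <- list(theta0 = fit$theta0[1], theta1 = fit$theta1[1],
                pi = fit$pi[1], logL = fit$logL_M1[1],
                n_cells_used = fit$n_cells_used[1])
    if (trace) out$trace <- fit$trace[[1L]]
    out
}

## Re-key a config so variant 1 of a sub-problem uses the substream of
## variant `index` of the full problem.
.shiftSeed <- function(config, index) {
    config$rng_seed <- config$rng_seed + as.integer(index) - 1L
    config
}

#' deltaBIC for a single variant
#'
#' Fits both the one-component model (M0, one parameter) and the
#' two-component mixture (M1, three parameters) and returns the BIC
#' difference \code{deltaBIC = BIC(M0) - BIC(M1)} with
#' \code{BIC = n_parameters * log(n_cells) - 2 * log L} (natural log).
#' Higher deltaBIC means stronger evidence for across-cell heteroplasmy
#' heterogeneity, i.e. clonal informativeness.
#'
#' Unlike the batch fitter (which replaces the deltaBIC of unfittable
#' variants by a \code{-Inf} selection sentinel), this single-variant
#' operation always reports the raw BIC difference -- e.g. the penalty-only
#' value \code{-2 log(n)} when no alternative reads are present.
#'
#' @inheritParams fitTwoComponentEM
#' @return A one-row \code{DataFrame} with the columns documented in
#'   \code{\link{fitDeltaBIC}}.
#' @export
deltaBIC <- function(ad, dp, config = fitConfig(), variant_index = 1L) {
    mc <- MitoCounts(matrix(as.numeric(ad), 1L),
                     matrix(as.numeric(dp), 1L),
                     data.frame(position = 1L, ref = "A", alt = "G"))
    out <- fitDeltaBIC(mc, .shiftSeed(config, variant_index))
    out$delta_bic <- out$bic_M0 - out$bic_M1
    out
}

#' Fit the binomial mixture to every variant and compute deltaBIC
#'
#' For each variant the one-component binomial model and the two-component
#' binomial mixture are fit on the cells with depth >= \code{min_dp}, and
#' variants are scored by \code{deltaBIC = BIC(M0) - BIC(M1)}. Variants that
#' cannot be fit (fewer than \code{min_cells} usable cells, or no
#' alternative reads at all) keep their row -- index alignment is preserved
#' -- with a \code{-Inf} deltaBIC sentinel and an explanatory flag.
#'
#' @param mc a \linkS4class{MitoCounts}.
#' @param config a \code{\link{fitConfig}}.
#' @return A \code{DataFrame}, one row per variant (rownames = variant ids):
#'   \code{variant_id}, \code{n_cells_used}, \code{theta0}, \code{theta1},
#'   \code{pi}, \code{logL_M0}, \code{logL_M1}, \code{bic_M0},
#'   \code{bic_M1}, \code{delta_bic}, \code{flag} (\code{"ok"},
#'   \code{"low_coverage"} or \code{"no_alt"}).
#' @examples
#' sim <- simulateClones(simConfig(variants_per_clone = 2, noise_sites = 50,
#'                                 per_base_error = 0))
#' fits <- fitDeltaBIC(simCounts(sim))
#' head(fits[order(-fits$delta_bic), ])
#' @export
fitDeltaBIC <- function(mc, config = fitConfig()) {
    AD <- adCounts(mc)
    DP <- dpCounts(mc)
    V <- nrow(AD)
    used <- DP >= config$min_dp & DP > 0
    inits <- .emInits(AD, DP, used, config)
    fit <- em_batch_cpp(AD, DP, inits$pi, inits$t0, inits$t1,
                        config$tol, config$max_iter, config$min_dp,
                        keep_trace = FALSE)
    n_used <- fit$n_cells_used
    logL0 <- fit$logL_M0
    logL1 <- fit$logL_M1
    bic0 <- 1 * log(n_used) - 2 * logL0
    bic1 <- 3 * log(n_used) - 2 * logL1
    dbic <- bic0 - bic1
    total_ad <- rowSums(AD * used)
    flag <- rep("ok", V)
    flag[total_ad == 0] <- "no_alt"
    flag[n_used < config$min_cells] <- "low_coverage"
    dbic[flag != "ok"] <- -Inf
    out <- S4Vectors::DataFrame(
        variant_id = variantIds(mc),
        n_cells_used = n_used,
        theta0 = fit$theta0, theta1 = fit$theta1, pi = fit$pi,
        logL_M0 = logL0, logL_M1 = logL1,
        bic_M0 = bic0, bic_M1 = bic1,
        delta_bic = dbic, flag = flag,
        row.names = variantIds(mc))
    S4Vectors::metadata(out) <- list(config = config)
    out
}

#' Write a per-variant deltaBIC table as TSV
#'
#' @param fits table from \code{\link{fitDeltaBIC}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeDeltaBIC <- function(fits, path) {
    write.table(as.data.frame(fits), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}
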