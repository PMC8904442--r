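## Clone assignment: maximum-likelihood EM for a binomial mixture over
## cells. P(cell j | clone k) = prod_v Binom(AD_vj | DP_vj, af_vk); cells
## with zero depth at a variant contribute a factor of 1 there. This is a
## deliberately simple maximum-likelihood counterpart of the variational
## clustering stage usually run downstream; it makes the pipeline testable
## end-to-end.

.cloneEStep <- function(AD, DP, af, w, lch_cell) {
    af <- pmin(pmax(af, 1e-9), 1 - 1e-9)
    ll_ck <- crossprod(AD, log(af)) + crossprod(DP - AD, log1p(-af))
    ll_ck <- sweep(ll_ck, 2L, log(w), "+")
    m <- apply(ll_ck, 1L, max)
    post <- exp(ll_ck - m)
    rs <- rowSums(post)
    list(post = post / rs, logL = sum(m + log(rs)) + sum(lch_cell))
}

#' Assign cells to K clones from selected variants
#'
#' Fits, by EM with restarts, a K-component mixture in which each clone k
#' has its own per-variant heteroplasmy \code{af[v, k]} and each cell's
#' allele counts are independent binomials given its clone. Deterministic
#' under the configured seed. For \code{K = 1} the closed-form pooled fit is
#' returned.
#'
#' @param mc a \linkS4class{MitoCounts} restricted to the selected variants.
#' @param K number of clones (\code{1 <= K <= n_cells}).
#' @param config a \code{\link{fitConfig}} (restarts, tolerance, seed).
#' @return A \linkS4class{CloneAssignment}.
#' @examples
#' ad <- rbind(c(0, 0, 9, 10), c(8, 10, 0, 0))
#' dp <- matrix(10, 2, 4)
#' mc <- MitoCounts(ad, dp, data.frame(position = c(5L, 9L), ref = "A",
#'                                     alt = "C"))
#' ca <- fitClones(mc, K = 2)
#' hardAssign(ca)
#' @export
fitClones <- function(mc, K, config = fitConfig()) {
    if (nrow(mc) < 1L) stop("empty variant set: nothing to cluster on")
    K <- as.integer(K)
    N <- ncol(mc)
    if (K < 1L) stop("K must be >= 1")
    if (K > N) stop("K exceeds the number of cells")
    AD <- adCounts(mc)
    DP <- dpCounts(mc)
    lch_cell <- colSums(matrix(lchoose(DP, AD), nrow(mc)))

    if (K == 1L) {
        af <- rowSums(AD) / pmax(rowSums(DP), 1)
        es <- .cloneEStep(AD, DP, matrix(af, ncol = 1L), 1, lch_cell)
        return(new("CloneAssignment",
                   prob = matrix(1, N, 1L,
                                 dimnames = list(colnames(mc), "clone1")),
                   cloneAF = matrix(pmin(pmax(af, 0), 1), ncol = 1L,
                                    dimnames = list(rownames(mc), "clone1")),
                   weights = 1, logL = es$logL, nClones = 1L))
    }

    best <- NULL
    withr::with_seed(config$rng_seed, {
        for (r in seq_len(config$n_restarts)) {
            ## random soft seeding of cells to clones
            post <- matrix(rexp(N * K), N, K)
            post <- post / rowSums(post)
            w <- rep(1 / K, K)
            af <- matrix(0.5, nrow(mc), K)
            logL <- -Inf
            for (it in seq_len(config$max_iter)) {
                ## M-step from current posteriors
                denom <- DP %*% post
                af <- ifelse(denom > 0, (AD %*% post) / pmax(denom, 1e-12),
                             af)
                w <- pmax(colMeans(post), 1e-12)
                w <- w / sum(w)
                es <- .cloneEStep(AD, DP, af, w, lch_cell)
                post <- es$post
                if (is.finite(logL) && abs(es$logL - logL) < config$tol) {
                    logL <- es$logL
                    break
                }
                logL <- es$logL
            }
            if (is.null(best) || logL > best$logL)
                best <- list(post = post, af = af, w = w, logL = logL)
        }
    })
    dimnames(best$post) <- list(colnames(mc), paste0("clone", seq_len(K)))
    dimnames(best$af) <- list(rownames(mc), paste0("clone", seq_len(K)))
    new("CloneAssignment", prob = best$post,
        cloneAF = pmin(pmax(best$af, 0), 1),
        weights = best$w, logL = best$logL, nClones = K)
}

#' Choose the number of clones by BIC
#'
#' Fits the clone model for each K in \code{k_range} and returns the K
#' minimising \code{BIC = (K * n_variants + K - 1) * log(n_cells) - 2 logL}
#' (heteroplasmy matrix plus free mixture weights). Ties within 1e-9 go to
#' the smaller K (parsimony).
#'
#' @param mc a \linkS4class{MitoCounts} of selected variants.
#' @param k_range candidate clone counts.
#' @param config a \code{\link{fitConfig}}.
#' @return A list: \code{K} (chosen), \code{bic} (named numeric over
#'   \code{k_range}), \code{fits} (list of \linkS4class{CloneAssignment}).
#' @export
pickK <- function(mc, k_range = 1:6, config = fitConfig()) {
    k_range <- sort(unique(as.integer(k_range)))
    stopifnot(length(k_range) >= 1L)
    V <- nrow(mc)
    N <- ncol(mc)
    fits <- lapply(k_range, function(k) fitClones(mc, k, config))
    bic <- vapply(seq_along(k_range), function(i) {
        k <- k_range[i]
        (k * V + k - 1) * log(N) - 2 * fits[[i]]@logL
    }, 0)
    names(bic) <- k_range
    best <- which(bic <= min(bic) + 1e-9)[1L]   # tie -> smaller K
    list(K = k_range[best], bic = bic, fits = setNames(fits, k_range))
}

#' Write clone assignment outputs as TSV
#'
#' Writes soft posterior probabilities with hardened labels
#' (\code{clone_assign.tsv}) and the per-clone heteroplasmy matrix
#' (\code{clone_af.tsv}).
#'
#' @param ca a \linkS4class{CloneAssignment}.
#' @param dir output directory.
#' @param prob_floor confidence floor for the hardened label column.
#' @return \code{dir}, invisibly.
#' @export
writeCloneAssignment <- function(ca, dir, prob_floor = 0.8) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    hard <- hardAssign(ca, prob_floor)
    soft <- as.data.frame(cloneProbs(ca))
    tab <- cbind(data.frame(cell = rownames(cloneProbs(ca))), soft,
                 data.frame(assigned_clone = ifelse(is.na(hard), "unassigned",
                                                    paste0("clone", hard))))
    write.table(tab, file.path(dir, "clone_assign.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    afd <- cbind(data.frame(variant_id = rownames(cloneAF(ca))),
                 as.data.frame(cloneAF(ca)))
    write.table(afd, file.path(dir, "clone_af.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    invisible(dir)
}
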