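#' RankingEval: PR/ROC evaluation of a variant ranking
#'
#' Result of \code{\link{prRoc}}: precision, recall and false-positive-rate
#' arrays over the threshold sweep, with the areas under the
#' precision-recall curve (step interpolation) and the ROC curve
#' (trapezoid).
#'
#' @slot thresholds unique score thresholds, descending.
#' @slot precision,recall,fpr numeric arrays aligned with
#'   \code{thresholds}.
#' @slot auprc,auroc areas under the PR and ROC curves.
#' @aliases RankingEval-class
#' @exportClass RankingEval
setClass("RankingEval", representation(
    thresholds = "numeric",
    precision = "numeric",
    recall = "numeric",
    fpr = "numeric",
    auprc = "numeric",
    auroc = "numeric"))

setMethod("show", "RankingEval", function(object) {
    cat(sprintf("RankingEval: AUPRC = %.4f, AUROC = %.4f (%d thresholds)\n",
                object@auprc, object@auroc, length(object@thresholds)))
    invisible(NULL)
})

#' Precision-recall and ROC evaluation of a deltaBIC ranking
#'
#' Sweeps over the unique score values as thresholds (tied scores are
#' treated atomically; \code{-Inf} sentinels rank last). AUPRC uses
#' step-wise interpolation (precision held constant between recall steps,
#' avoiding the optimistic linear interpolation in PR space); AUROC uses the
#' trapezoid rule, equivalent to average-rank tie handling.
#'
#' @param scores numeric per-variant scores (higher = more clonal).
#' @param truth logical (or 0/1) ground-truth labels.
#' @return A \linkS4class{RankingEval}.
#' @examples
#' ev <- prRoc(c(4, 3, 2, 1), c(TRUE, FALSE, TRUE, FALSE))
#' ev@auroc  # 0.75
#' @export
prRoc <- function(scores, truth) {
    truth <- as.logical(truth)
    if (length(scores) != length(truth))
        stop("scores and truth must have equal length")
    if (anyNA(scores) || anyNA(truth)) stop("NA in scores or truth")
    P <- sum(truth)
    Ng <- sum(!truth)
    if (P == 0L || Ng == 0L)
        stop("truth must contain at least one positive and one negative")
    ord <- order(scores, decreasing = TRUE)
    s <- scores[ord]
    t <- truth[ord]
    grp_last <- which(diff(s) != 0)            # end of each tied block
    grp_last <- c(grp_last, length(s))
    tp <- cumsum(t)[grp_last]
    fp <- cumsum(!t)[grp_last]
    thresholds <- s[grp_last]
    precision <- tp / (tp + fp)
    recall <- tp / P
    fpr <- fp / Ng
    auprc <- sum(diff(c(0, recall)) * precision)
    auroc <- sum(diff(c(0, fpr)) * (c(0, utils::head(tp / P, -1)) +
                                    recall) / 2)
    new("RankingEval", thresholds = thresholds, precision = precision,
        recall = recall, fpr = fpr, auprc = auprc, auroc = auroc)
}

#' Precision and recall of the set selected at a fixed threshold
#'
#' Evaluates the selection \{score > threshold\} against the truth labels.
#' An empty selection has undefined precision, returned as \code{NaN}.
#'
#' @inheritParams prRoc
#' @param threshold the deltaBIC cutoff (selection is strictly greater).
#' @return Named numeric vector \code{c(precision, recall)}.
#' @export
operatingPoint <- function(scores, truth, threshold) {
    truth <- as.logical(truth)
    stopifnot(length(scores) == length(truth))
    sel <- !is.na(scores) & scores > threshold
    tp <- sum(sel & truth)
    c(precision = if (sum(sel)) tp / sum(sel) else NaN,
      recall = tp / sum(truth))
}

## Best one-to-one matching score between rows and columns of a
## contingency table: exhaustive over injections of the smaller dimension
## (cluster counts here are single digits).
.bestMatchSum <- function(C) {
    transposed <- nrow(C) > ncol(C)
    if (transposed) C <- t(C)
    r <- nrow(C)
    cols <- seq_len(ncol(C))
    if (r == 0L) return(0)
    if (r > 8L) stop("one-to-one matching supports at most 8 clusters")
    best <- 0
    rec <- function(row, used, acc) {
        if (row > r) {
            if (acc > best) best <<- acc
            return(invisible(NULL))
        }
        for (cc in cols[!used]) {
            used[cc] <- TRUE
            rec(row + 1L, used, acc + C[row, cc])
            used[cc] <- FALSE
        }
    }
    rec(1L, rep(FALSE, ncol(C)), 0)
    best
}

#' Concordance between clone assignments and reference labels
#'
#' Hardens the posterior assignment by maximum probability with a
#' confidence floor (cells below it are "unassigned" and excluded), builds
#' the confusion matrix of hardened clones against the reference labels,
#' and reports the concordance: the accuracy of the best one-to-one
#' clone-to-label matching (cluster indices are arbitrary, so an optimal
#' rectangular matching aligns them).
#'
#' @param assign a \linkS4class{CloneAssignment} or a cells x clones
#'   posterior matrix.
#' @param labels reference labels, one per cell.
#' @param prob_floor minimum posterior for a confident assignment.
#' @return A list: \code{confusion} (hardened clones x labels),
#'   \code{concordance}, \code{n_assigned}, \code{frac_assigned}.
#' @export
cloneConcordance <- function(assign, labels, prob_floor = 0.8) {
    prob <- if (is(assign, "CloneAssignment")) cloneProbs(assign) else
        as.matrix(assign)
    if (nrow(prob) != length(labels))
        stop("labels must align with the cells of the assignment")
    K <- ncol(prob)
    hard <- max.col(prob, ties.method = "first")
    conf <- apply(prob, 1L, max) >= prob_floor
    labels <- factor(labels)
    conf_mat <- table(factor(hard[conf], levels = seq_len(K)),
                      labels[conf], dnn = c("clone", "label"))
    n_assigned <- sum(conf)
    concordance <- if (n_assigned)
        .bestMatchSum(unclass(conf_mat)) / n_assigned else NaN
    list(confusion = conf_mat, concordance = concordance,
         n_assigned = n_assigned,
         frac_assigned = n_assigned / length(labels))
}
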