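#' MitoCounts: paired AD/DP allele count matrices for single cells
#'
#' Container for per-variant, per-cell mitochondrial allele counts: an
#' alternative-allele depth matrix (\code{AD}) and a total depth matrix
#' (\code{DP}) of identical shape (variants x cells), carried inside a
#' \linkS4class{SummarizedExperiment} whose \code{rowData} records the variant
#' position, reference and alternative allele on the rCRS mitochondrial
#' genome. Rows are never reordered by any operation in this package, so
#' downstream indices always refer to reader/constructor order.
#'
#' @slot .
#'   Inherits all slots from \linkS4class{SummarizedExperiment}; assays are
#'   \code{AD} and \code{DP}.
#'
#' @seealso \code{\link{MitoCounts}} (constructor), \code{\link{readCellSNP}}
#' @aliases MitoCounts-class
#' @exportClass MitoCounts
setClass("MitoCounts", contains = "SummarizedExperiment")

.validMitoCounts <- function(object) {
    msg <- character()
    an <- SummarizedExperiment::assayNames(object)
    if (!all(c("AD", "DP") %in% an))
        return("assays must contain 'AD' and 'DP'")
    AD <- SummarizedExperiment::assay(object, "AD")
    DP <- SummarizedExperiment::assay(object, "DP")
    if (!identical(dim(AD), dim(DP)))
        msg <- c(msg, "AD and DP must have identical dimensions")
    if (length(AD)) {
        if (any(AD < 0, na.rm = TRUE))
            msg <- c(msg, "AD contains negative counts")
        bad <- which(AD > DP)
        if (length(bad)) {
            i <- arrayInd(bad[1L], dim(AD))
            msg <- c(msg, sprintf(
                "AD > DP at variant %d ('%s'), cell %d ('%s')",
                i[1L], rownames(AD)[i[1L]] %||% "?",
                i[2L], colnames(AD)[i[2L]] %||% "?"))
        }
    }
    rd <- SummarizedExperiment::rowData(object)
    need <- c("position", "ref", "alt", "id")
    if (!all(need %in% colnames(rd)))
        return(c(msg, sprintf("rowData must contain columns: %s",
                              paste(need, collapse = ", "))))
    if (nrow(rd)) {
        if (any(rd$position < 1L | rd$position > RCRS_LENGTH))
            msg <- c(msg, sprintf("variant positions must lie in [1, %d]",
                                  RCRS_LENGTH))
        if (!all(rd$ref %in% DNA_BASES) || !all(rd$alt %in% DNA_BASES))
            msg <- c(msg, "ref and alt alleles must be single bases A/C/G/T")
        if (any(rd$ref == rd$alt))
            msg <- c(msg, "ref and alt alleles must differ")
    }
    if (length(msg)) msg else TRUE
}

setValidity("MitoCounts", .validMitoCounts)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a MitoCounts object
#'
#' @param AD,DP integer matrices (variants x cells) of alternative-allele and
#'   total depths; \code{0 <= AD <= DP} entry-wise.
#' @param variants a \code{data.frame} (or \code{DataFrame}) with columns
#'   \code{position} (1-based rCRS coordinate), \code{ref} and \code{alt}
#'   (single bases); an \code{id} column of the form \code{"7207G>A"} is
#'   derived if absent.
#' @param cells character vector of cell barcodes (defaults to the column
#'   names of \code{AD}, or \code{cell1..cellN}).
#' @return A \linkS4class{MitoCounts} object.
#' @examples
#' ad <- matrix(c(0, 5, 0, 2, 8, 0), nrow = 3)
#' dp <- matrix(10, 3, 2)
#' v <- data.frame(position = c(100L, 200L, 300L), ref = "A", alt = "G")
#' mc <- MitoCounts(ad, dp, v)
#' @export
MitoCounts <- function(AD, DP, variants, cells = NULL) {
    AD <- as.matrix(AD)
    DP <- as.matrix(DP)
    storage.mode(AD) <- "double"
    storage.mode(DP) <- "double"
    variants <- as.data.frame(variants)
    if (!all(c("position", "ref", "alt") %in% colnames(variants)))
        stop("'variants' needs columns position, ref, alt")
    variants$position <- as.integer(variants$position)
    if (is.null(variants$id))
        variants$id <- variantId(variants$position, variants$ref, variants$alt)
    if (nrow(variants) != nrow(AD))
        stop("number of variants does not match nrow(AD)")
    if (is.null(cells))
        cells <- colnames(AD) %||% paste0("cell", seq_len(ncol(AD)))
    if (length(cells) != ncol(AD))
        stop("number of cells does not match ncol(AD)")
    dimnames(AD) <- dimnames(DP) <- list(variants$id, cells)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(AD = AD, DP = DP),
        rowData = S4Vectors::DataFrame(variants))
    new("MitoCounts", se)
}

#' Variant identifier strings
#'
#' Builds the conventional \code{"{pos}{ref}>{alt}"} label (e.g.
#' \code{"7207G>A"}) used throughout for mitochondrial variants.
#'
#' @param position integer 1-based rCRS positions.
#' @param ref,alt single-base alleles.
#' @return Character vector of labels.
#' @export
variantId <- function(position, ref, alt) {
    paste0(position, ref, ">", alt)
}

#' @describeIn MitoCounts alternative-allele count matrix.
#' @param x,object a \code{MitoCounts} object.
#' @export
adCounts <- function(x) SummarizedExperiment::assay(x, "AD")

#' @describeIn MitoCounts total depth matrix.
#' @export
dpCounts <- function(x) SummarizedExperiment::assay(x, "DP")

#' @describeIn MitoCounts variant metadata (position, ref, alt, id).
#' @export
variantInfo <- function(x) SummarizedExperiment::rowData(x)

#' @describeIn MitoCounts variant id labels.
#' @export
variantIds <- function(x) SummarizedExperiment::rowData(x)$id

#' @describeIn MitoCounts cell barcodes.
#' @export
cellBarcodes <- function(x) colnames(x)

setMethod("show", "MitoCounts", function(object) {
    cat(sprintf("MitoCounts: %d variants x %d cells\n",
                nrow(object), ncol(object)))
    dp <- dpCounts(object)
    if (length(dp))
        cat(sprintf("  mean depth %.1f; nonzero AD entries %d\n",
                    mean(dp), sum(adCounts(object) > 0)))
    invisible(NULL)
})

#' KneeResult: automatic deltaBIC cutoff
#'
#' Result of \code{\link{findKnee}}: the ascending-sorted deltaBIC values,
#' the min-max normalised cumulative curve on which the knee was located,
#' the knee index/threshold, and the per-variant selection mask (variants
#' with deltaBIC strictly greater than the threshold).
#'
#' @slot sortedValues numeric, finite deltaBIC values in ascending order.
#' @slot xNorm,yNorm numeric, normalised curve coordinates in [0, 1].
#' @slot kneeIndex integer index into \code{sortedValues} (NA under fallback).
#' @slot threshold numeric deltaBIC cutoff.
#' @slot selectedMask logical per input value (original order).
#' @slot usedFallback logical, TRUE when no knee could be located and the
#'   \code{deltaBIC > 0} fallback rule was applied.
#' @aliases KneeResult-class
#' @exportClass KneeResult
setClass("KneeResult", representation(
    sortedValues = "numeric",
    xNorm = "numeric",
    yNorm = "numeric",
    kneeIndex = "integer",
    threshold = "numeric",
    selectedMask = "logical",
    usedFallback = "logical"))

setValidity("KneeResult", function(object) {
    msg <- character()
    if (is.unsorted(object@sortedValues))
        msg <- c(msg, "sortedValues must be non-decreasing")
    if (!object@usedFallback && !is.na(object@kneeIndex)) {
        if (object@threshold != object@sortedValues[object@kneeIndex])
            msg <- c(msg, "threshold must equal sortedValues[kneeIndex]")
    }
    if (length(msg)) msg else TRUE
})

#' @describeIn KneeResult the deltaBIC cutoff.
#' @param x,object a \code{KneeResult}.
#' @export
kneeThreshold <- function(x) x@threshold

#' @describeIn KneeResult logical selection mask in original variant order.
#' @export
selectedMask <- function(x) x@selectedMask

setMethod("show", "KneeResult", function(object) {
    cat(sprintf(
        "KneeResult: threshold %.4g; %d / %d variants selected%s\n",
        object@threshold, sum(object@selectedMask),
        length(object@selectedMask),
        if (object@usedFallback) " (fallback: deltaBIC > 0)" else ""))
    invisible(NULL)
})

#' CloneAssignment: posterior clone memberships for cells
#'
#' Result of \code{\link{fitClones}}: per-cell posterior probabilities over
#' clones, the per-clone heteroplasmy (allele frequency) estimates for each
#' variant, clone weights and the maximised log-likelihood.
#'
#' @slot prob numeric matrix, cells x clones; rows sum to 1.
#' @slot cloneAF numeric matrix, variants x clones, entries in [0, 1].
#' @slot weights numeric clone mixing proportions.
#' @slot logL numeric maximised log-likelihood.
#' @slot nClones integer number of clones K.
#' @aliases CloneAssignment-class
#' @exportClass CloneAssignment
setClass("CloneAssignment", representation(
    prob = "matrix",
    cloneAF = "matrix",
    weights = "numeric",
    logL = "numeric",
    nClones = "integer"))

setValidity("CloneAssignment", function(object) {
    msg <- character()
    if (ncol(object@prob) != object@nClones)
        msg <- c(msg, "prob must have nClones columns")
    if (nrow(object@prob) &&
        any(abs(rowSums(object@prob) - 1) > 1e-8))
        msg <- c(msg, "rows of prob must sum to 1")
    if (length(object@cloneAF) &&
        (any(object@cloneAF < 0) || any(object@cloneAF > 1)))
        msg <- c(msg, "cloneAF entries must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' @describeIn CloneAssignment cells x clones posterior matrix.
#' @param x,object a \code{CloneAssignment}.
#' @export
cloneProbs <- function(x) x@prob

#' @describeIn CloneAssignment variants x clones heteroplasmy matrix.
#' @export
cloneAF <- function(x) x@cloneAF

#' @describeIn CloneAssignment hardened clone labels; cells whose maximum
#'   posterior is below \code{prob_floor} are \code{NA} ("unassigned").
#' @param prob_floor minimum posterior probability for a confident call.
#' @export
hardAssign <- function(x, prob_floor = 0.8) {
    lab <- max.col(x@prob, ties.method = "first")
    lab[apply(x@prob, 1L, max) < prob_floor] <- NA_integer_
    setNames(lab, rownames(x@prob))
}

setMethod("show", "CloneAssignment", function(object) {
    cat(sprintf("CloneAssignment: %d cells x %d clones, logL = %.2f\n",
                nrow(object@prob), object@nClones, object@logL))
    hl <- hardAssign(object)
    cat(sprintf("  confidently assigned (p > 0.8): %d / %d cells\n",
                sum(!is.na(hl)), length(hl)))
    invisible(NULL)
})

#' MitoSimulation: synthetic clonal dataset with ground truth
#'
#' Output of \code{\link{simulateClones}}: the candidate-variant
#' \linkS4class{MitoCounts} matrix presented to the caller (all sites with at
#' least one alternative read in at least one cell), aligned truth labels,
#' the per-cell clone assignment and the generating configuration.
#'
#' @slot counts a \linkS4class{MitoCounts} of candidate variants.
#' @slot truth \code{DataFrame}, one row per candidate variant: \code{id},
#'   \code{position}, \code{ref}, \code{alt}, \code{class} (one of
#'   \code{"clonal"}, \code{"noise"}, \code{"error"}), \code{isClonal}, and
#'   \code{expectedAF} (variants x clones matrix of planted allele
#'   frequencies; 0 for non-carrier clones).
#' @slot cloneOfCell integer clone label per cell (1..n_clones).
#' @slot cloneVariants list of character vectors: planted variant ids carried
#'   by each clone.
#' @slot config the \code{\link{simConfig}} list used.
#' @aliases MitoSimulation-class
#' @exportClass MitoSimulation
setClass("MitoSimulation", representation(
    counts = "MitoCounts",
    truth = "DataFrame",
    cloneOfCell = "integer",
    cloneVariants = "list",
    config = "list"))

#' @describeIn MitoSimulation candidate-variant count matrix.
#' @param x,object a \code{MitoSimulation}.
#' @export
simCounts <- function(x) x@counts

#' @describeIn MitoSimulation aligned truth table.
#' @export
simTruth <- function(x) x@truth

#' @describeIn MitoSimulation clone label per cell.
#' @export
cloneLabels <- function(x) x@cloneOfCell

setMethod("show", "MitoSimulation", function(object) {
    cat(sprintf(
        "MitoSimulation: %d candidate variants x %d cells (%d clonal, %d clones)\n",
        nrow(object@counts), ncol(object@counts),
        sum(object@truth$isClonal), length(object@cloneVariants)))
    invisible(NULL)
})
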