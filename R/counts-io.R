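## cellSNP-lite style I/O: sparse AD/DP MatrixMarket matrices with a VCF of
## variant sites and a one-barcode-per-line samples file.

CELLSNP_FILES <- c(AD = "cellSNP.tag.AD.mtx", DP = "cellSNP.tag.DP.mtx",
                   VCF = "cellSNP.base.vcf", SAMPLES = "cellSNP.samples.tsv")

#' Read a cellSNP-lite output directory
#'
#' Reads the paired sparse AD/DP matrices (\code{cellSNP.tag.AD.mtx},
#' \code{cellSNP.tag.DP.mtx}) together with the variant VCF
#' (\code{cellSNP.base.vcf} or \code{.vcf.gz}; only CHROM/POS/REF/ALT are
#' consumed) and the cell barcode file (\code{cellSNP.samples.tsv}). Rows are
#' aligned to VCF record order and columns to barcode order; entries missing
#' from the sparse files are zeros.
#'
#' @param dir path to a cellSNP-lite output directory.
#' @return A \linkS4class{MitoCounts} object.
#' @examples
#' sim <- simulateClones(simConfig(variants_per_clone = 2, noise_sites = 20))
#' d <- tempfile(); writeCellSNP(simCounts(sim), d)
#' mc <- readCellSNP(d)
#' @export
readCellSNP <- function(dir) {
    if (!dir.exists(dir))
        stop("directory not found: ", dir)
    pth <- function(f) file.path(dir, f)
    for (f in CELLSNP_FILES[c("AD", "DP", "SAMPLES")])
        if (!file.exists(pth(f)))
            stop("missing file in cellSNP directory: ", f)
    vcf_path <- pth(CELLSNP_FILES[["VCF"]])
    if (!file.exists(vcf_path)) vcf_path <- paste0(vcf_path, ".gz")
    if (!file.exists(vcf_path))
        stop("missing file in cellSNP directory: cellSNP.base.vcf(.gz)")

    AD <- as.matrix(Matrix::readMM(pth(CELLSNP_FILES[["AD"]])))
    DP <- as.matrix(Matrix::readMM(pth(CELLSNP_FILES[["DP"]])))
    cells <- readLines(pth(CELLSNP_FILES[["SAMPLES"]]))
    cells <- cells[nzchar(cells)]
    variants <- .readSitesVcf(vcf_path)

    if (!identical(dim(AD), dim(DP)))
        stop(sprintf("AD matrix is %dx%d but DP matrix is %dx%d (%s vs %s)",
                     nrow(AD), ncol(AD), nrow(DP), ncol(DP),
                     CELLSNP_FILES[["AD"]], CELLSNP_FILES[["DP"]]))
    if (nrow(AD) != nrow(variants))
        stop(sprintf("%s has %d rows but %s lists %d variants",
                     CELLSNP_FILES[["AD"]], nrow(AD),
                     basename(vcf_path), nrow(variants)))
    if (ncol(AD) != length(cells))
        stop(sprintf("%s has %d columns but %s lists %d barcodes",
                     CELLSNP_FILES[["AD"]], ncol(AD),
                     CELLSNP_FILES[["SAMPLES"]], length(cells)))
    MitoCounts(AD, DP, variants, cells)
}

## Minimal site-list VCF reader: CHROM/POS/REF/ALT of a records-only VCF.
## Uses vcfR when there is at least one record; a header-only file yields an
## empty variant table.
.readSitesVcf <- function(path) {
    lines <- readLines(path)
    body <- lines[!startsWith(lines, "#") & nzchar(lines)]
    if (!length(body)) {
        return(data.frame(position = integer(), ref = character(),
                          alt = character(), id = character()))
    }
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    fix <- matrix(fix, ncol = ncol(fix), dimnames = dimnames(fix))
    pos <- as.integer(fix[, "POS"])
    ref <- toupper(fix[, "REF"])
    alt <- toupper(fix[, "ALT"])
    if (any(grepl(",", alt, fixed = TRUE)))
        stop("multi-allelic ALT records found in ", basename(path),
             "; cellSNP-lite writes one row per alternative allele")
    data.frame(position = pos, ref = ref, alt = alt,
               id = variantId(pos, ref, alt))
}

.writeSitesVcf <- function(variants, path, chrom = "chrM") {
    header <- c("##fileformat=VCFv4.2",
                sprintf("##contig=<ID=%s,length=%d>", chrom, RCRS_LENGTH),
                paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", sep = "\t"))
    rows <- character(0)
    if (nrow(variants))
        rows <- paste(chrom, variants$position, variants$id, variants$ref,
                      variants$alt, ".", "PASS", ".", sep = "\t")
    writeLines(c(header, rows), path)
}

#' Write a MitoCounts object in cellSNP-lite layout
#'
#' Writes \code{cellSNP.tag.AD.mtx}, \code{cellSNP.tag.DP.mtx},
#' \code{cellSNP.base.vcf} and \code{cellSNP.samples.tsv} into \code{dir},
#' re-readable with \code{\link{readCellSNP}}.
#'
#' @param mc a \linkS4class{MitoCounts}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeCellSNP <- function(mc, dir) {
    if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
        stop("cannot create output directory: ", dir)
    pth <- function(f) file.path(dir, f)
    Matrix::writeMM(methods::as(Matrix::Matrix(adCounts(mc), sparse = TRUE),
                                "generalMatrix"),
                    pth(CELLSNP_FILES[["AD"]]))
    Matrix::writeMM(methods::as(Matrix::Matrix(dpCounts(mc), sparse = TRUE),
                                "generalMatrix"),
                    pth(CELLSNP_FILES[["DP"]]))
    .writeSitesVcf(as.data.frame(variantInfo(mc)), pth(CELLSNP_FILES[["VCF"]]))
    writeLines(cellBarcodes(mc), pth(CELLSNP_FILES[["SAMPLES"]]))
    invisible(dir)
}

#' Error-prone rCRS regions excluded by default
#'
#' The three regions of the rCRS mitochondrial genome in which frequent
#' false-positive variant calls arise (positions 302-315, 513-525 and
#' 3105-3109), as 1-based inclusive intervals.
#'
#' @return An \code{\link[IRanges]{IRanges}} of the three intervals.
#' @export
defaultBlacklist <- function() {
    IRanges::IRanges(start = c(302L, 513L, 3105L),
                     end = c(315L, 525L, 3109L))
}

#' Remove variants falling in blacklisted regions
#'
#' Drops every variant whose position lies inside any of the given 1-based
#' inclusive intervals; order of the remaining variants is preserved and the
#' operation is idempotent. An empty result is legal.
#'
#' @param mc a \linkS4class{MitoCounts}.
#' @param regions an \code{\link[IRanges]{IRanges}} of 1-based inclusive
#'   intervals; defaults to \code{\link{defaultBlacklist}()}.
#' @return The filtered \linkS4class{MitoCounts}.
#' @export
applyBlacklist <- function(mc, regions = defaultBlacklist()) {
    if (length(regions) == 0L) return(mc)
    pos <- variantInfo(mc)$position
    hit <- IRanges::overlapsAny(IRanges::IRanges(pos, pos), regions)
    mc[!hit, ]
}

#' Write the selected variant subset plus a deltaBIC table
#'
#' Writes the AD/DP matrices restricted to \code{selected} (original relative
#' order preserved, cell order untouched) in cellSNP-lite layout, together
#' with \code{deltaBIC.tsv} giving each retained variant's label and fit
#' statistics when a fit table is supplied.
#'
#' @param mc a \linkS4class{MitoCounts}.
#' @param selected integer or logical index of variants to keep.
#' @param dir output directory.
#' @param fits optional per-variant fit table from \code{\link{fitDeltaBIC}}
#'   (aligned with \code{mc}); its rows for the selected variants are written
#'   to \code{deltaBIC.tsv}.
#' @return \code{dir}, invisibly.
#' @export
writeSelected <- function(mc, selected, dir, fits = NULL) {
    if (is.logical(selected)) {
        if (length(selected) != nrow(mc))
            stop("logical 'selected' must have one entry per variant")
        selected <- which(selected)
    }
    selected <- as.integer(selected)
    if (length(selected) && (min(selected) < 1L || max(selected) > nrow(mc)))
        stop("'selected' indices out of range")
    sub <- mc[selected, ]
    writeCellSNP(sub, dir)
    tab <- data.frame(variant_id = variantIds(sub))
    if (!is.null(fits)) {
        if (nrow(fits) != nrow(mc))
            stop("'fits' must be aligned with 'mc' (one row per variant)")
        tab <- as.data.frame(fits[selected, , drop = FALSE])
    }
    write.table(tab, file.path(dir, "deltaBIC.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    invisible(dir)
}
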