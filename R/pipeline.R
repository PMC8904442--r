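## End-to-end pipeline: read -> (blacklist) -> fit -> knee -> select ->
## (clones), with a run manifest, plus the command-line front end.

.stageMsg <- function(...) message("[mitomix] ", sprintf(...))

#' Run the full variant-selection pipeline
#'
#' Reads a cellSNP-lite directory (or takes a \linkS4class{MitoCounts}
#' directly), optionally removes blacklisted error-prone regions, fits the
#' per-variant binomial mixture, determines the deltaBIC cutoff at the knee
#' of the cumulative curve (or uses a fixed cutoff), writes the selected
#' variants, the deltaBIC table, a knee diagnostic and a JSON run manifest,
#' and optionally assigns cells to clones on the selected variants.
#'
#' @param cellsnp_dir input cellSNP-lite directory (ignored when
#'   \code{counts} is given).
#' @param out_dir output directory.
#' @param counts optional \linkS4class{MitoCounts} used instead of reading
#'   from disk.
#' @param min_dp,min_cells pre-filter knobs, see \code{\link{fitConfig}}.
#' @param blacklist apply \code{\link{defaultBlacklist}} first (default
#'   FALSE, matching generic input where the error-prone-region filter is
#'   opt-in).
#' @param deltabic_cutoff optional fixed deltaBIC cutoff bypassing the knee.
#' @param clones optional number of clones K; when given, clone assignment
#'   runs on the selected variants and its outputs are written too.
#' @param seed integer seed for the EM restart substreams.
#' @param plot write \code{knee.png} diagnostic (default TRUE).
#' @return Invisibly, a list: \code{counts}, \code{fits}, \code{knee},
#'   \code{selected} (integer indices into the fitted matrix),
#'   \code{assignment} (or NULL), \code{manifest}.
#' @export
runMitomix <- function(cellsnp_dir = NULL, out_dir, counts = NULL,
                       min_dp = 1, min_cells = 5, blacklist = FALSE,
                       deltabic_cutoff = NULL, clones = NULL, seed = 1L,
                       plot = TRUE) {
    if (is.null(counts)) {
        if (is.null(cellsnp_dir)) stop("need cellsnp_dir or counts")
        .stageMsg("reading %s", cellsnp_dir)
        counts <- readCellSNP(cellsnp_dir)
    }
    if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
        stop("cannot create output directory: ", out_dir)
    n_in <- nrow(counts)
    .stageMsg("input: %d variants x %d cells", n_in, ncol(counts))
    if (isTRUE(blacklist)) {
        counts <- applyBlacklist(counts)
        .stageMsg("blacklist filter: %d variants retained", nrow(counts))
    }
    config <- fitConfig(rng_seed = as.integer(seed), min_dp = min_dp,
                        min_cells = min_cells)
    fits <- fitDeltaBIC(counts, config)
    .stageMsg("fit %d variants (%d flagged)", nrow(fits),
              sum(fits$flag != "ok"))
    if (is.null(deltabic_cutoff)) {
        knee <- findKnee(fits$delta_bic)
        .stageMsg("knee threshold: deltaBIC > %.4g", kneeThreshold(knee))
    } else {
        knee <- NULL
        .stageMsg("fixed threshold: deltaBIC > %.4g", deltabic_cutoff)
    }
    sel_mask <- if (is.null(knee)) {
        is.finite(fits$delta_bic) & fits$delta_bic > deltabic_cutoff
    } else selectedMask(knee)
    selected <- which(sel_mask)
    .stageMsg("selected %d informative variants", length(selected))

    writeDeltaBIC(cbind(as.data.frame(fits),
                        selected = sel_mask),
                  file.path(out_dir, "deltaBIC.tsv"))
    writeSelected(counts, selected, file.path(out_dir, "passed"), fits)
    if (plot && !is.null(knee))
        plotKnee(knee, file.path(out_dir, "knee.png"))

    assignment <- NULL
    if (!is.null(clones) && length(selected)) {
        assignment <- fitClones(counts[selected, ], as.integer(clones),
                                config)
        writeCloneAssignment(assignment, out_dir)
        .stageMsg("assigned %d cells to %d clones",
                  sum(!is.na(hardAssign(assignment))), as.integer(clones))
    }

    manifest <- list(
        tool = "mitomix", version = as.character(packageVersion("mitomix")),
        created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
        seed = as.integer(seed),
        params = list(min_dp = min_dp, min_cells = min_cells,
                      blacklist = isTRUE(blacklist),
                      deltabic_cutoff = deltabic_cutoff,
                      clones = if (is.null(clones)) NULL else
                          as.integer(clones),
                      knee_threshold = if (is.null(knee)) NULL else
                          kneeThreshold(knee)),
        inputs = if (!is.null(cellsnp_dir)) .inputHashes(cellsnp_dir) else
            list(),
        counts = list(variants_in = n_in, variants_fit = nrow(fits),
                      variants_selected = length(selected),
                      cells = ncol(counts)),
        outputs = list(deltabic_tsv = "deltaBIC.tsv", passed_dir = "passed",
                       clone_assign = if (is.null(assignment)) NULL else
                           "clone_assign.tsv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null")
    invisible(list(counts = counts, fits = fits, knee = knee,
                   selected = selected, assignment = assignment,
                   manifest = manifest))
}

.inputHashes <- function(dir) {
    fs <- list.files(dir, full.names = TRUE)
    as.list(tools::md5sum(fs))
}

#' Simulate a dataset and write it to disk
#'
#' Convenience wrapper: \code{\link{simulateClones}} +
#' \code{\link{writeSimulation}}.
#'
#' @param out_dir output directory.
#' @param config a \code{\link{simConfig}}.
#' @return The \linkS4class{MitoSimulation}, invisibly.
#' @export
simulateToDir <- function(out_dir, config = simConfig()) {
    sim <- simulateClones(config)
    writeSimulation(sim, out_dir)
    .stageMsg("simulated %d candidate variants x %d cells -> %s",
              nrow(simCounts(sim)), ncol(simCounts(sim)), out_dir)
    invisible(sim)
}

#' Benchmark a deltaBIC table against a simulation truth table
#'
#' Joins a \code{deltaBIC.tsv} (from \code{\link{runMitomix}}) with a
#' \code{truth.tsv} (from \code{\link{writeSimulation}}) on variant id and
#' computes AUPRC/AUROC of the ranking plus the precision/recall of the
#' selected set.
#'
#' @param deltabic_tsv path to a deltaBIC table with columns
#'   \code{variant_id}, \code{delta_bic} and (optionally) \code{selected}.
#' @param truth_tsv path to a truth table with columns \code{id} and
#'   \code{isClonal}.
#' @param out_json optional path; metrics are written there as JSON.
#' @return A list of metrics.
#' @export
benchmarkRun <- function(deltabic_tsv, truth_tsv, out_json = NULL) {
    db <- read.table(deltabic_tsv, header = TRUE, sep = "\t")
    tr <- read.table(truth_tsv, header = TRUE, sep = "\t")
    m <- match(db$variant_id, tr$id)
    if (anyNA(m))
        stop("variants in the deltaBIC table are missing from the truth table")
    truth <- as.logical(tr$isClonal[m])
    ev <- prRoc(db$delta_bic, truth)
    metrics <- list(auprc = ev@auprc, auroc = ev@auroc,
                    n_variants = nrow(db), n_clonal = sum(truth))
    if (!is.null(db$selected)) {
        sel <- as.logical(db$selected)
        tp <- sum(sel & truth)
        metrics$precision <- if (sum(sel)) tp / sum(sel) else NaN
        metrics$recall <- tp / sum(truth)
        metrics$n_selected <- sum(sel)
    }
    if (!is.null(out_json))
        jsonlite::write_json(metrics, out_json, auto_unbox = TRUE,
                             digits = NA, pretty = TRUE)
    metrics
}

.cliStop <- function(...) {
    message("[mitomix] error: ", sprintf(...))
    1L
}

#' Command-line entry point
#'
#' Implements the \code{mitomix} command with subcommands \code{fit}
#' (pipeline on a cellSNP-lite directory), \code{simulate} (write a
#' synthetic dataset) and \code{benchmark} (score a run against simulation
#' truth). Installed as the \code{exec/mitomix} script; also callable
#' directly for testing. CLI results are identical to the library API under
#' the same inputs and seed.
#'
#' @param args character vector of command-line arguments
#'   (\code{commandArgs(trailingOnly = TRUE)}).
#' @return Integer exit status (0 on success), invisibly.
#' @export
mitomixCLI <- function(args = commandArgs(trailingOnly = TRUE)) {
    usage <- "usage: mitomix <fit|simulate|benchmark> [options]"
    if (!length(args)) {
        message(usage)
        return(invisible(1L))
    }
    sub <- args[1L]
    rest <- args[-1L]
    if (!requireNamespace("optparse", quietly = TRUE))
        stop("the CLI requires the 'optparse' package")
    status <- tryCatch(
        switch(sub,
               fit = .cliFit(rest),
               simulate = .cliSimulate(rest),
               benchmark = .cliBenchmark(rest),
               { message(usage); 1L }),
        error = function(e) .cliStop("%s", conditionMessage(e)))
    invisible(as.integer(status))
}

.cliFit <- function(args) {
    ol <- list(
        optparse::make_option("--cellsnp", type = "character"),
        optparse::make_option("--out", type = "character"),
        optparse::make_option("--min-dp", type = "double", default = 1,
                              dest = "min_dp"),
        optparse::make_option("--min-cells", type = "integer", default = 5L,
                              dest = "min_cells"),
        optparse::make_option("--blacklist", action = "store_true",
                              default = FALSE),
        optparse::make_option("--deltabic-cutoff", type = "double",
                              default = NA, dest = "deltabic_cutoff"),
        optparse::make_option("--clones", type = "integer", default = NA),
        optparse::make_option("--seed", type = "integer", default = 1L))
    op <- optparse::parse_args(optparse::OptionParser(option_list = ol),
                               args = args)
    if (is.null(op$cellsnp) || is.null(op$out))
        stop("fit requires --cellsnp and --out")
    runMitomix(cellsnp_dir = op$cellsnp, out_dir = op$out,
               min_dp = op$min_dp, min_cells = op$min_cells,
               blacklist = op$blacklist,
               deltabic_cutoff = if (is.na(op$deltabic_cutoff)) NULL else
                   op$deltabic_cutoff,
               clones = if (is.na(op$clones)) NULL else op$clones,
               seed = op$seed)
    0L
}

.cliSimulate <- function(args) {
    ol <- list(
        optparse::make_option("--out", type = "character"),
        optparse::make_option("--n-cells", type = "integer", default = 90L,
                              dest = "n_cells"),
        optparse::make_option("--n-clones", type = "integer", default = 3L,
                              dest = "n_clones"),
        optparse::make_option("--variants-per-clone", type = "integer",
                              default = 10L, dest = "m"),
        optparse::make_option("--af-mu", type = "double", default = 0.1,
                              dest = "mu"),
        optparse::make_option("--ratio", type = "character",
                              default = NULL),
        optparse::make_option("--tree", type = "character",
                              default = "branched"),
        optparse::make_option("--noise-sites", type = "integer",
                              default = 3500L, dest = "noise_sites"),
        optparse::make_option("--seed", type = "integer", default = 1L))
    op <- optparse::parse_args(optparse::OptionParser(option_list = ol),
                               args = args)
    if (is.null(op$out)) stop("simulate requires --out")
    ratio <- NULL
    if (!is.null(op$ratio)) {
        ratio <- suppressWarnings(as.numeric(strsplit(op$ratio, ":")[[1L]]))
        if (anyNA(ratio) || length(ratio) != op$n_clones ||
            any(ratio <= 0))
            stop("invalid ratio string: ", op$ratio)
    }
    cfg <- simConfig(n_cells = op$n_cells, n_clones = op$n_clones,
                     variants_per_clone = op$m, clonal_af_mu = op$mu,
                     clone_ratio = ratio, tree = op$tree,
                     noise_sites = op$noise_sites, rng_seed = op$seed)
    simulateToDir(op$out, cfg)
    0L
}

.cliBenchmark <- function(args) {
    ol <- list(
        optparse::make_option("--deltabic", type = "character"),
        optparse::make_option("--truth", type = "character"),
        optparse::make_option("--out", type = "character", default = NULL))
    op <- optparse::parse_args(optparse::OptionParser(option_list = ol),
                               args = args)
    if (is.null(op$deltabic) || is.null(op$truth))
        stop("benchmark requires --deltabic and --truth")
    metrics <- benchmarkRun(op$deltabic, op$truth, op$out)
    message(paste(sprintf("%s = %.4g", names(metrics),
                          unlist(metrics)), collapse = ", "))
    0L
}
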