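#' Simulation configuration
#'
#' Parameters of the count-level clonal simulator. Defaults reproduce the
#' benchmark design: 90 cells in 3 equal clones on a branched lineage tree,
#' 10 clone-specific variants per clone with allele frequencies drawn from a
#' log-normal with median \code{clonal_af_mu} = 0.1 and log-scale standard
#' deviation 0.005, roughly 3500 elevated-noise sites whose per-cell VAF is
#' exponential with mean 0.44\%, per-base sequencing error 1e-4 elsewhere,
#' and uneven coverage: about half the 16,569 bp mitochondrial genome is
#' on-target at 1000x mean depth while off-target positions get 2\% of that
#' (per-cell depths are Poisson around the class mean).
#'
#' @param n_cells total number of cells.
#' @param n_clones number of clones.
#' @param variants_per_clone clone-specific variants per clone (M); the
#'   benchmark grid is \{5, 10, 25, 50\}.
#' @param clonal_af_mu median clonal allele frequency (grid \{0.01, 0.05,
#'   0.1\}).
#' @param clonal_af_sigma log-scale standard deviation of the clonal AF.
#' @param clone_ratio relative clone sizes, e.g. \code{c(1, 1, 1)} or
#'   \code{c(2, 4, 4)}; converted to cell counts by largest-remainder
#'   rounding.
#' @param tree lineage tree: \code{"branched"} (all variants private),
#'   \code{"linear"} (each clone's variants inherited by all downstream
#'   clones) or \code{"mixed"} (one internal branch: clone 1 private, a
#'   block shared by clones 2 and 3, plus a private block each).
#' @param genome_length mitochondrial genome length (rCRS).
#' @param noise_sites number of elevated-noise positions.
#' @param noise_mean_vaf mean of the exponential per-cell VAF at elevated
#'   noise sites.
#' @param per_base_error baseline per-base, per-alt error allele frequency.
#' @param on_target_depth mean depth of on-target positions.
#' @param off_target_fraction off-target mean depth as a fraction of
#'   on-target.
#' @param on_target_prob fraction of genome positions that are on-target.
#' @param rng_seed integer seed; identical configs give bit-identical data.
#' @return A list of class \code{"SimConfig"}.
#' @export
simConfig <- function(n_cells = 90L, n_clones = 3L,
                      variants_per_clone = 10L,
                      clonal_af_mu = 0.1, clonal_af_sigma = 0.005,
                      clone_ratio = NULL,
                      tree = c("branched", "linear", "mixed"),
                      genome_length = RCRS_LENGTH,
                      noise_sites = 3500L, noise_mean_vaf = 0.0044,
                      per_base_error = 1e-4,
                      on_target_depth = 1000, off_target_fraction = 0.02,
                      on_target_prob = 0.5, rng_seed = 1L) {
    tree <- match.arg(tree)
    if (is.null(clone_ratio)) clone_ratio <- rep(1, n_clones)
    if (length(clone_ratio) != n_clones)
        stop("clone_ratio must have one entry per clone")
    if (any(clone_ratio <= 0)) stop("clone_ratio entries must be positive")
    if (tree == "mixed" && n_clones != 3L)
        stop("the 'mixed' tree is defined for exactly 3 clones")
    stopifnot(n_cells >= n_clones, variants_per_clone >= 1L,
              clonal_af_mu > 0, clonal_af_mu <= 1, clonal_af_sigma >= 0,
              noise_mean_vaf >= 0, noise_mean_vaf <= 1,
              per_base_error >= 0, per_base_error <= 1,
              on_target_depth > 0, off_target_fraction > 0,
              on_target_prob >= 0, on_target_prob <= 1)
    n_blocks <- if (tree == "mixed") 4L else n_clones
    if (n_blocks * variants_per_clone + noise_sites > genome_length - 33L)
        stop("not enough free genome positions for the requested variants")
    structure(list(n_cells = as.integer(n_cells),
                   n_clones = as.integer(n_clones),
                   variants_per_clone = as.integer(variants_per_clone),
                   clonal_af_mu = clonal_af_mu,
                   clonal_af_sigma = clonal_af_sigma,
                   clone_ratio = clone_ratio, tree = tree,
                   genome_length = as.integer(genome_length),
                   noise_sites = as.integer(noise_sites),
                   noise_mean_vaf = noise_mean_vaf,
                   per_base_error = per_base_error,
                   on_target_depth = on_target_depth,
                   off_target_fraction = off_target_fraction,
                   on_target_prob = on_target_prob,
                   rng_seed = as.integer(rng_seed)),
              class = "SimConfig")
}

## Largest-remainder apportionment of n_cells to the clone ratio; ties go to
## the earlier clone.
.cloneSizes <- function(n_cells, ratio) {
    q <- n_cells * ratio / sum(ratio)
    sizes <- floor(q)
    rem <- n_cells - sum(sizes)
    if (rem > 0) {
        ord <- order(-(q - sizes), seq_along(q))
        sizes[ord[seq_len(rem)]] <- sizes[ord[seq_len(rem)]] + 1
    }
    as.integer(sizes)
}

#' Plant clonal variants on a lineage tree
#'
#' Chooses clone sizes (largest-remainder rounding of the clone ratio),
#' assigns cells to clones, fixes the per-position coverage class for the
#' run, draws distinct variant positions from the on-target (covered)
#' portion of the genome outside the error-prone blacklist regions (spiked
#' variants and observed noise SNPs both presuppose read coverage), assigns reference/alternative alleles, and
#' builds the clone-membership structure implied by the lineage tree:
#' \describe{
#'   \item{branched}{each clone carries its own M private variants;}
#'   \item{linear}{clones form a chain c1 -> c2 -> ...; each clone's M new
#'     variants are inherited by all downstream clones (the last clone
#'     carries \code{n_clones * M});}
#'   \item{mixed}{(3 clones) clone 1 carries M private variants; one block of
#'     M is shared by clones 2 and 3; clones 2 and 3 additionally carry M
#'     private variants each.}
#' }
#' The planted allele frequency of each (variant, clone) membership is drawn
#' once as \code{exp(N(log mu, sigma^2))} clipped to (0, 1] -- all cells of a
#' clone share the same expected heteroplasmy, as inherited mitochondrial
#' variants propagate clonally.
#'
#' Uses the current RNG state; \code{\link{simulateClones}} seeds it from the
#' config for reproducibility.
#'
#' @param config a \code{\link{simConfig}}.
#' @return A list (truth skeleton): \code{clone_sizes}, \code{clone_of_cell},
#'   \code{variants} (data.frame with position/ref/alt/id/block),
#'   \code{membership} (variants x clones logical), \code{expected_af}
#'   (variants x clones).
#' @export
plantTreeVariants <- function(config) {
    K <- config$n_clones
    M <- config$variants_per_clone
    sizes <- .cloneSizes(config$n_cells, config$clone_ratio)
    clone_of_cell <- rep(seq_len(K), sizes)

    ## coverage classes are fixed per run; planted (and elevated-noise)
    ## variants live in covered, on-target regions -- spiked variants and
    ## empirically observed noise SNPs both require read coverage
    on_target <- runif(config$genome_length) < config$on_target_prob
    bl <- defaultBlacklist()
    bl_pos <- unlist(lapply(seq_along(bl), function(i)
        seq(IRanges::start(bl)[i], IRanges::end(bl)[i])))
    free <- setdiff(which(on_target), bl_pos)

    n_blocks <- if (config$tree == "mixed") 4L else K
    n_var <- n_blocks * M
    if (n_var > length(free))
        stop("not enough free positions to plant clonal variants")
    pos <- sort(sample(free, n_var))
    ref <- sample(DNA_BASES, n_var, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(DNA_BASES, r), 1L), "")
    block <- rep(seq_len(n_blocks), each = M)

    membership <- matrix(FALSE, n_var, K)
    for (b in seq_len(n_blocks)) {
        rows <- block == b
        carriers <- switch(config$tree,
            branched = b,
            linear = b:K,
            mixed = list(1L, c(2L, 3L), 2L, 3L)[[b]])
        membership[rows, carriers] <- TRUE
    }

    expected_af <- matrix(0, n_var, K)
    n_draws <- sum(membership)
    draws <- pmin(exp(rnorm(n_draws, log(config$clonal_af_mu),
                            config$clonal_af_sigma)), 1)
    expected_af[membership] <- draws

    variants <- data.frame(position = pos, ref = unname(ref), alt = unname(alt),
                           id = variantId(pos, ref, alt), block = block)
    list(clone_sizes = sizes, clone_of_cell = clone_of_cell,
         variants = variants, membership = membership,
         expected_af = expected_af, on_target = on_target)
}

#' Sample AD/DP counts for every genome site
#'
#' Generates the full (position x alt) count data: per-cell depths are
#' Poisson around the position's coverage-class mean (on-target positions at
#' \code{on_target_depth}, off-target at \code{off_target_fraction} of it);
#' each position's three possible alternative alleles are independent
#' candidate sites. The allele frequency of a site in a cell is the planted
#' clonal AF when the cell's clone carries the variant, an exponential
#' per-cell draw (mean \code{noise_mean_vaf}, clipped to [0, 1]) at elevated
#' noise sites, and \code{per_base_error} everywhere else; AD is then
#' binomial given DP and the AF.
#'
#' Uses the current RNG state (see \code{\link{simulateClones}}).
#'
#' @param truth output of \code{\link{plantTreeVariants}}.
#' @param config a \code{\link{simConfig}}.
#' @return A list: \code{counts} (a \linkS4class{MitoCounts} of all
#'   \code{3 * genome_length} sites), \code{site_class} (character:
#'   clonal/noise/error), \code{noise_ids} (ids of elevated-noise sites).
#' @export
sampleCounts <- function(truth, config) {
    L <- config$genome_length
    N <- config$n_cells
    K <- config$n_clones

    ref <- sample(DNA_BASES, L, replace = TRUE)
    ref[truth$variants$position] <- truth$variants$ref

    on_target <- truth$on_target
    depth_mean <- ifelse(on_target, config$on_target_depth,
                         config$on_target_depth * config$off_target_fraction)
    DPpos <- matrix(rpois(L * N, rep(depth_mean, N)), L, N)

    free_noise <- setdiff(which(on_target), truth$variants$position)
    if (length(free_noise) < config$noise_sites)
        stop("not enough on-target positions for the requested noise sites")
    noise_pos <- sample(free_noise, config$noise_sites)
    noise_alt <- vapply(ref[noise_pos],
                        function(r) sample(setdiff(DNA_BASES, r), 1L), "")

    ## per-position list of the three non-reference bases
    alt_options <- matrix("", L, 3L)
    for (b in DNA_BASES) {
        rows <- ref == b
        alt_options[rows, ] <- matrix(rep(setdiff(DNA_BASES, b),
                                          each = sum(rows)), ncol = 3L)
    }

    cell_clone <- truth$clone_of_cell
    AD_list <- vector("list", 3L)
    class_list <- vector("list", 3L)
    for (k in 1:3) {
        alt_k <- alt_options[, k]
        AF <- matrix(config$per_base_error, L, N)
        cls <- rep("error", L)
        nz <- noise_pos[noise_alt == alt_k[noise_pos]]
        if (length(nz)) {
            AF[nz, ] <- pmin(matrix(
                rexp(length(nz) * N, rate = 1 / config$noise_mean_vaf),
                length(nz), N), 1)
            cls[nz] <- "noise"
        }
        cv <- which(truth$variants$alt == alt_k[truth$variants$position])
        if (length(cv)) {
            vpos <- truth$variants$position[cv]
            ## expected AF per cell = planted AF of the cell's clone (0 for
            ## non-carriers -> keep baseline error)
            af_vc <- truth$expected_af[cv, , drop = FALSE][, cell_clone,
                                                           drop = FALSE]
            base <- AF[vpos, , drop = FALSE]
            AF[vpos, ] <- ifelse(af_vc > 0, af_vc, base)
            cls[vpos] <- "clonal"
        }
        AD_list[[k]] <- matrix(rbinom(L * N, DPpos, AF), L, N)
        class_list[[k]] <- cls
    }

    pos_all <- rep(seq_len(L), 3L)
    ref_all <- rep(ref, 3L)
    alt_all <- c(alt_options[, 1], alt_options[, 2], alt_options[, 3])
    variants <- data.frame(position = pos_all, ref = ref_all, alt = alt_all,
                           id = variantId(pos_all, ref_all, alt_all))
    AD <- do.call(rbind, AD_list)
    DP <- rbind(DPpos, DPpos, DPpos)
    counts <- MitoCounts(AD, DP, variants,
                         cells = sprintf("cell%03d", seq_len(N)))
    list(counts = counts,
         site_class = c(class_list[[1]], class_list[[2]], class_list[[3]]),
         noise_ids = variantId(noise_pos, ref[noise_pos], noise_alt))
}

#' Keep candidate sites: at least one alternative read in at least one cell
#'
#' @param sampled output of \code{\link{sampleCounts}}.
#' @param truth output of \code{\link{plantTreeVariants}}.
#' @return A list: \code{counts} (candidate \linkS4class{MitoCounts}),
#'   \code{truth} (aligned \code{DataFrame} with id, position, ref, alt,
#'   class, isClonal, expectedAF).
#' @export
emitCandidates <- function(sampled, truth) {
    keep <- rowSums(adCounts(sampled$counts)) > 0
    counts <- sampled$counts[keep, ]
    cls <- sampled$site_class[keep]
    ids <- variantIds(counts)
    m <- match(ids, truth$variants$id)
    eaf <- matrix(0, length(ids), ncol(truth$expected_af))
    hit <- !is.na(m)
    eaf[hit, ] <- truth$expected_af[m[hit], , drop = FALSE]
    colnames(eaf) <- paste0("clone", seq_len(ncol(eaf)))
    td <- S4Vectors::DataFrame(as.data.frame(variantInfo(counts)),
                               class = cls, isClonal = cls == "clonal",
                               expectedAF = I(eaf))
    rownames(td) <- ids
    list(counts = counts, truth = td)
}

#' Simulate a clonal single-cell mitochondrial dataset
#'
#' End-to-end generator: plants clonal variants on the lineage tree, samples
#' depths and allele counts for every genome site, and returns the candidate
#' sites (>= 1 alternative read in >= 1 cell) with aligned ground truth.
#' Fully reproducible: identical configs (including \code{rng_seed}) give
#' bit-identical output.
#'
#' @param config a \code{\link{simConfig}}.
#' @return A \linkS4class{MitoSimulation}.
#' @examples
#' sim <- simulateClones(simConfig(variants_per_clone = 5, noise_sites = 100))
#' sim
#' @export
simulateClones <- function(config = simConfig()) {
    withr::with_seed(config$rng_seed, {
        truth <- plantTreeVariants(config)
        sampled <- sampleCounts(truth, config)
        cand <- emitCandidates(sampled, truth)
    })
    clone_vars <- lapply(seq_len(config$n_clones), function(k)
        truth$variants$id[truth$membership[, k]])
    new("MitoSimulation",
        counts = cand$counts, truth = cand$truth,
        cloneOfCell = truth$clone_of_cell,
        cloneVariants = clone_vars,
        config = unclass(config))
}

#' Write a simulation to disk in cellSNP-lite layout plus truth tables
#'
#' Writes the candidate AD/DP/VCF/barcodes via \code{\link{writeCellSNP}},
#' a \code{truth.tsv} (variant id, class, isClonal, per-clone expected AF)
#' and a \code{clones.tsv} (cell barcode, clone label).
#'
#' @param sim a \linkS4class{MitoSimulation}.
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
    writeCellSNP(simCounts(sim), dir)
    td <- simTruth(sim)
    eaf <- as.matrix(td$expectedAF)
    colnames(eaf) <- paste0("expectedAF_", seq_len(ncol(eaf)))
    tab <- cbind(as.data.frame(td[, c("id", "position", "ref", "alt",
                                      "class", "isClonal")]),
                 as.data.frame(eaf))
    write.table(tab, file.path(dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(data.frame(cell = cellBarcodes(simCounts(sim)),
                           clone = cloneLabels(sim)),
                file.path(dir, "clones.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    invisible(dir)
}
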