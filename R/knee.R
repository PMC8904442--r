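#' Discrete curvature of a sampled function
#'
#' Curvature K(x) = f''(x) / (1 + f'(x)^2)^(3/2) of a function sampled on a
#' uniform grid, using central finite differences at interior points and
#' one-sided differences at the two endpoints.
#'
#' @param y function values on a uniform grid (length >= 3).
#' @param dx grid spacing (default 1).
#' @return Numeric curvature values, one per sample.
#' @examples
#' x <- seq(-1, 1, length.out = 201)
#' curvatureFD(x^2, dx = x[2] - x[1])[101]  # ~2 at the vertex
#' @export
curvatureFD <- function(y, dx = 1) {
    n <- length(y)
    if (n < 3L) stop("need at least 3 points to estimate curvature")
    stopifnot(dx > 0)
    d1 <- numeric(n)
    d2 <- numeric(n)
    i <- 2:(n - 1)
    d1[i] <- (y[i + 1] - y[i - 1]) / (2 * dx)
    d2[i] <- (y[i + 1] - 2 * y[i] + y[i - 1]) / dx^2
    d1[1] <- (y[2] - y[1]) / dx
    d1[n] <- (y[n] - y[n - 1]) / dx
    d2[1] <- (y[3] - 2 * y[2] + y[1]) / dx^2
    d2[n] <- (y[n] - 2 * y[n - 1] + y[n - 2]) / dx^2
    d2 / (1 + d1^2)^1.5
}

#' Locate the deltaBIC selection threshold at the knee of the cumulative
#' distribution
#'
#' Forms the empirical cumulative distribution of the finite deltaBIC
#' values -- x the sorted values, y the cumulative fraction, both min-max
#' normalised to [0, 1] -- and places the threshold at the knee of this
#' concave increasing curve: the point of maximum vertical distance above
#' the diagonal, the Kneedle criterion (on a normalised curve the
#' maximum-distance point is where the discrete curvature peaks; sensitivity
#' 1, no smoothing, ties broken towards the larger value, i.e. the higher
#' threshold and fewer selected variants). Variants with deltaBIC strictly
#' greater than the threshold are selected. On this curve the knee marks
#' where the distribution's bulk (noise) ends and the sharply increasing
#' informative tail begins.
#'
#' With fewer than 5 finite values, or a degenerate curve with no knee (all
#' values equal), the function falls back to selecting \code{deltaBIC > 0}
#' with a warning.
#'
#' @param deltabic numeric deltaBIC values (may contain \code{-Inf}
#'   sentinels, which are excluded from the curve and never selected).
#' @return A \linkS4class{KneeResult}.
#' @examples
#' db <- c(rnorm(200), rnorm(10, 500))
#' kr <- findKnee(db)
#' kneeThreshold(kr); sum(selectedMask(kr))
#' @export
findKnee <- function(deltabic) {
    fin <- is.finite(deltabic)
    vals <- deltabic[fin]
    fallback <- function(reason) {
        warning("findKnee: ", reason, "; falling back to deltaBIC > 0 rule")
        new("KneeResult",
            sortedValues = sort(vals), xNorm = numeric(), yNorm = numeric(),
            kneeIndex = NA_integer_, threshold = 0,
            selectedMask = !is.na(deltabic) & deltabic > 0,
            usedFallback = TRUE)
    }
    if (length(vals) < 5L)
        return(fallback("fewer than 5 finite deltaBIC values"))
    s <- sort(vals)
    n <- length(s)
    if (s[1] == s[n])
        return(fallback("degenerate cumulative distribution (no knee)"))
    x_norm <- (s - s[1]) / (s[n] - s[1])
    y_norm <- seq_len(n) / n
    diffcurve <- y_norm - x_norm
    ## Kneedle with sensitivity 1: candidates within one grid step (1/n, in
    ## normalised units) of the maximum are equivalent knees; take the
    ## largest, i.e. the higher threshold and fewer selected variants.
    idx <- which(diffcurve >= max(diffcurve) - 1 / n)
    knee <- idx[length(idx)]
    thr <- s[knee]
    new("KneeResult",
        sortedValues = s, xNorm = x_norm, yNorm = y_norm,
        kneeIndex = as.integer(knee), threshold = thr,
        selectedMask = !is.na(deltabic) & deltabic > thr,
        usedFallback = FALSE)
}

#' Plot the cumulative deltaBIC curve with the knee cutoff
#'
#' Diagnostic plot of the normalised cumulative deltaBIC curve with the
#' selected knee marked, optionally written to a PNG file.
#'
#' @param kr a \linkS4class{KneeResult}.
#' @param png_file optional path; when given the plot is written there.
#' @return \code{NULL}, invisibly.
#' @export
plotKnee <- function(kr, png_file = NULL) {
    if (!is.null(png_file)) {
        grDevices::png(png_file, width = 700, height = 500)
        on.exit(grDevices::dev.off())
    }
    if (!length(kr@xNorm)) {
        graphics::plot.new()
        graphics::title("deltaBIC knee (fallback rule: deltaBIC > 0)")
        return(invisible(NULL))
    }
    graphics::plot(kr@xNorm, kr@yNorm, type = "l",
                   xlab = "normalised deltaBIC",
                   ylab = "cumulative fraction of variants",
                   main = sprintf("deltaBIC knee: threshold %.3g (%d selected)",
                                  kr@threshold, sum(kr@selectedMask)))
    graphics::abline(v = kr@xNorm[kr@kneeIndex], lty = 2, col = "red")
    graphics::points(kr@xNorm[kr@kneeIndex], kr@yNorm[kr@kneeIndex],
                     pch = 19, col = "red")
    invisible(NULL)
}
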