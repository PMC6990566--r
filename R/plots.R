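#' Red-tone heatmap of a contact matrix
#'
#' Sequential white-to-red map of (optionally log-scaled) contacts;
#' missing bins are drawn gray.
#'
#' @param m a [ContactMatrix-class].
#' @param file output PNG path.
#' @param region optional 0-based bin range (integer vector) to plot.
#' @param log if `TRUE` (default), plot `log1p` of the values.
#' @param width,height device size in pixels.
#' @return `file`, invisibly.
#' @export
plotContactHeatmap <- function(m, file, region = NULL, log = TRUE,
                               width = 480, height = 480) {
    nb <- nBins(m)
    if (is.null(region)) {
        region <- seq_len(nb) - 1L
    }
    if (!length(region)) {
        stop("empty region")
    }
    if (any(region < 0 | region >= nb)) {
        stop("region outside matrix")
    }
    v <- contactValues(m, na = TRUE)[region + 1L, region + 1L,
                                     drop = FALSE]
    if (log) {
        v <- log1p(v)
    }
    grDevices::png(file, width = width, height = height)
    on.exit(grDevices::dev.off())
    graphics::par(mar = c(2, 2, 2, 1))
    pal <- grDevices::colorRampPalette(c("white", "#fee0d2", "#fb6a4a",
                                         "#a50f15"))(100)
    graphics::image(seq_along(region), seq_along(region),
                    t(v[rev(seq_len(nrow(v))), , drop = FALSE]),
                    col = pal, useRaster = TRUE, axes = FALSE,
                    xlab = "", ylab = "",
                    main = paste(sampleId(m), chromName(m)))
    # missing bins gray
    na.rows <- which(apply(v, 1, function(z) all(is.na(z))))
    if (length(na.rows)) {
        ry <- nrow(v) - na.rows + 1
        graphics::rect(0.5, ry - 0.5, length(region) + 0.5, ry + 0.5,
                       col = "grey70", border = NA)
        graphics::rect(na.rows - 0.5, 0.5, na.rows + 0.5,
                       length(region) + 0.5, col = "grey70", border = NA)
    }
    invisible(file)
}

#' Blue-red heatmap of a coefficient map
#'
#' Diverging blue-white-red map centered at zero; masked / invalid cells
#' are gray.
#'
#' @param cm a [CoefficientMap-class].
#' @param file output PNG path.
#' @param width,height device size in pixels.
#' @return `file`, invisibly.
#' @export
plotCoefficientHeatmap <- function(cm, file, width = 480, height = 480) {
    b <- coefficientGrid(cm)
    G <- nrow(b)
    lim <- suppressWarnings(max(abs(b), na.rm = TRUE))
    if (!is.finite(lim) || lim == 0) {
        lim <- 1
    }
    grDevices::png(file, width = width, height = height)
    on.exit(grDevices::dev.off())
    graphics::par(mar = c(2, 2, 2, 1))
    pal <- grDevices::colorRampPalette(c("#2166ac", "white",
                                         "#b2182b"))(101)
    graphics::image(seq_len(G), seq_len(G),
                    t(b[rev(seq_len(G)), , drop = FALSE]),
                    col = pal, zlim = c(-lim, lim), useRaster = TRUE,
                    axes = FALSE, xlab = "", ylab = "", main = cm@svId)
    nas <- which(is.na(t(b[rev(seq_len(G)), , drop = FALSE])),
                 arr.ind = TRUE)
    if (nrow(nas)) {
        graphics::rect(nas[, 1] - 0.5, nas[, 2] - 0.5, nas[, 1] + 0.5,
                       nas[, 2] + 0.5, col = "grey70", border = NA)
    }
    invisible(file)
}

#' QQ plot of observed versus null p-values
#'
#' @param qq data.frame from [qqPoints()].
#' @param file output PNG path.
#' @param main title.
#' @return `file`, invisibly.
#' @export
plotQQ <- function(qq, file, main = "QQ") {
    grDevices::png(file, width = 480, height = 480)
    on.exit(grDevices::dev.off())
    lim <- range(c(qq$expected, qq$observed), finite = TRUE)
    graphics::plot(qq$expected, qq$observed, pch = 16, cex = 0.6,
                   xlim = lim, ylim = lim,
                   xlab = "expected -log10(p)",
                   ylab = "observed -log10(p)", main = main)
    graphics::abline(0, 1, col = "grey50")
    invisible(file)
}
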