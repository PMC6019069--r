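#' @include AllClasses.R AllGenerics.R
NULL

#' Circular region of interest
#'
#' Pixel set of a circle, matching the circular stimulation ROIs drawn
#' on the imaging frame. Coordinates are 1-based (row, column).
#'
#' @param centerRow,centerCol circle centre in pixels.
#' @param diameter_px circle diameter in pixels.
#' @param frameDim integer length-2 (rows, columns); pixels outside the
#'   frame are dropped.
#' @return Two-column integer matrix of (row, col) pixel coordinates.
#' @export
circleROI <- function(centerRow, centerCol, diameter_px, frameDim) {
    r <- diameter_px / 2
    rows <- max(1, floor(centerRow - r)):min(frameDim[1], ceiling(centerRow + r))
    cols <- max(1, floor(centerCol - r)):min(frameDim[2], ceiling(centerCol + r))
    g <- expand.grid(row = rows, col = cols)
    keep <- (g$row - centerRow)^2 + (g$col - centerCol)^2 <= r^2
    m <- as.matrix(g[keep, , drop = FALSE])
    if (!nrow(m)) stop("ROI contains no pixels inside the frame")
    rownames(m) <- NULL
    m
}

# linear pixel indices into the (frame, row, col) stack, one column per pixel
.pixelMatrix <- function(movie) {
    f <- movieFrames(movie)
    d <- dim(f)
    matrix(f, nrow = d[1])
}

.roiColumns <- function(movie, roi) {
    d <- dim(movieFrames(movie))
    if (any(roi[, 1] < 1) || any(roi[, 1] > d[2]) ||
        any(roi[, 2] < 1) || any(roi[, 2] > d[3]))
        stop("ROI pixel outside frame bounds")
    (roi[, 2] - 1L) * d[2] + roi[, 1]
}

#' Mean-intensity time series of a region of interest
#'
#' @param movie a \linkS4class{FluorescenceMovie}.
#' @param roi two-column (row, col) matrix of pixel coordinates, e.g.
#'   from \code{\link{circleROI}}.
#' @return Numeric vector: per-frame arithmetic mean over the ROI.
#' @export
extractTrace <- function(movie, roi) {
    roi <- as.matrix(roi)
    if (!nrow(roi)) stop("ROI is empty")
    pm <- .pixelMatrix(movie)[, .roiColumns(movie, roi), drop = FALSE]
    rowMeans(pm)
}

#' Relative fluorescence change (delta-F/F0)
#'
#' Two baseline modes. With \code{baselineFrames}, F0 is the mean of the
#' raw series over a fixed pre-stimulus window and the result is
#' \code{(F - F0)/F0}. With a \code{reference} series (the mean
#' intensity of a brain area with no calcium activity), F0 is
#' time-dependent and the result is \code{(F(t) - F0(t))/F0(t)}, which
#' cancels any per-frame multiplicative artefact shared by the signal
#' and reference regions — stimulation-laser bleed-through and detector
#' gain drifts in particular.
#'
#' @param raw numeric vector of raw mean intensities.
#' @param baselineFrames integer indices of the pre-stimulus window
#'   (fixed mode).
#' @param reference numeric vector the length of \code{raw}
#'   (time-dependent mode); exactly one of the two must be given.
#' @param frameInterval_s frame interval used for the time axis.
#' @param label cell identity token attached to the trace.
#' @return data.frame with columns \code{time_s} (t = 0 at the first
#'   frame), \code{dff} and \code{label}.
#' @export
computeDff <- function(raw, baselineFrames = NULL, reference = NULL,
                       frameInterval_s = 0.8, label = "cell") {
    if (is.null(baselineFrames) == is.null(reference))
        stop("give exactly one of baselineFrames or reference")
    if (!is.null(baselineFrames)) {
        f0 <- mean(raw[baselineFrames])
        if (!is.finite(f0) || f0 <= 0)
            stop("baseline F0 must be strictly positive")
        dff <- (raw - f0) / f0
    } else {
        if (length(reference) != length(raw))
            stop("reference series must match raw length")
        if (any(reference <= 0))
            stop("reference baseline must be strictly positive")
        dff <- (raw - reference) / reference
    }
    data.frame(time_s = (seq_along(raw) - 1) * frameInterval_s,
               dff = dff, label = label, stringsAsFactors = FALSE)
}

#' Pixelwise Pearson correlation map
#'
#' Correlates a seed trace with the time series of every pixel, giving a
#' single image of Pearson coefficients in [-1, 1]. Pixels with zero
#' variance (or a constant seed) are assigned 0 so maps render cleanly.
#'
#' @param movie a \linkS4class{FluorescenceMovie}.
#' @param seed numeric vector, length equal to the frame count (e.g. the
#'   \code{dff} column of a trace).
#' @return Matrix (rows x columns) of correlation coefficients.
#' @export
correlationMap <- function(movie, seed) {
    d <- dim(movieFrames(movie))
    if (length(seed) != d[1])
        stop("seed length must equal the number of frames")
    r <- suppressWarnings(as.vector(stats::cor(seed, .pixelMatrix(movie))))
    r[!is.finite(r)] <- 0
    matrix(r, nrow = d[2], ncol = d[3])
}

#' Render a correlation map as a two-color [-1, 1] heat map
#'
#' Writes a PNG with a symmetric diverging palette (blue for -1, white
#' for 0, red for +1), or draws on the current device when \code{file}
#' is \code{NULL}.
#'
#' @param map matrix from \code{\link{correlationMap}}.
#' @param file optional PNG path.
#' @return Invisibly, \code{file} (or \code{NULL}).
#' @export
plotCorrelationMap <- function(map, file = NULL) {
    pal <- grDevices::colorRampPalette(c("#2166AC", "#FFFFFF", "#B2182B"))(256)
    if (!is.null(file)) {
        grDevices::png(file, width = ncol(map), height = nrow(map))
        on.exit(grDevices::dev.off())
        graphics::par(mar = c(0, 0, 0, 0))
    }
    graphics::image(t(map[nrow(map):1, , drop = FALSE]), col = pal,
                    zlim = c(-1, 1), axes = FALSE, useRaster = TRUE)
    invisible(file)
}

.sustainedRun <- function(flag, minRun) {
    # index of the first element starting >= minRun consecutive TRUEs
    if (!any(flag)) return(NA_integer_)
    r <- rle(flag)
    ends <- cumsum(r$lengths)
    i <- which(r$values & r$lengths >= minRun)
    if (!length(i)) return(NA_integer_)
    ends[i[1]] - r$lengths[i[1]] + 1L
}

#' Detect dip / depolarization features of a calcium trace
#'
#' Characterizes the biphasic phenomenology of ciliary-photoreceptor
#' responses: a transient calcium dip (hyperpolarization proxy) followed
#' by a strong increase (depolarization proxy). An excursion only counts
#' if sustained for at least \code{minRun} consecutive frames, rejecting
#' single-frame noise. The depolarization is searched to the end of the
#' trace, so a rise after stimulus offset is still counted (the
#' depolarization follows even when the UV stimulus is switched off
#' during the dip).
#'
#' Response classes: \code{biphasic_cPRC} (dip then rise),
#' \code{hyperpolarizing_only} (dip, no rise), \code{onset_depolarizing}
#' (rise starting within \code{onsetWindow_s} of stimulus onset, no
#' preceding dip), \code{delayed_depolarizing} (rise starting later, no
#' dip), \code{none}.
#'
#' @param trace data.frame from \code{\link{computeDff}} (columns
#'   \code{time_s}, \code{dff}).
#' @param onset_s,offset_s stimulus window in seconds.
#' @param dipThreshold,depolThreshold positive thresholds on
#'   delta-F/F0; default 3x the pre-stimulus standard deviation of the
#'   trace (floored at 0.05 for noise-free traces whose pre-stimulus
#'   s.d. is zero).
#' @param minRun consecutive frames required for a sustained excursion.
#' @param onsetWindow_s boundary between onset and delayed
#'   depolarization, seconds after stimulus onset.
#' @return One-row data.frame: \code{dip_present},
#'   \code{dip_min_time_s}, \code{depol_onset_time_s},
#'   \code{depol_peak}, \code{response_class}.
#' @export
detectResponse <- function(trace, onset_s, offset_s, dipThreshold = NULL,
                           depolThreshold = NULL, minRun = 3,
                           onsetWindow_s = 10) {
    tm <- trace$time_s
    v <- trace$dff
    if (onset_s >= offset_s || onset_s < tm[1] || offset_s > tm[length(tm)])
        stop("stimulus window must satisfy onset < offset within the trace")
    auto <- max(3 * stats::sd(v[tm < onset_s]), 0.05)
    if (is.null(dipThreshold)) dipThreshold <- auto
    if (is.null(depolThreshold)) depolThreshold <- auto
    if (dipThreshold <= 0 || depolThreshold <= 0)
        stop("thresholds must be positive")

    post <- which(tm >= onset_s)
    dipStart <- .sustainedRun(v[post] < -dipThreshold, minRun)
    dipPresent <- !is.na(dipStart)
    dipMinTime <- NA_real_
    searchFrom <- post[1]
    if (dipPresent) {
        dipIdx <- post[dipStart]
        # dip minimum: lowest point between dip start and recovery (or end)
        below <- v[dipIdx:length(v)] < -dipThreshold
        recover <- which(!below)[1]
        dipEnd <- if (is.na(recover)) length(v) else dipIdx + recover - 2L
        dipMinTime <- tm[dipIdx:dipEnd][which.min(v[dipIdx:dipEnd])]
        searchFrom <- dipIdx
    }
    rng <- searchFrom:length(v)
    riseStart <- .sustainedRun(v[rng] > depolThreshold, minRun)
    depolOnset <- if (is.na(riseStart)) NA_real_ else tm[rng[riseStart]]
    depolPeak <- if (is.na(riseStart)) NA_real_ else
        max(v[rng[riseStart]:length(v)])

    cls <- if (dipPresent && !is.na(depolOnset)) "biphasic_cPRC"
        else if (dipPresent) "hyperpolarizing_only"
        else if (!is.na(depolOnset) && depolOnset - onset_s <= onsetWindow_s)
            "onset_depolarizing"
        else if (!is.na(depolOnset)) "delayed_depolarizing"
        else "none"
    data.frame(dip_present = dipPresent, dip_min_time_s = dipMinTime,
               depol_onset_time_s = depolOnset, depol_peak = depolPeak,
               response_class = cls, stringsAsFactors = FALSE)
}

#' Classify cells from paired 405/488 nm responses
#'
#' Joint labels over both stimulation wavelengths, following the
#' wavelength-specific phenomenology of the ciliary-photoreceptor
#' circuit: \code{cPRC_like} cells are biphasic under 405 nm and show a
#' prolonged dip only under 488 nm; \code{RGW_follower} cells track the
#' cPRC response at 405 nm but do not respond at 488 nm;
#' \code{SN_early} cells depolarize promptly at 405 nm only;
#' \code{SN_late} cells depolarize with a delay at 405 nm and show at
#' most a weak response at 488 nm (peak amplitude below
#' \code{weakRatio} times the 405 nm peak — a configurable boundary,
#' not validated against real data). Everything else is \code{none}.
#'
#' @param traces long-format data.frame with columns \code{cell},
#'   \code{wavelength_nm} (405 and 488 required for every cell),
#'   \code{time_s}, \code{dff}.
#' @param onset_s,offset_s stimulus window (shared by both programs).
#' @param weakRatio 488/405 peak-amplitude ratio below which a 488 nm
#'   depolarization still counts as "weak-or-none".
#' @param ... passed to \code{\link{detectResponse}}.
#' @return data.frame with one row per cell: \code{cell},
#'   \code{class_405}, \code{class_488}, \code{joint_class}.
#' @export
classifyCells <- function(traces, onset_s, offset_s, weakRatio = 0.5, ...) {
    cells <- unique(traces$cell)
    out <- lapply(cells, function(cl) {
        sub <- traces[traces$cell == cl, , drop = FALSE]
        if (!all(c(405, 488) %in% sub$wavelength_nm))
            stop("cell ", cl, " is missing a wavelength condition")
        det <- lapply(c(405, 488), function(w) {
            s <- sub[sub$wavelength_nm == w, , drop = FALSE]
            detectResponse(data.frame(time_s = s$time_s, dff = s$dff),
                           onset_s, offset_s, ...)
        })
        c405 <- det[[1]]$response_class
        c488 <- det[[2]]$response_class
        weak488 <- c488 == "none" ||
            (!is.na(det[[2]]$depol_peak) && !is.na(det[[1]]$depol_peak) &&
             det[[2]]$depol_peak < weakRatio * det[[1]]$depol_peak)
        joint <- if (c405 == "biphasic_cPRC" && c488 == "hyperpolarizing_only")
                "cPRC_like"
            else if (c405 %in% c("biphasic_cPRC", "hyperpolarizing_only") &&
                     c488 == "none") "RGW_follower"
            else if (c405 == "onset_depolarizing" && c488 == "none") "SN_early"
            else if (c405 == "delayed_depolarizing" && weak488) "SN_late"
            else "none"
        data.frame(cell = cl, class_405 = c405, class_488 = c488,
                   joint_class = joint, stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Read / write fluorescence movies as multi-page TIFF
#'
#' Intensities are stored as 32-bit float scaled to [0, 1] by
#' \code{maxIntensity}; \code{readMovieTiff} multiplies back. Stimulus
#' annotations are not stored in the TIFF and must be re-attached.
#'
#' @param file TIFF path.
#' @param frameInterval_s frame interval to attach on read.
#' @param maxIntensity intensity corresponding to 1.0 in the file.
#' @return \code{readMovieTiff}: a \linkS4class{FluorescenceMovie}.
#' @export
readMovieTiff <- function(file, frameInterval_s = 0.8, maxIntensity = 1) {
    pages <- tiff::readTIFF(file, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    arr <- array(0, c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
    for (i in seq_along(pages)) arr[i, , ] <- pages[[i]] * maxIntensity
    FluorescenceMovie(arr, frameInterval_s)
}

#' @rdname readMovieTiff
#' @param movie a \linkS4class{FluorescenceMovie} to write.
#' @export
writeMovieTiff <- function(movie, file, maxIntensity = max(movieFrames(movie))) {
    f <- movieFrames(movie)
    pages <- lapply(seq_len(dim(f)[1]), function(i)
        pmin(pmax(f[i, , ] / maxIntensity, 0), 1))
    tiff::writeTIFF(pages, file, bits.per.sample = 32L)
    invisible(file)
}
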