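#' @include AllClasses.R AllGenerics.R
NULL

#' Preset analysis windows for vertical-column assays
#'
#' Windows in seconds relative to stimulus onset: \code{"fig3E"}
#' (1.5--3.5 min, the vertical-swimming action-spectrum window),
#' \code{"methods_action"} (the last 2 min of a 3.5-min stimulus, i.e.
#' also 90--210 s), \code{"cuvette"} (the last 45 s of a 60-s cuvette
#' stimulus) and \code{"ratio"} (the last 2 min of a 4-min ratio-mixture
#' condition).
#'
#' @param preset window name.
#' @return Numeric length-2 (start, end) in seconds.
#' @export
analysisWindow <- function(preset = c("fig3E", "methods_action", "cuvette",
                                      "ratio")) {
    switch(match.arg(preset),
           fig3E = c(90, 210),
           methods_action = c(90, 210),
           cuvette = c(15, 60),
           ratio = c(120, 240))
}

.larvaZAt <- function(samples, times) {
    # linear interpolation of z(t); NA outside the larva's recording
    sp <- split(samples, samples$larva_id)
    do.call(rbind, lapply(names(sp), function(id) {
        s <- sp[[id]]
        z <- if (nrow(s) > 1)
            stats::approx(s$t_s, s$z_mm, xout = times, rule = 1)$y
        else ifelse(times == s$t_s, s$z_mm, NA_real_)
        data.frame(larva_id = id, t(z), stringsAsFactors = FALSE)
    }))
}

#' Binned vertical displacement across larvae
#'
#' For each contiguous half-open time bin, the mean over larvae of the
#' vertical displacement z(bin end) - z(bin start), positive upward.
#' Larvae not present for the whole bin are excluded from that bin, so
#' partial residence never biases the bin mean.
#'
#' @param trajs a \linkS4class{TrajectorySet}.
#' @param binWidth_s bin width in seconds (default 30 s).
#' @param tStart_s time of the first bin edge (default 0).
#' @return data.frame with one row per bin: \code{bin_start_s},
#'   \code{bin_end_s}, \code{mean_mm}, \code{se_mm}, \code{n}.
#' @export
binDisplacement <- function(trajs, binWidth_s = 30, tStart_s = 0) {
    if (binWidth_s <= 0) stop("bin width must be positive")
    s <- trajectorySamples(trajs)
    if (!nrow(s)) stop("no trajectories")
    edges <- seq(tStart_s, max(s$t_s), by = binWidth_s)
    if (length(edges) < 2) stop("recording shorter than one bin")
    z <- .larvaZAt(s, edges)
    zm <- as.matrix(z[, -1, drop = FALSE])
    out <- lapply(seq_len(length(edges) - 1), function(i) {
        d <- zm[, i + 1] - zm[, i]
        d <- d[!is.na(d)]
        data.frame(bin_start_s = edges[i], bin_end_s = edges[i + 1],
                   mean_mm = if (length(d)) mean(d) else NA_real_,
                   se_mm = if (length(d) > 1)
                       stats::sd(d) / sqrt(length(d)) else NA_real_,
                   n = length(d))
    })
    do.call(rbind, out)
}

#' Net vertical displacement over an analysis window
#'
#' Two estimators, positive upward. \code{"per_larva"} (default): mean
#' over larvae of z(window end) - z(window start), each larva tracked
#' across the whole window. \code{"center_of_mass"}: displacement of
#' the population mean depth between the two window edges, using every
#' larva present at each edge; the two coincide exactly when all larvae
#' span the window, but the centre-of-mass proxy tolerates track
#' turnover at the cost of mixing composition changes into the
#' displacement.
#'
#' @param trajs a \linkS4class{TrajectorySet}.
#' @param window numeric length-2 (start, end) in seconds, e.g. from
#'   \code{\link{analysisWindow}}.
#' @param method displacement estimator.
#' @return List with \code{mean_mm}, \code{se_mm}, \code{n} and, for
#'   the per-larva estimator, \code{per_larva} (named vector of
#'   per-larva displacements).
#' @export
netDisplacement <- function(trajs, window,
                            method = c("per_larva", "center_of_mass")) {
    method <- match.arg(method)
    s <- trajectorySamples(trajs)
    if (!nrow(s)) stop("no trajectories")
    if (window[1] >= window[2] || window[1] < min(s$t_s) ||
        window[2] > max(s$t_s))
        stop("analysis window outside the recording")
    z <- .larvaZAt(s, window)
    if (method == "center_of_mass") {
        z0 <- z[, 2][!is.na(z[, 2])]
        z1 <- z[, 3][!is.na(z[, 3])]
        if (!length(z0) || !length(z1))
            stop("no larva present at a window edge")
        return(list(mean_mm = mean(z1) - mean(z0),
                    se_mm = sqrt(stats::var(z1) / length(z1) +
                                 stats::var(z0) / length(z0)),
                    n = min(length(z0), length(z1))))
    }
    d <- z[, 3] - z[, 2]
    names(d) <- z$larva_id
    d <- d[!is.na(d)]
    if (!length(d)) stop("no larva spans the analysis window")
    list(mean_mm = mean(d),
         se_mm = if (length(d) > 1) stats::sd(d) / sqrt(length(d)) else NA_real_,
         n = length(d), per_larva = d)
}

#' Classify instantaneous heading direction
#'
#' Sign of the per-second vertical velocity with a symmetric dead-band:
#' velocities within \code{deadband_mm_s} of zero are \code{"neutral"},
#' larger upward velocities \code{"up"}, larger downward ones
#' \code{"down"}. Velocity is the forward difference between successive
#' samples of each larva; the last sample of each track repeats the
#' previous heading.
#'
#' @param trajs a \linkS4class{TrajectorySet}.
#' @param deadband_mm_s half-width of the neutral velocity band.
#' @return The sample table with \code{vz_mm_s} and \code{heading}
#'   columns appended.
#' @export
headingDirection <- function(trajs, deadband_mm_s = 0.1) {
    s <- trajectorySamples(trajs)
    sp <- split(seq_len(nrow(s)), s$larva_id)
    s$vz_mm_s <- NA_real_
    for (idx in sp) {
        if (length(idx) < 2) next
        v <- diff(s$z_mm[idx]) / diff(s$t_s[idx])
        s$vz_mm_s[idx] <- c(v, v[length(v)])
    }
    s$heading <- ifelse(is.na(s$vz_mm_s), NA_character_,
                 ifelse(s$vz_mm_s > deadband_mm_s, "up",
                 ifelse(s$vz_mm_s < -deadband_mm_s, "down", "neutral")))
    s
}

#' Action spectrum of vertical swimming
#'
#' Net vertical displacement per stimulus wavelength within a common
#' analysis window, assuming equal-photon-flux stimuli across
#' wavelengths. Downward swimming (avoidance) is negative, upward
#' (phototaxis) positive.
#'
#' @param trials named list mapping wavelength (nm, as names) to
#'   \linkS4class{TrajectorySet} objects.
#' @param window numeric length-2 analysis window, seconds.
#' @return data.frame with columns \code{wavelength_nm}, \code{net_mm},
#'   \code{se_mm}, \code{n}, sorted by wavelength.
#' @export
actionSpectrum <- function(trials, window = analysisWindow("fig3E")) {
    if (!length(trials)) stop("empty trial set")
    out <- do.call(rbind, lapply(names(trials), function(w) {
        nd <- netDisplacement(trials[[w]], window)
        data.frame(wavelength_nm = as.numeric(w), net_mm = nd$mean_mm,
                   se_mm = nd$se_mm, n = nd$n)
    }))
    out <- out[order(out$wavelength_nm), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Balance point of a ratio-response curve
#'
#' The UV fraction at which antagonistic upward (phototaxis) and
#' downward (UV avoidance) drives cancel and net vertical displacement
#' crosses zero. The crossing is located by linear interpolation between
#' the two grid fractions bracketing the sign change from positive to
#' negative; with multiple crossings, the one whose positive endpoint is
#' largest is taken. A fraction with exactly zero response is returned
#' as-is.
#'
#' @param fractions strictly increasing UV fractions in [0, 1].
#' @param response net displacement (mm) per fraction, positive upward.
#' @return Interpolated UV fraction of zero net displacement.
#' @export
balancePoint <- function(fractions, response) {
    if (length(fractions) != length(response) || length(fractions) < 2)
        stop("fractions and response must be equal-length (>= 2)")
    if (any(diff(fractions) <= 0))
        stop("fractions must be strictly increasing")
    if (any(response == 0))
        return(fractions[which(response == 0)[1]])
    cand <- which(response[-length(response)] > 0 & response[-1] < 0)
    if (!length(cand))
        stop("no sign change: response does not cross zero")
    i <- cand[which.max(response[cand])]
    fractions[i] + (fractions[i + 1] - fractions[i]) *
        response[i] / (response[i] - response[i + 1])
}

.sidakAlpha <- function(alpha, m) 1 - (1 - alpha)^(1 / m)

#' Welch t-tests with Holm-Sidak or Sidak-Bonferroni correction
#'
#' Runs a Welch (unequal-variance) two-sample t-test for each of m
#' paired group comparisons and applies a family-wise correction.
#' Holm-Sidak is step-down: p-values are sorted ascending and compared
#' to alpha_i = 1 - (1 - alpha)^(1/(m - i + 1)), rejecting until the
#' first failure. Sidak-Bonferroni is single-step with
#' alpha' = 1 - (1 - alpha)^(1/m); its rejections are always a subset
#' of Holm-Sidak's. Comparisons where both groups are constant are
#' flagged degenerate and never rejected.
#'
#' @param a,b numeric vectors (one comparison) or lists of numeric
#'   vectors (m comparisons, paired by position).
#' @param correction \code{"holm_sidak"} or \code{"sidak_bonferroni"}.
#' @param alpha family-wise error rate.
#' @return data.frame with one row per comparison: \code{comparison},
#'   \code{t}, \code{df}, \code{p}, \code{alpha_adj}, \code{reject},
#'   \code{degenerate}.
#' @export
compareGroups <- function(a, b, correction = c("holm_sidak",
                                               "sidak_bonferroni"),
                          alpha = 0.05) {
    correction <- match.arg(correction)
    if (!is.list(a)) a <- list(a)
    if (!is.list(b)) b <- list(b)
    if (length(a) != length(b))
        stop("a and b must contain the same number of groups")
    m <- length(a)
    res <- do.call(rbind, lapply(seq_len(m), function(i) {
        x <- a[[i]]; y <- b[[i]]
        if (length(x) < 2 || length(y) < 2)
            stop("at least 2 observations per group required")
        if (stats::sd(x) == 0 && stats::sd(y) == 0)
            return(data.frame(comparison = i, t = NA_real_, df = NA_real_,
                              p = NA_real_, degenerate = TRUE))
        tt <- stats::t.test(x, y, var.equal = FALSE)
        data.frame(comparison = i, t = unname(tt$statistic),
                   df = unname(tt$parameter), p = tt$p.value,
                   degenerate = FALSE)
    }))
    res$alpha_adj <- NA_real_
    res$reject <- FALSE
    ok <- which(!res$degenerate)
    if (length(ok)) {
        if (correction == "sidak_bonferroni") {
            res$alpha_adj[ok] <- .sidakAlpha(alpha, m)
            res$reject[ok] <- res$p[ok] <= res$alpha_adj[ok]
        } else {
            ord <- ok[order(res$p[ok])]
            for (r in seq_along(ord)) {
                ai <- .sidakAlpha(alpha, m - r + 1)
                res$alpha_adj[ord[r]] <- ai
                if (res$p[ord[r]] <= ai) res$reject[ord[r]] <- TRUE
                else break   # step-down stops at the first failure
            }
        }
    }
    res[, c("comparison", "t", "df", "p", "alpha_adj", "reject", "degenerate")]
}

#' Track swimming larvae in a video stack
#'
#' Per-frame detections are centroids of connected components of pixels
#' above \code{intensityThreshold}; detections are linked across
#' consecutive frames by greedy nearest-neighbour assignment (closest
#' pair first, ties broken toward the lower track id) within
#' \code{maxLinkDistance_px}; unmatched detections seed new tracks and
#' tracks missing a frame are closed (no gap bridging, adequate at the
#' low larval densities of column assays but a documented limitation
#' for crossing tracks). Tracks shorter than \code{minTrackLength}
#' frames are dropped. Pixel rows increase downward, so z (upward, mm)
#' is \code{(frame rows - row) * mmPerPx}.
#'
#' @param frames 3-D array (frame, row, column) of video intensities.
#' @param intensityThreshold detection threshold on pixel intensity.
#' @param maxLinkDistance_px maximum frame-to-frame displacement.
#' @param minTrackLength minimum track length in frames.
#' @param mmPerPx spatial calibration (required).
#' @param frameInterval_s temporal calibration.
#' @param arenaHeight_mm water-column height; default inferred from the
#'   frame height and calibration.
#' @return A \linkS4class{TrajectorySet}.
#' @export
trackParticles <- function(frames, intensityThreshold, maxLinkDistance_px = 10,
                           minTrackLength = 3, mmPerPx = NULL,
                           frameInterval_s = 1,
                           arenaHeight_mm = NULL) {
    if (is.null(mmPerPx)) stop("spatial calibration mmPerPx is required")
    d <- dim(frames)
    if (is.null(arenaHeight_mm)) arenaHeight_mm <- d[2] * mmPerPx
    nextId <- 1L
    active <- data.frame(id = integer(0), row = numeric(0), col = numeric(0))
    pts <- vector("list", d[1])
    for (t in seq_len(d[1])) {
        bin <- frames[t, , ] > intensityThreshold
        det <- NULL
        if (any(bin)) {
            lab <- EBImage::bwlabel(bin + 0)
            ij <- which(lab > 0, arr.ind = TRUE)
            lv <- lab[lab > 0]
            det <- data.frame(
                row = as.vector(tapply(ij[, 1], lv, mean)),
                col = as.vector(tapply(ij[, 2], lv, mean)))
        }
        if (is.null(det) || !nrow(det)) { active <- active[0, ]; next }
        assigned <- rep(NA_integer_, nrow(det))
        if (nrow(active)) {
            dist <- outer(active$row, det$row, "-")^2 +
                    outer(active$col, det$col, "-")^2
            cand <- which(dist <= maxLinkDistance_px^2, arr.ind = TRUE)
            if (nrow(cand)) {
                ordc <- order(dist[cand], active$id[cand[, 1]])
                usedTrack <- logical(nrow(active))
                for (k in ordc) {
                    ti <- cand[k, 1]; di <- cand[k, 2]
                    if (!usedTrack[ti] && is.na(assigned[di])) {
                        usedTrack[ti] <- TRUE
                        assigned[di] <- active$id[ti]
                    }
                }
            }
        }
        newIdx <- which(is.na(assigned))
        if (length(newIdx)) {
            assigned[newIdx] <- seq(nextId, length.out = length(newIdx))
            nextId <- nextId + length(newIdx)
        }
        active <- data.frame(id = assigned, row = det$row, col = det$col)
        pts[[t]] <- data.frame(larva_id = assigned, frame = t,
                               row = det$row, col = det$col)
    }
    allPts <- do.call(rbind, pts)
    if (is.null(allPts) || !nrow(allPts))
        return(TrajectorySet(data.frame(larva_id = character(0),
                                        t_s = numeric(0), x_mm = numeric(0),
                                        z_mm = numeric(0)),
                             arenaHeight_mm))
    keep <- names(which(table(allPts$larva_id) >= minTrackLength))
    allPts <- allPts[allPts$larva_id %in% as.integer(keep), , drop = FALSE]
    samples <- data.frame(
        larva_id = sprintf("track_%04d", allPts$larva_id),
        t_s = (allPts$frame - 1) * frameInterval_s,
        x_mm = allPts$col * mmPerPx,
        z_mm = pmin(pmax((d[2] - allPts$row) * mmPerPx, 0), arenaHeight_mm),
        stringsAsFactors = FALSE)
    TrajectorySet(samples, arenaHeight_mm)
}
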