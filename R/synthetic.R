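#' @include AllClasses.R AllGenerics.R stimulus.R
NULL

.withSeed <- function(seed, code) {
    if (is.null(seed)) code else withr::with_seed(seed, code)
}

#' Reference connectome fixture specification
#'
#' Per-class cell counts and per-edge-class synapse-count ranges for
#' \code{\link{makeReferenceConnectome}}. The counts of cPRC (4),
#' IN_RGW (4), IN_preMN (6), MS (2) and Ser_h1 (2) cells are fixed
#' properties of the reconstructed circuit and cannot be overridden.
#'
#' @param SN_flask,IN_sn,vMN,IN_pro,rPRC_adult_eye configurable class
#'   sizes (minimum 4, 2, 2, 2, 1 respectively).
#' @param synapseRange integer length-2: uniform range for per-edge
#'   synapse counts.
#' @return List of class counts plus the synapse range.
#' @export
connectomeFixtureSpec <- function(SN_flask = 4, IN_sn = 2, vMN = 2,
                                  IN_pro = 2, rPRC_adult_eye = 4,
                                  synapseRange = c(2L, 10L)) {
    if (SN_flask < 4 || IN_sn < 2 || vMN < 2 || IN_pro < 2 ||
        rPRC_adult_eye < 1)
        stop("configurable class sizes below their minima")
    list(counts = c(cPRC = 4L, IN_RGW = 4L, IN_NOS = 4L,
                    SN_flask = as.integer(SN_flask),
                    IN_sn = as.integer(IN_sn), IN_preMN = 6L, MS = 2L,
                    vMN = as.integer(vMN), IN_pro = as.integer(IN_pro),
                    rPRC_eyespot = 2L,
                    rPRC_adult_eye = as.integer(rPRC_adult_eye),
                    Ser_h1 = 2L, MC = 1L, ciliary_band = 2L),
         synapseRange = as.integer(synapseRange))
}

# directed edge classes realized by the fixture (presynaptic -> postsynaptic);
# SN_flask has no outgoing edges, and no rPRC-circuit cell feeds the cPRC
# circuit, so the reverse bridge search is empty by construction
.fixtureEdgeClasses <- function() {
    rbind(
        c("cPRC", "IN_RGW"), c("cPRC", "IN_NOS"), c("cPRC", "SN_flask"),
        c("IN_RGW", "IN_sn"), c("IN_RGW", "IN_preMN"), c("IN_RGW", "MS"),
        c("IN_RGW", "Ser_h1"),
        c("IN_preMN", "vMN"),
        c("MS", "vMN"), c("MS", "IN_pro"),
        c("rPRC_adult_eye", "IN_pro"), c("IN_pro", "IN_sn"),
        c("IN_sn", "vMN"),
        c("rPRC_eyespot", "ciliary_band"), c("rPRC_eyespot", "vMN"),
        c("Ser_h1", "MC"))
}

#' Deterministic reference connectome emulating the larval head circuits
#'
#' Generates a cell table and synapse matrix whose topology realizes
#' the circuit organization used throughout the package: ciliary
#' photoreceptors project onto RGW/NOS interneurons and flask sensory
#' neurons (which have no postsynaptic partners); RGW interneurons
#' contact the rhabdomeric visual circuit directly (onto the Schnoerkel
#' interneurons) and indirectly through six premotor interneurons and
#' two median mechanosensory cells; adult-eye photoreceptors reach the
#' ventral motoneurons through three interneuron layers
#' (IN_pro -> IN_sn -> vMN); eyespot photoreceptors contact the ciliary
#' band and motoneurons; no cell of the rPRC circuit feeds back into
#' the cPRC circuit.
#'
#' @param spec from \code{\link{connectomeFixtureSpec}}.
#' @param seed RNG seed for the synapse-count draws.
#' @param deterministic if \code{TRUE}, every synapse count is pinned
#'   to the midpoint of the spec range (no randomness at all).
#' @return A \linkS4class{SynapseMatrix}.
#' @export
makeReferenceConnectome <- function(spec = connectomeFixtureSpec(), seed = 1,
                                    deterministic = FALSE) {
    fixed <- c(cPRC = 4L, IN_RGW = 4L, IN_preMN = 6L, MS = 2L, Ser_h1 = 2L)
    if (!all(spec$counts[names(fixed)] == fixed))
        stop("spec alters a fixed class count")
    cls <- rep(names(spec$counts), spec$counts)
    idx <- unlist(lapply(spec$counts, seq_len), use.names = FALSE)
    ids <- paste0(cls, "_", idx)
    side <- ifelse(cls %in% c("MS", "MC"), "median",
                   ifelse(idx %% 2 == 1, "left", "right"))
    cells <- data.frame(cell_id = ids, name = ids, cell_class = cls,
                        side = side, stringsAsFactors = FALSE)
    n <- length(ids)
    m <- matrix(0L, n, n, dimnames = list(ids, ids))
    ec <- .fixtureEdgeClasses()
    rng <- spec$synapseRange
    .withSeed(if (deterministic) NULL else seed, {
        for (e in seq_len(nrow(ec))) {
            pre <- which(cls == ec[e, 1])
            post <- which(cls == ec[e, 2])
            k <- length(pre) * length(post)
            cnt <- if (deterministic)
                rep(as.integer(round(mean(rng))), k)
            else sample(seq(rng[1], rng[2]), k, replace = TRUE)
            m[pre, post] <- matrix(cnt, length(pre), length(post))
        }
    })
    SynapseMatrix(m, cells)
}

#' Synthetic ciliary branch set with target total length
#'
#' Branch lengths are drawn and rescaled so they sum exactly to
#' \code{totalLength_um}; diameters are Gaussian around the measured
#' branch calibre (130 nm mean, 19 nm s.d.), truncated positive.
#'
#' @param nBranches number of branches.
#' @param diameterMean_nm,diameterSd_nm diameter distribution, nm.
#' @param totalLength_um target summed branch length, um.
#' @param seed RNG seed.
#' @return A \linkS4class{CiliaryBranchSet}.
#' @export
makeBranchSet <- function(nBranches = 100, diameterMean_nm = 130,
                          diameterSd_nm = 19, totalLength_um = 677,
                          seed = 1) {
    stopifnot(nBranches >= 1, diameterMean_nm > 0, totalLength_um > 0)
    .withSeed(seed, {
        len <- stats::rexp(nBranches)
        len <- len / sum(len) * totalLength_um
        dia <- stats::rnorm(nBranches, diameterMean_nm, diameterSd_nm)
        while (any(dia <= 0))
            dia[dia <= 0] <- stats::rnorm(sum(dia <= 0), diameterMean_nm,
                                          diameterSd_nm)
        CiliaryBranchSet(dia, len)
    })
}

.lognormTemplate <- function(wl, lambdaMax, halfWidth) {
    # unit-peak log-normal-in-wavelength bump with FWHM ~ halfWidth nm
    sigma <- log((lambdaMax + halfWidth / 2) / (lambdaMax - halfWidth / 2)) /
        (2 * sqrt(2 * log(2)))
    exp(-(log(wl / lambdaMax))^2 / (2 * sigma^2))
}

#' Synthetic opsin dark / bleached spectrum pair
#'
#' The dark spectrum is a unit-peak log-normal-in-wavelength bump at
#' \code{lambdaMaxDark}; the bleached spectrum is the dark spectrum
#' minus a depletion bump at \code{lambdaMaxDiff} (clamped at zero), so
#' the dark-minus-light difference peaks at \code{lambdaMaxDiff} by
#' construction. This is a behavioural stand-in for a measured pigment
#' spectrum, not a model of opsin photochemistry.
#'
#' @param lambdaMaxDark_nm dark-spectrum peak, nm.
#' @param lambdaMaxDiff_nm difference-spectrum peak, nm.
#' @param halfWidth_nm approximate FWHM of the bumps, nm.
#' @param noise Gaussian noise s.d. added to both spectra (absorbance
#'   units; peak height is 1).
#' @param grid_nm wavelength grid.
#' @param depletion amplitude of the depletion bump.
#' @param seed RNG seed.
#' @return List: \code{dark} and \code{bleached}
#'   (\linkS4class{AbsorbanceSpectrum} objects) plus the ground-truth
#'   \code{lambdaMaxDark_nm} and \code{lambdaMaxDiff_nm}.
#' @export
simulateSpectrum <- function(lambdaMaxDark_nm = 384, lambdaMaxDiff_nm = 370,
                             halfWidth_nm = 50, noise = 0.01,
                             grid_nm = seq(330, 500), depletion = 0.5,
                             seed = 1) {
    if (lambdaMaxDark_nm < min(grid_nm) || lambdaMaxDark_nm > max(grid_nm))
        stop("lambdaMax must lie within the grid")
    dark <- .lognormTemplate(grid_nm, lambdaMaxDark_nm, halfWidth_nm)
    dep <- depletion * .lognormTemplate(grid_nm, lambdaMaxDiff_nm, halfWidth_nm)
    bleached <- pmax(dark - dep, 0)
    .withSeed(seed, {
        if (noise > 0) {
            dark <- dark + stats::rnorm(length(grid_nm), 0, noise)
            bleached <- bleached + stats::rnorm(length(grid_nm), 0, noise)
        }
        list(dark = AbsorbanceSpectrum(grid_nm, dark),
             bleached = AbsorbanceSpectrum(grid_nm, bleached),
             lambdaMaxDark_nm = lambdaMaxDark_nm,
             lambdaMaxDiff_nm = lambdaMaxDiff_nm)
    })
}

#' Parameters of the synthetic fluorescence-movie generator
#'
#' Plants Gaussian-blob cells of the circuit's response classes on a
#' uniform background. Ciliary photoreceptors get an elevated resting
#' amplitude (their high resting calcium makes them identifiable
#' without stimulation); the knockout mode lowers it and flattens their
#' response kernels.
#'
#' @param frameDim (rows, cols) of the movie.
#' @param cells data.frame with columns \code{cell}, \code{class}
#'   (one of \code{cPRC}, \code{RGW}, \code{SN_early}, \code{SN_late}),
#'   \code{row}, \code{col}, \code{radius_px}; default plants one cell
#'   of each class in separate quadrants.
#' @param background background intensity (counts).
#' @param restingAmplitude named vector of per-class blob amplitudes.
#' @param photonNoise noise scale: per-pixel Gaussian noise with s.d.
#'   \code{photonNoise * sqrt(intensity)} (Poisson-like); 0 disables.
#' @param knockout flatten cPRC kernels and lower cPRC resting signal.
#' @return Parameter list for \code{\link{simulateMovie}}.
#' @export
movieModelParams <- function(frameDim = c(64, 64),
        cells = data.frame(
            cell = c("cPRC_a", "RGW_a", "SNe_a", "SNl_a"),
            class = c("cPRC", "RGW", "SN_early", "SN_late"),
            row = c(16, 16, 48, 48), col = c(16, 48, 16, 48),
            radius_px = 4, stringsAsFactors = FALSE),
        background = 100,
        restingAmplitude = c(cPRC = 300, RGW = 150, SN_early = 150,
                             SN_late = 150),
        photonNoise = 1, knockout = FALSE) {
    if (any(cells$row < 1) || any(cells$row > frameDim[1]) ||
        any(cells$col < 1) || any(cells$col > frameDim[2]))
        stop("planted cell outside the frame")
    list(frameDim = frameDim, cells = cells, background = background,
         restingAmplitude = restingAmplitude, photonNoise = photonNoise,
         knockout = knockout)
}

# wavelength-conditional response kernels (delta-F/F relative to resting);
# t is time in seconds since stimulus onset, negative before
.responseKernel <- function(class, wavelength_nm, t, knockout = FALSE) {
    k <- numeric(length(t))
    on <- t >= 0
    if (class == "cPRC" && !knockout) {
        if (wavelength_nm < 450) {          # UV-violet: biphasic
            k[on & t < 16] <- -0.4
            ramp <- on & t >= 16
            k[ramp] <- 2.0 * (1 - exp(-(t[ramp] - 16) / 10))
        } else {                            # blue: prolonged dip only
            k[on] <- -0.4
        }
    } else if (class == "RGW") {
        if (wavelength_nm < 450) {
            k[on & t < 16] <- -0.25
            ramp <- on & t >= 16
            k[ramp] <- 1.2 * (1 - exp(-(t[ramp] - 16) / 10))
        }
    } else if (class == "SN_early") {
        if (wavelength_nm < 450) {
            ramp <- on & t >= 2
            k[ramp] <- 1.5 * (1 - exp(-(t[ramp] - 2) / 5))
        }
    } else if (class == "SN_late") {
        if (wavelength_nm < 450) {
            ramp <- on & t >= 20
            k[ramp] <- 1.5 * (1 - exp(-(t[ramp] - 20) / 10))
        }
    }
    k
}

#' Simulate a calcium-imaging movie with planted response classes
#'
#' Each planted cell is a Gaussian blob whose amplitude is modulated by
#' a wavelength-conditional response kernel: biphasic (dip then strong
#' rise) for ciliary photoreceptors under UV-violet light, a prolonged
#' dip only under blue light, a scaled biphasic response for RGW
#' followers under UV-violet only, and onset / delayed depolarizations
#' for the early and late sensory neurons under UV-violet only.
#' Poisson-like noise is added per pixel. Ground truth is returned
#' alongside the movie.
#'
#' @param params from \code{\link{movieModelParams}}.
#' @param wavelength_nm stimulation wavelength (405 or 488 in the
#'   standard programs).
#' @param nFrames total frames.
#' @param onsetFrame,offsetFrame stimulus window (frames, 1-based).
#' @param frameInterval_s frame interval (default 0.8 s = 1.25/s).
#' @param seed RNG seed.
#' @return List: \code{movie} (\linkS4class{FluorescenceMovie}) and
#'   \code{truth} (the planted cell table with its classes).
#' @export
simulateMovie <- function(params = movieModelParams(), wavelength_nm = 405,
                          nFrames = 150, onsetFrame = 25, offsetFrame = 100,
                          frameInterval_s = 0.8, seed = 1) {
    d <- params$frameDim
    tRel <- (seq_len(nFrames) - onsetFrame) * frameInterval_s
    base <- matrix(params$background, d[1], d[2])
    blobs <- list()
    for (i in seq_len(nrow(params$cells))) {
        ci <- params$cells[i, ]
        amp <- params$restingAmplitude[[ci$class]]
        if (params$knockout && ci$class == "cPRC") amp <- amp * 0.2
        g <- outer((seq_len(d[1]) - ci$row)^2, (seq_len(d[2]) - ci$col)^2, "+")
        blobs[[i]] <- list(profile = amp * exp(-g / (2 * ci$radius_px^2)),
                           kernel = .responseKernel(ci$class, wavelength_nm,
                                                    tRel, params$knockout))
    }
    arr <- array(0, c(nFrames, d[1], d[2]))
    .withSeed(seed, {
        for (f in seq_len(nFrames)) {
            img <- base
            for (b in blobs)
                img <- img + b$profile * (1 + b$kernel[f])
            img <- pmax(img, 0)
            if (params$photonNoise > 0)
                img <- img + stats::rnorm(length(img),
                                          sd = params$photonNoise * sqrt(img))
            arr[f, , ] <- pmax(img, 0)
        }
    })
    movie <- FluorescenceMovie(arr, frameInterval_s,
        data.frame(onset_frame = onsetFrame, offset_frame = offsetFrame,
                   wavelength_nm = wavelength_nm))
    list(movie = movie, truth = params$cells)
}

.raisedCosine <- function(wl, center, halfSupport) {
    x <- abs(wl - center) / halfSupport
    ifelse(x <= 1, 0.5 * (1 + cos(pi * x)), 0)
}

#' Parameters of the larval vertical-swimming generator
#'
#' A drift-diffusion model of vertical position driven by two
#' antagonistic photoresponses: a broad phototactic (upward) spectral
#' sensitivity spanning roughly 380--600 nm and a UV-violet avoidance
#' (downward) sensitivity peaked near 380 nm, engaging only after a
#' latency of about one minute. Both are simple raised-cosine bumps —
#' behavioural stand-ins anchored to the observed wavelength boundaries
#' (downward swimming at 340--400 nm, upward at 440--600 nm, neutral
#' near 420 nm), not opsin absorption spectra. The avoidance speed is
#' calibrated so that the two drives cancel exactly at
#' \code{balanceFraction} under the 380/480 nm mixture (solving the
#' zero-drift condition for the avoidance speed); the knockout mode
#' removes the avoidance drive entirely.
#'
#' @param vPhototaxis_mm_s upward drift speed scale, mm/s.
#' @param ptCenter_nm,ptHalfSupport_nm raised-cosine centre and
#'   half-support of the phototaxis sensitivity.
#' @param uvCenter_nm,uvHalfSupport_nm same for the avoidance
#'   sensitivity.
#' @param avoidanceLatency_s delay before the avoidance drive engages
#'   (default 60 s); a hard switch by default.
#' @param smoothLatency if \code{TRUE}, the avoidance drive ramps up
#'   linearly over 20 s around the latency instead of switching.
#' @param noise_mm_sqrt_s diffusion scale of vertical position.
#' @param balanceFraction UV fraction of the 380/480 mixture at which
#'   net drift is zero (default 0.40).
#' @param knockout disable the avoidance drive (UV-insensitive mutant).
#' @param arenaHeight_mm,arenaWidth_mm column dimensions.
#' @return Parameter list with the calibrated avoidance speed
#'   \code{vAvoidance_mm_s}.
#' @export
behaviorModelParams <- function(vPhototaxis_mm_s = 0.3, ptCenter_nm = 490,
                                ptHalfSupport_nm = 130, uvCenter_nm = 380,
                                uvHalfSupport_nm = 60,
                                avoidanceLatency_s = 60,
                                smoothLatency = FALSE,
                                noise_mm_sqrt_s = 0.5,
                                balanceFraction = 0.40, knockout = FALSE,
                                arenaHeight_mm = 160, arenaWidth_mm = 31) {
    if (vPhototaxis_mm_s < 0 || noise_mm_sqrt_s < 0 || avoidanceLatency_s < 0)
        stop("speeds, noise and latency must be nonnegative")
    p <- list(vPhototaxis_mm_s = vPhototaxis_mm_s, ptCenter_nm = ptCenter_nm,
              ptHalfSupport_nm = ptHalfSupport_nm, uvCenter_nm = uvCenter_nm,
              uvHalfSupport_nm = uvHalfSupport_nm,
              avoidanceLatency_s = avoidanceLatency_s,
              smoothLatency = smoothLatency,
              noise_mm_sqrt_s = noise_mm_sqrt_s,
              balanceFraction = balanceFraction, knockout = knockout,
              arenaHeight_mm = arenaHeight_mm, arenaWidth_mm = arenaWidth_mm)
    # calibration: v_uv solves  v_pt * S_pt_eff(b) = v_uv * S_uv_eff(b)
    # for the 380/480 mixture at the balance fraction b
    b <- balanceFraction
    sPt <- b * .raisedCosine(380, ptCenter_nm, ptHalfSupport_nm) +
        (1 - b) * .raisedCosine(480, ptCenter_nm, ptHalfSupport_nm)
    sUv <- b * .raisedCosine(380, uvCenter_nm, uvHalfSupport_nm) +
        (1 - b) * .raisedCosine(480, uvCenter_nm, uvHalfSupport_nm)
    if (sUv <= 0) stop("avoidance sensitivity vanishes at the balance mixture")
    p$vAvoidance_mm_s <- vPhototaxis_mm_s * sPt / sUv
    p
}

.effectiveDrives <- function(params, schedule) {
    e <- epochs(schedule)
    f <- e$duration_ms / periodMs(schedule)
    c(pt = sum(f * .raisedCosine(e$wavelength_nm, params$ptCenter_nm,
                                 params$ptHalfSupport_nm)),
      uv = sum(f * .raisedCosine(e$wavelength_nm, params$uvCenter_nm,
                                 params$uvHalfSupport_nm)))
}

#' Analytic expected vertical drift of the swimming model
#'
#' Closed form of the generator's drive equation: before the avoidance
#' latency, drift = v_pt * S_pt(effective); after it,
#' drift = v_pt * S_pt - v_uv * S_uv, with the schedule's effective
#' sensitivities computed from its time-averaged wavelength fractions.
#'
#' @param params from \code{\link{behaviorModelParams}}.
#' @param schedule a \linkS4class{StimulusSchedule}.
#' @param phase \code{"pre"} (before latency) or \code{"post"}.
#' @return Drift in mm/s (positive upward).
#' @export
expectedDrift <- function(params, schedule, phase = c("post", "pre")) {
    phase <- match.arg(phase)
    s <- .effectiveDrives(params, schedule)
    drift <- params$vPhototaxis_mm_s * s[["pt"]]
    if (phase == "post" && !params$knockout)
        drift <- drift - params$vAvoidance_mm_s * s[["uv"]]
    drift
}

#' Simulate larval swimming trajectories in a vertical column
#'
#' Euler-Maruyama simulation of the drift-diffusion model in
#' \code{\link{behaviorModelParams}}: vertical drift from the two
#' antagonistic drives (avoidance engaging after its latency),
#' Gaussian positional noise, and reflecting boundaries at the column
#' floor and surface. Horizontal position is an independent reflected
#' random walk across the column width. Larvae start uniformly
#' distributed.
#'
#' @param params from \code{\link{behaviorModelParams}}.
#' @param schedule a \linkS4class{StimulusSchedule} (use
#'   \code{\link{dutyCycleSchedule}} with \code{uvFraction} 0 or 1 for
#'   monochromatic programs).
#' @param nLarvae number of larvae.
#' @param duration_s recording duration (default the schedule's total
#'   duration).
#' @param dt_s integration / sampling step.
#' @param seed RNG seed.
#' @return A \linkS4class{TrajectorySet}.
#' @export
simulateTrajectories <- function(params = behaviorModelParams(),
                                 schedule = dutyCycleSchedule(1, 395, 480),
                                 nLarvae = 50,
                                 duration_s = schedule@totalDuration_s,
                                 dt_s = 0.5, seed = 1) {
    stopifnot(nLarvae >= 1, duration_s > 0, dt_s > 0)
    s <- .effectiveDrives(params, schedule)
    H <- params$arenaHeight_mm
    W <- params$arenaWidth_mm
    times <- seq(0, duration_s, by = dt_s)
    nT <- length(times)
    .withSeed(seed, {
        z <- matrix(0, nT, nLarvae)
        x <- matrix(0, nT, nLarvae)
        z[1, ] <- stats::runif(nLarvae, 0, H)
        x[1, ] <- stats::runif(nLarvae, 0, W)
        sdStep <- params$noise_mm_sqrt_s * sqrt(dt_s)
        for (i in 2:nT) {
            t <- times[i - 1]
            gate <- if (params$knockout) 0
                else if (params$smoothLatency)
                    min(1, max(0, (t - params$avoidanceLatency_s + 10) / 20))
                else as.numeric(t > params$avoidanceLatency_s)
            drift <- params$vPhototaxis_mm_s * s[["pt"]] -
                gate * params$vAvoidance_mm_s * s[["uv"]]
            zn <- z[i - 1, ] + drift * dt_s + stats::rnorm(nLarvae, 0, sdStep)
            xn <- x[i - 1, ] + stats::rnorm(nLarvae, 0, sdStep)
            # reflecting boundaries
            for (rep in 1:3) {
                zn <- ifelse(zn < 0, -zn, zn)
                zn <- ifelse(zn > H, 2 * H - zn, zn)
                xn <- ifelse(xn < 0, -xn, xn)
                xn <- ifelse(xn > W, 2 * W - xn, xn)
            }
            z[i, ] <- pmin(pmax(zn, 0), H)
            x[i, ] <- pmin(pmax(xn, 0), W)
        }
        samples <- data.frame(
            larva_id = rep(sprintf("larva_%04d", seq_len(nLarvae)),
                           each = nT),
            t_s = rep(times, nLarvae),
            x_mm = as.vector(x), z_mm = as.vector(z),
            stringsAsFactors = FALSE)
        TrajectorySet(samples, H)
    })
}

#' Render a trajectory set as a synthetic tracking video
#'
#' Draws each larva as a Gaussian blob on a dark background with
#' optional sensor noise, at every sample time shared by the
#' trajectories. Row coordinates increase downward:
#' \code{row = rows - z/mmPerPx}. Particles whose centre falls outside
#' the frame are clipped with a warning.
#'
#' @param trajs a \linkS4class{TrajectorySet} whose larvae share a
#'   common time grid.
#' @param frameDim (rows, cols) in pixels.
#' @param mmPerPx spatial calibration.
#' @param particleRadius_px Gaussian blob s.d. in pixels.
#' @param amplitude blob peak intensity.
#' @param noise Gaussian sensor noise s.d.
#' @param seed RNG seed.
#' @return List: \code{frames} (3-D array), \code{times} (per-frame
#'   seconds), \code{mmPerPx}.
#' @export
renderVideo <- function(trajs, frameDim = NULL, mmPerPx = 1,
                        particleRadius_px = 2, amplitude = 100, noise = 2,
                        seed = 1) {
    s <- trajectorySamples(trajs)
    times <- sort(unique(s$t_s))
    H <- arenaHeight(trajs)
    if (is.null(frameDim))
        frameDim <- c(ceiling(H / mmPerPx) + 1,
                      ceiling(max(s$x_mm, 1) / mmPerPx) + 1)
    arr <- array(0, c(length(times), frameDim[1], frameDim[2]))
    clipped <- FALSE
    rows <- seq_len(frameDim[1]); cols <- seq_len(frameDim[2])
    .withSeed(seed, {
        for (i in seq_along(times)) {
            sub <- s[s$t_s == times[i], , drop = FALSE]
            img <- matrix(0, frameDim[1], frameDim[2])
            for (j in seq_len(nrow(sub))) {
                pr <- frameDim[1] - sub$z_mm[j] / mmPerPx
                pc <- sub$x_mm[j] / mmPerPx
                if (pr < 1 || pr > frameDim[1] || pc < 1 || pc > frameDim[2]) {
                    clipped <- TRUE
                    next
                }
                g <- outer((rows - pr)^2, (cols - pc)^2, "+")
                img <- img + amplitude * exp(-g / (2 * particleRadius_px^2))
            }
            if (noise > 0)
                img <- img + stats::rnorm(length(img), 0, noise)
            arr[i, , ] <- img
        }
    })
    if (clipped) warning("some particles fell outside the frame and were clipped")
    list(frames = arr, times = times, mmPerPx = mmPerPx)
}
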