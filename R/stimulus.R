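#' @include AllClasses.R AllGenerics.R
NULL

# CODATA constants, fixed so flux values are bit-reproducible
.PLANCK <- 6.62607015e-34   # J s
.C_LIGHT <- 2.99792458e8    # m / s

#' Photon flux of a monochromatic source
#'
#' Converts radiant power to photon rate via the photon energy
#' \eqn{E = hc/\lambda}: \code{flux = power * wavelength / (h c)}.
#'
#' @param power_w radiant power in watts (>= 0).
#' @param wavelength_nm wavelength in nanometres (> 0).
#' @return Photons per second.
#' @examples
#' photonFlux(5.59e-6, 405)   # ~1.1e13 photons/s
#' photonFlux(4.62e-6, 488)   # ~1.1e13 photons/s
#' @export
photonFlux <- function(power_w, wavelength_nm) {
    if (any(power_w < 0)) stop("power must be nonnegative")
    if (any(wavelength_nm <= 0)) stop("wavelength must be positive")
    power_w * (wavelength_nm * 1e-9) / (.PLANCK * .C_LIGHT)
}

#' Imaging-to-stimulus area ratio
#'
#' Ratio of the scanned imaging frame area to the area of a circular
#' stimulation region of interest: \code{(width * height) / (pi r^2)}.
#' With the 254 x 254 px frame the 18--24 px ROI diameters used for
#' local stimulation give ratios of roughly 254 down to 143.
#'
#' @param frameWidth_px,frameHeight_px frame dimensions in pixels.
#' @param roiDiameter_px ROI diameter in pixels (> 0, no larger than the
#'   smaller frame side).
#' @return Dimensionless area ratio.
#' @export
areaRatio <- function(frameWidth_px, frameHeight_px, roiDiameter_px) {
    if (roiDiameter_px <= 0) stop("ROI diameter must be positive")
    if (roiDiameter_px > min(frameWidth_px, frameHeight_px))
        stop("ROI diameter exceeds frame")
    (frameWidth_px * frameHeight_px) / (pi * (roiDiameter_px / 2)^2)
}

#' Build a two-wavelength duty-cycle schedule
#'
#' Realizes a target UV photon-time fraction by rapid alternation within
#' a short repeat period: a UV epoch of \code{uvFraction * period} ms
#' followed by a fill epoch for the remainder (e.g. a 10% UV / 90% blue
#' mixture at a 500 ms period is 50 ms of 380 nm then 450 ms of 480 nm).
#' Zero-duration epochs are omitted. Durations are kept as real
#' milliseconds, with no quantization to any device switching grid.
#'
#' @param uvFraction fraction of the period at the UV wavelength, in
#'   [0, 1].
#' @param uvWavelength_nm UV epoch wavelength (default 380 nm).
#' @param fillWavelength_nm fill epoch wavelength (default 480 nm).
#' @param period_ms repeat period (default 500 ms).
#' @param totalDuration_s total program duration (default 240 s, one
#'   4-min stimulus condition).
#' @return A \linkS4class{StimulusSchedule}.
#' @export
dutyCycleSchedule <- function(uvFraction, uvWavelength_nm = 380,
                              fillWavelength_nm = 480, period_ms = 500,
                              totalDuration_s = 240) {
    if (uvFraction < 0 || uvFraction > 1)
        stop("uvFraction must lie in [0, 1]")
    e <- data.frame(wavelength_nm = c(uvWavelength_nm, fillWavelength_nm),
                    duration_ms = c(uvFraction, 1 - uvFraction) * period_ms)
    e <- e[e$duration_ms > 0, , drop = FALSE]
    rownames(e) <- NULL
    new("StimulusSchedule", period_ms = period_ms, epochs = e,
        totalDuration_s = totalDuration_s)
}

#' Time-averaged fraction of a schedule spent at a wavelength
#'
#' Inverse of \code{\link{dutyCycleSchedule}}: the fraction of each
#' repeat period spent at \code{wavelength_nm}. Composing the two is the
#' identity on [0, 1].
#'
#' @param schedule a \linkS4class{StimulusSchedule}.
#' @param wavelength_nm wavelength whose time share is requested.
#' @return Fraction in [0, 1].
#' @export
timeAveragedRatio <- function(schedule, wavelength_nm) {
    e <- epochs(schedule)
    sum(e$duration_ms[e$wavelength_nm == wavelength_nm]) / periodMs(schedule)
}

#' Wavelength of maximal absorbance
#'
#' Returns the wavelength of the global absorbance maximum, after an
#' optional moving-average smoothing over a window of \code{smoothWindow}
#' nanometres. Ties are broken toward the shorter wavelength.
#'
#' @param spectrum an \linkS4class{AbsorbanceSpectrum} with at least 3
#'   points.
#' @param smoothWindow full smoothing window width in nm (0 = none).
#' @return lambda-max in nm.
#' @export
spectrumPeak <- function(spectrum, smoothWindow = 0) {
    wl <- wavelengths(spectrum)
    ab <- absorbance(spectrum)
    if (length(wl) < 3) stop("spectrum needs at least 3 points")
    if (smoothWindow > 0) {
        half <- smoothWindow / 2
        ab <- vapply(seq_along(wl), function(i) {
            mean(ab[abs(wl - wl[i]) <= half])
        }, numeric(1))
    }
    wl[which.max(ab)]   # which.max takes the first (shortest-wavelength) tie
}

#' Dark-minus-light difference spectrum
#'
#' Pointwise \code{dark - light} on the dark spectrum's wavelength grid;
#' the light spectrum is linearly interpolated onto that grid if the
#' grids differ. Grid points outside the light spectrum's range are an
#' error (non-overlapping grids cannot be differenced).
#'
#' @param dark,light \linkS4class{AbsorbanceSpectrum} objects.
#' @return An \linkS4class{AbsorbanceSpectrum} of differences on the
#'   dark grid.
#' @export
differenceSpectrum <- function(dark, light) {
    wl <- wavelengths(dark)
    lw <- wavelengths(light)
    if (max(lw) < min(wl) || min(lw) > max(wl))
        stop("spectra have non-overlapping wavelength grids")
    if (identical(wl, lw)) {
        lv <- absorbance(light)
    } else {
        if (min(wl) < min(lw) || max(wl) > max(lw))
            stop("light spectrum does not cover the dark grid")
        lv <- stats::approx(lw, absorbance(light), xout = wl)$y
    }
    AbsorbanceSpectrum(wl, absorbance(dark) - lv)
}

#' Read / write two-column spectrum CSVs
#'
#' Spectra are exchanged as CSV with columns \code{wavelength_nm} and
#' \code{absorbance}.
#'
#' @param file path to the CSV.
#' @return \code{readSpectrum}: an \linkS4class{AbsorbanceSpectrum}.
#' @export
readSpectrum <- function(file) {
    df <- utils::read.csv(file)
    AbsorbanceSpectrum(df$wavelength_nm, df$absorbance)
}

#' @rdname readSpectrum
#' @param spectrum an \linkS4class{AbsorbanceSpectrum} to write.
#' @export
writeSpectrum <- function(spectrum, file) {
    utils::write.csv(data.frame(wavelength_nm = wavelengths(spectrum),
                                absorbance = absorbance(spectrum)),
                     file, row.names = FALSE)
    invisible(file)
}
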