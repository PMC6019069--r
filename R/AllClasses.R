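#' @import methods
NULL

#' Controlled vocabulary of cell classes
#'
#' Cell classes used to annotate neurons of the larval head circuits:
#' ciliary photoreceptors (\code{cPRC}) and their postsynaptic partners
#' (\code{IN_RGW}, \code{IN_NOS}, \code{SN_flask}, \code{Ser_h1},
#' \code{MC}), the rhabdomeric visual circuit (\code{rPRC_eyespot},
#' \code{rPRC_adult_eye}, \code{IN_pro}, \code{IN_sn}, \code{vMN}),
#' candidate bridge cells (\code{IN_preMN}, \code{MS}), effectors
#' (\code{ciliary_band}) and a catch-all \code{other}.
#'
#' @return Character vector of admissible \code{cell_class} tokens.
#' @export
cellClassVocabulary <- function() {
    c("cPRC", "IN_RGW", "IN_NOS", "SN_flask", "IN_sn", "IN_preMN", "MS",
      "vMN", "IN_pro", "rPRC_eyespot", "rPRC_adult_eye", "Ser_h1", "MC",
      "ciliary_band", "other")
}

.checkCellTable <- function(cells) {
    msg <- NULL
    need <- c("cell_id", "name", "cell_class", "side")
    if (!is.data.frame(cells) || !all(need %in% names(cells)))
        return("cells must be a data.frame with columns cell_id, name, cell_class, side")
    if (anyDuplicated(cells$cell_id))
        msg <- c(msg, "duplicate cell_id")
    if (!all(cells$cell_class %in% cellClassVocabulary()))
        msg <- c(msg, paste("unknown cell_class:",
                 paste(unique(setdiff(cells$cell_class, cellClassVocabulary())),
                       collapse = ", ")))
    if (!all(cells$side %in% c("left", "right", "median", "unknown")))
        msg <- c(msg, "side must be one of left/right/median/unknown")
    msg
}

#' SynapseMatrix: directed synapse counts between annotated cells
#'
#' A square nonnegative-integer matrix of synapse counts. Rows are
#' presynaptic, columns postsynaptic (the usual connectome-matrix
#' orientation), aligned to a cell-annotation table.
#'
#' @slot counts integer matrix; \code{counts[i, j]} is the number of
#'   synapses from cell \code{i} (presynaptic) onto cell \code{j}
#'   (postsynaptic).
#' @slot cells data.frame with columns \code{cell_id}, \code{name},
#'   \code{cell_class} (from \code{\link{cellClassVocabulary}}) and
#'   \code{side}, in matrix order.
#' @export
setClass("SynapseMatrix",
    representation(counts = "matrix", cells = "data.frame"),
    validity = function(object) {
        m <- object@counts
        msg <- NULL
        if (nrow(m) != ncol(m))
            msg <- c(msg, "counts must be square")
        if (any(m < 0) || any(m != round(m)))
            msg <- c(msg, "counts must be nonnegative integers")
        msg <- c(msg, .checkCellTable(object@cells))
        if (is.null(msg) && nrow(object@cells) != nrow(m))
            msg <- c(msg, "cells table does not match matrix dimension")
        if (is.null(msg) &&
            (!identical(rownames(m), object@cells$cell_id) ||
             !identical(colnames(m), object@cells$cell_id)))
            msg <- c(msg, "dimnames must equal cells$cell_id in order")
        if (is.null(msg)) TRUE else msg
    })

#' Construct a SynapseMatrix
#'
#' @param counts square nonnegative integer matrix, rows presynaptic.
#' @param cells cell-annotation data.frame (\code{cell_id}, \code{name},
#'   \code{cell_class}, \code{side}) in matrix order.
#' @return A \linkS4class{SynapseMatrix}.
#' @examples
#' cells <- data.frame(cell_id = c("a", "b"), name = c("a", "b"),
#'                     cell_class = c("cPRC", "IN_RGW"), side = "left")
#' m <- matrix(c(0L, 3L, 0L, 0L), 2, 2, byrow = TRUE,
#'             dimnames = list(c("a", "b"), c("a", "b")))
#' SynapseMatrix(m, cells)
#' @export
SynapseMatrix <- function(counts, cells) {
    storage.mode(counts) <- "integer"
    if (is.null(rownames(counts))) rownames(counts) <- cells$cell_id
    if (is.null(colnames(counts))) colnames(counts) <- cells$cell_id
    cells$cell_id <- as.character(cells$cell_id)
    new("SynapseMatrix", counts = counts, cells = cells)
}

#' CircuitDefinition: two disjoint cell-class sets
#'
#' Names the cell classes making up the ciliary-photoreceptor circuit and
#' the rhabdomeric-photoreceptor circuit for the bridge-path search.
#'
#' @slot cprcCircuit character vector of classes in the cPRC circuit.
#' @slot rprcCircuit character vector of classes in the rPRC circuit.
#' @export
setClass("CircuitDefinition",
    representation(cprcCircuit = "character", rprcCircuit = "character"),
    validity = function(object) {
        msg <- NULL
        voc <- cellClassVocabulary()
        if (!all(c(object@cprcCircuit, object@rprcCircuit) %in% voc))
            msg <- c(msg, "circuit classes must come from cellClassVocabulary()")
        if (length(intersect(object@cprcCircuit, object@rprcCircuit)))
            msg <- c(msg, "circuit class sets must be disjoint")
        if (is.null(msg)) TRUE else msg
    })

#' Default circuit definition
#'
#' The cPRC circuit comprises the ciliary photoreceptors and all neurons
#' directly postsynaptic to them; the rPRC circuit comprises the eyespot
#' and adult-eye photoreceptors with their interneurons and motoneurons.
#'
#' @param cprcCircuit,rprcCircuit character vectors of cell classes.
#' @return A \linkS4class{CircuitDefinition}.
#' @export
circuitDefinition <- function(
        cprcCircuit = c("cPRC", "IN_RGW", "IN_NOS", "SN_flask", "Ser_h1", "MC"),
        rprcCircuit = c("rPRC_eyespot", "rPRC_adult_eye", "IN_pro", "IN_sn", "vMN")) {
    new("CircuitDefinition", cprcCircuit = cprcCircuit, rprcCircuit = rprcCircuit)
}

#' CiliaryBranchSet: morphometry of branched sensory cilia
#'
#' Per-branch diameters and lengths of the ramified sensory cilia of a
#' ciliary photoreceptor, plus per-cell basal-body counts.
#'
#' @slot diameter_nm numeric, branch diameters in nanometres.
#' @slot length_um numeric, branch lengths in micrometres.
#' @slot basalBodies integer, basal bodies per cell (may be empty).
#' @slot basalBodyRange numeric length-2 plausibility range for
#'   basal-body counts (default 12--15 per cell).
#' @export
setClass("CiliaryBranchSet",
    representation(diameter_nm = "numeric", length_um = "numeric",
                   basalBodies = "integer", basalBodyRange = "numeric"),
    validity = function(object) {
        msg <- NULL
        if (length(object@diameter_nm) != length(object@length_um))
            msg <- c(msg, "diameter and length vectors must have equal length")
        if (any(object@diameter_nm <= 0) || any(object@length_um <= 0))
            msg <- c(msg, "diameters and lengths must be positive")
        r <- object@basalBodyRange
        if (length(r) != 2 || r[1] > r[2])
            msg <- c(msg, "basalBodyRange must be c(lo, hi)")
        if (length(object@basalBodies) &&
            (any(object@basalBodies < r[1]) || any(object@basalBodies > r[2])))
            msg <- c(msg, "basal-body count outside plausibility range")
        if (is.null(msg)) TRUE else msg
    })

#' Construct a CiliaryBranchSet
#'
#' @param diameter_nm branch diameters, nm.
#' @param length_um branch lengths, um.
#' @param basalBodies optional per-cell basal-body counts.
#' @param basalBodyRange plausibility range for basal-body counts.
#' @return A \linkS4class{CiliaryBranchSet}.
#' @export
CiliaryBranchSet <- function(diameter_nm, length_um, basalBodies = integer(0),
                             basalBodyRange = c(12, 15)) {
    new("CiliaryBranchSet", diameter_nm = as.numeric(diameter_nm),
        length_um = as.numeric(length_um),
        basalBodies = as.integer(basalBodies),
        basalBodyRange = as.numeric(basalBodyRange))
}

#' StimulusSchedule: repeating wavelength program
#'
#' An ordered set of (wavelength, duration) epochs repeated with a fixed
#' period, realizing a photon-time mixture of wavelengths.
#'
#' @slot period_ms repeat period, milliseconds.
#' @slot epochs data.frame with columns \code{wavelength_nm} and
#'   \code{duration_ms}; durations sum to the period.
#' @slot totalDuration_s total program duration, seconds.
#' @export
setClass("StimulusSchedule",
    representation(period_ms = "numeric", epochs = "data.frame",
                   totalDuration_s = "numeric"),
    validity = function(object) {
        msg <- NULL
        e <- object@epochs
        if (!all(c("wavelength_nm", "duration_ms") %in% names(e)))
            msg <- c(msg, "epochs needs wavelength_nm and duration_ms columns")
        else {
            if (any(e$duration_ms <= 0))
                msg <- c(msg, "epoch durations must be positive")
            if (abs(sum(e$duration_ms) - object@period_ms) > 1e-9 * object@period_ms)
                msg <- c(msg, "epoch durations must sum to the period")
        }
        if (object@period_ms <= 0)
            msg <- c(msg, "period must be positive")
        if (is.null(msg)) TRUE else msg
    })

#' AbsorbanceSpectrum: absorbance on a wavelength grid
#'
#' @slot wavelength_nm strictly increasing wavelength grid, nm.
#' @slot absorbance absorbance values (arbitrary units), same length.
#' @export
setClass("AbsorbanceSpectrum",
    representation(wavelength_nm = "numeric", absorbance = "numeric"),
    validity = function(object) {
        msg <- NULL
        if (length(object@wavelength_nm) != length(object@absorbance))
            msg <- c(msg, "wavelength and absorbance must have equal length")
        if (length(object@wavelength_nm) > 1 &&
            any(diff(object@wavelength_nm) <= 0))
            msg <- c(msg, "wavelength grid must be strictly increasing")
        if (is.null(msg)) TRUE else msg
    })

#' Construct an AbsorbanceSpectrum
#'
#' @param wavelength_nm strictly increasing wavelength grid, nm.
#' @param absorbance absorbance values.
#' @return An \linkS4class{AbsorbanceSpectrum}.
#' @export
AbsorbanceSpectrum <- function(wavelength_nm, absorbance) {
    new("AbsorbanceSpectrum", wavelength_nm = as.numeric(wavelength_nm),
        absorbance = as.numeric(absorbance))
}

#' FluorescenceMovie: time-lapse intensity stack with stimulus epochs
#'
#' @slot frames numeric array indexed (frame, row, column).
#' @slot frameInterval_s seconds between frames (default 0.8 s, i.e.
#'   1.25 frames/s).
#' @slot stimuli data.frame with columns \code{onset_frame},
#'   \code{offset_frame} (1-based, inclusive) and \code{wavelength_nm}.
#' @export
setClass("FluorescenceMovie",
    representation(frames = "array", frameInterval_s = "numeric",
                   stimuli = "data.frame"),
    validity = function(object) {
        msg <- NULL
        if (length(dim(object@frames)) != 3)
            msg <- c(msg, "frames must be a 3-D (frame, row, column) array")
        if (object@frameInterval_s <= 0)
            msg <- c(msg, "frameInterval_s must be positive")
        s <- object@stimuli
        if (nrow(s)) {
            if (!all(c("onset_frame", "offset_frame", "wavelength_nm") %in% names(s)))
                msg <- c(msg, "stimuli needs onset_frame, offset_frame, wavelength_nm")
            else if (any(s$onset_frame >= s$offset_frame) ||
                     any(s$offset_frame > dim(object@frames)[1]) ||
                     any(s$onset_frame < 1))
                msg <- c(msg, "stimulus epochs must satisfy 1 <= onset < offset <= n frames")
        }
        if (is.null(msg)) TRUE else msg
    })

#' Construct a FluorescenceMovie
#'
#' @param frames 3-D array (frame, row, column).
#' @param frameInterval_s frame interval in seconds.
#' @param stimuli stimulus annotation data.frame.
#' @return A \linkS4class{FluorescenceMovie}.
#' @export
FluorescenceMovie <- function(frames, frameInterval_s = 0.8,
        stimuli = data.frame(onset_frame = integer(0),
                             offset_frame = integer(0),
                             wavelength_nm = numeric(0))) {
    new("FluorescenceMovie", frames = frames,
        frameInterval_s = frameInterval_s, stimuli = stimuli)
}

#' TrajectorySet: time-stamped larval positions in a vertical arena
#'
#' Positions are in millimetres with \code{z} increasing upward from the
#' arena floor; video row coordinates (which increase downward) must be
#' converted at calibration time.
#'
#' @slot samples data.frame with columns \code{larva_id}, \code{t_s},
#'   \code{x_mm}, \code{z_mm}, sorted by larva then time.
#' @slot arenaHeight_mm water-column height (default 160 mm).
#' @export
setClass("TrajectorySet",
    representation(samples = "data.frame", arenaHeight_mm = "numeric"),
    validity = function(object) {
        msg <- NULL
        s <- object@samples
        if (!all(c("larva_id", "t_s", "x_mm", "z_mm") %in% names(s)))
            return("samples needs larva_id, t_s, x_mm, z_mm columns")
        if (nrow(s)) {
            dt <- unlist(tapply(s$t_s, s$larva_id, diff), use.names = FALSE)
            if (length(dt) && any(dt <= 0))
                msg <- c(msg, "time must be strictly increasing within each larva")
            if (any(s$z_mm < -1e-9) ||
                any(s$z_mm > object@arenaHeight_mm + 1e-9))
                msg <- c(msg, "z must lie within [0, arena height]")
        }
        if (is.null(msg)) TRUE else msg
    })

#' Construct a TrajectorySet
#'
#' @param samples data.frame with columns \code{larva_id}, \code{t_s},
#'   \code{x_mm}, \code{z_mm}.
#' @param arenaHeight_mm water-column height in mm.
#' @return A \linkS4class{TrajectorySet}.
#' @export
TrajectorySet <- function(samples, arenaHeight_mm = 160) {
    samples <- samples[order(samples$larva_id, samples$t_s), , drop = FALSE]
    rownames(samples) <- NULL
    new("TrajectorySet", samples = samples, arenaHeight_mm = arenaHeight_mm)
}
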