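#' @include AllClasses.R
NULL

#' Accessors for depthgauge containers
#'
#' Small accessor generics so downstream code never touches slots:
#' \code{synapseCounts} and \code{cellTable} for
#' \linkS4class{SynapseMatrix}; \code{epochs} and \code{periodMs} for
#' \linkS4class{StimulusSchedule}; \code{wavelengths} and
#' \code{absorbance} for \linkS4class{AbsorbanceSpectrum};
#' \code{movieFrames}, \code{frameInterval} and \code{stimulusTable} for
#' \linkS4class{FluorescenceMovie}; \code{trajectorySamples} and
#' \code{arenaHeight} for \linkS4class{TrajectorySet}.
#'
#' @param x an object of the matching class.
#' @return The slot contents (matrix, data.frame or numeric vector).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("synapseCounts", function(x) standardGeneric("synapseCounts"))
#' @rdname accessors
#' @export
setMethod("synapseCounts", "SynapseMatrix", function(x) x@counts)

#' @rdname accessors
#' @export
setGeneric("cellTable", function(x) standardGeneric("cellTable"))
#' @rdname accessors
#' @export
setMethod("cellTable", "SynapseMatrix", function(x) x@cells)

#' @rdname accessors
#' @export
setGeneric("epochs", function(x) standardGeneric("epochs"))
#' @rdname accessors
#' @export
setMethod("epochs", "StimulusSchedule", function(x) x@epochs)

#' @rdname accessors
#' @export
setGeneric("periodMs", function(x) standardGeneric("periodMs"))
#' @rdname accessors
#' @export
setMethod("periodMs", "StimulusSchedule", function(x) x@period_ms)

#' @rdname accessors
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))
#' @rdname accessors
#' @export
setMethod("wavelengths", "AbsorbanceSpectrum", function(x) x@wavelength_nm)

#' @rdname accessors
#' @export
setGeneric("absorbance", function(x) standardGeneric("absorbance"))
#' @rdname accessors
#' @export
setMethod("absorbance", "AbsorbanceSpectrum", function(x) x@absorbance)

#' @rdname accessors
#' @export
setGeneric("movieFrames", function(x) standardGeneric("movieFrames"))
#' @rdname accessors
#' @export
setMethod("movieFrames", "FluorescenceMovie", function(x) x@frames)

#' @rdname accessors
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))
#' @rdname accessors
#' @export
setMethod("frameInterval", "FluorescenceMovie", function(x) x@frameInterval_s)

#' @rdname accessors
#' @export
setGeneric("stimulusTable", function(x) standardGeneric("stimulusTable"))
#' @rdname accessors
#' @export
setMethod("stimulusTable", "FluorescenceMovie", function(x) x@stimuli)

#' @rdname accessors
#' @export
setGeneric("trajectorySamples", function(x) standardGeneric("trajectorySamples"))
#' @rdname accessors
#' @export
setMethod("trajectorySamples", "TrajectorySet", function(x) x@samples)

#' @rdname accessors
#' @export
setGeneric("arenaHeight", function(x) standardGeneric("arenaHeight"))
#' @rdname accessors
#' @export
setMethod("arenaHeight", "TrajectorySet", function(x) x@arenaHeight_mm)

#' @rdname accessors
#' @export
setGeneric("branchDiameters", function(x) standardGeneric("branchDiameters"))
#' @rdname accessors
#' @export
setMethod("branchDiameters", "CiliaryBranchSet", function(x) x@diameter_nm)

#' @rdname accessors
#' @export
setGeneric("branchLengths", function(x) standardGeneric("branchLengths"))
#' @rdname accessors
#' @export
setMethod("branchLengths", "CiliaryBranchSet", function(x) x@length_um)

setMethod("show", "SynapseMatrix", function(object) {
    cat("SynapseMatrix:", nrow(object@counts), "cells,",
        sum(object@counts), "synapses\n")
    tab <- table(object@cells$cell_class)
    cat("  classes:", paste(names(tab), tab, sep = ":", collapse = " "), "\n")
})

setMethod("show", "CircuitDefinition", function(object) {
    cat("CircuitDefinition\n  cPRC circuit:",
        paste(object@cprcCircuit, collapse = ", "),
        "\n  rPRC circuit:", paste(object@rprcCircuit, collapse = ", "), "\n")
})

setMethod("show", "CiliaryBranchSet", function(object) {
    cat("CiliaryBranchSet:", length(object@diameter_nm), "branches, total length",
        round(sum(object@length_um), 1), "um, mean diameter",
        round(mean(object@diameter_nm), 1), "nm\n")
})

setMethod("show", "StimulusSchedule", function(object) {
    cat("StimulusSchedule: period", object@period_ms, "ms, total",
        object@totalDuration_s, "s\n")
    for (i in seq_len(nrow(object@epochs)))
        cat(sprintf("  %g nm for %g ms\n", object@epochs$wavelength_nm[i],
                    object@epochs$duration_ms[i]))
})

setMethod("show", "AbsorbanceSpectrum", function(object) {
    cat("AbsorbanceSpectrum:", length(object@wavelength_nm), "points,",
        min(object@wavelength_nm), "-", max(object@wavelength_nm), "nm\n")
})

setMethod("show", "FluorescenceMovie", function(object) {
    d <- dim(object@frames)
    cat(sprintf("FluorescenceMovie: %d frames of %dx%d px at %.3g s/frame, %d stimulus epoch(s)\n",
                d[1], d[2], d[3], object@frameInterval_s, nrow(object@stimuli)))
})

setMethod("show", "TrajectorySet", function(object) {
    s <- object@samples
    cat("TrajectorySet:", length(unique(s$larva_id)), "larvae,",
        nrow(s), "samples, arena height", object@arenaHeight_mm, "mm\n")
})
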