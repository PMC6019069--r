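#' @include AllClasses.R AllGenerics.R
NULL

#' Read a synapse-count connectivity matrix and cell annotations
#'
#' The matrix CSV carries cell identifiers in its first row and first
#' column; the body holds directed synapse counts with rows presynaptic
#' and columns postsynaptic. The companion annotation CSV has columns
#' \code{cell_id}, \code{name}, \code{cell_class}, \code{side}.
#'
#' @param matrixFile path to the connectivity CSV.
#' @param cellsFile path to the cell-annotation CSV; if \code{NULL},
#'   every cell is annotated as class \code{other}.
#' @return A \linkS4class{SynapseMatrix}.
#' @seealso \code{\link{saveConnectivity}} for the inverse.
#' @export
loadConnectivity <- function(matrixFile, cellsFile = NULL) {
    raw <- utils::read.csv(matrixFile, row.names = 1, check.names = FALSE)
    m <- as.matrix(raw)
    if (nrow(m) != ncol(m))
        stop("connectivity matrix must be square, got ",
             nrow(m), "x", ncol(m))
    if (!is.numeric(m) || any(is.na(m)) || any(m < 0) || any(m != round(m)))
        stop("connectivity entries must be nonnegative integers")
    if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m)))
        stop("duplicate cell ids in connectivity matrix")
    if (!identical(rownames(m), colnames(m)))
        stop("row and column cell ids must match")
    if (is.null(cellsFile)) {
        cells <- data.frame(cell_id = rownames(m), name = rownames(m),
                            cell_class = "other", side = "unknown",
                            stringsAsFactors = FALSE)
    } else {
        cells <- utils::read.csv(cellsFile, stringsAsFactors = FALSE)
        cells$cell_id <- as.character(cells$cell_id)
        if (!setequal(cells$cell_id, rownames(m)))
            stop("annotation cell ids do not match matrix cell ids")
        cells <- cells[match(rownames(m), cells$cell_id), , drop = FALSE]
        rownames(cells) <- NULL
    }
    SynapseMatrix(m, cells)
}

#' Write a SynapseMatrix and its cell annotations to CSV
#'
#' Round-trips bit-exactly through \code{\link{loadConnectivity}}.
#'
#' @param x a \linkS4class{SynapseMatrix}.
#' @param matrixFile path for the connectivity CSV.
#' @param cellsFile optional path for the annotation CSV.
#' @return Invisibly, \code{matrixFile}.
#' @export
saveConnectivity <- function(x, matrixFile, cellsFile = NULL) {
    m <- synapseCounts(x)
    df <- data.frame(cell_id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.csv(df, matrixFile, row.names = FALSE, quote = FALSE)
    if (!is.null(cellsFile))
        utils::write.csv(cellTable(x), cellsFile, row.names = FALSE,
                         quote = FALSE)
    invisible(matrixFile)
}

#' Group a synapse matrix by cell class
#'
#' Entry (A, B) of the grouped matrix is the total number of synapses
#' from all cells of class A onto all cells of class B; the grand total
#' is conserved.
#'
#' @param x a \linkS4class{SynapseMatrix}.
#' @param classes optional character vector overriding the cell classes
#'   (same order as the matrix); defaults to the annotation table.
#' @return An integer matrix indexed by cell class.
#' @export
groupMatrix <- function(x, classes = NULL) {
    m <- synapseCounts(x)
    if (is.null(classes)) classes <- cellTable(x)$cell_class
    if (length(classes) != nrow(m))
        stop("one class label per cell required")
    if (!all(classes %in% cellClassVocabulary()))
        stop("unknown class label: ",
             paste(setdiff(classes, cellClassVocabulary()), collapse = ", "))
    f <- factor(classes, levels = unique(classes))
    g <- rowsum(t(rowsum(m, f)), f)           # sum rows then columns by class
    storage.mode(g) <- "integer"
    t(g)[levels(f), levels(f), drop = FALSE]
}

#' Enumerate short synaptic bridge paths between two circuits
#'
#' Finds every directed path of at most \code{maxHops} edges from a cell
#' of the source circuit to a cell of the target circuit. Each edge must
#' carry at least \code{minSynapses} synapses. For two-hop paths the
#' intermediary cell must belong to neither circuit, so within-circuit
#' hops are never counted as bridges; a one-hop edge between a
#' source-circuit cell and a target-circuit cell is a "direct" bridge.
#'
#' @param x a \linkS4class{SynapseMatrix}.
#' @param circuits a \linkS4class{CircuitDefinition}.
#' @param direction \code{"cprc_to_rprc"} or \code{"rprc_to_cprc"}.
#' @param maxHops maximum number of edges per path (1 or 2).
#' @param minSynapses minimum synapse count per edge for an edge to be
#'   considered connected. The default of 1 counts every synapse, since
#'   no stricter threshold is part of the search definition.
#' @return data.frame with one row per path: \code{from}, \code{via}
#'   (\code{NA} for direct paths), \code{to}, \code{hops},
#'   \code{synapses1}, \code{synapses2} (\code{NA} for direct),
#'   \code{bridge_class} (the intermediary's class, or
#'   \code{"direct:<target class>"}). Rows are ordered lexicographically
#'   by the path's cell ids.
#' @export
findBridgePaths <- function(x, circuits = circuitDefinition(),
                            direction = c("cprc_to_rprc", "rprc_to_cprc"),
                            maxHops = 2, minSynapses = 1) {
    direction <- match.arg(direction)
    m <- synapseCounts(x)
    cls <- cellTable(x)$cell_class
    ids <- cellTable(x)$cell_id
    if (direction == "cprc_to_rprc") {
        srcClasses <- circuits@cprcCircuit; tgtClasses <- circuits@rprcCircuit
    } else {
        srcClasses <- circuits@rprcCircuit; tgtClasses <- circuits@cprcCircuit
    }
    src <- which(cls %in% srcClasses)
    tgt <- which(cls %in% tgtClasses)
    mid <- which(!(cls %in% srcClasses) & !(cls %in% tgtClasses))
    conn <- m >= minSynapses

    rows <- list()
    # direct (1-hop) bridges
    for (i in src) for (j in tgt) if (conn[i, j])
        rows[[length(rows) + 1L]] <- data.frame(
            from = ids[i], via = NA_character_, to = ids[j], hops = 1L,
            synapses1 = m[i, j], synapses2 = NA_integer_,
            bridge_class = paste0("direct:", cls[j]),
            stringsAsFactors = FALSE)
    # 2-hop bridges through cells outside both circuits
    if (maxHops >= 2)
        for (i in src) for (k in mid) if (conn[i, k])
            for (j in tgt) if (conn[k, j])
                rows[[length(rows) + 1L]] <- data.frame(
                    from = ids[i], via = ids[k], to = ids[j], hops = 2L,
                    synapses1 = m[i, k], synapses2 = m[k, j],
                    bridge_class = cls[k], stringsAsFactors = FALSE)
    out <- if (length(rows)) do.call(rbind, rows) else
        data.frame(from = character(0), via = character(0), to = character(0),
                   hops = integer(0), synapses1 = integer(0),
                   synapses2 = integer(0), bridge_class = character(0),
                   stringsAsFactors = FALSE)
    ord <- order(out$from, ifelse(is.na(out$via), "", out$via), out$to)
    out <- out[ord, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Tally bridge paths by bridge class
#'
#' Aggregates the output of \code{\link{findBridgePaths}} by bridge
#' class: direct edges are keyed by their target class
#' (\code{"direct:<class>"}), two-hop paths by the class of their
#' intermediary cell.
#'
#' @param paths data.frame from \code{\link{findBridgePaths}}.
#' @return data.frame with one row per bridge class: \code{bridge_class},
#'   \code{n_paths}, \code{n_intermediaries} (distinct intermediary
#'   cells; 0 for direct classes) and \code{total_synapses} (sum of all
#'   edge synapse counts over the class's paths).
#' @export
classifyBridges <- function(paths) {
    if (!nrow(paths))
        return(data.frame(bridge_class = character(0), n_paths = integer(0),
                          n_intermediaries = integer(0),
                          total_synapses = integer(0),
                          stringsAsFactors = FALSE))
    sp <- split(paths, paths$bridge_class)
    out <- do.call(rbind, lapply(names(sp), function(k) {
        p <- sp[[k]]
        data.frame(bridge_class = k, n_paths = nrow(p),
                   n_intermediaries = length(unique(stats::na.omit(p$via))),
                   total_synapses = sum(p$synapses1, p$synapses2, na.rm = TRUE),
                   stringsAsFactors = FALSE)
    }))
    out <- out[order(out$bridge_class), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Sensory membrane surface area of branched cilia
#'
#' Models each ciliary branch as an open cylinder (no end caps, a
#' negligible fraction of the surface) and returns the summed lateral
#' area \eqn{\sum_i \pi d_i L_i} in square micrometres.
#'
#' @param branches a \linkS4class{CiliaryBranchSet} (diameters in nm,
#'   lengths in um).
#' @return Total membrane area in um^2.
#' @examples
#' # one aggregate branch with the morphometry of a whole cPRC
#' membraneArea(CiliaryBranchSet(130, 677))   # ~276 um^2
#' @export
membraneArea <- function(branches) {
    d_um <- branchDiameters(branches) * 1e-3
    sum(pi * d_um * branchLengths(branches))
}
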