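## Constructors, accessors and show() methods for the domain classes.

#' Construct an AbundanceTable
#'
#' @param values numeric matrix, features x samples, with dimnames.
#' @param kind scale tag: \code{"counts"}, \code{"relative"},
#'   \code{"absolute"} or \code{"log"}.
#' @param flags optional character vector of flagged sample IDs.
#' @return An \code{\linkS4class{AbundanceTable}}.
#' @examples
#' m <- matrix(c(2, 3, 5, 1, 0, 9), nrow = 3,
#'             dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' abundanceTable(m, kind = "counts")
#' @export
abundanceTable <- function(values, kind = "counts", flags = character(0)) {
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    new("AbundanceTable", values = values, kind = kind, flags = flags)
}

#' Construct a LoadVector
#'
#' @param load positive numeric vector of bacterial loads
#'   (ug DNA / mg stool), named by sample ID (or supply \code{sampleIDs}).
#' @param sampleIDs optional sample IDs when \code{load} is unnamed.
#' @return A \code{\linkS4class{LoadVector}}.
#' @examples
#' loadVector(c(s1 = 8.2, s2 = 11.5))
#' @export
loadVector <- function(load, sampleIDs = names(load)) {
    load <- setNames(as.numeric(load), sampleIDs)
    new("LoadVector", load = load)
}

#' @rdname abundanceValues
#' @export
setGeneric("abundanceValues", function(x) standardGeneric("abundanceValues"))

#' Extract the numeric matrix from a container
#'
#' @param x an \code{AbundanceTable}, \code{DeltaTable} or
#'   \code{DistanceMatrix}.
#' @return The underlying numeric matrix.
#' @export
setMethod("abundanceValues", "AbundanceTable", function(x) x@values)

#' @rdname abundanceValues
#' @export
setMethod("abundanceValues", "DeltaTable", function(x) x@values)

#' @rdname abundanceKind
#' @export
setGeneric("abundanceKind", function(x) standardGeneric("abundanceKind"))

#' Scale tag of an AbundanceTable
#'
#' @param x an \code{AbundanceTable}.
#' @return \code{"counts"}, \code{"relative"}, \code{"absolute"} or
#'   \code{"log"}.
#' @export
setMethod("abundanceKind", "AbundanceTable", function(x) x@kind)

#' @rdname featureIDs
#' @export
setGeneric("featureIDs", function(x) standardGeneric("featureIDs"))

#' Feature and sample identifiers
#'
#' @param x a container with feature rows and/or sample columns.
#' @return Character vector of IDs.
#' @export
setMethod("featureIDs", "AbundanceTable", function(x) rownames(x@values))

#' @rdname featureIDs
#' @export
setMethod("featureIDs", "DeltaTable", function(x) rownames(x@values))

#' @rdname sampleIDs
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))

#' @rdname featureIDs
#' @export
setMethod("sampleIDs", "AbundanceTable", function(x) colnames(x@values))

#' @rdname featureIDs
#' @export
setMethod("sampleIDs", "LoadVector", function(x) names(x@load))

#' @rdname featureIDs
#' @export
setMethod("sampleIDs", "DistanceMatrix", function(x) rownames(x@D))

#' @rdname sampleLoads
#' @export
setGeneric("sampleLoads", function(x) standardGeneric("sampleLoads"))

#' Per-sample bacterial loads
#'
#' @param x a \code{LoadVector}.
#' @return Named numeric vector, ug bacterial DNA / mg stool.
#' @export
setMethod("sampleLoads", "LoadVector", function(x) x@load)

#' @rdname distanceValues
#' @export
setGeneric("distanceValues", function(x) standardGeneric("distanceValues"))

#' Symmetric dissimilarity matrix
#'
#' @param x a \code{DistanceMatrix}.
#' @return The square numeric matrix of dissimilarities.
#' @export
setMethod("distanceValues", "DistanceMatrix", function(x) x@D)

#' @rdname ordCoordinates
#' @export
setGeneric("ordCoordinates", function(x) standardGeneric("ordCoordinates"))

#' Ordination accessors
#'
#' @param x an \code{Ordination}.
#' @return \code{ordCoordinates}: samples x axes coordinate matrix;
#'   \code{ordEigenvalues}: all eigenvalues (decreasing);
#'   \code{ordProportionExplained}: per-retained-axis fraction of the
#'   positive-eigenvalue sum.
#' @export
setMethod("ordCoordinates", "Ordination", function(x) x@coordinates)

#' @rdname ordCoordinates
#' @export
setGeneric("ordEigenvalues", function(x) standardGeneric("ordEigenvalues"))

#' @rdname ordCoordinates
#' @export
setMethod("ordEigenvalues", "Ordination", function(x) x@eigenvalues)

#' @rdname ordCoordinates
#' @export
setGeneric("ordProportionExplained",
           function(x) standardGeneric("ordProportionExplained"))

#' @rdname ordCoordinates
#' @export
setMethod("ordProportionExplained", "Ordination",
          function(x) x@proportionExplained)

#' @rdname deltaProvenance
#' @export
setGeneric("deltaProvenance", function(x) standardGeneric("deltaProvenance"))

#' Provenance tag of a DeltaTable
#'
#' @param x a \code{DeltaTable}.
#' @return \code{"relative"}, \code{"absolute"}, \code{"log"} or
#'   \code{"nutrition"}.
#' @export
setMethod("deltaProvenance", "DeltaTable", function(x) x@provenance)

setMethod("show", "AbundanceTable", function(object) {
    cat(sprintf("AbundanceTable [%s]: %d features x %d samples\n",
                object@kind, nrow(object@values), ncol(object@values)))
    if (length(object@flags))
        cat("  flagged samples:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "LoadVector", function(object) {
    cat(sprintf("LoadVector: %d samples, load %.3g-%.3g ug DNA/mg stool\n",
                length(object@load), min(object@load), max(object@load)))
})

setMethod("show", "DeltaTable", function(object) {
    cat(sprintf("DeltaTable [%s]: %d features x %d subjects (Tend - T0)\n",
                object@provenance, nrow(object@values), ncol(object@values)))
})

setMethod("show", "DistanceMatrix", function(object) {
    cat(sprintf("DistanceMatrix [%s]: %d samples\n",
                object@method, nrow(object@D)))
})

setMethod("show", "Ordination", function(object) {
    cat(sprintf("Ordination: %d samples, %d retained axes\n",
                nrow(object@coordinates), ncol(object@coordinates)))
    k <- min(2L, length(object@proportionExplained))
    if (k)
        cat(sprintf("  axis %d: %.1f%% of positive-eigenvalue variance\n",
                    seq_len(k), 100 * object@proportionExplained[seq_len(k)]),
            sep = "")
})

setMethod("show", "PermanovaResult", function(object) {
    cat(sprintf(
        "PERMANOVA: %s  pseudo-F = %.3f  R2 = %.3f  p = %.4g (%d perms%s)\n",
        object@term, object@pseudoF, object@R2, object@p, object@nPerm,
        if (is.na(object@blockedBy)) ""
        else paste0(", blocked by ", object@blockedBy)))
})

setMethod("show", "CohortSpec", function(object) {
    cat(sprintf(paste0(
        "CohortSpec: %d subjects x %s; %d genera (%d planted, rho = %.2f), ",
        "%d eukaryal taxa\n  subjectEffectSD = %.2f, calprotectinSlope = ",
        "%.2f, seed = %d\n"),
        object@nSubjects, paste(object@timepoints, collapse = "/"),
        object@nGenera, length(object@plantedGenera), object@plantedRho,
        object@nEuk, object@subjectEffectSD, object@calprotectinSlope,
        object@seed))
})

setMethod("show", "SyntheticCohort", function(object) {
    cat("SyntheticCohort\n")
    cat("  16S: "); show(object@counts16S)
    cat("  18S: "); show(object@counts18S)
    cat(sprintf("  %d questionnaire days, %d metadata rows\n",
                nrow(object@questionnaires), nrow(object@metadata)))
})

#' Components of a synthetic cohort
#'
#' @param x a \code{SyntheticCohort}.
#' @return \code{cohortCounts}: the 16S (or 18S) count table;
#'   \code{cohortLoads}: the \code{LoadVector}; \code{cohortQuestionnaires}
#'   and \code{cohortMetadata}: data.frames; \code{cohortTruth}: the list of
#'   planted effects.
#' @param table \code{"16S"} or \code{"18S"}.
#' @export
cohortCounts <- function(x, table = c("16S", "18S")) {
    table <- match.arg(table)
    if (table == "16S") x@counts16S else x@counts18S
}

#' @rdname cohortCounts
#' @export
cohortLoads <- function(x) x@loads

#' @rdname cohortCounts
#' @export
cohortQuestionnaires <- function(x) x@questionnaires

#' @rdname cohortCounts
#' @export
cohortMetadata <- function(x) x@metadata

#' @rdname cohortCounts
#' @export
cohortTruth <- function(x) x@truth
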