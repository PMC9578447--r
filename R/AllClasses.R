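#' @import methods
#' @importFrom stats complete.cases cor cov dist hclust lm median model.matrix
#'   pf pnorm pt quantile rbinom rlnorm rmultinom rnorm rpois runif sd setNames
#'   as.dist var coef
#' @importFrom utils read.csv read.delim write.csv head tail
NULL

## Central value container: a features x samples abundance matrix tagged with
## the scale it lives on. "counts" are integer reads, "relative" columns sum
## to 1, "absolute" is relative x bacterial load, "log" is natural-log scale.

#' AbundanceTable: a features x samples abundance matrix
#'
#' The central container of the package: a non-negative numeric matrix with
#' feature IDs as rownames and sample IDs as colnames, plus a \code{kind} tag
#' recording the scale of the values (\code{"counts"}, \code{"relative"},
#' \code{"absolute"} or \code{"log"}; log-scale tables may be negative).
#'
#' @slot values numeric matrix, features in rows, samples in columns.
#' @slot kind character scalar, one of \code{"counts"}, \code{"relative"},
#'   \code{"absolute"}, \code{"log"}.
#' @slot flags character vector of sample IDs flagged by an operation
#'   (for example all-zero columns found by \code{\link{toRelative}}).
#'
#' @seealso \code{\link{abundanceTable}} for the user constructor,
#'   \code{\link{toRelative}}, \code{\link{toAbsolute}},
#'   \code{\link{prevalenceFilter}}, \code{\link{logTransform}}.
#' @exportClass AbundanceTable
setClass("AbundanceTable",
    representation(values = "matrix", kind = "character", flags = "character"),
    prototype(kind = "counts", flags = character(0)))

setValidity("AbundanceTable", function(object) {
    v <- object@values
    msg <- character(0)
    if (!is.numeric(v))
        msg <- c(msg, "'values' must be a numeric matrix")
    if ((nrow(v) > 0 && is.null(rownames(v))) ||
        (ncol(v) > 0 && is.null(colnames(v))))
        msg <- c(msg, "'values' must have feature rownames and sample colnames")
    if (anyDuplicated(rownames(v)))
        msg <- c(msg, "duplicate feature IDs")
    if (anyDuplicated(colnames(v)))
        msg <- c(msg, "duplicate sample IDs")
    if (length(object@kind) != 1L ||
        !object@kind %in% c("counts", "relative", "absolute", "log"))
        msg <- c(msg, "'kind' must be one of counts/relative/absolute/log")
    if (length(object@kind) == 1L && object@kind != "log" &&
        length(v) && any(v < 0, na.rm = TRUE))
        msg <- c(msg, "negative values in a non-log table")
    if (identical(object@kind, "counts") && length(v) &&
        any(abs(v - round(v)) > 1e-8, na.rm = TRUE))
        msg <- c(msg, "kind='counts' requires integer-valued entries")
    if (identical(object@kind, "relative") && ncol(v)) {
        cs <- colSums(v)
        bad <- cs > 0 & abs(cs - 1) > 1e-9
        if (any(bad))
            msg <- c(msg, sprintf(
                "relative columns must sum to 1 (off: %s)",
                paste(head(colnames(v)[bad], 3), collapse = ", ")))
    }
    if (length(msg)) msg else TRUE
})

#' LoadVector: per-sample total bacterial load
#'
#' Total bacterial DNA per unit stool mass (micrograms of bacterial DNA per
#' milligram of stool), one positive value per sample, used to translate
#' relative abundances into absolute ones.
#'
#' @slot load named numeric vector; names are sample IDs, values are loads
#'   in ug DNA / mg stool.
#' @seealso \code{\link{loadVector}}, \code{\link{toAbsolute}},
#'   \code{\link{loadFromCt}}.
#' @exportClass LoadVector
setClass("LoadVector", representation(load = "numeric"))

setValidity("LoadVector", function(object) {
    msg <- character(0)
    if (is.null(names(object@load)) || anyDuplicated(names(object@load)))
        msg <- c(msg, "'load' must be named by unique sample IDs")
    if (any(!is.finite(object@load)) || any(object@load <= 0))
        msg <- c(msg, "loads must be positive and finite")
    if (length(msg)) msg else TRUE
})

#' DeltaTable: per-subject post-minus-pre differences
#'
#' A feature (or dietary component) x subject matrix of Tend - T0 values.
#' Only subjects with both timepoints appear as columns; subjects lacking a
#' timepoint are absent, never zero-filled.
#'
#' @slot values numeric matrix, features x subjects.
#' @slot provenance character scalar: \code{"relative"}, \code{"absolute"},
#'   \code{"log"} or \code{"nutrition"}.
#' @seealso \code{\link{buildDelta}}, \code{\link{deltaRetentionFilter}}.
#' @exportClass DeltaTable
setClass("DeltaTable",
    representation(values = "matrix", provenance = "character"))

setValidity("DeltaTable", function(object) {
    msg <- character(0)
    if (is.null(rownames(object@values)) || is.null(colnames(object@values)))
        msg <- c(msg, "'values' needs feature rownames and subject colnames")
    if (anyDuplicated(colnames(object@values)))
        msg <- c(msg, "duplicate subject IDs")
    if (length(object@provenance) != 1L ||
        !object@provenance %in% c("relative", "absolute", "log", "nutrition"))
        msg <- c(msg, "'provenance' must be relative/absolute/log/nutrition")
    if (length(msg)) msg else TRUE
})

#' DistanceMatrix: symmetric sample dissimilarities
#'
#' @slot D symmetric numeric matrix with zero diagonal; dimnames are sample
#'   IDs.
#' @slot method character scalar naming the dissimilarity.
#' @slot flags character vector of flagged sample pairs (for example pairs of
#'   all-zero samples whose Bray-Curtis distance is 0 by convention).
#' @seealso \code{\link{brayCurtis}}, \code{\link{pcoa}},
#'   \code{\link{permanova}}.
#' @exportClass DistanceMatrix
setClass("DistanceMatrix",
    representation(D = "matrix", method = "character", flags = "character"),
    prototype(method = "bray-curtis", flags = character(0)))

setValidity("DistanceMatrix", function(object) {
    D <- object@D
    msg <- character(0)
    if (nrow(D) != ncol(D))
        msg <- c(msg, "distance matrix must be square")
    if (is.null(rownames(D)) || !identical(rownames(D), colnames(D)))
        msg <- c(msg, "dimnames must be identical sample IDs")
    if (nrow(D)) {
        if (max(abs(D - t(D))) > 1e-12)
            msg <- c(msg, "matrix not symmetric")
        if (max(abs(diag(D))) > 1e-12)
            msg <- c(msg, "diagonal not zero")
        if (any(D < -1e-12))
            msg <- c(msg, "negative dissimilarities")
    }
    if (length(msg)) msg else TRUE
})

#' Ordination: a principal-coordinates embedding
#'
#' @slot coordinates samples x axes matrix of principal coordinates.
#' @slot eigenvalues numeric, all eigenvalues of the Gower-centered matrix in
#'   decreasing order (negative ones included for reporting).
#' @slot proportionExplained numeric, fraction of the positive-eigenvalue sum
#'   carried by each retained axis.
#' @seealso \code{\link{pcoa}}, \code{\link{axisCorrelations}}.
#' @exportClass Ordination
setClass("Ordination",
    representation(coordinates = "matrix", eigenvalues = "numeric",
                   proportionExplained = "numeric"))

setValidity("Ordination", function(object) {
    msg <- character(0)
    if (is.unsorted(rev(object@eigenvalues), strict = FALSE))
        msg <- c(msg, "eigenvalues must be sorted in decreasing order")
    if (ncol(object@coordinates) != length(object@proportionExplained))
        msg <- c(msg, "one proportionExplained entry per retained axis")
    if (length(msg)) msg else TRUE
})

#' PermanovaResult: one-term PERMANOVA on a distance matrix
#'
#' @slot term name of the tested covariate.
#' @slot pseudoF observed pseudo-F statistic.
#' @slot R2 fraction of total sum of squares explained by the term.
#' @slot p permutation p-value.
#' @slot nPerm number of permutations used (excluding the observed one).
#' @slot blockedBy name of the blocking factor, or \code{NA_character_} for an
#'   unrestricted test.
#' @seealso \code{\link{permanova}}.
#' @exportClass PermanovaResult
setClass("PermanovaResult",
    representation(term = "character", pseudoF = "numeric", R2 = "numeric",
                   p = "numeric", nPerm = "numeric", blockedBy = "character"))

setValidity("PermanovaResult", function(object) {
    msg <- character(0)
    if (object@R2 < -1e-12 || object@R2 > 1 + 1e-12)
        msg <- c(msg, "R2 outside [0, 1]")
    if (object@p < 1 / (object@nPerm + 1) - 1e-12 || object@p > 1 + 1e-12)
        msg <- c(msg, "p outside [1/(nPerm+1), 1]")
    if (length(msg)) msg else TRUE
})

#' CohortSpec: parameters of the synthetic paired cohort
#'
#' Describes the statistical structure of a simulated diet-intervention
#' cohort: a strong per-subject compositional signature, lognormal bacterial
#' loads, genera whose absolute abundance tracks the subject's adherence
#' improvement, an inverse adherence-calprotectin link, and a sparse unstable
#' eukaryal community tied to sweets intake.
#'
#' @slot nSubjects number of subjects (>= 4).
#' @slot nGenera number of bacterial genera.
#' @slot nEuk number of eukaryal taxa.
#' @slot timepoints ordered timepoint labels, first is baseline.
#' @slot subjectEffectSD log-scale SD of the per-subject compositional
#'   signature (0 removes the subject signal).
#' @slot plantedGenera integer indices (1-based) of genera whose absolute
#'   abundance change is tied to the adherence-score change.
#' @slot plantedRho target Spearman correlation between per-subject change in
#'   daily adherence score and change in absolute abundance of planted genera.
#' @slot calprotectinSlope log-scale slope of post-intervention fecal
#'   calprotectin on the standardized score change (negative = planted
#'   inverse association).
#' @slot seed integer RNG seed; identical spec + seed gives byte-identical
#'   output.
#' @seealso \code{\link{cohortSpec}}, \code{\link{generateCohort}}.
#' @exportClass CohortSpec
setClass("CohortSpec",
    representation(nSubjects = "integer", nGenera = "integer",
                   nEuk = "integer", timepoints = "character",
                   subjectEffectSD = "numeric", plantedGenera = "integer",
                   plantedRho = "numeric", calprotectinSlope = "numeric",
                   seed = "integer"))

setValidity("CohortSpec", function(object) {
    msg <- character(0)
    if (object@nSubjects < 4L)
        msg <- c(msg, "nSubjects must be >= 4")
    if (object@nGenera < 1L || object@nEuk < 0L)
        msg <- c(msg, "non-positive table dimensions")
    if (length(object@timepoints) < 2L || anyDuplicated(object@timepoints))
        msg <- c(msg, "need >= 2 distinct timepoint labels")
    if (object@subjectEffectSD < 0)
        msg <- c(msg, "subjectEffectSD must be >= 0")
    if (length(object@plantedGenera) &&
        (min(object@plantedGenera) < 1L ||
         max(object@plantedGenera) > object@nGenera))
        msg <- c(msg, "plantedGenera index out of range")
    if (abs(object@plantedRho) > 1)
        msg <- c(msg, "plantedRho must lie in [-1, 1]")
    if (length(msg)) msg else TRUE
})

#' SyntheticCohort: a simulated paired diet-intervention dataset
#'
#' @slot counts16S bacterial genus-level count \code{AbundanceTable}.
#' @slot counts18S eukaryal taxon-level count \code{AbundanceTable}.
#' @slot loads \code{LoadVector} of per-sample bacterial loads.
#' @slot questionnaires data.frame of daily adherence records (one row per
#'   subject-day; see \code{\link{scoreDay}} for the columns).
#' @slot metadata per-sample clinical/lifestyle data.frame keyed by
#'   \code{sample_id}.
#' @slot truth list recording every planted effect (genus indices, slopes,
#'   per-subject score changes) so recovery tests can compare against it.
#' @slot spec the \code{CohortSpec} that generated the cohort.
#' @seealso \code{\link{generateCohort}}, \code{\link{writeCohort}}.
#' @exportClass SyntheticCohort
setClass("SyntheticCohort",
    representation(counts16S = "AbundanceTable", counts18S = "AbundanceTable",
                   loads = "LoadVector", questionnaires = "data.frame",
                   metadata = "data.frame", truth = "list",
                   spec = "CohortSpec"))

setValidity("SyntheticCohort", function(object) {
    msg <- character(0)
    s16 <- colnames(object@counts16S@values)
    if (!all(s16 %in% object@metadata$sample_id))
        msg <- c(msg, "16S samples missing from metadata")
    if (!all(s16 %in% names(object@loads@load)))
        msg <- c(msg, "16S samples missing from loads")
    if (length(msg)) msg else TRUE
})
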