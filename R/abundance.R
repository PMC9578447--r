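## Abundance preprocessing: relative/absolute transforms, prevalence and
## delta retention filters, half-minimum log transform, qPCR load conversion,
## paired post-minus-pre delta matrices.

#' Convert a count table to relative abundances
#'
#' Divides each sample column by its total. All-zero columns are left at zero
#' and recorded in the table's \code{flags} slot (with a warning), since a
#' proportion is undefined for them.
#'
#' @param tbl an \code{AbundanceTable} of kind \code{"counts"} (or any
#'   non-negative table to renormalize).
#' @return An \code{AbundanceTable} of kind \code{"relative"}; every non-zero
#'   column sums to 1.
#' @examples
#' m <- matrix(c(2, 3, 5), ncol = 1, dimnames = list(paste0("g", 1:3), "s1"))
#' abundanceValues(toRelative(abundanceTable(m)))
#' @export
toRelative <- function(tbl) {
    stopifnot(is(tbl, "AbundanceTable"))
    v <- tbl@values
    if (any(v < 0)) stop("negative entries in abundance table")
    cs <- colSums(v)
    zero <- cs == 0
    if (any(zero))
        warning("all-zero sample column(s) left unnormalized: ",
                paste(colnames(v)[zero], collapse = ", "))
    nz <- !zero
    v[, nz] <- sweep(v[, nz, drop = FALSE], 2, cs[nz], "/")
    abundanceTable(v, kind = "relative", flags = colnames(v)[zero])
}

#' Scale relative abundances to absolute abundances
#'
#' Quantitative microbiome profiling step: multiplies, per sample, the
#' relative abundance of each feature by that sample's total bacterial load,
#' so column sums equal the loads (ug bacterial DNA / mg stool).
#'
#' @param tbl an \code{AbundanceTable} of kind \code{"relative"}.
#' @param loads a \code{\linkS4class{LoadVector}} covering every sample in
#'   \code{tbl}.
#' @return An \code{AbundanceTable} of kind \code{"absolute"}.
#' @examples
#' m <- matrix(c(0.2, 0.3, 0.5), ncol = 1,
#'             dimnames = list(paste0("g", 1:3), "s1"))
#' rel <- abundanceTable(m, kind = "relative")
#' abundanceValues(toAbsolute(rel, loadVector(c(s1 = 10))))
#' @export
toAbsolute <- function(tbl, loads) {
    stopifnot(is(tbl, "AbundanceTable"), is(loads, "LoadVector"))
    if (tbl@kind != "relative")
        stop("toAbsolute expects a relative-abundance table")
    miss <- setdiff(colnames(tbl@values), names(loads@load))
    if (length(miss))
        stop("no bacterial load for sample(s): ", paste(miss, collapse = ", "))
    l <- loads@load[colnames(tbl@values)]
    v <- sweep(tbl@values, 2, l, "*")
    abundanceTable(v, kind = "absolute", flags = tbl@flags)
}

#' Drop rare features by prevalence
#'
#' Prevalence of a feature is the number of samples in which it is present
#' (value strictly positive). Features with prevalence below the threshold
#' are removed before correlation screens to reduce spurious hits; the
#' default threshold drops features seen in fewer than 10 samples.
#'
#' @param tbl an \code{AbundanceTable}.
#' @param minPrevalence minimum number of positive samples required to keep a
#'   feature (default 10); features with prevalence \code{< minPrevalence}
#'   are dropped.
#' @return The filtered \code{AbundanceTable}, with the dropped feature IDs
#'   available in \code{attr(, "dropped")}.
#' @export
prevalenceFilter <- function(tbl, minPrevalence = 10) {
    stopifnot(is(tbl, "AbundanceTable"))
    prev <- rowSums(tbl@values > 0)
    keep <- prev >= minPrevalence
    out <- abundanceTable(tbl@values[keep, , drop = FALSE],
                          kind = tbl@kind, flags = tbl@flags)
    attr(out, "dropped") <- rownames(tbl@values)[!keep]
    out
}

#' Log-transform with per-feature half-minimum zero imputation
#'
#' For each feature, zeros are imputed with half the minimum positive value
#' observed for that feature across all samples of the table, then the
#' natural log is taken. Brings skewed abundance data closer to normality
#' before parametric modelling.
#'
#' @param tbl an \code{AbundanceTable} with non-negative values; every
#'   feature must have at least one positive value.
#' @return An \code{AbundanceTable} of kind \code{"log"}.
#' @examples
#' m <- matrix(c(0, 4, 8), nrow = 1, dimnames = list("g1", paste0("s", 1:3)))
#' abundanceValues(logTransform(abundanceTable(m)))  # ln(2), ln(4), ln(8)
#' @export
logTransform <- function(tbl) {
    stopifnot(is(tbl, "AbundanceTable"))
    v <- tbl@values
    if (any(v < 0)) stop("negative entries in abundance table")
    allZero <- rowSums(v > 0) == 0
    if (any(allZero))
        stop("cannot impute all-zero feature(s): ",
             paste(rownames(v)[allZero], collapse = ", "))
    for (i in seq_len(nrow(v))) {
        z <- v[i, ] == 0
        if (any(z)) v[i, z] <- min(v[i, !z]) / 2
    }
    abundanceTable(log(v), kind = "log", flags = tbl@flags)
}

#' Build a per-subject delta (post minus pre) matrix
#'
#' Subtracts, per subject, each feature's value at the baseline timepoint
#' from its value at the post-intervention timepoint. Only subjects with
#' exactly one sample at each timepoint contribute a column; subjects lacking
#' a timepoint are omitted (never zero-filled).
#'
#' @param tbl an \code{AbundanceTable} (relative, absolute or log scale).
#' @param sampleSubjects named character vector mapping sample ID to subject.
#' @param sampleTimepoints named character vector mapping sample ID to
#'   timepoint label.
#' @param t0Label,tendLabel the baseline and post-intervention labels.
#' @return A \code{\linkS4class{DeltaTable}} with provenance equal to the
#'   input table's kind.
#' @export
buildDelta <- function(tbl, sampleSubjects, sampleTimepoints,
                       t0Label = "T0", tendLabel = "Tend") {
    stopifnot(is(tbl, "AbundanceTable"))
    samples <- colnames(tbl@values)
    subj <- sampleSubjects[samples]
    tp <- sampleTimepoints[samples]
    if (any(is.na(subj)) || any(is.na(tp)))
        stop("every sample needs a subject and a timepoint label")
    pick <- function(label) {
        s <- samples[tp == label]
        dup <- names(which(table(subj[s]) > 1))
        if (length(dup))
            stop("duplicate samples at ", label, " for subject(s): ",
                 paste(dup, collapse = ", "))
        setNames(s, subj[s])
    }
    at0 <- pick(t0Label)
    at1 <- pick(tendLabel)
    common <- intersect(names(at0), names(at1))
    if (!length(common))
        stop("no subject has both timepoints")
    common <- common[order(common)]
    d <- tbl@values[, at1[common], drop = FALSE] -
         tbl@values[, at0[common], drop = FALSE]
    colnames(d) <- common
    prov <- if (tbl@kind %in% c("relative", "absolute", "log"))
        tbl@kind else "nutrition"
    new("DeltaTable", values = d, provenance = prov)
}

#' Build a delta matrix from a nutrition / metadata table
#'
#' Same pairing logic as \code{\link{buildDelta}} for a component x sample
#' numeric matrix of dietary intakes or clinical values.
#'
#' @param values numeric matrix, components x samples.
#' @inheritParams buildDelta
#' @return A \code{DeltaTable} with provenance \code{"nutrition"}.
#' @export
buildNutritionDelta <- function(values, sampleSubjects, sampleTimepoints,
                                t0Label = "T0", tendLabel = "Tend") {
    tbl <- new("AbundanceTable", values = as.matrix(values), kind = "log",
               flags = character(0))  # kind bypasses non-negativity; retagged
    d <- buildDelta(tbl, sampleSubjects, sampleTimepoints, t0Label, tendLabel)
    new("DeltaTable", values = d@values, provenance = "nutrition")
}

#' Retention filter for delta matrices
#'
#' Keeps features whose delta differs from zero in at least
#' \code{minNonzeroSubjects} subjects AND whose absolute change exceeds
#' \code{minChange} in at least one subject. Applied on the relative scale
#' the default \code{minChange = 0.01} is the "change exceeded 1%" rule.
#'
#' @param delta a \code{\linkS4class{DeltaTable}}.
#' @param minNonzeroSubjects minimum number of subjects with a nonzero delta
#'   (default 10).
#' @param minChange minimum absolute change required in at least one subject
#'   (default 0.01, i.e. one percentage point of relative abundance).
#' @return The filtered \code{DeltaTable}; dropped feature IDs in
#'   \code{attr(, "dropped")}.
#' @export
deltaRetentionFilter <- function(delta, minNonzeroSubjects = 10,
                                 minChange = 0.01) {
    stopifnot(is(delta, "DeltaTable"))
    v <- delta@values
    keep <- rowSums(v != 0) >= minNonzeroSubjects &
            apply(abs(v), 1, function(x) any(x > minChange))
    out <- new("DeltaTable", values = v[keep, , drop = FALSE],
               provenance = delta@provenance)
    attr(out, "dropped") <- rownames(v)[!keep]
    out
}

#' Bacterial load from qPCR Ct values and a standard curve
#'
#' Converts per-sample qPCR cycle-threshold values into bacterial DNA loads
#' via a standard curve of Ct against log10(DNA): \code{DNA = 10^((ct -
#' intercept) / slope)}, divided by stool mass. A perfectly efficient
#' reaction has slope -3.32 (one cycle earlier per doubling).
#'
#' @param ct numeric vector of Ct values, named by sample ID.
#' @param slope,intercept standard-curve parameters (Ct = intercept + slope *
#'   log10(DNA)); slope must be negative.
#' @param stoolMass stool mass in mg per sample (scalar or vector aligned
#'   with \code{ct}).
#' @return A \code{\linkS4class{LoadVector}} in ug DNA / mg stool (units of
#'   the curve's DNA quantity per mg).
#' @examples
#' # Ct at the curve intercept means 1 DNA unit:
#' sampleLoads(loadFromCt(c(s1 = 20), slope = -3.32, intercept = 20,
#'                        stoolMass = 1))
#' @export
loadFromCt <- function(ct, slope, intercept, stoolMass) {
    if (slope >= 0)
        stop("qPCR standard-curve slope must be negative")
    if (any(stoolMass <= 0))
        stop("stool mass must be positive")
    dna <- 10^((ct - intercept) / slope)
    loadVector(dna / stoolMass, sampleIDs = names(ct))
}
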