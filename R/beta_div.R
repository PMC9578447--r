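## Beta diversity from first principles: Bray-Curtis dissimilarity,
## principal coordinates (Gower double-centering + eigendecomposition), and
## single-term PERMANOVA with optional subject-identity blocking via
## restricted (within-block) permutations.

#' Bray-Curtis dissimilarity between samples
#'
#' \eqn{D_{ij} = 1 - 2 \sum_g \min(x_{gi}, x_{gj}) / (\sum_g x_{gi} +
#' \sum_g x_{gj})}. Abundance-weighted and bounded in [0, 1]; identical
#' columns give 0, disjoint supports give 1. A pair of all-zero samples is
#' assigned distance 0 by convention and flagged.
#'
#' @param tbl an \code{AbundanceTable} with non-negative values (counts,
#'   relative or absolute scale) and at least two samples.
#' @return A \code{\linkS4class{DistanceMatrix}}.
#' @examples
#' m <- cbind(s1 = c(1, 0, 3), s2 = c(2, 2, 0))
#' rownames(m) <- paste0("g", 1:3)
#' distanceValues(brayCurtis(abundanceTable(m)))  # off-diagonal = 0.75
#' @export
brayCurtis <- function(tbl) {
    stopifnot(is(tbl, "AbundanceTable"))
    v <- tbl@values
    if (any(v < 0)) stop("negative entries in abundance table")
    n <- ncol(v)
    if (n < 2) stop("need at least two samples")
    tot <- colSums(v)
    D <- matrix(0, n, n, dimnames = list(colnames(v), colnames(v)))
    flags <- character(0)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        denom <- tot[i] + tot[j]
        if (denom == 0) {
            d <- 0  # two empty samples: no basis for dissimilarity
            flags <- c(flags, paste(colnames(v)[i], colnames(v)[j], sep = "|"))
        } else {
            d <- 1 - 2 * sum(pmin(v[, i], v[, j])) / denom
        }
        D[i, j] <- D[j, i] <- d
    }
    if (length(flags))
        warning("all-zero sample pair(s) set to distance 0: ",
                paste(flags, collapse = "; "))
    new("DistanceMatrix", D = D, method = "bray-curtis", flags = flags)
}

## Gower-centered matrix G = -1/2 J A J with A = D^2, J = I - 11'/n.
.gowerCenter <- function(D) {
    A <- -0.5 * D^2
    rm_ <- rowMeans(A)
    cm_ <- colMeans(A)
    A - outer(rm_, rep(1, ncol(A))) - outer(rep(1, nrow(A)), cm_) + mean(A)
}

#' Principal coordinates analysis of a distance matrix
#'
#' Classical metric scaling: the squared-distance matrix is Gower
#' double-centered (\eqn{-\frac12 J D^2 J}), eigendecomposed, and coordinates
#' are eigenvectors scaled by the square root of their eigenvalues. Axes with
#' negative eigenvalues (non-Euclidean dissimilarities such as Bray-Curtis
#' can produce them) are discarded and reported via \code{ordEigenvalues};
#' the proportion explained is computed over positive eigenvalues only.
#'
#' @param D a \code{\linkS4class{DistanceMatrix}}.
#' @param nAxes number of axes to retain (truncated with a warning if fewer
#'   positive eigenvalues exist).
#' @return An \code{\linkS4class{Ordination}}.
#' @export
pcoa <- function(D, nAxes = 2) {
    stopifnot(is(D, "DistanceMatrix"))
    G <- .gowerCenter(D@D)
    e <- eigen((G + t(G)) / 2, symmetric = TRUE)
    tolE <- max(abs(e$values)) * 1e-10
    pos <- which(e$values > tolE)
    if (nAxes > length(pos)) {
        warning("only ", length(pos), " positive eigenvalue(s); truncating")
        nAxes <- length(pos)
    }
    keep <- pos[seq_len(nAxes)]
    coords <- e$vectors[, keep, drop = FALSE] %*%
        diag(sqrt(e$values[keep]), nrow = length(keep))
    dimnames(coords) <- list(rownames(D@D), paste0("PCo", seq_len(nAxes)))
    new("Ordination", coordinates = coords, eigenvalues = e$values,
        proportionExplained = e$values[keep] / sum(e$values[pos]))
}

## Permutation engine: returns a list of index vectors. With blocks, each
## permutation shuffles positions within every block independently; blocks of
## size 1 are fixed points. exhaustive=TRUE enumerates every distinct
## permutation (cartesian product over blocks).
.permIndices <- function(n, blocks, nPerm, exhaustive, seed) {
    if (is.null(blocks)) blocks <- rep(1L, n)
    idxByBlock <- split(seq_len(n), blocks)
    if (exhaustive) {
        permsOf <- function(v) {
            if (length(v) <= 1L) return(list(v))
            out <- list()
            for (k in seq_along(v))
                for (rest in permsOf(v[-k]))
                    out[[length(out) + 1L]] <- c(v[k], rest)
            out
        }
        blockPerms <- lapply(idxByBlock, permsOf)
        combos <- expand.grid(lapply(blockPerms, seq_along))
        lapply(seq_len(nrow(combos)), function(r) {
            idx <- integer(n)
            for (b in seq_along(idxByBlock))
                idx[idxByBlock[[b]]] <- blockPerms[[b]][[combos[r, b]]]
            idx
        })
    } else {
        if (!is.null(seed)) set.seed(seed)
        lapply(seq_len(nPerm), function(r) {
            idx <- seq_len(n)
            for (b in idxByBlock)
                if (length(b) > 1L) idx[b] <- b[sample.int(length(b))]
            idx
        })
    }
}

## Single-term PERMANOVA machinery (McArdle-Anderson): SS from the Gower-
## centered inner-product matrix and the hat matrix of the model [1, X].
.permanovaF <- function(G, x) {
    n <- nrow(G)
    X <- if (is.numeric(x)) {
        cbind(1, x)
    } else {
        model.matrix(~ factor(x))
    }
    q <- qr(X)
    H <- tcrossprod(qr.Q(q)[, seq_len(q$rank), drop = FALSE])
    ssTotal <- sum(diag(G))
    ssModel <- sum(H * G)  # tr(HG), H symmetric
    dfM <- q$rank - 1L
    dfR <- n - q$rank
    ssResid <- ssTotal - ssModel
    list(F = (ssModel / dfM) / (ssResid / dfR),
         R2 = ssModel / ssTotal, dfM = dfM, dfR = dfR)
}

#' PERMANOVA with optional subject-identity blocking
#'
#' Permutational multivariate analysis of variance on a distance matrix for a
#' single term (a grouping factor or a numeric covariate), with the
#' permutation null restricted within blocks when a blocking factor (for
#' example subject identity in a paired design) is supplied — the analogue of
#' the \code{strata} option of \code{vegan::adonis}. Sums of squares follow
#' the McArdle-Anderson identity: the squared-distance matrix is Gower
#' centered and the model sum of squares is the trace of its product with
#' the hat matrix of the single-term model (an intercept plus the factor
#' dummies or the centered covariate).
#'
#' @param D a \code{\linkS4class{DistanceMatrix}}.
#' @param covariate per-sample values, named by sample ID or aligned with the
#'   distance matrix: a character/factor grouping or a numeric covariate.
#' @param blocks optional per-sample blocking labels (permutations shuffle
#'   covariate values only within a block; single-sample blocks are fixed).
#' @param nPerm number of random permutations (default 999; the observed
#'   statistic is included in the null via the +1/+1 convention, so the
#'   smallest attainable p is 1/(nPerm+1)).
#' @param exhaustive enumerate all distinct permutations instead of sampling;
#'   p is then the exact fraction of permutations (identity included) with
#'   \eqn{F \ge F_{obs}}. Only sensible for small n.
#' @param seed RNG seed for the permutation stream.
#' @param term label for the tested covariate in the result.
#' @return A \code{\linkS4class{PermanovaResult}}.
#' @export
permanova <- function(D, covariate, blocks = NULL, nPerm = 999,
                      exhaustive = FALSE, seed = NULL, term = "covariate") {
    stopifnot(is(D, "DistanceMatrix"))
    n <- nrow(D@D)
    ids <- rownames(D@D)
    align <- function(v) {
        if (!is.null(names(v))) {
            miss <- setdiff(ids, names(v))
            if (length(miss))
                stop("covariate/blocks missing sample(s): ",
                     paste(miss, collapse = ", "))
            v[ids]
        } else {
            if (length(v) != n)
                stop("unnamed covariate must match the number of samples")
            v
        }
    }
    x <- align(covariate)
    if (length(unique(x)) < 2L) stop("constant covariate")
    if (!is.null(blocks)) blocks <- as.character(align(blocks))
    G <- .gowerCenter(D@D)
    obs <- .permanovaF(G, x)
    idx <- .permIndices(n, blocks, nPerm, exhaustive, seed)
    fPerm <- vapply(idx, function(i) .permanovaF(G, x[i])$F, numeric(1))
    tol <- 1e-8 * max(1, abs(obs$F))   # count numerically tied F as >=
    if (exhaustive) {
        p <- mean(fPerm >= obs$F - tol)
        nP <- length(idx)
    } else {
        p <- (1 + sum(fPerm >= obs$F - tol)) / (nPerm + 1)
        nP <- nPerm
    }
    new("PermanovaResult", term = term, pseudoF = obs$F, R2 = obs$R2,
        p = p, nPerm = as.numeric(nP),
        blockedBy = if (is.null(blocks)) NA_character_ else "blocks")
}

#' Correlate ordination axes with metadata variables
#'
#' Extracts each requested principal-coordinate axis and runs the Spearman
#' correlation screen of \code{\link{correlationScreen}} against every
#' numeric metadata column, with one Benjamini-Hochberg family across the
#' whole (axis x variable) screen. Variables with fewer than 3 non-missing
#' values, or constant over the samples, are skipped with a note.
#'
#' @param ord an \code{\linkS4class{Ordination}}.
#' @param metadata data.frame of per-sample covariates with a
#'   \code{sample_id} column (or rownames) matching the ordination.
#' @param axes integer vector of axis numbers to screen (default first two).
#' @return data.frame with columns \code{feature} (axis), \code{covariate},
#'   \code{rho}, \code{p}, \code{q}, \code{n}; skipped variables listed in
#'   \code{attr(, "skipped")}.
#' @export
axisCorrelations <- function(ord, metadata, axes = c(1, 2)) {
    stopifnot(is(ord, "Ordination"))
    co <- ord@coordinates
    axes <- axes[axes <= ncol(co)]
    ids <- rownames(co)
    if ("sample_id" %in% names(metadata)) {
        rownames(metadata) <- metadata$sample_id
    }
    miss <- setdiff(ids, rownames(metadata))
    if (length(miss))
        stop("metadata missing sample(s): ", paste(miss, collapse = ", "))
    md <- metadata[ids, setdiff(names(metadata), "sample_id"), drop = FALSE]
    num <- vapply(md, is.numeric, logical(1))
    axisTbl <- t(co[, axes, drop = FALSE])
    rownames(axisTbl) <- colnames(co)[axes]
    correlationScreen(axisTbl, md[, num, drop = FALSE])
}
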