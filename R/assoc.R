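## Rank-based correlation screens with BH-FDR control, OLS covariate models,
## and deterministic heatmap ordering.

#' Spearman rank correlation with a t-approximation p-value
#'
#' Ranks both vectors with average ranks for ties, computes the Pearson
#' correlation of the ranks, and derives a two-sided p-value from
#' \eqn{t = \rho \sqrt{(n-2)/(1-\rho^2)}} on \eqn{n-2} degrees of freedom.
#' Pairs with a missing value in either vector are dropped (pairwise
#' deletion) and the effective n is reported.
#'
#' @param x,y paired numeric vectors.
#' @return List with \code{rho}, \code{p}, \code{n} (complete pairs used).
#' @examples
#' spearmanCor(1:3, c(10, 20, 30))$rho  # 1
#' @export
spearmanCor <- function(x, y) {
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    n <- length(x)
    if (n < 3)
        stop("need at least 3 complete pairs")
    if (var(x) == 0 || var(y) == 0)
        stop("Spearman correlation undefined for a constant vector")
    rx <- rank(x); ry <- rank(y)
    rho <- cor(rx, ry)
    if (abs(rho) >= 1) {
        p <- 0
    } else {
        tstat <- rho * sqrt((n - 2) / (1 - rho^2))
        p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
    }
    list(rho = rho, p = p, n = n)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Classic FDR step-up: with p-values sorted ascending,
#' \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j}, capped at 1, mapped back to
#' the input order. \code{NA}s are passed through without contributing to the
#' family size.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return Vector of q-values, same length and order as \code{p}.
#' @examples
#' bhFDR(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bhFDR <- function(p) {
    q <- rep(NA_real_, length(p))
    ok <- which(!is.na(p))
    pv <- p[ok]
    if (any(pv < 0 | pv > 1))
        stop("p-values must lie in [0, 1]")
    m <- length(pv)
    if (m) {
        o <- order(pv)
        qq <- pv[o] * m / seq_len(m)
        qq <- rev(cummin(rev(qq)))      # enforce step-up monotonicity
        qq <- pmin(qq, 1)
        q[ok[o]] <- qq
    }
    q
}

.screenMatrix <- function(features) {
    if (is(features, "AbundanceTable") || is(features, "DeltaTable"))
        features@values
    else as.matrix(features)
}

#' Spearman correlation screen of features against covariates
#'
#' Correlates every feature (row of an abundance or delta table) against
#' every numeric covariate column, applying one Benjamini-Hochberg family
#' across the entire screen — one q-value family per call, mirroring
#' per-figure FDR control. Constant or too-sparse pairs (fewer than 3
#' complete observations, or zero variance) are skipped and listed in
#' \code{attr(, "skipped")}.
#'
#' @param features an \code{AbundanceTable}, \code{DeltaTable} or numeric
#'   matrix (features x samples/subjects). Apply prevalence or delta
#'   retention filters upstream.
#' @param covariates data.frame or matrix of per-sample (or per-subject)
#'   covariates, rows aligned with the feature columns (matched by name when
#'   rownames/names are available).
#' @param qMax,rhoMin optional reporting cut-offs; rows with \code{q > qMax}
#'   or \code{|rho| < rhoMin} are dropped from the output (the full screen is
#'   still used for the BH family).
#' @return data.frame with columns \code{feature}, \code{covariate},
#'   \code{rho}, \code{p}, \code{q}, \code{n}, sorted by q then p.
#' @export
correlationScreen <- function(features, covariates, qMax = 1, rhoMin = 0) {
    fm <- .screenMatrix(features)
    cm <- as.data.frame(covariates)
    if (!is.null(rownames(cm)) && !is.null(colnames(fm)) &&
        all(colnames(fm) %in% rownames(cm)))
        cm <- cm[colnames(fm), , drop = FALSE]
    if (nrow(cm) != ncol(fm))
        stop("covariate rows must align with feature columns")
    if (!nrow(fm) || !ncol(cm)) stop("empty screen")
    res <- list()
    skipped <- character(0)
    for (g in rownames(fm)) for (v in colnames(cm)) {
        x <- fm[g, ]
        y <- cm[[v]]
        if (!is.numeric(y)) next
        ok <- is.finite(x) & is.finite(y)
        if (sum(ok) < 3 || var(x[ok]) == 0 || var(y[ok]) == 0) {
            skipped <- c(skipped, paste(g, v, sep = " ~ "))
            next
        }
        s <- spearmanCor(x, y)
        res[[length(res) + 1L]] <- data.frame(
            feature = g, covariate = v, rho = s$rho, p = s$p, n = s$n,
            stringsAsFactors = FALSE)
    }
    if (!length(res)) stop("no testable feature-covariate pairs")
    tab <- do.call(rbind, res)
    tab$q <- bhFDR(tab$p)
    tab <- tab[tab$q <= qMax & abs(tab$rho) >= rhoMin, , drop = FALSE]
    tab <- tab[order(tab$q, tab$p, tab$feature, tab$covariate), ]
    rownames(tab) <- NULL
    tab <- tab[, c("feature", "covariate", "rho", "p", "q", "n")]
    attr(tab, "skipped") <- skipped
    tab
}

#' Ordinary least-squares fit with classical inference
#'
#' Fits \code{response ~ intercept + design} by least squares and reports
#' coefficient estimates, classical standard errors, t statistics and
#' two-sided p-values, plus the model R-squared. Log-transformation of
#' abundance responses (half-minimum imputation + \code{log}) is the
#' caller's responsibility.
#'
#' @param response numeric vector.
#' @param design data.frame of explanatory variables (factors allowed; a
#'   two-level factor such as gender becomes a 0/1 indicator). \code{NULL} or
#'   an empty data.frame fits the intercept-only model.
#' @return List with \code{coefficients} (data.frame: term, estimate, se, t,
#'   p), \code{r_squared}, \code{n}, \code{fitted}, \code{residuals}.
#' @export
olsFit <- function(response, design = NULL) {
    if (is.null(design) || !length(design)) {
        design <- data.frame(row.names = seq_along(response))
    }
    design <- as.data.frame(design)
    if (nrow(design) != length(response))
        stop("design rows must match the response length")
    dat <- cbind(.y = response, design)
    dat <- dat[complete.cases(dat), , drop = FALSE]
    k <- ncol(design) + 1L
    if (nrow(dat) <= k)
        stop("need more observations than coefficients")
    fit <- lm(.y ~ ., data = dat)
    if (any(is.na(coef(fit)))) {
        bad <- names(coef(fit))[is.na(coef(fit))]
        stop("rank-deficient design; collinear column(s): ",
             paste(bad, collapse = ", "))
    }
    sm <- summary(fit)
    co <- sm$coefficients
    list(coefficients = data.frame(
             term = rownames(co), estimate = co[, 1], se = co[, 2],
             t = co[, 3], p = co[, 4], row.names = NULL,
             stringsAsFactors = FALSE),
         r_squared = sm$r.squared,
         n = nrow(dat),
         fitted = unname(fit$fitted.values),
         residuals = unname(fit$residuals))
}

#' Deterministic row/column ordering for an association heatmap
#'
#' Reshapes an association table into a feature x covariate rho matrix
#' (missing pairs as 0), then orders rows and columns by average-linkage
#' hierarchical clustering on a 1 - correlation distance between rho
#' profiles, so features with similar co-interaction patterns sit together.
#' Rows and columns are pre-sorted by label, making the ordering invariant to
#' the input row order; with fewer than 3 rows the label ordering is
#' returned as is.
#'
#' @param assoc data.frame as returned by \code{\link{correlationScreen}}, or
#'   a numeric rho matrix.
#' @return List with \code{rowOrder} and \code{colOrder} (character vectors
#'   of labels in display order) and \code{rho} (the reshaped matrix).
#' @export
heatmapOrder <- function(assoc) {
    if (is.data.frame(assoc)) {
        feats <- sort(unique(assoc$feature))
        covs <- sort(unique(assoc$covariate))
        m <- matrix(0, length(feats), length(covs),
                    dimnames = list(feats, covs))
        m[cbind(match(assoc$feature, feats),
                match(assoc$covariate, covs))] <- assoc$rho
    } else {
        m <- as.matrix(assoc)
        m <- m[order(rownames(m)), order(colnames(m)), drop = FALSE]
    }
    orderOf <- function(mat) {
        if (nrow(mat) < 3 || ncol(mat) < 2)
            return(rownames(mat))
        d <- as.dist(1 - .rhoSimilarity(mat))
        hc <- hclust(d, method = "average")
        rownames(mat)[hc$order]
    }
    list(rowOrder = orderOf(m), colOrder = orderOf(t(m)), rho = m)
}

## Pairwise similarity between rows for heatmap clustering: the rho values
## themselves are the profile, so similarity is row-wise Pearson; degenerate
## (constant) rows fall back to 0 similarity.
.rhoSimilarity <- function(mat) {
    n <- nrow(mat)
    s <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
    for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i == j) { s[i, j] <- 1; next }
        r <- if (sd(mat[i, ]) == 0 || sd(mat[j, ]) == 0) 0
             else cor(mat[i, ], mat[j, ])
        s[i, j] <- if (is.na(r)) 0 else r
    }
    s
}
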