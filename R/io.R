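## Plain-text readers and writers: TSV count tables (first column
## feature_id, remaining columns sample IDs), CSV loads/metadata keyed by
## sample_id, CSV questionnaires keyed by (subject, date). All UTF-8 with
## deterministic column order; mixed (CRLF) line endings are accepted.

.checkIDs <- function(ids, what) {
    dup <- unique(ids[duplicated(ids)])
    if (length(dup))
        stop("duplicate ", what, " ID(s): ", paste(dup, collapse = ", "))
}

#' Read / write an abundance count table (TSV)
#'
#' @param path TSV file, first column \code{feature_id}, one column per
#'   sample.
#' @param kind scale tag to stamp on the table (default \code{"counts"}).
#' @return \code{readCounts}: an \code{AbundanceTable}.
#' @export
readCounts <- function(path, kind = "counts") {
    df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (names(df)[1] != "feature_id")
        stop("malformed count table (first column must be 'feature_id'): ",
             path)
    .checkIDs(df$feature_id, "feature")
    .checkIDs(names(df)[-1], "sample")
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$feature_id
    abundanceTable(m, kind = kind)
}

#' @rdname readCounts
#' @param tbl an \code{AbundanceTable} to write.
#' @export
writeCounts <- function(tbl, path) {
    v <- tbl@values
    df <- cbind(data.frame(feature_id = if (is.null(rownames(v)))
                               character(0) else rownames(v),
                           stringsAsFactors = FALSE),
                as.data.frame(v, check.names = FALSE))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}

#' Read / write per-sample bacterial loads (CSV)
#'
#' @param path CSV with columns \code{sample_id}, \code{load_ug_per_mg}.
#' @return \code{readLoads}: a \code{LoadVector}.
#' @export
readLoads <- function(path) {
    df <- read.csv(path, stringsAsFactors = FALSE)
    need <- c("sample_id", "load_ug_per_mg")
    if (!all(need %in% names(df)))
        stop("loads file needs columns sample_id, load_ug_per_mg: ", path)
    .checkIDs(df$sample_id, "sample")
    loadVector(df$load_ug_per_mg, sampleIDs = df$sample_id)
}

#' @rdname readLoads
#' @param loads a \code{LoadVector} to write.
#' @export
writeLoads <- function(loads, path) {
    write.csv(data.frame(sample_id = names(loads@load),
                         load_ug_per_mg = unname(loads@load)),
              path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Read daily questionnaire records (CSV)
#'
#' One row per (subject, date); \code{food_colors} as semicolon-separated
#' labels; boolean items as 0/1.
#'
#' @param path CSV file.
#' @return data.frame in the format \code{\link{scoreTable}} expects.
#' @export
readQuestionnaires <- function(path) {
    df <- read.csv(path, stringsAsFactors = FALSE,
                   colClasses = c(food_colors = "character"))
    dup <- duplicated(df[, c("subject", "date")])
    if (any(dup))
        stop("duplicate (subject, date) questionnaire row(s): ",
             paste(unique(paste(df$subject[dup], df$date[dup])),
                   collapse = ", "))
    df$food_colors[is.na(df$food_colors)] <- ""
    df
}

#' Read per-sample clinical/lifestyle metadata (CSV)
#'
#' @param path CSV keyed by \code{sample_id}.
#' @return data.frame with unique sample IDs.
#' @export
readMetadata <- function(path) {
    df <- read.csv(path, stringsAsFactors = FALSE)
    if (!"sample_id" %in% names(df))
        stop("metadata needs a sample_id column: ", path)
    .checkIDs(df$sample_id, "sample")
    df
}

#' Write an association table (TSV)
#'
#' @param assoc data.frame from \code{\link{correlationScreen}}.
#' @param path output TSV.
#' @export
writeAssociations <- function(assoc, path) {
    utils::write.table(assoc, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}

#' Write a distance matrix (square labeled TSV)
#'
#' @param D a \code{DistanceMatrix}.
#' @param path output TSV.
#' @export
writeDistances <- function(D, path) {
    df <- data.frame(sample_id = rownames(D@D), D@D, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}
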