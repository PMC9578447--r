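## End-to-end orchestration: adherence scoring -> abundance preprocessing ->
## ordination + PERMANOVA -> correlation screens + OLS, from a config list
## or YAML file, with deterministic outputs and a JSON manifest.

#' Assemble a pipeline configuration
#'
#' Builds (and validates lazily; file existence is checked by
#' \code{\link{runPipeline}} before any compute) the configuration consumed
#' by \code{\link{runPipeline}}. Defaults mirror the analysis conventions:
#' prevalence filter at 10 samples, delta retention at 10 subjects and a 1%
#' change, 999 permutations, reporting cut-offs q < 0.2 and |rho| >= 0.4 for
#' the delta screen.
#'
#' @param counts16S path to the bacterial genus count TSV.
#' @param questionnaires path to the daily questionnaire CSV.
#' @param metadata path to the per-sample metadata CSV.
#' @param loads path to the loads CSV, or \code{NULL} if \code{ct} is given.
#' @param ct optional list \code{list(path=, slope=, intercept=)}; the CSV
#'   needs columns \code{sample_id}, \code{ct}, \code{stool_mass_mg}.
#' @param counts18S optional eukaryal count TSV.
#' @param t0Label,tendLabel timepoint labels in the metadata.
#' @param t0Window,tendWindow length-2 date ranges of the baseline and
#'   intervention questionnaire windows.
#' @param prevalenceMin,deltaMinNonzero,deltaMinChange filter thresholds.
#' @param deltaScale \code{"absolute"} (linear, default) or \code{"log"}
#'   scale for the delta-vs-score screen.
#' @param nPerm,seed permutation count and global seed.
#' @param qMax,rhoMin reporting cut-offs for the delta screen output.
#' @param permanovaCovariates metadata columns tested one term at a time
#'   with subject blocking (default \code{"med_score"}).
#' @return A named list of class \code{pipelineConfig}.
#' @export
pipelineConfig <- function(counts16S, questionnaires, metadata,
                           loads = NULL, ct = NULL, counts18S = NULL,
                           t0Label = "T0", tendLabel = "Tend",
                           t0Window = c("2024-01-01", "2024-01-07"),
                           tendWindow = c("2024-01-08", "2024-02-04"),
                           prevalenceMin = 10, deltaMinNonzero = 10,
                           deltaMinChange = 0.01,
                           deltaScale = c("absolute", "log"),
                           nPerm = 999, seed = 1, qMax = 0.2, rhoMin = 0.4,
                           permanovaCovariates = "med_score") {
    cfg <- list(counts_16s = counts16S, counts_18s = counts18S,
                loads = loads, ct = ct, questionnaires = questionnaires,
                metadata = metadata, t0_label = t0Label,
                tend_label = tendLabel,
                t0_window = as.character(t0Window),
                tend_window = as.character(tendWindow),
                prevalence_min = prevalenceMin,
                delta_min_nonzero = deltaMinNonzero,
                delta_min_change = deltaMinChange,
                delta_scale = match.arg(deltaScale),
                n_perm = nPerm, seed = seed, q_max = qMax, rho_min = rhoMin,
                permanova_covariates = permanovaCovariates)
    stopifnot(cfg$prevalence_min >= 0, cfg$delta_min_nonzero >= 0,
              cfg$delta_min_change >= 0, cfg$n_perm >= 1)
    class(cfg) <- "pipelineConfig"
    cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the \code{\link{pipelineConfig}}
#'   arguments (snake_case as in the returned list).
#' @return A \code{pipelineConfig}.
#' @export
readPipelineConfig <- function(path) {
    y <- yaml::read_yaml(path)
    pipelineConfig(
        counts16S = y$counts_16s, questionnaires = y$questionnaires,
        metadata = y$metadata, loads = y$loads, ct = y$ct,
        counts18S = y$counts_18s,
        t0Label = y$t0_label %||% "T0", tendLabel = y$tend_label %||% "Tend",
        t0Window = y$t0_window %||% c("2024-01-01", "2024-01-07"),
        tendWindow = y$tend_window %||% c("2024-01-08", "2024-02-04"),
        prevalenceMin = y$prevalence_min %||% 10,
        deltaMinNonzero = y$delta_min_nonzero %||% 10,
        deltaMinChange = y$delta_min_change %||% 0.01,
        deltaScale = y$delta_scale %||% "absolute",
        nPerm = y$n_perm %||% 999, seed = y$seed %||% 1,
        qMax = y$q_max %||% 0.2, rhoMin = y$rho_min %||% 0.4,
        permanovaCovariates = y$permanova_covariates %||% "med_score")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.configHash <- function(cfg) {
    tmp <- tempfile(fileext = ".json")
    on.exit(unlink(tmp))
    writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                                null = "null"), tmp)
    unname(tools::md5sum(tmp))
}

.stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: daily adherence scoring and per-subject score changes;
#' relative and absolute abundance transformation; Bray-Curtis dissimilarity,
#' PCoA and PERMANOVA (subject identity unrestricted, then each configured
#' covariate with subject-identity blocking); the post-intervention Spearman
#' screen of prevalence-filtered genera against metadata; the delta screen of
#' retained genera's absolute-abundance changes against the per-subject score
#' change; PCoA-axis correlations; and an OLS model of the two genera most
#' correlated with daily steps (log absolute abundance at the
#' post-intervention timepoint on steps, age, gender, BMI and fruit intake).
#' All result tables plus a JSON manifest (package version, config and its
#' hash, seed) are written under \code{outDir}; with a fixed seed the run is
#' fully deterministic. Inputs are validated before any computation.
#'
#' @param cfg a \code{\link{pipelineConfig}} (or path to a YAML config).
#' @param outDir output directory.
#' @return Invisibly, a list with the in-memory results: \code{scores},
#'   \code{deltaScores}, \code{relative}, \code{absolute}, \code{bray},
#'   \code{ordination}, \code{permanova} (data.frame), \code{postScreen},
#'   \code{deltaScreen}, \code{axisScreen}, \code{ols}, \code{manifest}.
#' @export
runPipeline <- function(cfg, outDir) {
    if (is.character(cfg)) cfg <- readPipelineConfig(cfg)
    stopifnot(inherits(cfg, "pipelineConfig"))

    ## -- validate inputs before any compute
    files <- c(cfg$counts_16s, cfg$counts_18s, cfg$questionnaires,
               cfg$metadata, cfg$loads, cfg$ct$path)
    missing <- files[!file.exists(files)]
    if (length(missing))
        stop("missing input file(s): ", paste(missing, collapse = ", "))
    if (is.null(cfg$loads) && is.null(cfg$ct))
        stop("config must provide either 'loads' or 'ct' (Ct + curve)")
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)

    seeds <- cfg$seed + c(perm = 1, screen = 2)  # fixed fan-out per stage

    ## -- adherence scores
    quest <- .stage("med_score", {
        scoreTable(readQuestionnaires(cfg$questionnaires))
    })
    scores <- summarizeScores(quest, cfg$tend_window)
    dScore <- deltaScore(quest, cfg$t0_window, cfg$tend_window)

    ## -- abundance preprocessing
    md <- .stage("metadata", readMetadata(cfg$metadata))
    rownames(md) <- md$sample_id
    res <- .stage("abundance", {
        counts <- readCounts(cfg$counts_16s)
        loads <- if (!is.null(cfg$loads)) readLoads(cfg$loads) else {
            ctTab <- read.csv(cfg$ct$path, stringsAsFactors = FALSE)
            lv <- loadFromCt(setNames(ctTab$ct, ctTab$sample_id),
                             slope = cfg$ct$slope,
                             intercept = cfg$ct$intercept,
                             stoolMass = ctTab$stool_mass_mg)
            lv
        }
        rel <- toRelative(counts)
        list(counts = counts, loads = loads, rel = rel,
             abs = toAbsolute(rel, loads))
    })
    sampleSubj <- setNames(md$subject, md$sample_id)
    sampleTp <- setNames(md$timepoint, md$sample_id)

    ## -- beta diversity
    beta <- .stage("beta_div", {
        bc <- brayCurtis(res$rel)
        ord <- pcoa(bc, nAxes = 2)
        prs <- list(permanova(bc, sampleSubj, nPerm = cfg$n_perm,
                              seed = seeds["perm"], term = "subject"))
        for (v in cfg$permanova_covariates) {
            if (!v %in% names(md)) next
            prs[[length(prs) + 1L]] <- permanova(
                bc, setNames(md[[v]], md$sample_id),
                blocks = sampleSubj, nPerm = cfg$n_perm,
                seed = seeds["perm"], term = v)
        }
        list(bc = bc, ord = ord, prs = prs)
    })
    permTab <- do.call(rbind, lapply(beta$prs, function(p) data.frame(
        term = p@term, pseudo_F = p@pseudoF, R2 = p@R2, p = p@p,
        n_perm = p@nPerm, blocked = !is.na(p@blockedBy))))
    permTab$q <- bhFDR(permTab$p)

    ## -- correlation screens
    tendSamples <- md$sample_id[md$timepoint == cfg$tend_label]
    screens <- .stage("assoc", {
        filt <- prevalenceFilter(res$rel, cfg$prevalence_min)
        numCols <- names(md)[vapply(md, is.numeric, logical(1))]
        numCols <- setdiff(numCols, "gender")
        post <- correlationScreen(
            filt@values[, tendSamples, drop = FALSE],
            md[tendSamples, numCols, drop = FALSE])

        dRel <- buildDelta(res$rel, sampleSubj, sampleTp,
                           cfg$t0_label, cfg$tend_label)
        dRelKept <- deltaRetentionFilter(dRel, cfg$delta_min_nonzero,
                                         cfg$delta_min_change)
        absTbl <- if (cfg$delta_scale == "log") logTransform(res$abs)
                  else res$abs
        dAbs <- buildDelta(absTbl, sampleSubj, sampleTp,
                           cfg$t0_label, cfg$tend_label)
        kept <- intersect(rownames(dRelKept@values), rownames(dAbs@values))
        dAbsKept <- new("DeltaTable",
                        values = dAbs@values[kept, , drop = FALSE],
                        provenance = dAbs@provenance)
        subj <- colnames(dAbsKept@values)
        deltaScreen <- correlationScreen(
            dAbsKept, data.frame(delta_med_score = dScore[subj],
                                 row.names = subj))
        axisScreen <- axisCorrelations(beta$ord, md[, c("sample_id", numCols)])
        list(post = post, delta = deltaScreen, axis = axisScreen,
             deltaAbs = dAbsKept, dRel = dRelKept)
    })

    ## -- OLS for the steps association
    ols <- .stage("ols", {
        st <- screens$post[screens$post$covariate == "steps", ]
        if (!nrow(st)) NULL else {
            targets <- head(st$feature[order(-abs(st$rho))], 2)
            logAbs <- logTransform(res$abs)
            lapply(setNames(targets, targets), function(g) {
                olsFit(logAbs@values[g, tendSamples],
                       md[tendSamples, c("steps", "age", "gender", "bmi",
                                         "fruits")])
            })
        }
    })

    ## -- outputs
    manifest <- list(package = "micromed",
                     version = as.character(utils::packageVersion("micromed")),
                     config = unclass(cfg), config_hash = .configHash(cfg),
                     seed = cfg$seed)
    paths <- list(
        scores = file.path(outDir, "scores.tsv"),
        delta_scores = file.path(outDir, "delta_scores.tsv"),
        distances = file.path(outDir, "bray_curtis.tsv"),
        ordination = file.path(outDir, "ordination.tsv"),
        permanova = file.path(outDir, "permanova.tsv"),
        post_screen = file.path(outDir, "screen_post.tsv"),
        delta_screen = file.path(outDir, "screen_delta.tsv"),
        axis_screen = file.path(outDir, "screen_axes.tsv"),
        ols = file.path(outDir, "ols.json"),
        manifest = file.path(outDir, "manifest.json"))
    wt <- function(x, p) utils::write.table(
        x, p, sep = "\t", quote = FALSE, row.names = FALSE,
        fileEncoding = "UTF-8")
    wt(scores, paths$scores)
    wt(data.frame(subject = names(dScore), delta_med_score = unname(dScore)),
       paths$delta_scores)
    writeDistances(beta$bc, paths$distances)
    ordTab <- data.frame(sample_id = rownames(beta$ord@coordinates),
                         beta$ord@coordinates, check.names = FALSE)
    wt(ordTab, paths$ordination)
    wt(permTab, paths$permanova)
    writeAssociations(screens$post, paths$post_screen)
    writeAssociations(
        screens$delta[screens$delta$q <= cfg$q_max &
                      abs(screens$delta$rho) >= cfg$rho_min, , drop = FALSE],
        paths$delta_screen)
    writeAssociations(screens$axis, paths$axis_screen)
    if (!is.null(ols))
        jsonlite::write_json(
            lapply(ols, function(f) f[c("coefficients", "r_squared", "n")]),
            paths$ols, auto_unbox = TRUE, digits = NA, dataframe = "rows")
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")

    invisible(list(scores = scores, deltaScores = dScore,
                   relative = res$rel, absolute = res$abs, bray = beta$bc,
                   ordination = beta$ord, permanova = permTab,
                   postScreen = screens$post, deltaScreen = screens$delta,
                   axisScreen = screens$axis, ols = ols,
                   manifest = manifest, paths = paths))
}
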