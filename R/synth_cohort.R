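## Synthetic paired-cohort generator.
##
## Emulates the statistical structure of a 4-week diet-intervention cohort:
## a strong per-subject compositional signature (log-normal perturbation of a
## shared genus profile + multinomial sampling), log-normal bacterial loads,
## daily adherence questionnaires whose mean score rises from ~15-16 at
## baseline to ~23 during the intervention, designated "beneficial" genera
## whose post-intervention absolute abundance rises with the subject's score
## improvement, an inverse adherence-calprotectin/WBC association, a steps
## effect on two butyrate-producer-like genera, and a sparse unstable
## eukaryome with one taxon tied to sweets intake.

#' Construct a CohortSpec
#'
#' @param nSubjects number of subjects (default 20, the cohort scale the
#'   generator emulates).
#' @param nGenera number of bacterial genera (default 150).
#' @param nEuk number of eukaryal taxa (default 30).
#' @param timepoints ordered labels; the first is baseline, the second is
#'   post-intervention, any further labels are follow-up visits with
#'   baseline-like structure (washout).
#' @param subjectEffectSD log-scale SD of the per-subject genus profile
#'   perturbation (default 0.35, calibrated so subject identity explains
#'   roughly 70 percent of Bray-Curtis variance at the default design;
#'   0 removes the subject signature).
#' @param plantedGenera 1-based indices of the adherence-responsive genera
#'   (default 1:5).
#' @param plantedRho target Spearman correlation between the per-subject
#'   score change and the planted genera's absolute-abundance change
#'   (default 0.8).
#' @param calprotectinSlope log-scale slope of post-intervention fecal
#'   calprotectin on the standardized score change (default -0.5).
#' @param seed integer RNG seed.
#' @return A \code{\linkS4class{CohortSpec}}.
#' @export
cohortSpec <- function(nSubjects = 20, nGenera = 150, nEuk = 30,
                       timepoints = c("T0", "Tend"), subjectEffectSD = 0.35,
                       plantedGenera = 1:5, plantedRho = 0.8,
                       calprotectinSlope = -0.5, seed = 1) {
    new("CohortSpec", nSubjects = as.integer(nSubjects),
        nGenera = as.integer(nGenera), nEuk = as.integer(nEuk),
        timepoints = as.character(timepoints),
        subjectEffectSD = as.numeric(subjectEffectSD),
        plantedGenera = as.integer(plantedGenera),
        plantedRho = as.numeric(plantedRho),
        calprotectinSlope = as.numeric(calprotectinSlope),
        seed = as.integer(seed))
}

## Daily questionnaire item rates. Baseline rates put the expected daily
## score around 15-16; intervention rates around 23, echoing the observed
## cohort shift. Poisson items are capped by scoring, Bernoulli items are
## the binary components.
.Q_RATES <- list(
    baseline = list(veg = 3.2, fruit = 1.6, oil = 1.0, grains = 1.3,
                    water = 4.0, colorP = 0.55, nuts = 0.35, legumes = 0.35,
                    yogurt = 0.40, step = 0.30, exercise = 0.30),
    intervention = list(veg = 5.5, fruit = 3.0, oil = 2.6, grains = 3.0,
                        water = 6.0, colorP = 0.84, nuts = 0.75,
                        legumes = 0.75, yogurt = 0.78, step = 0.74,
                        exercise = 0.65))

.simulateDays <- function(subject, dates, rates, adjLog) {
    n <- length(dates)
    lam <- function(l) l * exp(adjLog)
    pr <- function(p) stats::plogis(stats::qlogis(p) + adjLog)
    nColors <- rbinom(n, 6, pr(rates$colorP))
    colors <- vapply(nColors, function(k)
        paste(sort(sample(.MED_COLORS, k)), collapse = ";"), character(1))
    data.frame(
        subject = subject, date = as.character(dates),
        vegetables = rpois(n, lam(rates$veg)),
        fruits = rpois(n, lam(rates$fruit)),
        food_colors = colors,
        olive_oil_tbsp = rpois(n, lam(rates$oil)),
        nuts_seeds = rbinom(n, 1, pr(rates$nuts)),
        legumes_soy = rbinom(n, 1, pr(rates$legumes)),
        yogurt = rbinom(n, 1, pr(rates$yogurt)),
        whole_grains = rpois(n, lam(rates$grains)),
        water_glasses = rpois(n, lam(rates$water)),
        step_goal_met = rbinom(n, 1, pr(rates$step)),
        exercised = rbinom(n, 1, pr(rates$exercise)),
        stringsAsFactors = FALSE)
}

.softmax <- function(lw) {
    w <- exp(lw - max(lw[is.finite(lw)]))
    w[!is.finite(lw) & lw < 0] <- 0
    w / sum(w)
}

#' Generate a synthetic paired diet-intervention cohort
#'
#' Draws, under a single seed, (i) 35 daily questionnaire records per subject
#' (7 baseline days + 28 intervention days) with per-subject adherence and
#' improvement heterogeneity; (ii) bacterial counts from per-subject
#' log-normal genus profiles (dispersion \code{subjectEffectSD}) via
#' multinomial sampling at depths uniform in 5,000-15,000 reads; (iii)
#' log-normal bacterial loads, mildly increasing with adherence improvement;
#' (iv) a post-intervention log-abundance shift of the planted genera equal
#' to \code{plantedEffect * s_gj}, where \code{s_gj} has correlation
#' \code{plantedRho} with the subject's standardized score change, so the
#' realized Spearman correlation between delta score and delta absolute
#' abundance approaches \code{plantedRho}; (v) clinical metadata with fecal
#' calprotectin and leukocyte counts declining in the improvers; (vi) a
#' sparse, low-richness eukaryal table whose per-sample dominant taxon is
#' resampled independently at every timepoint (no subject signature) with
#' one taxon tied to sweets servings. Every planted parameter is recorded in
#' the returned \code{truth} list.
#'
#' Planted (diet-responsive) genera carry a damped subject signature
#' (log-SD at most 0.4): their between-subject spread would otherwise
#' dominate the ranks of the absolute-abundance changes and attenuate the
#' planted correlation far below its target.
#'
#' @param spec a \code{\linkS4class{CohortSpec}}.
#' @param plantedEffect log-scale effect size of the planted
#'   post-intervention shift per unit of the latent adherence signal
#'   (default 1.5).
#' @return A \code{\linkS4class{SyntheticCohort}}.
#' @examples
#' ch <- generateCohort(cohortSpec(nSubjects = 6, nGenera = 40, seed = 7))
#' ch
#' @export
generateCohort <- function(spec, plantedEffect = 1.5) {
    stopifnot(is(spec, "CohortSpec"))
    validObject(spec)
    set.seed(spec@seed)
    nS <- spec@nSubjects; nG <- spec@nGenera; nE <- spec@nEuk
    tps <- spec@timepoints
    subjects <- sprintf("sub%02d", seq_len(nS))
    genera <- sprintf("g%03d", seq_len(nG))
    euks <- sprintf("e%02d", seq_len(nE))
    samples <- as.vector(outer(subjects, tps, paste, sep = "_"))
    sampleSubj <- setNames(rep(subjects, length(tps)), samples)
    sampleTp <- setNames(rep(tps, each = nS), samples)

    ## --- questionnaires -------------------------------------------------
    baseDates <- as.Date("2024-01-01") + 0:6
    intDates <- as.Date("2024-01-08") + 0:27
    uAdh <- rnorm(nS, 0, 0.45)      # stable adherence propensity
    vImp <- rnorm(nS, 0, 0.35)      # intervention-specific improvement
    quest <- do.call(rbind, lapply(seq_len(nS), function(j) {
        rbind(.simulateDays(subjects[j], baseDates, .Q_RATES$baseline,
                            uAdh[j]),
              .simulateDays(subjects[j], intDates, .Q_RATES$intervention,
                            uAdh[j] + vImp[j]))
    }))
    quest <- scoreTable(quest)
    t0Win <- range(baseDates)
    tendWin <- range(intDates)
    dScore <- deltaScore(quest, t0Win, tendWin)[subjects]
    z <- as.numeric(scale(dScore))

    ## --- bacterial composition ------------------------------------------
    baseProfile <- rnorm(nG, 0, 1.5)
    stepsGenera <- setdiff(seq_len(nG), spec@plantedGenera)
    stepsGenera <- utils::tail(stepsGenera, 2L)
    stepsBeta <- if (spec@subjectEffectSD > 0) 1.2 else 0
    baseProfile[spec@plantedGenera] <- 1.0   # moderately abundant responders
    baseProfile[stepsGenera] <- 0.8
    subjSD <- rep(spec@subjectEffectSD, nG)
    subjSD[spec@plantedGenera] <- min(spec@subjectEffectSD, 0.4)
    subjEff <- matrix(rnorm(nG * nS, 0, 1), nG, nS) * subjSD
    stepsMean <- pmax(rnorm(nS, 8000, 2500), 2000)
    zSteps <- as.numeric(scale(stepsMean))
    subjEff[stepsGenera, ] <- subjEff[stepsGenera, ] +
        rep(stepsBeta * zSteps, each = length(stepsGenera))
    profiles <- baseProfile + subjEff      # nG x nS, log scale

    rho <- spec@plantedRho
    latent <- matrix(rnorm(length(spec@plantedGenera) * nS), ncol = nS)
    latent <- rho * rep(z, each = nrow(latent)) +
        sqrt(1 - rho^2) * latent           # cor(latent, z) -> plantedRho

    counts <- matrix(0, nG, length(samples),
                     dimnames = list(genera, samples))
    depth <- round(runif(length(samples), 5000, 15000))
    for (k in seq_along(samples)) {
        j <- match(sampleSubj[k], subjects)
        lw <- profiles[, j] + rnorm(nG, 0, 0.35)
        if (sampleTp[k] == tps[2] && length(spec@plantedGenera))
            lw[spec@plantedGenera] <- lw[spec@plantedGenera] +
                plantedEffect * latent[, j]
        counts[, k] <- rmultinom(1, depth[k], .softmax(lw))
    }

    ## --- loads -----------------------------------------------------------
    loadAdhSlope <- 0.15
    load0 <- rlnorm(nS, log(10), 0.4)
    loads <- numeric(length(samples))
    names(loads) <- samples
    for (k in seq_along(samples)) {
        j <- match(sampleSubj[k], subjects)
        loads[k] <- if (sampleTp[k] == tps[2])
            load0[j] * exp(loadAdhSlope * z[j] + rnorm(1, 0, 0.2))
        else load0[j] * exp(rnorm(1, 0, 0.2))
    }

    ## --- eukaryome: sparse, unstable, sweets-driven ----------------------
    sweets <- matrix(rpois(nS * length(tps),
                           rep(c(2.2, rep(1.2, length(tps) - 1L)),
                               each = nS)),
                     nS, length(tps), dimnames = list(subjects, tps))
    eukCounts <- matrix(0, nE, length(samples),
                        dimnames = list(euks, samples))
    if (nE > 0) {
        eukDepth <- round(runif(length(samples), 3000, 9000))
        for (k in seq_along(samples)) {
            j <- match(sampleSubj[k], subjects)
            present <- rbinom(nE, 1, 0.25) == 1
            dom <- sample.int(nE, 1)      # dominance redrawn per sample
            present[dom] <- TRUE
            present[1] <- runif(1) < 0.9  # sweets taxon nearly ubiquitous
            lw <- rnorm(nE, -1, 1)
            lw[dom] <- lw[dom] + 4
            lw[1] <- lw[1] + 0.8 * sweets[j, sampleTp[k]]
            lw[!present] <- -Inf
            eukCounts[, k] <- rmultinom(1, eukDepth[k], .softmax(lw))
        }
    }

    ## --- clinical / lifestyle metadata -----------------------------------
    age <- round(runif(nS, 25, 55))
    gender <- rbinom(nS, 1, 0.65)
    bmi <- round(rnorm(nS, 25, 3.5), 1)
    cal0 <- rlnorm(nS, log(16.5), 0.6)
    wbc0 <- pmax(rnorm(nS, 6.8, 1.1), 3.5)
    sMean <- summarizeScores(quest, t0Win)
    sInt <- summarizeScores(quest, tendWin)
    baseScore <- setNames(sMean$mean, sMean$subject)[subjects]
    intScore <- setNames(sInt$mean, sInt$subject)[subjects]
    md <- do.call(rbind, lapply(seq_along(samples), function(k) {
        j <- match(sampleSubj[k], subjects)
        post <- sampleTp[k] == tps[2]
        cal <- if (post) cal0[j] * exp(spec@calprotectinSlope * z[j] +
                                       rnorm(1, 0, 0.25))
               else cal0[j] * exp(rnorm(1, 0, 0.15))
        wbc <- if (post) wbc0[j] * exp(0.5 * spec@calprotectinSlope * z[j] +
                                       rnorm(1, 0, 0.08))
               else wbc0[j] * exp(rnorm(1, 0, 0.05))
        data.frame(
            sample_id = samples[k], subject = sampleSubj[k],
            timepoint = sampleTp[k], age = age[j], gender = gender[j],
            bmi = bmi[j],
            steps = round(stepsMean[j] + (post * 600) + rnorm(1, 0, 800)),
            sleep_hours = round(rnorm(1, 7, 0.8), 1),
            resting_hr = round(rnorm(1, 62, 6)),
            calprotectin = round(cal, 1),
            wbc = round(wbc, 2),
            neutrophils = round(wbc * 0.55 + rnorm(1, 0, 0.2), 2),
            lymphocytes = round(wbc * 0.28 + rnorm(1, 0, 0.1), 2),
            fruits = round(if (post) intScore[j] * 0.1 else
                           baseScore[j] * 0.1, 2) + rpois(1, 1),
            sweets = sweets[j, sampleTp[k]],
            med_score = round(if (post) intScore[j] else baseScore[j], 2),
            stringsAsFactors = FALSE)
    }))
    rownames(md) <- NULL

    truth <- list(
        planted_genera = genera[spec@plantedGenera],
        planted_indices = spec@plantedGenera,
        planted_rho = rho, planted_effect = plantedEffect,
        steps_genera = genera[stepsGenera], steps_beta = stepsBeta,
        calprotectin_slope = spec@calprotectinSlope,
        load_adherence_slope = loadAdhSlope,
        sweets_taxon = if (nE > 0) euks[1] else character(0),
        delta_scores = as.list(round(dScore, 4)),
        t0_window = as.character(t0Win),
        tend_window = as.character(tendWin),
        t0_label = tps[1], tend_label = tps[2])

    new("SyntheticCohort",
        counts16S = abundanceTable(counts, kind = "counts"),
        counts18S = abundanceTable(eukCounts, kind = "counts"),
        loads = loadVector(loads), questionnaires = quest,
        metadata = md, truth = truth, spec = spec)
}

#' Write a synthetic cohort to plain-text files
#'
#' Emits \code{counts_16s.tsv} and \code{counts_18s.tsv} (features x samples,
#' first column \code{feature_id}), \code{loads.csv} (\code{sample_id},
#' \code{load_ug_per_mg}), \code{questionnaires.csv}, \code{metadata.csv} and
#' \code{truth.json}. The files round-trip losslessly through
#' \code{\link{readCounts}}, \code{\link{readLoads}},
#' \code{\link{readQuestionnaires}} and \code{\link{readMetadata}}.
#'
#' @param cohort a \code{SyntheticCohort}.
#' @param dir output directory (created if absent).
#' @return Invisibly, the named vector of file paths written.
#' @export
writeCohort <- function(cohort, dir) {
    stopifnot(is(cohort, "SyntheticCohort"))
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- c(counts_16s = file.path(dir, "counts_16s.tsv"),
               counts_18s = file.path(dir, "counts_18s.tsv"),
               loads = file.path(dir, "loads.csv"),
               questionnaires = file.path(dir, "questionnaires.csv"),
               metadata = file.path(dir, "metadata.csv"),
               truth = file.path(dir, "truth.json"))
    writeCounts(cohort@counts16S, paths["counts_16s"])
    writeCounts(cohort@counts18S, paths["counts_18s"])
    writeLoads(cohort@loads, paths["loads"])
    q <- cohort@questionnaires
    write.csv(q[, setdiff(names(q), "med_score")], paths["questionnaires"],
              row.names = FALSE, quote = TRUE)
    write.csv(cohort@metadata, paths["metadata"], row.names = FALSE,
              quote = TRUE)
    jsonlite::write_json(cohort@truth, paths["truth"], auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    invisible(paths)
}
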