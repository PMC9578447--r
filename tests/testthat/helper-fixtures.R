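# Shared fixtures, built in code.

# A questionnaire row with every item at or above its cap.
fullDay <- function(subject = "s1", date = "2024-01-01") {
    data.frame(subject = subject, date = date, vegetables = 5, fruits = 3,
               food_colors = "red;green;yellow;orange;white;purple",
               olive_oil_tbsp = 3, nuts_seeds = 1, legumes_soy = 1,
               yogurt = 1, whole_grains = 3, water_glasses = 5,
               step_goal_met = 1, exercised = 1, stringsAsFactors = FALSE)
}

emptyDay <- function(subject = "s1", date = "2024-01-01") {
    data.frame(subject = subject, date = date, vegetables = 0, fruits = 0,
               food_colors = "", olive_oil_tbsp = 0, nuts_seeds = 0,
               legumes_soy = 0, yogurt = 0, whole_grains = 0,
               water_glasses = 0, step_goal_met = 0, exercised = 0,
               stringsAsFactors = FALSE)
}

# A questionnaire row whose total equals `total` (0..30), filled greedily
# across the capped components.
dayWithTotal <- function(total, subject = "s1", date = "2024-01-01") {
    stopifnot(total >= 0, total <= 30)
    caps <- c(vegetables = 5, water_glasses = 5, whole_grains = 3,
              fruits = 3, olive_oil_tbsp = 3, nuts_seeds = 1,
              legumes_soy = 1, yogurt = 1, step_goal_met = 1, exercised = 1)
    rec <- emptyDay(subject, date)
    left <- total
    nColors <- min(left, 6)
    rec$food_colors <- paste(c("red", "green", "yellow", "orange", "white",
                               "purple")[seq_len(nColors)], collapse = ";")
    left <- left - nColors
    for (item in names(caps)) {
        take <- min(left, caps[[item]])
        rec[[item]] <- take
        left <- left - take
    }
    stopifnot(left == 0)
    rec
}

randomCounts <- function(nFeat = 8, nSamp = 5, seed = 1, lambda = 20) {
    set.seed(seed)
    m <- matrix(rpois(nFeat * nSamp, lambda), nFeat, nSamp,
                dimnames = list(sprintf("g%02d", seq_len(nFeat)),
                                sprintf("s%02d", seq_len(nSamp))))
    abundanceTable(m, kind = "counts")
}

# Independent brute-force PERMANOVA oracle for a categorical factor:
# classic within-group sum-of-squares identity on the raw distances,
# enumerated over every label permutation.
bruteForcePermanova <- function(D, groups) {
    n <- nrow(D)
    ssTotal <- sum(D[upper.tri(D)]^2) / n
    Fof <- function(g) {
        ssW <- 0
        for (lev in unique(g)) {
            idx <- which(g == lev)
            sub <- D[idx, idx, drop = FALSE]
            ssW <- ssW + sum(sub[upper.tri(sub)]^2) / length(idx)
        }
        a <- length(unique(g))
        ((ssTotal - ssW) / (a - 1)) / (ssW / (n - a))
    }
    allPerms <- function(v) {
        if (length(v) <= 1) return(list(v))
        out <- list()
        for (k in seq_along(v))
            for (r in allPerms(v[-k])) out[[length(out) + 1]] <- c(v[k], r)
        out
    }
    fObs <- Fof(groups)
    fAll <- vapply(allPerms(seq_len(n)),
                   function(i) Fof(groups[i]), numeric(1))
    list(F = fObs, p = mean(fAll >= fObs - 1e-8 * max(1, abs(fObs))))
}

# Delta screen of absolute-abundance changes against score changes for a
# generated cohort; returns planted recovery and overall discovery rates.
deltaScreenRates <- function(ch, qRecovery = 0.2, qNull = 0.05) {
    tr <- cohortTruth(ch)
    rel <- toRelative(cohortCounts(ch))
    ab <- toAbsolute(rel, cohortLoads(ch))
    md <- cohortMetadata(ch)
    ss <- setNames(md$subject, md$sample_id)
    st <- setNames(md$timepoint, md$sample_id)
    ds <- deltaScore(cohortQuestionnaires(ch), tr$t0_window, tr$tend_window)
    dAbs <- buildDelta(ab, ss, st, tr$t0_label, tr$tend_label)
    dRel <- buildDelta(rel, ss, st, tr$t0_label, tr$tend_label)
    kept <- rownames(abundanceValues(deltaRetentionFilter(dRel)))
    subj <- colnames(abundanceValues(dAbs))
    scr <- correlationScreen(
        abundanceValues(dAbs)[kept, , drop = FALSE],
        data.frame(delta_med_score = ds[subj], row.names = subj))
    list(recovery = mean(tr$planted_genera %in%
                             scr$feature[scr$q < qRecovery]),
         discovery = mean(scr$q < qNull),
         screen = scr, truth = tr)
}
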