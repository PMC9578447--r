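# Small designs keep the generator tests fast; the planted-effect recovery
# at the full default design is exercised in test-acceptance.R.
smallSpec <- function(...) {
    defaults <- list(nSubjects = 10, nGenera = 60, nEuk = 8, seed = 5)
    args <- utils::modifyList(defaults, list(...))
    do.call(cohortSpec, args)
}

test_that("identical spec and seed give identical cohorts", {
    a <- generateCohort(smallSpec())
    b <- generateCohort(smallSpec())
    expect_identical(abundanceValues(cohortCounts(a)),
                     abundanceValues(cohortCounts(b)))
    expect_identical(abundanceValues(cohortCounts(a, "18S")),
                     abundanceValues(cohortCounts(b, "18S")))
    expect_identical(sampleLoads(cohortLoads(a)), sampleLoads(cohortLoads(b)))
    expect_identical(cohortQuestionnaires(a), cohortQuestionnaires(b))
    expect_identical(cohortMetadata(a), cohortMetadata(b))
    # and written files are byte-identical
    d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
    writeCohort(a, d1); writeCohort(b, d2)
    for (f in list.files(d1))
        expect_identical(readLines(file.path(d1, f)),
                         readLines(file.path(d2, f)))
    # a different seed changes the tables
    c2 <- generateCohort(smallSpec(seed = 6))
    expect_false(identical(abundanceValues(cohortCounts(a)),
                           abundanceValues(cohortCounts(c2))))
})

test_that("cohort dimensions follow the spec", {
    ch <- generateCohort(cohortSpec(nSubjects = 20, nGenera = 40, nEuk = 6,
                                    timepoints = c("T0", "Tend", "M6"),
                                    seed = 3))
    expect_equal(ncol(abundanceValues(cohortCounts(ch))), 60L)
    expect_equal(nrow(abundanceValues(cohortCounts(ch))), 40L)
    expect_equal(nrow(cohortMetadata(ch)), 60L)
    # 7 baseline + 28 intervention questionnaire days per subject
    expect_equal(nrow(cohortQuestionnaires(ch)), 20L * 35L)
    # every sample covered by metadata and loads
    expect_true(all(sampleIDs(cohortCounts(ch)) %in%
                        cohortMetadata(ch)$sample_id))
    expect_true(all(sampleIDs(cohortCounts(ch)) %in%
                        sampleIDs(cohortLoads(ch))))
})

test_that("invalid cohort specs are rejected", {
    expect_error(generateCohort(cohortSpec(nSubjects = 2)), "nSubjects")
    expect_error(generateCohort(cohortSpec(nGenera = 10,
                                           plantedGenera = 11)),
                 "out of range")
    expect_error(generateCohort(cohortSpec(plantedRho = 1.4)), "plantedRho")
})

test_that("truth records every planted effect", {
    ch <- generateCohort(smallSpec())
    tr <- cohortTruth(ch)
    expect_length(tr$planted_genera, 5L)
    expect_true(all(tr$planted_genera %in% featureIDs(cohortCounts(ch))))
    expect_equal(tr$planted_rho, 0.8)
    expect_length(tr$steps_genera, 2L)
    expect_lt(tr$calprotectin_slope, 0)
    expect_length(tr$delta_scores, 10L)
})

test_that("cohort files round-trip through the readers", {
    ch <- generateCohort(smallSpec())
    d <- withr::local_tempdir()
    paths <- writeCohort(ch, d)
    counts <- readCounts(paths[["counts_16s"]])
    expect_equal(abundanceValues(counts),
                 abundanceValues(cohortCounts(ch)))
    loads <- readLoads(paths[["loads"]])
    expect_equal(sampleLoads(loads), sampleLoads(cohortLoads(ch)),
                 tolerance = 1e-12)
    q <- readQuestionnaires(paths[["questionnaires"]])
    expect_equal(nrow(q), nrow(cohortQuestionnaires(ch)))
    expect_equal(scoreTable(q)$med_score,
                 cohortQuestionnaires(ch)$med_score)
    md <- readMetadata(paths[["metadata"]])
    expect_equal(md$sample_id, cohortMetadata(ch)$sample_id)
})

test_that("an empty eukaryal table writes a header-only file", {
    ch <- generateCohort(smallSpec(nEuk = 0))
    d <- withr::local_tempdir()
    paths <- writeCohort(ch, d)
    lines <- readLines(paths[["counts_18s"]])
    expect_equal(length(lines), 1L)
    back <- readCounts(paths[["counts_18s"]])
    expect_equal(nrow(abundanceValues(back)), 0L)
})

test_that("the adherence trajectory matches the intended study conditions", {
    base <- intv <- numeric(0)
    for (s in 1:5) {
        ch <- generateCohort(cohortSpec(seed = s))
        tr <- cohortTruth(ch)
        q <- cohortQuestionnaires(ch)
        base <- c(base, mean(summarizeScores(q, tr$t0_window)$mean))
        intv <- c(intv, mean(summarizeScores(q, tr$tend_window)$mean))
    }
    # baseline near 15-16, intervention within [20, 26], clear increase
    expect_gt(mean(base), 13)
    expect_lt(mean(base), 18)
    expect_gt(mean(intv), 20)
    expect_lt(mean(intv), 26)
    expect_gt(mean(intv - base), 4)
})

test_that("subject identity explains most compositional variance", {
    subjectR2 <- function(sd, seed) {
        ch <- generateCohort(smallSpec(subjectEffectSD = sd, seed = seed))
        md <- cohortMetadata(ch)
        bc <- brayCurtis(toRelative(cohortCounts(ch)))
        permanova(bc, setNames(md$subject, md$sample_id), nPerm = 9,
                  seed = 1, term = "subject")@R2
    }
    # monotone in the subject-effect dispersion (averaged over replicates)
    r2 <- vapply(c(0.1, 0.35, 1.0), function(sd)
        mean(vapply(1:3, function(s) subjectR2(sd, s), numeric(1))),
        numeric(1))
    expect_true(all(diff(r2) > 0))
    # the default emulates a strong (~70%) subject signature
    expect_gt(r2[2], 0.5)
})

test_that("without a subject effect the subject PERMANOVA is null", {
    ps <- vapply(1:4, function(s) {
        ch <- generateCohort(smallSpec(subjectEffectSD = 0, seed = 10 + s))
        md <- cohortMetadata(ch)
        bc <- brayCurtis(toRelative(cohortCounts(ch)))
        permanova(bc, setNames(md$subject, md$sample_id), nPerm = 99,
                  seed = 1, term = "subject")@p
    }, numeric(1))
    expect_gt(mean(ps), 0.2)
})

test_that("the eukaryome lacks a subject signature and tracks sweets", {
    ch <- generateCohort(cohortSpec(seed = 8))
    md <- cohortMetadata(ch)
    euk <- cohortCounts(ch, "18S")
    relE <- suppressWarnings(toRelative(euk))
    bcE <- suppressWarnings(brayCurtis(relE))
    prSubj <- permanova(bcE, setNames(md$subject, md$sample_id),
                        nPerm = 99, seed = 1, term = "subject")
    # far below the bacterial ~0.7; dominance is resampled per sample
    expect_lt(prSubj@R2, 0.6)
    # the designated taxon follows sweets servings
    tr <- cohortTruth(ch)
    sw <- setNames(md$sweets, md$sample_id)
    x <- abundanceValues(relE)[tr$sweets_taxon, names(sw)]
    expect_gt(spearmanCor(x, sw)$rho, 0.3)
})
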