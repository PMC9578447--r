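test_that("toRelative normalizes columns and flags all-zero samples", {
    m <- cbind(s1 = c(2, 3, 5), s2 = c(0, 0, 0))
    rownames(m) <- paste0("g", 1:3)
    expect_warning(rel <- toRelative(abundanceTable(m)), "all-zero")
    v <- abundanceValues(rel)
    expect_equal(v[, "s1"], c(g1 = 0.2, g2 = 0.3, g3 = 0.5))
    expect_equal(unname(v[, "s2"]), c(0, 0, 0))
    expect_identical(rel@flags, "s2")
    expect_identical(abundanceKind(rel), "relative")
    tbl <- randomCounts(10, 6, seed = 3)
    expect_equal(unname(colSums(abundanceValues(toRelative(tbl)))),
                 rep(1, 6))
})

test_that("toAbsolute scales by the load and conserves column sums", {
    m <- matrix(c(0.2, 0.3, 0.5), ncol = 1,
                dimnames = list(paste0("g", 1:3), "s1"))
    rel <- abundanceTable(m, kind = "relative")
    ab <- toAbsolute(rel, loadVector(c(s1 = 10)))
    expect_equal(abundanceValues(ab)[, 1], c(g1 = 2, g2 = 3, g3 = 5))
    expect_identical(abundanceKind(ab), "absolute")
    # identity load leaves the table unchanged
    expect_equal(abundanceValues(toAbsolute(rel, loadVector(c(s1 = 1)))),
                 abundanceValues(rel))
    # conservation on a random table
    tbl <- toRelative(randomCounts(12, 7, seed = 5))
    lv <- loadVector(setNames(runif(7, 2, 40), sampleIDs(tbl)))
    expect_equal(colSums(abundanceValues(toAbsolute(tbl, lv))),
                 sampleLoads(lv), tolerance = 1e-9)
    expect_error(toAbsolute(tbl, loadVector(c(zz = 5))), "no bacterial load")
})

test_that("toAbsolute with column-sum loads inverts toRelative", {
    counts <- randomCounts(9, 5, seed = 8)
    lv <- loadVector(colSums(abundanceValues(counts)))
    back <- toAbsolute(toRelative(counts), lv)
    expect_equal(abundanceValues(back), abundanceValues(counts),
                 tolerance = 1e-12)
})

test_that("prevalenceFilter drops features seen in too few samples", {
    # 59 samples; prevalences 12, 10, 9, 1, 0
    n <- 59
    m <- rbind(a = c(rep(1, 12), rep(0, n - 12)),
               b = c(rep(1, 10), rep(0, n - 10)),
               c = c(rep(1, 9), rep(0, n - 9)),
               d = c(1, rep(0, n - 1)),
               e = rep(0, n))
    colnames(m) <- sprintf("s%02d", seq_len(n))
    tbl <- abundanceTable(m)
    out <- prevalenceFilter(tbl, 10)
    expect_identical(featureIDs(out), c("a", "b"))
    expect_identical(attr(out, "dropped"), c("c", "d", "e"))
    # threshold 0 is the identity; the filter is idempotent
    expect_identical(featureIDs(prevalenceFilter(tbl, 0)), featureIDs(tbl))
    expect_identical(featureIDs(prevalenceFilter(out, 10)),
                     featureIDs(out))
})

test_that("logTransform imputes half the feature minimum before log", {
    m <- matrix(c(0, 4, 8), nrow = 1, dimnames = list("g1", paste0("s", 1:3)))
    out <- abundanceValues(logTransform(abundanceTable(m)))
    expect_equal(unname(out[1, ]), log(c(2, 4, 8)))
    # rows without zeros are plain log; within-row ordering is preserved
    m2 <- matrix(c(3, 1, 9), nrow = 1, dimnames = list("g1", paste0("s", 1:3)))
    out2 <- abundanceValues(logTransform(abundanceTable(m2)))
    expect_equal(unname(out2[1, ]), log(c(3, 1, 9)))
    expect_identical(order(out2[1, ]), order(m2[1, ]))
    m3 <- rbind(g1 = c(1, 2), g2 = c(0, 0))
    colnames(m3) <- c("s1", "s2")
    expect_error(logTransform(abundanceTable(m3)), "g2")
})

test_that("buildDelta subtracts T0 from Tend per subject", {
    m <- cbind(a_T0 = c(0.10, 0.5), a_Tend = c(0.13, 0.4),
               b_T0 = c(0.2, 0.3), b_Tend = c(0.2, 0.3))
    rownames(m) <- c("g1", "g2")
    tbl <- abundanceTable(m, kind = "absolute")
    subj <- setNames(rep(c("a", "b"), each = 2), colnames(m))
    tp <- setNames(rep(c("T0", "Tend"), 2), colnames(m))
    d <- buildDelta(tbl, subj, tp)
    expect_equal(abundanceValues(d)["g1", "a"], 0.03)
    expect_equal(unname(abundanceValues(d)[, "b"]), c(0, 0))
    # antisymmetry under label swap
    dRev <- buildDelta(tbl, subj, tp, t0Label = "Tend", tendLabel = "T0")
    expect_equal(abundanceValues(dRev), -abundanceValues(d))
    # subjects missing a timepoint are absent, not zero-filled
    tp2 <- tp; tp2["b_Tend"] <- "M6"
    d2 <- buildDelta(tbl, subj, tp2)
    expect_identical(colnames(abundanceValues(d2)), "a")
    # duplicate samples at one timepoint are an error
    tp3 <- tp; tp3["b_T0"] <- "Tend"
    expect_error(buildDelta(tbl, subj, tp3), "duplicate samples")
})

test_that("delta retention keeps widespread, sizeable changes only", {
    nS <- 15
    mk <- function(x) setNames(x, sprintf("sub%02d", seq_len(nS)))
    v <- rbind(
        wide_big = mk(c(rep(0.02, 12), rep(0, 3))),    # 12 nonzero, max .02
        wide_small = mk(c(rep(0.005, 12), rep(0, 3))), # change never > 1%
        narrow_big = mk(c(rep(0.05, 5), rep(0, 10))),  # only 5 subjects
        zero = mk(rep(0, nS)))
    d <- new("DeltaTable", values = v, provenance = "relative")
    out <- deltaRetentionFilter(d, minNonzeroSubjects = 10, minChange = 0.01)
    expect_identical(rownames(abundanceValues(out)), "wide_big")
    expect_setequal(attr(out, "dropped"),
                    c("wide_small", "narrow_big", "zero"))
    # idempotent
    again <- deltaRetentionFilter(out, 10, 0.01)
    expect_identical(abundanceValues(again), abundanceValues(out))
})

test_that("loadFromCt inverts the qPCR standard curve", {
    # Ct at the intercept corresponds to one DNA unit
    expect_equal(unname(sampleLoads(loadFromCt(c(s1 = 20), slope = -3.32,
                                               intercept = 20,
                                               stoolMass = 1))), 1)
    # one slope unit fewer cycles = tenfold more DNA
    l <- sampleLoads(loadFromCt(c(a = 20, b = 20 - 3.32), slope = -3.32,
                                intercept = 20, stoolMass = 1))
    expect_equal(unname(l["b"] / l["a"]), 10)
    # load is per unit stool mass
    l2 <- loadFromCt(c(a = 20), slope = -3.32, intercept = 20, stoolMass = 4)
    expect_equal(unname(sampleLoads(l2)), 0.25)
    expect_error(loadFromCt(c(a = 20), slope = 3.32, intercept = 20,
                            stoolMass = 1), "negative")
    expect_error(loadFromCt(c(a = 20), slope = -3.32, intercept = 20,
                            stoolMass = 0), "positive")
})
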