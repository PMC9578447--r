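test_that("brayCurtis matches hand-computed values and its bounds", {
    m <- cbind(s1 = c(1, 0, 3), s2 = c(2, 2, 0), s3 = c(1, 0, 3),
               s4 = c(0, 5, 0))
    rownames(m) <- paste0("g", 1:3)
    D <- distanceValues(brayCurtis(abundanceTable(m)))
    expect_equal(D["s1", "s2"], 0.75)        # 1 - 2*1/8
    expect_equal(D["s1", "s3"], 0)           # identical columns
    expect_equal(D["s1", "s4"], 1)           # disjoint supports
    expect_true(all(D >= 0 & D <= 1))
    expect_equal(D, t(D))
})

test_that("brayCurtis is invariant to joint rescaling of a sample pair", {
    m <- cbind(s1 = c(4, 1, 0, 2), s2 = c(1, 3, 2, 0))
    rownames(m) <- paste0("g", 1:4)
    d1 <- distanceValues(brayCurtis(abundanceTable(m)))["s1", "s2"]
    d2 <- distanceValues(brayCurtis(abundanceTable(m * 7)))["s1", "s2"]
    expect_equal(d1, d2)
})

test_that("an all-zero sample pair is flagged and set to 0", {
    m <- cbind(s1 = c(0, 0), s2 = c(0, 0), s3 = c(1, 2))
    rownames(m) <- c("g1", "g2")
    expect_warning(D <- brayCurtis(abundanceTable(m)), "all-zero")
    expect_equal(distanceValues(D)["s1", "s2"], 0)
    expect_identical(D@flags, "s1|s2")
})

test_that("brayCurtis agrees with vegan::vegdist", {
    tbl <- randomCounts(15, 8, seed = 21)
    mine <- distanceValues(brayCurtis(tbl))
    ref <- as.matrix(vegan::vegdist(t(abundanceValues(tbl)),
                                    method = "bray"))
    expect_equal(mine, ref[rownames(mine), colnames(mine)],
                 tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("pcoa reproduces Euclidean configurations to 1e-9", {
    set.seed(7)
    pts <- matrix(rnorm(2 * 9), ncol = 2,
                  dimnames = list(paste0("s", 1:9), NULL))
    D <- as.matrix(dist(pts))
    dm <- new("DistanceMatrix", D = D, method = "euclidean")
    ord <- pcoa(dm, nAxes = 2)
    rec <- as.matrix(dist(ordCoordinates(ord)))
    expect_equal(rec, D, tolerance = 1e-9)
    # eigenvalues agree with classical scaling
    ref <- cmdscale(D, k = 2, eig = TRUE)
    expect_equal(ordEigenvalues(ord)[1:2], ref$eig[1:2], tolerance = 1e-9)
    expect_equal(sum(ordProportionExplained(ord)), 1, tolerance = 1e-9)
})

test_that("pcoa of collinear points puts all variance on one axis", {
    D <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3,
                dimnames = list(paste0("s", 1:3), paste0("s", 1:3)))
    dm <- new("DistanceMatrix", D = D, method = "euclidean")
    expect_warning(ord <- pcoa(dm, nAxes = 2), "truncating")
    co <- ordCoordinates(ord)
    expect_equal(ncol(co), 1L)
    expect_equal(abs(co[1, 1] - co[3, 1]), 2, tolerance = 1e-9)
    expect_equal(abs(co[1, 1] - co[2, 1]), 1, tolerance = 1e-9)
    expect_equal(ordProportionExplained(ord), 1)
})

test_that("duplicated samples get identical coordinates", {
    m <- cbind(s1 = c(5, 1, 2), s2 = c(5, 1, 2), s3 = c(0, 4, 1),
               s4 = c(2, 2, 2))
    rownames(m) <- paste0("g", 1:3)
    ord <- pcoa(brayCurtis(abundanceTable(m)), nAxes = 2)
    co <- ordCoordinates(ord)
    expect_equal(co["s1", ], co["s2", ], tolerance = 1e-9)
})

test_that("exhaustive permanova matches brute-force enumeration", {
    set.seed(11)
    pts <- matrix(rnorm(12), ncol = 2,
                  dimnames = list(paste0("s", 1:6), NULL))
    D <- as.matrix(dist(pts))
    dm <- new("DistanceMatrix", D = D, method = "euclidean")
    groups <- setNames(rep(c("a", "b"), each = 3), rownames(D))
    res <- permanova(dm, groups, exhaustive = TRUE)
    oracle <- bruteForcePermanova(D, unname(groups))
    expect_equal(res@pseudoF, oracle$F, tolerance = 1e-10)
    expect_identical(res@p, oracle$p)
    expect_equal(res@nPerm, factorial(6))
})

test_that("separated groups reach the minimal attainable p", {
    # two tight, well-separated clusters of three samples
    m <- cbind(s1 = c(10, 0), s2 = c(11, 1), s3 = c(10, 1),
               s4 = c(0, 10), s5 = c(1, 11), s6 = c(1, 10))
    rownames(m) <- c("g1", "g2")
    dm <- brayCurtis(abundanceTable(m))
    groups <- setNames(rep(c("a", "b"), each = 3), sampleIDs(dm))
    res <- permanova(dm, groups, exhaustive = TRUE)
    # only orderings reproducing the exact two-cluster split (either label
    # orientation) reach the observed F: 2 * 3! * 3! of the 720
    expect_equal(res@p, 72 / 720)
    expect_gt(res@R2, 0.8)
})

test_that("permanova agrees with vegan::adonis2 on F and R2", {
    tbl <- randomCounts(20, 12, seed = 31)
    dm <- brayCurtis(tbl)
    set.seed(5)
    grp <- setNames(sample(c("x", "y", "z"), 12, replace = TRUE),
                    sampleIDs(dm))
    cov <- setNames(rnorm(12), sampleIDs(dm))
    dref <- as.dist(distanceValues(dm))
    refG <- vegan::adonis2(dref ~ g, data = data.frame(g = unname(grp)),
                           permutations = 30)
    resG <- permanova(dm, grp, nPerm = 30, seed = 1)
    expect_equal(resG@pseudoF, refG$F[1], tolerance = 1e-8)
    expect_equal(resG@R2, refG$R2[1], tolerance = 1e-8)
    refN <- vegan::adonis2(dref ~ v, data = data.frame(v = unname(cov)),
                           permutations = 30)
    resN <- permanova(dm, cov, nPerm = 30, seed = 1)
    expect_equal(resN@pseudoF, refN$F[1], tolerance = 1e-8)
    expect_equal(resN@R2, refN$R2[1], tolerance = 1e-8)
})

test_that("blocking restricts permutations within blocks", {
    set.seed(13)
    pts <- matrix(rnorm(12), ncol = 2,
                  dimnames = list(paste0("s", 1:6), NULL))
    dm <- new("DistanceMatrix", D = as.matrix(dist(pts)),
              method = "euclidean")
    ids <- sampleIDs(dm)
    x <- setNames(rep(c("pre", "post"), 3), ids)
    blocks <- setNames(rep(c("b1", "b2", "b3"), each = 2), ids)
    res <- permanova(dm, x, blocks = blocks, exhaustive = TRUE)
    # 2 arrangements per block: 2^3 = 8 restricted permutations
    expect_equal(res@nPerm, 8)
    expect_gte(res@p, 1 / 8)
    # one block holding every sample equals the unblocked analysis
    oneBlock <- setNames(rep("all", 6), ids)
    a <- permanova(dm, x, blocks = oneBlock, exhaustive = TRUE)
    b <- permanova(dm, x, exhaustive = TRUE)
    expect_identical(a@p, b@p)
    expect_equal(a@pseudoF, b@pseudoF)
})

test_that("permanova rejects a constant covariate", {
    dm <- brayCurtis(randomCounts(5, 4, seed = 2))
    expect_error(permanova(dm, setNames(rep(1, 4), sampleIDs(dm))),
                 "constant")
})

test_that("axisCorrelations screens metadata and skips constants", {
    tbl <- randomCounts(12, 10, seed = 17)
    ord <- pcoa(brayCurtis(toRelative(tbl)), nAxes = 2)
    co <- ordCoordinates(ord)
    md <- data.frame(sample_id = rownames(co),
                     self = co[, 1],           # the axis itself
                     noise = rnorm(10),
                     flat = rep(1, 10))
    res <- axisCorrelations(ord, md)
    self1 <- res[res$feature == "PCo1" & res$covariate == "self", ]
    expect_equal(self1$rho, 1)
    expect_true(any(grepl("flat", attr(res, "skipped"))))
})
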