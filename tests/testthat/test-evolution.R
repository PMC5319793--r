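test_that("editing divergence is 1 minus Spearman's rho with ties", {
    expect_equal(editingDivergence(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3)), 0)
    expect_equal(editingDivergence(c(0.1, 0.2, 0.3), c(0.3, 0.2, 0.1)), 2)
    # worked example: d^2 = (0, 1, 1) -> rho = 1 - 6*2/(3*8) = 0.5
    expect_equal(editingDivergence(c(0.1, 0.3, 0.2), c(0.1, 0.2, 0.3)), 0.5)
    expect_true(is.na(editingDivergence(c(0.1, NA, 0.2), c(0.1, 0.2, NA))))
    # symmetry
    a <- c(0.1, 0.5, 0, 0, 0.3); b <- c(0.2, 0.1, 0, 0.4, 0.3)
    expect_equal(editingDivergence(a, b), editingDivergence(b, a))
})

test_that("neighbor joining is consistent on additive matrices", {
    # 4 taxa, worked tree: the AB|CD split with exact branch lengths
    tr0 <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):1);")
    d <- ape::cophenetic.phylo(tr0)
    nj <- buildNjTree(d)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr0), nj)), 0)
    # path lengths reproduce the input distances exactly
    expect_equal(ape::cophenetic.phylo(nj)[rownames(d), colnames(d)], d)

    # 3 taxa: closed-form three-point solution
    d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
                 dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
    nj3 <- buildNjTree(d3)
    expect_equal(ape::cophenetic.phylo(nj3)[rownames(d3), colnames(d3)], d3)

    # random additive 6-taxon matrices: topology recovered
    for (s in 1:20) {
        am <- randomAdditiveMatrix(6, seed = s)
        got <- buildNjTree(am$d)
        expect_equal(as.numeric(ape::dist.topo(ape::unroot(am$tree), got)), 0)
    }

    expect_error(buildNjTree(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("negative NJ branches are clamped preserving path lengths", {
    # a non-additive matrix known to give a negative internal branch
    d <- matrix(c(0, 2, 2, 2,
                  2, 0, 2, 2,
                  2, 2, 0, 0.1,
                  2, 2, 0.1, 0), 4,
                dimnames = list(letters[1:4], letters[1:4]))
    tr <- buildNjTree(d)
    expect_true(all(tr$edge.length >= 0))
})

test_that("divergence-time regression recovers linear relations", {
    t <- c(10, 20, 30, 40, 50)
    r <- divergenceTimeRegression(0.01 * t, t)
    expect_equal(r$slope, 0.01)
    expect_equal(r$intercept, 0, tolerance = 1e-12)
    expect_equal(r$rho, 1)
    expect_error(divergenceTimeRegression(c(1, 2, 3), c(5, 5, 5)),
                 "constant")
})

test_that("editing status calls respect coverage and level thresholds", {
    expect_equal(callEditingStatus(0.025, 100), "edited")
    expect_equal(callEditingStatus(c(0.01, 0.00), c(50, 30)), "unedited")
    expect_equal(callEditingStatus(0.01, 15), "undefined")
    expect_equal(callEditingStatus(0.5, 100, dna_base = "G"), "unedited")
    expect_equal(callEditingStatus(NA_real_, NA_real_), "undefined")
})

test_that("parsimony dating takes the most distant edited species", {
    st <- c(mel = "edited", sim = "edited", yak = "unedited",
            ana = "unedited", pse = "unedited", vir = "undefined")
    a <- assignAge(st, min_defined = 4)
    expect_true(a$dated)
    expect_equal(a$age, "sim")

    # intervening losses are allowed
    st2 <- c(mel = "edited", sim = "unedited", yak = "unedited",
             ana = "unedited", pse = "edited", vir = "unedited")
    expect_equal(assignAge(st2, 5)$age, "pse")

    # edited only in the anchor: age is the anchor itself
    st3 <- c(mel = "edited", sim = "unedited", yak = "unedited",
             ana = "unedited", pse = "unedited", vir = "unedited")
    expect_equal(assignAge(st3, 5)$age, "mel")

    # fewer than the required defined species: never dated
    st4 <- c(mel = "edited", sim = "edited", yak = "undefined",
             ana = "undefined", pse = "unedited", vir = "unedited")
    a4 <- assignAge(st4, 5)
    expect_false(a4$dated)
    expect_true(is.na(a4$age))

    expect_error(assignAge(c(mel = "unedited", sim = "edited"), 1),
                 "anchor")
})

test_that("cluster fractions count nearest-neighbour distances", {
    r <- clusterFraction(c(100, 120, 500), max_dist = 30)
    expect_equal(r$fraction, 2 / 3)
    expect_equal(clusterFraction(c(42), 30)$fraction, 0)
    expect_equal(clusterFraction(c(1, 5, 9, 12), 10)$fraction, 1)

    g <- clusterFraction(c(100, 120, 500, 600, 605), max_dist = 30,
                         groups = c("y", "y", "y", "o", "o"), n_boot = 100)
    expect_equal(g$fraction[g$group == "o"], 1)
    expect_equal(g$fraction[g$group == "y"], 2 / 3)
    expect_true(all(g$sd >= 0))
})

test_that("level-difference metrics follow their definitions", {
    m <- levelDifferenceMetrics(c(0.4, 0.4, 0.3), c(0.4, 0.0, 0.1))
    expect_equal(m$normalized_diff, c(0, 2, 1))
    expect_equal(m$conservation, c(1, 0, 0.5))
    # conservation = 1 - normalized_diff / 2 wherever defined
    expect_equal(m$conservation, 1 - m$normalized_diff / 2)
    m0 <- levelDifferenceMetrics(0, 0)
    expect_true(is.na(m0$normalized_diff) && is.na(m0$conservation))
})

test_that("the rank-test kernel matches exact enumeration", {
    expect_equal(rankGroupTest(c(1, 2, 3), c(4, 5, 6)), 0.1)
    expect_equal(rankGroupTest(c(2, 2, 2), c(2, 2, 2)), 1)

    # exact DP equals complete enumeration, with and without ties
    set.seed(4)
    for (r in 1:10) {
        a <- sample(1:6, 4, TRUE); b <- sample(1:6, 5, TRUE)
        if (length(unique(c(a, b))) == 1) next
        expect_equal(rankGroupTest(a, b), oracleMWU(a, b))
    }

    # exact and normal approximation agree reasonably at moderate n
    set.seed(9)
    a <- rnorm(10); b <- rnorm(10) + 0.5
    p_exact <- rankGroupTest(a, b)                       # n = 20 -> exact
    p_norm <- suppressWarnings(wilcox.test(a, b, exact = FALSE)$p.value)
    expect_lt(abs(p_exact - p_norm), 0.01)

    # paired: all-zero differences give p = 1; sign asymmetry is detected
    expect_equal(rankGroupTest(c(1, 2, 3), c(1, 2, 3), paired = TRUE), 1)
    p <- rankGroupTest(1:10 + 1, 1:10, paired = TRUE)
    expect_lt(p, 0.01)
    expect_error(rankGroupTest(1:3, 1:4, paired = TRUE), "length")
})
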