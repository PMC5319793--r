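# Build a window with a planted perfect inverted repeat: arm1 carries the
# site, arm2 is its reverse complement after a poly-A loop; flanks are
# poly-A so the planted stem is exactly recoverable.
plantHairpin <- function(np = 30, loop = 10, lead = 40, trail = 40,
                         seed = 1) {
    set.seed(seed)
    arm1 <- sample(c("C", "G", "U"), np, TRUE)  # no A: arm is unambiguous
    comp <- c(A = "U", C = "G", G = "C", U = "A")
    arm2 <- rev(comp[arm1])
    s <- c(rep("A", lead), arm1, rep("A", loop), arm2, rep("A", trail))
    list(seq = paste(s, collapse = ""),
         a1 = c(lead + 1, lead + np),
         a2 = c(lead + np + loop + 1, lead + np + loop + np))
}

test_that("a planted perfect inverted repeat is recovered exactly", {
    hp <- plantHairpin(np = 30, loop = 10)
    site <- hp$a1[1] + 5
    cand <- foldWindow(hp$seq, site, half_window = 200)
    expect_gte(length(cand), 1)
    best <- cand[[1]]
    expect_equal(nPaired(best), 30)
    expect_equal(unname(armRanges(best)$first), hp$a1)
    expect_equal(unname(armRanges(best)$second), hp$a2)
    ecs <- findProximalEcs(cand, site)
    expect_false(is.null(ecs))

    f <- extractFeatures(ecs, site, hp$seq)
    expect_equal(f$stem_length, 30)
    expect_equal(f$paired_total, 30)
    expect_equal(f$pct_paired, 1)
    expect_equal(f$max_bulge, 0)
    expect_equal(f$dist_to_edge, 5)
})

test_that("featureless windows yield no candidates", {
    polyA <- strrep("A", 301)
    expect_length(foldWindow(polyA, 150), 0)
    expect_warning(res <- foldWindow(strrep("ACGU", 8), 16), "40 nt")
    expect_length(res, 0)
})

test_that("stem filters enforce the 20-pair and 8-bulge thresholds", {
    mk <- function(np, bulge_at = NULL, bulge_len = 0) {
        i <- seq_len(np)
        j <- 200 - i
        if (!is.null(bulge_at)) i[i >= bulge_at] <- i[i >= bulge_at] + bulge_len
        DuplexStructure(cbind(i, j), rep("WC", np))
    }
    expect_false(is.null(findProximalEcs(list(mk(30)), site = 10)))
    expect_null(findProximalEcs(list(mk(19)), site = 10))
    expect_null(findProximalEcs(list(mk(25, bulge_at = 10, bulge_len = 9)),
                                site = 5))
    # bulge of exactly 8 passes
    expect_false(is.null(findProximalEcs(list(mk(25, bulge_at = 10,
                                                 bulge_len = 8)), site = 5)))
    # the candidate must cover the editing site
    expect_null(findProximalEcs(list(mk(30)), site = 100))
})

test_that("banded search matches exhaustive enumeration on small windows", {
    set.seed(42)
    hits <- 0
    for (r in 1:40) {
        # plant a complementary run of 5-8 in a window of at most 30 nt
        np <- sample(5:8, 1)
        lead <- sample(2:4, 1)
        arm1 <- sample(c("C", "G", "U"), np, TRUE)
        comp <- c(A = "U", C = "G", G = "C", U = "A")
        gap <- sample(5:6, 1)
        s <- c(rep("A", lead), arm1, rep("A", gap), rev(comp[arm1]))
        s <- c(s, rep("A", max(0, 30 - length(s))))[1:30]
        s <- s[!is.na(s)]
        # pad with unpairable poly-A so the 30-nt window clears the
        # minimum window width; padding cannot add pairs
        seq <- paste(c(s, rep("A", 40)), collapse = "")
        oracle <- oracleMaxRun(seq)
        cand <- foldWindow(seq, lead + 1, half_window = 200)
        if (!length(cand)) next
        hits <- hits + 1
        expect_equal(nPaired(cand[[1]]), oracle)
    }
    expect_gt(hits, 30)
})

test_that("conservation smoothing averages with truncated edges", {
    tr <- ConservationTrack(list(c = rep(0.8, 200)))
    sm <- smoothConservation(tr, 51)
    expect_equal(conservationAt(sm, "c", c(1, 26, 100, 200)), rep(0.8, 4))

    spike <- rep(0, 201); spike[101] <- 1
    sm2 <- smoothConservation(ConservationTrack(list(c = spike)), 51)
    expect_equal(conservationAt(sm2, "c", 101), 1 / 51)
    expect_equal(conservationAt(sm2, "c", 50), 0)

    # step 0 -> 1 produces the closed-form monotone ramp of width 51
    step <- c(rep(0, 100), rep(1, 100))
    sm3 <- smoothConservation(ConservationTrack(list(c = step)), 51)
    ramp <- conservationAt(sm3, "c", 76:125)
    expect_true(all(diff(ramp) > 0))
    expect_equal(conservationAt(sm3, "c", 100), 25 / 51)  # 25 ones in window
    expect_error(smoothConservation(tr, 50), "odd")
})

test_that("distal ECS search honours distance, length and score filters", {
    set.seed(7)
    np <- 30
    arm1 <- sample(c("C", "G", "U"), np, TRUE)
    comp <- c(A = "U", C = "G", G = "C", U = "A")
    mkseq <- function(block_at) {
        n <- 4000
        s <- rep("A", n)
        site <- 500
        s[(site - 10):(site - 10 + np - 1)] <- arm1
        s[block_at:(block_at + np - 1)] <- rev(comp[arm1])
        paste(s, collapse = "")
    }
    mktrack <- function(block_at, score) {
        v <- rep(0.4, 4000)
        v[(block_at - 30):(block_at + np + 30)] <- score
        smoothConservation(ConservationTrack(list(c = v)), 51)
    }
    site <- 500
    found <- findDistalEcs(mkseq(1500), mktrack(1500, 0.95), "c", site)
    expect_false(is.null(found))
    expect_equal(nPaired(found), np)
    # beyond 2,500 bp: not found
    expect_null(findDistalEcs(mkseq(3400), mktrack(3400, 0.95), "c", site))
    # insufficient conservation: not found
    expect_null(findDistalEcs(mkseq(1500), mktrack(1500, 0.85), "c", site))
})

test_that("duplex energies order as a nearest-neighbour model should", {
    gc <- function(np) {
        s <- paste(c(rep("G", np), rep("A", 10), rep("C", np)),
                   collapse = "")
        d <- DuplexStructure(cbind(1:np, (2 * np + 10):(np + 11)),
                             rep("WC", np))
        freeEnergy(d, s)
    }
    expect_equal(freeEnergy(DuplexStructure(matrix(integer(), 0, 2),
                                            character()), "ACGU"), 0)
    expect_lt(gc(30), gc(20))
    expect_lt(gc(20), 0)

    # an interior bulge makes the energy less negative
    np <- 20
    s_b <- paste(c(rep("G", 10), "A", "A", "A", rep("G", 10), rep("A", 8),
                   rep("C", 20)), collapse = "")
    pairs_b <- cbind(c(1:10, 14:23), 51:32)
    e_b <- freeEnergy(DuplexStructure(pairs_b, rep("WC", 20)), s_b)
    expect_gt(e_b, gc(20))

    # monotone: adding an outer WC pair never increases the energy
    s <- paste(c(rep("G", 21), rep("A", 8), rep("C", 21)), collapse = "")
    inner <- DuplexStructure(cbind(2:21, 49:30), rep("WC", 20))
    outer <- DuplexStructure(cbind(1:21, 50:30), rep("WC", 21))
    expect_lte(freeEnergy(outer, s), freeEnergy(inner, s))
})

test_that("feature extraction flags sites outside the stem", {
    d <- DuplexStructure(cbind(10:29, 70:51), rep("WC", 20))
    s <- strrep("G", 80)
    expect_error(extractFeatures(d, 40, s), "outside the stem")

    # a bulged editing arm reduces pct_paired and registers the bulge
    db <- DuplexStructure(cbind(c(10:19, 23:32), 70:51), rep("WC", 20))
    xb <- rep("G", 80); xb[51:70] <- "C"
    f <- extractFeatures(db, 12, paste(xb, collapse = ""))
    expect_equal(f$max_bulge, 3)
    expect_lt(f$pct_paired, 1)
    expect_equal(f$stem_length, 23)
    expect_equal(f$paired_upstream, 2)
    expect_equal(f$paired_downstream, 17)
})
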