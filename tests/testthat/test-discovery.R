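pileRow <- function(site, sample, A, C, G, T, ref = "A") {
    data.frame(site_id = site, sample_id = sample, ref_base = ref,
               n_A = A, n_C = C, n_G = G, n_T = T,
               coverage = A + C + G + T, stringsAsFactors = FALSE)
}

test_that("variant calling applies the 2-read support threshold", {
    p <- rbind(pileRow("s1", "wb", 98, 0, 2, 0),
               pileRow("s2", "wb", 99, 0, 1, 0))
    v <- callVariants(p, min_alt = 2)
    expect_equal(v$site_id, "s1")
    expect_equal(v$alt_base, "G")
    expect_equal(v$level, 0.02)

    # bidirectionally transcribed sites are dropped regardless of counts
    v2 <- callVariants(rbind(p, pileRow("s3", "wb", 50, 0, 50, 0)),
                       exclude_bidirectional = "s3")
    expect_false("s3" %in% v2$site_id)

    # counts pool across samples before calling
    p3 <- rbind(pileRow("s4", "a", 99, 0, 1, 0), pileRow("s4", "b", 99, 0, 1, 0))
    expect_equal(callVariants(p3)$alt_reads, 2)
})

test_that("frequency cutoff selection picks the smallest passing cutoff", {
    cv <- data.frame(cutoff = c(0.01, 0.05, 0.10),
                     n_ag = c(60, 75, 85), n_total = c(100, 100, 100))
    expect_equal(selectFrequencyCutoff(cv)$cutoff, 0.10)
    cv$n_ag <- c(85, 90, 95)
    expect_equal(selectFrequencyCutoff(cv)$cutoff, 0.01)
    cv$n_ag <- c(10, 20, 30)
    expect_error(selectFrequencyCutoff(cv), "best: 0.300")
})

test_that("shared-site identification respects the cutoff in both species", {
    calls_a <- data.frame(site_id = c("x1", "x2"), ref_base = "A",
                          alt_base = "G", alt_reads = c(12, 12),
                          coverage = 100, level = c(0.12, 0.12))
    calls_b <- data.frame(site_id = c("cb:10", "cb:20"), ref_base = "A",
                          alt_base = "G", alt_reads = c(12, 8),
                          coverage = 100, level = c(0.12, 0.08))
    ortho <- data.frame(site_id = c("x1", "x2"), species_a = "A",
                        species_b = "B", contig_b = "cb", pos_b = c(10, 20),
                        strand_flip = FALSE)
    res <- identifySharedEditing(calls_a, calls_b, ortho, cutoff = 0.10)
    expect_equal(res$sites$site_id, "x1")   # x2 is 8% in species B
})

test_that("ADAR-null validation separates genuine from error calls", {
    wt <- rbind(pileRow("s1", "wt", 80, 0, 20, 0),
                pileRow("s2", "wt", 97, 0, 3, 0),
                pileRow("s3", "wt", 96, 0, 4, 0))
    null <- rbind(pileRow("s1", "ko", 100, 0, 0, 0),
                  pileRow("s2", "ko", 97, 0, 3, 0))
    res <- estimateFdrWithNull(wt, null)
    st <- setNames(res$sites$status, res$sites$site_id)
    expect_equal(st[["s1"]], "genuine")       # no altered reads in null
    expect_equal(st[["s2"]], "rejected")      # identical proportions, p = 1
    expect_equal(st[["s3"]], "unevaluable")   # no null coverage
    expect_equal(res$sites$p[res$sites$site_id == "s2"], 1)
    expect_equal(res$fdr, 1 / 2)              # s3 excluded from denominator
})

test_that("candidate filters follow the more-than-two-reads rule", {
    wt <- rbind(pileRow("s1", "wt", 98, 0, 2, 0),    # only 2 altered reads
                pileRow("s2", "wt", 996, 0, 4, 0))   # 4 reads but 0.4% level
    res <- estimateFdrWithNull(wt, pileRow("s0", "ko", 100, 0, 0, 0))
    expect_equal(nrow(res$sites), 0)
})

test_that("level quantification uses G/(A+G) with coverage minima", {
    p <- rbind(pileRow("s1", "a", 75, 0, 25, 0),
               pileRow("s2", "a", 15, 0, 4, 0),
               pileRow("s3", "a", 60, 0, 40, 0))
    lm <- quantifyLevels(p, min_cov = 20,
                         dna_base = c(s1 = "A", s2 = "A", s3 = "G"))
    lv <- editingLevels(lm)
    expect_equal(lv["s1", "a"], 0.25)
    expect_true(is.na(lv["s2", "a"]))          # coverage 19 < 20
    expect_equal(lv["s3", "a"], 0)             # non-A DNA base
    expect_true(SummarizedExperiment::rowData(lm)$non_a[3])

    # scale-free: multiplying all counts by k leaves levels unchanged
    p10 <- p; p10[, 4:7] <- p10[, 4:7] * 10; p10$coverage <- p10$coverage * 10
    expect_equal(editingLevels(quantifyLevels(p10, 20))["s1", ],
                 editingLevels(quantifyLevels(p, 20))["s1", ])
})

test_that("platform combination prefers validated mmPCR measurements", {
    mk <- function(level, cov) LevelMatrix(matrix(level, 1, 1,
                                                  dimnames = list("s1", "wb")),
                                           matrix(cov, 1, 1), "mmpcr")
    rna <- LevelMatrix(matrix(0.2, 1, 1, dimnames = list("s1", "wb")),
                       matrix(100, 1, 1), "rnaseq")
    cmb <- combinePlatforms(rna, mk(0.30, 60), mk(0.35, 60))
    expect_equal(editingLevels(cmb)["s1", "wb"], 0.325)
    expect_equal(platforms(cmb)["s1", "wb"], "mmpcr")

    # replicate disagreement > 10% falls back to RNA-seq
    cmb2 <- combinePlatforms(rna, mk(0.30, 60), mk(0.45, 60))
    expect_equal(editingLevels(cmb2)["s1", "wb"], 0.2)
    expect_equal(platforms(cmb2)["s1", "wb"], "rnaseq")

    # low replicate coverage also falls back
    cmb3 <- combinePlatforms(rna, mk(0.30, 40), mk(0.35, 60))
    expect_equal(platforms(cmb3)["s1", "wb"], "rnaseq")
})

test_that("representative level is the max over covered entries", {
    lm <- LevelMatrix(matrix(c(0.05, 0.40, 0.12), 1,
                             dimnames = list("s1", c("a", "b", "c"))),
                      matrix(c(100, 100, 100), 1))
    expect_equal(unname(representativeLevel(lm)), 0.40)
    lm2 <- LevelMatrix(matrix(c(0.05, 0.40), 1,
                              dimnames = list("s1", c("a", "b"))),
                       matrix(c(100, 19), 1))
    expect_equal(unname(representativeLevel(lm2)), 0.05)
    lm3 <- LevelMatrix(matrix(0.07, 1, 1, dimnames = list("s1", "a")),
                       matrix(10, 1, 1))
    expect_true(is.na(representativeLevel(lm3)))
})
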