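smallConfig <- function(...) simConfig(n_sites = 60L, n_genes = 20L, ...)

test_that("the generator is deterministic given seed and config", {
    cfg <- smallConfig(rng_seed = 5)
    a <- simulateLevels(cfg); b <- simulateLevels(cfg)
    expect_identical(editingLevels(a$levels), editingLevels(b$levels))
    expect_identical(a$truth$sites, b$truth$sites)
    ra <- simulateReads(a$levels, cfg); rb <- simulateReads(b$levels, cfg)
    expect_identical(ra, rb)
    sa <- simulateSequences(a$truth, a$levels, cfg)
    sb <- simulateSequences(b$truth, b$levels, cfg)
    expect_identical(as.character(sa$sequences[[1]]),
                     as.character(sb$sequences[[1]]))
})

test_that("degenerate walks collapse to the birth level", {
    # all branch lengths zero: every species carries the birth level exactly
    cfg0 <- smallConfig(tree = "(((a:0,b:0):0,c:0):0,d:0);",
                        root_edge_length = 0, rng_seed = 2)
    sim <- simulateLevels(cfg0)
    lv <- editingLevels(sim$levels)
    expect_true(all(apply(lv, 1, function(x) length(unique(x[x > 0])) <= 1)))
    born <- apply(lv, 1, function(x) if (any(x > 0)) x[x > 0][1] else 0)
    expect_equal(unname(born[born > 0]),
                 sim$truth$sites$birth_level[born > 0])

    # zero walk sd on a real tree: descendant species share the level
    cfg1 <- smallConfig(level_walk_sd = 0, rng_seed = 2)
    lv1 <- editingLevels(simulateLevels(cfg1)$levels)
    expect_true(all(apply(lv1, 1, function(x) length(unique(x[x > 0])) <= 1)))
})

test_that("level divergence grows with path distance on the tree", {
    # Monte-Carlo check of the random-walk variance: mean |level difference|
    # between two leaves increases with their path distance
    tr <- ape::read.tree(text = simConfig()$tree)
    pt <- ape::cophenetic.phylo(tr)
    close_pair <- c("mel", "sim"); far_pair <- c("mel", "vir")
    d_close <- d_far <- numeric(20)
    for (r in 1:20) {
        sim <- simulateLevels(smallConfig(n_sites = 200L, rng_seed = 100 + r,
                                          root_edge_length = 200))
        lv <- editingLevels(sim$levels)
        both <- lv[, "mel"] > 0 & lv[, "sim"] > 0 & lv[, "vir"] > 0
        d_close[r] <- mean(abs(lv[both, "mel"] - lv[both, "sim"]))
        d_far[r] <- mean(abs(lv[both, "mel"] - lv[both, "vir"]))
    }
    expect_lt(pt["mel", "sim"], pt["mel", "vir"])
    expect_gt(mean(d_far), mean(d_close))
    expect_gt(mean(d_far > d_close), 0.9)
})

test_that("read simulation respects the error model", {
    lev <- matrix(0, 50, 2, dimnames = list(sprintf("s%02d", 1:50),
                                            c("sp1", "sp2")))
    cfg <- smallConfig(error_rate = 0)
    p0 <- simulateReads(lev, cfg, adar_null = FALSE)
    expect_true(all(p0$n_G == 0))

    lev1 <- matrix(1, 50, 2, dimnames = dimnames(lev))
    p1 <- simulateReads(lev1, cfg, adar_null = FALSE)
    expect_true(all(p1$n_G == p1$coverage))

    # mean observed level matches level + err * (1 - level) at high coverage
    cfg2 <- simConfig(coverage_mean = 500, rng_seed = 7)
    lev2 <- matrix(0.3, 1000, 1, dimnames = list(sprintf("s%04d", 1:1000), "sp"))
    p2 <- simulateReads(lev2, cfg2, adar_null = FALSE)
    obs <- p2$n_G / p2$coverage
    expect_lt(abs(mean(obs) - (0.3 + 0.01 * 0.7)), 0.01)

    # the ADAR-null sample carries errors only
    cfg3 <- smallConfig(rng_seed = 3)
    lev3 <- matrix(0.5, 200, 1, dimnames = list(sprintf("s%03d", 1:200), "sp"))
    p3 <- simulateReads(lev3, cfg3, adar_null = TRUE)
    nul <- p3[p3$sample_id == "sp_null", ]
    expect_lt(mean(nul$n_G / nul$coverage), 0.03)
})

test_that("planted conservation classes have the constructed means", {
    cfg <- smallConfig(n_sites = 90L, rng_seed = 11)
    sim <- simulateLevels(cfg)
    tr <- simulateConservation(sim$truth, cfg)
    st <- sim$truth$sites
    sreg <- function(id) conservationAt(tr, id, (300 - 15):(300 + 30))
    freg <- function(id) conservationAt(tr, id,
                                        c((300 - 61):(300 - 16), (300 + 31):(300 + 76)))
    for (cls in c("high", "moderate", "none")) {
        ids <- st$site_id[st$constraint_class == cls]
        if (!length(ids)) next
        ms <- mean(vapply(ids, function(i) mean(sreg(i)), 0))
        mf <- mean(vapply(ids, function(i) mean(freg(i)), 0))
        if (cls == "high") { expect_gt(ms, 0.9); expect_gt(mf, 0.9) }
        if (cls == "moderate") { expect_gt(ms, 0.9); expect_lt(mf, 0.7) }
        if (cls == "none") { expect_lt(ms, 0.7); expect_lt(mf, 0.7) }
    }
})

test_that("cis effects couple planted features to levels only when asked", {
    # null construction: no structure/motif effect, stems independent of level
    cfg0 <- simConfig(n_sites = 500L, structure_effect = 0, motif_effect = 0,
                      rng_seed = 13)
    sim0 <- simulateLevels(cfg0)
    st0 <- sim0$truth$sites
    ok <- st0$has_stem
    r0 <- cor(st0$n_p[ok], st0$birth_level[ok], method = "spearman")
    expect_lt(abs(r0), 0.1)

    # logistic link recovery: level regressed on n_p has a positive slope
    cfg1 <- simConfig(n_sites = 500L, rng_seed = 13)
    st1 <- simulateLevels(cfg1)$truth$sites
    ok <- st1$has_stem
    fit <- summary(lm(qlogis(pmin(pmax(st1$birth_level[ok], 1e-3), 1 - 1e-3))
                      ~ st1$n_p[ok]))
    expect_gt(fit$coefficients[2, 1], 0)
    expect_lt(fit$coefficients[2, 4], 0.01)
})

test_that("expression shifts follow the 3'UTR editing burden", {
    cfg <- simConfig(n_sites = 400L, n_genes = 150L, rng_seed = 17)
    sim <- simulateLevels(cfg)
    ex <- simulateExpression(sim$truth, cfg)
    g <- ex$expression
    expect_equal(g$true_log2fc[g$n_utr3_sites == 0], rep(0, sum(g$n_utr3_sites == 0)))
    expect_true(all(g$true_log2fc[g$n_utr3_sites == 1] == cfg$expression_shift))
    expect_true(all(g$true_log2fc[g$n_utr3_sites >= 2] == 2 * cfg$expression_shift))
    # null: no shift -> group medians indistinguishable
    cfg0 <- simConfig(n_sites = 400L, n_genes = 150L, expression_shift = 0,
                      rng_seed = 17)
    ex0 <- simulateExpression(simulateLevels(cfg0)$truth, cfg0)
    g0 <- ex0$expression
    p <- rankGroupTest(g0$log2fc[g0$utr3_edited], g0$log2fc[!g0$utr3_edited])
    expect_gt(p, 0.01)
})
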