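featcols <- c("free_energy", "stem_length", "max_bulge", "pct_paired",
              "dist_to_edge", "paired_total", "paired_downstream",
              "paired_upstream")

mkFeats <- function(ids, pass = TRUE, value = 1) {
    f <- as.data.frame(matrix(value, length(ids), length(featcols),
                              dimnames = list(NULL, featcols)))
    cbind(data.frame(site_id = ids, stringsAsFactors = FALSE), f,
          ecs_pass = pass)
}

mkPairs <- function(n_pa = 10, n_pp = 10, n_other = 5) {
    data.frame(site_id = sprintf("s%03d", seq_len(n_pa + n_pp + n_other)),
               class = c(rep("presence_absence", n_pa),
                         rep("presence_presence", n_pp),
                         rep("other", n_other)),
               anchor_level = 0.4,
               other_level = c(rep(0.001, n_pa), rep(0.3, n_pp),
                               rep(0.05, n_other)),
               motif_anchor = 5, motif_other = 4,
               stringsAsFactors = FALSE)
}

test_that("feature assembly applies the ECS inclusion rules", {
    pairs <- mkPairs()
    ids <- pairs$site_id
    fa <- mkFeats(ids); fo <- mkFeats(ids, value = 2)

    rows <- assembleFeatures(pairs, fa, fo, "presence_absence")
    # PA and PP pairs enter the classification set; "other" never does
    expect_equal(nrow(rows), 20)
    expect_equal(sum(rows$outcome == "edited"), 10)
    expect_true(all(rows$delta_free_energy == 1))        # other - anchor
    expect_true(all(rows$delta_motif_score == -1))

    # anchor ECS failing the filter excludes the pair in PA mode
    fa2 <- fa; fa2$ecs_pass[1] <- FALSE
    expect_equal(nrow(assembleFeatures(pairs, fa2, fo, "presence_absence")),
                 19)
    # ...but pass-in-either suffices in PP mode
    fa3 <- fa; fa3$ecs_pass <- FALSE
    rows_pp <- assembleFeatures(pairs, fa3, fo, "presence_presence")
    expect_equal(nrow(rows_pp), 10)
    expect_true(is.numeric(rows_pp$outcome))
    expect_true(all(rows_pp$outcome == 0.3))

    # a species with no folded candidate contributes zero features...
    fo4 <- fo[-(1:2), ]
    r4 <- assembleFeatures(pairs, fa, fo4, "presence_absence")
    expect_equal(r4$delta_paired_total[1:2], c(-1, -1))   # 0 - anchor
    # ...unless strict mode excludes it
    r5 <- assembleFeatures(pairs, fa, fo4, "presence_absence",
                           strict = TRUE)
    expect_equal(nrow(r5), 18)

    # identical species -> all deltas zero
    r6 <- assembleFeatures(pairs, fa, fa, "presence_absence")
    expect_true(all(as.matrix(r6[, paste0("delta_", featcols)]) == 0))

    expect_error(assembleFeatures(mkPairs(0, 0, 5), fa, fo,
                                  "presence_absence"), "eligible")
})

simRows <- function(n = 150, seed = 1) {
    set.seed(seed)
    df <- data.frame(site_id = sprintf("s%03d", 1:n),
                     anchor_level = runif(n),
                     delta_motif_score = rnorm(n))
    for (f in featcols) df[[paste0("delta_", f)]] <- rnorm(n)
    df
}

test_that("the presence model recovers a planted feature", {
    rows <- simRows(150, 3)
    rows$outcome <- factor(ifelse(rows$delta_free_energy > 0,
                                  "edited", "unedited"))
    rep <- fitPresenceModel(rows, ntree = 500, seed = 3)
    expect_equal(rep$importance$feature[which.max(rep$importance$importance)],
                 "delta_free_energy")
    expect_gt(rep$accuracy, 0.9)

    rows1 <- rows; rows1$outcome <- factor(rep("edited", nrow(rows)))
    expect_error(fitPresenceModel(rows1), "both classes")
})

test_that("pure-noise features give chance-level OOB accuracy", {
    rows <- simRows(200, 5)
    set.seed(99)
    rows$outcome <- factor(sample(c("edited", "unedited"), 200, TRUE,
                                  prob = c(0.6, 0.4)))
    rep <- fitPresenceModel(rows, ntree = 500, seed = 5)
    expect_lt(abs(rep$accuracy - 0.6), 0.1)
})

test_that("level models report out-of-bag R-squared", {
    rows <- simRows(150, 7)
    rows$outcome <- rows$anchor_level        # deterministic target
    red <- fitLevelModel(rows, with_cis_features = FALSE, ntree = 500,
                         seed = 7)
    expect_gt(red$r2, 0.95)

    set.seed(7)
    rows2 <- rows; rows2$outcome <- sample(rows$outcome)   # permuted
    prm <- fitLevelModel(rows2, ntree = 500, seed = 7)
    expect_lt(prm$r2, 0.05)

    rows3 <- rows; rows3$outcome <- rep(0.5, nrow(rows))
    expect_error(fitLevelModel(rows3), "variance")
})

test_that("model comparison is reproducible and ~0 on matched models", {
    rows <- simRows(150, 11)
    set.seed(50)
    rows$outcome <- pmin(pmax(rows$anchor_level + rnorm(150, 0, 0.15),
                              0), 1)
    # no cis signal: full and reduced should tie within resampling noise
    cmp <- compareModels(rows, n_refits = 5, ntree = 300, seed = 2)
    expect_lt(abs(cmp$delta_r2), 0.1)
    # reproducibility given seed
    cmp2 <- compareModels(rows, n_refits = 5, ntree = 300, seed = 2)
    expect_identical(cmp$deltas, cmp2$deltas)
})
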