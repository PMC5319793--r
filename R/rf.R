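#' Assemble the feature table for the random-forest models
#'
#' One row per eligible cross-species site pair, with the anchor-species
#' editing level, the motif-score change, and the changes (other minus
#' anchor) of the 8 structural features as predictors. Eligibility follows
#' the ECS inclusion rules: for the presence/absence analysis the predicted
#' ECS must pass the stem filter in the anchor species (it may or may not
#' be present in the other species); for the presence/presence analysis it
#' must pass in at least one of the two species. A species without a
#' passing ECS contributes the features of its best folded-but-failing
#' candidate; if it has no candidate at all, its paired counts, stem length
#' and free energy enter as 0 (set \code{strict = TRUE} to exclude such
#' rows instead).
#'
#' @param pairs data.frame with columns \code{site_id, class}
#'   (\code{presence_absence} / \code{presence_presence} / other),
#'   \code{anchor_level, other_level, motif_anchor, motif_other}
#' @param feats_anchor,feats_other data.frames keyed by \code{site_id} with
#'   an \code{ecs_pass} logical and the 8 feature columns of
#'   [extractFeatures()] (a missing site_id means no folded candidate)
#' @param mode \code{"presence_absence"} (classification rows: both
#'   presence/absence and presence/presence pairs, anchor-pass rule) or
#'   \code{"presence_presence"} (regression rows: presence/presence pairs,
#'   pass-in-either rule)
#' @param strict exclude species without any folded candidate instead of
#'   zero-filling
#' @return data.frame of feature rows with an \code{outcome} column (factor
#'   edited/unedited for classification; the other species' level for
#'   regression)
#' @export
assembleFeatures <- function(pairs, feats_anchor, feats_other,
                             mode = c("presence_absence",
                                      "presence_presence"),
                             strict = FALSE) {
    mode <- match.arg(mode)
    featcols <- c("free_energy", "stem_length", "max_bulge", "pct_paired",
                  "dist_to_edge", "paired_total", "paired_downstream",
                  "paired_upstream")
    getfeat <- function(tab, ids) {
        idx <- match(ids, tab$site_id)
        out <- as.data.frame(matrix(0, length(ids), length(featcols),
                                    dimnames = list(NULL, featcols)))
        ok <- !is.na(idx)
        out[ok, ] <- tab[idx[ok], featcols]
        list(f = out, present = ok,
             pass = ifelse(ok, tab$ecs_pass[idx], FALSE))
    }
    fa <- getfeat(feats_anchor, pairs$site_id)
    fo <- getfeat(feats_other, pairs$site_id)
    if (mode == "presence_absence") {
        keep <- pairs$class %in% c("presence_absence", "presence_presence") &
            fa$pass
        outcome <- factor(ifelse(pairs$class == "presence_presence",
                                 "edited", "unedited"),
                          levels = c("unedited", "edited"))
    } else {
        keep <- pairs$class == "presence_presence" & (fa$pass | fo$pass)
        outcome <- pairs$other_level
    }
    if (strict) keep <- keep & fa$present & fo$present
    if (!any(keep)) stop("no eligible site pairs for mode ", mode)
    rows <- data.frame(site_id = pairs$site_id,
                       anchor_level = pairs$anchor_level,
                       delta_motif_score = pairs$motif_other -
                           pairs$motif_anchor)
    df <- fo$f - fa$f
    names(df) <- paste0("delta_", featcols)
    rows <- cbind(rows, df)
    rows$outcome <- outcome
    rows[keep, , drop = FALSE]
}

.rfPredictors <- function(rows, reduced = FALSE) {
    if (reduced) rows[, "anchor_level", drop = FALSE]
    else rows[, setdiff(names(rows), c("site_id", "outcome")), drop = FALSE]
}

.importanceTable <- function(rf) {
    imp <- randomForest::importance(rf, type = 1, scale = TRUE)
    data.frame(feature = rownames(imp), importance = unname(imp[, 1]),
               stringsAsFactors = FALSE)
}

#' Random-forest model of editing presence/absence
#'
#' Classification forest predicting whether a site edited in the anchor
#' species is edited in the other species, from the motif and structural
#' feature changes. Feature importance is the permutation accuracy drop
#' divided by its standard deviation; accuracy is out-of-bag.
#'
#' @param rows feature table from [assembleFeatures()] (classification
#'   outcome; both classes must be present)
#' @param ntree trees (default 1000; the heavyweight setting is 10000)
#' @param mtry features sampled per split (default 3)
#' @param seed RNG seed for reproducibility
#' @return an \code{ImportanceReport} list: \code{type}, \code{importance}
#'   data.frame, \code{accuracy} (OOB), \code{n}, \code{forest}
#' @export
fitPresenceModel <- function(rows, ntree = 1000L, mtry = 3L, seed = 1L) {
    y <- rows$outcome
    if (!is.factor(y)) stop("presence model needs a factor outcome")
    y <- droplevels(y)
    if (nlevels(y) < 2L)
        stop("both classes must be present to fit the presence model")
    x <- .rfPredictors(rows)
    set.seed(seed)
    rf <- randomForest::randomForest(x, y, ntree = ntree,
                                     mtry = min(mtry, ncol(x)),
                                     importance = TRUE)
    acc <- 1 - unname(rf$err.rate[ntree, "OOB"])
    structure(list(type = "classification",
                   importance = .importanceTable(rf),
                   accuracy = acc, n = nrow(rows), forest = rf),
              class = "ImportanceReport")
}

#' Random-forest model of editing-level change
#'
#' Regression forest predicting the other species' editing level. The full
#' model uses the anchor level plus the motif and structural feature
#' changes; the reduced model (\code{with_cis_features = FALSE}) uses the
#' anchor level alone with \code{mtry = 1}. The explained variation is
#' \code{R^2 = 1 - MSE / Var(outcome)} with the out-of-bag MSE; importance
#' is the permutation increase in MSE divided by its standard deviation.
#'
#' @param rows feature table from [assembleFeatures()] (numeric outcome)
#' @param with_cis_features include motif/structure deltas? (default TRUE)
#' @param ntree,mtry,seed as in [fitPresenceModel()]
#' @return an \code{ImportanceReport} list with \code{r2} instead of
#'   accuracy
#' @export
fitLevelModel <- function(rows, with_cis_features = TRUE, ntree = 1000L,
                          mtry = 3L, seed = 1L) {
    y <- rows$outcome
    if (!is.numeric(y)) stop("level model needs a numeric outcome")
    if (var(y) == 0) stop("outcome has zero variance; R^2 undefined")
    x <- .rfPredictors(rows, reduced = !with_cis_features)
    set.seed(seed)
    rf <- randomForest::randomForest(
        x, y, ntree = ntree,
        mtry = if (with_cis_features) min(mtry, ncol(x)) else 1L,
        importance = TRUE)
    r2 <- 1 - rf$mse[ntree] / var(y)
    structure(list(type = "regression",
                   importance = .importanceTable(rf),
                   r2 = r2, n = nrow(rows), forest = rf),
              class = "ImportanceReport")
}

#' @export
print.ImportanceReport <- function(x, ...) {
    cat("ImportanceReport (", x$type, ", n = ", x$n, ")\n", sep = "")
    if (x$type == "classification")
        cat("OOB accuracy:", round(x$accuracy, 3), "\n")
    else cat("OOB R^2:", round(x$r2, 3), "\n")
    imp <- x$importance[order(-x$importance$importance), ]
    print(utils::head(imp, 10), row.names = FALSE)
    invisible(x)
}

#' Compare the full and reduced editing-level models
#'
#' Refits both regression models \code{n_refits} times with different seeds
#' on the same rows and reports the difference in out-of-bag R^2 (full
#' minus reduced) with its seed-resampling interval.
#'
#' @param rows feature table from [assembleFeatures()] (numeric outcome)
#' @param n_refits refits (default 20)
#' @param ntree,mtry as in [fitLevelModel()]
#' @param seed base seed; refit i uses \code{seed + i}
#' @return list with \code{delta_r2} (mean), \code{interval} (range over
#'   refits), \code{r2_full}, \code{r2_reduced} (means) and the per-refit
#'   \code{deltas}
#' @export
compareModels <- function(rows, n_refits = 20L, ntree = 1000L, mtry = 3L,
                          seed = 1L) {
    r2f <- r2r <- numeric(n_refits)
    for (i in seq_len(n_refits)) {
        r2f[i] <- fitLevelModel(rows, TRUE, ntree, mtry, seed + i)$r2
        r2r[i] <- fitLevelModel(rows, FALSE, ntree, mtry, seed + i)$r2
    }
    d <- r2f - r2r
    list(delta_r2 = mean(d), interval = range(d),
         r2_full = mean(r2f), r2_reduced = mean(r2r), deltas = d)
}
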