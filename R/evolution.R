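#' Editing-level divergence between two species
#'
#' Divergence is \code{1 - Spearman's rho} over the sites with defined
#' levels in both species (at least 3 required). Spearman's rho is the
#' Pearson correlation of mid-ranks, which handles the frequent ties at 0.
#' Sites that are not an A at the DNA level should enter with level 0
#' (see [quantifyLevels()]).
#'
#' @param levels_a,levels_b numeric vectors of per-site levels (NA =
#'   undefined)
#' @return divergence in [0, 2], or \code{NA} with fewer than 3 shared
#'   sites
#' @export
editingDivergence <- function(levels_a, levels_b) {
    ok <- !is.na(levels_a) & !is.na(levels_b)
    if (sum(ok) < 3L) return(NA_real_)
    1 - cor(levels_a[ok], levels_b[ok], method = "spearman")
}

#' All-pairs editing divergence matrix
#'
#' @param levels a \linkS4class{LevelMatrix} (sites x species) or plain
#'   matrix
#' @return symmetric matrix of 1 - Spearman's rho values, diagonal 0
#' @export
divergenceMatrix <- function(levels) {
    lv <- if (is(levels, "LevelMatrix")) editingLevels(levels)
          else as.matrix(levels)
    sp <- colnames(lv)
    d <- matrix(0, length(sp), length(sp), dimnames = list(sp, sp))
    for (i in seq_along(sp)) for (j in seq_along(sp)) {
        if (j <= i) next
        d[i, j] <- d[j, i] <- editingDivergence(lv[, i], lv[, j])
    }
    d
}

#' Neighbor-joining tree from a divergence matrix
#'
#' Saitou-Nei neighbor joining (via \code{ape::nj}). Negative branch
#' lengths, which NJ can produce on noisy non-additive input, are clamped
#' to 0 with the deficit transferred to the sister branch so path lengths
#' are preserved; the topology is the object of interest.
#'
#' @param d symmetric distance matrix with species names
#' @return an unrooted \code{ape::phylo} tree
#' @export
buildNjTree <- function(d) {
    d <- as.matrix(d)
    if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
        stop("distance matrix must be symmetric")
    tr <- ape::nj(as.dist(d))
    neg <- which(tr$edge.length < 0)
    for (e in neg) {
        deficit <- tr$edge.length[e]
        tr$edge.length[e] <- 0
        parent <- tr$edge[e, 1]
        sib <- which(tr$edge[, 1] == parent & seq_len(nrow(tr$edge)) != e)
        if (length(sib))
            tr$edge.length[sib[1]] <- tr$edge.length[sib[1]] + deficit
    }
    tr
}

#' Regress editing divergence on divergence time
#'
#' @param distances,times numeric vectors over species pairs (>= 3 pairs
#'   with both defined)
#' @return list with \code{slope}, \code{intercept}, \code{rho} (Spearman)
#' @export
divergenceTimeRegression <- function(distances, times) {
    ok <- !is.na(distances) & !is.na(times)
    if (sum(ok) < 3L) stop("need at least 3 species pairs")
    x <- times[ok]; y <- distances[ok]
    if (var(x) == 0) stop("divergence times are constant; slope undefined")
    fit <- lm(y ~ x)
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         rho = suppressWarnings(cor(x, y, method = "spearman")))
}

#' Call a site's editing status in one species
#'
#' A site is \code{"edited"} if its level is >= 2\% in at least one
#' dataset; \code{"unedited"} if every dataset covers it with >= 20 reads
#' and the level is <= 1.5\% in all of them, or if the DNA base is not an
#' A; otherwise \code{"undefined"} (coverage insufficient to assert
#' absence).
#'
#' @param levels,coverages numeric vectors over datasets
#' @param dna_base the site's DNA base in this species (default "A")
#' @param edited_level,absence_level,min_cov thresholds (2\%, 1.5\%, 20)
#' @return \code{"edited"}, \code{"unedited"} or \code{"undefined"}
#' @export
callEditingStatus <- function(levels, coverages, dna_base = "A",
                              edited_level = 0.02, absence_level = 0.015,
                              min_cov = 20L) {
    if (!is.na(dna_base) && dna_base != "A") return("unedited")
    ok <- !is.na(levels)
    if (!any(ok)) return("undefined")
    if (any(levels[ok] >= edited_level)) return("edited")
    if (all(coverages[ok] >= min_cov) && all(levels[ok] <= absence_level))
        return("unedited")
    "undefined"
}

#' Date an editing site by parsimony
#'
#' The site's age is the most distantly related species (from the anchor)
#' in which it is also edited, on the parsimony assumption that editing
#' events rarely originate independently on different lineages (intervening
#' losses are allowed). Sites with a well-defined (edited or unedited)
#' status in fewer than \code{min_defined} non-anchor species are not
#' dated.
#'
#' @param status named character vector of statuses
#'   (\code{edited/unedited/undefined}) with the anchor species first;
#'   names order species by increasing divergence from the anchor
#' @param min_defined minimum defined non-anchor species (default 5)
#' @return list with \code{age} (species name, \code{NA} when undated),
#'   \code{dated} flag and \code{n_defined}
#' @export
assignAge <- function(status, min_defined = 5L) {
    species <- names(status)
    if (is.null(species)) stop("status must be named by species")
    if (status[1] != "edited")
        stop("the anchor species must be edited (sites are anchored on ",
             "anchor-species editing sites)")
    rest <- status[-1]
    n_def <- sum(rest != "undefined")
    if (n_def < min_defined)
        return(list(age = NA_character_, dated = FALSE, n_defined = n_def))
    edited <- which(rest == "edited")
    age <- if (length(edited)) names(rest)[max(edited)] else species[1]
    list(age = age, dated = TRUE, n_defined = n_def)
}

#' Fraction of clustered editing sites
#'
#' A site is clustered if its nearest other site (same strand and contig)
#' lies within \code{max_dist} bases. When \code{groups} is given the
#' fraction is computed per group with a bootstrap standard deviation.
#'
#' @param positions integer vector of site positions on one contig/strand
#' @param max_dist clustering distance (30, 40 or 50 bp in the standard
#'   analysis)
#' @param groups optional factor (e.g. age class) per site
#' @param n_boot bootstrap resamples for the per-group SD (default 1000)
#' @return with \code{groups = NULL}, a list with \code{fraction} and the
#'   per-site logical \code{clustered}; otherwise a data.frame with
#'   columns \code{group, n, fraction, sd}
#' @export
clusterFraction <- function(positions, max_dist = 30L, groups = NULL,
                            n_boot = 1000L) {
    clusteredFlag <- function(pos) {
        n <- length(pos)
        if (n < 2L) return(rep(FALSE, n))
        o <- order(pos)
        gaps <- diff(pos[o])
        nn <- pmin(c(gaps, Inf), c(Inf, gaps))
        out <- logical(n)
        out[o] <- nn <= max_dist
        out
    }
    cl <- clusteredFlag(positions)
    if (is.null(groups))
        return(list(fraction = mean(cl), clustered = cl))
    groups <- as.factor(groups)
    res <- lapply(levels(groups), function(g) {
        f <- cl[groups == g]
        bs <- vapply(seq_len(n_boot), function(i)
            mean(sample(f, length(f), replace = TRUE)), 0)
        data.frame(group = g, n = length(f), fraction = mean(f),
                   sd = sd(bs))
    })
    do.call(rbind, res)
}

#' Normalized editing-level difference and editing conservation
#'
#' The normalized difference is the ratio of the editing difference to the
#' mean editing level, \code{|e1 - e2| / ((e1 + e2)/2)}; editing
#' conservation is \code{1 - |e1 - e2| / (e1 + e2)} (equal to
#' \code{1 - normalized_diff / 2}). Both are undefined when both levels are
#' 0. Pairwise comparisons conventionally restrict to sites edited at
#' least 20\% in one or both strains.
#'
#' @param e1,e2 editing levels
#' @return data.frame with \code{normalized_diff} and \code{conservation}
#' @export
levelDifferenceMetrics <- function(e1, e2) {
    s <- e1 + e2
    nd <- ifelse(s > 0, abs(e1 - e2) / (s / 2), NA_real_)
    data.frame(normalized_diff = nd,
               conservation = ifelse(s > 0, 1 - abs(e1 - e2) / s, NA_real_))
}

# Exact permutation distribution of a rank sum via dynamic programming on
# doubled mid-ranks (handles ties); returns the two-sided p-value for
# drawing `k` of the ranks with observed sum `obs`.
.exactRankSumP <- function(ranks2, k, obs2) {
    N <- length(ranks2)
    total <- sum(ranks2)
    # dp[j+1, s+1] = number of j-subsets with doubled rank sum s
    dp <- matrix(0, k + 1L, total + 1L)
    dp[1L, 1L] <- 1
    for (r in ranks2) {
        jmax <- k
        for (j in jmax:1L) {
            nz <- which(dp[j, ] > 0)
            if (length(nz))
                dp[j + 1L, nz + r] <- dp[j + 1L, nz + r] + dp[j, nz]
        }
    }
    cnt <- dp[k + 1L, ]
    tot <- sum(cnt)
    nzc <- cnt[cnt > 0]
    s <- which(cnt > 0) - 1L
    mu <- sum(ranks2) * k / N
    dev <- abs(obs2 - mu)
    sum(nzc[abs(s - mu) >= dev - 1e-9]) / tot
}

#' Two-sided rank test between two groups
#'
#' The generic rank-test kernel used by the group comparisons throughout
#' the package: a two-sided Mann-Whitney U test for unpaired groups or a
#' Wilcoxon signed-rank test for paired ones. For a combined sample size of
#' at most 25 the p-value is computed by exact enumeration of the
#' permutation distribution (a rank-sum DP that handles ties); above that,
#' the tie-corrected normal approximation is used. All values tied gives
#' p = 1.
#'
#' @param a,b numeric vectors; equal lengths required when paired
#' @param paired paired test? (default FALSE)
#' @return two-sided p-value
#' @examples
#' rankGroupTest(c(1, 2, 3), c(4, 5, 6))   # exact: 0.1
#' @export
rankGroupTest <- function(a, b, paired = FALSE) {
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (!length(a) || !length(b)) stop("groups must be non-empty")
    if (paired) {
        if (length(a) != length(b)) stop("paired groups must match in length")
        d <- a - b
        d <- d[d != 0]
        if (!length(d)) return(1)
        n <- length(d)
        r <- rank(abs(d))
        if (n <= 25L) {
            k <- sum(d > 0)
            # signed-rank: enumerate sums of the positive-sign subset over
            # all 2^n sign assignments; equivalent DP over subset sums
            ranks2 <- as.integer(round(2 * r))
            obs2 <- as.integer(round(2 * sum(r[d > 0])))
            total <- sum(ranks2)
            cnt <- rep(0, total + 1L); cnt[1L] <- 1
            for (x in ranks2) {
                nz <- which(cnt > 0)
                add <- rep(0, total + 1L)
                add[nz + x] <- cnt[nz]
                cnt <- cnt + add
            }
            nzc <- cnt[cnt > 0]
            s <- which(cnt > 0) - 1L
            mu <- total / 2
            dev <- abs(obs2 - mu)
            return(sum(nzc[abs(s - mu) >= dev - 1e-9]) / sum(cnt))
        }
        return(suppressWarnings(
            wilcox.test(a, b, paired = TRUE, exact = FALSE)$p.value))
    }
    if (length(unique(c(a, b))) == 1L) return(1)
    N <- length(a) + length(b)
    if (N <= 25L) {
        r <- rank(c(a, b))
        ranks2 <- as.integer(round(2 * r))
        obs2 <- as.integer(round(2 * sum(r[seq_along(a)])))
        return(.exactRankSumP(ranks2, length(a), obs2))
    }
    suppressWarnings(wilcox.test(a, b, exact = FALSE)$p.value)
}
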