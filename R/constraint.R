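#' Sliding-window conservation profile around a site
#'
#' Slides windows of \code{window} bases across the region within
#' \code{flank} bases of the editing site and collects each window's score
#' distribution. Windows containing any masked or undefined base are
#' dropped (flanking regions falling into a disallowed genic context are
#' excluded through \code{mask}).
#'
#' @param track a \linkS4class{ConservationTrack}
#' @param contig contig of the site
#' @param site 1-based site position
#' @param window window size (default 30)
#' @param flank flanking extent on each side (default 60)
#' @param mask optional integer vector of masked (disallowed) positions on
#'   the contig
#' @return list of windows, each with \code{offset} (window start relative
#'   to the site) and \code{scores}; errors if the track does not cover the
#'   site.
#' @export
windowProfile <- function(track, contig, site, window = 30L, flank = 60L,
                          mask = NULL) {
    if (is.na(conservationAt(track, contig, site)))
        stop("site not covered by the conservation track")
    starts <- (site - flank):(site + flank - window + 1L)
    out <- list()
    for (s in starts) {
        pos <- s:(s + window - 1L)
        if (!is.null(mask) && any(pos %in% mask)) next
        v <- conservationAt(track, contig, pos)
        if (anyNA(v)) next
        out[[length(out) + 1L]] <- list(offset = s - site, scores = v)
    }
    out
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' D is the maximum absolute difference between the two empirical CDFs;
#' the p-value uses the asymptotic KS distribution (adequate at the sample
#' sizes arising here, 30-92 bases per region).
#'
#' @param x,y non-empty numeric samples
#' @return list with \code{D} and \code{p}
#' @export
ksTwoSample <- function(x, y) {
    stopifnot(length(x) > 0, length(y) > 0)
    kt <- suppressWarnings(ks.test(x, y, exact = FALSE))
    list(D = unname(kt$statistic), p = kt$p.value)
}

#' Classify editing sites by evolutionary constraint
#'
#' For each site the S region spans 15 bases upstream to 30 bases
#' downstream of the site (46 bases, transcribed-strand orientation) and
#' the F region is the two flanking 46-base intervals pooled. Sites with
#' mean conservation > 0.9 in both regions are \code{"high"}; of the rest,
#' sites whose S region is significantly more conserved than their F
#' region (two-sample KS, BH-corrected p < \code{alpha} across the batch,
#' with mean S > mean F) are \code{"moderate"}; the others are
#' \code{"none"}. Masked bases are excluded; a fully masked or uncovered S
#' region makes the site unevaluable.
#'
#' @param track a \linkS4class{ConservationTrack}
#' @param sites data.frame with columns \code{site_id, contig, pos} (or a
#'   GRanges from [readSiteTable()])
#' @param mask optional named list of masked position vectors per contig
#' @param alpha FDR level (default 0.05)
#' @param high_mean mean-conservation threshold for the high class
#'   (default 0.9)
#' @return data.frame with \code{site_id, class, mean_S, mean_F, KS_D,
#'   p_raw, p_fdr}
#' @export
classifyConstraint <- function(track, sites, mask = NULL, alpha = 0.05,
                               high_mean = 0.9) {
    if (is(sites, "GRanges")) {
        sites <- data.frame(site_id = S4Vectors::mcols(sites)$site_id,
                            contig = as.character(GenomicRanges::seqnames(sites)),
                            pos = GenomicRanges::start(sites),
                            stringsAsFactors = FALSE)
    }
    n <- nrow(sites)
    res <- data.frame(site_id = sites$site_id,
                      class = NA_character_, mean_S = NA_real_,
                      mean_F = NA_real_, KS_D = NA_real_,
                      p_raw = NA_real_, p_fdr = NA_real_,
                      stringsAsFactors = FALSE)
    Ss <- Fs <- vector("list", n)
    for (i in seq_len(n)) {
        ct <- sites$contig[i]; p0 <- sites$pos[i]
        spos <- (p0 - 15L):(p0 + 30L)
        fpos <- c((p0 - 15L - 46L):(p0 - 16L), (p0 + 31L):(p0 + 76L))
        mk <- if (is.null(mask)) integer() else mask[[ct]]
        spos <- setdiff(spos, mk); fpos <- setdiff(fpos, mk)
        sv <- conservationAt(track, ct, spos)
        fv <- conservationAt(track, ct, fpos)
        Ss[[i]] <- sv[!is.na(sv)]; Fs[[i]] <- fv[!is.na(fv)]
    }
    evaluable <- lengths(Ss) > 0 & lengths(Fs) > 0
    res$class[!evaluable] <- "unevaluable"
    res$mean_S[evaluable] <- vapply(Ss[evaluable], mean, 0)
    res$mean_F[evaluable] <- vapply(Fs[evaluable], mean, 0)
    high <- evaluable & res$mean_S > high_mean & res$mean_F > high_mean
    res$class[high] <- "high"
    test <- which(evaluable & !high)
    for (i in test) {
        kt <- ksTwoSample(Ss[[i]], Fs[[i]])
        res$KS_D[i] <- kt$D
        res$p_raw[i] <- kt$p
    }
    if (length(test)) {
        res$p_fdr[test] <- p.adjust(res$p_raw[test], "BH")
        res$class[test] <- ifelse(
            res$p_fdr[test] < alpha & res$mean_S[test] > res$mean_F[test],
            "moderate", "none")
    }
    res
}

#' Normalized conservation profile across windows
#'
#' Expresses each window of a [windowProfile()] as minus the KS D statistic
#' relative to the window with the highest conservation (largest mean
#' score), whose own value is 0.
#'
#' @param windows a list of windows from [windowProfile()]
#' @return data.frame with \code{offset} and \code{profile} (\code{-D}
#'   versus the best window)
#' @export
normalizedConservationProfile <- function(windows) {
    stopifnot(length(windows) > 0)
    means <- vapply(windows, function(w) mean(w$scores), 0)
    best <- which.max(means)
    prof <- vapply(seq_along(windows), function(i) {
        if (i == best) return(0)
        -ksTwoSample(windows[[i]]$scores, windows[[best]]$scores)$D
    }, 0)
    data.frame(offset = vapply(windows, `[[`, 0, "offset"), profile = prof)
}

#' Excess of constrained sites among edited versus lowly edited sites
#'
#' Estimates the fraction of editing events that are likely functional as
#' the difference between the fraction of constrained (highly or
#' moderately) sites among edited sites and among lowly edited (<
#' \code{low_cutoff}) sites, taking the latter as a neutral baseline; a
#' two-sided Fisher's exact test on the 2x2 counts supplies the p-value.
#'
#' @param constraint_class character vector of classes
#'   (\code{high/moderate/none}) per site
#' @param representative_level numeric vector of representative levels per
#'   site
#' @param low_cutoff the lowly edited threshold (default 0.015)
#' @return list with \code{excess} (difference of fractions),
#'   \code{frac_edited}, \code{frac_low}, \code{p} and the 2x2
#'   \code{table}; fractions are \code{NA} when a stratum is empty.
#' @export
functionalFraction <- function(constraint_class, representative_level,
                               low_cutoff = 0.015) {
    ok <- !is.na(constraint_class) & !is.na(representative_level) &
        constraint_class %in% c("high", "moderate", "none")
    cc <- constraint_class[ok]; lv <- representative_level[ok]
    constrained <- cc %in% c("high", "moderate")
    edited <- lv >= low_cutoff
    tab <- rbind(edited = c(constrained = sum(edited & constrained),
                            unconstrained = sum(edited & !constrained)),
                 low = c(sum(!edited & constrained),
                         sum(!edited & !constrained)))
    if (any(rowSums(tab) == 0))
        return(list(excess = NA_real_, frac_edited = NA_real_,
                    frac_low = NA_real_, p = NA_real_, table = tab))
    fe <- tab[1, 1] / sum(tab[1, ])
    fl <- tab[2, 1] / sum(tab[2, ])
    list(excess = fe - fl, frac_edited = fe, frac_low = fl,
         p = fisher.test(tab)$p.value, table = tab)
}
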