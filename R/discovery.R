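#' Call RNA variants from pileup counts
#'
#' Counts are pooled per site across samples and one call is emitted per
#' (site, mismatch type) whose alternative base is supported by at least
#' \code{min_alt} reads (counts are assumed to be post quality filtering,
#' base and mapping quality >= 20 upstream). Sites in bidirectionally
#' transcribed regions (overlapping sense/antisense gene pairs) are removed
#' regardless of their counts.
#'
#' @param pileup a pileup data.frame ([readPileup()])
#' @param min_alt minimum supporting reads for a call (default 2)
#' @param exclude_bidirectional character vector of site_ids lying in
#'   sense/antisense gene overlaps, to be discarded
#' @return data.frame with one row per call: \code{site_id, ref_base,
#'   alt_base, alt_reads, coverage, level} (level = alt_reads / coverage)
#' @export
callVariants <- function(pileup, min_alt = 2L, exclude_bidirectional = NULL) {
    if (!nrow(pileup)) {
        return(data.frame(site_id = character(), ref_base = character(),
                          alt_base = character(), alt_reads = integer(),
                          coverage = integer(), level = numeric()))
    }
    if (!is.null(exclude_bidirectional))
        pileup <- pileup[!(pileup$site_id %in% exclude_bidirectional), ,
                         drop = FALSE]
    agg <- stats::aggregate(pileup[, c("n_A", "n_C", "n_G", "n_T")],
                            by = list(site_id = pileup$site_id,
                                      ref_base = pileup$ref_base), sum)
    out <- list()
    bases <- c("A", "C", "G", "T")
    for (b in bases) {
        alt <- agg[[paste0("n_", b)]]
        keep <- agg$ref_base != b & alt >= min_alt
        if (!any(keep)) next
        cov <- rowSums(agg[keep, c("n_A", "n_C", "n_G", "n_T")])
        out[[b]] <- data.frame(site_id = agg$site_id[keep],
                               ref_base = agg$ref_base[keep],
                               alt_base = b, alt_reads = alt[keep],
                               coverage = cov, level = alt[keep] / cov,
                               stringsAsFactors = FALSE)
    }
    if (!length(out)) {
        return(data.frame(site_id = character(), ref_base = character(),
                          alt_base = character(), alt_reads = integer(),
                          coverage = integer(), level = numeric()))
    }
    res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
    res[order(res$site_id, res$alt_base), , drop = FALSE]
}

#' Choose the minimum frequency cutoff reaching an A-to-G fraction target
#'
#' Given counts of shared variants by mismatch type over a grid of minimum
#' level cutoffs, returns the smallest cutoff at which the fraction of
#' variants that are A-to-G reaches the target (80\% by default), along with
#' the whole fraction-versus-cutoff curve.
#'
#' @param curve data.frame with columns \code{cutoff}, \code{n_ag} (A-to-G
#'   variants passing the cutoff) and \code{n_total} (all variants passing)
#' @param target required A-to-G fraction (default 0.80)
#' @return list with \code{cutoff} (the selected minimum level),
#'   \code{fraction} at that cutoff and \code{curve} (input with an added
#'   \code{ag_fraction} column)
#' @export
selectFrequencyCutoff <- function(curve, target = 0.80) {
    stopifnot(all(c("cutoff", "n_ag", "n_total") %in% names(curve)))
    curve <- curve[order(curve$cutoff), , drop = FALSE]
    curve$ag_fraction <- ifelse(curve$n_total > 0,
                                curve$n_ag / curve$n_total, NA_real_)
    ok <- which(!is.na(curve$ag_fraction) & curve$ag_fraction >= target)
    if (!length(ok))
        stop(sprintf(
            "no cutoff reaches an A-to-G fraction of %.2f (best: %.3f)",
            target, max(curve$ag_fraction, na.rm = TRUE)))
    list(cutoff = curve$cutoff[ok[1]], fraction = curve$ag_fraction[ok[1]],
         curve = curve)
}

# Tabulate the shared-variant mismatch spectrum over a cutoff grid.
.sharedVariantCurve <- function(calls_a, calls_b, ortho, grid) {
    sh <- .sharedCalls(calls_a, calls_b, ortho)
    n_ag <- n_total <- integer(length(grid))
    for (i in seq_along(grid)) {
        pass <- sh$level_a >= grid[i] & sh$level_b >= grid[i]
        n_total[i] <- sum(pass)
        n_ag[i] <- sum(pass & sh$ref_base == "A" & sh$alt_base == "G")
    }
    data.frame(cutoff = grid, n_ag = n_ag, n_total = n_total)
}

# Join variant calls of two species through the orthology map. Calls are on
# the transcribed (sense) strand, so a strand-flipped mapping preserves the
# mismatch identity (an A-to-G stays A-to-G) and needs no recoding; a site
# whose orthologous position carries a different mismatch type is excluded
# with a message. Species-B calls are keyed by "contig:pos" when the
# orthology's coordinates are composite, or by plain site_id otherwise.
.sharedCalls <- function(calls_a, calls_b, ortho) {
    m <- merge(calls_a, ortho, by = "site_id")
    bkey <- paste0(m$contig_b, ":", m$pos_b)
    if (!any(bkey %in% calls_b$site_id) &&
        any(m$site_id %in% calls_b$site_id))
        bkey <- m$site_id
    idx <- match(paste(bkey, m$ref_base, m$alt_base),
                 paste(calls_b$site_id, calls_b$ref_base, calls_b$alt_base))
    found <- !is.na(idx)
    typeclash <- !found & bkey %in% calls_b$site_id
    if (any(typeclash))
        message(sum(typeclash),
                " site(s) map to a different mismatch type; excluded")
    data.frame(site_id = m$site_id[found],
               ref_base = m$ref_base[found], alt_base = m$alt_base[found],
               level_a = m$level[found], level_b = calls_b$level[idx[found]],
               stringsAsFactors = FALSE)
}

#' Identify editing sites shared between two species
#'
#' Variants called in both species at orthologous positions and at a level
#' at or above the frequency cutoff in each are retained; orthologous sites
#' are merged so each is counted once. When \code{cutoff} is \code{NULL} it
#' is chosen with [selectFrequencyCutoff()] over \code{grid} so the A-to-G
#' fraction of the shared set reaches \code{target}.
#'
#' @param calls_a,calls_b variant-call tables from [callVariants()]; species
#'   B call \code{site_id}s must match the orthology's
#'   \code{contig_b:pos_b} key or its \code{site_id}s
#' @param ortho orthology map ([readOrthology()])
#' @param cutoff minimum level in both species, or \code{NULL} to select
#' @param grid cutoff grid used when selecting
#' @param target A-to-G fraction target used when selecting
#' @return list with \code{sites} (data.frame of shared A-to-G sites with
#'   levels in both species), \code{cutoff} used, and \code{curve} (the
#'   fraction-vs-cutoff table)
#' @export
identifySharedEditing <- function(calls_a, calls_b, ortho, cutoff = NULL,
                                  grid = c(0.01, 0.015, 0.02, 0.03, 0.05,
                                           0.10, 0.15, 0.20),
                                  target = 0.80) {
    curve <- .sharedVariantCurve(calls_a, calls_b, ortho, grid)
    if (is.null(cutoff)) {
        sel <- selectFrequencyCutoff(curve, target)
        cutoff <- sel$cutoff
    }
    sh <- .sharedCalls(calls_a, calls_b, ortho)
    keep <- sh$level_a >= cutoff & sh$level_b >= cutoff &
        sh$ref_base == "A" & sh$alt_base == "G"
    sites <- sh[keep, , drop = FALSE]
    sites <- sites[!duplicated(sites$site_id), , drop = FALSE]
    list(sites = sites, cutoff = cutoff,
         curve = within(curve, ag_fraction <- ifelse(n_total > 0,
                                                     n_ag / n_total, NA)))
}

#' Validate candidate sites against an ADAR-null sample
#'
#' Candidate sites are those edited in the wild type (more than two altered
#' reads and level >= 1.5\%). A candidate with zero altered reads in the
#' ADAR-null sample is genuine outright; otherwise a two-sided Fisher's
#' exact test compares the A-to-G occurrences between wild type and null,
#' p-values are Benjamini-Hochberg corrected, and adjusted p < alpha calls
#' the site genuine. The estimated false-discovery rate is the fraction of
#' candidates not called genuine; candidates without null-sample coverage
#' are reported unevaluable and excluded from the denominator.
#'
#' @param wt,null pileup data.frames for the wild-type and ADAR-null sample
#'   (single sample each; ref base A sites are used)
#' @param alpha significance level after correction (default 0.05)
#' @param min_alt_reads candidate support threshold (default 3, i.e. more
#'   than two altered reads)
#' @param min_level candidate level threshold (default 0.015)
#' @return list with \code{sites} (per-candidate table: counts, p, adjusted
#'   p, status in \{genuine, rejected, unevaluable\}) and \code{fdr}
#' @export
estimateFdrWithNull <- function(wt, null, alpha = 0.05,
                                min_alt_reads = 3L, min_level = 0.015) {
    wt <- wt[wt$ref_base == "A", , drop = FALSE]
    level <- with(wt, ifelse(n_A + n_G > 0, n_G / (n_A + n_G), 0))
    cand <- wt[wt$n_G >= min_alt_reads & level >= min_level, , drop = FALSE]
    if (!nrow(cand))
        return(list(sites = data.frame(), fdr = NA_real_))
    nm <- match(cand$site_id, null$site_id)
    nullcov <- ifelse(is.na(nm), 0L, null$coverage[nm])
    res <- data.frame(site_id = cand$site_id,
                      g_wt = cand$n_G, a_wt = cand$n_A,
                      g_null = ifelse(is.na(nm), NA_integer_, null$n_G[nm]),
                      a_null = ifelse(is.na(nm), NA_integer_, null$n_A[nm]),
                      p = NA_real_, p_adj = NA_real_,
                      status = NA_character_, stringsAsFactors = FALSE)
    unev <- is.na(nm) | nullcov == 0L
    res$status[unev] <- "unevaluable"
    clean <- !unev & res$g_null == 0L
    res$status[clean] <- "genuine"
    test <- which(!unev & res$g_null > 0L)
    for (i in test) {
        tab <- matrix(c(res$g_wt[i], res$a_wt[i],
                        res$g_null[i], res$a_null[i]), 2, byrow = TRUE)
        res$p[i] <- fisher.test(tab)$p.value
    }
    if (length(test)) {
        res$p_adj[test] <- p.adjust(res$p[test], "BH")
        res$status[test] <- ifelse(res$p_adj[test] < alpha,
                                   "genuine", "rejected")
    }
    denom <- sum(!unev)
    fdr <- if (denom) sum(res$status == "rejected") / denom else NA_real_
    list(sites = res, fdr = fdr)
}

#' Quantify editing levels from pileups
#'
#' The editing level is G/(A+G) on the transcribed strand. Entries with
#' total coverage below \code{min_cov} are undefined (\code{NA}). A site
#' whose DNA base is not A is defined as having an editing level of 0 and
#' flagged.
#'
#' @param pileup a pileup data.frame
#' @param min_cov minimum read coverage (20 for RNA-seq, 50 for mmPCR-seq)
#' @param dna_base optional named character vector, DNA base per site_id
#'   (defaults to A everywhere)
#' @param platform platform label recorded in the result
#' @return a \linkS4class{LevelMatrix} (sites x samples); the non-A flag is
#'   in \code{rowData(x)$non_a}
#' @export
quantifyLevels <- function(pileup, min_cov = 20L, dna_base = NULL,
                           platform = "rnaseq") {
    sites <- sort(unique(pileup$site_id))
    samples <- sort(unique(pileup$sample_id))
    lev <- cov <- matrix(NA_real_, length(sites), length(samples),
                         dimnames = list(sites, samples))
    i <- match(pileup$site_id, sites)
    j <- match(pileup$sample_id, samples)
    cov[cbind(i, j)] <- pileup$coverage
    ag <- pileup$n_A + pileup$n_G
    lev[cbind(i, j)] <- ifelse(ag > 0, pileup$n_G / ag, NA_real_)
    lev[!is.na(cov) & cov < min_cov] <- NA_real_
    non_a <- rep(FALSE, length(sites))
    if (!is.null(dna_base)) {
        non_a <- dna_base[sites] != "A" & !is.na(dna_base[sites])
        lev[non_a, ] <- ifelse(is.na(cov[non_a, , drop = FALSE]), NA_real_, 0)
    }
    out <- LevelMatrix(lev, cov, platform)
    SummarizedExperiment::rowData(out)$non_a <- unname(non_a)
    out
}

#' Combine RNA-seq and mmPCR-seq level measurements
#'
#' mmPCR-seq entries are kept only where both biological replicates have
#' coverage >= \code{min_cov_mmpcr} and their levels differ by at most
#' \code{max_rep_diff}; the combined value is the replicate mean. Where both
#' platforms provide a value, the mmPCR-seq measurement wins. Provenance is
#' recorded per entry in the \code{platform} assay.
#'
#' @param rnaseq a \linkS4class{LevelMatrix} of RNA-seq levels
#' @param mmpcr_rep1,mmpcr_rep2 LevelMatrix objects for the two mmPCR-seq
#'   replicates, with the same column (sample) names as each other
#' @param min_cov_mmpcr replicate coverage requirement (default 50)
#' @param max_rep_diff maximum replicate level difference (default 0.10)
#' @return a combined \linkS4class{LevelMatrix} over the union of sites and
#'   the RNA-seq samples
#' @export
combinePlatforms <- function(rnaseq, mmpcr_rep1, mmpcr_rep2,
                             min_cov_mmpcr = 50L, max_rep_diff = 0.10) {
    stopifnot(identical(colnames(mmpcr_rep1), colnames(mmpcr_rep2)))
    sites <- union(rownames(rnaseq), rownames(mmpcr_rep1))
    samples <- colnames(rnaseq)
    lev <- cov <- matrix(NA_real_, length(sites), length(samples),
                         dimnames = list(sites, samples))
    pf <- matrix(NA_character_, length(sites), length(samples),
                 dimnames = list(sites, samples))
    ri <- match(rownames(rnaseq), sites)
    lev[ri, ] <- editingLevels(rnaseq)
    cov[ri, ] <- coverages(rnaseq)
    pf[ri, ][!is.na(editingLevels(rnaseq))] <- "rnaseq"
    common <- intersect(samples, colnames(mmpcr_rep1))
    l1 <- editingLevels(mmpcr_rep1); l2 <- editingLevels(mmpcr_rep2)
    c1 <- coverages(mmpcr_rep1); c2 <- coverages(mmpcr_rep2)
    mi <- match(rownames(mmpcr_rep1), sites)
    for (s in common) {
        ok <- !is.na(l1[, s]) & !is.na(l2[, s]) &
            c1[, s] >= min_cov_mmpcr & c2[, s] >= min_cov_mmpcr &
            abs(l1[, s] - l2[, s]) <= max_rep_diff
        if (!any(ok)) next
        lev[mi[ok], s] <- (l1[ok, s] + l2[ok, s]) / 2
        cov[mi[ok], s] <- pmin(c1[ok, s], c2[ok, s])
        pf[mi[ok], s] <- "mmpcr"
    }
    LevelMatrix(lev, cov, pf)
}

#' Representative editing level per site
#'
#' The maximal editing level across all samples/datasets (entries with
#' coverage >= \code{min_cov}) is used as a site's representative level.
#'
#' @param levels a \linkS4class{LevelMatrix} over many datasets
#' @param min_cov coverage requirement per entry (default 20)
#' @return named numeric vector, \code{NA} where no entry qualifies
#' @export
representativeLevel <- function(levels, min_cov = 20L) {
    lv <- editingLevels(levels)
    cv <- coverages(levels)
    lv[!is.na(cv) & cv < min_cov] <- NA_real_
    apply(lv, 1, function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE))
}
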