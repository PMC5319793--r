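# Duplex (editing stem / ECS) prediction via banded complementarity search.
#
# Candidate stems are found by enumerating maximal runs of consecutive
# complementary base pairs (Watson-Crick plus G:U wobble) along the
# anti-diagonals of the window's self-pairing matrix, then chaining runs
# separated by small bulges with a dynamic program that maximizes the
# number of paired bases. This replaces a thermodynamic folder with the
# only properties the downstream analyses consume: the base-pair list, the
# pass/fail stem filters, and the 8 structural features. The minimum
# hairpin loop is enforced during the search, not after it.

# 4x4 lookup of pairable bases (A,C,G,U codes 1..4): Watson-Crick + G:U
.PAIRTAB <- local({
    M <- matrix(FALSE, 4, 4)
    ok <- rbind(c(1, 4), c(4, 1), c(2, 3), c(3, 2), c(3, 4), c(4, 3))
    M[ok] <- TRUE
    M
})

# Maximal complementary runs between positions of `x` (self mode) or
# between `x` and a second region `y` (cross mode, antiparallel). A run is
# a set of consecutive pairs (i, j), (i+1, j-1), ... all complementary;
# runs live on anti-diagonals (constant i + j).
.complementRuns <- function(xc, yc = NULL, min_loop = 4L, min_run = 5L) {
    cx <- match(xc, .RNA)
    cy <- if (is.null(yc)) cx else match(yc, .RNA)
    n <- length(cx); m <- length(cy)
    runs <- vector("list", 256)
    nr <- 0L
    ccs <- if (is.null(yc)) (min_loop + 3L):(2L * n - min_loop - 1L)
           else 2L:(n + m)
    for (cc in ccs) {
        lo <- max(1L, cc - m)
        hi <- if (is.null(yc)) (cc - min_loop - 1L) %/% 2L
              else min(n, cc - 1L)
        if (lo > hi) next
        i <- lo:hi
        a <- cx[i]; b <- cy[cc - i]
        ok <- !is.na(a) & !is.na(b) & .PAIRTAB[cbind(a, b)]
        r <- rle(ok)
        hits <- r$values & r$lengths >= min_run
        if (!any(hits)) next
        ends <- cumsum(r$lengths)
        for (k in which(hits)) {
            ie <- i[ends[k]]; is <- ie - r$lengths[k] + 1L
            nr <- nr + 1L
            if (nr > length(runs)) runs <- c(runs, vector("list", length(runs)))
            runs[[nr]] <- c(is, ie, cc - ie, cc - is, r$lengths[k])
        }
    }
    if (!nr) return(NULL)
    out <- do.call(rbind, runs[seq_len(nr)])
    colnames(out) <- c("is", "ie", "js", "je", "len")
    out
}

# Chain complementary runs into stems. Consecutive runs may be separated
# by a bulge/internal loop of at most `max_gap` unpaired bases per side;
# each junction pays an affine penalty (gap_open + gap_ext per skipped
# base on the larger side), so gluing a short chance run onto a stem never
# profits, while genuine bulged continuations do. The chain maximizing
# the alignment-style score (2 per pair minus penalties) wins; `pairs`
# reports its paired-base count.
.chainRuns <- function(runs, max_gap = 12L, gap_open = 12, gap_ext = 4) {
    o <- order(runs[, "is"], runs[, "je"])
    runs <- runs[o, , drop = FALSE]
    R <- nrow(runs)
    is <- runs[, "is"]; ie <- runs[, "ie"]
    js <- runs[, "js"]; je <- runs[, "je"]; len <- runs[, "len"]
    dp <- 2 * len
    parent <- rep(NA_integer_, R)
    for (r in seq_len(R)) {
        gi <- is[r] - ie - 1L
        gj <- js - je[r] - 1L
        ok <- which(gi >= 0L & gj >= 0L & gi <= max_gap & gj <= max_gap)
        if (length(ok)) {
            gain <- dp[ok] - gap_open - gap_ext * pmax(gi[ok], gj[ok])
            q <- which.max(gain)
            if (gain[q] > 0) {
                dp[r] <- 2 * len[r] + gain[q]
                parent[r] <- ok[q]
            }
        }
    }
    best <- which.max(dp)
    chain <- integer()
    b <- best
    while (!is.na(b)) {
        chain <- c(b, chain)
        b <- parent[b]
    }
    list(rows = chain, pairs = sum(len[chain]), score = dp[best],
         runs = runs)
}

.chainToDuplex <- function(runs, rows, xc, yc = NULL, joffset = 0L) {
    pr <- list(); ty <- character()
    for (r in rows) {
        i <- runs[r, "is"]:runs[r, "ie"]
        jj <- rev(runs[r, "js"]:runs[r, "je"])   # j decreases as i increases
        if (is.null(yc)) pr[[length(pr) + 1L]] <- cbind(i, jj)
        else pr[[length(pr) + 1L]] <- cbind(i, jj + joffset)
        b2 <- if (is.null(yc)) xc[jj] else yc[jj]
        ty <- c(ty, .pairType(xc[i], b2))
    }
    p <- do.call(rbind, pr)
    DuplexStructure(cbind(pmin(p[, 1], p[, 2]), pmax(p[, 1], p[, 2])), ty)
}

#' Predict candidate editing stems around a site
#'
#' Folds the region within \code{half_window} bases of the editing site by
#' a banded complementarity search: maximal runs of consecutive
#' complementary base pairs (Watson-Crick plus G:U wobble) are enumerated
#' along the anti-diagonals of the window's self-pairing matrix and chained
#' across bulges of at most \code{max_gap} bases per side, maximizing the
#' paired-base count. Up to \code{max_candidates} non-overlapping
#' candidates are returned, best (most paired bases) first.
#'
#' @param sequence the transcribed-strand sequence (character, RNAString or
#'   DNA input; T is converted to U)
#' @param site_index 1-based position of the edited A within \code{sequence}
#' @param half_window search radius (default 200, clipped at sequence ends)
#' @param min_loop minimum hairpin loop: pairs closer than this are never
#'   formed (default 4)
#' @param min_run minimum complementary run length used as a chain anchor
#'   (default 5)
#' @param max_gap largest bulge the chainer may bridge, per side
#'   (default 12; the ECS filter later demands at most 8)
#' @param max_candidates maximum stems returned
#' @return list of \linkS4class{DuplexStructure} (possibly empty), pair
#'   coordinates relative to \code{sequence}
#' @export
foldWindow <- function(sequence, site_index, half_window = 200L,
                       min_loop = 4L, min_run = 5L, max_gap = 12L,
                       max_candidates = 3L) {
    x <- .toRna(sequence)
    n <- nchar(x)
    if (site_index < 1L || site_index > n) stop("site outside sequence")
    ws <- max(1L, site_index - half_window)
    we <- min(n, site_index + half_window)
    if (we - ws + 1L < 40L) {
        warning("window shorter than 40 nt; no candidates")
        return(list())
    }
    xc <- strsplit(substr(x, ws, we), "")[[1]]
    runs <- .complementRuns(xc, min_loop = min_loop, min_run = min_run)
    out <- list()
    while (!is.null(runs) && nrow(runs) && length(out) < max_candidates) {
        ch <- .chainRuns(runs, max_gap = max_gap)
        if (ch$pairs < 5L) break
        d <- .chainToDuplex(ch$runs, ch$rows, xc)
        out[[length(out) + 1L]] <- DuplexStructure(d@pairs + (ws - 1L),
                                                   d@pairType)
        # drop runs overlapping the found stem before searching again
        used <- unlist(lapply(ch$rows, function(r)
            c(ch$runs[r, "is"]:ch$runs[r, "ie"],
              ch$runs[r, "js"]:ch$runs[r, "je"])))
        runs <- ch$runs
        hit <- vapply(seq_len(nrow(runs)), function(r)
            any(c(runs[r, "is"]:runs[r, "ie"],
                  runs[r, "js"]:runs[r, "je"]) %in% used), TRUE)
        runs <- runs[!hit, , drop = FALSE]
    }
    out[order(-vapply(out, nPaired, 0L))]
}

# longest run of unpaired bases strictly inside the stem, per arm side
.maxBulge <- function(duplex) {
    p <- duplexPairs(duplex)
    if (!nrow(p)) return(0L)
    runmax <- function(pos) {
        pos <- sort(pos)
        if (length(pos) < 2L) return(0L)
        max(diff(pos) - 1L)
    }
    max(runmax(p[, 1]), runmax(p[, 2]))
}

#' Filter stem candidates to an editing complementary sequence
#'
#' Keeps the best candidate (most paired bases) that covers the editing
#' site and passes the stem filters: at least \code{min_paired} bases
#' paired and a maximum bulge (longest unpaired run inside the stem, on
#' either side) of \code{max_bulge}.
#'
#' @param candidates list of \linkS4class{DuplexStructure} from
#'   [foldWindow()]
#' @param site 1-based editing-site position (same coordinates as the
#'   candidates)
#' @param min_paired minimum paired bases (default 20)
#' @param max_bulge maximum bulge size (default 8)
#' @return a \linkS4class{DuplexStructure} or \code{NULL}
#' @export
findProximalEcs <- function(candidates, site, min_paired = 20L,
                            max_bulge = 8L) {
    best <- NULL
    for (d in candidates) {
        if (nPaired(d) < min_paired) next
        if (.maxBulge(d) > max_bulge) next
        a <- armRanges(d)
        covers <- (site >= a$first[1] && site <= a$first[2]) ||
                  (site >= a$second[1] && site <= a$second[2])
        if (!covers) next
        if (is.null(best) || nPaired(d) > nPaired(best)) best <- d
    }
    best
}

#' Smooth a conservation track with a centred moving average
#'
#' Positions within half a window of a block edge (or of an undefined gap)
#' use the truncated window: the mean is taken over the defined values
#' actually present in the window.
#'
#' @param track a \linkS4class{ConservationTrack}
#' @param window odd window size in bases (default 51)
#' @return a smoothed \linkS4class{ConservationTrack}
#' @export
smoothConservation <- function(track, window = 51L) {
    if (window %% 2L == 0L) stop("window must be odd")
    h <- (window - 1L) %/% 2L
    scores <- lapply(track@scores, function(v) {
        n <- length(v)
        def <- !is.na(v)
        vz <- ifelse(def, v, 0)
        cs <- cumsum(c(0, vz))
        cn <- cumsum(c(0, as.numeric(def)))
        lo <- pmax(seq_len(n) - h, 1L)
        hi <- pmin(seq_len(n) + h, n)
        s <- cs[hi + 1L] - cs[lo]
        k <- cn[hi + 1L] - cn[lo]
        out <- ifelse(k > 0, s / k, NA_real_)
        out[!def] <- NA_real_
        out
    })
    ConservationTrack(scores, track@offsets)
}

#' Search for a distal (intronic) editing complementary sequence
#'
#' Scans the smoothed conservation track for conserved blocks (length >=
#' \code{min_len}, smoothed score >= \code{min_score}) within
#' \code{max_dist} bases of the editing site, folds each block against the
#' site-anchored segment, and applies the same stem filters as the proximal
#' search.
#'
#' @param sequence the transcribed-strand sequence containing site and
#'   candidate regions
#' @param smoothed a smoothed \linkS4class{ConservationTrack}
#'   ([smoothConservation()])
#' @param contig contig name of \code{sequence} within the track
#' @param site 1-based editing-site position
#' @param max_dist maximum distance to the block (default 2500)
#' @param min_len minimum block length (default 20)
#' @param min_score minimum smoothed conservation (default 0.90)
#' @param arm_half,min_paired,max_bulge as in [foldWindow()] /
#'   [findProximalEcs()]
#' @return a \linkS4class{DuplexStructure} or \code{NULL}
#' @export
findDistalEcs <- function(sequence, smoothed, contig, site,
                          max_dist = 2500L, min_len = 20L, min_score = 0.90,
                          arm_half = 60L, min_paired = 20L, max_bulge = 8L) {
    x <- .toRna(sequence)
    n <- nchar(x)
    lo <- max(1L, site - max_dist)
    hi <- min(n, site + max_dist)
    sc <- conservationAt(smoothed, contig, lo:hi)
    if (all(is.na(sc))) {
        message("no track coverage near the site; no distal ECS")
        return(NULL)
    }
    ok <- !is.na(sc) & sc >= min_score
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    best <- NULL
    ps <- max(1L, site - arm_half)
    pe <- min(n, site + arm_half)
    for (b in which(r$values & r$lengths >= min_len)) {
        bs <- lo + starts[b] - 1L
        be <- lo + ends[b] - 1L
        if (be >= ps && bs <= pe) next     # the site's own segment
        pc <- strsplit(substr(x, ps, pe), "")[[1]]
        bc <- strsplit(substr(x, bs, be), "")[[1]]
        runs <- .complementRuns(pc, bc)
        if (is.null(runs)) next
        ch <- .chainRuns(runs)
        if (ch$pairs < 5L) next
        d <- .chainToDuplex(ch$runs, ch$rows, pc, bc, joffset = bs - 1L)
        # lift the pattern arm into sequence coordinates
        p <- duplexPairs(d)
        p[, 1] <- p[, 1] + ps - 1L
        d <- DuplexStructure(p, d@pairType)
        # pairs: first column in site segment, second within the block;
        # enforce first < second ordering used by DuplexStructure
        if (nPaired(d) < min_paired || .maxBulge(d) > max_bulge) next
        a <- armRanges(d)
        covers <- (site >= a$first[1] && site <= a$first[2]) ||
                  (site >= a$second[1] && site <= a$second[2])
        if (!covers) next
        if (is.null(best) || nPaired(d) > nPaired(best)) best <- d
    }
    best
}
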