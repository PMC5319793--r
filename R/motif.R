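#' Build the ADAR triplet motif weight matrix
#'
#' The matrix is deduced from the nucleotide triplets (editing site plus its
#' immediately adjacent nucleotides) of highly edited sites (level >= 50\%).
#' Position-wise frequencies receive an additive pseudocount; the centre
#' position is fixed to A and the background is uniform.
#'
#' @param triplets character vector of RNA triplets (e.g. \code{"UAG"});
#'   DNA input (T) is accepted and converted
#' @param pseudocount additive smoothing constant (default 0.5; must be > 0
#'   for the log-odds scoring downstream)
#' @return a \linkS4class{MotifMatrix}
#' @examples
#' m <- buildMotifMatrix(c("UAG", "UAG", "AAG"), pseudocount = 0.5)
#' motifProbs(m)
#' @export
buildMotifMatrix <- function(triplets, pseudocount = 0.5) {
    triplets <- .toRna(triplets)
    if (!length(triplets)) stop("at least one triplet is required")
    if (any(nchar(triplets) != 3L)) stop("triplets must have length 3")
    b <- do.call(rbind, strsplit(triplets, ""))
    if (any(b[, 2] != "A"))
        stop("triplet centre must be A (the edited adenosine)")
    counts <- cbind(m1 = table(factor(b[, 1], levels = .RNA)),
                    p1 = table(factor(b[, 3], levels = .RNA)))
    probs <- sweep(counts + pseudocount, 2,
                   colSums(counts + pseudocount), "/")
    probs <- matrix(probs, 4, 2, dimnames = list(.RNA, c("m1", "p1")))
    new("MotifMatrix", probs = probs, pseudocount = pseudocount)
}

#' Average motif matrices across species
#'
#' Arithmetic mean of per-species position probabilities, renormalized.
#' Motif matrices are essentially identical across species, so downstream
#' scoring uses this shared average matrix.
#'
#' @param matrices list of \linkS4class{MotifMatrix} objects
#' @return a \linkS4class{MotifMatrix}
#' @export
averageMotifMatrix <- function(matrices) {
    stopifnot(length(matrices) >= 1L)
    p <- Reduce(`+`, lapply(matrices, motifProbs)) / length(matrices)
    p <- sweep(p, 2, colSums(p), "/")
    new("MotifMatrix", probs = p,
        pseudocount = mean(vapply(matrices, function(m) m@pseudocount, 0)))
}

#' Score the 16 possible editing triplets
#'
#' Raw scores are log-odds against a uniform background summed over the -1
#' and +1 positions, then affinely rescaled so the worst triplet maps to 0
#' and the best to 10. A degenerate matrix (all 16 raw scores equal) yields
#' all-zero scaled scores with \code{degenerate = TRUE}.
#'
#' @param matrix a \linkS4class{MotifMatrix}
#' @return data.frame with \code{triplet}, \code{raw} (log2 odds) and
#'   \code{scaled} (0-10); attribute \code{degenerate} flags a zero score
#'   range.
#' @export
scoreTriplets <- function(matrix) {
    p <- motifProbs(matrix)
    if (matrix@pseudocount <= 0 && any(p == 0))
        stop("zero probabilities without a pseudocount give infinite scores; ",
             "rebuild the matrix with pseudocount > 0")
    grid <- expand.grid(m1 = .RNA, p1 = .RNA, stringsAsFactors = FALSE)
    raw <- log2(p[grid$m1, "m1"] / 0.25) + log2(p[grid$p1, "p1"] / 0.25)
    rng <- range(raw)
    degenerate <- diff(rng) < 1e-12
    scaled <- if (degenerate) rep(0, length(raw))
              else (raw - rng[1]) / diff(rng) * 10
    out <- data.frame(triplet = paste0(grid$m1, "A", grid$p1),
                      raw = unname(raw), scaled = unname(scaled),
                      stringsAsFactors = FALSE)
    attr(out, "degenerate") <- degenerate
    out
}

#' Look up the scaled score of triplets
#'
#' @param triplets character vector of triplets
#' @param scores a score table from [scoreTriplets()]
#' @return numeric vector of scaled scores
#' @export
tripletScore <- function(triplets, scores) {
    scores$scaled[match(.toRna(triplets), scores$triplet)]
}

#' Classify a cross-species site pair as Presence/Absence or
#' Presence/Presence
#'
#' Presence requires an editing level of at least 10\% in at least one
#' dataset; absence requires at most 1.5\% in all datasets with a
#' measurement. Pairs where the anchor species shows presence and the other
#' absence are \code{"presence_absence"}; presence in both is
#' \code{"presence_presence"}; anything else is \code{"other"}.
#'
#' @param levels_anchor,levels_other numeric vectors of per-dataset levels
#'   (NA = no measurement); at least one measurement required in each
#' @param presence_level,absence_level thresholds (defaults 0.10 / 0.015)
#' @return one of \code{"presence_absence"}, \code{"presence_presence"},
#'   \code{"other"}
#' @export
classifySitePair <- function(levels_anchor, levels_other,
                             presence_level = 0.10, absence_level = 0.015) {
    la <- levels_anchor[!is.na(levels_anchor)]
    lo <- levels_other[!is.na(levels_other)]
    if (!length(la) || !length(lo))
        stop("at least one measurement is required in each species")
    anchor_presence <- any(la >= presence_level)
    other_presence <- any(lo >= presence_level)
    other_absence <- all(lo <= absence_level)
    if (anchor_presence && other_absence) "presence_absence"
    else if (anchor_presence && other_presence) "presence_presence"
    else "other"
}

#' Exact binomial test against the sequencing error rate
#'
#' One-sided upper-tail probability that at least \code{alt_reads} of
#' \code{coverage} reads carry the alternative base when the true rate is
#' the typical A-to-G sequencing error rate (1\%). Used to ask whether an
#' "absent" site shows any evidence of editing above error.
#'
#' @param alt_reads alternative-base read count
#' @param coverage total reads (0 gives \code{NA})
#' @param error_rate assumed error rate (default 0.01)
#' @return p-value, \code{P(X >= alt_reads | n = coverage, p = error_rate)}
#' @export
binomialErrorTest <- function(alt_reads, coverage, error_rate = 0.01) {
    stopifnot(all(alt_reads >= 0 & alt_reads <= coverage, na.rm = TRUE))
    ifelse(coverage == 0, NA_real_,
           pbinom(alt_reads - 1, coverage, error_rate, lower.tail = FALSE))
}

#' Test for motif-score asymmetry between species
#'
#' Among Presence/Absence pairs, counts how often the triplet motif score is
#' higher in the anchor (edited) species than in the other (unedited)
#' species; ties are excluded and the differing pairs are tested against a
#' symmetric 50/50 split with a two-sided exact binomial test. Scores should
#' come from the shared average motif matrix.
#'
#' @param score_anchor,score_other numeric vectors of triplet scores per
#'   site pair
#' @return list with \code{frac_higher_anchor} and \code{frac_higher_other}
#'   (fractions over all pairs), \code{n_differing}, and \code{p} (NA when
#'   no pair differs)
#' @export
motifAsymmetryTest <- function(score_anchor, score_other) {
    stopifnot(length(score_anchor) == length(score_other))
    d <- score_anchor - score_other
    d <- d[!is.na(d)]
    n <- length(d)
    hi_a <- sum(d > 0); hi_o <- sum(d < 0)
    if (hi_a + hi_o == 0)
        return(list(frac_higher_anchor = 0, frac_higher_other = 0,
                    n_differing = 0L, p = NA_real_))
    p <- binom.test(hi_a, hi_a + hi_o, 0.5)$p.value
    list(frac_higher_anchor = if (n) hi_a / n else 0,
         frac_higher_other = if (n) hi_o / n else 0,
         n_differing = hi_a + hi_o, p = p)
}
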