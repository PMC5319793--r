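# Nearest-neighbour duplex energy model.
#
# Stacking free energies (kcal/mol, 37 C) for adjacent base pairs, indexed
# as stack[p1, p2] where p1 is the 5'-adjacent pair on the editing-side
# strand and a pair "XY" means X on that strand paired to Y. Watson-Crick
# values follow the standard nearest-neighbour set; wobble-containing
# stacks use representative values. Absolute energies are not comparable to
# a full thermodynamic folder; only orderings and filter outcomes are used
# downstream.

.PAIRS6 <- c("AU", "UA", "CG", "GC", "GU", "UG")

.stackTable <- local({
    S <- matrix(NA_real_, 6, 6, dimnames = list(.PAIRS6, .PAIRS6))
    put <- function(p1, p2, v) {
        S[p1, p2] <<- v
        # the same stack read from the opposite strand
        flip <- function(p) paste0(substr(p, 2, 2), substr(p, 1, 1))
        S[flip(p2), flip(p1)] <<- v
    }
    put("AU", "AU", -0.93); put("AU", "UA", -1.10); put("UA", "AU", -1.33)
    put("CG", "UA", -2.08); put("CG", "AU", -2.11); put("GC", "UA", -2.24)
    put("GC", "AU", -2.35); put("CG", "GC", -2.36); put("GC", "GC", -3.26)
    put("GC", "CG", -3.42)
    put("AU", "GC", -2.24); put("AU", "CG", -2.08); put("UA", "GC", -2.35)
    put("UA", "CG", -2.11); put("CG", "CG", -3.26); put("UA", "UA", -0.93)
    for (p1 in .PAIRS6) for (p2 in .PAIRS6) {
        if (is.na(S[p1, p2])) S[p1, p2] <- -1.0   # wobble-containing stacks
    }
    S["GU", "UG"] <- S["UG", "GU"] <- -0.5
    S
})

# length-dependent bulge / internal-loop penalty (kcal/mol)
.loopPenalty <- function(len) 3.2 + 1.1 * log(len)

#' Free energy of a fixed duplex pairing
#'
#' Evaluates the given base-pair list with a nearest-neighbour stacking
#' model: adjacent pairs contribute a stacking term, and every bulge or
#' internal loop between consecutive pairs contributes a length-dependent
#' penalty. G:U wobble pairs are allowed. When the stem joins an editing
#' segment to a distal complementary region, the two segments are treated
#' as joined by a 100-adenosine linker that contributes no pairs (so only
#' the listed pairs matter). The helix-initiation constant is omitted so
#' that any paired duplex has non-positive energy; the result is clamped at
#' 0.
#'
#' @param duplex a \linkS4class{DuplexStructure}
#' @param sequence the sequence the pair coordinates refer to
#' @return energy in kcal/mol (<= 0; 0 for an empty duplex)
#' @examples
#' s <- paste0(strrep("G", 10), strrep("A", 8), strrep("C", 10))
#' d <- DuplexStructure(cbind(1:10, 28:19), rep("WC", 10))
#' freeEnergy(d, s)
#' @export
freeEnergy <- function(duplex, sequence) {
    p <- duplexPairs(duplex)
    if (!nrow(p)) return(0)
    x <- strsplit(.toRna(sequence), "")[[1]]
    o <- order(p[, 1])
    p <- p[o, , drop = FALSE]
    pr <- paste0(x[p[, 1]], x[p[, 2]])
    bad <- !(pr %in% .PAIRS6)
    if (any(bad))
        stop("pair ", which(bad)[1], " (", pr[bad][1],
             ") is not a valid RNA base pair")
    e <- 0
    for (r in seq_len(nrow(p) - 1L)) {
        li <- p[r + 1L, 1] - p[r, 1] - 1L
        lj <- p[r, 2] - p[r + 1L, 2] - 1L
        if (li == 0L && lj == 0L) {
            e <- e + .stackTable[pr[r], pr[r + 1L]]
        } else {
            e <- e + .loopPenalty(li + lj)
        }
    }
    min(e, 0)
}

#' Extract the 8 structural features of an editing stem
#'
#' The features are: free energy; stem length (bases spanned by the
#' outermost pairs on the editing side); max bulge (longest unpaired run
#' inside the stem on either side); percent of the stem that is base
#' paired; distance from the editing site to the closest stem edge (along
#' the editing side); number of paired bases in the entire stem; and,
#' separately, the numbers of paired bases downstream and upstream of the
#' editing site within the stem.
#'
#' @param duplex a \linkS4class{DuplexStructure}
#' @param site 1-based editing-site position; must lie within the stem
#'   (otherwise the edge distance is undefined and an error is raised)
#' @param sequence the folded sequence (for the energy term)
#' @return one-row data.frame with columns \code{free_energy, stem_length,
#'   max_bulge, pct_paired, dist_to_edge, paired_total, paired_downstream,
#'   paired_upstream}
#' @export
extractFeatures <- function(duplex, site, sequence) {
    p <- duplexPairs(duplex)
    if (!nrow(p)) stop("empty duplex")
    a <- armRanges(duplex)
    onFirst <- site >= a$first[1] && site <= a$first[2]
    onSecond <- site >= a$second[1] && site <= a$second[2]
    if (!onFirst && !onSecond)
        stop("editing site lies outside the stem; distance to edge undefined")
    edit_pos <- if (onFirst) p[, 1] else p[, 2]
    span <- if (onFirst) a$first else a$second
    stem_length <- span[2] - span[1] + 1L
    data.frame(
        free_energy = freeEnergy(duplex, sequence),
        stem_length = stem_length,
        max_bulge = .maxBulge(duplex),
        pct_paired = nrow(p) / stem_length,
        dist_to_edge = min(site - span[1], span[2] - site),
        paired_total = nrow(p),
        paired_downstream = sum(edit_pos > site),
        paired_upstream = sum(edit_pos < site))
}
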