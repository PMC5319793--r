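#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData
#' @importFrom stats cor lm coef median na.omit p.adjust pbinom quantile rbeta
#'   rbinom rnbinom rnorm runif sd setNames var wilcox.test ks.test fisher.test
#'   binom.test cor.test plogis reorder aggregate as.dist rle
#' @importFrom utils read.delim write.table packageVersion head tail
NULL

#' Editing levels and coverages for sites across samples or species
#'
#' A \code{LevelMatrix} holds per-site, per-sample editing levels (the
#' fraction of reads carrying G at an A site, G/(A+G)), read coverages, and
#' the measurement platform of each entry. It extends
#' \linkS4class{SummarizedExperiment} with three assays:
#' \describe{
#'   \item{\code{level}}{numeric in [0,1]; \code{NA} where coverage is below
#'     the platform minimum (20 reads for RNA-seq, 50 for mmPCR-seq).}
#'   \item{\code{coverage}}{non-negative read counts.}
#'   \item{\code{platform}}{\code{"rnaseq"} or \code{"mmpcr"} provenance.}
#' }
#'
#' @seealso [quantifyLevels()], [combinePlatforms()], [representativeLevel()]
#' @export
setClass("LevelMatrix", contains = "SummarizedExperiment")

.validLevelMatrix <- function(object) {
    msg <- NULL
    an <- SummarizedExperiment::assayNames(object)
    need <- c("level", "coverage", "platform")
    if (!all(need %in% an))
        msg <- c(msg, paste("assays must include", paste(need, collapse = ", ")))
    else {
        lv <- SummarizedExperiment::assay(object, "level")
        if (any(lv < -1e-12 | lv > 1 + 1e-12, na.rm = TRUE))
            msg <- c(msg, "levels must lie in [0, 1]")
        cv <- SummarizedExperiment::assay(object, "coverage")
        if (any(cv < 0, na.rm = TRUE))
            msg <- c(msg, "coverages must be non-negative")
        pf <- SummarizedExperiment::assay(object, "platform")
        ok <- pf %in% c("rnaseq", "mmpcr") | is.na(pf)
        if (!all(ok))
            msg <- c(msg, "platform entries must be 'rnaseq' or 'mmpcr'")
    }
    if (is.null(msg)) TRUE else msg
}
setValidity("LevelMatrix", .validLevelMatrix)

#' Construct a LevelMatrix
#'
#' @param level numeric matrix of editing levels (sites x samples), values in
#'   [0,1] or \code{NA}.
#' @param coverage numeric matrix of read coverages, same dimensions.
#' @param platform either a single string (recycled) or a character matrix of
#'   \code{"rnaseq"} / \code{"mmpcr"} entries.
#' @return a \linkS4class{LevelMatrix}
#' @examples
#' lm <- LevelMatrix(matrix(0.2, 2, 2, dimnames = list(c("s1","s2"), c("a","b"))),
#'                   matrix(100, 2, 2))
#' editingLevels(lm)
#' @export
LevelMatrix <- function(level, coverage, platform = "rnaseq") {
    level <- as.matrix(level)
    coverage <- as.matrix(coverage)
    stopifnot(all(dim(level) == dim(coverage)))
    if (!is.matrix(platform)) {
        platform <- matrix(as.character(platform), nrow(level), ncol(level))
    }
    dimnames(coverage) <- dimnames(platform) <- dimnames(level)
    new("LevelMatrix", SummarizedExperiment::SummarizedExperiment(
        assays = list(level = level, coverage = coverage, platform = platform)))
}

#' @describeIn LevelMatrix editing-level matrix accessor
#' @param x a \code{LevelMatrix}
#' @export
editingLevels <- function(x) SummarizedExperiment::assay(x, "level")

#' @describeIn LevelMatrix coverage matrix accessor
#' @export
coverages <- function(x) SummarizedExperiment::assay(x, "coverage")

#' @describeIn LevelMatrix platform provenance accessor
#' @export
platforms <- function(x) SummarizedExperiment::assay(x, "platform")

#' Per-base conservation track
#'
#' Stores per-base conservation probabilities (e.g. phastCons posteriors) in
#' [0,1], addressed by contig and 1-based position. Positions outside the
#' stored blocks, or stored as \code{NA}, report as undefined rather than 0.
#'
#' @slot scores named list, one numeric vector per contig.
#' @slot offsets named integer vector; 1-based position of the first element
#'   of each contig's vector.
#' @seealso [readConservation()], [smoothConservation()], [conservationAt()]
#' @export
setClass("ConservationTrack",
         representation(scores = "list", offsets = "integer"))

setValidity("ConservationTrack", function(object) {
    msg <- NULL
    if (!identical(names(object@scores), names(object@offsets)))
        msg <- c(msg, "scores and offsets must share contig names")
    for (v in object@scores) {
        if (any(v < 0 | v > 1, na.rm = TRUE)) {
            msg <- c(msg, "conservation values must lie in [0, 1]")
            break
        }
    }
    if (any(object@offsets < 1L)) msg <- c(msg, "offsets are 1-based (>= 1)")
    if (is.null(msg)) TRUE else msg
})

#' @param scores named list of numeric vectors (one per contig).
#' @param offsets named integer vector of 1-based start positions.
#' @rdname ConservationTrack-class
#' @export
ConservationTrack <- function(scores, offsets = NULL) {
    if (is.null(offsets))
        offsets <- setNames(rep(1L, length(scores)), names(scores))
    new("ConservationTrack", scores = scores,
        offsets = setNames(as.integer(offsets), names(scores)))
}

#' Query a conservation track
#'
#' @param track a \linkS4class{ConservationTrack}
#' @param contig contig name
#' @param pos integer vector of 1-based positions
#' @return numeric vector of scores; \code{NA} for undefined positions.
#' @export
conservationAt <- function(track, contig, pos) {
    v <- track@scores[[contig]]
    if (is.null(v)) return(rep(NA_real_, length(pos)))
    idx <- pos - track@offsets[[contig]] + 1L
    out <- rep(NA_real_, length(pos))
    ok <- idx >= 1L & idx <= length(v)
    out[ok] <- v[idx[ok]]
    out
}

setMethod("show", "ConservationTrack", function(object) {
    n <- sum(vapply(object@scores, function(v) sum(!is.na(v)), 0))
    cat("ConservationTrack with", length(object@scores), "contig(s),",
        n, "defined base(s)\n")
})

#' A predicted editing stem (dsRNA duplex)
#'
#' Represents the double-stranded stem formed between the region containing an
#' editing site and its editing complementary sequence (ECS). Base pairs are
#' stored as rows of a two-column matrix of 1-based positions within the
#' folded sequence, first column strictly less than the second; pairs are
#' non-crossing (nested), and each base appears in at most one pair.
#'
#' @slot pairs integer matrix (n x 2) of paired positions.
#' @slot pairType character vector, \code{"WC"} (Watson-Crick) or \code{"GU"}
#'   (wobble) per pair.
#' @slot contig optional name of the folded sequence.
#' @seealso [foldWindow()], [findProximalEcs()], [extractFeatures()]
#' @export
setClass("DuplexStructure",
         representation(pairs = "matrix", pairType = "character",
                        contig = "character"))

setValidity("DuplexStructure", function(object) {
    p <- object@pairs
    msg <- NULL
    if (ncol(p) != 2L) return("pairs must have two columns")
    if (nrow(p)) {
        if (any(p[, 1] >= p[, 2]))
            msg <- c(msg, "pair first position must precede second")
        if (anyDuplicated(c(p[, 1], p[, 2])))
            msg <- c(msg, "each base may appear in only one pair")
        o <- order(p[, 1])
        if (is.unsorted(rev(p[o, 2])))
            msg <- c(msg, "pairs must be non-crossing (nested)")
        if (length(object@pairType) != nrow(p))
            msg <- c(msg, "one pairType per pair")
        if (!all(object@pairType %in% c("WC", "GU")))
            msg <- c(msg, "pairType must be 'WC' or 'GU'")
    }
    if (is.null(msg)) TRUE else msg
})

#' @param pairs integer matrix (n x 2) of paired 1-based positions.
#' @param pairType character vector of \code{"WC"}/\code{"GU"} per pair.
#' @param contig optional sequence name.
#' @rdname DuplexStructure-class
#' @export
DuplexStructure <- function(pairs, pairType, contig = NA_character_) {
    pairs <- matrix(as.integer(pairs), ncol = 2)
    if (nrow(pairs)) {
        o <- order(pairs[, 1])
        pairs <- pairs[o, , drop = FALSE]
        pairType <- pairType[o]
    }
    new("DuplexStructure", pairs = pairs, pairType = as.character(pairType),
        contig = contig)
}

#' @describeIn DuplexStructure number of base pairs in the stem
#' @param x a \code{DuplexStructure}
#' @export
nPaired <- function(x) nrow(x@pairs)

#' @describeIn DuplexStructure base-pair matrix accessor
#' @export
duplexPairs <- function(x) x@pairs

#' @describeIn DuplexStructure the two stem arms as 1-based [start, end]
#'   ranges (list with elements \code{first} and \code{second})
#' @export
armRanges <- function(x) {
    if (!nrow(x@pairs)) return(list(first = c(NA, NA), second = c(NA, NA)))
    list(first = range(x@pairs[, 1]), second = range(x@pairs[, 2]))
}

setMethod("show", "DuplexStructure", function(object) {
    a <- armRanges(object)
    cat("DuplexStructure:", nPaired(object), "pairs",
        sprintf("(%d GU)", sum(object@pairType == "GU")))
    if (nPaired(object))
        cat(sprintf("; arms [%d,%d] ~ [%d,%d]", a$first[1], a$first[2],
                    a$second[1], a$second[2]))
    cat("\n")
})

#' ADAR triplet motif weight matrix
#'
#' Position-wise nucleotide probabilities for the bases immediately 5' (-1)
#' and 3' (+1) of the edited adenosine (the centre position is fixed to A).
#' Built from the triplets of highly edited sites; see [buildMotifMatrix()].
#'
#' @slot probs 4 x 2 numeric matrix, rows A/C/G/U, columns \code{m1} (-1
#'   position) and \code{p1} (+1 position); each column sums to 1.
#' @slot pseudocount the additive smoothing constant used.
#' @export
setClass("MotifMatrix",
         representation(probs = "matrix", pseudocount = "numeric"))

setValidity("MotifMatrix", function(object) {
    p <- object@probs
    msg <- NULL
    if (!identical(rownames(p), c("A", "C", "G", "U")) ||
        !identical(colnames(p), c("m1", "p1")))
        msg <- c(msg, "probs must be a 4x2 matrix with rows A,C,G,U and columns m1,p1")
    else if (any(abs(colSums(p) - 1) > 1e-9))
        msg <- c(msg, "each position's probabilities must sum to 1")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "MotifMatrix", function(object) {
    cat("MotifMatrix (pseudocount", object@pseudocount, ")\n")
    print(round(object@probs, 3))
})

#' @describeIn MotifMatrix probability matrix accessor
#' @param x a \code{MotifMatrix}
#' @export
motifProbs <- function(x) x@probs
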