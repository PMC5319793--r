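.SITE_CATEGORIES <- c("nonsynonymous", "synonymous", "stoploss",
                      "5UTR", "3UTR", "intron")

#' Read an editing-site table
#'
#' Sites are single bases given in a BED-like tab-separated file with columns
#' \code{contig, start, end, site_id, category, strand, gene}, 0-based
#' half-open coordinates (so \code{end == start + 1}). Internally the package
#' stores 1-based coordinates (the \linkS4class{GRanges} convention); the
#' shift happens here and is undone by [writeSiteTable()].
#'
#' @param path path to the TSV (lines starting with \code{#} are ignored)
#' @return a \linkS4class{GRanges} with metadata columns \code{site_id},
#'   \code{category} (one of nonsynonymous, synonymous, stoploss, 5UTR, 3UTR,
#'   intron) and \code{gene}.
#' @export
readSiteTable <- function(path) {
    raw <- readLines(path)
    keep <- !grepl("^#", raw) & nzchar(raw)
    lineno <- which(keep)
    if (!length(lineno)) {
        return(GenomicRanges::GRanges(site_id = character(),
                                      category = character(),
                                      gene = character()))
    }
    fields <- strsplit(raw[keep], "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf != 7L))
        stop("malformed site row at line ", lineno[which(nf != 7L)[1]],
             ": expected 7 tab-separated fields")
    m <- do.call(rbind, fields)
    start0 <- suppressWarnings(as.integer(m[, 2]))
    end0 <- suppressWarnings(as.integer(m[, 3]))
    bad <- is.na(start0) | is.na(end0)
    if (any(bad))
        stop("malformed site row at line ", lineno[which(bad)[1]],
             ": non-integer coordinates")
    if (any(end0 != start0 + 1L))
        stop("site at line ", lineno[which(end0 != start0 + 1L)[1]],
             " has end != start + 1; editing sites are single bases")
    if (!all(m[, 5] %in% .SITE_CATEGORIES))
        stop("unknown genic category '",
             m[which(!(m[, 5] %in% .SITE_CATEGORIES))[1], 5], "'")
    if (!all(m[, 6] %in% c("+", "-")))
        stop("strand must be '+' or '-' (line ",
             lineno[which(!(m[, 6] %in% c("+", "-")))[1]], ")")
    gr <- GenomicRanges::GRanges(
        seqnames = m[, 1],
        ranges = IRanges::IRanges(start = start0 + 1L, width = 1L),
        strand = m[, 6])
    S4Vectors::mcols(gr)$site_id <- m[, 4]
    S4Vectors::mcols(gr)$category <- m[, 5]
    S4Vectors::mcols(gr)$gene <- m[, 7]
    names(gr) <- m[, 4]
    gr
}

#' Write an editing-site table
#'
#' Inverse of [readSiteTable()]: emits BED-like 0-based half-open rows.
#'
#' @param sites a \code{GRanges} as returned by [readSiteTable()]
#' @param path output path
#' @export
writeSiteTable <- function(sites, path) {
    df <- data.frame(
        contig = as.character(GenomicRanges::seqnames(sites)),
        start = GenomicRanges::start(sites) - 1L,
        end = GenomicRanges::start(sites),
        site_id = S4Vectors::mcols(sites)$site_id,
        category = S4Vectors::mcols(sites)$category,
        strand = as.character(GenomicRanges::strand(sites)),
        gene = S4Vectors::mcols(sites)$gene)
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read a per-site pileup count table
#'
#' Expects a TSV with header columns \code{site_id, sample_id, ref_base,
#' n_A, n_C, n_G, n_T}; counts are taken post base/mapping-quality filtering.
#'
#' @param path input TSV path
#' @return a data.frame with an added \code{coverage} column (sum of the four
#'   counts). Negative counts and duplicate (site, sample) keys are errors; an
#'   empty file yields an empty table.
#' @export
readPileup <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("site_id", "sample_id", "ref_base", "n_A", "n_C", "n_G", "n_T")
    if (!nrow(df)) {
        df <- as.data.frame(setNames(rep(list(character(0)), 3), need[1:3]))
        for (k in need[4:7]) df[[k]] <- integer(0)
        df$coverage <- integer(0)
        return(df)
    }
    miss <- setdiff(need, names(df))
    if (length(miss)) stop("pileup missing column(s): ", paste(miss, collapse = ", "))
    cnt <- as.matrix(df[, c("n_A", "n_C", "n_G", "n_T")])
    if (any(cnt < 0)) stop("negative count in pileup at row ",
                           which(rowSums(cnt < 0) > 0)[1])
    key <- paste(df$site_id, df$sample_id)
    if (anyDuplicated(key))
        stop("duplicate (site, sample) key in pileup: ", key[duplicated(key)][1])
    df$coverage <- rowSums(cnt)
    df
}

#' @rdname readPileup
#' @param pileup a pileup data.frame
#' @export
writePileup <- function(pileup, path) {
    write.table(pileup[, c("site_id", "sample_id", "ref_base",
                           "n_A", "n_C", "n_G", "n_T")],
                path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a fixedStep wiggle conservation track
#'
#' Parses the fixedStep dialect (\code{fixedStep chrom=... start=... step=1})
#' with one value per line. Wiggle coordinates are 1-based; they are kept
#' 1-based internally. Values must lie in [0,1] and the step must be 1.
#'
#' @param path wiggle file path
#' @return a \linkS4class{ConservationTrack}
#' @export
readConservation <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !grepl("^(track|#)", lines)]
    decl <- grep("^fixedStep", lines)
    if (!length(decl)) stop("no fixedStep declaration found in ", path)
    scores <- list(); offsets <- integer()
    bounds <- c(decl, length(lines) + 1L)
    for (i in seq_along(decl)) {
        hdr <- lines[decl[i]]
        getfield <- function(key) {
            m <- regmatches(hdr, regexec(paste0(key, "=([^ \t]+)"), hdr))[[1]]
            if (length(m) < 2) stop("fixedStep declaration missing ", key)
            m[2]
        }
        chrom <- getfield("chrom")
        start <- as.integer(getfield("start"))
        step <- if (grepl("step=", hdr)) as.integer(getfield("step")) else 1L
        if (!identical(step, 1L)) stop("only step=1 fixedStep tracks are supported")
        vals <- as.numeric(lines[(decl[i] + 1L):(bounds[i + 1L] - 1L)])
        if (anyNA(vals)) stop("non-numeric value in wiggle block ", i)
        if (any(vals < 0 | vals > 1))
            stop("conservation value outside [0, 1]: ",
                 vals[which(vals < 0 | vals > 1)[1]])
        if (is.null(scores[[chrom]])) {
            scores[[chrom]] <- vals
            offsets[chrom] <- start
        } else {
            # extend the contig vector, padding any gap with NA (undefined)
            old <- scores[[chrom]]; o <- offsets[[chrom]]
            lo <- min(o, start)
            hi <- max(o + length(old) - 1L, start + length(vals) - 1L)
            merged <- rep(NA_real_, hi - lo + 1L)
            merged[(o - lo + 1L):(o - lo + length(old))] <- old
            merged[(start - lo + 1L):(start - lo + length(vals))] <- vals
            scores[[chrom]] <- merged
            offsets[chrom] <- lo
        }
    }
    ConservationTrack(scores, offsets)
}

#' @rdname readConservation
#' @param track a \code{ConservationTrack}
#' @export
writeConservation <- function(track, path) {
    con <- file(path, "w")
    on.exit(close(con))
    for (chrom in names(track@scores)) {
        v <- track@scores[[chrom]]
        off <- track@offsets[[chrom]]
        # emit one fixedStep block per run of defined values
        def <- !is.na(v)
        r <- rle(def)
        at <- cumsum(c(1L, r$lengths))
        for (i in seq_along(r$values)) {
            if (!r$values[i]) next
            idx <- at[i]:(at[i + 1L] - 1L)
            writeLines(sprintf("fixedStep chrom=%s start=%d step=1",
                               chrom, off + idx[1] - 1L), con)
            writeLines(format(v[idx], trim = TRUE, scientific = FALSE), con)
        }
    }
    invisible(path)
}

#' Read a cross-species orthology map
#'
#' TSV with columns \code{site_id, species_a, species_b, contig_b, pos_b,
#' strand_flip} mapping sites of species A onto coordinates in species B.
#' \code{pos_b} is 0-based in the file (as in the site tables) and converted
#' to 1-based on read; \code{strand_flip} is 0/1.
#'
#' @param path TSV path
#' @return a data.frame with 1-based \code{pos_b} and logical
#'   \code{strand_flip}
#' @export
readOrthology <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("site_id", "species_a", "species_b", "contig_b", "pos_b",
              "strand_flip")
    miss <- setdiff(need, names(df))
    if (length(miss)) stop("orthology missing column(s): ",
                           paste(miss, collapse = ", "))
    df$pos_b <- as.integer(df$pos_b) + 1L
    df$strand_flip <- as.logical(as.integer(df$strand_flip))
    df
}

#' Read a gene expression table (gene, log2fc, mean_expr)
#'
#' @param path TSV path
#' @return data.frame
#' @export
readExpressionTable <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    miss <- setdiff(c("gene", "log2fc"), names(df))
    if (length(miss)) stop("expression table missing column(s): ",
                           paste(miss, collapse = ", "))
    df
}

#' Read miRNAs with expression fractions
#'
#' @param fasta path to a miRNA FASTA (mature sequences, RNA or DNA alphabet)
#' @param expr path to a TSV with columns \code{mirna_id, fraction} giving
#'   each miRNA's fraction of total miRNA reads
#' @return data.frame with columns \code{mirna_id, seq, fraction}; sequences
#'   are uppercase RNA.
#' @export
readMirnaExpression <- function(fasta, expr) {
    seqs <- Biostrings::readBStringSet(fasta)
    ed <- read.delim(expr, stringsAsFactors = FALSE)
    miss <- setdiff(c("mirna_id", "fraction"), names(ed))
    if (length(miss)) stop("miRNA expression table missing column(s): ",
                           paste(miss, collapse = ", "))
    data.frame(mirna_id = names(seqs),
               seq = .toRna(as.character(seqs)),
               fraction = ed$fraction[match(names(seqs), ed$mirna_id)],
               stringsAsFactors = FALSE)
}
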