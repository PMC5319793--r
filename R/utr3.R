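#' Compare expression change across 3'UTR-editing gene groups
#'
#' Two-sided Mann-Whitney U tests of log2 fold change between each gene
#' group and the control group (genes edited outside the 3'UTR, or unedited
#' controls). Grouping conventionally uses only sites with editing level
#' above 5\% and at least 20 reads in the wild type.
#'
#' @param genes data.frame with columns \code{gene, group, log2fc}
#' @param control the control group label (default \code{"control"})
#' @return data.frame with one row per non-control group: \code{group, n,
#'   median_log2fc, control_median, p}
#' @export
groupExpressionComparison <- function(genes, control = "control") {
    stopifnot(all(c("group", "log2fc") %in% names(genes)))
    ctrl <- genes$log2fc[genes$group == control]
    if (!length(ctrl)) stop("control group '", control, "' is empty")
    grps <- setdiff(unique(genes$group), control)
    res <- lapply(grps, function(g) {
        v <- genes$log2fc[genes$group == g]
        data.frame(group = g, n = length(v),
                   median_log2fc = median(v),
                   control_median = median(ctrl),
                   p = rankGroupTest(v, ctrl))
    })
    do.call(rbind, res)
}

#' Compare nascent and polyA editing levels by genic category
#'
#' Uses sites covered by at least \code{min_cov} reads in both datasets
#' with a nascent editing level above \code{min_nascent_level}; the
#' per-site difference (polyA minus nascent) is compared between 3'UTR and
#' CDS sites with a two-sided Mann-Whitney U test.
#'
#' @param level_nascent,level_polya numeric vectors of per-site levels
#' @param cov_nascent,cov_polya matching coverage vectors
#' @param category character vector of genic categories per site
#'   (\code{nonsynonymous/synonymous/stoploss} count as CDS)
#' @param min_cov coverage filter (default 20)
#' @param min_nascent_level nascent level filter (default 0.05)
#' @return list with \code{sites} (per-site differences after filtering)
#'   and \code{p} (3'UTR vs CDS; NA when a group is empty)
#' @export
nascentPolyaComparison <- function(level_nascent, cov_nascent,
                                   level_polya, cov_polya, category,
                                   min_cov = 20L, min_nascent_level = 0.05) {
    keep <- !is.na(level_nascent) & !is.na(level_polya) &
        cov_nascent >= min_cov & cov_polya >= min_cov &
        level_nascent > min_nascent_level
    cds <- c("nonsynonymous", "synonymous", "stoploss")
    df <- data.frame(category = category[keep],
                     nascent = level_nascent[keep],
                     polya = level_polya[keep])
    df$difference <- df$polya - df$nascent
    a <- df$difference[df$category == "3UTR"]
    b <- df$difference[df$category %in% cds]
    p <- if (length(a) && length(b)) rankGroupTest(a, b) else NA_real_
    list(sites = df, p = p)
}

# Exclusive seed-match classification at every position of a UTR (5'->3').
# An 8mer is a reverse-complement match to miRNA positions 2-8 followed by
# an A (opposite position 1); a 7mer-m8 is the 2-8 match without the A
# anchor; a 7mer-A1 is the 2-7 match plus the A anchor, not extendable to
# an 8mer.
.seedMatches <- function(utr, mir) {
    rc7 <- .revCompRna(substr(mir, 2, 8))
    rc6 <- .revCompRna(substr(mir, 2, 7))
    n <- nchar(utr)
    out <- list()
    add <- function(type, s, e)
        out[[length(out) + 1L]] <<- data.frame(type = type, start = s,
                                               end = e)
    for (p in seq_len(n - 6L)) {
        if (substr(utr, p, p + 6L) == rc7) {
            if (p + 7L <= n && substr(utr, p + 7L, p + 7L) == "A")
                add("8mer", p, p + 7L)
            else add("7mer-m8", p, p + 6L)
        } else if (substr(utr, p, p + 5L) == rc6 &&
                   substr(utr, p + 6L, p + 6L) == "A" &&
                   !(p > 1L && substr(utr, p - 1L, p + 5L) == rc7)) {
            add("7mer-A1", p, p + 6L)
        }
    }
    if (!length(out)) return(data.frame(type = character(),
                                        start = integer(), end = integer()))
    do.call(rbind, out)
}

#' Scan for miRNA seed matches gained or lost by editing
#'
#' Predicts canonical miRNA target sites (8mer, 7mer-m8, 7mer-A1; seed =
#' miRNA positions 2-8) in the unedited 3'UTR and in each single-edit
#' (A-to-G) variant, and reports matches present only in the edited
#' sequence as gained and those present only in the unedited sequence as
#' lost. Edits are evaluated independently (no combinatorial multi-edit
#' variants). Only miRNAs above the expression-fraction filter are
#' scanned.
#'
#' @param utr_seq the 3'UTR sequence (transcribed strand; T is converted
#'   to U)
#' @param edit_positions 1-based positions of the edited As within
#'   \code{utr_seq} (an edit at a non-A position is an error)
#' @param mirnas data.frame with \code{mirna_id, seq, fraction} (see
#'   [readMirnaExpression()])
#' @param min_fraction miRNA expression filter (default 0.001, i.e. >0.1\%
#'   of miRNA reads)
#' @param include_unchanged also report matches unaffected by the edit
#' @return data.frame with \code{mirna_id, type, start, end, edit_pos,
#'   status} (\code{gained_by_editing} / \code{lost_by_editing} /
#'   \code{unchanged})
#' @export
scanMirnaSeedChanges <- function(utr_seq, edit_positions, mirnas,
                                 min_fraction = 0.001,
                                 include_unchanged = FALSE) {
    utr <- .toRna(utr_seq)
    chars <- strsplit(utr, "")[[1]]
    bad <- edit_positions[chars[edit_positions] != "A"]
    if (length(bad))
        stop("edit position ", bad[1], " is not an A in the unedited UTR")
    mirnas <- mirnas[mirnas$fraction > min_fraction, , drop = FALSE]
    out <- list()
    for (i in seq_len(nrow(mirnas))) {
        mir <- .toRna(mirnas$seq[i])
        un <- .seedMatches(utr, mir)
        unkey <- paste(un$type, un$start)
        for (ep in edit_positions) {
            ec <- chars; ec[ep] <- "G"
            ed <- .seedMatches(paste(ec, collapse = ""), mir)
            edkey <- paste(ed$type, ed$start)
            gained <- ed[!(edkey %in% unkey), , drop = FALSE]
            lost <- un[!(unkey %in% edkey), , drop = FALSE]
            # only changes touching the edited window are attributable
            touches <- function(df) df[ep >= df$start - 1L &
                                       ep <= df$end + 1L, , drop = FALSE]
            gained <- touches(gained); lost <- touches(lost)
            rows <- list()
            if (nrow(gained))
                rows$g <- cbind(gained, status = "gained_by_editing")
            if (nrow(lost))
                rows$l <- cbind(lost, status = "lost_by_editing")
            if (include_unchanged) {
                unch <- un[unkey %in% edkey, , drop = FALSE]
                if (nrow(unch)) rows$u <- cbind(unch, status = "unchanged")
            }
            for (r in rows) {
                r$mirna_id <- mirnas$mirna_id[i]
                r$edit_pos <- ep
                out[[length(out) + 1L]] <- r
            }
        }
    }
    if (!length(out))
        return(data.frame(mirna_id = character(), type = character(),
                          start = integer(), end = integer(),
                          edit_pos = integer(), status = character()))
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res[, c("mirna_id", "type", "start", "end", "edit_pos", "status")]
}
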