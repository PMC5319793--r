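# Independent oracles used to validate the statistical kernels and scanners.
# These deliberately use brute force / direct enumeration and share no code
# with the implementations they check.

# Two-sided Fisher's exact p for a 2x2 table by hypergeometric enumeration:
# sum the probabilities of all tables with the same margins whose
# probability does not exceed the observed table's (with a relative
# tolerance for ties).
oracleFisher2x2 <- function(a, b, c, d) {
    r1 <- a + b; r2 <- c + d; c1 <- a + c
    amin <- max(0, c1 - r2); amax <- min(r1, c1)
    avals <- amin:amax
    logp <- lchoose(r1, avals) + lchoose(r2, c1 - avals) -
        lchoose(r1 + r2, c1)
    p <- exp(logp)
    pobs <- p[avals == a]
    sum(p[p <= pobs * (1 + 1e-7)])
}

# Benjamini-Hochberg step-up from the definition: find the largest k with
# p_(k) <= k/m * alpha ... expressed as adjusted p-values via the cumulative
# minimum from the largest p.
oracleBH <- function(p) {
    m <- length(p)
    o <- order(p, decreasing = TRUE)
    ro <- order(o)
    pmin(1, cummin(p[o] * m / (m:1)))[ro]
}

# Upper-tail binomial probability by direct summation of the pmf.
oracleBinomTail <- function(k, n, prob) {
    kk <- k:n
    sum(choose(n, kk) * prob^kk * (1 - prob)^(n - kk))
}

# Two-sample KS D by evaluating both ECDFs at every data point.
oracleKsD <- function(x, y) {
    grid <- sort(unique(c(x, y)))
    Fx <- vapply(grid, function(g) mean(x <= g), 0)
    Fy <- vapply(grid, function(g) mean(y <= g), 0)
    max(abs(Fx - Fy))
}

# Exact two-sided Mann-Whitney p by complete enumeration of group
# assignments (combn); handles ties through mid-ranks. Only for tiny n.
oracleMWU <- function(a, b) {
    x <- c(a, b)
    r <- rank(x)
    na <- length(a)
    idx <- utils::combn(length(x), na)
    sums <- apply(idx, 2, function(i) sum(r[i]))
    obs <- sum(r[seq_len(na)])
    mu <- mean(sums)
    mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
}

# Longest contiguous complementary (WC + GU) segment pair within one
# sequence, by exhaustive enumeration over all (i, j, length) with a
# minimum loop separation. Oracle for the banded duplex search.
oracleMaxRun <- function(seq, min_loop = 4L) {
    x <- strsplit(toupper(chartr("T", "U", seq)), "")[[1]]
    n <- length(x)
    pairable <- function(a, b) {
        (a == "A" & b == "U") | (a == "U" & b == "A") |
        (a == "C" & b == "G") | (a == "G" & b == "C") |
        (a == "G" & b == "U") | (a == "U" & b == "G")
    }
    best <- 0L
    for (i in seq_len(n)) for (j in seq_len(n)) {
        if (j - i <= min_loop) next
        l <- 0L
        while (i + l <= n && j - l >= 1 && j - l - (i + l) > min_loop &&
               pairable(x[i + l], x[j - l])) l <- l + 1L
        best <- max(best, l)
    }
    best
}

# Brute-force seed-match classification of a UTR against one miRNA:
# checks every window for the three canonical types with the exclusive
# (strongest-type) convention.
oracleSeedMatches <- function(utr, mir) {
    rc <- function(s) {
        comp <- c(A = "U", C = "G", G = "C", U = "A")
        paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
    }
    utr <- toupper(chartr("T", "U", utr)); mir <- toupper(chartr("T", "U", mir))
    rc7 <- rc(substr(mir, 2, 8)); rc6 <- rc(substr(mir, 2, 7))
    n <- nchar(utr)
    res <- list()
    for (p in 1:n) {
        w8 <- substr(utr, p, p + 7)
        w7 <- substr(utr, p, p + 6)
        if (nchar(w8) == 8 && w8 == paste0(rc7, "A")) {
            res[[length(res) + 1]] <- data.frame(type = "8mer", start = p)
        } else if (nchar(w7) == 7 && w7 == rc7) {
            res[[length(res) + 1]] <- data.frame(type = "7mer-m8", start = p)
        } else if (nchar(w7) == 7 && w7 == paste0(rc6, "A") &&
                   !(p > 1 && substr(utr, p - 1, p + 5) == rc7)) {
            res[[length(res) + 1]] <- data.frame(type = "7mer-A1", start = p)
        }
    }
    if (!length(res)) return(data.frame(type = character(), start = integer()))
    do.call(rbind, res)
}

# A small additive (tree-metric) distance matrix with known topology, for
# the NJ consistency checks.
randomAdditiveMatrix <- function(n_tips, seed) {
    set.seed(seed)
    tr <- ape::rtree(n_tips, br = function(k) runif(k, 0.3, 2))
    list(tree = tr, d = ape::cophenetic.phylo(tr))
}
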