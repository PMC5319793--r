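#' Synthetic-data generator configuration
#'
#' Defines the generative model used to exercise the pipeline end to end:
#' editing sites are born on branches of a species tree (uniformly, weighted
#' by branch length), start at a level set by a logistic function of their
#' planted cis features (stem paired-base count and triplet motif strength)
#' and evolve along descendant branches as a Gaussian random walk with
#' standard deviation \code{level_walk_sd * sqrt(branch length)}, reflected
#' into [0,1]. Read counts are drawn binomially on a negative-binomial
#' coverage with a 1\% A-to-G sequencing error; an ADAR-null sample carries
#' errors only. Sequences receive planted hairpin duplexes and motif
#' triplets; conservation tracks receive planted constrained windows; 3'UTR
#' edited genes receive expression shifts and optional planted miRNA
#' seed-match gains.
#'
#' Defaults emulate the study conditions: six Drosophilid species with
#' published divergence times, mean coverage 100 (the observed 95-127 reads
#' per site), 1\% error, birth levels bounded below at 5\% (the level at
#' which sites enter the targeted panel), and a 20/20/60 mix of
#' highly/moderately/un-constrained sites.
#'
#' @param ... named overrides of any default field.
#' @return a list of class \code{"SimConfig"}.
#' @examples
#' cfg <- simConfig(n_sites = 50, rng_seed = 42)
#' cfg$error_rate
#' @export
simConfig <- function(...) {
    cfg <- list(
        tree = paste0("(((((mel:5.4,sim:5.4):7.4,yak:12.8):31.4,",
                      "ana:44.2):10.7,pse:54.9):8,vir:62.9);"),
        n_sites             = 1000L,
        n_genes             = 200L,
        coverage_mean       = 100,
        coverage_dispersion = 5,
        error_rate          = 0.01,
        level_walk_sd       = 0.04,   # per sqrt(Myr)
        min_birth_level     = 0.05,
        structure_effect    = 1.0,    # logistic coefficient on (n_p - 28)/8
        motif_effect        = 1.0,    # logistic coefficient on motif strength
        frac_structured     = 0.8,    # probability a site gets a planted stem
        fraction_high       = 0.2,
        fraction_moderate   = 0.2,
        expression_shift    = 0.5,
        expression_sd       = 0.5,
        seed_gain_fraction  = 0.5,    # of stemless 3'UTR sites: planted miRNA seed gains
        contig_len          = 600L,
        site_pos            = 300L,
        root_edge_length    = 40,     # Myr of stem lineage above the root:
                                      # ancestral sites shared by all species
        stem_min_pairs      = 22L,
        stem_max_pairs      = 40L,
        rng_seed            = 1L
    )
    dots <- list(...)
    if (length(dots)) {
        bad <- setdiff(names(dots), names(cfg))
        if (length(bad))
            stop("unknown sim config field(s): ", paste(bad, collapse = ", "))
        cfg[names(dots)] <- dots
    }
    if (cfg$error_rate < 0 || cfg$error_rate >= 1)
        stop("error_rate must lie in [0, 1)")
    if (cfg$level_walk_sd < 0 || cfg$coverage_mean <= 0)
        stop("rates must be non-negative")
    class(cfg) <- "SimConfig"
    cfg
}

# reflect a value into [0, 1] (triangle fold), preserving variance near the
# boundaries where truncation would not
.reflect01 <- function(x) {
    r <- x %% 2
    ifelse(r > 1, 2 - r, r)
}

# generative motif strength in [0, 1] from the two flanking bases;
# encodes the ADAR preference for 5' U and 3' G
.motifStrength <- function(m1, p1) {
    w5 <- c(A = 0.4, C = 0.1, G = 0.0, U = 1.0)
    w3 <- c(A = 0.3, C = 0.3, G = 1.0, U = 0.2)
    (w5[m1] + w3[p1]) / 2
}

.SIM_CATEGORIES <- c(nonsynonymous = 0.35, synonymous = 0.20, stoploss = 0.01,
                     "5UTR" = 0.04, "3UTR" = 0.25, intron = 0.15)

#' Simulate true editing levels along a phylogeny
#'
#' Each site is born once, on a branch chosen with probability proportional
#' to branch length; species diverging before the birth branch have level 0.
#' The birth level is a logistic function of the site's planted cis features
#' (paired-base count of its stem and motif strength) plus noise, bounded
#' below by \code{min_birth_level}; levels then diffuse along descendant
#' branches as a reflected Gaussian random walk.
#'
#' @param config a [simConfig()]
#' @return a list with \code{levels} (a \linkS4class{LevelMatrix} of exact
#'   levels, sites x species, coverage \code{NA}) and \code{truth} (a list
#'   with per-site and per-gene ground-truth tables, the tree, and the
#'   config).
#' @export
simulateLevels <- function(config = simConfig()) {
    tr <- ape::read.tree(text = config$tree)
    if (is.null(tr) || length(tr$tip.label) < 2L)
        stop("tree must have at least 2 leaves")
    .withSubstream(config$rng_seed, "levels", {
        n <- config$n_sites
        tr <- stats::reorder(tr, "cladewise")
        edges <- tr$edge
        elen <- tr$edge.length
        ntip <- length(tr$tip.label)
        nnode <- ntip + tr$Nnode

        # cis covariates, drawn here so that birth levels can depend on them
        has_stem <- runif(n) < config$frac_structured
        n_p <- ifelse(has_stem,
                      sample(config$stem_min_pairs:config$stem_max_pairs, n,
                             replace = TRUE), NA_integer_)
        m1 <- sample(.RNA, n, replace = TRUE, prob = c(0.25, 0.2, 0.15, 0.4))
        p1 <- sample(.RNA, n, replace = TRUE, prob = c(0.25, 0.2, 0.35, 0.2))
        mstr <- .motifStrength(m1, p1)
        eta <- -1 +
            config$structure_effect * (ifelse(has_stem, n_p, 20) - 28) / 8 +
            config$motif_effect * 2 * (mstr - 0.55) +
            rnorm(n, 0, 0.8)
        birth_level <- pmax(plogis(eta), config$min_birth_level)

        # birth branch, weighted by branch length; index 0 is the stem
        # lineage above the root (ancestral sites, present in all species)
        wts <- c(config$root_edge_length, elen)
        if (all(wts == 0)) {
            birth_edge <- sample(nrow(edges) + 1L, n, replace = TRUE) - 1L
        } else {
            birth_edge <- sample(nrow(edges) + 1L, n, replace = TRUE,
                                 prob = wts) - 1L
        }
        u <- runif(n)

        sdw <- config$level_walk_sd
        lv <- matrix(NA_real_, nnode, n)
        root <- ntip + 1L
        anc <- which(birth_edge == 0L)
        if (length(anc))
            lv[root, anc] <- .reflect01(birth_level[anc] +
                rnorm(length(anc), 0,
                      sdw * sqrt((1 - u[anc]) * config$root_edge_length)))
        for (e in seq_len(nrow(edges))) {
            p <- edges[e, 1]; ch <- edges[e, 2]; L <- elen[e]
            out <- rep(NA_real_, n)
            born <- which(birth_edge == e)
            if (length(born))
                out[born] <- .reflect01(birth_level[born] +
                    rnorm(length(born), 0, sdw * sqrt((1 - u[born]) * L)))
            alive <- which(!is.na(lv[p, ]))
            if (length(alive))
                out[alive] <- .reflect01(lv[p, alive] +
                    rnorm(length(alive), 0, sdw * sqrt(L)))
            lv[ch, ] <- out
        }
        species <- tr$tip.label
        lev <- t(lv[seq_len(ntip), , drop = FALSE])
        lev[is.na(lev)] <- 0
        site_id <- sprintf("s%04d", seq_len(n))
        dimnames(lev) <- list(site_id, species)

        gene <- sprintf("g%03d", sample(config$n_genes, n, replace = TRUE))
        category <- sample(names(.SIM_CATEGORIES), n, replace = TRUE,
                           prob = .SIM_CATEGORIES)
        cclass <- sample(c("high", "moderate", "none"), n, replace = TRUE,
                         prob = c(config$fraction_high, config$fraction_moderate,
                                  1 - config$fraction_high - config$fraction_moderate))
        panel <- .simMirnaPanel()
        # seed gains go to stemless 3'UTR sites so the planted 8mer and a
        # planted stem never overwrite each other
        seed_gain <- category == "3UTR" & !has_stem &
            runif(n) < config$seed_gain_fraction
        seed_mirna <- ifelse(seed_gain,
                             sample(panel$mirna_id[panel$fraction > 0.001], n,
                                    replace = TRUE), NA_character_)

        # genomic coordinates on a pseudo-chromosome: genes are laid out
        # every 5 kb and a gene's sites fall within its 1.5 kb body, so
        # same-gene sites can be clustered (within 30-50 bp) by chance
        gene_idx <- as.integer(sub("g", "", gene))
        genomic_pos <- gene_idx * 5000L +
            sample.int(1500L, n, replace = TRUE)

        sites <- data.frame(
            site_id = site_id, gene = gene, category = category,
            genomic_pos = genomic_pos,
            birth_edge = birth_edge, birth_level = birth_level,
            has_stem = has_stem, n_p = n_p,
            motif_triplet = paste0(m1, "A", p1), motif_strength = unname(mstr),
            constraint_class = cclass,
            seed_gain = seed_gain, seed_mirna = seed_mirna,
            stringsAsFactors = FALSE)
        genes <- data.frame(gene = sprintf("g%03d", seq_len(config$n_genes)),
                            stringsAsFactors = FALSE)
        genes$n_utr3_sites <- as.integer(
            table(factor(gene[category == "3UTR"], levels = genes$gene)))
        genes$utr3_edited <- genes$n_utr3_sites > 0L

        truth <- list(sites = sites, genes = genes, tree = tr, config = config)
        levels <- LevelMatrix(lev, matrix(NA_real_, nrow(lev), ncol(lev)))
        list(levels = levels, truth = truth)
    })
}

#' Simulate pileup read counts from true editing levels
#'
#' Coverage is negative binomial with mean \code{coverage_mean} and size
#' \code{coverage_dispersion}; the G count is binomial with success
#' probability \code{level + error_rate * (1 - level)}; remaining reads are A
#' apart from error-distributed C/T at \code{error_rate / 2} each. One sample
#' per species is produced (named \code{<species>_wb}); if
#' \code{adar_null = TRUE} an additional sample for the first (anchor)
#' species is generated with the level forced to 0, emulating an ADAR-null
#' mutant that carries sequencing errors only.
#'
#' @param trueLevels a \linkS4class{LevelMatrix} of true levels (or a plain
#'   matrix, sites x species)
#' @param config a [simConfig()]
#' @param adar_null generate the ADAR-null sample for the anchor species?
#' @param n_replicates samples per species (replicates share the true level)
#' @return a pileup data.frame as from [readPileup()]
#' @export
simulateReads <- function(trueLevels, config = simConfig(), adar_null = TRUE,
                          n_replicates = 1L) {
    lev <- if (is(trueLevels, "LevelMatrix")) editingLevels(trueLevels)
           else as.matrix(trueLevels)
    .assertProb(lev, "true levels")
    .withSubstream(config$rng_seed, "reads", {
        err <- config$error_rate
        blocks <- list()
        emit <- function(levelVec, sample_id) {
            n <- length(levelVec)
            cov <- rnbinom(n, mu = config$coverage_mean,
                           size = config$coverage_dispersion)
            pG <- levelVec + err * (1 - levelVec)
            nG <- rbinom(n, cov, pG)
            nC <- rbinom(n, cov - nG, err / 2)
            nT <- rbinom(n, cov - nG - nC, err / 2)
            data.frame(site_id = rownames(lev), sample_id = sample_id,
                       ref_base = "A",
                       n_A = cov - nG - nC - nT, n_C = nC, n_G = nG, n_T = nT,
                       coverage = cov, stringsAsFactors = FALSE)
        }
        for (sp in colnames(lev)) {
            for (r in seq_len(n_replicates)) {
                sid <- if (n_replicates == 1L) paste0(sp, "_wb")
                       else sprintf("%s_wb_rep%d", sp, r)
                blocks[[sid]] <- emit(lev[, sp], sid)
            }
        }
        if (adar_null) {
            anchor <- colnames(lev)[1]
            blocks[[paste0(anchor, "_null")]] <-
                emit(rep(0, nrow(lev)), paste0(anchor, "_null"))
        }
        do.call(rbind, c(blocks, list(make.row.names = FALSE)))
    })
}

# The bundled synthetic miRNA panel (mature sequences, 5'->3'). These are
# synthetic constructs, not miRBase entries; seeds (positions 2-8) carry Cs
# so that an A->G edit in a target can complete a match. Fractions mimic a
# head miRNA profile where a fixed subset clears the 0.1% expression filter.
.simMirnaPanel <- function() {
    data.frame(
        mirna_id = sprintf("syn-mir-%02d", 1:10),
        seq = c("UAAGGCACGCGGUGAAUGCCA", "UCACAGCCCUAUACAAUCUGC",
                "UGGCAGUGUGGUUAGCUGGUU", "AGCUACAUCAGGUACUGGGUU",
                "UCCCUGAGACCCUAACUUGUG", "UAUGGCACUGGAAGAAUUCAC",
                "UGAGAUCAUCGUGAAAGCCAG", "ACUGGCCUACAAAGUCCCAGU",
                "UUCGUUGUCGACGAAACCUGC", "AGGCAAGAUGCUGGCAUAGCU"),
        fraction = c(0.12, 0.08, 0.05, 0.04, 0.03, 0.02, 0.015, 0.012,
                     0.0005, 0.0002),
        stringsAsFactors = FALSE)
}

#' Simulate genomic sequences with planted stems and motifs
#'
#' Every site is placed on its own contig (one window per site) at
#' \code{site_pos}, in the RNA alphabet on the transcribed strand. The motif
#' triplet from the ground truth is written at positions -1/+1; structured
#' sites get a perfect inverted-repeat stem of \code{n_p} pairs whose second
#' arm lies downstream of a short loop. Sites flagged for a miRNA seed gain
#' get the corresponding near-match 8mer written around the site (the edit
#' A->G completes the match). For species in which the site is absent (true
#' level 0), planted properties are degraded: the 5' motif base is mutated
#' and the stem's ECS arm is scrambled, so presence/absence pairs differ in
#' at least one planted cis feature.
#'
#' @param truth the truth list from [simulateLevels()]
#' @param trueLevels the LevelMatrix of true levels from [simulateLevels()]
#' @param config a [simConfig()]
#' @return a list with \code{sequences} (named list of
#'   \code{Biostrings::RNAStringSet}, one per species), \code{sites} (a
#'   \code{GRanges} site table for the anchor coordinates), and
#'   \code{stems} (per-site planted stem coordinates, \code{NA} when none).
#' @export
simulateSequences <- function(truth, trueLevels, config = simConfig()) {
    lev <- if (is(trueLevels, "LevelMatrix")) editingLevels(trueLevels)
           else as.matrix(trueLevels)
    st <- truth$sites
    n <- nrow(st)
    L <- config$contig_len
    sp0 <- config$site_pos
    panel <- .simMirnaPanel()
    .withSubstream(config$rng_seed, "sequences", {
        base <- matrix(sample(.RNA, n * L, replace = TRUE,
                              prob = c(0.3, 0.2, 0.2, 0.3)), n, L)
        base[, sp0] <- "A"
        trip <- do.call(rbind, strsplit(st$motif_triplet, ""))
        base[, sp0 - 1L] <- trip[, 1]
        base[, sp0 + 1L] <- trip[, 3]

        # planted miRNA seed gains: write the near-match 8mer so the edited
        # (A->G) form equals rc(seed 2-8) + A; done before stem planting so
        # the second arm stays complementary to the final first arm
        gains <- which(st$seed_gain)
        for (i in gains) {
            mir <- panel$seq[panel$mirna_id == st$seed_mirna[i]]
            seed <- substr(mir, 2, 8)
            target <- paste0(.revCompRna(seed), "A")   # the 8mer site
            tb <- strsplit(target, "")[[1]]
            gpos <- which(tb == "G")
            gpos <- gpos[gpos <= 7]
            if (!length(gpos)) next
            k <- gpos[sample(length(gpos), 1L)]
            tb[k] <- "A"                                # the editable position
            s <- sp0 - k + 1L
            base[i, s:(s + 7L)] <- tb
            st$motif_triplet[i] <- paste0(base[i, sp0 - 1L], "A",
                                          base[i, sp0 + 1L])
        }

        stems <- data.frame(site_id = st$site_id,
                            arm1_start = NA_integer_, arm1_end = NA_integer_,
                            arm2_start = NA_integer_, arm2_end = NA_integer_,
                            n_p = st$n_p, dist_to_edge = NA_integer_)
        for (i in seq_len(n)) {
            if (!st$has_stem[i]) next
            np <- st$n_p[i]
            d <- sample(2:(np - 3L), 1L)          # site offset into the arm
            a1s <- sp0 - d; a1e <- a1s + np - 1L
            loop <- sample(4:12, 1L)
            a2s <- a1e + loop + 1L; a2e <- a2s + np - 1L
            if (a2e > L) {                         # fall back: arm upstream
                a2e <- a1s - loop - 1L; a2s <- a2e - np + 1L
            }
            a2lo <- min(a2s, a2e); a2hi <- max(a2s, a2e)
            arm1 <- base[i, a1s:a1e]
            base[i, a2lo:a2hi] <- rev(.rnaComplement[arm1])
            # poly-A loop: A cannot pair A, so the loop contributes no
            # chance pairs and planted features are exactly recoverable
            loopRange <- if (a2lo > a1e) (a1e + 1L):(a2lo - 1L)
                         else (a2hi + 1L):(a1s - 1L)
            loopRange <- loopRange[loopRange >= 1L & loopRange <= L]
            if (any(st$seed_gain[i]))
                loopRange <- loopRange[abs(loopRange - sp0) > 7L]
            base[i, loopRange] <- "A"
            # block single-base extension of the planted stem: A cannot
            # pair with A, so the stem ends exactly where planted
            block <- c(a1s - 1L, a1s - 2L, a1e + 1L, a1e + 2L,
                       a2lo - 1L, a2lo - 2L, a2hi + 1L, a2hi + 2L)
            for (fl in block) {
                if (fl < 1L || fl > L) next
                if (st$seed_gain[i] && abs(fl - sp0) <= 7L) next
                base[i, fl] <- "A"
            }
            stems$arm1_start[i] <- a1s; stems$arm1_end[i] <- a1e
            stems$arm2_start[i] <- a2lo
            stems$arm2_end[i] <- a2hi
            stems$dist_to_edge[i] <- min(sp0 - a1s, a1e - sp0)
        }

        species <- colnames(lev)
        seqs <- list()
        for (sp in species) {
            m <- base
            absent <- which(lev[, sp] == 0)
            for (i in absent) {
                if (runif(1) < 0.8)                    # degrade the motif
                    m[i, sp0 - 1L] <- "C"
                if (st$has_stem[i] && runif(1) < 0.8) { # scramble the ECS arm
                    idx <- stems$arm2_start[i]:stems$arm2_end[i]
                    hit <- sample(idx, min(10L, length(idx)))
                    m[i, hit] <- sample(.RNA, length(hit), replace = TRUE)
                }
            }
            ss <- Biostrings::RNAStringSet(apply(m, 1, paste, collapse = ""))
            names(ss) <- st$site_id
            seqs[[sp]] <- ss
        }
        gr <- GenomicRanges::GRanges(
            seqnames = st$site_id,
            ranges = IRanges::IRanges(start = sp0, width = 1L), strand = "+")
        S4Vectors::mcols(gr)$site_id <- st$site_id
        S4Vectors::mcols(gr)$category <- st$category
        S4Vectors::mcols(gr)$gene <- st$gene
        names(gr) <- st$site_id
        truth$sites <- st
        list(sequences = seqs, sites = gr, stems = stems, truth = truth)
    })
}

#' Simulate a conservation track with planted constrained windows
#'
#' Background scores are Beta(2,2) (mean 0.5). Sites of class \code{"high"}
#' get Beta(19,1) scores (mean 0.95) over both the S region (15 bp upstream
#' to 30 bp downstream of the site) and the two flanking 46-bp F regions;
#' \code{"moderate"} sites get the elevated S region only; \code{"none"}
#' sites are background everywhere.
#'
#' @param truth the truth list from [simulateLevels()]
#' @param config a [simConfig()]
#' @return a \linkS4class{ConservationTrack} over the per-site contigs
#' @export
simulateConservation <- function(truth, config = simConfig()) {
    st <- truth$sites
    L <- config$contig_len
    sp0 <- config$site_pos
    .withSubstream(config$rng_seed, "conservation", {
        scores <- list()
        for (i in seq_len(nrow(st))) {
            v <- rbeta(L, 2, 2)
            sreg <- (sp0 - 15L):(sp0 + 30L)
            freg <- c((sp0 - 15L - 46L):(sp0 - 16L), (sp0 + 31L):(sp0 + 76L))
            cls <- st$constraint_class[i]
            if (cls == "high") {
                v[sreg] <- rbeta(length(sreg), 19, 1)
                v[freg] <- rbeta(length(freg), 19, 1)
            } else if (cls == "moderate") {
                v[sreg] <- rbeta(length(sreg), 19, 1)
            }
            scores[[st$site_id[i]]] <- v
        }
        ConservationTrack(scores)
    })
}

#' Simulate gene expression shifts and the miRNA panel
#'
#' Control genes draw \code{log2fc ~ Normal(0, expression_sd)}; genes with
#' one edited 3'UTR site are shifted by \code{expression_shift}, and genes
#' with more than one by twice that, emulating the de-repression of
#' 3'UTR-edited transcripts when editing is removed.
#'
#' @param truth the truth list from [simulateLevels()]
#' @param config a [simConfig()]
#' @return a list with \code{expression} (data.frame gene, log2fc,
#'   mean_expr, true_log2fc) and \code{mirnas} (the bundled synthetic panel
#'   with expression fractions).
#' @export
simulateExpression <- function(truth, config = simConfig()) {
    g <- truth$genes
    .withSubstream(config$rng_seed, "expression", {
        shift <- ifelse(g$n_utr3_sites >= 2L, 2 * config$expression_shift,
                 ifelse(g$n_utr3_sites == 1L, config$expression_shift, 0))
        g$true_log2fc <- shift
        g$log2fc <- rnorm(nrow(g), shift, config$expression_sd)
        g$mean_expr <- round(2^rnorm(nrow(g), 7, 2), 2)
        list(expression = g[, c("gene", "log2fc", "mean_expr", "true_log2fc",
                                "n_utr3_sites", "utr3_edited")],
             mirnas = .simMirnaPanel())
    })
}
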