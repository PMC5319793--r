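#' Run the full editing-evolution pipeline on a synthetic dataset
#'
#' Chains every stage on data from the bundled generator: level simulation
#' and read sampling; variant calling, shared-site identification with
#' automatic frequency-cutoff selection, and FDR estimation against the
#' ADAR-null sample; level quantification and representative levels; motif
#' matrix, triplet scores and the cross-species motif asymmetry test; stem
#' (ECS) prediction and structural features; divergence matrix, NJ tree,
#' divergence-time regression, parsimony dating and clustering; constraint
#' classification and the functional-fraction estimate; random-forest
#' presence and level models; and the 3'UTR expression and miRNA seed-scan
#' analyses. Every output table is written to \code{out_dir} with a header
#' comment recording the package version, configuration hash and RNG seed.
#'
#' @param sim_config a [simConfig()]
#' @param config a [pipelineConfig()]
#' @param out_dir output directory (created if needed)
#' @param n_fold_sites cap on the number of sites folded per species (the
#'   costliest stage); \code{Inf} folds all
#' @return invisibly, a list with the main in-memory results
#' @export
runPipeline <- function(sim_config = simConfig(), config = pipelineConfig(),
                        out_dir = tempfile("editevol_run_"),
                        n_fold_sites = Inf) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    message("editevol pipeline: seed ", sim_config$rng_seed,
            ", config hash ", substr(configHash(config), 1, 8))
    tbl <- function(df, name) .writeResultTable(df, file.path(out_dir, name),
                                                config)

    ## --- simulate ---------------------------------------------------------
    sim <- simulateLevels(sim_config)
    truth <- sim$truth
    reads <- simulateReads(sim$levels, sim_config)
    seqres <- simulateSequences(truth, sim$levels, sim_config)
    truth <- seqres$truth
    track <- simulateConservation(truth, sim_config)
    expr <- simulateExpression(truth, sim_config)
    species <- colnames(editingLevels(sim$levels))
    anchor <- species[1]
    st <- truth$sites
    tbl(st, "sim_truth_sites.tsv")

    ## --- discovery --------------------------------------------------------
    wb <- function(sp) reads[reads$sample_id == paste0(sp, "_wb"), ]
    calls <- lapply(species, function(sp) callVariants(wb(sp),
                                                       config$min_alt_reads))
    names(calls) <- species
    ortho <- data.frame(site_id = st$site_id, species_a = anchor,
                        species_b = species[2], contig_b = st$site_id,
                        pos_b = NA_integer_, strand_flip = FALSE)
    shared <- identifySharedEditing(calls[[anchor]], calls[[species[2]]],
                                    ortho, grid = config$cutoff_grid,
                                    target = config$ag_fraction)
    tbl(shared$curve, "shared_variant_curve.tsv")
    tbl(shared$sites, "shared_sites.tsv")
    fdr <- estimateFdrWithNull(wb(anchor),
                               reads[reads$sample_id ==
                                     paste0(anchor, "_null"), ],
                               alpha = config$alpha,
                               min_alt_reads = config$fdr_min_alt_reads,
                               min_level = config$fdr_min_level)
    tbl(fdr$sites, "fdr_report.tsv")

    ## --- quantification ---------------------------------------------------
    lm_all <- quantifyLevels(reads, min_cov = config$min_cov_rnaseq)
    wbcols <- paste0(species, "_wb")
    lev <- editingLevels(lm_all)[, wbcols, drop = FALSE]
    cov <- coverages(lm_all)[, wbcols, drop = FALSE]
    colnames(lev) <- colnames(cov) <- species
    # representative level = max across the anchor species' datasets
    anchor_cols <- grep(paste0("^", species[1], "_(?!null)"),
                        colnames(lm_all), perl = TRUE, value = TRUE)
    rep_level <- representativeLevel(lm_all[, anchor_cols, drop = FALSE],
                                     config$min_cov_rnaseq)
    tbl(data.frame(site_id = names(rep_level),
                   representative_level = unname(rep_level)),
        "representative_levels.tsv")

    ## --- motif ------------------------------------------------------------
    aseq <- as.character(seqres$sequences[[anchor]])
    spos <- sim_config$site_pos
    tripletOf <- function(seqs) substr(seqs, spos - 1L, spos + 1L)
    high <- which(!is.na(lev[, anchor]) &
                  lev[, anchor] >= config$motif_high_level)
    motifs <- lapply(species, function(sp) {
        hs <- which(!is.na(lev[, sp]) & lev[, sp] >= config$motif_high_level)
        if (length(hs) < 5) return(NULL)
        buildMotifMatrix(tripletOf(as.character(
            seqres$sequences[[sp]]))[hs], config$motif_pseudocount)
    })
    motifs <- motifs[!vapply(motifs, is.null, TRUE)]
    avg <- averageMotifMatrix(motifs)
    scores <- scoreTriplets(avg)
    tbl(as.data.frame(motifProbs(avg)), "motif_matrix.tsv")
    tbl(scores, "triplet_scores.tsv")

    other <- species[length(species)]   # most diverged comparison
    pclass <- vapply(seq_len(nrow(st)), function(i) {
        if (is.na(lev[i, anchor]) || is.na(lev[i, other])) return("other")
        classifySitePair(lev[i, anchor], lev[i, other],
                         config$presence_level, config$absence_level)
    }, "")
    trip_a <- tripletOf(aseq)
    trip_o <- tripletOf(as.character(seqres$sequences[[other]]))
    pa <- pclass == "presence_absence"
    asym <- motifAsymmetryTest(tripletScore(trip_a[pa], scores),
                               tripletScore(trip_o[pa], scores))
    tbl(data.frame(comparison = paste(anchor, "vs", other),
                   n_pairs = sum(pa),
                   frac_higher_anchor = asym$frac_higher_anchor,
                   frac_higher_other = asym$frac_higher_other,
                   p = ifelse(is.na(asym$p), NA, asym$p)),
        "motif_asymmetry.tsv")

    ## --- structure --------------------------------------------------------
    foldFeats <- function(seqs) {
        idx <- seq_len(min(n_fold_sites, nrow(st)))
        rows <- lapply(idx, function(i) {
            cand <- foldWindow(seqs[i], spos, config$ecs_half_window)
            ecs <- findProximalEcs(cand, spos, config$ecs_min_paired,
                                   config$ecs_max_bulge)
            best <- if (!is.null(ecs)) ecs
                    else if (length(cand)) cand[[1]] else NULL
            if (is.null(best)) return(NULL)
            f <- try(extractFeatures(best, spos, seqs[i]), silent = TRUE)
            if (inherits(f, "try-error")) return(NULL)
            cbind(site_id = st$site_id[i], f, ecs_pass = !is.null(ecs))
        })
        do.call(rbind, rows)
    }
    feats_a <- foldFeats(as.character(seqres$sequences[[anchor]]))
    feats_o <- foldFeats(as.character(seqres$sequences[[other]]))
    tbl(feats_a, "ecs_features_anchor.tsv")

    ## --- evolution --------------------------------------------------------
    d <- divergenceMatrix(lev)
    write.table(d, file.path(out_dir, "divergence_matrix.tsv"),
                sep = "\t", quote = FALSE)
    tree <- buildNjTree(d)
    ape::write.tree(tree, file.path(out_dir, "nj_tree.nwk"))
    times <- ape::cophenetic.phylo(truth$tree)[species, species]
    ut <- upper.tri(d)
    reg <- divergenceTimeRegression(d[ut], times[ut])
    tbl(data.frame(slope = reg$slope, intercept = reg$intercept,
                   rho = reg$rho), "divergence_time_regression.tsv")

    ages <- vapply(seq_len(nrow(st)), function(i) {
        status <- vapply(species, function(sp) {
            callEditingStatus(lev[i, sp], cov[i, sp],
                              edited_level = config$edited_level,
                              absence_level = config$absence_level,
                              min_cov = config$min_cov_rnaseq)
        }, "")
        if (status[1] != "edited") return(NA_character_)
        a <- assignAge(status, config$min_defined_species - 1L)
        if (a$dated) a$age else NA_character_
    }, "")
    age_tab <- data.frame(site_id = st$site_id, age = ages)
    tbl(age_tab, "site_ages.tsv")
    dated <- !is.na(ages)
    if (any(dated)) {
        cf <- clusterFraction(st$genomic_pos[dated], max_dist = 30L,
                              groups = ages[dated], n_boot = 200L)
        tbl(cf, "cluster_fractions.tsv")
    }

    ## --- constraint -------------------------------------------------------
    siteTab <- data.frame(site_id = st$site_id, contig = st$site_id,
                          pos = spos)
    cons <- classifyConstraint(track, siteTab, alpha = config$alpha)
    tbl(cons, "constraint_calls.tsv")
    ff <- functionalFraction(cons$class, rep_level[st$site_id],
                             low_cutoff = config$absence_level)
    tbl(data.frame(excess = ff$excess, frac_edited = ff$frac_edited,
                   frac_low = ff$frac_low, p = ff$p),
        "functional_fraction.tsv")

    ## --- random forest ----------------------------------------------------
    pairs <- data.frame(site_id = st$site_id, class = pclass,
                        anchor_level = lev[, anchor],
                        other_level = lev[, other],
                        motif_anchor = tripletScore(trip_a, scores),
                        motif_other = tripletScore(trip_o, scores))
    rf_out <- list()
    rows_cls <- try(assembleFeatures(pairs, feats_a, feats_o,
                                     "presence_absence"), silent = TRUE)
    if (!inherits(rows_cls, "try-error") &&
        nlevels(droplevels(rows_cls$outcome)) == 2L) {
        rf_out$presence <- fitPresenceModel(rows_cls, config$rf_ntree,
                                            config$rf_mtry,
                                            seed = config$rng_seed)
        tbl(rf_out$presence$importance, "rf_presence_importance.tsv")
    }
    rows_reg <- try(assembleFeatures(pairs, feats_a, feats_o,
                                     "presence_presence"), silent = TRUE)
    if (!inherits(rows_reg, "try-error") && nrow(rows_reg) >= 20L &&
        var(rows_reg$outcome) > 0) {
        cmp <- compareModels(rows_reg, n_refits = 5L,
                             ntree = config$rf_ntree, mtry = config$rf_mtry,
                             seed = config$rng_seed)
        rf_out$level_comparison <- cmp
        tbl(data.frame(r2_full = cmp$r2_full, r2_reduced = cmp$r2_reduced,
                       delta_r2 = cmp$delta_r2,
                       lo = cmp$interval[1], hi = cmp$interval[2]),
            "rf_model_comparison.tsv")
    }

    ## --- 3'UTR ------------------------------------------------------------
    g <- expr$expression
    site_ok <- !is.na(lev[, anchor]) & lev[, anchor] > config$utr3_min_level
    utr3_genes <- unique(st$gene[st$category == "3UTR" & site_ok])
    multi <- names(which(table(st$gene[st$category == "3UTR" & site_ok]) > 1))
    elsewhere <- setdiff(unique(st$gene[site_ok]), utr3_genes)
    g$group <- ifelse(g$gene %in% multi, "utr3_multi_site",
               ifelse(g$gene %in% utr3_genes, "utr3_one_site",
               ifelse(g$gene %in% elsewhere, "control", NA)))
    gg <- g[!is.na(g$group), ]
    cmp_expr <- groupExpressionComparison(gg)
    tbl(cmp_expr, "utr3_expression_comparison.tsv")

    seedrows <- list()
    # scan sites present in the anchor (absent sites have their planted
    # properties degraded by construction)
    true_anchor <- editingLevels(sim$levels)[, anchor]
    gain_sites <- which(st$seed_gain & true_anchor > 0)
    for (i in utils::head(gain_sites, 25)) {
        utr <- substr(aseq[i], spos - 30L, spos + 30L)
        sc <- scanMirnaSeedChanges(utr, 31L, expr$mirnas,
                                   config$mirna_min_fraction)
        if (nrow(sc)) {
            sc$site_id <- st$site_id[i]
            seedrows[[length(seedrows) + 1L]] <- sc
        }
    }
    seed_tab <- if (length(seedrows)) do.call(rbind, seedrows)
                else data.frame()
    tbl(seed_tab, "mirna_seed_changes.tsv")

    invisible(list(truth = truth, levels = lev, coverages = cov,
                   shared = shared, fdr = fdr, scores = scores,
                   asymmetry = asym, divergence = d, tree = tree,
                   regression = reg, ages = age_tab, constraint = cons,
                   functional_fraction = ff, rf = rf_out,
                   expression = cmp_expr, seed_changes = seed_tab,
                   out_dir = out_dir))
}
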