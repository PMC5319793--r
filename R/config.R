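#' Pipeline configuration with standard thresholds
#'
#' Collects every tunable threshold of the pipeline in one serializable list.
#' Defaults are the values used throughout the analyses: variant calls need
#' >= 2 supporting reads; FDR candidates need > 2 altered reads and level
#' >= 1.5\%; the shared-variant frequency cutoff is chosen so the A-to-G
#' fraction reaches 80\%; coverage minima are 20 (RNA-seq) and 50 (mmPCR-seq)
#' reads; presence/absence calls use 10\% / 1.5\%; the edited-status call uses
#' 2\%; the assumed A-to-G sequencing error rate is 1\%; motif matrices are
#' built from sites edited >= 50\%; conservation smoothing uses a 51-bp
#' window and constraint profiling a 30-bp window over +/- 60 bp flanks;
#' proximal ECS search folds +/- 200 bp and keeps stems with >= 20 paired
#' bases and max bulge 8; distal ECS search scans 2,500 bp for blocks >= 20
#' bases with smoothed conservation >= 0.90; random forests use 1,000 trees
#' (set \code{rf_ntree = 10000} for the heavyweight setting) with 3 features
#' per split.
#'
#' @param ... named overrides of any default, e.g.
#'   \code{pipelineConfig(min_cov_rnaseq = 10)}.
#' @param yaml optional path to a YAML file of overrides (applied before
#'   \code{...}).
#' @return a named list of class \code{"PipelineConfig"}.
#' @examples
#' cfg <- pipelineConfig(rng_seed = 7)
#' cfg$presence_level
#' @export
pipelineConfig <- function(..., yaml = NULL) {
    cfg <- list(
        min_alt_reads      = 2L,     # variant call support
        fdr_min_alt_reads  = 3L,     # "more than two altered reads"
        fdr_min_level      = 0.015,
        ag_fraction        = 0.80,
        cutoff_grid        = c(0.01, 0.015, 0.02, 0.03, 0.05, 0.10, 0.15, 0.20),
        min_cov_rnaseq     = 20L,
        min_cov_mmpcr      = 50L,
        mmpcr_rep_max_diff = 0.10,
        presence_level     = 0.10,
        absence_level      = 0.015,
        edited_level       = 0.02,
        error_rate         = 0.01,
        motif_high_level   = 0.50,
        motif_pseudocount  = 0.5,
        smooth_window      = 51L,
        profile_window     = 30L,
        profile_flank      = 60L,
        s_up               = 15L,
        s_down             = 30L,
        f_len              = 46L,
        ecs_half_window    = 200L,
        ecs_min_paired     = 20L,
        ecs_max_bulge      = 8L,
        distal_max_dist    = 2500L,
        distal_min_len     = 20L,
        distal_min_score   = 0.90,
        rf_ntree           = 1000L,
        rf_mtry            = 3L,
        alpha              = 0.05,
        min_defined_species = 5L,
        utr3_min_level     = 0.05,
        mirna_min_fraction = 0.001,
        de_min_abs_log2fc  = 0.2,
        rng_seed           = 1L
    )
    if (!is.null(yaml)) {
        ov <- yaml::read_yaml(yaml)
        cfg[names(ov)] <- ov
    }
    dots <- list(...)
    if (length(dots)) {
        bad <- setdiff(names(dots), names(cfg))
        if (length(bad))
            stop("unknown config field(s): ", paste(bad, collapse = ", "))
        cfg[names(dots)] <- dots
    }
    class(cfg) <- "PipelineConfig"
    cfg
}

#' Stable hash of a configuration
#'
#' Used to stamp output tables so results can be traced to the exact
#' thresholds that produced them.
#'
#' @param cfg a \code{PipelineConfig} (or any serializable list)
#' @return an md5 hex string
#' @export
configHash <- function(cfg) {
    tf <- tempfile()
    on.exit(unlink(tf))
    writeLines(yaml::as.yaml(unclass(cfg)), tf)
    unname(tools::md5sum(tf))
}

#' @export
print.PipelineConfig <- function(x, ...) {
    cat("PipelineConfig (hash ", substr(configHash(x), 1, 8), ")\n", sep = "")
    str(unclass(x), give.attr = FALSE)
    invisible(x)
}

#' @importFrom utils str
NULL
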