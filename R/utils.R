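# Internal helpers: RNG substreams, alphabet handling, table stamping.

# One global seed; per-module substreams derived by hashing module name + seed
# so that regenerating one table never perturbs another.
.substreamSeed <- function(seed, module) {
    h <- 0
    for (k in utf8ToInt(module)) h <- (h * 131 + k) %% 2147483647
    as.integer((h + as.numeric(seed) * 48271) %% 2147483647)
}

.withSubstream <- function(seed, module, expr) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    set.seed(.substreamSeed(seed, module))
    on.exit({
        if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
    })
    force(expr)
}

.RNA <- c("A", "C", "G", "U")

# DNA input T is mapped to U: sequence-dependent operations work on the
# transcribed (sense) strand in the RNA alphabet.
.toRna <- function(x) chartr("Tt", "Uu", toupper(as.character(x)))

.rnaComplement <- c(A = "U", C = "G", G = "C", U = "A", N = "N")

.revCompRna <- function(x) {
    paste(rev(.rnaComplement[strsplit(.toRna(x), "")[[1]]]), collapse = "")
}

# Is (b1, b2) a valid pair? Returns "WC", "GU" or NA.
.pairType <- function(b1, b2) {
    wc <- (b1 == "A" & b2 == "U") | (b1 == "U" & b2 == "A") |
          (b1 == "C" & b2 == "G") | (b1 == "G" & b2 == "C")
    gu <- (b1 == "G" & b2 == "U") | (b1 == "U" & b2 == "G")
    ifelse(wc, "WC", ifelse(gu, "GU", NA_character_))
}

# Write a result table with a header comment recording provenance.
.writeResultTable <- function(df, path, cfg = NULL) {
    con <- file(path, "w")
    on.exit(close(con))
    hash <- if (is.null(cfg)) "none" else configHash(cfg)
    writeLines(sprintf("# editevol %s config=%s seed=%s",
                       as.character(utils::packageVersion("editevol")), hash,
                       if (is.null(cfg)) "NA" else cfg$rng_seed), con)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

.assertProb <- function(x, name) {
    if (any(x < 0 | x > 1, na.rm = TRUE))
        stop(name, " must lie in [0, 1]")
    invisible(x)
}
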