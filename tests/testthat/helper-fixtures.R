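# In-code fixtures shared across test files.

tinyCorpus <- function() {
    BgcCorpus(list(
        bgcA = c("PF1;PF2", "-", "PF3", "PF4"),
        bgcB = c("PF1;PF2", "PF3", "PF5"),
        bgcC = c("PF4", "PF3", "PF1;PF2")
    ))
}

# Random corpus of single-domain tokens for round-trip / property tests.
randomCorpus <- function(nBgcs, vocabSize = 40L, seed = 1L) {
    set.seed(seed)
    vocab <- sprintf("PF%05d", seq_len(vocabSize))
    tokens <- lapply(seq_len(nBgcs), function(i) {
        n <- sample(2:10, 1)
        tok <- sample(c(vocab, "-"), n, replace = TRUE)
        if (all(tok == "-")) tok[1] <- vocab[1]
        tok
    })
    names(tokens) <- sprintf("RB%04d", seq_len(nBgcs))
    BgcCorpus(tokens)
}

# Minimal antiSMASH-flavoured region GenBank text.
writeTestGenBank <- function(path, genes, contigEdge = FALSE,
                             product = "NRPS") {
    lines <- c(
        "LOCUS       test_region         9000 bp    DNA     linear   BCT",
        "DEFINITION  synthetic test region.",
        "FEATURES             Location/Qualifiers",
        "     region          1..9000",
        sprintf('                     /contig_edge="%s"',
                if (contigEdge) "True" else "False"),
        sprintf('                     /product="%s"', product))
    for (i in seq_len(nrow(genes))) {
        loc <- sprintf("%d..%d", genes$start[i], genes$end[i])
        if (!is.null(genes$strand) && genes$strand[i] < 0)
            loc <- sprintf("complement(%s)", loc)
        lines <- c(lines,
            sprintf("     CDS             %s", loc),
            sprintf('                     /locus_tag="%s"', genes$gene_id[i]))
    }
    lines <- c(lines, "ORIGIN", "//")
    writeLines(lines, path)
    invisible(path)
}

randomHits <- function(n, seed = 1L) {
    set.seed(seed)
    starts <- sample(1:300, n, replace = TRUE)
    data.frame(
        gene_id = sprintf("gene%02d", sample(1:8, n, replace = TRUE)),
        domain_accession = sprintf("PF%05d", sample(1:30, n, replace = TRUE)),
        ali_start = starts,
        ali_end = starts + sample(20:80, n, replace = TRUE),
        bitscore = round(runif(n, 20, 300), 1),
        i_evalue = signif(10^runif(n, -30, -4), 2),
        stringsAsFactors = FALSE)
}
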