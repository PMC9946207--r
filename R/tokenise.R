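## Tokenisation and corpus I/O: HMMER3 domtblout parsing, antiSMASH-style
## GenBank CDS extraction, gene tokenisation, corpus-level filters and the
## cluster-file format.

#' Parse an HMMER3 \code{--domtblout} domain table
#'
#' Reads per-domain hits from an \code{hmmscan --domtblout} file. In the
#' hmmscan orientation the target is the profile HMM (the domain model) and
#' the query is the protein, so \code{domain_accession} is taken from the
#' target name column and \code{gene_id} from the query name column. Hits
#' with an independent E-value above \code{maxIEvalue} are discarded.
#'
#' @param path Path to a domtblout file.
#' @param maxIEvalue Maximum independent (i-)E-value for a domain hit to be
#'   retained. The upstream hmmscan convention is not standardised; 0.001 is
#'   a conservative default and can be relaxed to match any pipeline.
#' @return A data.frame with columns \code{gene_id}, \code{domain_accession},
#'   \code{ali_start}, \code{ali_end}, \code{bitscore}, \code{i_evalue}.
#' @seealso \code{\link{tokeniseBgc}}, \code{\link{writeDomtbl}}
#' @export
parseDomtbl <- function(path, maxIEvalue = 0.001) {
    if (!file.exists(path)) stop("domtblout file not found: ", path)
    lines <- readLines(path)
    keep <- !grepl("^#", lines) & nzchar(trimws(lines))
    lineno <- which(keep)
    lines <- lines[keep]
    if (length(lines) == 0L) {
        return(data.frame(gene_id = character(0),
                          domain_accession = character(0),
                          ali_start = integer(0), ali_end = integer(0),
                          bitscore = numeric(0), i_evalue = numeric(0),
                          stringsAsFactors = FALSE))
    }
    fields <- strsplit(trimws(lines), "[ \t]+")
    nf <- vapply(fields, length, integer(1))
    if (any(nf < 22L)) {
        bad <- lineno[which(nf < 22L)[1]]
        stop("malformed domtblout row at line ", bad,
             ": expected >= 22 whitespace-separated fields")
    }
    getcol <- function(i) vapply(fields, `[[`, character(1), i)
    suppressWarnings({
        ali_start <- as.integer(getcol(18))
        ali_end <- as.integer(getcol(19))
        bitscore <- as.numeric(getcol(14))
        i_evalue <- as.numeric(getcol(13))
    })
    bad <- which(is.na(ali_start) | is.na(ali_end) | is.na(bitscore) |
                 is.na(i_evalue))
    if (length(bad))
        stop("malformed domtblout row at line ", lineno[bad[1]],
             ": non-numeric coordinate/score fields")
    hits <- data.frame(
        gene_id = getcol(4),
        domain_accession = getcol(1),
        ali_start = ali_start,
        ali_end = ali_end,
        bitscore = bitscore,
        i_evalue = i_evalue,
        stringsAsFactors = FALSE)
    hits[hits$i_evalue <= maxIEvalue, , drop = FALSE]
}

#' Parse CDS features from an antiSMASH-style GenBank region file
#'
#' A minimal feature-table reader sufficient for antiSMASH region files: it
#' extracts CDS features (gene id from \code{locus_tag}, falling back to
#' \code{protein_id} then \code{gene}), their genomic start/end, and the
#' region-level \code{contig_edge} and \code{product} qualifiers.
#'
#' @param path Path to a GenBank file containing one region/cluster.
#' @return A list with elements \code{genes} (data.frame \code{gene_id},
#'   \code{start}, \code{end}, ordered by \code{start}), \code{contig_edge}
#'   (logical) and \code{product} (character, possibly \code{NA}).
#' @export
parseRegionGenBank <- function(path) {
    if (!file.exists(path)) stop("GenBank file not found: ", path)
    lines <- readLines(path)
    fstart <- grep("^FEATURES", lines)
    if (length(fstart) == 0L) stop("no FEATURES table in ", path)
    fend <- grep("^(ORIGIN|//)", lines)
    fend <- if (length(fend)) min(fend[fend > fstart[1]]) else length(lines) + 1L
    feat <- lines[(fstart[1] + 1L):(fend - 1L)]

    ## A new feature starts at column 6 with a key; qualifiers start with '/'
    key_idx <- grep("^ {2,6}\\S", feat)
    keys <- sub("^\\s*(\\S+).*$", "\\1", feat[key_idx])
    bounds <- c(key_idx, length(feat) + 1L)

    genes <- list()
    contig_edge <- FALSE
    product <- NA_character_
    for (i in seq_along(key_idx)) {
        block <- feat[key_idx[i]:(bounds[i + 1L] - 1L)]
        key <- keys[i]
        loc <- sub("^\\s*\\S+\\s+", "", block[1])
        quals <- paste(block[-1], collapse = " ")
        qual1 <- function(name) {
            m <- regmatches(quals,
                regexpr(sprintf('/%s="?[^"/]*', name), quals))
            if (length(m) == 0L) return(NA_character_)
            sub(sprintf('^/%s="?', name), "", m[1])
        }
        if (key %in% c("region", "cluster", "cand_cluster", "protocluster")) {
            ce <- qual1("contig_edge")
            if (!is.na(ce) && tolower(trimws(ce)) == "true") contig_edge <- TRUE
            pr <- qual1("product")
            if (is.na(product) && !is.na(pr)) product <- trimws(pr)
        } else if (key == "CDS") {
            nums <- regmatches(loc, gregexpr("[0-9]+", loc))[[1]]
            if (length(nums) < 2L) next
            gid <- qual1("locus_tag")
            if (is.na(gid)) gid <- qual1("protein_id")
            if (is.na(gid)) gid <- qual1("gene")
            if (is.na(gid)) next
            genes[[length(genes) + 1L]] <- data.frame(
                gene_id = trimws(gid),
                start = as.integer(nums[1]),
                end = as.integer(nums[length(nums)]),
                stringsAsFactors = FALSE)
        }
    }
    genes <- if (length(genes)) do.call(rbind, genes) else
        data.frame(gene_id = character(0), start = integer(0),
                   end = integer(0), stringsAsFactors = FALSE)
    genes <- genes[order(genes$start, genes$end, genes$gene_id), ,
                   drop = FALSE]
    rownames(genes) <- NULL
    list(genes = genes, contig_edge = contig_edge, product = product)
}

#' Tokenise one BGC from its genes and domain hits
#'
#' Converts each gene into the ordered string of its biosynthetic domains.
#' Per gene, hits whose accession is in \code{biosynDomains} are kept and
#' ordered along the protein by alignment start (ties broken by alignment
#' end, then by accession text); repeated identical accessions within a gene
#' are collapsed to one occurrence at their first alignment start. A gene
#' with no retained domain becomes the empty token \code{"-"}. Gene order
#' follows genomic start coordinate.
#'
#' @param genes data.frame with columns \code{gene_id}, \code{start},
#'   \code{end} (as from \code{\link{parseRegionGenBank}}).
#' @param hits data.frame of domain hits (as from \code{\link{parseDomtbl}}).
#' @param biosynDomains Character vector of biosynthetic domain accessions;
#'   hits outside this set are dropped. \code{NULL} keeps all domains.
#' @return Character vector of gene tokens, one per gene, in genomic order.
#' @export
tokeniseBgc <- function(genes, hits, biosynDomains = NULL) {
    unknown <- setdiff(unique(hits$gene_id), genes$gene_id)
    if (length(unknown))
        stop("domain hit(s) reference unknown gene(s): ",
             paste(head(unknown, 5), collapse = ", "))
    ord <- order(genes$start, genes$end, genes$gene_id)
    genes <- genes[ord, , drop = FALSE]
    if (!is.null(biosynDomains))
        hits <- hits[hits$domain_accession %in% biosynDomains, , drop = FALSE]
    vapply(genes$gene_id, function(g) {
        h <- hits[hits$gene_id == g, , drop = FALSE]
        if (nrow(h) == 0L) return("-")
        ## order along the protein; repeated accessions collapse to their
        ## first (earliest-start) occurrence
        h <- h[order(h$ali_start, h$ali_end, h$domain_accession), ,
               drop = FALSE]
        h <- h[!duplicated(h$domain_accession), , drop = FALSE]
        paste(h$domain_accession, collapse = ";")
    }, character(1), USE.NAMES = FALSE)
}

#' Tokenise a directory of region GenBank files with their domain tables
#'
#' Convenience wrapper pairing each region GenBank file with a domtblout of
#' the same base name, applying \code{\link{tokeniseBgc}} and assembling a
#' corpus. BGCs flagged as lying on a contig edge are excluded by default,
#' since fragmented regions yield unreliable token sequences.
#'
#' @param gbkDir Directory of \code{.gbk}/\code{.gb} region files.
#' @param domtblDir Directory of matching \code{.domtbl}/\code{.txt} files
#'   (same base name as the GenBank file).
#' @param biosynDomains Character vector of biosynthetic domain accessions,
#'   e.g. from \code{\link{readDomainList}}.
#' @param maxIEvalue Passed to \code{\link{parseDomtbl}}.
#' @param includeContigEdge Keep contig-edge BGCs (default \code{FALSE}).
#' @return A \code{\linkS4class{BgcCorpus}}; BGC ids are the GenBank base
#'   names.
#' @export
tokeniseDirectory <- function(gbkDir, domtblDir, biosynDomains = NULL,
                              maxIEvalue = 0.001,
                              includeContigEdge = FALSE) {
    gbks <- list.files(gbkDir, pattern = "\\.(gbk|gb|gbff)$",
                       full.names = TRUE)
    if (length(gbks) == 0L) stop("no GenBank files in ", gbkDir)
    tokens <- list(); cls <- character(0); edge <- logical(0)
    for (gbk in gbks) {
        base <- sub("\\.[^.]+$", "", basename(gbk))
        cand <- file.path(domtblDir, paste0(base, c(".domtbl", ".txt")))
        dtab <- cand[file.exists(cand)]
        if (length(dtab) == 0L)
            stop("no domtblout found for region ", base, " in ", domtblDir)
        region <- parseRegionGenBank(gbk)
        if (region$contig_edge && !includeContigEdge) next
        hits <- parseDomtbl(dtab[1], maxIEvalue = maxIEvalue)
        hits <- hits[hits$gene_id %in% region$genes$gene_id, , drop = FALSE]
        tokens[[base]] <- tokeniseBgc(region$genes, hits, biosynDomains)
        cls <- c(cls, if (is.na(region$product)) NA_character_ else
            region$product)
        edge <- c(edge, region$contig_edge)
    }
    if (length(tokens) == 0L) stop("all BGCs were excluded (contig edge?)")
    BgcCorpus(tokens, biosynClass = cls, contigEdge = edge)
}

#' Read a plain-text domain accession list
#'
#' One accession per line; blank lines and lines starting with \code{#} are
#' ignored.
#' @param path File path.
#' @return Character vector of accessions.
#' @export
readDomainList <- function(path) {
    x <- trimws(readLines(path))
    x[nzchar(x) & !startsWith(x, "#")]
}

#' Filter a corpus by domain frequency and BGC informativeness
#'
#' Applies the two corpus-level filters once, in order: (1) domains occurring
#' fewer than \code{minDomainCount} times corpus-wide are deleted from every
#' token (a token emptied this way becomes \code{"-"}); (2) BGCs left with
#' fewer than \code{minNonemptyGenes} non-empty genes are removed. Counts are
#' computed on the input corpus, so the operation is idempotent.
#'
#' @param corpus A \code{\linkS4class{BgcCorpus}}.
#' @param minDomainCount Minimum corpus-wide domain occurrence count
#'   (default 3).
#' @param minNonemptyGenes Minimum non-empty genes per BGC (default 2).
#' @return The filtered \code{BgcCorpus}.
#' @export
filterCorpus <- function(corpus, minDomainCount = 3L,
                         minNonemptyGenes = 2L) {
    if (nBgc(corpus) == 0L) stop("empty corpus")
    counts <- domainCounts(corpus)
    keepDom <- names(counts)[counts >= minDomainCount]
    newTok <- lapply(corpus@tokens, function(tok) {
        vapply(tok, function(t) {
            if (t == "-") return("-")
            doms <- strsplit(t, ";", fixed = TRUE)[[1]]
            doms <- doms[doms %in% keepDom]
            if (length(doms) == 0L) "-" else paste(doms, collapse = ";")
        }, character(1), USE.NAMES = FALSE)
    })
    nne <- vapply(newTok, function(t) sum(t != "-"), integer(1))
    keep <- nne >= minNonemptyGenes
    if (!any(keep)) stop("no BGC passes the non-empty-gene filter")
    new("BgcCorpus",
        tokens = newTok[keep],
        biosynClass = corpus@biosynClass[keep],
        strain = corpus@strain[keep],
        contigEdge = corpus@contigEdge[keep])
}

#' Read / write the cluster-file format
#'
#' The cluster file is a headerless UTF-8 CSV: one BGC per line,
#' \code{bgc_id,gene1,gene2,...}, domains within a gene joined by \code{";"},
#' an empty gene written as \code{"-"}. \code{","} and \code{";"} are
#' reserved and may not occur inside accession text. Optional metadata
#' (class, strain) travels in a sidecar summary written by
#' \code{\link{writeCorpusSummary}}; the cluster file itself carries only
#' tokens, so write-then-read is the identity on tokens and ids bit-exactly.
#'
#' @param path File path.
#' @return \code{readClusterFile} returns a \code{\linkS4class{BgcCorpus}}.
#' @export
readClusterFile <- function(path) {
    if (!file.exists(path)) stop("cluster file not found: ", path)
    lines <- readLines(path, encoding = "UTF-8")
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0L) stop("empty cluster file: ", path)
    parts <- strsplit(lines, ",", fixed = TRUE)
    short <- which(vapply(parts, length, integer(1)) < 2L)
    if (length(short))
        stop("malformed cluster-file line ", short[1],
             ": need an id and at least one gene")
    ids <- vapply(parts, `[[`, character(1), 1)
    if (anyDuplicated(ids))
        stop("duplicate bgc_id in cluster file: ",
             ids[duplicated(ids)][1])
    tokens <- lapply(parts, function(p) p[-1])
    names(tokens) <- ids
    BgcCorpus(tokens)
}

#' @rdname readClusterFile
#' @param corpus A \code{\linkS4class{BgcCorpus}} to write.
#' @return \code{writeClusterFile} returns \code{path} invisibly.
#' @export
writeClusterFile <- function(corpus, path) {
    bad <- vapply(corpus@tokens, function(tok) any(grepl(",", tok,
        fixed = TRUE)), logical(1))
    if (any(bad))
        stop("token contains reserved character ',' in BGC ",
             names(corpus@tokens)[bad][1])
    if (any(grepl("[,;]", names(corpus@tokens))))
        stop("bgc_id contains a reserved character (',' or ';')")
    lines <- vapply(seq_along(corpus@tokens), function(i) {
        paste(c(names(corpus@tokens)[i], corpus@tokens[[i]]),
              collapse = ",")
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
    invisible(path)
}

#' Summarise a corpus per BGC
#'
#' @param corpus A \code{\linkS4class{BgcCorpus}}.
#' @return data.frame with columns \code{bgc_id}, \code{n_genes},
#'   \code{n_nonempty}, \code{class}, \code{strain}.
#' @export
corpusSummary <- function(corpus) {
    data.frame(
        bgc_id = names(corpus@tokens),
        n_genes = vapply(corpus@tokens, length, integer(1)),
        n_nonempty = vapply(corpus@tokens, function(t) sum(t != "-"),
                            integer(1)),
        class = corpus@biosynClass,
        strain = corpus@strain,
        stringsAsFactors = FALSE, row.names = NULL)
}

#' @rdname corpusSummary
#' @param path Output TSV path.
#' @export
writeCorpusSummary <- function(corpus, path) {
    utils::write.table(corpusSummary(corpus), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}
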