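## Synthetic fixtures: tokenised corpora with planted sub-clusters and
## paired strain presence matrices with planted links, each with machine-
## readable ground truth, so the whole pipeline is testable without any
## external data.

#' Generate a synthetic tokenised corpus with planted sub-clusters
#'
#' Emulates the co-evolving-gene structure the detection methods target:
#' a dedicated token block (\code{SC<k>_T<j>}) per planted sub-cluster,
#' disjoint between sub-clusters, with each BGC built as the union of 1-3
#' planted sub-clusters plus \code{Poisson(noiseRate)} noise genes drawn
#' from a separate noise vocabulary (\code{NOISE_<j>}, sized five times the
#' planted vocabulary). With probability \code{pContig} a planted
#' sub-cluster's genes stay contiguous in the BGC (adjacency signal);
#' otherwise they are interleaved with the other genes (co-localisation
#' signal only). Experimentally characterised sub-clusters span roughly
#' 2-12 genes; the default size range 3-6 sits in that band. A fraction
#' \code{dupFrac} of BGCs is duplicated verbatim (id suffix \code{_dup}) to
#' exercise the redundancy filter.
#'
#' @param nBgcs Number of (pre-duplication) BGCs.
#' @param nPlanted Number of planted sub-clusters (>= 2).
#' @param noiseRate Poisson mean of noise genes per BGC.
#' @param pContig Probability that a planted sub-cluster is laid out
#'   contiguously.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @param sizeRange Inclusive range of planted sub-cluster sizes
#'   (default 3:6).
#' @param dupFrac Fraction of BGCs duplicated verbatim (default 0.1).
#' @return A list with \code{corpus} (a \code{\linkS4class{BgcCorpus}}),
#'   \code{planted} (data.frame \code{subcluster_id}, \code{tokens} list
#'   column) and \code{groundTruth} (data.frame \code{bgc_id},
#'   \code{subcluster_id}, \code{contiguous}, list column
#'   \code{gene_indices}).
#' @export
generateCorpus <- function(nBgcs, nPlanted, noiseRate, pContig, seed = 1L,
                           sizeRange = c(3L, 6L), dupFrac = 0.1) {
    if (nPlanted < 2L) stop("need at least 2 planted sub-clusters")
    if (nBgcs < 1L) stop("need at least 1 BGC")
    if (pContig < 0 || pContig > 1 || noiseRate < 0)
        stop("impossible parameters")
    withSeed(seed, {
        sizes <- sample(sizeRange[1]:sizeRange[2], nPlanted, replace = TRUE)
        planted <- lapply(seq_len(nPlanted), function(k)
            sprintf("SC%d_T%d", k, seq_len(sizes[k])))
        noiseVocab <- sprintf("NOISE_%d", seq_len(5L * sum(sizes)))

        tokens <- list()
        gt <- list()
        for (b in seq_len(nBgcs)) {
            id <- sprintf("BGC%04d", b)
            nsub <- sample(1:3, 1)
            subs <- sample.int(nPlanted, min(nsub, nPlanted))
            contig <- runif(length(subs)) < pContig
            nNoise <- rpois(1, noiseRate)
            noise <- if (nNoise > 0)
                sample(noiseVocab, nNoise, replace = TRUE) else character(0)

            ## blocks: contiguous sub-clusters stay whole; interleaved ones
            ## and noise genes are single-gene blocks, then block order is
            ## shuffled
            blocks <- list(); blockSub <- integer(0)
            for (si in seq_along(subs)) {
                if (contig[si]) {
                    blocks[[length(blocks) + 1L]] <- planted[[subs[si]]]
                    blockSub <- c(blockSub, subs[si])
                } else {
                    for (tk in planted[[subs[si]]]) {
                        blocks[[length(blocks) + 1L]] <- tk
                        blockSub <- c(blockSub, subs[si])
                    }
                }
            }
            for (tk in noise) {
                blocks[[length(blocks) + 1L]] <- tk
                blockSub <- c(blockSub, NA_integer_)
            }
            ord <- sample.int(length(blocks))
            blocks <- blocks[ord]; blockSub <- blockSub[ord]
            toks <- unlist(blocks, use.names = FALSE)
            tokens[[id]] <- toks

            pos <- cumsum(lengths(blocks)) - lengths(blocks) + 1L
            for (si in seq_along(subs)) {
                idxs <- unlist(lapply(which(blockSub == subs[si]),
                    function(bi) pos[bi]:(pos[bi] + length(blocks[[bi]]) - 1L)))
                gt[[length(gt) + 1L]] <- list(
                    bgc_id = id,
                    subcluster_id = sprintf("PSC%02d", subs[si]),
                    contiguous = contig[si],
                    gene_indices = sort(idxs))
            }
        }
        nDup <- floor(dupFrac * nBgcs)
        if (nDup > 0) {
            dupIds <- names(tokens)[sample.int(nBgcs, nDup)]
            for (id in dupIds) {
                did <- paste0(id, "_dup")
                tokens[[did]] <- tokens[[id]]
                for (g in gt) if (g$bgc_id == id) {
                    g$bgc_id <- did
                    gt[[length(gt) + 1L]] <- g
                }
            }
        }
        gtDf <- data.frame(
            bgc_id = vapply(gt, `[[`, character(1), "bgc_id"),
            subcluster_id = vapply(gt, `[[`, character(1), "subcluster_id"),
            contiguous = vapply(gt, `[[`, logical(1), "contiguous"),
            stringsAsFactors = FALSE)
        gtDf$gene_indices <- lapply(gt, `[[`, "gene_indices")
        plantedDf <- data.frame(
            subcluster_id = sprintf("PSC%02d", seq_len(nPlanted)),
            stringsAsFactors = FALSE)
        plantedDf$tokens <- planted
        list(corpus = BgcCorpus(tokens), planted = plantedDf,
             groundTruth = gtDf)
    })
}

#' Write corpus ground truth to TSV
#'
#' @param gt Ground-truth data.frame from \code{\link{generateCorpus}}.
#' @param path Output path.
#' @export
writeGroundTruthTsv <- function(gt, path) {
    flat <- data.frame(
        bgc_id = gt$bgc_id,
        subcluster_id = gt$subcluster_id,
        contiguous = gt$contiguous,
        gene_indices = vapply(gt$gene_indices, paste, character(1),
                              collapse = ";"),
        stringsAsFactors = FALSE)
    utils::write.table(flat, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Generate a paired genomic/metabolomic strain presence dataset
#'
#' Creates two strain-by-feature presence matrices with \code{nLinks}
#' planted links: each linked genomic/metabolomic feature pair shares a
#' presence pattern, except that the metabolomic side is deleted (the gene
#' cluster is cryptic) at rate \code{flipRate} in strains where the genomic
#' feature is present -- presence is never added, preserving the asymmetry
#' that a gene cluster is required to synthesise a product. Unlinked
#' features are independent Bernoulli draws (genomic features at rate 0.4,
#' metabolomic at 0.3 -- unremarkable mid-range prevalences that keep the
#' background scores well away from the planted ones without making them
#' degenerate).
#'
#' @param nStrains Number of strains.
#' @param nFeatures Number of features on each side.
#' @param nLinks Number of planted links (<= nFeatures).
#' @param flipRate Cryptic-deletion rate in [0, 1].
#' @param seed Integer seed.
#' @return A list with \code{genomic}, \code{metabolomic} (logical
#'   matrices, strains x features) and \code{links} (data.frame
#'   \code{genomic_feature}, \code{metabolomic_feature}).
#' @export
generatePairedDataset <- function(nStrains, nFeatures, nLinks, flipRate,
                                  seed = 1L) {
    if (nLinks > nFeatures) stop("nLinks must be <= nFeatures")
    withSeed(seed, {
        strains <- sprintf("strain%03d", seq_len(nStrains))
        gNames <- sprintf("GF_%03d", seq_len(nFeatures))
        mNames <- sprintf("MM_%03d", seq_len(nFeatures))
        G <- matrix(runif(nStrains * nFeatures) < 0.4, nStrains, nFeatures,
                    dimnames = list(strains, gNames))
        M <- matrix(runif(nStrains * nFeatures) < 0.3, nStrains, nFeatures,
                    dimnames = list(strains, mNames))
        gLink <- sample.int(nFeatures, nLinks)
        mLink <- sample.int(nFeatures, nLinks)
        for (l in seq_len(nLinks)) {
            g <- G[, gLink[l]]
            keep <- runif(nStrains) >= flipRate
            M[, mLink[l]] <- g & keep
        }
        list(genomic = G, metabolomic = M,
             links = data.frame(genomic_feature = gNames[gLink],
                                metabolomic_feature = mNames[mLink],
                                stringsAsFactors = FALSE))
    })
}

#' Write domain hits in HMMER3 domtblout format
#'
#' Emits a minimal but well-formed \code{hmmscan --domtblout} table (target
#' = domain model, query = gene) from a hits data.frame, for fixtures and
#' round-trip tests of \code{\link{parseDomtbl}}.
#'
#' @param hits data.frame with columns \code{gene_id},
#'   \code{domain_accession}, \code{ali_start}, \code{ali_end},
#'   \code{bitscore}, \code{i_evalue}.
#' @param path Output path.
#' @export
writeDomtbl <- function(hits, path) {
    header <- c(
        "#                                                               --- full sequence --- -------------- this domain -------------   hmm coord   ali coord   env coord",
        "# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target",
        "#------------------- ---------- ----- -------------------- ---------- ----- --------- ------ ----- --- --- --------- --------- ------ ----- ----- ----- ----- ----- ----- ----- ---- ---------------------")
    rows <- vapply(seq_len(nrow(hits)), function(i) {
        sprintf("%-20s %-10s %5d %-20s %-10s %5d %9.2g %6.1f %5.1f %3d %3d %9.2g %9.2g %6.1f %5.1f %5d %5d %5d %5d %5d %5d %4.2f -",
                hits$domain_accession[i], "-", 200L,
                hits$gene_id[i], "-", 400L,
                hits$i_evalue[i], hits$bitscore[i], 0.0, 1L, 1L,
                hits$i_evalue[i], hits$i_evalue[i], hits$bitscore[i], 0.0,
                1L, 200L, hits$ali_start[i], hits$ali_end[i],
                hits$ali_start[i], hits$ali_end[i], 0.95)
    }, character(1))
    writeLines(c(header, rows, "#"), path)
    invisible(path)
}
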