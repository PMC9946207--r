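## Strain-level correlation of genomic sub-cluster features with
## mass-spectral substructure motifs: asymmetric co-occurrence score and
## permutation-based significance.

#' Asymmetric strain co-occurrence score
#'
#' Score for one (genomic feature, metabolomic feature) pair from its 2x2
#' strain co-occurrence counts:
#' \code{w11*n11 + w01*n01 + w10*n10 + w00*n00}. The default weights
#' (+10 for joint presence, -10 for metabolite-without-feature, 0 otherwise)
#' encode the biological asymmetry that a gene cluster is required to make a
#' product but may be cryptic: a strain producing the metabolite without the
#' genomic feature is evidence against the link, a silent gene cluster is
#' not.
#'
#' @param n11 Strains with both features present.
#' @param n01 Strains with the metabolomic feature only.
#' @param n10 Strains with the genomic feature only.
#' @param n00 Strains with neither.
#' @param w11,w01,w10,w00 Weights (defaults 10, -10, 0, 0).
#' @return The score (vectorised over the counts).
#' @export
metcalfScore <- function(n11, n01, n10, n00,
                         w11 = 10, w01 = -10, w10 = 0, w00 = 0) {
    if (any(c(n11, n01, n10, n00) < 0)) stop("counts must be non-negative")
    w11 * n11 + w01 * n01 + w10 * n10 + w00 * n00
}

scorePair <- function(g, m, w11 = 10, w01 = -10, w10 = 0, w00 = 0) {
    n11 <- sum(g & m); n01 <- sum(!g & m)
    n10 <- sum(g & !m); n00 <- sum(!g & !m)
    w11 * n11 + w01 * n01 + w10 * n10 + w00 * n00
}

#' Permutation p-value for a feature pair
#'
#' The null distribution is generated by permuting the strain assignment of
#' the metabolomic presence vector \code{nPerm} times and recomputing the
#' score; the p-value uses the standard pseudocount construction
#' \code{(1 + #(null >= observed)) / (nPerm + 1)}, so it is never exactly 0.
#'
#' @param g,m Logical (or 0/1) presence vectors over the same strain order.
#' @param nPerm Number of permutations (default 1000).
#' @param seed Integer seed; the global RNG is left untouched.
#' @param w11,w01,w10,w00 Score weights (see \code{\link{metcalfScore}}).
#' @return The permutation p-value in (0, 1].
#' @export
permutationPvalue <- function(g, m, nPerm = 1000L, seed = 1L,
                              w11 = 10, w01 = -10, w10 = 0, w00 = 0) {
    g <- as.logical(g); m <- as.logical(m)
    if (length(g) != length(m)) stop("vectors must have equal length")
    if (length(g) < 2L) stop("need at least 2 strains")
    obs <- scorePair(g, m, w11, w01, w10, w00)
    withSeed(seed, {
        ge <- 0L
        for (i in seq_len(nPerm)) {
            s <- scorePair(g, sample(m), w11, w01, w10, w00)
            if (s >= obs) ge <- ge + 1L
        }
        (1 + ge) / (nPerm + 1)
    })
}

#' Read / write a strain-by-feature presence matrix
#'
#' CSV with strains as rows (first column holds the strain ids, with a
#' header row naming the features); cells are 0/1.
#'
#' @param path File path.
#' @return \code{readPresenceMatrix}: a logical matrix, strains x features.
#' @export
readPresenceMatrix <- function(path) {
    df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
    mat <- as.matrix(df) != 0
    if (anyDuplicated(rownames(mat))) stop("duplicate strain ids")
    mat
}

#' @rdname readPresenceMatrix
#' @param mat Logical or 0/1 matrix with strain rownames and feature
#'   colnames.
#' @export
writePresenceMatrix <- function(mat, path) {
    df <- as.data.frame(mat * 1L)
    utils::write.csv(df, path, row.names = TRUE, quote = FALSE)
    invisible(path)
}

#' Correlate all genomic features with all metabolomic features
#'
#' Intersects the two presence matrices on their shared strains, then for
#' every (genomic feature, metabolomic feature) pair computes the 2x2
#' counts, the asymmetric co-occurrence score and a permutation p-value.
#' Each pair gets its own deterministic permutation stream derived from
#' \code{seed}, so results do not depend on pair order.
#'
#' @param genomic Strain-by-feature presence matrix of sub-cluster features
#'   (motifs or clans).
#' @param metabolomic Strain-by-feature presence matrix of Mass2Motifs.
#' @param alpha Significance threshold on the permutation p-value
#'   (default 0.1).
#' @param nPerm Permutations per pair (default 1000).
#' @param seed Integer seed.
#' @param w11,w01,w10,w00 Score weights.
#' @return data.frame with one row per pair: \code{genomic_feature},
#'   \code{metabolomic_feature}, \code{n11}, \code{n01}, \code{n10},
#'   \code{n00}, \code{score}, \code{perm_p}, \code{significant}; sorted by
#'   decreasing score then increasing p.
#' @export
correlateAll <- function(genomic, metabolomic, alpha = 0.1, nPerm = 1000L,
                         seed = 1L, w11 = 10, w01 = -10, w10 = 0, w00 = 0) {
    shared <- intersect(rownames(genomic), rownames(metabolomic))
    if (length(shared) < 2L) stop("need at least 2 shared strains")
    G <- genomic[shared, , drop = FALSE] != 0
    M <- metabolomic[shared, , drop = FALSE] != 0
    res <- vector("list", ncol(G) * ncol(M))
    idx <- 0L
    for (i in seq_len(ncol(G))) {
        g <- G[, i]
        for (j in seq_len(ncol(M))) {
            m <- M[, j]
            idx <- idx + 1L
            n11 <- sum(g & m); n01 <- sum(!g & m)
            n10 <- sum(g & !m); n00 <- sum(!g & !m)
            sc <- w11 * n11 + w01 * n01 + w10 * n10 + w00 * n00
            pp <- permutationPvalue(g, m, nPerm = nPerm,
                                    seed = seed + idx,
                                    w11 = w11, w01 = w01, w10 = w10,
                                    w00 = w00)
            res[[idx]] <- data.frame(
                genomic_feature = colnames(G)[i],
                metabolomic_feature = colnames(M)[j],
                n11 = n11, n01 = n01, n10 = n10, n00 = n00,
                score = sc, perm_p = pp, significant = pp < alpha,
                stringsAsFactors = FALSE)
        }
    }
    out <- do.call(rbind, res)
    out <- out[order(-out$score, out$perm_p, out$genomic_feature,
                     out$metabolomic_feature), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Write correlation results to TSV
#' @param results data.frame from \code{\link{correlateAll}}.
#' @param path Output path.
#' @export
writeCorrelationTsv <- function(results, path) {
    utils::write.table(results, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
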