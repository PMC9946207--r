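## Redundancy filtering: Adjacency-Index similarity network over BGCs and
## clique-representative selection.

## Unordered adjacent-domain bigrams of one BGC. Empty genes are excluded
## before concatenation, so domains of consecutive non-empty genes count as
## adjacent; pairs are unordered, making the index strand-orientation-free.
domainBigrams <- function(tokens) {
    doms <- unlist(strsplit(tokens[tokens != "-"], ";", fixed = TRUE),
                   use.names = FALSE)
    if (length(doms) < 2L) return(character(0))
    a <- doms[-length(doms)]
    b <- doms[-1L]
    unique(paste(pmin(a, b), pmax(a, b), sep = "\r"))
}

nDomains <- function(tokens) {
    length(unlist(strsplit(tokens[tokens != "-"], ";", fixed = TRUE),
                  use.names = FALSE))
}

#' Adjacency Index between two tokenised BGCs
#'
#' The Adjacency Index (AI) is the Jaccard index of the two BGCs' sets of
#' unordered adjacent-domain pairs, where each BGC's pair set is built from
#' consecutive domains in its concatenated non-empty token sequence. It is
#' symmetric and lies in [0, 1]; identical BGCs score 1. A BGC with fewer
#' than two domains has an empty pair set and the AI is defined as 0
#' (degenerate case).
#'
#' @param tokensA,tokensB Character vectors of gene tokens (as stored in a
#'   \code{\linkS4class{BgcCorpus}}).
#' @return A number in [0, 1].
#' @seealso \code{\link{isContained}}, \code{\link{selectRepresentatives}}
#' @export
adjacencyIndex <- function(tokensA, tokensB) {
    pa <- domainBigrams(tokensA)
    pb <- domainBigrams(tokensB)
    if (length(pa) == 0L || length(pb) == 0L) return(0)
    length(intersect(pa, pb)) / length(union(pa, pb))
}

#' Containment of one BGC within another
#'
#' \code{TRUE} iff the adjacency-pair set of the BGC with fewer pairs is a
#' subset of the other's (evaluated on the same unordered bigram sets as
#' \code{\link{adjacencyIndex}}). A BGC with an empty pair set (< 2 domains)
#' is never considered contained, to avoid trivially linking degenerate
#' BGCs to everything.
#'
#' @inheritParams adjacencyIndex
#' @return Logical.
#' @export
isContained <- function(tokensA, tokensB) {
    pa <- domainBigrams(tokensA)
    pb <- domainBigrams(tokensB)
    if (length(pa) == 0L || length(pb) == 0L) return(FALSE)
    if (length(pa) <= length(pb)) all(pa %in% pb) else all(pb %in% pa)
}

#' Select non-redundant representative BGCs
#'
#' Builds a similarity network connecting two BGCs when their Adjacency
#' Index exceeds \code{aiCutoff} or one is fully contained within the other,
#' then keeps, from every maximal clique of size >= 2, only the member with
#' the most domains. Isolated BGCs are always kept.
#'
#' Overlapping maximal cliques are processed in decreasing size order (ties
#' broken by the lexicographically smallest member id); a BGC removed by an
#' earlier clique stays removed, and a BGC already chosen as a
#' representative cannot be removed by a later clique. On equal domain
#' counts the lexicographically smallest id wins. The procedure is
#' deterministic and idempotent.
#'
#' @param corpus A \code{\linkS4class{BgcCorpus}}.
#' @param aiCutoff Adjacency-Index threshold (default 0.95).
#' The clique reduction is applied repeatedly until no BGC is removed
#' (protected representatives of overlapping cliques can stay connected
#' after one round), which makes the whole operation idempotent.
#'
#' @return A list with \code{keep} (character vector of retained bgc ids, in
#'   corpus order) and \code{removed} (data.frame \code{bgc_id},
#'   \code{representative}).
#' @export
selectRepresentatives <- function(corpus, aiCutoff = 0.95) {
    ids <- bgcIds(corpus)
    removedAll <- data.frame(bgc_id = character(0),
                             representative = character(0),
                             stringsAsFactors = FALSE)
    repeat {
        round <- representativeRound(corpus, aiCutoff)
        if (nrow(round$removed) == 0L) break
        removedAll <- rbind(removedAll, round$removed)
        corpus <- subsetCorpus(corpus, round$keep)
    }
    list(keep = ids[!ids %in% removedAll$bgc_id], removed = removedAll)
}

## One round of clique-representative reduction.
representativeRound <- function(corpus, aiCutoff) {
    ids <- bgcIds(corpus)
    n <- length(ids)
    bigrams <- lapply(corpus@tokens, domainBigrams)
    ndom <- vapply(corpus@tokens, nDomains, integer(1))
    edges <- integer(0)
    if (n >= 2L) {
        for (i in seq_len(n - 1L)) {
            pa <- bigrams[[i]]
            for (j in (i + 1L):n) {
                pb <- bigrams[[j]]
                if (length(pa) == 0L || length(pb) == 0L) next
                inter <- sum(pa %in% pb)
                ai <- inter / (length(pa) + length(pb) - inter)
                contained <- (inter == length(pa)) || (inter == length(pb))
                if (ai > aiCutoff || contained)
                    edges <- c(edges, i, j)
            }
        }
    }
    if (length(edges) == 0L) {
        return(list(keep = ids,
                    removed = data.frame(bgc_id = character(0),
                                         representative = character(0),
                                         stringsAsFactors = FALSE)))
    }
    g <- igraph::make_empty_graph(n = n, directed = FALSE)
    igraph::V(g)$name <- ids
    g <- igraph::add_edges(g, edges)
    cliques <- igraph::max_cliques(g, min = 2)
    members <- lapply(cliques, function(cl) sort(igraph::V(g)$name[cl]))
    ord <- order(-vapply(members, length, integer(1)),
                 vapply(members, `[[`, character(1), 1))
    members <- members[ord]

    removed <- character(0)
    removedBy <- character(0)
    protected <- character(0)
    ndomById <- setNames(ndom, ids)
    for (cl in members) {
        alive <- setdiff(cl, removed)
        if (length(alive) < 2L) next
        rep_id <- alive[order(-ndomById[alive], alive)][1]
        protected <- union(protected, rep_id)
        drop <- setdiff(alive, c(rep_id, protected))
        removed <- c(removed, drop)
        removedBy <- c(removedBy, rep(rep_id, length(drop)))
    }
    list(keep = ids[!ids %in% removed],
         removed = data.frame(bgc_id = removed, representative = removedBy,
                              stringsAsFactors = FALSE))
}

#' Remove redundant BGCs from a corpus
#'
#' Convenience wrapper around \code{\link{selectRepresentatives}} returning
#' the reduced corpus.
#'
#' @inheritParams selectRepresentatives
#' @return A \code{\linkS4class{BgcCorpus}} restricted to representatives.
#' @export
filterRedundancy <- function(corpus, aiCutoff = 0.95) {
    subsetCorpus(corpus, selectRepresentatives(corpus, aiCutoff)$keep)
}
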