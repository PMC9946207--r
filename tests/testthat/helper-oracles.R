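# Independent oracles used to validate the statistical machinery. These
# deliberately take a different computational route from the package code:
# explicit enumeration of position subsets instead of closed-form tails,
# bitmask subset search instead of igraph, and the textbook step-down
# formula instead of p.adjust.

# Exhaustive placement enumeration: positions carry 0/1/2 adjacency
# interactions; every subset of size Btot is equally likely. Returns
# P(I >= Iobs) for each requested Iobs.
oracleAdjacencyTail <- function(N1, N2, N3, Btot, IobsVec) {
    inter <- c(rep(0L, N1), rep(1L, N2), rep(2L, N3))
    Ntot <- length(inter)
    if (Btot == 0) {
        Ivals <- 0L
    } else {
        sets <- utils::combn(Ntot, Btot)
        Ivals <- colSums(matrix(inter[sets], nrow = Btot))
    }
    vapply(IobsVec, function(io) mean(Ivals >= io), numeric(1))
}

# Same enumeration for co-localisation: K of the positions count as
# co-localised.
oracleColocTail <- function(K, Ntot, Btot, xobs) {
    inter <- c(rep(1L, K), rep(0L, Ntot - K))
    if (Btot == 0) return(as.numeric(0 >= xobs))
    sets <- utils::combn(Ntot, Btot)
    xvals <- colSums(matrix(inter[sets], nrow = Btot))
    mean(xvals >= xobs)
}

# Monte-Carlo placement oracle via sequential hypergeometric sampling
# (R's rhyper, an independent code path from the enumerated tail).
mcAdjacencyTail <- function(N1, N2, N3, Btot, Iobs, nDraw = 1e5) {
    Ntot <- N1 + N2 + N3
    b3 <- stats::rhyper(nDraw, N3, Ntot - N3, Btot)
    b2 <- stats::rhyper(nDraw, N2, N1, Btot - b3)
    mean(b2 + 2 * b3 >= Iobs)
}

# Brute-force maximal cliques of an adjacency matrix (n <= 20) by bitmask
# subset enumeration. Returns a sorted list of sorted member index vectors.
bruteMaxCliques <- function(adj, minSize = 2L) {
    n <- nrow(adj)
    isClique <- function(members) {
        if (length(members) < 2L) return(TRUE)
        all(adj[t(utils::combn(members, 2))])
    }
    cliques <- list()
    for (mask in seq_len(2^n - 1L)) {
        members <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
        if (length(members) < minSize || !isClique(members)) next
        extendable <- any(vapply(setdiff(seq_len(n), members), function(v)
            all(adj[v, members]), logical(1)))
        if (!extendable)
            cliques[[length(cliques) + 1L]] <- members
    }
    cliques[order(vapply(cliques, paste, character(1), collapse = ","))]
}

# Textbook Benjamini-Yekutieli step-down adjustment.
byReference <- function(p) {
    m <- length(p)
    cm <- sum(1 / seq_len(m))
    ord <- order(p)
    q <- p[ord] * m * cm / seq_len(m)
    q <- rev(cummin(rev(q)))
    q <- pmin(q, 1)
    out <- numeric(m)
    out[ord] <- q
    out
}

# Exact permutation tail of the co-occurrence score: enumerate all
# placements of the metabolomic positives over the strains.
exactPermTail <- function(g, m, w11 = 10, w01 = -10) {
    g <- as.logical(g); m <- as.logical(m)
    n <- length(g); k <- sum(m)
    obs <- w11 * sum(g & m) + w01 * sum(!g & m)
    if (k == 0 || k == n) return(1)
    sets <- utils::combn(n, k)
    scores <- apply(sets, 2, function(idx) {
        mm <- logical(n); mm[idx] <- TRUE
        w11 * sum(g & mm) + w01 * sum(!g & mm)
    })
    mean(scores >= obs)
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
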