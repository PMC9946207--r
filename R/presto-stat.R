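## Statistical sub-cluster detection: duplicate-gene simplification, pairwise
## adjacency / co-localisation counting, exact hypergeometric p-values,
## Benjamini-Yekutieli correction, iterative maximal-clique extraction, and
## K-means grouping into sub-cluster families and clans.

#' Simplify duplicate genes within a BGC
#'
#' The co-localisation null model becomes computationally hard when a gene
#' occurs many times in one BGC. Every token occurring k >= 2 times is
#' therefore replaced in place by empty genes (\code{"-"}), and a single
#' copy is appended at the end of the cluster preceded by a \code{"-"}
#' separator, so that afterwards every non-empty token occurs exactly once
#' and only two co-localisation states (co-localised / not) remain to be
#' counted. Appended copies follow first-occurrence order; each sits between
#' separators, so it is adjacent to nothing.
#'
#' @param tokens Character vector of gene tokens for one BGC.
#' @return Character vector of gene tokens with unique non-empty tokens.
#' @export
preprocessDuplicates <- function(tokens) {
    nonEmpty <- tokens[tokens != "-"]
    dup <- unique(nonEmpty[duplicated(nonEmpty)])
    if (length(dup) == 0L) return(tokens)
    out <- tokens
    out[out %in% dup] <- "-"
    ## first-occurrence order of the duplicated tokens
    dupOrdered <- unique(nonEmpty)[unique(nonEmpty) %in% dup]
    for (t in dupOrdered) out <- c(out, "-", t)
    out
}

## Apply the duplicate simplification to every BGC of a corpus.
preprocessCorpusDuplicates <- function(corpus) {
    new("BgcCorpus",
        tokens = lapply(corpus@tokens, preprocessDuplicates),
        biosynClass = corpus@biosynClass,
        strain = corpus@strain,
        contigEdge = corpus@contigEdge)
}

#' Count adjacency and co-localisation interactions for all gene pairs
#'
#' For every ordered pair (A fixed, B placed) of distinct non-empty tokens
#' that co-occur in at least one BGC, counts the quantities entering the
#' hypergeometric null model in which gene B is distributed at random over
#' all positions not occupied by A. Positions are all gene slots, including
#' empty \code{"-"} slots (they are occupiable under the null but contribute
#' no observed interaction); BGC boundaries and \code{"-"} slots break
#' adjacency. Pairs that never share a BGC have zero observed interactions
#' and a p-value of 1, so they are not enumerated (but they still count
#' towards the number of tests, see \code{\link{pairQvalues}}).
#'
#' The corpus must already be simplified with
#' \code{\link{preprocessDuplicates}} so every token occurs at most once per
#' BGC.
#'
#' @param corpus A \code{\linkS4class{BgcCorpus}} (duplicate-simplified).
#' @param pairs Optional 2-column character matrix of (A, B) token pairs to
#'   restrict to; tokens absent from the corpus raise an error.
#' @return data.frame of directed counts with columns \code{tokenA} (fixed),
#'   \code{tokenB}, \code{N1}, \code{N2}, \code{N3} (available positions not
#'   adjacent / adjacent on one side / adjacent on both sides to A),
#'   \code{Ntot}, \code{Btot}, \code{Iobs} (observed adjacency
#'   interactions), \code{K} (available positions co-localised with A) and
#'   \code{xobs} (observed co-localisations).
#' @export
countInteractions <- function(corpus, pairs = NULL) {
    tokList <- corpus@tokens
    tok <- unlist(tokList, use.names = FALSE)
    bgcIdx <- rep(seq_along(tokList),
                  vapply(tokList, length, integer(1)))
    S <- length(tok)
    vocab <- sort(unique(tok[tok != "-"]))
    if (!is.null(pairs)) {
        miss <- setdiff(unique(as.vector(pairs)), vocab)
        if (length(miss))
            stop("token(s) absent from corpus: ",
                 paste(head(miss, 5), collapse = ", "))
    }
    code <- match(tok, vocab)            # NA for "-"
    ## neighbour codes within each BGC; boundaries give NA
    left <- c(NA_integer_, code[-S])
    left[c(1L, which(diff(bgcIdx) != 0L) + 1L)] <- NA_integer_
    right <- c(code[-1L], NA_integer_)
    right[c(which(diff(bgcIdx) != 0L), S)] <- NA_integer_

    Btot <- tabulate(code, nbins = length(vocab))
    slotsPerBgc <- vapply(tokList, length, integer(1))

    wanted <- NULL
    if (!is.null(pairs))
        wanted <- paste(pairs[, 1], pairs[, 2], sep = "\r")

    res <- vector("list", length(vocab))
    for (ai in seq_along(vocab)) {
        isA <- !is.na(code) & code == ai
        nA <- Btot[ai]
        adjA <- (( !is.na(left) & left == ai)) + ((!is.na(right) & right == ai))
        avail <- !isA
        Ntot <- S - nA
        N3 <- sum(avail & adjA == 2L)
        N2 <- sum(avail & adjA == 1L)
        N1 <- Ntot - N2 - N3
        aBgcs <- unique(bgcIdx[isA])
        K <- sum(slotsPerBgc[aBgcs]) - nA
        inABgc <- bgcIdx %in% aBgcs
        ## per-token observed interactions, vectorised over all B at once
        sel <- !is.na(code) & !isA
        xobsAll <- tabulate(code[sel & inABgc], nbins = length(vocab))
        IobsAll <- numeric(length(vocab))
        contrib <- sel & adjA > 0L
        if (any(contrib)) {
            t2 <- tapply(adjA[contrib], code[contrib], sum)
            IobsAll[as.integer(names(t2))] <- as.numeric(t2)
        }
        bs <- which(xobsAll > 0L)
        if (!is.null(wanted)) {
            key <- paste(vocab[ai], vocab[bs], sep = "\r")
            bs <- bs[key %in% wanted]
        }
        if (length(bs) == 0L) next
        res[[ai]] <- data.frame(
            tokenA = vocab[ai], tokenB = vocab[bs],
            N1 = N1, N2 = N2, N3 = N3, Ntot = Ntot,
            Btot = Btot[bs], Iobs = as.integer(IobsAll[bs]),
            K = K, xobs = as.integer(xobsAll[bs]),
            stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
    if (is.null(out))
        out <- data.frame(tokenA = character(0), tokenB = character(0),
                          N1 = integer(0), N2 = integer(0), N3 = integer(0),
                          Ntot = integer(0), Btot = integer(0),
                          Iobs = integer(0), K = integer(0),
                          xobs = integer(0), stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
}

#' Exact adjacency p-value under the multivariate hypergeometric null
#'
#' Gene B's \code{Btot} occurrences are placed uniformly at random over the
#' available positions, which fall in three categories with respect to the
#' fixed gene A: not adjacent (\code{N1} positions), adjacent on one side
#' (\code{N2}), adjacent on both sides (\code{N3}). A placement
#' (b1, b2, b3) has probability
#' \code{choose(N1,b1)*choose(N2,b2)*choose(N3,b3)/choose(Ntot,Btot)} and
#' produces \code{I = b2 + 2*b3} adjacency interactions. The p-value is the
#' upper tail \code{P(I >= Iobs)}, enumerated over (b2, b3) in log space
#' (b1 is implied) and summed from smallest to largest term.
#'
#' @param N1,N2,N3 Available position counts per category; their sum must
#'   equal \code{Ntot}.
#' @param Ntot Total available positions.
#' @param Btot Number of occurrences of gene B to place.
#' @param Iobs Observed number of adjacency interactions.
#' @return \code{P(I >= Iobs)}, a number in [0, 1].
#' @seealso \code{\link{colocalisationPvalue}}
#' @export
adjacencyPvalue <- function(N1, N2, N3, Ntot, Btot, Iobs) {
    if (N1 < 0 || N2 < 0 || N3 < 0 || N1 + N2 + N3 != Ntot)
        stop("invalid counts: need N1 + N2 + N3 = Ntot, all non-negative")
    if (Btot > Ntot) stop("invalid counts: Btot > Ntot")
    if (Btot < 0 || Iobs < 0) stop("invalid counts: negative Btot or Iobs")
    if (Iobs == 0) return(1)
    if (Iobs > 2 * Btot) return(0)
    b3 <- 0:min(N3, Btot)
    b2 <- 0:min(N2, Btot)
    grid <- expand.grid(b2 = b2, b3 = b3)
    grid$b1 <- Btot - grid$b2 - grid$b3
    grid <- grid[grid$b1 >= 0 & grid$b1 <= N1, , drop = FALSE]
    grid <- grid[grid$b2 + 2 * grid$b3 >= Iobs, , drop = FALSE]
    if (nrow(grid) == 0L) return(0)
    lp <- lchoose(N1, grid$b1) + lchoose(N2, grid$b2) +
        lchoose(N3, grid$b3) - lchoose(Ntot, Btot)
    p <- sum(exp(sort(lp)))
    min(1, p)
}

#' Hypergeometric co-localisation p-value
#'
#' After duplicate simplification only two co-localisation states remain,
#' so placing gene B's occurrences at random over the available positions
#' (of which \code{K} are co-localised with A) gives a standard
#' hypergeometric law for the number of co-localisations X. Returns the
#' upper tail \code{P(X >= xobs)}.
#'
#' @param K Available positions co-localised with A.
#' @param Ntot Total available positions.
#' @param Btot Occurrences of gene B.
#' @param xobs Observed co-localisations.
#' @return \code{P(X >= xobs)}, a number in [0, 1].
#' @export
colocalisationPvalue <- function(K, Ntot, Btot, xobs) {
    if (K < 0 || K > Ntot) stop("invalid counts: need 0 <= K <= Ntot")
    if (Btot > Ntot) stop("invalid counts: Btot > Ntot")
    if (xobs < 0 || Btot < 0) stop("invalid counts: negative xobs or Btot")
    if (xobs == 0) return(1)
    phyper(xobs - 1, K, Ntot - K, Btot, lower.tail = FALSE)
}

#' Conservative per-pair p-values
#'
#' Each unordered token pair has two directional p-values (A fixed and B
#' fixed) per interaction type; only the larger of the two is kept, to be
#' conservative.
#'
#' @param counts Directed counts from \code{\link{countInteractions}}.
#' @return data.frame with one row per unordered pair: \code{tokenA},
#'   \code{tokenB} (lexicographic order), \code{p_adj}, \code{p_coloc}.
#' @export
conservativePairPvalues <- function(counts) {
    if (nrow(counts) == 0L)
        return(data.frame(tokenA = character(0), tokenB = character(0),
                          p_adj = numeric(0), p_coloc = numeric(0),
                          stringsAsFactors = FALSE))
    padj <- vapply(seq_len(nrow(counts)), function(i)
        adjacencyPvalue(counts$N1[i], counts$N2[i], counts$N3[i],
                        counts$Ntot[i], counts$Btot[i], counts$Iobs[i]),
        numeric(1))
    pcol <- vapply(seq_len(nrow(counts)), function(i)
        colocalisationPvalue(counts$K[i], counts$Ntot[i], counts$Btot[i],
                             counts$xobs[i]),
        numeric(1))
    a <- pmin(counts$tokenA, counts$tokenB)
    b <- pmax(counts$tokenA, counts$tokenB)
    key <- paste(a, b, sep = "\r")
    agg_adj <- tapply(padj, key, max)
    agg_col <- tapply(pcol, key, max)
    keys <- sort(names(agg_adj))
    parts <- strsplit(keys, "\r", fixed = TRUE)
    data.frame(
        tokenA = vapply(parts, `[[`, character(1), 1),
        tokenB = vapply(parts, `[[`, character(1), 2),
        p_adj = as.numeric(agg_adj[keys]),
        p_coloc = as.numeric(agg_col[keys]),
        stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Yekutieli correction
#'
#' Step-down FDR control under arbitrary dependency:
#' \code{q_(i) = min(1, min_{j>=i} p_(j) * m * c(m) / j)} with
#' \code{c(m) = sum(1/(1:m))}, returned in input order. \code{nTests} allows
#' correcting for tests whose p-value is exactly 1 and was not materialised
#' (pairs that never co-occur).
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @param nTests Total number of tests m (default \code{length(p)}; must be
#'   at least that).
#' @return Adjusted q-values, same length and order as \code{p}.
#' @export
byCorrect <- function(p, nTests = length(p)) {
    if (length(p) == 0L) return(numeric(0))
    if (any(is.na(p)) || any(p < 0) || any(p > 1))
        stop("p-values must lie in [0, 1]")
    if (nTests < length(p)) stop("nTests must be >= length(p)")
    stats::p.adjust(p, method = "BY", n = nTests)
}

#' Adjusted q-values for pair statistics
#'
#' Applies \code{\link{byCorrect}} separately to the adjacency and the
#' co-localisation p-value sets.
#'
#' @param pairs data.frame from \code{\link{conservativePairPvalues}}.
#' @param nTests Total number of token pairs tested (see
#'   \code{\link{byCorrect}}).
#' @return \code{pairs} with added columns \code{q_adj}, \code{q_coloc}.
#' @export
pairQvalues <- function(pairs, nTests = nrow(pairs)) {
    pairs$q_adj <- byCorrect(pairs$p_adj, nTests)
    pairs$q_coloc <- byCorrect(pairs$p_coloc, nTests)
    pairs
}

#' Detect sub-clusters as maximal cliques under iterated thresholds
#'
#' Builds an undirected graph on tokens with an edge between two tokens
#' whenever the smaller of their adjacency and co-localisation q-values is
#' strictly below a threshold tau, records all maximal cliques of size >= 2,
#' and repeats with tau set to every distinct q-value below the initial
#' threshold (in decreasing order). Iterating the threshold peels nested
#' structures apart: a clique polluted by one marginal edge at tau0
#' reappears in clean form once tau drops below that edge's q-value. The
#' output is the union of distinct cliques by token set, each tagged with
#' the largest tau at which it appeared.
#'
#' @param pairs data.frame with \code{tokenA}, \code{tokenB}, \code{q_adj},
#'   \code{q_coloc} (see \code{\link{pairQvalues}}).
#' @param tau0 Initial threshold (default 0.1).
#' @return data.frame with columns \code{subcluster_id}, \code{tau} and a
#'   list column \code{tokens}.
#' @export
detectSubclusters <- function(pairs, tau0 = 0.1) {
    empty <- data.frame(subcluster_id = character(0), tau = numeric(0))
    empty$tokens <- list()
    qmin <- pmin(pairs$q_adj, pairs$q_coloc)
    if (nrow(pairs) == 0L || !any(qmin < tau0)) return(empty)
    taus <- c(tau0, sort(unique(qmin[qmin < tau0]), decreasing = TRUE))
    nodes <- sort(unique(c(pairs$tokenA, pairs$tokenB)))
    seen <- new.env(hash = TRUE, parent = emptyenv())
    out_tokens <- list(); out_tau <- numeric(0)
    for (tau in taus) {
        sel <- qmin < tau
        if (!any(sel)) next
        g <- igraph::graph_from_data_frame(
            pairs[sel, c("tokenA", "tokenB")], directed = FALSE,
            vertices = nodes)
        cls <- igraph::max_cliques(g, min = 2)
        for (cl in cls) {
            toks <- sort(nodes[as.integer(cl)])
            key <- paste(toks, collapse = "\r")
            if (!is.null(seen[[key]])) next
            seen[[key]] <- TRUE
            out_tokens[[length(out_tokens) + 1L]] <- toks
            out_tau <- c(out_tau, tau)
        }
    }
    if (length(out_tokens) == 0L) return(empty)
    res <- data.frame(
        subcluster_id = sprintf("SC%04d", seq_along(out_tokens)),
        tau = out_tau, stringsAsFactors = FALSE)
    res$tokens <- out_tokens
    res
}

#' Filter putative sub-clusters and attach their occurrences
#'
#' A sub-cluster occurs in a BGC when the BGC's token set contains all of
#' the sub-cluster's tokens. Sub-clusters with fewer than \code{minGenes}
#' tokens or occurring in fewer than \code{minBgcs} BGCs are removed as
#' likely false positives.
#'
#' @param subs data.frame from \code{\link{detectSubclusters}}.
#' @param corpus The \code{\linkS4class{BgcCorpus}} the statistics were
#'   computed on (pre-duplicate-simplification is fine; token sets are
#'   unchanged by the simplification).
#' @param minGenes Minimum tokens per sub-cluster (default 3).
#' @param minBgcs Minimum occurrences (default 2).
#' @return \code{subs} filtered, with a list column \code{occurrences} of
#'   BGC ids and a column \code{n_occurrences}.
#' @export
filterSubclusters <- function(subs, corpus, minGenes = 3L, minBgcs = 2L) {
    tokenSets <- lapply(corpus@tokens, function(t) unique(t[t != "-"]))
    ids <- bgcIds(corpus)
    occ <- lapply(subs$tokens, function(tk) {
        hit <- vapply(tokenSets, function(s) all(tk %in% s), logical(1))
        ids[hit]
    })
    keep <- lengths(subs$tokens) >= minGenes & lengths(occ) >= minBgcs
    out <- subs[keep, , drop = FALSE]
    out$occurrences <- occ[keep]
    out$n_occurrences <- lengths(out$occurrences)
    rownames(out) <- NULL
    out
}

## K-means that tolerates duplicated rows: clusters the distinct rows and
## maps assignments back. Errors if k exceeds the number of points.
kmeansBinary <- function(mat, k, nstart = 10L) {
    if (k > nrow(mat)) stop("k larger than number of points")
    keyOf <- apply(mat, 1, paste, collapse = "")
    uniq <- !duplicated(keyOf)
    umat <- mat[uniq, , drop = FALSE]
    ukey <- keyOf[uniq]
    if (k >= nrow(umat)) {
        uassign <- seq_len(nrow(umat))
    } else {
        uassign <- kmeans(umat, centers = k, nstart = nstart,
                          iter.max = 100L)$cluster
    }
    uassign[match(keyOf, ukey)]
}

#' Group sub-clusters into families and clans
#'
#' Sub-clusters are encoded as binary presence vectors over the token
#' vocabulary and K-means-clustered into \code{kFam} sub-cluster families
#' (SCFs); the family centroids are clustered again into \code{kClan}
#' sub-cluster clans (SCCs). Within each family, a member whose token set is
#' a subset of another member's with an identical occurrence set is dropped
#' as redundant (it carries no extra information).
#'
#' Defaults mirror a roughly 10:1 reduction at each level:
#' \code{kFam = ceiling(0.1 * n)} and \code{kClan = ceiling(0.2 * kFam)}.
#'
#' @param subs Filtered sub-clusters from \code{\link{filterSubclusters}}.
#' @param kFam,kClan Numbers of families and clans; \code{NULL} for the
#'   defaults above.
#' @param seed Integer seed for the K-means restarts.
#' @return A list with \code{subclusters} (input rows minus redundant
#'   members, with \code{family_id} and \code{clan_id} columns) and
#'   \code{families} (data.frame \code{family_id}, \code{clan_id},
#'   \code{n_members}).
#' @export
clusterFamiliesClans <- function(subs, kFam = NULL, kClan = NULL, seed = 1L) {
    n <- nrow(subs)
    if (n == 0L) stop("no sub-clusters to cluster")
    if (is.null(kFam)) kFam <- max(1L, ceiling(0.1 * n))
    if (kFam > n) stop("k larger than number of points")
    vocab <- sort(unique(unlist(subs$tokens)))
    mat <- matrix(0L, n, length(vocab), dimnames = list(NULL, vocab))
    for (i in seq_len(n)) mat[i, subs$tokens[[i]]] <- 1L
    set.seed(seed)
    fam <- kmeansBinary(mat, kFam)
    subs$family_id <- sprintf("SCF%03d", fam)

    ## drop nested members with identical occurrences within each family
    occKey <- vapply(subs$occurrences, function(o)
        paste(sort(o), collapse = "\r"), character(1))
    drop <- logical(n)
    for (f in unique(fam)) {
        idx <- which(fam == f)
        if (length(idx) < 2L) next
        for (i in idx) for (j in idx) {
            if (i == j || drop[i]) next
            ti <- subs$tokens[[i]]; tj <- subs$tokens[[j]]
            if (occKey[i] == occKey[j] && all(ti %in% tj) &&
                (length(ti) < length(tj) || (length(ti) == length(tj) && i > j)))
                drop[i] <- TRUE
        }
    }

    nFamObs <- length(unique(fam))
    if (is.null(kClan)) kClan <- max(1L, ceiling(0.2 * kFam))
    if (kClan > nFamObs) kClan <- nFamObs
    cent <- matrix(0, nFamObs, length(vocab))
    famLevels <- sort(unique(fam))
    for (i in seq_along(famLevels))
        cent[i, ] <- colMeans(mat[fam == famLevels[i], , drop = FALSE])
    clanOfFam <- kmeansBinary(cent, kClan)
    names(clanOfFam) <- famLevels
    subs$clan_id <- sprintf("SCC%03d", clanOfFam[as.character(fam)])

    out <- subs[!drop, , drop = FALSE]
    rownames(out) <- NULL
    families <- data.frame(
        family_id = sprintf("SCF%03d", famLevels),
        clan_id = sprintf("SCC%03d", as.integer(clanOfFam)),
        n_members = as.integer(table(fam)[as.character(famLevels)]),
        stringsAsFactors = FALSE)
    list(subclusters = out, families = families)
}

#' Run the full statistical sub-cluster detection pipeline
#'
#' Duplicate simplification, interaction counting, exact hypergeometric
#' p-values, conservative pair merging, Benjamini-Yekutieli correction over
#' all token pairs (pairs never sharing a BGC enter the correction with
#' p = 1), iterated maximal-clique detection, filtering, and family/clan
#' clustering.
#'
#' @param corpus A filtered, non-redundant \code{\linkS4class{BgcCorpus}}.
#' @param tau0 Initial clique threshold on q-values (default 0.1).
#' @param minGenes,minBgcs Sub-cluster filters (defaults 3 and 2).
#' @param kFam,kClan Family/clan counts (see
#'   \code{\link{clusterFamiliesClans}}).
#' @param seed Seed for the K-means step.
#' @return A list with \code{subclusters}, \code{families} and \code{pairs}
#'   (the per-pair statistics table).
#' @export
prestoStat <- function(corpus, tau0 = 0.1, minGenes = 3L, minBgcs = 2L,
                       kFam = NULL, kClan = NULL, seed = 1L) {
    prep <- preprocessCorpusDuplicates(corpus)
    counts <- countInteractions(prep)
    pairs <- conservativePairPvalues(counts)
    m <- choose(length(vocabulary(corpus)), 2)
    pairs <- pairQvalues(pairs, nTests = max(m, nrow(pairs)))
    subs <- detectSubclusters(pairs, tau0 = tau0)
    subs <- filterSubclusters(subs, corpus, minGenes = minGenes,
                              minBgcs = minBgcs)
    if (nrow(subs) == 0L)
        return(list(subclusters = subs, families = NULL, pairs = pairs))
    cl <- clusterFamiliesClans(subs, kFam = kFam, kClan = kClan, seed = seed)
    list(subclusters = cl$subclusters, families = cl$families, pairs = pairs)
}

#' Write sub-clusters and pair statistics to TSV
#'
#' @param subs Sub-cluster data.frame (with list columns \code{tokens} and
#'   \code{occurrences}).
#' @param path Output path.
#' @export
writeSubclustersTsv <- function(subs, path) {
    flat <- data.frame(
        subcluster_id = subs$subcluster_id,
        tau = subs$tau,
        tokens = vapply(subs$tokens, paste, character(1), collapse = ";"),
        n_occurrences = subs$n_occurrences,
        bgc_ids = vapply(subs$occurrences, paste, character(1),
                         collapse = "|"),
        family_id = if ("family_id" %in% names(subs)) subs$family_id else NA,
        clan_id = if ("clan_id" %in% names(subs)) subs$clan_id else NA,
        stringsAsFactors = FALSE)
    utils::write.table(flat, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeSubclustersTsv
#' @param pairs Pair statistics data.frame from \code{\link{pairQvalues}}.
#' @export
writePairStatsTsv <- function(pairs, path) {
    utils::write.table(pairs, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
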