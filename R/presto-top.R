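## Topic-model sub-cluster motifs: online variational Bayes LDA over
## bag-of-token BGCs, truncated motif extraction, BGC querying with the
## gene-to-motif probability cut-offs, u_mass coherence, and reference
## overlap evaluation.

## Evaluate expr with a temporary RNG state seeded by `seed`, restoring the
## caller's RNG afterwards.
withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(expr)
}

## Bag-of-words encoding: one entry per document with token indices into
## `vocab` and their multiplicities; empty genes excluded, unknown tokens
## dropped.
bagOfWords <- function(tokenList, vocab) {
    lapply(tokenList, function(tok) {
        tok <- tok[tok != "-"]
        idx <- match(tok, vocab)
        idx <- idx[!is.na(idx)]
        if (length(idx) == 0L)
            return(list(ids = integer(0), cts = numeric(0)))
        tab <- table(idx)
        list(ids = as.integer(names(tab)), cts = as.numeric(tab))
    })
}

dirichletExpectation <- function(mat) {
    digamma(mat) - digamma(rowSums(mat))
}

## Variational E-step for one document: returns gamma (length K) and the
## K x n_d responsibility matrix phi (columns sum to 1).
inferDocument <- function(ids, cts, expElogBeta, alpha, iterations = 50L,
                          tol = 1e-4) {
    K <- nrow(expElogBeta)
    gamma <- rep(alpha + sum(cts) / K, K)
    eb <- expElogBeta[, ids, drop = FALSE]
    phi <- matrix(0, K, length(ids))
    for (it in seq_len(max(1L, iterations))) {
        expElogTheta <- exp(digamma(gamma) - digamma(sum(gamma)))
        phi <- eb * expElogTheta
        norm <- colSums(phi)
        norm[norm == 0] <- 1e-100
        phi <- sweep(phi, 2, norm, "/")
        gammaNew <- alpha + as.numeric(phi %*% cts)
        delta <- mean(abs(gammaNew - gamma))
        gamma <- gammaNew
        if (delta < tol) break
    }
    list(gamma = gamma, phi = phi)
}

## Plug-in per-token log-likelihood of documents under posterior-mean
## theta / phi estimates.
docLogLik <- function(docs, phiHat, alpha, iterations = 50L) {
    ll <- 0; ntok <- 0
    for (d in docs) {
        if (length(d$ids) == 0L) next
        inf <- inferDocument(d$ids, d$cts, phiHat + 1e-100, alpha,
                             iterations)
        theta <- inf$gamma / sum(inf$gamma)
        pw <- as.numeric(t(theta) %*% phiHat[, d$ids, drop = FALSE])
        ll <- ll + sum(d$cts * log(pw + 1e-100))
        ntok <- ntok + sum(d$cts)
    }
    if (ntok == 0) return(NA_real_)
    ll / ntok
}

#' Fit an LDA topic model on a tokenised corpus
#'
#' Trains latent Dirichlet allocation by online variational Bayes on the
#' bag-of-words representation of the corpus (token frequency per BGC; gene
#' order ignored; empty genes excluded). The model is updated with
#' mini-batches of \code{max(chunkMin, ceiling(chunkFrac * n))} documents
#' and learning rate \code{(1 + t)^-decay} for the t-th update; for corpora
#' smaller than the minimum chunk size this reduces to repeated full-batch
#' updates. Priors are symmetric \code{1/nTopics} unless overridden. A
#' held-out document subset is set aside before training and its plug-in
#' per-token log-likelihood is recorded after every pass.
#'
#' Training is reproducible for a fixed seed: all randomness (topic
#' initialisation, held-out split) is drawn from a private RNG stream
#' seeded with \code{seed}.
#'
#' @param corpus A \code{\linkS4class{BgcCorpus}}.
#' @param nTopics Number of topics (sub-cluster motifs); must be >= 2.
#' @param seed Integer seed.
#' @param iterations Per-document variational iteration cap (default 500).
#' @param chunkFrac Mini-batch size as a fraction of the corpus
#'   (default 0.05).
#' @param chunkMin Minimum mini-batch size (default 2000).
#' @param passes Number of passes over the corpus (default 50; small corpora
#'   need many full-batch updates where a large corpus gets many mini-batch
#'   updates per pass).
#' @param alpha,beta Symmetric Dirichlet priors; default \code{1/nTopics}.
#' @param decay Learning-rate decay exponent (default 0.5).
#' @param holdoutFrac Fraction of documents held out for the per-pass
#'   log-likelihood (default 0.05, at least 1 document).
#' @return A \code{\linkS4class{TopicModel}}.
#' @export
fitLda <- function(corpus, nTopics, seed = 1L, iterations = 500L,
                   chunkFrac = 0.05, chunkMin = 2000L, passes = 50L,
                   alpha = 1 / nTopics, beta = 1 / nTopics, decay = 0.5,
                   holdoutFrac = 0.05) {
    if (nTopics < 2L) stop("nTopics must be >= 2")
    vocab <- vocabulary(corpus)
    if (length(vocab) < 2L)
        stop("vocabulary must contain at least 2 tokens")
    docsAll <- bagOfWords(corpus@tokens, vocab)
    D <- length(docsAll)
    if (D == 0L) stop("empty corpus")
    K <- as.integer(nTopics)
    V <- length(vocab)
    chunkSize <- max(as.integer(chunkMin), ceiling(chunkFrac * D))

    withSeed(seed, {
        nHold <- min(D - 1L, max(1L, round(holdoutFrac * D)))
        holdIdx <- sample.int(D, nHold)
        trainIdx <- setdiff(seq_len(D), holdIdx)
        docs <- docsAll[trainIdx]
        lambda <- matrix(rgamma(K * V, shape = 100, rate = 100), K, V)
        logLik <- numeric(0)
        t <- 0L
        for (pass in seq_len(passes)) {
            starts <- seq(1L, length(docs), by = chunkSize)
            for (s in starts) {
                chunk <- docs[s:min(s + chunkSize - 1L, length(docs))]
                expElogBeta <- exp(dirichletExpectation(lambda))
                sstats <- matrix(0, K, V)
                for (d in chunk) {
                    if (length(d$ids) == 0L) next
                    inf <- inferDocument(d$ids, d$cts, expElogBeta, alpha,
                                         iterations)
                    sstats[, d$ids] <- sstats[, d$ids] +
                        sweep(inf$phi, 2, d$cts, "*")
                }
                rho <- (1 + t)^(-decay)
                lambdaHat <- beta + (length(docs) / length(chunk)) * sstats
                lambda <- (1 - rho) * lambda + rho * lambdaHat
                t <- t + 1L
            }
            phiHat <- lambda / rowSums(lambda)
            logLik <- c(logLik, docLogLik(docsAll[holdIdx], phiHat, alpha,
                                          iterations = min(iterations, 50L)))
        }
        phi <- lambda / rowSums(lambda)
        colnames(phi) <- vocab
        new("TopicModel",
            nTopics = K, alpha = alpha, beta = beta, phi = phi,
            vocab = vocab, seed = as.integer(seed),
            chunkSize = as.integer(chunkSize),
            iterations = as.integer(iterations), logLik = logLik)
    })
}

#' Extract truncated sub-cluster motifs from a topic model
#'
#' For each topic, tokens are sorted by descending probability (ties broken
#' by token text) and the shortest prefix whose probabilities sum to at
#' least \code{cumulative} is kept as the motif's features; the long flat
#' tail of near-zero probabilities is noise and is cut away.
#'
#' @param model A \code{\linkS4class{TopicModel}}.
#' @param cumulative Cumulative probability to retain (default 0.95).
#' @return data.frame with columns \code{topic_id}, \code{token},
#'   \code{probability}, ordered by topic then descending probability.
#' @export
extractMotifs <- function(model, cumulative = 0.95) {
    phi <- model@phi
    res <- lapply(seq_len(nrow(phi)), function(k) {
        p <- phi[k, ]
        ord <- order(-p, names(p))
        p <- p[ord]
        ncut <- which(cumsum(p) >= cumulative - 1e-12)[1]
        if (is.na(ncut)) ncut <- length(p)
        data.frame(topic_id = k, token = names(p)[seq_len(ncut)],
                   probability = as.numeric(p[seq_len(ncut)]),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
}

#' Infer the topic mixture of one BGC
#'
#' Variational inference of the document-topic posterior for a query BGC
#' under a trained model, with a fixed iteration cap for reproducibility.
#'
#' @param model A \code{\linkS4class{TopicModel}}.
#' @param tokens Character vector of gene tokens; unknown tokens dropped.
#' @param iterations Variational iteration cap (default 50).
#' @return Named list: \code{theta} (topic proportions), \code{geneGamma}
#'   (matrix genes x topics of per-gene topic responsibilities, rows sum to
#'   1; one row per non-empty gene with a known token, rownames are the gene
#'   indices into \code{tokens}).
#' @export
inferBgcTopics <- function(model, tokens, iterations = 50L) {
    geneIdx <- which(tokens != "-" & tokens %in% model@vocab)
    if (length(geneIdx) == 0L) {
        warning("BGC has no tokens known to the model")
        return(list(theta = rep(1 / model@nTopics, model@nTopics),
                    geneGamma = matrix(numeric(0), 0, model@nTopics)))
    }
    w <- match(tokens[geneIdx], model@vocab)
    tab <- table(w)
    ids <- as.integer(names(tab))
    cts <- as.numeric(tab)
    phi <- model@phi
    inf <- inferDocument(ids, cts, phi + 1e-100, model@alpha,
                         iterations = iterations)
    theta <- inf$gamma / sum(inf$gamma)
    ## per-gene responsibility: gamma_{g,k} proportional to theta_k * phi_{k,w_g}
    gg <- t(phi[, w, drop = FALSE] * theta)
    norm <- rowSums(gg)
    norm[norm == 0] <- 1e-100
    gg <- gg / norm
    rownames(gg) <- geneIdx
    list(theta = theta, geneGamma = gg)
}

#' Match a BGC's genes against sub-cluster motifs
#'
#' For every topic, genes whose gene-to-motif probability (the per-token
#' posterior topic responsibility, see \code{\link{inferBgcTopics}}) reaches
#' \code{gammaMin} form a candidate match. A match is emitted when it has at
#' least two genes, its summed gene-to-motif probability exceeds
#' \code{gammaSumMin}, and its overlap score -- the sum of the motif's
#' feature probabilities over the distinct tokens present in the match --
#' reaches \code{overlapMin}.
#'
#' @param model A \code{\linkS4class{TopicModel}}.
#' @param motifs Motif features from \code{\link{extractMotifs}}.
#' @param tokens Character vector of gene tokens of the query BGC.
#' @param bgcId Identifier recorded in the output (default \code{"query"}).
#' @param gammaMin Per-gene probability cut-off (default 0.3).
#' @param gammaSumMin Cut-off on the summed probabilities (default 1.1);
#'   with the per-gene cut-off this enforces "more than one gene".
#' @param overlapMin Overlap-score threshold (default 0.15).
#' @param iterations Inference iteration cap (default 50).
#' @return data.frame with one row per emitted match: \code{bgc_id},
#'   \code{topic_id}, \code{gamma_sum}, \code{overlap_score}, plus list
#'   columns \code{genes} (gene indices into \code{tokens}) and
#'   \code{gammas}.
#' @export
queryBgc <- function(model, motifs, tokens, bgcId = "query",
                     gammaMin = 0.3, gammaSumMin = 1.1, overlapMin = 0.15,
                     iterations = 50L) {
    empty <- data.frame(bgc_id = character(0), topic_id = integer(0),
                        gamma_sum = numeric(0), overlap_score = numeric(0))
    empty$genes <- list(); empty$gammas <- list()
    inf <- inferBgcTopics(model, tokens, iterations = iterations)
    gg <- inf$geneGamma
    if (nrow(gg) == 0L) return(empty)
    geneIdx <- as.integer(rownames(gg))
    rows <- list()
    for (k in seq_len(model@nTopics)) {
        hit <- which(gg[, k] >= gammaMin)
        if (length(hit) < 2L) next
        gsum <- sum(gg[hit, k])
        if (gsum <= gammaSumMin) next
        feat <- motifs[motifs$topic_id == k, , drop = FALSE]
        present <- unique(tokens[geneIdx[hit]])
        ov <- sum(feat$probability[feat$token %in% present])
        if (ov < overlapMin) next
        row <- data.frame(bgc_id = bgcId, topic_id = k, gamma_sum = gsum,
                          overlap_score = ov, stringsAsFactors = FALSE)
        row$genes <- list(geneIdx[hit])
        row$gammas <- list(as.numeric(gg[hit, k]))
        rows[[length(rows) + 1L]] <- row
    }
    if (length(rows) == 0L) return(empty)
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Query every BGC of a corpus against the motifs
#'
#' @inheritParams queryBgc
#' @param corpus A \code{\linkS4class{BgcCorpus}}.
#' @return Row-bound \code{\link{queryBgc}} results for all BGCs.
#' @export
queryCorpus <- function(model, motifs, corpus, gammaMin = 0.3,
                        gammaSumMin = 1.1, overlapMin = 0.15,
                        iterations = 50L) {
    res <- lapply(bgcIds(corpus), function(id)
        queryBgc(model, motifs, corpus@tokens[[id]], bgcId = id,
                 gammaMin = gammaMin, gammaSumMin = gammaSumMin,
                 overlapMin = overlapMin, iterations = iterations))
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
}

#' u_mass topic coherence
#'
#' For each topic, takes the \code{topM} highest-probability tokens and sums
#' \code{log((D(w_i, w_j) + 1) / D(w_j))} over ordered pairs i < j, where D
#' is the number of corpus documents containing a token (pair: both tokens).
#' A token absent from the corpus contributes through the +1 smoothing in
#' the numerator; an absent conditioning token uses a document frequency of
#' 1 so the term stays finite. Returns the mean over topics; higher (closer
#' to zero) is more coherent.
#'
#' @param model A \code{\linkS4class{TopicModel}}.
#' @param corpus A \code{\linkS4class{BgcCorpus}}.
#' @param topM Number of top tokens per topic (default 20).
#' @return Mean u_mass coherence (a negative number).
#' @export
coherenceUmass <- function(model, corpus, topM = 20L) {
    docSets <- lapply(corpus@tokens, function(t) unique(t[t != "-"]))
    docFreq <- function(w) sum(vapply(docSets, function(s) w %in% s,
                                      logical(1)))
    coFreq <- function(wi, wj) sum(vapply(docSets, function(s)
        (wi %in% s) && (wj %in% s), logical(1)))
    perTopic <- vapply(seq_len(model@nTopics), function(k) {
        p <- model@phi[k, ]
        ord <- order(-p, names(p))
        top <- names(p)[ord][seq_len(min(topM, length(p)))]
        dfs <- vapply(top, docFreq, numeric(1))
        total <- 0
        for (j in seq_along(top)) {
            if (j == 1L) next
            denom <- max(dfs[j], 1)
            for (i in seq_len(j - 1L))
                total <- total + log((coFreq(top[i], top[j]) + 1) / denom)
        }
        total
    }, numeric(1))
    mean(perTopic)
}

#' Compare detected sub-clusters with reference sub-clusters
#'
#' For every reference sub-cluster, the overlap is the largest fraction of
#' the reference's genes found in any detected sub-cluster of the same BGC;
#' the reference counts as detected when the overlap reaches
#' \code{overlapMin}.
#'
#' @param detected data.frame with column \code{bgc_id} and a list column
#'   \code{genes} (gene identifiers or tokens) of detected sub-clusters.
#' @param references data.frame of the same shape for the references.
#' @param overlapMin Detection threshold on the overlap (default 0.6).
#' @return \code{references} with added columns \code{overlap} and
#'   \code{detected}.
#' @export
matchReferenceSubclusters <- function(detected, references,
                                      overlapMin = 0.6) {
    if (any(lengths(references$genes) == 0L))
        stop("reference sub-cluster with zero genes")
    ov <- vapply(seq_len(nrow(references)), function(i) {
        ref <- unique(references$genes[[i]])
        cand <- detected[detected$bgc_id == references$bgc_id[i], ,
                         drop = FALSE]
        if (nrow(cand) == 0L) return(0)
        max(vapply(cand$genes, function(g)
            length(intersect(ref, g)) / length(ref), numeric(1)))
    }, numeric(1))
    references$overlap <- ov
    references$detected <- ov >= overlapMin
    references
}

#' Serialise / deserialise a topic model as JSON
#'
#' The model file is plain JSON carrying the priors, seed, vocabulary and
#' per-topic \code{[token, probability]} feature lists at full precision, so
#' it is portable and diff-able (unlike opaque binary model dumps), and
#' write-read-write round-trips are byte-identical.
#'
#' @param model A \code{\linkS4class{TopicModel}}.
#' @param path Output path.
#' @export
writeTopicModel <- function(model, path) {
    topics <- lapply(seq_len(model@nTopics), function(k) {
        p <- model@phi[k, ]
        ord <- order(-p, names(p))
        mapply(function(tok, pr) list(tok, pr),
               names(p)[ord], as.numeric(p[ord]),
               SIMPLIFY = FALSE, USE.NAMES = FALSE)
    })
    obj <- list(
        n_topics = model@nTopics,
        alpha = model@alpha,
        beta = model@beta,
        seed = model@seed,
        chunk_size = model@chunkSize,
        iterations = model@iterations,
        log_likelihood = model@logLik,
        vocabulary = model@vocab,
        topics = topics)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = FALSE)
    invisible(path)
}

#' @rdname writeTopicModel
#' @return \code{readTopicModel} returns the \code{TopicModel}.
#' @export
readTopicModel <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = FALSE)
    vocab <- as.character(unlist(obj$vocabulary))
    K <- as.integer(obj$n_topics)
    phi <- matrix(0, K, length(vocab), dimnames = list(NULL, vocab))
    for (k in seq_len(K)) {
        for (feat in obj$topics[[k]])
            phi[k, feat[[1]]] <- as.numeric(feat[[2]])
    }
    new("TopicModel",
        nTopics = K,
        alpha = as.numeric(obj$alpha),
        beta = as.numeric(obj$beta),
        phi = phi,
        vocab = vocab,
        seed = as.integer(obj$seed),
        chunkSize = as.integer(obj$chunk_size),
        iterations = as.integer(obj$iterations),
        logLik = as.numeric(unlist(obj$log_likelihood)))
}

#' Write motif matches to TSV
#'
#' @param matches data.frame from \code{\link{queryCorpus}}.
#' @param path Output path.
#' @export
writeMatchesTsv <- function(matches, path) {
    flat <- data.frame(
        bgc_id = matches$bgc_id,
        topic_id = matches$topic_id,
        genes = vapply(matches$genes, paste, character(1), collapse = ";"),
        gammas = vapply(matches$gammas, function(g)
            paste(sprintf("%.6f", g), collapse = ";"), character(1)),
        gamma_sum = matches$gamma_sum,
        overlap_score = matches$overlap_score,
        stringsAsFactors = FALSE)
    utils::write.table(flat, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
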