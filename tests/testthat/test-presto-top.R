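# A small hand-built model lets the query rules be tested deterministically,
# independent of training.
handModel <- function() {
    vocab <- c("t1", "t2", "t3", "t4", "u1", "u2")
    phi <- rbind(
        c(0.45, 0.30, 0.20, 0.05, 0.00, 0.00),
        c(0.00, 0.00, 0.00, 0.00, 0.60, 0.40))
    phi <- phi / rowSums(phi)
    colnames(phi) <- vocab
    new("TopicModel", nTopics = 2L, alpha = 0.5, beta = 0.5, phi = phi,
        vocab = vocab, seed = 1L, chunkSize = 10L, iterations = 50L,
        logLik = numeric(0))
}

test_that("motif truncation keeps the minimal 0.95 prefix", {
    vocab <- c("t1", "t2", "t3", "t4")
    phi <- matrix(c(0.6, 0.3, 0.05, 0.05,
                    0.96, 0.02, 0.01, 0.01), 2, 4, byrow = TRUE,
                  dimnames = list(NULL, vocab))
    m <- new("TopicModel", nTopics = 2L, alpha = 0.5, beta = 0.5, phi = phi,
             vocab = vocab, seed = 1L, chunkSize = 1L, iterations = 1L,
             logLik = numeric(0))
    mot <- extractMotifs(m)
    expect_equal(mot$token[mot$topic_id == 1], c("t1", "t2", "t3"))
    expect_equal(mot$token[mot$topic_id == 2], "t1")

    # uniform row over 20 tokens: 19 features reach 0.95 exactly
    vocab20 <- sprintf("w%02d", 1:20)
    phiU <- matrix(1 / 20, 2, 20, dimnames = list(NULL, vocab20))
    mU <- new("TopicModel", nTopics = 2L, alpha = 0.05, beta = 0.05,
              phi = phiU, vocab = vocab20, seed = 1L, chunkSize = 1L,
              iterations = 1L, logLik = numeric(0))
    motU <- extractMotifs(mU)
    expect_equal(sum(motU$topic_id == 1), 19L)
})

test_that("motif features always satisfy cumulative minimality", {
    fx <- generateCorpus(80, 5, 1, 0.9, seed = 31)
    corp <- filterCorpus(fx$corpus)
    model <- fitLda(corp, nTopics = 8, seed = 31, passes = 15)
    mot <- extractMotifs(model)
    for (k in seq_len(nTopics(model))) {
        p <- mot$probability[mot$topic_id == k]
        expect_true(all(diff(p) <= 1e-12))
        expect_gte(sum(p), 0.95 - 1e-9)
        if (length(p) > 1)
            expect_lt(sum(p[-length(p)]), 0.95)
    }
})

test_that("LDA training is deterministic for a fixed seed", {
    fx <- generateCorpus(60, 4, 1, 0.9, seed = 5)
    corp <- filterCorpus(fx$corpus)
    m1 <- fitLda(corp, nTopics = 6, seed = 99, passes = 8)
    m2 <- fitLda(corp, nTopics = 6, seed = 99, passes = 8)
    expect_identical(topicWordMatrix(m1), topicWordMatrix(m2))
    expect_identical(m1@logLik, m2@logLik)
    expect_error(fitLda(corp, nTopics = 1, seed = 1), "nTopics")
    one <- BgcCorpus(list(b1 = c("X", "X"), b2 = c("X", "X")))
    expect_error(fitLda(one, nTopics = 2, seed = 1), "vocabulary")
})

test_that("topics recover planted token blocks with disjoint vocabularies", {
    # no noise and full contiguity: each BGC is a pure mixture of planted
    # blocks, so each block should dominate one topic
    fx <- generateCorpus(150, 5, 0, 1, seed = 77, dupFrac = 0)
    corp <- fx$corpus
    model <- fitLda(corp, nTopics = 5, seed = 77, passes = 40)
    mot <- extractMotifs(model)
    hit <- vapply(fx$planted$tokens, function(pl) {
        max(vapply(seq_len(5), function(k) {
            top <- mot$token[mot$topic_id == k][seq_len(min(sum(
                mot$topic_id == k), length(pl)))]
            jaccard(top, pl)
        }, numeric(1)))
    }, numeric(1))
    expect_gte(sum(hit >= 0.8), 4)
    expect_length(model@logLik, 40L)
})

test_that("gene-to-motif responsibilities normalise over topics", {
    model <- handModel()
    toks <- c("t1", "-", "t2", "u1", "t3")
    inf <- inferBgcTopics(model, toks)
    expect_equal(unname(rowSums(inf$geneGamma)), rep(1, 4),
                 tolerance = 1e-6)
    expect_equal(sum(inf$theta), 1, tolerance = 1e-9)
    expect_warning(inferBgcTopics(model, c("zzz", "-")), "no tokens")
})

test_that("match emission enforces the gene, gamma-sum and overlap rules", {
    model <- handModel()
    motifs <- extractMotifs(model)
    # one strong gene only: rejected (a sub-cluster needs > 1 gene)
    one <- queryBgc(model, motifs, c("t1", "u1", "u2"))
    expect_false(1 %in% one$topic_id)
    # two clean topic-1 genes and two topic-2 genes: both topics match
    two <- queryBgc(model, motifs, c("t1", "t2", "t3", "u1", "u2"))
    expect_setequal(two$topic_id, c(1L, 2L))
    m1 <- two[two$topic_id == 1, ]
    expect_equal(sort(m1$genes[[1]]), c(1L, 2L, 3L))
    expect_gt(m1$gamma_sum, 1.1)
    expect_gte(m1$overlap_score, 0.15)
    # overlap equals the sum of the motif's feature probabilities present
    feat <- motifs[motifs$topic_id == 1, ]
    expect_equal(m1$overlap_score,
                 sum(feat$probability[feat$token %in% c("t1", "t2", "t3")]))

    # the gamma-sum cut-off rejects a two-gene candidate at sum <= 1.1
    few <- queryBgc(model, motifs, c("t1", "t2", "t3", "u1", "u2"),
                    gammaSumMin = 3.5)
    expect_false(1 %in% few$topic_id)
})

test_that("raising any cut-off never increases the number of matches", {
    fx <- generateCorpus(60, 4, 1.5, 0.9, seed = 19)
    corp <- filterCorpus(fx$corpus)
    model <- fitLda(corp, nTopics = 8, seed = 19, passes = 15)
    motifs <- extractMotifs(model)
    base <- nrow(queryCorpus(model, motifs, corp))
    expect_lte(nrow(queryCorpus(model, motifs, corp, gammaMin = 0.5)), base)
    expect_lte(nrow(queryCorpus(model, motifs, corp, gammaSumMin = 2)), base)
    expect_lte(nrow(queryCorpus(model, motifs, corp, overlapMin = 0.5)),
               base)
})

test_that("u_mass coherence equals an incidence-matrix oracle", {
    fx <- generateCorpus(40, 3, 1, 0.9, seed = 23)
    corp <- filterCorpus(fx$corpus)
    model <- fitLda(corp, nTopics = 4, seed = 23, passes = 10)
    got <- coherenceUmass(model, corp, topM = 8)

    # oracle: binary document-token incidence and its cross-product
    vocab <- vocabulary(corp)
    X <- vapply(vocab, function(w) vapply(geneTokens(corp),
        function(t) w %in% t, logical(1)), logical(nBgc(corp)))
    co <- crossprod(X)
    df <- diag(co)
    phi <- topicWordMatrix(model)
    per <- vapply(seq_len(nTopics(model)), function(k) {
        p <- phi[k, ]
        top <- names(p)[order(-p, names(p))][1:8]
        s <- 0
        for (j in 2:8) for (i in 1:(j - 1))
            s <- s + log((co[top[i], top[j]] + 1) / max(df[top[j]], 1))
        s
    }, numeric(1))
    expect_equal(got, mean(per), tolerance = 1e-12)

    # closed-form sanity: always co-occurring pair term is log((d+1)/d)
    corp2 <- BgcCorpus(list(b1 = c("A", "B"), b2 = c("A", "B"),
                            b3 = c("A", "B")))
    phi2 <- matrix(c(0.7, 0.3), 1, 2, dimnames = list(NULL, c("A", "B")))
    m2 <- new("TopicModel", nTopics = 2L, alpha = 0.5, beta = 0.5,
              phi = rbind(phi2, phi2), vocab = c("A", "B"), seed = 1L,
              chunkSize = 1L, iterations = 1L, logLik = numeric(0))
    expect_equal(coherenceUmass(m2, corp2, topM = 2), log(4 / 3))
})

test_that("reference sub-cluster overlap follows the 0.6 criterion", {
    detected <- data.frame(bgc_id = c("b1", "b1", "b2"),
                           stringsAsFactors = FALSE)
    detected$genes <- list(c("g1", "g2", "g3"), c("g7", "g8"),
                           c("g1", "g2"))
    refs <- data.frame(bgc_id = c("b1", "b1", "b2"),
                       stringsAsFactors = FALSE)
    refs$genes <- list(c("g1", "g2", "g3", "g4", "g5"),  # 3/5 shared
                       c("g7", "g8"),                     # identical
                       c("g4", "g5"))                     # disjoint
    out <- matchReferenceSubclusters(detected, refs)
    expect_equal(out$overlap, c(0.6, 1.0, 0.0))
    expect_equal(out$detected, c(TRUE, TRUE, FALSE))
    refs$genes[[1]] <- character(0)
    expect_error(matchReferenceSubclusters(detected, refs), "zero genes")
})

test_that("model JSON round-trips byte-identically and preserves the model", {
    fx <- generateCorpus(40, 3, 1, 0.9, seed = 41)
    corp <- filterCorpus(fx$corpus)
    model <- fitLda(corp, nTopics = 4, seed = 41, passes = 8)
    p1 <- withr::local_tempfile(fileext = ".json")
    p2 <- withr::local_tempfile(fileext = ".json")
    writeTopicModel(model, p1)
    back <- readTopicModel(p1)
    expect_equal(topicWordMatrix(back), topicWordMatrix(model),
                 tolerance = 1e-12)
    expect_identical(modelVocabulary(back), modelVocabulary(model))
    writeTopicModel(back, p2)
    expect_identical(readLines(p1), readLines(p2))
})
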