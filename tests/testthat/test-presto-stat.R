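test_that("duplicate genes are blanked in place and appended once", {
    expect_equal(preprocessDuplicates(c("A", "B", "A", "C")),
                 c("-", "B", "-", "C", "-", "A"))
    expect_equal(preprocessDuplicates(c("A", "B", "C")), c("A", "B", "C"))
    expect_equal(preprocessDuplicates(c("A", "A", "B", "B")),
                 c("-", "-", "-", "-", "-", "A", "-", "B"))
})

test_that("after duplicate preprocessing every non-empty token is unique", {
    set.seed(13)
    vocab <- sprintf("T%d", 1:6)
    for (i in 1:30) {
        tok <- sample(c(vocab, "-"), sample(3:12, 1), replace = TRUE)
        out <- preprocessDuplicates(tok)
        ne <- out[out != "-"]
        expect_equal(anyDuplicated(ne), 0L)
        expect_setequal(unique(ne), unique(tok[tok != "-"]))
        # appended copies follow first-occurrence order
        dup <- unique(tok[tok != "-"])[unique(tok[tok != "-"]) %in%
            tok[tok != "-"][duplicated(tok[tok != "-"])]]
        if (length(dup))
            expect_equal(utils::tail(ne, length(dup)), dup)
    }
})

test_that("interaction counting matches hand enumeration on tiny corpora", {
    # one BGC [A, B]: fixing A, the only available slot is B's, adjacent on
    # one side
    c1 <- countInteractions(BgcCorpus(list(b = c("A", "B"))))
    a <- c1[c1$tokenA == "A" & c1$tokenB == "B", ]
    expect_equal(a$Ntot, 1L); expect_equal(a$N2, 1L)
    expect_equal(a$N1, 0L); expect_equal(a$N3, 0L)
    expect_equal(a$Btot, 1L); expect_equal(a$Iobs, 1L)
    expect_equal(a$K, 1L); expect_equal(a$xobs, 1L)

    # a dash breaks adjacency but not co-localisation
    c2 <- countInteractions(BgcCorpus(list(b = c("A", "-", "B"))))
    a2 <- c2[c2$tokenA == "A" & c2$tokenB == "B", ]
    expect_equal(a2$Iobs, 0L)
    expect_equal(a2$xobs, 1L)

    # tokens never sharing a BGC produce no counted pair
    c3 <- countInteractions(BgcCorpus(list(b1 = c("A", "X"),
                                           b2 = c("B", "Y"))))
    expect_false(any(c3$tokenA == "A" & c3$tokenB == "B"))

    # a BGC sandwiching B between two As: adjacent on both sides
    c4 <- countInteractions(BgcCorpus(list(b = c("A", "B", "A"))))
    expect_equal(c4$Iobs[c4$tokenA == "A" & c4$tokenB == "B"], 2L)

    # BGC boundaries break adjacency: A ends b2 and B starts b3, which
    # must not count as an interaction
    c5 <- countInteractions(BgcCorpus(list(b1 = c("A", "-", "B"),
                                           b2 = c("A"), b3 = c("B"))))
    a5 <- c5[c5$tokenA == "A" & c5$tokenB == "B", ]
    expect_equal(a5$Iobs, 0L)
    expect_equal(a5$xobs, 1L)

    expect_error(countInteractions(tinyCorpus(),
                                   pairs = cbind("ZZZ", "PF3")),
                 "absent")
})

test_that("adjacency p-value equals the placement-enumeration oracle", {
    expect_equal(adjacencyPvalue(2, 2, 0, 4, 1, 0), 1)
    # N2 = 2 of 4 positions adjacent: P(I >= 1) for one placed B is 1/2
    expect_equal(adjacencyPvalue(2, 2, 0, 4, 1, 1), 0.5)
    set.seed(101)
    for (i in 1:60) {
        Ntot <- sample(2:9, 1)
        N3 <- sample(0:min(2, Ntot - 1), 1)
        N2 <- sample(0:(Ntot - N3 - 1), 1)
        N1 <- Ntot - N2 - N3
        Btot <- sample(1:Ntot, 1)
        Iobs <- sample(0:(2 * Btot), 1)
        got <- adjacencyPvalue(N1, N2, N3, Ntot, Btot, Iobs)
        want <- oracleAdjacencyTail(N1, N2, N3, Btot, Iobs)
        expect_equal(got, want, tolerance = 1e-11)
    }
    expect_error(adjacencyPvalue(1, 1, 1, 3, 5, 0), "Btot")
    expect_error(adjacencyPvalue(1, 1, 1, 4, 2, 1), "N1 \\+ N2 \\+ N3")
})

test_that("adjacency placement probabilities are normalised and monotone", {
    cases <- list(c(5, 3, 1, 9, 4), c(2, 2, 2, 6, 3), c(8, 0, 0, 8, 5),
                  c(0, 4, 2, 6, 4))
    for (cs in cases) {
        N1 <- cs[1]; N2 <- cs[2]; N3 <- cs[3]; Ntot <- cs[4]; Btot <- cs[5]
        # tail at 0 is the total probability mass
        expect_equal(adjacencyPvalue(N1, N2, N3, Ntot, Btot, 0), 1)
        p <- vapply(0:(2 * Btot), function(io)
            adjacencyPvalue(N1, N2, N3, Ntot, Btot, io), numeric(1))
        expect_true(all(diff(p) <= 1e-12))
    }
})

test_that("co-localisation p-value matches its enumeration oracle", {
    expect_equal(colocalisationPvalue(5, 10, 2, 0), 1)
    expect_equal(colocalisationPvalue(10, 10, 3, 2), 1)
    expect_equal(colocalisationPvalue(5, 10, 2, 2), 2 / 9)
    set.seed(202)
    for (i in 1:40) {
        Ntot <- sample(2:10, 1)
        K <- sample(0:Ntot, 1)
        Btot <- sample(1:Ntot, 1)
        xobs <- sample(0:Btot, 1)
        expect_equal(colocalisationPvalue(K, Ntot, Btot, xobs),
                     oracleColocTail(K, Ntot, Btot, xobs),
                     tolerance = 1e-11)
    }
    expect_error(colocalisationPvalue(11, 10, 2, 1), "K")
})

test_that("the conservative pair p-value is the max over directions", {
    corp <- BgcCorpus(list(b1 = c("A", "B", "C"), b2 = c("B", "A"),
                           b3 = c("C", "A", "B")))
    counts <- countInteractions(corp)
    pairs <- conservativePairPvalues(counts)
    for (r in seq_len(nrow(pairs))) {
        sel <- (counts$tokenA == pairs$tokenA[r] &
                counts$tokenB == pairs$tokenB[r]) |
               (counts$tokenA == pairs$tokenB[r] &
                counts$tokenB == pairs$tokenA[r])
        dir <- counts[sel, ]
        pd <- vapply(seq_len(nrow(dir)), function(i)
            adjacencyPvalue(dir$N1[i], dir$N2[i], dir$N3[i], dir$Ntot[i],
                            dir$Btot[i], dir$Iobs[i]), numeric(1))
        expect_equal(pairs$p_adj[r], max(pd))
        expect_true(all(pairs$p_adj[r] >= pd))
    }
})

test_that("Benjamini-Yekutieli correction matches hand and reference values", {
    expect_equal(byCorrect(0.05), 0.05)
    # m = 3, c(3) = 11/6: all three step down to 0.01 * 3 * 11/6 = 0.055
    expect_equal(byCorrect(c(0.01, 0.02, 0.03)), rep(0.055, 3))
    expect_equal(byCorrect(rep(1, 5)), rep(1, 5))
    expect_error(byCorrect(c(0.1, 1.2)), "0, 1")

    set.seed(33)
    for (i in 1:1000) {
        p <- runif(sample(1:20, 1))
        expect_equal(byCorrect(p), byReference(p), tolerance = 1e-12)
    }
})

test_that("BY output is monotone in sorted order and permutation-stable", {
    set.seed(44)
    p <- runif(50)
    q <- byCorrect(p)
    expect_true(all(diff(q[order(p)]) >= -1e-12))
    perm <- sample(50)
    expect_equal(byCorrect(p[perm]), q[perm])
    # accounting for uncomputed tests at p = 1 gives the padded adjustment
    expect_equal(byCorrect(p, nTests = 80),
                 byReference(c(p, rep(1, 30)))[1:50])
})

test_that("iterated clique detection reports cliques with their thresholds", {
    mk <- function(a, b, q) data.frame(tokenA = a, tokenB = b,
                                       q_adj = q, q_coloc = 1,
                                       stringsAsFactors = FALSE)
    # nothing below the initial threshold
    none <- detectSubclusters(mk("A", "B", 0.5))
    expect_equal(nrow(none), 0L)

    # triangle at q = 0.01
    tri <- detectSubclusters(rbind(mk("A", "B", 0.01), mk("B", "C", 0.01),
                                   mk("A", "C", 0.01)))
    expect_equal(nrow(tri), 1L)
    expect_equal(tri$tokens[[1]], c("A", "B", "C"))
    expect_equal(tri$tau, 0.1)

    # shrinking tau peels {A,B} out of the triangle
    mix <- detectSubclusters(rbind(mk("A", "B", 0.01), mk("B", "C", 0.05),
                                   mk("A", "C", 0.05)))
    keys <- vapply(mix$tokens, paste, character(1), collapse = ",")
    expect_setequal(keys, c("A,B,C", "A,B"))
    expect_equal(mix$tau[keys == "A,B,C"], 0.1)
    expect_equal(mix$tau[keys == "A,B"], 0.05)
})

test_that("maximal cliques at a threshold equal brute-force enumeration", {
    set.seed(55)
    for (rep in 1:30) {
        n <- sample(4:12, 1)
        nodes <- sprintf("N%02d", seq_len(n))
        adj <- matrix(FALSE, n, n)
        pairs <- t(utils::combn(n, 2))
        on <- runif(nrow(pairs)) < 0.35
        qs <- ifelse(on, 0.01, 0.5)
        pdf <- data.frame(tokenA = nodes[pairs[, 1]],
                          tokenB = nodes[pairs[, 2]],
                          q_adj = qs, q_coloc = 1,
                          stringsAsFactors = FALSE)
        adj[pairs[on, , drop = FALSE]] <- TRUE
        adj <- adj | t(adj)
        got <- detectSubclusters(pdf, tau0 = 0.1)
        want <- bruteMaxCliques(adj)
        gotKeys <- sort(vapply(got$tokens, paste, character(1),
                               collapse = ","))
        wantKeys <- sort(vapply(want, function(m)
            paste(nodes[m], collapse = ","), character(1)))
        expect_equal(gotKeys, wantKeys)
    }
})

test_that("sub-cluster filtering enforces size and occurrence floors", {
    corp <- BgcCorpus(list(
        b1 = c("A", "B", "C", "X"), b2 = c("A", "B", "C"),
        b3 = c("D", "E", "F"), b4 = c("G", "H")))
    subs <- data.frame(subcluster_id = c("s1", "s2", "s3"),
                       tau = 0.1, stringsAsFactors = FALSE)
    subs$tokens <- list(c("A", "B"),          # too small
                        c("D", "E", "F"),     # one BGC only
                        c("A", "B", "C"))     # kept, two BGCs
    out <- filterSubclusters(subs, corp)
    expect_equal(out$subcluster_id, "s3")
    expect_setequal(out$occurrences[[1]], c("b1", "b2"))
    expect_equal(out$n_occurrences, 2L)
})

test_that("family/clan clustering separates planted groups and drops nested
           duplicates", {
    subs <- data.frame(subcluster_id = sprintf("s%d", 1:6), tau = 0.1,
                       stringsAsFactors = FALSE)
    subs$tokens <- list(c("A", "B", "C"), c("A", "B", "C", "D"),
                        c("A", "C", "D"),
                        c("X", "Y", "Z"), c("X", "Y", "W"),
                        c("X", "Z", "W"))
    subs$occurrences <- list(c("b1", "b2"), c("b1", "b2"), c("b3", "b4"),
                             c("b5", "b6"), c("b7", "b8"), c("b5", "b9"))
    cl <- clusterFamiliesClans(subs, kFam = 2, kClan = 1, seed = 7)
    fam <- setNames(cl$subclusters$family_id, cl$subclusters$subcluster_id)
    # s1 is a subset of s2 with identical occurrences -> dropped
    expect_false("s1" %in% names(fam))
    # the two disjoint-vocabulary groups land in different families
    expect_length(unique(fam[c("s2", "s3")]), 1L)
    expect_length(unique(fam[c("s4", "s5", "s6")]), 1L)
    expect_false(fam[["s2"]] == fam[["s4"]])

    # k equal to the number of points puts every sub-cluster in its own
    # family
    cl2 <- clusterFamiliesClans(subs, kFam = 6, kClan = 2, seed = 7)
    expect_length(unique(cl2$subclusters$family_id),
                  nrow(cl2$subclusters))
    expect_error(clusterFamiliesClans(subs, kFam = 10, seed = 1), "larger")
})

test_that("the full statistical pipeline recovers planted sub-clusters", {
    fx <- generateCorpus(nBgcs = 120, nPlanted = 6, noiseRate = 1.5,
                         pContig = 0.9, seed = 17)
    corp <- filterRedundancy(filterCorpus(fx$corpus))
    res <- prestoStat(corp, seed = 17)
    expect_gt(nrow(res$subclusters), 0)
    expect_true(all(lengths(res$subclusters$tokens) >= 3))
    expect_true(all(res$subclusters$n_occurrences >= 2))
    best <- vapply(fx$planted$tokens, function(pl)
        max(vapply(res$subclusters$tokens, jaccard, numeric(1), b = pl)),
        numeric(1))
    expect_gte(sum(best >= 0.8), 5)
})
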