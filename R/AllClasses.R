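#' @import methods
#' @importFrom stats phyper p.adjust kmeans rbinom rpois runif rgamma setNames
#' @importFrom utils head combn
NULL

#' Corpus of tokenised biosynthetic gene clusters
#'
#' A \code{BgcCorpus} holds a collection of BGCs in tokenised form: each gene
#' is represented by the ordered string of its biosynthetic (sub)Pfam domains,
#' joined by \code{";"}, and a gene without any retained domain is the empty
#' token \code{"-"}. Gene order follows genomic order. The token vocabulary
#' and per-domain occurrence counts are derived views (see
#' \code{\link{vocabulary}} and \code{\link{domainCounts}}), so they can never
#' drift out of sync with the tokens.
#'
#' @slot tokens A named list; one character vector of gene tokens per BGC,
#'   names are the BGC identifiers.
#' @slot biosynClass Character vector of biosynthetic class labels (may be
#'   \code{NA}), parallel to \code{tokens}.
#' @slot strain Character vector of strain labels (may be \code{NA}),
#'   parallel to \code{tokens}.
#' @slot contigEdge Logical vector flagging BGCs that lie on a contig edge,
#'   parallel to \code{tokens}.
#'
#' @seealso \code{\link{BgcCorpus}} for the constructor,
#'   \code{\link{readClusterFile}} / \code{\link{writeClusterFile}} for the
#'   on-disk format, \code{\link{filterCorpus}} for the corpus-level filters.
#' @exportClass BgcCorpus
setClass("BgcCorpus",
    slots = c(
        tokens = "list",
        biosynClass = "character",
        strain = "character",
        contigEdge = "logical"
    )
)

setValidity("BgcCorpus", function(object) {
    n <- length(object@tokens)
    ids <- names(object@tokens)
    if (is.null(ids) || any(is.na(ids)) || any(ids == ""))
        return("every BGC must have a non-empty id (names of 'tokens')")
    if (anyDuplicated(ids))
        return("duplicate BGC ids")
    if (length(object@biosynClass) != n || length(object@strain) != n ||
        length(object@contigEdge) != n)
        return("metadata vectors must be parallel to 'tokens'")
    for (i in seq_len(n)) {
        tok <- object@tokens[[i]]
        if (!is.character(tok) || length(tok) == 0L)
            return(sprintf("BGC '%s' has no genes", ids[i]))
        if (any(is.na(tok)) || any(tok == ""))
            return(sprintf("BGC '%s' has an empty/NA token; use '-'", ids[i]))
    }
    TRUE
})

#' Construct a tokenised-BGC corpus
#'
#' @param tokens Named list of character vectors; each element is one BGC as
#'   an ordered sequence of gene tokens (domains joined by \code{";"}, empty
#'   gene \code{"-"}), named by BGC id.
#' @param biosynClass Optional character vector of class labels per BGC.
#' @param strain Optional character vector of strain labels per BGC.
#' @param contigEdge Optional logical vector per BGC; defaults to
#'   \code{FALSE}.
#' @return A \code{\linkS4class{BgcCorpus}}.
#' @examples
#' corp <- BgcCorpus(list(
#'     bgcA = c("PF00501;PF00550", "-", "PF00106"),
#'     bgcB = c("PF00501;PF00550", "PF00106")
#' ))
#' nBgc(corp)
#' vocabulary(corp)
#' @export
BgcCorpus <- function(tokens, biosynClass = NULL, strain = NULL,
                      contigEdge = NULL) {
    n <- length(tokens)
    if (is.null(biosynClass)) biosynClass <- rep(NA_character_, n)
    if (is.null(strain)) strain <- rep(NA_character_, n)
    if (is.null(contigEdge)) contigEdge <- rep(FALSE, n)
    new("BgcCorpus",
        tokens = tokens,
        biosynClass = as.character(biosynClass),
        strain = as.character(strain),
        contigEdge = as.logical(contigEdge))
}

#' @describeIn BgcCorpus Number of BGCs in the corpus.
#' @param x,object A \code{BgcCorpus}.
#' @export
nBgc <- function(x) length(x@tokens)

#' BGC identifiers
#' @param x A \code{\linkS4class{BgcCorpus}}.
#' @return Character vector of BGC ids.
#' @export
bgcIds <- function(x) names(x@tokens)

#' Gene tokens of one or all BGCs
#' @param x A \code{\linkS4class{BgcCorpus}}.
#' @param id Optional single BGC id; if omitted the full named list is
#'   returned.
#' @return A character vector (one BGC) or named list (all BGCs).
#' @export
geneTokens <- function(x, id = NULL) {
    if (is.null(id)) return(x@tokens)
    if (!id %in% names(x@tokens)) stop("unknown BGC id: ", id)
    x@tokens[[id]]
}

#' Strain labels per BGC
#' @param x A \code{\linkS4class{BgcCorpus}}.
#' @export
strains <- function(x) setNames(x@strain, names(x@tokens))

#' Biosynthetic class labels per BGC
#' @param x A \code{\linkS4class{BgcCorpus}}.
#' @export
biosynClasses <- function(x) setNames(x@biosynClass, names(x@tokens))

#' Contig-edge flags per BGC
#' @param x A \code{\linkS4class{BgcCorpus}}.
#' @export
contigEdges <- function(x) setNames(x@contigEdge, names(x@tokens))

#' Token vocabulary of a corpus
#'
#' The set of distinct non-empty gene tokens present in the corpus, sorted.
#' @param x A \code{\linkS4class{BgcCorpus}}.
#' @return Character vector.
#' @export
vocabulary <- function(x) {
    tok <- unlist(x@tokens, use.names = FALSE)
    sort(unique(tok[tok != "-"]))
}

#' Domain occurrence counts of a corpus
#'
#' Counts each domain accession every time it occurs in a gene token,
#' corpus-wide.
#' @param x A \code{\linkS4class{BgcCorpus}}.
#' @return Named integer vector, sorted by domain accession.
#' @export
domainCounts <- function(x) {
    tok <- unlist(x@tokens, use.names = FALSE)
    tok <- tok[tok != "-"]
    doms <- unlist(strsplit(tok, ";", fixed = TRUE), use.names = FALSE)
    if (length(doms) == 0L) return(setNames(integer(0), character(0)))
    tab <- table(doms)
    setNames(as.integer(tab), names(tab))
}

#' Subset a corpus by BGC id
#' @param x A \code{\linkS4class{BgcCorpus}}.
#' @param ids Character vector of BGC ids to keep (order preserved as given).
#' @return A \code{BgcCorpus} restricted to \code{ids}.
#' @export
subsetCorpus <- function(x, ids) {
    idx <- match(ids, names(x@tokens))
    if (anyNA(idx)) stop("unknown BGC id(s): ",
                         paste(ids[is.na(idx)], collapse = ", "))
    new("BgcCorpus",
        tokens = x@tokens[idx],
        biosynClass = x@biosynClass[idx],
        strain = x@strain[idx],
        contigEdge = x@contigEdge[idx])
}

setMethod("show", "BgcCorpus", function(object) {
    nne <- vapply(object@tokens, function(t) sum(t != "-"), integer(1))
    cat("BgcCorpus with", length(object@tokens), "BGCs\n")
    cat("  vocabulary size:", length(vocabulary(object)), "tokens,",
        length(domainCounts(object)), "distinct domains\n")
    cat("  non-empty genes per BGC: median",
        if (length(nne)) stats::median(nne) else 0, "\n")
    ids <- names(object@tokens)
    cat("  ids:", paste(head(ids, 4), collapse = ", "),
        if (length(ids) > 4) "..." else "", "\n")
})

#' Latent Dirichlet allocation topic model over gene tokens
#'
#' Fitted by \code{\link{fitLda}}. Topics are interpreted as sub-cluster
#' motifs: recurring combinations of gene tokens that tend to occur together
#' in BGCs.
#'
#' @slot nTopics Number of topics (motifs).
#' @slot alpha Symmetric document-topic Dirichlet prior (default 1/nTopics).
#' @slot beta Symmetric topic-token Dirichlet prior (default 1/nTopics).
#' @slot phi Numeric matrix, nTopics x vocabulary; each row is a topic's
#'   probability distribution over tokens (rows sum to 1).
#' @slot vocab Ordered character vector of tokens (columns of \code{phi}).
#' @slot seed Integer seed used for training.
#' @slot chunkSize Mini-batch size used during online variational inference.
#' @slot iterations Per-document variational iteration cap used in training.
#' @slot logLik Numeric vector: variational lower bound per training pass,
#'   on the held-out documents (see \code{\link{fitLda}}).
#' @exportClass TopicModel
setClass("TopicModel",
    slots = c(
        nTopics = "integer",
        alpha = "numeric",
        beta = "numeric",
        phi = "matrix",
        vocab = "character",
        seed = "integer",
        chunkSize = "integer",
        iterations = "integer",
        logLik = "numeric"
    )
)

setValidity("TopicModel", function(object) {
    if (object@nTopics < 2L) return("nTopics must be >= 2")
    if (nrow(object@phi) != object@nTopics)
        return("phi must have nTopics rows")
    if (ncol(object@phi) != length(object@vocab))
        return("phi columns must match vocabulary")
    rs <- rowSums(object@phi)
    if (any(abs(rs - 1) > 1e-6))
        return("phi rows must each sum to 1")
    if (any(object@phi < 0)) return("phi must be non-negative")
    TRUE
})

setMethod("show", "TopicModel", function(object) {
    cat("TopicModel:", object@nTopics, "topics over",
        length(object@vocab), "tokens\n")
    cat("  alpha =", signif(object@alpha, 4),
        " beta =", signif(object@beta, 4),
        " seed =", object@seed, "\n")
    if (length(object@logLik))
        cat("  final held-out bound per token:",
            signif(object@logLik[length(object@logLik)], 6), "\n")
})

#' Number of topics in a model
#' @param x A \code{\linkS4class{TopicModel}}.
#' @export
nTopics <- function(x) x@nTopics

#' Topic-token probability matrix
#' @param x A \code{\linkS4class{TopicModel}}.
#' @return Matrix nTopics x vocabulary, rows summing to 1.
#' @export
topicWordMatrix <- function(x) x@phi

#' Vocabulary of a topic model
#' @param x A \code{\linkS4class{TopicModel}}.
#' @export
modelVocabulary <- function(x) x@vocab
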