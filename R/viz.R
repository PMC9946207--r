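## Minimal SVG report of sub-cluster / motif matches on one BGC: gene arrows
## in genomic order, colour-grouped per hit, one track per hit. The SVG text
## is built deterministically so fixed inputs give byte-identical files.

svgPalette <- c("#1b9e77", "#d95f02", "#7570b3", "#e7298a", "#66a61e",
                "#e6ab02", "#a6761d", "#666666")

svgEsc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
}

geneArrow <- function(x, y, w, h, fill) {
    tip <- min(10, w * 0.3)
    pts <- sprintf("%.1f,%.1f", c(x, x + w - tip, x + w, x + w - tip, x),
                   c(y, y, y + h / 2, y + h, y + h))
    sprintf('<polygon points="%s" fill="%s" stroke="#333333" stroke-width="1"/>',
            paste(pts, collapse = " "), fill)
}

#' Render sub-cluster and motif matches on a BGC as SVG
#'
#' Draws the BGC's genes as arrows in genomic order with their tokens as
#' labels, then one track per hit: statistical sub-clusters (matched by
#' token) and topic-motif matches (matched by gene index), each with its
#' own colour and a legend entry carrying the id and score. The output is
#' plain deterministic SVG text.
#'
#' @param tokens Character vector of gene tokens of the BGC.
#' @param bgcId Identifier used in the title.
#' @param statHits Optional sub-cluster data.frame (list column
#'   \code{tokens}, columns \code{subcluster_id}, \code{tau}).
#' @param topHits Optional motif-match data.frame (list columns
#'   \code{genes}, \code{gammas}; columns \code{topic_id},
#'   \code{overlap_score}) as from \code{\link{queryBgc}}; gene indices must
#'   lie inside the BGC.
#' @param out Output file path.
#' @return \code{out}, invisibly.
#' @export
renderMatches <- function(tokens, bgcId, statHits = NULL, topHits = NULL,
                          out) {
    n <- length(tokens)
    if (!is.null(topHits) && nrow(topHits) > 0) {
        allIdx <- unlist(topHits$genes)
        if (any(allIdx < 1L | allIdx > n))
            stop("motif match references a gene index outside the BGC")
    }
    gw <- 70; gh <- 18; gap <- 6; x0 <- 10; y0 <- 30
    nStat <- if (is.null(statHits)) 0L else nrow(statHits)
    nTop <- if (is.null(topHits)) 0L else nrow(topHits)
    nTracks <- nStat + nTop
    width <- x0 * 2 + n * (gw + gap)
    height <- y0 + (nTracks + 1) * (gh + 14) + 20
    lines <- c(
        sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">',
                width, height),
        sprintf('<text x="%d" y="18" font-family="monospace" font-size="13">%s</text>',
                x0, svgEsc(bgcId)))
    ## base track: uncoloured genes with token labels
    for (i in seq_len(n)) {
        x <- x0 + (i - 1) * (gw + gap)
        lines <- c(lines,
            geneArrow(x, y0, gw, gh, "#dddddd"),
            sprintf('<text x="%.1f" y="%.1f" font-family="monospace" font-size="8">%s</text>',
                    x + 2, y0 + gh + 10, svgEsc(tokens[i])))
    }
    track <- 0L
    emit <- function(lines, hitGenes, label, colour) {
        y <- y0 + (track + 1L) * (gh + 14)
        for (i in hitGenes) {
            x <- x0 + (i - 1) * (gw + gap)
            lines <- c(lines, geneArrow(x, y, gw, gh, colour))
        }
        c(lines,
          sprintf('<text x="%d" y="%.1f" font-family="monospace" font-size="9" fill="%s">%s</text>',
                  x0, y + gh + 11, colour, svgEsc(label)))
    }
    if (nStat > 0) for (h in seq_len(nStat)) {
        colour <- svgPalette[(track %% length(svgPalette)) + 1L]
        genes <- which(tokens %in% statHits$tokens[[h]])
        label <- sprintf("%s tau=%.3g n=%d", statHits$subcluster_id[h],
                         statHits$tau[h], length(genes))
        lines <- emit(lines, genes, label, colour)
        track <- track + 1L
    }
    if (nTop > 0) for (h in seq_len(nTop)) {
        colour <- svgPalette[(track %% length(svgPalette)) + 1L]
        genes <- topHits$genes[[h]]
        label <- sprintf("motif %d overlap=%.3f", topHits$topic_id[h],
                         topHits$overlap_score[h])
        lines <- emit(lines, genes, label, colour)
        track <- track + 1L
    }
    lines <- c(lines, "</svg>")
    writeLines(lines, out, useBytes = TRUE)
    invisible(out)
}

#' Write a run-configuration record
#'
#' Serialises the parameters, seeds and package version of a run as JSON
#' next to its outputs, so any output directory documents how it was made.
#'
#' @param params Named list of parameters.
#' @param outDir Directory to write \code{run_config.json} into.
#' @return The config file path, invisibly.
#' @export
writeRunConfig <- function(params, outDir) {
    cfg <- c(list(tool = "subclust",
                  version = as.character(utils::packageVersion("subclust")),
                  timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
             params)
    path <- file.path(outDir, "run_config.json")
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(path)
}
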