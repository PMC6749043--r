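# Pathway over-representation and topology-impact screening, plus the
# curated metabolite-protein network.
#
# Enrichment is the standard hypergeometric over-representation test per
# pathway (BH-corrected across pathways); topology impact is the summed
# relative betweenness centrality of the matched nodes divided by the
# pathway total, and pathways with impact strictly above 0.1 are screened
# as potential targets.

#' Load packaged pathway graphs
#'
#' Reads the edge-list fixtures (KEGG compound identifiers as node labels)
#' listed in a pathway index CSV.  The packaged set covers the ten serum
#' amino-acid / energy pathways relevant to the hypertensive-rat biomarkers
#' plus five decoys.
#'
#' @param index_path index CSV with columns \code{id}, \code{name},
#'   \code{file}, \code{decoy}.
#' @return list of \code{pathway_graph} objects (\code{id}, \code{name},
#'   \code{graph} (igraph), \code{nodes}, \code{decoy}).
#' @export
load_pathways <- function(index_path = nmrmetab_extdata("pathways",
                                                        "pathway_index.csv")) {
  idx <- utils::read.csv(index_path, stringsAsFactors = FALSE)
  dir <- dirname(index_path)
  lapply(seq_len(nrow(idx)), function(i) {
    edges <- utils::read.table(file.path(dir, idx$file[i]),
                               col.names = c("from", "to"),
                               stringsAsFactors = FALSE)
    g <- igraph::graph_from_data_frame(edges, directed = FALSE)
    if (igraph::vcount(g) < 2) {
      stop("pathway '", idx$id[i], "' has fewer than 2 nodes", call. = FALSE)
    }
    structure(list(id = idx$id[i], name = idx$name[i], graph = g,
                   nodes = igraph::V(g)$name,
                   connected = igraph::is_connected(g),
                   decoy = as.logical(idx$decoy[i])),
              class = "pathway_graph")
  })
}

#' Map metabolite names to compound identifiers
#'
#' Uses the packaged name-to-KEGG fixture; unmappable metabolites (no row
#' or NA identifier, e.g. lipoprotein signals) are dropped with a warning
#' and recorded in the \code{"unmapped"} attribute.
#'
#' @param metabolites character vector of metabolite names.
#' @param map_path compound map CSV (\code{metabolite}, \code{kegg_id}).
#' @return character vector of compound identifiers.
#' @export
map_to_compounds <- function(metabolites,
                             map_path = nmrmetab_extdata("compound_map.csv")) {
  map <- utils::read.csv(map_path, stringsAsFactors = FALSE,
                         na.strings = "NA")
  key <- normalize_metabolite(map$metabolite)
  ids <- map$kegg_id[match(normalize_metabolite(metabolites), key)]
  unmapped <- metabolites[is.na(ids)]
  if (length(unmapped)) {
    warning("unmappable metabolite(s) excluded from pathway analysis: ",
            paste(unmapped, collapse = ", "), call. = FALSE)
  }
  out <- ids[!is.na(ids)]
  attr(out, "unmapped") <- unmapped
  out
}

#' Hypergeometric pathway over-representation
#'
#' Upper-tail hypergeometric p per pathway: with \code{N} background
#' compounds, \code{K} of them in the pathway, and \code{n} mapped
#' biomarkers of which \code{k} hit the pathway,
#' \code{p = P(X >= k)} for \code{X ~ Hypergeom(N, K, n)}; BH-adjusted
#' across pathways.
#'
#' @param compounds mapped biomarker compound identifiers.
#' @param pathways list of \code{pathway_graph}s.
#' @param background compound universe; defaults to the union of all
#'   pathway nodes and the supplied compounds.
#' @return data.frame: \code{id}, \code{name}, \code{n_nodes},
#'   \code{n_matched}, \code{matched}, \code{enrichment_p},
#'   \code{enrichment_p_adjusted}.
#' @export
enrich <- function(compounds, pathways, background = NULL) {
  compounds <- unique(compounds)
  if (is.null(background)) {
    background <- unique(c(unlist(lapply(pathways, `[[`, "nodes")),
                           compounds))
  }
  if (!all(compounds %in% background)) {
    background <- unique(c(background, compounds))
  }
  N <- length(background)
  n <- length(compounds)
  rows <- lapply(pathways, function(pw) {
    nodes <- intersect(pw$nodes, background)
    hits <- intersect(compounds, nodes)
    k <- length(hits); K <- length(nodes)
    p <- if (k == 0) 1 else stats::phyper(k - 1, K, N - K, n,
                                          lower.tail = FALSE)
    data.frame(id = pw$id, name = pw$name, n_nodes = length(pw$nodes),
               n_matched = k, matched = paste(hits, collapse = ";"),
               enrichment_p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$enrichment_p_adjusted <- stats::p.adjust(out$enrichment_p,
                                               method = "BH")
  out
}

#' Topology impact of matched nodes in a pathway
#'
#' Relative betweenness centrality (node betweenness normalized by
#' \code{(n-1)(n-2)/2} on the undirected graph) summed over matched nodes,
#' divided by the sum over all pathway nodes; lies in [0, 1].  When every
#' node has zero betweenness (e.g. a two-node pathway) the matched-node
#' fraction is returned instead so a full match still scores 1.
#'
#' @param compounds matched biomarker compound identifiers.
#' @param pathway a \code{pathway_graph}.
#' @return impact value in [0, 1].
#' @export
topology_impact <- function(compounds, pathway) {
  g <- pathway$graph
  nv <- igraph::vcount(g)
  if (nv == 0) stop("empty pathway graph", call. = FALSE)
  matched <- intersect(compounds, igraph::V(g)$name)
  if (!length(matched)) return(0)
  btw <- igraph::betweenness(g, directed = FALSE)
  norm <- (nv - 1) * (nv - 2) / 2
  if (norm <= 0 || sum(btw) == 0) {
    return(length(matched) / nv)
  }
  rbc <- btw / norm
  sum(rbc[matched]) / sum(rbc)
}

#' Score and screen pathways by impact
#'
#' Combines enrichment and topology impact per pathway, then retains
#' pathways with impact strictly above the threshold (0.1 by default),
#' sorted by impact descending with enrichment p as the tiebreak.
#'
#' @param compounds mapped biomarker compound identifiers.
#' @param pathways list of \code{pathway_graph}s.
#' @param background optional compound universe (see \code{\link{enrich}}).
#' @return data.frame of pathway results with an \code{impact} column.
#' @export
pathway_results <- function(compounds, pathways, background = NULL) {
  res <- enrich(compounds, pathways, background)
  res$impact <- vapply(pathways, function(pw) {
    topology_impact(compounds, pw)
  }, numeric(1))
  res
}

#' @rdname pathway_results
#' @param results data.frame from \code{pathway_results}.
#' @param impact_threshold retain pathways with \code{impact >} this value.
#' @export
screen_pathways <- function(results, impact_threshold = 0.1) {
  keep <- results$impact > impact_threshold
  out <- results[keep, , drop = FALSE]
  out[order(-out$impact, out$enrichment_p), , drop = FALSE]
}

#' Metabolite-protein bipartite network
#'
#' Restricts the curated metabolite-to-protein mapping (hypertension-related
#' enzymes: TH, CBS, DDC, CTH, TYR, HDC, PLD2, AGXT2, KAT, ALT) to the
#' supplied biomarkers and returns the bipartite edge list plus a node
#' table for graph viewers.
#'
#' @param biomarkers metabolite names.
#' @param map_path curated mapping CSV (\code{metabolite}, \code{protein}).
#' @return list with \code{edges} (metabolite, protein) and \code{nodes}
#'   (name, type).
#' @export
build_metabolite_protein_network <- function(
    biomarkers,
    map_path = nmrmetab_extdata("metabolite_protein_map_synthetic.csv")) {
  map <- utils::read.csv(map_path, stringsAsFactors = FALSE)
  keep <- normalize_metabolite(map$metabolite) %in%
    normalize_metabolite(biomarkers)
  edges <- map[keep, , drop = FALSE]
  if (!nrow(edges)) {
    warning("no curated protein links for the supplied biomarkers",
            call. = FALSE)
  }
  nodes <- data.frame(
    name = c(unique(edges$metabolite), unique(edges$protein)),
    type = rep(c("metabolite", "protein"),
               c(length(unique(edges$metabolite)),
                 length(unique(edges$protein)))),
    stringsAsFactors = FALSE)
  list(edges = edges, nodes = nodes)
}
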