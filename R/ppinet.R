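# Protein-interaction network stage: confidence filtering, hub scoring
# (degree, betweenness), and MCODE-style dense-subnetwork extraction.

#' Build a PPI graph from a confidence-scored edge list
#'
#' Keeps edges with confidence at least `min_confidence` (inclusive, so
#' the conventional 0.700 "high confidence" edges pass), removes
#' self-loops, collapses duplicate edges keeping the maximum confidence,
#' and drops isolated nodes.
#'
#' @param edges data frame (or TSV path) with columns `protein_a`,
#'   `protein_b`, `confidence` (unnamed three-column input accepted).
#' @param min_confidence retention threshold in `[0, 1]` (default 0.7).
#' @return an undirected simple `igraph` graph with edge attribute
#'   `confidence`.
#' @export
load_ppi_graph <- function(edges, min_confidence = 0.7) {
  if (is.character(edges)) {
    edges <- utils::read.delim(edges, stringsAsFactors = FALSE)
  }
  if (ncol(edges) < 3) stop("edge list needs 3 columns: node, node, confidence")
  edges <- edges[, 1:3]
  names(edges) <- c("protein_a", "protein_b", "confidence")
  edges$confidence <- as.numeric(edges$confidence)
  if (any(is.na(edges$confidence)) ||
      any(edges$confidence < 0 | edges$confidence > 1)) {
    stop("confidence scores must be numbers in [0, 1]")
  }
  if (anyNA(edges$protein_a) || anyNA(edges$protein_b)) {
    stop("malformed rows: missing node names")
  }
  edges <- edges[edges$protein_a != edges$protein_b, , drop = FALSE]
  edges <- edges[edges$confidence >= min_confidence, , drop = FALSE]
  if (nrow(edges) == 0) {
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  # collapse duplicates (either orientation) keeping the max confidence
  key <- paste(pmin(edges$protein_a, edges$protein_b),
               pmax(edges$protein_a, edges$protein_b), sep = "\r")
  ord <- order(key, -edges$confidence)
  edges <- edges[ord[!duplicated(key[ord])], , drop = FALSE]
  igraph::graph_from_data_frame(edges, directed = FALSE)
}

#' Degree and betweenness hub table
#'
#' Degree counts incident interactions; betweenness is the unnormalized
#' shortest-path count share on the unweighted graph (endpoints excluded),
#' counting each unordered pair once.
#'
#' @param g an undirected `igraph` graph.
#' @return data frame with `node`, `degree`, `betweenness`, sorted by
#'   decreasing degree.
#' @export
centrality <- function(g) {
  if (igraph::vcount(g) == 0) {
    return(data.frame(node = character(0), degree = integer(0),
                      betweenness = numeric(0)))
  }
  out <- data.frame(
    node = igraph::V(g)$name %||% as.character(seq_len(igraph::vcount(g))),
    degree = unname(igraph::degree(g)),
    betweenness = unname(igraph::betweenness(g, directed = FALSE,
                                             normalized = FALSE))
  )
  out[order(-out$degree, out$node), , drop = FALSE]
}

graph_density <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2) return(0)
  2 * igraph::ecount(g) / (n * (n - 1))
}

# Highest k-core of a graph: the subgraph induced by nodes of maximum
# coreness. Returns list(k, subgraph).
highest_kcore <- function(g) {
  if (igraph::vcount(g) == 0) return(list(k = 0, subgraph = g))
  core <- igraph::coreness(g)
  k <- max(core)
  list(k = k, subgraph = igraph::induced_subgraph(g, which(core == k)))
}

#' Extract dense subnetworks (MCODE-style)
#'
#' Seeded, density-based clustering: each node is weighted by the product
#' of its neighborhood's highest k-core number and that core's density;
#' clusters grow outward from the highest-weight unvisited seed, admitting
#' neighbors whose weight is at least `(1 - node_score_cutoff)` times the
#' seed weight; clusters whose induced subgraph has maximum coreness below
#' `kcore_filter` are discarded. Clusters are node-disjoint and ranked by
#' `score = density * size`.
#'
#' @param g an undirected `igraph` graph.
#' @param node_score_cutoff expansion tolerance (default 0.2).
#' @param kcore_filter minimum k-core a cluster must contain (default 2).
#' @return data frame with one row per cluster: `rank`, `score`, `size`,
#'   `density`, `seed`, `members` (comma-separated); attribute
#'   `membership` holds the node lists.
#' @export
dense_subnetworks <- function(g, node_score_cutoff = 0.2, kcore_filter = 2) {
  empty <- data.frame(rank = integer(0), score = numeric(0),
                      size = integer(0), density = numeric(0),
                      seed = character(0), members = character(0))
  attr(empty, "membership") <- list()
  n <- igraph::vcount(g)
  if (n == 0 || igraph::ecount(g) == 0) return(empty)
  nodes <- igraph::V(g)$name %||% as.character(seq_len(n))

  weight <- vapply(seq_len(n), function(v) {
    nb <- c(v, as.integer(igraph::neighbors(g, v)))
    sub <- igraph::induced_subgraph(g, nb)
    hk <- highest_kcore(sub)
    hk$k * graph_density(hk$subgraph)
  }, numeric(1))

  visited <- rep(FALSE, n)
  clusters <- list()
  for (seed in order(-weight)) {
    if (visited[seed]) next
    members <- seed
    visited[seed] <- TRUE
    frontier <- seed
    threshold <- (1 - node_score_cutoff) * weight[seed]
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) {
        for (u in as.integer(igraph::neighbors(g, v))) {
          if (!visited[u] && weight[u] >= threshold) {
            visited[u] <- TRUE
            members <- c(members, u)
            nxt <- c(nxt, u)
          }
        }
      }
      frontier <- nxt
    }
    if (length(members) < 2) next
    sub <- igraph::induced_subgraph(g, members)
    if (max(igraph::coreness(sub)) < kcore_filter) next
    clusters[[length(clusters) + 1L]] <- list(
      seed = nodes[seed], members = sort(nodes[members]),
      size = length(members), density = graph_density(sub),
      score = graph_density(sub) * length(members))
  }
  if (!length(clusters)) return(empty)
  out <- data.frame(
    score = vapply(clusters, `[[`, 0, "score"),
    size = vapply(clusters, `[[`, 0L, "size"),
    density = vapply(clusters, `[[`, 0, "density"),
    seed = vapply(clusters, `[[`, "", "seed"),
    members = vapply(clusters, function(cl) paste(cl$members, collapse = ","), "")
  )
  ord <- order(-out$score, -out$size)
  out <- out[ord, , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  attr(out, "membership") <- lapply(clusters[ord], `[[`, "members")
  out
}

#' Simulate a random graph with planted dense subgraphs
#'
#' Erdos-Renyi background over `n_background` nodes at edge probability
#' `p_background`, with cliques-like planted groups wired at `p_within`
#' and attached to the background by one low-confidence edge each.
#' Planted edges receive high confidence, background edges moderate
#' confidence, so the default 0.7 filter retains the planted structure.
#'
#' @param n_background background node count.
#' @param planted_sizes integer vector of planted subgraph sizes.
#' @param p_background background edge probability (default 0.05).
#' @param p_within planted within-group edge probability (default 1).
#' @param seed integer seed.
#' @return list with `edges` (data frame `protein_a`, `protein_b`,
#'   `confidence`) and `truth` (node membership list).
#' @export
simulate_ppi_graph <- function(n_background, planted_sizes = integer(0),
                               p_background = 0.05, p_within = 1, seed = 1L) {
  stopifnot(n_background >= 2, all(planted_sizes >= 2),
            p_background >= 0, p_background <= 1,
            p_within >= 0, p_within <= 1)
  with_seed(seed, {
    bg <- sprintf("bg%03d", seq_len(n_background))
    edges <- list()
    pairs <- utils::combn(bg, 2)
    on <- stats::runif(ncol(pairs)) < p_background
    if (any(on)) {
      edges[[1]] <- data.frame(protein_a = pairs[1, on], protein_b = pairs[2, on],
                               confidence = stats::runif(sum(on), 0.7, 0.85))
    }
    truth <- list()
    for (i in seq_along(planted_sizes)) {
      nm <- sprintf("pl%d_%02d", i, seq_len(planted_sizes[i]))
      truth[[i]] <- nm
      pp <- utils::combn(nm, 2)
      on <- stats::runif(ncol(pp)) < p_within
      if (any(on)) {
        edges[[length(edges) + 1L]] <- data.frame(
          protein_a = pp[1, on], protein_b = pp[2, on],
          confidence = stats::runif(sum(on), 0.9, 0.999))
      }
      edges[[length(edges) + 1L]] <- data.frame(
        protein_a = nm[1], protein_b = sample(bg, 1),
        confidence = stats::runif(1, 0.4, 0.6))
    }
    list(edges = do.call(rbind, edges), truth = truth)
  })
}
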