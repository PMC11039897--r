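graph_density_simple <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2) return(0)
  2 * igraph::ecount(g) / (n * (n - 1))
}

#' MCODE vertex weighting
#'
#' Scores each node by the density of the densest core around it: nodes
#' with degree below `degree_cutoff` get weight 0; for every other node
#' the induced subgraph on its closed neighbourhood is core-decomposed,
#' and the weight is `k * d`, where `k` is the highest core order present
#' and `d` the edge density (`2E / (V (V - 1))`) of that highest k-core.
#'
#' @param graph A simple undirected [igraph::igraph]; vertices must be
#'   named.
#' @param degree_cutoff Minimum degree for a non-zero weight (default 2).
#' @return Named numeric vector of vertex weights.
#' @export
vertex_weights <- function(graph, degree_cutoff = 2) {
  stopifnot(degree_cutoff >= 2)
  nodes <- igraph::V(graph)$name
  if (is.null(nodes)) stop("graph vertices must be named", call. = FALSE)
  deg <- igraph::degree(graph)
  w <- stats::setNames(numeric(length(nodes)), nodes)
  for (v in nodes[deg >= degree_cutoff]) {
    nb <- igraph::neighbors(graph, v)$name
    sub <- igraph::induced_subgraph(graph, c(v, nb))
    core <- igraph::coreness(sub)
    k_max <- max(core)
    if (k_max == 0) next
    kcore <- igraph::induced_subgraph(sub, names(core)[core >= k_max])
    w[v] <- k_max * graph_density_simple(kcore)
  }
  w
}

#' MCODE dense-complex discovery
#'
#' Finds dense subnetworks ("complexes") in a protein-interaction graph.
#' Unassigned nodes are taken as seeds in order of decreasing
#' [vertex_weights()] score (ties by node name); from each seed a
#' breadth-first expansion up to `max_depth` levels adds unassigned
#' neighbours whose weight is at least
#' `seed_weight * (1 - node_score_cutoff)`. Each node belongs to at most
#' one complex. Candidate complexes lacking a k-core of order `k_core` are
#' discarded; with `haircut` enabled, members of degree < 2 in the
#' complex-induced subgraph are pruned iteratively. The complex score is
#' the density of the member-induced subgraph times its size, and
#' complexes are returned in decreasing score order (ties by smallest
#' member name).
#'
#' @param graph A simple undirected named [igraph::igraph].
#' @param degree_cutoff Minimum degree for vertex scoring (default 2).
#' @param node_score_cutoff Fractional weight drop tolerated during
#'   expansion (default 0.2).
#' @param k_core Minimum core order a complex must contain (default 2).
#' @param max_depth Maximum breadth-first expansion depth (default 100).
#' @param haircut Iteratively remove singly-connected members
#'   (default `TRUE`).
#' @return A tibble with one row per complex: `complex_id`, `seed_node`,
#'   `score`, `size`, and `members` (list column of character vectors).
#' @export
find_complexes <- function(graph, degree_cutoff = 2,
                           node_score_cutoff = 0.2, k_core = 2,
                           max_depth = 100, haircut = TRUE) {
  stopifnot(node_score_cutoff > 0, node_score_cutoff < 1, k_core >= 1)
  if (igraph::vcount(graph) == 0) {
    return(tibble(complex_id = integer(0), seed_node = character(0),
                  score = numeric(0), size = integer(0),
                  members = list()))
  }
  w <- vertex_weights(graph, degree_cutoff)
  assigned <- character(0)
  raw <- list()
  seeds <- names(sort(w[w > 0], decreasing = TRUE))
  # stable deterministic order: weight descending, then name
  seeds <- seeds[order(-w[seeds], seeds)]

  for (seed in seeds) {
    if (seed %in% assigned) next
    threshold <- w[seed] * (1 - node_score_cutoff)
    members <- seed
    frontier <- seed
    depth <- 0
    while (length(frontier) > 0 && depth < max_depth) {
      nb <- unique(unlist(lapply(frontier, function(v) {
        igraph::neighbors(graph, v)$name
      })))
      nb <- setdiff(nb, c(members, assigned))
      add <- nb[w[nb] >= threshold]
      members <- c(members, add)
      frontier <- add
      depth <- depth + 1
    }
    sub <- igraph::induced_subgraph(graph, members)
    if (max(igraph::coreness(sub)) < k_core) next
    if (haircut) {
      repeat {
        deg <- igraph::degree(sub)
        weak <- names(deg)[deg < 2]
        if (length(weak) == 0) break
        sub <- igraph::induced_subgraph(
          sub, setdiff(igraph::V(sub)$name, weak))
        if (igraph::vcount(sub) < 2) break
      }
    }
    members <- sort(igraph::V(sub)$name)
    if (length(members) < 2) next
    assigned <- c(assigned, members)
    raw[[length(raw) + 1]] <- list(
      seed = seed, members = members,
      score = graph_density_simple(sub) * length(members)
    )
  }

  if (length(raw) == 0) {
    return(tibble(complex_id = integer(0), seed_node = character(0),
                  score = numeric(0), size = integer(0),
                  members = list()))
  }
  scores <- vapply(raw, `[[`, numeric(1), "score")
  firsts <- vapply(raw, function(x) x$members[1], character(1))
  ord <- order(-scores, firsts)
  tibble(
    complex_id = seq_along(ord),
    seed_node = vapply(raw[ord], `[[`, character(1), "seed"),
    score = scores[ord],
    size = vapply(raw[ord], function(x) length(x$members), integer(1)),
    members = lapply(raw[ord], `[[`, "members")
  )
}

#' Hub proteins across discovered complexes
#'
#' @param complexes Output of [find_complexes()].
#' @return Tibble with one row per member node: `node`, `complex_id`,
#'   `score`.
#' @export
hub_nodes <- function(complexes) {
  if (nrow(complexes) == 0) {
    return(tibble(node = character(0), complex_id = integer(0),
                  score = numeric(0)))
  }
  tidyr::unnest(
    tibble(node = complexes$members, complex_id = complexes$complex_id,
           score = complexes$score),
    "node"
  )
}
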