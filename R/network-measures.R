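# Per-trial phonological networks: undirected graphs over a trial's unique
# correct productions, with an edge wherever two productions are at edit
# distance 1. The headline statistics are component-weighted: instead of the
# usual giant-component-only convention, the mean clustering coefficient and
# the degree assortativity are averaged across ALL components, weighted by
# node count, with isolates (and components on which the statistic is
# undefined) contributing zero. Poor performance marked by fragmented
# networks therefore penalises the statistic instead of being dropped.

#' Build the phonological network of one trial
#'
#' Nodes are the trial's unique correct productions (tonal syllables); two
#' nodes share an edge iff their slot-wise edit distance is exactly 1. The
#' stimulus is not a node of this graph — it is only attached afterwards for
#' hop computation (see [hop_distribution()]) — unless
#' `include_stimulus = TRUE`.
#'
#' @param productions Character vector of tonal pinyin strings: the trial's
#'   correct productions (duplicates are collapsed).
#' @param stimulus Optional single tonal pinyin string; required later for
#'   [hop_distribution()].
#' @param mapping A slot mapping from [pinyin_mapping()].
#' @param include_stimulus If `TRUE`, the stimulus is added as a node of the
#'   scored graph itself (an alternative convention provided for
#'   sensitivity analyses).
#' @return A `fluency_network` object: an igraph graph plus node metadata.
#'   Supports [glance()], [tidy()], [autoplot()], and the measure accessors
#'   [count_components()], [weighted_mean_clustering()],
#'   [weighted_assortativity()], [local_clustering()], [hop_distribution()].
#' @examples
#' net <- trial_network(c("zai1", "zai3", "zai4"), stimulus = "wai4")
#' glance(net)
#' @export
trial_network <- function(productions, stimulus = NULL,
                          mapping = pinyin_mapping(),
                          include_stimulus = FALSE) {
  labels <- unique(as.character(productions))
  stim_syl <- if (!is.null(stimulus)) parse_pinyin(stimulus, mapping) else NULL
  if (include_stimulus && !is.null(stimulus)) {
    labels <- unique(c(labels, stimulus))
  }
  syl <- if (length(labels)) parse_pinyin(labels, mapping) else NULL
  g <- igraph::make_empty_graph(n = length(labels), directed = FALSE)
  igraph::V(g)$name <- labels
  if (length(labels) >= 2L) {
    d <- .pairwise_edit(syl)
    idx <- which(d == 1L & upper.tri(d), arr.ind = TRUE)
    if (nrow(idx)) g <- igraph::add_edges(g, as.vector(t(idx)))
  }
  structure(
    list(graph = g, nodes = syl, stimulus = stim_syl,
         include_stimulus = include_stimulus),
    class = "fluency_network"
  )
}

#' Coerce an igraph graph to a fluency network
#'
#' Wraps an arbitrary undirected igraph graph so the component-weighted
#' measures can be applied to it directly (e.g. to worked examples or
#' simulated graphs that did not come from a response stream). Syllable
#' metadata and the stimulus are absent, so [hop_distribution()] is not
#' available on the result.
#'
#' @param graph An undirected igraph graph.
#' @return A `fluency_network`.
#' @examples
#' g <- igraph::make_full_graph(9, directed = FALSE)
#' weighted_mean_clustering(as_fluency_network(igraph::add_vertices(g, 1)))
#' @export
as_fluency_network <- function(graph) {
  stopifnot(igraph::is_igraph(graph), !igraph::is_directed(graph))
  if (is.null(igraph::V(graph)$name)) {
    igraph::V(graph)$name <- paste0("v", seq_len(igraph::vcount(graph)))
  }
  structure(list(graph = graph, nodes = NULL, stimulus = NULL,
                 include_stimulus = FALSE),
            class = "fluency_network")
}

# full pairwise slot-wise distance matrix for a syllable tibble
.pairwise_edit <- function(syl) {
  n <- nrow(syl)
  d <- matrix(0L, n, n)
  cols <- c(.slot_cols, "T")
  for (s in cols) {
    v <- as.character(syl[[s]])
    v[is.na(v)] <- "∅"
    d <- d + outer(v, v, "!=")
  }
  d
}

#' @export
print.fluency_network <- function(x, ...) {
  g <- x$graph
  cat("<fluency_network> ", igraph::vcount(g), " nodes, ",
      igraph::ecount(g), " edges, ", count_components(x),
      " component(s)\n", sep = "")
  if (!is.null(x$stimulus)) cat("stimulus: ", x$stimulus$pinyin, "\n", sep = "")
  invisible(x)
}

#' Number of connected components
#'
#' Counts the connected components of a trial network; isolated nodes each
#' count as a component. Many components mark a fragmented search that failed
#' to produce a coherent neighbourhood.
#'
#' @param net A `fluency_network` from [trial_network()].
#' @return Integer component count (`NA` for an empty network).
#' @export
count_components <- function(net) {
  n <- igraph::vcount(net$graph)
  if (n == 0L) return(NA_integer_)
  igraph::components(net$graph)$no
}

#' Local clustering coefficient of each node
#'
#' The proportion of a node's neighbour pairs that are themselves connected:
#' triangles through the node divided by `choose(degree, 2)`. Nodes of degree
#' below 2 are assigned 0 (not `NA`), the convention that makes the
#' component-weighted average well defined with isolates contributing zero.
#'
#' @inheritParams count_components
#' @return Named numeric vector, one value per node.
#' @export
local_clustering <- function(net) {
  g <- net$graph
  n <- igraph::vcount(g)
  if (n == 0L) return(numeric(0))
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = TRUE))
  k <- rowSums(A)
  tri <- diag(A %*% A %*% A) / 2
  cc <- ifelse(k < 2, 0, tri / (k * (k - 1) / 2))
  stats::setNames(as.numeric(cc), igraph::V(g)$name)
}

# node-count-weighted average of a per-component statistic
.component_weighted <- function(net, f) {
  g <- net$graph
  n <- igraph::vcount(g)
  if (n == 0L) return(NA_real_)
  comp <- igraph::components(g)
  vals <- vapply(seq_len(comp$no), function(i) {
    members <- which(comp$membership == i)
    f(g, members)
  }, numeric(1))
  sum(vals * comp$csize) / n
}

#' Component-weighted mean clustering coefficient
#'
#' The mean local clustering coefficient of each component, averaged over
#' components with weights proportional to node count, isolates contributing
#' zero. A 10-node network made of a fully connected 9-node component (mean
#' clustering 1) plus one isolate scores 0.9: the isolate dilutes the value
#' by its 10% share. Under the degree-below-2 convention of
#' [local_clustering()] this equals the plain mean of local clustering over
#' all nodes.
#'
#' @inheritParams count_components
#' @return Numeric in `[0, 1]` (`NA` for an empty network).
#' @export
weighted_mean_clustering <- function(net) {
  n <- igraph::vcount(net$graph)
  if (n == 0L) return(NA_real_)
  cc <- local_clustering(net)
  comp <- igraph::components(net$graph)
  per_comp <- tapply(cc, comp$membership, mean)
  sum(per_comp * comp$csize) / n
}

#' Component-weighted degree assortativity (mixing by degree)
#'
#' Within each component, assortativity is the Pearson correlation of
#' endpoint degrees over edges, each edge counted in both orientations so the
#' result is orientation-independent; values near -1 mark star-like
#' (disassortative) structure, values near +1 mark hubs linked to hubs. The
#' per-component values are then averaged with node-count weights. Isolates,
#' and components on which the correlation is undefined (no edges, or zero
#' degree variance as in a single edge or a cycle), contribute zero.
#'
#' @inheritParams count_components
#' @return Numeric in `[-1, 1]` (`NA` for an empty network).
#' @export
weighted_assortativity <- function(net) {
  .component_weighted(net, function(g, members) {
    sub <- igraph::induced_subgraph(g, members)
    m <- igraph::ecount(sub)
    if (m == 0L) return(0)
    deg <- igraph::degree(sub)
    e <- igraph::as_edgelist(sub, names = FALSE)
    dx <- c(deg[e[, 1]], deg[e[, 2]])
    dy <- c(deg[e[, 2]], deg[e[, 1]])
    if (stats::sd(dx) == 0 || stats::sd(dy) == 0) return(0)
    stats::cor(dx, dy)
  })
}

#' Hop distribution of correct responses from the stimulus
#'
#' Attaches the stimulus to the trial network (adding an edge to every
#' response at edit distance 1 from it) and bins the responses by their
#' shortest-path distance, in edges, from the stimulus. Responses with no
#' path to the stimulus are binned as `"disconnected"`.
#'
#' @inheritParams count_components
#' @return A tibble with columns `hop` (character: `"1"`, `"2"`, ...,
#'   `"disconnected"`) and `n` (response count).
#' @export
hop_distribution <- function(net) {
  if (is.null(net$stimulus)) {
    stop("network was built without a stimulus", call. = FALSE)
  }
  g <- net$graph
  stim_label <- net$stimulus$pinyin
  has_stim <- stim_label %in% igraph::V(g)$name
  if (!has_stim) {
    g <- igraph::add_vertices(g, 1, name = stim_label)
    if (!is.null(net$nodes) && nrow(net$nodes)) {
      neigh <- which(edit_distance(net$stimulus, net$nodes) == 1L)
      if (length(neigh)) {
        sv <- igraph::vcount(g)
        g <- igraph::add_edges(g, as.vector(rbind(sv, neigh)))
      }
    }
  }
  dists <- igraph::distances(g, v = stim_label)[1, ]
  dists <- dists[names(dists) != stim_label]
  hop <- ifelse(is.infinite(dists), "disconnected", as.character(dists))
  out <- tibble::as_tibble(table(hop), .name_repair = ~c("hop", "n"))
  lev <- suppressWarnings(as.numeric(out$hop))
  out[order(is.na(lev), lev), ]
}

#' @rdname glance.fluency_network
#' @export
tidy.fluency_network <- function(x, ...) {
  g <- x$graph
  if (igraph::vcount(g) == 0L) {
    return(tibble::tibble(label = character(), degree = integer(),
                          local_cc = numeric(), component = integer(),
                          hop = character()))
  }
  out <- tibble::tibble(
    label = igraph::V(g)$name,
    degree = as.integer(igraph::degree(g)),
    local_cc = as.numeric(local_clustering(x)),
    component = as.integer(igraph::components(g)$membership)
  )
  if (!is.null(x$stimulus)) {
    hd <- hop_distribution(x)
    # recompute per-node hops for the node table
    gs <- g
    stim_label <- x$stimulus$pinyin
    if (!stim_label %in% igraph::V(gs)$name) {
      gs <- igraph::add_vertices(gs, 1, name = stim_label)
      neigh <- which(edit_distance(x$stimulus, x$nodes) == 1L)
      if (length(neigh)) {
        sv <- igraph::vcount(gs)
        gs <- igraph::add_edges(gs, as.vector(rbind(sv, neigh)))
      }
    }
    d <- igraph::distances(gs, v = stim_label)[1, out$label]
    out$hop <- ifelse(is.infinite(d), "disconnected", as.character(d))
  }
  out
}

#' Summarise a fluency network
#'
#' `glance()` returns the one-row trial summary (node/edge counts, number of
#' components `NC`, component-weighted mean clustering `CC_bar`, and
#' component-weighted assortativity `M`); `tidy()` returns the node table
#' (label, degree, local clustering, component, and hop from the stimulus
#' when one was given).
#'
#' @param x A `fluency_network`.
#' @param ... Unused.
#' @return A tibble.
#' @export
glance.fluency_network <- function(x, ...) {
  tibble::tibble(
    n_nodes = igraph::vcount(x$graph),
    n_edges = igraph::ecount(x$graph),
    NC = count_components(x),
    CC_bar = weighted_mean_clustering(x),
    M = weighted_assortativity(x)
  )
}

#' Network measures for every trial
#'
#' Builds the phonological network of each trial in a classified response
#' table and returns its component-weighted measures together with the hop
#' histogram of correct responses from the stimulus.
#'
#' Trials with no correct production have no network; their measures are
#' reported as missing.
#'
#' @inheritParams score_trials
#' @param include_stimulus Passed to [trial_network()].
#' @param keep_networks If `TRUE`, the `fluency_network` objects are kept in
#'   a list column `network`.
#' @return A tibble with one row per (participant, trial): `n_nodes`,
#'   `n_edges`, `NC`, `CC_bar`, `M`, hop counts `hop1`, `hop2`,
#'   `hop3_plus`, `disconnected`, and a `hops` list column with the full
#'   histogram.
#' @export
network_scores <- function(classified, mapping = pinyin_mapping(),
                           include_stimulus = FALSE, keep_networks = FALSE) {
  if (!"is_correct" %in% names(classified)) {
    stop("run classify_productions() first", call. = FALSE)
  }
  res <- classified |>
    dplyr::group_by(.data$participant_id, .data$trial_id, .data$stimulus) |>
    dplyr::group_modify(function(d, key) {
      prods <- d$response[d$is_correct]
      if (!length(prods)) {
        return(tibble::tibble(
          n_nodes = 0L, n_edges = 0L, NC = NA_integer_,
          CC_bar = NA_real_, M = NA_real_,
          hop1 = 0L, hop2 = 0L, hop3_plus = 0L, disconnected = 0L,
          hops = list(tibble::tibble(hop = character(), n = integer())),
          network = list(NULL)
        ))
      }
      net <- trial_network(prods, stimulus = key$stimulus, mapping = mapping,
                           include_stimulus = include_stimulus)
      hd <- hop_distribution(net)
      hop_n <- function(lbl) sum(hd$n[hd$hop == lbl])
      num <- suppressWarnings(as.numeric(hd$hop))
      dplyr::bind_cols(
        glance(net),
        tibble::tibble(
          hop1 = hop_n("1"), hop2 = hop_n("2"),
          hop3_plus = sum(hd$n[!is.na(num) & num >= 3]),
          disconnected = hop_n("disconnected"),
          hops = list(hd),
          network = list(net)
        )
      )
    }) |>
    dplyr::ungroup()
  if (!keep_networks) res$network <- NULL
  res
}

#' Export a fluency network as an edge list or GraphML
#'
#' `write_network_edgelist()` writes a TSV of edges (`from`, `to`);
#' `write_network_graphml()` writes GraphML with node attributes `label`,
#' `degree`, `local_cc`, `component`, and `hop` when a stimulus is present.
#'
#' @inheritParams count_components
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network_edgelist <- function(net, path) {
  e <- igraph::as_edgelist(net$graph)
  readr::write_tsv(tibble::tibble(from = e[, 1], to = e[, 2]), path)
  invisible(path)
}

#' @rdname write_network_edgelist
#' @export
write_network_graphml <- function(net, path) {
  g <- net$graph
  nt <- tidy(net)
  igraph::V(g)$degree <- nt$degree
  igraph::V(g)$local_cc <- nt$local_cc
  igraph::V(g)$component <- nt$component
  if (!is.null(nt$hop)) igraph::V(g)$hop <- nt$hop
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
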