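# Independent oracles and graph fixtures used across the suite.

# wrap a raw igraph graph in the network class (measures only touch $graph)
as_net <- function(g) as_fluency_network(g)

random_net <- function(n, p = 0.25) {
  as_net(igraph::sample_gnp(n, p, directed = FALSE))
}

# union-find component count, independent of igraph
oracle_components <- function(g) {
  n <- igraph::vcount(g)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  e <- igraph::as_edgelist(g, names = FALSE)
  for (k in seq_len(nrow(e))) {
    a <- find(e[k, 1]); b <- find(e[k, 2])
    if (a != b) parent[a] <- b
  }
  length(unique(vapply(seq_len(n), find, numeric(1))))
}

# brute-force local clustering: enumerate neighbour pairs
oracle_local_cc <- function(g) {
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  n <- nrow(A)
  vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    pairs <- utils::combn(nb, 2)
    closed <- sum(A[cbind(pairs[1, ], pairs[2, ])])
    closed / (k * (k - 1) / 2)
  }, numeric(1))
}

# component-weighted mean clustering via igraph transitivity
oracle_weighted_cc <- function(g) {
  if (igraph::vcount(g) == 0) return(NA_real_)
  cc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  mean(cc)
}

# component-weighted assortativity via igraph's estimator per component
oracle_weighted_m <- function(g) {
  n <- igraph::vcount(g)
  if (n == 0) return(NA_real_)
  comp <- igraph::components(g)
  vals <- vapply(seq_len(comp$no), function(i) {
    sub <- igraph::induced_subgraph(g, which(comp$membership == i))
    if (igraph::ecount(sub) == 0) return(0)
    m <- suppressWarnings(igraph::assortativity_degree(sub))
    if (is.na(m) || is.nan(m)) 0 else m
  }, numeric(1))
  sum(vals * comp$csize) / n
}

# all labelled graphs on n nodes (edge-subset enumeration)
all_graphs <- function(n) {
  pairs <- utils::combn(n, 2)
  m <- ncol(pairs)
  lapply(seq_len(2^m) - 1L, function(mask) {
    on <- which(bitwAnd(mask, 2^(seq_len(m) - 1L)) > 0)
    g <- igraph::make_empty_graph(n, directed = FALSE)
    if (length(on)) g <- igraph::add_edges(g, as.vector(pairs[, on]))
    g
  })
}

# one-trial response table in the pipeline's input format
trial_tbl <- function(responses, stimulus, participant = "p1", trial = "t1") {
  tibble::tibble(participant_id = participant, trial_id = trial,
                 stimulus = stimulus,
                 response_index = seq_along(responses),
                 response = responses)
}
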