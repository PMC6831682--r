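m <- pinyin_mapping()

test_that("trial networks connect immediate neighbours only", {
  # tone family forms a triangle (pairwise tone substitutions)
  net <- trial_network(c("zai1", "zai3", "zai4"), stimulus = "wai4",
                       mapping = m)
  g <- glance(net)
  expect_equal(g$n_nodes, 3)
  expect_equal(g$n_edges, 3)
  expect_equal(g$NC, 1)
  expect_equal(g$CC_bar, 1)
  # every edge endpoint pair is at edit distance exactly 1
  el <- igraph::as_edgelist(net$graph)
  expect_true(all(edit_distance(parse_pinyin(el[, 1], m),
                                parse_pinyin(el[, 2], m)) == 1L))
  # single correct response
  g1 <- glance(trial_network("ma1", mapping = m))
  expect_equal(g1[, c("n_nodes", "n_edges", "NC")],
               tibble::tibble(n_nodes = 1, n_edges = 0, NC = 1))
  # three mutually distant responses -> three components
  expect_equal(count_components(
    trial_network(c("zai1", "wu2", "xiang4"), mapping = m)), 3)
  # duplicates collapse
  expect_equal(glance(trial_network(c("ma1", "ma1"), mapping = m))$n_nodes, 1)
})

test_that("the fully connected 9-node component plus one isolate scores 0.9", {
  g <- igraph::add_vertices(igraph::make_full_graph(9, directed = FALSE), 1)
  net <- as_net(g)
  expect_identical(weighted_mean_clustering(net), 0.9)
  expect_equal(count_components(net), 2)
  expect_equal(unname(local_clustering(net)), c(rep(1, 9), 0))
})

test_that("local clustering follows the closed forms", {
  expect_equal(unname(local_clustering(as_net(
    igraph::make_full_graph(3, directed = FALSE)))), rep(1, 3))
  star <- as_net(igraph::make_star(4, mode = "undirected"))
  expect_equal(unname(local_clustering(star))[1], 0)  # hub of a 3-leaf star
  expect_equal(weighted_mean_clustering(as_net(
    igraph::make_empty_graph(4, directed = FALSE))), 0)  # all isolates
})

test_that("assortativity hits the star extreme and weights symmetrically", {
  star <- as_net(igraph::make_star(5, mode = "undirected"))  # K1,4
  expect_equal(weighted_assortativity(star), -1)
  # degree-regular components (single edge, cycle) contribute zero
  expect_equal(weighted_assortativity(as_net(
    igraph::make_ring(4, directed = FALSE))), 0)
  expect_equal(weighted_assortativity(as_net(
    igraph::make_graph(c(1, 2), n = 2, directed = FALSE))), 0)
  # two-component weighting equals the size-weighted mean of per-component M
  set.seed(21)
  g1 <- igraph::sample_gnp(8, 0.4); g2 <- igraph::sample_gnp(8, 0.4)
  both <- igraph::disjoint_union(g1, g2)
  expect_equal(weighted_assortativity(as_net(both)),
               (8 * oracle_weighted_m(g1) + 8 * oracle_weighted_m(g2)) / 16)
})

test_that("adding an isolate dilutes a positive weighted clustering", {
  g <- igraph::make_full_graph(5, directed = FALSE)
  with_iso <- igraph::add_vertices(g, 1)
  expect_lt(weighted_mean_clustering(as_net(with_iso)),
            weighted_mean_clustering(as_net(g)))
})

test_that("measures agree with independent oracles on random graphs", {
  set.seed(31)
  for (rep in 1:60) {
    n <- sample(2:12, 1)
    net <- random_net(n, p = stats::runif(1, 0.1, 0.6))
    g <- net$graph
    expect_equal(count_components(net), oracle_components(g))
    expect_equal(unname(local_clustering(net)), oracle_local_cc(g),
                 tolerance = 1e-8)
    expect_equal(weighted_mean_clustering(net), oracle_weighted_cc(g),
                 tolerance = 1e-8)
    expect_equal(weighted_assortativity(net), oracle_weighted_m(g),
                 tolerance = 1e-8)
  }
})

test_that("hop distributions bin shortest paths from the stimulus", {
  # three immediate neighbours of the stimulus -> {1: 3}
  hd <- hop_distribution(trial_network(c("shuai4", "wai1", "wai2"),
                                       stimulus = "wai4", mapping = m))
  expect_equal(hd, tibble::tibble(hop = "1", n = 3L))
  # chain: shuai4 is hop 1, shuan4 reaches the stimulus through it
  hd2 <- hop_distribution(trial_network(c("shuai4", "shuan4"),
                                        stimulus = "wai4", mapping = m))
  expect_equal(hd2, tibble::tibble(hop = c("1", "2"), n = c(1L, 1L)))
  # a response sharing no edge with anything is disconnected
  hd3 <- hop_distribution(trial_network(c("shuai4", "tu2"),
                                        stimulus = "wai4", mapping = m))
  expect_equal(hd3$n[hd3$hop == "disconnected"], 1L)
  # hop-1 count equals the stimulus degree in the augmented graph
  net <- trial_network(c("shuai4", "shuan4", "wai1", "zai4"),
                       stimulus = "wai4", mapping = m)
  hd4 <- hop_distribution(net)
  stim_deg <- sum(edit_distance(net$stimulus, net$nodes) == 1L)
  expect_equal(sum(hd4$n[hd4$hop == "1"]), stim_deg)
})

test_that("the stimulus joins the scored graph only on request", {
  out <- trial_network(c("zai1", "zai3"), stimulus = "zai4", mapping = m)
  expect_equal(glance(out)$n_nodes, 2)
  incl <- trial_network(c("zai1", "zai3"), stimulus = "zai4", mapping = m,
                        include_stimulus = TRUE)
  expect_equal(glance(incl)$n_nodes, 3)
  expect_equal(glance(incl)$CC_bar, 1)  # tone family triangle again
})

test_that("tidy() and network export carry node attributes", {
  net <- trial_network(c("zai1", "zai3", "shuai4"), stimulus = "wai4",
                       mapping = m)
  td <- tidy(net)
  expect_setequal(names(td),
                  c("label", "degree", "local_cc", "component", "hop"))
  expect_equal(nrow(td), 3)
  ef <- tempfile(fileext = ".tsv"); gf <- tempfile(fileext = ".graphml")
  write_network_edgelist(net, ef)
  back <- readr::read_tsv(ef, show_col_types = FALSE)
  expect_equal(nrow(back), glance(net)$n_edges)
  write_network_graphml(net, gf)
  g2 <- igraph::read_graph(gf, format = "graphml")
  expect_equal(igraph::vcount(g2), 3)
  expect_true("local_cc" %in% igraph::vertex_attr_names(g2))
})

test_that("network scores report fragmented and empty trials sensibly", {
  lex_words <- c("wai4", "shuai4", "shuan4", "zai4", "zai1")
  cls <- classify_productions(dplyr::bind_rows(
    trial_tbl(c("shuai4", "shuan4", "zai2"), "wai4", trial = "t1"),
    trial_tbl(c("zai2", "zai2"), "wai4", trial = "t2")), lex_words)
  ns <- network_scores(cls, m)
  t1 <- ns[ns$trial_id == "t1", ]
  expect_equal(t1$n_nodes, 2)
  expect_equal(t1$NC, 1)
  t2 <- ns[ns$trial_id == "t2", ]  # no correct productions
  expect_equal(t2$n_nodes, 0)
  expect_true(is.na(t2$CC_bar) && is.na(t2$M) && is.na(t2$NC))
})
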