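prevalence_table <- function(n_samples, nonzero_per_ko, kos) {
  m <- matrix(0, length(kos), n_samples,
              dimnames = list(kos, sprintf("s%03d", seq_len(n_samples))))
  for (i in seq_along(kos)) m[i, seq_len(nonzero_per_ko[i])] <- 5
  omics_table(m, "funMG")
}

test_that("prevalence filter uses >= semantics at the 50% boundary", {
  u <- reaction_universe(
    ko_reactions = list(K49 = "R1", K50 = "R1", K51 = "R1"),
    reaction_sides = list(R1 = list(reactants = "A", products = "B")),
    compound_names = list(A = "alpha", B = "bravo"))
  t <- prevalence_table(100, c(K49 = 49, K50 = 50, K51 = 51),
                        c("K49", "K50", "K51"))
  net <- build_network(u, t, prevalence = 0.5)
  expect_false("K49" %in% net$kos)
  expect_true(all(c("K50", "K51") %in% net$kos))
  expect_error(build_network(u, t, prevalence = 0), "prevalence")
  expect_error(build_network(u, t, prevalence = 1.2), "prevalence")
})

test_that("cofactor removal commutes with network construction", {
  for (seed in 1:5) {
    u <- random_universe(seed = seed, n_ko = 10, n_compound = 8, n_reaction = 8)
    cof <- names(u$compound_names)[1:2]
    t <- prevalence_table(4, rep(4, 10), names(u$ko_reactions))
    with_cof <- build_network(u, t, cofactors = cof)
    post_hoc <- remove_cofactors(build_network(u, t, cofactors = character()), cof)
    expect_equal(with_cof$edges, post_hoc$edges)
    expect_equal(with_cof$kos, post_hoc$kos)
    expect_equal(with_cof$compounds, post_hoc$compounds)
  }
})

test_that("raising prevalence or enlarging the cofactor set only removes", {
  u <- random_universe(seed = 11, n_ko = 12, n_compound = 9, n_reaction = 10)
  t <- prevalence_table(10, rep(c(3, 6, 10), each = 4), names(u$ko_reactions))
  n_lo <- build_network(u, t, prevalence = 0.3, cofactors = character())
  n_hi <- build_network(u, t, prevalence = 0.7, cofactors = character())
  expect_true(all(n_hi$kos %in% n_lo$kos))
  n_cof <- build_network(u, t, prevalence = 0.3,
                         cofactors = names(u$compound_names)[1:3])
  expect_lte(nrow(n_cof$edges), nrow(n_lo$edges))
  expect_true(all(
    dplyr::anti_join(n_cof$edges, n_lo$edges,
                     by = c("ko", "compound", "role")) |> nrow() == 0))
})

test_that("KO projection follows the shared-compound rule with labeled edges", {
  u <- tiny_universe()
  t <- prevalence_table(2, rep(2, 3), c("KO1", "KO2", "KO3"))
  net <- build_network(u, t, cofactors = "W")
  g <- project_ko(net)
  expect_setequal(igraph::V(g)$name, c("KO1", "KO2", "KO3"))
  expect_equal(igraph::ecount(g), 1)
  e <- igraph::ends(g, 1)
  expect_setequal(as.character(e), c("KO1", "KO2"))
  expect_equal(igraph::E(g)$shared, "B")
  # cofactors never appear as nodes in the compound projection
  gc <- project_compound(net)
  expect_false("W" %in% igraph::V(gc)$name)
  # KO1: A -> B gives compound edge A - B labeled KO1
  expect_true(igraph::are_adjacent(gc, "A", "B"))
  eid <- igraph::get_edge_ids(gc, c("A", "B"))
  expect_equal(igraph::E(gc)$shared[eid], "KO1")
})

test_that("projections equal brute-force pairwise intersections", {
  for (seed in 1:4) {
    u <- random_universe(seed = seed, n_ko = 10, n_compound = 8, n_reaction = 9)
    t <- prevalence_table(3, rep(3, 10), names(u$ko_reactions))
    net <- build_network(u, t, cofactors = character())
    g <- project_ko(net)
    cpd_sets <- split(net$edges$compound, net$edges$ko)
    kos <- net$kos
    for (i in seq_along(kos)) {
      for (j in seq_len(i - 1)) {
        shared <- intersect(cpd_sets[[kos[i]]], cpd_sets[[kos[j]]])
        expect_equal(igraph::are_adjacent(g, kos[i], kos[j]), length(shared) > 0)
        if (length(shared) > 0) {
          eid <- igraph::get_edge_ids(g, c(kos[i], kos[j]))
          expect_setequal(strsplit(igraph::E(g)$shared[eid], ",")[[1]], shared)
        }
      }
    }
  }
})

test_that("compound projection equals KO projection of the role-swapped universe", {
  u <- random_universe(seed = 21, n_ko = 8, n_compound = 7, n_reaction = 8)
  t <- prevalence_table(3, rep(3, 8), names(u$ko_reactions))
  net <- build_network(u, t, cofactors = character())
  g_cpd <- project_compound(net)
  # role-swapped: treat compounds as the "ko" column
  swapped <- net
  swapped$edges <- dplyr::tibble(ko = net$edges$compound,
                                 compound = net$edges$ko,
                                 role = net$edges$role)
  g_swap <- project_ko(swapped)
  expect_setequal(igraph::V(g_cpd)$name, igraph::V(g_swap)$name)
  el1 <- apply(igraph::as_edgelist(g_cpd), 1, function(r) paste(sort(r), collapse = "~"))
  el2 <- apply(igraph::as_edgelist(g_swap), 1, function(r) paste(sort(r), collapse = "~"))
  expect_setequal(el1, el2)
})

test_that("removing a compound from the cofactor list can only add edges", {
  u <- random_universe(seed = 31, n_ko = 10, n_compound = 8, n_reaction = 9)
  t <- prevalence_table(3, rep(3, 10), names(u$ko_reactions))
  cof_all <- names(u$compound_names)[1:3]
  g_small <- project_ko(build_network(u, t, cofactors = cof_all))
  g_big <- project_ko(build_network(u, t, cofactors = cof_all[-1]))
  el_small <- apply(igraph::as_edgelist(g_small), 1,
                    function(r) paste(sort(r), collapse = "~"))
  el_big <- apply(igraph::as_edgelist(g_big), 1,
                  function(r) paste(sort(r), collapse = "~"))
  expect_true(all(el_small %in% el_big))
})

test_that("betweenness matches closed forms on path and star graphs", {
  path3 <- igraph::make_graph(~ A - B, B - C)
  bc <- betweenness_centrality(path3)
  expect_equal(bc$bc_raw[bc$node == "B"], 1)
  expect_equal(bc$bc_norm[bc$node == "B"], 1)
  star <- igraph::make_star(6, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("hub", paste0("leaf", 1:5))
  bs <- betweenness_centrality(star)
  expect_equal(bs$bc_norm[bs$node == "hub"], 1)
  expect_true(all(bs$bc_raw[bs$node != "hub"] == 0))
  # < 3 nodes -> all zero
  g2 <- igraph::make_graph(~ A - B)
  expect_true(all(betweenness_centrality(g2)$bc_raw == 0))
})

test_that("betweenness matches brute-force shortest-path enumeration", {
  withr::with_seed(55, {
    for (i in 1:25) {
      n <- sample(4:10, 1)
      adj <- matrix(0, n, n)
      adj[upper.tri(adj)] <- rbinom(n * (n - 1) / 2, 1, 0.35)
      adj <- adj + t(adj)
      dimnames(adj) <- list(paste0("v", 1:n), paste0("v", 1:n))
      g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
      got <- betweenness_centrality(g)
      expect_equal(got$bc_raw, brute_betweenness(adj), tolerance = 1e-12)
      # conservation: total raw BC equals total interior visits over all pairs
      expect_equal(sum(got$bc_raw), sum(brute_betweenness(adj)), tolerance = 1e-12)
    }
  })
})

test_that("subnetwork report compares subset and whole-graph centralities", {
  g <- igraph::make_graph(~ A - B, B - C, C - D, D - E)
  rep <- betweenness_centrality(g)
  full <- subnetwork_report(g, rep, igraph::V(g)$name, "all")
  expect_equal(full$mean_bc_raw, full$whole_mean_bc_raw)
  expect_equal(full$bc_ratio, 1)
  expect_warning(sub <- subnetwork_report(g, rep, c("B", "C", "ZZ"), "mid"),
                 "absent")
  expect_equal(sub$n_missing, 1)
  expect_gt(sub$mean_bc_raw, full$mean_bc_raw)
  expect_error(subnetwork_report(g, rep, character()), "empty")
})

test_that("activity ratios match direct arithmetic and stay finite", {
  u <- tiny_universe()
  t_mg <- sum_normalize(prevalence_table(4, rep(4, 3), c("KO1", "KO2", "KO3")))
  mt_vals <- matrix(c(8, 0, 2, 2, 4, 4, 0, 1), 2,
                    dimnames = list(c("KO1", "KO2"), sprintf("s%03d", 1:4)))
  t_mt <- sum_normalize(omics_table(mt_vals, "funMT"))
  net <- build_network(u, t_mg, cofactors = "W")
  net <- attach_activity(net, t_mt, t_mg)
  act <- net$activity
  eps <- attr(act, "eps")
  expect_equal(act$ratio[act$ko == "KO1"],
               (mean(t_mt$values["KO1", ]) + eps) / (mean(t_mg$values["KO1", ]) + eps))
  # KO3 missing from funMT: flagged but finite
  expect_equal(act$flag[act$ko == "KO3"], "missing_layer")
  expect_true(all(is.finite(act$ratio) & act$ratio > 0))
  # equal means -> ratio 1
  net2 <- attach_activity(net, t_mg, t_mg)
  expect_true(all(abs(net2$activity$ratio - 1) < 1e-12))
})

test_that("GraphML output is byte-identical across repeated writes", {
  u <- random_universe(seed = 41, n_ko = 8, n_compound = 7, n_reaction = 8)
  t <- prevalence_table(3, rep(3, 8), names(u$ko_reactions))
  g <- project_ko(build_network(u, t, cofactors = character()))
  p1 <- withr::local_tempfile(fileext = ".graphml")
  p2 <- withr::local_tempfile(fileext = ".graphml")
  write_network_graphml(g, p1)
  write_network_graphml(g, p2)
  expect_identical(readLines(p1), readLines(p2))
})
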