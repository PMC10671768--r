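test_that("up_subnetwork induces the subgraph on up-labeled genes", {
  tri <- triangle()
  calls <- fake_calls(c("A", "B", "C"), c("up", "up", "unchanged"))
  sub <- up_subnetwork(tri, calls)
  expect_setequal(igraph::V(sub)$name, c("A", "B"))
  expect_equal(igraph::ecount(sub), 1)

  s4 <- star_s4()
  calls2 <- fake_calls(c("c", "l1", "l2", "l3", "l4"),
                       c("up", "up", "up", "down", "unchanged"))
  sub2 <- up_subnetwork(s4, calls2)
  expect_equal(igraph::vcount(sub2), 3)
  expect_equal(igraph::ecount(sub2), 2)

  expect_error(up_subnetwork(tri, fake_calls("A", "unchanged")), "up")
  expect_error(up_subnetwork(tri, fake_calls("Z", "up")), "none")
  expect_message(up_subnetwork(tri, fake_calls(c("A", "B", "Q"),
                                               rep("up", 3))), "absent")
})

test_that("rank_hubs sorts by degree, then betweenness, then gene id", {
  # A and B share top degree; A has higher betweenness in the full net
  g <- named_graph(c("A-B", "A-C", "A-D", "B-E", "B-F", "C-D", "E-F", "D-G"))
  calls <- fake_calls(igraph::V(g)$name, rep("up", igraph::vcount(g)))
  sub <- up_subnetwork(g, calls)
  rk <- rank_hubs(g, sub, calls)
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g)
  ord <- order(-deg, -btw, igraph::V(g)$name)
  expect_identical(rk$gene_id, igraph::V(g)$name[ord])
  expect_identical(rk$rank, seq_len(nrow(rk)))

  # all-equal degrees and betweenness: lexicographic order of last resort
  tri <- triangle()
  calls3 <- fake_calls(c("A", "B", "C"), rep("up", 3))
  rk3 <- rank_hubs(tri, up_subnetwork(tri, calls3), calls3)
  expect_identical(rk3$gene_id, c("A", "B", "C"))

  # deterministic total order: repeated runs identical
  expect_identical(rank_hubs(g, sub, calls), rk)
})

test_that("degree scope switches between subnetwork and full-network degree", {
  # hub is weakly connected inside the up-set but dominant in the full net
  g <- named_graph(c("h-x1", "h-x2", "h-x3", "h-x4", "h-u1",
                     "u1-u2", "u2-u3", "u1-u3"))
  calls <- fake_calls(igraph::V(g)$name,
                      ifelse(igraph::V(g)$name %in% c("h", "u1", "u2", "u3"),
                             "up", "unchanged"))
  sub <- up_subnetwork(g, calls)
  rk_sub <- rank_hubs(g, sub, calls, degree_scope = "sub")
  rk_full <- rank_hubs(g, sub, calls, degree_scope = "full")
  expect_equal(rk_sub$gene_id[1], "u1")
  expect_equal(rk_full$gene_id[1], "h")
})

test_that("top_n_targets truncates and warns when short", {
  g <- gen_network(50, 2, seed = 4)
  calls <- fake_calls(igraph::V(g)$name, rep("up", 50))
  rk <- rank_hubs(g, up_subnetwork(g, calls), calls)
  expect_equal(nrow(top_n_targets(rk, 5)), 5)
  expect_identical(top_n_targets(rk, 5)$gene_id, rk$gene_id[1:5])
  rk3 <- rk[1:3, ]
  class(rk3) <- class(rk)
  expect_warning(t3 <- top_n_targets(rk3, 5), "3")
  expect_equal(nrow(t3), 3)
  expect_equal(nrow(top_n_targets(rk, 1)), 1)
})

test_that("entropy contributions match closed-form removals", {
  s4 <- star_s4()
  ec <- entropy_contribution(s4, "c", mode = "individual",
                             variant = "vertex", log_base = 2)
  expect_equal(unname(ec$contributions["c"]), 2, tolerance = 1e-12)
  tri <- triangle()
  ec2 <- entropy_contribution(tri, "A", mode = "individual",
                              variant = "vertex", log_base = 2)
  expect_equal(unname(ec2$contributions["A"]), log2(3) - 1, tolerance = 1e-12)
  # isolated vertex contributes nothing
  g <- named_graph(c("a-b", "b-c"), isolated = "z")
  ec3 <- entropy_contribution(g, "z", mode = "individual",
                              variant = "vertex", log_base = 2)
  expect_equal(unname(ec3$contributions["z"]), 0)
  expect_error(entropy_contribution(tri, "nope"), "nope")
})

test_that("cumulative mode returns the net entropy after all removals", {
  s4 <- star_s4()
  ec <- entropy_contribution(s4, c("c", "l1"), mode = "cumulative",
                             variant = "vertex", log_base = 2)
  expect_equal(ec$net_entropy, 0)
  expect_equal(sum(ec$contributions), ec$initial_entropy - ec$net_entropy,
               tolerance = 1e-12)
  # removing every vertex of a connected graph leaves zero entropy
  tri <- triangle()
  ec2 <- entropy_contribution(tri, c("A", "B", "C"), mode = "cumulative",
                              variant = "vertex", log_base = 2)
  expect_equal(ec2$net_entropy, 0)
})

test_that("individual contributions need not sum to the cumulative drop", {
  s4 <- star_s4()
  ind <- entropy_contribution(s4, c("c", "l1"), mode = "individual",
                              variant = "vertex", log_base = 2)
  cum <- entropy_contribution(s4, c("c", "l1"), mode = "cumulative",
                              variant = "vertex", log_base = 2)
  drop_cum <- cum$initial_entropy - cum$net_entropy
  expect_false(isTRUE(all.equal(sum(ind$contributions), drop_cum)))
})

test_that("pathway score is the degree-weighted up fraction", {
  g <- named_graph(c("g1-a", "g1-b", "g1-c", "g1-d",
                     "g2-a",
                     "g3-a", "g3-b", "g3-c", "g3-d", "g3-e"))
  expect_equal(unname(igraph::degree(g)[c("g1", "g2", "g3")]), c(4, 1, 5))
  calls <- fake_calls(igraph::V(g)$name,
                      ifelse(igraph::V(g)$name %in% c("g1", "g3"),
                             "up", "unchanged"))
  ps <- pathway_score(g, calls, c("g1", "g2", "g3"), set_name = "wnt")
  expect_equal(ps$score, 0.9)
  expect_equal(ps$n_up_in_set, 2)
  expect_equal(ps$n_set, 3)
  none <- pathway_score(g, fake_calls(igraph::V(g)$name,
                                      rep("unchanged", igraph::vcount(g))),
                        c("g1", "g2", "g3"))
  expect_equal(none$score, 0)
  all_up <- pathway_score(g, fake_calls(igraph::V(g)$name,
                                        rep("up", igraph::vcount(g))),
                          c("g1", "g2", "g3"))
  expect_equal(all_up$score, 1)
  expect_error(pathway_score(g, calls, c("q1", "q2")), "absent")
})

test_that("gene sets read from GMT and 2-column TSV", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("wnt\tdesc\tg1\tg2\tg3", "mapk\tdesc\tg4\tg5"), f)
  sets <- read_gene_sets(f)
  expect_equal(sets$wnt, c("g1", "g2", "g3"))
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("set_name\tgene_id", "wnt\tg1", "wnt\tg2", "mapk\tg9"), f2)
  sets2 <- read_gene_sets(f2)
  expect_equal(sort(names(sets2)), c("mapk", "wnt"))
  expect_equal(unname(sets2$wnt), c("g1", "g2"))
})
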