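test_that("validation orders a chain and rejects cycles", {
  g <- causal_graph(rbind(c("A", "B"), c("B", "C")), group = "s")
  expect_equal(g$topo_order, c("A", "B", "C"))
  expect_equal(unname(g$roles), c("exogenous", "endogenous", "endogenous"))
  expect_error(causal_graph(rbind(c("A", "B"), c("B", "A")), group = "s"),
               "cycle")
  expect_error(causal_graph(rbind(c("A", "B"), c("B", "C"), c("C", "A")),
                            group = "s"), "cycle")
})

test_that("correlated errors may not duplicate an edge", {
  expect_error(
    causal_graph(rbind(c("A", "B")), correlated_errors = list(c("A", "B")),
                 group = "s"),
    "also a directed edge")
  g <- causal_graph(rbind(c("A", "B"), c("C", "B")),
                    correlated_errors = list(c("A", "C")), group = "s")
  expect_equal(nrow(g$correlated_errors), 1)
})

test_that("lag interactions must reference an existing edge", {
  expect_error(
    causal_graph(rbind(c("A", "B")),
                 lag_interactions = list(B = "C"), group = "s"),
    "not an edge")
  g <- causal_graph(rbind(c("A", "B")),
                    lag_interactions = list(B = "A"), group = "s")
  expect_equal(g$lag_interactions$B, "A")
})

test_that("the declared partial order refines ties deterministically", {
  edges <- rbind(c("Z", "R"), c("Q", "R"))
  g1 <- causal_graph(edges, group = "s")
  expect_equal(g1$topo_order, c("Q", "Z", "R")) # alphabetical fallback
  g2 <- causal_graph(edges, group = "s", order = c("Z", "Q"))
  expect_equal(g2$topo_order, c("Z", "Q", "R"))
})

test_that("a chain yields the textbook claim, a saturated DAG none", {
  g <- causal_graph(rbind(c("A", "B"), c("B", "C")), group = "s")
  bs <- basis_set(g)
  expect_equal(nrow(bs), 1)
  expect_equal(bs$indep, "A")
  expect_equal(bs$response, "C")
  expect_equal(bs$conditioning[[1]], "B")

  sat <- causal_graph(rbind(c("A", "B"), c("A", "C"), c("B", "C")),
                      group = "s")
  expect_equal(nrow(basis_set(sat)), 0)
})

test_that("exogenous-exogenous and correlated-error pairs are excluded", {
  g <- causal_graph(rbind(c("A", "C"), c("B", "C"), c("B", "D")),
                    group = "s")
  bs <- basis_set(g)
  # (A, B) both exogenous: excluded; claims are (A,D) and (C,D)
  expect_equal(nrow(bs), 2)
  expect_setequal(paste(bs$indep, bs$response), c("A D", "C D"))
  g2 <- causal_graph(rbind(c("A", "C"), c("B", "C"), c("B", "D")),
                     correlated_errors = list(c("C", "D")), group = "s")
  expect_equal(nrow(basis_set(g2)), 1)
})

test_that("basis sets match the igraph oracle on random DAGs", {
  skip_if_not_installed("igraph")
  set.seed(77)
  for (i in 1:60) {
    g <- random_dag(sample(3:7, 1))
    bs <- basis_set(g)
    oracle <- basis_oracle(g)
    expect_equal(nrow(bs), length(oracle))
    if (nrow(bs) > 0) {
      impl_keys <- claim_keys(
        lapply(seq_len(nrow(bs)), function(k) c(bs$indep[k], bs$response[k])),
        bs$conditioning)
      or_keys <- claim_keys(lapply(oracle, `[[`, "pair"),
                            lapply(oracle, `[[`, "conditioning"))
      expect_identical(impl_keys, or_keys)
      # the claimed-independent node never causally descends from the
      # response
      ig <- igraph::graph_from_edgelist(as.matrix(g$edges))
      for (k in seq_len(nrow(bs))) {
        if (bs$indep[k] %in% igraph::V(ig)$name &&
            bs$response[k] %in% igraph::V(ig)$name) {
          reach <- names(igraph::subcomponent(ig, bs$response[k],
                                              mode = "out"))
          expect_false(bs$indep[k] %in% setdiff(reach, bs$response[k]))
        }
      }
    }
  }
})

test_that("adding an edge between a claimed pair removes only that claim", {
  set.seed(42)
  for (i in 1:10) {
    g <- random_dag(6, p_edge = 0.3, p_ce = 0)
    bs <- basis_set(g)
    if (nrow(bs) == 0) next
    pick <- bs[1, ]
    g2 <- causal_graph(rbind(as.matrix(g$edges),
                             c(pick$indep, pick$response)),
                       group = g$group)
    bs2 <- basis_set(g2)
    expect_equal(nrow(bs2), nrow(bs) - 1)
    expect_false(any(bs2$indep == pick$indep &
                       bs2$response == pick$response))
    # surviving claims condition on weakly larger parent unions
    for (k in seq_len(nrow(bs2))) {
      old <- bs$conditioning[bs$indep == bs2$indep[k] &
                               bs$response == bs2$response[k]]
      if (length(old) == 1) {
        expect_true(all(old[[1]] %in% bs2$conditioning[[k]]))
      }
    }
  }
})

test_that("graphs round-trip through their JSON representation", {
  f <- tempfile(fileext = ".json")
  g <- causal_graph(rbind(c("A", "C"), c("B", "C")),
                    correlated_errors = list(c("A", "B")),
                    lag_interactions = list(C = "A"),
                    group = "station", order = c("B", "A", "C"),
                    lag_variable = "prev")
  write_causal_graph(g, f)
  back <- read_causal_graph(f)
  expect_equal(back$edges, g$edges)
  expect_equal(back$correlated_errors, g$correlated_errors)
  expect_equal(back$lag_interactions, g$lag_interactions)
  expect_equal(back$group, "station")
  expect_equal(back$topo_order, g$topo_order)
  shipped <- system.file("extdata", "subestuary_graph.json",
                         package = "savsem")
  expect_s3_class(read_causal_graph(shipped), "causal_graph")
})
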