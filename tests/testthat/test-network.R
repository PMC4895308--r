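test_that("build_graph constructs, collapses duplicates, keeps opposite parallels", {
  g <- build_graph(list(c("A", "B", 1), c("B", "C", -1)))
  expect_equal(sort(graph_nodes(g)), c("A", "B", "C"))
  expect_equal(nrow(g$edges), 2L)

  dup <- build_graph(data.frame(source = c("A", "A"), target = c("B", "B"),
                                sign = c(1, 1)))
  expect_equal(nrow(dup$edges), 1L)

  par <- build_graph(data.frame(source = c("A", "A"), target = c("B", "B"),
                                sign = c(1, -1)))
  expect_equal(nrow(par$edges), 2L)
  expect_setequal(par$edges$sign, c(1L, -1L))
})

test_that("build_graph rejects malformed records, naming the offender", {
  expect_error(build_graph(data.frame(source = "A", target = "B", sign = 0)),
               "malformed edge record 1")
  expect_error(build_graph(data.frame(source = c("A", ""),
                                      target = c("B", "C"),
                                      sign = c(1, 1))),
               "record 2")
  expect_error(build_graph(list(c("A", "B"))), "malformed edge record")
  expect_error(build_graph(data.frame(source = "A", target = "B",
                                      effect = "binding")),
               "unknown effect")
})

test_that("effect terms map to signs as in the pathway convention", {
  expect_equal(effect_to_sign(c("activation", "expression",
                                "inhibition", "repression")),
               c(1L, 1L, -1L, -1L))
  expect_equal(effect_to_sign(c("+1", "-1", "1")), c(1L, -1L, 1L))
  expect_equal(effect_to_sign(c(1, -1)), c(1L, -1L))
  expect_error(effect_to_sign(0), "invalid edge sign")
})

test_that("shortest_path_parity reproduces the hand-checked censuses", {
  chain <- build_graph(data.frame(source = c("A", "X"), target = c("X", "B"),
                                  sign = c(1, -1)))
  p <- shortest_path_parity(chain, "A", "B")
  expect_equal(p$hop, 2)
  expect_equal(p$n_activation, 0)
  expect_equal(p$n_inhibition, 1)

  diamond <- build_graph(data.frame(source = c("A", "A", "X", "Y"),
                                    target = c("X", "Y", "B", "B"),
                                    sign = rep(1, 4)))
  p <- shortest_path_parity(diamond, "A", "B")
  expect_equal(p$hop, 2)
  expect_equal(p$n_activation, 2)
  expect_equal(p$n_inhibition, 0)

  # nine 2-edge shortest paths, eight even-parity and one odd
  nine <- do.call(rbind, lapply(1:9, function(k) data.frame(
    source = c("r", paste0("m", k)), target = c(paste0("m", k), "g"),
    sign = c(if (k == 9) -1 else 1, 1))))
  p <- shortest_path_parity(build_graph(nine), "r", "g")
  expect_equal(p$hop, 2)
  expect_equal(p$n_activation, 8)
  expect_equal(p$n_inhibition, 1)
})

test_that("degenerate parity cases follow the conventions", {
  g <- build_graph(data.frame(source = "A", target = "B", sign = 1),
                   nodes = c("A", "B", "Z"))
  self <- shortest_path_parity(g, "A", "A")
  expect_equal(self$hop, 0)
  expect_equal(self$n_activation, 1)
  expect_equal(self$n_inhibition, 0)

  un <- shortest_path_parity(g, "B", "A")
  expect_equal(un$hop, Inf)
  expect_equal(un$n_activation + un$n_inhibition, 0)

  # opposite-sign parallel edges are two distinct one-hop paths
  par <- build_graph(data.frame(source = c("A", "A"), target = c("B", "B"),
                                sign = c(1, -1)))
  p <- shortest_path_parity(par, "A", "B")
  expect_equal(p$hop, 1)
  expect_equal(p$n_activation, 1)
  expect_equal(p$n_inhibition, 1)
  expect_equal(conflict_distance(p), Inf)

  expect_error(shortest_path_parity(g, "nope", "B"), "unknown.*nope")
  expect_error(shortest_path_parity(g, "A", "nope"), "unknown.*nope")
})

test_that("conflict_distance matches the printed worked values", {
  expect_equal(conflict_distance(list(hop = 3, n_activation = 2,
                                      n_inhibition = 0)), 3)
  expect_equal(conflict_distance(list(hop = 3, n_activation = 0,
                                      n_inhibition = 1)), -3)
  expect_equal(conflict_distance(list(hop = 2, n_activation = 8,
                                      n_inhibition = 1)), 18 / 7)
  expect_equal(conflict_distance(list(hop = 5, n_activation = 4,
                                      n_inhibition = 4)), Inf)
  expect_equal(conflict_distance(list(hop = Inf, n_activation = 0,
                                      n_inhibition = 0)), Inf)
  expect_equal(conflict_distance(list(hop = 0, n_activation = 1,
                                      n_inhibition = 0)), 0)
  expect_error(conflict_distance(list(hop = 2, n_activation = 0,
                                      n_inhibition = 0)), "invalid parity")
})

test_that("conflict distance sign and magnitude behave as designed", {
  set.seed(7)
  for (i in 1:200) {
    hop <- sample(1:6, 1)
    na <- sample(0:6, 1)
    ni <- sample(0:6, 1)
    if (na + ni == 0) next
    dc <- conflict_distance(list(hop = hop, n_activation = na,
                                 n_inhibition = ni))
    if (na == ni) {
      expect_identical(dc, Inf)
    } else {
      expect_identical(dc > 0, na > ni)
      expect_gte(abs(dc), hop)
    }
  }
  # |d_c| is minimal when one parity class is empty, and inflates toward
  # the tie: with 10 paths at hop 2, censuses (10,0), (7,3), (6,4)
  mags <- sapply(list(c(10, 0), c(7, 3), c(6, 4)), function(cnt)
    abs(conflict_distance(list(hop = 2, n_activation = cnt[1],
                               n_inhibition = cnt[2]))))
  expect_equal(mags[1], 2)
  expect_true(all(diff(mags) > 0))
})

test_that("all-activation graphs reduce d_c to the hop distance", {
  set.seed(11)
  for (i in 1:20) {
    g <- random_signed_graph(sample(4:10, 1), p = 0.3, inhibition = 0)
    nodes <- graph_nodes(g)
    for (s in sample(nodes, 3)) {
      for (t in sample(nodes, 3)) {
        p <- shortest_path_parity(g, s, t)
        dc <- conflict_distance(p)
        if (is.finite(p$hop)) expect_equal(dc, p$hop)
      }
    }
  }
})

test_that("layered DP parity counts agree with exhaustive enumeration", {
  set.seed(19)
  for (i in 1:60) {
    g <- random_signed_graph(sample(4:12, 1), p = runif(1, 0.1, 0.5))
    nodes <- graph_nodes(g)
    st <- sample(nodes, 2)
    got <- shortest_path_parity(g, st[1], st[2])
    want <- enum_parity(g, st[1], st[2])
    expect_equal(got$hop, want$hop)
    expect_equal(got$n_activation, want$n_activation)
    expect_equal(got$n_inhibition, want$n_inhibition)
  }
})

test_that("edge tables read in headered, pre-signed and SIF-like forms", {
  headered <- write_tsv(data.frame(source = c("A", "B"),
                                   target = c("B", "C"),
                                   effect = c("activation", "repression")),
                        tempfile(fileext = ".tsv"))
  tab <- read_edge_table(headered)
  expect_equal(tab$sign, c(1L, -1L))

  signed <- write_tsv(data.frame(source = "A", target = "B", effect = "-1"),
                      tempfile(fileext = ".tsv"))
  expect_equal(read_edge_table(signed)$sign, -1L)

  sif <- tempfile(fileext = ".sif")
  writeLines(c("A\tB\tactivation", "B\tC\tinhibition"), sif)
  tab <- read_edge_table(sif)
  expect_equal(tab$source, c("A", "B"))
  expect_equal(tab$sign, c(1L, -1L))

  bad <- write_tsv(data.frame(source = "A", target = "B"),
                   tempfile(fileext = ".tsv"))
  expect_error(read_edge_table(bad), "effect/sign")
})
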