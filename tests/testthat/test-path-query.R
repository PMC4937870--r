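test_that("net effect is the parity of inhibition counts", {
  expect_equal(net_effect(c(-1, -1)), 1L)     # inhibition of an inhibitor
  expect_equal(net_effect(1), 1L)
  expect_equal(net_effect(c(-1, 1, -1)), 1L)
  expect_equal(net_effect(c(-1, 1, 1)), -1L)
  expect_error(net_effect(integer(0)), class = "popnet_value_error")
  expect_error(net_effect(c(1, 0)), class = "popnet_value_error")
})

test_that("sign-sequence enumeration matches the two- and three-step tables", {
  expect_equal(valid_sign_sequences(2, 1L),
               list(c(1L, 1L), c(-1L, -1L)))
  three <- valid_sign_sequences(3, 1L)
  expect_equal(three, list(c(1L, 1L, 1L), c(1L, -1L, -1L),
                           c(-1L, 1L, -1L), c(-1L, -1L, 1L)))
  expect_error(valid_sign_sequences(0), class = "popnet_value_error")
})

test_that("sequence counts and membership agree with exhaustive enumeration", {
  # independent oracle: all 2^k sign vectors via expand.grid, filtered
  for (k in 1:6) {
    grid <- as.matrix(expand.grid(rep(list(c(1L, -1L)), k)))
    for (net in c(1L, -1L)) {
      expected <- grid[apply(grid, 1, prod) == net, , drop = FALSE]
      got <- valid_sign_sequences(k, net)
      expect_length(got, 2^(k - 1))
      expect_equal(nrow(expected), length(got))
      expect_setequal(apply(expected, 1, paste, collapse = ","),
                      vapply(got, paste, character(1), collapse = ","))
    }
  }
})

test_that("fixture paths to IL-8 match the worked examples", {
  net <- fixture_net()
  pcb <- enumerate_paths(net, "PCB153", 3, net = 1L,
                         restrict_targets = "IL-8")
  expect_length(pcb, 1)
  expect_equal(pcb[[1]]$node_ids, c("PCB153", "PXR", "CREB1", "IL-8"))
  expect_equal(pcb[[1]]$effects, c(-1L, -1L, 1L))

  tcdd <- enumerate_paths(net, "TCDD", 3, net = 1L,
                          restrict_targets = "IL-8")
  expect_length(tcdd, 1)
  expect_equal(tcdd[[1]]$node_ids, c("TCDD", "AhR", "IL-8"))
  expect_equal(tcdd[[1]]$steps, 2)
})

test_that("parallel edges give distinct paths only when signs differ", {
  dup <- toy_network(list(c("A", "B", "+"), c("A", "B", "+"),
                          c("A", "B", "-")))
  act <- enumerate_paths(dup, "A", 1, net = 1L)
  inh <- enumerate_paths(dup, "A", 1, net = -1L)
  expect_length(act, 1)
  expect_length(inh, 1)
})

test_that("self-loops are stored but never traversed", {
  net <- toy_network(list(c("A", "A", "+"), c("A", "B", "+")))
  expect_equal(nrow(net$interactions), 2)
  paths <- enumerate_paths(net, "A", 3, net = 1L)
  expect_equal(paths_to_keys(paths), "A|B:+")
})

test_that("path enumeration equals the brute-force oracle on random graphs", {
  skip_if_not_installed("igraph")
  withr::local_seed(421)
  for (trial in 1:60) {
    net <- random_network(sample(3:8, 1), sample(4:20, 1))
    src <- sample(net$entities$id, 1)
    k <- sample(1:4, 1)
    for (sgn in c(1L, -1L)) {
      got <- sort(paths_to_keys(enumerate_paths(net, src, k, net = sgn)))
      expect_equal(got, oracle_paths(net, src, k, sgn))
    }
  }
})

test_that("enumeration is parity-correct, depth-bounded and monotone in depth", {
  withr::local_seed(99)
  for (trial in 1:25) {
    net <- random_network(6, 14)
    src <- sample(net$entities$id, 1)
    p3 <- enumerate_paths(net, src, 3, net = 1L)
    expect_true(all(vapply(p3, function(p) prod(p$effects) == 1L,
                           logical(1))))
    expect_true(all(vapply(p3, function(p) p$steps, integer(1)) <= 3))
    p4 <- enumerate_paths(net, src, 4, net = 1L)
    expect_true(all(paths_to_keys(p3) %in% paths_to_keys(p4)))
  }
  expect_error(enumerate_paths(random_network(4, 5), "A", 0),
               class = "popnet_value_error")
  expect_error(enumerate_paths(random_network(4, 5), "nope", 3),
               class = "popnet_lookup_error")
})

test_that("minimal activation depth matches the worked-example arithmetic", {
  net <- fixture_net()
  expect_equal(min_activation_depth(net, "TCDD", "IL-8", 3), 2L)
  expect_equal(min_activation_depth(net, "PCB153", "IL-8", 3), 3L)
  expect_equal(min_activation_depth(net, "ppDDE", "IL-8", 3), 2L)
  # paths are simple and have >= 1 edge, so a node never reaches itself
  expect_true(is.na(min_activation_depth(net, "TCDD", "TCDD", 3)))
  # PCB153 reaches PXR only with net inhibition
  expect_true(is.na(min_activation_depth(net, "PCB153", "PXR", 3)))
})

test_that("paths export one row per path with chains and net effect", {
  net <- fixture_net()
  paths <- enumerate_paths(net, "PCB153", 3, net = 1L,
                           restrict_targets = "IL-8")
  df <- paths_as_data_frame(paths)
  expect_equal(df$nodes, "PCB153|PXR|CREB1|IL-8")
  expect_equal(df$signs, "--+")
  expect_equal(df$net, 1L)
  out <- withr::local_tempfile(fileext = ".tsv")
  write_paths(paths, out)
  expect_equal(utils::read.delim(out)$steps, 3L)
})
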