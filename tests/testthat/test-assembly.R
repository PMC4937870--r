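test_that("the IL-8 shortest-paths assembly has the expected worked-example structure", {
  net <- fixture_net()
  asm <- build_shortest_paths_network(net, fixture_sources(), "IL-8", 3)
  expect_setequal(asm$nodes, c("TCDD", "PCB153", "ppDDE", "AhR", "PXR",
                               "AR", "CREB1", "IL-8"))
  expect_equal(nrow(asm$edges), 7)
  expect_equal(asm$terminal_targets, "IL-8")
  # terminal target keeps only upstream interactions
  expect_false(any(asm$edges$source == "IL-8"))
  # every retained path is minimal for its pair
  for (r in asm$paths) {
    expect_equal(r$path$steps,
                 min_activation_depth(net, r$source, r$target, 3))
  }
})

test_that("all tied minimal paths are retained", {
  # two disjoint 2-step routes S -> T; oracle is the hand-enumerated set
  net <- toy_network(list(c("S", "A", "+"), c("A", "T", "+"),
                          c("S", "B", "-"), c("B", "T", "-"),
                          c("S", "C", "+"), c("C", "D", "+"),
                          c("D", "T", "+")))
  asm <- build_shortest_paths_network(net, "S", "T", 3)
  keys <- sort(paths_to_keys(lapply(asm$paths, `[[`, "path")))
  expect_equal(keys, c("S|A|T:++", "S|B|T:--"))
  # the longer 3-step route contributes nothing under shortest-only
  expect_false("D" %in% asm$nodes)
})

test_that("a shorter net-inhibition path does not redefine the minimum", {
  net <- toy_network(list(c("S", "T", "-"),
                          c("S", "A", "+"), c("A", "T", "+")))
  asm <- build_shortest_paths_network(net, "S", "T", 3)
  expect_equal(sort(paths_to_keys(lapply(asm$paths, `[[`, "path"))),
               "S|A|T:++")
})

test_that("mixed-message intermediates are detected", {
  # the canonical scenario: a linker activated by one source and
  # inhibited by the primary target of the other
  net <- toy_network(list(c("S1", "A", "+"), c("A", "N", "+"),
                          c("N", "T", "+"),
                          c("S2", "B", "+"), c("B", "N", "-"),
                          c("N", "T2", "-"), c("S1", "T2", "+"),
                          c("S2", "T", "+")))
  asm <- suppressWarnings(
    build_shortest_paths_network(net, c("S1", "S2"), c("T", "T2"), 3))
  expect_equal(detect_conflicts(asm, net), "N")

  fx <- fixture_net()
  full <- suppressWarnings(build_shortest_paths_network(
    fx, fixture_sources(),
    c("IL-8", "IL-6", "TNFa", "fetuinA", "cyclinD1"), 3))
  expect_equal(detect_conflicts(full, fx), character(0))

  one_edge <- build_shortest_paths_network(
    toy_network(list(c("S", "T", "+"))), "S", "T", 3)
  expect_equal(detect_conflicts(one_edge, toy_network(list(c("S", "T", "+")))), character(0))
})

test_that("conflict removal keeps targets with a concordant bypass", {
  # N is conflicted; T stays reachable from both sources without it
  net <- toy_network(list(
    c("S1", "N", "+"), c("N", "T", "+"),
    c("S1", "B", "+"), c("B", "T", "+"),   # tied bypass for S1
    c("S2", "N", "-"), c("N", "T2", "-"),  # S2 inhibits the linker
    c("S2", "D", "+"), c("D", "T", "+")
  ))
  asm <- suppressWarnings(
    build_shortest_paths_network(net, c("S1", "S2"), c("T", "T2"), 3))
  expect_true("N" %in% asm$nodes)
  fin <- remove_conflicts(asm, net)
  expect_equal(fin$removed_conflicts, "N")
  expect_false("N" %in% fin$nodes)
  expect_equal(fin$terminal_targets, "T")
  expect_equal(detect_conflicts(fin, net), character(0))
})

test_that("targets reachable only through a conflicted node are dropped", {
  net <- toy_network(list(
    c("S1", "A", "+"), c("A", "N", "+"), c("N", "T", "+"),
    c("S2", "N", "-"), c("N", "T2", "-")
  ))
  asm <- suppressWarnings(
    build_shortest_paths_network(net, c("S1", "S2"), c("T", "T2"), 3))
  fin <- remove_conflicts(asm, net)
  expect_false("N" %in% fin$nodes)
  expect_false("T" %in% fin$nodes)
  expect_equal(fin$terminal_targets, character(0))
})

test_that("conflict-free assemblies are a fixpoint of removal", {
  net <- fixture_net()
  asm <- build_shortest_paths_network(net, fixture_sources(), "IL-8", 3)
  fin <- remove_conflicts(asm, net)
  expect_identical(fin$nodes, asm$nodes)
  expect_identical(fin$edges, asm$edges)
  expect_equal(fin$removed_conflicts, character(0))
})

test_that("removal always terminates in a concordant, sound network", {
  withr::local_seed(2024)
  for (trial in 1:30) {
    net <- random_network(7, 16)
    ids <- net$entities$id
    sources <- sample(ids, 2)
    targets <- setdiff(sample(ids, 3), sources)
    if (!length(targets)) next
    asm <- tryCatch(
      suppressWarnings(
        build_shortest_paths_network(net, sources, targets, 3)),
      popnet_value_error = function(e) NULL)
    if (is.null(asm)) next
    fin <- remove_conflicts(asm, net)
    expect_equal(detect_conflicts(fin, net), character(0))
    # soundness: every surviving target is net-activation reachable from
    # every source over the retained paths
    for (t in fin$terminal_targets) {
      srcs <- unique(vapply(Filter(function(r) r$target == t, fin$paths),
                            `[[`, character(1), "source"))
      expect_setequal(srcs, sources)
    }
    # every edge lies on a retained path
    on_path <- unique(unlist(lapply(fin$paths, function(r) {
      p <- r$path
      paste(p$node_ids[-length(p$node_ids)], p$node_ids[-1], p$effects)
    })))
    expect_true(all(paste(fin$edges$source, fin$edges$target,
                          fin$edges$effect) %in% on_path))
  }
})

test_that("re-running on conflict can recover alternative routes", {
  # the only assembled route to T passes through conflicted N, but a
  # longer concordant detour exists in the base network
  net <- toy_network(list(
    c("S1", "N", "+"), c("N", "T", "+"),
    c("S2", "N", "-"), c("N", "T2", "-"),
    c("S1", "B", "+"), c("B", "C", "+"), c("C", "T", "+"),
    c("S2", "D", "+"), c("D", "T", "+")
  ))
  asm <- suppressWarnings(
    build_shortest_paths_network(net, c("S1", "S2"), c("T", "T2"), 3))
  expect_true("N" %in% detect_conflicts(asm, net))
  pruned <- remove_conflicts(asm, net)
  rerun <- remove_conflicts(asm, net, rerun_on_conflict = TRUE)
  expect_true("T" %in% rerun$terminal_targets)
  expect_true("B" %in% rerun$nodes)  # detour only findable by re-running
  expect_false("B" %in% pruned$nodes)
  expect_equal(detect_conflicts(rerun, net), character(0))
})

test_that("assembly exports GraphML, DOT and a removal log", {
  net <- fixture_net()
  asm <- build_shortest_paths_network(net, fixture_sources(), "IL-8", 3)
  gml <- withr::local_tempfile(fileext = ".graphml")
  dot <- withr::local_tempfile(fileext = ".dot")
  log <- withr::local_tempfile(fileext = ".tsv")
  write_assembled_graphml(asm, net, gml)
  write_assembled_dot(asm, net, dot)
  write_removal_log(asm, log)
  x <- xml2::read_xml(gml)
  xml2::xml_ns_strip(x)
  expect_length(xml2::xml_find_all(x, ".//node"), length(asm$nodes))
  expect_length(xml2::xml_find_all(x, ".//edge"), nrow(asm$edges))
  dot_txt <- readLines(dot)
  expect_true(any(grepl("digraph", dot_txt)))
  expect_true(any(grepl("color=red, arrowhead=tee", dot_txt)))
  expect_equal(nrow(utils::read.delim(log)), 0)
})
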