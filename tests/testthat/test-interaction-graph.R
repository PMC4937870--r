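test_that("TSV loading maps effect tokens to sign codes and preserves rows", {
  path <- write_temp_tsv(c(
    "source\ttarget\teffect\tmechanism",
    "A\tB\tactivation\tbinding",
    "B\tC\tinhibition\tphosphorylation",
    "C\tD\tunspecified\tbinding"
  ))
  net <- load_network(path)
  expect_equal(nrow(net$interactions), 3)
  expect_equal(net$interactions$effect, c(1L, -1L, 0L))
  # omitted optional columns get defaults
  expect_equal(unique(net$interactions$trust), "high")
  expect_equal(unique(net$interactions$directness), "direct")
  # auto-created entities default to generic_protein
  expect_setequal(net$entities$id, c("A", "B", "C", "D"))
  expect_equal(unique(net$entities$entity_class), "generic_protein")
})

test_that("malformed edge tables raise named, classed errors", {
  no_col <- write_temp_tsv(c("source\ttarget\tmechanism", "A\tB\tbinding"))
  expect_error(load_network(no_col), "effect",
               class = "popnet_format_error")
  bad_tok <- write_temp_tsv(c(
    "source\ttarget\teffect\tmechanism",
    "A\tB\tactivation\tbinding",
    "X\tY\tactivated\tbinding"
  ))
  expect_error(load_network(bad_tok), "row 2.*activated",
               class = "popnet_value_error")
  empty_id <- write_temp_tsv(c(
    "source\ttarget\teffect\tmechanism", "\tB\tactivation\tbinding"
  ))
  expect_error(load_network(empty_id), "empty",
               class = "popnet_value_error")
})

test_that("the packaged fixture network has the expected cast of entities", {
  fx <- pop_fixture()
  ent <- fx$network$entities
  expect_equal(sum(ent$entity_class == "compound"), 3)
  expect_equal(sum(ent$entity_class == "receptor"), 3)
  expect_true(all(c("AhR", "PXR", "AR", "CREB1", "RelA", "c-Jun", "IL-8",
                    "IL-6", "TNFa", "fetuinA", "cyclinD1") %in% ent$id))
})

test_that("evidence filtering keeps exactly the qualifying edges", {
  net <- interaction_network(data.frame(
    source = "A", target = c("B", "C", "D", "E"),
    effect = c(1L, 1L, -1L, 0L), mechanism = "binding",
    trust = c("high", "low", "high", "high"),
    directness = c("direct", "direct", "indirect", "direct"),
    provenance = "", stringsAsFactors = FALSE
  ))
  out <- filter_evidence(net)
  expect_equal(nrow(out$interactions), 1)
  expect_equal(out$interactions$target, "B")
  # entities retained even when isolated; input untouched
  expect_equal(nrow(out$entities), 5)
  expect_equal(nrow(net$interactions), 4)

  # the fixture is already high-trust/direct/known: filtering is a no-op,
  # and filtering twice equals filtering once (idempotence)
  fx <- pop_fixture()$network
  once <- filter_evidence(fx)
  expect_equal(nrow(once$interactions), nrow(fx$interactions))
  expect_identical(filter_evidence(once)$interactions, once$interactions)

  all_low <- interaction_network(data.frame(
    source = "A", target = "B", effect = 1L, mechanism = "binding",
    trust = "low", directness = "direct", provenance = "",
    stringsAsFactors = FALSE
  ))
  filtered <- filter_evidence(all_low)
  expect_equal(nrow(filtered$interactions), 0)
  expect_equal(nrow(filtered$entities), 2)
})

test_that("primary targets are direct binding targets with downstream edges", {
  net <- fixture_net()
  expect_equal(primary_targets(net, "TCDD"), "AhR")
  expect_equal(primary_targets(net, "PCB153"), "PXR")
  expect_equal(primary_targets(net, "ppDDE"), "AR")
  expect_error(primary_targets(net, "nosuch"), class = "popnet_lookup_error")

  # binding a dead-end node yields nothing
  dead_end <- toy_network(list(c("C", "R", "+")))
  expect_equal(primary_targets(dead_end, "C"), character(0))
  # primary targets are always among the direct successors
  succ <- unique(net$interactions$target[net$interactions$source == "TCDD"])
  expect_true(all(primary_targets(net, "TCDD") %in% succ))
})

test_that("TSV and GraphML exports round-trip the edge multiset", {
  net <- fixture_net()
  edge_key <- function(n) {
    ia <- n$interactions
    sort(paste(ia$source, ia$target, ia$effect, ia$mechanism, ia$trust,
               ia$directness))
  }
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, tsv, "tsv")
  expect_equal(edge_key(load_network(tsv)), edge_key(net))

  gml <- withr::local_tempfile(fileext = ".graphml")
  write_network(net, gml, "graphml")
  back <- read_graphml(gml)
  expect_equal(edge_key(back), edge_key(net))
  expect_equal(back$entities[order(back$entities$id), ],
               net$entities[order(net$entities$id), ],
               ignore_attr = TRUE)
})

test_that("SIF export encodes signs as relation tokens, keeping parallel edges", {
  one <- toy_network(list(c("A", "B", "+")))
  sif <- withr::local_tempfile(fileext = ".sif")
  write_network(one, sif, "sif")
  expect_equal(readLines(sif), "A\tactivates\tB")

  both <- toy_network(list(c("A", "B", "+"), c("A", "B", "-")))
  write_network(both, sif, "sif")
  expect_setequal(readLines(sif), c("A\tactivates\tB", "A\tinhibits\tB"))
})

test_that("entity removal takes incident interactions with it", {
  net <- fixture_net()
  out <- delete_entities(net, "RelA")
  expect_false("RelA" %in% out$entities$id)
  expect_false(any(out$interactions$source == "RelA" |
                     out$interactions$target == "RelA"))
  expect_equal(nrow(out$interactions),
               nrow(net$interactions) -
                 sum(net$interactions$source == "RelA" |
                       net$interactions$target == "RelA"))
})
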