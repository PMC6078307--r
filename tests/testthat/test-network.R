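toy_records <- function() {
  data.frame(
    block_a = c("metabolite", "clinical", "metabolite"),
    block_b = c("brain", "brain", "clinical"),
    variable_a = c("M1", "C1", "M1"),
    variable_b = c("B1", "B1", "C2"),
    modality = c("functional", "functional", NA),
    r = c(0.5, -0.4, 0.3),
    p = c(0.001, 0.02, 0.2),
    q = c(0.01, 0.10, 0.6),
    stringsAsFactors = FALSE
  )
}

test_that("network assembly thresholds, types and dedupes", {
  rec <- toy_records()
  net <- build_network(rec, mode = "p", alpha = 0.05)
  expect_equal(nrow(net$edges), 2)  # M1-C2 fails p < .05
  expect_setequal(net$nodes$type, c("metabolite", "clinical", "brain"))
  expect_equal(net$nodes$modality[net$nodes$type == "brain"], "functional")

  # q-mode keeps only the q-passing edge
  netq <- build_network(rec, mode = "q", alpha = 0.05)
  expect_equal(nrow(netq$edges), 1)
  expect_equal(netq$edges$r, 0.5)

  # near-1 alpha admits every record; nodes = distinct variables
  all_in <- build_network(rec, mode = "p", alpha = 1 - 1e-9)
  expect_equal(nrow(all_in$edges), 3)
  expect_equal(nrow(all_in$nodes), 4)

  # duplicated pair rows collapse to the first occurrence
  dup <- rbind(rec, transform(rec[1, ], r = 0.9))
  expect_equal(nrow(build_network(dup)$edges), 2)
  expect_equal(build_network(dup)$edges$r[1], 0.5)

  expect_equal(nrow(build_network(rec[0, ])$edges), 0)
  expect_error(build_network(rec, alpha = 1.5), "alpha")
  within <- transform(rec, block_b = block_a)
  expect_error(build_network(within), "within-block")
})

test_that("alpha relaxation only ever adds edges", {
  sp <- cohort_spec(seed = 61)
  rec <- block_correlations(simulate_blocks(sp))
  prev <- character(0)
  for (a in c(0.001, 0.01, 0.05, 0.2, 0.8)) {
    net <- build_network(rec, "p", a)
    cur <- paste(net$edges$from, net$edges$to)
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("first-neighbor extraction keeps the induced subgraph", {
  # chain: metabolite M - brain B - clinical C; C is retained because the
  # B-C edge lies in the induced subgraph on {M, B's neighbors}
  rec <- toy_records()
  net <- build_network(rec, "p", 0.05)
  sub <- metabolite_first_neighbors(net)
  expect_setequal(sub$nodes$label, c("M1", "B1", "C1"))
  expect_equal(nrow(sub$edges), 2)

  # an isolated clinical node (no path to a metabolite) is dropped
  rec2 <- rbind(rec, data.frame(block_a = "clinical", block_b = "brain",
                                variable_a = "C9", variable_b = "B9",
                                modality = "anatomical", r = 0.4,
                                p = 0.001, q = 0.001))
  sub2 <- metabolite_first_neighbors(build_network(rec2, "p", 0.05))
  expect_false(any(sub2$nodes$label %in% c("C9", "B9")))

  empty <- build_network(rec[0, ])
  expect_warning(out <- metabolite_first_neighbors(empty), "no metabolite")
  expect_equal(nrow(out$nodes), 0)
})

test_that("effect classification separates direct, indirect and none", {
  rec <- toy_records()
  sub <- metabolite_first_neighbors(build_network(rec, "p", 0.05))
  eff <- classify_effects(sub)
  # M1-C1: no direct edge, B1 adjacent to both -> indirect via B1
  row <- eff[eff$metabolite == "M1" & eff$target == "C1", ]
  expect_equal(row$status, "indirect")
  expect_equal(row$mediators, "B1")

  # single metabolite, no edges at all -> none
  lonely <- build_network(toy_records()[1, , drop = FALSE], "p", 0.0005)
  eff0 <- classify_effects(lonely, metabolites = "M1", targets = "C1")
  expect_equal(eff0$status, "none")
  expect_equal(eff0$mediators, "")

  # every indirect call is certified by a length-2 path in the network
  for (i in which(eff$status == "indirect")) {
    m <- eff$metabolite[i]
    meds <- strsplit(eff$mediators[i], ",")[[1]]
    for (md in meds) {
      e <- sub$edges
      touches <- function(a, b) any((e$from == a & e$to == b) |
                                      (e$from == b & e$to == a))
      md_id <- sub$nodes$id[sub$nodes$label == md]
      expect_true(touches(m, md_id))
      expect_true(touches(eff$target[i], md_id))
    }
  }
})

test_that("reference tables rebuild the published tripartite structure", {
  rec <- reward_associations()
  expect_equal(nrow(rec), 28)
  net <- reference_reward_network()
  # strongest printed association survives with its r
  e <- net$edges
  hit <- e[(e$from == "Indole" | e$to == "Indole") &
             (e$from == "B_R_NAcc|func" | e$to == "B_R_NAcc|func"), ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$r, 0.59608)

  # the row printed as "p < 0.050" is included at alpha = 0.05
  expect_true("B_R_ALSHorp|anat" %in% net$nodes$id)

  sub <- metabolite_first_neighbors(net)
  expect_true(all(c("YFAS", "ANX", "BMI") %in% sub$nodes$label))
  expect_true(any(grepl("NAcc", sub$nodes$label)))
  expect_true(any(grepl("Amg", sub$nodes$label)))
  expect_true(any(grepl("ALS", sub$nodes$label)))  # aINS metrics retained
})

test_that("graph exports round-trip and encode edge signs", {
  net <- build_network(toy_records(), "p", 0.25)
  # GraphML round trip preserves node and edge attributes
  gpath <- tempfile(fileext = ".graphml")
  export_graph(net, gpath, "graphml")
  back <- read_graphml_network(gpath)
  expect_setequal(back$nodes$name, net$nodes$id)
  expect_setequal(back$nodes$type, net$nodes$type)
  expect_equal(sort(back$edges$r), sort(net$edges$r), tolerance = 1e-9)
  expect_equal(sort(back$edges$p), sort(net$edges$p), tolerance = 1e-9)

  # SIF: sign token tracks r
  spath <- tempfile(fileext = ".sif")
  export_graph(net, spath, "sif")
  sif <- readLines(spath)
  expect_length(sif, nrow(net$edges))
  expect_true(any(grepl("\tneg\t", sif)))  # C1-B1 has r < 0
  expect_true(any(grepl("\tpos\t", sif)))

  # TSV round trip
  tpath <- tempfile(fileext = ".tsv")
  export_graph(net, tpath, "tsv")
  tsv <- read.delim(tpath, stringsAsFactors = FALSE)
  expect_equal(tsv$r, net$edges$r, tolerance = 1e-12)
  expect_identical(tsv$from, net$edges$from)

  # empty network still yields a valid GraphML document
  epath <- tempfile(fileext = ".graphml")
  export_graph(build_network(toy_records()[0, ]), epath, "graphml")
  eback <- read_graphml_network(epath)
  expect_equal(nrow(eback$nodes), 0)

  expect_error(export_graph(net, tempfile(), "dot"), "arg")
})
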