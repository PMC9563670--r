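test_that("a feedback loop condenses into one conjunctive node", {
  g <- condense_loops(fig_loop_graph())
  expect_equal(nrow(g$nodes), 3L)
  loop_node <- g$nodes[g$nodes$kind == "condensed_loop", ]
  expect_equal(loop_node$genes, "B;C;D;E")
  # acyclic: topological order exists
  ig <- igraph::graph_from_data_frame(g$edges[, c("from", "to")],
                                      vertices = g$nodes$id)
  expect_true(igraph::is_dag(ig))
  # A -> loop -> F preserved
  lab <- setNames(g$nodes$genes, g$nodes$id)
  expect_setequal(paste(lab[g$edges$from], lab[g$edges$to]),
                  c("A B;C;D;E", "B;C;D;E F"))
})

test_that("acyclic graphs pass through loop condensation unchanged", {
  g <- fig_binding_graph()
  expect_true(graphs_equal(g, condense_loops(g)))
})

test_that("loop condensation matches a reachability SCC oracle on random digraphs", {
  for (seed in 1:20) {
    g <- random_digraph(sample(4:10, 1), 0.25, seed)
    cond <- condense_loops(g)
    got <- sort(vapply(node_genes(cond), function(x) paste(sort(x), collapse = ","),
                       character(1)))
    expect_equal(unname(got), reachability_scc_oracle(g), label = paste("seed", seed))
    ig <- igraph::graph_from_data_frame(
      cond$edges[, c("from", "to")], vertices = cond$nodes$id)
    expect_true(igraph::is_dag(ig))
  }
})

test_that("a binding event expands into member and merged variants", {
  vars <- expand_bindings(fig_binding_graph())
  expect_length(vars, 3L)
  labels <- sort(vapply(vars, function(v)
    paste(sort(v$nodes$genes), collapse = "|"), character(1)))
  expect_equal(labels, c("A|B;C|D", "A|B|D", "A|C|D"))
  # no binding edges remain
  expect_true(all(vapply(vars, function(v)
    !any(v$edges$subtype == "binding/association"), logical(1))))
})

test_that("independent binding events combine multiplicatively", {
  g <- pathway_graph(
    "two_bindings",
    nodes = data.frame(id = LETTERS[1:8], genes = LETTERS[1:8],
                       kind = "simple", stringsAsFactors = FALSE),
    edges = data.frame(
      from = c("A", "A", "B", "C", "D", "D", "E", "F", "B", "E"),
      to = c("B", "C", "D", "D", "E", "F", "G", "G", "C", "F"),
      sign = 1L,
      subtype = c(rep("activation", 8), "binding/association",
                  "binding/association"),
      stringsAsFactors = FALSE
    )
  )
  vars <- expand_bindings(g)
  expect_length(vars, 9L)  # 3 choices per binding pair
  # graph with no binding edges yields a single identical variant
  plain <- fig_loop_graph()
  expect_length(expand_bindings(plain), 1L)
  expect_true(graphs_equal(plain, expand_bindings(plain)[[1]]))
})

test_that("the binding variant cap truncates deterministically", {
  g <- pathway_graph(
    "capped",
    nodes = data.frame(id = c("A", "B", "C", "D", "E"),
                       genes = c("A", "B", "C", "D", "E"),
                       kind = "simple", stringsAsFactors = FALSE),
    edges = data.frame(
      from = c("A", "A", "B", "C", "B", "D"),
      to = c("B", "C", "D", "E", "C", "E"),
      sign = 1L,
      subtype = c("activation", "activation", "activation", "activation",
                  "binding/association", "binding/association"),
      stringsAsFactors = FALSE
    )
  )
  expect_warning(vars <- expand_bindings(g, cap = 4L), "keeping first 4")
  expect_length(vars, 4L)
  expect_warning(vars2 <- expand_bindings(g, cap = 4L), "keeping first")
  expect_identical(vapply(vars, function(v) paste(v$nodes$id, collapse = "|"),
                          character(1)),
                   vapply(vars2, function(v) paste(v$nodes$id, collapse = "|"),
                          character(1)))
})

test_that("the binding topology yields exactly its three chains", {
  ss <- enumerate_subpathways(fig_binding_graph())
  expect_equal(vapply(ss$subpaths, function(s) paste(s$labels, collapse = ">"),
                      character(1)),
               c("A>B+C>D", "A>B>D", "A>C>D"))
  expect_true(all(vapply(ss$subpaths, function(s) all(s$signs == 1L),
                         logical(1))))
})

test_that("an isolated node is a chain of length one", {
  g <- pathway_graph("lone",
                     data.frame(id = "X", genes = "X", kind = "simple"),
                     data.frame(from = character(), to = character(),
                                sign = integer(), subtype = character()))
  ss <- enumerate_subpathways(g)
  expect_length(ss$subpaths, 1L)
  expect_equal(ss$subpaths[[1]]$labels, "X")
  expect_length(ss$subpaths[[1]]$signs, 0L)
})

test_that("enumeration matches the igraph all-simple-paths oracle on random DAGs", {
  for (seed in 1:200) {
    g <- random_dag(sample(4:12, 1), stats::runif(1, 0.1, 0.4), seed)
    ss <- enumerate_subpathways(g)
    got <- vapply(ss$subpaths, function(s) paste(s$labels, collapse = ">"),
                  character(1))
    expect_equal(got, igraph_path_oracle(g), label = paste("seed", seed))
  }
})

test_that("enumeration is deterministic and honours caps", {
  g <- random_dag(10, 0.35, 99)
  a <- enumerate_subpathways(g)
  b <- enumerate_subpathways(g)
  expect_identical(a, b)
  expect_warning(
    capped <- enumerate_subpathways(g, enumeration_config(max_paths_per_pathway = 2L)),
    "truncated")
  expect_length(capped$subpaths, 2L)
})

test_that("any_node start policy adds suffix chains", {
  g <- pathway_graph(
    "chain3",
    data.frame(id = c("A", "B", "C"), genes = c("A", "B", "C"),
               kind = "simple", stringsAsFactors = FALSE),
    data.frame(from = c("A", "B"), to = c("B", "C"), sign = 1L,
               subtype = "activation", stringsAsFactors = FALSE)
  )
  entry <- enumerate_subpathways(g)
  any_start <- enumerate_subpathways(g, enumeration_config(start_policy = "any_node"))
  expect_length(entry$subpaths, 1L)
  expect_length(any_start$subpaths, 3L)  # A>B>C, B>C, C
})

test_that("step signs follow the edges of the chain", {
  g <- pathway_graph(
    "signed",
    data.frame(id = c("A", "B", "C"), genes = c("A", "B", "C"),
               kind = "simple", stringsAsFactors = FALSE),
    data.frame(from = c("A", "B"), to = c("B", "C"), sign = c(1L, -1L),
               subtype = c("activation", "inhibition"), stringsAsFactors = FALSE)
  )
  ss <- enumerate_subpathways(g)
  expect_equal(ss$subpaths[[1]]$signs, c(1L, -1L))
})
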