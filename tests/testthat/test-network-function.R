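test_that("CpG-to-gene mapping unions, dedups and reports unmapped", {
  ann <- toy_annotation(
    c("p1", "p2", "p3"),
    links = data.frame(cpg_id = c("p1", "p1", "p2"),
                       gene = c("A", "B", "B"),
                       tss = c(100L, 200L, 300L), strand = "+",
                       stringsAsFactors = FALSE))
  got <- map_cpg_to_genes(c("p1", "p2", "p3"), ann)
  expect_identical(got$genes, c("A", "B"))
  expect_identical(got$unmapped, "p3")
  expect_identical(map_cpg_to_genes(character(0), ann)$genes, character(0))
  expect_error(map_cpg_to_genes(c("p1", "p9"), ann), "p9")
})

test_that("mapping equals the brute-force pair scan on synthetic annotation", {
  co <- generate_cohort(sim_config(n_cpg = 300, n_dm = 20, n_genes = 50,
                                   seed = 17))
  panel <- sample(co$annotation$probes$cpg_id, 80)
  got <- map_cpg_to_genes(panel, co$annotation)
  want <- character(0)
  for (p in panel) {
    want <- c(want, co$annotation$links$gene[co$annotation$links$cpg_id == p])
  }
  expect_identical(got$genes, sort(unique(want)))
})

test_that("effector classification partitions with validated precedence", {
  genes <- sprintf("G%03d", 1:180)
  validated <- sprintf("G%03d", 1:91)
  database <- sprintf("G%03d", 92:132)   # 41 genes
  cls <- classify_effector_status(genes, validated, database)
  expect_identical(cls$n_validated, 91L)
  expect_identical(cls$n_database, 41L)
  expect_identical(cls$n_novel, 48L)
  expect_identical(cls$n_validated + cls$n_database + cls$n_novel, 180L)

  # no references -> all novel
  expect_identical(classify_effector_status(genes, character(0),
                                            character(0))$n_novel, 180L)
  # a gene in both references counts once, as validated
  both <- classify_effector_status(c("X"), c("X"), c("X"))
  expect_identical(both$n_validated, 1L)
  expect_identical(both$n_database, 0L)
})

test_that("hypergeometric ORA matches exact combinatorial tails", {
  bg <- sprintf("G%02d", 1:20)
  sets <- structure(list(S1 = bg[1:5]), class = "gene_set_collection")
  ora <- hypergeometric_ora(bg[1:5], sets, bg)
  expect_equal(ora$p_value, 1 / choose(20, 5), tolerance = 1e-12)

  # zero overlap includes the 0 term: upper tail from 0 is 1
  sets2 <- structure(list(S1 = bg[6:8]), class = "gene_set_collection")
  ora2 <- hypergeometric_ora(bg[1:3], sets2, bg)
  expect_identical(ora2$p_value, 1)

  expect_error(hypergeometric_ora("X", sets, bg), "outside")
  expect_error(hypergeometric_ora("G01", sets, character(0)), "empty")
})

test_that("planted enriched sets surface with the smallest adjusted p", {
  genes <- sprintf("G%03d", 1:400)
  out <- generate_gene_sets(genes, n_sets = 30, enriched_fraction = 0.1,
                            seed = 21)
  ora <- hypergeometric_ora(out$truth$query_genes, out$sets, genes)
  expect_true(ora$set_name[1] %in% out$truth$enriched_sets)
  expect_true(all(ora$adj_p >= ora$p_value))
  # BH here is the same shared routine as in the screening module
  expect_equal(ora$adj_p[order(match(ora$set_name, names(out$sets)))],
               benjamini_hochberg(ora$p_value[order(match(ora$set_name,
                                                          names(out$sets)))]),
               tolerance = 1e-14)
})

test_that("edge lists load with threshold, dedup and error reporting", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("node_a\tnode_b\tcombined_score",
               "A\tB\t499", "B\tC\t500", "C\tD\t900",
               "D\tC\t700", "E\tE\t950"), path)
  net <- load_edge_list(path, min_score = 500)
  # 499 dropped (threshold inclusive at 500), C-D/D-C merged keeping max,
  # self-loop E-E dropped
  expect_identical(nrow(net$edges), 2L)
  cd <- net$edges[net$edges$node_a == "C" & net$edges$node_b == "D", ]
  expect_identical(cd$combined_score, 900L)
  expect_setequal(net$nodes, c("B", "C", "D"))

  writeLines(c("node_a\tnode_b\tcombined_score",
               "A\tB\t500", "B\tC\tnot_a_number"), path)
  expect_error(load_edge_list(path), "line 3")
})

test_that("star and path graphs yield the closed-form centralities", {
  star <- interaction_network(data.frame(
    node_a = "hub", node_b = c("l1", "l2", "l3", "l4"),
    combined_score = 900L))
  sc <- composite_node_score(star)
  expect_identical(sc$node[1], "hub")
  expect_identical(sc$composite[1], 1)
  expect_true(all(sc$composite[-1] == 0))

  path3 <- interaction_network(data.frame(
    node_a = c("A", "B"), node_b = c("B", "C"), combined_score = 900L))
  sc3 <- composite_node_score(path3)
  expect_identical(sc3$betweenness_c[sc3$node == "B"], 1)
  expect_identical(sc3$betweenness_c[sc3$node == "A"], 0)
})

test_that("betweenness equals the exhaustive path-counting oracle", {
  for (s in 1:50) {
    n <- sample(5:12, 1)
    ed <- random_graph_edges(n, seed = s)
    net <- interaction_network(ed)
    sc <- composite_node_score(net, top_k = n)
    want <- betweenness_oracle(net$edges, net$nodes)
    expect_equal(sc$betweenness_c[match(names(want), sc$node)],
                 unname(want), tolerance = 1e-9)
  }
})

test_that("composite ranking is invariant to node input order", {
  ed <- random_graph_edges(10, seed = 99)
  net1 <- interaction_network(ed)
  net2 <- interaction_network(ed[sample(nrow(ed)), ],
                              nodes = rev(net1$nodes))
  s1 <- composite_node_score(net1, top_k = 10)
  s2 <- composite_node_score(net2, top_k = 10)
  expect_identical(s1$node, s2$node)
  expect_equal(s1$composite, s2$composite, tolerance = 1e-12)
  expect_error(composite_node_score(net1, w_degree = 0.7, w_between = 0.5),
               "sum to 1")
})

test_that("planted hubs occupy the top composite ranks across seeds", {
  wins <- vapply(1:5, function(s) {
    genes <- sprintf("G%02d", 1:25)
    out <- generate_interaction_network(genes, n_hubs = 2, seed = s)
    sc <- composite_node_score(out$network, top_k = 2)
    all(out$truth$hub_nodes %in% sc$node)
  }, logical(1))
  expect_gte(sum(wins), 4)
})
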