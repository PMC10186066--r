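toy_obo <- function(extra = character(0)) {
  path <- withr::local_tempfile(fileext = ".obo",
                                .local_envir = parent.frame())
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0000001", "name: root", "namespace: biological_process",
    "",
    "[Term]", "id: GO:0000002", "name: B", "namespace: biological_process",
    "is_a: GO:0000001 ! root", "",
    "[Term]", "id: GO:0000003", "name: C", "namespace: biological_process",
    "is_a: GO:0000001 ! root", "",
    "[Term]", "id: GO:0000004", "name: D", "namespace: biological_process",
    "is_a: GO:0000002 ! B", "is_a: GO:0000003 ! C", "",
    "[Term]", "id: GO:0000005", "name: old", "namespace: biological_process",
    "is_obsolete: true", "",
    "[Term]", "id: GO:0000010", "name: mf root",
    "namespace: molecular_function", "",
    extra), path)
  path
}

test_that("OBO parsing captures is_a, namespace, obsolete and part_of", {
  g <- read_obo(toy_obo(c("[Term]", "id: GO:0000006", "name: P",
                          "namespace: biological_process",
                          "relationship: part_of GO:0000002 ! B", "")))
  expect_s3_class(g, "ontology")
  expect_identical(sort(g$`GO:0000004`$is_a), c("GO:0000002", "GO:0000003"))
  expect_true(g$`GO:0000005`$obsolete)
  expect_identical(g$`GO:0000010`$namespace, "molecular_function")
  expect_identical(g$`GO:0000006`$part_of, "GO:0000002")
  expect_identical(g$`GO:0000006`$is_a, character(0))
})

test_that("propagation closes annotations over the DAG (diamond case)", {
  g <- read_obo(toy_obo())
  anno <- list(g1 = "GO:0000004", g2 = "GO:0000002", g3 = "GO:0000001")
  closed <- propagate(anno, g)
  expect_identical(closed$g1,
                   c("GO:0000001", "GO:0000002", "GO:0000003", "GO:0000004"))
  expect_identical(closed$g2, c("GO:0000001", "GO:0000002"))
  expect_identical(closed$g3, "GO:0000001")   # root-only is unchanged
})

test_that("unknown and obsolete terms are dropped; cycles are fatal", {
  g <- read_obo(toy_obo())
  expect_message(closed <- propagate(list(g1 = c("GO:0000002", "GO:9999999")),
                                     g),
                 "absent from the ontology")
  expect_identical(closed$g1, c("GO:0000001", "GO:0000002"))
  expect_identical(propagate(list(g1 = "GO:0000005"), g)$g1, character(0))
  cyc <- structure(list(
    A = list(name = "a", namespace = "biological_process", is_a = "B",
             part_of = character(0), obsolete = FALSE),
    B = list(name = "b", namespace = "biological_process", is_a = "A",
             part_of = character(0), obsolete = FALSE)),
    class = "ontology")
  expect_error(propagate(list(g1 = "A"), cyc), "cycle")
})

test_that("propagation equals the worklist closure oracle on random DAGs", {
  set.seed(53)
  for (rep in 1:25) {
    g <- random_dag(sample(10:60, 1L))
    ids <- names(g)
    anno <- list(gene = sample(ids, min(3L, length(ids))))
    got <- propagate(anno, g)$gene
    want <- sort(Reduce(union, lapply(anno$gene, oracle_closure, graph = g)))
    expect_identical(got, want)
  }
})

test_that("OG term sets are unions over member genes", {
  tab <- og_table_from_counts(cbind(A = c(2L, 1L, 1L), B = c(0L, 0L, 1L)))
  genes <- lapply(tab$rows, function(r) unlist(r, use.names = FALSE))
  # OG1: two genes with t1 / t2; OG2: unannotated; OG3: overlapping sets
  gt <- setNames(list("t1", "t2", c("t1", "t2"), "t1"),
                 c(genes[[1L]], genes[[3L]]))
  sets <- og_term_sets(tab, gt)
  expect_identical(sets[[1L]], c("t1", "t2"))
  expect_identical(sets[[2L]], character(0))   # unannotated OG kept
  expect_identical(sets[[3L]], c("t1", "t2"))  # duplicates collapse
})

test_that("go_test builds per-term urns and sorts deterministically", {
  g <- read_obo(toy_obo())
  # planted counts: N=20 background OGs, K=7 with the term, n=6 study,
  # k=4 study OGs with the term -> worked urn 3010/38760
  bg <- paste0("og", 1:20)
  study <- paste0("og", 1:6)
  term <- "GO:0000004"
  with_term <- c(paste0("og", 1:4), paste0("og", 7:9))  # 4 in study, 3 out
  og_terms <- setNames(lapply(bg, function(o) {
    if (o %in% with_term) c("GO:0000001", term) else "GO:0000001"
  }), bg)
  res <- go_test(study, bg, og_terms, g, namespace = "BP")
  row <- res[res$term_id == term, ]
  expect_identical(c(row$N, row$K, row$n, row$k), c(20L, 7L, 6L, 4L))
  expect_equal(row$p_raw, 3010 / 38760, tolerance = 1e-12)
  expect_equal(row$neg_log10_p, -log10(row$p_raw))
  # a term carried by every background OG is never enriched
  root_row <- res[res$term_id == "GO:0000001", ]
  expect_identical(root_row$p_raw, 1)
  expect_identical(res$term_id, res$term_id[order(res$p_raw, res$term_id)])
  # study members carrying the term are reported
  expect_identical(row$og_ids, paste(sort(paste0("og", 1:4)), collapse = ","))
})

test_that("min_annotated prunes rare terms and BH matches the step-up rule", {
  g <- read_obo(toy_obo())
  bg <- paste0("og", 1:10)
  og_terms <- setNames(lapply(1:10, function(i) {
    c("GO:0000001", if (i <= 2) "GO:0000002")
  }), bg)
  res <- go_test(bg[1:3], bg, og_terms, g, min_annotated = 3L)
  expect_false("GO:0000002" %in% res$term_id)   # only 2 annotated
  # frozen step-up example: {0.01, 0.02, 0.03} -> {0.03, 0.03, 0.03}
  expect_identical(stats::p.adjust(c(0.01, 0.02, 0.03), "BH"),
                   rep(0.03, 3))
  expect_true(all(res$p_adj <= 1))
  expect_true(all(diff(res$p_adj[order(res$p_raw)]) >= 0))
})

test_that("empty study warns; study outside background errors", {
  g <- read_obo(toy_obo())
  og_terms <- list(og1 = "GO:0000001")
  expect_warning(res <- go_test(character(0), "og1", og_terms, g), "empty")
  expect_identical(nrow(res), 0L)
  expect_error(go_test("og2", "og1", og_terms, g), "not in background")
})

test_that("elim removes significant children's OGs from ancestors", {
  g <- read_obo(toy_obo())
  # strong signal concentrated in the leaf GO:0000004; its parent
  # GO:0000002 is annotated to exactly the same OGs, so after elimination
  # the parent's signal must vanish (p_elim >= p_classic)
  bg <- paste0("og", 1:40)
  study <- paste0("og", 1:8)
  leaf_ogs <- paste0("og", 1:8)
  og_terms <- setNames(lapply(bg, function(o) {
    if (o %in% leaf_ogs) c("GO:0000001", "GO:0000002", "GO:0000004")
    else "GO:0000001"
  }), bg)
  classic <- go_test(study, bg, og_terms, g)
  elim <- elim_test(study, bg, og_terms, g, elim_alpha = 0.01)
  p_parent_classic <- classic$p_raw[classic$term_id == "GO:0000002"]
  p_parent_elim <- elim$p_raw[elim$term_id == "GO:0000002"]
  expect_lt(classic$p_raw[classic$term_id == "GO:0000004"], 0.01)
  expect_gte(p_parent_elim, p_parent_classic)
  expect_identical(p_parent_elim, 1)  # everything explained by the child
  # leaf result identical in both modes
  expect_identical(elim$p_raw[elim$term_id == "GO:0000004"],
                   classic$p_raw[classic$term_id == "GO:0000004"])
})

test_that("elim with alpha 0 reduces exactly to classic", {
  set.seed(61)
  g <- random_dag(40)
  bg <- paste0("og", 1:30)
  og_terms <- setNames(lapply(bg, function(o)
    sample(names(g), sample(0:5, 1L))), bg)
  study <- sample(bg, 10)
  classic <- go_test(study, bg, og_terms, g, min_annotated = 1L)
  elim0 <- elim_test(study, bg, og_terms, g, min_annotated = 1L,
                     elim_alpha = 0)
  expect_equal(elim0, classic)
})

test_that("induced subgraph contains ancestors with deterministic edges", {
  g <- read_obo(toy_obo())
  sub <- induced_subgraph("GO:0000004", g)
  expect_identical(nrow(sub), 4L)  # D->B, D->C, B->root, C->root
  expect_identical(sub$child, sort(sub$child))
  # shared ancestors appear once for sibling selections
  sub2 <- induced_subgraph(c("GO:0000002", "GO:0000003"), g)
  expect_identical(nrow(sub2), 2L)
  expect_identical(nrow(induced_subgraph(character(0), g)), 0L)
  expect_error(induced_subgraph("GO:9999999", g), "not in ontology")
})
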