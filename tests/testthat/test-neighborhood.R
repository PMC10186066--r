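mk_hit <- function(q, s, bitscore, evalue = 1e-10) {
  data.frame(qseqid = q, sseqid = s, pident = 90, length = 100,
             mismatch = 5, gapopen = 1, qstart = 1, qend = 100,
             sstart = 1, send = 100, evalue = evalue, bitscore = bitscore,
             stringsAsFactors = FALSE)
}

test_that("best_hits picks max bitscore with deterministic tie-breaks", {
  hits <- rbind(mk_hit("a1", "b2", 300), mk_hit("a1", "b1", 250))
  expect_identical(best_hits(hits)$sseqid, "b2")
  ties <- rbind(mk_hit("a1", "b2", 200), mk_hit("a1", "b1", 200))
  expect_identical(best_hits(ties)$sseqid, "b1")   # lexicographic
  ev <- rbind(mk_hit("a1", "b2", 200, evalue = 1e-20),
              mk_hit("a1", "b1", 200, evalue = 1e-10))
  expect_identical(best_hits(ev)$sseqid, "b2")     # smaller evalue first
  selfh <- rbind(mk_hit("a1", "a1", 999), mk_hit("a1", "b1", 10))
  expect_identical(best_hits(selfh)$sseqid, "b1")  # self-hits removed
})

test_that("reciprocal best hits require agreement in both directions", {
  smap <- c(a1 = "A", a3 = "A", b2 = "B")
  mutual <- rbind(mk_hit("a1", "b2", 300), mk_hit("b2", "a1", 290))
  rbh <- reciprocal_best_hits(mutual, smap)
  expect_identical(rbh$gene_a, "a1")
  expect_identical(rbh$gene_b, "b2")
  expect_identical(rbh$bitscore_ab, 300)
  expect_identical(rbh$bitscore_ba, 290)
  oneway <- rbind(mk_hit("a1", "b2", 300), mk_hit("b2", "a3", 400),
                  mk_hit("b2", "a1", 100))
  expect_identical(nrow(reciprocal_best_hits(oneway, smap)), 0L)
  expect_error(reciprocal_best_hits(mutual, c(a1 = "A")), "species map")
})

test_that("RBH equals the O(n^2) brute-force oracle on random tables", {
  set.seed(99)
  for (rep in 1:30) {
    n_sp <- sample(2:3, 1L)
    genes <- paste0(rep(letters[1:n_sp], each = 4), 1:4)
    smap <- setNames(rep(paste0("S", 1:n_sp), each = 4), genes)
    hits <- random_hit_table(genes, sample(10:40, 1L))
    got <- reciprocal_best_hits(hits, smap)
    expect_identical(sort(paste(got$gene_a, got$gene_b)),
                     oracle_rbh(hits, smap))
    # symmetric inputs (both directions present) are direction-agnostic
    swapped <- hits
    swapped[, c("qseqid", "sseqid")] <- hits[, c("sseqid", "qseqid")]
    both <- rbind(hits, swapped)
    both_rev <- rbind(swapped, hits)
    g3 <- reciprocal_best_hits(both, smap)
    g4 <- reciprocal_best_hits(both_rev, smap)
    expect_identical(paste(g3$gene_a, g3$gene_b),
                     paste(g4$gene_a, g4$gene_b))
  }
})

test_that("additional_ogs ranks by links, bitscore, then og id", {
  rbh <- data.frame(gene_a = c("g1", "g2", "g1"),
                    gene_b = c("x1", "x2", "y1"),
                    bitscore_ab = c(100, 110, 400),
                    bitscore_ba = c(90, 100, 380),
                    evalue_ab = 1e-20, evalue_ba = 1e-20,
                    stringsAsFactors = FALSE)
  mem <- c(g1 = "OG_F", g2 = "OG_F", x1 = "OG_X", x2 = "OG_X", y1 = "OG_Y")
  nb <- additional_ogs("OG_F", rbh, mem, n = 1)
  expect_identical(nb$neighbors$og_id, "OG_X")      # 2 links beat 1
  expect_identical(nb$neighbors$link_count, 2L)
  nb2 <- additional_ogs("OG_F", rbh, mem, n = 5)
  expect_identical(nb2$neighbors$og_id, c("OG_X", "OG_Y"))
  # tie on links resolved by max bitscore
  rbh_tie <- rbh[c(1, 3), ]
  nb3 <- additional_ogs("OG_F", rbh_tie, mem, n = 2)
  expect_identical(nb3$neighbors$og_id, c("OG_Y", "OG_X"))
  expect_identical(nb3$neighbors$max_bitscore, c(400, 100))
})

test_that("unmapped genes become singleton pseudo-OGs; n=0 keeps focal hits", {
  rbh <- data.frame(gene_a = "g1", gene_b = "lone",
                    bitscore_ab = 200, bitscore_ba = 190,
                    evalue_ab = 1e-30, evalue_ba = 1e-30,
                    stringsAsFactors = FALSE)
  mem <- c(g1 = "OG_F")
  nb <- additional_ogs("OG_F", rbh, mem, n = 3)
  expect_identical(nb$neighbors$og_id, "singleton:lone")
  hits <- rbind(mk_hit("g1", "g2", 100), mk_hit("g1", "lone", 200))
  nb0 <- additional_ogs("OG_F", rbh, c(g1 = "OG_F", g2 = "OG_F"), n = 0,
                        hits = hits)
  expect_identical(nrow(nb0$neighbors), 0L)
  expect_identical(nb0$extended_hits$sseqid, "g2")  # focal-internal only
})

test_that("neighborhoods are invariant to hit-row order", {
  set.seed(17)
  genes <- c(paste0("a", 1:5), paste0("b", 1:5), paste0("c", 1:5))
  smap <- setNames(rep(c("A", "B", "C"), each = 5), genes)
  mem <- setNames(rep(c("OG1", "OG2", "OG3"), each = 5), genes)
  hits <- random_hit_table(genes, 60)
  rbh1 <- reciprocal_best_hits(hits, smap)
  perm <- hits[sample.int(nrow(hits)), ]
  rbh2 <- reciprocal_best_hits(perm, smap)
  expect_identical(rbh1, rbh2)
  expect_identical(additional_ogs("OG1", rbh1, mem, n = 2)$neighbors,
                   additional_ogs("OG1", rbh2, mem, n = 2)$neighbors)
})

test_that("extended hits only touch focal or selected OG genes", {
  set.seed(23)
  genes <- c(paste0("a", 1:4), paste0("b", 1:4))
  smap <- setNames(rep(c("A", "B"), each = 4), genes)
  mem <- setNames(c("OG1", "OG1", "OG2", "OG2", "OG1", "OG2", "OG3", "OG3"),
                  genes)
  hits <- random_hit_table(genes, 40)
  rbh <- reciprocal_best_hits(hits, smap)
  nb <- additional_ogs("OG1", rbh, mem, n = 1, hits = hits)
  sel <- c(names(mem)[mem == "OG1"],
           unlist(lapply(nb$neighbors$og_id, function(og)
             names(mem)[mem == og])))
  expect_true(all(nb$extended_hits$qseqid %in% sel |
                    nb$extended_hits$sseqid %in% sel))
})
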