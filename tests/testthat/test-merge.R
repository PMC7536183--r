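test_that("gene overlap classes match the enclosed/partial/none rules", {
  ref <- build_set("ref", list(mk_tx("rt", "rg", list(c(100, 200)), source = "ref")))
  cls <- function(s, e) classify_gene_overlap(
    list(gene_id = "c", chrom = "chr1", start = s, end = e, strand = "+"), ref)
  expect_equal(cls(120, 180)$class, "ENCLOSED_OR_FULL")
  expect_equal(cls(120, 180)$best, "rg")
  expect_equal(cls(150, 250)$class, "PARTIAL")
  expect_equal(cls(300, 400)$class, "NONE")
  expect_equal(cls(100, 200)$class, "ENCLOSED_OR_FULL")  # identical boundaries
  # candidate enclosing the reference gene straddles both boundaries
  expect_equal(cls(50, 250)$class, "PARTIAL")
})

test_that("enclosure beats partial overlap with another reference gene", {
  ref <- build_set("ref", list(
    mk_tx("a.t", "a", list(c(100, 1000)), source = "ref"),
    mk_tx("b.t", "b", list(c(900, 2000)), source = "ref")))
  # enclosed in b, partially overlapping a
  got <- classify_gene_overlap(
    list(gene_id = "c", chrom = "chr1", start = 950, end = 1500, strand = "+"), ref)
  expect_equal(got$class, "ENCLOSED_OR_FULL")
  expect_equal(got$best, "b")
})

test_that("best enclosing gene: largest overlap, smallest span, then ID", {
  ref <- build_set("ref", list(
    mk_tx("wide.t", "wide", list(c(0, 5000)), source = "ref"),
    mk_tx("tight.t", "tight", list(c(900, 2100)), source = "ref")))
  got <- classify_gene_overlap(
    list(gene_id = "c", chrom = "chr1", start = 1000, end = 2000, strand = "+"), ref)
  expect_equal(got$best, "tight")
})

test_that("transcript admission enforces bounds and chain duplicates", {
  ref <- ref_two_genes()
  cand <- build_set("D2", list(
    mk_tx("oob", "cg", list(c(450, 550), c(600, 700)), source = "D2"),
    mk_tx("dup", "cg", list(c(1000, 1500), c(2000, 2500)), source = "D2"),
    mk_tx("new", "cg", list(c(1200, 1450), c(2100, 2400)), source = "D2")))
  # target gene R1 spans (1000, 5000); 'oob' lies before it
  adm <- admit_transcripts(ref, "R1", cand, c("oob", "dup", "new"))
  expect_equal(adm$fates$fate,
               c("discarded_out_of_bounds", "duplicate_skipped", "added"))
  g <- adm$set$genes[adm$set$genes$gene_id == "R1", ]
  expect_equal(g$sources, "D2,ref")
  expect_equal(c(g$start, g$end), c(1000, 5000))  # boundary untouched
})

test_that("the two-annotation scenario yields the documented fates", {
  ref <- ref_two_genes()
  cand <- build_set("D2", list(
    # gene 1: encloses within R1; transcript 1.1 pokes past the boundary
    mk_tx("t1.1", "C1", list(c(4500, 4900), c(5200, 6000)), source = "D2"),
    mk_tx("t1.2", "C1", list(c(1100, 1400), c(2100, 2400)), source = "D2"),
    mk_tx("t1.3", "C1", list(c(3100, 3300)), source = "D2"),
    # gene 2: straddles R1's right boundary
    mk_tx("t2.1", "C2", list(c(4000, 7000)), source = "D2"),
    # gene 3: outside both reference genes
    mk_tx("t3.1", "C3", list(c(13000, 13500)), source = "D2"),
    mk_tx("t3.2", "C3", list(c(14000, 15000)), source = "D2")),
    genes = dplyr::bind_rows(
      mk_gene("C1", 1000, 5000, sources = "D2"),
      mk_gene("C2", 4000, 7000, sources = "D2"),
      mk_gene("C3", 13000, 15000, sources = "D2")))
  res <- merge_pair(ref, cand)
  gf <- tibble::deframe(res$report$gene_fates[, c("gene_id", "fate")])
  expect_equal(gf[["C1"]], "merged_into")
  expect_equal(gf[["C2"]], "discarded_partial")
  expect_equal(gf[["C3"]], "added_new")
  tf <- tibble::deframe(res$report$transcript_fates[, c("transcript_id", "fate")])
  expect_equal(tf[["t1.1"]], "discarded_out_of_bounds")
  expect_equal(tf[["t1.2"]], "added")
  expect_equal(tf[["t1.3"]], "added")
  expect_equal(tf[["t2.1"]], "discarded_with_partial_gene")
  expect_equal(tf[["t3.1"]], "added")
  expect_equal(tf[["t3.2"]], "added")
  expect_equal(nrow(res$set$genes), 3L)
  expect_true(all(c("t1.2", "t1.3") %in%
                    res$set$transcripts$transcript_id[res$set$transcripts$gene_id == "R1"]))
  # reference boundaries immutable
  expect_identical(res$set$genes[res$set$genes$gene_id %in% c("R1", "R2"),
                                 c("start", "end")],
                   ref$genes[, c("start", "end")])
  # non-overlapping genes enter as lncRNA entries
  expect_equal(res$set$genes$biotype[res$set$genes$gene_id == "C3"], "lncRNA")
})

test_that("self-merge changes no counts and skips every transcript", {
  fx <- gen_annotations(fixture_spec(seed = 9, n_genes = 25, n_sources = 1))
  s <- normalize_annotation(fx$reference)
  res <- merge_pair(s, s)
  expect_equal(annotation_counts(res$set), annotation_counts(s))
  expect_true(all(res$report$transcript_fates$fate == "duplicate_skipped"))
  expect_true(all(res$report$gene_fates$fate == "merged_into"))
})

test_that("fates conserve inputs and truth-labelled fixtures are recovered", {
  for (seed in c(1, 2, 3)) {
    fx <- gen_annotations(fixture_spec(seed = seed, n_genes = 40))
    for (k in seq_along(fx$candidates)) {
      cand <- fx$candidates[[k]]
      res <- merge_pair(fx$reference, cand)
      rep <- res$report
      expect_equal(nrow(rep$gene_fates), nrow(cand$genes))
      expect_equal(nrow(rep$transcript_fates), nrow(cand$transcripts))
      expect_equal(sum(rep$counts$transcripts), nrow(cand$transcripts))
      truth <- fx$truth[fx$truth$source == cand$name, ]
      tf <- merge(rep$transcript_fates, truth, by = "transcript_id")
      expect_equal(tf$fate, tf$transcript_fate)
      gtruth <- truth[!is.na(truth$gene_fate), c("gene_id", "gene_fate")]
      gf <- merge(rep$gene_fates, unique(gtruth), by = "gene_id")
      expect_equal(gf$fate, gf$gene_fate)
    }
  }
})

test_that("indexed classification agrees with the all-pairs oracle", {
  for (seed in 1:10) {
    fx <- gen_annotations(fixture_spec(seed = 100 + seed, n_genes = 30))
    cand <- fx$candidates[[1]]
    for (aware in c(FALSE, TRUE)) {
      got <- lnckit:::classify_genes_bulk(cand$genes, fx$reference, aware)
      for (i in seq_len(nrow(cand$genes))) {
        want <- oracle_gene_overlap(cand$genes[i, ], fx$reference$genes, aware)
        expect_equal(got$class[i], want$class)
        if (want$class == "ENCLOSED_OR_FULL") expect_equal(got$best[i], want$best)
      }
    }
  }
})

test_that("merging is monotone and keeps every transcript inside its gene", {
  fx <- gen_annotations(fixture_spec(seed = 5, n_genes = 30, n_sources = 3))
  res <- merge_all(fx$reference, fx$candidates)
  expect_length(res$reports, 3)
  expect_gte(nrow(res$set$genes), nrow(fx$reference$genes))
  expect_gte(nrow(res$set$transcripts), nrow(fx$reference$transcripts))
  tr <- res$set$transcripts
  g <- res$set$genes[match(tr$gene_id, res$set$genes$gene_id), ]
  expect_true(all(tr$start >= g$start & tr$end <= g$end))
})

test_that("merge order matters when a candidate nests in an added gene", {
  ref <- build_set("ref", list(mk_tx("r.t", "r", list(c(100, 200)), source = "ref")))
  a <- build_set("A", list(mk_tx("a.t", "a1", list(c(300, 600)), source = "A")))
  b <- build_set("B", list(mk_tx("b.t", "b1", list(c(350, 500)), source = "B")))
  ab <- merge_all(ref, list(a, b))$set
  ba <- merge_all(ref, list(b, a))$set
  expect_setequal(ab$genes$gene_id, c("r", "a1"))
  expect_setequal(ba$genes$gene_id, c("r", "b1"))
})

test_that("an empty candidate list returns the reference unchanged", {
  ref <- ref_two_genes()
  res <- merge_all(ref, list())
  expect_equal(annotation_counts(res$set), annotation_counts(ref))
  expect_length(res$reports, 0)
})

test_that("source-membership accounting covers every gene exactly once", {
  ref <- ref_two_genes()
  cand <- build_set("D2", list(
    mk_tx("x1", "C1", list(c(1100, 1300))),  # into R1
    mk_tx("x2", "C3", list(c(13000, 14000)))),
    genes = dplyr::bind_rows(mk_gene("C1", 1100, 1300, sources = "D2"),
                             mk_gene("C3", 13000, 14000, sources = "D2")))
  cand$transcripts$source <- "D2"
  merged <- merge_pair(ref, cand)$set
  cm <- contribution_matrix(merged)
  expect_equal(sum(cm$intersections$count), nrow(merged$genes))
  expect_equal(cm$membership$sources[cm$membership$gene_id == "R1"], "D2,ref")
  expect_equal(cm$membership$sources[cm$membership$gene_id == "C3"], "D2")
  # single-source set: no multi-source combinations
  cm0 <- contribution_matrix(ref)
  expect_true(all(cm0$intersections$n_sources == 1))
})

test_that("gene ID collisions on addition are renamed and recorded", {
  ref <- build_set("ref", list(mk_tx("r.t", "g1", list(c(100, 200)), source = "ref")))
  cand <- build_set("C", list(mk_tx("c.t", "g1", list(c(500, 900)), source = "C")))
  res <- merge_pair(ref, cand)
  expect_true("g1_C" %in% res$set$genes$gene_id)
  expect_equal(res$report$renamed_genes, "g1")
})
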