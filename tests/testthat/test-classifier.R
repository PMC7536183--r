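one_tx <- function(tid, exons, strand = "+", chrom = "chr1",
                   biotype = "lncRNA") {
  mk_tx(tid, paste0(tid, ".g"), exons, chrom = chrom, strand = strand,
        biotype = biotype, source = "x")
}

test_that("the 200-bp and 0.75 sense-overlap pre-filters act at their
           boundaries", {
  ref <- build_set("ref", list(
    one_tx("pc1", list(c(0, 2000)), strand = "+", biotype = "protein_coding")))
  cands <- build_set("cand", list(
    one_tx("short", list(c(5000, 5120), c(5200, 5260))),     # 180 bp exonic
    one_tx("mono200", list(c(7000, 7200))),                  # exactly 200 bp
    one_tx("sense_hi", list(c(0, 800), c(2500, 2700)), strand = "+"),   # 800/1000 in sense
    one_tx("anti_hi", list(c(0, 800), c(2500, 2700)), strand = "-"),    # same, antisense
    one_tx("sense_lo", list(c(1500, 2250)), strand = "+")))  # 500/750 ~ 0.67
  pf <- prefilter(cands, ref)
  expect_equal(pf$removed_short, "short")
  expect_equal(pf$removed_sense_overlap, "sense_hi")
  expect_setequal(pf$kept, c("mono200", "anti_hi", "sense_lo"))
})

test_that("genic pairs get the documented direction, location and subtype", {
  mrna <- one_tx("m", list(c(500, 700), c(4500, 5000)), strand = "+",
                 biotype = "protein_coding")
  # lncRNA inside the intron, opposite strand, no exon-exon contact
  lnc <- one_tx("l", list(c(1000, 2000)), strand = "-")
  r <- classify_genic(lnc$transcript, mrna$transcript, lnc$exons, mrna$exons)
  expect_equal(r$direction, "antisense")
  expect_equal(r$location, "intronic")
  expect_equal(r$subtype, "nested")

  # lncRNA containing the partner, same strand, exon overlap
  big <- one_tx("l2", list(c(400, 800), c(4000, 5200)), strand = "+")
  r2 <- classify_genic(big$transcript, mrna$transcript, big$exons, mrna$exons)
  expect_equal(unlist(r2[, c("direction", "location", "subtype")], use.names = FALSE),
               c("sense", "exonic", "containing"))

  # identical spans classify as nested by the tie rule
  twin <- one_tx("l3", list(c(500, 700), c(4500, 5000)), strand = "+")
  r3 <- classify_genic(twin$transcript, mrna$transcript, twin$exons, mrna$exons)
  expect_equal(r3$subtype, "nested")

  # straddling one boundary is overlapping
  strad <- one_tx("l4", list(c(100, 600)), strand = "+")
  expect_equal(classify_genic(strad$transcript, mrna$transcript, strad$exons,
                              mrna$exons)$subtype, "overlapping")
})

test_that("intergenic orientation and side follow 5'/3' geometry", {
  cfg <- classifier_config()
  lnc <- one_tx("l", list(c(23000, 24000)), strand = "+")$transcript
  mrna_left <- one_tx("m", list(c(5000, 8000)), strand = "-")$transcript
  r <- classify_intergenic(lnc, mrna_left, cfg)
  expect_equal(r$location, "divergent")   # 5' ends face across the gap
  expect_equal(r$direction, "upstream")
  expect_equal(r$distance, 15000L)

  lnc2 <- one_tx("l2", list(c(1000, 2000)), strand = "+")$transcript
  mrna_right <- one_tx("m2", list(c(15000, 20000)), strand = "-")$transcript
  r2 <- classify_intergenic(lnc2, mrna_right, cfg)
  expect_equal(r2$location, "convergent") # 3' ends face across the gap
  expect_equal(r2$direction, "downstream")
  expect_equal(r2$distance, 13000L)

  same <- one_tx("m3", list(c(15000, 20000)), strand = "+")$transcript
  expect_equal(classify_intergenic(lnc2, same, cfg)$location, "same_strand")

  # overlapping spans must go through the genic path
  expect_error(classify_intergenic(lnc2,
    one_tx("m4", list(c(1500, 3000)))$transcript, cfg), "overlap")
  expect_error(classify_genic(lnc2, same,
    one_tx("l2", list(c(1000, 2000)))$exons,
    one_tx("m3", list(c(15000, 20000)))$exons), "overlap")
})

test_that("orientation labels are relative: invariant under mirror
           reflection, with sense/antisense fixed by relative strand only", {
  cfg <- classifier_config()
  flip <- function(s) if (s == "+") "-" else "+"
  for (i in 1:20) {
    set.seed(i)
    s1 <- sample(c("+", "-"), 1); s2 <- sample(c("+", "-"), 1)
    a <- one_tx("a", list(c(1000, 2000)), strand = s1)$transcript
    b <- one_tx("b", list(c(20000, 25000)), strand = s2)$transcript
    # mirror the locus around x = 30000 and flip both strands
    mirror <- function(t) {
      m <- t; m$start <- 30000 - t$end; m$end <- 30000 - t$start
      m$strand <- flip(t$strand); m
    }
    expect_equal(classify_intergenic(mirror(a), mirror(b), cfg)$location,
                 classify_intergenic(a, b, cfg)$location)
    # sense/antisense depends only on the relative strand
    ag <- a; ag$end <- 21000  # overlap for genic check
    agf <- ag; agf$strand <- flip(s1)
    bf <- b; bf$strand <- flip(s2)
    ex_a <- tibble::tibble(start = 1000, end = 21000)
    ex_b <- tibble::tibble(start = 20000, end = 25000)
    expect_equal(classify_genic(agf, bf, ex_a, ex_b)$direction,
                 classify_genic(ag, b, ex_a, ex_b)$direction)
  }
})

test_that("classification matches the brute-force oracle on random fixtures", {
  cfg <- classifier_config()
  for (seed in 1:10) {
    fx <- gen_classification(fixture_spec(seed = 200 + seed, n_genes = 15))
    got <- classify_all(fx$candidates, fx$reference, cfg)
    want <- oracle_classify_all(fx$candidates, fx$reference, cfg)
    key <- function(d) paste(d$lnc_transcript_id, d$partner_transcript_id,
                             d$type, d$direction, d$location,
                             ifelse(is.na(d$subtype), "-", d$subtype),
                             ifelse(is.na(d$distance), "-", d$distance))
    expect_setequal(key(got$records), key(want))
  }
})

test_that("planted configurations are recovered exactly with best partners", {
  fx <- gen_classification(fixture_spec(seed = 77, n_genes = 50))
  res <- classify_all(fx$candidates, fx$reference)
  best <- res$records[res$records$is_best_partner, ]
  expect_equal(nrow(best), 50L)
  expect_equal(sum(res$records$is_best_partner),
               length(unique(res$records$lnc_transcript_id)))
  cmp <- merge(best, fx$truth, by = "lnc_transcript_id")
  expect_equal(cmp$type.x, cmp$type.y)
  expect_equal(cmp$direction.x, cmp$direction.y)
  expect_equal(cmp$location.x, cmp$location.y)
  genic <- !is.na(cmp$subtype.y)
  expect_equal(cmp$subtype.x[genic], cmp$subtype.y[genic])
  expect_equal(cmp$distance[!genic], cmp$gap[!genic])
})

test_that("count-matrix marginals conserve the classified totals and every
           record occupies exactly one cell", {
  fx <- gen_classification(fixture_spec(seed = 88, n_genes = 60))
  res <- classify_all(fx$candidates, fx$reference)
  best <- res$records[res$records$is_best_partner, ]
  cm <- res$count_matrix
  expect_equal(sum(cm$genic) + sum(cm$intergenic), nrow(best))
  expect_equal(sum(cm$genic), sum(best$type == "GENIC"))
  expect_equal(unname(rowSums(cm$intergenic)),
               unname(as.vector(table(factor(
                 best$direction[best$type == "INTERGENIC"],
                 levels = c("upstream", "downstream"))))))
  # mutually exclusive, exhaustive cells
  g <- best[best$type == "GENIC", ]
  expect_true(all(g$direction %in% c("sense", "antisense")))
  expect_true(all(g$location %in% c("exonic", "intronic")))
  expect_true(all(g$subtype %in% c("overlapping", "containing", "nested")))
  i <- best[best$type == "INTERGENIC", ]
  expect_true(all(i$location %in% c("convergent", "divergent", "same_strand")))
})

test_that("lncRNAs with no partner in the window stay unclassified", {
  ref <- build_set("ref", list(one_tx("m", list(c(0, 1000)), chrom = "chrZ",
                                      biotype = "protein_coding")))
  far <- build_set("cand", list(one_tx("l", list(c(500000, 501000)), chrom = "chrZ")))
  res <- classify_all(far, ref)
  expect_equal(res$unclassified, "l")
  expect_equal(nrow(res$records), 0L)
  # empty reference: everything unclassified
  res2 <- classify_all(far, annotation_set("empty"))
  expect_equal(res2$unclassified, "l")
})

test_that("the window expands past window_min only when nothing is nearer", {
  cfg <- classifier_config(window_min = 10000, window_max = 100000)
  ref <- build_set("ref", list(
    one_tx("near", list(c(12000, 13000)), biotype = "protein_coding"),
    one_tx("far", list(c(60000, 61000)), biotype = "protein_coding")))
  lnc <- build_set("cand", list(one_tx("l", list(c(0, 5000)))))
  res <- classify_all(lnc, ref, cfg)
  # 'near' is within window_min (gap 7000) so 'far' is not reported
  expect_equal(res$records$partner_transcript_id, "near")

  lnc2 <- build_set("cand", list(one_tx("l2", list(c(0, 1000)))))
  ref2 <- build_set("ref", list(one_tx("far", list(c(60000, 61000)),
                                       biotype = "protein_coding")))
  res2 <- classify_all(lnc2, ref2, cfg)
  expect_equal(res2$records$partner_transcript_id, "far")
  # the strict-band alternative drops partners closer than window_min
  resb <- classify_all(lnc, ref, classifier_config(strict_band = TRUE))
  expect_equal(resb$records$partner_transcript_id, "far")
})
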