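## Seeded synthetic-data generators. Fixture chromosomes are short
## synthetic contigs (<= 1e6 bp) so brute-force per-base oracles stay
## feasible; every generated record carries a ground-truth label so module
## outputs can be checked exactly without external downloads.

#' Fixture specification
#'
#' @param seed integer seed; fixes every generated artifact bit-for-bit.
#' @param n_genes number of reference genes.
#' @param n_sources number of candidate annotation sources.
#' @param n_tissues number of tissues in expression fixtures (default 31,
#'   the GTEx-style solid-tissue panel the scores are designed for).
#' @param replicates_per_tissue samples per tissue (default 10).
#' @param overlap_mix named proportions of candidate genes engineered to be
#'   `enclosed`, `partial` or `disjoint` w.r.t. the reference.
#' @param planted_specific_fraction fraction of genes planted as
#'   tissue-specific in expression fixtures (default 0.2).
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_genes = 50L, n_sources = 2L,
                         n_tissues = 31L, replicates_per_tissue = 10L,
                         overlap_mix = c(enclosed = 0.4, partial = 0.2,
                                         disjoint = 0.4),
                         planted_specific_fraction = 0.2) {
  stopifnot(abs(sum(overlap_mix) - 1) < 1e-8,
            all(names(overlap_mix) %in% c("enclosed", "partial", "disjoint")),
            n_genes >= 1, n_tissues >= 2, replicates_per_tissue >= 1,
            planted_specific_fraction >= 0, planted_specific_fraction <= 1)
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 n_sources = as.integer(n_sources),
                 n_tissues = as.integer(n_tissues),
                 replicates_per_tissue = as.integer(replicates_per_tissue),
                 overlap_mix = overlap_mix,
                 planted_specific_fraction = planted_specific_fraction),
            class = "fixture_spec")
}

with_fixture_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# lay out n non-overlapping gene slots along synthetic contigs
layout_slots <- function(n, gene_len_range = c(2000L, 20000L),
                         gap_range = c(5000L, 30000L), contig_len = 1e6) {
  chrom_i <- 1L; pos <- 0L
  slots <- vector("list", n)
  for (i in seq_len(n)) {
    len <- sample(gene_len_range[1]:gene_len_range[2], 1)
    gap <- sample(gap_range[1]:gap_range[2], 1)
    if (pos + gap + len > contig_len) { chrom_i <- chrom_i + 1L; pos <- 0L }
    start <- pos + gap
    slots[[i]] <- list(chrom = paste0("ctgA", chrom_i), start = start,
                       end = start + len)
    pos <- start + len
  }
  slots
}

# build a transcript (and exons) spanning [start, end) with n_exons exons
make_transcript <- function(tid, gid, chrom, start, end, strand, biotype,
                            source, n_exons = NULL) {
  span <- end - start
  if (is.null(n_exons)) n_exons <- sample(1:min(5L, max(1L, span %/% 400L)), 1)
  if (n_exons == 1) {
    ex_s <- start; ex_e <- end
  } else {
    cuts <- sort(sample(seq(start + 100L, end - 100L, by = 50L),
                        2L * (n_exons - 1L)))
    ex_s <- c(start, cuts[seq(2, length(cuts), by = 2)])
    ex_e <- c(cuts[seq(1, length(cuts), by = 2)], end)
  }
  keep <- ex_s < ex_e
  ex_s <- ex_s[keep]; ex_e <- ex_e[keep]
  list(
    transcript = list(transcript_id = tid, gene_id = gid, chrom = chrom,
                      start = min(ex_s), end = max(ex_e), strand = strand,
                      biotype = biotype, source = source),
    exons = list(transcript_id = rep(tid, length(ex_s)), chrom = chrom,
                 start = ex_s, end = ex_e, strand = strand)
  )
}

#' Generate a reference annotation and engineered candidate annotations
#'
#' The reference holds non-overlapping genes (a mix of protein-coding and
#' lncRNA) on short synthetic contigs. Each candidate source contains genes
#' engineered to be enclosed in, partially overlapping, or disjoint from
#' the reference genes in the proportions of `spec$overlap_mix`, plus
#' transcripts duplicating reference exon chains (intended fate:
#' duplicate_skipped) and transcripts extending beyond their target
#' reference gene boundary (intended fate: discarded_out_of_bounds).
#'
#' @param spec fixture_spec.
#' @param with_duplicates,with_out_of_bounds plant those transcript cases
#'   in enclosed candidate genes (default TRUE).
#' @return list with `reference`, `candidates` (list of annotation_set) and
#'   `truth` (tibble: source, gene_id, transcript_id, kind, intended fate).
#' @export
gen_annotations <- function(spec, with_duplicates = TRUE,
                            with_out_of_bounds = TRUE) {
  with_fixture_seed(spec$seed, {
    n <- spec$n_genes
    slots <- layout_slots(n)
    genes <- list(); txs <- list(); exs <- list()
    for (i in seq_len(n)) {
      s <- slots[[i]]
      strand <- sample(c("+", "-"), 1)
      biotype <- sample(c("protein_coding", "lncRNA"), 1, prob = c(0.5, 0.5))
      gid <- sprintf("REFG%04d", i)
      genes[[i]] <- list(gene_id = gid, chrom = s$chrom, start = s$start,
                         end = s$end, strand = strand, biotype = biotype,
                         sources = "ref")
      for (k in seq_len(sample(1:2, 1))) {
        tk <- make_transcript(sprintf("REFT%04d.%d", i, k), gid, s$chrom,
                              s$start, s$end, strand, biotype, "ref")
        txs[[length(txs) + 1]] <- tk$transcript
        exs[[length(exs) + 1]] <- tk$exons
      }
    }
    reference <- annotation_set("ref",
                                genes = dplyr::bind_rows(genes),
                                transcripts = dplyr::bind_rows(txs),
                                exons = dplyr::bind_rows(exs))

    truth <- list()
    candidates <- vector("list", spec$n_sources)
    mix <- spec$overlap_mix[c("enclosed", "partial", "disjoint")]
    mix[is.na(mix)] <- 0
    for (s_i in seq_len(spec$n_sources)) {
      tag <- sprintf("src%d", s_i)
      kinds <- sample(rep(names(mix), round(mix * n))[seq_len(n)])
      cg <- list(); ct <- list(); ce <- list()
      for (i in seq_len(length(kinds))) {
        kind <- kinds[i]
        if (is.na(kind)) next
        ref_g <- reference$genes[i, ]
        gid <- sprintf("%s_G%04d", tag, i)
        strand <- sample(c("+", "-"), 1)
        if (kind == "enclosed") {
          pad <- max(1L, (ref_g$end - ref_g$start) %/% 10L)
          gs <- ref_g$start + sample(0:pad, 1)
          ge <- ref_g$end - sample(0:pad, 1)
        } else if (kind == "partial") {
          w <- ref_g$end - ref_g$start
          gs <- ref_g$start + w %/% 2L
          ge <- ref_g$end + w   # straddles the right boundary
        } else {
          slot <- slots[[i]]
          gap_end <- slot$start - 200L
          gs <- gap_end - sample(1000:3000, 1)
          ge <- gap_end - 100L
          if (gs <= 0) { gs <- slot$end + 100L; ge <- gs + 1500L }
        }
        cg[[length(cg) + 1]] <- list(
          gene_id = gid, chrom = ref_g$chrom, start = gs, end = ge,
          strand = strand, biotype = "lncRNA", sources = tag)
        tk <- make_transcript(paste0(gid, ".t1"), gid, ref_g$chrom, gs, ge,
                              strand, "lncRNA", tag)
        ct[[length(ct) + 1]] <- tk$transcript
        ce[[length(ce) + 1]] <- tk$exons
        truth[[length(truth) + 1]] <- list(
          source = tag, gene_id = gid, transcript_id = paste0(gid, ".t1"),
          kind = kind,
          gene_fate = c(enclosed = "merged_into", partial = "discarded_partial",
                        disjoint = "added_new")[kind],
          transcript_fate = c(enclosed = "added",
                              partial = "discarded_with_partial_gene",
                              disjoint = "added")[kind])
        if (kind == "enclosed" && with_duplicates) {
          # copy a reference transcript's exon chain under this gene
          ref_tx <- reference$transcripts[reference$transcripts$gene_id == ref_g$gene_id, ][1, ]
          ref_ex <- reference$exons[reference$exons$transcript_id == ref_tx$transcript_id, ]
          did <- paste0(gid, ".dup")
          ct[[length(ct) + 1]] <- list(
            transcript_id = did, gene_id = gid, chrom = ref_tx$chrom,
            start = ref_tx$start, end = ref_tx$end, strand = ref_tx$strand,
            biotype = "lncRNA", source = tag)
          ce[[length(ce) + 1]] <- list(
            transcript_id = rep(did, nrow(ref_ex)), chrom = ref_ex$chrom,
            start = ref_ex$start, end = ref_ex$end, strand = ref_tx$strand)
          truth[[length(truth) + 1]] <- list(
            source = tag, gene_id = gid, transcript_id = did,
            kind = "duplicate_transcript", gene_fate = NA_character_,
            transcript_fate = "duplicate_skipped")
          # the gene record is widened to the ref boundary to hold the copy
          cg[[length(cg)]]$start <- min(cg[[length(cg)]]$start, ref_tx$start)
          cg[[length(cg)]]$end <- max(cg[[length(cg)]]$end, ref_tx$end)
        }
        if (kind == "enclosed" && with_out_of_bounds) {
          # a mis-assigned transcript poking beyond the reference gene
          oid <- paste0(gid, ".oob")
          os <- ref_g$end - 500L
          oe <- ref_g$end + 2000L
          tk <- make_transcript(oid, gid, ref_g$chrom, os, oe, strand,
                                "lncRNA", tag, n_exons = 2L)
          ct[[length(ct) + 1]] <- tk$transcript
          ce[[length(ce) + 1]] <- tk$exons
          truth[[length(truth) + 1]] <- list(
            source = tag, gene_id = gid, transcript_id = oid,
            kind = "out_of_bounds_transcript", gene_fate = NA_character_,
            transcript_fate = "discarded_out_of_bounds")
        }
      }
      candidates[[s_i]] <- annotation_set(
        tag, genes = dplyr::bind_rows(cg),
        transcripts = dplyr::bind_rows(ct), exons = dplyr::bind_rows(ce))
    }
    list(reference = reference, candidates = candidates,
         truth = dplyr::bind_rows(truth))
  })
}

#' Generate a tissue-structured count matrix with planted specific genes
#'
#' Negative-binomial counts. Ubiquitous genes share one mean across all
#' tissues; planted tissue-specific genes have a low baseline plus a
#' strongly elevated mean (50x) in one randomly chosen tissue, recorded in
#' the ground truth.
#'
#' @param spec fixture_spec.
#' @param base_mean mean count of ubiquitous genes (default 100).
#' @param specific_fold fold elevation in the planted tissue (default 50).
#' @param dispersion NB size parameter (default 10).
#' @return list with `counts` (expression_matrix of raw counts) and `truth`
#'   (tibble gene_id, specific, planted_tissue, base_mean).
#' @export
gen_expression <- function(spec, base_mean = 100, specific_fold = 50,
                           dispersion = 10) {
  with_fixture_seed(spec$seed + 1L, {
    n_g <- spec$n_genes
    tissues <- sprintf("tissue%02d", seq_len(spec$n_tissues))
    samples <- paste0(rep(tissues, each = spec$replicates_per_tissue), "_r",
                      rep(seq_len(spec$replicates_per_tissue), spec$n_tissues))
    tissue_of <- rep(tissues, each = spec$replicates_per_tissue)
    n_spec <- round(spec$planted_specific_fraction * n_g)
    specific <- c(rep(TRUE, n_spec), rep(FALSE, n_g - n_spec))
    planted <- ifelse(specific, sample(tissues, n_g, replace = TRUE),
                      NA_character_)
    gene_ids <- sprintf("G%04d", seq_len(n_g))
    mu <- matrix(base_mean, nrow = n_g, ncol = length(samples))
    for (i in which(specific)) {
      mu[i, ] <- base_mean / 20
      mu[i, tissue_of == planted[i]] <- base_mean / 20 * specific_fold
    }
    counts <- matrix(stats::rnbinom(length(mu), size = dispersion, mu = mu),
                     nrow = n_g, dimnames = list(gene_ids, samples))
    gm <- tibble::tibble(gene_id = gene_ids,
                         biotype = sample(c("protein_coding", "lncRNA"), n_g,
                                          replace = TRUE),
                         length = sample(200:5000, n_g, replace = TRUE))
    sm <- tibble::tibble(sample = samples, tissue = tissue_of)
    list(counts = expression_matrix(counts, gm, sm),
         truth = tibble::tibble(gene_id = gene_ids, specific = specific,
                                planted_tissue = planted,
                                base_mean = base_mean))
  })
}

#' Generate a piecewise-constant score track over fixture contigs
#'
#' Random runs with Uniform(0, 1) scores; optionally, designated intervals
#' (e.g. protein-coding exons) are overwritten with high-score runs and
#' others with low-score runs to plant a conservation contrast.
#'
#' @param spec fixture_spec.
#' @param chroms chromosome names to cover.
#' @param chrom_len contig length (default 1e6).
#' @param run_len mean run length in bp (default 500).
#' @param high_intervals,low_intervals optional tibbles (`chrom`, `start`,
#'   `end`) whose bases are overwritten with scores in `[0.8, 1]` /
#'   `[0, 0.2]`.
#' @return score_track.
#' @export
gen_score_track <- function(spec, chroms = "ctgA1", chrom_len = 1e6,
                            run_len = 500, high_intervals = NULL,
                            low_intervals = NULL) {
  with_fixture_seed(spec$seed + 2L, {
    runs <- list()
    for (ch in chroms) {
      n_draw <- ceiling(chrom_len / 50) + 10
      lens <- pmax(50L, as.integer(stats::rexp(n_draw, 1 / run_len)))
      ends <- pmin(chrom_len, cumsum(as.numeric(lens)))
      k <- which(ends >= chrom_len)[1]
      ends <- ends[seq_len(k)]
      starts <- c(0, ends[-k])
      runs[[ch]] <- tibble::tibble(
        chrom = ch, start = as.integer(starts), end = as.integer(ends),
        score = round(stats::runif(k), 4))
    }
    runs <- dplyr::bind_rows(runs)
    overwrite <- function(runs, iv, lo, hi) {
      for (i in seq_len(nrow(iv))) {
        r <- iv[i, ]
        # clip existing runs out of the interval, then insert a new run
        keep <- !(runs$chrom == r$chrom & runs$start < r$end & runs$end > r$start)
        cut <- runs[!keep, ]
        left <- cut[cut$start < r$start, ]
        if (nrow(left)) left$end <- pmin(left$end, r$start)
        right <- cut[cut$end > r$end, ]
        if (nrow(right)) right$start <- pmax(right$start, r$end)
        runs <- dplyr::bind_rows(
          runs[keep, ], left[left$start < left$end, ],
          right[right$start < right$end, ],
          tibble::tibble(chrom = r$chrom, start = r$start, end = r$end,
                         score = round(stats::runif(1, lo, hi), 4)))
      }
      runs
    }
    if (!is.null(high_intervals) && nrow(high_intervals))
      runs <- overwrite(runs, high_intervals, 0.8, 1)
    if (!is.null(low_intervals) && nrow(low_intervals))
      runs <- overwrite(runs, low_intervals, 0, 0.2)
    score_track(runs)
  })
}

#' Generate planted lncRNA/mRNA configurations for the classifier
#'
#' Builds a reference of protein-coding transcripts and candidate lncRNA
#' transcripts planted in known positional configurations — genic
#' (sense/antisense x exonic/intronic x nested/containing/overlapping) and
#' intergenic (divergent/convergent/same_strand at a known gap) — with the
#' intended class recorded per candidate.
#'
#' @param spec fixture_spec (`n_genes` = number of planted configurations).
#' @return list with `candidates` and `reference` (annotation_sets) and
#'   `truth` (tibble: lnc id, partner id, intended type/direction/
#'   location/subtype, gap).
#' @export
gen_classification <- function(spec) {
  with_fixture_seed(spec$seed + 3L, {
    n <- spec$n_genes
    classes <- tibble::tibble(
      type = c(rep("GENIC", 6), rep("INTERGENIC", 3)),
      location = c("exonic", "exonic", "exonic", "intronic", "intronic",
                   "exonic", "divergent", "convergent", "same_strand"),
      subtype = c("nested", "containing", "overlapping", "nested", "nested",
                  "nested", NA, NA, NA),
      sense = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, NA, NA, NA)
    )
    pick <- classes[sample(nrow(classes), n, replace = TRUE), ]
    slot_w <- 400000L
    rg <- list(); rt <- list(); re <- list()
    cg <- list(); ct <- list(); ce <- list()
    truth <- list()
    for (i in seq_len(n)) {
      base <- (i - 1L) * slot_w + 50000L
      p <- pick[i, ]
      m_strand <- sample(c("+", "-"), 1)
      # partner mRNA: 3 exons over a 12-kb span
      ms <- base; me <- base + 12000L
      mid <- sprintf("MRNA%04d", i)
      mgid <- sprintf("PCG%04d", i)
      m_ex <- tibble::tibble(
        transcript_id = mid, chrom = "ctgB1",
        start = c(ms, ms + 5000L, ms + 10000L),
        end = c(ms + 1500L, ms + 6500L, me), strand = m_strand)
      rg[[i]] <- tibble::tibble(gene_id = mgid, chrom = "ctgB1", start = ms,
                                end = me, strand = m_strand,
                                biotype = "protein_coding", sources = "ref")
      rt[[i]] <- tibble::tibble(transcript_id = mid, gene_id = mgid,
                                chrom = "ctgB1", start = ms, end = me,
                                strand = m_strand, biotype = "protein_coding",
                                source = "ref")
      re[[i]] <- m_ex
      lid <- sprintf("LNC%04d", i)
      lgid <- sprintf("LNCG%04d", i)
      gap <- NA_integer_
      if (p$type == "GENIC") {
        l_strand <- if (p$sense) m_strand else setdiff(c("+", "-"), m_strand)
        if (p$subtype == "nested" && p$location == "exonic") {
          ls <- ms + 200L; le <- ms + 1200L          # inside exon 1
          l_ex <- tibble::tibble(transcript_id = lid, chrom = "ctgB1",
                                 start = ls, end = le, strand = l_strand)
        } else if (p$subtype == "nested" && p$location == "intronic") {
          ls <- ms + 2000L; le <- ms + 4000L         # inside intron 1
          l_ex <- tibble::tibble(transcript_id = lid, chrom = "ctgB1",
                                 start = ls, end = le, strand = l_strand)
        } else if (p$subtype == "containing") {
          ls <- ms - 2000L; le <- me + 2000L
          l_ex <- tibble::tibble(transcript_id = lid, chrom = "ctgB1",
                                 start = c(ls, ms + 4800L), end = c(ms + 1000L, le),
                                 strand = l_strand)
        } else {                                      # overlapping
          ls <- ms - 3000L; le <- ms + 1000L
          l_ex <- tibble::tibble(transcript_id = lid, chrom = "ctgB1",
                                 start = ls, end = le, strand = l_strand)
        }
      } else {
        gap <- sample(11000:60000, 1)
        right_of_mrna <- sample(c(TRUE, FALSE), 1)
        ls <- if (right_of_mrna) me + gap else ms - gap - 1500L
        le <- ls + 1500L
        # choose the lnc strand that realizes the requested orientation
        if (p$location == "same_strand") {
          l_strand <- m_strand
        } else if (p$location == "divergent") {
          # left transcript must be on '-': heads meet in the gap
          l_strand <- if (right_of_mrna) {
            if (m_strand == "-") "+" else NA
          } else {
            if (m_strand == "+") "-" else NA
          }
          if (is.na(l_strand)) {
            m_strand <- setdiff(c("+", "-"), m_strand)
            rg[[i]]$strand <- m_strand; rt[[i]]$strand <- m_strand
            re[[i]]$strand <- m_strand
            l_strand <- if (right_of_mrna) "+" else "-"
          }
        } else {  # convergent: left transcript on '+', tails meet
          l_strand <- if (right_of_mrna) {
            if (m_strand == "+") "-" else NA
          } else {
            if (m_strand == "-") "+" else NA
          }
          if (is.na(l_strand)) {
            m_strand <- setdiff(c("+", "-"), m_strand)
            rg[[i]]$strand <- m_strand; rt[[i]]$strand <- m_strand
            re[[i]]$strand <- m_strand
            l_strand <- if (right_of_mrna) "-" else "+"
          }
        }
        l_ex <- tibble::tibble(transcript_id = lid, chrom = "ctgB1",
                               start = ls, end = le, strand = l_strand)
      }
      cg[[i]] <- tibble::tibble(gene_id = lgid, chrom = "ctgB1",
                                start = min(l_ex$start), end = max(l_ex$end),
                                strand = l_ex$strand[1], biotype = "lncRNA",
                                sources = "cand")
      ct[[i]] <- tibble::tibble(transcript_id = lid, gene_id = lgid,
                                chrom = "ctgB1", start = min(l_ex$start),
                                end = max(l_ex$end), strand = l_ex$strand[1],
                                biotype = "lncRNA", source = "cand")
      ce[[i]] <- l_ex
      side <- if (p$type == "INTERGENIC") {
        partner_right <- rt[[i]]$start >= ct[[i]]$end
        if (ct[[i]]$strand == "-") {
          if (partner_right) "upstream" else "downstream"
        } else {
          if (partner_right) "downstream" else "upstream"
        }
      } else NA_character_
      truth[[i]] <- tibble::tibble(
        lnc_transcript_id = lid, partner_transcript_id = mid,
        type = p$type,
        direction = if (p$type == "GENIC") {
          if (ct[[i]]$strand == rt[[i]]$strand) "sense" else "antisense"
        } else side,
        location = p$location,
        subtype = p$subtype, gap = gap)
    }
    list(
      reference = annotation_set("ref", genes = dplyr::bind_rows(rg),
                                 transcripts = dplyr::bind_rows(rt),
                                 exons = dplyr::bind_rows(re)),
      candidates = annotation_set("cand", genes = dplyr::bind_rows(cg),
                                  transcripts = dplyr::bind_rows(ct),
                                  exons = dplyr::bind_rows(ce)),
      truth = dplyr::bind_rows(truth)
    )
  })
}
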