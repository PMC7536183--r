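# Independent brute-force oracles. These deliberately share no code with the
# package implementations they check.

# all-pairs scan over reference genes: overlap class of one candidate gene
oracle_gene_overlap <- function(cand, ref_genes, strand_aware = FALSE) {
  cls <- "NONE"; best <- NA_character_
  best_key <- NULL
  for (i in seq_len(nrow(ref_genes))) {
    r <- ref_genes[i, ]
    if (r$chrom != cand$chrom) next
    if (strand_aware && r$strand != cand$strand) next
    ov <- min(r$end, cand$end) - max(r$start, cand$start)
    if (ov <= 0) next
    if (r$start <= cand$start && cand$end <= r$end) {
      key <- list(-ov, r$end - r$start, r$gene_id)
      better <- is.null(best_key) ||
        key[[1]] < best_key[[1]] ||
        (key[[1]] == best_key[[1]] && key[[2]] < best_key[[2]]) ||
        (key[[1]] == best_key[[1]] && key[[2]] == best_key[[2]] &&
           key[[3]] < best_key[[3]])
      if (cls != "ENCLOSED_OR_FULL" || better) { best <- r$gene_id; best_key <- key }
      cls <- "ENCLOSED_OR_FULL"
    } else if (cls != "ENCLOSED_OR_FULL") {
      cls <- "PARTIAL"
    }
  }
  list(class = cls, best = best)
}

# straight-line implementation of the published TMM recipe
oracle_tmm <- function(counts, logratioTrim = 0.30, sumTrim = 0.05) {
  lib <- colSums(counts)
  f75 <- vapply(seq_len(ncol(counts)),
                function(j) quantile(counts[, j] / lib[j], 0.75, names = FALSE),
                numeric(1))
  ref <- which.min(abs(f75 - mean(f75)))
  one <- function(j) {
    if (j == ref) return(1)
    o <- counts[, j]; r <- counts[, ref]
    keep <- o > 0 & r > 0
    o <- o[keep]; r <- r[keep]
    po <- o / lib[j]; pr <- r / lib[ref]
    M <- log2(po / pr)
    A <- 0.5 * log2(po * pr)
    w <- (lib[j] - o) / (lib[j] * o) + (lib[ref] - r) / (lib[ref] * r)
    n <- length(M)
    loM <- floor(n * logratioTrim) + 1; hiM <- n + 1 - loM
    loA <- floor(n * sumTrim) + 1; hiA <- n + 1 - loA
    keep2 <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    f <- sum(M[keep2] / w[keep2]) / sum(1 / w[keep2])
    2^f
  }
  f <- vapply(seq_len(ncol(counts)), one, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

# per-base expansion of a score track over one interval
oracle_mean_score <- function(chrom, start, end, runs, uncovered = "ignore") {
  bases <- rep(NA_real_, end - start)
  for (i in seq_len(nrow(runs))) {
    r <- runs[i, ]
    if (r$chrom != chrom) next
    lo <- max(r$start, start); hi <- min(r$end, end)
    if (lo < hi) bases[(lo - start + 1):(hi - start)] <- r$score
  }
  if (uncovered == "zero") bases[is.na(bases)] <- 0
  if (all(is.na(bases))) NA_real_ else mean(bases, na.rm = TRUE)
}

# per-base bitmap union of a set of intervals (single chromosome)
oracle_interval_union <- function(starts, ends) {
  if (!length(starts)) return(matrix(integer(), ncol = 2))
  lo <- min(starts)
  bits <- logical(max(ends) - lo)
  for (i in seq_along(starts)) bits[(starts[i] - lo + 1):(ends[i] - lo)] <- TRUE
  r <- rle(bits)
  pos <- c(0L, cumsum(r$lengths))
  out <- cbind(lo + pos[-length(pos)][r$values], lo + pos[-1][r$values])
  out
}

# first-principles positional classifier for one lnc/partner pair
oracle_classify_pair <- function(l, p, lex, pex) {
  overlap <- l$start < p$end && p$start < l$end
  if (overlap) {
    exonic <- FALSE
    for (a in seq_len(nrow(lex))) for (b in seq_len(nrow(pex))) {
      if (lex$start[a] < pex$end[b] && pex$start[b] < lex$end[a]) exonic <- TRUE
    }
    sub <- if (l$start >= p$start && l$end <= p$end) "nested"
    else if (p$start >= l$start && p$end <= l$end) "containing"
    else "overlapping"
    data.frame(type = "GENIC",
               direction = if (l$strand == p$strand) "sense" else "antisense",
               location = if (exonic) "exonic" else "intronic",
               subtype = sub, distance = NA_integer_)
  } else {
    right <- p$start >= l$end
    gap <- if (right) p$start - l$end else l$start - p$end
    side <- if (l$strand == "-") { if (right) "upstream" else "downstream"
    } else { if (right) "downstream" else "upstream" }
    ori <- if (l$strand == p$strand) "same_strand" else {
      left_str <- if (right) l$strand else p$strand
      if (left_str == "-") "divergent" else "convergent"
    }
    data.frame(type = "INTERGENIC", direction = side, location = ori,
               subtype = NA_character_, distance = gap)
  }
}

# brute-force classification of every candidate against every reference
# transcript, with the same window rule
oracle_classify_all <- function(candidates, reference, cfg) {
  out <- list()
  for (i in seq_len(nrow(candidates$transcripts))) {
    l <- candidates$transcripts[i, ]
    lex <- candidates$exons[candidates$exons$transcript_id == l$transcript_id, ]
    rows <- list()
    for (j in seq_len(nrow(reference$transcripts))) {
      p <- reference$transcripts[j, ]
      if (p$chrom != l$chrom || p$transcript_id == l$transcript_id) next
      pex <- reference$exons[reference$exons$transcript_id == p$transcript_id, ]
      r <- oracle_classify_pair(l, p, lex, pex)
      r$lnc_transcript_id <- l$transcript_id
      r$partner_transcript_id <- p$transcript_id
      rows[[length(rows) + 1]] <- r
    }
    if (!length(rows)) next
    rows <- do.call(rbind, rows)
    genic <- rows[rows$type == "GENIC", ]
    inter <- rows[rows$type == "INTERGENIC", ]
    near <- inter[!is.na(inter$distance) & inter$distance <= cfg$window_min, ]
    inter <- if (nrow(near)) near else
      inter[!is.na(inter$distance) & inter$distance <= cfg$window_max, ]
    out[[length(out) + 1]] <- rbind(genic, inter)
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

# tiny helpers shared across test files -------------------------------------

make_counts_em <- function(values, biotype = NULL, length = NULL,
                           tissue = NULL) {
  g <- rownames(values); s <- colnames(values)
  expression_matrix(
    values,
    gene_meta = tibble::tibble(
      gene_id = g,
      biotype = biotype %||% rep("lncRNA", length(g)),
      length = length %||% rep(1000L, length(g))),
    sample_meta = tibble::tibble(
      sample = s, tissue = tissue %||% paste0("t", seq_along(s)))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

sorted_tables <- function(set) {
  list(
    genes = dplyr::arrange(set$genes, .data$gene_id),
    transcripts = dplyr::arrange(set$transcripts, .data$transcript_id),
    exons = dplyr::arrange(set$exons, .data$transcript_id, .data$start)
  )
}

expect_same_annotation <- function(a, b) {
  ta <- sorted_tables(a); tb <- sorted_tables(b)
  expect_equal(as.data.frame(ta$genes), as.data.frame(tb$genes))
  expect_equal(as.data.frame(ta$transcripts), as.data.frame(tb$transcripts))
  expect_equal(as.data.frame(ta$exons), as.data.frame(tb$exons))
}
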