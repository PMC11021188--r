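# Conversion-aware nascent-read analysis (SLAM-seq style).
#
# All genome positions in this module are 1-based, matching SAM/GTF
# directly (R indexing is 1-based; keeping one convention end to end
# avoids off-by-one translation at every boundary). Mismatches are always
# recomputed from the reference FASTA; MD tags, when present, serve only
# as a cross-check. Secondary/supplementary/duplicate alignments are
# excluded up front.

FLAG_PAIRED <- 1L; FLAG_UNMAPPED <- 4L; FLAG_REVERSE <- 16L
FLAG_READ1 <- 64L; FLAG_READ2 <- 128L
FLAG_SECONDARY <- 256L; FLAG_DUP <- 1024L; FLAG_SUPPL <- 2048L

has_flag <- function(flag, bit) bitwAnd(flag, bit) != 0L

# drop secondary, supplementary, duplicate and unmapped records
filter_primary <- function(records) {
  bad <- has_flag(records$flag, FLAG_SECONDARY) |
    has_flag(records$flag, FLAG_SUPPL) |
    has_flag(records$flag, FLAG_DUP) |
    has_flag(records$flag, FLAG_UNMAPPED)
  records[!bad, , drop = FALSE]
}

parse_cigar <- function(cigar) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  list(len = as.integer(sub("[MIDNSHP=X]", "", ops)),
       op = sub("\\d+", "", ops))
}

# Walk one alignment: aligned (reference-consuming match) positions with
# their read bases and qualities. Soft clips consume query only; D/N skip
# reference columns; insertions consume query only.
walk_alignment <- function(pos, cigar, seq, qual) {
  cg <- parse_cigar(cigar)
  qseq <- strsplit(seq, "")[[1]]
  q <- utf8ToInt(qual) - 33L
  rp <- pos; qp <- 1L
  ref_pos <- integer(0); bases <- character(0); quals <- integer(0)
  for (k in seq_along(cg$op)) {
    len <- cg$len[k]
    switch(cg$op[k],
           "M" = , "=" = , "X" = {
             ref_pos <- c(ref_pos, seq.int(rp, rp + len - 1L))
             bases <- c(bases, qseq[seq.int(qp, qp + len - 1L)])
             quals <- c(quals, q[seq.int(qp, qp + len - 1L)])
             rp <- rp + len; qp <- qp + len
           },
           "I" = , "S" = { qp <- qp + len },
           "D" = , "N" = { rp <- rp + len },
           "H" = , "P" = NULL)
  }
  data.frame(pos = ref_pos, base = bases, qual = quals,
             stringsAsFactors = FALSE)
}

#' Build a pileup from aligned records
#'
#' One column per covered reference position: per-base counts, coverage,
#' the variant (most frequent non-reference) allele with its supporting
#' read count, mean base quality of variant-supporting reads and the
#' variant frequency. Soft-clipped and inserted bases are excluded,
#' deletions skip columns. Only primary, mapped alignments contribute.
#'
#' @param records SAM record data.frame (see [read_sam()]); must be from
#'   one sample.
#' @param reference named character vector of chromosome sequences.
#' @return data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `A`, `C`, `G`, `T`, `coverage`, `var`, `var_count`, `var_freq`,
#'   `var_qual`.
#' @export
build_pileup <- function(records, reference) {
  records <- filter_primary(records)
  if (nrow(records) == 0L)
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), A = integer(), C = integer(),
                      G = integer(), T = integer(), coverage = integer(),
                      var = character(), var_count = integer(),
                      var_freq = numeric(), var_qual = numeric()))
  walks <- lapply(seq_len(nrow(records)), function(i) {
    w <- walk_alignment(records$pos[i], records$cigar[i], records$seq[i],
                        records$qual[i])
    w$chrom <- records$rname[i]
    w
  })
  dt <- data.table::rbindlist(walks)
  dt <- dt[dt$base %in% BASES, ]
  agg <- dt[, list(count = .N, qsum = sum(qual)),
            by = c("chrom", "pos", "base")]
  data.table::setorderv(agg, c("chrom", "pos"))
  refsplit <- lapply(reference, function(s) strsplit(s, "")[[1]])
  cols <- agg[, {
    cnt <- stats::setNames(rep(0L, 4L), BASES)
    qs <- stats::setNames(rep(0, 4L), BASES)
    cnt[base] <- count; qs[base] <- qsum
    rb <- refsplit[[chrom[1]]][pos[1]]
    nonref <- setdiff(BASES, rb)
    vc <- cnt[nonref]
    vb <- nonref[order(-vc, nonref)][1L]
    list(ref = rb, A = cnt[["A"]], C = cnt[["C"]], G = cnt[["G"]],
         T = cnt[["T"]], coverage = sum(cnt),
         var = if (cnt[[vb]] > 0L) vb else NA_character_,
         var_count = cnt[[vb]],
         var_freq = cnt[[vb]] / sum(cnt),
         var_qual = if (cnt[[vb]] > 0L) qs[[vb]] / cnt[[vb]] else NA_real_)
  }, by = c("chrom", "pos")]
  as.data.frame(cols)
}

#' Call SNPs from pileup columns with fixed thresholds
#'
#' A column is called iff coverage >= `min_coverage`, variant-supporting
#' reads >= `min_reads2`, mean variant base quality >= `min_avg_qual`,
#' variant frequency >= `min_var_freq`, and the significance of the variant
#' count against a sequencing-error null is <= `max_p`. The significance is
#' a one-sided exact binomial tail P(X >= var_count | coverage, err_null);
#' the upstream tool's exact test statistic is not published, so this is a
#' documented, pluggable approximation.
#'
#' @param columns pileup data.frame from [build_pileup()].
#' @param min_coverage,min_reads2,min_avg_qual,min_var_freq,max_p the five
#'   published thresholds (defaults 20, 5, 15, 0.25, 0.01).
#' @param err_null per-base error probability of the null model.
#' @return data.frame of called SNPs: `chrom`, `pos`, `ref`, `alt`,
#'   `freq`, `var_count`, `coverage`, `p`.
#' @export
call_snps <- function(columns, min_coverage = 20L, min_reads2 = 5L,
                      min_avg_qual = 15, min_var_freq = 0.25,
                      max_p = 0.01, err_null = 0.01) {
  keep <- !is.na(columns$var) &
    columns$coverage >= min_coverage &
    columns$var_count >= min_reads2 &
    columns$var_qual >= min_avg_qual &
    columns$var_freq >= min_var_freq
  cand <- columns[keep, , drop = FALSE]
  if (nrow(cand) == 0L)
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      freq = numeric(), var_count = integer(),
                      coverage = integer(), p = numeric()))
  p <- stats::pbinom(cand$var_count - 1L, cand$coverage, err_null,
                     lower.tail = FALSE)
  cand <- cand[p <= max_p, , drop = FALSE]
  p <- p[p <= max_p]
  out <- data.frame(chrom = cand$chrom, pos = cand$pos, ref = cand$ref,
                    alt = cand$var, freq = cand$var_freq,
                    var_count = cand$var_count, coverage = cand$coverage,
                    p = p, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Union SNP consensus across control samples
#'
#' Natural SNPs are cataloged from unconverted (alkylation-minus) control
#' samples; the consensus is the set union across samples keyed by
#' (chrom, pos, alt).
#'
#' @param per_sample_snps list of SNP data.frames from [call_snps()].
#' @return Deduplicated SNP data.frame sorted by chrom, pos.
#' @export
consensus_snps <- function(per_sample_snps) {
  if (length(per_sample_snps) < 1L) stop("at least one sample required")
  all <- do.call(rbind, lapply(per_sample_snps, function(s)
    s[, c("chrom", "pos", "ref", "alt")]))
  out <- all[!duplicated(all[, c("chrom", "pos", "alt")]), , drop = FALSE]
  out <- out[order(out$chrom, out$pos, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify fragments as labeled or unlabeled by T->C conversions
#'
#' Per fragment (read pair), the transcript strand is inferred from the
#' mate flags (read 2 carries the transcript-sense sequence under RF
#' strandness). Candidate conversions are genomic T->C mismatches for
#' plus-sense fragments and A->G for minus-sense fragments, recomputed from
#' the reference. Positions in the SNP consensus are masked regardless of
#' allele; bases below `min_base_quality` are ignored; positions covered by
#' both mates are counted once. A fragment is labeled iff at least one
#' conversion survives. Orphan mates are classified from the single read
#' and flagged.
#'
#' @param records SAM record data.frame.
#' @param reference named character vector of chromosome sequences.
#' @param snps SNP consensus data.frame (`chrom`, `pos`); may be empty.
#' @param min_base_quality minimum Phred quality for a conversion to count
#'   (default 20).
#' @return data.frame, one row per fragment: `qname`, `strand`,
#'   `n_conversions`, `labeled`, `orphan`; conversion genome positions are
#'   attached as a list column `positions`.
#' @export
classify_fragments <- function(records, reference, snps = NULL,
                               min_base_quality = 20L) {
  records <- filter_primary(records)
  snp_key <- if (!is.null(snps) && nrow(snps))
    paste(snps$chrom, snps$pos) else character(0)
  refsplit <- lapply(reference, function(s) strsplit(s, "")[[1]])
  groups <- split(seq_len(nrow(records)), records$qname)
  groups <- groups[unique(records$qname)]  # keep input order
  out <- vector("list", length(groups))
  i <- 0L
  for (qn in names(groups)) {
    grp <- records[groups[[qn]], , drop = FALSE]
    r2 <- grp[has_flag(grp$flag, FLAG_READ2), , drop = FALSE]
    orphan <- nrow(grp) < 2L
    if (nrow(r2) >= 1L) {
      sense <- if (has_flag(r2$flag[1], FLAG_REVERSE)) "-" else "+"
    } else {
      # only read 1 present: read 1 is antisense to the transcript
      sense <- if (has_flag(grp$flag[1], FLAG_REVERSE)) "+" else "-"
    }
    from <- if (sense == "+") "T" else "A"
    to <- if (sense == "+") "C" else "G"
    walks <- lapply(seq_len(nrow(grp)), function(k) {
      w <- walk_alignment(grp$pos[k], grp$cigar[k], grp$seq[k],
                          grp$qual[k])
      w$chrom <- grp$rname[k]
      w
    })
    w <- do.call(rbind, walks)
    conv <- w[w$qual >= min_base_quality &
                refsplit_base(refsplit, w$chrom, w$pos) == from &
                w$base == to, , drop = FALSE]
    conv <- conv[!(paste(conv$chrom, conv$pos) %in% snp_key), ,
                 drop = FALSE]
    upos <- unique(paste(conv$chrom, conv$pos))
    i <- i + 1L
    out[[i]] <- list(qname = qn, strand = sense,
                     n_conversions = length(upos),
                     labeled = length(upos) >= 1L, orphan = orphan,
                     positions = sort(unique(conv$pos)))
  }
  res <- data.frame(
    qname = vapply(out, `[[`, character(1), "qname"),
    strand = vapply(out, `[[`, character(1), "strand"),
    n_conversions = vapply(out, `[[`, integer(1), "n_conversions"),
    labeled = vapply(out, `[[`, logical(1), "labeled"),
    orphan = vapply(out, `[[`, logical(1), "orphan"),
    stringsAsFactors = FALSE)
  res$positions <- lapply(out, `[[`, "positions")
  res
}

refsplit_base <- function(refsplit, chrom, pos) {
  vapply(seq_along(pos), function(i) refsplit[[chrom[i]]][pos[i]],
         character(1))
}

#' Count fragments per gene (stranded, fragment-level)
#'
#' Re-implementation of paired-end exon counting as interval arithmetic: a
#' fragment is assigned to a gene iff both mates are mapped (when
#' `require_both_mapped`), the union of its aligned blocks overlaps the
#' gene's exon union by at least `min_overlap` bases, and the fragment's
#' inferred transcript strand matches the gene strand (reverse-stranded
#' library rule). Fragments assignable to more than one gene are discarded
#' as ambiguous.
#'
#' @param records SAM record data.frame.
#' @param gene_models exon table from [gene_model_table()].
#' @param min_overlap minimum fragment/exon-union overlap in nt
#'   (default 10).
#' @param strandedness `"reverse"` (default) or `"none"`.
#' @param require_both_mapped drop orphan fragments (default TRUE).
#' @return Named integer vector of counts over all genes in `gene_models`,
#'   with attributes `n_ambiguous` and `n_unassigned`.
#' @export
count_labeled <- function(records, gene_models, min_overlap = 10L,
                          strandedness = c("reverse", "none"),
                          require_both_mapped = TRUE) {
  strandedness <- match.arg(strandedness)
  records <- filter_primary(records)
  gids <- unique(gene_models$gene_id)
  exon_union <- lapply(gids, function(g) gene_exon_union(gene_models, g))
  names(exon_union) <- gids
  gchrom <- vapply(gids, function(g)
    gene_models$chrom[match(g, gene_models$gene_id)], character(1))
  gstrand <- vapply(gids, function(g)
    gene_models$strand[match(g, gene_models$gene_id)], character(1))
  counts <- stats::setNames(integer(length(gids)), gids)
  n_ambiguous <- 0L; n_unassigned <- 0L
  groups <- split(seq_len(nrow(records)), records$qname)
  for (qn in names(groups)) {
    grp <- records[groups[[qn]], , drop = FALSE]
    if (require_both_mapped && nrow(grp) < 2L) { next }
    # fragment aligned-block union and transcript strand
    pos <- unique(unlist(lapply(seq_len(nrow(grp)), function(k)
      walk_alignment(grp$pos[k], grp$cigar[k], grp$seq[k],
                     grp$qual[k])$pos)))
    chrom <- grp$rname[1]
    r2 <- grp[has_flag(grp$flag, FLAG_READ2), , drop = FALSE]
    sense <- if (nrow(r2) >= 1L) {
      if (has_flag(r2$flag[1], FLAG_REVERSE)) "-" else "+"
    } else if (has_flag(grp$flag[1], FLAG_REVERSE)) "+" else "-"
    hits <- character(0)
    for (g in gids) {
      if (gchrom[[g]] != chrom) next
      if (strandedness == "reverse" && gstrand[[g]] != sense) next
      ov <- sum(pos %in% exon_union[[g]])
      if (ov >= min_overlap) hits <- c(hits, g)
    }
    if (length(hits) == 1L) counts[hits] <- counts[hits] + 1L
    else if (length(hits) > 1L) n_ambiguous <- n_ambiguous + 1L
    else n_unassigned <- n_unassigned + 1L
  }
  attr(counts, "n_ambiguous") <- n_ambiguous
  attr(counts, "n_unassigned") <- n_unassigned
  counts
}

#' Flag non-expressed genes across samples
#'
#' A gene is flagged as non-expressed (background group) when its raw
#' counts sum to fewer than `min_total` reads across all samples.
#'
#' @param count_matrix numeric matrix, genes x samples (or a list of named
#'   count vectors, which is column-bound).
#' @param min_total threshold (default 10; a total of exactly 10 is NOT
#'   flagged).
#' @return Named logical vector.
#' @export
flag_nonexpressed <- function(count_matrix, min_total = 10L) {
  if (is.list(count_matrix) && !is.matrix(count_matrix))
    count_matrix <- do.call(cbind, count_matrix)
  rowSums(count_matrix) < min_total
}

#' Chromosome-level gene-set enrichment
#'
#' For each chromosome: enrichment ratio = (fraction of the gene set on the
#' chromosome) / (fraction of all genes on the chromosome); significance is
#' the upper-tail hypergeometric probability P(X >= k) of drawing k set
#' genes from the chromosome's K genes in n draws out of N, corrected
#' across chromosomes by Benjamini-Hochberg.
#'
#' @param gene_set character vector of gene ids (must be a subset of the
#'   universe).
#' @param universe named character vector mapping gene id -> chromosome.
#' @return data.frame per chromosome: `chrom`, `K` (universe genes), `k`
#'   (set genes), `ratio`, `p`, `p_adj`.
#' @export
chrom_enrichment <- function(gene_set, universe) {
  if (!all(gene_set %in% names(universe)))
    stop("gene_set must be a subset of the universe")
  N <- length(universe); n <- length(gene_set)
  chroms <- sort(unique(universe))
  rows <- lapply(chroms, function(ch) {
    K <- sum(universe == ch)
    k <- sum(universe[gene_set] == ch)
    ratio <- (k / n) / (K / N)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(chrom = ch, K = K, k = k, ratio = ratio, p = p)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}
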