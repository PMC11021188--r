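# Synthetic aligned read sets for conversion-aware nascent-transcript
# analysis: paired-end, reverse-stranded (RF) fragments with planted
# T->C conversions (transcript sense), genomic SNP alleles, and sequencing
# errors, emitted as minimal valid SAM plus complete ground truth.
#
# SAM dialect: @HD/@SQ header, primary alignments only, mate flags set,
# MD/NM tags emitted, M-only CIGARs. RF strandness: read 2 carries the
# transcript-sense sequence (read 2 maps forward on plus-strand genes).

BASES <- c("A", "C", "G", "T")

#' Generate a random reference genome
#'
#' @param chrom_lengths named integer vector (chromosome -> length in bp).
#' @param seed integer seed.
#' @return Named character vector of uppercase sequences.
#' @export
gen_reference <- function(chrom_lengths, seed = 1L) {
  set.seed(as.integer(seed))
  vapply(chrom_lengths, function(n)
    paste(sample(BASES, n, replace = TRUE), collapse = ""), character(1))
}

#' Build a simple gene-model table
#'
#' One row per exon: `gene_id`, `chrom`, `strand`, `start`, `end`
#' (1-based, inclusive, as in GTF).
#'
#' @param genes list of `list(gene_id, chrom, strand, exons)` where `exons`
#'   is a 2-column matrix of start/end pairs.
#' @return Exon data.frame.
#' @export
gene_model_table <- function(genes) {
  do.call(rbind, lapply(genes, function(g) {
    ex <- g$exons
    data.frame(gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
               start = as.integer(ex[, 1]), end = as.integer(ex[, 2]),
               stringsAsFactors = FALSE)
  }))
}

# exon-union positions of one gene, as a sorted integer vector
gene_exon_union <- function(gene_models, gid) {
  ex <- gene_models[gene_models$gene_id == gid, , drop = FALSE]
  sort(unique(unlist(mapply(function(s, e)
    if (e >= s) seq.int(s, e) else integer(0),
    ex$start, ex$end, SIMPLIFY = FALSE))))
}

revcomp <- function(s) {
  chartr("ACGTacgt", "TGCAtgca",
         vapply(s, function(x) paste(rev(strsplit(x, "")[[1]]),
                                     collapse = ""), character(1),
                USE.NAMES = FALSE))
}

phred_char <- function(q) intToUtf8(q + 33L, multiple = FALSE)

# MD tag for an M-only alignment: runs of matches punctuated by ref bases
md_tag <- function(ref_bases, read_bases) {
  n <- length(ref_bases)
  out <- character(0)
  run <- 0L
  for (i in seq_len(n)) {
    if (ref_bases[i] == read_bases[i]) run <- run + 1L
    else {
      out <- c(out, as.character(run), ref_bases[i])
      run <- 0L
    }
  }
  paste(c(out, as.character(run)), collapse = "")
}

#' Generate a paired-end RF-stranded read set with planted conversions
#'
#' Fragments are drawn uniformly across genes, placed within single exons
#' (M-only CIGARs). Each fragment is labeled (nascent) with probability
#' `p_label`; in labeled fragments every transcript-sense uridine converts
#' independently with probability `p_conv` (genomic T->C on plus-strand
#' genes, A->G on minus-strand genes). SNP alternative alleles are planted
#' in ALL fragments regardless of label. Sequencing errors hit each read
#' base independently with probability `err` (random different base, random
#' quality 10-30); all other bases get quality 37.
#'
#' @param gene_models exon table from [gene_model_table()].
#' @param reference named character vector from [gen_reference()].
#' @param p_label fraction of labeled (nascent) fragments.
#' @param p_conv per-uridine conversion probability in labeled fragments.
#' @param snps data.frame with `chrom`, `pos` (1-based), `alt`; may be
#'   empty.
#' @param err per-base sequencing error rate.
#' @param n_fragments number of fragments.
#' @param read_length mate length in bp (clipped to the fragment).
#' @param frag_range fragment length range (uniform draw, clipped to the
#'   exon).
#' @param seed integer seed; everything is deterministic given it.
#' @return List: `sam` (character vector of SAM lines), `records` (parsed
#'   data.frame, same dialect as [read_sam()]), `reference`, `gene_models`,
#'   and `truth` (per fragment: qname, gene, chrom, strand, start, end,
#'   labeled flag, conversion positions, SNP positions covered, per-read
#'   error positions; plus the planted `snps` and the seed).
#' @export
gen_read_set <- function(gene_models, reference, p_label = 0.5,
                         p_conv = 0.1, snps = NULL, err = 0.001,
                         n_fragments = 1000L, read_length = 60L,
                         frag_range = c(80L, 160L), seed = 1L) {
  stopifnot(p_label >= 0, p_label <= 1, p_conv >= 0, p_conv <= 1,
            err >= 0, err <= 1)
  gids <- unique(gene_models$gene_id)
  for (g in gids)
    if (length(gene_exon_union(gene_models, g)) == 0L)
      stop("gene with zero exonic length: ", g)
  if (is.null(snps))
    snps <- data.frame(chrom = character(), pos = integer(),
                       alt = character())
  set.seed(as.integer(seed))

  refsplit <- lapply(reference, function(s) strsplit(s, "")[[1]])
  exons_by_gene <- lapply(gids, function(g) {
    ex <- gene_models[gene_models$gene_id == g, , drop = FALSE]
    ex[order(ex$start), , drop = FALSE]
  })
  names(exons_by_gene) <- gids

  sam_records <- vector("list", 2L * n_fragments)
  truth_rows <- vector("list", n_fragments)
  for (fi in seq_len(n_fragments)) {
    gid <- sample(gids, 1L)
    ex <- exons_by_gene[[gid]]
    w <- ex$end - ex$start + 1L
    ei <- sample.int(nrow(ex), 1L, prob = w)
    exlen <- w[ei]
    flen <- min(exlen,
                sample(seq.int(frag_range[1], frag_range[2]), 1L))
    s <- ex$start[ei] + sample.int(exlen - flen + 1L, 1L) - 1L
    e <- s + flen - 1L
    chrom <- ex$chrom[ei]
    strand <- ex$strand[ei]
    fragseq <- refsplit[[chrom]][s:e]

    # plant SNP alleles (all fragments)
    snp_here <- snps[snps$chrom == chrom & snps$pos >= s & snps$pos <= e, ,
                     drop = FALSE]
    if (nrow(snp_here))
      fragseq[snp_here$pos - s + 1L] <- snp_here$alt

    # plant conversions on transcript-sense uridines of labeled fragments
    labeled <- stats::runif(1) < p_label
    conv_pos <- integer(0)
    if (labeled && p_conv > 0) {
      u_base <- if (strand == "+") "T" else "A"
      u_new <- if (strand == "+") "C" else "G"
      upos <- which(fragseq == u_base)
      if (length(upos)) {
        hit <- upos[stats::runif(length(upos)) < p_conv]
        fragseq[hit] <- u_new
        conv_pos <- s + hit - 1L
      }
    }

    rl <- min(read_length, flen)
    # left/right mate genomic sequences (SAM SEQ is genome-forward)
    left_seq <- fragseq[seq_len(rl)]
    right_seq <- fragseq[seq.int(flen - rl + 1L, flen)]
    left_pos <- s
    right_pos <- e - rl + 1L

    # sequencing errors, independent per read
    err_left <- integer(0); err_right <- integer(0)
    qual_left <- rep(37L, rl); qual_right <- rep(37L, rl)
    if (err > 0) {
      hit <- which(stats::runif(rl) < err)
      for (i in hit) {
        left_seq[i] <- sample(setdiff(BASES, left_seq[i]), 1L)
        qual_left[i] <- sample(10:30, 1L)
      }
      err_left <- left_pos + hit - 1L
      hit <- which(stats::runif(rl) < err)
      for (i in hit) {
        right_seq[i] <- sample(setdiff(BASES, right_seq[i]), 1L)
        qual_right[i] <- sample(10:30, 1L)
      }
      err_right <- right_pos + hit - 1L
    }

    # RF strandness: read 2 is transcript-sense. Plus-strand gene: left
    # mate forward = read2 (163/83); minus-strand gene: left mate forward
    # = read1 (99/147).
    if (strand == "+") {
      flag_left <- 163L; flag_right <- 83L
      qn_left <- 2L; qn_right <- 1L
    } else {
      flag_left <- 99L; flag_right <- 147L
      qn_left <- 1L; qn_right <- 2L
    }
    qname <- sprintf("frag%06d", fi)
    ref_left <- refsplit[[chrom]][left_pos:(left_pos + rl - 1L)]
    ref_right <- refsplit[[chrom]][right_pos:(right_pos + rl - 1L)]
    tlen <- flen
    mk <- function(flag, pos, seqb, qual, refb, mate_pos, tl, readno) {
      list(qname = qname, flag = flag, rname = chrom, pos = pos,
           mapq = 60L, cigar = sprintf("%dM", rl), rnext = "=",
           pnext = mate_pos, tlen = tl,
           seq = paste(seqb, collapse = ""),
           qual = phred_char(qual),
           nm = sum(seqb != refb), md = md_tag(refb, seqb),
           read = readno)
    }
    sam_records[[2L * fi - 1L]] <-
      mk(flag_left, left_pos, left_seq, qual_left, ref_left, right_pos,
         tlen, qn_left)
    sam_records[[2L * fi]] <-
      mk(flag_right, right_pos, right_seq, qual_right, ref_right, left_pos,
         -tlen, qn_right)
    truth_rows[[fi]] <- list(
      qname = qname, gene = gid, chrom = chrom, strand = strand,
      start = s, end = e, labeled = labeled, conversions = conv_pos,
      snp_positions = if (nrow(snp_here)) snp_here$pos else integer(0),
      errors_left = err_left, errors_right = err_right)
  }

  records <- data.frame(
    qname = vapply(sam_records, `[[`, character(1), "qname"),
    flag = vapply(sam_records, `[[`, integer(1), "flag"),
    rname = vapply(sam_records, `[[`, character(1), "rname"),
    pos = vapply(sam_records, `[[`, integer(1), "pos"),
    mapq = vapply(sam_records, `[[`, integer(1), "mapq"),
    cigar = vapply(sam_records, `[[`, character(1), "cigar"),
    rnext = vapply(sam_records, `[[`, character(1), "rnext"),
    pnext = vapply(sam_records, `[[`, integer(1), "pnext"),
    tlen = vapply(sam_records, `[[`, integer(1), "tlen"),
    seq = vapply(sam_records, `[[`, character(1), "seq"),
    qual = vapply(sam_records, `[[`, character(1), "qual"),
    nm = vapply(sam_records, `[[`, integer(1), "nm"),
    md = vapply(sam_records, `[[`, character(1), "md"),
    stringsAsFactors = FALSE)

  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(reference),
                      nchar(reference)))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s\tNM:i:%d\tMD:Z:%s",
                  records$qname, records$flag, records$rname, records$pos,
                  records$mapq, records$cigar, records$rnext, records$pnext,
                  records$tlen, records$seq, records$qual, records$nm,
                  records$md)
  list(sam = c(header, body), records = records, reference = reference,
       gene_models = gene_models,
       truth = list(fragments = truth_rows, snps = snps,
                    p_label = p_label, p_conv = p_conv, err = err,
                    seed = as.integer(seed)))
}
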