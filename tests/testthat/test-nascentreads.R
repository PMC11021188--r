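# Pileup construction, SNP calling, conversion-aware fragment
# classification, fragment counting and chromosome enrichment.

test_that("alignment walking handles crafted CIGARs", {
  # reference positions covered by 3S5M2I4M1D3M starting at pos 11:
  # M blocks: 11-15, 16-19 (after insertion), deletion skips 20, 21-23
  r <- make_record("q1", 0L, "chr1", 11L, "3S5M2I4M1D3M",
                   seq = paste(rep("A", 17), collapse = ""))
  w <- txbodies:::walk_alignment(r$pos, r$cigar, r$seq, r$qual)
  expect_equal(w$pos, c(11:15, 16:19, 21:23))
  # query indexing: soft clip consumes query, insertion consumes query
  expect_equal(nrow(w), 12L)

  # hand-enumerated oracle on a mixed alignment with known bases
  r2 <- make_record("q2", 0L, "chr1", 5L, "2M1I3M",
                    seq = "ACGTTA", qual_str = "IIIIII")
  w2 <- txbodies:::walk_alignment(r2$pos, r2$cigar, r2$seq, r2$qual)
  expect_equal(w2$pos, c(5, 6, 7, 8, 9))
  expect_equal(w2$base, c("A", "C", "T", "T", "A"))
  expect_equal(w2$qual, rep(40L, 5))
})

test_that("build_pileup counts bases per column", {
  ref <- c(chr1 = "AAAAAAAAAATAAAA")  # T at position 11
  recs <- rbind(
    make_record("a", 0L, "chr1", 10L, "3M", "ATA"),
    make_record("b", 0L, "chr1", 11L, "2M", "TA"),
    make_record("c", 0L, "chr1", 11L, "1M", "C"))
  pu <- build_pileup(recs, ref)
  col <- pu[pu$pos == 11, ]
  expect_equal(col$coverage, 3L)
  expect_equal(col$ref, "T")
  expect_equal(col$var, "C")
  expect_equal(col$var_count, 1L)
  expect_equal(col$var_freq, 1 / 3, tolerance = 1e-12)
  # positions with no coverage emit no column
  expect_false(any(pu$pos == 14))
  # secondary/duplicate records excluded
  recs2 <- rbind(recs, make_record("d", 256L, "chr1", 11L, "1M", "C"))
  expect_equal(build_pileup(recs2, ref)[pu$pos == 11, ]$coverage, 3L)
})

test_that("call_snps applies the five thresholds exactly", {
  col <- function(cov, var_count, qual, freq = var_count / cov)
    data.frame(chrom = "chr1", pos = 1L, ref = "A", A = cov - var_count,
               C = var_count, G = 0L, T = 0L, coverage = cov, var = "C",
               var_count = var_count, var_freq = freq, var_qual = qual)
  # coverage boundary: 19 fails, 20 passes
  expect_equal(nrow(call_snps(col(19, 10, 30))), 0L)
  expect_equal(nrow(call_snps(col(20, 10, 30))), 1L)
  # variant-read boundary: 4 fails, 5 passes
  expect_equal(nrow(call_snps(col(20, 4, 30, freq = 0.3))), 0L)
  expect_equal(nrow(call_snps(col(20, 5, 30))), 1L)
  # quality boundary: 14.9 fails, 15 passes
  expect_equal(nrow(call_snps(col(40, 20, 14.9))), 0L)
  expect_equal(nrow(call_snps(col(40, 20, 15))), 1L)
  # frequency boundary: 0.24 fails, 0.25 passes
  expect_equal(nrow(call_snps(col(100, 24, 30))), 0L)
  expect_equal(nrow(call_snps(col(100, 25, 30))), 1L)
  # significance: variant count consistent with a 1% error null fails
  expect_equal(nrow(call_snps(col(2000, 500, 30, freq = 0.25))), 1L)
  p_marginal <- stats::pbinom(4, 20, 0.01, lower.tail = FALSE)
  expect_equal(call_snps(col(20, 5, 30))$p, p_marginal, tolerance = 1e-12)

  # decision matches a direct re-evaluation of the 5 thresholds across a
  # random sweep
  set.seed(9)
  for (i in 1:100) {
    cov <- sample(10:60, 1); vc <- sample(1:cov, 1)
    q <- stats::runif(1, 5, 40)
    cc <- col(cov, vc, q)
    called <- nrow(call_snps(cc)) == 1L
    oracle <- cov >= 20 && vc >= 5 && q >= 15 && vc / cov >= 0.25 &&
      stats::pbinom(vc - 1, cov, 0.01, lower.tail = FALSE) <= 0.01
    expect_identical(called, oracle)
  }
})

test_that("consensus_snps is a union keyed by chrom/pos/alt", {
  a <- data.frame(chrom = "chr1", pos = 10L, ref = "A", alt = "C")
  b <- data.frame(chrom = "chr1", pos = 20L, ref = "G", alt = "T")
  u <- consensus_snps(list(a, b))
  expect_equal(nrow(u), 2L)
  expect_equal(nrow(consensus_snps(list(a, a))), 1L)
  expect_error(consensus_snps(list()), "at least one")

  # four unconverted control samples: all planted SNPs recovered, no
  # conversion-like false calls when conversion rate is zero
  fx <- fix_genome()
  calls <- lapply(1:4, function(i) {
    rs <- gen_read_set(fx$gm, fx$ref, p_label = 0, p_conv = 0,
                       snps = fx$snps, err = 0.001, n_fragments = 600,
                       seed = 40 + i)
    call_snps(build_pileup(rs$records, fx$ref))
  })
  cons <- consensus_snps(calls)
  expect_true(all(paste(fx$snps$chrom, fx$snps$pos, fx$snps$alt) %in%
                    paste(cons$chrom, cons$pos, cons$alt)))
  expect_equal(nrow(cons), nrow(fx$snps))
})

test_that("classify_fragments applies strand, SNP and quality rules", {
  ref <- c(chr1 = paste(rep("T", 40), collapse = ""))
  # plus-sense pair (read2 forward): one T->C at pos 5, quality 37
  seqs <- function(s) paste(rep("T", 20), collapse = "")
  r2 <- make_record("f1", 163L, "chr1", 1L, "20M",
                    paste0("TTTT", "C", strrep("T", 15)))
  r1 <- make_record("f1", 83L, "chr1", 21L, "20M", strrep("T", 20))
  cl <- classify_fragments(rbind(r2, r1), ref, snps = NULL)
  expect_true(cl$labeled)
  expect_equal(cl$n_conversions, 1L)
  expect_equal(cl$strand, "+")
  expect_equal(cl$positions[[1]], 5L)

  # same mismatch at a consensus SNP position -> unlabeled
  cl2 <- classify_fragments(rbind(r2, r1), ref,
                            snps = data.frame(chrom = "chr1", pos = 5L))
  expect_false(cl2$labeled)

  # zero mismatches -> unlabeled
  clean2 <- make_record("f2", 163L, "chr1", 1L, "20M", strrep("T", 20))
  clean1 <- make_record("f2", 83L, "chr1", 21L, "20M", strrep("T", 20))
  expect_false(classify_fragments(rbind(clean2, clean1), ref)$labeled)

  # low-quality conversion ignored
  lowq <- make_record("f3", 163L, "chr1", 1L, "20M",
                      paste0("TTTT", "C", strrep("T", 15)),
                      qual_str = paste0("IIII", "+", strrep("I", 15)))
  low1 <- make_record("f3", 83L, "chr1", 21L, "20M", strrep("T", 20))
  expect_false(classify_fragments(rbind(lowq, low1), ref,
                                  min_base_quality = 20L)$labeled)

  # minus-sense fragment: A->G counts, T->C does not
  refm <- c(chr1 = paste(rep("A", 40), collapse = ""))
  m1 <- make_record("f4", 99L, "chr1", 1L, "20M",
                    paste0("AAA", "G", strrep("A", 16)))
  m2 <- make_record("f4", 147L, "chr1", 21L, "20M", strrep("A", 20))
  clm <- classify_fragments(rbind(m1, m2), refm)
  expect_equal(clm$strand, "-")
  expect_true(clm$labeled)

  # overlapping mates: the same conversion position counts once
  o2 <- make_record("f5", 163L, "chr1", 1L, "20M",
                    paste0("TTTT", "C", strrep("T", 15)))
  o1 <- make_record("f5", 83L, "chr1", 3L, "20M",
                    paste0("TT", "C", strrep("T", 17)))
  clo <- classify_fragments(rbind(o2, o1), ref)
  expect_equal(clo$n_conversions, 1L)

  # orphan mate classified from the single read, flagged
  orph <- classify_fragments(r2, ref)
  expect_true(orph$orphan)
  expect_equal(orph$strand, "+")
})

test_that("SNP-set and quality monotonicity hold", {
  fx <- fix_genome()
  rs <- gen_read_set(fx$gm, fx$ref, p_label = 0.5, p_conv = 0.15,
                     snps = fx$snps, err = 0.005, n_fragments = 300,
                     seed = 77)
  n_labeled <- function(snps, q)
    sum(classify_fragments(rs$records, fx$ref, snps = snps,
                           min_base_quality = q)$labeled)
  base <- n_labeled(NULL, 20L)
  # enlarging the SNP consensus never increases labeled fragments
  grown <- rbind(fx$snps[, c("chrom", "pos")],
                 data.frame(chrom = "chr1", pos = c(150L, 800L, 2200L)))
  expect_lte(n_labeled(fx$snps, 20L), base)
  expect_lte(n_labeled(grown, 20L), n_labeled(fx$snps, 20L))
  # raising min_base_quality never increases labeled fragments
  qs <- c(2L, 20L, 35L, 40L)
  counts <- vapply(qs, function(q) n_labeled(fx$snps, q), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("strand symmetry: reverse-complementing the world preserves verdicts", {
  fx <- fix_genome(chr_len = 2000L)
  gm <- gene_model_table(list(
    list(gene_id = "gA", chrom = "chr1", strand = "+",
         exons = rbind(c(101L, 900L)))))
  rs <- gen_read_set(gm, fx$ref, p_label = 0.5, p_conv = 0.2, snps = NULL,
                     err = 0, n_fragments = 150, seed = 10)
  cl <- classify_fragments(rs$records, fx$ref)

  # mirror: reverse-complement the reference and remap all alignments
  L <- nchar(fx$ref[["chr1"]])
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  ref_rc <- c(chr1 = rc(fx$ref[["chr1"]]))
  recs <- rs$records
  rl <- nchar(recs$seq)
  recs$pos <- L - (recs$pos + rl - 1L) + 1L
  recs$seq <- vapply(recs$seq, rc, character(1), USE.NAMES = FALSE)
  recs$qual <- vapply(recs$qual, function(q)
    paste(rev(strsplit(q, "")[[1]]), collapse = ""), character(1),
    USE.NAMES = FALSE)
  # flip orientation bits for read and mate
  recs$flag <- bitwXor(recs$flag, 16L + 32L)
  cl_rc <- classify_fragments(recs, ref_rc)
  ord <- match(cl$qname, cl_rc$qname)
  expect_equal(cl$labeled, cl_rc$labeled[ord])
  expect_equal(cl$n_conversions, cl_rc$n_conversions[ord])
})

test_that("count_labeled matches the overlap and strand rules", {
  ref <- c(chr1 = paste(rep("A", 600), collapse = ""))
  gm <- gene_model_table(list(
    list(gene_id = "gP", chrom = "chr1", strand = "+",
         exons = rbind(c(101L, 200L))),
    list(gene_id = "gM", chrom = "chr1", strand = "-",
         exons = rbind(c(301L, 400L)))))

  pair <- function(qn, left_pos, right_pos, rl, plus_sense = TRUE) {
    fl <- if (plus_sense) c(163L, 83L) else c(99L, 147L)
    rbind(make_record(qn, fl[1], "chr1", left_pos, sprintf("%dM", rl),
                      strrep("A", rl)),
          make_record(qn, fl[2], "chr1", right_pos, sprintf("%dM", rl),
                      strrep("A", rl)))
  }

  # fragment overlapping the exon by 9 nt -> not counted; 10 nt -> counted
  ov9 <- pair("o9", 72L, 82L, 20L)    # covers 72..101 => overlap 1? no:
  # right mate 82..101 -> fragment spans 72..101, exon 101..200 overlap 1
  # craft precisely: left read ends at 109 -> overlap 9; at 110 -> 10
  ov9 <- pair("o9", 90L, 90L, 20L)    # spans 90..109, overlap 9
  ov10 <- pair("o10", 91L, 91L, 20L)  # spans 91..110, overlap 10
  expect_equal(unname(count_labeled(ov9, gm)["gP"]), 0L)
  expect_equal(unname(count_labeled(ov10, gm)["gP"]), 1L)

  # wrong strand not counted under the reverse rule
  wrong <- pair("w", 120L, 140L, 20L, plus_sense = FALSE)
  expect_equal(unname(count_labeled(wrong, gm)["gP"]), 0L)
  right <- pair("r", 320L, 340L, 20L, plus_sense = FALSE)
  expect_equal(unname(count_labeled(right, gm)["gM"]), 1L)

  # orphan fragments dropped when both mates are required
  orphan <- make_record("solo", 163L, "chr1", 120L, "20M", strrep("A", 20))
  expect_equal(sum(count_labeled(orphan, gm)), 0L)
  expect_equal(sum(count_labeled(orphan, gm,
                                 require_both_mapped = FALSE)), 1L)

  # ambiguous fragments (overlapping two genes enough) are discarded
  gm_amb <- gene_model_table(list(
    list(gene_id = "g1", chrom = "chr1", strand = "+",
         exons = rbind(c(101L, 200L))),
    list(gene_id = "g2", chrom = "chr1", strand = "+",
         exons = rbind(c(150L, 250L)))))
  amb <- pair("a", 150L, 160L, 30L)   # spans 150..189, inside both
  cnt <- count_labeled(amb, gm_amb)
  expect_equal(sum(cnt), 0L)
  expect_equal(attr(cnt, "n_ambiguous"), 1L)
})

test_that("count_labeled equals a brute-force oracle on simulated reads", {
  fx <- fix_genome()
  rs <- gen_read_set(fx$gm, fx$ref, p_label = 0.5, p_conv = 0.1,
                     snps = NULL, err = 0, n_fragments = 200, seed = 55)
  cnt <- count_labeled(rs$records, fx$gm)

  # independent oracle: per-fragment interval arithmetic from raw records
  exon_rng <- list(
    gA = c(101L, 1400L, "+"), gB = c(1601L, 2900L, "-"))
  oracle <- c(gA = 0L, gB = 0L)
  for (qn in unique(rs$records$qname)) {
    grp <- rs$records[rs$records$qname == qn, ]
    lo <- min(grp$pos); hi <- max(grp$pos + nchar(grp$seq) - 1L)
    covered <- sort(unique(c(seq(grp$pos[1], grp$pos[1] +
                                   nchar(grp$seq[1]) - 1L),
                             seq(grp$pos[2], grp$pos[2] +
                                   nchar(grp$seq[2]) - 1L))))
    r2flag <- grp$flag[bitwAnd(grp$flag, 128L) != 0][1]
    sense <- if (bitwAnd(r2flag, 16L) != 0) "-" else "+"
    hits <- character(0)
    for (g in names(exon_rng)) {
      er <- exon_rng[[g]]
      if (er[3] != sense) next
      ov <- sum(covered >= as.integer(er[1]) & covered <= as.integer(er[2]))
      if (ov >= 10) hits <- c(hits, g)
    }
    if (length(hits) == 1L) oracle[hits] <- oracle[hits] + 1L
  }
  expect_equal(unname(cnt["gA"]), unname(oracle["gA"]))
  expect_equal(unname(cnt["gB"]), unname(oracle["gB"]))
})

test_that("flag_nonexpressed applies the <10-total rule", {
  counts <- cbind(s1 = c(gA = 3L, gB = 5L, gC = 0L),
                  s2 = c(6L, 5L, 0L))
  fl <- flag_nonexpressed(counts)
  expect_identical(unname(fl), c(TRUE, FALSE, TRUE))  # 9 flagged, 10 not
})

test_that("chrom_enrichment matches ratio arithmetic and brute-force tails", {
  # N=100, K=10 on chr4; set n=10 with k=5 -> ratio 5
  u <- c(rep("chr4", 10), rep("chr1", 90))
  names(u) <- paste0("g", seq_along(u))
  set <- c(paste0("g", 1:5), paste0("g", 11:15))
  res <- chrom_enrichment(set, u)
  expect_equal(res$ratio[res$chrom == "chr4"], 5.0)
  # k = n*K/N exactly -> ratio 1
  set2 <- c(paste0("g", 1), paste0("g", 11:19))
  res2 <- chrom_enrichment(set2, u)
  expect_equal(res2$ratio[res2$chrom == "chr4"], 1.0)

  # upper-tail p equals choose() enumeration for small universes
  set.seed(31)
  for (i in 1:20) {
    N <- sample(10:50, 1)
    K <- sample(1:(N - 1), 1)
    n <- sample(1:N, 1)
    uu <- c(rep("cA", K), rep("cB", N - K))
    names(uu) <- paste0("x", seq_len(N))
    ss <- sample(names(uu), n)
    rr <- chrom_enrichment(ss, uu)
    k <- sum(uu[ss] == "cA")
    expect_equal(rr$p[rr$chrom == "cA"], hyper_tail_oracle(k, N, K, n),
                 tolerance = 1e-12)
  }

  # BH adjustment matches an independent step-up on random p-vectors
  set.seed(4)
  for (i in 1:20) {
    p <- stats::runif(sample(2:25, 1))
    expect_equal(stats::p.adjust(p, "BH"), bh_oracle(p),
                 tolerance = 1e-12)
  }

  expect_error(chrom_enrichment("nope", u), "subset")
})
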