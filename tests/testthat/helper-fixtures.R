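# Shared fixture builders. Everything is generated in code at test time;
# no binary fixtures.

fix_grid <- function(shape = c(16, 48, 48), spacing = c(0.3, 0.1, 0.1)) {
  voxel_grid(shape, spacing)
}

# small two-gene genome with SNP positions guaranteed to differ from ref
fix_genome <- function(seed = 5L, chr_len = 3000L) {
  ref <- gen_reference(c(chr1 = chr_len), seed = seed)
  gm <- gene_model_table(list(
    list(gene_id = "gA", chrom = "chr1", strand = "+",
         exons = rbind(c(101L, 1400L))),
    list(gene_id = "gB", chrom = "chr1", strand = "-",
         exons = rbind(c(1601L, 2900L)))))
  pos <- c(500L, 2100L)
  refb <- substring(ref, pos, pos)
  alt <- ifelse(refb == "A", "C", "A")
  list(ref = ref, gm = gm,
       snps = data.frame(chrom = "chr1", pos = pos, ref = refb, alt = alt,
                         stringsAsFactors = FALSE))
}

# one crafted SAM record row in the package's record dialect
make_record <- function(qname, flag, rname, pos, cigar, seq,
                        qual_str = NULL) {
  if (is.null(qual_str)) qual_str <- strrep("F", nchar(seq))
  data.frame(qname = qname, flag = as.integer(flag), rname = rname,
             pos = as.integer(pos), mapq = 60L, cigar = cigar,
             rnext = "=", pnext = 0L, tlen = 0L, seq = seq,
             qual = qual_str, nm = NA_integer_, md = NA_character_,
             stringsAsFactors = FALSE)
}

# body record constructed directly (bypassing rendering) for tracking tests
make_body <- function(nucleus, frame, centroid_um, identity = "mir430",
                      state = "initiating-elongating", vox = NULL) {
  list(voxels = vox %||% as.integer(frame * 1000 + nucleus),
       n_voxels = length(vox %||% 1L),
       centroid_um = centroid_um, nucleus = nucleus, frame = frame,
       identity = identity, state = state, intensity = list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# exhaustive 26-neighbor local-maxima oracle for small images
maxima_oracle <- function(arr, threshold) {
  dm <- dim(arr)
  out <- NULL
  for (z in 1:dm[1]) for (y in 1:dm[2]) for (x in 1:dm[3]) {
    v <- arr[z, y, x]
    if (v <= threshold) next
    ok <- TRUE
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      if (dz == 0 && dy == 0 && dx == 0) next
      zz <- z + dz; yy <- y + dy; xx <- x + dx
      if (zz < 1 || zz > dm[1] || yy < 1 || yy > dm[2] ||
          xx < 1 || xx > dm[3]) next
      if (v < arr[zz, yy, xx]) ok <- FALSE
    }
    if (ok) out <- rbind(out, c(z, y, x))
  }
  out
}

# independent hypergeometric upper tail by direct choose() enumeration
hyper_tail_oracle <- function(k, N, K, n) {
  ks <- k:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# reference Benjamini-Hochberg step-up, written independently of p.adjust
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}
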