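# Oligopaint probe assembly and library QC.
#
# Each library oligo is a 5'->3' concatenation of six segments: forward
# priming, reverse-transcriptase priming, gene-specific readout, genomic
# target, group-specific readout, and reverse priming. Library design rules:
# assembled length 130-137 nt, probe density 10 +/- 1 per kb of target
# gene, genes at least 40 kb long and covered by at least 400 probes.

PROBE_SEGMENT_ORDER <- c("fwd_priming", "rt_priming", "gene_readout",
                         "genomic_target", "group_readout", "rev_priming")

is_iupac <- function(s) {
  grepl("^[ACGTURYSWKMBDHVN]+$", toupper(s))
}

#' Assemble Oligopaint probes and run library QC
#'
#' Concatenates the six probe segments in fixed 5'->3' order and flags
#' design-rule violations per oligo and per gene.
#'
#' @param segments data.frame with columns `gene`, `group` (one of `"up"`,
#'   `"down"`, `"mir430-single-probe"`) and the six segment columns
#'   `fwd_priming`, `rt_priming`, `gene_readout`, `genomic_target`,
#'   `group_readout`, `rev_priming` (IUPAC nucleotide strings).
#' @param gene_lengths named numeric vector of target gene lengths in bp.
#' @param length_window allowed assembled length range, nt.
#' @param density_window allowed probes-per-kilobase range.
#' @param min_probes minimum probes per gene.
#' @param min_gene_length minimum gene length, bp.
#' @return List with `probes` (data.frame: gene, group, sequence, length,
#'   `length_ok`) and `gene_qc` (data.frame: gene, n_probes, length_bp,
#'   density per kb and the three per-gene flags, plus overall `pass`).
#' @export
assemble_and_validate_probes <- function(segments, gene_lengths,
                                         length_window = c(130L, 137L),
                                         density_window = c(9, 11),
                                         min_probes = 400L,
                                         min_gene_length = 40000L) {
  missing_cols <- setdiff(PROBE_SEGMENT_ORDER, names(segments))
  if (length(missing_cols))
    stop("segments is missing columns: ", paste(missing_cols, collapse = ", "))
  for (col in PROBE_SEGMENT_ORDER) {
    bad <- !is_iupac(segments[[col]])
    if (any(bad))
      stop(sprintf("non-IUPAC characters in segment '%s' (row %d)",
                   col, which(bad)[1]))
  }
  seqs <- do.call(paste0, segments[PROBE_SEGMENT_ORDER])
  len <- nchar(seqs)
  probes <- data.frame(gene = segments$gene, group = segments$group,
                       sequence = toupper(seqs), length = len,
                       length_ok = len >= length_window[1] &
                         len <= length_window[2],
                       stringsAsFactors = FALSE)
  genes <- sort(unique(probes$gene))
  qc <- do.call(rbind, lapply(genes, function(g) {
    n <- sum(probes$gene == g)
    gl <- unname(gene_lengths[g])
    if (is.na(gl)) stop("no gene length supplied for gene ", g)
    dens <- n / (gl / 1000)
    data.frame(gene = g, n_probes = n, length_bp = gl,
               density_per_kb = dens,
               density_ok = dens >= density_window[1] &
                 dens <= density_window[2],
               probe_count_ok = n >= min_probes,
               gene_length_ok = gl >= min_gene_length,
               stringsAsFactors = FALSE)
  }))
  qc$pass <- qc$density_ok & qc$probe_count_ok & qc$gene_length_ok
  list(probes = probes, gene_qc = qc)
}
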