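# Plain-text I/O. Images travel as a self-describing text format (shape,
# spacing and channel in a header, one voxel value per line in column-major
# z,y,x order) because the package is deliverable as text only; FASTA goes
# through Biostrings when available; SAM is written/read in the minimal
# dialect the simulator emits.

#' Write a SAM file
#' @param sam character vector of SAM lines (header + records), e.g.
#'   `gen_read_set()$sam`.
#' @param path output path.
#' @export
write_sam <- function(sam, path) writeLines(sam, path)

#' Read a SAM file into the record data.frame used by this package
#'
#' Parses the eleven mandatory columns plus NM/MD tags when present.
#' Header lines are skipped.
#'
#' @param path SAM file path.
#' @return data.frame with columns `qname`, `flag`, `rname`, `pos`,
#'   `mapq`, `cigar`, `rnext`, `pnext`, `tlen`, `seq`, `qual`, `nm`, `md`.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  tag <- function(f, prefix) {
    hit <- f[startsWith(f, prefix)]
    if (length(hit)) sub(prefix, "", hit[1]) else NA_character_
  }
  data.frame(
    qname = vapply(fields, `[[`, character(1), 1),
    flag = as.integer(vapply(fields, `[[`, character(1), 2)),
    rname = vapply(fields, `[[`, character(1), 3),
    pos = as.integer(vapply(fields, `[[`, character(1), 4)),
    mapq = as.integer(vapply(fields, `[[`, character(1), 5)),
    cigar = vapply(fields, `[[`, character(1), 6),
    rnext = vapply(fields, `[[`, character(1), 7),
    pnext = as.integer(vapply(fields, `[[`, character(1), 8)),
    tlen = as.integer(vapply(fields, `[[`, character(1), 9)),
    seq = vapply(fields, `[[`, character(1), 10),
    qual = vapply(fields, `[[`, character(1), 11),
    nm = as.integer(vapply(fields, tag, character(1), "NM:i:")),
    md = vapply(fields, tag, character(1), "MD:Z:"),
    stringsAsFactors = FALSE)
}

#' Write a reference as FASTA
#' @param reference named character vector of sequences.
#' @param path output path.
#' @export
write_fasta <- function(reference, path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(reference), path)
  } else {
    con <- file(path, "w"); on.exit(close(con))
    for (nm in names(reference)) {
      writeLines(paste0(">", nm), con)
      writeLines(reference[[nm]], con)
    }
  }
  invisible(path)
}

#' Read a FASTA reference into a named character vector
#' @param path FASTA path.
#' @export
read_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    ss <- Biostrings::readDNAStringSet(path)
    stats::setNames(as.character(ss), names(ss))
  } else {
    lines <- readLines(path)
    hdr <- grep("^>", lines)
    ends <- c(hdr[-1] - 1L, length(lines))
    stats::setNames(
      vapply(seq_along(hdr), function(i)
        paste(lines[(hdr[i] + 1L):ends[i]], collapse = ""), character(1)),
      sub("^>", "", sub("\\s.*", "", lines[hdr])))
  }
}

#' Write gene models as GTF exon lines
#' @param gene_models exon table from [gene_model_table()].
#' @param path output path.
#' @export
write_gtf <- function(gene_models, path) {
  writeLines(sprintf(
    "%s\tsim\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
    gene_models$chrom, gene_models$start, gene_models$end,
    gene_models$strand, gene_models$gene_id), path)
  invisible(path)
}

#' Write a volume image as self-describing text
#' @param img a [volume_image()].
#' @param path output path.
#' @export
write_image_text <- function(img, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    paste0("# txbodies volume v1"),
    paste0("# shape_zyx ", paste(img$grid$shape, collapse = " ")),
    paste0("# spacing_um ", paste(format(img$grid$spacing, digits = 17),
                                  collapse = " ")),
    paste0("# channel ", img$channel),
    paste0("# frame ", img$frame)), con)
  writeLines(format(as.numeric(img$data), digits = 17, trim = TRUE), con)
  invisible(path)
}

#' Read a volume image written by [write_image_text()]
#' @param path input path.
#' @export
read_image_text <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  val <- function(key) sub(paste0("# ", key, " "), "",
                           hdr[startsWith(hdr, paste0("# ", key, " "))])
  shape <- as.integer(strsplit(val("shape_zyx"), " ")[[1]])
  spacing <- as.numeric(strsplit(val("spacing_um"), " ")[[1]])
  frame <- suppressWarnings(as.integer(val("frame")))
  vals <- as.numeric(lines[!startsWith(lines, "#")])
  volume_image(array(vals, dim = shape), voxel_grid(shape, spacing),
               channel = val("channel"), frame = frame)
}

#' Serialize a ground-truth object to JSON (lossless round trip)
#' @param truth any simulator truth list.
#' @param path output path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(serialize_truth(truth), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

serialize_truth <- function(x) {
  if (inherits(x, "voxel_grid"))
    return(list(.class = "voxel_grid", shape = x$shape,
                spacing = x$spacing))
  if (is.list(x)) return(lapply(x, serialize_truth))
  x
}

#' Read a truth JSON written by [write_truth_json()]
#' @param path input path.
#' @export
read_truth_json <- function(path) {
  deserialize_truth(jsonlite::read_json(path, simplifyVector = FALSE))
}

deserialize_truth <- function(x) {
  if (is.list(x) && identical(x$.class, "voxel_grid"))
    return(voxel_grid(unlist(x$shape), unlist(x$spacing)))
  if (is.list(x)) {
    if (length(x) > 0 && is.null(names(x)) &&
        all(vapply(x, function(e) is.atomic(e) && length(e) == 1L,
                   logical(1))) &&
        length(unique(vapply(x, typeof, character(1)))) == 1L)
      return(unlist(x))  # JSON array of scalars -> atomic vector
    return(lapply(x, deserialize_truth))
  }
  x
}

#' Write a spot table as TSV
#' @param spots `spot_record` data.frame.
#' @param path output path.
#' @export
write_spot_tsv <- function(spots, path) {
  utils::write.table(spots, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a spot table TSV
#' @param path input path.
#' @export
read_spot_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
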