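#' Write / read a library manifest
#'
#' The manifest is a plain TSV with columns element_id, sublib_index,
#' barcode, promoter, full_sequence.
#'
#' @param manifest data.frame from [build_library()].
#' @param path File path.
#' @export
write_manifest <- function(manifest, path) {
  write.table(manifest, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  m <- read.delim(path, stringsAsFactors = FALSE)
  needed <- c("element_id", "barcode", "full_sequence")
  if (!all(needed %in% names(m))) {
    stop("manifest must contain columns: ", paste(needed, collapse = ", "))
  }
  m
}

#' Write library elements as FASTA
#' @param manifest Library manifest.
#' @param path Output FASTA path.
#' @export
write_library_fasta <- function(manifest, path) {
  seqs <- Biostrings::DNAStringSet(manifest$full_sequence)
  names(seqs) <- manifest$element_id
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Write paired reads as FASTQ
#'
#' @param reads List with character vectors \code{r1} and \code{r2} (from
#'   [simulate_reads()]).
#' @param r1_path,r2_path Output paths.
#' @export
write_read_fastq <- function(reads, r1_path, r2_path) {
  for (side in c("r1", "r2")) {
    s <- Biostrings::DNAStringSet(reads[[side]])
    names(s) <- paste0("read", seq_along(s))
    Biostrings::writeXStringSet(
      s, if (side == "r1") r1_path else r2_path, format = "fastq")
  }
  invisible(c(r1_path, r2_path))
}

#' Read paired FASTQ into character vectors
#' @param r1_path,r2_path FASTQ paths (gzipped accepted).
#' @return List with \code{r1} and \code{r2} character vectors.
#' @export
read_read_fastq <- function(r1_path, r2_path) {
  list(r1 = as.character(Biostrings::readDNAStringSet(r1_path,
                                                      format = "fastq")),
       r2 = as.character(Biostrings::readDNAStringSet(r2_path,
                                                      format = "fastq")))
}

#' Write unique insertions as qBED-style TSV
#'
#' Columns: element_id, start, end (= start + 1), umi_count (reads
#' supporting the insertion), strand, umi — the interval dialect used by the
#' calling-cards community, on element coordinates.
#'
#' @param unique_events data.frame from [dedup_insertions()].
#' @param path Output path.
#' @export
write_qbed <- function(unique_events, path) {
  q <- data.frame(element_id = unique_events$element_id,
                  start = unique_events$coordinate,
                  end = unique_events$coordinate + 1L,
                  umi_count = unique_events$multiplicity,
                  strand = unique_events$strand,
                  umi = unique_events$umi)
  write.table(q, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
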