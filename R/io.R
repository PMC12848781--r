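# File-format boundaries. FASTA goes through Biostrings; FASTQ records
# are written/read as plain 4-line text (qualities are synthetic
# constants here); call tables use a cytosine-report-style TSV dialect.

#' Write a reference genome as FASTA
#' @param reference named character vector of chromosome sequences.
#' @param path output file.
#' @export
write_fasta <- function(reference, path) {
  dss <- Biostrings::DNAStringSet(reference)
  Biostrings::writeXStringSet(dss, path)
  invisible(path)
}

#' Read a FASTA reference into a named character vector
#' @param path FASTA file.
#' @export
read_fasta <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  out <- as.character(dss)
  names(out) <- sub("\\s.*$", "", names(dss))
  out
}

#' Write reads as FASTQ (constant quality)
#' @param ids,seqs read names and sequences.
#' @param path output file (`.gz` supported).
#' @export
write_fastq <- function(ids, seqs, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  qual <- vapply(nchar(seqs), function(n) strrep("I", n), character(1))
  writeLines(paste0("@", ids, "\n", seqs, "\n+\n", qual), con)
  invisible(path)
}

#' Read a FASTQ file
#' @param path FASTQ file (`.gz` supported).
#' @return data.frame `read_id`, `seq`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) {
    stop("malformed FASTQ: ", path, " has ", length(lines),
         " lines (record ", length(lines) %/% 4L + 1L, " truncated)")
  }
  ids <- sub("^@", "", lines[seq(1L, length(lines), by = 4L)])
  ids <- sub("\\s.*$", "", ids)
  data.frame(read_id = ids, seq = lines[seq(2L, length(lines), by = 4L)],
             stringsAsFactors = FALSE)
}

#' Write a methylation-call table as cytosine-report-style TSV
#'
#' Columns: cell, chrom, pos (1-based), strand, count_meth,
#' count_unmeth, context.
#' @param calls methylation-call table.
#' @param path output file.
#' @export
write_calls <- function(calls, path) {
  out <- data.frame(cell = calls$cell, chrom = calls$chrom, pos = calls$pos,
                    strand = calls$strand, count_meth = calls$meth,
                    count_unmeth = calls$total - calls$meth,
                    context = calls$context)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cytosine-report-style TSV into a methylation-call table
#' @param path TSV from [write_calls()].
#' @export
read_calls <- function(path) {
  tb <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  data.frame(cell = tb$cell, chrom = tb$chrom, pos = tb$pos,
             strand = tb$strand, context = tb$context,
             meth = tb$count_meth, total = tb$count_meth + tb$count_unmeth,
             stringsAsFactors = FALSE)
}

#' Export pooled site levels as bedGraph
#' @param pooled pooled table ([pseudo_bulk()]).
#' @param path output file.
#' @export
write_bedgraph <- function(pooled, path) {
  out <- data.frame(pooled$chrom, pooled$pos - 1L, pooled$pos,
                    round(pooled$meth / pooled$total, 4))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file of intervals
#' @param path BED (>= 3 columns, 0-based half-open).
#' @return data.frame `chrom`, `start`, `end` (+ `name` if present).
#' @export
read_bed <- function(path) {
  tb <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  out <- data.frame(chrom = tb[[1]], start = tb[[2]], end = tb[[3]],
                    stringsAsFactors = FALSE)
  if (ncol(tb) >= 4L) out$name <- tb[[4]]
  out
}
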