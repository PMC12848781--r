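#' Classify cytosine trinucleotide contexts on a reference genome
#'
#' NOMe-seq partitions cytosines by their reference trinucleotide, read
#' 5'->3' on the site's own strand:
#'
#' * `WCG` (W = A/T): endogenous CpG methylation, unconfounded by the GpC
#'   methyltransferase.
#' * `GCH` (H = A/C/T): GpC sites methylated enzymatically in accessible
#'   chromatin; their methylation level reads out accessibility.
#' * `WCH`: essentially unmethylated in vivo; residual signal measures
#'   bisulfite conversion failure.
#' * `EXCLUDED`: `GCG` (ambiguous between endogenous and enzymatic
#'   methylation), `CCG`/`CCH` (upstream C is neither W nor G), and
#'   chromosome-edge cytosines lacking a flanking base.
#'
#' The W/G upstream definitions make the classes disjoint: every cytosine
#' receives exactly one label.
#'
#' @param reference named character vector of chromosome sequences
#'   (A/C/G/T), or a [Biostrings::DNAStringSet].
#' @param chromosome chromosome name.
#' @param position 1-based position of the cytosine (plus-strand
#'   coordinates regardless of `strand`).
#' @param strand `"+"` or `"-"`. On `"-"` the base at `position` must be
#'   `G` on the plus strand (a cytosine on the minus strand); the
#'   trinucleotide is read on the reverse complement.
#' @return one of `"WCG"`, `"GCH"`, `"WCH"`, `"EXCLUDED"` (vectorised over
#'   `position`/`strand`).
#' @seealso [annotate_contexts()] for whole-genome annotation.
#' @export
classify_context <- function(reference, chromosome, position, strand) {
  reference <- as_reference(reference)
  seq <- reference[[chromosome]]
  n <- nchar(seq)
  stopifnot(all(position >= 1L), all(position <= n))
  base <- substring(seq, position, position)
  plus <- strand == "+"
  if (any(base[plus] != "C") || any(base[!plus] != "G")) {
    stop("position is not a cytosine on the requested strand")
  }
  up <- character(length(position))
  down <- character(length(position))
  # plus strand: upstream = position-1, downstream = position+1
  if (any(plus)) {
    up[plus] <- substring(seq, position[plus] - 1L, position[plus] - 1L)
    down[plus] <- substring(seq, position[plus] + 1L, position[plus] + 1L)
  }
  # minus strand: read on the reverse complement; upstream (5' on minus)
  # is plus position+1 complemented, downstream is position-1 complemented
  if (any(!plus)) {
    up[!plus] <- dna_complement(
      substring(seq, position[!plus] + 1L, position[!plus] + 1L))
    down[!plus] <- dna_complement(
      substring(seq, position[!plus] - 1L, position[!plus] - 1L))
  }
  context_from_flanks(up, down)
}

# vectorised trinucleotide rule; "" (chromosome edge) -> EXCLUDED
context_from_flanks <- function(up, down) {
  ctx <- rep("EXCLUDED", length(up))
  w_up <- up %in% c("A", "T")
  g_up <- up == "G"
  h_down <- down %in% c("A", "C", "T")
  g_down <- down == "G"
  ctx[w_up & g_down] <- "WCG"
  ctx[g_up & h_down] <- "GCH"
  ctx[w_up & h_down] <- "WCH"
  ctx
}

dna_complement <- function(x) {
  chartr("ACGTN", "TGCAN", x)
}

dna_revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

as_reference <- function(reference) {
  if (methods::is(reference, "DNAStringSet")) {
    out <- as.character(reference)
    names(out) <- names(reference)
    return(out)
  }
  stopifnot(is.character(reference), !is.null(names(reference)))
  reference
}

#' Annotate every cytosine on both strands of a reference
#'
#' Scans each chromosome once and labels every plus-strand `C` and every
#' minus-strand `C` (a plus-strand `G`) with its trinucleotide context.
#'
#' @inheritParams classify_context
#' @return data.frame with columns `chrom`, `pos` (1-based plus-strand
#'   coordinate of the cytosine), `strand`, `context`.
#' @export
annotate_contexts <- function(reference) {
  reference <- as_reference(reference)
  out <- lapply(names(reference), function(chrom) {
    seq <- reference[[chrom]]
    bases <- strsplit(seq, "", fixed = TRUE)[[1]]
    n <- length(bases)
    pos_c <- which(bases == "C")
    pos_g <- which(bases == "G")
    flank <- function(p, off) {
      q <- p + off
      out <- rep("", length(p))
      ok <- q >= 1L & q <= n
      out[ok] <- bases[q[ok]]
      out
    }
    ctx_plus <- context_from_flanks(flank(pos_c, -1L), flank(pos_c, +1L))
    ctx_minus <- context_from_flanks(dna_complement(flank(pos_g, +1L)),
                                     dna_complement(flank(pos_g, -1L)))
    data.frame(
      chrom = chrom,
      pos = c(pos_c, pos_g),
      strand = rep(c("+", "-"), c(length(pos_c), length(pos_g))),
      context = c(ctx_plus, ctx_minus),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  out[order(match(out$chrom, names(reference)), out$pos, out$strand), ,
      drop = FALSE]
}
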