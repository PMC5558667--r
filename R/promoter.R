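#' Extract the upstream promoter window of a gene
#'
#' Takes \code{width} bp 5' of the gene start on the coding strand
#' (reverse-complemented for minus-strand genes), truncated at the
#' chromosome edge.
#'
#' @param chrom_seq chromosome sequence (character scalar)
#' @param gene gene annotation (needs \code{start}, \code{end},
#'   \code{strand})
#' @param width window size in bp (default 1500)
#' @return upstream sequence, 5'->3' on the coding strand (may be shorter
#'   than \code{width} at a chromosome edge; empty string when flush)
#' @export
extract_upstream <- function(chrom_seq, gene, width = 1500L) {
  L <- nchar(chrom_seq)
  if (gene$strand == "-") {
    s <- gene$end + 1L
    e <- min(L, gene$end + width)
    if (s > e) return("")
    revcomp(substr(chrom_seq, s, e))
  } else {
    s <- max(1L, gene$start - width)
    e <- gene$start - 1L
    if (s > e) return("")
    toupper(substr(chrom_seq, s, e))
  }
}

#' Load an IUPAC promoter-motif dictionary
#' @param path TSV with columns \code{motif_name}, \code{iupac};
#'   \code{NULL} loads the shipped default
#' @return data.frame
#' @export
load_motif_dict <- function(path = NULL) {
  if (is.null(path)) path <- extdata_path("promoter_motifs.tsv")
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Scan promoter sequences for IUPAC motifs
#'
#' Reports all matches on both strands (overlaps allowed); offsets are
#' 1-based positions on the given (plus) sequence.
#'
#' @param upstream named character vector of upstream sequences (names =
#'   gene ids)
#' @param motifs data.frame with \code{motif_name}, \code{iupac}
#' @return data.frame with \code{gene_id}, \code{motif_name}, \code{strand},
#'   \code{offset}, \code{matched}
#' @export
scan_promoter <- function(upstream, motifs) {
  iupac <- names(Biostrings::IUPAC_CODE_MAP)
  bad <- vapply(motifs$iupac, function(m)
    any(!strsplit(toupper(m), "")[[1]] %in% iupac), logical(1))
  if (any(bad))
    stop("invalid IUPAC symbol in motif: ", motifs$motif_name[bad][1L])
  out <- list()
  for (g in names(upstream)) {
    seq <- toupper(upstream[[g]])
    if (!nzchar(seq)) next
    subj <- Biostrings::DNAString(seq)
    for (k in seq_len(nrow(motifs))) {
      pat <- toupper(motifs$iupac[k])
      for (strand in c("+", "-")) {
        p <- if (strand == "+") pat else revcomp(pat)
        if (nchar(p) > nchar(seq)) next
        m <- Biostrings::matchPattern(p, subj, fixed = FALSE)
        if (!length(m)) next
        out[[length(out) + 1L]] <- data.frame(
          gene_id = g, motif_name = motifs$motif_name[k], strand = strand,
          offset = Biostrings::start(m),
          matched = as.character(m), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(gene_id = character(), motif_name = character(),
                      strand = character(), offset = integer(),
                      matched = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Tabulate motif counts per gene
#' @param hits data.frame from [scan_promoter()]
#' @return data.frame gene x motif counts (long format)
#' @export
motif_counts <- function(hits) {
  if (!nrow(hits)) {
    return(data.frame(gene_id = character(), motif_name = character(),
                      count = integer(), stringsAsFactors = FALSE))
  }
  agg <- stats::aggregate(list(count = rep(1L, nrow(hits))),
                          by = hits[c("gene_id", "motif_name")], FUN = sum)
  agg[order(agg$gene_id, agg$motif_name), , drop = FALSE]
}
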