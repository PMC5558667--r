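#' Map a CDS coordinate to its genomic position
#'
#' @param cds_pos 1-based position within the spliced CDS
#' @param gene gene annotation (see [read_gff3()]); CDS segments fall back to
#'   exons when absent
#' @return 1-based genomic position
#' @keywords internal
cds_to_genomic <- function(cds_pos, gene) {
  segs <- gene$cds_segments
  if (is.null(segs) || nrow(segs) == 0L) segs <- gene$exons
  lens <- segs[, "end"] - segs[, "start"] + 1L
  if (gene$strand == "-") {
    ord <- rev(seq_len(nrow(segs)))   # transcription order on minus strand
  } else {
    ord <- seq_len(nrow(segs))
  }
  cum <- cumsum(lens[ord])
  k <- which(cds_pos <= cum)[1L]
  if (is.na(k)) stop("CDS position ", cds_pos, " beyond CDS of ", gene$gene_id)
  within <- cds_pos - c(0L, cum)[k]
  seg <- segs[ord[k], , drop = TRUE]
  if (gene$strand == "-") seg["end"] - within + 1L else seg["start"] + within - 1L
}

#' Genomic span of a protein-coordinate interval (BED 0-based half-open)
#'
#' @param protein_start,protein_end 1-based inclusive residue coordinates
#' @param gene gene annotation
#' @return list with \code{chrom}, \code{bed_start}, \code{bed_end},
#'   \code{strand}
#' @export
domain_genomic_span <- function(protein_start, protein_end, gene) {
  cds_s <- (protein_start - 1L) * 3L + 1L
  cds_e <- protein_end * 3L
  g1 <- cds_to_genomic(cds_s, gene)
  g2 <- cds_to_genomic(cds_e, gene)
  list(chrom = gene$chromosome,
       bed_start = min(g1, g2) - 1L, bed_end = max(g1, g2),
       strand = gene$strand)
}

#' Write per-stage result tables to a directory
#'
#' Writes one TSV per supplied stage (\code{hits}, \code{calls},
#' \code{pairs}, \code{patterns}, \code{properties}, any other data.frame by
#' its name) plus \code{domains.bed} (BED6, 0-based half-open) when both
#' domain hits and gene annotations are available.  Empty data.frames yield
#' header-only files.
#'
#' @param results named list of data.frames; optionally an element
#'   \code{genes} (list of gene annotations) used for BED output
#' @param out_dir output directory, created if needed
#' @return named character vector of written paths, invisibly
#' @export
write_results_tables <- function(results, out_dir) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                          showWarnings = FALSE)
  if (!ok || file.access(out_dir, 2L) != 0L)
    stop("cannot write to directory: ", out_dir)
  written <- character()
  for (nm in names(results)) {
    x <- results[[nm]]
    if (!is.data.frame(x)) next
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE)
    written[nm] <- p
  }
  hits <- results$hits
  genes <- results$genes
  if (is.data.frame(hits) && nrow(hits) && !is.null(genes)) {
    by_id <- setNames(genes, vapply(genes, `[[`, "", "gene_id"))
    rows <- lapply(seq_len(nrow(hits)), function(i) {
      g <- by_id[[hits$protein_id[i]]]
      if (is.null(g)) return(NULL)
      sp <- domain_genomic_span(hits$start[i], hits$end[i], g)
      data.frame(chrom = sp$chrom, start = sp$bed_start, end = sp$bed_end,
                 name = hits$protein_id[i], score = hits$mismatch_count[i],
                 strand = sp$strand, stringsAsFactors = FALSE)
    })
    bed <- do.call(rbind, rows)
    if (!is.null(bed)) {
      p <- file.path(out_dir, "domains.bed")
      write.table(bed, p, sep = "\t", quote = FALSE,
                  row.names = FALSE, col.names = FALSE)
      written["domains_bed"] <- p
    }
  }
  invisible(written)
}
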