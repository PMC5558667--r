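#' Read gene models from a GFF3 file
#'
#' Parses \code{gene}, \code{mRNA}/\code{transcript}, \code{exon} and
#' \code{CDS} features linked through \code{ID}/\code{Parent} attributes.
#' When a gene carries several transcripts the one with the longest total CDS
#' is retained, so exactly one model is reported per locus.  Coordinates stay
#' 1-based inclusive; exon lists are stored in ascending genomic order with
#' the strand recorded separately.
#'
#' @param path path to a GFF3 file
#' @return list of gene annotations ordered by (chromosome, start); each is a
#'   list with \code{gene_id}, \code{chromosome}, \code{start}, \code{end},
#'   \code{strand}, \code{exons} (matrix start,end) and \code{cds_segments}
#'   (matrix start,end,phase)
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(list())
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(f) < 9L)
  if (length(bad)) stop("malformed GFF3 row at line ", bad[1L])
  tab <- data.frame(
    seqid = vapply(f, `[`, "", 1L), type = vapply(f, `[`, "", 3L),
    start = as.integer(vapply(f, `[`, "", 4L)),
    end = as.integer(vapply(f, `[`, "", 5L)),
    strand = vapply(f, `[`, "", 7L),
    phase = vapply(f, `[`, "", 8L),
    attrs = vapply(f, `[`, "", 9L), stringsAsFactors = FALSE)
  attr_field <- function(attrs, key) {
    m <- regmatches(attrs, regexpr(paste0("(^|;)", key, "=[^;]*"), attrs))
    out <- rep(NA_character_, length(attrs))
    hit <- lengths(regmatches(attrs, gregexpr(paste0("(^|;)", key, "="), attrs))) > 0
    out[hit] <- sub(paste0("^;?", key, "="), "", m)
    out
  }
  tab$id <- attr_field(tab$attrs, "ID")
  tab$parent <- attr_field(tab$attrs, "Parent")

  genes <- tab[tab$type == "gene", , drop = FALSE]
  mrnas <- tab[tab$type %in% c("mRNA", "transcript"), , drop = FALSE]
  exons <- tab[tab$type == "exon", , drop = FALSE]
  cdss  <- tab[tab$type == "CDS", , drop = FALSE]
  mrna2gene <- setNames(mrnas$parent, mrnas$id)

  gene_of <- function(parent) {
    # Parent may be an mRNA id or (in terse files) directly a gene id
    if (is.na(parent)) return(NA_character_)
    if (parent %in% genes$id) parent else mrna2gene[parent]
  }
  orphan <- vapply(cdss$parent, function(p) is.na(gene_of(p)), logical(1))
  if (any(orphan)) {
    warning("skipping ", sum(orphan), " CDS feature(s) with no parent gene")
    cdss <- cdss[!orphan, , drop = FALSE]
  }

  out <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    tx <- mrnas$id[!is.na(mrnas$parent) & mrnas$parent == g$id]
    pick_features <- function(feat, parents) {
      feat[!is.na(feat$parent) & feat$parent %in% parents, , drop = FALSE]
    }
    if (length(tx)) {
      cds_len <- vapply(tx, function(t) {
        cc <- pick_features(cdss, t)
        if (nrow(cc)) sum(cc$end - cc$start + 1L) else 0L
      }, integer(1))
      best <- tx[which.max(cds_len)]   # ties: first in file order
      ex <- pick_features(exons, best)
      cc <- pick_features(cdss, best)
    } else {
      ex <- pick_features(exons, g$id)
      cc <- pick_features(cdss, g$id)
    }
    ord <- order(ex$start)
    exm <- cbind(start = ex$start[ord], end = ex$end[ord])
    ordc <- order(cc$start)
    ccm <- cbind(start = cc$start[ordc], end = cc$end[ordc],
                 phase = suppressWarnings(as.integer(cc$phase[ordc])))
    if (!nrow(exm) && nrow(ccm)) exm <- ccm[, c("start", "end"), drop = FALSE]
    if (!nrow(exm)) exm <- cbind(start = g$start, end = g$end)
    list(gene_id = g$id, chromosome = g$seqid,
         start = g$start, end = g$end, strand = g$strand,
         exons = exm, cds_segments = ccm)
  })
  ord <- order(vapply(out, `[[`, "", "chromosome"),
               vapply(out, function(x) x$start, integer(1)))
  out[ord]
}

#' Write gene annotations as GFF3
#'
#' One gene/mRNA pair per annotation with its exon and CDS children; used by
#' the synthetic-data generators.
#'
#' @param genes list of gene annotations (see [read_gff3()])
#' @param path output path
#' @return \code{path}, invisibly
#' @export
write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (g in genes) {
    mid <- paste0(g$gene_id, ".1")
    row <- function(type, s, e, ph, attrs)
      paste(g$chromosome, "bhlhfam", type, s, e, ".", g$strand, ph, attrs,
            sep = "\t")
    writeLines(row("gene", g$start, g$end, ".", paste0("ID=", g$gene_id)), con)
    writeLines(row("mRNA", g$start, g$end, ".",
                   paste0("ID=", mid, ";Parent=", g$gene_id)), con)
    ex <- g$exons
    for (i in seq_len(nrow(ex)))
      writeLines(row("exon", ex[i, "start"], ex[i, "end"], ".",
                     paste0("ID=", mid, ".exon", i, ";Parent=", mid)), con)
    cc <- g$cds_segments
    if (!is.null(cc)) for (i in seq_len(nrow(cc))) {
      ph <- if ("phase" %in% colnames(cc) && !is.na(cc[i, "phase"]))
        cc[i, "phase"] else 0L
      writeLines(row("CDS", cc[i, "start"], cc[i, "end"], ph,
                     paste0("ID=", mid, ".cds;Parent=", mid)), con)
    }
  }
  invisible(path)
}

#' Read a synteny block table
#'
#' Tab-delimited with six coordinate columns (\code{chrom_a}, \code{start_a},
#' \code{end_a}, \code{chrom_b}, \code{start_b}, \code{end_b}) and an
#' optional block id; lines starting with \code{#} are skipped.
#'
#' @param path path to the table
#' @return data.frame of blocks, one per row
#' @export
read_synteny_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    return(data.frame(chrom_a = character(), start_a = integer(),
                      end_a = integer(), chrom_b = character(),
                      start_b = integer(), end_b = integer(),
                      block_id = character(), stringsAsFactors = FALSE))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  out <- lapply(seq_along(f), function(i) {
    x <- f[[i]]
    if (length(x) < 6L) stop("malformed synteny row at line ", lineno[i])
    sa <- suppressWarnings(as.integer(x[2:3]))
    sb <- suppressWarnings(as.integer(x[5:6]))
    if (anyNA(sa) || anyNA(sb))
      stop("non-numeric coordinate at line ", lineno[i])
    if (sa[1] > sa[2] || sb[1] > sb[2])
      stop("start > end at line ", lineno[i])
    data.frame(chrom_a = x[1], start_a = sa[1], end_a = sa[2],
               chrom_b = x[4], start_b = sb[1], end_b = sb[2],
               block_id = if (length(x) >= 7L) x[7] else paste0("block", i),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
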