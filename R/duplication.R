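#' Global protein identity between two sequences
#'
#' Needleman-Wunsch global alignment (BLOSUM62, standard gap costs);
#' identity = identical positions / alignment length.
#'
#' @param seq_a,seq_b protein sequences (character scalars)
#' @return fraction in [0, 1]
#' @export
protein_identity <- function(seq_a, seq_b) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
    type = "global")
  Biostrings::pid(aln, type = "PID1") / 100
}

#' Detect tandem duplicate pairs from gene order
#'
#' Family members that are adjacent in the full gene order of one chromosome
#' (rank difference 1, i.e. no intervening gene of any kind) and whose global
#' protein identity reaches \code{identity_min} are called tandem
#' duplicates.
#'
#' @param family_ids character vector of family gene ids
#' @param all_genes list of gene annotations for the whole genome, as from
#'   [read_gff3()] (any order; ranked internally by chromosome and start)
#' @param proteins data.frame from [read_fasta()] giving the protein of each
#'   family gene (ids must match \code{family_ids}); \code{NULL} skips the
#'   identity check
#' @param identity_min minimum global protein identity (default 0.4)
#' @return data.frame with \code{gene_a}, \code{gene_b}, \code{chromosome},
#'   \code{identity}, \code{dup_type = "tandem"}
#' @export
find_tandem_pairs <- function(family_ids, all_genes, proteins = NULL,
                              identity_min = 0.4) {
  ids <- vapply(all_genes, `[[`, "", "gene_id")
  chrom <- vapply(all_genes, `[[`, "", "chromosome")
  start <- vapply(all_genes, function(g) as.integer(g$start), integer(1))
  ord <- order(chrom, start)
  ids <- ids[ord]; chrom <- chrom[ord]
  seqs <- if (!is.null(proteins)) setNames(proteins$sequence, proteins$id)
  out <- list()
  for (k in seq_len(length(ids) - 1L)) {
    a <- ids[k]; b <- ids[k + 1L]
    if (chrom[k] != chrom[k + 1L]) next
    if (!(a %in% family_ids && b %in% family_ids)) next
    idy <- NA_real_
    if (!is.null(seqs)) {
      if (is.na(seqs[a]) || is.na(seqs[b])) next
      idy <- protein_identity(seqs[[a]], seqs[[b]])
      if (idy < identity_min) next
    }
    out[[length(out) + 1L]] <- data.frame(
      gene_a = a, gene_b = b, chromosome = chrom[k], identity = idy,
      dup_type = "tandem", stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      chromosome = character(), identity = numeric(),
                      dup_type = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Assign segmental duplicate pairs from synteny blocks
#'
#' A family pair (a, b) is segmental when a lies in a block's A-region and b
#' in the paired B-region (or vice versa).  Containment uses the gene start
#' coordinate, so straddlers are resolved deterministically.  Pairs already
#' called tandem are not re-flagged.
#'
#' @param family_genes list of gene annotations for the family members
#' @param blocks data.frame from [read_synteny_table()]
#' @param tandem optional data.frame of tandem pairs (from
#'   [find_tandem_pairs()]) to exclude
#' @return data.frame with \code{gene_a}, \code{gene_b}, \code{block_id},
#'   \code{dup_type = "segmental"}
#' @export
assign_segmental <- function(family_genes, blocks, tandem = NULL) {
  empty <- data.frame(gene_a = character(), gene_b = character(),
                      block_id = character(), dup_type = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(blocks) || length(family_genes) < 2L) return(empty)
  ids <- vapply(family_genes, `[[`, "", "gene_id")
  chrom <- vapply(family_genes, `[[`, "", "chromosome")
  start <- vapply(family_genes, function(g) as.integer(g$start), integer(1))
  in_region <- function(i, rc, rs, re) chrom[i] == rc & start[i] >= rs & start[i] <= re
  tkey <- character(0)
  if (!is.null(tandem) && nrow(tandem)) {
    tkey <- paste(pmin(tandem$gene_a, tandem$gene_b),
                  pmax(tandem$gene_a, tandem$gene_b))
  }
  out <- list()
  seen <- character(0)
  n <- length(ids)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    key <- paste(min(ids[i], ids[j]), max(ids[i], ids[j]))
    if (key %in% tkey || key %in% seen) next
    for (bk in seq_len(nrow(blocks))) {
      blk <- blocks[bk, ]
      hit <- (in_region(i, blk$chrom_a, blk$start_a, blk$end_a) &&
              in_region(j, blk$chrom_b, blk$start_b, blk$end_b)) ||
             (in_region(j, blk$chrom_a, blk$start_a, blk$end_a) &&
              in_region(i, blk$chrom_b, blk$start_b, blk$end_b))
      if (hit) {
        seen <- c(seen, key)
        out[[length(out) + 1L]] <- data.frame(
          gene_a = min(ids[i], ids[j]), gene_b = max(ids[i], ids[j]),
          block_id = blk$block_id, dup_type = "segmental",
          stringsAsFactors = FALSE)
        break
      }
    }
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Ka/Ks, selection class and age for duplicate pairs
#'
#' Aligns each pair's proteins globally, back-translates onto the CDS,
#' computes NG86 Ka/Ks and dates the event with the synonymous clock.
#'
#' @param pairs data.frame with \code{gene_a}, \code{gene_b} (and
#'   \code{dup_type})
#' @param cds data.frame from [read_fasta()] (coding sequences per gene)
#' @param proteins data.frame from [read_fasta()] (protein per gene)
#' @param lambda_syn synonymous clock rate (substitutions/site/year)
#' @return \code{pairs} extended with \code{ka}, \code{ks}, \code{ratio},
#'   \code{selection}, \code{t_mya}, \code{lambda_syn}
#' @export
pair_kaks <- function(pairs, cds, proteins, lambda_syn = 6.5e-9) {
  cds_map <- setNames(cds$sequence, cds$id)
  prot_map <- setNames(proteins$sequence, proteins$id)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs$gene_a[i]; b <- pairs$gene_b[i]
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(prot_map[[a]]), Biostrings::AAString(prot_map[[b]]),
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
      type = "global")
    cp <- codon_align(cds_map[[a]], cds_map[[b]],
                      as.character(Biostrings::alignedPattern(aln)),
                      as.character(Biostrings::alignedSubject(aln)))
    kk <- ng86_kaks(cp)
    data.frame(ka = kk$ka, ks = kk$ks, ratio = kk$ratio,
               selection = classify_selection(kk$ratio),
               t_mya = divergence_time(kk$ks, lambda_syn),
               lambda_syn = lambda_syn, stringsAsFactors = FALSE)
  })
  cbind(pairs, do.call(rbind, rows))
}
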