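#' Reverse-complement a DNA string
#' @param dna DNA text (ACGTN)
#' @return reverse complement, uppercase
#' @export
revcomp <- function(dna) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(dna))))
}

# exact-match chaining of CDS against one genomic strand; exons in genomic
# order or NULL when the CDS is not derivable.  Greedy: longest exact match
# first, shortest intron first, with backtracking.  With gt_only = TRUE
# every intron must carry canonical GT..AG dinucleotides; the caller retries
# without the constraint only if no GT..AG parse exists anywhere.
.chain_cds <- function(cdsv, genv, gt_only = TRUE) {
  n <- length(cdsv)
  L <- length(genv)
  failed <- new.env(parent = emptyenv())
  solve <- function(ci, gi) {
    key <- paste(ci, gi)
    if (!is.null(failed[[key]])) return(NULL)
    r <- 0L
    while (ci + r <= n && gi + r <= L && cdsv[ci + r] == genv[gi + r]) r <- r + 1L
    if (r > 0L && ci + r - 1L >= n) {
      return(matrix(c(gi, gi + (n - ci)), ncol = 2,
                    dimnames = list(NULL, c("start", "end"))))
    }
    if (r == 0L) { failed[[key]] <- TRUE; return(NULL) }
    for (s in seq(r, 1L)) {
      ci2 <- ci + s
      j <- gi + s                        # first intron base
      if (gt_only && !(j + 1L <= L && genv[j] == "G" && genv[j + 1L] == "T"))
        next
      e <- j + 3L                        # minimal intron length 4
      while (e <= L - (n - ci2 + 1L)) {
        if (genv[e - 1L] == "A" && genv[e] == "G") {
          rest <- solve(ci2, e + 1L)
          if (!is.null(rest)) {
            return(rbind(c(start = gi, end = gi + s - 1L), rest))
          }
        }
        e <- e + 1L
      }
    }
    failed[[key]] <- TRUE
    NULL
  }
  for (gi in which(genv == cdsv[1L])) {
    res <- solve(1L, gi)
    if (!is.null(res)) return(res)
  }
  NULL
}

#' Infer exon coordinates by exact-matching a CDS against genomic DNA
#'
#' Greedy longest-exact-match chaining with backtracking; intron boundaries
#' with canonical GT..AG dinucleotides are preferred.  The plus strand is
#' tried first, then the reverse complement; exons are always returned in
#' ascending genomic (plus-strand) coordinates.
#'
#' @param cds coding sequence (character scalar)
#' @param genomic genomic sequence containing the gene (character scalar)
#' @return list with \code{exons} (matrix start,end, 1-based inclusive) and
#'   \code{strand}
#' @export
infer_gene_structure <- function(cds, genomic) {
  cdsv <- strsplit(toupper(cds), "")[[1]]
  genv <- strsplit(toupper(genomic), "")[[1]]
  if (!length(cdsv)) stop("empty CDS")
  rcv <- strsplit(revcomp(genomic), "")[[1]]
  L <- length(genv)
  # canonical GT..AG parses on either strand take precedence over any
  # non-canonical parse
  for (gt_only in c(TRUE, FALSE)) {
    ex <- .chain_cds(cdsv, genv, gt_only = gt_only)
    if (!is.null(ex)) return(list(exons = ex, strand = "+"))
    ex <- .chain_cds(cdsv, rcv, gt_only = gt_only)
    if (!is.null(ex)) {
      flipped <- cbind(start = L - ex[, "end"] + 1L,
                       end = L - ex[, "start"] + 1L)
      return(list(exons = flipped[order(flipped[, "start"]), , drop = FALSE],
                  strand = "-"))
    }
  }
  stop("CDS is not derivable from the genomic sequence")
}

#' Map introns onto bHLH domain coordinates
#'
#' Each intron falling inside the domain's codon span is reported as the
#' profile index of the codon it interrupts (phase 1/2) or the codon
#' immediately 3' of it (phase 0), plus the phase.  Introns outside the
#' domain are ignored for pattern typing.  An intron landing on a loop
#' residue with no profile coordinate gets \code{domain_position = NA}.
#'
#' @param exons exon matrix (start, end) in ascending genomic order
#' @param hit the gene's accepted \code{domain_hit}
#' @param gene gene annotation supplying \code{gene_id} and \code{strand}
#' @return intron assignment: list with \code{gene_id}, \code{events}
#'   (data.frame \code{domain_position}, \code{phase}) and
#'   \code{pattern_id} (\code{"intronless"} when no domain introns,
#'   otherwise \code{NA} until [assign_pattern()])
#' @export
map_introns_to_domain <- function(exons, hit, gene) {
  strand <- gene$strand %||% "+"
  lens <- exons[, "end"] - exons[, "start"] + 1L
  if (strand == "-") lens <- rev(lens)   # transcription order
  n_introns <- length(lens) - 1L
  events <- data.frame(domain_position = integer(), phase = integer())
  if (n_introns > 0L) {
    cum <- cumsum(lens)[seq_len(n_introns)]  # CDS bases before each intron
    for (c_ in cum) {
      phase <- c_ %% 3L
      q <- c_ %/% 3L + 1L                    # codon index (protein position)
      if (q < hit$start || q > hit$end) next
      pidx <- names(hit$pos_map)[!is.na(hit$pos_map) & hit$pos_map == q]
      events <- rbind(events, data.frame(
        domain_position = if (length(pidx)) as.integer(pidx[1]) else NA_integer_,
        phase = phase))
    }
  }
  list(gene_id = gene$gene_id %||% hit$protein_id, events = events,
       pattern_id = if (nrow(events) == 0L) "intronless" else NA_character_)
}

#' Load an intron-pattern catalog
#'
#' @param path TSV with columns \code{pattern_id}, \code{positions}
#'   (comma-separated profile indices) and optional \code{phases};
#'   \code{NULL} loads the shipped catalog (pattern IV prefilled)
#' @return named list: pattern id -> list(positions, phases)
#' @export
load_pattern_catalog <- function(path = NULL) {
  if (is.null(path)) path <- extdata_path("intron_patterns.tsv")
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    colClasses = "character")
  if (anyDuplicated(tab$pattern_id)) stop("duplicate pattern label")
  out <- lapply(seq_len(nrow(tab)), function(i) {
    ph <- tab$phases[i] %||% ""
    list(positions = as.integer(strsplit(tab$positions[i], ",")[[1]]),
         phases = if (!is.na(ph) && nzchar(ph))
           as.integer(strsplit(ph, ",")[[1]]) else NULL)
  })
  setNames(out, tab$pattern_id)
}

#' Assign a catalog pattern label to an intron assignment
#'
#' The label of the catalog entry whose position set equals the event
#' positions (phases compared only when the catalog specifies them);
#' \code{"intronless"} for an empty event list, \code{"novel"} otherwise.
#'
#' @param assignment from [map_introns_to_domain()]
#' @param catalog from [load_pattern_catalog()]
#' @return pattern label (character scalar)
#' @export
assign_pattern <- function(assignment, catalog) {
  ev <- assignment$events
  if (nrow(ev) == 0L) return("intronless")
  if (anyNA(ev$domain_position)) return("novel")
  for (lab in names(catalog)) {
    entry <- catalog[[lab]]
    if (is.null(entry$phases)) {
      if (setequal(ev$domain_position, entry$positions)) return(lab)
    } else {
      a <- sort(paste(ev$domain_position, ev$phase))
      b <- sort(paste(entry$positions, entry$phases))
      if (identical(a, b)) return(lab)
    }
  }
  "novel"
}

#' Discover intron patterns by clustering identical position sets
#'
#' Assignments sharing the same domain-position set get one label, labels
#' ordered by frequency rank (\code{P1} most common).
#'
#' @param assignments list of intron assignments
#' @return data.frame with \code{gene_id}, \code{position_set},
#'   \code{discovered_pattern}
#' @export
discover_patterns <- function(assignments) {
  keys <- vapply(assignments, function(a) {
    if (nrow(a$events) == 0L) "intronless"
    else paste(sort(a$events$domain_position), collapse = ",")
  }, character(1))
  ids <- vapply(assignments, `[[`, "", "gene_id")
  tb <- sort(table(keys[keys != "intronless"]), decreasing = TRUE)
  labels <- setNames(paste0("P", seq_along(tb)), names(tb))
  labels["intronless"] <- "intronless"
  data.frame(gene_id = ids, position_set = keys,
             discovered_pattern = unname(labels[keys]),
             stringsAsFactors = FALSE)
}
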