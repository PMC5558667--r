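.load_scale <- function(file, value_col) {
  key <- paste0("scale_", file)
  if (!is.null(.bhlhfam_cache[[key]])) return(.bhlhfam_cache[[key]])
  tab <- read.delim(extdata_path(file), comment.char = "#",
                    stringsAsFactors = FALSE)
  v <- setNames(tab[[value_col]], tab$residue)
  .bhlhfam_cache[[key]] <- v
  v
}

.load_pka <- function(path = NULL) {
  if (is.null(path)) path <- extdata_path("pka_expasy.tsv")
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch sum over the termini and ionisable side chains
#' (D, E, C, Y negative; H, K, R positive) with the configured pKa set.
#'
#' @param counts named integer vector of residue counts
#' @param ph pH value
#' @param pka pKa table (data.frame group/pka/sign)
#' @return net charge (elementary charges)
#' @keywords internal
net_charge <- function(counts, ph, pka) {
  q <- 0
  for (i in seq_len(nrow(pka))) {
    g <- pka$group[i]
    n <- if (g %in% c("Nterm", "Cterm")) 1L else unname(counts[g])
    if (is.na(n) || n == 0L) next
    if (pka$sign[i] > 0) {
      q <- q + n / (1 + 10^(ph - pka$pka[i]))
    } else {
      q <- q - n / (1 + 10^(pka$pka[i] - ph))
    }
  }
  q
}

#' Isoelectric point by bisection
#'
#' The net-charge function is strictly decreasing in pH, so the pI is its
#' unique root on [0, 14]; bisection runs until |net charge| < 1e-4.
#'
#' @param sequence protein sequence (character scalar)
#' @param pka optional pKa table path
#' @return pI in pH units
#' @export
isoelectric_point <- function(sequence, pka = NULL) {
  pk <- if (is.null(pka)) .load_pka() else .load_pka(pka)
  r <- strsplit(toupper(sequence), "")[[1]]
  r <- r[r %in% AA20]
  counts <- table(factor(r, levels = AA20))
  lo <- 0; hi <- 14
  repeat {
    mid <- (lo + hi) / 2
    q <- net_charge(counts, mid, pk)
    if (abs(q) < 1e-4 || (hi - lo) < 1e-9) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
}

#' Physicochemical properties of a protein
#'
#' Length, molecular weight (average isotopic residue masses plus one
#' water), isoelectric point (bisection on the net-charge function with an
#' ExPASy-style pKa set), GRAVY (mean Kyte-Doolittle hydropathy) and charged
#' residue counts (Asp+Glu negative, Arg+Lys positive).  \code{X} residues
#' are excluded from GRAVY, pI and mass with a warning.
#'
#' @param protein single-row data.frame from [read_fasta()] or a character
#'   scalar
#' @return data.frame row: \code{protein_id}, \code{length}, \code{mw},
#'   \code{pi}, \code{gravy}, \code{n_negative}, \code{n_positive}
#' @export
protein_properties <- function(protein) {
  if (is.data.frame(protein)) {
    id <- protein$id[1L]; seq <- protein$sequence[1L]
  } else {
    id <- names(protein)[1L] %||% "protein"; seq <- unname(protein[1L])
  }
  r <- strsplit(toupper(seq), "")[[1]]
  n_all <- length(r)
  if (any(r == "X")) {
    warning("excluding ", sum(r == "X"), " X residue(s) of ", id,
            " from GRAVY/pI/mass")
  }
  bad <- setdiff(unique(r), c(AA20, "X"))
  if (length(bad)) stop("invalid protein residue(s): ", paste(bad, collapse = ""))
  r <- r[r %in% AA20]
  kd <- .load_scale("kyte_doolittle.tsv", "hydropathy")
  masses <- .load_scale("residue_masses.tsv", "mass")
  data.frame(
    protein_id = id,
    length = n_all,
    mw = sum(masses[r]) + 18.0153,
    pi = isoelectric_point(paste(r, collapse = "")),
    gravy = mean(kd[r]),
    n_negative = sum(r %in% c("D", "E")),
    n_positive = sum(r %in% c("R", "K")),
    stringsAsFactors = FALSE)
}

#' Properties for a whole proteome
#' @param proteins data.frame from [read_fasta()]
#' @return data.frame, one row per protein
#' @export
proteome_properties <- function(proteins) {
  do.call(rbind, lapply(seq_len(nrow(proteins)), function(i)
    protein_properties(proteins[i, , drop = FALSE])))
}
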