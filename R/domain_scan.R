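#' Align one protein to the consensus profile
#'
#' Exhaustive sliding-window search over all start positions and loop lengths
#' (\code{profile$loop_min}..\code{profile$loop_max}): the basic region and
#' both helices are matched at fixed length while the loop is matched with
#' variable length, so positions after the loop keep their profile numbering
#' regardless of the actual loop.  Mismatches are counted only at conserved
#' positions (a gap at a conserved position counts as a mismatch).  Ties are
#' broken by smallest start coordinate, then smallest loop length.
#'
#' @param protein a single-row data.frame from [read_fasta()], or a named
#'   character scalar (name = protein id)
#' @param profile a [load_profile()] object
#' @return a \code{domain_hit} (list with \code{protein_id}, \code{start},
#'   \code{end}, \code{loop_len}, \code{residue_at}, \code{pos_map},
#'   \code{mismatch_count}, \code{accepted}) or \code{NULL} when the protein
#'   is shorter than the minimal window
#' @export
align_to_profile <- function(protein, profile) {
  if (is.data.frame(protein)) {
    id <- protein$id[1L]; seq <- protein$sequence[1L]
  } else {
    id <- names(protein)[1L] %||% "protein"; seq <- unname(protein[1L])
  }
  x <- strsplit(seq, "")[[1]]
  L <- length(x)
  p <- profile$positions
  n_idx <- nrow(p)
  has_loop <- length(profile$loop_span) == 2L
  loop_first <- if (has_loop) profile$loop_span[1] else n_idx + 1L
  loop_last <- if (has_loop) profile$loop_span[2] else n_idx
  npre <- loop_first - 1L
  npost <- n_idx - loop_last
  loop_lens <- if (has_loop) seq(profile$loop_min, profile$loop_max) else 0L

  cons_idx <- p$index[p$conserved]
  offset_of <- function(idx, l) {
    ifelse(idx < loop_first, idx,
      ifelse(idx > loop_last, npre + l + (idx - loop_last),
        ifelse(idx - loop_first + 1L <= l, npre + (idx - loop_first + 1L), NA_integer_)))
  }

  best <- NULL
  for (l in loop_lens) {
    w <- npre + l + npost
    if (L < w) next
    starts <- seq_len(L - w + 1L)
    mism <- integer(length(starts))
    for (ci in cons_idx) {
      off <- offset_of(ci, l)
      if (is.na(off)) { mism <- mism + 1L; next }
      res <- x[starts + off - 1L]
      mism <- mism + !(res %in% profile$allowed[[ci]])
    }
    m <- min(mism)
    s <- starts[which.max(mism == m)]   # first (smallest) start at the minimum
    if (is.null(best) || m < best$m || (m == best$m && s < best$s)) {
      best <- list(m = m, s = s, l = l, w = w)
    }
  }
  if (is.null(best)) return(NULL)

  off_all <- offset_of(p$index, best$l)
  residue_at <- rep(NA_character_, n_idx)
  mapped <- !is.na(off_all)
  residue_at[mapped] <- x[best$s + off_all[mapped] - 1L]
  names(residue_at) <- p$index
  pos_map <- as.integer(ifelse(mapped, best$s + off_all - 1L, NA_integer_))
  names(pos_map) <- p$index
  structure(list(protein_id = id, start = best$s, end = best$s + best$w - 1L,
                 loop_len = best$l, residue_at = residue_at,
                 pos_map = pos_map, mismatch_count = best$m,
                 accepted = NA),
            class = "domain_hit")
}

#' Scan a proteome for bHLH domains
#'
#' Runs [align_to_profile()] on every protein, applies the mismatch budget
#' (default: up to nine mismatches at the 19 conserved positions) and returns
#' the accepted hits ordered by protein id.
#'
#' @param proteins data.frame from [read_fasta()]
#' @param profile a [load_profile()] object
#' @param max_mismatch maximum allowed mismatches at conserved positions
#' @return list of accepted \code{domain_hit} objects
#' @export
scan_proteome <- function(proteins, profile, max_mismatch = 9L) {
  stopifnot(is.data.frame(proteins), nrow(proteins) > 0L)
  ord <- order(proteins$id)
  hits <- list()
  for (i in ord) {
    h <- align_to_profile(proteins[i, , drop = FALSE], profile)
    if (is.null(h)) next
    h$accepted <- h$mismatch_count <= max_mismatch
    if (h$accepted) hits[[length(hits) + 1L]] <- h
  }
  hits
}

#' Tabulate domain hits
#' @param hits list of \code{domain_hit}
#' @return data.frame with one row per hit
#' @export
hits_table <- function(hits) {
  if (!length(hits)) {
    return(data.frame(protein_id = character(), start = integer(),
                      end = integer(), loop_len = integer(),
                      mismatch_count = integer(), accepted = logical(),
                      domain_seq = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(hits, function(h) data.frame(
    protein_id = h$protein_id, start = h$start, end = h$end,
    loop_len = h$loop_len, mismatch_count = h$mismatch_count,
    accepted = isTRUE(h$accepted),
    domain_seq = paste(ifelse(is.na(h$residue_at), "-", h$residue_at),
                       collapse = ""),
    stringsAsFactors = FALSE)))
}

#' Per-position conservation across accepted hits
#'
#' For each profile index, the frequency of the modal residue among non-gap
#' entries; indices whose modal frequency exceeds \code{threshold} are
#' flagged conserved-in-dataset (the classic "more than 50% identity" rule).
#'
#' @param hits non-empty list of \code{domain_hit}
#' @param threshold flagging threshold (strict inequality)
#' @return data.frame with \code{index}, \code{modal_residue},
#'   \code{frequency}, \code{n}, \code{conserved_in_dataset}
#' @export
position_conservation <- function(hits, threshold = 0.5) {
  if (!length(hits)) stop("no hits: conservation undefined")
  idx <- names(hits[[1]]$residue_at)
  mat <- vapply(hits, function(h) h$residue_at, character(length(idx)))
  if (is.null(dim(mat))) mat <- matrix(mat, ncol = length(hits))
  rows <- lapply(seq_along(idx), function(i) {
    r <- mat[i, ]
    r <- r[!is.na(r)]
    if (!length(r)) {
      return(data.frame(index = as.integer(idx[i]), modal_residue = NA_character_,
                        frequency = NA_real_, n = 0L,
                        conserved_in_dataset = FALSE, stringsAsFactors = FALSE))
    }
    tb <- sort(table(r), decreasing = TRUE)
    freq <- as.numeric(tb[1L]) / length(r)
    data.frame(index = as.integer(idx[i]), modal_residue = names(tb)[1L],
               frequency = freq, n = length(r),
               conserved_in_dataset = freq > threshold, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
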