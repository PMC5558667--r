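#' Load a bHLH consensus profile
#'
#' The profile is a per-position allowed-residue model of the domain with
#' region labels (\code{basic}, \code{helix1}, \code{loop}, \code{helix2})
#' and conserved-position flags.  Mismatches during scanning are counted only
#' at conserved positions.  The shipped default encodes the classic
#' 19-conserved-residue layout (basic 5, helix1 5, loop 1, helix2 8) and the
#' labelled positions the DNA-binding classifier depends on.
#'
#' @param path profile TSV with columns \code{index}, \code{region},
#'   \code{allowed_residues} (\code{*} = any), \code{conserved},
#'   \code{label}, \code{consensus}; \code{NULL} loads the shipped default
#' @param loop_min,loop_max bounds on the loop length considered when
#'   matching (residues)
#' @return object of class \code{bhlh_profile}
#' @export
load_profile <- function(path = NULL, loop_min = 5L, loop_max = 25L) {
  if (is.null(path)) path <- extdata_path("bhlh_consensus_profile.tsv")
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    colClasses = c(label = "character"))
  need <- c("index", "region", "allowed_residues", "conserved")
  if (!all(need %in% names(tab)))
    stop("profile table must have columns: ", paste(need, collapse = ", "))
  if (is.null(tab$label)) tab$label <- ""
  tab$label[is.na(tab$label)] <- ""
  if (anyDuplicated(tab$index)) stop("duplicate profile index")
  if (!identical(as.integer(tab$index), seq_len(nrow(tab))))
    stop("profile indices must run 1..n without gaps")
  regions <- c("basic", "helix1", "loop", "helix2")
  if (!all(tab$region %in% regions))
    stop("unknown region: ", setdiff(tab$region, regions)[1L])
  allowed <- lapply(tab$allowed_residues, function(a) {
    if (identical(a, "*")) return(AA20)
    r <- strsplit(a, "")[[1]]
    if (!length(r) || !all(r %in% AA20))
      stop("empty or invalid allowed-residue set: '", a, "'")
    r
  })
  loop_idx <- tab$index[tab$region == "loop"]
  if (length(loop_idx) && !identical(loop_idx, seq(min(loop_idx), max(loop_idx))))
    stop("loop region must be contiguous")
  loop_span <- if (length(loop_idx)) c(min(loop_idx), max(loop_idx)) else integer()
  # a full-domain profile (all four regions) must carry the classifier labels
  if (all(regions %in% tab$region)) {
    required <- c("His/Lys-9", "Glu-13", "Arg-14", "Gln-15", "Arg-16",
                  "Arg-17", "Gln-22", "Leu-27", "Leu-54")
    miss <- setdiff(required, tab$label)
    if (length(miss))
      stop("profile missing labelled position(s): ", paste(miss, collapse = ", "))
  }
  dup_lab <- tab$label[nzchar(tab$label)][duplicated(tab$label[nzchar(tab$label)])]
  if (length(dup_lab)) stop("duplicate profile label: ", dup_lab[1L])
  structure(list(
    positions = data.frame(index = as.integer(tab$index), region = tab$region,
                           conserved = as.logical(tab$conserved),
                           label = tab$label,
                           consensus = tab$consensus %||% rep(NA_character_, nrow(tab)),
                           stringsAsFactors = FALSE),
    allowed = allowed,
    loop_span = loop_span,
    loop_min = as.integer(loop_min), loop_max = as.integer(loop_max)
  ), class = "bhlh_profile")
}

#' @export
print.bhlh_profile <- function(x, ...) {
  p <- x$positions
  cat("bHLH consensus profile: ", nrow(p), " positions, ",
      sum(p$conserved), " conserved (",
      paste(vapply(c("basic", "helix1", "loop", "helix2"),
                   function(r) sum(p$conserved & p$region == r), 0L),
            collapse = "/"), ")\n", sep = "")
  if (length(x$loop_span))
    cat("variable loop at indices ", x$loop_span[1], "-", x$loop_span[2],
        " (matched length ", x$loop_min, "-", x$loop_max, ")\n", sep = "")
  invisible(x)
}

#' Profile index carrying a given label
#' @param profile a \code{bhlh_profile}
#' @param label label text, e.g. \code{"Glu-13"}
#' @return integer profile index
#' @export
profile_label_index <- function(profile, label) {
  i <- profile$positions$index[profile$positions$label == label]
  if (!length(i)) stop("profile lacks labelled position: ", label)
  i[1L]
}

#' Consensus domain sequence of a profile at reference loop length
#' @param profile a \code{bhlh_profile}
#' @return character scalar
#' @export
profile_consensus <- function(profile) {
  cons <- profile$positions$consensus
  if (anyNA(cons)) stop("profile has no consensus column")
  paste(cons, collapse = "")
}
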