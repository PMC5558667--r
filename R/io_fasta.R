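#' Read a FASTA file into a sequence record table
#'
#' Sequences are uppercased and wrapped lines concatenated.  The record id is
#' the first whitespace-delimited token of the header; the remainder is kept
#' as the description.
#'
#' @param path path to a FASTA file
#' @return data.frame with columns \code{id}, \code{description},
#'   \code{sequence}; zero rows for an empty file
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) {
    return(data.frame(id = character(), description = character(),
                      sequence = character(), stringsAsFactors = FALSE))
  }
  ss <- Biostrings::readBStringSet(path)
  headers <- names(ss)
  id <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  dup <- id[duplicated(id)]
  if (length(dup)) stop("duplicate FASTA id: ", dup[1L])
  if (any(!nzchar(id))) stop("empty FASTA id in ", path)
  seqs <- toupper(as.character(ss))
  if (any(!nzchar(seqs))) stop("empty sequence for id: ", id[!nzchar(seqs)][1L])
  data.frame(id = id, description = desc, sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Write sequence records as FASTA (60-column wrap)
#'
#' @param records data.frame with columns \code{id}, \code{sequence} and
#'   optionally \code{description}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
write_fasta <- function(records, path) {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  ss <- Biostrings::BStringSet(records$sequence)
  desc <- records$description %||% rep("", nrow(records))
  names(ss) <- ifelse(nzchar(desc), paste(records$id, desc), records$id)
  Biostrings::writeXStringSet(ss, filepath = path, width = 60L)
  invisible(path)
}
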