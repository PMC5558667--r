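#' Count basic residues in the basic region of a domain hit
#'
#' Counts Arg/Lys/His at basic-region profile positions; gaps are excluded.
#' With \code{mode = "literal"} it instead counts all aligned residues in
#' the basic region (the literal reading of "fewer than six residues").
#'
#' @param hit an accepted \code{domain_hit}
#' @param profile a [load_profile()] object
#' @param mode \code{"basic_residues"} (default) or \code{"literal"}
#' @return integer count
#' @export
count_basic_residues <- function(hit, profile, mode = c("basic_residues", "literal")) {
  mode <- match.arg(mode)
  idx <- profile$positions$index[profile$positions$region == "basic"]
  res <- hit$residue_at[as.character(idx)]
  res <- res[!is.na(res)]
  if (mode == "literal") length(res) else sum(res %in% c("R", "K", "H"))
}

.res_at <- function(hit, profile, label) {
  i <- profile_label_index(profile, label)
  hit$residue_at[[as.character(i)]]
}

#' Classify the DNA-binding category of a domain
#'
#' Four-way residue-rule classification.  A basic region with fewer than six
#' basic residues cannot contact DNA (\code{NON_DNA_BINDING}).  Otherwise
#' Glu-13 together with Arg-16 defines E-box recognition; within E-box
#' binders the triple His/Lys-9 + Glu-13 + Arg-17 confers G-box specificity
#' (\code{G_BOX} vs \code{E_BOX_NON_G}).  E-box non-recognisers with a basic
#' region are unspecific binders (\code{NON_E_BOX_BINDER}).  A gap at a
#' labelled position makes its flag false.
#'
#' @inheritParams count_basic_residues
#' @param basic_min minimum basic residues for DNA binding (default 6)
#' @return data.frame row (a binding call) with the category, basic count
#'   and the residue flags justifying it
#' @export
classify_binding <- function(hit, profile, basic_min = 6L,
                             mode = c("basic_residues", "literal")) {
  mode <- match.arg(mode)
  if (!isTRUE(hit$accepted)) stop("classify_binding requires an accepted hit")
  bc <- count_basic_residues(hit, profile, mode)
  r9 <- .res_at(hit, profile, "His/Lys-9")
  flags <- c(
    has_his_lys9 = isTRUE(r9 %in% c("H", "K")),
    has_glu13 = isTRUE(.res_at(hit, profile, "Glu-13") == "E"),
    has_arg16 = isTRUE(.res_at(hit, profile, "Arg-16") == "R"),
    has_arg17 = isTRUE(.res_at(hit, profile, "Arg-17") == "R"))
  dim_flags <- dimer_tetramer_flags(hit, profile)
  category <- if (bc < basic_min) {
    "NON_DNA_BINDING"
  } else if (flags[["has_glu13"]] && flags[["has_arg16"]]) {
    if (flags[["has_his_lys9"]] && flags[["has_arg17"]]) "G_BOX" else "E_BOX_NON_G"
  } else {
    "NON_E_BOX_BINDER"
  }
  data.frame(protein_id = hit$protein_id, category = category,
             basic_count = bc,
             has_his_lys9 = flags[["has_his_lys9"]],
             has_glu13 = flags[["has_glu13"]],
             has_arg16 = flags[["has_arg16"]],
             has_arg17 = flags[["has_arg17"]],
             has_leu27 = dim_flags[["has_leu27"]],
             has_leu54 = dim_flags[["has_leu54"]],
             tetramer_ready = dim_flags[["tetramer_ready"]],
             stringsAsFactors = FALSE)
}

#' Dimerization / tetramerization residue flags
#'
#' Leu-27 (helix 1) and Leu-54 (helix 2) mark dimerization competence;
#' the Arg-14 + Gln-15 + Gln-22 triple marks potential tetramer formation
#' (the MYC2-style enhanced DNA clamp).
#'
#' @inheritParams count_basic_residues
#' @return named logical vector: \code{has_leu27}, \code{has_leu54},
#'   \code{tetramer_ready}
#' @export
dimer_tetramer_flags <- function(hit, profile) {
  c(has_leu27 = isTRUE(.res_at(hit, profile, "Leu-27") == "L"),
    has_leu54 = isTRUE(.res_at(hit, profile, "Leu-54") == "L"),
    tetramer_ready = isTRUE(.res_at(hit, profile, "Arg-14") == "R") &&
      isTRUE(.res_at(hit, profile, "Gln-15") == "Q") &&
      isTRUE(.res_at(hit, profile, "Gln-22") == "Q"))
}

#' Classify all accepted hits
#' @param hits list of accepted \code{domain_hit}
#' @param profile a [load_profile()] object
#' @param ... passed to [classify_binding()]
#' @return data.frame of binding calls, one row per hit
#' @export
classify_all <- function(hits, profile, ...) {
  if (!length(hits)) {
    return(data.frame(protein_id = character(), category = character(),
                      basic_count = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(hits, classify_binding, profile = profile, ...))
}
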