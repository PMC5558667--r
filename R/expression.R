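#' Log2-transform an expression matrix
#'
#' Elementwise \eqn{\log_2(x + pseudocount)}; the pseudocount keeps zeros
#' finite for heatmap display.
#'
#' @param expr numeric matrix or data.frame of nonnegative values
#' @param pseudocount added before the log (default 1)
#' @return transformed matrix
#' @export
log2_matrix <- function(expr, pseudocount = 1) {
  m <- as.matrix(expr)
  if (any(m < 0)) stop("expression values must be >= 0")
  log2(m + pseudocount)
}

#' Relative expression by the 2^(-ddCt) method
#'
#' \deqn{2^{-[(Ct_{target,treat} - Ct_{ref,treat}) -
#'            (Ct_{target,ctrl} - Ct_{ref,ctrl})]}}
#'
#' @param ct_target_treat,ct_ref_treat Ct of target and reference gene in
#'   the treated/test condition
#' @param ct_target_ctrl,ct_ref_ctrl Ct of target and reference gene in the
#'   control condition
#' @return fold change (positive)
#' @export
ddct <- function(ct_target_treat, ct_ref_treat, ct_target_ctrl, ct_ref_ctrl) {
  stopifnot(is.finite(ct_target_treat), is.finite(ct_ref_treat),
            is.finite(ct_target_ctrl), is.finite(ct_ref_ctrl))
  dd <- (ct_target_treat - ct_ref_treat) - (ct_target_ctrl - ct_ref_ctrl)
  2^(-dd)
}

#' Fold changes for a qPCR Ct table
#'
#' Expects triplicate-mean Ct columns for target and reference gene under a
#' test condition and a control; fold change per row by [ddct()].
#'
#' @param qpcr data.frame with columns \code{gene_id}, \code{condition},
#'   \code{ct_target}, \code{ct_reference}, \code{ct_target_ctrl},
#'   \code{ct_reference_ctrl}
#' @return input with an added \code{relative_expression} column
#' @export
qpcr_fold_changes <- function(qpcr) {
  need <- c("ct_target", "ct_reference", "ct_target_ctrl", "ct_reference_ctrl")
  stopifnot(all(need %in% names(qpcr)))
  qpcr$relative_expression <- mapply(ddct, qpcr$ct_target, qpcr$ct_reference,
                                     qpcr$ct_target_ctrl, qpcr$ct_reference_ctrl)
  qpcr
}

#' Read a genes-by-samples expression matrix from TSV
#' @param path TSV with gene ids in the first column and a header row
#' @return numeric matrix with gene rownames
#' @export
read_expression_matrix <- function(path) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  storage.mode(m) <- "double"
  m
}
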