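#' Pairwise p-distance with pairwise gap deletion
#'
#' Proportion of differing sites among columns where neither sequence has a
#' gap (\code{-}).
#'
#' @param aligned_a,aligned_b equal-length aligned sequences (character
#'   scalars)
#' @return fraction in [0, 1]
#' @export
p_distance <- function(aligned_a, aligned_b) {
  a <- strsplit(aligned_a, "")[[1]]
  b <- strsplit(aligned_b, "")[[1]]
  if (length(a) != length(b)) stop("aligned sequences differ in length")
  ok <- a != "-" & b != "-"
  if (!any(ok)) stop("no comparable (gap-free) columns")
  mean(a[ok] != b[ok])
}

#' Distance matrix over an alignment
#'
#' @param alignment named character vector of equal-length aligned sequences
#' @param model \code{"p"} (p-distance) or \code{"poisson"}
#'   (Poisson correction, \eqn{-\ln(1-p)})
#' @return symmetric matrix with zero diagonal, labelled by sequence names
#' @export
dist_matrix <- function(alignment, model = c("p", "poisson")) {
  model <- match.arg(model)
  n <- length(alignment)
  labels <- names(alignment)
  if (is.null(labels) || anyDuplicated(labels))
    stop("alignment must carry unique names")
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  if (n > 1) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    p <- p_distance(alignment[[i]], alignment[[j]])
    v <- if (model == "poisson") -log(1 - p) else p
    d[i, j] <- d[j, i] <- v
  }
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration with the standard Q-criterion.  Ties in Q are
#' broken by the lexicographically smallest pair of representative labels
#' (the smallest leaf label in each subtree).  Negative branch lengths are
#' reported as computed, with a warning, never clamped.  The last three
#' nodes are joined by the three-point formulas, giving the usual unrooted
#' topology with a trifurcating root.
#'
#' @param d symmetric distance matrix with row/column names (or a
#'   \code{dist})
#' @return an \code{ape::phylo} tree
#' @export
nj_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  labels <- rownames(d)
  n <- nrow(d)
  if (is.null(labels)) stop("distance matrix must have labels")
  if (n < 3) stop("neighbor joining requires at least 3 taxa")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix is not symmetric")
  frag <- labels
  rep_ <- labels
  D <- d
  neg <- FALSE
  while (nrow(D) > 3) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    tol <- 1e-12 * max(1, abs(qmin))
    cand <- which(Q <= qmin + tol, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    keys <- apply(cand, 1L, function(ij) {
      pr <- sort(c(rep_[ij[1]], rep_[ij[2]]))
      paste(pr, collapse = "\r")
    })
    pick <- cand[order(keys)[1L], ]
    i <- pick[[1]]; j <- pick[[2]]
    bi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    bj <- D[i, j] - bi
    if (bi < 0 || bj < 0) neg <- TRUE
    newfrag <- sprintf("(%s:%.17g,%s:%.17g)", frag[i], bi, frag[j], bj)
    newrep <- min(rep_[i], rep_[j])
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    frag <- c(frag[keep], newfrag)
    rep_ <- c(rep_[keep], newrep)
  }
  a <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  cc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  if (min(a, b, cc) < 0) neg <- TRUE
  if (neg) warning("negative branch length(s) in NJ tree (reported, not clamped)")
  nwk <- sprintf("(%s:%.17g,%s:%.17g,%s:%.17g);",
                 frag[1], a, frag[2], b, frag[3], cc)
  ape::read.tree(text = nwk)
}

# tip labels descending from every node (index = ape node id)
.clade_tips <- function(tr) {
  n <- length(tr$tip.label)
  tips <- vector("list", n + tr$Nnode)
  for (i in seq_len(n)) tips[[i]] <- tr$tip.label[i]
  tr2 <- stats::reorder(tr, "postorder")
  for (k in seq_len(nrow(tr2$edge))) {
    p <- tr2$edge[k, 1]; ch <- tr2$edge[k, 2]
    tips[[p]] <- c(tips[[p]], tips[[ch]])
  }
  tips
}

# canonical non-trivial bipartition key per internal node ('' = trivial/root)
.bipart_keys <- function(tr) {
  n <- length(tr$tip.label)
  all_t <- sort(tr$tip.label)
  ref <- all_t[1]
  tips <- .clade_tips(tr)
  ids <- (n + 1):(n + tr$Nnode)
  keys <- setNames(rep(NA_character_, length(ids)), ids)
  for (nd in ids) {
    cl <- sort(tips[[nd]])
    side <- if (ref %in% cl) setdiff(all_t, cl) else cl
    if (length(side) < 2 || length(side) > n - 2) next
    keys[as.character(nd)] <- paste(side, collapse = "|")
  }
  keys
}

#' Neighbor-joining tree with bootstrap support
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate and annotates each internal node of the full-data tree with the
#' percentage of replicates containing its bipartition
#' (\code{tree$node.label}; trivial bipartitions and the root get \code{NA}).
#' With the same seed the output is identical.
#'
#' @param alignment named character vector of equal-length aligned sequences
#' @param n_reps number of bootstrap replicates (default 1000)
#' @param seed optional RNG seed
#' @param model distance model, see [dist_matrix()]
#' @return an \code{ape::phylo} with integer supports in \code{node.label}
#' @export
bootstrap_support <- function(alignment, n_reps = 1000L, seed = NULL,
                              model = c("p", "poisson")) {
  model <- match.arg(model)
  if (n_reps < 1) stop("n_reps must be >= 1")
  ncol <- unique(nchar(alignment))
  if (length(ncol) != 1L) stop("alignment sequences differ in length")
  if (ncol < 1L) stop("alignment has no columns")
  if (!is.null(seed)) set.seed(seed)
  chars <- do.call(rbind, strsplit(alignment, ""))
  rownames(chars) <- names(alignment)
  main <- nj_tree(dist_matrix(alignment, model))
  keys <- .bipart_keys(main)
  counts <- setNames(numeric(length(keys)), names(keys))
  for (rep in seq_len(n_reps)) {
    cols <- sample.int(ncol, ncol, replace = TRUE)
    boot_aln <- setNames(apply(chars[, cols, drop = FALSE], 1L, paste,
                               collapse = ""), names(alignment))
    bt <- suppressWarnings(nj_tree(dist_matrix(boot_aln, model)))
    bk <- unique(stats::na.omit(.bipart_keys(bt)))
    counts <- counts + (keys %in% bk)
  }
  sup <- ifelse(is.na(keys), NA_real_, 100 * counts / n_reps)
  main$node.label <- as.character(round(sup))
  main$node.label[is.na(sup)] <- ""
  main
}

#' Cut subfamilies at a bootstrap support threshold
#'
#' Maximal clades whose subtending node support is strictly greater than
#' \code{min_support} become subfamilies, numbered in preorder traversal
#' order (\code{S1}, \code{S2}, ...); leaves in no such clade are reported
#' unassigned.
#'
#' @param tree an \code{ape::phylo} with supports in \code{node.label}
#' @param min_support support threshold (strict inequality; default 50)
#' @return list with \code{assignments} (named character: tip -> subfamily)
#'   and \code{unassigned} (character vector of tips)
#' @export
extract_subfamilies <- function(tree, min_support = 50) {
  n <- length(tree$tip.label)
  if (is.null(tree$node.label)) stop("tree carries no support values")
  sup <- suppressWarnings(as.numeric(tree$node.label))
  tips <- .clade_tips(tree)
  children <- split(tree$edge[, 2], tree$edge[, 1])
  memb <- setNames(character(0), character(0))
  counter <- 0L
  recurse <- function(nd) {
    if (nd <= n) return(invisible(NULL))
    s <- sup[nd - n]
    if (!is.na(s) && s > min_support) {
      counter <<- counter + 1L
      lab <- paste0("S", counter)
      for (t in tips[[nd]]) memb[t] <<- lab
    } else {
      for (ch in children[[as.character(nd)]]) recurse(ch)
    }
    invisible(NULL)
  }
  recurse(n + 1L)
  list(assignments = memb,
       unassigned = setdiff(tree$tip.label, names(memb)))
}
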