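NUC <- c("A", "C", "G", "T")

.codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
}

# per-codon synonymous site count: for each of the 3 positions, the fraction
# of the 3 single-nucleotide changes that are synonymous.  Changes creating a
# stop codon count as nonsynonymous, so syn + nonsyn sites = 3 per codon.
.syn_sites_table <- function() {
  if (!is.null(.bhlhfam_cache$syn_sites)) return(.bhlhfam_cache$syn_sites)
  gc <- .codon_table()
  codons <- names(gc)
  s <- setNames(numeric(length(codons)), codons)
  for (cd in codons) {
    if (gc[[cd]] == "*") { s[cd] <- NA_real_; next }
    nt <- strsplit(cd, "")[[1]]
    syn <- 0
    for (pos in 1:3) for (alt in setdiff(NUC, nt[pos])) {
      mut <- nt; mut[pos] <- alt
      mc <- paste(mut, collapse = "")
      if (gc[[mc]] != "*" && gc[[mc]] == gc[[cd]]) syn <- syn + 1
    }
    s[cd] <- syn / 3
  }
  .bhlhfam_cache$syn_sites <- s
  s
}

# average synonymous/nonsynonymous differences between two codons over all
# minimal mutational pathways; pathways passing through a stop codon are
# excluded (if every pathway does, all are used as a fallback).
.codon_diff <- function(ca, cb, gc) {
  na_ <- strsplit(ca, "")[[1]]
  nb <- strsplit(cb, "")[[1]]
  pos <- which(na_ != nb)
  k <- length(pos)
  if (k == 0L) return(c(sd = 0, nd = 0))
  perms <- switch(as.character(k),
    "1" = list(pos),
    "2" = list(pos, rev(pos)),
    "3" = {
      pm <- list()
      for (i in 1:3) for (j in 1:3) for (l in 1:3)
        if (length(unique(c(i, j, l))) == 3L)
          pm[[length(pm) + 1L]] <- pos[c(i, j, l)]
      pm
    })
  eval_path <- function(order_) {
    cur <- na_
    sd <- 0; nd <- 0
    for (p in order_) {
      prev <- paste(cur, collapse = "")
      cur[p] <- nb[p]
      nxt <- paste(cur, collapse = "")
      if (gc[[nxt]] == "*" && nxt != cb) return(NULL)   # through a stop
      if (gc[[prev]] == gc[[nxt]]) sd <- sd + 1 else nd <- nd + 1
    }
    c(sd = sd, nd = nd)
  }
  res <- lapply(perms, eval_path)
  ok <- !vapply(res, is.null, logical(1))
  if (!any(ok)) {
    res <- lapply(perms, function(order_) {
      cur <- na_; sd <- 0; nd <- 0
      for (p in order_) {
        prev <- paste(cur, collapse = ""); cur[p] <- nb[p]
        nxt <- paste(cur, collapse = "")
        if (gc[[prev]] == gc[[nxt]]) sd <- sd + 1 else nd <- nd + 1
      }
      c(sd = sd, nd = nd)
    })
    ok <- rep(TRUE, length(res))
  }
  mat <- do.call(rbind, res[ok])
  colMeans(mat)
}

.codon_diff_tables <- function() {
  if (!is.null(.bhlhfam_cache$diff_sd)) {
    return(list(sd = .bhlhfam_cache$diff_sd, nd = .bhlhfam_cache$diff_nd))
  }
  gc <- .codon_table()
  codons <- names(gc)[.codon_table() != "*"]
  nsd <- matrix(NA_real_, 64, 64, dimnames = list(names(gc), names(gc)))
  nnd <- nsd
  for (ca in codons) for (cb in codons) {
    if (!is.na(nsd[cb, ca])) {            # symmetric: reuse
      nsd[ca, cb] <- nsd[cb, ca]; nnd[ca, cb] <- nnd[cb, ca]; next
    }
    d <- .codon_diff(ca, cb, gc)
    nsd[ca, cb] <- d[["sd"]]; nnd[ca, cb] <- d[["nd"]]
  }
  .bhlhfam_cache$diff_sd <- nsd
  .bhlhfam_cache$diff_nd <- nnd
  list(sd = nsd, nd = nnd)
}

.split_codons <- function(cds) {
  if (nchar(cds) %% 3 != 0) stop("CDS length not divisible by 3")
  substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
}

#' Translate a CDS (standard genetic code)
#' @param cds DNA string, length divisible by 3
#' @return protein string; terminal stop dropped
#' @export
translate_cds <- function(cds) {
  gc <- .codon_table()
  aa <- gc[.split_codons(toupper(cds))]
  if (anyNA(aa)) stop("CDS contains a non-ACGT codon")
  if (length(aa) && aa[length(aa)] == "*") aa <- aa[-length(aa)]
  paste(aa, collapse = "")
}

#' Back-translate a protein alignment onto codon sequences
#'
#' Expands each gap-free protein alignment column into the corresponding
#' codon pair; columns with a gap in either sequence are dropped.  Each CDS
#' must translate exactly to its aligned (degapped) protein; a terminal stop
#' codon is tolerated and stripped.
#'
#' @param cds_a,cds_b coding sequences (character scalars)
#' @param aln_a,aln_b the aligned protein sequences (equal length, with
#'   \code{-} gaps)
#' @return list with codon vectors \code{a} and \code{b} (equal length)
#' @export
codon_align <- function(cds_a, cds_b, aln_a, aln_b) {
  if (nchar(aln_a) != nchar(aln_b)) stop("protein alignment rows differ in length")
  check <- function(cds, aln, who) {
    cod <- .split_codons(toupper(cds))
    gc <- .codon_table()
    aa <- gc[cod]
    if (anyNA(aa)) stop("non-ACGT codon in CDS ", who)
    if (length(aa) && aa[length(aa)] == "*") {
      cod <- cod[-length(cod)]; aa <- aa[-length(aa)]
    }
    if (any(aa == "*"))
      stop("internal stop codon ", cod[which(aa == "*")[1]], " in CDS ", who)
    prot <- gsub("-", "", aln, fixed = TRUE)
    pa <- strsplit(prot, "")[[1]]
    if (length(aa) != length(pa))
      stop("CDS ", who, " length does not match its aligned protein")
    mismatch <- which(aa != pa)
    if (length(mismatch))
      stop("CDS ", who, " codon ", mismatch[1], " (", cod[mismatch[1]],
           ") translates to ", aa[mismatch[1]], ", protein has ", pa[mismatch[1]])
    cod
  }
  ca <- check(cds_a, aln_a, "a")
  cb <- check(cds_b, aln_b, "b")
  a_chars <- strsplit(aln_a, "")[[1]]
  b_chars <- strsplit(aln_b, "")[[1]]
  ia <- cumsum(a_chars != "-")
  ib <- cumsum(b_chars != "-")
  keep <- a_chars != "-" & b_chars != "-"
  list(a = ca[ia[keep]], b = cb[ib[keep]])
}

#' Nei-Gojobori (1986) Ka/Ks from paired codons
#'
#' Synonymous site fractions per codon from the universal code (changes to
#' stop codons counted nonsynonymous so sites sum to 3 per codon), averaged
#' over the two sequences; differences averaged over all minimal mutational
#' pathways excluding those through stops; Jukes-Cantor correction
#' \eqn{d = -3/4 \ln(1 - 4p/3)} applied to both proportions.  A proportion
#' at or beyond 3/4 leaves the corresponding rate undefined (\code{NA},
#' saturated); \code{ratio} is \code{NA} when \code{ks} is zero or undefined.
#'
#' @param codon_pairs list with codon vectors \code{a} and \code{b}
#'   (from [codon_align()])
#' @return list of class \code{kaks_result}: \code{s_sites}, \code{n_sites},
#'   \code{sd}, \code{nd}, \code{ps}, \code{pn}, \code{ks}, \code{ka},
#'   \code{ratio}, \code{n_codons}
#' @export
ng86_kaks <- function(codon_pairs) {
  a <- toupper(codon_pairs$a)
  b <- toupper(codon_pairs$b)
  if (!length(a) || length(a) != length(b)) stop("need >= 1 paired codon")
  syn <- .syn_sites_table()
  if (anyNA(syn[a]) || anyNA(syn[b])) stop("stop codon among paired codons")
  s_sites <- (sum(syn[a]) + sum(syn[b])) / 2
  n_sites <- 3 * length(a) - s_sites
  tabs <- .codon_diff_tables()
  idx <- cbind(match(a, rownames(tabs$sd)), match(b, colnames(tabs$sd)))
  sd <- sum(tabs$sd[idx])
  nd <- sum(tabs$nd[idx])
  ps <- sd / s_sites
  pn <- nd / n_sites
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  ks <- jc(ps)
  ka <- jc(pn)
  ratio <- if (is.na(ks) || is.na(ka) || ks == 0) NA_real_ else ka / ks
  structure(list(s_sites = s_sites, n_sites = n_sites, sd = sd, nd = nd,
                 ps = ps, pn = pn, ks = ks, ka = ka, ratio = ratio,
                 n_codons = length(a)),
            class = "kaks_result")
}

#' Selection class from a Ka/Ks ratio
#' @param ratio Ka/Ks ratio (may be \code{NA})
#' @return one of \code{"purifying"}, \code{"neutral"}, \code{"positive"},
#'   \code{"undefined"}
#' @export
classify_selection <- function(ratio) {
  if (is.na(ratio)) return("undefined")
  if (ratio < 1) "purifying" else if (ratio > 1) "positive" else "neutral"
}

#' Molecular-clock divergence time from Ks
#'
#' \eqn{T = K_s / (2\lambda)}, reported in millions of years.  The default
#' clock is the grass-standard synonymous rate.
#'
#' @param ks synonymous substitutions per synonymous site (may be \code{NA})
#' @param lambda_syn synonymous substitutions per site per year
#' @return time in Mya (\code{NA} when \code{ks} is undefined)
#' @export
divergence_time <- function(ks, lambda_syn = 6.5e-9) {
  stopifnot(lambda_syn > 0)
  if (is.na(ks)) return(NA_real_)
  if (ks < 0) stop("ks must be >= 0")
  ks / (2 * lambda_syn) / 1e6
}
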