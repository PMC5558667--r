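# shared fixtures: default profile, engineered domains, independent oracles

default_profile <- load_profile()
CONSENSUS <- profile_consensus(default_profile)

embed_domain <- function(domain, n_flank = 30L, c_flank = 20L) {
  set_flank <- function(n) paste(rep("M", n), collapse = "")
  paste0(set_flank(n_flank), domain, set_flank(c_flank))
}

# consensus domain with specific profile positions replaced
mutate_domain <- function(replacements, base = CONSENSUS) {
  d <- strsplit(base, "")[[1]]
  for (i in seq_along(replacements)) {
    d[as.integer(names(replacements)[i])] <- replacements[[i]]
  }
  paste(d, collapse = "")
}

# engineered domain for each DNA-binding category (all within the mismatch
# budget; consensus basic region holds 9 basic residues)
category_domain <- function(category) {
  switch(category,
    G_BOX = CONSENSUS,
    E_BOX_NON_G = mutate_domain(c("9" = "A", "17" = "Q")),
    NON_E_BOX_BINDER = mutate_domain(c("13" = "Q")),
    NON_DNA_BINDING = mutate_domain(c("3" = "A", "4" = "A", "5" = "A",
                                      "6" = "A")),
    stop("unknown category"))
}

aligned_hit <- function(sequence, id = "t1", profile = default_profile) {
  h <- align_to_profile(setNames(sequence, id), profile)
  h$accepted <- TRUE
  h
}

# ---- independent brute-force NG86 oracle (written from the 1986 method) ----
# deliberately naive: explicit loops and recursive pathway enumeration

oracle_ng86 <- function(codons_a, codons_b) {
  GC <- as.character(Biostrings::GENETIC_CODE)
  names(GC) <- names(Biostrings::GENETIC_CODE)
  nucs <- c("A", "C", "G", "T")
  syn_sites_one <- function(codon) {
    nt <- strsplit(codon, "")[[1]]
    s <- 0
    for (p in 1:3) {
      for (n in nucs) {
        if (n == nt[p]) next
        mut <- nt; mut[p] <- n
        mc <- paste(mut, collapse = "")
        if (GC[[mc]] != "*" && GC[[mc]] == GC[[codon]]) s <- s + 1 / 3
      }
    }
    s
  }
  pair_diffs <- function(ca, cb, allow_stops = FALSE) {
    a <- strsplit(ca, "")[[1]]; b <- strsplit(cb, "")[[1]]
    walk <- function(cur, remaining) {
      if (!length(remaining)) return(list(c(0, 0)))
      acc <- list()
      for (i in seq_along(remaining)) {
        p <- remaining[i]
        nxt <- cur; nxt[p] <- b[p]
        cod <- paste(nxt, collapse = "")
        if (!allow_stops && GC[[cod]] == "*" && length(remaining) > 1L) next
        syn_step <- GC[[paste(cur, collapse = "")]] == GC[[cod]]
        for (tl in walk(nxt, remaining[-i])) {
          acc[[length(acc) + 1L]] <- tl + if (syn_step) c(1, 0) else c(0, 1)
        }
      }
      acc
    }
    paths <- walk(a, which(a != b))
    if (!length(paths)) paths <- walk(a, which(a != b))  # unreachable guard
    if (!length(paths)) stop("no pathway")
    m <- do.call(rbind, paths)
    colMeans(m)
  }
  S <- 0
  for (cd in c(codons_a, codons_b)) S <- S + syn_sites_one(cd)
  S <- S / 2
  N <- 3 * length(codons_a) - S
  sd <- 0; nd <- 0
  for (k in seq_along(codons_a)) {
    d <- tryCatch(pair_diffs(codons_a[k], codons_b[k]),
                  error = function(e) pair_diffs(codons_a[k], codons_b[k],
                                                 allow_stops = TRUE))
    sd <- sd + d[1]; nd <- nd + d[2]
  }
  ps <- sd / S; pn <- nd / N
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(s_sites = S, n_sites = N, sd = sd, nd = nd,
       ks = jc(ps), ka = jc(pn))
}

# random mutated codon pair for oracle comparisons (sense codons only)
random_codon_pair <- function(n_codons, p_mut = 0.1) {
  GC <- as.character(Biostrings::GENETIC_CODE)
  names(GC) <- names(Biostrings::GENETIC_CODE)
  sense <- names(GC)[GC != "*"]
  a <- sample(sense, n_codons, replace = TRUE)
  b <- vapply(a, function(cd) {
    nt <- strsplit(cd, "")[[1]]
    for (p in 1:3) {
      if (runif(1) < p_mut) {
        cand <- sample(setdiff(c("A", "C", "G", "T"), nt[p]), 1L)
        tmp <- nt; tmp[p] <- cand
        if (GC[[paste(tmp, collapse = "")]] != "*") nt <- tmp
      }
    }
    paste(nt, collapse = "")
  }, character(1))
  list(a = a, b = unname(b))
}

# random additive (tree-metric) distance matrix with its generating tree
random_additive_case <- function(n_leaves) {
  tr <- ape::rtree(n_leaves, br = NULL)
  tr$edge.length <- runif(nrow(tr$edge), 0.01, 0.5)
  tr <- ape::unroot(tr)
  d <- ape::cophenetic.phylo(tr)
  d <- d[order(rownames(d)), order(colnames(d))]
  list(tree = tr, d = d)
}

splice_exons <- function(genomic, exons, strand = "+") {
  pieces <- vapply(seq_len(nrow(exons)), function(i)
    substr(genomic, exons[i, "start"], exons[i, "end"]), character(1))
  cds <- paste(pieces, collapse = "")
  if (strand == "-") revcomp(cds) else cds
}
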