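.rand_protein <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")
.rand_dna <- function(n, alphabet = NUC) paste(sample(alphabet, n, replace = TRUE), collapse = "")

.aa_codons <- function() {
  if (!is.null(.bhlhfam_cache$aa_codons)) return(.bhlhfam_cache$aa_codons)
  gc <- .codon_table()
  out <- split(names(gc), unname(gc))
  out[["*"]] <- NULL
  .bhlhfam_cache$aa_codons <- out
  out
}

# reverse-translate a protein with uniformly random synonymous codons
.rev_translate <- function(protein) {
  tab <- .aa_codons()
  aa <- strsplit(protein, "")[[1]]
  paste(vapply(aa, function(a) {
    cods <- tab[[a]]
    cods[sample.int(length(cods), 1L)]
  }, character(1)), collapse = "")
}

#' Generate a synthetic proteome with planted bHLH domains
#'
#' Planted proteins embed the profile's consensus domain (reference loop
#' length) mutated at exactly \code{k} conserved positions, with \code{k}
#' drawn from \code{mismatch_counts}; mutations go to residues outside the
#' allowed set.  Both planted proteins and composition-random decoys are
#' verified against the profile by rejection sampling, so the truth ledger
#' is exact: each planted protein's best window is the planted window at its
#' planted mismatch count, and every decoy exceeds the acceptance budget.
#'
#' @param n_proteins total proteins
#' @param n_planted number with a planted domain
#' @param mismatch_counts integer vector of planted mismatch counts,
#'   recycled to \code{n_planted}
#' @param seed RNG seed
#' @param profile a [load_profile()] object (default shipped profile)
#' @param decoy_budget mismatch count decoys must exceed (default 9)
#' @return list with \code{proteins} (data.frame as from [read_fasta()]) and
#'   \code{truth} (data.frame: \code{protein_id}, \code{planted},
#'   \code{domain_start}, \code{domain_end}, \code{true_mismatch},
#'   \code{seed})
#' @export
gen_proteome <- function(n_proteins, n_planted, mismatch_counts = 0:9,
                         seed = 1L, profile = NULL, decoy_budget = 9L) {
  stopifnot(n_planted <= n_proteins)
  if (is.null(profile)) profile <- load_profile()
  set.seed(seed)
  cons <- strsplit(profile_consensus(profile), "")[[1]]
  cons_idx <- profile$positions$index[profile$positions$conserved]
  ks <- rep_len(as.integer(mismatch_counts), n_planted)
  ids <- sprintf("syn%04d", seq_len(n_proteins))
  planted_flag <- c(rep(TRUE, n_planted), rep(FALSE, n_proteins - n_planted))

  make_planted <- function(id, k) {
    # verification: within the budget the planted window must be the best hit
    # at exactly k mismatches; beyond it, no window may fall inside the
    # budget (alternative framings can beat a heavily mutated planting, so
    # the exact-window requirement is not meaningful there)
    for (try in 1:100) {
      dom <- cons
      mut <- sample(cons_idx, k)
      for (m in mut) {
        pool <- setdiff(AA20, profile$allowed[[m]])
        dom[m] <- sample(pool, 1L)
      }
      nfl <- sample(20:60, 1L)
      cfl <- sample(20:60, 1L)
      seqc <- paste0(.rand_protein(nfl), paste(dom, collapse = ""),
                     .rand_protein(cfl))
      h <- align_to_profile(setNames(seqc, id), profile)
      ok <- if (k <= decoy_budget) {
        !is.null(h) && h$mismatch_count == k && h$start == nfl + 1L
      } else {
        !is.null(h) && h$mismatch_count > decoy_budget
      }
      if (ok) {
        return(list(seq = seqc, start = nfl + 1L, end = nfl + length(dom), k = k))
      }
    }
    stop("could not plant a verified domain with k = ", k)
  }
  make_decoy <- function(id) {
    for (try in 1:100) {
      seqc <- .rand_protein(sample(120:300, 1L))
      h <- align_to_profile(setNames(seqc, id), profile)
      if (is.null(h) || h$mismatch_count > decoy_budget) return(seqc)
    }
    stop("could not generate a decoy exceeding the budget")
  }

  seqs <- character(n_proteins)
  truth <- data.frame(protein_id = ids, planted = planted_flag,
                      domain_start = NA_integer_, domain_end = NA_integer_,
                      true_mismatch = NA_integer_, seed = seed,
                      stringsAsFactors = FALSE)
  for (i in seq_len(n_proteins)) {
    if (planted_flag[i]) {
      p <- make_planted(ids[i], ks[i])
      seqs[i] <- p$seq
      truth$domain_start[i] <- p$start
      truth$domain_end[i] <- p$end
      truth$true_mismatch[i] <- p$k
    } else {
      seqs[i] <- make_decoy(ids[i])
    }
  }
  list(proteins = data.frame(id = ids, description = "", sequence = seqs,
                             stringsAsFactors = FALSE),
       truth = truth)
}

#' Simulate codon-sequence pairs under a chosen omega
#'
#' An ancestor of random sense codons evolves along two independent
#' branches by uniform single-nucleotide proposals: synonymous changes are
#' always accepted, nonsynonymous ones with probability \code{omega}, and
#' stop-creating changes are rejected.  Proposal counts are set so the
#' expected synonymous divergence of the pair is \code{expected_ks}.
#'
#' @param n_codons codons per sequence
#' @param omega nonsynonymous/synonymous acceptance ratio (> 0 allowed to be
#'   0 for the forced-ka0 case)
#' @param expected_ks target pairwise synonymous divergence (rejected above
#'   1.5: too close to saturation for the JC correction)
#' @param n_pairs number of independent pairs
#' @param seed RNG seed
#' @return list with \code{cds} (data.frame of sequences, ids
#'   \code{pairNNN_a/_b}) and \code{truth} (per pair: realized synonymous
#'   and nonsynonymous substitution events, omega, seed)
#' @export
gen_codon_pairs <- function(n_codons, omega, expected_ks, n_pairs, seed = 1L) {
  stopifnot(omega >= 0, n_codons >= 1, n_pairs >= 1)
  if (expected_ks > 1.5)
    stop("expected_ks = ", expected_ks,
         " implies near-saturated synonymous proportions (>= 3/4); refusing")
  set.seed(seed)
  gc <- .codon_table()
  sense <- names(gc)[gc != "*"]
  n_prop <- round(3 * n_codons * expected_ks / 2)   # per branch

  evolve <- function(codons) {
    syn_ev <- 0L; nonsyn_ev <- 0L
    for (p in seq_len(n_prop)) {
      site <- sample.int(3L * n_codons, 1L)
      ci <- (site - 1L) %/% 3L + 1L
      off <- (site - 1L) %% 3L + 1L
      nt <- strsplit(codons[ci], "")[[1]]
      alt <- sample(setdiff(NUC, nt[off]), 1L)
      mut <- nt; mut[off] <- alt
      mc <- paste(mut, collapse = "")
      if (gc[[mc]] == "*") next
      if (gc[[mc]] == gc[[codons[ci]]]) {
        codons[ci] <- mc; syn_ev <- syn_ev + 1L
      } else if (stats::runif(1) < omega) {
        codons[ci] <- mc; nonsyn_ev <- nonsyn_ev + 1L
      }
    }
    list(codons = codons, syn = syn_ev, nonsyn = nonsyn_ev)
  }

  ids <- character(0); seqs <- character(0)
  truth <- list()
  for (k in seq_len(n_pairs)) {
    anc <- sample(sense, n_codons, replace = TRUE)
    a <- evolve(anc)
    b <- evolve(anc)
    pid <- sprintf("pair%03d", k)
    ids <- c(ids, paste0(pid, "_a"), paste0(pid, "_b"))
    seqs <- c(seqs, paste(a$codons, collapse = ""), paste(b$codons, collapse = ""))
    truth[[k]] <- data.frame(pair_id = pid, omega = omega,
                             expected_ks = expected_ks,
                             syn_events = a$syn + b$syn,
                             nonsyn_events = a$nonsyn + b$nonsyn,
                             seed = seed, stringsAsFactors = FALSE)
  }
  list(cds = data.frame(id = ids, description = "", sequence = seqs,
                        stringsAsFactors = FALSE),
       truth = do.call(rbind, truth))
}

#' Generate multi-exon gene models with introns at chosen domain positions
#'
#' Each plan yields one gene: a protein with the consensus domain flanked by
#' random residues, a CDS by random synonymous reverse translation, and a
#' genomic sequence where GT..AG introns interrupt the CDS exactly at the
#' requested (profile position, phase) coordinates.  Intron interiors avoid
#' internal AG so exact-match chaining recovers the truth unambiguously.
#'
#' @param intron_plans list of plans: each a list with \code{positions}
#'   (profile indices), \code{phases} (same length, 0/1/2; default all 0)
#'   and optional \code{strand} (\code{"+"}/\code{"-"})
#' @param seed RNG seed
#' @param profile a [load_profile()] object
#' @param flank_aa protein flank length on each side of the domain
#' @return list with \code{genes} (annotations as from [read_gff3()]),
#'   \code{genomic} and \code{cds} (FASTA data.frames; one chromosome per
#'   gene) and \code{truth} (per gene: exon coordinates, planted events)
#' @export
gen_gene_models <- function(intron_plans, seed = 1L, profile = NULL,
                            flank_aa = 10L) {
  if (is.null(profile)) profile <- load_profile()
  set.seed(seed)
  n_idx <- nrow(profile$positions)
  genes <- list(); genomic <- list(); cds_tab <- list(); truth <- list()
  for (gi in seq_along(intron_plans)) {
    plan <- intron_plans[[gi]]
    pos <- plan$positions %||% integer()
    phases <- plan$phases %||% rep(0L, length(pos))
    strand <- plan$strand %||% "+"
    if (length(pos) && (any(pos < 1L) || any(pos > n_idx)))
      stop("requested intron position outside the domain profile")
    gene_id <- plan$gene_id %||% sprintf("simgene%03d", gi)
    chrom <- paste0(gene_id, "_chr")

    # rejection sampling: rebuild until exact-match chaining recovers the
    # planted structure unambiguously (random flanks can otherwise offer a
    # coincidental alternative GT..AG parse)
    build <- function() {
      protein <- paste0(.rand_protein(flank_aa), profile_consensus(profile),
                        .rand_protein(flank_aa))
      cds <- .rev_translate(protein)
      # CDS break coordinate of an intron at (profile position p, phase f)
      cuts <- if (length(pos)) {
        q <- flank_aa + pos        # protein position of profile index
        sort(3L * (q - 1L) + phases)
      } else integer()
      if (anyDuplicated(cuts)) stop("duplicate intron coordinates in plan")
      seg_bounds <- c(0L, cuts, nchar(cds))
      pieces <- mapply(function(s, e) substr(cds, s + 1L, e),
                       head(seg_bounds, -1L), tail(seg_bounds, -1L))
      introns <- vapply(seq_along(cuts), function(i)
        paste0("GT", .rand_dna(sample(40:80, 1L), alphabet = c("A", "C", "T")),
               "AG"), character(1))
      body <- pieces[1L]
      exons <- cbind(start = 101L, end = 100L + nchar(pieces[1L]))
      for (i in seq_along(introns)) {
        body <- paste0(body, introns[i], pieces[i + 1L])
        s <- exons[nrow(exons), "end"] + nchar(introns[i]) + 1L
        exons <- rbind(exons, c(start = s, end = s + nchar(pieces[i + 1L]) - 1L))
      }
      chrom_seq <- paste0(.rand_dna(100L), body, .rand_dna(100L))
      if (strand == "-") {
        L <- nchar(chrom_seq)
        chrom_seq <- revcomp(chrom_seq)
        exons <- cbind(start = L - exons[, "end"] + 1L,
                       end = L - exons[, "start"] + 1L)
        exons <- exons[order(exons[, "start"]), , drop = FALSE]
      }
      list(cds = cds, chrom_seq = chrom_seq, exons = exons)
    }
    ok <- FALSE
    for (try in 1:50) {
      gb <- build()
      st <- tryCatch(infer_gene_structure(gb$cds, gb$chrom_seq),
                     error = function(e) NULL)
      if (!is.null(st) && identical(st$strand, strand) &&
          identical(unname(st$exons), unname(gb$exons))) { ok <- TRUE; break }
    }
    if (!ok) stop("could not build an unambiguous gene model for ", gene_id)
    cds <- gb$cds; chrom_seq <- gb$chrom_seq; exons <- gb$exons
    g <- list(gene_id = gene_id, chromosome = chrom,
              start = min(exons[, "start"]), end = max(exons[, "end"]),
              strand = strand, exons = exons,
              cds_segments = cbind(exons, phase = NA_integer_))
    genes[[gi]] <- g
    genomic[[gi]] <- data.frame(id = chrom, description = "",
                                sequence = chrom_seq, stringsAsFactors = FALSE)
    cds_tab[[gi]] <- data.frame(id = gene_id, description = "",
                                sequence = cds, stringsAsFactors = FALSE)
    truth[[gi]] <- data.frame(
      gene_id = gene_id, strand = strand,
      exons = paste(apply(exons, 1L, paste, collapse = "-"), collapse = ";"),
      positions = paste(pos, collapse = ","),
      phases = paste(phases, collapse = ","),
      expected_pattern = if (!length(pos)) "intronless" else NA_character_,
      seed = seed, stringsAsFactors = FALSE)
  }
  list(genes = genes, genomic = do.call(rbind, genomic),
       cds = do.call(rbind, cds_tab), truth = do.call(rbind, truth))
}

#' Generate a genome layout with planted tandem and segmental duplicates
#'
#' Family genes carry near-identical bHLH proteins (consensus domain plus
#' lightly mutated flanks); fillers are random proteins.  Planted tandem
#' pairs occupy adjacent gene-order ranks on one chromosome; planted
#' segmental pairs sit inside paired synteny-block regions on two other
#' chromosomes.
#'
#' @param n_chromosomes chromosomes to lay out (>= 3 recommended)
#' @param n_tandem,n_segmental planted pair counts
#' @param seed RNG seed
#' @param profile a [load_profile()] object
#' @param n_lone additional isolated family genes
#' @return list with \code{genes} (annotations), \code{proteins} and
#'   \code{cds} (FASTA data.frames), \code{blocks} (synteny data.frame),
#'   \code{family_ids} and \code{truth} (planted pair lists)
#' @export
gen_duplication_layout <- function(n_chromosomes = 3L, n_tandem = 2L,
                                   n_segmental = 3L, seed = 1L,
                                   profile = NULL, n_lone = 2L) {
  if (is.null(profile)) profile <- load_profile()
  set.seed(seed)
  cons <- profile_consensus(profile)
  noncons <- profile$positions$index[!profile$positions$conserved]

  family_protein <- function() {
    dom <- strsplit(cons, "")[[1]]
    for (m in sample(noncons, 3L)) dom[m] <- sample(AA20, 1L)
    paste0(.rand_protein(15L), paste(dom, collapse = ""), .rand_protein(15L))
  }

  gene_len <- 1000L
  spacing <- 10000L
  chrom_of <- function(k) sprintf("chr%02d", k)
  genes <- list(); prot <- list(); cds_tab <- list()
  add_gene <- function(id, chrom, slot, is_family) {
    s <- 1L + (slot - 1L) * spacing
    e <- s + gene_len - 1L
    p <- if (is_family) family_protein() else .rand_protein(sample(150:300, 1L))
    genes[[length(genes) + 1L]] <<- list(
      gene_id = id, chromosome = chrom, start = s, end = e, strand = "+",
      exons = cbind(start = s, end = e),
      cds_segments = cbind(start = s, end = e, phase = 0L))
    prot[[length(prot) + 1L]] <<- data.frame(id = id, description = "",
                                             sequence = p, stringsAsFactors = FALSE)
    cds_tab[[length(cds_tab) + 1L]] <<- data.frame(
      id = id, description = "", sequence = .rev_translate(p),
      stringsAsFactors = FALSE)
    c(start = s, end = e)
  }

  filler_i <- 0L
  add_filler <- function(chrom, slot) {
    filler_i <<- filler_i + 1L
    add_gene(sprintf("fill%03d", filler_i), chrom, slot, FALSE)
  }

  truth_tandem <- list(); truth_seg <- list()
  family_ids <- character(0)
  # chromosome 1: tandem pairs and lone family genes, fillers between
  slot <- 1L
  for (t in seq_len(n_tandem)) {
    add_filler(chrom_of(1L), slot); slot <- slot + 1L
    a <- sprintf("tand%02da", t); b <- sprintf("tand%02db", t)
    add_gene(a, chrom_of(1L), slot, TRUE); slot <- slot + 1L
    add_gene(b, chrom_of(1L), slot, TRUE); slot <- slot + 1L
    family_ids <- c(family_ids, a, b)
    truth_tandem[[t]] <- data.frame(gene_a = a, gene_b = b,
                                    stringsAsFactors = FALSE)
  }
  for (l in seq_len(n_lone)) {
    add_filler(chrom_of(1L), slot); slot <- slot + 1L
    id <- sprintf("lone%02d", l)
    add_gene(id, chrom_of(1L), slot, TRUE); slot <- slot + 1L
    family_ids <- c(family_ids, id)
  }
  add_filler(chrom_of(1L), slot)
  # segmental pairs across the last two chromosomes
  ca <- chrom_of(max(2L, n_chromosomes - 1L))
  cb <- chrom_of(max(3L, n_chromosomes))
  blocks <- list()
  slot_a <- 1L; slot_b <- 1L
  for (s_ in seq_len(n_segmental)) {
    add_filler(ca, slot_a); slot_a <- slot_a + 1L
    add_filler(cb, slot_b); slot_b <- slot_b + 1L
    a <- sprintf("seg%02da", s_); b <- sprintf("seg%02db", s_)
    ga <- add_gene(a, ca, slot_a, TRUE); slot_a <- slot_a + 1L
    gb <- add_gene(b, cb, slot_b, TRUE); slot_b <- slot_b + 1L
    family_ids <- c(family_ids, a, b)
    blocks[[s_]] <- data.frame(
      chrom_a = ca, start_a = max(1L, ga["start"] - 2000L),
      end_a = ga["end"] + 2000L,
      chrom_b = cb, start_b = max(1L, gb["start"] - 2000L),
      end_b = gb["end"] + 2000L,
      block_id = sprintf("blk%02d", s_), stringsAsFactors = FALSE)
    truth_seg[[s_]] <- data.frame(gene_a = a, gene_b = b,
                                  stringsAsFactors = FALSE)
  }
  add_filler(ca, slot_a); add_filler(cb, slot_b)

  list(genes = genes,
       proteins = do.call(rbind, prot),
       cds = do.call(rbind, cds_tab),
       blocks = if (length(blocks)) do.call(rbind, blocks) else
         read_synteny_table(tempfile_empty()),
       family_ids = family_ids,
       truth = list(tandem = if (length(truth_tandem))
                      do.call(rbind, truth_tandem) else NULL,
                    segmental = if (length(truth_seg))
                      do.call(rbind, truth_seg) else NULL,
                    seed = seed))
}

tempfile_empty <- function() {
  f <- tempfile(fileext = ".tsv"); file.create(f); f
}

#' Generate group-structured expression matrices and qPCR Ct tables
#'
#' Expression: each gene group prefers one tissue; values are Gaussian noise
#' around a base mean plus \code{effect_size} in the preferred tissue,
#' clamped at zero.  qPCR: Ct values back-computed from planted fold changes
#' against a constant reference gene, with triplicate jitter of
#' \code{noise_sd}.
#'
#' @param groups integer vector of genes per group
#' @param tissues tissue (column) names
#' @param effect_size added mean in the preferred tissue
#' @param noise_sd Gaussian noise SD (0 = noise-free)
#' @param seed RNG seed
#' @param base_mean baseline expression mean
#' @param n_qpcr genes with qPCR measurements
#' @return list with \code{matrix} (genes x tissues), \code{qpcr}
#'   (Ct table) and \code{truth} (group structure and planted fold changes)
#' @export
gen_expression <- function(groups = c(8L, 8L, 8L),
                           tissues = c("leaf", "root", "stem", "spike"),
                           effect_size = 3, noise_sd = 0.5, seed = 1L,
                           base_mean = 5, n_qpcr = 8L) {
  set.seed(seed)
  n_genes <- sum(groups)
  gene_ids <- character(0); grp <- integer(0)
  for (g in seq_along(groups)) {
    gene_ids <- c(gene_ids, sprintf("expr_g%d_%02d", g, seq_len(groups[g])))
    grp <- c(grp, rep(g, groups[g]))
  }
  pref <- tissues[(grp - 1L) %% length(tissues) + 1L]
  mu <- matrix(base_mean, n_genes, length(tissues),
               dimnames = list(gene_ids, tissues))
  for (i in seq_len(n_genes)) mu[i, pref[i]] <- mu[i, pref[i]] + effect_size
  m <- mu + matrix(rnorm(length(mu), 0, noise_sd), nrow(mu))
  m[m < 0] <- 0
  dimnames(m) <- dimnames(mu)

  n_qpcr <- min(n_qpcr, n_genes)
  folds <- sample(c(0.25, 0.5, 1, 2, 4, 8, 16), n_qpcr, replace = TRUE)
  trip <- function(ct) mean(ct + rnorm(3L, 0, noise_sd))
  qpcr <- do.call(rbind, lapply(seq_len(n_qpcr), function(i) {
    data.frame(gene_id = gene_ids[i], condition = "treatment",
               ct_target = trip(24 - log2(folds[i])),
               ct_reference = trip(18),
               ct_target_ctrl = trip(24),
               ct_reference_ctrl = trip(18),
               stringsAsFactors = FALSE)
  }))
  list(matrix = m, qpcr = qpcr,
       truth = list(groups = data.frame(gene_id = gene_ids, group = grp,
                                        preferred_tissue = pref,
                                        stringsAsFactors = FALSE),
                    folds = data.frame(gene_id = gene_ids[seq_len(n_qpcr)],
                                       fold = folds, stringsAsFactors = FALSE),
                    seed = seed))
}

#' Write a default synthetic bundle to a directory
#'
#' Emits a proteome with planted domains, gene models for intron typing,
#' a duplication layout with paired synteny blocks, expression and qPCR
#' tables, and a truth ledger for every file — everything [run_pipeline()]
#' consumes.
#'
#' @param out_dir output directory
#' @param seed RNG seed (each generator derives its own sub-seed)
#' @param noise_sd expression noise (0 = noise-free recovery)
#' @return named list of written paths plus the in-memory truth ledgers,
#'   invisibly
#' @export
write_sim_bundle <- function(out_dir, seed = 1L, noise_sd = 0) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  prof <- load_profile()
  pr <- gen_proteome(60L, 30L, mismatch_counts = 0:9, seed = seed,
                     profile = prof)
  dup <- gen_duplication_layout(seed = seed + 1L, profile = prof)
  gm <- gen_gene_models(list(
    list(positions = c(9L, 31L), phases = c(0L, 0L)),
    list(positions = c(9L, 31L), phases = c(0L, 0L), strand = "-"),
    list(positions = integer(), phases = integer()),
    list(positions = 20L, phases = 1L)), seed = seed + 2L, profile = prof)
  ex <- gen_expression(seed = seed + 3L, noise_sd = noise_sd)

  paths <- list(
    proteome = file.path(out_dir, "proteome.fasta"),
    dup_proteins = file.path(out_dir, "dup_proteins.fasta"),
    dup_cds = file.path(out_dir, "dup_cds.fasta"),
    dup_gff = file.path(out_dir, "dup_genes.gff3"),
    blocks = file.path(out_dir, "synteny_blocks.tsv"),
    model_gff = file.path(out_dir, "gene_models.gff3"),
    model_cds = file.path(out_dir, "gene_models_cds.fasta"),
    model_genomic = file.path(out_dir, "gene_models_genomic.fasta"),
    expression = file.path(out_dir, "expression.tsv"),
    qpcr = file.path(out_dir, "qpcr.tsv"))
  write_fasta(pr$proteins, paths$proteome)
  write_fasta(dup$proteins, paths$dup_proteins)
  write_fasta(dup$cds, paths$dup_cds)
  write_gff3(dup$genes, paths$dup_gff)
  write.table(dup$blocks, paths$blocks, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write_gff3(gm$genes, paths$model_gff)
  write_fasta(gm$cds, paths$model_cds)
  write_fasta(gm$genomic, paths$model_genomic)
  em <- data.frame(gene_id = rownames(ex$matrix), ex$matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(em, paths$expression, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(ex$qpcr, paths$qpcr, sep = "\t", quote = FALSE,
              row.names = FALSE)
  truth_path <- file.path(out_dir, "truth_proteome.tsv")
  write.table(pr$truth, truth_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(paths, list(
    truth = list(proteome = pr$truth, duplication = dup$truth,
                 gene_models = gm$truth, expression = ex$truth,
                 family_ids = dup$family_ids))))
}
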