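test_that("structure inference recovers planted exons on both strands", {
  gm <- gen_gene_models(list(
    list(positions = c(9L, 31L), phases = c(0L, 0L)),
    list(positions = c(9L, 31L), phases = c(0L, 0L), strand = "-"),
    list(positions = integer(), phases = integer())), seed = 13)
  # two planted introns recovered exactly
  st1 <- infer_gene_structure(gm$cds$sequence[1], gm$genomic$sequence[1])
  expect_equal(st1$strand, "+")
  expect_equal(unname(st1$exons), unname(gm$genes[[1]]$exons))
  # minus strand
  st2 <- infer_gene_structure(gm$cds$sequence[2], gm$genomic$sequence[2])
  expect_equal(st2$strand, "-")
  expect_equal(unname(st2$exons), unname(gm$genes[[2]]$exons))
  # CDS equal to a genomic substring -> single exon
  st3 <- infer_gene_structure(gm$cds$sequence[3], gm$genomic$sequence[3])
  expect_equal(nrow(st3$exons), 1L)
  # not derivable -> error
  expect_error(infer_gene_structure("ATGTTTAAACCC",
                                    paste(rep("G", 400), collapse = "")),
               "not derivable")
})

test_that("splicing inferred exons reproduces the CDS (round trip)", {
  set.seed(29)
  plans <- lapply(1:12, function(i) {
    n_intr <- sample(0:2, 1)
    pos <- sort(sample(5:50, n_intr))
    list(positions = as.integer(pos),
         phases = sample(0:2, n_intr, replace = TRUE),
         strand = sample(c("+", "-"), 1))
  })
  gm <- gen_gene_models(plans, seed = 37)
  for (i in seq_along(plans)) {
    st <- infer_gene_structure(gm$cds$sequence[i], gm$genomic$sequence[i])
    spliced <- splice_exons(gm$genomic$sequence[i], st$exons, st$strand)
    expect_identical(spliced, gm$cds$sequence[i])
  }
})

test_that("intron events map onto profile coordinates with phases", {
  gm <- gen_gene_models(list(list(positions = 9L, phases = 0L),
                             list(positions = c(20L, 43L), phases = c(1L, 2L))),
                        seed = 19)
  hit1 <- aligned_hit(translate_cds(gm$cds$sequence[1]), "g1")
  asn1 <- map_introns_to_domain(gm$genes[[1]]$exons, hit1, gm$genes[[1]])
  # intron between the codons of positions 8 and 9, phase 0 -> event (9, 0)
  expect_equal(asn1$events$domain_position, 9L)
  expect_equal(asn1$events$phase, 0L)
  hit2 <- aligned_hit(translate_cds(gm$cds$sequence[2]), "g2")
  asn2 <- map_introns_to_domain(gm$genes[[2]]$exons, hit2, gm$genes[[2]])
  expect_equal(asn2$events$domain_position, c(20L, 43L))
  expect_equal(asn2$events$phase, c(1L, 2L))
  # genomic offset invariance
  g_shift <- gm$genes[[2]]
  g_shift$exons <- g_shift$exons + 1000L
  asn_shift <- map_introns_to_domain(g_shift$exons, hit2, g_shift)
  expect_identical(asn_shift$events, asn2$events)
})

test_that("pattern assignment matches the catalog by position set", {
  catalog <- load_pattern_catalog()
  ev <- function(pos, ph) list(gene_id = "g",
                               events = data.frame(domain_position = pos,
                                                   phase = ph))
  expect_equal(assign_pattern(ev(c(9L, 31L), c(0L, 0L)), catalog), "IV")
  expect_equal(assign_pattern(ev(c(31L, 9L), c(1L, 2L)), catalog), "IV")
  expect_equal(assign_pattern(ev(integer(), integer()), catalog), "intronless")
  expect_equal(assign_pattern(ev(c(9L, 30L), c(0L, 0L)), catalog), "novel")
  # phase-aware entries compare phases too
  cat2 <- list(X = list(positions = 9L, phases = 1L))
  expect_equal(assign_pattern(ev(9L, 1L), cat2), "X")
  expect_equal(assign_pattern(ev(9L, 0L), cat2), "novel")
})

test_that("pattern discovery clusters identical position sets by frequency", {
  asns <- c(replicate(3, list(gene_id = "a",
                              events = data.frame(domain_position = c(9L, 31L),
                                                  phase = c(0L, 0L))),
                      simplify = FALSE),
            replicate(1, list(gene_id = "b",
                              events = data.frame(domain_position = 20L,
                                                  phase = 0L)),
                      simplify = FALSE),
            list(list(gene_id = "c",
                      events = data.frame(domain_position = integer(),
                                          phase = integer()))))
  disc <- discover_patterns(asns)
  expect_equal(disc$discovered_pattern[1], "P1")
  expect_equal(disc$discovered_pattern[4], "P2")
  expect_equal(disc$discovered_pattern[5], "intronless")
})

test_that("promoter extraction respects strand and chromosome edges", {
  chrom <- paste0(paste(rep("A", 50), collapse = ""), "CCGGTT",
                  paste(rep("A", 30), collapse = ""))
  gplus <- list(start = 51L, end = 56L, strand = "+")
  expect_equal(extract_upstream(chrom, gplus, width = 10),
               paste(rep("A", 10), collapse = ""))
  expect_equal(nchar(extract_upstream(chrom, gplus, width = 1500)), 50L)
  gminus <- list(start = 51L, end = 56L, strand = "-")
  up <- extract_upstream(chrom, gminus, width = 10)
  expect_equal(up, paste(rep("T", 10), collapse = ""))
  gflush <- list(start = 1L, end = 5L, strand = "+")
  expect_equal(extract_upstream(chrom, gflush), "")
})

test_that("IUPAC promoter scan finds planted motifs on both strands", {
  filler <- paste(rep("A", 20), collapse = "")
  seq3 <- paste0(filler, "TGACG", filler, "TGACG", filler, "TGACG", filler)
  motifs <- data.frame(motif_name = "TGACG-motif", iupac = "TGACG",
                       stringsAsFactors = FALSE)
  hits <- scan_promoter(c(g1 = seq3), motifs)
  expect_equal(sum(hits$strand == "+"), 3L)
  # degenerate pattern matches each realisation
  m2 <- data.frame(motif_name = "DRE-core", iupac = "RCCGAC")
  hits2 <- scan_promoter(c(g2 = paste0(filler, "GCCGAC", filler, "ACCGAC")),
                         m2)
  expect_setequal(hits2$matched[hits2$strand == "+"], c("GCCGAC", "ACCGAC"))
  # reverse-strand planting reported with strand '-'
  hits3 <- scan_promoter(c(g3 = paste0(filler, revcomp("TGACG"), filler)),
                         motifs)
  expect_equal(hits3$strand, "-")
  # strand symmetry: counts swap under reverse complement
  hits_fwd <- scan_promoter(c(g = seq3), motifs)
  hits_rev <- scan_promoter(c(g = revcomp(seq3)), motifs)
  expect_equal(sum(hits_fwd$strand == "+"), sum(hits_rev$strand == "-"))
  expect_equal(nrow(hits_fwd), nrow(hits_rev))
  expect_error(scan_promoter(c(g = "ACGT"),
                             data.frame(motif_name = "bad", iupac = "AJC")),
               "IUPAC")
})

test_that("expression transforms follow the stated arithmetic", {
  expect_equal(log2_matrix(matrix(8), pseudocount = 0)[1], 3)
  expect_equal(log2_matrix(matrix(0), pseudocount = 1)[1], 0)
  m <- matrix(c(1, 5, 2, 9), 2)
  lm <- log2_matrix(m)
  expect_true(all(apply(lm, 2, diff) * apply(m, 2, diff) >= 0))  # monotone
  expect_error(log2_matrix(matrix(-1)), ">= 0")

  expect_equal(ddct(20, 18, 20, 18), 1.0)
  expect_equal(ddct(20, 18, 24, 18), 16.0)
  x <- ddct(21.3, 17.9, 24.2, 18.4)
  expect_equal(ddct(24.2, 18.4, 21.3, 17.9), 1 / x)
  q <- data.frame(gene_id = "g", condition = "t", ct_target = 20,
                  ct_reference = 18, ct_target_ctrl = 24,
                  ct_reference_ctrl = 18)
  expect_equal(qpcr_fold_changes(q)$relative_expression, 16)
})
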