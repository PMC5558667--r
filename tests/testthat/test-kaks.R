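test_that("codon alignment back-translates and validates", {
  # identical pair, gapless
  cp <- codon_align("ATGGCTAAA", "ATGGCTAAA", "MAK", "MAK")
  expect_equal(cp$a, c("ATG", "GCT", "AAA"))
  expect_equal(cp$b, cp$a)
  # one 1-residue gap drops exactly one codon column
  cp2 <- codon_align("ATGGCTAAA", "ATGAAA", "MAK", "M-K")
  expect_equal(length(cp2$a), 2L)
  expect_equal(cp2$a, c("ATG", "AAA"))
  # terminal stop tolerated, internal stop rejected
  expect_silent(codon_align("ATGAAATAA", "ATGAAA", "MK", "MK"))
  expect_error(codon_align("ATGTAAAAA", "ATGGCTAAA", "M-K", "MAK"), "stop")
  # translation mismatch names the first bad codon
  expect_error(codon_align("ATGGCTAAA", "ATGGCTAAA", "MAY", "MAY"), "codon 3")
})

test_that("NG86 reproduces the hand-computed worked example", {
  cp <- list(a = c(rep("GCT", 9), "TTT"), b = c(rep("GCT", 9), "TTC"))
  k <- ng86_kaks(cp)
  expect_equal(k$s_sites, 28 / 3, tolerance = 1e-12)
  expect_equal(k$sd, 1)
  expect_equal(k$nd, 0)
  expect_equal(k$ps, 3 / 28, tolerance = 1e-12)
  expect_equal(k$ks, -0.75 * log(1 - 4 * (3 / 28) / 3), tolerance = 1e-12)
  expect_equal(k$ka, 0)
  # identical sequences: zero rates, undefined ratio
  k0 <- ng86_kaks(list(a = c("ATG", "GCT"), b = c("ATG", "GCT")))
  expect_equal(k0$sd + k0$nd, 0)
  expect_equal(k0$ks, 0)
  expect_true(is.na(k0$ratio))
})

test_that("NG86 is symmetric and conserves sites", {
  set.seed(17)
  for (rep in 1:10) {
    cp <- random_codon_pair(50)
    k1 <- ng86_kaks(cp)
    k2 <- ng86_kaks(list(a = cp$b, b = cp$a))
    for (f in c("s_sites", "n_sites", "sd", "nd", "ka", "ks"))
      expect_equal(k1[[f]], k2[[f]], tolerance = 1e-12)
    expect_equal(k1$s_sites + k1$n_sites, 3 * 50, tolerance = 1e-12)
  }
})

test_that("NG86 matches the independent brute-force oracle", {
  set.seed(23)
  for (rep in 1:25) {
    cp <- random_codon_pair(60, p_mut = runif(1, 0.02, 0.25))
    mine <- ng86_kaks(cp)
    orc <- oracle_ng86(cp$a, cp$b)
    for (f in c("s_sites", "n_sites", "sd", "nd", "ka", "ks"))
      expect_equal(mine[[f]], orc[[f]], tolerance = 1e-10, label = f)
  }
})

test_that("divergence dating is linear with the synonymous clock", {
  expect_equal(divergence_time(0), 0)
  expect_equal(divergence_time(0.13, lambda_syn = 6.5e-9), 10)
  expect_equal(divergence_time(0.26), 2 * divergence_time(0.13))
  expect_true(is.na(divergence_time(NA_real_)))
  expect_error(divergence_time(0.1, lambda_syn = 0))
})

test_that("selection classes follow the Ka/Ks ratio", {
  expect_equal(classify_selection(0.2), "purifying")
  expect_equal(classify_selection(1.99), "positive")
  expect_equal(classify_selection(1), "neutral")
  expect_equal(classify_selection(NA_real_), "undefined")
})

make_gene <- function(id, chrom, start) {
  list(gene_id = id, chromosome = chrom, start = start, end = start + 999L,
       strand = "+", exons = cbind(start = start, end = start + 999L),
       cds_segments = cbind(start = start, end = start + 999L, phase = 0L))
}

test_that("tandem calling requires adjacency in the full gene order", {
  genes <- list(make_gene("x1", "chr1", 1000), make_gene("x2", "chr1", 5000),
                make_gene("famA", "chr1", 9000), make_gene("famB", "chr1", 13000),
                make_gene("x3", "chr1", 17000), make_gene("famC", "chr1", 21000),
                make_gene("famD", "chr2", 1000))
  fam <- c("famA", "famB", "famC", "famD")
  # ranks 3,4 adjacent -> tandem; famB..famC separated by x3 -> not
  tp <- find_tandem_pairs(fam, genes, proteins = NULL)
  expect_equal(nrow(tp), 1L)
  expect_equal(c(tp$gene_a, tp$gene_b), c("famA", "famB"))
  # chromosome boundary never yields a pair
  genes2 <- list(make_gene("famA", "chr1", 90000), make_gene("famB", "chr2", 1))
  expect_equal(nrow(find_tandem_pairs(c("famA", "famB"), genes2, NULL)), 0L)
  # invariant to genes added on other chromosomes
  tp2 <- find_tandem_pairs(fam, c(genes, list(make_gene("y", "chr9", 1))), NULL)
  expect_identical(tp[c("gene_a", "gene_b")], tp2[c("gene_a", "gene_b")])
  # identity threshold filters dissimilar neighbours
  prots <- data.frame(id = fam,
                      sequence = c(CONSENSUS, CONSENSUS,
                                   paste(rep("W", 56), collapse = ""),
                                   CONSENSUS), stringsAsFactors = FALSE)
  tp3 <- find_tandem_pairs(fam, genes, prots, identity_min = 0.4)
  expect_equal(nrow(tp3), 1L)
  expect_gt(tp3$identity[1], 0.9)
})

test_that("segmental assignment uses block containment by gene start", {
  fam_genes <- list(make_gene("a", "chr1", 150000), make_gene("b", "chr3", 550000),
                    make_gene("c", "chr5", 1000))
  blocks <- data.frame(chrom_a = "chr1", start_a = 100000, end_a = 200000,
                       chrom_b = "chr3", start_b = 500000, end_b = 600000,
                       block_id = "blk1", stringsAsFactors = FALSE)
  seg <- assign_segmental(fam_genes, blocks)
  expect_equal(nrow(seg), 1L)
  expect_setequal(c(seg$gene_a, seg$gene_b), c("a", "b"))
  # gene outside every block -> no pair
  expect_false("c" %in% c(seg$gene_a, seg$gene_b))
  # straddler: start inside counts, start outside does not
  fam2 <- list(make_gene("a", "chr1", 199500), make_gene("b", "chr3", 550000))
  expect_equal(nrow(assign_segmental(fam2, blocks)), 1L)
  fam3 <- list(make_gene("a", "chr1", 200001), make_gene("b", "chr3", 550000))
  expect_equal(nrow(assign_segmental(fam3, blocks)), 0L)
  # a pair already tandem is not re-flagged
  tand <- data.frame(gene_a = "a", gene_b = "b", stringsAsFactors = FALSE)
  expect_equal(nrow(assign_segmental(fam_genes, blocks, tandem = tand)), 0L)
})

test_that("pair_kaks wires alignment, NG86, selection and dating together", {
  set.seed(31)
  gp <- gen_codon_pairs(n_codons = 120, omega = 0.3, expected_ks = 0.2,
                        n_pairs = 1, seed = 41)
  cds <- gp$cds
  cds$id <- c("gA", "gB")
  prots <- data.frame(id = cds$id,
                      sequence = vapply(cds$sequence, translate_cds, ""),
                      stringsAsFactors = FALSE)
  pairs <- data.frame(gene_a = "gA", gene_b = "gB", dup_type = "tandem",
                      stringsAsFactors = FALSE)
  res <- pair_kaks(pairs, cds, prots, lambda_syn = 6.5e-9)
  expect_true(res$ks >= 0 && res$ka >= 0)
  expect_equal(res$t_mya, res$ks / (2 * 6.5e-9) / 1e6)
  expect_true(res$selection %in% c("purifying", "neutral", "positive",
                                   "undefined"))
})
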