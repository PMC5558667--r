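test_that("generators are seed-deterministic", {
  p1 <- gen_proteome(10, 5, seed = 8)
  p2 <- gen_proteome(10, 5, seed = 8)
  expect_identical(p1, p2)
  g1 <- gen_codon_pairs(30, 0.5, 0.2, 2, seed = 8)
  g2 <- gen_codon_pairs(30, 0.5, 0.2, 2, seed = 8)
  expect_identical(g1, g2)
  e1 <- gen_expression(seed = 8)
  e2 <- gen_expression(seed = 8)
  expect_identical(e1, e2)
  d1 <- write_sim_bundle(withr::local_tempdir(), seed = 4)
  d2 <- write_sim_bundle(withr::local_tempdir(), seed = 4)
  for (f in c("proteome", "dup_gff", "expression"))
    expect_identical(readLines(d1[[f]]), readLines(d2[[f]]))
})

test_that("planted proteomes are recovered exactly at the extremes", {
  pr0 <- gen_proteome(12, 8, mismatch_counts = 0L, seed = 21)
  hits0 <- scan_proteome(pr0$proteins, default_profile)
  t0 <- pr0$truth[pr0$truth$planted, ]
  expect_setequal(hits_table(hits0)$protein_id, t0$protein_id)
  ht0 <- hits_table(hits0)
  expect_equal(ht0$mismatch_count, rep(0L, 8))
  expect_equal(ht0$start,
               t0$domain_start[match(ht0$protein_id, t0$protein_id)])
  # mismatch 10 plantings are never accepted
  pr10 <- gen_proteome(6, 6, mismatch_counts = 10L, seed = 22)
  expect_length(scan_proteome(pr10$proteins, default_profile), 0L)
})

test_that("codon-pair simulation honours omega and ks limits", {
  z <- gen_codon_pairs(50, omega = 0, expected_ks = 0.3, n_pairs = 3, seed = 9)
  for (k in 1:3) {
    a <- z$cds$sequence[2 * k - 1]; b <- z$cds$sequence[2 * k]
    cp <- list(a = bhlhfam:::.split_codons(a), b = bhlhfam:::.split_codons(b))
    expect_equal(ng86_kaks(cp)$nd, 0)
    expect_equal(ng86_kaks(cp)$ka, 0)
  }
  expect_equal(z$truth$nonsyn_events, rep(0L, 3))
  # expected_ks = 0 -> identical sequences
  z0 <- gen_codon_pairs(40, omega = 0.5, expected_ks = 0, n_pairs = 2, seed = 9)
  expect_identical(z0$cds$sequence[1], z0$cds$sequence[2])
  # saturation guard
  expect_error(gen_codon_pairs(40, 0.5, expected_ks = 2, n_pairs = 1),
               "satur")
})

test_that("gene-model plans map to downstream pattern calls", {
  gm <- gen_gene_models(list(
    list(positions = c(9L, 31L), phases = c(0L, 0L)),
    list(positions = c(9L, 31L), phases = c(0L, 0L), strand = "-"),
    list(positions = integer(), phases = integer())), seed = 3)
  catalog <- load_pattern_catalog()
  labs <- vapply(1:3, function(i) {
    hit <- aligned_hit(translate_cds(gm$cds$sequence[i]), gm$genes[[i]]$gene_id)
    assign_pattern(map_introns_to_domain(gm$genes[[i]]$exons, hit,
                                         gm$genes[[i]]), catalog)
  }, character(1))
  expect_equal(labs, c("IV", "IV", "intronless"))
  # minus-strand twin yields the identical assignment
  hit_p <- aligned_hit(translate_cds(gm$cds$sequence[1]), "p")
  hit_m <- aligned_hit(translate_cds(gm$cds$sequence[2]), "m")
  a_p <- map_introns_to_domain(gm$genes[[1]]$exons, hit_p, gm$genes[[1]])
  a_m <- map_introns_to_domain(gm$genes[[2]]$exons, hit_m, gm$genes[[2]])
  expect_identical(a_p$events, a_m$events)
  expect_error(gen_gene_models(list(list(positions = 99L, phases = 0L))),
               "outside")
})

test_that("duplication layouts are recovered exactly from the truth", {
  dup <- gen_duplication_layout(n_tandem = 2, n_segmental = 3, seed = 14)
  tand <- find_tandem_pairs(dup$family_ids, dup$genes, dup$proteins)
  expect_equal(tand[order(tand$gene_a), c("gene_a", "gene_b")],
               dup$truth$tandem[order(dup$truth$tandem$gene_a), ],
               ignore_attr = TRUE)
  fam_genes <- dup$genes[vapply(dup$genes, `[[`, "", "gene_id") %in%
                           dup$family_ids]
  seg <- assign_segmental(fam_genes, dup$blocks, tandem = tand)
  expect_equal(seg[order(seg$gene_a), c("gene_a", "gene_b")],
               dup$truth$segmental[order(dup$truth$segmental$gene_a), ],
               ignore_attr = TRUE)
  # a filler between a planted pair breaks the tandem call
  ids <- vapply(dup$genes, `[[`, "", "gene_id")
  pair1 <- dup$truth$tandem[1, ]
  g_b <- dup$genes[[which(ids == pair1$gene_b)]]
  wedge <- list(gene_id = "wedge", chromosome = g_b$chromosome,
                start = g_b$start - 100L, end = g_b$start - 50L, strand = "+",
                exons = cbind(start = g_b$start - 100L, end = g_b$start - 50L),
                cds_segments = cbind(start = g_b$start - 100L,
                                     end = g_b$start - 50L, phase = 0L))
  tand2 <- find_tandem_pairs(dup$family_ids, c(dup$genes, list(wedge)),
                             dup$proteins)
  expect_false(any(tand2$gene_a == pair1$gene_a &
                     tand2$gene_b == pair1$gene_b))
  # empty block table -> zero segmental calls
  empty_blocks <- dup$blocks[0, ]
  expect_equal(nrow(assign_segmental(fam_genes, empty_blocks)), 0L)
})

test_that("noise-free expression recovers planted folds and structure", {
  ex <- gen_expression(noise_sd = 0, seed = 6)
  q <- qpcr_fold_changes(ex$qpcr)
  expect_equal(q$relative_expression, ex$truth$folds$fold, tolerance = 1e-12)
  # effect_size = 0 -> no tissue-specific signal anywhere
  ex0 <- gen_expression(effect_size = 0, noise_sd = 0, seed = 6)
  expect_true(all(apply(ex0$matrix, 1, function(r) diff(range(r))) == 0))
  # preferred tissue carries the maximum in the noise-free case
  top <- colnames(ex$matrix)[apply(ex$matrix, 1, which.max)]
  expect_equal(top, ex$truth$groups$preferred_tissue)
})
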