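test_that("default profile encodes the 19-conserved 5/5/1/8 layout", {
  p <- default_profile$positions
  expect_equal(sum(p$conserved), 19L)
  expect_equal(vapply(c("basic", "helix1", "loop", "helix2"),
                      function(r) sum(p$conserved & p$region == r), 0L),
               c(basic = 5L, helix1 = 5L, loop = 1L, helix2 = 8L))
  for (lab in c("His/Lys-9", "Glu-13", "Arg-14", "Gln-15", "Arg-16",
                "Arg-17", "Gln-22", "Leu-27", "Leu-54"))
    expect_equal(sum(p$label == lab), 1L)
})

test_that("profile validation rejects broken tables, accepts toy profiles", {
  f <- withr::local_tempfile(fileext = ".tsv")
  # full-domain profile missing the Glu-13 label -> classifier dependency error
  tab <- read.delim(extdata_path("bhlh_consensus_profile.tsv"),
                    comment.char = "#", colClasses = c(label = "character"))
  tab$label[tab$label == "Glu-13"] <- ""
  write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_profile(f), "Glu-13")

  # single-position toy profile loads with empty loop span
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("index\tregion\tallowed_residues\tconserved\tlabel\tconsensus",
               "1\tbasic\tE\t1\t\tE"), f2)
  toy <- load_profile(f2)
  expect_length(toy$loop_span, 0L)

  # duplicate index / unknown region / empty residue set
  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("index\tregion\tallowed_residues\tconserved\tlabel\tconsensus",
               "1\tbasic\tE\t1\t\tE", "1\tbasic\tR\t1\t\tR"), f3)
  expect_error(load_profile(f3), "duplicate")
  f4 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("index\tregion\tallowed_residues\tconserved\tlabel\tconsensus",
               "1\tbogus\tE\t1\t\tE"), f4)
  expect_error(load_profile(f4), "region")
})

test_that("alignment finds planted domains with exact mismatch counts", {
  seq0 <- paste0(paste(rep("G", 40), collapse = ""), CONSENSUS,
                 paste(rep("G", 10), collapse = ""))
  h <- align_to_profile(setNames(seq0, "x"), default_profile)
  expect_equal(h$start, 41L)
  expect_equal(h$mismatch_count, 0L)

  # three conserved positions mutated to disallowed residues
  dom3 <- mutate_domain(c("13" = "G", "27" = "G", "54" = "G"))
  h3 <- align_to_profile(setNames(embed_domain(dom3), "x3"), default_profile)
  expect_equal(h3$mismatch_count, 3L)

  # poly-alanine never passes the budget
  ha <- align_to_profile(setNames(paste(rep("A", 200), collapse = ""), "pa"),
                         default_profile)
  expect_gt(ha$mismatch_count, 9L)

  # translation invariance: 50 extra leading residues shift start only
  set.seed(11)
  prefix <- paste(sample(AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                         50, replace = TRUE), collapse = "")
  h0 <- align_to_profile(setNames(embed_domain(CONSENSUS), "a"),
                         default_profile)
  hs <- align_to_profile(setNames(paste0(prefix, embed_domain(CONSENSUS)), "b"),
                         default_profile)
  expect_equal(hs$start, h0$start + 50L)
  expect_equal(hs$mismatch_count, h0$mismatch_count)
  expect_equal(unname(hs$residue_at), unname(h0$residue_at))
})

test_that("mismatch count is monotone in planted mutations", {
  set.seed(42)
  cons_idx <- default_profile$positions$index[default_profile$positions$conserved]
  order_mut <- sample(cons_idx)
  dom <- strsplit(CONSENSUS, "")[[1]]
  prev <- 0L
  for (k in 1:6) {
    i <- order_mut[k]
    pool <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                    default_profile$allowed[[i]])
    dom[i] <- sample(pool, 1L)
    h <- align_to_profile(
      setNames(embed_domain(paste(dom, collapse = "")), "m"), default_profile)
    expect_equal(h$mismatch_count, prev + 1L)
    prev <- h$mismatch_count
  }
})

test_that("scan honours the nine-mismatch acceptance boundary", {
  pr <- gen_proteome(6L, 6L, mismatch_counts = c(8L, 9L, 9L, 10L, 10L, 11L),
                    seed = 5L, profile = default_profile)
  hits <- scan_proteome(pr$proteins, default_profile, max_mismatch = 9L)
  got <- hits_table(hits)$protein_id
  want <- pr$truth$protein_id[pr$truth$true_mismatch <= 9L]
  expect_setequal(got, want)
})

test_that("position conservation reports modal frequencies", {
  h1 <- aligned_hit(embed_domain(CONSENSUS), "a")
  hits10 <- lapply(1:10, function(i) aligned_hit(embed_domain(CONSENSUS),
                                                 paste0("h", i)))
  pc <- position_conservation(hits10)
  expect_true(all(pc$frequency == 1.0))
  expect_true(all(pc$conserved_in_dataset[pc$n > 0]))

  # 2/3 agreement at position 1 (non-conserved, free residue)
  hits3 <- list(aligned_hit(embed_domain(CONSENSUS), "a"),
                aligned_hit(embed_domain(CONSENSUS), "b"),
                aligned_hit(embed_domain(mutate_domain(c("1" = "W"))), "c"))
  pc3 <- position_conservation(hits3, threshold = 0.5)
  expect_equal(pc3$frequency[pc3$index == 1], 2 / 3, tolerance = 1e-12)
  expect_true(pc3$conserved_in_dataset[pc3$index == 1])
  pc_strict <- position_conservation(hits3, threshold = 1.0)
  expect_false(pc_strict$conserved_in_dataset[pc_strict$index == 1])

  expect_error(position_conservation(list()), "no hits")
})

test_that("protein properties match hand-computed values", {
  expect_equal(protein_properties("LLLL")$gravy, 3.8)
  expect_equal(protein_properties("G")$mw, 75.07, tolerance = 1e-3)
  pi_d <- protein_properties("DDDD")$pi
  pi_k <- protein_properties("KKKK")$pi
  expect_lt(pi_d, 7)
  expect_gt(pi_k, 7)
  # pI is a root of the net-charge function
  counts <- table(factor(strsplit("DDDD", "")[[1]],
                         levels = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]))
  expect_lt(abs(bhlhfam:::net_charge(counts, pi_d, bhlhfam:::.load_pka())),
            1e-3)
  expect_warning(p <- protein_properties("GXG"), "X residue")
  expect_equal(p$length, 3L)
  expect_equal(p$mw, 2 * 57.0519 + 18.0153, tolerance = 1e-3)
  expect_equal(protein_properties("DKRE")$n_negative, 2L)
  expect_equal(protein_properties("DKRE")$n_positive, 2L)
})
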