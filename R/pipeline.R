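#' Build a pipeline run configuration
#'
#' Defaults reproduce the published settings where stated: a nine-mismatch
#' budget, 1000 bootstrap replicates, subfamily support threshold 50 and a
#' 1500 bp upstream promoter window.
#'
#' @param proteome,cds,genome_fasta,gff,synteny,expression,qpcr input paths
#'   (\code{NULL} = stage skipped)
#' @param profile_path,pattern_catalog,motif_dict config-file paths
#'   (\code{NULL} = shipped defaults)
#' @param out_dir output directory
#' @param max_mismatch domain-scan mismatch budget
#' @param identity_min tandem protein-identity threshold
#' @param lambda_syn synonymous clock rate (substitutions/site/year)
#' @param bootstrap_reps,seed bootstrap replicates and RNG seed
#' @param min_support subfamily support threshold (strict)
#' @param upstream_width promoter window (bp)
#' @param stages character vector of stages, or \code{"all"}; stages:
#'   scan, classify, phylo, dup, structure, promoter, expr
#' @return a \code{bhlh_config} list
#' @export
run_config <- function(proteome = NULL, cds = NULL, genome_fasta = NULL,
                       gff = NULL, synteny = NULL, expression = NULL,
                       qpcr = NULL, profile_path = NULL,
                       pattern_catalog = NULL, motif_dict = NULL,
                       out_dir = "bhlh_run", max_mismatch = 9L,
                       identity_min = 0.4, lambda_syn = 6.5e-9,
                       bootstrap_reps = 1000L, seed = 1L, min_support = 50,
                       upstream_width = 1500L, stages = "all") {
  cfg <- as.list(environment())
  class(cfg) <- "bhlh_config"
  cfg
}

#' Hash of a run configuration
#' @param config a \code{bhlh_config}
#' @return md5 hex string
#' @export
config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  # version-stable text serialization
  keys <- sort(names(config))
  writeLines(vapply(keys, function(k)
    paste0(k, "=", paste(format(config[[k]], digits = 15), collapse = ",")),
    character(1)), f)
  unname(tools::md5sum(f))
}

.stage_requirements <- list(
  scan = "proteome", classify = "proteome", phylo = "proteome",
  dup = c("proteome", "gff"), structure = c("proteome", "gff"),
  promoter = c("genome_fasta", "gff"), expr = character())

#' Run the analysis pipeline
#'
#' Stages run in dependency order (scan, classify/properties, phylogeny,
#' duplication, structure, promoter, expression); each stage writes its TSV
#' into \code{config$out_dir} and contributes to a summary report (family
#' size, per-chromosome counts, binding-category counts, tandem/segmental
#' counts, intron-pattern histogram).  Every run records the package
#' version, seed, clock rate and config hash in \code{run.log}; when the
#' stored config hash matches and a report exists the cached report is
#' returned, and any config change forces full recomputation.
#'
#' @param config a [run_config()] object
#' @return list with \code{report} (data.frame key/value), \code{tables}
#'   (paths) and the in-memory stage results
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "bhlh_config"))
  stages <- config$stages
  all_stages <- names(.stage_requirements)
  if (identical(stages, "all")) {
    stages <- all_stages[vapply(all_stages, function(s) {
      req <- .stage_requirements[[s]]
      all(vapply(req, function(r) !is.null(config[[r]]), logical(1))) &&
        (s != "expr" || !is.null(config$expression) || !is.null(config$qpcr))
    }, logical(1))]
  }
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  # fail before any work when a selected stage lacks inputs
  for (s in stages) {
    req <- .stage_requirements[[s]]
    for (r in req) {
      if (is.null(config[[r]]))
        stop("stage '", s, "' requires input '", r, "'")
      if (!file.exists(config[[r]]))
        stop("stage '", s, "' input does not exist: ", config[[r]])
    }
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  hash_file <- file.path(config$out_dir, "config.hash")
  report_file <- file.path(config$out_dir, "report.tsv")
  if (file.exists(hash_file) && file.exists(report_file) &&
      identical(readLines(hash_file, warn = FALSE)[1], hash)) {
    rep_cache <- read.delim(report_file, comment.char = "#",
                            stringsAsFactors = FALSE)
    return(list(report = rep_cache, tables = NULL, cached = TRUE))
  }

  profile <- load_profile(config$profile_path)
  warnings_seen <- character(0)
  note <- function(w) warnings_seen <<- c(warnings_seen, w)
  report <- list()
  results <- list()
  out <- list()

  proteins <- NULL
  hits <- NULL
  if (length(intersect(stages, c("scan", "classify", "phylo", "dup",
                                 "structure")))) {
    proteins <- read_fasta(config$proteome)
    hits <- scan_proteome(proteins, profile,
                          max_mismatch = config$max_mismatch)
    ht <- hits_table(hits)
    results$hits <- ht
    report$family_size <- nrow(ht)
    if ("scan" %in% stages) {
      fam <- proteins[proteins$id %in% ht$protein_id, , drop = FALSE]
      results$properties <- withCallingHandlers(
        proteome_properties(fam),
        warning = function(w) { note(conditionMessage(w))
                                invokeRestart("muffleWarning") })
    }
  }

  if ("classify" %in% stages && length(hits)) {
    calls <- classify_all(hits, profile)
    results$calls <- calls
    for (cat in c("G_BOX", "E_BOX_NON_G", "NON_E_BOX_BINDER",
                  "NON_DNA_BINDING"))
      report[[paste0("category_", cat)]] <- sum(calls$category == cat)
  }

  if ("phylo" %in% stages && length(hits) >= 3L) {
    aln <- setNames(
      vapply(hits, function(h)
        paste(ifelse(is.na(h$residue_at), "-", h$residue_at), collapse = ""),
        character(1)),
      vapply(hits, `[[`, "", "protein_id"))
    tree <- withCallingHandlers(
      bootstrap_support(aln, n_reps = config$bootstrap_reps,
                        seed = config$seed),
      warning = function(w) { note(conditionMessage(w))
                              invokeRestart("muffleWarning") })
    ape::write.tree(tree, file.path(config$out_dir, "tree.nwk"))
    sf <- extract_subfamilies(tree, min_support = config$min_support)
    results$subfamilies <- data.frame(
      protein_id = c(names(sf$assignments), sf$unassigned),
      subfamily = c(unname(sf$assignments),
                    rep("unassigned", length(sf$unassigned))),
      stringsAsFactors = FALSE)
    report$n_subfamilies <- length(unique(sf$assignments))
    report$n_unassigned <- length(sf$unassigned)
  }

  genes <- NULL
  if (length(intersect(stages, c("dup", "structure", "promoter")))) {
    genes <- read_gff3(config$gff)
    results$genes <- genes
  }

  if ("dup" %in% stages && length(hits)) {
    fam_ids <- intersect(hits_table(hits)$protein_id,
                         vapply(genes, `[[`, "", "gene_id"))
    chroms <- vapply(genes, `[[`, "", "chromosome")
    for (ch in sort(unique(chroms[vapply(genes, `[[`, "", "gene_id") %in%
                                    fam_ids])))
      report[[paste0("chrom_", ch)]] <-
        sum(chroms == ch & vapply(genes, `[[`, "", "gene_id") %in% fam_ids)
    tandem <- find_tandem_pairs(fam_ids, genes, proteins,
                                identity_min = config$identity_min)
    seg <- if (!is.null(config$synteny)) {
      fam_genes <- genes[vapply(genes, `[[`, "", "gene_id") %in% fam_ids]
      assign_segmental(fam_genes, read_synteny_table(config$synteny),
                       tandem = tandem)
    } else NULL
    pairs <- rbind(tandem[c("gene_a", "gene_b", "dup_type")],
                   if (!is.null(seg)) seg[c("gene_a", "gene_b", "dup_type")])
    if (!is.null(pairs) && nrow(pairs) && !is.null(config$cds)) {
      cds <- read_fasta(config$cds)
      have <- pairs$gene_a %in% cds$id & pairs$gene_b %in% cds$id
      if (any(have))
        pairs <- rbind(
          pair_kaks(pairs[have, , drop = FALSE], cds, proteins,
                    lambda_syn = config$lambda_syn),
          if (any(!have)) cbind(pairs[!have, , drop = FALSE], ka = NA,
                                ks = NA, ratio = NA, selection = "undefined",
                                t_mya = NA, lambda_syn = config$lambda_syn))
    }
    results$pairs <- pairs
    report$n_tandem <- nrow(tandem)
    report$n_segmental <- if (is.null(seg)) 0L else nrow(seg)
  }

  if ("structure" %in% stages && length(hits)) {
    catalog <- load_pattern_catalog(config$pattern_catalog)
    byid <- setNames(genes, vapply(genes, `[[`, "", "gene_id"))
    rows <- list()
    for (h in hits) {
      g <- byid[[h$protein_id]]
      if (is.null(g)) next
      asn <- map_introns_to_domain(g$exons, h, g)
      lab <- assign_pattern(asn, catalog)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = asn$gene_id, pattern = lab,
        positions = paste(asn$events$domain_position, collapse = ","),
        phases = paste(asn$events$phase, collapse = ","),
        stringsAsFactors = FALSE)
    }
    patt <- do.call(rbind, rows)
    results$patterns <- patt
    if (!is.null(patt))
      for (p in sort(unique(patt$pattern)))
        report[[paste0("pattern_", p)]] <- sum(patt$pattern == p)
  }

  if ("promoter" %in% stages) {
    genome <- read_fasta(config$genome_fasta)
    gmap <- setNames(genome$sequence, genome$id)
    ids <- vapply(genes, `[[`, "", "gene_id")
    upstream <- setNames(vapply(genes, function(g) {
      cs <- gmap[[g$chromosome]]
      if (is.null(cs)) "" else extract_upstream(cs, g, config$upstream_width)
    }, character(1)), ids)
    mot <- load_motif_dict(config$motif_dict)
    mh <- scan_promoter(upstream[nzchar(upstream)], mot)
    results$motif_hits <- mh
    results$motif_counts <- motif_counts(mh)
    report$n_motif_hits <- nrow(mh)
  }

  if ("expr" %in% stages) {
    if (!is.null(config$expression)) {
      m <- read_expression_matrix(config$expression)
      lm <- log2_matrix(m)
      results$log2_expression <- data.frame(gene_id = rownames(lm), lm,
                                            check.names = FALSE,
                                            stringsAsFactors = FALSE)
    }
    if (!is.null(config$qpcr)) {
      q <- read.delim(config$qpcr, stringsAsFactors = FALSE)
      results$qpcr <- qpcr_fold_changes(q)
    }
  }

  tables <- write_results_tables(
    results[vapply(results, is.data.frame, logical(1)) |
              names(results) == "genes"],
    config$out_dir)
  rep_df <- data.frame(key = names(report),
                       value = vapply(report, function(v)
                         paste(format(v), collapse = ";"), character(1)),
                       stringsAsFactors = FALSE)
  con <- file(report_file, "w")
  writeLines(paste0("# config_hash=", hash), con)
  suppressWarnings(write.table(rep_df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  close(con)
  writeLines(hash, hash_file)
  log_lines <- c(
    paste0("bhlhfam version: ",
           as.character(utils::packageVersion("bhlhfam"))),
    paste0("seed: ", config$seed),
    paste0("lambda_syn: ", format(config$lambda_syn)),
    paste0("config_hash: ", hash),
    paste0("stages: ", paste(stages, collapse = ",")),
    if (length(warnings_seen)) paste0("warning: ", unique(warnings_seen)))
  writeLines(log_lines, file.path(config$out_dir, "run.log"))
  list(report = rep_df, tables = tables, results = results,
       warnings = unique(warnings_seen), cached = FALSE)
}
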