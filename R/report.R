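#' Default symbiosis-gene keyword sets
#'
#' Category -> phrase lists for the description-line keyword scan:
#' candidate symbiosis genes (glutamate dehydrogenase, glutathione
#' S-transferase, lectin, glutamine synthetase, lipase, phospholipase,
#' ferritin) plus the lectin subtypes distinguished in holobiont EST
#' surveys (c-type, g-type, galectin, ricin B, mannose binding, ...).
#'
#' @return Named list of character vectors.
#' @export
defaultSymbiosisKeywords <- function() {
  list(
    "glutamate dehydrogenase" = "glutamate dehydrogenase",
    "glutathione S-transferase" = c("glutathione s-transferase",
                                    "glutathione transferase"),
    "lectin" = "lectin",
    "glutamine synthetase" = "glutamine synthetase",
    "lipase" = "lipase",
    "phospholipase" = "phospholipase",
    "ferritin" = "ferritin")
}

#' @rdname defaultSymbiosisKeywords
#' @return \code{defaultLectinKeywords}: lectin-subtype categories.
#' @export
defaultLectinKeywords <- function() {
  list(
    "c-type lectin" = "c-type lectin",
    "g-type lectin" = "g-type lectin",
    "galectin" = "galectin",
    "fucolectin" = "fucolectin",
    "ricin b lectin" = "ricin b",
    "mannose binding lectin" = "mannose binding",
    "rhamnose binding lectin" = "rhamnose binding",
    "lectin receptor kinase" = "lectin receptor kinase",
    "selectin" = "selectin",
    "other lectins" = "lectin")
}

#' Keyword scan of annotation descriptions
#'
#' Counts, per sample and category, the unigenes whose description matches
#' at least one phrase of the category (plain case-insensitive substring
#' matching -- protein descriptions are free text). A unigene counts once
#' per category, at its first matching phrase; a \code{"Total"} row sums
#' the categories.
#'
#' @param annotations data.frame with columns \code{unigene},
#'   \code{sample}, \code{description}.
#' @param keyword_sets Named list category -> phrase vector.
#' @return Integer matrix (categories + Total) x samples.
#' @export
keywordScan <- function(annotations,
                        keyword_sets = defaultSymbiosisKeywords()) {
  samples <- sort(unique(annotations$sample))
  if (!length(samples)) samples <- character(0)
  out <- matrix(0L, length(keyword_sets) + 1L, length(samples),
                dimnames = list(c(names(keyword_sets), "Total"), samples))
  desc <- tolower(annotations$description)
  for (ci in seq_along(keyword_sets)) {
    hit <- rep(FALSE, nrow(annotations))
    for (phrase in keyword_sets[[ci]])
      hit <- hit | grepl(tolower(phrase), desc, fixed = TRUE)
    # one count per unigene per category
    if (any(hit)) {
      u <- annotations[hit, c("unigene", "sample")]
      u <- u[!duplicated(u$unigene), , drop = FALSE]
      tab <- table(u$sample)
      out[ci, names(tab)] <- as.integer(tab)
    }
  }
  out["Total", ] <- colSums(out[seq_along(keyword_sets), , drop = FALSE])
  out
}

#' Compare GC-content distributions between groups
#'
#' Normalized histograms at \code{bin_width} plus the two-sample
#' Kolmogorov-Smirnov statistic for every group pair (statistic only; the
#' comparison is descriptive).
#'
#' @param groups Named list of numeric vectors of GC fractions.
#' @param bin_width Histogram bin width (default 0.01).
#' @return A list with \code{histograms} (named list of density
#'   histograms) and \code{ks} (symmetric matrix of KS statistics).
#' @export
gcCompare <- function(groups, bin_width = 0.01) {
  if (!length(groups)) stop("no groups")
  if (any(!lengths(groups))) stop("empty group")
  breaks <- seq(0, 1, by = bin_width)
  hists <- lapply(groups, function(g)
    graphics::hist(pmin(pmax(g, 0), 1), breaks = breaks, plot = FALSE))
  n <- length(groups)
  ks <- matrix(0, n, n, dimnames = list(names(groups), names(groups)))
  if (n > 1)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      st <- suppressWarnings(stats::ks.test(groups[[i]], groups[[j]]))
      ks[i, j] <- ks[j, i] <- unname(st$statistic)
    }
  list(histograms = hists, ks = ks)
}

#' Run the full holobiont EST pipeline
#'
#' Executes the stages in order -- simulate (or accept reads), clean
#' (length filter + poly-A trimming), partition into rRNA/mRNA, LCA
#' taxonomic classification of both fractions, six-frame cross-sample
#' clustering, CTLD mining (translated similarity-search seeding, grammar
#' scan, per-sample dedup, sugar/WIGL classification) and, when at least
#' three unique domains exist, alignment, block curation and NJ phylogeny
#' -- then assembles the report bundle. Any stage failure aborts with the
#' stage name.
#'
#' @param config A \code{\link{simulationConfig}} (the pipeline simulates
#'   its input) or a \linkS4class{HolobiontSim}.
#' @param out_dir Optional output directory; when given, all intermediates
#'   (FASTAs, TSV tables, Newick tree, JSON manifest, log) are written.
#' @param min_len Length-filter threshold (bp).
#' @param rule Partition rule.
#' @param top_percent,min_score_nt,min_score_aa LCA and search thresholds.
#' @param cluster_threshold Clustering identity threshold.
#' @param kmer_filter k-mer prefilter for clustering (0 = exact).
#' @param ctld_min_score Seed-search score threshold for CTLD mining.
#' @param dedupe_threshold Domain dedup identity threshold.
#' @return A list-style report bundle with elements \code{cleaned},
#'   \code{partition}, \code{taxon_table}, \code{clusters}, \code{venn},
#'   \code{domains}, \code{unique_domains}, \code{wigl}, \code{gc},
#'   \code{tree}, \code{stats}, \code{log}.
#' @export
runPipeline <- function(config, out_dir = NULL, min_len = 200L,
                        rule = partitionRule(), top_percent = 10,
                        min_score_nt = 40, min_score_aa = 50,
                        cluster_threshold = 0.5, kmer_filter = 5L,
                        ctld_min_score = 60, dedupe_threshold = 0.97) {
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, paste0(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  sim <- stage("simulate", {
    if (methods::is(config, "SimulationConfig")) simulateHolobiont(config)
    else if (methods::is(config, "HolobiontSim")) config
    else stop("config must be a SimulationConfig or HolobiontSim")
  })
  note("simulated ", length(sim@reads), " reads, seed ", sim@config@seed)

  cleaned <- stage("clean", {
    trimmed <- trimPolyA(sim@reads)
    lengthFilter(trimmed, min_len = min_len)$kept
  })
  note("cleaned: ", length(cleaned), " unigenes pass the ", min_len,
       " bp filter")
  stats_tab <- sampleStats(cleaned)

  taxonomy <- demoTaxonomy()
  ref_taxa <- stats::setNames(sim@refTaxa$taxon, sim@refTaxa$subject)

  nt_scheme <- scoringScheme("nucleotide")
  rrna_refs <- sim@references[matchesRrnaKeyword(names(sim@references))]
  hits_rrna <- stage("partition", {
    if (length(rrna_refs))
      searchHomology(cleaned, rrna_refs, nt_scheme,
                     min_score = min_score_nt, ref_taxa = ref_taxa)
    else emptyHits()
  })
  part <- stage("partition", partitionUnigenes(cleaned, hits_rrna, rule))
  mrna <- partitionFraction(part, cleaned, "mRNA")
  rrna <- partitionFraction(part, cleaned, "rRNA")
  note("partition: ", length(rrna), " rRNA / ", length(mrna), " mRNA")

  gene_refs <- sim@references[!matchesRrnaKeyword(names(sim@references))]
  hits_mrna <- stage("classify", {
    if (length(mrna) && length(gene_refs))
      searchHomology(mrna, gene_refs, nt_scheme,
                     min_score = min_score_nt, ref_taxa = ref_taxa)
    else emptyHits()
  })
  taxon_table <- stage("classify", {
    asn_r <- if (length(rrna))
      lcaAssignAll(hits_rrna, names(rrna), taxonomy,
                   top_percent = top_percent, min_score = min_score_nt)
    else character(0)
    asn_m <- if (length(mrna))
      lcaAssignAll(hits_mrna, names(mrna), taxonomy,
                   top_percent = top_percent, min_score = min_score_nt)
    else character(0)
    asn <- rbind(
      if (length(asn_r)) data.frame(id = names(asn_r),
        sample = unname(sampleOf(rrna)[names(asn_r)]), fraction = "rRNA",
        taxon = unname(asn_r), stringsAsFactors = FALSE),
      if (length(asn_m)) data.frame(id = names(asn_m),
        sample = unname(sampleOf(mrna)[names(asn_m)]), fraction = "mRNA",
        taxon = unname(asn_m), stringsAsFactors = FALSE))
    if (is.null(asn) || !nrow(asn)) NULL else buildTaxonCountTable(asn)
  })
  note("classified against ", length(gene_refs), " reference transcripts")

  clusters <- venn <- NULL
  if (length(mrna) >= 2) {
    clusters <- stage("cluster",
      clusterSixFrames(mrna, threshold = cluster_threshold,
                       kmer_filter = kmer_filter))
    venn <- stage("cluster", vennCounts(clusters))
    note("clustered ", length(mrna), " mRNA unigenes into ",
         length(clusters), " unigene-level clusters")
  } else note("clustering skipped: fewer than 2 mRNA unigenes")

  domains <- .emptyDomains(); unique_domains <- .emptyDomains()
  tree <- NULL
  if (length(mrna)) {
    aa_scheme <- scoringScheme("protein")
    seeds <- stage("ctld-scan",
      searchHomology(mrna, sim@proteinRefs, aa_scheme,
                     min_score = ctld_min_score))
    domains <- stage("ctld-scan", scanCtld(mrna, seed_hits = seeds))
    unique_domains <- stage("ctld-scan", {
      parts <- split(domains, domains$sample)
      res <- lapply(parts, dedupeDomains,
                    identity_threshold = dedupe_threshold)
      out <- do.call(rbind, res)
      if (is.null(out)) .emptyDomains() else { rownames(out) <- NULL; out }
    })
    note("CTLD: ", nrow(domains), " domain(s), ", nrow(unique_domains),
         " unique after dedup")
    if (nrow(unique_domains) >= 3) {
      tree <- stage("phylo", {
        peps <- stats::setNames(
          unique_domains$domain_seq,
          paste0(unique_domains$unigene, "|", unique_domains$frame, "|",
                 unique_domains$start))
        msa <- progressiveAlign(peps)
        cur <- curateBlocks(msa, max_gap_fraction = 0,
                            min_conservation = 0.2, min_block_length = 10L)
        use <- if (length(cur$kept) >= 30) cur$msa else msa
        njTree(distanceMatrix(use))
      })
      note("phylogeny over ", nrow(unique_domains), " unique domains")
    } else note("phylogeny skipped: fewer than 3 unique domains")
  } else note("CTLD scan skipped: empty mRNA fraction")

  gc <- stage("report", {
    groups <- split(unname(gcContent(cleaned)), cleaned@sample)
    groups <- groups[lengths(groups) > 0]
    if (length(groups)) gcCompare(groups) else NULL
  })
  annotations <- stage("report", {
    if (nrow(hits_mrna)) {
      best <- hits_mrna[!duplicated(hits_mrna$query_id), , drop = FALSE]
      data.frame(unigene = best$query_id,
                 sample = unname(sampleOf(mrna)[best$query_id]),
                 description = best$subject_description,
                 stringsAsFactors = FALSE)
    } else data.frame(unigene = character(0), sample = character(0),
                      description = character(0), stringsAsFactors = FALSE)
  })
  keywords <- keywordScan(annotations)

  bundle <- list(sim = sim, cleaned = cleaned, stats = stats_tab,
                 partition = part, taxon_table = taxon_table,
                 clusters = clusters, venn = venn, domains = domains,
                 unique_domains = unique_domains,
                 wigl = wiglVariants(unique_domains), gc = gc,
                 keywords = keywords, tree = tree, log = log_lines,
                 params = list(min_len = min_len, top_percent = top_percent,
                               min_score_nt = min_score_nt,
                               min_score_aa = min_score_aa,
                               cluster_threshold = cluster_threshold,
                               kmer_filter = kmer_filter,
                               ctld_min_score = ctld_min_score,
                               dedupe_threshold = dedupe_threshold,
                               seed = sim@config@seed))
  class(bundle) <- "HolobiontReport"
  if (!is.null(out_dir)) writeReportBundle(bundle, out_dir)
  bundle
}

#' @export
print.HolobiontReport <- function(x, ...) {
  cat("HolobiontReport\n")
  cat("  cleaned unigenes:", length(x$cleaned), "\n")
  cat("  rRNA/mRNA:", sum(x$partition@labels$label == "rRNA"), "/",
      sum(x$partition@labels$label == "mRNA"), "\n")
  if (!is.null(x$clusters)) cat("  clusters:", length(x$clusters), "\n")
  cat("  CTLD domains:", nrow(x$domains), "(", nrow(x$unique_domains),
      "unique )\n")
  if (!is.null(x$tree)) cat("  NJ tree over",
                            length(x$tree$tip.label), "domains\n")
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Writes every intermediate: cleaned FASTA, partition label TSV and
#' per-fraction FASTAs, taxon count table, cluster membership and Venn
#' TSVs, domain tables and FASTA, Newick tree, per-sample statistics, the
#' keyword-scan table, a JSON run manifest and the plain-text log.
#'
#' @param bundle A \code{HolobiontReport}.
#' @param out_dir Output directory.
#' @return \code{out_dir}, invisibly.
#' @export
writeReportBundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(out_dir, ...)
  writeFasta(bundle$cleaned, fp("cleaned.fasta"))
  utils::write.table(bundle$partition@labels, fp("partition_labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (frac in c("rRNA", "mRNA")) {
    sub <- partitionFraction(bundle$partition, bundle$cleaned, frac)
    if (length(sub)) writeFasta(sub, fp(paste0(tolower(frac), ".fasta")))
  }
  if (!is.null(bundle$taxon_table))
    writeTaxonCountTable(bundle$taxon_table, fp("taxon_counts.tsv"))
  if (!is.null(bundle$clusters)) {
    cl <- bundle$clusters
    rows <- do.call(rbind, lapply(seq_along(cl@members), function(k)
      data.frame(cluster = k, member = cl@members[[k]],
                 sample = unname(cl@sample[cl@members[[k]]]),
                 representative = cl@members[[k]] == cl@representatives[k],
                 stringsAsFactors = FALSE)))
    utils::write.table(rows, fp("clusters.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    venn <- data.frame(subset = names(bundle$venn$subset_counts),
                       clusters = unname(bundle$venn$subset_counts))
    utils::write.table(venn, fp("venn.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  utils::write.table(bundle$domains, fp("ctld_domains.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$unique_domains, fp("ctld_unique.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(bundle$unique_domains))
    writeFasta(stats::setNames(
      bundle$unique_domains$domain_seq,
      paste0(bundle$unique_domains$unigene, "|",
             bundle$unique_domains$frame)), fp("ctld_unique.fasta"))
  if (!is.null(bundle$tree))
    ape::write.tree(bundle$tree, fp("ctld_nj.nwk"))
  utils::write.table(bundle$stats, fp("sample_stats.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(bundle$keywords), fp("keywords.tsv"),
                     sep = "\t", quote = FALSE, row.names = TRUE)
  manifest <- c(list(package_version =
                       as.character(utils::packageVersion("HolobiontEST"))),
                bundle$params)
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  writeLines(bundle$log, fp("run.log"))
  invisible(out_dir)
}
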