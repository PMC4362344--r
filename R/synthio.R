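AA_FREE <- setdiff(names(.CODON_OF), c("C", "W"))  # never creates spurious
                                                   # cysteines or tryptophans

#' Simulation profile for one synthetic holobiont library
#'
#' @param sample_id Sample label.
#' @param n_reads Number of background reads (rRNA + mRNA mixture); planted
#'   CTLD and negative-control transcripts are added on top.
#' @param taxon_mix Named fractions (summing to 1) of background mRNA reads
#'   per taxon. Default: an acantharian host, a haptophyte photosymbiont, a
#'   gammaproteobacterial associate and a ciliate bystander.
#' @param gc_by_taxon Named GC targets in [0, 1] covering every taxon.
#' @param rrna_fraction Fraction of background reads drawn as windows of the
#'   packaged ribosomal references.
#' @param n_planted_ctld Number of CTLD-bearing transcripts; each founds one
#'   distinct domain family.
#' @param n_multidomain How many of those transcripts carry a second domain
#'   (a redundant near-copy of another family).
#' @param n_redundant_copies Total near-duplicate planted domains (>=
#'   \code{n_multidomain}); copies beyond the multi-domain ones are emitted
#'   as extra single-domain transcripts. Total planted domains =
#'   \code{n_planted_ctld + n_redundant_copies}.
#' @param n_negative_ctld Negative-control transcripts built without any
#'   cysteine or tryptophan codon (no 4-cysteine architecture).
#' @param wigl_variants WIGL-like 4-mers cycled over families.
#' @param sugar_motifs Sugar-binding 3-mers cycled over families.
#' @return A \linkS4class{SampleProfile}.
#' @export
sampleProfile <- function(sample_id, n_reads = 300L,
                          taxon_mix = c(Acantharea = 0.5, Haptophyta = 0.2,
                                        Gammaproteobacteria = 0.2,
                                        Ciliophora = 0.1),
                          gc_by_taxon = c(Acantharea = 0.46,
                                          Haptophyta = 0.55,
                                          Gammaproteobacteria = 0.40,
                                          Ciliophora = 0.50),
                          rrna_fraction = 0.05, n_planted_ctld = 0L,
                          n_multidomain = 0L, n_redundant_copies = 0L,
                          n_negative_ctld = 0L, wigl_variants = "WIGL",
                          sugar_motifs = "EPN") {
  methods::new("SampleProfile", sample_id = sample_id,
               n_reads = as.integer(n_reads), taxon_mix = taxon_mix,
               gc_by_taxon = gc_by_taxon, rrna_fraction = rrna_fraction,
               n_planted_ctld = as.integer(n_planted_ctld),
               n_multidomain = as.integer(n_multidomain),
               n_redundant_copies = as.integer(n_redundant_copies),
               n_negative_ctld = as.integer(n_negative_ctld),
               wigl_variants = wigl_variants, sugar_motifs = sugar_motifs)
}

#' Simulation configuration
#'
#' Read lengths are drawn from a truncated normal; the defaults (mean 350,
#' sd 90, minimum 150, maximum 1200) emulate the scale of a 454 EST survey
#' while keeping a tail of reads below the 200 bp cleaning threshold.
#'
#' @param profiles List of \code{\link{sampleProfile}} objects (a single
#'   profile may be passed directly).
#' @param seed Integer RNG seed; every per-sample stream is derived from
#'   (seed, sample_id) so adding a sample does not perturb the others.
#' @param read_length_mean,read_length_sd,read_length_min,read_length_max
#'   Truncated-normal read-length parameters in bp.
#' @param polyA_len_range Poly-A tail length interval (nt), applied to
#'   eukaryotic mRNA reads.
#' @param mutation_rate Per-site substitution rate applied to
#'   reference-derived reads, in [0, 0.3].
#' @param n_shared_genes Transcript families present in every sample
#'   (shared orthologs for cross-sample clustering).
#' @param shared_reads_per_sample Reads drawn from each shared gene in each
#'   sample.
#' @param genes_per_taxon Private reference genes per (sample, taxon).
#' @param gene_length Reference gene length in bp.
#' @return A \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(profiles, seed = 1L, read_length_mean = 350,
                             read_length_sd = 90, read_length_min = 150,
                             read_length_max = 1200,
                             polyA_len_range = c(10, 30),
                             mutation_rate = 0.02, n_shared_genes = 0L,
                             shared_reads_per_sample = 2L,
                             genes_per_taxon = 3L, gene_length = 900L) {
  if (methods::is(profiles, "SampleProfile")) profiles <- list(profiles)
  cfg <- methods::new("SimulationConfig", profiles = profiles,
                      seed = as.integer(seed),
                      read_length_mean = read_length_mean,
                      read_length_sd = read_length_sd,
                      read_length_min = read_length_min,
                      read_length_max = read_length_max,
                      polyA_len_range = as.numeric(polyA_len_range),
                      mutation_rate = mutation_rate,
                      n_shared_genes = as.integer(n_shared_genes),
                      genes_per_taxon = as.integer(genes_per_taxon),
                      gene_length = as.integer(gene_length))
  attr(cfg, "shared_reads_per_sample") <- as.integer(shared_reads_per_sample)
  cfg
}

#' Read a simulation configuration from JSON
#'
#' The JSON mirrors the constructor arguments: every dataset-level field of
#' \code{\link{simulationConfig}} plus a \code{profiles} array whose entries
#' hold \code{\link{sampleProfile}} arguments (maps such as
#' \code{taxon_mix} as JSON objects).
#'
#' @param path Path to a JSON file.
#' @return A \linkS4class{SimulationConfig}.
#' @export
readSimulationConfig <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(j$profiles)) stop("config must define 'profiles'")
  profiles <- lapply(j$profiles, function(p) {
    for (field in c("taxon_mix", "gc_by_taxon"))
      if (!is.null(p[[field]]))
        p[[field]] <- unlist(p[[field]])
    for (field in c("wigl_variants", "sugar_motifs"))
      if (!is.null(p[[field]]))
        p[[field]] <- as.character(unlist(p[[field]]))
    do.call(sampleProfile, p)
  })
  args <- lapply(j[setdiff(names(j), "profiles")], function(v)
    if (is.list(v)) unlist(v) else v)
  do.call(simulationConfig, c(list(profiles = profiles), args))
}

#' Packaged synthetic ribosomal references
#'
#' Synthetic rRNA reference sequences whose description lines carry the
#' ribosomal keywords (18S/16S/28S/23S/ITS...) and a taxon label; the
#' generator derives ribosomal reads from them.
#'
#' @return A list with \code{seqs} (\code{DNAStringSet}) and \code{taxa}
#'   (named character subject id -> taxon).
#' @export
referenceRrnas <- function() {
  path <- system.file("extdata", "synthetic_rrna_refs.fasta",
                      package = "HolobiontEST")
  seqs <- Biostrings::readDNAStringSet(path)
  tax_path <- system.file("extdata", "synthetic_ref_taxa.tsv",
                          package = "HolobiontEST")
  tab <- utils::read.table(tax_path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  list(seqs = seqs, taxa = stats::setNames(tab$taxon, tab$subject))
}

#' Packaged demonstration taxonomy
#'
#' A small hand-built taxonomy containing the bacterial and eukaryotic
#' groups a holobiont EST survey typically reports (Proteobacteria classes,
#' Bacteroidetes, Rhizaria subgroups, Alveolata subgroups, ...).
#'
#' @return A \linkS4class{TaxonomyMap}.
#' @export
demoTaxonomy <- function() {
  readTaxonomyMap(system.file("extdata", "taxonomy_demo.tsv",
                              package = "HolobiontEST"))
}

.isProkaryote <- function(taxon, taxonomy) {
  taxon %in% names(taxonomy@parent) &&
    "Bacteria" %in% taxonPath(taxonomy, taxon)
}

.mutate <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  if (length(hit)) {
    for (i in hit)
      ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
    seq <- paste(ch, collapse = "")
  }
  seq
}

# -- CTLD template machinery -------------------------------------------------

# Architecture of the packaged anchor domain, discovered by scanning it with
# the default grammar; free positions are everything outside the conserved
# cysteines, the WIGL-like motif and the sugar-motif column.
.scaffoldArch <- function(scaffold = referenceCtldAnchor(),
                          grammar = ctldGrammar()) {
  d <- .scanPeptide(scaffold, grammar)
  if (nrow(d) != 1L) stop("anchor reference must contain exactly one domain")
  chars <- strsplit(scaffold, "")[[1]]
  wigl_start <- as.integer(regexpr(d$wigl[1], scaffold, fixed = TRUE))
  sugar_start <- as.integer(regexpr("EPN", scaffold, fixed = TRUE))
  fixed <- c(d$cys1 + 1L, d$cys2 + 1L, d$cys3 + 1L, d$cys4 + 1L,
             wigl_start:(wigl_start + 3L), sugar_start:(sugar_start + 2L))
  list(chars = chars, len = length(chars),
       cys = c(d$cys1, d$cys2, d$cys3, d$cys4) + 1L,
       wigl_start = wigl_start, sugar_start = sugar_start,
       free = setdiff(seq_along(chars), fixed))
}

.mutateFree <- function(chars, free, prob) {
  hit <- free[stats::runif(length(free)) < prob]
  if (length(hit))
    chars[hit] <- sample(AA_FREE, length(hit), replace = TRUE)
  chars
}

.applyMotifs <- function(chars, arch, wigl, sugar) {
  stopifnot(nchar(wigl) == 4L, nchar(sugar) == 3L)
  chars[arch$wigl_start:(arch$wigl_start + 3L)] <- strsplit(wigl, "")[[1]]
  chars[arch$sugar_start:(arch$sugar_start + 2L)] <- strsplit(sugar, "")[[1]]
  chars
}

#' Embed a CTLD peptide template in a nucleotide sequence
#'
#' Reverse-translates \code{template} with a fixed most-frequent-codon
#' table and frames it so that translating the returned sequence in the
#' stated frame recovers the template exactly (negative frames place the
#' template on the reverse complement).
#'
#' @param template Peptide matching the CTLD grammar.
#' @param frame Integer in \{-3..-1, +1..+3\}.
#' @param grammar Grammar used to validate the template.
#' @return A nucleotide sequence (character).
#' @examples
#' tpl <- referenceCtldAnchor()
#' nt <- plantCtld(tpl, frame = 2)
#' grepl(tpl, sixFrameTranslate(nt)[["+2"]], fixed = TRUE)
#' @export
plantCtld <- function(template, frame, grammar = ctldGrammar()) {
  if (!frame %in% c(-3:-1, 1:3)) stop("frame must be in -3..-1, +1..+3")
  if (nrow(.scanPeptide(template, grammar)) < 1L)
    stop("template does not satisfy the CTLD grammar")
  nt <- .revTranslate(template)
  prefix <- strrep("G", abs(frame) - 1L)
  sense <- paste0(prefix, nt)
  if (frame > 0) sense else .revComp(sense)
}

# ---------------------------------------------------------------------------

.readLengths <- function(n, cfg) {
  .truncNorm(n, cfg@read_length_mean, cfg@read_length_sd,
             cfg@read_length_min, cfg@read_length_max)
}

# locate a planted domain peptide in the six frames of a (cleaned) read
.locateDomain <- function(read, domain_pep) {
  frames <- sixFrameTranslate(read)
  for (fr in names(frames)) {
    pos <- regexpr(domain_pep, frames[[fr]], fixed = TRUE)
    if (pos > 0L)
      return(list(frame = fr, start = as.integer(pos) - 1L,
                  end = as.integer(pos) - 1L + nchar(domain_pep)))
  }
  stop("planted domain not recoverable from read (generator bug)")
}

#' Simulate a synthetic holobiont EST dataset
#'
#' Generates, per sample: ribosomal reads as mutated windows of the
#' packaged rRNA references; background mRNA reads as mutated windows of
#' per-(sample, taxon) reference genes drawn at the taxon GC target, with
#' poly-A tails (uniform within \code{polyA_len_range}) on eukaryotic
#' transcripts and random strand orientation; optional shared-ortholog
#' reads present in every sample; planted CTLD-bearing transcripts
#' (single- and multi-domain, with redundant near-copies) and
#' cysteine-free negative controls. Every read receives one truth record;
#' every planted domain receives a truth record whose coordinates refer to
#' the six-frame translation of the poly-A/poly-T-trimmed read.
#'
#' Deterministic for a fixed seed: all FASTA/TSV outputs are byte
#' identical across runs.
#'
#' @param config A \code{\link{simulationConfig}}.
#' @param out_dir Optional directory; when given, per-sample read FASTAs,
#'   the reference FASTA, the subject-taxon sidecar and both truth tables
#'   are written there.
#' @return A \linkS4class{HolobiontSim}.
#' @export
simulateHolobiont <- function(config, out_dir = NULL) {
  methods::validObject(config)
  rr <- referenceRrnas()
  taxonomy <- demoTaxonomy()
  grammar <- ctldGrammar()
  arch <- .scaffoldArch()
  shared_per_sample <- attr(config, "shared_reads_per_sample")
  if (is.null(shared_per_sample)) shared_per_sample <- 2L

  # ---- reference genes ----
  genes <- list()     # id -> sequence
  gene_taxon <- character(0)
  for (p in config@profiles) {
    for (taxon in names(p@taxon_mix)) {
      if (p@taxon_mix[[taxon]] <= 0) next
      set.seed(.deriveSeed(config@seed,
                           paste("genes", p@sample_id, taxon, sep = "|")))
      for (g in seq_len(config@genes_per_taxon)) {
        gid <- paste0("gene_", p@sample_id, "_", taxon, "_", g)
        genes[[gid]] <- .randNt(config@gene_length, p@gc_by_taxon[[taxon]])
        gene_taxon[gid] <- taxon
      }
    }
  }
  shared_ids <- character(0)
  if (config@n_shared_genes > 0) {
    set.seed(.deriveSeed(config@seed, "shared"))
    for (g in seq_len(config@n_shared_genes)) {
      gid <- paste0("gene_shared_", g)
      genes[[gid]] <- .randNt(400L, 0.5)
      gene_taxon[gid] <- "Eukaryota"
      shared_ids <- c(shared_ids, gid)
    }
  }

  read_ids <- character(0); read_seqs <- character(0)
  read_sample <- character(0)
  truth_reads <- list(); truth_domains <- list()

  for (p in config@profiles) {
    sid <- p@sample_id
    set.seed(.deriveSeed(config@seed, sid))
    n <- p@n_reads
    n_rrna <- round(p@rrna_fraction * n)
    n_mrna <- n - n_rrna
    counter <- 0L
    newId <- function(prefix) {
      counter <<- counter + 1L
      paste0(sid, "_", prefix, counter)
    }
    emit <- function(id, seq, fraction, taxon, source, ctld = FALSE,
                     negative = FALSE) {
      read_ids[[length(read_ids) + 1L]] <<- id
      read_seqs[[length(read_seqs) + 1L]] <<- seq
      read_sample[[length(read_sample) + 1L]] <<- sid
      truth_reads[[length(truth_reads) + 1L]] <<- data.frame(
        id = id, sample = sid, fraction = fraction, taxon = taxon,
        source = source, length = nchar(seq), ctld = ctld,
        negative = negative, stringsAsFactors = FALSE)
    }
    lens <- .readLengths(n, config)

    # ribosomal reads
    if (n_rrna > 0) {
      ref_idx <- sample(length(rr$seqs), n_rrna, replace = TRUE)
      for (k in seq_len(n_rrna)) {
        ref <- rr$seqs[[ref_idx[k]]]
        rid <- sub("\\s.*$", "", names(rr$seqs)[ref_idx[k]])
        L <- min(lens[k], length(ref))
        s0 <- sample.int(length(ref) - L + 1L, 1L)
        w <- .mutate(as.character(Biostrings::subseq(ref, s0, s0 + L - 1L)),
                     config@mutation_rate)
        if (stats::runif(1) < 0.5) w <- .revComp(w)
        emit(newId("r"), w, "rRNA", unname(rr$taxa[rid]), rid)
      }
    }

    # background mRNA reads
    if (n_mrna > 0) {
      taxa_draw <- sample(names(p@taxon_mix), n_mrna, replace = TRUE,
                          prob = p@taxon_mix)
      for (k in seq_len(n_mrna)) {
        taxon <- taxa_draw[k]
        gid <- paste0("gene_", sid, "_", taxon, "_",
                      sample.int(config@genes_per_taxon, 1L))
        gene <- genes[[gid]]
        L <- min(lens[n_rrna + k], nchar(gene))
        s0 <- sample.int(nchar(gene) - L + 1L, 1L)
        w <- .mutate(substr(gene, s0, s0 + L - 1L), config@mutation_rate)
        if (!.isProkaryote(taxon, taxonomy)) {
          tail_len <- sample(config@polyA_len_range[1]:
                               config@polyA_len_range[2], 1L)
          w <- paste0(w, strrep("A", tail_len))
        }
        if (stats::runif(1) < 0.5) w <- .revComp(w)
        emit(newId("m"), w, "mRNA", taxon, gid)
      }
    }

    # shared-ortholog reads (full-length transcripts, lightly mutated)
    for (gid in shared_ids) {
      for (k in seq_len(shared_per_sample)) {
        w <- .mutate(genes[[gid]], config@mutation_rate)
        tail_len <- sample(config@polyA_len_range[1]:
                             config@polyA_len_range[2], 1L)
        w <- paste0(w, strrep("A", tail_len))
        if (stats::runif(1) < 0.5) w <- .revComp(w)
        emit(newId("s"), w, "mRNA", "Eukaryota", gid)
      }
    }

    # planted CTLD transcripts
    if (p@n_planted_ctld > 0) {
      base <- .mutateFree(arch$chars, arch$free, 0.35)
      fam_templates <- lapply(seq_len(p@n_planted_ctld), function(f) {
        ch <- .mutateFree(base, arch$free, 0.25)
        wigl <- p@wigl_variants[(f - 1L) %% length(p@wigl_variants) + 1L]
        sugar <- p@sugar_motifs[(f - 1L) %% length(p@sugar_motifs) + 1L]
        .applyMotifs(ch, arch, wigl, sugar)
      })
      copyOf <- function(f) {
        ch <- fam_templates[[f]]
        pos <- sample(arch$free, 1L)
        ch[pos] <- sample(setdiff(AA_FREE, ch[pos]), 1L)
        ch
      }
      n_extra <- p@n_redundant_copies - p@n_multidomain
      jobs <- list()
      for (j in seq_len(p@n_planted_ctld)) {
        doms <- list(list(family = j, copy = FALSE,
                          chars = fam_templates[[j]]))
        if (j <= p@n_multidomain) {
          src <- sample(seq_len(p@n_planted_ctld), 1L)
          doms[[2]] <- list(family = src, copy = TRUE, chars = copyOf(src))
        }
        jobs[[length(jobs) + 1L]] <- doms
      }
      for (e in seq_len(n_extra)) {
        src <- sample(seq_len(p@n_planted_ctld), 1L)
        jobs[[length(jobs) + 1L]] <- list(
          list(family = src, copy = TRUE, chars = copyOf(src)))
      }
      for (job in jobs) {
        lead <- sample(AA_FREE, 8L, replace = TRUE)
        pep <- lead
        dom_info <- list()
        for (d in job) {
          dom_start_aa <- length(pep)          # 0-based within peptide
          pep <- c(pep, d$chars)
          dom_info[[length(dom_info) + 1L]] <-
            list(family = d$family, copy = d$copy,
                 pep = paste(d$chars, collapse = ""))
          pep <- c(pep, sample(AA_FREE, 12L, replace = TRUE))  # linker/tail
        }
        sense <- .revTranslate(paste(pep, collapse = ""))
        frame <- sample(c(-3:-1, 1:3), 1L)
        prefix_nt <- paste(sample(c("C", "G"), abs(frame) - 1L,
                                  replace = TRUE), collapse = "")
        sense <- paste0(prefix_nt, sense)
        tail_len <- sample(config@polyA_len_range[1]:
                             config@polyA_len_range[2], 1L)
        sense_tailed <- paste0(sense, strrep("A", tail_len))
        read <- if (frame > 0) sense_tailed else .revComp(sense_tailed)
        id <- newId("ctld")
        emit(id, read, "mRNA", names(p@taxon_mix)[1],
             "planted_ctld", ctld = TRUE)
        clean <- .trimPolyAOne(read, 10L)
        for (d in dom_info) {
          loc <- .locateDomain(clean, d$pep)
          dsc <- .scanPeptide(d$pep, grammar)
          truth_domains[[length(truth_domains) + 1L]] <- data.frame(
            read = id, sample = sid, family = paste0(sid, "_f", d$family),
            redundant_copy = d$copy, frame = loc$frame,
            start = loc$start, end = loc$end,
            cys1 = loc$start + dsc$cys1[1], cys2 = loc$start + dsc$cys2[1],
            cys3 = loc$start + dsc$cys3[1], cys4 = loc$start + dsc$cys4[1],
            wigl = dsc$wigl[1], sugar_motif = substr(
              d$pep, arch$sugar_start, arch$sugar_start + 2L),
            domain_seq = d$pep, stringsAsFactors = FALSE)
        }
      }
    }

    # negative controls: no cysteine/tryptophan codons anywhere
    for (k in seq_len(p@n_negative_ctld)) {
      pep <- paste(sample(AA_FREE, 130L, replace = TRUE), collapse = "")
      emit(newId("neg"), .revTranslate(pep), "mRNA",
           names(p@taxon_mix)[1], "negative_control", negative = TRUE)
    }
  }

  reads <- UnigeneSet(
    Biostrings::DNAStringSet(stats::setNames(unlist(read_seqs),
                                             unlist(read_ids))),
    sample = unlist(read_sample))
  gene_set <- Biostrings::DNAStringSet(unlist(genes))
  names(gene_set) <- paste0(names(genes), " ", gene_taxon[names(genes)],
                            " reference transcript, synthetic")
  references <- c(rr$seqs, gene_set)
  ref_taxa <- data.frame(
    subject = c(sub("\\s.*$", "", names(rr$seqs)), names(genes)),
    taxon = c(unname(rr$taxa[sub("\\s.*$", "", names(rr$seqs))]),
              unname(gene_taxon[names(genes)])),
    stringsAsFactors = FALSE)
  tr <- if (length(truth_reads)) do.call(rbind, truth_reads) else
    data.frame()
  td <- if (length(truth_domains)) do.call(rbind, truth_domains) else
    .emptyTruthDomains()
  sim <- methods::new("HolobiontSim", reads = reads,
                      references = references,
                      proteinRefs = referenceCtlds(), refTaxa = ref_taxa,
                      truthReads = tr, truthDomains = td, config = config)
  if (!is.null(out_dir)) writeSimulation(sim, out_dir)
  sim
}

.emptyTruthDomains <- function() {
  data.frame(read = character(0), sample = character(0),
             family = character(0), redundant_copy = logical(0),
             frame = character(0), start = integer(0), end = integer(0),
             cys1 = integer(0), cys2 = integer(0), cys3 = integer(0),
             cys4 = integer(0), wigl = character(0),
             sugar_motif = character(0), domain_seq = character(0),
             stringsAsFactors = FALSE)
}

#' Write a simulated dataset to disk
#'
#' @param sim A \linkS4class{HolobiontSim}.
#' @param out_dir Output directory (created if needed).
#' @return \code{out_dir}, invisibly.
#' @export
writeSimulation <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (sid in unique(sim@reads@sample)) {
    sel <- sim@reads@sample == sid
    writeFasta(sim@reads[sel], file.path(out_dir,
                                         paste0("reads_", sid, ".fasta")))
  }
  writeFasta(sim@references, file.path(out_dir, "references.fasta"))
  utils::write.table(sim@refTaxa, file.path(out_dir, "ref_taxa.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim@truthReads, file.path(out_dir, "truth_reads.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim@truthDomains,
                     file.path(out_dir, "truth_domains.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}

setMethod("show", "HolobiontSim", function(object) {
  cat("HolobiontSim:", length(object@reads), "reads,",
      length(object@references), "references,",
      nrow(object@truthDomains), "planted domain(s)\n")
  invisible(object)
})
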