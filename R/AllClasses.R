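#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib HolobiontEST, .registration = TRUE
NULL

#' Sample-tagged unigene set
#'
#' Container for assembled unigenes (contigs + singletons of an EST
#' assembly), pairing a \linkS4class{DNAStringSet} with a per-sequence sample
#' label. Identifiers are the names of the underlying string set and must be
#' unique.
#'
#' @slot sequences A \code{\link[Biostrings]{DNAStringSet}} of unigenes.
#' @slot sample Character vector, one sample label per unigene.
#' @aliases UnigeneSet
#' @exportClass UnigeneSet
setClass("UnigeneSet",
  representation(sequences = "DNAStringSet", sample = "character"))

setValidity("UnigeneSet", function(object) {
  n <- length(object@sequences)
  ids <- names(object@sequences)
  if (length(object@sample) != n)
    return("'sample' must have one entry per sequence")
  if (n == 0L) return(TRUE)
  if (is.null(ids) || any(is.na(ids)) || any(!nzchar(ids)))
    return("all unigenes must have non-empty identifiers")
  if (anyDuplicated(ids))
    return(paste0("duplicate unigene identifier(s): ",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  if (n && any(Biostrings::width(object@sequences) < 1L))
    return("empty sequence record")
  TRUE
})

#' Construct a UnigeneSet
#'
#' @param sequences A \code{DNAStringSet} or named character vector.
#' @param sample Sample label(s), recycled to the number of sequences.
#' @return A \linkS4class{UnigeneSet}.
#' @examples
#' u <- UnigeneSet(c(u1 = "ACGT", u2 = "GGCC"), sample = "S1")
#' gcContent(u)
#' @export
UnigeneSet <- function(sequences, sample = NA_character_) {
  if (!methods::is(sequences, "DNAStringSet"))
    sequences <- Biostrings::DNAStringSet(sequences)
  new("UnigeneSet", sequences = sequences,
      sample = rep_len(as.character(sample), length(sequences)))
}

#' Taxonomy as a parent map
#'
#' A tree of taxon labels stored as a child-to-parent map; the root is its
#' own parent. Optionally carries a rank label per node.
#'
#' @slot parent Named character vector, node -> parent.
#' @slot rank Named character vector, node -> rank (possibly empty).
#' @aliases TaxonomyMap
#' @exportClass TaxonomyMap
setClass("TaxonomyMap",
  representation(parent = "character", rank = "character"))

setValidity("TaxonomyMap", function(object) {
  p <- object@parent
  if (is.null(names(p)) || any(!nzchar(names(p))))
    return("parent map must be named by node")
  if (anyDuplicated(names(p))) return("duplicate node labels")
  roots <- names(p)[p == names(p)]
  if (length(roots) != 1L) return("exactly one root (self-parent) required")
  missing <- setdiff(unique(p), names(p))
  if (length(missing))
    return(paste0("parent(s) not present as nodes: ",
                  paste(missing, collapse = ", ")))
  # every node must reach the root (also excludes cycles)
  for (node in names(p)) {
    seen <- character(0)
    cur <- node
    while (p[[cur]] != cur) {
      if (cur %in% seen) return(paste0("cycle involving node ", node))
      seen <- c(seen, cur)
      cur <- p[[cur]]
    }
  }
  TRUE
})

#' @param parent Named character vector mapping node -> parent (root maps to
#'   itself).
#' @param rank Optional named character vector of rank labels.
#' @rdname TaxonomyMap-class
#' @export
taxonomyMap <- function(parent, rank = character(0)) {
  new("TaxonomyMap", parent = parent, rank = rank)
}

#' Taxon-by-sample count table
#'
#' Count table in the layout of a taxonomic-distribution report: rows are
#' taxon labels (plus the reserved rows \code{"No hits"}, \code{"Not
#' assigned"} and \code{"Total"} where applicable), columns are
#' (sample, fraction) pairs with fraction one of \code{"rRNA"} or
#' \code{"mRNA"}.
#'
#' @slot counts Numeric matrix of unigene counts.
#' @slot sample Character vector: sample of each column.
#' @slot fraction Character vector: fraction of each column.
#' @aliases TaxonCountTable
#' @exportClass TaxonCountTable
setClass("TaxonCountTable",
  representation(counts = "matrix", sample = "character",
                 fraction = "character"))

setValidity("TaxonCountTable", function(object) {
  if (length(object@sample) != ncol(object@counts) ||
      length(object@fraction) != ncol(object@counts))
    return("one sample and fraction label required per column")
  if (is.null(rownames(object@counts)))
    return("counts must have taxon row names")
  if (!all(object@fraction %in% c("rRNA", "mRNA")))
    return("fraction labels must be 'rRNA' or 'mRNA'")
  TRUE
})

#' @param counts Numeric matrix with taxon row names.
#' @param sample Sample label per column.
#' @param fraction \code{"rRNA"}/\code{"mRNA"} per column.
#' @rdname TaxonCountTable-class
#' @export
taxonCountTable <- function(counts, sample, fraction) {
  colnames(counts) <- paste(sample, fraction, sep = ":")
  new("TaxonCountTable", counts = counts, sample = as.character(sample),
      fraction = as.character(fraction))
}

#' Cross-sample identity clusters
#'
#' Result of greedy identity clustering. Every input sequence belongs to
#' exactly one cluster; the representative is the longest member (ties broken
#' by identifier).
#'
#' @slot members List of character vectors of member ids, one per cluster.
#' @slot representatives Character vector of representative ids.
#' @slot sample Named character vector mapping member id -> sample label.
#' @slot params List of clustering parameters.
#' @aliases ClusterSet
#' @exportClass ClusterSet
setClass("ClusterSet",
  representation(members = "list", representatives = "character",
                 sample = "character", params = "list"))

setValidity("ClusterSet", function(object) {
  if (length(object@members) != length(object@representatives))
    return("one representative per cluster required")
  ids <- unlist(object@members, use.names = FALSE)
  if (anyDuplicated(ids)) return("a sequence may belong to only one cluster")
  ok <- mapply(function(r, m) r %in% m, object@representatives,
               object@members)
  if (length(ok) && !all(ok)) return("representatives must be members")
  TRUE
})

#' C-type lectin domain grammar
#'
#' Operational definition of a c-type lectin domain (CTLD): four conserved
#' cysteines with bounded spacings, a WIGL-like 4-mer between the first and
#' third cysteine, and a sugar-binding motif position between the second and
#' fourth cysteine.
#'
#' @slot nCys Number of conserved cysteines (4).
#' @slot cysGapBounds 3 x 2 matrix of (min, max) residues between
#'   consecutive conserved cysteines.
#' @slot wiglPattern List of 4 character vectors: allowed residues at each
#'   position of the WIGL-like motif.
#' @slot sugarClasses Named character vector mapping known sugar-binding
#'   motifs to their binding class.
#' @aliases CTLDGrammar
#' @exportClass CTLDGrammar
setClass("CTLDGrammar",
  representation(nCys = "integer", cysGapBounds = "matrix",
                 wiglPattern = "list", sugarClasses = "character"))

setValidity("CTLDGrammar", function(object) {
  if (object@nCys != 4L) return("grammar is defined for 4 conserved cysteines")
  b <- object@cysGapBounds
  if (!is.numeric(b) || nrow(b) != 3L || ncol(b) != 2L)
    return("cysGapBounds must be a 3 x 2 matrix")
  if (any(b <= 0) || any(b[, 1] > b[, 2]))
    return("gap bounds must be positive with min <= max")
  if (length(object@wiglPattern) != 4L)
    return("WIGL-like pattern must have 4 positions")
  TRUE
})

#' Per-sample simulation profile
#'
#' Describes one synthetic holobiont library: its read count, taxon mixture,
#' per-taxon GC targets, ribosomal fraction and planted c-type lectin domain
#' layout.
#'
#' @aliases SampleProfile
#' @exportClass SampleProfile
setClass("SampleProfile",
  representation(sample_id = "character", n_reads = "integer",
                 taxon_mix = "numeric", gc_by_taxon = "numeric",
                 rrna_fraction = "numeric", n_planted_ctld = "integer",
                 n_multidomain = "integer", n_redundant_copies = "integer",
                 n_negative_ctld = "integer", wigl_variants = "character",
                 sugar_motifs = "character"))

setValidity("SampleProfile", function(object) {
  if (length(object@sample_id) != 1L || !nzchar(object@sample_id))
    return("sample_id must be a single non-empty label")
  mix <- object@taxon_mix
  if (length(mix) && abs(sum(mix) - 1) > 1e-9)
    return("taxon_mix fractions must sum to 1")
  if (any(mix < 0 | mix > 1)) return("taxon_mix fractions must lie in [0,1]")
  gc <- object@gc_by_taxon
  if (!all(names(mix) %in% names(gc)))
    return("gc_by_taxon must cover every taxon in taxon_mix")
  if (any(gc < 0 | gc > 1)) return("gc_by_taxon values must lie in [0,1]")
  if (object@rrna_fraction < 0 || object@rrna_fraction > 1)
    return("rrna_fraction must lie in [0,1]")
  if (object@n_multidomain > object@n_planted_ctld)
    return("n_multidomain must not exceed n_planted_ctld")
  if (object@n_multidomain > 0 &&
      object@n_redundant_copies < object@n_multidomain)
    return("each multidomain transcript consumes one redundant copy")
  if (object@n_redundant_copies > 0 && object@n_planted_ctld == 0)
    return("redundant copies require planted CTLD transcripts")
  TRUE
})

#' Simulation configuration
#'
#' Dataset-level parameters of the synthetic holobiont EST generator; see
#' \code{\link{simulationConfig}}.
#'
#' @aliases SimulationConfig
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(profiles = "list", seed = "integer",
                 read_length_mean = "numeric", read_length_sd = "numeric",
                 read_length_min = "numeric", read_length_max = "numeric",
                 polyA_len_range = "numeric", mutation_rate = "numeric",
                 n_shared_genes = "integer", genes_per_taxon = "integer",
                 gene_length = "integer"))

setValidity("SimulationConfig", function(object) {
  if (!length(object@profiles)) return("at least one sample profile required")
  if (!all(vapply(object@profiles, methods::is, TRUE, "SampleProfile")))
    return("profiles must be SampleProfile objects")
  ids <- vapply(object@profiles, function(p) p@sample_id, "")
  if (anyDuplicated(ids)) return("duplicate sample_id")
  if (object@read_length_min >= object@read_length_mean)
    return("read_length_min must be below read_length_mean")
  if (object@mutation_rate < 0 || object@mutation_rate > 0.3)
    return("mutation_rate must lie in [0, 0.3]")
  if (length(object@polyA_len_range) != 2L ||
      object@polyA_len_range[1] > object@polyA_len_range[2])
    return("polyA_len_range must be an increasing length-2 interval")
  TRUE
})

#' Synthetic holobiont dataset
#'
#' Output bundle of \code{\link{simulateHolobiont}}: the reads with their
#' sample tags, the reference sequence sets the generator drew from, the
#' subject-to-taxon sidecar, and per-read / per-planted-domain truth tables.
#'
#' @aliases HolobiontSim
#' @exportClass HolobiontSim
setClass("HolobiontSim",
  representation(reads = "UnigeneSet", references = "DNAStringSet",
                 proteinRefs = "AAStringSet", refTaxa = "data.frame",
                 truthReads = "data.frame", truthDomains = "data.frame",
                 config = "SimulationConfig"))

#' rRNA/mRNA partition result
#'
#' @slot labels data.frame with columns \code{id}, \code{sample},
#'   \code{label} (\code{"rRNA"}/\code{"mRNA"}) and \code{trigger_subject}
#'   (the subject of the qualifying hit, \code{NA} for mRNA).
#' @slot counts Sample-by-label count matrix.
#' @aliases PartitionResult
#' @exportClass PartitionResult
setClass("PartitionResult",
  representation(labels = "data.frame", counts = "matrix"))

setValidity("PartitionResult", function(object) {
  lab <- object@labels
  need <- c("id", "sample", "label", "trigger_subject")
  if (!all(need %in% names(lab)))
    return(paste("labels must carry columns:", paste(need, collapse = ", ")))
  if (!all(lab$label %in% c("rRNA", "mRNA")))
    return("labels must be 'rRNA' or 'mRNA'")
  if (any(lab$label == "rRNA" & is.na(lab$trigger_subject)))
    return("every rRNA label requires a triggering hit")
  TRUE
})
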