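#' Path from a node to the root
#'
#' @param taxonomy A \linkS4class{TaxonomyMap}.
#' @param node Node label.
#' @return Character vector from \code{node} up to the root (inclusive).
#' @export
taxonPath <- function(taxonomy, node) {
  p <- taxonomy@parent
  if (!node %in% names(p)) stop("taxon not in taxonomy: ", node)
  path <- node
  while (p[[node]] != node) {
    node <- p[[node]]
    path <- c(path, node)
  }
  path
}

#' Lowest common ancestor of a set of taxa
#'
#' @param taxonomy A \linkS4class{TaxonomyMap}.
#' @param taxa Character vector of node labels.
#' @return The deepest node ancestral to (or equal to) every input taxon.
#' @export
lcaOf <- function(taxonomy, taxa) {
  taxa <- unique(taxa)
  if (!length(taxa)) stop("no taxa given")
  paths <- lapply(taxa, function(t) rev(taxonPath(taxonomy, t)))
  common <- paths[[1]]
  for (p in paths[-1]) {
    k <- min(length(common), length(p))
    eq <- common[seq_len(k)] == p[seq_len(k)]
    common <- common[seq_len(if (all(eq)) k else which(!eq)[1] - 1L)]
  }
  common[length(common)]
}

#' LCA taxonomic assignment of one unigene
#'
#' Implements MEGAN-style binning: among the hits scoring at least
#' \code{min_score}, those within \code{top_percent} percent of the best
#' bitscore vote, and the unigene is assigned to the lowest common ancestor
#' of their subject taxa. No hits at all gives \code{"No hits"}; hits all
#' below \code{min_score} give \code{"Not assigned"}.
#'
#' @param hits Hit data.frame for a single query (column
#'   \code{subject_taxon} must be filled for qualifying hits).
#' @param taxonomy A \linkS4class{TaxonomyMap}.
#' @param top_percent Bitscore window below the best hit, in percent.
#' @param min_score Minimum bitscore for a hit to count.
#' @return A single taxon label (or \code{"No hits"}/\code{"Not assigned"}).
#' @export
lcaAssign <- function(hits, taxonomy, top_percent = 10, min_score = 50) {
  if (!nrow(hits)) return("No hits")
  ok <- hits$bitscore >= min_score
  if (!any(ok)) return("Not assigned")
  h <- hits[ok, , drop = FALSE]
  best <- max(h$bitscore)
  h <- h[h$bitscore >= best * (1 - top_percent / 100), , drop = FALSE]
  taxa <- unique(h$subject_taxon)
  missing <- setdiff(taxa, names(taxonomy@parent))
  if (length(missing))
    stop("subject taxon missing from taxonomy: ",
         paste(missing, collapse = ", "))
  lcaOf(taxonomy, taxa)
}

#' LCA assignment for many unigenes
#'
#' @param hits Hit data.frame covering any number of queries.
#' @param ids Unigene ids to assign (ids absent from \code{hits} get
#'   \code{"No hits"}).
#' @inheritParams lcaAssign
#' @return Named character vector id -> taxon label.
#' @export
lcaAssignAll <- function(hits, ids, taxonomy, top_percent = 10,
                         min_score = 50) {
  byq <- split(seq_len(nrow(hits)), hits$query_id)
  vapply(ids, function(id) {
    rows <- byq[[id]]
    if (is.null(rows)) "No hits"
    else lcaAssign(hits[rows, , drop = FALSE], taxonomy, top_percent,
                   min_score)
  }, "")
}

.RESERVED_ROWS <- c("Unidentified", "No hits", "Not assigned", "Total")

#' Build a taxon-by-(sample, fraction) count table
#'
#' Tabulates LCA assignments into the layout of a taxonomic-distribution
#' report: one row per observed taxon plus the reserved rows
#' \code{"No hits"}, \code{"Not assigned"} and \code{"Total"}. The total row
#' counts all unigenes of that column.
#'
#' @param assignments data.frame with columns \code{id}, \code{sample},
#'   \code{fraction} (\code{"rRNA"}/\code{"mRNA"}) and \code{taxon}.
#' @return A \linkS4class{TaxonCountTable}.
#' @export
buildTaxonCountTable <- function(assignments) {
  stopifnot(all(c("id", "sample", "fraction", "taxon") %in%
                names(assignments)))
  cols <- unique(assignments[, c("sample", "fraction")])
  cols <- cols[order(cols$sample, cols$fraction), , drop = FALSE]
  taxa <- sort(setdiff(unique(assignments$taxon), .RESERVED_ROWS))
  rows <- c(taxa, "No hits", "Not assigned", "Total")
  counts <- matrix(0, length(rows), nrow(cols),
                   dimnames = list(rows, NULL))
  for (k in seq_len(nrow(cols))) {
    sel <- assignments$sample == cols$sample[k] &
      assignments$fraction == cols$fraction[k]
    tab <- table(assignments$taxon[sel])
    counts[names(tab), k] <- as.numeric(tab)
    counts["Total", k] <- sum(sel)
  }
  taxonCountTable(counts, cols$sample, cols$fraction)
}

.tctColumn <- function(x, sample, fraction) {
  k <- which(x@sample == sample & x@fraction == fraction)
  if (length(k) != 1L)
    stop("no unique column for sample '", sample, "', fraction '",
         fraction, "'")
  k
}

#' Group count with optional subtree roll-up
#'
#' @param x A \linkS4class{TaxonCountTable}.
#' @param group Row label or taxon.
#' @param sample,fraction Column selector.
#' @param taxonomy Optional \linkS4class{TaxonomyMap}; when given and
#'   \code{group} is a taxon, counts of all rows inside the group's subtree
#'   are summed.
#' @return A single count.
#' @export
groupCount <- function(x, group, sample, fraction, taxonomy = NULL) {
  k <- .tctColumn(x, sample, fraction)
  if (group %in% rownames(x@counts) && is.null(taxonomy))
    return(x@counts[group, k])
  if (!is.null(taxonomy)) {
    rows <- rownames(x@counts)
    inside <- vapply(rows, function(r) {
      r %in% names(taxonomy@parent) && group %in% taxonPath(taxonomy, r)
    }, TRUE)
    if (any(inside)) return(sum(x@counts[inside, k]))
  }
  stop("group not present in table: ", group)
}

#' @describeIn percentOfTotal Percentage of the column total contributed by
#'   a group row, with the presentation rounding used in taxonomic reports:
#'   values of at least 1 percent are rounded to the nearest integer,
#'   smaller values to one decimal (\code{formatted = TRUE}); raw floats
#'   with \code{formatted = FALSE}.
#' @param formatted Apply the presentation rounding rule (default).
#' @param taxonomy Optional taxonomy for subtree roll-up of \code{group}.
#' @export
setMethod("percentOfTotal", "TaxonCountTable",
  function(x, group, sample, fraction, formatted = TRUE, taxonomy = NULL) {
    k <- .tctColumn(x, sample, fraction)
    total <- x@counts["Total", k]
    if (!isTRUE(total > 0)) stop("zero or missing total for column")
    val <- 100 * groupCount(x, group, sample, fraction, taxonomy) / total
    if (!formatted) return(val)
    if (val >= 1) .roundHalfUp(val, 0) else .roundHalfUp(val, 1)
  })

setMethod("show", "TaxonCountTable", function(object) {
  cat("TaxonCountTable:", nrow(object@counts), "rows x",
      ncol(object@counts), "columns\n")
  print(utils::head(object@counts, 12))
  if (nrow(object@counts) > 12) cat("  ...\n")
  invisible(object)
})

#' Write a taxon count table as TSV
#'
#' @param x A \code{TaxonCountTable}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeTaxonCountTable <- function(x, path) {
  hdr <- paste(c("taxon", paste(x@sample, x@fraction, sep = ":")),
               collapse = "\t")
  body <- apply(cbind(rownames(x@counts), x@counts), 1, paste,
                collapse = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a taxon count table written by \code{writeTaxonCountTable} (or
#' transcribed from a publication-style table)
#'
#' @param path TSV path; header \code{taxon<TAB>sample:fraction...}.
#' @return A \code{TaxonCountTable}.
#' @export
readTaxonCountTable <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           quote = "", comment.char = "#")
  counts <- as.matrix(tab[, -1, drop = FALSE])
  rownames(counts) <- tab[[1]]
  parts <- strsplit(colnames(counts), ":", fixed = TRUE)
  taxonCountTable(counts, vapply(parts, `[`, "", 1),
                  vapply(parts, `[`, "", 2))
}
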