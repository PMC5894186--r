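#' Read gene models from GFF3
#'
#' Parses `gene` and `CDS` features linked by `ID`/`Parent`. CDS intervals
#' are merged per gene (sorted, overlap-collapsed) and must fall inside the
#' gene span. All coordinates are kept in R's native 1-based closed
#' convention (`GRanges`); the GFF3 file already uses that convention, so no
#' shift is applied on input.
#'
#' @param path Path to a GFF3 file.
#' @return A `gene_models` object: list with elements
#'   * `genes`: `GRanges` of gene spans, names = gene ids;
#'   * `cds`: `GRangesList` of merged CDS intervals, one element per gene;
#'   * `go`: named list of GO-term character vectors (empty here; attach
#'     with [attach_go_terms()]).
#' @export
read_gene_models <- function(path) {
  gff <- rtracklayer::import(path, format = "gff3")
  if (any(BiocGenerics::start(gff) > BiocGenerics::end(gff)))
    stop("GFF3 feature with end < start")
  types <- as.character(gff$type)
  genes <- gff[types == "gene"]
  cds <- gff[types == "CDS"]
  gene_ids <- as.character(genes$ID)
  if (anyDuplicated(gene_ids)) stop("duplicate gene ID in GFF3")
  names(genes) <- gene_ids
  parent <- as.character(S4Vectors::unstrsplit(cds$Parent, ","))
  orphan <- !(parent %in% gene_ids)
  if (any(orphan)) {
    warning(sum(orphan), " CDS feature(s) without a parent gene skipped")
    cds <- cds[!orphan]
    parent <- parent[!orphan]
  }
  cds_by_gene <- S4Vectors::split(GenomicRanges::granges(cds),
                                  factor(parent, levels = gene_ids))
  cds_by_gene <- GenomicRanges::reduce(cds_by_gene)
  new_gene_models(GenomicRanges::granges(genes), cds_by_gene)
}

new_gene_models <- function(genes, cds, go = NULL) {
  if (is.null(go))
    go <- stats::setNames(vector("list", length(genes)), names(genes))
  structure(list(genes = genes, cds = cds, go = go),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", length(x$genes), "genes,",
      sum(lengths(x$cds)), "CDS intervals,",
      sum(lengths(x$go) > 0), "genes with GO terms\n")
  invisible(x)
}

#' Attach GO terms to gene models
#'
#' @param models A `gene_models` object.
#' @param go_map Named list from [read_go_map()].
#' @return The models with the `go` slot filled; genes absent from the map
#'   keep an empty term set.
#' @export
attach_go_terms <- function(models, go_map) {
  ids <- names(models$genes)
  models$go <- stats::setNames(
    lapply(ids, function(g) unique(go_map[[g]])), ids)
  models
}

#' Write gene models to GFF3
#'
#' Emits one `gene` line per gene and one `CDS` line per merged CDS
#' interval, linked by `ID`/`Parent`.
#'
#' @param models A `gene_models` object.
#' @param path Output path.
#' @export
write_gene_models <- function(models, path) {
  g <- models$genes
  gene_lines <- sprintf("%s\tgadarch\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                        as.character(GenomicRanges::seqnames(g)),
                        BiocGenerics::start(g), BiocGenerics::end(g),
                        as.character(BiocGenerics::strand(g)),
                        names(g))
  cds_flat <- unlist(models$cds)
  cds_lines <- character(0)
  if (length(cds_flat) > 0) {
    parent <- rep(names(models$cds), lengths(models$cds))
    cds_lines <- sprintf(
      "%s\tgadarch\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds;Parent=%s",
      as.character(GenomicRanges::seqnames(cds_flat)),
      BiocGenerics::start(cds_flat), BiocGenerics::end(cds_flat),
      as.character(BiocGenerics::strand(cds_flat)),
      parent, parent)
  }
  writeLines(c("##gff-version 3", gene_lines, cds_lines), path)
  invisible(path)
}

#' Write STR loci to GFF3
#'
#' One `tandem_repeat` feature per locus with `unit_size`, `motif` and
#' `copies` attributes.
#'
#' @param loci `GRanges` from [find_strs()].
#' @param path Output path.
#' @export
write_str_gff <- function(loci, path) {
  lines <- sprintf(
    "%s\tgadarch\ttandem_repeat\t%d\t%d\t.\t+\t.\tunit_size=%d;motif=%s;copies=%.3f",
    as.character(GenomicRanges::seqnames(loci)),
    BiocGenerics::start(loci), BiocGenerics::end(loci),
    loci$unit_size, loci$motif, loci$copy_number)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}
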