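# Gene-model containers
#
# A `Transcript` is a list(transcript_id, gene_id, chrom, strand, exons, cds)
# where exons/cds are integer matrices with columns start, end (1-based,
# inclusive, sorted by genomic start, non-overlapping). An `annotation` is a
# list with one element per gene: list(gene_id, chrom, strand, transcripts).
# Plain lists keep the coordinate arithmetic transparent; heavier containers
# buy nothing at the scale fusion-call tables have.

#' Construct a transcript gene model
#'
#' @param transcript_id,gene_id identifiers.
#' @param chrom chromosome name.
#' @param strand "+" or "-".
#' @param exons two-column matrix (start, end) of 1-based inclusive exon
#'   intervals; rows may be unsorted, they are sorted by genomic start.
#' @param cds like `exons`, possibly zero-row; must lie within the exon union.
#' @return a `Transcript` list.
#' @export
transcript <- function(transcript_id, gene_id, chrom, strand, exons,
                       cds = matrix(integer(0), ncol = 2)) {
  exons <- as_interval_matrix(exons, sprintf("exons of %s", transcript_id))
  cds <- as_interval_matrix(cds, sprintf("CDS of %s", transcript_id),
                            allow_empty = TRUE)
  fs_assert(strand %in% c("+", "-"),
            sprintf("transcript %s: strand must be + or -", transcript_id))
  if (nrow(cds) > 0) {
    within <- vapply(seq_len(nrow(cds)), function(i) {
      any(cds[i, 1] >= exons[, 1] & cds[i, 2] <= exons[, 2])
    }, logical(1))
    fs_assert(all(within),
              sprintf("transcript %s: CDS extends outside exons",
                      transcript_id))
  }
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 chrom = chrom, strand = strand, exons = exons, cds = cds),
            class = "Transcript")
}

as_interval_matrix <- function(m, what, allow_empty = FALSE) {
  m <- matrix(as.integer(as.matrix(m)), ncol = 2)
  colnames(m) <- c("start", "end")
  if (nrow(m) == 0) {
    fs_assert(allow_empty, sprintf("%s: empty interval set", what))
    return(m)
  }
  fs_assert(all(m[, 1] <= m[, 2]), sprintf("%s: start > end", what))
  fs_assert(all(m[, 1] >= 1L), sprintf("%s: coordinates must be >= 1", what))
  m <- m[order(m[, 1]), , drop = FALSE]
  if (nrow(m) > 1) {
    fs_assert(all(m[-1, 1] > m[-nrow(m), 2]),
              sprintf("%s: overlapping intervals", what))
  }
  m
}

#' Assemble an annotation from transcripts
#'
#' @param transcripts list of [transcript()] objects.
#' @param genome optional genome (named character vector); when given, all
#'   coordinates are checked against chromosome lengths.
#' @return an `annotation` object: a named list of genes.
#' @export
annotation <- function(transcripts, genome = NULL) {
  genes <- list()
  for (tx in transcripts) {
    g <- genes[[tx$gene_id]]
    if (is.null(g)) {
      genes[[tx$gene_id]] <- list(gene_id = tx$gene_id, chrom = tx$chrom,
                                  strand = tx$strand, transcripts = list(tx))
    } else {
      fs_assert(g$chrom == tx$chrom && g$strand == tx$strand,
                sprintf("gene %s: transcripts disagree on chrom/strand",
                        tx$gene_id))
      genes[[tx$gene_id]]$transcripts <- c(g$transcripts, list(tx))
    }
  }
  if (!is.null(genome)) {
    for (g in genes) {
      len <- chrom_len(genome, g$chrom)
      for (tx in g$transcripts) {
        fs_assert(all(tx$exons[, 2] <= len),
                  sprintf("transcript %s: coordinates exceed chromosome %s",
                          tx$transcript_id, g$chrom))
      }
    }
  }
  structure(genes, class = "annotation")
}

ann_gene <- function(ann, gene_id) {
  g <- ann[[gene_id]]
  if (is.null(g)) fs_error(sprintf("unknown gene id '%s'", gene_id))
  g
}

# Total CDS length of a transcript in bp.
cds_length <- function(tx) {
  if (nrow(tx$cds) == 0) 0L else sum(tx$cds[, 2] - tx$cds[, 1] + 1L)
}

#' @export
print.annotation <- function(x, ...) {
  ntx <- sum(vapply(x, function(g) length(g$transcripts), integer(1)))
  cat(sprintf("annotation: %d genes, %d transcripts on %d chromosome(s)\n",
              length(x), ntx,
              length(unique(vapply(x, `[[`, "", "chrom")))))
  invisible(x)
}
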