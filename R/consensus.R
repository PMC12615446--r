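# Cross-tool / cross-sample consolidation: unique fusions, parental gene
# pairs, partner statistics and the coding-potential consensus vote.

#' Deduplicate fusion calls into unique fusions
#'
#' Two calls merge when they share the ordered gene pair, chromosomes and
#' strands, and both breakpoints agree within `bp_tolerance` (transitive
#' closure within a group). The merged record keeps the breakpoints of the
#' member call with most junction reads (ties broken by the
#' lexicographically smallest (bp5, bp3)) and unions tools and samples.
#'
#' @param calls fusion-call data.frame (unified columns).
#' @param bp_tolerance maximum breakpoint distance for merging (default 0,
#'   i.e. exact breakpoints).
#' @return data.frame of unique fusions: call columns plus `fusion_id`,
#'   `tools`, `samples` (comma-joined sorted sets) and `n_calls`.
#' @export
deduplicate_calls <- function(calls, bp_tolerance = 0L) {
  fs_assert(bp_tolerance >= 0, "bp_tolerance must be >= 0")
  if (nrow(calls) == 0) return(calls)
  gkey <- paste(calls$gene5, calls$gene3, calls$chrom5, calls$chrom3,
                calls$strand5, calls$strand3, sep = "\r")
  cluster <- integer(nrow(calls))
  next_id <- 0L
  for (k in unique(gkey)) {
    idx <- which(gkey == k)
    # union-find over breakpoint proximity within the gene-pair group
    parent <- seq_along(idx)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (a in seq_along(idx)) {
      for (b in seq_len(a - 1L)) {
        if (abs(calls$bp5[idx[a]] - calls$bp5[idx[b]]) <= bp_tolerance &&
            abs(calls$bp3[idx[a]] - calls$bp3[idx[b]]) <= bp_tolerance) {
          ra <- find(a); rb <- find(b)
          if (ra != rb) parent[ra] <- rb
        }
      }
    }
    roots <- vapply(seq_along(idx), find, integer(1))
    for (r in unique(roots)) {
      next_id <- next_id + 1L
      cluster[idx[roots == r]] <- next_id
    }
  }
  merged <- lapply(split(seq_len(nrow(calls)), cluster), function(members) {
    sub <- calls[members, , drop = FALSE]
    best <- order(-sub$junction_reads, sub$bp5, sub$bp3)[1]
    rec <- sub[best, c("gene5", "gene3", "chrom5", "bp5", "strand5",
                       "chrom3", "bp3", "strand3"), drop = FALSE]
    rec$junction_reads <- max(sub$junction_reads)
    rec$tools <- paste(sort(unique(sub$tool)), collapse = ",")
    rec$samples <- paste(sort(unique(sub$sample_id)), collapse = ",")
    rec$n_calls <- nrow(sub)
    rec
  })
  out <- do.call(rbind, merged)
  out <- out[order(out$gene5, out$gene3, out$bp5, out$bp3), , drop = FALSE]
  out$fusion_id <- paste0(pair_key(out$gene5, out$gene3), "@",
                          out$bp5, ":", out$bp3)
  rownames(out) <- NULL
  out
}

#' Aggregate unique fusions into parental gene pairs
#'
#' @param unique_fusions data.frame from [deduplicate_calls()].
#' @return list with:
#'   \item{pairs}{data.frame gene5, gene3, n_isoforms (distinct breakpoint
#'     pairs), breakpoints (semicolon list of bp5:bp3), tools, samples.}
#'   \item{partner_degree}{named integer vector: distinct partner genes per
#'     gene, counted over both sides.}
#'   \item{n_fusion_genes}{number of distinct genes involved in any fusion.}
#' @export
aggregate_pairs <- function(unique_fusions) {
  uf <- unique_fusions
  key <- pair_key(uf$gene5, uf$gene3)
  pairs <- lapply(split(seq_len(nrow(uf)), key), function(members) {
    sub <- uf[members, , drop = FALSE]
    bps <- unique(paste0(sub$bp5, ":", sub$bp3))
    data.frame(
      gene5 = sub$gene5[1], gene3 = sub$gene3[1],
      n_isoforms = length(bps),
      breakpoints = paste(sort(bps), collapse = ";"),
      tools = paste(sort(unique(unlist(strsplit(sub$tools, ",")))),
                    collapse = ","),
      samples = paste(sort(unique(unlist(strsplit(sub$samples, ",")))),
                      collapse = ","),
      stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, pairs)
  pairs <- pairs[order(pairs$gene5, pairs$gene3), , drop = FALSE]
  rownames(pairs) <- NULL
  upairs <- unique(pairs[, c("gene5", "gene3")])
  genes <- unique(c(upairs$gene5, upairs$gene3))
  degree <- vapply(genes, function(g) {
    length(unique(c(upairs$gene3[upairs$gene5 == g],
                    upairs$gene5[upairs$gene3 == g])))
  }, integer(1))
  list(pairs = pairs, partner_degree = degree,
       n_fusion_genes = length(genes))
}

#' Fraction of annotated genes involved in fusions
#'
#' @param n_fusion_genes genes participating in at least one fusion.
#' @param n_annotated_genes total annotated genes (> 0).
#' @return percentage rounded half-up to one decimal.
#' @export
gene_fraction <- function(n_fusion_genes, n_annotated_genes) {
  fs_assert(n_annotated_genes > 0, "n_annotated_genes must be > 0")
  round_half_up(100 * n_fusion_genes / n_annotated_genes, 1L)
}

#' Coding-potential consensus vote
#'
#' Consensus is "coding" with at least two coding votes, "noncoding" with at
#' least two noncoding votes, and "undetermined" otherwise (e.g. a 1-1 split
#' with one predictor missing).
#'
#' @param vote_table data.frame with columns fusion_id, tool, label; labels
#'   must be "coding" or "noncoding"; at most 3 votes per fusion.
#' @return data.frame fusion_id, n_coding, n_noncoding, consensus.
#' @export
coding_vote <- function(vote_table) {
  bad <- setdiff(unique(vote_table$label), c("coding", "noncoding"))
  fs_assert(length(bad) == 0,
            sprintf("unknown coding label(s): %s", paste(bad, collapse = ", ")))
  res <- lapply(split(vote_table, vote_table$fusion_id), function(sub) {
    fs_assert(nrow(sub) <= 3,
              sprintf("fusion %s has more than 3 votes", sub$fusion_id[1]))
    nc <- sum(sub$label == "coding")
    nn <- sum(sub$label == "noncoding")
    data.frame(fusion_id = sub$fusion_id[1], n_coding = nc, n_noncoding = nn,
               consensus = if (nc >= 2) "coding"
                           else if (nn >= 2) "noncoding"
                           else "undetermined",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
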