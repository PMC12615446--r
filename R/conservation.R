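# Presence/absence conservation of fusion gene pairs across genotypes, with
# hierarchical clustering of genotypes on their binary fusion profiles, and
# ortholog-mediated cross-species conservation.

#' Build a binary presence/absence matrix of fusion pairs across genotypes
#'
#' A cell is 1 when the ordered reference pair occurs in that genotype's
#' pair set (detection in even a single sample of the genotype counts).
#' Duplicate entries within a genotype set are ignored.
#'
#' @param reference_pairs data.frame with columns gene5, gene3 (the
#'   reference pair universe; row order is preserved).
#' @param per_genotype_pair_sets named list: genotype -> character vector of
#'   ordered pair keys ("gene5_gene3", as from [read_genotype_pairs()]) or a
#'   data.frame with gene5/gene3 columns.
#' @return binary integer matrix, pairs in rows, genotypes in columns.
#' @export
build_presence_matrix <- function(reference_pairs, per_genotype_pair_sets) {
  fs_assert(!is.null(names(per_genotype_pair_sets)) &&
              !anyDuplicated(names(per_genotype_pair_sets)),
            "genotype names must be present and unique")
  keys <- pair_key(reference_pairs$gene5, reference_pairs$gene3)
  cells <- vapply(per_genotype_pair_sets, function(s) {
    if (is.data.frame(s)) s <- pair_key(s$gene5, s$gene3)
    as.integer(keys %in% unique(s))
  }, integer(length(keys)))
  cells <- matrix(cells, nrow = length(keys),
                  dimnames = list(keys, names(per_genotype_pair_sets)))
  cells
}

#' Count fusion pairs conserved across genotypes
#'
#' A pair is "conserved across multiple genotypes" when present in at least
#' 2 genotypes (including the reference genotype when its column is in the
#' matrix); `min_genotypes` gives a second, stricter tally.
#'
#' @param matrix binary presence matrix from [build_presence_matrix()].
#' @param min_genotypes threshold for the stricter tally (default 10).
#' @return list(n_conserved_ge2, n_conserved_ge_min, conserved_pairs =
#'   data.frame pair, n_genotypes for rows with >= 2 genotypes).
#' @export
conserved_pairs <- function(matrix, min_genotypes = 10L) {
  fs_assert(min_genotypes >= 1, "min_genotypes must be >= 1")
  rs <- rowSums(matrix)
  keep <- rs >= 2
  list(n_conserved_ge2 = sum(rs >= 2),
       n_conserved_ge_min = sum(rs >= min_genotypes),
       conserved_pairs = data.frame(pair = rownames(matrix)[keep],
                                    n_genotypes = unname(rs[keep]),
                                    stringsAsFactors = FALSE))
}

# Pairwise Jaccard distance between binary profile columns:
# d(A, B) = 1 - |A & B| / |A | B|; two empty profiles have distance 0.
jaccard_dist <- function(m) {
  inter <- crossprod(m)
  ones <- matrix(colSums(m), ncol(m), ncol(m))
  union <- ones + t(ones) - inter
  d <- 1 - inter / union
  d[union == 0] <- 0
  stats::as.dist(d)
}

#' Hierarchically cluster genotypes on their fusion profiles
#'
#' Agglomerative clustering of genotype columns using Jaccard distance and
#' average (UPGMA) linkage. Deterministic for a given column order.
#'
#' @param matrix binary presence matrix (pairs x genotypes).
#' @param method linkage passed to [stats::hclust()] (default "average").
#' @return an `hclust` object; convert with [ape::as.phylo()] or export with
#'   [write_genotype_tree()].
#' @export
cluster_genotypes <- function(matrix, method = "average") {
  fs_assert(ncol(matrix) >= 2, "clustering needs >= 2 genotypes")
  stats::hclust(jaccard_dist(matrix), method = method)
}

#' Write a genotype clustering as Newick
#' @param hc `hclust` from [cluster_genotypes()].
#' @param path output file.
#' @export
write_genotype_tree <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Map fusion pairs across species through an ortholog table
#'
#' A native pair (g5, g3) is conserved when some foreign fusion pair
#' (h5, h3) satisfies: h5 is orthologous to g5 AND h3 is orthologous to g3,
#' direction preserved. Many-to-many ortholog relations are allowed.
#'
#' @param pairs data.frame of native pairs (gene5, gene3).
#' @param ortholog_table data.frame gene_a (native), gene_b (foreign).
#' @param foreign_fusion_pairs data.frame of foreign pairs (gene5, gene3).
#' @return `pairs` with an added logical column `conserved` and a column
#'   `foreign_matches` (semicolon list of matching foreign pair keys).
#' @export
map_orthologous_fusions <- function(pairs, ortholog_table,
                                    foreign_fusion_pairs) {
  orth <- split(ortholog_table$gene_b, ortholog_table$gene_a)
  fkeys <- pair_key(foreign_fusion_pairs$gene5, foreign_fusion_pairs$gene3)
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    h5 <- orth[[pairs$gene5[i]]]
    h3 <- orth[[pairs$gene3[i]]]
    if (is.null(h5) || is.null(h3)) return(character(0))
    cand <- as.vector(outer(h5, h3, pair_key))
    intersect(cand, fkeys)
  })
  pairs$conserved <- lengths(res) > 0
  pairs$foreign_matches <- vapply(res, function(x) {
    paste(sort(unique(x)), collapse = ";")
  }, character(1))
  pairs
}
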