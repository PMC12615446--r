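# Expression-level analyses: parental-gene co-expression, fusion-present vs
# fusion-absent fold changes, and Livak 2^-ddCt relative quantification.

#' Co-expression of fusion parental genes
#'
#' Each fusion pair contributes one point: the mean-across-samples TPM of its
#' 5' and 3' parents, both transformed as log2(TPM + 1). Returns the Pearson
#' correlation over those points. Pairs whose genes are missing from the
#' matrix are dropped with a warning.
#'
#' @param expr_matrix numeric gene-by-sample TPM matrix.
#' @param pairs data.frame with columns gene5, gene3.
#' @return list(R = Pearson correlation, points = data.frame with one row
#'   per usable pair: gene5, gene3, log_tpm5, log_tpm3).
#' @export
parental_correlation <- function(expr_matrix, pairs) {
  present <- pairs$gene5 %in% rownames(expr_matrix) &
    pairs$gene3 %in% rownames(expr_matrix)
  if (any(!present)) {
    warning(sprintf("parental_correlation: dropping %d pair(s) missing from the matrix",
                    sum(!present)))
  }
  pairs <- pairs[present, , drop = FALSE]
  fs_assert(nrow(pairs) >= 3,
            "parental_correlation needs >= 3 pairs with both genes present")
  x <- log2(rowMeans(expr_matrix)[pairs$gene5] + 1)
  y <- log2(rowMeans(expr_matrix)[pairs$gene3] + 1)
  fs_assert(stats::sd(x) > 0 && stats::sd(y) > 0, "degenerate correlation")
  list(R = stats::cor(x, y),
       points = data.frame(gene5 = pairs$gene5, gene3 = pairs$gene3,
                           log_tpm5 = unname(x), log_tpm3 = unname(y),
                           stringsAsFactors = FALSE))
}

#' Fusion-present vs fusion-absent fold change of parental genes
#'
#' For each fusion, samples are split into a fusion-present (F/P) group and
#' a fusion-absent (F/A) group; each parental gene's fold change is
#' (mean TPM in F/P + 1) / (mean TPM in F/A + 1), the pseudocount guarding
#' against zero expression. Status is "up" at fold change >= `fc_threshold`,
#' "down" at <= 1/fc_threshold, else "unchanged". Fusions with an empty F/A
#' group are skipped with a warning.
#'
#' @param expr_matrix numeric gene-by-sample TPM matrix.
#' @param pairs data.frame with columns fusion_id, gene5, gene3.
#' @param fusion_presence named list: fusion_id -> character vector of F/P
#'   sample names (all other matrix columns form the F/A group).
#' @param fc_threshold fold-change threshold (default 2).
#' @return data.frame gene, fusion_id, mean_fp, mean_fa, fc, status.
#' @export
fp_fa_fold_change <- function(expr_matrix, pairs, fusion_presence,
                              fc_threshold = 2) {
  res <- list()
  for (i in seq_len(nrow(pairs))) {
    fid <- pairs$fusion_id[i]
    fp <- intersect(fusion_presence[[fid]], colnames(expr_matrix))
    fa <- setdiff(colnames(expr_matrix), fp)
    if (length(fp) == 0 || length(fa) == 0) {
      warning(sprintf("fusion %s: empty F/P or F/A group, skipped", fid))
      next
    }
    for (gene in c(pairs$gene5[i], pairs$gene3[i])) {
      fs_assert(gene %in% rownames(expr_matrix),
                sprintf("gene %s absent from expression matrix", gene))
      m_fp <- mean(expr_matrix[gene, fp])
      m_fa <- mean(expr_matrix[gene, fa])
      fc <- (m_fp + 1) / (m_fa + 1)
      res[[length(res) + 1L]] <- data.frame(
        gene = gene, fusion_id = fid, mean_fp = m_fp, mean_fa = m_fa,
        fc = fc,
        status = if (fc >= fc_threshold) "up"
                 else if (fc <= 1 / fc_threshold) "down"
                 else "unchanged",
        stringsAsFactors = FALSE)
    }
  }
  if (length(res) == 0) {
    return(data.frame(gene = character(0), fusion_id = character(0),
                      mean_fp = numeric(0), mean_fa = numeric(0),
                      fc = numeric(0), status = character(0)))
  }
  do.call(rbind, res)
}

#' Livak 2^-ddCt relative quantification
#'
#' Per replicate, dCt = Ct(target) - Ct(reference); ddCt is the difference
#' of group-mean dCt (treated minus control) and the relative quantity is
#' rq = 2^-ddCt. Per-replicate RQ values, 2^-(dCt - mean dCt of control),
#' give the reported mean +/- SD for the treated group, and the p-value
#' comes from a two-sided Welch t-test on the dCt values.
#'
#' @param ct_table data.frame with columns sample_id, group, gene, ct,
#'   replicate.
#' @param target,reference gene names (reference must have a Ct in every
#'   replicate).
#' @param control_label,treated_label values of the `group` column.
#' @return list: target_gene, reference_gene, dct_control, dct_treated,
#'   ddct, rq, rq_mean, rq_sd, p_value.
#' @export
ddct <- function(ct_table, target, reference,
                 control_label = "control", treated_label = "treated") {
  group_dct <- function(label) {
    sub <- ct_table[ct_table$group == label, , drop = FALSE]
    fs_assert(nrow(sub) > 0, sprintf("no Ct rows for group '%s'", label))
    reps <- unique(sub[, c("sample_id", "replicate")])
    vapply(seq_len(nrow(reps)), function(i) {
      rows <- sub[sub$sample_id == reps$sample_id[i] &
                    sub$replicate == reps$replicate[i], , drop = FALSE]
      ct_t <- rows$ct[rows$gene == target]
      ct_r <- rows$ct[rows$gene == reference]
      fs_assert(length(ct_r) == 1,
                sprintf("missing reference Ct for %s replicate %s in group %s",
                        reps$sample_id[i], reps$replicate[i], label))
      fs_assert(length(ct_t) == 1,
                sprintf("missing target Ct for %s replicate %s in group %s",
                        reps$sample_id[i], reps$replicate[i], label))
      ct_t - ct_r
    }, numeric(1))
  }
  dct_c <- group_dct(control_label)
  dct_t <- group_dct(treated_label)
  fs_assert(length(dct_c) >= 2 && length(dct_t) >= 2,
            "ddct needs >= 2 replicates per group")
  ddct_val <- mean(dct_t) - mean(dct_c)
  rq_reps <- 2^(-(dct_t - mean(dct_c)))
  p <- if (stats::sd(dct_c) == 0 && stats::sd(dct_t) == 0) {
    if (isTRUE(all.equal(mean(dct_c), mean(dct_t)))) 1 else 0
  } else {
    stats::t.test(dct_t, dct_c)$p.value
  }
  list(target_gene = target, reference_gene = reference,
       dct_control = dct_c, dct_treated = dct_t,
       ddct = ddct_val, rq = 2^(-ddct_val),
       rq_mean = mean(rq_reps), rq_sd = stats::sd(rq_reps),
       p_value = p)
}
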