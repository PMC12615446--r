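# Long-read validation of predicted fusions from BLAST tabular hits, and
# benchmarking of fusion callers against a truth set.

#' Filter long-read alignment hits supporting fusion junctions
#'
#' A hit supports its query junction when the percent identity exceeds
#' `min_identity` and the alignment length exceeds `min_len` (both strictly
#' by default, matching "greater than 80%" / "exceeding 150 bp"). A fusion
#' is validated when at least one hit supports it. When the tabular input
#' carries a subject-length column, the estimated transcript length is the
#' subject length of the best-bitscore supporting hit.
#'
#' @param hits data.frame from [read_blast_tab()]; query_id identifies the
#'   fusion junction.
#' @param min_identity identity threshold in percent (default 80).
#' @param min_len alignment-length threshold in bp (default 150).
#' @param strict logical; TRUE (default) uses strict inequalities.
#' @return data.frame fusion_id, n_supporting_hits, validated, est_length
#'   (NA when no supporting hit or no subject-length column).
#' @export
filter_longread_hits <- function(hits, min_identity = 80, min_len = 150,
                                 strict = TRUE) {
  cmp <- if (strict) `>` else `>=`
  has_slen <- "subject_len" %in% names(hits)
  res <- lapply(split(hits, hits$query_id), function(sub) {
    sup <- sub[cmp(sub$pct_identity, min_identity) &
                 cmp(sub$aln_len, min_len), , drop = FALSE]
    est <- NA_real_
    if (nrow(sup) > 0 && has_slen) {
      est <- sup$subject_len[which.max(sup$bitscore)]
    }
    data.frame(fusion_id = sub$query_id[1],
               n_supporting_hits = nrow(sup),
               validated = nrow(sup) >= 1,
               est_length = est,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Benchmark fusion callers against a truth set
#'
#' Predictions and truth are matched on the ordered gene-pair key, with an
#' optional breakpoint tolerance (then bp5/bp3 columns are required on both
#' sides and a prediction matches a truth entry when both breakpoints agree
#' within the tolerance). Per tool: TP = truth entries recovered, FP =
#' unique predictions matching no truth entry, TF = total true fusions,
#' sensitivity S = 100*TP/TF, precision P = 100*TP/(TP+FP) (0 when the tool
#' predicts nothing), and F = the harmonic mean of S/100 and P/100
#' (2SP/(S+P), the standard F1). Tools are ranked by F, then S.
#'
#' @param per_tool_predictions named list: tool -> data.frame with gene5,
#'   gene3 (and bp5, bp3 when `match_tolerance` > 0).
#' @param truth_pairs non-empty data.frame of true fusions (same columns).
#' @param match_tolerance breakpoint tolerance in bp (default 0 = gene-pair
#'   key only).
#' @return data.frame tool, TP, FP, TF, S, P, F, sorted best first.
#' @export
benchmark_metrics <- function(per_tool_predictions, truth_pairs,
                              match_tolerance = 0L) {
  fs_assert(!is.null(truth_pairs) && nrow(truth_pairs) > 0,
            "benchmark_metrics: empty truth set")
  use_bp <- match_tolerance > 0
  truth_keys <- unique(pair_key(truth_pairs$gene5, truth_pairs$gene3))
  matches_truth <- function(pred_row) {
    if (!use_bp) {
      return(pair_key(pred_row$gene5, pred_row$gene3) %in% truth_keys)
    }
    any(truth_pairs$gene5 == pred_row$gene5 &
          truth_pairs$gene3 == pred_row$gene3 &
          abs(truth_pairs$bp5 - pred_row$bp5) <= match_tolerance &
          abs(truth_pairs$bp3 - pred_row$bp3) <= match_tolerance)
  }
  truth_hit_by <- function(preds, truth_row) {
    if (!use_bp) {
      return(pair_key(truth_row$gene5, truth_row$gene3) %in%
               pair_key(preds$gene5, preds$gene3))
    }
    any(preds$gene5 == truth_row$gene5 & preds$gene3 == truth_row$gene3 &
          abs(preds$bp5 - truth_row$bp5) <= match_tolerance &
          abs(preds$bp3 - truth_row$bp3) <= match_tolerance)
  }
  TF <- if (use_bp) nrow(truth_pairs) else length(truth_keys)
  rows <- lapply(names(per_tool_predictions), function(tool) {
    preds <- per_tool_predictions[[tool]]
    if (!is.null(preds) && nrow(preds) > 0) {
      dedup_cols <- c("gene5", "gene3", if (use_bp) c("bp5", "bp3"))
      preds <- unique(preds[, dedup_cols, drop = FALSE])
    }
    if (is.null(preds) || nrow(preds) == 0) {
      TP <- 0L; FP <- 0L
    } else {
      TP <- sum(vapply(seq_len(if (use_bp) nrow(truth_pairs)
                               else length(truth_keys)), function(i) {
        if (use_bp) truth_hit_by(preds, truth_pairs[i, , drop = FALSE])
        else truth_keys[i] %in% pair_key(preds$gene5, preds$gene3)
      }, logical(1)))
      FP <- sum(!vapply(seq_len(nrow(preds)), function(i) {
        matches_truth(preds[i, , drop = FALSE])
      }, logical(1)))
    }
    S <- 100 * TP / TF
    P <- if (TP + FP > 0) 100 * TP / (TP + FP) else 0
    F1 <- if (S + P > 0) 2 * (S / 100) * (P / 100) / ((S + P) / 100) else 0
    data.frame(tool = tool, TP = TP, FP = FP, TF = TF,
               S = S, P = P, F = F1, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$F, -out$S, out$tool), , drop = FALSE]
  rownames(out) <- NULL
  out
}
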