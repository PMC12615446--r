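# Shared fixtures and independent oracles.

# One-row unified fusion call.
toy_call <- function(gene5 = "gA", gene3 = "gB", chrom5 = "c1", bp5 = 100L,
                     strand5 = "+", chrom3 = "c2", bp3 = 500L,
                     strand3 = "+", sample_id = "s1", tool = "toolA",
                     junction_reads = 7L) {
  data.frame(sample_id = sample_id, tool = tool, gene5 = gene5,
             gene3 = gene3, chrom5 = chrom5, bp5 = bp5, strand5 = strand5,
             chrom3 = chrom3, bp3 = bp3, strand3 = strand3,
             junction_reads = junction_reads, stringsAsFactors = FALSE)
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
}

# Exhaustive SHS oracle: tries every (b, f) split over the clipped windows
# by direct character comparison, independent of lcp/lcs-based detect_shs.
# Windows are taken with the same strand-aware extraction helpers that the
# operator uses (those are pinned by their own hand-derived tests); the
# search over splits is what this oracle makes exhaustive.
shs_oracle <- function(call, genome, K = 20L, L_min = 4L) {
  seg5 <- fusionscope:::seg5_tail(genome, call$chrom5, call$bp5,
                                  call$strand5, K)
  seg3 <- fusionscope:::seg3_head(genome, call$chrom3, call$bp3,
                                  call$strand3, K)
  aft5 <- fusionscope:::after_bp5(genome, call$chrom5, call$bp5,
                                  call$strand5, K)
  bef3 <- fusionscope:::before_bp3(genome, call$chrom3, call$bp3,
                                   call$strand3, K)
  chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]
  a5 <- chars(aft5); s3 <- chars(seg3); s5 <- chars(seg5); b3 <- chars(bef3)
  n5 <- length(s5); n3 <- length(b3)
  best_f <- 0L
  for (f in seq_len(min(length(a5), length(s3)))) {
    if (all(a5[1:f] == s3[1:f] & a5[1:f] != "N")) best_f <- f
  }
  best_b <- 0L
  for (b in seq_len(min(n5, n3))) {
    x <- s5[(n5 - b + 1):n5]; y <- b3[(n3 - b + 1):n3]
    if (all(x == y & x != "N")) best_b <- b
  }
  tot <- best_f + best_b
  if (tot >= L_min) {
    seq <- paste0(substr(seg5, nchar(seg5) - best_b + 1, nchar(seg5)),
                  substr(seg3, 1, best_f))
    list(shs_len = tot, shs_seq = seq)
  } else {
    list(shs_len = 0L, shs_seq = "")
  }
}

# Brute-force deduplication oracle at tolerance 0: exact equality on every
# identity field.
dedup_oracle_tol0 <- function(calls) {
  key <- paste(calls$gene5, calls$gene3, calls$chrom5, calls$chrom3,
               calls$strand5, calls$strand3, calls$bp5, calls$bp3,
               sep = "|")
  split(seq_len(nrow(calls)), key)
}
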