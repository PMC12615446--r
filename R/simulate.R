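# Seeded synthetic-data generator: a toy multi-chromosome genome with
# multi-exon genes on both strands, planted fusion events of known mechanism,
# correlated parental-gene expression, long-read alignment tables straddling
# the validation thresholds, and replicated qPCR Ct values. Every generator
# is a pure function of its seed. The planted truth labels let the whole
# pipeline be verified end to end with no external data.

#' Generate a toy genome and annotation
#'
#' Chromosomes are uniform-random A/C/G/T sequences. Genes of 2-6 exons are
#' packed left to right with random intergenic gaps, on both strands;
#' roughly half carry a CDS spanning all exons. Canonical GT..AG motifs (in
#' transcription orientation) are written at every annotated intron edge, so
#' junctions planted at exon boundaries are canonical by construction.
#'
#' @param n_chroms number of chromosomes (default 2).
#' @param chrom_len chromosome length in bp (>= 5000; default 1e5).
#' @param n_genes total genes, distributed round-robin (default 40).
#' @param seed integer seed.
#' @return list(genome = named character vector, ann = `annotation`).
#' @export
generate_genome <- function(n_chroms = 2L, chrom_len = 100000L,
                            n_genes = 40L, seed = 1L) {
  fs_assert(chrom_len >= 5000, "chrom_len must be >= 5000")
  set.seed(seed)
  chroms <- paste0("chr", seq_len(n_chroms))
  bases <- c("A", "C", "G", "T")
  seq_chars <- lapply(chroms, function(ch) sample(bases, chrom_len, TRUE))
  names(seq_chars) <- chroms

  txs <- list()
  cursor <- stats::setNames(rep(1L, n_chroms), chroms)
  for (gi in seq_len(n_genes)) {
    ch <- chroms[(gi - 1L) %% n_chroms + 1L]
    n_ex <- sample(2:6, 1)
    ex_len <- sample(90:240, n_ex, TRUE)
    in_len <- if (n_ex > 1) sample(60:180, n_ex - 1L, TRUE) else integer(0)
    gap <- sample(300:800, 1)
    start <- cursor[[ch]] + gap
    ends <- start + cumsum(ex_len) + c(0L, cumsum(in_len)) - 1L
    starts <- ends - ex_len + 1L
    gene_end <- ends[n_ex]
    if (gene_end > chrom_len - 200L) {
      fs_error(sprintf(
        "infeasible packing: gene %d does not fit on %s (need %d bp)",
        gi, ch, gene_end))
    }
    strand <- sample(c("+", "-"), 1)
    # canonical intron edges in transcription orientation
    for (k in seq_len(n_ex - 1L)) {
      is <- ends[k] + 1L        # intron genomic start
      ie <- starts[k + 1L] - 1L # intron genomic end
      if (strand == "+") {
        seq_chars[[ch]][c(is, is + 1L)] <- c("G", "T")
        seq_chars[[ch]][c(ie - 1L, ie)] <- c("A", "G")
      } else {
        seq_chars[[ch]][c(is, is + 1L)] <- c("C", "T")
        seq_chars[[ch]][c(ie - 1L, ie)] <- c("A", "C")
      }
    }
    gid <- sprintf("g%03d", gi)
    exons <- cbind(starts, ends)
    has_cds <- stats::runif(1) < 0.5
    txs[[gi]] <- transcript(
      transcript_id = paste0(gid, ".t1"), gene_id = gid, chrom = ch,
      strand = strand, exons = exons,
      cds = if (has_cds) exons else matrix(integer(0), ncol = 2))
    cursor[[ch]] <- gene_end
  }
  genome <- vapply(seq_chars, paste, character(1), collapse = "")
  list(genome = genome, ann = annotation(txs, genome = genome))
}

# --- planting helpers --------------------------------------------------------

# Exon matrix of the (single) transcript in transcription order.
tx_of <- function(ann, gid) ann_gene(ann, gid)$transcripts[[1]]

exons_tx_order <- function(tx) {
  if (tx$strand == "+") tx$exons
  else tx$exons[rev(seq_len(nrow(tx$exons))), , drop = FALSE]
}

# Coding bases from transcript start through a genomic position (inclusive),
# and strictly before it, assuming CDS == exons (generator construction).
exon_bases_through <- function(tx, bp) {
  ex <- exons_tx_order(tx)
  tot <- 0L
  for (i in seq_len(nrow(ex))) {
    if (bp >= ex[i, 1] && bp <= ex[i, 2]) {
      off <- if (tx$strand == "+") bp - ex[i, 1] + 1L else ex[i, 2] - bp + 1L
      return(tot + off)
    }
    tot <- tot + ex[i, 2] - ex[i, 1] + 1L
  }
  NA_integer_
}

expected_frame <- function(tx5, bp5, tx3, bp3) {
  if (nrow(tx5$cds) == 0 || nrow(tx3$cds) == 0) return("not_applicable")
  L5 <- exon_bases_through(tx5, bp5)
  O3 <- exon_bases_through(tx3, bp3) - 1L
  if ((L5 - O3) %% 3L == 0L) "in_frame" else "frameshift"
}

# bp5 at the transcription-direction 3' end of an internal exon (one that is
# followed by an intron), so the donor GT written at the intron edge applies.
boundary_bp5 <- function(tx) {
  ex <- exons_tx_order(tx)
  j <- sample(seq_len(nrow(ex) - 1L), 1)
  if (tx$strand == "+") ex[j, 2] else ex[j, 1]
}

# bp3 at the transcription-direction 5' start of an exon preceded by an
# intron (acceptor AG written at the intron edge).
boundary_bp3 <- function(tx) {
  ex <- exons_tx_order(tx)
  j <- sample(2:nrow(ex), 1)
  if (tx$strand == "+") ex[j, 1] else ex[j, 2]
}

# A position strictly inside an exon, `margin` bases away from both edges.
midexon_bp <- function(tx, margin = 12L) {
  ex <- exons_tx_order(tx)
  ok <- which(ex[, 2] - ex[, 1] + 1L >= 2L * margin + 3L)
  j <- if (length(ok) == 1) ok else sample(ok, 1)
  sample((ex[j, 1] + margin):(ex[j, 2] - margin), 1)
}

# Write a string into a chromosome char vector along the genome forward
# strand starting at `pos`.
poke <- function(seq_chars, chrom, pos, s) {
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  seq_chars[[chrom]][pos:(pos + length(v) - 1L)] <- v
  seq_chars
}

#' Plant fusion events of known mechanism
#'
#' Constructs fusion calls whose junction features are controlled:
#' \describe{
#'   \item{canonical_boundary}{joins internal exon boundaries of two genes;
#'     GT-AG guaranteed by the genome construction; boundary class "both".}
#'   \item{canonical_novel}{mid-exon breakpoints; GT/AG written into the
#'     genome at the junction; boundary class "none".}
#'   \item{canonical_shs}{like canonical_novel plus an engineered
#'     k-bp homology (k in 4-9) on the 5' side, yielding mechanism "both".}
#'   \item{shs}{mid-exon breakpoints with an engineered k-bp homology after
#'     bp5 copying the 3' segment start; donor/acceptor kept non-canonical;
#'     mechanism "shs".}
#'   \item{noncanonical}{mid-exon breakpoints with neither signal
#'     (rejection-sampled); mechanism "other".}
#'   \item{readthrough}{exon-boundary junction of two adjacent genes on one
#'     chromosome; intrachromosomal canonical fusion.}
#' }
#' Each event uses a fresh pair of genes (no gene reuse, so events cannot
#' interfere), and emits 1-3 duplicate calls attributed to pseudo-tools
#' toolA/toolB/toolC for deduplication tests. Candidate junctions whose
#' random context violates the intended label (e.g. chance microhomology at
#' a canonical junction) are rejected and re-drawn.
#'
#' @param genome named character vector from [generate_genome()].
#' @param ann matching `annotation`.
#' @param counts named integer vector of events per mechanism label.
#' @param seed integer seed.
#' @param K,L_min SHS parameters used for rejection checks (defaults 20, 4).
#' @return list(calls = fusion-call data.frame, truth = data.frame of
#'   planted events with expected labels, genome = possibly edited genome).
#' @export
plant_fusions <- function(genome, ann,
                          counts = c(canonical_boundary = 5L,
                                     canonical_novel = 3L,
                                     canonical_shs = 2L,
                                     shs = 3L,
                                     noncanonical = 4L,
                                     readthrough = 2L),
                          seed = 1L, K = 20L, L_min = 4L) {
  set.seed(seed)
  labels <- rep(names(counts), counts)
  # read-through events need genomically adjacent unused genes, so place
  # them before other events consume the gene pool
  labels <- labels[order(labels != "readthrough")]
  n_events <- length(labels)
  gene_ids <- names(ann)
  fs_assert(length(gene_ids) >= 2L * n_events,
            sprintf("need >= %d genes for %d events", 2L * n_events,
                    n_events))
  seq_chars <- lapply(genome, function(s) strsplit(s, "", fixed = TRUE)[[1]])
  used <- character(0)

  # adjacency along each chromosome for read-through events
  pos_df <- data.frame(
    gid = gene_ids,
    chrom = vapply(ann, `[[`, "", "chrom"),
    start = vapply(ann, function(g) min(g$transcripts[[1]]$exons[, 1]),
                   integer(1)),
    stringsAsFactors = FALSE)
  pos_df <- pos_df[order(pos_df$chrom, pos_df$start), ]

  materialize <- function(sc) vapply(sc, paste, character(1), collapse = "")

  check_call <- function(call, sc) {
    g <- materialize(sc)
    motifs <- extract_junction_motifs(call, g)
    shs <- detect_shs(call, g, K = K, L_min = L_min)
    cbind(motifs, shs)
  }

  mk_call <- function(g5, g3, bp5, bp3) {
    data.frame(sample_id = "S1", tool = "toolA",
               gene5 = g5, gene3 = g3,
               chrom5 = ann_gene(ann, g5)$chrom, bp5 = bp5,
               strand5 = ann_gene(ann, g5)$strand,
               chrom3 = ann_gene(ann, g3)$chrom, bp3 = bp3,
               strand3 = ann_gene(ann, g3)$strand,
               junction_reads = 0L, stringsAsFactors = FALSE)
  }

  pick_genes <- function(label) {
    avail <- setdiff(gene_ids, used)
    if (label == "readthrough") {
      n <- nrow(pos_df)
      adj <- which(pos_df$chrom[-n] == pos_df$chrom[-1] &
                     pos_df$gid[-n] %in% avail &
                     pos_df$gid[-1] %in% avail)
      fs_assert(length(adj) > 0,
                "no adjacent gene pair left for a read-through event")
      j <- if (length(adj) == 1) adj else sample(adj, 1)
      return(pos_df$gid[c(j, j + 1L)])
    }
    sample(avail, 2)
  }

  calls <- list(); truth <- list()
  tools <- c("toolA", "toolB", "toolC")
  for (ei in seq_len(n_events)) {
    label <- labels[ei]
    placed <- FALSE
    for (attempt in 1:60) {
      gs <- pick_genes(label)
      g5 <- gs[1]; g3 <- gs[2]
      tx5 <- tx_of(ann, g5); tx3 <- tx_of(ann, g3)
      cand <- seq_chars
      k <- 0L
      if (label %in% c("canonical_boundary", "readthrough")) {
        bp5 <- boundary_bp5(tx5); bp3 <- boundary_bp3(tx3)
        call <- mk_call(g5, g3, bp5, bp3)
        chk <- check_call(call, cand)
        ok <- chk$canonical && chk$shs_len == 0
        exp_mech <- "canonical_splice"; exp_bnd <- "both"
      } else if (label == "canonical_novel") {
        bp5 <- midexon_bp(tx5); bp3 <- midexon_bp(tx3)
        call <- mk_call(g5, g3, bp5, bp3)
        cand <- plant_motifs(cand, call)
        chk <- check_call(call, cand)
        ok <- chk$canonical && chk$shs_len == 0
        exp_mech <- "canonical_splice"; exp_bnd <- "none"
      } else if (label == "canonical_shs") {
        k <- sample(4:9, 1)
        bp5 <- midexon_bp(tx5, margin = k + 4L); bp3 <- midexon_bp(tx3)
        call <- mk_call(g5, g3, bp5, bp3)
        cand <- plant_motifs(cand, call)
        s <- before_bp3(materialize(cand), call$chrom3, bp3, call$strand3, k)
        cand <- plant_seg5_suffix(cand, call, s)
        chk <- check_call(call, cand)
        ok <- chk$canonical && chk$shs_len >= k
        exp_mech <- "both"; exp_bnd <- "none"
      } else if (label == "shs") {
        k <- sample(4:9, 1)
        bp5 <- midexon_bp(tx5, margin = k + 4L); bp3 <- midexon_bp(tx3)
        call <- mk_call(g5, g3, bp5, bp3)
        t3 <- seg3_head(materialize(cand), call$chrom3, bp3, call$strand3, k)
        cand <- plant_after5(cand, call, t3)
        chk <- check_call(call, cand)
        ok <- !chk$canonical && chk$shs_len >= k
        exp_mech <- "shs"; exp_bnd <- "none"
      } else if (label == "noncanonical") {
        bp5 <- midexon_bp(tx5); bp3 <- midexon_bp(tx3)
        call <- mk_call(g5, g3, bp5, bp3)
        chk <- check_call(call, cand)
        ok <- !chk$canonical && chk$shs_len == 0
        exp_mech <- "other"; exp_bnd <- "none"
      } else {
        fs_error(sprintf("unknown mechanism label '%s'", label))
      }
      if (!ok) next
      seq_chars <- cand
      used <- c(used, g5, g3)
      fid <- sprintf("F%03d", ei)
      n_dup <- sample(1:3, 1)
      ev_tools <- sample(tools, n_dup)
      reads <- sample(5:60, n_dup)
      ev_calls <- do.call(rbind, lapply(seq_len(n_dup), function(d) {
        cc <- call
        cc$sample_id <- sprintf("S%d", sample(1:6, 1))
        cc$tool <- ev_tools[d]
        cc$junction_reads <- reads[d]
        cc
      }))
      calls[[ei]] <- ev_calls
      truth[[ei]] <- data.frame(
        fusion_id = fid, label = label, gene5 = g5, gene3 = g3,
        chrom5 = call$chrom5, bp5 = bp5, strand5 = call$strand5,
        chrom3 = call$chrom3, bp3 = bp3, strand3 = call$strand3,
        shs_k = k,
        expected_mechanism = exp_mech,
        expected_boundary = exp_bnd,
        expected_locality = if (call$chrom5 == call$chrom3)
          "intrachromosomal" else "interchromosomal",
        expected_frame = expected_frame(tx5, bp5, tx3, bp3),
        n_calls = n_dup,
        stringsAsFactors = FALSE)
      placed <- TRUE
      break
    }
    fs_assert(placed,
              sprintf("placement failed for a '%s' event after 60 attempts",
                      label))
  }
  list(calls = do.call(rbind, calls), truth = do.call(rbind, truth),
       genome = materialize(seq_chars))
}

# Write GT after bp5 and AG before bp3, both in transcription orientation.
plant_motifs <- function(seq_chars, call) {
  if (call$strand5 == "+") {
    seq_chars <- poke(seq_chars, call$chrom5, call$bp5 + 1L, "GT")
  } else {
    seq_chars <- poke(seq_chars, call$chrom5, call$bp5 - 2L, "AC")
  }
  if (call$strand3 == "+") {
    seq_chars <- poke(seq_chars, call$chrom3, call$bp3 - 2L, "AG")
  } else {
    seq_chars <- poke(seq_chars, call$chrom3, call$bp3 + 1L, "CT")
  }
  seq_chars
}

# Make the last nchar(s) transcribed bases of the 5' segment equal s.
plant_seg5_suffix <- function(seq_chars, call, s) {
  k <- nchar(s)
  if (call$strand5 == "+") {
    poke(seq_chars, call$chrom5, call$bp5 - k + 1L, s)
  } else {
    poke(seq_chars, call$chrom5, call$bp5, revcomp(s))
  }
}

# Make the nchar(s) bases after bp5 (transcription direction) equal s.
plant_after5 <- function(seq_chars, call, s) {
  k <- nchar(s)
  if (call$strand5 == "+") {
    poke(seq_chars, call$chrom5, call$bp5 + 1L, s)
  } else {
    poke(seq_chars, call$chrom5, call$bp5 - k, revcomp(s))
  }
}

#' Simulate a TPM expression matrix with correlated parental pairs
#'
#' Log-normal expression: each gene has a log2-scale mean; the two parents
#' of a fusion pair share a latent factor so their pair-level means
#' correlate at `rho` on the log scale. Per-sample noise is added on top.
#' For each fusion a random subset of samples is marked fusion-present, and
#' the parental genes of that fusion are scaled by `fusion_effect` in those
#' samples.
#'
#' @param genes character vector of gene ids (or an `annotation`).
#' @param pairs data.frame with columns fusion_id, gene5, gene3.
#' @param n_samples number of samples (default 26).
#' @param rho target log-scale correlation of pair means, 0 <= rho < 1.
#' @param fusion_effect multiplicative TPM effect in fusion-present samples
#'   (default 1 = none).
#' @param seed integer seed.
#' @param mu0,sigma_gene,sigma_sample log2-scale location, between-gene SD
#'   and within-gene sample SD (defaults 4, 2, 0.3).
#' @return list(tpm = gene x sample matrix, presence = named list
#'   fusion_id -> fusion-present sample names).
#' @export
simulate_expression <- function(genes, pairs, n_samples = 26L, rho = 0.5,
                                fusion_effect = 1, seed = 1L, mu0 = 4,
                                sigma_gene = 2, sigma_sample = 0.3) {
  fs_assert(rho >= 0 && rho < 1, "rho must be in [0, 1)")
  fs_assert(fusion_effect > 0, "fusion_effect must be > 0")
  if (inherits(genes, "annotation")) genes <- names(genes)
  genes <- unique(c(genes, pairs$gene5, pairs$gene3))
  set.seed(seed)
  mu <- stats::setNames(rep(NA_real_, length(genes)), genes)
  for (i in seq_len(nrow(pairs))) {
    lat <- stats::rnorm(1, 0, sigma_gene)
    for (g in c(pairs$gene5[i], pairs$gene3[i])) {
      if (is.na(mu[[g]])) {
        mu[[g]] <- mu0 + sqrt(rho) * lat +
          sqrt(1 - rho) * stats::rnorm(1, 0, sigma_gene)
      }
    }
  }
  mu[is.na(mu)] <- mu0 + stats::rnorm(sum(is.na(mu)), 0, sigma_gene)
  samples <- sprintf("sample%02d", seq_len(n_samples))
  eps <- matrix(stats::rnorm(length(genes) * n_samples, 0, sigma_sample),
                length(genes), n_samples)
  tpm <- 2^(mu + eps)
  dimnames(tpm) <- list(genes, samples)
  presence <- list()
  for (i in seq_len(nrow(pairs))) {
    n_fp <- sample(seq(max(1L, floor(n_samples * 0.2)),
                       max(2L, floor(n_samples * 0.5))), 1)
    n_fp <- min(n_fp, n_samples - 1L)
    fp <- sort(sample(samples, n_fp))
    presence[[pairs$fusion_id[i]]] <- fp
    if (fusion_effect != 1) {
      tpm[c(pairs$gene5[i], pairs$gene3[i]), fp] <-
        tpm[c(pairs$gene5[i], pairs$gene3[i]), fp] * fusion_effect
    }
  }
  list(tpm = tpm, presence = presence)
}

#' Simulate long-read BLAST hits with threshold-straddling decoys
#'
#' True hits have identity in (81, 100] and alignment length in (151, 200],
#' so they pass the default validation filter; decoys fail it on exactly one
#' side (identity <= 80 with good length, or length <= 150 with good
#' identity). A subject-length column is always present.
#'
#' @param fusion_ids junction query ids.
#' @param n_true number of fusions given one true hit each (first
#'   `n_true` ids).
#' @param n_decoy number of decoy hits spread over all ids.
#' @param seed integer seed.
#' @return list(hits = BLAST-tabular data.frame, truth = data.frame
#'   fusion_id, has_true_hit).
#' @export
simulate_longread_hits <- function(fusion_ids, n_true, n_decoy, seed = 1L) {
  fs_assert(n_true <= length(fusion_ids),
            "n_true exceeds number of fusion ids")
  set.seed(seed)
  mk_hit <- function(qid, ident, len, slen) {
    st <- sample(1:200, 1)
    data.frame(query_id = qid,
               subject_id = sprintf("lr_read_%05d", sample(1:99999, 1)),
               pct_identity = round(ident, 2), aln_len = len,
               mismatches = round(len * (100 - ident) / 100),
               gap_opens = sample(0:2, 1),
               qstart = 1L, qend = len,
               sstart = st, send = st + len - 1L,
               evalue = 1e-50, bitscore = round(1.9 * len * ident / 100),
               subject_len = slen, stringsAsFactors = FALSE)
  }
  true_ids <- fusion_ids[seq_len(n_true)]
  hits <- lapply(true_ids, function(q) {
    mk_hit(q, stats::runif(1, 81.01, 100), sample(152:200, 1),
           sample(500:1500, 1))
  })
  if (n_decoy > 0) {
    for (d in seq_len(n_decoy)) {
      q <- sample(fusion_ids, 1)
      if (d %% 2 == 0) {
        hits[[length(hits) + 1L]] <- mk_hit(q, stats::runif(1, 50, 80),
                                            sample(152:200, 1),
                                            sample(500:1500, 1))
      } else {
        hits[[length(hits) + 1L]] <- mk_hit(q, stats::runif(1, 81.01, 100),
                                            sample(100:150, 1),
                                            sample(500:1500, 1))
      }
    }
  }
  list(hits = do.call(rbind, hits),
       truth = data.frame(fusion_id = fusion_ids,
                          has_true_hit = fusion_ids %in% true_ids,
                          stringsAsFactors = FALSE))
}

#' Simulate a replicated qPCR Ct table
#'
#' A stable reference gene (Ct about 20) and a target whose treated-group Ct
#' is shifted by -log2(fold_change) relative to control (Ct about 25), with
#' Gaussian cycle noise.
#'
#' @param fold_change planted relative quantity (> 0).
#' @param n_reps replicates per group (>= 2; default 3).
#' @param noise_sd Ct noise SD in cycles (default 0.2).
#' @param seed integer seed.
#' @param target,reference gene names.
#' @return Ct data.frame (sample_id, group, gene, ct, replicate).
#' @export
simulate_qpcr <- function(fold_change = 2, n_reps = 3L, noise_sd = 0.2,
                          seed = 1L, target = "fusion_target",
                          reference = "EF1a") {
  fs_assert(fold_change > 0, "fold_change must be > 0")
  fs_assert(n_reps >= 2, "n_reps must be >= 2")
  set.seed(seed)
  rows <- list()
  for (grp in c("control", "treated")) {
    for (r in seq_len(n_reps)) {
      ct_ref <- 20 + stats::rnorm(1, 0, noise_sd)
      ct_tgt <- 25 - (grp == "treated") * log2(fold_change) +
        stats::rnorm(1, 0, noise_sd)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = grp, group = grp,
        gene = c(reference, target), ct = c(ct_ref, ct_tgt),
        replicate = r, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Generate and write a complete synthetic dataset
#'
#' Writes the exact formats the pipeline reads: genome.fa, annotation.gff3,
#' fusion_calls.tsv (unified dialect), expression.tsv, presence.json,
#' ct_table.tsv, longread_hits.tsv, and truth.json with all planted labels.
#'
#' @param outdir output directory (created if missing).
#' @param seed integer seed driving every component.
#' @param n_chroms,chrom_len,n_genes genome parameters.
#' @param counts planted events per mechanism, see [plant_fusions()].
#' @param n_samples,rho,fusion_effect expression parameters.
#' @param qpcr_fold_change,qpcr_noise_sd qPCR parameters.
#' @return invisibly, the list of generated objects.
#' @export
simulate_dataset <- function(outdir, seed = 1L, n_chroms = 2L,
                             chrom_len = 100000L, n_genes = 40L,
                             counts = c(canonical_boundary = 5L,
                                        canonical_novel = 3L,
                                        canonical_shs = 2L, shs = 3L,
                                        noncanonical = 4L, readthrough = 2L),
                             n_samples = 26L, rho = 0.5, fusion_effect = 1,
                             qpcr_fold_change = 2, qpcr_noise_sd = 0.2) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_genome(n_chroms, chrom_len, n_genes, seed = seed)
  planted <- plant_fusions(gen$genome, gen$ann, counts = counts,
                           seed = seed + 1L)
  pairs <- data.frame(fusion_id = planted$truth$fusion_id,
                      gene5 = planted$truth$gene5,
                      gene3 = planted$truth$gene3,
                      stringsAsFactors = FALSE)
  expr <- simulate_expression(gen$ann, pairs, n_samples = n_samples,
                              rho = rho, fusion_effect = fusion_effect,
                              seed = seed + 2L)
  lr <- simulate_longread_hits(planted$truth$fusion_id,
                               n_true = max(1L, nrow(planted$truth) - 3L),
                               n_decoy = 10L, seed = seed + 3L)
  ct <- simulate_qpcr(fold_change = qpcr_fold_change,
                      noise_sd = qpcr_noise_sd, seed = seed + 4L)
  write_fasta(planted$genome, file.path(outdir, "genome.fa"))
  write_gff3(gen$ann, file.path(outdir, "annotation.gff3"))
  write_fusion_calls(planted$calls, file.path(outdir, "fusion_calls.tsv"))
  write_expression_matrix(expr$tpm, file.path(outdir, "expression.tsv"))
  jsonlite::write_json(expr$presence, file.path(outdir, "presence.json"))
  utils::write.table(ct, file.path(outdir, "ct_table.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_blast_tab(lr$hits, file.path(outdir, "longread_hits.tsv"))
  jsonlite::write_json(list(planted = planted$truth,
                            longread = lr$truth),
                       file.path(outdir, "truth.json"), dataframe = "rows")
  invisible(list(genome = planted$genome, ann = gen$ann,
                 calls = planted$calls, truth = planted$truth,
                 expression = expr, longread = lr, ct = ct))
}
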