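# Junction-level characterization of fusion calls.
#
# Breakpoint convention: bp5 is the genomic coordinate (1-based) of the LAST
# transcribed base contributed by the 5' parental gene; bp3 is the FIRST
# transcribed base contributed by the 3' parental gene. All sequence windows
# are taken in each gene's transcription direction: on the minus strand
# "downstream" means decreasing genomic coordinate and sequences are
# reverse-complemented.

# --- strand-aware sequence windows ------------------------------------------

# Last n transcribed bases of the 5' segment, ending at bp5 (clipped).
seg5_tail <- function(genome, chrom, bp, strand, n) {
  if (n <= 0) return("")
  len <- chrom_len(genome, chrom)
  if (strand == "+") {
    gslice(genome, chrom, max(1L, bp - n + 1L), bp)
  } else {
    revcomp(gslice(genome, chrom, bp, min(len, bp + n - 1L)))
  }
}

# First n transcribed bases of the 3' segment, starting at bp3 (clipped).
seg3_head <- function(genome, chrom, bp, strand, n) {
  if (n <= 0) return("")
  len <- chrom_len(genome, chrom)
  if (strand == "+") {
    gslice(genome, chrom, bp, min(len, bp + n - 1L))
  } else {
    revcomp(gslice(genome, chrom, max(1L, bp - n + 1L), bp))
  }
}

# n bases immediately AFTER bp5 in the 5' gene's transcription direction.
after_bp5 <- function(genome, chrom, bp, strand, n) {
  if (n <= 0) return("")
  len <- chrom_len(genome, chrom)
  if (strand == "+") {
    gslice(genome, chrom, bp + 1L, min(len, bp + n))
  } else {
    revcomp(gslice(genome, chrom, max(1L, bp - n), bp - 1L))
  }
}

# n bases immediately BEFORE bp3 in the 3' gene's transcription direction.
before_bp3 <- function(genome, chrom, bp, strand, n) {
  if (n <= 0) return("")
  len <- chrom_len(genome, chrom)
  if (strand == "+") {
    gslice(genome, chrom, max(1L, bp - n), bp - 1L)
  } else {
    revcomp(gslice(genome, chrom, bp + 1L, min(len, bp + n)))
  }
}

# --- operators ---------------------------------------------------------------

#' Classify fusion locality
#'
#' A fusion is interchromosomal when its parental genes sit on different
#' chromosomes, intrachromosomal otherwise (read-through fusions between
#' adjacent genes are intrachromosomal by construction).
#'
#' @param calls fusion-call data.frame (unified columns).
#' @return character vector, "interchromosomal" or "intrachromosomal".
#' @export
classify_locality <- function(calls) {
  ifelse(calls$chrom5 != calls$chrom3,
         "interchromosomal", "intrachromosomal")
}

# Does bp5 fall on the transcription-direction 3' end of any exon of gene5?
bp5_at_boundary <- function(gene, bp5) {
  any(vapply(gene$transcripts, function(tx) {
    if (gene$strand == "+") any(tx$exons[, 2] == bp5)
    else any(tx$exons[, 1] == bp5)
  }, logical(1)))
}

# Does bp3 fall on the transcription-direction 5' start of any exon of gene3?
bp3_at_boundary <- function(gene, bp3) {
  any(vapply(gene$transcripts, function(tx) {
    if (gene$strand == "+") any(tx$exons[, 1] == bp3)
    else any(tx$exons[, 2] == bp3)
  }, logical(1)))
}

#' Classify breakpoints against annotated exon boundaries
#'
#' A breakpoint "is at a boundary" when, for any annotated transcript isoform
#' of its gene, bp5 coincides with the transcription-direction 3' end of an
#' exon (5' side) or bp3 with the transcription-direction 5' start of an exon
#' (3' side). On the minus strand the transcriptional end of an exon is its
#' genomic start, and vice versa.
#'
#' @param calls fusion-call data.frame.
#' @param ann an `annotation` object containing both parental genes.
#' @return character vector in {"both", "one", "none"}.
#' @export
breakpoint_boundary_class <- function(calls, ann) {
  vapply(seq_len(nrow(calls)), function(i) {
    g5 <- ann_gene(ann, calls$gene5[i])
    g3 <- ann_gene(ann, calls$gene3[i])
    n <- bp5_at_boundary(g5, calls$bp5[i]) + bp3_at_boundary(g3, calls$bp3[i])
    c("none", "one", "both")[n + 1L]
  }, character(1))
}

#' Extract donor/acceptor splice motifs at a fusion junction
#'
#' The donor motif is the 2-mer immediately after bp5 in the 5' gene's
#' transcription direction (the first two intron-side bases); the acceptor
#' motif is the 2-mer immediately before bp3 in the 3' gene's direction.
#' A junction is canonical when the pair is exactly GT-AG.
#'
#' @param calls fusion-call data.frame.
#' @param genome named character vector of chromosome sequences.
#' @return data.frame with columns donor_motif, acceptor_motif, canonical.
#' @export
extract_junction_motifs <- function(calls, genome) {
  res <- lapply(seq_len(nrow(calls)), function(i) {
    donor <- after_bp5(genome, calls$chrom5[i], calls$bp5[i],
                       calls$strand5[i], 2L)
    acceptor <- before_bp3(genome, calls$chrom3[i], calls$bp3[i],
                           calls$strand3[i], 2L)
    fs_assert(nchar(donor) == 2 && nchar(acceptor) == 2,
              sprintf("call %d: breakpoint too close to contig edge", i))
    data.frame(donor_motif = donor, acceptor_motif = acceptor,
               canonical = donor == "GT" && acceptor == "AG",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Detect short homologous sequences (SHS) at a fusion junction
#'
#' Measures exact microhomology straddling the breakpoint: `f` is the length
#' of the longest common prefix of the K bases after bp5 (5' gene direction)
#' and the 3' segment's first K bases; `b` is the longest common suffix of
#' the 5' segment's last K bases and the K bases before bp3 (3' gene
#' direction). The SHS length is `f + b` when it reaches `L_min`, else 0.
#' N never matches. Windows are clipped at chromosome ends.
#'
#' @param calls fusion-call data.frame.
#' @param genome genome sequences.
#' @param K window size in bp (default 20).
#' @param L_min minimum reportable SHS length (default 4).
#' @return data.frame with columns shs_len, shs_seq.
#' @export
detect_shs <- function(calls, genome, K = 20L, L_min = 4L) {
  res <- lapply(seq_len(nrow(calls)), function(i) {
    c5 <- calls$chrom5[i]; b5 <- calls$bp5[i]; s5 <- calls$strand5[i]
    c3 <- calls$chrom3[i]; b3 <- calls$bp3[i]; s3 <- calls$strand3[i]
    f <- lcp_len(after_bp5(genome, c5, b5, s5, K),
                 seg3_head(genome, c3, b3, s3, K))
    b <- lcs_len(seg5_tail(genome, c5, b5, s5, K),
                 before_bp3(genome, c3, b3, s3, K))
    if (f + b >= L_min) {
      data.frame(shs_len = f + b,
                 shs_seq = paste0(seg5_tail(genome, c5, b5, s5, b),
                                  seg3_head(genome, c3, b3, s3, f)),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(shs_len = 0L, shs_seq = "", stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, res)
}

#' Build the junction query sequence
#'
#' Concatenates, in transcription orientation, the last `flank` transcribed
#' bases of the 5' segment (ending at bp5) and the first `flank` transcribed
#' bases of the 3' segment (starting at bp3); each side is clipped at the
#' chromosome end, so the result has length at most 2*flank. This is the
#' sequence used to search long-read data for the fusion.
#'
#' @param calls fusion-call data.frame.
#' @param genome genome sequences.
#' @param flank bases per side (default 100).
#' @return character vector of junction sequences.
#' @export
build_junction_query <- function(calls, genome, flank = 100L) {
  vapply(seq_len(nrow(calls)), function(i) {
    paste0(seg5_tail(genome, calls$chrom5[i], calls$bp5[i],
                     calls$strand5[i], flank),
           seg3_head(genome, calls$chrom3[i], calls$bp3[i],
                     calls$strand3[i], flank))
  }, character(1))
}

# CDS bases of the 5' gene transcribed up to and including bp5.
cds_bases_through <- function(tx, bp, strand) {
  if (strand == "+") {
    sum(pmax(0L, pmin(tx$cds[, 2], bp) - tx$cds[, 1] + 1L))
  } else {
    sum(pmax(0L, tx$cds[, 2] - pmax(tx$cds[, 1], bp) + 1L))
  }
}

# CDS bases of the 3' gene transcribed strictly before bp3.
cds_bases_before <- function(tx, bp, strand) {
  if (strand == "+") {
    sum(pmax(0L, pmin(tx$cds[, 2], bp - 1L) - tx$cds[, 1] + 1L))
  } else {
    sum(pmax(0L, tx$cds[, 2] - pmax(tx$cds[, 1], bp + 1L) + 1L))
  }
}

inside_cds <- function(tx, bp) {
  nrow(tx$cds) > 0 && any(bp >= tx$cds[, 1] & bp <= tx$cds[, 2])
}

# Transcript choice when a gene has several CDS-bearing isoforms: prefer one
# whose exon boundary matches the breakpoint, else the longest CDS.
pick_frame_tx <- function(gene, bp, side) {
  txs <- Filter(function(tx) nrow(tx$cds) > 0, gene$transcripts)
  if (length(txs) == 0) return(NULL)
  at_bnd <- vapply(txs, function(tx) {
    if (side == "5") {
      if (gene$strand == "+") any(tx$exons[, 2] == bp)
      else any(tx$exons[, 1] == bp)
    } else {
      if (gene$strand == "+") any(tx$exons[, 1] == bp)
      else any(tx$exons[, 2] == bp)
    }
  }, logical(1))
  if (any(at_bnd)) return(txs[at_bnd][[1]])
  lens <- vapply(txs, cds_length, integer(1))
  txs[[which.max(lens)]]
}

#' Classify reading-frame preservation of a fusion
#'
#' Applicable only when both parental genes carry a CDS and both breakpoints
#' fall inside it. Let L5 be the number of coding bases of the 5' gene from
#' its start codon through bp5 (inclusive) and O3 the number of coding bases
#' of the 3' gene strictly before bp3; the fusion is in frame when
#' L5 mod 3 == O3 mod 3, otherwise it is a frameshift.
#'
#' @param calls fusion-call data.frame.
#' @param ann an `annotation` object.
#' @return character vector in {"in_frame", "frameshift", "not_applicable"}.
#' @export
classify_frame <- function(calls, ann) {
  vapply(seq_len(nrow(calls)), function(i) {
    g5 <- ann_gene(ann, calls$gene5[i])
    g3 <- ann_gene(ann, calls$gene3[i])
    tx5 <- pick_frame_tx(g5, calls$bp5[i], "5")
    tx3 <- pick_frame_tx(g3, calls$bp3[i], "3")
    if (is.null(tx5) || is.null(tx3) ||
        !inside_cds(tx5, calls$bp5[i]) || !inside_cds(tx3, calls$bp3[i])) {
      return("not_applicable")
    }
    L5 <- cds_bases_through(tx5, calls$bp5[i], g5$strand)
    O3 <- cds_bases_before(tx3, calls$bp3[i], g3$strand)
    if (L5 %% 3L == O3 %% 3L) "in_frame" else "frameshift"
  }, character(1))
}

#' Annotate fusion calls
#'
#' Runs the full junction characterization on each call: locality, exon
#' boundary class, donor/acceptor motifs, SHS detection, mechanism,
#' reading frame and the junction query sequence.
#'
#' Mechanism assignment: "both" when the junction is canonical (GT-AG) and
#' carries an SHS of at least `L_min`; "canonical_splice" when canonical
#' only; "shs" when only the SHS signal is present; "other" otherwise.
#'
#' @param calls fusion-call data.frame.
#' @param genome genome sequences.
#' @param ann an `annotation` object.
#' @param K,L_min SHS parameters, see [detect_shs()].
#' @param flank junction-query flank, see [build_junction_query()].
#' @return data.frame: unified call columns plus annotation columns.
#' @export
annotate_fusions <- function(calls, genome, ann, K = 20L, L_min = 4L,
                             flank = 100L) {
  fs_assert(nrow(calls) > 0, "no fusion calls to annotate")
  out <- tryCatch({
    motifs <- extract_junction_motifs(calls, genome)
    shs <- detect_shs(calls, genome, K = K, L_min = L_min)
    data.frame(
      calls,
      locality = classify_locality(calls),
      boundary_class = breakpoint_boundary_class(calls, ann),
      motifs,
      shs,
      mechanism = ifelse(motifs$canonical & shs$shs_len > 0, "both",
                  ifelse(motifs$canonical, "canonical_splice",
                  ifelse(shs$shs_len > 0, "shs", "other"))),
      frame = classify_frame(calls, ann),
      junction_seq = build_junction_query(calls, genome, flank = flank),
      stringsAsFactors = FALSE
    )
  }, fs_error = function(e) {
    fs_error(sprintf("annotate_fusions: %s", conditionMessage(e)))
  })
  out
}

#' Summarize junction mechanisms over a set of annotated fusions
#'
#' @param annotated data.frame from [annotate_fusions()].
#' @return list with `motif_counts` (data.frame donor/acceptor/count, sorted
#'   by count descending), and `category_proportions`,
#'   `locality_proportions`, `boundary_proportions` (named numeric vectors
#'   summing to 1).
#' @export
mechanism_summary <- function(annotated) {
  fs_assert(nrow(annotated) > 0, "mechanism_summary: empty input")
  motif <- as.data.frame(table(paste(annotated$donor_motif,
                                     annotated$acceptor_motif, sep = "-")),
                         stringsAsFactors = FALSE)
  names(motif) <- c("motif", "count")
  motif <- motif[order(-motif$count, motif$motif), ]
  rownames(motif) <- NULL
  prop <- function(x, levels) {
    tab <- table(factor(x, levels = levels))
    stats::setNames(as.numeric(tab) / length(x), levels)
  }
  list(
    motif_counts = motif,
    category_proportions = prop(annotated$mechanism,
                                c("canonical_splice", "shs", "both", "other")),
    locality_proportions = prop(annotated$locality,
                                c("interchromosomal", "intrachromosomal")),
    boundary_proportions = prop(annotated$boundary_class,
                                c("both", "one", "none"))
  )
}
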