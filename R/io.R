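# Readers and writers for the external formats the pipeline touches:
# FASTA genomes, GFF3 gene models, fusion-call TSVs (unified dialect plus a
# STAR-Fusion-style adapter), BLAST tabular (outfmt 6), TPM matrices and
# qPCR Ct tables. Coordinates are 1-based inclusive throughout (GFF3
# convention).

#' Read a genome FASTA
#'
#' Sequences are uppercased and any character outside A/C/G/T/N is replaced
#' by N (a message reports the replacement count). Sequence names are the
#' first whitespace-delimited token of each header.
#'
#' @param path FASTA file.
#' @return named character vector of chromosome sequences.
#' @export
read_fasta <- function(path) {
  fs_assert(file.exists(path), sprintf("file not found: %s", path))
  seqs <- tryCatch(Biostrings::readDNAStringSet(path, format = "fasta"),
                   error = function(e) {
                     fs_error(sprintf("FASTA format error in %s: %s",
                                      path, conditionMessage(e)))
                   })
  fs_assert(length(seqs) > 0, sprintf("empty FASTA file: %s", path))
  nm <- sub("\\s.*$", "", names(seqs))
  fs_assert(all(nzchar(nm)), "FASTA record with empty name")
  fs_assert(!anyDuplicated(nm),
            sprintf("duplicate sequence name(s): %s",
                    paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  x <- toupper(as.character(seqs))
  fs_assert(all(nchar(x) > 0), "FASTA record with empty sequence")
  n_bad <- sum(vapply(x, function(s) {
    nchar(s) - nchar(gsub("[^ACGTN]", "", s))
  }, numeric(1)))
  if (n_bad > 0) {
    x <- gsub("[^ACGTN]", "N", x)
    message(sprintf("read_fasta: replaced %d non-ACGTN character(s) with N",
                    n_bad))
  }
  names(x) <- nm
  x
}

#' Write a genome FASTA
#'
#' Inverse of [read_fasta()] on valid data.
#'
#' @param genome named character vector of sequences.
#' @param path output file.
#' @export
write_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path,
                              width = 70L)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Expects gene, mRNA (or transcript) rows carrying `ID`, and exon/CDS rows
#' carrying `Parent` pointing at an mRNA. Returns an [annotation()].
#'
#' @param path GFF3 file.
#' @param genome optional genome for coordinate validation.
#' @return an `annotation` object.
#' @export
read_gff3 <- function(path, genome = NULL) {
  fs_assert(file.exists(path), sprintf("file not found: %s", path))
  g <- rtracklayer::readGFF(path)
  g$type <- as.character(g$type)
  g$strand <- as.character(g$strand)
  gene_rows <- g[g$type == "gene", , drop = FALSE]
  mrna_rows <- g[g$type %in% c("mRNA", "transcript"), , drop = FALSE]
  fs_assert(all(!is.na(gene_rows$ID) & nzchar(gene_rows$ID)),
            "gene row without ID attribute")
  fs_assert(all(!is.na(mrna_rows$ID) & nzchar(mrna_rows$ID)),
            "mRNA row without ID attribute")
  gene_ids <- gene_rows$ID

  first_parent <- function(rows) {
    vapply(rows$Parent, function(p) {
      if (length(p) == 0) NA_character_ else as.character(p[[1]])
    }, character(1))
  }
  mrna_parent <- first_parent(mrna_rows)
  for (i in seq_along(mrna_parent)) {
    fs_assert(!is.na(mrna_parent[i]) && mrna_parent[i] %in% gene_ids,
              sprintf("mRNA %s: Parent '%s' is not a known gene",
                      mrna_rows$ID[i], mrna_parent[i]))
  }

  part_rows <- g[g$type %in% c("exon", "CDS"), , drop = FALSE]
  part_parent <- first_parent(part_rows)
  txs <- list()
  for (i in seq_len(nrow(mrna_rows))) {
    tid <- mrna_rows$ID[i]
    mine <- part_rows[!is.na(part_parent) & part_parent == tid, , drop = FALSE]
    exons <- mine[mine$type == "exon", c("start", "end"), drop = FALSE]
    cds <- mine[mine$type == "CDS", c("start", "end"), drop = FALSE]
    fs_assert(nrow(exons) > 0, sprintf("mRNA %s has no exon rows", tid))
    txs[[length(txs) + 1L]] <- transcript(
      transcript_id = tid, gene_id = mrna_parent[i],
      chrom = as.character(mrna_rows$seqid[i]),
      strand = mrna_rows$strand[i],
      exons = as.matrix(exons),
      cds = if (nrow(cds) > 0) as.matrix(cds) else matrix(integer(0), ncol = 2)
    )
  }
  orphans <- part_parent[!is.na(part_parent) &
                           !(part_parent %in% mrna_rows$ID)]
  fs_assert(length(orphans) == 0,
            sprintf("exon/CDS row(s) with unknown Parent: %s",
                    paste(unique(orphans), collapse = ", ")))
  bad <- part_rows$Parent[vapply(part_rows$Parent, length, integer(1)) == 0]
  fs_assert(length(bad) == 0, "exon/CDS row without Parent attribute")
  annotation(txs, genome = genome)
}

#' Write an annotation as GFF3
#'
#' @param ann an `annotation` object.
#' @param path output file.
#' @export
write_gff3 <- function(ann, path) {
  lines <- "##gff-version 3"
  for (g in ann) {
    span <- range(unlist(lapply(g$transcripts, function(tx) tx$exons)))
    lines <- c(lines, sprintf("%s\tfusionscope\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                              g$chrom, span[1], span[2], g$strand, g$gene_id))
    for (tx in g$transcripts) {
      lines <- c(lines, sprintf(
        "%s\tfusionscope\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
        g$chrom, min(tx$exons[, 1]), max(tx$exons[, 2]), g$strand,
        tx$transcript_id, g$gene_id))
      for (i in seq_len(nrow(tx$exons))) {
        lines <- c(lines, sprintf(
          "%s\tfusionscope\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
          g$chrom, tx$exons[i, 1], tx$exons[i, 2], g$strand,
          tx$transcript_id))
      }
      if (nrow(tx$cds) > 0) {
        for (i in seq_len(nrow(tx$cds))) {
          lines <- c(lines, sprintf(
            "%s\tfusionscope\tCDS\t%d\t%d\t.\t%s\t0\tParent=%s",
            g$chrom, tx$cds[i, 1], tx$cds[i, 2], g$strand,
            tx$transcript_id))
        }
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

unified_cols <- c("sample_id", "tool", "gene5", "gene3", "chrom5", "bp5",
                  "strand5", "chrom3", "bp3", "strand3", "junction_reads")

#' Read fusion calls
#'
#' Two dialects:
#' \describe{
#'   \item{unified}{TSV with header columns (exact order): sample_id, tool,
#'     gene5, gene3, chrom5, bp5, strand5, chrom3, bp3, strand3,
#'     junction_reads. bp5 is the last transcribed base of the 5' segment,
#'     bp3 the first transcribed base of the 3' segment (1-based).}
#'   \item{star_fusion}{a STAR-Fusion-style table with columns FusionName
#'     ("GENEA--GENEB"), JunctionReadCount, LeftBreakpoint and
#'     RightBreakpoint in "chrom:pos:strand" form.}
#' }
#'
#' @param path TSV file.
#' @param dialect "unified" (default) or "star_fusion".
#' @param sample_id,tool used to fill those fields for the star_fusion
#'   dialect, which does not carry them.
#' @return data.frame of fusion calls in unified column order.
#' @export
read_fusion_calls <- function(path, dialect = c("unified", "star_fusion"),
                              sample_id = "sample1", tool = "STAR-Fusion") {
  dialect <- match.arg(dialect)
  fs_assert(file.exists(path), sprintf("file not found: %s", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- sub("^#", "", names(df))
  if (dialect == "unified") {
    fs_assert(identical(names(df), unified_cols),
              sprintf("unified fusion TSV must have columns: %s",
                      paste(unified_cols, collapse = ", ")))
    calls <- df
  } else {
    need <- c("FusionName", "JunctionReadCount", "LeftBreakpoint",
              "RightBreakpoint")
    fs_assert(all(need %in% names(df)),
              sprintf("star_fusion dialect needs columns: %s",
                      paste(need, collapse = ", ")))
    split_bp <- function(x, line) {
      parts <- strsplit(x, ":", fixed = TRUE)[[1]]
      fs_assert(length(parts) == 3,
                sprintf("line %d: breakpoint '%s' is not chrom:pos:strand",
                        line, x))
      parts
    }
    calls <- do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
      genes <- strsplit(df$FusionName[i], "--", fixed = TRUE)[[1]]
      fs_assert(length(genes) == 2,
                sprintf("line %d: FusionName '%s' is not GENEA--GENEB",
                        i + 1L, df$FusionName[i]))
      l <- split_bp(df$LeftBreakpoint[i], i + 1L)
      r <- split_bp(df$RightBreakpoint[i], i + 1L)
      data.frame(sample_id = sample_id, tool = tool,
                 gene5 = genes[1], gene3 = genes[2],
                 chrom5 = l[1], bp5 = l[2], strand5 = l[3],
                 chrom3 = r[1], bp3 = r[2], strand3 = r[3],
                 junction_reads = df$JunctionReadCount[i],
                 stringsAsFactors = FALSE)
    }))
  }
  validate_calls(calls)
}

validate_calls <- function(calls) {
  for (col in c("bp5", "bp3", "junction_reads")) {
    v <- suppressWarnings(as.integer(calls[[col]]))
    bad <- which(is.na(v))
    fs_assert(length(bad) == 0,
              sprintf("line %d: unparseable %s '%s'", bad[1] + 1L, col,
                      calls[[col]][bad[1]]))
    calls[[col]] <- v
  }
  bad <- which(!(calls$strand5 %in% c("+", "-")) |
                 !(calls$strand3 %in% c("+", "-")))
  fs_assert(length(bad) == 0,
            sprintf("line %d: strand must be '+' or '-'", bad[1] + 1L))
  fs_assert(all(calls$bp5 >= 1 & calls$bp3 >= 1),
            "breakpoint coordinates must be >= 1")
  fs_assert(all(nzchar(calls$gene5) & nzchar(calls$gene3)),
            "empty gene id in fusion calls")
  fs_assert(all(calls$junction_reads >= 0),
            "junction_reads must be non-negative")
  calls
}

#' Write fusion calls in the unified dialect
#' @param calls data.frame of calls.
#' @param path output TSV.
#' @export
write_fusion_calls <- function(calls, path) {
  utils::write.table(calls[, unified_cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

blast_cols <- c("query_id", "subject_id", "pct_identity", "aln_len",
                "mismatches", "gap_opens", "qstart", "qend", "sstart",
                "send", "evalue", "bitscore")

#' Read BLAST tabular output (outfmt 6)
#'
#' Parses the 12 standard columns positionally; a 13th column, when present,
#' is taken as the subject length (`subject_len`).
#'
#' @param path tabular file without header.
#' @return data.frame of alignment hits.
#' @export
read_blast_tab <- function(path) {
  fs_assert(file.exists(path), sprintf("file not found: %s", path))
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  fs_assert(ncol(df) >= 12,
            sprintf("BLAST tabular needs >= 12 columns, found %d", ncol(df)))
  has_slen <- ncol(df) >= 13
  df <- df[, seq_len(if (has_slen) 13 else 12), drop = FALSE]
  names(df) <- c(blast_cols, if (has_slen) "subject_len")
  fs_assert(all(df$pct_identity >= 0 & df$pct_identity <= 100),
            "pct_identity outside [0, 100]")
  fs_assert(all(df$aln_len >= 1), "alignment length < 1")
  df
}

#' Write alignment hits as BLAST tabular
#' @param hits data.frame as returned by [read_blast_tab()].
#' @param path output file.
#' @export
write_blast_tab <- function(hits, path) {
  keep <- c(blast_cols, if ("subject_len" %in% names(hits)) "subject_len")
  utils::write.table(hits[, keep], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene-by-sample TPM matrix
#'
#' TSV whose first column holds gene ids and remaining columns one sample
#' each. Values must be non-negative.
#'
#' @param path TSV file.
#' @return numeric matrix, genes in rows.
#' @export
read_expression_matrix <- function(path) {
  fs_assert(file.exists(path), sprintf("file not found: %s", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  fs_assert(ncol(df) >= 2, "expression matrix needs gene id + >=1 sample")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  fs_assert(!anyNA(m), "non-numeric TPM value")
  fs_assert(all(m >= 0), "negative TPM value")
  rownames(m) <- df[[1]]
  m
}

#' Write a TPM matrix
#' @param m numeric matrix with gene rownames.
#' @param path output TSV.
#' @export
write_expression_matrix <- function(m, path) {
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

ct_cols <- c("sample_id", "group", "gene", "ct", "replicate")

#' Read a qPCR Ct table
#'
#' TSV with columns sample_id, group, gene, ct (cycles), replicate.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_ct_table <- function(path) {
  fs_assert(file.exists(path), sprintf("file not found: %s", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  fs_assert(all(ct_cols %in% names(df)),
            sprintf("Ct table needs columns: %s",
                    paste(ct_cols, collapse = ", ")))
  fs_assert(is.numeric(df$ct) && !anyNA(df$ct), "non-numeric Ct value")
  df
}

annotated_cols <- c(unified_cols, "locality", "boundary_class",
                    "donor_motif", "acceptor_motif", "canonical",
                    "shs_len", "shs_seq", "mechanism", "frame",
                    "junction_seq")

#' Write annotated fusions as TSV
#'
#' One row per annotated fusion: the unified call columns followed by
#' locality, boundary_class, donor/acceptor motifs, canonical flag, SHS
#' length and sequence, mechanism, frame and junction query sequence.
#' Round-trips losslessly through [read_annotated_fusions()].
#'
#' @param records annotated-fusion data.frame from [annotate_fusions()].
#' @param path output TSV.
#' @export
write_annotated_fusions <- function(records, path) {
  fs_assert(all(annotated_cols %in% names(records)),
            "records are not an annotated-fusion table")
  out <- records[, annotated_cols]
  out$shs_seq[out$shs_seq == ""] <- "."
  out$junction_seq[out$junction_seq == ""] <- "."
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an annotated-fusion TSV written by [write_annotated_fusions()]
#' @param path TSV file.
#' @return data.frame.
#' @export
read_annotated_fusions <- function(path) {
  fs_assert(file.exists(path), sprintf("file not found: %s", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  fs_assert(identical(names(df), annotated_cols),
            "not an annotated-fusion TSV")
  df$shs_seq[df$shs_seq == "."] <- ""
  df$junction_seq[df$junction_seq == "."] <- ""
  df$canonical <- as.logical(df$canonical)
  df
}

#' Read per-genotype fusion-pair lists
#'
#' TSV with columns genotype, gene5, gene3.
#'
#' @param path TSV file.
#' @return named list: genotype -> character vector of ordered pair keys.
#' @export
read_genotype_pairs <- function(path) {
  fs_assert(file.exists(path), sprintf("file not found: %s", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  fs_assert(all(c("genotype", "gene5", "gene3") %in% names(df)),
            "genotype pair list needs columns genotype, gene5, gene3")
  split(pair_key(df$gene5, df$gene3), df$genotype)
}

#' Read an ortholog-pair table
#'
#' Two-column TSV (header `gene_a`, `gene_b`); many-to-many rows allowed.
#'
#' @param path TSV file.
#' @return data.frame with columns gene_a, gene_b.
#' @export
read_ortholog_table <- function(path) {
  fs_assert(file.exists(path), sprintf("file not found: %s", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  fs_assert(ncol(df) >= 2, "ortholog table needs two columns")
  stats::setNames(df[, 1:2], c("gene_a", "gene_b"))
}
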