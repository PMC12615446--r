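test_that("genome generation is deterministic and canonical at intron edges", {
  g1 <- generate_genome(2, 50000, 20, seed = 7)
  g2 <- generate_genome(2, 50000, 20, seed = 7)
  expect_identical(g1$genome, g2$genome)
  d1 <- withr::local_tempdir()
  write_fasta(g1$genome, file.path(d1, "a.fa"))
  write_fasta(g2$genome, file.path(d1, "b.fa"))
  write_gff3(g1$ann, file.path(d1, "a.gff3"))
  write_gff3(g2$ann, file.path(d1, "b.gff3"))
  expect_identical(readLines(file.path(d1, "a.fa")),
                   readLines(file.path(d1, "b.fa")))
  expect_identical(readLines(file.path(d1, "a.gff3")),
                   readLines(file.path(d1, "b.gff3")))
  expect_length(g1$ann, 20)

  # every annotated intron begins GT and ends AG in transcription direction
  for (g in g1$ann) {
    tx <- g$transcripts[[1]]
    ex <- tx$exons
    for (k in seq_len(nrow(ex) - 1)) {
      intron <- substr(g1$genome[[g$chrom]], ex[k, 2] + 1, ex[k + 1, 1] - 1)
      if (g$strand == "-") intron <- revcomp(intron)
      expect_identical(substr(intron, 1, 2), "GT")
      expect_identical(substr(intron, nchar(intron) - 1, nchar(intron)),
                       "AG")
    }
  }
  expect_error(generate_genome(1, 5000, 50, seed = 1), "infeasible packing")
})

test_that("planted fusions carry their advertised signals", {
  gen <- generate_genome(seed = 31)
  p <- plant_fusions(gen$genome, gen$ann,
                     counts = c(canonical_boundary = 3, shs = 3,
                                readthrough = 2, noncanonical = 2),
                     seed = 31)
  expect_equal(nrow(p$truth), 10)
  expect_equal(sum(p$truth$n_calls), nrow(p$calls))

  # SHS events: detected homology at least the engineered k
  shs_truth <- p$truth[p$truth$label == "shs", ]
  calls <- p$calls[!duplicated(paste(p$calls$gene5, p$calls$gene3)), ]
  for (i in seq_len(nrow(shs_truth))) {
    call <- calls[calls$gene5 == shs_truth$gene5[i], ]
    r <- detect_shs(call, p$genome)
    expect_gte(r$shs_len, shs_truth$shs_k[i])
  }

  # read-through events are intrachromosomal by construction
  expect_true(all(p$truth$expected_locality[p$truth$label == "readthrough"] ==
                    "intrachromosomal"))
  rt <- p$truth[p$truth$label == "readthrough", ]
  expect_true(all(rt$chrom5 == rt$chrom3))

  # canonical-boundary events land on annotated exon edges
  cb <- p$truth[p$truth$label == "canonical_boundary", ]
  bcls <- breakpoint_boundary_class(
    calls[match(cb$gene5, calls$gene5), ], gen$ann)
  expect_true(all(bcls == "both"))
})

test_that("expression simulator honours rho, effects and non-negativity", {
  pairs <- data.frame(fusion_id = sprintf("F%03d", 1:300),
                      gene5 = sprintf("a%03d", 1:300),
                      gene3 = sprintf("b%03d", 1:300))
  sim0 <- simulate_expression(character(0), pairs, n_samples = 12, rho = 0,
                              seed = 3)
  expect_true(all(sim0$tpm >= 0))
  expect_lt(abs(parental_correlation(sim0$tpm, pairs)$R), 0.15)

  # presence map marks a proper nonempty subset of samples per fusion
  expect_true(all(lengths(sim0$presence) >= 1))
  expect_true(all(lengths(sim0$presence) < 12))

  # a planted 4x fusion effect is recovered as "up" for most fusions
  sim4 <- simulate_expression(character(0), pairs[1:40, ], n_samples = 26,
                              rho = 0.5, fusion_effect = 4, seed = 11)
  fc <- fp_fa_fold_change(sim4$tpm, pairs[1:40, ], sim4$presence)
  expect_gte(mean(fc$status == "up"), 0.95)
})

test_that("long-read simulator straddles the validation thresholds", {
  ids <- sprintf("F%03d", 1:12)
  lr <- simulate_longread_hits(ids, n_true = 10, n_decoy = 14, seed = 5)
  expect_true("subject_len" %in% names(lr$hits))
  r <- filter_longread_hits(lr$hits)
  validated <- r$fusion_id[r$validated]
  expect_setequal(validated, ids[1:10])
  # decoys fail on exactly one side each
  decoys <- lr$hits[lr$hits$pct_identity <= 80 | lr$hits$aln_len <= 150, ]
  expect_equal(nrow(decoys), 14)
  expect_true(all(xor(decoys$pct_identity <= 80, decoys$aln_len <= 150)))
})

test_that("qPCR simulator matches the Livak identity at zero noise", {
  ct <- simulate_qpcr(fold_change = 2, noise_sd = 0, seed = 1)
  r <- ddct(ct, "fusion_target", "EF1a")
  expect_equal(r$rq, 2.0)
  expect_equal(nrow(ct), 2 * 3 * 2)  # 2 groups x 3 reps x 2 genes

  # fold_change 1 stays near rq 1 under mild noise
  set.seed(1)
  rqs <- vapply(1:25, function(s) {
    ddct(simulate_qpcr(1, noise_sd = 0.1, seed = s),
         "fusion_target", "EF1a")$rq
  }, numeric(1))
  expect_true(all(rqs > 0.7 & rqs < 1.4))
  expect_equal(median(rqs), 1, tolerance = 0.15)
})

test_that("simulate_dataset writes a coherent, rereadable bundle", {
  d <- withr::local_tempdir()
  sim <- simulate_dataset(d, seed = 9)
  genome <- read_fasta(file.path(d, "genome.fa"))
  ann <- read_gff3(file.path(d, "annotation.gff3"), genome = genome)
  calls <- read_fusion_calls(file.path(d, "fusion_calls.tsv"))
  expect_identical(genome, sim$genome)
  expect_equal(nrow(calls), nrow(sim$calls))
  truth <- jsonlite::read_json(file.path(d, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(nrow(truth$planted), nrow(sim$truth))
  expr <- read_expression_matrix(file.path(d, "expression.tsv"))
  expect_equal(dim(expr), dim(sim$expression$tpm))
  hits <- read_blast_tab(file.path(d, "longread_hits.tsv"))
  expect_equal(nrow(hits), nrow(sim$longread$hits))
})
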