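test_that("locality is purely a chromosome comparison", {
  calls <- rbind(toy_call(chrom5 = "c1", chrom3 = "c2"),
                 toy_call(chrom5 = "c1", chrom3 = "c1"),
                 # read-through-style pair, same chromosome opposite strands
                 toy_call(chrom5 = "c1", chrom3 = "c1",
                          strand5 = "+", strand3 = "-"))
  expect_identical(classify_locality(calls),
                   c("interchromosomal", "intrachromosomal",
                     "intrachromosomal"))
})

test_that("boundary class is strand-aware and isoform-tolerant", {
  # plus-strand gene: exons [1,100], [201,300]; minus-strand gene:
  # exons [11,20], [31,40]
  ann <- annotation(list(
    transcript("p.t1", "gP", "c1", "+", rbind(c(1, 100), c(201, 300))),
    transcript("m.t1", "gM", "c2", "-", rbind(c(11, 20), c(31, 40)))))

  # 5' side on '+': boundary iff bp5 at an exon genomic END
  for (bp in c(100, 300)) {
    expect_identical(breakpoint_boundary_class(
      toy_call(gene5 = "gP", gene3 = "gM", bp5 = bp, bp3 = 15), ann), "one")
  }
  expect_identical(breakpoint_boundary_class(
    toy_call(gene5 = "gP", gene3 = "gM", bp5 = 50, bp3 = 15), ann), "none")

  # 5' side on '-': the transcriptional end of an exon is its genomic START
  for (bp in c(11, 31)) {
    expect_identical(breakpoint_boundary_class(
      toy_call(gene5 = "gM", gene3 = "gP", bp5 = bp, bp3 = 50), ann), "one")
  }
  for (bp in c(20, 40, 15)) {
    expect_identical(breakpoint_boundary_class(
      toy_call(gene5 = "gM", gene3 = "gP", bp5 = bp, bp3 = 50), ann), "none")
  }

  # 3' side on '-': the transcriptional start of an exon is its genomic END
  for (bp in c(20, 40)) {
    expect_identical(breakpoint_boundary_class(
      toy_call(gene5 = "gP", gene3 = "gM", bp5 = 50, bp3 = bp), ann), "one")
  }
  expect_identical(breakpoint_boundary_class(
    toy_call(gene5 = "gP", gene3 = "gM", bp5 = 100, bp3 = 40), ann), "both")

  # any isoform may carry the boundary
  ann2 <- annotation(list(
    transcript("p.t1", "gP", "c1", "+", rbind(c(1, 100), c(201, 300))),
    transcript("p.t2", "gP", "c1", "+", rbind(c(1, 150), c(201, 300))),
    transcript("q.t1", "gQ", "c1", "+", rbind(c(401, 500)))))
  expect_identical(breakpoint_boundary_class(
    toy_call(gene5 = "gP", gene3 = "gQ", bp5 = 150, bp3 = 401), ann2),
    "both")

  expect_error(breakpoint_boundary_class(
    toy_call(gene5 = "nope", gene3 = "gP"), ann), "unknown gene")
})

test_that("junction motifs follow transcription direction on both strands", {
  # '+/+': donor after bp5, acceptor before bp3
  g <- c(c1 = "AAAAAGTCCC", c2 = "CCCAGTTTTT")
  call <- toy_call(chrom5 = "c1", bp5 = 5, strand5 = "+",
                   chrom3 = "c2", bp3 = 6, strand3 = "+")
  m <- extract_junction_motifs(call, g)
  expect_identical(m$donor_motif, "GT")
  expect_identical(m$acceptor_motif, "AG")
  expect_true(m$canonical)

  # minus-strand 5' gene: genomic (bp5-2, bp5-1) == "AC" reads as donor "GT"
  g2 <- c(c1 = "AAAAACTTTT", c2 = "CCCAGTTTTT")
  m2 <- extract_junction_motifs(
    toy_call(chrom5 = "c1", bp5 = 7, strand5 = "-",
             chrom3 = "c2", bp3 = 6, strand3 = "+"), g2)
  expect_identical(m2$donor_motif, "GT")

  # minus-strand 3' gene: genomic (bp3+1, bp3+2) == "CT" reads as "AG"
  g3 <- c(c1 = "AAAAAGTCCC", c2 = "TTTTTCTAAA")
  m3 <- extract_junction_motifs(
    toy_call(chrom5 = "c1", bp5 = 5, strand5 = "+",
             chrom3 = "c2", bp3 = 5, strand3 = "-"), g3)
  expect_identical(m3$acceptor_motif, "AG")

  # GA-AG is reported verbatim but non-canonical
  g4 <- c(c1 = "AAAAAGACCC", c2 = "CCCAGTTTTT")
  m4 <- extract_junction_motifs(
    toy_call(chrom5 = "c1", bp5 = 5, strand5 = "+",
             chrom3 = "c2", bp3 = 6, strand3 = "+"), g4)
  expect_identical(m4$donor_motif, "GA")
  expect_false(m4$canonical)

  expect_error(extract_junction_motifs(
    toy_call(chrom5 = "c1", bp5 = 9, strand5 = "+",
             chrom3 = "c2", bp3 = 6, strand3 = "+"), g),
    "too close to contig edge")
})

test_that("minus-strand motifs equal plus-strand motifs on the mirrored genome", {
  set.seed(401)
  for (i in 1:25) {
    L <- 60L
    s <- random_seq(L)
    g <- c(c1 = s, m1 = revcomp(s))
    bp5 <- sample(10:50, 1); bp3 <- sample(10:50, 1)
    minus <- extract_junction_motifs(
      toy_call(chrom5 = "c1", bp5 = bp5, strand5 = "-",
               chrom3 = "c1", bp3 = bp3, strand3 = "-"), g)
    mirrored <- extract_junction_motifs(
      toy_call(chrom5 = "m1", bp5 = L - bp5 + 1L, strand5 = "+",
               chrom3 = "m1", bp3 = L - bp3 + 1L, strand3 = "+"), g)
    expect_identical(minus, mirrored)
  }
})

test_that("detect_shs matches a hand-built b=3/f=2 junction and thresholds", {
  g <- c(c5 = paste0("TTTTTTTGCA", "CGTTTTTTTT"),
         c3 = paste0("AAAAAAAGCA", "CGAAAAAAAA"))
  call <- toy_call(chrom5 = "c5", bp5 = 10, strand5 = "+",
                   chrom3 = "c3", bp3 = 11, strand3 = "+")
  r <- detect_shs(call, g)
  expect_equal(r$shs_len, 5L)
  expect_identical(r$shs_seq, "GCACG")
  orc <- shs_oracle(call, g)
  expect_equal(r$shs_len, orc$shs_len)
  expect_identical(r$shs_seq, orc$shs_seq)

  # no flanking identity
  g0 <- c(c5 = paste0(strrep("A", 10), strrep("C", 10)),
          c3 = paste0(strrep("G", 10), strrep("T", 10)))
  r0 <- detect_shs(toy_call(chrom5 = "c5", bp5 = 10, strand5 = "+",
                            chrom3 = "c3", bp3 = 11, strand3 = "+"), g0)
  expect_equal(r0$shs_len, 0L)
  expect_identical(r0$shs_seq, "")

  # b=2, f=1 stays below the default L_min = 4
  g1 <- c(c5 = paste0("TTTTTTTTCA", "CGTTTTTTTT"),
          c3 = paste0("AAAAAAAACA", "CAAAAAAAAA"))
  r1 <- detect_shs(toy_call(chrom5 = "c5", bp5 = 10, strand5 = "+",
                            chrom3 = "c3", bp3 = 11, strand3 = "+"), g1)
  expect_equal(r1$shs_len, 0L)
  # but it is reported with L_min lowered
  r1b <- detect_shs(toy_call(chrom5 = "c5", bp5 = 10, strand5 = "+",
                             chrom3 = "c3", bp3 = 11, strand3 = "+"), g1,
                    L_min = 3L)
  expect_equal(r1b$shs_len, 3L)

  # N never matches
  gn <- c(c5 = paste0("TTTTTTTNNN", "NNTTTTTTTT"),
          c3 = paste0("AAAAAAANNN", "NNAAAAAAAA"))
  rn <- detect_shs(toy_call(chrom5 = "c5", bp5 = 10, strand5 = "+",
                            chrom3 = "c3", bp3 = 11, strand3 = "+"), gn)
  expect_equal(rn$shs_len, 0L)
})

test_that("junction query is clipped, oriented and length-bounded", {
  g <- c(c1 = random_seq(400), c2 = random_seq(400))
  full <- build_junction_query(
    toy_call(chrom5 = "c1", bp5 = 200, strand5 = "+",
             chrom3 = "c2", bp3 = 100, strand3 = "+"), g)
  expect_equal(nchar(full), 200L)
  expect_identical(substr(full, 1, 100), substr(g[["c1"]], 101, 200))
  expect_identical(substr(full, 101, 200), substr(g[["c2"]], 100, 199))

  clipped <- build_junction_query(
    toy_call(chrom5 = "c1", bp5 = 40, strand5 = "+",
             chrom3 = "c2", bp3 = 100, strand3 = "+"), g)
  expect_equal(nchar(clipped), 140L)

  # minus-strand 3' gene: second half is the reverse complement of the
  # genomic bases from bp3 downward
  g10 <- c(c1 = "AAAAAAAAAA", c2 = "ACGTACGTAC")
  q <- build_junction_query(
    toy_call(chrom5 = "c1", bp5 = 5, strand5 = "+",
             chrom3 = "c2", bp3 = 10, strand3 = "-"), g10, flank = 10)
  expect_identical(substr(q, 6, nchar(q)), revcomp("ACGTACGTAC"))
})

test_that("frame classification uses CDS arithmetic mod 3", {
  ann <- annotation(list(
    transcript("a.t1", "gA", "c1", "+", rbind(c(1, 400)), rbind(c(1, 400))),
    transcript("b.t1", "gB", "c2", "+", rbind(c(1, 300)), rbind(c(1, 300))),
    transcript("u.t1", "gU", "c3", "+", rbind(c(1, 300)),
               rbind(c(151, 300)))))
  # L5 = 300, O3 = 99 -> in frame
  expect_identical(classify_frame(
    toy_call(gene5 = "gA", gene3 = "gB", bp5 = 300, bp3 = 100), ann),
    "in_frame")
  # L5 = 301, O3 = 99 -> frameshift
  expect_identical(classify_frame(
    toy_call(gene5 = "gA", gene3 = "gB", bp5 = 301, bp3 = 100), ann),
    "frameshift")
  # breakpoint in the 5' UTR of the 3' gene -> not applicable
  expect_identical(classify_frame(
    toy_call(gene5 = "gA", gene3 = "gU", bp5 = 300, bp3 = 100), ann),
    "not_applicable")
  # gene without CDS -> not applicable
  ann2 <- annotation(list(
    transcript("a.t1", "gA", "c1", "+", rbind(c(1, 400)), rbind(c(1, 400))),
    transcript("n.t1", "gN", "c2", "+", rbind(c(1, 300)))))
  expect_identical(classify_frame(
    toy_call(gene5 = "gA", gene3 = "gN", bp5 = 300, bp3 = 100), ann2),
    "not_applicable")
})

test_that("minus-strand frame arithmetic counts transcribed CDS bases", {
  # minus gene: exons/CDS [101,200] and [301,400]; transcription starts at
  # 400. bp5 = 350 -> L5 = 51; as a 3' gene bp3 = 350 -> O3 = 50.
  ann <- annotation(list(
    transcript("m.t1", "gM", "c1", "-", rbind(c(101, 200), c(301, 400)),
               rbind(c(101, 200), c(301, 400))),
    transcript("a.t1", "gA", "c2", "+", rbind(c(1, 400)), rbind(c(1, 400)))))
  # L5 = 51, O3 = 0 -> 51 mod 3 == 0 mod 3 -> in frame
  expect_identical(classify_frame(
    toy_call(gene5 = "gM", gene3 = "gA", bp5 = 350, bp3 = 1), ann),
    "in_frame")
  # L5 = 300 (gA through bp5=300), O3 = 50 (gM bp3=350): 0 vs 2 -> shift
  expect_identical(classify_frame(
    toy_call(gene5 = "gA", gene3 = "gM", bp5 = 300, bp3 = 350), ann),
    "frameshift")
  # crossing into gM's second transcribed exon: bp3 = 150 -> O3 = 100 + 50
  expect_identical(classify_frame(
    toy_call(gene5 = "gA", gene3 = "gM", bp5 = 300, bp3 = 150), ann),
    "in_frame")
})

test_that("annotate_fusions assigns mechanisms and summary proportions sum to 1", {
  gen <- generate_genome(seed = 21)
  p <- plant_fusions(gen$genome, gen$ann, seed = 21)
  annotated <- annotate_fusions(p$calls, p$genome, gen$ann)
  expect_equal(nrow(annotated), nrow(p$calls))
  expect_true(all(annotated$canonical ==
                    (annotated$donor_motif == "GT" &
                       annotated$acceptor_motif == "AG")))
  expect_true(all((annotated$mechanism == "both") ==
                    (annotated$canonical & annotated$shs_len >= 4)))
  expect_true(all(annotated$shs_len == nchar(annotated$shs_seq)))

  s <- mechanism_summary(annotated)
  expect_equal(sum(s$category_proportions), 1, tolerance = 1e-9)
  expect_equal(sum(s$locality_proportions), 1, tolerance = 1e-9)
  expect_equal(sum(s$boundary_proportions), 1, tolerance = 1e-9)
  expect_true(all(diff(s$motif_counts$count) <= 0))
  expect_error(mechanism_summary(annotated[0, ]), "empty")

  # 3 canonical + 1 other toy check
  toy <- annotated[1:4, ]
  toy$mechanism <- c("canonical_splice", "canonical_splice",
                     "canonical_splice", "other")
  expect_equal(unname(mechanism_summary(toy)$category_proportions["canonical_splice"]),
               0.75)
})
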