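test_that("FASTA reading handles wrapping, case and rejects empty records", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "acg", "t", ">b", "NNNN"), f)
  recs <- read_genome_fasta(f)
  expect_equal(recs$id, c("a", "b"))
  expect_equal(recs$sequence, c("ACGT", "NNNN"))

  writeLines(c(">a", "", ">b", "AC"), f)
  expect_error(read_genome_fasta(f), "empty sequence.*'a'")

  writeLines(c(">a", "ACGT", ">a", "GG"), f)
  expect_error(read_genome_fasta(f), "duplicated")
})

test_that("FASTA writing round-trips", {
  f <- withr::local_tempfile(fileext = ".fa")
  seqs <- tibble::tibble(id = c("x", "y"),
                         sequence = c(strrep("ACGTN", 40), "TTTT"))
  write_genome_fasta(seqs, f)
  expect_equal(read_genome_fasta(f), seqs)
})

test_that("GFF3 parsing converts coordinates and orders exons by strand", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t1\t300\t.\t+\t.\tID=g1;description=demo gene",
    "chr1\tsrc\tmRNA\t1\t300\t.\t+\t.\tID=g1.t1;Parent=g1",
    "chr1\tsrc\texon\t1\t100\t.\t+\t.\tID=e1;Parent=g1.t1",
    "chr1\tsrc\texon\t201\t300\t.\t+\t.\tID=e2;Parent=g1.t1",
    "chr1\tsrc\tCDS\t1\t100\t.\t+\t0\tID=c1;Parent=g1.t1",
    "chr1\tsrc\tgene\t1\t300\t.\t-\t.\tID=g2",
    "chr1\tsrc\tmRNA\t1\t300\t.\t-\t.\tID=g2.t1;Parent=g2",
    "chr1\tsrc\texon\t1\t100\t.\t-\t.\tID=e3;Parent=g2.t1",
    "chr1\tsrc\texon\t201\t300\t.\t-\t.\tID=e4;Parent=g2.t1"
  ), f)
  gm <- read_gene_models(f, "sp")
  g1 <- gm[gm$gene_id == "g1", ]
  expect_equal(g1$start, c(0L, 200L))
  expect_equal(g1$end, c(100L, 300L))
  expect_equal(g1$description[1], "demo gene")
  # minus strand: transcription order is descending coordinate
  g2 <- gm[gm$gene_id == "g2", ]
  expect_equal(g2$start[g2$exon_rank == 1], 200L)
  expect_equal(g2$start[g2$exon_rank == 2], 0L)
})

test_that("canonical transcript is the longest total CDS", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t1\t500\t.\t+\t.\tID=g1",
    "chr1\tsrc\tmRNA\t1\t500\t.\t+\t.\tID=g1.tA;Parent=g1",
    "chr1\tsrc\texon\t1\t100\t.\t+\t.\tID=eA;Parent=g1.tA",
    "chr1\tsrc\tCDS\t1\t50\t.\t+\t0\tID=cA;Parent=g1.tA",
    "chr1\tsrc\tmRNA\t1\t500\t.\t+\t.\tID=g1.tB;Parent=g1",
    "chr1\tsrc\texon\t1\t100\t.\t+\t.\tID=eB1;Parent=g1.tB",
    "chr1\tsrc\texon\t201\t500\t.\t+\t.\tID=eB2;Parent=g1.tB",
    "chr1\tsrc\tCDS\t1\t100\t.\t+\t0\tID=cB1;Parent=g1.tB",
    "chr1\tsrc\tCDS\t201\t500\t.\t+\t0\tID=cB2;Parent=g1.tB"
  ), f)
  gm <- read_gene_models(f, "sp")
  expect_equal(unique(gm$transcript_id), "g1.tB")
  expect_equal(nrow(gm), 2L)
})

test_that("exons without a known parent are a format error", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t1\t300\t.\t+\t.\tID=g1",
    "chr1\tsrc\tmRNA\t1\t300\t.\t+\t.\tID=g1.t1;Parent=g1",
    "chr1\tsrc\texon\t1\t100\t.\t+\t.\tID=e1;Parent=nosuch"
  ), f)
  expect_error(read_gene_models(f, "sp"), "unknown transcript")
})

test_that("intron extraction yields transcription-oriented sequences", {
  genome <- tibble::tibble(
    id = "chr1",
    # 0-based: exon1 [0,5), intron [5,12), exon2 [12,20)
    sequence = "ACGTAGGGGGGGTTTCCCAA")
  plus <- tibble::tibble(
    species = "sp", gene_id = "gp", transcript_id = "gp.t1",
    chromosome = "chr1", strand = "+", exon_rank = 1:2,
    start = c(0L, 12L), end = c(5L, 20L), description = "")
  ip <- extract_introns(genome, plus)
  expect_equal(nrow(ip), 1L)
  expect_equal(ip$start, 5L)
  expect_equal(ip$end, 12L)
  expect_equal(ip$length, 7L)
  expect_equal(ip$sequence, "GGGGGGG")
  expect_equal(ip$upstream_exon_seq, "ACGTA")
  expect_equal(ip$downstream_exon_seq, "TTTCCCAA")

  minus <- plus
  minus$strand <- "-"
  minus$start <- c(12L, 0L)   # exon_rank 1 is the high-coordinate exon
  minus$end <- c(20L, 5L)
  im <- extract_introns(genome, minus)
  expect_equal(im$start, 5L)
  expect_equal(im$end, 12L)
  # reverse complement of GGGGGGG is CCCCCCC
  expect_equal(im$sequence, "CCCCCCC")
  expect_equal(im$upstream_exon_seq, "TTGGGAAA")  # revcomp of TTTCCCAA
})

test_that("plus-strand gene and its mirrored minus-strand twin give the same introns", {
  set.seed(11)
  fwd <- random_dna(400)
  genome_f <- tibble::tibble(id = "c", sequence = fwd)
  genome_r <- tibble::tibble(
    id = "c",
    sequence = as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(fwd))))
  ex <- tibble::tibble(
    species = "sp", gene_id = "g", transcript_id = "g.t1",
    chromosome = "c", strand = "+", exon_rank = 1:3,
    start = c(10L, 120L, 300L), end = c(80L, 200L, 390L), description = "")
  L <- 400L
  mir <- ex
  mir$strand <- "-"
  mir$start <- L - ex$end
  mir$end <- L - ex$start
  i_f <- extract_introns(genome_f, ex)
  i_r <- extract_introns(genome_r, mir)
  expect_equal(i_f$sequence, i_r$sequence)
  expect_equal(i_f$upstream_exon_seq, i_r$upstream_exon_seq)
  expect_equal(i_f$downstream_exon_seq, i_r$downstream_exon_seq)
})

test_that("exon+intron lengths add up to the genomic span of each gene", {
  sim <- small_sim()
  for (s in sim$config$species[1:2]) {
    gm <- sim$gene_models[sim$gene_models$species == s, ]
    ints <- extract_introns(sim$genomes[[s]], gm)
    span <- gm |>
      dplyr::group_by(gene_id) |>
      dplyr::summarise(span = max(end) - min(start),
                       exon_total = sum(end - start), .groups = "drop")
    itot <- ints |>
      dplyr::group_by(gene_id) |>
      dplyr::summarise(intron_total = sum(length), .groups = "drop")
    j <- dplyr::inner_join(span, itot, by = "gene_id")
    expect_true(all(j$exon_total + j$intron_total == j$span))
  }
})

test_that("long introns are omitted and counted at the extraction cap", {
  genome <- tibble::tibble(id = "c", sequence = strrep("A", 1200))
  ex <- tibble::tibble(
    species = "sp", gene_id = "g", transcript_id = "g.t1",
    chromosome = "c", strand = "+", exon_rank = 1:3,
    start = c(0L, 510L, 1100L), end = c(10L, 520L, 1120L), description = "")
  res <- extract_introns(genome, ex, max_len = 500L)
  expect_equal(nrow(res), 1L)           # the 580-nt intron is dropped
  expect_equal(res$intron_index, 1L)
  expect_equal(attr(res, "n_over_cap"), 1L)
})

test_that("BLAST tabular parsing is typed and rejects malformed rows", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "q1\tchr1\t100.00\t120\t0\t0\t1\t120\t501\t620\t1e-60\t222",
    "q1\tchr2\t91.50\t118\t10\t0\t1\t118\t70\t187\t2e-40\t180"), f)
  h <- read_blast_hits(f)
  expect_equal(nrow(h), 2L)
  expect_equal(h$subject_id, c("chr1", "chr2"))
  expect_equal(h$evalue, c(1e-60, 2e-40))
  writeLines("q1\tchr1\t100.0", f)
  expect_error(read_blast_hits(f), "line 1.*expected 12")
})

test_that("hit tables round-trip through the outfmt-6 writer", {
  sim <- small_sim()
  f <- withr::local_tempfile(fileext = ".tsv")
  h <- sim$hits[1:50, ]
  write_blast_hits(h, f)
  h2 <- read_blast_hits(f)
  expect_equal(h2$query_id, h$query_id)
  expect_equal(h2$subject_start, h$subject_start)
  expect_equal(h2$evalue, h$evalue, tolerance = 1e-3)
})

test_that("RepeatMasker .out parsing converts coordinates and classes", {
  f <- withr::local_tempfile(fileext = ".out")
  writeLines(c(
    "   SW   perc perc perc  query     position in query    matching repeat",
    "score   div. del. ins.  sequence  begin  end   (left)  repeat  class/family  begin end (left) ID",
    "",
    "  463   11.8  0.0  0.0  chr1      101    190   (1000)  +  AluY  SINE/Alu  1  90  (0)  1",
    "  300   20.0  1.0  0.0  chr2      5      54    (500)   C  L1    LINE/L1   1  50  (0)  2",
    "  120   9.0   0.0  0.0  chr2      400    420   (100)   +  X     Unknown   1  21  (0)  3"
  ), f)
  r <- read_repeatmasker(f)
  expect_equal(r$start, c(100L, 4L, 399L))
  expect_equal(r$end, c(190L, 54L, 420L))
  expect_equal(r$repeat_class, c("SINE", "LINE", "other"))
})

test_that("Newick trees round-trip and malformed input errors", {
  expect_equal(write_tree(read_tree(text = "(A:1,B:2);")), "(A:1,B:2);")
  five <- "(((human:0.007,chimp:0.007):0.02,macaque:0.06):0.03,(cow:0.09,dog:0.08):0.03);"
  tr <- read_tree(text = five)
  tr2 <- read_tree(text = write_tree(tr))
  expect_equal(tr2$tip.label, tr$tip.label)
  expect_equal(tr2$edge.length, tr$edge.length, tolerance = 1e-9)
  expect_error(read_tree(text = "((A:1,B"), "Newick")
  expect_error(read_tree(text = "(A:1,B:-2);"), "negative")
  # branch lengths survive at 1e-9 resolution
  tr$edge.length[1] <- 0.123456789123
  expect_equal(read_tree(text = write_tree(tr))$edge.length[1],
               0.123456789123, tolerance = 1e-12)
})
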