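test_that("read_genome parses, normalises and validates FASTA", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">c1 description", "ACGT", ">c2", "acgu", "nNtT"), fa)
  g <- read_genome(fa)
  expect_named(g, c("c1", "c2"))
  expect_equal(as.character(g[["c1"]]), "ACGT")
  expect_equal(as.character(g[["c2"]]), "ACGTNNTT")

  writeLines(c(">c1", "ACGT", ">c1", "GGGG"), fa)
  expect_error(read_genome(fa), "duplicate")
  writeLines(character(0), fa)
  expect_error(read_genome(fa), "no records")
  writeLines(c(">c1", "ACRT"), fa)
  expect_error(read_genome(fa), "characters outside")
})

test_that("read_gene_models picks the longest CDS transcript, ties by id", {
  fx <- write_fixture(
    c(">c1", paste(rep("ACGT", 30), collapse = "")),
    c(
      gff_feat("c1", "gene", 1, 60, "+", "ID=gA"),
      gff_feat("c1", "mRNA", 1, 30, "+", "ID=tA2;Parent=gA"),
      gff_feat("c1", "CDS", 1, 9, "+", "Parent=tA2", 0),
      gff_feat("c1", "mRNA", 1, 60, "+", "ID=tA1;Parent=gA"),
      gff_feat("c1", "CDS", 1, 15, "+", "Parent=tA1", 0),
      gff_feat("c1", "gene", 61, 90, "+", "ID=gB"),
      gff_feat("c1", "mRNA", 61, 90, "+", "ID=tB2;Parent=gB"),
      gff_feat("c1", "CDS", 61, 72, "+", "Parent=tB2", 0),
      gff_feat("c1", "mRNA", 61, 90, "+", "ID=tB1;Parent=gB"),
      gff_feat("c1", "CDS", 61, 72, "+", "Parent=tB1", 0)
    )
  )
  m <- read_gene_models(fx$gff)
  expect_equal(nrow(m), 2)
  expect_equal(m$transcript_id[m$gene_id == "gA"], "tA1")  # longest CDS
  expect_equal(m$transcript_id[m$gene_id == "gB"], "tB1")  # tie -> smallest id
  segA <- m$cds_segments[[which(m$gene_id == "gA")]]
  expect_equal(unname(segA[, "start"]), 0L)
  expect_equal(unname(segA[, "end"]), 15L)
})

test_that("gene records resolve strand, flank and splicing correctly", {
  # plus-strand gene: CDS at 1..9 (ATG AAA TGA), then 12 nt of flank
  plus_cds <- "ATGAAATGA"
  plus_flank <- "CTATCGAAGCTT"
  # minus-strand gene occupying 31..39 on the plus strand; its upstream-of-
  # start plus-strand region 25..30 is the reverse complement of the flank
  minus_cds_sense <- "ATGCCCTGA"
  minus_flank_sense <- "AAAGCT"
  contig <- paste0(
    plus_cds, plus_flank, "GG",                       # 1..23
    revcomp(minus_flank_sense), "A",                  # 24..30
    revcomp(minus_cds_sense),                         # 31..39
    "AC"
  )
  fx <- write_fixture(
    c(">c1", contig),
    c(
      gff_feat("c1", "gene", 1, 9, "+", "ID=g1"),
      gff_feat("c1", "mRNA", 1, 9, "+", "ID=t1;Parent=g1"),
      gff_feat("c1", "CDS", 1, 9, "+", "Parent=t1", 0),
      gff_feat("c1", "gene", 31, 39, "-", "ID=g2"),
      gff_feat("c1", "mRNA", 31, 39, "-", "ID=t2;Parent=g2"),
      gff_feat("c1", "CDS", 31, 39, "-", "Parent=t2", 0)
    )
  )
  g <- read_genome(fx$fasta)
  m <- read_gene_models(fx$gff)
  rec <- build_gene_records(g, m, flank_len = 12L)

  r1 <- rec[rec$gene_id == "g1", ]
  expect_equal(r1$cds_nt, plus_cds)
  expect_equal(r1$flank_nt, plus_flank)
  expect_equal(r1$flank_source, "genomic")

  r2 <- rec[rec$gene_id == "g2", ]
  expect_equal(r2$cds_nt, minus_cds_sense)
  # flank read 5'->3' in coding sense: revcomp of plus-strand 19..30
  expect_equal(r2$flank_nt, revcomp(substr(contig, 19, 30)))
  expect_equal(substr(r2$flank_nt, 2, 7), minus_flank_sense)
})

test_that("flank is truncated at the contig edge and flagged", {
  fx <- write_fixture(
    c(">c1", "ATGAAATGACGTA"),  # only 4 nt past the stop
    c(
      gff_feat("c1", "gene", 1, 9, "+", "ID=g1"),
      gff_feat("c1", "mRNA", 1, 9, "+", "ID=t1;Parent=g1"),
      gff_feat("c1", "CDS", 1, 9, "+", "Parent=t1", 0)
    )
  )
  rec <- build_gene_records(read_genome(fx$fasta), read_gene_models(fx$gff),
                            flank_len = 300L)
  expect_equal(rec$flank_nt, "CGTA")
  expect_true(rec$flank_truncated)
})

test_that("spliced three_prime_UTR flank wins over the genomic flank", {
  # UTR split across two segments with an intervening intron
  contig <- paste0("ATGAAATGA", "CCC", "GTTTTT", "AAA", "GGGGGG", "T")
  fx <- write_fixture(
    c(">c1", contig),
    c(
      gff_feat("c1", "gene", 1, 9, "+", "ID=g1"),
      gff_feat("c1", "mRNA", 1, 28, "+", "ID=t1;Parent=g1"),
      gff_feat("c1", "CDS", 1, 9, "+", "Parent=t1", 0),
      gff_feat("c1", "three_prime_UTR", 13, 18, "+", "Parent=t1"),
      gff_feat("c1", "three_prime_UTR", 22, 27, "+", "Parent=t1")
    )
  )
  rec <- build_gene_records(read_genome(fx$fasta), read_gene_models(fx$gff))
  expect_equal(rec$flank_source, "spliced_utr")
  expect_equal(rec$flank_nt, "GTTTTTGGGGGG")
})

test_that("malformed CDS models are skipped with a warning and counted", {
  fx <- write_fixture(
    c(">c1", "ATGAAATGAATGAAACCCTTTATGAAATAAGG"),
    c(
      gff_feat("c1", "gene", 1, 9, "+", "ID=good"),
      gff_feat("c1", "mRNA", 1, 9, "+", "ID=t1;Parent=good"),
      gff_feat("c1", "CDS", 1, 9, "+", "Parent=t1", 0),
      gff_feat("c1", "gene", 10, 18, "+", "ID=nostop"),
      gff_feat("c1", "mRNA", 10, 18, "+", "ID=t2;Parent=nostop"),
      gff_feat("c1", "CDS", 10, 18, "+", "Parent=t2", 0),
      gff_feat("c1", "gene", 19, 30, "+", "ID=badlen"),
      gff_feat("c1", "mRNA", 19, 30, "+", "ID=t3;Parent=badlen"),
      gff_feat("c1", "CDS", 19, 29, "+", "Parent=t3", 0)
    )
  )
  g <- read_genome(fx$fasta)
  m <- read_gene_models(fx$gff)
  expect_warning(expect_warning(
    rec <- build_gene_records(g, m),
    "stop codon"
  ), "codon multiple")
  expect_equal(rec$gene_id, "good")
  rs <- attr(rec, "run_summary")
  expect_equal(rs$n_skipped, 2L)
  expect_equal(rs$skip_reasons$no_stop, 1L)
  expect_equal(rs$skip_reasons$bad_length, 1L)
})

test_that("every emitted record ends in a stop codon", {
  sim <- simulate_genome(small_cfg(30, seed = 11))
  rec <- build_gene_records(sim$genome, sim$models)
  stops <- substr(rec$cds_nt, nchar(rec$cds_nt) - 2, nchar(rec$cds_nt))
  expect_true(all(stops %in% c("TAA", "TAG", "TGA")))
})

test_that("records survive genome reverse-complement round trip", {
  sim <- simulate_genome(small_cfg(25, seed = 3))
  rec <- build_gene_records(sim$genome, sim$models, flank_len = 300L)
  flipped <- flip_assembly(sim$genome, sim$models)
  rec2 <- build_gene_records(flipped$genome, flipped$models, flank_len = 300L)
  expect_equal(sort(rec$cds_nt), sort(rec2$cds_nt))
  expect_equal(sort(rec$flank_nt), sort(rec2$flank_nt))
  # same gene keeps the same sequences, coordinates aside
  j <- dplyr::inner_join(rec, rec2, by = "gene_id")
  expect_equal(j$cds_nt.x, j$cds_nt.y)
  expect_equal(j$flank_nt.x, j$flank_nt.y)
})

test_that("candidate TSV output is deterministic and ordered", {
  sim <- simulate_genome(small_cfg(15, seed = 5))
  res <- screen_genome(sim$genome, sim$models)
  f1 <- tempfile(fileext = ".tsv")
  f2 <- tempfile(fileext = ".tsv")
  write_candidates(res, f1)
  write_candidates(screen_genome(sim$genome, sim$models), f2)
  expect_identical(readLines(f1), readLines(f2))
  d <- readr::read_tsv(f1, show_col_types = FALSE)
  expect_equal(nrow(d), 15)
  expect_equal(names(d)[1:4], c("gene_id", "contig", "strand", "stop_codon"))

  empty <- res[0, ]
  f3 <- tempfile(fileext = ".tsv")
  write_candidates(empty, f3)
  expect_length(readLines(f3), 1)  # header only
})
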