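make_entry <- function(group_id, species, gene_id, protein_aa, stop_codon,
                       flank_nt) {
  tibble::tibble(
    group_id = group_id, species = species, gene_id = gene_id,
    protein_aa = protein_aa, stop_codon = stop_codon, flank_nt = flank_nt
  )
}

fixture_group <- function() {
  dplyr::bind_rows(
    make_entry("grp1", "sp_a", "a1", "MAAV", "TGA", "CTATCGAAGCTTTAG"),
    make_entry("grp1", "sp_b", "b1", "MAAV", "TGA", "CTAGCTAGCAAGCTTTGA"),
    make_entry("grp1", "sp_c", "c1", "MAAV", "TGA", "CTTTCGAAGCTTTAA"),
    make_entry("grp1", "sp_d", "d1", "MAVSRL", "TAA", "GGGTTTTGA")
  )
}

test_that("ortholog entries are classified exactly like screened genes", {
  e <- classify_entries(fixture_group())
  expect_equal(
    e$mechanism_class,
    c("readthrough_PTS1", "readthrough_PTS1", "readthrough_PTS1", "in_ORF_PTS1")
  )
  expect_equal(e$pts1_tripeptide[1], "SKL")
  expect_equal(e$orf_terminal_pts1[4], "SRL")

  none <- classify_entries(
    make_entry("g", "sp", "x1", "MAAV", "TAA", "GGGTTTTGA")
  )
  expect_equal(none$mechanism_class, "none")
})

test_that("an empty flank falls back to the ORF terminus", {
  e <- classify_entries(
    make_entry("g", "sp", "x1", "MAVSRL", "TAA", "")
  )
  expect_equal(e$mechanism_class, "in_ORF_PTS1")
  expect_equal(e$ext_status, "open")
  expect_equal(e$ext_len_aa, 0L)
})

test_that("group summaries count mechanisms and core-context conservation", {
  s <- summarize_group(fixture_group())
  expect_equal(s$n_species, 4L)
  expect_equal(s$n_readthrough_PTS1, 3L)
  expect_equal(s$n_in_ORF_PTS1, 1L)
  expect_equal(s$n_none, 0L)
  expect_equal(s$n_readthrough_PTS1 + s$n_in_ORF_PTS1 + s$n_other + s$n_none,
               s$n_species)
  expect_true(s$conserved_core_context)

  single <- summarize_group(fixture_group()[1, ])
  expect_equal(single$n_species, 1L)

  expect_error(summarize_group(fixture_group()[0, ]), "empty")
  mixed <- fixture_group()
  mixed$group_id[2] <- "grp2"
  expect_error(summarize_group(mixed), "more than one group_id")
})

test_that("noncore readthrough breaks core-context conservation", {
  grp <- dplyr::bind_rows(
    make_entry("g", "sp_a", "a1", "MAAV", "TGA", "CTATCGAAGCTTTAG"),
    make_entry("g", "sp_b", "b1", "MAAV", "TAA", "CTATCGAAGCTTTAG")
  )
  s <- grp |>
    classify_entries(context_mode = "any") |>
    summarize_groups()
  expect_equal(s$n_readthrough_PTS1, 1L)
  expect_equal(s$n_other, 1L)
  expect_false(s$conserved_core_context)

  no_rt <- summarize_group(
    make_entry("g", "sp", "x1", "MAAV", "TAA", "GGGTTTTGA")
  )
  expect_true(is.na(no_rt$conserved_core_context))
})

test_that("a species seen twice keeps its best-priority mechanism", {
  grp <- dplyr::bind_rows(
    make_entry("g", "sp_a", "a1", "MAAV", "TAA", "GGGTTTTGA"),
    make_entry("g", "sp_a", "a2", "MAAV", "TGA", "CTATCGAAGCTTTAG")
  )
  s <- summarize_group(grp)
  expect_equal(s$n_species, 1L)
  expect_equal(s$n_readthrough_PTS1, 1L)
  per <- tidy(s)
  expect_equal(per$gene_id, "a2")
})

test_that("groups TSV round-trips and the matrix file carries aggregates", {
  f <- tempfile(fileext = ".tsv")
  readr::write_tsv(fixture_group(), f)
  entries <- read_ortholog_groups(f)
  expect_equal(nrow(entries), 4)

  s <- summarize_groups(classify_entries(entries))
  out <- tempfile(fileext = ".tsv")
  write_conservation(s, out)
  d <- readr::read_tsv(out, show_col_types = FALSE)
  expect_equal(nrow(d), 5)  # 4 species rows + 1 aggregate
  agg <- d[d$species == "*", ]
  expect_equal(agg$n_readthrough_PTS1, 3)
  expect_s3_class(autoplot(s), "ggplot")

  bad <- fixture_group()
  bad$stop_codon[1] <- "TGG"
  readr::write_tsv(bad, f)
  expect_error(read_ortholog_groups(f), "stop_codon")
})

test_that("conservation classification agrees with the genome screen", {
  sim <- simulate_genome(simulate_config(n_genes = 60, seed = 17))
  res <- screen_genome(sim$genome, sim$models)
  entries <- sim_to_entries(sim)
  cls <- classify_entries(entries)
  j <- dplyr::inner_join(
    tidy(res)[, c("gene_id", "mechanism_class")],
    cls[, c("gene_id", "mechanism_class")],
    by = "gene_id", suffix = c(".screen", ".cons")
  )
  expect_equal(nrow(j), 60)
  expect_equal(j$mechanism_class.screen, j$mechanism_class.cons)
})
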