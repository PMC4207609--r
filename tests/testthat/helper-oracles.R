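# Independent oracles and small fixture builders shared across tests.

AA20 <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

# every tripeptide over the 20-letter alphabet
all_tripeptides <- function() {
  g <- expand.grid(AA20, AA20, AA20, stringsAsFactors = FALSE)
  paste0(g[[3]], g[[2]], g[[1]])
}

# the published motif pattern, written out verbatim rather than assembled,
# so the test route is independent of pts1_regex()
verbatim_pts1_pattern <- function() {
  "(^\\*[^*]*?([ASTPCE]RL|[SATPCVNG]KL|S[SNH]L|ARI|S[KR]M|[AG]NL|SN[IM]|[SA][KRQ]Y|HHL|[QS][KRQ]F)\\*)"
}

# brute-force first-in-frame-stop scanner (independent of call_extension)
oracle_first_stop_codons <- function(flank) {
  n <- nchar(flank) %/% 3
  i <- 0L
  while (i < n) {
    codon <- substr(flank, 3 * i + 1, 3 * i + 3)
    if (codon %in% c("TAA", "TAG", "TGA")) return(i)
    i <- i + 1L
  }
  NA_integer_
}

random_dna <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a gene-record row shaped like build_gene_records() output
make_record <- function(gene_id, cds_nt, flank_nt, strand = "+",
                        contig = "c1", tx_start = 0L,
                        flank_source = "genomic") {
  tibble::tibble(
    gene_id = gene_id, contig = contig, strand = strand,
    tx_start = tx_start, cds_nt = cds_nt, flank_nt = flank_nt,
    flank_source = flank_source, flank_truncated = FALSE
  )
}

# write FASTA/GFF3 text fixtures and return their paths
write_fixture <- function(fasta_lines, gff_lines) {
  fa <- tempfile(fileext = ".fa")
  gff <- tempfile(fileext = ".gff3")
  writeLines(fasta_lines, fa)
  writeLines(c("##gff-version 3", gff_lines), gff)
  list(fasta = fa, gff = gff)
}

gff_feat <- function(contig, type, start, end, strand, attrs, phase = ".") {
  paste(contig, "test", type, start, end, ".", strand, phase, attrs, sep = "\t")
}

# convert a simulation's screened records into ortholog-entry form
sim_to_entries <- function(sim, flank_len = 600L) {
  rec <- build_gene_records(sim$genome, sim$models, flank_len = flank_len)
  tibble::tibble(
    group_id = rec$gene_id,
    species = "simulated",
    gene_id = rec$gene_id,
    protein_aa = translate_dna(substr(rec$cds_nt, 1, nchar(rec$cds_nt) - 3L)),
    stop_codon = substr(rec$cds_nt, nchar(rec$cds_nt) - 2L, nchar(rec$cds_nt)),
    flank_nt = rec$flank_nt
  )
}

# compact simulation config for fast tests
small_cfg <- function(n_genes, seed, planted = 3L, decoy = 2L, ...) {
  simulate_config(
    n_genes = n_genes, n_planted_readthrough_pts1 = planted,
    n_decoy_context_only = decoy, n_decoy_pts1_wrong_stop = decoy,
    n_decoy_in_orf_pts1 = decoy, seed = seed, ...
  )
}
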