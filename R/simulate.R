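NUC <- c("A", "C", "G", "T")

sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

# sense codons per amino acid, for encoding a prescribed peptide
codons_for <- function(aa) {
  gc <- Biostrings::GENETIC_CODE
  lapply(setNames(aa, aa), function(a) names(gc)[gc == a])
}

#' Configuration for the synthetic-genome generator
#'
#' Defines the composition of a simulated screen: background protein-coding
#' genes plus planted readthrough-PTS1 genes and three decoy classes
#' (core TGA-CT context without PTS1; PTS1-bearing extension behind a
#' non-TGA stop; PTS1 at the regular ORF terminus). All lengths are sampled
#' uniformly from the given ranges.
#'
#' @param n_genes Total genes.
#' @param n_planted_readthrough_pts1 Genes with TGA stop, +1..+3 = CTA, and
#'   an extension ending in a PTS1 tripeptide.
#' @param n_decoy_context_only Genes with TGA-CT context but a PTS1-free
#'   extension.
#' @param n_decoy_pts1_wrong_stop Genes with a PTS1-bearing extension behind
#'   a TAA/TAG stop.
#' @param n_decoy_in_orf_pts1 Genes whose regular ORF ends in a PTS1
#'   tripeptide.
#' @param cds_len_range CDS length range in codons (including start and
#'   stop).
#' @param ext_len_range Planted/decoy extension length range in codons.
#' @param intergenic_len_range Intergenic spacer length range in nt (must
#'   accommodate the longest extension plus its stop).
#' @param minus_strand_fraction Fraction of genes placed on the minus
#'   strand.
#' @param seed Integer seed; identical configs generate byte-identical
#'   output.
#' @return A `sim_config` list.
#' @export
simulate_config <- function(n_genes = 200L,
                            n_planted_readthrough_pts1 = 10L,
                            n_decoy_context_only = 10L,
                            n_decoy_pts1_wrong_stop = 10L,
                            n_decoy_in_orf_pts1 = 10L,
                            cds_len_range = c(100L, 300L),
                            ext_len_range = c(5L, 30L),
                            intergenic_len_range = c(200L, 400L),
                            minus_strand_fraction = 0.5,
                            seed = 42L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    n_planted_readthrough_pts1 = as.integer(n_planted_readthrough_pts1),
    n_decoy_context_only = as.integer(n_decoy_context_only),
    n_decoy_pts1_wrong_stop = as.integer(n_decoy_pts1_wrong_stop),
    n_decoy_in_orf_pts1 = as.integer(n_decoy_in_orf_pts1),
    cds_len_range = as.integer(cds_len_range),
    ext_len_range = as.integer(ext_len_range),
    intergenic_len_range = as.integer(intergenic_len_range),
    minus_strand_fraction = minus_strand_fraction,
    seed = as.integer(seed)
  )
  n_special <- cfg$n_planted_readthrough_pts1 + cfg$n_decoy_context_only +
    cfg$n_decoy_pts1_wrong_stop + cfg$n_decoy_in_orf_pts1
  if (n_special > cfg$n_genes) {
    abort("planted + decoy genes exceed n_genes")
  }
  if (any(c(cfg$cds_len_range, cfg$intergenic_len_range) <= 0) ||
      any(diff(cfg$cds_len_range) < 0, diff(cfg$ext_len_range) < 0,
          diff(cfg$intergenic_len_range) < 0)) {
    abort("length ranges must be positive and non-decreasing")
  }
  if (cfg$cds_len_range[1] < 4) abort("cds_len_range minimum must be >= 4 codons")
  needs_ext <- cfg$n_planted_readthrough_pts1 + cfg$n_decoy_pts1_wrong_stop
  if (needs_ext > 0 && cfg$ext_len_range[2] < 4) {
    abort("ext_len_range too short to carry a PTS1 extension (need >= 4 codons)")
  }
  if (cfg$intergenic_len_range[1] < 3 * cfg$ext_len_range[2] + 3) {
    abort("intergenic_len_range minimum must exceed the longest extension + stop")
  }
  if (cfg$minus_strand_fraction < 0 || cfg$minus_strand_fraction > 1) {
    abort("minus_strand_fraction must lie in [0, 1]")
  }
  structure(cfg, class = "sim_config")
}

with_preserved_rng <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  force(code)
}

#' Simulate a genome with planted readthrough-PTS1 structure
#'
#' Generates an annotated single-contig genome in which every gene's truth
#' class is known. Background genes are random sense codons; their 3'
#' regions are rejection-sampled so that no background gene carries a core
#' TGA-CT context, a PTS1-terminated extension, or an in-ORF PTS1 — the
#' background contributes zero positives by construction, which makes exact
#' planted-truth recovery testable. Planted genes get a TGA stop followed by
#' CTA and an extension ending in a PTS1 tripeptide drawn uniformly from
#' [pts1_tripeptide_set()]; decoys carry exactly one signal each.
#'
#' @param config A `sim_config` from [simulate_config()].
#' @return A list of class `rt_simulation`: `genome` (DNAStringSet),
#'   `models` (gene-model tibble as from [read_gene_models()]), `truth`
#'   (tibble: `gene_id`, `planted_class`, `planted_tripeptide`), and
#'   `config`.
#' @export
simulate_genome <- function(config = simulate_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_preserved_rng(config$seed, {
    sense <- sense_codons()
    pts1 <- pts1_tripeptide_set()
    by_aa <- codons_for(c(LETTERS[LETTERS %in% Biostrings::GENETIC_CODE]))
    rand_codons <- function(n) {
      if (n <= 0) character(0) else sample(sense, n, replace = TRUE)
    }
    rand_nt <- function(n) {
      if (n <= 0) "" else paste0(sample(NUC, n, replace = TRUE), collapse = "")
    }
    rsample <- function(v) v[sample.int(length(v), 1)]  # safe for length 1
    encode_peptide <- function(aa) {
      vapply(strsplit(aa, "")[[1]],
             function(a) rsample(by_aa[[a]]), character(1))
    }
    rint <- function(range) rsample(seq(range[1], range[2]))

    classes <- c(
      rep("readthrough_PTS1", config$n_planted_readthrough_pts1),
      rep("context_only", config$n_decoy_context_only),
      rep("pts1_wrong_stop", config$n_decoy_pts1_wrong_stop),
      rep("in_orf_pts1", config$n_decoy_in_orf_pts1)
    )
    classes <- c(classes, rep("background", config$n_genes - length(classes)))
    if (length(classes) > 1) classes <- sample(classes)
    strands <- ifelse(
      stats::runif(config$n_genes) < config$minus_strand_fraction, "-", "+"
    )

    last_tri <- function(codons) {
      translate_dna(paste0(utils::tail(codons, 3), collapse = ""))
    }

    make_gene <- function(cls) {
      n_cds <- rint(config$cds_len_range)
      tri <- NA_character_
      # body: start codon + random sense codons; reject accidental in-ORF PTS1
      repeat {
        body <- c("ATG", rand_codons(n_cds - 2L))
        if (cls == "in_orf_pts1") {
          tri <- sample(pts1, 1)
          body[(length(body) - 2):length(body)] <- encode_peptide(tri)
          break
        }
        if (!(last_tri(body) %in% pts1)) break
      }
      # stop codon + extension region + terminal stop, per class
      repeat {
        if (cls == "readthrough_PTS1") {
          stop1 <- "TGA"
          tri <- sample(pts1, 1)
          n_ext <- max(rint(config$ext_len_range), 4L)
          mid <- translate_dna(paste0(rand_codons(n_ext - 4L), collapse = ""))
          ext <- c("CTA", encode_peptide(paste0(mid, tri)))
        } else if (cls == "pts1_wrong_stop") {
          stop1 <- sample(c("TAA", "TAG"), 1)
          tri <- sample(pts1, 1)
          n_ext <- max(rint(config$ext_len_range), 4L)
          mid <- translate_dna(paste0(rand_codons(n_ext - 4L), collapse = ""))
          ext <- c("CTA", encode_peptide(paste0(mid, tri)))
        } else if (cls == "context_only") {
          stop1 <- "TGA"
          ext <- c(paste0("CT", sample(NUC, 1)), rand_codons(rint(config$ext_len_range) - 1L))
          if (length(ext) >= 3 && last_tri(ext) %in% pts1) next
        } else { # background / in_orf_pts1: clean 3' region
          stop1 <- sample(STOP_CODONS, 1)
          ext <- rand_codons(rsample(0:config$ext_len_range[2]))
          first2 <- if (length(ext)) substr(ext[1], 1, 2) else ""
          if (stop1 == "TGA" && first2 == "CT") next
          if (length(ext) >= 3 && last_tri(ext) %in% pts1) next
        }
        break
      }
      stop2 <- sample(STOP_CODONS, 1)
      ext_nt <- paste0(ext, collapse = "")
      spacer_len <- max(rint(config$intergenic_len_range), nchar(ext_nt) + 3L)
      spacer <- paste0(ext_nt, stop2,
                       rand_nt(spacer_len - nchar(ext_nt) - 3L))
      list(
        cds = paste0(paste0(body, collapse = ""), stop1),
        spacer = spacer,
        tripeptide = tri
      )
    }

    genes <- lapply(classes, make_gene)
    ids <- sprintf("gene%04d", seq_len(config$n_genes))
    contig <- "chr_sim"

    pieces <- character(0)
    pos <- nchar(lead <- rand_nt(50L))  # leading pad
    pieces <- lead
    rows <- vector("list", config$n_genes)
    for (i in seq_len(config$n_genes)) {
      g <- genes[[i]]
      unit <- paste0(g$cds, g$spacer)
      cds_len <- nchar(g$cds)
      sp_len <- nchar(g$spacer)
      if (strands[i] == "+") {
        seg <- cbind(start = pos, end = pos + cds_len)
        pieces <- c(pieces, unit)
      } else {
        seg <- cbind(start = pos + sp_len, end = pos + sp_len + cds_len)
        pieces <- c(pieces, revcomp(unit))
      }
      rows[[i]] <- tibble(
        gene_id = ids[i],
        transcript_id = paste0(ids[i], ".t1"),
        contig = contig,
        strand = strands[i],
        cds_segments = list(seg),
        utr3_segments = list(NULL)
      )
      pos <- pos + nchar(unit)
    }
    pieces <- c(pieces, rand_nt(50L))  # trailing pad
    genome <- setNames(
      Biostrings::DNAStringSet(paste0(pieces, collapse = "")), contig
    )
    truth <- tibble(
      gene_id = ids,
      planted_class = classes,
      planted_tripeptide = vapply(genes, function(g) g$tripeptide, character(1))
    )
    structure(
      list(
        genome = genome,
        models = bind_rows(rows),
        truth = truth,
        config = config
      ),
      class = "rt_simulation"
    )
  })
}

#' Write a simulation to FASTA + GFF3 + truth TSV
#'
#' Emits `<prefix>.fa`, `<prefix>.gff3` and `<prefix>_truth.tsv`. Output is
#' byte-identical for identical configs.
#'
#' @param sim An `rt_simulation` from [simulate_genome()].
#' @param out_prefix Path prefix for the three files.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_simulation <- function(sim, out_prefix) {
  stopifnot(inherits(sim, "rt_simulation"))
  fa <- paste0(out_prefix, ".fa")
  gff <- paste0(out_prefix, ".gff3")
  truth <- paste0(out_prefix, "_truth.tsv")

  lines <- unlist(lapply(names(sim$genome), function(id) {
    s <- as.character(sim$genome[[id]])
    c(paste0(">", id),
      substring(s, seq(1, nchar(s), 70), pmin(seq(70, nchar(s) + 69, 70), nchar(s))))
  }))
  writeLines(lines, fa)

  gff_lines <- c("##gff-version 3")
  for (i in seq_len(nrow(sim$models))) {
    m <- sim$models[i, ]
    seg <- m$cds_segments[[1]]
    lo <- min(seg[, "start"]) + 1L  # back to 1-based inclusive
    hi <- max(seg[, "end"])
    f <- function(type, attrs) {
      paste(m$contig, "rtscreen_sim", type, lo, hi, ".", m$strand,
            if (type == "CDS") "0" else ".", attrs, sep = "\t")
    }
    gff_lines <- c(
      gff_lines,
      f("gene", paste0("ID=", m$gene_id)),
      f("mRNA", paste0("ID=", m$transcript_id, ";Parent=", m$gene_id)),
      f("CDS", paste0("ID=cds.", m$transcript_id, ";Parent=", m$transcript_id))
    )
  }
  writeLines(gff_lines, gff)
  readr::write_tsv(sim$truth, truth, na = "")
  invisible(c(fasta = fa, gff3 = gff, truth = truth))
}
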