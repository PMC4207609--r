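#' Read a genome FASTA into a DNAStringSet
#'
#' Loads a (multi-)FASTA file, uppercases all sequences and converts RNA `U`
#' to `T`. Only the characters `A`, `C`, `G`, `T`, `N` are accepted after
#' normalisation.
#'
#' @param path Path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet], one element per contig.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">c1", "acgu"), fa)
#' read_genome(fa)
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path))
  }
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0) {
    abort(paste0("FASTA file contains no records: ", path))
  }
  ids <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(ids)) {
    abort(paste0(
      "duplicate contig id(s) in FASTA: ",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    ))
  }
  seqs <- toupper(as.character(raw))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  if (any(nchar(seqs) == 0)) {
    abort("FASTA contains empty sequence record(s)")
  }
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    abort(paste0(
      "contig(s) contain characters outside {A,C,G,T,N,U}: ",
      paste(ids[bad], collapse = ", ")
    ))
  }
  setNames(Biostrings::DNAStringSet(seqs), ids)
}

#' Read gene models from a GFF3 file
#'
#' Parses gene/mRNA/CDS (and optional three_prime_UTR) features and returns
#' one model per gene. When a gene has several mRNAs, the transcript with the
#' longest total CDS is kept; ties are broken by the lexicographically
#' smallest transcript id. Coordinates are converted once from GFF3 1-based
#' inclusive to 0-based half-open.
#'
#' @param path Path to a GFF3 file.
#' @return A tibble with columns `gene_id`, `transcript_id`, `contig`,
#'   `strand`, and list-columns `cds_segments` / `utr3_segments`, each a
#'   two-column integer matrix (`start`, `end`; 0-based half-open) with rows
#'   in transcription order.
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("GFF3 file not found: ", path))
  }
  gr <- rtracklayer::import(path, format = "gff3")
  df <- tibble(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start0 = GenomicRanges::start(gr) - 1L,
    end0 = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    id = as.character(gr$ID),
    parent = vapply(
      as.list(gr$Parent),
      function(p) if (length(p)) p[[1]] else NA_character_,
      character(1)
    )
  )

  mrna <- df |> filter(.data$type %in% c("mRNA", "transcript"))
  if (nrow(mrna) == 0) {
    abort("GFF3 contains no mRNA/transcript features")
  }
  segs <- df |>
    filter(.data$type %in% c("CDS", "three_prime_UTR"), !is.na(.data$parent))

  models <- segs |>
    filter(.data$parent %in% mrna$id) |>
    left_join(
      mrna |> select(transcript_id = "id", gene_id = "parent"),
      by = c(parent = "transcript_id"),
      keep = TRUE
    ) |>
    mutate(gene_id = coalesce(.data$gene_id, .data$parent)) |>
    group_by(.data$transcript_id) |>
    group_modify(function(d, key) {
      cds <- d |> filter(.data$type == "CDS") |> arrange(.data$start0)
      utr <- d |> filter(.data$type == "three_prime_UTR") |> arrange(.data$start0)
      minus <- cds$strand[1] == "-"
      seg_mat <- function(x) {
        if (nrow(x) == 0) return(NULL)
        m <- cbind(start = x$start0, end = x$end0)
        if (minus) m[rev(seq_len(nrow(m))), , drop = FALSE] else m
      }
      tibble(
        gene_id = d$gene_id[1],
        contig = cds$contig[1],
        strand = cds$strand[1],
        cds_len = sum(cds$end0 - cds$start0),
        cds_segments = list(seg_mat(cds)),
        utr3_segments = list(seg_mat(utr))
      )
    }) |>
    ungroup()

  models |>
    group_by(.data$gene_id) |>
    arrange(desc(.data$cds_len), .data$transcript_id, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    select(
      "gene_id", "transcript_id", "contig", "strand",
      "cds_segments", "utr3_segments"
    ) |>
    arrange(.data$contig, map_int(.data$cds_segments, ~ min(.x[, "start"])))
}

# Spliced sequence of 0-based half-open segments, in reading orientation.
# Segments arrive in transcription order; on the minus strand each segment is
# extracted from the plus strand and the concatenation is reverse-complemented
# segment-wise in that order.
splice_segments <- function(contig_seq, segments, strand) {
  pieces <- vapply(seq_len(nrow(segments)), function(i) {
    s <- segments[i, "start"]
    e <- segments[i, "end"]
    p <- as.character(Biostrings::subseq(contig_seq, start = s + 1L, end = e))
    if (strand == "-") revcomp(p) else p
  }, character(1))
  paste0(pieces, collapse = "")
}

#' Reverse-complement a DNA string
#'
#' @param x Character vector of DNA strings (`A`/`C`/`G`/`T`/`N`).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Assemble strand-resolved gene records with 3' flanks
#'
#' For every gene model, extracts the CDS (stop codon included) and the
#' downstream flank, both in reading orientation (minus-strand genes are
#' reverse-complemented). If the model carries `three_prime_UTR` segments the
#' flank is their spliced concatenation (`flank_source = "spliced_utr"`);
#' otherwise the unspliced genomic sequence downstream of the stop codon is
#' used (`flank_source = "genomic"`), truncated at the contig edge.
#'
#' Genes whose CDS length is not a multiple of 3 or does not end in a stop
#' codon are skipped with a warning; skip counts are attached as the
#' `run_summary` attribute.
#'
#' @param genome A [Biostrings::DNAStringSet] from [read_genome()].
#' @param models Gene-model tibble from [read_gene_models()].
#' @param flank_len Genomic flank length in nt (default 600).
#' @return A tibble with one row per well-formed gene: `gene_id`, `contig`,
#'   `strand`, `tx_start` (0-based contig start, for deterministic ordering),
#'   `cds_nt`, `flank_nt`, `flank_source`, `flank_truncated`.
#' @export
build_gene_records <- function(genome, models, flank_len = 600L) {
  stopifnot(flank_len >= 3)
  missing_contigs <- setdiff(unique(models$contig), names(genome))
  if (length(missing_contigs)) {
    abort(paste0(
      "gene model contig(s) absent from genome: ",
      paste(missing_contigs, collapse = ", ")
    ))
  }

  skip <- c(bad_length = 0L, no_stop = 0L)
  rows <- map(seq_len(nrow(models)), function(i) {
    m <- models[i, ]
    contig_seq <- genome[[m$contig]]
    clen <- length(contig_seq)
    cds <- m$cds_segments[[1]]
    cds_nt <- splice_segments(contig_seq, cds, m$strand)
    if (nchar(cds_nt) %% 3 != 0 || nchar(cds_nt) < 6) {
      skip["bad_length"] <<- skip["bad_length"] + 1L
      warn(paste0("skipping ", m$gene_id, ": CDS length not a codon multiple"))
      return(NULL)
    }
    stop_codon <- substr(cds_nt, nchar(cds_nt) - 2L, nchar(cds_nt))
    if (!stop_codon %in% STOP_CODONS) {
      skip["no_stop"] <<- skip["no_stop"] + 1L
      warn(paste0("skipping ", m$gene_id, ": CDS does not end in a stop codon"))
      return(NULL)
    }

    utr <- m$utr3_segments[[1]]
    truncated <- FALSE
    if (!is.null(utr) && nrow(utr) > 0) {
      flank_nt <- splice_segments(contig_seq, utr, m$strand)
      flank_source <- "spliced_utr"
    } else {
      if (m$strand == "+") {
        from <- max(cds[, "end"])
        to <- min(from + flank_len, clen)
        truncated <- to - from < flank_len
        flank_nt <- if (to > from) {
          as.character(Biostrings::subseq(contig_seq, from + 1L, to))
        } else ""
      } else {
        to <- min(cds[, "start"])
        from <- max(to - flank_len, 0L)
        truncated <- to - from < flank_len
        flank_nt <- if (to > from) {
          revcomp(as.character(Biostrings::subseq(contig_seq, from + 1L, to)))
        } else ""
      }
      flank_source <- "genomic"
    }

    tibble(
      gene_id = m$gene_id,
      contig = m$contig,
      strand = m$strand,
      tx_start = min(cds[, "start"]),
      cds_nt = cds_nt,
      flank_nt = flank_nt,
      flank_source = flank_source,
      flank_truncated = truncated
    )
  })
  out <- bind_rows(rows) |> arrange(.data$contig, .data$tx_start)
  attr(out, "run_summary") <- list(
    n_models = nrow(models),
    n_records = nrow(out),
    n_skipped = sum(skip),
    skip_reasons = as.list(skip)
  )
  out
}

#' Write a candidate report table to TSV
#'
#' Emits the fixed screen-report columns in a deterministic order (reports
#' are already sorted by contig then transcript start by [screen_genome()]).
#' Re-running on identical input produces a byte-identical file.
#'
#' @param reports Screen-report tibble from [screen_genome()] or
#'   [screen_records()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(reports, path) {
  cols <- c(
    "gene_id", "contig", "strand", "stop_codon", "context_plus1_4",
    "context_core_pass", "plus3_A", "plus4_G", "ext_status", "ext_len_aa",
    "ext_peptide", "pts1_hit", "pts1_tripeptide", "orf_terminal_pts1",
    "mechanism_class", "flank_source"
  )
  missing <- setdiff(cols, names(reports))
  if (length(missing)) {
    abort(paste0("report is missing column(s): ", paste(missing, collapse = ", ")))
  }
  readr::write_tsv(reports[, cols], path, na = "")
  invisible(path)
}

#' Reverse-complement an assembly and flip annotation strands
#'
#' Utility for strand-invariance checks: every contig is reverse-complemented
#' and every gene model's strand and coordinates are mirrored, so the encoded
#' genes are unchanged in the coding sense.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param models Gene-model tibble from [read_gene_models()].
#' @return A list with elements `genome` and `models`.
#' @export
flip_assembly <- function(genome, models) {
  lens <- setNames(Biostrings::width(genome), names(genome))
  flip_segs <- function(segs, L) {
    if (is.null(segs)) return(NULL)
    m <- cbind(start = L - segs[, "end"], end = L - segs[, "start"])
    m[rev(seq_len(nrow(m))), , drop = FALSE]
  }
  models2 <- models |>
    mutate(
      cds_segments = map2_(.data$cds_segments, lens[.data$contig], flip_segs),
      utr3_segments = map2_(.data$utr3_segments, lens[.data$contig], flip_segs),
      strand = ifelse(.data$strand == "+", "-", "+")
    )
  list(genome = Biostrings::reverseComplement(genome), models = models2)
}

map2_ <- function(x, y, f) map(seq_along(x), function(i) f(x[[i]], y[[i]]))
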