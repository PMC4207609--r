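MECHANISM_LEVELS <- c(
  "readthrough_PTS1", "in_ORF_PTS1", "readthrough_PTS1_noncore_context",
  "PTS2", "none"
)

# Shared classifier behind both the genome screen and the conservation stage.
# Takes per-gene stop codon, downstream flank and regular-ORF protein, runs
# extension calling + context classification + PTS1/PTS2 scanning, and
# assigns the mechanism class by fixed priority:
# readthrough_PTS1 > in_ORF_PTS1 > readthrough_PTS1_noncore_context > PTS2 > none.
rt_classify <- function(stop_codon, flank_nt, protein_aa,
                        max_ext_nt = 600L, context_mode = c("tga-ct", "any"),
                        include_pts2 = FALSE, pts2_window = 40L) {
  context_mode <- match.arg(context_mode)
  ext <- call_extension(flank_nt, max_ext_nt = max_ext_nt)
  ctx <- classify_context(stop_codon, flank_nt)
  p1 <- scan_extension_pts1(ext$ext_aa, ext$status)
  orf <- scan_orf_terminal_pts1(protein_aa)
  p2 <- if (include_pts2) {
    scan_pts2(protein_aa, window = pts2_window)
  } else {
    tibble(
      pts2_nonapeptide = rep(NA_character_, nrow(ext)),
      pts2_offset = rep(NA_integer_, nrow(ext))
    )
  }

  has_ext_pts1 <- !is.na(p1$pts1_tripeptide)
  mechanism <- case_when(
    ctx$core_pass & has_ext_pts1 ~ "readthrough_PTS1",
    !is.na(orf$orf_terminal_pts1) ~ "in_ORF_PTS1",
    context_mode == "any" & has_ext_pts1 ~ "readthrough_PTS1_noncore_context",
    include_pts2 & !is.na(p2$pts2_nonapeptide) ~ "PTS2",
    .default = "none"
  )

  tibble(
    stop_codon = ctx$stop_codon,
    context_plus1_4 = substr(flank_nt, 1, 4),
    context_core_pass = ctx$core_pass,
    plus3_A = ctx$plus3_A,
    plus4_G = ctx$plus4_G,
    ext_status = ext$status,
    ext_len_aa = ext$ext_len_aa,
    ext_peptide = ext$ext_aa,
    ext_terminal_stop = ext$terminal_stop,
    pts1_hit = p1$pts1_hit,
    pts1_tripeptide = p1$pts1_tripeptide,
    orf_terminal_pts1 = orf$orf_terminal_pts1,
    pts2_nonapeptide = p2$pts2_nonapeptide,
    mechanism_class = mechanism
  )
}

#' Screen assembled gene records for readthrough-derived PTS1 isoforms
#'
#' For every gene record, calls the in-frame extension from the 3' flank,
#' classifies the stop codon context against the leaky TGA-CT element, scans
#' the translated extension for a terminal PTS1, checks the regular ORF
#' terminus for an in-ORF PTS1, and assigns a mechanism class. All genes are
#' reported (not only TGA-CT hits) so downstream conservation analysis sees
#' the non-readthrough mechanisms of the same loci; filter on
#' `mechanism_class` or `context_core_pass` as needed.
#'
#' Under `context_mode = "tga-ct"` (the screen's inclusion filter) a
#' PTS1-bearing extension behind a non-core context is not called a
#' readthrough candidate; under `"any"` it is reported as
#' `readthrough_PTS1_noncore_context`.
#'
#' @param records Gene-record tibble from [build_gene_records()].
#' @param max_ext_nt Maximum extension length in nt (default 600).
#' @param context_mode `"tga-ct"` (default) or `"any"`.
#' @param include_pts2 Also run the approximate PTS2 consensus scan
#'   (default `FALSE`).
#' @param pts2_window N-terminal window for the PTS2 scan.
#' @return A tibble of class `rt_screen`, one row per gene, sorted by contig
#'   then transcript start, with the report columns written by
#'   [write_candidates()]. A `run_summary` attribute carries scan and
#'   mechanism tallies.
#' @export
screen_records <- function(records, max_ext_nt = 600L,
                           context_mode = c("tga-ct", "any"),
                           include_pts2 = FALSE, pts2_window = 40L) {
  context_mode <- match.arg(context_mode)
  if (nrow(records) == 0) {
    abort("no gene records to screen (all models skipped?)")
  }
  protein_aa <- translate_dna(
    substr(records$cds_nt, 1, nchar(records$cds_nt) - 3L)
  )
  cls <- rt_classify(
    stop_codon = substr(
      records$cds_nt, nchar(records$cds_nt) - 2L, nchar(records$cds_nt)
    ),
    flank_nt = records$flank_nt,
    protein_aa = protein_aa,
    max_ext_nt = max_ext_nt,
    context_mode = context_mode,
    include_pts2 = include_pts2,
    pts2_window = pts2_window
  )
  out <- bind_cols(
    records |> select("gene_id", "contig", "strand", "tx_start", "flank_source"),
    cls
  ) |>
    arrange(.data$contig, .data$tx_start) |>
    relocate("flank_source", .after = last_col())

  rs <- attr(records, "run_summary")
  attr(out, "run_summary") <- c(
    rs[c("n_models", "n_skipped", "skip_reasons")],
    list(
      n_screened = nrow(out),
      context_mode = context_mode,
      mechanism_tally = as.list(table(
        factor(out$mechanism_class, levels = MECHANISM_LEVELS)
      ))
    )
  )
  class(out) <- c("rt_screen", class(out))
  out
}

#' Screen a genome end-to-end
#'
#' Convenience wrapper: [build_gene_records()] then [screen_records()].
#'
#' @inheritParams build_gene_records
#' @inheritParams screen_records
#' @return An `rt_screen` tibble; see [screen_records()].
#' @examples
#' sim <- simulate_genome(simulate_config(
#'   n_genes = 20, n_planted_readthrough_pts1 = 2, n_decoy_context_only = 2,
#'   n_decoy_pts1_wrong_stop = 2, n_decoy_in_orf_pts1 = 2, seed = 1
#' ))
#' res <- screen_genome(sim$genome, sim$models)
#' dplyr::count(res, mechanism_class)
#' @export
screen_genome <- function(genome, models, flank_len = 600L, max_ext_nt = 600L,
                          context_mode = c("tga-ct", "any"),
                          include_pts2 = FALSE, pts2_window = 40L) {
  if (flank_len < max_ext_nt) {
    warn("flank_len shorter than max_ext_nt: long extensions may be left open")
  }
  records <- build_gene_records(genome, models, flank_len = flank_len)
  screen_records(
    records, max_ext_nt = max_ext_nt, context_mode = context_mode,
    include_pts2 = include_pts2, pts2_window = pts2_window
  )
}

#' @export
print.rt_screen <- function(x, ...) {
  rs <- attr(x, "run_summary")
  cat("<rt_screen> ", nrow(x), " genes screened",
      if (!is.null(rs$n_skipped) && rs$n_skipped > 0) {
        paste0(" (", rs$n_skipped, " models skipped)")
      } else "",
      "\n", sep = "")
  tally <- table(factor(x$mechanism_class, levels = MECHANISM_LEVELS))
  for (m in names(tally)) {
    if (tally[[m]] > 0) cat("  ", format(m, width = 34), tally[[m]], "\n")
  }
  NextMethod()
}
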