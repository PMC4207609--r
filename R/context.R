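#' Classify a stop codon context against the leaky readthrough element
#'
#' Efficient translational readthrough requires a TGA stop codon immediately
#' followed by the dinucleotide CT (the core element); an A at position +3
#' and a G at +4 further weaken termination and are reported as enhancer
#' flags, not filters. TAA and TAG stops terminate more tightly and never
#' pass the core filter.
#'
#' @param stop_codon Character vector of stop codons (`TAA`/`TAG`/`TGA`).
#' @param downstream Character vector of downstream nucleotides (0 nt or
#'   more); positions missing from a short flank yield `NA` and `FALSE`
#'   flags.
#' @return A tibble with one row per input: `stop_codon`, `plus1_2`,
#'   `plus3`, `plus4`, `core_pass`, `plus3_A`, `plus4_G`.
#' @examples
#' classify_context("TGA", "CTAG") # core_pass, plus3_A, plus4_G all TRUE
#' classify_context("TAA", "CTA")  # core_pass FALSE
#' @export
classify_context <- function(stop_codon, downstream) {
  if (!all(stop_codon %in% STOP_CODONS)) {
    abort("stop_codon must be one of TAA, TAG, TGA")
  }
  n <- max(length(stop_codon), length(downstream))
  stop_codon <- rep_len(stop_codon, n)
  downstream <- rep_len(downstream, n)
  plus1_2 <- ifelse(nchar(downstream) >= 2, substr(downstream, 1, 2), NA)
  plus3 <- ifelse(nchar(downstream) >= 3, substr(downstream, 3, 3), NA)
  plus4 <- ifelse(nchar(downstream) >= 4, substr(downstream, 4, 4), NA)
  core <- stop_codon == "TGA" & !is.na(plus1_2) & plus1_2 == "CT"
  tibble(
    stop_codon = stop_codon,
    plus1_2 = plus1_2,
    plus3 = plus3,
    plus4 = plus4,
    core_pass = core,
    plus3_A = core & !is.na(plus3) & plus3 == "A",
    plus4_G = core & !is.na(plus4) & plus4 == "G"
  )
}
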