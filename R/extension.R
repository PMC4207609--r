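STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Translate DNA to protein with the standard genetic code
#'
#' Stop codons are rendered `*`; any codon containing a character outside
#' `A`/`C`/`G`/`T` (e.g. `N`) is rendered `X` and is never read as a stop.
#'
#' @param nt Character vector of DNA strings; each length must be a multiple
#'   of 3.
#' @return Character vector of amino-acid strings.
#' @examples
#' translate_dna("TCGAAGCTT") # "SKL"
#' translate_dna("TGA")       # "*"
#' @export
translate_dna <- function(nt) {
  vapply(nt, function(s) {
    n <- nchar(s)
    if (n %% 3 != 0) {
      abort("translate_dna: sequence length must be a multiple of 3")
    }
    if (n == 0) return("")
    codons <- substring(s, seq(1, n, by = 3), seq(3, n, by = 3))
    aa <- unname(Biostrings::GENETIC_CODE[codons])
    aa[is.na(aa)] <- "X"
    paste0(aa, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

split_codons <- function(s) {
  n_full <- nchar(s) %/% 3
  if (n_full == 0) return(character(0))
  substring(s, seq(1, by = 3, length.out = n_full),
            seq(3, by = 3, length.out = n_full))
}

#' Call the in-frame readthrough extension from a 3' flank
#'
#' Walks the flank codon by codon in the frame continuing the coding
#' sequence, from the first nucleotide after the annotated stop codon to the
#' next in-frame stop. The extension excludes both stops. A codon containing
#' `N` translates to `X` and is never treated as a stop.
#'
#' `status` is `"closed"` when a terminating stop was found, `"empty"` when
#' the very first flank codon is a stop (zero-length extension), and
#' `"open"` when no in-frame stop occurs within `max_ext_nt` or before the
#' flank ends; open extensions are ineligible for PTS1 calling because the
#' motif requires a terminal stop.
#'
#' @param flank_nt Character vector of downstream flank sequences in reading
#'   orientation.
#' @param max_ext_nt Maximum extension length in nt (multiple of 3;
#'   default 600, i.e. 200 codons).
#' @return A tibble with one row per flank: `ext_nt`, `ext_aa`, `ext_len_aa`,
#'   `status`, `terminal_stop`.
#' @examples
#' call_extension("CTATCGAAGCTTTAGGGG") # LSKL, closed, TAG
#' @export
call_extension <- function(flank_nt, max_ext_nt = 600L) {
  if (max_ext_nt <= 0 || max_ext_nt %% 3 != 0) {
    abort("max_ext_nt must be a positive multiple of 3")
  }
  k <- max_ext_nt %/% 3L
  one <- function(fl) {
    codons <- split_codons(fl)
    # a stop at codon k+1 still closes a maximum-length extension
    codons <- codons[seq_len(min(length(codons), k + 1L))]
    hit <- which(codons %in% STOP_CODONS)
    if (length(hit)) {
      j <- hit[1]
      ext <- codons[seq_len(j - 1L)]
      status <- if (j == 1L) "empty" else "closed"
      term <- codons[j]
    } else {
      ext <- codons[seq_len(min(length(codons), k))]
      status <- "open"
      term <- "none"
    }
    c(paste0(ext, collapse = ""), status, term)
  }
  m <- vapply(flank_nt, one, character(3), USE.NAMES = FALSE)
  tibble(
    ext_nt = m[1, ],
    ext_aa = translate_dna(m[1, ]),
    ext_len_aa = nchar(m[1, ]) %/% 3L,
    status = m[2, ],
    terminal_stop = m[3, ]
  )
}
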