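PTS1_ALTERNATIVES <- c(
  "[ASTPCE]RL", "[SATPCVNG]KL", "S[SNH]L", "ARI", "S[KR]M",
  "[AG]NL", "SN[IM]", "[SA][KRQ]Y", "HHL", "[QS][KRQ]F"
)

#' The PTS1 motif regular expression
#'
#' The pattern applied to a translated extension rendered as
#' `"*" <extension> "*"` (annotated stop and terminal in-frame stop both
#' written `*`): anchored at the first stop, forbidding internal stops, and
#' requiring one of ten C-terminal tripeptide alternatives immediately before
#' the terminal stop.
#'
#' @return A single regular-expression string.
#' @export
pts1_regex <- function() {
  paste0("(^\\*[^*]*?(", paste(PTS1_ALTERNATIVES, collapse = "|"), ")\\*)")
}

#' Enumerate the PTS1 tripeptide set
#'
#' Expands the ten motif alternatives of [pts1_regex()] into the full set of
#' admissible C-terminal tripeptides (37 in total, prototype SKL), in a
#' stable reporting order following the alternatives left to right.
#'
#' @return Character vector of tripeptides.
#' @examples
#' "SKL" %in% pts1_tripeptide_set()
#' @export
pts1_tripeptide_set <- function() {
  expand_alt <- function(alt) {
    classes <- regmatches(alt, gregexpr("\\[[A-Z]+\\]|[A-Z]", alt))[[1]]
    sets <- lapply(classes, function(cl) {
      strsplit(gsub("[][]", "", cl), "")[[1]]
    })
    grid <- do.call(expand.grid, c(sets, stringsAsFactors = FALSE))
    apply(grid, 1, paste0, collapse = "")
  }
  unique(unlist(lapply(PTS1_ALTERNATIVES, expand_alt), use.names = FALSE))
}

# first motif alternative (in published order) matching a tripeptide, or NA
pts1_alternative_of <- function(tripeptide) {
  vapply(tripeptide, function(tp) {
    if (is.na(tp)) return(NA_character_)
    hit <- which(vapply(
      PTS1_ALTERNATIVES,
      function(a) grepl(paste0("^", a, "$"), tp),
      logical(1)
    ))
    if (length(hit)) PTS1_ALTERNATIVES[hit[1]] else NA_character_
  }, character(1), USE.NAMES = FALSE)
}

#' Scan a readthrough extension for a terminal PTS1 motif
#'
#' Applies [pts1_regex()] to `"*" + ext_aa + "*"`. A hit requires a closed
#' extension (the regex demands a terminal stop) of at least 3 residues whose
#' last tripeptide matches one of the motif alternatives. Ambiguous residues
#' (`X`) never participate in a hit.
#'
#' @param ext_aa Character vector of translated extensions (no `*`).
#' @param status Extension status from [call_extension()] (`"closed"`,
#'   `"open"`, `"empty"`); recycled.
#' @return A tibble with one row per input: `pts1_tripeptide`, `pts1_hit`
#'   (the motif alternative matched), both `NA` when there is no hit.
#' @examples
#' scan_extension_pts1("LSKL", "closed") # hit: SKL
#' scan_extension_pts1("SKLA", "closed") # no hit: motif not terminal
#' @export
scan_extension_pts1 <- function(ext_aa, status = "closed") {
  n <- max(length(ext_aa), length(status))
  ext_aa <- rep_len(ext_aa, n)
  status <- rep_len(status, n)
  pat <- pts1_regex()
  tri <- vapply(seq_len(n), function(i) {
    if (status[i] != "closed" || is.na(ext_aa[i]) || nchar(ext_aa[i]) < 3) {
      return(NA_character_)
    }
    rendered <- paste0("*", ext_aa[i], "*")
    m <- regexec(pat, rendered, perl = TRUE)[[1]]
    if (m[1] == -1) return(NA_character_)
    # capture group 2 is the tripeptide alternative
    substr(rendered, m[3], m[3] + attr(m, "match.length")[3] - 1L)
  }, character(1))
  tibble(pts1_tripeptide = tri, pts1_hit = pts1_alternative_of(tri))
}

#' Check a protein's own C-terminus for a PTS1 motif
#'
#' Some orthologs encode the PTS1 within the regular open reading frame and
#' need no readthrough ("in-ORF PTS1"). This tests the final tripeptide of
#' the annotated protein against [pts1_tripeptide_set()].
#'
#' @param protein_aa Character vector of protein sequences (no stops).
#' @return A tibble with one row per input: `orf_terminal_pts1` (the
#'   tripeptide, or `NA`), `orf_pts1_alternative`.
#' @export
scan_orf_terminal_pts1 <- function(protein_aa) {
  set <- pts1_tripeptide_set()
  tri <- ifelse(
    !is.na(protein_aa) & nchar(protein_aa) >= 3,
    substr(protein_aa, nchar(protein_aa) - 2L, nchar(protein_aa)),
    NA_character_
  )
  tri[!tri %in% set] <- NA_character_
  tibble(orf_terminal_pts1 = tri, orf_pts1_alternative = pts1_alternative_of(tri))
}

#' Approximate N-terminal PTS2 consensus scan
#'
#' Scans the N-terminal window of a protein for the canonical type-2
#' peroxisomal targeting nonapeptide consensus
#' `R-[LVIQ]-x-x-[LVIH]-[LSGA]-x-[HQ]-[LAF]`. This is a coarse consensus
#' match, not a trained predictor; results are labelled approximate wherever
#' reported and the scan is off by default in the screen.
#'
#' @param protein_aa Character vector of protein sequences.
#' @param window Number of N-terminal residues within which the nonapeptide
#'   must lie entirely (default 40; 0 disables the scan).
#' @return A tibble with one row per input: `pts2_nonapeptide`,
#'   `pts2_offset` (0-based start position, `NA` if no hit).
#' @examples
#' scan_pts2("MRLAVLSGHLAAA") # hit at offset 1
#' @export
scan_pts2 <- function(protein_aa, window = 40L) {
  pat <- "R[LVIQ]..[LVIH][LSGA].[HQ][LAF]"
  res <- vapply(protein_aa, function(p) {
    if (window < 9 || is.na(p)) return(c(NA_character_, NA_character_))
    region <- substr(p, 1, min(window, nchar(p)))
    m <- regexpr(pat, region, perl = TRUE)
    if (m == -1) return(c(NA_character_, NA_character_))
    c(substr(region, m, m + 8L), as.character(m - 1L))
  }, character(2), USE.NAMES = FALSE)
  tibble(
    pts2_nonapeptide = res[1, ],
    pts2_offset = as.integer(res[2, ])
  )
}
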