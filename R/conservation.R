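#' Read an ortholog-group table
#'
#' Expects a TSV with columns `group_id`, `species`, `gene_id`,
#' `protein_aa` (regular ORF translation, no stop), `stop_codon`,
#' `flank_nt` (3' flank in reading orientation; may be empty).
#'
#' @param path Path to the groups TSV.
#' @return A tibble of ortholog entries.
#' @export
read_ortholog_groups <- function(path) {
  cols <- c("group_id", "species", "gene_id", "protein_aa", "stop_codon", "flank_nt")
  d <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    na = character()
  )
  missing <- setdiff(cols, names(d))
  if (length(missing)) {
    abort(paste0("groups TSV missing column(s): ", paste(missing, collapse = ", ")))
  }
  bad <- !d$stop_codon %in% STOP_CODONS
  if (any(bad)) {
    abort(paste0(
      "invalid stop_codon for entries: ",
      paste(d$gene_id[bad], collapse = ", ")
    ))
  }
  d[, cols]
}

#' Classify the peroxisomal-targeting mechanism of ortholog entries
#'
#' Runs exactly the same extension calling, context classification and PTS
#' scanning as the genome screen on each entry's stop codon, 3' flank and
#' protein sequence. An empty flank yields an open zero-length extension, so
#' the mechanism is decided from the ORF terminus (and PTS2 scan, if
#' enabled) alone.
#'
#' @param entries Ortholog-entry tibble from [read_ortholog_groups()] (or any
#'   tibble with those columns).
#' @inheritParams screen_records
#' @return The input with the screen's classification columns appended,
#'   including `mechanism_class`.
#' @export
classify_entries <- function(entries, max_ext_nt = 600L,
                             context_mode = c("tga-ct", "any"),
                             include_pts2 = FALSE, pts2_window = 40L) {
  context_mode <- match.arg(context_mode)
  if (nrow(entries) == 0) abort("no ortholog entries supplied")
  cls <- rt_classify(
    stop_codon = entries$stop_codon,
    flank_nt = entries$flank_nt,
    protein_aa = entries$protein_aa,
    max_ext_nt = max_ext_nt,
    context_mode = context_mode,
    include_pts2 = include_pts2,
    pts2_window = pts2_window
  )
  bind_cols(entries |> select(-"stop_codon"), cls)
}

#' Summarise targeting-mechanism conservation across ortholog groups
#'
#' Per group, tabulates the mechanism class of every species (a species
#' present more than once keeps its best-priority mechanism) and aggregates:
#' counts per mechanism and whether the core TGA-CT context is shared by all
#' readthrough-positive species (`NA` when the group has none).
#'
#' @param entries Classified entries from [classify_entries()].
#' @return A list-free tibble of class `rt_conservation`, one row per group:
#'   `group_id`, `n_species`, `n_readthrough_PTS1`, `n_in_ORF_PTS1`,
#'   `n_other`, `n_none`, `conserved_core_context`. The per-species mechanism
#'   table is attached as attribute `per_species` (also a tibble).
#' @export
summarize_groups <- function(entries) {
  if (nrow(entries) == 0) abort("empty ortholog group")
  if (!"mechanism_class" %in% names(entries)) {
    abort("entries must first be classified with classify_entries()")
  }
  per_species <- entries |>
    mutate(.prio = match(.data$mechanism_class, MECHANISM_LEVELS)) |>
    group_by(.data$group_id, .data$species) |>
    arrange(.data$.prio, .data$gene_id, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    select(
      "group_id", "species", "gene_id", "mechanism_class",
      "context_core_pass", "pts1_tripeptide", "orf_terminal_pts1"
    ) |>
    arrange(.data$group_id, .data$species)

  readthrough <- c("readthrough_PTS1", "readthrough_PTS1_noncore_context")
  out <- per_species |>
    group_by(.data$group_id) |>
    summarise(
      n_species = n(),
      n_readthrough_PTS1 = sum(.data$mechanism_class == "readthrough_PTS1"),
      n_in_ORF_PTS1 = sum(.data$mechanism_class == "in_ORF_PTS1"),
      n_other = sum(.data$mechanism_class %in%
                      c("readthrough_PTS1_noncore_context", "PTS2")),
      n_none = sum(.data$mechanism_class == "none"),
      conserved_core_context = ifelse(
        sum(.data$mechanism_class %in% readthrough) == 0,
        NA,
        all(.data$context_core_pass[.data$mechanism_class %in% readthrough])
      ),
      .groups = "drop"
    )
  attr(out, "per_species") <- per_species
  class(out) <- c("rt_conservation", class(out))
  out
}

#' Summarise a single ortholog group
#'
#' Classifies and summarises one group's entries; all entries must share the
#' same `group_id`.
#'
#' @inheritParams classify_entries
#' @return A one-row `rt_conservation` tibble; see [summarize_groups()].
#' @export
summarize_group <- function(entries, max_ext_nt = 600L,
                            context_mode = c("tga-ct", "any"),
                            include_pts2 = FALSE) {
  if (nrow(entries) == 0) abort("empty ortholog group")
  if (length(unique(entries$group_id)) != 1) {
    abort("entries mix more than one group_id")
  }
  entries |>
    classify_entries(
      max_ext_nt = max_ext_nt, context_mode = context_mode,
      include_pts2 = include_pts2
    ) |>
    summarize_groups()
}

#' Write the conservation matrix TSV
#'
#' One row per group x species with the mechanism class, followed by one
#' aggregate row per group (`species = "*"`) carrying the group counts and
#' the shared-core-context flag.
#'
#' @param summary An `rt_conservation` tibble from [summarize_groups()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_conservation <- function(summary, path) {
  per_species <- attr(summary, "per_species")
  if (is.null(per_species)) abort("summary lacks the per_species attribute")
  sp <- per_species |>
    select("group_id", "species", "gene_id", "mechanism_class") |>
    mutate(
      n_species = NA_integer_, n_readthrough_PTS1 = NA_integer_,
      n_in_ORF_PTS1 = NA_integer_, n_other = NA_integer_,
      n_none = NA_integer_, conserved_core_context = NA
    )
  agg <- summary |>
    as_tibble() |>
    mutate(species = "*", gene_id = NA_character_, mechanism_class = NA_character_)
  out <- bind_rows(sp, agg) |>
    arrange(.data$group_id, .data$species == "*", .data$species)
  readr::write_tsv(out, path, na = "")
  invisible(path)
}

#' @export
print.rt_conservation <- function(x, ...) {
  cat("<rt_conservation> ", nrow(x), " ortholog group(s)\n", sep = "")
  NextMethod()
}
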