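#' Tidy a screen result
#'
#' The screen report is already tabular; `tidy()` strips the result class
#' and attributes, returning a plain tibble (one row per gene).
#'
#' @param x An `rt_screen` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy rt_screen
#' @export
tidy.rt_screen <- function(x, ...) {
  out <- as_tibble(x)
  attr(out, "run_summary") <- NULL
  out
}

#' One-row summary of a screen run
#'
#' @param x An `rt_screen` object.
#' @param ... Unused.
#' @return A one-row tibble: genes screened/skipped and per-mechanism
#'   tallies.
#' @method glance rt_screen
#' @export
glance.rt_screen <- function(x, ...) {
  rs <- attr(x, "run_summary")
  tally <- table(factor(x$mechanism_class, levels = MECHANISM_LEVELS))
  tibble(
    n_models = rs$n_models %||% nrow(x),
    n_screened = nrow(x),
    n_skipped = rs$n_skipped %||% 0L,
    n_readthrough_PTS1 = unname(tally[["readthrough_PTS1"]]),
    n_in_ORF_PTS1 = unname(tally[["in_ORF_PTS1"]]),
    n_noncore = unname(tally[["readthrough_PTS1_noncore_context"]]),
    n_PTS2 = unname(tally[["PTS2"]]),
    n_none = unname(tally[["none"]]),
    n_core_context = sum(x$context_core_pass)
  )
}

#' @method tidy rt_conservation
#' @export
#' @rdname tidy.rt_screen
tidy.rt_conservation <- function(x, ...) {
  attr(x, "per_species")
}

#' @method glance rt_conservation
#' @export
#' @rdname glance.rt_screen
glance.rt_conservation <- function(x, ...) {
  tibble(
    n_groups = nrow(x),
    n_species_rows = sum(x$n_species),
    n_groups_readthrough_conserved =
      sum(x$n_readthrough_PTS1 == x$n_species),
    n_groups_any_readthrough = sum(x$n_readthrough_PTS1 > 0)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
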