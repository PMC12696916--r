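#' Tidy and summarise design results
#'
#' Broom-style accessors. `tidy()` returns one row per design or
#' observation; `glance()` returns a one-row summary.
#'
#' @param x A `paratope_designs`, `epitope_panel` or `fragment_library`.
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy.paratope_designs <- function(x, ...) {
  as_tibble(x) |>
    mutate(
      min_support = purrr::map_int(.data$support, function(s) {
        as.integer(min(s))
      }),
      n_fragments = purrr::map_int(.data$fragments, nrow)
    ) |>
    select(
      "epitope_seq", "paratope_seq", "orientation", "c_score",
      "solubility", "min_support", "n_fragments"
    )
}

#' @rdname tidiers
#' @export
glance.paratope_designs <- function(x, ...) {
  tibble(
    n_candidates = nrow(x),
    best_c_score = if (nrow(x) > 0) max(x$c_score) else NA_real_,
    best_solubility = if (nrow(x) > 0) max(x$solubility) else NA_real_
  )
}

#' @rdname tidiers
#' @export
tidy.epitope_panel <- function(x, ...) {
  as_tibble(x) |>
    select(
      "start", "end", "label", "epitope_seq", "paratope_seq",
      "orientation", "c_score", "solubility"
    )
}

#' @rdname tidiers
#' @export
glance.epitope_panel <- function(x, ...) {
  tibble(
    target_id = attr(x, "target_id"),
    target_length = nchar(attr(x, "target_seq")),
    n_windows = nrow(x),
    n_designed = sum(!is.na(x$paratope_seq)),
    mean_c_score = mean(x$c_score, na.rm = TRUE),
    mean_solubility = mean(x$solubility, na.rm = TRUE)
  )
}

#' @rdname tidiers
#' @export
tidy.fragment_library <- function(x, ...) {
  as_tibble(x)
}

#' @rdname tidiers
#' @export
glance.fragment_library <- function(x, ...) {
  tibble(
    n_keys = nrow(x),
    n_observations = sum(x$count),
    min_len = attr(x, "min_len"),
    max_len = attr(x, "max_len")
  )
}
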