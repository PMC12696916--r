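#' Build a fragment library from structures
#'
#' Mines every structure for beta-strand paired fragments and indexes
#' every contiguous sub-window of every fragment (lengths `min_len` to
#' `max_len`) under its target-side subsequence and orientation.
#' Observations of the same (target subsequence, complementary
#' subsequence, orientation) accumulate counts, so counts are additive
#' over input structures. Windows containing `'X'` on either side are
#' excluded.
#'
#' @param structures A `protein_structure` or list of them.
#' @param min_len,max_len Sub-window length bounds (`max_len >= min_len >= 2`).
#' @param cutoff Hydrogen-bond energy threshold for mining.
#' @param symmetric When `TRUE`, each pairing is indexed in both directions
#'   (the complementary side also becomes a target-side key) via
#'   [symmetrize_pairs()]. Default `FALSE`: fragments are indexed exactly
#'   as mined.
#' @return A `fragment_library`: a tibble with columns `target_subseq`,
#'   `orientation`, `comp_subseq`, `count`, `sources`, carrying `min_len`
#'   and `max_len` attributes.
#' @export
build_library <- function(structures, min_len = 3L, max_len = 9L,
                          cutoff = -0.5, symmetric = FALSE) {
  if (inherits(structures, "protein_structure")) structures <- list(structures)
  if (min_len < 2 || max_len < min_len) {
    abort("need max_len >= min_len >= 2")
  }
  if (length(structures) == 0) {
    warn("no structures supplied; returning an empty library")
    return(new_fragment_library(empty_observations(), min_len, max_len))
  }
  pairs <- purrr::map(structures, detect_strand_pairs,
    min_len = 2L, cutoff = cutoff
  ) |> bind_rows()
  library_from_pairs(pairs, min_len, max_len, symmetric = symmetric)
}

#' Index mined paired fragments into a library
#'
#' @param pairs A paired-fragment tibble from [detect_strand_pairs()].
#' @inheritParams build_library
#' @export
library_from_pairs <- function(pairs, min_len = 3L, max_len = 9L,
                               symmetric = FALSE) {
  if (min_len < 2 || max_len < min_len) {
    abort("need max_len >= min_len >= 2")
  }
  if (symmetric && nrow(pairs) > 0) pairs <- symmetrize_pairs(pairs)
  obs <- purrr::pmap(pairs, fragment_windows,
    min_len = min_len, max_len = max_len
  ) |> bind_rows()
  if (nrow(obs) == 0) {
    return(new_fragment_library(empty_observations(), min_len, max_len))
  }
  obs <- obs |>
    group_by(.data$target_subseq, .data$orientation, .data$comp_subseq) |>
    summarise(
      count = sum(.data$count),
      sources = paste(sort(unique(.data$sources)), collapse = ","),
      .groups = "drop"
    ) |>
    arrange(
      .data$target_subseq, .data$orientation,
      desc(.data$count), .data$comp_subseq
    )
  new_fragment_library(obs, min_len, max_len)
}

#' Swap target and complementary sides of paired fragments
#'
#' Each beta-strand pairing is evidence in both directions: the
#' complementary strand also faces the target strand. Returns the input
#' fragments plus their side-swapped duplicates.
#'
#' @param pairs A paired-fragment tibble.
#' @return A paired-fragment tibble with twice the rows.
#' @export
symmetrize_pairs <- function(pairs) {
  swapped <- pairs |>
    rename(
      target_chain = "comp_chain", target_start = "comp_start",
      target_end = "comp_end", target_seq = "comp_seq",
      comp_chain = "target_chain", comp_start = "target_start",
      comp_end = "target_end", comp_seq = "target_seq"
    )
  bind_rows(pairs, swapped)
}

empty_observations <- function() {
  tibble(
    target_subseq = character(), orientation = character(),
    comp_subseq = character(), count = integer(), sources = character()
  )
}

new_fragment_library <- function(obs, min_len, max_len) {
  structure(obs,
    min_len = as.integer(min_len), max_len = as.integer(max_len),
    class = c("fragment_library", class(obs))
  )
}

#' @export
print.fragment_library <- function(x, ...) {
  cat(
    "<fragment_library> ", nrow(x), " keys, ",
    sum(x$count), " observations (window ", attr(x, "min_len"),
    "-", attr(x, "max_len"), ")\n",
    sep = ""
  )
  NextMethod()
}

# all sub-windows of one paired fragment as observation rows
fragment_windows <- function(target_seq, comp_seq, orientation, source_id,
                             min_len, max_len, ...) {
  L <- nchar(target_seq)
  rows <- list()
  for (l in min_len:min(max_len, L)) {
    for (a in seq_len(L - l + 1L)) {
      b <- a + l - 1L
      tw <- substr(target_seq, a, b)
      cw <- comp_window(comp_seq, a, b, L, orientation)
      if (grepl("X", tw, fixed = TRUE) || grepl("X", cw, fixed = TRUE)) next
      rows[[length(rows) + 1L]] <- tibble(
        target_subseq = tw, orientation = orientation, comp_subseq = cw,
        count = 1L, sources = source_id
      )
    }
  }
  bind_rows(rows)
}

# complementary subsequence facing target window [a, b]; comp_seq is N->C,
# antiparallel pairing maps target position k to comp position L + 1 - k
comp_window <- function(comp_seq, a, b, L, orientation) {
  if (orientation == "antiparallel") {
    substr(comp_seq, L + 1L - b, L + 1L - a)
  } else {
    substr(comp_seq, a, b)
  }
}

#' Query a fragment library
#'
#' @param lib A `fragment_library`.
#' @param target_subseq Target-side subsequence (length within the
#'   library's window bounds).
#' @param orientation `"antiparallel"` or `"parallel"`.
#' @return Matching observations ordered by descending count, then
#'   lexicographic complementary subsequence.
#' @export
query_library <- function(lib, target_subseq,
                          orientation = c("antiparallel", "parallel")) {
  orientation <- match.arg(orientation)
  l <- nchar(target_subseq)
  if (l < attr(lib, "min_len") || l > attr(lib, "max_len")) {
    abort(paste0(
      "query length ", l, " outside library window [",
      attr(lib, "min_len"), ", ", attr(lib, "max_len"), "]"
    ))
  }
  ori <- orientation
  out <- lib |>
    filter(.data$target_subseq == !!target_subseq, .data$orientation == ori) |>
    arrange(desc(.data$count), .data$comp_subseq)
  as_tibble(out)
}

#' Read and write fragment libraries as TSV
#'
#' The serialization is a plain tab-separated table with columns
#' `target_subseq`, `orientation`, `comp_subseq`, `count`, `sources`,
#' preceded by two comment lines recording the window bounds.
#'
#' @param lib A `fragment_library`.
#' @param path File path.
#' @return `write_library()` returns `path` invisibly; `read_library()`
#'   returns a `fragment_library`.
#' @export
write_library <- function(lib, path) {
  header <- c(
    paste0("# min_len=", attr(lib, "min_len")),
    paste0("# max_len=", attr(lib, "max_len"))
  )
  writeLines(header, path)
  readr::write_tsv(as_tibble(lib), path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_library
#' @export
read_library <- function(path) {
  hdr <- readLines(path, n = 2)
  min_len <- as.integer(sub("# min_len=", "", hdr[1], fixed = TRUE))
  max_len <- as.integer(sub("# max_len=", "", hdr[2], fixed = TRUE))
  obs <- readr::read_tsv(path,
    comment = "#", show_col_types = FALSE,
    col_types = readr::cols(
      target_subseq = "c", orientation = "c", comp_subseq = "c",
      count = "i", sources = "c"
    )
  )
  new_fragment_library(as_tibble(obs), min_len, max_len)
}
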