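#' Enumerate epitope windows along a target
#'
#' Tiles the unmasked part of a target with windows of `min_len` residues
#' advancing by `step`, the final window stretching (up to `max_len`) to
#' end exactly at the target's last residue. Windows touching the mask
#' are dropped. All coordinates are 1-based inclusive.
#'
#' @param target_len Target sequence length.
#' @param mask Integer vector of masked residue indices (e.g. a disulfide-
#'   bonded N-terminal region).
#' @param min_len,max_len Window length bounds (auto mode uses 7-9).
#' @param step Window start increment.
#' @return A tibble of windows: `start`, `end`, `label`.
#' @export
enumerate_windows <- function(target_len, mask = integer(),
                              min_len = 7L, max_len = 9L, step = 3L) {
  if (target_len < min_len) abort("target shorter than min_len")
  mask <- as.integer(mask)
  unmasked <- setdiff(seq_len(target_len), mask)
  if (length(unmasked) == 0 || max(unmasked) - min(unmasked) + 1L < min_len) {
    warn("unmasked region shorter than min_len; no windows")
    return(tibble(start = integer(), end = integer(), label = character()))
  }
  first <- min(unmasked)
  starts <- seq(from = first, to = target_len - min_len + 1L, by = step)
  if (length(starts) == 0) {
    warn("unmasked region shorter than min_len; no windows")
    return(tibble(start = integer(), end = integer(), label = character()))
  }
  ends <- starts + min_len - 1L
  # final window stretches to the target end when max_len allows
  last <- length(starts)
  if (target_len - starts[last] + 1L <= max_len) {
    ends[last] <- target_len
  }
  w <- tibble(start = as.integer(starts), end = as.integer(ends))
  w <- filter(w, purrr::map2_lgl(
    .data$start, .data$end,
    function(s, e) !any(seq(s, e) %in% mask)
  ))
  mutate(w, label = paste0(.data$start, "-", .data$end))
}

#' Validate epitope windows
#'
#' Checks explicit windows against the target length and mask, rejecting
#' any window out of range, inverted, or intersecting the mask. Window
#' labels accept either an ASCII hyphen or an en-dash.
#'
#' @param windows A data frame with `start` and `end` columns (1-based
#'   inclusive), or a character vector of `"start-end"` labels.
#' @param target_len Target sequence length.
#' @param mask Masked residue indices.
#' @return The validated window tibble (`start`, `end`, `label`).
#' @export
validate_windows <- function(windows, target_len, mask = integer()) {
  if (is.character(windows)) windows <- parse_window_labels(windows)
  windows <- as_tibble(windows)
  if (!all(c("start", "end") %in% names(windows))) {
    abort("windows need 'start' and 'end' columns")
  }
  windows <- mutate(windows,
    start = as.integer(.data$start), end = as.integer(.data$end),
    label = paste0(.data$start, "-", .data$end)
  )
  bad_range <- windows$start < 1 | windows$end > target_len |
    windows$start > windows$end
  bad_mask <- purrr::map2_lgl(
    windows$start, windows$end,
    function(s, e) any(seq(s, e) %in% mask)
  )
  if (any(bad_range | bad_mask)) {
    offending <- windows$label[bad_range | bad_mask]
    abort(paste0(
      "invalid windows: ", paste(offending, collapse = ", "),
      " (out of range or intersecting the mask)"
    ))
  }
  windows[, c("start", "end", "label")]
}

parse_window_labels <- function(labels) {
  m <- stringr::str_match(labels, "^(\\d+)[-–](\\d+)$")
  if (anyNA(m[, 1])) {
    abort(paste0(
      "cannot parse window labels: ",
      paste(labels[is.na(m[, 1])], collapse = ", ")
    ))
  }
  tibble(start = as.integer(m[, 2]), end = as.integer(m[, 3]))
}

#' Scan a target sequence with epitope windows
#'
#' Runs [cascade_assemble()] on every window's epitope subsequence and
#' keeps the top-ranked design per window. Windows with no feasible
#' design are retained with `NA` design columns. Windows are processed
#' independently, so permuting them permutes the panel identically.
#'
#' @param target_seq Target amino-acid sequence.
#' @param windows Validated window tibble (see [validate_windows()]).
#' @param lib A `fragment_library`.
#' @param target_id Identifier for the target.
#' @param mask Masked residue indices (carried in the panel).
#' @param ... Cascade parameters passed to [cascade_assemble()].
#' @return An `epitope_panel` tibble: one row per window with `start`,
#'   `end`, `label`, `epitope_seq`, `paratope_seq`, `orientation`,
#'   `c_score`, `solubility`, `support`.
#' @export
scan_epitopes <- function(target_seq, windows, lib, target_id = "target",
                          mask = integer(), ...) {
  target_seq <- toupper(unname(target_seq))
  rows <- purrr::pmap(
    windows[, c("start", "end", "label")],
    function(start, end, label) {
      epi <- substr(target_seq, start, end)
      designs <- tryCatch(
        cascade_assemble(lib, epi, ...),
        error = function(e) {
          warn(paste0("window ", label, ": ", conditionMessage(e)))
          empty_designs()
        }
      )
      if (nrow(designs) == 0) {
        tibble(
          start = start, end = end, label = label, epitope_seq = epi,
          paratope_seq = NA_character_, orientation = NA_character_,
          c_score = NA_real_, solubility = NA_real_,
          support = list(NULL)
        )
      } else {
        best <- designs[1, ]
        tibble(
          start = start, end = end, label = label, epitope_seq = epi,
          paratope_seq = best$paratope_seq, orientation = best$orientation,
          c_score = best$c_score, solubility = best$solubility,
          support = best$support
        )
      }
    }
  ) |> bind_rows()
  structure(rows,
    target_id = target_id, target_seq = target_seq, mask = as.integer(mask),
    class = c("epitope_panel", class(rows))
  )
}

#' @export
print.epitope_panel <- function(x, ...) {
  cat(
    "<epitope_panel> target ", attr(x, "target_id"), " (",
    nchar(attr(x, "target_seq")), " aa): ", nrow(x), " windows, ",
    sum(!is.na(x$paratope_seq)), " designed\n",
    sep = ""
  )
  NextMethod()
}

#' Write a design panel as TSV
#'
#' @param panel An `epitope_panel`.
#' @param path Output path.
#' @export
write_panel <- function(panel, path) {
  flat <- as_tibble(panel) |>
    mutate(support = purrr::map_chr(
      .data$support,
      function(s) if (is.null(s)) "" else paste(s, collapse = ",")
    ))
  readr::write_tsv(flat, path)
  invisible(path)
}

#' The mature human IAPP sequence fixture
#'
#' Returns the 37-residue mature human islet amyloid polypeptide
#' (UniProt P10997, processed chain), shipped as a FASTA fixture. The
#' N-terminal region (residues 1-8) contains the Cys2-Cys7 disulfide and
#' is conventionally masked during epitope scanning.
#'
#' @return A named character scalar (name = `"IAPP"`).
#' @export
iapp_sequence <- function() {
  fasta <- system.file("extdata", "iapp.fasta", package = "cascadesign")
  lines <- readLines(fasta)
  seq <- paste(lines[!startsWith(lines, ">")], collapse = "")
  stats::setNames(seq, "IAPP")
}

#' The nine canonical IAPP epitope windows
#'
#' The irregular window list used to scan mature IAPP (lengths 7-9,
#' sparing the disulfide-bonded N-terminal region, residues 1-8).
#'
#' @return A window tibble (`start`, `end`, `label`).
#' @export
iapp_windows <- function() {
  validate_windows(
    c(
      "9-17", "12-18", "15-22", "19-26", "20-28",
      "22-29", "26-32", "26-34", "30-37"
    ),
    target_len = 37L, mask = 1:8
  )
}
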