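#' Canonical construct names
#'
#' Derives the canonical construct name from an edit list. Panel grafts
#' (edits carrying a window label) are named `DesAb_<start>-<end>` or
#' `DesAb_neg`. Monobody constructs are named
#' `"<N-k->?<BC token>(BC)-<FG token>(FG)"` with `wt` for untouched
#' loops. Other single-domain engineering variants are named
#' `"<insert>_<cysteine suffix>"`. Printed en-dashes in window names are
#' normalised to ASCII hyphens in machine output; both are accepted on
#' input by [parse_construct_name()].
#'
#' @param edits An edit tibble (see [replay_edits()]).
#' @param scaffold Scaffold name; names containing `"monobody"` (case
#'   insensitive) use the two-loop naming grammar.
#' @param sites Site names of the scaffold, in naming order.
#' @param tokens Optional token list maintained by the editing functions.
#' @return A character scalar.
#' @export
construct_name <- function(edits, scaffold = "sdAb",
                           sites = c("BC", "FG"), tokens = NULL) {
  grafts <- filter(edits, .data$kind == "graft")
  labels <- grafts$label[!is.na(grafts$label)]
  if (length(labels) > 0) {
    lab <- normalize_dash(labels[[length(labels)]])
    return(paste0("DesAb_", lab))
  }
  if (grepl("monobody", scaffold, ignore.case = TRUE)) {
    prefix <- ""
    tr <- filter(edits, .data$kind == "truncate_n")
    if (nrow(tr) > 0) prefix <- paste0("N-", sum(tr$position), "-")
    token_for <- function(site_name) {
      e <- filter(
        edits,
        .data$kind %in% c("graft", "replace_loop"), .data$site == site_name
      )
      if (nrow(e) == 0) "wt" else e$after[nrow(e)]
    }
    body <- paste(
      vapply(sites, function(s) paste0(token_for(s), "(", s, ")"), character(1)),
      collapse = "-"
    )
    return(paste0(prefix, body))
  }
  # single-domain engineering variant: designed insert + cysteine suffix
  insert <- if (nrow(grafts) > 0) {
    core_insert(grafts$after[nrow(grafts)], grafts$mode[nrow(grafts)])
  } else {
    scaffold
  }
  suffix <- tokens$cys_suffix %||% cys_suffix_from_edits(edits)
  if (is.null(suffix)) insert else paste(insert, suffix, sep = "_")
}

core_insert <- function(after, mode) {
  if (identical(mode, "full_loop")) {
    sub("EEE$", "", sub("^GS", "", after))
  } else {
    after
  }
}

cys_suffix_from_edits <- function(edits) {
  subs <- filter(edits, .data$kind == "substitute")
  if (nrow(subs) != 2) {
    return(NULL)
  }
  paste0("C23", subs$after[1], "C97", subs$after[2])
}

normalize_dash <- function(x) {
  gsub("–", "-", x)
}

#' Parse a canonical construct name
#'
#' Inverts [construct_name()]: recovers the edit summary encoded in a
#' printed construct name. Accepts both ASCII hyphens and en-dashes in
#' window labels.
#'
#' @param name A construct name string.
#' @return A list with `type` (`"panel"` or `"monobody"`) and either
#'   `window_start`/`window_end`/`negative`, or
#'   `truncate_n`/`site_tokens` (named character vector, `"wt"` for
#'   untouched loops).
#' @export
parse_construct_name <- function(name) {
  name <- normalize_dash(name)
  if (name == "DesAb_neg") {
    return(list(
      type = "panel", negative = TRUE,
      window_start = NA_integer_, window_end = NA_integer_
    ))
  }
  m <- stringr::str_match(name, "^DesAb_(\\d+)-(\\d+)$")
  if (!is.na(m[1, 1])) {
    return(list(
      type = "panel", negative = FALSE,
      window_start = as.integer(m[1, 2]), window_end = as.integer(m[1, 3])
    ))
  }
  m <- stringr::str_match(
    name, "^(?:N-(\\d+)-)?(wt|[A-Z]+)\\(([A-Z]+)\\)-(wt|[A-Z]+)\\(([A-Z]+)\\)$"
  )
  if (!is.na(m[1, 1])) {
    tokens <- stats::setNames(c(m[1, 3], m[1, 5]), c(m[1, 4], m[1, 6]))
    return(list(
      type = "monobody",
      truncate_n = if (is.na(m[1, 2])) 0L else as.integer(m[1, 2]),
      site_tokens = tokens
    ))
  }
  m <- stringr::str_match(name, "^([A-Z]+)_(C23[A-Z]C97[A-Z])$")
  if (!is.na(m[1, 1])) {
    return(list(type = "sdab_variant", insert = m[1, 2], cys_suffix = m[1, 3]))
  }
  abort(paste0("cannot parse construct name: ", name))
}
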