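#' Scaffold templates
#'
#' A scaffold template is the sequence of an antibody-like scaffold
#' together with its binding-loop sites (e.g. `CDR3` for a single-domain
#' antibody; `BC` and `FG` for a monobody), any numbered residues of
#' interest (e.g. the conserved cysteines `C23`/`C97` of the sdAb
#' framework), and the extent of its N-terminal region. Site coordinates
#' are 1-based inclusive. Numbered labels use the scaffold's published
#' numbering; `numbering_offset` maps them onto raw sequence indices
#' (`raw index = label number + numbering_offset`).
#'
#' @param name Scaffold name (e.g. `"sdAb"`, `"monobody"`).
#' @param sequence Amino-acid sequence.
#' @param sites Named list of `c(start, end)` loop sites; must be in
#'   bounds and mutually non-overlapping.
#' @param numbered Named integer vector of label numbers, e.g.
#'   `c(C23 = 23, C97 = 97)`.
#' @param numbering_offset Offset from label numbering to raw index.
#' @param n_terminal_region Length of the N-terminal region preceding the
#'   first site (informational).
#' @return A `scaffold_template` list.
#' @export
scaffold_template <- function(name, sequence, sites = list(),
                              numbered = integer(), numbering_offset = 0L,
                              n_terminal_region = NULL) {
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  sites <- purrr::map(sites, function(s) as.integer(s[1:2]))
  for (nm in names(sites)) {
    s <- sites[[nm]]
    if (s[1] < 1 || s[2] > L || s[1] > s[2]) {
      abort(paste0("site ", nm, " out of sequence bounds"))
    }
  }
  if (length(sites) > 1) {
    iv <- purrr::map(sites, function(s) seq(s[1], s[2]))
    if (length(unlist(iv)) != length(unique(unlist(iv)))) {
      abort("scaffold sites overlap")
    }
  }
  numbered_raw <- stats::setNames(
    as.integer(numbered) + as.integer(numbering_offset), names(numbered)
  )
  for (nm in names(numbered_raw)) {
    idx <- numbered_raw[[nm]]
    expected <- substr(nm, 1, 1)
    if (idx < 1 || idx > L) abort(paste0("numbered residue ", nm, " out of bounds"))
    if (expected %in% AA_STANDARD && substr(sequence, idx, idx) != expected) {
      abort(paste0(
        "numbered residue ", nm, " does not match template (found ",
        substr(sequence, idx, idx), " at raw index ", idx, ")"
      ))
    }
  }
  structure(
    list(
      name = name, sequence = sequence, sites = sites,
      numbered = numbered_raw,
      n_terminal_region = n_terminal_region %||%
        (if (length(sites) > 0) min(purrr::map_int(sites, 1)) - 1L else 0L),
      edits = empty_edits(), tokens = list()
    ),
    class = "scaffold_template"
  )
}

#' @export
print.scaffold_template <- function(x, ...) {
  cat(
    "<scaffold_template> ", x$name, " (", nchar(x$sequence), " aa); sites: ",
    paste(
      purrr::imap_chr(x$sites, function(s, nm) {
        paste0(nm, " [", s[1], "-", s[2], "]")
      }),
      collapse = ", "
    ),
    if (nrow(x$edits) > 0) paste0("; ", nrow(x$edits), " edit(s)") else "",
    "\n",
    sep = ""
  )
  invisible(x)
}

empty_edits <- function() {
  tibble(
    kind = character(), site = character(), position = integer(),
    before = character(), after = character(), mode = character(),
    label = character()
  )
}

add_edit <- function(t, kind, site = NA_character_, position = NA_integer_,
                     before = NA_character_, after = NA_character_,
                     mode = NA_character_, label = NA_character_) {
  t$edits <- bind_rows(t$edits, tibble(
    kind = kind, site = site, position = as.integer(position),
    before = before, after = after, mode = mode, label = label
  ))
  t
}

check_edit_order <- function(t, kind) {
  rank <- c(truncate_n = 1, substitute = 2, replace_loop = 3, graft = 4)
  if (nrow(t$edits) > 0 && any(rank[t$edits$kind] > rank[[kind]])) {
    abort(paste0(
      "edits must follow the canonical order ",
      "truncate > substitute > replace_loop > graft; cannot add '", kind, "'"
    ))
  }
  invisible(t)
}

#' Remove the conserved sdAb disulfide bond
#'
#' Applies one of the two cysteine-substitution schemes to the numbered
#' residues `C23` and `C97`: scheme `"AA"` substitutes both with alanine
#' (suffix `C23AC97A`); scheme `"AV"` substitutes Cys23 with alanine and
#' Cys97 with valine (suffix `C23AC97V`).
#'
#' @param t A `scaffold_template` with numbered residues `C23` and `C97`.
#' @param scheme `"AA"` or `"AV"`.
#' @return The substituted template, carrying the scheme suffix.
#' @export
substitute_cysteines <- function(t, scheme = c("AA", "AV")) {
  scheme <- match.arg(scheme)
  check_edit_order(t, "substitute")
  for (lbl in c("C23", "C97")) {
    if (!lbl %in% names(t$numbered)) {
      abort(paste0("template has no numbered residue ", lbl))
    }
    idx <- t$numbered[[lbl]]
    if (substr(t$sequence, idx, idx) != "C") {
      abort(paste0(
        "residue at ", lbl, " (raw index ", idx, ") is not cysteine; ",
        "already substituted or template misconfigured"
      ))
    }
  }
  repl <- if (scheme == "AA") c(C23 = "A", C97 = "A") else c(C23 = "A", C97 = "V")
  for (lbl in names(repl)) {
    idx <- t$numbered[[lbl]]
    t <- add_edit(t, "substitute",
      position = idx,
      before = "C", after = repl[[lbl]]
    )
    substr(t$sequence, idx, idx) <- repl[[lbl]]
  }
  t$tokens$cys_suffix <- paste0("C23", repl[["C23"]], "C97", repl[["C97"]])
  t
}

#' Truncate the scaffold N-terminus
#'
#' Removes the first `n` residues and shifts all site and numbered-residue
#' indices by `-n`. Truncation may not reach the earliest loop site.
#'
#' @param t A `scaffold_template`.
#' @param n Number of residues to remove (`1 <= n < first site start`).
#' @return The truncated template, carrying the `N-<n>-` name prefix.
#' @export
truncate_n_terminus <- function(t, n) {
  n <- as.integer(n)
  check_edit_order(t, "truncate_n")
  first_site <- if (length(t$sites) > 0) {
    min(purrr::map_int(t$sites, 1))
  } else {
    nchar(t$sequence) + 1L
  }
  if (n < 1 || n >= first_site) {
    abort(paste0(
      "truncation of ", n, " residues reaches the earliest site (start ",
      first_site, ")"
    ))
  }
  t <- add_edit(t, "truncate_n",
    position = n,
    before = substr(t$sequence, 1, n), after = ""
  )
  t$sequence <- substr(t$sequence, n + 1L, nchar(t$sequence))
  t$sites <- purrr::map(t$sites, function(s) s - n)
  t$numbered <- t$numbered - n
  t$n_terminal_region <- max(0L, t$n_terminal_region - n)
  t$tokens$trunc_prefix <- paste0("N-", n, "-")
  t
}

#' Replace a scaffold loop
#'
#' Substitutes the residues of a loop site with a new sequence, updating
#' the site bounds and shifting downstream coordinates.
#'
#' @param t A `scaffold_template`.
#' @param site Site name (e.g. `"FG"`).
#' @param seq Replacement sequence (non-empty).
#' @return The edited template; the site's name token becomes `seq`.
#' @export
replace_loop <- function(t, site, seq) {
  if (!site %in% names(t$sites)) abort(paste0("unknown site: ", site))
  seq <- toupper(seq)
  if (nchar(seq) == 0) abort("replacement sequence must be non-empty")
  check_edit_order(t, "replace_loop")
  t <- splice_site(t, site, seq, kind = "replace_loop")
  t$tokens[[paste0("site_", site)]] <- seq
  t
}

splice_site <- function(t, site, insert, kind, mode = NA_character_,
                        label = NA_character_) {
  s <- t$sites[[site]]
  before <- substr(t$sequence, s[1], s[2])
  t <- add_edit(t, kind,
    site = site, position = s[1],
    before = before, after = insert, mode = mode, label = label
  )
  t$sequence <- paste0(
    substr(t$sequence, 1, s[1] - 1L), insert,
    substr(t$sequence, s[2] + 1L, nchar(t$sequence))
  )
  shift <- nchar(insert) - (s[2] - s[1] + 1L)
  t$sites[[site]] <- c(s[1], s[1] + nchar(insert) - 1L)
  for (nm in names(t$sites)) {
    if (nm != site && t$sites[[nm]][1] > s[2]) {
      t$sites[[nm]] <- t$sites[[nm]] + shift
    }
  }
  if (length(t$numbered) > 0) {
    after_site <- t$numbered > s[2]
    t$numbered[after_site] <- t$numbered[after_site] + shift
  }
  t
}

#' Graft a designed paratope into a scaffold loop
#'
#' Replaces the residues of a loop site with the designed sequence. In
#' `"core"` mode the bare paratope is inserted; in `"full_loop"` mode the
#' insert is flanked as `GS<insert>EEE`, the complete designed CDR3 loop
#' architecture.
#'
#' @param t A `scaffold_template`.
#' @param site Site to graft into (e.g. `"CDR3"`, `"BC"`).
#' @param insert Designed paratope sequence (non-empty, standard letters).
#' @param mode `"core"` or `"full_loop"`.
#' @param label Optional panel label (e.g. `"9-17"` or `"neg"`) used for
#'   designed-antibody naming.
#' @return A `construct` object (see [construct_name()]).
#' @export
graft <- function(t, site, insert, mode = c("core", "full_loop"),
                  label = NULL) {
  mode <- match.arg(mode)
  if (!site %in% names(t$sites)) abort(paste0("unknown site: ", site))
  insert <- toupper(insert)
  if (nchar(insert) == 0) abort("insert must be non-empty")
  bad <- setdiff(strsplit(insert, "")[[1]], AA_STANDARD)
  if (length(bad) > 0) {
    abort(paste0("invalid residues in insert: ", paste(bad, collapse = "")))
  }
  effective <- if (mode == "full_loop") paste0("GS", insert, "EEE") else insert
  t <- splice_site(t, site, effective,
    kind = "graft", mode = mode,
    label = label %||% NA_character_
  )
  t$tokens[[paste0("site_", site)]] <- effective
  new_construct(
    name = construct_name(t$edits,
      scaffold = t$name, sites = names(t$sites),
      tokens = t$tokens
    ),
    sequence = t$sequence, scaffold = t$name, edits = t$edits
  )
}

new_construct <- function(name, sequence, scaffold, edits) {
  structure(
    list(name = name, sequence = sequence, scaffold = scaffold, edits = edits),
    class = "construct"
  )
}

#' @export
print.construct <- function(x, ...) {
  cat(
    "<construct> ", x$name, " (", nchar(x$sequence), " aa, scaffold ",
    x$scaffold, ", ", nrow(x$edits), " edits)\n",
    sep = ""
  )
  invisible(x)
}

#' Replay an edit list on a template
#'
#' Applies a construct's recorded edits to the unedited template sequence
#' and returns the resulting sequence. For every construct this must
#' reproduce the construct sequence byte for byte.
#'
#' @param template The unedited `scaffold_template` the edits were made on.
#' @param edits An edit tibble (`construct$edits`).
#' @return The replayed sequence string.
#' @export
replay_edits <- function(template, edits) {
  seq <- template$sequence
  for (i in seq_len(nrow(edits))) {
    e <- edits[i, ]
    seq <- switch(e$kind,
      truncate_n = {
        if (substr(seq, 1, e$position) != e$before) {
          abort("replay mismatch in truncate_n")
        }
        substr(seq, e$position + 1L, nchar(seq))
      },
      substitute = {
        if (substr(seq, e$position, e$position) != e$before) {
          abort("replay mismatch in substitute")
        }
        paste0(
          substr(seq, 1, e$position - 1L), e$after,
          substr(seq, e$position + 1L, nchar(seq))
        )
      },
      replace_loop = ,
      graft = {
        end <- e$position + nchar(e$before) - 1L
        if (substr(seq, e$position, end) != e$before) {
          abort(paste0("replay mismatch in ", e$kind))
        }
        paste0(
          substr(seq, 1, e$position - 1L), e$after,
          substr(seq, end + 1L, nchar(seq))
        )
      },
      abort(paste0("unknown edit kind: ", e$kind))
    )
  }
  seq
}
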