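#' Enumerate single-graft scaffold variants
#'
#' Builds the Cartesian product of graft sites and insert sequences, one
#' graft per construct with all other sites untouched, in deterministic
#' site-major, insert-minor order.
#'
#' @param t A `scaffold_template`.
#' @param inserts Character vector of insert sequences (non-empty).
#' @param sites Site names to graft into (non-empty).
#' @param mode Graft mode for every construct (`"core"` or `"full_loop"`).
#' @return A list of `construct` objects with unique names.
#' @export
enumerate_variants <- function(t, inserts, sites = names(t$sites),
                               mode = "core") {
  if (length(inserts) == 0) abort("no inserts supplied")
  if (length(sites) == 0) abort("no sites supplied")
  out <- list()
  for (site in sites) {
    for (insert in inserts) {
      out[[length(out) + 1L]] <- graft(t, site, insert, mode = mode)
    }
  }
  names(out) <- vapply(out, function(x) x$name, character(1))
  if (anyDuplicated(names(out))) {
    abort(paste0(
      "duplicate construct names: ",
      paste(unique(names(out)[duplicated(names(out))]), collapse = ", ")
    ))
  }
  out
}

#' Graft a design panel into a scaffold
#'
#' Produces one construct per designed window of an epitope panel, plus a
#' negative-control construct carrying the 9-residue small-side-chain
#' sequence, named `DesAb_<start>-<end>` and `DesAb_neg`. For a
#' disulfide-engineered single-domain scaffold, the template must already
#' carry its cysteine substitutions (no cysteine may remain at a numbered
#' position).
#'
#' @param panel An `epitope_panel` from [scan_epitopes()].
#' @param t The (engineered) `scaffold_template`.
#' @param site Graft site, default the first site of the template.
#' @param mode Graft mode (the designed CDR3 architecture is
#'   `"full_loop"`: `GS<paratope>EEE`).
#' @param negative_length Length of the negative-control insert.
#' @return A list of `construct` objects.
#' @export
build_panel_constructs <- function(panel, t, site = names(t$sites)[1],
                                   mode = "full_loop", negative_length = 9L) {
  if (nrow(panel) == 0) abort("panel is empty")
  cys_left <- names(t$numbered)[
    startsWith(names(t$numbered), "C") &
      substr(t$sequence, t$numbered, t$numbered) == "C"
  ]
  if (length(cys_left) > 0) {
    abort(paste0(
      "template still carries cysteines at ",
      paste(cys_left, collapse = ", "),
      "; apply substitute_cysteines() first"
    ))
  }
  designed <- filter(as_tibble(panel), !is.na(.data$paratope_seq))
  out <- purrr::pmap(
    designed[, c("label", "paratope_seq")],
    function(label, paratope_seq) {
      graft(t, site, paratope_seq, mode = mode, label = label)
    }
  )
  out <- c(out, list(
    graft(t, site, make_negative_control(negative_length),
      mode = mode, label = "neg"
    )
  ))
  names(out) <- vapply(out, function(x) x$name, character(1))
  out
}

#' Construct panels as tibbles and files
#'
#' `construct_manifest()` flattens a list of constructs into a manifest
#' tibble (name, scaffold, length, sequence, edit summary);
#' `write_constructs_fasta()` writes one FASTA record per construct with
#' the construct name as header; `write_manifest()` writes the manifest
#' as TSV.
#'
#' @param constructs A list of `construct` objects.
#' @return A tibble with one row per construct.
#' @export
construct_manifest <- function(constructs) {
  purrr::map(constructs, function(x) {
    tibble(
      name = x$name, scaffold = x$scaffold, length = nchar(x$sequence),
      sequence = x$sequence,
      edits = paste(
        purrr::pmap_chr(
          x$edits[, c("kind", "site", "position", "after")],
          function(kind, site, position, after) {
            paste0(
              kind, "[", ifelse(is.na(site), position, site), ":",
              after, "]"
            )
          }
        ),
        collapse = ";"
      )
    )
  }) |> bind_rows()
}

#' @rdname construct_manifest
#' @param path Output file path.
#' @export
write_constructs_fasta <- function(constructs, path) {
  seqs <- Biostrings::AAStringSet(
    stats::setNames(
      vapply(constructs, function(x) x$sequence, character(1)),
      vapply(constructs, function(x) x$name, character(1))
    )
  )
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' @rdname construct_manifest
#' @export
write_manifest <- function(constructs, path) {
  readr::write_tsv(construct_manifest(constructs), path)
  invisible(path)
}

#' Read a target sequence from FASTA
#'
#' @param path FASTA file with at least one record; the first is used.
#' @return Named character scalar.
#' @export
read_target_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0) abort(paste0("no sequences in ", path))
  stats::setNames(
    as.character(seqs[[1]]),
    strsplit(names(seqs)[1], "\\s+")[[1]][1]
  )
}
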