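#' Plant complementary beta-sheet fixtures
#'
#' Builds synthetic two-strand antiparallel sheets in which chain A
#' carries a chosen target-side fragment and chain B a complementary
#' strand, so that mining the structures provably recovers a stated
#' (target fragment -> complementary fragment) mapping. Complementary
#' sequences are drawn at random (reproducibly under `seed`) from the
#' standard alphabet without proline, which lacks the backbone amide
#' donor that carries the ladder. Long fragments can be split into two
#' overlapping sub-fragments planted in separate sheets, which exercises
#' the cascade's fragment-linking step.
#'
#' @param targets Character vector of target-side fragment sequences
#'   (optionally named; names become fixture labels).
#' @param seed Integer seed fixing the complementary sequences.
#' @param comp_seqs Optional character vector overriding the random
#'   complementary sequences (same length as `targets`).
#' @param split Logical (recycled): split the planted pair into two
#'   overlapping sheets instead of one full-length sheet.
#' @param overlap Overlap between split sub-fragments (>= 2).
#' @param geometry A [sheet_geometry()].
#' @return A list with `structures` (list of `protein_structure`) and
#'   `manifest` (tibble: `label`, `target_frag`, `comp_frag`,
#'   `structure_id`).
#' @export
plant_complement_sheets <- function(targets, seed = 1L, comp_seqs = NULL,
                                    split = FALSE, overlap = 2L,
                                    geometry = sheet_geometry()) {
  if (length(targets) == 0) abort("no target fragments supplied")
  labels <- names(targets) %||% paste0("frag", seq_along(targets))
  labels[labels == ""] <- paste0("frag", which(labels == ""))
  if (is.null(comp_seqs)) {
    comp_seqs <- with_local_seed(seed, {
      vapply(
        nchar(targets),
        function(n) random_peptide(n, exclude = "P"), character(1)
      )
    })
  }
  if (length(comp_seqs) != length(targets)) {
    abort("comp_seqs must match targets in length")
  }
  split <- rep_len(split, length(targets))

  structures <- list()
  manifest <- list()
  for (k in seq_along(targets)) {
    tseq <- toupper(targets[[k]])
    cseq <- toupper(comp_seqs[[k]])
    if (nchar(cseq) != nchar(tseq)) {
      abort("complementary sequence length must match target")
    }
    pieces <- if (split[k] && nchar(tseq) >= 2 * overlap + 2) {
      mid <- ceiling(nchar(tseq) / 2)
      list(
        c(1L, min(nchar(tseq), mid + ceiling(overlap / 2))),
        c(max(1L, mid - floor(overlap / 2) + 1L), nchar(tseq))
      )
    } else {
      list(c(1L, nchar(tseq)))
    }
    for (p in seq_along(pieces)) {
      rng <- pieces[[p]]
      tfrag <- substr(tseq, rng[1], rng[2])
      # antiparallel partner: chain B runs N->C against the reversed window
      cfrag_aligned <- substr(cseq, rng[1], rng[2])
      cfrag <- paste(rev(strsplit(cfrag_aligned, "")[[1]]), collapse = "")
      sid <- paste0(
        "planted_", labels[k],
        if (length(pieces) > 1) paste0("_part", p) else ""
      )
      sheet <- build_ideal_sheet(
        list(
          strand_spec(tfrag, "antiparallel"),
          strand_spec(cfrag, "antiparallel")
        ),
        geometry = geometry, structure_id = sid
      )
      structures[[length(structures) + 1L]] <- sheet
      manifest[[length(manifest) + 1L]] <- tibble(
        label = labels[k], part = p,
        target_frag = tfrag, comp_frag = cfrag, structure_id = sid
      )
    }
  }
  list(structures = structures, manifest = bind_rows(manifest))
}

#' Write sheet fixtures to a directory
#'
#' Generates planted-complement sheet fixtures for a set of target
#' fragments, writes one PDB file per structure plus a `manifest.tsv`
#' recording the planted pairs, deterministically under `seed`.
#'
#' @inheritParams plant_complement_sheets
#' @param dir Output directory.
#' @param force Overwrite a non-empty directory.
#' @return The manifest tibble (with a `file` column), invisibly.
#' @export
write_sheet_fixtures <- function(targets, dir, seed = 1L, comp_seqs = NULL,
                                 split = FALSE, force = FALSE) {
  if (dir.exists(dir) && length(dir(dir)) > 0 && !force) {
    abort(paste0("output directory not empty: ", dir, " (use force = TRUE)"))
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  planted <- plant_complement_sheets(targets,
    seed = seed,
    comp_seqs = comp_seqs, split = split
  )
  files <- vapply(planted$structures, function(s) {
    f <- file.path(dir, paste0(attr(s, "structure_id"), ".pdb"))
    write_pdb(s, f)
    f
  }, character(1))
  manifest <- mutate(planted$manifest, file = basename(files))
  readr::write_tsv(manifest, file.path(dir, "manifest.tsv"))
  invisible(manifest)
}

# reproducible draws without disturbing the caller's RNG state
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

random_peptide <- function(n, exclude = character()) {
  alphabet <- setdiff(AA_STANDARD, strsplit(paste(exclude, collapse = ""), "")[[1]])
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
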