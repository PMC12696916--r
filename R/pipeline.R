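#' Read scaffold templates from a YAML config
#'
#' The config is a structured document with a top-level `scaffolds` map;
#' each entry has `sequence`, optional `sites` (name -> `[start, end]`),
#' optional `numbered` (label -> number), `numbering_offset` and
#' `n_terminal_region`. See the shipped
#' `extdata/scaffolds_synthetic.yaml` for the format.
#'
#' @param path YAML file path.
#' @return A named list of [scaffold_template()] objects.
#' @export
read_scaffold_config <- function(path) {
  if (!file.exists(path)) abort(paste0("scaffold config not found: ", path))
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$scaffolds)) abort("scaffold config needs a 'scaffolds' map")
  purrr::imap(cfg$scaffolds, function(entry, nm) {
    scaffold_template(
      name = nm,
      sequence = entry$sequence,
      sites = purrr::map(entry$sites %||% list(), unlist),
      numbered = unlist(entry$numbered %||% list()),
      numbering_offset = entry$numbering_offset %||% 0L,
      n_terminal_region = entry$n_terminal_region
    )
  })
}

#' @rdname read_scaffold_config
#' @export
example_scaffolds <- function() {
  read_scaffold_config(
    system.file("extdata", "scaffolds_synthetic.yaml", package = "cascadesign")
  )
}

#' Run configuration for the design pipeline
#'
#' Collects and validates every knob of the end-to-end pipeline: the
#' structure inputs (PDB paths, in-memory structures, or a fixture
#' specification), the mining, cascade and scan parameters, the scaffold
#' template, and the output directory. All randomness is confined to
#' fixture generation and fixed by `seed`.
#'
#' @param structures Character vector of PDB paths, a list of
#'   `protein_structure` objects, or `NULL` when `fixture_targets` is
#'   given.
#' @param fixture_targets Optional named character vector of target-side
#'   fragments; when given, planted sheet fixtures are generated as the
#'   structure input (names label the fixtures).
#' @param target_seq Target sequence (defaults to the shipped IAPP
#'   fixture).
#' @param target_id Target identifier.
#' @param windows Window tibble or labels; `NULL` auto-enumerates.
#' @param mask Masked residue indices.
#' @param min_len,max_len Library window bounds.
#' @param hbond_cutoff Hydrogen-bond energy threshold, kcal/mol.
#' @param overlap_min,beam_width,max_candidates Cascade parameters.
#' @param orientations Orientations searched by the cascade.
#' @param scaffold A `scaffold_template`, or name of a shipped template
#'   (`"sdAb"` is engineered with the `"AA"` cysteine scheme before
#'   grafting).
#' @param graft_site,graft_mode Grafting parameters.
#' @param out_dir Output directory (created when missing).
#' @param seed Integer seed for fixture generation.
#' @param strict Fail (error) when any window has no feasible design.
#' @return A validated `run_config` list.
#' @export
run_config <- function(structures = NULL, fixture_targets = NULL,
                       target_seq = NULL, target_id = NULL,
                       windows = NULL, mask = 1:8,
                       min_len = 3L, max_len = 9L, hbond_cutoff = -0.5,
                       overlap_min = 2L, beam_width = 64L,
                       max_candidates = 10L,
                       orientations = c("antiparallel", "parallel"),
                       scaffold = "sdAb", graft_site = NULL,
                       graft_mode = "full_loop",
                       out_dir = NULL, seed = 1L, strict = FALSE) {
  if (is.null(structures) && is.null(fixture_targets)) {
    abort("need 'structures' (PDB paths) or 'fixture_targets'")
  }
  if (is.null(target_seq)) {
    tgt <- iapp_sequence()
    target_seq <- unname(tgt)
    target_id <- target_id %||% names(tgt)
  }
  target_id <- target_id %||% "target"
  if (min_len < 2 || max_len < min_len) abort("need max_len >= min_len >= 2")
  if (hbond_cutoff >= 0) abort("hbond_cutoff must be negative")
  if (overlap_min < 1 || beam_width < 1 || max_candidates < 1) {
    abort("cascade parameters must be positive")
  }
  if (is.character(scaffold)) {
    templates <- example_scaffolds()
    if (!scaffold %in% names(templates)) {
      abort(paste0("unknown shipped scaffold: ", scaffold))
    }
    tpl <- templates[[scaffold]]
    if (scaffold == "sdAb") tpl <- substitute_cysteines(tpl, "AA")
    scaffold <- tpl
  }
  if (!inherits(scaffold, "scaffold_template")) {
    abort("scaffold must be a scaffold_template or shipped template name")
  }
  structure(
    list(
      structures = structures, fixture_targets = fixture_targets,
      target_seq = toupper(target_seq), target_id = target_id,
      windows = windows, mask = as.integer(mask),
      min_len = as.integer(min_len), max_len = as.integer(max_len),
      hbond_cutoff = hbond_cutoff, overlap_min = as.integer(overlap_min),
      beam_width = as.integer(beam_width),
      max_candidates = as.integer(max_candidates),
      orientations = orientations, scaffold = scaffold,
      graft_site = graft_site %||% names(scaffold$sites)[1],
      graft_mode = graft_mode, out_dir = out_dir,
      seed = as.integer(seed), strict = isTRUE(strict)
    ),
    class = "run_config"
  )
}

#' Run the design pipeline end to end
#'
#' Mines the input structures, builds the fragment library, scans the
#' target with epitope windows, grafts the top design per window (plus
#' the negative control) into the scaffold, and optionally writes the
#' library TSV, panel TSV, construct FASTA and construct manifest into
#' the configured output directory. Deterministic: identical
#' configuration and seed give identical outputs.
#'
#' @param config A [run_config()].
#' @return A list with `library`, `panel`, `constructs`, `manifest`, and
#'   (when fixtures were generated) `fixture_manifest`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) abort("config must be a run_config")

  structures <- config$structures
  fixture_manifest <- NULL
  if (!is.null(config$fixture_targets)) {
    planted <- plant_complement_sheets(config$fixture_targets,
      seed = config$seed
    )
    structures <- c(
      if (is.character(structures)) purrr::map(structures, read_pdb) else structures,
      planted$structures
    )
    fixture_manifest <- planted$manifest
  } else if (is.character(structures)) {
    structures <- purrr::map(structures, read_pdb)
  }

  lib <- build_library(structures,
    min_len = config$min_len, max_len = config$max_len,
    cutoff = config$hbond_cutoff, symmetric = TRUE
  )

  windows <- config$windows
  if (is.null(windows)) {
    windows <- enumerate_windows(nchar(config$target_seq), mask = config$mask)
  }
  windows <- validate_windows(windows, nchar(config$target_seq), config$mask)

  panel <- scan_epitopes(
    config$target_seq, windows, lib,
    target_id = config$target_id, mask = config$mask,
    orientations = config$orientations,
    overlap_min = config$overlap_min, beam_width = config$beam_width,
    max_candidates = config$max_candidates
  )
  undesigned <- sum(is.na(panel$paratope_seq))
  if (undesigned > 0 && config$strict) {
    abort(paste0(undesigned, " window(s) have no feasible design (strict mode)"))
  }

  constructs <- build_panel_constructs(
    panel, config$scaffold,
    site = config$graft_site, mode = config$graft_mode
  )
  manifest <- construct_manifest(constructs)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_library(lib, file.path(config$out_dir, "library.tsv"))
    write_panel(panel, file.path(config$out_dir, "panel.tsv"))
    write_constructs_fasta(
      constructs, file.path(config$out_dir, "constructs.fasta")
    )
    write_manifest(constructs, file.path(config$out_dir, "constructs.tsv"))
    if (!is.null(fixture_manifest)) {
      readr::write_tsv(
        fixture_manifest, file.path(config$out_dir, "fixtures.tsv")
      )
    }
  }

  list(
    library = lib, panel = panel, constructs = constructs,
    manifest = manifest, fixture_manifest = fixture_manifest
  )
}
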