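#' Protein structures as residue-level tibbles
#'
#' A `protein_structure` is a tibble with one row per residue and the
#' backbone atom coordinates needed for beta-strand mining. Columns:
#'
#' * `chain` — chain identifier (single character in PDB output),
#' * `resi` — residue sequence number, 1-based and strictly increasing
#'   within a chain,
#' * `aa` — one-letter amino-acid code; nonstandard residues are `"X"`,
#' * `eligible` — `TRUE` when all four backbone atoms (N, CA, C, O) are
#'   present; only eligible residues take part in strand mining,
#' * `n_x` ... `o_z` — Cartesian coordinates of the N, CA, C and O backbone
#'   atoms, in Angstrom.
#'
#' The structure identifier is carried in the `structure_id` attribute.
#'
#' @param residues A data frame with the columns listed above (the
#'   coordinate columns may contain `NA` for missing atoms).
#' @param structure_id Character scalar naming the structure.
#' @return A `protein_structure` tibble.
#' @export
new_structure <- function(residues, structure_id = "structure") {
  res <- as_tibble(residues)
  needed <- c("chain", "resi", "aa", coord_cols())
  missing <- setdiff(needed, names(res))
  if (length(missing) > 0) {
    abort(paste0("missing residue columns: ", paste(missing, collapse = ", ")))
  }
  res$resi <- as.integer(res$resi)
  res$eligible <- stats::complete.cases(res[coord_cols()])
  bad_aa <- setdiff(unique(res$aa), c(AA_STANDARD, "X"))
  if (length(bad_aa) > 0) {
    abort(paste0("invalid amino-acid codes: ", paste(bad_aa, collapse = ", ")))
  }
  incr <- vapply(
    split(res$resi, res$chain),
    function(x) all(diff(x) > 0),
    logical(1)
  )
  if (!all(incr)) {
    abort("residue numbers must be strictly increasing within each chain")
  }
  res <- res[, c("chain", "resi", "aa", "eligible", coord_cols())]
  structure(res,
    structure_id = structure_id,
    class = c("protein_structure", class(res))
  )
}

coord_cols <- function() {
  as.vector(t(outer(c("n", "ca", "c", "o"), c("x", "y", "z"), paste, sep = "_")))
}

#' @export
print.protein_structure <- function(x, ...) {
  ch <- table(x$chain)
  cat(
    "<protein_structure> ", attr(x, "structure_id"), ": ",
    length(ch), " chain(s), ", nrow(x), " residues (",
    sum(x$eligible), " eligible)\n",
    sep = ""
  )
  NextMethod()
}

#' Extract a chain sequence
#'
#' @param structure A [new_structure()] tibble.
#' @param chain Chain identifier.
#' @return One-letter sequence string of the chain, N to C.
#' @export
chain_sequence <- function(structure, chain) {
  paste(structure$aa[structure$chain == chain], collapse = "")
}

#' Read a protein structure from a PDB file
#'
#' Parses ATOM records (first alternate location only, hydrogens ignored)
#' and keeps the N, CA, C and O backbone atoms of each residue. Residues
#' missing any backbone atom are retained but flagged ineligible for
#' mining; residues with a nonstandard identity are recorded as `"X"`.
#'
#' @param path Path to a PDB file containing ATOM records.
#' @param structure_id Identifier for the returned structure; defaults to
#'   the file name without extension.
#' @return A `protein_structure` tibble.
#' @export
read_pdb <- function(path, structure_id = NULL) {
  if (!file.exists(path)) {
    abort(paste0("cannot read PDB file: ", path))
  }
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, verbose = FALSE)),
    error = function(e) abort(paste0("no ATOM records in ", path))
  )
  atoms <- as_tibble(pdb$atom)
  atoms <- filter(atoms, .data$type == "ATOM")
  if (nrow(atoms) == 0) {
    abort(paste0("no ATOM records in ", path))
  }
  # first-conformer semantics for alternate locations
  if ("alt" %in% names(atoms)) {
    atoms <- filter(atoms, is.na(.data$alt) | .data$alt %in% c("", "A"))
  }
  atoms <- filter(atoms, .data$elety %in% c("N", "CA", "C", "O"))
  atoms$chain[is.na(atoms$chain)] <- "A"

  wide <- atoms |>
    distinct(.data$chain, .data$resno, .data$elety, .keep_all = TRUE) |>
    mutate(elety = tolower(.data$elety)) |>
    tidyr::pivot_wider(
      id_cols = c("chain", "resno", "resid"),
      names_from = "elety",
      values_from = c("x", "y", "z"),
      names_glue = "{elety}_{.value}"
    )
  for (col in coord_cols()) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }
  res <- tibble(
    chain = wide$chain,
    resi = as.integer(wide$resno),
    aa = aa_three_to_one(wide$resid)
  )
  res <- dplyr::bind_cols(res, wide[coord_cols()])
  res <- arrange(res, .data$chain, .data$resi)
  new_structure(
    res,
    structure_id = structure_id %||% sub("\\.[^.]*$", "", basename(path))
  )
}

aa_three_to_one <- function(resid) {
  one <- suppressWarnings(bio3d::aa321(resid))
  one[!one %in% AA_STANDARD] <- "X"
  one
}

aa_one_to_three <- function(aa) {
  three <- suppressWarnings(bio3d::aa123(aa))
  three[aa == "X" | is.na(three) | three == "aa123"] <- "UNK"
  three
}

#' Write a protein structure to a PDB file
#'
#' Emits standard ATOM records (N, CA, C, O per residue, coordinates to
#' three decimals), preserving chain identifiers. Round trips with
#' [read_pdb()] up to coordinate precision.
#'
#' @param structure A `protein_structure` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  if (nrow(structure) == 0) {
    abort("nothing to write: structure has no residues")
  }
  rec <- list()
  serial <- 0L
  for (i in seq_len(nrow(structure))) {
    row <- structure[i, ]
    for (atom in c("N", "CA", "C", "O")) {
      pre <- tolower(atom)
      xyz <- c(
        row[[paste0(pre, "_x")]], row[[paste0(pre, "_y")]],
        row[[paste0(pre, "_z")]]
      )
      if (anyNA(xyz)) next
      serial <- serial + 1L
      rec[[serial]] <- sprintf(
        "ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, sprintf(" %-3s", atom), aa_one_to_three(row$aa),
        substr(row$chain, 1, 1), row$resi, xyz[1], xyz[2], xyz[3],
        1.00, 0.00, substr(atom, 1, 1)
      )
    }
  }
  con <- tryCatch(
    file(path, "w"),
    error = function(e) abort(paste0("cannot write PDB file: ", path)),
    warning = function(w) abort(paste0("cannot write PDB file: ", path))
  )
  on.exit(close(con))
  writeLines(c(unlist(rec), "END"), con)
  invisible(path)
}

#' Apply a rigid motion to a structure
#'
#' Rotates (about the origin) and translates all backbone coordinates.
#' Strand mining results are invariant under this operation.
#'
#' @param structure A `protein_structure` tibble.
#' @param rotation 3x3 rotation matrix.
#' @param translation Length-3 numeric offset in Angstrom.
#' @return The transformed `protein_structure`.
#' @export
transform_structure <- function(structure, rotation = diag(3),
                                translation = c(0, 0, 0)) {
  for (atom in c("n", "ca", "c", "o")) {
    cols <- paste0(atom, c("_x", "_y", "_z"))
    xyz <- as.matrix(structure[cols])
    xyz <- sweep(xyz %*% t(rotation), 2, translation, "+")
    structure[cols] <- as_tibble(xyz, .name_repair = ~cols)
  }
  structure
}
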