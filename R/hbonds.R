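#' Detect backbone hydrogen bonds
#'
#' Applies the DSSP electrostatic criterion to all backbone N-H...O=C
#' donor/acceptor pairs. The amide hydrogen is not read from the file but
#' reconstructed from the donor N, its CA and the preceding residue's C
#' (placed 1.0 A from N along the externally bisecting direction). The
#' interaction energy is
#'
#'   E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)  kcal/mol
#'
#' and a bond is called when E < `cutoff`. Chain-first residues and
#' prolines carry no amide hydrogen and never donate. Within a chain,
#' donor and acceptor must be at least 3 residues apart.
#'
#' @param structure A `protein_structure` tibble.
#' @param cutoff Energy threshold in kcal/mol (default -0.5).
#' @return A tibble with columns `donor_chain`, `donor_resi`,
#'   `acceptor_chain`, `acceptor_resi`, `energy`; zero rows when no bond
#'   meets the criterion.
#' @export
detect_hbonds <- function(structure, cutoff = -0.5) {
  don <- donor_table(structure)
  acc <- acceptor_table(structure)
  empty <- tibble(
    donor_chain = character(), donor_resi = integer(),
    acceptor_chain = character(), acceptor_resi = integer(),
    energy = double()
  )
  if (nrow(don) == 0 || nrow(acc) == 0) {
    return(empty)
  }

  # distance prefilter on N...O (DSSP energies beyond 6 A never reach the
  # cutoff); candidate pairs evaluated vectorised
  dn <- as.matrix(don[c("n_x", "n_y", "n_z")])
  ao <- as.matrix(acc[c("o_x", "o_y", "o_z")])
  d2 <- outer(rowSums(dn^2), rowSums(ao^2), "+") - 2 * dn %*% t(ao)
  cand <- which(d2 < 6.0^2, arr.ind = TRUE)
  if (nrow(cand) == 0) {
    return(empty)
  }

  di <- cand[, 1]
  ai <- cand[, 2]
  same_res <- don$chain[di] == acc$chain[ai] & don$resi[di] == acc$resi[ai]
  too_close <- don$chain[di] == acc$chain[ai] &
    abs(don$resi[di] - acc$resi[ai]) < 3
  keep <- !(same_res | too_close)
  di <- di[keep]
  ai <- ai[keep]
  if (length(di) == 0) {
    return(empty)
  }

  e <- dssp_energy(
    as.matrix(don[di, c("n_x", "n_y", "n_z")]),
    as.matrix(don[di, c("h_x", "h_y", "h_z")]),
    as.matrix(acc[ai, c("c_x", "c_y", "c_z")]),
    as.matrix(acc[ai, c("o_x", "o_y", "o_z")])
  )
  hit <- e < cutoff
  tibble(
    donor_chain = don$chain[di][hit],
    donor_resi = don$resi[di][hit],
    acceptor_chain = acc$chain[ai][hit],
    acceptor_resi = acc$resi[ai][hit],
    energy = e[hit]
  ) |>
    arrange(
      .data$donor_chain, .data$donor_resi,
      .data$acceptor_chain, .data$acceptor_resi
    )
}

# DSSP electrostatic energy, kcal/mol; inputs are row-matched matrices
dssp_energy <- function(n, h, c, o) {
  rd <- function(a, b) sqrt(rowSums((a - b)^2))
  27.888 * (1 / rd(o, n) + 1 / rd(c, h) - 1 / rd(o, h) - 1 / rd(c, n))
}

# eligible donors with reconstructed amide H
donor_table <- function(structure) {
  res <- filter(structure, .data$eligible)
  if (nrow(res) == 0) {
    return(res[0, ])
  }
  prev <- res |>
    mutate(resi = .data$resi + 1L) |>
    select("chain", "resi", pc_x = "c_x", pc_y = "c_y", pc_z = "c_z")
  don <- res |>
    left_join(prev, by = c("chain", "resi")) |>
    filter(!is.na(.data$pc_x), .data$aa != "P")
  if (nrow(don) == 0) {
    return(don)
  }
  np <- as.matrix(don[c("n_x", "n_y", "n_z")])
  u1 <- unit_rows(np - as.matrix(don[c("pc_x", "pc_y", "pc_z")]))
  u2 <- unit_rows(np - as.matrix(don[c("ca_x", "ca_y", "ca_z")]))
  hdir <- u1 + u2
  hlen <- sqrt(rowSums(hdir^2))
  ok <- hlen > 1e-6
  don <- don[ok, ]
  h <- np[ok, , drop = FALSE] + hdir[ok, , drop = FALSE] / hlen[ok]
  don$h_x <- h[, 1]
  don$h_y <- h[, 2]
  don$h_z <- h[, 3]
  don
}

acceptor_table <- function(structure) {
  filter(structure, .data$eligible)
}

unit_rows <- function(m) {
  m / sqrt(rowSums(m^2))
}
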