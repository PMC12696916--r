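#' Detect beta-strand pairings
#'
#' Finds maximal contiguous runs of residue pairs joined by a backbone
#' hydrogen-bond ladder and reports each run as a paired fragment. Each
#' hydrogen bond supports one residue-to-residue pairing diagonal:
#' antiparallel diagonals have constant `i + j`, parallel diagonals
#' constant `j - i` (the slanted parallel ladder bonds are attributed to
#' the diagonal by donor side). Bonded pairs on a diagonal are clustered
#' (gaps of at most one unbonded pair are bridged); a cluster qualifies as
#' a ladder when it carries at least two hydrogen bonds, and a run is
#' extended by the terminal pleat pair at each end where both partners
#' remain in-chain (directly bonded pairs alternate along a ladder, so
#' the outermost pair of a pleat carries no bond of its own). Runs
#' shorter than `min_len` are discarded.
#'
#' Orientation is assigned from the strand direction vectors: the sign of
#' the summed dot products of consecutive CA-CA steps along the two sides.
#'
#' @param structure A `protein_structure` tibble.
#' @param min_len Minimum fragment length (>= 2); default 3.
#' @param cutoff Hydrogen-bond energy threshold passed to [detect_hbonds()].
#' @return A tibble of paired fragments with columns `source_id`,
#'   `target_chain`, `target_start`, `target_end`, `target_seq`,
#'   `comp_chain`, `comp_start`, `comp_end`, `comp_seq`, `orientation`,
#'   `register`, `n_hbonds`. `comp_seq` is always reported N to C of its
#'   own chain; for antiparallel pairs target residue `i` faces comp
#'   residue `register - i`, for parallel pairs residue `i + register`.
#' @export
detect_strand_pairs <- function(structure, min_len = 3L, cutoff = -0.5) {
  if (min_len < 2) abort("min_len must be at least 2")
  hb <- detect_hbonds(structure, cutoff = cutoff)
  out <- empty_pairs()
  if (nrow(hb) == 0) {
    return(out)
  }
  src <- attr(structure, "structure_id")
  chains <- split(structure, structure$chain)

  # orient every bond so side 1 precedes side 2 (chain order, then resi)
  flip <- hb$donor_chain > hb$acceptor_chain |
    (hb$donor_chain == hb$acceptor_chain & hb$donor_resi > hb$acceptor_resi)
  b <- tibble(
    c1 = ifelse(flip, hb$acceptor_chain, hb$donor_chain),
    r1 = ifelse(flip, hb$acceptor_resi, hb$donor_resi),
    c2 = ifelse(flip, hb$donor_chain, hb$acceptor_chain),
    r2 = ifelse(flip, hb$donor_resi, hb$acceptor_resi),
    donor_side = ifelse(flip, 2L, 1L)
  )

  groups <- split(b, paste(b$c1, b$c2, sep = "\r"))
  frags <- list()
  for (grp in groups) {
    c1 <- grp$c1[1]
    c2 <- grp$c2[1]
    intra <- c1 == c2
    res1 <- chains[[c1]]
    res2 <- chains[[c2]]

    # antiparallel diagonals: every bond on diagonal s = i + j supports
    # the pair (i, s - i)
    anti <- mutate(grp, diag = .data$r1 + .data$r2, pos = .data$r1)
    for (s in unique(anti$diag)) {
      d <- filter(anti, .data$diag == s)
      frags <- c(frags, diagonal_runs(
        d$pos, nrow(d), s, "antiparallel",
        res1, res2, c1, c2, intra, min_len, src, extend = TRUE
      ))
    }

    # parallel diagonals: a bond (i, j) with the donor on side 1 supports
    # pairing offset j - i + 1; donor on side 2 supports j - i - 1
    par <- mutate(grp,
      diag = .data$r2 - .data$r1 + ifelse(.data$donor_side == 1L, 1L, -1L),
      pos = .data$r1
    )
    if (intra) par <- filter(par, .data$diag >= 3L)
    for (dd in unique(par$diag)) {
      d <- filter(par, .data$diag == dd)
      frags <- c(frags, diagonal_runs(
        d$pos, nrow(d), dd, "parallel",
        res1, res2, c1, c2, intra, min_len, src, extend = TRUE
      ))
    }
  }
  if (length(frags) == 0) {
    return(out)
  }
  bind_rows(frags) |>
    arrange(
      .data$target_chain, .data$target_start,
      .data$comp_chain, .data$comp_start
    )
}

empty_pairs <- function() {
  tibble(
    source_id = character(),
    target_chain = character(), target_start = integer(),
    target_end = integer(), target_seq = character(),
    comp_chain = character(), comp_start = integer(),
    comp_end = integer(), comp_seq = character(),
    orientation = character(), register = integer(),
    n_hbonds = integer()
  )
}

# cluster bonded pair positions on one diagonal into ladder runs and
# convert qualifying runs into paired-fragment rows
diagonal_runs <- function(pos, n_bonds_total, diag, orientation,
                          res1, res2, c1, c2, intra, min_len, src, extend) {
  counts <- table(pos)
  pos <- sort(unique(pos))
  # split where consecutive bonded pairs are more than 2 apart
  cl <- cumsum(c(1L, diff(pos) > 2))
  out <- list()
  for (k in unique(cl)) {
    p <- pos[cl == k]
    nb <- sum(counts[as.character(p)])
    if (nb < 2) next # isolated single H-bonds never seed a fragment
    a <- min(p)
    bnd <- max(p)
    if (extend) {
      if (pair_in_chain(a - 1L, diag, orientation, res1, res2, intra)) {
        a <- a - 1L
      }
      if (pair_in_chain(bnd + 1L, diag, orientation, res1, res2, intra)) {
        bnd <- bnd + 1L
      }
    }
    run <- trim_run(a, bnd, diag, orientation, res1, res2, intra)
    if (is.null(run) || run[2] - run[1] + 1L < min_len) next
    out[[length(out) + 1L]] <- fragment_row(
      run[1], run[2], diag, orientation, res1, res2, c1, c2, src,
      n_hbonds = as.integer(nb)
    )
  }
  out
}

partner_of <- function(i, diag, orientation) {
  if (orientation == "antiparallel") diag - i else i + diag
}

pair_in_chain <- function(i, diag, orientation, res1, res2, intra) {
  j <- partner_of(i, diag, orientation)
  ok <- i %in% res1$resi[res1$eligible] & j %in% res2$resi[res2$eligible]
  if (intra) ok <- ok && (j - i >= 2L)
  isTRUE(ok)
}

# restrict a run to pair positions whose residues exist and are eligible on
# both sides (contiguously); returns c(start, end) or NULL
trim_run <- function(a, b, diag, orientation, res1, res2, intra) {
  ok <- vapply(
    a:b, pair_in_chain, logical(1),
    diag = diag, orientation = orientation,
    res1 = res1, res2 = res2, intra = intra
  )
  if (!all(ok)) {
    # keep the longest contiguous valid stretch
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    good <- which(r$values)
    if (length(good) == 0) {
      return(NULL)
    }
    gi <- good[which.max(r$lengths[good])]
    a2 <- (a:b)[starts[gi]]
    b2 <- (a:b)[ends[gi]]
    return(c(a2, b2))
  }
  c(a, b)
}

fragment_row <- function(a, b, diag, orientation, res1, res2, c1, c2, src,
                         n_hbonds) {
  idx1 <- match(a:b, res1$resi)
  tseq <- paste(res1$aa[idx1], collapse = "")
  if (orientation == "antiparallel") {
    jr <- sort(diag - c(a, b))
  } else {
    jr <- c(a, b) + diag
  }
  idx2 <- match(jr[1]:jr[2], res2$resi)
  cseq <- paste(res2$aa[idx2], collapse = "")
  ori <- orientation_from_vectors(res1, res2, a:b, jr[1]:jr[2], orientation)
  tibble(
    source_id = src %||% "structure",
    target_chain = c1, target_start = as.integer(a), target_end = as.integer(b),
    target_seq = tseq,
    comp_chain = c2, comp_start = as.integer(jr[1]),
    comp_end = as.integer(jr[2]), comp_seq = cseq,
    orientation = ori, register = as.integer(diag),
    n_hbonds = n_hbonds
  )
}

# orientation from strand direction vectors: sign of the summed dot
# products of consecutive CA steps taken along paired positions
orientation_from_vectors <- function(res1, res2, i_range, j_range, fallback) {
  if (length(i_range) < 2) {
    return(fallback)
  }
  ca1 <- as.matrix(res1[match(i_range, res1$resi), c("ca_x", "ca_y", "ca_z")])
  ca2 <- as.matrix(res2[match(j_range, res2$resi), c("ca_x", "ca_y", "ca_z")])
  if (fallback == "antiparallel") ca2 <- ca2[rev(seq_len(nrow(ca2))), , drop = FALSE]
  v1 <- diff(ca1)
  v2 <- diff(ca2)
  s <- sum(rowSums(v1 * v2))
  # v2 follows the pairing order; reversed traversal flips its sign
  if (fallback == "antiparallel") s <- -s
  if (s >= 0) "parallel" else "antiparallel"
}
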