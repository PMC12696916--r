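#' Assemble complementary peptides for an epitope (the cascade)
#'
#' Links overlapping library fragments into full-length complementary
#' peptides. Seeds are fragments whose target-side subsequence matches a
#' prefix of the epitope; extension fragments must start inside the
#' covered region, overlap it by at least `overlap_min` positions, and
#' agree exactly with the current complementary residues across the
#' overlap. A candidate is emitted only when every epitope position is
#' covered. Assembly never mixes orientations within one candidate.
#'
#' Candidates are de-duplicated by paratope sequence (keeping the best
#' supported variant) and ranked by complementarity score, then
#' solubility, then lexicographically; at most `max_candidates` are
#' returned. The search is breadth-limited to `beam_width` partial
#' assemblies per coverage depth, which is exhaustive whenever the number
#' of compatible partials stays below the beam width.
#'
#' @param lib A `fragment_library`.
#' @param epitope_seq Epitope sequence (no `'X'`).
#' @param orientations Orientations to design in; one candidate set per
#'   orientation, merged before ranking.
#' @param min_frag_len Minimum seed/extension fragment length; defaults to
#'   the library's `min_len`.
#' @param overlap_min Minimum overlap between consecutive fragments (>= 1).
#' @param beam_width Maximum partial assemblies kept per depth.
#' @param max_candidates Maximum designs returned.
#' @return A `paratope_designs` tibble with columns `epitope_seq`,
#'   `paratope_seq`, `orientation`, `c_score`, `solubility`, `support`
#'   (list of per-position counts) and `fragments` (list of the fragments
#'   used, as `target_subseq`, `comp_subseq`, `offset`).
#' @export
cascade_assemble <- function(lib, epitope_seq,
                             orientations = c("antiparallel", "parallel"),
                             min_frag_len = NULL, overlap_min = 2L,
                             beam_width = 64L, max_candidates = 10L) {
  epitope_seq <- toupper(epitope_seq)
  if (grepl("X", epitope_seq, fixed = TRUE)) {
    abort("epitope contains 'X'")
  }
  bad <- setdiff(strsplit(epitope_seq, "")[[1]], AA_STANDARD)
  if (length(bad) > 0) {
    abort(paste0("invalid residues in epitope: ", paste(bad, collapse = "")))
  }
  min_frag_len <- min_frag_len %||% attr(lib, "min_len")
  if (overlap_min < 1) abort("overlap_min must be >= 1")
  L <- nchar(epitope_seq)
  if (L < min_frag_len) abort("epitope shorter than min_frag_len")

  designs <- purrr::map(
    orientations,
    function(ori) {
      assemble_one_orientation(
        lib, epitope_seq, ori, min_frag_len, overlap_min, beam_width
      )
    }
  ) |> bind_rows()
  finalize_designs(designs, max_candidates)
}

finalize_designs <- function(designs, max_candidates) {
  if (nrow(designs) == 0) {
    return(new_paratope_designs(empty_designs()))
  }
  designs <- designs |>
    mutate(
      c_score = purrr::map_dbl(.data$support, complementarity_from_support),
      solubility = purrr::map_dbl(.data$paratope_seq, solubility_score)
    ) |>
    arrange(
      desc(.data$c_score), desc(.data$solubility),
      .data$paratope_seq, .data$orientation
    ) |>
    distinct(.data$paratope_seq, .keep_all = TRUE) |>
    utils::head(max_candidates)
  new_paratope_designs(designs)
}

empty_designs <- function() {
  tibble(
    epitope_seq = character(), paratope_seq = character(),
    orientation = character(), support = list(), fragments = list(),
    c_score = double(), solubility = double()
  )
}

new_paratope_designs <- function(x) {
  x <- as_tibble(x)
  cols <- c(
    "epitope_seq", "paratope_seq", "orientation", "c_score",
    "solubility", "support", "fragments"
  )
  x <- x[, intersect(cols, names(x))]
  structure(x, class = c("paratope_designs", setdiff(class(x), "paratope_designs")))
}

# beam-limited left-to-right assembly for one orientation
assemble_one_orientation <- function(lib, epitope_seq, orientation,
                                     min_frag_len, overlap_min, beam_width) {
  L <- nchar(epitope_seq)
  max_len <- min(attr(lib, "max_len"), L)
  lens <- seq(from = min_frag_len, to = max_len)
  if (length(lens) == 0) {
    return(empty_designs())
  }

  # all usable fragment placements: epitope window [a, b] -> comp residues
  # aligned to epitope positions
  placements <- list()
  for (l in lens) {
    for (a in seq_len(L - l + 1L)) {
      b <- a + l - 1L
      hits <- query_library(lib, substr(epitope_seq, a, b), orientation)
      if (nrow(hits) == 0) next
      for (h in seq_len(nrow(hits))) {
        aligned <- aligned_residues(hits$comp_subseq[h], orientation)
        placements[[length(placements) + 1L]] <- list(
          a = a, b = b, aligned = aligned,
          count = hits$count[h],
          target_subseq = hits$target_subseq[h],
          comp_subseq = hits$comp_subseq[h]
        )
      }
    }
  }
  if (length(placements) == 0) {
    return(empty_designs())
  }
  starts <- vapply(placements, function(p) p$a, integer(1))

  seeds <- placements[starts == 1L]
  frontier <- purrr::map(seeds, function(p) {
    list(
      covered = p$b, aligned = p$aligned,
      support = rep(p$count, p$b), frags = list(p)
    )
  })
  complete <- list()
  while (length(frontier) > 0) {
    done <- vapply(frontier, function(s) s$covered == L, logical(1))
    complete <- c(complete, frontier[done])
    frontier <- prune_beam(frontier[!done], beam_width)
    if (length(frontier) == 0) break
    nxt <- list()
    for (st in frontier) {
      cov <- st$covered
      cand <- placements[starts >= 2L & starts <= cov - overlap_min + 1L]
      for (p in cand) {
        if (p$b <= cov) next # must extend coverage
        ov <- seq(p$a, cov)
        if (!identical(st$aligned[ov], p$aligned[seq_along(ov)])) next
        aligned <- c(st$aligned, p$aligned[(cov - p$a + 2L):length(p$aligned)])
        support <- c(st$support, rep(0L, p$b - cov))
        support[p$a:p$b] <- support[p$a:p$b] + p$count
        nxt[[length(nxt) + 1L]] <- list(
          covered = p$b, aligned = aligned,
          support = support, frags = c(st$frags, list(p))
        )
      }
    }
    frontier <- nxt
  }
  if (length(complete) == 0) {
    return(empty_designs())
  }
  # collapse to the best-supported state per paratope before building rows
  par <- vapply(
    complete,
    function(st) paratope_from_aligned(st$aligned, orientation), character(1)
  )
  cs <- vapply(
    complete,
    function(st) complementarity_from_support(st$support), double(1)
  )
  ord <- order(par, -cs)
  keep <- ord[!duplicated(par[ord])]
  tibble(
    epitope_seq = epitope_seq,
    paratope_seq = par[keep],
    orientation = orientation,
    support = purrr::map(complete[keep], function(st) as.integer(st$support)),
    fragments = purrr::map(complete[keep], function(st) {
      tibble(
        target_subseq = vapply(st$frags, function(p) p$target_subseq, character(1)),
        comp_subseq = vapply(st$frags, function(p) p$comp_subseq, character(1)),
        offset = vapply(st$frags, function(p) p$a, integer(1))
      )
    })
  )
}

# comp_subseq (N->C of its own chain) as residues aligned to ascending
# epitope positions
aligned_residues <- function(comp_subseq, orientation) {
  r <- strsplit(comp_subseq, "")[[1]]
  if (orientation == "antiparallel") rev(r) else r
}

# the paratope peptide, N to C: an antiparallel partner runs against the
# epitope, so its N->C sequence is the reverse of the aligned residues
paratope_from_aligned <- function(aligned, orientation) {
  if (orientation == "antiparallel") aligned <- rev(aligned)
  paste(aligned, collapse = "")
}

# deterministic beam pruning: rank by current complementarity, then
# aligned sequence, then support
prune_beam <- function(states, beam_width) {
  if (length(states) <= beam_width) {
    return(unique_states(states))
  }
  states <- unique_states(states)
  key <- vapply(states, function(s) {
    sprintf(
      "%012.8f\r%s", -complementarity_from_support(s$support),
      paste(s$aligned, collapse = "")
    )
  }, character(1))
  states[order(key)][seq_len(min(beam_width, length(states)))]
}

unique_states <- function(states) {
  sig <- vapply(states, function(s) {
    paste(s$covered, paste(s$aligned, collapse = ""),
      paste(s$support, collapse = ","),
      sep = "\r"
    )
  }, character(1))
  states[!duplicated(sig)]
}

#' Complementarity score
#'
#' Scores the structural evidence behind a design: the mean, over epitope
#' positions, of `log10(1 + n_i)` where `n_i` is the number of library
#' observations supporting the pairing at position `i`. Zero when nothing
#' supports the design; strictly increasing in every count.
#'
#' @param design One row of a `paratope_designs` tibble, or a design list
#'   with a `support` field.
#' @return A non-negative scalar.
#' @export
complementarity_score <- function(design) {
  support <- if (is.data.frame(design)) design$support[[1]] else design$support
  complementarity_from_support(support)
}

complementarity_from_support <- function(support) {
  if (length(support) == 0) {
    return(0)
  }
  mean(log10(1 + support))
}

# Kyte-Doolittle hydropathy
KD_HYDROPATHY <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

#' Intrinsic solubility score
#'
#' A simplified intrinsic solubility profile: each residue gets
#' `z = 0.6 * (-H) + 0.4 * q`, where `H` is the Kyte-Doolittle hydropathy
#' rescaled linearly to `[-1, 1]` over the 20 residues and `q` is +1 for
#' the charged residues D, E, K, R and 0 otherwise. The profile is
#' smoothed by a centred moving average of width `min(window, length)`
#' (reduced to the nearest odd width) and the score is the mean of the
#' smoothed profile. Higher means more soluble. This is a documented
#' simplification of published intrinsic-solubility predictors, not a
#' numerical reproduction of any of them.
#'
#' @param seq Amino-acid sequence (standard letters only).
#' @param window Odd smoothing window width, default 7.
#' @return A scalar; higher = more soluble.
#' @export
solubility_score <- function(seq, window = 7L) {
  mean(solubility_profile(seq, window)$smoothed)
}

#' @rdname solubility_score
#' @return `solubility_profile()` returns a tibble with `position`,
#'   `residue`, `intrinsic` and `smoothed` columns.
#' @export
solubility_profile <- function(seq, window = 7L) {
  seq <- toupper(seq)
  r <- strsplit(seq, "")[[1]]
  if (length(r) == 0) abort("sequence must be non-empty")
  if (!all(r %in% AA_STANDARD)) {
    abort(paste0(
      "non-standard residues in sequence: ",
      paste(setdiff(r, AA_STANDARD), collapse = "")
    ))
  }
  h <- KD_HYDROPATHY[r] / max(abs(KD_HYDROPATHY)) # rescale to [-1, 1]
  q <- as.numeric(r %in% c("D", "E", "K", "R"))
  z <- 0.6 * (-h) + 0.4 * q
  w <- min(window, length(r))
  if (w %% 2 == 0) w <- w - 1L
  h2 <- (w - 1) %/% 2
  smoothed <- vapply(seq_along(z), function(i) {
    mean(z[max(1, i - h2):min(length(z), i + h2)])
  }, double(1))
  tibble(
    position = seq_along(z), residue = r,
    intrinsic = unname(z), smoothed = smoothed
  )
}

#' Negative-control sequences
#'
#' `make_negative_control()` builds a deterministic sequence over the
#' small-side-chain alphabet S, G, A by repeating the pattern
#' S,G,A,A,A,G,S,G,S; length 9 gives `"SGAAAGSGS"`, the canonical
#' non-binding control. `is_negative_control()` tests whether a sequence
#' uses only the small-side-chain alphabet.
#'
#' @param length Desired length (>= 1).
#' @return A sequence string.
#' @export
make_negative_control <- function(length = 9L) {
  if (length < 1) abort("length must be >= 1")
  pattern <- strsplit("SGAAAGSGS", "")[[1]]
  paste(pattern[((seq_len(length) - 1L) %% 9L) + 1L], collapse = "")
}

#' @rdname make_negative_control
#' @param seq Sequence to test.
#' @export
is_negative_control <- function(seq) {
  r <- strsplit(toupper(seq), "")[[1]]
  length(r) > 0 && all(r %in% c("S", "G", "A"))
}
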