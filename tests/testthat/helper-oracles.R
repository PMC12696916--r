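# Independent brute-force oracles used to cross-check the mining and
# assembly implementations on small inputs.

# All-pairs hydrogen-bond search: plain double loop, no prefilter, the
# electrostatic formula written out step by step.
oracle_hbonds <- function(structure, cutoff = -0.5) {
  res <- as.data.frame(structure)
  res <- res[res$eligible, ]
  out <- list()
  for (di in seq_len(nrow(res))) {
    d <- res[di, ]
    if (d$aa == "P") next
    prev <- res[res$chain == d$chain & res$resi == d$resi - 1L, ]
    if (nrow(prev) != 1) next
    n <- c(d$n_x, d$n_y, d$n_z)
    ca <- c(d$ca_x, d$ca_y, d$ca_z)
    cprev <- c(prev$c_x, prev$c_y, prev$c_z)
    u1 <- (n - cprev) / sqrt(sum((n - cprev)^2))
    u2 <- (n - ca) / sqrt(sum((n - ca)^2))
    hd <- u1 + u2
    if (sqrt(sum(hd^2)) < 1e-6) next
    h <- n + hd / sqrt(sum(hd^2))
    for (ai in seq_len(nrow(res))) {
      a <- res[ai, ]
      if (a$chain == d$chain && abs(a$resi - d$resi) < 3) next
      cc <- c(a$c_x, a$c_y, a$c_z)
      o <- c(a$o_x, a$o_y, a$o_z)
      dist <- function(p, q) sqrt(sum((p - q)^2))
      e <- 27.888 *
        (1 / dist(o, n) + 1 / dist(cc, h) - 1 / dist(o, h) - 1 / dist(cc, n))
      if (e < cutoff) {
        out[[length(out) + 1L]] <- data.frame(
          donor_chain = d$chain, donor_resi = d$resi,
          acceptor_chain = a$chain, acceptor_resi = a$resi,
          energy = e
        )
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(
      donor_chain = character(), donor_resi = integer(),
      acceptor_chain = character(), acceptor_resi = integer(),
      energy = double()
    ))
  }
  out <- do.call(rbind, out)
  out[order(out$donor_chain, out$donor_resi, out$acceptor_chain, out$acceptor_resi), ]
}

# Exhaustive strand-pair search: enumerate every interval on every pairing
# diagonal and keep the maximal ones satisfying the ladder definition
# (pairs in-chain and eligible; >= 2 H-bonds; bonded pairs never more than
# 2 apart; ends at most one pair beyond the outermost bonded pair).
oracle_strand_pairs <- function(structure, min_len = 3L, cutoff = -0.5) {
  hb <- oracle_hbonds(structure, cutoff)
  res <- as.data.frame(structure)
  chains <- sort(unique(res$chain))
  valid_pair <- function(c1, i, c2, j) {
    r1 <- res[res$chain == c1 & res$resi == i, ]
    r2 <- res[res$chain == c2 & res$resi == j, ]
    ok <- nrow(r1) == 1 && nrow(r2) == 1 && r1$eligible && r2$eligible
    if (ok && c1 == c2) ok <- (j - i) >= 2
    ok
  }
  # (position, multiplicity) of bonds supporting diagonal `dg` between c1, c2
  bond_positions <- function(c1, c2, orientation, dg) {
    pos <- integer()
    for (k in seq_len(nrow(hb))) {
      b <- hb[k, ]
      # orient so side 1 precedes side 2
      if (b$donor_chain < b$acceptor_chain ||
        (b$donor_chain == b$acceptor_chain && b$donor_resi < b$acceptor_resi)) {
        bc1 <- b$donor_chain
        br1 <- b$donor_resi
        bc2 <- b$acceptor_chain
        br2 <- b$acceptor_resi
        donor_side <- 1L
      } else {
        bc1 <- b$acceptor_chain
        br1 <- b$acceptor_resi
        bc2 <- b$donor_chain
        br2 <- b$donor_resi
        donor_side <- 2L
      }
      if (bc1 != c1 || bc2 != c2) next
      if (orientation == "antiparallel") {
        if (br1 + br2 == dg) pos <- c(pos, br1)
      } else {
        supported <- br2 - br1 + ifelse(donor_side == 1L, 1L, -1L)
        if (supported == dg) pos <- c(pos, br1)
      }
    }
    pos
  }
  found <- list()
  for (c1 in chains) {
    for (c2 in chains[chains >= c1]) {
      for (orientation in c("antiparallel", "parallel")) {
        r1 <- res$resi[res$chain == c1]
        r2 <- res$resi[res$chain == c2]
        diags <- if (orientation == "antiparallel") {
          unique(outer(r1, r2, "+"))
        } else {
          unique(outer(r2, r1, "-"))
        }
        for (dg in sort(diags)) {
          if (c1 == c2 && orientation == "parallel" && dg < 3) next
          pos <- bond_positions(c1, c2, orientation, dg)
          if (length(pos) < 2) next
          lo <- min(r1)
          hi <- max(r1)
          ok_interval <- function(a, b) {
            pp <- sort(pos[pos >= a & pos <= b])
            if (length(pp) < 2) {
              return(FALSE)
            }
            if (any(diff(sort(unique(pp))) > 2)) {
              return(FALSE)
            }
            if (a < min(pp) - 1 || b > max(pp) + 1) {
              return(FALSE)
            }
            for (i in a:b) {
              j <- if (orientation == "antiparallel") dg - i else i + dg
              if (!valid_pair(c1, i, c2, j)) {
                return(FALSE)
              }
            }
            TRUE
          }
          ivs <- list()
          for (a in lo:hi) {
            for (b in a:hi) {
              if (b - a + 1 < min_len) next
              if (ok_interval(a, b)) ivs[[length(ivs) + 1L]] <- c(a, b)
            }
          }
          if (length(ivs) == 0) next
          # keep maximal intervals only
          for (iv in ivs) {
            contained <- any(vapply(ivs, function(o) {
              (o[1] < iv[1] && o[2] >= iv[2]) || (o[1] <= iv[1] && o[2] > iv[2])
            }, logical(1)))
            if (!contained) {
              found[[length(found) + 1L]] <- data.frame(
                target_chain = c1, target_start = iv[1], target_end = iv[2],
                comp_chain = c2, orientation = orientation, register = dg
              )
            }
          }
        }
      }
    }
  }
  if (length(found) == 0) {
    return(data.frame(
      target_chain = character(), target_start = integer(),
      target_end = integer(), comp_chain = character(),
      orientation = character(), register = integer()
    ))
  }
  out <- unique(do.call(rbind, found))
  out[order(out$target_chain, out$target_start, out$comp_chain, out$register), ]
}

# Exhaustive cascade enumeration by depth-first search over all fragment
# placements (no beam), de-duplicated by paratope keeping the best support.
oracle_assemble <- function(lib, epitope_seq, orientation,
                            min_frag_len = NULL, overlap_min = 2L) {
  min_frag_len <- min_frag_len %||% attr(lib, "min_len")
  L <- nchar(epitope_seq)
  lib_df <- as.data.frame(lib)
  lib_df <- lib_df[lib_df$orientation == orientation, ]
  placements <- list()
  for (l in seq(min_frag_len, min(attr(lib, "max_len"), L))) {
    for (a in seq_len(L - l + 1L)) {
      b <- a + l - 1L
      key <- substr(epitope_seq, a, b)
      hits <- lib_df[lib_df$target_subseq == key, ]
      for (h in seq_len(nrow(hits))) {
        r <- strsplit(hits$comp_subseq[h], "")[[1]]
        if (orientation == "antiparallel") r <- rev(r)
        placements[[length(placements) + 1L]] <- list(
          a = a, b = b, aligned = r, count = hits$count[h]
        )
      }
    }
  }
  results <- new.env()
  recurse <- function(covered, aligned, support) {
    if (covered == L) {
      paratope <- paste(
        if (orientation == "antiparallel") rev(aligned) else aligned,
        collapse = ""
      )
      cs <- mean(log10(1 + support))
      prev <- results[[paratope]]
      if (is.null(prev) || cs > prev) results[[paratope]] <- cs
      # a completed assembly can still be extended past nothing; stop here
      return(invisible())
    }
    for (p in placements) {
      if (p$a < 2 || p$a > covered - overlap_min + 1L) next
      if (p$b <= covered) next
      ov <- seq(p$a, covered)
      if (!identical(aligned[ov], p$aligned[seq_along(ov)])) next
      new_aligned <- c(aligned, p$aligned[(covered - p$a + 2L):length(p$aligned)])
      new_support <- c(support, rep(0, p$b - covered))
      new_support[p$a:p$b] <- new_support[p$a:p$b] + p$count
      recurse(p$b, new_aligned, new_support)
    }
  }
  for (p in placements) {
    if (p$a != 1L) next
    recurse(p$b, p$aligned, rep(p$count, p$b))
  }
  keys <- ls(results)
  data.frame(
    paratope_seq = keys,
    c_score = vapply(keys, function(k) results[[k]], double(1)),
    row.names = NULL
  )
}

# small random library builder for cascade oracle tests
random_library <- function(epitope, n_extra = 10, seed = 1) {
  withr::with_seed(seed, {
    L <- nchar(epitope)
    rows <- list()
    add <- function(a, b, comp, count) {
      rows[[length(rows) + 1L]] <<- data.frame(
        target_subseq = substr(epitope, a, b), orientation = "antiparallel",
        comp_subseq = comp, count = count, sources = "synthetic"
      )
    }
    aa <- setdiff(
      strsplit("ARNDQEGHILKMFSTWYV", "")[[1]], character(0)
    )
    # guaranteed covering path
    mid <- ceiling(L / 2)
    comp_full <- paste(sample(aa, L, replace = TRUE), collapse = "")
    aligned <- rev(strsplit(comp_full, "")[[1]])
    piece <- function(a, b) {
      paste(rev(aligned[a:b]), collapse = "")
    }
    add(1, mid + 1, piece(1, mid + 1), sample(1:5, 1))
    add(mid, L, piece(mid, L), sample(1:5, 1))
    # random noise fragments
    for (k in seq_len(n_extra)) {
      l <- sample(3:min(6, L), 1)
      a <- sample(1:(L - l + 1), 1)
      add(a, a + l - 1, paste(sample(aa, l, replace = TRUE), collapse = ""),
        count = sample(1:4, 1)
      )
    }
    obs <- do.call(rbind, rows)
    obs <- dplyr::summarise(
      dplyr::group_by(obs, target_subseq, orientation, comp_subseq),
      count = sum(count), sources = "synthetic", .groups = "drop"
    )
    structure(tibble::as_tibble(obs),
      min_len = 3L, max_len = 9L,
      class = c("fragment_library", class(tibble::tibble()))
    )
  })
}

# random rigid motion for invariance tests
random_rigid <- function(seed) {
  withr::with_seed(seed, {
    th <- stats::runif(3, -pi, pi)
    rx <- matrix(c(
      1, 0, 0, 0, cos(th[1]), -sin(th[1]),
      0, sin(th[1]), cos(th[1])
    ), 3, 3, byrow = TRUE)
    ry <- matrix(c(
      cos(th[2]), 0, sin(th[2]), 0, 1, 0,
      -sin(th[2]), 0, cos(th[2])
    ), 3, 3, byrow = TRUE)
    rz <- matrix(c(
      cos(th[3]), -sin(th[3]), 0, sin(th[3]),
      cos(th[3]), 0, 0, 0, 1
    ), 3, 3, byrow = TRUE)
    list(rotation = rx %*% ry %*% rz, translation = stats::runif(3, -20, 20))
  })
}

`%||%` <- function(x, y) if (is.null(x)) y else x
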