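make_library <- function(df, min_len = 3L, max_len = 9L) {
  cascadesign:::new_fragment_library(tibble::as_tibble(df), min_len, max_len)
}

test_that("an epitope covered by one full-length fragment yields it directly", {
  lib <- make_library(data.frame(
    target_subseq = "NFLVH", orientation = "antiparallel",
    comp_subseq = "KQWER", count = 4L, sources = "s"
  ))
  des <- cascade_assemble(lib, "NFLVH")
  expect_equal(nrow(des), 1L)
  expect_equal(des$paratope_seq, "KQWER")
  expect_equal(des$support[[1]], rep(4L, 5))
  expect_equal(des$c_score, log10(5))
  expect_equal(nchar(des$paratope_seq), nchar(des$epitope_seq))
})

test_that("overlapping fragments that agree are linked into one paratope", {
  # epitope ABCDEFGH-like 8-mer; fragments cover 1-5 and 4-8, agreeing on
  # the aligned overlap
  epi <- "NFLVHSSN"
  comp_aligned <- strsplit("QWERTYAD", "")[[1]] # desired pairing, pos 1..8
  piece <- function(a, b) paste(rev(comp_aligned[a:b]), collapse = "")
  lib <- make_library(data.frame(
    target_subseq = c(substr(epi, 1, 5), substr(epi, 4, 8)),
    orientation = "antiparallel",
    comp_subseq = c(piece(1, 5), piece(4, 8)),
    count = c(2L, 3L), sources = "s"
  ), min_len = 3L, max_len = 5L)
  des <- cascade_assemble(lib, epi)
  expect_equal(nrow(des), 1L)
  expect_equal(des$paratope_seq, paste(rev(comp_aligned), collapse = ""))
  expect_equal(des$support[[1]], c(2L, 2L, 2L, 5L, 5L, 3L, 3L, 3L))
  expect_equal(nrow(des$fragments[[1]]), 2L)
})

test_that("fragments disagreeing in the overlap cannot be linked", {
  epi <- "NFLVHSSN"
  lib <- make_library(data.frame(
    target_subseq = c(substr(epi, 1, 5), substr(epi, 4, 8)),
    orientation = "antiparallel",
    comp_subseq = c("TREWQ", "DAYTK"), # K conflicts with R at position 4/5
    count = 1L, sources = "s"
  ), min_len = 3L, max_len = 5L)
  expect_equal(nrow(cascade_assemble(lib, epi)), 0L)
})

test_that("epitopes containing X are rejected; uncoverable ones give none", {
  lib <- make_library(data.frame(
    target_subseq = "NFL", orientation = "antiparallel",
    comp_subseq = "KQW", count = 1L, sources = "s"
  ))
  expect_error(cascade_assemble(lib, "NXL"), "X")
  expect_equal(nrow(cascade_assemble(lib, "WWWWW")), 0L)
})

test_that("cascade assembly matches exhaustive enumeration on random libraries", {
  for (seed in 1:8) {
    epi <- withr::with_seed(seed + 100, {
      paste(sample(strsplit("ARNDQEGHILKMFSTWYV", "")[[1]], 8, TRUE),
        collapse = ""
      )
    })
    lib <- random_library(epi, n_extra = 12, seed = seed)
    got <- cascade_assemble(lib, epi,
      orientations = "antiparallel",
      beam_width = 4096L, max_candidates = 1000L
    )
    want <- oracle_assemble(lib, epi, "antiparallel")
    expect_setequal(got$paratope_seq, want$paratope_seq)
    want_cs <- want$c_score[match(got$paratope_seq, want$paratope_seq)]
    expect_equal(got$c_score, want_cs, tolerance = 1e-12)
    # ranking: descending c_score
    expect_true(all(diff(got$c_score) <= 1e-12))
  }
})

test_that("cascade output is deterministic", {
  epi <- "NFLVHSSN"
  lib <- random_library(epi, n_extra = 15, seed = 42)
  a <- cascade_assemble(lib, epi)
  b <- cascade_assemble(lib, epi)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("complementarity score follows its closed form", {
  d0 <- list(support = rep(0L, 5))
  expect_equal(complementarity_score(d0), 0)
  d1 <- list(support = c(9L, 9L, 9L))
  expect_equal(complementarity_score(d1), 1.0)
  # doubling every count strictly increases C
  for (seed in 1:5) {
    n <- withr::with_seed(seed, sample(0:20, 6, TRUE))
    expect_gt(
      complementarity_score(list(support = 2L * n + 1L)),
      complementarity_score(list(support = n))
    )
  }
})

test_that("solubility favours charged over hydrophobic sequences", {
  expect_gt(solubility_score("EEEEEEE"), solubility_score("LLLLLLL"))
  expect_gt(solubility_score("KRDEKRD"), solubility_score("ILVFILV"))
})

test_that("solubility score is reversal invariant", {
  for (seq in c("NFLVHSSN", "ACDEFGHIKLMNP", "KR", "W")) {
    rev_seq <- paste(rev(strsplit(seq, "")[[1]]), collapse = "")
    expect_equal(solubility_score(seq), solubility_score(rev_seq))
  }
})

test_that("solubility of poly-alanine equals its hand-computed value", {
  # z_A = 0.6 * (-1.8 / 4.5) + 0.4 * 0 = -0.24 at every position
  expect_equal(solubility_score("AAAAAAA"), -0.24, tolerance = 1e-12)
  expect_error(solubility_score("ABZ"), "non-standard")
})

test_that("negative control sequences use the small-side-chain alphabet", {
  expect_equal(make_negative_control(9), "SGAAAGSGS")
  expect_true(is_negative_control(make_negative_control(9)))
  for (n in c(1, 5, 12, 20)) {
    s <- make_negative_control(n)
    expect_equal(nchar(s), n)
    expect_true(all(strsplit(s, "")[[1]] %in% c("S", "G", "A")))
  }
  expect_false(is_negative_control("FETLTLR"))
  expect_error(make_negative_control(0), ">= 1")
})

test_that("planted complement sheets are recovered as top candidates", {
  for (seed in 1:5) {
    epi <- withr::with_seed(seed, {
      paste(sample(strsplit("ARNDQEGHILKMFSTWYV", "")[[1]], 8, TRUE),
        collapse = ""
      )
    })
    planted <- plant_complement_sheets(stats::setNames(epi, "e"), seed = seed)
    lib <- build_library(planted$structures)
    des <- cascade_assemble(lib, epi)
    expect_gt(nrow(des), 0)
    expect_equal(des$paratope_seq[1], planted$manifest$comp_frag[1])
  }
})
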