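test_that("H-bond detection matches the all-pairs oracle on ideal sheets", {
  cases <- list(
    build_ideal_sheet(list(strand_spec("NFLVHS"), strand_spec("KQWERT"))),
    build_ideal_sheet(list(
      strand_spec("NFLVHS", "parallel"), strand_spec("KQWERT", "parallel")
    )),
    build_ideal_sheet(list(
      strand_spec("NFLVHSSN"), strand_spec("KQWERTYA"),
      strand_spec("ADGHIKLM", "parallel")
    ))
  )
  for (st in cases) {
    got <- as.data.frame(detect_hbonds(st))
    want <- oracle_hbonds(st)
    expect_equal(got[, 1:4], want[, 1:4], ignore_attr = TRUE)
    expect_equal(got$energy, want$energy, tolerance = 1e-10)
  }
})

test_that("strands far apart and short extended chains have no H-bonds", {
  s1 <- build_ideal_sheet(strand_spec("NFLVHS"))
  s2 <- transform_structure(
    build_ideal_sheet(strand_spec("KQWERT")),
    translation = c(0, 20, 0)
  )
  s2$chain <- "B"
  far <- new_structure(rbind(as.data.frame(s1), as.data.frame(s2)), "far")
  expect_equal(nrow(detect_hbonds(far)), 0L)
  expect_equal(nrow(oracle_hbonds(far)), 0L)

  # single extended 5-residue chain: |i - j| >= 3 plus geometry exclude all
  ext <- build_ideal_sheet(strand_spec("NFLVH"))
  expect_equal(nrow(detect_hbonds(ext)), 0L)
})

test_that("strand-pair detection matches the exhaustive run oracle", {
  cases <- list(
    build_ideal_sheet(list(strand_spec("NFLVHSSN"), strand_spec("KQWERTYA"))),
    build_ideal_sheet(list(
      strand_spec("NFLVHS", "parallel"), strand_spec("KQWERT", "parallel")
    )),
    build_ideal_sheet(list(
      strand_spec("NFLVHS"), strand_spec("KQWERT"),
      strand_spec("ADGHIK", "parallel")
    )),
    build_ideal_sheet(list(
      strand_spec("NFLVHSS"), strand_spec("QWERT", register = 1)
    ))
  )
  for (st in cases) {
    got <- as.data.frame(detect_strand_pairs(st, min_len = 3))
    want <- oracle_strand_pairs(st, min_len = 3)
    key <- c(
      "target_chain", "target_start", "target_end", "comp_chain",
      "orientation", "register"
    )
    expect_equal(
      got[do.call(order, got[key]), key],
      want[do.call(order, want[key]), key],
      ignore_attr = TRUE
    )
  }
})

test_that("an ideal antiparallel 8+8 sheet gives one full-length fragment", {
  sheet <- build_ideal_sheet(list(
    strand_spec("NFLVHSSN"), strand_spec("KQWERTYA")
  ))
  pairs <- detect_strand_pairs(sheet, min_len = 3)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$target_seq, "NFLVHSSN")
  expect_equal(pairs$comp_seq, "KQWERTYA")
  expect_equal(pairs$orientation, "antiparallel")
  expect_equal(pairs$target_end - pairs$target_start + 1L, 8L)
  # length filter
  expect_equal(nrow(detect_strand_pairs(sheet, min_len = 9)), 0L)
})

test_that("three stacked strands pair only with their neighbours", {
  sheet <- build_ideal_sheet(list(
    strand_spec("NFLVHS"), strand_spec("KQWERT"),
    strand_spec("ADGHIK", "parallel")
  ))
  pairs <- detect_strand_pairs(sheet)
  combos <- paste(pairs$target_chain, pairs$comp_chain)
  expect_setequal(combos, c("A B", "B C"))
  expect_false("A C" %in% combos)
})

test_that("parallel two-strand sheets are mined as parallel full overlaps", {
  sheet <- build_ideal_sheet(list(
    strand_spec("NFLVHS", "parallel"), strand_spec("KQWERT", "parallel")
  ))
  pairs <- detect_strand_pairs(sheet)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$orientation, "parallel")
  expect_equal(pairs$target_seq, "NFLVHS")
  expect_equal(pairs$comp_seq, "KQWERT")
})

test_that("library indexing counts every sub-window once", {
  frag <- tibble::tibble(
    source_id = "s", target_chain = "A", target_start = 1L, target_end = 5L,
    target_seq = "NFLVH", comp_chain = "B", comp_start = 1L, comp_end = 5L,
    comp_seq = "KQWER", orientation = "antiparallel", register = 6L,
    n_hbonds = 3L
  )
  lib <- library_from_pairs(frag, min_len = 3, max_len = 5)
  expect_equal(nrow(lib), 6L) # 3 + 2 + 1 windows
  expect_equal(sum(lib$count), 6L)

  # the complementary triplet facing F-L-V, read N to C
  hit <- query_library(lib, "FLV")
  expect_equal(hit$comp_subseq, "QWE")
  expect_equal(hit$count, 1L)
})

test_that("library counts are additive over duplicated structures", {
  sheet <- build_ideal_sheet(list(strand_spec("NFLVH"), strand_spec("KQWER")))
  one <- build_library(list(sheet), min_len = 3, max_len = 5)
  two <- build_library(list(sheet, sheet), min_len = 3, max_len = 5)
  expect_equal(two$count, 2L * one$count)
  expect_equal(two$target_subseq, one$target_subseq)
  expect_equal(sum(one$count), 6L)
})

test_that("library queries are ordered and validated", {
  obs <- tibble::tibble(
    target_subseq = c("NFL", "NFL"), orientation = "antiparallel",
    comp_subseq = c("ZZZ", "AAA"), count = c(1L, 3L),
    sources = "s"
  )
  obs$comp_subseq <- c("TTT", "AAA")
  lib <- cascadesign:::new_fragment_library(obs, 3L, 9L)
  got <- query_library(lib, "NFL")
  expect_equal(got$comp_subseq, c("AAA", "TTT")) # count 3 first
  expect_equal(got$count, c(3L, 1L))

  expect_equal(nrow(query_library(lib, "QQQ")), 0L)
  expect_error(query_library(lib, "NF"), "outside")

  # linear-scan equivalence
  manual <- obs[obs$target_subseq == "NFL" & obs$orientation == "antiparallel", ]
  manual <- manual[order(-manual$count, manual$comp_subseq), ]
  expect_equal(as.data.frame(got), as.data.frame(manual), ignore_attr = TRUE)
})

test_that("fragments containing X never enter the library", {
  frag <- tibble::tibble(
    source_id = "s", target_chain = "A", target_start = 1L, target_end = 5L,
    target_seq = "NFXVH", comp_chain = "B", comp_start = 1L, comp_end = 5L,
    comp_seq = "KQWER", orientation = "antiparallel", register = 6L,
    n_hbonds = 3L
  )
  lib <- library_from_pairs(frag, min_len = 3, max_len = 5)
  expect_false(any(grepl("X", lib$target_subseq)))
  # every window of NFXVH with length >= 3 touches the X
  expect_equal(nrow(lib), 0L)
})

test_that("library serialization round trips through TSV", {
  sheet <- build_ideal_sheet(list(strand_spec("NFLVH"), strand_spec("KQWER")))
  lib <- build_library(sheet, min_len = 3, max_len = 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_library(lib, path)
  back <- read_library(path)
  expect_equal(as.data.frame(back), as.data.frame(lib))
  expect_equal(attr(back, "min_len"), attr(lib, "min_len"))
  expect_equal(attr(back, "max_len"), attr(lib, "max_len"))
})

test_that("total library observations equal the sub-window sum", {
  sheets <- list(
    build_ideal_sheet(list(strand_spec("NFLVHSS"), strand_spec("KQWERTY"))),
    build_ideal_sheet(list(strand_spec("GHIKLM"), strand_spec("ADNQRS")))
  )
  min_len <- 3L
  max_len <- 6L
  pairs <- dplyr::bind_rows(lapply(sheets, detect_strand_pairs, min_len = 2L))
  lib <- library_from_pairs(pairs, min_len, max_len)
  expected <- sum(vapply(pairs$target_seq, function(s) {
    L <- nchar(s)
    ls <- seq(min_len, min(max_len, L))
    sum(L - ls + 1L)
  }, double(1)))
  expect_equal(sum(lib$count), expected)
})
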