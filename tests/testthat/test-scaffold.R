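test_that("cysteine substitution schemes edit both conserved positions", {
  sdab <- example_scaffolds()$sdAb
  aa <- substitute_cysteines(sdab, "AA")
  expect_equal(substr(aa$sequence, 23, 23), "A")
  expect_equal(substr(aa$sequence, 97, 97), "A")
  expect_equal(aa$tokens$cys_suffix, "C23AC97A")
  expect_false(grepl("C", substr(aa$sequence, 23, 23)))

  av <- substitute_cysteines(sdab, "AV")
  expect_equal(substr(av$sequence, 97, 97), "V")
  expect_equal(av$tokens$cys_suffix, "C23AC97V")

  # applying twice violates the precondition
  expect_error(substitute_cysteines(aa, "AA"), "not cysteine")
})

test_that("grafting inserts core or full designed loops with exact bookkeeping", {
  sdab <- substitute_cysteines(example_scaffolds()$sdAb, "AA")
  full <- graft(sdab, "CDR3", "FETLTLR", mode = "full_loop")
  expect_true(grepl("GSFETLTLREEE", full$sequence, fixed = TRUE))
  expect_equal(
    nchar(full$sequence),
    nchar(sdab$sequence) - 12L + nchar("GSFETLTLREEE")
  )

  core <- graft(sdab, "CDR3", "FETLTLR", mode = "core")
  expect_true(grepl("FETLTLR", core$sequence, fixed = TRUE))
  expect_false(grepl("GSFETLTLREEE", core$sequence, fixed = TRUE))
  expect_equal(nchar(core$sequence), nchar(sdab$sequence) - 12L + 7L)

  expect_error(graft(sdab, "CDR3", ""), "non-empty")
  expect_error(graft(sdab, "H3", "FETLTLR"), "unknown site")
})

test_that("N-terminal truncation shifts sites and respects the first site", {
  mono <- example_scaffolds()$monobody
  t8 <- truncate_n_terminus(mono, 8)
  expect_equal(nchar(t8$sequence), nchar(mono$sequence) - 8L)
  expect_equal(t8$sites$BC, mono$sites$BC - 8L)
  expect_equal(t8$sites$FG, mono$sites$FG - 8L)
  expect_equal(t8$tokens$trunc_prefix, "N-8-")
  expect_equal(truncate_n_terminus(mono, 4)$tokens$trunc_prefix, "N-4-")
  expect_error(truncate_n_terminus(mono, 23), "reaches")
})

test_that("loop replacement rewrites the site and updates bounds", {
  mono <- example_scaffolds()$monobody
  r <- replace_loop(mono, "FG", "AAAAS")
  expect_equal(r$sites$FG[2] - r$sites$FG[1] + 1L, 5L)
  expect_equal(
    substr(r$sequence, r$sites$FG[1], r$sites$FG[2]), "AAAAS"
  )
  expect_equal(nchar(r$sequence), nchar(mono$sequence) - 10L + 5L)
  expect_error(replace_loop(mono, "FG", ""), "non-empty")
  expect_error(replace_loop(mono, "XY", "AAAAS"), "unknown site")
})

test_that("the four single-graft monobody variants carry their printed names", {
  mono <- example_scaffolds()$monobody
  v <- enumerate_variants(mono, c("FETLTLR", "GSFETLTLREEE"), c("BC", "FG"))
  expect_equal(names(v), c(
    "FETLTLR(BC)-wt(FG)", "GSFETLTLREEE(BC)-wt(FG)",
    "wt(BC)-FETLTLR(FG)", "wt(BC)-GSFETLTLREEE(FG)"
  ))
  expect_length(enumerate_variants(mono, "FETLTLR", "BC"), 1L)
  expect_error(enumerate_variants(mono, character(), "BC"), "no inserts")
})

test_that("engineered monobody constructs replay and conserve length", {
  mono <- example_scaffolds()$monobody
  builds <- list(
    list(n = 4L, fg = NULL, insert = "FETLTLR", name = "N-4-FETLTLR(BC)-wt(FG)"),
    list(n = 8L, fg = "AAAAS", insert = "FETLTLR", name = "N-8-FETLTLR(BC)-AAAAS(FG)"),
    list(n = 8L, fg = "AAAAS", insert = "GSFETLTLREEE", name = "N-8-GSFETLTLREEE(BC)-AAAAS(FG)"),
    list(n = 8L, fg = "EGYYSSY", insert = "FETLTLR", name = "N-8-FETLTLR(BC)-EGYYSSY(FG)"),
    list(n = 8L, fg = "PTSDYG", insert = "FETLTLR", name = "N-8-FETLTLR(BC)-PTSDYG(FG)")
  )
  for (b in builds) {
    t <- truncate_n_terminus(mono, b$n)
    if (!is.null(b$fg)) t <- replace_loop(t, "FG", b$fg)
    cons <- graft(t, "BC", b$insert, mode = "core")
    expect_equal(cons$name, b$name)
    # edit replay reproduces the sequence byte for byte
    expect_equal(replay_edits(mono, cons$edits), cons$sequence)
    # length conservation
    fg_len <- if (is.null(b$fg)) 10L else nchar(b$fg)
    expect_equal(
      nchar(cons$sequence),
      nchar(mono$sequence) - b$n - 10L + fg_len - 8L + nchar(b$insert)
    )
  }
})

test_that("construct names round trip through the parser", {
  names <- c(
    "FETLTLR(BC)-wt(FG)", "GSFETLTLREEE(BC)-wt(FG)",
    "wt(BC)-FETLTLR(FG)", "wt(BC)-GSFETLTLREEE(FG)",
    "N-4-FETLTLR(BC)-wt(FG)", "N-8-FETLTLR(BC)-AAAAS(FG)",
    "N-8-GSFETLTLREEE(BC)-AAAAS(FG)", "N-8-FETLTLR(BC)-EGYYSSY(FG)",
    "N-8-FETLTLR(BC)-PTSDYG(FG)"
  )
  for (nm in names) {
    p <- parse_construct_name(nm)
    expect_equal(p$type, "monobody")
    rebuilt <- paste0(
      if (p$truncate_n > 0) paste0("N-", p$truncate_n, "-") else "",
      p$site_tokens[["BC"]], "(BC)-", p$site_tokens[["FG"]], "(FG)"
    )
    expect_equal(rebuilt, nm)
  }
  for (lbl in c("9-17", "12-18", "30-37")) {
    p <- parse_construct_name(paste0("DesAb_", lbl))
    expect_equal(paste0(p$window_start, "-", p$window_end), lbl)
  }
  expect_true(parse_construct_name("DesAb_neg")$negative)
  # en-dash form accepted
  expect_equal(parse_construct_name("DesAb_9–17")$window_start, 9L)
  expect_error(parse_construct_name("whatever"), "cannot parse")
})

test_that("canonical edit order is enforced", {
  mono <- example_scaffolds()$monobody
  r <- replace_loop(mono, "FG", "AAAAS")
  expect_error(truncate_n_terminus(r, 4), "canonical order")
})

test_that("misconfigured numbered residues are rejected at template build", {
  expect_error(
    scaffold_template("bad", "AAAAAAAAAA",
      sites = list(L1 = c(8, 9)),
      numbered = c(C3 = 3)
    ),
    "does not match"
  )
})

test_that("panel grafting emits one construct per design plus the control", {
  target <- iapp_sequence()
  w <- iapp_windows()
  targets <- stats::setNames(
    vapply(seq_len(nrow(w)), function(i) {
      substr(target, w$start[i], w$end[i])
    }, character(1)),
    w$label
  )
  planted <- plant_complement_sheets(targets, seed = 3)
  lib <- build_library(planted$structures)
  panel <- scan_epitopes(target, w, lib, target_id = "IAPP", mask = 1:8)

  sdab <- substitute_cysteines(example_scaffolds()$sdAb, "AA")
  cons <- build_panel_constructs(panel, sdab)
  expect_length(cons, 10L)
  expect_equal(
    names(cons),
    c(paste0("DesAb_", w$label), "DesAb_neg")
  )
  neg <- cons[["DesAb_neg"]]
  expect_true(grepl("SGAAAGSGS", neg$sequence, fixed = TRUE))
  # edits replay against the unedited template (substitutions included)
  for (x in cons) {
    expect_equal(replay_edits(example_scaffolds()$sdAb, x$edits), x$sequence)
  }

  # unsubstituted sdAb refused
  expect_error(
    build_panel_constructs(panel, example_scaffolds()$sdAb),
    "substitute_cysteines"
  )
  expect_error(build_panel_constructs(panel[0, ], sdab), "empty")

  # FASTA emission: one record per construct, headers are names
  path <- withr::local_tempfile(fileext = ".fasta")
  write_constructs_fasta(cons, path)
  fa <- Biostrings::readAAStringSet(path)
  expect_length(fa, 10L)
  expect_equal(names(fa), names(cons))
  expect_equal(
    as.character(fa[["DesAb_neg"]]), cons[["DesAb_neg"]]$sequence
  )
})
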