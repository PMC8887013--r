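test_that("PTS1 set enumeration matches brute-force expansion", {
  # independent brute-force enumeration of the published grammar
  expected <- character()
  for (a in c("S", "A", "P")) for (b in c("K", "R")) for (d in c("L", "M"))
    expected <- c(expected, paste0(a, b, d))
  expected <- sort(union(setdiff(expected, c("AKM", "PKM", "PRM")), "SRI"))

  got <- enumerate_pts1_set(pts_motif_config())
  expect_identical(got, expected)
  expect_length(got, 10)
  expect_true(all(c("SKL", "SRI") %in% got))
  expect_false(any(c("AKM", "PKM", "PRM") %in% got))
})

test_that("PTS1 scanning is C-terminally anchored and exclusion-aware", {
  m <- scan_pts1("MAGVSKL")
  expect_equal(m$motif, "SKL")
  expect_equal(m$position, 5)
  expect_null(scan_pts1("MAGVPRM"))     # excluded tripeptide
  expect_null(scan_pts1("SKLMAGV"))     # internal motif never matches
  expect_null(scan_pts1("KL"))          # too short: silent non-match
  expect_equal(scan_pts1("MAGVSRI")$motif, "SRI")
})

test_that("PTS2 scanning honors the class variant and the window", {
  m <- scan_pts2("MARLQQQQQHLGG")
  expect_equal(nrow(m), 1)
  expect_equal(m$position, 3)
  expect_equal(m$motif, "RLQQQQQHL")

  # same nonapeptide pushed past the window: no match
  far <- paste0(strrep("G", 59), "RLQQQQQHL", "GG")
  expect_equal(nrow(scan_pts2(far)), 0)
  # nonapeptide straddling the window end: no match
  straddle <- paste0(strrep("G", 35), "RLQQQQQHL", strrep("G", 20))
  expect_equal(nrow(scan_pts2(straddle)), 0)
  expect_equal(scan_pts2(paste0(strrep("G", 31), "RLQQQQQHL"))$position, 32)

  # V at position 2 only matches under the LIV variant
  vseq <- "MARVQQQQQHL"
  expect_equal(nrow(scan_pts2(vseq)), 0)
  liv <- pts_motif_config(pts2_position2_class = c("L", "I", "V"))
  expect_equal(nrow(scan_pts2(vseq, liv)), 1)
})

test_that("scanners agree with positional oracles on random proteins", {
  set.seed(101)
  cfg <- pts_motif_config()
  ok <- vapply(1:2000, function(i) {
    s <- random_protein(sample(3:120, 1))
    m1 <- scan_pts1(s, cfg)
    identical(if (is.null(m1)) NA_character_ else m1$motif,
              oracle_pts1(s)) &&
      identical(scan_pts2(s, cfg)$position, oracle_pts2(s))
  }, logical(1))
  expect_equal(sum(ok), 2000L)
})

test_that("enlarging the PTS2 class or window never removes a match", {
  set.seed(202)
  small <- pts_motif_config()
  big_class <- pts_motif_config(pts2_position2_class = c("L", "I", "V"))
  big_window <- pts_motif_config(pts2_window = 80)
  for (i in 1:300) {
    s <- random_protein(sample(9:120, 1))
    base <- scan_pts2(s, small)$position
    expect_true(all(base %in% scan_pts2(s, big_class)$position))
    expect_true(all(base %in% scan_pts2(s, big_window)$position))
  }
})

test_that("no decoy ending in an excluded tripeptide is ever matched", {
  set.seed(303)
  for (i in 1:200) {
    s <- paste0(random_protein(sample(5:60, 1)),
                sample(c("AKM", "PKM", "PRM"), 1))
    expect_null(scan_pts1(s))
  }
})

test_that("peroxisomal calling combines motif, predictor and TM filter", {
  proteome <- data.frame(
    id = c("gdh", "memb", "predonly", "plain", "both"),
    description = "",
    sequence = c("MAGVSKL",            # motif only
                 "MAGVSKL",            # motif but TM helices
                 "MAGVQQQ",            # predictor only
                 "MAGVQQQ",            # nothing
                 "MAGVSKL"),           # motif + predictor
    stringsAsFactors = FALSE)
  tm <- data.frame(protein_id = proteome$id, tool = "tmhmm",
                   setting = "default",
                   label = c("other", "membrane", "other", "other", "other"),
                   raw_label = "", score = c(0, 2, 0, 0, 0),
                   stringsAsFactors = FALSE)
  pred <- data.frame(protein_id = c("predonly", "both"),
                     tool = "pts1predictor", setting = "default",
                     label = "peroxisomal", raw_label = "Targeted",
                     score = 0.9, stringsAsFactors = FALSE)
  calls <- call_peroxisomal_candidates(proteome, tm, pred)
  tiers <- setNames(calls$tier, calls$protein_id)
  expect_equal(tiers[["gdh"]], "+?")       # motif, predictor negative
  expect_equal(tiers[["memb"]], "-")       # TM proteins filtered out
  expect_equal(tiers[["predonly"]], "+?")  # predictor alone suffices
  expect_equal(tiers[["plain"]], "-")
  expect_equal(tiers[["both"]], "+")       # both channels agree
})

test_that("TM evidence for unknown proteins is ignored with a warning", {
  proteome <- data.frame(id = "p1", description = "", sequence = "MAGVSKL",
                         stringsAsFactors = FALSE)
  tm <- data.frame(protein_id = c("p1", "ghost"), tool = "tmhmm",
                   setting = "default", label = "other", raw_label = "",
                   score = c(0, 2), stringsAsFactors = FALSE)
  expect_warning(calls <- call_peroxisomal_candidates(proteome, tm),
                 "absent from")
  expect_equal(calls$tier, "+?")
})
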