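test_that("signal-peptide detector applies the tripartite rule", {
  p <- paste0("M", "KK", strrep("L", 10), "ASA", strrep("Q", 40))
  sp <- detect_signal_peptide(p)
  expect_true(sp$present)
  expect_equal(sp$cleavage_pos, 16L)  # cleavage right after the ASA
  expect_gte(sp$core_mean_kd, 1.6)

  # hydrophilic N-terminus: no call
  expect_false(detect_signal_peptide(paste0("M", strrep("D", 50)))$present)
  # hydrophobic core but negatively charged n-region: no call
  neg <- paste0("MDDDD", strrep("L", 10), "ASA", strrep("Q", 40))
  expect_false(detect_signal_peptide(neg)$present)
  # core too deep (beyond the first 45 residues): no call
  deep <- paste0(strrep("Q", 45), strrep("L", 10), "ASA", strrep("Q", 20))
  expect_false(detect_signal_peptide(deep)$present)
})

test_that("TM detector finds maximal non-overlapping hydrophobic windows", {
  polar <- strrep("S", 30)
  p1 <- paste0(polar, strrep("I", 19), polar)
  seg1 <- detect_tm_segments(p1)
  expect_equal(nrow(seg1), 1L)
  # the mean-threshold window may legitimately absorb polar flanks around a
  # strongly hydrophobic core; it must cover the core and clear the threshold
  expect_lte(seg1$start, 31L)
  expect_gte(seg1$end, 49L)
  expect_gte(seg1$mean_kd, 1.6)

  expect_equal(nrow(detect_tm_segments(strrep("S", 80))), 0L)

  p2 <- paste0(polar, strrep("I", 20), strrep("D", 10), strrep("L", 21), polar)
  seg2 <- detect_tm_segments(p2)
  expect_equal(nrow(seg2), 2L)
  expect_true(all(seg2$mean_kd >= 1.6))
  expect_true(seg2$start[2] > seg2$end[1])

  # mature_from skips an N-terminal core
  seg3 <- detect_tm_segments(p1, mature_from = 50L)
  expect_equal(nrow(seg3), 0L)
})

test_that("GPI detector requires both the hydrophobic tail and an omega site", {
  core <- strrep("Q", 60)
  pos <- paste0(core, "GSA", strrep("L", 18))
  g <- detect_gpi(pos)
  expect_true(g$present)
  expect_equal(g$omega_site, nchar(pos) - 18L)

  expect_false(detect_gpi(paste0(core, strrep("E", 25)))$present)
  # hydrophobic tail but no small omega candidate in the 15-35 band
  noomega <- paste0(core, strrep("K", 11), strrep("L", 24))
  expect_false(detect_gpi(noomega)$present)
  expect_false(detect_gpi("MKKLLL")$present)  # too short for a call
})

test_that("classification follows the secretory logic with a warning fallback", {
  sp_yes <- structure(list(present = TRUE, cleavage_pos = 16L), class = "sp_call")
  sp_no <- structure(list(present = FALSE), class = "sp_call")
  gpi_yes <- structure(list(present = TRUE, omega_site = 100L), class = "gpi_call")
  gpi_no <- structure(list(present = FALSE), class = "gpi_call")
  tm_yes <- data.frame(start = 10L, end = 30L, mean_kd = 3)
  tm_no <- data.frame(start = integer(), end = integer(), mean_kd = numeric())

  expect_equal(classify_localization(sp_no, tm_no, gpi_no)$klass, "cytosolic")
  expect_equal(classify_localization(sp_yes, tm_no, gpi_no)$klass, "secreted")
  expect_equal(classify_localization(sp_yes, tm_yes, gpi_no)$klass,
               "membrane_bound_tm")
  expect_equal(classify_localization(sp_yes, tm_no, gpi_yes)$klass,
               "membrane_bound_gpi")
  # TM without a signal peptide is incoherent: cytosolic + warning
  odd <- classify_localization(sp_no, tm_yes, gpi_no)
  expect_equal(odd$klass, "cytosolic")
  expect_true(odd$warning_flag)
})

test_that("planted localization classes are recovered on synthetic proteins", {
  gen <- generate_ca_cds(
    200, config = list(class = rep(c("cytosolic", "secreted",
                                     "membrane_bound_tm",
                                     "membrane_bound_gpi"), 50)), seed = 42)
  loc <- localize_table(gen$aa)
  expect_gte(mean(loc$class == gen$truth$class), 0.95)
  sp_idx <- !is.na(gen$truth$cleavage_pos)
  expect_gte(mean(abs(loc$cleavage_pos[sp_idx] -
                      gen$truth$cleavage_pos[sp_idx]) <= 2), 0.90)
  gpi_idx <- !is.na(gen$truth$omega_site)
  expect_true(all(loc$gpi_present[gpi_idx]))
})

test_that("localization calls are deterministic and overridable", {
  gen <- generate_ca_cds(4, seed = 8)
  expect_identical(localize_table(gen$aa), localize_table(gen$aa))

  override <- data.frame(id = gen$truth$id[1], sp_present = FALSE,
                         cleavage_pos = NA_integer_, n_tm = 0L,
                         gpi_present = FALSE, omega_site = NA_integer_,
                         stringsAsFactors = FALSE)
  loc <- localize_table(gen$aa, external = override)
  expect_equal(loc$class[1], "cytosolic")
})
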