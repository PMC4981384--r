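test_that("ORF finder returns the longest ATG-initiated stop-terminated frame", {
  orf <- find_orf(list(id = "t", sequence = "ATGAAATAA"))
  expect_equal(orf$length_bp, 9L)
  expect_equal(orf$protein$sequence, "MK")
  expect_equal(orf$start, 0L)
  expect_equal(orf$end, 9L)

  # longer ORF in another frame wins; tie broken by smallest start
  s <- paste0("CC", "ATGAAAAAATAA", "C", "ATGAAATAA")
  orf2 <- find_orf(list(id = "t2", sequence = s))
  expect_equal(orf2$length_bp, 12L)
  expect_equal(orf2$start, 2L)

  expect_error(find_orf(list(id = "t3", sequence = "CCCCCC")), "no ATG")
  expect_error(find_orf(list(id = "t4", sequence = "ATG")), "too short")
})

test_that("ORF calls obey the length laws on generated transcripts", {
  gen <- generate_ca_cds(6, seed = 5)
  for (i in 1:6) {
    orf <- find_orf(gen$nt[i, ])
    expect_equal(orf$end - orf$start, orf$length_bp)
    expect_equal(orf$length_bp %% 3L, 0L)
    expect_equal(nchar(orf$protein$sequence), orf$length_bp / 3 - 1)
    expect_match(orf$protein$sequence, "^M")
    expect_true(substring(gen$nt$sequence[i], orf$end - 2, orf$end)
                %in% c("TAA", "TAG", "TGA"))
    # generator truth agrees
    expect_equal(orf$start, gen$truth$orf_start_0based[i])
    expect_equal(orf$length_bp, gen$truth$orf_bp[i])
  }
})

test_that("translation follows the standard code, stops unemitted, N gives X", {
  expect_equal(translate_cds("ATGTAA"), "M")
  expect_equal(translate_cds("CAC"), "H")
  expect_equal(translate_cds("ATGNNNTAA"), "MX")
  expect_equal(translate_cds("ATGAAATAGAAA"), "MK")  # stop terminates early
  expect_error(translate_cds("ATGA"), "divisible by 3")
})

test_that("molecular weight matches the residue-mass oracle and is additive", {
  expect_equal(compute_mw("G"), 57.0519 + 18.01524, tolerance = 1e-6)
  expect_error(compute_mw("GX"), "residue 'X'")
  set.seed(11)
  for (k in 1:20) {
    a <- random_peptide(sample(1:30, 1))
    b <- random_peptide(sample(1:30, 1))
    expect_equal(compute_mw(paste0(a, b)),
                 compute_mw(a) + compute_mw(b) - 18.01524, tolerance = 1e-9)
  }
})

test_that("pI agrees with an independent Bjellqvist implementation", {
  set.seed(3)
  for (k in 1:40) {
    p <- random_peptide(sample(5:90, 1))
    expect_equal(compute_pi(p), seqinr::computePI(strsplit(p, "")[[1]]),
                 tolerance = 1e-4)
  }
})

test_that("pI bisection converges to a charge root for all short peptides", {
  aas <- strsplit("ARNDCEQGHILKMFPSTWYV", "")[[1]]
  singles <- aas
  set.seed(4)
  doubles <- as.vector(outer(aas, aas, paste0))
  triples <- replicate(300, random_peptide(3))
  for (p in c(singles, doubles, triples)) {
    pi <- compute_pi(p)
    expect_true(pi > 0 && pi < 14)
    chars <- strsplit(p, "")[[1]]
    counts <- as.list(setNames(
      vapply(c("D", "E", "C", "Y", "H", "K", "R"),
             function(r) sum(chars == r), numeric(1)),
      c("D", "E", "C", "Y", "H", "K", "R")))
    q <- crucarb:::.net_charge(counts, chars[1], chars[length(chars)],
                               pi, crucarb:::.BJELLQVIST)
    expect_lt(abs(q), 1e-4)
  }
})

test_that("pI is monotone in charged residues under fixed terminal pKs", {
  set.seed(9)
  for (k in 1:50) {
    p <- random_peptide(sample(3:40, 1))
    base <- compute_pi(p, uniform_pka)
    expect_gte(compute_pi(paste0(p, "R"), uniform_pka), base - 1e-6)
    expect_lte(compute_pi(paste0(p, "D"), uniform_pka), base + 1e-6)
  }
})

test_that("sequon scan applies the N-X-S/T rule with X != P", {
  expect_equal(scan_sequons("NGS"), 1L)
  expect_equal(scan_sequons("NPS"), 0L)
  expect_equal(scan_sequons("NGSNGT"), 2L)
  # brute-force window oracle on random peptides
  set.seed(12)
  for (k in 1:20) {
    p <- random_peptide(60)
    ch <- strsplit(p, "")[[1]]
    brute <- sum(vapply(seq_len(58), function(i)
      ch[i] == "N" && ch[i + 1] != "P" && ch[i + 2] %in% c("S", "T"),
      logical(1)))
    expect_equal(scan_sequons(p), brute)
  }
})

test_that("physchem profile fields are coherent", {
  p <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"
  prof <- physchem_profile(p)
  expect_equal(prof$length_aa, nchar(p))
  expect_equal(length(prof$kd_profile), nchar(p))
  expect_gt(prof$mw_kda, 0)
  expect_true(prof$pi > 0 && prof$pi < 14)
  expect_equal(unname(prof$st_y_sites["Y"]), 1)
})
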