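test_that("generators are seed-deterministic down to bytes", {
  g1 <- generate_ca_cds(5, seed = 99)
  g2 <- generate_ca_cds(5, seed = 99)
  expect_identical(g1, g2)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_fasta(g1$nt, f1); write_fasta(g2$nt, f2)
  expect_identical(readLines(f1), readLines(f2))
  g3 <- generate_ca_cds(5, seed = 100)
  expect_false(identical(g1$nt$sequence, g3$nt$sequence))

  q1 <- generate_qpcr(data.frame(gene = "g", efficiency = 2), folds = 1,
                      seed = 5)
  q2 <- generate_qpcr(data.frame(gene = "g", efficiency = 2), folds = 1,
                      seed = 5)
  expect_identical(q1, q2)
})

test_that("generator validates contradictory configurations", {
  expect_error(generate_ca_cds(2, config = list(sp = FALSE, gpi = TRUE)),
               "contradictory")
  expect_error(generate_ca_cds(1, config = list(class = "nuclear")),
               "unknown class")
  expect_error(generate_qpcr(data.frame(gene = "g", efficiency = 0.9),
                             folds = 1), "efficiency")
})

test_that("an all-cytosolic batch closes the loop through the classifier", {
  gen <- generate_ca_cds(10, config = list(class = "cytosolic"), seed = 77)
  loc <- localize_table(gen$aa)
  expect_true(all(loc$class == "cytosolic"))
  expect_true(all(!loc$sp_present))
})

test_that("the full pipeline reproduces the six-isozyme repertoire structure", {
  gen <- synthetic_study_set(seed = 19)
  out <- withr::local_tempdir()
  res <- run_all(pipeline_config(gen$nt, out_dir = out))

  counts <- res$summary$counts
  expect_equal(counts$n, 6L)
  expect_equal(counts$n_complete_triad, 5L)
  expect_equal(counts$n_carp, 1L)
  expect_equal(counts$n_signal_peptide, 5L)
  expect_equal(unname(counts$n_per_class["cytosolic"]), 1L)
  expect_equal(unname(counts$n_per_class["secreted"]), 4L)
  expect_equal(unname(counts$n_per_class["membrane_bound_gpi"]), 1L)

  # the CARP rows carry the planted Y-R-H triplet
  expect_true(all(res$carp_codons$triplet == "Y-R-H"))
  # per-stage outputs exist
  for (f in c("physchem.tsv", "localization.tsv", "active_site.tsv",
              "carp_codons.tsv", "summary.tsv", "distances.tsv", "nj.nwk",
              "run_log.json"))
    expect_true(file.exists(file.path(out, f)))
})

test_that("pipeline runs are deterministic and fail cleanly on empty input", {
  gen <- synthetic_study_set(seed = 4)
  o1 <- withr::local_tempdir(); o2 <- withr::local_tempdir()
  run_all(pipeline_config(gen$nt, out_dir = o1))
  run_all(pipeline_config(gen$nt, out_dir = o2))
  for (f in list.files(o1))
    expect_identical(readLines(file.path(o1, f)),
                     readLines(file.path(o2, f)))

  empty <- data.frame(id = character(), description = character(),
                      sequence = character(), stringsAsFactors = FALSE)
  out <- file.path(withr::local_tempdir(), "never")
  expect_error(run_all(pipeline_config(empty, out_dir = out)))
  expect_false(dir.exists(out))  # no partial outputs
})

test_that("the pipeline carries the expression stage when Ct data are supplied", {
  gen <- synthetic_study_set(seed = 6)
  genes <- data.frame(gene = c("ca4", "rplp0"), efficiency = c(2, 1.95))
  folds <- rbind(c(1, 6, 0.5), c(1, 1, 1))
  q <- generate_qpcr(genes, folds, noise_sd = 0, seed = 6)
  cfg <- pipeline_config(gen$nt, ct = q$ct, dilution_series = q$dilution_series,
                         expression_design = list(targets = "ca4",
                                                  reference = "rplp0",
                                                  control_fraction = "total"))
  res <- run_all(cfg)
  pf <- res$pfaffl
  expect_equal(pf$ratio[pf$sample_fraction == "calcifying"], 6,
               tolerance = 0.02)
  expect_equal(pf$ratio[pf$sample_fraction == "polyps"], 0.5,
               tolerance = 0.02)
  expect_error(pipeline_config(gen$nt, ct = q$ct),
               "curves or a dilution series")
})
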