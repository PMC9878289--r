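test_that("observations cover exactly the PSV sites within the read span", {
  cfg <- test_cfg()
  read <- make_read(70247700, strrep("A", 150))
  obs <- extract_psv_observations(read, cfg)
  expect_setequal(obs$pos, c(70247724, 70247773))

  ctrl <- make_read(11000100, strrep("A", 150), chrom = "chr1")
  expect_equal(nrow(extract_psv_observations(ctrl, cfg)), 0)
})

test_that("an N at a covered PSV is passed through and then dropped by the classifier", {
  cfg <- test_cfg()
  seq <- strrep("A", 150)
  substr(seq, 70247724 - 70247700 + 1, 70247724 - 70247700 + 1) <- "N"
  read <- make_read(70247700, seq)
  obs <- extract_psv_observations(read, cfg)
  expect_true("N" %in% obs$base)
  only_n <- obs[obs$base == "N", ]
  expect_equal(classify_read(only_n, cfg$thresholds), "UNINFORMATIVE")
})

test_that("majority vote classifies reads, ties are AMBIGUOUS", {
  thr <- calling_thresholds()
  ob <- function(base, s1, s2, qual = 30) {
    tibble::tibble(read_id = "r", read_row = 1L, chrom = "chr5", pos = 1L,
                   smn1_base = s1, smn2_base = s2, base = base, qual = qual)
  }
  expect_equal(classify_read(ob("C", "C", "T"), thr), "SMN1")
  expect_equal(classify_read(ob("T", "C", "T"), thr), "SMN2")
  expect_equal(classify_read(dplyr::bind_rows(ob("C", "C", "T"),
                                              ob("T", "C", "T")), thr),
               "AMBIGUOUS")
  expect_equal(classify_read(dplyr::bind_rows(ob("C", "C", "T"),
                                              ob("C", "C", "T"),
                                              ob("T", "C", "T")), thr),
               "SMN1")
  # only third alleles: a tie at zero
  expect_equal(classify_read(ob("G", "C", "T"), thr), "AMBIGUOUS")
  # below the quality gate
  expect_equal(classify_read(ob("C", "C", "T", qual = 10), thr),
               "UNINFORMATIVE")
  expect_equal(classify_read(ob("C", "C", "T")[0, ], thr), "UNINFORMATIVE")
})

test_that("majority vote agrees with a Hamming-distance oracle whenever distances differ", {
  # Oracle: compare each read against both paralog templates by Hamming
  # distance. Substitution errors off PSV sites add equally to both
  # distances, so the distances differ exactly when the PSV majority does.
  cfg <- test_cfg()
  params <- simulation_params(haploid_depth = 20, error_rate = 0.01)
  sim <- simulate_sample(geno("s", 1, 1), params, cfg, seed = 77)
  pad <- as.integer(ceiling(params$fragment_mean + 3 * params$fragment_sd))
  tpl1 <- smascreen:::interval_template(cfg$smn_region, pad, cfg, "smn1")
  tpl2 <- smascreen:::interval_template(cfg$smn_region, pad, cfg, "smn2")
  smn <- sim$reads[grepl("^SMN", sim$reads$read_id), ]
  cls <- classify_reads(smn, cfg)$read_class
  hamming <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  checked <- 0L
  for (i in seq_len(nrow(smn))) {
    off <- smn$pos[i] - tpl1$start + 1L
    ref1 <- substr(tpl1$seq, off, off + nchar(smn$seq[i]) - 1L)
    ref2 <- substr(tpl2$seq, off, off + nchar(smn$seq[i]) - 1L)
    d1 <- hamming(smn$seq[i], ref1)
    d2 <- hamming(smn$seq[i], ref2)
    if (d1 != d2) {
      expect_equal(cls[i], if (d1 < d2) "SMN1" else "SMN2")
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 50)
})

test_that("classification partitions the read set", {
  cfg <- test_cfg()
  sim <- simulate_sample(geno("s", 2, 1), simulation_params(haploid_depth = 10),
                         cfg, seed = 12)
  cls <- classify_reads(sim$reads, cfg)
  counts <- table(factor(cls$read_class,
                         c("SMN1", "SMN2", "AMBIGUOUS", "UNINFORMATIVE")))
  expect_equal(sum(counts), nrow(sim$reads))
  expect_gt(counts[["SMN1"]], 0)
  expect_gt(counts[["SMN2"]], 0)
})

test_that("swapping the allele definitions swaps SMN1 and SMN2 exactly", {
  cfg <- test_cfg()
  sim <- simulate_sample(geno("s", 2, 1), simulation_params(haploid_depth = 10),
                         cfg, seed = 13)
  swapped <- cfg
  swapped$psv_sites$smn1_base <- cfg$psv_sites$smn2_base
  swapped$psv_sites$smn2_base <- cfg$psv_sites$smn1_base
  a <- classify_reads(sim$reads, cfg)$read_class
  b <- classify_reads(sim$reads, swapped)$read_class
  expect_identical(b == "SMN1", a == "SMN2")
  expect_identical(b == "SMN2", a == "SMN1")
  expect_identical(b == "AMBIGUOUS", a == "AMBIGUOUS")
})

test_that("on error-free reads every classification matches the template of origin", {
  cfg <- test_cfg()
  sim <- simulate_sample(geno("s", 2, 2),
                         simulation_params(haploid_depth = 20, error_rate = 0),
                         cfg, seed = 21)
  cls <- classify_reads(sim$reads, cfg)
  informative <- cls$read_class %in% c("SMN1", "SMN2", "AMBIGUOUS")
  origin <- sub("_.*", "", cls$read_id)
  # every informative read is assigned to its true template, never the other
  expect_true(all(cls$read_class[informative] == origin[informative]))
  # and every SMN read covering >= 1 PSV is informative
  obs <- psv_observations(sim$reads, cfg)
  covering <- unique(obs$read_row)
  expect_true(all(cls$read_class[covering] %in% c("SMN1", "SMN2")))
})

test_that("pileup counts carry no SMN1 support when SMN1 is absent", {
  cfg <- test_cfg()
  sim <- simulate_sample(geno("s", 0, 2),
                         simulation_params(haploid_depth = 50, error_rate = 0),
                         cfg, seed = 2)
  pu <- build_pileup(sim$reads, cfg)
  expect_equal(pu$smn1_count, rep(0L, 3))
  expect_true(all(pu$smn2_count > 0))
  # MAPQ-0 reads are the evidence: nothing was filtered on mapping quality
  expect_true(all(sim$reads$mapq[grepl("^SMN", sim$reads$read_id)] == 0))
})

test_that("pileup of an empty read set is all zeros", {
  pu <- build_pileup(make_read(1, "ACGT")[0, ], test_cfg())
  expect_equal(nrow(pu), 3)
  expect_equal(pu$smn1_count + pu$smn2_count + pu$other_count, rep(0L, 3))
})

test_that("gapped alignments over a PSV are skipped with a warning", {
  cfg <- test_cfg()
  read <- make_read(70247700, strrep("A", 150), cigar = "75M1D75M")
  w <- capture_warnings(obs <- psv_observations(read, cfg))
  expect_gt(length(w), 0)
  expect_match(w, "non-M CIGAR", all = TRUE)
  expect_equal(nrow(obs), 0)
})

test_that("base-quality gate removes low-quality PSV evidence from the pileup", {
  cfg <- test_cfg()
  seq <- strrep("A", 150)
  s1 <- cfg$psv_sites$smn1_base[1]
  substr(seq, 25, 25) <- s1 # site 70247724 at offset 25 of a read at 70247700
  lowq <- strrep("?", 150)
  substr(lowq, 25, 25) <- "+" # Phred 10 at the PSV
  reads <- dplyr::bind_rows(
    make_read(70247700, seq, read_id = "hi"),
    make_read(70247700, seq, read_id = "lo", qual = lowq)
  )
  pu <- build_pileup(reads, cfg)
  expect_equal(pu$smn1_count[pu$pos == 70247724], 1L)
})
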