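# Shared fixtures: everything is generated in code at test time.

test_cfg <- function() default_locus_config()

geno <- function(id, smn1, smn2) {
  list(sample_id = id, smn1_copies = smn1, smn2_copies = smn2)
}

# A single ungapped read as a one-row tibble, defaulting to Q30 bases.
make_read <- function(pos, seq, chrom = "chr5", read_id = "r1", qual = NULL,
                      mapq = 0L, flag = 0L, cigar = NULL) {
  tibble::tibble(
    read_id = read_id, flag = as.integer(flag), chrom = chrom,
    pos = as.integer(pos), mapq = as.integer(mapq),
    cigar = cigar %||% paste0(nchar(seq), "M"),
    seq = seq, qual = qual %||% strrep("?", nchar(seq)),
    mate_chrom = NA_character_, mate_pos = NA_integer_, tlen = 0L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# The study panel: 12 homozygous-deletion positives (smn2 in 1..3) and
# 4 non-deleted negatives (carriers and 2-copy samples).
panel_genotypes <- function() {
  tibble::tibble(
    sample_id = sprintf("ctrl%02d", 1:16),
    smn1_copies = c(rep(0L, 12), 1L, 2L, 1L, 2L),
    smn2_copies = c(rep(1:3, 4), 2L, 2L, 1L, 0L)
  )
}

# In-memory screen of one simulated genotype (no SAM round trip).
sim_and_screen <- function(smn1, smn2, seed, params = simulation_params(),
                           cfg = test_cfg()) {
  sim <- simulate_sample(geno("s", smn1, smn2), params, cfg, seed)
  screen_sample(sim$reads, cfg, sample_id = "s")
}
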