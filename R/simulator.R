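#' Simulation parameters for the aligned-read generator
#'
#' Defaults mirror the assay's sequencing design: 2 x 150 bp paired reads
#' (300-cycle chemistry) from ~300 bp capture fragments, a per-base
#' substitution error rate of 0.001, and a haploid depth of 50X per gene copy
#' (so a diploid control gene sits at 100X, comfortably clear of the 20X
#' failure threshold and on the same order as the assay's observed control
#' depth).
#'
#' @param haploid_depth Mean fold-coverage contributed by one gene copy.
#' @param read_length Read length in bases.
#' @param paired Emit read pairs (`TRUE`) or single reads.
#' @param error_rate Per-base substitution probability in `[0, 0.1]`.
#' @param fragment_mean,fragment_sd Capture fragment length model (normal,
#'   truncated to `[read_length, fragment_mean + 3 * fragment_sd]`).
#' @param low_qual_fraction Fraction of bases assigned Phred 10 instead of the
#'   default Phred 30, for exercising the base-quality gate.
#'
#' @return A named list of class `sim_params`.
#' @export
simulation_params <- function(haploid_depth = 50,
                              read_length = 150,
                              paired = TRUE,
                              error_rate = 0.001,
                              fragment_mean = 300,
                              fragment_sd = 30,
                              low_qual_fraction = 0) {
  if (haploid_depth <= 0) abort("haploid_depth must be > 0")
  if (read_length < 50) abort("read_length must be >= 50")
  if (error_rate < 0 || error_rate > 0.1) abort("error_rate must be in [0, 0.1]")
  if (low_qual_fraction < 0 || low_qual_fraction > 1) {
    abort("low_qual_fraction must be in [0, 1]")
  }
  structure(list(
    haploid_depth = as.numeric(haploid_depth),
    read_length = as.integer(read_length),
    paired = isTRUE(paired),
    error_rate = as.numeric(error_rate),
    fragment_mean = as.numeric(fragment_mean),
    fragment_sd = as.numeric(fragment_sd),
    low_qual_fraction = as.numeric(low_qual_fraction)
  ), class = "sim_params")
}

BASES <- c("A", "C", "G", "T")
Q30_CHAR <- "?" # Phred 30, offset 33
Q10_CHAR <- "+" # Phred 10

# Deterministic reference template for an interval, padded on both sides so
# fragments overhanging the interval can still be sequenced. The template is a
# fixed pseudo-random sequence keyed on the interval coordinates; SMN1/SMN2
# variants write their PSV alleles on top of the shared backbone, so the two
# paralog templates differ only at PSV positions.
interval_template <- function(interval, pad, cfg = NULL,
                              paralog = c("none", "smn1", "smn2")) {
  paralog <- match.arg(paralog)
  tpl_start <- interval$start - pad
  len <- interval$end + pad - tpl_start + 1L
  seed <- as.integer((interval$start + 7L * interval$end) %% 2147483587)
  chars <- withr::with_seed(seed, sample(BASES, len, replace = TRUE))
  if (paralog != "none") {
    base_col <- paste0(paralog, "_base")
    ps <- cfg$psv_sites[cfg$psv_sites$chrom == interval$chrom, ]
    off <- ps$pos - tpl_start + 1L
    keep <- off >= 1 & off <= len
    chars[off[keep]] <- ps[[base_col]][keep]
  }
  list(seq = paste(chars, collapse = ""), start = tpl_start)
}

# Draw reads for one template at a given copy number. Fragment starts are
# uniform over every position whose fragment overlaps the interval, so
# per-base depth inside the interval is flat with mean copies * haploid_depth.
sim_reads_from_template <- function(tpl, interval, copies, params, mapq, origin) {
  L <- params$read_length
  len <- interval$end - interval$start + 1L
  if (copies == 0) return(empty_read_tbl())
  if (params$paired) {
    span <- len + params$fragment_mean - 1
    n <- rpois(1L, copies * params$haploid_depth * span / (2 * L))
    if (n == 0) return(empty_read_tbl())
    fl <- round(rnorm(n, params$fragment_mean, params$fragment_sd))
    fl <- pmin(pmax(fl, L), params$fragment_mean + 3 * params$fragment_sd)
    fs <- (interval$start - fl + 1L) + floor(runif(n) * (len + fl - 1))
    r1 <- fs
    r2 <- fs + fl - L
    ids <- paste0(origin, "_", seq_len(n))
    off1 <- r1 - tpl$start + 1L
    off2 <- r2 - tpl$start + 1L
    tibble(
      read_id = rep(ids, 2L),
      flag = rep(c(99L, 147L), each = n),
      chrom = interval$chrom,
      pos = as.integer(c(r1, r2)),
      mapq = as.integer(mapq),
      cigar = paste0(L, "M"),
      seq = substring(tpl$seq, c(off1, off2), c(off1, off2) + L - 1L),
      qual = strrep(Q30_CHAR, L),
      mate_chrom = interval$chrom,
      mate_pos = as.integer(c(r2, r1)),
      tlen = as.integer(c(fl, -fl))
    )
  } else {
    n <- rpois(1L, copies * params$haploid_depth * (len + L - 1) / L)
    if (n == 0) return(empty_read_tbl())
    pos <- (interval$start - L + 1L) + floor(runif(n) * (len + L - 1))
    off <- pos - tpl$start + 1L
    tibble(
      read_id = paste0(origin, "_", seq_len(n)),
      flag = 0L,
      chrom = interval$chrom,
      pos = as.integer(pos),
      mapq = as.integer(mapq),
      cigar = paste0(L, "M"),
      seq = substring(tpl$seq, off, off + L - 1L),
      qual = strrep(Q30_CHAR, L),
      mate_chrom = NA_character_,
      mate_pos = NA_integer_,
      tlen = 0L
    )
  }
}

empty_read_tbl <- function() {
  tibble(
    read_id = character(), flag = integer(), chrom = character(),
    pos = integer(), mapq = integer(), cigar = character(),
    seq = character(), qual = character(), mate_chrom = character(),
    mate_pos = integer(), tlen = integer()
  )
}

inject_base_errors <- function(seqs, error_rate, read_length) {
  if (error_rate <= 0 || length(seqs) == 0) return(seqs)
  n_bases <- length(seqs) * read_length
  hit <- which(runif(n_bases) < error_rate)
  if (length(hit) == 0) return(seqs)
  i <- (hit - 1L) %/% read_length + 1L
  j <- (hit - 1L) %% read_length + 1L
  shift <- sample.int(3L, length(hit), replace = TRUE)
  for (k in seq_along(hit)) {
    cur <- substr(seqs[i[k]], j[k], j[k])
    substr(seqs[i[k]], j[k], j[k]) <-
      BASES[(match(cur, BASES) - 1L + shift[k]) %% 4L + 1L]
  }
  seqs
}

inject_low_quals <- function(quals, fraction, read_length) {
  if (fraction <= 0 || length(quals) == 0) return(quals)
  hit <- which(runif(length(quals) * read_length) < fraction)
  i <- (hit - 1L) %/% read_length + 1L
  j <- (hit - 1L) %% read_length + 1L
  for (k in seq_along(hit)) substr(quals[i[k]], j[k], j[k]) <- Q10_CHAR
  quals
}

#' Simulate one sample's aligned reads with known SMN1/SMN2 copy numbers
#'
#' Emulates the post-alignment view of a capture-panel library: reads over the
#' SMN capture region are drawn from `smn1_copies` SMN1 template copies and
#' `smn2_copies` SMN2 template copies (identical except at the PSV positions)
#' and are all reported in SMN1-anchored coordinates with MAPQ 0, reflecting
#' paralog co-mapping; each control interval is sequenced at diploid depth
#' (2 x `haploid_depth`) with MAPQ 60. Read counts are Poisson, fragment
#' starts uniform, and each emitted base is substituted to a uniformly chosen
#' different base with probability `error_rate`. Output is deterministic
#' given `seed`. Read ids are prefixed with the template of origin, giving
#' downstream tests ground truth for per-read classification.
#'
#' @param genotype One-row data frame (or named list) with `sample_id`,
#'   `smn1_copies`, `smn2_copies`. `smn1_copies = 0` is a homozygous SMN1
#'   exon 7 deletion (the screened condition); 1 a carrier; 2+ unaffected.
#' @param params A [simulation_params()] object.
#' @param cfg An [locus_config()] object.
#' @param seed Integer seed; same inputs and seed give identical reads.
#'
#' @return A list with `reads` (tibble, one row per read) and `truth` (one-row
#'   tibble: `sample_id`, `smn1_copies`, `smn2_copies`, `expected_call`).
#' @export
#' @examples
#' cfg <- default_locus_config()
#' sim <- simulate_sample(list(sample_id = "s1", smn1_copies = 0, smn2_copies = 2),
#'                        simulation_params(haploid_depth = 10), cfg, seed = 1)
#' sim$truth
simulate_sample <- function(genotype, params, cfg, seed) {
  g <- as.list(genotype)
  if (is.null(g$sample_id) || is.na(g$smn1_copies) || is.na(g$smn2_copies) ||
      g$smn1_copies < 0 || g$smn2_copies < 0) {
    abort("genotype needs sample_id and nonnegative smn1_copies, smn2_copies")
  }
  total_copies <- g$smn1_copies + g$smn2_copies
  if (total_copies == 0 && (nrow(cfg$control_genes) == 0 || params$haploid_depth == 0)) {
    abort("nothing to simulate: zero template copies and zero control depth")
  }
  pad <- as.integer(ceiling(params$fragment_mean + 3 * params$fragment_sd))

  reads <- withr::with_seed(as.integer(seed), {
    smn1_tpl <- interval_template(cfg$smn_region, pad, cfg, "smn1")
    smn2_tpl <- interval_template(cfg$smn_region, pad, cfg, "smn2")
    parts <- list(
      sim_reads_from_template(smn1_tpl, cfg$smn_region, g$smn1_copies,
                              params, mapq = 0L, origin = "SMN1"),
      sim_reads_from_template(smn2_tpl, cfg$smn_region, g$smn2_copies,
                              params, mapq = 0L, origin = "SMN2")
    )
    for (i in seq_len(nrow(cfg$control_genes))) {
      ctrl <- cfg$control_genes[i, ]
      tpl <- interval_template(ctrl, pad)
      parts[[length(parts) + 1L]] <-
        sim_reads_from_template(tpl, ctrl, copies = 2L, params,
                                mapq = 60L, origin = ctrl$label)
    }
    out <- dplyr::bind_rows(parts)
    out$seq <- inject_base_errors(out$seq, params$error_rate, params$read_length)
    out$qual <- inject_low_quals(out$qual, params$low_qual_fraction,
                                 params$read_length)
    out
  })

  truth <- tibble(
    sample_id = g$sample_id,
    smn1_copies = as.integer(g$smn1_copies),
    smn2_copies = as.integer(g$smn2_copies),
    expected_call = if (g$smn1_copies == 0) "POSITIVE" else "NEGATIVE"
  )
  list(reads = reads, truth = truth)
}

#' Simulate a cohort to SAM files with a truth table
#'
#' Runs [simulate_sample()] for each genotype with per-sample seed
#' `base_seed + sample index`, writes one SAM file per sample plus a truth
#' table (`truth.tsv`) and a cohort manifest (`manifest.tsv`) into `out_dir`.
#'
#' @param genotypes Data frame with columns `sample_id` (unique),
#'   `smn1_copies`, `smn2_copies`; one row per sample.
#' @param params A [simulation_params()] object.
#' @param cfg An [locus_config()] object.
#' @param base_seed Integer; sample `i` uses seed `base_seed + i`.
#' @param out_dir Output directory (created if needed).
#'
#' @return A tibble manifest: `sample_id`, `smn1_copies`, `smn2_copies`,
#'   `expected_call`, `seed`, `sam_path`.
#' @export
simulate_cohort <- function(genotypes, params, cfg, base_seed, out_dir) {
  genotypes <- as_tibble(genotypes)
  if (nrow(genotypes) > 0 && anyDuplicated(genotypes$sample_id)) {
    abort(paste0("duplicate sample_id: ",
                 paste(unique(genotypes$sample_id[duplicated(genotypes$sample_id)]),
                       collapse = ", ")))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- purrr::map_dfr(seq_len(nrow(genotypes)), function(i) {
    seed_i <- as.integer(base_seed) + i
    sim <- simulate_sample(genotypes[i, ], params, cfg, seed = seed_i)
    sam_path <- file.path(out_dir, paste0(genotypes$sample_id[i], ".sam"))
    write_sam(sim$reads, sam_path, cfg = cfg)
    dplyr::mutate(sim$truth, seed = seed_i, sam_path = sam_path)
  })
  if (nrow(manifest) == 0) {
    manifest <- tibble(sample_id = character(), smn1_copies = integer(),
                       smn2_copies = integer(), expected_call = character(),
                       seed = integer(), sam_path = character())
  }
  readr::write_tsv(manifest[c("sample_id", "smn1_copies", "smn2_copies",
                              "expected_call")],
                   file.path(out_dir, "truth.tsv"))
  readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  manifest
}

#' Read a truth table written by [simulate_cohort()]
#'
#' @param path Path to a `truth.tsv` file.
#' @return A tibble with `sample_id`, `smn1_copies`, `smn2_copies`,
#'   `expected_call`.
#' @export
read_truth <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    sample_id = readr::col_character(),
                    smn1_copies = readr::col_integer(),
                    smn2_copies = readr::col_integer(),
                    expected_call = readr::col_character()
                  ))
}
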