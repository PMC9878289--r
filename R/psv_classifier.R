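#' Extract PSV base observations from reads
#'
#' For every read and every configured paralog-specific variant (PSV) site the
#' read's aligned span covers, reports the read base and its Phred quality at
#' that site. Offsets are computed by ungapped arithmetic, which is exact for
#' pure-match alignments; reads whose CIGAR carries indels or clipping over
#' the locus are skipped with a warning rather than mis-read. Mapping quality
#' is deliberately ignored: reads co-mapping to both paralogs carry MAPQ ~0
#' and are exactly the evidence the method needs.
#'
#' @param reads Read tibble ([read_sam()] / [simulate_sample()] format).
#' @param cfg An [locus_config()] object.
#' @return A tibble with one row per (read, covered PSV site):
#'   `read_id`, `read_row`, `chrom`, `pos`, `smn1_base`, `smn2_base`,
#'   `base`, `qual`.
#' @export
psv_observations <- function(reads, cfg) {
  ps <- cfg$psv_sites
  if (nrow(reads) == 0) return(empty_obs_tbl())
  ungapped <- grepl("^[0-9]+M$", reads$cigar)
  len <- nchar(reads$seq)
  out <- purrr::map_dfr(seq_len(nrow(ps)), function(i) {
    off <- ps$pos[i] - reads$pos + 1L
    covers <- reads$chrom == ps$chrom[i] & off >= 1L & off <= len
    gapped_hit <- covers & !ungapped
    if (any(gapped_hit)) {
      warn(paste0(sum(gapped_hit), " read(s) with non-M CIGAR over PSV ",
                  ps$chrom[i], ":", ps$pos[i], " skipped"))
    }
    take <- which(covers & ungapped)
    if (length(take) == 0) return(empty_obs_tbl())
    tibble(
      read_id = reads$read_id[take],
      read_row = take,
      chrom = ps$chrom[i],
      pos = ps$pos[i],
      smn1_base = ps$smn1_base[i],
      smn2_base = ps$smn2_base[i],
      base = substr(reads$seq[take], off[take], off[take]),
      qual = qual_char_to_phred(substr(reads$qual[take], off[take], off[take]))
    )
  })
  if (nrow(out) == 0) empty_obs_tbl() else out
}

empty_obs_tbl <- function() {
  tibble(read_id = character(), read_row = integer(), chrom = character(),
         pos = integer(), smn1_base = character(), smn2_base = character(),
         base = character(), qual = integer())
}

#' Extract PSV observations for a single read
#'
#' Single-read convenience over [psv_observations()].
#'
#' @param read A one-row read tibble (or named list with `read_id`, `chrom`,
#'   `pos`, `seq`, `qual`, `cigar`).
#' @param cfg An [locus_config()] object.
#' @return A tibble of observations (possibly empty).
#' @export
extract_psv_observations <- function(read, cfg) {
  read <- as_tibble(as.list(read))
  if (is.null(read$cigar)) read$cigar <- paste0(nchar(read$seq), "M")
  psv_observations(read, cfg)
}

#' Classify one read from its PSV observations
#'
#' Majority vote over usable observations: bases with quality below
#' `min_base_quality` or equal to `N` are dropped; the remainder are matched
#' against the configured SMN1 and SMN2 alleles. `SMN1` if SMN1 matches
#' outnumber SMN2 matches, `SMN2` for the converse, `AMBIGUOUS` on a tie
#' (including reads showing only third alleles), and `UNINFORMATIVE` when no
#' usable observation remains. The tie rule is deliberately conservative: an
#' ambiguous read never contributes SMN1 evidence.
#'
#' @param observations Observation tibble from [psv_observations()].
#' @param thresholds A [calling_thresholds()] object.
#' @return One of `"SMN1"`, `"SMN2"`, `"AMBIGUOUS"`, `"UNINFORMATIVE"`.
#' @export
classify_read <- function(observations, thresholds = calling_thresholds()) {
  usable <- observations$qual >= thresholds$min_base_quality &
    observations$base != "N"
  obs <- observations[usable, ]
  if (nrow(obs) == 0) return("UNINFORMATIVE")
  n1 <- sum(obs$base == obs$smn1_base)
  n2 <- sum(obs$base == obs$smn2_base)
  if (n1 > n2) "SMN1" else if (n2 > n1) "SMN2" else "AMBIGUOUS"
}

#' Classify every read in a read set
#'
#' Vectorised [classify_read()] over a read tibble: assigns each read to
#' SMN1, SMN2, AMBIGUOUS or UNINFORMATIVE from its PSV bases.
#'
#' @param reads Read tibble.
#' @param cfg An [locus_config()] object.
#' @return `reads` with an added `read_class` character column.
#' @export
#' @examples
#' cfg <- default_locus_config()
#' sim <- simulate_sample(list(sample_id = "s", smn1_copies = 2, smn2_copies = 0),
#'                        simulation_params(haploid_depth = 5, error_rate = 0),
#'                        cfg, seed = 7)
#' dplyr::count(classify_reads(sim$reads, cfg), read_class)
classify_reads <- function(reads, cfg) {
  thr <- cfg$thresholds
  if (nrow(reads) == 0) {
    return(dplyr::mutate(reads, read_class = character()))
  }
  obs <- psv_observations(reads, cfg)
  usable <- obs[obs$qual >= thr$min_base_quality & obs$base != "N", ]
  n1 <- n2 <- n_obs <- integer(nrow(reads))
  if (nrow(usable) > 0) {
    agg <- usable |>
      dplyr::group_by(.data$read_row) |>
      dplyr::summarise(
        n1 = sum(.data$base == .data$smn1_base),
        n2 = sum(.data$base == .data$smn2_base),
        n = dplyr::n(), .groups = "drop"
      )
    n1[agg$read_row] <- agg$n1
    n2[agg$read_row] <- agg$n2
    n_obs[agg$read_row] <- agg$n
  }
  cls <- dplyr::case_when(
    n_obs == 0 ~ "UNINFORMATIVE",
    n1 > n2 ~ "SMN1",
    n2 > n1 ~ "SMN2",
    TRUE ~ "AMBIGUOUS"
  )
  dplyr::mutate(reads, read_class = cls)
}

#' Build per-site PSV pileup counts
#'
#' Aggregates, for each PSV site, the number of quality-passing read bases
#' matching the SMN1 allele, the SMN2 allele, or neither (third alleles and
#' `N`). Each read contributes at most one observation per site. Reads with
#' MAPQ 0 are included by design: paralog co-mapping makes MAPQ uninformative
#' at these sites, and filtering on it would discard the entire signal.
#'
#' @param reads Read tibble.
#' @param cfg An [locus_config()] object.
#' @return A tibble with one row per PSV site: `chrom`, `pos`, `smn1_count`,
#'   `smn2_count`, `other_count`.
#' @export
build_pileup <- function(reads, cfg) {
  thr <- cfg$thresholds
  ps <- cfg$psv_sites
  base_tbl <- tibble(chrom = ps$chrom, pos = ps$pos,
                     smn1_count = 0L, smn2_count = 0L, other_count = 0L)
  if (nrow(reads) == 0) return(base_tbl)
  obs <- psv_observations(reads, cfg)
  obs <- obs[obs$qual >= thr$min_base_quality, ]
  if (nrow(obs) == 0) return(base_tbl)
  agg <- obs |>
    dplyr::group_by(.data$chrom, .data$pos) |>
    dplyr::summarise(
      smn1_count = sum(.data$base == .data$smn1_base),
      smn2_count = sum(.data$base == .data$smn2_base),
      other_count = sum(.data$base != .data$smn1_base &
                          .data$base != .data$smn2_base),
      .groups = "drop"
    )
  out <- dplyr::rows_update(base_tbl, agg, by = c("chrom", "pos"))
  out[order(match(out$pos, ps$pos)), ]
}
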