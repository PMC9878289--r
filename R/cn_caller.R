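#' Compute per-sample coverage and QC metrics
#'
#' Depth over each control interval is the number of aligned bases falling in
#' the interval divided by its length; `mean_control_depth` averages over
#' control intervals. Uniformity is the fraction of targeted control bases
#' covered at >= 0.2 x the sample's mean control depth. `psv_total_depth` is
#' the mean, over PSV sites, of all quality-passing observations regardless
#' of allele.
#'
#' @param reads Read tibble.
#' @param pileup Pileup tibble from [build_pileup()].
#' @param cfg An [locus_config()] object.
#' @return A one-row tibble: `mean_control_depth`, `uniformity`,
#'   `psv_total_depth`, `total_reads`, and `per_gene_depth` (list column
#'   holding a per-interval tibble).
#' @export
compute_metrics <- function(reads, pileup, cfg) {
  cg <- cfg$control_genes
  if (nrow(reads) == 0) {
    per_gene <- dplyr::mutate(cg, depth = 0)
    return(tibble(
      mean_control_depth = 0, uniformity = 0, psv_total_depth = 0,
      total_reads = 0L, per_gene_depth = list(per_gene)
    ))
  }
  read_end <- reads$pos + nchar(reads$seq) - 1L
  depths <- vapply(seq_len(nrow(cg)), function(i) {
    on_chrom <- reads$chrom == cg$chrom[i]
    overlap <- pmax(0L, pmin(read_end[on_chrom], cg$end[i]) -
                      pmax(reads$pos[on_chrom], cg$start[i]) + 1L)
    sum(overlap) / (cg$end[i] - cg$start[i] + 1L)
  }, numeric(1))
  mean_depth <- mean(depths)

  uniformity <- if (mean_depth == 0) 0 else {
    threshold <- 0.2 * mean_depth
    covered <- 0L
    total <- 0L
    for (i in seq_len(nrow(cg))) {
      on_chrom <- which(reads$chrom == cg$chrom[i])
      len <- cg$end[i] - cg$start[i] + 1L
      total <- total + len
      if (length(on_chrom) == 0) next
      ir <- IRanges::IRanges(start = reads$pos[on_chrom],
                             end = read_end[on_chrom])
      cov <- IRanges::coverage(ir, width = max(cg$end[i], max(read_end[on_chrom])))
      per_base <- as.integer(IRanges::Views(cov, cg$start[i], cg$end[i])[[1]])
      covered <- covered + sum(per_base >= threshold)
    }
    covered / total
  }

  tibble(
    mean_control_depth = mean_depth,
    uniformity = uniformity,
    psv_total_depth = mean(pileup$smn1_count + pileup$smn2_count +
                             pileup$other_count),
    total_reads = nrow(reads),
    per_gene_depth = list(dplyr::mutate(cg, depth = depths))
  )
}

#' Apply sample-level quality control
#'
#' A sample fails when the pre-capture library failed (a wet-lab flag carried
#' as metadata), when mean control-gene depth is strictly below
#' `min_control_depth` (20X by default -- exactly 20.0X passes), when mean
#' PSV-site depth is strictly below `min_psv_total_depth`, or when coverage
#' uniformity is strictly below `min_uniformity`. The reason names the first
#' failing rule in that order.
#'
#' @param metrics Metrics tibble from [compute_metrics()].
#' @param thresholds A [calling_thresholds()] object.
#' @param library_failed Optional wet-lab flag: insufficient pre-capture
#'   library forces a FAIL.
#' @return A list with `pass` (logical) and `fail_reason` (empty string when
#'   passing).
#' @export
qc_sample <- function(metrics, thresholds = calling_thresholds(),
                      library_failed = FALSE) {
  reason <-
    if (isTRUE(library_failed)) {
      "insufficient pre-capture library"
    } else if (metrics$mean_control_depth < thresholds$min_control_depth) {
      sprintf("control depth < %gX", thresholds$min_control_depth)
    } else if (metrics$psv_total_depth < thresholds$min_psv_total_depth) {
      sprintf("PSV depth < %g", thresholds$min_psv_total_depth)
    } else if (metrics$uniformity < thresholds$min_uniformity) {
      sprintf("uniformity < %g", thresholds$min_uniformity)
    } else ""
  list(pass = reason == "", fail_reason = reason)
}

#' Compute the SMN1 exon 7 coverage score
#'
#' The score expresses SMN1 exon 7 support in copy-equivalents: at each PSV
#' site, SMN1-supporting depth is divided by half the mean control-gene depth
#' (control genes are diploid, so half their depth corresponds to one gene
#' copy), and the per-site scores are averaged. A sample with two intact SMN1
#' copies scores ~2, a carrier ~1, and a homozygous exon 7 deletion ~0.
#'
#' @param pileup Pileup tibble from [build_pileup()].
#' @param metrics Metrics tibble from [compute_metrics()]; must have
#'   `mean_control_depth > 0` (samples with zero control depth fail QC before
#'   scoring).
#' @return A list of class `coverage_score`: `score` (mean over sites) and
#'   `per_site` (tibble with `chrom`, `pos`, `smn1_count`, `site_score`).
#' @export
coverage_score <- function(pileup, metrics) {
  if (metrics$mean_control_depth <= 0) {
    abort("coverage score undefined: mean control depth is zero (sample should have failed QC)")
  }
  one_copy_depth <- metrics$mean_control_depth / 2
  per_site <- tibble(
    chrom = pileup$chrom,
    pos = pileup$pos,
    smn1_count = pileup$smn1_count,
    site_score = pileup$smn1_count / one_copy_depth
  )
  structure(list(score = mean(per_site$site_score), per_site = per_site),
            class = "coverage_score")
}

#' @export
print.coverage_score <- function(x, ...) {
  cat("<coverage_score>", format(x$score, digits = 4),
      "SMN1 copy-equivalents\n")
  print(x$per_site)
  invisible(x)
}

#' Emit the qualitative screen call for one sample
#'
#' QC takes precedence: a failed sample is reported `FAIL` with no score.
#' Otherwise the sample is `POSITIVE` (homozygous SMN1 exon 7 deletion)
#' when the coverage score is below `deletion_score_cutoff`, else `NEGATIVE`.
#' Carriers (one SMN1 copy, score ~1) are screen negative by design.
#'
#' @param score A [coverage_score()] object (may be `NULL` when QC failed).
#' @param qc QC result from [qc_sample()].
#' @param thresholds A [calling_thresholds()] object.
#' @param sample_id Sample identifier.
#' @param metrics Optional metrics tibble to carry into the result.
#' @return A one-row tibble: `sample_id`, `call`, `score`, QC metrics and
#'   `fail_reason`.
#' @export
call_sample <- function(score, qc, thresholds = calling_thresholds(),
                        sample_id = "sample", metrics = NULL) {
  if (!qc$pass) {
    call <- "FAIL"
    score_val <- NA_real_
  } else {
    score_val <- score$score
    call <- if (score_val < thresholds$deletion_score_cutoff) "POSITIVE" else "NEGATIVE"
  }
  tibble(
    sample_id = sample_id,
    call = call,
    score = score_val,
    mean_control_depth = if (is.null(metrics)) NA_real_ else metrics$mean_control_depth,
    uniformity = if (is.null(metrics)) NA_real_ else metrics$uniformity,
    psv_total_depth = if (is.null(metrics)) NA_real_ else metrics$psv_total_depth,
    total_reads = if (is.null(metrics)) NA_integer_ else metrics$total_reads,
    fail_reason = qc$fail_reason
  )
}

#' Screen one sample's reads end to end
#'
#' Convenience pipeline: pileup, metrics, QC, coverage score, call.
#'
#' @param reads Read tibble.
#' @param cfg An [locus_config()] object.
#' @param sample_id Sample identifier.
#' @param library_failed Wet-lab pre-capture library failure flag.
#' @return A one-row result tibble (see [call_sample()]).
#' @export
#' @examples
#' cfg <- default_locus_config()
#' sim <- simulate_sample(list(sample_id = "s1", smn1_copies = 0, smn2_copies = 2),
#'                        simulation_params(haploid_depth = 30), cfg, seed = 11)
#' screen_sample(sim$reads, cfg, sample_id = "s1")
screen_sample <- function(reads, cfg, sample_id = "sample",
                          library_failed = FALSE) {
  pileup <- build_pileup(reads, cfg)
  metrics <- compute_metrics(reads, pileup, cfg)
  qc <- qc_sample(metrics, cfg$thresholds, library_failed = library_failed)
  score <- if (qc$pass) coverage_score(pileup, metrics) else NULL
  call_sample(score, qc, cfg$thresholds, sample_id = sample_id,
              metrics = metrics)
}
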