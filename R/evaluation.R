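#' Run the screen over a batch of SAM files
#'
#' Each file is read, screened and reported independently; an unreadable or
#' malformed file yields a `FAIL` row with reason `"unreadable input"` and
#' the batch continues. Per-sample results do not depend on processing order.
#'
#' @param sam_paths Character vector of SAM file paths.
#' @param cfg An [locus_config()] object.
#' @param sample_ids Sample identifiers; defaults to file basenames without
#'   extension.
#' @return A cohort tibble (class `sma_cohort`) with one row per sample, the
#'   configuration attached as attribute `config`.
#' @export
run_batch <- function(sam_paths, cfg, sample_ids = NULL) {
  if (is.null(sample_ids)) {
    sample_ids <- sub("\\.[sb]am$", "", basename(sam_paths))
  }
  stopifnot(length(sample_ids) == length(sam_paths))
  rows <- purrr::map2_dfr(sam_paths, sample_ids, function(path, id) {
    tryCatch({
      reads <- read_sam(path)
      screen_sample(reads, cfg, sample_id = id)
    }, error = function(e) {
      tibble(sample_id = id, call = "FAIL", score = NA_real_,
             mean_control_depth = NA_real_, uniformity = NA_real_,
             psv_total_depth = NA_real_, total_reads = NA_integer_,
             fail_reason = "unreadable input")
    })
  })
  if (nrow(rows) == 0) {
    rows <- tibble(sample_id = character(), call = character(),
                   score = numeric(), mean_control_depth = numeric(),
                   uniformity = numeric(), psv_total_depth = numeric(),
                   total_reads = integer(), fail_reason = character())
  }
  new_sma_cohort(rows, cfg)
}

new_sma_cohort <- function(rows, cfg = NULL) {
  structure(as_tibble(rows), config = cfg,
            class = c("sma_cohort", class(as_tibble(rows))))
}

#' Assemble a confusion table for the screen
#'
#' Sensitivity is TP / (TP + FN) and specificity TN / (TN + FP), the standard
#' screening-assay definitions. Cells with an empty denominator give `NA`
#' (not applicable) rather than zero. Failed samples sit outside the 2x2
#' table and are reported through the failure rate.
#'
#' @param tp,fp,tn,fn Nonnegative cell counts.
#' @param fail_count Number of samples failing QC.
#' @return An object of class `sma_confusion`.
#' @export
#' @examples
#' confusion_table(tp = 12, fn = 0, tn = 4, fp = 0)
confusion_table <- function(tp, fp, tn, fn, fail_count = 0) {
  cells <- c(tp = tp, fp = fp, tn = tn, fn = fn, fail_count = fail_count)
  if (any(cells < 0)) abort("confusion counts must be nonnegative")
  total <- tp + fp + tn + fn + fail_count
  structure(list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    fail_count = fail_count, total = total,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    failure_rate = if (total > 0) fail_count / total else NA_real_
  ), class = "sma_confusion")
}

#' Evaluate screen calls against a truth table
#'
#' Joins the cohort's calls to the expected calls and fills the confusion
#' table: a `POSITIVE` call on a truly deleted sample is a true positive, a
#' `POSITIVE` on a non-deleted sample a false positive, and so on. `FAIL`
#' samples are excluded from the 2x2 cells and counted in the failure rate,
#' which the assay reports separately.
#'
#' @param summary Cohort tibble from [run_batch()] (or any data frame with
#'   `sample_id` and `call`).
#' @param truth Truth tibble with `sample_id` and `expected_call`; every
#'   cohort sample must be present.
#' @return An `sma_confusion` object; see [confusion_table()].
#' @export
evaluate <- function(summary, truth) {
  missing_ids <- setdiff(summary$sample_id, truth$sample_id)
  if (length(missing_ids) > 0) {
    abort(paste0("sample(s) missing from truth table: ",
                 paste(head(missing_ids, 5), collapse = ", ")))
  }
  joined <- dplyr::left_join(as_tibble(summary)[c("sample_id", "call")],
                             as_tibble(truth)[c("sample_id", "expected_call")],
                             by = "sample_id")
  confusion_table(
    tp = sum(joined$call == "POSITIVE" & joined$expected_call == "POSITIVE"),
    fp = sum(joined$call == "POSITIVE" & joined$expected_call == "NEGATIVE"),
    tn = sum(joined$call == "NEGATIVE" & joined$expected_call == "NEGATIVE"),
    fn = sum(joined$call == "NEGATIVE" & joined$expected_call == "POSITIVE"),
    fail_count = sum(joined$call == "FAIL")
  )
}

#' @export
print.sma_confusion <- function(x, ...) {
  fmt_pct <- function(v) if (is.na(v)) "n/a" else sprintf("%.1f%%", 100 * v)
  cat("<sma_confusion>", x$total, "samples\n")
  cat(sprintf("  TP %d  FN %d   sensitivity %s\n", x$tp, x$fn,
              fmt_pct(x$sensitivity)))
  cat(sprintf("  TN %d  FP %d   specificity %s\n", x$tn, x$fp,
              fmt_pct(x$specificity)))
  cat(sprintf("  failed %d   failure rate %s\n", x$fail_count,
              fmt_pct(x$failure_rate)))
  invisible(x)
}

#' @describeIn confusion_table Cell counts as a tibble, one row per cell.
#' @param x An `sma_confusion` object.
#' @param ... Unused.
#' @method tidy sma_confusion
#' @export
tidy.sma_confusion <- function(x, ...) {
  tibble(
    cell = c("tp", "fp", "tn", "fn", "fail"),
    count = c(x$tp, x$fp, x$tn, x$fn, x$fail_count)
  )
}

#' @describeIn confusion_table One-row performance summary (sensitivity,
#'   specificity, failure rate).
#' @method glance sma_confusion
#' @export
glance.sma_confusion <- function(x, ...) {
  tibble(
    total = x$total, tp = x$tp, fp = x$fp, tn = x$tn, fn = x$fn,
    fail_count = x$fail_count,
    sensitivity = x$sensitivity, specificity = x$specificity,
    failure_rate = x$failure_rate
  )
}

#' Write per-sample and batch reports
#'
#' Writes `summary.tsv` (one row per sample), one JSON report per sample
#' (call, score, metrics, thresholds used, software version), and optionally
#' a coverage-score scatter plot with the deletion cutoff line. The report
#' timestamp lives in its own JSON key (`generated_at`) so everything else is
#' byte-deterministic across re-runs.
#'
#' @param summary Cohort tibble from [run_batch()].
#' @param out_dir Output directory (created if needed).
#' @param cfg Locus configuration; defaults to the one attached to `summary`.
#' @param plot If `TRUE`, also write `scores.png`.
#' @return Invisible character vector of files written.
#' @export
write_reports <- function(summary, out_dir, cfg = attr(summary, "config"),
                          plot = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- file.path(out_dir, "summary.tsv")
  readr::write_tsv(as_tibble(summary)[, c("sample_id", "call", "score",
                                          "mean_control_depth", "uniformity",
                                          "fail_reason")],
                   files[1])
  thr <- if (!is.null(cfg)) unclass(cfg$thresholds) else NULL
  version <- as.character(utils::packageVersion("smascreen"))
  for (i in seq_len(nrow(summary))) {
    row <- as.list(as_tibble(summary)[i, ])
    report <- list(
      sample_id = row$sample_id,
      call = row$call,
      score = row$score,
      metrics = list(
        mean_control_depth = row$mean_control_depth,
        uniformity = row$uniformity,
        psv_total_depth = row$psv_total_depth,
        total_reads = row$total_reads
      ),
      fail_reason = row$fail_reason,
      thresholds = thr,
      software_version = version,
      generated_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    )
    path <- file.path(out_dir, paste0(row$sample_id, ".json"))
    jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA, null = "null", na = "null")
    files <- c(files, path)
  }
  if (isTRUE(plot)) {
    p <- autoplot(new_sma_cohort(summary, cfg))
    png_path <- file.path(out_dir, "scores.png")
    ggplot2::ggsave(png_path, p, width = 7, height = 4, dpi = 150)
    files <- c(files, png_path)
  }
  invisible(files)
}

#' Plot per-sample coverage scores with the deletion cutoff
#'
#' Scatter of the SMN1 exon 7 coverage score per sample with a dotted
#' horizontal line at the deletion cutoff; samples below the line are screen
#' positive. Failed samples have no score and are omitted.
#'
#' @param object A cohort tibble from [run_batch()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sma_cohort
#' @export
autoplot.sma_cohort <- function(object, ...) {
  cfg <- attr(object, "config")
  cutoff <- if (!is.null(cfg)) cfg$thresholds$deletion_score_cutoff else 0.5
  df <- as_tibble(object)
  df <- df[!is.na(df$score), ]
  df$idx <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$idx, y = .data$score,
                                   colour = .data$call)) +
    ggplot2::geom_point(alpha = 0.7, size = 1.5) +
    ggplot2::geom_hline(yintercept = cutoff, linetype = "dotted") +
    ggplot2::scale_colour_manual(values = c(POSITIVE = "#c0392b",
                                            NEGATIVE = "#2c3e50")) +
    ggplot2::labs(x = "sample", y = "SMN1 exon 7 coverage score (copy-equivalents)",
                  colour = "screen call") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.sma_cohort
#' @param summary A cohort tibble from [run_batch()].
#' @export
plot_coverage_scores <- function(summary, ...) autoplot.sma_cohort(summary, ...)
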