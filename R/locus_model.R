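#' Calling thresholds for the SMA screen
#'
#' Bundles the quality-control and calling thresholds used throughout the
#' screen. Defaults reflect the assay's operating point: samples fail when
#' mean control-gene depth drops below 20X, coverage uniformity is expected
#' above 95%, PSV base observations need Phred >= 20, and a coverage score
#' below 0.5 copy-equivalents (the midpoint between zero and one SMN1 copy)
#' is called a homozygous exon 7 deletion.
#'
#' @param min_control_depth Minimum mean fold-coverage over control genes.
#' @param min_uniformity Minimum fraction of targeted control bases covered at
#'   >= 0.2 x the sample's mean control depth.
#' @param min_base_quality Minimum Phred base quality for a read base to count
#'   as PSV evidence.
#' @param deletion_score_cutoff Coverage score (SMN1 copy-equivalents) below
#'   which a sample is screen positive.
#' @param min_psv_total_depth Minimum mean total read depth across PSV sites;
#'   guards the score against sheer assay dropout.
#'
#' @return A named list of class `sma_thresholds`.
#' @export
#' @examples
#' calling_thresholds()
calling_thresholds <- function(min_control_depth = 20,
                               min_uniformity = 0.95,
                               min_base_quality = 20,
                               deletion_score_cutoff = 0.5,
                               min_psv_total_depth = 20) {
  thr <- list(
    min_control_depth = as.numeric(min_control_depth),
    min_uniformity = as.numeric(min_uniformity),
    min_base_quality = as.numeric(min_base_quality),
    deletion_score_cutoff = as.numeric(deletion_score_cutoff),
    min_psv_total_depth = as.numeric(min_psv_total_depth)
  )
  structure(thr, class = "sma_thresholds")
}

#' Construct an SMN locus configuration
#'
#' The locus configuration is the genomic model of the assay: the
#' paralog-specific variant (PSV) sites that discriminate SMN1 from SMN2
#' reads, the exon 7 target interval that contains them, the enclosing SMN
#' capture region in SMN1-anchored hg38 coordinates, the diploid control-gene
#' intervals used for depth normalisation, and the calling thresholds.
#' All coordinates are 1-based inclusive (SAM/VCF convention).
#'
#' @param psv_sites Data frame with columns `chrom`, `pos`, `smn1_base`,
#'   `smn2_base`; one row per paralog-discriminating position.
#' @param exon7 One-row data frame (`chrom`, `start`, `end`, `label`) for the
#'   SMN1 exon 7 target interval; must contain every PSV position.
#' @param smn_region One-row data frame for the SMN capture region enclosing
#'   `exon7`.
#' @param control_genes Data frame of control-gene intervals (>= 1 row),
#'   disjoint from `smn_region`.
#' @param thresholds A [calling_thresholds()] object (or named list of
#'   overrides; omitted values take the defaults).
#'
#' @return An object of class `smn_locus_config`.
#' @seealso [load_locus_config()], [validate_config()]
#' @export
locus_config <- function(psv_sites, exon7, smn_region, control_genes,
                         thresholds = calling_thresholds()) {
  if (!inherits(thresholds, "sma_thresholds")) {
    thresholds <- do.call(calling_thresholds, as.list(thresholds))
  }
  cfg <- structure(
    list(
      psv_sites = as_interval_tbl(psv_sites,
                                  c("chrom", "pos", "smn1_base", "smn2_base")),
      exon7 = as_interval_tbl(exon7, c("chrom", "start", "end", "label")),
      smn_region = as_interval_tbl(smn_region, c("chrom", "start", "end", "label")),
      control_genes = as_interval_tbl(control_genes,
                                      c("chrom", "start", "end", "label")),
      thresholds = thresholds
    ),
    class = "smn_locus_config"
  )
  violations <- validate_config(cfg)
  if (length(violations) > 0) {
    abort(c("invalid locus configuration", setNames(violations, rep("x", length(violations)))))
  }
  cfg
}

as_interval_tbl <- function(x, cols) {
  x <- as_tibble(x)
  missing_cols <- setdiff(cols, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("missing field(s): ", paste(missing_cols, collapse = ", ")))
  }
  x[cols]
}

#' Validate an SMN locus configuration
#'
#' Checks every structural invariant of the locus model and returns the
#' violations as data rather than raising: each element names the offending
#' field and the rule it breaks. [locus_config()] and [load_locus_config()]
#' call this internally and refuse to return an invalid configuration, so a
#' loaded config always validates to an empty vector.
#'
#' @param cfg An `smn_locus_config` (or a list shaped like one).
#' @return Character vector of violation descriptions; empty if valid.
#' @export
#' @examples
#' validate_config(default_locus_config())
validate_config <- function(cfg) {
  v <- character()
  say <- function(...) v[[length(v) + 1L]] <<- paste0(...)

  ps <- cfg$psv_sites
  if (is.null(ps) || nrow(ps) < 1) say("psv_sites: at least one PSV site required")
  if (!is.null(ps) && nrow(ps) >= 1) {
    bases <- c("A", "C", "G", "T")
    if (anyDuplicated(ps$pos)) {
      say("psv_sites: duplicate PSV position ",
          paste(unique(ps$pos[duplicated(ps$pos)]), collapse = ", "))
    }
    for (i in seq_len(nrow(ps))) {
      if (!ps$smn1_base[i] %in% bases || !ps$smn2_base[i] %in% bases) {
        say("psv_sites[", i, "]: bases must be one of A, C, G, T")
      } else if (ps$smn1_base[i] == ps$smn2_base[i]) {
        say("psv_sites[", i, "] (pos ", ps$pos[i],
            "): smn1_base equals smn2_base")
      }
      if (ps$pos[i] < 1) say("psv_sites[", i, "]: pos must be >= 1")
    }
  }

  chk_interval <- function(int, field) {
    ok <- TRUE
    for (i in seq_len(nrow(int))) {
      if (int$start[i] < 1) { say(field, ": start must be >= 1"); ok <- FALSE }
      if (int$end[i] < int$start[i]) { say(field, ": end < start"); ok <- FALSE }
    }
    ok
  }
  e7_ok <- !is.null(cfg$exon7) && nrow(cfg$exon7) == 1 && chk_interval(cfg$exon7, "exon7")
  sr_ok <- !is.null(cfg$smn_region) && nrow(cfg$smn_region) == 1 &&
    chk_interval(cfg$smn_region, "smn_region")

  if (is.null(cfg$control_genes) || nrow(cfg$control_genes) < 1) {
    say("control_genes: at least one control interval required")
  } else {
    chk_interval(cfg$control_genes, "control_genes")
  }

  if (e7_ok && !is.null(ps) && nrow(ps) >= 1) {
    outside <- ps$chrom != cfg$exon7$chrom |
      ps$pos < cfg$exon7$start | ps$pos > cfg$exon7$end
    if (any(outside)) {
      say("psv_sites: position(s) ", paste(ps$pos[outside], collapse = ", "),
          " outside exon7")
    }
  }
  if (e7_ok && sr_ok) {
    if (cfg$exon7$chrom != cfg$smn_region$chrom ||
        cfg$exon7$start < cfg$smn_region$start ||
        cfg$exon7$end > cfg$smn_region$end) {
      say("exon7 outside smn_region")
    }
  }
  if (sr_ok && !is.null(cfg$control_genes) && nrow(cfg$control_genes) >= 1) {
    cg <- cfg$control_genes
    hit <- cg$chrom == cfg$smn_region$chrom &
      cg$start <= cfg$smn_region$end & cg$end >= cfg$smn_region$start
    if (any(hit)) {
      say("control_genes: interval(s) ", paste(cg$label[hit], collapse = ", "),
          " overlap smn_region")
    }
  }

  thr <- cfg$thresholds
  if (!is.null(thr)) {
    num <- vapply(thr, function(x) is.numeric(x) && length(x) == 1, TRUE)
    if (!all(num)) {
      say("thresholds: all values must be single numbers")
    } else {
      if (any(unlist(thr) < 0)) say("thresholds: all values must be nonnegative")
      if (thr$min_uniformity < 0 || thr$min_uniformity > 1) {
        say("thresholds: min_uniformity must be in [0, 1]")
      }
      if (thr$deletion_score_cutoff <= 0 || thr$deletion_score_cutoff > 1) {
        say("thresholds: deletion_score_cutoff must be in (0, 1]")
      }
    }
  }
  v
}

#' Load an SMN locus configuration from a YAML file
#'
#' Reads the human-editable locus description (sections `psv_sites`, `exon7`,
#' `smn_region`, `control_genes`, `thresholds`) and returns a fully validated
#' configuration. Omitted thresholds take the [calling_thresholds()] defaults.
#' See the packaged default at
#' `system.file("extdata", "default_config.yaml", package = "smascreen")`
#' for the schema.
#'
#' @param path Path to a YAML configuration file.
#' @return An `smn_locus_config`.
#' @export
#' @examples
#' cfg <- load_locus_config(system.file("extdata", "default_config.yaml",
#'                                      package = "smascreen"))
#' cfg$psv_sites
load_locus_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  raw <- tryCatch(yaml::read_yaml(path), error = function(e) {
    abort(paste0("config parse failure in '", path, "': ", conditionMessage(e)))
  })
  need <- c("psv_sites", "exon7", "smn_region", "control_genes")
  missing_sec <- setdiff(need, names(raw))
  if (length(missing_sec) > 0) {
    abort(paste0("config missing section(s): ", paste(missing_sec, collapse = ", ")))
  }
  rows_to_tbl <- function(x) dplyr::bind_rows(lapply(x, as_tibble))
  thr <- do.call(calling_thresholds, raw$thresholds %||% list())
  locus_config(
    psv_sites = rows_to_tbl(raw$psv_sites),
    exon7 = as_tibble(raw$exon7),
    smn_region = as_tibble(raw$smn_region),
    control_genes = rows_to_tbl(raw$control_genes),
    thresholds = thr
  )
}

#' Write an SMN locus configuration to YAML
#'
#' Inverse of [load_locus_config()]: a written config re-loads to an equal
#' object.
#'
#' @param cfg An `smn_locus_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_locus_config <- function(cfg, path) {
  row_list <- function(tbl) lapply(seq_len(nrow(tbl)), function(i) as.list(tbl[i, ]))
  out <- list(
    psv_sites = row_list(cfg$psv_sites),
    exon7 = as.list(cfg$exon7),
    smn_region = as.list(cfg$smn_region),
    control_genes = row_list(cfg$control_genes),
    thresholds = unclass(cfg$thresholds)
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

#' The packaged default locus configuration
#'
#' Three PSV sites at the published SMN1 hg38 positions chr5:70247724,
#' chr5:70247773 and chr5:70247921. The exon 7 site chr5:70247773 carries the
#' canonical c.840C>T paralog difference (SMN1 = C, SMN2 = T); the base pairs
#' at the other two positions are editable placeholders, as are the three
#' synthetic control-gene intervals -- edit the YAML to match a real panel
#' design.
#'
#' @return An `smn_locus_config`.
#' @export
default_locus_config <- function() {
  load_locus_config(system.file("extdata", "default_config.yaml",
                                package = "smascreen", mustWork = TRUE))
}

#' @export
print.smn_locus_config <- function(x, ...) {
  cat("<smn_locus_config>\n")
  cat("  PSV sites:", nrow(x$psv_sites), "at",
      paste0(x$psv_sites$chrom[1], ":",
             paste(x$psv_sites$pos, collapse = ", ")), "\n")
  cat("  exon7:     ", fmt_interval(x$exon7), "\n", sep = "")
  cat("  smn_region:", fmt_interval(x$smn_region), "\n")
  cat("  control genes:", nrow(x$control_genes),
      paste0("(", paste(x$control_genes$label, collapse = ", "), ")"), "\n")
  cat("  thresholds: control depth >=", x$thresholds$min_control_depth,
      "X, uniformity >=", x$thresholds$min_uniformity,
      ", base qual >=", x$thresholds$min_base_quality,
      ", deletion cutoff <", x$thresholds$deletion_score_cutoff, "\n")
  invisible(x)
}

fmt_interval <- function(int) {
  paste0(int$chrom, ":", int$start, "-", int$end, " (", int$label, ")")
}

#' @export
print.sma_thresholds <- function(x, ...) {
  cat("<sma_thresholds>\n")
  for (nm in names(x)) cat(" ", nm, "=", x[[nm]], "\n")
  invisible(x)
}
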