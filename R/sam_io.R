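#' Write aligned reads to a SAM file
#'
#' Emits a valid SAM file with a header declaring every contig the reads (and,
#' if supplied, the locus configuration) touch. Mate fields and template
#' length are written for paired reads so a round trip through [read_sam()]
#' preserves position, sequence, base qualities and pairing flags.
#'
#' @param reads Read tibble as produced by [simulate_sample()] or
#'   [read_sam()].
#' @param path Output path.
#' @param cfg Optional [locus_config()]; when given, its intervals are added
#'   to the header contigs.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, path, cfg = NULL) {
  contig_end <- c(
    if (nrow(reads) > 0) {
      tapply(reads$pos + nchar(reads$seq), reads$chrom, max)
    },
    if (!is.null(cfg)) {
      ivs <- dplyr::bind_rows(cfg$smn_region, cfg$control_genes, cfg$exon7)
      tapply(ivs$end, ivs$chrom, max)
    }
  )
  contig_end <- tapply(as.numeric(contig_end), names(contig_end), max)
  header <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", names(contig_end),
            as.integer(contig_end + 10000)),
    "@PG\tID:smascreen\tPN:smascreen"
  )
  if (nrow(reads) == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  rnext <- dplyr::case_when(
    is.na(reads$mate_chrom) ~ "*",
    reads$mate_chrom == reads$chrom ~ "=",
    TRUE ~ reads$mate_chrom
  )
  body <- paste(reads$read_id, reads$flag, reads$chrom, reads$pos, reads$mapq,
                reads$cigar, rnext,
                ifelse(is.na(reads$mate_pos), 0L, reads$mate_pos),
                ifelse(is.na(reads$tlen), 0L, reads$tlen),
                reads$seq, reads$qual, sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read aligned reads from a SAM file
#'
#' Parses via Rsamtools (SAM is converted to BAM with htslib, then scanned),
#' so any spec-conformant SAM is accepted and malformed records raise a parse
#' error. Unmapped records are dropped: the screen only consumes mapped
#' evidence.
#'
#' @param path Path to a SAM file.
#' @return A tibble with columns `read_id`, `flag`, `chrom`, `pos`, `mapq`,
#'   `cigar`, `seq`, `qual`, `mate_chrom`, `mate_pos`, `tlen`.
#' @export
read_sam <- function(path) {
  if (!file.exists(path)) abort(paste0("SAM file not found: ", path))
  bam <- tryCatch(
    Rsamtools::asBam(path, tempfile(), indexDestination = FALSE,
                     overwrite = TRUE),
    error = function(e) {
      abort(paste0("malformed SAM '", path, "': ", conditionMessage(e)))
    }
  )
  on.exit(unlink(bam), add = TRUE)
  what <- c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual",
            "mrnm", "mpos", "isize")
  x <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(what = what))[[1]]
  # htslib can skip a malformed trailing record with only a stderr warning;
  # cross-check converted record count against the file's body lines.
  expected <- count_lines(path) - count_header_lines(path)
  if (length(x$flag) != expected) {
    abort(paste0("malformed SAM '", path, "': ", expected,
                 " alignment line(s) but ", length(x$flag),
                 " parsed record(s)"))
  }
  mapped <- bitwAnd(x$flag, 4L) == 0L & !is.na(x$pos)
  tibble(
    read_id = x$qname[mapped],
    flag = as.integer(x$flag[mapped]),
    chrom = as.character(x$rname[mapped]),
    pos = as.integer(x$pos[mapped]),
    mapq = as.integer(x$mapq[mapped]),
    cigar = as.character(x$cigar[mapped]),
    seq = as.character(x$seq)[mapped],
    qual = as.character(x$qual)[mapped],
    mate_chrom = as.character(x$mrnm[mapped]),
    mate_pos = as.integer(x$mpos[mapped]),
    tlen = as.integer(x$isize[mapped])
  )
}

count_lines <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  n <- 0L
  last <- as.raw(10L)
  repeat {
    chunk <- readBin(con, "raw", n = 1048576L)
    if (length(chunk) == 0) break
    n <- n + sum(chunk == as.raw(10L))
    last <- chunk[length(chunk)]
  }
  if (last != as.raw(10L)) n <- n + 1L # unterminated final line
  n
}

count_header_lines <- function(path) {
  con <- file(path, "r")
  on.exit(close(con))
  n <- 0L
  repeat {
    l <- readLines(con, n = 1L)
    if (length(l) == 0 || !startsWith(l, "@")) break
    n <- n + 1L
  }
  n
}

# Phred scores for one base per read: character at position `off` of each
# qual string (offset-33 encoding).
QUAL_CHARS <- strsplit(rawToChar(as.raw(33:126)), "")[[1]]

qual_char_to_phred <- function(ch) {
  match(ch, QUAL_CHARS) - 1L
}
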