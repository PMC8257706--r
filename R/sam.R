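#' Alignment tables
#'
#' Aligned reads are held in a `data.table` with one row per SAM record:
#' `read_id`, `chrom`, `pos` (1-based leftmost mapped position), `cigar`,
#' `seq`, `strand` (`+`/`-`), `mate_pos` (1-based or `NA`), `is_first`
#' (first mate in the pair) and `flag` (the SAM flag). Optional columns
#' carry auxiliary tags: `assignment` (`ga:Z:` on output) and the
#' simulator's truth tags `true_allele` (`ta:Z:`) and `true_gene`
#' (`tg:Z:`). The SAM header is kept in `attr(x, "header")`.
#'
#' Only mapped records are represented; the pipeline consumes uniquely
#' aligned reads.
#'
#' @name alignment-table
NULL

.aln_cols <- c("read_id", "chrom", "pos", "cigar", "seq", "strand",
               "mate_pos", "is_first", "flag")

#' Read alignments from a SAM text file
#'
#' Parses the plain-text SAM layout; unmapped records (flag 0x4) are
#' dropped. Strand and mate ordering are derived from the flag; `PNEXT` 0
#' becomes `NA`. Recognised auxiliary tags `ga:Z:` (allele assignment),
#' `ta:Z:` and `tg:Z:` (simulator truth) populate the optional columns.
#'
#' @param path SAM file.
#' @return an alignment `data.table` (see [alignment-table]) with the header
#'   lines in `attr(x, "header")`.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (!length(body)) {
    out <- data.table::data.table(read_id = character(0), chrom = character(0),
                                  pos = integer(0), cigar = character(0),
                                  seq = character(0), strand = character(0),
                                  mate_pos = integer(0), is_first = logical(0),
                                  flag = integer(0))
    data.table::setattr(out, "header", hdr)
    return(out)
  }
  f <- data.table::tstrsplit(body, "\t", fixed = TRUE, keep = 1:11)
  flag <- as.integer(f[[2]])
  out <- data.table::data.table(
    read_id = f[[1]],
    chrom = f[[3]],
    pos = as.integer(f[[4]]),
    cigar = f[[6]],
    seq = f[[10]],
    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    mate_pos = ifelse(as.integer(f[[8]]) == 0L, NA_integer_, as.integer(f[[8]])),
    is_first = bitwAnd(flag, 64L) > 0L | bitwAnd(flag, 1L) == 0L,
    flag = flag)
  tagmap <- c(assignment = "ga", true_allele = "ta", true_gene = "tg")
  for (col in names(tagmap)) {
    patt <- paste0("\t", tagmap[[col]], ":Z:([^\t]+)")
    hit <- regmatches(body, regexec(patt, body))
    val <- vapply(hit, function(h) if (length(h) == 2) h[2] else NA_character_,
                  character(1))
    if (any(!is.na(val))) out[[col]] <- val
  }
  out <- out[bitwAnd(out$flag, 4L) == 0L]
  data.table::setattr(out, "header", hdr)
  out[]
}

#' Write alignments to a SAM text file
#'
#' @param alignments an alignment `data.table`; optional columns
#'   `assignment`, `true_allele`, `true_gene` are emitted as `ga:Z:`,
#'   `ta:Z:`, `tg:Z:` tags.
#' @param path output path.
#' @param header header lines; defaults to `attr(alignments, "header")`, or
#'   a minimal `@HD` line when absent.
#' @export
write_sam <- function(alignments, path, header = NULL) {
  if (is.null(header)) header <- attr(alignments, "header")
  if (is.null(header) || !length(header)) header <- "@HD\tVN:1.6\tSO:coordinate"
  a <- alignments
  mate <- ifelse(is.na(a$mate_pos), 0L, a$mate_pos)
  rnext <- ifelse(is.na(a$mate_pos), "*", "=")
  fields <- paste(a$read_id, a$flag, a$chrom, a$pos, 255L, a$cigar,
                  rnext, mate, 0L, a$seq, "*", sep = "\t")
  for (col in c("assignment", "true_allele", "true_gene")) {
    if (!is.null(a[[col]])) {
      tg <- c(assignment = "ga", true_allele = "ta", true_gene = "tg")[[col]]
      has <- !is.na(a[[col]])
      fields[has] <- paste0(fields[has], "\t", tg, ":Z:", a[[col]][has])
    }
  }
  writeLines(c(header, fields), path)
  invisible(path)
}

# SAM flag for a simulated paired, properly mapped record.
.pair_flag <- function(is_first, reverse) {
  1L + 2L + ifelse(reverse, 16L, 0L) + ifelse(reverse, 0L, 32L) +
    ifelse(is_first, 64L, 128L)
}
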