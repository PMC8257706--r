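#' Parse a CIGAR string into operations
#'
#' Supports the operations the pipeline consumes: `M` (aligned), `N`
#' (skipped intron), `D` (deletion, advances reference), `I` (insertion,
#' advances read) and `S` (soft clip, advances read).
#'
#' @param cigar a single CIGAR string.
#' @return a list with integer vector `len` and character vector `op`.
#' @keywords internal
parse_cigar <- function(cigar) {
  toks <- regmatches(cigar, gregexpr("\\d+[MNDIS]", cigar))[[1]]
  if (!length(toks) || sum(nchar(toks)) != nchar(cigar))
    stop("unparsable CIGAR: ", cigar)
  list(len = as.integer(sub("[MNDIS]$", "", toks)),
       op = sub("^\\d+", "", toks))
}

#' Remove PCR duplicates from sorted alignments
#'
#' Among records sharing the conventional duplicate key
#' `(chrom, pos, strand, mate_pos)` exactly the first encountered is kept.
#' Kept/removed counts are attached as attributes `n_kept` / `n_removed`.
#'
#' @param alignments an alignment `data.table` sorted by `(chrom, pos)`.
#' @return the deduplicated table.
#' @export
dedupe_alignments <- function(alignments) {
  a <- alignments
  if (nrow(a) > 1) {
    grouped <- !is.unsorted(match(a$chrom, unique(a$chrom)))
    by_pos <- all(tapply(a$pos, a$chrom, function(p) !is.unsorted(p)))
    if (!grouped || !by_pos)
      stop("alignments are not sorted by (chrom, pos); sort them first")
  }
  dup <- duplicated(a, by = c("chrom", "pos", "strand", "mate_pos"))
  out <- a[!dup]
  data.table::setattr(out, "header", attr(alignments, "header"))
  data.table::setattr(out, "n_kept", nrow(out))
  data.table::setattr(out, "n_removed", sum(dup))
  out
}

.assign_category <- function(n_seen, n_g1, n_g2) {
  if (n_g1 >= 1L && n_g2 >= 1L) "CONFLICTING"
  else if (n_g1 >= 1L) "GENOME1"
  else if (n_g2 >= 1L) "GENOME2"
  else "UNASSIGNED"
}

# Per-read SNP base tallies: walks the CIGAR so that each reference SNP
# position under an M segment maps to its read base. Returns
# c(seen, g1, g2). SNPs under N/D gaps are never counted.
.read_tally <- function(chrom, pos, cigar, seq, sidx) {
  s <- sidx[[chrom]]
  if (is.null(s)) return(c(0L, 0L, 0L))
  cg <- parse_cigar(cigar)
  if (sum(cg$len[cg$op %in% c("M", "S", "I")]) != nchar(seq))
    stop("CIGAR/sequence length mismatch: ", cigar, " vs ", nchar(seq), " bases")
  refp <- pos
  readp <- 1L
  seen <- 0L; g1 <- 0L; g2 <- 0L
  for (k in seq_along(cg$op)) {
    len <- cg$len[k]
    switch(cg$op[k],
      M = {
        lo <- findInterval(refp - 1L, s$pos) + 1L
        hi <- findInterval(refp + len - 1L, s$pos)
        if (hi >= lo) {
          for (j in lo:hi) {
            base <- substr(seq, readp + (s$pos[j] - refp), readp + (s$pos[j] - refp))
            seen <- seen + 1L
            if (base == s$ref[j]) g1 <- g1 + 1L
            else if (base == s$alt[j]) g2 <- g2 + 1L
          }
        }
        refp <- refp + len
        readp <- readp + len
      },
      N = { refp <- refp + len },
      D = { refp <- refp + len },
      I = { readp <- readp + len },
      S = { readp <- readp + len })
  }
  c(seen, g1, g2)
}

#' Assign a single read to a parental genome
#'
#' Walks the read's CIGAR and compares the read base at every covered SNP
#' position with the two strain alleles. Bases matching the reference-strain
#' allele count towards genome 1 (paternal B6 role), bases matching the
#' alternate-strain allele towards genome 2 (maternal JF1 role); bases
#' matching neither (sequencing errors) are uninformative. A read is
#' `GENOME1`/`GENOME2` when it has informative bases for exactly one genome,
#' `CONFLICTING` when both genomes are supported, and `UNASSIGNED` when it
#' covers no SNP or no base matched either allele.
#'
#' @param read a one-row alignment `data.table` (or list) with `chrom`,
#'   `pos`, `cigar`, `seq`.
#' @param snps a SNP `data.table` or a prebuilt index from `snp_index()`.
#' @return a list with `category`, `n_snps_seen`, `n_g1_bases`,
#'   `n_g2_bases`.
#' @export
assign_read <- function(read, snps) {
  sidx <- if (is.data.frame(snps)) snp_index(snps) else snps
  t <- .read_tally(read$chrom[[1]], read$pos[[1]], read$cigar[[1]],
                   read$seq[[1]], sidx)
  list(category = .assign_category(t[1], t[2], t[3]),
       n_snps_seen = t[1], n_g1_bases = t[2], n_g2_bases = t[3])
}

#' Assign a read pair (fragment) to a parental genome
#'
#' Combines the per-mate SNP tallies and applies the same categorisation
#' rule: agreeing mates give that genome, a single informative mate decides,
#' opposing mates are `CONFLICTING`.
#'
#' @param r1 first mate (one-row alignment table or list).
#' @param r2 second mate or `NULL` for single-end fragments.
#' @param snps SNP table or `snp_index()`.
#' @return a list as in [assign_read()].
#' @export
assign_fragment <- function(r1, r2, snps) {
  sidx <- if (is.data.frame(snps)) snp_index(snps) else snps
  t <- .read_tally(r1$chrom[[1]], r1$pos[[1]], r1$cigar[[1]], r1$seq[[1]], sidx)
  if (!is.null(r2)) {
    if (r1$read_id[[1]] != r2$read_id[[1]])
      stop("mates have different read ids: ", r1$read_id[[1]], " vs ",
           r2$read_id[[1]])
    t <- t + .read_tally(r2$chrom[[1]], r2$pos[[1]], r2$cigar[[1]],
                         r2$seq[[1]], sidx)
  }
  list(category = .assign_category(t[1], t[2], t[3]),
       n_snps_seen = t[1], n_g1_bases = t[2], n_g2_bases = t[3])
}

#' Split alignments between the two parental genomes
#'
#' Tallies every record, combines mates by `read_id`, and partitions the
#' fragments into genome-1 and genome-2 sets. The partition is exhaustive
#' and exclusive: every input fragment is exactly one of genome1, genome2,
#' unassigned or conflicting.
#'
#' @param alignments a deduplicated alignment `data.table`.
#' @param snps SNP table or `snp_index()`.
#' @return a list with `genome1` and `genome2` (alignment tables, an
#'   `assignment` column added), `assignments` (one row per fragment:
#'   `read_id`, `category`, tallies), and `summary` (named counts `g1`,
#'   `g2`, `unassigned`, `conflicting`, `total` in fragments).
#' @export
split_alignments <- function(alignments, snps) {
  sidx <- if (is.data.frame(snps)) snp_index(snps) else snps
  a <- alignments
  n <- nrow(a)
  seen <- integer(n); g1 <- integer(n); g2 <- integer(n)
  if (n) {
    for (i in seq_len(n)) {
      t <- .read_tally(a$chrom[i], a$pos[i], a$cigar[i], a$seq[i], sidx)
      seen[i] <- t[1]; g1[i] <- t[2]; g2[i] <- t[3]
    }
  }
  tall <- data.table::data.table(read_id = a$read_id, seen = seen,
                                 g1 = g1, g2 = g2)
  frag <- tall[, list(n_snps_seen = sum(seen), n_g1_bases = sum(g1),
                      n_g2_bases = sum(g2)), by = "read_id"]
  frag$category <- mapply(.assign_category, frag$n_snps_seen,
                          frag$n_g1_bases, frag$n_g2_bases)
  summary <- c(
    g1 = sum(frag$category == "GENOME1"),
    g2 = sum(frag$category == "GENOME2"),
    unassigned = sum(frag$category == "UNASSIGNED"),
    conflicting = sum(frag$category == "CONFLICTING"),
    total = nrow(frag))
  cat_of <- frag$category[match(a$read_id, frag$read_id)]
  out1 <- a[cat_of == "GENOME1"]
  out2 <- a[cat_of == "GENOME2"]
  if (nrow(out1)) out1$assignment <- "GENOME1"
  if (nrow(out2)) out2$assignment <- "GENOME2"
  data.table::setattr(out1, "header", attr(alignments, "header"))
  data.table::setattr(out2, "header", attr(alignments, "header"))
  list(genome1 = out1, genome2 = out2, assignments = frag, summary = summary)
}
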