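#' Read a reference genome from FASTA
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] that upper-cases the
#' sequences and keeps only the first word of each FASTA header as the
#' chromosome name.
#'
#' @param path FASTA file.
#' @return a named [Biostrings::DNAStringSet].
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  Biostrings::DNAStringSet(toupper(g))
}

#' Write a genome to FASTA (60-column lines)
#'
#' @param genome a named [Biostrings::DNAStringSet].
#' @param path output path.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 60)
  invisible(path)
}

#' N-mask a genome at SNP positions
#'
#' Replaces the base at every SNP position with `N` so that alignment to the
#' masked reference is unbiased between the two parental genomes. If the
#' genome base at a SNP differs from the recorded reference allele the
#' position is still masked, but the mismatch is counted and reported via
#' `attr(x, "n_ref_mismatch")` and a warning.
#'
#' @param genome a named [Biostrings::DNAStringSet].
#' @param snps a SNP `data.table` (see [snp-table]); every `chrom` must be a
#'   sequence name of `genome` and every `pos` within its length.
#' @return the masked `DNAStringSet`, same names and lengths, with attribute
#'   `n_ref_mismatch`.
#' @export
mask_genome <- function(genome, snps) {
  stopifnot(methods::is(genome, "DNAStringSet"))
  out <- genome
  n_mismatch <- 0L
  if (nrow(snps)) {
    missing <- setdiff(unique(snps$chrom), names(genome))
    if (length(missing))
      stop("SNP chromosome(s) absent from genome: ",
           paste(missing, collapse = ", "))
    for (chr in unique(snps$chrom)) {
      s <- snps[snps$chrom == chr]
      len <- length(genome[[chr]])
      bad <- s$pos > len
      if (any(bad))
        stop("SNP beyond end of ", chr, " (length ", len, "): pos ",
             paste(utils::head(s$pos[bad], 3), collapse = ", "))
      observed <- as.character(Biostrings::extractAt(
        genome[[chr]], IRanges::IRanges(s$pos, width = 1)))
      n_mismatch <- n_mismatch + sum(observed != s$ref)
      out[[chr]] <- Biostrings::replaceLetterAt(
        genome[[chr]], s$pos, rep.int("N", nrow(s)))
    }
    if (n_mismatch > 0)
      warning(n_mismatch, " SNP position(s) where the genome base does not ",
              "match the recorded reference allele (masked anyway)")
  }
  attr(out, "n_ref_mismatch") <- n_mismatch
  out
}
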