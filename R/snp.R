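#' SNP tables
#'
#' A SNP table is a `data.table` with columns `chrom` (character), `pos`
#' (integer, 1-based), `ref` (single base, genome 1 / reference strain,
#' paternal B6 role) and `alt` (single base, genome 2 / alternate strain,
#' maternal JF1 role). Rows are unique on `(chrom, pos)` and sorted.
#'
#' @name snp-table
NULL

.valid_bases <- c("A", "C", "G", "T")

#' Build a validated SNP table
#'
#' @param chrom,pos,ref,alt parallel vectors of chromosome, 1-based position
#'   and the two strain alleles.
#' @param swap_strains if `TRUE`, swap ref/alt so that the roles of the two
#'   genomes are exchanged (reciprocal cross orientation).
#' @return a sorted SNP `data.table` (see [snp-table]).
#' @export
snp_table <- function(chrom, pos, ref, alt, swap_strains = FALSE) {
  dt <- data.table::data.table(chrom = as.character(chrom),
                               pos = as.integer(pos),
                               ref = toupper(as.character(ref)),
                               alt = toupper(as.character(alt)))
  if (nrow(dt)) {
    if (any(dt$pos < 1L)) stop("SNP positions must be >= 1")
    if (!all(dt$ref %in% .valid_bases) || !all(dt$alt %in% .valid_bases))
      stop("SNP alleles must be single bases in {A,C,G,T}")
    if (any(dt$ref == dt$alt)) stop("ref and alt alleles must differ")
    if (anyDuplicated(dt, by = c("chrom", "pos")))
      stop("duplicate (chrom, pos) entries in SNP set")
  }
  if (swap_strains) data.table::setnames(dt, c("ref", "alt"), c("alt", "ref"))
  data.table::setkeyv(dt, c("chrom", "pos"))
  dt[]
}

#' Read a strain SNP table from VCF or TSV
#'
#' Accepts a VCF 4.x file (only CHROM/POS/REF/ALT are used) or a three-column
#' TSV dialect `chrom<TAB>pos<TAB>ref>alt`. Only biallelic single-base
#' substitutions are retained: indels (REF or ALT longer than one base) and
#' multi-allelic records (comma in ALT) are dropped, and the number dropped
#' is reported via `attr(x, "n_dropped")` and a message.
#'
#' @param path path to the VCF or TSV file.
#' @param swap_strains see [snp_table()].
#' @return a sorted SNP `data.table` with attribute `n_dropped`.
#' @export
read_snp_table <- function(path, swap_strains = FALSE) {
  if (!file.exists(path)) stop("SNP file not found: ", path)
  lines <- readLines(path)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  is_vcf <- any(startsWith(lines, "##fileformat=VCF")) ||
    (length(body) && length(strsplit(lines[body[1]], "\t", fixed = TRUE)[[1]]) >= 8)
  chrom <- character(0); pos <- integer(0); ref <- character(0); alt <- character(0)
  n_dropped <- 0L
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (is_vcf) {
      if (length(f) < 5)
        stop("malformed VCF line ", i, ": fewer than 5 fields")
      p <- suppressWarnings(as.integer(f[2]))
      if (is.na(p)) stop("malformed VCF line ", i, ": non-integer POS")
      if (p < 1L) stop("malformed VCF line ", i, ": POS must be >= 1")
      r <- toupper(f[4]); a <- toupper(f[5])
      if (nchar(r) != 1L || grepl(",", a, fixed = TRUE) || nchar(a) != 1L ||
          !(r %in% .valid_bases) || !(a %in% .valid_bases) || r == a) {
        n_dropped <- n_dropped + 1L
        next
      }
      chrom <- c(chrom, f[1]); pos <- c(pos, p); ref <- c(ref, r); alt <- c(alt, a)
    } else {
      if (length(f) != 3)
        stop("malformed TSV line ", i, ": expected 3 fields (chrom, pos, ref>alt)")
      p <- suppressWarnings(as.integer(f[2]))
      if (is.na(p)) stop("malformed TSV line ", i, ": non-integer pos")
      if (p < 1L) stop("malformed TSV line ", i, ": pos must be >= 1")
      ra <- strsplit(toupper(f[3]), ">", fixed = TRUE)[[1]]
      if (length(ra) != 2)
        stop("malformed TSV line ", i, ": allele field must be 'ref>alt'")
      if (nchar(ra[1]) != 1L || nchar(ra[2]) != 1L ||
          !all(ra %in% .valid_bases) || ra[1] == ra[2]) {
        n_dropped <- n_dropped + 1L
        next
      }
      chrom <- c(chrom, f[1]); pos <- c(pos, p)
      ref <- c(ref, ra[1]); alt <- c(alt, ra[2])
    }
  }
  out <- snp_table(chrom, pos, ref, alt, swap_strains = swap_strains)
  if (n_dropped > 0)
    message(n_dropped, " non-SNP or multi-allelic record(s) dropped from ", path)
  data.table::setattr(out, "n_dropped", n_dropped)
  out
}

#' Write a SNP table as TSV (`chrom pos ref>alt`)
#'
#' @param snps a SNP `data.table`.
#' @param path output path.
#' @export
write_snp_table <- function(snps, path) {
  out <- data.table::data.table(chrom = snps$chrom, pos = snps$pos,
                                allele = paste0(snps$ref, ">", snps$alt))
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Intersect two strain SNP sets
#'
#' Keeps SNPs whose `(chrom, pos)` occurs in both sets with identical
#' ref/alt alleles. Positions present in both but with discordant alleles are
#' dropped; the count is reported via `attr(x, "n_discordant")`.
#'
#' @param a,b SNP `data.table`s.
#' @return the concordant intersection, sorted, with attribute
#'   `n_discordant`.
#' @export
intersect_snp_sets <- function(a, b) {
  m <- merge(a, b, by = c("chrom", "pos"), suffixes = c("", ".b"))
  keep <- m$ref == m$ref.b & m$alt == m$alt.b
  out <- snp_table(m$chrom[keep], m$pos[keep], m$ref[keep], m$alt[keep])
  n_disc <- sum(!keep)
  if (n_disc > 0)
    message(n_disc, " shared position(s) with discordant alleles dropped")
  data.table::setattr(out, "n_discordant", n_disc)
  out
}

# Fast per-chromosome lookup structure used by the read-assignment walk.
snp_index <- function(snps) {
  idx <- split(snps, by = "chrom")
  lapply(idx, function(d) list(pos = d$pos, ref = d$ref, alt = d$alt))
}
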