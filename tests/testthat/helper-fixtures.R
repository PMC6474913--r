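# Programmatic BAM/FASTA fixtures: reads are specified as plain tuples,
# written as SAM text and converted to a sorted, indexed BAM.

make_test_bam <- function(reads, ref, dir = tempfile("fix_"),
                          chrom = "chrT") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "ref.fa")
  writeLines(c(paste0(">", chrom), ref), fasta)
  Rsamtools::indexFa(fasta)
  n <- nrow(reads)
  cigar <- if ("cigar" %in% names(reads)) reads$cigar
           else paste0(nchar(reads$seq), "M")
  baseq <- if ("baseq" %in% names(reads)) reads$baseq else rep(37L, n)
  qual <- vapply(seq_len(n), function(i)
    strrep(rawToChar(as.raw(baseq[i] + 33L)), nchar(reads$seq[i])), "")
  mapq <- if ("mapq" %in% names(reads)) reads$mapq else rep(37L, n)
  flag <- if ("flag" %in% names(reads)) reads$flag else rep(0L, n)
  sam <- file.path(dir, "r.sam")
  writeLines(c("@HD\tVN:1.6",
               sprintf("@SQ\tSN:%s\tLN:%d", chrom, nchar(ref)),
               paste(sprintf("r%03d", seq_len(n)), flag, chrom, reads$pos,
                     mapq, cigar, "*", 0L, 0L, reads$seq, qual, sep = "\t")),
             sam)
  bam <- Rsamtools::asBam(sam, file.path(dir, "r"), overwrite = TRUE,
                          indexDestination = TRUE)
  list(bam = bam, fasta = fasta, chrom = chrom, dir = dir)
}

# relaxed filters so tiny hand-built reads pass length/quality gates
lax_filters <- function(...) {
  filter_settings(min_baseq = 13L, min_mapq = 25L, min_length = 2L, ...)
}
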