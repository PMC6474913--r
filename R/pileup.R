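# Extraction of canonicalised cytosine observations (step 1) and CpG
# dinucleotide piles (step 2) from BAM + FASTA.

#' Read filter settings
#'
#' Canonical high-throughput-sequencing filters: minimum base quality,
#' minimum mapping quality and minimum DNA fragment length, plus optional
#' masked regions (e.g. low-mappability) and excluded individual sites.
#' Defaults follow common ancient-DNA practice and are user-overridable.
#'
#' @param min_baseq minimum Phred base quality (default 13).
#' @param min_mapq minimum mapping quality (default 25).
#' @param min_length minimum fragment (query) length in bp (default 30).
#' @param mask optional masked regions: a `GRanges`, a BED file path, or a
#'   data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @param exclude optional excluded sites: a data.frame with `chrom`, `pos`
#'   (0-based) or a 2-column TSV file path.
#' @return A list of class `filter_settings`.
#' @export
filter_settings <- function(min_baseq = 13L, min_mapq = 25L,
                            min_length = 30L, mask = NULL, exclude = NULL) {
  if (min_baseq < 0 || min_mapq < 0 || min_length < 0)
    stopf("filter thresholds must be >= 0")
  structure(list(min_baseq = as.integer(min_baseq),
                 min_mapq = as.integer(min_mapq),
                 min_length = as.integer(min_length),
                 mask = mask, exclude = exclude),
            class = "filter_settings")
}

# normalise mask input to a GRanges (or NULL)
as_mask_granges <- function(mask) {
  if (is.null(mask)) return(NULL)
  if (methods::is(mask, "GRanges")) return(mask)
  if (is.character(mask)) return(rtracklayer::import(mask, format = "BED"))
  if (is.data.frame(mask))
    return(GenomicRanges::GRanges(mask$chrom,
             IRanges::IRanges(start = mask$start + 1L, end = mask$end)))
  stopf("unsupported mask specification")
}

as_exclude_sites <- function(exclude, chrom) {
  if (is.null(exclude)) return(integer())
  if (is.character(exclude)) {
    exclude <- read.table(exclude, header = FALSE, sep = "\t",
                          col.names = c("chrom", "pos"))
  }
  as.integer(exclude$pos[exclude$chrom == chrom])   # 0-based
}

# masked 1-based positions on `chrom` as an integer set membership test
mask_hits <- function(pos1, mask_gr, chrom) {
  if (is.null(mask_gr)) return(rep(FALSE, length(pos1)))
  gr <- mask_gr[as.character(GenomicRanges::seqnames(mask_gr)) == chrom]
  if (!length(gr)) return(rep(FALSE, length(pos1)))
  IRanges::overlapsAny(IRanges::IRanges(pos1, pos1), IRanges::ranges(gr))
}

open_fasta <- function(fasta) {
  if (!file.exists(fasta)) stopf("FASTA file '%s' not found", fasta)
  if (!file.exists(paste0(fasta, ".fai"))) Rsamtools::indexFa(fasta)
  Rsamtools::FaFile(fasta)
}

ref_chars <- function(fasta, chrom) {
  fa <- open_fasta(fasta)
  idx <- Rsamtools::scanFaIndex(fa)
  hit <- as.character(GenomicRanges::seqnames(idx)) == chrom
  if (!any(hit)) stopf("chromosome '%s' absent from FASTA '%s'", chrom, fasta)
  seq <- Rsamtools::getSeq(fa, GenomicRanges::GRanges(chrom,
           IRanges::IRanges(1, GenomicRanges::width(idx)[hit])))
  toupper(dna_chars(seq[[1]]))
}

# Internal workhorse: one row per aligned base of every filter-passing read
# on `chrom`. Columns: read_id, strand, mapq, Q, qwidth, ref_pos (1-based),
# base, baseq, eps, k (0-based clamped terminal distance), v ("5p"/"3p").
read_base_table <- function(bam, chrom, filters, K_max,
                            region = NULL, with_qname = FALSE) {
  if (!file.exists(bam)) stopf("BAM file '%s' not found", bam)
  bai <- c(paste0(bam, ".bai"), sub("\\.bam$", ".bai", bam))
  if (!any(file.exists(bai)))
    stopf("missing BAM index for '%s' (expected .bai)", bam)
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  if (!chrom %in% names(hdr))
    stopf("chromosome '%s' absent from BAM header of '%s'", chrom, bam)
  which <- if (is.null(region)) {
    GenomicRanges::GRanges(chrom, IRanges::IRanges(1, hdr[[chrom]]))
  } else region
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE,
                                 isDuplicate = FALSE)
  what <- c("pos", "cigar", "seq", "qual", "strand", "mapq")
  if (with_qname) what <- c(what, "qname")
  param <- Rsamtools::ScanBamParam(flag = flag, which = which, what = what)
  res <- Rsamtools::scanBam(bam, param = param)[[1]]
  n <- length(res$pos)
  empty <- data.table::data.table(
    read_id = integer(), strand = character(), mapq = integer(),
    Q = numeric(), qwidth = integer(), ref_pos = integer(),
    base = character(), baseq = integer(), eps = numeric(),
    k = integer(), v = character())
  if (n == 0L) return(empty)
  qwidth <- Biostrings::width(res$seq)
  mapq <- res$mapq
  mapq[is.na(mapq)] <- 0L
  keep <- mapq >= filters$min_mapq & qwidth >= filters$min_length
  if (!any(keep)) return(empty)
  pos <- res$pos[keep]; cigar <- res$cigar[keep]
  seqs <- res$seq[keep]; quals <- res$qual[keep]
  strand <- as.character(res$strand)[keep]
  mapq <- mapq[keep]; qwidth <- qwidth[keep]
  nr <- length(pos)

  ops <- c("M", "=", "X")
  refR <- GenomicAlignments::cigarRangesAlongReferenceSpace(cigar, pos = pos,
                                                            ops = ops)
  qryR <- GenomicAlignments::cigarRangesAlongQuerySpace(cigar, ops = ops)
  nb <- S4Vectors::elementNROWS(refR)
  rid <- rep(rep.int(seq_len(nr), nb), unlist(IRanges::width(refR)))
  w <- unlist(IRanges::width(refR))
  ref_pos <- rep(unlist(IRanges::start(refR)), w) + sequence(w) - 1L
  q_pos <- rep(unlist(IRanges::start(qryR)), w) + sequence(w) - 1L

  off <- cumsum(as.numeric(qwidth)) - qwidth
  seq_raw <- charToRaw(paste(as.character(seqs), collapse = ""))
  qual_raw <- charToRaw(paste(as.character(quals), collapse = ""))
  idx <- off[rid] + q_pos
  base <- toupper(rawToChar(seq_raw[idx], multiple = TRUE))
  baseq <- as.integer(qual_raw[idx]) - 33L

  qw <- qwidth[rid]
  pos_orig <- q_pos
  rev <- strand[rid] == "-"
  pos_orig[rev] <- qw[rev] - q_pos[rev] + 1L
  d5 <- pos_orig - 1L
  d3 <- qw - pos_orig
  k <- pmin(d5, d3, K_max - 1L)
  v <- c("3p", "5p")[(d5 <= d3) + 1L]

  out <- data.table::data.table(
    read_id = rid, strand = strand[rid], mapq = mapq[rid],
    Q = mapq_to_prob(mapq[rid]), qwidth = qw,
    ref_pos = ref_pos, base = base, baseq = baseq,
    eps = phred_to_prob(baseq), k = as.integer(k), v = v)
  if (with_qname) out[, qname := res$qname[keep][rid]]
  out
}

#' Extract canonicalised cytosine observations (step 1 input)
#'
#' Walks every aligned, filter-passing read base over a reference cytosine.
#' Reference-C positions are observed by forward-strand reads and
#' reference-G positions (the opposite strand's cytosine) by reverse-strand
#' reads, whose bases are complemented into C-strand space. Each
#' observation records the base class (`C`/`T`/`OTHER`), the distance `k`
#' from the nearer read terminus in the original read orientation (ties go
#' to 5', interior positions clamp to `K_max - 1`), the terminus `v`, the
#' sequencing-error probability from base quality and the mapping-error
#' probability from MAPQ, and whether the reference context is CpG. N bases
#' in read or reference are ignored, as are masked regions and excluded
#' sites.
#'
#' @param bam path to a coordinate-sorted, indexed BAM file.
#' @param fasta path to the reference FASTA used for mapping.
#' @param chrom chromosome name.
#' @param filters a [filter_settings()].
#' @param K_max number of modelled terminal positions (default 20).
#' @return A `data.table` with columns `site` (0-based C-strand coordinate),
#'   `obs`, `k`, `v`, `eps`, `Q`, `in_cpg`, `strand`.
#' @export
extract_cytosine_observations <- function(bam, fasta, chrom,
                                          filters = filter_settings(),
                                          K_max = 20L) {
  refc <- ref_chars(fasta, chrom)
  bt <- read_base_table(bam, chrom, filters, K_max)
  L <- length(refc)
  bt <- bt[baseq >= filters$min_baseq & base != "N"]
  if (nrow(bt) == 0L)
    return(data.table::data.table(site = integer(), obs = character(),
      k = integer(), v = character(), eps = numeric(), Q = numeric(),
      in_cpg = logical(), strand = character()))
  bt[, refbase := refc[ref_pos]]
  bt <- bt[(strand == "+" & refbase == "C") |
           (strand == "-" & refbase == "G")]
  # CpG context on the observed strand; unknown context (N or chromosome
  # edge) is dropped so it cannot contaminate the non-CpG pool
  ctx <- ifelse(bt$strand == "+",
                ifelse(bt$ref_pos < L, refc[pmin(bt$ref_pos + 1L, L)], "N"),
                ifelse(bt$ref_pos > 1L, refc[pmax(bt$ref_pos - 1L, 1L)], "N"))
  bt[, ctx_base := ifelse(strand == "+", ctx, comp_base(ctx))]
  bt <- bt[ctx_base %in% c("A", "C", "G", "T")]
  bt[, in_cpg := ctx_base == "G"]
  bt[, obs := ifelse(strand == "+", base, comp_base(base))]
  bt[, obs := ifelse(obs %in% c("C", "T"), obs, "OTHER")]
  bt <- bt[!mask_hits(ref_pos, as_mask_granges(filters$mask), chrom)]
  excl <- as_exclude_sites(filters$exclude, chrom)
  if (length(excl)) bt <- bt[!(ref_pos - 1L) %in% excl]
  out <- bt[, .(site = ref_pos - 1L, obs, k, v, eps, Q, in_cpg, strand)]
  data.table::setorder(out, site)
  out[]
}

#' Balance CpG and non-CpG observation counts
#'
#' The step-1 likelihood uses equal amounts of cytosine observations within
#' and outside CpG context. All CpG-context observations are kept; non-CpG
#' observations are subsampled uniformly (seeded, reproducible) to the same
#' count. If fewer non-CpG observations exist, all are kept and a warning
#' is raised.
#'
#' @param observations a table from [extract_cytosine_observations()].
#' @param seed integer seed for the subsample (NULL = current RNG stream).
#' @return The balanced observation table.
#' @export
balance_contexts <- function(observations, seed = NULL) {
  obs <- data.table::as.data.table(observations)
  idx_cpg <- which(obs$in_cpg)
  idx_non <- which(!obs$in_cpg)
  n_cpg <- length(idx_cpg)
  if (length(idx_non) < n_cpg) {
    warnf("only %d non-CpG observations available for %d CpG observations",
          length(idx_non), n_cpg)
    return(obs)
  }
  pick <- with_seed(seed, sample(idx_non, n_cpg))
  out <- obs[sort(c(idx_cpg, pick))]
  out[]
}

# CpG site list (1-based C positions) on a chromosome, within regions,
# outside masks, minus excluded sites
cpg_sites_1based <- function(refc, chrom, regions = NULL, filters = NULL) {
  L <- length(refc)
  if (L < 2L) return(integer())
  p <- which(refc[-L] == "C" & refc[-1L] == "G")
  if (!is.null(regions)) {
    gr <- as_regions_granges(regions, chrom)
    gr <- gr[as.character(GenomicRanges::seqnames(gr)) == chrom]
    keep <- IRanges::overlapsAny(IRanges::IRanges(p, p), IRanges::ranges(gr))
    p <- p[keep]
  }
  if (!is.null(filters)) {
    mg <- as_mask_granges(filters$mask)
    if (!is.null(mg))
      p <- p[!(mask_hits(p, mg, chrom) | mask_hits(p + 1L, mg, chrom))]
    excl <- as_exclude_sites(filters$exclude, chrom)
    if (length(excl)) p <- p[!(p - 1L) %in% excl]
  }
  p
}

# regions: GRanges, BED path, or data.frame(chrom?, start, end) 0-based
as_regions_granges <- function(regions, chrom, check_overlap = FALSE) {
  if (methods::is(regions, "GRanges")) {
    gr <- regions
  } else if (is.character(regions)) {
    gr <- rtracklayer::import(regions, format = "BED")
  } else if (is.data.frame(regions)) {
    ch <- if ("chrom" %in% names(regions)) regions$chrom else chrom
    if (any(regions$end <= regions$start)) {
      bad <- which(regions$end <= regions$start)
      stopf("malformed region(s) with end <= start at row(s) %s",
            paste(bad, collapse = ", "))
    }
    gr <- GenomicRanges::GRanges(ch,
            IRanges::IRanges(start = regions$start + 1L, end = regions$end))
  } else stopf("unsupported region specification")
  if (check_overlap) {
    ov <- GenomicRanges::findOverlaps(gr, drop.self = TRUE,
                                      drop.redundant = TRUE)
    if (length(ov))
      stopf("overlapping regions: %s",
            paste(sprintf("%d/%d", S4Vectors::queryHits(ov),
                          S4Vectors::subjectHits(ov)), collapse = ", "))
  }
  gr
}

#' Extract CpG dinucleotide piles (step 2 input)
#'
#' For every reference CG dinucleotide (symmetric CpG context) in the
#' requested regions, collects all overlapping filter-passing reads into a
#' pile. Each read contributes one dinucleotide observation whose `base1`
#' and `base2` are the sequenced strand's bases at the C and G reference
#' positions (reverse-strand stored bases are complemented back into the
#' sequenced strand; the strand-deaminable cytosine is then position 1 for
#' forward and position 2 for reverse reads). Bases failing the base-quality
#' threshold, N bases, and positions not covered by the read are recorded as
#' missing (NA) and marginalised by the model; reads missing both bases are
#' dropped. Overlapping CpGs (CGCG runs) are kept as separate sites, and a
#' read may contribute to several piles.
#'
#' @inheritParams extract_cytosine_observations
#' @param regions optional regions restriction: `GRanges`, BED file path, or
#'   data.frame with `start`, `end` (0-based half-open). NULL = whole
#'   chromosome.
#' @return A `data.table` with one row per dinucleotide observation:
#'   `cpg_id`, `chrom`, `cpg_start` (0-based coordinate of the C), `read_id`,
#'   `strand`, `Q`, `base1`, `eps1`, `k1`, `v1`, `base2`, `eps2`, `k2`, `v2`.
#'   The attribute `"sites"` holds all 0-based CpG starts in scope
#'   (including sites with no coverage).
#' @export
extract_cpg_piles <- function(bam, fasta, chrom, regions = NULL,
                              filters = filter_settings(), K_max = 20L) {
  refc <- ref_chars(fasta, chrom)
  p <- cpg_sites_1based(refc, chrom, regions, filters)
  bt <- read_base_table(bam, chrom, filters, K_max)
  out_empty <- data.table::data.table(
    cpg_id = integer(), chrom = character(), cpg_start = integer(),
    read_id = integer(), strand = character(), Q = numeric(),
    base1 = character(), eps1 = numeric(), k1 = integer(), v1 = character(),
    base2 = character(), eps2 = numeric(), k2 = integer(), v2 = character())
  data.table::setattr(out_empty, "sites", p - 1L)
  if (!length(p) || nrow(bt) == 0L) return(out_empty)
  # base-level handling: low-quality or N bases become missing
  bt[baseq < filters$min_baseq | base == "N",
     `:=`(base = NA_character_, baseq = NA_integer_, eps = NA_real_)]
  site_of <- integer(length(refc))
  site_of[p] <- seq_along(p)
  b1 <- bt[ref_pos %in% p]
  b1[, cpg_id := site_of[ref_pos]]
  b2 <- bt[ref_pos %in% (p + 1L)]
  b2[, cpg_id := site_of[ref_pos - 1L]]
  d1 <- b1[, .(cpg_id, read_id, strand, Q,
               base1 = ifelse(strand == "+", base, comp_base(base)),
               eps1 = eps, k1 = k, v1 = v)]
  d2 <- b2[, .(cpg_id, read_id, strand, Q,
               base2 = ifelse(strand == "+", base, comp_base(base)),
               eps2 = eps, k2 = k, v2 = v)]
  m <- merge(d1, d2, by = c("cpg_id", "read_id"), all = TRUE,
             suffixes = c("", ".2"))
  m[, strand := data.table::fifelse(is.na(strand), strand.2, strand)]
  m[, Q := data.table::fifelse(is.na(Q), Q.2, Q)]
  m <- m[!(is.na(base1) & is.na(base2))]
  m[is.na(base1), `:=`(eps1 = NA_real_, k1 = NA_integer_, v1 = NA_character_)]
  m[is.na(base2), `:=`(eps2 = NA_real_, k2 = NA_integer_, v2 = NA_character_)]
  out <- m[, .(cpg_id, chrom = chrom, cpg_start = p[cpg_id] - 1L, read_id,
               strand, Q, base1, eps1, k1, v1, base2, eps2, k2, v2)]
  data.table::setorder(out, cpg_start, read_id)
  data.table::setattr(out, "sites", p - 1L)
  out[]
}
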