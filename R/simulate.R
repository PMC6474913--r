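# Methylation-aware ancient-DNA read simulator: fragments drawn from N
# diploid genomes (cells of one individual) with per-CpG methylation flags,
# methylation- and position-specific deamination, sequencing errors,
# optional true variants and adapters. Emits a coordinate-sorted indexed
# BAM at true alignment positions plus a full ground-truth record.

#' Simulation configuration
#'
#' @param n_genomes number of diploid genomes (cells) sampled from
#'   (default 100).
#' @param coverage target fold coverage.
#' @param D_true a [deamination_profile()] of true deamination rates; reads
#'   deaminate C->T on the sequenced strand at the methylated or
#'   unmethylated rate by position/terminus. Cytosines outside CpG context
#'   use the unmethylated rates.
#' @param methylation a single level in `[0, 1]` applied to every CpG, or a
#'   data.frame with `start` (0-based C coordinate) and `level` giving
#'   per-CpG methylation levels (missing sites default to
#'   `default_level`).
#' @param default_level level for CpGs absent from a methylation map
#'   (default 0.75).
#' @param frag_meanlog,frag_sdlog lognormal fragment-length parameters
#'   (defaults log(70) and 0.25, typical of ancient DNA).
#' @param frag_min,frag_max truncation bounds in bp (defaults 30, 150).
#' @param frag_lengths optional empirical fragment-length pool (integer
#'   vector, e.g. observed lengths from a real library); when supplied,
#'   lengths are resampled from it (truncated to `[frag_min, frag_max]`)
#'   instead of the lognormal.
#' @param baseq constant Phred base quality emitted (default 30).
#' @param mapq mapping quality emitted (default 37).
#' @param variant_rate probability that a CpG site carries an injected true
#'   variant (default 0).
#' @param p_het probability an injected variant is heterozygous
#'   (default 2/3, i.e. het:hom odds of 2:1).
#' @param adapter adapter sequence appended in FASTQ output when the
#'   fragment is shorter than `read_length`.
#' @param read_length sequencing read length for FASTQ output (NULL =
#'   fragments emitted full length, no adapter).
#' @param chrom name of the simulated chromosome.
#' @param seed integer seed; all randomness in [simulate_reads()] derives
#'   from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genomes = 100L, coverage = 5,
                       D_true = deamination_preset("ds_high"),
                       methylation = 0.75, default_level = 0.75,
                       frag_meanlog = log(70), frag_sdlog = 0.25,
                       frag_min = 30L, frag_max = 150L, frag_lengths = NULL,
                       baseq = 30L, mapq = 37L,
                       variant_rate = 0, p_het = 2 / 3,
                       adapter = "AGATCGGAAGAGC", read_length = NULL,
                       chrom = "chrS", seed = NULL) {
  if (n_genomes < 1L) stopf("n_genomes must be >= 1")
  if (coverage <= 0) stopf("coverage must be > 0")
  check_prob(variant_rate, "variant_rate")
  check_prob(p_het, "p_het")
  structure(as.list(environment()), class = "sim_config")
}

#' Draw per-genome methylation flags
#'
#' Each genome (cell) flags each CpG methylated with probability equal to
#' the site's map level: one Bernoulli per genome per site, symmetric
#' across strands and shared by both haplotype copies.
#'
#' @param levels numeric vector of per-site methylation levels in `[0, 1]`.
#' @param n_genomes number of genomes.
#' @param seed integer seed (NULL = current RNG stream).
#' @return Logical matrix `length(levels) x n_genomes`.
#' @export
flag_methylation <- function(levels, n_genomes, seed = NULL) {
  check_prob(levels, "levels")
  with_seed(seed, {
    matrix(runif(length(levels) * n_genomes) < levels,
           nrow = length(levels), ncol = n_genomes)
  })
}

#' Inject true dinucleotide variants at CpG sites
#'
#' Builds the individual's two haplotypes from the reference. At each CpG,
#' with probability `variant_rate` the CG is replaced on one (heterozygous)
#' or both (homozygous) haplotypes by a TG or CA allele (equal odds).
#' Variant alleles carry no methylatable CpG cytosine.
#'
#' @param reference reference sequence (character string, `DNAString`, or
#'   character vector of bases).
#' @param variant_rate per-CpG variant probability.
#' @param seed integer seed.
#' @param p_het probability a variant is heterozygous (default 2/3).
#' @return List with `hap1`, `hap2` (character vectors of bases), `sites`
#'   (0-based reference CpG C coordinates) and `variants` (data.frame:
#'   `site`, `genotype`, `hap1_allele`, `hap2_allele`).
#' @export
inject_variants <- function(reference, variant_rate, seed = NULL,
                            p_het = 2 / 3) {
  check_prob(variant_rate, "variant_rate")
  refc <- dna_chars(reference)
  L <- length(refc)
  p <- which(refc[-L] == "C" & refc[-1L] == "G")   # 1-based C positions
  hap1 <- refc; hap2 <- refc
  with_seed(seed, {
    hit <- which(runif(length(p)) < variant_rate)
    if (length(hit)) {
      het <- runif(length(hit)) < p_het
      allele <- sample(c("TG", "CA"), length(hit), replace = TRUE)
      which_hap <- sample(1:2, length(hit), replace = TRUE)
      a1 <- ifelse(het & which_hap == 2L, "CG", allele)
      a2 <- ifelse(het & which_hap == 1L, "CG", allele)
      pos <- p[hit]
      sub <- function(hap, al) {
        hap[pos] <- substr(al, 1, 1)
        hap[pos + 1L] <- substr(al, 2, 2)
        hap
      }
      hap1 <- sub(hap1, a1)
      hap2 <- sub(hap2, a2)
      variants <- data.frame(site = pos - 1L,
                             genotype = ifelse(het, "het", "hom"),
                             hap1_allele = a1, hap2_allele = a2,
                             stringsAsFactors = FALSE)
    } else {
      variants <- data.frame(site = integer(), genotype = character(),
                             hap1_allele = character(),
                             hap2_allele = character(),
                             stringsAsFactors = FALSE)
    }
    list(hap1 = hap1, hap2 = hap2, sites = p - 1L, variants = variants)
  })
}

#' Generate a random reference sequence
#'
#' Uniform base composition; CpGs then arise at roughly 1/16 of dinucleotide
#' positions. Deterministic given `seed`.
#'
#' @param length sequence length in bp.
#' @param seed integer seed.
#' @return A character string.
#' @export
sim_reference <- function(length, seed = NULL) {
  with_seed(seed, paste(sample(c("A", "C", "G", "T"), length,
                               replace = TRUE), collapse = ""))
}

# per-site methylation levels resolved against the CpG site list (0-based)
resolve_levels <- function(methylation, sites0, default_level) {
  if (is.numeric(methylation) && length(methylation) == 1L)
    return(rep(methylation, length(sites0)))
  if (is.data.frame(methylation)) {
    lv <- rep(default_level, length(sites0))
    m <- match(sites0, methylation$start)
    lv[!is.na(m)] <- methylation$level[m[!is.na(m)]]
    return(lv)
  }
  if (is.numeric(methylation) && length(methylation) == length(sites0))
    return(methylation)
  stopf("unsupported methylation specification")
}

#' Simulate ancient-DNA reads with methylation-dependent damage
#'
#' Draws DNA fragments (genome, haplotype, strand and start uniform;
#' lengths truncated-lognormal) until the target coverage is reached. On
#' the sequenced strand, every cytosine deaminates C->T with the methylated
#' rate if it belongs to a CpG flagged methylated in the fragment's genome,
#' and with the unmethylated rate otherwise (including all non-CpG
#' cytosines). `k` is the distance to the nearer fragment terminus (clamped
#' at `K_max - 1`, ties to 5') and `v` that terminus. Uniform sequencing
#' errors are applied at the rate implied by the emitted base quality.
#' Reads are written as a coordinate-sorted, indexed BAM at their true
#' positions with correct FLAG/orientation; optional FASTQ output appends
#' the adapter when the fragment is shorter than the read length.
#'
#' @param reference reference sequence (string, `DNAString` or base vector).
#' @param config a [sim_config()].
#' @param out_dir output directory (default: a fresh temporary directory).
#' @param fastq if TRUE, also write `reads.fastq.gz`.
#' @return A list of class `adna_sim`: `bam`, `fasta`, `chrom`, `config`,
#'   and `truth` (list with `sites` 0-based CpG starts, `levels`, `flags`
#'   site x genome matrix, `n_cg_copies` per site, `f_site` realized
#'   per-site methylated fraction, `variants`, `hap1`, `hap2`, `fragments`
#'   provenance table).
#' @export
simulate_reads <- function(reference, config = sim_config(),
                           out_dir = tempfile("adna_sim_"), fastq = FALSE) {
  refc <- dna_chars(reference)
  L <- length(refc)
  if (L < config$frag_max)
    stopf("reference (%d bp) shorter than the maximum fragment length (%d bp)",
          L, config$frag_max)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  D <- config$D_true
  K <- D$K_max

  with_seed(config$seed, {
    gt <- inject_variants(refc, config$variant_rate, seed = NULL,
                          p_het = config$p_het)
    sites0 <- gt$sites
    levels <- resolve_levels(config$methylation, sites0,
                             config$default_level)
    flags <- flag_methylation(levels, config$n_genomes, seed = NULL)

    # methylatable-cytosine lookup per haplotype and strand: coordinate ->
    # site index (0 = not a CpG cytosine on that strand of that haplotype)
    hapmat <- rbind(gt$hap1, gt$hap2)
    site_fwd <- site_rev <- matrix(0L, 2, L)
    for (h in 1:2) {
      is_cg <- hapmat[h, sites0 + 1L] == "C" & hapmat[h, sites0 + 2L] == "G"
      site_fwd[h, sites0[is_cg] + 1L] <- which(is_cg)
      site_rev[h, sites0[is_cg] + 2L] <- which(is_cg)
    }

    # fragment draws until the target number of sequenced bases
    target <- config$coverage * L
    pool <- config$frag_lengths
    if (!is.null(pool)) {
      pool <- as.integer(pool[pool >= config$frag_min &
                              pool <= config$frag_max])
      if (!length(pool)) stopf("no usable empirical fragment lengths")
    }
    lens <- integer(0)
    while (sum(lens) < target) {
      n_draw <- max(1000L, ceiling(target / 60))
      cand <- if (is.null(pool)) {
        round(rlnorm(n_draw, config$frag_meanlog, config$frag_sdlog))
      } else sample(pool, n_draw, replace = TRUE)
      cand <- cand[cand >= config$frag_min & cand <= config$frag_max]
      lens <- c(lens, as.integer(cand))
    }
    lens <- lens[seq_len(which(cumsum(as.numeric(lens)) >= target)[1])]
    nf <- length(lens)
    genome <- sample.int(config$n_genomes, nf, replace = TRUE)
    hap <- sample.int(2L, nf, replace = TRUE)
    strand <- sample(c("+", "-"), nf, replace = TRUE)
    start <- floor(runif(nf, 1, L - lens + 1 + 1))  # uniform 1..L-len+1
    start <- pmin(as.integer(start), L - lens + 1L)

    # per-base expansion (coordinates always ascending along the reference)
    bidx <- rep.int(seq_len(nf), lens)
    coord <- rep(start, lens) + sequence(lens) - 1L
    hap_b <- hap[bidx]
    base_ref <- hapmat[cbind(hap_b, coord)]       # haplotype base
    fwd_b <- strand[bidx] == "+"
    seq_base <- base_ref
    seq_base[!fwd_b] <- comp_base(base_ref[!fwd_b])

    # read-orientation position, terminal distance and terminus
    pos_in <- sequence(lens)
    len_b <- lens[bidx]
    pos_orig <- pos_in
    pos_orig[!fwd_b] <- len_b[!fwd_b] - pos_in[!fwd_b] + 1L
    d5 <- pos_orig - 1L
    d3 <- len_b - pos_orig
    kb <- pmin(d5, d3, K - 1L)
    vb <- c("3p", "5p")[(d5 <= d3) + 1L]

    # deamination of sequenced-strand cytosines
    isC <- seq_base == "C"
    sid <- integer(sum(isC))
    ci <- which(isC)
    f_rows <- fwd_b[ci]
    sid[f_rows] <- site_fwd[cbind(hap_b[ci][f_rows], coord[ci][f_rows])]
    sid[!f_rows] <- site_rev[cbind(hap_b[ci][!f_rows], coord[ci][!f_rows])]
    meth <- sid > 0L & flags[cbind(pmax(sid, 1L), genome[bidx][ci])]
    rate <- deam_rate(D, meth, kb[ci], vb[ci])
    deam <- runif(length(ci)) < rate
    seq_base[ci[deam]] <- "T"
    n_deam_per_frag <- tabulate(bidx[ci[deam]], nbins = nf)

    # uniform sequencing errors at the configured base quality
    eps <- phred_to_prob(config$baseq)
    err <- which(runif(length(seq_base)) < eps)
    if (length(err)) {
      alt <- matrix(c("C","G","T", "A","G","T", "A","C","T", "A","C","G"),
                    nrow = 4, byrow = TRUE,
                    dimnames = list(c("A","C","G","T"), NULL))
      pickv <- sample.int(3L, length(err), replace = TRUE)
      seq_base[err] <- alt[cbind(match(seq_base[err], rownames(alt)), pickv)]
    }

    # store in reference orientation (reverse reads are re-complemented)
    stored <- seq_base
    stored[!fwd_b] <- comp_base(seq_base[!fwd_b])
    reads <- vapply(split(stored, bidx), paste, "", collapse = "")

    # write FASTA reference + SAM -> sorted indexed BAM
    fasta <- file.path(out_dir, "reference.fa")
    writeLines(c(paste0(">", config$chrom), paste(refc, collapse = "")),
               fasta)
    Rsamtools::indexFa(fasta)
    qual <- vapply(lens, function(l)
      strrep(rawToChar(as.raw(config$baseq + 33L)), l), "")
    qname <- sprintf("f%07d", seq_len(nf))
    sam <- file.path(out_dir, "reads.sam")
    hdr <- c("@HD\tVN:1.6\tSO:unknown",
             sprintf("@SQ\tSN:%s\tLN:%d", config$chrom, L))
    recs <- paste(qname, ifelse(strand == "+", 0L, 16L), config$chrom,
                  start, config$mapq, paste0(lens, "M"), "*", 0L, 0L,
                  reads, qual, sep = "\t")
    writeLines(c(hdr, recs), sam)
    bam <- Rsamtools::asBam(sam, file.path(out_dir, "reads"),
                            overwrite = TRUE, indexDestination = TRUE)
    unlink(sam)

    if (fastq) {
      fq <- file.path(out_dir, "reads.fastq.gz")
      rl <- config$read_length
      seq5to3 <- vapply(split(seq_base, bidx), paste, "", collapse = "")
      seq5to3[strand == "-"] <- vapply(
        strsplit(seq5to3[strand == "-"], ""),
        function(x) paste(rev(x), collapse = ""), "")
      if (!is.null(rl)) {
        seq5to3 <- substr(paste0(seq5to3, strrep(config$adapter,
                    ceiling(rl / max(1, nchar(config$adapter))))), 1, rl)
      }
      con <- gzfile(fq, "w")
      writeLines(paste0("@", qname, "\n", seq5to3, "\n+\n",
                        vapply(nchar(seq5to3), function(l)
                          strrep(rawToChar(as.raw(config$baseq + 33L)), l),
                          "")), con)
      close(con)
    }

    n_cg <- (gt$hap1[sites0 + 1L] == "C" & gt$hap1[sites0 + 2L] == "G") +
            (gt$hap2[sites0 + 1L] == "C" & gt$hap2[sites0 + 2L] == "G")
    f_site <- ifelse(n_cg > 0, rowMeans(flags), NA_real_)
    fragments <- data.frame(qname = qname, genome = genome, hap = hap,
                            strand = strand, start = start - 1L,
                            length = lens, n_deam = n_deam_per_frag,
                            stringsAsFactors = FALSE)
    structure(list(
      bam = bam, fasta = fasta, chrom = config$chrom, config = config,
      truth = list(sites = sites0, levels = levels, flags = flags,
                   n_cg_copies = as.integer(n_cg), f_site = f_site,
                   variants = gt$variants, hap1 = gt$hap1, hap2 = gt$hap2,
                   fragments = fragments)
    ), class = "adna_sim")
  })
}

#' True methylated fraction per window
#'
#' Ground-truth counterpart of [estimate_f()]: for each window, the number
#' of methylated CG copies over the total CG copies across the
#' `2 * n_genomes` haplotype copies of the window's sites. Haplotype copies
#' carrying a variant (non-CG) allele are excluded from the denominator.
#'
#' @param truth the `truth` element of an `adna_sim` object.
#' @param windows data.frame with `start`, `end` (0-based half-open).
#' @return Numeric vector of true `f` per window (NA where the window holds
#'   no CG copies).
#' @export
truth_f_per_window <- function(truth, windows) {
  n_gen <- ncol(truth$flags)
  meth_site <- truth$n_cg_copies * rowSums(truth$flags)
  tot_site <- truth$n_cg_copies * n_gen
  vapply(seq_len(nrow(windows)), function(i) {
    inw <- truth$sites >= windows$start[i] & truth$sites < windows$end[i]
    tot <- sum(tot_site[inw])
    if (tot == 0) NA_real_ else sum(meth_site[inw]) / tot
  }, numeric(1))
}
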