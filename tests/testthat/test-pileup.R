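# BAM/FASTA extraction: canonicalisation, filters, masking, context
# balancing, dinucleotide piles.

test_that("forward read over a CpG yields one C-strand observation", {
  # reference AACGTT, read CT at the C (pos 3): C observed in CpG context;
  # the G position gives nothing from a forward read
  fx <- make_test_bam(data.frame(pos = 3, seq = "CT", flag = 0), "AACGTT")
  obs <- extract_cytosine_observations(fx$bam, fx$fasta, fx$chrom,
                                       filters = lax_filters())
  expect_equal(nrow(obs), 1L)
  expect_equal(obs$site, 2L)       # 0-based
  expect_equal(obs$obs, "C")
  expect_true(obs$in_cpg)
  expect_equal(obs$k, 0L)
  expect_equal(obs$v, "5p")
  expect_equal(obs$strand, "+")
})

test_that("reverse-strand bases are complemented into C-strand space", {
  # reference AACGTT: reverse read over the G (pos 4) showing A = deaminated
  # C on the minus strand; 5' neighbour (on plus strand) is C -> CpG
  fx <- make_test_bam(data.frame(pos = 3, seq = "CA", flag = 16), "AACGTT")
  obs <- extract_cytosine_observations(fx$bam, fx$fasta, fx$chrom,
                                       filters = lax_filters())
  g_obs <- as.data.frame(obs)[obs$site == 3L, ]
  expect_equal(nrow(g_obs), 1L)
  expect_equal(g_obs$obs, "T")
  expect_true(g_obs$in_cpg)
  expect_equal(g_obs$strand, "-")
  # for a reverse read the right end is its 5' terminus
  expect_equal(g_obs$v, "5p")
})

test_that("read-, base- and site-level filters are honoured", {
  ref <- "AACGTTACGTAACGTT"
  reads <- data.frame(
    pos = c(2, 2, 2, 7), seq = c("ACGT", "ACGT", "ACGT", "ACGT"),
    flag = 0, mapq = c(37, 10, 37, 37), baseq = c(37, 37, 5, 37))
  fx <- make_test_bam(reads, ref)
  f0 <- lax_filters()
  obs <- extract_cytosine_observations(fx$bam, fx$fasta, fx$chrom, f0)
  # low-MAPQ read and low-baseq bases dropped
  expect_true(all(obs$Q <= 10^(-25 / 10)))
  expect_equal(sum(obs$site == 2), 1L)   # only the two good reads' C
  expect_equal(sum(obs$site == 7), 1L)
  # fragment-length filter
  fl <- filter_settings(min_baseq = 13, min_mapq = 25, min_length = 10)
  expect_equal(nrow(extract_cytosine_observations(fx$bam, fx$fasta,
                                                  fx$chrom, fl)), 0L)
  # masking removes sites inside the masked range
  fm <- lax_filters(mask = data.frame(chrom = "chrT", start = 0, end = 5))
  obs_m <- extract_cytosine_observations(fx$bam, fx$fasta, fx$chrom, fm)
  expect_false(any(obs_m$site <= 4))
  # single-site exclusion
  fe <- lax_filters(exclude = data.frame(chrom = "chrT", pos = 7))
  obs_e <- extract_cytosine_observations(fx$bam, fx$fasta, fx$chrom, fe)
  expect_false(any(obs_e$site == 7))
})

test_that("observation counts match an independent walk over alignments", {
  set.seed(31)
  L <- 2000
  ref <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
               collapse = "")
  refc <- strsplit(ref, "")[[1]]
  n <- 150
  len <- sample(30:60, n, replace = TRUE)
  pos <- sample(L - max(len), n, replace = TRUE)
  seqs <- vapply(seq_len(n), function(i)
    substr(ref, pos[i], pos[i] + len[i] - 1), "")
  flags <- sample(c(0L, 16L), n, replace = TRUE)
  fx <- make_test_bam(data.frame(pos = pos, seq = seqs, flag = flags), ref)
  obs <- extract_cytosine_observations(fx$bam, fx$fasta, fx$chrom)
  # independent count: loop over reads and reference positions
  expected <- 0L
  for (i in seq_len(n)) {
    for (p in pos[i]:(pos[i] + len[i] - 1)) {
      rb <- refc[p]
      if (flags[i] == 0L && rb == "C" && p < L) expected <- expected + 1L
      if (flags[i] == 16L && rb == "G" && p > 1) expected <- expected + 1L
    }
  }
  expect_equal(nrow(obs), expected)
  # every emitted observation passes every filter
  expect_true(all(obs$Q <= 10^(-25 / 10) & obs$eps <= 10^(-13 / 10)))
})

test_that("extraction is invariant under reverse-complementing the fixture", {
  set.seed(33)
  L <- 500
  refc <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  ref <- paste(refc, collapse = "")
  n <- 40
  len <- sample(30:40, n, replace = TRUE)
  pos <- sample(L - 40, n, replace = TRUE)
  seqs <- vapply(seq_len(n), function(i)
    substr(ref, pos[i], pos[i] + len[i] - 1), "")
  flags <- sample(c(0L, 16L), n, replace = TRUE)
  fx <- make_test_bam(data.frame(pos = pos, seq = seqs, flag = flags), ref)
  obs <- extract_cytosine_observations(fx$bam, fx$fasta, fx$chrom)

  # reverse-complement the world: reference, read placement, strand
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc <- function(s) paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  ref2 <- rc(ref)
  pos2 <- L - (pos + len - 1) + 1
  seqs2 <- vapply(seqs, rc, "")
  flags2 <- ifelse(flags == 0L, 16L, 0L)
  fx2 <- make_test_bam(data.frame(pos = pos2, seq = seqs2, flag = flags2),
                       ref2)
  obs2 <- extract_cytosine_observations(fx2$bam, fx2$fasta, fx2$chrom)
  expect_equal(nrow(obs), nrow(obs2))
  # map mirrored coordinates back and compare the full observation sets
  obs2$site <- L - 1L - obs2$site
  key <- function(d) sort(paste(d$site, d$obs, d$k, d$v, d$in_cpg))
  expect_equal(key(obs), key(obs2))
})

test_that("balance_contexts enforces equal context counts, reproducibly", {
  set.seed(41)
  obs <- data.frame(site = 1:1100, obs = "C", k = 0L, v = "5p", eps = 0.01,
                    Q = 0.01, in_cpg = rep(c(TRUE, FALSE), c(100, 1000)),
                    strand = "+")
  bal <- balance_contexts(obs, seed = 9)
  expect_equal(sum(bal$in_cpg), 100L)
  expect_equal(sum(!bal$in_cpg), 100L)
  bal2 <- balance_contexts(obs, seed = 9)
  expect_identical(bal$site, bal2$site)
  # shortage: keep everything, warn
  obs2 <- data.frame(site = 1:140, obs = "C", k = 0L, v = "5p", eps = 0.01,
                     Q = 0.01, in_cpg = rep(c(TRUE, FALSE), c(100, 40)),
                     strand = "+")
  expect_warning(bal3 <- balance_contexts(obs2, seed = 9), "non-CpG")
  expect_equal(nrow(bal3), 140L)
})

test_that("CpG piles collect clean and overlapping dinucleotides", {
  fx <- make_test_bam(data.frame(pos = 1, seq = "ACGT", flag = 0), "ACGT")
  piles <- extract_cpg_piles(fx$bam, fx$fasta, fx$chrom,
                             filters = lax_filters())
  expect_equal(nrow(piles), 1L)
  expect_equal(piles$cpg_start, 1L)
  expect_equal(piles$base1, "C")
  expect_equal(piles$base2, "G")
  expect_equal(attr(piles, "sites"), 1L)

  # overlapping CpGs: both sites emitted, the read contributes to both
  fx2 <- make_test_bam(data.frame(pos = 1, seq = "ACGCGT", flag = 0),
                       "ACGCGT")
  piles2 <- extract_cpg_piles(fx2$bam, fx2$fasta, fx2$chrom,
                              filters = lax_filters())
  expect_equal(attr(piles2, "sites"), c(1L, 3L))
  expect_equal(nrow(piles2), 2L)
  expect_equal(piles2$cpg_start, c(1L, 3L))
})

test_that("reverse reads in piles carry sequenced-strand bases", {
  # deaminated reverse read over ACGT: minus-strand C (over the G) reads T,
  # stored as A; canonical pile observation is (G, T)? no -- (G, C) clean,
  # (G, T) when deaminated
  fx <- make_test_bam(data.frame(pos = 1, seq = "ACAT", flag = 16), "ACGT")
  piles <- extract_cpg_piles(fx$bam, fx$fasta, fx$chrom,
                             filters = lax_filters())
  expect_equal(nrow(piles), 1L)
  expect_equal(piles$strand, "-")
  expect_equal(piles$base1, "G")   # complement of stored C
  expect_equal(piles$base2, "T")   # complement of stored A: deaminated C
})

test_that("pile sizes match an independent overlap count", {
  set.seed(47)
  L <- 3000
  refc <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  ref <- paste(refc, collapse = "")
  n <- 120
  len <- sample(30:50, n, replace = TRUE)
  pos <- sample(L - 50, n, replace = TRUE)
  seqs <- vapply(seq_len(n), function(i)
    substr(ref, pos[i], pos[i] + len[i] - 1), "")
  flags <- sample(c(0L, 16L), n, replace = TRUE)
  fx <- make_test_bam(data.frame(pos = pos, seq = seqs, flag = flags), ref)
  piles <- extract_cpg_piles(fx$bam, fx$fasta, fx$chrom)
  cg <- which(refc[-L] == "C" & refc[-1] == "G")
  expected <- 0L
  for (p in cg) for (i in seq_len(n))
    if (pos[i] <= p + 1 && pos[i] + len[i] - 1 >= p) expected <- expected + 1L
  expect_equal(nrow(piles), expected)
  expect_equal(attr(piles, "sites"), cg - 1L)
})
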