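# Independent brute-force oracle: exhaustive enumeration over every latent
# state (mismapping, allele copy, methylation, deamination, per-base
# sequencing-error outcome), multiplying raw probabilities. Kept free of
# package internals on purpose.

.ocomp <- c(A = "T", C = "G", G = "C", T = "A")

oerr <- function(x, b, eps) {
  if (is.na(x)) return(1)
  if (x == b) 1 - eps else eps / 3
}

oracle_single_base <- function(obs, d_meth, d_unmeth, F, in_cpg, eps, Q) {
  u <- if (obs == "OTHER") 0.5 else 0.25
  meth_states <- if (in_cpg) list(c(1, F), c(0, 1 - F)) else list(c(0, 1))
  p_mapped <- 0
  for (ms in meth_states) {
    d <- if (ms[1] == 1) d_meth else d_unmeth
    for (deam in c(TRUE, FALSE)) {
      pd <- if (deam) d else 1 - d
      emitted <- if (deam) "T" else "C"
      for (x in c("A", "C", "G", "T")) {
        cls <- if (x %in% c("C", "T")) x else "OTHER"
        if (cls == obs)
          p_mapped <- p_mapped + ms[2] * pd * oerr(x, emitted, eps)
      }
    }
  }
  Q * u + (1 - Q) * p_mapped
}

# o: list/one-row df with base1, base2, eps1, eps2, Q, strand, k1, v1, k2, v2
oracle_dinuc <- function(o, g, f, D) {
  u <- (if (is.na(o$base1)) 1 else 0.25) * (if (is.na(o$base2)) 1 else 0.25)
  if (g == "OTHER") return(o$Q * u + (1 - o$Q) * u)
  al <- strsplit(g, "/", fixed = TRUE)[[1]]
  rate <- function(meth, k, v) {
    m <- if (meth) D$rate_meth else D$rate_unmeth
    unname(m[min(k, D$K_max - 1) + 1, v])
  }
  pallele <- function(a) {
    if (o$strand == "+") {
      tb <- c(substr(a, 1, 1), substr(a, 2, 2)); dpos <- 1
      kd <- o$k1; vd <- o$v1
    } else {
      tb <- unname(.ocomp[c(substr(a, 1, 1), substr(a, 2, 2))]); dpos <- 2
      kd <- o$k2; vd <- o$v2
    }
    deaminable <- identical(tb[dpos], "C") && !is.na(kd)
    meth_states <- if (a == "CG") list(c(1, f), c(0, 1 - f))
                   else list(c(0, 1))
    tot <- 0
    for (ms in meth_states) {
      if (ms[2] == 0) next
      states <- if (deaminable) {
        d <- rate(ms[1] == 1, kd, vd)
        list(c(1, d), c(0, 1 - d))
      } else list(c(0, 1))
      for (ds in states) {
        emitted <- tb
        if (ds[1] == 1) emitted[dpos] <- "T"
        p <- oerr(o$base1, emitted[1], o$eps1) *
             oerr(o$base2, emitted[2], o$eps2)
        tot <- tot + ms[2] * ds[2] * p
      }
    }
    tot
  }
  o$Q * u + (1 - o$Q) * 0.5 * (pallele(al[1]) + pallele(al[2]))
}

.ognames <- c("CG/CG", "CG/TG", "CG/CA", "TG/TG", "TG/CA", "CA/CA", "OTHER")

oracle_window_ll <- function(f, piles, D, prior) {
  piles <- as.data.frame(piles)
  total <- 0
  for (id in unique(piles$cpg_id)) {
    sub <- piles[piles$cpg_id == id, , drop = FALSE]
    site_p <- 0
    for (gi in seq_along(.ognames)) {
      pg <- prior$probs[[gi]]
      if (pg == 0) next
      prod_p <- 1
      for (r in seq_len(nrow(sub)))
        prod_p <- prod_p * oracle_dinuc(sub[r, ], .ognames[gi], f, D)
      site_p <- site_p + pg * prod_p
    }
    total <- total + log(site_p)
  }
  total
}

# random valid inputs for property tests (uses its own RNG stream)
random_profile <- function(K = 5) {
  u <- matrix(runif(K * 2, 0, 0.25), K, 2, dimnames = list(NULL, c("5p", "3p")))
  m <- u + matrix(runif(K * 2, 0, 0.5), K, 2)
  deamination_profile(rate_unmeth = u, rate_meth = pmin(m, 0.95))
}

random_pile_table <- function(n_sites, max_reads = 3, K = 5) {
  rows <- list()
  bases <- c("A", "C", "G", "T")
  for (s in seq_len(n_sites)) {
    for (r in seq_len(sample(max_reads, 1))) {
      miss <- sample(c("none", "b1", "b2"), 1, prob = c(0.7, 0.15, 0.15))
      b1 <- if (miss == "b1") NA_character_ else sample(bases, 1)
      b2 <- if (miss == "b2") NA_character_ else sample(bases, 1)
      rows[[length(rows) + 1L]] <- data.frame(
        cpg_id = s, chrom = "chrT", cpg_start = 10L * s,
        read_id = r, strand = sample(c("+", "-"), 1),
        Q = runif(1, 0, 0.4),
        base1 = b1, eps1 = if (is.na(b1)) NA_real_ else runif(1, 0, 0.15),
        k1 = if (is.na(b1)) NA_integer_ else sample(0:(K - 1), 1),
        v1 = if (is.na(b1)) NA_character_ else sample(c("5p", "3p"), 1),
        base2 = b2, eps2 = if (is.na(b2)) NA_real_ else runif(1, 0, 0.15),
        k2 = if (is.na(b2)) NA_integer_ else sample(0:(K - 1), 1),
        v2 = if (is.na(b2)) NA_character_ else sample(c("5p", "3p"), 1),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
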