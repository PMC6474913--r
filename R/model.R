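# Probabilistic kernels: per-observation probabilities for the step-1
# deamination likelihood and per-pile probabilities for the step-2
# methylation likelihood. Pure functions, no I/O.

# Dinucleotide genotype space: diploid unordered genotypes over alleles
# {CG, TG, CA} -- the alleles confoundable with strand-specific deamination
# signal -- plus an aggregate OTHER state.
.GT_ALLELES <- list(
  `CG/CG` = c("CG", "CG"), `CG/TG` = c("CG", "TG"), `CG/CA` = c("CG", "CA"),
  `TG/TG` = c("TG", "TG"), `TG/CA` = c("TG", "CA"), `CA/CA` = c("CA", "CA"),
  OTHER = NA)
.GT_NAMES <- names(.GT_ALLELES)

#' Probability of a single cytosine observation
#'
#' The per-observation likelihood term used in step 1. A reference cytosine
#' (canonicalised to C-strand space) is deaminated with effective rate
#' `d = F * d_meth + (1 - F) * d_unmeth` when in CpG context (methylation
#' status is unknown, so the genome-wide fraction `F` weights the two rates)
#' and `d = d_unmeth` outside CpG context. The emitted base (T with
#' probability `d`, else C) is pushed through a uniform sequencing-error
#' channel (`eps`, misread to each other base with `eps/3`) and a mapping
#' -error mixture (`Q`, uniform 1/4 per base when mismapped). Observations
#' are collapsed to the classes `"C"`, `"T"`, `"OTHER"` (the two non-C/T
#' bases).
#'
#' @param obs observed base class, `"C"`, `"T"` or `"OTHER"` (vectorised).
#' @param d_meth,d_unmeth deamination probabilities for methylated and
#'   unmethylated cytosines at this read position/terminus.
#' @param F genome-wide fraction of methylated CpGs.
#' @param in_cpg logical; is the reference cytosine in CpG context?
#' @param eps,Q sequencing-error and mapping-error probabilities.
#' @return Probability of the observation; sums to 1 over the three classes.
#' @export
single_base_prob <- function(obs, d_meth, d_unmeth, F, in_cpg, eps, Q) {
  for (nm in c("d_meth", "d_unmeth", "F", "eps", "Q"))
    check_prob(get(nm), nm)
  if (!all(obs %in% c("C", "T", "OTHER")))
    stopf("'obs' must be one of C, T, OTHER")
  d <- ifelse(in_cpg, F * d_meth + (1 - F) * d_unmeth, d_unmeth)
  p_mapped <- ifelse(obs == "C", (1 - d) * (1 - eps) + d * (eps / 3),
              ifelse(obs == "T", d * (1 - eps) + (1 - d) * (eps / 3),
                     2 * eps / 3))
  u <- ifelse(obs == "OTHER", 0.5, 0.25)
  Q * u + (1 - Q) * p_mapped
}

#' Prior over the dinucleotide genotype space
#'
#' Diploid genotype prior at a reference CpG site, marginalised over in the
#' step-2 likelihood so that true variants (e.g. a germline CG->TG allele,
#' which mimics full deamination) are not mistaken for methylation signal.
#' Alleles are drawn independently with probabilities CG: `1 - 3*theta`,
#' TG: `theta`, CA: `theta`, any other dinucleotide: `theta`; unordered
#' diploid genotypes containing an "other" allele collapse into the
#' aggregate `OTHER` state.
#'
#' @param theta per-allele alternate probability, in `[0, 0.25]`
#'   (default 0.001, a typical per-site heterozygosity scale).
#' @return Object of class `genotype_prior`: list with `theta` and a
#'   7-vector `probs` over `CG/CG, CG/TG, CG/CA, TG/TG, TG/CA, CA/CA, OTHER`.
#' @export
genotype_prior <- function(theta = 0.001) {
  if (!is.finite(theta) || theta < 0 || theta > 0.25)
    stopf("'theta' must be in [0, 0.25]")
  pc <- 1 - 3 * theta
  probs <- c(`CG/CG` = pc^2, `CG/TG` = 2 * pc * theta, `CG/CA` = 2 * pc * theta,
             `TG/TG` = theta^2, `TG/CA` = 2 * theta^2, `CA/CA` = theta^2,
             OTHER = 0)
  probs["OTHER"] <- 1 - sum(probs)
  structure(list(theta = theta, probs = probs), class = "genotype_prior")
}

# --- internal: affine-in-f observation probabilities ------------------------
#
# For every genotype g, p(obs | g, f, D) = A_g + B_g * f, because each read
# carries at most one Bernoulli(f) methylation draw (on a sampled CG allele
# copy). Computing (A, B) once per window makes likelihood evaluation over f
# a cheap vector operation.
#
# obs table columns: base1, base2 (sequenced-strand bases at reference
# positions p and p+1 of the CpG; NA = missing), eps1, eps2, Q, strand
# ("+"/"-"), k1, v1, k2, v2 (terminal coordinates per base).
dinuc_affine <- function(obs, D) {
  n <- nrow(obs)
  if (!all(obs$strand %in% c("+", "-"))) stopf("strand must be '+' or '-'")
  kk <- c(obs$k1, obs$k2)
  if (any(kk >= D$K_max, na.rm = TRUE))
    stopf("observation position k >= profile K_max (%d): profile/pile mismatch",
          D$K_max)
  # per-position error factors err(x | true base b); missing base -> 1
  errs <- function(base, eps) {
    out <- lapply(c(A = "A", C = "C", G = "G", T = "T"), function(b)
      ifelse(is.na(base), 1, ifelse(base == b, 1 - eps, eps / 3)))
    out
  }
  e1 <- errs(obs$base1, obs$eps1)
  e2 <- errs(obs$base2, obs$eps2)
  fwd <- obs$strand == "+"
  # deaminable position: 1 on forward reads, 2 on reverse reads
  kd <- ifelse(fwd, obs$k1, obs$k2)
  vd <- ifelse(fwd, obs$v1, obs$v2)
  have_d <- !is.na(kd)
  d1 <- d0 <- numeric(n)
  d1[have_d] <- deam_rate(D, TRUE, kd[have_d], vd[have_d])
  d0[have_d] <- deam_rate(D, FALSE, kd[have_d], vd[have_d])
  eTd <- ifelse(fwd, e1$T, e2$T)   # error factor for emitted T at deam pos
  eCd <- ifelse(fwd, e1$C, e2$C)
  pd_m <- d1 * eTd + (1 - d1) * eCd   # deaminable C, methylated copy
  pd_u <- d0 * eTd + (1 - d0) * eCd   # deaminable C, unmethylated / non-CpG
  eo_G <- ifelse(fwd, e2$G, e1$G)     # non-deaminable position, true G
  # allele emission probabilities on the sequenced strand:
  #   forward: CG -> (C*, G); TG -> (T, G); CA -> (C*, A)   (* = deaminable)
  #   reverse: CG -> (G, C*); TG -> (A, C*); CA -> (G, T)
  paCG_m <- pd_m * eo_G
  paCG_u <- pd_u * eo_G
  paTG <- ifelse(fwd, e1$T * e2$G, e1$A * pd_u)
  paCA <- ifelse(fwd, pd_u * e2$A, e1$G * e2$T)
  u <- ifelse(is.na(obs$base1), 1, 0.25) * ifelse(is.na(obs$base2), 1, 0.25)
  Q <- obs$Q
  hq <- (1 - Q) * 0.5
  A <- matrix(0, n, 7, dimnames = list(NULL, .GT_NAMES))
  B <- matrix(0, n, 7, dimnames = list(NULL, .GT_NAMES))
  dCG <- paCG_m - paCG_u
  A[, "CG/CG"] <- Q * u + hq * 2 * paCG_u;         B[, "CG/CG"] <- hq * 2 * dCG
  A[, "CG/TG"] <- Q * u + hq * (paCG_u + paTG);    B[, "CG/TG"] <- hq * dCG
  A[, "CG/CA"] <- Q * u + hq * (paCG_u + paCA);    B[, "CG/CA"] <- hq * dCG
  A[, "TG/TG"] <- Q * u + hq * 2 * paTG
  A[, "TG/CA"] <- Q * u + hq * (paTG + paCA)
  A[, "CA/CA"] <- Q * u + hq * 2 * paCA
  A[, "OTHER"] <- u
  list(A = A, B = B)
}

#' Probability of one dinucleotide observation given a genotype
#'
#' The step-2 per-read likelihood term `p(X | g, f, D)`. With probability
#' `Q` the read is mismapped and emits uniformly over the base space;
#' otherwise it samples one of the two allele copies. A CG copy is
#' methylated with probability `f` (an independent Bernoulli per read, since
#' reads are distinct molecules); its strand-deaminable cytosine (position 1
#' for forward-strand reads, position 2 for reverse-strand reads, bases
#' being the sequenced strand's bases at reference positions p/p+1)
#' deaminates C->T at the methylated or unmethylated profile rate. A TG
#' copy is truly T,G; a CA copy's cytosine is a non-CpG cytosine, deaminable
#' at the unmethylated rate. The aggregate OTHER genotype emits uniformly.
#' Missing bases are marginalised (factor 1).
#'
#' @param obs a one-row data.frame (or list) with fields `base1`, `base2`,
#'   `eps1`, `eps2`, `Q`, `strand`, `k1`, `v1`, `k2`, `v2`.
#' @param g genotype: index 1..7 or name among
#'   `CG/CG, CG/TG, CG/CA, TG/TG, TG/CA, CA/CA, OTHER`.
#' @param f methylated fraction in `[0, 1]`.
#' @param D a [deamination_profile()].
#' @return The probability of the observed (possibly partial) base pair.
#' @export
dinucleotide_obs_prob <- function(obs, g, f, D) {
  check_prob(f, "f")
  if (is.character(g)) g <- match(g, .GT_NAMES)
  if (is.na(g) || g < 1 || g > 7) stopf("invalid genotype state")
  obs <- as.data.frame(obs, stringsAsFactors = FALSE)
  if (all(is.na(obs$base1)) && all(is.na(obs$base2)))
    stopf("at least one base must be observed")
  ab <- dinuc_affine(obs, D)
  unname(ab$A[, g] + ab$B[, g] * f)
}

# internal: factory returning a fast log-likelihood function of f for a set
# of piles. piles: data.table with cpg_id grouping plus the obs columns.
make_window_loglik <- function(piles, D, prior) {
  if (nrow(piles) == 0L) return(function(f) 0)
  ab <- dinuc_affine(piles, D)
  grp <- match(piles$cpg_id, unique(piles$cpg_id))
  lp <- log(prior$probs)
  keep <- is.finite(lp)   # genotypes with zero prior cannot contribute
  A <- ab$A[, keep, drop = FALSE]
  B <- ab$B[, keep, drop = FALSE]
  lpk <- lp[keep]
  function(f) {
    M <- log(A + B * f)
    S <- rowsum(M, grp, reorder = FALSE)        # per-pile per-genotype loglik
    S <- sweep(S, 2, lpk, `+`)
    m <- apply(S, 1, max)
    site_ll <- ifelse(is.finite(m),
                      m + log(rowSums(exp(S - m))), -Inf)
    sum(site_ll)
  }
}

#' Window log-likelihood of the methylated fraction
#'
#' Step-2 likelihood: the sum over CpG sites of
#' `log sum_g p(G = g) * prod_reads p(X | g, f, D)`, computed stably in log
#' space. Sites with empty piles contribute 0.
#'
#' @param f methylated fraction in `[0, 1]`.
#' @param piles a pile table as produced by [extract_cpg_piles()]: one row
#'   per dinucleotide observation with a `cpg_id` grouping column.
#' @param D a [deamination_profile()].
#' @param prior a [genotype_prior()].
#' @return The log-likelihood at `f`.
#' @export
window_log_likelihood <- function(f, piles, D, prior = genotype_prior()) {
  check_prob(f, "f")
  ll <- make_window_loglik(piles, D, prior)
  ll(f)
}
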