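# Accuracy evaluation: RMSD/bias of f estimates against simulation truth,
# and a damage-spectrum consistency screen for the simulator.

#' RMSD and bias of methylation estimates
#'
#' Root mean squared deviation `sqrt(mean((f_hat - f_true)^2))` and mean
#' signed bias over non-NA windows. Estimates are joined to truth on
#' `(chrom, start, end)` exactly; a windowing mismatch is an error, not a
#' silent intersection.
#'
#' @param estimates data.frame from [estimate_f_regions()].
#' @param truth data.frame with `chrom`, `start`, `end`, `f_true` (e.g.
#'   built from [truth_f_per_window()]).
#' @return A list: `rmsd`, `bias`, `n` (windows compared), `n_na` (windows
#'   with undefined estimate or truth).
#' @export
evaluate_rmsd <- function(estimates, truth) {
  key_e <- paste(estimates$chrom, estimates$start, estimates$end)
  key_t <- paste(truth$chrom, truth$start, truth$end)
  m <- match(key_e, key_t)
  if (any(is.na(m)) || length(key_e) != length(key_t))
    stopf("estimate and truth windows do not match exactly (%d vs %d rows, %d unmatched)",
          length(key_e), length(key_t), sum(is.na(m)))
  f_true <- truth$f_true[m]
  err <- estimates$f_mle - f_true
  ok <- !is.na(err)
  list(rmsd = sqrt(mean(err[ok]^2)), bias = mean(err[ok]),
       n = sum(ok), n_na = sum(!ok))
}

#' Damage-spectrum consistency screen
#'
#' Recounts C->T conversions in the emitted reads of a simulation, binned by
#' (terminal position `k`, terminus `v`, methylation flag), and compares the
#' observed conversion fraction with the fraction expected from the
#' configured deamination matrices and the sequencing-error rate
#' (`p = d (1 - eps) + (1 - d) eps / 3` plus the mismatch channel). The
#' count is made directly from the BAM and the truth haplotypes,
#' independently of the simulator's internal bookkeeping.
#'
#' @param sim an `adna_sim` object from [simulate_reads()].
#' @param min_n minimum observations for a bin to be reported (default 50).
#' @return A `data.table` with columns `k`, `v`, `meth`, `n`, `n_T`,
#'   `p_obs`, `p_exp`, `se`, `z`.
#' @export
damage_spectrum <- function(sim, min_n = 50L) {
  cfg <- sim$config
  D <- cfg$D_true
  bt <- read_base_table(sim$bam, sim$chrom,
                        filter_settings(min_baseq = 0L, min_mapq = 0L,
                                        min_length = 0L), D$K_max,
                        with_qname = TRUE)
  frag <- sim$truth$fragments
  fi <- match(bt$qname, frag$qname)
  bt[, genome := frag$genome[fi]]
  bt[, hap := frag$hap[fi]]
  hapmat <- rbind(sim$truth$hap1, sim$truth$hap2)
  bt[, hbase := hapmat[cbind(hap, ref_pos)]]
  fwd <- bt$strand == "+"
  # sequenced-strand cytosine slots: haplotype C on forward reads,
  # haplotype G on reverse reads (stored complemented)
  bt <- bt[(fwd & hbase == "C") | (!fwd & hbase == "G")]
  bt[, obs_T := ifelse(strand == "+", base == "T", base == "A")]
  L <- ncol(hapmat)
  sites0 <- sim$truth$sites
  site_fwd <- site_rev <- matrix(0L, 2, L)
  for (h in 1:2) {
    is_cg <- hapmat[h, sites0 + 1L] == "C" & hapmat[h, sites0 + 2L] == "G"
    site_fwd[h, sites0[is_cg] + 1L] <- which(is_cg)
    site_rev[h, sites0[is_cg] + 2L] <- which(is_cg)
  }
  sid <- ifelse(bt$strand == "+", site_fwd[cbind(bt$hap, bt$ref_pos)],
                site_rev[cbind(bt$hap, bt$ref_pos)])
  bt[, meth := sid > 0L & sim$truth$flags[cbind(pmax(sid, 1L), genome)]]
  eps <- phred_to_prob(cfg$baseq)
  agg <- bt[, .(n = .N, n_T = sum(obs_T)), by = .(k, v, meth)]
  agg[, d := deam_rate(D, meth, k, v)]
  agg[, p_exp := d * (1 - eps) + (1 - d) * eps / 3]
  agg[, p_obs := n_T / n]
  agg[, se := sqrt(p_exp * (1 - p_exp) / n)]
  agg[, z := (p_obs - p_exp) / se]
  agg <- agg[n >= min_n]
  data.table::setorder(agg, meth, v, k)
  agg[]
}
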