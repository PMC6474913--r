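# Step 1: maximum-likelihood estimation of the position-specific
# deamination profile from balanced cytosine observations.

#' Model configuration
#'
#' Bundles the tunable model parameters shared across the two estimation
#' steps.
#'
#' @param F_global expected genome-wide fraction of methylated CpGs
#'   (default 0.75, the typical mammalian somatic value). Used in step 1 to
#'   disentangle the methylated and unmethylated deamination rates.
#' @param K_max number of modelled terminal read positions (default 20).
#' @param theta per-allele alternate probability of the genotype prior
#'   (default 0.001).
#' @param min_baseq,min_mapq,min_length filter thresholds, see
#'   [filter_settings()].
#' @return A list of class `model_config`.
#' @export
model_config <- function(F_global = 0.75, K_max = 20L, theta = 0.001,
                         min_baseq = 13L, min_mapq = 25L, min_length = 30L) {
  check_prob(F_global, "F_global")
  if (K_max < 1L) stopf("K_max must be >= 1")
  structure(list(F_global = F_global, K_max = as.integer(K_max),
                 theta = theta, min_baseq = as.integer(min_baseq),
                 min_mapq = as.integer(min_mapq),
                 min_length = as.integer(min_length)),
            class = "model_config")
}

# negative log-likelihood of one (k, v) bin given aggregated counts.
# cnt: data.table with obs, in_cpg, eps, Q, n
bin_nll <- function(par, cnt, F_global) {
  d0 <- par[1]; d1 <- par[2]
  p <- single_base_prob(cnt$obs, d_meth = d1, d_unmeth = d0, F = F_global,
                        in_cpg = cnt$in_cpg, eps = cnt$eps, Q = cnt$Q)
  -sum(cnt$n * log(p))
}

# 2x2 observed-information standard errors by central finite differences
bin_se <- function(par, cnt, F_global, h = 1e-5) {
  # boundary MLEs have no regular observed-information standard error
  if (any(par < 2 * h) || any(par > 1 - 2 * h)) return(c(NA_real_, NA_real_))
  f <- function(x) bin_nll(x, cnt, F_global)
  H <- matrix(NA_real_, 2, 2)
  for (i in 1:2) for (j in 1:2) {
    ei <- ej <- c(0, 0); ei[i] <- h; ej[j] <- h
    H[i, j] <- (f(par + ei + ej) - f(par + ei - ej) -
                f(par - ei + ej) + f(par - ei - ej)) / (4 * h * h)
  }
  se <- tryCatch(sqrt(diag(solve(H))), error = function(e) c(NA_real_, NA_real_))
  if (any(!is.finite(se))) c(NA_real_, NA_real_) else se
}

#' Estimate the position-specific deamination profile (step 1)
#'
#' Maximises the step-1 likelihood over the deamination rates at methylated
#' and unmethylated cytosines. Because every observation touches exactly one
#' (position, terminus) bin, the likelihood factorises over bins and each is
#' maximised independently as a 2-parameter problem in
#' `(d_unmeth, d_meth)`: CpG-context observations contribute through the
#' mixture `F_global * d_meth + (1 - F_global) * d_unmeth` (their
#' methylation state is unknown) and non-CpG observations through
#' `d_unmeth` alone. Observations are aggregated by
#' `(obs, in_cpg, eps, Q)` within each bin, so runtime is independent of
#' coverage. Standard errors come from the observed Fisher information
#' (central finite differences).
#'
#' @param observations a (preferably context-balanced, see
#'   [balance_contexts()]) table from [extract_cytosine_observations()].
#' @param config a [model_config()].
#' @param drop_snp_sites if TRUE (default), cytosine sites where more than
#'   `max_other_frac` of observations are neither C nor T are dropped before
#'   estimation; such sites are likely A/G polymorphisms, which the step-1
#'   model does not represent.
#' @param max_other_frac threshold for the SNP-site guard (default 0.2).
#' @return A [deamination_profile()] with rates, standard errors and per-bin
#'   observation counts. Bins without observations get rate 0 and count 0.
#' @export
estimate_deamination <- function(observations, config = model_config(),
                                 drop_snp_sites = TRUE,
                                 max_other_frac = 0.2) {
  obs <- data.table::as.data.table(observations)
  if (nrow(obs) == 0L) stopf("no cytosine observations supplied")
  if (drop_snp_sites) {
    bad <- obs[, .(frac = mean(obs == "OTHER")), by = site][frac > max_other_frac]
    if (nrow(bad)) obs <- obs[!site %in% bad$site]
    if (nrow(obs) == 0L) stopf("all sites removed by the SNP-site guard")
  }
  K <- config$K_max
  cnts <- obs[, .(n = .N), by = .(k, v, obs, in_cpg, eps, Q)]
  shape <- function() matrix(0, K, 2, dimnames = list(NULL, c("5p", "3p")))
  r0 <- shape(); r1 <- shape(); s0 <- shape(); s1 <- shape(); nn <- shape()
  s0[] <- NA_real_; s1[] <- NA_real_
  for (vv in c("5p", "3p")) for (kk in 0:(K - 1)) {
    cnt <- cnts[k == kk & v == vv]
    if (nrow(cnt) == 0L) next
    nn[kk + 1L, vv] <- sum(cnt$n)
    if (all(cnt$Q >= 0.99)) {
      warnf("bin (k=%d, %s): all observations near-certainly mismapped; flat likelihood, rates set to 0",
            kk, vv)
      next
    }
    fit <- optim(c(0.01, 0.1), bin_nll, cnt = cnt, F_global = config$F_global,
                 method = "L-BFGS-B", lower = 1e-8, upper = 1 - 1e-8,
                 control = list(factr = 1e7))
    r0[kk + 1L, vv] <- fit$par[1]
    r1[kk + 1L, vv] <- fit$par[2]
    se <- bin_se(fit$par, cnt, config$F_global)
    s0[kk + 1L, vv] <- se[1]
    s1[kk + 1L, vv] <- se[2]
  }
  deamination_profile(rate_unmeth = r0, rate_meth = r1,
                      se_unmeth = s0, se_meth = s1, n_obs = nn,
                      F_global = config$F_global)
}
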