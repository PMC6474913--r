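# Step 2: windowed maximum-likelihood estimation of f, the fraction of
# methylated CpG copies, with a 95% profile-likelihood confidence interval.

.CHI2_95 <- 3.841459  # qchisq(0.95, df = 1)

#' Build sliding windows over CpG sites
#'
#' Windows are defined by a number of consecutive CpG sites (not base
#' pairs), advancing by `step` sites. A final partial window is emitted only
#' if it holds at least `max(5, n_cpg / 5)` sites, and is flagged. Window
#' coordinates span the first site's C to the last site's G (half-open).
#'
#' @param sites ordered 0-based coordinates of CpG C positions.
#' @param n_cpg window size in CpG sites (default 50).
#' @param step advance in sites (default `n_cpg`, i.e. non-overlapping).
#' @param chrom chromosome label for the output.
#' @return A data.frame with `chrom`, `start`, `end` (0-based half-open),
#'   `first`, `last` (site indices), `n_cpg`, `partial`.
#' @export
make_windows <- function(sites, n_cpg = 50L, step = n_cpg, chrom = "chr") {
  if (n_cpg < 1L) stopf("n_cpg must be >= 1")
  if (step < 1L || step > n_cpg) stopf("step must be in [1, n_cpg]")
  n <- length(sites)
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), first = integer(), last = integer(),
                      n_cpg = integer(), partial = logical())
  if (n == 0L) return(empty)
  if (is.unsorted(sites)) stopf("sites must be sorted")
  floor_n <- max(5, n_cpg / 5)
  starts <- seq.int(1L, n, by = step)
  rows <- lapply(starts, function(s) {
    e <- min(s + n_cpg - 1L, n)
    len <- e - s + 1L
    partial <- len < n_cpg
    if (partial && len < floor_n) return(NULL)
    data.frame(chrom = chrom, start = sites[s], end = sites[e] + 2L,
               first = s, last = e, n_cpg = len, partial = partial)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

# assemble one estimate record
.f_record <- function(chrom, start, end, n_cpg, n_obs, f = NA_real_,
                      lo = NA_real_, hi = NA_real_, ll = NA_real_,
                      flag = "ok") {
  data.frame(chrom = chrom, start = start, end = end, n_cpg = n_cpg,
             n_obs = n_obs, f_mle = f, ci_low = lo, ci_high = hi,
             loglik = ll, flag = flag, stringsAsFactors = FALSE)
}

#' Estimate the methylated fraction in one window (step 2)
#'
#' Maximises the window log-likelihood over `f` in `[0, 1]` by a dense
#' 101-point grid followed by bounded scalar refinement (tolerance 1e-6); a
#' grid pass first guards against multimodality. The 95% confidence interval
#' is the profile-likelihood set `{f : 2 (l(f_hat) - l(f)) <= 3.841}`, found
#' by bisection on each side and clipped to `[0, 1]`. Windows with no
#' informative observations return `NA` with a reason flag (`"no_data"` or
#' `"flat_likelihood"`).
#'
#' @param piles pile table for one window (see [extract_cpg_piles()]).
#' @param D a [deamination_profile()] (estimated in step 1 or known).
#' @param prior a [genotype_prior()].
#' @param sites optional 0-based CpG site coordinates in the window,
#'   including uncovered sites (used for `n_cpg` and coordinates).
#' @param chrom,start,end optional window annotation (derived from the data
#'   when omitted).
#' @param partial logical; marks a partial trailing window.
#' @return A one-row data.frame: `chrom`, `start`, `end`, `n_cpg`, `n_obs`,
#'   `f_mle`, `ci_low`, `ci_high`, `loglik`, `flag`.
#' @export
estimate_f <- function(piles, D, prior = genotype_prior(), sites = NULL,
                       chrom = NULL, start = NULL, end = NULL,
                       partial = FALSE) {
  piles <- data.table::as.data.table(piles)
  if (is.null(sites)) sites <- attr(piles, "sites")
  n_obs <- nrow(piles)
  n_cpg <- if (!is.null(sites)) length(sites)
           else length(unique(piles$cpg_id))
  if (is.null(chrom)) chrom <- if (n_obs) piles$chrom[1] else NA_character_
  if (is.null(start))
    start <- if (!is.null(sites) && length(sites)) min(sites)
             else if (n_obs) min(piles$cpg_start) else NA_integer_
  if (is.null(end))
    end <- if (!is.null(sites) && length(sites)) max(sites) + 2L
           else if (n_obs) max(piles$cpg_start) + 2L else NA_integer_
  base_flag <- if (partial) "partial" else "ok"
  if (n_obs == 0L)
    return(.f_record(chrom, start, end, n_cpg, 0L, flag = "no_data"))

  ll <- make_window_loglik(piles, D, prior)
  grid <- seq(0, 1, length.out = 101L)
  llg <- vapply(grid, ll, numeric(1))
  fin <- is.finite(llg)
  if (!any(fin) || (max(llg[fin]) - min(llg[fin])) < 1e-8)
    return(.f_record(chrom, start, end, n_cpg, n_obs,
                     flag = "flat_likelihood"))
  i <- which.max(llg)
  lo_b <- grid[max(1L, i - 1L)]
  hi_b <- grid[min(length(grid), i + 1L)]
  opt <- optimize(ll, lower = lo_b, upper = hi_b, maximum = TRUE,
                  tol = 1e-6)
  if (opt$objective >= llg[i]) {
    f_hat <- opt$maximum; ll_hat <- opt$objective
  } else {
    f_hat <- grid[i]; ll_hat <- llg[i]
  }
  cut <- ll_hat - .CHI2_95 / 2
  # bisection towards each boundary; -Inf handled as "below the cut"
  below <- function(f) {
    v <- ll(f)
    !is.finite(v) || v < cut
  }
  bisect <- function(lo, hi, lo_below) {
    # invariant: one end below cut, other end at/above
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      if (below(mid) == lo_below) lo <- mid else hi <- mid
      if (abs(hi - lo) < 1e-7) break
    }
    (lo + hi) / 2
  }
  ci_lo <- if (!below(0)) 0 else bisect(0, f_hat, lo_below = TRUE)
  ci_hi <- if (!below(1)) 1 else bisect(1, f_hat, lo_below = TRUE)
  if (ci_hi < ci_lo) { tmp <- ci_lo; ci_lo <- ci_hi; ci_hi <- tmp }
  ci_lo <- min(ci_lo, f_hat); ci_hi <- max(ci_hi, f_hat)
  .f_record(chrom, start, end, n_cpg, n_obs, f = f_hat,
            lo = max(0, ci_lo), hi = min(1, ci_hi), ll = ll_hat,
            flag = base_flag)
}

#' Estimate f across windows or BED regions
#'
#' Maps [estimate_f()] over a set of windows (from [make_windows()]) or
#' user-supplied regions, producing one record per window including NA
#' records for windows without usable data. Output is sorted by coordinate.
#'
#' @param piles full pile table for the chromosome/regions of interest.
#' @param windows a data.frame with `chrom`, `start`, `end` (0-based
#'   half-open) and optionally `partial`; or a BED file path. User regions
#'   must be non-overlapping and well-formed (checked).
#' @param D a [deamination_profile()].
#' @param prior a [genotype_prior()].
#' @param validate if TRUE, reject malformed or overlapping regions (the
#'   default for BED input; sliding windows from [make_windows()] may
#'   legitimately overlap when `step < n_cpg`).
#' @return A data.frame with one row per window, columns as [estimate_f()].
#' @export
estimate_f_regions <- function(piles, windows, D, prior = genotype_prior(),
                               validate = is.character(windows)) {
  piles <- data.table::as.data.table(piles)
  sites <- attr(piles, "sites")
  if (is.character(windows)) {
    gr <- as_regions_granges(windows, chrom = NULL, check_overlap = validate)
    windows <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                          start = GenomicRanges::start(gr) - 1L,
                          end = GenomicRanges::end(gr))
  } else if (validate) {
    if (any(windows$end <= windows$start))
      stopf("malformed region(s) with end <= start at row(s) %s",
            paste(which(windows$end <= windows$start), collapse = ", "))
    as_regions_granges(windows, chrom = windows$chrom[1],
                       check_overlap = TRUE)
  }
  if (!"partial" %in% names(windows)) windows$partial <- FALSE
  out <- lapply(seq_len(nrow(windows)), function(i) {
    w <- windows[i, ]
    sub <- piles[cpg_start >= w$start & cpg_start < w$end]
    wsites <- if (!is.null(sites)) sites[sites >= w$start & sites < w$end]
    estimate_f(sub, D, prior, sites = wsites, chrom = w$chrom,
               start = w$start, end = w$end, partial = isTRUE(w$partial))
  })
  out <- do.call(rbind, out)
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Write methylation estimates as a BED-like TSV
#'
#' Tab-separated, 0-based half-open, columns `chrom`, `start`, `end`,
#' `n_cpg`, `n_obs`, `f_mle`, `ci_low`, `ci_high`, `loglik`, `flag`;
#' undefined values are the literal `NA`.
#'
#' @param estimates data.frame from [estimate_f_regions()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_estimates <- function(estimates, path) {
  write.table(estimates, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_estimates
#' @export
read_estimates <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
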