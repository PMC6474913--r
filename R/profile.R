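#' Position-specific deamination profile
#'
#' Container for post-mortem C-to-T deamination rates along a DNA fragment,
#' indexed by methylation state (methylated/unmethylated cytosine), read
#' position `k` (0-based distance from the assigned terminus) and terminus
#' (`"5p"` or `"3p"`). Methylated cytosines deaminate faster than
#' unmethylated ones; both rates decay from the fragment ends towards a
#' plateau in the double-stranded interior, which is why rates are modelled
#' per terminal position up to `K_max` and clamped beyond.
#'
#' @param rate_unmeth,rate_meth numeric `K_max x 2` matrices of deamination
#'   probabilities, columns `"5p"` and `"3p"`, row `i` = position `k = i - 1`.
#' @param se_unmeth,se_meth optional matrices of matching shape with standard
#'   errors of the estimates.
#' @param n_obs optional `K_max x 2` matrix of observation counts per
#'   position/terminus bin.
#' @param F_global assumed genome-wide fraction of methylated CpGs used when
#'   the profile was estimated (default 0.75, typical of mammalian somatic
#'   tissue).
#' @return An object of class `deam_profile`.
#' @export
deamination_profile <- function(rate_unmeth, rate_meth,
                                se_unmeth = NULL, se_meth = NULL,
                                n_obs = NULL, F_global = 0.75) {
  rate_unmeth <- as.matrix(rate_unmeth)
  rate_meth <- as.matrix(rate_meth)
  if (!identical(dim(rate_unmeth), dim(rate_meth)))
    stopf("rate matrices must have identical dimensions")
  if (ncol(rate_unmeth) != 2L)
    stopf("rate matrices must have 2 columns (5p, 3p)")
  if (nrow(rate_unmeth) < 1L) stopf("K_max must be >= 1")
  check_prob(rate_unmeth, "rate_unmeth")
  check_prob(rate_meth, "rate_meth")
  check_prob(F_global, "F_global")
  dimnames(rate_unmeth) <- dimnames(rate_meth) <-
    list(NULL, c("5p", "3p"))
  shape <- function(m) {
    if (is.null(m)) return(NULL)
    m <- as.matrix(m)
    if (!identical(dim(m), dim(rate_unmeth)))
      stopf("auxiliary matrices must match the rate matrix shape")
    dimnames(m) <- list(NULL, c("5p", "3p"))
    m
  }
  structure(list(
    K_max = nrow(rate_unmeth),
    rate_unmeth = rate_unmeth,
    rate_meth = rate_meth,
    se_unmeth = shape(se_unmeth),
    se_meth = shape(se_meth),
    n_obs = shape(n_obs),
    F_global = F_global
  ), class = "deam_profile")
}

#' @export
print.deam_profile <- function(x, ...) {
  cat(sprintf("Deamination profile: K_max = %d, F_global = %.3f\n",
              x$K_max, x$F_global))
  cat(sprintf("  5' k=0: unmeth %.4f, meth %.4f | 3' k=0: unmeth %.4f, meth %.4f\n",
              x$rate_unmeth[1, "5p"], x$rate_meth[1, "5p"],
              x$rate_unmeth[1, "3p"], x$rate_meth[1, "3p"]))
  if (!is.null(x$n_obs))
    cat(sprintf("  total observations: %.0f\n", sum(x$n_obs)))
  invisible(x)
}

# vectorized rate lookup; k 0-based (clamped), v in c("5p","3p")
deam_rate <- function(profile, meth, k, v) {
  n <- max(length(meth), length(k), length(v))
  meth <- rep_len(meth, n)
  k <- rep_len(pmin(pmax(as.integer(k), 0L), profile$K_max - 1L), n)
  j <- rep_len(ifelse(v == "5p", 1L, 2L), n)
  idx <- cbind(k + 1L, j)
  out <- profile$rate_unmeth[idx]
  out[meth] <- profile$rate_meth[idx][meth]
  out
}

#' Built-in true deamination profiles for simulation
#'
#' Three decay-shaped profiles spanning the damage ranges and library
#' chemistries commonly seen in ancient samples. Double-stranded-library
#' profiles (`ds_*`) concentrate C-to-T damage at the 5' terminus (the
#' complementary-strand G-to-A signal at 3' ends of mapped reads emerges
#' automatically from strand-uniform fragment sampling in the simulator);
#' the single-stranded-library profile (`ss_mid`) shows elevated C-to-T at
#' both termini. In all presets the methylated rate exceeds the
#' unmethylated one, the signal this package exploits.
#'
#' @param name one of `"ds_high"`, `"ds_mid"`, `"ss_low"`.
#' @param K_max number of modelled terminal positions (default 20).
#' @return A [deamination_profile()].
#' @export
deamination_preset <- function(name = c("ds_high", "ds_mid", "ss_low"),
                               K_max = 20L) {
  name <- match.arg(name)
  k <- 0:(K_max - 1)
  decay <- function(a, lambda, c0) a * exp(-lambda * k) + c0
  mk <- function(m5, u5, m3, u3)
    deamination_profile(rate_unmeth = cbind(`5p` = u5, `3p` = u3),
                        rate_meth = cbind(`5p` = m5, `3p` = m3))
  switch(name,
    ds_high = mk(
      m5 = decay(0.40, 0.40, 0.020), u5 = decay(0.15, 0.40, 0.010),
      m3 = decay(0.06, 0.50, 0.012), u3 = decay(0.02, 0.50, 0.006)),
    ds_mid = mk(
      m5 = decay(0.20, 0.35, 0.015), u5 = decay(0.08, 0.35, 0.008),
      m3 = decay(0.03, 0.45, 0.010), u3 = decay(0.012, 0.45, 0.005)),
    ss_low = mk(
      m5 = decay(0.10, 0.30, 0.010), u5 = decay(0.035, 0.30, 0.005),
      m3 = decay(0.10, 0.30, 0.010), u3 = decay(0.035, 0.30, 0.005))
  )
}

#' Write / read a deamination profile as TSV
#'
#' Plain-text persistence for the two-step workflow: step 1 writes the
#' estimated profile, step 2 reads it back. Columns: terminus (`5p`/`3p`),
#' position (0-based), rate_unmeth, rate_meth, se_unmeth, se_meth, n_obs.
#' A `#` header line carries `K_max` and `F_global`.
#'
#' @param profile a [deamination_profile()].
#' @param path file path.
#' @return `read_profile` returns a `deam_profile`; `write_profile` returns
#'   `path` invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "deam_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#K_max=%d\tF_global=%.10g", profile$K_max,
                     profile$F_global), con)
  grab <- function(m, v) if (is.null(m)) rep(NA_real_, profile$K_max) else m[, v]
  df <- do.call(rbind, lapply(c("5p", "3p"), function(v) {
    data.frame(terminus = v, position = 0:(profile$K_max - 1),
               rate_unmeth = profile$rate_unmeth[, v],
               rate_meth = profile$rate_meth[, v],
               se_unmeth = grab(profile$se_unmeth, v),
               se_meth = grab(profile$se_meth, v),
               n_obs = grab(profile$n_obs, v))
  }))
  writeLines(paste(colnames(df), collapse = "\t"), con)
  write.table(format(df, digits = 12, scientific = FALSE, trim = TRUE),
              con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "#"))
    stopf("profile file '%s': missing '#K_max=...' header (line 1)", path)
  hdr <- strsplit(sub("^#", "", lines[1]), "\t")[[1]]
  kv <- strsplit(hdr, "=")
  vals <- setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  K_max <- as.integer(vals[["K_max"]])
  F_global <- as.numeric(vals[["F_global"]])
  df <- read.table(text = lines[-1], header = TRUE, sep = "\t",
                   na.strings = c("NA", ""))
  need <- c("terminus", "position", "rate_unmeth", "rate_meth")
  if (!all(need %in% names(df)))
    stopf("profile file '%s': missing columns %s", path,
          paste(setdiff(need, names(df)), collapse = ", "))
  if (nrow(df) != 2L * K_max)
    stopf("profile file '%s': expected %d rows, found %d", path,
          2L * K_max, nrow(df))
  bad <- which(df$rate_unmeth < 0 | df$rate_unmeth > 1 |
               df$rate_meth < 0 | df$rate_meth > 1)
  if (length(bad))
    stopf("profile file '%s': rate outside [0,1] at data line %d", path,
          bad[1])
  pull <- function(col) {
    m <- matrix(NA_real_, K_max, 2, dimnames = list(NULL, c("5p", "3p")))
    for (v in c("5p", "3p")) {
      sub <- df[df$terminus == v, ]
      m[sub$position + 1L, v] <- sub[[col]]
    }
    if (all(is.na(m))) NULL else m
  }
  deamination_profile(rate_unmeth = pull("rate_unmeth"),
                      rate_meth = pull("rate_meth"),
                      se_unmeth = pull("se_unmeth"),
                      se_meth = pull("se_meth"),
                      n_obs = pull("n_obs"),
                      F_global = F_global)
}
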