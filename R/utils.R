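# Internal helpers shared across modules.

#' @import data.table
#' @importFrom stats optim optimize rbinom rlnorm runif setNames uniroot
#' @importFrom utils packageVersion read.table write.table
NULL

# complement lookup covering ambiguity codes we may meet; N stays N
.COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

comp_base <- function(x) {
  out <- .COMP[x]
  out[is.na(out)] <- "N"
  unname(out)
}

revcomp_chars <- function(x) rev(comp_base(x))

# Phred score -> error probability
phred_to_prob <- function(q) 10^(-q / 10)

# mapping quality -> mismap probability, capped away from certainty
mapq_to_prob <- function(mapq, cap = 0.99) pmin(phred_to_prob(mapq), cap)

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Evaluate an expression under a temporary RNG state seeded with `seed`;
# the caller's RNG stream is untouched. seed = NULL uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

check_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stopf("'%s' must be a probability in [0, 1]", name)
  invisible(x)
}

# split one DNA string into a character vector of single bases
dna_chars <- function(x) {
  if (methods::is(x, "DNAString") || methods::is(x, "DNAStringSet"))
    x <- as.character(x)
  if (length(x) == 1L && nchar(x) > 1L) strsplit(x, "", fixed = TRUE)[[1]]
  else as.character(x)
}
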