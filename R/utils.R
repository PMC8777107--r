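#' Round half-up to a fixed number of decimals
#'
#' Reporting-boundary rounding for percentages. Base `round()` rounds half to
#' even; published concordance/frequency tables round half away from zero, so
#' 20.685 must print as 20.69.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 2).
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

# log-sum-exp over a numeric vector; tolerates -Inf entries
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# integer draws from a normal(mean, sd) truncated (by rejection) to [lo, hi]
rtruncnorm_int <- function(n, mean, sd, lo, hi) {
  if (lo > hi) stop("truncation range is empty")
  out <- integer(0)
  while (length(out) < n) {
    draw <- as.integer(round(stats::rnorm(n - length(out), mean, sd)))
    out <- c(out, draw[draw >= lo & draw <= hi])
  }
  out
}

# n random molecular barcodes of length `len` over {A,C,G,T}
random_barcodes <- function(n, len = 7L) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE),
              nrow = n, ncol = len)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

stop_with <- function(class, msg) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
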