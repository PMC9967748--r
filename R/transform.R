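#' Centered log-ratio (Aitchison) transformation
#'
#' Maps read counts to the unconstrained abundance scale used by every
#' downstream statistic. For sample \eqn{s} and taxon \eqn{t},
#' \deqn{y_{ts} = \log(c_{ts} + pc) - \frac{1}{T}\sum_{t'} \log(c_{t's} + pc)}
#' i.e. the log count relative to the geometric mean of its sample
#' (composition). Each transformed column sums to zero; on strictly positive
#' data with `pseudocount = 0` the transform is exactly invariant to
#' per-sample scaling (sequencing depth).
#'
#' @param x a [count_table] or a numeric matrix (taxa x samples).
#' @param pseudocount non-negative value added to every count before taking
#'   logs. Must be positive unless all counts are strictly positive.
#' @param base logarithm base (natural log by default).
#' @return A numeric matrix of class `abundance_table` with the same
#'   dimnames as the input and attribute `pseudocount`.
#' @examples
#' ct <- count_table(matrix(c(1L, 3L), 2, 1, dimnames = list(c("a", "b"), "s1")))
#' clr_transform(ct)  # -log(2)/2, +log(2)/2
#' @export
clr_transform <- function(x, pseudocount = 1, base = exp(1)) {
  m <- if (inherits(x, "count_table")) x$counts else as.matrix(x)
  stopifnot(is.numeric(pseudocount), length(pseudocount) == 1L, pseudocount >= 0)
  if (pseudocount == 0 && any(m == 0)) {
    stop("pseudocount = 0 requires strictly positive counts")
  }
  lm_ <- log(m + pseudocount, base = base)
  out <- sweep(lm_, 2L, colMeans(lm_), "-")
  structure(out, pseudocount = pseudocount, class = c("abundance_table", "matrix", "array"))
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table (CLR): %d taxa x %d samples, pseudocount %g\n",
              nrow(x), ncol(x), attr(x, "pseudocount")))
  invisible(x)
}
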