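#' Adjust p-values for multiple testing
#'
#' Family-wise error rate control via Bonferroni or Holm's step-down
#' procedure, false discovery rate control via Benjamini-Hochberg, or no
#' adjustment. The number of tests `m` is the full vector length, including
#' genes with p = 1. Computation is delegated to [stats::p.adjust()]; this
#' wrapper fixes the method vocabulary used across the package and
#' validates its input.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param method One of `"holm"`, `"bonferroni"`, `"bh"`, `"none"`.
#' @return Adjusted p-values, same length and order as `p`.
#' @examples
#' adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "holm") # 0.04 0.06 0.06 0.06
#' @export
adjust_pvalues <- function(p, method = c("holm", "bonferroni", "bh", "none")) {
  method <- match.arg(tolower(method[1L]),
                      c("holm", "bonferroni", "bh", "none"))
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  switch(method,
         none = as.numeric(p),
         bh = stats::p.adjust(p, method = "BH"),
         stats::p.adjust(p, method = method))
}
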