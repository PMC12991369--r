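# The exact ConNIS probability model. Under the null of non-essentiality,
# h insertion sites fall uniformly (without replacement) among the b
# positions of a gene; L is the length of a maximal insertion-free run.
# Its pmf is
#   P(L = i) = C(b - i - 1, b - h - i) / C(b - 1, b - h - 1),
# supported on 1 <= i <= b - h. The upper tail telescopes through the
# hockey-stick identity to
#   P(L >= l) = C(b - l, h) / C(b - 1, h),
# which is the form evaluated here (in log space, so b up to 1e7 is safe).

#' Probability mass function of the longest insertion-free run
#'
#' Distribution of the length of a maximal insertion-free run in a gene of
#' `b` bp carrying `h_hat` uniformly placed insertion sites. Values of `i`
#' outside the support `1..(b - h_hat)` return 0.
#'
#' @param i Run length(s), vectorized.
#' @param b Gene length in bp.
#' @param h_hat Number of insertion sites, `1 <= h_hat < b`.
#' @return Probabilities, same length as `i`.
#' @examples
#' gap_pmf(1:3, b = 5, h_hat = 2) # 1/2, 1/3, 1/6
#' @export
gap_pmf <- function(i, b, h_hat) {
  if (length(b) != 1L || length(h_hat) != 1L)
    stop("b and h_hat must be scalars")
  if (h_hat < 1 || h_hat >= b)
    stop("h_hat must satisfy 1 <= h_hat < b")
  p <- numeric(length(i))
  ok <- i >= 1 & i <= b - h_hat & i == floor(i)
  p[ok] <- exp(lchoose(b - i[ok] - 1, b - h_hat - i[ok]) -
                 lchoose(b - 1, b - h_hat - 1))
  p
}

#' ConNIS tail probability of an insertion-free run
#'
#' Probability of observing an insertion-free run of at least `l` bp in a
#' gene of length `b` expected to carry `h_hat` insertion sites, with the
#' expectation down-weighted by `w` to `h_eff = round(h_hat * w)` (ties
#' half-up) so that genes in low-density genomic regions are harder to call
#' essential. Degenerate cases: `l <= 1` or `h_eff = 0` give p = 1; an
#' observed run longer than the support maximum `b - h_eff` gives exactly 0;
#' `h_eff >= b` lies outside the model and gives 0 with a warning.
#'
#' @param l Observed longest run(s), `0 <= l <= b`.
#' @param b Gene length(s) in bp.
#' @param h_hat Expected insertion-site count(s) before weighting.
#' @param w Weight in `(0, 1]` applied to `h_hat`.
#' @return p-values in `[0, 1]`; vectorized over `l`, `b`, `h_hat`.
#' @examples
#' connis_tail(2, 5, 2)          # 0.5
#' connis_tail(5, 10, 3)         # 10/84
#' connis_tail(5, 10, 3, w = .5) # 10/36
#' @export
connis_tail <- function(l, b, h_hat, w = 1) {
  if (length(w) != 1L || is.na(w) || w <= 0 || w > 1)
    stop("w must be a single value in (0, 1]")
  n <- max(length(l), length(b), length(h_hat))
  l <- rep_len(as.numeric(l), n)
  b <- rep_len(as.numeric(b), n)
  h_hat <- rep_len(as.numeric(h_hat), n)
  if (any(l < 0 | l > b)) stop("l must satisfy 0 <= l <= b")
  if (any(h_hat < 0)) stop("h_hat must be >= 0")
  h_eff <- round_half_up(h_hat * w)
  p <- numeric(n)
  over <- h_eff >= b
  if (any(over))
    warning("weighted insertion density >= 1 for ", sum(over),
            " gene(s); tail probability set to 0")
  ok <- !over & h_eff >= 1 & l > 1
  p[ok] <- exp(lchoose(b[ok] - l[ok], h_eff[ok]) -
                 lchoose(b[ok] - 1, h_eff[ok]))
  p[!over & (h_eff < 1 | l <= 1)] <- 1
  pmin(pmax(p, 0), 1)
}

#' Call essential genes with ConNIS
#'
#' Computes per-gene ConNIS tail probabilities from the gene summaries,
#' adjusts them for multiple testing, and labels genes essential at level
#' `alpha`. The expected insertion-site count of gene `j` is
#' `round(eff_length_j * theta)` with `theta` the genome-wide insertion
#' density (half-up rounding), matched to the same truncated interval as the
#' observed run `l_j`.
#'
#' @param genes Gene table, see [gene_set()]; ignored when `summary` is
#'   given.
#' @param iss An [insertion_set()].
#' @param w Weight in `(0, 1]` for the insertion density.
#' @param alpha Significance level in `(0, 1)`.
#' @param correction Multiple-testing method, see [adjust_pvalues()].
#' @param trunc_frac Distal truncation fraction, see [truncate_genes()].
#' @param theta Genome-wide insertion density; defaults to
#'   [genome_density()] of `iss` (computed from the full, read-filtered set,
#'   never per truncated gene).
#' @param summary Optional precomputed [summarize_genes()] table.
#' @return A `data.frame` (one row per gene): `gene_id`, `l`, `k`,
#'   `eff_length`, `h_hat`, `h_eff`, `p_value`, `p_adjusted`, `essential`,
#'   `label`, plus `method` and `tuning` bookkeeping columns.
#' @examples
#' iss <- insertion_set(51:60, genome_length = 100)
#' genes <- gene_set(c("g1", "g2"), c(1, 51), c(50, 60))
#' call_connis(genes, iss, alpha = 0.05, correction = "bonferroni")
#' @export
call_connis <- function(genes, iss, w = 1, alpha = 0.05,
                        correction = "holm", trunc_frac = 0,
                        theta = NULL, summary = NULL) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  s <- summary %||% summarize_genes(genes, iss, trunc_frac)
  theta <- theta %||% genome_density(iss)
  h_hat <- round_half_up(s$eff_length * theta)
  if (theta == 0) {
    warning("insertion density is 0; all ConNIS p-values are 1")
    p <- rep(1, nrow(s))
  } else {
    p <- connis_tail(s$l, s$eff_length, h_hat, w)
  }
  method_result(s, method = "connis", tuning = w, p = p,
                alpha = alpha, correction = correction,
                extra = data.frame(h_hat = h_hat,
                                   h_eff = round_half_up(h_hat * w)))
}

# Shared assembly of the per-method result table: adjusts p-values, applies
# the essentiality cut, and keeps the summary statistics a reader needs to
# audit a call.
method_result <- function(s, method, tuning, p, alpha, correction,
                          extra = NULL) {
  adj <- adjust_pvalues(p, correction)
  out <- data.frame(gene_id = s$gene_id, l = s$l, k = s$k,
                    eff_length = s$eff_length,
                    stringsAsFactors = FALSE)
  if (!is.null(extra)) out <- cbind(out, extra)
  out$p_value <- p
  out$p_adjusted <- adj
  out$essential <- adj <= alpha
  out$label <- ifelse(out$essential, "essential", "non-essential")
  out$method <- method
  out$tuning <- tuning
  out
}
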