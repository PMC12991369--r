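# Labeling-instability criterion for data-driven tuning. Gene labels are
# recomputed on m subsamples of the observed insertion sites; a candidate
# tuning value is scored by the average Bernoulli variance of the per-gene
# labeling probability, normalized by the number of genes ever labeled
# essential. Stable labeling (phi near 0) marks a well-supported tuning
# value; phi = 0.25 is coin-flip instability.

#' Subsample an insertion-site set
#'
#' Draws `floor(h * fraction)` distinct insertion positions uniformly
#' without replacement from the `h` observed sites; read counts travel with
#' their positions. The genome length is unchanged, so the subsample's
#' density is `h_sub / b` and per-gene expected counts downstream are
#' `round(eff_length * h_sub / b)`.
#'
#' @param iss An [insertion_set()].
#' @param fraction Share of sites per subsample, in `(0, 1)`.
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used.
#' @return An [insertion_set()] with `floor(h * fraction)` sites.
#' @export
subsample_insertions <- function(iss, fraction = 0.5, seed = NULL) {
  stopifnot(inherits(iss, "insertion_set"))
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  h <- length(iss$pos)
  n_sub <- floor(h * fraction)
  if (n_sub < 1) stop("fraction * h < 1: subsample would be empty")
  if (!is.null(seed)) set.seed(seed)
  idx <- sort(sample.int(h, n_sub))
  structure(list(pos = iss$pos[idx], count = iss$count[idx],
                 genome_length = iss$genome_length),
            class = "insertion_set")
}

# One derived RNG stream per subsample, so results do not depend on the
# order in which subsamples are evaluated.
subsample_seeds <- function(seed, m) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, m)
}

#' Essentiality label matrix across subsamples
#'
#' Applies one labeling method at one tuning value to each of `m`
#' subsamples and records the binary essential / non-essential call per
#' gene and subsample. The same multiple-testing correction used for final
#' calls is applied within every subsample.
#'
#' @inheritParams call_method
#' @param m Number of subsamples (>= 2).
#' @param fraction Share of insertion sites per subsample.
#' @param seed Master seed; subsample `d` uses a stream seed derived from
#'   it.
#' @return A logical matrix, genes in rows (named by `gene_id`), subsamples
#'   in columns.
#' @export
label_matrix <- function(genes, iss, method = "connis", tuning = 1,
                         m = 500, fraction = 0.5, alpha = 0.05,
                         correction = "holm", trunc_frac = 0, seed = 1) {
  if (m < 2) stop("m must be >= 2")
  seeds <- subsample_seeds(seed, m)
  L <- matrix(FALSE, nrow(genes), m, dimnames = list(genes$gene_id, NULL))
  for (d in seq_len(m)) {
    set.seed(seeds[d])
    iss_d <- subsample_insertions(iss, fraction)
    res <- call_method(genes, iss_d, method = method, tuning = tuning,
                       alpha = alpha, correction = correction,
                       trunc_frac = trunc_frac)
    L[, d] <- res$essential
  }
  L
}

#' Labeling instability of a label matrix
#'
#' For a genes-by-subsamples binary label matrix, estimates the per-gene
#' probability `pi_hat` of an essential call, counts the genes ever labeled
#' essential (`q`), and returns the instability
#' `phi = sum(pi_hat * (1 - pi_hat)) / q`, the mean Bernoulli variance over
#' counted genes. `phi = 0` means every gene is labeled consistently;
#' `phi = 0.25` is the maximum, reached when every counted gene is labeled
#' essential in exactly half of the subsamples. When no gene is ever
#' labeled essential (`q = 0`) the criterion carries no information and is
#' reported as 0 with `degenerate = TRUE`.
#'
#' @param L Logical or 0/1 matrix, genes in rows, subsamples (>= 2) in
#'   columns.
#' @return A list with `phi`, `q`, `pi_hat` and `degenerate`.
#' @examples
#' L <- rbind(c(1, 1, 1, 1), c(1, 0, 0, 0), c(0, 0, 0, 0))
#' instability_phi(L)$phi # (0 + 0.1875) / 2 = 0.09375
#' @export
instability_phi <- function(L) {
  L <- as.matrix(L)
  if (ncol(L) < 2) stop("need at least 2 subsamples")
  if (anyNA(L) || !all(L %in% c(0, 1)))
    stop("label matrix must be binary")
  pi_hat <- rowMeans(L)
  q <- sum(pi_hat > 0)
  phi <- if (q == 0) 0 else sum(pi_hat * (1 - pi_hat)) / q
  list(phi = phi, q = q, pi_hat = pi_hat, degenerate = q == 0)
}

#' Select a tuning value from an instability sequence
#'
#' Very small tuning values can drive the instability to 0 trivially, with
#' (nearly) no gene ever labeled essential; such values are uninformative.
#' They are excluded by keeping only grid values at or above `w_max`, the
#' smallest value attaining the maximum instability, and the selected value
#' is the instability minimizer over the remainder. Ties resolve to the
#' smallest value, the conservative choice (fewer expected insertions,
#' fewer essential calls).
#'
#' @param grid Ascending candidate tuning values.
#' @param phi Instability value per grid point.
#' @return A list with `ws` (selected value), `w_max`, and their indices.
#' @examples
#' select_tuning(seq(0.1, 0.5, 0.1), c(0, 0.10, 0.20, 0.15, 0.18)) # ws 0.4
#' @export
select_tuning <- function(grid, phi) {
  if (length(grid) == 0) stop("empty tuning grid")
  if (length(grid) != length(phi))
    stop("grid and phi must have equal length")
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must be ascending")
  i_max <- which(phi >= max(phi) - 1e-12)[1L]
  cand <- seq.int(i_max, length(grid))
  i_sel <- cand[which.min(phi[cand])]
  list(ws = grid[i_sel], w_max = grid[i_max],
       index = i_sel, index_max = i_max)
}

#' Tune a labeling method by labeling instability
#'
#' Full tuning sweep: draws `m` insertion-site subsamples, labels every
#' gene under each candidate tuning value in each subsample, computes the
#' instability profile over the grid, and selects the tuning value by the
#' [select_tuning()] rule. For the mixture classifier (`exp_gamma`) the
#' mixture is refitted within every subsample, so the whole labeling
#' procedure is resampled.
#'
#' @inheritParams label_matrix
#' @param grid Ascending candidate tuning values (weights `w` or
#'   thresholds `t`).
#' @param keep_pi_hat Keep the genes-by-grid matrix of labeling
#'   probabilities in the result.
#' @return An object of class `instability_profile`: a list with `grid`,
#'   `phi`, `q`, `degenerate` (per grid value), `ws`, `w_max`, `pi_hat`
#'   (if kept), and the scheme parameters `m`, `fraction`, `method`,
#'   `seed`.
#' @export
instability_tune <- function(genes, iss, method = "connis",
                             grid = seq(0.1, 1, by = 0.1), m = 500,
                             fraction = 0.5, alpha = 0.05,
                             correction = "holm", trunc_frac = 0.05,
                             seed = 1, keep_pi_hat = TRUE) {
  method <- match.arg(method, c("connis", "binomial", "geometric",
                                "tn5gaps", "exp_gamma"))
  if (m < 2) stop("m must be >= 2")
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must be ascending")
  seeds <- subsample_seeds(seed, m)
  p_genes <- nrow(genes)
  z <- length(grid)
  counts <- matrix(0L, p_genes, z, dimnames = list(genes$gene_id, grid))
  b <- iss$genome_length
  for (d in seq_len(m)) {
    set.seed(seeds[d])
    iss_d <- subsample_insertions(iss, fraction)
    s_d <- summarize_genes(genes, iss_d, trunc_frac)
    theta_d <- length(iss_d$pos) / b
    ov_d <- if (method == "tn5gaps") longest_overlapping_run(s_d, iss_d)
    fit_d <- if (method == "exp_gamma") fit_exp_gamma(s_d$insertion_index)
    h_hat_d <- round_half_up(s_d$eff_length * theta_d)
    for (y in seq_len(z)) {
      ess <- switch(method,
        connis = {
          p <- connis_tail(s_d$l, s_d$eff_length, h_hat_d, grid[y])
          adjust_pvalues(p, correction) <= alpha
        },
        binomial = {
          p <- binomial_pvalue(s_d$k, s_d$eff_length, theta_d, grid[y])
          adjust_pvalues(p, correction) <= alpha
        },
        geometric = {
          p <- geometric_pvalue(s_d$l, theta_d, grid[y])
          adjust_pvalues(p, correction) <= alpha
        },
        tn5gaps = {
          p <- tn5gaps_pvalue(ov_d$l_ov, ov_d$n, theta_d, grid[y])
          adjust_pvalues(p, correction) <= alpha
        },
        exp_gamma = {
          exp_gamma_label(s_d$insertion_index, fit_d, grid[y])$label ==
            "essential"
        })
      counts[, y] <- counts[, y] + ess
    }
  }
  pi_hat <- counts / m
  q <- colSums(pi_hat > 0)
  phi <- ifelse(q == 0, 0, colSums(pi_hat * (1 - pi_hat)) / pmax(q, 1))
  sel <- select_tuning(grid, phi)
  structure(list(grid = grid, phi = as.numeric(phi), q = as.integer(q),
                 degenerate = q == 0, ws = sel$ws, w_max = sel$w_max,
                 pi_hat = if (keep_pi_hat) pi_hat,
                 method = method, m = m, fraction = fraction,
                 alpha = alpha, correction = correction,
                 trunc_frac = trunc_frac, seed = seed),
            class = "instability_profile")
}

#' @export
print.instability_profile <- function(x, ...) {
  cat(sprintf("instability profile (%s, m = %d, fraction = %.2f):\n",
              x$method, x$m, x$fraction))
  print(data.frame(tuning = x$grid, phi = signif(x$phi, 4), q = x$q,
                   selected = x$grid == x$ws), row.names = FALSE)
  cat(sprintf("w_max = %g, selected tuning value ws = %g\n", x$w_max, x$ws))
  invisible(x)
}
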