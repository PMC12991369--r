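# Weighted versions of three established Tn5 essentiality callers, and the
# exponential-vs-gamma insertion-index mixture classifier. The weight w
# enters the three density-based methods only through theta -> theta * w;
# observed statistics (k, l) are never rescaled.

#' Weighted binomial essentiality p-value
#'
#' Lower-tail probability of observing at most `k` insertion sites in a
#' gene of `b_eff` bp when each position carries an insertion with
#' probability `theta * w`: essential genes have fewer insertions than
#' expected.
#'
#' @param k Observed insertion-site count(s).
#' @param b_eff Effective gene length(s) in bp.
#' @param theta Genome-wide insertion density.
#' @param w Weight in `(0, 1]`.
#' @return p-values `P(X <= k)`, `X ~ Binomial(b_eff, theta * w)`.
#' @examples
#' binomial_pvalue(0, 10, 0.1) # 0.9^10
#' @export
binomial_pvalue <- function(k, b_eff, theta, w = 1) {
  tw <- theta * w
  if (tw >= 1) stop("weighted insertion density theta * w must be < 1")
  if (tw <= 0) stop("weighted insertion density theta * w must be > 0")
  if (any(k < 0 | k > b_eff)) stop("k must satisfy 0 <= k <= b_eff")
  stats::pbinom(k, size = b_eff, prob = tw)
}

#' Weighted geometric essentiality p-value
#'
#' Tail probability `(1 - theta * w)^(l - 1)` of an insertion-free run of at
#' least `l` bp under independent per-position insertions. This is the
#' large-gene limit of [connis_tail()]; runs of length 0 or 1 give p = 1.
#'
#' @param l Observed longest insertion-free run(s).
#' @inheritParams binomial_pvalue
#' @return p-values in `[0, 1]`.
#' @examples
#' geometric_pvalue(11, 0.1) # 0.9^10
#' @export
geometric_pvalue <- function(l, theta, w = 1) {
  tw <- theta * w
  if (tw >= 1) stop("weighted insertion density theta * w must be < 1")
  if (tw <= 0) stop("weighted insertion density theta * w must be > 0")
  (1 - tw)^(pmax(l, 1) - 1)
}

#' Weighted Tn5Gaps (Gumbel) essentiality p-value
#'
#' Extreme-value approximation to the probability of the longest
#' insertion-free gap overlapping a gene. With per-position insertion
#' probability `p_ins = theta * w`, `q = 1 - p_ins`, scale
#' `beta = 1 / log(1 / q)` and location
#' `mu = log(n * p_ins) * beta + gamma * beta - 1/2` (Euler-Mascheroni
#' `gamma`, i.e. the expected longest failure run among `n` Bernoulli
#' trials), the p-value is `1 - exp(-exp(-(l_ov - mu) / beta))`.
#'
#' @param l_ov Longest insertion-free run(s) overlapping the gene (full
#'   genome-wide length, not clipped to the gene).
#' @param n Number of Bernoulli trials attributed to the gene, see
#'   [longest_overlapping_run()].
#' @inheritParams binomial_pvalue
#' @return p-values in `[0, 1]`.
#' @export
tn5gaps_pvalue <- function(l_ov, n, theta, w = 1) {
  tw <- theta * w
  if (tw >= 1) stop("weighted insertion density theta * w must be < 1")
  if (tw <= 0) stop("weighted insertion density theta * w must be > 0")
  if (any(n < 1)) stop("n must be >= 1")
  euler_gamma <- 0.57721566490153286
  beta <- 1 / log(1 / (1 - tw))
  mu <- log(n * tw) * beta + euler_gamma * beta - 0.5
  pmin(pmax(1 - exp(-exp(-(l_ov - mu) / beta)), 0), 1)
}

#' Longest genome-wide insertion-free run overlapping each gene
#'
#' Among all maximal genome-wide insertion-free runs intersecting a gene's
#' effective interval, returns the longest one at its full (unclipped)
#' length `l_ov`, together with the trial count
#' `n = eff_length + (l_ov - overlap)` used by [tn5gaps_pvalue()]. With an
#' empty insertion set the whole genome is one run (`l_ov = b`, with a
#' warning).
#'
#' @param genes Gene table with `eff_start` / `eff_end` columns (see
#'   [truncate_genes()]); plain `start` / `end` are used as fallback.
#' @param iss An [insertion_set()].
#' @return A `data.frame` with columns `gene_id`, `l_ov`, `n`.
#' @examples
#' iss <- insertion_set(c(8, 25), genome_length = 40)
#' longest_overlapping_run(truncate_genes(gene_set("g", 11, 20)), iss)
#' @export
longest_overlapping_run <- function(genes, iss) {
  stopifnot(inherits(iss, "insertion_set"))
  if (is.null(genes$eff_start)) genes <- truncate_genes(genes, 0)
  b <- iss$genome_length
  P <- iss$pos
  if (length(P) == 0L) {
    warning("empty insertion set: the whole genome is one insertion-free run")
    return(data.frame(gene_id = genes$gene_id, l_ov = b,
                      n = rep(b, nrow(genes)), stringsAsFactors = FALSE))
  }
  # Maximal runs lie between consecutive insertion sites (with sentinels at
  # the genome ends): run i spans run_start[i] .. run_end[i].
  run_start <- c(1, P + 1)
  run_end <- c(P - 1, b)
  run_len <- run_end - run_start + 1
  l_ov <- n <- numeric(nrow(genes))
  for (j in seq_len(nrow(genes))) {
    s <- genes$eff_start[j]; e <- genes$eff_end[j]
    i1 <- findInterval(s - 1, run_end) + 1L # first run ending >= s
    i2 <- findInterval(e, run_start)        # last run starting <= e
    idx <- seq.int(i1, i2)
    idx <- idx[run_len[idx] > 0]
    if (length(idx) == 0L) {
      l_ov[j] <- 0
      n[j] <- e - s + 1
    } else {
      best <- idx[which.max(run_len[idx])]
      l_ov[j] <- run_len[best]
      overlap <- min(run_end[best], e) - max(run_start[best], s) + 1
      n[j] <- (e - s + 1) + (l_ov[j] - overlap)
    }
  }
  data.frame(gene_id = genes$gene_id, l_ov = l_ov, n = n,
             stringsAsFactors = FALSE)
}

#' @rdname call_connis
#' @export
call_binomial <- function(genes, iss, w = 1, alpha = 0.05,
                          correction = "holm", trunc_frac = 0,
                          theta = NULL, summary = NULL) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  s <- summary %||% summarize_genes(genes, iss, trunc_frac)
  theta <- theta %||% genome_density(iss)
  if (theta == 0) {
    warning("insertion density is 0; all binomial p-values are 1")
    p <- rep(1, nrow(s))
  } else {
    p <- binomial_pvalue(s$k, s$eff_length, theta, w)
  }
  method_result(s, "binomial", w, p, alpha, correction)
}

#' @rdname call_connis
#' @export
call_geometric <- function(genes, iss, w = 1, alpha = 0.05,
                           correction = "holm", trunc_frac = 0,
                           theta = NULL, summary = NULL) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  s <- summary %||% summarize_genes(genes, iss, trunc_frac)
  theta <- theta %||% genome_density(iss)
  if (theta == 0) {
    warning("insertion density is 0; all geometric p-values are 1")
    p <- rep(1, nrow(s))
  } else {
    p <- geometric_pvalue(s$l, theta, w)
  }
  method_result(s, "geometric", w, p, alpha, correction)
}

#' @rdname call_connis
#' @export
call_tn5gaps <- function(genes, iss, w = 1, alpha = 0.05,
                         correction = "holm", trunc_frac = 0,
                         theta = NULL, summary = NULL) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  s <- summary %||% summarize_genes(genes, iss, trunc_frac)
  theta <- theta %||% genome_density(iss)
  if (theta == 0) {
    warning("insertion density is 0; all Tn5Gaps p-values are 1")
    p <- rep(1, nrow(s))
    ov <- data.frame(l_ov = rep(NA_real_, nrow(s)), n = NA_real_)
  } else {
    ov <- longest_overlapping_run(s, iss)
    p <- tn5gaps_pvalue(ov$l_ov, ov$n, theta, w)
  }
  method_result(s, "tn5gaps", w, p, alpha, correction,
                extra = data.frame(l_ov = ov$l_ov, n_trials = ov$n))
}

#' Fit the exponential-vs-gamma insertion-index mixture
#'
#' Fits a two-component mixture to the gene-wise insertion indices
#' `d = k / eff_length`: an exponential component for the (nearly)
#' insertion-free essential genes and a gamma component for the
#' non-essential bulk. Fitting is by EM; the initial split point is the
#' antimode of a kernel density estimate of `d` (falling back to the 10th
#' percentile, with a warning, when no antimode exists). Zero indices are
#' displaced to half the smallest positive index for density evaluation
#' only.
#'
#' @param d Vector of insertion indices (>= 50 values, all >= 0).
#' @param max_iter Maximum EM iterations.
#' @param tol Stop when the log-likelihood increase falls below `tol`.
#' @return An object of class `exp_gamma_fit`: `mix_weight`, `exp_rate`,
#'   `gamma_shape`, `gamma_rate`, `converged`, `split_point`, `zero_repl`,
#'   `loglik` (trace of the EM objective), `n_iter`.
#' @export
fit_exp_gamma <- function(d, max_iter = 500, tol = 1e-8) {
  if (length(d) < 50) stop("need at least 50 insertion indices to fit")
  if (anyNA(d) || any(d < 0)) stop("insertion indices must be >= 0")
  zero_repl <- NA_real_
  if (any(d == 0)) {
    if (all(d == 0)) stop("all insertion indices are zero; nothing to fit")
    zero_repl <- min(d[d > 0]) / 2
    d[d == 0] <- zero_repl
  }
  split <- find_antimode(d)
  if (is.na(split)) {
    warning("no antimode found in the insertion-index distribution; ",
            "splitting at the 10th percentile")
    split <- as.numeric(stats::quantile(d, 0.1))
  }
  low <- d <= split
  if (!any(low) || all(low)) low <- d <= stats::quantile(d, 0.1)
  pi1 <- max(mean(low), 1 / length(d))
  lambda <- 1 / max(mean(d[low]), .Machine$double.xmin)
  m2 <- mean(d[!low]); v2 <- stats::var(d[!low])
  if (!isTRUE(v2 > 0)) { shape <- 1; rate <- 1 / m2 } else {
    shape <- m2^2 / v2; rate <- m2 / v2
  }
  loglik <- -Inf; trace <- numeric(0); converged <- FALSE; it <- 0
  for (it in seq_len(max_iter)) {
    f1 <- pi1 * stats::dexp(d, lambda)
    f2 <- (1 - pi1) * stats::dgamma(d, shape = shape, rate = rate)
    mix <- f1 + f2
    mix[mix <= 0 | !is.finite(mix)] <- .Machine$double.xmin
    ll <- sum(log(mix))
    trace <- c(trace, ll)
    if (is.finite(loglik) && ll - loglik < tol) { converged <- TRUE; break }
    loglik <- ll
    r1 <- f1 / mix
    pi1 <- min(max(mean(r1), 1e-8), 1 - 1e-8)
    lambda <- sum(r1) / max(sum(r1 * d), .Machine$double.xmin)
    r2 <- 1 - r1
    s2 <- sum(r2)
    if (s2 <= 0) break
    wm <- sum(r2 * d) / s2
    wlog <- sum(r2 * log(d)) / s2
    shape <- gamma_shape_mle(log(wm) - wlog, shape)
    rate <- shape / wm
  }
  structure(list(mix_weight = pi1, exp_rate = lambda, gamma_shape = shape,
                 gamma_rate = rate, converged = converged,
                 split_point = split, zero_repl = zero_repl,
                 loglik = trace, n_iter = it),
            class = "exp_gamma_fit")
}

#' @export
print.exp_gamma_fit <- function(x, ...) {
  cat(sprintf(paste0("exp-gamma mixture fit: pi = %.3f, exp rate = %.4g, ",
                     "gamma(shape = %.3g, rate = %.4g), %sconverged in %d ",
                     "iterations\n"),
              x$mix_weight, x$exp_rate, x$gamma_shape, x$gamma_rate,
              if (x$converged) "" else "NOT ", x$n_iter))
  invisible(x)
}

# Antimode of a kernel density estimate: the x of minimum density between
# the two highest local maxima; NA when the estimate is unimodal.
find_antimode <- function(d) {
  dens <- stats::density(d, n = 512)
  y <- dens$y
  n <- length(y)
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n],
              FALSE)
  peaks <- which(is_max)
  if (length(peaks) < 2) return(NA_real_)
  top2 <- sort(peaks[order(y[peaks], decreasing = TRUE)][1:2])
  valley <- top2[1] + which.min(y[top2[1]:top2[2]]) - 1L
  dens$x[valley]
}

# Weighted gamma shape MLE: solve log(a) - digamma(a) = s by Newton steps
# on log(a); s > 0 whenever the weighted data are not all equal.
gamma_shape_mle <- function(s, init) {
  if (!isTRUE(s > 0)) return(init)
  a <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
  for (i in 1:50) {
    f <- log(a) - digamma(a) - s
    fp <- 1 / a - trigamma(a)
    step <- f / (fp * a) # Newton on log(a)
    a_new <- a * exp(-step)
    if (!is.finite(a_new) || a_new <= 0) break
    if (abs(a_new - a) < 1e-10 * a) { a <- a_new; break }
    a <- a_new
  }
  a
}

#' Classify a gene by its exponential-vs-gamma likelihood ratio
#'
#' Computes `LR = log2(f_exp(d) / f_gamma(d))` under a fitted mixture and
#' labels a gene `essential` when `LR >= t`, `non-essential` when
#' `LR <= -t`, and `ambiguous` otherwise.
#'
#' @param d Insertion index (vectorized).
#' @param fit An `exp_gamma_fit` from [fit_exp_gamma()].
#' @param t Positive log2 likelihood-ratio threshold.
#' @return A `data.frame` with columns `LR` and `label`.
#' @export
exp_gamma_label <- function(d, fit, t) {
  stopifnot(inherits(fit, "exp_gamma_fit"))
  if (t <= 0) stop("t must be > 0")
  if (!is.na(fit$zero_repl)) d[d == 0] <- fit$zero_repl
  lr <- log2(stats::dexp(d, fit$exp_rate) /
               stats::dgamma(d, shape = fit$gamma_shape,
                             rate = fit$gamma_rate))
  label <- ifelse(lr >= t, "essential",
                  ifelse(lr <= -t, "non-essential", "ambiguous"))
  data.frame(LR = lr, label = label, stringsAsFactors = FALSE)
}

#' @rdname call_connis
#' @param t Log2 likelihood-ratio threshold of the exponential-vs-gamma
#'   classifier (its tuning value; `w`, `alpha` and `correction` do not
#'   apply to this method).
#' @param fit Optional pre-fitted `exp_gamma_fit` (refitted from the data
#'   otherwise).
#' @export
call_exp_gamma <- function(genes, iss, t = 2, trunc_frac = 0,
                           summary = NULL, fit = NULL) {
  s <- summary %||% summarize_genes(genes, iss, trunc_frac)
  fit <- fit %||% fit_exp_gamma(s$insertion_index)
  lab <- exp_gamma_label(s$insertion_index, fit, t)
  out <- data.frame(gene_id = s$gene_id, l = s$l, k = s$k,
                    eff_length = s$eff_length, LR = lab$LR,
                    p_value = NA_real_, p_adjusted = NA_real_,
                    essential = lab$label == "essential",
                    label = lab$label, method = "exp_gamma", tuning = t,
                    stringsAsFactors = FALSE)
  attr(out, "fit") <- fit
  out
}

#' Run any essentiality caller by name
#'
#' Uniform dispatcher used by the tuning and evaluation layers: `tuning` is
#' the weight `w` for `connis`, `binomial`, `geometric` and `tn5gaps`, and
#' the log2 threshold `t` for `exp_gamma`.
#'
#' @param genes,iss,alpha,correction,trunc_frac,theta,summary As in
#'   [call_connis()].
#' @param method Method name.
#' @param tuning Tuning value (weight or threshold).
#' @param ... Passed through to the method-specific caller.
#' @return The method's result `data.frame` (see [call_connis()]).
#' @export
call_method <- function(genes, iss,
                        method = c("connis", "binomial", "geometric",
                                   "tn5gaps", "exp_gamma"),
                        tuning = 1, alpha = 0.05, correction = "holm",
                        trunc_frac = 0, theta = NULL, summary = NULL, ...) {
  method <- match.arg(method)
  if (method == "exp_gamma")
    call_exp_gamma(genes, iss, t = tuning, trunc_frac = trunc_frac,
                   summary = summary, ...)
  else
    switch(method,
           connis = call_connis, binomial = call_binomial,
           geometric = call_geometric, tn5gaps = call_tn5gaps)(
      genes, iss, w = tuning, alpha = alpha, correction = correction,
      trunc_frac = trunc_frac, theta = theta, summary = summary)
}
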