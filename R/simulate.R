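# Synthetic TraDIS library simulator with known ground truth. A genome is
# tiled with genes of log-normal length; a subset of genes is essential and
# reserves a contiguous insertion-free block covering at least a fraction c
# of the gene; insertion sites are drawn without replacement with per-bp
# probability proportional to an intensity profile (uniform, sinusoidal, or
# uniform with cold spots); optional noise insertions are placed uniformly
# over the whole genome, reserved blocks included, and can therefore
# violate the insertion-free blocks exactly as library contamination would.

#' Simulation configuration
#'
#' Defaults emulate an *E. coli*-scale organism: a 4.6 Mb genome carrying
#' 4,000 genes with log-normal lengths (median about 900 bp) of which 300
#' are essential. Intensity profiles: `"uniform"`; `"sinusoidal"` with
#' per-bp weight `1 + A * sin(2 * pi * cycles * x / B)` (floored at 0.01);
#' `"coldspots"`, uniform except in `n_coldspots` non-overlapping windows
#' of `coldspot_length` bp where the weight is divided by
#' `coldspot_factor`.
#'
#' @param genome_length Genome size `B` in bp.
#' @param n_genes Number of genes to place.
#' @param n_essential Number of essential genes.
#' @param free_fraction Minimum insertion-free share `c` of each essential
#'   gene, in `(0, 1]`.
#' @param n_is Number of profile-driven insertion sites.
#' @param n_noise Number of uniform noise insertion sites (may fall inside
#'   reserved blocks).
#' @param profile `"uniform"`, `"sinusoidal"` or `"coldspots"`.
#' @param sine_amplitude,sine_cycles Sinusoidal profile parameters
#'   (amplitude `A < 1`, number of full periods along the genome).
#' @param n_coldspots,coldspot_length,coldspot_factor Cold-spot profile
#'   parameters.
#' @param gene_length_meanlog,gene_length_sdlog Log-normal gene-length
#'   parameters.
#' @param min_gene_length,max_gene_length Clamp for drawn gene lengths, bp.
#' @param read_geom_prob Success probability of the shifted geometric
#'   distribution generating per-site read counts.
#' @param seed Seed applied by [simulate_library()].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(genome_length = 4.6e6, n_genes = 4000,
                       n_essential = 300, free_fraction = 0.75,
                       n_is = 2e5, n_noise = 0,
                       profile = c("uniform", "sinusoidal", "coldspots"),
                       sine_amplitude = 0.5, sine_cycles = 3,
                       n_coldspots = 25, coldspot_length = 1e4,
                       coldspot_factor = 10,
                       gene_length_meanlog = log(900),
                       gene_length_sdlog = 0.5,
                       min_gene_length = 90, max_gene_length = 9000,
                       read_geom_prob = 0.1, seed = 1) {
  profile <- match.arg(profile)
  cfg <- as.list(environment())
  if (cfg$free_fraction <= 0 || cfg$free_fraction > 1)
    stop("free_fraction must be in (0, 1]")
  if (cfg$n_is + cfg$n_noise > cfg$genome_length)
    stop("more insertion sites requested than genome positions")
  if (cfg$n_essential > cfg$n_genes)
    stop("n_essential must not exceed n_genes")
  class(cfg) <- "sim_config"
  cfg
}

#' Per-bp insertion intensity profile
#'
#' @param config A [sim_config()].
#' @param coldspot_windows Optional precomputed `data.frame` of cold-spot
#'   windows (`start`, `end`); drawn uniformly (non-overlapping) otherwise,
#'   using the current RNG stream.
#' @return A numeric weight vector of length `genome_length`, with the
#'   window table attached as attribute `"coldspots"` for that profile.
#' @export
intensity_profile <- function(config, coldspot_windows = NULL) {
  B <- config$genome_length
  switch(config$profile,
    uniform = rep(1, B),
    sinusoidal = {
      A <- config$sine_amplitude
      if (A >= 1) {
        warning("sine amplitude >= 1; intensities are floored at 0.01")
      }
      pmax(1 + A * sin(2 * pi * config$sine_cycles * seq_len(B) / B), 0.01)
    },
    coldspots = {
      wn <- coldspot_windows %||%
        draw_coldspots(B, config$n_coldspots, config$coldspot_length)
      w <- rep(1, B)
      for (i in seq_len(nrow(wn)))
        w[wn$start[i]:wn$end[i]] <- 1 / config$coldspot_factor
      attr(w, "coldspots") <- wn
      w
    })
}

# Uniformly placed, non-overlapping cold-spot windows (rejection sampling).
draw_coldspots <- function(B, n_spots, spot_length) {
  if (n_spots * spot_length > B / 2)
    stop("cold spots would cover more than half the genome")
  starts <- integer(0)
  tries <- 0
  while (length(starts) < n_spots) {
    cand <- sample.int(B - spot_length + 1L, 1L)
    if (!any(abs(cand - starts) < spot_length)) starts <- c(starts, cand)
    tries <- tries + 1
    if (tries > 1000 * n_spots) stop("could not place cold spots")
  }
  starts <- sort(starts)
  data.frame(start = starts, end = starts + as.integer(spot_length) - 1L)
}

#' Simulate a TraDIS library with known ground truth
#'
#' Generation steps: (1) place genes along the genome, separated by
#' multinomially distributed intergenic gaps; (2) pick the essential genes
#' and reserve, uniformly within each, a contiguous block of
#' `ceiling(free_fraction * length)` bp whose intensity is zeroed; (3) draw
#' `n_is` distinct insertion positions without replacement with probability
#' proportional to the intensity profile; (4) add `n_noise` distinct
#' uniform noise positions anywhere on the genome; (5) draw per-site read
#' counts from a shifted geometric distribution; (6) attach truth labels.
#' Before noise, every essential gene therefore contains an insertion-free
#' run of at least `ceiling(free_fraction * length)` bp.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_library`: `genes` (gene table), `iss`
#'   ([insertion_set()]), `truth` (`gene_id`, `essential`), `reserved`
#'   (per essential gene: `block_start`, `block_end`), `coldspots` (window
#'   table or `NULL`), `noise_pos` (the noise positions), and `config`.
#' @export
simulate_library <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  B <- config$genome_length
  p <- config$n_genes

  len <- round(stats::rlnorm(p, config$gene_length_meanlog,
                             config$gene_length_sdlog))
  len <- pmin(pmax(len, config$min_gene_length), config$max_gene_length)
  spare <- B - sum(len)
  if (spare < 0)
    stop("genes do not fit the genome; reduce n_genes or gene lengths")
  gaps <- as.numeric(stats::rmultinom(1, spare, rep(1, p + 1L)))
  start <- cumsum(gaps[seq_len(p)] + c(0, len[seq_len(p - 1L)])) + 1
  genes <- gene_set(sprintf("g%04d", seq_len(p)), start, start + len - 1,
                    sample(c("+", "-"), p, replace = TRUE),
                    genome_length = B)

  essential_idx <- sort(sample.int(p, config$n_essential))
  essential <- seq_len(p) %in% essential_idx
  block_len <- as.integer(ceiling(config$free_fraction *
                                    genes$length[essential_idx]))
  offset <- vapply(genes$length[essential_idx] - block_len,
                   function(slack) sample.int(slack + 1L, 1L) - 1L,
                   integer(1))
  reserved <- data.frame(gene_id = genes$gene_id[essential_idx],
                         block_start = genes$start[essential_idx] + offset,
                         stringsAsFactors = FALSE)
  reserved$block_end <- reserved$block_start + block_len - 1L

  w <- intensity_profile(config)
  coldspots <- attr(w, "coldspots")
  for (i in seq_len(nrow(reserved)))
    w[reserved$block_start[i]:reserved$block_end[i]] <- 0

  if (sum(w > 0) < config$n_is)
    stop("not enough positive-intensity positions for n_is draws")
  pos <- weighted_positions(w, config$n_is)

  noise_pos <- integer(0)
  if (config$n_noise > 0) {
    free <- rep(TRUE, B)
    free[pos] <- FALSE
    open <- which(free)
    if (length(open) < config$n_noise)
      stop("not enough free positions for noise insertions")
    noise_pos <- sort(open[sample.int(length(open), config$n_noise)])
    pos <- c(pos, noise_pos)
  }
  counts <- stats::rgeom(length(pos), config$read_geom_prob) + 1
  iss <- insertion_set(pos, counts, genome_length = B)

  structure(list(genes = genes, iss = iss,
                 truth = data.frame(gene_id = genes$gene_id,
                                    essential = essential,
                                    stringsAsFactors = FALSE),
                 reserved = reserved, coldspots = coldspots,
                 noise_pos = noise_pos, config = config),
            class = "sim_library")
}

# n distinct positions, probability proportional to weights, without
# replacement, via exponential keys (weight 0 excludes a position).
weighted_positions <- function(w, n) {
  keys <- stats::rexp(length(w)) / w
  sort(order(keys)[seq_len(n)])
}

#' @export
print.sim_library <- function(x, ...) {
  cat(sprintf(paste0("sim_library: %.0f bp genome, %d genes (%d essential),",
                     " %d insertion sites (%d noise), profile '%s'\n"),
              x$config$genome_length, nrow(x$genes), sum(x$truth$essential),
              length(x$iss$pos), length(x$noise_pos), x$config$profile))
  invisible(x)
}
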