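#' Construct a gene annotation table
#'
#' A gene set is a plain `data.frame` with one row per gene and columns
#' `gene_id`, `start`, `end`, `strand` and `length`. Coordinates are 1-based
#' and inclusive, the convention in which all run-length formulas of the
#' package are stated.
#'
#' @param gene_id Character vector of unique gene identifiers.
#' @param start,end Integer vectors of 1-based inclusive bp coordinates.
#' @param strand Character vector in `"+"`, `"-"`, `"*"` (unknown); recycled.
#' @param genome_length Optional genome length in bp used to validate `end`.
#' @return A `data.frame` with columns `gene_id`, `start`, `end`, `strand`,
#'   `length` (where `length = end - start + 1`).
#' @examples
#' gene_set(c("g1", "g2"), c(190, 400), c(255, 720))
#' @export
gene_set <- function(gene_id, start, end, strand = "*", genome_length = NULL) {
  gene_id <- as.character(gene_id)
  start <- as.integer(round(start))
  end <- as.integer(round(end))
  strand <- rep_len(as.character(strand), length(gene_id))
  strand[!strand %in% c("+", "-")] <- "*"
  if (length(start) != length(gene_id) || length(end) != length(gene_id))
    stop("gene_id, start and end must have equal length")
  if (anyNA(start) || anyNA(end)) stop("gene coordinates must not be NA")
  if (any(start < 1L)) stop("gene start coordinates must be >= 1")
  if (any(end < start)) stop("gene end must be >= start")
  if (!is.null(genome_length) && any(end > genome_length))
    stop("gene end exceeds genome length")
  if (anyDuplicated(gene_id))
    stop("duplicated gene_id: ", gene_id[duplicated(gene_id)][1L])
  data.frame(gene_id = gene_id, start = start, end = end, strand = strand,
             length = end - start + 1L, stringsAsFactors = FALSE)
}

#' Construct an insertion-site set
#'
#' An insertion-site set holds the distinct genome positions at which a
#' transposon insertion was observed, each with a read count. Duplicate
#' positions are merged by summing their read counts; the model throughout
#' the package is about insertion *sites*, so a position contributes once to
#' the site count `h` regardless of its read count.
#'
#' @param positions Integer vector of 1-based genome positions.
#' @param counts Read counts per position (default all 1); summed over
#'   duplicated positions.
#' @param genome_length Genome length `b` in bp.
#' @return An object of class `insertion_set`: a list with sorted integer
#'   `pos`, numeric `count`, and `genome_length`.
#' @examples
#' iss <- insertion_set(c(100, 100, 200), c(5, 3, 1), genome_length = 1000)
#' n_sites(iss)        # 2
#' genome_density(iss) # 0.002
#' @export
insertion_set <- function(positions, counts = NULL, genome_length) {
  if (is.null(counts)) counts <- rep(1, length(positions))
  if (length(counts) != length(positions))
    stop("positions and counts must have equal length")
  genome_length <- as.numeric(genome_length)
  if (length(genome_length) != 1L || is.na(genome_length) || genome_length < 1)
    stop("genome_length must be a single positive number")
  if (length(positions)) {
    if (!all(is_wholenumber(positions)))
      stop("non-integer insertion position")
    if (any(positions < 1 | positions > genome_length))
      stop("insertion position outside [1, genome_length]")
    if (anyNA(counts) || any(counts < 1))
      stop("read counts must be >= 1")
  }
  pos <- as.integer(round(positions))
  if (anyDuplicated(pos)) {
    agg <- rowsum(as.numeric(counts), group = pos)
    pos <- as.integer(rownames(agg))
    counts <- as.numeric(agg[, 1L])
  }
  o <- order(pos)
  structure(list(pos = pos[o], count = as.numeric(counts)[o],
                 genome_length = genome_length),
            class = "insertion_set")
}

#' @export
print.insertion_set <- function(x, ...) {
  cat(sprintf("insertion_set: %d sites on a %.0f bp genome (density %.4g)\n",
              length(x$pos), x$genome_length,
              length(x$pos) / x$genome_length))
  invisible(x)
}

#' Number of distinct insertion sites
#'
#' @param iss An [insertion_set()].
#' @return Integer `h`, the number of distinct insertion positions.
#' @export
n_sites <- function(iss) {
  stopifnot(inherits(iss, "insertion_set"))
  length(iss$pos)
}

#' Genome-wide insertion density
#'
#' The density `theta = h / b`, where `h` is the number of distinct
#' insertion sites and `b` the genome length. All callers use this
#' genome-wide value (possibly down-weighted) as the per-bp insertion
#' probability under the non-essentiality null.
#'
#' @param iss An [insertion_set()].
#' @return A number in `[0, 1]`. Warns when `h = 0` (all downstream tests
#'   degenerate to p = 1).
#' @export
genome_density <- function(iss) {
  stopifnot(inherits(iss, "insertion_set"))
  h <- length(iss$pos)
  if (h == 0L)
    warning("insertion set is empty; insertion density is 0 and all tests are degenerate")
  h / iss$genome_length
}

#' Remove low-read-count insertion sites
#'
#' Sites supported by fewer than `min_reads` reads are dropped; the site
#' count and density of the returned set reflect the filtered sites. Used to
#' suppress spurious insertion sites before testing.
#'
#' @param iss An [insertion_set()].
#' @param min_reads Minimum read count to keep a site (>= 1).
#' @return A filtered [insertion_set()].
#' @export
filter_min_reads <- function(iss, min_reads = 1) {
  stopifnot(inherits(iss, "insertion_set"))
  if (length(min_reads) != 1L || is.na(min_reads) || min_reads < 1)
    stop("min_reads must be a single value >= 1")
  keep <- iss$count >= min_reads
  if (!any(keep))
    warning("no insertion site passes min_reads = ", min_reads,
            "; returning an empty set")
  structure(list(pos = iss$pos[keep], count = iss$count[keep],
                 genome_length = iss$genome_length),
            class = "insertion_set")
}

#' Truncate distal gene ends
#'
#' Removes `floor(trunc_frac * length)` bp from each end of every gene,
#' reflecting the common assumption that the distal gene ends tolerate
#' insertions even in essential genes. With `trunc_frac < 0.5` the effective
#' interval is always non-empty.
#'
#' @param genes A gene table from [gene_set()] or [load_annotation()].
#' @param trunc_frac Fraction in `[0, 0.5)` trimmed from each end.
#' @return `genes` with added columns `eff_start`, `eff_end`, `eff_length`.
#' @examples
#' truncate_genes(gene_set("g", 1, 100), 0.05) # effective interval [6, 95]
#' @export
truncate_genes <- function(genes, trunc_frac = 0) {
  if (length(trunc_frac) != 1L || is.na(trunc_frac) ||
      trunc_frac < 0 || trunc_frac >= 0.5)
    stop("trunc_frac must be in [0, 0.5)")
  cut <- as.integer(floor(trunc_frac * genes$length))
  genes$eff_start <- genes$start + cut
  genes$eff_end <- genes$end - cut
  genes$eff_length <- genes$eff_end - genes$eff_start + 1L
  if (any(genes$eff_length < 1L)) # cannot occur for trunc_frac < 0.5
    stop("truncation produced an empty gene interval")
  genes
}

#' Per-gene insertion summaries
#'
#' For every (optionally truncated) gene interval, counts the insertion
#' sites it contains (`k`) and the longest run of consecutive positions
#' carrying no insertion site (`l`), with runs bounded by insertion sites
#' and by the interval ends. `l` and `k` are the sufficient statistics for
#' all essentiality callers in the package.
#'
#' @param genes Gene table; see [gene_set()].
#' @param iss An [insertion_set()].
#' @param trunc_frac Fraction trimmed from each gene end, see
#'   [truncate_genes()].
#' @return A `data.frame` with the gene columns plus `eff_start`, `eff_end`,
#'   `eff_length`, `k`, `l` and `insertion_index` (`k / eff_length`).
#' @examples
#' iss <- insertion_set(c(13, 17), genome_length = 30)
#' summarize_genes(gene_set("g", 11, 20), iss) # k = 2, l = 3
#' @export
summarize_genes <- function(genes, iss, trunc_frac = 0) {
  stopifnot(inherits(iss, "insertion_set"))
  if (nrow(genes) && max(genes$end) > iss$genome_length)
    stop("gene interval outside the genome")
  g <- truncate_genes(genes, trunc_frac)
  P <- iss$pos
  i1 <- findInterval(g$eff_start - 1L, P) + 1L # first site >= eff_start
  i2 <- findInterval(g$eff_end, P)            # last site <= eff_end
  k <- pmax(i2 - i1 + 1L, 0L)
  l <- integer(nrow(g))
  for (j in seq_len(nrow(g))) {
    if (k[j] == 0L) {
      l[j] <- g$eff_length[j]
    } else {
      pp <- P[i1[j]:i2[j]]
      gap <- max(pp[1L] - g$eff_start[j], g$eff_end[j] - pp[k[j]])
      if (k[j] > 1L) gap <- max(gap, max(diff(pp)) - 1L)
      l[j] <- gap
    }
  }
  g$k <- k
  g$l <- l
  g$insertion_index <- k / g$eff_length
  g
}
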