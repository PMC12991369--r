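# Readers and writers for the small set of plain-text formats the tool
# consumes and emits: GFF3 / BED gene annotations, TRANSIT-style
# variableStep wiggle and two-column TSV insertion files, result and truth
# tables. All formats are single-sequence.

#' Load gene annotations from GFF3 or BED
#'
#' GFF3: rows whose feature type equals `feature_type` (default `"gene"`)
#' are kept; the gene identifier is taken from the first available of the
#' `ID`, `locus_tag` or `Name` attribute. BED intervals (0-based,
#' half-open) are converted to the package's 1-based inclusive convention.
#'
#' @param path Path to the annotation file.
#' @param format `"gff3"` or `"bed"`.
#' @param feature_type GFF3 feature type to keep (column 3).
#' @return A gene table as from [gene_set()].
#' @export
load_annotation <- function(path, format = c("gff3", "bed"),
                            feature_type = "gene") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  if (format == "gff3") {
    ids <- starts <- ends <- strands <- character(0)
    for (ln in which(keep)) {
      f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1L]]
      if (length(f) < 8L)
        stop("malformed GFF3 record at line ", ln, " of ", path)
      if (f[3L] != feature_type) next
      if (!grepl("^[0-9]+$", f[4L]) || !grepl("^[0-9]+$", f[5L]))
        stop("malformed GFF3 record at line ", ln, " of ", path,
             ": non-numeric coordinates")
      attr9 <- if (length(f) >= 9L) f[9L] else ""
      id <- NA_character_
      for (key in c("ID", "locus_tag", "Name")) {
        m <- regmatches(attr9, regexec(paste0("(?:^|;)\\s*", key, "=([^;]+)"),
                                       attr9))[[1L]]
        if (length(m) == 2L) { id <- m[2L]; break }
      }
      ids <- c(ids, id)
      starts <- c(starts, f[4L]); ends <- c(ends, f[5L])
      strands <- c(strands, f[7L])
    }
    if (length(ids) == 0L)
      stop("no gene features (type '", feature_type, "') in ", path)
    ids[is.na(ids)] <- paste0("gene_", which(is.na(ids)))
    gene_set(ids, as.integer(starts), as.integer(ends), strands)
  } else {
    rows <- which(keep & !grepl("^(track|browser)", lines))
    if (length(rows) == 0L) stop("no gene features in ", path)
    ids <- character(length(rows)); starts <- ends <- integer(length(rows))
    strands <- rep("*", length(rows))
    for (i in seq_along(rows)) {
      ln <- rows[i]
      f <- strsplit(lines[ln], "[\t ]+")[[1L]]
      if (length(f) < 3L || !grepl("^[0-9]+$", f[2L]) ||
          !grepl("^[0-9]+$", f[3L]))
        stop("malformed BED record at line ", ln, " of ", path)
      starts[i] <- as.integer(f[2L]) + 1L # 0-based half-open -> 1-based
      ends[i] <- as.integer(f[3L])
      ids[i] <- if (length(f) >= 4L) f[4L] else paste0("gene_", i)
      if (length(f) >= 6L) strands[i] <- f[6L]
    }
    gene_set(ids, starts, ends, strands)
  }
}

#' Load insertion sites from wiggle or TSV
#'
#' The wiggle dialect is TRANSIT-style `variableStep`: a header line
#' `variableStep chrom=<name>` followed by `position value` lines. The TSV
#' format has two columns, `position` and `read_count`, with or without a
#' header row. Duplicate positions have their read counts summed.
#'
#' @param path Path to the insertion file.
#' @param format `"wig"` or `"tsv"`.
#' @param genome_length Genome length `b` in bp (required; neither format
#'   carries it).
#' @return An [insertion_set()].
#' @export
load_insertions <- function(path, format = c("wig", "tsv"), genome_length) {
  format <- match.arg(format)
  if (missing(genome_length)) stop("genome_length must be supplied")
  if (!file.exists(path)) stop("insertion file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  data_rows <- integer(0)
  if (format == "wig") {
    seen_header <- FALSE
    for (ln in seq_along(lines)) {
      line <- lines[ln]
      if (grepl("^\\s*(#|$)", line) || grepl("^track", line)) next
      if (grepl("^variableStep", line)) { seen_header <- TRUE; next }
      if (grepl("^fixedStep", line))
        stop("fixedStep wiggle is not supported (line ", ln, " of ", path, ")")
      if (!seen_header)
        stop("wiggle data before variableStep header at line ", ln,
             " of ", path)
      data_rows <- c(data_rows, ln)
    }
  } else {
    data_rows <- which(!grepl("^\\s*(#|$)", lines))
    if (length(data_rows) &&
        grepl("^[^0-9]", sub("^\\s*", "", lines[data_rows[1L]])))
      data_rows <- data_rows[-1L] # header row
  }
  pos <- numeric(length(data_rows)); cnt <- numeric(length(data_rows))
  for (i in seq_along(data_rows)) {
    ln <- data_rows[i]
    f <- strsplit(sub("^\\s+", "", lines[ln]), "[\t ,;]+")[[1L]]
    if (length(f) < 2L || is.na(suppressWarnings(as.numeric(f[1L]))) ||
        is.na(suppressWarnings(as.numeric(f[2L]))))
      stop("malformed insertion record at line ", ln, " of ", path)
    pos[i] <- as.numeric(f[1L]); cnt[i] <- as.numeric(f[2L])
  }
  if (length(pos) && !all(is_wholenumber(pos)))
    stop("non-integer insertion position in ", path)
  if (length(pos) && any(pos < 1 | pos > genome_length))
    stop("insertion position outside [1, ", genome_length, "] in ", path)
  insertion_set(pos, cnt, genome_length)
}

#' Write gene annotations
#'
#' @param genes Gene table.
#' @param path Output path.
#' @param format `"gff3"` or `"bed"`.
#' @param genome_length Optional; written as a `##sequence-region` GFF3
#'   pragma when given.
#' @param seqid Sequence name used in the output.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(genes, path, format = c("gff3", "bed"),
                             genome_length = NULL, seqid = "chr") {
  format <- match.arg(format)
  if (format == "gff3") {
    header <- "##gff-version 3"
    if (!is.null(genome_length))
      header <- c(header,
                  sprintf("##sequence-region %s 1 %.0f", seqid, genome_length))
    body <- sprintf("%s\tconnis\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                    seqid, genes$start, genes$end,
                    ifelse(genes$strand %in% c("+", "-"), genes$strand, "."),
                    genes$gene_id)
    writeLines(c(header, body), path)
  } else {
    writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", seqid, genes$start - 1L,
                       genes$end, genes$gene_id,
                       ifelse(genes$strand %in% c("+", "-"), genes$strand, ".")),
               path)
  }
  invisible(path)
}

#' Write insertion sites
#'
#' @param iss An [insertion_set()].
#' @param path Output path.
#' @param format `"wig"` (TRANSIT-style variableStep) or `"tsv"`.
#' @param seqid Sequence name used in the wiggle header.
#' @return `path`, invisibly.
#' @export
write_insertions <- function(iss, path, format = c("wig", "tsv"),
                             seqid = "chr") {
  format <- match.arg(format)
  if (format == "wig") {
    writeLines(c(sprintf("variableStep chrom=%s", seqid),
                 sprintf("%d %.10g", iss$pos, iss$count)), path)
  } else {
    writeLines(c("position\tread_count",
                 sprintf("%d\t%.10g", iss$pos, iss$count)), path)
  }
  invisible(path)
}

#' Write and read ground-truth essentiality labels
#'
#' @param truth A `data.frame` with columns `gene_id` and `essential`
#'   (logical), as produced by [simulate_library()].
#' @param path Output path (two-column TSV, labels written as
#'   `essential` / `non-essential`).
#' @return `path` invisibly for the writer; the truth `data.frame` for the
#'   reader.
#' @export
write_truth <- function(truth, path) {
  writeLines(c("gene_id\tlabel",
               sprintf("%s\t%s", truth$gene_id,
                       ifelse(truth$essential, "essential", "non-essential"))),
             path)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  data.frame(gene_id = as.character(tab$gene_id),
             essential = tab$label == "essential",
             stringsAsFactors = FALSE)
}
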