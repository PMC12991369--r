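test_that("GFF3 and BED annotations load with the package coordinate convention", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "##sequence-region chr 1 5000",
    "chr\tsim\tgene\t190\t255\t.\t+\t.\tID=thrA;Name=thrA",
    "chr\tsim\tCDS\t190\t255\t.\t+\t.\tID=cds1;Parent=thrA",
    "chr\tsim\tgene\t400\t720\t.\t-\t.\tlocus_tag=b0002"), gff)
  g <- load_annotation(gff, "gff3")
  expect_equal(g$gene_id, c("thrA", "b0002"))
  expect_equal(g$start, c(190L, 400L))
  expect_equal(g$length, c(66L, 321L))
  expect_equal(g$strand, c("+", "-"))

  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr\t189\t255\tgeneA\t0\t+", "chr\t399\t720\tgeneB"), bed)
  gb <- load_annotation(bed, "bed")
  # 0-based half-open -> 1-based inclusive
  expect_equal(gb$start, c(190L, 400L))
  expect_equal(gb$end, c(255L, 720L))
  expect_equal(gb$length, c(66L, 321L))
})

test_that("annotation round-trips through BED and GFF3 preserve intervals", {
  g <- gene_set(c("a", "b", "c"), c(1, 50, 120), c(30, 119, 200),
                c("+", "-", "*"))
  for (fmt in c("bed", "gff3")) {
    f <- withr::local_tempfile()
    write_annotation(g, f, fmt, genome_length = 500)
    g2 <- load_annotation(f, fmt)
    expect_equal(g2[, c("gene_id", "start", "end", "length")],
                 g[, c("gene_id", "start", "end", "length")])
  }
})

test_that("malformed and empty annotation files raise informative errors", {
  bad <- withr::local_tempfile()
  writeLines(c("chr\tsim\tgene\t10\t99\t.\t+\t.\tID=x",
               "chr\tsim\tgene\tten\t99\t.\t+\t.\tID=y"), bad)
  expect_error(load_annotation(bad, "gff3"), "line 2")
  empty <- withr::local_tempfile()
  writeLines("##gff-version 3", empty)
  expect_error(load_annotation(empty, "gff3"), "no gene features")
  badbed <- withr::local_tempfile()
  writeLines("chr\tx\t100", badbed)
  expect_error(load_annotation(badbed, "bed"), "line 1")
})

test_that("insertion files merge duplicate positions and validate ranges", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("position\tread_count", "100\t5", "100\t3", "200\t1"), tsv)
  iss <- load_insertions(tsv, "tsv", genome_length = 1000)
  expect_equal(n_sites(iss), 2L)
  expect_equal(iss$pos, c(100L, 200L))
  expect_equal(iss$count, c(8, 1))

  wig <- withr::local_tempfile(fileext = ".wig")
  writeLines(c("variableStep chrom=chr", "7 2"), wig)
  iw <- load_insertions(wig, "wig", genome_length = 10)
  expect_equal(iw$pos, 7L)
  expect_equal(iw$count, 2)

  oob <- withr::local_tempfile()
  writeLines(c("position\tread_count", "0\t5"), oob)
  expect_error(load_insertions(oob, "tsv", genome_length = 10), "outside")
  frac <- withr::local_tempfile()
  writeLines(c("position\tread_count", "2.5\t5"), frac)
  expect_error(load_insertions(frac, "tsv", genome_length = 10),
               "non-integer")
  fs <- withr::local_tempfile()
  writeLines(c("fixedStep chrom=chr start=1 step=1", "1"), fs)
  expect_error(load_insertions(fs, "wig", genome_length = 10), "fixedStep")
})

test_that("insertion sets round-trip through wig and tsv writers", {
  iss <- insertion_set(c(3, 9, 250), c(2, 7, 1), genome_length = 300)
  for (fmt in c("wig", "tsv")) {
    f <- withr::local_tempfile()
    write_insertions(iss, f, fmt)
    iss2 <- load_insertions(f, fmt, genome_length = 300)
    expect_equal(iss2$pos, iss$pos)
    expect_equal(iss2$count, iss$count)
  }
})

test_that("read-count filtering recomputes the site set and density", {
  iss <- insertion_set(c(5, 9), c(1, 3), genome_length = 100)
  f2 <- filter_min_reads(iss, 2)
  expect_equal(f2$pos, 9L)
  expect_equal(n_sites(f2), 1L)
  expect_equal(genome_density(f2), 0.01)
  expect_equal(filter_min_reads(iss, 1)$pos, iss$pos) # identity
  expect_warning(f0 <- filter_min_reads(insertion_set(c(5, 9), c(1, 1), 100), 2),
                 "no insertion site")
  expect_equal(n_sites(f0), 0L)
})

test_that("distal truncation removes floor(frac * length) from each end", {
  g <- truncate_genes(gene_set("g", 1, 100), 0.05)
  expect_equal(c(g$eff_start, g$eff_end, g$eff_length), c(6L, 95L, 90L))
  g0 <- truncate_genes(gene_set("g", 11, 40), 0)
  expect_equal(c(g0$eff_start, g0$eff_end), c(11L, 40L))
  # small genes: floor(0.05 * 7) = 0, interval unchanged
  g7 <- truncate_genes(gene_set("g", 3, 9), 0.05)
  expect_equal(g7$eff_length, 7L)
  expect_error(truncate_genes(gene_set("g", 1, 100), 0.5), "trunc_frac")
})

test_that("gene summaries match hand-worked examples", {
  iss <- insertion_set(c(13, 17), genome_length = 30)
  s <- summarize_genes(gene_set("g", 11, 20), iss)
  expect_equal(s$k, 2L)
  expect_equal(s$l, 3L) # runs 11-12, 14-16, 18-20
  s2 <- summarize_genes(gene_set("g", 11, 20),
                        insertion_set(integer(0), genome_length = 30))
  expect_equal(c(s2$k, s2$l), c(0L, 10L))
  s3 <- summarize_genes(gene_set("g", 11, 12),
                        insertion_set(c(11, 12), genome_length = 30))
  expect_equal(c(s3$k, s3$l), c(2L, 0L))
})

test_that("gene summaries agree with a naive position-by-position scan", {
  set.seed(42)
  for (rep in 1:25) {
    b <- sample(50:200, 1)
    h <- sample(0:40, 1)
    pos <- if (h > 0) sort(sample.int(b, h)) else integer(0)
    iss <- insertion_set(pos, genome_length = b)
    s <- sample.int(b - 10, 1); e <- s + sample.int(10, 1)
    summ <- summarize_genes(gene_set("g", s, e), iss)
    oracle <- naive_gene_scan(s, e, pos)
    expect_equal(summ$k, oracle$k)
    expect_equal(summ$l, oracle$l)
    # free runs partition the non-insertion positions of the interval
    expect_equal(sum(oracle$runs) + oracle$k, summ$eff_length)
  }
})

test_that("genome density is h / b with a degenerate-empty warning", {
  expect_equal(genome_density(insertion_set(1:5, genome_length = 50)), 0.1)
  expect_warning(th <- genome_density(insertion_set(integer(0),
                                                    genome_length = 50)),
                 "empty")
  expect_equal(th, 0)
})
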