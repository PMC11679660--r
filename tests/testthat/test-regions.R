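test_that("differential-expression filter applies strict thresholds and collapses duplicates", {
  tab <- data.frame(
    gene = c("A", "B", "C", "D", "A"),
    log2fc = c(1.2, -1.5, 1.0, 0.4, 2.0),
    padj = c(0.01, 0.04, 0.001, 0.001, 0.02))
  out <- filter_de_cpgs(tab)
  expect_equal(out$gene, c("A", "B"))        # C fails strict >1, D fails |lfc|
  expect_equal(out$log2fc, c(1.2, -1.5))     # first occurrence of A retained
  expect_error(filter_de_cpgs(data.frame(gene = "A", log2fc = 1)),
               "missing required column")
  expect_error(filter_de_cpgs(transform(tab, padj = padj * 100)), "\\[0, 1\\]")
})

test_that("radius selection uses gap distance with an inclusive boundary", {
  genes <- data.frame(gene = "G1", chrom = "chr1", start = 22000, end = 30000,
                      strand = "+")
  el <- function(s, e) data.frame(chrom = "chr1", start = s, end = e,
                                  strand = "+")
  expect_equal(nrow(select_near(el(1000, 2000), genes)), 1)   # gap exactly 20000
  expect_equal(nrow(select_near(el(999, 1999), genes)), 0)    # gap 20001
  expect_error(select_near(el(0, 10), genes, radius_bp = -1), ">= 0")
})

test_that("selection matches a brute-force all-pairs distance scan", {
  set.seed(101)
  n <- 1000
  elements <- data.frame(
    chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
    start = sample.int(5e5, n), strand = "+")
  elements$end <- elements$start + sample(50:2000, n, replace = TRUE)
  genes <- data.frame(
    gene = sprintf("G%02d", 1:20),
    chrom = sample(c("chr1", "chr2"), 20, replace = TRUE),
    start = sample.int(5e5, 20), strand = "+")
  genes$end <- genes$start + sample(5000:30000, 20, replace = TRUE)
  radius <- 20000
  ann <- select_near(elements, genes, radius_bp = radius)

  ## oracle: elementwise scan over every (element, gene) pair
  brute <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(20)) {
      if (elements$chrom[i] != genes$chrom[j]) next
      gap <- max(0, genes$start[j] - elements$end[i],
                 elements$start[i] - genes$end[j])
      if (gap <= radius) brute <- brute + 1L
    }
  }
  expect_equal(nrow(ann), brute)
  ## nearest-gene assignment agrees with the oracle's minimum gap
  near <- ann[ann$nearest, ]
  for (k in sample(seq_len(nrow(near)), 25)) {
    e <- near[k, ]
    cand <- genes[genes$chrom == e$chrom, ]
    gaps <- pmax(0, cand$start - e$end, e$start - cand$end)
    expect_equal(e$distance, min(gaps))
  }
})

test_that("region merge joins on shared bases only and matches a position-set oracle", {
  x <- data.frame(chrom = "chr1", start = c(0, 5, 30), end = c(10, 20, 40))
  expect_equal(merge_regions(x)[, c("start", "end")],
               data.frame(start = c(0, 30), end = c(20, 40)))
  book <- data.frame(chrom = "chr1", start = c(0, 10), end = c(10, 20))
  expect_equal(nrow(merge_regions(book)), 2)   # bookended, no shared base

  set.seed(7)
  n <- 500
  rand <- data.frame(chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
                     start = sample.int(3000, n, replace = TRUE))
  rand$end <- rand$start + sample.int(80, n, replace = TRUE)
  merged <- merge_regions(rand)
  ## oracle: explicit base-position sets
  posset <- function(df) {
    unlist(lapply(seq_len(nrow(df)), function(i) {
      paste(df$chrom[i], seq(df$start[i], df$end[i] - 1L))
    }))
  }
  expect_setequal(unique(posset(rand)), posset(merged))
  ## disjoint + sorted
  for (ch in unique(merged$chrom)) {
    m <- merged[merged$chrom == ch, ]
    expect_true(all(diff(m$start) > 0))
    ## disjoint: no shared base; bookended output rows are allowed
    expect_true(all(m$start[-1] >= m$end[-nrow(m)]))
  }
  ## idempotence and length bound
  expect_equal(merge_regions(merged), merged)
  expect_lte(sum(merged$end - merged$start), sum(rand$end - rand$start))
  expect_error(merge_regions(data.frame(chrom = "chr1", start = 5, end = 5)),
               "malformed")
})

test_that("positional classification follows exon > gene body > strand-aware flank", {
  gene_p <- data.frame(gene = "G", chrom = "chr1", start = 1000, end = 9000,
                       strand = "+")
  gene_m <- transform(gene_p, strand = "-")
  exons <- data.frame(gene = "G", start = c(1000, 4000), end = c(1500, 4500))
  el <- function(s, e) list(chrom = "chr1", start = s, end = e)
  ## 1 bp of exon overlap wins over intronic
  expect_equal(classify_relation(el(4499, 5000), gene_p, exons)$relation, "exonic")
  expect_equal(classify_relation(el(2000, 2500), gene_p, exons)$relation, "intronic")
  ## flank past the gene end: downstream on +, upstream on -
  expect_equal(classify_relation(el(14000, 14500), gene_p, exons)$relation,
               "downstream")
  expect_equal(classify_relation(el(14000, 14500), gene_m, exons)$relation,
               "upstream")
  expect_equal(classify_relation(el(14000, 14500), gene_m, exons)$distance, 5000)
  expect_error(classify_relation(el(50000, 50100), gene_p, exons,
                                 radius_bp = 20000), "radius")
})

test_that("radius zero selects exactly the overlapping elements", {
  genes <- data.frame(gene = "G", chrom = "chr1", start = 100, end = 200,
                      strand = "+")
  elements <- data.frame(chrom = "chr1",
                         start = c(150, 200, 90, 250), end = c(160, 210, 100, 260),
                         strand = "+")
  ann <- select_near(elements, genes, radius_bp = 0)
  ## overlap [150,160); bookended [200,210) and [90,100) have gap 0 under the
  ## half-open convention and are therefore also within radius 0
  expect_true(all(ann$distance == 0))
  expect_equal(sort(ann$start), c(90, 150, 200))
})
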