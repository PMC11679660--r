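## handy builders for constructed tail fixtures
tail_seq <- function(a, spacer, b, flank = "CC") {
  paste0(flank, strrep("A", a), spacer, strrep("A", b), flank)
}

test_that("spacer-removing substitutions merge adjacent A runs", {
  fl <- 2L
  ## A^29 G A^7 with G>A at the spacer: 29 -> 37
  s <- tail_seq(29, "G", 7)
  r <- polyA_extension(s, anchor = fl + 1L, pos = fl + 30L, ref = "G", alt = "A")
  expect_equal(r$before, 29)
  expect_equal(r$after, 37)
  expect_equal(r$extension, 8)
  ## A^25 C A^10 with C>A: 25 -> 36
  r2 <- polyA_extension(tail_seq(25, "C", 10), anchor = fl + 1L,
                        pos = fl + 26L, ref = "C", alt = "A")
  expect_equal(c(r2$before, r2$after), c(25, 36))
  ## A^20 G A^6 with G>A: 20 -> 27 (round trip of a 20 bp tail)
  r3 <- polyA_extension(tail_seq(20, "G", 6), anchor = fl + 1L,
                        pos = fl + 21L, ref = "G", alt = "A")
  expect_equal(c(r3$before, r3$after), c(20, 27))
})

test_that("no merge across an intervening non-A base; ref/alt validation", {
  ## ...A^20 C G A^5...: substituting the G two bases from the anchored run
  ## cannot bridge the intervening C, so the run stays at 20
  s <- paste0("TT", strrep("A", 20), "CG", strrep("A", 5), "TT")
  r <- polyA_extension(s, anchor = 3L, pos = 24L, ref = "G", alt = "A")
  expect_equal(r$before, 20)
  expect_equal(r$after, 20)
  expect_equal(r$extension, 0)
  ## a substituted base directly adjacent to the run extends it by exactly 1
  adj <- polyA_extension(s, anchor = 3L, pos = 23L, ref = "C", alt = "A")
  expect_equal(adj$extension, 1)
  ## alt equal to ref leaves the run unchanged
  r0 <- polyA_extension(s, anchor = 3L, pos = 24L, ref = "G", alt = "G")
  expect_equal(r0$extension, 0)
  expect_error(polyA_extension(s, 3, 24, ref = "T", alt = "A"),
               "reference mismatch")
  expect_error(polyA_extension(s, 3, 24, ref = "GC", alt = "A"),
               "single-nucleotide")
})

test_that("run lengths agree with an exhaustive homopolymer scan on random sequences", {
  set.seed(77)
  rle_oracle <- function(chars, anchor, base) {
    r <- rle(chars)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    i <- which(starts <= anchor & anchor <= ends)
    if (r$values[i] != base) 0L else r$lengths[i]
  }
  for (rep in 1:200) {
    n <- sample(30:80, 1)
    chars <- sample(c("A", "A", "A", "C", "G", "T"), n, replace = TRUE)
    pos <- sample(n, 1)
    alt <- sample(c("A", "C", "G", "T"), 1)
    anchor <- sample(n, 1)
    seqs <- paste(chars, collapse = "")
    r <- polyA_extension(seqs, anchor, pos, ref = chars[pos], alt = alt)
    edited <- chars; edited[pos] <- alt
    expect_identical(r$before, rle_oracle(chars, anchor, "A"))
    expect_identical(r$after, rle_oracle(edited, anchor, "A"))
  }
})

test_that("reverse-complementing the sequence and flipping strand is invariant", {
  set.seed(31)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (rep in 1:50) {
    n <- sample(40:70, 1)
    chars <- sample(c("A", "A", "T", "C", "G"), n, replace = TRUE)
    pos <- sample(n, 1)
    alt <- sample(c("A", "C", "G", "T"), 1)
    anchor <- sample(n, 1)
    fwd <- polyA_extension(paste(chars, collapse = ""), anchor, pos,
                           ref = chars[pos], alt = alt, strand = "+")
    rc <- rev(unname(comp[chars]))
    rev_res <- polyA_extension(paste(rc, collapse = ""),
                               anchor = n + 1L - anchor, pos = n + 1L - pos,
                               ref = comp[[chars[pos]]], alt = comp[[alt]],
                               strand = "-")
    expect_equal(rev_res$before, fwd$before)
    expect_equal(rev_res$after, fwd$after)
  }
})

test_that("variants are located within the correct Alu substructure", {
  alu <- list(start = 100, end = 400,
              left_monomer_start = 100, left_monomer_end = 230,
              linker_start = 230, linker_end = 245,
              right_monomer_start = 245, right_monomer_end = 370,
              tail_start = 370, tail_end = 400)
  expect_equal(locate_in_alu(380, alu), "tail")
  expect_equal(locate_in_alu(235, alu), "linker")
  expect_equal(locate_in_alu(150, alu), "left_monomer")
  expect_equal(locate_in_alu(300, alu), "right_monomer")
  expect_equal(locate_in_alu(401, alu), "outside")   # 1 bp past the element
  expect_equal(locate_in_alu(400, alu), "tail")      # last base, half-open end
  bad <- alu; bad$tail_end <- 500
  expect_error(locate_in_alu(380, bad), "substructure")
})

test_that("simulated elements round-trip through the measurement path", {
  cfg <- sim_config(seed = 5)
  retro <- simulate_retro_sequences(cfg)
  tab <- polya_table(retro$sequences, retro$alu_table, retro$variants)
  expect_equal(tab$before, retro$variants$truth_before)
  expect_equal(tab$after, retro$variants$truth_after)
  ## unplanted elements carry tails of the genomic average length 21-26
  plain <- setdiff(retro$alu_table$name, retro$variants$element)
  for (nm in plain) {
    a <- retro$alu_table[retro$alu_table$name == nm, ]
    expect_true((a$tail_end - a$tail_start) %in% 21:26)
  }
  ## determinism: identical seed, identical bytes
  retro2 <- simulate_retro_sequences(sim_config(seed = 5))
  expect_identical(retro$sequences, retro2$sequences)
  expect_error(simulate_retro_sequences(cfg, planted = data.frame(
    a = 0L, spacer = "G", b = 3L)), "run lengths")
})
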