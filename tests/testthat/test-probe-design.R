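test_that("the 17-mer probe occurs exactly once in the consensus, forward strand", {
  hits <- scan_kmer(c(consensus = alu_consensus()), alu_probe(), "forward")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 25L)
  expect_equal(substr(alu_consensus(), hits$start + 1L,
                      hits$start + nchar(alu_probe())), alu_probe())
})

test_that("k-mer scanning reports exact, overlapping, strand-aware hits", {
  expect_equal(nrow(scan_kmer(c(c1 = "AAAA"), "CCC")), 0L)
  # overlapping occurrences are all reported
  ov <- scan_kmer(c(c1 = "AAAAA"), "AA", "forward")
  expect_equal(ov$start, 0:3)
  # sequences shorter than the probe yield nothing
  expect_equal(nrow(scan_kmer(c(c1 = "AC"), "ACGT")), 0L)
  # N never matches
  expect_equal(nrow(scan_kmer(c(c1 = "ACGNACGT"), "ACGT", "forward")), 1L)
  # minus-strand hits sit at the forward position of the reverse complement
  g <- c(c1 = "TTTCCAAAGTGCTGGGATTAGGG")  # contains revcomp of the ALU probe
  h <- scan_kmer(g, alu_probe(), "both")
  expect_equal(h$strand, "-")
  expect_equal(h$start, 3L)
})

test_that("planted-copy genomes are recovered exactly at substitution rate 0", {
  g <- generate_genome(repeat_genome_model(c(chr1 = 120000L, chr2 = 80000L),
                                           n_copies = c(25L, 10L), seed = 141))
  hits <- scan_kmer(g$genome, alu_probe(), "forward")
  expect_equal(nrow(hits), 35L)
  expect_equal(sort(hits$start[hits$chrom == "chr1"]),
               sort(g$bed$start[g$bed$chrom == "chr1"]) + 25L)
})

test_that("scanning agrees with a naive sliding-window oracle", {
  set.seed(151)
  g <- generate_genome(repeat_genome_model(c(chr1 = 60000L), n_copies = 15L,
                                           substitution_rate = 0.05, seed = 151))
  seq1 <- as.character(g$genome[[1]])
  for (probe in c(alu_probe(), "ACGTACGTACGT", substr(alu_consensus(), 100, 116))) {
    got <- scan_kmer(g$genome, probe, "forward")
    expect_equal(got$start, naive_scan(seq1, probe))
  }
})

test_that("forward hits mirror reverse-complement hits on the minus strand", {
  g <- generate_genome(repeat_genome_model(c(chr1 = 50000L), n_copies = 12L,
                                           seed = 161))
  probe <- alu_probe()
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(probe)))
  both <- scan_kmer(g$genome, probe, "both")
  fwd_of_rc <- scan_kmer(g$genome, rc, "forward")
  minus <- both[both$strand == "-", ]
  expect_equal(minus$start, fwd_of_rc$start)
  expect_equal(nrow(both),
               nrow(scan_kmer(g$genome, probe, "forward")) + nrow(fwd_of_rc))
})

test_that("bin densities use floor binning and conserve totals", {
  hits <- tibble::tibble(chrom = "chr1", start = c(100L, 600000L),
                         end = c(117L, 600017L), strand = "+")
  bins <- bin_density(hits, c(chr1 = 1200000L))
  expect_equal(bins$count, c(1L, 1L, 0L))
  expect_equal(bins$bin_start, c(0, 500000, 1000000))

  # boundary hit falls in the following (half-open) bin
  b2 <- bin_density(tibble::tibble(chrom = "chr1", start = 500000L,
                                   end = 500017L, strand = "+"),
                    c(chr1 = 1200000L))
  expect_equal(b2$count, c(0L, 1L, 0L))

  empty <- bin_density(tibble::tibble(chrom = character(), start = integer(),
                                      end = integer(), strand = character()),
                       c(chr1 = 700000L))
  expect_true(all(empty$count == 0L))

  set.seed(171)
  g <- generate_genome(repeat_genome_model(c(chr1 = 400000L, chr2 = 300000L),
                                           n_copies = 40L, seed = 171))
  h <- scan_kmer(g$genome, alu_probe(), "both")
  bd <- bin_density(h, c(chr1 = 400000L, chr2 = 300000L))
  for (ch in c("chr1", "chr2")) {
    expect_equal(sum(bd$count[bd$chrom == ch]), sum(h$chrom == ch))
  }

  expect_error(bin_density(tibble::tibble(chrom = "chr1", start = 900000L,
                                          end = 900017L, strand = "+"),
                           c(chr1 = 700000L)), "beyond chromosome end")
})

test_that("specificity fractions use full containment", {
  ann <- tibble::tibble(chrom = "chr1", start = 0L, end = 100L, name = "alu")
  hits <- tibble::tibble(chrom = "chr1", start = c(10L, 200L),
                         end = c(27L, 217L), strand = "+")
  expect_equal(annotation_overlap_fraction(hits, ann), 0.5)
  # a hit straddling the interval edge is not contained
  straddle <- tibble::tibble(chrom = "chr1", start = 90L, end = 107L, strand = "+")
  expect_equal(annotation_overlap_fraction(straddle, ann), 0)
  inside <- tibble::tibble(chrom = "chr1", start = c(0L, 50L), end = c(17L, 67L),
                           strand = "+")
  expect_equal(annotation_overlap_fraction(inside, ann), 1)

  ann10 <- tibble::tibble(chrom = "chr1", start = seq(0L, 9000L, 1000L),
                          end = seq(300L, 9300L, 1000L),
                          name = sprintf("alu%02d", 1:10))
  h3 <- tibble::tibble(chrom = "chr1", start = c(10L, 1010L, 2010L),
                       end = c(27L, 1027L, 2027L), strand = "+")
  expect_equal(covered_element_fraction(ann10, h3), 0.3)
  expect_equal(covered_element_fraction(ann10, h3[0, ]), 0)
  expect_error(covered_element_fraction(ann10[0, ], h3), "empty")
})

test_that("probe ranking prefers specific, frequent k-mers deterministically", {
  # genome of planted consensus copies in annotated regions only
  g <- generate_genome(repeat_genome_model(c(chr1 = 60000L), n_copies = 20L,
                                           seed = 181))
  ranking <- design_probe(substr(alu_consensus(), 20, 60), g$genome, g$bed,
                          k = 17L)
  expect_equal(ranking$overlap_fraction[1], 1)
  expect_true(ranking$specific[1])
  expect_equal(ranking$total_hits[1], max(ranking$total_hits))

  # a k-mer planted many times outside the annotation ranks below specific
  # candidates even with more hits
  decoy <- substr(alu_consensus(), 30, 46)
  chr <- as.character(g$genome[[1]])
  spam <- paste(rep(decoy, 60), collapse = "")
  boosted <- Biostrings::DNAStringSet(c(chr1 = paste0(chr, spam)))
  r2 <- design_probe(substr(alu_consensus(), 20, 60), boosted, g$bed, k = 17L)
  decoy_row <- which(r2$sequence == decoy)
  expect_false(r2$specific[decoy_row])
  expect_gt(r2$total_hits[decoy_row], max(r2$total_hits[r2$specific]))
  expect_true(all(which(r2$specific) < decoy_row))

  # k = nchar(consensus): a single trivially ranked candidate
  cons <- substr(alu_consensus(), 1, 30)
  r3 <- design_probe(cons, g$genome, g$bed, k = 30L)
  expect_equal(nrow(r3), 1L)
  expect_equal(r3$source_offset, 0L)

  expect_error(design_probe("ACGT", g$genome, g$bed, k = 17L), "shorter")
})
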