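test_that("localization tables round-trip and enforce their schema", {
  set.seed(271)
  pts <- random_localizations(100)
  path <- file.path(tempdir(), "loc.tsv")
  write_localization_table(pts, path)
  back <- read_localization_table(path)
  expect_equal(as.data.frame(back), as.data.frame(pts), tolerance = 1e-12)

  # a negative precision is rejected with its physical line number
  bad <- pts
  bad$precision_x_nm[7] <- -5
  bad_path <- file.path(tempdir(), "bad.tsv")
  utils::write.table(bad, bad_path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_localization_table(bad_path), "line\\(s\\) 8")

  # header-only file: an empty set, not an error
  empty_path <- file.path(tempdir(), "empty.tsv")
  writeLines(paste(names(pts), collapse = "\t"), empty_path)
  expect_equal(nrow(read_localization_table(empty_path)), 0L)

  # missing mandatory column is named in the error
  nox <- pts[setdiff(names(pts), "x_nm")]
  nox_path <- file.path(tempdir(), "nox.tsv")
  utils::write.table(nox, nox_path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_localization_table(nox_path), "x_nm")
})

test_that("BED intervals parse, validate and round-trip", {
  path <- file.path(tempdir(), "a.bed")
  writeLines(c("track name=test", "chr1\t100\t200\talu"), path)
  bed <- read_bed(path)
  expect_equal(bed$chrom, "chr1")
  expect_equal(bed$start, 100L)
  expect_equal(bed$end, 200L)
  expect_equal(bed$name, "alu")

  writeLines("chr1\t300\t200\tx", path)
  expect_error(read_bed(path), "start >= end")

  set.seed(281)
  iv <- tibble::tibble(chrom = sample(c("chr1", "chr2"), 30, replace = TRUE),
                       start = sample.int(100000L, 30),
                       name = sprintf("elt%02d", 1:30))
  iv$end <- iv$start + sample(50:300, 30, replace = TRUE)
  iv <- iv[, c("chrom", "start", "end", "name")]
  iv <- iv[order(iv$chrom, iv$start), ]
  rt <- file.path(tempdir(), "rt.bed")
  write_bed(iv, rt)
  expect_equal(as.data.frame(read_bed(rt)), as.data.frame(iv))
})

test_that("FASTA reading truncates headers and tolerates CRLF", {
  lf <- file.path(tempdir(), "lf.fa")
  crlf <- file.path(tempdir(), "crlf.fa")
  lines <- c(">chr1 some description", "ACGTACGTAA", "CCGGTT")
  writeLines(lines, lf)
  writeLines(paste0(lines, "\r"), crlf, sep = "\n")
  a <- read_fasta(lf)
  b <- read_fasta(crlf)
  expect_equal(names(a), "chr1")
  expect_equal(as.character(a[[1]]), "ACGTACGTAACCGGTT")
  expect_equal(as.character(a), as.character(b))

  # soft-masked bases become N (and can never match) when requested
  mask <- file.path(tempdir(), "mask.fa")
  writeLines(c(">c", "ACGTacgtACGT"), mask)
  masked <- read_fasta(mask, mask_lowercase = TRUE)
  expect_equal(as.character(masked[[1]]), "ACGTNNNNACGT")
  plain <- read_fasta(mask)
  expect_equal(as.character(plain[[1]]), "ACGTACGTACGT")
})

test_that("TIFF stacks round-trip integer counts", {
  set.seed(291)
  frames <- replicate(4, matrix(rpois(32 * 24, 40), 24, 32), simplify = FALSE)
  path <- file.path(tempdir(), "stack.tif")
  write_stack(frames, path)
  back <- read_stack(path)
  expect_length(back, 4L)
  expect_equal(back, frames)
})

test_that("the pipeline validates configs before running and is reproducible", {
  out1 <- file.path(tempdir(), "run1")
  cfg <- list(seed = 7L, out_dir = out1,
              stages = c("simulate", "cluster", "shells"),
              simulate = list(n_clusters = 12L, nucleus_radius_nm = 3000,
                              het_background_per_nm2 = 4e-4),
              cluster = list(radius_nm = 100, min_points = 10L),
              shells = list(max_radius_nm = 500))
  man <- run_pipeline(cfg)
  expect_equal(names(man$stages), c("simulate", "cluster", "shells"))
  expect_true(all(vapply(man$stages, function(s) s$records > 0, logical(1))))
  expect_true(file.exists(file.path(out1, "manifest.json")))

  # rerunning the same config and seed reproduces the outputs bit for bit
  out2 <- file.path(tempdir(), "run2")
  cfg2 <- cfg
  cfg2$out_dir <- out2
  run_pipeline(cfg2)
  for (f in c("simulated_points.tsv", "clusters.csv", "shell_profile.csv")) {
    expect_equal(unname(tools::md5sum(file.path(out1, f))),
                 unname(tools::md5sum(file.path(out2, f))))
  }

  # dependency and schema validation happen before any computation
  expect_error(run_pipeline(list(stages = "shells", out_dir = tempdir())),
               "needs clusters")
  expect_error(run_pipeline(list(stages = "cluster", out_dir = tempdir())),
               "localization source")
  expect_error(run_pipeline(list(stages = "simulate", bogus = 1)),
               "unknown config key")
  expect_error(run_pipeline(list(stages = "warp")), "unknown stage")
})

test_that("the command-line entry point maps errors to exit codes", {
  # validation problems exit 2
  expect_equal(suppressMessages(comboloc_main(character(0))), 2L)
  expect_equal(suppressMessages(comboloc_main(c("cluster"))), 2L)
  expect_equal(suppressMessages(comboloc_main(c("frobnicate", "--x", "1"))), 2L)

  # a simulate -> dose fit flow succeeds end to end
  pre <- file.path(tempdir(), "cli_doses")
  expect_equal(suppressMessages(
    comboloc_main(c("simulate", "--what", "doses", "--seed", "3",
                    "--out", pre))), 0L)
  fitfile <- file.path(tempdir(), "fit.json")
  expect_equal(suppressMessages(
    comboloc_main(c("dose", "--mode", "fit", "--counts",
                    paste0(pre, "_counts.csv"), "--out", fitfile))), 0L)
  fit <- jsonlite::read_json(fitfile, simplifyVector = TRUE)
  expect_lt(abs(fit$a - 3054), 500)
  expect_lt(abs(fit$c - 21390), 500)

  # probe scan over a planted genome
  gpre <- file.path(tempdir(), "cli_genome")
  expect_equal(suppressMessages(
    comboloc_main(c("simulate", "--what", "genome", "--seed", "5",
                    "--out", gpre))), 0L)
  expect_equal(suppressMessages(
    comboloc_main(c("probe", "--mode", "scan", "--genome",
                    paste0(gpre, ".fasta"), "--out", gpre))), 0L)
  hits <- read_bed(paste0(gpre, "_hits.bed"))
  expect_gt(nrow(hits), 0L)
})
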