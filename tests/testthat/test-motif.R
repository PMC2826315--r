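test_that("masked sequence loading follows the lowercase/N convention", {
  s <- masked_seqs(c(s1 = "ACgtNAC", s2 = "ACGTACG"))
  expect_equal(s[[1]]$mask, c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_false(any(s[[2]]$mask))
  expect_error(masked_seqs(c(s1 = "ACXT")), "non-IUPAC")
  expect_error(masked_seqs(c(a = "ACGT", a = "ACGT")), "unique")
})

test_that("FASTA round trip preserves case-encoded masks", {
  seqs <- c(p1 = "ACGTacgtNNACGT", p2 = "acgACGTACGTtga")
  path <- file.path(withr::local_tempdir(), "p.fasta")
  write_masked_fasta(seqs, path)
  back <- read_masked_fasta(path)
  expect_equal(
    unlist(lapply(back, `[[`, "mask")),
    unlist(lapply(masked_seqs(seqs), `[[`, "mask")),
    ignore_attr = TRUE
  )
})

test_that("sequences without a legal window are excluded with a warning", {
  expect_warning(
    enc <- dspeaks:::encode_seqs(
      masked_seqs(c(bad = "acgtacgtacgt", ok = "ACGTACGTACGT")), 6
    ),
    "no fully unmasked window"
  )
  expect_equal(length(enc), 1)
  expect_error(
    suppressWarnings(
      dspeaks:::encode_seqs(masked_seqs(c(bad = "acgtacgt")), 4)
    ),
    "legal window"
  )
})

test_that("PWM construction matches the pseudocount formula", {
  # beta = 0: plain frequencies
  pwm0 <- pwm_from_sites(c("AA", "AC"), beta = 0)
  expect_equal(unname(unclass(pwm0)["A", 1]), 1.0)
  expect_equal(unname(unclass(pwm0)["A", 2]), 0.5)
  expect_equal(unname(unclass(pwm0)["C", 2]), 0.5)
  # beta = 1, uniform background: A column 1 = (2 + 0.25) / 3
  pwm1 <- pwm_from_sites(c("AA", "AC"), beta = 1)
  expect_equal(unname(unclass(pwm1)["A", 1]), 2.25 / 3, tolerance = 1e-12)
  # identical sites, beta = 0: indicator columns
  pwmI <- pwm_from_sites(rep("ACGT", 5), beta = 0)
  expect_equal(unclass(pwmI)[, 1], c(A = 1, C = 0, G = 0, T = 0))
  # columns always sum to one
  expect_equal(colSums(unclass(pwm1)), rep(1, 2), tolerance = 1e-9)
  expect_error(pwm_from_sites(character(0)), "empty")
  expect_error(pwm_from_sites(c("AA", "ACG")), "same length")
})

test_that("information content has the known closed forms", {
  uniform <- pwm_from_sites(c("AAAA", "CCCC", "GGGG", "TTTT"), beta = 0)
  expect_equal(info_content(uniform), rep(0, 4), tolerance = 1e-12)
  certain <- pwm_from_sites(c("A", "A"), beta = 0)
  expect_equal(unname(info_content(certain)), 2, tolerance = 1e-12)
  half <- pwm_from_sites(c("A", "C"), beta = 0)
  expect_equal(unname(info_content(half)), 1, tolerance = 1e-12)
})

test_that("degenerate single-letter sequences converge to the trivial motif", {
  seqs <- masked_seqs(setNames(
    rep(paste(rep("A", 30), collapse = ""), 6), paste0("s", 1:6)
  ))
  r <- gibbs_motif(seqs, width = 4, seed = 1, chains = 1)
  expect_equal(r$consensus, "AAAA")
  expect_true(r$converged)
})

test_that("the sampler recovers exact planted sites in short sequences", {
  # 20 sequences of 200 bp with an exact planted 8-mer: consensus and
  # >= 90% of positions recovered in >= 90% of 20 seeds
  planted <- "GTAACGTC"
  ok <- vapply(1:20, function(seed) {
    set.seed(seed + 1000)
    seqs <- vapply(1:20, function(i) {
      chars <- sample(c("A", "C", "G", "T"), 200, replace = TRUE)
      at <- sample(1:(200 - 8 + 1), 1)
      chars[at:(at + 7)] <- strsplit(planted, "")[[1]]
      paste(chars, collapse = "")
    }, character(1))
    names(seqs) <- paste0("s", 1:20)
    truth_at <- vapply(seqs, function(s) {
      as.integer(regexpr(planted, s, fixed = TRUE))
    }, integer(1))
    r <- gibbs_motif(masked_seqs(seqs), width = 8, seed = seed)
    r$consensus == planted && mean(r$sites$start == truth_at) >= 0.9
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("reported sites never overlap masked positions", {
  cfg <- promoter_config(13, n_seqs = 10, mu = 0, length = 400)
  sim <- simulate_expression(cfg)
  prom <- simulate_promoters(cfg, sim$truth)
  seqs <- masked_seqs(prom$sequences)
  r <- gibbs_motif(seqs, width = 10, seed = 2, chains = 2)
  for (i in seq_len(nrow(r$sites))) {
    rec <- seqs[[which(vapply(seqs, `[[`, "", "id") == r$sites$sequence_id[i])]]
    expect_false(any(rec$mask[r$sites$start[i]:(r$sites$start[i] + 9)]))
  }
})

test_that("a fixed seed reproduces the motif result exactly", {
  cfg <- promoter_config(17, n_seqs = 8, mu = 0.1, length = 300)
  sim <- simulate_expression(cfg)
  prom <- simulate_promoters(cfg, sim$truth)
  seqs <- masked_seqs(prom$sequences)
  r1 <- gibbs_motif(seqs, width = 10, seed = 99, chains = 2)
  r2 <- gibbs_motif(seqs, width = 10, seed = 99, chains = 2)
  expect_identical(r1$sites, r2$sites)
  expect_identical(unclass(r1$pwm), unclass(r2$pwm))
  expect_identical(r1$score, r2$score)
})

fake_result <- function(consensus, score) {
  structure(
    list(consensus = consensus, score = score, width = nchar(consensus)),
    class = "motif_result"
  )
}

test_that("multi-run grouping reports the majority consensus and support", {
  runs <- c(
    lapply(1:8, function(i) fake_result("ACGTACGTAC", 100 + i)),
    list(fake_result("TTTTTTTTTT", 50), fake_result("GGGGGGGGGG", 60))
  )
  ms <- multi_run_consensus(runs, d_max = 1)
  expect_equal(ms$support, 0.8)
  expect_equal(ms$consensus, "ACGTACGTAC")
  expect_equal(ms$best$score, 108)

  one <- multi_run_consensus(list(fake_result("ACGTACGTAC", 1)))
  expect_equal(one$support, 1.0)

  expect_warning(
    ms2 <- multi_run_consensus(list(
      fake_result("AAAAAAAAAA", 1), fake_result("CCCCCCCCCC", 2),
      fake_result("GGGGGGGGGG", 3)
    )),
    "distinct"
  )
  expect_equal(ms2$support, 1 / 3)
  # near-misses within the Hamming tolerance join the representative group
  ms3 <- multi_run_consensus(list(
    fake_result("ACGTACGTAC", 5), fake_result("ACGTACGTAT", 4),
    fake_result("TTTTTTTTTT", 1)
  ), d_max = 1)
  expect_equal(ms3$support, 2 / 3)
  expect_error(
    multi_run_consensus(list(fake_result("AAAA", 1), fake_result("AAAAA", 2))),
    "width"
  )
})

test_that("hamming distance counts mismatches and checks lengths", {
  expect_equal(hamming("ACGT", "ACGT"), 0)
  expect_equal(hamming("ACGT", "ACGA"), 1)
  expect_error(hamming("ACG", "ACGT"), "equal length")
})

test_that("motif exports are well formed", {
  pwm <- pwm_from_sites(c("ACGT", "ACGG", "ACGT"), beta = 1)
  dir <- withr::local_tempdir()
  write_pwm_tsv(pwm, file.path(dir, "pwm.tsv"))
  tbl <- readr::read_tsv(file.path(dir, "pwm.tsv"), show_col_types = FALSE)
  expect_equal(tbl$base, c("A", "C", "G", "T"))
  expect_equal(unname(as.matrix(tbl[, -1])), unname(unclass(pwm)),
    tolerance = 1e-12, ignore_attr = TRUE
  )

  res <- structure(
    list(
      pwm = pwm, consensus = pwm_consensus(pwm),
      sites = tibble::tibble(sequence_id = "s1", start = 1, site = "ACGT"),
      background = rep(0.25, 4)
    ),
    class = "motif_result"
  )
  write_meme_motif(res, file.path(dir, "m.meme"))
  lines <- readLines(file.path(dir, "m.meme"))
  expect_true(any(grepl("^MEME version", lines)))
  expect_true(any(grepl("letter-probability matrix", lines)))
  probs <- lines[(which(grepl("letter-probability", lines)) + 1):length(lines)]
  expect_equal(length(probs), 4) # one row per motif column
})
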