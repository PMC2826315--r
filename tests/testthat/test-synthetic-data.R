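test_that("default configuration matches the emulated study design", {
  cfg <- synth_config()
  sim <- simulate_expression(cfg)
  expect_equal(dim(sim$raw$values), c(5950L, 17L))
  expect_equal(dim(sim$background), c(5950L, 17L))
  expect_equal(nrow(cfg$design), 17L)
  expect_equal(sum(cfg$design$tissue == "AMC"), 9L)
  expect_equal(cfg$promoter_length, 2000L)
  expect_match(cfg$motif_consensus, "CAGCTG")
})

test_that("identical seeds give bit-identical output from all generators", {
  cfg <- promoter_config(7, n_seqs = 12, length = 300)
  a <- simulate_expression(cfg)
  b <- simulate_expression(cfg)
  expect_identical(a$raw$values, b$raw$values)
  expect_identical(a$background, b$background)
  expect_identical(
    simulate_annotations(cfg, a$truth),
    simulate_annotations(cfg, b$truth)
  )
  expect_identical(
    simulate_promoters(cfg, a$truth)$sequences,
    simulate_promoters(cfg, b$truth)$sequences
  )
})

test_that("a null design yields no heavy DS tail (Monte-Carlo)", {
  # all effects zero: over 20 seeds the mean count of |DS| > 3 stays
  # below 1% of genes
  counts <- vapply(1:20, function(seed) {
    cfg <- one_block_config(seed, n_genes = 400, effect_size = 0)
    sim <- simulate_expression(cfg)
    x <- log_transform(sim$raw)
    p <- discriminating_score(x, default_contrasts(x$design)$AMC)
    sum(abs(p$ds) > 3, na.rm = TRUE)
  }, numeric(1))
  expect_lt(mean(counts), 0.01 * 400)
})

test_that("realized within-block correlation tracks the configured target", {
  mean_r <- vapply(1:20, function(seed) {
    cfg <- one_block_config(seed, n_genes = 150, size = 30, r = 0.9)
    sim <- simulate_expression(cfg)
    v <- log2(sim$raw$values[sim$truth$blocks$block$genes, ])
    r <- cor(t(v))
    mean(r[upper.tri(r)])
  }, numeric(1))
  expect_lt(abs(mean(mean_r) - 0.9), 0.05)
})

test_that("generator rejects invalid configurations", {
  expect_error(
    synth_config(n_genes = 50, blocks = default_blocks()),
    "n_genes"
  )
  # overlapping explicit gene sets
  expect_error(
    synth_config(
      n_genes = 100, tissue_signature_size = 0,
      blocks = list(
        a = planted_block(3, "AMC", genes = c("g00001", "g00002", "g00003")),
        b = planted_block(3, "AMC", genes = c("g00003", "g00004", "g00005"))
      )
    ),
    "overlap"
  )
  # a contrast group with < 2 samples
  bad_design <- default_design()[c(1:6, 10:17), ] # drop all AMC V1
  expect_error(
    simulate_expression(synth_config(
      n_genes = 60, design = bad_design, tissue_signature_size = 0,
      blocks = list()
    )),
    "contrast"
  )
})

test_that("planted annotation enrichment is recoverable (hypergeometric)", {
  # block of 30 genes, planted-term probability 0.8, background 0.01,
  # 2000 genes: the planted term's one-sided tail p < 1e-6 in >= 95% of
  # 20 seeds (oracle: exhaustive summation over the realized counts)
  hits <- vapply(1:20, function(seed) {
    cfg <- one_block_config(seed, n_genes = 2000, size = 30)
    truth <- list(blocks = list(block = list(
      genes = sprintf("g%05d", 1:30), go_term = "GO:TEST"
    )))
    ann <- simulate_annotations(cfg, truth)
    genes <- sprintf("g%05d", 1:2000)
    term_genes <- unique(ann$gene_id[ann$term_id == "GO:TEST"])
    k <- length(intersect(term_genes, truth$blocks$block$genes))
    p <- hyper_tail_oracle(k, length(term_genes), 2000, 30)
    p < 1e-6
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("annotation edge cases behave", {
  cfg <- synth_config(
    n_genes = 50, tissue_signature_size = 0, blocks = list(),
    go_background_rate = 0
  )
  ann <- simulate_annotations(cfg, list(blocks = list()))
  expect_equal(nrow(ann), 0)
  expect_error(
    simulate_annotations(
      synth_config(n_genes = 50, blocks = list(), tissue_signature_size = 0,
                   go_n_terms = 0),
      list(blocks = list())
    ),
    "go_n_terms"
  )
})

test_that("promoters carry one mutated site each, never on masked bases", {
  cfg <- promoter_config(3, n_seqs = 20, mu = 0.1)
  sim <- simulate_expression(cfg)
  prom <- simulate_promoters(cfg, sim$truth)
  expect_length(prom$sequences, 20)
  expect_true(all(nchar(prom$sequences) == 2000))
  sites <- prom$truth$motif$sites
  W <- nchar(cfg$motif_consensus)
  for (i in seq_len(nrow(sites))) {
    s <- prom$sequences[[sites$gene_id[i]]]
    window <- substr(s, sites$start[i], sites$start[i] + W - 1)
    expect_identical(window, toupper(window)) # planted site never masked
    expect_identical(toupper(window), sites$site[i])
  }
})

test_that("site mutation load matches the binomial expectation", {
  # mu = 0.1, width 10, 50 sequences: mean Hamming distance to the
  # consensus ~ W * mu = 1.0 (+/- 0.4 over 20 seeds)
  mean_ham <- vapply(1:20, function(seed) {
    cfg <- promoter_config(seed, n_seqs = 50, mu = 0.1, length = 200)
    sim <- simulate_expression(cfg)
    prom <- simulate_promoters(cfg, sim$truth)
    mean(vapply(
      prom$truth$motif$sites$site,
      function(s) hamming(s, cfg$motif_consensus), numeric(1)
    ))
  }, numeric(1))
  expect_lt(abs(mean(mean_ham) - 1.0), 0.4)
})

test_that("mu = 0 plants exact consensus copies", {
  cfg <- promoter_config(5, n_seqs = 10, mu = 0, length = 150)
  sim <- simulate_expression(cfg)
  prom <- simulate_promoters(cfg, sim$truth)
  expect_true(all(prom$truth$motif$sites$site == cfg$motif_consensus))
})

test_that("promoter length below motif width is rejected", {
  cfg <- promoter_config(1, n_seqs = 5, length = 5)
  sim <- simulate_expression(cfg)
  expect_error(simulate_promoters(cfg, sim$truth), "motif width")
})
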