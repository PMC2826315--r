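test_that("discriminating score reproduces hand-computed values", {
  v <- rbind(
    flat = c(1, 1, 1, 1),
    sep = c(2, 2, 0, 0)
  )
  colnames(v) <- paste0("s", 1:4)
  x <- make_xset(v)
  con <- ds_contrast(c("s1", "s2"), c("s3", "s4"))
  p <- discriminating_score(x, con)
  # identical in both groups: flat gene has SD 0 -> DS 0, flagged
  expect_equal(p$ds[p$gene_id == "flat"], 0)
  expect_equal(p$flag[p$gene_id == "flat"], "degenerate")
  # {2,2} vs {0,0}: DS = 2 / sqrt(4/3)
  expect_equal(p$ds[p$gene_id == "sep"], 2 / sqrt(4 / 3), tolerance = 1e-9)
})

test_that("default AMC contrast takes V1 against all other alleles", {
  con <- default_contrasts(default_design())
  expect_setequal(
    con$AMC$group2,
    default_design()$sample_id[default_design()$tissue == "AMC" &
      default_design()$allele == "V1"]
  )
  expect_equal(length(con$AMC$group1), 6)
  expect_equal(length(con$CNS$group1), 2) # V14 only
  expect_error(ds_contrast("s1", "s1"), "disjoint")
  expect_error(ds_contrast("s1", c("s2", "s3")), "at least 2")
})

test_that("DS is antisymmetric and invariant under positive affine maps", {
  set.seed(21)
  v <- matrix(rnorm(50 * 6, 8), 50, 6,
    dimnames = list(sprintf("g%02d", 1:50), paste0("s", 1:6))
  )
  x <- make_xset(v)
  fwd <- ds_contrast(paste0("s", 1:3), paste0("s", 4:6))
  rev <- ds_contrast(paste0("s", 4:6), paste0("s", 1:3))
  expect_equal(
    discriminating_score(x, fwd)$ds,
    -discriminating_score(x, rev)$ds,
    tolerance = 1e-12
  )
  y <- make_xset(3.7 * v + 11)
  expect_equal(
    discriminating_score(y, fwd)$ds,
    discriminating_score(x, fwd)$ds,
    tolerance = 1e-9
  )
})

test_that("genes with too few unmasked samples are flagged, not scored", {
  v <- matrix(rnorm(12, 8), 2, 6,
    dimnames = list(c("g1", "g2"), paste0("s", 1:6))
  )
  v[1, c(1, 2)] <- NA # only one unmasked value left in group1
  x <- make_xset(v)
  p <- discriminating_score(x, ds_contrast(paste0("s", 1:3), paste0("s", 4:6)))
  expect_true(is.na(p$ds[p$gene_id == "g1"]))
  expect_equal(p$flag[p$gene_id == "g1"], "insufficient")
})

test_that("window smoothing matches the hand example and stays in range", {
  v <- matrix(rnorm(5 * 4, 8), 5, 4,
    dimnames = list(paste0("g", 1:5), paste0("s", 1:4))
  )
  x <- make_xset(v)
  p <- discriminating_score(x, ds_contrast(c("s1", "s2"), c("s3", "s4")))
  p$ds <- c(0, 0, 3, 0, 0) # overwrite with the worked profile
  sm <- smooth_scores(p, paste0("g", 1:5), w = 3)
  expect_equal(sm$smoothed, c(0, 1, 1, 1, 0))
  # constant profile is a fixed point for any window
  p$ds <- rep(2.5, 5)
  for (w in c(1, 2, 4, 5)) {
    expect_equal(smooth_scores(p, paste0("g", 1:5), w = w)$smoothed,
      rep(2.5, 5),
      tolerance = 1e-12
    )
  }
  expect_error(smooth_scores(p, paste0("g", 1:5), w = 0), "window")
  expect_error(smooth_scores(p, paste0("g", 1:5), w = 6), "window")
  # smoothing never exceeds the raw DS range
  set.seed(31)
  p$ds <- rnorm(5)
  sm2 <- smooth_scores(p, paste0("g", 1:5), w = 3)
  expect_gte(min(sm2$smoothed), min(p$ds))
  expect_lte(max(sm2$smoothed), max(p$ds))
})

make_profile <- function(smoothed) {
  n <- length(smoothed)
  v <- matrix(rnorm(n * 4, 8), n, 4,
    dimnames = list(sprintf("g%03d", seq_len(n)), paste0("s", 1:4))
  )
  x <- make_xset(v)
  p <- discriminating_score(x, ds_contrast(c("s1", "s2"), c("s3", "s4")))
  p <- smooth_scores(p, sprintf("g%03d", seq_len(n)), w = 1)
  p$smoothed <- smoothed
  p
}

test_that("find_peaks keeps wide runs above the threshold, sorted by apex", {
  # flat zero profile: nothing to call
  expect_equal(nrow(find_peaks(make_profile(rep(0, 100)), min_width = 5)), 0)

  # one bump
  sm <- rep(0.01, 200)
  sm[50:80] <- 1
  sm[65] <- 1.5
  pk <- find_peaks(make_profile(sm), threshold_quantile = 0.9, min_width = 10)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$apex_pos, 65)
  expect_equal(pk$direction, "under_in_mutant")

  # two bumps, the higher one first; narrow blips dropped
  sm2 <- rep(0.01, 300)
  sm2[40:70] <- -1
  sm2[55] <- -1.2
  sm2[200:230] <- 2
  sm2[215] <- 2.5
  sm2[280:282] <- 3
  pk2 <- find_peaks(make_profile(sm2), threshold_quantile = 0.8, min_width = 10)
  expect_equal(nrow(pk2), 2)
  expect_equal(pk2$apex_pos, c(215, 55))
  expect_equal(pk2$direction, c("under_in_mutant", "over_in_mutant"))
})

test_that("best node maximizes aligned DS among apex ancestors", {
  # 5 leaves; first three tightly clustered, DS (2.5,3,3.5,0,0):
  # the 3-leaf node strictly beats both the 2-leaf sub-node (mean 3 vs
  # 2.75) and its parent (mean 1.8)
  d <- matrix(1, 5, 5)
  diag(d) <- 0
  d[1:3, 1:3] <- 0.05
  diag(d) <- 0
  ids <- paste0("g", 1:5)
  dimnames(d) <- list(ids, ids)
  t <- average_linkage(d)

  v <- matrix(rnorm(20, 8), 5, 4, dimnames = list(ids, paste0("s", 1:4)))
  x <- make_xset(v)
  p <- discriminating_score(x, ds_contrast(c("s1", "s2"), c("s3", "s4")))
  p$ds <- c(2.5, 3, 3.5, 0, 0)
  p <- smooth_scores(p, leaf_order(t), w = 5)
  interval <- tibble::tibble(
    apex_gene = "g1", apex_smoothed = 3, direction = "under_in_mutant"
  )
  for (st in c("mean", "z")) {
    pk <- best_node_for_peak(t, p, interval,
      min_size = 2, max_size = 5, score_type = st
    )
    expect_setequal(pk$genes, c("g1", "g2", "g3"))
  }
  expect_error(
    best_node_for_peak(t, p, interval, min_size = 10),
    "size bounds"
  )
})

test_that("equal node scores break toward the smaller node", {
  # chain tree over 4 leaves with constant DS: every ancestor has the same
  # mean, so the smallest eligible ancestor must win
  d <- matrix(1, 4, 4)
  d[1, 2] <- d[2, 1] <- 0.1
  d[3, 4] <- d[4, 3] <- 0.8
  diag(d) <- 0
  ids <- paste0("g", 1:4)
  dimnames(d) <- list(ids, ids)
  t <- average_linkage(d)
  v <- matrix(rnorm(16, 8), 4, 4, dimnames = list(ids, paste0("s", 1:4)))
  x <- make_xset(v)
  p <- discriminating_score(x, ds_contrast(c("s1", "s2"), c("s3", "s4")))
  p$ds <- rep(2, 4)
  p <- smooth_scores(p, leaf_order(t), w = 2)
  interval <- tibble::tibble(
    apex_gene = "g1", apex_smoothed = 2, direction = "under_in_mutant"
  )
  pk <- best_node_for_peak(t, p, interval,
    min_size = 2, max_size = 4, score_type = "mean"
  )
  expect_setequal(pk$genes, c("g1", "g2"))
})

test_that("correlated core extraction recovers planted tight clusters", {
  # one latent profile with r ~ 0.95: the whole peak is the core
  set.seed(41)
  m <- 12
  ns <- 8
  z <- rnorm(ns, 0, 3)
  v <- matrix(rep(z, each = m), m, ns) + matrix(rnorm(m * ns, 0, 0.3), m, ns)
  dimnames(v) <- list(sprintf("g%02d", 1:m), paste0("s", 1:ns))
  x <- make_xset(v)
  p <- discriminating_score(x, ds_contrast(paste0("s", 1:4), paste0("s", 5:8)))
  p$ds <- rep(1, m)
  peak <- structure(
    list(genes = rownames(v), direction = "under_in_mutant"),
    class = "ds_peak"
  )
  expect_setequal(correlated_subcluster(x, peak, p, r_min = 0.9), rownames(v))

  # two tight, mutually uncorrelated halves of 10 and 6: the larger wins
  set.seed(42)
  z1 <- rnorm(ns, 0, 3)
  z2 <- rnorm(ns, 0, 3)
  v2 <- rbind(
    matrix(rep(z1, each = 10), 10, ns) + matrix(rnorm(10 * ns, 0, 0.3), 10),
    matrix(rep(z2, each = 6), 6, ns) + matrix(rnorm(6 * ns, 0, 0.3), 6)
  )
  dimnames(v2) <- list(sprintf("g%02d", 1:16), paste0("s", 1:ns))
  x2 <- make_xset(v2)
  p2 <- discriminating_score(x2, ds_contrast(paste0("s", 1:4), paste0("s", 5:8)))
  p2$ds <- rep(1, 16)
  peak2 <- structure(
    list(genes = rownames(v2), direction = "under_in_mutant"),
    class = "ds_peak"
  )
  expect_setequal(
    correlated_subcluster(x2, peak2, p2, r_min = 0.9),
    sprintf("g%02d", 1:10)
  )

  # no aligned cluster of size >= 3: empty with warning
  p2$ds <- rep(-1, 16) # wrong direction everywhere
  expect_warning(
    out <- correlated_subcluster(x2, peak2, p2, r_min = 0.9),
    "direction"
  )
  expect_length(out, 0)
})

test_that("gene-set intersection is sorted and handles edge cases", {
  expect_equal(intersect_genes(c("b", "a"), c("a", "b")), c("a", "b"))
  expect_length(intersect_genes(c("a"), c("b")), 0)
  expect_equal(intersect_genes(character(0), "a"), character(0))
})
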