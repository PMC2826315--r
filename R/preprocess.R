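#' LOWESS intensity-dependent normalization against a tissue median reference
#'
#' For each sample, M = log2(sample) - log2(reference) is regressed on
#' A = (log2(sample) + log2(reference)) / 2 by locally weighted regression
#' ([stats::lowess()]); the fitted intensity-dependent trend is subtracted
#' from the sample's log2 values. The reference for a sample is the gene-wise
#' median of log2 intensities across all samples of the same tissue (a
#' median pseudo-array, the standard single-channel choice). Output is on the
#' log2 scale.
#'
#' @param x an [xset()] on the raw scale, positive where unmasked
#' @param span lowess smoother span (fraction of points), default 0.4
#' @return an [xset()] on the log2 scale, same shape, gene ids and design
#' @export
lowess_normalize <- function(x, span = 0.4) {
  stopifnot(inherits(x, "xset"))
  if (x$log2) stop("lowess_normalize expects raw-scale intensities")
  v <- masked_values(x)
  if (any(v <= 0, na.rm = TRUE)) stop("raw intensities must be positive where unmasked")
  lv <- log2(v)
  out <- lv
  for (tis in unique(x$design$tissue)) {
    cols <- x$design$sample_id[x$design$tissue == tis]
    ref <- apply(lv[, cols, drop = FALSE], 1, median, na.rm = TRUE)
    for (s in cols) {
      ok <- !is.na(lv[, s]) & !is.na(ref)
      if (sum(ok) < 50) {
        stop("sample ", s, " has fewer than 50 unmasked genes; lowess fit unstable")
      }
      A <- (lv[ok, s] + ref[ok]) / 2
      M <- lv[ok, s] - ref[ok]
      fit <- lowess(A, M, f = span)
      trend <- approx(fit$x, fit$y, xout = A, rule = 2, ties = mean)$y
      out[ok, s] <- lv[ok, s] - trend
    }
  }
  vals <- x$values
  vals[!x$mask] <- out[!x$mask]
  vals[x$mask] <- NA_real_
  xset(vals, x$design, mask = x$mask, log2 = TRUE)
}

#' Mask spots not exceeding twice the mean local background
#'
#' Per sample, the threshold is 2 x the mean of that sample's per-spot local
#' background values; entries whose linear-scale intensity is <= threshold
#' are masked (a strict `>` keeps a spot). Genes masked in more than
#' `max_masked_frac` of samples are dropped entirely. Masking is monotone:
#' no entry is ever unmasked.
#'
#' @param x an [xset()]; raw or log2 scale (log2 values are compared on the
#'   linear scale as 2^value)
#' @param background numeric matrix of per-spot local background values,
#'   same shape as `x$values`, raw intensity units
#' @param max_masked_frac genes masked in more than this fraction of samples
#'   are dropped (default 0.5)
#' @return an [xset()] with updated mask, possibly fewer genes
#' @export
filter_background <- function(x, background, max_masked_frac = 0.5) {
  stopifnot(inherits(x, "xset"))
  if (!identical(dim(background), dim(x$values))) {
    stop("background must have the same shape as the expression matrix")
  }
  if (any(background < 0, na.rm = TRUE)) stop("background values must be non-negative")
  linear <- if (x$log2) 2^x$values else x$values
  thr <- 2 * colMeans(background, na.rm = TRUE)
  below <- sweep(linear, 2, thr, FUN = "<=")
  below[is.na(below)] <- TRUE
  mask <- x$mask | below
  keep <- rowMeans(mask) <= max_masked_frac
  if (!any(keep)) stop("all genes masked beyond max_masked_frac; nothing left")
  xset(
    x$values[keep, , drop = FALSE], x$design,
    mask = mask[keep, , drop = FALSE], log2 = x$log2
  )
}

#' Log2-transform a raw-scale expression set
#'
#' @param x an [xset()] on the raw scale with positive unmasked values
#' @return an [xset()] on the log2 scale; masked entries are left untouched
#'   and stay masked
#' @export
log_transform <- function(x) {
  stopifnot(inherits(x, "xset"))
  if (x$log2) stop("already on the log2 scale")
  v <- x$values
  un <- !x$mask & !is.na(v)
  if (any(v[un] <= 0)) stop("non-positive unmasked values cannot be log-transformed")
  v[un] <- log2(v[un])
  xset(v, x$design, mask = x$mask, log2 = TRUE)
}

#' Replicate-correlation quality control
#'
#' Pearson correlation over pairwise-complete genes for every pair of
#' replicate samples within the same (allele, tissue) group. Pairs with
#' r below `min_r` are flagged `low_correlation`; pairs with fewer than 10
#' common unmasked genes are flagged `uncomputable`.
#'
#' @param x an [xset()] on the log2 scale
#' @param min_r flagging threshold (default 0.7)
#' @return tibble with columns tissue, allele, sample_1, sample_2, n_genes,
#'   r, flag
#' @export
replicate_qc <- function(x, min_r = 0.7) {
  stopifnot(inherits(x, "xset"))
  if (!x$log2) stop("replicate_qc expects log2-scale values")
  v <- masked_values(x)
  groups <- x$design %>%
    group_by(tissue, allele) %>%
    summarise(samples = list(sample_id), .groups = "drop") %>%
    filter(map_int(samples, length) >= 2)
  rows <- list()
  for (i in seq_len(nrow(groups))) {
    ss <- groups$samples[[i]]
    for (a in seq_len(length(ss) - 1)) {
      for (b in (a + 1):length(ss)) {
        ok <- !is.na(v[, ss[a]]) & !is.na(v[, ss[b]])
        n_ok <- sum(ok)
        r <- if (n_ok >= 10) cor(v[ok, ss[a]], v[ok, ss[b]]) else NA_real_
        flag <- if (n_ok < 10) {
          "uncomputable"
        } else if (r < min_r) "low_correlation" else "ok"
        rows[[length(rows) + 1]] <- tibble(
          tissue = groups$tissue[i], allele = groups$allele[i],
          sample_1 = ss[a], sample_2 = ss[b],
          n_genes = n_ok, r = r, flag = flag
        )
      }
    }
  }
  bind_rows(rows)
}

#' Run the full preprocessing chain
#'
#' LOWESS normalization (which returns log2 values), then the background
#' filter, then replicate QC, mirroring the normalize / filter / log order
#' of the original protocol (the log transform happens inside normalization).
#'
#' @inheritParams lowess_normalize
#' @inheritParams filter_background
#' @inheritParams replicate_qc
#' @return list with `x` (log2-scale filtered [xset()]) and `qc` (tibble)
#' @export
preprocess <- function(x, background, span = 0.4, max_masked_frac = 0.5,
                       min_r = 0.7) {
  norm <- lowess_normalize(x, span = span)
  filt <- filter_background(norm, background, max_masked_frac = max_masked_frac)
  list(x = filt, qc = replicate_qc(filt, min_r = min_r))
}
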