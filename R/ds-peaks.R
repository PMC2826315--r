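#' Define a two-group contrast within one tissue
#'
#' `group1` is the reference (wild-type-like) group, `group2` the mutant
#' group. The Discriminating Score is DS = (M1 - M2) / SD, so negative DS
#' means overexpression in the mutant group.
#'
#' @param group1,group2 disjoint character vectors of sample ids, each with
#'   at least 2 samples
#' @param tissue tissue label for reporting
#' @return a `ds_contrast` list
#' @export
ds_contrast <- function(group1, group2, tissue = NA_character_) {
  group1 <- as.character(group1)
  group2 <- as.character(group2)
  if (length(intersect(group1, group2)) > 0) stop("contrast groups must be disjoint")
  if (length(group1) < 2 || length(group2) < 2) {
    stop("each contrast group needs at least 2 samples")
  }
  structure(
    list(group1 = group1, group2 = group2, tissue = tissue),
    class = "ds_contrast"
  )
}

#' Standard contrasts from a design table
#'
#' AMC: V1 against all other alleles; CNS: V1 against the V14 wild type only
#' (the other alleles behave differently in that tissue).
#'
#' @param design design tibble with sample_id, allele, tissue
#' @return named list of [ds_contrast()]s (one per tissue present)
#' @export
default_contrasts <- function(design) {
  design <- as_tibble(design)
  out <- list()
  if ("AMC" %in% design$tissue) {
    d <- design[design$tissue == "AMC", ]
    out$AMC <- ds_contrast(
      d$sample_id[d$allele != "V1"], d$sample_id[d$allele == "V1"], "AMC"
    )
  }
  if ("CNS" %in% design$tissue) {
    d <- design[design$tissue == "CNS", ]
    out$CNS <- ds_contrast(
      d$sample_id[d$allele == "V14"], d$sample_id[d$allele == "V1"], "CNS"
    )
  }
  out
}

#' Per-gene Discriminating Score for a contrast
#'
#' DS = (M1 - M2) / SD, with M1 the mean of the gene's unmasked values in
#' `group1`, M2 in `group2`, and SD the sample (n-1) standard deviation over
#' the union of both groups' unmasked values. Genes with |SD| below 1e-12
#' get DS = 0 and flag `"degenerate"`; genes unmasked in fewer than 2
#' samples of either group get DS = NA and flag `"insufficient"`.
#'
#' @param x an [xset()] on the log2 scale
#' @param contrast a [ds_contrast()]
#' @return a `ds_profile` object: tibble with gene_id, m1, m2, sd, ds, flag;
#'   the contrast is stored as an attribute
#' @export
discriminating_score <- function(x, contrast) {
  stopifnot(inherits(x, "xset"), inherits(contrast, "ds_contrast"))
  if (!x$log2) stop("discriminating_score expects log2-scale values")
  miss <- setdiff(c(contrast$group1, contrast$group2), x$design$sample_id)
  if (length(miss) > 0) stop("unknown sample ids: ", paste(miss, collapse = ", "))
  v <- masked_values(x)
  v1 <- v[, contrast$group1, drop = FALSE]
  v2 <- v[, contrast$group2, drop = FALSE]
  n1 <- rowSums(!is.na(v1))
  n2 <- rowSums(!is.na(v2))
  m1 <- rowMeans(v1, na.rm = TRUE)
  m2 <- rowMeans(v2, na.rm = TRUE)
  pooled <- cbind(v1, v2)
  sds <- apply(pooled, 1, sd, na.rm = TRUE)
  ds <- (m1 - m2) / sds
  flag <- rep("ok", nrow(v))
  deg <- !is.na(sds) & abs(sds) < 1e-12
  ds[deg] <- 0
  flag[deg] <- "degenerate"
  insuf <- n1 < 2 | n2 < 2
  ds[insuf] <- NA_real_
  flag[insuf] <- "insufficient"
  tbl <- tibble(
    gene_id = gene_ids(x), m1 = unname(m1), m2 = unname(m2),
    sd = unname(sds), ds = unname(ds), n1 = unname(n1), n2 = unname(n2),
    flag = flag
  )
  structure(tbl,
    class = c("ds_profile", class(tbl)),
    contrast = contrast, window = NA_integer_
  )
}

#' Smooth a DS profile along a dendrogram leaf order
#'
#' Each leaf-order position gets the mean raw DS over a centered sliding
#' window of `w` genes, truncated at the profile edges; missing DS values
#' are excluded from each window mean.
#'
#' @param profile a `ds_profile` from [discriminating_score()]
#' @param order character vector: leaf order covering all scored genes
#'   (see [leaf_order()])
#' @param w window size in genes (default 100)
#' @return the `ds_profile` reordered to `order`, with columns `position`
#'   and `smoothed` added
#' @export
smooth_scores <- function(profile, order, w = 100) {
  stopifnot(inherits(profile, "ds_profile"))
  n <- nrow(profile)
  if (w < 1 || w > n) stop("window w must be in [1, number of genes]")
  if (!setequal(order, profile$gene_id)) {
    stop("`order` must be a permutation of the profile's gene ids")
  }
  tbl <- profile[match(order, profile$gene_id), ]
  ds <- tbl$ds
  ok <- !is.na(ds)
  vals <- ifelse(ok, ds, 0)
  half_lo <- floor((w - 1) / 2)
  half_hi <- floor(w / 2)
  cs <- cumsum(c(0, vals))
  cn <- cumsum(c(0, as.numeric(ok)))
  i <- seq_len(n)
  lo <- pmax(1, i - half_lo)
  hi <- pmin(n, i + half_hi)
  counts <- cn[hi + 1] - cn[lo]
  sums <- cs[hi + 1] - cs[lo]
  sm <- ifelse(counts > 0, sums / counts, NA_real_)
  tbl$position <- i
  tbl$smoothed <- sm
  structure(tbl,
    class = class(profile),
    contrast = attr(profile, "contrast"), window = as.integer(w)
  )
}

#' Candidate peak intervals in a smoothed DS profile
#'
#' Candidates are maximal runs of positions where |smoothed DS| is at or
#' above a threshold (default the 90th percentile of |smoothed DS|), at
#' least `min_width` positions wide. Detection is deliberately liberal:
#' coherent-noise clusters produce smoothed bumps comparable to true
#' peaks, and the enrichment filter downstream is what separates them, so
#' the threshold's job is only to not miss real peaks. Each interval carries its apex (the
#' position of maximum |smoothed DS|) and the DS sign there. Intervals are
#' returned sorted by apex |smoothed DS|, descending. Positive apex DS means
#' underexpression in the mutant group (`under_in_mutant`), negative means
#' overexpression (`over_in_mutant`).
#'
#' @param profile a smoothed `ds_profile` (see [smooth_scores()])
#' @param threshold_quantile quantile of |smoothed DS| used as threshold
#'   (default 0.90)
#' @param min_width minimum interval width in genes (default 20)
#' @return tibble with columns start, end, apex_pos, apex_gene,
#'   apex_smoothed, direction (possibly 0 rows)
#' @export
find_peaks <- function(profile, threshold_quantile = 0.90, min_width = 20) {
  stopifnot(inherits(profile, "ds_profile"))
  if (!"smoothed" %in% names(profile)) stop("profile is not smoothed; run smooth_scores()")
  sm <- abs(profile$smoothed)
  thr <- quantile(sm, threshold_quantile, na.rm = TRUE, names = FALSE)
  above <- !is.na(sm) & sm >= thr & sm > 0
  empty <- tibble(
    start = integer(0), end = integer(0), apex_pos = integer(0),
    apex_gene = character(0), apex_smoothed = numeric(0),
    direction = character(0)
  )
  if (!any(above)) return(empty)
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values & runs$lengths >= min_width
  if (!any(keep)) return(empty)
  out <- map(which(keep), function(j) {
    s <- starts[j]; e <- ends[j]
    apex <- s + which.max(sm[s:e]) - 1L
    tibble(
      start = s, end = e, apex_pos = apex,
      apex_gene = profile$gene_id[apex],
      apex_smoothed = profile$smoothed[apex],
      direction = if (profile$smoothed[apex] < 0) "over_in_mutant" else "under_in_mutant"
    )
  })
  bind_rows(out) %>%
    arrange(desc(abs(apex_smoothed)))
}

#' Resolve a candidate interval to its best-fitting dendrogram node
#'
#' Every ancestor node of the apex leaf is scored on the raw DS of its
#' member leaves, sign-aligned with the peak direction. The default score
#' is the standardized aggregate mean(DS) * sqrt(min(m, w)) (m = leaves
#' with non-missing DS, w = the profile's smoothing window), which peaks at
#' the full co-expressed block: a plain mean is maximized by small noisy
#' sub-nodes of a homogeneous block, while the sqrt weight rewards extent
#' and punishes dilution by non-differential neighbours. The effective
#' evidence size is capped at one smoothing window because DS errors of
#' co-clustered genes are correlated at that scale — an uncapped sqrt(m)
#' lets large coherent-noise clusters outscore true blocks.
#' `score_type = "mean"` gives the plain mean. The best-scoring node within
#' the size bounds is selected; ties go to the smaller node.
#'
#' @param t a `gene_dendro` over the same genes as `profile`
#' @param profile a smoothed `ds_profile`
#' @param interval one row of [find_peaks()] output
#' @param min_size,max_size node size bounds (defaults 5 and 1000)
#' @param score_type `"z"` (default) or `"mean"`
#' @return a `ds_peak` object: list with `genes`, `node` (merge row),
#'   `direction`, `score`, `mean_ds`, `apex_gene`, `apex_smoothed`, `n`
#' @export
best_node_for_peak <- function(t, profile, interval, min_size = 5,
                               max_size = 1000, score_type = c("z", "mean")) {
  stopifnot(inherits(t, "gene_dendro"), inherits(profile, "ds_profile"))
  score_type <- match.arg(score_type)
  w_cap <- attr(profile, "window")
  if (is.null(w_cap) || is.na(w_cap)) w_cap <- t$n
  apex_gene <- interval$apex_gene
  leaf_idx <- match(apex_gene, t$labels)
  if (is.na(leaf_idx)) stop("apex gene not in dendrogram: ", apex_gene)
  dir_sign <- if (interval$direction == "over_in_mutant") -1 else 1

  # ancestor chain of the apex leaf through the merge matrix
  k <- nrow(t$merge)
  parent_of_leaf <- integer(t$n)
  parent_of_node <- integer(k)
  for (i in seq_len(k)) {
    for (v in t$merge[i, ]) {
      if (v < 0) parent_of_leaf[-v] <- i else parent_of_node[v] <- i
    }
  }
  chain <- integer(0)
  node <- parent_of_leaf[leaf_idx]
  while (node != 0) {
    chain <- c(chain, node)
    node <- parent_of_node[node]
  }

  leaves <- node_leaves(t)
  ds_by_gene <- setNames(profile$ds, profile$gene_id)
  best <- NULL
  for (nd in chain) {
    members <- t$labels[leaves[[nd]]]
    dsv <- ds_by_gene[members]
    m <- sum(!is.na(dsv))
    if (m < min_size || m > max_size) next
    mu <- mean(dir_sign * dsv, na.rm = TRUE)
    sc <- if (score_type == "z") mu * sqrt(min(m, w_cap)) else mu
    if (is.null(best) || sc > best$score ||
        (sc == best$score && m < best$n)) {
      best <- list(
        node = nd, genes = sort(members), score = sc, mean_ds = mu, n = m
      )
    }
  }
  if (is.null(best)) {
    stop(
      "no ancestor node within size bounds for interval with apex ",
      apex_gene
    )
  }
  structure(
    list(
      genes = best$genes, node = best$node, direction = interval$direction,
      score = best$score, mean_ds = best$mean_ds, n = best$n,
      apex_gene = apex_gene, apex_smoothed = interval$apex_smoothed
    ),
    class = "ds_peak"
  )
}

#' @export
print.ds_peak <- function(x, ...) {
  cat(sprintf(
    "<ds_peak> %d genes, %s, node score %.3f (mean DS %.3f), apex %s\n",
    length(x$genes), x$direction, x$score, x$mean_ds, x$apex_gene
  ))
  invisible(x)
}

#' Extract the highly correlated core of a peak
#'
#' Re-clusters the peak's member genes only (Pearson correlation distance,
#' average linkage) on the contrast tissue's samples — the within-tissue
#' correlation is what makes a strongly differential gene set cohere, since
#' a strong allele response alone drives within-tissue r above 0.9 — cuts
#' the new dendrogram at distance `1 - r_min`, and returns the largest
#' resulting cluster (of size >= 3) whose mean member DS has the peak's
#' direction. Returns an empty set with a warning when no such cluster
#' exists.
#'
#' @param x an [xset()] (log2 scale) holding at least the peak's genes
#' @param peak a `ds_peak`
#' @param profile the `ds_profile` used to call the peak (its contrast
#'   determines the tissue whose samples are used)
#' @param r_min correlation threshold (default 0.9)
#' @return character vector of gene ids (possibly empty)
#' @export
correlated_subcluster <- function(x, peak, profile, r_min = 0.9) {
  stopifnot(inherits(peak, "ds_peak"))
  if (length(peak$genes) < 3) stop("peak must have at least 3 member genes")
  contrast <- attr(profile, "contrast")
  tis <- if (!is.null(contrast) && !is.na(contrast$tissue) &&
             contrast$tissue %in% x$design$tissue) contrast$tissue else NULL
  sub <- xset_subset(x, genes = peak$genes, tissue = tis)
  d <- correlation_distance(sub)
  t <- average_linkage(d)
  cl <- cut_at_distance(t, 1 - r_min)
  dir_sign <- if (peak$direction == "over_in_mutant") -1 else 1
  ds_by_gene <- setNames(profile$ds, profile$gene_id)
  sizes <- sort(table(cl), decreasing = TRUE)
  for (cid in as.integer(names(sizes))) {
    members <- names(cl)[cl == cid]
    if (length(members) < 3) break
    if (mean(dir_sign * ds_by_gene[members], na.rm = TRUE) > 0) {
      return(sort(members))
    }
  }
  warning("no correlated cluster of size >= 3 in the peak's direction")
  character(0)
}

#' Intersect two gene sets
#'
#' @param a,b character vectors of gene ids
#' @return sorted character vector of the shared genes
#' @export
intersect_genes <- function(a, b) {
  sort(intersect(unique(as.character(a)), unique(as.character(b))))
}

#' Call, resolve and annotate peaks for one contrast
#'
#' Convenience wrapper: DS, smoothing along the dendrogram, candidate
#' intervals, node resolution, and (optionally) enrichment-based retention.
#'
#' @param x an [xset()] on the log2 scale
#' @param t a `gene_dendro` over the genes of `x`
#' @param contrast a [ds_contrast()]
#' @param w smoothing window (default 100)
#' @param threshold_quantile,min_width see [find_peaks()]
#' @param min_size,max_size,score_type see [best_node_for_peak()]
#' @param annotations optional gene/term tibble; when given, each peak gets
#'   enrichment results and `best_term` / `best_p` columns
#' @param universe gene universe for enrichment (default all genes of `x`)
#' @param alpha retention threshold on the best term p-value (default 0.001);
#'   only applied when annotations are given
#' @return list with `profile` (smoothed `ds_profile`), `candidates`
#'   (interval tibble), and `peaks`: tibble with peak_id, direction, n,
#'   score, mean_ds, apex_smoothed, interval bounds, genes (list-column),
#'   and enrichment columns when annotations were supplied (`retained`
#'   flags peaks passing `alpha`). Peaks are ordered by apex |smoothed DS|
#'   (the profile height that ranks peaks), descending.
#' @export
call_peaks <- function(x, t, contrast, w = 100, threshold_quantile = 0.90,
                       min_width = 20, min_size = 5, max_size = 1000,
                       score_type = "z", annotations = NULL,
                       universe = gene_ids(x), alpha = 0.001) {
  profile <- discriminating_score(x, contrast) %>%
    smooth_scores(leaf_order(t), w = w)
  candidates <- find_peaks(profile, threshold_quantile, min_width)
  peaks <- list()
  for (i in seq_len(nrow(candidates))) {
    pk <- tryCatch(
      best_node_for_peak(
        t, profile, candidates[i, ],
        min_size = min_size, max_size = max_size, score_type = score_type
      ),
      error = function(e) NULL
    )
    if (is.null(pk)) next
    row <- tibble(
      peak_id = NA_integer_, direction = pk$direction, n = pk$n,
      score = pk$score, mean_ds = pk$mean_ds, apex_gene = pk$apex_gene,
      apex_smoothed = candidates$apex_smoothed[i],
      start = candidates$start[i], end = candidates$end[i],
      genes = list(pk$genes)
    )
    if (!is.null(annotations)) {
      enr <- fisher_enrichment(pk$genes, universe, annotations)
      row$best_term <- if (nrow(enr) > 0) enr$term_id[1] else NA_character_
      row$best_p <- if (nrow(enr) > 0) enr$p[1] else 1
      row$enrichment <- list(enr)
    }
    peaks[[length(peaks) + 1]] <- row
  }
  peaks <- bind_rows(peaks)
  if (nrow(peaks) > 0) {
    # drop duplicate nodes (two candidate intervals can resolve to one node)
    peaks <- peaks[!duplicated(map_chr(peaks$genes, ~ paste(.x, collapse = ","))), ]
    peaks$peak_id <- seq_len(nrow(peaks))
    if (!is.null(annotations)) peaks$retained <- peaks$best_p < alpha
  }
  list(profile = profile, candidates = candidates, peaks = peaks)
}

#' Retain peaks with a significantly enriched term
#'
#' @param peaks peak tibble from [call_peaks()] (needs a `best_p` column)
#' @param alpha significance threshold on the best term's p-value
#'   (default 0.001)
#' @return the retained rows of `peaks`
#' @export
filter_significant_peaks <- function(peaks, alpha = 0.001) {
  if (nrow(peaks) == 0) return(peaks)
  if (!"best_p" %in% names(peaks)) stop("peaks carry no enrichment results")
  filter(peaks, best_p < alpha)
}
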