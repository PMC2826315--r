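#' Default 17-sample, two-tissue, four-allele design
#'
#' Two tissues (AMC, CNS) by four alleles ordered by phenotype severity
#' (V14 wild type, then V13, V24, V1). Replicates: 2 per allele and tissue,
#' except 3 for AMC V1 and the design totals 17 samples (one CNS wild-type
#' extraction is absent, as in the study design this emulates).
#'
#' @return tibble with columns sample_id, allele, tissue, replicate
#' @export
default_design <- function() {
  alloc <- tibble(
    tissue = rep(c("AMC", "CNS"), each = 4),
    allele = rep(c("V14", "V13", "V24", "V1"), 2),
    n = c(2, 2, 2, 3, 2, 2, 2, 2)
  )
  tidyr::uncount(alloc, n, .id = "replicate") %>%
    mutate(sample_id = sprintf("%s_%s_%d", tissue, allele, replicate)) %>%
    select(sample_id, allele, tissue, replicate)
}

#' Describe a planted block of co-expressed differential genes
#'
#' A block is a set of genes sharing (i) a differential shift of
#' `effect_size` log2 units on mutant (V1) samples of the block's tissue(s)
#' and (ii) a deterministic co-expression profile scaled so the expected
#' within-block pairwise Pearson correlation hits `within_correlation`.
#' Blocks with the same `cluster` label share the profile component and
#' therefore co-cluster (e.g. a shared AMC/CNS core plus tissue-only genes
#' inside one peak).
#'
#' @param size number of genes
#' @param tissue `"AMC"`, `"CNS"`, or `"both"` (differential in both tissues)
#' @param direction `"up_in_V1"` or `"down_in_V1"`
#' @param effect_size differential shift, log2 units (>= 0)
#' @param within_correlation target pairwise Pearson r in `[0, 1)`
#' @param go_term annotation term planted on this block's genes
#' @param carries_motif do this block's promoters carry the planted motif?
#' @param cluster label grouping blocks into one co-expression cluster;
#'   defaults to a block-specific label
#' @param cluster_correlation optional target correlation between this
#'   block's genes and the cluster's lead block (first block of the
#'   cluster). When set, the block loads only partially on the cluster
#'   profile and tops up its within-block correlation with a block-private
#'   profile, so within-block r can exceed the cross-block r (needed for a
#'   loose halo around a tight core). Default NULL: share the full cluster
#'   profile.
#' @param genes optional explicit gene ids (otherwise assigned automatically)
#' @return a `planted_block` list
#' @export
planted_block <- function(size, tissue = c("AMC", "CNS", "both"),
                          direction = c("up_in_V1", "down_in_V1"),
                          effect_size = 1, within_correlation = 0.9,
                          go_term = NULL, carries_motif = FALSE,
                          cluster = NULL, cluster_correlation = NULL,
                          genes = NULL) {
  tissue <- match.arg(tissue)
  direction <- match.arg(direction)
  stopifnot(size >= 1, effect_size >= 0)
  if (within_correlation < 0 || within_correlation >= 1) {
    stop("within_correlation must be in [0, 1)")
  }
  structure(
    list(
      size = as.integer(size), tissue = tissue, direction = direction,
      effect_size = effect_size, within_correlation = within_correlation,
      go_term = go_term, carries_motif = carries_motif,
      cluster = cluster, cluster_correlation = cluster_correlation,
      genes = genes
    ),
    class = "planted_block"
  )
}

#' Default planted blocks emulating the three-peak, shared-core structure
#'
#' Five blocks in three co-expression clusters. Cluster "peak1" holds a
#' 28-gene shared AMC/CNS core with a strong (8-fold) response in both
#' tissues — strong enough that the allele pattern alone makes the core
#' genes mutually correlated above r = 0.9 within each tissue, which is
#' what the within-peak r > 0.9 extraction keys on — plus 58 CNS-only
#' genes with an equally strong CNS response (so the CNS core holds ~86
#' genes of which 28 are shared) and 50 AMC-only genes with a moderate
#' response that widen the AMC peak but stay below the within-AMC core
#' cut. Two further AMC clusters give an underexpressed 40-gene peak and
#' a 26-gene peak with weak effects.
#'
#' @return list of `planted_block`s
#' @export
default_blocks <- function() {
  list(
    shared_core = planted_block(28, "both", "up_in_V1",
      effect_size = 3, within_correlation = 0.95,
      go_term = "GO:0045165", carries_motif = TRUE, cluster = "peak1"
    ),
    cns_peak1 = planted_block(58, "CNS", "up_in_V1",
      effect_size = 2.8, within_correlation = 0.9,
      go_term = "GO:0045165", cluster = "peak1"
    ),
    amc_peak1 = planted_block(50, "AMC", "up_in_V1",
      effect_size = 0.8, within_correlation = 0.9,
      go_term = "GO:0045165", cluster = "peak1",
      cluster_correlation = 0.45
    ),
    amc_peak2 = planted_block(40, "AMC", "down_in_V1",
      effect_size = 0.5, within_correlation = 0.9,
      go_term = "GO:0000502", cluster = "peak2"
    ),
    amc_peak3 = planted_block(26, "AMC", "up_in_V1",
      effect_size = 0.5, within_correlation = 0.9,
      go_term = "GO:0004871", cluster = "peak3"
    )
  )
}

#' Configuration for the synthetic-data generator
#'
#' Defaults emulate the study design: 5950 genes, 17 samples over two tissues
#' and four alleles, planted differential blocks with a 28-gene shared core,
#' a tissue signature, planted GO annotations, and 2000-bp promoters
#' (a -1700..+300 window) carrying a degenerate 10-mer with a CAGCTG core.
#'
#' @param n_genes number of genes
#' @param design sample design tibble (see [default_design()])
#' @param blocks list of [planted_block()]s
#' @param tissue_signature_size genes shifted between tissues in all alleles
#' @param tissue_signature_effect size of that shift, log2 units
#' @param baseline_mean,baseline_sd per-gene baseline log2 intensity
#' @param noise_sd residual per-entry noise sigma, log2 units
#' @param background_mean mean local background, raw intensity units
#' @param bias optional `list(intercept, slope, samples)` intensity-dependent
#'   bias injected per sample on the log2 scale: M shift = intercept +
#'   slope * A (for normalization testing); `samples = NULL` targets all
#' @param motif_consensus planted motif (default carries a CAGCTG core)
#' @param motif_mutation_rate per-position probability of mutating a planted
#'   site away from consensus
#' @param promoter_length promoter length, bp
#' @param gc_content background GC fraction
#' @param mask_rate per-bp rate of repeat-mask run starts
#' @param mask_mean_len mean masked run length, bp
#' @param go_n_terms number of background annotation terms
#' @param go_background_rate per gene-term background annotation probability
#' @param go_annotation_prob probability a block gene receives its planted term
#' @param seed integer seed; every generator is fully reproducible from it
#' @return a `synth_config` list
#' @export
synth_config <- function(n_genes = 5950, design = default_design(),
                         blocks = default_blocks(),
                         tissue_signature_size = 300,
                         tissue_signature_effect = 0.8,
                         baseline_mean = 9, baseline_sd = 1,
                         noise_sd = 0.35, background_mean = 16,
                         bias = NULL,
                         motif_consensus = "GTCAGCTGAC",
                         motif_mutation_rate = 0.1,
                         promoter_length = 2000, gc_content = 0.4,
                         mask_rate = 5e-4, mask_mean_len = 150,
                         go_n_terms = 50, go_background_rate = 0.01,
                         go_annotation_prob = 0.8, seed = 1) {
  stopifnot(
    noise_sd > 0, baseline_sd >= 0,
    motif_mutation_rate >= 0, motif_mutation_rate <= 1,
    gc_content > 0, gc_content < 1
  )
  design <- as_tibble(design)
  blocks <- check_blocks(blocks, n_genes, tissue_signature_size)
  structure(
    list(
      n_genes = as.integer(n_genes), design = design, blocks = blocks,
      tissue_signature_size = as.integer(tissue_signature_size),
      tissue_signature_effect = tissue_signature_effect,
      baseline_mean = baseline_mean, baseline_sd = baseline_sd,
      noise_sd = noise_sd, background_mean = background_mean, bias = bias,
      motif_consensus = toupper(motif_consensus),
      motif_mutation_rate = motif_mutation_rate,
      promoter_length = as.integer(promoter_length),
      gc_content = gc_content, mask_rate = mask_rate,
      mask_mean_len = mask_mean_len,
      go_n_terms = as.integer(go_n_terms),
      go_background_rate = go_background_rate,
      go_annotation_prob = go_annotation_prob,
      seed = as.integer(seed)
    ),
    class = "synth_config"
  )
}

# Validate blocks, assign gene ids, fill cluster labels.
check_blocks <- function(blocks, n_genes, signature_size) {
  if (length(blocks) == 0) return(blocks)
  if (is.null(names(blocks)) || any(names(blocks) == "")) {
    names(blocks) <- sprintf("block%d", seq_along(blocks))
  }
  total <- sum(map_int(blocks, ~ .x$size))
  if (n_genes < total + signature_size) {
    stop("n_genes must be >= sum of block sizes + tissue_signature_size")
  }
  all_ids <- sprintf("g%05d", seq_len(n_genes))
  taken <- character(0)
  next_free <- 1L
  for (nm in names(blocks)) {
    b <- blocks[[nm]]
    if (is.null(b$genes)) {
      b$genes <- all_ids[next_free:(next_free + b$size - 1L)]
      next_free <- next_free + b$size
    } else {
      b$genes <- as.character(b$genes)
      if (length(b$genes) != b$size) stop("block '", nm, "': genes != size")
    }
    if (length(intersect(b$genes, taken)) > 0) {
      stop("blocks overlap in gene ids (block '", nm, "')")
    }
    taken <- c(taken, b$genes)
    if (is.null(b$cluster)) b$cluster <- nm
    blocks[[nm]] <- b
  }
  blocks
}

# Deterministic per-sample profile patterns orthogonal to both contrasts:
# (1) tissue contrast, (2) CNS non-contrast alleles vs rest, (3) CNS V13 vs
# V24. These carry the shared variance that sets within-block correlation
# without touching either contrast's group means or pooled SD.
contrast_orthogonal_patterns <- function(design) {
  t1 <- as.numeric(design$tissue == "AMC")
  t2 <- as.numeric(design$tissue == "CNS" & design$allele %in% c("V13", "V24"))
  t3 <- (design$tissue == "CNS") *
    ((design$allele == "V13") - (design$allele == "V24"))
  # mean-centered so planted profiles do not shift genes' overall intensity
  # (keeps block genes inside the bulk intensity range the LOWESS fit covers)
  map(list(t1, t2, t3), ~ .x - mean(.x))
}

# Block-private patterns (replicate contrasts inside the CNS V13 / V24
# pairs): invisible to both contrasts and orthogonal to the cluster
# patterns; used to top up within-block correlation of halo blocks.
private_patterns <- function(design) {
  mk <- function(allele) {
    idx <- which(design$tissue == "CNS" & design$allele == allele)
    p <- numeric(nrow(design))
    if (length(idx) >= 2) p[idx[1:2]] <- c(1, -1)
    p - mean(p)
  }
  keep(list(mk("V13"), mk("V24")), ~ stats::var(.x) > 0)
}

# Differential indicator for a block: V1 samples of the block's tissue(s).
block_diff_pattern <- function(block, design) {
  tis <- if (block$tissue == "both") c("AMC", "CNS") else block$tissue
  s <- as.numeric(design$allele == "V1" & design$tissue %in% tis)
  if (block$direction == "down_in_V1") s <- -s
  s - mean(s) # centered: the shift moves groups apart, not the gene mean
}

check_contrast_groups <- function(design) {
  for (tis in intersect(c("AMC", "CNS"), unique(design$tissue))) {
    d <- design[design$tissue == tis, ]
    g2 <- sum(d$allele == "V1")
    g1 <- if (tis == "AMC") sum(d$allele != "V1") else sum(d$allele == "V14")
    if (g2 < 2 || g1 < 2) {
      stop("contrast groups for tissue ", tis, " need >= 2 samples each")
    }
  }
}

#' Generate a synthetic expression data set with recorded ground truth
#'
#' Produces raw (linear-scale) intensities 2^(baseline + planted structure +
#' noise), a per-spot local-background matrix, and a truth record sufficient
#' to score recovery of every downstream stage. Identical `(config, seed)`
#' give bit-identical output.
#'
#' Within-block correlation is induced by deterministic per-cluster sample
#' profiles orthogonal to both contrasts; the profile amplitude `a` solves
#' `a^2 var(p) + delta^2 var(d) = sigma^2 r/(1-r)` so the expected pairwise
#' within-block r equals the configured target while the block's contrast DS
#' stays at its design value.
#'
#' @param config a [synth_config()]
#' @return list with `raw` (an [xset()], raw scale), `background` (matrix),
#'   and `truth` (list: blocks with gene ids, signature genes, config echo)
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  design <- config$design
  check_contrast_groups(design)
  n <- config$n_genes
  m <- nrow(design)
  sigma <- config$noise_sd

  set.seed(config$seed)
  ids <- sprintf("g%05d", seq_len(n))
  baseline <- rnorm(n, config$baseline_mean, config$baseline_sd)
  log2v <- matrix(baseline, n, m) +
    matrix(rnorm(n * m, 0, sigma), n, m)
  dimnames(log2v) <- list(ids, design$sample_id)

  patterns <- contrast_orthogonal_patterns(design)
  clusters <- unique(map_chr(config$blocks, "cluster"))
  cluster_pattern <- setNames(
    patterns[((seq_along(clusters) - 1L) %% length(patterns)) + 1L],
    clusters
  )

  privates <- private_patterns(design)
  next_private <- 1L
  lead_alpha <- list() # per cluster: lead block's profile amplitude and block
  for (nm in names(config$blocks)) {
    b <- config$blocks[[nm]]
    d_pat <- block_diff_pattern(b, design)
    p_pat <- cluster_pattern[[b$cluster]]
    v_target <- sigma^2 * b$within_correlation / (1 - b$within_correlation)
    v_d <- stats::var(b$effect_size * d_pat)
    v_p <- stats::var(p_pat)
    use_private <- !is.null(b$cluster_correlation) &&
      !is.null(lead_alpha[[b$cluster]])
    if (use_private) {
      # partial loading beta on the cluster profile chosen so the expected
      # correlation with the lead block is cluster_correlation; the
      # remaining shared variance comes from a block-private pattern
      lead <- lead_alpha[[b$cluster]]
      var_b <- v_target + sigma^2
      var_l <- lead$v_shared + sigma^2
      cov_d <- stats::cov(b$effect_size * d_pat, lead$d_scaled)
      beta <- (b$cluster_correlation * sqrt(var_b * var_l) - cov_d) /
        (lead$alpha * v_p)
      beta <- max(0, beta)
      g2 <- v_target - v_d - beta^2 * v_p
      if (g2 < 0) {
        warning("block '", nm, "': cluster_correlation too high for its ",
                "within_correlation; private profile omitted")
        g2 <- 0
      }
      if (next_private > length(privates)) {
        stop("no private pattern left for block '", nm, "'")
      }
      q_pat <- privates[[next_private]]
      next_private <- next_private + 1L
      gam <- sqrt(g2 / stats::var(q_pat))
      z <- b$effect_size * d_pat + beta * p_pat + gam * q_pat
    } else {
      a2 <- v_target - v_d
      if (a2 < 0) {
        warning("block effect alone exceeds the correlation target; profile omitted")
        a2 <- 0
      }
      a <- if (v_p > 0) sqrt(a2 / v_p) else 0
      z <- b$effect_size * d_pat + a * p_pat
      if (is.null(lead_alpha[[b$cluster]])) {
        lead_alpha[[b$cluster]] <- list(
          alpha = a, v_shared = v_target, d_scaled = b$effect_size * d_pat
        )
      }
    }
    log2v[b$genes, ] <- log2v[b$genes, ] + rep(z, each = b$size)
  }

  sig_genes <- character(0)
  if (config$tissue_signature_size > 0) {
    used <- unlist(map(config$blocks, "genes"))
    free <- setdiff(ids, used)
    sig_genes <- free[seq_len(config$tissue_signature_size)]
    half <- rep(c(1, -1), length.out = length(sig_genes))
    t_pat <- patterns[[1]]
    log2v[sig_genes, ] <- log2v[sig_genes, ] +
      outer(half * config$tissue_signature_effect, t_pat)
  }

  if (!is.null(config$bias)) {
    bias <- config$bias
    targets <- if (is.null(bias$samples)) design$sample_id else bias$samples
    for (tis in unique(design$tissue)) {
      cols <- design$sample_id[design$tissue == tis]
      ref <- apply(log2v[, cols, drop = FALSE], 1, median)
      for (s in intersect(targets, cols)) {
        A <- (log2v[, s] + ref) / 2
        log2v[, s] <- log2v[, s] + bias$intercept + bias$slope * A
      }
    }
  }

  background <- matrix(
    rgamma(n * m, shape = 16, rate = 16 / config$background_mean), n, m,
    dimnames = dimnames(log2v)
  )

  truth <- list(
    n_genes = n,
    blocks = map(config$blocks, function(b) {
      b[c("genes", "tissue", "direction", "effect_size",
          "within_correlation", "go_term", "carries_motif", "cluster")]
    }),
    signature_genes = sig_genes,
    seed = config$seed
  )

  list(
    raw = xset(2^log2v, design, log2 = FALSE),
    background = background,
    truth = truth
  )
}

#' Generate a gene-to-term annotation table with planted enrichments
#'
#' Every gene receives each background term independently with
#' `go_background_rate`; each planted block's genes additionally receive the
#' block's term with `go_annotation_prob`.
#'
#' @param config a [synth_config()]
#' @param truth truth record from [simulate_expression()]
#' @return tibble with columns `gene_id`, `term_id` (unique rows, sorted)
#' @export
simulate_annotations <- function(config, truth) {
  stopifnot(inherits(config, "synth_config"))
  if (config$go_n_terms < 1) stop("go_n_terms must be >= 1")
  set.seed(config$seed + 1L)
  ids <- sprintf("g%05d", seq_len(config$n_genes))
  terms <- sprintf("T%03d", seq_len(config$go_n_terms))
  planted <- unique(unlist(map(truth$blocks, "go_term")))
  terms <- unique(c(terms, planted))

  hits <- matrix(
    runif(length(ids) * length(terms)) < config$go_background_rate,
    length(ids), length(terms), dimnames = list(ids, terms)
  )
  for (b in truth$blocks) {
    if (is.null(b$go_term)) next
    got <- runif(length(b$genes)) < config$go_annotation_prob
    hits[b$genes[got], b$go_term] <- TRUE
  }
  idx <- which(hits, arr.ind = TRUE)
  tibble(gene_id = ids[idx[, 1]], term_id = terms[idx[, 2]]) %>%
    arrange(gene_id, term_id)
}

#' Generate masked promoter sequences with one planted motif site each
#'
#' One promoter of `promoter_length` bp per gene of every motif-carrying
#' block: i.i.d. background at the configured GC content, contiguous
#' lowercase-masked runs (Poisson-placed starts, geometric lengths), and one
#' planted site per sequence — the consensus with each position mutated to a
#' random other base with probability `motif_mutation_rate`, placed uniformly
#' among fully unmasked windows. Planted sites never overlap masked
#' positions.
#'
#' @param config a [synth_config()]
#' @param truth truth record from [simulate_expression()]
#' @param genes optional explicit gene ids (overrides the motif-carrying
#'   block membership; useful for standalone motif benchmarks)
#' @return list with `sequences` (named character, lowercase = masked) and
#'   `truth` (input truth plus a `motif` record with per-sequence sites)
#' @export
simulate_promoters <- function(config, truth, genes = NULL) {
  stopifnot(inherits(config, "synth_config"))
  W <- nchar(config$motif_consensus)
  L <- config$promoter_length
  if (L < W) stop("promoter_length must be >= motif width")
  if (is.null(genes)) {
    genes <- unlist(map(keep(truth$blocks, ~ isTRUE(.x$carries_motif)), "genes"))
  }
  genes <- unique(as.character(genes))
  if (length(genes) == 0) {
    return(list(sequences = setNames(character(0), character(0)), truth = truth))
  }

  set.seed(config$seed + 2L)
  bases <- c("A", "C", "G", "T")
  pb <- c((1 - config$gc_content) / 2, config$gc_content / 2,
          config$gc_content / 2, (1 - config$gc_content) / 2)
  cons <- strsplit(config$motif_consensus, "")[[1]]
  if (!all(cons %in% bases)) stop("motif_consensus must be over ACGT")

  seqs <- character(length(genes))
  sites <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    chars <- sample(bases, L, replace = TRUE, prob = pb)
    mask <- rep(FALSE, L)
    n_runs <- stats::rpois(1, config$mask_rate * L)
    if (n_runs > 0) {
      starts <- sample.int(L, n_runs, replace = TRUE)
      lens <- stats::rgeom(n_runs, 1 / config$mask_mean_len) + 1L
      for (j in seq_len(n_runs)) {
        mask[starts[j]:min(L, starts[j] + lens[j] - 1L)] <- TRUE
      }
    }
    ok_start <- which(vapply(
      seq_len(L - W + 1L),
      function(s) !any(mask[s:(s + W - 1L)]), logical(1)
    ))
    if (length(ok_start) == 0) { # fully masked draw: clear the mask (rare)
      mask[] <- FALSE
      ok_start <- seq_len(L - W + 1L)
    }
    start <- if (length(ok_start) == 1) ok_start else sample(ok_start, 1)
    site <- cons
    mut <- runif(W) < config$motif_mutation_rate
    for (j in which(mut)) site[j] <- sample(setdiff(bases, cons[j]), 1)
    chars[start:(start + W - 1L)] <- site
    chars[mask] <- tolower(chars[mask])
    seqs[i] <- paste(chars, collapse = "")
    sites[[i]] <- tibble(
      gene_id = genes[i], start = start, site = paste(site, collapse = "")
    )
  }
  names(seqs) <- genes
  truth$motif <- list(
    consensus = config$motif_consensus,
    mutation_rate = config$motif_mutation_rate,
    sites = bind_rows(sites)
  )
  list(sequences = seqs, truth = truth)
}

#' Write synthetic data to disk as plain-text artifacts
#'
#' Writes the expression/design TSVs, background TSV, annotation TSV,
#' promoter FASTA (lowercase = masked) and truth JSON under `dir`.
#'
#' @param sim output of [simulate_expression()]
#' @param annotations tibble from [simulate_annotations()]
#' @param promoters output of [simulate_promoters()] (or NULL)
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_synthetic <- function(sim, annotations = NULL, promoters = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_xset(sim$raw, file.path(dir, "raw"))
  bg <- as_tibble(sim$background, rownames = "gene_id")
  readr::write_tsv(bg, file.path(dir, "background.tsv"))
  truth <- if (!is.null(promoters)) promoters$truth else sim$truth
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  if (!is.null(annotations)) {
    readr::write_tsv(annotations, file.path(dir, "annotations.tsv"))
  }
  if (!is.null(promoters) && length(promoters$sequences) > 0) {
    write_masked_fasta(promoters$sequences, file.path(dir, "promoters.fasta"))
  }
  invisible(dir)
}
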