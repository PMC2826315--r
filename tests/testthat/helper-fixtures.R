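# Small deterministic fixtures shared across test files.

# A minimal two-tissue design: 2 replicates everywhere, 3 for AMC V1.
small_design <- function() default_design()

# Expression set with known values: genes x samples matrix filled by hand.
make_xset <- function(values, log2 = TRUE, design = NULL) {
  if (is.null(design)) {
    design <- tibble::tibble(
      sample_id = colnames(values),
      allele = rep("V14", ncol(values)),
      tissue = rep("AMC", ncol(values)),
      replicate = seq_len(ncol(values))
    )
  }
  xset(values, design, log2 = log2)
}

# Single-block synthetic config at reduced size (fast tests).
one_block_config <- function(seed, n_genes = 2000, effect_size = 0.7,
                             r = 0.9, size = 40, tissue = "AMC") {
  synth_config(
    n_genes = n_genes, tissue_signature_size = 0, seed = seed,
    blocks = list(block = planted_block(size, tissue, "up_in_V1",
      effect_size = effect_size, within_correlation = r,
      go_term = "GO:TEST"
    ))
  )
}

# Promoter-only config: one motif-carrying block, no expression structure.
promoter_config <- function(seed, n_seqs = 50, mu = 0.1, length = 2000) {
  synth_config(
    n_genes = max(n_seqs + 10, 60), tissue_signature_size = 0, seed = seed,
    motif_mutation_rate = mu, promoter_length = length,
    blocks = list(m = planted_block(n_seqs, "both", "up_in_V1",
      effect_size = 0, carries_motif = TRUE
    ))
  )
}

# Brute-force O(n^3) average-linkage oracle: merges the closest pair of
# clusters, inter-cluster distance = mean of all cross-pair distances.
# Returns a list of merges: each with the two member sets and the height.
upgma_oracle <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  merges <- list()
  while (length(clusters) > 1) {
    k <- length(clusters)
    best <- c(NA, NA)
    best_d <- Inf
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        dd <- mean(d[clusters[[a]], clusters[[b]]])
        if (dd < best_d - 1e-12) {
          best_d <- dd
          best <- c(a, b)
        }
      }
    }
    merges[[length(merges) + 1]] <- list(
      a = sort(clusters[[best[1]]]), b = sort(clusters[[best[2]]]),
      height = best_d
    )
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  merges
}

# Convert an hclust-style merge matrix + heights into the same form.
merges_from_dendro <- function(t) {
  leaves <- node_leaves(t)
  lapply(seq_len(nrow(t$merge)), function(i) {
    ch <- t$merge[i, ]
    get <- function(v) if (v < 0) -v else leaves[[v]]
    list(a = sort(get(ch[1])), b = sort(get(ch[2])), height = t$height[i])
  })
}

# Exhaustive hypergeometric upper tail by summation of exact choose() terms.
hyper_tail_oracle <- function(k, K, N, n) {
  j <- k:min(n, K)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}
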