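#' Analysis parameters for the full pipeline
#'
#' One place for every stage's tunables, echoed into the run report.
#'
#' @param span lowess span for normalization
#' @param max_masked_frac gene-dropping threshold in the background filter
#' @param min_r replicate-QC flag threshold
#' @param w DS smoothing window (genes)
#' @param threshold_quantile,min_width candidate-peak detection knobs
#' @param min_size,max_size,score_type node-selection knobs
#' @param alpha enrichment retention threshold (best-term p-value)
#' @param r_min correlation threshold for the within-peak core
#' @param motif_width,n_runs,beta,d_max motif-stage knobs
#' @return a named list of parameters
#' @export
pipeline_params <- function(span = 0.4, max_masked_frac = 0.5, min_r = 0.7,
                            w = 100, threshold_quantile = 0.90,
                            min_width = 20, min_size = 5, max_size = 1000,
                            score_type = "z", alpha = 0.001, r_min = 0.9,
                            motif_width = 10, n_runs = 20, beta = 1,
                            d_max = 1) {
  as.list(environment())
}

#' Run the full analysis pipeline on synthetic data
#'
#' simulate -> preprocess (LOWESS, background filter, QC) -> cluster ->
#' per-tissue DS peaks with enrichment retention -> within-peak correlated
#' cores -> cross-tissue shared genes -> Gibbs motif discovery on the shared
#' genes' promoters. Every stage is seeded from `config$seed`, so a second
#' invocation with the same config reproduces the outputs byte-identically.
#' The ground truth is never consulted except by [score_run()].
#'
#' @param config a [synth_config()]
#' @param params a [pipeline_params()] list
#' @param outdir optional directory; when given, every stage artifact plus a
#'   JSON report is written there
#' @param verbose print stage progress messages
#' @return a `pipeline_run`: list with `config`, `params`, `truth`, `qc`,
#'   `dendro`, per-tissue `contrasts` results (profile, candidates, peaks),
#'   `cores`, `shared_genes`, `motif` (a `motif_summary` or NULL), `report`
#' @export
run_pipeline <- function(config = synth_config(), params = pipeline_params(),
                         outdir = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message("[dspeaks] ", sprintf(...))

  say("simulate: %d genes x %d samples", config$n_genes, nrow(config$design))
  sim <- simulate_expression(config)
  annotations <- simulate_annotations(config, sim$truth)
  prom <- simulate_promoters(config, sim$truth)
  truth <- prom$truth

  say("preprocess")
  prep <- preprocess(
    sim$raw, sim$background,
    span = params$span, max_masked_frac = params$max_masked_frac,
    min_r = params$min_r
  )
  x <- prep$x

  say("cluster %d surviving genes", nrow(x$values))
  dendro <- average_linkage(correlation_distance(x))

  contrasts <- default_contrasts(x$design)
  results <- list()
  cores <- list()
  for (tis in names(contrasts)) {
    say("peaks: %s contrast", tis)
    res <- call_peaks(
      x, dendro, contrasts[[tis]],
      w = min(params$w, nrow(x$values)),
      threshold_quantile = params$threshold_quantile,
      min_width = params$min_width, min_size = params$min_size,
      max_size = params$max_size, score_type = params$score_type,
      annotations = annotations, universe = gene_ids(x),
      alpha = params$alpha
    )
    results[[tis]] <- res
    retained <- filter_significant_peaks(res$peaks, alpha = params$alpha)
    if (nrow(retained) > 0) {
      # the top peak is the one with the highest smoothed-DS apex (the
      # profile height ranks peaks; node score only resolves a peak's node)
      top <- retained %>% arrange(desc(abs(apex_smoothed))) %>% slice(1)
      pk <- structure(
        list(
          genes = top$genes[[1]], node = NA, direction = top$direction,
          score = top$score, mean_ds = top$mean_ds, n = top$n,
          apex_gene = top$apex_gene, apex_smoothed = NA
        ),
        class = "ds_peak"
      )
      cores[[tis]] <- correlated_subcluster(
        x, pk, res$profile, r_min = params$r_min
      )
    } else {
      cores[[tis]] <- character(0)
    }
  }

  shared <- if (length(cores) >= 2) {
    Reduce(intersect_genes, cores)
  } else {
    character(0)
  }
  say("shared genes across tissues: %d", length(shared))

  motif <- NULL
  motif_seqs <- prom$sequences[intersect(shared, names(prom$sequences))]
  if (length(motif_seqs) >= 5 && params$n_runs >= 1) {
    say("motif discovery on %d promoters", length(motif_seqs))
    motif <- gibbs_motif_runs(
      masked_seqs(motif_seqs),
      width = params$motif_width, n_runs = params$n_runs,
      beta = params$beta, seed = config$seed + 100L, d_max = params$d_max
    )
  } else if (length(shared) > 0) {
    warning("fewer than 5 shared genes with promoters; motif stage skipped")
  } else {
    warning("empty shared-gene set; motif stage skipped")
  }

  report <- build_report(config, params, prep$qc, results, cores, shared, motif)
  run <- structure(
    list(
      config = config, params = params, truth = truth, x = x, qc = prep$qc,
      dendro = dendro, contrasts = results, cores = cores,
      shared_genes = shared, promoters = prom$sequences, motif = motif,
      annotations = annotations, report = report
    ),
    class = "pipeline_run"
  )
  if (!is.null(outdir)) write_run(run, outdir)
  run
}

build_report <- function(config, params, qc, results, cores, shared, motif) {
  peaks_out <- map(results, function(res) {
    pk <- res$peaks
    if (nrow(pk) == 0) return(list())
    map(seq_len(nrow(pk)), function(i) {
      list(
        peak_id = pk$peak_id[i], direction = pk$direction[i],
        n = pk$n[i], score = pk$score[i], mean_ds = pk$mean_ds[i],
        apex_smoothed = pk$apex_smoothed[i],
        best_term = if ("best_term" %in% names(pk)) pk$best_term[i] else NULL,
        best_p = if ("best_p" %in% names(pk)) pk$best_p[i] else NULL,
        retained = if ("retained" %in% names(pk)) pk$retained[i] else NULL,
        genes = pk$genes[[i]]
      )
    })
  })
  motif_out <- if (!is.null(motif)) {
    list(
      consensus = motif$consensus, support = motif$support,
      n_runs = motif$n_runs, best_score = motif$best$score,
      ic = motif$best$ic,
      sites = as.list(motif$best$sites)
    )
  }
  list(
    seed = config$seed,
    n_genes = config$n_genes,
    parameters = params[order(names(params))],
    qc = as.list(qc),
    peaks = peaks_out,
    cores = cores,
    shared_genes = shared,
    motif = motif_out
  )
}

#' Write every artifact of a pipeline run to a directory
#'
#' @param run a `pipeline_run`
#' @param outdir output directory (created if needed)
#' @return `outdir`, invisibly
#' @export
write_run <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(run$qc, file.path(outdir, "replicate_qc.tsv"))
  writeLines(dendro_newick(run$dendro), file.path(outdir, "dendrogram.nwk"))
  readr::write_tsv(
    tibble(position = seq_along(leaf_order(run$dendro)), gene_id = leaf_order(run$dendro)),
    file.path(outdir, "leaf_order.tsv")
  )
  for (tis in names(run$contrasts)) {
    res <- run$contrasts[[tis]]
    readr::write_tsv(
      as_tibble(res$profile),
      file.path(outdir, sprintf("ds_profile_%s.tsv", tis))
    )
    pk <- res$peaks
    if (nrow(pk) > 0) {
      flat <- pk %>%
        mutate(genes = map_chr(genes, ~ paste(.x, collapse = ","))) %>%
        select(-dplyr::any_of("enrichment"))
      readr::write_tsv(flat, file.path(outdir, sprintf("peaks_%s.tsv", tis)))
      if ("enrichment" %in% names(pk)) {
        enr <- bind_rows(setNames(pk$enrichment, pk$peak_id), .id = "peak_id")
        readr::write_tsv(enr, file.path(outdir, sprintf("enrichment_%s.tsv", tis)))
      }
    }
    if (length(run$cores[[tis]]) > 0) {
      writeLines(run$cores[[tis]], file.path(outdir, sprintf("core_genes_%s.txt", tis)))
    }
  }
  writeLines(run$shared_genes, file.path(outdir, "shared_genes.txt"))
  if (!is.null(run$motif)) {
    write_pwm_tsv(run$motif$best$pwm, file.path(outdir, "motif_pwm.tsv"))
    write_meme_motif(run$motif$best, file.path(outdir, "motif.meme"))
    readr::write_tsv(run$motif$best$sites, file.path(outdir, "motif_sites.tsv"))
    readr::write_tsv(
      tibble(column = seq_along(run$motif$best$ic), bits = run$motif$best$ic),
      file.path(outdir, "motif_ic.tsv")
    )
  }
  jsonlite::write_json(
    run$report, file.path(outdir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(outdir)
}

#' Score a pipeline run against the generator's ground truth
#'
#' Recall and precision of each tissue's top retained peak against the
#' best-matching planted block, recovery of the declared shared block by the
#' cross-tissue core intersection, and exactness of recovered motif sites.
#'
#' @param run a `pipeline_run`
#' @param truth a truth record (defaults to the run's own)
#' @return list with `peaks` (tibble per tissue), `shared` (recovered
#'   fraction of the shared block), `motif_site_accuracy` (fraction of
#'   planted sites recovered at the exact position, NA without a motif
#'   stage), `motif_consensus_hamming` (NA without a motif stage)
#' @export
score_run <- function(run, truth = run$truth) {
  rows <- list()
  for (tis in names(run$contrasts)) {
    pk <- run$contrasts[[tis]]$peaks
    retained <- if (nrow(pk) > 0 && "retained" %in% names(pk)) {
      filter(pk, retained)
    } else {
      pk
    }
    if (nrow(retained) == 0) {
      rows[[tis]] <- tibble(
        tissue = tis, block = NA_character_, n_peak = 0L,
        recall = NA_real_, precision = NA_real_
      )
      next
    }
    top <- retained %>% arrange(desc(abs(apex_smoothed))) %>% slice(1)
    genes <- top$genes[[1]]
    blocks <- keep(truth$blocks, ~ .x$tissue %in% c(tis, "both"))
    ov <- map_int(blocks, ~ length(intersect(.x$genes, genes)))
    b <- names(blocks)[which.max(ov)]
    bg <- blocks[[b]]$genes
    rows[[tis]] <- tibble(
      tissue = tis, block = b, n_peak = length(genes),
      recall = length(intersect(bg, genes)) / length(bg),
      precision = length(intersect(bg, genes)) / length(genes)
    )
  }
  shared_blocks <- keep(truth$blocks, ~ .x$tissue == "both")
  shared_truth <- unlist(map(shared_blocks, "genes"))
  shared_frac <- if (length(shared_truth) > 0) {
    length(intersect(shared_truth, run$shared_genes)) / length(shared_truth)
  } else {
    NA_real_
  }
  site_acc <- NA_real_
  cons_ham <- NA_real_
  if (!is.null(run$motif) && !is.null(truth$motif)) {
    found <- run$motif$best$sites
    planted <- truth$motif$sites
    j <- left_join(
      found, planted,
      by = c("sequence_id" = "gene_id"), suffix = c("_found", "_true")
    )
    site_acc <- mean(j$start_found == j$start_true, na.rm = TRUE)
    if (nchar(run$motif$consensus) == nchar(truth$motif$consensus)) {
      cons_ham <- hamming(run$motif$consensus, truth$motif$consensus)
    }
  }
  list(
    peaks = bind_rows(rows),
    shared = shared_frac,
    motif_site_accuracy = site_acc,
    motif_consensus_hamming = cons_ham
  )
}
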