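#' Tidy a DS profile
#' @param x a `ds_profile`
#' @param ... unused
#' @return plain tibble (gene_id, ds, flag, and position/smoothed when
#'   smoothed)
#' @export
tidy.ds_profile <- function(x, ...) {
  as_tibble(as.data.frame(x))
}

#' One-row summary of a DS profile
#' @param x a `ds_profile`
#' @param ... unused
#' @return tibble with tissue, n_genes, n_flagged, window, and the smoothed
#'   extremes (NA when not smoothed)
#' @export
glance.ds_profile <- function(x, ...) {
  contrast <- attr(x, "contrast")
  sm <- if ("smoothed" %in% names(x)) x$smoothed else NA_real_
  tibble(
    tissue = contrast$tissue,
    n_genes = nrow(x),
    n_flagged = sum(x$flag != "ok"),
    window = attr(x, "window"),
    max_smoothed = suppressWarnings(max(sm, na.rm = TRUE)),
    min_smoothed = suppressWarnings(min(sm, na.rm = TRUE))
  )
}

#' Tidy a PWM into long format
#' @param x a `pwm`
#' @param ... unused
#' @return tibble with position, base, freq
#' @export
tidy.pwm <- function(x, ...) {
  f <- unclass(x)
  tibble(
    position = rep(seq_len(ncol(f)), each = 4),
    base = rep(rownames(f), ncol(f)),
    freq = as.vector(f)
  )
}

#' Tidy a motif result into its site table
#' @param x a `motif_result`
#' @param ... unused
#' @return tibble with sequence_id, start, site
#' @export
tidy.motif_result <- function(x, ...) x$sites

#' One-row summary of a motif result
#' @param x a `motif_result`
#' @param ... unused
#' @return tibble with consensus, width, n_sites, score, total_ic, sweeps,
#'   converged
#' @export
glance.motif_result <- function(x, ...) {
  tibble(
    consensus = x$consensus, width = x$width, n_sites = nrow(x$sites),
    score = x$score, total_ic = sum(x$ic), sweeps = x$sweeps,
    converged = x$converged
  )
}

#' Tidy a multi-run motif summary into its per-run group table
#' @param x a `motif_summary`
#' @param ... unused
#' @return tibble with run, consensus, score, group
#' @export
tidy.motif_summary <- function(x, ...) x$groups

#' One-row summary of a multi-run motif summary
#' @param x a `motif_summary`
#' @param ... unused
#' @return tibble with consensus, support, n_runs, best_score
#' @export
glance.motif_summary <- function(x, ...) {
  tibble(
    consensus = x$consensus, support = x$support, n_runs = x$n_runs,
    best_score = x$best$score
  )
}

#' One-row summary of a pipeline run
#' @param x a `pipeline_run`
#' @param ... unused
#' @return tibble with genes surviving, retained peaks per tissue, core
#'   sizes, shared genes, motif consensus and support
#' @export
glance.pipeline_run <- function(x, ...) {
  n_retained <- map_int(x$contrasts, function(res) {
    pk <- res$peaks
    if (nrow(pk) == 0 || !"retained" %in% names(pk)) 0L else sum(pk$retained)
  })
  tibble(
    n_genes_surviving = nrow(x$x$values),
    n_retained_peaks = sum(n_retained),
    n_core_amc = length(x$cores$AMC %||% character(0)),
    n_core_cns = length(x$cores$CNS %||% character(0)),
    n_shared = length(x$shared_genes),
    motif_consensus = if (is.null(x$motif)) NA_character_ else x$motif$consensus,
    motif_support = if (is.null(x$motif)) NA_real_ else x$motif$support
  )
}
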