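#' Load repeat-masked promoter sequences
#'
#' Lowercase bases and `N`s follow the RepeatMasker convention: they are
#' flagged as masked and never contribute motif sites. IUPAC ambiguity
#' codes are accepted but treated as masked positions; any other character
#' is an error, as are duplicate ids.
#'
#' @param path FASTA file path
#' @return a `masked_seqs` object (list of per-sequence records with `id`,
#'   `seq` (uppercase string) and `mask` (logical, TRUE = masked))
#' @export
read_masked_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  masked_seqs(setNames(as.character(ss), names(ss)))
}

#' @rdname read_masked_fasta
#' @param sequences named character vector of sequences (lowercase = masked)
#' @export
masked_seqs <- function(sequences) {
  if (is.null(names(sequences)) || anyDuplicated(names(sequences))) {
    stop("sequences must have unique ids")
  }
  iupac <- c("A", "C", "G", "T", "N", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")
  recs <- imap(sequences, function(s, id) {
    chars <- strsplit(s, "")[[1]]
    up <- toupper(chars)
    if (!all(up %in% iupac)) {
      stop("non-IUPAC character in sequence ", id)
    }
    mask <- chars != up | !(up %in% c("A", "C", "G", "T"))
    list(id = id, seq = paste(up, collapse = ""), mask = mask)
  })
  structure(unname(recs), class = "masked_seqs")
}

#' @export
print.masked_seqs <- function(x, ...) {
  lens <- map_int(x, ~ nchar(.x$seq))
  cat(sprintf(
    "<masked_seqs> %d sequences, lengths %d..%d, %.1f%% masked\n",
    length(x), min(lens), max(lens),
    100 * mean(unlist(map(x, "mask")))
  ))
  invisible(x)
}

#' Write sequences with lowercase masking to FASTA
#'
#' @param sequences named character vector (lowercase = masked) or a
#'   `masked_seqs` object
#' @param path output file
#' @return `path`, invisibly
#' @export
write_masked_fasta <- function(sequences, path) {
  if (inherits(sequences, "masked_seqs")) {
    sequences <- setNames(
      map_chr(sequences, function(r) {
        chars <- strsplit(r$seq, "")[[1]]
        chars[r$mask] <- tolower(chars[r$mask])
        paste(chars, collapse = "")
      }),
      map_chr(sequences, "id")
    )
  }
  Biostrings::writeXStringSet(
    Biostrings::BStringSet(sequences), path, width = 80
  )
  invisible(path)
}

BASES <- c("A", "C", "G", "T")

# Integer-encode a masked_seqs object: codes 1..4, NA at masked positions;
# precompute legal window starts and the lookup-index matrix used by the
# sampler's scoring step.
encode_seqs <- function(seqs, width) {
  stopifnot(inherits(seqs, "masked_seqs"))
  enc <- map(seqs, function(r) {
    code <- match(strsplit(r$seq, "")[[1]], BASES)
    code[r$mask] <- NA_integer_
    L <- length(code)
    if (L < width) {
      return(list(id = r$id, code = code, starts = integer(0)))
    }
    ok <- !is.na(code)
    run <- stats::filter(as.numeric(ok), rep(1, width), sides = 1)
    starts <- which(run[width:L] == width)
    list(id = r$id, code = code, starts = starts)
  })
  dropped <- map_chr(enc, "id")[map_int(enc, ~ length(.x$starts)) == 0]
  if (length(dropped) > 0) {
    warning(
      "excluding sequence(s) with no fully unmasked window: ",
      paste(dropped, collapse = ", ")
    )
    enc <- keep(enc, ~ length(.x$starts) > 0)
  }
  if (length(enc) == 0) stop("no sequence has a legal window of width ", width)
  enc
}

#' Position weight matrix from aligned sites
#'
#' frequency(j, a) = (count(j, a) + beta * background(a)) / (n + beta):
#' the pseudocount is distributed according to the background composition.
#'
#' @param sites character vector of equal-length site strings (or a matrix
#'   of integer base codes, rows = sites)
#' @param beta total pseudocount (default 1)
#' @param background length-4 background probabilities (A, C, G, T),
#'   default uniform
#' @return a `pwm` object: 4 x W probability matrix (rows A, C, G, T) with
#'   `beta` and `background` attributes
#' @export
pwm_from_sites <- function(sites, beta = 1, background = rep(0.25, 4)) {
  stopifnot(beta >= 0, length(background) == 4)
  background <- background / sum(background)
  if (is.character(sites)) {
    if (length(sites) == 0) stop("empty site list")
    W <- unique(nchar(sites))
    if (length(W) != 1) stop("sites must all have the same length")
    codes <- t(matrix(
      vapply(strsplit(toupper(sites), ""), function(ch) match(ch, BASES),
        integer(W)
      ),
      nrow = W
    ))
    if (anyNA(codes)) stop("sites must be over ACGT")
  } else {
    codes <- sites
    if (nrow(codes) == 0) stop("empty site list")
    W <- ncol(codes)
  }
  counts <- vapply(
    seq_len(W),
    function(j) tabulate(codes[, j], nbins = 4), numeric(4)
  )
  freq <- (counts + beta * background) / (nrow(codes) + beta)
  structure(freq,
    dimnames = list(BASES, NULL),
    beta = beta, background = background, class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> width %d, consensus %s\n", ncol(x), pwm_consensus(x)))
  print(round(unclass(x), 3))
  invisible(x)
}

#' Consensus string of a PWM (most probable base per column)
#' @param pwm a `pwm`
#' @return character string of length `ncol(pwm)`
#' @export
pwm_consensus <- function(pwm) {
  paste(BASES[apply(unclass(pwm), 2, which.max)], collapse = "")
}

#' Per-column information content of a PWM, in bits
#'
#' IC(j) = sum_a f(j, a) log2(f(j, a) / background(a)), with 0 log 0 = 0.
#'
#' @param pwm a `pwm`
#' @param background length-4 background probabilities; defaults to the
#'   PWM's stored background
#' @return numeric vector of length `ncol(pwm)`
#' @export
info_content <- function(pwm, background = NULL) {
  f <- unclass(pwm)
  if (is.null(background)) background <- attr(pwm, "background")
  if (is.null(background)) background <- rep(0.25, 4)
  background <- background / sum(background)
  term <- f * log2(f / background)
  term[f == 0] <- 0
  colSums(term)
}

#' One-occurrence-per-sequence Gibbs motif sampler
#'
#' Searches `seqs` for a shared motif of width `width` under the OOPS model
#' (exactly one site per sequence). Initialization draws one site uniformly
#' among each sequence's fully unmasked windows. Each sweep visits the
#' sequences in random order; for each, a PWM is built from all other
#' sequences' current sites (predictive step) and a new site is sampled
#' with probability proportional to the window's product of f(j, base) /
#' background(base) (sampling step); windows overlapping masked positions
#' have probability zero. Every `shift_every` sweeps a deterministic phase
#' move shifts all sites together by the offset (within +/-3) that
#' maximizes the total log-odds score, countering the sampler's phase-drift
#' failure mode. Sampling stops after `max_iter` sweeps, or once no site has
#' changed for `patience` consecutive sweeps, or once the best total
#' log-odds score seen has not improved for `patience` sweeps (a sampler at
#' equilibrium keeps jittering individual sites, so a score plateau is the
#' practical convergence signal); the best-scoring site configuration seen
#' is returned. The background is the global unmasked mononucleotide
#' composition unless supplied. A fixed seed gives an identical trajectory.
#'
#' @param seqs a `masked_seqs` object (at least 2 usable sequences; the
#'   design target is 5 or more)
#' @param width motif width (default 10)
#' @param beta total pseudocount for the PWM (default 1)
#' @param background optional length-4 background probabilities
#' @param seed RNG seed
#' @param chains independent sampling chains per run; the best-scoring
#'   chain is returned (default 4 — nucleation from a uniform random start
#'   fails in a sizeable fraction of chains, so a run restarts internally)
#' @param max_iter maximum sweeps per chain (default 500)
#' @param patience stop a chain once the best score has not improved for
#'   this many sweeps (default 150)
#' @param shift_every phase-move period in sweeps (default 10)
#' @return a `motif_result`: list with `pwm`, `sites` (tibble sequence_id,
#'   start, site), `consensus`, `ic` (bits per column), `score` (sum of
#'   site log-odds), `sweeps`, `converged`
#' @export
gibbs_motif <- function(seqs, width = 10, beta = 1, background = NULL,
                        seed = 1, chains = 4, max_iter = 500,
                        patience = 150, shift_every = 10) {
  enc <- encode_seqs(seqs, width)
  ns <- length(enc)
  if (ns < 2) stop("need at least 2 usable sequences")
  if (is.null(background)) {
    comp <- tabulate(unlist(map(enc, "code")), nbins = 4)
    background <- comp / sum(comp)
  }
  background <- background / sum(background)
  if (any(background <= 0)) background <- (background + 1e-6) / sum(background + 1e-6)

  codes0 <- map(enc, function(e) {
    cd <- e$code
    cd[is.na(cd)] <- 0L
    as.integer(cd)
  })
  starts <- map(enc, ~ as.integer(.x$starts))

  set.seed(seed)
  best <- NULL
  sweeps_total <- 0L
  for (ch in seq_len(chains)) {
    res <- .gibbs_core(
      codes0, starts, as.integer(width), beta, background,
      as.integer(max_iter), as.integer(patience), as.integer(shift_every)
    )
    sweeps_total <- sweeps_total + res$sweeps
    if (is.null(best) || res$best_score > best$best_score) best <- res
  }

  pick <- best$pick
  site_start <- map_int(seq_len(ns), ~ enc[[.x]]$starts[pick[.x] + 1L])
  codes <- t(vapply(
    seq_len(ns),
    function(i) enc[[i]]$code[site_start[i]:(site_start[i] + width - 1L)],
    integer(width)
  ))
  pwm <- pwm_from_sites(codes, beta = beta, background = background)
  lr <- log(unclass(pwm)) - log(background)
  score <- sum(lr[cbind(as.vector(t(codes)), rep(seq_len(width), ns))])
  sites <- tibble(
    sequence_id = map_chr(enc, "id"),
    start = site_start,
    site = map_chr(seq_len(ns), ~ paste(BASES[codes[.x, ]], collapse = ""))
  )
  structure(
    list(
      pwm = pwm, sites = sites, consensus = pwm_consensus(pwm),
      ic = info_content(pwm), score = score, width = width,
      background = background, seed = seed, sweeps = sweeps_total,
      converged = isTRUE(best$converged)
    ),
    class = "motif_result"
  )
}

#' @export
print.motif_result <- function(x, ...) {
  cat(sprintf(
    "<motif_result> %s (width %d, %d sites, score %.1f, %d sweeps%s)\n",
    x$consensus, x$width, nrow(x$sites), x$score, x$sweeps,
    if (x$converged) ", converged" else ""
  ))
  invisible(x)
}

#' Hamming distance between two equal-length strings
#' @param a,b character strings of equal length
#' @return integer
#' @export
hamming <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  if (length(ca) != length(cb)) stop("strings must have equal length")
  sum(ca != cb)
}

#' Run the Gibbs sampler many times and keep the majority motif
#'
#' The sampler is stochastic, so it is restarted `n_runs` times from
#' different seeds; the motif identified in most runs is reported (see
#' [multi_run_consensus()]).
#'
#' @inheritParams gibbs_motif
#' @param n_runs number of independent restarts (default 20)
#' @param d_max Hamming tolerance for grouping run consensuses (default 1)
#' @param seed base seed; run r uses seed + r - 1
#' @return a `motif_summary` (see [multi_run_consensus()]) with the
#'   individual `runs` attached
#' @export
gibbs_motif_runs <- function(seqs, width = 10, n_runs = 20, beta = 1,
                             background = NULL, seed = 1, chains = 4,
                             max_iter = 500, patience = 150,
                             shift_every = 10, d_max = 1) {
  runs <- map(seq_len(n_runs), function(r) {
    gibbs_motif(
      seqs, width = width, beta = beta, background = background,
      seed = seed + r - 1L, chains = chains, max_iter = max_iter,
      patience = patience, shift_every = shift_every
    )
  })
  out <- multi_run_consensus(runs, d_max = d_max)
  out$runs <- runs
  out
}

#' Group run consensuses and report the majority motif
#'
#' Runs are sorted by score (best first) and greedily grouped: a run joins
#' the first existing group whose representative consensus is within
#' Hamming distance `d_max`, otherwise it founds a new group. Support is
#' the largest group's share of all runs; the returned motif is the
#' highest-scoring member of that group.
#'
#' @param results list of `motif_result`s of equal width
#' @param d_max Hamming tolerance (default 1)
#' @return a `motif_summary`: list with `consensus`, `support`, `best`
#'   (a `motif_result`), `n_runs`, and `groups` (tibble: consensus, score,
#'   group id per run)
#' @export
multi_run_consensus <- function(results, d_max = 1) {
  stopifnot(length(results) >= 1)
  widths <- unique(map_int(results, "width"))
  if (length(widths) != 1) stop("all runs must share the motif width")
  ord <- order(map_dbl(results, "score"), decreasing = TRUE)
  reps <- character(0)
  group <- integer(length(results))
  for (i in ord) {
    cons <- results[[i]]$consensus
    hit <- which(map_lgl(reps, ~ hamming(.x, cons) <= d_max))
    if (length(hit) == 0) {
      reps <- c(reps, cons)
      group[i] <- length(reps)
    } else {
      group[i] <- hit[1]
    }
  }
  sizes <- tabulate(group)
  top <- which.max(sizes)
  support <- sizes[top] / length(results)
  members <- which(group == top)
  best <- results[[members[which.max(map_dbl(results[members], "score"))]]]
  if (length(results) > 1 && sizes[top] == 1) {
    warning("all run consensuses are distinct beyond d_max; support is 1/n")
  }
  structure(
    list(
      consensus = best$consensus, support = support, best = best,
      n_runs = length(results),
      groups = tibble(
        run = seq_along(results),
        consensus = map_chr(results, "consensus"),
        score = map_dbl(results, "score"),
        group = group
      )
    ),
    class = "motif_summary"
  )
}

#' @export
print.motif_summary <- function(x, ...) {
  cat(sprintf(
    "<motif_summary> %s, support %.2f over %d runs (best score %.1f)\n",
    x$consensus, x$support, x$n_runs, x$best$score
  ))
  invisible(x)
}

#' Export a PWM as a tab-delimited 4 x W table
#' @param pwm a `pwm`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_pwm_tsv <- function(pwm, path) {
  tbl <- as_tibble(unclass(pwm), .name_repair = ~ sprintf("p%d", seq_along(.x)))
  tbl <- dplyr::bind_cols(tibble(base = BASES), tbl)
  readr::write_tsv(tbl, path)
  invisible(path)
}

#' Export a motif in MEME minimal format
#' @param result a `motif_result`
#' @param path output file
#' @param name motif name (default the consensus)
#' @return `path`, invisibly
#' @export
write_meme_motif <- function(result, path, name = result$consensus) {
  pwm <- unclass(result$pwm)
  bg <- result$background
  lines <- c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "strands: +", "",
    "Background letter frequencies",
    sprintf("A %.5f C %.5f G %.5f T %.5f", bg[1], bg[2], bg[3], bg[4]), "",
    sprintf("MOTIF %s", name),
    sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= %d",
      ncol(pwm), nrow(result$sites)
    ),
    apply(pwm, 2, function(col) sprintf("%.6f %.6f %.6f %.6f", col[1], col[2], col[3], col[4]))
  )
  writeLines(lines, path)
  invisible(path)
}
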