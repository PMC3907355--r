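#' Fit the null (background) model of IBD sharing from control pairs
#'
#' The null model for a putatively unrelated pair is: the number of IBD
#' segments of length >= t follows a Poisson distribution whose mean is the
#' control-cohort average count per pair, and segment lengths follow a
#' distribution fitted to the control segments above t. The default length
#' law is a shifted exponential on (length - t), whose maximum-likelihood
#' mean excess is the sample mean of (length - t); the retained empirical
#' sample is also stored for a histogram-density variant.
#'
#' Pairs listed in `control_pairs` but absent from `controls` count as
#' zero-segment pairs; the manifest must therefore list pairs, not just
#' segments, or the count mean is biased upward.
#'
#' @param controls [segment_set] of control-pair segments (IBD1; any IBD2
#'   rows are ignored for the count/length fit).
#' @param control_pairs data.frame with columns id1, id2 listing every
#'   control pair, or NULL to use the pairs present in `controls`.
#' @param t Minimum segment length in cM (default 2.5).
#' @return Object of class `background_model` with fields
#'   `segment_count_mean`, `length_mean_excess_cM` (mean of length - t),
#'   `length_mean_cM` (= t + mean excess), `t`, `n_pairs`,
#'   `empirical_lengths` and `degenerate` (TRUE when no control segment
#'   reaches t).
#' @export
fit_background <- function(controls, control_pairs = NULL, t = 2.5) {
  stopifnot(inherits(controls, "segment_set"), t >= 0)
  if (is.null(control_pairs)) {
    if (nrow(controls) == 0L)
      stop("estimation error: no control pairs and no control segments")
    control_pairs <- unique(data.frame(id1 = pmin(controls$id1, controls$id2),
                                       id2 = pmax(controls$id1, controls$id2)))
  }
  if (nrow(control_pairs) == 0L)
    stop("estimation error: control pair manifest is empty")
  keys <- pair_key(control_pairs$id1, control_pairs$id2)
  if (anyDuplicated(keys)) keys <- unique(keys)
  keep <- controls$length_cM >= t & controls$state == "IBD1"
  seg_keys <- pair_key(controls$id1[keep], controls$id2[keep])
  unknown <- !(seg_keys %in% keys)
  if (any(unknown))
    warning(sum(unknown), " control segment(s) from pairs not in the ",
            "manifest were ignored")
  seg_keys <- seg_keys[!unknown]
  lens <- controls$length_cM[keep][!unknown]
  counts <- table(factor(seg_keys, levels = keys))
  mu <- as.numeric(sum(counts)) / length(keys)
  if (length(lens) == 0L) {
    model <- list(segment_count_mean = 0, length_mean_excess_cM = NA_real_,
                  length_mean_cM = NA_real_, t = t, n_pairs = length(keys),
                  empirical_lengths = numeric(0), degenerate = TRUE)
    class(model) <- "background_model"
    warning("degenerate background model: no control segment reaches t = ", t,
            "; the null log-likelihood of any observed segment is -Inf")
    return(model)
  }
  theta <- mean(lens - t)
  model <- list(segment_count_mean = mu,
                length_mean_excess_cM = theta,
                length_mean_cM = t + theta,
                t = t, n_pairs = length(keys),
                empirical_lengths = lens,
                degenerate = FALSE)
  class(model) <- "background_model"
  model
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf(paste0("<background_model> t = %.3g cM; count mean %.4g ",
                     "segments/pair; mean excess %.4g cM (%d pairs%s)\n"),
              x$t, x$segment_count_mean,
              if (x$degenerate) NA else x$length_mean_excess_cM, x$n_pairs,
              if (x$degenerate) ", DEGENERATE" else ""))
  invisible(x)
}

#' Background length log-density (shifted exponential above t)
#'
#' @param l Segment lengths in cM, all >= t.
#' @param model A `background_model`.
#' @return Vector of log densities; -Inf everywhere for a degenerate model.
#' @export
background_length_logpdf <- function(l, model) {
  if (any(l < model$t - 1e-9))
    stop("contract violation: segment shorter than t in null likelihood")
  if (model$degenerate) return(rep(-Inf, length(l)))
  th <- model$length_mean_excess_cM
  -log(th) - (l - model$t) / th
}

#' Null log-likelihood of a pair's segments under the background model
#'
#' log P(n | Poisson(count mean)) + sum of log background length densities.
#'
#' @param lengths Numeric vector of the pair's segment lengths (cM), all
#'   >= t; may be empty.
#' @param model A `background_model`.
#' @return Log-likelihood (scalar).
#' @export
null_loglik <- function(lengths, model) {
  n <- length(lengths)
  if (model$degenerate) {
    return(if (n == 0L) 0 else -Inf)  # Poisson(0): P(0) = 1
  }
  stats::dpois(n, model$segment_count_mean, log = TRUE) +
    sum(background_length_logpdf(lengths, model))
}

#' Draw synthetic unrelated pairs from a background model
#'
#' Parametric sampler used for calibration and parametric-bootstrap checks:
#' each pair's segment count is Poisson(count mean) and lengths are
#' t + Exponential(mean excess).
#'
#' @param model A `background_model` (or a list with `segment_count_mean`,
#'   `length_mean_excess_cM`, `t`).
#' @param n_pairs Number of pairs to draw.
#' @return List of numeric length vectors, one per pair.
#' @export
simulate_background_pairs <- function(model, n_pairs) {
  stopifnot(n_pairs >= 1)
  ns <- stats::rpois(n_pairs, model$segment_count_mean)
  lens <- model$t + stats::rexp(sum(ns), rate = 1 / model$length_mean_excess_cM)
  f <- rep.int(seq_len(n_pairs), ns)
  out <- rep(list(numeric(0)), n_pairs)
  if (length(lens)) out[unique(f)] <- split(lens, f)
  out
}

#' Turn simulated per-pair length vectors into a segment set
#'
#' Places each segment uniformly at random on the genetic map (uniform in
#' cM, chromosome chosen with probability proportional to its length),
#' which matches the uniform-placement assumption of the excess-IBD scan.
#'
#' @param length_list List of numeric per-pair length vectors, as produced
#'   by [simulate_background_pairs()].
#' @param map [genetic_map].
#' @param ids Optional character vector of 2*length(length_list) individual
#'   ids; defaults to CTRL<i>a / CTRL<i>b.
#' @return A [segment_set].
#' @export
background_segment_set <- function(length_list, map, ids = NULL) {
  n <- length(length_list)
  if (is.null(ids)) {
    ids <- as.vector(rbind(sprintf("CTRL%04da", seq_len(n)),
                           sprintf("CTRL%04db", seq_len(n))))
  }
  stopifnot(length(ids) == 2L * n)
  chroms <- attr(map, "chromosomes")
  clen <- attr(map, "chrom_cM")
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    lens <- length_list[[i]]
    if (!length(lens)) next
    ch <- sample(chroms, length(lens), replace = TRUE, prob = clen)
    lo <- vapply(seq_along(lens), function(k) {
      a <- map[[ch[k]]]
      cmin <- a$cM[1L]; cmax <- a$cM[length(a$cM)]
      stats::runif(1, cmin, max(cmin, cmax - lens[k]))
    }, numeric(1))
    hi <- lo + lens
    # clamp to chromosome end (segments longer than the chromosome)
    cmax <- vapply(ch, function(cc) {
      a <- map[[cc]]; a$cM[length(a$cM)]
    }, numeric(1))
    hi <- pmin(hi, cmax)
    keep <- hi > lo
    if (!any(keep)) next
    sbp <- mapply(function(cc, x) interpolate_bp(map, cc, x), ch[keep], lo[keep])
    ebp <- mapply(function(cc, x) interpolate_bp(map, cc, x), ch[keep], hi[keep])
    rows[[i]] <- data.frame(id1 = ids[2L * i - 1L], id2 = ids[2L * i],
                            chrom = ch[keep], start_bp = sbp, end_bp = ebp,
                            start_cM = lo[keep], end_cM = hi[keep],
                            length_cM = hi[keep] - lo[keep], state = "IBD1")
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) as.data.frame(data.table::rbindlist(rows)) else
    data.frame(id1 = character(), id2 = character(), chrom = character(),
               start_bp = numeric(), end_bp = numeric(), start_cM = numeric(),
               end_cM = numeric(), length_cM = numeric(), state = character())
  attr(out, "pair_ids") <- data.frame(id1 = ids[seq(1, 2 * n, by = 2)],
                                      id2 = ids[seq(2, 2 * n, by = 2)])
  ss <- segment_set(out, provenance = "synthetic-background")
  attr(ss, "pair_ids") <- attr(out, "pair_ids")
  ss
}

#' Serialize / restore a background model as a key-value text file
#' @param model A `background_model`.
#' @param path File path.
#' @export
write_background <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("segment_count_mean\t%.10g", model$segment_count_mean),
    sprintf("length_mean_excess_cM\t%.10g", model$length_mean_excess_cM),
    sprintf("t\t%.10g", model$t),
    sprintf("n_pairs\t%d", model$n_pairs),
    sprintf("degenerate\t%d", as.integer(model$degenerate)),
    sprintf("empirical_lengths\t%s",
            paste(sprintf("%.6f", model$empirical_lengths), collapse = ","))),
    con)
  invisible(path)
}

#' @rdname write_background
#' @export
read_background <- function(path) {
  kv <- strsplit(readLines(path), "\t")
  vals <- stats::setNames(vapply(kv, function(x) x[2], character(1)),
                          vapply(kv, function(x) x[1], character(1)))
  lens <- if (nzchar(vals[["empirical_lengths"]]))
    as.numeric(strsplit(vals[["empirical_lengths"]], ",")[[1]]) else numeric(0)
  model <- list(
    segment_count_mean = as.numeric(vals[["segment_count_mean"]]),
    length_mean_excess_cM = as.numeric(vals[["length_mean_excess_cM"]]),
    length_mean_cM = as.numeric(vals[["t"]]) +
      as.numeric(vals[["length_mean_excess_cM"]]),
    t = as.numeric(vals[["t"]]),
    n_pairs = as.integer(vals[["n_pairs"]]),
    empirical_lengths = lens,
    degenerate = as.integer(vals[["degenerate"]]) == 1L)
  class(model) <- "background_model"
  model
}
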