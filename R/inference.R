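#' Maximized alternative log-likelihood for one hypothesis
#'
#' Under the alternative, np of the pair's n segments are attributed to the
#' hypothesized relationship (Poisson count, conditioned length law) and
#' the remaining n - np to the background. The likelihood is maximized
#' over np; for a given np the optimal attribution is the np longest
#' segments whenever the relationship's length law dominates the
#' background's in likelihood ratio (guarded by a brute-force oracle in the
#' test-suite for small n).
#'
#' @param lengths Numeric vector of the pair's IBD1 segment lengths (cM),
#'   all >= t (filter first).
#' @param hyp [relationship_hypothesis].
#' @param background `background_model`.
#' @param params [relate_params].
#' @return list(loglik, n_attributed).
#' @export
alternative_loglik <- function(lengths, hyp, background, params) {
  n <- length(lengths)
  cm <- conditioned_models(hyp, params)
  lambda <- cm$count_mean_geq_t
  mu <- background$segment_count_mean
  l_sorted <- sort(lengths, decreasing = TRUE)
  lp_rel <- if (n) cm$length_logpdf(l_sorted) else numeric(0)
  lp_bg <- if (n) background_length_logpdf(l_sorted, background) else numeric(0)
  cum_rel <- c(0, cumsum(lp_rel))              # np longest to relationship
  cum_bg <- c(0, cumsum(rev(lp_bg)))           # the rest to background
  np <- 0:n
  ll <- stats::dpois(np, lambda, log = TRUE) +
    stats::dpois(n - np, mu, log = TRUE) +
    cum_rel[np + 1L] + rev(cum_bg)[np + 1L]
  ll[is.nan(ll)] <- -Inf
  best <- which.max(ll)
  list(loglik = ll[best], n_attributed = np[best])
}

.format_confset <- function(cs) {
  if (nrow(cs) == 0L) return("")
  parts <- vapply(split(cs$d, cs$a), function(ds) {
    ds <- sort(unique(ds))
    runs <- split(ds, cumsum(c(1, diff(ds) != 1)))
    paste(vapply(runs, function(x)
      if (length(x) > 1) paste0(x[1], "-", x[length(x)]) else
        as.character(x), character(1)), collapse = ",")
  }, character(1))
  paste(sprintf("a%s:d%s", names(parts), parts), collapse = ";")
}

#' Classify one pair of individuals
#'
#' Evaluates the maximized log-likelihood of every hypothesis on the grid,
#' tests the best against the background-only null with a 2-df chi-square
#' likelihood-ratio test, and reports the hypothesis confidence set (all
#' (d, a) within chisq(confidence, df)/2 of the maximum). The
#' parent-offspring rule takes precedence when the genome-wide IBD
#' fraction exceeds its threshold. With `use_ibd2_siblings` and IBD2
#' segments present, the full-sibling hypothesis is evaluated with the
#' IBD2-aware model and every other hypothesis (and the null) carries the
#' null IBD2 term.
#'
#' @param pair_segments Either a [segment_set] holding one pair's segments
#'   (IBD1 rows, plus IBD2 rows for the IBD2-aware sibling model) or a
#'   numeric vector of IBD1 segment lengths in cM.
#' @param background `background_model`.
#' @param params [relate_params].
#' @param grid Optional list of hypotheses (default [hypothesis_grid()]).
#' @param total_cM Genome length used for the parent-offspring fraction
#'   (default 100 * r).
#' @return list of class `pair_result`: pair_id, best_d, best_a, family,
#'   degree, related, max_loglik, null_loglik, lrt, p_value, n_attributed,
#'   confidence_set (data.frame of d, a), total_ibd_cM.
#' @export
classify_pair <- function(pair_segments, background, params,
                          grid = NULL, total_cM = 100 * params$r) {
  if (is.null(grid)) grid <- hypothesis_grid(params)
  if (length(grid) == 0L) stop("parameter error: empty hypothesis grid")
  if (inherits(pair_segments, "segment_set") ||
      is.data.frame(pair_segments)) {
    is1 <- pair_segments$state == "IBD1"
    ibd1 <- pair_segments$length_cM[is1]
    ibd2 <- pair_segments$length_cM[!is1]
    if (params$use_ibd2_siblings && any(!is1)) {
      # ISCA-style reporting: every IBD2 row must lie within the extent of
      # some merged IBD1 row
      d2 <- pair_segments[!is1, , drop = FALSE]
      d1 <- pair_segments[is1, , drop = FALSE]
      for (k in seq_len(nrow(d2))) {
        inside <- d1$chrom == d2$chrom[k] &
          d1$start_cM <= d2$start_cM[k] + 1e-6 &
          d1$end_cM >= d2$end_cM[k] - 1e-6
        if (!any(inside))
          stop("input error: IBD2 segment outside any IBD1 extent")
      }
    }
    pid <- if (nrow(pair_segments))
      c(pair_segments$id1[1L], pair_segments$id2[1L]) else c(NA, NA)
  } else {
    ibd1 <- as.numeric(pair_segments)
    ibd2 <- numeric(0)
    pid <- c(NA, NA)
  }
  t <- params$t
  lengths <- ibd1[ibd1 >= t]
  total_ibd <- sum(ibd1)
  use_ibd2 <- params$use_ibd2_siblings && length(ibd2) > 0
  ibd2_term <- if (use_ibd2) {
    sibling_ibd2_loglik(ibd2[ibd2 >= t], total_ibd, params, background)
  } else c(alt = 0, null = 0)

  ll0 <- null_loglik(lengths, background) + ibd2_term[["null"]]
  lls <- numeric(length(grid))
  nps <- integer(length(grid))
  for (i in seq_along(grid)) {
    alt <- alternative_loglik(lengths, grid[[i]], background, params)
    extra <- if (use_ibd2 && grid[[i]]$family == "full_sibling")
      ibd2_term[["alt"]] else ibd2_term[["null"]]
    lls[i] <- alt$loglik + extra
    nps[i] <- alt$n_attributed
  }
  ds <- vapply(grid, `[[`, integer(1), "d")
  as <- vapply(grid, `[[`, integer(1), "a")
  best_ll <- max(lls)
  cand <- which(lls >= best_ll - 1e-9)
  best <- cand[order(ds[cand], as[cand])][1L]  # ties: smaller d (closer)
  lrt <- max(0, 2 * (best_ll - ll0))
  if (!is.finite(ll0) && is.finite(best_ll)) lrt <- Inf
  p <- stats::pchisq(lrt, df = 2, lower.tail = FALSE)
  crit <- stats::qchisq(params$confidence, df = params$profile_df) / 2
  in_set <- lls >= best_ll - crit
  confidence_set <- data.frame(d = ds[in_set], a = as[in_set])

  po <- is.finite(total_ibd) &&
    parent_offspring_test(min(1, total_ibd / total_cM), params)
  related <- po || p < params$alpha
  hyp <- if (po) relationship_hypothesis(1, 0) else grid[[best]]
  structure(list(
    id1 = pid[1L], id2 = pid[2L],
    best_d = if (related) hyp$d else NA_integer_,
    best_a = if (related) hyp$a else NA_integer_,
    family = if (related) hyp$family else "unrelated",
    degree = if (related) hyp$degree else NA_integer_,
    related = related,
    max_loglik = best_ll, null_loglik = ll0, lrt = lrt, p_value = p,
    n_attributed = nps[best],
    confidence_set = confidence_set,
    total_ibd_cM = total_ibd), class = "pair_result")
}

#' @export
print.pair_result <- function(x, ...) {
  cat(sprintf("<pair_result> %s-%s: %s%s (p = %.3g, LRT = %.2f, np = %d)\n",
              x$id1, x$id2, x$family,
              if (x$related) sprintf(" d=%d a=%d degree %d",
                                     x$best_d, x$best_a, x$degree) else "",
              x$p_value, x$lrt, x$n_attributed))
  invisible(x)
}

#' Classify every requested pair of a cohort
#'
#' @param segments [segment_set] for the whole cohort (the background must
#'   come from a disjoint or explicitly flagged control set).
#' @param pairs data.frame with columns id1, id2 of pairs to classify.
#' @param background `background_model`.
#' @param params [relate_params].
#' @param total_cM Genome length for the parent-offspring fraction.
#' @return data.frame (one row per pair, input order preserved) with the
#'   pair ids, best (d, a), family, degree, n_attributed, log-likelihoods,
#'   p-value and a compact confidence-set string.
#' @export
run_cohort <- function(segments, pairs, background, params,
                       total_cM = 100 * params$r) {
  stopifnot(is.data.frame(pairs), nrow(pairs) >= 1L)
  grid <- hypothesis_grid(params)
  keys <- pair_key(segments$id1, segments$id2)
  rows <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    k <- pair_key(pairs$id1[i], pairs$id2[i])
    seg <- segments[keys == k, , drop = FALSE]
    res <- classify_pair(segment_set(seg, attr(segments, "provenance")),
                         background, params, grid, total_cM)
    rows[[i]] <- data.frame(
      id1 = pairs$id1[i], id2 = pairs$id2[i],
      related = res$related, family = res$family,
      d = res$best_d, a = res$best_a, degree = res$degree,
      n_attributed = res$n_attributed,
      max_loglik = res$max_loglik, null_loglik = res$null_loglik,
      p_value = res$p_value,
      confidence_set = .format_confset(res$confidence_set),
      total_ibd_cM = res$total_ibd_cM)
  }
  out <- as.data.frame(data.table::rbindlist(rows))
  rownames(out) <- NULL
  out
}

#' Write cohort results as TSV
#' @param results data.frame from [run_cohort()].
#' @param path Output path.
#' @export
write_results <- function(results, path) {
  data.table::fwrite(results, path, sep = "\t")
  invisible(path)
}
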