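#' Model parameters for relationship inference
#'
#' Collects the tunable constants of the segment models. `r` is the
#' expected number of recombination events per generation (total map length
#' / 100; about 35 in humans, reduced by m/100 when masking is active via
#' [adjust_r()]); `c` the number of autosomes; `t` the minimum segment
#' length in cM; `z` the standard-deviation multiplier of the
#' parent-offspring rule; `h` and `b_mb` the masking threshold and flank;
#' `alpha` and `confidence` the test size and confidence level; `d_max` the
#' deepest relationship (total meioses) on the hypothesis grid;
#' `po_sigma` the standard deviation of the full-sibling genome-wide IBD
#' fraction (simulated constant, see the methods vignette);
#' `use_ibd2_siblings` switches on the IBD2-aware full-sibling model;
#' `profile_df` the chi-square degrees of freedom used for the confidence
#' set (2 by default).
#'
#' @return Object of class `relate_params`.
#' @export
relate_params <- function(r = 35, c = 22, t = 2.5, z = 2.33,
                        h = 4, b_mb = 1, alpha = 0.001, confidence = 0.999,
                        d_max = 15, po_sigma = SIGMA_SIB,
                        use_ibd2_siblings = FALSE, profile_df = 2) {
  stopifnot(r > 0, c >= 1, t >= 0, z >= 0, alpha > 0, alpha < 1,
            confidence > 0, confidence < 1, d_max >= 2,
            profile_df %in% c(1, 2))
  structure(list(r = r, c = c, t = t, z = z, h = h, b_mb = b_mb,
                 alpha = alpha, confidence = confidence, d_max = d_max,
                 po_sigma = po_sigma,
                 use_ibd2_siblings = isTRUE(use_ibd2_siblings),
                 profile_df = profile_df),
            class = "relate_params")
}

#' Standard deviation of the full-sibling genome-wide IBD fraction
#'
#' Constant used by the parent-offspring rule (threshold 0.75 + z * sigma).
#' Computed once from 10,000 gene-dropped sibling pairs on the default
#' 22-autosome, 3500-cM map (seed 104); see the methods vignette.
#' @export
SIGMA_SIB <- 0.04416

#' A relationship hypothesis (d meioses, a shared ancestors)
#'
#' `d` is the total number of meioses separating the pair along the path(s)
#' through the shared ancestor(s); `a` is the number of shared ancestors (0
#' for direct ancestor-descendant). The model family follows from (d, a):
#' parent-offspring (a=0, d=1), ancestor-descendant (a=0, d>1), full
#' sibling (a=2, d=2), avuncular (a=2, d=3), generic otherwise. The
#' conventional degree label is d - 1 when a = 2, else d (full siblings are
#' 1st degree; avuncular, grandparent and half-sibling are all 2nd).
#'
#' @param d Total meioses (integer >= 1).
#' @param a Shared ancestors: 0, 1 or 2.
#' @return Object of class `relationship_hypothesis` with fields d, a,
#'   family, degree.
#' @export
relationship_hypothesis <- function(d, a) {
  stopifnot(length(d) == 1L, length(a) == 1L, d >= 1, a %in% 0:2)
  if (d == 1L && a != 0) stop("d = 1 requires a = 0 (parent-offspring)")
  family <- if (a == 0 && d == 1) "parent_offspring"
  else if (a == 0) "ancestor_descendant"
  else if (a == 2 && d == 2) "full_sibling"
  else if (a == 2 && d == 3) "avuncular"
  else "generic"
  structure(list(d = as.integer(d), a = as.integer(a), family = family,
                 degree = as.integer(d - (a == 2))),
            class = "relationship_hypothesis")
}

#' @export
print.relationship_hypothesis <- function(x, ...) {
  cat(sprintf("<hypothesis> d=%d a=%d (%s, degree %d)\n",
              x$d, x$a, x$family, x$degree))
  invisible(x)
}

#' @export
format.relationship_hypothesis <- function(x, ...)
  sprintf("(d=%d,a=%d)", x$d, x$a)

#' Expected IBD segment length under a relationship hypothesis (cM)
#'
#' For a = 2 the exponential mean is 100/d (recombination alone breaks
#' segments; empirically preferable for full relatives). For a = 1 the
#' mean 100/(d + c/r) also accounts for breakage at chromosome boundaries,
#' and for ancestor-descendant relationships (a = 0, d > 1) the first
#' meiosis is invisible in a pairwise comparison, giving
#' 100/((d - 1) + c/r). As d grows the boundary-aware form converges to
#' 100/d from below.
#'
#' @param hyp [relationship_hypothesis].
#' @param params [relate_params].
#' @return Mean segment length in cM.
#' @export
mean_segment_length <- function(hyp, params) {
  d <- hyp$d; r <- params$r; c <- params$c
  if (hyp$a == 2L) 100 / d
  else if (hyp$a == 1L) 100 / (d + c / r)
  else if (d == 1L) 100 * r / c      # parent-offspring: whole chromosomes
  else 100 / ((d - 1) + c / r)
}

#' Expected number of IBD segments under a relationship hypothesis
#'
#' Generic form a(rd + c)/2^(d-1); ancestor-descendant form
#' (r(d-1) + c)/2^(d-1) (c whole chromosomes for parent-offspring at
#' d = 1). Full siblings are special because IBD2 regions merge flanking
#' IBD1 segments in detectors that do not distinguish states: the expected
#' number of merged segments is rd/2 + 3c/4 (d = 2), derived from the union
#' of the two per-parent sharing processes. The avuncular expectation
#' equals the full-sibling one exactly, for all r and c.
#'
#' @inheritParams mean_segment_length
#' @return Expected segment count (unconditioned on the minimum length t).
#' @export
mean_segment_count <- function(hyp, params) {
  d <- hyp$d; a <- hyp$a; r <- params$r; c <- params$c
  if (a == 0L) {
    if (d == 1L) c else (r * (d - 1) + c) / 2^(d - 1)
  } else if (a == 2L && d %in% c(2L, 3L)) {
    # full sibling (d=2) and avuncular (d=3): merged-segment expectation
    # of the sibling union process
    r * 2 / 2 + 3 * c / 4
  } else {
    a * (r * d + c) / 2^(d - 1)
  }
}

# Sibling merged-length mixture parameters. Pieces of the sibling union
# process are exponential with mean 100/(2d) = 25 cM at d = 2; with the
# chromosome-boundary hazard c/(100r) added to the piece exit rate (the
# same correction the exponential models apply), the piece scale becomes
# theta = 100/(2d + c/r). The continuation probability rho is then fixed
# by conservation -- mixture mean x expected merged count = sibling
# genome coverage (3/4) x 100r, the identity every other family
# satisfies -- giving rho = (M - theta)/(M + theta) with M the
# conservation mean. Both parameters reduce to the exact boundary-free
# law (theta = 25, rho = 1/2) as c/r -> 0.
.sib_mix <- function(params, boundary_aware = TRUE, d = 2) {
  if (!boundary_aware) return(list(theta = 100 / (2 * d), rho = 1 / 2))
  cr <- params$c / params$r
  theta <- 100 / (2 * d + cr)
  lam <- params$r * d / 2 + 3 * params$c / 4    # expected merged count
  M <- 0.75 * 100 * params$r / lam              # conservation mean
  list(theta = theta, rho = (M - theta) / (M + theta))
}

#' Full-sibling merged-segment length density (mixture of gammas)
#'
#' Detectors that do not distinguish IBD1 from IBD2 report, for full
#' siblings, merged segments in which k IBD2 regions have bridged k + 1
#' IBD1 stretches. A merged segment is an excursion of the
#' maternal-by-paternal sharing process: the number of bridges decays
#' geometrically, P(k) proportional to rho^k, and conditional on k the
#' length is the sum of 2k + 1 exponential pieces of scale theta, i.e.
#' Gamma(2k+1, theta). Summing over k gives the closed form
#' f(l) = (1 - rho) exp(-l/theta) cosh(l sqrt(rho)/theta) / theta.
#' Ignoring chromosome boundaries the law is exact with theta =
#' 100/(2d) = 25 cM and rho = 1/2 (each continuation event has
#' probability 1/2), with mean 75 cM. The default adds the
#' chromosome-boundary hazard to the pieces (theta = 100/(2d + c/r), rho
#' fixed by the count-times-mean conservation identity), which matches the
#' genome-wide distribution far better and is what the classifier uses.
#' Custom `weights` over k (e.g. all mass at k = 0, which reduces the
#' density to a plain exponential of scale theta) are supported for
#' diagnostics.
#'
#' @param l Lengths in cM.
#' @param params [relate_params] (the sibling structure d = 2 is used).
#' @param weights Optional numeric vector of mixture weights over
#'   k = 0, 1, ... (normalized internally); NULL for the geometric
#'   weights.
#' @param boundary_aware Use the boundary-corrected piece scale and
#'   continuation probability (default TRUE); FALSE gives the exact
#'   boundary-free law.
#' @return Log-density values.
#' @export
sibling_length_logpdf <- function(l, params, weights = NULL,
                                  boundary_aware = TRUE) {
  mx <- .sib_mix(params, boundary_aware)
  th <- mx$theta; rho <- mx$rho
  if (is.null(weights)) {
    # closed form of sum_k (1-rho) rho^k Gamma(l; 2k+1, th)
    b <- sqrt(rho) / th
    logcosh <- abs(l * b) + log1p(exp(-2 * abs(l * b))) - log(2)
    log1p(-rho) + logcosh - l / th - log(th)
  } else {
    w <- weights / sum(weights)
    dens <- vapply(l, function(x)
      sum(w * stats::dgamma(x, shape = 2 * seq_along(w) - 1, scale = th)),
      numeric(1))
    log(dens)
  }
}

#' @rdname sibling_length_logpdf
#' @param t Lower truncation point in cM.
#' @return `sibling_length_survival`: P(L >= t) under the mixture.
#' @export
sibling_length_survival <- function(t, params, boundary_aware = TRUE) {
  mx <- .sib_mix(params, boundary_aware)
  th <- mx$theta; s <- sqrt(mx$rho)
  a1 <- (1 - s) / th
  a2 <- (1 + s) / th
  (1 - mx$rho) / (2 * th) * (exp(-a1 * t) / a1 + exp(-a2 * t) / a2)
}

#' Log-likelihood of segments attributed to a relationship hypothesis
#'
#' Length densities conditioned on length >= t: exponential laws use the
#' memoryless form, the full-sibling mixture is renormalized by its
#' survival at t.
#'
#' @param l Lengths (cM), all >= t.
#' @param hyp [relationship_hypothesis].
#' @param params [relate_params].
#' @return Vector of conditioned log-densities.
#' @export
relationship_length_logpdf <- function(l, hyp, params) {
  t <- params$t
  if (any(l < t - 1e-9)) stop("contract violation: segment shorter than t")
  if (hyp$family == "full_sibling") {
    sibling_length_logpdf(l, params) - log(sibling_length_survival(t, params))
  } else {
    m <- mean_segment_length(hyp, params)
    -log(m) - (l - t) / m
  }
}

#' Conditioned count mean and length law for a hypothesis
#'
#' All formulas condition on segments reaching the minimum length t: the
#' Poisson count mean is multiplied by P(length >= t) under the
#' hypothesis's length law, and the length density is renormalized on
#' [t, Inf). At t = 0 both components are the identity.
#'
#' @inheritParams mean_segment_length
#' @return list(count_mean_geq_t, length_logpdf = function(l), p_geq_t).
#' @export
conditioned_models <- function(hyp, params) {
  t <- params$t
  p <- if (hyp$family == "full_sibling") {
    sibling_length_survival(t, params) / sibling_length_survival(0, params)
  } else {
    exp(-t / mean_segment_length(hyp, params))
  }
  list(count_mean_geq_t = mean_segment_count(hyp, params) * p,
       length_logpdf = function(l) relationship_length_logpdf(l, hyp, params),
       p_geq_t = p)
}

#' IBD2-aware full-sibling likelihood components
#'
#' With a detector that reports IBD2 segments separately (overlapping the
#' merged IBD1 segments), the full-sibling model adds an IBD2 term: under
#' the alternative, the number of IBD2 segments is Poisson with mean
#' rd/2 + c/4 (d = 2; 40.5 for r = 35, c = 22) and lengths are exponential
#' with mean 25 cM. Under the null, conditioned on the total merged IBD1
#' length T, the expected IBD2 count is the background count mean times
#' T/(100 r), and lengths follow the background law. Both sides condition
#' on length >= t.
#'
#' @param ibd2_lengths Numeric vector of IBD2 segment lengths (cM), >= t.
#' @param T_ibd1_cM Total merged IBD1 length of the pair in cM.
#' @param params [relate_params].
#' @param background `background_model`.
#' @return c(alt = ..., null = ...) log-likelihood contributions.
#' @export
sibling_ibd2_loglik <- function(ibd2_lengths, T_ibd1_cM, params, background) {
  t <- params$t; r <- params$r; c <- params$c
  n2 <- length(ibd2_lengths)
  m2 <- 100 / (2 * 2)                           # 25 cM at d = 2
  lambda2 <- (r * 2 / 2 + c / 4) * exp(-t / m2) # (2rd+c)/2^d at d=2, cond. on t
  alt <- stats::dpois(n2, lambda2, log = TRUE) +
    sum(-log(m2) - (ibd2_lengths - t) / m2)
  mu2 <- background$segment_count_mean * T_ibd1_cM / (100 * r)
  null <- if (background$degenerate || mu2 == 0) {
    if (n2 == 0L) 0 else -Inf
  } else {
    stats::dpois(n2, mu2, log = TRUE) +
      sum(background_length_logpdf(ibd2_lengths, background))
  }
  c(alt = alt, null = null)
}

#' Parent-offspring decision rule
#'
#' Parent-offspring pairs are IBD1 across the entire genome, so their total
#' IBD length is deterministic; the pair is called parent-offspring when
#' the genome-wide IBD fraction is at least z standard deviations above the
#' full-sibling expectation of 0.75. The sibling standard deviation
#' (`params$po_sigma`) is a simulated constant (see [SIGMA_SIB]).
#'
#' @param total_ibd_fraction Fraction of the genome covered by the pair's
#'   (IBD2-merged) segments, in [0, 1].
#' @param params [relate_params].
#' @return TRUE when the parent-offspring rule fires.
#' @export
parent_offspring_test <- function(total_ibd_fraction, params) {
  if (!is.numeric(total_ibd_fraction) || total_ibd_fraction < 0 ||
      total_ibd_fraction > 1 + 1e-9)
    stop("input error: total_ibd_fraction must be in [0, 1]")
  total_ibd_fraction >= 0.75 + params$z * params$po_sigma
}

#' The hypothesis grid enumerated by the classifier
#'
#' All (d, a) with d = 2..d_max and a in {0, 1, 2}; parent-offspring
#' (d = 1, a = 0) is handled by its deterministic rule rather than the
#' likelihood grid.
#'
#' @param params [relate_params].
#' @return List of [relationship_hypothesis] objects.
#' @export
hypothesis_grid <- function(params) {
  out <- list()
  for (a in 0:2) for (d in 2:params$d_max)
    out[[length(out) + 1L]] <- relationship_hypothesis(d, a)
  out
}
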