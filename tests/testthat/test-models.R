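params_default <- relate_params()

test_that("expected segment lengths follow the model family forms", {
  p <- params_default
  expect_equal(mean_segment_length(relationship_hypothesis(2, 2), p), 50)
  expect_equal(mean_segment_length(relationship_hypothesis(2, 0), p),
               100 / (1 + 22 / 35), tolerance = 1e-9)   # ~61.40 cM
  expect_equal(round(mean_segment_length(relationship_hypothesis(2, 0), p), 2),
               61.40)
  # boundary-aware mean converges to 100/d monotonically from below
  gap <- vapply(2:30, function(d)
    100 / d - mean_segment_length(relationship_hypothesis(d, 1), p),
    numeric(1))
  expect_true(all(gap > 0))
  expect_true(all(diff(gap) < 0))
  expect_lt(gap[length(gap)], 0.25)
})

test_that("expected segment counts: parent-offspring, cousins, avuncular", {
  p <- params_default
  po <- relationship_hypothesis(1, 0)
  expect_equal(mean_segment_count(po, p), 22)   # one segment per autosome
  # ... whose total expected length is the whole genome
  expect_equal(mean_segment_count(po, p) * mean_segment_length(po, p),
               3500, tolerance = 1e-9)
  expect_equal(mean_segment_count(relationship_hypothesis(4, 2), p),
               2 * (35 * 4 + 22) / 8)           # 40.5 expected segments
  # avuncular count equals the full-sibling count for all (r, c)
  set.seed(5)
  for (i in 1:10) {
    pp <- relate_params(r = runif(1, 20, 50), c = sample(15:30, 1))
    expect_equal(mean_segment_count(relationship_hypothesis(3, 2), pp),
                 mean_segment_count(relationship_hypothesis(2, 2), pp))
  }
})

test_that("conditioning on the minimum length t behaves as closed forms", {
  # r = c makes the grandparent mean exactly 50 cM
  p50 <- relate_params(r = 22, c = 22, t = 2.5)
  gp <- relationship_hypothesis(2, 0)
  expect_equal(mean_segment_length(gp, p50), 50)
  cm <- conditioned_models(gp, p50)
  expect_equal(cm$p_geq_t, exp(-2.5 / 50), tolerance = 1e-12)
  expect_equal(cm$count_mean_geq_t,
               mean_segment_count(gp, p50) * exp(-0.05), tolerance = 1e-9)

  # t = 0 is the identity on both components
  p0 <- relate_params(t = 0)
  cm0 <- conditioned_models(relationship_hypothesis(5, 2), p0)
  expect_equal(cm0$p_geq_t, 1)
  expect_equal(cm0$count_mean_geq_t,
               mean_segment_count(relationship_hypothesis(5, 2), p0))

  # conditioned densities integrate to 1 on [t, Inf)
  for (hyp in list(relationship_hypothesis(2, 2),
                   relationship_hypothesis(3, 2),
                   relationship_hypothesis(6, 1),
                   relationship_hypothesis(4, 0))) {
    q <- integrate(function(x)
      exp(relationship_length_logpdf(x, hyp, params_default)),
      params_default$t, Inf, rel.tol = 1e-9)
    expect_equal(q$value, 1, tolerance = 1e-6)
  }
})

test_that("the sibling merged-length mixture is a proper density", {
  p <- params_default
  # k forced to 0 reduces to the plain exponential of the piece scale
  l <- c(3, 10, 42)
  expect_equal(sibling_length_logpdf(l, p, weights = c(1),
                                     boundary_aware = FALSE),
               dexp(l, rate = 1 / 25, log = TRUE), tolerance = 1e-12)
  # closed form equals the explicit truncated mixture sum (rho = 1/2)
  w <- 0.5^(1:30)
  expect_equal(sibling_length_logpdf(l, p, boundary_aware = FALSE),
               sibling_length_logpdf(l, p, weights = w,
                                     boundary_aware = FALSE),
               tolerance = 1e-8)
  # both variants integrate to 1; survivals match numeric integration
  for (ba in c(TRUE, FALSE)) {
    q <- integrate(function(x) exp(sibling_length_logpdf(x, p,
                                                         boundary_aware = ba)),
                   0, Inf, rel.tol = 1e-10)
    expect_equal(q$value, 1, tolerance = 1e-8)
    q2 <- integrate(function(x) exp(sibling_length_logpdf(x, p,
                                                          boundary_aware = ba)),
                    2.5, Inf, rel.tol = 1e-10)
    expect_equal(q2$value, sibling_length_survival(2.5, p, boundary_aware = ba),
                 tolerance = 1e-8)
  }
})

test_that("simulated boundary-free sibling segments match the mixture (KS)", {
  # on a single very long chromosome, interior merged segments follow the
  # mixture law exactly; chromosome-end truncation is excluded by dropping
  # boundary-touching segments
  set.seed(31)
  map1 <- genetic_map(data.frame(chrom = "chr1", bp = c(0, 3500e6),
                                 cM = c(0, 3500)))
  lens <- c()
  while (length(lens) < 8000) {
    ss <- simulate_relative_pair(2, 2, map1, mode = "germline")
    interior <- ss$start_cM > 1e-9 & ss$end_cM < 3500 - 1e-9
    lens <- c(lens, ss$length_cM[interior])
  }
  p <- params_default
  cdf <- function(x) 1 - sibling_length_survival(x, p, boundary_aware = FALSE)
  ks <- suppressWarnings(ks.test(lens, cdf))
  expect_gt(ks$p.value, 0.01)
  # and the mixture mean (75 cM) matches the sample mean within 3 SE
  expect_lt(abs(mean(lens) - 75), 3 * sd(lens) / sqrt(length(lens)))
})

test_that("IBD2 sibling components: trivial cases and conservation", {
  p <- params_default
  bg <- default_background_generator()
  z <- sibling_ibd2_loglik(numeric(0), 0, p, bg)
  expect_equal(z[["null"]], 0)            # Poisson mean 0, zero segments
  expect_equal(z[["alt"]], -(35 * 2 / 2 + 22 / 4) * exp(-2.5 / 25))
  # boundary-free conservation: the interior start rate rd/2 alone accounts
  # for a quarter of the genome in segments of mean 25 cM; the c/4 term is
  # the boundary-start correction
  expect_equal((35 * 2 / 2) * 25, 0.25 * 3500, tolerance = 1e-9)
})

test_that("the parent-offspring rule fires on full-genome sharing only", {
  p <- params_default
  expect_true(parent_offspring_test(1.0, p))
  expect_false(parent_offspring_test(0.75, p))
  expect_false(parent_offspring_test(0.80, p))
  expect_error(parent_offspring_test(1.4, p), "input")
})

test_that("gene-dropping conservation oracle holds for every model family", {
  # For each (d, a): simulated mean total IBD length must equal the
  # Mendelian coverage expectation, and the simulated merged-segment count
  # must match the model's Poisson mean. All tested models are exact except
  # avuncular, whose count/length laws the method states as approximations
  # (documented allowance 6.5% on the count).
  set.seed(77)
  map <- make_synthetic_map()
  cases <- list(
    list(d = 1, a = 0, coverage = 1,      nrep = 40,  allow = 0),
    list(d = 2, a = 0, coverage = 0.5,    nrep = 600, allow = 0),
    list(d = 2, a = 2, coverage = 0.75,   nrep = 600, allow = 0),
    list(d = 3, a = 2, coverage = 0.5,    nrep = 600, allow = 0.065),
    list(d = 4, a = 2, coverage = 0.25,   nrep = 600, allow = 0),
    list(d = 6, a = 2, coverage = 0.0625, nrep = 600, allow = 0))
  p <- params_default
  total_cM <- map_total_cM(map)
  for (cs in cases) {
    counts <- numeric(cs$nrep); totals <- numeric(cs$nrep)
    for (i in seq_len(cs$nrep)) {
      ss <- simulate_relative_pair(cs$d, cs$a, map, mode = "germline")
      counts[i] <- nrow(ss)
      totals[i] <- sum(ss$length_cM)
    }
    lambda <- mean_segment_count(relationship_hypothesis(cs$d, cs$a), p)
    se_n <- stats::sd(counts) / sqrt(cs$nrep)
    se_l <- stats::sd(totals) / sqrt(cs$nrep)
    expect_lt(abs(mean(counts) - lambda), 3 * se_n + cs$allow * lambda + 1e-9,
              label = sprintf("count (d=%d,a=%d): sim %.2f vs model %.2f",
                              cs$d, cs$a, mean(counts), lambda))
    expect_lt(abs(mean(totals) - cs$coverage * total_cM), 3 * se_l + 1e-9,
              label = sprintf("total length (d=%d,a=%d)", cs$d, cs$a))
  }
  # algebraic conservation of the boundary-aware forms:
  # count * 100r/(rd+c) = coverage * total for the generic/half families,
  # and the ancestor-descendant pair (Eq-4/Eq-5 style) likewise
  r <- p$r; c <- p$c
  for (cs in cases[c(2, 5, 6)]) {
    lambda <- mean_segment_count(relationship_hypothesis(cs$d, cs$a), p)
    meanlen <- if (cs$a == 0) 100 / ((cs$d - 1) + c / r)
               else 100 / (cs$d + c / r)
    expect_equal(lambda * meanlen, cs$coverage * total_cM, tolerance = 1e-9)
  }
})
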