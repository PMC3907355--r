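# Shared fixtures, all built in code.

# deterministic two-chromosome map with a uniform 1 cM/Mb rate
tiny_map <- function() {
  genetic_map(data.frame(
    chrom = c("chr1", "chr1", "chr2", "chr2"),
    bp = c(0, 100e6, 0, 50e6),
    cM = c(0, 100, 0, 50)))
}

# one-chromosome linear map of the given genetic length (1 cM/Mb)
line_map <- function(total_cM = 3500) {
  genetic_map(data.frame(chrom = "chr1", bp = c(0, total_cM * 1e6),
                         cM = c(0, total_cM)))
}

# canonical segment row(s) on a linear 1 cM/Mb map
seg_row <- function(id1, id2, chrom, start_cM, end_cM, state = "IBD1") {
  data.frame(id1 = id1, id2 = id2, chrom = chrom,
             start_bp = start_cM * 1e6, end_bp = end_cM * 1e6,
             start_cM = start_cM, end_cM = end_cM,
             length_cM = end_cM - start_cM, state = state)
}

# control cohort covering the whole tiny_map genome uniformly (one pair)
uniform_controls <- function(map) {
  rows <- lapply(attr(map, "chromosomes"), function(ch) {
    a <- map[[ch]]
    seg_row("U1", "U2", ch, a$cM[1], a$cM[length(a$cM)])
  })
  segment_set(do.call(rbind, rows), "uniform")
}

# default synthetic background generator: study conditions for control
# cohorts (about 2 segments >= t per unrelated pair, mean excess 1 cM)
default_background_generator <- function(t = 2.5) {
  structure(list(segment_count_mean = 2, length_mean_excess_cM = 1,
                 length_mean_cM = t + 1, t = t, n_pairs = 0L,
                 empirical_lengths = numeric(0), degenerate = FALSE),
            class = "background_model")
}
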