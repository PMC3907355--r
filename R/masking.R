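#' Scan a control cohort for genomic windows with excess IBD
#'
#' Tiles the genome into contiguous windows of `window_cM` (the last window
#' of each chromosome may be shorter) and compares, per window, the observed
#' total IBD length of all control-pair segments (truncated at window
#' boundaries) with the length expected if pairwise IBD were distributed
#' uniformly across the genome. The expected length of a window is the
#' genome-wide observed total times window_length / total_cM, so summing
#' observed over all windows conserves the cohort total exactly.
#'
#' @param controls [segment_set] of control-pair segments (all segments are
#'   used; the scan precedes any minimum-length thresholding).
#' @param map [genetic_map].
#' @param window_cM Window width in cM (default 0.5).
#' @return data.frame with one row per window: chrom, start_cM, end_cM,
#'   start_bp, end_bp, observed_cM, expected_cM, ratio (0 where expected is
#'   0).
#' @export
excess_ibd_scan <- function(controls, map, window_cM = 0.5) {
  stopifnot(inherits(controls, "segment_set"), window_cM > 0)
  if (nrow(controls) == 0L)
    stop("estimation error: control segment set is empty")
  chroms <- attr(map, "chromosomes")
  total_cM <- attr(map, "total_cM")
  total_obs <- sum(controls$length_cM)
  out <- lapply(chroms, function(ch) {
    a <- map[[ch]]
    lo <- a$cM[1L]; hi <- a$cM[length(a$cM)]
    brk <- seq(lo, hi, by = window_cM)
    if (brk[length(brk)] < hi) brk <- c(brk, hi)
    ws <- brk[-length(brk)]; we <- brk[-1L]
    obs <- numeric(length(ws))
    seg <- controls[controls$chrom == ch, , drop = FALSE]
    if (nrow(seg)) {
      # overlap of each segment with each window, accumulated per window
      i1 <- findInterval(seg$start_cM, brk, rightmost.closed = TRUE)
      i2 <- findInterval(seg$end_cM, brk, left.open = TRUE,
                         rightmost.closed = TRUE)
      i1 <- pmax(1L, pmin(i1, length(ws)))
      i2 <- pmax(1L, pmin(i2, length(ws)))
      for (k in seq_len(nrow(seg))) {
        w <- i1[k]:i2[k]
        ov <- pmin(seg$end_cM[k], we[w]) - pmax(seg$start_cM[k], ws[w])
        obs[w] <- obs[w] + pmax(0, ov)
      }
    }
    data.frame(chrom = ch, start_cM = ws, end_cM = we,
               start_bp = interpolate_bp(map, ch, ws),
               end_bp = interpolate_bp(map, ch, we),
               observed_cM = obs,
               expected_cM = total_obs * (we - ws) / total_cM)
  })
  out <- as.data.frame(data.table::rbindlist(out))
  out$ratio <- ifelse(out$expected_cM > 0, out$observed_cM / out$expected_cM, 0)
  out
}

#' Build a mask from an excess-IBD window scan
#'
#' Windows whose observed/expected ratio exceeds the threshold `h` are
#' selected and adjacent selected windows on a chromosome are coalesced into
#' single regions. Each region reports the length-weighted mean ratio of
#' its windows.
#'
#' @param scan Window table from [excess_ibd_scan()].
#' @param h Ratio threshold (default 4).
#' @return data.frame of class `ibd_mask` with columns chrom, start_bp,
#'   end_bp, length_cM, ratio; regions are sorted and non-overlapping.
#' @export
build_mask <- function(scan, h = 4) {
  if (!is.numeric(h) || h <= 0) stop("parameter error: h must be > 0")
  sel <- scan$ratio > h
  empty <- data.frame(chrom = character(), start_bp = numeric(),
                      end_bp = numeric(), length_cM = numeric(),
                      ratio = numeric())
  if (!any(sel)) return(structure(empty, class = c("ibd_mask", "data.frame")))
  s <- scan[sel, , drop = FALSE]
  s <- s[order(s$chrom, s$start_cM), , drop = FALSE]
  new_run <- c(TRUE, s$chrom[-1L] != s$chrom[-nrow(s)] |
                 abs(s$start_cM[-1L] - s$end_cM[-nrow(s)]) > 1e-9)
  run <- cumsum(new_run)
  out <- lapply(split(seq_len(nrow(s)), run), function(idx) {
    d <- s[idx, , drop = FALSE]
    w <- d$end_cM - d$start_cM
    data.frame(chrom = d$chrom[1L],
               start_bp = d$start_bp[1L],
               end_bp = d$end_bp[nrow(d)],
               length_cM = sum(w),
               ratio = sum(d$ratio * w) / sum(w))
  })
  out <- as.data.frame(data.table::rbindlist(out))
  out <- out[order(out$chrom, out$start_bp), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("ibd_mask", "data.frame"))
}

#' Read / write a mask as a BED-like TSV
#'
#' Columns: chrom, start_bp, end_bp, length_cM, ratio (tab-delimited, with
#' header). `length_cM` is the genetic length of the region and `ratio` the
#' observed/expected IBD ratio that triggered masking.
#'
#' @param path File path.
#' @return An `ibd_mask` data.frame.
#' @export
read_mask <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t", data.table = FALSE)
  need <- c("chrom", "start_bp", "end_bp", "length_cM", "ratio")
  if (!all(need %in% names(dt)))
    stop("mask file must have columns: ", paste(need, collapse = ", "))
  dt <- dt[order(dt$chrom, dt$start_bp), need, drop = FALSE]
  structure(dt, class = c("ibd_mask", "data.frame"))
}

#' @rdname read_mask
#' @param mask An `ibd_mask`.
#' @export
write_mask <- function(mask, path) {
  data.table::fwrite(as.data.frame(mask), path, sep = "\t")
  invisible(path)
}

#' Total masked genetic length, m (cM)
#' @param mask An `ibd_mask`.
#' @export
mask_total_cM <- function(mask) if (nrow(mask)) sum(mask$length_cM) else 0

#' Apply a mask to a segment set
#'
#' For each segment, masked regions are handled with three rules, applied
#' left-to-right along the chromosome:
#' \enumerate{
#'   \item a segment that wholly contains a region and extends at least
#'     `b_mb` megabases past both region ends keeps its extent but its
#'     `length_cM` is reduced by the region's genetic length;
#'   \item any other segment crossing a region boundary is truncated at the
#'     boundary, retaining the portion outside the region (when both flanks
#'     are outside but shorter than `b_mb`, the longer flank is retained;
#'     remnants that still cross another region are re-processed);
#'   \item segments entirely inside a region are removed.
#' }
#' The function never increases a segment's length or the segment count.
#'
#' @param segments A [segment_set].
#' @param mask An `ibd_mask` (sorted, non-overlapping regions).
#' @param map [genetic_map] used to recompute genetic coordinates of
#'   truncated segments.
#' @param b_mb Minimum flank, in megabases, for the length-subtraction rule
#'   (default 1).
#' @return list(segments = masked [segment_set], m = total masked cM). `m`
#'   is subtracted from 100*r via [adjust_r()] in all downstream models.
#' @export
apply_mask <- function(segments, mask, map, b_mb = 1.0) {
  stopifnot(inherits(segments, "segment_set"))
  m <- mask_total_cM(mask)
  if (nrow(mask) == 0L || nrow(segments) == 0L)
    return(list(segments = segments, m = m))
  b <- b_mb * 1e6
  rows <- vector("list", nrow(segments))
  for (i in seq_len(nrow(segments))) {
    seg <- segments[i, , drop = FALSE]
    reg <- mask[mask$chrom == seg$chrom, , drop = FALSE]
    deduct <- 0
    alive <- TRUE
    j <- 1L
    while (alive && j <= nrow(reg)) {
      rs <- reg$start_bp[j]; re <- reg$end_bp[j]
      if (re <= seg$start_bp || rs >= seg$end_bp) { j <- j + 1L; next }
      if (seg$start_bp <= rs && seg$end_bp >= re &&
          rs - seg$start_bp >= b && seg$end_bp - re >= b) {
        deduct <- deduct + reg$length_cM[j]           # rule (i)
        j <- j + 1L
      } else if (seg$start_bp >= rs && seg$end_bp <= re) {
        alive <- FALSE                                # rule (iii)
      } else if (seg$start_bp < rs && seg$end_bp <= re) {
        seg$end_bp <- rs                              # rule (ii), right cut
        j <- j + 1L
      } else if (seg$start_bp >= rs && seg$end_bp > re) {
        seg$start_bp <- re                            # rule (ii), left cut
        j <- j + 1L
      } else {
        # contains the region but a flank is shorter than b: keep the longer
        # outside portion, deterministically (ties keep the left)
        left <- rs - seg$start_bp; right <- seg$end_bp - re
        if (left >= right) seg$end_bp <- rs else seg$start_bp <- re
        j <- j + 1L
      }
      if (alive && seg$end_bp - seg$start_bp <= 0) alive <- FALSE
    }
    if (alive) {
      seg$start_cM <- interpolate_cM(map, seg$chrom, seg$start_bp)
      seg$end_cM <- interpolate_cM(map, seg$chrom, seg$end_bp)
      seg$length_cM <- max(0, seg$end_cM - seg$start_cM - deduct)
      if (seg$length_cM > 0 && seg$end_cM > seg$start_cM) rows[[i]] <- seg
    }
  }
  out <- data.table::rbindlist(rows[!vapply(rows, is.null, logical(1))])
  out <- if (nrow(out)) as.data.frame(out) else
    as.data.frame(segments)[0, , drop = FALSE]
  list(segments = segment_set(out, provenance =
                                paste0(attr(segments, "provenance"), "+masked")),
       m = m)
}

#' Adjust the expected recombination count for masked genome
#'
#' Masked regions hide recombination events, so the expected number of
#' recombinations per generation used by all models is reduced: r - m/100.
#'
#' @param r Expected recombination events per generation (e.g. 35).
#' @param m Total masked genetic length in cM.
#' @return Adjusted r.
#' @export
adjust_r <- function(r, m) {
  if (!is.numeric(m) || m < 0) stop("parameter error: m must be >= 0")
  if (m / 100 >= r) stop("parameter error: m/100 must be smaller than r")
  r - m / 100
}
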