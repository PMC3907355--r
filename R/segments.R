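#' IBD segment sets
#'
#' A segment set is a data.frame of pairwise IBD segments with canonical
#' columns `id1`, `id2` (unordered pair, stored sorted), `chrom`,
#' `start_bp`, `end_bp` (0-based, half-open), `start_cM`, `end_cM`,
#' `length_cM` (= end_cM - start_cM) and `state` ("IBD1" or "IBD2").
#'
#' @param segments data.frame with at least the canonical columns (missing
#'   cM columns are an error here; the readers fill them from a map).
#' @param provenance Free-text provenance string (detector name, run
#'   parameters, simulation seed).
#' @return data.frame of class `segment_set`.
#' @export
segment_set <- function(segments, provenance = "unknown") {
  need <- c("id1", "id2", "chrom", "start_bp", "end_bp",
            "start_cM", "end_cM", "length_cM", "state")
  miss <- setdiff(need, names(segments))
  if (length(miss)) stop("segment_set: missing columns: ", paste(miss, collapse = ", "))
  segments <- as.data.frame(segments)[, need]
  if (nrow(segments)) {
    if (any(segments$end_bp <= segments$start_bp, na.rm = TRUE))
      stop("segment_set: start_bp must be < end_bp")
    if (any(segments$end_cM <= segments$start_cM))
      stop("segment_set: start_cM must be < end_cM")
    # length may be SHORTER than the cM extent (mask-deducted segments keep
    # their extent) but never longer
    if (any(segments$length_cM - (segments$end_cM - segments$start_cM) > 1e-6))
      stop("segment_set: length_cM exceeds end_cM - start_cM")
    if (any(segments$length_cM <= 0))
      stop("segment_set: length_cM must be > 0")
    if (!all(segments$state %in% c("IBD1", "IBD2")))
      stop("segment_set: state must be IBD1 or IBD2")
    flip <- segments$id1 > segments$id2
    if (any(flip)) {
      tmp <- segments$id1[flip]
      segments$id1[flip] <- segments$id2[flip]
      segments$id2[flip] <- tmp
    }
  }
  rownames(segments) <- NULL
  structure(segments, class = c("segment_set", "data.frame"),
            provenance = provenance)
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf("<segment_set> %d segments, %d pairs [%s]\n",
              nrow(x), length(unique(pair_key(x$id1, x$id2))),
              attr(x, "provenance")))
  if (nrow(x)) print.data.frame(utils::head(x, 6L))
  invisible(x)
}

#' Canonical key for an unordered pair of individual ids
#' @param id1,id2 Character vectors of individual ids.
#' @return Character vector, `"a|b"` with a <= b.
#' @export
pair_key <- function(id1, id2) {
  paste(pmin(id1, id2), pmax(id1, id2), sep = "|")
}

.sex_chrom <- c("X", "Y", "chrX", "chrY", "23", "24", "chr23", "chr24")

.drop_nonautosomes <- function(df, map) {
  known <- attr(map, "chromosomes")
  bad <- !(df$chrom %in% known)
  if (any(bad)) {
    sex <- bad & df$chrom %in% .sex_chrom
    if (any(sex)) {
      warning(sum(sex), " segment(s) on sex chromosomes dropped ",
              "(models count autosomes only)")
      df <- df[!sex, , drop = FALSE]
      bad <- !(df$chrom %in% known)
    }
    if (any(bad))
      stop("coordinate error: unknown chromosome id(s): ",
           paste(unique(df$chrom[bad]), collapse = ", "))
  }
  df
}

#' Read pairwise IBD segment files
#'
#' Three tab-delimited dialects are supported:
#' \describe{
#'   \item{generic_tsv}{the canonical 9-column format written by
#'     [write_ibd_segments()] (0-based half-open bp, header line).}
#'   \item{germline_match}{6 columns, no header: id1, id2, chrom, start_bp,
#'     end_bp, length_cM; 1-based inclusive coordinates, no IBD state
#'     (all segments are IBD1). Genetic coordinates are recomputed from the
#'     map, as detectors differ in whether they emit them.}
#'   \item{isca_ibd12}{6 columns, no header: id1, id2, chrom, start_bp,
#'     end_bp, state; 1-based inclusive, explicit IBD1/IBD2 state column.}
#' }
#' 1-based inclusive dialects are converted to the internal 0-based
#' half-open convention on read. Segments on sex chromosomes are dropped
#' with a warning; other unknown chromosome ids are an error.
#'
#' @param path Input file.
#' @param dialect One of "generic_tsv", "germline_match", "isca_ibd12".
#' @param map [genetic_map] used to (re)compute genetic coordinates.
#' @return A [segment_set].
#' @export
read_ibd_segments <- function(path,
                              dialect = c("generic_tsv", "germline_match",
                                          "isca_ibd12"),
                              map) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("segment file not found: ", path)
  header <- dialect == "generic_tsv"
  dt <- tryCatch(
    data.table::fread(path, header = header, sep = "\t", data.table = FALSE,
                      colClasses = list(character = 1:3)),
    error = function(e) stop("parse error in ", path, ": ", conditionMessage(e)))
  if (nrow(dt) == 0L)
    return(segment_set(data.frame(id1 = character(), id2 = character(),
                                  chrom = character(), start_bp = integer(),
                                  end_bp = integer(), start_cM = numeric(),
                                  end_cM = numeric(), length_cM = numeric(),
                                  state = character()),
                       provenance = dialect))
  df <- switch(dialect,
    generic_tsv = {
      need <- c("id1", "id2", "chrom", "start_bp", "end_bp",
                "start_cM", "end_cM", "length_cM", "state")
      if (!all(need %in% names(dt)))
        stop("parse error in ", path, ": generic_tsv requires columns ",
             paste(need, collapse = ", "))
      dt[, need]
    },
    germline_match = {
      if (ncol(dt) < 6L)
        stop("parse error in ", path, ": germline_match requires 6 columns")
      names(dt)[1:6] <- c("id1", "id2", "chrom", "start_bp", "end_bp", "len")
      dt$start_bp <- as.numeric(dt$start_bp) - 1  # 1-based inclusive -> 0-based
      dt$state <- "IBD1"
      dt
    },
    isca_ibd12 = {
      if (ncol(dt) < 6L)
        stop("parse error in ", path, ": isca_ibd12 requires 6 columns")
      names(dt)[1:6] <- c("id1", "id2", "chrom", "start_bp", "end_bp", "state")
      dt$start_bp <- as.numeric(dt$start_bp) - 1
      if (!all(dt$state %in% c("IBD1", "IBD2"))) {
        bad <- which(!(dt$state %in% c("IBD1", "IBD2")))[1L]
        stop("parse error in ", path, " line ", bad,
             ": state must be IBD1 or IBD2")
      }
      dt
    })
  bad <- !is.finite(df$start_bp) | !is.finite(as.numeric(df$end_bp)) |
    df$end_bp <= df$start_bp
  if (any(bad))
    stop("parse error in ", path, " line ", which(bad)[1L],
         ": malformed coordinates")
  df <- .drop_nonautosomes(df, map)
  if (dialect != "generic_tsv") {
    df$start_cM <- NA_real_
    df$end_cM <- NA_real_
    for (ch in unique(df$chrom)) {
      i <- df$chrom == ch
      df$start_cM[i] <- interpolate_cM(map, ch, df$start_bp[i])
      df$end_cM[i] <- interpolate_cM(map, ch, df$end_bp[i])
    }
    df$length_cM <- df$end_cM - df$start_cM
  }
  drop <- df$length_cM <= 0
  if (any(drop)) df <- df[!drop, , drop = FALSE]
  segment_set(df[, c("id1", "id2", "chrom", "start_bp", "end_bp",
                     "start_cM", "end_cM", "length_cM", "state")],
              provenance = dialect)
}

#' Write a segment set in the canonical 9-column TSV format
#' @param segments A [segment_set].
#' @param path Output path.
#' @export
write_ibd_segments <- function(segments, path) {
  stopifnot(inherits(segments, "segment_set"))
  data.table::fwrite(as.data.frame(segments), path, sep = "\t")
  invisible(path)
}

#' Merge IBD segments across multiple detector runs
#'
#' Some detectors are run several times with different random restarts; the
#' recommended post-processing is to merge, per pair and chromosome, all
#' segments that overlap or lie within a fixed physical gap (1 Mb by
#' default) of one another across any of the runs. Genetic coordinates of a
#' merged segment are recomputed from its merged physical extent.
#'
#' @param runs List of [segment_set] objects (or a single one).
#' @param map [genetic_map].
#' @param gap_mb Maximum physical gap, in megabases, for two segments to be
#'   merged (default 1).
#' @return A [segment_set]; idempotent on its own output and independent of
#'   the order of `runs`.
#' @export
merge_multirun <- function(runs, map, gap_mb = 1.0) {
  if (inherits(runs, "segment_set")) runs <- list(runs)
  stopifnot(length(runs) >= 1L, gap_mb >= 0)
  pooled <- data.table::rbindlist(lapply(runs, as.data.frame))
  pooled <- as.data.frame(pooled)
  if (nrow(pooled) == 0L)
    return(segment_set(pooled, provenance = "multirun-merge"))
  known <- attr(map, "chromosomes")
  if (!all(pooled$chrom %in% known))
    stop("coordinate error: inconsistent chromosome ids across runs")
  gap <- gap_mb * 1e6
  key <- paste(pair_key(pooled$id1, pooled$id2), pooled$chrom, pooled$state,
               sep = "\r")
  out <- lapply(split(seq_len(nrow(pooled)), key), function(idx) {
    d <- pooled[idx, , drop = FALSE]
    o <- order(d$start_bp, d$end_bp)
    s <- d$start_bp[o]; e <- d$end_bp[o]
    m_start <- s[1L]; m_end <- e[1L]
    res_s <- numeric(0); res_e <- numeric(0)
    for (i in seq_along(s)[-1L]) {
      if (s[i] - m_end <= gap) {
        m_end <- max(m_end, e[i])
      } else {
        res_s <- c(res_s, m_start); res_e <- c(res_e, m_end)
        m_start <- s[i]; m_end <- e[i]
      }
    }
    res_s <- c(res_s, m_start); res_e <- c(res_e, m_end)
    ch <- d$chrom[1L]
    scm <- interpolate_cM(map, ch, res_s)
    ecm <- interpolate_cM(map, ch, res_e)
    data.frame(id1 = pmin(d$id1[1L], d$id2[1L]),
               id2 = pmax(d$id1[1L], d$id2[1L]),
               chrom = ch, start_bp = res_s, end_bp = res_e,
               start_cM = scm, end_cM = ecm, length_cM = ecm - scm,
               state = d$state[1L])
  })
  out <- as.data.frame(data.table::rbindlist(out))
  out <- out[order(out$id1, out$id2, out$chrom, out$start_bp), , drop = FALSE]
  segment_set(out, provenance = "multirun-merge")
}

#' Per-pair segment lengths above a minimum length
#'
#' Utility used by the background fit and the classifier: splits a segment
#' set into a named list (by canonical pair key) of numeric length vectors,
#' keeping segments with `length_cM >= t` and the requested state.
#'
#' @param segments A [segment_set].
#' @param t Minimum segment length in cM.
#' @param state IBD state to keep (default "IBD1").
#' @return Named list of numeric vectors.
#' @export
segment_lengths_by_pair <- function(segments, t = 0, state = "IBD1") {
  keep <- segments$length_cM >= t & segments$state == state
  split(segments$length_cM[keep],
        pair_key(segments$id1[keep], segments$id2[keep]))
}

#' All unordered pairs among a set of individual ids
#' @param ids Character vector of ids.
#' @return data.frame with columns id1, id2 (one row per unordered pair).
#' @export
all_pairs <- function(ids) {
  ids <- sort(unique(as.character(ids)))
  if (length(ids) < 2L) return(data.frame(id1 = character(), id2 = character()))
  cmb <- utils::combn(ids, 2L)
  data.frame(id1 = cmb[1L, ], id2 = cmb[2L, ])
}

#' Read a control-cohort pair manifest (TSV of id1, id2)
#'
#' The manifest lists every putatively unrelated pair in the control cohort,
#' including pairs that share no detected segment; omitting zero-segment
#' pairs would bias the background segment-count mean upward.
#'
#' @param path Tab-delimited file with two columns (header optional).
#' @return data.frame with columns id1, id2.
#' @export
read_pair_manifest <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("id", first, ignore.case = TRUE)
  dt <- data.table::fread(path, header = has_header, sep = "\t",
                          data.table = FALSE, colClasses = "character")
  if (ncol(dt) < 2L) stop("pair manifest must have two columns")
  data.frame(id1 = pmin(dt[[1L]], dt[[2L]]), id2 = pmax(dt[[1L]], dt[[2L]]))
}
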