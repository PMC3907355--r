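#' Genetic map objects
#'
#' A genetic map is a per-chromosome table of strictly increasing anchor
#' points pairing physical position (bp) with genetic position (cM).
#' Genetic coordinates between anchors are obtained by linear interpolation;
#' positions beyond the outermost anchors are clamped to the boundary value.
#' The total map length in cM determines the expected number of
#' recombination events per meiosis, r = total_cM / 100 (about 35 in
#' humans), and the number of chromosomes gives the autosome count c used by
#' the relationship models.
#'
#' @param anchors data.frame with columns `chrom`, `bp`, `cM`.
#' @return An object of class `genetic_map`: a named list of per-chromosome
#'   anchor tables, with attributes `chromosomes`, `chrom_cM` (genetic length
#'   of each chromosome), `total_cM` and `n_chrom`.
#' @export
genetic_map <- function(anchors) {
  stopifnot(is.data.frame(anchors), all(c("chrom", "bp", "cM") %in% names(anchors)))
  anchors$chrom <- as.character(anchors$chrom)
  chroms <- unique(anchors$chrom)
  per <- lapply(chroms, function(ch) {
    a <- anchors[anchors$chrom == ch, c("bp", "cM"), drop = FALSE]
    a <- a[order(a$bp), , drop = FALSE]
    if (nrow(a) < 2L)
      stop("genetic map: chromosome ", ch, " needs at least 2 anchors")
    if (any(diff(a$bp) <= 0) || any(diff(a$cM) <= 0))
      stop("genetic map: anchors for chromosome ", ch,
           " must be strictly increasing in both bp and cM")
    if (any(a$bp < 0) || any(a$cM < 0))
      stop("genetic map: negative coordinates on chromosome ", ch)
    list(bp = a$bp, cM = a$cM)
  })
  names(per) <- chroms
  chrom_cM <- vapply(per, function(a) a$cM[length(a$cM)] - a$cM[1L], numeric(1))
  structure(per,
            class = "genetic_map",
            chromosomes = chroms,
            chrom_cM = chrom_cM,
            total_cM = sum(chrom_cM),
            n_chrom = length(chroms))
}

#' Read a genetic map from a 3-column TSV (chrom, bp, cM)
#'
#' @param path Path to a tab-delimited file with columns chrom, bp, cM
#'   (header optional; detected from the first line).
#' @return A [genetic_map] object.
#' @export
read_genetic_map <- function(path) {
  if (!file.exists(path)) stop("genetic map file not found: ", path)
  first <- readLines(path, n = 1L)
  has_header <- grepl("chrom", first, ignore.case = TRUE)
  dt <- data.table::fread(path, header = has_header, sep = "\t",
                          data.table = FALSE)
  if (ncol(dt) < 3L) stop("genetic map file must have 3 columns (chrom, bp, cM)")
  names(dt)[1:3] <- c("chrom", "bp", "cM")
  genetic_map(dt[, 1:3])
}

#' Write a genetic map as a 3-column TSV
#' @param map A [genetic_map].
#' @param path Output path.
#' @export
write_genetic_map <- function(map, path) {
  stopifnot(inherits(map, "genetic_map"))
  rows <- lapply(attr(map, "chromosomes"), function(ch)
    data.frame(chrom = ch, bp = map[[ch]]$bp, cM = map[[ch]]$cM))
  data.table::fwrite(data.table::rbindlist(rows), path, sep = "\t")
  invisible(path)
}

#' @export
print.genetic_map <- function(x, ...) {
  cat(sprintf("<genetic_map> %d chromosomes, %.2f cM total (r = %.3f)\n",
              attr(x, "n_chrom"), attr(x, "total_cM"),
              attr(x, "total_cM") / 100))
  invisible(x)
}

#' Total genetic length and derived model constants
#' @param map A [genetic_map].
#' @return Total map length in cM.
#' @export
map_total_cM <- function(map) attr(map, "total_cM")

#' @rdname map_total_cM
#' @export
map_r <- function(map) attr(map, "total_cM") / 100

#' @rdname map_total_cM
#' @export
map_n_chrom <- function(map) attr(map, "n_chrom")

.map_chrom <- function(map, chrom) {
  a <- map[[as.character(chrom)]]
  if (is.null(a))
    stop("coordinate error: chromosome '", chrom, "' not in genetic map")
  a
}

#' Interpolate genetic position (cM) from physical position (bp)
#'
#' Linear interpolation between the flanking anchors of the map; positions
#' outside the anchored range are clamped to the boundary cM value.
#'
#' @param map A [genetic_map].
#' @param chrom Chromosome id present in the map.
#' @param bp Numeric vector of physical positions.
#' @return Numeric vector of genetic positions in cM (monotone
#'   non-decreasing in `bp`).
#' @export
interpolate_cM <- function(map, chrom, bp) {
  a <- .map_chrom(map, chrom)
  stats::approx(a$bp, a$cM, xout = bp, rule = 2, ties = "ordered")$y
}

#' Interpolate physical position (bp) from genetic position (cM)
#'
#' Inverse of [interpolate_cM()]; clamped at chromosome ends and rounded to
#' integer base pairs.
#'
#' @inheritParams interpolate_cM
#' @param cM Numeric vector of genetic positions.
#' @export
interpolate_bp <- function(map, chrom, cM) {
  a <- .map_chrom(map, chrom)
  round(stats::approx(a$cM, a$bp, xout = cM, rule = 2, ties = "ordered")$y)
}

#' Per-chromosome genetic lengths
#' @param map A [genetic_map].
#' @return Named numeric vector of chromosome lengths in cM.
#' @export
chrom_lengths_cM <- function(map) attr(map, "chrom_cM")
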