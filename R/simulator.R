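# Gene-dropping pedigree simulator. Haplotypes are run-length mosaics of
# founder-haplotype labels: per chromosome, a pair of vectors (ends, labs)
# where ends are increasing cM block endpoints (last = chromosome length)
# and labs are integer founder-haplotype labels.

# sex-averaged genetic lengths of the 22 human autosomes (cM), used as the
# relative length profile of synthetic maps
.human_autosome_cM <- c(284, 269, 223, 214, 204, 192, 187, 168, 166, 181,
                        158, 175, 126, 119, 141, 134, 128, 117, 107, 108,
                        62, 74)

#' Build a synthetic genome-wide genetic map
#'
#' Chromosome genetic lengths follow a human-like profile scaled to
#' `total_cM` (so r = total_cM/100, about 35 for the default). Each
#' chromosome gets `anchors_per_chrom` monotone bp/cM anchors with mild
#' recombination-rate heterogeneity around 1 cM/Mb, drawn from the current
#' RNG state (seed for reproducibility).
#'
#' @param n_chrom Number of autosomes (default 22).
#' @param total_cM Total map length in cM (default 3500).
#' @param anchors_per_chrom Anchors per chromosome (default 25).
#' @return A [genetic_map] with chromosomes named "chr1"... per-chromosome
#'   cM starting at 0.
#' @export
make_synthetic_map <- function(n_chrom = 22, total_cM = 3500,
                               anchors_per_chrom = 25) {
  stopifnot(n_chrom >= 1, total_cM > 0, anchors_per_chrom >= 2)
  prof <- if (n_chrom == 22) .human_autosome_cM else {
    p <- rev(seq_len(n_chrom) + 2)
    p
  }
  len <- prof / sum(prof) * total_cM
  rows <- lapply(seq_len(n_chrom), function(i) {
    cm <- seq(0, len[i], length.out = anchors_per_chrom)
    # mild rate heterogeneity: bp spacing ~ cM spacing / rate, rate in
    # [0.7, 1.3] cM/Mb
    rate <- stats::runif(anchors_per_chrom - 1L, 0.7, 1.3)
    bp <- cumsum(c(0, diff(cm) / rate * 1e6))
    data.frame(chrom = paste0("chr", i), bp = round(bp), cM = cm)
  })
  genetic_map(as.data.frame(data.table::rbindlist(rows)))
}

#' Pedigree structures
#'
#' A pedigree is a data.frame with columns `id`, `parent1`, `parent2`
#' (both NA for founders, both non-NA otherwise) and optionally
#' `generation`. Rows are topologically sorted on construction; cycles are
#' an error.
#'
#' @param df data.frame with id, parent1, parent2 (NA or "0" for missing).
#' @return data.frame of class `pedigree`, parents before children.
#' @export
pedigree <- function(df) {
  stopifnot(all(c("id", "parent1", "parent2") %in% names(df)))
  df$id <- as.character(df$id)
  for (p in c("parent1", "parent2")) {
    df[[p]] <- as.character(df[[p]])
    df[[p]][df[[p]] %in% c("0", "", "NA")] <- NA_character_
  }
  if (anyDuplicated(df$id)) stop("pedigree: duplicate individual ids")
  fnd <- is.na(df$parent1) & is.na(df$parent2)
  if (any(is.na(df$parent1) != is.na(df$parent2)))
    stop("pedigree: each non-founder needs exactly 2 parents")
  miss <- setdiff(c(df$parent1[!fnd], df$parent2[!fnd]), df$id)
  if (length(miss)) stop("pedigree: unknown parent id(s): ",
                         paste(miss, collapse = ", "))
  # topological sort (Kahn); failure to place everyone means a cycle
  placed <- character(0)
  remaining <- df
  ord <- integer(0)
  while (nrow(remaining)) {
    ready <- (is.na(remaining$parent1) | remaining$parent1 %in% placed) &
      (is.na(remaining$parent2) | remaining$parent2 %in% placed)
    if (!any(ready)) stop("structure error: pedigree contains a cycle")
    placed <- c(placed, remaining$id[ready])
    ord <- c(ord, match(remaining$id[ready], df$id))
    remaining <- remaining[!ready, , drop = FALSE]
  }
  out <- df[ord, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("pedigree", "data.frame"))
}

#' Read a pedigree from a TSV (id, parent1, parent2[, generation])
#' @param path File path; header required.
#' @export
read_pedigree <- function(path) {
  pedigree(data.table::fread(path, header = TRUE, sep = "\t",
                             data.table = FALSE, colClasses = "character"))
}

#' Founders of a pedigree
#' @param ped A [pedigree].
#' @export
founders <- function(ped) ped$id[is.na(ped$parent1)]

#' One simulated meiosis on one chromosome
#'
#' Crossover count is Poisson(chrom_cM / 100) with positions uniform in cM
#' (no interference); the gamete alternates between the parent's two
#' haplotypes, starting from a fair coin.
#' @noRd
.meiosis_chrom <- function(h1, h2, L) {
  ncx <- stats::rpois(1L, L / 100)
  cur <- if (stats::runif(1) < 0.5) 1L else 2L
  if (ncx == 0L)
    return(structure(if (cur == 1L) h1 else h2, ncx = 0L))
  cx <- sort(stats::runif(ncx, 0, L))
  los <- c(0, cx); his <- c(cx, L)
  haps <- list(h1, h2)
  ends <- labs <- vector("list", ncx + 1L)
  for (i in seq_len(ncx + 1L)) {
    h <- haps[[cur]]
    j1 <- findInterval(los[i], h$ends) + 1L        # ends <= lo are passed
    j2 <- findInterval(his[i], h$ends, left.open = TRUE) + 1L
    e <- h$ends[j1:j2]
    e[length(e)] <- his[i]
    ends[[i]] <- e
    labs[[i]] <- h$labs[j1:j2]
    cur <- 3L - cur
  }
  ends <- unlist(ends, use.names = FALSE)
  labs <- unlist(labs, use.names = FALSE)
  keep <- c(labs[-length(labs)] != labs[-1L], TRUE)   # coalesce same label
  structure(list(ends = ends[keep], labs = labs[keep]), ncx = ncx)
}

#' Simulate one gamete (meiosis) from a parent's mosaic
#'
#' @param parent Mosaic (list per chromosome of h1/h2 block lists) as
#'   produced by [gene_drop()] / [founder_mosaic()].
#' @param map [genetic_map].
#' @return A haplotype set: list per chromosome of (ends, labs), with
#'   attribute `n_crossovers` = total crossover count across chromosomes.
#' @export
meiosis_gamete <- function(parent, map) {
  clen <- attr(map, "chrom_cM")
  out <- vector("list", length(parent))
  names(out) <- names(parent)
  ncx <- 0L
  for (i in seq_along(parent)) {
    g <- .meiosis_chrom(parent[[i]]$h1, parent[[i]]$h2, clen[[i]])
    ncx <- ncx + attr(g, "ncx")
    attr(g, "ncx") <- NULL
    out[[i]] <- g
  }
  structure(out, n_crossovers = ncx)
}

#' Founder mosaic with two fresh haplotype labels
#' @param map [genetic_map].
#' @param labels Integer vector of length 2.
#' @export
founder_mosaic <- function(map, labels) {
  clen <- attr(map, "chrom_cM")
  out <- lapply(clen, function(L)
    list(h1 = list(ends = L, labs = labels[1L]),
         h2 = list(ends = L, labs = labels[2L])))
  names(out) <- attr(map, "chromosomes")
  out
}

#' Gene-drop a pedigree on a genetic map
#'
#' Founders receive distinct haplotype labels (two each); every
#' non-founder's two haplotypes are independent meioses of its parents'
#' mosaics, with crossovers Poisson in genetic distance.
#'
#' @param ped A [pedigree].
#' @param map A [genetic_map].
#' @return Named list of mosaics, one per individual; each mosaic is a list
#'   per chromosome of `h1`/`h2` block lists.
#' @export
gene_drop <- function(ped, map) {
  mos <- vector("list", nrow(ped))
  names(mos) <- ped$id
  fidx <- 0L
  for (i in seq_len(nrow(ped))) {
    if (is.na(ped$parent1[i])) {
      fidx <- fidx + 1L
      mos[[i]] <- founder_mosaic(map, c(2L * fidx - 1L, 2L * fidx))
    } else {
      g1 <- meiosis_gamete(mos[[ped$parent1[i]]], map)
      g2 <- meiosis_gamete(mos[[ped$parent2[i]]], map)
      mos[[i]] <- mapply(function(a, b) list(h1 = a, h2 = b),
                         g1, g2, SIMPLIFY = FALSE)
    }
  }
  mos
}

# labels of a haplotype evaluated on elementary intervals delimited by `brk`
.labels_on <- function(h, mids) h$labs[findInterval(mids, h$ends,
                                                    left.open = TRUE) + 1L]

#' True IBD segments between two simulated individuals
#'
#' IBD1 marks intervals where exactly one haplotype label is shared between
#' the two mosaics (under the best one-to-one matching), IBD2 where both
#' are. Adjacent same-state intervals are coalesced. Output modes:
#' \describe{
#'   \item{state}{IBD1-only stretches as IBD1 rows and IBD2 stretches as
#'     IBD2 rows (exact state track).}
#'   \item{germline}{runs of any sharing merged into single IBD1 rows, as
#'     detectors that cannot distinguish states report them.}
#'   \item{isca}{the merged IBD1 rows of `germline` plus each IBD2 stretch
#'     as an additional overlapping IBD2 row.}
#' }
#'
#' @param mosaic_a,mosaic_b Mosaics from [gene_drop()] (same map).
#' @param map [genetic_map].
#' @param pair_id Character vector of the two individual ids.
#' @param mode Output representation (see above).
#' @param bp Compute physical coordinates from the map (TRUE); FALSE leaves
#'   NA bp for speed in large simulations.
#' @return A [segment_set] (symmetric in the two mosaics).
#' @export
true_ibd <- function(mosaic_a, mosaic_b, map, pair_id = c("A", "B"),
                     mode = c("state", "germline", "isca"), bp = TRUE) {
  mode <- match.arg(mode)
  if (!identical(names(mosaic_a), names(mosaic_b)) ||
      !identical(names(mosaic_a), attr(map, "chromosomes")))
    stop("coordinate error: mosaics and map disagree on chromosomes")
  acc_lo <- acc_hi <- vector("list", length(mosaic_a))
  acc_st <- acc_ch <- vector("list", length(mosaic_a))
  chroms <- names(mosaic_a)
  for (ci in seq_along(mosaic_a)) {
    A <- mosaic_a[[ci]]; B <- mosaic_b[[ci]]
    ends <- sort(unique(c(A$h1$ends, A$h2$ends, B$h1$ends, B$h2$ends)))
    mids <- (c(0, ends[-length(ends)]) + ends) / 2
    a1 <- .labels_on(A$h1, mids); a2 <- .labels_on(A$h2, mids)
    b1 <- .labels_on(B$h1, mids); b2 <- .labels_on(B$h2, mids)
    ibd2 <- (a1 == b1 & a2 == b2) | (a1 == b2 & a2 == b1)
    state <- ibd2 * 2L + (!ibd2 & (a1 == b1 | a1 == b2 | a2 == b1 | a2 == b2))
    r <- rle(state)
    hi <- ends[cumsum(r$lengths)]
    lo <- c(0, hi[-length(hi)])
    keep <- r$values > 0L
    if (!any(keep)) next
    lo <- lo[keep]; hi <- hi[keep]; st <- r$values[keep]
    if (mode == "state") {
      o_lo <- lo; o_hi <- hi; o_st <- st
    } else {
      # merge touching runs of any sharing into union IBD1 segments
      new_run <- c(TRUE, lo[-1L] - hi[-length(hi)] > 1e-9)
      o_lo <- lo[new_run]
      run_last <- c(which(new_run)[-1L] - 1L, length(hi))
      o_hi <- hi[run_last]
      o_st <- rep(1L, length(o_lo))
      if (mode == "isca" && any(st == 2L)) {
        o_lo <- c(o_lo, lo[st == 2L])
        o_hi <- c(o_hi, hi[st == 2L])
        o_st <- c(o_st, rep(2L, sum(st == 2L)))
      }
    }
    acc_lo[[ci]] <- o_lo; acc_hi[[ci]] <- o_hi; acc_st[[ci]] <- o_st
    acc_ch[[ci]] <- rep(chroms[ci], length(o_lo))
  }
  lo <- unlist(acc_lo, use.names = FALSE)
  hi <- unlist(acc_hi, use.names = FALSE)
  st <- unlist(acc_st, use.names = FALSE)
  ch <- unlist(acc_ch, use.names = FALSE)
  if (is.null(lo)) lo <- hi <- st <- numeric(0)
  if (is.null(ch)) ch <- character(0)
  cm0 <- vapply(chroms, function(cc) map[[cc]]$cM[1L], numeric(1))[ch]
  if (length(ch)) cm0 <- as.numeric(cm0) else cm0 <- numeric(0)
  sbp <- ebp <- rep(NA_real_, length(lo))
  if (bp && length(lo)) {
    for (cc in unique(ch)) {
      i <- which(ch == cc)
      sbp[i] <- interpolate_bp(map, cc, lo[i] + cm0[i])
      ebp[i] <- interpolate_bp(map, cc, hi[i] + cm0[i])
    }
  }
  out <- data.frame(id1 = rep(pair_id[1L], length(lo)),
                    id2 = rep(pair_id[2L], length(lo)),
                    chrom = ch, start_bp = sbp, end_bp = ebp,
                    start_cM = lo + cm0, end_cM = hi + cm0,
                    length_cM = hi - lo,
                    state = c("IBD1", "IBD2")[st])
  if (nrow(out) && !all(is.na(out$start_bp))) {
    same <- out$end_bp <= out$start_bp        # sub-bp segments after rounding
    out$end_bp[same] <- out$start_bp[same] + 1
  }
  segment_set(out, provenance = paste0("gene-drop/", mode))
}

#' Perturb simulated segments to emulate detector imperfection
#'
#' Boundary jitter (Gaussian, cM, clamped to the chromosome), false
#' negatives (segments dropped independently) and false positives
#' (Poisson-many uniform segments inserted per pair with exponential
#' lengths). All rates default to 0, making the function the identity.
#'
#' @param segments [segment_set].
#' @param map [genetic_map].
#' @param boundary_jitter_cM SD of endpoint jitter in cM.
#' @param fp_rate Expected inserted segments per pair.
#' @param fn_rate Probability of dropping each segment.
#' @param fp_length_cM Mean length of inserted segments (default 3).
#' @return A [segment_set].
#' @export
add_segment_noise <- function(segments, map, boundary_jitter_cM = 0,
                              fp_rate = 0, fn_rate = 0, fp_length_cM = 3) {
  stopifnot(fp_rate >= 0, fn_rate >= 0, fn_rate <= 1,
            boundary_jitter_cM >= 0)
  df <- as.data.frame(segments)
  if (fn_rate > 0 && nrow(df))
    df <- df[stats::runif(nrow(df)) >= fn_rate, , drop = FALSE]
  if (boundary_jitter_cM > 0 && nrow(df)) {
    for (ch in unique(df$chrom)) {
      i <- which(df$chrom == ch)
      a <- map[[ch]]
      lo <- a$cM[1L]; hi <- a$cM[length(a$cM)]
      s <- pmax(lo, pmin(hi, df$start_cM[i] +
                           stats::rnorm(length(i), 0, boundary_jitter_cM)))
      e <- pmax(lo, pmin(hi, df$end_cM[i] +
                           stats::rnorm(length(i), 0, boundary_jitter_cM)))
      bad <- e <= s
      s[bad] <- df$start_cM[i][bad]; e[bad] <- df$end_cM[i][bad]
      df$start_cM[i] <- s; df$end_cM[i] <- e
      df$start_bp[i] <- interpolate_bp(map, ch, s)
      df$end_bp[i] <- interpolate_bp(map, ch, e)
      df$length_cM[i] <- e - s
    }
    df <- df[df$length_cM > 0 & df$end_bp > df$start_bp, , drop = FALSE]
  }
  if (fp_rate > 0) {
    pairs <- unique(df[, c("id1", "id2"), drop = FALSE])
    if (nrow(pairs)) {
      ins <- lapply(seq_len(nrow(pairs)), function(i) {
        k <- stats::rpois(1L, fp_rate)
        if (k == 0L) return(NULL)
        lens <- stats::rexp(k, 1 / fp_length_cM)
        fake <- background_segment_set(list(lens), map)
        if (!nrow(fake)) return(NULL)
        fake$id1 <- pairs$id1[i]; fake$id2 <- pairs$id2[i]
        as.data.frame(fake)
      })
      ins <- ins[!vapply(ins, is.null, logical(1))]
      if (length(ins))
        df <- rbind(df, as.data.frame(data.table::rbindlist(ins)))
    }
  }
  segment_set(df, provenance = paste0(attr(segments, "provenance"), "+noise"))
}

#' Emit biallelic marker genotypes from simulated mosaics
#'
#' Looks up each individual's two founder-haplotype labels at the supplied
#' sites and copies the founder alleles, then applies de-novo mutation
#' (allele flips at the given expected rate per transmitted site, applied
#' to non-founders) and genotyping error (one allele of a call flipped at
#' the given rate per polymorphic site per individual).
#'
#' @param mosaics Named list of mosaics from [gene_drop()].
#' @param sites data.frame with columns chrom, cM (site positions).
#' @param founder_alleles Matrix (sites x founder-haplotype labels) of 0/1
#'   alleles; column j corresponds to integer haplotype label j.
#' @param ped [pedigree] (used to identify non-founders for mutation).
#' @param mutation_rate Expected de-novo mutations per transmitted site
#'   (default 1e-7).
#' @param error_rate Genotyping error probability per site per individual
#'   (default 0.001).
#' @return Integer matrix (sites x individuals) of genotypes 0/1/2.
#' @export
emit_markers <- function(mosaics, sites, founder_alleles, ped,
                         mutation_rate = 1e-7, error_rate = 0.001) {
  stopifnot(mutation_rate >= 0, mutation_rate <= 1,
            error_rate >= 0, error_rate <= 1)
  n_sites <- nrow(sites)
  ids <- names(mosaics)
  nonf <- ids[!(ids %in% founders(ped))]
  hap_allele <- function(mos, hap) {
    al <- integer(n_sites)
    for (ch in unique(sites$chrom)) {
      i <- which(sites$chrom == ch)
      h <- mos[[ch]][[hap]]
      labs <- h$labs[findInterval(sites$cM[i], h$ends, left.open = TRUE) + 1L]
      al[i] <- founder_alleles[cbind(i, labs)]
    }
    al
  }
  H <- array(0L, dim = c(n_sites, length(ids), 2L),
             dimnames = list(NULL, ids, NULL))
  for (id in ids) {
    H[, id, 1L] <- hap_allele(mosaics[[id]], "h1")
    H[, id, 2L] <- hap_allele(mosaics[[id]], "h2")
  }
  # de-novo mutations: each non-founder haplotype is one transmitted gamete
  for (id in nonf) for (hap in 1:2) {
    k <- stats::rbinom(1L, n_sites, mutation_rate)
    if (k > 0L) {
      at <- sample.int(n_sites, k)
      H[at, id, hap] <- 1L - H[at, id, hap]
    }
  }
  G <- H[, , 1L, drop = FALSE][, , 1L] + H[, , 2L, drop = FALSE][, , 1L]
  G <- matrix(as.integer(G), nrow = n_sites, ncol = length(ids),
              dimnames = list(NULL, ids))
  # genotyping errors: flip one allele of the call
  for (id in ids) {
    k <- stats::rbinom(1L, n_sites, error_rate)
    if (k > 0L) {
      at <- sample.int(n_sites, k)
      g <- G[at, id]
      G[at, id] <- ifelse(g == 0L, 1L, ifelse(g == 2L, 1L,
                          ifelse(stats::runif(k) < 0.5, 0L, 2L)))
    }
  }
  G
}

#' Simulate one relative pair and return its true IBD segments
#'
#' Convenience wrapper: builds the minimal pedigree for (d, a) with
#' [ped_relative_pair()], gene-drops it on the map and extracts the true
#' IBD segments of the target pair.
#'
#' @param d,a Relationship hypothesis (total meioses, shared ancestors).
#' @param map [genetic_map].
#' @param mode Output representation of [true_ibd()].
#' @param bp Compute physical coordinates (FALSE by default for speed).
#' @return A [segment_set] for the simulated pair.
#' @export
simulate_relative_pair <- function(d, a, map, mode = "germline", bp = FALSE) {
  ped <- ped_relative_pair(d, a)
  pr <- attr(ped, "pair")
  mos <- gene_drop(ped, map)
  true_ibd(mos[[pr[1L]]], mos[[pr[2L]]], map, pair_id = pr,
           mode = mode, bp = bp)
}
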