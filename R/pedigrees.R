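# Canonical pedigree constructors used throughout the test-suite and the
# validation simulations.

#' Minimal pedigree connecting a pair with a given (d, a)
#'
#' Builds the smallest pedigree in which the returned pair of individuals
#' is separated by `d` meioses through `a` shared ancestors: a lineal chain
#' for a = 0 (ancestor-descendant), half relatives through one shared
#' founder for a = 1, and full relatives through a shared couple for a = 2
#' (siblings at d = 2, avuncular at d = 3, cousin-type beyond). Every
#' married-in parent is a fresh founder.
#'
#' @param d Total meioses (>= 1; >= 2 for a > 0).
#' @param a Shared ancestors (0, 1 or 2).
#' @return A [pedigree] with attribute `pair` (the two individual ids).
#' @export
ped_relative_pair <- function(d, a) {
  stopifnot(d >= 1, a %in% 0:2, a == 0 || d >= 2)
  rows <- list()
  add <- function(id, p1 = NA, p2 = NA)
    rows[[length(rows) + 1L]] <<- data.frame(id = id, parent1 = p1,
                                             parent2 = p2)
  chain <- function(top, steps, tag) {
    # extend `steps` meioses below `top`, one fresh spouse per step
    cur <- top
    for (s in seq_len(steps)) {
      sp <- sprintf("SP_%s%d", tag, s)
      ch <- sprintf("C_%s%d", tag, s)
      add(sp)
      add(ch, cur, sp)
      cur <- ch
    }
    cur
  }
  if (a == 0L) {
    add("A1"); add("A2")
    add("C_L0", "A1", "A2")
    bottom <- if (d > 1) chain("C_L0", d - 1L, "L") else "C_L0"
    pair <- c("A1", bottom)
  } else if (a == 1L) {
    add("F"); add("SPA"); add("SPB")
    add("H_A1", "F", "SPA")
    add("H_B1", "F", "SPB")
    d1 <- d %/% 2L; d2 <- d - d1
    pa <- if (d1 > 1) chain("H_A1", d1 - 1L, "A") else "H_A1"
    pb <- if (d2 > 1) chain("H_B1", d2 - 1L, "B") else "H_B1"
    pair <- c(pa, pb)
  } else {
    add("A1"); add("A2")
    add("S_A1", "A1", "A2")
    add("S_B1", "A1", "A2")
    d1 <- d %/% 2L; d2 <- d - d1
    pa <- if (d1 > 1) chain("S_A1", d1 - 1L, "A") else "S_A1"
    pb <- if (d2 > 1) chain("S_B1", d2 - 1L, "B") else "S_B1"
    pair <- c(pa, pb)
  }
  ped <- pedigree(as.data.frame(data.table::rbindlist(rows, fill = TRUE)))
  attr(ped, "pair") <- pair
  ped
}

#' The 46-member, 15-generation validation pedigree
#'
#' Two offspring are born in each of 15 successive generations; one child
#' of each generation marries a fresh founder and parents the next. With
#' the two top founders and 14 married-in founders this gives 16 founders
#' plus 30 children = 46 members and choose(46, 2) = 1035 pairs, of which
#' 330 are unrelated, 75 are 1st degree (60 parent-offspring + 15 full
#' sibling), 84 2nd, 78 3rd, 72 4th and 66 5th degree.
#'
#' @param n_generations Number of offspring generations (default 15).
#' @return A [pedigree] with a `generation` column.
#' @export
ped_fifteen_generation <- function(n_generations = 15) {
  stopifnot(n_generations >= 1)
  rows <- list(data.frame(id = "F0a", parent1 = NA, parent2 = NA, generation = 0),
               data.frame(id = "F0b", parent1 = NA, parent2 = NA, generation = 0))
  p1 <- "F0a"; p2 <- "F0b"
  for (g in seq_len(n_generations)) {
    ca <- sprintf("G%02da", g); cb <- sprintf("G%02db", g)
    rows[[length(rows) + 1L]] <- data.frame(id = ca, parent1 = p1,
                                            parent2 = p2, generation = g)
    rows[[length(rows) + 1L]] <- data.frame(id = cb, parent1 = p1,
                                            parent2 = p2, generation = g)
    if (g < n_generations) {
      sp <- sprintf("S%02d", g + 1L)
      rows[[length(rows) + 1L]] <- data.frame(id = sp, parent1 = NA,
                                              parent2 = NA, generation = g)
      p1 <- ca; p2 <- sp
    }
  }
  pedigree(as.data.frame(data.table::rbindlist(rows)))
}

#' Documented relationship (d, a, degree) of every pair in a pedigree
#'
#' For each unordered pair: if one is an ancestor of the other, a = 0 and
#' d is the number of meioses between them; otherwise d is the minimum of
#' depth(x) + depth(y) over common ancestors and a the number of common
#' ancestors attaining it (at most 2). Pairs with no common ancestor are
#' labelled unrelated. Degree is d - 1 when a = 2, else d.
#'
#' @param ped A [pedigree].
#' @return data.frame: id1, id2, d, a, degree, family ("unrelated" where
#'   no common ancestor exists).
#' @export
pedigree_relationships <- function(ped) {
  ids <- ped$id
  # minimal meiosis depth to every ancestor (including self at depth 0)
  anc <- list()
  for (i in seq_len(nrow(ped))) {
    id <- ped$id[i]
    a <- c(stats::setNames(0L, id))
    if (!is.na(ped$parent1[i])) {
      for (p in c(ped$parent1[i], ped$parent2[i])) {
        pa <- anc[[p]] + 1L
        for (nm in names(pa)) {
          a[nm] <- if (nm %in% names(a)) min(a[[nm]], pa[[nm]]) else pa[[nm]]
        }
      }
    }
    anc[[id]] <- a
  }
  prs <- all_pairs(ids)
  out <- lapply(seq_len(nrow(prs)), function(k) {
    x <- prs$id1[k]; y <- prs$id2[k]
    ax <- anc[[x]]; ay <- anc[[y]]
    if (y %in% names(ax) || x %in% names(ay)) {
      d <- if (y %in% names(ax)) ax[[y]] else ay[[x]]
      return(data.frame(id1 = x, id2 = y, d = d, a = 0L,
                        degree = d,
                        family = if (d == 1) "parent_offspring"
                        else "ancestor_descendant"))
    }
    com <- intersect(names(ax), names(ay))
    if (!length(com))
      return(data.frame(id1 = x, id2 = y, d = NA_integer_, a = NA_integer_,
                        degree = NA_integer_, family = "unrelated"))
    tot <- ax[com] + ay[com]
    d <- min(tot)
    a <- min(2L, sum(tot == d))
    fam <- if (a == 2L && d == 2L) "full_sibling"
    else if (a == 2L && d == 3L) "avuncular"
    else "generic"
    data.frame(id1 = x, id2 = y, d = as.integer(d), a = a,
               degree = as.integer(d - (a == 2L)), family = fam)
  })
  as.data.frame(data.table::rbindlist(out))
}
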