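#' Pedigree graph container
#'
#' A directed acyclic parent-to-child structure with union (reproductive
#' partnership) records. Individuals are rows of a data.frame with at least
#' \code{id}, \code{sex}, \code{father}, \code{mother} (parent ids or
#' \code{NA}); simulated pedigrees carry full metadata (site, haplogroups,
#' birth year, age at death, generation, founder and observed flags).
#'
#' @param individuals data.frame with columns id, sex, father, mother (plus
#'   optional metadata columns).
#' @param unions data.frame with columns male_id, female_id (one row per
#'   reproductive partnership).
#' @param levirate_events data.frame logging widow re-partnering events
#'   (columns widow, deceased, successor, relation), may be empty.
#' @param replacement_generation generation at which a new founder cohort
#'   took over reproduction, or \code{NA}.
#' @return object of class \code{pedigree_graph}.
#' @export
new_pedigree_graph <- function(individuals, unions,
                               levirate_events = NULL,
                               replacement_generation = NA_integer_) {
  stopifnot(all(c("id", "sex", "father", "mother") %in% names(individuals)))
  individuals$id <- as.character(individuals$id)
  if (anyDuplicated(individuals$id)) stop("duplicate individual ids in pedigree")
  for (col in c("father", "mother")) {
    bad <- !is.na(individuals[[col]]) &
      !(individuals[[col]] %in% individuals$id)
    if (any(bad)) {
      stop("pedigree parent not present: ",
           paste(unique(individuals[[col]][bad]), collapse = ", "))
    }
  }
  if (is.null(levirate_events)) {
    levirate_events <- data.frame(widow = character(), deceased = character(),
                                  successor = character(),
                                  relation = character(),
                                  stringsAsFactors = FALSE)
  }
  ped <- structure(list(individuals = individuals, unions = unions,
                        levirate_events = levirate_events,
                        replacement_generation = replacement_generation),
                   class = "pedigree_graph")
  if (!"generation" %in% names(individuals)) {
    ped$individuals$generation <- pedigree_generations(ped)
  }
  if (!"founder" %in% names(ped$individuals)) {
    ped$individuals$founder <- is.na(ped$individuals$father) &
      is.na(ped$individuals$mother)
  }
  ped
}

#' @export
print.pedigree_graph <- function(x, ...) {
  cat(sprintf("pedigree_graph: %d individuals, %d unions, %d generations\n",
              nrow(x$individuals), nrow(x$unions),
              max(x$individuals$generation)))
  invisible(x)
}

#' Generation index per individual
#'
#' Founders (no recorded parents) are generation 1; a child's generation is
#' one more than the maximum of its recorded parents'. Fails on cyclic
#' parent structures.
#'
#' @param ped a \code{pedigree_graph}.
#' @return integer vector aligned with \code{ped$individuals}.
#' @export
pedigree_generations <- function(ped) {
  ind <- ped$individuals
  n <- nrow(ind)
  gen <- rep(NA_integer_, n)
  idx <- stats::setNames(seq_len(n), ind$id)
  fa <- idx[ind$father]
  mo <- idx[ind$mother]
  gen[is.na(fa) & is.na(mo)] <- 1L
  for (pass in seq_len(n + 1)) {
    todo <- which(is.na(gen))
    if (!length(todo)) break
    if (pass > n) stop("cyclic parent structure in pedigree")
    for (i in todo) {
      par <- c(fa[i], mo[i])
      par <- par[!is.na(par)]
      if (!anyNA(gen[par])) gen[i] <- max(gen[par]) + 1L
    }
  }
  gen
}

#' Pedigree kinship coefficient
#'
#' Probability that one allele drawn at random from each of two individuals
#' is identical by descent, computed by the standard recursion over
#' recorded parents (founders are taken as unrelated and non-inbred).
#' Parent-child and full siblings have kinship 1/4.
#'
#' @param ped a \code{pedigree_graph}.
#' @param a,b individual ids.
#' @param cache optional environment for memoization across calls.
#' @return numeric kinship coefficient in \code{[0, 0.5]} (above 0.5 only
#'   for inbred self-kinship).
#' @export
pedigree_kinship <- function(ped, a, b, cache = NULL) {
  ind <- ped$individuals
  idx <- stats::setNames(seq_len(nrow(ind)), ind$id)
  gen <- ind$generation
  fa <- ind$father
  mo <- ind$mother
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  phi <- function(x, y) {
    if (is.na(x) || is.na(y)) return(0)
    key <- if (x <= y) paste(x, y, sep = "\r") else paste(y, x, sep = "\r")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    i <- idx[[x]]; j <- idx[[y]]
    val <- if (x == y) {
      0.5 * (1 + phi(fa[i], mo[i]))
    } else if (gen[i] >= gen[j]) {
      # i cannot be an ancestor of j: recurse through i's parents
      0.5 * (phi(fa[i], y) + phi(mo[i], y))
    } else {
      0.5 * (phi(fa[j], x) + phi(mo[j], x))
    }
    cache[[key]] <- val
    val
  }
  phi(as.character(a), as.character(b))
}

#' Genealogical degree of relationship
#'
#' Genetic degree derived from the pedigree kinship coefficient phi as
#' \code{-log2(2*phi)} rounded to the nearest integer: parent-child and
#' full siblings are degree 1, avuncular/grandparent/half-sibling degree 2,
#' first cousins degree 3, second cousins degree 5. Unrelated pairs give
#' \code{Inf}.
#'
#' @inheritParams pedigree_kinship
#' @return numeric degree (\code{Inf} when kinship is 0).
#' @export
relationship_degree <- function(ped, a, b, cache = NULL) {
  phi <- pedigree_kinship(ped, a, b, cache)
  if (phi <= 0) return(Inf)
  round(-log2(2 * phi))
}

#' Patrilineal ancestor chain
#' @param ped pedigree.
#' @param id individual id.
#' @return character vector of ids following father links, starting at
#'   \code{id}, ending at the patriline founder.
#' @export
patriline_of <- function(ped, id) {
  ind <- ped$individuals
  fa <- stats::setNames(ind$father, ind$id)
  chain <- as.character(id)
  while (!is.na(fa[[chain[length(chain)]]])) {
    chain <- c(chain, fa[[chain[length(chain)]]])
  }
  chain
}

#' Agnatic relation between two males
#'
#' Classifies the relation through exclusively male links:
#' \code{father_son}, \code{full_brothers}, \code{paternal_half_brothers},
#' \code{paternal_uncle_nephew}, \code{other_agnate} (sharing a patrilineal
#' ancestor otherwise) or \code{unrelated}.
#'
#' @param ped pedigree.
#' @param m1,m2 male individual ids.
#' @return character scalar relation label.
#' @export
agnatic_relation <- function(ped, m1, m2) {
  ind <- ped$individuals
  fa <- stats::setNames(ind$father, ind$id)
  mo <- stats::setNames(ind$mother, ind$id)
  m1 <- as.character(m1); m2 <- as.character(m2)
  f1 <- fa[[m1]]; f2 <- fa[[m2]]
  if ((!is.na(f1) && f1 == m2) || (!is.na(f2) && f2 == m1)) {
    return("father_son")
  }
  if (!is.na(f1) && !is.na(f2) && f1 == f2) {
    same_mother <- !is.na(mo[[m1]]) && !is.na(mo[[m2]]) && mo[[m1]] == mo[[m2]]
    return(if (same_mother) "full_brothers" else "paternal_half_brothers")
  }
  # paternal uncle: one male shares a father with the other's father
  uncle_of <- function(u, nephew) {
    fn <- fa[[nephew]]
    !is.na(fn) && !is.na(fa[[u]]) && !is.na(fa[[fn]]) && fa[[u]] == fa[[fn]] &&
      u != fn
  }
  if (uncle_of(m1, m2) || uncle_of(m2, m1)) return("paternal_uncle_nephew")
  p1 <- patriline_of(ped, m1)
  p2 <- patriline_of(ped, m2)
  if (length(intersect(p1, p2)) > 0) return("other_agnate")
  "unrelated"
}

#' Children of an individual
#' @param ped pedigree.
#' @param id parent id.
#' @return character vector of child ids.
#' @export
children_of <- function(ped, id) {
  ind <- ped$individuals
  ind$id[(!is.na(ind$father) & ind$father == id) |
           (!is.na(ind$mother) & ind$mother == id)]
}

#' Subset a pedigree to its observed (buried) individuals
#'
#' Parent links pointing at unobserved individuals are retained in the
#' metadata but the returned individual table contains only observed rows.
#' @param ped pedigree with an \code{observed} logical column.
#' @return data.frame of observed individuals.
#' @export
observed_individuals <- function(ped) {
  stopifnot("observed" %in% names(ped$individuals))
  ped$individuals[ped$individuals$observed, , drop = FALSE]
}
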