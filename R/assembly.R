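#' Constraints used during pedigree assembly
#'
#' @param enforce_mt_mother_child require matching mtDNA labels along
#'   mother-child edges (default TRUE).
#' @param enforce_y_father_son require matching Y labels along father-son
#'   edges (default TRUE).
#' @param allow_missing_individuals infer single unobserved parents that
#'   connect at least two observed relatives (default TRUE).
#' @return object of class \code{assembly_constraints}.
#' @export
assembly_constraints <- function(enforce_mt_mother_child = TRUE,
                                 enforce_y_father_son = TRUE,
                                 allow_missing_individuals = TRUE) {
  structure(list(enforce_mt_mother_child = enforce_mt_mother_child,
                 enforce_y_father_son = enforce_y_father_son,
                 allow_missing_individuals = allow_missing_individuals),
            class = "assembly_constraints")
}

# orientation of a parent_child pair: returns parent id, child id or NULL
# when age information cannot decide (no guessing)
orient_parent_child <- function(a, b, meta) {
  ba <- meta$birth_year[meta$id == a]
  bb <- meta$birth_year[meta$id == b]
  if (length(ba) == 1 && length(bb) == 1 && !is.na(ba) && !is.na(bb) &&
      ba != bb) {
    return(if (ba < bb) c(a, b) else c(b, a))
  }
  phases <- c(early = 1, middle = 2, late = 3)
  pa <- phases[meta$phase[meta$id == a]]
  pb <- phases[meta$phase[meta$id == b]]
  if (length(pa) == 1 && length(pb) == 1 && !is.na(pa) && !is.na(pb) &&
      pa != pb) {
    return(if (pa < pb) c(a, b) else c(b, a))
  }
  # adult/subadult contrast: a subadult cannot be the parent of an adult
  aa <- meta$age_class[meta$id == a]
  ab <- meta$age_class[meta$id == b]
  if (length(aa) == 1 && length(ab) == 1) {
    if (aa == "adult" && ab == "subadult") return(c(a, b))
    if (aa == "subadult" && ab == "adult") return(c(b, a))
  }
  NULL
}

#' Assemble pedigrees from pairwise relatedness calls
#'
#' Connected components over first- and second-degree calls become
#' candidate pedigrees. Within each component parent-child pairs are
#' oriented by birth year, chronological phase or adult/subadult contrast
#' (equal or unknown ages are left unresolved rather than guessed);
#' fathers and mothers are assigned by sex; uniparental-haplogroup
#' constraints are checked along every oriented edge; sibling sets are
#' grouped and, when no consistent observed parent exists, a single
#' unobserved parent connecting at least two observed relatives is
#' emitted as an inferred individual. Irreconcilable constraints produce a
#' per-component conflict report and leave the edge unresolved.
#'
#' @param calls data.frame from [classify_pairs()] (id_a, id_b, degree).
#' @param individuals metadata data.frame (id, sex, plus birth_year /
#'   phase / age_class / y_haplogroup / mt_haplogroup when available).
#' @param constraints an [assembly_constraints()].
#' @return list of \code{pedigree_graph} objects (one per component, in
#'   deterministic order), each carrying attributes \code{conflicts}
#'   (data.frame) and \code{member_ids}; inferred ghost individuals have
#'   ids prefixed \code{"inferred_"}.
#' @export
assemble_pedigrees <- function(calls, individuals,
                               constraints = assembly_constraints()) {
  close_deg <- c(first_degree_labels, "second")
  edges <- calls[calls$degree %in% close_deg, , drop = FALSE]
  if (!nrow(edges)) return(list())
  g <- igraph::graph_from_data_frame(edges[, c("id_a", "id_b")],
                                     directed = FALSE)
  comp <- igraph::components(g)
  membership <- split(names(comp$membership), comp$membership)
  membership <- membership[order(vapply(membership, min, character(1)))]
  lapply(membership, function(ids) {
    assemble_component(ids, edges, individuals, constraints)
  })
}

assemble_component <- function(ids, edges, individuals, constraints) {
  meta <- individuals[individuals$id %in% ids, , drop = FALSE]
  in_comp <- edges$id_a %in% ids & edges$id_b %in% ids
  e <- edges[in_comp, , drop = FALSE]
  conflicts <- list()
  add_conflict <- function(a, b, reason) {
    conflicts[[length(conflicts) + 1L]] <<- data.frame(
      id_a = a, id_b = b, reason = reason, stringsAsFactors = FALSE)
  }
  father <- stats::setNames(rep(NA_character_, length(ids)), ids)
  mother <- stats::setNames(rep(NA_character_, length(ids)), ids)
  meta_field <- function(id, field) {
    if (!field %in% names(meta)) return(NA)
    v <- meta[[field]][meta$id == id]
    if (length(v) != 1) NA else v
  }
  # ambiguous first-degree pairs with near-complete IBD1 coverage can only
  # be parent-child (siblings sit near p1 = 1/2); slight IBD2 from a
  # distantly consanguineous parental union pushes such pairs out of the
  # strict parent_child bin
  is_pc <- e$degree == "parent_child"
  if ("p1" %in% names(e)) {
    is_pc <- is_pc | (e$degree == "first_ambiguous" & !is.na(e$p1) &
                        e$p1 > 0.9)
  }
  pc <- e[is_pc, , drop = FALSE]
  ord <- order(pc$id_a, pc$id_b)
  for (r in ord) {
    a <- pc$id_a[r]; b <- pc$id_b[r]
    o <- orient_parent_child(a, b, meta)
    if (is.null(o)) {
      add_conflict(a, b, "parent_child orientation unresolved")
      next
    }
    parent <- o[1]; child <- o[2]
    psex <- meta_field(parent, "sex")
    if (is.na(psex) || !psex %in% c("male", "female")) {
      add_conflict(parent, child, "parent sex unknown")
      next
    }
    if (psex == "male") {
      if (constraints$enforce_y_father_son &&
          identical(meta_field(child, "sex"), "male")) {
        yp <- meta_field(parent, "y_haplogroup")
        yc <- meta_field(child, "y_haplogroup")
        if (!is.na(yp) && !is.na(yc) && yp != yc) {
          add_conflict(parent, child, "Y haplogroup mismatch on father-son")
          next
        }
      }
      if (!is.na(father[[child]]) && father[[child]] != parent) {
        add_conflict(parent, child, "second father candidate")
        next
      }
      father[[child]] <- parent
    } else {
      if (constraints$enforce_mt_mother_child) {
        mp <- meta_field(parent, "mt_haplogroup")
        mc <- meta_field(child, "mt_haplogroup")
        if (!is.na(mp) && !is.na(mc) && mp != mc) {
          add_conflict(parent, child, "mtDNA mismatch on mother-child")
          next
        }
      }
      if (!is.na(mother[[child]]) && mother[[child]] != parent) {
        add_conflict(parent, child, "second mother candidate")
        next
      }
      mother[[child]] <- parent
    }
  }
  # sibling grouping: siblings share parents; propagate known parents and
  # check mtDNA consistency within full-sibling sets
  sib <- e[e$degree == "sibling", , drop = FALSE]
  ghost_rows <- list()
  if (nrow(sib)) {
    sg <- igraph::graph_from_data_frame(sib[, c("id_a", "id_b")],
                                        directed = FALSE)
    sets <- split(names(igraph::components(sg)$membership),
                  igraph::components(sg)$membership)
    ghost_n <- 0L
    for (set in sets) {
      set <- sort(set)
      for (side in c("father", "mother")) {
        vec <- if (side == "father") father else mother
        known <- unique(stats::na.omit(vec[set]))
        if (length(known) > 1) {
          # legitimately possible for 3/4-sibling sets (levirate offspring
          # share a mother while their fathers are brothers): surfaced,
          # never merged
          add_conflict(set[1], set[2],
                       paste("multiple", side, "candidates across sibling set"))
        } else if (length(known) == 1) {
          # a parent known for part of the set is never propagated to the
          # rest: a missing parent-child call may mean a different,
          # unobserved parent
        } else if (constraints$allow_missing_individuals &&
                   length(set) >= 2) {
          ghost_n <- ghost_n + 1L
          gid <- sprintf("inferred_%s_%s%d", set[1],
                         substr(side, 1, 1), ghost_n)
          ghost_rows[[gid]] <- data.frame(
            id = gid, sex = if (side == "father") "male" else "female",
            father = NA_character_, mother = NA_character_,
            stringsAsFactors = FALSE)
          for (s in set) {
            if (side == "father") father[[s]] <- gid else mother[[s]] <- gid
          }
        }
      }
    }
  }
  ind <- data.frame(id = ids,
                    sex = vapply(ids, function(i) {
                      s <- meta_field(i, "sex")
                      if (is.na(s)) "unknown" else s
                    }, character(1)),
                    father = unname(father[ids]),
                    mother = unname(mother[ids]),
                    stringsAsFactors = FALSE)
  if (length(ghost_rows)) {
    ghosts <- do.call(rbind, ghost_rows)
    ghosts$observed <- FALSE
    ind$observed <- TRUE
    ind <- rbind(ind, ghosts[, names(ind)])
  }
  # carry metadata columns over where available
  for (col in c("site", "birth_year", "age_class", "phase", "y_haplogroup",
                "mt_haplogroup")) {
    if (col %in% names(meta)) {
      ind[[col]] <- meta[[col]][match(ind$id, meta$id)]
    }
  }
  couples <- unique(ind[!is.na(ind$father) & !is.na(ind$mother),
                        c("father", "mother")])
  unions <- data.frame(male_id = couples$father, female_id = couples$mother,
                       stringsAsFactors = FALSE)
  ped <- new_pedigree_graph(ind, unions)
  attr(ped, "conflicts") <- if (length(conflicts)) {
    do.call(rbind, conflicts)
  } else {
    data.frame(id_a = character(), id_b = character(), reason = character(),
               stringsAsFactors = FALSE)
  }
  attr(ped, "member_ids") <- ids
  ped
}

#' Patriliny and exogamy metrics of a pedigree
#'
#' Sons and daughters are individuals with at least one recorded parent;
#' mothers are split into exogamous (no parent present) and lineage
#' (parent present) mothers, with \code{exogamy_rate_postfounding}
#' computed over partners of non-founder fathers only (founding-
#' generation wives are exogamous by construction); patriline purity is
#' the fraction of fathers
#' whose father-chain ends in a male flagged as founder (when founder
#' flags exist) with a consistent Y label along the chain (when labels
#' exist).
#'
#' @param ped a \code{pedigree_graph}.
#' @return list of counts and ratios (class \code{social_metrics}).
#' @export
patriliny_metrics <- function(ped) {
  ind <- ped$individuals
  has_parent <- !is.na(ind$father) | !is.na(ind$mother)
  n_sons <- sum(has_parent & ind$sex == "male")
  n_daughters <- sum(has_parent & ind$sex == "female")
  mothers <- unique(stats::na.omit(ind$mother))
  mother_has_parent <- has_parent[match(mothers, ind$id)]
  fathers <- unique(stats::na.omit(ind$father))
  # post-founding mothers: partners of non-founder fathers; the founding
  # generation's wives are exogamous by construction (the community does
  # not predate its founders), so parameter recovery uses this subset
  founder_flag <- if ("founder" %in% names(ind)) ind$founder else
    is.na(ind$father) & is.na(ind$mother)
  nonfounder_father <- !is.na(ind$father) &
    !founder_flag[match(ind$father, ind$id)]
  pf_mothers <- unique(ind$mother[nonfounder_father & !is.na(ind$mother)])
  pf_has_parent <- has_parent[match(pf_mothers, ind$id)]
  pure <- vapply(fathers, function(f) {
    chain <- patriline_of(ped, f)
    head_ok <- if ("founder" %in% names(ind)) {
      isTRUE(ind$founder[match(chain[length(chain)], ind$id)])
    } else TRUE
    y_ok <- if ("y_haplogroup" %in% names(ind)) {
      ys <- ind$y_haplogroup[match(chain, ind$id)]
      ys <- ys[!is.na(ys)]
      length(unique(ys)) <= 1
    } else TRUE
    head_ok && y_ok
  }, logical(1))
  structure(list(n_sons = n_sons, n_daughters = n_daughters,
                 n_exogamous_mothers = sum(!mother_has_parent),
                 n_lineage_mothers = sum(mother_has_parent),
                 n_fathers = length(fathers),
                 exogamy_rate_postfounding = if (length(pf_mothers)) {
                   mean(!pf_has_parent)
                 } else NA_real_,
                 patriline_purity = if (length(fathers)) mean(pure) else
                   NA_real_),
            class = "social_metrics")
}

#' Shared-partner (levirate-consistent) unions
#'
#' All pairs of distinct males sharing a reproductive partner, labelled
#' with their agnatic relation; pairs whose males are agnates are flagged
#' levirate-consistent (the alternative reading being concurrent
#' polyandry).
#'
#' @param ped a \code{pedigree_graph} with union records.
#' @return data.frame with male_a, male_b, female, relation,
#'   levirate_consistent.
#' @export
detect_shared_partner_unions <- function(ped) {
  u <- unique(ped$unions[, c("male_id", "female_id")])
  females <- unique(u$female_id[duplicated(u$female_id)])
  rows <- list()
  for (f in females) {
    males <- sort(unique(u$male_id[u$female_id == f]))
    if (length(males) < 2) next
    cmb <- utils::combn(males, 2)
    for (k in seq_len(ncol(cmb))) {
      rel <- agnatic_relation(ped, cmb[1, k], cmb[2, k])
      rows[[length(rows) + 1L]] <- data.frame(
        male_a = cmb[1, k], male_b = cmb[2, k], female = f, relation = rel,
        levirate_consistent = rel != "unrelated", stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(male_a = character(), male_b = character(),
                      female = character(), relation = character(),
                      levirate_consistent = logical(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Reproductive-partner counts per individual
#'
#' @param ped a \code{pedigree_graph} with union records.
#' @return data.frame with id, sex, n_partners (individuals in at least
#'   one union only).
#' @export
partner_counts <- function(ped) {
  u <- unique(ped$unions[, c("male_id", "female_id")])
  ids <- c(u$male_id, u$female_id)
  if (!length(ids)) {
    return(data.frame(id = character(), sex = character(),
                      n_partners = integer(), stringsAsFactors = FALSE))
  }
  cnt <- table(ids)
  sex <- ped$individuals$sex[match(names(cnt), ped$individuals$id)]
  data.frame(id = names(cnt), sex = sex, n_partners = as.integer(cnt),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Sex counts of unrelated individuals
#'
#' "Unrelated" means no first-, second- or third-degree call to anyone at
#' the same site.
#'
#' @param calls data.frame from [classify_pairs()].
#' @param individuals metadata (id, site, sex).
#' @return data.frame with site, sex and count of unrelated individuals.
#' @export
unrelated_sex_counts <- function(calls, individuals) {
  close_deg <- c(first_degree_labels, "second", "third", "identical")
  rel <- calls[calls$degree %in% close_deg, , drop = FALSE]
  site <- stats::setNames(individuals$site, individuals$id)
  same_site <- site[rel$id_a] == site[rel$id_b]
  related_ids <- unique(c(rel$id_a[same_site], rel$id_b[same_site]))
  unrel <- individuals[!individuals$id %in% related_ids, , drop = FALSE]
  as.data.frame(table(site = unrel$site, sex = unrel$sex),
                responseName = "n", stringsAsFactors = FALSE)
}
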