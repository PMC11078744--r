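#' @title Founder-labelled genome transmission
#' @description Genomes are represented as labelled diplotypes: per
#'   chromosome, two haplotypes, each a tiling of \code{[0, length_cM)} by
#'   founder-haplotype labels. Founders carry two uniquely labelled
#'   whole-chromosome tiles; meiosis recombines parental haplotypes with
#'   Poisson crossovers (no interference) so that identity by descent can
#'   be read off exactly from label equality.
#' @name transmission
NULL

founder_haplotype <- function(length_cM, label) {
  list(bp = c(0, length_cM), lab = label)
}

# label of haplotype h at positions x (vectorized); tiles are [bp_i, bp_{i+1})
lab_at <- function(h, x) {
  h$lab[findInterval(x, h$bp, rightmost.closed = TRUE)]
}

# extract [s, e) from haplotype h as (bp, lab) pieces
splice_haplotype <- function(h, s, e) {
  keep <- which(h$bp[-length(h$bp)] < e & h$bp[-1] > s)
  bp <- h$bp[c(keep, max(keep) + 1L)]
  bp[1] <- s
  bp[length(bp)] <- e
  list(bp = bp, lab = h$lab[keep])
}

merge_tiles <- function(bp, lab) {
  n <- length(lab)
  if (n <= 1) return(list(bp = bp, lab = lab))
  changed <- lab[-1] != lab[-n]
  list(bp = c(bp[1], bp[2:n][changed], bp[n + 1L]),
       lab = lab[c(TRUE, changed)])
}

# one meiosis on a single chromosome: crossover count ~ Poisson(L/100),
# positions uniform, random starting haplotype, no interference
meiosis_chrom <- function(chrom_pair, L) {
  k <- stats::rpois(1, L / 100)
  start <- sample.int(2L, 1L)
  if (k == 0) return(chrom_pair[[start]])
  cuts <- sort(stats::runif(k, 0, L))
  bounds <- c(0, cuts, L)
  pieces_bp <- numeric(0)
  pieces_lab <- integer(0)
  for (j in seq_len(length(bounds) - 1L)) {
    src <- chrom_pair[[((start - 1L + j - 1L) %% 2L) + 1L]]
    sp <- splice_haplotype(src, bounds[j], bounds[j + 1L])
    if (length(pieces_bp)) {
      pieces_bp <- c(pieces_bp[-length(pieces_bp)], sp$bp)
    } else {
      pieces_bp <- sp$bp
    }
    pieces_lab <- c(pieces_lab, sp$lab)
  }
  merge_tiles(pieces_bp, pieces_lab)
}

#' Transmit founder-labelled genomes through a pedigree
#'
#' Founders receive two uniquely labelled whole-chromosome tiles per
#' chromosome; every child genome is formed from one gamete of each parent,
#' each gamete produced by Poisson-crossover meiosis (crossover count
#' Poisson(length/100), positions uniform, random starting haplotype, no
#' interference). Deterministic given \code{seed}.
#'
#' @param ped a \code{pedigree_graph}; children must have both parents
#'   recorded or none (founders).
#' @param map a \code{genetic_map}.
#' @param seed optional integer seed.
#' @return named list of diplotypes; each diplotype is a list over
#'   chromosomes of \code{list(h1, h2)} haplotype tilings.
#' @export
drop_genomes <- function(ped, map = default_genetic_map(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ind <- ped$individuals
  half_orphan <- xor(is.na(ind$father), is.na(ind$mother))
  if (any(half_orphan)) {
    stop("cannot transmit genome: individual(s) with exactly one recorded ",
         "parent: ", paste(ind$id[half_orphan], collapse = ", "))
  }
  ord <- order(ind$generation)
  genomes <- vector("list", nrow(ind))
  names(genomes) <- ind$id
  next_label <- 1L
  for (i in ord) {
    id <- ind$id[i]
    if (is.na(ind$father[i])) {
      l1 <- next_label
      l2 <- next_label + 1L
      next_label <- next_label + 2L
      genomes[[id]] <- lapply(map$length_cM, function(L) {
        list(h1 = founder_haplotype(L, l1), h2 = founder_haplotype(L, l2))
      })
    } else {
      pa <- genomes[[ind$father[i]]]
      ma <- genomes[[ind$mother[i]]]
      genomes[[id]] <- lapply(seq_len(nrow(map)), function(ci) {
        L <- map$length_cM[ci]
        list(h1 = meiosis_chrom(pa[[ci]], L), h2 = meiosis_chrom(ma[[ci]], L))
      })
    }
  }
  names(genomes) <- ind$id
  genomes
}

#' True pairwise IBD segments between two diplotypes
#'
#' At each map position the IBD state is 2 where the two haplotype labels
#' of \code{a} match both of \code{b}'s as a multiset, 1 where exactly one
#' pair matches, 0 otherwise; maximal runs are emitted as segments.
#' Symmetric in its arguments.
#'
#' @param a,b diplotypes from [drop_genomes()].
#' @param map the shared \code{genetic_map}.
#' @return data.frame with columns chrom, start_cM, end_cM, length_cM,
#'   state ("IBD1"/"IBD2").
#' @export
pairwise_ibd <- function(a, b, map = default_genetic_map()) {
  if (length(a) != nrow(map) || length(b) != nrow(map)) {
    stop("diplotypes do not match the genetic map")
  }
  chrom <- character(0); s0 <- numeric(0); e0 <- numeric(0)
  st0 <- integer(0)
  for (ci in seq_len(nrow(map))) {
    ac <- a[[ci]]
    bc <- b[[ci]]
    bp <- sort(unique(c(ac$h1$bp, ac$h2$bp, bc$h1$bp, bc$h2$bp)))
    mids <- (bp[-1] + bp[-length(bp)]) / 2
    a1 <- lab_at(ac$h1, mids); a2 <- lab_at(ac$h2, mids)
    b1 <- lab_at(bc$h1, mids); b2 <- lab_at(bc$h2, mids)
    state <- pmax((a1 == b1) + (a2 == b2), (a1 == b2) + (a2 == b1))
    r <- rle(state)
    keep <- r$values > 0
    if (!any(keep)) next
    ends <- bp[-1][cumsum(r$lengths)]
    starts <- c(bp[1], ends[-length(ends)])
    chrom <- c(chrom, rep(map$chrom[ci], sum(keep)))
    s0 <- c(s0, starts[keep]); e0 <- c(e0, ends[keep])
    st0 <- c(st0, r$values[keep])
  }
  data.frame(chrom = chrom, start_cM = s0, end_cM = e0,
             length_cM = e0 - s0,
             state = c("IBD1", "IBD2")[st0], stringsAsFactors = FALSE)
}

# founder-haplotype labels carried anywhere in a diplotype; two genomes
# with disjoint label sets share no IBD, which lets all-pairs scans skip
# unrelated pairs exactly
diplotype_labels <- function(a) {
  unique(unlist(lapply(a, function(ch) c(ch$h1$lab, ch$h2$lab)),
                use.names = FALSE))
}

#' Runs of homozygosity of one diplotype
#'
#' Maximal intervals where the two haplotype labels coincide, i.e. where
#' the individual's two chromosomes are identical by descent. All runs are
#' reported; the conventional > 4 cM filter for consanguinity detection is
#' applied downstream.
#'
#' @param a a diplotype.
#' @param map the \code{genetic_map}.
#' @return data.frame with columns chrom, start_cM, end_cM, length_cM.
#' @export
roh_segments <- function(a, map = default_genetic_map()) {
  out <- vector("list", nrow(map))
  for (ci in seq_len(nrow(map))) {
    ac <- a[[ci]]
    bp <- sort(unique(c(ac$h1$bp, ac$h2$bp)))
    mids <- (bp[-1] + bp[-length(bp)]) / 2
    hom <- lab_at(ac$h1, mids) == lab_at(ac$h2, mids)
    r <- rle(hom)
    ends <- bp[-1][cumsum(r$lengths)]
    starts <- c(bp[1], ends[-length(ends)])
    keep <- r$values
    if (!any(keep)) next
    out[[ci]] <- data.frame(chrom = map$chrom[ci], start_cM = starts[keep],
                            end_cM = ends[keep],
                            length_cM = ends[keep] - starts[keep],
                            stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) {
    return(data.frame(chrom = character(), start_cM = numeric(),
                      end_cM = numeric(), length_cM = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Ancient-DNA-style observation model for IBD segments
#'
#' @param min_detect_cM minimum detectable segment length (default 8 cM,
#'   the conventional detection floor for haplotype-IBD callers on imputed
#'   ancient genomes).
#' @param snps_per_cM SNP density used to assign \code{n_snps} (default a
#'   220-per-cM-equivalent density).
#' @param boundary_jitter_cM segment boundaries are jittered uniformly by
#'   up to this much on each side (clipped to the chromosome).
#' @param dropout_prob function of segment length giving the probability
#'   that a segment is missed entirely; should be monotone decreasing.
#'   The default, 0.5 * exp(-length / 10), emulates the detection loss of
#'   haplotype-IBD calling on coverage-matched ancient genomes; pass
#'   \code{NULL} for no dropout.
#' @param seed optional integer seed used by [degrade_segments()].
#' @return object of class \code{observation_model}.
#' @export
observation_model <- function(min_detect_cM = 8, snps_per_cM = 220,
                              boundary_jitter_cM = 0.5,
                              dropout_prob = function(l) 0.5 * exp(-l / 10),
                              seed = NULL) {
  if (min_detect_cM < 0 || snps_per_cM <= 0 || boundary_jitter_cM < 0) {
    stop("invalid observation model parameters")
  }
  structure(list(min_detect_cM = min_detect_cM, snps_per_cM = snps_per_cM,
                 boundary_jitter_cM = boundary_jitter_cM,
                 dropout_prob = dropout_prob, seed = seed),
            class = "observation_model")
}

#' Degrade true IBD segments to observed ones
#'
#' Boundaries are jittered by up to \code{boundary_jitter_cM} (clipped to
#' the chromosome), segments are dropped stochastically with probability
#' \code{dropout_prob(length)}, segments shorter than \code{min_detect_cM}
#' are removed, and \code{n_snps} is assigned as round(length x
#' snps_per_cM). Deterministic given the model seed.
#'
#' @param segs segment data.frame as from [pairwise_ibd()] (optionally with
#'   id columns).
#' @param model an [observation_model()].
#' @param map the \code{genetic_map}.
#' @return degraded segment data.frame with an \code{n_snps} column.
#' @export
degrade_segments <- function(segs, model, map = default_genetic_map()) {
  stopifnot(inherits(model, "observation_model"))
  if (!is.null(model$seed)) set.seed(model$seed)
  if (nrow(segs) == 0) {
    segs$n_snps <- numeric(0)
    return(segs)
  }
  lens <- chrom_length(map, segs$chrom)
  if (model$boundary_jitter_cM > 0) {
    j <- model$boundary_jitter_cM
    segs$start_cM <- pmax(0, segs$start_cM + stats::runif(nrow(segs), -j, j))
    segs$end_cM <- pmin(lens, segs$end_cM + stats::runif(nrow(segs), -j, j))
    ok <- segs$start_cM < segs$end_cM
    segs <- segs[ok, , drop = FALSE]
  }
  segs$length_cM <- segs$end_cM - segs$start_cM
  if (!is.null(model$dropout_prob)) {
    p <- model$dropout_prob(segs$length_cM)
    segs <- segs[stats::runif(nrow(segs)) >= p, , drop = FALSE]
  }
  segs <- segs[segs$length_cM >= model$min_detect_cM, , drop = FALSE]
  segs$n_snps <- round(segs$length_cM * model$snps_per_cM)
  rownames(segs) <- NULL
  segs
}

#' Pairwise IBD for a set of individuals
#'
#' Computes true IBD segments for every unordered pair among \code{ids},
#' optionally degrades them with an observation model, and returns an
#' \code{ibd_pairs} object with recomputed summaries.
#'
#' @param genomes named list from [drop_genomes()].
#' @param ids individual ids to include (default all).
#' @param map genetic map.
#' @param model optional [observation_model()] applied to the pooled
#'   segment table.
#' @return an \code{ibd_pairs} object.
#' @export
compute_pairwise_ibd <- function(genomes, ids = names(genomes),
                                 map = default_genetic_map(), model = NULL) {
  ids <- as.character(ids)
  n <- length(ids)
  labels <- lapply(ids, function(id) diplotype_labels(genomes[[id]]))
  acc <- list()
  for (i in seq_len(max(0, n - 1))) {
    for (j in seq((i + 1), n)) {
      if (!any(labels[[i]] %in% labels[[j]])) next
      segs <- pairwise_ibd(genomes[[ids[i]]], genomes[[ids[j]]], map)
      if (nrow(segs)) {
        segs$id_a <- ids[i]
        segs$id_b <- ids[j]
        acc[[length(acc) + 1L]] <- segs
      }
    }
  }
  segs <- if (length(acc)) do.call(rbind, acc) else empty_segments()
  if (!is.null(model) && nrow(segs)) {
    segs <- degrade_segments(segs, model, map)
  }
  if (nrow(segs) && !"n_snps" %in% names(segs)) segs$n_snps <- NA_real_
  ibd_pairs_from_segments(segs, map)
}
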