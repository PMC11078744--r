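#' Filter IBD pairs into network edges
#'
#' Implements the segment and pair filters used for haplotype-IBD sharing
#' networks on imputed ancient genomes: individuals with at most
#' \code{min_snp_count} covered SNPs are dropped; segments are kept only
#' if longer than 8 cM with a density above 220 SNPs per cM; a pair
#' becomes an edge only if it retains at least one segment longer than
#' 12 cM, and if its longest retained segment is shorter than 16 cM it
#' must retain at least two segments longer than 12 cM. The edge weight is
#' the longest single retained segment (maximum IBD), not total sharing.
#'
#' @param pairs an \code{ibd_pairs} object with per-segment rows carrying
#'   \code{n_snps}.
#' @param individuals metadata data.frame with \code{id} and
#'   \code{snp_count} (individuals missing a count are retained).
#' @param min_snp_count coverage threshold (default 450,000).
#' @param min_segment_cM segment-length floor (default 8).
#' @param min_snps_per_cM segment-density floor (default 220).
#' @param edge_min_cM minimum segment length supporting an edge
#'   (default 12).
#' @param single_segment_min_cM below this longest-segment length a pair
#'   needs more than one supporting segment (default 16).
#' @return data.frame of edges: id_a, id_b, weight, n_segments (count of
#'   retained supporting segments).
#' @export
filter_edges <- function(pairs, individuals = NULL, min_snp_count = 450000,
                         min_segment_cM = 8, min_snps_per_cM = 220,
                         edge_min_cM = 12, single_segment_min_cM = 16) {
  stopifnot(inherits(pairs, "ibd_pairs"))
  segs <- pairs$segments
  empty <- data.frame(id_a = character(), id_b = character(),
                      weight = numeric(), n_segments = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(segs) == 0) return(empty)
  if (!is.null(individuals) && "snp_count" %in% names(individuals)) {
    low <- individuals$id[!is.na(individuals$snp_count) &
                            individuals$snp_count <= min_snp_count]
    segs <- segs[!(segs$id_a %in% low) & !(segs$id_b %in% low), ,
                 drop = FALSE]
  }
  dens <- segs$n_snps / segs$length_cM
  segs <- segs[segs$length_cM > min_segment_cM &
                 (is.na(dens) | dens > min_snps_per_cM), , drop = FALSE]
  segs <- segs[segs$length_cM > edge_min_cM, , drop = FALSE]
  if (nrow(segs) == 0) return(empty)
  key <- paste(segs$id_a, segs$id_b, sep = "\r")
  n_seg <- tapply(key, key, length)
  mx <- tapply(segs$length_cM, key, max)
  keep <- mx >= single_segment_min_cM | n_seg >= 2
  if (!any(keep)) return(empty)
  ids <- do.call(rbind, strsplit(names(mx)[keep], "\r", fixed = TRUE))
  out <- data.frame(id_a = ids[, 1], id_b = ids[, 2],
                    weight = as.numeric(mx[keep]),
                    n_segments = as.integer(n_seg[keep]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$id_a, out$id_b), , drop = FALSE]
}

#' Build a kinship (IBD-sharing) network
#'
#' Nodes are the individuals appearing in at least one retained edge,
#' after an optional restriction to adults (threshold 18 years: adult
#' \code{age_class} or \code{age_min >= 18}). The graph is undirected and
#' simple; a pair with many segments is one edge.
#'
#' @param edges edge data.frame from [filter_edges()].
#' @param individuals metadata (id, site, sex and age columns).
#' @param adults_only drop edges with a non-adult endpoint.
#' @return object of class \code{kin_network}: list with \code{nodes},
#'   \code{edges}, \code{adults_only}.
#' @export
build_network <- function(edges, individuals, adults_only = FALSE) {
  is_adult <- function(ids) {
    m <- match(ids, individuals$id)
    cls <- if ("age_class" %in% names(individuals)) {
      individuals$age_class[m]
    } else NA_character_
    amin <- if ("age_min" %in% names(individuals)) {
      individuals$age_min[m]
    } else NA_real_
    (!is.na(cls) & cls == "adult") | (!is.na(amin) & amin >= 18)
  }
  if (adults_only && nrow(edges)) {
    keep <- is_adult(edges$id_a) & is_adult(edges$id_b)
    edges <- edges[keep, , drop = FALSE]
  }
  ids <- sort(unique(c(edges$id_a, edges$id_b)))
  m <- match(ids, individuals$id)
  nodes <- data.frame(id = ids,
                      site = if ("site" %in% names(individuals)) {
                        individuals$site[m]
                      } else NA_character_,
                      sex = if ("sex" %in% names(individuals)) {
                        individuals$sex[m]
                      } else NA_character_,
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, adults_only = adults_only),
            class = "kin_network")
}

#' @export
print.kin_network <- function(x, ...) {
  cat(sprintf("kin_network: %d nodes, %d edges%s\n", nrow(x$nodes),
              nrow(x$edges), if (x$adults_only) " (adults only)" else ""))
  invisible(x)
}

#' Per-node network statistics
#'
#' Degree centrality k (number of links), strength w (sum of incident
#' edge weights), within-module degree k_W and between-module degree k_B
#' with the burial site as the module, and the ratio k_B/k (in [0, 1]).
#' Always k = k_W + k_B.
#'
#' @param network a \code{kin_network}.
#' @return data.frame with id, site, sex, k, w, k_W, k_B, kB_over_k;
#'   group means \code{mean_k} and \code{mean_w} (overall and by sex) are
#'   attached as attribute \code{group_means}.
#' @export
node_stats <- function(network) {
  stopifnot(inherits(network, "kin_network"))
  nodes <- network$nodes
  e <- network$edges
  site <- stats::setNames(nodes$site, nodes$id)
  k <- w <- kb <- stats::setNames(numeric(nrow(nodes)), nodes$id)
  if (nrow(e)) {
    for (col in c("id_a", "id_b")) {
      t_k <- table(e[[col]])
      k[names(t_k)] <- k[names(t_k)] + as.numeric(t_k)
      t_w <- tapply(e$weight, e[[col]], sum)
      w[names(t_w)] <- w[names(t_w)] + as.numeric(t_w)
      cross <- site[e$id_a] != site[e$id_b]
      t_b <- tapply(as.numeric(cross), e[[col]], sum)
      kb[names(t_b)] <- kb[names(t_b)] + as.numeric(t_b)
    }
  }
  out <- data.frame(id = nodes$id, site = nodes$site, sex = nodes$sex,
                    k = as.numeric(k), w = as.numeric(w),
                    k_W = as.numeric(k - kb), k_B = as.numeric(kb),
                    kB_over_k = ifelse(k > 0, kb / k, NA_real_),
                    stringsAsFactors = FALSE)
  by_sex <- lapply(split(out, out$sex), function(d) {
    c(mean_k = mean(d$k), mean_w = mean(d$w))
  })
  attr(out, "group_means") <- list(mean_k = mean(out$k),
                                   mean_w = mean(out$w), by_sex = by_sex)
  out
}

# two-sample KS statistic D = sup |ECDF_a - ECDF_b|
ks_statistic <- function(a, b) {
  pts <- sort(c(a, b))
  fa <- findInterval(pts, sort(a)) / length(a)
  fb <- findInterval(pts, sort(b)) / length(b)
  max(abs(fa - fb))
}

#' Two-sample Kolmogorov-Smirnov test with a permutation null
#'
#' D is the supremum distance between the two empirical CDFs; the null is
#' built by pooling both samples and re-splitting at the original sizes
#' \code{n_perm} times (pooled relabelling, the standard exchangeable
#' null). p = (1 + #\{D* >= D\}) / (1 + n_perm).
#'
#' @param values_a,values_b nonempty numeric samples.
#' @param n_perm number of permutations (default 1000).
#' @param seed optional integer seed.
#' @return list with \code{D}, \code{p} and \code{n_perm}.
#' @export
ks_permutation_test <- function(values_a, values_b, n_perm = 1000,
                                seed = NULL) {
  if (!length(values_a) || !length(values_b)) {
    stop("both samples must be nonempty")
  }
  if (!is.null(seed)) set.seed(seed)
  d_obs <- ks_statistic(values_a, values_b)
  pool <- c(values_a, values_b)
  na <- length(values_a)
  n <- length(pool)
  exceed <- 0L
  for (i in seq_len(n_perm)) {
    idx <- sample.int(n, na)
    d <- ks_statistic(pool[idx], pool[-idx])
    if (d >= d_obs - 1e-12) exceed <- exceed + 1L
  }
  list(D = d_obs, p = (1 + exceed) / (1 + n_perm), n_perm = n_perm)
}

#' Welch's two-sample t-test
#'
#' Welch statistic with Welch-Satterthwaite degrees of freedom and a
#' two-sided p-value.
#'
#' @param values_a,values_b numeric samples of size >= 2.
#' @return list with \code{t}, \code{df}, \code{p}.
#' @export
welch_t_test <- function(values_a, values_b) {
  if (length(values_a) < 2 || length(values_b) < 2) {
    stop("both samples must have size >= 2")
  }
  va <- stats::var(values_a) / length(values_a)
  vb <- stats::var(values_b) / length(values_b)
  if (!is.finite(va + vb) || va + vb == 0) stop("non-finite variance")
  t <- (mean(values_a) - mean(values_b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(values_a) - 1) +
                         vb^2 / (length(values_b) - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}
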