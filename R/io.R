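#' @title Tabular readers and writers
#' @description All tables are UTF-8, tab-separated with a header row,
#'   decimal point '.', missing values as empty cells. Readers are total on
#'   their documented dialects and reject rows violating type invariants
#'   with named errors.
#' @name io
NULL

read_tsv_base <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, na.strings = c("", "NA"),
                    check.names = FALSE, comment.char = "")
}

write_tsv_base <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("format error in %s: missing required column(s): %s",
                 what, paste(missing, collapse = ", ")))
  }
}

#' Read an individual-metadata table
#'
#' Expected columns: \code{id}, \code{site}, \code{sex} (required);
#' \code{age_class}, \code{age_min}, \code{age_max}, \code{phase},
#' \code{y_haplogroup}, \code{mt_haplogroup}, \code{snp_count},
#' \code{grave_x}, \code{grave_y} (optional). Unknown or empty cells map to
#' \code{"unknown"} / \code{NA}. Row order is preserved.
#'
#' Invariants enforced: ids unique; \code{y_haplogroup} absent for females;
#' individuals with an age range starting at 18 years or more are adults
#' (the adulthood threshold used throughout is 18 years).
#'
#' @param path path to a tab-separated table.
#' @return data.frame of individuals, one row per input row.
#' @export
read_individuals <- function(path) {
  df <- read_tsv_base(path)
  require_columns(df, c("id", "site", "sex"), "individual table")
  if (anyDuplicated(df$id)) {
    stop("validation error: duplicate individual id(s): ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  }
  opt_chr <- c("age_class", "phase", "y_haplogroup", "mt_haplogroup")
  for (col in opt_chr) {
    df[[col]] <- if (col %in% names(df)) as.character(df[[col]]) else
      NA_character_
  }
  opt_num <- c("age_min", "age_max", "snp_count", "grave_x", "grave_y")
  for (col in opt_num) {
    df[[col]] <- if (col %in% names(df)) as.numeric(df[[col]]) else NA_real_
  }
  df$sex <- ifelse(is.na(df$sex) | !(df$sex %in% c("male", "female")),
                   "unknown", df$sex)
  df$age_class <- ifelse(is.na(df$age_class) |
                           !(df$age_class %in% c("adult", "subadult")),
                         "unknown", df$age_class)
  df$phase <- ifelse(is.na(df$phase) |
                       !(df$phase %in% c("early", "middle", "late")),
                     "unknown", df$phase)
  bad_y <- df$sex == "female" & !is.na(df$y_haplogroup) & nzchar(df$y_haplogroup)
  if (any(bad_y)) {
    stop("validation error: y_haplogroup present for female individual(s): ",
         paste(df$id[bad_y], collapse = ", "))
  }
  # adult <=> age_min >= 18 where both stated
  has_both <- df$age_class %in% c("adult", "subadult") & !is.na(df$age_min)
  bad_age <- has_both & ((df$age_class == "adult") != (df$age_min >= 18))
  if (any(bad_age)) {
    stop("validation error: age_class inconsistent with age range for: ",
         paste(df$id[bad_age], collapse = ", "))
  }
  if (any(!is.na(df$snp_count) & df$snp_count < 0)) {
    stop("validation error: negative snp_count")
  }
  df
}

#' Write an individual-metadata table
#' @param individuals data.frame as returned by [read_individuals()].
#' @param path output path.
#' @export
write_individuals <- function(individuals, path) {
  cols <- c("id", "site", "sex", "age_class", "age_min", "age_max", "phase",
            "y_haplogroup", "mt_haplogroup", "snp_count", "grave_x", "grave_y")
  cols <- intersect(cols, names(individuals))
  write_tsv_base(individuals[, cols, drop = FALSE], path)
  invisible(path)
}

canonical_pair <- function(id_a, id_b) {
  a <- pmin(as.character(id_a), as.character(id_b))
  b <- pmax(as.character(id_a), as.character(id_b))
  list(id_a = a, id_b = b, key = paste(a, b, sep = "\r"))
}

#' Read a pairwise IBD table
#'
#' Two dialects are auto-detected by header. Per-segment rows carry columns
#' \code{id_a, id_b, chrom, start_cM, end_cM} (optional \code{n_snps},
#' \code{state}); per-pair summary rows carry \code{id_a, id_b,
#' total_ibd1_cM, total_ibd2_cM, n_segments, max_ibd_cM}. Segments are
#' grouped per unordered pair (the pair key is order-independent) and
#' summaries are recomputed from segments when segment rows are present.
#'
#' @param path path to a tab-separated table.
#' @param map a \code{genetic_map} used for bounds validation
#'   (default [default_genetic_map()]).
#' @return An object of class \code{ibd_pairs}: list with \code{segments}
#'   (data.frame, possibly empty) and \code{summary} (one row per pair).
#' @export
read_ibd_pairs <- function(path, map = default_genetic_map()) {
  df <- read_tsv_base(path)
  if ("chrom" %in% names(df)) {
    require_columns(df, c("id_a", "id_b", "chrom", "start_cM", "end_cM"),
                    "IBD segment table")
    if (!"n_snps" %in% names(df)) df$n_snps <- NA_real_
    if (!"state" %in% names(df)) df$state <- "IBD1"
    if (any(df$start_cM >= df$end_cM)) {
      stop("format error: segment with start_cM >= end_cM")
    }
    lens <- chrom_length(map, df$chrom)
    out_of_bounds <- df$start_cM < 0 | df$end_cM > lens + 1e-9
    if (any(out_of_bounds)) {
      stop("validation error: segment beyond bounds of map chromosome ",
           paste(unique(df$chrom[out_of_bounds]), collapse = ", "))
    }
    cp <- canonical_pair(df$id_a, df$id_b)
    segs <- data.frame(id_a = cp$id_a, id_b = cp$id_b, chrom = df$chrom,
                       start_cM = df$start_cM, end_cM = df$end_cM,
                       length_cM = df$end_cM - df$start_cM,
                       n_snps = df$n_snps, state = df$state,
                       stringsAsFactors = FALSE)
    ibd_pairs_from_segments(segs, map)
  } else {
    require_columns(df, c("id_a", "id_b", "total_ibd1_cM", "total_ibd2_cM",
                          "n_segments", "max_ibd_cM"), "IBD summary table")
    cp <- canonical_pair(df$id_a, df$id_b)
    df$id_a <- cp$id_a
    df$id_b <- cp$id_b
    if (anyDuplicated(cp$key)) {
      agg <- stats::aggregate(
        df[, c("total_ibd1_cM", "total_ibd2_cM", "n_segments")],
        by = list(id_a = df$id_a, id_b = df$id_b), FUN = sum)
      mx <- stats::aggregate(df["max_ibd_cM"],
                             by = list(id_a = df$id_a, id_b = df$id_b),
                             FUN = max)
      df <- merge(agg, mx, by = c("id_a", "id_b"))
    }
    structure(list(segments = empty_segments(), summary = df, map = map),
              class = "ibd_pairs")
  }
}

empty_segments <- function() {
  data.frame(id_a = character(), id_b = character(), chrom = character(),
             start_cM = numeric(), end_cM = numeric(), length_cM = numeric(),
             n_snps = numeric(), state = character(), stringsAsFactors = FALSE)
}

#' Build an \code{ibd_pairs} object from a segment data.frame
#'
#' Summaries (total IBD1/IBD2, segment count, maximum segment length) are
#' recomputed from the segments; the pair key is order-independent.
#'
#' @param segs data.frame with columns id_a, id_b, chrom, start_cM, end_cM,
#'   length_cM, n_snps, state.
#' @param map genetic map.
#' @return \code{ibd_pairs} object.
#' @export
ibd_pairs_from_segments <- function(segs, map = default_genetic_map()) {
  if (nrow(segs) == 0) {
    return(structure(list(segments = empty_segments(),
                          summary = data.frame(id_a = character(),
                                               id_b = character(),
                                               total_ibd1_cM = numeric(),
                                               total_ibd2_cM = numeric(),
                                               n_segments = integer(),
                                               max_ibd_cM = numeric(),
                                               stringsAsFactors = FALSE),
                          map = map), class = "ibd_pairs"))
  }
  cp <- canonical_pair(segs$id_a, segs$id_b)
  segs$id_a <- cp$id_a
  segs$id_b <- cp$id_b
  key <- cp$key
  ibd1 <- tapply(segs$length_cM * (segs$state == "IBD1"), key, sum)
  ibd2 <- tapply(segs$length_cM * (segs$state == "IBD2"), key, sum)
  nseg <- tapply(key, key, length)
  mx <- tapply(segs$length_cM, key, max)
  ids <- do.call(rbind, strsplit(names(nseg), "\r", fixed = TRUE))
  summary <- data.frame(id_a = ids[, 1], id_b = ids[, 2],
                        total_ibd1_cM = as.numeric(ibd1),
                        total_ibd2_cM = as.numeric(ibd2),
                        n_segments = as.integer(nseg),
                        max_ibd_cM = as.numeric(mx),
                        stringsAsFactors = FALSE)
  rownames(summary) <- NULL
  structure(list(segments = segs, summary = summary, map = map),
            class = "ibd_pairs")
}

#' Write pairwise IBD segments to the segment-table dialect
#' @param pairs an \code{ibd_pairs} object with segments.
#' @param path output path.
#' @export
write_ibd_pairs <- function(pairs, path) {
  stopifnot(inherits(pairs, "ibd_pairs"))
  write_tsv_base(pairs$segments, path)
  invisible(path)
}

#' Write a network edge list
#'
#' One row per edge: \code{id_a}, \code{id_b}, \code{weight} (the maximum
#' IBD length in cM) and \code{same_site} flag. A round-trip through
#' [read_network_edges()] reproduces the edge set.
#'
#' @param network a \code{kin_network} from [build_network()].
#' @param path output path.
#' @export
write_network_edges <- function(network, path) {
  stopifnot(inherits(network, "kin_network"))
  e <- network$edges
  site <- stats::setNames(network$nodes$site, network$nodes$id)
  out <- data.frame(id_a = e$id_a, id_b = e$id_b, weight = e$weight,
                    same_site = unname(site[e$id_a] == site[e$id_b]),
                    stringsAsFactors = FALSE)
  write_tsv_base(out, path)
  invisible(path)
}

#' Read a network edge list written by [write_network_edges()]
#' @param path input path.
#' @return data.frame with columns id_a, id_b, weight, same_site.
#' @export
read_network_edges <- function(path) {
  df <- read_tsv_base(path)
  require_columns(df, c("id_a", "id_b", "weight"), "edge list")
  df
}

#' Read a radiocarbon calibration curve
#'
#' IntCal-dialect text: comment lines starting with \code{#}, then comma- or
#' whitespace-separated columns; the first three are calendar age (cal BP),
#' conventional radiocarbon age (BP) and its one-sigma error. Rows are
#' returned sorted ascending by cal BP; linear interpolation between knots
#' is provided by [curve_at()].
#'
#' @param path path to curve file.
#' @return An object of class \code{calibration_curve}: data.frame with
#'   columns \code{cal_BP}, \code{c14_age_BP}, \code{sigma}.
#' @export
read_calibration_curve <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2) stop("format error: calibration curve needs >= 2 rows")
  fields <- strsplit(trimws(lines), "[,\\s]+")
  n_ok <- vapply(fields, length, 1L)
  if (any(n_ok < 3)) stop("format error: calibration curve rows need 3 columns")
  mat <- t(vapply(fields, function(f) as.numeric(f[1:3]), numeric(3)))
  if (anyNA(mat)) stop("format error: non-numeric calibration curve entry")
  df <- data.frame(cal_BP = mat[, 1], c14_age_BP = mat[, 2], sigma = mat[, 3])
  if (anyDuplicated(df$cal_BP)) {
    stop("format error: duplicated cal_BP in calibration curve")
  }
  if (any(df$sigma <= 0)) stop("format error: non-positive curve sigma")
  df <- df[order(df$cal_BP), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("calibration_curve", "data.frame")
  df
}

#' Write a calibration curve in the same dialect
#' @param curve a \code{calibration_curve}.
#' @param path output path.
#' @param comment optional header comment line(s).
#' @export
write_calibration_curve <- function(curve, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(as.data.frame(unclass(curve))[
    , c("cal_BP", "c14_age_BP", "sigma")],
    con, sep = ",", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Interpolate a calibration curve
#' @param curve a \code{calibration_curve}.
#' @param cal_BP calendar ages (cal BP) at which to evaluate.
#' @return list with \code{c14_age_BP} and \code{sigma}, linearly
#'   interpolated between knots.
#' @export
curve_at <- function(curve, cal_BP) {
  rng <- range(curve$cal_BP)
  if (any(cal_BP < rng[1] - 1e-9 | cal_BP > rng[2] + 1e-9)) {
    stop("requested cal_BP outside calibration curve range")
  }
  list(c14_age_BP = stats::approx(curve$cal_BP, curve$c14_age_BP,
                                  xout = cal_BP, rule = 2)$y,
       sigma = stats::approx(curve$cal_BP, curve$sigma,
                             xout = cal_BP, rule = 2)$y)
}

#' Read radiocarbon measurements
#'
#' Columns: \code{individual_id}, \code{c14_age_BP}, \code{sigma}.
#' @param path input path.
#' @return data.frame of dates.
#' @export
read_c14_dates <- function(path) {
  df <- read_tsv_base(path)
  require_columns(df, c("individual_id", "c14_age_BP", "sigma"),
                  "radiocarbon date table")
  if (any(df$sigma <= 0)) stop("validation error: non-positive sigma")
  df
}

#' Write radiocarbon measurements
#' @param dates data.frame with individual_id, c14_age_BP, sigma.
#' @param path output path.
#' @export
write_c14_dates <- function(dates, path) {
  write_tsv_base(dates[, c("individual_id", "c14_age_BP", "sigma")], path)
  invisible(path)
}

#' Write a pedigree in a PLINK-fam-like dialect plus unions sidecar
#'
#' The main file has columns \code{id}, \code{father_id}, \code{mother_id},
#' \code{sex} (missing parents empty); the sidecar lists reproductive
#' unions as \code{male_id}, \code{female_id}.
#'
#' @param pedigree a \code{pedigree_graph}.
#' @param path path for the fam-like file.
#' @param unions_path path for the unions sidecar.
#' @export
write_pedigree <- function(pedigree, path, unions_path) {
  ind <- pedigree$individuals
  write_tsv_base(data.frame(id = ind$id, father_id = ind$father,
                            mother_id = ind$mother, sex = ind$sex,
                            stringsAsFactors = FALSE), path)
  write_tsv_base(pedigree$unions[, c("male_id", "female_id"), drop = FALSE],
                 unions_path)
  invisible(path)
}

#' Read a pedigree written by [write_pedigree()]
#' @param path fam-like file path.
#' @param unions_path unions sidecar path.
#' @return a \code{pedigree_graph} (metadata limited to sex/parents).
#' @export
read_pedigree <- function(path, unions_path = NULL) {
  df <- read_tsv_base(path)
  require_columns(df, c("id", "father_id", "mother_id", "sex"),
                  "pedigree file")
  unions <- if (!is.null(unions_path)) {
    u <- read_tsv_base(unions_path)
    require_columns(u, c("male_id", "female_id"), "unions sidecar")
    u
  } else {
    data.frame(male_id = character(), female_id = character(),
               stringsAsFactors = FALSE)
  }
  ind <- data.frame(id = as.character(df$id),
                    sex = df$sex,
                    father = ifelse(is.na(df$father_id) | df$father_id == "",
                                    NA_character_, as.character(df$father_id)),
                    mother = ifelse(is.na(df$mother_id) | df$mother_id == "",
                                    NA_character_, as.character(df$mother_id)),
                    stringsAsFactors = FALSE)
  new_pedigree_graph(ind, unions)
}

#' Write pairwise relatedness calls in a KIN-style dialect
#'
#' Columns: pair ids, inferred degree, second-degree subtype, kinship
#' coefficient, segment count and maximum IBD length.
#' @param calls data.frame from [classify_pairs()].
#' @param path output path.
#' @export
write_relatedness_calls <- function(calls, path) {
  cols <- c("id_a", "id_b", "degree", "subtype", "kinship",
            "n_segments", "max_ibd_cM")
  write_tsv_base(calls[, intersect(cols, names(calls)), drop = FALSE], path)
  invisible(path)
}
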