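#' Genetic map container
#'
#' A genetic map is an ordered table of chromosomes with sex-averaged
#' lengths in centimorgans (cM). Coordinates throughout the package are
#' real-valued cM, 0-based, half-open \code{[start, end)}.
#'
#' @param chrom character vector of chromosome names.
#' @param length_cM positive numeric vector of chromosome lengths in cM.
#' @return An object of class \code{genetic_map}: a data.frame with columns
#'   \code{chrom} and \code{length_cM} and attribute \code{total_cM}.
#' @export
genetic_map <- function(chrom, length_cM) {
  if (length(chrom) != length(length_cM)) {
    stop("chrom and length_cM must have equal length")
  }
  if (any(!is.finite(length_cM)) || any(length_cM <= 0)) {
    stop("chromosome lengths must be strictly positive")
  }
  if (anyDuplicated(chrom)) stop("duplicate chromosome names")
  m <- data.frame(chrom = as.character(chrom), length_cM = as.numeric(length_cM),
                  stringsAsFactors = FALSE)
  attr(m, "total_cM") <- sum(m$length_cM)
  class(m) <- c("genetic_map", "data.frame")
  m
}

#' Default autosomal genetic map
#'
#' Twenty-two autosomes with published sex-averaged lengths totalling about
#' 3,540 cM. The exact lengths are a configuration knob, not a result: all
#' cM thresholds used downstream presuppose a standard autosomal map of this
#' scale, and any map built with [genetic_map()] can be substituted.
#'
#' @return A \code{genetic_map} with 22 autosomes.
#' @export
default_genetic_map <- function() {
  genetic_map(
    chrom = paste0("chr", 1:22),
    length_cM = c(286.3, 268.6, 223.4, 214.6, 204.1, 192.0, 187.2, 168.0,
                  166.4, 181.1, 158.2, 174.7, 125.9, 120.2, 141.9, 134.0,
                  128.5, 117.5, 107.9, 108.3, 62.8, 74.1)
  )
}

#' Total map length in cM
#' @param map a \code{genetic_map}.
#' @return numeric scalar, sum of chromosome lengths.
#' @export
map_total_cM <- function(map) {
  stopifnot(inherits(map, "genetic_map"))
  sum(map$length_cM)
}

#' Length of one chromosome
#' @param map a \code{genetic_map}.
#' @param chrom chromosome name.
#' @return numeric scalar length in cM.
#' @keywords internal
chrom_length <- function(map, chrom) {
  i <- match(chrom, map$chrom)
  if (anyNA(i)) stop("unknown chromosome: ", paste(chrom[is.na(i)], collapse = ", "))
  map$length_cM[i]
}
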