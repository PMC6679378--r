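#' Simulate a multi-chromosome genetic map
#'
#' Builds a framework marker map with evenly spaced markers along each
#' chromosome and physical (Mb) positions obtained by a fixed Mb-per-cM
#' scaling.  The deterministic cM-to-Mb relation gives an exactly known
#' cis/trans geometry, so distance-window classifications can be checked
#' against simulated truth.
#'
#' @param chr_lengths_cM Numeric vector of chromosome lengths in centiMorgans.
#'   Names, if present, are used as chromosome names; otherwise chromosomes
#'   are named `"1"`, `"2"`, ...
#' @param spacing_cM Marker spacing in cM (markers at 0, spacing, 2*spacing,
#'   ... up to the chromosome length).
#' @param mb_per_cM Physical scaling, megabases per centiMorgan (default 2,
#'   roughly the genome-wide average for the rat).
#'
#' @return A `data.frame` of class `"genmap"` with columns `marker`, `chr`,
#'   `cM`, `Mb`, ordered by chromosome then position.
#' @examples
#' map <- sim_map(c(100, 80), spacing_cM = 10)
#' table(map$chr)
#' @export
sim_map <- function(chr_lengths_cM, spacing_cM, mb_per_cM = 2) {
  if (!is.numeric(chr_lengths_cM) || length(chr_lengths_cM) < 1L ||
      any(!is.finite(chr_lengths_cM)) || any(chr_lengths_cM <= 0)) {
    stopf("chromosome lengths must be positive finite numbers")
  }
  if (!is_number(spacing_cM) || spacing_cM <= 0) {
    stopf("marker spacing must be a positive number")
  }
  if (!is_number(mb_per_cM) || mb_per_cM <= 0) {
    stopf("mb_per_cM must be a positive number")
  }
  chr_names <- names(chr_lengths_cM)
  if (is.null(chr_names)) chr_names <- as.character(seq_along(chr_lengths_cM))
  pieces <- lapply(seq_along(chr_lengths_cM), function(i) {
    pos <- seq(0, chr_lengths_cM[i], by = spacing_cM)
    data.frame(
      marker = sprintf("c%s.m%d", chr_names[i], seq_along(pos)),
      chr = chr_names[i],
      cM = pos,
      Mb = pos * mb_per_cM,
      stringsAsFactors = FALSE
    )
  })
  map <- do.call(rbind, pieces)
  rownames(map) <- NULL
  class(map) <- c("genmap", "data.frame")
  attr(map, "mb_per_cM") <- mb_per_cM
  map
}

validate_map <- function(map) {
  need <- c("marker", "chr", "cM", "Mb")
  if (!is.data.frame(map) || !all(need %in% names(map))) {
    stopf("a genetic map needs columns %s", paste(need, collapse = ", "))
  }
  if (anyDuplicated(map$marker)) stopf("duplicated marker names in map")
  for (ch in unique(map$chr)) {
    cm <- map$cM[map$chr == ch]
    mb <- map$Mb[map$chr == ch]
    if (is.unsorted(cm, strictly = TRUE)) {
      stopf("cM positions not strictly increasing on chromosome %s", ch)
    }
    if (is.unsorted(mb)) {
      stopf("Mb positions not monotone on chromosome %s", ch)
    }
  }
  invisible(map)
}

#' Read / write a genetic map
#'
#' Maps are stored as tab-separated text with columns
#' `marker`, `chr`, `cM`, `Mb`.
#'
#' @param path File path.
#' @return `read_map` returns a `"genmap"` data frame; `write_map` returns
#'   `path` invisibly.
#' @export
read_map <- function(path) {
  map <- read_tsv_file(path, colClasses = c(marker = "character", chr = "character"))
  class(map) <- c("genmap", "data.frame")
  validate_map(map)
  map
}

#' @rdname read_map
#' @param map A `"genmap"` data frame.
#' @export
write_map <- function(map, path) {
  validate_map(map)
  write_tsv_file(as.data.frame(map)[, c("marker", "chr", "cM", "Mb")], path)
}

# chromosome lengths (max cM) in map order
map_chr_lengths <- function(map) {
  chrs <- unique(map$chr)
  stats::setNames(vapply(chrs, function(ch) max(map$cM[map$chr == ch]), 0), chrs)
}
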