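#' Meiotic recombination fraction under the Haldane map function
#'
#' Converts a map distance in centimorgan to the per-meiosis recombination
#' fraction assuming no crossover interference, `r = (1 - exp(-2d/100)) / 2`.
#'
#' @param d Map distance in centimorgan (vectorised, `d >= 0`).
#' @return Recombination fraction in `[0, 0.5)`.
#' @seealso [ril_recombination_fraction()] for the selfed-RIL expansion.
#' @export
haldane_r <- function(d) {
  if (any(is.na(d)) || any(d < 0)) stop("map distance must be non-negative")
  0.5 * (1 - exp(-2 * d / 100))
}

#' Recombination fraction between selfed-RIL genotypes
#'
#' For recombinant inbred lines taken to homozygosity by repeated selfing,
#' the observed recombination fraction between the two homozygous genotype
#' classes expands the meiotic fraction `r` to `R = 2r / (1 + 2r)`
#' (Haldane-Waddington). With the Haldane map function for `r` this gives a
#' closed form in the map distance, monotone in `d` and bounded above by the
#' unlinked-locus value `R(r = 1/2) = 1/2`.
#'
#' @param d Map distance in centimorgan (vectorised, `d >= 0`).
#' @return RIL-class recombination fraction in `[0, 1/2)`.
#' @examples
#' ril_recombination_fraction(c(0, 10, 1e6))
#' @export
ril_recombination_fraction <- function(d) {
  r <- haldane_r(d)
  2 * r / (1 + 2 * r)
}

#' Construct a genetic map
#'
#' A genetic map is a data frame of markers with a chromosome label and a
#' position in centimorgan, sorted by chromosome (in order of first
#' appearance) and position. Marker ids must be unique and positions
#' non-negative; input given out of order is sorted with a notice.
#'
#' @param marker Character vector of unique marker ids.
#' @param chromosome Chromosome labels, one per marker.
#' @param position Positions in centimorgan, `>= 0`.
#' @return A `genetic_map`: data frame with columns `marker`, `chromosome`,
#'   `position`.
#' @export
genetic_map <- function(marker, chromosome, position) {
  marker <- as.character(marker)
  chromosome <- as.character(chromosome)
  position <- as.numeric(position)
  if (length(marker) != length(chromosome) || length(marker) != length(position))
    stop("marker, chromosome and position must have equal length")
  if (anyNA(position)) stop("non-numeric or missing marker position")
  if (any(position < 0)) stop("negative marker position")
  dup <- marker[duplicated(marker)]
  if (length(dup))
    stop("duplicate marker id(s): ", paste(unique(dup), collapse = ", "))
  chr_levels <- unique(chromosome)
  ord <- order(match(chromosome, chr_levels), position)
  if (is.unsorted(ord)) {
    message("genetic map input was not sorted by (chromosome, position); sorting")
    marker <- marker[ord]; chromosome <- chromosome[ord]; position <- position[ord]
  }
  map <- data.frame(marker = marker, chromosome = chromosome,
                    position = position, stringsAsFactors = FALSE)
  class(map) <- c("genetic_map", "data.frame")
  map
}

#' Read a genetic map from a delimited text file
#'
#' Expects tab-delimited text with a header and columns `marker`,
#' `chromosome` and `position_cM` (or `position`).
#'
#' @param path Path to the map file.
#' @return A [genetic_map()].
#' @export
read_genetic_map <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  pos_col <- intersect(c("position_cM", "position"), names(x))
  if (!all(c("marker", "chromosome") %in% names(x)) || !length(pos_col))
    stop("map file must have columns marker, chromosome, position_cM")
  genetic_map(x$marker, x$chromosome, x[[pos_col[1]]])
}

#' Write a genetic map to a delimited text file
#'
#' @param map A [genetic_map()].
#' @param path Output path (tab-delimited, columns marker, chromosome,
#'   position_cM).
#' @return `path`, invisibly.
#' @export
write_genetic_map <- function(map, path) {
  out <- data.frame(marker = map$marker, chromosome = map$chromosome,
                    position_cM = map$position)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build the genome-scan evaluation grid
#'
#' The grid contains every marker position plus interpolated points inserted
#' from the left of each inter-marker interval at multiples of `step`, so
#' that consecutive grid positions within a chromosome never differ by more
#' than `step`.
#'
#' @param map A [genetic_map()].
#' @param step Maximum spacing between consecutive grid positions, in
#'   centimorgan (`> 0`).
#' @return A `scan_grid`: data frame with columns `chromosome`, `position`
#'   and `marker` (the marker id at marker positions, `NA` at interpolated
#'   points).
#' @examples
#' m <- genetic_map(c("a", "b"), c("1", "1"), c(0, 5))
#' build_scan_grid(m, step = 2)$position  # 0 2 4 5
#' @export
build_scan_grid <- function(map, step = 2) {
  if (!is.numeric(step) || length(step) != 1 || is.na(step) || step <= 0)
    stop("step must be a single positive number")
  pieces <- lapply(unique(map$chromosome), function(ch) {
    sub <- map[map$chromosome == ch, , drop = FALSE]
    pos <- unique(sub$position)
    grid_pos <- pos
    for (j in seq_len(length(pos) - 1L)) {
      gap <- pos[j + 1L] - pos[j]
      if (gap > step) {
        fill <- seq(pos[j] + step, pos[j + 1L], by = step)
        fill <- fill[fill < pos[j + 1L] - 1e-9]
        grid_pos <- c(grid_pos, fill)
      }
    }
    grid_pos <- sort(unique(grid_pos))
    mk <- sub$marker[match(grid_pos, sub$position)]
    data.frame(chromosome = ch, position = grid_pos, marker = mk,
               stringsAsFactors = FALSE)
  })
  grid <- do.call(rbind, pieces)
  rownames(grid) <- NULL
  attr(grid, "step") <- step
  class(grid) <- c("scan_grid", "data.frame")
  grid
}
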