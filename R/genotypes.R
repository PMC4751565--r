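#' Construct a RIL genotype matrix
#'
#' Genotypes of a biparental recombinant inbred population are coded 0 for
#' the A-parent homozygote, 1 for the B-parent homozygote and `NA` for
#' missing. With this 0/1 coding an estimated QTL effect is the full
#' difference between the two homozygous classes. Columns are reordered to
#' match the map; a line with no informative marker on some chromosome is
#' allowed (conditional probabilities fall back to 0.5 there) but triggers a
#' warning.
#'
#' @param codes Numeric matrix (lines x markers) with values in `{0, 1, NA}`;
#'   rownames are line ids, colnames marker ids.
#' @param map A [genetic_map()] whose markers match `colnames(codes)`.
#' @return A `geno_matrix` (matrix with class attribute).
#' @export
genotype_matrix <- function(codes, map) {
  if (is.null(rownames(codes)) || is.null(colnames(codes)))
    stop("codes must have line ids as rownames and marker ids as colnames")
  unknown <- setdiff(colnames(codes), map$marker)
  if (length(unknown))
    stop("unknown marker column(s): ", paste(unknown, collapse = ", "))
  absent <- setdiff(map$marker, colnames(codes))
  if (length(absent))
    stop("marker(s) on map absent from genotypes: ",
         paste(utils::head(absent, 5), collapse = ", "))
  codes <- codes[, map$marker, drop = FALSE]
  bad <- !(codes %in% c(0, 1) | is.na(codes))
  if (any(bad)) stop("genotype codes must be 0, 1 or NA")
  storage.mode(codes) <- "integer"
  for (ch in unique(map$chromosome)) {
    mi <- map$marker[map$chromosome == ch]
    empty <- rowSums(!is.na(codes[, mi, drop = FALSE])) == 0
    if (any(empty))
      warning(sum(empty), " line(s) have no informative marker on chromosome ",
              ch, "; conditional probabilities there default to 0.5")
  }
  structure(codes, class = c("geno_matrix", class(codes)))
}

#' Read RIL genotypes from a delimited text file
#'
#' Tab-delimited with a header: first column the line id, remaining columns
#' one per marker with symbols `A` (A-parent class), `B` (B-parent class)
#' and `-` for missing. Residual heterozygous calls coded `H` are treated as
#' missing with a logged count (the two-class RIL model ignores residual
#' heterozygosity). Marker columns may appear in any order; they are
#' validated against and reordered to the map.
#'
#' @param path Path to the genotype file.
#' @param map A [genetic_map()].
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, map) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  line_id <- x[[1]]
  sym <- as.matrix(x[, -1, drop = FALSE])
  rownames(sym) <- line_id
  n_het <- sum(sym == "H", na.rm = TRUE)
  if (n_het > 0)
    message(n_het, " heterozygous call(s) treated as missing")
  known <- sym %in% c("A", "B", "-", "H", "", NA)
  if (!all(known)) {
    offending <- unique(sym[!known])
    stop("genotype symbol(s) outside {A, B, -}: ",
         paste(offending, collapse = ", "))
  }
  codes <- matrix(NA_integer_, nrow(sym), ncol(sym), dimnames = dimnames(sym))
  codes[sym == "A"] <- 0L
  codes[sym == "B"] <- 1L
  geno <- genotype_matrix(codes, map)
  miss <- rowMeans(is.na(geno))
  message(sprintf("read %d lines x %d markers; mean per-line missing fraction %.3f",
                  nrow(geno), ncol(geno), mean(miss)))
  geno
}

#' Write RIL genotypes to a delimited text file
#'
#' @param geno A [genotype_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(geno, path) {
  sym <- matrix("-", nrow(geno), ncol(geno), dimnames = dimnames(geno))
  sym[which(geno == 0L)] <- "A"
  sym[which(geno == 1L)] <- "B"
  out <- data.frame(line = rownames(geno), sym, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Conditional P(B) given one informative flank at distance d (0 = A, 1 = B).
.one_side_prob <- function(g, d) {
  R <- ril_recombination_fraction(d)
  ifelse(g == 1L, 1 - R, R)
}

# Conditional P(B) given flanks gL at distance dL and gR at distance dR,
# from the two-state Markov chain with RIL-class transition probabilities.
.two_side_prob <- function(gL, dL, gR, dR) {
  RL <- ril_recombination_fraction(dL)
  RR <- ril_recombination_fraction(dR)
  pLB <- ifelse(gL == 1L, 1 - RL, RL)   # P(gL -> B)
  pLA <- 1 - pLB                        # P(gL -> A)
  pBR <- ifelse(gR == 1L, 1 - RR, RR)   # P(B -> gR)
  pAR <- ifelse(gR == 1L, RR, 1 - RR)   # P(A -> gR)
  num <- pLB * pBR
  den <- num + pLA * pAR
  out <- num / den
  out[den == 0] <- 0.5   # contradictory co-located flanks
  out
}

#' Conditional QTL genotype probabilities on a scan grid
#'
#' For every line and grid position, computes `x = P(genotype B | nearest
#' non-missing flanking markers)` from the two-state Markov chain along the
#' chromosome whose transition probability between loci `d` cM apart is the
#' RIL-class recombination fraction [ril_recombination_fraction()]. A
#' position observed at a non-missing marker reproduces the observed code
#' exactly (A gives 0, B gives 1); a flank missing on one side conditions on
#' the single informative side; a line with no informative marker on the
#' chromosome scores 0.5 everywhere on it.
#'
#' @param geno A [genotype_matrix()].
#' @param map The [genetic_map()] the genotypes are indexed by.
#' @param grid A [build_scan_grid()] result (or any data frame with columns
#'   `chromosome` and `position`).
#' @return Matrix (lines x grid positions) of probabilities in `[0, 1]`,
#'   with the grid attached as attribute `"grid"`.
#' @export
qtl_genotype_probs <- function(geno, map, grid) {
  n <- nrow(geno)
  out <- matrix(0.5, n, nrow(grid),
                dimnames = list(rownames(geno), NULL))
  for (ch in unique(grid$chromosome)) {
    gi <- which(grid$chromosome == ch)
    mi <- which(map$chromosome == ch)
    if (!length(mi)) next
    pm <- map$position[mi]
    pg <- grid$position[gi]
    X <- geno[, mi, drop = FALSE]
    complete <- rowSums(is.na(X)) == 0L
    inside <- pg >= pm[1L] & pg <= pm[length(pm)]
    # fast path: lines fully informative, query within the marker span
    if (any(complete) && length(mi) >= 2L && any(inside)) {
      pgi <- pg[inside]
      li <- findInterval(pgi, pm)
      li[li >= length(pm)] <- length(pm) - 1L
      dL <- pgi - pm[li]
      dR <- pm[li + 1L] - pgi
      gL <- X[complete, li, drop = FALSE]
      gR <- X[complete, li + 1L, drop = FALSE]
      nr <- sum(complete)
      out[complete, gi[inside]] <- .two_side_prob(
        gL, matrix(dL, nr, length(pgi), byrow = TRUE),
        gR, matrix(dR, nr, length(pgi), byrow = TRUE))
    }
    # general path: per-line nearest informative flanks
    general <- if (length(mi) >= 2L && all(inside)) which(!complete) else seq_len(n)
    for (i in general) {
      idx <- which(!is.na(X[i, ]))
      if (!length(idx)) next                   # stays 0.5
      pos_i <- pm[idx]
      g_i <- X[i, idx]
      li <- findInterval(pg, pos_i)
      has_left <- li >= 1L
      has_right <- li < length(idx)
      p <- rep(0.5, length(pg))
      both <- has_left & has_right
      if (any(both))
        p[both] <- .two_side_prob(g_i[li[both]], pg[both] - pos_i[li[both]],
                                  g_i[li[both] + 1L],
                                  pos_i[li[both] + 1L] - pg[both])
      left_only <- has_left & !has_right
      if (any(left_only))
        p[left_only] <- .one_side_prob(g_i[li[left_only]],
                                       pg[left_only] - pos_i[li[left_only]])
      right_only <- !has_left & has_right
      if (any(right_only))
        p[right_only] <- .one_side_prob(g_i[li[right_only] + 1L],
                                        pos_i[li[right_only] + 1L] - pg[right_only])
      out[i, gi] <- p
    }
  }
  attr(out, "grid") <- grid
  out
}
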