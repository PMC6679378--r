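#' Haldane map function
#'
#' Converts genetic distance (cM) to recombination fraction under no
#' crossover interference: `r = (1 - exp(-2 d / 100)) / 2`.
#'
#' @param d_cM Genetic distance(s) in centiMorgans, >= 0.
#' @return Recombination fraction(s) in `[0, 0.5)`.
#' @examples
#' haldane_r(c(0, 2.5, 10))
#' @export
haldane_r <- function(d_cM) {
  if (any(!is.finite(d_cM)) || any(d_cM < 0)) {
    stopf("genetic distances must be non-negative")
  }
  (1 - exp(-2 * d_cM / 100)) / 2
}

#' F2 genotype transition matrix
#'
#' Transition probabilities between the three F2 genotypes (AA, AB, BB) at
#' two loci separated by recombination fraction `r`, from two independent
#' meioses per individual.
#'
#' @param r Recombination fraction in `[0, 0.5]`.
#' @return 3x3 stochastic matrix, rows = genotype at the first locus.
#' @export
f2_transition_matrix <- function(r) {
  if (!is_number(r) || r < 0 || r > 0.5) {
    stopf("recombination fraction must lie in [0, 0.5]")
  }
  s <- 1 - r
  matrix(c(s^2,     2 * r * s,     r^2,
           r * s,   s^2 + r^2,     r * s,
           r^2,     2 * r * s,     s^2),
         3, 3, byrow = TRUE,
         dimnames = list(c("AA", "AB", "BB"), c("AA", "AB", "BB")))
}

#' Insert pseudomarkers into a genetic map
#'
#' Builds the evaluation grid for genome scans: the union of the typed
#' markers and pseudomarkers inserted so that no two adjacent grid loci are
#' more than `step_cM` apart.  Pseudomarker Mb positions are linearly
#' interpolated between the flanking markers.
#'
#' @param map A `"genmap"`.
#' @param step_cM Maximum grid spacing in cM.
#' @return Data frame with columns `locus`, `chr`, `cM`, `Mb`, `marker`
#'   (NA at pseudomarkers) and `marker_index` (column of the genotype
#'   matrix, NA at pseudomarkers).
#' @export
insert_pseudomarkers <- function(map, step_cM) {
  validate_map(map)
  if (!is_number(step_cM) || step_cM <= 0) stopf("step_cM must be positive")
  pieces <- lapply(unique(map$chr), function(ch) {
    idx <- which(map$chr == ch)
    cm <- map$cM[idx]; mb <- map$Mb[idx]
    grid_cm <- cm[1]
    if (length(cm) > 1L) {
      for (k in seq_len(length(cm) - 1L)) {
        gap <- cm[k + 1L] - cm[k]
        n_ins <- max(0L, ceiling(gap / step_cM) - 1L)
        if (n_ins > 0L) {
          grid_cm <- c(grid_cm, cm[k] + gap * seq_len(n_ins) / (n_ins + 1L))
        }
        grid_cm <- c(grid_cm, cm[k + 1L])
      }
    }
    grid_mb <- stats::approx(cm, mb, xout = grid_cm, rule = 2)$y
    mk <- match(round(grid_cm, 9), round(cm, 9))
    data.frame(
      locus = ifelse(is.na(mk),
                     sprintf("c%s.loc%g", ch, grid_cm),
                     map$marker[idx][mk]),
      chr = ch, cM = grid_cm, Mb = grid_mb,
      marker = ifelse(is.na(mk), NA_character_, map$marker[idx][mk]),
      marker_index = ifelse(is.na(mk), NA_integer_, idx[mk]),
      stringsAsFactors = FALSE
    )
  })
  grid <- do.call(rbind, pieces)
  rownames(grid) <- NULL
  grid
}

#' Conditional genotype probabilities on a pseudomarker grid
#'
#' Forward-backward computation on the three-state Markov chain of F2
#' genotypes along each chromosome, for every individual.  Transition
#' probabilities come from the Haldane map function; the emission model
#' allows a global genotyping error rate (`P(observed | true) = 1 -
#' error_rate` on a match, `error_rate / 2` otherwise); missing
#' observations emit uniformly.  The chain's stationary prior is the F2
#' segregation prior (1/4, 1/2, 1/4).
#'
#' @param cross An `"f2cross"`.
#' @param step_cM Grid spacing for [insert_pseudomarkers()] (default 2.5).
#' @param error_rate Genotyping error rate in `[0, 0.5)` (default 0.002).
#' @return Object of class `"genoprobs"`: list with `probs` (array
#'   individuals x grid loci x 3 genotypes) and `grid` (the pseudomarker
#'   grid data frame).
#' @examples
#' map <- sim_map(100, 10)
#' cr <- sim_f2_cross(map, sim_architecture(20, seed = 1))
#' gp <- calc_genoprob(cr, step_cM = 5)
#' apply(gp$probs, 1:2, sum)[1:3, 1:3]  # all 1
#' @export
calc_genoprob <- function(cross, step_cM = 2.5, error_rate = 0.002) {
  map <- cross$map
  if (!is_number(error_rate) || error_rate < 0 || error_rate >= 0.5) {
    stopf("error_rate must lie in [0, 0.5)")
  }
  grid <- insert_pseudomarkers(map, step_cM)
  n <- nrow(cross$geno)
  L <- nrow(grid)
  probs <- array(NA_real_, c(n, L, 3),
                 dimnames = list(cross$id, grid$locus, c("AA", "AB", "BB")))
  for (ch in unique(grid$chr)) {
    gidx <- which(grid$chr == ch)
    probs[, gidx, ] <- fb_chromosome(cross$geno, grid[gidx, , drop = FALSE],
                                     error_rate)
  }
  structure(list(probs = probs, grid = grid, step_cM = step_cM,
                 error_rate = error_rate),
            class = "genoprobs")
}

# emission matrix (n x 3) at one grid locus
emission_at <- function(geno, marker_index, error_rate) {
  n <- nrow(geno)
  E <- matrix(1, n, 3)
  if (!is.na(marker_index)) {
    obs <- geno[, marker_index]
    typed <- !is.na(obs)
    if (any(typed)) {
      Em <- matrix(error_rate / 2, sum(typed), 3)
      Em[cbind(seq_len(sum(typed)), obs[typed])] <- 1 - error_rate
      E[typed, ] <- Em
    }
  }
  E
}

# vectorized forward-backward over individuals for one chromosome
fb_chromosome <- function(geno, grid, error_rate) {
  n <- nrow(geno)
  L <- nrow(grid)
  prior <- c(0.25, 0.5, 0.25)
  Tlist <- lapply(haldane_r(diff(grid$cM)), f2_transition_matrix)
  E <- lapply(seq_len(L), function(k) emission_at(geno, grid$marker_index[k],
                                                  error_rate))
  rescale <- function(m) {
    s <- rowSums(m)
    bad <- s <= 0 | !is.finite(s)
    if (any(bad)) { m[bad, ] <- 1; s[bad] <- 3 }  # impossible data -> uniform
    m / s
  }
  f <- vector("list", L)
  f[[1]] <- rescale(sweep(E[[1]], 2, prior, `*`))
  if (L > 1L) for (k in seq_len(L - 1L)) {
    f[[k + 1L]] <- rescale((f[[k]] %*% Tlist[[k]]) * E[[k + 1L]])
  }
  b <- vector("list", L)
  b[[L]] <- matrix(1, n, 3)
  if (L > 1L) for (k in rev(seq_len(L - 1L))) {
    b[[k]] <- rescale((b[[k + 1L]] * E[[k + 1L]]) %*% t(Tlist[[k]]))
  }
  out <- array(NA_real_, c(n, L, 3))
  for (k in seq_len(L)) out[, k, ] <- rescale(f[[k]] * b[[k]])
  out
}

#' @export
print.genoprobs <- function(x, ...) {
  cat(sprintf("genotype probabilities: %d individuals x %d grid loci (step %g cM, error rate %g)\n",
              dim(x$probs)[1], dim(x$probs)[2], x$step_cM, x$error_rate))
  invisible(x)
}

#' Write genotype probabilities as a long table
#'
#' One row per individual x grid locus with columns `id`, `locus`, `chr`,
#' `cM`, `Mb`, `P_AA`, `P_AB`, `P_BB` (tab-separated).
#'
#' @param gp A `"genoprobs"` object.
#' @param path File path.
#' @export
write_genoprob <- function(gp, path) {
  n <- dim(gp$probs)[1]; L <- dim(gp$probs)[2]
  df <- data.frame(
    id = rep(dimnames(gp$probs)[[1]], times = L),
    locus = rep(gp$grid$locus, each = n),
    chr = rep(gp$grid$chr, each = n),
    cM = rep(gp$grid$cM, each = n),
    Mb = rep(gp$grid$Mb, each = n),
    P_AA = as.vector(gp$probs[, , 1]),
    P_AB = as.vector(gp$probs[, , 2]),
    P_BB = as.vector(gp$probs[, , 3]),
    stringsAsFactors = FALSE
  )
  write_tsv_file(df, path)
}
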