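#' Gray-level run-length matrix along one direction
#'
#' A run is a maximal set of consecutive in-ROI voxels with the same
#' discretized level along the direction; runs break at the ROI boundary.
#' Every ROI voxel belongs to exactly one run, so the matrix satisfies
#' sum_ij r(i,j) * j = n_voxels.
#'
#' Runs are found without walking voxels one by one: voxels are keyed by
#' (line id, step along the line) for the direction, sorted, and run
#' breaks located by vectorized comparison.
#'
#' @param d a [discretize()]d ROI.
#' @param direction integer length-3 offset with entries in -1, 0, 1 (not
#'   all zero).
#' @return An object of class `glrlm`: `matrix` (n_bins x max run length,
#'   integer counts), `n_runs`, `n_voxels`, `direction`.
#' @export
glrlm_compute <- function(d, direction) {
  stopifnot(inherits(d, "discretized_roi"))
  o <- as.integer(direction)
  if (length(o) != 3L || all(o == 0L) || any(abs(o) > 1L))
    stop("glrlm_compute: direction must be a nonzero offset in {-1,0,1}^3")
  lev <- d$levels
  dm <- dim(lev)
  if (!any(!is.na(lev))) stop("glrlm_compute: empty ROI")
  co <- arrayInd(seq_along(lev), dm)
  # step index along the line: every nonzero axis advances once per step
  nz <- which(o != 0L)
  step <- if (o[nz[1]] == 1L) co[, nz[1]] - 1L else dm[nz[1]] - co[, nz[1]]
  # line id: the start coordinate of the line this voxel lies on
  B <- max(dm) + max(dm) + 2L
  id <- 0
  for (k in 1:3) id <- id * B + (co[, k] - step * o[k] + max(dm))
  ord <- order(id, step)
  v <- lev[ord]
  new_line <- c(TRUE, diff(id[ord]) != 0)
  keep <- !is.na(v)
  prev_keep <- c(FALSE, keep[-length(keep)])
  prev_v <- c(NA_integer_, v[-length(v)])
  starts <- keep & (new_line | !prev_keep |
                      (!is.na(prev_v) & prev_v != v))
  starts[is.na(starts)] <- FALSE
  run_id <- cumsum(starts)
  run_id[!keep] <- NA
  lens <- tabulate(run_id[keep])
  levs <- v[starts]
  n_runs <- length(lens)
  max_len <- max(lens)
  nb <- d$n_bins
  r <- matrix(tabulate(levs + (lens - 1L) * nb, nbins = nb * max_len),
              nb, max_len)
  structure(list(matrix = r, n_runs = n_runs, n_voxels = sum(keep),
                 direction = o),
            class = "glrlm")
}

#' Run percentage
#'
#' RP = n_runs / n_voxels, in (0, 1]. Low for smooth (homogeneous)
#' images, 1 when every voxel is its own run (maximally rough).
#'
#' @param g a [glrlm_compute()] result.
#' @export
feature_rp <- function(g) {
  stopifnot(inherits(g, "glrlm"))
  g$n_runs / g$n_voxels
}

#' Gray-level nonuniformity of a run-length matrix
#'
#' GLN = sum_i (sum_j r(i,j))^2 / n_runs; small when runs are spread
#' evenly across gray levels, equal to n_runs when a single level holds
#' all runs.
#'
#' @param g a [glrlm_compute()] result.
#' @export
feature_gln_rl <- function(g) {
  stopifnot(inherits(g, "glrlm"))
  if (g$n_runs == 0) stop("feature_gln_rl: no runs")
  sum(rowSums(g$matrix)^2) / g$n_runs
}

#' Run-length features for one direction
#'
#' The 16 run-length features of the bank.
#'
#' @param g a [glrlm_compute()] result.
#' @return named numeric vector (names e.g. `GLRLM_RP`).
#' @export
glrlm_features <- function(g) {
  stopifnot(inherits(g, "glrlm"))
  r <- g$matrix
  nr <- g$n_runs
  np <- g$n_voxels
  nb <- nrow(r); ml <- ncol(r)
  i <- matrix(seq_len(nb), nb, ml)
  j <- matrix(seq_len(ml), nb, ml, byrow = TRUE)
  ri <- rowSums(r)  # runs per gray level
  rj <- colSums(r)  # runs per length
  p <- r / nr
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  c(GLRLM_SRE    = sum(r / j^2) / nr,
    GLRLM_LRE    = sum(r * j^2) / nr,
    GLRLM_GLN    = sum(ri^2) / nr,
    GLRLM_GLNN   = sum(ri^2) / nr^2,
    GLRLM_RLN    = sum(rj^2) / nr,
    GLRLM_RLNN   = sum(rj^2) / nr^2,
    GLRLM_RP     = nr / np,
    GLRLM_GLV    = sum(p * (i - mu_i)^2),
    GLRLM_RLV    = sum(p * (j - mu_j)^2),
    GLRLM_RE     = -sum(xlog2(p)),
    GLRLM_LGLRE  = sum(r / i^2) / nr,
    GLRLM_HGLRE  = sum(r * i^2) / nr,
    GLRLM_SRLGLE = sum(r / (i^2 * j^2)) / nr,
    GLRLM_SRHGLE = sum(r * i^2 / j^2) / nr,
    GLRLM_LRLGLE = sum(r * j^2 / i^2) / nr,
    GLRLM_LRHGLE = sum(r * i^2 * j^2) / nr)
}

# run-length features averaged over a direction set
glrlm_features_mean <- function(d, directions) {
  fs <- lapply(directions, function(o) glrlm_features(glrlm_compute(d, o)))
  Reduce(`+`, fs) / length(fs)
}
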