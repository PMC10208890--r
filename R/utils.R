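#' Evaluate an expression with a temporary RNG seed
#'
#' Runs \code{expr} under \code{set.seed(seed)} and restores the caller's RNG
#' state afterwards, so seeded generators are pure functions of their inputs.
#'
#' @param seed integer scalar seed.
#' @param expr expression to evaluate.
#' @return The value of \code{expr}.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Pairwise Euclidean distance matrix between two point sets
#'
#' @param a,b numeric matrices with 3 columns (rows are points).
#' @return \code{nrow(a) x nrow(b)} matrix of distances in the input units.
#' @keywords internal
dist_mat <- function(a, b) {
  d2 <- outer(rowSums(a * a), rowSums(b * b), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

#' Trimmed mean and standard deviation
#'
#' Sorts the values, drops \code{floor(trim * n)} from each tail, and returns
#' mean and SD of the surviving values. Used for the significance thresholds
#' applied to chemical-shift and relaxation difference profiles.
#'
#' @param x numeric vector (NAs removed).
#' @param trim fraction trimmed from each tail (default 0.10).
#' @param sd_on compute sigma on the \code{"trimmed"} set (default) or the
#'   \code{"full"} set.
#' @return list with \code{mean}, \code{sd}, \code{n_used}.
#' @export
trimmed_stats <- function(x, trim = 0.10, sd_on = c("trimmed", "full")) {
  sd_on <- match.arg(sd_on)
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 1L) stop("no finite values")
  k <- floor(trim * n)
  xs <- sort(x)
  kept <- if (k > 0L) xs[(k + 1L):(n - k)] else xs
  s <- if (sd_on == "trimmed") stats::sd(kept) else stats::sd(x)
  if (length(kept) < 2L) s <- 0
  list(mean = mean(kept), sd = if (is.na(s)) 0 else s, n_used = length(kept))
}

# residue keys "chain:resid", used wherever per-residue tables are joined
residue_key <- function(chain, resid) paste(chain, resid, sep = ":")

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name))
  invisible(x)
}
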