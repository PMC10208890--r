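#' Construct an assigned 1H/15N peak list
#'
#' @param resid integer residue numbers (unique).
#' @param dH,dN amide 1H and 15N chemical shifts (ppm).
#' @param height peak heights (> 0, arbitrary units).
#' @param label spectrum label.
#' @return object of class \code{peak_list} (a data.frame).
#' @export
peak_list <- function(resid, dH, dN, height, label = "") {
  if (anyDuplicated(resid)) stop("duplicate residue assignment(s): ",
                                 paste(unique(resid[duplicated(resid)]), collapse = ", "))
  if (any(!is.finite(dH)) || any(!is.finite(dN))) stop("non-finite chemical shift")
  if (any(height <= 0)) stop("peak heights must be > 0")
  out <- data.frame(resid = as.integer(resid), dH = dH, dN = dN,
                    height = height)
  attr(out, "label") <- label
  class(out) <- c("peak_list", "data.frame")
  out
}

#' Parse an assigned peak list file
#'
#' Two dialects are read: a Sparky-style assignment table with lines like
#' \code{A45N-H 118.32 8.05 1.2e6} (assignment, 15N shift, 1H shift,
#' height), and a plain TSV with header columns \code{resid dN dH height}.
#' Lines whose assignment cannot be parsed (e.g. \code{?-?}) are skipped
#' with a warning; duplicate residue assignments are an error.
#'
#' @param path file path.
#' @param format \code{"auto"}, \code{"sparky"}, or \code{"tsv"}.
#' @return a \code{peak_list}.
#' @export
parse_peak_list <- function(path, format = c("auto", "sparky", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (format == "auto")
    format <- if (grepl("\\bresid\\b", first)) "tsv" else "sparky"
  if (format == "tsv") {
    tb <- utils::read.table(path, header = TRUE)
    return(peak_list(tb$resid, tb$dH, tb$dN, tb$height, label = basename(path)))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^\\s*(#|Assignment)", lines)]
  rec <- list()
  skipped <- 0L
  for (ln in lines) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(f) < 4L) { skipped <- skipped + 1L; next }
    m <- regmatches(f[1], regexec("^[A-Za-z]([0-9]+)N-?H", f[1]))[[1]]
    if (length(m) < 2L) { skipped <- skipped + 1L; next }
    rec[[length(rec) + 1L]] <- data.frame(resid = as.integer(m[2]),
                                          dN = as.numeric(f[2]),
                                          dH = as.numeric(f[3]),
                                          height = as.numeric(f[4]))
  }
  if (skipped > 0L)
    warning(skipped, " unparsable assignment line(s) skipped")
  if (!length(rec)) stop("no parsable peaks in ", path)
  tb <- do.call(rbind, rec)
  peak_list(tb$resid, tb$dH, tb$dN, tb$height, label = basename(path))
}

#' Write a peak list in the plain TSV dialect
#' @param peaks a \code{peak_list}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_peak_list <- function(peaks, path) {
  utils::write.table(peaks[, c("resid", "dN", "dH", "height")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Composite 1H/15N chemical-shift perturbation
#'
#' The standard amide composite shift
#' \code{delta = sqrt((dH^2 + (dN/5)^2) / 2)} between matched wild-type and
#' variant peaks, i.e. the 15N difference is down-weighted by its ~5-fold
#' larger shift dispersion before averaging in quadrature. Residues present
#' in the wild type but missing from the variant are recorded separately
#' (candidates for broadening beyond detection). Symmetric in its two
#' arguments.
#'
#' @param wt,variant \code{peak_list}s sharing at least one residue.
#' @return object of class \code{csp_result}: data.frame of \code{resid}
#'   and \code{delta} (ppm) with attribute \code{missing_in_variant}.
#' @export
composite_csp <- function(wt, variant) {
  common <- intersect(wt$resid, variant$resid)
  if (!length(common)) stop("no residues shared between peak lists")
  iw <- match(common, wt$resid)
  iv <- match(common, variant$resid)
  ddH <- variant$dH[iv] - wt$dH[iw]
  ddN <- variant$dN[iv] - wt$dN[iw]
  delta <- sqrt((ddH^2 + (ddN / 5)^2) / 2)
  out <- data.frame(resid = common, delta = delta)
  attr(out, "missing_in_variant") <- setdiff(wt$resid, variant$resid)
  class(out) <- c("csp_result", "data.frame")
  out
}

#' Significance threshold for chemical-shift perturbations
#'
#' Sorts the per-residue composite shifts, drops \code{floor(trim * n)}
#' values from each tail, and returns \code{mean + k * sd} of the trimmed
#' set (sigma on the trimmed set by default; the robust threshold used for
#' calling significant perturbations).
#'
#' @param deltas numeric vector of composite shifts (ppm), length >= 5.
#' @param trim tail fraction (default 0.10).
#' @param k sigma multiplier (default 1.5).
#' @param sd_on \code{"trimmed"} (default) or \code{"full"}.
#' @return threshold in ppm.
#' @export
csp_threshold <- function(deltas, trim = 0.10, k = 1.5,
                          sd_on = c("trimmed", "full")) {
  deltas <- deltas[is.finite(deltas)]
  if (length(deltas) < 5L) stop("need at least 5 values")
  ts <- trimmed_stats(deltas, trim = trim, sd_on = match.arg(sd_on))
  ts$mean + k * ts$sd
}

#' Classify line-broadened residues
#'
#' Variant heights are first rescaled by the median per-residue
#' height ratio over common residues (robust to receiver-gain or
#' concentration differences and to a perturbed minority), then a residue
#' is called broadened when its rescaled intensity ratio drops to
#' \code{cutoff} or below (default: loss of at least 50 percent of the
#' wild-type intensity). Residues assigned in the wild type but absent
#' from the variant are broadened beyond detection and always flagged.
#'
#' @param wt,variant \code{peak_list}s with >= 5 common residues.
#' @param cutoff intensity-ratio cutoff (default 0.5).
#' @return list with \code{broadened} (integer residues, including those
#'   missing from the variant), \code{ratios} (named rescaled ratios),
#'   \code{scale} (median normalization factor).
#' @export
classify_broadened <- function(wt, variant, cutoff = 0.5) {
  common <- intersect(wt$resid, variant$resid)
  if (length(common) < 5L) stop("need at least 5 common residues")
  iw <- match(common, wt$resid)
  iv <- match(common, variant$resid)
  hw <- wt$height[iw]
  hv <- variant$height[iv]
  bad <- hw == 0
  if (any(bad)) {
    warning("residue(s) with zero wild-type height excluded: ",
            paste(common[bad], collapse = ", "))
    common <- common[!bad]
    hw <- hw[!bad]
    hv <- hv[!bad]
  }
  ratio <- hv / hw
  scale <- stats::median(ratio)
  rr <- stats::setNames(ratio / scale, common)
  broad <- common[rr <= cutoff]
  list(broadened = sort(c(broad, setdiff(wt$resid, variant$resid))),
       ratios = rr, scale = scale)
}

#' Rank variants by total spectral perturbation
#'
#' Orders variants by the number of significant chemical-shift
#' perturbations plus line-broadened residues (descending); ties are broken
#' by the total composite-shift sum. Input order does not matter.
#'
#' @param results named list; each element a list with components
#'   \code{csp} (a \code{csp_result}), \code{threshold} (ppm), and
#'   \code{broadened} (integer residues).
#' @return data.frame ranked by perturbation count with columns
#'   \code{variant}, \code{n_significant}, \code{n_broadened},
#'   \code{total}, \code{delta_sum}.
#' @export
perturbation_rank <- function(results) {
  if (length(results) < 2L) stop("need at least 2 variants to rank")
  rows <- lapply(names(results), function(nm) {
    r <- results[[nm]]
    nsig <- sum(r$csp$delta >= r$threshold)
    data.frame(variant = nm, n_significant = nsig,
               n_broadened = length(r$broadened),
               total = nsig + length(r$broadened),
               delta_sum = sum(r$csp$delta))
  })
  tb <- do.call(rbind, rows)
  tb <- tb[order(-tb$total, -tb$delta_sum, tb$variant), , drop = FALSE]
  rownames(tb) <- NULL
  tb
}
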