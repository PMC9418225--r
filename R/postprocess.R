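#' Volume fractions of a temperature-difference field
#'
#' Partitions the compared voxels into the fraction with difference at or
#' above the threshold (`V_plus`), at or below its negative (`V_minus`),
#' and strictly between (`V_zero`). Values exactly at +-threshold count in
#' `V_plus`/`V_minus`. The partition is exhaustive and exclusive and the
#' three percentages sum to 100 exactly.
#'
#' @param deltaT numeric vector/array of per-voxel differences (degC);
#'   non-finite entries are not allowed.
#' @param threshold positive threshold (degC, default 1).
#' @return named numeric vector `c(V_plus, V_minus, V_zero)` in percent.
#' @export
volume_fractions <- function(deltaT, threshold = 1) {
  d <- as.numeric(deltaT)
  if (!length(d)) stop("empty field")
  if (any(!is.finite(d))) stop("non-finite values in field")
  stopifnot(threshold > 0)
  n <- length(d)
  vp <- 100 * sum(d >= threshold) / n
  vm <- 100 * sum(d <= -threshold) / n
  c(V_plus = vp, V_minus = vm, V_zero = 100 - vp - vm)
}

#' Wilcoxon signed-rank statistic (brute-rank form)
#'
#' Drops zero differences (classical practice; the dropped count is
#' reported), ranks the absolute values with midranks for ties, and returns
#' the positive/negative rank sums. The reported `statistic` is the
#' smaller of the two sums.
#'
#' @param d numeric vector of paired differences.
#' @return list with `W_plus`, `W_minus`, `statistic`, `n_nonzero`,
#'   `n_zero`.
#' @export
signed_rank_statistic <- function(d) {
  d <- as.numeric(d)
  nz <- d != 0
  dd <- d[nz]
  if (!length(dd))
    return(list(W_plus = 0, W_minus = 0, statistic = 0,
                n_nonzero = 0L, n_zero = sum(!nz)))
  r <- rank(abs(dd))
  wp <- sum(r[dd > 0]); wm <- sum(r[dd < 0])
  list(W_plus = wp, W_minus = wm, statistic = min(wp, wm),
       n_nonzero = length(dd), n_zero = sum(!nz))
}

#' Compare two temperature fields on the same domain
#'
#' Computes the per-voxel difference T1 - T2, the +-threshold volume
#' fractions, and a two-sided paired Wilcoxon signed-rank test (normal
#' approximation; zero differences dropped before ranking and counted).
#' Identical fields are reported as degenerate (no test possible).
#'
#' @param T1,T2 numeric arrays/vectors over the same voxel ordering; NA
#'   voxels (outside the domain) must match and are excluded.
#' @param threshold volume-fraction threshold (degC).
#' @return object of class `field_comparison`.
#' @export
compare_fields <- function(T1, T2, threshold = 1) {
  if (!identical(dim(T1), dim(T2)) || length(T1) != length(T2))
    stop("fields have different shapes")
  a <- as.numeric(T1); b <- as.numeric(T2)
  if (!identical(is.na(a), is.na(b))) stop("NA (out-of-domain) masks differ")
  keep <- !is.na(a)
  d <- a[keep] - b[keep]
  vf <- volume_fractions(d, threshold)
  sr <- signed_rank_statistic(d)
  degenerate <- sr$n_nonzero == 0L
  p <- if (degenerate) NA_real_ else
    suppressWarnings(stats::wilcox.test(d, exact = FALSE)$p.value)
  structure(list(deltaT = d, threshold = threshold,
                 fractions = vf, signed_rank = sr,
                 p_value = p, degenerate = degenerate,
                 n = length(d)),
            class = "field_comparison")
}

#' @export
print.field_comparison <- function(x, ...) {
  cat(sprintf("field_comparison over %d voxels (threshold %g degC)\n",
              x$n, x$threshold))
  cat(sprintf("  V+ %.2f%%  V- %.2f%%  V0 %.2f%%\n",
              x$fractions[["V_plus"]], x$fractions[["V_minus"]],
              x$fractions[["V_zero"]]))
  if (x$degenerate) {
    cat("  fields identical: signed-rank test degenerate\n")
  } else {
    cat(sprintf("  signed-rank statistic %.6g (W+ %.6g, W- %.6g), p = %.3g; %d zero differences dropped\n",
                x$signed_rank$statistic, x$signed_rank$W_plus,
                x$signed_rank$W_minus, x$p_value, x$signed_rank$n_zero))
  }
  invisible(x)
}

#' Normalized temperature histogram
#'
#' Bin counts normalized to probabilities (summing to one), with the
#' sample skewness attached — the fields produced by the coupled model are
#' typically non-normal and skewed, which is why downstream comparisons
#' use rank statistics.
#'
#' @param T_field numeric array/vector (NA entries excluded).
#' @param bins number of bins or a vector of break points.
#' @return data frame with `lower`, `upper`, `mid`, `count`, `prob`;
#'   attributes `skewness` and `n`.
#' @export
export_histogram <- function(T_field, bins = 30) {
  v <- as.numeric(T_field)
  v <- v[is.finite(v)]
  if (!length(v)) stop("empty field")
  h <- graphics::hist(v, breaks = bins, plot = FALSE)
  out <- data.frame(lower = utils::head(h$breaks, -1),
                    upper = utils::tail(h$breaks, -1),
                    mid = h$mids, count = h$counts,
                    prob = h$counts / length(v))
  m <- mean(v); s2 <- mean((v - m)^2)
  attr(out, "skewness") <- if (s2 > 0) mean((v - m)^3) / s2^1.5 else 0
  attr(out, "n") <- length(v)
  out
}

#' Write fields as a legacy VTK structured-points file
#'
#' ASCII VTK (legacy, STRUCTURED_POINTS) with one SCALARS record per named
#' field, in the package's voxel order (x fastest). NA values are written
#' as nan. Field names should carry units, e.g. `P_a_Pa` or `T_degC`.
#'
#' @param path output file.
#' @param grid the `voxel_grid` providing dimensions and spacing.
#' @param fields named list of numeric arrays/vectors of grid length.
#' @export
write_vtk_structured_points <- function(path, grid, fields) {
  stopifnot(inherits(grid, "voxel_grid"), length(fields) > 0,
            !is.null(names(fields)))
  n <- prod(grid$shape)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "hemotherm fields (SI units; temperatures degC)",
               "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", grid$shape[1], grid$shape[2], grid$shape[3]),
               "ORIGIN 0 0 0",
               sprintf("SPACING %.9g %.9g %.9g", grid$spacing[1], grid$spacing[2], grid$spacing[3]),
               sprintf("POINT_DATA %d", n)), con)
  for (nm in names(fields)) {
    v <- as.numeric(fields[[nm]])
    if (length(v) != n) stop("field ", nm, " has wrong length")
    writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
    vs <- format(v, digits = 10, trim = TRUE, scientific = TRUE)
    vs[is.na(v)] <- "nan"
    writeLines(vs, con)
  }
  invisible(path)
}
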