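#' UMI clonal analytics
#'
#' Every transduced founder cell carries a random UMI next to its guide, so
#' the set of UMIs observed in an organ enumerates the clones that engrafted.
#' Real samples also contain low-read background UMIs (ambient RNA, PCR and
#' sequencing artefacts). A knee plot of log10(rank) against log10(reads) per
#' UMI separates the clone plateau from this background; the inflection point
#' of a four-parameter sigmoid fitted to the curve estimates the clone count.
#' UMI prefixes additionally partition one sample into 4^k internal
#' replicates that behave as technical replicates for enrichment statistics.
#'
#' @name invivo_umi
NULL

#' Knee-plot points from a UMI count table
#'
#' UMIs are ranked by read count (descending), ties broken by UMI
#' lexicographic order; rank is 1-based.
#'
#' @param umi_counts data frame with columns `umi` and `count` (per-guide
#'   entries for the same UMI are summed first)
#' @return data frame: umi, reads, rank, log10_rank, log10_reads, ordered by
#'   rank
#' @export
knee_points <- function(umi_counts) {
  stopifnot(nrow(umi_counts) >= 1L)
  dt <- data.table::as.data.table(umi_counts)[, .(reads = sum(count)),
                                              by = umi]
  dt <- dt[order(-reads, umi)]
  dt[, rank := .I]
  out <- as.data.frame(dt)
  out$log10_rank <- log10(out$rank)
  out$log10_reads <- log10(out$reads)
  out
}

sigmoid4 <- function(x, L, k, x0, b) L / (1 + exp(-k * (x - x0))) + b

#' Fit the knee-plot sigmoid
#'
#' Nonlinear least squares of y = L / (1 + exp(-k (x - x0))) + b on the
#' log10(rank)/log10(reads) points, where L is the curve height, k the
#' steepness, x0 the inflection abscissa and b the vertical offset. The top
#' `exclude_top` UMIs by read count and all UMIs with fewer than `min_reads`
#' reads are excluded from fitting (in that order). Initialisation is
#' multi-start: |L| = max(y) - min(y) and b chosen from the data direction,
#' x0 at the 25/50/75 percent quantiles of x, k in {1, 5, 20} of both signs;
#' each start is pre-optimized with Nelder-Mead before the nls polish, and
#' the best residual sum of squares wins. Because (L, k, b) ->
#' (-L, -k, b + L) traces the identical curve, results are canonicalized to
#' k > 0.
#'
#' @param points output of [knee_points()]
#' @param exclude_top number of highest-read UMIs disregarded for fitting
#' @param min_reads minimum reads for a UMI to enter the fit
#' @return a `sigmoid_fit` list: L, k, x0, b, rss, converged, n_points, and
#'   `reason` when not converged
#' @export
fit_knee <- function(points, exclude_top = 50L, min_reads = 10L) {
  keep <- points$rank > exclude_top & points$reads >= min_reads
  pts <- points[keep, , drop = FALSE]
  if (nrow(pts) < 8L) {
    return(structure(list(L = NA_real_, k = NA_real_, x0 = NA_real_,
                          b = NA_real_, rss = NA_real_, converged = FALSE,
                          n_points = nrow(pts), reason = "insufficient data"),
                     class = "sigmoid_fit"))
  }
  x <- pts$log10_rank
  y <- pts$log10_reads
  dir <- if (y[length(y)] >= y[1L]) 1 else -1  # knee curves: -1
  span <- max(y) - min(y)
  if (span == 0) span <- .Machine$double.eps
  # for k > 0 the curve runs from plateau b (left) to b + L (right); for
  # k < 0 the plateaus swap. Choose L and b so every start already follows
  # the data's direction.
  starts <- list()
  for (x00 in unname(quantile(x, c(0.25, 0.5, 0.75)))) {
    for (k0 in c(1, 5, 20, -1, -5, -20)) {
      if (k0 > 0) {
        L0 <- dir * span
        b0 <- if (dir > 0) min(y) else max(y)
      } else {
        L0 <- -dir * span
        b0 <- if (dir > 0) max(y) else min(y)
      }
      starts[[length(starts) + 1L]] <-
        list(L = L0, k = k0, x0 = x00, b = b0)
    }
  }
  rssf <- function(p) {
    e <- exp(pmin(700, pmax(-700, -p[2] * (x - p[3]))))
    sum((y - (p[1] / (1 + e) + p[4]))^2)
  }
  best <- NULL
  best_fallback <- NULL
  for (st in starts) {
    # derivative-free pre-optimization stabilizes Gauss-Newton on knees
    # whose lower plateau is short after the min_reads filter
    op <- stats::optim(unlist(st), rssf,
                       control = list(maxit = 2000, reltol = 1e-12))
    fit <- tryCatch(
      suppressWarnings(nls(y ~ L / (1 + exp(-k * (x - x0))) + b,
          start = as.list(op$par),
          control = stats::nls.control(maxiter = 200, tol = 1e-9,
                                       scaleOffset = 1))),
      error = function(e) NULL)
    if (is.null(fit)) {
      if (op$convergence == 0 &&
          (is.null(best_fallback) || op$value < best_fallback$rss)) {
        p <- op$par
        best_fallback <- list(L = unname(p["L"]), k = unname(p["k"]),
                              x0 = unname(p["x0"]), b = unname(p["b"]),
                              rss = op$value, method = "nelder-mead")
      }
      next
    }
    rss <- sum(resid(fit)^2)
    if (is.null(best) || rss < best$rss) {
      cf <- coef(fit)
      best <- list(L = unname(cf["L"]), k = unname(cf["k"]),
                   x0 = unname(cf["x0"]), b = unname(cf["b"]), rss = rss,
                   method = "nls")
    }
  }
  if (is.null(best)) best <- best_fallback
  if (!is.null(best) && best$k < 0) {
    # (L, k, b) -> (-L, -k, b + L) traces the identical curve; canonicalize
    # to k > 0 so fitted parameters are reproducible
    best <- within(best, {b <- b + L; L <- -L; k <- -k})
  }
  if (is.null(best)) {
    return(structure(list(L = NA_real_, k = NA_real_, x0 = NA_real_,
                          b = NA_real_, rss = NA_real_, converged = FALSE,
                          n_points = nrow(pts), reason = "no start converged"),
                     class = "sigmoid_fit"))
  }
  structure(c(best, list(converged = TRUE, n_points = nrow(pts))),
            class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  if (!x$converged) {
    cat("sigmoid fit: not converged (", x$reason, ")\n", sep = "")
  } else {
    cat(sprintf(
      "sigmoid fit: L=%.4g k=%.4g x0=%.4g b=%.4g rss=%.4g (n=%d)\n",
      x$L, x$k, x$x0, x$b, x$rss, x$n_points))
  }
  invisible(x)
}

#' Clone count from a fitted knee
#'
#' The clone count is the number of UMIs with 1-based rank at most
#' round(10^x0) (half-up rounding), clamped to \[0, number of UMIs\]. UMIs
#' excluded from fitting (the top ranks) still count: they are real clones,
#' only disregarded for curve fitting.
#'
#' @param fit a converged `sigmoid_fit`
#' @param points the [knee_points()] the fit was computed on
#' @return a `clone_estimate` list: x0, clone_count, n_umis_total, n_umis_fit;
#'   or a non-estimate with `reason` when the fit did not converge
#' @export
count_clones <- function(fit, points) {
  n_total <- nrow(points)
  if (!isTRUE(fit$converged)) {
    return(structure(list(x0 = NA_real_, clone_count = NA_integer_,
                          n_umis_total = n_total, n_umis_fit = fit$n_points,
                          reason = fit$reason %||% "fit not converged"),
                     class = "clone_estimate"))
  }
  cut <- floor(10^fit$x0 + 0.5)  # half-up
  clone_count <- as.integer(max(0, min(n_total, cut)))
  structure(list(x0 = fit$x0, clone_count = clone_count,
                 n_umis_total = n_total, n_umis_fit = fit$n_points),
            class = "clone_estimate")
}

#' Estimate clones for one sample in a single call
#'
#' Convenience wrapper: [knee_points()] then [fit_knee()] then
#' [count_clones()].
#'
#' @inheritParams fit_knee
#' @param umi_counts per-sample UMI count data frame (columns umi, count)
#' @return a `clone_estimate`
#' @export
estimate_clones <- function(umi_counts, exclude_top = 50L, min_reads = 10L) {
  pts <- knee_points(umi_counts)
  count_clones(fit_knee(pts, exclude_top, min_reads), pts)
}

#' Split a UMI count table into internal replicates by UMI prefix
#'
#' Each (guide, UMI) entry is assigned to the replicate keyed by the first
#' `prefix_length` UMI bases, giving 4^prefix_length internal replicates
#' (prefix 0 collapses everything into one table). Per-guide sums across
#' replicates equal the collapsed counts by construction.
#'
#' @param umi_counts data frame with columns guide_id, umi, count (no N in
#'   any UMI; N-containing UMIs must have been discarded upstream)
#' @param prefix_length integer in \[0, 5\]
#' @return a `replicate_set`: list(prefix_length, tables) where `tables` is a
#'   named list (one per prefix over \{A,C,G,T\}^prefix_length, including
#'   empty ones) of data frames guide_id, count
#' @export
split_internal_replicates <- function(umi_counts, prefix_length) {
  stopifnot(prefix_length >= 0L, prefix_length <= 5L)
  if (any(grepl("N", umi_counts$umi, fixed = TRUE))) {
    stop("UMIs containing N must be filtered before replicate splitting")
  }
  if (any(nchar(umi_counts$umi) < prefix_length)) {
    stop("all UMIs must be at least prefix_length long")
  }
  prefixes <- if (prefix_length == 0L) "" else {
    apply(expand.grid(rep(list(DNA_BASES), prefix_length),
                      stringsAsFactors = FALSE)[, prefix_length:1, drop = FALSE],
          1L, paste0, collapse = "")
  }
  prefixes <- sort(prefixes)
  key <- substr(umi_counts$umi, 1L, prefix_length)
  dt <- data.table::data.table(prefix = key,
                               guide_id = umi_counts$guide_id,
                               count = umi_counts$count)
  agg <- dt[, .(count = sum(count)), by = .(prefix, guide_id)]
  tables <- lapply(prefixes, function(p) {
    sub <- agg[prefix == p]
    df <- data.frame(guide_id = sub$guide_id, count = sub$count,
                     stringsAsFactors = FALSE)
    df[order(df$guide_id), , drop = FALSE]
  })
  names(tables) <- prefixes
  structure(list(prefix_length = as.integer(prefix_length), tables = tables),
            class = "replicate_set")
}

#' Collapse a replicate set (or UMI table) to per-guide counts
#'
#' @param x a `replicate_set` or a UMI count data frame
#' @return data frame guide_id, count (ordered by guide_id)
#' @export
collapse_counts <- function(x) {
  if (inherits(x, "replicate_set")) {
    dt <- data.table::rbindlist(x$tables)
  } else {
    dt <- data.table::as.data.table(x)[, .(count = sum(count)), by = guide_id]
  }
  dt <- data.table::as.data.table(dt)[, .(count = sum(count)), by = guide_id]
  df <- as.data.frame(dt[order(guide_id)])
  df
}
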