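# Recurrence quantification analysis. A series is (optionally) time-delay
# embedded, pairwise state distances are thresholded into a binary
# recurrence matrix, and features are read off the diagonal and vertical
# line structures: REC (recurrence rate), DET (determinism), LAM
# (laminarity), Lmean/Lmax (mean/longest diagonal line) and DIV = 1/Lmax.
# The line of identity and a Theiler band |i-j| <= w around it are excluded
# from every count; masked cells also break line runs.

#' RQA configuration
#'
#' @param m embedding dimension (>= 1; `m = 1` analyses the series itself,
#'   giving the 24 x 24 recurrence plot of an hourly day-long recording).
#' @param tau embedding delay in samples (hours for hourly series).
#' @param eps absolute recurrence threshold; if `NULL` (default) the
#'   threshold is adaptive: `eps_k` times the standard deviation of the
#'   input series, so patients with different amplitudes are thresholded on
#'   a comparable scale.
#' @param eps_k multiplier for the adaptive (SD-based) threshold.
#' @param norm distance norm in embedded space: `"maximum"` (Chebyshev,
#'   default) or `"euclidean"`. Irrelevant when `m = 1`.
#' @param theiler Theiler window `w` (>= 0): cells with `|i - j| <= w` are
#'   excluded from all counts. `w = 0` excludes only the line of identity;
#'   the default `w = 1` also drops its immediate neighbours, which on a
#'   24-point series would otherwise inflate the recurrence rate with
#'   trivial self-similarity.
#' @param lmin minimum line length for DET and LAM (standard convention: 2).
#' @return list of class `rqa_config`.
#' @export
rqa_config <- function(m = 1, tau = 1, eps = NULL, eps_k = 1.0,
                       norm = c("maximum", "euclidean"), theiler = 1,
                       lmin = 2) {
  norm <- match.arg(norm)
  stopifnot(m >= 1, tau >= 1, m == round(m), tau == round(tau),
            theiler >= 0, lmin >= 2, eps_k >= 0)
  if (!is.null(eps) && eps < 0) stop("eps must be >= 0")
  structure(list(m = as.integer(m), tau = as.integer(tau), eps = eps,
                 eps_k = eps_k, norm = norm, theiler = as.integer(theiler),
                 lmin = as.integer(lmin)),
            class = "rqa_config")
}

#' Time-delay (Takens) embedding
#'
#' Reconstructs m-dimensional state vectors
#' `v_i = (x_i, x_{i+tau}, ..., x_{i+(m-1)tau})` from a scalar series.
#'
#' @param x numeric series (no missing values).
#' @param m embedding dimension.
#' @param tau delay in samples.
#' @return numeric matrix with `length(x) - (m-1)*tau` rows and `m` columns.
#' @examples
#' nrow(embed_series(rnorm(24), m = 2, tau = 1))  # 23
#' @export
embed_series <- function(x, m = 1, tau = 1) {
  x <- as.numeric(x)
  stopifnot(m >= 1, tau >= 1)
  if (anyNA(x)) stop("embedding requires a complete series (no NA)")
  nv <- length(x) - (m - 1) * tau
  if (nv < 2) {
    stop(sprintf("series of length %d too short for embedding (m=%d, tau=%d)",
                 length(x), m, tau))
  }
  vapply(seq_len(m) - 1L, function(k) x[(1 + k * tau):(nv + k * tau)],
         numeric(nv))
}

#' Build a recurrence matrix from embedded state vectors
#'
#' `R[i, j] = 1` iff the distance between states i and j is at most `eps`.
#' The matrix is stored in full (symmetric, `R[i, i] = 1`); the Theiler
#' window is recorded and applied by the feature counts, not baked into the
#' stored matrix.
#'
#' @param vectors embedding matrix (rows = state vectors) or a plain
#'   numeric vector (treated as `m = 1`).
#' @param eps recurrence threshold (>= 0).
#' @param norm `"maximum"` or `"euclidean"`.
#' @param theiler Theiler window `w`.
#' @return object of class `recurrence_matrix`.
#' @export
recurrence_matrix <- function(vectors, eps, norm = c("maximum", "euclidean"),
                              theiler = 1) {
  norm <- match.arg(norm)
  if (is.null(dim(vectors))) vectors <- matrix(as.numeric(vectors), ncol = 1)
  nv <- nrow(vectors)
  if (eps < 0) stop("eps must be >= 0")
  if (nv < 2) stop("need at least 2 state vectors")
  D <- if (norm == "euclidean") {
    as.matrix(dist(vectors, method = "euclidean"))
  } else {
    Reduce(pmax, lapply(seq_len(ncol(vectors)),
                        function(j) abs(outer(vectors[, j], vectors[, j], "-"))))
  }
  R <- matrix(as.integer(D <= eps), nv, nv)
  structure(list(R = R, n_vectors = nv, eps = eps, norm = norm,
                 theiler = as.integer(theiler)),
            class = "recurrence_matrix")
}

#' @export
print.recurrence_matrix <- function(x, ...) {
  cat(sprintf("<recurrence_matrix> %d x %d, eps=%.4g (%s norm), Theiler w=%d\n",
              x$n_vectors, x$n_vectors, x$eps, x$norm, x$theiler))
  invisible(x)
}

run_lengths_of_ones <- function(v) {
  r <- rle(v)
  r$lengths[r$values == 1L]
}

# All maximal diagonal run lengths outside the Theiler band (both triangles).
diagonal_run_lengths <- function(rm) {
  R <- rm$R; n <- rm$n_vectors; w <- rm$theiler
  lens <- integer(0)
  for (k in seq_len(n - 1)) {
    if (k <= w) next
    d <- R[cbind(seq_len(n - k), seq_len(n - k) + k)]
    rl <- run_lengths_of_ones(d)
    lens <- c(lens, rl, rl)   # matrix symmetry: offset -k mirrors +k
  }
  lens
}

# All maximal vertical run lengths; Theiler-masked cells break runs.
vertical_run_lengths <- function(rm) {
  R <- rm$R; n <- rm$n_vectors; w <- rm$theiler
  lens <- integer(0)
  for (j in seq_len(n)) {
    v <- R[, j]
    v[abs(seq_len(n) - j) <= w] <- 0L
    lens <- c(lens, run_lengths_of_ones(v))
  }
  lens
}

line_histogram <- function(lens, lmin) {
  if (length(lens) == 0) {
    return(data.frame(length = integer(0), count = integer(0),
                      counted = logical(0)))
  }
  tab <- table(lens)
  data.frame(length = as.integer(names(tab)),
             count = as.integer(tab),
             counted = as.integer(names(tab)) >= lmin)
}

#' Histogram of diagonal line lengths
#'
#' Maximal runs of recurrent cells along each diagonal outside the Theiler
#' band, tallied by length. Runs shorter than `lmin` are tallied too
#' (flagged `counted = FALSE`): they contribute to the DET denominator.
#'
#' @param rm a [recurrence_matrix()].
#' @param lmin minimum line length considered a "line".
#' @return data.frame: `length`, `count`, `counted`.
#' @export
diagonal_line_histogram <- function(rm, lmin = 2) {
  stopifnot(inherits(rm, "recurrence_matrix"))
  line_histogram(diagonal_run_lengths(rm), lmin)
}

#' Histogram of vertical line lengths
#'
#' As [diagonal_line_histogram()], with runs counted down each column;
#' Theiler-masked cells break runs. By matrix symmetry this equals the
#' horizontal-line histogram.
#'
#' @inheritParams diagonal_line_histogram
#' @return data.frame: `length`, `count`, `counted`.
#' @export
vertical_line_histogram <- function(rm, lmin = 2) {
  stopifnot(inherits(rm, "recurrence_matrix"))
  line_histogram(vertical_run_lengths(rm), lmin)
}

#' RQA features of a recurrence matrix
#'
#' * REC: recurrent cells / all cells, both outside the Theiler band.
#' * DET: recurrent points on diagonal lines of length >= `lmin` / all
#'   recurrent points.
#' * LAM: recurrent points on vertical lines of length >= `lmin` / all
#'   recurrent points.
#' * Lmean: mean diagonal line length among lines >= `lmin`.
#' * Lmax: longest diagonal line (the line of identity is excluded by the
#'   Theiler band); DIV = 1/Lmax.
#'
#' When no recurrent point lies outside the Theiler band, REC is 0 and the
#' remaining features are `NA` with a `reason` attribute — never silent
#' zeros — so cohort statistics can exclude them explicitly.
#'
#' @param rm a [recurrence_matrix()].
#' @param lmin minimum line length for DET/LAM/Lmean.
#' @return object of class `rqa_features`: list with REC, DET, LAM, Lmean,
#'   Lmax, DIV, n_recurrent, and optionally `reason`.
#' @export
rqa_features <- function(rm, lmin = 2) {
  stopifnot(inherits(rm, "recurrence_matrix"))
  n <- rm$n_vectors; w <- rm$theiler
  band <- abs(row(rm$R) - col(rm$R)) <= w
  n_off <- sum(!band)
  if (n_off == 0) stop("Theiler window leaves no countable cells")
  n_rec <- sum(rm$R[!band])
  REC <- n_rec / n_off
  if (n_rec == 0) {
    return(structure(list(REC = 0, DET = NA_real_, LAM = NA_real_,
                          Lmean = NA_real_, Lmax = NA_integer_,
                          DIV = NA_real_, n_recurrent = 0L,
                          reason = "no recurrent points outside the Theiler window"),
                     class = "rqa_features"))
  }
  dl <- diagonal_run_lengths(rm)
  vl <- vertical_run_lengths(rm)
  DET <- sum(dl[dl >= lmin]) / n_rec
  LAM <- sum(vl[vl >= lmin]) / n_rec
  Lmax <- max(dl)
  Lmean <- if (any(dl >= lmin)) mean(dl[dl >= lmin]) else NA_real_
  structure(list(REC = REC, DET = DET, LAM = LAM, Lmean = Lmean,
                 Lmax = as.integer(Lmax), DIV = 1 / Lmax,
                 n_recurrent = as.integer(n_rec)),
            class = "rqa_features")
}

#' @export
print.rqa_features <- function(x, ...) {
  if (!is.null(x$reason)) {
    cat(sprintf("<rqa_features> REC=0 (%s)\n", x$reason))
    return(invisible(x))
  }
  cat(sprintf(
    "<rqa_features> REC=%.3f DET=%.3f LAM=%.3f Lmean=%s Lmax=%d DIV=%.4f\n",
    x$REC, x$DET, x$LAM,
    if (is.na(x$Lmean)) "NA" else sprintf("%.2f", x$Lmean), x$Lmax, x$DIV))
  invisible(x)
}

#' Full RQA of one temperature series
#'
#' Embeds the series, thresholds distances into a recurrence matrix (with
#' the per-series adaptive threshold unless an absolute `eps` is
#' configured), and computes the feature set.
#'
#' @param series a complete hourly [cbt_series()] (run [fill_gaps()] first)
#'   or a plain numeric vector.
#' @param config an [rqa_config()].
#' @return list: `features` ([rqa_features()]), `matrix`
#'   ([recurrence_matrix()]), `config`.
#' @examples
#' s <- cbt_series(37 + 0.4 * cos(2 * pi * (0:23) / 24))
#' analyze_rqa(s)$features
#' @export
analyze_rqa <- function(series, config = rqa_config()) {
  stopifnot(inherits(config, "rqa_config"))
  x <- if (inherits(series, "cbt_series")) series$values else as.numeric(series)
  if (anyNA(x)) {
    stop("RQA requires a complete series: fill gaps (or reject) first")
  }
  eps <- config$eps %||% (config$eps_k * sd(x))
  V <- embed_series(x, config$m, config$tau)
  rm_ <- recurrence_matrix(V, eps = eps, norm = config$norm,
                           theiler = config$theiler)
  list(features = rqa_features(rm_, lmin = config$lmin), matrix = rm_,
       config = config)
}

#' RQA features for a list of series, as a table
#'
#' Series rejected by [fill_gaps()] are reported with `NA` features and the
#' rejection reason, never silently dropped.
#'
#' @param series_list list of hourly [cbt_series()].
#' @param config an [rqa_config()].
#' @param max_gap_hours passed to [fill_gaps()].
#' @return data.frame with one row per (patient, phase).
#' @export
rqa_table <- function(series_list, config = rqa_config(), max_gap_hours = 2) {
  rows <- lapply(series_list, function(s) {
    base <- data.frame(patient_id = s$patient_id, group = s$group,
                       phase = s$phase, stringsAsFactors = FALSE)
    res <- tryCatch({
      filled <- fill_gaps(s, max_gap_hours = max_gap_hours)
      f <- analyze_rqa(filled, config)$features
      cbind(base, data.frame(REC = f$REC, DET = f$DET, LAM = f$LAM,
                             Lmean = f$Lmean, Lmax = f$Lmax, DIV = f$DIV,
                             rqa_note = f$reason %||% "",
                             stringsAsFactors = FALSE))
    }, circarq_gap_error = function(e) {
      cbind(base, data.frame(REC = NA_real_, DET = NA_real_, LAM = NA_real_,
                             Lmean = NA_real_, Lmax = NA_integer_,
                             DIV = NA_real_, rqa_note = conditionMessage(e),
                             stringsAsFactors = FALSE))
    })
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Plot a recurrence matrix
#'
#' Square black/white raster with both axes in hours.
#'
#' @param x a [recurrence_matrix()].
#' @param main plot title.
#' @param ... further arguments passed to [graphics::image()].
#' @export
plot.recurrence_matrix <- function(x, main = "Recurrence plot", ...) {
  n <- x$n_vectors
  graphics::image(0:(n - 1), 0:(n - 1), x$R, zlim = c(0, 1),
                  col = c("white", "black"), xlab = "time (h)",
                  ylab = "time (h)", main = main, useRaster = TRUE, ...)
  graphics::box()
  graphics::mtext(sprintf("eps=%.3g, %s norm, w=%d", x$eps, x$norm, x$theiler),
                  side = 3, line = 0.2, cex = 0.7)
  invisible(x)
}
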