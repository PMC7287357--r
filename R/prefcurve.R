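#' Choice counts over ordered stimulus levels
#'
#' Bundles one individual's aggregated choices: how many times each stimulus
#' level was chosen across its repeated trials. This is the input to
#' [fit_preference_curve()].
#'
#' @param levels k >= 3 strictly increasing stimulus values (s.d. units).
#' @param counts non-negative integer count per level, summing to >= 1.
#' @return An object of class `choice_counts`.
#' @export
choice_counts <- function(levels, counts) {
  if (!is.numeric(levels) || length(levels) < 3L || any(!is.finite(levels)) ||
      is.unsorted(levels, strictly = TRUE))
    stop("'levels' must be >= 3 finite, strictly increasing values",
         call. = FALSE)
  if (!is.numeric(counts) || length(counts) != length(levels) ||
      any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts)))
    stop("'counts' must be non-negative integers, one per level",
         call. = FALSE)
  if (sum(counts) < 1)
    stop("'counts' must contain at least one choice", call. = FALSE)
  structure(list(levels = as.numeric(levels), counts = as.numeric(counts)),
            class = "choice_counts")
}

# GCV gam fit of counts ~ s(levels) with total edf capped at 'cap'.
# Basis dimension k-1 already bounds edf by k-1 for k >= 5; for very few
# levels the cap is enforced by increasing the smoothing parameter.
# With GCV smoothing the chosen smoothing parameter is clamped to a
# moderate window: at 7 data points unconstrained GCV is erratic,
# over-smoothing a single-level count spike to a near-line while barely
# smoothing diffuse counts, which destroys the comparability of strength
# and tolerance across individuals. The default policy avoids this
# entirely by applying one common penalty to every curve.
.sp_window <- c(0.05, 5)
.sp_common <- 0.5

.fit_capped_gam <- function(levels, counts, cap, sp = NULL) {
  k <- length(levels)
  kb <- max(3L, k - 1L)
  dat <- data.frame(x = levels, y = counts)
  fit_at <- function(sp_val) {
    if (is.null(sp_val))
      mgcv::gam(y ~ s(x, k = kb, bs = "cr"), data = dat)
    else
      mgcv::gam(y ~ s(x, k = kb, bs = "cr"), data = dat, sp = sp_val)
  }
  fit <- fit_at(sp)
  if (is.null(sp)) {
    sp_gcv <- min(max(fit$sp, .sp_window[1]), .sp_window[2])
    if (sp_gcv != fit$sp) fit <- fit_at(sp_gcv)
  }
  edf <- sum(fit$edf)
  if (is.null(sp) && edf > cap + 1e-6) {
    # increase the penalty until the total edf meets the cap
    f <- function(lsp) sum(fit_at(exp(lsp))$edf) - cap
    lo <- log(max(fit$sp, 1e-8))
    hi <- lo
    while (f(hi) > 0 && hi < 40) hi <- hi + 2
    root <- stats::uniroot(f, c(lo, hi))$root
    fit <- fit_at(exp(root))
    edf <- sum(fit$edf)
  }
  list(fit = fit, edf = edf)
}

#' Fit a spline preference curve to choice counts
#'
#' Penalized cubic regression spline fit (a generalized additive model) of
#' choice counts against stimulus level, the standard smoother behind
#' preference-function analysis. The default smoothing policy (`"common"`)
#' applies one moderate fixed penalty (`sp = 0.5`) to every individual, the
#' way preference-function studies apply a single smoothing setting across
#' all splines so that the extracted traits are comparable between
#' individuals and against the random-choice null. `smoothing = "gcv"`
#' instead selects the penalty per curve by generalized cross-validation,
#' with the total effective degrees of freedom constrained to `[2, k - 1]`
#' (so 7 noisy counts are never interpolated) and the smoothing parameter
#' clamped to a moderate window (`[0.05, 5]`); with as few as 7 counts,
#' per-curve GCV is erratic, which is why it is not the default. A number
#' fixes the penalty explicitly; large values approach the least-squares
#' straight line through the counts. The curve is evaluated on a uniform
#' grid spanning the level range and negative fitted heights are clipped
#' to 0, since attractiveness is estimated from non-negative counts.
#'
#' @param data a [choice_counts()] object.
#' @param smoothing `"common"` (default), `"gcv"`, or a single
#'   non-negative number used as the fixed smoothing parameter.
#' @param grid_size number of evaluation points (>= 101; default 501).
#' @return An object of class `preference_curve`: list with `grid`, `height`
#'   (non-negative, length `grid_size`), `edf`, `sp`, and the source `data`.
#' @examples
#' cc <- choice_counts(-3:3, c(0, 0, 0, 0, 1, 1, 2))
#' crv <- fit_preference_curve(cc)
#' extract_traits(crv)
#' @export
fit_preference_curve <- function(data, smoothing = "common",
                                 grid_size = 501) {
  if (!inherits(data, "choice_counts"))
    data <- do.call(choice_counts, as.list(data)[c("levels", "counts")])
  grid_size <- .check_count(grid_size, "grid_size", lower = 101L)
  k <- length(data$levels)
  if (identical(smoothing, "common")) {
    sp <- .sp_common
  } else if (identical(smoothing, "gcv") || identical(smoothing, "auto")) {
    sp <- NULL
  } else {
    .check_number(smoothing, "smoothing", lower = 0)
    sp <- smoothing
  }
  res <- .fit_capped_gam(data$levels, data$counts, cap = k - 1, sp = sp)
  grid <- seq(data$levels[1], data$levels[k], length.out = grid_size)
  height <- as.numeric(predict(res$fit, newdata = data.frame(x = grid)))
  height <- pmax(height, 0)
  structure(list(grid = grid, height = height, edf = res$edf,
                 sp = unname(res$fit$sp), source = data),
            class = "preference_curve")
}

#' @export
print.preference_curve <- function(x, ...) {
  cat("Preference curve on [", x$grid[1], ",", x$grid[length(x$grid)],
      "], ", length(x$grid), " grid points, edf ", round(x$edf, 2), "\n",
      sep = "")
  tr <- extract_traits(x)
  cat(sprintf("  peak %.3f  peak height %.3f  strength %.3f  tolerance %.3f\n",
              tr$peak, tr$peak_height, tr$strength, tr$tolerance))
  invisible(x)
}

.peak_tol <- 1e-9

#' Peak preference of a curve
#'
#' The stimulus value at which the preference curve is maximal. If several
#' grid points tie for the maximum (heights within 1e-9 of it, e.g. a flat
#' curve or a plateau), the midpoint of the tying set is returned, so a flat
#' curve has its peak at the centre of the stimulus range.
#'
#' @param curve a [fit_preference_curve()] result.
#' @return Peak location in stimulus (s.d.) units.
#' @export
extract_peak <- function(curve) {
  stopifnot(inherits(curve, "preference_curve"))
  h <- curve$height
  idx <- which(h >= max(h) - .peak_tol)
  mean(range(curve$grid[idx]))
}

#' Preference strength of a curve
#'
#' How sharply attractiveness falls away from the peak, operationalized as
#' the scale-invariant ratio `(h_peak - h_mean) / h_mean`, where `h_mean` is
#' the mean curve height over the evaluation grid. A flat curve (or a curve
#' of zero height) has strength 0; concentrating the same number of choices
#' on fewer levels increases strength. Multiplying all counts by a constant
#' leaves strength unchanged.
#'
#' @param curve a [fit_preference_curve()] result.
#' @return Unitless strength >= 0.
#' @export
extract_strength <- function(curve) {
  stopifnot(inherits(curve, "preference_curve"))
  hbar <- mean(curve$height)
  if (hbar <= .peak_tol) return(0)
  max(0, (max(curve$height) - hbar) / hbar)
}

#' Tolerance of a preference curve
#'
#' Width of the stimulus range over which the curve stays at or above a set
#' fraction (default one half) of its peak height. The `"broad"` definition
#' sums the lengths of all such regions; `"strict"` measures only the
#' contiguous region containing the peak. Lengths are measured on the
#' evaluation grid with linear interpolation at threshold crossings. A flat
#' or zero-height curve has tolerance equal to the full stimulus range.
#'
#' @param curve a [fit_preference_curve()] result.
#' @param at height fraction in (0, 1) at which width is measured.
#' @param definition `"broad"` (default) or `"strict"`.
#' @return Tolerance in stimulus (s.d.) units, in (0, range].
#' @export
extract_tolerance <- function(curve, at = 0.5,
                              definition = c("broad", "strict")) {
  stopifnot(inherits(curve, "preference_curve"))
  .check_number(at, "at", lower = 0, upper = 1,
                strict_lower = TRUE, strict_upper = TRUE)
  definition <- match.arg(definition)
  g <- curve$grid
  h <- curve$height
  full <- g[length(g)] - g[1]
  hmax <- max(h)
  if (hmax <= .peak_tol) return(full)       # no-signal convention
  thr <- at * hmax
  above <- h >= thr
  if (all(above)) return(full)

  # per-interval covered length with linear interpolation at crossings
  seg_len <- function(i) {
    a <- above[i]; b <- above[i + 1L]
    dx <- g[i + 1L] - g[i]
    if (a && b) return(dx)
    if (!a && !b) return(0)
    frac <- (thr - h[i]) / (h[i + 1L] - h[i])  # crossing position in [0,1]
    if (a) frac * dx else (1 - frac) * dx
  }
  lens <- vapply(seq_len(length(g) - 1L), seg_len, numeric(1))
  if (definition == "broad") return(sum(lens))

  # strict: contiguous run of above-threshold points containing the peak
  peak_i <- which.max(h)
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  ri <- which(runs$values & starts <= peak_i & ends >= peak_i)
  lo <- starts[ri]; hi <- ends[ri]
  width <- if (hi > lo) g[hi] - g[lo] else 0
  if (lo > 1L) width <- width + seg_len(lo - 1L)
  if (hi < length(g)) width <- width + seg_len(hi)
  width
}

#' Extract all preference-function traits from a curve
#'
#' @param curve a [fit_preference_curve()] result.
#' @param at height fraction for tolerance (default 0.5).
#' @param definition tolerance definition, `"broad"` (default) or `"strict"`.
#' @return A one-row data frame with `peak`, `peak_height`, `strength`,
#'   `tolerance`, `edf`.
#' @export
extract_traits <- function(curve, at = 0.5,
                           definition = c("broad", "strict")) {
  definition <- match.arg(definition)
  data.frame(peak = extract_peak(curve),
             peak_height = max(curve$height),
             strength = extract_strength(curve),
             tolerance = extract_tolerance(curve, at, definition),
             edf = curve$edf)
}

#' Fit one individual's preference function from its trial records
#'
#' Aggregates a single fish's trial records into choice counts and, provided
#' the fish successfully chose a shell at least `min_choices` times (default
#' 3, the standard inclusion rule for four- or five-trial designs), fits the
#' preference curve and extracts all traits. Fish with fewer successful
#' choices are excluded rather than fitted.
#'
#' @param trials data frame of one fish's trials with columns `fish_id`,
#'   `trial_index` and `choice` (1-based level index, `NA` = no choice).
#' @param levels stimulus levels on offer (default `-3:3`).
#' @param min_choices inclusion threshold on successful choices (default 3).
#' @param at,definition tolerance options, see [extract_tolerance()].
#' @param smoothing see [fit_preference_curve()].
#' @return A one-row data frame with `n_trials`, `n_choices`, `included`
#'   and (when included) the traits; excluded fish carry `NA` traits.
#' @export
fit_individual <- function(trials, levels = -3:3, min_choices = 3,
                           at = 0.5, definition = "broad",
                           smoothing = "common") {
  if (is.null(trials) || nrow(trials) == 0L)
    stop("empty trial list", call. = FALSE)
  if (length(unique(trials$fish_id)) != 1L)
    stop("'trials' must belong to a single fish", call. = FALSE)
  ch <- trials$choice
  ok <- !is.na(ch)
  base <- data.frame(fish_id = trials$fish_id[1],
                     n_trials = nrow(trials), n_choices = sum(ok),
                     stringsAsFactors = FALSE)
  if (sum(ok) < min_choices)
    return(cbind(base, included = FALSE, peak = NA_real_,
                 peak_height = NA_real_, strength = NA_real_,
                 tolerance = NA_real_, edf = NA_real_))
  counts <- tabulate(ch[ok], nbins = length(levels))
  crv <- fit_preference_curve(choice_counts(levels, counts),
                              smoothing = smoothing)
  cbind(base, included = TRUE, extract_traits(crv, at, definition))
}

#' Fit preference functions for every fish in a choice dataset
#'
#' Applies [fit_individual()] to each fish of a simulated or observed
#' [generate_choice_dataset()]-style dataset and returns the per-fish trait
#' table (excluded fish retained with `included = FALSE`).
#'
#' @param dataset a `choice_dataset` (list with `fish`, `trials`, `levels`).
#' @param ... passed to [fit_individual()].
#' @return Data frame with one row per fish: fish metadata, inclusion flag
#'   and preference-function traits.
#' @export
fit_cohort <- function(dataset, ...) {
  stopifnot(is.list(dataset), !is.null(dataset$fish),
            !is.null(dataset$trials))
  rows <- lapply(seq_len(nrow(dataset$fish)), function(i) {
    id <- dataset$fish$fish_id[i]
    tr <- dataset$trials[dataset$trials$fish_id == id, , drop = FALSE]
    out <- fit_individual(tr, levels = dataset$levels, ...)
    cbind(dataset$fish[i, c("fish_id", "sex", "body_size_mm", "task")],
          out[, setdiff(names(out), "fish_id"), drop = FALSE])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
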