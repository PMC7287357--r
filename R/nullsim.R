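#' Random-choice null distribution of preference-function traits
#'
#' Simulates replicates of a fish making `n_choices` purely random
#' (uniform) choices out of `k` stimulus options, fits each replicate's
#' preference curve and extracts its traits. The resulting trait samples are
#' the null expectation under random choice and serve as the reference group
#' when testing whether observed preference-function traits are non-random.
#' Null replicates always make exactly `n_choices` successful choices;
#' no-choice trials are not part of the null.
#'
#' @param n_reps number of simulated random choosers (default 1000).
#' @param n_choices successful choices per replicate (default 4).
#' @param k number of stimulus options (default 7).
#' @param levels stimulus values; default `k` equally spaced values from -3
#'   to +3 s.d.
#' @param seed optional integer seed.
#' @param at,definition tolerance options, see [extract_tolerance()].
#' @return A data frame of class `null_distribution` with columns
#'   `replicate`, `peak`, `peak_height`, `strength`, `tolerance`; simulation
#'   settings are stored as attributes (`n_reps`, `n_choices`, `k`,
#'   `levels`, `seed`).
#' @examples
#' nd <- simulate_random_traits(n_reps = 50, seed = 1)
#' colMeans(nd[, c("peak", "strength", "tolerance")])
#' @export
simulate_random_traits <- function(n_reps = 1000, n_choices = 4, k = 7,
                                   levels = seq(-3, 3, length.out = k),
                                   seed = NULL, at = 0.5,
                                   definition = "broad") {
  n_reps <- .check_count(n_reps, "n_reps")
  n_choices <- .check_count(n_choices, "n_choices")
  k <- .check_count(k, "k", lower = 3L)
  stopifnot(length(levels) == k)
  .maybe_seed(seed)

  # memoise: many replicates share the same count vector
  cache <- new.env(parent = emptyenv())
  one <- function(counts) {
    key <- paste(counts, collapse = ",")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    crv <- fit_preference_curve(choice_counts(levels, counts))
    tr <- extract_traits(crv, at = at, definition = definition)
    cache[[key]] <- tr
    tr
  }
  draws <- matrix(sample.int(k, n_reps * n_choices, replace = TRUE),
                  nrow = n_reps)
  rows <- lapply(seq_len(n_reps), function(i)
    one(tabulate(draws[i, ], nbins = k)))
  out <- cbind(replicate = seq_len(n_reps), do.call(rbind, rows))
  out$edf <- NULL
  attr(out, "n_reps") <- n_reps
  attr(out, "n_choices") <- n_choices
  attr(out, "k") <- k
  attr(out, "levels") <- levels
  attr(out, "seed") <- seed
  class(out) <- c("null_distribution", "data.frame")
  out
}

#' @export
print.null_distribution <- function(x, ...) {
  cat("Random-choice null:", attr(x, "n_reps"), "replicates of",
      attr(x, "n_choices"), "choices among", attr(x, "k"), "levels\n")
  print(round(vapply(x[c("peak", "strength", "tolerance")],
                     function(v) c(mean = mean(v), sd = sd(v)),
                     numeric(2)), 3))
  invisible(x)
}

#' Nonparametric comparison of observed traits against the random-choice null
#'
#' Bootstrap companion to the parametric contrasts: resamples the null trait
#' values into groups of the same size as the observed group and compares
#' group means. The empirical p-value uses the add-one correction
#' `(1 + #extreme) / (n_resamples + 1)` so it is never exactly zero.
#'
#' @param observed numeric vector of observed trait values for one task.
#' @param null a [simulate_random_traits()] result.
#' @param trait `"peak"`, `"strength"` or `"tolerance"`.
#' @param side `"greater"` tests whether the observed mean is larger than
#'   expected under random choice, `"less"` the reverse.
#' @param n_resamples bootstrap resamples (default 1e4).
#' @param seed optional integer seed.
#' @return List with `null_mean`, `null_sd`, `observed_mean`, `empirical_p`,
#'   `side`, `n_resamples`.
#' @export
empirical_comparison <- function(observed, null,
                                 trait = c("peak", "strength", "tolerance"),
                                 side = c("greater", "less"),
                                 n_resamples = 1e4, seed = NULL) {
  trait <- match.arg(trait)
  side <- match.arg(side)
  observed <- observed[is.finite(observed)]
  if (length(observed) == 0L)
    stop("'observed' must be non-empty", call. = FALSE)
  if (!inherits(null, "null_distribution"))
    stop("'null' must be a null_distribution", call. = FALSE)
  if (attr(null, "n_reps") < 10L)
    stop("null distribution too small (n_reps < 10)", call. = FALSE)
  n_resamples <- .check_count(n_resamples, "n_resamples", lower = 100L)
  .maybe_seed(seed)

  vals <- null[[trait]]
  m <- length(observed)
  obs_mean <- mean(observed)
  res <- matrix(sample(vals, m * n_resamples, replace = TRUE), nrow = m)
  null_means <- colMeans(res)
  extreme <- if (side == "greater") null_means >= obs_mean
             else null_means <= obs_mean
  list(null_mean = mean(vals), null_sd = sd(vals),
       observed_mean = obs_mean,
       empirical_p = (1 + sum(extreme)) / (n_resamples + 1),
       side = side, n_resamples = n_resamples)
}
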