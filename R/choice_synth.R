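#' Latent preference driving simulated choices
#'
#' Constructs the latent preference used by [generate_choice_dataset()]. A
#' simulated fish evaluates stimulus level `x` (in population s.d. units)
#' with the Gaussian-bump utility `u(x) = -((x - mu)/omega)^2` and, on each
#' trial in which it makes a choice, picks level `x_j` with probability
#' proportional to `exp(beta * u(x_j))` (a softmax). This minimal family
#' spans the shapes relevant to preference-function analysis: `beta = 0`
#' gives purely random (flat) choice, `mu` inside the tested range gives a
#' closed preference, and `mu` at or beyond the range boundary gives an
#' open-ended preference.
#'
#' @param mu most attractive stimulus level (s.d. units on the stimulus axis).
#' @param omega width of the attraction window (s.d. units, > 0).
#' @param beta choice sharpness (unitless, >= 0); 0 means random choice.
#' @param p_nochoice probability that a trial ends with no choice, in [0, 1);
#'   independent of the stimulus levels.
#' @return An object of class `latent_preference`.
#' @examples
#' latent_preference(mu = 3, omega = 2, beta = 3, p_nochoice = 0.1)
#' @export
latent_preference <- function(mu = 0, omega = 1, beta = 1, p_nochoice = 0) {
  .check_number(mu, "mu")
  .check_number(omega, "omega", lower = 0, strict_lower = TRUE)
  .check_number(beta, "beta", lower = 0)
  .check_number(p_nochoice, "p_nochoice", lower = 0, upper = 1,
                strict_upper = TRUE)
  structure(list(mu = mu, omega = omega, beta = beta,
                 p_nochoice = p_nochoice),
            class = "latent_preference")
}

#' Choice probabilities implied by a latent preference
#'
#' @param pref a [latent_preference()].
#' @param levels stimulus levels on offer (s.d. units).
#' @return Probability of choosing each level, conditional on a choice being
#'   made (sums to 1).
#' @export
choice_probabilities <- function(pref, levels = -3:3) {
  stopifnot(inherits(pref, "latent_preference"))
  u <- -((levels - pref$mu) / pref$omega)^2
  w <- exp(pref$beta * (u - max(u)))  # shift for numerical stability
  w / sum(w)
}

#' Simulate a multi-level shelter-choice dataset
#'
#' Generates the fish roster and trial records of one choice task: each fish
#' is offered the same ordered array of stimulus levels (by default the 7
#' replica levels at -3..+3 population s.d.) on `trials_per_fish` repeated
#' trials. Body sizes are drawn from sex-specific normal distributions
#' (defaults 36.5 +/- 4.5 mm standard length for males, 30.1 +/- 2.4 mm for
#' females, truncated at 0.1 mm). On each trial the fish makes no choice
#' with probability `p_nochoice` and otherwise chooses a level under the
#' softmax law of [latent_preference()].
#'
#' @param task label of the manipulated attribute, one of `"size"`,
#'   `"length"`, `"aperture"`, `"intactness"` (free-form labels allowed).
#' @param n_males,n_females number of fish of each sex (>= 1 in total).
#' @param trials_per_fish repeated trials per fish (>= 1).
#' @param pref a [latent_preference()], or a function
#'   `function(body_size_mm, sex)` returning one, for body-size- or
#'   sex-dependent preferences.
#' @param levels stimulus levels on offer (default `-3:3`).
#' @param seed optional integer seed.
#' @param size_mean,size_sd named numeric vectors (`male`, `female`) of body
#'   size means and s.d. in mm.
#' @return A list of class `choice_dataset` with elements `fish` (columns
#'   `fish_id`, `sex`, `body_size_mm`, `task`) and `trials` (columns
#'   `fish_id`, `trial_index`, `choice`; `choice` is the 1-based level index
#'   or `NA` for a no-choice trial), plus `levels`.
#' @examples
#' d <- generate_choice_dataset(task = "size", seed = 1,
#'   pref = latent_preference(mu = 3, omega = 2, beta = 3, p_nochoice = 0.1))
#' table(d$trials$choice, useNA = "ifany")
#' @export
generate_choice_dataset <- function(task = "size", n_males = 10,
                                    n_females = 10, trials_per_fish = 4,
                                    pref = latent_preference(),
                                    levels = -3:3, seed = NULL,
                                    size_mean = c(male = 36.5, female = 30.1),
                                    size_sd = c(male = 4.5, female = 2.4)) {
  n_males <- .check_count(n_males, "n_males", lower = 0L)
  n_females <- .check_count(n_females, "n_females", lower = 0L)
  if (n_males + n_females < 1L)
    stop("need at least one fish", call. = FALSE)
  trials_per_fish <- .check_count(trials_per_fish, "trials_per_fish")
  if (length(levels) < 3L || is.unsorted(levels, strictly = TRUE))
    stop("'levels' must be >= 3 strictly increasing values", call. = FALSE)
  .maybe_seed(seed)

  sex <- rep(c("male", "female"), c(n_males, n_females))
  n_fish <- length(sex)
  body <- rnorm(n_fish, size_mean[sex], size_sd[sex])
  body <- pmax(body, 0.1)  # truncate non-physical draws
  fish <- data.frame(
    fish_id = sprintf("%s_%s_%02d", task, substr(sex, 1, 1), seq_len(n_fish)),
    sex = sex, body_size_mm = body, task = task,
    stringsAsFactors = FALSE
  )

  k <- length(levels)
  one_fish <- function(i) {
    p <- if (is.function(pref)) pref(body[i], sex[i]) else pref
    stopifnot(inherits(p, "latent_preference"))
    probs <- choice_probabilities(p, levels)
    nochoice <- runif(trials_per_fish) < p$p_nochoice
    ch <- ifelse(nochoice, NA_integer_,
                 sample.int(k, trials_per_fish, replace = TRUE, prob = probs))
    data.frame(fish_id = fish$fish_id[i],
               trial_index = seq_len(trials_per_fish),
               choice = as.integer(ch), stringsAsFactors = FALSE)
  }
  trials <- do.call(rbind, lapply(seq_len(n_fish), one_fish))
  structure(list(fish = fish, trials = trials, levels = levels, seed = seed),
            class = "choice_dataset")
}

#' @export
print.choice_dataset <- function(x, ...) {
  cat("Choice dataset:", nrow(x$fish), "fish,", nrow(x$trials), "trials,",
      length(x$levels), "stimulus levels;",
      sum(is.na(x$trials$choice)), "no-choice trials\n")
  invisible(x)
}

#' Simulate a binary chirality-choice dataset
#'
#' Each fish participates in a single two-choice task between a right-coiled
#' (the naturally occurring chirality) and a left-coiled shell replica. A
#' fish makes a choice with probability `1 - p_nochoice` for its sex and, if
#' it chooses, picks the right-coiled option with probability `p_right`.
#' Defaults are calibrated to the observed rates of a chirality experiment
#' in which 16 of 20 choosing females and 12 of 14 choosing males took the
#' right-coiled replica, with males declining to choose in 6 of 20 trials.
#'
#' @param n_females,n_males fish per sex.
#' @param p_right_f,p_right_m probability of choosing the right-coiled shell
#'   given a choice is made.
#' @param p_nochoice_f,p_nochoice_m probability of making no choice.
#' @param seed optional integer seed.
#' @return A data frame of class `chirality_dataset` with one row per sex
#'   and columns `sex`, `n_offered`, `n_chose`, `n_right`.
#' @export
generate_chirality_dataset <- function(n_females = 20, n_males = 20,
                                       p_right_f = 16 / 20,
                                       p_right_m = 12 / 14,
                                       p_nochoice_f = 0,
                                       p_nochoice_m = 6 / 20,
                                       seed = NULL) {
  n_females <- .check_count(n_females, "n_females", lower = 0L)
  n_males <- .check_count(n_males, "n_males", lower = 0L)
  .check_number(p_right_f, "p_right_f", lower = 0, upper = 1)
  .check_number(p_right_m, "p_right_m", lower = 0, upper = 1)
  .check_number(p_nochoice_f, "p_nochoice_f", lower = 0, upper = 1)
  .check_number(p_nochoice_m, "p_nochoice_m", lower = 0, upper = 1)
  .maybe_seed(seed)
  draw <- function(n, p_no, p_r) {
    chose <- rbinom(1, n, 1 - p_no)
    right <- rbinom(1, chose, p_r)
    c(n_offered = n, n_chose = chose, n_right = right)
  }
  f <- draw(n_females, p_nochoice_f, p_right_f)
  m <- draw(n_males, p_nochoice_m, p_right_m)
  out <- data.frame(sex = c("female", "male"),
                    rbind(f, m), row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "seed") <- seed
  class(out) <- c("chirality_dataset", "data.frame")
  out
}

#' Default latent preferences per choice task
#'
#' The generator defaults used by [run_pipeline()]: strong open-ended
#' preferences for overall size and intactness, an intermediate open-ended
#' preference for shell length, and a weak, broad preference for aperture
#' width — mirroring the ordering of preference strength and tolerance
#' reported across these tasks in shelter-choice experiments. Each has a 10%
#' no-choice rate.
#'
#' @return Named list of [latent_preference()] objects.
#' @export
default_task_preferences <- function() {
  list(
    size       = latent_preference(mu = 3, omega = 2,   beta = 3,   p_nochoice = 0.1),
    length     = latent_preference(mu = 3, omega = 2,   beta = 2,   p_nochoice = 0.1),
    aperture   = latent_preference(mu = 2, omega = 3,   beta = 1,   p_nochoice = 0.1),
    intactness = latent_preference(mu = 3, omega = 1.5, beta = 3.5, p_nochoice = 0.1)
  )
}
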