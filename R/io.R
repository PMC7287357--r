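# CSV readers/writers for the pipeline's tabular artifacts. Schemas:
#   shells: shell_id,length_mm,width_mm,aperture_mm
#   trials: fish_id,sex,body_size_mm,task,trial_index,choice_level
#           (choice_level empty = no choice)
#   traits: fish_id,task,sex,body_size_mm,n_choices,peak,strength,
#           tolerance,peak_height,included
#   null:   replicate,peak,strength,tolerance

#' Write / read a shell population as CSV
#'
#' @param pop a [generate_shell_population()] result.
#' @param path output CSV path.
#' @return `path` (write) or a `shell_population` (read), invisibly for
#'   write.
#' @export
write_shells_csv <- function(pop, path) {
  write.csv(as.data.frame(pop)[, c("shell_id", "length_mm", "width_mm",
                                   "aperture_mm")],
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_shells_csv
#' @export
read_shells_csv <- function(path) {
  pop <- read.csv(path)
  class(pop) <- c("shell_population", "data.frame")
  pop
}

#' Write / read choice trials as CSV
#'
#' One row per trial, fish metadata repeated; a no-choice trial has an empty
#' `choice_level` field.
#'
#' @param dataset a `choice_dataset`.
#' @param path CSV path.
#' @return `path` invisibly (write); a `choice_dataset` (read).
#' @export
write_trials_csv <- function(dataset, path) {
  m <- merge(dataset$trials, dataset$fish, by = "fish_id", sort = FALSE)
  out <- m[order(m$fish_id, m$trial_index),
           c("fish_id", "sex", "body_size_mm", "task", "trial_index",
             "choice")]
  names(out)[names(out) == "choice"] <- "choice_level"
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trials_csv
#' @param levels stimulus levels of the design (not recoverable from the
#'   CSV; default `-3:3`).
#' @export
read_trials_csv <- function(path, levels = -3:3) {
  d <- read.csv(path, na.strings = "")
  fish <- unique(d[, c("fish_id", "sex", "body_size_mm", "task")])
  rownames(fish) <- NULL
  trials <- d[, c("fish_id", "trial_index", "choice_level")]
  names(trials)[3] <- "choice"
  structure(list(fish = fish, trials = trials, levels = levels, seed = NULL),
            class = "choice_dataset")
}

#' Write a per-fish trait table as CSV
#'
#' @param traits a [fit_cohort()] result.
#' @param path CSV path.
#' @export
write_traits_csv <- function(traits, path) {
  cols <- c("fish_id", "task", "sex", "body_size_mm", "n_choices",
            "peak", "strength", "tolerance", "peak_height", "included")
  write.csv(traits[, intersect(cols, names(traits))], path,
            row.names = FALSE, na = "")
  invisible(path)
}

#' Write a null distribution as CSV plus JSON summary
#'
#' @param null a [simulate_random_traits()] result.
#' @param csv_path,json_path output paths; either may be `NULL` to skip.
#' @export
write_null_csv <- function(null, csv_path, json_path = NULL) {
  if (!is.null(csv_path))
    write.csv(null[, c("replicate", "peak", "strength", "tolerance")],
              csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    summ <- lapply(c(peak = "peak", strength = "strength",
                     tolerance = "tolerance"), function(tr) {
      v <- null[[tr]]
      list(mean = mean(v), sd = sd(v),
           quantiles = as.list(setNames(
             quantile(v, c(0.025, 0.25, 0.5, 0.75, 0.975)),
             c("q2.5", "q25", "q50", "q75", "q97.5"))))
    })
    jsonlite::write_json(
      list(n_reps = attr(null, "n_reps"), n_choices = attr(null, "n_choices"),
           k = attr(null, "k"), seed = attr(null, "seed"), traits = summ),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(csv_path)
}
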