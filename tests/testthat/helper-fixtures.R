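# shared fixture builders (all data generated in code)

cc7 <- function(...) choice_counts(-3:3, c(...))

# random count vectors from n choices among 7 levels, for property loops
random_counts <- function(n_choices = 4) {
  tabulate(sample.int(7, n_choices, replace = TRUE), nbins = 7)
}

# minimal group table accepted by fit_group_model: one trait column filled
# with arbitrary response values, groups in 'task'
group_table <- function(values, groups, body = NULL, reference = NULL) {
  lev <- unique(as.character(groups))
  if (!is.null(reference)) lev <- c(reference, setdiff(lev, reference))
  data.frame(
    fish_id = sprintf("f%03d", seq_along(values)),
    task = factor(as.character(groups), levels = lev),
    sex = NA_character_,
    body_size_centred = if (is.null(body)) 0 else body - mean(body),
    peak = values, strength = values, tolerance = values
  )
}
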