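#' Default pipeline configuration
#'
#' Builds the configuration list driving [run_pipeline()]. Every stochastic
#' stage derives its own seed from the single master `seed`, so one integer
#' reproduces the whole run. The defaults are the study conditions the
#' synthetic generator emulates: a 113-shell wild population, four choice
#' tasks with 10 males and 10 females each and 4 trials per fish at a 10%
#' no-choice rate, a 1000-replicate random-choice null of 4 choices among 7
#' options, broad tolerance at half peak height, and chirality groups of 20
#' fish per sex.
#'
#' @param seed master integer seed (default 1).
#' @param ... overrides for any top-level config entry.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = as.integer(seed),
    shells = list(n = 113, mean_length = 43.2, sd_length = 5.8,
                  mean_width = 32.3, mean_aperture = 15.0,
                  isometry_noise = 0.01),
    choices = list(n_males = 10, n_females = 10, trials_per_fish = 4,
                   levels = -3:3),
    task_preferences = lapply(default_task_preferences(), unclass),
    fitting = list(smoothing = "common", tolerance_at = 0.5,
                   tolerance_definition = "broad", min_choices = 3),
    null = list(n_reps = 1000, n_choices = 4, k = 7),
    contrasts = list(n_mc = 1e5),
    models = list(transform = list(peak = "identity", strength = "identity",
                                   tolerance = "identity"),
                  heteroscedasticity_alpha = 0.05),
    chirality = list(n_females = 20, n_males = 20, p_right_f = 16 / 20,
                     p_right_m = 12 / 14, p_nochoice_f = 0,
                     p_nochoice_m = 6 / 20)
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(cfg[[nm]]) && is.list(dots[[nm]]))
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    else cfg[[nm]] <- dots[[nm]]
  }
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Read / write a pipeline configuration (YAML or JSON)
#'
#' Configurations round-trip losslessly: `read_config(write_config(cfg, f))`
#' reproduces `cfg`.
#'
#' @param cfg a [pipeline_config()].
#' @param path file path ending in `.yaml`, `.yml` or `.json`.
#' @return `path` invisibly (write); a `pipeline_config` (read).
#' @export
write_config <- function(cfg, path) {
  plain <- rapply(unclass(cfg), identity, how = "replace")
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(plain, path)
  else jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA,
                            pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- pipeline_config(seed = raw$seed)
  for (nm in setdiff(names(raw), "seed")) {
    if (is.list(cfg[[nm]]) && is.list(raw[[nm]]))
      cfg[[nm]][names(raw[[nm]])] <- raw[[nm]]
    else cfg[[nm]] <- raw[[nm]]
  }
  cfg
}

# Brown-Forsythe (median-based Levene) test p-value for heteroscedasticity
.levene_p <- function(y, g) {
  z <- abs(y - ave(y, g, FUN = median))
  anova(lm(z ~ g))[1, "Pr(>F)"]
}

#' Run the full preference-function pipeline
#'
#' Executes the whole analysis chain on synthetic data: (1) generate the
#' wild shell population and its morphometric summaries; (2) simulate the
#' four choice tasks; (3) fit per-fish preference curves and extract
#' traits; (4) simulate the random-choice null; (5) fit per-trait group
#' models (per-group variance when a Brown-Forsythe test flags
#' heteroscedasticity) and compute Dunnett-vs-random and all-pairs
#' contrasts plus bootstrap comparisons; (6) simulate and model the binary
#' chirality task. All artifacts are written under `out_dir` as CSV/JSON
#' together with a manifest listing every file with its MD5 checksum and
#' the seeds used.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing); `NULL` runs the
#'   pipeline without writing files.
#' @param quiet suppress stage messages.
#' @return A list of class `pipeline_result` with elements `shells`,
#'   `choice_data`, `traits`, `null`, `models`, `contrasts`,
#'   `empirical`, `chirality`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  files <- character()
  emit <- function(writer, obj, fname) {
    if (is.null(out_dir)) return(invisible(NULL))
    path <- file.path(out_dir, fname)
    writer(obj, path)
    files[[length(files) + 1L]] <<- path
    files <<- files
    invisible(path)
  }
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  seed <- config$seed

  # 1. shells ---------------------------------------------------------------
  shells <- stage("shells", do.call(generate_shell_population,
    c(config$shells, list(seed = .derive_seed(seed, 1)))))
  say("shells: ", nrow(shells), " simulated")
  emit(write_shells_csv, shells, "shells.csv")
  shell_summary <- summarize_population(shells)
  isometry <- test_isometry(shells)
  pc1 <- pca_variance_explained(shells)
  emit(function(o, p) write.csv(o, p, row.names = FALSE), shell_summary,
       "shell_summary.csv")
  emit(function(o, p) write.csv(o, p, row.names = FALSE), isometry,
       "isometry.csv")

  # 2. choice tasks ----------------------------------------------------------
  tasks <- names(config$task_preferences)
  choice_data <- stage("choices", {
    out <- list()
    for (i in seq_along(tasks)) {
      pr <- do.call(latent_preference, config$task_preferences[[i]])
      out[[tasks[i]]] <- generate_choice_dataset(
        task = tasks[i],
        n_males = config$choices$n_males,
        n_females = config$choices$n_females,
        trials_per_fish = config$choices$trials_per_fish,
        pref = pr, levels = config$choices$levels,
        seed = .derive_seed(seed, 10 + i))
    }
    out
  })
  n_trials <- sum(vapply(choice_data, function(d) nrow(d$trials), 1L))
  say("choices: ", length(tasks), " tasks, ", n_trials, " trials")
  for (t in tasks)
    emit(write_trials_csv, choice_data[[t]], paste0("trials_", t, ".csv"))

  # 3. per-fish preference functions ----------------------------------------
  traits <- stage("fit", do.call(rbind, lapply(choice_data, fit_cohort,
    min_choices = config$fitting$min_choices,
    at = config$fitting$tolerance_at,
    definition = config$fitting$tolerance_definition,
    smoothing = config$fitting$smoothing)))
  rownames(traits) <- NULL
  say("fit: ", sum(traits$included), "/", nrow(traits), " fish included")
  emit(write_traits_csv, traits, "traits.csv")

  # 4. random-choice null -----------------------------------------------------
  null <- stage("null", simulate_random_traits(
    n_reps = config$null$n_reps, n_choices = config$null$n_choices,
    k = config$null$k, seed = .derive_seed(seed, 20),
    at = config$fitting$tolerance_at,
    definition = config$fitting$tolerance_definition))
  say("null: ", attr(null, "n_reps"), " replicates")
  if (!is.null(out_dir)) {
    write_null_csv(null, file.path(out_dir, "null_traits.csv"),
                   file.path(out_dir, "null_summary.json"))
    files <- c(files, file.path(out_dir, "null_traits.csv"),
               file.path(out_dir, "null_summary.json"))
  }

  # 5. group models and contrasts --------------------------------------------
  tt <- build_trait_table(traits, null = null)
  models <- list(); contrasts <- list(); empirical <- list()
  stage("compare", for (tr in c("peak", "strength", "tolerance")) {
    transform <- config$models$transform[[tr]]
    lev_p <- .levene_p(if (transform == "ln") log(tt[[tr]]) else tt[[tr]],
                       tt$task)
    variance <- if (is.finite(lev_p) &&
                    lev_p < config$models$heteroscedasticity_alpha)
      "per-group" else "pooled"
    fit <- if (variance == "per-group") {
      # degenerate small groups can defeat the variance model; fall back
      tryCatch(fit_group_model(tt, trait = tr, variance = "per-group",
                               transform = transform),
               error = function(e) {
                 say("compare: per-group variance fit failed for ", tr,
                     " (", conditionMessage(e), "); using pooled variance")
                 fit_group_model(tt, trait = tr, variance = "pooled",
                                 transform = transform)
               })
    } else {
      fit_group_model(tt, trait = tr, variance = "pooled",
                      transform = transform)
    }
    models[[tr]] <- fit
    contrasts[[tr]] <- list(
      dunnett = dunnett_vs_reference(fit, n_mc = config$contrasts$n_mc,
                                     seed = .derive_seed(seed, 30)),
      allpairs = allpairs_contrasts(fit, n_mc = config$contrasts$n_mc,
                                    seed = .derive_seed(seed, 31),
                                    exclude = "RANDOM"))
    side <- if (tr == "tolerance") "less" else "greater"
    empirical[[tr]] <- lapply(setNames(tasks, tasks), function(t)
      empirical_comparison(tt[[tr]][tt$task == t], null, trait = tr,
                           side = side, seed = .derive_seed(seed, 32)))
  })
  say("compare: 3 traits x (", length(tasks), " Dunnett + ",
      length(tasks) * (length(tasks) - 1) / 2, " pairwise) contrasts")

  # 6. chirality ---------------------------------------------------------------
  chir_data <- stage("chirality", do.call(generate_chirality_dataset,
    c(config$chirality, list(seed = .derive_seed(seed, 40)))))
  chir <- stage("chirality", {
    s_right <- setNames(chir_data$n_right, chir_data$sex)
    f_right <- setNames(chir_data$n_chose - chir_data$n_right,
                        chir_data$sex)
    list(data = chir_data,
         overall = fit_binary_logit(sum(s_right), sum(f_right)),
         # sex model on the left-coiled choice (the rarer outcome)
         sex = fit_binary_logit(f_right, s_right, predictor = "sex"))
  })
  say("chirality: ", sum(chir_data$n_chose), " choices, ",
      sum(chir_data$n_right), " right-coiled")

  # 7. results + manifest -------------------------------------------------------
  result_json <- list(
    seed = seed,
    shells = list(summary = shell_summary, isometry = isometry,
                  pc1_fraction = pc1),
    inclusion = list(n_fish = nrow(traits), n_included = sum(traits$included),
                     n_trials = n_trials,
                     nochoice_rate = mean(is.na(do.call(rbind,
                       lapply(choice_data, `[[`, "trials"))$choice))),
    models = lapply(models, function(m) list(
      trait = m$trait, variance = m$variance, transform = m$transform,
      loglik = m$loglik, coefficients = m$coefficients)),
    contrasts = lapply(contrasts, function(cc) lapply(cc, identity)),
    chirality = list(data = chir_data,
                     overall = chir$overall$coefficients,
                     sex = chir$sex$coefficients)
  )
  if (!is.null(out_dir)) {
    rp <- file.path(out_dir, "results.json")
    jsonlite::write_json(result_json, rp, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", force = TRUE)
    files <- c(files, rp)
    manifest <- list(
      package_version = as.character(utils::packageVersion("shellprefs")),
      r_version = R.version.string,
      seed = seed,
      stage_seeds = list(shells = .derive_seed(seed, 1),
                         choices = lapply(setNames(seq_along(tasks), tasks),
                                          function(i) .derive_seed(seed, 10 + i)),
                         null = .derive_seed(seed, 20),
                         contrasts = c(.derive_seed(seed, 30),
                                       .derive_seed(seed, 31)),
                         empirical = .derive_seed(seed, 32),
                         chirality = .derive_seed(seed, 40)),
      files = lapply(setNames(files, basename(files)), function(f)
        list(md5 = unname(tools::md5sum(f)), bytes = file.size(f)))
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  structure(list(shells = shells, shell_summary = shell_summary,
                 isometry = isometry, pc1_fraction = pc1,
                 choice_data = choice_data, traits = traits, null = null,
                 trait_table = tt, models = models, contrasts = contrasts,
                 empirical = empirical, chirality = chir,
                 config = config, files = files),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("shellprefs pipeline run (seed ", x$config$seed, ")\n", sep = "")
  cat(" fish included: ", sum(x$traits$included), "/", nrow(x$traits),
      "; null reps: ", attr(x$null, "n_reps"), "\n", sep = "")
  for (tr in names(x$contrasts)) {
    cat(" Dunnett vs RANDOM, ", tr, ":\n", sep = "")
    print(x$contrasts[[tr]]$dunnett[, c("label", "estimate", "statistic",
                                        "p_adjusted")],
          row.names = FALSE, digits = 3)
  }
  invisible(x)
}
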