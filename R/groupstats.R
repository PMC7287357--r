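#' Assemble the trait table for group-level analysis
#'
#' Combines the per-fish trait table from [fit_cohort()] (included fish
#' only) with, optionally, the random-choice null replicates from
#' [simulate_random_traits()], which enter as independent rows of a
#' reference group labelled `"RANDOM"`. Body size is mean-centred over the
#' real fish so that model coefficients are interpretable at the average
#' body size; null rows carry no sex or body size.
#'
#' @param traits per-fish trait table (from [fit_cohort()], possibly several
#'   tasks row-bound together).
#' @param null optional `null_distribution` to include as the reference
#'   group.
#' @param reference_label group label for null rows (default `"RANDOM"`).
#' @return A data frame of class `trait_table` with columns `fish_id`,
#'   `task` (factor), `sex`, `body_size_centred`, `peak`, `strength`,
#'   `tolerance`.
#' @export
build_trait_table <- function(traits, null = NULL,
                              reference_label = "RANDOM") {
  stopifnot(is.data.frame(traits))
  real <- traits[traits$included %in% TRUE, , drop = FALSE]
  if (nrow(real) == 0L) stop("no included fish in 'traits'", call. = FALSE)
  grand <- mean(real$body_size_mm)
  out <- data.frame(
    fish_id = real$fish_id,
    task = as.character(real$task),
    sex = real$sex,
    body_size_centred = real$body_size_mm - grand,
    peak = real$peak, strength = real$strength, tolerance = real$tolerance,
    stringsAsFactors = FALSE
  )
  if (!is.null(null)) {
    stopifnot(inherits(null, "null_distribution"))
    nd <- data.frame(
      fish_id = sprintf("null_%04d", null$replicate),
      task = reference_label, sex = NA_character_,
      body_size_centred = NA_real_,
      peak = null$peak, strength = null$strength,
      tolerance = null$tolerance, stringsAsFactors = FALSE
    )
    out <- rbind(out, nd)
  }
  lev <- unique(out$task)
  if (reference_label %in% lev)   # reference first => baseline coding
    lev <- c(reference_label, setdiff(lev, reference_label))
  out$task <- factor(out$task, levels = lev)
  attr(out, "body_size_grand_mean") <- grand
  class(out) <- c("trait_table", "data.frame")
  out
}

.coef_table <- function(est, se, df) {
  stat <- est / se
  p <- if (is.finite(df)) 2 * pt(-abs(stat), df) else 2 * pnorm(-abs(stat))
  data.frame(term = names(est), estimate = unname(est), se = unname(se),
             statistic = unname(stat), df = df, p = unname(p),
             stringsAsFactors = FALSE)
}

#' Group linear model for a preference-function trait
#'
#' Fits a trait against choice task (and optionally mean-centred body size
#' and their interaction) by linear model, with either a pooled residual
#' variance or one residual variance per task group (a heteroscedastic
#' generalized least-squares fit via [nlme::gls()] with
#' `varIdent(~ 1 | task)`). The response may be ln-transformed. When the
#' interaction is requested it is first screened with a maximum-likelihood
#' ratio test and dropped if non-significant (joint p > `interaction_alpha`),
#' mirroring standard practice for these analyses.
#'
#' With two groups and per-group variances the squared t-statistic of the
#' group term equals the Welch two-sample statistic (REML estimation, the
#' default, makes this exact).
#'
#' @param table a [build_trait_table()] result.
#' @param trait `"peak"`, `"strength"` or `"tolerance"`.
#' @param predictors character subset of
#'   `c("task", "body_size", "interaction")`; `"task"` is always included.
#'   Rows with missing body size (e.g. RANDOM rows) are dropped when body
#'   size is a predictor.
#' @param variance `"pooled"` or `"per-group"`.
#' @param transform `"identity"` or `"ln"` (requires positive trait values).
#' @param method `"REML"` (default; standard errors and the Welch identity)
#'   or `"ML"` (required for likelihood-ratio tests).
#' @param interaction_alpha screening level for dropping the interaction.
#' @return An object of class `group_model_fit`: list with `coefficients`
#'   (term, estimate, se, statistic, df, p), `loglik`, `sigma` (per group),
#'   `vcov`, the fitted `model`, and the fit options.
#' @export
fit_group_model <- function(table, trait = c("peak", "strength", "tolerance"),
                            predictors = "task",
                            variance = c("pooled", "per-group"),
                            transform = c("identity", "ln"),
                            method = c("REML", "ML"),
                            interaction_alpha = 0.05) {
  trait <- match.arg(trait)
  variance <- match.arg(variance)
  transform <- match.arg(transform)
  method <- match.arg(method)
  predictors <- unique(c("task", predictors))
  bad <- setdiff(predictors, c("task", "body_size", "interaction"))
  if (length(bad))
    stop("unknown predictors: ", paste(bad, collapse = ", "), call. = FALSE)

  dat <- data.frame(y = table[[trait]], task = table$task,
                    body_size_centred = table$body_size_centred)
  use_body <- any(c("body_size", "interaction") %in% predictors)
  keep <- is.finite(dat$y) & !is.na(dat$task)
  if (use_body) keep <- keep & is.finite(dat$body_size_centred)
  dat <- droplevels(dat[keep, , drop = FALSE])
  tab <- table(dat$task)
  if (length(tab) < 2L || any(tab < 2L))
    stop("need >= 2 groups with >= 2 observations each", call. = FALSE)
  if (transform == "ln") {
    if (any(dat$y <= 0))
      stop("ln transform requires strictly positive trait values",
           call. = FALSE)
    dat$y <- log(dat$y)
  }

  rhs <- "task"
  if ("body_size" %in% predictors || "interaction" %in% predictors)
    rhs <- c(rhs, "body_size_centred")
  want_int <- "interaction" %in% predictors
  form_of <- function(with_int)
    stats::as.formula(paste("y ~", paste(c(rhs,
      if (with_int) "task:body_size_centred"), collapse = " + ")))

  mm <- model.matrix(form_of(want_int), dat)
  if (qr(mm)$rank < ncol(mm)) {
    qq <- qr(mm)
    dropped <- colnames(mm)[qq$pivot[seq.int(qq$rank + 1L, ncol(mm))]]
    stop("singular design; collinear terms: ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }

  fit_one <- function(form, meth) {
    if (variance == "pooled") {
      m <- lm(form, data = dat)
      ll <- as.numeric(logLik(m, REML = (meth == "REML")))
      list(model = m, loglik = ll,
           n_par = length(coef(m)) + 1L,
           coefs = coef(m), V = vcov(m),
           df = nrow(dat) - length(coef(m)),
           sigma = setNames(rep(summary(m)$sigma, nlevels(dat$task)),
                            levels(dat$task)))
    } else {
      controls <- list(nlme::glsControl(tolerance = 1e-8),
                       nlme::glsControl(),
                       nlme::glsControl(opt = "optim"))
      m <- NULL
      for (ctl in controls) {
        m <- tryCatch(nlme::gls(form, data = dat,
                                weights = nlme::varIdent(form = ~ 1 | task),
                                method = meth, control = ctl),
                      error = function(e) NULL)
        if (!is.null(m)) break
      }
      if (is.null(m)) {
        gv <- tapply(dat$y, dat$task, var)
        hint <- if (any(gv < 1e-10))
          paste0(" (group(s) with ~zero variance: ",
                 paste(names(gv)[gv < 1e-10], collapse = ", "), ")")
        else ""
        stop("per-group variance fit did not converge", hint, call. = FALSE)
      }
      ratios <- coef(m$modelStruct$varStruct, unconstrained = FALSE,
                     allCoef = TRUE)
      list(model = m, loglik = as.numeric(logLik(m)),
           n_par = length(coef(m)) + nlevels(dat$task),
           coefs = coef(m), V = vcov(m),
           df = nrow(dat) - length(coef(m)),
           sigma = m$sigma * ratios[levels(dat$task)])
    }
  }

  interaction_p <- NA_real_
  with_int <- want_int
  if (want_int) {
    full <- fit_one(form_of(TRUE), "ML")
    red <- fit_one(form_of(FALSE), "ML")
    chi2 <- max(0, 2 * (full$loglik - red$loglik))
    dfi <- full$n_par - red$n_par
    interaction_p <- pchisq(chi2, dfi, lower.tail = FALSE)
    if (interaction_p > interaction_alpha) with_int <- FALSE
  }
  form <- form_of(with_int)
  res <- fit_one(form, method)

  structure(list(
    coefficients = .coef_table(res$coefs, sqrt(diag(as.matrix(res$V))),
                               res$df),
    loglik = res$loglik, n_par = res$n_par, df_resid = res$df,
    sigma = res$sigma, vcov = as.matrix(res$V), model = res$model,
    trait = trait, transform = transform, variance = variance,
    method = method, formula = form, data = dat, n = nrow(dat),
    interaction_kept = with_int, interaction_p = interaction_p,
    task_levels = levels(dat$task)
  ), class = "group_model_fit")
}

#' @export
print.group_model_fit <- function(x, ...) {
  cat(sprintf("Group model for %s (%s variance, %s response, %s)\n",
              x$trait, x$variance,
              if (x$transform == "ln") "ln" else "identity", x$method))
  print(x$coefficients, row.names = FALSE, digits = 4)
  cat("logLik:", round(x$loglik, 3), " n:", x$n, "\n")
  invisible(x)
}

# contrast vector (in coefficient space) for group a minus group b,
# assuming treatment coding of 'task' with the first level as baseline
.contrast_vector <- function(fit, a, b) {
  cn <- rownames(fit$vcov)
  v <- setNames(numeric(length(cn)), cn)
  ca <- paste0("task", a); cb <- paste0("task", b)
  if (ca %in% cn) v[ca] <- 1
  else if (a != fit$task_levels[1]) stop("unknown group: ", a, call. = FALSE)
  if (cb %in% cn) v[cb] <- v[cb] - 1
  else if (b != fit$task_levels[1]) stop("unknown group: ", b, call. = FALSE)
  v
}

# single-step max-|t| multiplicity adjustment by Monte Carlo over the joint
# distribution of the contrast statistics
.mc_adjust <- function(fit, L, labels, n_mc, seed, adjustment) {
  n_mc <- .check_count(n_mc, "n_mc", lower = 1000L)
  .maybe_seed(seed)
  est <- as.numeric(L %*% fit$coefficients$estimate[
    match(rownames(fit$vcov), fit$coefficients$term)])
  V <- L %*% fit$vcov %*% t(L)
  se <- sqrt(diag(V))
  tstat <- est / se
  R <- stats::cov2cor(V)
  m <- nrow(L)
  df <- fit$df_resid
  p_raw <- if (is.finite(df)) 2 * pt(-abs(tstat), df)
           else 2 * pnorm(-abs(tstat))
  # draws of the max absolute statistic under the joint null
  ch <- chol(R + diag(1e-12, m))
  Z <- matrix(rnorm(n_mc * m), n_mc, m) %*% ch
  if (is.finite(df))
    Z <- Z / sqrt(rchisq(n_mc, df) / df)   # multivariate t scaling
  maxabs <- apply(abs(Z), 1L, max)
  p_adj <- vapply(abs(tstat), function(t0) mean(maxabs >= t0), numeric(1))
  data.frame(label = labels, estimate = est, se = se, statistic = tstat,
             p_raw = p_raw, p_adjusted = pmax(p_adj, p_raw),
             adjustment = adjustment, stringsAsFactors = FALSE)
}

#' Dunnett-type contrasts of every task against a reference group
#'
#' Many-to-one comparisons of each choice task back to a single reference
#' group (by default the `"RANDOM"` random-choice group), with single-step
#' family-wise error control. The adjustment is computed by Monte-Carlo
#' sampling of the contrasts' joint statistic (correlation taken from the
#' model's coefficient covariance; scaled to the multivariate t when the
#' residual degrees of freedom are finite): the adjusted p-value of contrast
#' i is the probability that the maximum absolute statistic across the
#' family exceeds `|t_i|`. Adjusted p-values are never below raw ones.
#'
#' @param fit a [fit_group_model()] result whose task factor contains the
#'   reference level.
#' @param reference reference group label (default `"RANDOM"`).
#' @param n_mc Monte-Carlo draws (>= 1000; default 1e5).
#' @param seed optional integer seed.
#' @return Data frame with columns `label`, `estimate`, `se`, `statistic`,
#'   `p_raw`, `p_adjusted`, `adjustment`.
#' @export
dunnett_vs_reference <- function(fit, reference = "RANDOM", n_mc = 1e5,
                                 seed = NULL) {
  stopifnot(inherits(fit, "group_model_fit"))
  if (!reference %in% fit$task_levels)
    stop("reference level '", reference, "' not in the fitted groups",
         call. = FALSE)
  others <- setdiff(fit$task_levels, reference)
  L <- t(vapply(others, function(g) .contrast_vector(fit, g, reference),
                numeric(nrow(fit$vcov))))
  .mc_adjust(fit, L, paste(others, "-", reference), n_mc, seed, "dunnett-mc")
}

#' All pairwise contrasts between task groups
#'
#' Tukey-style all-pairs comparisons among the fitted task groups with the
#' same single-step Monte-Carlo max-|t| adjustment as
#' [dunnett_vs_reference()].
#'
#' @inheritParams dunnett_vs_reference
#' @param exclude group labels to leave out (e.g. `"RANDOM"` when only the
#'   real tasks should be compared); default none.
#' @return Data frame as in [dunnett_vs_reference()], one row per pair.
#' @export
allpairs_contrasts <- function(fit, n_mc = 1e5, seed = NULL,
                               exclude = character()) {
  stopifnot(inherits(fit, "group_model_fit"))
  lev <- setdiff(fit$task_levels, exclude)
  if (length(lev) < 2L) stop("need >= 2 groups to contrast", call. = FALSE)
  pairs <- utils::combn(lev, 2L)
  L <- t(apply(pairs, 2L, function(p) .contrast_vector(fit, p[2], p[1])))
  .mc_adjust(fit, L, paste(pairs[2, ], "-", pairs[1, ]), n_mc, seed,
             "allpairs-mc")
}

#' Likelihood-ratio test between nested group models
#'
#' @param full,reduced [fit_group_model()] results fitted with
#'   `method = "ML"` on the same data and transform, the reduced model
#'   nested in the full one.
#' @return List with `chi2`, `df` and `p`.
#' @export
lrt <- function(full, reduced) {
  stopifnot(inherits(full, "group_model_fit"),
            inherits(reduced, "group_model_fit"))
  if (full$method != "ML" || reduced$method != "ML")
    stop("likelihood-ratio tests require method = 'ML' fits", call. = FALSE)
  if (full$trait != reduced$trait || full$transform != reduced$transform ||
      full$n != reduced$n)
    stop("models must be fitted to the same transformed data", call. = FALSE)
  df <- full$n_par - reduced$n_par
  if (df < 0)
    stop("'reduced' has more parameters than 'full'; not nested",
         call. = FALSE)
  red_terms <- reduced$coefficients$term
  if (!all(red_terms %in% full$coefficients$term) &&
      reduced$variance == full$variance)
    stop("'reduced' is not nested in 'full'", call. = FALSE)
  chi2 <- 2 * (full$loglik - reduced$loglik)
  if (chi2 < -1e-6)
    stop("'full' has lower likelihood than 'reduced'; models not nested",
         call. = FALSE)
  chi2 <- max(0, chi2)
  list(chi2 = chi2, df = df,
       p = if (df == 0) 1 else pchisq(chi2, df, lower.tail = FALSE))
}

#' Variance inflation factors
#'
#' Collinearity diagnostic for a set of predictors: each predictor is
#' regressed on all the others and `VIF = 1 / (1 - R^2)`. Factors are coded
#' numerically (two-level factors as 0/1 dummies). Values above ~5 indicate
#' problematic multicollinearity, e.g. between sex and body size when the
#' sexes differ strongly in size. Perfect collinearity yields `Inf`.
#'
#' @param table a data frame (e.g. a [build_trait_table()] result with a
#'   `sex` column, or any predictor table).
#' @param predictors character vector of >= 2 column names.
#' @return Named numeric vector of VIFs (all >= 1).
#' @export
vif <- function(table, predictors) {
  if (length(predictors) < 2L)
    stop("need at least 2 predictors", call. = FALSE)
  cols <- lapply(predictors, function(p) {
    x <- table[[p]]
    if (is.null(x)) stop("missing predictor column: ", p, call. = FALSE)
    if (is.character(x) || is.factor(x)) as.numeric(factor(x)) else x
  })
  X <- do.call(cbind, cols)
  colnames(X) <- predictors
  X <- X[complete.cases(X), , drop = FALSE]
  out <- vapply(seq_along(predictors), function(j) {
    y <- X[, j]
    others <- X[, -j, drop = FALSE]
    if (var(y) == 0) return(1)
    res <- lm.fit(cbind(1, others), y)$residuals
    r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  setNames(out, predictors)
}
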