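#' Plot per-task preference-function summaries
#'
#' One panel per choice task showing the group-level preference curve (a
#' spline fitted to the pooled choice counts of all included fish), the
#' per-fish choice counts as jittered points, and — when a wild shell
#' population is supplied — a scaled density underlay of the corresponding
#' natural attribute distribution on the standardized stimulus axis.
#' Purely presentational; no numeric contract.
#'
#' @param result a [run_pipeline()] result, or a list with `choice_data`,
#'   `traits` and optionally `shells`.
#' @param out_dir directory for the PNG files (created if missing).
#' @param wild optional `shell_population` used for the density underlays
#'   (defaults to `result$shells`).
#' @return Invisibly, the paths of the files written (one per task).
#' @export
plot_preference_summary <- function(result, out_dir,
                                    wild = result$shells) {
  if (is.null(result$choice_data) || is.null(result$traits))
    stop("missing fitted inputs: need 'choice_data' and 'traits'",
         call. = FALSE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  # map a task to the wild attribute whose density it manipulates
  attr_of <- c(length = "length_mm", aperture = "aperture_mm",
               size = "pc1", intactness = NA)
  paths <- character()
  for (task in names(result$choice_data)) {
    d <- result$choice_data[[task]]
    ids <- result$traits$fish_id[result$traits$included &
                                   result$traits$task == task]
    trials <- d$trials[d$trials$fish_id %in% ids & !is.na(d$trials$choice), ]
    if (nrow(trials) == 0L) {
      warning("no included choices for task '", task, "'; panel skipped")
      next
    }
    counts <- tabulate(trials$choice, nbins = length(d$levels))
    crv <- fit_preference_curve(choice_counts(d$levels, counts))
    per_fish <- table(trials$fish_id, factor(trials$choice,
                                             levels = seq_along(d$levels)))

    path <- file.path(out_dir, paste0("preference_", task, ".png"))
    grDevices::png(path, width = 900, height = 650, res = 110)
    graphics::par(mar = c(4.2, 4.2, 2.5, 1))
    ymax <- max(per_fish, crv$height / max(sum(counts) / 28, 1)) * 1.15
    graphics::plot(NA, xlim = range(d$levels), ylim = c(0, ymax),
                   xlab = "stimulus level (population s.d.)",
                   ylab = "choices per fish",
                   main = paste0(task, " choice task"))
    a <- attr_of[[task]]
    if (!is.null(wild) && !is.na(a)) {
      x_std <- if (identical(a, "pc1")) {
        m <- scale(as.matrix(wild[, c("length_mm", "width_mm",
                                      "aperture_mm")]))
        pr <- stats::prcomp(m, center = FALSE, scale. = FALSE)
        scores <- pr$x[, 1] * sign(pr$rotation[1, 1])
        scores / sd(scores)
      } else {
        (wild[[a]] - mean(wild[[a]])) / sd(wild[[a]])
      }
      dn <- density(x_std)
      graphics::polygon(dn$x, dn$y / max(dn$y) * ymax * 0.5,
                        col = "grey85", border = NA)
    }
    for (i in seq_len(nrow(per_fish)))
      graphics::points(jitter(d$levels, amount = 0.08),
                       as.numeric(per_fish[i, ]),
                       pch = 16, col = grDevices::adjustcolor("grey35", 0.5),
                       cex = 0.7)
    scale_fac <- max(per_fish) / max(crv$height, 1e-12)
    graphics::lines(crv$grid, crv$height * scale_fac,
                    lwd = 2, col = "steelblue")
    grDevices::dev.off()
    paths <- c(paths, path)
  }
  invisible(paths)
}
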