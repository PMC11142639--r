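#' Simulate a two-group TZP experiment with known truth
#'
#' Draws `n_per_group` granulosa cells per group.  Control cells follow the
#' base [goc_spec()]; treated cells follow the same spec with the mean TZP
#' count per cell, mean TZP length and mean cell volume scaled by
#' `(1 + effect)`.  Per cell, the TZP count is Poisson around the group
#' mean, cell volume is lognormal with coefficient of variation
#' `cell_volume_cv`, and each TZP is an explicit filament polyline built by
#' the 3D filament generator on a standard cell geometry, so the group
#' contrast can be pushed through [measure_filaments()],
#' [aggregate_per_cell()] and [t_test_report()] exactly as measured data
#' would be.  Per-cell seeds are derived deterministically from the master
#' seed.
#'
#' @param geff A [group_effect_spec()].
#' @param cell_radius Semi-axis of the standard spherical cell body (um).
#' @return An object of class `group_experiment`: per group a list with
#'   `filaments` (flat list, `parent_cell` set), `cell_table` (`cell`,
#'   `volume`, `true_n_tzp`), and shared `oocyte` ([oocyte_model()]) and
#'   `truth` (the generating means per group).
#' @export
simulate_group_experiment <- function(geff, cell_radius = 4) {
  stopifnot(inherits(geff, "group_effect_spec"))
  base <- geff$base
  groups <- list(
    control = list(count_mean = base$n_tzp,
                   length_mean = base$tzp_length_mean,
                   volume_mean = geff$cell_volume_mean),
    treated = list(count_mean = base$n_tzp * (1 + geff$effect_tzp_count),
                   length_mean = base$tzp_length_mean *
                     (1 + geff$effect_tzp_length),
                   volume_mean = geff$cell_volume_mean *
                     (1 + geff$effect_cell_volume)))
  seeds <- derive_seeds(geff$seed, 2L * geff$n_per_group)
  oo <- oocyte_model(c(0, 0, 0), base$oocyte_radius, base$zona_thickness)
  sdlog <- sqrt(log(1 + geff$cell_volume_cv^2))
  out <- list()
  for (gi in seq_along(groups)) {
    g <- groups[[gi]]
    filaments <- list()
    cells <- vector("list", geff$n_per_group)
    for (ci in seq_len(geff$n_per_group)) {
      sd_i <- seeds[(gi - 1L) * geff$n_per_group + ci]
      cell <- with_seed(sd_i, {
        n_tzp <- stats::rpois(1, g$count_mean)
        vol <- stats::rlnorm(1, log(g$volume_mean) - sdlog^2 / 2, sdlog)
        phi <- stats::runif(1, 0, 2 * pi)
        elev <- stats::runif(1, -0.3, 0.3)
        u <- c(cos(phi) * cos(elev), sin(phi) * cos(elev), sin(elev))
        center <- u * (base$oocyte_radius + base$zona_thickness +
                         cell_radius + 0.5)
        fl <- vector("list", n_tzp)
        for (k in seq_len(n_tzp)) {
          away <- stats::runif(1) < base$away_fraction
          fl[[k]] <- make_tzp_filament(center, rep(cell_radius, 3),
                                       base$oocyte_radius,
                                       length_mean = g$length_mean,
                                       length_sd = base$tzp_length_sd,
                                       width = base$tzp_width_mean,
                                       tortuosity = base$tortuosity,
                                       away = away, parent_cell = ci)
        }
        list(n_tzp = n_tzp, vol = vol, fl = fl)
      })
      filaments <- c(filaments, cell$fl)
      cells[[ci]] <- data.frame(cell = ci, volume = cell$vol,
                                true_n_tzp = cell$n_tzp)
    }
    out[[names(groups)[gi]]] <- list(filaments = filaments,
                                     cell_table = do.call(rbind, cells))
  }
  structure(list(control = out$control, treated = out$treated,
                 oocyte = oo,
                 truth = list(control = groups$control,
                              treated = groups$treated,
                              effects = geff[c("effect_tzp_count",
                                               "effect_tzp_length",
                                               "effect_cell_volume")],
                              n_per_group = geff$n_per_group,
                              seed = geff$seed)),
            class = "group_experiment")
}

#' @export
print.group_experiment <- function(x, ...) {
  cat(sprintf("group_experiment: %d cells per group; imposed effects count %+.0f%%, length %+.0f%%, volume %+.0f%%\n",
              x$truth$n_per_group,
              100 * x$truth$effects$effect_tzp_count,
              100 * x$truth$effects$effect_tzp_length,
              100 * x$truth$effects$effect_cell_volume))
  invisible(x)
}

#' Measure and test a simulated group experiment
#'
#' Runs the measurement pipeline on both groups: per-filament metrics,
#' per-cell aggregation, group summaries, percent changes relative to the
#' control mean and two-sample t-tests, for TZPs per cell, TZP length and
#' cell volume.
#'
#' @param sim A `group_experiment` from [simulate_group_experiment()].
#' @param variant t-test variant, see [t_test_report()].
#' @return A list with per-endpoint `effect_report`s (`tzp_count`,
#'   `tzp_length`, `cell_volume`), the per-cell tables and group
#'   summaries.
#' @export
group_experiment_stats <- function(sim, variant = "student") {
  stopifnot(inherits(sim, "group_experiment"))
  per_group <- lapply(sim[c("control", "treated")], function(g) {
    metrics <- measure_filaments(g$filaments, sim$oocyte)
    agg <- aggregate_per_cell(metrics, cells = g$cell_table$cell)
    list(metrics = metrics, per_cell = agg,
         counts = agg$n_tzp, lengths = metrics$length,
         volumes = g$cell_table$volume)
  })
  ctrl <- per_group$control; trt <- per_group$treated
  list(
    tzp_count = t_test_report(ctrl$counts, trt$counts, variant = variant),
    tzp_length = t_test_report(ctrl$lengths, trt$lengths, variant = variant),
    cell_volume = t_test_report(ctrl$volumes, trt$volumes,
                                variant = variant),
    summaries = rbind(
      summarize_group(ctrl$counts, "control TZPs/cell"),
      summarize_group(trt$counts, "treated TZPs/cell"),
      summarize_group(ctrl$lengths, "control TZP length (um)"),
      summarize_group(trt$lengths, "treated TZP length (um)"),
      summarize_group(ctrl$volumes, "control cell volume (um^3)"),
      summarize_group(trt$volumes, "treated cell volume (um^3)")),
    per_cell = list(control = ctrl$per_cell, treated = trt$per_cell)
  )
}
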