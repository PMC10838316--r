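#' Default run configuration
#'
#' One nested list drives a whole study. Defaults mirror the standard
#' bi-hemispheric protocol: 2 mA through 5 x 5 cm pads, conventional
#' anode over the affected-side M1 (C3/C4), candidate grids with
#' 11.11 mm spacing, a 2 mm gray-matter ROI at the hand-knob target, and
#' the 8/11/2 cortical/subcortical/brainstem class split of a 21-subject
#' cohort.
#'
#' @param ... overrides merged into the defaults (nested lists merge
#'   recursively).
#' @return nested configuration list.
#' @export
default_run_config <- function(...) {
  cfg <- list(
    cohort = list(
      n = 21L,
      class_counts = list(cortical = 8L, subcortical = 11L, brainstem = 2L),
      effect_params = list(intercept = 40, k = 1.2, b = 10, sd = 5)
    ),
    mesh = list(
      layer_radii = c(92, 86, 80, 78, 70),
      mesh_size = 9
    ),
    conductivities = as.list(conductivity_map()),
    solver = list(tol = 1e-9, method = "direct"),
    electrodes = list(current = 2, size = c(50, 50)),
    grid = list(extent = 44.44, spacing = 11.11),
    optimizer = list(min_separation = 70, max_iterations = 10L,
                     rel_tol = 1e-4),
    roi = list(radius = 2),
    seed = 1L
  )
  over <- list(...)
  if (length(over)) cfg <- utils::modifyList(cfg, over)
  cfg
}

#' Load a run configuration from a YAML file
#'
#' Values present in the file override the defaults of
#' [default_run_config()]; everything else keeps its default. The merged
#' configuration is validated before any computation.
#'
#' @param path YAML file.
#' @return validated configuration list.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config error: file not found: ", path)
  # keep YAML-1.1 boolean-like scalars (n, y, on, off, ...) as literal
  # strings so the cohort-size key `n` survives as a key name
  keep <- function(x) x
  user <- yaml::read_yaml(path, handlers = list("bool#yes" = keep,
                                                "bool#no" = keep))
  cfg <- utils::modifyList(default_run_config(), user)
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  needed <- c("cohort", "mesh", "conductivities", "solver", "electrodes",
              "grid", "optimizer", "roi", "seed")
  miss <- setdiff(needed, names(cfg))
  if (length(miss)) {
    stop("config error: missing sections: ", paste(miss, collapse = ", "))
  }
  if (sum(unlist(cfg$cohort$class_counts)) != cfg$cohort$n) {
    stop("config error: class counts must sum to the cohort size")
  }
  if (any(diff(unlist(cfg$mesh$layer_radii)) >= 0)) {
    stop("config error: layer radii must be strictly decreasing")
  }
  if (cfg$roi$radius <= 0) stop("config error: ROI radius must be positive")
  invisible(cfg)
}

#' Simulate a single montage on a head model
#'
#' Assembles (or reuses) the FEM system, applies the montage currents,
#' solves for the potential and summarizes the field in the target ROI.
#'
#' @param head a `head_model`.
#' @param montage a `montage`.
#' @param roi a [roi_spec()]; defaults to a 2 mm sphere at the head's
#'   stored target.
#' @param system,factor optional precomputed system/factorization.
#' @param tol solver tolerance; @param method `"cg"` or `"direct"`.
#' @return list with `solution` (`field_solution`) and `summary`
#'   (`roi_field_summary`).
#' @export
simulate_tdcs <- function(head, montage, roi = NULL, system = NULL,
                          factor = NULL, tol = 1e-9,
                          method = c("cg", "direct")) {
  if (is.null(roi)) roi <- roi_spec(head$target)
  if (is.null(system)) system <- assemble_system(head)
  system <- apply_montage_currents(system, montage)
  sol <- solve_potential(system, tol = tol, factor = factor,
                         method = match.arg(method))
  list(solution = sol, summary = roi_summary(sol, head, roi))
}

# One subject's full within-subject comparison.
run_subject <- function(head, cfg) {
  system <- assemble_system(head)
  factor <- if (identical(cfg$solver$method, "direct")) {
    factorize_system(system)
  } else {
    NULL
  }
  roi <- roi_spec(head$target, radius = cfg$roi$radius)
  conv <- conventional_montage(head, current = cfg$electrodes$current,
                               size = unlist(cfg$electrodes$size))
  conv_sim <- simulate_tdcs(head, conv, roi, system = system, factor = factor,
                            tol = cfg$solver$tol, method = cfg$solver$method)
  anode_grid <- build_candidate_grid(head, conv$anode$center,
                                     extent = cfg$grid$extent,
                                     spacing = cfg$grid$spacing)
  cathode_grid <- build_candidate_grid(head, conv$cathode$center,
                                       extent = cfg$grid$extent,
                                       spacing = cfg$grid$spacing)
  opt <- optimize_montage(
    head, roi, anode_grid, cathode_grid,
    config = list(current = cfg$electrodes$current,
                  size = unlist(cfg$electrodes$size),
                  min_separation = cfg$optimizer$min_separation,
                  max_iterations = cfg$optimizer$max_iterations,
                  rel_tol = cfg$optimizer$rel_tol,
                  conventional = conv),
    system = system, factor = factor
  )
  opt_sim <- simulate_tdcs(head, opt$montage, roi, system = system,
                           factor = factor, tol = cfg$solver$tol,
                           method = cfg$solver$method)
  dist <- montage_distances(conv, opt$montage)
  tibble::tibble(
    conv_field = conv_sim$summary$mean_magnitude,
    conv_normal = conv_sim$summary$normal_component,
    opt_field = opt_sim$summary$mean_magnitude,
    opt_normal = opt_sim$summary$normal_component,
    improvement_pct = improvement_pct(conv_sim$summary$mean_magnitude,
                                      opt_sim$summary$mean_magnitude),
    dist,
    roi_n_elements = conv_sim$summary$n_elements,
    opt_iterations = opt$iterations,
    n_evaluated = opt$n_evaluated
  )
}

#' Run the full within-subject simulation study on a synthetic cohort
#'
#' For every synthetic subject: build the lesioned head model, place the
#' conventional C3/C4 montage, solve, optimize the montage on the
#' candidate grids (conventional positions always included), solve the
#' optimized montage, and record ROI field summaries, the improvement
#' percentage and montage displacement distances. Afterwards the cohort
#' is tested with the group battery: paired Wilcoxon (conventional vs
#' optimized field), Mann-Whitney (displacement D by cortical vs
#' non-cortical lesion), Spearman with 95% CI (D vs initial FMA-UE, and
#' improvement vs FMA-UE), plus KS normality screens.
#'
#' Per-subject failures are isolated: failed subjects keep their row with
#' a `status` message and the run continues.
#'
#' @param config nested configuration from [default_run_config()] /
#'   [load_run_config()].
#' @param out_dir optional directory; when given, writes `cohort.csv`,
#'   `stats.json` (JSON-lines), and `summary.txt`, each stamped with the
#'   seed and config hash.
#' @param progress print per-subject progress lines.
#' @return object of class `tdcs_study`: `cohort` (tibble), `stats`
#'   (tibble), `config`, `n_failed`.
#' @export
run_study <- function(config = default_run_config(), out_dir = NULL,
                      progress = interactive()) {
  validate_run_config(config)
  cohort <- generate_synthetic_cohort(
    n = config$cohort$n,
    class_counts = unlist(config$cohort$class_counts),
    effect_params = config$cohort$effect_params,
    seed = config$seed,
    head_params = list(
      layer_radii = unlist(config$mesh$layer_radii),
      conductivities = unlist(config$conductivities),
      mesh_size = config$mesh$mesh_size
    ),
    build_heads = TRUE
  )
  n <- nrow(cohort$covariates)
  res_rows <- vector("list", n)
  for (i in seq_len(n)) {
    row <- cohort$covariates[i, ]
    t0 <- Sys.time()
    out <- tryCatch(
      cbind(run_subject(cohort$heads[[i]], config),
            tibble::tibble(status = "ok")),
      error = function(e) tibble::tibble(status = paste0("failed: ",
                                                         conditionMessage(e)))
    )
    res_rows[[i]] <- dplyr::bind_cols(row, out)
    if (isTRUE(progress)) {
      message(sprintf("[%s] %s (%.1fs)", row$subject_id, out$status[1L],
                      as.numeric(Sys.time() - t0, units = "secs")))
    }
  }
  cohort_tbl <- dplyr::bind_rows(res_rows)
  ok <- cohort_tbl$status == "ok"
  n_failed <- sum(!ok)

  stats_tbl <- compute_group_stats(cohort_tbl[ok, ])
  study <- structure(
    list(cohort = cohort_tbl, stats = stats_tbl, config = config,
         n_failed = n_failed),
    class = "tdcs_study"
  )
  if (!is.null(out_dir)) write_study_outputs(study, out_dir)
  study
}

compute_group_stats <- function(tbl) {
  out <- list()
  add <- function(report, comparison) {
    report$comparison <- comparison
    out[[length(out) + 1L]] <<- report
  }
  if (nrow(tbl) >= 5L) {
    add(tryCatch(wilcoxon_signed_rank(tbl$conv_field, tbl$opt_field),
                 error = empty_report("wilcoxon_signed_rank")),
        "optimized vs conventional ROI field")
    cortical <- tbl$class == "cortical"
    if (any(cortical) && any(!cortical)) {
      add(tryCatch(mann_whitney_u(tbl$d_total[cortical],
                                  tbl$d_total[!cortical]),
                   error = empty_report("mann_whitney_u")),
          "displacement D, cortical vs non-cortical")
      add(tryCatch(mann_whitney_u(tbl$improvement_pct[cortical],
                                  tbl$improvement_pct[!cortical]),
                   error = empty_report("mann_whitney_u")),
          "field improvement, cortical vs non-cortical")
    }
    add(tryCatch(spearman_ci(tbl$d_total, tbl$fma_ue),
                 error = empty_report("spearman")),
        "displacement D vs initial FMA-UE")
    add(tryCatch(spearman_ci(tbl$improvement_pct, tbl$fma_ue),
                 error = empty_report("spearman")),
        "field improvement vs initial FMA-UE")
    add(tryCatch(ks_normality(tbl$conv_field),
                 error = empty_report("ks_normality")),
        "normality of conventional ROI fields")
  }
  dplyr::bind_rows(out)
}

empty_report <- function(test) {
  function(e) {
    new_stats_report(test = test, statistic = NA_real_, p_value = NA_real_,
                     n = 0L, method = paste0("failed: ",
                                             conditionMessage(e)))
  }
}

config_hash <- function(config) {
  # stable short hash of the deparsed config (no extra dependencies)
  txt <- paste(deparse(config), collapse = "")
  raw <- utils::head(charToRaw(txt), 10000L)
  sprintf("%08x", sum(as.integer(raw) * seq_along(raw)) %% 0xFFFFFFF)
}

write_study_outputs <- function(study, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- sprintf("# tdcsim study seed=%s config=%s",
                   study$config$seed, config_hash(study$config))
  csv_path <- file.path(out_dir, "cohort.csv")
  con <- file(csv_path, "w")
  writeLines(stamp, con)
  utils::write.csv(study$cohort, con, row.names = FALSE)
  close(con)
  stats_path <- file.path(out_dir, "stats.json")
  con <- file(stats_path, "w")
  writeLines(stamp, con)
  for (i in seq_len(nrow(study$stats))) {
    writeLines(jsonlite::toJSON(as.list(study$stats[i, ]), auto_unbox = TRUE,
                                digits = NA, na = "null"), con)
  }
  close(con)
  summary_path <- file.path(out_dir, "summary.txt")
  writeLines(c(stamp, utils::capture.output(print(study))), summary_path)
  invisible(out_dir)
}

#' @export
print.tdcs_study <- function(x, ...) {
  ok <- x$cohort$status == "ok"
  cat(sprintf("<tdcs_study> %d subjects (%d failed), seed %s\n",
              nrow(x$cohort), x$n_failed, x$config$seed))
  if (any(ok)) {
    tbl <- x$cohort[ok, ]
    cat(sprintf(
      "  ROI field (V/m): conventional median %.3f [%.3f-%.3f], optimized median %.3f [%.3f-%.3f]\n",
      median(tbl$conv_field), quantile(tbl$conv_field, 0.25),
      quantile(tbl$conv_field, 0.75),
      median(tbl$opt_field), quantile(tbl$opt_field, 0.25),
      quantile(tbl$opt_field, 0.75)
    ))
    cat(sprintf("  improvement %%: mean %.1f, max %.1f; displacement D median %.1f mm\n",
                mean(tbl$improvement_pct), max(tbl$improvement_pct),
                median(tbl$d_total)))
  }
  if (nrow(x$stats)) {
    for (i in seq_len(nrow(x$stats))) {
      s <- x$stats[i, ]
      cat(sprintf("  %s: %s p = %.4g%s\n", s$comparison, s$test, s$p_value,
                  if (!is.na(s$effect)) {
                    sprintf(", rho = %.2f [%.2f, %.2f]", s$effect, s$ci_low,
                            s$ci_high)
                  } else ""))
    }
  }
  invisible(x)
}
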