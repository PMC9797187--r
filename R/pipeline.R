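# Run configuration, scale presets, seeding, result persistence and the
# top-level drivers binding the modules into the four experiments. The
# desk preset reduces counts only (shifts, repetitions, population); it
# never alters formulas or thresholds.

#' Scale preset
#'
#' `paper` reproduces the published design sizes; `desk` shrinks the
#' counts so each experiment finishes in minutes on one CPU while
#' preserving all algorithmic structure (50 shifts, class counts 5-7,
#' 100 train / 20 val per class, 10 evaluation samples per bin, 2
#' evolutionary replicates at population 40 for 15 generations).
#'
#' @param name `"paper"` or `"desk"`.
#' @return a named list of counts.
#' @export
scale_preset <- function(name = c("desk", "paper")) {
  name <- match.arg(name)
  if (name == "paper") {
    list(name = "paper", class_counts = 4:9, n_shifts = 150L,
         n_train_per_class = 500L, n_val_per_class = 50L, epochs = 5L,
         eval_samples_per_bin = 60L, n_bins = 100L,
         evo_pop = 100L, evo_generations = 40L, evo_mutation_off = 30L,
         evo_replicates = 12L, n_steps = 10L, n_reps = 15L,
         obj_permutations = 100L, obj_train = 500L, obj_val = 50L,
         obj_eval_outlines = 80L, n_observers = 10L, n_boot = 100000L)
  } else {
    list(name = "desk", class_counts = 5:7, n_shifts = 50L,
         n_train_per_class = 100L, n_val_per_class = 20L, epochs = 5L,
         eval_samples_per_bin = 10L, n_bins = 100L,
         evo_pop = 40L, evo_generations = 15L, evo_mutation_off = 11L,
         evo_replicates = 2L, n_steps = 10L, n_reps = 3L,
         obj_permutations = 3L, obj_train = 60L, obj_val = 15L,
         obj_eval_outlines = 10L, n_observers = 6L, n_boot = 2000L)
  }
}

#' Run configuration
#'
#' @param experiment one of `"invariant"`, `"evolution"`,
#'   `"within_category"`, `"objects"`, `"psychophysics"`.
#' @param seed global integer seed; every sub-computation derives its own
#'   seed from it.
#' @param scale `"desk"` or `"paper"`.
#' @param engine a `feature_extractor` or `responder_model`; defaults to
#'   a categorical responder over `planted_borders` when `NULL`.
#' @param planted_borders border positions used by responder engines and
#'   as experiment input where borders are required.
#' @param out_dir output directory (`NULL` for no persistence).
#' @return a `run_config`.
#' @export
run_config <- function(experiment, seed = 1L, scale = "desk", engine = NULL,
                       planted_borders = default_planted_borders(),
                       out_dir = NULL) {
  experiment <- match.arg(experiment, c("invariant", "evolution",
                                        "within_category", "objects",
                                        "psychophysics"))
  structure(list(experiment = experiment, seed = as.integer(seed),
                 scale = scale_preset(scale), engine = engine,
                 planted_borders = sort(wrap_hue(planted_borders)),
                 out_dir = out_dir),
            class = "run_config")
}

#' Default 7-border reference set
#'
#' A fixed, unevenly spaced 7-border partition used as the planted truth
#' of the synthetic study conditions (narrow warm categories, a broad
#' green region, mirroring the qualitative layout of human hue
#' categories).
#'
#' @return sorted numeric vector of 7 hues.
#' @export
default_planted_borders <- function() {
  c(0.045, 0.125, 0.21, 0.40, 0.52, 0.63, 0.84)
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Execute a configured experiment and persist its artifacts
#'
#' Runs the named experiment at the configured scale, writes all
#' intermediate artifacts (row stacks, counts, estimates, logs) as
#' CSV/JSON plus a manifest carrying the config and seed, and returns
#' the in-memory results. Re-running with the same config reproduces
#' identical outputs.
#'
#' @param cfg a [run_config()].
#' @return list of experiment results (invisibly when persisted).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  sc <- cfg$scale
  engine <- cfg$engine
  if (is.null(engine)) {
    engine <- categorical_responder(cfg$planted_borders, label_noise = 0.05)
  }
  grid <- eval_grid(sc$n_bins, sc$eval_samples_per_bin)
  res <- switch(cfg$experiment,
    invariant = {
      rows <- if (inherits(engine, "responder_model")) {
        simulate_row_stack(engine, sc$class_counts, sc$n_shifts, grid,
                           seed = cfg$seed)
      } else {
        run_invariant_experiment(
          engine, sc$class_counts, sc$n_shifts,
          probe_train_config(sc$n_train_per_class, sc$n_val_per_class,
                             epochs = sc$epochs),
          grid, seed = cfg$seed)
      }
      tc <- accumulate_transition_counts(rows)
      borders <- detect_peaks(tc)
      protos <- if (borders$n_borders >= 2) compute_prototypes(borders, tc)
                else NULL
      list(rows = rows, transition_count = tc, borders = borders,
           prototypes = protos)
    },
    evolution = {
      fitness <- if (inherits(engine, "responder_model")) {
        planted_fitness_oracle(cfg$planted_borders)
      } else {
        function(bs) evaluate_fitness(bs, engine)
      }
      ecfg <- evolution_config(
        pop_size = sc$evo_pop, n_elite = max(1L, sc$evo_pop %/% 10L),
        n_offspring = sc$evo_pop - max(1L, sc$evo_pop %/% 10L),
        n_generations = sc$evo_generations,
        mutation_off_after = sc$evo_mutation_off,
        n_replicates = sc$evo_replicates)
      runs <- lapply(seq_len(sc$evo_replicates), function(r)
        run_evolution(fitness, ecfg, seed = derive_seed(cfg$seed, r)))
      list(runs = runs,
           summary = summarize_replicates(runs,
                                          n_top = max(1L, sc$evo_pop %/% 10L)))
    },
    within_category = {
      list(error_curve = within_category_error_curve(
        engine, border_set(cfg$planted_borders), n_steps = sc$n_steps,
        n_reps = sc$n_reps,
        grid = eval_grid(sc$n_bins, sc$eval_samples_per_bin),
        seed = cfg$seed))
    },
    objects = {
      list(result = object_color_experiment(
        engine, border_set(cfg$planted_borders),
        n_permutations = sc$obj_permutations, n_train = sc$obj_train,
        n_val = sc$obj_val, n_eval_outlines = sc$obj_eval_outlines,
        n_bins = sc$n_bins, seed = cfg$seed))
    },
    psychophysics = {
      tables <- lapply(seq_len(sc$n_observers), function(i)
        simulate_observer(cfg$planted_borders, lapse = 0.05,
                          jitter_sd = 0.01, id = sprintf("sim%02d", i),
                          seed = derive_seed(cfg$seed, i)))
      ana <- observer_transition_analysis(tables)
      boot <- bootstrap_correlation_test(tables, n_boot = sc$n_boot,
                                         seed = derive_seed(cfg$seed, 777L))
      list(tables = tables, analysis = ana, bootstrap = boot)
    }
  )
  if (!is.null(cfg$out_dir)) {
    persist_results(cfg, res)
    return(invisible(res))
  }
  res
}

# write the standard artifact files for a pipeline result
persist_results <- function(cfg, res) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(experiment = cfg$experiment, seed = cfg$seed,
                   scale = cfg$scale$name,
                   planted_borders = cfg$planted_borders,
                   engine = if (is.null(cfg$engine)) "categorical_responder"
                            else class(cfg$engine)[1],
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  write_json_file(manifest, file.path(cfg$out_dir, "manifest.json"))
  if (!is.null(res$transition_count)) {
    tc <- res$transition_count
    utils::write.csv(
      data.frame(edge = seq_len(tc$n_bins) - 1L, raw = tc$raw,
                 smoothed = tc$smoothed),
      file.path(cfg$out_dir, "transition_count.csv"), row.names = FALSE)
  }
  if (!is.null(res$borders)) {
    write_json_file(list(positions = res$borders$positions,
                         n_borders = res$borders$n_borders),
                    file.path(cfg$out_dir, "borders.json"))
  }
  if (!is.null(res$prototypes)) {
    utils::write.csv(res$prototypes,
                     file.path(cfg$out_dir, "prototypes.csv"),
                     row.names = FALSE)
  }
  if (!is.null(res$rows)) {
    export_row_stack_png(res$rows, file.path(cfg$out_dir, "row_stack.png"))
  }
  if (!is.null(res$summary)) {
    utils::write.csv(res$summary, file.path(cfg$out_dir, "evolution_summary.csv"),
                     row.names = FALSE)
  }
  if (!is.null(res$runs)) {
    logs <- do.call(rbind, lapply(seq_along(res$runs), function(i) {
      d <- res$runs[[i]]$records
      d$replicate <- i
      d
    }))
    utils::write.csv(logs, file.path(cfg$out_dir, "evolution_log.csv"),
                     row.names = FALSE)
  }
  if (!is.null(res$error_curve)) {
    utils::write.csv(res$error_curve,
                     file.path(cfg$out_dir, "error_curve.csv"),
                     row.names = FALSE)
  }
  if (!is.null(res$result) && inherits(res$result, "object_experiment_result")) {
    utils::write.csv(res$result$median,
                     file.path(cfg$out_dir, "object_accuracy_median.csv"),
                     row.names = FALSE)
  }
  if (!is.null(res$bootstrap)) {
    write_json_file(list(p_value = res$bootstrap$p_value,
                         observed = res$bootstrap$observed),
                    file.path(cfg$out_dir, "bootstrap.json"))
  }
  invisible(cfg$out_dir)
}

#' Load a manifest back into an equivalent run configuration
#' @param path manifest JSON written by [run_pipeline()].
#' @return a [run_config()] (engine defaults to the categorical
#'   responder recorded in the manifest).
#' @export
read_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  run_config(m$experiment, seed = m$seed, scale = m$scale,
             planted_borders = m$planted_borders)
}

#' Export a stack of classification rows as a figure-style heatmap PNG
#'
#' Each row of the image is one classification row; each pixel is
#' colored with the hue of the band center its bin was assigned to.
#'
#' @param rows list of `classification_row`.
#' @param path PNG output path.
#' @export
export_row_stack_png <- function(rows, path) {
  n <- length(rows)
  nb <- rows[[1]]$n_bins
  img <- array(0, dim = c(n, nb, 3))
  for (i in seq_len(n)) {
    r <- rows[[i]]
    img[i, , ] <- hue_to_rgb(r$bands$centers[r$mode_row + 1L])
  }
  png::writePNG(img, target = path)
  invisible(path)
}
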