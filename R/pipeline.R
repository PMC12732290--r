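# End-to-end orchestration: generate/ingest -> balance -> split -> extract
# -> select -> evaluate, Monte-Carlo repetition over independently seeded
# runs, and report writing. Every stage seed derives deterministically from
# the pipeline seed.

#' Pipeline configuration
#'
#' @param synth a [synth_config()] describing the synthetic dataset, or
#'   `NULL` when `manifest` is given.
#' @param manifest optional [dataset_manifest()] (or path to a manifest
#'   JSON) of an on-disk image dataset.
#' @param balance_target per-class target count for SMOTE balancing of the
#'   training partition (`NULL` disables balancing).
#' @param balance_exempt class names exempt from oversampling.
#' @param smote_mode `"train_only"` (leakage-safe default: only the training
#'   partition is oversampled) or `"whole"` (oversample before splitting).
#' @param split_fraction outer train fraction (default 0.70).
#' @param network a [network_spec()] for image feature extraction (default
#'   [default_menet_spec()]).
#' @param fitness a [fitness_spec()].
#' @param num_particles,max_iter swarm settings for the selection run.
#' @param out_dir optional directory where [write_report()] persists
#'   artifacts after the run.
#' @param seed master seed; stage seeds derive from it.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(synth = synth_config(),
                            manifest = NULL,
                            balance_target = NULL,
                            balance_exempt = character(0),
                            smote_mode = c("train_only", "whole"),
                            split_fraction = 0.7,
                            network = NULL,
                            fitness = fitness_spec(),
                            num_particles = 30L,
                            max_iter = 100L,
                            out_dir = NULL,
                            seed = 1L) {
  smote_mode <- match.arg(smote_mode)
  structure(list(synth = synth, manifest = manifest,
                 balance_target = balance_target,
                 balance_exempt = balance_exempt,
                 smote_mode = smote_mode,
                 split_fraction = split_fraction,
                 network = network, fitness = fitness,
                 num_particles = as.integer(num_particles),
                 max_iter = as.integer(max_iter),
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

# Flatten per-class image lists into (list of arrays, labels).
flatten_manifest <- function(manifest) {
  imgs <- manifest_images(manifest)
  list(images = do.call(c, unname(imgs)),
       labels = rep(seq_along(imgs), vapply(imgs, length, integer(1))),
       class_names = names(manifest$classes))
}

# SMOTE-balance per-class image lists (flattened pixel space, values
# clipped to [0, 1]).
balance_images <- function(class_images, target, exempt, seed) {
  out <- class_images
  for (cl in names(class_images)) {
    if (cl %in% exempt) next
    imgs <- class_images[[cl]]
    need <- target - length(imgs)
    if (need <= 0) next
    d <- dim(imgs[[1]])
    flat <- t(vapply(imgs, as.numeric, numeric(prod(d))))
    k <- min(5L, nrow(flat) - 1L)
    synth <- smote_generate(flat, need, k = k, seed = seed, clip = c(0, 1))
    out[[cl]] <- c(imgs, lapply(seq_len(need), function(i)
      array(synth[i, ], d)))
    seed <- seed + 1L
  }
  out
}

#' Run the full pipeline once
#'
#' Image mode: stratified split, SMOTE balancing of the training partition,
#' deep feature extraction, QBPSO wrapper selection (fitness evaluated on an
#' internal split of the training partition), final held-out evaluation.
#' Feature mode: the extractor stage is skipped and selection runs directly
#' on the (optionally planted) feature table.
#'
#' @param config a [pipeline_config()].
#' @return object of class `report_bundle`: `selection`
#'   (`selection_result`), `confusion`, `metrics`, `fval` (best
#'   loss + penalty, the minimized objective value), `n_selected`,
#'   `accuracy`, `plan` (balance plan or `NULL`), `elapsed` (seconds; not
#'   part of the deterministic payload), `config`.
#' @export
run_pipeline <- function(config) {
  t0 <- proc.time()[["elapsed"]]
  fitness <- config$fitness
  fitness$seed <- config$seed
  plan <- NULL
  if (!is.null(config$manifest) ||
      (!is.null(config$synth) && config$synth$mode == "images")) {
    manifest <- config$manifest
    if (is.character(manifest)) manifest <- read_manifest_json(manifest)
    if (is.null(manifest)) {
      sc <- config$synth; sc$seed <- config$seed
      manifest <- generate_synthetic_images(sc)
    }
    if (config$smote_mode == "whole" && !is.null(config$balance_target)) {
      plan <- plan_balance(manifest$counts, config$balance_target,
                           config$balance_exempt)
      manifest$classes <- balance_images(manifest_images(manifest),
                                         config$balance_target,
                                         config$balance_exempt,
                                         config$seed + 11L)
      manifest$counts <- vapply(manifest$classes, length, integer(1))
    }
    sp <- split_dataset(manifest, config$split_fraction,
                        seed = config$seed + 1L)
    if (config$smote_mode == "train_only" &&
        !is.null(config$balance_target)) {
      plan <- plan_balance(sp$train$counts, config$balance_target,
                           config$balance_exempt)
      sp$train$classes <- balance_images(manifest_images(sp$train),
                                         config$balance_target,
                                         config$balance_exempt,
                                         config$seed + 11L)
      sp$train$counts <- vapply(sp$train$classes, length, integer(1))
    }
    net <- config$network
    if (is.null(net))
      net <- default_menet_spec(num_classes = length(manifest$classes),
                                seed = config$seed + 2L)
    net <- menet_init(net)
    tr <- flatten_manifest(sp$train)
    te <- flatten_manifest(sp$test)
    feats <- rbind(extract_features(tr$images, net),
                   extract_features(te$images, net))
    data <- feature_matrix(feats, c(tr$labels, te$labels),
                           length(manifest$classes))
    outer_split <- list(train = seq_along(tr$labels),
                        test = length(tr$labels) + seq_along(te$labels))
  } else {
    sc <- config$synth; sc$seed <- config$seed
    data <- generate_synthetic_features(sc)
    outer_split <- NULL
  }
  qcfg <- qbpso_config(dimension = ncol(data$values),
                       num_particles = config$num_particles,
                       max_iter = config$max_iter,
                       maximize = TRUE, seed = config$seed + 3L)
  sel <- run_selection(data, fitness, qcfg, outer_split = outer_split,
                       outer_fraction = config$split_fraction)
  bundle <- structure(
    list(selection = sel,
         confusion = sel$final_metrics$confusion,
         metrics = sel$final_metrics$metrics,
         fval = -sel$score,
         n_selected = length(sel$selected_indices),
         accuracy = sel$final_metrics$metrics$overall$accuracy,
         plan = plan,
         informative = attr(data, "informative"),
         elapsed = proc.time()[["elapsed"]] - t0,
         config = config),
    class = "report_bundle")
  if (!is.null(config$out_dir)) write_report(bundle, config$out_dir)
  bundle
}

#' Monte-Carlo repetition of the pipeline
#'
#' `n_runs` independent pipeline executions with per-run seeds
#' `base_seed + run_index`, aggregated with [summarize_runs()].  When
#' `compare` holds a second configuration, both are run on the same derived
#' seeds and their objective values are compared with [anova_f()] and
#' [two_sample_t()].
#'
#' @param config a [pipeline_config()].
#' @param n_runs number of independent runs (the reference protocol uses
#'   100; scale down for quick studies).
#' @param base_seed base of the derived per-run seeds (default: the
#'   config's seed).
#' @param compare optional second [pipeline_config()].
#' @return list with `records` (one row per run), `stats` ([summarize_runs()]),
#'   `bundles`, and, when comparing, `records_b`, `stats_b`, `anova`, `t_test`.
#' @export
run_monte_carlo <- function(config, n_runs = 100L, base_seed = config$seed,
                            compare = NULL) {
  stopifnot(n_runs >= 1)
  one_set <- function(cfg) {
    recs <- vector("list", n_runs)
    bundles <- vector("list", n_runs)
    for (i in seq_len(n_runs)) {
      cfg$seed <- as.integer(base_seed + i)
      cfg$out_dir <- NULL
      b <- run_pipeline(cfg)
      recs[[i]] <- data.frame(run = i, fval = b$fval,
                              seconds = b$elapsed,
                              accuracy = b$accuracy,
                              n_selected = b$n_selected)
      bundles[[i]] <- b
    }
    list(records = do.call(rbind, recs), bundles = bundles)
  }
  a <- one_set(config)
  out <- list(records = a$records, stats = summarize_runs(a$records),
              bundles = a$bundles)
  if (!is.null(compare)) {
    b <- one_set(compare)
    out$records_b <- b$records
    out$stats_b <- summarize_runs(b$records)
    out$anova <- anova_f(list(a$records$fval, b$records$fval))
    out$t_test <- two_sample_t(a$records$fval, b$records$fval)
  }
  out
}

#' Persist a report bundle
#'
#' Writes the confusion grid, the per-class metric table, the selection
#' mask JSON, the optimization trace and a machine-readable summary; every
#' table re-parses to the values in the bundle.
#'
#' @param bundle a `report_bundle`.
#' @param dir output directory (created if missing).
#' @return invisibly, the named file set.
#' @export
write_report <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(confusion = file.path(dir, "confusion.tsv"),
             metrics = file.path(dir, "metrics.tsv"),
             mask = file.path(dir, "mask.json"),
             trace = file.path(dir, "trace.tsv"),
             summary = file.path(dir, "summary.json"))
  write_confusion(bundle$confusion, files["confusion"])
  write_metrics_table(bundle$metrics, files["metrics"])
  write_mask_json(bundle$selection, files["mask"],
                  lambda = bundle$config$fitness$lambda,
                  seed = bundle$config$seed)
  write_trace(bundle$selection$result, files["trace"])
  jsonlite::write_json(
    list(accuracy = bundle$accuracy,
         misclassification = bundle$metrics$overall$misclassification,
         weighted_f1 = bundle$metrics$overall$weighted_f1,
         macc = bundle$metrics$overall$macc,
         fval = bundle$fval,
         n_selected = bundle$n_selected,
         seed = bundle$config$seed),
    files["summary"], auto_unbox = TRUE, digits = NA)
  invisible(files)
}

#' Deterministic payload of a report bundle
#'
#' The bundle minus wall-clock fields; two runs of the same configuration
#' and seed produce identical payloads.
#'
#' @param bundle a `report_bundle`.
#' @return list.
#' @export
bundle_payload <- function(bundle) {
  bundle$elapsed <- NULL
  unclass(bundle)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("Pipeline report\n")
  cat("  held-out accuracy:", format(round(x$accuracy, 4)), "\n")
  cat("  selected features:", x$n_selected, "\n")
  cat("  objective (loss + penalty):", format(x$fval), "\n")
  invisible(x)
}
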