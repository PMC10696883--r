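# Pipeline orchestration: a declarative YAML config drives the stage chain
# simulate -> shuffle -> split -> train -> evaluate -> scan -> discover ->
# mutate -> correlate, each stage writing plain-text artifacts plus a
# manifest entry (parameter hash, seed, input hashes) so every output is
# traceable and reruns with the same config are reproducible.

PIPELINE_STAGES <- c("simulate", "shuffle", "split", "train", "evaluate",
                     "scan", "discover", "mutate", "correlate")

run_config_schema <- function() {
  list(
    run_id = "character", out_dir = "character", seed = "integer",
    simulate = names(formals(synth_config)),
    model = names(formals(crnn_config)),
    split = c("ratios"),
    scan = c("window", "stride"),
    pwm = c("softness", "pseudocount", "both_strands"),
    discover = c("rnn_min", "pwm_max"),
    mutate = c("top_k"),
    correlate = c("censored_value", "strengths")
  )
}

#' Validate a pipeline configuration file
#'
#' Reads a YAML run configuration and validates it against the full
#' schema, reporting every problem at once (unknown keys, wrong types,
#' out-of-range values) rather than failing at the first.
#'
#' @param path Path to a YAML file.
#' @return The validated configuration (class `run_config`), or an error
#'   whose message lists all problems.
#' @export
validate_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  schema <- run_config_schema()
  errs <- character()
  note <- function(msg) errs <<- c(errs, msg)

  unknown_top <- setdiff(names(cfg), names(schema))
  if (length(unknown_top) > 0L) {
    note(sprintf("unknown top-level key(s): %s",
                 paste(unknown_top, collapse = ", ")))
  }
  for (sect in intersect(names(cfg), names(schema))) {
    allowed <- schema[[sect]]
    if (length(allowed) == 1L && allowed %in% c("character", "integer")) next
    unknown <- setdiff(names(cfg[[sect]]), allowed)
    if (length(unknown) > 0L) {
      note(sprintf("unknown key(s) in '%s': %s", sect,
                   paste(unknown, collapse = ", ")))
    }
  }
  if (!is.null(cfg$seed) &&
      (!is.numeric(cfg$seed) || cfg$seed != floor(cfg$seed))) {
    note("'seed' must be an integer")
  }
  chk_range <- function(sect, key, lo, hi, open_hi = FALSE) {
    v <- cfg[[sect]][[key]]
    if (is.null(v)) return()
    if (!is.numeric(v)) { note(sprintf("'%s.%s' must be numeric", sect, key)); return() }
    hi_ok <- if (open_hi) v < hi else v <= hi
    if (!(v >= lo && hi_ok)) {
      note(sprintf("'%s.%s' = %s out of range [%s, %s%s", sect, key,
                   format(v), format(lo), format(hi),
                   if (open_hi) ")" else "]"))
    }
  }
  chk_range("model", "conv_dropout", 0, 1, open_hi = TRUE)
  chk_range("model", "dense_dropout", 0, 1, open_hi = TRUE)
  chk_range("simulate", "planted_fraction", 0, 1)
  chk_range("simulate", "gc_content", 0, 1)
  chk_range("simulate", "motif_softness", 0, 0.75, open_hi = TRUE)
  chk_range("simulate", "noncanonical_peak_fraction", 0, 1)
  chk_range("discover", "rnn_min", 0, 1)
  if (!is.null(cfg$split$ratios)) {
    r <- cfg$split$ratios
    if (length(r) != 3L || any(r <= 0) || abs(sum(r) - 1) > 1e-9) {
      note("'split.ratios' must be three positive numbers summing to 1")
    }
  }
  if (length(errs) > 0L) {
    abort(paste0("invalid run configuration:\n",
                 paste("-", errs, collapse = "\n")),
          class = "crnntfbs_config_error")
  }
  cfg$run_id <- cfg$run_id %||% "run"
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  structure(cfg, class = "run_config")
}

stage_paths <- function(out_dir) {
  p <- function(...) file.path(out_dir, ...)
  list(
    reads = p("reads.fasta"), reads_truth = p("reads_truth.tsv"),
    peaks = p("peaks.narrowPeak"), decoys = p("decoys.narrowPeak"),
    peak_seqs = p("peak_seqs.fasta"), decoy_seqs = p("decoy_seqs.fasta"),
    peaks_truth = p("peaks_truth.tsv"), affinities = p("affinities.tsv"),
    dataset = p("dataset.tsv"),
    train = p("train.tsv"), validation = p("validation.tsv"),
    test = p("test.tsv"),
    model_dir = p("model"), metrics = p("metrics.json"),
    rnn_scan = p("rnn_scan.tsv"), pwm_scan = p("pwm_scan.tsv"),
    discovered = p("discovered.tsv"), variants = p("variants.tsv"),
    correlation = p("correlation.json"),
    manifest = p("manifest.tsv")
  )
}

write_dataset_tsv <- function(ds, path) {
  readr::write_tsv(mutate(ds, label = as.character(.data$label)), path,
                   progress = FALSE)
}

read_dataset_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE) |>
    mutate(label = factor(.data$label, levels = c("binding", "non_binding")))
}

require_inputs <- function(files, producer, stage) {
  missing <- files[!file.exists(files)]
  if (length(missing) > 0L) {
    abort(sprintf(
      "stage '%s' is missing input(s) %s: run stage '%s' first",
      stage, paste(basename(missing), collapse = ", "), producer
    ), class = "crnntfbs_missing_input")
  }
}

params_hash <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA)
  substr(unname(tools::md5sum(f)), 1L, 12L)
}

#' Run the pipeline stage chain
#'
#' Executes the requested stages in canonical order against a run
#' directory. Each stage reads its inputs from the directory (so a chain
#' can be resumed), writes plain-text outputs, and appends a manifest
#' entry recording the stage, its parameter hash, the seed and the md5 of
#' every file it wrote. Rerunning with an identical configuration
#' reproduces identical outputs.
#'
#' @param config A `run_config` (from [validate_run_config()]) or a path
#'   to a YAML configuration file.
#' @param stages Subset of
#'   `c("simulate","shuffle","split","train","evaluate","scan","discover",`
#'   `"mutate","correlate")`; always executed in canonical order.
#' @param quiet Suppress progress messages.
#' @return The manifest tibble, invisibly.
#' @export
run_pipeline <- function(config, stages = PIPELINE_STAGES, quiet = FALSE) {
  if (is.character(config)) config <- validate_run_config(config)
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad) > 0L) {
    abort(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")),
          class = "crnntfbs_config_error")
  }
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- stage_paths(out_dir)
  seed <- config$seed
  scfg <- do.call(synth_config, c(config$simulate %||% list(),
                                  list(seed = seed)))
  manifest <- list()
  log_stage <- function(stage, params, outputs) {
    outputs <- outputs[file.exists(outputs)]
    manifest[[length(manifest) + 1L]] <<- tibble(
      run_id = config$run_id, stage = stage, seed = seed,
      params_hash = params_hash(params),
      output = basename(outputs),
      md5 = unname(tools::md5sum(outputs))
    )
    if (!quiet) inform(sprintf("stage '%s' complete (%d file(s))",
                               stage, length(outputs)))
  }

  for (stage in stages) {
    switch(stage,
      simulate = {
        reads <- simulate_reads(scfg)
        write_fasta(reads$reads, paths$reads)
        readr::write_tsv(reads$truth, paths$reads_truth, progress = FALSE)
        pk <- simulate_peaks(scfg)
        write_narrowpeak(pk$peaks, paths$peaks)
        write_narrowpeak(pk$decoys, paths$decoys)
        write_fasta(pk$peak_seqs, paths$peak_seqs)
        write_fasta(pk$decoy_seqs, paths$decoy_seqs)
        readr::write_tsv(pk$truth, paths$peaks_truth, progress = FALSE)
        panel <- simulate_affinity_panel(
          scfg, strengths = config$correlate$strengths %||%
            eval(formals(simulate_affinity_panel)$strengths))
        readr::write_tsv(
          mutate(panel, kd_uM = ifelse(.data$censored, "NBD",
                                       as.character(.data$kd))) |>
            select("ligand_id", sequence = "seq", "kd_uM"),
          paths$affinities, progress = FALSE)
        log_stage("simulate", unclass(scfg),
                  unlist(paths[c("reads", "reads_truth", "peaks", "decoys",
                                 "peak_seqs", "decoy_seqs", "peaks_truth",
                                 "affinities")]))
      },
      shuffle = {
        require_inputs(paths$reads, "simulate", "shuffle")
        ds <- build_balanced_dataset(read_fasta(paths$reads), seed = seed)
        write_dataset_tsv(ds, paths$dataset)
        log_stage("shuffle", list(seed = seed), paths$dataset)
      },
      split = {
        require_inputs(paths$dataset, "shuffle", "split")
        ratios <- config$split$ratios %||% c(0.70, 0.15, 0.15)
        parts <- split_dataset(read_dataset_tsv(paths$dataset), ratios,
                               seed = seed)
        write_dataset_tsv(parts$train, paths$train)
        write_dataset_tsv(parts$validation, paths$validation)
        write_dataset_tsv(parts$test, paths$test)
        log_stage("split", list(ratios = ratios, seed = seed),
                  unlist(paths[c("train", "validation", "test")]))
      },
      train = {
        require_inputs(c(paths$train, paths$validation), "split", "train")
        mcfg <- do.call(crnn_config, c(config$model %||% list(),
                                       list(seed = seed)))
        m <- train(build_model(mcfg),
                   read_dataset_tsv(paths$train),
                   read_dataset_tsv(paths$validation), quiet = quiet)
        save_model(m, paths$model_dir)
        log_stage("train", unclass(mcfg),
                  file.path(paths$model_dir,
                            c("config.json", "params.json", "history.tsv")))
      },
      evaluate = {
        require_inputs(c(file.path(paths$model_dir, "config.json"),
                         paths$test), "train", "evaluate")
        m <- load_model(paths$model_dir)
        te <- read_dataset_tsv(paths$test)
        p <- predict(m, te)
        pos <- p[te$label == "binding"]; neg <- p[te$label == "non_binding"]
        metrics <- list(test_roc_auc = roc_auc(pos, neg)$auc,
                        test_pr_auc = pr_auc(pos, neg),
                        validation_auc = m$validation_auc,
                        n_test = nrow(te))
        jsonlite::write_json(metrics, paths$metrics, auto_unbox = TRUE,
                             digits = NA)
        log_stage("evaluate", list(), paths$metrics)
      },
      scan = {
        require_inputs(c(file.path(paths$model_dir, "config.json"),
                         paths$peak_seqs, paths$decoy_seqs),
                       "train/simulate", "scan")
        m <- load_model(paths$model_dir)
        window <- config$scan$window %||% m$config$input_length
        stride <- config$scan$stride %||% 1L
        seqs <- bind_rows(
          mutate(read_fasta(paths$peak_seqs), dataset = "positive"),
          mutate(read_fasta(paths$decoy_seqs), dataset = "decoy")
        )
        rnn <- scan_sequences(crnn_scorer(m), seqs, window, stride) |>
          left_join(select(seqs, peak_id = "id", "dataset"), by = "peak_id") |>
          group_by(.data$dataset) |>
          dplyr::group_modify(~assign_percentiles(.x)) |>
          ungroup()
        readr::write_tsv(rnn, paths$rnn_scan, progress = FALSE)
        pfm <- pwm_from_consensus(scfg$canonical_consensus,
                                  config$pwm$softness %||% 0.01)
        lom <- pfm_to_log_odds(pfm,
                               pseudocount = config$pwm$pseudocount %||% 0.1)
        pwm <- pwm_scan(lom, seqs,
                        both_strands = config$pwm$both_strands %||% TRUE) |>
          left_join(select(seqs, peak_id = "id", "dataset"), by = "peak_id")
        readr::write_tsv(pwm, paths$pwm_scan, progress = FALSE)
        log_stage("scan", list(window = window, stride = stride),
                  c(paths$rnn_scan, paths$pwm_scan))
      },
      discover = {
        require_inputs(c(paths$rnn_scan, paths$pwm_scan), "scan", "discover")
        rnn <- readr::read_tsv(paths$rnn_scan, show_col_types = FALSE,
                               progress = FALSE)
        pwm <- readr::read_tsv(paths$pwm_scan, show_col_types = FALSE,
                               progress = FALSE)
        found <- discover_noncanonical(
          select(rnn, -dplyr::any_of(c("dataset", "percentile"))),
          select(pwm, -dplyr::any_of(c("dataset", "strand"))),
          rnn_min = config$discover$rnn_min %||% 0.99,
          pwm_max = config$discover$pwm_max %||% 0
        )
        readr::write_tsv(found, paths$discovered, progress = FALSE)
        log_stage("discover", config$discover %||% list(), paths$discovered)
      },
      mutate = {
        require_inputs(c(paths$discovered,
                         file.path(paths$model_dir, "config.json")),
                       "discover/train", "mutate")
        m <- load_model(paths$model_dir)
        found <- readr::read_tsv(paths$discovered, show_col_types = FALSE,
                                 progress = FALSE)
        top_k <- min(config$mutate$top_k %||% 3L, nrow(found))
        eff <- purrr::map_dfr(seq_len(top_k), function(i) {
          saturation_mutagenesis(found$rnn_window[i], crnn_scorer(m),
                                 parent_id = found$peak_id[i])
        })
        readr::write_tsv(eff, paths$variants, progress = FALSE)
        log_stage("mutate", list(top_k = top_k), paths$variants)
      },
      correlate = {
        require_inputs(c(paths$affinities,
                         file.path(paths$model_dir, "config.json")),
                       "simulate/train", "correlate")
        m <- load_model(paths$model_dir)
        aff <- read_affinity_table(paths$affinities)
        scores <- tibble(ligand_id = aff$ligand_id,
                         score = predict(m, tibble(id = aff$ligand_id,
                                                   seq = aff$seq)))
        res <- affinity_correlation(
          scores, aff,
          censored_value = config$correlate$censored_value %||% 10)
        jsonlite::write_json(as.list(res), paths$correlation,
                             auto_unbox = TRUE, digits = NA)
        log_stage("correlate", config$correlate %||% list(),
                  paths$correlation)
      }
    )
  }
  manifest <- bind_rows(manifest)
  readr::write_tsv(manifest, paths$manifest, progress = FALSE)
  invisible(manifest)
}
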