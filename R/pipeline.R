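# End-to-end orchestration: simulate/read -> band-pass -> epochs -> PLV ->
# sparsity sweep -> group statistics, with a reproducible report.

# FNV-1a 32-bit hash of a character scalar (config fingerprinting without
# external digest dependencies)
fnv1a <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", h)
}

#' Build a validated pipeline run configuration
#'
#' @param out_dir output directory for all artifacts.
#' @param input_dir optional directory of recordings plus \code{cohort.tsv};
#'   when NULL a synthetic cohort is generated from \code{cohort}.
#' @param cohort a [cohort_spec()] used when simulating (default: a small
#'   demo cohort of 2 x 10 subjects, 60 s records).
#' @param bands named list of band definitions to analyze (non-empty).
#' @param epoch_length_s,n_epochs epoching parameters.
#' @param contiguous_epochs deterministic back-to-back epochs instead of
#'   random placement.
#' @param guard_s seconds discarded at each record end before segmentation
#'   (filter edge guard).
#' @param grid sparsity grid.
#' @param n_permutations permutation count for the statistics stage.
#' @param seed master seed for every random stage.
#' @param plv_aggregate PLV epoch aggregation ("epoch_mean" or "pooled").
#' @return validated list of class \code{run_config}.
#' @export
run_config <- function(out_dir,
                       input_dir = NULL,
                       cohort = cohort_spec(n_per_group = 10, duration_s = 60,
                                            seed = 1L),
                       bands = eeg_bands(),
                       epoch_length_s = 15,
                       n_epochs = NULL,
                       contiguous_epochs = FALSE,
                       guard_s = 1,
                       grid = sparsity_grid(),
                       n_permutations = 10000,
                       seed = 1L,
                       plv_aggregate = "epoch_mean") {
  if (!length(bands)) stop("band list must not be empty")
  if (!all(vapply(bands, inherits, logical(1), "band_definition")))
    stop("bands must be band_definition objects")
  if (is.null(names(bands)) || any(!nzchar(names(bands))))
    stop("bands must be a named list")
  if (epoch_length_s <= 0) stop("epoch_length_s must be positive")
  if (!is.null(input_dir) && !dir.exists(input_dir))
    stop("input_dir does not exist: ", input_dir)
  grid <- sort(unique(grid))
  if (any(grid <= 0 | grid >= 1)) stop("sparsity grid must lie in (0,1)")
  structure(list(out_dir = out_dir, input_dir = input_dir, cohort = cohort,
                 bands = bands, epoch_length_s = epoch_length_s,
                 n_epochs = n_epochs, contiguous_epochs = contiguous_epochs,
                 guard_s = guard_s, grid = grid,
                 n_permutations = n_permutations, seed = as.integer(seed),
                 plv_aggregate = plv_aggregate),
            class = "run_config")
}

# load recordings + cohort table from a directory of artifacts
load_input_dir <- function(dir) {
  tab_path <- file.path(dir, "cohort.tsv")
  if (!file.exists(tab_path)) stop("missing cohort table: ", tab_path)
  tab <- utils::read.delim(tab_path, stringsAsFactors = FALSE)
  files <- list.files(dir, pattern = "\\.(edf|tsv|csv)$", full.names = TRUE)
  files <- files[basename(files) != "cohort.tsv"]
  recs <- lapply(files, read_recording)
  names(recs) <- vapply(recs, function(r) r$subject_id, "")
  missing <- setdiff(tab$subject_id, names(recs))
  if (length(missing))
    stop("cohort table lists subjects without recordings: ",
         paste(missing, collapse = ", "))
  list(recordings = recs[tab$subject_id], table = tab)
}

#' Run the full analysis pipeline
#'
#' Stages: (1) simulate or load the cohort; (2) per subject and band:
#' optional pre-clean hook, zero-phase band-pass of the continuous record,
#' guard-interval discard, epoch segmentation, PLV matrix; (3) sparsity
#' sweep and metric tables; (4) permutation group contrasts and
#' reaction-time correlations. All artifacts are written under
#' \code{config$out_dir}; a JSON report records the config, its hash, package
#' version, consumed seeds and warnings. Deterministic given the seed.
#'
#' @param config a [run_config()].
#' @param pre_clean optional function(recording) -> recording applied before
#'   filtering (artifact-removal hook; the package ships none).
#' @param verbose print stage progress.
#' @return invisibly, a list with the report, metric/nodal tables, stats
#'   results and PLV matrices.
#' @export
run_pipeline <- function(config, pre_clean = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- "setup"
  warnings_log <- character()
  note <- function(w) warnings_log <<- c(warnings_log, w)
  result <- withCallingHandlers(
    tryCatch({
      dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
      stage <- "input"
      if (is.null(config$input_dir)) {
        say("simulating cohort (%d subjects)", 2 * config$cohort$n_per_group)
        cohort_seeded <- config$cohort
        cohort_seeded$seed <- config$seed
        cohort <- simulate_cohort(cohort_seeded)
        input <- list(recordings = cohort$recordings, table = cohort$table)
        utils::write.table(cohort$table, file.path(config$out_dir, "cohort.tsv"),
                           sep = "\t", row.names = FALSE, quote = FALSE)
      } else {
        input <- load_input_dir(config$input_dir)
      }
      fs <- input$recordings[[1]]$sampling_rate_hz
      n_epochs <- config$n_epochs
      if (is.null(n_epochs)) {
        usable <- ncol(input$recordings[[1]]$data) / fs - 2 * config$guard_s
        n_epochs <- max(1L, floor(usable / config$epoch_length_s))
      }
      stage <- "connectivity"
      plv_dir <- file.path(config$out_dir, "plv")
      dir.create(plv_dir, showWarnings = FALSE)
      metric_rows <- list(); nodal_rows <- list(); plvs <- list()
      seeds_used <- list(master = config$seed)
      mont <- montage_1020(input$recordings[[1]]$channel_labels)
      for (si in seq_along(input$recordings)) {
        rec <- input$recordings[[si]]
        if (!is.null(pre_clean)) rec <- pre_clean(rec)
        seg_seed <- config$seed + 10000L + si
        seeds_used[[rec$subject_id]] <- seg_seed
        guard <- round(config$guard_s * fs)
        for (bn in names(config$bands)) {
          band <- config$bands[[bn]]
          filt <- bandpass(rec, band)
          if (guard > 0)
            filt$data <- filt$data[, (guard + 1):(ncol(filt$data) - guard),
                                   drop = FALSE]
          eps <- segment_epochs(filt, config$epoch_length_s, n_epochs,
                                seed = seg_seed,
                                contiguous = config$contiguous_epochs)
          pm <- plv_matrix(eps, aggregate = config$plv_aggregate)
          if (any(pm$mask))
            note(sprintf("%s/%s: %d masked PLV entries", rec$subject_id, bn,
                         sum(pm$mask)))
          write_plv_matrix(pm, file.path(plv_dir,
                                         paste0(rec$subject_id, "_", bn, ".tsv")))
          sw <- metric_sweep(pm, config$grid, mont)
          metric_rows[[length(metric_rows) + 1L]] <- sw$metrics
          nodal_rows[[length(nodal_rows) + 1L]] <- sw$nodal
          plvs[[paste0(rec$subject_id, "_", bn)]] <- pm
        }
        say("subject %s done (%d/%d)", rec$subject_id, si,
            length(input$recordings))
      }
      stage <- "network"
      metric_table <- do.call(rbind, metric_rows)
      metric_table <- cbind(
        metric_table[, "subject_id", drop = FALSE],
        group = input$table$group[match(metric_table$subject_id,
                                        input$table$subject_id)],
        metric_table[, setdiff(names(metric_table), "subject_id")])
      nodal_table <- do.call(rbind, nodal_rows)
      utils::write.table(metric_table, file.path(config$out_dir, "metrics.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      utils::write.table(nodal_table, file.path(config$out_dir, "nodal.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      stage <- "stats"
      stat_seed <- config$seed + 777L
      seeds_used$stats <- stat_seed
      contrasts <- group_contrast_sweep(metric_table, input$table, nodal_table,
                                        n_permutations = config$n_permutations,
                                        seed = stat_seed)
      rtcor <- rt_metric_correlations(metric_table, input$table)
      utils::write.table(contrasts$range_level,
                         file.path(config$out_dir, "stats_range.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      utils::write.table(contrasts$threshold_level,
                         file.path(config$out_dir, "stats_threshold.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      utils::write.table(contrasts$nodal,
                         file.path(config$out_dir, "stats_nodal.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      utils::write.table(rtcor, file.path(config$out_dir, "stats_rt_correlation.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      stage <- "report"
      cfg_ser <- paste(utils::capture.output(utils::str(config)), collapse = "\n")
      report <- list(
        package = "plvnet",
        version = as.character(utils::packageVersion("plvnet")),
        config_hash = fnv1a(cfg_ser),
        seed = config$seed,
        seeds_used = seeds_used,
        bands = names(config$bands),
        n_subjects = nrow(input$table),
        n_epochs = n_epochs,
        sparsity_grid = config$grid,
        n_permutations = config$n_permutations,
        plv_aggregate = config$plv_aggregate,
        warnings = warnings_log
      )
      jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      md <- c("# plvnet run report", "",
              sprintf("- config hash: %s", report$config_hash),
              sprintf("- seed: %d", config$seed),
              sprintf("- subjects: %d, bands: %s", report$n_subjects,
                      paste(report$bands, collapse = ", ")),
              sprintf("- epochs: %d x %g s, PLV aggregation: %s", n_epochs,
                      config$epoch_length_s, config$plv_aggregate),
              sprintf("- sparsity grid: %g..%g (%d values)", min(config$grid),
                      max(config$grid), length(config$grid)),
              sprintf("- permutations: %d", config$n_permutations),
              if (length(warnings_log)) c("", "## Warnings", warnings_log))
      writeLines(md, file.path(config$out_dir, "report.md"))
      list(report = report, metric_table = metric_table,
           nodal_table = nodal_table, contrasts = contrasts,
           rt_correlations = rtcor, plv = plvs, cohort_table = input$table)
    }, error = function(e) {
      stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
           call. = FALSE)
    }),
    warning = function(w) {
      note(conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  invisible(result)
}
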