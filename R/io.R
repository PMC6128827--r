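#' Read and write traces
#'
#' Traces are stored as tab-separated text with header columns `time_s`,
#' `force_pN`, `extension_nm` and optionally `state`, plus an optional JSON
#' metadata sidecar (`<path>.json`) carrying sampling rate, seed and
#' condition. Values round-trip to better than 1e-6; metadata round-trips
#' exactly. Reading validates the header and that time is strictly
#' increasing, naming the offending line otherwise.
#'
#' @param path File path (`.tsv`).
#' @param trace A `snare_trace` (or compatible data frame).
#' @return `read_trace()`: a `snare_trace`. `write_trace()`: the path,
#'   invisibly.
#' @export
read_trace <- function(path) {
  dat <- utils::read.delim(path, check.names = FALSE)
  req <- c("time_s", "force_pN", "extension_nm")
  if (!all(req %in% names(dat))) {
    abort(sprintf("malformed header in %s: need columns %s", path,
                  paste(req, collapse = ", ")))
  }
  bad <- which(diff(dat$time_s) <= 0)
  if (length(bad) > 0) {
    # +1 for the header, +1 for the second row of the offending pair
    abort(sprintf("non-monotonic time in %s at line %d", path, bad[1] + 2))
  }
  meta <- list()
  side <- paste0(path, ".json")
  if (file.exists(side)) meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  out <- tibble(time = dat$time_s, force = dat$force_pN,
                extension = dat$extension_nm)
  if ("state" %in% names(dat)) out$state <- dat$state
  new_snare_trace(out,
                  sampling_rate = meta$sampling_rate %||%
                    round(1 / median(diff(out$time))),
                  seed = meta$seed, condition = meta$condition)
}

#' @rdname read_trace
#' @param state Include the true-state column if present.
#' @param metadata Extra fields for the JSON sidecar.
#' @export
write_trace <- function(trace, path, state = TRUE, metadata = list()) {
  dat <- data.frame(time_s = sprintf("%.9g", trace$time),
                    force_pN = sprintf("%.9g", trace$force),
                    extension_nm = sprintf("%.9g", trace$extension))
  if (state && "state" %in% names(trace)) dat$state <- trace$state
  utils::write.table(dat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- c(list(sampling_rate = trace_sampling_rate(trace),
                 seed = attr(trace, "seed"),
                 condition = attr(trace, "condition")),
            metadata)
  meta <- meta[!vapply(meta, is.null, logical(1))]
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Generate a deterministic tree of simulated experiments
#'
#' Builds, under `dir`, one sub-directory per condition containing
#' force-ramp cycles (`ramp/`), force-jump dwell sets at several forces
#' (`jump/F<force>/`), and a constant-force equilibrium scan on the 0.2 pN
#' grid (`scan/`). The `smoke` scale (a few cycles, >= 5 dwells per force,
#' 2 s scans) completes in well under a minute; the `paper` scale uses
#' >= 19 dwells per force and > 15 s per grid force. The tree is a pure
#' function of the seed: rebuilding with the same seed gives a
#' byte-identical tree.
#'
#' @param dir Output directory (must be empty unless `overwrite`).
#' @param scale `"smoke"` or `"paper"`.
#' @param seed Integer master seed; per-file seeds are derived from it.
#' @param conditions Condition labels (see [cpx_conditions()]).
#' @param overwrite Allow writing into a non-empty directory.
#' @return The directory, invisibly; a `manifest.json` records the
#'   configuration and seeds.
#' @export
make_fixtures <- function(dir, scale = c("smoke", "paper"), seed = 1,
                          conditions = c("none", "WT"), overwrite = FALSE) {
  scale <- match.arg(scale)
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !overwrite) {
    abort(sprintf("output dir %s exists and is non-empty; use overwrite = TRUE", dir))
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- if (scale == "smoke") {
    list(n_ramp = 4, n_dwell = 5, jump_forces = c(14, 14.4),
         scan_seconds = 2, scan_forces = seq(13, 15, 0.5),
         dwell_cap_s = 30, rate_jump = 100, rate_scan = 1200)
  } else {
    list(n_ramp = 10, n_dwell = 19, jump_forces = c(13.8, 14, 14.2, 14.4),
         scan_seconds = 15.5, scan_forces = seq(12, 16, 0.2),
         dwell_cap_s = 300, rate_jump = 100, rate_scan = 1200)
  }
  con_model <- snare_construct()
  fseed <- function(...) (seed * 1000L + sum(c(...))) %% .Machine$integer.max

  for (ci in seq_along(conditions)) {
    cond <- conditions[ci]
    base <- file.path(dir, cond)
    two <- scheme_two_state(if (cond == "none") "none" else "cpx")
    attr(two, "condition") <- cond
    three <- scheme_three_state(cond)
    full <- scheme_ramp_cycle(if (cond == "none") "none" else "cpx")
    attr(full, "condition") <- cond

    ramp_dir <- file.path(base, "ramp")
    dir.create(ramp_dir, recursive = TRUE, showWarnings = FALSE)
    cycle <- force_protocol(protocol_ramp(0.5, 17, 1),
                            protocol_ramp(17, 0.5, 1),
                            protocol_hold(0.5, 3))
    for (i in seq_len(cfg$n_ramp)) {
      tr <- simulate_trace(full, cycle, con_model, sampling_rate = 100,
                           seed = fseed(ci * 101, i))
      write_trace(tr, file.path(ramp_dir, sprintf("cycle_%02d.tsv", i)))
    }

    for (f in cfg$jump_forces) {
      jd <- file.path(base, "jump", sprintf("F%04.1f", f))
      dir.create(jd, recursive = TRUE, showWarnings = FALSE)
      prot <- force_protocol(protocol_hold(10, 0.5), protocol_jump(10, f),
                             protocol_hold(f, cfg$dwell_cap_s))
      for (i in seq_len(cfg$n_dwell)) {
        tr <- simulate_trace(two, prot,
                             extension = c(zippered = 0, unzipped = 25),
                             sampling_rate = cfg$rate_jump,
                             seed = fseed(ci * 211, round(f * 10), i))
        write_trace(tr, file.path(jd, sprintf("trace_%02d.tsv", i)))
      }
    }

    sc_dir <- file.path(base, "scan")
    dir.create(sc_dir, recursive = TRUE, showWarnings = FALSE)
    offs <- c(fully_zippered = 0, linker_open = 5.3, half_zippered = 13.0)
    for (f in cfg$scan_forces) {
      tr <- simulate_trace(three, protocol_hold(f, cfg$scan_seconds) |>
                             force_protocol(),
                           extension = offs,
                           sampling_rate = cfg$rate_scan,
                           seed = fseed(ci * 307, round(f * 10)))
      write_trace(tr, file.path(sc_dir, sprintf("F%04.1f.tsv", f)))
    }
  }
  manifest <- list(scale = scale, seed = seed, conditions = conditions,
                   config = cfg, package_version = "0.1.0")
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Assemble a machine-readable report from an experiment tree
#'
#' Runs the analysis stages over a [make_fixtures()]-style tree and writes
#' one summary table per figure-analog into `<dir>/report/`: ramp QC and
#' unzip-force summaries, per-force dwell/exponential fits, and equilibrium
#' population tables. Missing stage inputs yield a partial report with the
#' gaps listed explicitly. A run log records seeds and parameters; two runs
#' from the same tree differ only in the timestamp.
#'
#' @param dir An experiment directory produced by [make_fixtures()].
#' @return A list with `stages` (tibble of stage/condition status) and the
#'   summary objects, invisibly; files under `<dir>/report/`.
#' @export
report_experiment <- function(dir) {
  man_path <- file.path(dir, "manifest.json")
  manifest <- if (file.exists(man_path)) {
    jsonlite::read_json(man_path, simplifyVector = TRUE)
  } else list(conditions = list.dirs(dir, recursive = FALSE, full.names = FALSE))
  rep_dir <- file.path(dir, "report")
  dir.create(rep_dir, showWarnings = FALSE)
  stages <- list()
  out <- list()

  for (cond in manifest$conditions) {
    base <- file.path(dir, cond)

    ramp_files <- list.files(file.path(base, "ramp"), pattern = "\\.tsv$",
                             full.names = TRUE)
    if (length(ramp_files) > 0) {
      ev <- purrr::map(ramp_files, function(p) {
        detect_steps(read_trace(p), min_step = 3) |>
          mutate(file = basename(p))
      }) |> list_rbind()
      qc <- qc_signature(ev)
      unzips <- ev |> filter(.data$direction == "unzip")
      summ <- if (nrow(unzips) > 0) {
        transition_force_histogram(unzips)$summary
      } else tibble(mean = NA_real_, sd = NA_real_, n = 0L)
      utils::write.table(ev, file.path(rep_dir, paste0("ramp_events_", cond, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      out[[paste0("ramp_", cond)]] <- list(events = ev, qc = qc,
                                           unzip_summary = summ)
      stages[[length(stages) + 1]] <-
        tibble(condition = cond, stage = "ramp", status = "complete")
    } else {
      stages[[length(stages) + 1]] <-
        tibble(condition = cond, stage = "ramp", status = "absent")
    }

    jump_dirs <- list.dirs(file.path(base, "jump"), recursive = FALSE)
    if (length(jump_dirs) > 0) {
      fits <- purrr::map(jump_dirs, function(jd) {
        f <- as.numeric(sub("^F", "", basename(jd)))
        traces <- purrr::map(list.files(jd, pattern = "\\.tsv$",
                                        full.names = TRUE), read_trace)
        dw <- extract_latencies(traces, target_force = f)
        fit <- tryCatch(fit_exponential_mle(dw), error = function(e) NULL)
        if (is.null(fit)) return(NULL)
        tibble(force = f, rate = fit$rate, conf_low = fit$conf_low,
               conf_high = fit$conf_high, n = fit$n_uncensored,
               n_censored = fit$n_censored)
      }) |> purrr::compact() |> list_rbind()
      utils::write.table(fits, file.path(rep_dir, paste0("dwell_rates_", cond, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      out[[paste0("dwell_", cond)]] <- fits
      stages[[length(stages) + 1]] <-
        tibble(condition = cond, stage = "dwell", status = "complete")
    } else {
      stages[[length(stages) + 1]] <-
        tibble(condition = cond, stage = "dwell", status = "absent")
    }

    scan_files <- list.files(file.path(base, "scan"), pattern = "\\.tsv$",
                             full.names = TRUE)
    if (length(scan_files) > 0) {
      traces <- purrr::map(scan_files, read_trace)
      pt <- population_scan(
        traces,
        state_means = c(fully_zippered = 0, linker_open = 5.3,
                        half_zippered = 13.0),
        min_seconds = 2, seed = manifest$seed %||% 1)
      utils::write.table(pt, file.path(rep_dir, paste0("populations_", cond, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      out[[paste0("scan_", cond)]] <- pt
      stages[[length(stages) + 1]] <-
        tibble(condition = cond, stage = "scan", status = "complete")
    } else {
      stages[[length(stages) + 1]] <-
        tibble(condition = cond, stage = "scan", status = "absent")
    }
  }

  stages <- list_rbind(stages)
  utils::write.table(stages, file.path(rep_dir, "stages.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
         seed = manifest$seed, scale = manifest$scale,
         conditions = manifest$conditions,
         package_version = as.character(utils::packageVersion("snarezip"))),
    file.path(rep_dir, "run_log.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(stages = stages, summaries = out))
}
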