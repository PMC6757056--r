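# Pipeline orchestration: simulate -> count -> quantify -> facsfit -> seqfun
# with a single config and a machine-readable run report.

#' Build a pipeline run configuration
#'
#' @param template a `library_template` (or `NULL` to build the default
#'   N4+N5 design from `aptamer`).
#' @param aptamer aptamer sequence used when `template` is `NULL`.
#' @param controls control sequence set ([control_ribozyme()] rows);
#'   default the simulator's spike-ins.
#' @param control_name normalizing control (default `"sTRSVctl"`).
#' @param min_dna DNA coverage threshold (default 100).
#' @param percentile top-set percentile (default 95).
#' @param q contribution percentile (default 5).
#' @param min_support pairwise-contribution support floor (default 5).
#' @param sided t-test sidedness (default `"two"`).
#' @param allow_fallback permit top-25 normalization when the control is
#'   missing (default TRUE).
#' @param sim a `sim_config` when simulation is requested, else `NULL`.
#' @param out_dir optional directory for stage outputs (TSV/JSON).
#' @return list of class `run_config`.
#' @export
run_config <- function(template = NULL, aptamer = "GGCAGC",
                       controls = sim_control_sequences(),
                       control_name = "sTRSVctl", min_dna = 100,
                       percentile = 95, q = 5, min_support = 5,
                       sided = c("two", "one"), allow_fallback = TRUE,
                       sim = NULL, out_dir = NULL) {
  sided <- match.arg(sided)
  stopifnot(min_dna >= 0, percentile > 0, percentile < 100, q > 0, q < 100,
            min_support >= 0)
  if (is.null(template)) {
    template <- build_switch_template(aptamer, "loopI", c(4, 5))
  }
  structure(list(template = template, controls = controls,
                 control_name = control_name, min_dna = min_dna,
                 percentile = percentile, q = q, min_support = min_support,
                 sided = sided, allow_fallback = allow_fallback,
                 sim = sim, out_dir = out_dir),
            class = "run_config")
}

#' Run the analysis pipeline end to end
#'
#' Stages: (optionally) simulate ground truth and counts, apply the DNA
#' coverage filter, quantify RD / activation ratios / significance, fit the
#' sort-seq data, and run per-length sequence-function summaries. Stage
#' timings, filter totals and the control's RD (which must be 100) are
#' recorded in the run report.
#'
#' @param config a `run_config`; `config$sim` must be set (simulation-backed
#'   run) unless `counts` is supplied.
#' @param counts optional pre-computed `count_table` (skips simulation).
#' @param facs optional pre-computed `binned_sort_data`.
#' @return list with `activity`, `facs_fits`, `seqfun`, `truth` (when
#'   simulated) and `report`.
#' @export
run_pipeline <- function(config, counts = NULL, facs = NULL) {
  stopifnot(inherits(config, "run_config"))
  report <- list(stages = list(), warnings = character())
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- expr
    report$stages[[name]] <<- list(seconds = proc.time()[["elapsed"]] - t0)
    val
  }
  truth <- NULL
  if (is.null(counts)) {
    if (is.null(config$sim)) stop("no counts supplied and no sim config set")
    truth <- t_stage("simulate_truth", simulate_ground_truth(config$sim))
    counts <- t_stage("simulate_counts", simulate_counts(truth, config$sim))
    if (is.null(facs)) {
      facs <- t_stage("simulate_facs", simulate_facs(truth, config$sim))
    }
  }
  filtered <- t_stage("filter", filter_min_dna(counts, config$min_dna))
  report$filter <- attr(filtered, "filter_log")

  has_control <- config$control_name %in% rownames(filtered$counts)
  if (!has_control && !config$allow_fallback) {
    stop("control '", config$control_name,
         "' absent and fallback normalization disabled")
  }
  activity <- t_stage("quantify",
                      quantify_activity(filtered, control = config$control_name,
                                        sided = config$sided))
  report$normalization <- attr(activity, "normalization")[c("control",
                                                            "control_used")]
  ctl_rd <- activity[activity$variant == config$control_name,
                     c("rd_minus", "rd_plus")]
  report$control_rd <- if (nrow(ctl_rd)) as.list(ctl_rd) else NULL

  facs_fits <- NULL
  if (!is.null(facs)) {
    facs_fits <- t_stage("facsfit", fit_facs_bins(facs))
    ctl <- config$controls
    if (!is.null(ctl) && "reference_rfu" %in% names(ctl) &&
        sum(!is.na(ctl$reference_rfu)) >= 2L &&
        all(ctl$name %in% facs_fits$variant)) {
      known <- data.frame(name = ctl$name,
                          log10_fluor = log10(ctl$reference_rfu))
      known <- known[is.finite(known$log10_fluor), ]
      facs_fits <- t_stage("calibrate",
                           calibrate_and_normalize(facs_fits, known,
                                                   reference = config$control_name))
    }
  }

  sf <- t_stage("seqfun", {
    lib <- activity[!activity$is_control & is.finite(activity$log10_rd_minus), ]
    by_len <- split(lib, nchar(lib$variant))
    lapply(by_len, function(d) {
      if (nrow(d) < 3L || length(unique(d$log10_rd_minus)) < 2L) return(NULL)
      z <- standardize(d$log10_rd_minus)
      list(n = nrow(d),
           binning = assign_activity_bins(z),
           entropy = position_entropy(d$variant)$entropy,
           mi = mutual_information(d$variant)$mi,
           contribution = pairwise_percentile_contribution(
             d$variant, z, q = config$q, min_support = config$min_support))
    })
  })

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_activity_table(activity, file.path(config$out_dir, "activity.tsv"))
    write_count_table(filtered, file.path(config$out_dir, "counts.tsv"))
    if (!is.null(facs_fits)) {
      utils::write.table(facs_fits, file.path(config$out_dir, "facs_fits.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  list(activity = activity, facs_fits = facs_fits, seqfun = sf,
       truth = truth, counts = filtered, facs = facs, report = report)
}

#' Command-line entry point
#'
#' Thin dispatcher over the pipeline stages; intended to be called from an
#' Rscript wrapper as `switchseq_cli(commandArgs(trailingOnly = TRUE))`.
#' Subcommands: `simulate` (seeded end-to-end simulation run writing stage
#' outputs), `quantify` (counts TSV -> activity TSV), `facsfit` (bin TSV +
#' sidecar -> fit TSV).
#'
#' @param args character vector of CLI arguments.
#' @return invisibly, the result object of the subcommand.
#' @export
switchseq_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: switchseq <simulate|quantify|facsfit> [options]",
    "  simulate --seed INT --out DIR [--n-variants N] [--depth N]",
    "  quantify --counts FILE --out FILE [--control NAME] [--sided two|one]",
    "  facsfit  --bins FILE --out FILE", sep = "\n")
  if (length(args) < 1L) stop(usage, call. = FALSE)
  cmd <- args[1L]
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) == 1L && i < length(args)) args[i + 1L] else default
  }
  res <- switch(
    cmd,
    simulate = {
      seed <- as.integer(opt("--seed"))
      out <- opt("--out")
      if (is.na(seed) || is.null(out)) stop(usage, call. = FALSE)
      nv <- opt("--n-variants"); depth <- opt("--depth")
      sim <- sim_config(
        n_variants = if (is.null(nv)) NULL else as.integer(nv),
        depth_dna = if (is.null(depth)) 1e6 else as.numeric(depth),
        depth_rna = if (is.null(depth)) 1e6 else as.numeric(depth),
        seed = seed)
      run_pipeline(run_config(sim = sim, out_dir = out))
    },
    quantify = {
      counts <- opt("--counts"); out <- opt("--out")
      if (is.null(counts) || is.null(out)) stop(usage, call. = FALSE)
      act <- quantify_activity(read_count_table(counts),
                               control = opt("--control", "sTRSVctl"),
                               sided = opt("--sided", "two"))
      write_activity_table(act, out)
      act
    },
    facsfit = {
      bins <- opt("--bins"); out <- opt("--out")
      if (is.null(bins) || is.null(out)) stop(usage, call. = FALSE)
      fits <- fit_facs_bins(read_binned_sort_data(bins))
      utils::write.table(fits, out, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      fits
    },
    stop(usage, call. = FALSE)
  )
  invisible(res)
}
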