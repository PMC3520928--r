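# Stage orchestration: synth -> label -> freeenergy -> network/chevron ->
# flux, driven by a plain key=value config, with a reproducibility manifest.

#' Read / write a run configuration
#'
#' Plain-text `key = value` format, one pair per line, `#` comments.
#' Vector values are comma-separated. Recognized keys (with defaults):
#' `n_foldons` (4), `epsilon` (2), `entropy` (1.5), `coupling` (1),
#' `n_windows` (5), `n_frames` (5000), `kappa` (10), `sim_temperature` (1),
#' `threshold` (0.6), `k0` (1e6), `temperatures` (grid for the chevron),
#' `target_temperature`, `gauge` ("unfolded"), `seed` (1), `min_width`
#' (0.1), `out_dir` ("."), plus optional `structure_pdb`, `chain`,
#' `foldon_lengths`, `cutoff` (9.5), `min_seq_sep` (3), `sigma0` (1),
#' `sigma_exp` (0.15), `windows_files` (precomputed frame tables).
#'
#' @param path Config file path.
#' @return A named list of class `run_config` with validated fields.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, integer(1)) < 2L
  if (any(bad)) stop("malformed config line: ", lines[bad][1L], call. = FALSE)
  keys <- trimws(vapply(kv, `[[`, character(1), 1L))
  vals <- trimws(vapply(kv, function(x) paste(x[-1L], collapse = "="),
                        character(1)))
  cfg <- stats::setNames(as.list(vals), keys)
  validate_run_config(cfg)
}

#' @noRd
validate_run_config <- function(cfg) {
  num <- function(key, default) {
    v <- cfg[[key]]
    if (is.null(v)) return(default)
    out <- suppressWarnings(as.numeric(strsplit(as.character(v), ",")[[1]]))
    if (any(is.na(out))) stop("config key '", key, "' is not numeric",
                              call. = FALSE)
    out
  }
  chr <- function(key, default) as.character(cfg[[key]] %||% default)
  out <- list(
    n_foldons = as.integer(num("n_foldons", 4)),
    epsilon = num("epsilon", 2),
    entropy = num("entropy", 1.5),
    coupling = num("coupling", 1),
    n_windows = as.integer(num("n_windows", 5)),
    n_frames = as.integer(num("n_frames", 5000)),
    kappa = num("kappa", 10),
    sim_temperature = num("sim_temperature", 1),
    threshold = num("threshold", 0.6),
    k0 = num("k0", 1e6),
    temperatures = num("temperatures", seq(0.85, 1.25, by = 0.05)),
    target_temperature = num("target_temperature", NA_real_),
    gauge = chr("gauge", "unfolded"),
    seed = as.integer(num("seed", 1)),
    min_width = num("min_width", 0.1),
    cutoff = num("cutoff", 9.5),
    min_seq_sep = as.integer(num("min_seq_sep", 3)),
    sigma0 = num("sigma0", 1),
    sigma_exp = num("sigma_exp", 0.15),
    out_dir = chr("out_dir", ".")
  )
  if (is.na(out$target_temperature)) {
    out$target_temperature <- out$sim_temperature[1L]
  }
  with(out, {
    stopifnot(n_foldons >= 1, n_foldons <= 14,
              threshold > 0, threshold < 1,
              k0 > 0, n_windows >= 1, n_frames >= 100,
              all(temperatures > 0), min_width > 0, cutoff > 0,
              min_seq_sep >= 1)
  })
  class(out) <- "run_config"
  out
}

#' @rdname read_run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  keys <- setdiff(names(config), "class")
  lines <- vapply(keys, function(k) {
    paste0(k, " = ", paste(config[[k]], collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Run the pipeline stages
#'
#' Executes the requested stages in dependency order against the synthetic
#' landscape described by `config`: `synth` writes the umbrella-window
#' frame tables; `label` writes per-frame macrobasin labels; `freeenergy`
#' solves MBAR and writes one free-energy table per temperature; `network`
#' writes the rate matrix at the target temperature; `chevron` writes the
#' thermal chevron TSV; `flux` writes the folding flux table and DOT
#' diagram. A JSON manifest with parameters, seeds, and MD5 hashes of every
#' output is written at the end; identical configs and seeds give
#' byte-identical outputs.
#'
#' @param config A `run_config` (or path to one).
#' @param stages Subset of `c("synth", "label", "freeenergy", "network",
#'   "chevron", "flux")`; dependencies must be included or have been run
#'   into `config$out_dir` previously.
#' @return Invisibly, the manifest as a list.
#' @export
run_pipeline <- function(config,
                         stages = c("synth", "label", "freeenergy",
                                    "network", "chevron", "flux")) {
  if (is.character(config)) config <- read_run_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(config$out_dir, ...)
  outputs <- character(0)
  t_start <- proc.time()[["elapsed"]]
  log_stage <- function(name, t0) {
    message(sprintf("[foldkin] stage %-10s %.2fs", name,
                    proc.time()[["elapsed"]] - t0))
  }
  need <- function(path, stage, dep) {
    if (!file.exists(path)) {
      stop("stage '", stage, "' needs output of stage '", dep,
           "' (missing ", path, ")", call. = FALSE)
    }
    path
  }

  land <- synthetic_landscape(config$n_foldons, config$epsilon,
                              config$entropy, config$coupling, config$seed)
  qcols <- paste0("q_", seq_len(config$n_foldons))

  if ("synth" %in% stages) {
    t0 <- proc.time()[["elapsed"]]
    proto <- umbrella_protocol(config$n_windows, config$n_frames,
                               config$sim_temperature[1L], config$kappa)
    wins <- sample_umbrella_windows(land, proto,
                                    threshold = config$threshold,
                                    seed = config$seed)
    for (w in wins) {
      f <- p(sprintf("window_%02d.tsv", w$window_id))
      write_frame_table(w$frames, f)
      outputs <- c(outputs, f)
    }
    cfg_out <- config
    cfg_out$out_dir <- NULL  # path-free so reruns elsewhere are identical
    write_run_config(cfg_out, p("run_config.txt"))
    outputs <- c(outputs, p("run_config.txt"))
    log_stage("synth", t0)
  }

  load_windows <- function(stage) {
    files <- sort(list.files(config$out_dir, "^window_[0-9]+\\.tsv$",
                             full.names = TRUE))
    if (length(files) == 0L) {
      stop("stage '", stage, "' needs output of stage 'synth' ",
           "(no window_*.tsv in ", config$out_dir, ")", call. = FALSE)
    }
    proto <- umbrella_protocol(length(files), config$n_frames,
                               config$sim_temperature[1L], config$kappa)
    lapply(seq_along(files), function(i) {
      fr <- utils::read.delim(files[i])
      window_samples(i, proto$q0[i], proto$kappa[i], proto$temperature[i],
                     fr)
    })
  }

  if ("label" %in% stages) {
    t0 <- proc.time()[["elapsed"]]
    wins <- load_windows("label")
    lab <- do.call(rbind, lapply(wins, function(w) {
      lt <- label_trajectory(as.matrix(w$frames[, qcols]), config$threshold)
      data.frame(window_id = w$window_id, frame = w$frames$frame,
                 label = lt$labels, stringsAsFactors = FALSE)
    }))
    utils::write.table(lab, p("labels.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    outputs <- c(outputs, p("labels.tsv"))
    log_stage("label", t0)
  }

  if ("freeenergy" %in% stages) {
    t0 <- proc.time()[["elapsed"]]
    wins <- load_windows("freeenergy")
    labfile <- need(p("labels.tsv"), "freeenergy", "label")
    labels <- utils::read.delim(labfile,
                                colClasses = c(label = "character"))$label
    fit <- mbar_solve(wins)
    for (Tt in config$temperatures) {
      tab <- macrobasin_free_energies(fit, labels, Tt, config$gauge)
      f <- p(sprintf("free_energies_T%.4f.tsv", Tt))
      write_free_energy_table(tab, f)
      outputs <- c(outputs, f)
    }
    log_stage("freeenergy", t0)
  }

  load_table <- function(Tt, stage) {
    f <- need(p(sprintf("free_energies_T%.4f.tsv", Tt)), stage, "freeenergy")
    read_free_energy_table(f)
  }

  if ("network" %in% stages) {
    t0 <- proc.time()[["elapsed"]]
    tab <- load_table(config$target_temperature, "network")
    K <- build_rate_matrix(tab, config$k0)
    write_rate_matrix(K, p("rate_matrix.tsv"))
    outputs <- c(outputs, p("rate_matrix.tsv"))
    log_stage("network", t0)
  }

  if ("chevron" %in% stages) {
    t0 <- proc.time()[["elapsed"]]
    tabs <- lapply(config$temperatures, load_table, stage = "chevron")
    ch <- chevron_scan(tabs, config$k0)
    utils::write.table(as.data.frame(ch), p("chevron.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    outputs <- c(outputs, p("chevron.tsv"))
    log_stage("chevron", t0)
  }

  if ("flux" %in% stages) {
    t0 <- proc.time()[["elapsed"]]
    tab <- load_table(config$target_temperature, "flux")
    K <- build_rate_matrix(tab, config$k0)
    dec <- spectral_solve(K)
    unf <- strrep("0", config$n_foldons)
    if (!unf %in% rownames(K)) {
      stop("stage 'flux': fully unfolded macrobasin unsampled", call. = FALSE)
    }
    P0 <- stats::setNames(as.numeric(rownames(K) == unf), rownames(K))
    J <- cumulative_flux(dec, K, P0, tau = Inf)
    write_flux_table(J, p("flux.tsv"))
    writeLines(export_flux_dot(J, tab, config$min_width, "folding"),
               p("flux_folding.dot"))
    outputs <- c(outputs, p("flux.tsv"), p("flux_folding.dot"))
    log_stage("flux", t0)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("foldkin")),
    stages = stages,
    parameters = unclass(config),
    seed = config$seed,
    outputs = lapply(stats::setNames(nm = basename(outputs)), function(b) {
      unname(tools::md5sum(file.path(config$out_dir, b)))
    }),
    elapsed_seconds = round(proc.time()[["elapsed"]] - t_start, 3)
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
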