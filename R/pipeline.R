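#' Pipeline run configuration
#'
#' Bundles everything one end-to-end run needs: a [phantom_spec()] (or paths
#' to pre-existing inputs), the acquisition protocol, stage toggles and the
#' statistical options whose choice the output metadata must record.
#'
#' @param spec A [phantom_spec()], or `NULL` when `inputs` supplies files.
#' @param out_dir Output directory (created if missing).
#' @param flip_deg Flip angles of the VFA protocol.
#' @param timepoints Post-contrast time points to process.
#' @param downsample Block-downsampling factors (1..8 each).
#' @param min_block_fraction Minimum in-mask fraction to keep a block.
#' @param summary_stat Region summary statistic, `"median"` or `"mean"`.
#' @param relaxivity Relaxivity used for [Mn] estimation; defaults to the
#'   spec's value.
#' @param stages Named logical list toggling `phantom`, `mr`, `pet`,
#'   `multimodal`, `exvivo`, `secretion`.
#' @param inputs Optional named list of file paths used instead of the
#'   phantom generator: `labels`, `vfa` (nested list
#'   `vfa$pre`/`vfa[[timepoint]]`, each a character vector of per-angle
#'   NIfTI paths), `pet` (per-timepoint NIfTI), `secretion` (CSV).
#' @param seed Overrides the spec's `rng_seed` when not `NULL`.
#' @return Validated list of class `run_config`.
#' @export
pipeline_config <- function(spec = phantom_spec(),
                            out_dir = file.path(tempdir(), "memripet-run"),
                            flip_deg = c(4, 22),
                            timepoints = c("1h", "24h"),
                            downsample = c(2, 2, 2),
                            min_block_fraction = 0.5,
                            summary_stat = c("median", "mean"),
                            relaxivity = NULL,
                            stages = list(),
                            inputs = NULL,
                            seed = NULL) {
  summary_stat <- match.arg(summary_stat)
  def <- list(phantom = TRUE, mr = TRUE, pet = TRUE, multimodal = TRUE,
              exvivo = TRUE, secretion = TRUE)
  def[names(stages)] <- stages
  if (!is.null(spec) && !is.null(seed)) spec$rng_seed <- as.integer(seed)
  cfg <- structure(list(spec = spec, out_dir = out_dir,
                        flip_deg = flip_deg, timepoints = timepoints,
                        downsample = downsample,
                        min_block_fraction = min_block_fraction,
                        summary_stat = summary_stat,
                        relaxivity = relaxivity %||%
                          (if (!is.null(spec)) spec$relaxivity_r1 else NULL),
                        stages = def, inputs = inputs,
                        seed = if (!is.null(spec)) spec$rng_seed
                               else as.integer(seed %||% 0L)),
                   class = "run_config")
  validate_run_config(cfg)
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_run_config <- function(cfg) {
  st <- cfg$stages
  if (is.null(cfg$spec) && is.null(cfg$inputs))
    stop("configuration error: neither a phantom spec nor input paths given")
  if (is.null(cfg$spec)) {
    inp <- cfg$inputs
    check_file <- function(p, what) {
      if (is.null(p))
        stop(sprintf("configuration error: %s missing", what))
      if (!all(file.exists(unlist(p))))
        stop(sprintf("configuration error: %s file does not exist", what))
    }
    if (st$mr) {
      check_file(inp$vfa$pre, "pre-contrast VFA stack")
      for (tp in cfg$timepoints)
        check_file(inp$vfa[[tp]],
                   sprintf("post-contrast VFA stack for timepoint '%s'", tp))
    }
    if (st$pet)
      for (tp in cfg$timepoints)
        check_file(inp$pet[[tp]], sprintf("PET volume for timepoint '%s'", tp))
    if (st$mr) check_file(inp$labels, "VOI/label volume")
    if (st$secretion) check_file(inp$secretion, "secretion table")
  }
  if (st$multimodal && !(st$mr && st$pet))
    stop("configuration error: multimodal stage needs the MR and PET stages")
  invisible(cfg)
}

config_hash <- function(cfg) {
  f <- tempfile(fileext = ".rds")
  on.exit(unlink(f))
  # strip the out_dir so the hash identifies the scientific configuration
  cfg$out_dir <- NULL
  saveRDS(cfg, f, version = 2)
  unname(tools::md5sum(f))
}

write_table_stamped <- function(df, path, seed, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# memripet seed=%d config=%s", seed, hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Run the full phantom-to-report pipeline
#'
#' Generates (or loads) the multimodal dataset, fits T1 and converts to
#' filtered R1 maps, estimates manganese concentrations, computes
#' decay-corrected %ID/mL maps, correlates PET against MR voxel-wise on
#' block-downsampled VOI values and region-wise, quantifies the ex vivo
#' sections, and summarizes the secretion assay. All stage outputs are
#' written under `config$out_dir` (NIfTI volumes, TIFF sections, CSV
#' tables stamped with the seed and configuration hash, and a JSON run
#' log); deterministic stages are bit-identical across re-runs of the same
#' configuration.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a report list: correlation results per time point,
#'   the region summary table, the 24 h region-mean [Mn] index, islet
#'   tables and regressions, enrichment scores, the secretion summary, file
#'   paths, seed and configuration hash.
#' @export
run_pipeline <- function(config) {
  validate_run_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  seed <- config$seed
  st <- config$stages
  acq <- acquisition_params(flip_deg = config$flip_deg)
  report <- list(seed = seed, config_hash = hash, paths = character())
  tps <- config$timepoints
  run_stage <- function(name, expr) {
    tryCatch(force(expr), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  out <- function(...) {
    p <- file.path(config$out_dir, sprintf(...))
    report$paths <<- c(report$paths, p)
    p
  }

  # ---- phantom / input loading ----
  labels <- vfa <- pet_act <- sections <- secretion_tab <- NULL
  if (!is.null(config$spec)) {
    run_stage("phantom", {
      spec <- config$spec
      labels <- build_label_map(spec)
      write_volume(image_volume(array(as.numeric(labels$labels),
                                      dim = dim(labels$labels)),
                                labels$voxel_size_mm, "label"),
                   out("labels.nii"))
      vfa <- c(list(pre = simulate_vfa_stacks(labels, spec, "pre", acq)),
                stats::setNames(lapply(tps, function(tp)
                  simulate_vfa_stacks(labels, spec, tp, acq)), tps))
      for (tp in names(vfa))
        for (an in names(vfa[[tp]]))
          write_volume(vfa[[tp]][[an]], out("vfa_%s_%s.nii", tp, an))
      pet_act <- stats::setNames(lapply(tps, function(tp)
        simulate_pet_volume(labels, spec, tp)), tps)
      for (tp in tps) write_volume(pet_act[[tp]], out("pet_%s.nii", tp))
      if (st$exvivo) {
        sections <- stats::setNames(lapply(tps, function(tp)
          simulate_section(labels, spec, tp)), tps)
        for (tp in tps) {
          write_section(sections[[tp]]$autorad, out("autorad_%s.tif", tp))
          for (iso in names(sections[[tp]]$elemental))
            write_section(sections[[tp]]$elemental[[iso]],
                          out("msi_%s_%s.tif", iso, tp))
        }
      }
      if (st$secretion) {
        secretion_tab <- simulate_secretion(seed = spec$rng_seed)
        write_secretion(secretion_tab, out("secretion.csv"))
      }
    })
  } else {
    run_stage("load-inputs", {
      inp <- config$inputs
      lv <- read_volume(inp$labels)
      labels <- structure(list(labels = array(as.integer(round(lv$data)),
                                               dim = dim(lv$data)),
                                voxel_size_mm = lv$voxel_size_mm),
                           class = "label_volume")
      vfa <- lapply(inp$vfa, function(paths) lapply(paths, read_volume))
      pet_act <- lapply(inp$pet, read_volume)
      if (st$secretion) secretion_tab <- read_secretion(inp$secretion)
    })
  }

  frame_h <- c(pre = 0, `1h` = 1, `24h` = 24)
  voi <- pancreas_mask(labels)

  # ---- MR quantification ----
  r1 <- NULL
  if (st$mr) run_stage("mr", {
    r1 <- lapply(vfa, function(stacks) t1_to_r1(fit_t1_vfa(stacks, acq)))
    report$r1_excluded <- vapply(r1, function(x) x$n_filtered, numeric(1))
    mn_maps <- lapply(tps, function(tp)
      suppressWarnings(estimate_mn(r1$pre, r1[[tp]], config$relaxivity)))
    names(mn_maps) <- tps
    report$mn_voxelwise_median_mM <- vapply(mn_maps, function(m)
      stats::median(m$mn_mM[m$validity & voi]), numeric(1))
    if ("24h" %in% tps)
      report$mn_region_24h_mM <- as.numeric(
        estimate_mn(r1$pre, r1[["24h"]], config$relaxivity,
                    mode = "region_mean_24h",
                    voi_pre = voi & r1$pre$validity,
                    voi_post = voi & r1[["24h"]]$validity))
  })

  # ---- PET quantification ----
  pid <- NULL
  if (st$pet) run_stage("pet", {
    dose <- if (!is.null(config$spec)) config$spec$injected_dose_kBq
            else config$inputs$injected_dose_kBq
    pid <- stats::setNames(lapply(tps, function(tp)
      percent_id_per_ml(pet_act[[tp]], dose, frame_h[[tp]])), tps)
  })

  # ---- multimodal correlation and region summary ----
  if (st$multimodal) run_stage("multimodal", {
    sstat <- if (config$summary_stat == "median") stats::median else mean
    cors <- list(); region_rows <- list()
    for (tp in tps) {
      blocks <- downsample_blocks(list(pid = pid[[tp]]$pid_per_ml,
                                       r1 = r1[[tp]]$r1_s_inv),
                                  voi & r1[[tp]]$validity,
                                  config$downsample,
                                  config$min_block_fraction)
      cors[[tp]] <- correlate_pet_mr(blocks$pid, blocks$r1,
                                     level = "voxelwise",
                                     transform = "log10")
      regions <- list(pancreas = voi)
      if (any(labels$labels == 3L))
        regions$insulinoma <- labels$labels == 3L
      for (rn in names(regions)) {
        rmask <- regions[[rn]] & r1[[tp]]$validity
        region_rows[[paste(rn, tp)]] <- data.frame(
          region = rn, timepoint = tp,
          summary_stat = config$summary_stat,
          log10_pid = sstat(log10(pmax(pid[[tp]]$pid_per_ml[rmask],
                                       .Machine$double.xmin))),
          log10_r1 = sstat(log10(r1[[tp]]$r1_s_inv[rmask])),
          n_voxels = sum(rmask))
      }
    }
    report$correlations <- cors
    report$region_table <- do.call(rbind, c(region_rows,
                                             make.row.names = FALSE))
    write_table_stamped(report$region_table, out("region_summary.csv"),
                        seed, hash)
    cor_tab <- data.frame(timepoint = tps,
                          r = vapply(cors, function(x) x$r, numeric(1)),
                          p = vapply(cors, function(x) x$p, numeric(1)),
                          n = vapply(cors, function(x) x$n, numeric(1)),
                          transform = "log10", level = "voxelwise")
    write_table_stamped(cor_tab, out("correlations.csv"), seed, hash)
  })

  # ---- ex vivo ----
  if (st$exvivo && !is.null(sections)) run_stage("exvivo", {
    islets <- list(); enr <- list()
    for (tp in tps) {
      sec <- sections[[tp]]
      islets[[tp]] <- detect_islets(sec$autorad)
      write_table_stamped(islets[[tp]], out("islets_%s.csv", tp), seed, hash)
      imask <- sec$labels_msi == 2L | sec$labels_msi == 3L
      emask <- sec$labels_msi == 1L
      enr[[tp]] <- vapply(c("44Ca", "64Zn", "55Mn"), function(iso)
        islet_enrichment(sec$elemental[[iso]], imask, emask), numeric(1))
      rgb <- merge_elements(sec$elemental[["44Ca"]],
                            sec$elemental[["64Zn"]],
                            sec$elemental[["55Mn"]])
      tiff::writeTIFF(rgb / 255, out("merged_%s.tif", tp))
    }
    report$islets <- islets
    report$enrichment <- enr
    ok <- vapply(islets, nrow, integer(1)) >= 3
    if (any(ok)) {
      tp0 <- names(islets)[which(ok)[1]]
      report$islet_regression <- regress_signal_vs_diameter(islets[[tp0]])
    }
  })

  # ---- secretion ----
  if (st$secretion && !is.null(secretion_tab)) run_stage("secretion", {
    idx <- secretion_indexes(secretion_tab)
    report$secretion <- c(list(indexes = idx), summarize_secretion(idx))
    write_table_stamped(idx, out("secretion_indexes.csv"), seed, hash)
  })

  log_path <- file.path(config$out_dir, "run_log.json")
  jsonlite::write_json(list(seed = seed, config_hash = hash,
                            stages = st[unlist(st)],
                            outputs = basename(report$paths)),
                       log_path, auto_unbox = TRUE, pretty = TRUE)
  report$paths <- c(report$paths, log_path)
  class(report) <- "pipeline_report"
  invisible(report)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> seed %d, config %s\n", x$seed,
              substr(x$config_hash, 1, 8)))
  if (!is.null(x$correlations)) {
    for (tp in names(x$correlations)) {
      co <- x$correlations[[tp]]
      cat(sprintf("  %s voxelwise log10 PET-MR: r = %+.3f (p = %.3g, n = %d)\n",
                  tp, co$r, co$p, co$n))
    }
  }
  if (!is.null(x$enrichment))
    for (tp in names(x$enrichment))
      cat(sprintf("  %s enrichment Ca/Zn/Mn: %s\n", tp,
                  paste(sprintf("%.2f", x$enrichment[[tp]]), collapse = " / ")))
  if (!is.null(x$secretion)) {
    s <- x$secretion$summary
    cat(sprintf("  secretion index: %s\n",
                paste(sprintf("%s %.1f (n=%d)", s$group, s$mean, s$n),
                      collapse = ", ")))
  }
  cat(sprintf("  %d output files in run directory\n", length(x$paths)))
  invisible(x)
}
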