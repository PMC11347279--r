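# Config-driven orchestration of the analysis stages into a
# wildtype-vs-mutant comparison report.

.default_config <- function() {
  list(
    seed = 1L,
    output_dir = "channelgauge_out",
    preset = "null",
    n_frames = 60L,
    conditions = NULL,
    stages = list(rmsd = TRUE, rmsf = TRUE, cluster = TRUE, pore = TRUE,
                  ss = TRUE, angles = TRUE, sasa = TRUE, amd = TRUE),
    parameters = list(dz = 1, z_range = c(-12, 12), search_radius = 6,
                      stride = 5L, k_scan_max = 15L, plateau = 0.01,
                      sasa_threshold = 0.25, drift_window = 0.1,
                      a_dih = 3.5, dih_divisor = 5, b_total = 0.16,
                      anchor_quantile = 0.25))
}

#' Validate a pipeline configuration
#'
#' All problems are collected and returned together (not fail-fast):
#' unknown keys, non-positive slice spacing, bad scan ranges,
#' overlapping hinge/domain residue ranges, missing inputs for enabled
#' stages.
#'
#' @param config a list, or path to a YAML file.
#' @return list with `ok` (logical), `errors` (character vector) and
#'   `config` (the merged configuration with defaults filled in).
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  errors <- character(0)
  def <- .default_config()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown))
    errors <- c(errors, paste0("unknown config key(s): ",
                               paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(def, config[intersect(names(config), names(def))])
  unknown_p <- setdiff(names(cfg$parameters), names(def$parameters))
  if (length(unknown_p))
    errors <- c(errors, paste0("unknown parameter(s): ",
                               paste(unknown_p, collapse = ", ")))
  unknown_s <- setdiff(names(cfg$stages), names(def$stages))
  if (length(unknown_s))
    errors <- c(errors, paste0("unknown stage(s): ",
                               paste(unknown_s, collapse = ", ")))
  p <- cfg$parameters
  if (!is.numeric(p$dz) || p$dz <= 0)
    errors <- c(errors, "parameters$dz must be > 0")
  if (p$stride < 1) errors <- c(errors, "parameters$stride must be >= 1")
  if (p$plateau < 0) errors <- c(errors, "parameters$plateau must be >= 0")
  if (p$sasa_threshold <= 0 || p$sasa_threshold >= 1)
    errors <- c(errors, "parameters$sasa_threshold must be in (0, 1)")
  if (length(p$z_range) != 2L || p$z_range[2L] <= p$z_range[1L])
    errors <- c(errors, "parameters$z_range must be c(lo, hi) with hi > lo")
  if (is.null(cfg$preset) && is.null(cfg$conditions))
    errors <- c(errors, "either a preset or explicit conditions are required")
  if (!is.null(cfg$preset) &&
      !cfg$preset %in% c("null", "collapse", "hinge", "unfold",
                         "collapse+hinge+unfold"))
    errors <- c(errors, paste0("unknown preset: ", cfg$preset))
  if (isTRUE(cfg$stages$angles)) {
    doms <- synthetic_channel_domains()
    ok <- tryCatch({
      check_domain_disjoint(doms$hinge_PAS, doms$PAS, doms$TMD)
      check_domain_disjoint(doms$hinge_CNBD, doms$CNBD, doms$TMD)
      TRUE
    }, error = function(e) {
      errors <<- c(errors, conditionMessage(e))
      FALSE
    })
  }
  list(ok = length(errors) == 0L, errors = errors, config = cfg)
}

.config_hash <- function(cfg) {
  cfg$output_dir <- NULL      # the hash describes the analysis, not where it lands
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(utils::capture.output(utils::str(cfg)), f)
  unname(tools::md5sum(f))
}

.write_stage_csv <- function(df, path, hash, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# channelgauge ",
                      as.character(utils::packageVersion("channelgauge"))),
               paste0("# config_hash: ", hash),
               paste0("# seed: ", seed)), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Stages run per condition in dependency order (metrics, clustering,
#' then the independent pore / secondary-structure / angle / SASA / AMD
#' stages); a failing stage is marked failed and later independent
#' stages still run.  Every CSV output carries a provenance header
#' (package version, config hash, seed), and a rerun with the same
#' configuration is bit-identical.
#'
#' @param config list or YAML path (see [validate_config()]).
#' @return object of class `cg_report`: `summary` (per-condition
#'   metrics), `deltas` (each non-wildtype condition minus the first
#'   condition), `stage_status`, `output_dir`, `config`.
#' @export
run_pipeline <- function(config) {
  v <- validate_config(config)
  if (!v$ok) stop("invalid configuration:\n  - ",
                  paste(v$errors, collapse = "\n  - "))
  cfg <- v$config
  hash <- .config_hash(cfg)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  conds <- if (!is.null(cfg$conditions)) .load_conditions(cfg)
           else synth_preset(cfg$preset, seed = cfg$seed,
                             n_frames = cfg$n_frames)$conditions
  doms <- synthetic_channel_domains()
  motifs <- synthetic_channel_motifs()
  p <- cfg$parameters
  status <- list()
  summaries <- list()
  for (cname in names(conds)) {
    cond <- conds[[cname]]
    row <- list(condition = cname)
    run_stage <- function(stage, fn) {
      if (!isTRUE(cfg$stages[[stage]])) {
        status[[paste(cname, stage)]] <<- "disabled"
        return(NULL)
      }
      out <- tryCatch(fn(), error = function(e) {
        status[[paste(cname, stage)]] <<- paste("failed:", conditionMessage(e))
        NULL
      })
      if (!is.null(out)) status[[paste(cname, stage)]] <<- "ok"
      out
    }
    csvp <- function(stub) file.path(cfg$output_dir,
                                     paste0(cname, "_", stub, ".csv"))
    run_stage("rmsd", function() {
      r <- domain_rmsd(cond$channel, domain = doms$TMD, backbone_only = FALSE)
      .write_stage_csv(as.data.frame(r), csvp("rmsd_tmd"), hash, cfg$seed)
      row$rmsd_tmd_mean <<- mean(r$rmsd)
    })
    run_stage("rmsf", function() {
      pr <- rmsf_profile(cond$channel, sel = cg_selection())
      .write_stage_csv(as.data.frame(pr), csvp("rmsf"), hash, cfg$seed)
      row$rmsf_mean <<- mean(pr$rmsf)
    })
    run_stage("cluster", function() {
      nk <- floor((n_frames(cond$channel) - 1L) / p$stride)
      cl <- cluster_trajectory(cond$channel,
                               sel = domain_selection(doms$TMD),
                               k_scan = 2:min(p$k_scan_max, nk),
                               stride = p$stride, plateau = p$plateau)
      .write_stage_csv(cl$metrics, csvp("cluster_metrics"), hash, cfg$seed)
      .write_stage_csv(data.frame(frame = cl$distmat$frames,
                                  cluster = cl$labels),
                       csvp("cluster_labels"), hash, cfg$seed)
      row$chosen_k <<- cl$chosen_k
    })
    run_stage("pore", function() {
      axis <- cg_pore_axis(z_range = p$z_range, dz = p$dz)
      ts <- pore_timeseries(cond$channel, axis,
                            sel = domain_selection(doms$TMD),
                            search_radius = p$search_radius)
      .write_stage_csv(as.data.frame(ts), csvp("pore_profile"), hash, cfg$seed)
      .write_stage_csv(data.frame(frame = seq_along(ts$min_radius),
                                  min_radius = ts$min_radius,
                                  z_at_min = ts$min_z),
                       csvp("pore_min_radius"), hash, cfg$seed)
      row$pore_min_mean <<- mean(ts$min_radius)
    })
    run_stage("ss", function() {
      hp <- helix_propensity(cond$peptide)
      .write_stage_csv(as.data.frame(hp), csvp("helix_propensity"),
                       hash, cfg$seed)
      row$helix_propensity_mean <<- attr(hp, "domain_mean")
    })
    run_stage("angles", function() {
      tr <- list(list(dom = doms$PAS, hinge = doms$hinge_PAS,
                      tmd = doms$TMD, label = "PAS-hinge-TMD"),
                 list(dom = doms$CNBD, hinge = doms$hinge_CNBD,
                      tmd = doms$TMD, label = "CNBD-hinge-TMD"))
      as_ <- angle_timeseries(cond$channel, tr, window = p$drift_window)
      for (s in as_) {
        .write_stage_csv(data.frame(frame = seq_along(s$mean),
                                    time_ns = s$time_ns,
                                    angle_deg = s$mean),
                         csvp(paste0("angle_", gsub("[^A-Za-z]", "_",
                                                    s$label))),
                         hash, cfg$seed)
      }
      row$pas_angle_drift <<- as_[[1L]]$drift
      row$cnbd_angle_drift <<- as_[[2L]]$drift
    })
    run_stage("sasa", function() {
      me <- motif_exposure(cond$channel, motifs$interface,
                           threshold = p$sasa_threshold)
      .write_stage_csv(as.data.frame(me), csvp("motif_interface"),
                       hash, cfg$seed)
      row$interface_exposed_fraction <<- attr(me, "exposed_fraction")
    })
    run_stage("amd", function() {
      bp <- parameterize_dual_boost(cond$energies,
                                    n_atoms = n_atoms(cond$channel),
                                    n_residues = length(unique(
                                      cond$channel$topology$atoms$resid)),
                                    a_dih = p$a_dih,
                                    dih_divisor = p$dih_divisor,
                                    b_total = p$b_total)
      .write_stage_csv(data.frame(E_total = bp$E_total,
                                  alpha_total = bp$alpha_total,
                                  E_dih = bp$E_dih, alpha_dih = bp$alpha_dih),
                       csvp("amd_params"), hash, cfg$seed)
      row$amd_E_total <<- bp$E_total
    })
    summaries[[cname]] <- row
  }
  all_names <- unique(unlist(lapply(summaries, names)))
  summary_df <- do.call(rbind, lapply(summaries, function(r) {
    miss <- setdiff(all_names, names(r))
    for (m in miss) r[[m]] <- NA
    as.data.frame(r[all_names], stringsAsFactors = FALSE)
  }))
  rownames(summary_df) <- NULL
  deltas <- NULL
  if (nrow(summary_df) > 1L) {
    num <- vapply(summary_df, is.numeric, logical(1))
    ref <- summary_df[1L, num, drop = FALSE]
    deltas <- do.call(rbind, lapply(2:nrow(summary_df), function(i) {
      d <- summary_df[i, num, drop = FALSE] - ref
      d$condition <- paste0(summary_df$condition[i], " - ",
                            summary_df$condition[1L])
      d
    }))
    rownames(deltas) <- NULL
  }
  .write_stage_csv(summary_df, file.path(cfg$output_dir, "summary.csv"),
                   hash, cfg$seed)
  if (!is.null(deltas))
    .write_stage_csv(deltas, file.path(cfg$output_dir, "deltas.csv"),
                     hash, cfg$seed)
  structure(list(summary = summary_df, deltas = deltas,
                 stage_status = status, output_dir = cfg$output_dir,
                 config = cfg, config_hash = hash),
            class = "cg_report")
}

.load_conditions <- function(cfg) {
  lapply(cfg$conditions, function(cnd) {
    top <- read_structure(cnd$topology)
    out <- list(channel = read_trajectory(cnd$channel, top))
    if (!is.null(cnd$peptide_topology))
      out$peptide <- read_trajectory(cnd$peptide,
                                     read_structure(cnd$peptide_topology))
    if (!is.null(cnd$energies)) out$energies <- read_energy_series(cnd$energies)
    out
  })
}

#' @export
print.cg_report <- function(x, ...) {
  cat("cg_report:", nrow(x$summary), "condition(s); outputs in",
      x$output_dir, "\n")
  print(x$summary)
  if (!is.null(x$deltas)) {
    cat("deltas vs", x$summary$condition[1L], ":\n")
    print(x$deltas)
  }
  invisible(x)
}
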